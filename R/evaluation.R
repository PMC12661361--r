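#' Confusion counts for a binary task
#'
#' @param truth,pred Character vectors of true and predicted labels.
#' @param positive The positive-class label.
#' @param negative Optional negative-class label; default: everything else.
#' @return A list of class `"confusion_counts"`: `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion_counts(c("a", "a", "b"), c("a", "b", "b"), positive = "a")
#' @export
confusion_counts <- function(truth, pred, positive, negative = NULL) {
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  tpos <- truth == positive
  ppos <- pred == positive
  if (!is.null(negative)) {
    keep <- truth %in% c(positive, negative)
    tpos <- tpos[keep]; ppos <- ppos[keep]
  }
  structure(
    list(tp = sum(tpos & ppos), fp = sum(!tpos & ppos),
         tn = sum(!tpos & !ppos), fn = sum(tpos & !ppos)),
    class = "confusion_counts"
  )
}

#' Wald (normal-approximation) binomial confidence interval
#'
#' `p_hat +/- z * sqrt(p_hat (1 - p_hat) / n)`, clipped to \[0, 1\]. When
#' `p_hat` is exactly 0 or 1 the interval has zero width — the well-known
#' Wald pathology — and a warning is emitted unless suppressed.
#'
#' @param successes,trials Non-negative integers, `successes <= trials`,
#'   `trials >= 1`.
#' @param level Confidence level (default 0.95).
#' @param warn_degenerate Warn when the interval degenerates to a point.
#' @return Named numeric: `lower`, `upper`.
#' @examples
#' wald_ci(39, 40)  # lower bound 0.93 at two decimals
#' wald_ci(92, 93)  # lower bound 0.97 at two decimals
#' @export
wald_ci <- function(successes, trials, level = 0.95, warn_degenerate = TRUE) {
  if (trials < 1) stop("`trials` must be >= 1", call. = FALSE)
  if (successes < 0 || successes > trials) {
    stop("`successes` must be in [0, trials]", call. = FALSE)
  }
  p <- successes / trials
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / trials)
  if (half == 0 && warn_degenerate) {
    warning("Wald interval is degenerate (p-hat of 0 or 1)", call. = FALSE)
  }
  c(lower = max(0, p - half), upper = min(1, p + half))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `accuracy = (TP+TN)/total`. A metric with a zero denominator is reported
#' as `NA` (undefined), never as 0. Estimates keep full precision; rounding
#' to whole percents is display-only (see [format_percent()]).
#'
#' @param counts A [confusion_counts()] object.
#' @param ci Attach Wald confidence intervals?
#' @param level Confidence level for the intervals.
#' @return A tibble: `metric`, `estimate`, `successes`, `trials`, and (with
#'   `ci = TRUE`) `conf.low`, `conf.high`.
#' @examples
#' compute_metrics(confusion_counts(
#'   rep(c("II-IV", "I"), c(93, 40)),
#'   rep(c("II-IV", "I", "II-IV", "I"), c(92, 1, 1, 39)),
#'   positive = "II-IV"))
#' @export
compute_metrics <- function(counts, ci = TRUE, level = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  if (total == 0) stop("empty confusion table", call. = FALSE)
  rows <- tibble::tibble(
    metric = c("accuracy", "sensitivity", "specificity"),
    successes = c(counts$tp + counts$tn, counts$tp, counts$tn),
    trials = c(total, counts$tp + counts$fn, counts$tn + counts$fp)
  )
  rows$estimate <- ifelse(rows$trials > 0, rows$successes / rows$trials,
                          NA_real_)
  if (ci) {
    cis <- t(vapply(seq_len(nrow(rows)), function(i) {
      if (rows$trials[i] == 0) return(c(NA_real_, NA_real_))
      wald_ci(rows$successes[i], rows$trials[i], level,
              warn_degenerate = FALSE)
    }, numeric(2)))
    rows$conf.low <- cis[, 1]
    rows$conf.high <- cis[, 2]
  }
  rows[c("metric", "estimate",
         if (ci) c("conf.low", "conf.high"), "successes", "trials")]
}

#' Display-round a proportion as a whole percent
#'
#' @param p Proportion(s) in \[0, 1\].
#' @return Character, e.g. `"99%"`.
#' @export
format_percent <- function(p) {
  paste0(round(100 * p), "%")
}

# grouped stratified train/test sample split; returns character vector of
# training sample ids
split_samples <- function(sample_ids, labels, train_frac = 0.9, seed = 1L) {
  stopifnot(!anyDuplicated(sample_ids))
  set.seed(seed)
  train <- character(0)
  for (lab in unique(labels)) {
    ids <- sample_ids[labels == lab]
    n_tr <- max(1L, min(length(ids) - 1L, round(train_frac * length(ids))))
    train <- c(train, sample(ids, n_tr))
  }
  train
}

sample_level_outcomes <- function(predictions, policy) {
  predictions |>
    dplyr::group_by(.data$sample_id, .data$label) |>
    dplyr::group_modify(function(df, key) majority_vote(df$pred, policy)) |>
    dplyr::ungroup()
}

#' Repeated 90/10 train/test robustness assessment
#'
#' Draws `n_repeats` unique seeded grouped train/test splits (stratified by
#' sample-level label), trains one Gentle AdaBoost model per repeat, and
#' reports per-repeat signal-level metrics and sample-level (majority-voted)
#' accuracy. The best repeat is flagged by the highest mean of the
#' signal-level metrics (ties: lowest repeat index).
#'
#' @param dataset A labelled dataset from [build_dataset()].
#' @param n_repeats Number of repeats (default 15).
#' @param train_frac Training fraction (default 0.9).
#' @param rounds,nu,min_leaf,features Passed to [gentleboost()].
#' @param policy Vote policy for the sample-level aggregation.
#' @param seed Master seed; repeat `i` uses a seed derived from `(seed, i)`.
#' @return A list: `repeats` (one row per repeat: signal-level accuracy /
#'   sensitivity / specificity, sample-level accuracy, definitive fraction,
#'   partition hash, `best` flag) and `summary` (mean/min/max per metric).
#' @export
robustness_assessment <- function(dataset, n_repeats = 15L, train_frac = 0.9,
                                  rounds = 50L, nu = 0.5, min_leaf = 0.01,
                                  features = NULL, policy = vote_policy(),
                                  seed = 1L) {
  samp <- dplyr::distinct(dataset, .data$sample_id, .data$label)
  positive <- attr(dataset, "positive") %||% "positive"
  rows <- vector("list", n_repeats)
  for (i in seq_len(n_repeats)) {
    rep_seed <- derive_seed(seed, i)
    train_ids <- split_samples(samp$sample_id, samp$label, train_frac,
                               rep_seed)
    te <- dataset[!dataset$sample_id %in% train_ids, , drop = FALSE]
    if (length(unique(te$label)) < 2) {
      train_ids <- split_samples(samp$sample_id, samp$label, train_frac,
                                 derive_seed(rep_seed, 13L))
      te <- dataset[!dataset$sample_id %in% train_ids, , drop = FALSE]
      if (length(unique(te$label)) < 2) {
        stop("test split of repeat ", i, " contains a single class",
             call. = FALSE)
      }
    }
    tr <- dataset[dataset$sample_id %in% train_ids, , drop = FALSE]
    model <- gentleboost(tr, features = features, rounds = rounds, nu = nu,
                         min_leaf = min_leaf, seed = rep_seed)
    preds <- tibble::tibble(sample_id = te$sample_id, label = te$label,
                            pred = predict(model, te))
    sig <- compute_metrics(
      confusion_counts(preds$label, preds$pred, positive = positive),
      ci = FALSE)
    by_sample <- sample_level_outcomes(preds, policy)
    rows[[i]] <- tibble::tibble(
      repeat_id = i,
      signal_accuracy = sig$estimate[sig$metric == "accuracy"],
      signal_sensitivity = sig$estimate[sig$metric == "sensitivity"],
      signal_specificity = sig$estimate[sig$metric == "specificity"],
      sample_accuracy = mean(by_sample$decision == by_sample$label),
      definitive_fraction = mean(by_sample$decision != "indeterminate"),
      partition_hash = paste(sort(train_ids), collapse = "|")
    )
  }
  repeats <- dplyr::bind_rows(rows)
  mean_metric <- rowMeans(repeats[c("signal_accuracy", "signal_sensitivity",
                                    "signal_specificity")])
  repeats$best <- seq_len(n_repeats) == which.max(mean_metric)
  metric_cols <- c("signal_accuracy", "signal_sensitivity",
                   "signal_specificity", "sample_accuracy",
                   "definitive_fraction")
  summary <- repeats |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), min = min(.data$value),
                     max = max(.data$value), .groups = "drop")
  list(repeats = repeats, summary = summary)
}

#' Repeated train/test robustness of the full cascade
#'
#' Like [robustness_assessment()], but each repeat trains the complete
#' four-classifier cascade on the training samples and scores the
#' sample-level five-way final diagnosis on the held-out samples
#' (an indeterminate final label counts as an error).
#'
#' @param features Wide feature tibble for the whole cohort.
#' @param meta Sample metadata (with `class_label`).
#' @param n_repeats,train_frac,seed As in [robustness_assessment()].
#' @param signals Optional preprocessed signal tibble; enables per-stage
#'   utility-based sensor dropping inside each repeat (see
#'   [train_cascade()]'s `drop_worst`).
#' @param ... Passed to [train_cascade()].
#' @return A tibble, one row per repeat: `repeat_id`, `n_test`,
#'   `cascade_accuracy`, `definitive_fraction`, `partition_hash`. The
#'   pooled held-out per-sample decisions (with `repeat_id` and the true
#'   `class_label`) are attached as attribute `"decisions"`.
#' @export
cascade_robustness <- function(features, meta, n_repeats = 15L,
                               train_frac = 0.9, seed = 1L, signals = NULL,
                               ...) {
  rows <- vector("list", n_repeats)
  decs <- vector("list", n_repeats)
  for (i in seq_len(n_repeats)) {
    rep_seed <- derive_seed(seed, i)
    train_ids <- split_samples(meta$sample_id, meta$class_label, train_frac,
                               rep_seed)
    tr_feat <- features[features$sample_id %in% train_ids, , drop = FALSE]
    te_feat <- features[!features$sample_id %in% train_ids, , drop = FALSE]
    tr_sig <- if (!is.null(signals)) {
      signals[signals$sample_id %in% train_ids, , drop = FALSE]
    }
    cascade <- train_cascade(tr_feat,
                             meta[meta$sample_id %in% train_ids, ,
                                  drop = FALSE],
                             signals = tr_sig,
                             seed = rep_seed, ...)
    dec <- predict_cascade(cascade, te_feat)
    truth <- meta$class_label[match(dec$sample_id, meta$sample_id)]
    decs[[i]] <- dplyr::mutate(dec, repeat_id = i, class_label = truth,
                               .before = 1)
    rows[[i]] <- tibble::tibble(
      repeat_id = i,
      n_test = nrow(dec),
      cascade_accuracy = mean(dec$final == truth),
      definitive_fraction = mean(dec$final != "indeterminate"),
      partition_hash = paste(sort(train_ids), collapse = "|")
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "decisions") <- dplyr::bind_rows(decs)
  out
}

#' Learning curve over training-set size
#'
#' For each requested fraction, trains on a seeded grouped subsample of the
#' training samples and evaluates on a fixed held-out validation split.
#' Fractions leaving fewer than 2 samples per class are skipped with a
#' warning.
#'
#' @param dataset A labelled dataset from [build_dataset()].
#' @param fractions Increasing fractions in (0, 1] of the training samples.
#' @param val_frac Fraction of samples held out for validation.
#' @param rounds,nu,min_leaf,features Passed to [gentleboost()].
#' @param seed Master seed.
#' @return A tibble, one row per (fraction, split in train/validation):
#'   `fraction`, `split`, `n_samples`, `accuracy`.
#' @export
learning_curve <- function(dataset, fractions = c(0.2, 0.4, 0.6, 0.8, 1),
                           val_frac = 0.2, rounds = 50L, nu = 0.5,
                           min_leaf = 0.01, features = NULL, seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1),
            !is.unsorted(fractions))
  samp <- dplyr::distinct(dataset, .data$sample_id, .data$label)
  positive <- attr(dataset, "positive") %||% "positive"
  train_ids <- split_samples(samp$sample_id, samp$label, 1 - val_frac, seed)
  val <- dataset[!dataset$sample_id %in% train_ids, , drop = FALSE]
  tr_samp <- samp[samp$sample_id %in% train_ids, , drop = FALSE]
  out <- vector("list", length(fractions))
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    sub_ids <- if (f >= 1) {
      tr_samp$sample_id
    } else {
      split_samples(tr_samp$sample_id, tr_samp$label, f,
                    derive_seed(seed, i))
    }
    tab <- table(tr_samp$label[tr_samp$sample_id %in% sub_ids])
    if (length(tab) < 2 || any(tab < 2)) {
      warning("fraction ", f, " leaves < 2 samples in a class; skipped",
              call. = FALSE)
      next
    }
    tr <- dataset[dataset$sample_id %in% sub_ids, , drop = FALSE]
    model <- gentleboost(tr, features = features, rounds = rounds, nu = nu,
                         min_leaf = min_leaf, seed = seed)
    acc <- function(d) {
      cc <- confusion_counts(d$label, predict(model, d), positive = positive)
      (cc$tp + cc$tn) / (cc$tp + cc$tn + cc$fp + cc$fn)
    }
    out[[i]] <- tibble::tibble(
      fraction = f,
      split = c("train", "validation"),
      n_samples = c(length(sub_ids), dplyr::n_distinct(val$sample_id)),
      accuracy = c(acc(tr), acc(val))
    )
  }
  dplyr::bind_rows(out)
}
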