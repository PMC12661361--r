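#' Similarity coefficient of one sensor
#'
#' The mean Pearson correlation over all cross-category signal pairs of one
#' sensor: every trace recorded for a category-A sample is correlated with
#' every trace recorded for a category-B sample, and the coefficients are
#' averaged. Signals that are nearly identical across the two categories
#' yield a similarity near 1 — i.e. low discriminatory power. A pair
#' involving a zero-variance trace has no defined correlation and counts as
#' 0 by policy (with a message).
#'
#' @param traces Numeric matrix, one row per signal (equal-length traces).
#' @param labels Category label per row; exactly 2 distinct values, each
#'   present at least once.
#' @param max_pairs Optional cap: when the number of cross pairs exceeds it,
#'   a seeded random subsample of pairs is averaged instead (full
#'   enumeration, the default, is the tested contract).
#' @param seed Seed for the optional pair subsample.
#' @return The mean cross-category Pearson correlation, in \[-1, 1\].
#' @examples
#' tr <- rbind(sin(1:50), sin(1:50), -sin(1:50))
#' similarity_coefficient(tr, c("A", "A", "B"))  # -1
#' @export
similarity_coefficient <- function(traces, labels, max_pairs = Inf,
                                   seed = 1L) {
  traces <- as.matrix(traces)
  stopifnot(nrow(traces) == length(labels))
  cats <- unique(labels)
  if (length(cats) != 2) {
    stop("`labels` must contain exactly 2 categories", call. = FALSE)
  }
  a <- which(labels == cats[1])
  b <- which(labels == cats[2])
  sds <- apply(traces, 1, stats::sd)
  flat <- sds < .Machine$double.eps
  if (any(flat)) {
    message(sum(flat),
            " zero-variance trace(s); their pairs count as correlation 0")
  }
  Z <- traces
  Z[!flat, ] <- t(scale(t(traces[!flat, , drop = FALSE])))
  Z[flat, ] <- 0
  n_pairs <- length(a) * length(b)
  if (n_pairs > max_pairs) {
    set.seed(seed)
    pick <- sample.int(n_pairs, max_pairs)
    ai <- a[((pick - 1L) %% length(a)) + 1L]
    bi <- b[((pick - 1L) %/% length(a)) + 1L]
    r <- rowSums(Z[ai, , drop = FALSE] * Z[bi, , drop = FALSE]) /
      (ncol(traces) - 1L)
    return(mean(r))
  }
  R <- Z[a, , drop = FALSE] %*% t(Z[b, , drop = FALSE]) / (ncol(traces) - 1L)
  mean(R)
}

#' Rank sensors by discriminatory power
#'
#' Computes the similarity coefficient of every sensor on (preprocessed)
#' signals for a binary task and ranks sensors by utility: rank 1 is the
#' most useful sensor — the one with the *lowest* cross-category similarity.
#' Ties are broken by ascending sensor id.
#'
#' @param signals Preprocessed long signal tibble.
#' @param meta Sample metadata.
#' @param task Binary task defining the two categories (see
#'   [build_dataset()] for the task vocabulary).
#' @param sensors Sensor table; every sensor listed here must appear in
#'   `signals`.
#' @param max_pairs,seed Passed to [similarity_coefficient()].
#' @return A tibble of class `"sensor_utility"`: `sensor_id`, `similarity`,
#'   `rank` (a permutation of 1..n, 1 = most useful).
#' @export
rank_sensors <- function(signals, meta,
                         task = c("cancer_vs_healthy", "oc_vs_ec",
                                  "oc_stage", "ec_stage"),
                         sensors = sensor_array(), max_pairs = Inf,
                         seed = 1L) {
  task <- match.arg(task)
  check_signals(signals)
  missing_sensors <- setdiff(sensors$sensor_id, unique(signals$sensor_id))
  if (length(missing_sensors)) {
    stop("no signals for sensor(s): ",
         paste(missing_sensors, collapse = ", "), call. = FALSE)
  }
  lab <- task_labels(meta, task)
  keep <- signals$sample_id %in% names(lab)[!is.na(lab)]
  signals <- signals[keep, , drop = FALSE]
  sims <- vapply(sensors$sensor_id, function(sid) {
    sub <- signals[signals$sensor_id == sid, , drop = FALSE]
    keys <- setdiff(signal_keys(sub), "sensor_id")
    grp <- interaction(sub[keys], drop = TRUE, lex.order = TRUE)
    pieces <- split(seq_len(nrow(sub)), grp)
    traces <- t(vapply(pieces, function(idx) {
      sub$voltage_v[idx[order(sub$time_s[idx])]]
    }, numeric(length(pieces[[1]]))))
    labels <- unname(lab[vapply(pieces, function(idx) sub$sample_id[idx[1]],
                                character(1))])
    if (length(unique(labels)) < 2) {
      stop("sensor ", sid, ": need signals from both categories",
           call. = FALSE)
    }
    similarity_coefficient(traces, labels, max_pairs = max_pairs,
                           seed = seed)
  }, numeric(1))
  out <- tibble::tibble(sensor_id = sensors$sensor_id, similarity = sims) |>
    dplyr::arrange(.data$similarity, .data$sensor_id) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::arrange(.data$sensor_id)
  class(out) <- c("sensor_utility", class(out))
  out
}

# sample_id -> category label for a binary task (NA = sample not in task)
task_labels <- function(meta, task) {
  lab <- switch(task,
    cancer_vs_healthy = meta$cohort,
    oc_vs_ec = ifelse(meta$cohort == "cancer", meta$cancer_type,
                      NA_character_),
    oc_stage = ifelse(meta$cancer_type == "ovarian", meta$stage_group,
                      NA_character_),
    ec_stage = ifelse(meta$cancer_type == "endometrial", meta$stage_group,
                      NA_character_)
  )
  stats::setNames(lab, meta$sample_id)
}

#' Iterative sensor elimination
#'
#' For each step `k = 0 .. n_sensors - 1`, removes the feature rows of the
#' `k` least useful sensors (highest similarity), trains exactly one Gentle
#' AdaBoost model on the remaining training rows, and evaluates it on a
#' fixed grouped validation split — producing the performance matrix from
#' which the optimal sensor subset is selected. A step whose training rows
#' vanish (or collapse to a single class) is recorded as undefined and the
#' loop continues.
#'
#' @param dataset A labelled dataset from [build_dataset()] (training
#'   rows; the validation split is carved out of it by sample).
#' @param utility A `sensor_utility` table from [rank_sensors()] — computed
#'   on training data only.
#' @param rounds,nu,min_leaf,features Passed to [gentleboost()].
#' @param val_frac Fraction of samples held out (grouped, stratified) for
#'   the per-step validation metrics.
#' @param seed Seed for the validation split.
#' @return A tibble of class `"performance_matrix"`, one row per step:
#'   `k`, `sensors_excluded` (list-column), `sensors_kept` (list-column),
#'   `n_train_rows`, `accuracy`, `sensitivity`, `specificity`,
#'   `mean_metric`.
#' @export
iterative_elimination <- function(dataset, utility, rounds = 40L, nu = 0.5,
                                  min_leaf = 0.01, features = NULL,
                                  val_frac = 0.25, seed = 1L) {
  stopifnot(inherits(utility, "sensor_utility"))
  samp <- dplyr::distinct(dataset, .data$sample_id, .data$label)
  train_ids <- split_samples(samp$sample_id, samp$label, 1 - val_frac, seed)
  positive <- attr(dataset, "positive") %||% "positive"
  n_sensors <- nrow(utility)
  rows <- vector("list", n_sensors)
  for (k in 0:(n_sensors - 1L)) {
    excluded <- utility$sensor_id[utility$rank > n_sensors - k]
    kept <- sort(setdiff(utility$sensor_id, excluded))
    tr <- dataset[dataset$sample_id %in% train_ids &
                    dataset$sensor_id %in% kept, , drop = FALSE]
    va <- dataset[!dataset$sample_id %in% train_ids &
                    dataset$sensor_id %in% kept, , drop = FALSE]
    undefined <- nrow(tr) == 0 || length(unique(tr$label)) < 2 ||
      nrow(va) == 0 || length(unique(va$label)) < 2
    if (undefined) {
      rows[[k + 1L]] <- tibble::tibble(
        k = k, sensors_excluded = list(sort(excluded)),
        sensors_kept = list(kept), n_train_rows = nrow(tr),
        accuracy = NA_real_, sensitivity = NA_real_,
        specificity = NA_real_, mean_metric = NA_real_)
      next
    }
    model <- gentleboost(tr, features = features, rounds = rounds, nu = nu,
                         min_leaf = min_leaf, seed = seed)
    mm <- compute_metrics(
      confusion_counts(va$label, predict(model, va), positive = positive),
      ci = FALSE)
    est <- stats::setNames(mm$estimate, mm$metric)
    rows[[k + 1L]] <- tibble::tibble(
      k = k, sensors_excluded = list(sort(excluded)),
      sensors_kept = list(kept), n_train_rows = nrow(tr),
      accuracy = est[["accuracy"]], sensitivity = est[["sensitivity"]],
      specificity = est[["specificity"]],
      mean_metric = mean(est, na.rm = TRUE))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("performance_matrix", class(out))
  out
}

#' Select the optimal sensor subset from a performance matrix
#'
#' Returns the retained-sensor set of the row maximizing the mean of
#' accuracy, sensitivity and specificity; ties are broken towards retaining
#' more sensors (more training data).
#'
#' @param matrix A `performance_matrix` from [iterative_elimination()].
#' @return Integer vector of retained sensor ids (the winning subset), with
#'   the winning row index as attribute `"step"`.
#' @export
select_optimal <- function(matrix) {
  stopifnot(inherits(matrix, "performance_matrix"))
  defined <- which(!is.na(matrix$mean_metric))
  if (!length(defined)) {
    stop("all elimination steps are undefined", call. = FALSE)
  }
  best_val <- max(matrix$mean_metric[defined])
  cand <- defined[matrix$mean_metric[defined] >= best_val - 1e-12]
  sizes <- vapply(matrix$sensors_kept[cand], length, integer(1))
  win <- cand[which.max(sizes)]  # ties: more sensors; then earliest row
  out <- matrix$sensors_kept[[win]]
  attr(out, "step") <- matrix$k[win]
  out
}
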