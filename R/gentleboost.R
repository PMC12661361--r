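#' Fit a weighted-least-squares regression stump
#'
#' The Gentle AdaBoost weak learner: over every feature and every midpoint
#' threshold between adjacent distinct observed values, finds the depth-1
#' regression tree minimizing the weighted squared error
#' `sum(w * (y - f(x))^2)`, where each leaf value is the weighted mean of the
#' +/-1 labels falling in that leaf (hence always in \[-1, 1\]). A minimum
#' leaf weight fraction constrains the split; if no admissible split exists
#' (e.g. all rows identical) the stump degenerates to a constant predicting
#' the overall weighted mean.
#'
#' Ties in the weighted error are broken deterministically: earliest feature,
#' then lowest threshold.
#'
#' @param X Numeric matrix (rows = observations, columns = features).
#' @param y Numeric vector of labels in `{-1, +1}`.
#' @param w Non-negative weights summing to 1 (default uniform).
#' @param min_leaf Minimum fraction of total weight required in each leaf.
#' @return A list of class `"enose_stump"`: `feature` (column index),
#'   `threshold`, `left`, `right` (leaf values for `x <= threshold` and
#'   `x > threshold`).
#' @examples
#' fit_stump(matrix(c(0, 1)), c(-1, 1))
#' @export
fit_stump <- function(X, y, w = rep(1 / nrow(X), nrow(X)), min_leaf = 0.01) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 rows", call. = FALSE)
  if (!all(y %in% c(-1, 1))) stop("`y` must be in {-1, +1}", call. = FALSE)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("`w` must be non-negative and sum to 1", call. = FALSE)
  }
  prep <- stump_prep(X)
  st <- stump_search(prep, y, w, min_leaf)
  structure(st, class = "enose_stump")
}

# pre-sort each feature once so repeated stump searches are O(n) per feature
stump_prep <- function(X) {
  p <- ncol(X)
  ords <- vector("list", p)
  valid <- vector("list", p)
  thr <- vector("list", p)
  for (j in seq_len(p)) {
    o <- order(X[, j])
    xs <- X[o, j]
    ok <- which(diff(xs) > 0)
    ords[[j]] <- o
    valid[[j]] <- ok
    thr[[j]] <- (xs[ok] + xs[ok + 1L]) / 2
  }
  list(X = X, ords = ords, valid = valid, thr = thr, n = nrow(X), p = p)
}

stump_search <- function(prep, y, w, min_leaf) {
  W <- sum(w)
  SWY <- sum(w * y)
  const_val <- SWY / W
  best <- list(feature = 1L, threshold = -Inf,
               left = const_val, right = const_val)
  best_score <- -Inf
  for (j in seq_len(prep$p)) {
    ok <- prep$valid[[j]]
    if (!length(ok)) next
    o <- prep$ords[[j]]
    wo <- w[o]
    cw <- cumsum(wo)
    cwy <- cumsum(wo * y[o])
    swl <- cw[ok]; swyl <- cwy[ok]
    swr <- W - swl; swyr <- SWY - swyl
    admissible <- swl >= min_leaf * W & swr >= min_leaf * W & swl > 0 & swr > 0
    if (!any(admissible)) next
    score <- rep(-Inf, length(ok))
    score[admissible] <- swyl[admissible]^2 / swl[admissible] +
      swyr[admissible]^2 / swr[admissible]
    k <- which.max(score)
    if (score[k] > best_score + 1e-12) {
      best_score <- score[k]
      best <- list(feature = j, threshold = prep$thr[[j]][k],
                   left = swyl[k] / swl[k], right = swyr[k] / swr[k])
    }
  }
  best
}

stump_predict <- function(stump, x) {
  ifelse(x <= stump$threshold, stump$left, stump$right)
}

#' Train a Gentle AdaBoost ensemble
#'
#' At each round a regression stump is fitted to the current example weights
#' by weighted least squares; the additive model is updated
#' `F <- F + nu * f_m` and the weights multiplicatively reweighted
#' `w_i <- w_i * exp(-nu * y_i * f_m(x_i))` and renormalized. The training
#' exponential loss `mean(exp(-y * F))` is non-increasing in the round index
#' for any learning rate in (0, 1] and is recorded per round.
#'
#' @param dataset A labelled dataset from [build_dataset()], or any tibble
#'   with a `y` column in `{-1, +1}` plus numeric feature columns.
#' @param features Character vector of feature columns to use; default all
#'   registry features present (or, failing that, all numeric non-key
#'   columns).
#' @param rounds Number of boosting rounds M (>= 1).
#' @param nu Learning rate in (0, 1].
#' @param min_leaf Minimum leaf weight fraction for each stump.
#' @param seed Integer recorded in the model metadata (training itself is
#'   deterministic).
#' @return An object of class `"enose_boost"`: stump table, learning rate,
#'   kept features, per-round exponential loss, label coding.
#' @examples
#' d <- tibble::tibble(x1 = c(0, 1, 0, 1), y = c(-1, -1, 1, 1))
#' m <- gentleboost(d, features = "x1", rounds = 3)
#' predict(m, d)
#' @export
gentleboost <- function(dataset, features = NULL, rounds = 50L, nu = 0.5,
                        min_leaf = 0.01, seed = NA_integer_) {
  if (rounds < 1) stop("`rounds` must be >= 1", call. = FALSE)
  if (nu <= 0 || nu > 1) stop("`nu` must be in (0, 1]", call. = FALSE)
  if (is.null(features)) {
    features <- dataset_feature_names(dataset)
    if (!length(features)) {
      features <- setdiff(names(dataset)[vapply(dataset, is.numeric,
                                                logical(1))],
                          c("y", "measurement", "sensor_id", "batch_id"))
    }
  }
  y <- dataset$y
  if (is.null(y)) stop("dataset must carry a `y` column in {-1, +1}",
                       call. = FALSE)
  X <- as.matrix(dataset[features])
  n <- nrow(X)
  if (length(unique(y)) == 1L) {
    warning("all training labels identical; returning a constant model",
            call. = FALSE)
    stump <- list(feature = 1L, threshold = -Inf, left = y[1], right = y[1])
    return(new_enose_boost(
      stumps = tibble::tibble(feature = features[1], threshold = -Inf,
                              left = y[1], right = y[1]),
      nu = nu, features = features, loss = exp(-nu),
      positive = attr(dataset, "positive") %||% "positive",
      negative = attr(dataset, "negative") %||% "negative",
      seed = seed))
  }
  prep <- stump_prep(X)
  w <- rep(1 / n, n)
  Fx <- numeric(n)
  stump_feature <- integer(rounds)
  stump_threshold <- stump_left <- stump_right <- numeric(rounds)
  loss <- numeric(rounds)
  for (m in seq_len(rounds)) {
    st <- stump_search(prep, y, w, min_leaf)
    fx <- stump_predict(st, X[, st$feature])
    Fx <- Fx + nu * fx
    w <- w * exp(-nu * y * fx)
    w <- w / sum(w)
    stump_feature[m] <- st$feature
    stump_threshold[m] <- st$threshold
    stump_left[m] <- st$left
    stump_right[m] <- st$right
    loss[m] <- mean(exp(-y * Fx))
  }
  new_enose_boost(
    stumps = tibble::tibble(feature = features[stump_feature],
                            threshold = stump_threshold,
                            left = stump_left, right = stump_right),
    nu = nu, features = features, loss = loss,
    positive = attr(dataset, "positive") %||% "positive",
    negative = attr(dataset, "negative") %||% "negative",
    seed = seed)
}

new_enose_boost <- function(stumps, nu, features, loss, positive, negative,
                            seed) {
  structure(
    list(stumps = stumps, nu = nu, features = features, loss = loss,
         positive = positive, negative = negative, seed = seed),
    class = "enose_boost"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.enose_boost <- function(x, ...) {
  cat(sprintf(
    "<enose_boost> %d stumps, nu = %g, %d features (%s vs %s)\n",
    nrow(x$stumps), x$nu, length(x$features), x$positive, x$negative
  ))
  cat(sprintf("  final training exponential loss: %.4g\n",
              x$loss[length(x$loss)]))
  invisible(x)
}

#' Predict with a Gentle AdaBoost model
#'
#' The margin is `nu * sum_m f_m(x)`; the class is its sign, with the 0 tie
#' mapped to the positive class by convention.
#'
#' @param object An `enose_boost` model.
#' @param newdata Tibble or data frame containing every model feature.
#' @param type `"class"` (default) or `"margin"`.
#' @param ... Unused.
#' @return Character vector of class labels, or numeric margins.
#' @export
predict.enose_boost <- function(object, newdata,
                                type = c("class", "margin"), ...) {
  type <- match.arg(type)
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) {
    stop("newdata is missing model feature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  margin <- boost_margin(object, newdata)
  if (type == "margin") return(margin)
  ifelse(margin >= 0, object$positive, object$negative)
}

boost_margin <- function(object, newdata) {
  st <- object$stumps
  margin <- numeric(nrow(newdata))
  for (m in seq_len(nrow(st))) {
    x <- newdata[[st$feature[m]]]
    margin <- margin + ifelse(x <= st$threshold[m], st$left[m], st$right[m])
  }
  object$nu * margin
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Gentle AdaBoost model
#'
#' @param x An `enose_boost` model.
#' @param ... Unused.
#' @return One row per boosting round: `round`, `feature`, `threshold`,
#'   `left`, `right`, `train_exp_loss`.
#' @method tidy enose_boost
#' @export
tidy.enose_boost <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(round = seq_len(nrow(x$stumps))),
                   x$stumps,
                   tibble::tibble(train_exp_loss = x$loss))
}

#' One-row model summary
#'
#' @param x An `enose_boost` model.
#' @param ... Unused.
#' @return A one-row tibble: rounds, learning rate, number of features, the
#'   number of distinct features actually used by stumps, and the final
#'   training exponential loss.
#' @method glance enose_boost
#' @export
glance.enose_boost <- function(x, ...) {
  tibble::tibble(
    rounds = nrow(x$stumps),
    nu = x$nu,
    n_features = length(x$features),
    n_features_used = dplyr::n_distinct(x$stumps$feature),
    train_exp_loss = x$loss[length(x$loss)]
  )
}

#' Grouped, label-stratified fold assignment
#'
#' Assigns whole samples (groups) to folds so that all signals of a sample
#' share a fold, stratifying by the sample-level label so every fold sees
#' both classes.
#'
#' @param sample_ids Character vector, one entry per sample (unique).
#' @param labels Sample-level labels parallel to `sample_ids`.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return Integer fold id (1..k) per sample, named by sample id.
#' @export
make_folds <- function(sample_ids, labels, k = 5L, seed = 1L) {
  stopifnot(!anyDuplicated(sample_ids), length(labels) == length(sample_ids),
            k >= 2)
  draw <- function(s) {
    set.seed(s)
    fold <- integer(length(sample_ids))
    for (lab in unique(labels)) {
      idx <- which(labels == lab)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(sample.int(k), length(idx))
    }
    fold
  }
  fold <- draw(seed)
  ok <- all(vapply(seq_len(k), function(f) {
    length(unique(labels[fold == f])) == length(unique(labels)) ||
      sum(fold == f) == 0
  }, logical(1)))
  if (!ok) {
    fold <- draw(derive_seed(seed, 97L))
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(labels[fold == f])) == length(unique(labels)) ||
        sum(fold == f) == 0
    }, logical(1)))
    if (!ok) {
      stop("could not build folds containing every class; too few samples",
           call. = FALSE)
    }
  }
  stats::setNames(fold, sample_ids)
}

#' Grouped stratified k-fold cross-validation
#'
#' Folds are stratified by sample-level label and grouped by `sample_id`, so
#' all signals of a sample (including duplicate measurements) share a fold —
#' the leakage guard for replicate measurements.
#'
#' @param dataset A labelled dataset from [build_dataset()].
#' @param rounds,nu,min_leaf Gentle AdaBoost hyperparameters.
#' @param features Feature columns to use (default: registry features
#'   present).
#' @param folds Number of folds (default 5).
#' @param seed Integer seed controlling the fold draw.
#' @return A list: `fold_metrics` (per-fold tibble), `pooled` (tibble of
#'   pooled signal-level accuracy/sensitivity/specificity over all held-out
#'   predictions), `assignments` (named fold vector), `predictions`
#'   (held-out tibble: sample_id, fold, label, pred, margin).
#' @export
cross_validate <- function(dataset, rounds = 50L, nu = 0.5, min_leaf = 0.01,
                           features = NULL, folds = 5L, seed = 1L) {
  samp <- dataset |>
    dplyr::distinct(.data$sample_id, .data$label)
  if (anyDuplicated(samp$sample_id)) {
    stop("a sample carries more than one label", call. = FALSE)
  }
  fold_of <- make_folds(samp$sample_id, samp$label, k = folds, seed = seed)
  row_fold <- unname(fold_of[dataset$sample_id])
  preds <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- dataset[row_fold != f, , drop = FALSE]
    te <- dataset[row_fold == f, , drop = FALSE]
    if (nrow(te) == 0) next
    model <- gentleboost(tr, features = features, rounds = rounds, nu = nu,
                         min_leaf = min_leaf, seed = seed)
    preds[[f]] <- tibble::tibble(
      sample_id = te$sample_id,
      fold = f,
      label = te$label,
      pred = predict(model, te),
      margin = predict(model, te, type = "margin")
    )
  }
  predictions <- dplyr::bind_rows(preds)
  positive <- attr(dataset, "positive") %||% "positive"
  fold_metrics <- predictions |>
    dplyr::group_by(.data$fold) |>
    dplyr::group_modify(function(df, key) {
      cc <- confusion_counts(df$label, df$pred, positive = positive)
      compute_metrics(cc, ci = FALSE)
    }) |>
    dplyr::ungroup()
  pooled <- compute_metrics(
    confusion_counts(predictions$label, predictions$pred,
                     positive = positive),
    ci = FALSE
  )
  list(fold_metrics = fold_metrics, pooled = pooled,
       assignments = fold_of, predictions = predictions)
}

#' Hyperparameter search space
#'
#' @param rounds_range Integer range for the number of boosting rounds.
#' @param nu_range Range for the learning rate (within (0, 1]).
#' @param min_leaf_range Range for the stump minimum leaf weight fraction.
#' @return A list of class `"enose_space"`.
#' @export
hyperparameter_space <- function(rounds_range = c(10L, 500L),
                                 nu_range = c(0.01, 1),
                                 min_leaf_range = c(0.01, 0.2)) {
  stopifnot(rounds_range[1] >= 1, rounds_range[1] <= rounds_range[2],
            nu_range[1] > 0, nu_range[2] <= 1,
            min_leaf_range[1] > 0, min_leaf_range[2] < 0.5)
  structure(list(rounds_range = rounds_range, nu_range = nu_range,
                 min_leaf_range = min_leaf_range),
            class = "enose_space")
}

#' Budgeted seeded hyperparameter search
#'
#' Evaluates `budget` seeded quasi-random configurations of the constrained
#' space by grouped 5-fold cross-validation and returns the configuration
#' with the highest pooled CV accuracy, together with the full search trace
#' for audit. Candidate `i` is derived deterministically from `(seed, i)`, so
#' enlarging the budget extends — never changes — the candidate sequence, and
#' the best accuracy is non-decreasing in the budget.
#'
#' @param dataset A labelled dataset from [build_dataset()].
#' @param space A [hyperparameter_space()].
#' @param budget Number of configurations to evaluate (>= 1).
#' @param features,folds,seed Passed to [cross_validate()].
#' @return A list: `best` (one-row tibble with the winning configuration and
#'   its pooled metrics) and `trace` (one row per evaluated configuration).
#' @export
tune_gentleboost <- function(dataset, space = hyperparameter_space(),
                             budget = 10L, features = NULL, folds = 5L,
                             seed = 1L) {
  if (budget < 1) stop("`budget` must be >= 1", call. = FALSE)
  rows <- vector("list", budget)
  for (i in seq_len(budget)) {
    set.seed(derive_seed(seed, i))
    u <- stats::runif(3)
    # log-uniform in rounds so small and large ensembles are both explored
    rounds <- round(exp(log(space$rounds_range[1]) +
                          u[1] * diff(log(space$rounds_range))))
    nu <- space$nu_range[1] + u[2] * diff(space$nu_range)
    min_leaf <- space$min_leaf_range[1] + u[3] * diff(space$min_leaf_range)
    cv <- cross_validate(dataset, rounds = rounds, nu = nu,
                         min_leaf = min_leaf, features = features,
                         folds = folds, seed = seed)
    acc <- cv$pooled$estimate[cv$pooled$metric == "accuracy"]
    rows[[i]] <- tibble::tibble(eval = i, rounds = rounds, nu = nu,
                                min_leaf = min_leaf, cv_accuracy = acc)
  }
  trace <- dplyr::bind_rows(rows)
  best_i <- which.max(trace$cv_accuracy)  # first max: earliest candidate wins
  list(best = trace[best_i, ], trace = trace)
}
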