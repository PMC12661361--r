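#' The 85-entry feature registry
#'
#' The catalogue of per-signal features: 25 statistical descriptors of the
#' whole trace, 35 time-domain features anchored to the measurement phases
#' (baseline / exposure / recovery), and 25 frequency-domain features of the
#' mean-removed periodogram. The registry order is fixed; feature vectors and
#' feature tables always follow it.
#'
#' Degenerate-input policies (documented so every feature is finite on every
#' input): skewness and kurtosis of a zero-variance signal are 0; the
#' coefficient of variation is 0 when the mean is (numerically) 0; phase-mean
#' ratios are 0 when their denominator is (numerically) 0; autocorrelations
#' of a zero-variance signal are 0; every spectral statistic of an all-zero
#' spectrum is 0.
#'
#' @return A tibble with columns `feature` (name) and `category`
#'   (`"statistical"`, `"time"`, `"frequency"`), 85 rows.
#' @examples
#' dplyr::count(feature_registry(), category)
#' @export
feature_registry <- function() {
  statistical <- c(
    "stat_mean", "stat_median", "stat_sd", "stat_var", "stat_skewness",
    "stat_kurtosis", "stat_min", "stat_max", "stat_range", "stat_rms",
    "stat_mad_mean", "stat_mad_median", "stat_cv", "stat_energy",
    "stat_hist_entropy", "stat_q05", "stat_q10", "stat_q25", "stat_q75",
    "stat_q90", "stat_q95", "stat_iqr", "stat_trimmed_mean",
    "stat_zero_crossings", "stat_mean_crossings"
  )
  time <- c(
    "time_baseline_mean", "time_baseline_slope", "time_baseline_area",
    "time_exposure_mean", "time_exposure_slope", "time_exposure_area",
    "time_recovery_mean", "time_recovery_slope", "time_recovery_area",
    "time_max_slope", "time_min_slope", "time_argmax_s", "time_argmin_s",
    "time_rise_10_90", "time_decay_90_10", "time_peak_minus_baseline",
    "time_to_peak_s", "time_exposure_baseline_ratio",
    "time_recovery_exposure_ratio", "time_d1_mean", "time_d1_sd",
    "time_d1_max", "time_d1_min", "time_d1_skewness", "time_d2_mean",
    "time_d2_sd", "time_d2_max_abs", "time_acf_lag1", "time_acf_lag5",
    "time_acf_lag10", "time_acf_lag20", "time_piecewise_rms",
    "time_line_length", "time_hjorth_mobility", "time_hjorth_complexity"
  )
  frequency <- c(
    paste0("freq_band_power_", 1:8), paste0("freq_rel_power_", 1:8),
    "freq_centroid", "freq_spread", "freq_skewness", "freq_kurtosis",
    "freq_flatness", "freq_entropy", "freq_rolloff_85", "freq_rolloff_95",
    "freq_dominant"
  )
  tibble::tibble(
    feature = c(statistical, time, frequency),
    category = rep(c("statistical", "time", "frequency"),
                   times = c(length(statistical), length(time),
                             length(frequency)))
  )
}

# population moments with degenerate policy: skewness/kurtosis of a
# zero-variance vector are 0
moment_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 < .Machine$double.eps) return(0)
  mean((x - m)^3) / s2^1.5
}

moment_kurtosis <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 < .Machine$double.eps) return(0)
  mean((x - m)^4) / s2^2 - 3
}

ls_slope <- function(t, x) {
  if (length(t) < 2) return(0)
  tv <- t - mean(t)
  denom <- sum(tv^2)
  if (denom < .Machine$double.eps) return(0)
  sum(tv * (x - mean(x))) / denom
}

trapz_area <- function(t, x) {
  if (length(t) < 2) return(0)
  sum(diff(t) * (utils::head(x, -1) + utils::tail(x, -1)) / 2)
}

count_crossings <- function(x, level = 0) {
  y <- x - level
  sum(y[-length(y)] * y[-1] < 0)
}

hist_entropy <- function(x, bins = 16L) {
  r <- range(x)
  if (diff(r) < .Machine$double.eps * max(1, abs(r[2]))) return(0)
  cnt <- tabulate(
    pmin(pmax(findInterval(x, seq(r[1], r[2], length.out = bins + 1L),
                           rightmost.closed = TRUE), 1L), bins),
    nbins = bins
  )
  p <- cnt / sum(cnt)
  p <- p[p > 0]
  -sum(p * log(p))
}

acf_at <- function(x, lags) {
  m <- mean(x)
  denom <- sum((x - m)^2)
  vapply(lags, function(k) {
    if (denom < .Machine$double.eps || k >= length(x)) return(0)
    sum((x[seq_len(length(x) - k)] - m) * (x[(k + 1):length(x)] - m)) / denom
  }, numeric(1))
}

safe_ratio <- function(num, den) {
  if (abs(den) < 1e-12) 0 else num / den
}

# features of one aligned, preprocessed trace; returns named numeric(85)
# in registry order
extract_signal_features <- function(voltage, time_s,
                                    timeline = measurement_timeline()) {
  x <- as.numeric(voltage)
  t <- as.numeric(time_s)
  n <- length(x)
  if (n < 16L) {
    stop("signal too short for feature extraction (need >= 16 samples, got ",
         n, ")", call. = FALSE)
  }
  if (anyNA(x) || anyNA(t)) stop("signal contains missing values", call. = FALSE)
  dt <- stats::median(diff(t))

  out <- numeric(0)

  ## --- statistical block (whole trace) -----------------------------------
  m <- mean(x)
  s <- stats::sd(x)
  q <- stats::quantile(x, c(0.05, 0.10, 0.25, 0.75, 0.90, 0.95), names = FALSE)
  out <- c(out,
    stat_mean = m,
    stat_median = stats::median(x),
    stat_sd = s,
    stat_var = s^2,
    stat_skewness = moment_skewness(x),
    stat_kurtosis = moment_kurtosis(x),
    stat_min = min(x),
    stat_max = max(x),
    stat_range = diff(range(x)),
    stat_rms = sqrt(mean(x^2)),
    stat_mad_mean = mean(abs(x - m)),
    stat_mad_median = stats::median(abs(x - stats::median(x))),
    stat_cv = if (abs(m) < 1e-12) 0 else s / abs(m),
    stat_energy = sum(x^2),
    stat_hist_entropy = hist_entropy(x),
    stat_q05 = q[1], stat_q10 = q[2], stat_q25 = q[3],
    stat_q75 = q[4], stat_q90 = q[5], stat_q95 = q[6],
    stat_iqr = q[4] - q[3],
    stat_trimmed_mean = mean(x, trim = 0.1),
    stat_zero_crossings = count_crossings(x, 0),
    stat_mean_crossings = count_crossings(x, m)
  )

  ## --- time-domain block --------------------------------------------------
  phase <- timeline_phase(t, timeline)
  ib <- phase == "baseline"; ie <- phase == "exposure"; ir <- phase == "recovery"
  pmean <- function(idx) if (any(idx)) mean(x[idx]) else 0
  pslope <- function(idx) if (sum(idx) >= 2) ls_slope(t[idx], x[idx]) else 0
  parea <- function(idx) if (sum(idx) >= 2) trapz_area(t[idx], x[idx]) else 0

  d1 <- diff(x) / dt
  d2 <- diff(d1) / dt
  b_mean <- pmean(ib)
  peak <- max(x)
  i_peak <- which.max(x)
  delta <- peak - b_mean

  # 10-90% rise time after fan-on and 90-10% decay time after the peak,
  # relative to (baseline mean, peak); 0 when a threshold is never reached
  rise_t <- decay_t <- 0
  if (delta > 0) {
    after_fan <- which(t >= timeline$fan_on)
    t10 <- after_fan[x[after_fan] >= b_mean + 0.1 * delta][1]
    t90 <- after_fan[x[after_fan] >= b_mean + 0.9 * delta][1]
    if (!is.na(t10) && !is.na(t90) && t[t90] >= t[t10]) {
      rise_t <- t[t90] - t[t10]
    }
    after_peak <- seq(i_peak, n)
    d90 <- after_peak[x[after_peak] <= b_mean + 0.9 * delta][1]
    d10 <- after_peak[x[after_peak] <= b_mean + 0.1 * delta][1]
    if (!is.na(d90) && !is.na(d10) && t[d10] >= t[d90]) {
      decay_t <- t[d10] - t[d90]
    }
  }

  piecewise_res <- unlist(lapply(list(ib, ie, ir), function(idx) {
    if (sum(idx) < 2) return(numeric(0))
    sl <- ls_slope(t[idx], x[idx])
    ic <- mean(x[idx]) - sl * mean(t[idx])
    x[idx] - (ic + sl * t[idx])
  }))
  sd_x <- stats::sd(x)
  sd_d1 <- stats::sd(d1)
  sd_d2 <- stats::sd(d2)
  mobility <- if (sd_x < .Machine$double.eps) 0 else sd_d1 / sd_x
  mobility_d1 <- if (sd_d1 < .Machine$double.eps) 0 else sd_d2 / sd_d1
  complexity <- if (mobility < .Machine$double.eps) 0 else mobility_d1 / mobility
  ac <- acf_at(x, c(1L, 5L, 10L, 20L))

  out <- c(out,
    time_baseline_mean = b_mean,
    time_baseline_slope = pslope(ib),
    time_baseline_area = parea(ib),
    time_exposure_mean = pmean(ie),
    time_exposure_slope = pslope(ie),
    time_exposure_area = parea(ie),
    time_recovery_mean = pmean(ir),
    time_recovery_slope = pslope(ir),
    time_recovery_area = parea(ir),
    time_max_slope = max(d1),
    time_min_slope = min(d1),
    time_argmax_s = t[i_peak],
    time_argmin_s = t[which.min(x)],
    time_rise_10_90 = rise_t,
    time_decay_90_10 = decay_t,
    time_peak_minus_baseline = delta,
    time_to_peak_s = t[i_peak] - timeline$fan_on,
    time_exposure_baseline_ratio = safe_ratio(pmean(ie), b_mean),
    time_recovery_exposure_ratio = safe_ratio(pmean(ir), pmean(ie)),
    time_d1_mean = mean(d1),
    time_d1_sd = sd_d1,
    time_d1_max = max(d1),
    time_d1_min = min(d1),
    time_d1_skewness = moment_skewness(d1),
    time_d2_mean = mean(d2),
    time_d2_sd = sd_d2,
    time_d2_max_abs = max(abs(d2)),
    time_acf_lag1 = ac[1], time_acf_lag5 = ac[2],
    time_acf_lag10 = ac[3], time_acf_lag20 = ac[4],
    time_piecewise_rms = if (length(piecewise_res)) {
      sqrt(mean(piecewise_res^2))
    } else 0,
    time_line_length = sum(abs(diff(x))),
    time_hjorth_mobility = mobility,
    time_hjorth_complexity = complexity
  )

  ## --- frequency-domain block (mean-removed periodogram) ------------------
  xc <- x - m
  spec <- abs(stats::fft(xc))^2 / n
  nf <- floor(n / 2)
  P <- spec[2:(nf + 1L)]                 # positive frequencies, DC removed
  f <- (seq_len(nf)) / (n * dt)
  total <- sum(P)

  # 8 log-spaced bands from the fundamental to Nyquist
  edges <- exp(seq(log(f[1]), log(f[nf]), length.out = 9L))
  band <- pmin(pmax(findInterval(f, edges, rightmost.closed = TRUE), 1L), 8L)
  bp <- vapply(1:8, function(k) sum(P[band == k]), numeric(1))
  rel <- if (total < .Machine$double.eps) rep(0, 8) else bp / total

  if (total < .Machine$double.eps) {
    centroid <- spread <- f_skew <- f_kurt <- flat <- ent <- 0
    roll85 <- roll95 <- dominant <- 0
  } else {
    p <- P / total
    centroid <- sum(f * p)
    spread <- sqrt(sum((f - centroid)^2 * p))
    if (spread < .Machine$double.eps) {
      f_skew <- f_kurt <- 0
    } else {
      f_skew <- sum(((f - centroid) / spread)^3 * p)
      f_kurt <- sum(((f - centroid) / spread)^4 * p) - 3
    }
    tiny <- 1e-300
    flat <- exp(mean(log(P + tiny))) / (mean(P) + tiny)
    pp <- p[p > 0]
    ent <- -sum(pp * log(pp))
    cs <- cumsum(P)
    roll85 <- f[which(cs >= 0.85 * total)[1]]
    roll95 <- f[which(cs >= 0.95 * total)[1]]
    dominant <- f[which.max(P)]
  }
  out <- c(out,
    stats::setNames(bp, paste0("freq_band_power_", 1:8)),
    stats::setNames(rel, paste0("freq_rel_power_", 1:8)),
    freq_centroid = centroid,
    freq_spread = spread,
    freq_skewness = f_skew,
    freq_kurtosis = f_kurt,
    freq_flatness = flat,
    freq_entropy = ent,
    freq_rolloff_85 = roll85,
    freq_rolloff_95 = roll95,
    freq_dominant = dominant
  )
  reg <- feature_registry()$feature
  out <- out[reg]
  if (any(!is.finite(out))) {
    bad <- reg[!is.finite(out)]
    stop("non-finite feature value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Extract the 85 features of every signal
#'
#' @param signals Preprocessed long signal tibble.
#' @param timeline An [measurement_timeline()]; anchors the phase features.
#' @return A wide tibble: the signal key columns (`sample_id`,
#'   `measurement`, `sensor_id`, `batch_id` — whichever are present) followed
#'   by the 85 registry features in order.
#' @examples
#' cohort <- generate_cohort(generator_config(
#'   n_per_class = c("healthy" = 1, "OC-I" = 1), seed = 1))
#' feats <- cohort$signals |> preprocess_signals() |> extract_features()
#' dim(feats)
#' @export
extract_features <- function(signals, timeline = measurement_timeline()) {
  check_signals(signals)
  keys <- signal_keys(signals)
  grp <- interaction(signals[keys], drop = TRUE, lex.order = TRUE)
  pieces <- split(seq_len(nrow(signals)), grp)
  feat <- matrix(NA_real_, nrow = length(pieces),
                 ncol = nrow(feature_registry()),
                 dimnames = list(NULL, feature_registry()$feature))
  key_rows <- integer(length(pieces))
  for (i in seq_along(pieces)) {
    idx <- pieces[[i]]
    ord <- idx[order(signals$time_s[idx])]
    feat[i, ] <- extract_signal_features(signals$voltage_v[ord],
                                         signals$time_s[ord], timeline)
    key_rows[i] <- idx[1]
  }
  dplyr::bind_cols(signals[key_rows, keys, drop = FALSE],
                   tibble::as_tibble(feat))
}

#' Assemble a labelled feature dataset for one binary task
#'
#' Joins a feature table to sample metadata, restricts rows to the samples a
#' task concerns, and attaches the binary label. Tasks mirror the cascade
#' stages: cancer-vs-healthy, ovarian-vs-endometrial (cancer samples only),
#' and stage I vs II-IV within one cancer type.
#'
#' @param features Wide feature tibble from [extract_features()].
#' @param meta Sample metadata tibble (from [generate_cohort()] or
#'   [read_signals()]).
#' @param task One of `"cancer_vs_healthy"`, `"oc_vs_ec"`, `"oc_stage"`,
#'   `"ec_stage"`.
#' @return The feature tibble restricted to the task's samples, with `label`
#'   (character) and `y` (+1 positive / -1 negative) columns inserted after
#'   the keys. Attributes `task`, `positive` and `negative` record the label
#'   coding.
#' @export
build_dataset <- function(features, meta,
                          task = c("cancer_vs_healthy", "oc_vs_ec",
                                   "oc_stage", "ec_stage")) {
  task <- match.arg(task)
  orphans <- setdiff(unique(features$sample_id), meta$sample_id)
  if (length(orphans)) {
    stop("signals without metadata for sample id(s): ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::left_join(
    features,
    dplyr::select(meta, "sample_id", "cohort", "cancer_type", "stage_group"),
    by = "sample_id"
  )
  spec_ <- switch(task,
    cancer_vs_healthy = list(
      keep = rep(TRUE, nrow(joined)),
      label = joined$cohort, positive = "cancer", negative = "healthy"),
    oc_vs_ec = list(
      keep = joined$cohort == "cancer",
      label = joined$cancer_type, positive = "ovarian",
      negative = "endometrial"),
    oc_stage = list(
      keep = joined$cancer_type == "ovarian",
      label = joined$stage_group, positive = "II-IV", negative = "I"),
    ec_stage = list(
      keep = joined$cancer_type == "endometrial",
      label = joined$stage_group, positive = "II-IV", negative = "I")
  )
  out <- joined[spec_$keep, , drop = FALSE]
  lab <- spec_$label[spec_$keep]
  keys <- signal_keys(features)
  out <- out |>
    dplyr::mutate(label = lab,
                  y = ifelse(lab == spec_$positive, 1, -1),
                  .after = dplyr::all_of(keys)) |>
    dplyr::select(-"cohort", -"cancer_type", -"stage_group")
  attr(out, "task") <- task
  attr(out, "positive") <- spec_$positive
  attr(out, "negative") <- spec_$negative
  out
}

dataset_feature_names <- function(dataset) {
  intersect(feature_registry()$feature, names(dataset))
}

#' Iteratively remove redundant (highly correlated) features
#'
#' While any pair of retained features has an absolute Pearson correlation
#' above `threshold` on the supplied (training) rows, the pair member with
#' the smaller absolute point-biserial correlation to the training label is
#' dropped (ties drop the later registry entry). Zero-variance features carry
#' no information and break the correlation, so they are dropped up front.
#' The returned kept-list is a pure function of the training rows and must be
#' applied unchanged to validation/test rows.
#'
#' @param dataset A labelled dataset from [build_dataset()] — training rows
#'   only.
#' @param threshold Absolute-correlation threshold in (0, 1].
#' @return A list: `kept` (character vector of retained feature names, in
#'   registry order), `dropped` (named character vector, reason per dropped
#'   feature), `dataset` (the input restricted to kept features).
#' @export
remove_redundant <- function(dataset, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  }
  feats <- dataset_feature_names(dataset)
  X <- as.matrix(dataset[feats])
  if (nrow(X) < 2) stop("need at least 2 rows", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  dropped <- character(0)
  const <- sds < .Machine$double.eps
  if (all(const)) {
    warning("all features are constant on the training rows; nothing kept",
            call. = FALSE)
    return(list(kept = character(0),
                dropped = stats::setNames(rep("constant", length(feats)), feats),
                dataset = dataset[setdiff(names(dataset), feats)]))
  }
  if (any(const)) {
    dropped <- c(dropped, stats::setNames(rep("constant", sum(const)),
                                          feats[const]))
  }
  keep_idx <- which(!const)
  C <- abs(stats::cor(X[, keep_idx, drop = FALSE]))
  diag(C) <- 0
  y01 <- as.numeric(dataset$y == 1)
  pb <- abs(apply(X[, keep_idx, drop = FALSE], 2,
                  function(col) {
                    r <- suppressWarnings(stats::cor(col, y01))
                    if (is.na(r)) 0 else r
                  }))
  alive <- rep(TRUE, length(keep_idx))
  while (TRUE) {
    Cm <- C
    Cm[!alive, ] <- 0
    Cm[, !alive] <- 0
    mx <- max(Cm)
    if (mx <= threshold) break
    hit <- which(Cm == mx, arr.ind = TRUE)
    # deterministic pair choice: largest |r|, then earliest registry indices
    hit <- hit[order(pmin(hit[, 1], hit[, 2]), pmax(hit[, 1], hit[, 2])), ,
               drop = FALSE]
    i <- min(hit[1, ]); j <- max(hit[1, ])
    drop_j <- pb[j] < pb[i] || (pb[j] == pb[i])  # tie: drop later entry
    victim <- if (drop_j) j else i
    alive[victim] <- FALSE
    dropped <- c(dropped, stats::setNames(
      sprintf("|r|=%.3f with %s", mx,
              feats[keep_idx[if (drop_j) i else j]]),
      feats[keep_idx[victim]]))
  }
  kept <- feats[sort(keep_idx[alive])]
  list(kept = kept, dropped = dropped,
       dataset = dataset[c(setdiff(names(dataset), feats), kept)])
}
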