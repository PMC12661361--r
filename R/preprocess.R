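#' Preprocessing configuration
#'
#' Fixes the per-signal preprocessing contract. The pipeline order is fixed:
#' align -> baseline-correct -> smooth -> normalize. Every step acts on one
#' signal at a time; no information crosses samples, so preprocessing can
#' never leak between training and test data.
#'
#' @param smoothing_window Odd moving-average window length in samples;
#'   `1` disables smoothing.
#' @param normalization `"baseline"` (relative response (V - V0)/V0 with V0
#'   the pre-fan baseline mean), `"minmax"` (per-signal map to \[0, 1\]) or
#'   `"none"`.
#' @param target_length Common signal length in samples after alignment;
#'   `NULL` keeps the native length (all signals must then agree already).
#'
#' @return An object of class `"preprocess_config"`.
#' @export
preprocess_config <- function(smoothing_window = 5L,
                              normalization = c("baseline", "minmax", "none"),
                              target_length = NULL) {
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 1L || smoothing_window %% 2L == 0L) {
    stop("`smoothing_window` must be an odd integer >= 1", call. = FALSE)
  }
  if (!is.null(target_length) && target_length < 2) {
    stop("`target_length` must be >= 2", call. = FALSE)
  }
  structure(
    list(smoothing_window = smoothing_window,
         normalization = match.arg(normalization),
         target_length = target_length),
    class = "preprocess_config"
  )
}

signal_keys <- function(signals) {
  intersect(c("sample_id", "measurement", "sensor_id", "batch_id"),
            names(signals))
}

check_signals <- function(signals) {
  need <- c("sample_id", "sensor_id", "time_s", "voltage_v")
  miss <- setdiff(need, names(signals))
  if (length(miss)) {
    stop("signal table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(signals)
}

#' Align all signals to a common length
#'
#' Shorter signals are linearly interpolated onto `target_length` evenly
#' spaced points spanning their own time range (endpoints preserved); longer
#' signals are truncated from the end.
#'
#' @param signals Long signal tibble (`sample_id`, `sensor_id`, `time_s`,
#'   `voltage_v`, optionally `measurement`, `batch_id`).
#' @param target_length Target number of samples per signal (>= 2).
#' @return Signal tibble in which every signal has `target_length` points.
#' @export
align_length <- function(signals, target_length) {
  check_signals(signals)
  if (target_length < 2) stop("`target_length` must be >= 2", call. = FALSE)
  keys <- signal_keys(signals)
  signals |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (n < 2) stop("every signal needs at least 2 points", call. = FALSE)
      if (n == target_length) return(df[c("time_s", "voltage_v")])
      if (n > target_length) {
        return(df[seq_len(target_length), c("time_s", "voltage_v")])
      }
      tt <- seq(df$time_s[1], df$time_s[n], length.out = target_length)
      tibble::tibble(time_s = tt,
                     voltage_v = stats::approx(df$time_s, df$voltage_v,
                                               xout = tt)$y)
    }) |>
    dplyr::ungroup()
}

baseline_window_mean <- function(time_s, voltage_v, fan_on) {
  in_win <- time_s < fan_on
  if (sum(in_win) < 2) {
    stop("baseline window [0, fan_on) must contain at least 2 samples",
         call. = FALSE)
  }
  mean(voltage_v[in_win])
}

#' Baseline-correct signals
#'
#' Subtracts, per signal, the mean voltage over the pre-fan baseline window
#' `[0, fan_on)`. The removed baseline mean is kept in a `baseline_v0`
#' column so baseline-relative normalization can use it later.
#'
#' @inheritParams align_length
#' @param timeline An [measurement_timeline()]; defines the baseline window.
#' @return Signal tibble with corrected `voltage_v` and a `baseline_v0`
#'   column.
#' @export
baseline_correct <- function(signals, timeline = measurement_timeline()) {
  check_signals(signals)
  keys <- signal_keys(signals)
  signals |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(
      baseline_v0 = baseline_window_mean(.data$time_s, .data$voltage_v,
                                         timeline$fan_on),
      voltage_v = .data$voltage_v - .data$baseline_v0
    ) |>
    dplyr::ungroup()
}

moving_average <- function(x, window) {
  if (window == 1L) return(x)
  n <- length(x)
  half <- (window - 1L) %/% 2L
  # centered moving average with shrinking window at the edges
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth signals with a centered moving average
#'
#' @inheritParams align_length
#' @param window Odd window length in samples; `1` is the identity. Edges are
#'   handled by shrinking the window, so signal length is preserved.
#' @return Smoothed signal tibble.
#' @export
smooth_signals <- function(signals, window = 5L) {
  check_signals(signals)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 1", call. = FALSE)
  }
  if (window == 1L) return(signals)
  keys <- signal_keys(signals)
  signals |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(voltage_v = moving_average(.data$voltage_v, window)) |>
    dplyr::ungroup()
}

#' Normalize signals per signal
#'
#' * `"minmax"`: maps each signal's range onto \[0, 1\]; a constant signal
#'   maps to all zeros (stated degenerate policy, keeps downstream features
#'   finite).
#' * `"baseline"`: relative response (V - V0)/V0 where V0 is the pre-fan
#'   baseline mean of the raw trace. On a baseline-corrected input (with a
#'   `baseline_v0` column) this is `voltage_v / baseline_v0`; on a raw input
#'   the baseline mean is computed from `timeline`.
#' * `"none"`: identity.
#'
#' @inheritParams align_length
#' @param mode Normalization mode.
#' @param timeline Needed for `"baseline"` mode on raw (uncorrected) input.
#' @return Normalized signal tibble.
#' @export
normalize_signals <- function(signals, mode = c("baseline", "minmax", "none"),
                              timeline = measurement_timeline()) {
  check_signals(signals)
  mode <- match.arg(mode)
  if (mode == "none") return(signals)
  keys <- signal_keys(signals)
  if (mode == "minmax") {
    return(
      signals |>
        dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
        dplyr::mutate(voltage_v = {
          r <- range(.data$voltage_v)
          if (diff(r) < .Machine$double.eps * max(1, abs(r[2]))) {
            rep(0, length(.data$voltage_v))
          } else {
            (.data$voltage_v - r[1]) / diff(r)
          }
        }) |>
        dplyr::ungroup()
    )
  }
  # baseline-relative
  if ("baseline_v0" %in% names(signals)) {
    out <- signals |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::mutate(voltage_v = {
        if (abs(.data$baseline_v0[1]) < 1e-12) {
          stop("baseline-relative normalization needs a nonzero baseline mean",
               call. = FALSE)
        }
        .data$voltage_v / .data$baseline_v0
      }) |>
      dplyr::ungroup()
    return(out)
  }
  signals |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(voltage_v = {
      v0 <- baseline_window_mean(.data$time_s, .data$voltage_v,
                                 timeline$fan_on)
      if (abs(v0) < 1e-12) {
        stop("baseline-relative normalization needs a nonzero baseline mean",
             call. = FALSE)
      }
      (.data$voltage_v - v0) / v0
    }) |>
    dplyr::ungroup()
}

#' Run the full preprocessing pipeline
#'
#' Fixed order: align -> baseline-correct -> smooth -> normalize.
#'
#' @inheritParams align_length
#' @param timeline An [measurement_timeline()].
#' @param config A [preprocess_config()].
#' @return Preprocessed signal tibble (with `baseline_v0` column).
#' @examples
#' cohort <- generate_cohort(generator_config(
#'   n_per_class = c("healthy" = 1, "OC-I" = 1), seed = 1))
#' pp <- preprocess_signals(cohort$signals)
#' @export
preprocess_signals <- function(signals, timeline = measurement_timeline(),
                               config = preprocess_config()) {
  check_signals(signals)
  out <- signals
  if (!is.null(config$target_length)) {
    out <- align_length(out, config$target_length)
  }
  out <- baseline_correct(out, timeline)
  if (config$smoothing_window > 1L) {
    out <- smooth_signals(out, config$smoothing_window)
  }
  if (config$normalization != "none") {
    out <- normalize_signals(out, config$normalization, timeline)
  }
  out
}
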