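#' Default class response profiles for the synthetic cohort
#'
#' Phenomenological response profiles for the five diagnostic classes
#' (healthy, ovarian cancer stage I, ovarian cancer stage II-IV, endometrial
#' cancer stage I, endometrial cancer stage II-IV). Each class is described by
#' a per-sensor response amplitude (volts) and class-level rise/decay time
#' constants (seconds); disease classes differ from healthy both in amplitude
#' (a class-specific multiplicative shift on each discriminative sensor) and
#' in kinetics, so that class identity is encoded in signal shape as well as
#' magnitude. Sensors flagged non-discriminative in `sensors` inherit the
#' healthy profile in every class: their response carries no class
#' information by construction.
#'
#' @param sensors A sensor table from [sensor_array()].
#' @param amplitude_shift Named numeric: per-class multiplicative amplitude
#'   shift applied to discriminative sensors (0 = identical to healthy).
#' @param rise_tau,decay_tau Named numeric: per-class rise/decay time
#'   constants in seconds.
#' @param baseline_voltage Baseline (clean-air) voltage common to all sensors
#'   before sensor- and batch-level offsets.
#'
#' @return A tibble with one row per (class, sensor): `class_label`,
#'   `sensor_id`, `amplitude`, `rise_tau`, `decay_tau`, `baseline`.
#' @examples
#' profiles <- class_profiles(sensor_array())
#' dplyr::count(profiles, class_label)
#' @export
class_profiles <- function(sensors = sensor_array(),
                           amplitude_shift = c("healthy" = 0,
                                               "OC-I" = 0.25,
                                               "OC-II-IV" = 0.45,
                                               "EC-I" = -0.20,
                                               "EC-II-IV" = -0.35),
                           rise_tau = c("healthy" = 25,
                                        "OC-I" = 18,
                                        "OC-II-IV" = 13,
                                        "EC-I" = 32,
                                        "EC-II-IV" = 40),
                           decay_tau = c("healthy" = 60,
                                         "OC-I" = 45,
                                         "OC-II-IV" = 36,
                                         "EC-I" = 75,
                                         "EC-II-IV" = 90),
                           baseline_voltage = 2) {
  stopifnot(identical(sort(names(amplitude_shift)), sort(names(rise_tau))),
            identical(sort(names(rise_tau)), sort(names(decay_tau))))
  if (any(rise_tau <= 0) || any(decay_tau <= 0)) {
    stop("time constants must be positive", call. = FALSE)
  }
  classes <- names(amplitude_shift)
  n <- nrow(sensors)
  # fixed deterministic per-sensor structure: base amplitude pattern and a
  # sensitivity gain bounded away from zero so every discriminative sensor
  # carries class signal
  base_amp <- 0.8 + 0.35 * sin(seq_len(n) * 0.9)
  gain <- 0.55 + 0.45 * abs(cos(seq_len(n) * 0.55))
  # bank temperature scales amplitude up and speeds kinetics slightly
  temp01 <- (sensors$operating_temperature - min(sensors$operating_temperature)) /
    max(diff(range(sensors$operating_temperature)), 1)
  amp_scale <- 0.85 + 0.3 * temp01
  # kinetics vary mildly with bank temperature; the spread is kept small
  # enough that the class-level time-constant bands stay disjoint across
  # banks (signals are classified sensor-anonymously, so shape carries the
  # class signal that pooled amplitudes cannot)
  tau_scale <- 1.08 - 0.16 * temp01

  purrr::map_dfr(classes, function(cl) {
    disc <- sensors$discriminative
    amp <- base_amp * amp_scale * (1 + amplitude_shift[[cl]] * gain)
    rt <- rise_tau[[cl]] * tau_scale
    dt <- decay_tau[[cl]] * tau_scale
    # non-discriminative sensors respond exactly as in the healthy class
    amp[!disc] <- (base_amp * amp_scale * (1 + amplitude_shift[["healthy"]] * gain))[!disc]
    rt[!disc] <- (rise_tau[["healthy"]] * tau_scale)[!disc]
    dt[!disc] <- (decay_tau[["healthy"]] * tau_scale)[!disc]
    tibble::tibble(
      class_label = cl,
      sensor_id = sensors$sensor_id,
      amplitude = amp,
      rise_tau = rt,
      decay_tau = dt,
      baseline = baseline_voltage + 0.1 * sin(sensors$sensor_id * 1.7)
    )
  })
}

#' Generator configuration for a synthetic e-nose cohort
#'
#' @param n_per_class Named integer vector: samples per class. Names must
#'   match the class labels of the profile table. The default emulates a
#'   balanced desk-scale cohort of 60 subjects.
#' @param noise_sd Standard deviation (volts) of additive Gaussian sensor
#'   noise.
#' @param drift_range Length-2 numeric (volts/second): per-signal linear
#'   baseline drift slope is drawn uniformly from this interval.
#' @param batch_offset,batch_gain Numeric vectors (one entry per batch):
#'   additive voltage offset and multiplicative gain applied to every signal
#'   of a batch (lab/site effects). Defaults define 3 batches.
#' @param duplicate_fraction Fraction of samples measured in duplicate
#'   (two full 32-sensor measurements). Default 0: one measurement each.
#' @param seed Integer master seed; the whole cohort is reproducible from it.
#'
#' @return An object of class `"enose_config"` (a named list).
#' @examples
#' generator_config(seed = 7)
#' @export
generator_config <- function(n_per_class = c("healthy" = 20L, "OC-I" = 10L,
                                             "OC-II-IV" = 10L, "EC-I" = 10L,
                                             "EC-II-IV" = 10L),
                             noise_sd = 0.005,
                             drift_range = c(-2e-5, 2e-5),
                             batch_offset = c(0, 0.05, -0.04),
                             batch_gain = c(1, 1.03, 0.97),
                             duplicate_fraction = 0,
                             seed = 1L) {
  stopifnot(all(n_per_class >= 1), noise_sd >= 0,
            length(drift_range) == 2, drift_range[1] <= drift_range[2],
            length(batch_offset) == length(batch_gain),
            length(batch_offset) >= 1,
            duplicate_fraction >= 0, duplicate_fraction <= 1)
  if (is.null(names(n_per_class))) {
    stop("`n_per_class` must be named by class label", call. = FALSE)
  }
  structure(
    list(n_per_class = n_per_class, noise_sd = noise_sd,
         drift_range = drift_range, batch_offset = batch_offset,
         batch_gain = batch_gain, duplicate_fraction = duplicate_fraction,
         seed = as.integer(seed)),
    class = "enose_config"
  )
}

#' Simulate one sensor's voltage-time response
#'
#' Double-exponential exposure/recovery kinetics: the trace sits at
#' `baseline` until the fan starts, rises towards `baseline + amplitude` with
#' time constant `rise_tau` during exposure, and decays back towards baseline
#' with time constant `decay_tau` after sample removal. Additive Gaussian
#' noise and a linear drift are superimposed.
#'
#' @param amplitude Saturating response amplitude (volts).
#' @param rise_tau,decay_tau Rise/decay time constants (seconds), positive.
#' @param baseline Baseline voltage (volts).
#' @param timeline An [measurement_timeline()].
#' @param noise_sd Gaussian noise standard deviation (volts).
#' @param drift Linear drift slope (volts/second).
#' @param seed Optional integer; when given, the noise draw is seeded locally
#'   so the trace is reproducible in isolation.
#'
#' @return Numeric vector of voltages on [timeline_times()].
#' @examples
#' tl <- measurement_timeline()
#' v <- response_curve(1, 10, 40, 2, tl, noise_sd = 0, drift = 0)
#' mean(v[timeline_times(tl) >= 300 & timeline_times(tl) < 360]) # ~ 3 V
#' @export
response_curve <- function(amplitude, rise_tau, decay_tau, baseline,
                           timeline = measurement_timeline(),
                           noise_sd = 0, drift = 0, seed = NULL) {
  if (rise_tau <= 0 || decay_tau <= 0) {
    stop("`rise_tau` and `decay_tau` must be positive", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  t <- timeline_times(timeline)
  resp <- numeric(length(t))
  expo <- t >= timeline$fan_on & t < timeline$sample_removed
  rec <- t >= timeline$sample_removed
  resp[expo] <- amplitude * (1 - exp(-(t[expo] - timeline$fan_on) / rise_tau))
  peak <- amplitude *
    (1 - exp(-(timeline$sample_removed - timeline$fan_on) / rise_tau))
  resp[rec] <- peak * exp(-(t[rec] - timeline$sample_removed) / decay_tau)
  noise <- if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    stats::rnorm(length(t), 0, noise_sd)
  } else {
    0
  }
  baseline + resp + drift * t + noise
}

# deterministic child-seed derivation; keeps every derived seed < 2^31
derive_seed <- function(master, k) {
  as.integer((as.double(master) * 48271 + as.double(k) * 16807) %% 2147483587) + 1L
}

#' Generate a synthetic e-nose cohort
#'
#' Simulates a full cohort: every sample is measured once (or in duplicate,
#' see `duplicate_fraction`) on every sensor of the array, samples are
#' assigned round-robin to measurement batches, and batch offset/gain, linear
#' drift and Gaussian noise are applied to each trace. Ground-truth labels
#' are returned alongside, so downstream stages can be tested against known
#' structure.
#'
#' @param config A [generator_config()].
#' @param profiles A profile table from [class_profiles()].
#' @param sensors The sensor table the profiles were built for.
#' @param timeline An [measurement_timeline()].
#'
#' @return A list with two tibbles:
#'   * `signals`: long format, one row per time point —
#'     `sample_id`, `sensor_id`, `batch_id`, `time_s`, `voltage_v`;
#'   * `meta`: one row per sample — `sample_id`, `cohort`
#'     (healthy/cancer), `cancer_type` (ovarian/endometrial/none),
#'     `stage_group` (I, II-IV, none), `class_label`, `batch_id`,
#'     `n_measurements`.
#' @examples
#' cfg <- generator_config(n_per_class = c("healthy" = 2, "OC-I" = 2), seed = 1)
#' cohort <- generate_cohort(cfg)
#' dplyr::n_distinct(cohort$signals$sample_id)
#' @export
generate_cohort <- function(config = generator_config(),
                            profiles = class_profiles(sensors),
                            sensors = sensor_array(),
                            timeline = measurement_timeline()) {
  classes <- names(config$n_per_class)
  missing_cls <- setdiff(classes, unique(profiles$class_label))
  if (length(missing_cls)) {
    stop("no profile for class(es): ", paste(missing_cls, collapse = ", "),
         call. = FALSE)
  }
  n_batches <- length(config$batch_offset)
  t <- timeline_times(timeline)

  meta <- purrr::map_dfr(classes, function(cl) {
    n <- config$n_per_class[[cl]]
    tibble::tibble(
      class_label = cl,
      sample_id = sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "", cl), seq_len(n))
    )
  })
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample ids generated", call. = FALSE)
  }
  meta <- meta |>
    dplyr::mutate(
      cohort = ifelse(.data$class_label == "healthy", "healthy", "cancer"),
      cancer_type = dplyr::case_when(
        startsWith(.data$class_label, "OC") ~ "ovarian",
        startsWith(.data$class_label, "EC") ~ "endometrial",
        TRUE ~ "none"
      ),
      stage_group = dplyr::case_when(
        grepl("II-IV$", .data$class_label) ~ "II-IV",
        grepl("-I$", .data$class_label) ~ "I",
        TRUE ~ "none"
      ),
      batch_id = ((dplyr::row_number() - 1L) %% n_batches) + 1L
    )

  # duplicate measurements (optional): first ceiling(frac * n) samples
  n_dup <- ceiling(config$duplicate_fraction * nrow(meta))
  meta$n_measurements <- ifelse(seq_len(nrow(meta)) <= n_dup, 2L, 1L)

  prof_key <- profiles |>
    dplyr::arrange(.data$class_label, .data$sensor_id)

  signal_list <- vector("list", sum(meta$n_measurements) * nrow(sensors))
  idx <- 0L
  for (i in seq_len(nrow(meta))) {
    cl <- meta$class_label[i]
    b <- meta$batch_id[i]
    prof <- prof_key[prof_key$class_label == cl, ]
    for (m in seq_len(meta$n_measurements[i])) {
      set.seed(derive_seed(config$seed, i * 1000L + m))
      drifts <- stats::runif(nrow(sensors), config$drift_range[1],
                             config$drift_range[2])
      for (s in seq_len(nrow(sensors))) {
        p <- prof[s, ]
        clean <- response_curve(p$amplitude, p$rise_tau, p$decay_tau,
                                p$baseline, timeline, noise_sd = 0, drift = 0)
        v <- config$batch_offset[b] + config$batch_gain[b] * clean +
          drifts[s] * t +
          stats::rnorm(length(t), 0, config$noise_sd)
        idx <- idx + 1L
        signal_list[[idx]] <- tibble::tibble(
          sample_id = meta$sample_id[i],
          measurement = m,
          sensor_id = sensors$sensor_id[s],
          batch_id = b,
          time_s = t,
          voltage_v = v
        )
      }
    }
  }
  signals <- dplyr::bind_rows(signal_list)
  # duplicate measurements share the parent sample_id; the `measurement`
  # column keeps the replicates distinct, and grouping by sample_id keeps
  # them in the same CV fold / vote pool downstream
  meta <- dplyr::select(meta, "sample_id", "cohort", "cancer_type",
                        "stage_group", "class_label", "batch_id",
                        "n_measurements")
  list(signals = signals, meta = meta)
}
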