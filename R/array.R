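#' Describe a MOS sensor array
#'
#' Builds the sensor table for a metal-oxide-semiconductor (MOS) gas-sensor
#' array arranged in temperature-controlled banks. The default mirrors the
#' instrument this package models: 32 sensors in 4 banks of 8, with bank
#' operating temperatures spanning 200-400 degrees Celsius. Bank temperature
#' enters the synthetic generator as a mild scaling of response amplitude and
#' kinetics; no sensor chemistry is modelled.
#'
#' @param n_banks Number of temperature banks.
#' @param sensors_per_bank Number of sensors in each bank.
#' @param temperature_range Length-2 numeric, the operating temperatures (deg C)
#'   of the first and last bank; intermediate banks are evenly spaced.
#' @param non_discriminative Integer sensor ids whose response is planted to be
#'   identical across classes (useful ground truth for sensor-utility tests).
#'   Default: sensors 17 and 25.
#'
#' @return A tibble with one row per sensor: `sensor_id`, `bank_id`,
#'   `operating_temperature`, `discriminative`.
#' @examples
#' sensor_array()
#' sensor_array(n_banks = 2, sensors_per_bank = 3, non_discriminative = 5)
#' @export
sensor_array <- function(n_banks = 4L,
                         sensors_per_bank = 8L,
                         temperature_range = c(200, 400),
                         non_discriminative = c(17L, 25L)) {
  stopifnot(n_banks >= 1, sensors_per_bank >= 1, length(temperature_range) == 2)
  n <- n_banks * sensors_per_bank
  if (!all(non_discriminative %in% seq_len(n)) && length(non_discriminative) > 0) {
    stop("`non_discriminative` must be sensor ids in 1..", n, call. = FALSE)
  }
  temps <- if (n_banks == 1) {
    mean(temperature_range)
  } else {
    seq(temperature_range[1], temperature_range[2], length.out = n_banks)
  }
  tibble::tibble(
    sensor_id = seq_len(n),
    bank_id = rep(seq_len(n_banks), each = sensors_per_bank),
    operating_temperature = temps[rep(seq_len(n_banks), each = sensors_per_bank)],
    discriminative = !(seq_len(n) %in% non_discriminative)
  )
}

#' Define the measurement timeline of one e-nose run
#'
#' A measurement records each sensor's voltage over `duration` seconds. The
#' sample sits in the holder from the start; at `fan_on` a downstream fan
#' starts transporting headspace VOCs to the sensors (response onset); at
#' `sample_removed` the sample is taken out (recovery onset); at `fan_off`
#' the fan stops. The three analysis phases derived from the timeline are
#' baseline `[0, fan_on)`, exposure `[fan_on, sample_removed)` and recovery
#' `[sample_removed, duration)`.
#'
#' @param duration Total recording length in seconds.
#' @param fan_on Fan start time (s); response onset.
#' @param sample_removed Sample removal time (s); recovery onset.
#' @param fan_off Fan stop time (s).
#' @param sampling_interval Sampling interval in seconds; must divide
#'   `duration` evenly.
#'
#' @return An object of class `"enose_timeline"` (a named list).
#' @examples
#' measurement_timeline()
#' @export
measurement_timeline <- function(duration = 600,
                                 fan_on = 40,
                                 sample_removed = 360,
                                 fan_off = 500,
                                 sampling_interval = 1) {
  if (!(0 < fan_on && fan_on < sample_removed && sample_removed < fan_off &&
        fan_off <= duration)) {
    stop("timeline must satisfy 0 < fan_on < sample_removed < fan_off <= duration",
         call. = FALSE)
  }
  if (sampling_interval <= 0 ||
      abs(duration / sampling_interval - round(duration / sampling_interval)) > 1e-9) {
    stop("`sampling_interval` must be positive and divide `duration`", call. = FALSE)
  }
  structure(
    list(duration = duration, fan_on = fan_on, sample_removed = sample_removed,
         fan_off = fan_off, sampling_interval = sampling_interval),
    class = "enose_timeline"
  )
}

#' @export
print.enose_timeline <- function(x, ...) {
  cat(sprintf(
    "<enose_timeline> %gs @ %g Hz | fan on %gs, sample out %gs, fan off %gs\n",
    x$duration, 1 / x$sampling_interval, x$fan_on, x$sample_removed, x$fan_off
  ))
  invisible(x)
}

#' Time axis of a timeline
#'
#' @param timeline An `enose_timeline`.
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
timeline_times <- function(timeline) {
  seq(0, timeline$duration - timeline$sampling_interval,
      by = timeline$sampling_interval)
}

#' Phase of each time point
#'
#' @param times Numeric vector of times in seconds.
#' @param timeline An `enose_timeline`.
#' @return Character vector: `"baseline"`, `"exposure"` or `"recovery"`.
#' @export
timeline_phase <- function(times, timeline) {
  dplyr::case_when(
    times < timeline$fan_on ~ "baseline",
    times < timeline$sample_removed ~ "exposure",
    TRUE ~ "recovery"
  )
}
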