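test_that("sensor array has the expected bank structure", {
  arr <- sensor_array()
  expect_equal(nrow(arr), 32L)
  expect_equal(unname(table(arr$bank_id)), rep(8L, 4L),
               ignore_attr = TRUE)
  expect_false(anyDuplicated(arr$sensor_id) > 0)
  expect_equal(range(arr$operating_temperature), c(200, 400))
  # temperature constant within a bank
  expect_true(all(tapply(arr$operating_temperature, arr$bank_id,
                         function(x) length(unique(x))) == 1))
  expect_equal(arr$sensor_id[!arr$discriminative], c(17L, 25L))
})

test_that("timeline validation enforces event ordering and sampling", {
  expect_s3_class(measurement_timeline(), "enose_timeline")
  expect_error(measurement_timeline(fan_on = 400, sample_removed = 360),
               "fan_on")
  expect_error(measurement_timeline(sampling_interval = 7), "divide")
  expect_length(timeline_times(measurement_timeline()), 600L)
})

test_that("response curve is flat at zero amplitude and follows the
           saturating exponential", {
  tl <- measurement_timeline()
  t <- timeline_times(tl)
  flat <- response_curve(0, 10, 40, 2, tl, noise_sd = 0, drift = 0)
  expect_equal(flat, rep(2, length(t)))

  # closed form: amplitude 1 V, rise tau 10 s -> by 300 s the exposure term
  # 1 - exp(-(t - 40)/10) is saturated, so the 300-360 s window mean sits at
  # baseline + 1 V
  v <- response_curve(1, 10, 40, 2, tl, noise_sd = 0, drift = 0)
  win <- t >= 300 & t < 360
  expect_lt(abs(mean(v[win]) - 3), 0.01)
  # exact closed form at a mid-exposure point
  expect_equal(v[t == 100], 2 + (1 - exp(-60 / 10)))

  expect_error(response_curve(1, -1, 40, 2, tl), "positive")
  expect_error(response_curve(1, 10, 0, 2, tl), "positive")
})

test_that("response curve noise is reproducible under a fixed seed", {
  tl <- tiny_timeline()
  a <- response_curve(1, 10, 40, 2, tl, noise_sd = 0.05, seed = 7)
  b <- response_curve(1, 10, 40, 2, tl, noise_sd = 0.05, seed = 7)
  cc <- response_curve(1, 10, 40, 2, tl, noise_sd = 0.05, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, cc))
})

test_that("cohort generation yields the right counts and is deterministic", {
  sens <- small_array()
  cfg <- generator_config(
    n_per_class = c("healthy" = 5L, "OC-I" = 5L, "OC-II-IV" = 5L,
                    "EC-I" = 5L, "EC-II-IV" = 5L), seed = 3L)
  co <- generate_cohort(cfg, profiles = class_profiles(sens),
                        sensors = sens, timeline = tiny_timeline())
  expect_equal(nrow(co$meta), 25L)
  n_signals <- nrow(dplyr::distinct(
    co$signals, sample_id, measurement, sensor_id))
  expect_equal(n_signals, 25L * nrow(sens))
  co2 <- generate_cohort(cfg, profiles = class_profiles(sens),
                         sensors = sens, timeline = tiny_timeline())
  expect_identical(co, co2)
  # labels consistent with generating class
  expect_true(all(co$meta$cohort[co$meta$class_label == "healthy"] ==
                    "healthy"))
  expect_true(all(co$meta$stage_group[co$meta$class_label == "OC-II-IV"] ==
                    "II-IV"))
  expect_true(all(co$meta$cancer_type[startsWith(co$meta$class_label,
                                                 "EC")] == "endometrial"))
})

test_that("signal table invariants hold on generator output", {
  co <- small_cohort()
  expect_false(anyNA(co$signals$voltage_v))
  by_sig <- split(co$signals$time_s,
                  interaction(co$signals$sample_id, co$signals$sensor_id,
                              drop = TRUE))
  expect_true(all(vapply(by_sig, function(t) all(diff(t) > 0), logical(1))))
  expect_equal(unique(lengths(by_sig)),
               length(timeline_times(tiny_timeline())))
})

test_that("planted non-discriminative sensors are identical across classes", {
  sens <- sensor_array()
  prof <- class_profiles(sens)
  planted <- sens$sensor_id[!sens$discriminative]
  for (sid in planted) {
    sub <- prof[prof$sensor_id == sid, ]
    expect_equal(stats::var(sub$amplitude), 0)
    expect_equal(stats::var(sub$rise_tau), 0)
    expect_equal(stats::var(sub$decay_tau), 0)
  }
  # a discriminative sensor does vary
  sub <- prof[prof$sensor_id == 1L, ]
  expect_gt(stats::var(sub$amplitude), 0)
})

test_that("noise-free traces of planted sensors coincide across classes", {
  sens <- small_array()
  cfg <- generator_config(
    n_per_class = c("healthy" = 1L, "OC-II-IV" = 1L), noise_sd = 0,
    drift_range = c(0, 0), batch_offset = 0, batch_gain = 1, seed = 5L)
  co <- generate_cohort(cfg, profiles = class_profiles(sens),
                        sensors = sens, timeline = tiny_timeline())
  sig <- co$signals
  planted <- sens$sensor_id[!sens$discriminative]
  v_h <- sig$voltage_v[sig$sensor_id == planted &
                         startsWith(sig$sample_id, "healthy")]
  v_c <- sig$voltage_v[sig$sensor_id == planted &
                         startsWith(sig$sample_id, "OCIIIV")]
  expect_equal(v_h, v_c)
  # while a discriminative sensor differs by the configured amplitude gap
  v_h1 <- sig$voltage_v[sig$sensor_id == 1L &
                          startsWith(sig$sample_id, "healthy")]
  v_c1 <- sig$voltage_v[sig$sensor_id == 1L &
                          startsWith(sig$sample_id, "OCIIIV")]
  expect_gt(max(abs(v_h1 - v_c1)), 0.05)
})

test_that("batch offsets are recoverable from healthy baseline means", {
  # gains fixed at 1 so baseline-window batch means differ by the additive
  # offsets alone (up to noise Monte-Carlo error)
  cfg <- generator_config(
    n_per_class = c("healthy" = 9L), noise_sd = 0.005,
    drift_range = c(0, 0), batch_offset = c(0, 0.05, -0.04),
    batch_gain = c(1, 1, 1), seed = 9L)
  sens <- small_array()
  co <- generate_cohort(cfg, profiles = class_profiles(sens),
                        sensors = sens, timeline = tiny_timeline())
  sig <- co$signals[co$signals$time_s < tiny_timeline()$fan_on, ]
  bm <- tapply(sig$voltage_v, sig$batch_id, mean)
  expect_lt(abs(unname(bm[2] - bm[1]) - 0.05), 0.002)
  expect_lt(abs(unname(bm[3] - bm[1]) + 0.04), 0.002)
})

test_that("duplicate measurements share the sample id and double the rows", {
  sens <- small_array()
  cfg <- generator_config(n_per_class = c("healthy" = 2L, "OC-I" = 2L),
                          duplicate_fraction = 0.5, seed = 4L)
  co <- generate_cohort(cfg, profiles = class_profiles(sens),
                        sensors = sens, timeline = tiny_timeline())
  expect_equal(sum(co$meta$n_measurements == 2L), 2L)
  counts <- dplyr::count(
    dplyr::distinct(co$signals, sample_id, measurement,
                    sensor_id), sample_id)
  expect_setequal(counts$n, c(nrow(sens), 2L * nrow(sens)))
})

test_that("generator configuration is validated", {
  expect_error(generator_config(n_per_class = c(2, 3)), "named")
  expect_error(generator_config(noise_sd = -1))
  expect_error(generate_cohort(
    generator_config(n_per_class = c("unknown-class" = 2L)),
    profiles = class_profiles(small_array()), sensors = small_array(),
    timeline = tiny_timeline()), "no profile")
})
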