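# shared fixtures, built in code and memoised per test run

# short measurement timeline: same phase structure, fewer samples
tiny_timeline <- function() {
  measurement_timeline(duration = 120, fan_on = 10, sample_removed = 70,
                       fan_off = 100, sampling_interval = 1)
}

# 6-sensor array (2 banks x 3) with one planted non-discriminative sensor
small_array <- function() {
  sensor_array(n_banks = 2L, sensors_per_bank = 3L,
               non_discriminative = 5L)
}

memoise1 <- function(fn) {
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fn()
    cache
  }
}

# 16 samples x 6 sensors on the short timeline: fast structural fixture
small_cohort <- memoise1(function() {
  sens <- small_array()
  cfg <- generator_config(
    n_per_class = c("healthy" = 4L, "OC-I" = 3L, "OC-II-IV" = 3L,
                    "EC-I" = 3L, "EC-II-IV" = 3L),
    seed = 101L)
  generate_cohort(cfg, profiles = class_profiles(sens), sensors = sens,
                  timeline = tiny_timeline())
})

small_preprocessed <- memoise1(function() {
  preprocess_signals(small_cohort()$signals, tiny_timeline())
})

small_features <- memoise1(function() {
  extract_features(small_preprocessed(), tiny_timeline())
})

# synthetic labelled feature dataset with a cleanly separable feature and
# grouped rows (4 signals per sample); no generator involved
toy_dataset <- function(n_per_class = 10L, rows_per_sample = 4L, gap = 3,
                        noise = 0.3, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  meta <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)),
    label = rep(c("pos", "neg"), each = n_per_class)
  )
  rows <- meta[rep(seq_len(n), each = rows_per_sample), ]
  rows$y <- ifelse(rows$label == "pos", 1, -1)
  rows$f1 <- rows$y * gap / 2 + stats::rnorm(nrow(rows), 0, noise)
  rows$f2 <- stats::rnorm(nrow(rows))
  rows$f3 <- rows$f1 * 0.5 + stats::rnorm(nrow(rows), 0, noise)
  attr(rows, "positive") <- "pos"
  attr(rows, "negative") <- "neg"
  rows
}

# full-scale study cohort (32 sensors, 600-s timeline, 60 samples) used by
# the acceptance checks; memoised because generation + feature extraction
# take tens of seconds
study_cohort <- memoise1(function() {
  generate_cohort(generator_config(seed = 20260101L))
})

study_preprocessed <- memoise1(function() {
  preprocess_signals(study_cohort()$signals)
})

study_features <- memoise1(function() {
  extract_features(study_preprocessed())
})
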