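#' Write / read a cohort as plain delimited text
#'
#' Signals are stored long (`sample_id`, `measurement`, `sensor_id`,
#' `batch_id`, `time_s`, `voltage_v`), metadata as one row per sample. Both
#' files are plain TSV, re-readable by [read_signals()]; all pipeline
#' artifacts stay text for auditability.
#'
#' @param cohort A list with `signals` and `meta` tibbles (as returned by
#'   [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_signals <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig_path <- file.path(dir, "signals.tsv")
  meta_path <- file.path(dir, "metadata.tsv")
  readr::write_tsv(cohort$signals, sig_path)
  readr::write_tsv(cohort$meta, meta_path)
  invisible(c(signals = sig_path, meta = meta_path))
}

#' @rdname write_signals
#' @param dir Directory containing `signals.tsv` and `metadata.tsv`.
#' @return For `read_signals()`: a list with validated `signals` and `meta`
#'   tibbles.
#' @export
read_signals <- function(dir) {
  sig_path <- file.path(dir, "signals.tsv")
  meta_path <- file.path(dir, "metadata.tsv")
  for (p in c(sig_path, meta_path)) {
    if (!file.exists(p)) stop("missing file: ", p, call. = FALSE)
  }
  signals <- readr::read_tsv(sig_path, show_col_types = FALSE,
                             progress = FALSE)
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE,
                          progress = FALSE)
  need <- c("sample_id", "sensor_id", "time_s", "voltage_v")
  miss <- setdiff(need, names(signals))
  if (length(miss)) {
    stop("signals.tsv is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(signals$voltage_v)) {
    bad <- which(is.na(suppressWarnings(as.numeric(signals$voltage_v))))
    stop("non-numeric voltage at line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  }
  if (anyNA(signals$voltage_v) || anyNA(signals$time_s)) {
    bad <- which(is.na(signals$voltage_v) | is.na(signals$time_s))
    stop("missing voltage/time at data line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  }
  orphans <- setdiff(unique(signals$sample_id), meta$sample_id)
  if (length(orphans)) {
    stop("signals without metadata for sample id(s): ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  list(signals = signals, meta = meta)
}

#' Serialize a Gentle AdaBoost model as structured text
#'
#' Plain-text, full-precision (round-trip exact) model file: header lines
#' with the learning rate, label coding, seed and kept features, then one
#' tab-separated line per stump.
#'
#' @param model An `enose_boost` model.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_boost_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) sprintf("%.17g", x)
  writeLines(c(
    "enosedx_boost_model\tv1",
    paste0("nu\t", num(model$nu)),
    paste0("seed\t", model$seed),
    paste0("positive\t", model$positive),
    paste0("negative\t", model$negative),
    paste0("features\t", paste(model$features, collapse = ",")),
    paste0("loss\t", paste(num(model$loss), collapse = ",")),
    "stumps\tfeature\tthreshold\tleft\tright"
  ), con)
  writeLines(sprintf("stump\t%s\t%s\t%s\t%s", model$stumps$feature,
                     num(model$stumps$threshold), num(model$stumps$left),
                     num(model$stumps$right)), con)
  invisible(path)
}

#' @rdname write_boost_model
#' @export
read_boost_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "enosedx_boost_model")) {
    stop("not an enosedx model file: ", path, call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(key) {
    hit <- which(vapply(fields, function(f) f[1] == key, logical(1)))[1]
    fields[[hit]][2]
  }
  st <- fields[vapply(fields, function(f) f[1] == "stump", logical(1))]
  stumps <- tibble::tibble(
    feature = vapply(st, `[`, character(1), 2),
    threshold = as.numeric(vapply(st, `[`, character(1), 3)),
    left = as.numeric(vapply(st, `[`, character(1), 4)),
    right = as.numeric(vapply(st, `[`, character(1), 5))
  )
  new_enose_boost(
    stumps = stumps,
    nu = as.numeric(get("nu")),
    features = strsplit(get("features"), ",", fixed = TRUE)[[1]],
    loss = as.numeric(strsplit(get("loss"), ",", fixed = TRUE)[[1]]),
    positive = get("positive"),
    negative = get("negative"),
    seed = suppressWarnings(as.integer(get("seed")))
  )
}

#' Run the end-to-end analysis pipeline
#'
#' Chains every stage on one cohort: preprocessing, feature extraction,
#' sensor-utility ranking, iterative sensor elimination with optimal-subset
#' selection for the primary (cancer-vs-healthy) task, training of the
#' four-classifier cascade, cascade predictions for every sample, and the
#' repeated train/test robustness assessment of the cascade. All artifacts
#' are written as delimited text under `out_dir`, together with a manifest
#' recording the master seed and stage row counts.
#'
#' @param cohort A list with `signals` and `meta` (e.g. from
#'   [generate_cohort()] or [read_signals()]).
#' @param out_dir Output directory for artifacts; `NULL` skips writing.
#' @param timeline An [measurement_timeline()].
#' @param preprocess A [preprocess_config()].
#' @param sensors Sensor table describing the array.
#' @param redundancy_threshold Feature redundancy threshold.
#' @param eliminate Run sensor elimination / optimal-subset selection for
#'   the cancer-vs-healthy task? (The cascade then restricts stage 1 to the
#'   selected subset.)
#' @param rounds,nu,min_leaf Gentle AdaBoost hyperparameters for all stages.
#' @param policy Vote policy.
#' @param n_repeats Robustness repeats (0 skips the assessment).
#' @param seed Master seed; every random draw descends from it.
#' @param verbose Print one structured line per stage?
#' @return A list: `features`, `utility`, `performance` (or `NULL`),
#'   `sensors_kept`, `cascade`, `decisions`, `robustness` (or `NULL`),
#'   `manifest`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL,
                         timeline = measurement_timeline(),
                         preprocess = preprocess_config(),
                         sensors = sensor_array(),
                         redundancy_threshold = 0.95,
                         eliminate = TRUE, rounds = 60L, nu = 0.5,
                         min_leaf = 0.01, policy = vote_policy(),
                         n_repeats = 15L, seed = 1L, verbose = FALSE) {
  say <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  pp <- preprocess_signals(cohort$signals, timeline, preprocess)
  say("preprocess", "%d signal rows", nrow(pp))
  feats <- extract_features(pp, timeline)
  say("features", "%d signals x %d features", nrow(feats),
      nrow(feature_registry()))

  utility <- rank_sensors(pp, cohort$meta, task = "cancer_vs_healthy",
                          sensors = sensors, seed = derive_seed(seed, 2L))
  say("rank-sensors", "worst sensor #%d (similarity %.3f)",
      utility$sensor_id[which.max(utility$rank)], max(utility$similarity))

  performance <- NULL
  kept_sensors <- sort(sensors$sensor_id)
  if (eliminate) {
    ds1 <- build_dataset(feats, cohort$meta, "cancer_vs_healthy")
    performance <- iterative_elimination(
      ds1, utility, rounds = rounds, nu = nu, min_leaf = min_leaf,
      seed = derive_seed(seed, 3L))
    kept_sensors <- select_optimal(performance)
    say("eliminate", "%d steps, optimal subset keeps %d sensors",
        nrow(performance), length(kept_sensors))
  }

  cascade <- train_cascade(
    feats, cohort$meta, rounds = rounds, nu = nu, min_leaf = min_leaf,
    redundancy_threshold = redundancy_threshold,
    sensors_kept = list(cancer_vs_healthy = kept_sensors),
    policy = policy, seed = derive_seed(seed, 4L))
  decisions <- predict_cascade(cascade, feats)
  say("cascade", "%d samples classified, %d indeterminate",
      nrow(decisions), sum(decisions$final == "indeterminate"))

  robustness <- NULL
  if (n_repeats > 0) {
    robustness <- cascade_robustness(
      feats, cohort$meta, n_repeats = n_repeats,
      seed = derive_seed(seed, 5L), rounds = rounds, nu = nu,
      min_leaf = min_leaf, redundancy_threshold = redundancy_threshold,
      policy = policy)
    say("robustness", "mean cascade accuracy %.3f over %d repeats",
        mean(robustness$cascade_accuracy), n_repeats)
  }

  manifest <- tibble::tibble(
    stage = c("signals", "features", "utility", "decisions"),
    rows = c(nrow(cohort$signals), nrow(feats), nrow(utility),
             nrow(decisions)),
    seed = seed
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(feats, file.path(out_dir, "features.tsv"))
    readr::write_tsv(utility, file.path(out_dir, "sensor_utility.tsv"))
    if (!is.null(performance)) {
      flat <- performance |>
        dplyr::mutate(
          sensors_excluded = vapply(.data$sensors_excluded, paste,
                                    character(1), collapse = ","),
          sensors_kept = vapply(.data$sensors_kept, paste, character(1),
                                collapse = ","))
      readr::write_tsv(flat, file.path(out_dir, "performance_matrix.tsv"))
    }
    readr::write_tsv(dplyr::select(decisions, -dplyr::any_of("counts")),
                     file.path(out_dir, "decisions.tsv"))
    if (!is.null(robustness)) {
      readr::write_tsv(robustness, file.path(out_dir, "robustness.tsv"))
    }
    for (s in names(cascade$stages)) {
      write_boost_model(cascade$stages[[s]]$model,
                        file.path(out_dir, paste0("model_", s, ".txt")))
    }
    readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  }
  list(features = feats, utility = utility, performance = performance,
       sensors_kept = kept_sensors, cascade = cascade,
       decisions = decisions, robustness = robustness, manifest = manifest)
}
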