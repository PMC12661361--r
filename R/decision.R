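#' Threshold-gated vote policy
#'
#' A sample-level decision is declared only when the winning class holds more
#' than `threshold` of the per-signal predictions (strict comparison by
#' default; set `strict = FALSE` for ">="). Otherwise the sample is
#' explicitly `indeterminate` — never silently forced to a class.
#'
#' @param threshold Required winning fraction, in \[0.5, 1).
#' @param strict If `TRUE` (default) the fraction must strictly exceed the
#'   threshold; if `FALSE`, equality suffices.
#' @return A list of class `"vote_policy"`.
#' @export
vote_policy <- function(threshold = 0.90, strict = TRUE) {
  if (threshold < 0.5 || threshold >= 1) {
    stop("`threshold` must be in [0.5, 1)", call. = FALSE)
  }
  structure(list(threshold = threshold, strict = strict),
            class = "vote_policy")
}

#' Aggregate per-signal predictions by majority vote
#'
#' @param predictions Character vector of per-signal class predictions for
#'   one sample (length >= 1).
#' @param policy A [vote_policy()].
#' @return A one-row tibble: `n_predictions`, `top_class` (modal class, `NA`
#'   on an exact tie), `top_share` (its vote fraction), `decision` (the class
#'   if the gate passes, otherwise `"indeterminate"`), and a `counts`
#'   list-column with the per-class vote counts.
#' @examples
#' majority_vote(c(rep("ovarian", 29), "healthy"))      # 29/30: definitive
#' majority_vote(c(rep("ovarian", 27), rep("healthy", 3)))  # 0.90: gated out
#' @export
majority_vote <- function(predictions, policy = vote_policy()) {
  if (length(predictions) < 1) {
    stop("need at least one prediction", call. = FALSE)
  }
  counts <- table(predictions)
  n <- length(predictions)
  top <- max(counts)
  winners <- names(counts)[counts == top]
  tied <- length(winners) > 1
  top_class <- if (tied) NA_character_ else winners
  share <- top / n
  passes <- if (policy$strict) share > policy$threshold else
    share >= policy$threshold
  decision <- if (!tied && passes) top_class else "indeterminate"
  tibble::tibble(
    n_predictions = n,
    top_class = top_class,
    top_share = share,
    decision = decision,
    counts = list(stats::setNames(as.integer(counts), names(counts)))
  )
}

#' Train the four-classifier diagnostic cascade
#'
#' Trains one Gentle AdaBoost model per cascade stage: (1) cancer vs healthy
#' on all samples, (2) ovarian vs endometrial on cancer samples, (3) stage I
#' vs II-IV within ovarian cancer, (4) stage I vs II-IV within endometrial
#' cancer. Each stage applies redundancy removal to its own training rows and
#' may restrict to its own retained sensor subset.
#'
#' @param features Wide feature tibble from [extract_features()] (training
#'   samples only).
#' @param meta Sample metadata covering all feature rows.
#' @param rounds,nu,min_leaf Gentle AdaBoost hyperparameters (scalar, or a
#'   named list by task for per-stage values).
#' @param redundancy_threshold Passed to [remove_redundant()] per stage;
#'   `NULL` disables redundancy removal.
#' @param sensors_kept Optional named list (by task) of sensor ids each stage
#'   may use; `NULL` keeps all sensors everywhere.
#' @param signals Optional preprocessed signal tibble for the training
#'   samples; required when `drop_worst > 0`.
#' @param drop_worst Per stage, rank the sensors by utility on the training
#'   signals and exclude this many least-useful (highest-similarity)
#'   sensors before training and voting. Each stage thus gets its own
#'   utility ranking; vote denominators shrink accordingly.
#' @param policy A [vote_policy()] stored with the cascade.
#' @param seed Integer seed recorded in each model.
#' @return An object of class `"enose_cascade"`: per-stage models, kept
#'   features, kept sensors and the vote policy.
#' @export
train_cascade <- function(features, meta, rounds = 60L, nu = 0.5,
                          min_leaf = 0.01, redundancy_threshold = 0.95,
                          sensors_kept = NULL, signals = NULL,
                          drop_worst = 0L, policy = vote_policy(),
                          seed = 1L) {
  tasks <- c("cancer_vs_healthy", "oc_vs_ec", "oc_stage", "ec_stage")
  get_par <- function(par, task) {
    if (is.list(par)) par[[task]] else par
  }
  if (drop_worst > 0L && is.null(signals)) {
    stop("`drop_worst` needs the training `signals` for utility ranking",
         call. = FALSE)
  }
  all_sensors <- sort(unique(features$sensor_id))
  stages <- lapply(tasks, function(task) {
    ds <- build_dataset(features, meta, task)
    keep_sensors <- if (!is.null(sensors_kept)) sensors_kept[[task]] else NULL
    if (drop_worst > 0L) {
      stage_sensors <- keep_sensors %||% all_sensors
      sensor_tbl <- tibble::tibble(sensor_id = stage_sensors)
      ut <- rank_sensors(
        signals[signals$sample_id %in% unique(ds$sample_id) &
                  signals$sensor_id %in% stage_sensors, , drop = FALSE],
        meta, task = task, sensors = sensor_tbl)
      keep_sensors <-
        sort(ut$sensor_id[ut$rank <= nrow(ut) - drop_worst])
    }
    if (!is.null(keep_sensors)) {
      ds <- ds[ds$sensor_id %in% keep_sensors, , drop = FALSE]
    }
    kept <- dataset_feature_names(ds)
    if (!is.null(redundancy_threshold)) {
      rr <- remove_redundant(ds, redundancy_threshold)
      kept <- rr$kept
    }
    model <- gentleboost(ds, features = kept,
                         rounds = get_par(rounds, task),
                         nu = get_par(nu, task),
                         min_leaf = get_par(min_leaf, task), seed = seed)
    list(task = task, model = model, features = kept,
         sensors = keep_sensors %||% sort(unique(ds$sensor_id)))
  })
  names(stages) <- tasks
  structure(list(stages = stages, policy = policy, seed = seed),
            class = "enose_cascade")
}

#' @export
print.enose_cascade <- function(x, ...) {
  cat("<enose_cascade> 4 stages, vote threshold",
      sprintf("%s%.2f\n", if (x$policy$strict) ">" else ">=",
              x$policy$threshold))
  for (s in x$stages) {
    cat(sprintf("  %-18s %3d stumps, %2d features, %2d sensors\n", s$task,
                nrow(s$model$stumps), length(s$features),
                length(s$sensors)))
  }
  invisible(x)
}

vote_stage <- function(cascade, task, rows) {
  stage <- cascade$stages[[task]]
  if (is.null(stage)) stop("cascade has no model for stage ", task,
                           call. = FALSE)
  rows <- rows[rows$sensor_id %in% stage$sensors, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("no signals from the retained sensors of stage ", task,
         call. = FALSE)
  }
  preds <- predict(stage$model, rows)
  majority_vote(preds, cascade$policy)
}

#' Run the cascade on new samples
#'
#' For each sample: stage 1 votes cancer-vs-healthy; a definitive "healthy"
#' terminates; a definitive "cancer" routes to stage 2 (ovarian vs
#' endometrial), whose winner routes to the matching staging classifier
#' (stage I vs II-IV). An indeterminate vote at any stage terminates with
#' final label `"indeterminate"`; the path walked is always reported. Each
#' stage votes only over the sensors that stage retained, so vote
#' denominators can differ between stages.
#'
#' @param cascade An `enose_cascade` from [train_cascade()].
#' @param features Wide feature tibble of the samples to classify.
#' @return A tibble, one row per sample: per-stage decisions and vote shares
#'   (`NA` for stages not reached) and `final` in
#'   `{healthy, OC-I, OC-II-IV, EC-I, EC-II-IV, indeterminate}`.
#' @export
predict_cascade <- function(cascade, features) {
  ids <- unique(features$sample_id)
  purrr::map_dfr(ids, function(id) {
    rows <- features[features$sample_id == id, , drop = FALSE]
    out <- tibble::tibble(
      sample_id = id,
      stage1_decision = NA_character_, stage1_share = NA_real_,
      stage2_decision = NA_character_, stage2_share = NA_real_,
      stage3_decision = NA_character_, stage3_share = NA_real_,
      stage4_decision = NA_character_, stage4_share = NA_real_,
      final = NA_character_
    )
    v1 <- vote_stage(cascade, "cancer_vs_healthy", rows)
    out$stage1_decision <- v1$decision
    out$stage1_share <- v1$top_share
    if (v1$decision == "indeterminate") {
      out$final <- "indeterminate"; return(out)
    }
    if (v1$decision == "healthy") {
      out$final <- "healthy"; return(out)
    }
    v2 <- vote_stage(cascade, "oc_vs_ec", rows)
    out$stage2_decision <- v2$decision
    out$stage2_share <- v2$top_share
    if (v2$decision == "indeterminate") {
      out$final <- "indeterminate"; return(out)
    }
    if (v2$decision == "ovarian") {
      v3 <- vote_stage(cascade, "oc_stage", rows)
      out$stage3_decision <- v3$decision
      out$stage3_share <- v3$top_share
      out$final <- if (v3$decision == "indeterminate") "indeterminate" else
        paste0("OC-", v3$decision)
    } else {
      v4 <- vote_stage(cascade, "ec_stage", rows)
      out$stage4_decision <- v4$decision
      out$stage4_share <- v4$top_share
      out$final <- if (v4$decision == "indeterminate") "indeterminate" else
        paste0("EC-", v4$decision)
    }
    out
  })
}
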