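# independent restatement of the gate: winning class must hold strictly
# more than tau of the votes (or >= when not strict), no ties
vote_oracle <- function(n_a, n_b, tau = 0.9, strict = TRUE) {
  n <- n_a + n_b
  top <- max(n_a, n_b)
  if (n_a == n_b) return("indeterminate")
  winner <- if (n_a > n_b) "A" else "B"
  frac <- top / n
  ok <- if (strict) frac > tau else frac >= tau
  if (ok) winner else "indeterminate"
}

test_that("the vote gate matches brute-force enumeration for every split of
           up to 32 predictions", {
  for (strict in c(TRUE, FALSE)) {
    pol <- vote_policy(0.9, strict = strict)
    for (n in 1:32) {
      for (a in 0:n) {
        preds <- c(rep("A", a), rep("B", n - a))
        got <- majority_vote(preds, pol)
        expect_equal(got$decision, vote_oracle(a, n - a, 0.9, strict),
                     info = sprintf("n=%d a=%d strict=%s", n, a, strict))
        # counts conserved
        expect_equal(sum(unlist(got$counts)), n)
      }
    }
  }
})

test_that("the 29-of-30 example is definitive and the exact-90% split is
           gated out", {
  v29 <- majority_vote(c(rep("ovarian", 29), "healthy"))
  expect_equal(v29$decision, "ovarian")
  expect_equal(v29$top_share, 29 / 30)
  v27 <- majority_vote(c(rep("ovarian", 27), rep("healthy", 3)))
  expect_equal(v27$top_share, 0.9)
  expect_equal(v27$decision, "indeterminate")
  # the non-strict reading admits the boundary case
  v27b <- majority_vote(c(rep("ovarian", 27), rep("healthy", 3)),
                        vote_policy(0.9, strict = FALSE))
  expect_equal(v27b$decision, "ovarian")
})

test_that("unanimity is definitive and order does not matter", {
  expect_equal(majority_vote(rep("healthy", 30))$decision, "healthy")
  set.seed(31)
  preds <- c(rep("x", 28), rep("y", 2))
  expect_equal(majority_vote(preds), majority_vote(sample(preds)))
})

test_that("exact ties are indeterminate with no top class", {
  v <- majority_vote(c("a", "a", "b", "b"))
  expect_equal(v$decision, "indeterminate")
  expect_true(is.na(v$top_class))
})

test_that("vote policy and inputs are validated", {
  expect_error(vote_policy(0.3), "\\[0.5, 1\\)")
  expect_error(vote_policy(1), "\\[0.5, 1\\)")
  expect_error(majority_vote(character(0)), "at least one")
})

# a hand-made cascade whose stage models threshold one feature each, so the
# vote fractions are fully controlled by the feature table
fake_cascade <- function() {
  mk <- function(feature, positive, negative) {
    enosedx:::new_enose_boost(
      stumps = tibble::tibble(feature = feature, threshold = 0.5,
                              left = -1, right = 1),
      nu = 1, features = feature, loss = 1, positive = positive,
      negative = negative, seed = 0L)
  }
  structure(list(
    stages = list(
      cancer_vs_healthy = list(task = "cancer_vs_healthy",
                               model = mk("g1", "cancer", "healthy"),
                               features = "g1", sensors = 1:10),
      oc_vs_ec = list(task = "oc_vs_ec",
                      model = mk("g2", "ovarian", "endometrial"),
                      features = "g2", sensors = 1:10),
      oc_stage = list(task = "oc_stage", model = mk("g3", "II-IV", "I"),
                      features = "g3", sensors = 1:10),
      ec_stage = list(task = "ec_stage", model = mk("g4", "II-IV", "I"),
                      features = "g4", sensors = 1:10)),
    policy = vote_policy(0.9, strict = TRUE), seed = 0L),
    class = "enose_cascade")
}

fake_rows <- function(id, g1, g2 = 0, g3 = 0, g4 = 0) {
  tibble::tibble(sample_id = id, sensor_id = 1:10,
                 g1 = g1, g2 = g2, g3 = g3, g4 = g4)
}

test_that("a definitive healthy vote exits the cascade at stage 1", {
  dec <- predict_cascade(fake_cascade(), fake_rows("s1", g1 = rep(0, 10)))
  expect_equal(dec$final, "healthy")
  expect_equal(dec$stage1_decision, "healthy")
  expect_true(is.na(dec$stage2_decision))
  expect_true(is.na(dec$stage3_decision))
  expect_true(is.na(dec$stage4_decision))
})

test_that("a vote fraction exactly at the threshold stops the cascade as
           indeterminate", {
  # stage 2 splits 9 ovarian / 1 endometrial = 0.9 exactly: gated out
  rows <- fake_rows("s2", g1 = rep(1, 10), g2 = c(rep(1, 9), 0))
  dec <- predict_cascade(fake_cascade(), rows)
  expect_equal(dec$stage1_decision, "cancer")
  expect_equal(dec$stage2_decision, "indeterminate")
  expect_equal(dec$stage2_share, 0.9)
  expect_equal(dec$final, "indeterminate")
  expect_true(is.na(dec$stage3_decision))
  expect_true(is.na(dec$stage4_decision))
})

test_that("the cascade routes ovarian to the OC staging classifier and
           endometrial to the EC one", {
  oc <- predict_cascade(fake_cascade(),
                        fake_rows("s3", g1 = rep(1, 10), g2 = rep(1, 10),
                                  g3 = rep(0, 10)))
  expect_equal(oc$final, "OC-I")
  expect_true(is.na(oc$stage4_decision))
  ec <- predict_cascade(fake_cascade(),
                        fake_rows("s4", g1 = rep(1, 10), g2 = rep(0, 10),
                                  g4 = rep(1, 10)))
  expect_equal(ec$final, "EC-II-IV")
  expect_true(is.na(ec$stage3_decision))
})

test_that("cascade paths are internally consistent end to end", {
  co <- small_cohort()
  ft <- small_features()
  casc <- train_cascade(ft, co$meta, rounds = 60L, nu = 0.5,
                        seed = 7L)
  dec <- predict_cascade(casc, ft)
  expect_equal(nrow(dec), nrow(co$meta))
  for (i in seq_len(nrow(dec))) {
    r <- dec[i, ]
    if (r$final == "healthy") {
      expect_equal(r$stage1_decision, "healthy")
      expect_true(is.na(r$stage2_decision))
    }
    if (grepl("^OC", r$final)) {
      expect_equal(r$stage1_decision, "cancer")
      expect_equal(r$stage2_decision, "ovarian")
      expect_equal(paste0("OC-", r$stage3_decision), r$final)
      expect_true(is.na(r$stage4_decision))
    }
    if (grepl("^EC", r$final)) {
      expect_equal(r$stage1_decision, "cancer")
      expect_equal(r$stage2_decision, "endometrial")
      expect_equal(paste0("EC-", r$stage4_decision), r$final)
      expect_true(is.na(r$stage3_decision))
    }
    if (r$final == "indeterminate") {
      expect_true("indeterminate" %in%
                    c(r$stage1_decision, r$stage2_decision,
                      r$stage3_decision, r$stage4_decision))
    }
  }
})

test_that("a high-SNR cohort is classified correctly end to end at
           resubstitution", {
  co <- small_cohort()
  ft <- small_features()
  pp <- small_preprocessed()
  casc <- train_cascade(ft, co$meta, rounds = 60L, nu = 0.5,
                        signals = pp, drop_worst = 1L, seed = 7L)
  dec <- predict_cascade(casc, ft)
  truth <- co$meta$class_label[match(dec$sample_id, co$meta$sample_id)]
  expect_equal(dec$final, truth)
  # per-stage sensor restriction: the planted sensor is never voted on
  planted <- small_array()$sensor_id[!small_array()$discriminative]
  for (s in casc$stages) expect_false(planted %in% s$sensors)
})
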