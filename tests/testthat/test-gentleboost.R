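test_that("the separable pair yields the canonical stump", {
  st <- fit_stump(matrix(c(0, 1)), c(-1, 1))
  expect_equal(st$feature, 1L)
  expect_equal(st$threshold, 0.5)
  expect_equal(st$left, -1)
  expect_equal(st$right, 1)
})

test_that("all-positive labels give +1 leaves whatever the split", {
  st <- fit_stump(matrix(c(0, 1, 2, 3)), c(1, 1, 1, 1))
  expect_equal(st$left, 1)
  expect_equal(st$right, 1)
})

test_that("identical rows degrade to a constant weighted-mean stump", {
  X <- matrix(1, nrow = 4, ncol = 2)
  st <- fit_stump(X, c(1, 1, -1, 1), w = c(0.25, 0.25, 0.25, 0.25))
  expect_equal(st$left, st$right)
  expect_equal(st$left, 0.5)  # weighted mean of labels
})

test_that("the fitted stump matches exhaustive enumeration on random
           instances", {
  for (s in 1:40) {
    set.seed(s)
    n <- sample(5:30, 1)
    p <- sample(1:4, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- sample(c(-1, 1), n, replace = TRUE)
    w <- runif(n); w <- w / sum(w)
    st <- fit_stump(X, y, w, min_leaf = 1e-9)
    expect_equal(stump_sse(st, X, y, w), stump_oracle_sse(X, y, w),
                 tolerance = 1e-10)
  }
})

test_that("stump input validation catches bad labels and weights", {
  expect_error(fit_stump(matrix(c(0, 1)), c(0, 1)), "\\{-1, \\+1\\}")
  expect_error(fit_stump(matrix(c(0, 1)), c(-1, 1), w = c(0.9, 0.3)),
               "sum to 1")
  expect_error(fit_stump(matrix(1), c(1)), "at least 2")
})

test_that("a separable 1-D problem is solved in one round at nu = 1", {
  d <- tibble::tibble(x = c(-2, -1, 1, 2), y = c(-1, -1, 1, 1))
  m <- gentleboost(d, features = "x", rounds = 1L, nu = 1)
  expect_equal(sign(predict(m, d, type = "margin")), d$y)
})

test_that("an XOR-pattern toy reaches zero training error within 8 rounds", {
  d <- tibble::tibble(x1 = c(0, 1, 0.1, 0.9), x2 = c(0, 0.1, 1, 0.9),
                      y = c(-1, 1, 1, -1))
  m <- gentleboost(d, features = c("x1", "x2"), rounds = 8L, nu = 1)
  margin <- predict(m, d, type = "margin")
  expect_true(all(sign(margin) == d$y))
})

test_that("training exponential loss is non-increasing round over round", {
  for (s in 1:25) {
    set.seed(s)
    n <- 30
    d <- tibble::tibble(
      a = rnorm(n), b = rnorm(n),
      y = sample(c(-1, 1), n, replace = TRUE))
    nu <- sample(c(0.1, 0.5, 1), 1)
    m <- gentleboost(d, features = c("a", "b"), rounds = 15L, nu = nu)
    expect_true(all(diff(m$loss) <= 1e-12), info = paste("seed", s))
  }
})

test_that("margins are additive over stumps", {
  d <- toy_dataset(seed = 6)
  m <- gentleboost(d, features = c("f1", "f2", "f3"), rounds = 10L,
                   nu = 0.5)
  head_model <- m; head_model$stumps <- m$stumps[1:4, ]
  tail_model <- m; tail_model$stumps <- m$stumps[5:10, ]
  expect_equal(
    predict(m, d, type = "margin"),
    predict(head_model, d, type = "margin") +
      predict(tail_model, d, type = "margin"))
})

test_that("prediction agrees with an independently coded scorer", {
  d <- toy_dataset(n_per_class = 13L, seed = 7)  # 104 rows
  m <- gentleboost(d, features = c("f1", "f2", "f3"), rounds = 12L,
                   nu = 0.7)
  # naive per-row scorer
  naive <- vapply(seq_len(nrow(d)), function(i) {
    s <- 0
    for (k in seq_len(nrow(m$stumps))) {
      x <- d[[m$stumps$feature[k]]][i]
      s <- s + if (x <= m$stumps$threshold[k]) m$stumps$left[k] else
        m$stumps$right[k]
    }
    m$nu * s
  }, numeric(1))
  expect_equal(predict(m, d, type = "margin"), naive)
  expect_equal(predict(m, d),
               ifelse(naive >= 0, "pos", "neg"))
})

test_that("the zero margin maps to the positive class", {
  d <- toy_dataset(seed = 8)
  m <- gentleboost(d, features = "f1", rounds = 1L, nu = 1)
  m$stumps$left <- 0; m$stumps$right <- 0
  expect_equal(unique(predict(m, d)), attr(d, "positive"))
})

test_that("single-class training warns and returns a constant model", {
  d <- toy_dataset(seed = 9)
  d$y <- 1; d$label <- "pos"
  expect_warning(m <- gentleboost(d, features = "f1", rounds = 5L),
                 "identical")
  expect_equal(unique(predict(m, d)), "pos")
})

test_that("missing features in newdata are reported by name", {
  d <- toy_dataset(seed = 10)
  m <- gentleboost(d, features = c("f1", "f2"), rounds = 3L)
  expect_error(predict(m, d[c("sample_id", "f1")]), "f2")
})

test_that("tidy and glance summarize the ensemble", {
  d <- toy_dataset(seed = 11)
  m <- gentleboost(d, features = c("f1", "f2"), rounds = 6L, nu = 0.4)
  td <- tidy(m)
  expect_equal(nrow(td), 6L)
  expect_true(all(c("round", "feature", "threshold", "left", "right",
                    "train_exp_loss") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$rounds, 6L)
  expect_equal(gl$nu, 0.4)
  expect_equal(gl$train_exp_loss, m$loss[6])
})

test_that("grouped folds keep every sample's rows together", {
  d <- toy_dataset(n_per_class = 5L, rows_per_sample = 4L, seed = 12)
  cv <- cross_validate(d, rounds = 5L, folds = 5L, seed = 2)
  # 10 samples over 5 folds: 2 samples each
  expect_equal(unname(table(cv$assignments)), rep(2L, 5L),
               ignore_attr = TRUE)
  # no sample id in more than one fold among held-out predictions
  by_sample <- tapply(cv$predictions$fold, cv$predictions$sample_id,
                      function(f) length(unique(f)))
  expect_true(all(by_sample == 1))
})

test_that("cross-validation is invariant to row shuffling", {
  d <- toy_dataset(n_per_class = 6L, seed = 13)
  set.seed(99)
  shuffled <- d[sample.int(nrow(d)), ]
  attr(shuffled, "positive") <- "pos"; attr(shuffled, "negative") <- "neg"
  cv1 <- cross_validate(d, rounds = 8L, folds = 3L, seed = 5)
  cv2 <- cross_validate(shuffled, rounds = 8L, folds = 3L, seed = 5)
  expect_equal(cv1$pooled, cv2$pooled)
})

test_that("a cleanly separable dataset cross-validates perfectly", {
  d <- toy_dataset(n_per_class = 10L, gap = 6, noise = 0.2, seed = 14)
  cv <- cross_validate(d, rounds = 20L, nu = 0.5, folds = 5L, seed = 3)
  expect_equal(cv$pooled$estimate[cv$pooled$metric == "accuracy"], 1)
})

test_that("budget-1 tuning returns the single evaluated configuration and
           larger budgets never lose ground", {
  d <- toy_dataset(n_per_class = 6L, seed = 15)
  t1 <- tune_gentleboost(d, budget = 1L, folds = 3L, seed = 4)
  expect_equal(nrow(t1$trace), 1L)
  expect_equal(t1$best$eval, 1L)
  t3 <- tune_gentleboost(d, budget = 3L, folds = 3L, seed = 4)
  t6 <- tune_gentleboost(d, budget = 6L, folds = 3L, seed = 4)
  # same candidate sequence prefix
  expect_equal(t3$trace, t6$trace[1:3, ])
  expect_gte(t6$best$cv_accuracy, t3$best$cv_accuracy)
})

test_that("model text serialization round-trips exactly", {
  d <- toy_dataset(seed = 16)
  m <- gentleboost(d, features = c("f1", "f2", "f3"), rounds = 7L,
                   nu = 1 / 3, seed = 42L)
  path <- withr::local_tempfile(fileext = ".txt")
  write_boost_model(m, path)
  m2 <- read_boost_model(path)
  expect_equal(m2$stumps, m$stumps, tolerance = 0)
  expect_identical(m2$nu, m$nu)
  expect_identical(m2$features, m$features)
  expect_identical(m2$positive, m$positive)
  expect_equal(m2$loss, m$loss, tolerance = 0)
  expect_equal(predict(m2, d, type = "margin"),
               predict(m, d, type = "margin"))
})
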