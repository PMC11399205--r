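test_that("AUC equals exhaustive pair counting on small instances with ties", {
  expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  set.seed(201)
  for (i in 1:120) {
    n <- sample(2:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    # quantized scores so ties occur often
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    expect_equal(rocAuc(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC limits: perfect separation, all ties, label complement", {
  expect_identical(rocAuc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_identical(rocAuc(rep(0.3, 10), rep(0:1, 5)), 0.5)
  set.seed(202)
  s <- runif(50); l <- rbinom(50, 1, 0.4)
  expect_equal(rocAuc(s, l) + rocAuc(s, 1 - l), 1, tolerance = 1e-12)
  expect_error(rocAuc(s, rep(0, 50)), "degenerate")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(203)
  s <- runif(80); l <- rbinom(80, 1, 0.3); l[1:2] <- 0:1
  a <- rocAuc(s, l)
  expect_equal(rocAuc(qlogis(pmin(pmax(s, 1e-9), 1 - 1e-9)), l), a)
  expect_equal(rocAuc(s^3, l), a)
  expect_equal(rocAuc(100 * s - 3, l), a)
})

test_that("DeLong variance matches hand-enumerated structural components", {
  # 3 positives {0.8, 0.6, 0.9}, 3 negatives {0.1, 0.7, 0.3}, psi by psi:
  # V10 = (1, 2/3, 1) -- 0.6 loses only to 0.7
  # V01 = (1, 2/3, 1) -- 0.7 is beaten only by 0.8 and 0.9
  s <- c(0.8, 0.6, 0.9, 0.1, 0.7, 0.3)
  l <- c(1, 1, 1, 0, 0, 0)
  v10 <- c(1, 2 / 3, 1)
  v01 <- c(1, 2 / 3, 1)
  expect_equal(delongVariance(s, l), var(v10) / 3 + var(v01) / 3,
               tolerance = 1e-14)
  expect_equal(delongVariance(s, l), oracle_delong_var(s, l),
               tolerance = 1e-14)
  expect_identical(delongVariance(c(1, 2, 9, 10), c(0, 0, 1, 1)), 0)
})

test_that("DeLong variance matches the naive oracle under heavy ties", {
  set.seed(204)
  for (i in 1:30) {
    n <- sample(6:14, 1)
    l <- c(0, 0, 1, 1, rbinom(n - 4, 1, 0.5))
    s <- sample(seq(0, 1, 0.2), length(l), replace = TRUE)
    expect_equal(delongVariance(s, l), oracle_delong_var(s, l),
                 tolerance = 1e-12)
  }
})

test_that("DeLong variance and AUC agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(205)
  l <- rbinom(300, 1, 0.3); s <- rnorm(300, l)
  r <- pROC::roc(l, s, quiet = TRUE, direction = "<")
  expect_equal(rocAuc(s, l), as.numeric(pROC::auc(r)), tolerance = 1e-12)
  expect_equal(delongVariance(s, l), pROC::var(r), tolerance = 1e-12)
  l2 <- rbinom(250, 1, 0.4); s2 <- rnorm(250, 0.8 * l2)
  r2 <- pROC::roc(l2, s2, quiet = TRUE, direction = "<")
  rt <- pROC::roc.test(r, r2, method = "delong", paired = FALSE)
  cmp <- compareAuc(s, l, s2, l2)
  expect_equal(cmp@zStatistic, unname(rt$statistic), tolerance = 1e-10)
  expect_equal(cmp@pValue, rt$p.value, tolerance = 0.01)
})

test_that("DeLong variance shrinks as both classes grow", {
  set.seed(206)
  mk <- function(n) {
    l <- rep(0:1, n)
    list(s = rnorm(2 * n, l), l = l)
  }
  small <- mk(100); big <- mk(800)
  expect_gt(delongVariance(small$s, small$l),
            delongVariance(big$s, big$l))
})

test_that("bootstrap CI is deterministic, ordered, and collapses when exact", {
  set.seed(207)
  l <- rbinom(120, 1, 0.3); s <- rnorm(120, 1.5 * l)
  ci1 <- bootstrapAucCI(s, l, reps = 300, seed = 9)
  ci2 <- bootstrapAucCI(s, l, reps = 300, seed = 9)
  expect_identical(ci1, ci2)
  a <- rocAuc(s, l)
  expect_lte(ci1["low"], a)
  expect_gte(ci1["high"], a)
  # perfectly separated: every resample has AUC 1
  lp <- rep(0:1, each = 60); sp <- c(rnorm(60, 0), rnorm(60, 100))
  expect_identical(unname(bootstrapAucCI(sp, lp, reps = 100, seed = 9)),
                   c(1, 1))
  expect_error(bootstrapAucCI(s, l, reps = 0), "reps")
})

test_that("sensitivity at fixed specificity matches an exhaustive sweep", {
  lp <- rep(0:1, each = 50)
  sp <- c(rnorm(50, 0), rnorm(50, 10))
  expect_identical(sensitivityAtSpecificity(sp, lp), 1)
  expect_identical(sensitivityAtSpecificity(rep(0.4, 40), rep(0:1, 20)), 0)
  ben <- seq(0.01, 0.20, by = 0.01)
  mal <- c(0.15, 0.18, 0.25, 0.3, 0.9)
  s <- c(ben, mal); l <- c(rep(0, 20), rep(1, 5))
  expect_equal(sensitivityAtSpecificity(s, l, 0.95),
               oracle_sens_at_spec(s, l, 0.95))
  set.seed(208)
  for (i in 1:20) {
    s <- sample(seq(0, 1, 0.1), 30, replace = TRUE)
    l <- c(0, 1, rbinom(28, 1, 0.4))
    for (t in c(0.8, 0.9, 0.95))
      expect_equal(sensitivityAtSpecificity(s, l, t),
                   oracle_sens_at_spec(s, l, t))
  }
})

test_that("sensitivity at specificity is non-increasing in the target", {
  set.seed(209)
  s <- runif(200); l <- rbinom(200, 1, 0.3); l[1:2] <- 0:1
  sens <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99), function(t)
    sensitivityAtSpecificity(s, l, t), numeric(1))
  expect_true(all(diff(sens) <= 0))
})

test_that("comparing a group with itself gives z = 0, p = 1", {
  set.seed(210)
  s <- runif(100); l <- rbinom(100, 1, 0.4); l[1:4] <- c(0, 0, 1, 1)
  cmp <- compareAuc(s, l, s, l, groupA = "full", groupB = "full")
  expect_identical(cmp@zStatistic, 0)
  expect_identical(cmp@pValue, 1)
  expect_false(cmp@paired)
})

test_that("the overlapping flag is carried through to the comparison report", {
  set.seed(211)
  s <- runif(200); l <- rbinom(200, 1, 0.3); l[1:4] <- c(0, 0, 1, 1)
  sub <- seq_len(150)
  cmp <- compareAuc(s, l, s[sub], l[sub], "full", "certain", overlapping = TRUE)
  expect_true(cmp@overlapping)
  expect_output(show(cmp), "covariance ignored")
})

test_that("the performance report covers all groups with coherent counts", {
  nc <- scoreUncertainty(generateCohort(cohortPreset("screening", seed = 212)))
  ts <- calibrateThresholds(nc)
  rep1 <- evaluatePerformance(nc, ts, reps = 50, seed = 3)
  expect_identical(rep1$group,
                   c("full", "certain", "uncertain", "certain", "uncertain"))
  n <- nrow(nc)
  expect_true(all(rep1$n_benign + rep1$n_malignant ==
                  c(n, rep(NA, 4)) |
                  rep1$group != "full"))
  for (p in c(90, 95)) {
    sub <- rep1[!is.na(rep1$percentile) & rep1$percentile == p, ]
    expect_identical(sum(sub$n_benign + sub$n_malignant), n)
  }
  expect_true(all(rep1$ci_low <= rep1$auc & rep1$auc <= rep1$ci_high,
                  na.rm = TRUE))
  expect_true(all(rep1$overlapping[rep1$group == "certain"]))
  # deterministic given the seed
  rep2 <- evaluatePerformance(nc, ts, reps = 50, seed = 3)
  expect_identical(rep1, rep2)
})
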