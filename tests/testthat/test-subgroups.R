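test_that("size classes follow the Lung-RADS boundaries", {
  expect_identical(as.character(sizeClass(c(5.9, 6, 7.999, 8, 2, 40))),
                   c("small", "medium", "medium", "large", "small", "large"))
  expect_error(sizeClass(0), "positive")
  expect_error(sizeClass(-3), "positive")
  # partition: exactly one class for any positive diameter
  set.seed(301)
  d <- runif(500, 0.1, 50)
  expect_false(anyNA(sizeClass(d)))
})

test_that("t-test matches the closed-form pooled and Welch formulas", {
  a <- c(5.1, 6.3, 4.8, 7.2, 5.9, 6.1, 5.5, 6.8, 5.2, 6.0)
  b <- c(8.4, 9.1, 7.8, 10.2, 8.9, 9.5, 8.1, 9.9, 8.6, 9.3)
  # pooled-variance formula written out
  sp2 <- (9 * var(a) + 9 * var(b)) / 18
  tPooled <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 10 + 1 / 10))
  res <- sizeTTest(a, b)
  expect_equal(res$t, tPooled, tolerance = 1e-10)
  expect_identical(res$df, 18)
  expect_equal(res$p_value, 2 * pt(-abs(tPooled), 18), tolerance = 1e-10)
  # Welch formula written out
  se2 <- var(a) / 10 + var(b) / 10
  tW <- (mean(a) - mean(b)) / sqrt(se2)
  dfW <- se2^2 / ((var(a) / 10)^2 / 9 + (var(b) / 10)^2 / 9)
  resW <- sizeTTest(a, b, "welch")
  expect_equal(resW$t, tW, tolerance = 1e-10)
  expect_equal(resW$df, dfW, tolerance = 1e-10)
  expect_equal(resW$p_value, 2 * pt(-abs(tW), dfW), tolerance = 1e-10)
})

test_that("t-test limits: identical samples, separated samples, tiny samples", {
  x <- c(1, 2, 3)
  expect_equal(sizeTTest(x, x)$t, 0)
  expect_equal(sizeTTest(x, x)$p_value, 1)
  shifted <- sizeTTest(x, c(11.0001, 12.0002, 13.0001))
  expect_lt(shifted$p_value, 1e-3)
  expect_error(sizeTTest(1, x), "at least 2")
})

test_that("chi-square matches the definition expanded by hand on a 2x3 table", {
  tab <- rbind(c(20, 30, 50), c(40, 35, 25))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  res <- typeChisq(tab)  # correction only applies to 2x2
  expect_equal(res$statistic, stat, tolerance = 1e-12)
  expect_identical(res$df, 2L)
  expect_equal(res$p_value, pchisq(stat, 2, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("chi-square limits and invariances", {
  # identical row proportions -> statistic 0, p 1 (with and without Yates)
  tab <- rbind(c(10, 20), c(30, 60))
  expect_equal(typeChisq(tab, yates = FALSE)$statistic, 0)
  expect_equal(typeChisq(tab, yates = TRUE)$p_value, 1)
  # permutation invariance
  tab2 <- rbind(c(695, 123), c(136, 31))
  expect_equal(typeChisq(tab2)$statistic,
               typeChisq(tab2[2:1, ])$statistic)
  expect_equal(typeChisq(tab2)$statistic,
               typeChisq(tab2[, 2:1])$statistic)
  # structural zero margin
  expect_error(typeChisq(rbind(c(0, 0), c(5, 10))), "zero margin")
  expect_error(typeChisq(matrix(5, 1, 2)), "at least 2")
  expect_error(typeChisq(rbind(c(-1, 3), c(2, 2))), "non-negative")
})

test_that("Yates correction reproduces the benign solid/subsolid comparison", {
  # screening vs clinical benign nodules, solid vs subsolid counts
  counts <- rbind(screening = c(solid = 695, subsolid = 123),
                  clinical = c(solid = 136, subsolid = 31))
  pYates <- typeChisq(counts, yates = TRUE)$p_value
  pRaw <- typeChisq(counts, yates = FALSE)$p_value
  expect_lt(abs(pYates - 0.305), 0.005)
  expect_gt(abs(pRaw - 0.305), 0.01)
})

test_that("subgroup cell counts match a hand tally on a 12-record cohort", {
  nc <- toy_cohort()
  # hand-picked split: uncertain = the four nodules with members at 0.48/0.52
  asn <- data.frame(
    nodule_id = sprintf("t%02d", 1:12),
    threshold_percentile = 90,
    group = factor(c("certain", "certain", "uncertain", "uncertain",
                     "certain", "certain")[c(1:6, 1:6)],
                   levels = c("certain", "uncertain")))
  st <- buildSubgroupTable(nc, asn)
  s <- st$summary
  # benign nodules are t01-t03 and t07-t09; t03/t09 fall in the uncertain group
  bc <- s[s$label == "benign" & s$group == "certain", ]
  bu <- s[s$label == "benign" & s$group == "uncertain", ]
  expect_identical(bc$n, 4L)             # t01, t02, t07, t08
  expect_identical(bu$n, 2L)             # t03, t09
  expect_identical(bc$n_solid, 3L)
  expect_identical(bc$n_part_solid, 1L)  # t08
  expect_identical(bu$n_part_solid, 1L)  # t03
  expect_identical(bu$n_large, 2L)       # diameters 8 and 9
  expect_identical(bc$n_small, 2L)       # diameters 4, 3
  expect_equal(bc$mean_mm, mean(c(4, 6, 3, 6.5)))
  mu <- s[s$label == "malignant" & s$group == "uncertain", ]
  expect_identical(mu$n, 2L)             # t04 (5.9 mm), t10 (10 mm)
  expect_identical(mu$n_small, 1L)
  expect_identical(mu$n_large, 1L)
  expect_equal(mu$median_mm, (5.9 + 10) / 2)
  # counts at any stratification sum to the cohort size
  expect_identical(sum(s$n), 12L)
  expect_identical(sum(s$n_solid, s$n_part_solid, s$n_non_solid), 12L)
  expect_identical(sum(s$n_small, s$n_medium, s$n_large), 12L)
})

test_that("an all-certain cohort reports zero uncertain cells and no tests", {
  nc <- toy_cohort()
  asn <- data.frame(nodule_id = sprintf("t%02d", 1:12),
                    threshold_percentile = 90,
                    group = factor(rep("certain", 12),
                                   levels = c("certain", "uncertain")))
  st <- buildSubgroupTable(nc, asn)
  un <- st$summary[st$summary$group == "uncertain", ]
  expect_true(all(un$n == 0L))
  expect_identical(nrow(st$tests), 0L)
})

test_that("difficulty loaded on subsolid and large benign nodules shows up in the uncertain group", {
  nc <- scoreUncertainty(generateCohort(cohortPreset("screening", seed = 310)))
  ts <- calibrateThresholds(nc)
  asn <- assignGroups(nc, ts, 90)
  st <- buildSubgroupTable(nc, asn)
  s <- st$summary
  subsolidPct <- function(lab, grp) {
    r <- s[s$label == lab & s$group == grp, ]
    r$pct_part_solid + r$pct_non_solid
  }
  expect_gt(subsolidPct("benign", "uncertain"), subsolidPct("benign", "certain"))
  bc <- s[s$label == "benign" & s$group == "certain", ]
  bu <- s[s$label == "benign" & s$group == "uncertain", ]
  expect_gt(bu$mean_mm, bc$mean_mm)
  # the size t-test flags the benign difference
  tt <- st$tests[st$tests$label == "benign" & st$tests$test == "size_t", ]
  expect_lt(tt$p_value, 0.05)
})

test_that("assignments must cover the cohort", {
  nc <- toy_cohort()
  asn <- data.frame(nodule_id = sprintf("t%02d", 1:11),
                    threshold_percentile = 90,
                    group = factor(rep("certain", 11),
                                   levels = c("certain", "uncertain")))
  expect_error(buildSubgroupTable(nc, asn), "cover")
})
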