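checkTwoClass <- function(labels, minPerClass = 1L) {
  m <- sum(labels == 1L)
  n <- sum(labels == 0L)
  if (m < minPerClass || n < minPerClass)
    stop("degenerate group: need at least ", minPerClass,
         " nodule(s) of each class (got ", m, " malignant, ", n, " benign)")
  c(pos = m, neg = n)
}

#' Area under the ROC curve
#'
#' The Mann-Whitney formulation: the probability that a randomly chosen
#' malignant nodule scores strictly higher than a randomly chosen benign one,
#' with ties counting one half. Computed through midranks, which is
#' algebraically identical to exhaustive pair counting.
#'
#' @param scores numeric risk scores, oriented so that higher means more
#'   malignant.
#' @param labels 0/1 labels (1 = malignant, the positive class).
#' @return The AUC in \[0, 1\].
#' @examples
#' rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  cls <- checkTwoClass(labels)
  m <- as.numeric(cls[["pos"]]); n <- as.numeric(cls[["neg"]])
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - m * (m + 1) / 2) / (m * n)
}

# DeLong structural components via midranks.
# V10[i] = mean_j psi(x_i, y_j), V01[j] = mean_i psi(x_i, y_j) with
# psi = 1 / 0.5 / 0 for x > y / x == y / x < y.
delongComponents <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  m <- length(pos); n <- length(neg)
  rAll <- rank(c(pos, neg), ties.method = "average")
  rPos <- rank(pos, ties.method = "average")
  rNeg <- rank(neg, ties.method = "average")
  v10 <- (rAll[seq_len(m)] - rPos) / n
  v01 <- 1 - (rAll[m + seq_len(n)] - rNeg) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong variance of the AUC estimator
#'
#' The nonparametric variance estimate from DeLong's structural components:
#' `var(V10)/m + var(V01)/n`, where `V10[i]` is the tie-corrected fraction of
#' benign nodules that malignant nodule i outscores and `V01[j]` the symmetric
#' quantity for benign nodule j (sample variances with denominator m-1, n-1).
#'
#' @inheritParams rocAuc
#' @return The variance of the AUC estimate (0 for perfectly separated data).
#' @export
delongVariance <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  checkTwoClass(labels, minPerClass = 2L)
  comp <- delongComponents(scores, labels)
  stats::var(comp$v10) / length(comp$v10) +
    stats::var(comp$v01) / length(comp$v01)
}

#' Bootstrap percentile confidence interval for the AUC
#'
#' Nodule-level resampling with replacement; resamples containing a single
#' class are redrawn. The interval is the percentile interval of the
#' resampled AUCs (linear-interpolation quantiles), deterministic given the
#' seed.
#'
#' @inheritParams rocAuc
#' @param reps number of bootstrap resamples (>= 1); 1000 by default.
#' @param seed integer seed for the resampling.
#' @param conf confidence level (default 0.95).
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrapAucCI <- function(scores, labels, reps = 1000L, seed = 1L,
                           conf = 0.95) {
  if (reps < 1L) stop("reps must be at least 1")
  labels <- as.integer(labels)
  checkTwoClass(labels)
  n <- length(scores)
  withSeed(seed, {
    aucs <- vapply(seq_len(reps), function(r) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L) break
      }
      rocAuc(scores[idx], labels[idx])
    }, numeric(1))
    alpha <- (1 - conf) / 2
    ci <- stats::quantile(aucs, c(alpha, 1 - alpha), type = 7, names = FALSE)
    c(low = ci[1], high = ci[2])
  })
}

#' Sensitivity at a fixed specificity
#'
#' The maximum sensitivity over all decision thresholds whose specificity is
#' at least `target_spec`, with the convention that a nodule is called
#' positive iff its score strictly exceeds the threshold. Thresholds are swept
#' over the distinct observed scores plus -Inf.
#'
#' @inheritParams rocAuc
#' @param target_spec required specificity (default 0.95).
#' @return The achievable sensitivity, a proportion in \[0, 1\].
#' @export
sensitivityAtSpecificity <- function(scores, labels, target_spec = 0.95) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  checkTwoClass(labels)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  thr <- c(-Inf, sort(unique(scores)))
  best <- 0
  for (t in thr) {
    spec <- mean(neg <= t)
    if (spec >= target_spec) best <- max(best, mean(pos > t))
  }
  best
}

#' Compare two AUCs with DeLong variances
#'
#' Unpaired z-test: `z = (aucA - aucB) / sqrt(varA + varB)` with a two-sided
#' normal p-value, appropriate for disjoint groups such as certain vs
#' uncertain. For overlapping groups (full cohort vs its certain subset) the
#' covariance between the two estimates is not estimable from group-level
#' inputs; pass `overlapping = TRUE` so the report flags the approximation.
#'
#' @param scoresA,labelsA scores and 0/1 labels of group A.
#' @param scoresB,labelsB scores and 0/1 labels of group B.
#' @param groupA,groupB tags used in reporting.
#' @param overlapping set `TRUE` when the two groups share nodules.
#' @return An [AucComparison-class].
#' @examples
#' s <- runif(200); l <- rbinom(200, 1, 0.3)
#' compareAuc(s, l, s, l)  # identical groups: z = 0, p = 1
#' @export
compareAuc <- function(scoresA, labelsA, scoresB, labelsB,
                       groupA = "A", groupB = "B", overlapping = FALSE) {
  aucA <- rocAuc(scoresA, labelsA)
  aucB <- rocAuc(scoresB, labelsB)
  varA <- delongVariance(scoresA, labelsA)
  varB <- delongVariance(scoresB, labelsB)
  se <- sqrt(varA + varB)
  z <- if (se == 0) {
    if (aucA == aucB) 0 else sign(aucA - aucB) * Inf
  } else (aucA - aucB) / se
  p <- 2 * stats::pnorm(-abs(z))
  new("AucComparison",
      groupA = groupA, groupB = groupB,
      aucA = aucA, aucB = aucB, varA = varA, varB = varB,
      zStatistic = z, pValue = p,
      paired = FALSE, overlapping = overlapping)
}

setMethod("show", "AucComparison", function(object) {
  cat(sprintf("DeLong AUC comparison: %s vs %s\n", object@groupA, object@groupB))
  cat(sprintf("  AUC %s = %.4f (var %.2e), AUC %s = %.4f (var %.2e)\n",
              object@groupA, object@aucA, object@varA,
              object@groupB, object@aucB, object@varB))
  cat(sprintf("  z = %.3f, two-sided p = %.4g%s\n", object@zStatistic,
              object@pValue,
              if (object@overlapping)
                "  [overlapping groups: covariance ignored]" else ""))
  invisible(NULL)
})

#' Discrimination report across certainty groups
#'
#' For each requested percentile threshold, evaluates the ensemble risk's
#' discrimination on the full cohort and on its certain and uncertain
#' subgroups: class counts, AUC with a bootstrap percentile CI, sensitivity at
#' 95% specificity with its bootstrap CI, and DeLong comparison p-values
#' (certain vs full, flagged as overlapping; uncertain vs certain, unpaired).
#' Groups in which one class is absent are reported with `NA` metrics and a
#' warning rather than dropped.
#'
#' @param cohort a scored [NoduleCohort-class].
#' @param thresholds a [ThresholdSet-class].
#' @param percentiles which calibrated percentiles to evaluate.
#' @param reps bootstrap resamples per group.
#' @param seed seed for all bootstrap resampling.
#' @param target_spec specificity at which sensitivity is reported.
#' @return A data frame, one row per group x percentile, with columns
#'   `group`, `percentile`, `n_benign`, `n_malignant`, `auc`, `ci_low`,
#'   `ci_high`, `sens_at_spec`, `sens_ci_low`, `sens_ci_high`, `p_value`,
#'   `p_versus`, `overlapping`, `bootstrap_reps`, `seed`.
#' @export
evaluatePerformance <- function(cohort, thresholds, percentiles = c(90, 95),
                                reps = 1000L, seed = 1L, target_spec = 0.95) {
  stopifnot(is(cohort, "NoduleCohort"))
  scores <- ensembleRisks(cohort)
  ent <- uncertaintyScores(cohort)
  labels <- noduleLabels(cohort)

  bootCis <- function(s, l, subSeed) {
    # one resampling stream yields both the AUC and the sensitivity CI
    n <- length(s)
    withSeed(subSeed, {
      est <- matrix(NA_real_, reps, 2)
      for (r in seq_len(reps)) {
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          if (length(unique(l[idx])) == 2L) break
        }
        est[r, 1] <- rocAuc(s[idx], l[idx])
        est[r, 2] <- sensitivityAtSpecificity(s[idx], l[idx], target_spec)
      }
      list(auc = stats::quantile(est[, 1], c(0.025, 0.975), type = 7, names = FALSE),
           sens = stats::quantile(est[, 2], c(0.025, 0.975), type = 7, names = FALSE))
    })
  }

  rows <- list()
  addRow <- function(tag, pct, s, l, pval = NA_real_, pvs = NA_character_,
                     overlap = FALSE, subSeed = seed) {
    ok <- length(unique(l)) == 2L
    if (!ok) {
      warning("group '", tag, "' has a single class; metrics reported as NA")
      rows[[length(rows) + 1L]] <<- data.frame(
        group = tag, percentile = pct, n_benign = sum(l == 0L),
        n_malignant = sum(l == 1L), auc = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, sens_at_spec = NA_real_, sens_ci_low = NA_real_,
        sens_ci_high = NA_real_, p_value = pval, p_versus = pvs,
        overlapping = overlap, bootstrap_reps = reps, seed = seed)
      return(invisible(NULL))
    }
    ci <- bootCis(s, l, subSeed)
    rows[[length(rows) + 1L]] <<- data.frame(
      group = tag, percentile = pct, n_benign = sum(l == 0L),
      n_malignant = sum(l == 1L), auc = rocAuc(s, l),
      ci_low = ci$auc[1], ci_high = ci$auc[2],
      sens_at_spec = sensitivityAtSpecificity(s, l, target_spec),
      sens_ci_low = ci$sens[1], sens_ci_high = ci$sens[2],
      p_value = pval, p_versus = pvs, overlapping = overlap,
      bootstrap_reps = reps, seed = seed)
    invisible(NULL)
  }

  addRow("full", NA_real_, scores, labels)
  for (pct in percentiles) {
    cert <- ent <= cutoffFor(thresholds, pct)
    pC <- tryCatch(
      compareAuc(scores, labels, scores[cert], labels[cert],
                 "full", "certain", overlapping = TRUE)@pValue,
      error = function(e) NA_real_)
    addRow("certain", pct, scores[cert], labels[cert], pC, "full", TRUE,
           subSeed = seed + 1L)
    pU <- tryCatch(
      compareAuc(scores[cert], labels[cert], scores[!cert], labels[!cert],
                 "certain", "uncertain")@pValue,
      error = function(e) NA_real_)
    addRow("uncertain", pct, scores[!cert], labels[!cert], pU, "certain",
           FALSE, subSeed = seed + 2L)
  }
  do.call(rbind, rows)
}
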