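#' Lung-RADS size class of a nodule
#'
#' Small: diameter < 6 mm; medium: >= 6 and < 8 mm; large: >= 8 mm (closed
#' lower bounds).
#'
#' @param diameter_mm positive nodule diameters in millimetres.
#' @return Factor with levels `small`, `medium`, `large`.
#' @examples
#' sizeClass(c(5.9, 6, 7.999, 8))
#' @export
sizeClass <- function(diameter_mm) {
  if (anyNA(diameter_mm) || any(diameter_mm <= 0))
    stop("diameter_mm must be positive")
  cut(diameter_mm, breaks = c(0, 6, 8, Inf), right = FALSE,
      labels = c("small", "medium", "large"))
}

#' Independent two-sample t-test on nodule sizes
#'
#' Thin wrapper over [stats::t.test()] exposing the pooled-variance Student
#' test (the classical "independent samples t-test", the default) and the
#' Welch variant.
#'
#' @param a,b numeric samples, each with at least 2 values.
#' @param variant `"pooled"` (Student, equal variances) or `"welch"`.
#' @return List with elements `t`, `df`, `p_value` (two-sided) and `variant`.
#' @export
sizeTTest <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values")
  ht <- stats::t.test(a, b, var.equal = variant == "pooled")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, variant = variant)
}

#' Chi-square test on a contingency table
#'
#' Pearson's chi-square via [stats::chisq.test()] with optional Yates
#' continuity correction (applied by R to 2 x 2 tables only). The default is
#' Yates-corrected, which reproduces published solid-vs-subsolid comparisons
#' of benign nodules across screening and clinical cohorts.
#'
#' @param table matrix of counts, at least 2 x 2.
#' @param yates apply the continuity correction (2 x 2 only).
#' @return List with `statistic`, `df` and `p_value`.
#' @examples
#' typeChisq(rbind(c(695, 123), c(136, 31)))
#' @export
typeChisq <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("table must have at least 2 rows and 2 columns")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("structural zero margin: a row or column of the table is all zero")
  ht <- suppressWarnings(stats::chisq.test(table, correct = yates))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Characterize certain and uncertain nodules by size and type
#'
#' Builds the subgroup characterization table for one cohort at one triage
#' threshold: per (label x certainty group) cell it reports the group size,
#' counts and percentages by nodule type and by Lung-RADS size class, and the
#' mean +- SD and median \[IQR\] diameter. When both certainty groups are
#' populated it attaches, per label, the independent-samples t-test on
#' diameters (certain vs uncertain) and chi-square tests on solid-vs-subsolid
#' composition and on size-class composition (part-solid and non-solid are
#' pooled as subsolid for testing). Empty cells are reported as zero counts,
#' never dropped.
#'
#' @param cohort a [NoduleCohort-class].
#' @param assignments data frame from [assignGroups()] covering every nodule
#'   of the cohort.
#' @param t_variant t-test variant, see [sizeTTest()].
#' @return An object of class `SubgroupTable`: a list with `summary` (data
#'   frame, one row per label x group) and `tests` (data frame, one row per
#'   label x test, zero rows when a certainty group is empty).
#' @export
buildSubgroupTable <- function(cohort, assignments,
                               t_variant = c("pooled", "welch")) {
  stopifnot(is(cohort, "NoduleCohort"))
  t_variant <- match.arg(t_variant)
  idx <- match(noduleIds(cohort), assignments$nodule_id)
  if (anyNA(idx))
    stop("assignments must cover every nodule in the cohort")
  grp <- assignments$group[idx]
  lab <- noduleLabels(cohort)
  diam <- noduleDiameters(cohort)
  type <- noduleTypes(cohort)
  scls <- sizeClass(diam)
  subsolid <- type != "solid"

  quart <- function(v, p) unname(stats::quantile(v, p, type = 7))
  rows <- list(); tests <- list()
  for (L in 0:1) {
    labName <- if (L == 0L) "benign" else "malignant"
    for (g in c("certain", "uncertain")) {
      sel <- lab == L & grp == g
      n <- sum(sel)
      typeN <- as.integer(table(type[sel]))
      sizeN <- as.integer(table(scls[sel]))
      rows[[length(rows) + 1L]] <- data.frame(
        label = labName, group = g, n = n,
        n_solid = typeN[1], n_part_solid = typeN[2], n_non_solid = typeN[3],
        pct_solid = if (n) 100 * typeN[1] / n else NA_real_,
        pct_part_solid = if (n) 100 * typeN[2] / n else NA_real_,
        pct_non_solid = if (n) 100 * typeN[3] / n else NA_real_,
        n_small = sizeN[1], n_medium = sizeN[2], n_large = sizeN[3],
        pct_small = if (n) 100 * sizeN[1] / n else NA_real_,
        pct_medium = if (n) 100 * sizeN[2] / n else NA_real_,
        pct_large = if (n) 100 * sizeN[3] / n else NA_real_,
        mean_mm = if (n) mean(diam[sel]) else NA_real_,
        sd_mm = if (n > 1) stats::sd(diam[sel]) else NA_real_,
        median_mm = if (n) quart(diam[sel], 0.5) else NA_real_,
        iqr_lo_mm = if (n) quart(diam[sel], 0.25) else NA_real_,
        iqr_hi_mm = if (n) quart(diam[sel], 0.75) else NA_real_)
    }
    selC <- lab == L & grp == "certain"
    selU <- lab == L & grp == "uncertain"
    if (sum(selC) >= 2L && sum(selU) >= 2L) {
      tt <- sizeTTest(diam[selC], diam[selU], t_variant)
      tests[[length(tests) + 1L]] <- data.frame(
        label = labName, test = "size_t", statistic = tt$t, df = tt$df,
        p_value = tt$p_value)
      solidTab <- rbind(certain = c(solid = sum(selC & !subsolid),
                                    subsolid = sum(selC & subsolid)),
                        uncertain = c(sum(selU & !subsolid),
                                      sum(selU & subsolid)))
      ct <- tryCatch(typeChisq(solidTab), error = function(e) NULL)
      if (!is.null(ct))
        tests[[length(tests) + 1L]] <- data.frame(
          label = labName, test = "type_chisq", statistic = ct$statistic,
          df = ct$df, p_value = ct$p_value)
      sizeTab <- rbind(certain = as.integer(table(scls[selC])),
                       uncertain = as.integer(table(scls[selU])))
      colnames(sizeTab) <- levels(scls)
      st <- tryCatch(typeChisq(sizeTab[, colSums(sizeTab) > 0, drop = FALSE]),
                     error = function(e) NULL)
      if (!is.null(st))
        tests[[length(tests) + 1L]] <- data.frame(
          label = labName, test = "size_chisq", statistic = st$statistic,
          df = st$df, p_value = st$p_value)
    }
  }
  out <- list(summary = do.call(rbind, rows),
              tests = if (length(tests)) do.call(rbind, tests)
                      else data.frame(label = character(), test = character(),
                                      statistic = numeric(), df = numeric(),
                                      p_value = numeric()))
  class(out) <- "SubgroupTable"
  out
}

#' @export
print.SubgroupTable <- function(x, ...) {
  cat("Subgroup characterization (certain vs uncertain)\n")
  print(x$summary, digits = 3, row.names = FALSE)
  if (nrow(x$tests)) {
    cat("\nBetween-group tests:\n")
    print(x$tests, digits = 3, row.names = FALSE)
  } else cat("\n(no between-group tests: a certainty group is empty)\n")
  invisible(x)
}
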