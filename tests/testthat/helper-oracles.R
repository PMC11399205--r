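# Independent brute-force oracles, deliberately naive: these re-derive the
# statistics from their definitions and never share code with the package.

# binary entropy summed term by term
oracle_mean_entropy <- function(members) {
  h <- vapply(members, function(p) {
    s <- 0
    if (p > 0) s <- s - p * log2(p)
    if (p < 1) s <- s - (1 - p) * log2(1 - p)
    s
  }, numeric(1))
  sum(h) / length(h)
}

# AUC by exhaustive positive-negative pair counting (ties count 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (x in pos) for (y in neg)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

# DeLong structural components from the psi kernel, written out elementwise
oracle_delong_var <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  psi <- function(x, y) if (x > y) 1 else if (x == y) 0.5 else 0
  v10 <- vapply(pos, function(x) mean(vapply(neg, function(y) psi(x, y),
                                             numeric(1))), numeric(1))
  v01 <- vapply(neg, function(y) mean(vapply(pos, function(x) psi(x, y),
                                             numeric(1))), numeric(1))
  var(v10) / m + var(v01) / n
}

# sensitivity at fixed specificity by sweeping every threshold
oracle_sens_at_spec <- function(scores, labels, target = 0.95) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  best <- 0
  for (t in c(-Inf, sort(unique(scores)), Inf)) {
    if (mean(neg <= t) >= target)
      best <- max(best, mean(pos > t))
  }
  best
}

# small labelled cohort with hand-enumerable structure (12 nodules)
toy_cohort <- function() {
  members <- matrix(rep(c(0.05, 0.10, 0.48, 0.52, 0.90, 0.95), each = 4),
                    nrow = 6, ncol = 4, byrow = FALSE)
  members <- rbind(members, members)
  NoduleCohort(
    members,
    label = c(0L, 0L, 0L, 1L, 1L, 1L, 0L, 0L, 0L, 1L, 1L, 1L),
    diameter_mm = c(4, 6, 8, 5.9, 7.9, 12, 3, 6.5, 9, 10, 15, 22),
    nodule_type = c("solid", "solid", "part-solid", "solid", "non-solid",
                    "solid", "solid", "part-solid", "solid", "solid",
                    "solid", "non-solid"),
    cohort = "development",
    nodule_id = sprintf("t%02d", 1:12))
}
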