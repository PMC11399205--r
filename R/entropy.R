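#' Binary entropy in bits
#'
#' The Shannon entropy of a Bernoulli(p) outcome,
#' \deqn{H(p) = -[p \log_2 p + (1-p) \log_2 (1-p)],}
#' with the exact convention \eqn{0 \log_2 0 = 0}, so that `binaryEntropy(0)`
#' and `binaryEntropy(1)` are exactly 0 and `binaryEntropy(0.5)` is exactly 1.
#'
#' @param p numeric vector of probabilities in \[0, 1\].
#' @return Entropies in bits, same length as `p`, each in \[0, 1\].
#' @examples
#' binaryEntropy(c(0, 0.2, 0.5, 1))
#' @export
binaryEntropy <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop("p must be a probability in [0, 1]")
  h <- numeric(length(p))
  inner <- p > 0 & p < 1
  q <- p[inner]
  h[inner] <- -(q * log2(q) + (1 - q) * log2(1 - q))
  h
}

#' Mean entropy of an ensemble prediction vector
#'
#' The per-nodule uncertainty score: the average of the binary entropies of
#' the N member probabilities,
#' \deqn{\bar H = \frac{1}{N}\sum_{i=1}^{N} H(p_i).}
#' It is maximal (1 bit) when every member predicts 0.5 and zero exactly when
#' every member is 0 or 1. Note that it measures per-member confidence, not
#' inter-member disagreement: members alternating between 0 and 1 score 0.
#'
#' @param members numeric vector of N >= 1 member probabilities in \[0, 1\].
#' @return Mean entropy in bits, a scalar in \[0, 1\].
#' @examples
#' meanEntropy(rep(0.5, 20))   # 1
#' meanEntropy(c(0, 1, 0, 1))  # 0: each member individually certain
#' @export
meanEntropy <- function(members) {
  if (length(members) < 1L) stop("members must contain at least one probability")
  mean(binaryEntropy(members))
}

#' Ensemble malignancy risk
#'
#' The pooled malignancy-risk estimate for a nodule: the unweighted arithmetic
#' mean of the member probabilities.
#'
#' @inheritParams meanEntropy
#' @return A probability in \[min(members), max(members)\].
#' @examples
#' ensembleRisk(c(0, 1))  # 0.5
#' @export
ensembleRisk <- function(members) {
  if (length(members) < 1L) stop("members must contain at least one probability")
  if (!is.numeric(members) || anyNA(members) || any(members < 0) || any(members > 1))
    stop("members must be probabilities in [0, 1]")
  mean(members)
}

#' Score a cohort's uncertainty and ensemble risk
#'
#' Adds (or refreshes) `mean_entropy` and `ensemble_risk` columns in the
#' cohort's row metadata, computed row-wise from the member matrix with
#' [meanEntropy()] and [ensembleRisk()].
#'
#' @param x a [NoduleCohort-class].
#' @param ... unused.
#' @return The cohort with scored row metadata.
#' @examples
#' nc <- generateCohort(cohortPreset("screening", n_nodules = 50, seed = 1))
#' nc <- scoreUncertainty(nc)
#' head(uncertaintyScores(nc))
#' @name scoreUncertainty
NULL

#' @rdname scoreUncertainty
#' @export
setMethod("scoreUncertainty", "NoduleCohort", function(x, ...) {
  m <- memberProbs(x)
  ent <- binaryEntropy(as.vector(m))
  dim(ent) <- dim(m)
  rowData(x)$mean_entropy <- rowMeans(ent)
  rowData(x)$ensemble_risk <- rowMeans(m)
  validObject(x)
  x
})

#' Extract per-nodule scores from a scored cohort
#'
#' @param x a scored [NoduleCohort-class] (see [scoreUncertainty()]).
#' @return `uncertaintyScores()`: named vector of mean entropies (bits);
#'   `ensembleRisks()`: named vector of pooled malignancy risks.
#' @export
uncertaintyScores <- function(x) {
  stopifnot(is(x, "NoduleCohort"))
  rd <- rowData(x)
  if (!"mean_entropy" %in% colnames(rd))
    stop("cohort is unscored: run scoreUncertainty() first")
  out <- rd$mean_entropy
  names(out) <- rownames(x)
  out
}

#' @rdname uncertaintyScores
#' @export
ensembleRisks <- function(x) {
  stopifnot(is(x, "NoduleCohort"))
  rd <- rowData(x)
  if (!"ensemble_risk" %in% colnames(rd))
    stop("cohort is unscored: run scoreUncertainty() first")
  out <- rd$ensemble_risk
  names(out) <- rownames(x)
  out
}
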