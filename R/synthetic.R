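#' Latent difficulty model parameters
#'
#' The generator links each nodule's label, size and type to a latent
#' difficulty d in \[0, 1\] through a logistic model on
#' \deqn{z = intercept + malignant \cdot 1[malignant] + subsolid \cdot
#'   1[part\text{-}solid\ or\ non\text{-}solid] + benign\_size \cdot
#'   1[benign] \cdot s(diam) + \epsilon,\qquad \epsilon \sim N(0, \sigma^2),}
#' with \eqn{s(diam) = \min(\max(\log_2(diam/6), 0), 2)}, so difficulty rises
#' for subsolid nodules and for large benign nodules. Given d, the ensemble's
#' central tendency on the logit scale is
#' \eqn{e \sim N((2L-1)\,separation\,(1-d)^{decay},\ (noise \cdot 4d(1-d))^2)}
#' and members are conditionally i.i.d.
#' \eqn{Beta(\mu\kappa, (1-\mu)\kappa)} with \eqn{\mu = logit^{-1}(e)} and
#' concentration \eqn{\kappa = \kappa_c^{1-d} \kappa_u^{d}}. At d = 0 members
#' concentrate near 0 or 1 (mean entropy < 0.1 bits); at d = 1 they
#' concentrate around 0.5 (mean entropy near 1 bit); at intermediate d the
#' bell-shaped evidence noise lets the ensemble land confidently on the wrong
#' side, which is what degrades discrimination in the uncertain group.
#'
#' @param intercept baseline difficulty on the logit scale (small benign solid
#'   nodules).
#' @param malignant additive logit shift for malignant nodules.
#' @param subsolid additive logit shift for part-solid/non-solid nodules.
#' @param benign_size slope on the capped log2 size score, benign nodules only.
#' @param sigma SD of the per-nodule difficulty noise.
#' @param separation evidence magnitude at zero difficulty (logit scale).
#' @param decay exponent of the evidence collapse with difficulty.
#' @param noise scale of the bell-shaped evidence noise.
#' @param kappa_certain,kappa_uncertain Beta concentration at difficulty 0 / 1.
#' @param fixed if not `NA`, force this difficulty for every nodule (used for
#'   limit checks).
#' @return Named list of parameters.
#' @export
difficultyModel <- function(intercept = -2.7, malignant = 2.1, subsolid = 1.9,
                            benign_size = 2.8, sigma = 0.8, separation = 5,
                            decay = 3, noise = 2.2, kappa_certain = 500,
                            kappa_uncertain = 40, fixed = NA_real_) {
  list(intercept = intercept, malignant = malignant, subsolid = subsolid,
       benign_size = benign_size, sigma = sigma, separation = separation,
       decay = decay, noise = noise, kappa_certain = kappa_certain,
       kappa_uncertain = kappa_uncertain, fixed = fixed)
}

#' Construct a cohort simulation configuration
#'
#' Defaults describe a screening-like development cohort: 883 nodules of which
#' 65 are malignant, benign sizes log-normal around a 5 mm median, malignant
#' around 11 mm, type mixes of roughly 85%/69% solid among benign/malignant,
#' and an ensemble of 20 members.
#'
#' @param n_nodules cohort size.
#' @param malignant_fraction expected malignant fraction.
#' @param n_members ensemble size (>= 2).
#' @param type_mix either a 2 x 3 matrix (rows benign, malignant; columns
#'   solid, part-solid, non-solid) or a length-3 vector used for both labels.
#'   Rows must sum to 1 within 1e-9.
#' @param size_distribution list with `benign` and `malignant` elements, each
#'   `list(median_mm=, sdlog=)`, and `trunc_mm` (sizes are resampled below it).
#' @param difficulty_model see [difficultyModel()].
#' @param seed integer RNG seed.
#' @return A validated [CohortConfig-class].
#' @examples
#' cfg <- cohortConfig(n_nodules = 100, seed = 7)
#' nc <- generateCohort(cfg)
#' @export
cohortConfig <- function(n_nodules = 883L,
                         malignant_fraction = 65 / 883,
                         n_members = 20L,
                         type_mix = NULL,
                         size_distribution = NULL,
                         difficulty_model = difficultyModel(),
                         seed = 20260101L) {
  if (is.null(type_mix))
    type_mix <- rbind(benign = c(0.850, 0.033, 0.117),
                      malignant = c(0.692, 0.185, 0.123))
  if (is.vector(type_mix) && is.numeric(type_mix))
    type_mix <- rbind(benign = type_mix, malignant = type_mix)
  type_mix <- as.matrix(type_mix)
  dimnames(type_mix) <- list(c("benign", "malignant"), .NODULE_TYPES)
  if (is.null(size_distribution))
    size_distribution <- list(
      benign = list(median_mm = 5, sdlog = 0.415),
      malignant = list(median_mm = 11, sdlog = 0.559),
      trunc_mm = 2)
  new("CohortConfig",
      nNodules = as.integer(n_nodules),
      malignantFraction = as.numeric(malignant_fraction),
      nMembers = as.integer(n_members),
      typeMix = type_mix,
      sizeDistribution = size_distribution,
      difficultyModel = difficulty_model,
      seed = as.integer(seed))
}

#' Preset cohort configurations
#'
#' `"screening"` emulates a lung-cancer screening development cohort
#' (883 nodules, 65 malignant, mostly small benign nodules). `"clinical"`
#' emulates a clinically-detected external cohort (374 nodules, 207 malignant,
#' larger nodules, more solid malignancies) with a higher baseline difficulty
#' (+0.5 on the latent logit), reflecting the heterogeneous acquisition of
#' clinical data relative to a screening trial.
#'
#' @param preset `"screening"` or `"clinical"`.
#' @param n_nodules,seed overrides of the preset size and seed.
#' @return A [CohortConfig-class].
#' @export
cohortPreset <- function(preset = c("screening", "clinical"),
                         n_nodules = NULL, seed = 20260101L) {
  preset <- match.arg(preset)
  if (preset == "screening") {
    cfg <- cohortConfig(n_nodules = if (is.null(n_nodules)) 883L else n_nodules,
                        seed = seed)
  } else {
    cfg <- cohortConfig(
      n_nodules = if (is.null(n_nodules)) 374L else n_nodules,
      malignant_fraction = 207 / 374,
      type_mix = rbind(benign = c(0.814, 0.048, 0.138),
                       malignant = c(0.903, 0.073, 0.024)),
      size_distribution = list(
        benign = list(median_mm = 6.8, sdlog = 0.578),
        malignant = list(median_mm = 22.4, sdlog = 0.654),
        trunc_mm = 2),
      difficulty_model = difficultyModel(intercept = -2.7 + 0.5),
      seed = seed)
  }
  cfg
}

# run expr with the global RNG state saved and restored, seeding it first
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic nodule cohort
#'
#' Draws labels, types, sizes, latent difficulties and ensemble member
#' probability vectors according to the configuration; see [difficultyModel()]
#' for the generative model. Generation is bit-for-bit reproducible given the
#' config seed.
#'
#' @param config a [CohortConfig-class].
#' @param cohort cohort tag recorded in the output, `"development"` or
#'   `"external"`.
#' @param ... unused.
#' @return An unscored [NoduleCohort-class]. The latent difficulty is kept in
#'   `rowData(x)$difficulty` for diagnostics; it is not written by
#'   [writeCohort()].
#' @examples
#' nc <- generateCohort(cohortPreset("screening", n_nodules = 100, seed = 1))
#' nc
#' @name generateCohort
NULL

#' @rdname generateCohort
#' @export
setMethod("generateCohort", "CohortConfig", function(config,
    cohort = c("development", "external"), ...) {
  validObject(config)
  cohort <- match.arg(cohort)
  n <- config@nNodules
  dm <- config@difficultyModel
  withSeed(config@seed, {
    label <- stats::rbinom(n, 1L, config@malignantFraction)
    type <- character(n)
    diam <- numeric(n)
    for (L in 0:1) {
      idx <- which(label == L)
      if (!length(idx)) next
      row <- if (L == 0L) "benign" else "malignant"
      type[idx] <- sample(.NODULE_TYPES, length(idx), replace = TRUE,
                          prob = config@typeMix[row, ])
      sp <- config@sizeDistribution[[row]]
      d <- stats::rlnorm(length(idx), log(sp$median_mm), sp$sdlog)
      lo <- config@sizeDistribution$trunc_mm
      while (any(d < lo))
        d[d < lo] <- stats::rlnorm(sum(d < lo), log(sp$median_mm), sp$sdlog)
      diam[idx] <- d
    }
    subsolid <- type != "solid"
    sizeScore <- pmax(0, pmin(log2(diam / 6), 2))
    z <- dm$intercept + dm$malignant * label + dm$subsolid * subsolid +
      dm$benign_size * (1 - label) * sizeScore + stats::rnorm(n, 0, dm$sigma)
    difficulty <- stats::plogis(z)
    if (!is.na(dm$fixed)) difficulty <- rep(dm$fixed, n)
    kappa <- dm$kappa_certain^(1 - difficulty) * dm$kappa_uncertain^difficulty
    tau <- dm$noise * 4 * difficulty * (1 - difficulty)
    evidence <- stats::rnorm(n, (2 * label - 1) * dm$separation *
                                (1 - difficulty)^dm$decay, tau)
    mu <- stats::plogis(evidence)
    members <- matrix(
      stats::rbeta(n * config@nMembers,
                   rep(mu * kappa, config@nMembers),
                   rep((1 - mu) * kappa, config@nMembers)),
      nrow = n, ncol = config@nMembers)
    nc <- NoduleCohort(members, label = label, diameter_mm = diam,
                       nodule_type = type, cohort = cohort,
                       nodule_id = sprintf("%s%05d",
                                           if (cohort == "development") "dev" else "ext",
                                           seq_len(n)))
    rowData(nc)$difficulty <- difficulty
    nc
  })
})

#' Calibrate the generator to a target full-cohort AUC
#'
#' Searches over the difficulty-model intercept (holding every other parameter
#' fixed) until the simulated full-cohort AUC of the ensemble risk matches the
#' target. Each evaluation averages the AUC over `replicates` cohorts of size
#' `n` generated from seeds derived from the config seed, so the search is
#' deterministic and the simulated AUC is (to Monte-Carlo noise) monotonically
#' decreasing in the intercept; bisection brackets the target.
#'
#' @param config a [CohortConfig-class]; its `nNodules` is ignored in favour of
#'   `n`.
#' @param target_auc desired full-cohort AUC of ensemble risk vs label.
#' @param n simulation size per evaluation (default 2000).
#' @param replicates cohorts averaged per evaluation.
#' @param interval intercept search bracket.
#' @param tol AUC tolerance at which bisection stops.
#' @return The config with the calibrated intercept, with the achieved AUC in
#'   the attribute `"achieved_auc"`.
#' @export
calibrateDifficulty <- function(config, target_auc, n = 2000L, replicates = 3L,
                                interval = c(-8, 4), tol = 0.005) {
  stopifnot(is(config, "CohortConfig"), target_auc > 0.5, target_auc < 1)
  evalAuc <- function(a0) {
    mean(vapply(seq_len(replicates), function(r) {
      cfg <- config
      cfg@nNodules <- as.integer(n)
      cfg@seed <- as.integer((config@seed + 7907L * r) %% .Machine$integer.max)
      cfg@difficultyModel$intercept <- a0
      nc <- scoreUncertainty(generateCohort(cfg))
      rocAuc(ensembleRisks(nc), noduleLabels(nc))
    }, numeric(1)))
  }
  lo <- interval[1]; hi <- interval[2]
  if (evalAuc(lo) < target_auc || evalAuc(hi) > target_auc)
    stop("target_auc not bracketed by the intercept interval")
  for (i in seq_len(40)) {
    mid <- (lo + hi) / 2
    a <- evalAuc(mid)
    if (abs(a - target_auc) < tol) break
    if (a > target_auc) lo <- mid else hi <- mid
  }
  out <- config
  out@difficultyModel$intercept <- mid
  attr(out, "achieved_auc") <- a
  out
}
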