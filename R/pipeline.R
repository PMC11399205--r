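#' Assemble a pipeline run configuration
#'
#' @param development path to a cohort CSV, or a [CohortConfig-class] to
#'   simulate the development cohort.
#' @param external optional path or [CohortConfig-class] for the external
#'   cohort; `NULL` runs a development-only analysis.
#' @param percentiles triage percentiles in (0, 100).
#' @param bootstrap_reps bootstrap resamples for confidence intervals (>= 1).
#' @param seed master seed; stage-specific sub-seeds are derived from it so
#'   that, e.g., changing `bootstrap_reps` does not perturb cohort generation.
#' @param output_dir directory the report bundle is written to.
#' @return A validated list of class `RunConfig`.
#' @export
runConfig <- function(development, external = NULL, percentiles = c(90, 95),
                      bootstrap_reps = 1000L, seed = 1L,
                      output_dir = tempfile("uqtriage_run_")) {
  if (any(percentiles <= 0 | percentiles >= 100))
    stop("invalid RunConfig field 'percentiles': must lie strictly in (0, 100)")
  if (bootstrap_reps < 1L)
    stop("invalid RunConfig field 'bootstrap_reps': must be at least 1")
  cfg <- list(development = development, external = external,
              percentiles = sort(percentiles),
              bootstrap_reps = as.integer(bootstrap_reps),
              seed = as.integer(seed), output_dir = output_dir)
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [runConfig()]: `development`/`external` are either file
#' paths (string) or mappings with cohort-generator fields (`n_nodules`,
#' `malignant_fraction`, `n_members`, `seed`, optional `preset`, optional
#' `difficulty_model` overrides for [difficultyModel()]).
#'
#' @param path YAML file.
#' @return A `RunConfig`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  parseCohort <- function(node) {
    if (is.null(node)) return(NULL)
    if (is.character(node)) return(node)
    if (!is.null(node$preset)) {
      cfg <- cohortPreset(node$preset,
                          n_nodules = node$n_nodules,
                          seed = if (is.null(node$seed)) 20260101L else node$seed)
      return(cfg)
    }
    dm <- do.call(difficultyModel,
                  if (is.null(node$difficulty_model)) list()
                  else node$difficulty_model)
    args <- node[intersect(names(node),
                           c("n_nodules", "malignant_fraction", "n_members",
                             "seed"))]
    do.call(cohortConfig, c(args, list(difficulty_model = dm)))
  }
  runConfig(development = parseCohort(y$development),
            external = parseCohort(y$external),
            percentiles = if (is.null(y$percentiles)) c(90, 95)
                          else as.numeric(y$percentiles),
            bootstrap_reps = if (is.null(y$bootstrap_reps)) 1000L
                             else y$bootstrap_reps,
            seed = if (is.null(y$seed)) 1L else y$seed,
            output_dir = if (is.null(y$output_dir)) tempfile("uqtriage_run_")
                         else y$output_dir)
}

# derive independent stage sub-seeds from the master seed (all < 2^31)
stageSeeds <- function(seed) {
  withSeed(seed, {
    s <- sample.int(.Machine$integer.max - 1L, 4L)
    list(generate_dev = s[1], generate_ext = s[2],
         bootstrap_dev = s[3], bootstrap_ext = s[4])
  })
}

loadOrGenerate <- function(input, tag, subSeed) {
  if (is.character(input)) return(readCohort(input))
  if (is(input, "CohortConfig")) {
    cfg <- input
    cfg@seed <- as.integer(subSeed)
    return(generateCohort(cfg, cohort = tag))
  }
  stop("cohort input must be a file path or a CohortConfig")
}

writeScoresCsv <- function(cohort, path) {
  df <- data.frame(nodule_id = noduleIds(cohort),
                   mean_entropy = uncertaintyScores(cohort),
                   ensemble_risk = ensembleRisks(cohort), row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
}

#' Run the full uncertainty-triage analysis
#'
#' Executes score -> calibrate -> triage -> evaluate -> subgroup end to end
#' and writes a machine-readable report bundle: per-cohort scores CSV,
#' threshold JSON, assignment CSVs, performance JSON/CSV (one row per group x
#' percentile), subgroup summary and test CSVs, and a run manifest (seed,
#' package version, config digest). Identical config and seed produce a
#' byte-identical bundle.
#'
#' @param config a `RunConfig` from [runConfig()] or [readRunConfig()].
#' @param quiet suppress stage-progress messages.
#' @return Invisibly, a list with the in-memory results (`development`,
#'   `external` cohorts, `thresholds`, `assignments`, `performance`,
#'   `subgroups`, `output_dir`).
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- stageSeeds(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  dev <- stage("load_development",
               loadOrGenerate(config$development, "development",
                              seeds$generate_dev))
  say("load_development", "%d nodules (%d malignant)", nrow(dev),
      sum(noduleLabels(dev) == 1L))
  dev <- stage("score", scoreUncertainty(dev))
  ths <- stage("calibrate",
               calibrateThresholds(dev, percentiles = config$percentiles))
  say("calibrate", "cutoffs: %s",
      paste(sprintf("p%g=%.4f", ths@percentiles, ths@cutoffs), collapse = ", "))

  cohorts <- list(development = dev)
  if (!is.null(config$external)) {
    ext <- stage("load_external",
                 loadOrGenerate(config$external, "external", seeds$generate_ext))
    ext <- stage("score", scoreUncertainty(ext))
    say("load_external", "%d nodules (%d malignant)", nrow(ext),
        sum(noduleLabels(ext) == 1L))
    cohorts$external <- ext
  }

  assignments <- list(); perf <- list(); subgr <- list()
  for (tag in names(cohorts)) {
    nc <- cohorts[[tag]]
    asn <- do.call(rbind, lapply(config$percentiles, function(p)
      assignGroups(nc, ths, p)))
    assignments[[tag]] <- asn
    say("triage", "%s: %s", tag,
        paste(sprintf("p%g uncertain=%d", config$percentiles,
                      vapply(config$percentiles, function(p)
                        sum(asn$group == "uncertain" &
                            asn$threshold_percentile == p), integer(1))),
              collapse = ", "))
    perf[[tag]] <- stage("evaluate",
      evaluatePerformance(nc, ths, percentiles = config$percentiles,
                          reps = config$bootstrap_reps,
                          seed = seeds[[paste0("bootstrap_",
                                               substr(tag, 1, 3))]]))
    firstPct <- config$percentiles[1]
    subgr[[tag]] <- stage("subgroup",
      buildSubgroupTable(nc, asn[asn$threshold_percentile == firstPct, ]))

    writeScoresCsv(nc, file.path(out, sprintf("scores_%s.csv", tag)))
    utils::write.csv(asn, file.path(out, sprintf("assignments_%s.csv", tag)),
                     row.names = FALSE, quote = FALSE, eol = "\n")
    utils::write.csv(perf[[tag]],
                     file.path(out, sprintf("performance_%s.csv", tag)),
                     row.names = FALSE, quote = TRUE, eol = "\n")
    jsonlite::write_json(perf[[tag]],
                         file.path(out, sprintf("performance_%s.json", tag)),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    utils::write.csv(subgr[[tag]]$summary,
                     file.path(out, sprintf("subgroups_%s.csv", tag)),
                     row.names = FALSE, quote = FALSE, eol = "\n")
    utils::write.csv(subgr[[tag]]$tests,
                     file.path(out, sprintf("subgroup_tests_%s.csv", tag)),
                     row.names = FALSE, quote = FALSE, eol = "\n")
  }
  writeThresholds(ths, file.path(out, "thresholds.json"))

  manifest <- list(
    seed = config$seed,
    stage_seeds = seeds,
    percentiles = config$percentiles,
    bootstrap_reps = config$bootstrap_reps,
    package_version = as.character(utils::packageVersion("uqtriage")),
    cohorts = names(cohorts))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done", "bundle written to %s", out)
  invisible(list(development = dev,
                 external = cohorts$external,
                 thresholds = ths, assignments = assignments,
                 performance = perf, subgroups = subgr, output_dir = out))
}
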