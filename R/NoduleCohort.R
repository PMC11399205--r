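#' Construct a NoduleCohort
#'
#' Assembles per-nodule metadata and the ensemble member probability matrix
#' into a validated [NoduleCohort-class] object.
#'
#' @param members numeric matrix, nodules x ensemble members, probabilities in
#'   \[0, 1\].
#' @param label integer vector of ground-truth labels, 0 = benign,
#'   1 = malignant.
#' @param diameter_mm positive nodule diameters in millimetres.
#' @param nodule_type character or factor with levels `"solid"`,
#'   `"part-solid"`, `"non-solid"` (underscored spellings are accepted).
#' @param cohort cohort tag, typically `"development"` or `"external"`;
#'   recycled to all nodules if scalar.
#' @param nodule_id unique nodule identifiers; defaults to the rownames of
#'   `members` or zero-padded sequential ids.
#'
#' @return A [NoduleCohort-class].
#' @examples
#' m <- matrix(runif(40), nrow = 2)
#' nc <- NoduleCohort(m, label = c(0L, 1L), diameter_mm = c(5, 12),
#'                    nodule_type = c("solid", "part-solid"))
#' nc
#' @export
NoduleCohort <- function(members, label, diameter_mm, nodule_type,
                         cohort = "development", nodule_id = NULL) {
  members <- as.matrix(members)
  n <- nrow(members)
  if (is.null(nodule_id)) {
    nodule_id <- rownames(members)
    if (is.null(nodule_id))
      nodule_id <- sprintf("nod%05d", seq_len(n))
  }
  if (length(cohort) == 1L) cohort <- rep(cohort, n)
  nodule_type <- normalizeNoduleType(nodule_type)
  rownames(members) <- nodule_id
  colnames(members) <- sprintf("member_%02d", seq_len(ncol(members)))
  rd <- S4Vectors::DataFrame(
    cohort = as.character(cohort),
    label = as.integer(label),
    diameter_mm = as.numeric(diameter_mm),
    nodule_type = factor(nodule_type, levels = .NODULE_TYPES),
    row.names = nodule_id
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(members = members), rowData = rd)
  new("NoduleCohort", se)
}

# accept both "part-solid" and "part_solid" spellings (the CSV dialect uses
# underscores); always store hyphenated levels internally
normalizeNoduleType <- function(x) {
  x <- gsub("_", "-", as.character(x))
  bad <- setdiff(unique(x), .NODULE_TYPES)
  if (length(bad))
    stop("unknown nodule_type value(s): ", paste(bad, collapse = ", "))
  x
}

#' Accessors for NoduleCohort
#'
#' `memberProbs()` returns the nodules x members probability matrix;
#' `noduleLabels()`, `noduleDiameters()`, `noduleTypes()`, `cohortTag()` and
#' `noduleIds()` return the corresponding per-nodule metadata.
#'
#' @param x a [NoduleCohort-class].
#' @return A matrix (`memberProbs`) or vector of length `nrow(x)`.
#' @name NoduleCohort-accessors
NULL

#' @rdname NoduleCohort-accessors
#' @export
setMethod("memberProbs", "NoduleCohort", function(x)
  SummarizedExperiment::assay(x, "members"))

#' @rdname NoduleCohort-accessors
#' @export
setMethod("noduleLabels", "NoduleCohort", function(x) {
  out <- rowData(x)$label
  names(out) <- rownames(x)
  out
})

#' @rdname NoduleCohort-accessors
#' @export
setMethod("noduleDiameters", "NoduleCohort", function(x) {
  out <- rowData(x)$diameter_mm
  names(out) <- rownames(x)
  out
})

#' @rdname NoduleCohort-accessors
#' @export
setMethod("noduleTypes", "NoduleCohort", function(x) {
  out <- rowData(x)$nodule_type
  names(out) <- rownames(x)
  out
})

#' @rdname NoduleCohort-accessors
#' @export
setMethod("cohortTag", "NoduleCohort", function(x)
  as.character(unique(rowData(x)$cohort)))

#' @rdname NoduleCohort-accessors
#' @export
setMethod("noduleIds", "NoduleCohort", function(x) rownames(x))

setMethod("show", "NoduleCohort", function(object) {
  rd <- rowData(object)
  cat(sprintf("NoduleCohort: %d nodules x %d ensemble members\n",
              nrow(object), ncol(memberProbs(object))))
  cat(sprintf("  cohort tag(s): %s\n", paste(unique(rd$cohort), collapse = ", ")))
  cat(sprintf("  benign: %d   malignant: %d\n",
              sum(rd$label == 0L), sum(rd$label == 1L)))
  tt <- table(rd$nodule_type)
  cat(sprintf("  types: %s\n",
              paste(sprintf("%s=%d", names(tt), tt), collapse = "  ")))
  if ("mean_entropy" %in% colnames(rd))
    cat(sprintf("  mean entropy (bits): median %.3f, max %.3f\n",
                stats::median(rd$mean_entropy), max(rd$mean_entropy)))
  else
    cat("  (unscored: run scoreUncertainty())\n")
  invisible(NULL)
})
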