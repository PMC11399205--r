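#' Write a cohort to CSV
#'
#' The on-disk dialect is a UTF-8, LF-terminated CSV with header
#' `nodule_id,cohort,label,diameter_mm,nodule_type,member_01,...,member_NN`;
#' `label` is 0/1 and `nodule_type` uses underscored spellings
#' (`solid`, `part_solid`, `non_solid`). Numeric fields are written with 15
#' significant digits, so a write/read round trip preserves all fields to
#' within 1e-12.
#'
#' @param x a [NoduleCohort-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(x, path) {
  stopifnot(is(x, "NoduleCohort"))
  m <- memberProbs(x)
  df <- data.frame(
    nodule_id = rownames(x),
    cohort = as.character(rowData(x)$cohort),
    label = rowData(x)$label,
    diameter_mm = format(rowData(x)$diameter_mm, digits = 15, trim = TRUE,
                         scientific = FALSE),
    nodule_type = gsub("-", "_", as.character(rowData(x)$nodule_type)),
    stringsAsFactors = FALSE)
  mm <- apply(m, 2, function(col)
    format(col, digits = 15, trim = TRUE, scientific = FALSE))
  df <- cbind(df, as.data.frame(mm, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a cohort CSV
#'
#' Checks the file against the cohort schema without constructing an object:
#' header layout, label/type enums, diameter positivity, member probability
#' ranges, and nodule-id uniqueness.
#'
#' @param path file to validate.
#' @return A data frame of diagnostics with columns `row` (1-based data row,
#'   `NA` for file-level problems), `column` and `problem`; zero rows when the
#'   file is valid.
#' @export
validateCohortFile <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  diags <- list()
  note <- function(row, column, problem)
    diags[[length(diags) + 1L]] <<- data.frame(row = row, column = column,
                                               problem = problem)
  fixed <- c("nodule_id", "cohort", "label", "diameter_mm", "nodule_type")
  if (!identical(colnames(df)[seq_along(fixed)], fixed)) {
    note(NA_integer_, "header",
         paste0("expected leading columns ", paste(fixed, collapse = ",")))
    return(do.call(rbind, diags))
  }
  memberCols <- colnames(df)[-seq_along(fixed)]
  if (length(memberCols) < 2L ||
      !identical(memberCols, sprintf("member_%02d", seq_along(memberCols))))
    note(NA_integer_, "header",
         "member columns must be member_01..member_NN (N >= 2) in order")
  dup <- duplicated(df$nodule_id)
  for (i in which(dup))
    note(i, "nodule_id", paste0("duplicated nodule_id: ", df$nodule_id[i]))
  lab <- df$label
  for (i in which(!lab %in% c("0", "1")))
    note(i, "label", paste0("label must be 0 or 1, got '", lab[i], "'"))
  dmm <- suppressWarnings(as.numeric(df$diameter_mm))
  for (i in which(is.na(dmm) | dmm <= 0))
    note(i, "diameter_mm", paste0("diameter_mm must be a positive number, got '",
                                  df$diameter_mm[i], "'"))
  okType <- c("solid", "part_solid", "non_solid")
  for (i in which(!df$nodule_type %in% okType))
    note(i, "nodule_type", paste0("nodule_type must be one of ",
                                  paste(okType, collapse = "/"),
                                  ", got '", df$nodule_type[i], "'"))
  for (cn in memberCols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    for (i in which(is.na(v) | v < 0 | v > 1))
      note(i, cn, paste0("member probability out of [0, 1] for nodule_id ",
                         df$nodule_id[i], ": '", df[[cn]][i], "'"))
  }
  if (length(diags)) do.call(rbind, diags)
  else data.frame(row = integer(), column = character(), problem = character())
}

#' Read a cohort from CSV
#'
#' Parses and validates a file in the [writeCohort()] dialect. Any schema or
#' range violation aborts with a message naming the offending row/column.
#'
#' @param path file to read.
#' @return A [NoduleCohort-class].
#' @export
readCohort <- function(path) {
  diags <- validateCohortFile(path)
  if (nrow(diags))
    stop("invalid cohort file '", path, "':\n  ",
         paste(sprintf("row %s, %s: %s", diags$row, diags$column, diags$problem),
               collapse = "\n  "))
  df <- utils::read.csv(path, check.names = FALSE)
  memberCols <- grep("^member_\\d+$", colnames(df), value = TRUE)
  NoduleCohort(as.matrix(df[memberCols]),
               label = df$label,
               diameter_mm = df$diameter_mm,
               nodule_type = df$nodule_type,
               cohort = df$cohort,
               nodule_id = df$nodule_id)
}

#' Serialize / restore calibrated thresholds as JSON
#'
#' Thresholds are written as a JSON array of
#' `{percentile, cutoff, source_cohort, n_source}` records so that applying a
#' development-calibrated threshold to an external cohort is auditable.
#'
#' @param x a [ThresholdSet-class].
#' @param path JSON file path.
#' @return `writeThresholds()`: `path` invisibly; `readThresholds()`: a
#'   [ThresholdSet-class].
#' @export
writeThresholds <- function(x, path) {
  stopifnot(is(x, "ThresholdSet"))
  recs <- lapply(seq_along(x@percentiles), function(i)
    list(percentile = x@percentiles[i], cutoff = x@cutoffs[i],
         source_cohort = x@sourceCohort, n_source = x@nSource))
  # I(17) significant digits: cutoffs are order statistics of the scores, so
  # the serialized value must round-trip exactly for the tie rule to hold
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeThresholds
#' @export
readThresholds <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ThresholdSet",
      percentiles = as.numeric(recs$percentile),
      cutoffs = as.numeric(recs$cutoff),
      sourceCohort = unique(as.character(recs$source_cohort)),
      nSource = as.integer(unique(recs$n_source)))
}
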