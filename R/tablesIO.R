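CANONICAL_FEATURE_COLS <- c("feature_id", "mz", "charge", "rt",
                            "has_msms", "sequence")

.read_delim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = '"',
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "")
}

.write_delim <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = TRUE,
                     na = "")
  invisible(path)
}

#' Read a feature quantification table
#'
#' Reads a wide delimited table (one row per LC-MS feature, one column per
#' sample) in the canonical dialect or a vendor-style dialect supplied as
#' a column mapping.  Empty abundance cells are missing values and stay
#' missing (`NA`), never zero.
#'
#' @param path CSV/TSV path.
#' @param dialect Optional named character vector mapping canonical column
#'   names (`feature_id`, `mz`, `charge`, `rt`, `has_msms`, `sequence`) to
#'   the file's column names, for Progenesis-like exports.  Columns not
#'   mapped and not canonical are taken to be per-sample abundances.
#' @param samples Optional sample metadata (see [readSampleMeta()]); if
#'   given, abundance columns must all be known sample ids.
#' @return A list with `features` (data.frame of per-feature fields) and
#'   `abundance` (numeric matrix, features x samples, `NA` = missing).
#' @export
readFeatureTable <- function(path, dialect = NULL, samples = NULL) {
  raw <- .read_delim(path)
  if (!is.null(dialect)) {
    hit <- match(dialect, names(raw))
    if (anyNA(hit))
      stop("dialect column(s) not found: ",
           paste(dialect[is.na(hit)], collapse = ", "))
    names(raw)[hit] <- names(dialect)
  }
  need <- c("feature_id", "mz", "charge", "rt")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("required column(s) missing: ", paste(miss, collapse = ", "))
  if (!"has_msms" %in% names(raw)) raw$has_msms <- TRUE
  if (!"sequence" %in% names(raw)) raw$sequence <- NA_character_
  feat <- raw[CANONICAL_FEATURE_COLS]
  feat$has_msms <- as.logical(feat$has_msms)
  if (any(feat$mz <= 0)) stop("validation error: non-positive m/z")
  if (any(feat$charge == 0)) stop("validation error: zero charge")
  if (any(feat$rt < 0)) stop("validation error: negative retention time")
  if (anyDuplicated(feat$feature_id))
    stop("validation error: duplicate feature ids")
  scols <- setdiff(names(raw), CANONICAL_FEATURE_COLS)
  if (!is.null(samples)) {
    unknown <- setdiff(scols, samples$sample_id)
    if (length(unknown))
      stop("reconciliation error: sample(s) absent from metadata: ",
           paste(unknown, collapse = ", "))
  }
  ab <- as.matrix(raw[scols])
  storage.mode(ab) <- "double"
  rownames(ab) <- feat$feature_id
  if (any(ab < 0, na.rm = TRUE))
    stop("validation error: negative abundance value")
  list(features = feat, abundance = ab)
}

#' Write a feature quantification table (canonical dialect)
#'
#' @param features,abundance As returned by [readFeatureTable()] or
#'   [simulateExperiment()].
#' @param path Output CSV/TSV path.  Missing abundances are written as
#'   empty fields.
#' @return The path, invisibly.
#' @export
writeFeatureTable <- function(features, abundance, path) {
  stopifnot(identical(features$feature_id, rownames(abundance)))
  .write_delim(cbind(features[CANONICAL_FEATURE_COLS],
                     as.data.frame(abundance, check.names = FALSE)), path)
}

#' Read an identification table
#'
#' One row per (feature, engine) identification: database-search rows
#' carry a Mascot-like `score`, de novo rows an `alc` percentage.
#'
#' @param path CSV/TSV path with columns `feature_id`, `sequence`,
#'   `engine` (`database_search` or `de_novo`), `score`, `alc`,
#'   `protein_accessions`.
#' @return data.frame of identification records.
#' @export
readIdentTable <- function(path) {
  x <- .read_delim(path)
  need <- c("feature_id", "sequence", "engine")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("required column(s) missing: ", paste(miss, collapse = ", "))
  if (!"score" %in% names(x)) x$score <- NA_real_
  if (!"alc" %in% names(x)) x$alc <- NA_real_
  if (!"protein_accessions" %in% names(x)) x$protein_accessions <- ""
  if (!all(x$engine %in% c("database_search", "de_novo")))
    stop("validation error: unknown engine value")
  db <- x$engine == "database_search"
  if (any(db & is.na(x$score)) || any(!db & is.na(x$alc)))
    stop("validation error: engine/score mismatch ",
         "(database_search needs score, de_novo needs alc)")
  if (any(!db & !is.na(x$score)) || any(db & !is.na(x$alc)))
    stop("validation error: exactly one of score/alc may be populated")
  if (any(x$alc < 0 | x$alc > 100, na.rm = TRUE))
    stop("validation error: ALC% outside [0,100]")
  x$protein_accessions[is.na(x$protein_accessions)] <- ""
  x
}

#' Read sample metadata
#'
#' @param path CSV/TSV with columns `sample_id`, `group`,
#'   `experiment_id`.  Groups must be drawn from the five study groups
#'   (`RFposCCPpos_RA`, `RFnegCCPpos_RA`, `RFnegCCPneg_RA`,
#'   `RFneg_control`, `RFpos_control`).
#' @return data.frame of sample records.
#' @export
readSampleMeta <- function(path) {
  x <- .read_delim(path)
  miss <- setdiff(c("sample_id", "group"), names(x))
  if (length(miss))
    stop("required column(s) missing: ", paste(miss, collapse = ", "))
  if (!"experiment_id" %in% names(x)) x$experiment_id <- "exp1"
  if (anyDuplicated(x$sample_id))
    stop("validation error: duplicate sample ids")
  bad <- setdiff(unique(x$group), STUDY_GROUPS)
  if (length(bad))
    stop("validation error: unknown group(s): ",
         paste(bad, collapse = ", "))
  x
}

#' Write result tables to a directory
#'
#' @param dir Output directory (created if needed).
#' @param tables Named list of data.frames; each is written as
#'   `<name>.csv`.
#' @return Named character vector of written paths, invisibly.
#' @export
writeResultTables <- function(dir, tables) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(tables), function(nm) {
    .write_delim(as.data.frame(tables[[nm]]),
                 file.path(dir, paste0(nm, ".csv")))
  }, character(1))
  invisible(paths)
}

#' Assemble a SummarizedExperiment from feature data
#'
#' @param features Per-feature data.frame (`feature_id`, `mz`, `charge`,
#'   `rt`, `has_msms`, `sequence`).
#' @param abundance Features x samples matrix (`NA` = missing).
#' @param samples Sample metadata data.frame (`sample_id`, `group`,
#'   `experiment_id`).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `abundance`.
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData colData assays<- rowData<-
#' @export
buildExperiment <- function(features, abundance, samples) {
  stopifnot(identical(features$feature_id, rownames(abundance)))
  unknown <- setdiff(colnames(abundance), samples$sample_id)
  if (length(unknown))
    stop("reconciliation error: sample(s) absent from metadata: ",
         paste(unknown, collapse = ", "))
  samples <- samples[match(colnames(abundance), samples$sample_id), ]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance),
    rowData = S4Vectors::DataFrame(features, row.names = features$feature_id),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id))
}
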