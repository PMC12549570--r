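#' @import methods
#' @importFrom Biostrings AAStringSet readBStringSet
#' @importFrom S4Vectors DataFrame
NULL

AA_OK <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Germline reference set
#'
#' Container for immunoglobulin germline reference sequences: V and J
#' segments (amino acid, with per-residue IMGT unique-numbering positions
#' for V) and heavy-chain constant regions grouped by isotype.  Sequences
#' are stored degapped; IMGT coordinates are kept alongside so that
#' alignment columns can be mapped back to framework/CDR regions.
#'
#' @slot sequences An [Biostrings::AAStringSet] of degapped sequences,
#'   named by gene or accession.
#' @slot chain Character vector: `"heavy"`, `"kappa"` or `"lambda"`.
#' @slot segment Character vector: `"V"`, `"J"` or `"constant"`.
#' @slot isotypeGroup Character vector; isotype group label (`"IgA1"`,
#'   `"IgA2"`, `"IgG1"`..`"IgG4"`, `"IgM"`) for constant segments, `NA`
#'   otherwise.  Duplicate accessions with near-identical sequence share
#'   one group.
#' @slot imgtPositions List; for each V segment an integer vector giving
#'   the IMGT position of every residue (strictly increasing), `NULL` for
#'   J and constant segments.
#' @export
setClass("GermlineSet", slots = c(
  sequences = "AAStringSet",
  chain = "character",
  segment = "character",
  isotypeGroup = "character",
  imgtPositions = "list"
))

setValidity("GermlineSet", function(object) {
  n <- length(object@sequences)
  msgs <- character()
  if (length(object@chain) != n || length(object@segment) != n ||
      length(object@isotypeGroup) != n || length(object@imgtPositions) != n)
    msgs <- c(msgs, "slot lengths disagree with number of sequences")
  if (any(Biostrings::width(object@sequences) == 0))
    msgs <- c(msgs, "empty sequence in germline set")
  if (!all(object@chain %in% c("heavy", "kappa", "lambda")))
    msgs <- c(msgs, "chain must be heavy/kappa/lambda")
  if (!all(object@segment %in% c("V", "J", "constant")))
    msgs <- c(msgs, "segment must be V/J/constant")
  chars <- unique(strsplit(paste(as.character(object@sequences),
                                 collapse = ""), "")[[1]])
  if (!all(chars %in% AA_OK))
    msgs <- c(msgs, sprintf("non-amino-acid characters: %s",
                            paste(setdiff(chars, AA_OK), collapse = "")))
  isC <- object@segment == "constant"
  if (any(isC & is.na(object@isotypeGroup)))
    msgs <- c(msgs, "constant segment without isotype group")
  for (i in which(object@segment == "V")) {
    pos <- object@imgtPositions[[i]]
    if (is.null(pos))
      msgs <- c(msgs, sprintf("V segment %s lacks IMGT positions",
                              names(object@sequences)[i]))
    else if (length(pos) != Biostrings::width(object@sequences)[i] ||
             any(diff(pos) <= 0))
      msgs <- c(msgs, sprintf("invalid IMGT positions for %s",
                              names(object@sequences)[i]))
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn GermlineSet Number of germline records.
#' @param x A `GermlineSet`.
#' @export
setMethod("length", "GermlineSet", function(x) length(x@sequences))

#' @describeIn GermlineSet Subset by index, name or logical vector.
#' @param i Index vector.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "GermlineSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  if (is.logical(i)) i <- which(i)
  new("GermlineSet",
      sequences = x@sequences[i],
      chain = x@chain[i], segment = x@segment[i],
      isotypeGroup = x@isotypeGroup[i],
      imgtPositions = x@imgtPositions[i])
})

setMethod("show", "GermlineSet", function(object) {
  cat(sprintf("GermlineSet with %d sequences\n", length(object)))
  print(table(object@segment, object@chain))
  iso <- unique(stats::na.omit(object@isotypeGroup))
  if (length(iso))
    cat("isotype groups:", paste(sort(iso), collapse = ", "), "\n")
})

#' Accessors for GermlineSet
#'
#' @param x A [GermlineSet].
#' @return `germlineNames`: character vector of gene/accession names;
#'   `chainType`, `segmentType`, `isotypeGroup`: character vectors parallel
#'   to the sequences; `germlineSequences`: the degapped
#'   [Biostrings::AAStringSet]; `imgtPositions`: list of integer vectors.
#' @name germline-accessors
NULL

#' @rdname germline-accessors
#' @export
germlineNames <- function(x) names(x@sequences)
#' @rdname germline-accessors
#' @export
chainType <- function(x) x@chain
#' @rdname germline-accessors
#' @export
segmentType <- function(x) x@segment
#' @rdname germline-accessors
#' @export
isotypeGroup <- function(x) x@isotypeGroup
#' @rdname germline-accessors
#' @export
germlineSequences <- function(x) x@sequences
#' @rdname germline-accessors
#' @export
imgtPositions <- function(x) x@imgtPositions

#' Fitted sparse PLS-DA model
#'
#' Result of [splsda()]: per-component sparse X-weight vectors, scores and
#' the pieces needed for class prediction, plus (after tuning or stability
#' analysis) cross-validated balanced error rates and per-variable
#' selection frequencies.
#'
#' @slot ncomp Number of fitted components H.
#' @slot keepX Integer vector, variables retained per component.
#' @slot weights p x H matrix of sparse X-weights (exactly `keepX[h]`
#'   non-zero entries in column h).
#' @slot xLoadings p x H matrix of regression loadings used for deflation.
#' @slot yLoadings K x H matrix of Y-loadings.
#' @slot scores n x H matrix of sample coordinates.
#' @slot xCenter,xScale Numeric vectors used to standardize X.
#' @slot yCenter Numeric vector, column means of the class indicator matrix.
#' @slot levels Character vector of class labels (column order of Y).
#' @slot ber Numeric; cross-validated balanced error rate(s) (empty for a
#'   plain fit).
#' @slot occurrence Named numeric; per-variable selection frequency across
#'   cross-validation repeats (empty for a plain fit).
#' @export
setClass("SplsdaResult", slots = c(
  ncomp = "integer", keepX = "integer",
  weights = "matrix", xLoadings = "matrix", yLoadings = "matrix",
  scores = "matrix",
  xCenter = "numeric", xScale = "numeric", yCenter = "numeric",
  levels = "character",
  ber = "numeric", occurrence = "numeric"
))

setValidity("SplsdaResult", function(object) {
  msgs <- character()
  if (ncol(object@weights) != object@ncomp)
    msgs <- c(msgs, "weights must have ncomp columns")
  if (any(colSums(object@weights != 0) > object@keepX))
    msgs <- c(msgs, "non-zero weights per component must not exceed keepX")
  if (length(object@ber) && any(object@ber < 0 | object@ber > 1))
    msgs <- c(msgs, "BER outside [0,1]")
  if (length(object@occurrence) &&
      any(object@occurrence < 0 | object@occurrence > 1))
    msgs <- c(msgs, "occurrence outside [0,1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SplsdaResult", function(object) {
  cat(sprintf("SplsdaResult: %d component(s), keepX = %s, %d classes\n",
              object@ncomp, paste(object@keepX, collapse = "/"),
              length(object@levels)))
  if (length(object@ber))
    cat(sprintf("  mean CV balanced error rate: %.3f\n", mean(object@ber)))
  if (length(object@occurrence))
    cat(sprintf("  %d variable(s) with occurrence > 0.5\n",
                sum(object@occurrence > 0.5)))
})
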