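#' Load a germline reference set
#'
#' Reads amino-acid germline FASTA files into a [GermlineSet].  V-segment
#' records must be IMGT-gapped (gap character `.`): the gaps are stripped
#' and each retained residue is assigned the IMGT unique-numbering
#' position of the column it occupied.  Constant-region records carry an
#' isotype group; duplicate accessions with near-identical sequence (for
#' example the two IgG1 and the two IgM heavy-chain entries) are retained
#' as records but share a single isotype group, so they count once in
#' uniqueness decisions.
#'
#' Headers are of the form
#' `>NAME chain=heavy|kappa|lambda segment=V|J|constant [isotype=IgG1]`.
#'
#' @param source Either `"builtin"` (the packaged curated set: V and J
#'   segments plus the seven heavy-chain constant-region isotype groups;
#'   the packaged files are synthetic/curated fixtures, not an official
#'   IMGT or UniProt release) or a character vector of FASTA paths.
#' @return A [GermlineSet].
#' @examples
#' gl <- loadGermlineSet()
#' table(segmentType(gl))
#' @export
loadGermlineSet <- function(source = "builtin") {
  if (identical(source, "builtin")) {
    source <- system.file("extdata",
                          c("germline_v_synthetic.fasta",
                            "germline_j_synthetic.fasta",
                            "ig_constant_synthetic.fasta"),
                          package = "rfpeptidome", mustWork = TRUE)
  }
  seqs <- character(); chain <- character(); segment <- character()
  isotype <- character(); positions <- list()
  for (path in source) {
    raw <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) stop("malformed FASTA '", path,
                                             "': ", conditionMessage(e)))
    if (length(raw) == 0) stop("malformed FASTA '", path, "': no records")
    hdr <- names(raw)
    for (i in seq_along(raw)) {
      toks <- strsplit(hdr[i], "\\s+")[[1]]
      nm <- toks[1]
      kv <- toks[grepl("=", toks)]
      fields <- stats::setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
      s <- toupper(as.character(raw[[i]]))
      if (nchar(gsub("\\.", "", s)) == 0)
        stop("validation error: empty sequence for record '", nm, "'")
      seg <- if (!is.na(fields["segment"])) unname(fields["segment"]) else "V"
      if (seg == "V") {
        cols <- which(strsplit(s, "")[[1]] != ".")
        if (max(cols) > 128)
          stop("validation error: cannot resolve IMGT positions for V ",
               "segment '", nm, "' (gapped length ", max(cols), " > 128)")
        positions[length(positions) + 1L] <- list(as.integer(cols))
        s <- gsub("\\.", "", s)
      } else {
        positions[length(positions) + 1L] <- list(NULL)
      }
      seqs <- c(seqs, s)
      names(seqs)[length(seqs)] <- nm
      chain <- c(chain, if (!is.na(fields["chain"])) unname(fields["chain"])
                        else "heavy")
      segment <- c(segment, seg)
      isotype <- c(isotype, if (!is.na(fields["isotype"]))
                              unname(fields["isotype"]) else NA_character_)
    }
  }
  bad <- !vapply(strsplit(seqs, ""), function(ch) all(ch %in% AA_OK),
                 logical(1))
  if (any(bad))
    stop("validation error: non-amino-acid characters in record(s) ",
         paste(names(seqs)[bad], collapse = ", "))
  new("GermlineSet",
      sequences = Biostrings::AAStringSet(seqs),
      chain = chain, segment = segment, isotypeGroup = isotype,
      imgtPositions = positions)
}

#' IMGT framework/CDR region boundaries
#'
#' The fixed IMGT unique-numbering partition of a variable domain into
#' framework (FR) and complementarity-determining (CDR) regions:
#' FR1 1-26, CDR1 27-38, FR2 39-55, CDR2 56-65, FR3 66-104, CDR3 105-117,
#' FR4 118-128.
#'
#' @return A data.frame with columns `region`, `start`, `end` (inclusive
#'   IMGT positions).
#' @examples
#' regionAtPosition(30)  # "CDR1"
#' @export
defaultRegionMap <- function() {
  data.frame(
    region = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"),
    start = c(1L, 27L, 39L, 56L, 66L, 105L, 118L),
    end = c(26L, 38L, 55L, 65L, 104L, 117L, 128L),
    stringsAsFactors = FALSE
  )
}

#' @describeIn defaultRegionMap Region label(s) for IMGT position(s);
#'   `NA` outside 1-128.
#' @param position Integer vector of IMGT positions.
#' @param map A region map as returned by [defaultRegionMap()].
#' @export
regionAtPosition <- function(position, map = defaultRegionMap()) {
  idx <- findInterval(position, map$start)
  out <- rep(NA_character_, length(position))
  ok <- idx >= 1 & position >= 1 & position <= max(map$end)
  out[ok] <- map$region[idx[ok]]
  out
}
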