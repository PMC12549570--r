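#' @importFrom Biostrings pairwiseAlignment pattern subject score
#' @importFrom BiocGenerics start end
#' @importFrom utils data
NULL

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

.fold_il <- function(x) gsub("L", "I", x, fixed = TRUE)

#' Smith-Waterman local alignment of a peptide against a germline
#'
#' Optimal local alignment under an affine gap model (a gap of length L
#' costs `gapOpen + (L - 1) * gapExtend`), returning the score and the
#' subject (germline) residue indices aligned to peptide residues.
#' Scores are floored at zero (the empty local alignment).
#'
#' @param peptide,germline Amino-acid strings.
#' @param substitutionMatrix Scoring matrix (default BLOSUM62).
#' @param gapOpen,gapExtend Affine gap parameters (defaults 11 and 1, the
#'   conventional protein-search settings).
#' @return List with `score`, `subjectStart`, `subjectEnd`,
#'   `alignedSubjectPos` (integer vector of germline residue indices that
#'   are aligned, i.e. not opposite a gap), and `nAligned`.
#' @export
smithWaterman <- function(peptide, germline,
                          substitutionMatrix = NULL,
                          gapOpen = 11, gapExtend = 1) {
  if (!nzchar(peptide) || !nzchar(germline))
    stop("validation error: empty sequence")
  if (is.null(substitutionMatrix)) substitutionMatrix <- .blosum62()
  aln <- Biostrings::pairwiseAlignment(
    peptide, germline, type = "local",
    substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpen - gapExtend, gapExtension = gapExtend)
  sc <- Biostrings::score(aln)
  if (sc <= 0)
    return(list(score = 0, subjectStart = NA_integer_,
                subjectEnd = NA_integer_,
                alignedSubjectPos = integer(), nAligned = 0L))
  p <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  spos <- integer(); si <- BiocGenerics::start(subject(aln)) - 1L
  for (i in seq_along(s)) {
    if (s[i] != "-") si <- si + 1L
    if (s[i] != "-" && p[i] != "-") spos <- c(spos, si)
  }
  list(score = sc,
       subjectStart = BiocGenerics::start(subject(aln)),
       subjectEnd = BiocGenerics::end(subject(aln)),
       alignedSubjectPos = spos, nAligned = length(spos))
}

#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * score)` for a local-alignment score
#' against a database of `n` residues with a query of `m` residues.
#' Default `lambda`/`K` are the conventional gapped BLOSUM62 (gap 11/1)
#' parameters.
#'
#' @param score Alignment score(s).
#' @param m Query (peptide) length.
#' @param n Total database residue count.
#' @param lambda,K Karlin-Altschul parameters.
#' @return Expectation value(s).
#' @export
karlinAltschulEvalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  if (any(m <= 0) || any(n <= 0))
    stop("validation error: non-positive sequence/database length")
  K * m * n * exp(-lambda * score)
}

#' Match a peptide to immunoglobulin constant regions
#'
#' Exact substring search of the peptide in every constant-region
#' germline sequence.  Accessions sharing an isotype group (near-identical
#' duplicate UniProt entries) count once, so a peptide present only in
#' the two IgG1 accessions is still unique to IgG1.  Peptides matching
#' more than one isotype group are flagged non-unique and are excluded
#' from isotype quantification downstream.
#'
#' @param sequence Peptide amino-acid string.
#' @param germlines A [GermlineSet] containing constant segments.
#' @param ilEquivalent Treat I and L as indistinguishable (default FALSE;
#'   enabled for de-novo-derived sequences, which cannot separate the
#'   isobaric residues).
#' @return One-row data.frame: `sequence`, `matched` (logical),
#'   `isotype_group` (`NA` if none or ambiguous-representative label if
#'   unique), `unique_to_isotype`, `matched_groups` (comma-separated).
#' @export
matchConstantRegion <- function(sequence, germlines,
                                ilEquivalent = FALSE) {
  isC <- segmentType(germlines) == "constant"
  seqs <- as.character(germlineSequences(germlines))[isC]
  grp <- isotypeGroup(germlines)[isC]
  q <- if (ilEquivalent) .fold_il(sequence) else sequence
  t <- if (ilEquivalent) .fold_il(seqs) else seqs
  hit <- vapply(t, function(s) grepl(q, s, fixed = TRUE), logical(1))
  groups <- sort(unique(grp[hit]))
  data.frame(sequence = sequence, matched = length(groups) > 0,
             isotype_group = if (length(groups) == 1) groups else
               NA_character_,
             unique_to_isotype = length(groups) == 1,
             matched_groups = paste(groups, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Allocate a peptide to the immunoglobulin variable region
#'
#' Aligns the peptide locally against every V-segment germline, selects
#' the best-scoring gene (ties: lower E-value, then alphabetical name),
#' and accepts the assignment under either of two criterion sets: an
#' IgBLAST-style rule (E-value <= `evalueMax`, alignment confined to the
#' framework/CDR1/CDR2 part of the domain) or an IMGT-style rule
#' (E-value <= `evalueMax` and Smith-Waterman score > `swMin`).  The
#' assignment is CDR-labelled only when at least `minCdrResidues` aligned
#' residues fall inside a CDR span of the region map; an alignment that
#' crosses a boundary with that many CDR residues is labelled `FR+CDR`.
#'
#' @param sequence Peptide amino-acid string.
#' @param germlines A [GermlineSet] with V segments.
#' @param regionMap IMGT region boundaries ([defaultRegionMap()]).
#' @param evalueMax,swMin,minCdrResidues Acceptance criteria (defaults 1,
#'   30 and 3).
#' @param ilEquivalent Fold I/L before aligning (for de novo sequences).
#' @param lambda,K Karlin-Altschul parameters for the E-value.
#' @return One-row data.frame: `sequence`, `category` (`variable` or
#'   `non_ig`), `germline_gene`, `sw_score`, `e_value`,
#'   `n_cdr_residues`, `region_label` (`FR`, `CDR` or `FR+CDR`),
#'   `regions` (specific segments covered, comma-separated),
#'   `igblast_pass`, `imgt_pass`.
#' @export
assignVariableRegion <- function(sequence, germlines,
                                 regionMap = defaultRegionMap(),
                                 evalueMax = 1, swMin = 30,
                                 minCdrResidues = 3L,
                                 ilEquivalent = FALSE,
                                 lambda = 0.267, K = 0.041) {
  best <- .bestVGene(sequence, germlines, ilEquivalent)
  .vAssignment(sequence, best$gene, best$gidx, best$score, germlines,
               regionMap, evalueMax, swMin, minCdrResidues,
               ilEquivalent, lambda, K)
}

## Shared tail of variable-region assignment once the best gene and its
## score are known: detailed alignment for residue positions, E-value,
## acceptance under the two criterion sets, and region labelling.
.vAssignment <- function(sequence, gene, gidx, bestScore, germlines,
                         regionMap, evalueMax, swMin, minCdrResidues,
                         ilEquivalent, lambda, K) {
  idxV <- which(segmentType(germlines) == "V")
  dbN <- sum(Biostrings::width(germlineSequences(germlines)[idxV]))
  q <- if (ilEquivalent) .fold_il(sequence) else sequence
  g <- as.character(germlineSequences(germlines)[[gidx]])
  if (ilEquivalent) g <- .fold_il(g)
  best <- smithWaterman(q, g)
  ev <- karlinAltschulEvalue(bestScore, nchar(sequence), dbN,
                             lambda = lambda, K = K)
  pos <- imgtPositions(germlines)[[gidx]]
  imgt <- pos[best$alignedSubjectPos]
  regs <- regionAtPosition(imgt, regionMap)
  ncdr <- sum(grepl("^CDR", regs), na.rm = TRUE)
  covered <- unique(stats::na.omit(regs))
  imgt_pass <- ev <= evalueMax && bestScore > swMin
  igblast_pass <- ev <= evalueMax && !"CDR3" %in% covered &&
    length(covered) > 0
  accepted <- imgt_pass || igblast_pass
  label <- if (!accepted) NA_character_
    else if (ncdr >= minCdrResidues && any(grepl("^FR", covered)))
      "FR+CDR"
    else if (ncdr >= minCdrResidues) "CDR" else "FR"
  data.frame(sequence = sequence,
             category = if (accepted) "variable" else "non_ig",
             germline_gene = if (accepted) gene else NA_character_,
             sw_score = bestScore, e_value = ev,
             n_cdr_residues = ncdr, region_label = label,
             regions = paste(covered, collapse = ","),
             igblast_pass = igblast_pass, imgt_pass = imgt_pass,
             stringsAsFactors = FALSE)
}

## Vectorized local-alignment scores of many peptides against every V
## gene: one pairwiseAlignment call per germline with scoreOnly = TRUE.
## Returns the best gene per peptide (ties: alphabetical gene order) and
## its score, floored at zero like smithWaterman().
.bestVGene <- function(sequences, germlines, ilEquivalent) {
  idx <- which(segmentType(germlines) == "V")
  if (!length(idx)) stop("no V segments in germline set")
  vnames <- germlineNames(germlines)[idx]
  ord <- order(vnames)
  idx <- idx[ord]; vnames <- vnames[ord]
  q <- ifelse(ilEquivalent, .fold_il(sequences), sequences)
  bestScore <- rep(-Inf, length(q))
  bestGene <- rep(NA_integer_, length(q))
  sub <- .blosum62()
  for (k in seq_along(idx)) {
    g <- as.character(germlineSequences(germlines)[[idx[k]]])
    for (fold in unique(ilEquivalent)) {
      sel <- which(ilEquivalent == fold)
      sc <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(q[sel]),
        if (fold) .fold_il(g) else g,
        type = "local", substitutionMatrix = sub,
        gapOpening = 10, gapExtension = 1, scoreOnly = TRUE)
      sc <- pmax(sc, 0)
      upd <- sel[sc > bestScore[sel]]
      bestScore[upd] <- sc[sc > bestScore[sel]]
      bestGene[upd] <- k
    }
  }
  list(gene = vnames[bestGene], gidx = idx[bestGene],
       score = bestScore)
}

#' Annotate peptide sequences against the germline reference
#'
#' Every peptide receives exactly one category.  A constant-region match
#' takes precedence: peptides found in a constant-region sequence are
#' never scored against the V genes.  Remaining peptides are allocated to
#' the variable region via [assignVariableRegion()], or `non_ig`.
#'
#' @param sequences Character vector of peptide sequences (deduplicated
#'   internally).
#' @param germlines A [GermlineSet].
#' @param ilEquivalent Logical scalar or vector parallel to `sequences`
#'   (fold I/L; typically TRUE for de-novo-derived peptides only).
#' @param ... Passed to [assignVariableRegion()].
#' @return data.frame with one row per input sequence: `sequence`,
#'   `category` (`constant`/`variable`/`non_ig`), `isotype_group`,
#'   `unique_to_isotype`, `germline_gene`, `sw_score`, `e_value`,
#'   `n_cdr_residues`, `region_label`, `regions`, `ig_related`.
#' @export
annotatePeptides <- function(sequences, germlines, ilEquivalent = FALSE,
                             ...) {
  if (length(ilEquivalent) == 1)
    ilEquivalent <- rep(ilEquivalent, length(sequences))
  stopifnot(length(ilEquivalent) == length(sequences))
  key <- paste(sequences, ilEquivalent)
  uk <- !duplicated(key)
  rows <- vector("list", sum(uk))
  useq <- sequences[uk]; uil <- ilEquivalent[uk]
  cms <- lapply(seq_along(useq), function(i)
    matchConstantRegion(useq[i], germlines, ilEquivalent = uil[i]))
  isConst <- vapply(cms, `[[`, logical(1), "matched")
  vi <- which(!isConst)
  if (length(vi)) {
    best <- .bestVGene(useq[vi], germlines, uil[vi])
    dots <- list(...)
    arg <- function(nm, def) if (nm %in% names(dots)) dots[[nm]] else def
    regionMap <- arg("regionMap", defaultRegionMap())
    evalueMax <- arg("evalueMax", 1); swMin <- arg("swMin", 30)
    minCdr <- arg("minCdrResidues", 3L)
    lambda <- arg("lambda", 0.267); K <- arg("K", 0.041)
  }
  for (i in seq_along(useq)) {
    if (isConst[i]) {
      cm <- cms[[i]]
      rows[[i]] <- data.frame(
        sequence = useq[i], category = "constant",
        isotype_group = cm$isotype_group,
        unique_to_isotype = cm$unique_to_isotype,
        matched_groups = cm$matched_groups,
        germline_gene = NA_character_, sw_score = NA_real_,
        e_value = NA_real_, n_cdr_residues = NA_integer_,
        region_label = NA_character_, regions = "",
        ig_related = TRUE, stringsAsFactors = FALSE)
    } else {
      k <- match(i, vi)
      va <- .vAssignment(useq[i], best$gene[k], best$gidx[k],
                         best$score[k], germlines, regionMap,
                         evalueMax, swMin, minCdr, uil[i], lambda, K)
      rows[[i]] <- data.frame(
        sequence = useq[i], category = va$category,
        isotype_group = NA_character_, unique_to_isotype = FALSE,
        matched_groups = "",
        germline_gene = va$germline_gene, sw_score = va$sw_score,
        e_value = va$e_value, n_cdr_residues = va$n_cdr_residues,
        region_label = va$region_label, regions = va$regions,
        ig_related = va$category == "variable", stringsAsFactors = FALSE)
    }
  }
  ann <- do.call(rbind, rows)
  ann[match(key, key[uk]), , drop = FALSE]
}
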