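#' Isotype-level quantification from unique constant-region peptides
#'
#' Protein-level abundance of each immunoglobulin heavy-chain isotype
#' group: per sample, the sum of normalized abundances of peptides unique
#' to that isotype group.  Peptides matching more than one group
#' contribute nowhere.
#'
#' @param annotation Per-feature annotation data.frame
#'   ([annotatePeptides()] joined to features): must contain `category`,
#'   `isotype_group`, `unique_to_isotype` with rownames or a
#'   `feature_id` column matching `abundance`.
#' @param abundance Normalized features x samples matrix.
#' @return List with `abundance` (isotype groups x samples matrix; an
#'   isotype with no unique peptide is all-`NA`, with a warning), `z`
#'   (row Z-scores) and `peptideCounts` (unique peptides per isotype).
#' @export
quantifyIsotypes <- function(annotation, abundance) {
  ids <- if ("feature_id" %in% names(annotation)) annotation$feature_id
         else rownames(annotation)
  stopifnot(all(ids %in% rownames(abundance)))
  keep <- annotation$category == "constant" & annotation$unique_to_isotype
  groups <- sort(unique(stats::na.omit(annotation$isotype_group)))
  out <- matrix(NA_real_, length(groups), ncol(abundance),
                dimnames = list(groups, colnames(abundance)))
  counts <- stats::setNames(integer(length(groups)), groups)
  for (g in groups) {
    sel <- ids[keep & !is.na(annotation$isotype_group) &
               annotation$isotype_group == g]
    counts[g] <- length(sel)
    if (!length(sel)) {
      warning("isotype ", g, " has no unique peptides; abundance missing")
      next
    }
    sub <- abundance[sel, , drop = FALSE]
    out[g, ] <- colSums(sub, na.rm = TRUE)
    out[g, colSums(!is.na(sub)) == 0] <- NA  # all peptides missing
  }
  list(abundance = out, z = zScore(out), peptideCounts = counts)
}

#' Positivity calls against a control-derived cut-off
#'
#' Per isotype, the cut-off is the maximum abundance among samples of the
#' reference group; a sample is positive iff its abundance strictly
#' exceeds the cut-off (so no reference sample is ever positive).
#'
#' @param isotypeAbundance Isotype groups x samples matrix
#'   ([quantifyIsotypes()]).
#' @param groups Group label per sample (column).
#' @param referenceGroup Reference group name (default `RFneg_control`,
#'   the RF-negative disease controls).
#' @return List with `cutoffs` (named per isotype), `positive` (logical
#'   isotype x sample matrix) and `summary` (data.frame: isotype, group,
#'   n, n_positive, pct_positive).
#' @export
positivityCalls <- function(isotypeAbundance, groups,
                            referenceGroup = "RFneg_control") {
  groups <- as.character(groups)
  if (!any(groups == referenceGroup))
    stop("empty reference group: ", referenceGroup)
  refcols <- groups == referenceGroup
  cutoffs <- apply(isotypeAbundance[, refcols, drop = FALSE], 1, max,
                   na.rm = TRUE)
  pos <- sweep(isotypeAbundance, 1, cutoffs, ">")
  pos[is.na(pos)] <- FALSE
  lev <- unique(groups)
  rows <- list()
  for (iso in rownames(isotypeAbundance)) {
    for (g in lev) {
      sel <- groups == g
      rows[[length(rows) + 1L]] <- data.frame(
        isotype = iso, group = g, n = sum(sel),
        n_positive = sum(pos[iso, sel]),
        pct_positive = 100 * mean(pos[iso, sel]),
        stringsAsFactors = FALSE)
    }
  }
  list(cutoffs = cutoffs, positive = pos,
       summary = do.call(rbind, rows))
}

#' Protein-level group comparisons per isotype
#'
#' Kruskal-Wallis across groups followed by Dunn's pairwise post-hoc
#' test, per isotype, on the isotype-level abundances.  Pairwise
#' p-values are reported unadjusted (the peptide-level family-wise
#' adjustment does not apply at the protein level).
#'
#' @param isotypeAbundance Isotype groups x samples matrix.
#' @param groups Group label per sample.
#' @return data.frame with `isotype`, `kw_H`, `kw_p`, then one row per
#'   group pair with Dunn `z` and `p`.
#' @export
isotypeGroupTests <- function(isotypeAbundance, groups) {
  rows <- list()
  for (iso in rownames(isotypeAbundance)) {
    x <- isotypeAbundance[iso, ]
    if (all(is.na(x))) next
    kw <- kruskalWallis(x, groups)
    dn <- dunnPosthoc(x, groups)
    rows[[length(rows) + 1L]] <- data.frame(
      isotype = iso, kw_H = kw$H, kw_p = kw$p, dn,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
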