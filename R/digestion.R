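#' In-silico sequential Lys-C/chymotrypsin digestion
#'
#' Emulates the bench protocol used to release immunoglobulin peptides:
#' Lys-C first (cleaves C-terminal to K, including K-P bonds), then
#' chymotrypsin (cleaves C-terminal to F, Y, W or L, blocked when the
#' following residue is P).  Because both digestions run to completion on
#' the same molecule, the realized cleavage-site set is the union of the
#' two rules, with the proline block applying only to the chymotryptic
#' sites.
#'
#' @param sequence Amino-acid string (20 standard residues plus X).
#' @param maxMissedCleavages Maximum number of internal (missed) cleavage
#'   sites per reported peptide.
#' @param minLength Minimum peptide length to report (default 3, the
#'   shortest sequence retained anywhere downstream).
#' @return Character vector of unique peptides.
#' @examples
#' digestSequence("GGFPGGK")          # F-P bond blocked -> one peptide
#' digestSequence("AKCK", minLength = 2)
#' @export
digestSequence <- function(sequence, maxMissedCleavages = 0L,
                           minLength = 3L) {
  if (!nzchar(sequence)) stop("validation error: empty sequence")
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (!all(chars %in% AA_OK))
    stop("validation error: non-amino-acid characters: ",
         paste(unique(setdiff(chars, AA_OK)), collapse = ""))
  n <- length(chars)
  nxt <- c(chars[-1], "")
  cut <- which(chars == "K" |
               (chars %in% c("F", "Y", "W", "L") & nxt != "P"))
  cut <- cut[cut < n]                       # C-terminus is not a site
  bounds <- c(0L, cut, n)                   # fragment boundaries
  nfrag <- length(bounds) - 1L
  peps <- character()
  for (i in seq_len(nfrag)) {
    for (m in 0:maxMissedCleavages) {
      j <- i + m
      if (j > nfrag) break
      pep <- substr(sequence, bounds[i] + 1L, bounds[j + 1L])
      if (nchar(pep) >= minLength) peps <- c(peps, pep)
    }
  }
  unique(peps)
}
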