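# Independent oracles used by several test files.  These deliberately
# re-derive results from first principles with different code paths than
# the package implementations.

# Brute-force affine-gap Smith-Waterman (Gotoh recurrences) with score
# floored at zero.  A gap of length L costs gapOpen + (L - 1) * gapExtend.
oracleSmithWaterman <- function(a, b, sub, gapOpen = 11, gapExtend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)      # best ending in match/mismatch or 0
  E <- matrix(-Inf, n + 1, m + 1)   # gap in A (consume B)
  F <- matrix(-Inf, n + 1, m + 1)   # gap in B (consume A)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - gapOpen, E[i + 1, j] - gapExtend)
      F[i + 1, j + 1] <- max(H[i, j + 1] - gapOpen, F[i, j + 1] - gapExtend)
      d <- H[i, j] + sub[A[i], B[j]]
      H[i + 1, j + 1] <- max(0, d, E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

randomPeptide <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Exhaustive optimal greedy assignment for feature matching: repeatedly
# take the valid candidate pair with the globally smallest |delta m/z|
# (ties: |delta RT|, then feature ids) among pairs whose endpoints are
# still unused.
oracleMatch <- function(A, B, mzTol = 0.01, rtTol = 1.0) {
  pairs <- expand.grid(i = seq_len(nrow(A)), j = seq_len(nrow(B)))
  dmz <- abs(B$mz[pairs$j] - A$mz[pairs$i])
  drt <- abs(B$rt[pairs$j] - A$rt[pairs$i])
  ok <- A$charge[pairs$i] == B$charge[pairs$j] &
    dmz < mzTol & drt < rtTol &
    A$has_msms[pairs$i] & B$has_msms[pairs$j]
  pairs <- pairs[ok, , drop = FALSE]
  dmz <- dmz[ok]; drt <- drt[ok]
  out <- NULL
  usedA <- rep(FALSE, nrow(A)); usedB <- rep(FALSE, nrow(B))
  while (nrow(pairs) > 0) {
    o <- order(dmz, drt, A$feature_id[pairs$i], B$feature_id[pairs$j])
    k <- o[1]
    out <- rbind(out, data.frame(feature_id_a = A$feature_id[pairs$i[k]],
                                 feature_id_b = B$feature_id[pairs$j[k]],
                                 stringsAsFactors = FALSE))
    usedA[pairs$i[k]] <- TRUE; usedB[pairs$j[k]] <- TRUE
    keep <- !usedA[pairs$i] & !usedB[pairs$j]
    pairs <- pairs[keep, , drop = FALSE]
    dmz <- dmz[keep]; drt <- drt[keep]
  }
  if (is.null(out))
    out <- data.frame(feature_id_a = character(),
                      feature_id_b = character(), stringsAsFactors = FALSE)
  out[order(out$feature_id_a), , drop = FALSE]
}

# Small cohort design used where full study sizes are unnecessary.
smallDesign <- function(seed = 1L, ...) {
  cohortDesign(groupSizes = c(RFposCCPpos_RA = 8L, RFnegCCPpos_RA = 4L,
                              RFnegCCPneg_RA = 6L, RFneg_control = 8L,
                              RFpos_control = 4L),
               nBackgroundPeptides = 60L, nIgPeptides = 40L,
               nUpregulated = 10L, seed = seed, ...)
}
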