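#' Median/MAD reference normalization of abundances
#'
#' Corrects per-sample global intensity variation.  The reference sample
#' is the one whose total detected abundance is the median across
#' samples.  For every sample, log-ratios to the reference over
#' co-detected features are filtered to within 3 MAD of their median
#' (robust outlier rejection), and the scaling factor is the exponential
#' of the mean retained log-ratio.  All abundances are divided by their
#' sample's factor; the reference's factor is 1 by construction.
#'
#' @param abundance Features x samples matrix (`NA` = missing).
#' @param madMultiplier Outlier window half-width in MADs (default 3).
#' @return List with `abundance` (normalized matrix) and `factors`
#'   (named per-sample scaling factors).  A sample sharing no detected
#'   feature with the reference gets factor 1 with a warning.
#' @export
normalizeAbundance <- function(abundance, madMultiplier = 3) {
  stopifnot(is.matrix(abundance), ncol(abundance) >= 2)
  totals <- colSums(abundance, na.rm = TRUE)
  # the (upper-)middle sample in total-abundance rank order: an exact,
  # tie-stable choice (nearest-to-midpoint breaks ties on float noise)
  ref <- order(totals)[ceiling((ncol(abundance) + 1) / 2)]
  factors <- rep(1, ncol(abundance))
  names(factors) <- colnames(abundance)
  for (j in seq_len(ncol(abundance))) {
    shared <- !is.na(abundance[, j]) & !is.na(abundance[, ref]) &
      abundance[, j] > 0 & abundance[, ref] > 0
    if (!any(shared)) {
      warning("sample ", colnames(abundance)[j],
              " shares no detected features with the reference; factor 1")
      next
    }
    lr <- log(abundance[shared, j] / abundance[shared, ref])
    med <- stats::median(lr)
    dev <- stats::mad(lr)
    keep <- if (dev > 0) abs(lr - med) <= madMultiplier * dev else
      rep(TRUE, length(lr))
    factors[j] <- exp(mean(lr[keep]))
  }
  list(abundance = sweep(abundance, 2, factors, "/"), factors = factors)
}

#' Per-feature Z-scores across samples
#'
#' Standardized normalized abundance: `(x - mean) / sd` per feature row,
#' over non-missing values.
#'
#' @param x Numeric vector, or features x samples matrix (row-wise).
#' @return Standardized object of the same shape.  A constant feature
#'   yields all zeros with a warning; a feature with fewer than two
#'   non-missing values yields all `NA`.
#' @export
zScore <- function(x) {
  if (is.matrix(x)) return(t(apply(x, 1, zScore)))
  ok <- !is.na(x)
  if (sum(ok) < 2) return(rep(NA_real_, length(x)))
  s <- stats::sd(x[ok])
  if (s == 0) {
    warning("constant values: Z-scores set to 0")
    out <- x; out[ok] <- 0
    return(out)
  }
  (x - mean(x[ok])) / s
}

#' Kruskal-Wallis test (tie-corrected)
#'
#' @param values Numeric vector (missing values dropped).
#' @param groups Grouping factor parallel to `values`.
#' @return List with `H`, `df`, `p`.  If all values are identical,
#'   `H = 0`, `p = 1`.
#' @export
kruskalWallis <- function(values, groups) {
  ok <- !is.na(values)
  values <- values[ok]; groups <- factor(groups[ok])
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (length(unique(values)) == 1)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Rank-based pairwise z statistics after a Kruskal-Wallis test:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with tie correction `T = sum(t^3 - t)` over tie groups, and two-sided
#' normal p-values.
#'
#' @param values Numeric vector (missing dropped).
#' @param groups Grouping factor.
#' @return data.frame with `group1`, `group2`, `z`, `p` for every
#'   unordered pair; `z(i,j) = -z(j,i)` by construction.  Empty groups
#'   are excluded with a warning.
#' @export
dunnPosthoc <- function(values, groups) {
  ok <- !is.na(values)
  values <- values[ok]
  groups <- if (is.factor(groups)) groups[ok] else factor(groups[ok])
  empty <- levels(groups)[table(groups) == 0]
  if (length(empty)) {
    warning("empty group(s) excluded: ", paste(empty, collapse = ", "))
    groups <- droplevels(groups)
  }
  N <- length(values)
  r <- rank(values)
  t <- table(values)
  T <- sum(t^3 - t)
  v0 <- N * (N + 1) / 12 - T / (12 * (N - 1))
  lev <- levels(groups)
  mr <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(v0 * (1 / n[[i]] + 1 / n[[j]]))
    z[k] <- if (se > 0) (mr[[i]] - mr[[j]]) / se else 0
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             stringsAsFactors = FALSE)
}

#' Holm-Sidak step-down adjusted p-values
#'
#' Sorts p-values ascending, sets
#' `adj_(i) = 1 - (1 - p_(i))^(m - i + 1)`, enforces monotone
#' non-decrease, caps at 1 and restores the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return Adjusted p-values in the input order.
#' @export
holmSidak <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values outside [0,1]")
  out <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  if (m == 0) return(out)
  o <- order(pp)
  adj <- 1 - (1 - pp[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  res <- numeric(m)
  res[o] <- adj
  out[ok] <- res
  out
}

#' Fold change between two sample groups
#'
#' Ratio of mean abundance (missing excluded) of group A over group B.
#' A zero denominator is replaced by `epsilon` (conventionally the
#' smallest positive abundance in the matrix) and flagged; both means
#' zero yields 1, flagged.
#'
#' @param a,b Numeric vectors of abundances.
#' @param epsilon Replacement for a zero denominator.
#' @return List with `fc` and `flagged`.
#' @export
foldChange <- function(a, b, epsilon) {
  ma <- mean(a, na.rm = TRUE); mb <- mean(b, na.rm = TRUE)
  if (is.nan(ma)) ma <- 0
  if (is.nan(mb)) mb <- 0
  if (ma == 0 && mb == 0) return(list(fc = 1, flagged = TRUE))
  if (mb == 0) return(list(fc = ma / epsilon, flagged = TRUE))
  list(fc = ma / mb, flagged = FALSE)
}

#' Per-peptide differential abundance testing
#'
#' For every feature: Kruskal-Wallis across all groups, Dunn post-hoc
#' z/p for the contrast of interest, Holm-Sidak adjustment of the
#' contrast p-values across all features (the peptide-level family), and
#' fold change of group means.  A feature is called `up` when
#' `adj_p < alpha` and `fc > fcUp`, `down` when `adj_p < alpha` and
#' `fc < fcDown`, otherwise `ns`.
#'
#' @param abundance Normalized features x samples matrix.
#' @param groups Factor/character of group membership per sample (column).
#' @param contrast Length-2 character: numerator and denominator groups
#'   of the fold change (default RF+/CCP+ RA versus RF- controls).
#' @param alpha,fcUp,fcDown Calling thresholds (defaults 0.05, 5, 0.2).
#' @return List with `results` (data.frame: feature_id, group means,
#'   `kw_H`, `kw_p`, `dunn_z`, `dunn_p`, `adj_p`, `fc`, `fc_flagged`,
#'   `call`) and `z` (feature x sample Z-score matrix).
#' @export
differentialAbundance <- function(abundance, groups,
                                  contrast = c("RFposCCPpos_RA",
                                               "RFneg_control"),
                                  alpha = 0.05, fcUp = 5, fcDown = 0.2) {
  stopifnot(length(contrast) == 2, all(contrast %in% groups))
  groups <- factor(groups)
  eps <- suppressWarnings(min(abundance[abundance > 0], na.rm = TRUE))
  nF <- nrow(abundance)
  kw_H <- kw_p <- dunn_z <- dunn_p <- fc <- numeric(nF)
  fc_flag <- logical(nF)
  gm <- matrix(NA_real_, nF, nlevels(groups),
               dimnames = list(rownames(abundance), levels(groups)))
  for (i in seq_len(nF)) {
    x <- abundance[i, ]
    gm[i, ] <- tapply(x, groups, function(v) mean(v, na.rm = TRUE))
    kt <- kruskalWallis(x, groups)
    kw_H[i] <- kt$H; kw_p[i] <- kt$p
    dn <- dunnPosthoc(x, groups)
    hit <- which((dn$group1 == contrast[1] & dn$group2 == contrast[2]) |
                 (dn$group1 == contrast[2] & dn$group2 == contrast[1]))
    sgn <- if (dn$group1[hit] == contrast[1]) 1 else -1
    dunn_z[i] <- sgn * dn$z[hit]; dunn_p[i] <- dn$p[hit]
    f <- foldChange(x[groups == contrast[1]], x[groups == contrast[2]],
                    epsilon = eps)
    fc[i] <- f$fc; fc_flag[i] <- f$flagged
  }
  adj_p <- holmSidak(dunn_p)
  call <- ifelse(adj_p < alpha & fc > fcUp, "up",
                 ifelse(adj_p < alpha & fc < fcDown, "down", "ns"))
  res <- data.frame(feature_id = rownames(abundance),
                    kw_H = kw_H, kw_p = kw_p,
                    dunn_z = dunn_z, dunn_p = dunn_p, adj_p = adj_p,
                    fc = fc, fc_flagged = fc_flag, call = call,
                    stringsAsFactors = FALSE)
  res <- cbind(res, as.data.frame(gm))
  list(results = res, z = zScore(abundance))
}

#' Volcano-plot table
#'
#' @param results Differential results from [differentialAbundance()].
#' @return data.frame with `feature_id`, `log2_fc`,
#'   `neg_log10_adj_p` (adjusted p floored at the smallest representable
#'   positive double, with a `p_capped` flag) and `call`.
#' @export
volcanoTable <- function(results) {
  p <- results$adj_p
  capped <- !is.na(p) & p == 0
  p[capped] <- .Machine$double.xmin
  data.frame(feature_id = results$feature_id,
             log2_fc = log2(results$fc),
             neg_log10_adj_p = -log10(p),
             p_capped = capped,
             call = results$call, stringsAsFactors = FALSE)
}
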