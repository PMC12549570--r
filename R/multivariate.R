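#' Mean-impute missing values per peptide
#'
#' Multivariate projections need a complete matrix; missing abundances
#' are replaced by the peptide's mean across samples (rank tests remain
#' imputation-free).
#'
#' @param X Samples x peptides matrix.
#' @return Completed matrix.
#' @export
imputePeptideMeans <- function(X) {
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
  }
  X[is.na(X)] <- 0
  X
}

#' Principal component analysis of a peptide matrix
#'
#' Singular-value decomposition of the (column-centred, optionally
#' scaled) samples x peptides matrix.
#'
#' @param X Samples x peptides matrix (no missing values; see
#'   [imputePeptideMeans()]).
#' @param center,scale. Centring/scaling, as in [stats::prcomp()].
#' @return List with `scores`, `loadings`, `explainedVariance`
#'   (fractions, summing to at most 1).
#' @export
abundancePCA <- function(X, center = TRUE, scale. = FALSE) {
  if (nrow(X) < 2 || ncol(X) < 2)
    stop("need at least 2 samples and 2 features")
  pc <- stats::prcomp(X, center = center, scale. = scale.)
  if (all(pc$sdev == 0)) stop("rank-0 matrix")
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, explainedVariance = ev)
}

.soft_select <- function(u, keep) {
  p <- length(u)
  if (keep >= p) return(u)
  a <- abs(u)
  # degenerate columns (constant within a CV fold) contribute exact
  # zeros; never ask for more survivors than there are non-zero entries
  keep <- min(keep, sum(a > 0))
  if (keep == 0) return(numeric(p))
  if (keep >= p) return(u)
  thr <- sort(a, decreasing = TRUE)[keep + 1L]
  out <- sign(u) * pmax(a - thr, 0)
  nz <- which(out != 0)
  if (length(nz) != keep) {      # ties at the threshold: hard top-keep
    ord <- order(-a, seq_along(u))
    sel <- ord[seq_len(keep)]
    out <- numeric(p)
    out[sel] <- sign(u[sel]) * pmax(a[sel] - thr, a[sel] * 1e-12)
  }
  out
}

#' Fit a sparse PLS discriminant model
#'
#' From-scratch sparse PLS-DA: the class membership is one-hot encoded,
#' centred and scaled; for each component the dominant singular pair of
#' the cross-covariance `t(X) Y` is computed by alternating iteration,
#' with the X-weight vector soft-thresholded so that the `keepX[h]`
#' largest-magnitude entries survive (fewer when degenerate columns
#' yield exact-zero covariances), then renormalized; `X` and `Y` are
#' deflated by regression on the component score (regression mode).  The
#' sign convention makes each component's largest-magnitude weight
#' positive, so the fit is deterministic.
#'
#' @param X Samples x peptides matrix (complete; see
#'   [imputePeptideMeans()]).
#' @param y Class labels (factor or character), one per sample.
#' @param ncomp Number of components H.
#' @param keepX Integer vector (recycled to `ncomp`): variables retained
#'   per component; defaults to all (dense PLS-DA).
#' @param scale Standardize X columns (default TRUE).
#' @return An [SplsdaResult-class] object.
#' @export
splsda <- function(X, y, ncomp = 2L, keepX = ncol(X), scale = TRUE) {
  X <- as.matrix(X)
  y <- factor(y)
  y <- droplevels(y)
  ncomp <- as.integer(ncomp)
  keepX <- as.integer(rep_len(keepX, ncomp))
  if (any(keepX > ncol(X)))
    stop("keepX exceeds number of peptides")
  if (any(keepX < 1)) stop("keepX must be >= 1")
  lev <- levels(y)
  n <- nrow(X); p <- ncol(X); K <- length(lev)
  xc <- colMeans(X)
  xs <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  xs[xs == 0] <- 1
  Xh <- sweep(sweep(X, 2, xc), 2, xs, "/")
  Y <- outer(y, lev, "==") + 0
  yc <- colMeans(Y)
  ys <- apply(Y, 2, stats::sd)
  ys[ys == 0] <- 1
  Yh <- sweep(sweep(Y, 2, yc), 2, ys, "/")
  W <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  P <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  D <- matrix(0, K, ncomp, dimnames = list(lev, NULL))
  Tm <- matrix(0, n, ncomp, dimnames = list(rownames(X), NULL))
  for (h in seq_len(ncomp)) {
    M <- crossprod(Xh, Yh)
    sv <- svd(M, nu = 1, nv = 1)
    v <- sv$v[, 1]
    u <- numeric(p)
    for (it in seq_len(500)) {
      u_new <- .soft_select(drop(M %*% v), keepX[h])
      nrm <- sqrt(sum(u_new^2))
      if (nrm == 0) { u_new[which.max(abs(drop(M %*% v)))] <- 1; nrm <- 1 }
      u_new <- u_new / nrm
      v_new <- drop(crossprod(M, u_new))
      v_new <- v_new / sqrt(sum(v_new^2))
      if (sum((u_new - u)^2) < 1e-12) { u <- u_new; v <- v_new; break }
      u <- u_new; v <- v_new
    }
    if (u[which.max(abs(u))] < 0) u <- -u
    t_h <- drop(Xh %*% u)
    tt <- sum(t_h^2)
    ph <- drop(crossprod(Xh, t_h)) / tt
    dh <- drop(crossprod(Yh, t_h)) / tt
    Xh <- Xh - tcrossprod(t_h, ph)
    Yh <- Yh - tcrossprod(t_h, dh)
    W[, h] <- u; P[, h] <- ph; D[, h] <- dh * ys  # back to centred Y scale
    Tm[, h] <- t_h
  }
  new("SplsdaResult", ncomp = ncomp, keepX = keepX,
      weights = W, xLoadings = P, yLoadings = D, scores = Tm,
      xCenter = xc, xScale = xs, yCenter = yc, levels = lev,
      ber = numeric(), occurrence = numeric())
}

#' Predict class labels from a sparse PLS-DA model
#'
#' Computes predicted class scores by the PLS regression formula and
#' assigns each sample to the class with the maximal predicted score
#' (maximum-distance rule); ties are broken by class order.
#'
#' @param model An [SplsdaResult-class].
#' @param Xnew Samples x peptides matrix on the training feature set.
#' @return List with `class` (character labels) and `values` (samples x
#'   classes predicted score matrix).
#' @export
splsdaPredict <- function(model, Xnew) {
  Xs <- sweep(sweep(as.matrix(Xnew), 2, model@xCenter), 2,
              model@xScale, "/")
  W <- model@weights; P <- model@xLoadings; D <- model@yLoadings
  R <- W %*% solve(crossprod(P, W))
  pred <- Xs %*% R %*% t(D)
  pred <- sweep(pred, 2, model@yCenter, "+")
  colnames(pred) <- model@levels
  list(class = model@levels[max.col(pred, ties.method = "first")],
       values = pred)
}

.balanced_error <- function(truth, predicted) {
  lev <- unique(truth)
  mean(vapply(lev, function(l)
    mean(predicted[truth == l] != l), numeric(1)))
}

.stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (l in unique(y)) {
    idx <- sample(which(y == l))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

#' Cross-validated performance and selection stability
#'
#' Repeated stratified k-fold cross-validation of a sparse PLS-DA
#' configuration: per repeat, the mean over folds of the balanced error
#' rate (unweighted mean of per-class error rates, maximum-distance
#' prediction), and per peptide the fraction of repeats in which it was
#' selected on any component of any fold model (the occurrence).
#'
#' @param X Samples x peptides matrix (complete).
#' @param y Class labels.
#' @param ncomp,keepX Model configuration.
#' @param folds Number of folds (default 3).
#' @param repeats Number of repeats (default 50).
#' @param seed Integer seed driving fold assignment; the same seed always
#'   yields identical results.
#' @return List with `ber` (per-repeat mean BER), `occurrence` (named
#'   per-peptide selection frequency over repeats).
#' @export
splsdaCV <- function(X, y, ncomp, keepX, folds = 3L, repeats = 50L,
                     seed = 1L) {
  X <- as.matrix(X); y <- as.character(y)
  small <- names(which(table(y) < folds))
  if (length(small))
    warning("group(s) smaller than fold count (stratified fallback): ",
            paste(small, collapse = ", "))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  p <- ncol(X)
  sel_count <- stats::setNames(numeric(p), colnames(X))
  ber <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fold <- .stratified_folds(y, folds)
    fb <- numeric(folds)
    sel_rep <- logical(p)
    for (k in seq_len(folds)) {
      tr <- fold != k
      if (length(unique(y[tr])) < 2) { fb[k] <- NA; next }
      fit <- splsda(X[tr, , drop = FALSE], y[tr], ncomp = ncomp,
                    keepX = keepX)
      pr <- splsdaPredict(fit, X[!tr, , drop = FALSE])
      fb[k] <- .balanced_error(y[!tr], pr$class)
      sel_rep <- sel_rep | rowSums(fit@weights != 0) > 0
    }
    ber[r] <- mean(fb, na.rm = TRUE)
    sel_count <- sel_count + sel_rep
  }
  list(ber = ber, occurrence = sel_count / repeats)
}

#' Tune the number of components and per-component sparsity
#'
#' Sequential tuning on the balanced error rate under the
#' maximum-distance metric: for each component in turn, every candidate
#' `keepX` is evaluated by repeated stratified 3-fold cross-validation
#' with earlier components fixed; the candidate minimizing the mean BER
#' wins (ties: smallest `keepX`).  The number of components H is then
#' the smallest value in `Hgrid` attaining the minimal mean BER
#' (parsimony tie-break).  A final stability run at the tuned
#' configuration yields per-peptide occurrence over `repeats` repeats.
#'
#' @param X Samples x peptides matrix (complete).
#' @param y Class labels.
#' @param Hgrid Candidate component numbers (default 2:5).
#' @param keepXgrid Candidate per-component variable counts (default
#'   `c(1, 2, 3, 5, 10, 20, 50)`, clipped to the peptide count).
#' @param folds,repeats Cross-validation design (defaults 3 and 50).
#' @param seed Integer seed.
#' @return An [SplsdaResult-class] fitted on all data at the tuned
#'   configuration, with `ber` (per-repeat BER at that configuration)
#'   and `occurrence` filled in.
#' @export
splsdaTune <- function(X, y, Hgrid = 2:5,
                       keepXgrid = c(1L, 2L, 3L, 5L, 10L, 20L, 50L),
                       folds = 3L, repeats = 50L, seed = 1L) {
  X <- as.matrix(X)
  keepXgrid <- sort(unique(pmin(as.integer(keepXgrid), ncol(X))))
  maxH <- max(Hgrid)
  chosen <- integer(0)
  berByH <- rep(NA_real_, maxH)
  for (h in seq_len(maxH)) {
    means <- vapply(keepXgrid, function(k) {
      cv <- splsdaCV(X, y, ncomp = h, keepX = c(chosen, k),
                     folds = folds, repeats = repeats,
                     seed = seed + h * 1000L + k)
      mean(cv$ber)
    }, numeric(1))
    best <- keepXgrid[which.min(means)]   # which.min: smallest on ties
    chosen <- c(chosen, best)
    berByH[h] <- min(means)
  }
  cand <- Hgrid
  Hstar <- cand[which.min(berByH[cand])]
  keepXstar <- chosen[seq_len(Hstar)]
  stab <- splsdaCV(X, y, ncomp = Hstar, keepX = keepXstar,
                   folds = folds, repeats = repeats, seed = seed)
  fit <- splsda(X, y, ncomp = Hstar, keepX = keepXstar)
  fit@ber <- stab$ber
  fit@occurrence <- stab$occurrence
  fit
}

#' Flag discriminative peptides
#'
#' A peptide is discriminative when it satisfies the full conjunction:
#' adjusted p below `alpha`, fold change above `fcMin`, selection
#' occurrence above `occMin` across cross-validation repeats, allocation
#' to the immunoglobulin variable region, and the disease-control group
#' attaining the minimum of the per-group median Z-scores (most depleted
#' in controls).
#'
#' @param diffResults Differential results ([differentialAbundance()]).
#' @param occurrence Named per-feature selection frequency
#'   ([splsdaCV()]/[splsdaTune()]); features absent get 0.
#' @param vRegion Named logical per feature: variable-region allocation.
#' @param z Feature x sample Z-score matrix.
#' @param groups Group label per sample (column of `z`).
#' @param controlGroup The disease-control reference group (default
#'   `RFneg_control`).
#' @param alpha,fcMin,occMin Thresholds (defaults 0.05, 5, 0.5).
#' @return data.frame per feature: criteria columns, per-group median Z,
#'   and `discriminative`.
#' @export
selectDiscriminative <- function(diffResults, occurrence, vRegion, z,
                                 groups, controlGroup = "RFneg_control",
                                 alpha = 0.05, fcMin = 5, occMin = 0.5) {
  ids <- diffResults$feature_id
  occ <- occurrence[ids]
  occ[is.na(occ)] <- 0
  vr <- vRegion[ids]
  vr[is.na(vr)] <- FALSE
  groups <- as.character(groups)
  lev <- unique(groups)
  medz <- sapply(lev, function(g)
    apply(z[ids, groups == g, drop = FALSE], 1, stats::median,
          na.rm = TRUE))
  colnames(medz) <- lev
  ctl_lowest <- apply(medz, 1, function(v)
    !is.na(v[controlGroup]) && v[controlGroup] <= min(v, na.rm = TRUE))
  disc <- !is.na(diffResults$adj_p) & diffResults$adj_p < alpha &
    diffResults$fc > fcMin & occ > occMin & vr & ctl_lowest
  out <- data.frame(feature_id = ids, adj_p = diffResults$adj_p,
                    fc = diffResults$fc, occurrence = unname(occ),
                    v_region = unname(vr),
                    control_lowest_median_z = unname(ctl_lowest),
                    discriminative = unname(disc),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(medz))
}
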