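test_that("mean imputation completes a matrix without moving means", {
  X <- matrix(c(1, 2, NA, 4, NA, NA), 3, 2)
  Xi <- imputePeptideMeans(X)
  expect_false(anyNA(Xi))
  expect_equal(Xi[3, 1], mean(c(1, 2)))
  expect_equal(Xi[, 2], rep(4, 3))
  # an all-missing column falls back to zero
  expect_equal(imputePeptideMeans(matrix(NA_real_, 2, 1)),
               matrix(0, 2, 1))
})

test_that("PCA of collinear data puts all variance on PC1", {
  t_ <- seq(-1, 1, length.out = 10)
  X <- cbind(t_, 2 * t_, -t_) + 5
  pc <- abundancePCA(X)
  expect_equal(pc$explainedVariance[1], 1, tolerance = 1e-12)
  expect_equal(sum(pc$explainedVariance), 1, tolerance = 1e-12)
  expect_error(abundancePCA(X[1, , drop = FALSE]), "at least 2")
})

test_that("splsda with keepX = p equals dense PLS-DA", {
  set.seed(21)
  X <- matrix(rnorm(40 * 10), 40, 10,
              dimnames = list(NULL, paste0("p", 1:10)))
  y <- rep(c("a", "b"), each = 20)
  X[y == "a", 1:2] <- X[y == "a", 1:2] + 2
  dense <- splsda(X, y, ncomp = 2)
  expect_true(all(colSums(dense@weights != 0) == 10))
  # weight vectors are unit length
  expect_equal(unname(colSums(dense@weights^2)), c(1, 1),
               tolerance = 1e-9)
})

test_that("splsda selects exactly keepX variables per component", {
  set.seed(22)
  X <- matrix(rnorm(30 * 20), 30, 20,
              dimnames = list(NULL, paste0("p", 1:20)))
  y <- rep(c("a", "b", "c"), each = 10)
  fit <- splsda(X, y, ncomp = 3, keepX = c(5, 2, 7))
  expect_equal(unname(colSums(fit@weights != 0)), c(5L, 2L, 7L))
  expect_s4_class(fit, "SplsdaResult")
  expect_output(show(fit), "SplsdaResult")
  expect_error(splsda(X, y, keepX = 21), "exceeds")
  expect_error(splsda(X, y, keepX = 0), ">= 1")
})

test_that("splsda recovers informative variables under sparsity", {
  set.seed(23)
  n <- 40
  X <- matrix(rnorm(n * 50), n, 50,
              dimnames = list(NULL, paste0("p", 1:50)))
  y <- rep(c("a", "b"), each = n / 2)
  X[y == "a", 1:3] <- X[y == "a", 1:3] + 2
  fit <- splsda(X, y, ncomp = 1, keepX = 3)
  expect_setequal(colnames(X)[fit@weights[, 1] != 0],
                  c("p1", "p2", "p3"))
})

test_that("fit is deterministic and sample-duplication invariant", {
  set.seed(24)
  X <- matrix(rnorm(20 * 8), 20, 8,
              dimnames = list(NULL, paste0("p", 1:8)))
  y <- rep(c("a", "b"), each = 10)
  f1 <- splsda(X, y, ncomp = 2, keepX = 4)
  f2 <- splsda(X, y, ncomp = 2, keepX = 4)
  expect_identical(f1@weights, f2@weights)
  # duplicating every sample leaves the weights unchanged
  f3 <- splsda(rbind(X, X), c(y, y), ncomp = 2, keepX = 4)
  expect_equal(f3@weights, f1@weights, tolerance = 1e-6)
})

test_that("prediction separates separable training data", {
  set.seed(25)
  X <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(NULL, paste0("p", 1:10)))
  y <- rep(c("a", "b", "c"), each = 10)
  X[y == "a", 1] <- X[y == "a", 1] + 6
  X[y == "b", 2] <- X[y == "b", 2] + 6
  X[y == "c", 3] <- X[y == "c", 3] + 6
  fit <- splsda(X, y, ncomp = 2, keepX = 10)
  pr <- splsdaPredict(fit, X)
  expect_equal(pr$class, y)
  expect_equal(dim(pr$values), c(30L, 3L))
  # prediction is invariant to consistent feature permutation
  pm <- sample(10)
  fitp <- splsda(X[, pm], y, ncomp = 2, keepX = 10)
  prp <- splsdaPredict(fitp, X[, pm])
  expect_equal(prp$class, pr$class)
})

test_that("dense fit agrees with the mixOmics reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(26)
  X <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(paste0("s", 1:30), paste0("p", 1:12)))
  y <- rep(c("a", "b"), each = 15)
  X[y == "a", 1:3] <- X[y == "a", 1:3] + 2.5
  ours <- splsda(X, y, ncomp = 1)
  ref <- mixOmics::splsda(X, y, ncomp = 1)
  w_ours <- ours@weights[, 1]
  w_ref <- ref$loadings$X[, 1]
  cosine <- abs(sum(w_ours * w_ref) /
                sqrt(sum(w_ours^2) * sum(w_ref^2)))
  expect_gt(cosine, 0.99)
  # sparse variant: same variables selected
  ours_s <- splsda(X, y, ncomp = 1, keepX = 3)
  ref_s <- mixOmics::splsda(X, y, ncomp = 1, keepX = 3)
  expect_setequal(names(which(ours_s@weights[, 1] != 0)),
                  names(which(ref_s$loadings$X[, 1] != 0)))
})

test_that("cross-validation is seed-deterministic", {
  set.seed(27)
  X <- matrix(rnorm(24 * 10), 24, 10,
              dimnames = list(NULL, paste0("p", 1:10)))
  y <- rep(c("a", "b"), each = 12)
  cv1 <- splsdaCV(X, y, ncomp = 1, keepX = 5, repeats = 10, seed = 4)
  cv2 <- splsdaCV(X, y, ncomp = 1, keepX = 5, repeats = 10, seed = 4)
  expect_identical(cv1, cv2)
  cv3 <- splsdaCV(X, y, ncomp = 1, keepX = 5, repeats = 10, seed = 5)
  expect_false(identical(cv1$ber, cv3$ber))
  # occurrence is a frequency over repeats
  expect_true(all(cv1$occurrence >= 0 & cv1$occurrence <= 1))
  expect_length(cv1$ber, 10)
})

test_that("CV on strongly separable data attains near-zero BER", {
  set.seed(28)
  n <- 30
  X <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(NULL, paste0("p", 1:20)))
  y <- rep(c("a", "b"), each = n / 2)
  X[y == "a", 1:3] <- X[y == "a", 1:3] + 4
  cv <- splsdaCV(X, y, ncomp = 1, keepX = 3, repeats = 20, seed = 1)
  expect_lte(mean(cv$ber), 0.05)
  expect_true(all(cv$occurrence[c("p1", "p2", "p3")] > 0.5))
})

test_that("CV on pure noise sits at balanced chance", {
  # one fixed noise matrix can carry a spurious class correlation that
  # every CV repeat rediscovers, so the Monte-Carlo runs over
  # independent datasets, not over repeats of one dataset
  set.seed(29)
  means <- vapply(1:15, function(r) {
    X <- matrix(rnorm(40 * 15), 40, 15,
                dimnames = list(NULL, paste0("p", 1:15)))
    y <- rep(c("a", "b"), each = 20)
    mean(splsdaCV(X, y, ncomp = 1, keepX = 5, repeats = 5,
                  seed = r)$ber)
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lte(abs(mean(means) - 0.5), 2 * se)
})

test_that("groups smaller than the fold count trigger a warning", {
  set.seed(30)
  X <- matrix(rnorm(12 * 5), 12, 5,
              dimnames = list(NULL, paste0("p", 1:5)))
  y <- c(rep("a", 10), "b", "b")
  expect_warning(splsdaCV(X, y, ncomp = 1, keepX = 2, folds = 3,
                          repeats = 2, seed = 1),
                 "smaller than fold")
})

test_that("tuning picks a sparse model that solves an easy problem", {
  set.seed(32)
  n <- 30
  X <- matrix(rnorm(n * 30), n, 30,
              dimnames = list(NULL, paste0("p", 1:30)))
  y <- rep(c("a", "b", "c"), each = n / 3)
  X[y == "a", 1] <- X[y == "a", 1] + 5
  X[y == "b", 2] <- X[y == "b", 2] + 5
  fit <- splsdaTune(X, y, Hgrid = 2:3, keepXgrid = c(1, 2, 5),
                    repeats = 10, seed = 3)
  expect_lte(mean(fit@ber), 0.1)
  expect_true(all(fit@occurrence[c("p1", "p2")] > 0.5))
  expect_true(fit@ncomp %in% 2:3)
  expect_equal(length(fit@keepX), fit@ncomp)
})

test_that("discriminative selection is the strict conjunction", {
  diffres <- data.frame(
    feature_id = c("F1", "F2", "F3", "F4", "F5"),
    adj_p = c(0.01, 0.01, 0.2, 0.01, 0.01),
    fc = c(8, 8, 8, 4, 8), stringsAsFactors = FALSE)
  occ <- c(F1 = 0.9, F2 = 0.4, F3 = 0.9, F4 = 0.9, F5 = 0.9)
  vr <- c(F1 = TRUE, F2 = TRUE, F3 = TRUE, F4 = TRUE, F5 = FALSE)
  groups <- rep(c("RFposCCPpos_RA", "RFneg_control"), each = 4)
  z <- matrix(rep(c(1, 1, 1, 1, -1, -1, -1, -1), each = 5), 5, 8,
              dimnames = list(diffres$feature_id, NULL))
  out <- selectDiscriminative(diffres, occ, vr, z, groups)
  expect_equal(out$discriminative,
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # control group must attain the lowest per-group median Z
  z2 <- z; z2["F1", 5:8] <- 2
  out2 <- selectDiscriminative(diffres, occ, vr, z2, groups)
  expect_false(out2$discriminative[1])
  # features missing from the occurrence vector default to zero
  out3 <- selectDiscriminative(diffres, occ[-1], vr, z, groups)
  expect_false(out3$discriminative[1])
  expect_equal(out3$occurrence[1], 0)
})
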