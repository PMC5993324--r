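linSpace <- function(n) parameterSpace(paste0("p", seq_len(n)),
                                       lo = rep(0.001, n), hi = rep(1, n),
                                       scale = "linear")

test_that("basis counts and enumeration agree", {
  expect_identical(basisCount(35, 5), 658008)
  expect_identical(basisCount(8, 5), 1287)
  expect_identical(basisCount(7, 0), 1)
  for (n in c(1, 2, 4, 6)) for (d in c(0, 2, 5)) {
    idx <- multiIndices(n, d)
    expect_equal(nrow(idx), basisCount(n, d))
    expect_equal(nrow(unique(idx)), nrow(idx))
    expect_true(all(rowSums(idx) <= d))
    # graded order: total degree nondecreasing
    expect_true(!is.unsorted(rowSums(idx)))
  }
})

test_that("Legendre polynomials follow the P_m(1) = 1 convention", {
  expect_equal(legendreEval(2, 0), -0.5)
  for (m in 0:10) expect_equal(legendreEval(m, 1), 1)
  x <- seq(-1, 1, length.out = 7)
  expect_equal(legendreEval(3, x), (5 * x^3 - 3 * x) / 2)
  # derivative matches an analytic case and a central difference
  expect_equal(legendreDeriv(2, x), 3 * x)
  h <- 1e-6
  x0 <- 0.37
  expect_equal(legendreDeriv(7, x0),
               (legendreEval(7, x0 + h) - legendreEval(7, x0 - h)) / (2 * h),
               tolerance = 1e-8)
})

test_that("Legendre basis is orthogonal under Gauss-Legendre quadrature", {
  gl <- pracma::gaussLegendre(32, -1, 1)
  P <- sapply(0:10, function(m) legendreEval(m, gl$x))
  gram <- t(P) %*% (gl$w / 2 * P)
  offdiag <- gram - diag(diag(gram))
  expect_lt(max(abs(offdiag)), 1e-10)
  expect_equal(diag(gram), 1 / (2 * (0:10) + 1), tolerance = 1e-12)
  # the specific pair quoted as the oracle example
  expect_equal(sum(gl$w / 2 * legendreEval(3, gl$x) * legendreEval(5, gl$x)),
               0, tolerance = 1e-12)
})

test_that("design matrix matches naive tensor-product evaluation", {
  sp <- linSpace(3)
  Y <- sampleUniform(sp, 5, seed = 6)
  idx <- multiIndices(3, 4)
  A <- designMatrix(Y, idx)
  expect_equal(A[, 1], rep(1, 5))             # alpha = 0 column
  naive <- matrix(1, 5, nrow(idx))
  for (j in seq_len(nrow(idx)))
    for (k in 1:3)
      naive[, j] <- naive[, j] * legendreEval(idx[j, k], Y[, k])
  expect_equal(A, naive, tolerance = 1e-12)
  ones <- designMatrix(matrix(1, 1, 3), idx)
  expect_equal(as.numeric(ones), rep(1, nrow(idx)))
  expect_error(designMatrix(Y[, 1:2], idx), "dimension")
})

test_that("least squares recovers realizable coefficients exactly", {
  sp <- linSpace(2)
  idx <- multiIndices(2, 5)
  Y <- sampleUniform(sp, 4 * nrow(idx), seed = 8)
  A <- designMatrix(Y, idx)
  set.seed(1)
  truth <- rnorm(nrow(idx))
  x <- fitLeastSquares(A, A %*% truth)
  expect_equal(as.numeric(x), truth, tolerance = 1e-8)
  expect_equal(as.numeric(fitLeastSquares(A, rep(0, nrow(A)))),
               rep(0, nrow(idx)))
  # residual is orthogonal to the column space
  b <- rnorm(nrow(A))
  r <- b - A %*% fitLeastSquares(A, b)
  expect_lt(max(abs(crossprod(A, r))) / max(abs(b)), 1e-8)
  expect_error(fitLeastSquares(A[1:10, ], (A %*% truth)[1:10]), "fitL1")
  expect_warning(fitLeastSquares(cbind(A, A[, 2]),
                                 A %*% truth), "rank deficient")
})

test_that("l1 minimization is feasible and recovers planted sparsity", {
  set.seed(3)
  sp <- linSpace(8)
  idx <- multiIndices(8, 3)                 # 165 basis terms
  m <- 110                                  # undersampled
  Y <- sampleUniform(sp, m, seed = 13)
  A <- designMatrix(Y, idx)
  x0 <- numeric(nrow(idx))
  supp <- sample(nrow(idx), 10)
  x0[supp] <- rnorm(10)
  b <- as.numeric(A %*% x0)
  x <- fitL1(A, b, epsilon = 1e-8)
  expect_lte(sqrt(sum((A %*% x - b)^2)), 1e-8 * (1 + 1e-6))
  expect_lt(max(abs(x - x0)), 1e-4)
  expect_setequal(which(abs(x) > 1e-3), supp[abs(x0[supp]) > 1e-3])
  # huge epsilon: zero is feasible and l1-minimal
  expect_equal(fitL1(A, b, epsilon = 2 * sqrt(sum(b^2))),
               numeric(nrow(idx)))
  # noisy right-hand side still satisfies the constraint
  bn <- b + rnorm(m, 0, 0.05)
  eps <- 0.05 * sqrt(sum(bn^2))
  xn <- fitL1(A, bn, eps)
  expect_lte(sqrt(sum((A %*% xn - bn)^2)), eps * (1 + 1e-6))
  expect_error(fitL1(A[1:60, 1:2], bn[1:60], epsilon = 1e-10), "infeasible")
})

test_that("surrogate evaluation matches naive summation", {
  sp <- linSpace(3)
  Y <- sampleUniform(sp, 60, seed = 21)
  idx <- multiIndices(3, 3)
  set.seed(2)
  truth <- rnorm(nrow(idx))
  Z <- designMatrix(Y, idx) %*% truth
  fit <- fitSurrogate(Y, Z, sp, 3, method = "ls")
  y <- c(0.3, -0.5, 0.9)
  naive <- sum(sapply(seq_len(nrow(idx)), function(j)
    fit$coeffs[j, 1] * prod(sapply(1:3, function(k)
      legendreEval(idx[j, k], y[k])))))
  expect_equal(evaluateSurrogate(fit, y), naive, tolerance = 1e-12)
  # constant surrogate and the linear coordinate surrogate
  cfit <- fit; cfit$coeffs[] <- 0; cfit$coeffs[1, 1] <- 3
  expect_equal(evaluateSurrogate(cfit, c(-0.2, 0.4, 0)), 3)
  lfit <- fit; lfit$coeffs[] <- 0
  lfit$coeffs[which(idx[, 1] == 1 & rowSums(idx) == 1), 1] <- 1
  expect_equal(evaluateSurrogate(lfit, c(0.3, 0.9, -0.4)), 0.3)
  expect_warning(evaluateSurrogate(fit, c(1.2, 0, 0)), "extrapolation")
})

test_that("cross-validation partitions correctly and sees noise honestly", {
  sp <- linSpace(2)
  idx <- multiIndices(2, 3)
  Y <- sampleUniform(sp, 120, seed = 31)
  set.seed(4)
  truth <- rnorm(nrow(idx))
  Z <- designMatrix(Y, idx) %*% truth
  cv <- crossValidate(Y, Z, sp, 3, k = 6, method = "ls", seed = 2)
  expect_lt(cv$mean_abs_error, 1e-8)
  expect_false(anyNA(cv$errors))            # every sample held out once
  # pure-noise response: mean error near 0, sd near the noise level
  sdn <- 0.3
  Zn <- matrix(rnorm(120, 0, sdn))
  cvn <- crossValidate(Y, Zn, sp, 1, k = 6, method = "ls", seed = 2)
  expect_lt(abs(cvn$mean_error), 3 * sdn / sqrt(120))
  expect_equal(cvn$sd_error, sdn, tolerance = 0.35)
  expect_error(crossValidate(Y[1:20, ], Z[1:20, , drop = FALSE], sp, 5,
                             k = 10, method = "ls"), "l1")
})

test_that("surrogates and sample sets round-trip through their files", {
  sp <- gproteinSpace2()
  Y <- sampleUniform(sp, 40, seed = 17)
  idx <- multiIndices(2, 2)
  Z <- cbind(a = designMatrix(Y, idx) %*% rnorm(nrow(idx)),
             b = designMatrix(Y, idx) %*% rnorm(nrow(idx)))
  fit <- fitSurrogate(Y, Z, sp, 2, method = "ls")
  f <- tempfile(fileext = ".json")
  writeSurrogate(fit, f)
  fit2 <- readSurrogate(f)
  expect_equal(fit2$coeffs, fit$coeffs)
  expect_equal(fit2$basis, fit$basis)
  expect_equal(evaluateSurrogate(fit2, c(0.2, -0.7)),
               evaluateSurrogate(fit, c(0.2, -0.7)))
  fs <- tempfile(fileext = ".csv")
  writeSampleSet(Y, Z, fs, seed = 17)
  ss <- readSampleSet(fs)
  expect_equal(ss$Y, Y, ignore_attr = TRUE)
  expect_equal(unname(ss$Z), unname(Z))
  expect_equal(ss$seed, 17)
})
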