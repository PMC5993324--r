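linSpace3 <- parameterSpace(c("a", "b", "c"), lo = rep(0.1, 3),
                            hi = rep(1, 3), scale = "linear")

mkSurrogate <- function(space, degree, coeffs) {
  idx <- multiIndices(spaceDim(space), degree)
  cc <- matrix(coeffs, nrow(idx), 1)
  structure(list(basis = idx, degree = degree, coeffs = cc, space = space,
                 response_label = "z", method = "ls", epsilon = NA_real_),
            class = "gpcSurrogate")
}

test_that("linear and even responses give the textbook sensitivities", {
  idx <- multiIndices(3, 4)
  # z = y_1
  cc <- numeric(nrow(idx))
  cc[which(idx[, 1] == 1 & rowSums(idx) == 1)] <- 1
  s <- mkSurrogate(linSpace3, 4, cc)
  expect_equal(unname(sapply(1:3, function(j) sensitivityFromCoeffs(s, j))),
               c(1, 0, 0))
  # z = y_1^2 = (2 P_2(y_1) + P_0)/3: expected derivative vanishes by symmetry
  cc2 <- numeric(nrow(idx))
  cc2[1] <- 1 / 3
  cc2[which(idx[, 1] == 2 & rowSums(idx) == 2)] <- 2 / 3
  s2 <- mkSurrogate(linSpace3, 4, cc2)
  expect_equal(unname(sensitivityFromCoeffs(s2, 1)), 0)
  expect_error(sensitivityFromCoeffs(s2, 9), "range")
  expect_equal(unname(sensitivityFromCoeffs(s2, "a")), 0)
})

test_that("analytic sensitivities equal tensor Gauss-Legendre quadrature", {
  set.seed(5)
  idx <- multiIndices(3, 4)
  s <- mkSurrogate(linSpace3, 4, rnorm(nrow(idx)))
  gl <- pracma::gaussLegendre(10, -1, 1)
  grid <- as.matrix(expand.grid(1:10, 1:10, 1:10))
  pts <- cbind(gl$x[grid[, 1]], gl$x[grid[, 2]], gl$x[grid[, 3]])
  w <- gl$w[grid[, 1]] * gl$w[grid[, 2]] * gl$w[grid[, 3]] / 8
  G <- surrogateGradient(s, pts)
  for (j in 1:3)
    expect_equal(unname(sensitivityFromCoeffs(s, j)), sum(w * G[, j]),
                 tolerance = 1e-10)
})

test_that("analytic sensitivities agree with a Monte-Carlo derivative mean", {
  set.seed(6)
  idx <- multiIndices(2, 5)
  sp <- parameterSpace(c("a", "b"), c(0.1, 0.1), c(1, 1), scale = "linear")
  s <- mkSurrogate(sp, 5, rnorm(nrow(idx)))
  n <- 1e4
  Y <- sampleUniform(sp, n, seed = 77)
  G <- surrogateGradient(s, Y)
  for (j in 1:2) {
    se <- stats::sd(G[, j]) / sqrt(n)
    expect_lt(abs(mean(G[, j]) - sensitivityFromCoeffs(s, j)), 3 * se)
  }
})

test_that("screening retains exactly the parameters above threshold", {
  idx <- multiIndices(3, 3)
  cc <- numeric(nrow(idx))
  cc[which(idx[, 1] == 1 & rowSums(idx) == 1)] <- 0.5   # S_a = 0.5
  cc[which(idx[, 2] == 1 & rowSums(idx) == 1)] <- 0.004 # S_b below threshold
  s <- mkSurrogate(linSpace3, 3, cc)
  rep <- sensitivityReport(s, threshold = 0.01, n_mc = 500, seed = 2)
  expect_equal(rep$retained, "a")
  expect_equal(unname(rep$mean_over_responses),
               c(0.5, 0.004, 0), tolerance = 1e-12)
  # all-zero surrogate retains nothing
  s0 <- mkSurrogate(linSpace3, 3, numeric(nrow(idx)))
  rep0 <- sensitivityReport(s0, n_mc = 100)
  expect_length(rep0$retained, 0)
  expect_error(sensitivityReport(structure(list(coeffs = NULL),
                                           class = "gpcSurrogate")),
               "empty")
  # report files are written
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".json")
  writeSensitivityReport(rep, f1, f2)
  expect_true(file.exists(f1) && file.exists(f2))
  js <- jsonlite::fromJSON(f2)
  expect_equal(js$retained, "a")
})
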