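## a 1-D surrogate representing z(y) = y on the cube
identitySurrogate <- function() {
  sp <- parameterSpace("theta", -1, 1, "linear")
  idx <- multiIndices(1, 3)
  cc <- matrix(0, nrow(idx), 1)
  cc[which(idx[, 1] == 1), 1] <- 1
  structure(list(basis = idx, degree = 3, coeffs = cc, space = sp,
                 response_label = "z", method = "ls", epsilon = NA_real_),
            class = "gpcSurrogate")
}

test_that("the Gaussian log-likelihood matches a product of densities", {
  s <- identitySurrogate()
  d <- data.frame(mean = 0.2, sd = 0.3)
  expect_equal(logLikelihood(0.2, d, s), 0)
  expect_equal(logLikelihood(0.5, d, s), -1 / 2)
  expect_equal(logLikelihood(1.5, d, s), -Inf)
  # multi-point case against dnorm
  sp <- gproteinSpace2()
  Y <- sampleUniform(sp, 30, seed = 3)
  idx <- multiIndices(2, 2)
  Z <- cbind(designMatrix(Y, idx) %*% rnorm(nrow(idx)),
             designMatrix(Y, idx) %*% rnorm(nrow(idx)))
  fit <- fitSurrogate(Y, Z, sp, 2, method = "ls")
  d2 <- data.frame(mean = c(0.1, -0.2), sd = c(0.4, 0.7))
  y <- c(0.3, -0.6)
  s_hat <- evaluateSurrogate(fit, y)
  ref <- sum(stats::dnorm(d2$mean, s_hat, d2$sd, log = TRUE)) -
    sum(stats::dnorm(d2$mean, d2$mean, d2$sd, log = TRUE))
  expect_equal(logLikelihood(y, d2, fit), ref, tolerance = 1e-12)
  expect_error(logLikelihood(y, d2[1, , drop = FALSE], fit), "one surrogate")
})

test_that("a flat likelihood reproduces the uniform prior", {
  sp <- parameterSpace(c("a", "b"), c(0.1, 0.1), c(1, 1), scale = "linear")
  cfg <- mcmcConfig(chain_length = 6e4, burn_in = 1e4, proposal_sd = 0.6,
                    seed = 42)
  ch <- mhChain(cfg, function(y) 0, sp)
  expect_true(all(abs(ch$samples) <= 1))
  expect_gt(ch$acceptance_rate, 0)
  n_eff <- nrow(ch$samples) / 20           # crude autocorrelation discount
  for (j in 1:2) {
    expect_lt(abs(mean(ch$samples[, j])), 4 / sqrt(3) / sqrt(n_eff))
    expect_equal(stats::var(ch$samples[, j]), 1 / 3, tolerance = 0.15)
  }
})

test_that("compiled and R samplers agree with a closed-form posterior", {
  s <- identitySurrogate()
  d <- data.frame(mean = 0.2, sd = 0.3)
  lik <- surrogateLikelihood(s, d)
  cfg <- mcmcConfig(chain_length = 2e5, burn_in = 2e4, proposal_sd = 0.4,
                    seed = 11)
  ch <- mhChain(cfg, lik, s$space)
  # truncated-Gaussian moments on [-1, 1]
  a <- (-1 - 0.2) / 0.3; b <- (1 - 0.2) / 0.3
  zc <- stats::pnorm(b) - stats::pnorm(a)
  m_true <- 0.2 + 0.3 * (stats::dnorm(a) - stats::dnorm(b)) / zc
  v_true <- 0.3^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / zc -
                       ((stats::dnorm(a) - stats::dnorm(b)) / zc)^2)
  expect_equal(mean(ch$samples), m_true, tolerance = 0.02)
  expect_equal(stats::sd(ch$samples), sqrt(v_true), tolerance = 0.05)
  # R-path sampler targets the same distribution
  chR <- mhChain(mcmcConfig(4e4, 5e3, 0.4, seed = 12),
                 function(y) logLikelihood(y, d, s), s$space)
  expect_equal(mean(chR$samples), m_true, tolerance = 0.05)
  # determinism under a fixed seed
  ch2 <- mhChain(cfg, lik, s$space)
  expect_identical(ch$samples, ch2$samples)
})

test_that("a two-state target satisfies detailed balance empirically", {
  sp <- parameterSpace("s", 0.1, 1, "linear")
  p_ratio <- 3                     # target: P(y<0) : P(y>0) = 3 : 1
  lik <- function(y) if (y < 0) log(p_ratio) else 0
  ch <- mhChain(mcmcConfig(1e5, 1e4, 0.8, seed = 9), lik, sp)
  occ <- mean(ch$samples < 0)
  expect_equal(occ / (1 - occ), p_ratio, tolerance = 0.15)
  # crossing flows balance
  s <- ch$samples[, 1]
  ab <- sum(s[-length(s)] < 0 & s[-1] >= 0)
  ba <- sum(s[-length(s)] >= 0 & s[-1] < 0)
  expect_lt(abs(ab - ba), 2)
})

test_that("chain statistics are invariant to parameter ordering", {
  sp <- gproteinSpace2()
  spRev <- parameterSpace(rev(sp$name), rev(sp$lo), rev(sp$hi),
                          rev(sp$scale))
  lik <- function(y) -sum((y - c(0.3, -0.2))^2) * 8
  likRev <- function(y) -sum((y - c(-0.2, 0.3))^2) * 8
  ch <- mhChain(mcmcConfig(1e5, 1e4, 0.3, seed = 4), lik, sp)
  chR <- mhChain(mcmcConfig(1e5, 1e4, 0.3, seed = 5), likRev, spRev)
  expect_equal(colMeans(ch$samples)[["kGa"]],
               colMeans(chR$samples)[["kGa"]], tolerance = 0.02)
  expect_equal(colMeans(ch$samples)[["kGd"]],
               colMeans(chR$samples)[["kGd"]], tolerance = 0.02)
})

test_that("the sampler aborts when it stalls", {
  sp <- parameterSpace("s", 0.1, 1, "linear")
  lik <- function(y) if (abs(y) < 1e-4) 0 else -1e9
  expect_error(
    mhChain(mcmcConfig(3e4, 1e3, 0.5, seed = 2), lik, sp, init = 0),
    "stalled")
})

test_that("multi-chain convergence diagnostics separate same from shifted targets", {
  sp <- parameterSpace(c("a", "b"), c(0.1, 0.1), c(1, 1), scale = "linear")
  lik <- function(y) -sum(y^2) * 4
  shifted <- function(y) -sum((y - 0.6)^2) * 4
  chains <- lapply(1:2, function(i)
    mhChain(mcmcConfig(5e4, 5e3, 0.4, seed = 100 + i), lik, sp))
  chk <- convergenceCheck(chains, tol = 0.1)
  expect_true(chk$passed)
  bad <- mhChain(mcmcConfig(5e4, 5e3, 0.4, seed = 103), shifted, sp)
  chk2 <- convergenceCheck(list(chains[[1]], bad), tol = 0.1)
  expect_false(chk2$passed)
  expect_error(convergenceCheck(list(chains[[1]])), "2")
  # distances shrink roughly like 1/sqrt(length) for a flat target
  flat <- function(y) 0
  short <- lapply(1:2, function(i)
    mhChain(mcmcConfig(6e3, 1e3, 0.8, seed = 200 + i), flat, sp))
  long <- lapply(1:2, function(i)
    mhChain(mcmcConfig(2e5, 1e3, 0.8, seed = 200 + i), flat, sp))
  expect_lt(convergenceCheck(long)$max_distance,
            convergenceCheck(short)$max_distance)
})

test_that("posterior summaries report modes, means and correlations", {
  sp <- gproteinSpace2()
  const <- matrix(rep(c(0.25, -0.5), each = 10), ncol = 2,
                  dimnames = list(NULL, sp$name))
  ch <- structure(list(samples = const, log_post = rep(0, 10),
                       acceptance_rate = 0.3, seed = 1, space = sp),
                  class = "mcmcChain")
  s <- posteriorSummary(ch)
  expect_equal(unname(s$mean), unname(fromCube(c(0.25, -0.5), sp)),
               tolerance = 1e-12)
  expect_equal(unname(s$mode), unname(s$mean), tolerance = 0.05)
  expect_equal(s$correlation, diag(1, 2), ignore_attr = TRUE)
  set.seed(8)
  u <- matrix(runif(2e4, -1, 1), ncol = 2,
              dimnames = list(NULL, sp$name))
  chu <- structure(list(samples = u, log_post = rep(0, 1e4),
                        acceptance_rate = 0.3, seed = 1, space = sp),
                   class = "mcmcChain")
  su <- posteriorSummary(chu)
  expect_lt(abs(su$correlation[1, 2]), 3 / sqrt(1e4))
})

test_that("simulated annealing finds analytic minima and never regresses", {
  obj <- function(y) sum((y - c(0.3, -0.4))^2)
  res <- simulatedAnnealing(obj, c(-0.9, 0.9),
                            schedule = list(t0 = 0.5, t_end = 1e-5,
                                            n_steps = 20000, step_sd = 0.05),
                            seed = 3)
  expect_lt(sqrt(res$value), 1e-2)
  expect_equal(res$par, c(0.3, -0.4), tolerance = 2e-2)
  expect_true(!is.unsorted(rev(res$trace)))   # best-so-far is monotone
  at_min <- simulatedAnnealing(obj, c(0.3, -0.4), seed = 4)
  expect_lte(at_min$value, obj(c(0.3, -0.4)))
})

test_that("chains round-trip through their CSV + sidecar files", {
  s <- identitySurrogate()
  lik <- surrogateLikelihood(s, data.frame(mean = 0.1, sd = 0.5))
  ch <- mhChain(mcmcConfig(2e4, 2e3, 0.5, seed = 6), lik, s$space)
  f <- tempfile(fileext = ".csv")
  writeChain(ch, f)
  expect_true(file.exists(f) && file.exists(paste0(f, ".json")))
  df <- utils::read.csv(f)
  expect_equal(nrow(df), nrow(ch$samples))
  expect_equal(df$theta, fromCube(ch$samples, ch$space)[, 1])
})
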