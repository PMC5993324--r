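geom64 <- circleGeometry(N = 64)

test_that("geometry and ligand profile satisfy their defining identities", {
  g <- circleGeometry()
  expect_equal(g$N * g$ds, g$SA)
  expect_equal(g$SA, 2 * pi * g$radius)
  expect_equal(g$V, pi * g$radius^2)
  L <- ligandProfile(g, 10, 0.1)
  expect_equal(max(L), 10.2)
  expect_equal(min(L), 9.8)
  expect_equal(which.max(L), which.min(abs(g$alpha - pi)))
  expect_equal(mean(L), 10, tolerance = 1e-12)
  expect_equal(ligandProfile(g, 7, 0), rep(7, g$N))
  expect_error(ligandProfile(g, 0.1, 0.1), "negative")
})

test_that("nonlocal coefficients obey their normalizations and limits", {
  p <- polarizationParams()
  st <- membraneState(p, geom64)
  # uniform Gbg: the delta-normalized Hill switch sits at half saturation
  st$fields[, "Gbg"] <- 123
  st$fields[, "C42a"] <- 7.5
  st$fields[, "B1m"] <- 3
  for (q in c(1, 8, 100)) {
    p2 <- polarizationParams(q = q)
    nc <- nonlocalCoeffs(st, p2, geom64)
    expect_equal(nc$Gbgn_star, rep(0.5, geom64$N), tolerance = 1e-12)
  }
  nc <- nonlocalCoeffs(st, p, geom64)
  expect_equal(nc$ps, rep(1, geom64$N))
  expect_equal(nc$C42at_star, mean(st$fields[, "C42a"]))
  expect_equal(nc$B1t_star, mean(st$fields[, "B1m"]))
  expect_true(all(nc$Gbgn_star >= 0 & nc$Gbgn_star <= 1))
  # spatial mean of ps is 1 whenever C42at* > 0
  st$fields[, "C42a"] <- runif(geom64$N)
  nc2 <- nonlocalCoeffs(st, p, geom64)
  expect_equal(mean(nc2$ps), 1, tolerance = 1e-12)
  # vanishing integrals fall back to the Hill limit, not NaN
  st0 <- membraneState(p, geom64)
  nc0 <- nonlocalCoeffs(st0, p, geom64)
  expect_equal(nc0$Gbgn_star, rep(0, geom64$N))
  expect_equal(nc0$B1star, rep(0, geom64$N))
  expect_equal(nc0$ps, rep(1, geom64$N))
})

zeroParams <- function() {
  p <- polarizationParams()
  for (nm in names(p))
    if (!nm %in% c("q", "h", "C24t", "B1t", "Rt", "Gt", "C42t")) p[[nm]] <- 0
  class(p) <- "polarizationParams"
  p
}

test_that("the time step is the identity when nothing moves or reacts", {
  p <- zeroParams()
  st <- membraneState(p, geom64)
  st$fields[, "C42a"] <- runif(geom64$N)
  st2 <- polarizationStep(st, p, geom64, rep(10, geom64$N), dt = 0.1)
  expect_equal(st2$fields, st$fields, tolerance = 1e-14)
})

test_that("pure diffusion conserves mass and contracts variance", {
  p <- zeroParams()
  p$DC42a <- 0.05
  st <- membraneState(p, geom64)
  set.seed(2)
  st$fields[, "C42a"] <- runif(geom64$N)
  m0 <- sum(st$fields[, "C42a"]) * geom64$ds
  v_prev <- var(st$fields[, "C42a"])
  cur <- st
  for (i in 1:5) {
    cur <- polarizationStep(cur, p, geom64, rep(10, geom64$N), dt = 0.1)
    m <- sum(cur$fields[, "C42a"]) * geom64$ds
    expect_equal(m, m0, tolerance = 1e-10)
    v <- var(cur$fields[, "C42a"])
    expect_lte(v, v_prev + 1e-14)
    v_prev <- v
  }
})

test_that("a Fourier mode decays by the Crank-Nicolson amplification factor", {
  p <- zeroParams()
  D <- 0.01
  p$DC42a <- D
  g <- circleGeometry(N = 400)
  m <- 1                                  # integer mode on the circle
  k <- m / g$radius                       # wavenumber in arc length
  dt <- 0.05
  st <- membraneState(p, g)
  mode <- cos(k * g$ds * (seq_len(g$N) - 1))
  st$fields[, "C42a"] <- 10 + mode
  st2 <- polarizationStep(st, p, g, rep(10, g$N), dt = dt)
  # discrete-Laplacian eigenvalue: exact amplification of the scheme
  lam_d <- D * dt / 2 * (2 - 2 * cos(k * g$ds)) / g$ds^2
  keep <- abs(mode) > 1e-3          # avoid dividing by the mode's zeros
  got <- (st2$fields[keep, "C42a"] - 10) / mode[keep]
  expect_equal(got, rep((1 - lam_d) / (1 + lam_d), sum(keep)),
               tolerance = 1e-10)
  # continuous closed form agrees at this resolution
  lam <- D * k^2 * dt / 2
  expect_lt(max(abs(got - (1 - lam) / (1 + lam))), 1e-8)
})

test_that("a uniform ligand preserves spatial symmetry to steady state", {
  p <- polarizationParams()
  g <- circleGeometry(N = 100)
  st <- simulatePolarization(p, g, rep(10, g$N), t_end = 100, dt = 0.1)
  spread <- apply(st$fields, 2, function(w) diff(range(w)))
  expect_true(all(spread < 1e-8 * (1 + apply(st$fields, 2, max))))
  expect_equal(polarizationFactor(st$fields[, "C42"], g), 0,
               tolerance = 1e-8)
})

test_that("rotating the ligand gradient rotates the steady state", {
  p <- polarizationParams()
  g <- circleGeometry(N = 100)
  shift <- 25                               # quarter turn, multiple of 2pi/N
  L1 <- ligandProfile(g)
  L2 <- L1[((seq_len(g$N) - 1 - shift) %% g$N) + 1]
  s1 <- simulatePolarization(p, g, L1, t_end = 60, dt = 0.1)
  s2 <- simulatePolarization(p, g, L2, t_end = 60, dt = 0.1)
  rot <- s1$fields[((seq_len(g$N) - 1 - shift) %% g$N) + 1, ]
  expect_equal(s2$fields, rot, tolerance = 1e-9)
})

test_that("Cdc24 and Bem1 totals are conserved along a run", {
  p <- polarizationParams()
  g <- circleGeometry(N = 100)
  st <- simulatePolarization(p, g, t_end = 150, dt = 0.1)
  c24 <- st$C24c * g$V + sum(st$fields[, "C24m"]) * g$ds
  b1 <- st$B1c * g$V + sum(st$fields[, "B1m"]) * g$ds
  expect_equal(c24 / p$C24t, 1, tolerance = 1e-3)
  expect_equal(b1 / p$B1t, 1, tolerance = 1e-3)
  expect_gte(st$diagnostics$min_pool, 0)
})

test_that("the steady state is converged at the production time step", {
  p <- polarizationParams()
  g <- circleGeometry(N = 100)
  a <- simulatePolarization(p, g, t_end = 1000, dt = 0.05)
  b <- simulatePolarization(p, g, t_end = 1000, dt = 0.025)
  expect_lt(max(abs(a$fields - b$fields)) / max(abs(b$fields)), 1e-4)
})

test_that("polarization factor matches its geometric definition", {
  g <- circleGeometry(N = 200)
  expect_equal(polarizationFactor(rep(3, g$N), g), 0)
  half <- c(rep(2, g$N / 2), rep(0, g$N / 2))
  expect_equal(polarizationFactor(half, g), 0.5, tolerance = 1e-6)
  spike <- rep(0, g$N); spike[17] <- 5
  expect_equal(polarizationFactor(spike, g), 1 - g$ds / g$SA)
  # invariance under positive scaling and rotation
  set.seed(7)
  f <- rexp(g$N)
  pf <- polarizationFactor(f, g)
  expect_equal(polarizationFactor(10 * f, g), pf)
  expect_equal(polarizationFactor(f[c(51:200, 1:50)], g), pf,
               tolerance = 1e-12)
  expect_error(polarizationFactor(rep(0, g$N), g), "undefined")
})

test_that("the cut-off response penalizes weak activation as specified", {
  p <- polarizationParams()
  g <- circleGeometry()
  PF <- 0.8
  expect_equal(cutoffResponse(PF, p$C42t / (2 * g$SA), p, g), PF / 2)
  expect_equal(cutoffResponse(PF, p$C42t / g$SA, p, g), PF * 32 / 33)
  expect_equal(cutoffResponse(PF, 0, p, g), 0)
})

test_that("membrane states round-trip through CSV", {
  p <- polarizationParams()
  st <- membraneState(p, geom64)
  st$fields[, "C42a"] <- generatePolarizationProfile(geom64, 4, 5000)
  f <- tempfile(fileext = ".csv")
  writeMembraneState(st, geom64, f)
  df <- readMembraneState(f)
  expect_equal(df$alpha_rad, geom64$alpha)
  expect_equal(df$C42a, st$fields[, "C42a"])
})
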