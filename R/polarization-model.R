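#' Circular membrane geometry
#'
#' The cell membrane is a circle of given radius, discretized by \code{N}
#' equally spaced mesh points.  The mesh angle \eqn{\alpha \in [0, 2\pi)} is
#' measured from the negative x-axis, so the point \eqn{x(\alpha) =
#' -radius\cos\alpha} places the positive-x pole (towards the pheromone
#' source) at \eqn{\alpha = \pi}.  \code{SA} is the total arc length
#' \eqn{2\pi r} and \code{V} the enclosed area \eqn{\pi r^2}; membrane
#' concentrations are molecules per unit arc length squared-equivalent
#' (molecules/um^2 in the field's convention) and cytoplasmic pools
#' molecules per volume.
#'
#' @param radius circle radius, um (default 2).
#' @param N number of mesh points (default 400).
#' @return list of class \code{"circleGeometry"} with \code{radius, N, SA,
#'   V, ds, alpha, x, y}.
#' @export
circleGeometry <- function(radius = 2, N = 400) {
  stopifnot(radius > 0, N >= 4)
  alpha <- 2 * pi * (seq_len(N) - 1) / N
  structure(list(radius = radius, N = as.integer(N),
                 SA = 2 * pi * radius, V = pi * radius^2,
                 ds = 2 * pi * radius / N, alpha = alpha,
                 x = -radius * cos(alpha), y = -radius * sin(alpha)),
            class = "circleGeometry")
}

.polar_fields <- c("R", "RL", "G", "Ga", "Gbg", "Gd", "C24m", "C42", "C42a",
                   "B1m", "Cla4a")

## Baseline parameter table for the polarization model: previous estimates
## and ranges from earlier modelling work.  SA/V-scaled entries are resolved
## against the given geometry.
.polarization_table3 <- function(geometry = circleGeometry()) {
  SA <- geometry$SA; V <- geometry$V
  t3 <- rbind(
    data.frame(name = c("DR", "DRL"), est = 0.001, lo = NA, hi = NA),
    data.frame(name = c("DG", "DGa", "DGbg", "DGd", "DC24m", "DC42",
                        "DC42a", "DB1m"), est = 0.01, lo = 0.005, hi = 0.02),
    data.frame(name = "kRL",   est = 2e-3,      lo = NA, hi = NA),
    data.frame(name = "kRLm",  est = 1e-2,      lo = NA, hi = NA),
    data.frame(name = c("kRd0", "kRd1"), est = 4e-4, lo = NA, hi = NA),
    data.frame(name = "kRs",   est = 4 / SA,    lo = NA, hi = NA),
    data.frame(name = "kGa",   est = 1e-5 * SA, lo = NA, hi = NA),
    data.frame(name = "kGd",   est = 0.1,       lo = NA, hi = NA),
    data.frame(name = "kG1",   est = 1,         lo = NA, hi = NA),
    data.frame(name = "k42d",  est = 0.02,      lo = 0.02,        hi = 2),
    data.frame(name = "k42a",  est = 1e-5 * SA, lo = 1e-5 * SA,   hi = 1e-3 * SA),
    data.frame(name = "k24cm0", est = 0.04 * V / SA, lo = 0.004 * V / SA,
               hi = 0.4 * V / SA),
    data.frame(name = "k24cm1", est = 3.3e-3 * V, lo = 3.3e-4 * V,
               hi = 3.3e-2 * V),
    data.frame(name = "k24mc", est = 1,         lo = 0.1,  hi = 1),
    data.frame(name = "kB1mc", est = 0.01,      lo = 0.01, hi = 1),
    data.frame(name = "kB1cm", est = 1e-5 * V,  lo = 1e-5 * V, hi = 1e-3 * V),
    data.frame(name = "kCla4a", est = 0.006,    lo = 6e-4, hi = 0.06),
    data.frame(name = "kCla4d", est = 0.01,     lo = 1e-3, hi = 0.1),
    data.frame(name = "k24d",  est = SA / 3000, lo = 0.1 * SA / 3000,
               hi = 10 * SA / 3000),
    data.frame(name = "q",     est = 100,       lo = 1,    hi = 100),
    data.frame(name = "h",     est = 8,         lo = 1,    hi = 8),
    data.frame(name = "C24t",  est = 2000,      lo = 1000, hi = 3000),
    data.frame(name = "B1t",   est = 3000,      lo = 2000, hi = 5000),
    data.frame(name = "Rt",    est = 10000,     lo = NA,   hi = NA),
    data.frame(name = "Gt",    est = 10000,     lo = NA,   hi = NA),
    data.frame(name = "C42t",  est = 10000,     lo = 5000, hi = 20000))
  # entries quoted as +/-10% expand around the previous estimate
  pm <- is.na(t3$lo)
  t3$lo[pm] <- 0.9 * t3$est[pm]
  t3$hi[pm] <- 1.1 * t3$est[pm]
  t3$scale <- ifelse(t3$name %in% c("q", "h"), "linear", "log10")
  rownames(t3) <- NULL
  t3
}

#' Polarization model parameters
#'
#' The 35 parameters of the membrane polarization model: 10 diffusion
#' constants (um^2/s), 18 reaction rates, the two Hill exponents \code{q}
#' and \code{h}, and 5 total molecule counts.  Defaults are the baseline
#' estimates from previous modelling work, with the surface-area/volume
#' scaled entries resolved against the supplied geometry (e.g. \code{kRs} =
#' 4/SA, \code{k42a} = 1e-5 SA, \code{k24cm1} = 3.3e-3 V).
#'
#' @param ... named overrides of the baseline values.
#' @param geometry the \code{\link{circleGeometry}} the SA/V-scaled entries
#'   refer to.
#' @return named list of class \code{"polarizationParams"}.
#' @export
polarizationParams <- function(..., geometry = circleGeometry()) {
  t3 <- .polarization_table3(geometry)
  p <- as.list(stats::setNames(t3$est, t3$name))
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  if (any(unlist(p) < 0)) stop("all parameters must be nonnegative")
  if (p$q < 1 || p$h < 1) stop("Hill exponents must be >= 1")
  structure(p, class = "polarizationParams")
}

#' Natural-unit parameter vector for the polarization model
#'
#' Maps a cube point of a (sub)space onto a full parameter list, fixing the
#' remaining parameters at their baseline values.
#' @param y cube coordinate vector for \code{space}.
#' @param space a \code{parameterSpace} whose names are polarization
#'   parameters (e.g. \code{\link{polarizationSpace15}}).
#' @param geometry geometry for the baseline values.
#' @return a \code{polarizationParams}.
#' @export
polarizationParamsFromCube <- function(y, space, geometry = circleGeometry()) {
  nat <- fromCube(stats::setNames(y, space$name), space)
  do.call(polarizationParams,
          c(as.list(nat), list(geometry = geometry)))
}

#' Pheromone ligand profile along the membrane
#'
#' A linear gradient from the positive x-direction:
#' \eqn{L(\alpha) = midpoint + slope \cdot x(\alpha)} with
#' \eqn{x(\alpha) = -radius\cos\alpha}, so the maximum ligand sits at the
#' positive-x pole (\eqn{\alpha = \pi}).
#'
#' @param geometry a \code{\link{circleGeometry}}.
#' @param midpoint gradient midpoint, nM (default 10).
#' @param slope gradient slope, nM/um (default 0.1).
#' @return numeric vector of ligand concentrations per mesh point.
#' @export
ligandProfile <- function(geometry, midpoint = 10, slope = 0.1) {
  stopifnot(midpoint > 0)
  L <- midpoint + slope * geometry$x
  if (any(L < 0)) stop("ligand profile goes negative; reduce |slope|")
  L
}

#' Initial membrane state
#'
#' Uniform initial conditions: receptor, heterotrimeric G-protein and
#' inactive Cdc42 distributed evenly over the membrane (\code{Rt/SA},
#' \code{Gt/SA}, \code{C42t/SA}); everything else 0 on the membrane, and the
#' Cdc24/Bem1 pools fully cytoplasmic.  Symmetry is broken only by the
#' ligand gradient; no noise is injected.
#'
#' @param params a \code{polarizationParams}.
#' @param geometry a \code{circleGeometry}.
#' @return list of class \code{"membraneState"} with \code{fields} (N x 11
#'   matrix, columns R, RL, G, Ga, Gbg, Gd, C24m, C42, C42a, B1m, Cla4a),
#'   \code{C24c}, \code{B1c}, and \code{time}.
#' @export
membraneState <- function(params, geometry) {
  N <- geometry$N
  f <- matrix(0, N, length(.polar_fields),
              dimnames = list(NULL, .polar_fields))
  f[, "R"]   <- params$Rt / geometry$SA
  f[, "G"]   <- params$Gt / geometry$SA
  f[, "C42"] <- params$C42t / geometry$SA
  structure(list(fields = f, C24c = params$C24t / geometry$V,
                 B1c = params$B1t / geometry$V, time = 0),
            class = "membraneState")
}

#' Nonlocal coefficients of the polarization model
#'
#' The coupling coefficients that make the model nonlocal: the normalized
#' free-G-beta-gamma Hill switch \eqn{Gbgn^* = 1/(1 + (\delta\,Gbgn)^{-q})}
#' with \eqn{Gbgn = Gbg/[G]_0} and \eqn{\delta = SA/\int Gbgn\,ds}; the
#' Bem1 positive-feedback coefficient \eqn{B1^* = B1t^*/(1 +
#' (\gamma\,Gbgn^* [B1m])^{-h})} with \eqn{B1t^* = \int B1m\,ds/SA} and
#' \eqn{\gamma = SA/(2\int B1m\,ds)}; the membrane mean of active Cdc42
#' \eqn{C42at^* = \int C42a\,ds/SA}; and the receptor-synthesis bias
#' \eqn{p_s = C42a/C42at^*} (1 everywhere when \eqn{C42at^* = 0}).
#' Vanishing integrals are handled by the Hill-function limit (the switch
#' outputs 0 as its argument tends to 0 with positive exponent); Hill
#' arguments are clamped below at 1e-12 before exponentiation.
#'
#' @param state a \code{membraneState} (or an N x 11 field matrix).
#' @param params a \code{polarizationParams}.
#' @param geometry a \code{circleGeometry}.
#' @return list with fields \code{Gbgn}, \code{Gbgn_star}, \code{delta},
#'   \code{B1star}, \code{B1t_star}, \code{gamma}, \code{C42at_star},
#'   \code{ps}.
#' @export
nonlocalCoeffs <- function(state, params, geometry) {
  f <- if (inherits(state, "membraneState")) state$fields else state
  ds <- geometry$ds; SA <- geometry$SA
  G0 <- params$Gt / SA
  Gbgn <- f[, "Gbg"] / G0
  IG <- sum(Gbgn) * ds
  if (IG > 0) {
    delta <- SA / IG
    Gbgn_star <- .hill_up(delta * Gbgn, params$q)
  } else {
    delta <- NA_real_
    Gbgn_star <- rep(0, nrow(f))
  }
  IB <- sum(f[, "B1m"]) * ds
  B1t_star <- IB / SA
  if (IB > 0) {
    gamma <- SA / (2 * IB)
    B1star <- B1t_star * .hill_up(gamma * Gbgn_star * f[, "B1m"], params$h)
  } else {
    gamma <- NA_real_
    B1star <- rep(0, nrow(f))
  }
  C42at_star <- sum(f[, "C42a"]) * ds / SA
  ps <- if (C42at_star > 0) f[, "C42a"] / C42at_star else rep(1, nrow(f))
  list(Gbgn = Gbgn, Gbgn_star = Gbgn_star, delta = delta,
       B1star = B1star, B1t_star = B1t_star, gamma = gamma,
       C42at_star = C42at_star, ps = ps)
}

## increasing Hill switch u -> 1/(1 + u^-q), evaluated stably
.hill_up <- function(u, q) {
  u <- pmax(u, 1e-12)
  t <- -q * log(u)
  out <- ifelse(t > 700, 0, 1 / (1 + exp(t)))
  pmin(pmax(out, 0), 1)
}

.params_vector <- function(params) {
  t3names <- .polarization_table3()$name
  unlist(params[t3names])
}

#' Advance the polarization model
#'
#' \code{polarizationStep} advances one time step;
#' \code{simulatePolarization} runs to steady state (default \eqn{t = 1000}
#' s).  The scheme is Crank-Nicolson in the diffusion terms (second-order
#' periodic finite differences in space) with reactions handled
#' semi-implicitly: each field's linear decay coefficient is treated
#' implicitly with coefficients frozen at the step start, productions and
#' nonlocal coefficients explicitly, followed by one trapezoidal
#' fixed-point correction, giving second-order accuracy overall.  The
#' activated-Cla4 field has no diffusion term.  Cytoplasmic Cdc24 and Bem1
#' are recovered from their conservation constraints after each membrane
#' update, so the totals are conserved by construction.
#'
#' @param state a \code{membraneState}.
#' @param params a \code{polarizationParams}.
#' @param geometry a \code{circleGeometry}.
#' @param ligand ligand field (vector of length N), e.g.
#'   \code{\link{ligandProfile}}.
#' @param dt time step, s (default 0.05).
#' @return \code{polarizationStep}: the advanced \code{membraneState}.
#' @export
polarizationStep <- function(state, params, geometry, ligand, dt = 0.05) {
  stopifnot(dt > 0)
  res <- polar_simulate_cpp(state$fields, ligand, .params_vector(params),
                            geometry$radius, dt, 1L, 0L)
  .membrane_from_cpp(res, state$time + dt, params, geometry)
}

.membrane_from_cpp <- function(res, time, params, geometry) {
  f <- res$fields
  colnames(f) <- .polar_fields
  structure(list(fields = f,
                 C24c = (params$C24t - sum(f[, "C24m"]) * geometry$ds) / geometry$V,
                 B1c = (params$B1t - sum(f[, "B1m"]) * geometry$ds) / geometry$V,
                 time = time,
                 diagnostics = res$diagnostics),
            class = "membraneState")
}

#' @rdname polarizationStep
#' @param t_end final time, s (default 1000, by which the model is at
#'   steady state for baseline-range parameters).
#' @param warn_range warn when parameters fall outside the baseline ranges.
#' @return \code{simulatePolarization}: the final \code{membraneState};
#'   its \code{diagnostics} element reports \code{rel_change_10s} (relative
#'   state change over the final 10 s, a steady-state check),
#'   \code{min_field} and \code{min_pool}.
#' @export
simulatePolarization <- function(params, geometry, ligand = NULL,
                                 t_end = 1000, dt = 0.05,
                                 warn_range = TRUE) {
  if (is.null(ligand)) ligand <- ligandProfile(geometry)
  stopifnot(length(ligand) == geometry$N, dt > 0, t_end > 0)
  if (warn_range) {
    t3 <- .polarization_table3(geometry)
    v <- .params_vector(params)
    out <- v < t3$lo * (1 - 1e-9) | v > t3$hi * (1 + 1e-9)
    if (any(out))
      warning("parameter(s) outside baseline range: ",
              paste(t3$name[out], collapse = ", "))
  }
  nsteps <- ceiling(t_end / dt)
  win <- min(nsteps, ceiling(10 / dt))
  res <- polar_simulate_cpp(membraneState(params, geometry)$fields, ligand,
                            .params_vector(params), geometry$radius, dt,
                            as.integer(nsteps), as.integer(win))
  .membrane_from_cpp(res, nsteps * dt, params, geometry)
}

#' @export
print.membraneState <- function(x, ...) {
  cat("Membrane state at t =", x$time, "s;",
      nrow(x$fields), "mesh points\n")
  cat("  max C42a:", signif(max(x$fields[, "C42a"]), 4),
      " PF(C42a):",
      signif(tryCatch(polarizationFactor(x$fields[, "C42a"],
                                         attr(x, "geometry") %||%
                                           circleGeometry(N = nrow(x$fields))),
                      error = function(e) NA), 3), "\n")
  invisible(x)
}

#' Polarization factor of a membrane field
#'
#' \eqn{PF = 1 - 2 S_p/SA}, where \eqn{S_p} is the arc length of the
#' smallest contiguous arc around the field's maximum whose integral equals
#' half of the field's total (fractional mesh cells by linear
#' interpolation).  0 for a uniform field, approaching 1 for a sharp spike.
#' Invariant under positive scaling and under rotation of the field.
#'
#' @param field nonnegative field values per mesh point (not all zero).
#' @param geometry a \code{circleGeometry}.
#' @return PF in \code{[0, 1)}.
#' @export
polarizationFactor <- function(field, geometry) {
  N <- geometry$N
  stopifnot(length(field) == N)
  if (any(field < 0)) stop("field must be nonnegative")
  tot <- sum(field) * geometry$ds
  if (tot <= 0) stop("polarization factor undefined for an all-zero field")
  half <- tot / 2
  i <- which.max(field)
  mass <- field[i] * geometry$ds
  if (mass >= half) {
    Sp <- half / field[i]
    return(1 - 2 * Sp / geometry$SA)
  }
  cells <- 1L
  l <- i; r <- i
  repeat {
    ln <- if (l == 1L) N else l - 1L
    rn <- if (r == N) 1L else r + 1L
    # grow towards the larger neighbour; ties go right (deterministic)
    if (field[ln] > field[rn]) { nxt <- ln; l <- ln } else { nxt <- rn; r <- rn }
    add <- field[nxt] * geometry$ds
    if (mass + add >= half) {
      frac <- if (add > 0) (half - mass) / add else 1
      Sp <- (cells + frac) * geometry$ds
      return(1 - 2 * Sp / geometry$SA)
    }
    mass <- mass + add
    cells <- cells + 1L
    if (cells >= N) return(0)
  }
}

#' Cut-off polarization response
#'
#' The response used for surrogate fitting and inference:
#' \eqn{z = PF \cdot (ax)^n / (1 + (ax)^n)} with \eqn{x} the maximum of the
#' active-Cdc42 field and \eqn{a = 2 SA/C42t}, so that \eqn{ax = 1} exactly
#' when the peak equals half the uniform initial Cdc42 concentration.  The
#' Hill penalty (exponent \code{n_exp} = 5) suppresses states whose PF is
#' high only because a negligible amount of Cdc42 is activated.
#'
#' @param PF polarization factor.
#' @param maxC42a peak active-Cdc42 concentration (>= 0).
#' @param params a \code{polarizationParams} (for \code{C42t}).
#' @param geometry a \code{circleGeometry} (for \code{SA}).
#' @param n_exp Hill exponent of the cut-off (default 5).
#' @return the penalized response \eqn{z \in [0, 1)}.
#' @export
cutoffResponse <- function(PF, maxC42a, params, geometry, n_exp = 5) {
  stopifnot(maxC42a >= 0)
  ax <- 2 * geometry$SA / params$C42t * maxC42a
  if (ax == 0) return(0)
  PF * ax^n_exp / (1 + ax^n_exp)
}

#' Steady-state cut-off response at a parameter set
#'
#' Convenience wrapper: simulate to steady state and return the cut-off
#' response \code{z}, the PF and the peak active Cdc42.
#' @inheritParams simulatePolarization
#' @return list with \code{z}, \code{PF}, \code{maxC42a}, \code{state}.
#' @export
polarizationResponse <- function(params, geometry = circleGeometry(),
                                 ligand = NULL, t_end = 1000, dt = 0.05,
                                 warn_range = FALSE) {
  st <- simulatePolarization(params, geometry, ligand, t_end, dt,
                             warn_range = warn_range)
  c42a <- st$fields[, "C42a"]
  PF <- if (max(c42a) > 0) polarizationFactor(c42a, geometry) else 0
  list(z = cutoffResponse(PF, max(c42a), params, geometry),
       PF = PF, maxC42a = max(c42a), state = st)
}

#' Read / write membrane states as CSV
#'
#' Columns: \code{alpha_rad}, then one column per field.
#' @param state a \code{membraneState}; \code{geometry} its geometry.
#' @param path file path.
#' @export
writeMembraneState <- function(state, geometry, path) {
  df <- data.frame(alpha_rad = geometry$alpha, state$fields)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMembraneState
#' @return \code{readMembraneState}: data frame with \code{alpha_rad} and
#'   the field columns.
#' @export
readMembraneState <- function(path) utils::read.csv(path)

#' Plot the polarization profile
#'
#' Active Cdc42 against the recentred angle on \eqn{[-\pi, \pi]}, with the
#' pole facing the pheromone source at 0.
#' @param state a \code{membraneState}.
#' @param geometry a \code{circleGeometry}.
#' @param ... passed to \code{plot}.
#' @export
plotPolarizationProfile <- function(state, geometry, ...) {
  phi <- ((geometry$alpha - pi + pi) %% (2 * pi)) - pi
  o <- order(phi)
  graphics::plot(phi[o], state$fields[o, "C42a"], type = "l",
                 xlab = expression(alpha - pi ~ "(rad)"),
                 ylab = expression("[C42a] (molecules/" * mu * m^2 * ")"),
                 ...)
  invisible(state)
}
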