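#' Heterotrimeric G-protein cycle model
#'
#' An ODE model of the first stage of the yeast pheromone response: ligand
#' \eqn{L} (alpha-factor, nM) binds receptor \eqn{R} to form \eqn{RL}, which
#' activates heterotrimeric G-protein \eqn{G} into active \eqn{G\alpha}
#' (\eqn{Ga}) plus free \eqn{G\beta\gamma} (\eqn{Gbg}); deactivated
#' \eqn{G\alpha} (\eqn{Gd}) reassociates with \eqn{Gbg} to reform \eqn{G}.
#' Species are in molecules/cell, time in seconds.  The two derived species
#' are algebraic: \eqn{Gd = Gt - G - Ga} and \eqn{Gbg = Gt - G}.  The model
#' output is the free-\eqn{G\beta\gamma} fraction \eqn{Gbg/Gt}.
#'
#' \code{gproteinBaseline()} returns the baseline whole-cell parameter set
#' (literature estimates): \code{kRL} = 2e-3 /nM/s, \code{kRLm} = 1e-2 /s,
#' \code{kRs} = 4 molecules/s, \code{kRd0} = \code{kRd1} = 4e-4 /s,
#' \code{kGa} = 1e-5 /(molecules/cell)/s, \code{kGd} = 0.1 /s,
#' \code{kG1} = 1 /(molecules/cell)/s, \code{Gt} = 1e4 molecules/cell.
#'
#' @param ... named parameter overrides of the baseline values.
#' @return \code{gproteinParams}: a named list of the nine parameters.
#' @export
gproteinParams <- function(...) {
  p <- gproteinBaseline()
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  if (any(unlist(p) < 0) || p$Gt <= 0) stop("rates must be >= 0 and Gt > 0")
  structure(p, class = "gproteinParams")
}

#' @rdname gproteinParams
#' @export
gproteinBaseline <- function() {
  list(kRL = 2e-3, kRLm = 1e-2, kRs = 4, kRd0 = 4e-4, kRd1 = 4e-4,
       kGa = 1e-5, kGd = 0.1, kG1 = 1, Gt = 1e4)
}

#' Published point estimates for (kGa, kGd)
#'
#' \code{gproteinOptEstimate()} is the maximum-likelihood estimate
#' \eqn{(10^{-5}, 1.1\times 10^{-1})} from the original model study;
#' \code{gproteinModeEstimate()} is the posterior-mode estimate
#' \eqn{(7.1\times 10^{-6}, 9.0\times 10^{-2})} obtained by surrogate-based
#' MCMC.  Units: (molecules/cell)^-1 s^-1 and s^-1.
#' @return named numeric vector \code{c(kGa, kGd)}.
#' @export
gproteinOptEstimate <- function() c(kGa = 1e-5, kGd = 1.1e-1)

#' @rdname gproteinOptEstimate
#' @export
gproteinModeEstimate <- function() c(kGa = 7.1e-6, kGd = 9.0e-2)

#' Right-hand side of the G-protein ODEs
#'
#' Pure function returning d(R, RL, G, Ga)/dt with the algebraic species
#' substituted.
#' @param state named numeric vector \code{c(R, RL, G, Ga)} (molecules/cell).
#' @param params a \code{gproteinParams}.
#' @param L ligand concentration, nM.
#' @return named numeric vector of the four time derivatives.
#' @export
gproteinRHS <- function(state, params, L) {
  with(c(as.list(state), unclass(params)), {
    Gd  <- Gt - G - Ga
    Gbg <- Gt - G
    c(R  = -kRL * L * R + kRLm * RL - kRd0 * R + kRs,
      RL =  kRL * L * R - kRLm * RL - kRd1 * RL,
      G  = -kGa * RL * G + kG1 * Gd * Gbg,
      Ga =  kGa * RL * G - kGd * Ga)
  })
}

#' Initial condition: the pre-stimulus steady state
#'
#' With no ligand the receptor settles at \eqn{R = kRs/kRd0} and the
#' G-protein pool is fully assembled (\eqn{G = Gt}), so the response
#' \eqn{Gbg/Gt} is exactly 0 at \eqn{t = 0}.
#' @param params a \code{gproteinParams}.
#' @return named state vector \code{c(R, RL, G, Ga)}.
#' @export
gproteinInitialState <- function(params) {
  c(R = params$kRs / params$kRd0, RL = 0, G = params$Gt, Ga = 0)
}

#' Simulate the G-protein model
#'
#' Solves the four ODEs with a stiff-capable integrator (\code{deSolve::lsoda},
#' rtol 1e-8 / atol 1e-10) from the pre-stimulus steady state.
#'
#' @param params a \code{gproteinParams}.
#' @param L ligand dose, nM (constant in time).
#' @param times increasing time grid starting at 0, seconds.
#' @param rtol,atol solver tolerances.
#' @return data frame with columns \code{time, R, RL, G, Ga, Gbg_frac}.
#' @export
gproteinSimulate <- function(params, L, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(times[1] == 0, !is.unsorted(times))
  deriv <- function(t, y, parms) list(gproteinRHS(y, params, L))
  out <- deSolve::lsoda(gproteinInitialState(params), times, deriv,
                        parms = NULL, rtol = rtol, atol = atol)
  if (!is.null(attr(out, "istate")) && attr(out, "istate")[1] < 0)
    stop("ODE integration failed: istate = ", attr(out, "istate")[1])
  out <- as.data.frame(out)
  out$Gbg_frac <- (params$Gt - out$G) / params$Gt
  out
}

#' The standard observation grid
#'
#' The fifteen (ligand, time) observation points used throughout: a
#' time-course at \eqn{L = 1000} nM (\eqn{T} = 10, 30, 60, 120, 210, 300,
#' 450, 600 s) and a dose-response at \eqn{T = 60} s
#' (\eqn{L} = 1, 2, 5, 10, 20, 50, 100 nM).
#' @return data frame with columns \code{L_nM}, \code{T_s}.
#' @export
gproteinObsGrid <- function() {
  data.frame(
    L_nM = c(rep(1000, 8), 1, 2, 5, 10, 20, 50, 100),
    T_s  = c(10, 30, 60, 120, 210, 300, 450, 600, rep(60, 7)))
}

#' Response vector of free G-beta-gamma fractions
#'
#' One \eqn{Gbg/Gt} fraction per observation point.  Points sharing a ligand
#' dose share a single integration (the whole time-course at \eqn{L = 1000}
#' nM is one solve); each remaining dose is integrated to its observation
#' time.
#'
#' @param params a \code{gproteinParams}.
#' @param obs data frame with columns \code{L_nM}, \code{T_s} (e.g.
#'   \code{\link{gproteinObsGrid}} or an observation dataset).
#' @return numeric vector of fractions in \code{[0, 1]}, one per row of
#'   \code{obs}.
#' @export
gproteinResponse <- function(params, obs) {
  stopifnot(nrow(obs) >= 1)
  out <- numeric(nrow(obs))
  for (L in unique(obs$L_nM)) {
    i <- which(obs$L_nM == L)
    tt <- sort(unique(obs$T_s[i]))
    sim <- gproteinSimulate(params, L, times = union(0, tt))
    out[i] <- sim$Gbg_frac[match(obs$T_s[i], sim$time)]
  }
  out
}

#' Mean squared error of a response against observed means
#'
#' @param response numeric vector of model (or surrogate) responses.
#' @param data observation data frame with a \code{mean} column, same length.
#' @return mean over points of \code{(response - mean)^2}.
#' @export
responseMSE <- function(response, data) {
  if (length(response) != nrow(data))
    stop("response length (", length(response),
         ") does not match data rows (", nrow(data), ")")
  mean((response - data$mean)^2)
}

#' Read / write observation datasets
#'
#' CSV with columns \code{L_nM, T_s, mean, sd}; comment lines beginning with
#' \code{#} (used to record generating seeds) are preserved on write.
#' @param path file path.
#' @return \code{readObservations}: data frame of observation points.
#' @export
readObservations <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = "numeric")
  stopifnot(all(c("L_nM", "T_s", "mean", "sd") %in% names(df)))
  if (any(df$sd <= 0)) stop("observation sd must be > 0")
  df
}

#' @rdname readObservations
#' @param data observation data frame.
#' @param comment optional character vector written as leading # lines.
#' @export
writeObservations <- function(data, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  # full double precision so generated datasets round-trip bit-identically
  fmt <- data.frame(L_nM = data$L_nM, T_s = data$T_s,
                    mean = sprintf("%.17g", data$mean),
                    sd = sprintf("%.17g", data$sd))
  utils::write.csv(fmt, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled synthetic observation dataset
#'
#' The stand-in for the experimental free-G-beta-gamma measurements: model
#' responses at the published maximum-likelihood estimate
#' (\code{\link{gproteinOptEstimate}}) on the standard 15-point grid with
#' Gaussian noise added at the RMS residual scale of the published best fit
#' (sd \code{sqrt(1.3e-4)}), clipped to [0, 1].  It is synthetic - the
#' real measurements are only available as supplementary material of the
#' original experimental study - and is regenerated bit-identically by
#' \code{\link{generateGproteinData}} with seed 20181.
#' @return observation data frame with columns \code{L_nM, T_s, mean, sd}.
#' @export
gproteinSyntheticData <- function() {
  readObservations(system.file("extdata", "gprotein_obs_synthetic.csv",
                               package = "gpcyeast", mustWork = TRUE))
}
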