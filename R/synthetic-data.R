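#' Generate a synthetic G-protein observation dataset
#'
#' Stand-in for the experimental free-G-beta-gamma measurements: the model
#' response at a chosen generating parameter set on an observation grid,
#' plus i.i.d. Gaussian noise clipped to \code{[0, 1]}.  The reported
#' \code{sd} column carries the generating noise level, so the dataset
#' plugs directly into the Gaussian likelihood.  Fully determined by
#' (arguments, seed).
#'
#' @param params generating \code{gproteinParams} (default: baseline with
#'   the published maximum-likelihood \code{(kGa, kGd)}).
#' @param obs_grid data frame of \code{L_nM}, \code{T_s} observation points
#'   (default \code{\link{gproteinObsGrid}}).
#' @param noise_sd Gaussian noise standard deviation (scalar or per point).
#'   The default, \code{sqrt(1.3e-4)} (about 0.011), is the RMS residual of
#'   the published maximum-likelihood fit to the experimental dataset, i.e.
#'   the residual scale the real measurements exhibit around the model.
#' @param seed integer seed.
#' @return observation data frame with columns \code{L_nM, T_s, mean, sd}
#'   and attribute \code{truth} (the noiseless responses).
#' @export
generateGproteinData <- function(params = NULL, obs_grid = gproteinObsGrid(),
                                 noise_sd = sqrt(1.3e-4), seed = 1) {
  stopifnot(all(noise_sd > 0))
  if (is.null(params)) {
    opt <- gproteinOptEstimate()
    params <- gproteinParams(kGa = opt[["kGa"]], kGd = opt[["kGd"]])
  }
  resp <- gproteinResponse(params, obs_grid)
  set.seed(seed)
  noise_sd <- rep_len(noise_sd, length(resp))
  means <- pmin(pmax(resp + stats::rnorm(length(resp), 0, noise_sd), 0), 1)
  out <- data.frame(L_nM = obs_grid$L_nM, T_s = obs_grid$T_s,
                    mean = means, sd = noise_sd)
  attr(out, "truth") <- resp
  out
}

#' Generate a synthetic membrane polarization profile
#'
#' A von-Mises-shaped field on the circular mesh,
#' \eqn{f(\alpha) \propto e^{\kappa\cos(\alpha - center)}}, scaled so its
#' integral over the membrane equals \code{total}.  \eqn{\kappa = 0} gives
#' a uniform field (PF = 0); PF grows monotonically with \eqn{\kappa}.
#' The von Mises family is the natural unimodal density on the circle; the
#' generator is deterministic given its arguments.
#'
#' @param geometry a \code{\link{circleGeometry}}.
#' @param kappa sharpness parameter (>= 0).
#' @param total total amount of the species on the membrane (molecules).
#' @param center peak angle (default \eqn{\pi}, the pole facing the
#'   pheromone source).
#' @return numeric field over the mesh points.
#' @export
generatePolarizationProfile <- function(geometry, kappa, total = 1e4,
                                        center = pi) {
  stopifnot(kappa >= 0, total > 0)
  f <- exp(kappa * (cos(geometry$alpha - center) - 1))
  f * total / (sum(f) * geometry$ds)
}

#' Build a sample set by running the G-protein model
#'
#' Uniform cube samples of \code{space} are mapped to natural units (other
#' parameters fixed at the baseline) and the 15-point response vector
#' computed per sample.
#'
#' @param space a \code{parameterSpace} over G-protein parameter names.
#' @param count number of samples.
#' @param seed integer seed for the cube sampling.
#' @param obs_grid observation grid defining the response columns.
#' @return list with \code{Y} (cube samples), \code{Z} (responses, one
#'   column per observation point), \code{seed}.
#' @export
makeGproteinSampleSet <- function(space, count, seed = 1,
                                  obs_grid = gproteinObsGrid()) {
  Y <- sampleUniform(space, count, seed = seed)
  Z <- matrix(NA_real_, count, nrow(obs_grid))
  colnames(Z) <- paste0("L", obs_grid$L_nM, "_T", obs_grid$T_s)
  for (i in seq_len(count)) {
    nat <- fromCube(stats::setNames(Y[i, ], space$name), space)
    params <- do.call(gproteinParams, as.list(nat))
    Z[i, ] <- gproteinResponse(params, obs_grid)
  }
  list(Y = Y, Z = Z, seed = seed)
}

#' Build a sample set by running the polarization model
#'
#' Uniform cube samples of \code{space} (typically the screened
#' 15-parameter subspace) are mapped to full parameter sets and the
#' steady-state cut-off response \eqn{z} computed for each.  When
#' \code{path} is given, finished samples are appended to the CSV after
#' each run, so an interrupted job restarts where it left off and
#' reproduces the identical set (the cube samples are drawn up front from
#' the seed).  Per-sample simulation failures are recorded with
#' \code{ok = 0} and \code{z = NA} rather than dropped.
#'
#' @param space a \code{parameterSpace} over polarization parameter names.
#' @param count number of samples.
#' @param seed integer seed.
#' @param geometry mesh; coarser meshes make large sample sets cheap.
#' @param t_end,dt integration horizon and step for each sample.
#' @param path optional CSV path for incremental persistence.
#' @return list with \code{Y}, \code{Z} (columns \code{z}, \code{PF},
#'   \code{maxC42a}, \code{ok}), \code{seed}.
#' @export
makePdeSampleSet <- function(space, count, seed = 1,
                             geometry = circleGeometry(),
                             t_end = 1000, dt = 0.05, path = NULL) {
  stopifnot(count >= 1)
  Y <- sampleUniform(space, count, seed = seed)
  ligand <- ligandProfile(geometry)
  Z <- matrix(NA_real_, count, 4,
              dimnames = list(NULL, c("z", "PF", "maxC42a", "ok")))
  start <- 1L
  if (!is.null(path) && file.exists(path)) {
    prev <- readSampleSet(path)
    done <- nrow(prev$Y)
    if (done > 0) {
      if (!isTRUE(all.equal(prev$Y, Y[seq_len(done), , drop = FALSE],
                            check.attributes = FALSE)))
        stop("existing sample file does not match this space/seed")
      Z[seq_len(done), ] <- prev$Z
      start <- done + 1L
    }
  }
  for (i in seq(start, length.out = count - start + 1L)) {
    params <- polarizationParamsFromCube(Y[i, ], space, geometry)
    res <- tryCatch(
      polarizationResponse(params, geometry, ligand, t_end, dt),
      error = function(e) {
        warning("sample ", i, " failed: ", conditionMessage(e))
        NULL
      })
    Z[i, ] <- if (is.null(res)) c(NA, NA, NA, 0) else
      c(res$z, res$PF, res$maxC42a, 1)
    if (!is.null(path))
      writeSampleSet(Y[seq_len(i), , drop = FALSE],
                     Z[seq_len(i), , drop = FALSE], path, seed = seed)
  }
  list(Y = Y, Z = Z, seed = seed)
}
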