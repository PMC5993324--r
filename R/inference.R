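#' MCMC configuration
#'
#' @param chain_length total number of Metropolis-Hastings steps.
#' @param burn_in steps discarded from the front (\code{< chain_length}).
#' @param proposal_sd Gaussian random-walk proposal standard deviation, in
#'   cube units; scalar or per-dimension vector.
#' @param seed integer seed.
#' @param n_chains number of independent chains (for convergence checks).
#' @param thin keep every \code{thin}-th post-burn-in sample.
#' @return list of class \code{"mcmcConfig"}.
#' @export
mcmcConfig <- function(chain_length = 1e6, burn_in = 1e5, proposal_sd = 0.1,
                       seed = 1, n_chains = 1, thin = 1) {
  stopifnot(burn_in < chain_length, all(proposal_sd > 0), thin >= 1)
  structure(list(chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in),
                 proposal_sd = proposal_sd, seed = as.integer(seed),
                 n_chains = as.integer(n_chains), thin = as.integer(thin)),
            class = "mcmcConfig")
}

#' Gaussian log-likelihood of surrogate responses against observed data
#'
#' Independent Gaussian errors per observation with the dataset's reported
#' standard deviations:
#' \eqn{\log L(y) = -\sum_i (\hat s_i(y) - mean_i)^2 / (2 sd_i^2)} up to an
#' additive constant, where \eqn{\hat s_i} is the surrogate for the
#' \eqn{i}-th response.  Outside the cube (the uniform prior's support) the
#' value is \code{-Inf}.
#'
#' @param y cube coordinate vector.
#' @param data data frame with \code{mean} and \code{sd} columns, one row
#'   per surrogate response.
#' @param surrogate multi-response \code{gpcSurrogate} with one response per
#'   data row.
#' @return scalar log-likelihood.
#' @export
logLikelihood <- function(y, data, surrogate) {
  if (nrow(data) != ncol(surrogate$coeffs))
    stop("need one surrogate response per data point")
  if (any(data$sd <= 0)) stop("observation sd must be > 0")
  if (any(abs(y) > 1)) return(-Inf)
  s <- evaluateSurrogate(surrogate, y)
  -sum((s - data$mean)^2 / (2 * data$sd^2))
}

#' Bundle a surrogate and a dataset into a fast likelihood target
#'
#' The returned object is accepted by \code{\link{mhChain}} and evaluated in
#' compiled code, which makes \eqn{10^6}-step chains take seconds.
#'
#' When the surrogate's own approximation error is comparable to the
#' measurement noise, a likelihood built on the data sd alone is
#' over-confident and the posterior undercovers.  \code{model_sd} (scalar or
#' per response, e.g. the cross-validated error sd of the fit) is added to
#' the data sd in quadrature to account for emulator error.
#' @inheritParams logLikelihood
#' @param model_sd optional surrogate-error standard deviation folded into
#'   the observation sds (default 0: data sd only).
#' @return object of class \code{"surrogateLikelihood"}.
#' @export
surrogateLikelihood <- function(surrogate, data, model_sd = 0) {
  if (nrow(data) != ncol(surrogate$coeffs))
    stop("need one surrogate response per data point")
  if (any(data$sd <= 0)) stop("observation sd must be > 0")
  data$sd <- sqrt(data$sd^2 + rep_len(model_sd, nrow(data))^2)
  structure(list(surrogate = surrogate, data = data),
            class = "surrogateLikelihood")
}

#' Metropolis-Hastings sampling of the posterior
#'
#' Gaussian random-walk proposals in cube coordinates; proposals outside the
#' cube are rejected through the uniform prior (zero density outside, which
#' is exact, rather than reflecting).  The burn-in period is discarded and
#' the remainder optionally thinned.  Aborts with a diagnostic if no
#' proposal is accepted over \eqn{10^4} consecutive steps.
#'
#' @param config an \code{\link{mcmcConfig}}.
#' @param likelihood either a \code{\link{surrogateLikelihood}} (fast
#'   compiled path) or an R function \code{function(y) log-likelihood}.
#' @param space the \code{parameterSpace} (defines dimension and the map
#'   back to natural units).
#' @param init optional starting cube point; default drawn uniformly.
#' @return object of class \code{"mcmcChain"}: list with \code{samples}
#'   (kept steps x n, cube coordinates), \code{log_post},
#'   \code{acceptance_rate}, \code{seed}, \code{space}.
#' @export
mhChain <- function(config, likelihood, space, init = NULL) {
  n <- spaceDim(space)
  prop_sd <- rep_len(config$proposal_sd, n)
  set.seed(config$seed)
  y <- if (is.null(init)) stats::runif(n, -1, 1) else as.numeric(init)
  stopifnot(length(y) == n, all(abs(y) <= 1))
  if (inherits(likelihood, "surrogateLikelihood")) {
    sur <- likelihood$surrogate
    res <- mh_chain_cpp(y, sur$basis, sur$coeffs,
                        likelihood$data$mean, likelihood$data$sd,
                        prop_sd, config$chain_length, config$burn_in,
                        config$thin)
  } else {
    res <- .mh_chain_r(y, likelihood, prop_sd, config$chain_length,
                       config$burn_in, config$thin)
  }
  colnames(res$samples) <- space$name
  structure(list(samples = res$samples, log_post = drop(res$log_post),
                 acceptance_rate = res$acceptance_rate,
                 seed = config$seed, space = space),
            class = "mcmcChain")
}

.mh_chain_r <- function(y, loglik, prop_sd, steps, burn, thin) {
  n <- length(y)
  lp <- loglik(y)
  keep <- floor((steps - burn) / thin)
  samples <- matrix(NA_real_, keep, n)
  log_post <- numeric(keep)
  acc <- 0L; since_acc <- 0L; k <- 0L
  for (i in seq_len(steps)) {
    prop <- y + stats::rnorm(n, 0, prop_sd)
    lp_prop <- if (any(abs(prop) > 1)) -Inf else loglik(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
      y <- prop; lp <- lp_prop; acc <- acc + 1L; since_acc <- 0L
    } else {
      since_acc <- since_acc + 1L
      if (since_acc >= 10000L)
        stop("MCMC stalled: no acceptance over 10000 consecutive steps ",
             "(acceptance so far ", signif(acc / i, 3),
             "); reduce proposal_sd")
    }
    if (i > burn && (i - burn) %% thin == 0L && k < keep) {
      k <- k + 1L
      samples[k, ] <- y
      log_post[k] <- lp
    }
  }
  list(samples = samples[seq_len(k), , drop = FALSE],
       log_post = log_post[seq_len(k)], acceptance_rate = acc / steps)
}

#' @export
print.mcmcChain <- function(x, ...) {
  cat("MCMC chain:", nrow(x$samples), "retained samples in",
      ncol(x$samples), "dimension(s);",
      sprintf("acceptance %.1f%%", 100 * x$acceptance_rate), "\n")
  invisible(x)
}

#' Tune the proposal standard deviation
#'
#' Short pre-runs scale a common proposal width by bisection until the
#' acceptance rate lands in \code{target} (default 20-40\%); the tuned value
#' is then fixed for the production chain.
#' @param likelihood as in \code{\link{mhChain}}.
#' @param space parameter space.
#' @param target acceptable acceptance-rate window.
#' @param pilot_steps length of each pilot run.
#' @param seed seed for the pilots.
#' @param init optional starting cube point for the pilots (see
#'   \code{\link{startFromScan}}).
#' @return scalar proposal sd.
#' @export
tuneProposalSD <- function(likelihood, space, target = c(0.2, 0.4),
                           pilot_steps = 20000, seed = 1, init = NULL) {
  sd_try <- 0.2
  for (i in 1:12) {
    cfg <- mcmcConfig(chain_length = pilot_steps,
                      burn_in = floor(pilot_steps / 4),
                      proposal_sd = sd_try, seed = seed)
    acc <- tryCatch(mhChain(cfg, likelihood, space, init = init)$acceptance_rate,
                    error = function(e) 0)
    if (acc >= target[1] && acc <= target[2]) break
    sd_try <- if (acc > target[2]) sd_try * 2 else sd_try / 2
  }
  sd_try
}

#' Pick a chain starting point by a coarse likelihood scan
#'
#' Evaluates the surrogate likelihood on uniform cube samples and returns
#' the best point - a cheap way to start chains inside the high-probability
#' region instead of a random prior draw, which matters when the likelihood
#' concentrates on a thin ridge of the cube.
#' @param likelihood a \code{\link{surrogateLikelihood}}.
#' @param count number of scan points.
#' @param seed integer seed.
#' @return cube coordinate vector.
#' @export
startFromScan <- function(likelihood, count = 4000, seed = 1) {
  space <- likelihood$surrogate$space
  Y <- sampleUniform(space, count, seed = seed)
  Z <- evaluateSurrogate(likelihood$surrogate, Y)
  Z <- matrix(Z, nrow = count)
  ll <- -colSums((t(Z) - likelihood$data$mean)^2 /
                   (2 * likelihood$data$sd^2))
  Y[which.max(ll), ]
}

#' Multi-chain convergence diagnostic
#'
#' Compares per-parameter marginal distributions across independent chains:
#' a histogram total-variation distance (half the L1 distance between
#' normalized 50-bin histograms on \eqn{[-1,1]}) and the two-sample
#' Kolmogorov-Smirnov statistic.  The check passes when the largest
#' histogram distance over parameters and chain pairs is below \code{tol}.
#'
#' @param chains list of \code{mcmcChain}s over the same space.
#' @param tol pass/fail tolerance on the histogram distance.
#' @param bins number of histogram bins.
#' @return list with \code{hist_distance} and \code{ks_statistic} matrices
#'   (chain pair x parameter), \code{max_distance} and logical \code{passed}.
#' @export
convergenceCheck <- function(chains, tol = 0.1, bins = 50) {
  stopifnot(length(chains) >= 2)
  n <- ncol(chains[[1]]$samples)
  for (ch in chains) if (ncol(ch$samples) != n)
    stop("chains have unequal parameter dimension")
  breaks <- seq(-1, 1, length.out = bins + 1)
  pairs <- utils::combn(length(chains), 2)
  hd <- ks <- matrix(0, ncol(pairs), n)
  for (p in seq_len(ncol(pairs))) {
    a <- chains[[pairs[1, p]]]$samples
    b <- chains[[pairs[2, p]]]$samples
    for (j in seq_len(n)) {
      ha <- hist(a[, j], breaks = breaks, plot = FALSE)$counts / nrow(a)
      hb <- hist(b[, j], breaks = breaks, plot = FALSE)$counts / nrow(b)
      hd[p, j] <- sum(abs(ha - hb)) / 2
      xs <- sort(unique(c(a[, j], b[, j])))
      ks[p, j] <- max(abs(stats::ecdf(a[, j])(xs) - stats::ecdf(b[, j])(xs)))
    }
  }
  colnames(hd) <- colnames(ks) <- colnames(chains[[1]]$samples)
  list(hist_distance = hd, ks_statistic = ks,
       max_distance = max(hd), passed = max(hd) < tol)
}

#' Posterior summary of an MCMC chain
#'
#' Marginal histograms (unit area) per parameter, the marginal mode from the
#' highest-density bin (bins are uniform in cube coordinates, hence
#' logarithmic in natural units for log-scaled parameters), the mean
#' parameter set (computed in cube coordinates, then mapped to natural
#' units), central credible intervals, and the pairwise correlation matrix
#' of the cube coordinates.
#'
#' @param chain an \code{mcmcChain}.
#' @param bins histogram bins per marginal (default 100).
#' @param level credible-interval level (default 0.95).
#' @return object of class \code{"posteriorSummary"}: list with
#'   \code{mode}, \code{mean} (natural units), \code{ci} (natural-unit
#'   matrix lo/hi), \code{correlation}, \code{histograms}.
#' @export
posteriorSummary <- function(chain, bins = 100, level = 0.95) {
  s <- chain$samples
  stopifnot(nrow(s) >= 1)
  space <- chain$space
  breaks <- seq(-1, 1, length.out = bins + 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  mode_cube <- numeric(ncol(s))
  hists <- vector("list", ncol(s))
  for (j in seq_len(ncol(s))) {
    h <- hist(pmin(pmax(s[, j], -1), 1), breaks = breaks, plot = FALSE)
    mode_cube[j] <- mids[which.max(h$counts)]
    hists[[j]] <- data.frame(mid = mids, density = h$density)
  }
  names(hists) <- space$name
  alpha <- (1 - level) / 2
  ci_cube <- apply(s, 2, stats::quantile, probs = c(alpha, 1 - alpha))
  degenerate <- nrow(s) == 1 || any(apply(s, 2, stats::sd) == 0)
  corr <- if (degenerate) diag(1, ncol(s)) else stats::cor(s)
  dimnames(corr) <- list(space$name, space$name)
  structure(list(
    mode = fromCube(stats::setNames(mode_cube, space$name), space),
    mean = fromCube(stats::setNames(colMeans(s), space$name), space),
    mode_cube = mode_cube, mean_cube = colMeans(s),
    ci = apply(ci_cube, 1, function(r) fromCube(stats::setNames(r, space$name), space)),
    correlation = corr, histograms = hists, level = level),
    class = "posteriorSummary")
}

#' @export
print.posteriorSummary <- function(x, ...) {
  cat("Posterior summary\n")
  df <- data.frame(mode = x$mode, mean = x$mean,
                   ci_lo = x$ci[, 1], ci_hi = x$ci[, 2])
  print(signif(df, 3))
  invisible(x)
}

#' Simulated annealing on the cube
#'
#' Minimizes \code{objective} over \eqn{[-1,1]^n} with Gaussian moves
#' clipped to the cube and a geometric cooling schedule; the best-so-far
#' point is tracked so the result is never worse than the start.
#'
#' @param objective function of a cube vector returning a scalar to
#'   minimize (typically a surrogate-based misfit).
#' @param start starting cube vector (e.g. the posterior mean).
#' @param schedule list with \code{t0} (initial temperature), \code{t_end}
#'   (final), \code{n_steps}, and \code{step_sd} (move sd, cube units).
#' @param seed integer seed.
#' @return list with \code{par} (best cube point), \code{value},
#'   \code{trace} (best objective per step), \code{accepted}.
#' @export
simulatedAnnealing <- function(objective, start,
                               schedule = list(t0 = 1, t_end = 1e-4,
                                               n_steps = 20000,
                                               step_sd = 0.05),
                               seed = 1) {
  set.seed(seed)
  y <- pmin(pmax(as.numeric(start), -1), 1)
  f <- objective(y)
  best <- y; fbest <- f
  nst <- schedule$n_steps
  cool <- (schedule$t_end / schedule$t0)^(1 / max(nst - 1, 1))
  temp <- schedule$t0
  trace <- numeric(nst); acc <- 0L
  for (i in seq_len(nst)) {
    prop <- pmin(pmax(y + stats::rnorm(length(y), 0, schedule$step_sd), -1), 1)
    fp <- objective(prop)
    if (fp < f || stats::runif(1) < exp(-(fp - f) / temp)) {
      y <- prop; f <- fp; acc <- acc + 1L
      if (f < fbest) { best <- y; fbest <- f }
    }
    trace[i] <- fbest
    temp <- temp * cool
  }
  list(par = best, value = fbest, trace = trace, accepted = acc / nst)
}

#' Write an MCMC chain and its sidecar
#'
#' CSV of retained steps in natural units plus the log-posterior column; a
#' JSON sidecar records the configuration and acceptance diagnostics.
#' @param chain an \code{mcmcChain}.
#' @param path CSV path; the sidecar is \code{paste0(path, ".json")}.
#' @export
writeChain <- function(chain, path) {
  nat <- fromCube(chain$samples, chain$space)
  df <- as.data.frame(nat)
  df$log_post <- chain$log_post
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(seed = chain$seed,
                            acceptance_rate = chain$acceptance_rate,
                            n_samples = nrow(chain$samples),
                            space = as.data.frame(unclass(chain$space))),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
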