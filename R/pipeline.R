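#' Run configurations and manifests
#'
#' Pipeline stages are wired by a JSON run configuration holding the model
#' (\code{"gprotein"} or \code{"polarization"}), the parameter-space file or
#' bundled space name, surrogate degree, sample count, fit method, CV folds,
#' MCMC settings, seed, and output directory.  Every stage writes a
#' manifest (configuration, seed, package version, input-file checksums) so
#' any output can be regenerated; reruns with the same manifest are
#' byte-identical.
#'
#' @param path JSON config path.
#' @return named list with the configuration.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path)
  if (is.null(cfg$seed)) cfg$seed <- 1
  if (is.null(cfg$outdir)) cfg$outdir <- "."
  cfg
}

.config_space <- function(cfg) {
  sp <- cfg$space
  if (is.null(sp)) stop("config has no 'space' entry")
  if (is.character(sp) && length(sp) == 1 && !file.exists(sp)) {
    bundled <- list(gprotein2 = gproteinSpace2,
                    gprotein8 = gproteinSpace8,
                    polarization35 = polarizationSpace35,
                    polarization15 = polarizationSpace15)
    if (sp %in% names(bundled)) return(bundled[[sp]]())
    stop("space file not found: ", sp)
  }
  if (is.character(sp)) readParameterSpace(sp) else
    parameterSpace(sp$name, sp$lo, sp$hi, sp$scale)
}

.need_file <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop("missing upstream ", what, " file: expected at '",
         if (is.null(path)) "<unset>" else path, "'")
  path
}

.write_manifest <- function(cfg, outdir, stage, outputs) {
  tf <- tempfile()
  jsonlite::write_json(cfg[order(names(cfg))], tf, auto_unbox = TRUE,
                       digits = NA)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  jsonlite::write_json(
    list(stage = stage, config = cfg, config_md5 = hash,
         seed = cfg$seed, outputs = outputs,
         package_version = as.character(utils::packageVersion("gpcyeast"))),
    file.path(outdir, paste0("manifest_", stage, ".json")),
    auto_unbox = TRUE, digits = NA)
  invisible(hash)
}

#' Pipeline stage commands
#'
#' Thin, file-to-file wrappers over the package functions, mirroring the
#' command-line verbs (\code{synth}, \code{sample}, \code{fit}, \code{cv},
#' \code{sensitivity}, \code{screen}, \code{mcmc}, \code{converge},
#' \code{summarize}, \code{anneal}).  Each reads its predecessor's files,
#' writes its own outputs under \code{cfg$outdir}, and records a manifest.
#'
#' @param cfg a run-configuration list (see \code{\link{readRunConfig}}).
#' @return the path(s) written, invisibly (or the report object where one
#'   exists).
#' @export
cmdSynth <- function(cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  data <- generateGproteinData(noise_sd = cfg$noise_sd %||% sqrt(1.3e-4),
                               seed = cfg$seed)
  out <- file.path(cfg$outdir, "observations.csv")
  writeObservations(data, out, comment = paste0("synthetic; seed=", cfg$seed))
  .write_manifest(cfg, cfg$outdir, "synth", out)
  invisible(out)
}

#' @rdname cmdSynth
#' @export
cmdSample <- function(cfg) {
  if (is.null(cfg$count) || cfg$count < 1)
    stop("config 'count' must be a positive sample count")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  space <- .config_space(cfg)
  out <- file.path(cfg$outdir, "samples.csv")
  if (identical(cfg$model, "polarization")) {
    geom <- circleGeometry(N = cfg$mesh_N %||% 400)
    ss <- makePdeSampleSet(space, cfg$count, seed = cfg$seed,
                           geometry = geom, t_end = cfg$t_end %||% 1000,
                           dt = cfg$dt %||% 0.05, path = out)
    n_fail <- sum(ss$Z[, "ok"] == 0)
    message("polarization sampling done: ", cfg$count, " samples, ",
            n_fail, " failure(s)")
  } else {
    ss <- makeGproteinSampleSet(space, cfg$count, seed = cfg$seed)
    writeSampleSet(ss$Y, ss$Z, out, seed = cfg$seed)
  }
  .write_manifest(cfg, cfg$outdir, "sample", out)
  invisible(out)
}

#' @rdname cmdSynth
#' @export
cmdFit <- function(cfg) {
  ss <- readSampleSet(.need_file(cfg$samples %||%
                                   file.path(cfg$outdir, "samples.csv"),
                                 "sample-set"))
  space <- .config_space(cfg)
  keep <- !apply(ss$Z, 1, anyNA)
  Z <- ss$Z[keep, setdiff(colnames(ss$Z), c("ok", "PF", "maxC42a")),
            drop = FALSE]
  sur <- fitSurrogate(ss$Y[keep, , drop = FALSE], Z, space,
                      degree = cfg$degree %||% 5,
                      method = cfg$method %||% "auto",
                      epsilon = cfg$epsilon)
  out <- file.path(cfg$outdir, "surrogate.json")
  writeSurrogate(sur, out)
  .write_manifest(cfg, cfg$outdir, "fit", out)
  invisible(out)
}

#' @rdname cmdSynth
#' @export
cmdCv <- function(cfg) {
  ss <- readSampleSet(.need_file(cfg$samples %||%
                                   file.path(cfg$outdir, "samples.csv"),
                                 "sample-set"))
  space <- .config_space(cfg)
  keep <- !apply(ss$Z, 1, anyNA)
  Z <- ss$Z[keep, setdiff(colnames(ss$Z), c("ok", "PF", "maxC42a")),
            drop = FALSE]
  rep <- crossValidate(ss$Y[keep, , drop = FALSE], Z, space,
                       degree = cfg$degree %||% 5, k = cfg$folds %||% 10,
                       method = cfg$method %||% "auto", seed = cfg$seed,
                       epsilon = cfg$epsilon)
  out <- file.path(cfg$outdir, "cv.json")
  jsonlite::write_json(list(mean_error = rep$mean_error,
                            sd_error = rep$sd_error,
                            mean_abs_error = rep$mean_abs_error,
                            folds = rep$folds, method = rep$method),
                       out, auto_unbox = TRUE, digits = NA)
  .write_manifest(cfg, cfg$outdir, "cv", out)
  invisible(rep)
}

#' @rdname cmdSynth
#' @export
cmdSensitivity <- function(cfg) {
  sur <- readSurrogate(.need_file(cfg$surrogate %||%
                                    file.path(cfg$outdir, "surrogate.json"),
                                  "surrogate"))
  rep <- sensitivityReport(sur, threshold = cfg$threshold %||% 0.01,
                           seed = cfg$seed)
  writeSensitivityReport(rep,
                         csv_path = file.path(cfg$outdir, "sensitivity.csv"),
                         json_path = file.path(cfg$outdir, "sensitivity.json"))
  .write_manifest(cfg, cfg$outdir, "sensitivity",
                  file.path(cfg$outdir, "sensitivity.json"))
  invisible(rep)
}

#' @rdname cmdSynth
#' @export
cmdScreen <- function(cfg) {
  rep <- cmdSensitivity(cfg)
  sur <- readSurrogate(.need_file(cfg$surrogate %||%
                                    file.path(cfg$outdir, "surrogate.json"),
                                  "surrogate"))
  space <- sur$space
  reduced <- space[space$name %in% rep$retained, , drop = FALSE]
  class(reduced) <- c("parameterSpace", "data.frame")
  out <- file.path(cfg$outdir, "space_screened.json")
  writeParameterSpace(reduced, out)
  .write_manifest(cfg, cfg$outdir, "screen", out)
  invisible(reduced)
}

#' @rdname cmdSynth
#' @export
cmdMcmc <- function(cfg) {
  sur <- readSurrogate(.need_file(cfg$surrogate %||%
                                    file.path(cfg$outdir, "surrogate.json"),
                                  "surrogate"))
  data <- readObservations(.need_file(cfg$data %||%
                                        file.path(cfg$outdir,
                                                  "observations.csv"),
                                      "observation"))
  lik <- surrogateLikelihood(sur, data)
  prop_sd <- cfg$proposal_sd %||%
    tuneProposalSD(lik, sur$space, seed = cfg$seed)
  n_chains <- cfg$n_chains %||% 1
  outs <- character(n_chains)
  for (c_i in seq_len(n_chains)) {
    conf <- mcmcConfig(chain_length = cfg$chain_length %||% 1e6,
                       burn_in = cfg$burn_in %||% 1e5,
                       proposal_sd = prop_sd,
                       seed = cfg$seed + c_i - 1,
                       thin = cfg$thin %||% 1)
    ch <- mhChain(conf, lik, sur$space)
    outs[c_i] <- file.path(cfg$outdir, sprintf("chain_%d.csv", c_i))
    writeChain(ch, outs[c_i])
  }
  .write_manifest(cfg, cfg$outdir, "mcmc", outs)
  invisible(outs)
}

.read_chain <- function(path) {
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  space <- parameterSpace(side$space$name, side$space$lo, side$space$hi,
                          side$space$scale)
  df <- utils::read.csv(path)
  nat <- as.matrix(df[, space$name, drop = FALSE])
  structure(list(samples = toCube(nat, space), log_post = df$log_post,
                 acceptance_rate = side$acceptance_rate, seed = side$seed,
                 space = space),
            class = "mcmcChain")
}

#' @rdname cmdSynth
#' @export
cmdConverge <- function(cfg) {
  files <- cfg$chains %||% Sys.glob(file.path(cfg$outdir, "chain_*.csv"))
  if (length(files) < 2)
    stop("convergence check needs >= 2 chain files; found ", length(files))
  chains <- lapply(files, .read_chain)
  chk <- convergenceCheck(chains, tol = cfg$tol %||% 0.1)
  out <- file.path(cfg$outdir, "convergence.json")
  jsonlite::write_json(list(max_distance = chk$max_distance,
                            passed = chk$passed,
                            hist_distance = chk$hist_distance,
                            ks_statistic = chk$ks_statistic),
                       out, auto_unbox = TRUE, digits = NA)
  .write_manifest(cfg, cfg$outdir, "converge", out)
  invisible(chk)
}

#' @rdname cmdSynth
#' @export
cmdSummarize <- function(cfg) {
  path <- .need_file(cfg$chain %||% file.path(cfg$outdir, "chain_1.csv"),
                     "chain")
  summ <- posteriorSummary(.read_chain(path))
  out <- file.path(cfg$outdir, "posterior.json")
  jsonlite::write_json(list(mode = as.list(summ$mode),
                            mean = as.list(summ$mean),
                            ci = summ$ci, correlation = summ$correlation),
                       out, auto_unbox = TRUE, digits = NA)
  .write_manifest(cfg, cfg$outdir, "summarize", out)
  invisible(summ)
}

#' @rdname cmdSynth
#' @export
cmdAnneal <- function(cfg) {
  sur <- readSurrogate(.need_file(cfg$surrogate %||%
                                    file.path(cfg$outdir, "surrogate.json"),
                                  "surrogate"))
  data <- readObservations(.need_file(cfg$data %||%
                                        file.path(cfg$outdir,
                                                  "observations.csv"),
                                      "observation"))
  start <- if (!is.null(cfg$start)) as.numeric(cfg$start) else {
    summ <- cmdSummarize(cfg)
    summ$mean_cube
  }
  obj <- function(y) -logLikelihood(y, data, sur)
  res <- simulatedAnnealing(obj, start, seed = cfg$seed)
  out <- file.path(cfg$outdir, "anneal.json")
  jsonlite::write_json(
    list(par = as.list(fromCube(stats::setNames(res$par, sur$space$name),
                                sur$space)),
         objective = res$value, accepted = res$accepted),
    out, auto_unbox = TRUE, digits = NA)
  .write_manifest(cfg, cfg$outdir, "anneal", out)
  invisible(res)
}
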