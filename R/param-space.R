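#' Define a parameter space
#'
#' A parameter space is an ordered list of named parameters, each with a
#' natural-unit range and a scale (\code{"log10"} or \code{"linear"}), together
#' with the bijection onto the reference cube \eqn{[-1,1]^n} on which the
#' Legendre basis, the uniform prior and all sensitivities are defined.
#' Log-scaled parameters are mapped affinely in \eqn{\log_{10}} of their value,
#' so equal multiplicative steps become equal additive steps on the cube.
#'
#' @param name character vector of unique parameter names.
#' @param lo,hi numeric vectors of range endpoints in natural units
#'   (\code{lo < hi}; \code{lo > 0} where \code{scale == "log10"}).
#' @param scale character vector, each \code{"log10"} or \code{"linear"}.
#' @return An object of class \code{"parameterSpace"}: a data frame with
#'   columns \code{name}, \code{lo}, \code{hi}, \code{scale}.
#' @examples
#' sp <- parameterSpace(c("kGa", "kGd"), lo = c(1e-7, 1e-3), hi = c(1e-3, 10))
#' toCube(c(kGa = 1e-5, kGd = 1e-1), sp)
#' @export
parameterSpace <- function(name, lo, hi, scale = "log10") {
  n <- length(name)
  scale <- rep_len(scale, n)
  stopifnot(length(lo) == n, length(hi) == n, !anyDuplicated(name))
  if (!all(scale %in% c("log10", "linear")))
    stop("scale must be 'log10' or 'linear'")
  if (any(lo >= hi)) stop("lo must be < hi for every parameter")
  if (any(scale == "log10" & lo <= 0))
    stop("log10-scaled parameters require lo > 0")
  sp <- data.frame(name = as.character(name), lo = as.numeric(lo),
                   hi = as.numeric(hi), scale = scale,
                   stringsAsFactors = FALSE)
  class(sp) <- c("parameterSpace", "data.frame")
  sp
}

#' @export
print.parameterSpace <- function(x, ...) {
  cat("Parameter space with", nrow(x), "dimension(s)\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Dimension of a parameter space
#' @param space a \code{parameterSpace}.
#' @return integer dimension.
#' @export
spaceDim <- function(space) nrow(space)

## internal: endpoints on the mapped (possibly log) axis
.mapped_range <- function(space) {
  a <- ifelse(space$scale == "log10", log10(space$lo), space$lo)
  b <- ifelse(space$scale == "log10", log10(space$hi), space$hi)
  list(a = a, b = b)
}

#' Map natural parameter values to the reference cube
#'
#' @param p numeric vector or matrix (rows = parameter sets) in natural units,
#'   ordered as \code{space$name}.
#' @param space a \code{parameterSpace}.
#' @return cube coordinates in \eqn{[-1,1]^n}, same shape as \code{p}.
#' @export
toCube <- function(p, space) {
  p <- .as_param_matrix(p, space)
  r <- .mapped_range(space)
  for (j in seq_len(ncol(p))) {
    bad <- p[, j] < space$lo[j] | p[, j] > space$hi[j]
    if (any(bad))
      stop(sprintf("parameter '%s' outside its range [%g, %g]",
                   space$name[j], space$lo[j], space$hi[j]))
  }
  x <- p
  logj <- space$scale == "log10"
  x[, logj] <- log10(p[, logj, drop = FALSE])
  y <- sweep(sweep(x, 2, r$a), 2, r$b - r$a, "/") * 2 - 1
  .drop_like(y, p)
}

#' Map cube coordinates back to natural parameter values
#'
#' Exact inverse of \code{\link{toCube}}.
#' @param y numeric vector or matrix of cube coordinates in \eqn{[-1,1]^n}.
#' @param space a \code{parameterSpace}.
#' @return natural-unit values, same shape as \code{y}.
#' @export
fromCube <- function(y, space) {
  y <- .as_param_matrix(y, space, check_names = FALSE)
  if (any(y < -1 - 1e-12 | y > 1 + 1e-12))
    stop("cube coordinate outside [-1, 1]")
  r <- .mapped_range(space)
  x <- sweep(sweep((y + 1) / 2, 2, r$b - r$a, "*"), 2, r$a, "+")
  logj <- space$scale == "log10"
  x[, logj] <- 10^x[, logj, drop = FALSE]
  colnames(x) <- space$name
  .drop_like(x, y)
}

.as_param_matrix <- function(p, space, check_names = TRUE) {
  if (is.null(dim(p))) {
    if (length(p) != nrow(space))
      stop("expected ", nrow(space), " components, got ", length(p))
    if (check_names && !is.null(names(p)) && !identical(names(p), space$name))
      p <- p[space$name]
    p <- matrix(as.numeric(p), nrow = 1,
                dimnames = list(NULL, space$name))
    attr(p, "was_vector") <- TRUE
    return(p)
  }
  if (ncol(p) != nrow(space))
    stop("expected ", nrow(space), " columns, got ", ncol(p))
  p
}

.drop_like <- function(x, template) {
  if (isTRUE(attr(template, "was_vector"))) {
    out <- drop(x[1, ])
    names(out) <- colnames(x)
    out
  } else x
}

#' Sample the cube uniformly
#'
#' I.i.d. uniform samples on \eqn{[-1,1]^n}, the measure \eqn{\rho} under
#' which the Legendre basis is orthogonal and which serves as the MCMC prior.
#'
#' @param space a \code{parameterSpace}.
#' @param count number of samples.
#' @param seed optional integer seed (local to this call).
#' @return \code{count x n} matrix of cube coordinates.
#' @export
sampleUniform <- function(space, count, seed = NULL) {
  stopifnot(count >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- spaceDim(space)
  matrix(stats::runif(count * n, -1, 1), nrow = count,
         dimnames = list(NULL, space$name))
}

#' Read / write a parameter space as JSON
#'
#' The file holds a list of \code{{name, lo, hi, scale}} records.
#' @param path file path.
#' @return \code{readParameterSpace}: a \code{parameterSpace}.
#' @export
readParameterSpace <- function(path) {
  df <- jsonlite::fromJSON(path)
  parameterSpace(df$name, df$lo, df$hi, df$scale)
}

#' @rdname readParameterSpace
#' @param space a \code{parameterSpace} to serialize.
#' @export
writeParameterSpace <- function(space, path) {
  jsonlite::write_json(as.data.frame(unclass(space)), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Bundled parameter spaces
#'
#' \code{gproteinSpace2()} is the two-parameter study of the G-protein ODE
#' model: \code{kGa} log-uniform on \eqn{[10^{-7},10^{-3}]} and \code{kGd}
#' log-uniform on \eqn{[10^{-3},10]} (whole-cell units).
#'
#' \code{gproteinSpace8()} lets all eight kinetic rate constants vary, each
#' log-uniform over two orders of magnitude geometrically centred on the
#' baseline estimate; this centring is a reconstruction of ranges that were
#' only published in supplementary material, and is documented as such.
#'
#' \code{polarizationSpace35()} is the full 35-parameter space of the
#' membrane polarization model (the Hill exponents \code{q} and \code{h} are
#' linear, everything else log-uniform); \code{polarizationSpace15()} is the
#' screened 15-parameter subspace retained at sensitivity threshold 0.01.
#' @return a \code{parameterSpace}.
#' @export
gproteinSpace2 <- function() {
  parameterSpace(c("kGa", "kGd"), lo = c(1e-7, 1e-3), hi = c(1e-3, 10),
                 scale = "log10")
}

#' @rdname gproteinSpace2
#' @export
gproteinSpace8 <- function() {
  ctr <- unlist(gproteinBaseline()[c("kRL", "kRLm", "kRs", "kRd0", "kRd1",
                                     "kGa", "kGd", "kG1")])
  parameterSpace(names(ctr), lo = ctr / 10, hi = ctr * 10, scale = "log10")
}

#' @rdname gproteinSpace2
#' @export
polarizationSpace35 <- function() {
  tbl <- .polarization_table3()
  parameterSpace(tbl$name, tbl$lo, tbl$hi, tbl$scale)
}

#' @rdname gproteinSpace2
#' @export
polarizationSpace15 <- function() {
  keep <- c("k42a", "k42d", "DC42", "DC42a", "q", "h", "k24cm1", "kB1cm",
            "kB1mc", "C24t", "B1t", "kCla4a", "kCla4d", "k24cm0", "k24d")
  sp <- polarizationSpace35()
  out <- sp[match(keep, sp$name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("parameterSpace", "data.frame")
  out
}
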