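#' Analytic global sensitivity coefficient from Legendre coefficients
#'
#' The sensitivity of a response \eqn{z} to cube coordinate \eqn{y_j} is the
#' global derivative-based measure \eqn{S_j = E(\partial z/\partial y_j)}
#' under the uniform measure on \eqn{[-1,1]^n}.  For a Legendre expansion
#' this is analytic: the expectation factorizes over dimensions,
#' \eqn{E[P_m] = \delta_{m0}} and \eqn{E[P_m'] = (P_m(1) - P_m(-1))/2},
#' which is 1 for odd \eqn{m} and 0 for even \eqn{m}.  Hence
#' \eqn{S_j = \sum c_\alpha} over multi-indices with \eqn{\alpha_j} odd and
#' all other components zero.
#'
#' Sensitivities are reported with respect to the (dimensionless) cube
#' coordinates, so parameters of very different magnitudes are directly
#' comparable; the parameter space stored on the surrogate records the
#' mapping back to natural units.
#'
#' @param surrogate a \code{gpcSurrogate}.
#' @param j parameter index (1-based) or name.
#' @return numeric vector, one \eqn{S_j} per response.
#' @export
sensitivityFromCoeffs <- function(surrogate, j) {
  basis <- surrogate$basis
  if (is.character(j)) j <- match(j, surrogate$space$name)
  if (is.na(j) || j < 1 || j > ncol(basis))
    stop("parameter index out of range")
  sel <- basis[, j] %% 2L == 1L &
    rowSums(basis[, -j, drop = FALSE]) == 0L
  colSums(surrogate$coeffs[sel, , drop = FALSE])
}

#' Sensitivity matrix, screening, and report
#'
#' Computes the full parameter-by-response matrix of analytic sensitivity
#' coefficients, their means over responses, Monte-Carlo mean-absolute
#' sensitivities \eqn{E|\partial z/\partial y_j|} (no closed form exists;
#' estimated from \code{n_mc} uniform cube points using the surrogate's
#' analytic gradient), and the parameters retained by threshold screening.
#' Screening keeps parameter \eqn{j} when \eqn{|mean_r S_{j,r}|} exceeds
#' \code{threshold}; the equivalent criterion on \eqn{mean_r |S_{j,r}|} is
#' also reported since the two can differ when signs flip across responses.
#'
#' @param surrogate a \code{gpcSurrogate} (possibly multi-response).
#' @param threshold screening threshold on the magnitude of the mean
#'   sensitivity (default 0.01).
#' @param n_mc Monte-Carlo points for the mean-absolute sensitivities.
#' @param seed seed for the Monte-Carlo estimate.
#' @return object of class \code{"sensitivityReport"}: list with \code{S}
#'   (parameters x responses), \code{mean_over_responses},
#'   \code{mean_abs_over_responses}, \code{mean_abs_derivative},
#'   \code{threshold}, \code{retained}, \code{retained_abs}.
#' @export
sensitivityReport <- function(surrogate, threshold = 0.01, n_mc = 10000,
                              seed = 1) {
  if (is.null(surrogate$coeffs) || !nrow(surrogate$coeffs))
    stop("empty surrogate")
  space <- surrogate$space
  n <- spaceDim(space)
  nr <- ncol(surrogate$coeffs)
  S <- vapply(seq_len(n), function(j) sensitivityFromCoeffs(surrogate, j),
              numeric(nr))
  S <- if (nr == 1) matrix(S, ncol = 1) else t(S)
  rownames(S) <- space$name
  colnames(S) <- surrogate$response_label
  mean_S <- rowMeans(S)
  mean_abs_S <- rowMeans(abs(S))
  Ymc <- sampleUniform(space, n_mc, seed = seed)
  G <- surrogateGradient(surrogate, Ymc)
  if (length(dim(G)) == 2) {
    mad <- colMeans(abs(G))
  } else {
    mad <- rowMeans(apply(abs(G), c(2, 3), mean))
  }
  names(mad) <- space$name
  structure(list(S = S,
                 mean_over_responses = mean_S,
                 mean_abs_over_responses = mean_abs_S,
                 mean_abs_derivative = mad,
                 threshold = threshold,
                 retained = space$name[abs(mean_S) > threshold],
                 retained_abs = space$name[mean_abs_S > threshold]),
            class = "sensitivityReport")
}

#' @export
print.sensitivityReport <- function(x, ...) {
  cat("Global derivative-based sensitivities (cube coordinates)\n")
  df <- data.frame(mean_sensitivity = x$mean_over_responses,
                   mean_abs_sensitivity = x$mean_abs_over_responses)
  print(signif(df[order(-abs(df$mean_sensitivity)), ], 3))
  cat("retained at |mean S| >", x$threshold, ":",
      paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Write a sensitivity report
#'
#' CSV of the parameter-by-response sensitivity matrix plus a JSON summary
#' (means, mean absolute values, threshold, retained parameters).
#' @param report a \code{sensitivityReport}.
#' @param csv_path,json_path output paths (either may be NULL to skip).
#' @export
writeSensitivityReport <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(report$S), csv_path, row.names = TRUE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(mean_sensitivity = as.list(report$mean_over_responses),
           mean_abs_sensitivity = as.list(report$mean_abs_over_responses),
           mean_abs_derivative = as.list(report$mean_abs_derivative),
           threshold = report$threshold,
           retained = report$retained),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
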