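#' Size of the total-degree polynomial basis
#'
#' The number of multivariate polynomials of total degree at most \code{d} in
#' \code{n} variables, \eqn{\binom{n+d}{n}}.
#' @param n dimension (>= 1).
#' @param d maximum total degree (>= 0).
#' @return integer count.
#' @examples
#' basisCount(8, 5)   # 1287
#' basisCount(35, 5)  # 658008
#' @export
basisCount <- function(n, d) {
  stopifnot(n >= 1, d >= 0)
  round(choose(n + d, n))
}

#' Enumerate the total-degree multi-index set
#'
#' All multi-indices \eqn{\alpha} with \eqn{|\alpha| \le d}, in graded
#' lexicographic order (by total degree, then lexicographically with the
#' first dimension most significant), so that serialized coefficient files
#' are reproducible.
#' @param n dimension.
#' @param d maximum total degree.
#' @return integer matrix, \code{basisCount(n, d)} rows by \code{n} columns.
#' @export
multiIndices <- function(n, d) {
  idx <- multi_indices_cpp(as.integer(n), as.integer(d))
  storage.mode(idx) <- "integer"
  idx
}

#' Evaluate Legendre polynomials
#'
#' Standard (unnormalized) Legendre polynomials \eqn{P_m} with
#' \eqn{P_m(1) = 1}, by the three-term recurrence.  \code{legendreDeriv}
#' evaluates the derivative \eqn{P_m'}.
#' @param m degree (scalar, >= 0).
#' @param x evaluation points in \code{[-1, 1]} (vectorized).
#' @return numeric vector of values.
#' @export
legendreEval <- function(m, x) {
  stopifnot(m >= 0)
  if (m == 0) return(rep(1, length(x)))
  pm1 <- rep(1, length(x)); p <- x
  if (m >= 2) for (k in 2:m) {
    pn <- ((2 * k - 1) * x * p - (k - 1) * pm1) / k
    pm1 <- p; p <- pn
  }
  p
}

#' @rdname legendreEval
#' @export
legendreDeriv <- function(m, x) {
  stopifnot(m >= 0)
  if (m == 0) return(rep(0, length(x)))
  # P'_{k} = P'_{k-2} + (2k-1) P_{k-1}
  dpm1 <- rep(0, length(x)); dp <- rep(1, length(x))
  pm1 <- rep(1, length(x)); p <- x
  if (m >= 2) for (k in 2:m) {
    pn <- ((2 * k - 1) * x * p - (k - 1) * pm1) / k
    dpn <- dpm1 + (2 * k - 1) * p
    pm1 <- p; p <- pn
    dpm1 <- dp; dp <- dpn
  }
  dp
}

#' Assemble the Legendre design matrix
#'
#' \code{A[i, j]} is the \code{j}-th tensor-product Legendre basis polynomial
#' evaluated at cube sample \code{i}: \eqn{\prod_k P_{\alpha_j(k)}(y_{i,k})}.
#' @param Y matrix of cube samples (rows = samples, columns = dimensions).
#' @param basis integer multi-index matrix from \code{\link{multiIndices}},
#'   with the same number of columns as \code{Y}.
#' @return numeric matrix, \code{nrow(Y)} by \code{nrow(basis)}.
#' @export
designMatrix <- function(Y, basis) {
  Y <- as.matrix(Y)
  if (ncol(Y) != ncol(basis))
    stop("sample dimension (", ncol(Y), ") does not match basis dimension (",
         ncol(basis), ")")
  design_matrix_cpp(Y, basis)
}

#' Least-squares coefficient fit
#'
#' Minimizes \eqn{\|Ax - b\|_2} via QR; on rank deficiency a warning is
#' raised and the minimum-norm solution (SVD pseudo-inverse) returned.
#' @param A design matrix with \code{nrow(A) >= ncol(A)}.
#' @param b response vector or matrix (one column per response).
#' @return coefficient vector/matrix.
#' @export
fitLeastSquares <- function(A, b) {
  if (nrow(A) < ncol(A))
    stop("least squares needs at least as many samples as basis terms; ",
         "use fitL1() for undersampled designs")
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    warning("design matrix is rank deficient (rank ", qrA$rank, " < ",
            ncol(A), "); returning the minimum-norm solution")
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-12
    return(sv$v[, pos, drop = FALSE] %*%
             ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos]))
  }
  qr.coef(qrA, b)
}

#' l1-minimization with a quadratic constraint (basis-pursuit denoising)
#'
#' Solves \eqn{\min \|x\|_1} subject to \eqn{\|Ax - b\|_2 \le \epsilon},
#' the compressed-sensing recovery problem used for undersampled surrogate
#' fits.  Solved by ADMM: the splitting alternates a soft-threshold step
#' with an exact Euclidean projection onto the residual ball (computed
#' through a one-time SVD of \code{A} and a scalar root find), with
#' residual-balancing penalty adaptation.  The returned vector is feasible.
#'
#' @param A design matrix (undersampled rows < columns is the intended
#'   regime; oversampled also works).
#' @param b response vector.
#' @param epsilon constraint radius (>= 0); default \code{0.05 * ||b||_2}.
#' @param rho initial ADMM penalty.
#' @param maxit,tol iteration cap and convergence tolerance on the primal
#'   gap \code{max|x - z|}.
#' @return coefficient vector satisfying the quadratic constraint.
#' @export
fitL1 <- function(A, b, epsilon = 0.05 * sqrt(sum(b^2)), rho = 1,
                  maxit = 4000, tol = 1e-9) {
  stopifnot(epsilon >= 0)
  b <- as.numeric(b)
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * 1e-14
  U <- sv$u[, pos, drop = FALSE]; dd <- sv$d[pos]
  V <- sv$v[, pos, drop = FALSE]
  cc <- as.numeric(crossprod(U, b))
  b_perp2 <- sum((b - as.numeric(U %*% cc))^2)
  if (sqrt(b_perp2) > epsilon * (1 + 1e-8) + 1e-12)
    stop("infeasible: minimum attainable residual ", sqrt(b_perp2),
         " exceeds epsilon = ", epsilon)
  target2 <- max(epsilon^2 - b_perp2, 0)
  d2 <- dd^2

  project <- function(v) {
    w <- as.numeric(crossprod(V, v))
    r <- dd * w - cc
    if (sum(r^2) <= target2) return(v)
    g <- function(mu) sum((r / (1 + mu * d2))^2) - target2
    hi <- 1
    while (g(hi) > 0) hi <- hi * 10
    lo <- 0
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) lo <- mid else hi <- mid
    }
    mu <- (lo + hi) / 2
    v + as.numeric(V %*% (mu * dd * (cc - dd * w) / (1 + mu * d2)))
  }

  n <- ncol(A)
  x <- numeric(n); z <- numeric(n); u <- numeric(n)
  for (it in seq_len(maxit)) {
    x <- project(z - u)
    z_old <- z
    z <- sign(x + u) * pmax(abs(x + u) - 1 / rho, 0)
    u <- u + x - z
    prim <- max(abs(x - z))
    dual <- rho * max(abs(z - z_old))
    if (prim < tol && dual < tol) break
    if (prim > 10 * dual) { rho <- rho * 2; u <- u / 2 }
    else if (dual > 10 * prim) { rho <- rho / 2; u <- u * 2 }
  }
  project(z)
}

#' Construct and fit a polynomial-chaos surrogate
#'
#' Fits one Legendre coefficient vector per response column, by least squares
#' when the design is oversampled or by \code{\link{fitL1}} when
#' undersampled (Algorithm: choose degree, sample, assemble \code{A},
#' solve).
#'
#' @param Y cube sample matrix (rows = samples).
#' @param Z response vector or matrix (columns = response functions).
#' @param space the \code{parameterSpace} the samples live on.
#' @param degree maximum total polynomial degree.
#' @param method \code{"ls"}, \code{"l1"}, or \code{"auto"} (ls when
#'   oversampled, l1 otherwise).
#' @param epsilon l1 constraint radius (per response); default
#'   \code{0.05 * ||b||_2}.
#' @param response_label optional character labels for the responses.
#' @return object of class \code{"gpcSurrogate"}: list with elements
#'   \code{basis} (multi-index matrix), \code{degree}, \code{coeffs}
#'   (basis x response matrix), \code{space}, \code{response_label},
#'   \code{method}, \code{epsilon}.
#' @export
fitSurrogate <- function(Y, Z, space, degree, method = c("auto", "ls", "l1"),
                         epsilon = NULL, response_label = NULL) {
  method <- match.arg(method)
  Y <- as.matrix(Y); Z <- as.matrix(Z)
  stopifnot(nrow(Y) == nrow(Z), ncol(Y) == spaceDim(space))
  basis <- multiIndices(ncol(Y), degree)
  A <- designMatrix(Y, basis)
  if (method == "auto") method <- if (nrow(A) >= ncol(A)) "ls" else "l1"
  if (method == "ls") {
    coeffs <- as.matrix(fitLeastSquares(A, Z))
    eps_used <- rep(NA_real_, ncol(Z))
  } else {
    eps_used <- numeric(ncol(Z))
    coeffs <- matrix(0, nrow(basis), ncol(Z))
    for (r in seq_len(ncol(Z))) {
      eps_used[r] <- if (is.null(epsilon)) 0.05 * sqrt(sum(Z[, r]^2)) else epsilon
      coeffs[, r] <- fitL1(A, Z[, r], eps_used[r])
    }
  }
  if (is.null(response_label))
    response_label <- colnames(Z) %||% paste0("z", seq_len(ncol(Z)))
  colnames(coeffs) <- response_label
  structure(list(basis = basis, degree = degree, coeffs = coeffs,
                 space = space, response_label = response_label,
                 method = method, epsilon = eps_used),
            class = "gpcSurrogate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gpcSurrogate <- function(x, ...) {
  cat("Legendre polynomial-chaos surrogate\n")
  cat("  dimension:", ncol(x$basis), " degree:", x$degree,
      " basis terms:", nrow(x$basis), "\n")
  cat("  responses:", length(x$response_label),
      paste0("(", x$method, " fit)"), "\n")
  invisible(x)
}

#' Evaluate a surrogate on the cube
#'
#' \eqn{\hat z_r(y) = \sum_\alpha c_{\alpha,r} \prod_k P_{\alpha_k}(y_k)}.
#' Points slightly outside \eqn{[-1,1]^n} are evaluated with a warning
#' (polynomial extrapolation).
#' @param surrogate a \code{gpcSurrogate}.
#' @param y cube point (vector) or matrix of points (rows).
#' @return numeric matrix, points x responses (dropped to a vector for a
#'   single point and single response).
#' @export
evaluateSurrogate <- function(surrogate, y) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  if (any(abs(y) > 1))
    warning("evaluating surrogate outside [-1,1]^n (extrapolation)")
  A <- designMatrix(y, surrogate$basis)
  out <- A %*% surrogate$coeffs
  if (nrow(out) == 1 && ncol(out) == 1) return(unname(out[1, 1]))
  if (ncol(out) == 1) return(unname(drop(out)))
  out
}

#' Analytic cube gradient of a surrogate
#'
#' Derivatives of the surrogate with respect to the cube coordinates, used
#' for Monte-Carlo mean-absolute sensitivities.
#' @param surrogate a \code{gpcSurrogate}.
#' @param Y matrix of cube points (rows).
#' @return array \code{points x dimensions x responses} (the response slice
#'   is dropped when there is a single response).
#' @export
surrogateGradient <- function(surrogate, Y) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  basis <- surrogate$basis
  n <- ncol(basis); m <- nrow(Y); nb <- nrow(basis)
  # per-dimension factor tables P_{alpha(k)}(y_k) and their derivatives
  Fk <- vector("list", n); Dk <- vector("list", n)
  for (k in seq_len(n)) {
    degs <- basis[, k]
    P <- matrix(0, m, nb); D <- matrix(0, m, nb)
    for (dg in unique(degs)) {
      cols <- which(degs == dg)
      P[, cols] <- legendreEval(dg, Y[, k])
      D[, cols] <- legendreDeriv(dg, Y[, k])
    }
    Fk[[k]] <- P; Dk[[k]] <- D
  }
  # prefix/suffix products over dimensions
  pre <- vector("list", n + 1); suf <- vector("list", n + 1)
  pre[[1]] <- matrix(1, m, nb); suf[[n + 1]] <- matrix(1, m, nb)
  for (k in seq_len(n)) pre[[k + 1]] <- pre[[k]] * Fk[[k]]
  for (k in n:1) suf[[k]] <- suf[[k + 1]] * Fk[[k]]
  nr <- ncol(surrogate$coeffs)
  out <- array(0, c(m, n, nr))
  for (j in seq_len(n)) {
    G <- pre[[j]] * Dk[[j]] * suf[[j + 1]]
    out[, j, ] <- G %*% surrogate$coeffs
  }
  if (nr == 1) out <- out[, , 1, drop = TRUE]
  out
}

#' k-fold cross-validation of a surrogate fit
#'
#' Partitions the samples into \code{k} folds; for each fold the surrogate is
#' fit on the complement and the prediction error (surrogate minus model)
#' evaluated on the held-out fold.  Errors are pooled over folds.
#'
#' @param Y cube sample matrix.
#' @param Z response vector or matrix.
#' @param space parameter space of the samples.
#' @param degree polynomial degree.
#' @param k number of folds (>= 2).
#' @param method \code{"auto"}, \code{"ls"} or \code{"l1"} (applied to each
#'   training complement).
#' @param seed integer seed for the fold assignment.
#' @param epsilon optional l1 radius.
#' @return object of class \code{"gpcFitReport"}: list with per-response
#'   \code{mean_error}, \code{sd_error}, \code{mean_abs_error}, plus
#'   \code{method}, \code{epsilon}, \code{folds}, and the pooled
#'   \code{errors} matrix.
#' @export
crossValidate <- function(Y, Z, space, degree, k = 10,
                          method = c("auto", "ls", "l1"), seed = 1,
                          epsilon = NULL) {
  method <- match.arg(method)
  Y <- as.matrix(Y); Z <- as.matrix(Z)
  m <- nrow(Y)
  stopifnot(m >= k, k >= 2)
  nb <- basisCount(ncol(Y), degree)
  if (method == "ls" && (m - ceiling(m / k)) < nb)
    stop("folds leave fewer training samples than basis terms; ",
         "use method = 'l1' for undersampled fits")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), m))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  errs <- matrix(NA_real_, m, ncol(Z))
  for (i in seq_len(k)) {
    test <- fold == i
    fit <- fitSurrogate(Y[!test, , drop = FALSE], Z[!test, , drop = FALSE],
                        space, degree, method = method, epsilon = epsilon)
    pred <- designMatrix(Y[test, , drop = FALSE], fit$basis) %*% fit$coeffs
    errs[test, ] <- pred - Z[test, , drop = FALSE]
  }
  structure(list(mean_error = colMeans(errs),
                 sd_error = apply(errs, 2, stats::sd),
                 mean_abs_error = colMeans(abs(errs)),
                 method = method,
                 epsilon = epsilon %||% NA_real_,
                 folds = k, errors = errs),
            class = "gpcFitReport")
}

#' @export
print.gpcFitReport <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s fit)\n", x$folds, x$method))
  cat("  mean error:     ", signif(x$mean_error, 3), "\n")
  cat("  sd of error:    ", signif(x$sd_error, 3), "\n")
  cat("  mean abs error: ", signif(x$mean_abs_error, 3), "\n")
  invisible(x)
}

#' Serialize surrogates to JSON
#'
#' The file records the parameter space, degree, multi-index list,
#' coefficients, response labels and fit metadata, so a surrogate round-trips
#' across sessions.
#' @param surrogate a \code{gpcSurrogate}.
#' @param path file path.
#' @export
writeSurrogate <- function(surrogate, path) {
  obj <- list(space = as.data.frame(unclass(surrogate$space)),
              degree = surrogate$degree,
              indices = surrogate$basis,
              coeffs = surrogate$coeffs,
              response_label = surrogate$response_label,
              method = surrogate$method,
              epsilon = surrogate$epsilon)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeSurrogate
#' @return \code{readSurrogate}: the \code{gpcSurrogate}.
#' @export
readSurrogate <- function(path) {
  obj <- jsonlite::fromJSON(path)
  space <- parameterSpace(obj$space$name, obj$space$lo, obj$space$hi,
                          obj$space$scale)
  basis <- obj$indices
  storage.mode(basis) <- "integer"
  coeffs <- as.matrix(obj$coeffs)
  colnames(coeffs) <- obj$response_label
  structure(list(basis = basis, degree = obj$degree[1], coeffs = coeffs,
                 space = space, response_label = obj$response_label,
                 method = obj$method[1], epsilon = obj$epsilon),
            class = "gpcSurrogate")
}

#' Read / write sample sets
#'
#' CSV of cube coordinates followed by response columns, with the generating
#' seed recorded in a leading comment line.
#' @param Y cube samples; \code{Z} responses.
#' @param path file path.
#' @param seed generating seed recorded in the header.
#' @export
writeSampleSet <- function(Y, Z, path, seed = NA) {
  Y <- as.matrix(Y); Z <- as.matrix(Z)
  colnames(Y) <- colnames(Y) %||% paste0("y", seq_len(ncol(Y)))
  colnames(Z) <- colnames(Z) %||% paste0("z", seq_len(ncol(Z)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seed=", seed, " n_y=", ncol(Y)), con)
  utils::write.csv(cbind(Y, Z), con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSampleSet
#' @return \code{readSampleSet}: list with \code{Y}, \code{Z}, \code{seed}.
#' @export
readSampleSet <- function(path) {
  hdr <- readLines(path, n = 1)
  seed <- as.numeric(sub(".*seed=([^ ]+).*", "\\1", hdr))
  n_y <- as.integer(sub(".*n_y=([0-9]+).*", "\\1", hdr))
  df <- utils::read.csv(path, comment.char = "#")
  list(Y = as.matrix(df[, seq_len(n_y), drop = FALSE]),
       Z = as.matrix(df[, -seq_len(n_y), drop = FALSE]),
       seed = seed)
}
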