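#' PCA eigendecomposition of an expression matrix
#'
#' Decomposes the sample covariance matrix
#' `S = (X - Xbar)(X - Xbar)^T / (n - 1)` of a genes-by-samples matrix,
#' retaining the leading `D = min(n - 1, d)` components. The decomposition
#' is computed from the thin SVD of the centered matrix, which is exactly
#' the Gram-matrix route and avoids forming the `d x d` covariance when
#' `d >> n`.
#'
#' @param x Genes x samples numeric matrix, `n >= 2`, finite values.
#' @return An object of class `eigen_system`: list with `mean_profile`
#'   (per-gene means), `eigenvectors` (`d x D`, orthonormal columns),
#'   `eigenvalues` (non-increasing, clipped at zero), `pca_dimension`, and
#'   the dimensions `d`, `n`.
#' @export
pca_decompose <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("'x' must be a numeric matrix")
  n <- ncol(x); d <- nrow(x)
  if (n < 2) stop("at least 2 samples required")
  if (any(!is.finite(x))) stop("non-finite entries in 'x'")
  mu <- rowMeans(x)
  xc <- x - mu
  dd <- min(n - 1, d)
  sv <- svd(xc, nu = dd, nv = 0)
  lambda <- sv$d[seq_len(dd)]^2 / (n - 1)
  tol <- 1e-10 * max(lambda, 0)
  lambda[lambda < tol] <- 0
  structure(list(mean_profile = mu,
                 eigenvectors = sv$u,
                 eigenvalues = lambda,
                 pca_dimension = dd,
                 d = d, n = n),
            class = "eigen_system")
}

#' Shrink a PCA spectrum by trailing-eigenvalue means
#'
#' For a non-increasing spectrum of length `D` and a signal dimension
#' `ell`, the retained eigenvalues are reduced by the mean of the trailing
#' ones and the rest are zeroed:
#' \deqn{\tilde\lambda_i = \lambda_i - \frac{1}{D-i+1}\sum_{j=i+1}^{D} \lambda_j
#'   \quad (i \le \ell), \qquad \tilde\lambda_i = 0 \quad (i > \ell).}
#' A retained value that comes out negative (possible when \eqn{\lambda_i}
#' falls below its tail mean) is clipped to zero with a warning.
#'
#' @param eigenvalues Non-increasing non-negative numeric vector.
#' @param ell Number of components treated as signal, in `1..pca_dimension`.
#' @param pca_dimension `D`; defaults to `length(eigenvalues)`.
#' @return Shrunk spectrum of the same length.
#' @export
shrink_eigenvalues <- function(eigenvalues, ell, pca_dimension = length(eigenvalues)) {
  dd <- pca_dimension
  if (length(eigenvalues) != dd) stop("spectrum length must equal pca_dimension")
  if (any(diff(eigenvalues) > 1e-9 * max(abs(eigenvalues), 1)))
    stop("eigenvalues must be non-increasing")
  if (ell < 1 || ell > dd) stop("ell must lie in [1, ", dd, "]")
  # tail sums: sum_{j=i+1}^{D} lambda_j
  tail_sum <- rev(cumsum(rev(eigenvalues)))[-1]
  tail_sum <- c(tail_sum, 0)
  shrunk <- eigenvalues - tail_sum / (dd - seq_len(dd) + 1)
  shrunk[seq_len(dd) > ell] <- 0
  if (any(shrunk < 0)) {
    warning(sum(shrunk < 0), " shrunk eigenvalue(s) below zero clipped to 0")
    shrunk[shrunk < 0] <- 0
  }
  shrunk
}

#' Choose the RECODE signal dimension
#'
#' `method = "elbow"` (default) returns the largest index `i <= D` whose
#' eigenvalue exceeds the mean of the trailing eigenvalues and whose shrunk
#' value is positive — a simple elbow heuristic for the boundary between
#' signal and an approximately flat noise floor. `method = "fixed"` returns
#' a user-supplied `ell` unchanged.
#'
#' @param eigen An `eigen_system` (or a raw non-increasing spectrum).
#' @param method `"elbow"` or `"fixed"`.
#' @param ell Required for `method = "fixed"`.
#' @return Integer signal dimension.
#' @export
select_ell <- function(eigen, method = c("elbow", "fixed"), ell = NULL) {
  method <- match.arg(method)
  lambda <- if (inherits(eigen, "eigen_system")) eigen$eigenvalues else eigen
  dd <- length(lambda)
  if (method == "fixed") {
    if (is.null(ell)) stop("method = 'fixed' requires 'ell'")
    if (ell < 1 || ell > dd) stop("ell out of range [1, ", dd, "]")
    return(as.integer(ell))
  }
  if (all(lambda <= 0)) stop("degenerate data: all eigenvalues are zero")
  tail_sum <- c(rev(cumsum(rev(lambda)))[-1], 0)
  tail_len <- dd - seq_len(dd)
  tail_mean <- ifelse(tail_len > 0, tail_sum / pmax(tail_len, 1), Inf)
  above <- lambda > tail_mean & tail_len > 0
  shrunk_pos <- lambda - tail_sum / (tail_len + 1) > 0
  ok <- which(above & shrunk_pos)
  if (length(ok) == 0) stop("no eigenvalue exceeds its trailing mean")
  as.integer(max(ok))
}

#' RECODE denoising of a high-dimensional expression matrix
#'
#' Applies the PCA coordinate change, rescales each retained principal
#' direction `i <= ell` of the centered data by
#' `sqrt(shrunk_lambda_i / lambda_i)` (zero when `lambda_i = 0`), zeroes
#' directions beyond `ell`, and inverts the coordinate change. Per-gene
#' means are preserved exactly and the covariance trace never increases.
#'
#' @param x Genes x samples numeric matrix.
#' @param ell Signal dimension; defaults to [select_ell()] with the elbow
#'   heuristic.
#' @param return_details If `TRUE`, also return the eigensystem, the chosen
#'   `ell` and the shrunk spectrum.
#' @return Denoised matrix of the same shape and dimnames (attribute
#'   `recode_ell` records the dimension used), or a list when
#'   `return_details = TRUE`.
#' @export
apply_recode <- function(x, ell = NULL, return_details = FALSE) {
  unit <- attr(x, "unit")
  n <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  dd <- min(n - 1, nrow(x))
  sv <- svd(xc, nu = dd, nv = dd)
  lambda <- sv$d[seq_len(dd)]^2 / (n - 1)
  tol <- 1e-10 * max(lambda, 0)
  lambda[lambda < tol] <- 0
  if (is.null(ell)) {
    eig <- structure(list(eigenvalues = lambda), class = "eigen_system")
    ell <- select_ell(eig)
  }
  shrunk <- shrink_eigenvalues(lambda, ell, dd)
  scale <- ifelse(lambda > 0, sqrt(shrunk / lambda), 0)
  xt <- sv$u %*% (scale * sv$d[seq_len(dd)] * t(sv$v)) + mu
  dimnames(xt) <- dimnames(x)
  attr(xt, "unit") <- unit
  attr(xt, "recode_ell") <- as.integer(ell)
  if (return_details)
    return(list(x = xt, ell = as.integer(ell), eigenvalues = lambda,
                shrunk_eigenvalues = shrunk))
  xt
}
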