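#' Ledoit-Wolf shrinkage covariance estimate
#'
#' Regularised covariance for multivariate noise estimation: the sample
#' covariance is shrunk toward a scaled identity target, with the analytic
#' shrinkage intensity of the Ledoit-Wolf well-conditioned estimator. Rows
#' are observations (trials), columns features. The input is expected to be
#' (approximately) mean-centred; columns are re-centred internally.
#'
#' @param x Numeric matrix, trials x features, at least 2 rows.
#' @param center Logical; remove column means first (default TRUE).
#' @return A list with \code{sigma} (the shrunk covariance, symmetric PSD),
#'   \code{shrinkage} (intensity in [0, 1]) and \code{mu} (the scale of the
#'   identity target).
#' @references Ledoit, O. & Wolf, M. (2004). A well-conditioned estimator
#'   for large-dimensional covariance matrices. J. Multivariate Anal. 88.
#' @export
shrinkage_covariance <- function(x, center = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) stop("need at least 2 trials to estimate covariance",
                   call. = FALSE)
  if (p < 1L) stop("need at least 1 feature", call. = FALSE)
  if (center) x <- sweep(x, 2L, colMeans(x))
  s <- crossprod(x) / n
  mu <- sum(diag(s)) / p
  d2 <- sum((s - diag(mu, p))^2) / p
  if (d2 <= .Machine$double.eps * mu^2) {
    return(list(sigma = s, shrinkage = 0, mu = mu))
  }
  # average squared distance of single-observation outer products from S
  b2bar <- sum(rowSums(x^2)^2) / (n^2 * p) - sum(s^2) / (n * p)
  b2 <- min(max(b2bar, 0), d2)
  rho <- b2 / d2
  sigma <- rho * diag(mu, p) + (1 - rho) * s
  list(sigma = sigma, shrinkage = rho, mu = mu)
}

#' Moore-Penrose pseudoinverse of a symmetric PSD matrix
#'
#' Eigendecomposition-based pseudoinverse; eigenvalues below
#' \code{max(eigenvalue) * dim * machine-epsilon} are treated as zero.
#'
#' @param sigma Symmetric numeric matrix.
#' @return The pseudoinverse (symmetric matrix of the same dimension).
#' @export
psd_pinv <- function(sigma) {
  sigma <- as.matrix(sigma)
  stopifnot(nrow(sigma) == ncol(sigma))
  e <- eigen(sigma, symmetric = TRUE)
  tol <- max(abs(e$values)) * nrow(sigma) * .Machine$double.eps
  inv <- ifelse(e$values > tol, 1 / e$values, 0)
  e$vectors %*% (inv * t(e$vectors))
}
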