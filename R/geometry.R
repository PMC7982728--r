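#' @useDynLib riembci, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

is_square <- function(P) is.matrix(P) && nrow(P) == ncol(P)

assert_spd <- function(P, arg = "P", tol = 1e-10) {
  if (!is_square(P))
    stop("`", arg, "` must be a square numeric matrix", call. = FALSE)
  rel <- max(abs(P - t(P))) / max(abs(P), .Machine$double.eps)
  if (rel > tol)
    stop("`", arg, "` is not symmetric (relative asymmetry ", format(rel), ")",
         call. = FALSE)
  ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("`", arg, "` is not positive definite (smallest eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  invisible(TRUE)
}

assert_symmetric <- function(S, arg = "S", tol = 1e-8) {
  if (!is_square(S))
    stop("`", arg, "` must be a square numeric matrix", call. = FALSE)
  rel <- max(abs(S - t(S))) / max(abs(S), .Machine$double.eps)
  if (rel > tol)
    stop("`", arg, "` is not symmetric beyond tolerance (relative asymmetry ",
         format(rel), ")", call. = FALSE)
  invisible(TRUE)
}

assert_same_dim <- function(P1, P2) {
  if (!identical(dim(P1), dim(P2)))
    stop("matrices have mismatched dimensions: ",
         paste(dim(P1), collapse = "x"), " vs ",
         paste(dim(P2), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

# accepts a list of matrices or an n x n x I array; returns n x n x I array
as_cov_cube <- function(covs) {
  if (is.array(covs) && length(dim(covs)) == 3L) {
    if (dim(covs)[1L] != dim(covs)[2L])
      stop("covariance array must be n x n x I", call. = FALSE)
    return(covs)
  }
  if (is.matrix(covs)) covs <- list(covs)
  if (!is.list(covs) || length(covs) == 0L)
    stop("`covs` must be a non-empty list of square matrices or an n x n x I array",
         call. = FALSE)
  n <- nrow(covs[[1L]])
  for (P in covs) {
    if (!is_square(P) || nrow(P) != n)
      stop("all covariance matrices must be square with equal dimension",
           call. = FALSE)
  }
  array(unlist(covs), dim = c(n, n, length(covs)))
}

#' Sample covariance matrix of one trial
#'
#' Estimates the trial covariance as `X %*% t(X) / (n_samples - 1)`. The data
#' are taken as zero-mean (band-pass filtered EEG); set `center = TRUE` to
#' subtract channel means first. With `shrinkage > 0` the estimate is blended
#' with a scaled identity, `(1 - s) * P + s * (tr(P)/n) * I`, which guarantees
#' positive definiteness for rank-deficient windows.
#'
#' @param X numeric matrix, channels x samples.
#' @param shrinkage fraction in `[0, 1)` blended toward the scaled identity.
#' @param center subtract per-channel means before the outer product?
#' @return A symmetric positive-definite matrix, channels x channels.
#' @examples
#' X <- matrix(rnorm(3 * 200), 3, 200)
#' P <- estimate_scm(X)
#' all(eigen(P, symmetric = TRUE)$values > 0)
#' @export
estimate_scm <- function(X, shrinkage = 0, center = FALSE) {
  if (!is.matrix(X) || !is.numeric(X))
    stop("`X` must be a numeric matrix (channels x samples)", call. = FALSE)
  if (ncol(X) < 2L)
    stop("at least 2 samples are required to estimate a covariance", call. = FALSE)
  if (!all(is.finite(X)))
    stop("`X` contains non-finite values", call. = FALSE)
  if (shrinkage < 0 || shrinkage >= 1)
    stop("`shrinkage` must lie in [0, 1)", call. = FALSE)
  if (center) X <- X - rowMeans(X)
  P <- tcrossprod(X) / (ncol(X) - 1L)
  if (shrinkage > 0) {
    mu <- sum(diag(P)) / nrow(P)
    P <- (1 - shrinkage) * P + shrinkage * mu * diag(nrow(P))
  }
  P <- (P + t(P)) / 2
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("covariance is rank deficient at shrinkage 0 (smallest eigenvalue ",
         format(min(ev)), "); pass shrinkage > 0 or use a longer window",
         call. = FALSE)
  P
}

# covariance cube for all trials of an epoch window, with the automatic
# minimal-shrinkage fallback for near-singular estimates
scm_set <- function(epochs, shrinkage = 0, center = FALSE) {
  X <- epochs_to_cube(epochs)
  if (dim(X)[2L] < 2L)
    stop("at least 2 samples are required to estimate a covariance", call. = FALSE)
  if (shrinkage == 0 && dim(X)[2L] < dim(X)[1L])
    stop("rank-deficient covariance: ", dim(X)[2L], " samples < ",
         dim(X)[1L], " channels at shrinkage 0", call. = FALSE)
  P <- cpp_scm_cube(X, shrinkage, center)
  if (shrinkage == 0) {
    ev1 <- apply(P, 3, function(M)
      range(eigen(M, symmetric = TRUE, only.values = TRUE)$values))
    bad <- ev1[1L, ] <= 1e-12 * ev1[2L, ]
    if (any(bad)) {
      warning(sum(bad), " trial covariance(s) nearly singular; applying 1e-6 ",
              "relative shrinkage", call. = FALSE)
      P <- cpp_scm_cube(X, 1e-6, center)
    }
  }
  P
}

#' Geodesic (affine-invariant Riemannian) distance between SPD matrices
#'
#' `sqrt(sum(log(lambda_i)^2))` where `lambda_i` are the eigenvalues of
#' `solve(P1) %*% P2`, computed via a Cholesky-whitened symmetric
#' eigenproblem. Invariant under congruence `P -> t(W) %*% P %*% W` for any
#' invertible `W`.
#'
#' @param P1,P2 SPD matrices of equal dimension.
#' @return Nonnegative scalar distance.
#' @examples
#' riemannian_distance(diag(2), exp(2) * diag(2)) # 2 * sqrt(2)
#' @export
riemannian_distance <- function(P1, P2) {
  assert_spd(P1, "P1"); assert_spd(P2, "P2"); assert_same_dim(P1, P2)
  cpp_airm_dist(P1, P2)
}

#' Euclidean (Frobenius) distance between matrices
#'
#' @inheritParams riemannian_distance
#' @return `norm(P1 - P2, "F")`.
#' @export
euclidean_distance <- function(P1, P2) {
  if (!is_square(P1) || !is_square(P2))
    stop("inputs must be square matrices", call. = FALSE)
  assert_same_dim(P1, P2)
  norm(P1 - P2, "F")
}

#' Exponential map on the SPD manifold
#'
#' Maps a tangent vector (symmetric matrix) `S` at base point `P` back to the
#' manifold: `P^{1/2} expm(P^{-1/2} S P^{-1/2}) P^{1/2}`.
#'
#' @param P SPD base point.
#' @param S symmetric matrix of the same dimension.
#' @return An SPD matrix.
#' @export
exp_map <- function(P, S) {
  assert_spd(P, "P"); assert_symmetric(S, "S"); assert_same_dim(P, S)
  Ph <- cpp_sqrtm_spd(P); Pm <- cpp_invsqrtm_spd(P)
  M <- Ph %*% cpp_expm_sym(Pm %*% S %*% Pm) %*% Ph
  (M + t(M)) / 2
}

#' Logarithmic map on the SPD manifold
#'
#' Inverse of [exp_map()]: the tangent vector at `P` pointing to `Pi`,
#' `P^{1/2} logm(P^{-1/2} Pi P^{-1/2}) P^{1/2}`.
#'
#' @param P SPD base point.
#' @param Pi SPD matrix of the same dimension.
#' @return A symmetric matrix.
#' @export
log_map <- function(P, Pi) {
  assert_spd(P, "P"); assert_spd(Pi, "Pi"); assert_same_dim(P, Pi)
  Ph <- cpp_sqrtm_spd(P); Pm <- cpp_invsqrtm_spd(P)
  M <- Ph %*% cpp_logm_spd(Pm %*% Pi %*% Pm) %*% Ph
  (M + t(M)) / 2
}

#' Euclidean (arithmetic) mean of SPD matrices
#'
#' @param covs list of SPD matrices or an n x n x I array.
#' @return The elementwise average matrix.
#' @export
euclidean_mean <- function(covs) {
  P <- as_cov_cube(covs)
  apply(P, c(1, 2), mean)
}

#' Riemannian (Karcher/Frechet) mean of SPD matrices
#'
#' The SPD matrix minimizing the sum of squared geodesic distances to the
#' set, found by fixed-point iteration `M <- Exp_M(mean_i Log_M(P_i))`
#' initialized at the arithmetic mean. Convergence is declared when the
#' Frobenius norm of the mean whitened log (the manifold gradient) drops
#' below `tol`.
#'
#' @param covs list of SPD matrices or an n x n x I array.
#' @param tol convergence tolerance on the gradient norm.
#' @param max_iter maximum number of fixed-point iterations.
#' @return An SPD matrix with attributes `grad_norm` and `iterations`.
#' @examples
#' riemannian_mean(list(diag(2), diag(c(4, 4)))) # diag(2, 2)
#' @export
riemannian_mean <- function(covs, tol = 1e-8, max_iter = 200L) {
  P <- as_cov_cube(covs)
  res <- cpp_karcher_mean(P, tol, as.integer(max_iter))
  if (!res$converged)
    stop("Riemannian mean did not converge in ", max_iter,
         " iterations (gradient norm ", format(res$grad_norm), ")",
         call. = FALSE)
  structure(res$mean, grad_norm = res$grad_norm, iterations = res$iterations)
}

#' Tangent-space coordinates of SPD matrices at a reference point
#'
#' Whitens each matrix by the reference, takes the matrix logarithm, and
#' vectorizes the upper triangle row-major (diagonal first within each row)
#' with off-diagonal entries weighted by `sqrt(2)`, so that each row's
#' Euclidean norm equals the geodesic distance to the reference.
#'
#' @param covs list of SPD matrices or an n x n x I array.
#' @param reference SPD reference point (typically the Riemannian mean).
#' @return Numeric matrix, trials x `n*(n+1)/2`.
#' @examples
#' tangent_space_map(list(diag(c(exp(2), 1))), diag(2)) # c(2, 0, 0)
#' @export
tangent_space_map <- function(covs, reference) {
  assert_spd(reference, "reference")
  P <- as_cov_cube(covs)
  if (dim(P)[1L] != nrow(reference))
    stop("reference dimension does not match the covariance matrices",
         call. = FALSE)
  cpp_tangent_map(P, reference)
}

# index of the row-major upper-triangle vectorization used by
# tangent_space_map: tibble with columns row, col for each position
upper_index <- function(n) {
  rows <- rep(seq_len(n), times = n - seq_len(n) + 1L)
  cols <- unlist(lapply(seq_len(n), function(i) i:n))
  tibble::tibble(row = rows, col = cols)
}
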