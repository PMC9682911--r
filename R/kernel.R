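#' Tanimoto kernel between two count vectors
#'
#' Computes the Tanimoto (Jaccard/minmax-style) covariance
#' \deqn{k(x, x') = \sigma_f^2 \frac{\langle x, x'\rangle}
#'   {\|x\|^2 + \|x'\|^2 - \langle x, x'\rangle}}
#' between two non-negative bit/count vectors. This is a valid positive
#' semidefinite kernel on non-negative vectors, bounded in
#' `[0, sigma_f2]`, and equal to `sigma_f2` when `x == x2`.
#'
#' @param x,x2 Non-negative numeric vectors of equal length (fingerprint bits
#'   and/or fragment counts).
#' @param sigma_f2 Signal variance (kernel amplitude), a positive scalar.
#' @return A single covariance value.
#' @export
#' @examples
#' tanimoto_kernel(c(1, 1, 0), c(1, 0, 1), sigma_f2 = 2) # 2 * 1/(2 + 2 - 1)
tanimoto_kernel <- function(x, x2, sigma_f2 = 1) {
  stopifnot(length(x) == length(x2), sigma_f2 > 0)
  if (any(x < 0) || any(x2 < 0)) stop("Tanimoto kernel requires non-negative vectors")
  s <- sum(x * x2)
  denom <- sum(x * x) + sum(x2 * x2) - s
  if (denom == 0) stop("Tanimoto similarity undefined: both vectors are all-zero")
  sigma_f2 * s / denom
}

#' Tanimoto Gram matrix
#'
#' Vectorised Tanimoto similarity between the rows of two feature matrices.
#' Used internally to build GP covariance matrices; exported because it is
#' also useful for diversity analyses.
#'
#' @param x Numeric matrix (n1 x d), rows are molecules.
#' @param x2 Optional numeric matrix (n2 x d); defaults to `x`.
#' @param sigma_f2 Signal variance multiplier.
#' @return An n1 x n2 matrix of covariances.
#' @export
tanimoto_gram <- function(x, x2 = NULL, sigma_f2 = 1) {
  x <- as.matrix(x)
  x2 <- if (is.null(x2)) x else as.matrix(x2)
  stopifnot(ncol(x) == ncol(x2))
  if (any(x < 0) || any(x2 < 0)) stop("Tanimoto kernel requires non-negative vectors")
  s <- x %*% t(x2)
  denom <- outer(rowSums(x^2), rowSums(x2^2), "+") - s
  if (any(denom == 0)) {
    stop("Tanimoto similarity undefined: an all-zero feature vector is present")
  }
  sigma_f2 * s / denom
}

#' Intrinsic-coregionalisation (ICM) covariance
#'
#' Multitask covariance between observation (x, task i) and (x2, task j):
#' the shared Tanimoto input kernel scaled by the task-covariance entry,
#' `k(x, x2) * B[i, j]` with `B = L %*% t(L)` positive semidefinite by
#' construction.
#'
#' @param x,x2 Non-negative feature vectors.
#' @param i,j Tasks (name or index, see [azogp_tasks()]).
#' @param L Lower-triangular matrix whose Cholesky product defines the task
#'   covariance `B`; 4 x 4 for the full wavelength problem.
#' @param sigma_f2 Signal variance of the shared input kernel.
#' @return A single covariance value.
#' @export
icm_covariance <- function(x, x2, i, j, L, sigma_f2 = 1) {
  L <- as.matrix(L)
  stopifnot(nrow(L) == ncol(L))
  B <- L %*% t(L)
  ti <- if (is.character(i)) match(match_task(i), .TASKS) else as.integer(i)
  tj <- if (is.character(j)) match(match_task(j), .TASKS) else as.integer(j)
  stopifnot(ti >= 1, ti <= nrow(B), tj >= 1, tj <= nrow(B))
  tanimoto_kernel(x, x2, sigma_f2 = sigma_f2) * B[ti, tj]
}

# Cholesky with escalating jitter: start at 1e-6 * mean diagonal and multiply
# by 10 up to 1e-2 * mean diagonal before giving up. Returns the lower factor.
chol_with_jitter <- function(K) {
  scale <- mean(diag(K))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  jit <- 1e-6 * scale
  repeat {
    ch <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(ch)) {
      return(list(L = t(ch), jitter = jit))
    }
    jit <- jit * 10
    if (jit > 1e-2 * scale) {
      stop(sprintf(
        "covariance matrix not positive definite after maximum jitter (%.3g); n = %d, mean diag = %.3g",
        jit / 10, nrow(K), scale
      ))
    }
  }
}

# Gaussian log marginal likelihood and its gradient for a covariance
# K = K_signal + sigma_y2 * I, given precomputed pieces. Shared by the
# single-task and multitask fits.  Returns list(lml, alpha, chL, Kinv).
gauss_lml_pieces <- function(K, y) {
  n <- length(y)
  ch <- chol_with_jitter(K)
  Lc <- ch$L
  alpha <- backsolve(t(Lc), forwardsolve(Lc, y))
  lml <- -0.5 * sum(y * alpha) - sum(log(diag(Lc))) - 0.5 * n * log(2 * pi)
  list(lml = lml, alpha = alpha, chL = Lc, jitter = ch$jitter)
}
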