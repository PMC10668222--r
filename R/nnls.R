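#' Non-negative least squares
#'
#' Solves `min ||A x - b||^2` subject to `x >= 0` with the Lawson--Hanson
#' active-set algorithm, run on the normal equations.  A tiny ridge
#' (`1e-12`) stabilizes the passive-set solves when the columns of `A` are
#' nearly collinear, as they are for densely spaced Gaussian tuning
#' curves.
#'
#' @param A design matrix (m x n).
#' @param b response vector (length m).
#' @param tol relative tolerance on the dual feasibility test.
#' @param maxit cap on active-set iterations.
#' @return a list with `x` (the non-negative solution), `fitted`,
#'   `residual_rms` and `iterations`.
#' @export
nnls <- function(A, b, tol = 1e-10, maxit = 1000L) {
  if (!is.matrix(A) || !is.numeric(A)) stop("'A' must be a numeric matrix")
  stop_if_not_numeric(b, "b")
  if (nrow(A) != length(b)) stop("nrow(A) must equal length(b)")
  x <- nnls_normal(crossprod(A), drop(crossprod(A, b)), tol = tol,
                   maxit = maxit)
  fitted <- drop(A %*% x$x)
  list(x = x$x, fitted = fitted,
       residual_rms = sqrt(mean((fitted - b)^2)),
       iterations = x$iterations)
}

# Lawson-Hanson on precomputed normal equations (AtA, Atb); used when many
# right-hand sides share one design matrix
nnls_normal <- function(AtA, Atb, tol = 1e-10, maxit = 1000L) {
  n <- length(Atb)
  P <- logical(n)
  x <- numeric(n)
  w <- Atb
  thresh <- tol * max(abs(Atb), 1e-300)
  it <- 0L
  while (any(!P) && any(w[!P] > thresh) && it < maxit) {
    it <- it + 1L
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[P] <- solve(AtA[P, P, drop = FALSE] + diag(1e-12, sum(P)), Atb[P])
      if (all(s[P] > 0)) {
        x <- s
        break
      }
      Q <- P & (s <= 0)
      alpha <- min(x[Q] / (x[Q] - s[Q]))
      x <- x + alpha * (s - x)
      P[P] <- x[P] > tol * max(x)
      x[!P] <- 0
    }
    w <- Atb - drop(AtA %*% x)
  }
  list(x = x, iterations = it)
}
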