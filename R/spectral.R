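#' Spectral radius of a nonnegative adjacency matrix
#'
#' For symmetric input below `dense_cap` vertices a dense symmetric
#' eigensolver is used; at or above the cap a Lanczos iteration with full
#' reorthogonalization computes the extreme eigenvalue of the shifted
#' matrix `A + I` (the shift makes the Perron root the unique extreme
#' eigenvalue even for bipartite layers, whose extreme eigenvalues come in
#' +/- pairs). Convergence is declared when the residual estimate
#' `beta_m |e_m' y|` falls below `tol * max(1, lambda)`, which bounds the
#' eigenvalue error for symmetric matrices. Non-symmetric nonnegative input
#' (directed flow networks) uses power iteration on `A + I`, stopping when
#' both the Rayleigh-quotient change and the residual fall below `tol`.
#' Non-convergence within the iteration caps is an explicit error, never a
#' silent value.
#'
#' @param A square nonnegative matrix (base matrix or `Matrix` sparse).
#' @param tol convergence tolerance (default 1e-8).
#' @param max_iter power-iteration cap (non-symmetric path).
#' @param dense_cap below this dimension, symmetric input goes to the dense
#'   solver (default 500).
#' @param symmetric logical or `NA` (auto-detect).
#' @return the spectral radius (numeric scalar, >= 0), with attributes
#'   `method` and `iterations`.
#' @export
#' @examples
#' A <- matrix(1, 4, 4) - diag(4)
#' spectral_radius(A)  # complete graph on 4 vertices: 3
spectral_radius <- function(A, tol = 1e-8, max_iter = 200000L,
                            dense_cap = 500L, symmetric = NA) {
  n <- nrow(A)
  if (n != ncol(A)) stop("A must be square")
  if (n == 0L) return(structure(0, method = "empty", iterations = 0L))
  if (is.na(symmetric)) symmetric <- Matrix::isSymmetric(A)
  if (symmetric && n < dense_cap) {
    lam <- max(eigen(as.matrix(A), symmetric = TRUE, only.values = TRUE)$values)
    return(structure(max(lam, 0), method = "dense", iterations = 0L))
  }
  if (symmetric) return(lanczos_radius(A, tol = tol))
  # power iteration on the shifted matrix B = A + I
  v <- rep(1 / sqrt(n), n)
  lam <- 1
  it <- 0L
  check_every <- 10L
  repeat {
    for (b in seq_len(check_every)) {
      w <- as.numeric(A %*% v) + v
      nw <- sqrt(sum(w * w))
      if (nw == 0) return(structure(0, method = "power", iterations = it))
      v <- w / nw
      it <- it + 1L
    }
    w <- as.numeric(A %*% v) + v
    lam_new <- sum(v * w)                 # Rayleigh quotient of B
    res <- sqrt(sum((w - lam_new * v)^2)) # residual 2-norm
    ok <- if (symmetric) res <= tol * max(1, abs(lam_new))
          else res <= tol * max(1, abs(lam_new)) && abs(lam_new - lam) <= tol
    lam <- lam_new
    if (ok) break
    if (it >= max_iter)
      stop(sprintf("power iteration failed to converge in %d iterations (residual %.3g)",
                   it, res))
  }
  structure(max(lam - 1, 0), method = "power", iterations = it)
}

# Largest eigenvalue of symmetric nonnegative A via Lanczos on B = A + I
# with full reorthogonalization. The shift pins the Perron root as the
# unique largest eigenvalue of B; the residual bound |lam - lam_hat| <=
# beta_m |e_m' y| holds because B is symmetric.
lanczos_radius <- function(A, tol = 1e-8, max_basis = 600L) {
  n <- nrow(A)
  V <- matrix(0, n, max_basis)
  alpha <- numeric(max_basis); beta <- numeric(max_basis)
  v <- rep(1 / sqrt(n), n)
  V[, 1] <- v
  b_prev <- 0; v_prev <- numeric(n)
  top_of_tridiag <- function(m) {
    Tm <- diag(alpha[1:m], m, m)
    if (m > 1) {
      idx <- cbind(1:(m - 1), 2:m)
      Tm[idx] <- beta[1:(m - 1)]
      Tm[idx[, c(2, 1), drop = FALSE]] <- beta[1:(m - 1)]
    }
    ed <- eigen(Tm, symmetric = TRUE)
    list(lam = ed$values[1], tail = abs(ed$vectors[m, 1]))
  }
  for (m in seq_len(max_basis)) {
    w <- as.numeric(A %*% V[, m]) + V[, m]          # B v
    a <- sum(w * V[, m])
    w <- w - a * V[, m] - b_prev * v_prev
    # full reorthogonalization against the basis built so far
    w <- as.numeric(w - V[, 1:m, drop = FALSE] %*%
                      crossprod(V[, 1:m, drop = FALSE], w))
    alpha[m] <- a
    b <- sqrt(sum(w * w))
    exhausted <- b <= .Machine$double.eps * 100 * max(1, abs(a))
    if (exhausted || m %% 20L == 0L || m == max_basis) {
      tt <- top_of_tridiag(m)
      resid <- b * tt$tail
      if (exhausted || resid <= tol * max(1, abs(tt$lam))) {
        return(structure(max(tt$lam - 1, 0), method = "lanczos",
                         iterations = m))
      }
    }
    if (m == max_basis)
      stop(sprintf("Lanczos failed to converge within %d iterations", m))
    beta[m] <- b
    b_prev <- b; v_prev <- V[, m]
    V[, m + 1] <- w / b
  }
}

#' Full spectrum of an adjacency matrix
#'
#' Dense symmetric eigendecomposition, capped to keep memory and time
#' bounded; the spectral radius of large instances should instead use
#' [spectral_radius()].
#'
#' @param A symmetric matrix (base or sparse).
#' @param dense_cap refuse inputs larger than this (default 5000).
#' @return object of class `mpsn_spectrum`: list with `values` (sorted
#'   descending) and `tol` (solver tolerance indicator, 0 for direct dense).
#' @export
graph_spectrum <- function(A, dense_cap = 5000L) {
  n <- nrow(A)
  if (n > dense_cap)
    stop(sprintf("matrix dimension %d exceeds dense cap %d", n, dense_cap))
  vals <- sort(eigen(as.matrix(A), symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
  structure(list(values = vals, tol = 0), class = "mpsn_spectrum")
}

#' @export
print.mpsn_spectrum <- function(x, ...) {
  cat(sprintf("spectrum of %d eigenvalues; lambda1 = %.6f, lambda_min = %.6f\n",
              length(x$values), x$values[1], x$values[length(x$values)]))
  invisible(x)
}
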