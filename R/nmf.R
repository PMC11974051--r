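# Non-negative matrix factorization with NNDSVD initialisation and
# multiplicative (Frobenius) updates. Written for the residual-recovery
# setting: small k, deterministic runs, dense matrices of moderate size.

#' Nonnegative Double Singular Value Decomposition initialisation
#'
#' Deterministic NMF initialisation of Boutsidis & Gallopoulos: the leading
#' singular triplet seeds the first factor; each further factor uses the
#' dominant non-negative section of its singular vector pair. Exact zeros
#' are replaced by a small epsilon so multiplicative updates cannot lock
#' entries at zero.
#'
#' @param a Non-negative matrix.
#' @param k Number of factors, `k <= min(dim(a))`.
#' @param eps Replacement value for exact zeros (default 1e-10).
#' @return List with `w` (rows x k) and `h` (k x cols), both positive.
#' @export
nndsvd_init <- function(a, k, eps = 1e-10) {
  stopifnot(is.matrix(a), all(a >= 0), k >= 1, k <= min(dim(a)))
  sv <- svd(a, nu = k, nv = k)
  w <- matrix(0, nrow(a), k)
  h <- matrix(0, k, ncol(a))
  w[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  h[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      x <- sv$u[, j]
      y <- sv$v[, j]
      xp <- pmax(x, 0); xn <- pmax(-x, 0)
      yp <- pmax(y, 0); yn <- pmax(-y, 0)
      nxp <- sqrt(sum(xp^2)); nyp <- sqrt(sum(yp^2))
      nxn <- sqrt(sum(xn^2)); nyn <- sqrt(sum(yn^2))
      if (nxp * nyp >= nxn * nyn) {
        sig <- nxp * nyp
        u <- if (nxp > 0) xp / nxp else xp
        v <- if (nyp > 0) yp / nyp else yp
      } else {
        sig <- nxn * nyn
        u <- if (nxn > 0) xn / nxn else xn
        v <- if (nyn > 0) yn / nyn else yn
      }
      w[, j] <- sqrt(sv$d[j] * sig) * u
      h[j, ] <- sqrt(sv$d[j] * sig) * v
    }
  }
  w[w < eps] <- eps
  h[h < eps] <- eps
  list(w = w, h = h)
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimises the Frobenius reconstruction error with the classic Lee-Seung
#' multiplicative update rules, starting from [nndsvd_init()], so runs are
#' fully deterministic. Iteration stops when the relative change of the
#' reconstruction error falls below `tol` (checked every 10 iterations) or
#' at `max_iter`.
#'
#' @param a Non-negative matrix (rows x cols).
#' @param k Number of factors.
#' @param max_iter Iteration cap (default 10000).
#' @param tol Relative-change convergence tolerance (default 1e-5).
#' @return List with `w`, `h`, `n_iterations_used`, `converged`,
#'   `reconstruction_error` (Frobenius norm of `a - w h`).
#' @export
nmf_factorize <- function(a, k, max_iter = 10000L, tol = 1e-5) {
  stopifnot(is.matrix(a), all(a >= 0))
  init <- nndsvd_init(a, k)
  w <- init$w
  h <- init$h
  eps <- .Machine$double.eps
  err_old <- sqrt(sum((a - w %*% h)^2))
  n_used <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    h <- h * (crossprod(w, a)) / (crossprod(w) %*% h + eps)
    w <- w * (a %*% t(h)) / (w %*% tcrossprod(h) + eps)
    n_used <- it
    if (it %% 10L == 0L || it == max_iter) {
      err <- sqrt(sum((a - w %*% h)^2))
      if (abs(err_old - err) <= tol * max(err_old, eps)) {
        converged <- TRUE
        err_old <- err
        break
      }
      err_old <- err
    }
  }
  list(w = w, h = h,
       n_iterations_used = n_used,
       converged = converged,
       reconstruction_error = sqrt(sum((a - w %*% h)^2)))
}
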