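# Knight-Ruiz matrix balancing: diagonal scaling of a symmetric nonnegative
# contact matrix so that every unmasked row sum equals 1, correcting coverage
# bias. Implements the inner-outer Newton iteration of Knight & Ruiz (the
# conjugate-gradient inner solve with delta/Delta safeguarding), with a
# damped Sinkhorn fallback if the Newton iteration fails to converge.

#' Knight-Ruiz balancing weights
#'
#' Computes per-bin weights `w` such that the scaled matrix
#' `M'[i,j] = w[i] * M[i,j] * w[j]` has all unmasked row sums equal to 1
#' within `tol`. Bins with zero marginal, or with marginal below the
#' `mask_quantile` quantile of nonzero marginals, are masked first and get
#' weight `NA`.
#'
#' @param mat a raw `cifi_matrix`, or a plain symmetric nonnegative matrix.
#' @param tol convergence tolerance on row sums (default 1e-6).
#' @param max_iter maximum outer iterations (default 300).
#' @param mask_quantile marginal quantile (of nonzero marginals) below which
#'   bins are masked (default 0.02).
#' @return for a `cifi_matrix` input: a new `cifi_matrix` with `weights` set
#'   and `normalization` = `"KR"` (or `"KR-sinkhorn"` if the fallback was
#'   used). For a plain matrix: the numeric weight vector with attributes
#'   `converged` and `method`. Failure of both methods raises an error and
#'   leaves the input untouched.
#' @export
kr_balance <- function(mat, tol = 1e-6, max_iter = 300L, mask_quantile = 0.02) {
  is_cm <- inherits(mat, "cifi_matrix")
  A <- if (is_cm) full_symmetric(mat$counts) else methods::as(mat, "CsparseMatrix")
  if (nrow(A) != ncol(A)) stop("matrix must be square")
  n <- nrow(A)
  marg <- as.numeric(A %*% rep(1, n))
  nz <- marg > 0
  cutoff <- if (any(nz)) stats::quantile(marg[nz], mask_quantile) else Inf
  keep <- which(nz & marg >= cutoff)
  if (length(keep) < 2L) stop("kr_balance: fewer than 2 unmasked bins")
  Asub <- A[keep, keep, drop = FALSE]
  # masking can zero out further rows; iterate until stable
  repeat {
    rs <- as.numeric(Asub %*% rep(1, nrow(Asub)))
    ok <- rs > 0
    if (all(ok)) break
    keep <- keep[ok]
    Asub <- A[keep, keep, drop = FALSE]
  }
  x <- kr_core(Asub, tol = tol, max_iter = max_iter)
  method <- "KR"
  if (is.null(x)) {
    x <- sinkhorn_core(Asub, tol = tol, max_iter = 3000L)
    method <- "KR-sinkhorn"
    if (is.null(x))
      stop("kr_balance: neither Knight-Ruiz nor Sinkhorn converged after max_iter")
  }
  w <- rep(NA_real_, n)
  w[keep] <- x
  if (!is_cm) {
    attr(w, "converged") <- TRUE
    attr(w, "method") <- method
    return(w)
  }
  out <- mat
  out$weights <- w
  out$normalization <- method
  out
}

# Knight-Ruiz inner-outer iteration. Returns the scaling vector x with
# diag(x) A diag(x) doubly stochastic, or NULL on non-convergence.
kr_core <- function(A, tol = 1e-6, max_iter = 300L,
                    delta = 0.1, Delta = 3) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  g <- 0.9
  etamax <- 0.1
  eta <- etamax
  stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * as.numeric(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1
  rold <- rout
  i <- 0L
  while (rout > rt) {
    i <- i + 1L
    if (i > max_iter) return(NULL)
    k <- 0L
    y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- numeric(n)
    while (rho_km1 > innertol) {
      k <- k + 1L
      if (k == 1L) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      if (k > 10L * n + 50L) return(NULL)  # stalled inner CG
      w <- x * as.numeric(A %*% (x * p)) + v * p
      denom <- sum(p * w)
      if (!is.finite(denom) || denom <= 0) return(NULL)
      alpha <- rho_km1 / denom
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
    }
    x <- x * y
    if (any(!is.finite(x)) || any(x <= 0)) return(NULL)
    v <- x * as.numeric(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    # eta adjustment (heuristic forcing sequence from the original method)
    rat <- rout / rold
    rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / res_norm)
  }
  x
}

# Damped Sinkhorn fallback: alternately rescale rows/cols of the symmetric
# matrix; damping via sqrt keeps the symmetric iteration stable.
sinkhorn_core <- function(A, tol = 1e-6, max_iter = 3000L) {
  n <- nrow(A)
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    r <- x * as.numeric(A %*% x)
    if (any(r <= 0) || any(!is.finite(r))) return(NULL)
    if (max(abs(r - 1)) < tol) return(x)
    x <- x / sqrt(r)
  }
  NULL
}
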