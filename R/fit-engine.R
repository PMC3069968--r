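## Vectorized damped least-squares engine.
##
## All voxelwise fits in the package go through one Levenberg-Marquardt
## loop that iterates over every voxel simultaneously: residuals and
## Jacobians are V x K matrices, normal equations are solved in closed form
## per voxel (p <= 3), and per-voxel damping factors adapt independently.
## This keeps whole-slab nonlinear fits in plain R at interactive speed and
## makes them exactly reproducible.

## Solve (A + lam*diag(A)) delta = g for symmetric p x p systems stored
## column-wise, vectorized over rows. a11, a12, ... are vectors.
solve_damped_2 <- function(a11, a12, a22, g1, g2, lam) {
  d11 <- a11 * (1 + lam); d22 <- a22 * (1 + lam)
  det <- d11 * d22 - a12^2
  det[abs(det) < 1e-300] <- NA
  cbind((g1 * d22 - g2 * a12) / det,
        (g2 * d11 - g1 * a12) / det)
}

solve_damped_3 <- function(A, g, lam) {
  a11 <- A[, 1] * (1 + lam); a22 <- A[, 4] * (1 + lam); a33 <- A[, 6] * (1 + lam)
  a12 <- A[, 2]; a13 <- A[, 3]; a23 <- A[, 5]
  c11 <- a22 * a33 - a23^2
  c12 <- a13 * a23 - a12 * a33
  c13 <- a12 * a23 - a13 * a22
  c22 <- a11 * a33 - a13^2
  c23 <- a12 * a13 - a11 * a23
  c33 <- a11 * a22 - a12^2
  det <- a11 * c11 + a12 * c12 + a13 * c13
  det[abs(det) < 1e-300] <- NA
  cbind((c11 * g[, 1] + c12 * g[, 2] + c13 * g[, 3]) / det,
        (c12 * g[, 1] + c22 * g[, 2] + c23 * g[, 3]) / det,
        (c13 * g[, 1] + c23 * g[, 2] + c33 * g[, 3]) / det)
}

#' Voxelwise damped (Levenberg-Marquardt) least squares
#'
#' Minimizes \code{sum_k (Y[v,k] - fun(P)[v,k])^2} independently for every
#' voxel v, with box constraints applied by projection. Iterates until the
#' largest relative parameter change of an accepted step falls below
#' \code{tol} (default 1e-8) or \code{max_iter} iterations.
#'
#' @param Y V x K data matrix (rows = voxels, columns = frames)
#' @param fun model: maps a V x p parameter matrix to a V x K prediction
#' @param jac Jacobian: maps parameters to a list of p V x K matrices
#' @param par0 V x p starting values
#' @param lower,upper parameter bounds (length p)
#' @param tol relative-change convergence tolerance
#' @param max_iter iteration cap
#' @return list with \code{par} (V x p), logical \code{converged}, and
#'   \code{rss} per voxel
#' @export
fit_voxels_lm <- function(Y, fun, jac, par0, lower, upper,
                          tol = 1e-8, max_iter = 200L) {
  P <- as.matrix(par0)
  V <- nrow(P); p <- ncol(P)
  lam <- rep(1e-3, V)
  Fv <- fun(P)
  R <- Y - Fv
  sse <- rowSums(R^2)
  active <- rep(TRUE, V)
  converged <- rep(FALSE, V)
  clip <- function(M) {
    for (j in seq_len(p)) M[, j] <- pmin(pmax(M[, j], lower[j]), upper[j])
    M
  }
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    J <- jac(P)
    if (p == 1L) {
      a11 <- rowSums(J[[1]]^2); g1 <- rowSums(J[[1]] * R)
      delta <- matrix(g1 / (a11 * (1 + lam)), ncol = 1)
    } else if (p == 2L) {
      a11 <- rowSums(J[[1]]^2); a12 <- rowSums(J[[1]] * J[[2]])
      a22 <- rowSums(J[[2]]^2)
      delta <- solve_damped_2(a11, a12, a22,
                              rowSums(J[[1]] * R), rowSums(J[[2]] * R), lam)
    } else {
      A <- cbind(rowSums(J[[1]]^2), rowSums(J[[1]] * J[[2]]),
                 rowSums(J[[1]] * J[[3]]), rowSums(J[[2]]^2),
                 rowSums(J[[2]] * J[[3]]), rowSums(J[[3]]^2))
      g <- cbind(rowSums(J[[1]] * R), rowSums(J[[2]] * R), rowSums(J[[3]] * R))
      delta <- solve_damped_3(A, g, lam)
    }
    delta[!is.finite(delta)] <- 0
    delta[!active, ] <- 0
    Pnew <- clip(P + delta)
    Fnew <- fun(Pnew)
    Rnew <- Y - Fnew
    sse_new <- rowSums(Rnew^2)
    better <- active & (sse_new <= sse)
    rs <- abs(Pnew - P) / pmax(abs(P), 1e-12)
    relstep <- rs[, 1]
    for (j in seq_len(p)[-1]) relstep <- pmax(relstep, rs[, j])
    if (any(better)) {
      P[better, ] <- Pnew[better, , drop = FALSE]
      R[better, ] <- Rnew[better, , drop = FALSE]
      sse[better] <- sse_new[better]
      lam[better] <- pmax(lam[better] / 4, 1e-12)
      done <- better & (relstep < tol)
      converged[done] <- TRUE
      active[done] <- FALSE
    }
    worse <- active & !better
    lam[worse] <- lam[worse] * 8
    stalled <- active & (lam > 1e13)
    converged[stalled] <- TRUE   # no further descent possible
    active[stalled] <- FALSE
  }
  list(par = P, converged = converged, rss = sse, iterations = it)
}
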