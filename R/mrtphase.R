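# Assembly of the noise-induced drift term Omega(x), gauge-fixed
# least-squares solution of the phase-offset equation
#     L^dagger[dpsi] = Omega(x) + (2*pi/Tbar - omega),
# and the mean-return-time phase Theta = psi + dpsi.
#
# Omega and the right-hand side are computed branch-cut free from the
# complex eigenfunction Q = u e^{i psi} via grad(Q)/Q, whose real part is
# grad(ln u) and whose imaginary part is grad(psi).

#' Noise-induced drift term Omega(x) of the asymptotic phase
#'
#' \deqn{\Omega(x) = 2 \sum_{ij} G_{ij}\,\partial_i \ln u\,\partial_j \psi}
#' computed from the complex eigenfunction via
#' \eqn{\nabla \ln u = \Re(\nabla Q / Q)}, \eqn{\nabla\psi = \Im(\nabla Q/Q)}
#' with centered differences, which avoids the \eqn{2\pi} branch cut of the
#' wrapped phase.  The term diverges toward the phaseless point where
#' \eqn{u \to 0}.
#'
#' @param field a \code{phase_field} carrying the complex eigenfunction
#'   \code{Q} (from \code{\link{amplitude_phase}}).
#' @param model the \code{langevin_model}.
#' @return numeric vector of Omega values on the grid.
#' @export
omega_term <- function(field, model) {
  stopifnot(inherits(field, "phase_field"), !is.null(field$Q))
  g <- field$grid
  Q <- field$Q
  DX <- .op_dx(g); DY <- .op_dy(g)
  dQx <- as.numeric(DX %*% Re(Q)) + 1i * as.numeric(DX %*% Im(Q))
  dQy <- as.numeric(DY %*% Re(Q)) + 1i * as.numeric(DY %*% Im(Q))
  wx <- dQx / Q; wy <- dQy / Q
  a1 <- Re(wx); a2 <- Re(wy)   # grad ln u
  p1 <- Im(wx); p2 <- Im(wy)   # grad psi
  fl <- model_fields(model, grid_points(g))
  2 * (fl$G11 * a1 * p1 + fl$G12 * (a1 * p2 + a2 * p1) + fl$G22 * a2 * p2)
}

#' Solve the phase-offset equation by gauge-fixed damped least squares
#'
#' Minimizes the residual of \eqn{L^\dagger[\Delta\psi] = \Omega + \Delta\omega}
#' over the grid rows whose node lies outside an exclusion disc of radius
#' \code{r_min} around the phaseless point (where the right-hand side is
#' numerically unreliable), with a small Tikhonov damping that also fixes
#' the constant gauge freedom; the gauge is then pinned exactly by
#' subtracting the value at the anchor node.  Nodes inside the exclusion
#' disc are filled by harmonic (Laplace) inpainting from the surrounding
#' ring.
#'
#' @param Lbwd the backward \code{discrete_operator}.
#' @param Omega right-hand-side drift term (from \code{\link{omega_term}}).
#' @param delta_omega the frequency mismatch \eqn{2\pi/\bar T - \omega}.
#' @param phaseless the phaseless point (exclusion-disc center).
#' @param anchor point where the offset is gauged to zero (defaults to the
#'   phase-field anchor; falls back to the node of maximal x on the grid
#'   midline if missing).
#' @param r_min exclusion radius (same units as the coordinates); 0 keeps
#'   every row (appropriate when an analytic seed controls the origin, as
#'   for the linear spiral sink).
#' @param seed optional initial guess for \eqn{\Delta\psi}; the solver then
#'   computes a least-squares correction to it.
#' @param weights optional per-row confidence weights (e.g. the squared
#'   eigenfunction amplitude \eqn{u^2}): the right-hand side is computed
#'   from derivatives of \eqn{\ln u} and \eqn{\psi}, whose accuracy degrades
#'   as \eqn{u \to 0}, so rows are trusted in proportion to the amplitude.
#'   Unlike a hard exclusion disc, soft weighting keeps the near-phaseless
#'   rows weakly active, which pins the solution's singular structure and
#'   removes the constant/log-mode ambiguity a hard cut would leave.
#' @param compatibility if \code{TRUE}, the constant \eqn{\Delta\omega} is
#'   refit as a free parameter of the least squares (one extra column),
#'   which in the square case (\code{r_min = 0}) pins it to the discrete
#'   solvability value.  Default \code{FALSE}: the mean period computed
#'   from the conservative face fluxes already satisfies the discrete
#'   solvability condition to rounding-level accuracy, and with an
#'   exclusion disc the refit constant is not identifiable (it trades
#'   against a smooth log-like near-kernel mode).  The refit remains
#'   available as a consistency diagnostic.
#' @param damping Tikhonov damping weight; default \code{1e-8 * opscale}.
#' @param residual_threshold residuals above this flag the solution
#'   (warning and \code{flagged = TRUE}), they never fail silently.
#' @return object of class \code{delta_psi_solution}: \code{delta_psi},
#'   \code{r_min}, \code{residual_max}, \code{residual_rms},
#'   \code{residual_input_max}, \code{delta_omega_input},
#'   \code{delta_omega_used}, \code{retained} (logical mask), \code{anchor},
#'   \code{flagged}.
#' @export
solve_delta_psi <- function(Lbwd, Omega, delta_omega, phaseless,
                            anchor = NULL, r_min = 0, seed = NULL,
                            weights = NULL, compatibility = FALSE,
                            damping = NULL, residual_threshold = 1e-2) {
  stopifnot(inherits(Lbwd, "discrete_operator"), Lbwd$kind == "backward")
  g <- Lbwd$grid
  A <- Lbwd$matrix
  n <- nrow(A)
  Om <- Omega
  bad <- !is.finite(Om)
  Om[bad] <- 0
  pts <- grid_points(g)
  r <- sqrt((pts[, 1] - phaseless[1])^2 + (pts[, 2] - phaseless[2])^2)
  keep <- r >= r_min & !bad
  if (!any(keep)) stop("exclusion disc removed every row")
  if (is.null(weights)) w <- rep(1, n) else {
    stopifnot(length(weights) == n, all(weights >= 0))
    w <- weights / max(weights)
  }
  w[!keep] <- 0
  # rows trusted enough to count toward the reported residual: amplitude
  # above about a third of its maximum (weight > 0.1)
  retained <- keep & w > 0.1
  if (is.null(anchor))
    anchor <- c(g$x[g$N - 2], g$y[round(g$M / 2)])
  if (is.null(damping)) damping <- 1e-8 * max(abs(Matrix::diag(A)))
  act <- which(w > 0)
  Ar <- Matrix::Diagonal(x = w[act]) %*% A[act, , drop = FALSE]
  m <- length(act)
  if (isTRUE(compatibility)) {
    # append the constant as an extra unknown (coefficient -w per row)
    Ar <- cbind(Ar, Matrix::Matrix(-w[act], m, 1))
    br <- w[act] * Om[act]
  } else {
    br <- w[act] * (Om[act] + delta_omega)
  }
  nun <- ncol(Ar)
  if (!is.null(seed)) br <- br - as.numeric(Ar[, seq_len(n)] %*% seed)
  H <- Matrix::crossprod(Ar) + damping^2 * Matrix::Diagonal(nun)
  rhs <- as.numeric(Matrix::crossprod(Ar, br))
  xall <- as.numeric(Matrix::solve(H, rhs))
  x <- xall[seq_len(n)]
  if (!is.null(seed)) x <- x + seed
  delta_omega_used <- if (isTRUE(compatibility)) xall[n + 1] else delta_omega
  # harmonic inpainting, but only of nodes no active row touches: nodes
  # coupled to the active system through stencils are already determined by
  # the solve, and overwriting them would break those rows
  covered <- Matrix::colSums(abs(A[act, , drop = FALSE])) > 0
  inside <- which(!covered)
  if (length(inside) > 0) x <- .laplace_inpaint(g, x, inside)
  # exact gauge: zero at the anchor node
  ka <- grid_index(g, which.min(abs(g$x - anchor[1])),
                   which.min(abs(g$y - anchor[2])))
  x <- x - x[ka]
  res <- as.numeric(A[retained, , drop = FALSE] %*% x) -
    (Om[retained] + delta_omega_used)
  res_in <- res + (delta_omega_used - delta_omega)
  rmax <- max(abs(res)); rrms <- sqrt(mean(res^2))
  flagged <- max(abs(res_in)) > residual_threshold
  if (flagged)
    warning(sprintf("phase-offset residual %.3e exceeds threshold %.1e",
                    max(abs(res_in)), residual_threshold))
  structure(list(delta_psi = x, r_min = r_min, residual_max = rmax,
                 residual_rms = rrms, residual_input_max = max(abs(res_in)),
                 delta_omega_input = delta_omega,
                 delta_omega_used = delta_omega_used,
                 retained = retained, anchor = anchor,
                 anchor_node = ka, grid = g, flagged = flagged),
            class = "delta_psi_solution")
}

#' @export
print.delta_psi_solution <- function(x, ...) {
  cat(sprintf("phase offset: r_min = %g, residual max %.3e rms %.3e%s\n",
              x$r_min, x$residual_max, x$residual_rms,
              if (x$flagged) " [FLAGGED]" else ""))
  invisible(x)
}

# Dirichlet Laplace solve on a small node set with the surrounding values
# as boundary data (smooth fill of the exclusion disc)
.laplace_inpaint <- function(grid, x, inside) {
  n <- grid$N * grid$M
  idx <- rep(NA_integer_, n)
  idx[inside] <- seq_along(inside)
  nd <- grid_node(grid, inside)
  trips_i <- integer(0); trips_j <- integer(0); trips_v <- numeric(0)
  rhs <- numeric(length(inside))
  for (k in seq_along(inside)) {
    i <- nd[k, 1]; j <- nd[k, 2]
    nbrs <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    nbrs <- nbrs[nbrs[, 1] >= 1 & nbrs[, 1] <= grid$N &
                 nbrs[, 2] >= 1 & nbrs[, 2] <= grid$M, , drop = FALSE]
    deg <- nrow(nbrs)
    trips_i <- c(trips_i, k); trips_j <- c(trips_j, k); trips_v <- c(trips_v, deg)
    for (q in seq_len(deg)) {
      kk <- grid_index(grid, nbrs[q, 1], nbrs[q, 2])
      if (is.na(idx[kk])) rhs[k] <- rhs[k] + x[kk]
      else { trips_i <- c(trips_i, k); trips_j <- c(trips_j, idx[kk]); trips_v <- c(trips_v, -1) }
    }
  }
  Lap <- Matrix::sparseMatrix(i = trips_i, j = trips_j, x = trips_v,
                              dims = c(length(inside), length(inside)))
  x[inside] <- as.numeric(Matrix::solve(Lap, rhs))
  x
}

#' Mean-return-time phase Theta = psi + Delta-psi
#'
#' Adds the single-valued phase offset to the asymptotic phase and wraps to
#' \eqn{[0, 2\pi)}.  Both inputs must be gauged at the same anchor so that
#' \eqn{\Theta} is also zero there.
#'
#' @param psi_field the asymptotic-phase \code{phase_field} (anchored via
#'   \code{\link{align_zero_phase}}).
#' @param dpsi a \code{delta_psi_solution} gauged at the same anchor.
#' @return a \code{phase_field} labelled \code{"Theta"} (no complex
#'   eigenfunction attached; the amplitude u is carried over).
#' @export
mrt_phase <- function(psi_field, dpsi) {
  stopifnot(inherits(psi_field, "phase_field"),
            inherits(dpsi, "delta_psi_solution"))
  g <- psi_field$grid
  if (!identical(c(g$N, g$M), c(dpsi$grid$N, dpsi$grid$M)))
    stop("grid mismatch between phase field and phase offset")
  if (!is.null(psi_field$anchor)) {
    ka <- dpsi$anchor_node
    pa <- .phase_at(psi_field, psi_field$anchor[1], psi_field$anchor[2])
    da <- grid_interp(g, dpsi$delta_psi, psi_field$anchor[1], psi_field$anchor[2])
    if (abs(dpsi$anchor[1] - psi_field$anchor[1]) > 2 * g$dx ||
        abs(dpsi$anchor[2] - psi_field$anchor[2]) > 2 * g$dy)
      stop("anchor mismatch between psi and Delta-psi")
    off <- pa + da   # re-zero Theta at the shared anchor
  } else off <- 0
  th <- (psi_field$phase + dpsi$delta_psi - off) %% (2 * pi)
  out <- .new_phase_field(th, psi_field$u, NULL, psi_field$phaseless,
                          psi_field$winding, g, anchor = psi_field$anchor,
                          label = "Theta")
  out
}
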