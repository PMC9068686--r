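# Low-lying spectrum of the discretized operators: stationary density,
# leading complex mode (asymptotic phase), slowest real mode (stochastic
# isostables), and the phase-field utilities built on them.
#
# Eigensolves use shift-invert Arnoldi: a sparse LU factorization of
# (A - sigma I) with a small real shift sigma turns the low-lying eigenvalues
# (the only ones of interest) into the dominant ones of the inverse, which
# ARPACK then finds in a handful of iterations.

# shift-invert Arnoldi via igraph's ARPACK interface
.eigs_shift_invert <- function(A, sigma, nev, ncv = max(4 * nev, nev + 10),
                               maxiter = 5000, tol = 0) {
  n <- nrow(A)
  ncv <- min(ncv, n - 1L)
  lufac <- Matrix::lu(A - sigma * Matrix::Diagonal(n))
  fn <- function(x, extra) as.numeric(Matrix::solve(extra, x))
  res <- igraph::arpack(fn, extra = lufac, sym = FALSE, complex = TRUE,
                        options = list(bmat = "I", n = n, which = "LM",
                                       nev = nev, ncv = ncv, tol = tol,
                                       maxiter = maxiter))
  vals <- sigma + 1 / res$values
  ord <- order(-Re(vals))
  list(values = vals[ord],
       vectors = res$vectors[, ord, drop = FALSE])
}

# magnitude scale of an operator (largest diagonal entry)
.op_scale <- function(op) max(abs(Matrix::diag(op$matrix)))

.new_mode <- function(lambda, fun, kind, grid, normalization = NULL) {
  structure(list(lambda = lambda, fun = fun, kind = kind, grid = grid,
                 normalization = normalization),
            class = "spectral_mode")
}

#' @export
print.spectral_mode <- function(x, ...) {
  cat(sprintf("spectral mode [%s]: lambda = %s\n", x$kind,
              format(x$lambda, digits = 6)))
  invisible(x)
}

#' Low-lying spectrum of the backward operator
#'
#' Computes the \code{nev} eigenvalues of largest real part (and their
#' eigenfunctions) of the discretized backward operator by shift-invert
#' Arnoldi with a small positive real shift.  The result can be passed to
#' \code{\link{leading_complex_mode}} and \code{\link{floquet_mode}} so the
#' factorization is done once.
#'
#' @param op a backward \code{discrete_operator}.
#' @param nev number of eigenvalues to extract.
#' @param sigma real shift; default a small positive multiple of the
#'   operator scale, placed just right of the spectrum.
#' @return object of class \code{backward_spectrum} with \code{values}
#'   (complex, decreasing real part), \code{vectors}, \code{grid}.
#' @export
backward_spectrum <- function(op, nev = 24, sigma = NULL) {
  stopifnot(inherits(op, "discrete_operator"))
  if (is.null(sigma)) sigma <- 1e-4 * .op_scale(op)
  res <- .eigs_shift_invert(op$matrix, sigma, nev)
  structure(list(values = res$values, vectors = res$vectors,
                 grid = op$grid, sigma = sigma),
            class = "backward_spectrum")
}

#' @export
print.backward_spectrum <- function(x, ...) {
  cat("backward-operator spectrum,", length(x$values), "leading eigenvalues:\n")
  print(format(x$values[seq_len(min(8, length(x$values)))], digits = 4))
  invisible(x)
}

.as_spectrum <- function(x, nev = 24) {
  if (inherits(x, "backward_spectrum")) x
  else backward_spectrum(x, nev = nev)
}

# indices of the trivial (constant-eigenfunction, lambda ~ 0) modes
.trivial_modes <- function(spec, scale = max(abs(spec$values))) {
  which(abs(spec$values) < 1e-6 * max(scale, 1e-300))
}

#' Stationary probability density from the forward operator
#'
#' Extracts the eigenfunction of the discretized Fokker-Planck operator with
#' eigenvalue (numerically) zero, fixes its sign, clips roundoff negatives
#' and normalizes it to unit mass under the grid quadrature.
#'
#' @param op a forward \code{discrete_operator} with conserving closure.
#' @param nev size of the Arnoldi window used to confirm the spectral gap.
#' @return a \code{spectral_mode} with \code{kind = "stationary"}; the
#'   density is \code{$fun} and \code{$gap} reports the distance of the next
#'   eigenvalue from zero.
#' @export
stationary_density <- function(op, nev = 4) {
  stopifnot(inherits(op, "discrete_operator"), op$kind == "forward")
  scale <- .op_scale(op)
  res <- .eigs_shift_invert(op$matrix, sigma = 1e-6 * scale, nev = nev)
  i0 <- which.min(abs(res$values))
  lam0 <- res$values[i0]
  if (abs(lam0) > 1e-6 * scale)
    stop("no eigenvalue numerically at zero; forward closure not conserving?")
  gap <- min(abs(res$values[-i0] - lam0))
  if (gap < 1e-6 * scale)
    stop("stationary eigenvalue not separated from the rest of the spectrum")
  v <- Re(res$vectors[, i0])
  if (sum(v) < 0) v <- -v
  neg <- -min(v, 0)
  if (neg > 1e-8 * max(v))
    warning(sprintf("stationary density has negative parts (%.2e of max) before clipping",
                    neg / max(v)))
  v <- pmax(v, 0)
  v <- v / (sum(v) * op$grid$weight)
  .new_mode(lam0, v, "stationary", op$grid,
            normalization = "unit mass under cell quadrature")
}

#' Leading complex mode of the backward operator
#'
#' Among the nontrivial low-lying eigenvalues (excluding the zero eigenvalue
#' with constant eigenfunction), returns the one of largest real part with
#' nonzero imaginary part, conjugated so that \eqn{\omega = \Im\lambda_1 > 0}.
#' Its eigenfunction carries the stochastic asymptotic phase as its argument.
#' Also reports the robust-oscillator diagnostics: the quality factor
#' \eqn{|\omega/\mu|} and whether every other nontrivial eigenvalue has real
#' part below \eqn{2\mu}.
#'
#' @param x a backward \code{discrete_operator} or a precomputed
#'   \code{\link{backward_spectrum}}.
#' @param nev Arnoldi window size when \code{x} is an operator.
#' @return a \code{spectral_mode} with \code{kind = "complex_leading"} and
#'   fields \code{mu}, \code{omega}, \code{quality}, \code{gap_ok}.
#' @export
leading_complex_mode <- function(x, nev = 24) {
  spec <- .as_spectrum(x, nev)
  scale <- max(abs(spec$values))
  triv <- .trivial_modes(spec, scale)
  idx <- setdiff(seq_along(spec$values), triv)
  cplx <- idx[abs(Im(spec$values[idx])) > 1e-6 * scale]
  if (length(cplx) == 0)
    stop("leading nontrivial eigenvalue is real: system is not robustly oscillatory")
  i1 <- cplx[which.max(Re(spec$values[cplx]))]
  lam <- spec$values[i1]
  v <- spec$vectors[, i1]
  others <- setdiff(idx, i1)
  if (length(others) && max(Re(spec$values[others])) > Re(lam) + 1e-8 * scale)
    warning("a nontrivial eigenvalue decays slower than the leading complex pair")
  if (Im(lam) < 0) { lam <- Conj(lam); v <- Conj(v) }
  v <- v / max(Mod(v))
  mu <- Re(lam); omega <- Im(lam)
  pair_tol <- 1e-8 * scale
  rest <- spec$values[idx][abs(spec$values[idx] - lam) > pair_tol &
                           abs(spec$values[idx] - Conj(lam)) > pair_tol]
  gap_ok <- all(Re(rest) < 2 * mu + 1e-10 * scale)
  m <- .new_mode(lam, v, "complex_leading", spec$grid,
                 normalization = "unit max modulus")
  m$mu <- mu; m$omega <- omega; m$quality <- abs(omega / mu); m$gap_ok <- gap_ok
  m
}

#' Slowest-decaying purely real mode (stochastic isostables)
#'
#' Returns the nontrivial purely real eigenvalue of largest (least negative)
#' value and its real eigenfunction \eqn{\Sigma}, scaled to unit maximum
#' modulus with sign fixed so \eqn{\Sigma \le 0} at the domain center.  The
#' zero level set \eqn{\Sigma_0} is the "stochastic limit cycle" used to
#' anchor the zero phase.
#'
#' @inheritParams leading_complex_mode
#' @return a \code{spectral_mode} with \code{kind = "floquet"}.
#' @export
floquet_mode <- function(x, nev = 24) {
  spec <- .as_spectrum(x, nev)
  scale <- max(abs(spec$values))
  triv <- .trivial_modes(spec, scale)
  idx <- setdiff(seq_along(spec$values), triv)
  reals <- idx[abs(Im(spec$values[idx])) <= 1e-6 * scale]
  if (length(reals) == 0)
    stop("no purely real nontrivial eigenvalue in the Arnoldi window; increase nev")
  iF <- reals[which.max(Re(spec$values[reals]))]
  lam <- Re(spec$values[iF])
  v <- Re(spec$vectors[, iF])
  im_part <- max(abs(Im(spec$vectors[, iF])))
  v <- v / max(abs(v))
  g <- spec$grid
  center <- grid_interp(g, v, mean(g$bounds[1:2]), mean(g$bounds[3:4]))
  if (center > 0) v <- -v
  m <- .new_mode(lam, v, "floquet", g,
                 normalization = "unit max modulus, Sigma(center) <= 0")
  m$max_imag <- im_part
  m
}

## ---------------------------------------------------------------------------
## Phase fields
## ---------------------------------------------------------------------------

.new_phase_field <- function(phase, u, Q, phaseless, winding, grid,
                             anchor = NULL, label = "psi") {
  structure(list(phase = phase, u = u, Q = Q, phaseless = phaseless,
                 winding = winding, anchor = anchor, grid = grid,
                 label = label),
            class = "phase_field")
}

#' @export
print.phase_field <- function(x, ...) {
  cat(sprintf("phase field '%s' on %d x %d grid; phaseless point (%.4g, %.4g); winding %+d\n",
              x$label, x$grid$N, x$grid$M, x$phaseless[1], x$phaseless[2],
              x$winding))
  if (!is.null(x$anchor))
    cat(sprintf("  zero-phase anchor (%.4g, %.4g)\n", x$anchor[1], x$anchor[2]))
  invisible(x)
}

# wrapped phase at arbitrary points, interpolating cos/sin (branch-cut free)
.phase_at <- function(field, x, y) {
  g <- field$grid
  c_ <- grid_interp(g, cos(field$phase), x, y)
  s_ <- grid_interp(g, sin(field$phase), x, y)
  atan2(s_, c_) %% (2 * pi)
}

# winding number of the phase along a circle around a point
.winding_number <- function(grid, phase, center, radius, npts = 720) {
  th <- seq(0, 2 * pi, length.out = npts + 1)
  cx <- center[1] + radius * cos(th)
  cy <- center[2] + radius * sin(th)
  c_ <- grid_interp(grid, cos(phase), cx, cy)
  s_ <- grid_interp(grid, sin(phase), cx, cy)
  ang <- atan2(s_, c_)
  d <- diff(ang)
  d <- (d + pi) %% (2 * pi) - pi
  round(sum(d) / (2 * pi))
}

#' Amplitude and phase of a complex eigenfunction
#'
#' Splits the leading complex eigenfunction \eqn{Q = u e^{i\psi}} into its
#' modulus \eqn{u} (the amplitude) and wrapped argument \eqn{\psi} (the
#' stochastic asymptotic phase).  The phaseless point is located as the grid
#' argmin of \eqn{u}, refined by a local quadratic fit of \eqn{u^2}.  With
#' the eigenvalue convention \eqn{\omega = \Im\lambda_1 > 0} the phase
#' advances at rate \eqn{+\omega} along trajectories; its spatial winding
#' around the phaseless point is +1 for counterclockwise rotors and -1 for
#' clockwise ones (e.g. the heteroclinic oscillator), and is recorded, not
#' altered: conjugating the eigenfunction to force a winding would detach
#' it from its eigenvalue.
#'
#' @param mode a \code{spectral_mode} of kind \code{complex_leading}, or a
#'   complex vector of length N*M (then \code{grid} is required).
#' @param grid the \code{rect_grid} (taken from the mode if available).
#' @return a \code{phase_field} with elements \code{phase} (in
#'   \eqn{[0, 2\pi)}), \code{u}, \code{Q}, \code{phaseless}, \code{winding}.
#' @export
amplitude_phase <- function(mode, grid = NULL) {
  if (inherits(mode, "spectral_mode")) {
    Q <- mode$fun; grid <- mode$grid
  } else { Q <- mode; stopifnot(!is.null(grid)) }
  u <- Mod(Q)
  if (mean(u < 1e-12 * max(u)) > 0.01)
    stop("eigenfunction modulus vanishes on more than 1% of nodes; wrong mode?")
  psi <- Arg(Q) %% (2 * pi)
  k0 <- which.min(u)
  ij <- grid_node(grid, k0)
  phl <- .refine_minimum(grid, u^2, ij[1], ij[2])
  half <- 0.5 * min(diff(grid$bounds[1:2]), diff(grid$bounds[3:4]))
  # keep the probe circle inside the domain even for off-center phaseless pts
  rmax <- 0.95 * min(abs(phl[1] - grid$bounds[1:2]), abs(phl[2] - grid$bounds[3:4]))
  w <- .winding_number(grid, psi, phl, min(0.8 * half, rmax))
  if (abs(w) != 1)
    warning(sprintf("phase winding %+d around the phaseless point (expected +1 or -1)", w))
  .new_phase_field(psi, u, Q, phl, w, grid)
}

# sub-grid minimum of a sampled surface by quadratic fit on a 5x5 patch
.refine_minimum <- function(grid, z, i0, j0) {
  Z <- matrix(z, grid$N, grid$M)
  ii <- max(1, i0 - 2):min(grid$N, i0 + 2)
  jj <- max(1, j0 - 2):min(grid$M, j0 + 2)
  pts <- expand.grid(i = ii, j = jj)
  xs <- grid$x[pts$i]; ys <- grid$y[pts$j]
  zv <- Z[cbind(pts$i, pts$j)]
  X <- cbind(1, xs, ys, xs^2, xs * ys, ys^2)
  cf <- tryCatch(qr.solve(X, zv), error = function(e) NULL)
  fallback <- c(grid$x[i0], grid$y[j0])
  if (is.null(cf)) return(fallback)
  H <- matrix(c(2 * cf[4], cf[5], cf[5], 2 * cf[6]), 2, 2)
  if (det(H) <= 0) return(fallback)
  m <- -solve(H, cf[2:3])
  # trust the fit only within the patch
  if (abs(m[1] - grid$x[i0]) > 2.5 * grid$dx ||
      abs(m[2] - grid$y[j0]) > 2.5 * grid$dy) return(fallback)
  as.numeric(m)
}

#' Anchor the zero phase on the stochastic limit cycle
#'
#' Sets the phase to zero at the point of maximal x-coordinate on the zero
#' level set \eqn{\Sigma_0} of the stochastic isostable function (the
#' "stochastic limit cycle"), the same anchor being reused for both phase
#' functions so they can be compared.
#'
#' @param field a \code{phase_field}.
#' @param Sigma the isostable grid function (\code{spectral_mode} of kind
#'   \code{floquet}, or a numeric vector).
#' @return the re-anchored \code{phase_field} (phase 0 at the anchor).
#' @export
align_zero_phase <- function(field, Sigma) {
  stopifnot(inherits(field, "phase_field"))
  if (inherits(Sigma, "spectral_mode")) Sigma <- Sigma$fun
  g <- field$grid
  cl <- grDevices::contourLines(g$x, g$y, matrix(Sigma, g$N, g$M), levels = 0)
  if (length(cl) == 0) stop("Sigma zero level set is empty")
  xs <- unlist(lapply(cl, `[[`, "x"))
  ys <- unlist(lapply(cl, `[[`, "y"))
  imax <- which.max(xs)
  anchor <- c(xs[imax], ys[imax])
  if (anchor[1] >= g$bounds[2] - 0.51 * g$dx)
    warning("Sigma_0 anchor touches the domain boundary")
  ph0 <- .phase_at(field, anchor[1], anchor[2])
  out <- field
  out$phase <- (field$phase - ph0) %% (2 * pi)
  out$anchor <- anchor
  out
}
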