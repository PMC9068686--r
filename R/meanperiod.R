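# Stationary probability current and the mean return-time period from its
# line integral across a ray leaving the phaseless point.

#' Stationary probability current
#'
#' Computes \eqn{J_{0,i} = f_i P_0 - \sum_j \partial_j (G_{ij} P_0)} with
#' centered differences (one-sided at the borders).  For a divergence-free
#' stationary density the discrete interior divergence of the result is a
#' truncation-order diagnostic, reported alongside.
#'
#' @param P0 a \code{spectral_mode} of kind \code{stationary} (or a numeric
#'   density vector, then \code{grid} is required).
#' @param model the \code{langevin_model}.
#' @param grid the \code{rect_grid}.
#' @return object of class \code{current_field} with \code{Jx}, \code{Jy},
#'   \code{div_max_interior} and the grid.
#' @export
probability_current <- function(P0, model, grid = NULL) {
  if (inherits(P0, "spectral_mode")) { grid <- P0$grid; P0 <- P0$fun }
  stopifnot(!is.null(grid))
  fl <- model_fields(model, grid_points(grid))
  DX <- .op_dx(grid); DY <- .op_dy(grid)
  Jx <- fl$f[, 1] * P0 -
    (as.numeric(DX %*% (fl$G11 * P0)) + as.numeric(DY %*% (fl$G12 * P0)))
  Jy <- fl$f[, 2] * P0 -
    (as.numeric(DX %*% (fl$G12 * P0)) + as.numeric(DY %*% (fl$G22 * P0)))
  dv <- as.numeric(DX %*% Jx) + as.numeric(DY %*% Jy)
  nd <- grid_node(grid, seq_along(P0))
  interior <- nd[, 1] > 2 & nd[, 1] < grid$N - 1 & nd[, 2] > 2 & nd[, 2] < grid$M - 1
  # face-centered fluxes of the conservative forward discretization: their
  # discrete divergence is exactly L P0, so any cut through them carries the
  # same total rotation flux (up to the eigensolver residual)
  ff <- .face_flux_ops(model, grid)
  Fxf <- matrix(as.numeric(ff$Fx %*% P0), grid$N - 1, grid$M)
  Fyf <- matrix(as.numeric(ff$Fy %*% P0), grid$N, grid$M - 1)
  structure(list(Jx = Jx, Jy = Jy, Fxf = Fxf, Fyf = Fyf, grid = grid,
                 div_max_interior = max(abs(dv[interior]))),
            class = "current_field")
}

#' @export
print.current_field <- function(x, ...) {
  cat(sprintf("stationary current on %d x %d grid; max interior divergence %.3e\n",
              x$grid$N, x$grid$M, x$div_max_interior))
  invisible(x)
}

#' Mean return-time period from the stationary current
#'
#' The reciprocal mean period is the probability flux through a ray from the
#' phaseless point to the domain boundary: for the default \code{"+x"} ray,
#' \deqn{1/\bar T = \left|\int_{\bar x}^{x_+} J_{0,y}(x, \bar y)\,dx\right|.}
#' The current component transverse to the ray is interpolated bilinearly
#' (the phaseless point is generally off-grid) and integrated by the
#' trapezoidal rule.  For a divergence-free current the result does not
#' depend on the ray choice, which is exposed for diagnostics.
#'
#' @param J0 a \code{current_field}.
#' @param phaseless the phaseless point \code{c(x, y)} (strictly inside the
#'   domain), e.g. from \code{\link{amplitude_phase}}.
#' @param ray one of \code{"+x"}, \code{"-x"}, \code{"+y"}, \code{"-y"}.
#' @param method \code{"face"} (default) sums the conservative face fluxes
#'   of the forward discretization across the cut, which captures the full
#'   flux up to the wall (important when the current hugs a reflecting
#'   boundary) and is cut-independent by discrete conservation;
#'   \code{"node"} interpolates the node-centered current along the ray and
#'   integrates by the trapezoidal rule.
#' @return list with \code{Tbar}, \code{orientation} (sign of the rotation,
#'   +1 counterclockwise), \code{flux} (the signed integral) and \code{ray}.
#' @export
mean_period <- function(J0, phaseless, ray = c("+x", "-x", "+y", "-y"),
                        method = c("face", "node")) {
  stopifnot(inherits(J0, "current_field"))
  ray <- match.arg(ray)
  method <- match.arg(method)
  g <- J0$grid
  if (phaseless[1] <= g$bounds[1] || phaseless[1] >= g$bounds[2] ||
      phaseless[2] <= g$bounds[3] || phaseless[2] >= g$bounds[4])
    stop("phaseless point must lie strictly inside the domain")
  if (method == "face") return(.mean_period_face(J0, phaseless, ray))
  # sample coordinates along the ray, starting exactly at the phaseless point
  if (ray %in% c("+x", "-x")) {
    nodes <- if (ray == "+x") g$x[g$x > phaseless[1]] else rev(g$x[g$x < phaseless[1]])
    s <- c(phaseless[1], nodes)
    xq <- s; yq <- rep(phaseless[2], length(s))
    comp <- grid_interp(g, J0$Jy, xq, yq)
    flux <- sum(diff(s) * (comp[-1] + comp[-length(comp)]) / 2)
    # counterclockwise rotation carries positive Jy across either x ray
    # (the signed path element flips together with the sign of Jy)
    orientation <- sign(flux)
  } else {
    nodes <- if (ray == "+y") g$y[g$y > phaseless[2]] else rev(g$y[g$y < phaseless[2]])
    s <- c(phaseless[2], nodes)
    xq <- rep(phaseless[1], length(s)); yq <- s
    comp <- grid_interp(g, J0$Jx, xq, yq)
    flux <- sum(diff(s) * (comp[-1] + comp[-length(comp)]) / 2)
    # counterclockwise rotation carries negative Jx across either y ray
    orientation <- -sign(flux)
  }
  if (abs(flux) < 1e-12)
    stop("flux through the ray is numerically zero: no mean rotation")
  list(Tbar = 1 / abs(flux), orientation = orientation, flux = flux, ray = ray,
       method = "node")
}

# total face flux through the half-line cut from the phaseless point to the
# boundary; the cell containing the phaseless point contributes its face
# fraction beyond the point
.mean_period_face <- function(J0, phaseless, ray) {
  g <- J0$grid
  if (ray %in% c("+x", "-x")) {
    jf <- which.min(abs((g$y[-g$M] + g$dy / 2) - phaseless[2]))
    seg <- J0$Fyf[, jf]
    frac <- if (ray == "+x")
      pmin(pmax((g$x + g$dx / 2 - phaseless[1]) / g$dx, 0), 1)
    else
      pmin(pmax((phaseless[1] - (g$x - g$dx / 2)) / g$dx, 0), 1)
    flux <- sum(seg * frac) * g$dx
    # counterclockwise: Jy > 0 right of the phaseless point, < 0 left of it
    orientation <- if (ray == "+x") sign(flux) else -sign(flux)
  } else {
    ifc <- which.min(abs((g$x[-g$N] + g$dx / 2) - phaseless[1]))
    seg <- J0$Fxf[ifc, ]
    frac <- if (ray == "+y")
      pmin(pmax((g$y + g$dy / 2 - phaseless[2]) / g$dy, 0), 1)
    else
      pmin(pmax((phaseless[2] - (g$y - g$dy / 2)) / g$dy, 0), 1)
    flux <- sum(seg * frac) * g$dy
    # counterclockwise: Jx < 0 above the phaseless point, > 0 below it
    orientation <- if (ray == "+y") -sign(flux) else sign(flux)
  }
  if (abs(flux) < 1e-12)
    stop("flux through the ray is numerically zero: no mean rotation")
  list(Tbar = 1 / abs(flux), orientation = orientation, flux = flux, ray = ray,
       method = "face")
}
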