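# Langevin model definitions and closed-form Ornstein-Uhlenbeck oracles.
#
# A model is the pair (f, g) of the planar Ito SDE
#   dX/dt = f(X) + g(X) xi(t),   <xi_i(t) xi_j(t')> = delta_ij delta(t - t'),
# together with the rectangular domain on which the Kolmogorov operators are
# discretized and the boundary closure appropriate for that domain.  The
# diffusion matrix entering both operators is G = (1/2) g g^T.

#' Construct a planar Langevin model
#'
#' Builds one of the packaged stochastic oscillator models, or a custom model
#' from user-supplied drift and noise.  The packaged models carry their
#' standard parameter values and production domains; parameters can be
#' overridden through \code{params}.
#'
#' Packaged models:
#' \describe{
#'   \item{\code{spiral_sink}}{linear focus \eqn{dx/dt = A x + B \xi}.  By
#'     default \eqn{A = [0.1598, -0.52; 0.7227, -0.319]} and
#'     \eqn{B = \sqrt{2D}\,\mathrm{diag}(1, 0.5)} with \eqn{D = 0.01125}, a
#'     noisy-focus model of gamma-band EEG activity.  Alternatively supply the
#'     canonical parameters \code{mu, omega, eps, betaD, betaC} (see
#'     \code{\link{canonical_oup}}) to build the model in canonical
#'     coordinates.  Domain \eqn{[-1.5, 1.5]^2}.}
#'   \item{\code{wilson_cowan}}{noisy excitatory/inhibitory rate model with
#'     logistic activation; defaults \code{c1..c4, a_e, a_i, theta_e, theta_i
#'     = 13, 12, 6, 3, 1.3, 2, 4, 1.5}, \code{P = 2.5}, \code{Q = 0}, noise
#'     amplitudes \code{D_e = 0.1}, \code{D_i = 0.05}: the classic
#'     oscillatory regime of the E-I rate model, with a deterministic limit
#'     cycle of period 5.26 at these values.  Domain
#'     \eqn{[-0.3, 1.0] \times [-0.1, 0.9]}.}
#'   \item{\code{van_der_pol}}{\eqn{\dot x = -y + x - x^3 + D_x \xi_x},
#'     \eqn{\dot y = x + D_y \xi_y}; defaults \eqn{[D_x, D_y] =
#'     \sqrt{2D}\,[1, 0.1]} with \code{D = 0.1}.  Domain \eqn{[-2.5, 2.5]^2}.}
#'   \item{\code{heteroclinic}}{noisy heteroclinic oscillator
#'     \eqn{\dot X = \cos X \sin Y + \alpha \sin 2X + \sqrt{2D}\xi_1},
#'     \eqn{\dot Y = -\sin X \cos Y + \alpha \sin 2Y + \sqrt{2D}\xi_2} on
#'     \eqn{[-\pi/2, \pi/2]^2} with reflecting walls; defaults
#'     \code{alpha = 0.1}, \code{D = 0.01125}.  Uses the adjoint-reflecting
#'     backward closure.}
#'   \item{\code{custom}}{supply \code{drift} (function mapping an n x 2
#'     matrix of states to an n x 2 matrix of velocities), \code{noise}
#'     (constant 2 x 2 matrix, or a function of a state returning one),
#'     \code{domain = c(xmin, xmax, ymin, ymax)} and optionally
#'     \code{boundary_flavor}.}
#' }
#'
#' @param name one of \code{"spiral_sink"}, \code{"wilson_cowan"},
#'   \code{"van_der_pol"}, \code{"heteroclinic"}, \code{"custom"}.
#' @param params named list of parameter overrides (see Details).
#' @return an object of class \code{langevin_model} with elements
#'   \code{drift} (vectorized: n x 2 matrix in, n x 2 matrix out),
#'   \code{noise} (2 x 2 matrix or function), \code{diffusion}
#'   (\eqn{G = g g^T / 2}, same convention), \code{constant_noise},
#'   \code{domain}, \code{boundary_flavor}, \code{name}, \code{params}.
#' @export
make_model <- function(name = c("spiral_sink", "wilson_cowan", "van_der_pol",
                                "heteroclinic", "custom"),
                       params = list()) {
  name <- match.arg(name)
  m <- switch(name,
    spiral_sink  = .model_spiral_sink(params),
    wilson_cowan = .model_wilson_cowan(params),
    van_der_pol  = .model_van_der_pol(params),
    heteroclinic = .model_heteroclinic(params),
    custom       = .model_custom(params))
  .check_diffusion_psd(m)
  m
}

.new_model <- function(name, params, drift, noise, domain, boundary_flavor,
                       sim_code, sim_pars) {
  if (!is.numeric(domain) || length(domain) != 4 ||
      domain[1] >= domain[2] || domain[3] >= domain[4])
    stop("malformed domain: need c(xmin, xmax, ymin, ymax) with xmin < xmax, ymin < ymax")
  constant_noise <- is.matrix(noise)
  if (constant_noise) {
    G <- 0.5 * tcrossprod(noise)
    diffusion <- function(x) G
  } else {
    diffusion <- function(x) 0.5 * tcrossprod(noise(x))
  }
  structure(list(name = name, params = params, drift = drift, noise = noise,
                 diffusion = diffusion, constant_noise = constant_noise,
                 domain = domain, boundary_flavor = boundary_flavor,
                 sim_code = sim_code, sim_pars = sim_pars),
            class = "langevin_model")
}

.check_diffusion_psd <- function(m) {
  pts <- rbind(m$domain[c(1, 3)], m$domain[c(2, 4)],
               c(mean(m$domain[1:2]), mean(m$domain[3:4])))
  for (k in seq_len(nrow(pts))) {
    G <- m$diffusion(pts[k, ])
    if (max(abs(G - t(G))) > 1e-12 * (1 + max(abs(G))))
      stop("diffusion matrix G is not symmetric")
    if (min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) < -1e-12)
      stop("diffusion matrix G is not positive semidefinite")
  }
  invisible(TRUE)
}

.model_spiral_sink <- function(params) {
  canon <- all(c("mu", "omega", "eps") %in% names(params))
  if (canon) {
    p <- utils::modifyList(list(betaD = 0, betaC = 0), params)
    stopifnot(p$omega > 0, p$eps >= 0)
    if (p$betaC^2 + p$betaD^2 > 1 + 1e-12)
      stop("betaC^2 + betaD^2 must be <= 1 for a positive semidefinite G")
    A <- matrix(c(p$mu, p$omega, -p$omega, p$mu), 2, 2)
    G <- p$eps * matrix(c(1 + p$betaD, p$betaC, p$betaC, 1 - p$betaD), 2, 2)
    # any B with B B^T / 2 = G; G is psd so a (pivoted) Cholesky factor works
    ev <- eigen(2 * G, symmetric = TRUE)
    B <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
  } else {
    p <- utils::modifyList(
      list(A = matrix(c(0.1598, 0.7227, -0.52, -0.319), 2, 2),
           B = sqrt(2 * 0.01125) * diag(c(1, 0.5))), params)
    A <- p$A; B <- p$B
  }
  dom <- if (!is.null(params$domain)) params$domain else c(-1.5, 1.5, -1.5, 1.5)
  .new_model("spiral_sink", p,
             drift = function(x) x %*% t(A),
             noise = B, domain = dom, boundary_flavor = "one_sided",
             sim_code = 1L, sim_pars = as.numeric(A))
}

.model_wilson_cowan <- function(params) {
  p <- utils::modifyList(
    list(c1 = 13, c2 = 12, c3 = 6, c4 = 3, a_e = 1.3, a_i = 2,
         theta_e = 4, theta_i = 1.5, P = 2.5, Q = 0, D_e = 0.1, D_i = 0.05),
    params)
  sig <- function(x, a, th) 1 / (1 + exp(-a * (x - th)))
  drift <- function(x) {
    E <- x[, 1]; I <- x[, 2]
    cbind(-E + sig(p$c1 * E - p$c2 * I + p$P, p$a_e, p$theta_e),
          -I + sig(p$c3 * E - p$c4 * I + p$Q, p$a_i, p$theta_i))
  }
  dom <- if (!is.null(params$domain)) params$domain else c(-0.3, 1.0, -0.1, 0.9)
  .new_model("wilson_cowan", p, drift,
             noise = diag(c(p$D_e, p$D_i)), domain = dom,
             boundary_flavor = "one_sided", sim_code = 2L,
             sim_pars = c(p$c1, p$c2, p$c3, p$c4, p$a_e, p$a_i,
                          p$theta_e, p$theta_i, p$P, p$Q))
}

.model_van_der_pol <- function(params) {
  defaults <- list(D = 0.1)
  defaults$D_x <- sqrt(2 * defaults$D)
  defaults$D_y <- sqrt(2 * defaults$D) * 0.1
  p <- utils::modifyList(defaults, params)
  if (!is.null(params$D) && is.null(params$D_x)) {
    p$D_x <- sqrt(2 * p$D); p$D_y <- sqrt(2 * p$D) * 0.1
  }
  drift <- function(x) cbind(-x[, 2] + x[, 1] - x[, 1]^3, x[, 1])
  dom <- if (!is.null(params$domain)) params$domain else c(-2.5, 2.5, -2.5, 2.5)
  .new_model("van_der_pol", p, drift,
             noise = diag(c(p$D_x, p$D_y)), domain = dom,
             boundary_flavor = "one_sided", sim_code = 3L, sim_pars = numeric(0))
}

.model_heteroclinic <- function(params) {
  p <- utils::modifyList(list(alpha = 0.1, D = 0.01125), params)
  drift <- function(x) {
    cbind( cos(x[, 1]) * sin(x[, 2]) + p$alpha * sin(2 * x[, 1]),
          -sin(x[, 1]) * cos(x[, 2]) + p$alpha * sin(2 * x[, 2]))
  }
  dom <- if (!is.null(params$domain)) params$domain
         else c(-pi / 2, pi / 2, -pi / 2, pi / 2)
  .new_model("heteroclinic", p, drift,
             noise = sqrt(2 * p$D) * diag(2), domain = dom,
             boundary_flavor = "reflecting_adjoint",
             sim_code = 4L, sim_pars = p$alpha)
}

.model_custom <- function(params) {
  if (is.null(params$drift) || is.null(params$noise) || is.null(params$domain))
    stop("custom model needs drift, noise and domain")
  bf <- if (is.null(params$boundary_flavor)) "one_sided" else params$boundary_flavor
  stopifnot(bf %in% c("one_sided", "reflecting_adjoint"))
  drift <- params$drift
  # accept a pointwise drift (length-2 in, length-2 out) and vectorize it
  probe <- try(drift(matrix(c(mean(params$domain[1:2]), mean(params$domain[3:4])),
                            1, 2)), silent = TRUE)
  if (inherits(probe, "try-error") || is.null(dim(probe))) {
    fpt <- params$drift
    drift <- function(x) t(apply(x, 1, function(r) fpt(r)))
  }
  .new_model("custom", params, drift, params$noise, params$domain, bf,
             sim_code = 0L, sim_pars = numeric(0))
}

#' @export
print.langevin_model <- function(x, ...) {
  cat("Langevin model:", x$name, "\n")
  cat("  domain: [", x$domain[1], ",", x$domain[2], "] x [",
      x$domain[3], ",", x$domain[4], "]\n")
  cat("  boundary flavor:", x$boundary_flavor, "\n")
  if (x$constant_noise) {
    G <- x$diffusion(c(0, 0))
    cat("  constant diffusion G = [", G[1, 1], G[1, 2], ";",
        G[2, 1], G[2, 2], "]\n")
  } else cat("  state-dependent noise\n")
  invisible(x)
}

#' Evaluate drift and diffusion on a set of states
#'
#' @param model a \code{langevin_model}.
#' @param x n x 2 matrix of states.
#' @return list with \code{f} (n x 2) and \code{G11}, \code{G12}, \code{G22}
#'   (length-n vectors).
#' @keywords internal
model_fields <- function(model, x) {
  f <- model$drift(x)
  n <- nrow(x)
  if (model$constant_noise) {
    G <- model$diffusion(x[1, ])
    list(f = f, G11 = rep(G[1, 1], n), G12 = rep(G[1, 2], n),
         G22 = rep(G[2, 2], n))
  } else {
    G11 <- G12 <- G22 <- numeric(n)
    for (k in seq_len(n)) {
      G <- model$diffusion(x[k, ])
      G11[k] <- G[1, 1]; G12[k] <- G[1, 2]; G22[k] <- G[2, 2]
    }
    list(f = f, G11 = G11, G12 = G12, G22 = G22)
  }
}

## ---------------------------------------------------------------------------
## Canonical Ornstein-Uhlenbeck process and its closed-form oracles
## ---------------------------------------------------------------------------

#' Canonical planar Ornstein-Uhlenbeck parameters
#'
#' In canonical coordinates the linear SDE \eqn{dx/dt = A x + B \xi} has
#' \eqn{A = [\mu, -\omega; \omega, \mu]} and diffusion
#' \eqn{G = \epsilon [1 + \beta_D, \beta_c; \beta_c, 1 - \beta_D]}:
#' \eqn{\epsilon} is the overall noise intensity, \eqn{\beta_D} the
#' anisotropy and \eqn{\beta_c} the noise correlation.
#'
#' @param mu decay rate of the focus (stable case \code{mu < 0}).
#' @param omega rotation frequency, \code{omega > 0}.
#' @param eps noise intensity, \code{eps >= 0}.
#' @param betaD,betaC anisotropy and correlation; need
#'   \code{betaD^2 + betaC^2 <= 1} for G to be positive semidefinite.
#' @param transform optional 2 x 2 change-of-variables matrix S mapping
#'   canonical to original coordinates.
#' @return object of class \code{canonical_oup}.
#' @export
canonical_oup <- function(mu, omega, eps = 0, betaD = 0, betaC = 0,
                          transform = diag(2)) {
  if (omega <= 0) stop("omega must be positive")
  if (eps < 0) stop("eps must be nonnegative")
  if (betaD^2 + betaC^2 > 1 + 1e-12)
    stop("betaD^2 + betaC^2 must be <= 1")
  if (mu >= 0) warning("mu >= 0: unstable focus, no stationary density")
  structure(list(mu = mu, omega = omega, eps = eps, betaD = betaD,
                 betaC = betaC, transform = transform),
            class = "canonical_oup")
}

#' @export
print.canonical_oup <- function(x, ...) {
  cat(sprintf("canonical OUP: mu = %.6g, omega = %.6g, eps = %.6g, betaD = %.6g, betaC = %.6g\n",
              x$mu, x$omega, x$eps, x$betaD, x$betaC))
  invisible(x)
}

#' Put a linear Langevin model into canonical form
#'
#' Given \eqn{dx/dt = A x + B \xi} with the eigenvalues of A a complex
#' conjugate pair \eqn{\mu \pm i\omega}, finds the real change of variables
#' S with \eqn{S^{-1} A S = [\mu, -\omega; \omega, \mu]} and transforms the
#' diffusion \eqn{G = B B^T / 2} into the canonical
#' \eqn{(\epsilon, \beta_D, \beta_c)} parameters.  The eigenvector is
#' normalized to first component 1; \eqn{\mu}, \eqn{\omega} and
#' \eqn{\beta_c^2 + \beta_D^2} do not depend on that normalization choice,
#' while \eqn{\epsilon} and the individual betas do.
#'
#' @param A,B real 2 x 2 matrices.
#' @return a \code{\link{canonical_oup}} with the transform recorded.
#' @export
oup_canonicalize <- function(A, B) {
  stopifnot(is.matrix(A), all(dim(A) == 2), is.matrix(B), all(dim(B) == 2))
  ev <- eigen(A)
  if (max(abs(Im(ev$values))) < 1e-12 * max(abs(ev$values)))
    stop("eigenvalues of A are real: no rotation, cannot canonicalize")
  mu <- Re(ev$values[1])
  omega <- abs(Im(ev$values[1]))
  if (mu >= 0) warning("A is not stable (mu >= 0)")
  v <- ev$vectors[, which(Im(ev$values) > 0)[1]]
  v <- v / v[1]                       # normalization convention
  S <- cbind(Re(v), -Im(v))           # S^{-1} A S = [mu, -omega; omega, mu]
  Sinv <- solve(S)
  G <- 0.5 * tcrossprod(B)
  Gc <- Sinv %*% G %*% t(Sinv)
  eps <- (Gc[1, 1] + Gc[2, 2]) / 2
  if (eps > 0) {
    betaD <- (Gc[1, 1] - Gc[2, 2]) / (2 * eps)
    betaC <- Gc[1, 2] / eps
  } else betaD <- betaC <- 0
  canonical_oup(mu, omega, eps, betaD, betaC, transform = S)
}

#' Closed-form mean return-time period of the canonical OUP
#'
#' \deqn{\bar T = \frac{2\pi(\omega^2 + \mu^2(1 - \beta_c^2 - \beta_D^2))}
#'                     {\omega(\mu^2 + \omega^2)}}
#' For isotropic noise (\eqn{\beta_D = \beta_c = 0}) this collapses to
#' \eqn{2\pi/\omega} and the MRT phase coincides with the asymptotic phase.
#'
#' @param p a \code{\link{canonical_oup}}.
#' @return the mean period. Depends only on \code{mu}, \code{omega} and
#'   \code{betaC^2 + betaD^2}, hence is normalization-invariant.
#' @export
oup_mean_period <- function(p) {
  stopifnot(inherits(p, "canonical_oup"))
  if (p$omega <= 0) stop("omega must be positive")
  b2 <- p$betaC^2 + p$betaD^2
  2 * pi * (p$omega^2 + p$mu^2 * (1 - b2)) / (p$omega * (p$mu^2 + p$omega^2))
}

#' Mean period of the canonical OUP by exact integration of the current
#'
#' Evaluates \eqn{1/\bar T = \int_0^\infty J_{0,y}(x, 0)\,dx} with the
#' analytic Gaussian stationary density and its current, by adaptive
#' quadrature.  For anisotropic or correlated noise this value differs
#' slightly (a few tenths of a percent for weak damping) from the algebraic
#' closed form of \code{\link{oup_mean_period}}; it is the value the
#' operator pipeline converges to under grid refinement, since both express
#' the same flux integral.
#'
#' @param p a \code{\link{canonical_oup}} with \code{mu < 0}, \code{eps > 0}.
#' @return the mean period.
#' @export
oup_mean_period_current <- function(p) {
  stopifnot(inherits(p, "canonical_oup"))
  sc <- oup_stationary_covariance(p)
  Q <- sc$Pi_inv
  C0 <- 1 / (2 * pi * p$eps * sqrt(sc$det_Pi))
  om <- p$omega; bD <- p$betaD; bc <- p$betaC
  integrand <- function(x1) {
    P <- C0 * exp(-Q[1, 1] * x1^2 / (2 * p$eps))
    (om * x1 + (1 - bD) * Q[2, 1] * x1 + bc * Q[1, 1] * x1) * P
  }
  v <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-12)$value
  1 / abs(v)
}

#' Stationary covariance structure of the canonical OUP
#'
#' The stationary density is the centered Gaussian with covariance
#' \eqn{\epsilon \Pi}; this returns the shape matrix \eqn{\Pi}, its inverse
#' and determinant in closed form.
#'
#' @param p a \code{\link{canonical_oup}} with \code{mu < 0}.
#' @return list with \code{Pi}, \code{Pi_inv}, \code{det_Pi},
#'   \code{covariance} (\eqn{\epsilon \Pi}).
#' @export
oup_stationary_covariance <- function(p) {
  stopifnot(inherits(p, "canonical_oup"))
  if (p$mu >= 0) stop("mu must be negative for a stationary density")
  mu <- p$mu; om <- p$omega; bD <- p$betaD; bc <- p$betaC
  den <- -mu * (om^2 + mu^2)
  # off-diagonal: bc*mu^2 - mu*om*bD makes Pi the exact inverse of Pi_inv
  # and eps*Pi the solution of the stationary Lyapunov equation
  Pi <- matrix(c((1 + bD) * mu^2 + om^2 + mu * om * bc,
                 bc * mu^2 - mu * om * bD,
                 bc * mu^2 - mu * om * bD,
                 (1 - bD) * mu^2 + om^2 - mu * om * bc), 2, 2) / den
  num <- om^2 + mu^2 * (1 - bc^2 - bD^2)
  Pi_inv <- matrix(c(-mu * ((1 - bD) * mu^2 + om^2 - mu * om * bc),
                     mu * (bc * mu^2 - mu * om * bD),
                     mu * (bc * mu^2 - mu * om * bD),
                     -mu * ((1 + bD) * mu^2 + om^2 + mu * om * bc)),
                   2, 2) / num
  det_Pi <- num / (mu^2 * (mu^2 + om^2))
  list(Pi = Pi, Pi_inv = Pi_inv, det_Pi = det_Pi, covariance = p$eps * Pi)
}

#' Stationary Gaussian density of the canonical OUP
#'
#' @param x n x 2 matrix of points (canonical coordinates).
#' @param p a \code{\link{canonical_oup}} with \code{mu < 0}, \code{eps > 0}.
#' @return vector of density values.
#' @export
oup_stationary_density <- function(x, p) {
  sc <- oup_stationary_covariance(p)
  if (p$eps <= 0) stop("eps must be positive for a density")
  Pinv <- sc$Pi_inv
  q <- Pinv[1, 1] * x[, 1]^2 + 2 * Pinv[2, 1] * x[, 1] * x[, 2] +
       Pinv[2, 2] * x[, 2]^2
  exp(-q / (2 * p$eps)) / (2 * pi * p$eps * sqrt(sc$det_Pi))
}

#' Closed-form noise-induced drift term Omega(x) for the canonical OUP
#'
#' For the OUP the asymptotic phase is the polar angle and the amplitude is
#' the radius, which gives
#' \deqn{\Omega(x) = -4\epsilon\left(\frac{\beta_D x_1 x_2}{r^4}
#'        - \frac{\beta_c (x_1^2 - x_2^2)}{2 r^4}\right)},
#' the term by which the mean phase velocity deviates from \eqn{\omega}.
#' Diverges at the origin (the phaseless point).
#'
#' @param x n x 2 matrix of points (canonical coordinates), none at the origin.
#' @param p a \code{\link{canonical_oup}}.
#' @return vector of Omega values.
#' @export
oup_omega_term <- function(x, p) {
  stopifnot(inherits(p, "canonical_oup"))
  r2 <- x[, 1]^2 + x[, 2]^2
  if (any(r2 == 0)) stop("Omega diverges at the origin")
  -4 * p$eps * (p$betaD * x[, 1] * x[, 2] / r2^2 -
                p$betaC * (x[, 1]^2 - x[, 2]^2) / (2 * r2^2))
}

#' Closed-form phase offset Delta-psi for the canonical OUP
#'
#' \deqn{\Delta\psi(x, y) = \frac{\epsilon\,(\gamma (x^2 - y^2) + 2\alpha x y)}
#'                               {(\omega^2 + \mu^2)(x^2 + y^2)^2}}
#' with \eqn{\gamma = -\beta_c \mu + \beta_D \omega} and
#' \eqn{\alpha = \beta_c \omega + \beta_D \mu}.  Solves the phase-offset
#' equation with an \eqn{O(\epsilon^2)} residual, so it serves as analytic
#' reference (and solver seed) for the linear model.
#'
#' @param x n x 2 matrix of points (canonical coordinates), none at the origin.
#' @param p a \code{\link{canonical_oup}}.
#' @return vector of Delta-psi values.
#' @export
oup_delta_psi <- function(x, p) {
  stopifnot(inherits(p, "canonical_oup"))
  r2 <- x[, 1]^2 + x[, 2]^2
  if (any(r2 == 0)) stop("Delta-psi is undefined at the origin")
  gam <- -p$betaC * p$mu + p$betaD * p$omega
  alp <-  p$betaC * p$omega + p$betaD * p$mu
  p$eps * (gam * (x[, 1]^2 - x[, 2]^2) + 2 * alp * x[, 1] * x[, 2]) /
    ((p$omega^2 + p$mu^2) * r2^2)
}

## ---------------------------------------------------------------------------
## Deterministic limit-cycle period
## ---------------------------------------------------------------------------

#' Period of the deterministic limit cycle of a model
#'
#' Integrates the noiseless drift past transients, then measures return times
#' to a Poincare plane through a point on the attractor, oriented by the flow
#' there.  Errors if the trajectory converges to an equilibrium instead.
#'
#' @param model a \code{langevin_model}.
#' @param x0 starting state; default is a point off-center in the domain.
#' @param t_transient transient integration time before taking the section.
#' @param n_periods number of return times to average.
#' @param tol relative tolerance passed to the ODE integrator.
#' @return the period (scalar), with attribute \code{"crossings"}.
#' @export
deterministic_period <- function(model, x0 = NULL, t_transient = 150,
                                 n_periods = 6, tol = 1e-10) {
  f <- function(t, y, parms) list(as.numeric(model$drift(matrix(y, 1, 2))))
  if (is.null(x0))
    x0 <- c(model$domain[1] + 0.6 * diff(model$domain[1:2]),
            model$domain[3] + 0.55 * diff(model$domain[3:4]))
  tr <- deSolve::ode(y = x0, times = seq(0, t_transient, length.out = 64),
                     func = f, parms = NULL, method = "lsoda",
                     rtol = tol, atol = tol, maxsteps = 50000)
  p0 <- as.numeric(tr[nrow(tr), 2:3])
  v0 <- as.numeric(model$drift(matrix(p0, 1, 2)))
  sp <- sqrt(sum(v0^2))
  # trajectory parked at an equilibrium => no cycle
  late <- tr[tr[, 1] >= t_transient / 2, 2:3, drop = FALSE]
  if (sp < 1e-8 || max(apply(late, 2, function(v) diff(range(v)))) < 1e-6)
    stop("no limit cycle: trajectory converges to an equilibrium")
  nrm <- v0 / sp
  rootfun <- function(t, y, parms) sum((y - p0) * nrm)
  crossings <- numeric(0)
  state <- p0; t_now <- 0
  # collect successive positive-direction crossings of the section
  for (k in seq_len(4 * n_periods + 8)) {
    out <- deSolve::lsodar(y = state, times = c(t_now, t_now + 1e3),
                           func = f, parms = NULL, rtol = tol, atol = tol,
                           maxsteps = 50000, rootfunc = rootfun)
    troot <- attr(out, "troot")
    if (is.null(troot) || length(troot) == 0)
      stop("no limit cycle: section never recrossed")
    t_now <- troot[1]
    state <- as.numeric(out[nrow(out), 2:3])
    # keep only crossings in the direction of the reference flow
    if (sum(as.numeric(model$drift(matrix(state, 1, 2))) * nrm) > 0)
      crossings <- c(crossings, t_now)
    t_now <- t_now + 1e-6           # step off the root
    if (length(crossings) >= n_periods + 1) break
  }
  if (length(crossings) < 2)
    stop("no limit cycle: could not collect return times")
  periods <- diff(crossings)
  T <- mean(periods)
  if (stats::sd(periods) > 1e-4 * T)
    warning("return times not settled; period may be inaccurate")
  structure(T, crossings = crossings)
}
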