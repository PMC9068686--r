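# Model constructors and the closed-form Ornstein-Uhlenbeck oracles.

test_that("packaged models evaluate drift and diffusion as specified", {
  # zero-noise spiral sink has identically zero diffusion
  m0 <- make_model("spiral_sink", list(mu = -0.1, omega = 1, eps = 0))
  expect_equal(m0$diffusion(c(0.3, -0.2)), matrix(0, 2, 2))

  # heteroclinic drift vanishes at the origin (all sine terms zero)
  mh <- make_model("heteroclinic")
  expect_equal(as.numeric(mh$drift(matrix(0, 1, 2))), c(0, 0))
  expect_identical(mh$boundary_flavor, "reflecting_adjoint")
  expect_equal(mh$diffusion(c(0, 0)), 0.01125 * diag(2))

  # logistic activation crosses 1/2 exactly at its threshold
  mw <- make_model("wilson_cowan")
  p <- mw$params
  # E-nullcline contribution: -E + S_e(arg); choose state with arg = theta_e
  E <- 0.25
  Iv <- (p$c1 * E + p$P - p$theta_e) / p$c2
  f <- mw$drift(matrix(c(E, Iv), 1, 2))
  expect_equal(f[1, 1], -E + 0.5, tolerance = 1e-12)

  # van der Pol drift is the printed cubic lienard field
  mv <- make_model("van_der_pol")
  expect_equal(as.numeric(mv$drift(matrix(c(0.5, 1), 1, 2))),
               c(-1 + 0.5 - 0.125, 0.5))

  expect_error(make_model("spiral_sink",
    list(mu = -0.1, omega = 1, eps = 0.1, betaD = 0.9, betaC = 0.9)),
    "semidefinite")
})

test_that("oup_canonicalize recovers mu and omega from a general matrix", {
  A <- matrix(c(0.1598, 0.7227, -0.52, -0.319), 2, 2)
  B <- sqrt(2 * 0.01125) * diag(c(1, 0.5))
  p <- oup_canonicalize(A, B)
  expect_equal(p$mu, -0.0796, tolerance = 1e-10)
  expect_equal(p$omega, 0.564, tolerance = 1e-3)
  # transform diagonalizes A into the rotation normal form
  S <- p$transform
  canon <- solve(S) %*% A %*% S
  expect_equal(canon, matrix(c(p$mu, p$omega, -p$omega, p$mu), 2, 2),
               tolerance = 1e-10)
  expect_error(oup_canonicalize(matrix(c(1, 0, 0, 2), 2, 2), diag(2)),
               "real")
})

test_that("canonical invariants are independent of the eigenvector normalization", {
  A <- matrix(c(0.1598, 0.7227, -0.52, -0.319), 2, 2)
  B <- sqrt(2 * 0.01125) * diag(c(1, 0.5))
  p <- oup_canonicalize(A, B)
  b2 <- p$betaC^2 + p$betaD^2
  # rescaling/rotating the eigenvector = composing S with a rotation-scaling;
  # mu, omega, betaC^2+betaD^2 and the mean period must not move
  set.seed(42)
  for (k in 1:5) {
    th <- runif(1, 0, 2 * pi); sc <- runif(1, 0.2, 3)
    R <- sc * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    S2 <- p$transform %*% R
    G2 <- solve(S2) %*% (0.5 * tcrossprod(B)) %*% t(solve(S2))
    eps2 <- (G2[1, 1] + G2[2, 2]) / 2
    bD2 <- (G2[1, 1] - G2[2, 2]) / (2 * eps2); bc2 <- G2[1, 2] / eps2
    expect_equal(bD2^2 + bc2^2, b2, tolerance = 1e-9)
    p2 <- canonical_oup(p$mu, p$omega, eps2, bD2, bc2)
    expect_equal(oup_mean_period(p2), oup_mean_period(p), tolerance = 1e-9)
  }
  # the printed parameter triple of the gamma-band focus model carries the
  # same invariant set as our canonicalization of its (A, B)
  expect_equal(b2, (-0.74)^2 + 0.11^2, tolerance = 0.02)
})

test_that("mean period collapses to 2*pi/omega for isotropic noise and small mu", {
  expect_equal(oup_mean_period(canonical_oup(-0.3, 1.7, eps = 0.2)),
               2 * pi / 1.7)
  expect_equal(oup_mean_period(canonical_oup(-1e-9, 0.564, 0.1, -0.74, 0.11)),
               2 * pi / 0.564, tolerance = 1e-8)
  p <- canon_focus()
  expect_equal(oup_mean_period(p), 11.02, tolerance = 1e-3)
  # the exact flux integral of the analytic current sits within 1% of it
  expect_equal(oup_mean_period_current(p), oup_mean_period(p), tolerance = 0.01)
})

test_that("stationary covariance solves the Lyapunov equation", {
  p <- canon_focus()
  sc <- oup_stationary_covariance(p)
  expect_equal(sc$Pi %*% sc$Pi_inv, diag(2), tolerance = 1e-12)
  expect_equal(det(sc$Pi), sc$det_Pi, tolerance = 1e-12)
  # independent oracle: solve A C + C A^T + 2 G = 0 as a 3x3 linear system
  A <- matrix(c(p$mu, p$omega, -p$omega, p$mu), 2, 2)
  G <- p$eps * matrix(c(1 + p$betaD, p$betaC, p$betaC, 1 - p$betaD), 2, 2)
  M <- rbind(c(2 * A[1, 1], 2 * A[1, 2], 0),
             c(A[2, 1], A[1, 1] + A[2, 2], A[1, 2]),
             c(0, 2 * A[2, 1], 2 * A[2, 2]))
  v <- solve(M, -2 * c(G[1, 1], G[1, 2], G[2, 2]))
  C <- matrix(c(v[1], v[2], v[2], v[3]), 2, 2)
  expect_equal(sc$covariance, C, tolerance = 1e-10)
  expect_error(oup_stationary_covariance(
    suppressWarnings(canonical_oup(0.1, 1))), "negative")
})

test_that("closed-form Omega matches differentiation of the polar phase", {
  p <- canon_focus()
  # generic definition 2 sum G_ij d_i(ln u) d_j(psi) with u = r, psi = atan2
  set.seed(7)
  G <- p$eps * matrix(c(1 + p$betaD, p$betaC, p$betaC, 1 - p$betaD), 2, 2)
  for (k in 1:20) {
    x <- runif(2, -1.2, 1.2)
    if (sum(x^2) < 0.04) next
    h <- 1e-6
    num_grad <- function(f) c((f(x + c(h, 0)) - f(x - c(h, 0))) / (2 * h),
                              (f(x + c(0, h)) - f(x - c(0, h))) / (2 * h))
    glnu <- num_grad(function(z) 0.5 * log(sum(z^2)))
    gpsi <- num_grad(function(z) atan2(z[2], z[1]))
    ref <- 2 * as.numeric(t(glnu) %*% G %*% gpsi)
    expect_equal(oup_omega_term(matrix(x, 1, 2), p), ref, tolerance = 1e-5)
  }
  # homogeneity and isotropic degeneracy
  x <- matrix(c(0.4, -0.7), 1, 2)
  expect_equal(oup_omega_term(2.5 * x, p), oup_omega_term(x, p) / 2.5^2)
  expect_equal(oup_omega_term(x, canonical_oup(-0.1, 1, 0.3)), 0)
  expect_error(oup_omega_term(matrix(0, 1, 2), p), "origin")
})

test_that("closed-form phase offset solves its equation to O(eps^2)", {
  # apply the exact backward operator to the closed form and subtract Omega;
  # the residual splits into a constant (the frequency mismatch, absorbed by
  # the gauge) and a spatially varying part that must quarter when the
  # noise intensity eps is halved
  resid_scale <- function(eps_val) {
    p <- canonical_oup(-0.0796, 0.564, eps_val, -0.74, 0.11)
    A <- matrix(c(p$mu, p$omega, -p$omega, p$mu), 2, 2)
    G <- p$eps * matrix(c(1 + p$betaD, p$betaC, p$betaC, 1 - p$betaD), 2, 2)
    vals <- c()
    for (r in c(0.3, 0.6, 1.0)) for (th in seq(0, 2 * pi, length.out = 9)[-9]) {
      x <- r * c(cos(th), sin(th))
      h <- 1e-4
      f <- function(z) oup_delta_psi(matrix(z, 1, 2), p)
      d1 <- c((f(x + c(h, 0)) - f(x - c(h, 0))) / (2 * h),
              (f(x + c(0, h)) - f(x - c(0, h))) / (2 * h))
      dxx <- (f(x + c(h, 0)) - 2 * f(x) + f(x - c(h, 0))) / h^2
      dyy <- (f(x + c(0, h)) - 2 * f(x) + f(x - c(0, h))) / h^2
      dxy <- (f(x + c(h, h)) - f(x + c(h, -h)) - f(x + c(-h, h)) +
              f(x + c(-h, -h))) / (4 * h^2)
      lhs <- sum((A %*% x) * d1) + G[1, 1] * dxx + 2 * G[1, 2] * dxy +
        G[2, 2] * dyy
      vals <- c(vals, lhs - oup_omega_term(matrix(x, 1, 2), p))
    }
    max(abs(vals - mean(vals)))
  }
  r1 <- resid_scale(0.0046)
  r2 <- resid_scale(0.0023)
  expect_lt(r1, 0.05)            # small at the production noise level
  expect_lt(r2, r1 / 3.5)        # quarters when eps halves
  expect_gt(r2, r1 / 4.5)
  # point symmetry and isotropic degeneracy
  p <- canon_focus()
  x <- matrix(c(0.5, -0.3), 1, 2)
  expect_equal(oup_delta_psi(x, p), oup_delta_psi(-x, p))
  expect_equal(oup_delta_psi(x, canonical_oup(-0.1, 1, 0.3)), 0)
})

test_that("deterministic periods of the limit-cycle models are recovered", {
  expect_equal(as.numeric(deterministic_period(make_model("van_der_pol"))),
               6.663, tolerance = 1e-3)
  expect_equal(as.numeric(deterministic_period(make_model("wilson_cowan"))),
               5.26, tolerance = 2e-3)
  expect_error(deterministic_period(make_model("spiral_sink")), "no limit cycle")
})
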