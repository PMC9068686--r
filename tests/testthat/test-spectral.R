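# Low-lying spectrum extraction and the phase-field utilities.

test_that("stationary density matches the analytic Gaussian of the linear model", {
  ops <- small_oup_ops(64)
  P0 <- stationary_density(ops$Lf)
  expect_equal(P0$kind, "stationary")
  expect_lt(abs(P0$lambda), 1e-8)
  expect_true(all(P0$fun >= 0))
  expect_equal(sum(P0$fun) * ops$grid$weight, 1, tolerance = 1e-12)
  pa <- oup_stationary_density(grid_points(ops$grid), canon_focus())
  pa <- pa / (sum(pa) * ops$grid$weight)
  expect_lt(max(abs(P0$fun - pa)) / max(pa), 0.02)
})

test_that("leading complex mode recovers the linear-model eigenvalue exactly", {
  ops <- small_oup_ops()
  spec <- backward_spectrum(ops$Lb, nev = 16)
  mode <- leading_complex_mode(spec)
  p <- canon_focus()
  # centered differences are exact on the linear eigenfunction, so even a
  # coarse grid reproduces the eigenvalue to solver tolerance
  expect_equal(mode$mu, p$mu, tolerance = 1e-8)
  expect_equal(mode$omega, p$omega, tolerance = 1e-8)
  expect_true(mode$omega > 0)
  expect_equal(mode$quality, abs(p$omega / p$mu), tolerance = 1e-6)
  fl <- floquet_mode(spec)
  expect_equal(fl$lambda, 2 * p$mu, tolerance = 1e-6)  # radial mode decays at 2 mu
  expect_lt(fl$max_imag, 1e-8)
})

test_that("phase of the leading mode is the polar angle for the linear model", {
  ops <- small_oup_ops()
  spec <- backward_spectrum(ops$Lb, nev = 16)
  pf <- amplitude_phase(leading_complex_mode(spec))
  expect_true(all(pf$u >= 0))
  expect_lt(sqrt(sum(pf$phaseless^2)), ops$grid$dx)  # phaseless at the origin
  expect_equal(pf$winding, 1L)
  pts <- grid_points(ops$grid)
  r <- sqrt(rowSums(pts^2))
  d <- wrap_pi(pf$phase - atan2(pts[, 2], pts[, 1]))
  keep <- r > 0.2
  off <- atan2(mean(sin(d[keep])), mean(cos(d[keep])))
  expect_lt(sqrt(mean(wrap_pi(d[keep] - off)^2)), 0.05)
})

test_that("zero-phase alignment anchors on the isostable zero set and is idempotent", {
  ops <- small_oup_ops()
  spec <- backward_spectrum(ops$Lb, nev = 16)
  pf <- amplitude_phase(leading_complex_mode(spec))
  Sig <- floquet_mode(spec)
  al <- align_zero_phase(pf, Sig)
  expect_false(is.null(al$anchor))
  # phase at the anchor is zero (wrapped)
  ph_a <- stochphase:::.phase_at(al, al$anchor[1], al$anchor[2])
  expect_lt(min(ph_a, 2 * pi - ph_a), 1e-6)
  # idempotent and difference-preserving
  al2 <- align_zero_phase(al, Sig)
  expect_lt(max(abs(wrap_pi(al2$phase - al$phase))), 1e-9)
  expect_lt(max(abs(wrap_pi((al$phase - pf$phase) -
                            (al$phase[1] - pf$phase[1])))), 1e-9)
})

test_that("biorthogonality holds between the stationary and leading modes", {
  ops <- small_oup_ops()
  spec <- backward_spectrum(ops$Lb, nev = 16)
  mode <- leading_complex_mode(spec)
  P0 <- stationary_density(ops$Lf)
  ip <- sum(Conj(mode$fun) * P0$fun) * ops$grid$weight
  scale <- sqrt(sum(Mod(mode$fun)^2) * sum(P0$fun^2)) * ops$grid$weight
  expect_lt(Mod(ip) / scale, 1e-4)
})

test_that("eigenfunction identities of the polar decomposition hold on refinement", {
  # writing Q = u e^{i psi}, the eigenvalue relation splits into
  #   imag: L[psi] + 2 G_jk d_j(ln u) d_k(psi) = omega
  #   real: L[u]/u = mu + G_jk d_j(psi) d_k(psi)   (u-corrected form)
  # here L[psi] and L[u]/u are rebuilt from first and second derivatives of
  # log Q (branch-cut free), which differs from the raw eigen relation by
  # truncation error only: the residual must shrink at ~O(dx^2)
  # the linear model is exact at any resolution (its eigenfunction is a
  # polynomial), so a nonlinear model is needed to see the truncation decay;
  # derivatives of log Q are taken with stride-2 centered differences,
  # deliberately different from the assembly stencils so the check is not
  # an algebraic restatement of the eigenvalue relation
  m <- make_model("van_der_pol")
  G <- m$diffusion(c(0, 0))
  errs <- sapply(c(40, 80), function(N) {
    g <- make_grid(m$domain, N, N)
    Lb <- assemble_backward(m, g)
    mode <- leading_complex_mode(backward_spectrum(Lb, nev = 12))
    Z <- matrix(mode$fun, g$N, g$M)
    ii <- 3:(g$N - 2); jj <- 3:(g$M - 2)
    sh <- function(di, dj) Z[ii + di, jj + dj]
    Z0 <- sh(0, 0)
    w1 <- (sh(2, 0) - sh(-2, 0)) / (4 * g$dx) / Z0      # grad log Q
    w2 <- (sh(0, 2) - sh(0, -2)) / (4 * g$dy) / Z0
    h11 <- (sh(2, 0) - 2 * Z0 + sh(-2, 0)) / (2 * g$dx)^2 / Z0 - w1^2
    h22 <- (sh(0, 2) - 2 * Z0 + sh(0, -2)) / (2 * g$dy)^2 / Z0 - w2^2
    h12 <- (sh(2, 2) - sh(2, -2) - sh(-2, 2) + sh(-2, -2)) /
      (4 * (2 * g$dx) * (2 * g$dy)) / Z0 - w1 * w2
    pts <- grid_points(g)
    fl <- model_fields(m, pts)
    F1 <- matrix(fl$f[, 1], g$N, g$M)[ii, jj]
    F2 <- matrix(fl$f[, 2], g$N, g$M)[ii, jj]
    LlogQ <- F1 * w1 + F2 * w2 +
      G[1, 1] * h11 + 2 * G[1, 2] * h12 + G[2, 2] * h22
    quad_as <- G[1, 1] * Re(w1) * Im(w1) +
      G[1, 2] * (Re(w1) * Im(w2) + Re(w2) * Im(w1)) + G[2, 2] * Re(w2) * Im(w2)
    quad_ss <- G[1, 1] * Im(w1)^2 + 2 * G[1, 2] * Im(w1) * Im(w2) +
      G[2, 2] * Im(w2)^2
    res_imag <- Im(LlogQ) + 2 * quad_as - mode$omega   # L[psi] + Omega = omega
    res_real <- Re(LlogQ) + (G[1, 1] * Re(w1)^2 + 2 * G[1, 2] * Re(w1) * Re(w2) +
      G[2, 2] * Re(w2)^2) - quad_ss - mode$mu          # L[u]/u - |grad psi|_G^2 = mu
    X <- matrix(pts[, 1], g$N, g$M)[ii, jj]
    Y <- matrix(pts[, 2], g$N, g$M)[ii, jj]
    keep <- sqrt(X^2 + Y^2) > 0.8 & abs(X) < 2 & abs(Y) < 2
    c(max(abs(res_imag[keep])), max(abs(res_real[keep])))
  })
  # refinement 40 -> 80 shrinks both residuals
  expect_lt(errs[1, 2], errs[1, 1] / 2)
  expect_lt(errs[2, 2], errs[2, 1] / 2)
})

test_that("a non-oscillatory system is refused with a named condition", {
  # pure relaxation: all backward eigenvalues are real
  m <- make_model("custom", list(
    drift = function(x) -x, noise = 0.3 * diag(2),
    domain = c(-2, 2, -2, 2)))
  g <- make_grid(m$domain, 24, 24)
  spec <- backward_spectrum(assemble_backward(m, g), nev = 6)
  expect_error(leading_complex_mode(spec), "robustly oscillatory")
})

test_that("heteroclinic stationary density inherits the point symmetry of the drift", {
  m <- make_model("heteroclinic")
  g <- make_grid(m$domain, 48, 48)
  P0 <- stationary_density(assemble_forward(m, g))
  Z <- matrix(P0$fun, 48, 48)
  Zr <- Z[48:1, 48:1]   # (x, y) -> (-x, -y)
  expect_lt(max(abs(Z - Zr)) / max(Z), 1e-6)
})

test_that("eigenvalues converge under grid refinement for a nonlinear model", {
  m <- make_model("van_der_pol")
  lam <- sapply(c(40, 80, 120), function(N) {
    g <- make_grid(m$domain, N, N)
    leading_complex_mode(backward_spectrum(assemble_backward(m, g), nev = 12))$lambda
  })
  expect_lt(Mod(lam[3] - lam[2]), Mod(lam[2] - lam[1]))
})
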