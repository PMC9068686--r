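# Grid bookkeeping and the discretized forward/backward operators.

test_that("grid indexing round-trips and weights sum to the area", {
  g <- make_grid(c(-1.5, 1.5, -0.5, 2.5), 24, 16)
  k <- seq_len(g$N * g$M)
  nd <- grid_node(g, k)
  expect_identical(grid_index(g, nd[, 1], nd[, 2]), k)
  expect_equal(g$weight * g$N * g$M, g$area)
  pts <- grid_points(g)
  expect_true(all(pts[, 1] > g$bounds[1] & pts[, 1] < g$bounds[2]))
  expect_error(make_grid(c(1, 1, 0, 1), 20, 20), "degenerate")
  expect_error(make_grid(c(0, 1, 0, 1), 4, 20), "coarse")
})

test_that("constants are an exact null vector for both boundary flavors", {
  ops <- small_oup_ops()
  ones <- rep(1, ops$grid$N * ops$grid$M)
  expect_lt(max(abs(op_apply(ops$Lb, ones))), 1e-12)
  mh <- make_model("heteroclinic")
  gh <- make_grid(mh$domain, 32, 32)
  Lbh <- assemble_backward(mh, gh)
  expect_identical(Lbh$boundary_flavor, "reflecting_adjoint")
  expect_lt(max(abs(op_apply(Lbh, rep(1, 32 * 32)))), 1e-12)
})

test_that("backward operator is exact on the linear eigenfunction of a linear drift", {
  # for dx/dt = Ax the function x1 + i x2 is an eigenfunction of the
  # generator with eigenvalue mu + i omega; centered differences are exact
  # on polynomials of degree <= 2, so interior rows reproduce it to
  # rounding
  ops <- small_oup_ops()
  p <- canon_focus()
  pts <- grid_points(ops$grid)
  q <- pts[, 1] + 1i * pts[, 2]
  r <- op_apply(ops$Lb, q) - (p$mu + 1i * p$omega) * q
  nd <- grid_node(ops$grid, seq_along(q))
  interior <- nd[, 1] > 2 & nd[, 1] < ops$grid$N - 1 &
              nd[, 2] > 2 & nd[, 2] < ops$grid$M - 1
  expect_lt(max(Mod(r[interior])), 1e-12)
})

test_that("zero drift with unit diffusion gives the five-point Laplacian inside", {
  m <- make_model("custom", list(
    drift = function(x) 0 * x, noise = sqrt(2) * diag(2),
    domain = c(0, 1, 0, 1)))
  g <- make_grid(m$domain, 16, 16)
  Lb <- assemble_backward(m, g)
  k <- grid_index(g, 8, 8)
  row <- Lb$matrix[k, ]
  nb <- c(grid_index(g, 7, 8), grid_index(g, 9, 8),
          grid_index(g, 8, 7), grid_index(g, 8, 9))
  expect_equal(row[k], -2 / g$dx^2 - 2 / g$dy^2)
  expect_equal(as.numeric(row[nb]), rep(1 / g$dx^2, 4))
  expect_equal(sum(row != 0), 5)
})

test_that("forward operator conserves probability exactly", {
  ops <- small_oup_ops()
  expect_lt(max(abs(Matrix::colSums(ops$Lf$matrix))), 1e-12)
  mh <- make_model("heteroclinic")
  gh <- make_grid(mh$domain, 32, 32)
  Lfh <- assemble_forward(mh, gh)
  expect_lt(max(abs(Matrix::colSums(Lfh$matrix))), 1e-12)
})

test_that("forward operator annihilates the analytic Gaussian at truncation order", {
  p <- canon_focus()
  m <- canon_focus_model()
  err <- sapply(c(40, 80), function(N) {
    g <- make_grid(m$domain, N, N)
    Lf <- assemble_forward(m, g)
    P <- oup_stationary_density(grid_points(g), p)
    P <- P / (sum(P) * g$weight)
    max(abs(op_apply(Lf, P))) / max(P)
  })
  expect_lt(err[2], err[1] / 3)   # ~O(dx^2)
  expect_lt(err[2], 0.02)
})

test_that("one-sided backward operator is dual to the forward operator on interior bumps", {
  ops <- small_oup_ops()
  g <- ops$grid
  pts <- grid_points(g)
  bump <- function(cx, cy, s) exp(-((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2) / (2 * s^2))
  set.seed(3)
  for (k in 1:4) {
    u <- bump(runif(1, -0.4, 0.4), runif(1, -0.4, 0.4), 0.25)
    v <- bump(runif(1, -0.4, 0.4), runif(1, -0.4, 0.4), 0.3)
    lhs <- sum(op_apply(ops$Lb, u) * v) * g$weight
    rhs <- sum(u * op_apply(ops$Lf, v)) * g$weight
    # duality holds to truncation order for interior-supported functions
    expect_equal(lhs, rhs, tolerance = 0.05)
  }
})

test_that("interior consistency is second order for both operators", {
  m <- canon_focus_model()
  p <- canon_focus()
  A <- matrix(c(p$mu, p$omega, -p$omega, p$mu), 2, 2)
  G <- p$eps * matrix(c(1 + p$betaD, p$betaC, p$betaC, 1 - p$betaD), 2, 2)
  # smooth test function with analytic derivatives
  u <- function(x, y) sin(2 * x) * cos(1.5 * y)
  ux <- function(x, y) 2 * cos(2 * x) * cos(1.5 * y)
  uy <- function(x, y) -1.5 * sin(2 * x) * sin(1.5 * y)
  uxx <- function(x, y) -4 * u(x, y)
  uyy <- function(x, y) -2.25 * u(x, y)
  uxy <- function(x, y) -3 * cos(2 * x) * sin(1.5 * y)
  err <- sapply(c(40, 80, 160), function(N) {
    g <- make_grid(m$domain, N, N)
    Lb <- assemble_backward(m, g)
    pts <- grid_points(g)
    x <- pts[, 1]; y <- pts[, 2]
    f1 <- A[1, 1] * x + A[1, 2] * y; f2 <- A[2, 1] * x + A[2, 2] * y
    exact <- f1 * ux(x, y) + f2 * uy(x, y) + G[1, 1] * uxx(x, y) +
      2 * G[1, 2] * uxy(x, y) + G[2, 2] * uyy(x, y)
    nd <- grid_node(g, seq_along(x))
    interior <- nd[, 1] > 2 & nd[, 1] < N - 1 & nd[, 2] > 2 & nd[, 2] < N - 1
    max(abs(op_apply(Lb, u(x, y)) - exact)[interior])
  })
  expect_lt(err[2], err[1] / 3)
  expect_lt(err[3], err[2] / 3)
})

test_that("operator export writes readable triplets with a grid sidecar", {
  ops <- small_oup_ops()
  tf <- tempfile(fileext = ".tsv")
  df <- op_write_coo(ops$Lb, tf)
  back <- utils::read.table(tf, header = TRUE, sep = "\t")
  expect_equal(nrow(back), Matrix::nnzero(ops$Lb$matrix))
  meta <- jsonlite::read_json(sub("tsv$", "json", tf))
  expect_equal(meta$N, ops$grid$N)
  unlink(c(tf, sub("tsv$", "json", tf)))
})
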