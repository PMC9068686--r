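# Rectangular-grid discretization of the Kolmogorov forward and backward
# operators.
#
# The grid is cell-centered: N x M cells of size dx x dy tile the domain and
# the unknowns live at cell centers, so the uniform quadrature weight dx*dy
# sums exactly to the domain area and the reflecting (zero normal flux)
# closure of the forward operator sits naturally on the cell faces.
# Grid functions are stored as length-N*M vectors in column-major order of
# the N x M matrix U[i, j] (i indexes x, j indexes y): k = (j-1)*N + i.

#' Build a rectangular grid
#'
#' @param bounds numeric length-4: \code{c(xmin, xmax, ymin, ymax)}.
#' @param N,M number of cells along x and y (\code{N, M >= 8}).
#' @return object of class \code{rect_grid}: \code{bounds}, \code{N},
#'   \code{M}, \code{dx}, \code{dy}, node coordinates \code{x} (length N),
#'   \code{y} (length M), \code{weight} (scalar cell weight dx*dy) and
#'   \code{area}.
#' @export
make_grid <- function(bounds, N = 120, M = 120) {
  stopifnot(is.numeric(bounds), length(bounds) == 4)
  if (bounds[1] >= bounds[2] || bounds[3] >= bounds[4])
    stop("degenerate bounds")
  if (N < 8 || M < 8) stop("grid too coarse: need N, M >= 8")
  dx <- (bounds[2] - bounds[1]) / N
  dy <- (bounds[4] - bounds[3]) / M
  structure(list(bounds = bounds, N = as.integer(N), M = as.integer(M),
                 dx = dx, dy = dy,
                 x = bounds[1] + (seq_len(N) - 0.5) * dx,
                 y = bounds[3] + (seq_len(M) - 0.5) * dy,
                 weight = dx * dy,
                 area = (bounds[2] - bounds[1]) * (bounds[4] - bounds[3])),
            class = "rect_grid")
}

#' @export
print.rect_grid <- function(x, ...) {
  cat(sprintf("rect_grid %d x %d on [%g, %g] x [%g, %g] (dx = %g, dy = %g)\n",
              x$N, x$M, x$bounds[1], x$bounds[2], x$bounds[3], x$bounds[4],
              x$dx, x$dy))
  invisible(x)
}

#' Flattened index of grid node (i, j)
#' @param grid a \code{rect_grid}.
#' @param i,j cell indices along x and y.
#' @return integer flattened index.
#' @export
grid_index <- function(grid, i, j) (as.integer(j) - 1L) * grid$N + as.integer(i)

#' Cell indices (i, j) of flattened node k
#' @param grid a \code{rect_grid}.
#' @param k flattened index.
#' @return two-column integer matrix of (i, j).
#' @export
grid_node <- function(grid, k) {
  k <- as.integer(k) - 1L
  cbind(i = k %% grid$N + 1L, j = k %/% grid$N + 1L)
}

#' All node coordinates as an (N*M) x 2 matrix
#' @param grid a \code{rect_grid}.
#' @return matrix of node coordinates in flattened order.
#' @export
grid_points <- function(grid) {
  cbind(rep(grid$x, times = grid$M), rep(grid$y, each = grid$N))
}

## 1-D difference matrices ----------------------------------------------------

# centered first derivative; second-order one-sided rows at the ends
.d1_matrix <- function(n, h) {
  i <- c(2:(n - 1), 2:(n - 1), 1, 1, 1, n, n, n)
  j <- c(1:(n - 2), 3:n,       1, 2, 3, n - 2, n - 1, n)
  v <- c(rep(-0.5, n - 2), rep(0.5, n - 2),
         -1.5, 2, -0.5, 0.5, -2, 1.5) / h
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(n, n))
}

# centered second derivative; first-order one-sided rows at the ends
.d2_matrix <- function(n, h) {
  i <- c(rep(2:(n - 1), 3), 1, 1, 1, n, n, n)
  j <- c(1:(n - 2), 2:(n - 1), 3:n, 1, 2, 3, n - 2, n - 1, n)
  v <- c(rep(1, n - 2), rep(-2, n - 2), rep(1, n - 2),
         1, -2, 1, 1, -2, 1) / h^2
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(n, n))
}

# face averaging (n-1 faces between n cells)
.face_avg <- function(n) {
  Matrix::sparseMatrix(i = c(1:(n - 1), 1:(n - 1)), j = c(1:(n - 1), 2:n),
                       x = rep(0.5, 2 * (n - 1)), dims = c(n - 1, n))
}

# face-centered difference
.face_diff <- function(n, h) {
  Matrix::sparseMatrix(i = c(1:(n - 1), 1:(n - 1)), j = c(1:(n - 1), 2:n),
                       x = c(rep(-1 / h, n - 1), rep(1 / h, n - 1)),
                       dims = c(n - 1, n))
}

# divergence of face fluxes (boundary faces carry zero flux)
.div_matrix <- function(n, h) {
  i <- c(1:(n - 1), 2:n)
  j <- c(1:(n - 1), 1:(n - 1))
  v <- c(rep(1 / h, n - 1), rep(-1 / h, n - 1))
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(n, n - 1))
}

# 2-D operators acting on flattened grid functions
.op_dx  <- function(g) Matrix::kronecker(Matrix::Diagonal(g$M), .d1_matrix(g$N, g$dx))
.op_dy  <- function(g) Matrix::kronecker(.d1_matrix(g$M, g$dy), Matrix::Diagonal(g$N))
.op_dxx <- function(g) Matrix::kronecker(Matrix::Diagonal(g$M), .d2_matrix(g$N, g$dx))
.op_dyy <- function(g) Matrix::kronecker(.d2_matrix(g$M, g$dy), Matrix::Diagonal(g$N))
.op_dxy <- function(g) Matrix::kronecker(.d1_matrix(g$M, g$dy), .d1_matrix(g$N, g$dx))

.new_operator <- function(mat, grid, kind, boundary_flavor) {
  structure(list(matrix = mat, grid = grid, kind = kind,
                 boundary_flavor = boundary_flavor),
            class = "discrete_operator")
}

#' @export
print.discrete_operator <- function(x, ...) {
  cat(sprintf("discrete %s operator (%s closure), %d x %d, %d nonzeros\n",
              x$kind, x$boundary_flavor, nrow(x$matrix), ncol(x$matrix),
              Matrix::nnzero(x$matrix)))
  invisible(x)
}

#' Assemble the discretized Kolmogorov backward operator
#'
#' Discretizes \eqn{L^\dagger u = f \cdot \nabla u + \sum_{ij} G_{ij}
#' \partial_i \partial_j u} with second-order centered differences on
#' interior nodes.  For \code{boundary = "one_sided"} (unbounded systems
#' truncated to a large box) boundary rows use inward one-sided stencils:
#' second-order for first derivatives, first-order for second derivatives,
#' so that constants remain an exact null vector.  For
#' \code{boundary = "reflecting_adjoint"} (systems with hard walls, e.g. the
#' heteroclinic oscillator) the operator is the adjoint of the conservative
#' reflecting forward operator under the uniform cell quadrature, which makes
#' the discrete duality \eqn{\langle L^\dagger u, v\rangle = \langle u, L
#' v\rangle} exact.
#'
#' @param model a \code{langevin_model}.
#' @param grid a \code{rect_grid}; its bounds must match the model domain.
#' @param boundary override of \code{model$boundary_flavor}.
#' @return a \code{discrete_operator} with \code{kind = "backward"}.
#' @export
assemble_backward <- function(model, grid,
                              boundary = model$boundary_flavor) {
  .check_domain(model, grid)
  boundary <- match.arg(boundary, c("one_sided", "reflecting_adjoint"))
  if (boundary == "reflecting_adjoint") {
    Lf <- assemble_forward(model, grid)
    # uniform cell weights: the quadrature adjoint is the plain transpose
    return(.new_operator(Matrix::t(Lf$matrix), grid, "backward",
                         "reflecting_adjoint"))
  }
  fl <- model_fields(model, grid_points(grid))
  D <- function(v) Matrix::Diagonal(x = v)
  mat <- D(fl$f[, 1]) %*% .op_dx(grid) + D(fl$f[, 2]) %*% .op_dy(grid) +
    D(fl$G11) %*% .op_dxx(grid) + D(fl$G22) %*% .op_dyy(grid)
  if (any(fl$G12 != 0))
    mat <- mat + D(2 * fl$G12) %*% .op_dxy(grid)
  .new_operator(methods::as(mat, "CsparseMatrix"), grid, "backward", "one_sided")
}

# face-flux operators mapping a density vector to the probability flux
# through interior cell faces: J_i = f_i P - sum_j d_j (G_ij P) evaluated
# on x-faces ((N-1) x M) and y-faces (N x (M-1))
.face_flux_ops <- function(model, grid) {
  fl <- model_fields(model, grid_points(grid))
  N <- grid$N; M <- grid$M
  D <- function(v) Matrix::Diagonal(x = v)
  IM <- Matrix::Diagonal(M); IN <- Matrix::Diagonal(N)
  AX <- Matrix::kronecker(IM, .face_avg(N))
  AY <- Matrix::kronecker(.face_avg(M), IN)
  DXF <- Matrix::kronecker(IM, .face_diff(N, grid$dx))
  DYF <- Matrix::kronecker(.face_diff(M, grid$dy), IN)
  Fx <- D(as.numeric(AX %*% fl$f[, 1])) %*% AX - DXF %*% D(fl$G11)
  Fy <- D(as.numeric(AY %*% fl$f[, 2])) %*% AY - DYF %*% D(fl$G22)
  if (any(fl$G12 != 0)) {
    Fx <- Fx - AX %*% (.op_dy(grid) %*% D(fl$G12))
    Fy <- Fy - AY %*% (.op_dx(grid) %*% D(fl$G12))
  }
  list(Fx = Fx, Fy = Fy)
}

#' Assemble the discretized Kolmogorov forward (Fokker-Planck) operator
#'
#' Discretizes \eqn{L P = -\nabla \cdot J[P]} with the probability flux
#' \eqn{J_i = f_i P - \sum_j \partial_j (G_{ij} P)} evaluated on cell faces
#' and zero flux imposed on the domain boundary faces (reflecting closure).
#' Total probability is conserved exactly: the quadrature-weighted column
#' sums of the assembled matrix vanish.
#'
#' @inheritParams assemble_backward
#' @return a \code{discrete_operator} with \code{kind = "forward"}.
#' @export
assemble_forward <- function(model, grid) {
  .check_domain(model, grid)
  N <- grid$N; M <- grid$M
  IM <- Matrix::Diagonal(M); IN <- Matrix::Diagonal(N)
  DIVX <- Matrix::kronecker(IM, .div_matrix(N, grid$dx))
  DIVY <- Matrix::kronecker(.div_matrix(M, grid$dy), IN)
  # x-face flux: advective part uses face-averaged f and P; diffusive part
  # differences (G P) across the face; the cross term takes the centered
  # y-derivative of (G12 P) at nodes and averages it onto the face
  ff <- .face_flux_ops(model, grid)
  mat <- -(DIVX %*% ff$Fx + DIVY %*% ff$Fy)
  .new_operator(methods::as(mat, "CsparseMatrix"), grid, "forward", "reflecting")
}

.check_domain <- function(model, grid) {
  if (max(abs(model$domain - grid$bounds)) >
      1e-8 * max(1, max(abs(model$domain))))
    stop("grid bounds do not match the model domain")
  invisible(TRUE)
}

#' Apply a discrete operator to a (possibly complex) grid function
#'
#' @param op a \code{discrete_operator}.
#' @param u numeric or complex vector of length N*M.
#' @return vector of the same type.
#' @export
op_apply <- function(op, u) {
  if (is.complex(u))
    as.numeric(op$matrix %*% Re(u)) + 1i * as.numeric(op$matrix %*% Im(u))
  else as.numeric(op$matrix %*% u)
}

#' Export an operator as coordinate-list triplets
#'
#' Writes (row, col, value) triplets as tab-separated text plus a JSON
#' sidecar with the grid metadata; mainly for debugging and external
#' inspection.
#'
#' @param op a \code{discrete_operator}.
#' @param file path of the triplet file; the sidecar gets extension
#'   \code{.json}.
#' @return invisibly, the triplet data frame.
#' @export
op_write_coo <- function(op, file) {
  tm <- methods::as(op$matrix, "TsparseMatrix")
  df <- data.frame(row = tm@i + 1L, col = tm@j + 1L, value = tm@x)
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  g <- op$grid
  jsonlite::write_json(
    list(kind = op$kind, boundary_flavor = op$boundary_flavor,
         N = g$N, M = g$M, bounds = g$bounds, dx = g$dx, dy = g$dy),
    paste0(sub("\\.[^./]*$", "", file), ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(df)
}

#' Bilinear interpolation of a grid function
#'
#' Queries are clamped to the cell-center hull (nearest-value extension
#' beyond the outermost nodes).
#'
#' @param grid a \code{rect_grid}.
#' @param z grid function (length N*M vector).
#' @param x,y query coordinates (equal-length vectors).
#' @return interpolated values.
#' @export
grid_interp <- function(grid, z, x, y) {
  Z <- matrix(z, grid$N, grid$M)
  tx <- (x - grid$x[1]) / grid$dx
  ty <- (y - grid$y[1]) / grid$dy
  i0 <- pmin(pmax(floor(tx), 0), grid$N - 2); fx <- pmin(pmax(tx - i0, 0), 1)
  j0 <- pmin(pmax(floor(ty), 0), grid$M - 2); fy <- pmin(pmax(ty - j0, 0), 1)
  i0 <- i0 + 1L; j0 <- j0 + 1L
  Z[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    Z[cbind(i0 + 1L, j0)] * fx * (1 - fy) +
    Z[cbind(i0, j0 + 1L)] * (1 - fx) * fy +
    Z[cbind(i0 + 1L, j0 + 1L)] * fx * fy
}
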