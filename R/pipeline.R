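# Orchestration: model -> operators -> spectra -> mean period -> phase
# offset -> MRT phase -> optional Monte-Carlo check, with a serializable run
# manifest.  This is the package's single-call interface; each stage is an
# exported function and nothing here recomputes another stage's output.

#' Production grid settings for the packaged models
#'
#' @param model a \code{langevin_model} (or a model name).
#' @return list with \code{N}, \code{M} and \code{bounds}.
#' @export
default_grid_settings <- function(model) {
  name <- if (inherits(model, "langevin_model")) model$name else model
  bounds <- switch(name,
    spiral_sink  = c(-1.5, 1.5, -1.5, 1.5),
    wilson_cowan = c(-0.3, 1.0, -0.1, 0.9),
    van_der_pol  = c(-2.5, 2.5, -2.5, 2.5),
    heteroclinic = c(-pi / 2, pi / 2, -pi / 2, pi / 2),
    if (inherits(model, "langevin_model")) model$domain
    else stop("no default grid for model ", name))
  list(N = 120L, M = 120L, bounds = bounds)
}

#' Run the full phase-reduction pipeline
#'
#' Executes, in dependency order: operator assembly, stationary density,
#' backward spectrum (leading complex mode and isostable mode), mean period
#' from the stationary current, phase-offset solve, MRT phase assembly, and
#' (optionally) the Monte-Carlo MRT check.  Returns every intermediate
#' object plus a flat manifest of the scalar results; optionally writes the
#' manifest (JSON) and the grid fields (TSV) to a directory.
#'
#' @param config list with entries \code{model} (name or
#'   \code{langevin_model}), optional \code{params}, \code{N}, \code{M},
#'   \code{bounds}, \code{nev}, \code{r_min} (exclusion radius; default 0
#'   for the linear spiral sink, 5 grid cells otherwise), \code{mc} (either
#'   \code{NULL} or a list with \code{n}, \code{dt}, \code{seed},
#'   \code{level}, \code{k_points}), \code{out_dir}.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with all stage objects (\code{model},
#'   \code{grid}, \code{Lb}, \code{Lf}, \code{P0}, \code{spectrum},
#'   \code{mode}, \code{floquet}, \code{psi}, \code{J0}, \code{period},
#'   \code{dpsi}, \code{Theta}, \code{mc}) and \code{manifest}.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  model <- config$model
  if (!inherits(model, "langevin_model"))
    model <- make_model(model, config$params %||% list())
  gs <- default_grid_settings(model)
  N <- config$N %||% gs$N; M <- config$M %||% gs$M
  bounds <- config$bounds %||% gs$bounds
  if (N < 16 || M < 16)
    stop("pipeline requires N, M >= 16: coarser grids cannot resolve the phaseless region")
  if (!is.null(config$bounds) || !identical(bounds, model$domain))
    model$domain <- bounds
  grid <- make_grid(bounds, N, M)

  # the Monte-Carlo stage simulates the reflected process (the domain wall
  # is part of the truncated model), so the pipeline discretizes its exact
  # generator: the adjoint of the conservative reflecting forward operator.
  # The one-sided closure remains available through `boundary`; spectra
  # agree between the two closures to well below a percent.
  boundary <- config$boundary %||% "reflecting_adjoint"
  say("assembling operators (", N, " x ", M, ", ", boundary, ") ...")
  Lb <- assemble_backward(model, grid, boundary = boundary)
  Lf <- assemble_forward(model, grid)

  say("stationary density ...")
  P0 <- stationary_density(Lf)

  say("backward spectrum ...")
  spec <- backward_spectrum(Lb, nev = config$nev %||% 24)
  mode <- leading_complex_mode(spec)
  floq <- floquet_mode(spec)

  psi <- amplitude_phase(mode)
  psi <- align_zero_phase(psi, floq)

  say("mean period from the stationary current ...")
  J0 <- probability_current(P0, model)
  period <- mean_period(J0, psi$phaseless)
  delta_omega <- 2 * pi / period$Tbar - mode$omega

  say("phase offset ...")
  r_min <- config$r_min %||% 0
  seed <- config$dpsi_seed
  if (is.null(seed) && model$name == "spiral_sink" && !isFALSE(config$auto_seed)) {
    # linear model: the closed-form quadrupole offset is an O(eps^2)
    # accurate solution and carries the exact singular structure
    A <- t(model$drift(diag(2)))   # rows of drift(I) are A e_i
    pc <- suppressWarnings(oup_canonicalize(A, model$noise))
    Z <- grid_points(grid) %*% t(solve(pc$transform))
    seed <- oup_delta_psi(Z, pc)
  }
  dpsi <- solve_delta_psi(Lb, omega_term(psi, model), delta_omega,
                          psi$phaseless, anchor = psi$anchor, r_min = r_min,
                          seed = seed, weights = psi$u^2)
  Theta <- mrt_phase(psi, dpsi)

  mc <- NULL
  if (!is.null(config$mc)) {
    say("Monte-Carlo MRT check ...")
    mcc <- config$mc
    mc <- mrt_uniformity(Theta, model, level = mcc$level %||% 0,
                         k_points = mcc$k_points %||% 3,
                         n = mcc$n %||% 1e4, dt = mcc$dt %||% 1e-3,
                         seed = mcc$seed %||% 1,
                         horizon = 3 * period$Tbar)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("stochphase")),
    model = model$name, params = model$params[!vapply(model$params, is.function, TRUE)],
    grid = list(N = N, M = M, bounds = bounds),
    boundary_flavor = Lb$boundary_flavor,
    lambda1 = list(mu = mode$mu, omega = mode$omega),
    lambda_floq = floq$lambda,
    quality_factor = mode$quality,
    gap_ok = mode$gap_ok,
    Tbar = period$Tbar,
    two_pi_over_omega = 2 * pi / mode$omega,
    delta_omega = delta_omega,
    delta_omega_used = dpsi$delta_omega_used,
    orientation = period$orientation,
    phaseless = as.numeric(psi$phaseless),
    anchor = as.numeric(psi$anchor),
    r_min = r_min,
    dpsi_residual_max = dpsi$residual_max,
    dpsi_residual_input_max = dpsi$residual_input_max,
    dpsi_flagged = dpsi$flagged)
  if (!is.null(mc))
    manifest$mc <- list(grand_mean = mc$grand_mean, flatness = mc$flatness,
                        pass = mc$pass, n = mc$n, dt = mc$dt, seed = mc$seed)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    wr <- function(v, nm)
      utils::write.table(matrix(v, grid$N, grid$M),
                         file.path(config$out_dir, paste0(nm, ".tsv")),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
    wr(psi$phase, "psi"); wr(Theta$phase, "theta")
    wr(dpsi$delta_psi, "delta_psi"); wr(psi$u, "amplitude")
    wr(floq$fun, "sigma"); wr(P0$fun, "p0")
    if (!is.null(mc))
      write_return_time_report(mc, file.path(config$out_dir, "mrt_check.csv"))
    jsonlite::write_json(list(N = grid$N, M = grid$M, bounds = grid$bounds,
                              dx = grid$dx, dy = grid$dy),
                         file.path(config$out_dir, "grid.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  invisible(list(model = model, grid = grid, Lb = Lb, Lf = Lf, P0 = P0,
                 spectrum = spec, mode = mode, floquet = floq, psi = psi,
                 J0 = J0, period = period, dpsi = dpsi, Theta = Theta,
                 mc = mc, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
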