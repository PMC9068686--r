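# Monte-Carlo verification of the mean-return-time property: simulate the
# SDE with an Euler-Heun scheme, read the phase along each trajectory from a
# smooth interpolant, and record the first time the unwrapped phase has
# gained 2*pi.  If a phase field has the MRT property, that mean time is the
# same for every start point on an isochron and equals the mean period.

#' Simulate an ensemble of SDE trajectories
#'
#' Euler-Heun (predictor-corrector drift, single stochastic increment; for
#' the packaged constant-noise models this coincides with Euler-Maruyama in
#' distribution up to the deterministic corrector).  Paths reflect at the
#' domain walls for every model: the truncation box is part of the model
#' the discretized operators describe (their forward closure is
#' reflecting), so the simulated process matches the operator pipeline.
#' Wall contacts are rare for the unbounded models away from excitable
#' excursions, but not negligible, and ignoring the wall would let the
#' pathwise and ensemble descriptions drift apart.
#'
#' @param model a packaged \code{langevin_model} with constant noise.
#' @param x0 common start point \code{c(x, y)} inside the domain.
#' @param dt time step.
#' @param horizon total integration time per path.
#' @param n number of paths.
#' @param seed RNG seed (set via \code{set.seed}).
#' @param save_every thin the stored trajectory to every so-many steps.
#' @return list with matrices \code{x}, \code{y} (paths by saved times) and
#'   the vector \code{times} of saved time points.
#' @export
simulate_paths <- function(model, x0, dt = 1e-3, horizon = 10, n = 100,
                           seed = 1, save_every = 1L) {
  .check_simulable(model)
  stopifnot(dt > 0, n >= 1)
  if (x0[1] < model$domain[1] || x0[1] > model$domain[2] ||
      x0[2] < model$domain[3] || x0[2] > model$domain[4])
    stop("x0 outside the model domain")
  nsteps <- as.integer(round(horizon / dt))
  set.seed(seed)
  out <- cpp_simulate_paths(model$sim_code, model$sim_pars,
                            as.numeric(model$noise), as.numeric(x0), dt,
                            nsteps, as.integer(n), as.integer(save_every),
                            model$domain,
                            TRUE)  # reflect at the domain walls (see Details)
  out$times <- seq(0, nsteps %/% save_every) * (dt * save_every)
  out
}

.check_simulable <- function(model) {
  if (model$sim_code == 0L)
    stop("Monte-Carlo simulation is implemented for the packaged models only")
  if (!model$constant_noise)
    stop("Monte-Carlo simulation assumes a constant noise matrix")
  invisible(TRUE)
}

#' Continuous phase map from a grid phase field
#'
#' Bicubic (Catmull-Rom) interpolation applied to cos and sin of the phase
#' separately and recombined with \code{atan2}, which is continuous across
#' the \eqn{0/2\pi} branch cut.  Queries outside the domain are clamped to
#' the nearest boundary value.
#'
#' @param grid a \code{rect_grid} (taken from the field if omitted).
#' @param field a \code{phase_field} or a numeric vector of wrapped phases.
#' @return a function \code{(x, y) -> phase in [0, 2pi)}; the interpolation
#'   tables are attached as attributes for the Monte-Carlo backend.
#' @export
phase_interpolant <- function(field, grid = NULL) {
  if (inherits(field, "phase_field")) { grid <- field$grid; ph <- field$phase }
  else { ph <- field; stopifnot(!is.null(grid)) }
  cP <- cos(ph); sP <- sin(ph)
  g <- grid
  fn <- function(x, y) {
    if (any(x < g$bounds[1] - 1e-9) || any(x > g$bounds[2] + 1e-9) ||
        any(y < g$bounds[3] - 1e-9) || any(y > g$bounds[4] + 1e-9))
      stop("phase query outside the domain")
    cv <- cpp_interp2(cP, g$N, g$M, c(g$x[1], g$y[1]), c(g$dx, g$dy), x, y)
    sv <- cpp_interp2(sP, g$N, g$M, c(g$x[1], g$y[1]), c(g$dx, g$dy), x, y)
    atan2(sv, cv) %% (2 * pi)
  }
  attr(fn, "cosP") <- cP
  attr(fn, "sinP") <- sP
  attr(fn, "grid") <- g
  fn
}

#' Mean return time of a phase field from one start point
#'
#' Simulates \code{n} paths from \code{x0}, unwraps the interpolated phase
#' incrementally (assuming per-step increments below \eqn{\pi}) and records
#' the first time the unwrapped phase exceeds its initial value by
#' \eqn{2\pi}.  Paths not returning within the horizon invalidate the run
#' when they exceed 0.1\% of the ensemble.
#'
#' @param phase_map a \code{\link{phase_interpolant}} (or a
#'   \code{phase_field}, converted internally).
#' @param x0 start point.
#' @param model the \code{langevin_model} being simulated.
#' @param n number of realizations.
#' @param dt time step (the scheme is \eqn{O(10^{-3})} by default).
#' @param seed RNG seed.
#' @param horizon integration horizon; use about \eqn{3\bar T}.
#' @param on_invalid \code{"error"} (default) or \code{"warn"} when too many
#'   paths fail to return.
#' @return list with \code{mean}, \code{se}, \code{n}, \code{n_returned},
#'   \code{nonreturn_frac}, \code{times} (per-path return times),
#'   \code{clamped_steps}, \code{bigstep_count}.
#' @export
mean_return_time <- function(phase_map, x0, model, n = 1e4, dt = 1e-3,
                             seed = 1, horizon, on_invalid = "error") {
  if (inherits(phase_map, "phase_field")) phase_map <- phase_interpolant(phase_map)
  .check_simulable(model)
  g <- attr(phase_map, "grid")
  maxsteps <- as.integer(round(horizon / dt))
  set.seed(seed)
  out <- cpp_return_times(model$sim_code, model$sim_pars,
                          as.numeric(model$noise),
                          attr(phase_map, "cosP"), attr(phase_map, "sinP"),
                          g$N, g$M, c(g$x[1], g$y[1]), c(g$dx, g$dy),
                          as.numeric(x0), as.integer(n), dt, maxsteps,
                          model$domain,
                          TRUE)  # reflect at the domain walls (see Details)
  tms <- out$times[!is.na(out$times)]
  frac <- out$nonreturn / n
  if (frac > 1e-3) {
    msg <- sprintf("%.2f%% of paths did not return within the horizon", 100 * frac)
    if (identical(on_invalid, "error")) stop(msg) else warning(msg)
  }
  # grazing the phaseless point produces rare large increments; only a
  # systematic fraction indicates an undersized dt
  if (out$bigstep > 1e-5 * n * maxsteps)
    warning(sprintf("%d phase increments exceeded 2.5 rad; consider a smaller dt",
                    out$bigstep))
  list(mean = mean(tms), se = stats::sd(tms) / sqrt(length(tms)),
       n = n, n_returned = length(tms), nonreturn_frac = frac,
       times = tms, clamped_steps = out$clamped, bigstep_count = out$bigstep)
}

#' Sample points along an isochron of a phase field
#'
#' Extracts the level set \code{phase = level} (computed branch-cut free as
#' the zero contour of \eqn{\sin(\mathrm{phase} - \mathrm{level})} where
#' \eqn{\cos > 0}) and returns \code{k} points spread along the amplitude
#' direction, excluding a disc around the phaseless point.
#'
#' @param field a \code{phase_field}.
#' @param level isochron phase in \eqn{[0, 2\pi)}.
#' @param k number of points.
#' @param r_excl exclusion radius around the phaseless point; defaults to
#'   20\% of the smaller domain half-width, inside which phase diffusion is
#'   too strong for return times to settle within a few mean periods.
#' @return k x 2 matrix of points.
#' @export
isochron_points <- function(field, level, k = 3, r_excl = NULL) {
  stopifnot(inherits(field, "phase_field"), k >= 1)
  g <- field$grid
  if (is.null(r_excl))
    r_excl <- 0.20 * 0.5 * min(diff(g$bounds[1:2]), diff(g$bounds[3:4]))
  z <- sin(field$phase - level)
  cl <- grDevices::contourLines(g$x, g$y, matrix(z, g$N, g$M), levels = 0)
  if (length(cl) == 0) stop("isochron level set is empty")
  xs <- unlist(lapply(cl, `[[`, "x")); ys <- unlist(lapply(cl, `[[`, "y"))
  keep <- grid_interp(g, cos(field$phase - level), xs, ys) > 0.5
  r <- sqrt((xs - field$phaseless[1])^2 + (ys - field$phaseless[2])^2)
  # stay clear of the boundary too: the interpolant flattens there
  mrg <- 2.5
  inb <- xs > g$bounds[1] + mrg * g$dx & xs < g$bounds[2] - mrg * g$dx &
         ys > g$bounds[3] + mrg * g$dy & ys < g$bounds[4] - mrg * g$dy
  keep <- keep & r >= r_excl & inb
  if (!any(keep)) stop("isochron entirely inside the exclusion disc")
  xs <- xs[keep]; ys <- ys[keep]; r <- r[keep]
  ord <- order(r)
  qs <- stats::quantile(seq_along(ord), probs = seq(0.2, 0.8, length.out = k))
  sel <- ord[round(qs)]
  cbind(x = xs[sel], y = ys[sel])
}

#' Check the MRT property along one isochron
#'
#' Runs \code{\link{mean_return_time}} from \code{k_points} start points on
#' the chosen isochron and reports the per-point means, their flatness (max
#' relative spread), and a verdict against \code{tol} plus three combined
#' standard errors.
#'
#' @param field a \code{phase_field} (either phase notion).
#' @param model the \code{langevin_model}.
#' @param level isochron phase level.
#' @param k_points number of start points along the isochron (\code{>= 3}).
#' @param n,dt,seed Monte-Carlo settings (per point; seeds are offset).
#' @param horizon integration horizon, about \eqn{3\bar T}.
#' @param tol relative flatness tolerance (default 1\%).
#' @param r_excl exclusion radius passed to \code{\link{isochron_points}}.
#' @param on_invalid passed to \code{\link{mean_return_time}}; use
#'   \code{"warn"} when probing a field expected to violate the MRT
#'   property (non-returning tails are then part of the finding).
#' @return object of class \code{return_time_report}.
#' @export
mrt_uniformity <- function(field, model, level = 0, k_points = 3, n = 1e4,
                           dt = 1e-3, seed = 1, horizon, tol = 0.01,
                           r_excl = NULL, on_invalid = "error") {
  stopifnot(k_points >= 3)
  pts <- isochron_points(field, level, k_points, r_excl)
  pm <- phase_interpolant(field)
  means <- ses <- numeric(nrow(pts))
  runs <- vector("list", nrow(pts))
  for (k in seq_len(nrow(pts))) {
    runs[[k]] <- mean_return_time(pm, pts[k, ], model, n = n, dt = dt,
                                  seed = seed + k - 1, horizon = horizon,
                                  on_invalid = on_invalid)
    means[k] <- runs[[k]]$mean; ses[k] <- runs[[k]]$se
  }
  grand <- mean(means)
  flatness <- (max(means) - min(means)) / grand
  se_rel <- 3 * sqrt(max(ses)^2 + stats::median(ses)^2) / grand
  structure(list(points = pts, means = means, ses = ses, grand_mean = grand,
                 flatness = flatness, tol = tol, level = level,
                 pass = flatness <= tol + se_rel,
                 n = n, dt = dt, seed = seed, horizon = horizon,
                 label = field$label, runs = runs),
            class = "return_time_report")
}

#' @export
as.data.frame.return_time_report <- function(x, ...) {
  data.frame(x0 = x$points[, 1], y0 = x$points[, 2],
             mean = x$means, se = x$ses,
             n = vapply(x$runs, function(r) r$n_returned, 1),
             nonreturn_frac = vapply(x$runs, function(r) r$nonreturn_frac, 1))
}

#' Write a return-time report as CSV plus a JSON verdict
#'
#' @param x a \code{return_time_report}.
#' @param file CSV path; the verdict sidecar gets extension \code{.json}.
#' @return invisibly, the data frame written.
#' @export
write_return_time_report <- function(x, file) {
  df <- as.data.frame(x)
  utils::write.csv(df, file, row.names = FALSE)
  jsonlite::write_json(
    list(label = x$label, level = x$level, grand_mean = x$grand_mean,
         flatness = x$flatness, tol = x$tol, pass = x$pass,
         n = x$n, dt = x$dt, seed = x$seed, horizon = x$horizon),
    paste0(sub("\\.[^./]*$", "", file), ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(df)
}

#' @export
print.return_time_report <- function(x, ...) {
  cat(sprintf("MRT property check for '%s' isochron at level %.3f:\n",
              x$label, x$level))
  for (k in seq_along(x$means))
    cat(sprintf("  start (%+.3f, %+.3f): mean %.4f  SE %.4f\n",
                x$points[k, 1], x$points[k, 2], x$means[k], x$ses[k]))
  cat(sprintf("  grand mean %.4f, flatness %.3f%% (tol %.1f%% + 3 SE) -> %s\n",
              x$grand_mean, 100 * x$flatness, 100 * x$tol,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
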