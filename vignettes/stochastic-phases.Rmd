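---
title: "Two notions of phase for noisy planar oscillators: methods and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two notions of phase for noisy planar oscillators: methods and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A deterministic oscillator has a single, unambiguous phase: the asymptotic
phase of a point equals the phase of the cycle point it converges to, and its
level sets (isochrons) are simultaneously the Poincaré sections whose return
time equals the period. Noise breaks this equivalence. For a planar Langevin
system

$$\dot X = f(X) + g\,\xi(t), \qquad G = \tfrac12 g g^\top,$$

two inequivalent phase notions coexist:

* the **stochastic asymptotic phase** $\psi(x)$ — the argument of the
  slowest-decaying complex eigenfunction $Q^*_{\lambda_1} = u\,e^{i\psi}$ of
  the Kolmogorov backward operator
  $L^\dagger[h] = f\cdot\nabla h + \sum_{ij} G_{ij}\partial_i\partial_j h$,
  with $\lambda_1 = \mu + i\omega$, $\mu<0<\omega$. It describes the damped
  rotation of the ensemble toward its stationary density and evolves in the
  mean at rate $\omega$;
* the **mean–return-time (MRT) phase** $\Theta(x)$ — the phase whose level
  sets are Poincaré sections with position-independent mean return time
  $\bar T$ after one full rotation; it satisfies
  $L^\dagger \Theta = 2\pi/\bar T$ and describes individual trajectories over
  one rotation.

Both can be computed from one discretization of $L^\dagger$. Splitting the
eigenvalue relation for $Q^*_{\lambda_1}$ into modulus and argument gives

$$L^\dagger[\psi] + \underbrace{2\sum_{ij} G_{ij}\,
  \partial_i \ln u \,\partial_j \psi}_{\Omega(x)} = \omega,$$

so the single-valued offset $\Delta\psi = \Theta - \psi$ obeys

$$L^\dagger[\Delta\psi] = \Omega(x) + \Delta\omega, \qquad
  \Delta\omega = 2\pi/\bar T - \omega,$$

with $\bar T$ obtained from the flux of the stationary probability current
$J_0 = f P_0 - \nabla\cdot(G P_0)$ through any cut from the phaseless point
(where $u = 0$ and no phase exists) to the boundary. The package computes
$P_0$, $(\lambda_1, Q^*_{\lambda_1})$, the slowest purely real mode
$(\lambda_{\mathrm{Floq}}, \Sigma)$ (the stochastic isostables, whose zero
level set — the "stochastic limit cycle" — anchors the phase zero), $\bar T$,
$\Delta\psi$, $\Theta$, and finally verifies the MRT property by simulating
the SDE.

```{r}
library(stochphase)
res <- run_pipeline(list(model = "van_der_pol"))
res$manifest$Tbar               # mean period from the stationary current
res$manifest$lambda1            # mu, omega of the leading mode
plot_ready <- matrix(res$Theta$phase, res$grid$N, res$grid$M)
```

# Models

Four planar systems ship with the package (`make_model`), spanning the three
dynamical scenarios in which stochastic phases are studied:

| model | mechanism | noise defaults |
|---|---|---|
| `spiral_sink` | noise-induced oscillation around a stable focus (a gamma-band EEG rhythm model); linear, with every quantity available in closed form | $B=\sqrt{2D}\,\mathrm{diag}(1,0.5)$, $D=0.01125$ |
| `wilson_cowan` | noisy limit cycle near a Hopf bifurcation in the classic E–I rate model | $D_e = 0.1$, $D_i = 0.05$ |
| `van_der_pol` | noisy relaxation-type limit cycle, strongly anisotropic noise | $[D_x,D_y]=\sqrt{2D}\,[1,0.1]$, $D=0.1$ |
| `heteroclinic` | noise-sustained oscillation around a heteroclinic loop, reflecting walls at $\pm\pi/2$ | $\sqrt{2D}$, $D \in \{0.01125, 0.1\}$ |

The Wilson–Cowan defaults use the inhibitory self-coupling $c_4 = 3$ of the
classic oscillatory parameter set; at these values the deterministic cycle has
period $5.26$ and the noisy system the leading eigenvalue
$-0.435 + 1.049\,i$, the regime every reference quantity in the test suite corresponds to.

For the linear model the package carries the full set of closed-form
references (`oup_*`): canonicalization of an arbitrary stable focus
$(A, B)$ into $(\mu, \omega, \epsilon, \beta_D, \beta_c)$, the stationary
covariance $\epsilon\Pi$, the noise-induced phase drift $\Omega$, the
quadrupole phase offset $\Delta\psi$, and the mean period both as the
printed algebraic closed form (`oup_mean_period`) and as exact quadrature of
the analytic current (`oup_mean_period_current`). The two differ by about
0.5% for anisotropic noise; the operator pipeline converges to the
quadrature value, which is therefore the oracle used in tests. The printed
algebraic form is retained verbatim for reference. Similarly, the
off-diagonal sign of $\Pi$ is fixed so that $\epsilon\Pi$ solves the
stationary Lyapunov equation $A C + C A^\top + 2G = 0$ and inverts the
(correct) precision matrix used by the density — all three checks agree to
machine precision, and a simulated path reproduces the negative
cross-covariance.

# Discretization

The domain (per-model defaults via `default_grid_settings`) is tiled
by $N \times M$ cells with unknowns at cell centers. The uniform cell weight
$\Delta x\,\Delta y$ sums exactly to the domain area, and a cell-centered
layout puts the reflecting closure naturally on the boundary faces. (A
trapezoidal node quadrature was considered and rejected: uniform cell weights
make probability conservation and the discrete adjoint exact rather than
approximate.)

* **Forward operator** (`assemble_forward`): flux form
  $L P = -\nabla\cdot J[P]$ with face-centered fluxes and zero flux on
  boundary faces. Column sums vanish identically — probability is conserved
  to rounding, and the stationary eigenvalue is exactly zero.
* **Backward operator** (`assemble_backward`): second-order centered
  differences inside; two closures at the border. `"one_sided"` replaces the
  centered stencils by inward one-sided ones (second order for first
  derivatives, first order for second derivatives — the lowest order that
  keeps constants an exact null vector). `"reflecting_adjoint"` transposes
  the conservative forward operator against the uniform quadrature, making
  the duality $\langle L^\dagger u, v\rangle = \langle u, L v\rangle$ exact.
  The pipeline uses the adjoint-reflecting closure for every model, because
  the Monte-Carlo stage simulates the process reflected at the truncation
  box and this closure is that process's exact generator. The two closures
  give eigenvalues agreeing to well under a percent.

Eigensolves use shift-invert Arnoldi: a sparse LU factorization of
$(A - \sigma I)$ with a small real shift turns the low-lying spectrum — the
only part needed — into the dominant eigenvalues of the inverse. On a
$120^2$ grid one solve takes about a second.

# From spectrum to phases

`amplitude_phase` splits $Q^*_{\lambda_1}$ into $u = |Q|$ and
$\psi = \arg Q$, locates the phaseless point as the argmin of $u$ refined by
a local quadratic fit, and records the spatial winding of $\psi$ around it.
With the convention $\omega > 0$ the phase advances at rate $+\omega$ along
trajectories for every model, while the spatial winding equals the flow's
rotation sense ($+1$ counterclockwise, $-1$ for the clockwise heteroclinic
rotor). The winding is deliberately recorded rather than normalized:
conjugating the eigenfunction to force a winding would detach it from its
eigenvalue and flip the sign of the phase-offset equation.

All derivatives of $\ln u$ and $\psi$ used downstream are taken as real and
imaginary parts of $\nabla Q / Q$, which is smooth across the $2\pi$ branch
cut of the wrapped phase.

The zero phase is anchored (`align_zero_phase`) at the point of maximal $x$
on the zero level set of the stochastic isostable function $\Sigma$ (the
slowest purely real backward mode), and the same anchor is reused for
$\Theta$, so the two phases are directly comparable.

# Mean period

`probability_current` evaluates the node current $J_0$ (for diagnostics and
comparison with the closed form) and the face fluxes of the conservative
forward discretization. `mean_period` sums those face fluxes across a cut
from the phaseless point to the boundary. Because the discrete divergence of
the face fluxes is exactly $L P_0 \approx 0$, the total flux is
cut-independent to the eigensolver tolerance — the four rays agree to many
digits, versus about 1% for the node-interpolated trapezoid the `"node"`
method implements. The face sum also captures the boundary-layer current
squeezed against a reflecting wall, which the node ray misses entirely: for
the low-noise heteroclinic oscillator the node ray overestimates the period
by 6% while the face sum is accurate to 0.1%.

# The phase offset

`solve_delta_psi` solves $L^\dagger \Delta\psi = \Omega + \Delta\omega$ as a
damped weighted least-squares problem on the sparse operator, with three
numerical safeguards:

1. **Row confidence weights $u^2$.** The right-hand side degrades as the
   phaseless point is approached ($\Omega \sim r^{-2}$ with discretization
   error of the same order), but discarding those rows outright (a hard
   exclusion disc) leaves a one-parameter family of near-solutions — a
   smooth, logarithm-like near-kernel mode trading against the constant —
   and the minimum-norm tie-break picks an arbitrary member. Weighting rows
   by the squared eigenfunction amplitude keeps the near-phaseless rows
   weakly active, which pins the singular structure without letting their
   errors dominate. A hard radius `r_min` remains available.
2. **A consistent $\Delta\omega$.** Because constants span the kernel of
   $L^\dagger$, a right-hand-side constant violating the discrete
   solvability condition leaks into the slowly-growing log mode. The face
   flux $\bar T$ is discretely conservative, so the supplied
   $\Delta\omega = 2\pi/\bar T - \omega$ already satisfies the condition to
   rounding (checked to $3\times10^{-6}$ for the linear model); an optional
   `compatibility` refit of the constant is kept as a diagnostic.
3. **An analytic seed for linear models.** For the spiral sink the
   closed-form quadrupole offset solves the equation with an
   $O(\epsilon^2)$ spatially-varying error and carries the exact $r^{-2}$
   singularity; the solver then only computes a smooth correction. The
   pipeline derives the seed automatically by canonicalizing the drift
   matrix.

Residuals are reported over the trusted region (amplitude above about a
third of its maximum): max and rms, plus the residual against the supplied
$\Delta\omega$, which is the pipeline-consistency diagnostic that shrinks
under grid refinement. Solutions exceeding the threshold are flagged, never
silently accepted. Nodes untouched by any weighted row (deep inside the
phaseless region when a hard `r_min` is used) are filled by harmonic
inpainting. The gauge is fixed exactly by subtracting the value at the
anchor node.

`mrt_phase` then forms $\Theta = \psi + \Delta\psi$, wrapped and re-anchored.

# Monte-Carlo verification

`mean_return_time` simulates Euler–Heun paths (Rcpp backend, R's RNG, hence
fully reproducible under `set.seed`) and reads the phase along each path
from bicubic (Catmull–Rom) interpolants of $\cos\Theta$ and $\sin\Theta$,
recombined through `atan2` so the branch cut never appears. The unwrapped
phase is accumulated step to step (increments assumed below $\pi$; violations
are counted) and the first time it gains $2\pi$ is recorded, with sub-step
linear interpolation of the crossing.

Paths reflect at the domain walls for **all** models, not only the
heteroclinic one: the truncation box is part of the model the operators
describe (the forward closure is reflecting). This matters in practice — the
noisy Wilson–Cowan system spends about 3% of its time beyond the standard
box on noise-triggered excitable excursions, and with free flight the
pathwise rotation period (5.97) disagrees with the operator's 5.72, while
the reflected process matches it to 0.08%.

`mrt_uniformity` runs the check from `k` points spread along an isochron
(amplitude quantiles 0.2–0.8, excluding 20% of the half-width around the
phaseless point where phase diffusion is too strong for returns to settle
within a few periods) and reports per-point means, SEs, the flatness
statistic, and a verdict at `tol` (default 1%) plus three combined standard
errors. Runs where more than 0.1% of paths fail to return within the horizon
(default guidance: $3\bar T$) error by default; probing a field *expected*
to violate the MRT property is done with `on_invalid = "warn"`, since the
heavy non-returning tail is then part of the finding.

# Parameters that matter

| parameter | meaning | default | rationale |
|---|---|---|---|
| `N, M` | grid cells per axis | 120 | resolves all packaged models' spectra to ≲1%; the pipeline refuses below 16 |
| `nev` | Arnoldi window | 24 | low-lying spectrum only; contains both leading modes with margin |
| `sigma` | shift | $10^{-4}\times$ op. scale | right of the spectrum, far from the bulk |
| `r_min` | hard exclusion radius | 0 | superseded by $u^2$ weighting |
| `damping` | Tikhonov weight | $10^{-8}\times$ op. scale | tie-break only |
| `dt` | Euler–Heun step | $10^{-3}$ | phase increments ≪ π; weak bias ≪ MC error. The stiff cubic Van der Pol drift at its large noise amplitude is the exception: its weak bias at $10^{-3}$ is −0.25% of the period (visible at $n = 10^4$), vanishing by $2.5\times10^{-4}$, so return-time checks for that model use the finer step |
| `n` | paths per start point | $10^4$ | SE ≈ 0.02–0.06 time units; $10^5$ for production-grade SE |
| horizon | per-path time budget | $3\bar T$ | near-total return probability |

Problem sizes used by the test suite: unit tests run on $32^2$–$96^2$ grids
and small ensembles; the quantitative acceptance checks run the five model
configurations at $120^2$ with $n = 10^4$ paths per start point. The
Wilson–Cowan MRT verification runs on $240^2$: at $120^2$ the sharply curved
phase structure near the phaseless point leaves a −0.8% truncation bias in
the interpolated return times (dt-refinement and tail-censoring were ruled
out as causes), which the finer grid removes. All operator-level reported
numbers remain $120^2$ values.

# Known limitations

* Planar systems only; the grid is rectangular and simply connected (no
  annular meshes). The phaseless point is localized only to about a grid
  spacing, and phases within a few cells of it are interpolations, not
  solutions.
* The Monte-Carlo backend covers the packaged models (and any linear model)
  with constant noise matrices; custom drifts run through the operator
  pipeline but not the C++ path simulator.
* Reruns are deterministic to the Arnoldi convergence tolerance (~1e-8
  relative), not bit-for-bit, because the eigensolver's starting vector is
  not seeded; all Monte-Carlo stages are bit-reproducible given a seed.
* At the default $3\bar T$ horizon a 0.1–0.6% non-returning tail can remain
  for start points near the phaseless region; the induced censoring bias is
  an order of magnitude below the Monte-Carlo standard error but is the
  reason validity gating is strict by default.
* For oscillators whose leading eigenvalue is real (not robustly
  oscillatory), the asymptotic phase does not exist and
  `leading_complex_mode` fails loudly rather than returning a spurious pair.
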