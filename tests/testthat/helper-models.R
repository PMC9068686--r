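# Shared fixtures: canonical noisy-focus parameters and memoized pipeline
# runs so expensive eigensolves are shared between test files (the cache
# lives for the duration of one test session).

.fixture_cache <- new.env(parent = emptyenv())

canon_focus <- function() canonical_oup(mu = -0.0796, omega = 0.564,
                                        eps = 0.0046, betaD = -0.74,
                                        betaC = 0.11)

canon_focus_model <- function() {
  p <- canon_focus()
  make_model("spiral_sink", list(mu = p$mu, omega = p$omega, eps = p$eps,
                                 betaD = p$betaD, betaC = p$betaC))
}

# full production-grid pipeline, computed once per (model, variant)
cached_pipeline <- function(key, config) {
  if (!exists(key, envir = .fixture_cache)) {
    res <- suppressWarnings(run_pipeline(config, quiet = TRUE))
    assign(key, res, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

pipeline_oup <- function()
  cached_pipeline("oup", list(model = "spiral_sink",
    params = list(mu = -0.0796, omega = 0.564, eps = 0.0046,
                  betaD = -0.74, betaC = 0.11)))

pipeline_wc <- function() cached_pipeline("wc", list(model = "wilson_cowan"))
pipeline_vdp <- function() cached_pipeline("vdp", list(model = "van_der_pol"))
pipeline_het_low <- function() cached_pipeline("hetlo", list(model = "heteroclinic"))
pipeline_het_high <- function()
  cached_pipeline("hethi", list(model = "heteroclinic", params = list(D = 0.1)))

# small-grid operator fixture for unit tests
small_oup_ops <- function(N = 48) {
  key <- paste0("smallops", N)
  if (!exists(key, envir = .fixture_cache)) {
    m <- canon_focus_model()
    g <- make_grid(m$domain, N, N)
    assign(key, list(model = m, grid = g,
                     Lb = assemble_backward(m, g),
                     Lf = assemble_forward(m, g)),
           envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# wrapped angular difference in (-pi, pi]
wrap_pi <- function(x) atan2(sin(x), cos(x))
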