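# Shared fixtures. Heavy simulations are built once per test run and cached;
# all fixtures are generated in code, nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 16 modules of 8 x 8 px: same topology as the default detector, 9x fewer
# pixels, for fast unit tests.
small_geometry <- function(...) {
  geometry_config(layout = agipd_like_layout(c(8L, 8L), 4L), ...)
}

# Constant-concentration run with the default 2% artifact contamination:
# the frame-filter study condition.
filter_run <- function() cached_fixture("filter_run", {
  cfg <- simulation_config(geometry = geometry_config(),
                           pulses_per_train = 16L, duration = 60,
                           concentration = concentration_constant(1),
                           seed = 202L)
  run <- simulate_run(cfg)
  ph <- photonize(run$stack)
  metrics <- compute_metrics(ph)
  filt <- filter_outliers(metrics)
  list(run = run, photons = ph, metrics = metrics, filter = filt)
})

# 60-s autosampler elution run plus its full reduction: the end-to-end
# study condition.
autosampler_run <- function() cached_fixture("autosampler_run", {
  cfg <- simulation_config(geometry = geometry_config(),
                           pulses_per_train = 16L, duration = 60,
                           concentration = concentration_elution(30, 6),
                           seed = 101L)
  run <- simulate_run(cfg)
  red <- reduce_autosampler_run(run$stack, xgm = run$truth$xgm)
  list(run = run, reduction = red)
})

# Analytic solid-sphere reference data used across the analysis tests.
sphere_reference <- function() cached_fixture("sphere_reference", {
  radius <- 3
  s <- seq(0.05, 2.5, by = 0.02)
  prof <- analytic_intensity(solid_sphere(radius, i0 = 100), s)
  list(radius = radius, rg = sqrt(3 / 5) * radius, s = s, i = prof$i)
})
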