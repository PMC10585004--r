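# Synthetic profile helpers: buffer-like curves with controlled drift and
# noise, bypassing the frame simulator for speed and full control.
flat_profile <- function(s, level, sigma, t_mid, n_frames = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  i <- level + rnorm(length(s), 0, sigma)
  profile1d(s, i, rep(sigma, length(s)), counts = rep(n_frames, length(s)),
            meta = list(t_mid = t_mid, n_frames = n_frames))
}

test_that("the trace of a constant-concentration run is flat to Poisson noise", {
  fx <- filter_run()
  norm <- normalize_pulse_intensity(fx$photons, fx$run$truth$xgm)
  pairs <- average_frames(norm, keep = fx$filter$keep, mode = "per_second")
  profiles <- lapply(pairs, azimuthal_integrate, geom = fx$photons$geometry,
                     n_bins = 96)
  trace <- build_trace(profiles)
  v <- trace$intensity[is.finite(trace$intensity)]
  expect_gte(length(v), 60)
  expect_lt(sd(v) / mean(v), 0.02)
})

test_that("the elution trace peaks at the configured time and the sample window tracks true concentration", {
  fx <- autosampler_run()
  trace <- fx$reduction$trace
  peak_t <- trace$time[which.max(trace$intensity)]
  expect_lt(abs(peak_t - 30), 1)

  wins <- attr(trace, "windows")
  truth <- fx$run$truth
  conc_sec <- tapply(truth$concentration, floor(fx$run$stack$time), mean)
  top <- which(conc_sec >= 0.5 * max(conc_sec))  # seconds at >= 50% of peak
  overlap <- length(intersect(wins$sample, top)) / length(top)
  expect_gte(overlap, 0.9)
  # windows ordered buffer_before < sample < buffer_after and disjoint
  expect_lt(max(wins$buffer_before), min(wins$sample))
  expect_lt(max(wins$sample), min(wins$buffer_after))
})

test_that("a flat trace yields buffer-only annotation; an edge peak loses one buffer", {
  s <- seq(0.1, 2, length.out = 50)
  profs <- lapply(1:40, function(k) flat_profile(s, 5, 0.01, k - 0.5, seed = k))
  trace <- select_windows(build_trace(profs))
  expect_true("no_peak" %in% attr(trace, "flags"))
  expect_length(attr(trace, "windows")$sample, 0)

  # peak at the trailing edge: only buffer_before is available
  profs2 <- lapply(1:40, function(k)
    flat_profile(s, 5 + ifelse(k > 36, 3, 0), 0.01, k - 0.5, seed = 100 + k))
  trace2 <- select_windows(build_trace(profs2))
  expect_true("no_buffer_after" %in% attr(trace2, "flags"))
  expect_gt(length(attr(trace2, "windows")$buffer_before), 0)
})

test_that("buffer estimation identities: equal buffers, 7% drift interpolation", {
  s <- seq(0.1, 2, length.out = 60)
  before <- flat_profile(s, 4, 0.001, t_mid = 10, seed = 41)
  # before = after -> either mode returns the input, drift 0
  same <- buffer_estimate(before, before, mode = "average")
  expect_equal(same$i, before$i, tolerance = 1e-12)
  expect_identical(attr(same, "drift_stat"), 0)

  # after = 1.07 x before, interpolated at the midpoint -> 1.035 x before
  after <- profile1d(s, 1.07 * before$i, before$sigma, counts = before$counts,
                     meta = list(t_mid = 50, n_frames = 1000))
  mid <- buffer_estimate(before, after, mode = "interpolate", t_eval = 30)
  expect_equal(mid$i, 1.035 * before$i, tolerance = 1e-12)
  expect_equal(attr(mid, "drift_stat"), 0.07, tolerance = 1e-9)

  # single buffer -> degraded mode
  only <- buffer_estimate(before, NULL)
  expect_identical(attr(only, "mode_used"), "degraded_single")
})

test_that("interpolation beats averaging when buffer windows are asymmetric about the sample", {
  set.seed(55)
  s <- seq(0.1, 2, length.out = 80)
  sig <- 0.002
  base <- 4 + 0.5 * exp(-s)           # buffer shape
  signal <- 0.2 * exp(-(s * 2.4)^2 / 3)  # protein-like low-s signal
  drift <- function(t) 1 + 0.002 * (t - 30)  # 0.2%/s linear drift
  t_b1 <- 6; t_b2 <- 52; t_samp <- 22     # asymmetric flanking windows
  mk <- function(level, t) profile1d(s, level * drift(t) + rnorm(length(s), 0, sig),
                                     rep(sig, length(s)),
                                     meta = list(t_mid = t, n_frames = 1))
  before <- mk(base, t_b1); after <- mk(base, t_b2)
  sample_p <- mk(base + signal, t_samp)

  chi2_vs_truth <- function(buf) {
    out <- subtract_buffer(sample_p, buf, scale_policy = "none")
    chi2_fit(out$profile$i, signal * drift(t_samp), out$profile$sigma,
             fit_scale = FALSE)$chi2
  }
  c_int <- chi2_vs_truth(buffer_estimate(before, after, "interpolate",
                                         t_eval = t_samp))
  c_avg <- chi2_vs_truth(buffer_estimate(before, after, "average"))
  expect_lt(c_int, c_avg)
  expect_lt(c_int, 3)
})

test_that("subtraction is linear and self-subtraction is consistent with zero", {
  s <- seq(0.1, 2, length.out = 70)
  buf <- flat_profile(s, 6, 0.02, t_mid = 5, seed = 61)
  samp <- profile1d(s, buf$i + 0.5 * exp(-s), buf$sigma, counts = buf$counts,
                    meta = list(t_mid = 6))
  out <- subtract_buffer(samp, buf, scale_policy = "none")
  expect_equal(out$profile$i, 0.5 * exp(-s), tolerance = 1e-12)
  expect_equal(out$profile$sigma, sqrt(2) * buf$sigma, tolerance = 1e-12)

  # pure-buffer control: I_out = 0 within sigma in essentially every bin, c ~ 1
  buf2 <- flat_profile(s, 6, 0.02, t_mid = 7, seed = 62)
  self <- subtract_buffer(buf2, buf, scale_policy = "fit")
  expect_equal(self$scale, 1, tolerance = 0.01)
  expect_lte(mean(abs(self$profile$i) > 2 * self$profile$sigma), 0.1)
})

test_that("a planted 3% buffer mis-scaling is recovered by the high-s fit within 0.5%", {
  s <- seq(0.1, 2.5, length.out = 120)
  set.seed(63)
  base <- 5 + 0.3 * exp(-s)
  sig <- 0.003
  buf <- profile1d(s, (base + rnorm(length(s), 0, sig)) / 1.03,
                   rep(sig, length(s)), meta = list(t_mid = 2))
  samp <- profile1d(s, base + 0.3 * exp(-(s * 2.4)^2 / 3) + rnorm(length(s), 0, sig),
                    rep(sig, length(s)), meta = list(t_mid = 10))
  out <- subtract_buffer(samp, buf, scale_policy = "fit")
  expect_equal(out$scale, 1.03, tolerance = 0.005)
  expect_false("scale_limited" %in% out$flags)

  # a drastic mis-scaling pins the fit at the clamp and is flagged
  buf2 <- profile1d(s, base / 1.2, rep(sig, length(s)), meta = list(t_mid = 2))
  out2 <- subtract_buffer(samp, buf2, scale_policy = "fit")
  expect_identical(out2$scale, 1.05)
  expect_true("scale_limited" %in% out2$flags)
})

test_that("with zero protein everywhere the recovered form factor is consistent with zero", {
  fx <- cached_fixture("buffer_only_run", {
    cfg <- simulation_config(geometry = small_geometry(), pulses_per_train = 16L,
                             duration = 24,
                             concentration = concentration_constant(0),
                             seed = 404L)
    run <- simulate_run(cfg)
    ph <- photonize(run$stack)
    filt <- filter_outliers(compute_metrics(ph))
    ph <- normalize_pulse_intensity(ph, run$truth$xgm)
    pairs <- average_frames(ph, keep = filt$keep, mode = "per_second")
    profiles <- lapply(pairs, azimuthal_integrate, geom = ph$geometry, n_bins = 48)
    profiles
  })
  # odd/even-second split: any slow drift cancels in this null comparison
  first <- pool_profiles(fx, seq(1, 24, by = 2))
  second <- pool_profiles(fx, seq(2, 24, by = 2))
  out <- subtract_buffer(second, first, scale_policy = "none")
  frac <- mean(abs(out$profile$i) > 2 * out$profile$sigma, na.rm = TRUE)
  expect_lte(frac, 0.1)
})
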