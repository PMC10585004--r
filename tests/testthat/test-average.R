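toy_stack <- function(frame_vals, geom = small_geometry(), cell_bad = list()) {
  n <- length(frame_vals)
  frames <- vapply(frame_vals, function(v) {
    x <- rep(0L, prod(geom$dim))
    x[!as.vector(geom$mask)] <- as.integer(v)
    x
  }, integer(prod(geom$dim)))
  st <- frame_stack(frames, geom, train_id = rep(0L, n), pulse_id = seq_len(n) - 1L,
                    cell_id = seq_len(n) - 1L, time = rep(0, n),
                    data_kind = "photons", cell_bad = cell_bad)
  st
}

test_that("sum and count images satisfy the conservation identities", {
  st <- toy_stack(rep(4L, 10))
  pair <- average_frames(st, mode = "whole_run")[[1]]
  active <- !st$geometry$mask
  expect_true(all(pair$sum[active] == 40L))
  expect_true(all(pair$count[active] == 10L))
  expect_true(all(pair$sum[!active] == 0))
  # mean reconstruction: sum/count equals the arithmetic frame mean exactly
  expect_identical(mean_image(pair)[active], rep(4, sum(active)))
})

test_that("per-cell bad pixels reduce the count image only where frames of that cell contribute", {
  g <- small_geometry()
  bad_px <- which(!as.vector(g$mask))[5:7]
  st <- toy_stack(rep(2L, 6), geom = g,
                  cell_bad = setNames(list(bad_px), "2"))
  st$frames[bad_px, st$cell_id == 2L] <- 0L
  pair <- average_frames(st, mode = "whole_run")[[1]]
  expect_identical(as.vector(pair$count)[bad_px], rep(5L, 3))  # 6 frames - 1 in cell 2
  full <- setdiff(which(!as.vector(g$mask)), bad_px)
  expect_true(all(as.vector(pair$count)[full] == 6L))
})

test_that("per-second averaging makes one window per wall-clock second", {
  cfg <- simulation_config(geometry = small_geometry(), pulses_per_train = 352L,
                           duration = 3, flare_fraction = 0,
                           debris_fraction = 0, seed = 6L)
  run <- simulate_run(cfg)
  ph <- photonize(run$stack)
  pairs <- average_frames(ph, mode = "per_second")
  expect_length(pairs, 3L)
  expect_identical(vapply(pairs, `[[`, integer(1), "n_frames"),
                   rep(3520L, 3))  # 352 pulses x 10 trains each second
})

test_that("empty averaging windows are carried as flagged placeholders", {
  st <- toy_stack(rep(1L, 4))
  st$time <- c(0.1, 0.2, 2.3, 2.4)  # nothing in second 1
  pairs <- average_frames(st, mode = "per_second")
  expect_length(pairs, 3L)
  expect_true(pairs[[2]]$empty)
  expect_identical(pairs[[2]]$n_frames, 0L)
})

test_that("pulse-intensity normalization is a no-op for equal readings and suppresses train-level variance", {
  cfg <- simulation_config(geometry = small_geometry(), pulses_per_train = 16L,
                           duration = 6, sase_cv = 0, train_cv = 0.10,
                           flare_fraction = 0, debris_fraction = 0,
                           drift_rate = 0, seed = 13L)
  run <- simulate_run(cfg)
  ph <- photonize(run$stack)
  same <- normalize_pulse_intensity(ph, rep(3, n_frames(ph)))
  expect_equal(same$frames, ph$frames + 0, tolerance = 1e-12)

  norm <- normalize_pulse_intensity(ph, run$truth$xgm)
  tot_raw <- tapply(colSums(ph$frames), ph$train_id, mean)
  tot_norm <- tapply(colSums(norm$frames), norm$train_id, mean)
  expect_gt(var(tot_raw) / var(tot_norm), 5)

  expect_error(normalize_pulse_intensity(ph, c(NA, rep(1, n_frames(ph) - 1))),
               "missing")
  sk <- normalize_pulse_intensity(ph, c(NA, rep(1, n_frames(ph) - 1)),
                                  on_missing = "skip")
  expect_identical(sk$provenance$normalize$n_missing, 1L)
})

test_that("a uniform image integrates to a flat profile", {
  st <- toy_stack(7L)
  pair <- average_frames(st, mode = "whole_run")[[1]]
  prof <- azimuthal_integrate(pair, st$geometry, n_bins = 40)
  expect_true(all(abs(prof$i[!prof$empty] - 7) < 1e-12))
})

test_that("integration conserves photons and scales correctly with exposure", {
  fx <- filter_run()
  pair <- average_frames(fx$photons, keep = fx$filter$keep,
                         mode = "whole_run")[[1]]
  prof <- azimuthal_integrate(pair, fx$photons$geometry, n_bins = 64)
  # total photon conservation
  expect_equal(sum(prof$i * prof$counts, na.rm = TRUE), sum(pair$sum),
               tolerance = 1e-12)

  # doubling every frame's exposure: sum x2, count x1 -> I x2, sigma x sqrt(2)
  pair2 <- pair; pair2$sum <- pair$sum * 2L
  prof2 <- azimuthal_integrate(pair2, fx$photons$geometry, n_bins = 64)
  expect_equal(prof2$i, 2 * prof$i, tolerance = 1e-12)
  expect_equal(prof2$sigma, sqrt(2) * prof$sigma, tolerance = 1e-12)

  # rebinning conservation: the count-weighted mean of refined bins equals
  # the coarse bin value over every coarse bin
  fine <- azimuthal_integrate(pair, fx$photons$geometry, n_bins = 128)
  coarse_from_fine <- vapply(seq_len(64), function(k) {
    idx <- (2 * k - 1):(2 * k)
    sum(fine$i[idx] * fine$counts[idx], na.rm = TRUE) /
      sum(fine$counts[idx], na.rm = TRUE)
  }, numeric(1))
  cmp <- is.finite(coarse_from_fine) & !prof$empty
  expect_equal(coarse_from_fine[cmp], prof$i[cmp], tolerance = 1e-12)
})

test_that("sum/count TIFF pairs round-trip exactly", {
  fx <- filter_run()
  pair <- average_frames(fx$photons, keep = fx$filter$keep,
                         mode = "whole_run")[[1]]
  base <- file.path(tempdir(), "avg_run")
  write_sum_count_tiff(pair, base)
  back <- read_sum_count_tiff(base)
  expect_identical(back$sum + 0, pair$sum + 0)
  expect_identical(back$count, pair$count + 0L)
})

test_that("profiles round-trip through the 3-column ASCII format", {
  fx <- filter_run()
  pair <- average_frames(fx$photons, keep = fx$filter$keep,
                         mode = "whole_run")[[1]]
  prof <- azimuthal_integrate(pair, fx$photons$geometry, n_bins = 64)
  f <- tempfile(fileext = ".dat")
  write_dat(prof, f)
  back <- read_dat(f)
  keep <- !prof$empty
  expect_equal(back$s, prof$s[keep], tolerance = 1e-8)
  expect_equal(back$i, prof$i[keep], tolerance = 1e-7)
  expect_equal(back$sigma, prof$sigma[keep], tolerance = 1e-7)
  expect_equal(attr(back, "meta")$n_frames, profile_meta(prof)$n_frames)
})
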