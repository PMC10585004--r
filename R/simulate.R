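# Synthetic liquid-jet XFEL SAXS runs with ground truth.
#
# Each simulated frame is a Poisson draw per pixel of
#   (buffer_level * buffer_shape(s) + c(t) * I_model(s)) * pulse_factor * drift(t),
# converted to ADU with the single-photon gain and Gaussian read noise.
# Failure modes of the experiment are reproduced phenomenologically:
# anisotropic jet-edge flares confined to the inner modules, droplet-debris
# frames with a steep low-angle excess, lognormal pulse-to-pulse and
# train-to-train intensity fluctuation, slow multiplicative drift, and an
# autosampler elution (buffer-sample-buffer) concentration profile.

#' Elution concentration profiles
#'
#' \code{concentration_constant} keeps the protein concentration fixed
#' (reservoir delivery); \code{concentration_elution} is a Gaussian plug
#' injected into the buffer flow (autosampler delivery), peaking at
#' \code{peak_fraction} of the injected concentration to reflect dilution
#' along the delivery line.
#'
#' @param level constant concentration (scale factor, 1 = injected).
#' @return list describing the profile, class \code{concentration_profile}.
#' @export
concentration_constant <- function(level = 1) {
  if (level < 0) stop("concentration level must be >= 0")
  structure(list(kind = "constant", level = level), class = "concentration_profile")
}

#' @rdname concentration_constant
#' @param peak_time time of the elution maximum, s.
#' @param width Gaussian sigma of the plug, s (> 0).
#' @param peak_fraction maximum as a fraction of injected concentration.
#' @param injected injected concentration (scale factor).
#' @export
concentration_elution <- function(peak_time, width, peak_fraction = 0.8,
                                  injected = 1) {
  if (!is.numeric(width) || width <= 0) stop("elution width must be > 0")
  if (peak_fraction < 0 || peak_fraction > 1) stop("peak_fraction must be in [0, 1]")
  structure(list(kind = "elution", peak_time = peak_time, width = width,
                 peak_fraction = peak_fraction, injected = injected),
            class = "concentration_profile")
}

#' Evaluate an elution concentration profile
#'
#' Gaussian plug: zero far before (and after) the peak, maximum
#' \code{peak_fraction * injected} at \code{peak_time}, symmetric about it.
#' Contributions beyond 6 sigma are clipped to exactly zero.
#'
#' @param t time(s) in seconds.
#' @param profile a \code{concentration_profile}.
#' @return concentration scale factor(s) at \code{t}.
#' @export
elution_concentration <- function(t, profile) {
  stopifnot(inherits(profile, "concentration_profile"))
  if (profile$kind == "constant") return(rep(profile$level, length(t)))
  z <- (t - profile$peak_time) / profile$width
  c0 <- profile$peak_fraction * profile$injected * exp(-z^2 / 2)
  c0[abs(z) > 6] <- 0
  c0
}

#' Simulation configuration
#'
#' Defaults reflect the instrument conditions the package targets: 352
#' pulses per 10 Hz train (3520 frames/s), 69 ADU per photon, a mean buffer
#' level of 0.5 photons/pixel, ~10% lognormal pulse-intensity fluctuation
#' with an additional 10% train-level component (train-to-train variations
#' dominate on SASE machines), 1%/min multiplicative drift and 1% + 1%
#' flare/debris contamination.
#'
#' @param geometry a \code{\link{geometry_config}}.
#' @param pulses_per_train,trains_per_second pulse-train structure; the
#'   detector memory cell of a frame equals its pulse index within the train.
#' @param duration run length, s.
#' @param gain ADU per photon.
#' @param read_noise_sd Gaussian read noise, ADU.
#' @param buffer_level mean buffer scattering, photons/pixel/frame.
#' @param buffer_shape list(amp, exponent): the buffer profile is flat plus a
#'   weak power-law low-s term amp * (s_ref/s)^exponent, normalized to keep
#'   the mean at \code{buffer_level}.
#' @param sample a \code{\link{scattering_model}}; its I(0) is in
#'   photons/pixel/frame at unit concentration.
#' @param concentration a \code{concentration_profile}.
#' @param sase_cv,train_cv coefficients of variation of the lognormal
#'   per-pulse and shared per-train intensity factors.
#' @param drift_rate slow multiplicative drift, fraction per minute
#'   (linear, centred so the run mean is 1).
#' @param flare_fraction,debris_fraction per-frame artifact probabilities.
#' @param flare_amplitude photons/pixel added along a flare streak (median;
#'   per-event amplitudes are lognormal around it).
#' @param debris_amplitude photons/pixel of low-angle debris excess at the
#'   inner edge (median; lognormal per event).
#' @param bad_pixel_fraction fraction of active pixels that are bad per
#'   memory cell (bad-pixel sets differ from cell to cell).
#' @param n_bins bins of the reference grid on which ground truth is stored.
#' @param seed integer seed; mandatory, fixed seed gives bit-identical runs.
#' @return object of class \code{simulation_config}.
#' @export
simulation_config <- function(geometry = geometry_config(),
                              pulses_per_train = 352L, trains_per_second = 10L,
                              duration = 1,
                              gain = 69, read_noise_sd = 5,
                              buffer_level = 0.5,
                              buffer_shape = list(amp = 0.15, exponent = 2),
                              sample = solid_sphere(3.873, i0 = 0.3),
                              concentration = concentration_constant(1),
                              sase_cv = 0.10, train_cv = 0.10,
                              drift_rate = 0.01,
                              flare_fraction = 0.01, debris_fraction = 0.01,
                              flare_amplitude = 10, debris_amplitude = 2,
                              bad_pixel_fraction = 0.002,
                              n_bins = 96L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inherits(geometry, "geometry_config"),
            inherits(sample, "scattering_model"),
            inherits(concentration, "concentration_profile"))
  for (p in c(flare_fraction, debris_fraction, bad_pixel_fraction))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (flare_fraction + debris_fraction > 1)
    stop("flare_fraction + debris_fraction must not exceed 1")
  if (sase_cv < 0 || train_cv < 0) stop("intensity CVs must be >= 0")
  if (pulses_per_train < 1 || trains_per_second < 1 || duration <= 0)
    stop("pulse structure must be positive")
  structure(list(
    geometry = geometry, pulses_per_train = as.integer(pulses_per_train),
    trains_per_second = as.integer(trains_per_second), duration = duration,
    gain = gain, read_noise_sd = read_noise_sd,
    buffer_level = buffer_level, buffer_shape = buffer_shape,
    sample = sample, concentration = concentration,
    sase_cv = sase_cv, train_cv = train_cv, drift_rate = drift_rate,
    flare_fraction = flare_fraction, debris_fraction = debris_fraction,
    flare_amplitude = flare_amplitude, debris_amplitude = debris_amplitude,
    bad_pixel_fraction = bad_pixel_fraction,
    n_bins = as.integer(n_bins), seed = as.integer(seed)
  ), class = "simulation_config")
}

# lognormal sdlog for a given coefficient of variation; mean is 1.
lognorm_sdlog <- function(cv) sqrt(log(1 + cv^2))

rlnorm_unit <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sl <- lognorm_sdlog(cv)
  stats::rlnorm(n, meanlog = -sl^2 / 2, sdlog = sl)
}

#' Simulate a liquid-jet XFEL SAXS run
#'
#' Generates a full ADU frame stack plus ground truth: the model intensity
#' binned on the reference s grid, true Rg, per-frame labels
#' (clean/flare/debris), per-frame concentration, pulse-intensity factors,
#' drift factors and synthetic upstream intensity-monitor readings (true
#' pulse factor with 1% measurement noise).
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with elements \code{stack} (a \code{\link{frame_stack}} of
#'   ADU frames) and \code{truth} (class \code{ground_truth}).
#' @export
simulate_run <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  geom <- config$geometry
  npix <- prod(geom$dim)
  active <- which(!as.vector(geom$mask))
  s_pix <- as.vector(s_map(geom))

  # buffer shape: flat + weak power-law low-s term, normalized to mean 1
  s_act <- s_pix[active]
  s_ref <- stats::median(s_act)
  s_lo <- stats::quantile(s_act, 0.02)
  shape <- 1 + config$buffer_shape$amp *
    (s_ref / pmax(s_act, s_lo))^config$buffer_shape$exponent
  buffer_px <- config$buffer_level * shape / mean(shape)

  prot_px <- analytic_model_at(config$sample, s_act)

  ppt <- config$pulses_per_train; tps <- config$trains_per_second
  ntrain <- ceiling(config$duration * tps)
  nf <- ntrain * ppt
  train_id <- rep(seq_len(ntrain) - 1L, each = ppt)
  pulse_id <- rep(seq_len(ppt) - 1L, times = ntrain)
  cell_id <- pulse_id
  time <- train_id / tps

  train_factor <- rlnorm_unit(ntrain, config$train_cv)
  pulse_factor <- rlnorm_unit(nf, config$sase_cv) * train_factor[train_id + 1L]
  drift <- 1 + config$drift_rate * (time - config$duration / 2) / 60
  conc <- elution_concentration(time, config$concentration)

  u <- stats::runif(nf)
  labels <- rep("clean", nf)
  labels[u < config$flare_fraction] <- "flare"
  labels[u >= config$flare_fraction &
         u < config$flare_fraction + config$debris_fraction] <- "debris"

  # per-cell bad pixels (bad sets differ between memory cells)
  n_bad <- round(config$bad_pixel_fraction * length(active))
  cell_bad <- lapply(seq_len(ppt), function(cc)
    if (n_bad > 0) sort(sample(active, n_bad)) else integer(0))
  names(cell_bad) <- as.character(seq_len(ppt) - 1L)

  # geometry helpers for artifacts
  r_pix <- as.vector(pixel_radii(geom)) / geom$pixel_pitch  # radius in px
  ang_pix <- atan2(
    rep(seq_len(geom$dim[1]) - 0.5, times = geom$dim[2]) - geom$beam_center["y"],
    rep(seq_len(geom$dim[2]) - 0.5, each = geom$dim[1]) - geom$beam_center["x"])
  inner_px <- which(as.vector(geom$module_index) %in% geom$inner_modules &
                    !as.vector(geom$mask))
  r_inner <- max(r_pix[inner_px])
  s1 <- stats::quantile(s_act, 0.10)

  frames <- matrix(0L, npix, nf)
  lam_active0 <- buffer_px  # per active pixel
  for (f in seq_len(nf)) {
    lam <- (lam_active0 + conc[f] * prot_px) * pulse_factor[f] * drift[f]
    if (labels[f] == "flare") {
      # jet-edge flare: a streak along the axis set by the jet geometry
      # (roughly horizontal, jittering with jet pointing), symmetric through
      # the beam and confined to the inner-module region
      amp <- config$flare_amplitude * stats::rlnorm(1, 0, 0.15)
      phi0 <- stats::rnorm(1, 0, 0.2)
      dphi <- abs(((ang_pix[active] - phi0 + pi / 2) %% pi) - pi / 2)
      streak <- dphi < 0.7 & r_pix[active] <= r_inner
      lam[streak] <- lam[streak] + amp
    } else if (labels[f] == "debris") {
      amp <- config$debris_amplitude * stats::rlnorm(1, 0, 0.5)
      lam <- lam + amp * (s1 / pmax(s_act, s1))^3
    }
    bad <- cell_bad[[as.character(cell_id[f])]]
    ph <- stats::rpois(length(active), lam)
    adu <- as.integer(pmax(0, round(
      ph * config$gain + stats::rnorm(length(active), 0, config$read_noise_sd))))
    col <- integer(npix)
    col[active] <- adu
    if (length(bad)) col[bad] <- 0L
    frames[, f] <- col
  }

  stack <- frame_stack(frames, geom, train_id, pulse_id, cell_id, time,
                       data_kind = "adu", gain = config$gain,
                       cell_bad = cell_bad)
  stack$provenance$simulate <- list(seed = config$seed)

  bins <- s_bin_scheme(geom, n_bins = config$n_bins)
  i_true <- bin_mean(prot_px, s_act, bins)
  xgm <- pulse_factor * exp(stats::rnorm(nf, 0, 0.01))

  truth <- structure(list(
    s = bins$centers, i_true = i_true, true_rg = model_rg(config$sample),
    labels = labels, concentration = conc, pulse_factors = pulse_factor,
    drift = drift, xgm = xgm, config = config
  ), class = "ground_truth")
  list(stack = stack, truth = truth)
}

# Intensity of an analytic model evaluated at arbitrary (unsorted) s values.
analytic_model_at <- function(model, s) {
  o <- order(s)
  grid <- s[o]
  keep <- c(TRUE, diff(grid) > 0)
  p <- analytic_intensity(model, grid[keep])
  vals <- stats::approx(p$s, p$i, xout = s, rule = 2)$y
  vals
}

# Mean of a per-active-pixel quantity in each s bin (NA for empty bins).
bin_mean <- function(values, s_values, bins) {
  idx <- findInterval(s_values, bins$edges, rightmost.closed = TRUE)
  idx[idx < 1 | idx > bins$n] <- NA_integer_
  out <- rep(NA_real_, bins$n)
  agg <- tapply(values, idx, mean)
  out[as.integer(names(agg))] <- agg
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d frames: %d clean, %d flare, %d debris; true Rg %.3f nm\n",
              length(x$labels), sum(x$labels == "clean"), sum(x$labels == "flare"),
              sum(x$labels == "debris"), x$true_rg))
  invisible(x)
}

#' Write ground truth to a sidecar JSON + .dat profile
#' @param truth a \code{ground_truth}.
#' @param json_path path for the JSON sidecar.
#' @param dat_path optional path for the true profile as 3-column ASCII.
#' @export
write_ground_truth <- function(truth, json_path, dat_path = NULL) {
  obj <- list(true_rg = truth$true_rg, labels = truth$labels,
              concentration = truth$concentration,
              pulse_factors = truth$pulse_factors, xgm = truth$xgm)
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(dat_path)) {
    ok <- is.finite(truth$i_true)
    write_dat(profile1d(truth$s[ok], truth$i_true[ok], rep(0, sum(ok)),
                        meta = list(kind = "ground_truth")), dat_path)
  }
  invisible(json_path)
}
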