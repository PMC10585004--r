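# Elution-trace construction, sample/buffer window selection, flanking-buffer
# estimation and subtraction with bounded rescaling — the
# buffer-sample-buffer strategy of autosampler (in-flow injection) runs.

#' Build an elution trace from 1-s profiles
#'
#' One point per profile: the mean intensity over a chosen s window. Empty
#' windows (no kept frames in that second) propagate as NA gaps so the time
#' axis stays uniform. By default the window is the lowest quarter of the s
#' range, where the protein contribution is strongest.
#'
#' @param profiles list of \code{\link{profile1d}} on a shared bin grid.
#' @param s_window numeric(2) window in s (nm^-1); NULL for the default.
#' @return object of class \code{elution_trace}: data.frame with
#'   \code{time}, \code{intensity}, \code{n_frames}.
#' @export
build_trace <- function(profiles, s_window = NULL) {
  if (!length(profiles)) stop("no profiles given")
  ref <- profiles[[which(vapply(profiles, function(p) !all(p$empty), TRUE))[1]]]
  for (p in profiles)
    if (nrow(p) != nrow(ref) || any(abs(p$s - ref$s) > 1e-9))
      stop("profiles do not share a bin grid")
  if (is.null(s_window))
    s_window <- c(min(ref$s), min(ref$s) + 0.25 * diff(range(ref$s)))
  in_w <- ref$s >= s_window[1] & ref$s <= s_window[2]
  if (!any(in_w)) stop("s window lies outside the bin grid")
  vals <- vapply(profiles, function(p) {
    ii <- p$i[in_w & !p$empty]
    if (!length(ii)) NA_real_ else mean(ii)
  }, numeric(1))
  tt <- vapply(profiles, function(p) {
    tm <- profile_meta(p)$t_mid
    if (is.null(tm)) NA_real_ else tm
  }, numeric(1))
  nf <- vapply(profiles, function(p) {
    nn <- profile_meta(p)$n_frames
    if (is.null(nn)) NA_integer_ else as.integer(nn)
  }, integer(1))
  out <- data.frame(time = tt, intensity = vals, n_frames = nf)
  structure(out, class = c("elution_trace", "data.frame"),
            s_window = s_window)
}

#' Annotate buffer and sample windows on an elution trace
#'
#' Baseline = robust low quantile of the trace; noise is estimated from
#' first differences. Buffer windows are the maximal runs compatible with
#' the baseline (within \code{plateau_tol}) before and after the detected
#' peak; the sample window is the contiguous region around the peak above
#' \code{peak_fraction} of the baseline-subtracted peak height (default the
#' top 50%, i.e. the seconds with the highest protein concentration). When
#' no significant peak exists the whole trace is annotated as buffer and the
#' result is flagged (valid for pure-buffer runs). A peak at the trace edge
#' yields a before-only (or after-only) annotation with a warning flag.
#'
#' @param trace an \code{\link{elution_trace}}.
#' @param min_buffer_seconds minimum usable buffer window length, s.
#' @param plateau_tol absolute tolerance for "at baseline"; NULL for
#'   4 x the estimated noise.
#' @param peak_fraction sample threshold as fraction of peak height.
#' @return the trace with a \code{window} column (factor: buffer_before /
#'   sample / buffer_after / NA) and attributes \code{windows} (index lists)
#'   and \code{flags}.
#' @export
select_windows <- function(trace, min_buffer_seconds = 5,
                           plateau_tol = NULL, peak_fraction = 0.5) {
  stopifnot(inherits(trace, "elution_trace"))
  v <- trace$intensity
  ok <- is.finite(v)
  if (sum(ok) < 3 * min_buffer_seconds)
    stop("trace too short: need at least 3 x min_buffer_seconds points")
  baseline <- stats::quantile(v[ok], 0.10, names = FALSE)
  noise <- stats::mad(diff(v[ok])) / sqrt(2)
  if (!is.finite(noise) || noise == 0) noise <- stats::sd(v[ok]) / 10
  if (is.null(plateau_tol)) plateau_tol <- 4 * noise

  flags <- character(0)
  win <- rep(NA_character_, nrow(trace))
  peak_i <- which.max(ifelse(ok, v, -Inf))
  has_peak <- (v[peak_i] - baseline) > 5 * noise

  if (!has_peak) {
    win[ok] <- "buffer_before"
    flags <- c(flags, "no_peak")
  } else {
    thr <- baseline + peak_fraction * (v[peak_i] - baseline)
    above <- ok & v >= thr
    lo <- peak_i; while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- peak_i; while (hi < length(v) && above[hi + 1]) hi <- hi + 1
    win[lo:hi] <- "sample"

    # Buffer plateaus are found against a robust linear trend fitted per
    # side, so that slow intensity drift (the very situation the
    # buffer-sample-buffer scheme exists for) does not mask them.
    side_buffer <- function(side_idx) {
      side_idx <- side_idx[ok[side_idx]]
      if (length(side_idx) < min_buffer_seconds) return(integer(0))
      tt <- trace$time[side_idx]; vv <- v[side_idx]
      use <- rep(TRUE, length(vv))
      for (it in 1:6) {
        fit <- stats::lm.fit(cbind(1, tt[use]), vv[use])
        pred <- fit$coefficients[1] + fit$coefficients[2] * tt
        resid <- vv - pred
        sc <- max(stats::mad(resid[use]), noise / 2)
        new_use <- resid <= 3 * sc   # one-sided: elution tails rise upward
        if (identical(new_use, use)) break
        use <- new_use
        if (sum(use) < max(3, min_buffer_seconds)) break
      }
      at_base <- abs(vv - pred) <= max(plateau_tol, 3 * sc)
      cand <- side_idx[at_base]
      if (!length(cand)) return(integer(0))
      runs <- split(cand, cumsum(c(1, diff(cand) != 1)))
      best <- runs[[which.max(vapply(runs, length, integer(1)))]]
      if (length(best) >= min_buffer_seconds) best else integer(0)
    }
    before <- side_buffer(seq_len(max(lo - 1, 0)))
    win[before] <- "buffer_before"
    after <- if (hi < length(v)) side_buffer((hi + 1):length(v)) else integer(0)
    win[after] <- "buffer_after"
    if (!any(win == "buffer_before", na.rm = TRUE)) flags <- c(flags, "no_buffer_before")
    if (!any(win == "buffer_after", na.rm = TRUE)) flags <- c(flags, "no_buffer_after")
  }
  trace$window <- factor(win, levels = c("buffer_before", "sample", "buffer_after"))
  attr(trace, "windows") <- list(
    buffer_before = which(win == "buffer_before"),
    sample = which(win == "sample"),
    buffer_after = which(win == "buffer_after"))
  attr(trace, "flags") <- flags
  trace
}

#' Pool profiles of a window into one profile
#'
#' Exact Poisson pooling: per bin, summed photons and summed counts are
#' accumulated across the selected profiles (i.e. each 1-s profile is
#' weighted by how many frames contributed), then I = S/C and
#' sigma = sqrt(S)/C.
#'
#' @param profiles list of \code{\link{profile1d}} on a shared grid, carrying
#'   per-bin \code{counts}.
#' @param idx indices of the profiles to pool.
#' @param t_mid optional representative time for the pooled profile.
#' @return a \code{\link{profile1d}}.
#' @export
pool_profiles <- function(profiles, idx, t_mid = NULL) {
  if (!length(idx)) stop("no profiles selected for pooling")
  sel <- profiles[idx]
  ref <- sel[[1]]
  s_b <- rep(0, nrow(ref)); c_b <- rep(0, nrow(ref)); npx <- rep(0L, nrow(ref))
  for (p in sel) {
    if (!same_grid(p, ref)) stop("profiles do not share a bin grid")
    w <- !p$empty & is.finite(p$counts) & p$counts > 0
    s_b[w] <- s_b[w] + p$i[w] * p$counts[w]
    c_b[w] <- c_b[w] + p$counts[w]
    npx[w] <- pmax(npx[w], p$n_pix[w])
  }
  if (is.null(t_mid)) {
    tm <- vapply(sel, function(p) profile_meta(p)$t_mid %||% NA_real_, numeric(1))
    t_mid <- mean(tm, na.rm = TRUE)
  }
  nf <- sum(vapply(sel, function(p) profile_meta(p)$n_frames %||% 0, numeric(1)))
  i_b <- ifelse(c_b > 0, s_b / c_b, NA_real_)
  sig <- ifelse(c_b > 0, sqrt(pmax(s_b, 0)) / c_b, 0)
  profile1d(ref$s, i_b, sig, n_pix = npx, counts = c_b,
            meta = list(t_mid = t_mid, n_frames = nf, pooled_from = length(idx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate the buffer profile from flanking windows
#'
#' \code{mode = "average"}: unweighted per-bin mean of the before and after
#' buffers, sigma combined in quadrature over 2. \code{mode = "interpolate"}:
#' per-bin linear interpolation in time, evaluated at \code{t_eval}
#' (typically the sample-window midpoint) — the buffer-sample-buffer strategy
#' for slow intensity drift. The drift statistic is the median over bins of
#' |after - before| / before. With only one buffer available that buffer is
#' returned and the mode recorded as degraded.
#'
#' @param before,after \code{\link{profile1d}} buffer profiles (either may
#'   be NULL).
#' @param mode "average" or "interpolate".
#' @param t_eval evaluation time for interpolate mode.
#' @return a \code{\link{profile1d}} with attributes \code{drift_stat} and
#'   \code{mode_used}.
#' @export
buffer_estimate <- function(before, after, mode = c("average", "interpolate"),
                            t_eval = NULL) {
  mode <- match.arg(mode)
  if (is.null(before) && is.null(after)) stop("no buffer profile available")
  if (is.null(before) || is.null(after)) {
    out <- if (is.null(before)) after else before
    attr(out, "drift_stat") <- NA_real_
    attr(out, "mode_used") <- "degraded_single"
    return(out)
  }
  if (!same_grid(before, after)) stop("buffer profiles do not share a bin grid")
  w <- !before$empty & !after$empty & before$i > 0
  drift_stat <- stats::median(abs(after$i[w] - before$i[w]) / before$i[w])

  if (mode == "average") {
    i_b <- (before$i + after$i) / 2
    sig <- sqrt(before$sigma^2 + after$sigma^2) / 2
  } else {
    t1 <- profile_meta(before)$t_mid; t2 <- profile_meta(after)$t_mid
    if (is.null(t1) || is.null(t2) || !is.finite(t1) || !is.finite(t2))
      stop("interpolate mode needs t_mid metadata on both buffers")
    if (is.null(t_eval)) t_eval <- (t1 + t2) / 2
    wgt <- (t_eval - t1) / (t2 - t1)
    i_b <- (1 - wgt) * before$i + wgt * after$i
    sig <- sqrt(((1 - wgt) * before$sigma)^2 + (wgt * after$sigma)^2)
  }
  out <- profile1d(before$s, i_b, sig,
                   n_pix = before$n_pix,
                   counts = before$counts + after$counts,
                   meta = list(t_mid = if (mode == "interpolate") t_eval else
                     mean(c(profile_meta(before)$t_mid %||% NA_real_,
                            profile_meta(after)$t_mid %||% NA_real_), na.rm = TRUE)))
  attr(out, "drift_stat") <- drift_stat
  attr(out, "mode_used") <- mode
  out
}

#' Subtract the buffer from the sample profile
#'
#' Optionally fits a buffer scale factor c by least squares of sample
#' against buffer over a high-s window (default: the top 20% of the s range,
#' where the protein signal is negligible), clamped to
#' [1 - scale_bound, 1 + scale_bound] (default 5%, the maximum rescaling the
#' delivery scheme should ever require). Then I = I_sample - c * I_buffer
#' with sigma = sqrt(sigma_s^2 + c^2 sigma_b^2). A fitted c pinned at a
#' clamp boundary is flagged \code{scale_limited}.
#'
#' @param sample,buffer \code{\link{profile1d}} on a shared grid.
#' @param scale_policy "fit" or "none" (c = 1).
#' @param scale_bound clamp half-width b: c in [1-b, 1+b].
#' @param fit_window fraction of the s range (from the top) used for the fit.
#' @return object of class \code{subtraction_result}: \code{profile},
#'   \code{scale}, \code{flags}, \code{drift_stat}, \code{provenance}.
#' @export
subtract_buffer <- function(sample, buffer, scale_policy = c("fit", "none"),
                            scale_bound = 0.05, fit_window = 0.2) {
  scale_policy <- match.arg(scale_policy)
  if (!same_grid(sample, buffer)) stop("sample and buffer do not share a bin grid")
  flags <- character(0)
  cc <- 1
  if (scale_policy == "fit") {
    s_hi <- max(sample$s) - fit_window * diff(range(sample$s))
    w <- sample$s >= s_hi & !sample$empty & !buffer$empty & buffer$i > 0
    if (!any(w)) stop("no usable bins in the buffer-scaling fit window")
    wt <- ifelse(sample$sigma[w] > 0, 1 / sample$sigma[w]^2, 1)
    cc <- sum(wt * sample$i[w] * buffer$i[w]) / sum(wt * buffer$i[w]^2)
    lo <- 1 - scale_bound; hi <- 1 + scale_bound
    if (cc <= lo || cc >= hi) {
      cc <- min(max(cc, lo), hi)
      flags <- c(flags, "scale_limited")
    }
  }
  i_out <- sample$i - cc * buffer$i
  sig <- sqrt(sample$sigma^2 + cc^2 * buffer$sigma^2)
  prof <- profile1d(sample$s, i_out, sig, n_pix = sample$n_pix,
                    counts = sample$counts,
                    meta = list(buffer_scale = cc,
                                t_mid = profile_meta(sample)$t_mid %||% NA_real_))
  structure(list(
    profile = prof, scale = cc, flags = flags,
    drift_stat = attr(buffer, "drift_stat"),
    provenance = list(scale_policy = scale_policy, scale_bound = scale_bound,
                      fit_window = fit_window,
                      buffer_mode = attr(buffer, "mode_used"))
  ), class = "subtraction_result")
}

#' @export
print.subtraction_result <- function(x, ...) {
  cat(sprintf("<subtraction_result> buffer scale c = %.4f%s\n", x$scale,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  if (!is.null(x$drift_stat) && is.finite(x$drift_stat))
    cat(sprintf("  buffer drift before->after: %.2f%%\n", 100 * x$drift_stat))
  invisible(x)
}

#' Full autosampler reduction: stack to form factor
#'
#' Convenience pipeline: photonize, reject outlier frames, (optionally)
#' normalize by pulse intensity, average per second, integrate, build the
#' elution trace, select buffer-sample-buffer windows, estimate the buffer
#' and subtract.
#'
#' @param stack an ADU \code{\link{frame_stack}}.
#' @param xgm optional per-frame upstream intensity readings.
#' @param n_bins bins for the azimuthal integration.
#' @param buffer_mode "interpolate" (default) or "average".
#' @param scale_policy "none" (default) or "fit" buffer rescaling.
#' @param threshold photonization threshold.
#' @return list: \code{form_factor} (a \code{subtraction_result}),
#'   \code{trace}, \code{filter}, \code{profiles}, \code{sample},
#'   \code{buffer}.
#' @export
reduce_autosampler_run <- function(stack, xgm = NULL, n_bins = 96L,
                                   buffer_mode = "interpolate",
                                   scale_policy = "none", threshold = 0.7) {
  ph <- photonize(stack, threshold = threshold)
  metrics <- compute_metrics(ph)
  filt <- filter_outliers(metrics)
  if (!is.null(xgm)) ph <- normalize_pulse_intensity(ph, xgm)
  pairs <- average_frames(ph, keep = filt$keep, mode = "per_second")
  scheme <- s_bin_scheme(stack$geometry, n_bins = n_bins)
  profiles <- lapply(pairs, azimuthal_integrate, geom = stack$geometry,
                     scheme = scheme)
  trace <- build_trace(profiles)
  trace <- select_windows(trace)
  wins <- attr(trace, "windows")
  if (!length(wins$sample)) stop("no sample peak found in the elution trace")
  sample_p <- pool_profiles(profiles, wins$sample)
  before_p <- if (length(wins$buffer_before)) pool_profiles(profiles, wins$buffer_before) else NULL
  after_p <- if (length(wins$buffer_after)) pool_profiles(profiles, wins$buffer_after) else NULL
  buf <- buffer_estimate(before_p, after_p, mode = buffer_mode,
                         t_eval = profile_meta(sample_p)$t_mid)
  sub <- subtract_buffer(sample_p, buf, scale_policy = scale_policy)
  list(form_factor = sub, trace = trace, filter = filt, profiles = profiles,
       sample = sample_p, buffer = buf)
}
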