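# Frame averaging (whole-run or 1-s windows), pulse-intensity normalization,
# and azimuthal integration of sum/count images into 1-D profiles.

#' Binning scheme over the accessible momentum-transfer range
#'
#' Equispaced half-open bins [lo, hi) in s over the active-pixel range of the
#' geometry (the last bin is closed). Each pixel is assigned by its centre's
#' s value; no pixel splitting, so photon totals are conserved exactly under
#' any rebinning.
#'
#' @param geom a \code{\link{geometry_config}}.
#' @param n_bins number of bins (default 512).
#' @param s_range optional numeric(2) overriding the automatic range.
#' @param bin_edges optional explicit edges (overrides n_bins/s_range).
#' @return list with \code{edges}, \code{centers}, \code{n}, and
#'   \code{pixel_bin}: per-canvas-pixel bin index (NA for masked or
#'   out-of-range pixels).
#' @export
s_bin_scheme <- function(geom, n_bins = 512L, s_range = NULL, bin_edges = NULL) {
  s_pix <- as.vector(s_map(geom))
  if (is.null(bin_edges)) {
    if (is.null(s_range)) s_range <- range(s_pix, na.rm = TRUE)
    bin_edges <- seq(s_range[1], s_range[2], length.out = n_bins + 1L)
  }
  n <- length(bin_edges) - 1L
  idx <- findInterval(s_pix, bin_edges, rightmost.closed = TRUE)
  idx[is.na(s_pix) | idx < 1L | idx > n] <- NA_integer_
  centers <- (bin_edges[-1] + bin_edges[-(n + 1L)]) / 2
  # effective s per bin: the mean momentum transfer of the pixels actually
  # in the bin. Sparse low-angle bins fill asymmetrically on a coarse
  # detector, so the nominal centre would bias fits against the profile.
  s_eff <- centers
  ok <- !is.na(idx)
  agg <- tapply(s_pix[ok], idx[ok], mean)
  s_eff[as.integer(names(agg))] <- agg
  list(edges = bin_edges, centers = centers, s_eff = as.numeric(s_eff),
       n = n, pixel_bin = idx)
}

#' Average accepted frames into sum/count images
#'
#' Produces, per averaging window, the \emph{sum} of photons per pixel over
#' contributing frames and the \emph{count} of frames contributing per pixel.
#' The count varies from pixel to pixel because the set of bad pixels differs
#' between detector memory cells. \code{mode = "whole_run"} gives one pair;
#' \code{mode = "per_second"} one pair per 1-s wall-clock window (windows
#' with zero kept frames are carried as flagged placeholders so that the
#' elution-trace time axis stays uniform).
#'
#' @param stack a photonized (or normalized) \code{\link{frame_stack}}.
#' @param keep logical keep mask per frame (default: keep all).
#' @param mode "whole_run" or "per_second".
#' @return list of \code{sum_count_pair} objects.
#' @export
average_frames <- function(stack, keep = NULL,
                           mode = c("whole_run", "per_second")) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "frame_stack"))
  if (stack$data_kind == "adu")
    stop("photonize the stack before averaging")
  n <- n_frames(stack)
  if (is.null(keep)) keep <- rep(TRUE, n)
  if (length(keep) != n) stop("keep mask must align with the stack")
  if (!any(keep)) stop("keep mask rejects every frame")

  windows <- if (mode == "whole_run") {
    list(list(id = "run", idx = which(keep),
              t_mid = mean(range(stack$time))))
  } else {
    secs <- 0:floor(max(stack$time) + 1e-9)
    lapply(secs, function(w) {
      in_w <- keep & stack$time >= w & stack$time < w + 1
      list(id = sprintf("%04d", w), idx = which(in_w), t_mid = w + 0.5)
    })
  }

  npix <- nrow(stack$frames)
  mask_v <- as.vector(stack$geometry$mask)
  lapply(windows, function(w) {
    if (!length(w$idx)) {
      return(structure(list(
        sum = matrix(0, stack$geometry$dim[1], stack$geometry$dim[2]),
        count = matrix(0L, stack$geometry$dim[1], stack$geometry$dim[2]),
        window = w$id, t_mid = w$t_mid, n_frames = 0L, empty = TRUE),
        class = "sum_count_pair"))
    }
    sm <- rowSums(stack$frames[, w$idx, drop = FALSE])
    cnt <- rep(length(w$idx), npix)
    cells <- table(stack$cell_id[w$idx])
    for (cc in names(cells)) {
      bad <- stack$cell_bad[[cc]]
      if (length(bad)) cnt[bad] <- cnt[bad] - as.integer(cells[[cc]])
    }
    sm[mask_v] <- 0; cnt[mask_v] <- 0L
    sm[cnt == 0L] <- 0
    if (is.integer(stack$frames)) storage.mode(sm) <- "integer"
    structure(list(
      sum = matrix(sm, stack$geometry$dim[1], stack$geometry$dim[2]),
      count = matrix(as.integer(cnt), stack$geometry$dim[1], stack$geometry$dim[2]),
      window = w$id, t_mid = w$t_mid, n_frames = length(w$idx), empty = FALSE),
      class = "sum_count_pair")
  })
}

#' @export
print.sum_count_pair <- function(x, ...) {
  cat(sprintf("<sum_count_pair> window %s: %d frames, %0.4g photons total\n",
              x$window, x$n_frames, sum(x$sum)))
  invisible(x)
}

#' Mean image of a sum/count pair
#' @param pair a \code{sum_count_pair}.
#' @export
mean_image <- function(pair) {
  out <- pair$sum / pair$count
  out[pair$count == 0] <- NA_real_
  out
}

#' Normalize frames by measured pulse intensity
#'
#' Divides every frame by its relative pulse factor (reading / run-mean
#' reading), as done with upstream gas-monitor readings to remove SASE
#' pulse-to-pulse and train-to-train intensity fluctuation before averaging.
#'
#' @param stack a photonized \code{\link{frame_stack}}.
#' @param readings one positive reading per frame.
#' @param on_missing "error" (default) refuses on any non-finite reading;
#'   "skip" leaves affected frames unscaled (factor 1) and records how many.
#' @return the stack with numeric frames, \code{data_kind "normalized"}.
#' @export
normalize_pulse_intensity <- function(stack, readings,
                                      on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(stack, "frame_stack"))
  n <- n_frames(stack)
  if (length(readings) != n) stop("need one intensity reading per frame")
  bad <- !is.finite(readings) | readings <= 0
  if (any(bad)) {
    if (on_missing == "error")
      stop(sum(bad), " missing/invalid pulse-intensity readings ",
           "(set on_missing = \"skip\" to leave those frames unscaled)")
  }
  rel <- readings / mean(readings[!bad])
  rel[bad] <- 1
  stack$frames <- sweep(stack$frames, 2, rel, `/`)
  stack$data_kind <- "normalized"
  stack$provenance$normalize <- list(n_missing = sum(bad))
  stack
}

#' Azimuthal integration of a sum/count pair
#'
#' Pixels are assigned to s bins by their centre's momentum transfer; over
#' the full azimuthal range each bin gets
#' I = sum(sum-image) / sum(count-image) (photons per pixel per frame) and
#' sigma = sqrt(sum(sum-image)) / sum(count-image), Poisson on the summed
#' photons. Bins with no contributing pixels are flagged empty.
#'
#' @param pair a \code{sum_count_pair}.
#' @param geom the \code{\link{geometry_config}} the pair was recorded with.
#' @param n_bins,s_range,bin_edges binning controls, see
#'   \code{\link{s_bin_scheme}}.
#' @param scheme optionally a precomputed \code{s_bin_scheme} result.
#' @return a \code{\link{profile1d}} with per-bin pixel and count totals.
#' @export
azimuthal_integrate <- function(pair, geom, n_bins = 512L, s_range = NULL,
                                bin_edges = NULL, scheme = NULL) {
  stopifnot(inherits(pair, "sum_count_pair"), inherits(geom, "geometry_config"))
  if (is.null(scheme))
    scheme <- s_bin_scheme(geom, n_bins = n_bins, s_range = s_range,
                           bin_edges = bin_edges)
  idx <- scheme$pixel_bin
  sum_v <- as.vector(pair$sum); cnt_v <- as.vector(pair$count)
  use <- !is.na(idx) & cnt_v > 0
  if (!any(use) && pair$n_frames > 0)
    stop("all pixels of the requested s range are masked; empty bins: ",
         paste(seq_len(scheme$n), collapse = ","))
  f <- factor(idx[use], levels = seq_len(scheme$n))
  s_b <- as.numeric(tapply(sum_v[use], f, sum, default = 0))
  c_b <- as.numeric(tapply(cnt_v[use], f, sum, default = 0))
  npx <- as.integer(tapply(rep(1L, sum(use)), f, sum, default = 0))
  i_b <- ifelse(c_b > 0, s_b / c_b, NA_real_)
  sig <- ifelse(c_b > 0, sqrt(pmax(s_b, 0)) / c_b, NA_real_)
  profile1d(scheme$s_eff, i_b, ifelse(is.na(sig), 0, sig),
            n_pix = npx, counts = c_b,
            meta = list(window = pair$window, t_mid = pair$t_mid,
                        n_frames = pair$n_frames))
}

# ---- sum/count TIFF persistence -------------------------------------------

TIFF_SCALE <- 2^32 - 1

#' Write / read sum and count images as integer TIFF files
#'
#' Each average is persisted as two TIFFs, \code{<basename>_sum.tif} and
#' \code{<basename>_count.tif}, with 32-bit samples. Values must be
#' non-negative integers below 2^31; the round trip is exact.
#'
#' @param pair a \code{sum_count_pair}.
#' @param basename path prefix (without the _sum/_count suffix).
#' @export
write_sum_count_tiff <- function(pair, basename) {
  stopifnot(inherits(pair, "sum_count_pair"))
  for (part in c("sum", "count")) {
    img <- round(pair[[part]])
    if (any(img < 0) || any(img >= 2^31))
      stop(part, " image out of the storable integer range [0, 2^31)")
    tiff::writeTIFF(img / TIFF_SCALE, paste0(basename, "_", part, ".tif"),
                    bits.per.sample = 32L, compression = "none")
  }
  invisible(basename)
}

#' @rdname write_sum_count_tiff
#' @export
read_sum_count_tiff <- function(basename) {
  sm <- tiff::readTIFF(paste0(basename, "_sum.tif"), as.is = TRUE)
  cnt <- tiff::readTIFF(paste0(basename, "_count.tif"), as.is = TRUE)
  storage.mode(cnt) <- "integer"
  structure(list(sum = sm, count = cnt, window = as.character(basename),
                 t_mid = NA_real_, n_frames = max(cnt), empty = FALSE),
            class = "sum_count_pair")
}
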