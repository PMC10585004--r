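# Photonization: conversion of calibrated analog detector units (ADU) into
# integer photon counts using the single-photon gain and a threshold for the
# first photon.

#' Convert ADU values to photon counts
#'
#' A pixel reading below \code{threshold} photon-equivalents is set to zero;
#' anything at or above it is rounded to the nearest integer with a minimum
#' of one photon. With the instrument's 69 ADU single-photon gain and the
#' 0.7-photon threshold, 69 ADU maps to exactly 1 photon and 40 ADU (0.58
#' photons) to 0. Nearest-integer rounding above threshold is the standard
#' photonization convention for multi-photon values. Non-finite pixels are
#' treated as masked: they come back NA and are tallied in the
#' \code{n_nonfinite} attribute.
#'
#' @param frame numeric vector/matrix of ADU values.
#' @param gain ADU per photon (> 0).
#' @param threshold acceptance threshold for the first photon, in photons,
#'   in (0, 1). Default 0.7.
#' @return integer array of the same shape, with attributes \code{gain},
#'   \code{threshold}, \code{n_nonfinite}.
#' @export
adu_to_photons <- function(frame, gain, threshold = 0.7) {
  if (!is.numeric(gain) || length(gain) != 1 || gain <= 0) stop("gain must be > 0")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1) photons")
  p <- frame / gain
  bad <- !is.finite(p)
  p[bad] <- 0
  n <- ifelse(p < threshold, 0L, pmax(1L, as.integer(round(p))))
  n[bad] <- NA_integer_
  dim(n) <- dim(frame)
  attr(n, "gain") <- gain
  attr(n, "threshold") <- threshold
  attr(n, "n_nonfinite") <- sum(bad)
  n
}

#' Photonize a frame stack
#'
#' Applies \code{\link{adu_to_photons}} to every frame of an ADU
#' \code{frame_stack}, in column chunks to bound peak memory.
#'
#' @param stack a \code{frame_stack} with \code{data_kind == "adu"}.
#' @param gain ADU per photon; defaults to the gain recorded in the stack.
#' @param threshold first-photon threshold in photons.
#' @return the stack with integer photon frames, \code{data_kind "photons"}.
#' @export
photonize <- function(stack, gain = NULL, threshold = 0.7) {
  stopifnot(inherits(stack, "frame_stack"))
  if (stack$data_kind != "adu")
    stop("stack is already photonized (data_kind = ", stack$data_kind, ")")
  if (is.null(gain)) gain <- stack$gain
  if (is.null(gain)) stop("no gain recorded in stack; supply one")
  n <- ncol(stack$frames)
  chunk <- max(1L, as.integer(2e7 / nrow(stack$frames)))
  out <- stack$frames
  nonfinite <- 0L
  for (j0 in seq(1L, n, by = chunk)) {
    jj <- j0:min(n, j0 + chunk - 1L)
    ph <- adu_to_photons(stack$frames[, jj, drop = FALSE], gain, threshold)
    nonfinite <- nonfinite + attr(ph, "n_nonfinite")
    out[, jj] <- ph
  }
  storage.mode(out) <- "integer"
  stack$frames <- out
  stack$data_kind <- "photons"
  stack$provenance$photonize <- list(gain = gain, threshold = threshold,
                                     n_nonfinite = nonfinite)
  stack
}
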