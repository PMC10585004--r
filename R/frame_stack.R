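# FrameStack: ordered per-pulse detector images with train/pulse/cell
# bookkeeping. Frames are stored as a (n_pixels x n_frames) matrix in
# column-major canvas order; use frame_image() to recover a 2-D view.

#' Frame stack container
#'
#' @param frames numeric/integer matrix, one column per frame, rows in
#'   column-major order of the geometry canvas.
#' @param geometry a \code{\link{geometry_config}}.
#' @param train_id,pulse_id,cell_id integer vectors, one entry per frame;
#'   \code{cell_id} is the detector memory cell (= pulse index within train).
#' @param time acquisition time of each frame in seconds from run start.
#' @param data_kind one of "adu", "photons", "normalized".
#' @param gain ADU per photon used (or to be used) for photonization.
#' @param cell_bad named list (by cell id) of canvas pixel indices that are
#'   bad for that memory cell.
#' @return object of class \code{frame_stack}.
#' @export
frame_stack <- function(frames, geometry, train_id, pulse_id, cell_id, time,
                        data_kind = c("adu", "photons", "normalized"),
                        gain = NULL, cell_bad = list()) {
  data_kind <- match.arg(data_kind)
  stopifnot(inherits(geometry, "geometry_config"))
  frames <- as.matrix(frames)
  npix <- prod(geometry$dim)
  if (nrow(frames) != npix)
    stop(sprintf("frames have %d rows but geometry has %d pixels", nrow(frames), npix))
  n <- ncol(frames)
  for (v in list(train_id, pulse_id, cell_id, time))
    if (length(v) != n) stop("per-frame index vectors must match frame count")
  structure(list(
    frames = frames, geometry = geometry,
    train_id = as.integer(train_id), pulse_id = as.integer(pulse_id),
    cell_id = as.integer(cell_id), time = as.numeric(time),
    data_kind = data_kind, gain = gain, cell_bad = cell_bad,
    provenance = list()
  ), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames of %d x %d px [%s]\n",
              ncol(x$frames), x$geometry$dim[1], x$geometry$dim[2], x$data_kind))
  cat(sprintf("  trains %d..%d, cells %d..%d, t in [%.2f, %.2f] s\n",
              min(x$train_id), max(x$train_id), min(x$cell_id), max(x$cell_id),
              min(x$time), max(x$time)))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a \code{frame_stack}.
#' @export
n_frames <- function(stack) ncol(stack$frames)

#' Extract one frame as a 2-D image
#' @param stack a \code{frame_stack}.
#' @param idx frame index (1-based).
#' @export
frame_image <- function(stack, idx) {
  matrix(stack$frames[, idx], stack$geometry$dim[1], stack$geometry$dim[2])
}

#' Subset a stack by frame
#' @param stack a \code{frame_stack}.
#' @param idx logical or integer frame selector.
#' @export
subset_frames <- function(stack, idx) {
  stack$frames <- stack$frames[, idx, drop = FALSE]
  for (f in c("train_id", "pulse_id", "cell_id", "time"))
    stack[[f]] <- stack[[f]][idx]
  stack
}

#' Save / load a frame stack (native RDS container)
#'
#' @param stack a \code{frame_stack}.
#' @param path file path (.rds).
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  saveRDS(stack, path)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "frame_stack")) stop(path, " does not contain a frame_stack")
  x
}
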