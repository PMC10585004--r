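# Frame rejection: the 4-number inner-module occupancy metric and
# density-based (DBSCAN) outlier detection per detector memory cell.
#
# The metric counts, for each of the four designated inner modules, the
# number of unmasked pixels holding at least one photon. Jet-edge flares and
# droplet debris concentrate excess intensity at low angles, so affected
# frames stand out in this 4-vector. Because bad pixels and baseline differ
# between memory cells, clustering is done for each cell separately.

#' Per-frame inner-module occupancy metric
#'
#' @param frame integer photon image (matrix matching the geometry canvas).
#' @param geom a \code{\link{geometry_config}}.
#' @param inner_modules module ids to use; defaults to the geometry's
#'   designated inner set.
#' @return integer vector, one occupancy count (pixels with >= 1 photon)
#'   per inner module, masked pixels excluded.
#' @export
compute_metric <- function(frame, geom, inner_modules = geom$inner_modules) {
  stopifnot(inherits(geom, "geometry_config"))
  if (!all(inner_modules %in% geom$layout$module))
    stop("unknown inner module id(s): ",
         paste(setdiff(inner_modules, geom$layout$module), collapse = ","))
  v <- as.vector(frame)
  mod_v <- as.vector(geom$module_index)
  mask_v <- as.vector(geom$mask)
  vapply(inner_modules, function(m) {
    px <- which(mod_v == m & !mask_v)
    if (!length(px)) stop("module ", m, " has no unmasked pixels")
    sum(v[px] >= 1, na.rm = TRUE)
  }, integer(1))
}

#' Occupancy metrics for a whole stack
#'
#' @param stack a photonized \code{\link{frame_stack}}.
#' @param inner_modules module ids to use.
#' @return data.frame with \code{frame}, \code{cell_id} and columns
#'   \code{m1..m4} (one per inner module).
#' @export
compute_metrics <- function(stack, inner_modules = stack$geometry$inner_modules) {
  stopifnot(inherits(stack, "frame_stack"))
  if (stack$data_kind == "adu") stop("photonize the stack before computing metrics")
  geom <- stack$geometry
  mod_v <- as.vector(geom$module_index)
  mask_v <- as.vector(geom$mask)
  cols <- lapply(inner_modules, function(m) {
    px <- which(mod_v == m & !mask_v)
    if (!length(px)) stop("module ", m, " has no unmasked pixels")
    as.integer(colSums(stack$frames[px, , drop = FALSE] >= 1))
  })
  out <- data.frame(frame = seq_len(n_frames(stack)), cell_id = stack$cell_id)
  for (k in seq_along(cols)) out[[paste0("m", k)]] <- cols[[k]]
  out
}

# Plain DBSCAN on a points-by-features matrix. Returns integer labels,
# 0 = noise. Small n per cell group, so the O(n^2) distance matrix is fine.
dbscan_labels <- function(x, eps, min_pts) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))  # includes self
  core <- vapply(nbrs, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      for (k in nbrs[[j]]) {
        if (labels[k] == 0L) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  labels
}

# Robust per-column standardization: median / MAD, with IQR and sd fallbacks
# so constant or heavily tied integer columns never divide by zero.
robust_standardize <- function(x) {
  apply(x, 2, function(col) {
    ctr <- stats::median(col)
    sc <- stats::mad(col)
    if (sc == 0) sc <- stats::IQR(col) / 1.349
    if (sc == 0) sc <- stats::sd(col)
    if (!is.finite(sc) || sc == 0) sc <- 1
    (col - ctr) / sc
  })
}

# k-th nearest-neighbour distance for every point (excluding self).
knn_distance <- function(x, k) {
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  apply(d, 1, function(row) sort(row)[k])
}

# The classic DBSCAN eps choice: the elbow of the sorted k-distance curve
# with k = min_samples - 1. The elbow sits just above the edge of the dense
# bulk and below genuine outliers, adapting the radius to each run. Falls
# back to the 95th percentile when the curve is degenerate (e.g. all points
# identical).
kdist_elbow_eps <- function(x, min_samples) {
  kk <- max(1L, min(min_samples - 1L, nrow(x) - 1L))
  kd <- sort(knn_distance(x, k = kk))
  kd <- kd[is.finite(kd)]
  if (!length(kd) || max(kd) <= 0) return(0.5)
  n <- length(kd)
  # max distance to the chord from first to last point
  i <- seq_len(n)
  dx <- (i - 1) / (n - 1); dy <- (kd - kd[1]) / (kd[n] - kd[1])
  dist_chord <- abs(dy - dx) / sqrt(2)
  knee <- which.max(dist_chord)
  # the chord construction can cut slightly into the tail of the dense bulk;
  # absorb the remainder of the same regime (below twice the elbow value) so
  # the radius covers the whole bulk yet stays under any genuine jump
  eps <- max(kd[kd <= 2 * kd[knee]])
  eps <- max(eps, as.numeric(stats::quantile(kd, 0.50)))
  if (!is.finite(eps) || eps <= 0) eps <- 0.5
  eps
}

#' Density-based frame outlier rejection
#'
#' Groups the 4-number metrics by memory cell, robustly standardizes each
#' component (median/MAD), clusters each group with DBSCAN and rejects the
#' frames labelled noise; frames in any dense cluster are kept. When
#' \code{eps} is not given it is chosen per cell as the elbow of the sorted
#' (min_samples - 1)-nearest-neighbour distance curve of the standardized
#' metrics (the classic DBSCAN k-distance heuristic), which adapts the
#' rejection radius to the conditions of each run. Cells with fewer than
#' \code{min_samples} frames are merged into a pooled group. If every frame
#' of a cell is labelled noise the filter fails safe: it keeps them all and
#' records a warning instead of silently discarding a whole cell.
#'
#' @param metrics data.frame as from \code{\link{compute_metrics}}.
#' @param eps DBSCAN radius on standardized metrics (NULL = per-cell
#'   adaptive choice).
#' @param min_samples DBSCAN core-point threshold (neighbourhood size
#'   including the point itself). Default 10.
#' @return object of class \code{filter_result}: \code{keep} (logical per
#'   frame), \code{rejected_fraction}, \code{per_cell} summary table,
#'   \code{params} and \code{warnings}.
#' @export
filter_outliers <- function(metrics, eps = NULL, min_samples = 10L) {
  mcols <- grep("^m[0-9]+$", names(metrics), value = TRUE)
  if (!length(mcols)) stop("metrics must carry m1..mK columns")
  n <- nrow(metrics)
  x_all <- as.matrix(metrics[, mcols])
  cell <- as.character(metrics$cell_id)

  tab <- table(cell)
  small <- names(tab)[tab < min_samples]
  group <- cell
  warnings <- character(0)
  if (length(small)) {
    group[cell %in% small] <- ".pooled"
    warnings <- c(warnings, sprintf(
      "%d cell(s) with fewer than %d frames merged into a pooled group",
      length(small), min_samples))
  }
  if (sum(group == ".pooled") > 0 && sum(group == ".pooled") < min_samples)
    warnings <- c(warnings, "pooled group itself is smaller than min_samples")

  keep <- rep(TRUE, n)
  rows <- list()
  for (g in unique(group)) {
    idx <- which(group == g)
    xg <- robust_standardize(x_all[idx, , drop = FALSE])
    eps_g <- eps
    if (is.null(eps_g)) eps_g <- kdist_elbow_eps(xg, min_samples)
    labels <- dbscan_labels(xg, eps = eps_g, min_pts = min_samples)
    kp <- labels != 0L
    if (!any(kp)) {
      kp[] <- TRUE
      warnings <- c(warnings, sprintf(
        "cell group '%s': all frames labelled noise; fail-safe keep-all applied", g))
    }
    keep[idx] <- kp
    rows[[g]] <- data.frame(cell = g, n = length(idx),
                            n_rejected = sum(!kp), eps = eps_g)
  }
  per_cell <- do.call(rbind, rows)
  rownames(per_cell) <- NULL
  structure(list(
    keep = keep, rejected_fraction = mean(!keep), per_cell = per_cell,
    params = list(eps = eps, min_samples = min_samples,
                  standardization = "median/MAD"),
    warnings = warnings
  ), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> %d/%d frames rejected (%.2f%%)\n",
              sum(!x$keep), length(x$keep), 100 * x$rejected_fraction))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Write a JSON filtering report
#' @param result a \code{filter_result}.
#' @param path output JSON path.
#' @export
write_filter_report <- function(result, path) {
  jsonlite::write_json(list(
    rejected_fraction = result$rejected_fraction,
    per_cell = result$per_cell, params = result$params,
    warnings = result$warnings, keep = result$keep
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
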