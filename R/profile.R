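# Profile1D: a binned 1-D scattering curve with Poisson errors and per-bin
# bookkeeping, plus the 3-column ASCII .dat reader/writer used across
# small-angle software.

#' One-dimensional scattering profile
#'
#' @param s bin centres, nm^-1, strictly increasing.
#' @param i intensity per bin (photons pixel^-1 frame^-1 for reduced data;
#'   arbitrary units otherwise). NA marks empty bins.
#' @param sigma 1-sigma uncertainty, same units as \code{i}.
#' @param n_pix pixels contributing per bin (optional).
#' @param counts summed frame-count weight per bin (sum over pixels of the
#'   count image; used for exact pooling of profiles; optional).
#' @param meta named list of metadata (time window, frames averaged, ...).
#' @return object of class \code{profile1d}: a data.frame with columns
#'   \code{s}, \code{i}, \code{sigma}, \code{n_pix}, \code{counts},
#'   \code{empty}.
#' @export
profile1d <- function(s, i, sigma, n_pix = NULL, counts = NULL, meta = list()) {
  s <- as.numeric(s)
  if (length(s) == 0 || any(diff(s) <= 0)) stop("s must be strictly increasing")
  n <- length(s)
  if (length(i) != n || length(sigma) != n) stop("i and sigma must match s in length")
  if (any(sigma < 0, na.rm = TRUE)) stop("sigma must be >= 0")
  if (is.null(n_pix)) n_pix <- rep(NA_integer_, n)
  if (is.null(counts)) counts <- rep(NA_real_, n)
  out <- data.frame(s = s, i = as.numeric(i), sigma = as.numeric(sigma),
                    n_pix = n_pix, counts = counts,
                    empty = !is.finite(as.numeric(i)))
  structure(out, class = c("profile1d", "data.frame"), meta = meta)
}

#' @export
print.profile1d <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("<profile1d> %d bins, s in [%.4g, %.4g] nm^-1, %d empty\n",
              nrow(x), min(x$s), max(x$s), sum(x$empty)))
  if (length(m)) {
    keys <- names(m)[vapply(m, function(v) is.atomic(v) && length(v) == 1, TRUE)]
    for (k in keys) cat(sprintf("  %s: %s\n", k, format(m[[k]])))
  }
  invisible(x)
}

#' Metadata attached to a profile
#' @param p a \code{profile1d}.
#' @export
profile_meta <- function(p) attr(p, "meta")

same_grid <- function(a, b, tol = 1e-9) {
  nrow(a) == nrow(b) && all(abs(a$s - b$s) <= tol * pmax(1, abs(a$s)))
}

#' Write / read a 3-column ASCII profile (.dat)
#'
#' The de facto small-angle ASCII interchange format: comment/header lines
#' starting with '#', then whitespace-separated columns s, I, sigma. Empty
#' bins are skipped on write.
#'
#' @param profile a \code{profile1d}.
#' @param path output file.
#' @export
write_dat <- function(profile, path) {
  stopifnot(inherits(profile, "profile1d"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# jetsaxs 1-D scattering profile", con)
  writeLines("# columns: s[nm^-1]  I  sigma", con)
  m <- profile_meta(profile)
  for (k in names(m)) {
    v <- m[[k]]
    if (is.atomic(v)) writeLines(sprintf("# %s: %s", k, paste(format(v), collapse = " ")), con)
  }
  keep <- !profile$empty
  utils::write.table(
    format(profile[keep, c("s", "i", "sigma")], digits = 9, trim = TRUE,
           scientific = TRUE),
    con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dat
#' @export
read_dat <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^\\s*#", lines)
  meta <- list()
  for (h in lines[hdr]) {
    mm <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_.]+):\\s*(.*)$", h))[[1]]
    if (length(mm) == 3) meta[[mm[2]]] <- utils::type.convert(strsplit(mm[3], "\\s+")[[1]], as.is = TRUE)
  }
  body <- lines[!hdr & nzchar(trimws(lines))]
  if (!length(body)) stop("no data rows in ", path)
  tab <- utils::read.table(text = body, col.names = c("s", "i", "sigma"))
  profile1d(tab$s, tab$i, tab$sigma, meta = meta)
}
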