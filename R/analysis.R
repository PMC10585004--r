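# Form-factor analysis: Guinier fit, regularized indirect Fourier transform
# for p(r) and Dmax, and the reduced chi-square comparator with optimal
# scaling.

#' Guinier analysis
#'
#' Weighted linear fit of ln I versus s^2 at very small angles, where
#' I(s) = I(0) exp(-(s Rg)^2 / 3). With \code{auto_range} the fit window
#' starts at the first positive-intensity bin and is iteratively extended or
#' shrunk until s_max * Rg stays at or below \code{srg_limit} (default 1.3)
#' and the estimate is stable. Fewer than \code{min_points} qualifying points
#' flags the result; a non-decaying slope is an error ("no Guinier region").
#'
#' @param profile a \code{\link{profile1d}}.
#' @param auto_range iterate the fit window (default TRUE); otherwise all
#'   positive bins with s * Rg-guess <= srg_limit would be used as given.
#' @param srg_limit qualification limit on s_max * Rg.
#' @param min_points minimum number of fitted points before flagging.
#' @return object of class \code{guinier_result}: \code{i0}, \code{rg},
#'   \code{rg_se}, \code{range} (first/last bin index), \code{n_points},
#'   \code{srg} (at the range ends), \code{residual_runs_p}, \code{flagged}.
#' @export
guinier_fit <- function(profile, auto_range = TRUE, srg_limit = 1.3,
                        min_points = 30L) {
  stopifnot(inherits(profile, "profile1d"))
  usable <- !profile$empty & is.finite(profile$i)
  s <- profile$s; ii <- profile$i; sg <- profile$sigma
  # candidate bins: positive intensities (occasional noise-negative bins in
  # a subtracted profile are skipped, not allowed to truncate the window)
  cand <- which(usable & ii > 0)
  if (!length(cand)) stop("no positive intensities: no Guinier region")

  fit_window <- function(idx) {
    x <- s[idx]^2; y <- log(ii[idx])
    w <- if (all(sg[idx] == 0)) rep(1, length(idx)) else (ii[idx] / pmax(sg[idx], 1e-300))^2
    W <- sum(w); xm <- sum(w * x) / W; ym <- sum(w * y) / W
    sxx <- sum(w * (x - xm)^2)
    slope <- sum(w * (x - xm) * (y - ym)) / sxx
    list(slope = slope, intercept = ym - slope * xm,
         resid = y - (ym + slope * (x - xm)),
         slope_se = sqrt(1 / sxx))
  }
  # window = the first `k` candidate bins; iterate k until the range
  # qualifies (s_max * Rg <= srg_limit) and is stable
  if (length(cand) < 5)
    stop("too few positive low-angle points: no Guinier region")
  k <- min(length(cand), max(min_points, 5L))
  seen <- integer(0)
  for (iter in 1:30) {
    f <- fit_window(cand[1:k])
    if (f$slope >= 0) stop("intensity does not decay at low angles: no Guinier region")
    rg <- sqrt(-3 * f$slope)
    if (!auto_range) break
    # fixed-point iteration: the window implied by the current Rg estimate
    k_new <- max(5L, sum(s[cand] * rg <= srg_limit))
    k_new <- min(k_new, length(cand))
    if (k_new == k || k_new %in% seen) { k <- min(k, k_new); break }
    seen <- c(seen, k)
    k <- k_new
  }
  f <- fit_window(cand[1:k])
  if (f$slope >= 0) stop("intensity does not decay at low angles: no Guinier region")
  rg <- sqrt(-3 * f$slope)
  i0 <- exp(f$intercept)
  first <- cand[1]; last <- cand[k]
  # delta method for the Rg standard error
  rg_se <- 3 * f$slope_se / (2 * rg)
  # sign-runs test on residuals (normal approximation)
  sgn <- sign(f$resid); sgn <- sgn[sgn != 0]
  n_run <- 1 + sum(diff(sgn) != 0)
  np <- sum(sgn > 0); nm <- sum(sgn < 0)
  runs_p <- if (np > 0 && nm > 0) {
    mu <- 1 + 2 * np * nm / (np + nm)
    va <- 2 * np * nm * (2 * np * nm - np - nm) /
      ((np + nm)^2 * (np + nm - 1))
    2 * stats::pnorm(-abs(n_run - mu) / sqrt(max(va, 1e-12)))
  } else NA_real_
  structure(list(
    i0 = i0, rg = rg, rg_se = rg_se, range = c(first = first, last = last),
    n_points = as.integer(k),
    srg = c(first = s[first] * rg, last = s[last] * rg),
    residual_runs_p = runs_p,
    flagged = k < min_points
  ), class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("<guinier_result> I(0) = %.4g, Rg = %.4g nm (se %.2g)%s\n",
              x$i0, x$rg, x$rg_se, if (x$flagged) " [flagged: few points]" else ""))
  cat(sprintf("  %d points, sRg in [%.3f, %.3f]\n", x$n_points,
              x$srg["first"], x$srg["last"]))
  invisible(x)
}

# design matrix of the indirect transform: I(s_j) = sum_i A[j,i] p(r_i)
ift_design <- function(s, r) {
  dr <- r[2] - r[1]
  a <- outer(s, r, function(ss, rr) sinc_(ss * rr))
  4 * pi * dr * a
}

trapz_ <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Indirect Fourier transform: p(r) from I(s)
#'
#' Represents the pair distance distribution on an r-grid over [0, Dmax]
#' with p(0) = p(Dmax) = 0 enforced, and solves the sigma-weighted linear
#' least-squares problem I(s) = 4 pi Int p(r) sin(sr)/(sr) dr with a
#' second-difference smoothness penalty alpha. When alpha is NULL it is
#' chosen by the knee of an L-curve over a log-spaced scan. Optional
#' non-negativity is imposed by iteratively pinning negative nodes to zero.
#'
#' @param profile a \code{\link{profile1d}} with sigma > 0 (bins with
#'   sigma = 0 fall back to unit weights).
#' @param dmax maximum particle dimension, nm (> 0).
#' @param alpha smoothness weight; NULL for the automatic L-curve choice.
#' @param n_r number of r-grid points (default 101).
#' @param nonneg force p(r) >= 0.
#' @return object of class \code{pofr}: \code{r}, \code{p}, \code{dmax},
#'   \code{alpha}, derived \code{i0} and \code{rg}, \code{fit} (profile of
#'   the regenerated intensities), \code{chi2} (reduced, against the input).
#' @export
ift_pr <- function(profile, dmax, alpha = NULL, n_r = 101L, nonneg = FALSE) {
  stopifnot(inherits(profile, "profile1d"))
  if (!is.numeric(dmax) || dmax <= 0) stop("dmax must be > 0")
  use <- !profile$empty & is.finite(profile$i)
  s <- profile$s[use]; y <- profile$i[use]; sg <- profile$sigma[use]
  if (length(s) < 10) stop("too few usable bins for the transform")
  if (dmax < pi / max(s))
    warning("dmax is below the resolution limit pi/s_max; result will be poorly constrained")
  w <- if (all(sg == 0)) rep(1, length(s)) else 1 / pmax(sg, 1e-300)^2

  r <- seq(0, dmax, length.out = n_r)
  a_full <- ift_design(s, r)
  a <- a_full[, -c(1, n_r), drop = FALSE]        # endpoints fixed at zero
  # second differences on the full (zero-padded) p vector
  nd <- n_r - 2L
  d2 <- matrix(0, nd, nd)
  for (k in seq_len(nd)) {
    d2[k, k] <- -2
    if (k > 1) d2[k, k - 1] <- 1
    if (k < nd) d2[k, k + 1] <- 1
  }
  ata <- crossprod(a * sqrt(w))
  aty <- drop(crossprod(a, w * y))
  dtd <- crossprod(d2)
  scale0 <- sum(diag(ata)) / sum(diag(dtd))

  solve_alpha <- function(al) {
    m <- ata + al * dtd
    x <- tryCatch(solve(m, aty), error = function(e) NULL)
    if (is.null(x)) return(NULL)
    if (nonneg) {
      pinned <- rep(FALSE, nd)
      for (it in 1:25) {
        neg <- x < 0 & !pinned
        if (!any(neg)) break
        pinned <- pinned | neg
        free <- which(!pinned)
        x[] <- 0
        if (!length(free)) break
        x[free] <- solve(m[free, free, drop = FALSE], aty[free])
      }
      x[x < 0] <- 0
    }
    x
  }

  if (is.null(alpha)) {
    alphas <- scale0 * 10^seq(-8, 1, length.out = 24)
    pts <- lapply(alphas, function(al) {
      x <- solve_alpha(al)
      if (is.null(x)) return(NULL)
      rho <- sum(w * (y - drop(a %*% x))^2)
      eta <- sum((d2 %*% x)^2)
      c(log(rho + 1e-300), log(eta + 1e-300))
    })
    keep <- !vapply(pts, is.null, TRUE)
    if (!any(keep)) stop("indirect transform system is singular for all trial alphas")
    lcurve <- do.call(rbind, pts[keep])
    alpha <- alphas[keep][lcurve_knee(lcurve[, 1], lcurve[, 2])]
  }
  x <- solve_alpha(alpha)
  if (is.null(x))
    stop("ill-conditioned system at this alpha; increase the regularization")
  p <- c(0, x, 0)
  i_hat <- drop(a %*% x)
  chi2 <- sum(w * (y - i_hat)^2) / (length(y) - 1)
  i0 <- 4 * pi * trapz_(r, p)
  rg <- sqrt(trapz_(r, r^2 * p) / (2 * trapz_(r, p)))
  structure(list(
    r = r, p = p, dmax = dmax, alpha = alpha, i0 = i0, rg = rg,
    fit = profile1d(s, i_hat, rep(0, length(s))), chi2 = chi2,
    nonneg = nonneg
  ), class = "pofr")
}

# Knee of a curve by maximum distance to the chord between its endpoints.
lcurve_knee <- function(x, y) {
  n <- length(x)
  if (n < 3) return(n)
  x <- (x - x[1]) / max(abs(x[n] - x[1]), 1e-12)
  y <- (y - y[1]) / max(abs(y[n] - y[1]), 1e-12)
  dx <- x[n] - x[1]; dy <- y[n] - y[1]
  dist <- abs(dy * x - dx * y + dx * y[1] - dy * x[1]) / sqrt(dx^2 + dy^2)
  which.max(dist)
}

#' @export
print.pofr <- function(x, ...) {
  cat(sprintf("<pofr> Dmax = %.3g nm, alpha = %.3g, I(0) = %.4g, Rg = %.4g nm, chi2 = %.3g\n",
              x$dmax, x$alpha, x$i0, x$rg, x$chi2))
  invisible(x)
}

#' Write p(r) as two-column ASCII
#' @param pofr a \code{pofr}.
#' @param path output file.
#' @export
write_pr <- function(pofr, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# jetsaxs p(r)", sprintf("# dmax: %.6g", pofr$dmax),
               "# columns: r[nm]  p(r)"), con)
  utils::write.table(data.frame(r = pofr$r, p = pofr$p), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Estimate the maximum particle dimension
#'
#' Scans candidate Dmax values, scoring each by the reduced chi-square of
#' the indirect-transform fit plus penalties for negative p(r) mass and for
#' a p(r) that does not approach zero at the endpoint. The score falls
#' steeply until the true dimension is reached and then flattens; the knee
#' of this L-shaped curve is returned. A score curve with no clear drop
#' (e.g. a pure-noise profile) returns the scan bound with a
#' \code{no_knee} flag.
#'
#' @param profile a \code{\link{profile1d}}.
#' @param r_bounds numeric(2) scan range for Dmax, nm.
#' @param n_candidates number of scan points.
#' @param alpha regularization passed to \code{\link{ift_pr}} (NULL: a
#'   moderate fixed fraction of the automatic scale).
#' @return list: \code{dmax}, \code{flags}, \code{scan} (data.frame of
#'   candidate, chi2, neg_mass, end_slope, score).
#' @export
estimate_dmax <- function(profile, r_bounds, n_candidates = 25L, alpha = NULL) {
  if (length(r_bounds) != 2 || any(r_bounds <= 0) || diff(r_bounds) <= 0)
    stop("r_bounds must be positive and increasing")
  cand <- seq(r_bounds[1], r_bounds[2], length.out = n_candidates)
  rows <- lapply(cand, function(d) {
    fit <- tryCatch(suppressWarnings(ift_pr(profile, d, alpha = alpha)),
                    error = function(e) NULL)
    if (is.null(fit)) return(data.frame(dmax = d, chi2 = NA, neg = NA,
                                        end = NA, score = NA))
    pk <- max(abs(fit$p))
    neg <- sum(pmax(-fit$p, 0)) / max(sum(abs(fit$p)), 1e-300)
    end <- abs(fit$p[length(fit$p) - 1]) / max(pk, 1e-300)
    data.frame(dmax = d, chi2 = fit$chi2, neg = neg, end = end,
               score = fit$chi2 * (1 + 5 * neg) * (1 + end))
  })
  scan <- do.call(rbind, rows)
  ok <- is.finite(scan$score)
  flags <- character(0)
  if (sum(ok) < 3) return(list(dmax = r_bounds[2], flags = "no_knee", scan = scan))
  sc <- scan$score[ok]; dd <- scan$dmax[ok]
  if (max(sc) / max(min(sc), 1e-300) < 2 || which.min(sc) == 1) {
    flags <- c(flags, "no_knee")
    return(list(dmax = dd[which.min(sc)], flags = flags, scan = scan))
  }
  # knee = first candidate entering the flat plateau of the L-shaped score
  plateau <- min(sc) * 1.05
  kk <- which(sc <= plateau)[1]
  list(dmax = dd[kk], flags = flags, scan = scan)
}

#' Reduced chi-square with optimal scaling
#'
#' chi^2 = 1/(N-1) sum_j [(I_exp(s_j) - c I_calc(s_j)) / sigma(s_j)]^2 with
#' the scale given in closed form by
#' c = sum(I_exp I_calc / sigma^2) / sum(I_calc^2 / sigma^2). Invariant
#' under common rescaling of (I_exp, sigma) and under any rescaling of
#' I_calc.
#'
#' @param i_exp experimental intensities (or a \code{\link{profile1d}}, in
#'   which case \code{sigma} is taken from it).
#' @param i_calc model intensities on the same grid.
#' @param sigma experimental errors (> 0).
#' @param fit_scale fit c (default) or fix c = 1.
#' @return list of class \code{chi2_result}: \code{chi2}, \code{c},
#'   \code{n}.
#' @export
chi2_fit <- function(i_exp, i_calc, sigma = NULL, fit_scale = TRUE) {
  if (inherits(i_exp, "profile1d")) {
    use <- !i_exp$empty & is.finite(i_calc)
    sigma <- i_exp$sigma[use]
    i_calc <- i_calc[use]
    i_exp <- i_exp$i[use]
  }
  if (is.null(sigma)) stop("sigma required")
  if (length(i_exp) != length(i_calc) || length(i_exp) != length(sigma))
    stop("grids of i_exp, i_calc and sigma must be identical")
  ok <- sigma > 0 & is.finite(i_exp) & is.finite(i_calc)
  i_exp <- i_exp[ok]; i_calc <- i_calc[ok]; sigma <- sigma[ok]
  n <- length(i_exp)
  if (n < 2) stop("need at least 2 points")
  cc <- if (fit_scale)
    sum(i_exp * i_calc / sigma^2) / sum(i_calc^2 / sigma^2) else 1
  chi2 <- sum(((i_exp - cc * i_calc) / sigma)^2) / (n - 1)
  structure(list(chi2 = chi2, c = cc, n = n), class = "chi2_result")
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("<chi2_result> reduced chi2 = %.4g (c = %.4g, N = %d)\n",
              x$chi2, x$c, x$n))
  invisible(x)
}
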