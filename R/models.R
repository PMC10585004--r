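# Analytic scattering models: solid sphere, hollow (core-shell) sphere and
# Debye bead sets. These provide the simulator's ground truth and the
# reference curves for the chi-square comparator; they stand in for globular
# proteins (solid sphere), cage proteins whose hollow shape gives
# characteristic intensity minima (hollow shell), and arbitrary low-resolution
# shapes (bead set).

#' Scattering model constructors
#'
#' \code{solid_sphere} is a homogeneous sphere of radius \code{radius} (nm);
#' \code{hollow_shell} a spherical shell between \code{r_in} and \code{r_out};
#' \code{bead_set} a collection of homogeneous beads evaluated with the Debye
#' double sum over pairwise distances. \code{i0} is the forward intensity
#' I(0) in arbitrary units (for the simulator: photons per pixel per frame at
#' unit concentration).
#'
#' @param radius sphere radius, nm (> 0).
#' @param i0 forward intensity I(0) (> 0).
#' @return object of class \code{scattering_model}.
#' @export
solid_sphere <- function(radius, i0 = 1) {
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) || radius <= 0)
    stop("invalid 'radius': must be a single positive number")
  check_i0(i0)
  structure(list(kind = "solid_sphere", radius = radius, i0 = i0),
            class = "scattering_model")
}

#' @rdname solid_sphere
#' @param r_in,r_out inner and outer shell radii, nm (r_out > r_in >= 0).
#' @export
hollow_shell <- function(r_in, r_out, i0 = 1) {
  if (!is.numeric(r_in) || length(r_in) != 1 || !is.finite(r_in) || r_in < 0)
    stop("invalid 'r_in': must be a single number >= 0")
  if (!is.numeric(r_out) || length(r_out) != 1 || !is.finite(r_out) || r_out <= r_in)
    stop("invalid 'r_out': must exceed r_in")
  check_i0(i0)
  structure(list(kind = "hollow_shell", r_in = r_in, r_out = r_out, i0 = i0),
            class = "scattering_model")
}

#' @rdname solid_sphere
#' @param coords n x 3 matrix of bead centres, nm.
#' @param radii bead radii, nm; scalar or length-n vector.
#' @export
bead_set <- function(coords, radii, i0 = 1) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0 || ncol(coords) != 3)
    stop("invalid 'coords': need a non-empty n x 3 matrix")
  if (nrow(coords) > 2000)
    stop("invalid 'coords': bead count capped at 2000 (Debye sum is O(n^2))")
  radii <- rep_len(as.numeric(radii), nrow(coords))
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("invalid 'radii': must be positive")
  check_i0(i0)
  structure(list(kind = "bead_set", coords = coords, radii = radii, i0 = i0),
            class = "scattering_model")
}

check_i0 <- function(i0) {
  if (!is.numeric(i0) || length(i0) != 1 || !is.finite(i0) || i0 <= 0)
    stop("invalid 'i0': forward intensity must be a single positive number")
  invisible(TRUE)
}

#' @export
print.scattering_model <- function(x, ...) {
  cat("<scattering_model>", x$kind, "\n")
  switch(x$kind,
    solid_sphere = cat(sprintf("  radius %.3g nm, I(0) = %.3g\n", x$radius, x$i0)),
    hollow_shell = cat(sprintf("  r_in %.3g nm, r_out %.3g nm, I(0) = %.3g\n",
                               x$r_in, x$r_out, x$i0)),
    bead_set = cat(sprintf("  %d beads, I(0) = %.3g\n", nrow(x$coords), x$i0)))
  invisible(x)
}

# Normalized sphere amplitude A(x) = 3 (sin x - x cos x) / x^3, A(0) = 1.
sphere_amplitude <- function(x) {
  a <- numeric(length(x))
  small <- abs(x) < 1e-4
  a[small] <- 1 - x[small]^2 / 10
  xl <- x[!small]
  a[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  a
}

# sin(x)/x with the x -> 0 limit.
sinc_ <- function(x) ifelse(abs(x) < 1e-8, 1 - x^2 / 6, sin(x) / x)

#' Analytic scattering intensity
#'
#' Evaluates the model intensity on a momentum-transfer grid. The solid
#' sphere uses the squared sphere amplitude [3(sin x - x cos x)/x^3]^2 with
#' x = s R; the hollow shell the volume-weighted difference of two sphere
#' amplitudes; the bead set the Debye double sum
#' I(s) = sum_ij f_i(s) f_j(s) sinc(s d_ij). All are normalized so that
#' I(0) equals the model's configured forward intensity.
#'
#' @param model a \code{scattering_model}.
#' @param s strictly increasing grid of momentum transfer, nm^-1, s >= 0.
#' @return a \code{\link{profile1d}} with zero errors.
#' @export
analytic_intensity <- function(model, s) {
  stopifnot(inherits(model, "scattering_model"))
  if (any(s < 0) || any(diff(s) <= 0))
    stop("s grid must be non-negative and strictly increasing")
  i <- switch(model$kind,
    solid_sphere = model$i0 * sphere_amplitude(s * model$radius)^2,
    hollow_shell = {
      v_out <- model$r_out^3; v_in <- model$r_in^3
      amp <- (v_out * sphere_amplitude(s * model$r_out) -
              v_in * sphere_amplitude(s * model$r_in)) / (v_out - v_in)
      model$i0 * amp^2
    },
    bead_set = {
      f <- outer(s, model$radii, function(ss, rr) rr^3 * sphere_amplitude(ss * rr))
      d <- as.matrix(stats::dist(model$coords))
      raw <- vapply(seq_along(s), function(j) {
        ph <- sinc_(s[j] * d)
        drop(f[j, ] %*% ph %*% f[j, ])
      }, numeric(1))
      model$i0 * raw / sum(model$radii^3)^2
    })
  profile1d(s = s, i = i, sigma = rep(0, length(s)))
}

#' Radius of gyration of an analytic model
#'
#' Closed forms: sqrt(3/5) R for the solid sphere,
#' sqrt(3/5 (R_out^5 - R_in^5)/(R_out^3 - R_in^3)) for the shell, and the
#' volume-weighted second moment (with the 3/5 R^2 per-bead term) for bead
#' sets.
#'
#' @param model a \code{scattering_model}.
#' @return Rg in nm.
#' @export
model_rg <- function(model) {
  stopifnot(inherits(model, "scattering_model"))
  switch(model$kind,
    solid_sphere = sqrt(3 / 5) * model$radius,
    hollow_shell = sqrt(3 / 5 * (model$r_out^5 - model$r_in^5) /
                          (model$r_out^3 - model$r_in^3)),
    bead_set = {
      v <- model$radii^3
      com <- colSums(model$coords * v) / sum(v)
      d2 <- rowSums(sweep(model$coords, 2, com)^2)
      sqrt(sum(v * (d2 + 3 / 5 * model$radii^2)) / sum(v))
    })
}
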