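#' Film geometry for one-way release
#'
#' Describes the slab geometry of a film used in a one-way release
#' experiment: the full thickness, and optionally the thicknesses of the
#' two internal strata of a phase-separated film (a porous, oil-rich layer
#' facing the solvent and a compact, polymer-rich layer behind it).
#'
#' Thickness is usually measured in millimetres with a micrometer; all
#' internal computation is done in centimetres so that diffusion
#' coefficients carry their conventional cm^2/s units.
#'
#' @param thickness Total film thickness (a single positive number).
#' @param units Units of all thickness arguments, `"mm"` (default) or `"cm"`.
#' @param d1,d2 Optional layer thicknesses, in the same units. When given,
#'   both must be positive and sum to `thickness` (relative tolerance 1e-9).
#'
#' @return An object of class `"film_geometry"` with elements `d_cm` and,
#'   when layers are specified, `d1_cm` and `d2_cm`.
#'
#' @examples
#' film_geometry(0.062)                      # EG3-like film, 0.062 mm
#' film_geometry(0.08, d1 = 0.06, d2 = 0.02) # two-layer film
#' @export
film_geometry <- function(thickness, units = c("mm", "cm"),
                          d1 = NULL, d2 = NULL) {
  units <- match.arg(units)
  to_cm <- if (units == "mm") 0.1 else 1
  if (!is.numeric(thickness) || length(thickness) != 1L ||
      !is.finite(thickness) || thickness <= 0)
    stop("film thickness must be a single positive number", call. = FALSE)
  d <- thickness * to_cm
  geom <- list(d_cm = d, d1_cm = NULL, d2_cm = NULL)
  if (!is.null(d1) || !is.null(d2)) {
    if (is.null(d1) || is.null(d2))
      stop("both layer thicknesses d1 and d2 must be given", call. = FALSE)
    if (!is.numeric(d1) || !is.numeric(d2) || d1 <= 0 || d2 <= 0)
      stop("layer thicknesses d1 and d2 must be positive", call. = FALSE)
    d1 <- d1 * to_cm
    d2 <- d2 * to_cm
    if (abs((d1 + d2) - d) > 1e-9 * d)
      stop("layer thicknesses must satisfy d1 + d2 = thickness", call. = FALSE)
    geom$d1_cm <- d1
    geom$d2_cm <- d2
  }
  structure(geom, class = "film_geometry")
}

#' @export
print.film_geometry <- function(x, ...) {
  cat("Film geometry: thickness", format(x$d_cm * 10), "mm")
  if (!is.null(x$d1_cm))
    cat(" (layers ", format(x$d1_cm * 10), " + ", format(x$d2_cm * 10),
        " mm)", sep = "")
  cat("\n")
  invisible(x)
}

# Plausibility guard for diffusion coefficients: warn (once per call) when D
# falls outside the configurable range; release D values for small molecules
# in polymer films span roughly 1e-12 to 1e-8 cm^2/s.
check_D <- function(D, what = "D") {
  if (!is.numeric(D) || any(!is.finite(D)) || any(D <= 0))
    stop(what, " must be a positive, finite diffusion coefficient (cm^2/s)",
         call. = FALSE)
  rng <- getOption("filmrelease.D_range", c(1e-14, 1e-4))
  if (any(D < rng[1] | D > rng[2]))
    warning(what, " outside the plausible range [", format(rng[1]), ", ",
            format(rng[2]), "] cm^2/s", call. = FALSE)
  invisible(D)
}

#' Dimensionless diffusion time
#'
#' The group tau = D t / d^2 that the one-way release solution depends on;
#' every release curve collapses onto a single master curve in tau.
#'
#' @param D Diffusion coefficient, cm^2/s.
#' @param geometry A [film_geometry()].
#' @param t Time(s) in seconds, non-negative (vectorised).
#' @return Dimensionless time(s) tau >= 0.
#' @examples
#' dimensionless_time(1e-8, film_geometry(0.01, units = "cm"), 1e4) # 1
#' @export
dimensionless_time <- function(D, geometry, t) {
  check_D(D)
  stopifnot(inherits(geometry, "film_geometry"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("time must be finite and non-negative", call. = FALSE)
  D * t / geometry$d_cm^2
}

# Plane-sheet one-way release master curve as a function of tau = D t / d^2:
#   f(tau) = 1 - sum_{n>=0} 8/((2n+1)^2 pi^2) exp(-(2n+1)^2 pi^2 tau / 4).
# Truncation is adaptive: terms are summed until the next one drops below
# `tol`; the exponential decay in n^2 bounds the number of terms needed.
# For tau < 1e-6 the short-time square-root law 2 sqrt(tau/pi) is used
# instead (its error is O(exp(-1/tau)), far below machine precision there,
# while the series would need thousands of slowly-decaying terms).
fraction_from_tau <- function(tau, tol = 1e-14) {
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0 || tol > 1e-3)
    stop("series tolerance must lie in (0, 1e-3]", call. = FALSE)
  out <- numeric(length(tau))
  small <- tau < 1e-6
  out[small] <- 2 * sqrt(tau[small] / pi)
  idx <- which(!small)
  for (i in idx) {
    tau_i <- tau[i]
    # exp(-(2n+1)^2 pi^2 tau/4) < tol * pi^2/8 guarantees the term < tol
    nmax <- ceiling(0.5 * (sqrt(4 * max(log(8 / (pi^2 * tol)), 1) /
                                  (pi^2 * tau_i)) - 1)) + 5
    if (nmax > 1e6)
      stop("series did not converge within 1e6 terms", call. = FALSE)
    m <- 2 * (0:nmax) + 1
    s <- sum(8 / (m^2 * pi^2) * exp(-m^2 * pi^2 * tau_i / 4))
    out[i] <- min(max(1 - s, 0), 1)
  }
  out
}

#' Cumulative release fraction from a film (plane-sheet solution)
#'
#' Evaluates the series solution of Fick's second law for one-way release
#' from a plane sheet of thickness d with one impermeable face:
#' \deqn{M_t/M_\infty = 1 - \sum_{n=0}^{\infty}
#'   \frac{8}{(2n+1)^2\pi^2}
#'   \exp\!\left[-\frac{D(2n+1)^2\pi^2 t}{4 d^2}\right]}
#' The result is the fraction of the initially loaded compound that has
#' left the film by time t: exactly 0 at t = 0, monotone increasing in
#' both t and D, and approaching 1 at equilibrium.
#'
#' @inheritParams dimensionless_time
#' @param tol Series truncation tolerance: summation stops once the next
#'   term falls below this value. Must lie in (0, 1e-3].
#' @return Release fraction(s) in \[0, 1\], one per element of `t`.
#' @examples
#' g <- film_geometry(0.062)
#' release_fraction(1.096e-8, g, c(0, 300, 3000))
#' @seealso [release_curve()], [half_release_time()], [fit_D()]
#' @export
release_fraction <- function(D, geometry, t, tol = 1e-14) {
  tau <- dimensionless_time(D, geometry, t)
  fraction_from_tau(tau, tol = tol)
}

#' Model release curve at given sampling times
#'
#' Evaluates [release_fraction()] at a vector of sampling times and wraps
#' the result as a release-curve object.
#'
#' @inheritParams release_fraction
#' @param times Sampling times in seconds, non-decreasing, non-empty.
#' @return A [as_release_curve()] object.
#' @examples
#' release_curve(1e-8, film_geometry(0.05), times = seq(0, 3600, by = 600))
#' @export
release_curve <- function(D, geometry, times, tol = 1e-14) {
  if (length(times) == 0L)
    stop("times must be non-empty", call. = FALSE)
  if (is.unsorted(times))
    stop("times must be non-decreasing", call. = FALSE)
  as_release_curve(times, fraction = release_fraction(D, geometry, times,
                                                      tol = tol))
}

#' Time to reach a given release fraction
#'
#' Inverts the plane-sheet solution: finds the time at which the cumulative
#' release fraction reaches `fraction` (default one half). For the half
#' release the dimensionless root is tau = 0.19673, so
#' t_half = 0.19673 d^2 / D.
#'
#' @inheritParams release_fraction
#' @param fraction Target fraction in \[0, 1); 0 returns 0 exactly.
#' @return Time in seconds.
#' @examples
#' half_release_time(1e-8, film_geometry(0.005, units = "cm"))
#' @export
half_release_time <- function(D, geometry, fraction = 0.5) {
  check_D(D)
  stopifnot(inherits(geometry, "film_geometry"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction >= 1)
    stop("target fraction must lie in [0, 1)", call. = FALSE)
  if (fraction == 0) return(0)
  # bracket the root in tau, then bisect to high precision
  hi <- 1
  while (fraction_from_tau(hi) < fraction) hi <- hi * 2
  lo <- 1e-12
  while (fraction_from_tau(lo) > fraction) lo <- lo / 2
  root <- stats::uniroot(function(tau) fraction_from_tau(tau) - fraction,
                         c(lo, hi), tol = 1e-14)$root
  root * geometry$d_cm^2 / D
}
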