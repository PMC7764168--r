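#' Mass series of a swelling film
#'
#' Records the wet mass of a film over its contact time with a solvent,
#' together with the dry mass before contact.
#'
#' @param time_s Sampling times in seconds, non-decreasing.
#' @param mass_g Wet film masses in grams, >= 0.
#' @param m0_g Dry film mass in grams, > 0.
#' @return An object of class `"mass_series"`.
#' @export
mass_series <- function(time_s, mass_g, m0_g) {
  if (!is.numeric(time_s) || !is.numeric(mass_g) ||
      length(time_s) != length(mass_g) || length(time_s) == 0L)
    stop("time_s and mass_g must be numeric vectors of equal length",
         call. = FALSE)
  if (is.unsorted(time_s))
    stop("times must be non-decreasing", call. = FALSE)
  if (any(mass_g < 0)) stop("masses must be >= 0", call. = FALSE)
  if (!is.numeric(m0_g) || length(m0_g) != 1L || m0_g <= 0)
    stop("dry mass m0_g must be a single positive number", call. = FALSE)
  structure(list(time_s = time_s, mass_g = mass_g, m0_g = m0_g),
            class = "mass_series")
}

#' Swelling rate of a film
#'
#' Relative mass change s = (m_t - m_0) / m_0 of a film in contact with a
#' solvent: the mass of absorbed liquid per unit dry mass. Negative values
#' are meaningful and occur when the solvent extracts more material
#' (plasticiser, oil) than it deposits — films in ethanol lose mass and
#' show s down to about -0.06.
#'
#' @param m0 Dry film mass (> 0), grams.
#' @param mt Wet film mass(es) at time t, grams (vectorised).
#' @return Dimensionless swelling rate(s), always >= -1.
#' @examples
#' swelling_rate(1.0, 1.5)  # 0.5
#' swelling_rate(1.0, 0.95) # -0.05, net mass loss
#' @export
swelling_rate <- function(m0, mt) {
  if (!is.numeric(m0) || length(m0) != 1L || m0 <= 0)
    stop("dry mass m0 must be a single positive number", call. = FALSE)
  if (any(mt < 0)) stop("masses must be >= 0", call. = FALSE)
  (mt - m0) / m0
}

#' Equilibrium swelling of a mass series
#'
#' Computes the swelling rate at every sampling time and declares
#' equilibrium at the first time after which consecutive s values stop
#' changing: the two relative changes across a three-point window must both
#' fall below `rel_tol` (default 2%). If no such window exists the final s
#' is returned with `equilibrated = FALSE`.
#'
#' @param series A [mass_series()] with at least 3 points.
#' @param rel_tol Relative-change threshold for the plateau test.
#' @return A list of class `"swelling_equilibrium"`: `s_eq`, `t_eq`
#'   (seconds, `NA` if never equilibrated), `equilibrated`, and the full
#'   per-time `s` vector.
#' @examples
#' ms <- mass_series(0:5 * 600, c(1, 1.3, 1.45, 1.49, 1.50, 1.50), m0_g = 1)
#' equilibrium_swelling(ms)
#' @export
equilibrium_swelling <- function(series, rel_tol = 0.02) {
  stopifnot(inherits(series, "mass_series"))
  n <- length(series$time_s)
  if (n < 3L) stop("need at least 3 time points", call. = FALSE)
  s <- swelling_rate(series$m0_g, series$mass_g)
  ds <- diff(s)
  denom <- pmax(abs(s[-n]), .Machine$double.xmin)
  rel <- ifelse(ds == 0, 0, abs(ds) / denom)
  eq_idx <- NA_integer_
  for (i in 3:n) {
    if (rel[i - 2L] < rel_tol && rel[i - 1L] < rel_tol) {
      eq_idx <- i
      break
    }
  }
  equilibrated <- !is.na(eq_idx)
  structure(list(
    s_eq = if (equilibrated) s[eq_idx] else s[n],
    t_eq = if (equilibrated) series$time_s[eq_idx] else NA_real_,
    equilibrated = equilibrated,
    s = s, time_s = series$time_s),
    class = "swelling_equilibrium")
}

#' @export
print.swelling_equilibrium <- function(x, ...) {
  if (x$equilibrated)
    cat("Equilibrium swelling s =", format(x$s_eq, digits = 4),
        "reached at t =", format(x$t_eq), "s\n")
  else
    cat("No swelling equilibrium detected; last s =",
        format(x$s_eq, digits = 4), "\n")
  invisible(x)
}
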