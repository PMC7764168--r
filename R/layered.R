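#' Layered film system
#'
#' An ordered stack of film layers, each with its own thickness and
#' diffusion coefficient. Diffusive transport through stacked layers adds
#' like electrical resistances in series: each layer contributes a
#' resistance d_i / D_i, and the film as a whole behaves as a homogeneous
#' sheet with the effective coefficient returned by [effective_D()].
#'
#' @param thickness Per-layer thicknesses (positive).
#' @param D Per-layer diffusion coefficients in cm^2/s (positive), same
#'   length as `thickness`.
#' @param units Units of `thickness`, `"cm"` (default) or `"mm"`.
#' @return An object of class `"layer_system"` with elements `d_cm`
#'   (per-layer, cm), `D` and `total_cm`.
#' @examples
#' layer_system(c(0.003, 0.001), c(8.064e-9, 6.1e-10))
#' @export
layer_system <- function(thickness, D, units = c("cm", "mm")) {
  units <- match.arg(units)
  if (length(thickness) == 0L)
    stop("a layer system needs at least one layer", call. = FALSE)
  if (length(thickness) != length(D))
    stop("thickness and D must have the same length", call. = FALSE)
  if (!is.numeric(thickness) || any(!is.finite(thickness)) ||
      any(thickness <= 0))
    stop("all layer thicknesses must be positive", call. = FALSE)
  check_D(D)
  d_cm <- if (units == "mm") thickness * 0.1 else thickness
  structure(list(d_cm = d_cm, D = D, total_cm = sum(d_cm)),
            class = "layer_system")
}

#' @export
print.layer_system <- function(x, ...) {
  cat("Layer system:", length(x$d_cm), "layer(s), total",
      format(x$total_cm * 10), "mm\n")
  print(data.frame(thickness_mm = x$d_cm * 10, D_cm2_s = x$D))
  invisible(x)
}

#' Effective diffusion coefficient of a layered film
#'
#' Series-resistance composition: d / D = sum_i d_i / D_i, so
#' D = d / sum(d_i / D_i). The result always lies between the smallest and
#' largest per-layer coefficient and is invariant to layer order.
#'
#' @param system A [layer_system()].
#' @return Effective diffusion coefficient, cm^2/s.
#' @examples
#' # equal-thickness layers: harmonic mean
#' effective_D(layer_system(c(1, 1), c(1e-9, 3e-9))) # 1.5e-9
#' @export
effective_D <- function(system) {
  stopifnot(inherits(system, "layer_system"))
  system$total_cm / sum(system$d_cm / system$D)
}

#' Layer diffusivity ratio of a two-layer film
#'
#' For a two-layer film the series-resistance relation
#' d/D = d1/D1 + d2/D2 can be rearranged into a ratio form that needs only
#' two measurable dimensionless inputs:
#' \deqn{D_1/D_2 = \frac{D_1/D - d_1/d}{1 - d_1/d}}
#' `d1_over_d` is typically read off a cross-sectional micrograph, and
#' `D1_over_D` comes from release fits of the whole film and of the
#' oil-rich layer alone.
#'
#' @param D1_over_D Ratio of the first-layer coefficient to the effective
#'   whole-film coefficient; must exceed `d1_over_d`, otherwise the implied
#'   second-layer coefficient would be non-positive.
#' @param d1_over_d First-layer thickness fraction, strictly in (0, 1).
#' @return The ratio D1/D2.
#' @examples
#' two_layer_ratio(4.032, 0.75) # 13.128
#' @export
two_layer_ratio <- function(D1_over_D, d1_over_d) {
  if (!is.numeric(d1_over_d) || any(d1_over_d <= 0) || any(d1_over_d >= 1))
    stop("d1/d must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(D1_over_D) || any(!is.finite(D1_over_D)))
    stop("D1/D must be numeric and finite", call. = FALSE)
  if (any(D1_over_D <= d1_over_d))
    stop("degenerate geometry: D1/D must exceed d1/d ",
         "(otherwise the implied D2 is non-positive)", call. = FALSE)
  (D1_over_D - d1_over_d) / (1 - d1_over_d)
}

#' Decompose an effective diffusivity into two layer diffusivities
#'
#' Given the effective whole-film coefficient D, the first-layer
#' coefficient D1 and a two-layer geometry, solves the series-resistance
#' relation d/D = d1/D1 + d2/D2 for the second-layer coefficient D2 and
#' reports the dimensionless ratios used to compare films.
#'
#' @param D Effective diffusion coefficient of the whole film, cm^2/s.
#' @param D1 Diffusion coefficient of the first (solvent-facing) layer,
#'   cm^2/s.
#' @param geometry A [film_geometry()] carrying layer thicknesses `d1`, `d2`.
#' @return An object of class `"two_layer_fit"`: a list with `D`, `D1`,
#'   `D2`, `d1_over_d`, `D1_over_D` and `D1_over_D2`.
#' @examples
#' g <- film_geometry(0.08, d1 = 0.06, d2 = 0.02)
#' decompose_two_layer(D = 2.000e-9, D1 = 8.064e-9, g)
#' @export
decompose_two_layer <- function(D, D1, geometry) {
  check_D(D); check_D(D1, "D1")
  stopifnot(inherits(geometry, "film_geometry"))
  if (is.null(geometry$d1_cm))
    stop("geometry must carry layer thicknesses d1 and d2", call. = FALSE)
  d <- geometry$d_cm; d1 <- geometry$d1_cm; d2 <- geometry$d2_cm
  if (D1 / D <= d1 / d)
    stop("degenerate geometry: D1/D = ", format(D1 / D),
         " must exceed d1/d = ", format(d1 / d), call. = FALSE)
  D2 <- d2 / (d / D - d1 / D1)
  res <- list(D = D, D1 = D1, D2 = D2, d1_over_d = d1 / d,
              D1_over_D = D1 / D, D1_over_D2 = D1 / D2)
  stopifnot(min(D1, D2) <= D * (1 + 1e-12), D <= max(D1, D2) * (1 + 1e-12))
  structure(res, class = "two_layer_fit")
}

#' @export
print.two_layer_fit <- function(x, ...) {
  cat("Two-layer decomposition\n")
  cat("  D  =", format(x$D, digits = 4), "cm^2/s  (effective)\n")
  cat("  D1 =", format(x$D1, digits = 4), "cm^2/s   D2 =",
      format(x$D2, digits = 4), "cm^2/s\n")
  cat("  D1/D =", format(round(x$D1_over_D, 3), nsmall = 3),
      "  d1/d =", format(x$d1_over_d, digits = 3),
      "  D1/D2 =", format(round(x$D1_over_D2, 2), nsmall = 2), "\n")
  invisible(x)
}
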