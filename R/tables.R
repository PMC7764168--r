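#' Reference diffusion data for calcium-alginate CEO films
#'
#' Published reference values for cinnamon-essential-oil (CEO) release from
#' crosslinked calcium-alginate films, bundled as plain data frames so the
#' package's worked examples, round-trip validations and two-layer analysis
#' run without external downloads. Raw release time-series were never
#' deposited, so these per-film summaries (fitted diffusion coefficient,
#' film thickness, RMSE of the original fit) are the anchors the synthetic
#' generator and the fitting round-trips are built on.
#'
#' `alginate_film_layers` carries the two-layer analysis inputs for films
#' G, GA and GC: effective whole-film `D`, first-layer `D1` (both cm^2/s),
#' and the layer thickness fraction `d1_over_d` read off cross-sectional
#' micrographs. `alginate_release_ethanol` and `alginate_release_water`
#' list films released into absolute ethanol and into water at 4 degrees C;
#' `alginate_release_aqueous` covers the EG3 and EGC1 solvent series across
#' water fraction `w` of aqueous ethanol. Film codes: E = externally
#' crosslinked, G/A/C = gelatin / gum acacia / carboxymethylcellulose
#' emulsifier blend, trailing digit = glycerol level (0.3-1.2 g).
#'
#' @format Data frames with one row per film (or film/solvent pair):
#' \describe{
#'   \item{film}{film code}
#'   \item{w}{water fraction of the solvent (aqueous series only)}
#'   \item{thickness_mm}{film thickness, mm}
#'   \item{D}{diffusion coefficient, cm^2/s}
#'   \item{rmse}{RMSE of the original release fit (fraction units)}
#'   \item{D1, d1_over_d}{layer table only: first-layer coefficient and
#'     thickness fraction}
#' }
#' @name alginate_reference
#' @examples
#' with(alginate_film_layers, two_layer_ratio(D1 / D, d1_over_d))
NULL

#' @rdname alginate_reference
#' @export
alginate_film_layers <- data.frame(
  film = c("G", "GA", "GC"),
  D = c(2.000e-9, 6.680e-10, 4.140e-11),
  D1 = c(8.064e-9, 2.950e-9, 1.760e-10),
  d1_over_d = c(0.75, 0.73, 0.74),
  stringsAsFactors = FALSE
)

#' @rdname alginate_reference
#' @export
alginate_release_ethanol <- data.frame(
  film = c("EG1", "EG2", "EG3", "EG4",
           "EGA1", "EGA2", "EGA3", "EGA4",
           "EGC1", "EGC2", "EGC3", "EGC4"),
  thickness_mm = c(0.048, 0.053, 0.062, 0.079,
                   0.047, 0.051, 0.059, 0.076,
                   0.049, 0.050, 0.062, 0.072),
  D = c(5.800e-10, 3.433e-9, 1.096e-8, 1.606e-8,
        4.200e-11, 7.000e-10, 8.216e-9, 9.900e-9,
        8.800e-12, 4.510e-11, 3.340e-9, 5.938e-9),
  rmse = c(0.03248, 0.03436, 0.09119, 0.07104,
           0.05190, 0.06900, 0.09958, 0.1029,
           0.07831, 0.04025, 0.07512, 0.09671),
  stringsAsFactors = FALSE
)

#' @rdname alginate_reference
#' @export
alginate_release_water <- data.frame(
  film = c("EG11", "EG21", "EG31", "EGA11", "EGA21", "EGA31",
           "EGC11", "EGC21", "EGC31"),
  thickness_mm = c(0.047, 0.049, 0.053, 0.044, 0.050, 0.063,
                   0.046, 0.052, 0.060),
  D = c(4.050e-10, 5.100e-10, 6.354e-10, 4.500e-10, 5.085e-10, 8.500e-10,
        2.896e-10, 4.400e-10, 9.988e-10),
  rmse = c(0.05661, 0.03139, 0.04163, 0.01860, 0.02774, 0.04937,
           0.06030, 0.04030, 0.04996),
  stringsAsFactors = FALSE
)

#' @rdname alginate_reference
#' @export
alginate_release_aqueous <- data.frame(
  film = c(rep("EG3", 6), rep("EGC1", 6)),
  w = rep(c(0, 0.05, 0.30, 0.60, 0.95, 1), 2),
  thickness_mm = c(0.062, 0.062, 0.057, 0.056, 0.057, 0.053,
                   0.049, 0.047, 0.048, 0.041, 0.041, 0.046),
  D = c(1.127e-8, 1.099e-8, 3.900e-9, 2.156e-9, 1.712e-9, 6.354e-10,
        8.800e-12, 1.670e-11, 1.747e-10, 2.556e-10, 2.700e-10, 2.896e-10),
  rmse = c(0.08408, 0.08413, 0.07883, 0.04087, 0.09820, 0.04163,
           0.07830, 0.05916, 0.05616, 0.04232, 0.04515, 0.06030),
  stringsAsFactors = FALSE
)
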