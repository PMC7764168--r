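# filmrelease

Release-kinetics modelling for bioactive compounds diffusing out of thin
biopolymer films — the setting is controlled-release food packaging, where
cinnamon essential oil (CEO) embedded in a crosslinked calcium-alginate
film migrates into a food-simulating solvent (ethanol/water mixtures with
water fraction *w*). The package is written for packaging and
controlled-release researchers who need to turn measured cumulative-release
curves into diffusion coefficients and compare them across film
formulations and solvents.

## What it computes

**Forward model.** One-way release (solvent on a single face, impermeable
backing) from a plane sheet of thickness *d* follows Fick's second law:

    M_t / M_inf = 1 - sum_{n>=0} 8/((2n+1)^2 pi^2) exp(-D (2n+1)^2 pi^2 t / (4 d^2))

`release_fraction()` evaluates the series with adaptive truncation; the
curve depends on (D, d, t) only through tau = D t / d^2, with half release
at tau = 0.1967.

**Inverse problem.** `fit_D()` estimates D (cm^2/s) by least squares over
log10 D in [-14, -4], reporting the RMSE goodness-of-fit;
`bootstrap_ci()` adds a residual-resampling percentile interval.

**Layered films.** Two-layer films (porous oil-rich stratum over compact
polymer-rich stratum) obey series resistance, d/D = d1/D1 + d2/D2.
`effective_D()`, `decompose_two_layer()` and `two_layer_ratio()` compose
and invert it, e.g. D1/D2 = (D1/D - d1/d) / (1 - d1/d).

**Supporting analyses.** Swelling rate s = (m_t - m_0)/m_0 with plateau
detection (`equilibrium_swelling()`); an Einstein mean-squared-displacement
random-walk consistency check, MSD = 6 D t (`simulate_walk()`, `msd()`,
`estimate_D_from_msd()`); one-way ANOVA with Tukey HSD compact letter
display (`tukey_cld()`); and a ground-truth-carrying synthetic release
generator (`release_scenario()`, `generate_release_dataset()`,
`generate_solvent_series()`) standing in for the unpublished raw
measurements. Reference per-film diffusion tables are bundled
(`alginate_release_ethanol` and friends). A CLI (`rk_cli()`, installed as
`exec/filmrelease`) wraps the same functions as `simulate`, `fit`,
`decompose`, `walk`, `swell` and `report` subcommands.

## Worked example

```r
library(filmrelease)

g <- film_geometry(0.062)                 # EG3-like film, 0.062 mm
D <- 1.096e-8                             # cm^2/s
half_release_time(D, g) / 3600
#> [1] 0.1916649                          # hours to 50% release

# synthetic noisy experiment (sigma = 0.03 on the fraction scale) and refit
sc  <- release_scenario("demo", 0.062, c(EG3 = D), sigma = 0.03, seed = 7)
ds  <- generate_release_dataset(sc)
fit_D(ds[["EG3"]]$curve, ds[["EG3"]]$geometry)
#> Diffusion-coefficient fit (plane-sheet, one-way release)
#>   D_hat = 1.22e-08 cm^2/s   RMSE = 0.03283   (n = 20 points)

# two-layer ratio for film G of the bundled layer table
two_layer_ratio(D1_over_D = 4.032, d1_over_d = 0.75)
#> [1] 13.128                              # printed as 13.13

# compare fitted coefficients across films
d <- generate_replicate_groups(c(EG1 = 5.8e-10, EG2 = 3.43e-9, EG3 = 1.10e-8),
                               sd = 2e-10, n_per_group = 3, seed = 1)
tukey_cld(d)
#> Tukey HSD compact letter display (alpha = 0.05)
#>   group         mean n letters
#> 1   EG3 1.112010e-08 3       a
#> 2   EG2 3.503621e-09 3       b
#> 3   EG1 4.947707e-10 3       c
#> Groups sharing a letter are not significantly different.
```

The single noisy replicate above lands ~11% high — one sigma-0.03 draw on
20 points; the validation suite shows the estimator's median error across
the full reference grid stays under 5% and bootstrap intervals cover the
truth at their nominal rate.

## Scope

Fickian, constant-D transport only: no anomalous-release laws
(Korsmeyer-Peppas, Weibull), no concentration-dependent D, no
swelling-coupled moving boundaries, no image analysis of layer
thicknesses. See `vignettes/release-kinetics.Rmd` for the model
assumptions, numerical choices and limitations.
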