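# Independent oracles, deliberately dumber than the implementation.

# Plane-sheet master curve by brute-force summation at fixed high
# truncation (no adaptivity, no short-time branch).
brute_fraction <- function(tau, terms = 1e5) {
  vapply(tau, function(tt) {
    m <- 2 * (0:(terms - 1)) + 1
    1 - sum(8 / (m^2 * pi^2) * exp(-m^2 * pi^2 * tt / 4))
  }, numeric(1))
}

# Series-resistance effective coefficient, written as the literal
# rearrangement of the layer-sum relation.
oracle_effective_D <- function(d_i, D_i) {
  sum(d_i) / (d_i[1] / D_i[1] + sum(d_i[-1] / D_i[-1]))
}

# Two-line RMSE.
oracle_rmse <- function(a, b) {
  e <- a - b
  sqrt(sum(e * e) / length(e))
}

# Noiseless synthetic curve on a log-spaced dimensionless-time schedule.
make_curve <- function(D, thickness_mm, n = 20, tau_range = c(0.02, 2),
                       sigma = 0, seed = NULL) {
  g <- film_geometry(thickness_mm)
  tau <- 10^seq(log10(tau_range[1]), log10(tau_range[2]), length.out = n)
  times <- tau * g$d_cm^2 / D
  f <- release_fraction(D, g, times)
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    f <- pmin(pmax(f + rnorm(n, sd = sigma), 0), 1)
  }
  list(curve = as_release_curve(times, fraction = f), geometry = g)
}

# Does every pair of groups share a letter exactly when its adjusted
# p-value is non-significant?
letters_consistent <- function(cld) {
  p <- attr(cld, "p_matrix")
  alpha <- attr(cld, "alpha")
  sets <- strsplit(cld$letters, "")
  names(sets) <- cld$group
  for (a in cld$group) for (b in cld$group) {
    if (a == b) next
    share <- length(intersect(sets[[a]], sets[[b]])) > 0
    nonsig <- p[a, b] >= alpha
    if (share != nonsig) return(FALSE)
  }
  TRUE
}
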