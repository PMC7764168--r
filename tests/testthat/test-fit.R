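test_that("rmse matches its definition", {
  expect_identical(rmse(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9)), 0)
  expect_identical(rmse(c(0, 1), c(1, 0)), 1)
  set.seed(3)
  for (i in 1:20) {
    a <- runif(7); b <- runif(7)
    expect_equal(rmse(a, b), oracle_rmse(a, b), tolerance = 1e-12)
  }
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("noiseless curves across the published D range are recovered to 0.1%", {
  # spans the full reported range, 8.8e-12 to 1.606e-8 cm^2/s
  cases <- data.frame(D = c(8.8e-12, 5.8e-10, 3.34e-9, 1.606e-8),
                      th = c(0.049, 0.048, 0.062, 0.079))
  for (i in seq_len(nrow(cases))) {
    mk <- make_curve(cases$D[i], cases$th[i])
    fit <- fit_D(mk$curve, mk$geometry)
    expect_lt(abs(fit$D_hat - cases$D[i]) / cases$D[i], 1e-3)
    expect_lt(fit$rmse, 1e-6)
    expect_true(fit$converged)
  }
})

test_that("the optimiser beats a 200-point grid of the objective", {
  mk <- make_curve(3e-9, 0.05, sigma = 0.03, seed = 21)
  fit <- fit_D(mk$curve, mk$geometry)
  grid <- seq(-14, -4, length.out = 200)
  grid_rmse <- vapply(grid, function(l)
    rmse(mk$curve$fraction,
         release_fraction(10^l, mk$geometry, mk$curve$time_s)),
    numeric(1))
  expect_lte(fit$rmse, min(grid_rmse) + 1e-12)
})

test_that("fitting is equivariant under the tau-preserving rescaling", {
  k <- 2.5
  mk1 <- make_curve(1e-9, 0.05, sigma = 0.03, seed = 9)
  g2 <- film_geometry(0.05 * k)
  crv2 <- as_release_curve(mk1$curve$time_s, fraction = mk1$curve$fraction)
  f1 <- fit_D(mk1$curve, mk1$geometry)
  f2 <- fit_D(crv2, g2)
  expect_equal(f2$D_hat / f1$D_hat, k^2, tolerance = 1e-5)
  expect_equal(f2$rmse, f1$rmse, tolerance = 1e-9)
})

test_that("degenerate curves are rejected as non-identifiable", {
  g <- film_geometry(0.05)
  t <- seq(0, 1000, length.out = 10)
  expect_error(fit_D(as_release_curve(t, fraction = rep(0, 10)), g),
               "non-identifiable")
  expect_error(fit_D(as_release_curve(t, fraction = rep(0.4, 10)), g),
               "non-identifiable")
  expect_error(fit_D(as_release_curve(c(0, 1, 2), fraction = c(0, 0.1, 0.2)),
                     g), "3 points with t > 0")
})

test_that("moderate noise leaves the estimator nearly unbiased", {
  rel_err <- vapply(1:40, function(r) {
    mk <- make_curve(1.096e-8, 0.062, sigma = 0.03, seed = 500 + r)
    fit_D(mk$curve, mk$geometry)$D_hat / 1.096e-8 - 1
  }, numeric(1))
  expect_lt(abs(median(rel_err)), 0.05)
})

test_that("amount curves are normalised by the plateau or co-estimated", {
  g <- film_geometry(0.05)
  D <- 2e-9
  times <- c(10^seq(2, 4.2, length.out = 12),
             c(1, 1.05, 1.1) * 5 * g$d_cm^2 / D) # deep-plateau tail
  m_inf <- 12.5
  a <- m_inf * release_fraction(D, g, times)
  fit_p <- fit_D(as_release_curve(times, amount = a), g)
  expect_equal(fit_p$m_inf_used, m_inf, tolerance = 1e-3)
  expect_equal(fit_p$D_hat, D, tolerance = 1e-2)
  fit_e <- fit_D(as_release_curve(times, amount = a), g,
                 fit_options(m_inf = "estimate"))
  expect_equal(fit_e$m_inf_used, m_inf, tolerance = 1e-4)
  expect_equal(fit_e$D_hat, D, tolerance = 1e-3)
})

test_that("bootstrap interval collapses for noiseless data and is reproducible", {
  mk <- make_curve(1e-9, 0.05)
  ci <- bootstrap_ci(mk$curve, mk$geometry, fit_options(B = 100, seed = 4))
  expect_lt(diff(ci) / attr(ci, "D_hat"), 1e-6)
  mk2 <- make_curve(1e-9, 0.05, sigma = 0.03, seed = 31)
  opts <- fit_options(B = 120, seed = 77)
  ci_a <- bootstrap_ci(mk2$curve, mk2$geometry, opts)
  ci_b <- bootstrap_ci(mk2$curve, mk2$geometry, opts)
  expect_identical(as.numeric(ci_a), as.numeric(ci_b))
  expect_lte(ci_a[1], attr(ci_a, "D_hat"))
  expect_gte(ci_a[2], attr(ci_a, "D_hat"))
  expect_error(bootstrap_ci(mk2$curve, mk2$geometry,
                            fit_options(B = 50, seed = 1)), "B >= 100")
  expect_error(bootstrap_ci(mk2$curve, mk2$geometry, fit_options(B = 100)),
               "seed")
})
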