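test_that("noise-free generation reproduces the forward model exactly", {
  sc <- release_scenario("clean", 0.062, c(EG3 = 1.096e-8), sigma = 0)
  ds <- generate_release_dataset(sc)
  rec <- ds[["EG3"]]
  expect_equal(rec$curve$fraction,
               release_fraction(rec$D_true, rec$geometry, rec$curve$time_s),
               tolerance = 1e-15)
  truth <- attr(ds, "truth")
  expect_equal(truth$D_true, 1.096e-8)
  expect_equal(truth$thickness_mm, 0.062)
})

test_that("generation is reproducible under its seed and records truth", {
  sc <- release_scenario("noisy", 0.05, c(a = 1e-9, b = 5e-9),
                         sigma = 0.03, n_reps = 3, seed = 42)
  d1 <- generate_release_dataset(sc)
  d2 <- generate_release_dataset(sc)
  expect_identical(lapply(d1, `[[`, "curve"), lapply(d2, `[[`, "curve"))
  expect_equal(nrow(attr(d1, "truth")), 6)
  expect_true(all(c("label", "film", "rep", "D_true") %in%
                    names(attr(d1, "truth"))))
})

test_that("a seed is demanded for stochastic scenarios", {
  expect_error(release_scenario("x", 0.05, 1e-9, sigma = 0.03),
               "seed is mandatory")
  expect_silent(release_scenario("x", 0.05, 1e-9, sigma = 0))
})

test_that("schedules outside the informative band trigger a warning", {
  # all points in deep equilibrium: fraction > 0.95 everywhere
  sc <- release_scenario("late", 0.05, c(x = 1e-9), sigma = 0,
                         tau_range = c(5, 10))
  expect_warning(generate_release_dataset(sc), "weakly identifiable")
})

test_that("fits on generated data recover the generating coefficients", {
  sc <- release_scenario("grid", thickness_mm = 0.05,
                         D = c(lo = 5.8e-10, mid = 3.4e-9, hi = 1.6e-8),
                         sigma = 0.03, n_reps = 5, seed = 202)
  ds <- generate_release_dataset(sc)
  err <- vapply(ds, function(rec)
    abs(fit_D(rec$curve, rec$geometry)$D_hat - rec$D_true) / rec$D_true,
    numeric(1))
  expect_lt(median(err), 0.05)
})

test_that("solvent series interpolates log-linearly between its anchors", {
  sc <- release_scenario("EG3like", 0.062, c(x = 1e-8), sigma = 0)
  w <- c(0, 0.25, 0.5, 0.75, 1)
  ds <- generate_solvent_series(sc, w, profile = "decreasing",
                                D_anchors = c(1.127e-8, 6.354e-10))
  truth <- attr(ds, "truth")
  expect_equal(truth$w, w)
  expect_equal(truth$D_true[1], 1.127e-8)
  expect_equal(truth$D_true[5], 6.354e-10)
  l10 <- log10(truth$D_true)
  expect_equal(diff(l10), rep(diff(l10)[1], 4), tolerance = 1e-12)
  expect_true(all(diff(truth$D_true) < 0))
})

test_that("fitted solvent-series trends reproduce the imposed monotonicity", {
  w <- c(0, 0.3, 0.6, 1)
  sc_dec <- release_scenario("EG3like", 0.062, c(x = 1e-8),
                             sigma = 0.02, seed = 61)
  ds_dec <- generate_solvent_series(sc_dec, w, profile = "decreasing",
                                    D_anchors = c(1.127e-8, 6.354e-10))
  D_hat_dec <- vapply(ds_dec, function(r)
    fit_D(r$curve, r$geometry)$D_hat, numeric(1))
  expect_true(all(diff(D_hat_dec) < 0))

  sc_inc <- release_scenario("EGC1like", 0.049, c(x = 1e-10),
                             sigma = 0.02, seed = 62)
  ds_inc <- generate_solvent_series(sc_inc, w, profile = "increasing",
                                    D_anchors = c(8.800e-12, 2.896e-10))
  D_hat_inc <- vapply(ds_inc, function(r)
    fit_D(r$curve, r$geometry)$D_hat, numeric(1))
  expect_true(all(diff(D_hat_inc) > 0))
})

test_that("inconsistent anchors are a configuration error", {
  sc <- release_scenario("bad", 0.05, c(x = 1e-9), sigma = 0)
  expect_error(generate_solvent_series(sc, c(0, 1), "decreasing",
                                       D_anchors = c(1e-10, 1e-9)),
               "not decreasing")
  expect_error(generate_solvent_series(sc, c(0, 2), "decreasing",
                                       D_anchors = c(1e-9, 1e-10)),
               "\\[0, 1\\]")
})

test_that("replicate groups are exact at sd = 0 and reproducible", {
  g0 <- generate_replicate_groups(c(a = 1, b = 5), sd = 0,
                                  n_per_group = 3, seed = 1)
  expect_equal(g0$value, rep(c(1, 5), each = 3))
  ga <- generate_replicate_groups(c(a = 1, b = 5), sd = 1,
                                  n_per_group = 4, seed = 9)
  gb <- generate_replicate_groups(c(a = 1, b = 5), sd = 1,
                                  n_per_group = 4, seed = 9)
  expect_identical(ga, gb)
  expect_error(generate_replicate_groups(1:2, 1, 1, 1), "n_per_group")
})
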