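#' Simulate an ensemble of isotropic fixed-step random walks
#'
#' Each walker takes `n_steps` independent steps of fixed length
#' `step_length`, each in a direction drawn uniformly on the unit sphere
#' (a normalised Gaussian triple). This is the continuum hop picture of a
#' molecule diffusing through a polymer: a displacement of fixed size every
#' `dt` seconds, with no directional memory. The ensemble mean squared
#' displacement after n steps is exactly n * step_length^2, which makes the
#' walk a closed-form check of the Einstein relation MSD = 6 D t.
#'
#' @param n_walkers Number of walkers N >= 1.
#' @param n_steps Number of steps T >= 1.
#' @param step_length Hop length per step (any length unit; >= 0).
#' @param dt Seconds per step (> 0).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `"walk_ensemble"`: list with `x`, `y`, `z`
#'   ((T+1) x N position matrices, all walkers starting at the origin),
#'   `times` (seconds, length T+1), `step_length` and `dt`.
#' @examples
#' w <- simulate_walk(100, 50, step_length = 1, dt = 1, seed = 42)
#' estimate_D_from_msd(msd(w)) # close to 1/6
#' @export
simulate_walk <- function(n_walkers, n_steps, step_length = 1, dt = 1,
                          seed = NULL) {
  if (n_walkers < 1L || n_steps < 1L)
    stop("n_walkers and n_steps must be >= 1", call. = FALSE)
  if (step_length < 0) stop("step_length must be >= 0", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  gx <- matrix(stats::rnorm(n_steps * n_walkers), n_steps, n_walkers)
  gy <- matrix(stats::rnorm(n_steps * n_walkers), n_steps, n_walkers)
  gz <- matrix(stats::rnorm(n_steps * n_walkers), n_steps, n_walkers)
  nrm <- sqrt(gx^2 + gy^2 + gz^2)
  nrm[nrm == 0] <- 1 # probability-zero guard
  sc <- step_length / nrm
  zero <- matrix(0, 1L, n_walkers)
  pos <- function(g) rbind(zero, apply(g * sc, 2L, cumsum))
  structure(list(x = pos(gx), y = pos(gy), z = pos(gz),
                 times = (0:n_steps) * dt,
                 step_length = step_length, dt = dt),
            class = "walk_ensemble")
}

#' @export
print.walk_ensemble <- function(x, ...) {
  cat("Random-walk ensemble:", ncol(x$x), "walkers,",
      nrow(x$x) - 1L, "steps of length", format(x$step_length),
      "every", format(x$dt), "s\n")
  invisible(x)
}

#' Mean squared displacement of a walk ensemble
#'
#' Ensemble-averaged squared displacement from the starting position,
#' msd(t) = (1/N) sum_i |r_i(t) - r_i(0)|^2, evaluated at every recorded
#' time (displacement from the origin, not a time-averaged lag statistic).
#'
#' @param ensemble A [simulate_walk()] result.
#' @return A data frame of class `"msd_series"` with columns `lag_s` and
#'   `msd`; `msd[1]` (zero lag) is exactly 0.
#' @export
msd <- function(ensemble) {
  stopifnot(inherits(ensemble, "walk_ensemble"))
  m <- rowMeans(ensemble$x^2 + ensemble$y^2 + ensemble$z^2)
  structure(data.frame(lag_s = ensemble$times, msd = m),
            class = c("msd_series", "data.frame"))
}

#' Estimate a diffusion coefficient from an MSD series
#'
#' Through-origin least-squares fit of msd against lag time; in three
#' dimensions MSD = 6 D t, so the estimate is slope / 6. A non-positive
#' slope (possible only for degenerate input) triggers a warning and a
#' zero estimate.
#'
#' @param series An `"msd_series"` (or any data frame with columns `lag_s`
#'   and `msd`) with at least 2 positive lags.
#' @return Estimated D in (length unit)^2 / s.
#' @export
estimate_D_from_msd <- function(series) {
  if (!all(c("lag_s", "msd") %in% names(series)))
    stop("series must have columns lag_s and msd", call. = FALSE)
  t <- series$lag_s
  m <- series$msd
  keep <- t > 0
  if (sum(keep) < 2L)
    stop("need at least 2 positive lag times", call. = FALSE)
  slope <- sum(t[keep] * m[keep]) / sum(t[keep]^2)
  if (slope <= 0) {
    warning("non-positive MSD slope; returning D = 0", call. = FALSE)
    return(0)
  }
  slope / 6
}
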