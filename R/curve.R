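#' Construct a release curve
#'
#' A release curve records the cumulative amount of compound released from
#' one film/solvent pair against time. It can be built either directly from
#' release fractions (M_t / M_inf, dimensionless) or from raw released
#' amounts together with the equilibrium amount `m_inf`, in which case
#' fractions are `amount / m_inf`.
#'
#' Times are sorted; exact duplicate times are averaged (one warning).
#'
#' @param time_s Sampling times in seconds, first >= 0.
#' @param fraction Cumulative release fractions in \[0, 1\].
#' @param amount Raw released amounts (any consistent unit); requires
#'   `m_inf` unless the fit is asked to estimate it.
#' @param m_inf Amount released at equilibrium, same units as `amount`.
#' @return An object of class `"release_curve"`: a list with elements
#'   `time_s`, `fraction` (possibly `NULL` when only amounts are given),
#'   `amount` and `m_inf`.
#' @examples
#' as_release_curve(c(0, 60, 300), fraction = c(0, 0.12, 0.43))
#' as_release_curve(c(0, 60, 300), amount = c(0, 1.2, 4.3), m_inf = 10)
#' @export
as_release_curve <- function(time_s, fraction = NULL, amount = NULL,
                             m_inf = NULL) {
  if (!is.numeric(time_s) || length(time_s) == 0L || any(!is.finite(time_s)))
    stop("time_s must be non-empty, finite and numeric", call. = FALSE)
  if (time_s[which.min(time_s)] < 0)
    stop("times must be non-negative", call. = FALSE)
  if (is.null(fraction) && is.null(amount))
    stop("one of fraction or amount is required", call. = FALSE)
  y <- if (!is.null(fraction)) fraction else amount
  if (!is.numeric(y) || length(y) != length(time_s) || any(!is.finite(y)))
    stop("fraction/amount must be numeric and match time_s in length",
         call. = FALSE)
  ord <- order(time_s)
  time_s <- time_s[ord]
  y <- y[ord]
  if (anyDuplicated(time_s)) {
    warning("duplicate sampling times averaged", call. = FALSE)
    y <- as.numeric(tapply(y, time_s, mean))
    time_s <- sort(unique(time_s))
  }
  if (!is.null(fraction)) {
    if (any(y < 0 | y > 1))
      stop("release fractions must lie in [0, 1]", call. = FALSE)
    fraction <- y
    if (!is.null(m_inf) && !is.null(amount)) amount <- fraction * m_inf
    else amount <- NULL
  } else {
    amount <- y
    if (!is.null(m_inf)) {
      if (!is.numeric(m_inf) || length(m_inf) != 1L || m_inf <= 0)
        stop("m_inf must be a single positive amount", call. = FALSE)
      fraction <- amount / m_inf
      if (any(fraction < 0 | fraction > 1 + 1e-9))
        stop("amount/m_inf must lie in [0, 1]", call. = FALSE)
      fraction <- pmin(fraction, 1)
    }
  }
  structure(list(time_s = time_s, fraction = fraction, amount = amount,
                 m_inf = m_inf),
            class = "release_curve")
}

#' @export
print.release_curve <- function(x, ...) {
  n <- length(x$time_s)
  cat("Release curve: ", n, " points, t = ",
      format(min(x$time_s)), "..", format(max(x$time_s)), " s", sep = "")
  if (!is.null(x$fraction))
    cat(", fraction ", format(round(min(x$fraction), 4)), "..",
        format(round(max(x$fraction), 4)), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.release_curve <- function(x, ...) {
  d <- data.frame(time_s = x$time_s)
  if (!is.null(x$fraction)) d$fraction <- x$fraction
  if (!is.null(x$amount)) d$amount <- x$amount
  d
}

#' @export
length.release_curve <- function(x) length(x$time_s)

# Fractions for fitting: prefer explicit fractions; otherwise normalise
# amounts by m_inf (given, or fixed from the terminal plateau).
curve_fractions <- function(curve, m_inf_policy = "plateau") {
  if (!is.null(curve$fraction))
    return(list(fraction = curve$fraction, m_inf = curve$m_inf))
  a <- curve$amount
  m_inf <- curve$m_inf
  if (is.null(m_inf)) {
    if (identical(m_inf_policy, "plateau")) {
      n <- length(a)
      if (n < 3L)
        stop("need >= 3 points to fix m_inf from the plateau", call. = FALSE)
      tail3 <- a[(n - 2L):n]
      rel <- diff(tail3) / pmax(abs(tail3[-3L]), .Machine$double.xmin)
      if (any(abs(rel) >= 0.02))
        warning("no release plateau detected (last three samples change by ",
                ">= 2%); m_inf fixed to their mean anyway", call. = FALSE)
      m_inf <- mean(tail3)
      if (m_inf <= 0) stop("plateau amount is not positive", call. = FALSE)
    } else {
      return(list(fraction = NULL, m_inf = NULL)) # co-estimated downstream
    }
  }
  list(fraction = pmin(pmax(a / m_inf, 0), 1), m_inf = m_inf)
}
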