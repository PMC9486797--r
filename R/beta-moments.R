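#' Convert beta-value moments to Beta distribution shape parameters
#'
#' Method-of-moments estimation of the two shape parameters of a Beta
#' distribution from its mean and standard deviation. This is the bridge
#' between a reference panel (per cell type, per CpG beta mean and SD) and
#' the generative Beta law used to sample cell-specific methylation.
#'
#' A Beta distribution with mean \eqn{m} requires variance strictly below
#' \eqn{m(1-m)}. Infeasible inputs (SD too large for the mean) are handled
#' by clipping the SD to `clip_factor * sqrt(mean * (1 - mean))` with a
#' warning; only means outside (0, 1) are a hard error.
#'
#' @param mean Beta mean, strictly inside (0, 1). Vectorised.
#' @param sd Beta standard deviation, > 0. Recycled against `mean`.
#' @param clip_factor Fraction of the feasibility bound `sqrt(m(1-m))` that
#'   an infeasible SD is clipped to. Default 0.95.
#' @return A list with numeric vectors `a` and `b` (both > 0).
#' @examples
#' moments_to_beta_shapes(0.5, sqrt(1 / 12)) # uniform: a = b = 1
#' moments_to_beta_shapes(0.2, 0.1)          # a = 3, b = 12
#' @export
moments_to_beta_shapes <- function(mean, sd, clip_factor = 0.95) {
  if (any(!is.finite(mean)) || any(mean <= 0) || any(mean >= 1)) {
    stop("beta means must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(sd)) || any(sd <= 0)) {
    stop("beta standard deviations must be > 0", call. = FALSE)
  }
  n <- max(length(mean), length(sd))
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  bound <- sqrt(mean * (1 - mean))
  bad <- sd >= bound
  if (any(bad)) {
    warning(sum(bad), " infeasible mean/SD pair(s): sd^2 >= mean*(1-mean); ",
            "sd clipped to ", clip_factor, " * feasibility bound",
            call. = FALSE)
    sd[bad] <- clip_factor * bound[bad]
  }
  nu <- mean * (1 - mean) / sd^2 - 1 # total concentration a + b
  if (any(nu <= 0)) {
    stop("infeasible moments after clipping: sd^2 >= mean*(1-mean)",
         call. = FALSE)
  }
  list(a = mean * nu, b = (1 - mean) * nu)
}

#' Analytic mean and SD of a Beta distribution
#'
#' Inverse of [moments_to_beta_shapes()]; used for round-trip checks.
#'
#' @param a,b Shape parameters, > 0.
#' @return A list with `mean` and `sd`.
#' @export
beta_shapes_to_moments <- function(a, b) {
  stopifnot(all(a > 0), all(b > 0))
  s <- a + b
  list(mean = a / s, sd = sqrt(a * b / (s^2 * (s + 1))))
}
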