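#' Exponentially modified Gaussian peak profile
#'
#' Evaluates the EMG peak shape at times `t`. The EMG is the convolution of
#' a Gaussian (centre `apex_time`, width `sigma`, apex `height`) with a
#' normalised one-sided exponential decay of constant `tau`; it is the
#' standard model for tailing chromatographic peaks. The convolution
#' preserves area, so the total area equals `height * sigma * sqrt(2*pi)`
#' for every `tau`. With `tau = 0` the profile is the pure Gaussian.
#'
#' The implementation uses the scaled-complementary-error-function form
#' `h * r * sqrt(pi/2) * exp(-u^2/2) * erfcx((r - u)/sqrt(2))` with
#' `u = (t - mu)/sigma`, `r = sigma/tau`, switching for `u > r` to an
#' algebraically equivalent branch whose exponent is assembled before
#' exponentiation, so the evaluation is overflow-free for every
#' `tau/sigma` ratio.
#'
#' @param t Numeric vector of times (minutes).
#' @param peak A [peak_spec()].
#' @return Numeric vector of intensities (non-negative, finite).
#' @examples
#' p <- peak_spec("x", 10, height = 100, sigma = 0.1, tau = 0.2)
#' emg_profile(c(9.8, 10, 10.4), p)
#' @export
emg_profile <- function(t, peak) {
  if (!inherits(peak, "peak_spec")) {
    stop_chromaqc("`peak` must be a peak_spec object.",
                  "chromaqc_parameter_error")
  }
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop_chromaqc("`t` must be finite numeric.", "chromaqc_parameter_error")
  }
  mu <- peak$apex_time
  h <- peak$height
  sigma <- peak$sigma
  tau <- peak$tau
  u <- (t - mu) / sigma
  if (tau == 0) {
    return(h * exp(-u^2 / 2))
  }
  r <- sigma / tau
  y <- numeric(length(t))
  z <- (r - u) / sqrt(2)
  pre <- h * r * sqrt(pi / 2)
  main <- z >= 0
  # u <= r: erfcx argument non-negative, everything bounded
  y[main] <- pre * exp(-u[main]^2 / 2) * erfcx_safe(z[main])
  if (any(!main)) {
    # far tail u > r: erfcx(z) = 2*exp(z^2) - erfcx(-z); fold exp(z^2) into
    # the Gaussian factor so the exponent r*(r/2 - u) <= -r^2/2 never
    # overflows
    ut <- u[!main]
    y[!main] <- pre * (2 * exp(r * (r / 2 - ut)) -
                         exp(-ut^2 / 2) * erfcx_safe(-z[!main]))
  }
  pmax(y, 0)
}

# erfcx for non-negative arguments: pracma below 25, continued asymptotic
# expansion erfcx(x) ~ 1/(x sqrt(pi)) * (1 - 1/(2x^2) + 3/(4x^4)) above,
# where the direct exp(x^2)*erfc(x) form overflows.
erfcx_safe <- function(x) {
  out <- numeric(length(x))
  small <- x < 25
  if (any(small)) out[small] <- pracma::erfcx(x[small])
  if (any(!small)) {
    xl <- x[!small]
    out[!small] <- (1 - 1 / (2 * xl^2) + 3 / (4 * xl^4)) / (xl * sqrt(pi))
  }
  out
}
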