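#' Autocovariance of unit-variance fractional Gaussian noise
#'
#' Fractional Gaussian noise (fGn) with Hurst exponent `H` is the stationary
#' increment process of fractional Brownian motion. Its autocovariance at
#' integer lag `k` is
#' \deqn{\gamma_H(k) = \tfrac{1}{2}\left(|k+1|^{2H} - 2|k|^{2H} +
#'   |k-1|^{2H}\right).}
#' For `H = 0.5` the process is white noise and all nonzero lags vanish.
#'
#' @param H Hurst exponent, in (0, 1).
#' @param lag Integer lag (vectorised); the function is symmetric in `lag`.
#' @return Autocovariance value(s), with `fgn_covariance(H, 0) == 1`.
#' @examples
#' fgn_covariance(0.8, 0:4)
#' @export
fgn_covariance <- function(H, lag) {
  check_hurst(H)
  k <- abs(lag)
  0.5 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
}

#' Cross-covariance of correlated bivariate fractional Gaussian noise
#'
#' The time-reversible bivariate fGn model couples two unit-variance fGn
#' components with pointwise (lag-zero) correlation `rho`; the
#' cross-covariance takes the same second-difference form as the marginal
#' autocovariances, with exponent `H1 + H2`:
#' \deqn{\gamma_{12}(k) = \tfrac{\rho}{2}\left(|k+1|^{H_1+H_2} -
#'   2|k|^{H_1+H_2} + |k-1|^{H_1+H_2}\right),}
#' so that `gamma_12(0) = rho` exactly.
#'
#' @param H1,H2 Hurst exponents of the two components, each in (0, 1).
#' @param rho Pointwise correlation, in \[-1, 1\].
#' @param lag Integer lag (vectorised, symmetric).
#' @return Cross-covariance value(s).
#' @export
bfgn_cross_covariance <- function(H1, H2, rho, lag) {
  check_hurst(H1)
  check_hurst(H2)
  if (abs(rho) > 1) stop("`rho` must lie in [-1, 1], got ", rho)
  Hs <- H1 + H2
  k <- abs(lag)
  0.5 * rho * ((k + 1)^Hs - 2 * k^Hs + abs(k - 1)^Hs)
}

#' Spectral density of unit-variance fractional Gaussian noise
#'
#' Exact spectral density on the Nyquist interval, evaluated by truncating the
#' infinite aliasing sum and correcting the tail with its integral
#' approximation:
#' \deqn{S_H(f) = C_H \, |2\sin(\pi f)|^2 \sum_{j \in Z} |f + j|^{-(2H+1)},
#'   \quad C_H = \frac{\Gamma(2H+1)\sin(\pi H)}{(2\pi)^{2H+1}}.}
#' The density integrates to 1 over (-1/2, 1/2).
#'
#' @param f Frequencies in cycles/sample, in (-1/2, 1/2); `f = 0` yields 0
#'   for `H < 1/2`... (evaluated by continuity; the density is finite at 0 only
#'   for `H <= 1/2`, infinite otherwise and `Inf` is returned).
#' @param H Hurst exponent in (0, 1).
#' @param n_terms Number of aliasing terms kept on each side before the
#'   analytic tail correction.
#' @return Spectral density values.
#' @export
fgn_spectral_density <- function(f, H, n_terms = 100L) {
  check_hurst(H)
  a <- 2 * H + 1
  cH <- gamma(2 * H + 1) * sin(pi * H) / (2 * pi)^(2 * H + 1)
  s <- vapply(f, function(fi) {
    if (fi == 0) {
      return(if (H < 0.5) 0 else if (H == 0.5) 1 else Inf)
    }
    j <- seq(-n_terms, n_terms)
    acc <- sum(abs(fi + j)^(-a))
    # tail: 2 * integral_{n_terms + 1/2}^Inf x^-a dx
    acc <- acc + 2 * (n_terms + 0.5)^(-(a - 1)) / (a - 1)
    acc
  }, numeric(1))
  cH * (2 * sin(pi * f))^2 * s
}

#' Cross-spectral density of delayed, correlated bivariate fGn
#'
#' Spectral counterpart of [bfgn_cross_covariance()], including the phase
#' ramp induced by delaying the second component by `delta` samples:
#' \deqn{S_{12}(f) = \rho\, C_{12}\, |2\sin(\pi f)|^2
#'   \sum_j |f+j|^{-(H_1+H_2+1)} \, e^{+i 2\pi f \Delta},}
#' with the phase sign matching the estimator's conjugation convention
#' (`S_ab` conjugates the delayed channel `b`).
#'
#' @inheritParams bfgn_cross_covariance
#' @param f Frequencies in cycles/sample.
#' @param delta Delay of the second component, in samples.
#' @param n_terms Aliasing terms per side, as in [fgn_spectral_density()].
#' @return Complex cross-spectral density values.
#' @export
bfgn_cross_spectral_density <- function(f, H1, H2, rho, delta = 0,
                                        n_terms = 100L) {
  check_hurst(H1)
  check_hurst(H2)
  if (rho == 0) return(complex(length(f)))
  Hs <- H1 + H2
  a <- Hs + 1
  c12 <- gamma(Hs + 1) * sin(pi * Hs / 2) / (2 * pi)^(Hs + 1)
  s <- vapply(f, function(fi) {
    if (fi == 0) return(if (Hs < 1) 0 else if (Hs == 1) 1 else Inf)
    j <- seq(-n_terms, n_terms)
    sum(abs(fi + j)^(-a)) + 2 * (n_terms + 0.5)^(-(a - 1)) / (a - 1)
  }, numeric(1))
  rho * c12 * (2 * sin(pi * f))^2 * s * exp(2i * pi * f * delta)
}

#' Generalized (power-law) spectrum of fractional Brownian motion
#'
#' fBm is nonstationary; its generalized spectrum is the pure power law
#' \deqn{S_H(f) = C_H |f|^{-(2H+1)}} with the same constant as the fGn
#' density. It is meaningful only away from `f = 0`, e.g. restricted to a
#' wavelet passband.
#'
#' @param f Frequencies in cycles/sample (nonzero).
#' @param H Hurst exponent in (0, 1).
#' @return Generalized spectral density values.
#' @export
fbm_generalized_spectrum <- function(f, H) {
  check_hurst(H)
  cH <- gamma(2 * H + 1) * sin(pi * H) / (2 * pi)^(2 * H + 1)
  cH * abs(f)^(-(2 * H + 1))
}

#' Cross generalized spectrum of delayed, correlated bivariate fBm
#'
#' @inheritParams bfgn_cross_spectral_density
#' @return Complex generalized cross-spectrum values.
#' @export
bfbm_cross_generalized_spectrum <- function(f, H1, H2, rho, delta = 0) {
  check_hurst(H1)
  check_hurst(H2)
  if (rho == 0) return(complex(length(f)))
  Hs <- H1 + H2
  c12 <- gamma(Hs + 1) * sin(pi * Hs / 2) / (2 * pi)^(Hs + 1)
  rho * c12 * abs(f)^(-(Hs + 1)) * exp(2i * pi * f * delta)
}

#' Integrate fractional Gaussian noise to fractional Brownian motion
#'
#' fBm at unit sampling is the running sum of its fGn increments, anchored at
#' `B_H(0) = 0` (the returned series starts at the first increment). First
#' differences of the output reproduce the input exactly.
#'
#' @param fgn_series Numeric vector of increments.
#' @return Numeric vector of the same length, the cumulative sum.
#' @examples
#' integrate_to_fbm(rep(1, 5))
#' @export
integrate_to_fbm <- function(fgn_series) {
  if (length(fgn_series) == 0L) stop("empty input: nothing to integrate")
  if (!all(is.finite(fgn_series))) stop("input must be finite")
  cumsum(fgn_series)
}

check_hurst <- function(H) {
  if (!is.numeric(H) || length(H) != 1L || !is.finite(H) || H <= 0 || H >= 1) {
    stop("Hurst exponent must be a single value in (0, 1), got ",
         deparse(substitute(H)), " = ", format(H))
  }
  invisible(H)
}
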