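# Wavelet cross-spectrum, connectivity indices, band averaging and Hurst
# estimation.

#' Wavelet (cross-)spectrum of two coefficient sets
#'
#' Per-octave average of the coefficient products
#' \deqn{S^W_{ab}(j) = \frac{1}{n_j}\sum_k d_a(j,k)\, d_b(j,k)^*,}
#' with boundary-flagged coefficients excluded from the sums. Passing the
#' same object twice yields the (real, nonnegative) auto-spectrum.
#'
#' @param a,b [dtcwt_forward()] outputs from equal-length inputs with the
#'   same filter set and octave count.
#' @return An object of class `wavelet_spectrum`: complex vector `S` per
#'   octave, effective counts `nj_used`, flags for octaves with no usable
#'   coefficients, `J`, and the filter-set identifier.
#' @export
wavelet_cross_spectrum <- function(a, b = a) {
  if (!inherits(a, "dtcwt_coeffs") || !inherits(b, "dtcwt_coeffs")) {
    stop("inputs must be dtcwt_coeffs objects")
  }
  if (a$J != b$J || a$n != b$n) {
    stop("mismatched decompositions: a has (n, J) = (", a$n, ", ", a$J,
         "), b has (", b$n, ", ", b$J, ")")
  }
  if (a$filter_set != b$filter_set) stop("mismatched filter sets")
  J <- a$J
  S <- complex(J)
  nj_used <- integer(J)
  for (j in seq_len(J)) {
    keep <- !(a$boundary[[j]] | b$boundary[[j]])
    nj_used[j] <- sum(keep)
    S[j] <- if (nj_used[j] > 0) {
      mean(a$d[[j]][keep] * Conj(b$d[[j]][keep]))
    } else {
      NA_complex_
    }
  }
  structure(
    list(S = S, nj_used = nj_used, flagged = nj_used == 0L, J = J,
         n = a$n, filter_set = a$filter_set),
    class = "wavelet_spectrum"
  )
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  cat(sprintf("<wavelet_spectrum> J=%d octaves (n=%d)\n", x$J, x$n))
  print(data.frame(octave = seq_len(x$J), S = x$S, nj = x$nj_used))
  invisible(x)
}

new_profile <- function(index, basis, values, flagged, octaves = NULL,
                        freq = NULL, pair = NULL) {
  structure(
    list(index = index, basis = basis, values = values, flagged = flagged,
         octaves = octaves, freq = freq, pair = pair),
    class = "connectivity_profile"
  )
}

#' @export
print.connectivity_profile <- function(x, ...) {
  cat(sprintf("<connectivity_profile> %s (%s basis), %d %s\n", x$index,
              x$basis, length(x$values),
              if (x$basis == "wavelet") "octaves" else "frequency bins"))
  invisible(x)
}

check_spectra <- function(Saa, Sbb, Sab) {
  if (!all(vapply(list(Saa, Sbb, Sab), inherits, logical(1),
                  "wavelet_spectrum"))) {
    stop("arguments must be wavelet_spectrum objects")
  }
  if (length(unique(c(Saa$J, Sbb$J, Sab$J))) != 1L) {
    stop("spectra must share the same octave support")
  }
}

#' Wavelet coherence
#'
#' Complex-valued per-octave coherence
#' \deqn{\mathrm{W\mbox{-}COH}(j) = S_{ab}(j) / \sqrt{S_{aa}(j) S_{bb}(j)},}
#' with modulus at most 1. Octaves with a vanishing auto-spectrum are
#' flagged undefined and excluded from band averages. Sensitive to
#' instantaneous (zero-lag) correlation, hence to volume conduction.
#'
#' @param Saa,Sbb Auto-spectra ([wavelet_cross_spectrum()] of a channel with
#'   itself).
#' @param Sab Cross-spectrum of the pair.
#' @return A `connectivity_profile` with complex per-octave values.
#' @export
w_coh <- function(Saa, Sbb, Sab) {
  check_spectra(Saa, Sbb, Sab)
  den <- sqrt(Re(Saa$S) * Re(Sbb$S))
  flagged <- Saa$flagged | Sbb$flagged | Sab$flagged |
    !is.finite(den) | den == 0
  vals <- Sab$S / den
  vals[flagged] <- NA_complex_
  new_profile("COH", "wavelet", vals, flagged, octaves = seq_len(Sab$J))
}

#' Wavelet imaginary coherence
#'
#' Imaginary part of the normalized wavelet cross-spectrum,
#' \deqn{\mathrm{W\mbox{-}ICOH}(j) = \Im\{S_{ab}(j)\} /
#'   \sqrt{S_{aa}(j) S_{bb}(j)}.}
#' Vanishes (in expectation) for correlated but non-delayed signals, making
#' it robust to volume conduction; antisymmetric under channel swap. With
#' the conjugation convention `S_ab = <d_a conj(d_b)>`, a positive value
#' means channel `b` lags channel `a`.
#'
#' @inheritParams w_coh
#' @return A `connectivity_profile` with real per-octave values in
#'   \[-1, 1\].
#' @export
w_icoh <- function(Saa, Sbb, Sab) {
  p <- w_coh(Saa, Sbb, Sab)
  new_profile("ICOH", "wavelet", Im(p$values), p$flagged,
              octaves = p$octaves)
}

#' Wavelet weighted phase lag index
#'
#' Per-octave ratio of the signed to the absolute imaginary coefficient
#' products,
#' \deqn{\mathrm{W\mbox{-}wPLI}(j) = \frac{\sum_k \Im\{d_a d_b^*\}}
#'   {\sum_k |\Im\{d_a d_b^*\}|} \in [-1, 1].}
#' Needs the raw per-coefficient products, not averaged spectra. A zero
#' denominator (e.g. a channel with itself) is defined as 0 and flagged.
#' Sign flips under argument swap.
#'
#' @param a,b [dtcwt_forward()] outputs, as in [wavelet_cross_spectrum()].
#' @return A `connectivity_profile` with real per-octave values.
#' @export
w_wpli <- function(a, b) {
  if (a$J != b$J || a$n != b$n) stop("mismatched decompositions")
  if (a$filter_set != b$filter_set) stop("mismatched filter sets")
  J <- a$J
  vals <- numeric(J)
  flagged <- logical(J)
  for (j in seq_len(J)) {
    keep <- !(a$boundary[[j]] | b$boundary[[j]])
    im <- Im(a$d[[j]][keep] * Conj(b$d[[j]][keep]))
    den <- sum(abs(im))
    if (length(im) == 0L || den == 0) {
      vals[j] <- 0
      flagged[j] <- TRUE
    } else {
      vals[j] <- sum(im) / den
    }
  }
  new_profile("wPLI", "wavelet", vals, flagged, octaves = seq_len(J))
}

#' Octave band for averaging connectivity indices
#'
#' The contiguous octave range `j1..j2` over which scale-free behavior is
#' observed, together with the sampling rate and the mother-wavelet center
#' frequency needed to map octaves to frequencies.
#'
#' @param j1,j2 Octave range, `1 <= j1 <= j2`.
#' @param fs Sampling rate in Hz.
#' @param f0 Center frequency in cycles/sample (see
#'   [wavelet_center_frequency()]).
#' @return An object of class `scale_band`.
#' @export
scale_band <- function(j1, j2, fs = 1, f0 = wavelet_center_frequency()) {
  j1 <- as.integer(j1); j2 <- as.integer(j2)
  if (j1 < 1L || j2 < j1) stop("need 1 <= j1 <= j2")
  if (f0 <= 0 || f0 >= 1) stop("`f0` must lie in (0, 1) cycles/sample")
  structure(list(j1 = j1, j2 = j2, fs = fs, f0 = f0), class = "scale_band")
}

#' Band-averaged connectivity index
#'
#' The scalar functional-connectivity measure: the mean of the *absolute*
#' index values over the unflagged octaves in `band` (for wavelet profiles),
#' or over the frequency bins falling in the band's frequency range
#' `[f(j2), f(j1)]` (for Fourier profiles). Always in \[0, 1\].
#'
#' @param p A `connectivity_profile`.
#' @param band A [scale_band()].
#' @return Scalar band average.
#' @export
band_average <- function(p, band) {
  if (!inherits(p, "connectivity_profile")) {
    stop("`p` must be a connectivity_profile")
  }
  if (!inherits(band, "scale_band")) stop("`band` must be a scale_band")
  if (!is.null(p$octaves)) {
    if (band$j2 > max(p$octaves)) {
      stop("band extends beyond the profile's octave support")
    }
    sel <- p$octaves >= band$j1 & p$octaves <= band$j2 & !p$flagged
    if (!any(sel)) stop("no unflagged octaves left in the band")
    mean(Mod(p$values[sel]))
  } else {
    flo <- scale_to_frequency(band$j2, band$fs, band$f0)
    fhi <- scale_to_frequency(band$j1, band$fs, band$f0)
    sel <- p$freq >= flo & p$freq <= fhi & !p$flagged
    if (!any(sel)) stop("no unflagged frequency bins in the band")
    mean(Mod(p$values[sel]))
  }
}

#' Wavelet-domain Hurst exponent estimate
#'
#' Weighted least-squares fit of `log2 S(j)` against octave `j` over the
#' band, with weights `n_j` (the per-octave coefficient counts). The slope
#' `zeta` maps to the selfsimilarity exponent according to the declared
#' signal class: `H = (zeta + 1) / 2` for fGn (stationary noise),
#' `H = (zeta - 1) / 2` for fBm (integrated noise).
#'
#' @param Sdiag Auto-spectrum (`wavelet_cross_spectrum(a, a)`).
#' @param band A [scale_band()] with at least 3 octaves.
#' @param signal_class `"fGn"` or `"fBm"`.
#' @return An object of class `hurst_estimate` with fields `H`, `zeta`,
#'   `se` (standard error of `H` from the fit), `band`, `signal_class`.
#' @export
estimate_hurst <- function(Sdiag, band, signal_class = c("fGn", "fBm")) {
  signal_class <- match.arg(signal_class)
  if (!inherits(Sdiag, "wavelet_spectrum")) {
    stop("`Sdiag` must be a wavelet_spectrum")
  }
  j <- band$j1:band$j2
  if (length(j) < 3L) stop("need at least 3 octaves in the band")
  if (band$j2 > Sdiag$J) stop("band extends beyond the spectrum support")
  S <- Re(Sdiag$S[j])
  keep <- !Sdiag$flagged[j]
  j <- j[keep]; S <- S[keep]; w <- Sdiag$nj_used[j]
  if (length(j) < 3L) stop("need at least 3 unflagged octaves in the band")
  if (any(S <= 0)) stop("nonpositive spectrum value in the band")
  fit <- stats::lm(log2(S) ~ j, weights = w)
  zeta <- unname(stats::coef(fit)[2])
  se_zeta <- sqrt(stats::vcov(fit)[2, 2])
  H <- if (signal_class == "fGn") (zeta + 1) / 2 else (zeta - 1) / 2
  structure(
    list(H = H, zeta = zeta, se = se_zeta / 2, band = band,
         signal_class = signal_class, octaves_used = j),
    class = "hurst_estimate"
  )
}

#' @export
print.hurst_estimate <- function(x, ...) {
  cat(sprintf("<hurst_estimate> H = %.3f (se %.3f), slope zeta = %.3f, class %s, octaves %d..%d\n",
              x$H, x$se, x$zeta, x$signal_class, min(x$octaves_used),
              max(x$octaves_used)))
  invisible(x)
}
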