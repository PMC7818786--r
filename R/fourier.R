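# Welch (windowed Fourier) cross-spectral estimation and the Fourier
# connectivity indices.

#' Windowed Fourier (short-time) coefficients
#'
#' Frames the series with a sliding window (Hanning by default), applies the
#' window and an FFT to each frame, and returns the one-sided coefficient
#' matrix `g(l, k)` (frequency bin by frame). This is the estimator behind
#' the Welch cross-periodogram.
#'
#' The continuous Gabor-frame density condition `T0 * nu0 <= 1 / (4 pi)`
#' (hop `T0` seconds, modulation step `nu0` Hz) can be checked for
#' explicitly supplied lattice parameters via `T0` and `nu0`; the DFT grid
#' used here is complete per frame and is not subject to it.
#'
#' @param x Real numeric vector.
#' @param fs Sampling rate in Hz.
#' @param window_length Window length in samples (at most `length(x)`).
#' @param hop Frame advance in samples; default 50% overlap.
#' @param shape Window shape, only `"hanning"`.
#' @param T0,nu0 Optional explicit Gabor lattice parameters to validate.
#' @param demean Subtract the global series mean before framing (off by
#'   default: slow trends and drifts are deliberately left in).
#' @return An object of class `fourier_frames`: complex matrix `g` (bins x
#'   frames), `freq` in Hz, window metadata.
#' @export
fourier_frames <- function(x, fs, window_length, hop = window_length %/% 2,
                           shape = "hanning", T0 = NULL, nu0 = NULL,
                           demean = FALSE) {
  shape <- match.arg(shape, "hanning")
  n <- length(x)
  if (window_length > n) stop("`window_length` exceeds the series length")
  if (hop < 1L) stop("`hop` must be at least 1 sample")
  if (!is.null(T0) && !is.null(nu0) && T0 * nu0 > 1 / (4 * pi)) {
    stop("frame parameters violate the density condition T0 * nu0 <= 1/(4 pi): T0 * nu0 = ",
         format(T0 * nu0))
  }
  if (demean) x <- x - mean(x)
  w <- hanning_window(window_length)
  starts <- seq(1L, n - window_length + 1L, by = hop)
  frames <- vapply(starts, function(s) {
    x[s:(s + window_length - 1L)] * w
  }, numeric(window_length))
  G <- stats::mvfft(frames)
  nb <- window_length %/% 2 + 1L
  G <- G[seq_len(nb), , drop = FALSE]
  freq <- (seq_len(nb) - 1) / window_length * fs
  structure(
    list(g = G, freq = freq, fs = fs,
         window = list(shape = shape, length = window_length, hop = hop,
                       energy = sum(w^2))),
    class = "fourier_frames"
  )
}

hanning_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

#' @export
print.fourier_frames <- function(x, ...) {
  cat(sprintf("<fourier_frames> %d bins x %d frames (%s window, length %d, hop %d) @ %g Hz\n",
              nrow(x$g), ncol(x$g), x$window$shape, x$window$length,
              x$window$hop, x$fs))
  invisible(x)
}

#' Fourier connectivity indices from windowed coefficients
#'
#' Welch cross-spectrum `S(l) = (1/K) sum_k g_a(l,k) conj(g_b(l,k))` and the
#' three per-frequency indices: coherence (complex), imaginary coherence,
#' and the weighted phase lag index (computed from the per-frame imaginary
#' parts, zero-denominator bins defined as 0 and flagged). Bins with a
#' vanishing auto-spectrum are flagged.
#'
#' @param fa,fb [fourier_frames()] objects with identical framing.
#' @return Named list of three `connectivity_profile` objects: `coh`,
#'   `icoh`, `wpli`.
#' @export
fourier_indices <- function(fa, fb) {
  if (!inherits(fa, "fourier_frames") || !inherits(fb, "fourier_frames")) {
    stop("inputs must be fourier_frames objects")
  }
  if (!identical(dim(fa$g), dim(fb$g)) ||
      !isTRUE(all.equal(fa$freq, fb$freq))) {
    stop("frames must share the same framing (window, hop, length)")
  }
  cross <- fa$g * Conj(fb$g)
  Sab <- rowMeans(cross)
  Saa <- rowMeans(Mod(fa$g)^2)
  Sbb <- rowMeans(Mod(fb$g)^2)
  den <- sqrt(Saa * Sbb)
  flag_auto <- den == 0 | !is.finite(den)
  coh <- Sab / den
  coh[flag_auto] <- NA_complex_
  im <- Im(cross)
  wden <- rowSums(abs(im))
  flag_w <- wden == 0
  wpli <- ifelse(flag_w, 0, rowSums(im) / pmax(wden, .Machine$double.xmin))
  list(
    coh = new_profile("COH", "fourier", coh, flag_auto, freq = fa$freq),
    icoh = new_profile("ICOH", "fourier", Im(coh), flag_auto,
                       freq = fa$freq),
    wpli = new_profile("wPLI", "fourier", wpli, flag_w, freq = fa$freq)
  )
}

#' Octave-matched Fourier connectivity profile
#'
#' Fourier counterpart of the per-octave wavelet indices: for each octave
#' `j` the Welch estimate is computed with a Hanning window of length
#' `2^(j+2)` samples (50% overlap), matching the bandwidth of the wavelet
#' filters at that octave, and the index is averaged (in absolute value)
#' over the bins falling inside the octave's frequency band
#' `[f0 fs / 2^(j+1), f0 fs / 2^j]`.
#'
#' @param x1,x2 Real numeric vectors (same length).
#' @param fs Sampling rate in Hz.
#' @param octaves Integer vector of octaves to compute.
#' @param f0 Mother-wavelet center frequency (for the band edges).
#' @return Named list of `connectivity_profile` objects (`coh`, `icoh`,
#'   `wpli`) with one value per requested octave, `basis = "fourier"` and
#'   the octave vector attached.
#' @export
fourier_octave_indices <- function(x1, x2, fs = 1, octaves,
                                   f0 = wavelet_center_frequency()) {
  n <- length(x1)
  if (length(x2) != n) stop("`x1` and `x2` must have the same length")
  vals <- matrix(NA_real_, nrow = length(octaves), ncol = 3,
                 dimnames = list(NULL, c("coh", "icoh", "wpli")))
  flagged <- matrix(FALSE, nrow = length(octaves), ncol = 3,
                    dimnames = list(NULL, c("coh", "icoh", "wpli")))
  for (i in seq_along(octaves)) {
    j <- octaves[i]
    W <- 2^(j + 2)
    if (W > n) {
      flagged[i, ] <- TRUE
      next
    }
    fa <- fourier_frames(x1, fs, W)
    fb <- fourier_frames(x2, fs, W)
    idx <- fourier_indices(fa, fb)
    flo <- f0 * fs / 2^(j + 1)
    fhi <- f0 * fs / 2^j
    for (k in c("coh", "icoh", "wpli")) {
      p <- idx[[k]]
      sel <- p$freq >= flo & p$freq <= fhi & !p$flagged
      if (!any(sel)) {
        flagged[i, k] <- TRUE
      } else {
        # average of signed values for icoh/wpli, modulus for coh, so the
        # per-octave Fourier profile mirrors the wavelet one
        vals[i, k] <- if (k == "coh") mean(Mod(p$values[sel])) else
          mean(Re(p$values[sel]))
      }
    }
  }
  kinds <- c(coh = "COH", icoh = "ICOH", wpli = "wPLI")
  out <- lapply(names(kinds), function(k) {
    new_profile(kinds[[k]], "fourier-octave", vals[, k], flagged[, k],
                octaves = octaves)
  })
  names(out) <- names(kinds)
  out
}
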