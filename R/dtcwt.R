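# Forward dual-tree complex wavelet transform (1-D, analysis only).

# full linear convolution via the C loop in stats::filter (direct O(n L),
# cheaper than FFT convolution at these filter lengths)
conv_full <- function(x, h) {
  L <- length(h)
  if (L == 1L) return(x * h)
  xp <- c(rep(0, L - 1), x, rep(0, L - 1))
  y <- stats::filter(xp, h, method = "convolution", sides = 1)
  as.numeric(y[L:length(xp)])
}

# one analysis stage: symmetric extension, filter, decimate by two.
# Output index k is aligned with input sample 2k + offset; the one-sample
# `offset` realizes the level-1 one-sample delay of tree B (offset -1). Both trees must
# be given the same (E, c0) alignment so that only the filters and the
# offset carry their relative delay.
analysis_stage <- function(x, h, E, c0, offset = 0L) {
  n <- length(x)
  xe <- c(x[E:1], x, x[n:(n - E + 1)])
  yf <- conv_full(xe, h)
  idx <- seq(2 + E + c0 + offset, by = 2, length.out = n %/% 2)
  yf[idx]
}

#' Forward dual-tree complex wavelet transform
#'
#' Decomposes a real series into per-octave complex detail coefficients
#' `d(j, k)`: the real part comes from one real discrete wavelet transform
#' (tree A), the imaginary part from a second one whose filters are offset so
#' that the two real wavelets form an approximate Hilbert pair. Octave
#' `j = 1` is the finest scale (highest frequency); coefficient counts halve
#' per octave. Boundary handling is symmetric extension, and coefficients
#' whose support overlaps a boundary are flagged so that spectral averages
#' can exclude them.
#'
#' If `length(x)` is not a multiple of `2^J` the series is truncated to the
#' largest feasible length with a warning (zero padding would inject
#' trend-like artifacts).
#'
#' @param x Real numeric vector.
#' @param J Number of octaves; defaults to the maximum feasible for the
#'   filter length, `floor(log2(n / Lq))`.
#' @param filter_bank Filter bank from [dtcwt_filter_bank()].
#' @return An object of class `dtcwt_coeffs`: a list with `d` (complex
#'   coefficient vectors per octave), `boundary` (logical flags per octave),
#'   `nj`, `J`, `n`, and `filter_set`.
#' @export
dtcwt_forward <- function(x, J = NULL, filter_bank = dtcwt_filter_bank()) {
  if (!is.numeric(x)) stop("`x` must be a numeric vector")
  if (!all(is.finite(x))) stop("`x` must be finite")
  n_in <- length(x)
  fb <- filter_bank
  J_max <- floor(log2(n_in / fb$Lq))
  if (is.null(J)) J <- J_max
  J <- as.integer(J)
  if (J < 1L) stop("`J` must be at least 1")
  if (J > J_max) {
    stop(sprintf("J = %d is too large for n = %d with this filter bank; the maximum feasible J is %d",
                 J, n_in, J_max))
  }
  n <- (n_in %/% 2^J) * 2^J
  if (n < n_in) {
    warning(sprintf("series length %d truncated to %d (largest multiple of 2^%d)",
                    n_in, n, J))
    x <- x[seq_len(n)]
  }
  d <- vector("list", J)
  boundary <- vector("list", J)
  aA <- x
  aB <- x
  support <- 1
  for (j in seq_len(J)) {
    if (j == 1L) {
      E <- fb$L1
      c0 <- floor((fb$L1 - 1) / 2)
      dA <- analysis_stage(aA, fb$h1a1, E, c0, 0L)
      dB <- analysis_stage(aB, fb$h1a1, E, c0, -1L)
      aA0 <- analysis_stage(aA, fb$h0a1, E, c0, 0L)
      aB <- analysis_stage(aB, fb$h0a1, E, c0, -1L)
      aA <- aA0
      support <- support + (fb$L1 - 1)
    } else {
      E <- fb$Lq
      c0 <- floor((fb$Lq - 1) / 2)
      dA <- analysis_stage(aA, fb$h1a, E, c0)
      dB <- analysis_stage(aB, fb$h1b, E, c0)
      aA <- analysis_stage(aA, fb$h0a, E, c0)
      aB <- analysis_stage(aB, fb$h0b, E, c0)
      support <- support + (fb$Lq - 1) * 2^(j - 1)
    }
    d[[j]] <- complex(real = dA, imaginary = fb$sign * dB)
    nj <- length(dA)
    nb <- min(nj, ceiling(support / 2 / 2^j))
    flags <- rep(FALSE, nj)
    if (nb > 0) flags[c(seq_len(nb), nj - seq_len(nb) + 1L)] <- TRUE
    boundary[[j]] <- flags
  }
  structure(
    list(d = d, boundary = boundary,
         nj = vapply(d, length, integer(1)),
         J = J, n = n, filter_set = fb$name),
    class = "dtcwt_coeffs"
  )
}

#' @export
print.dtcwt_coeffs <- function(x, ...) {
  cat(sprintf("<dtcwt_coeffs> n=%d, J=%d octaves, filters: %s\n",
              x$n, x$J, x$filter_set))
  cat("  coefficients per octave:", paste(x$nj, collapse = ", "), "\n")
  invisible(x)
}

#' Map a dyadic scale (octave) to frequency
#'
#' Scales `a = 2^j` are converted to frequencies as
#' `f = f0 * fs / 2^j`, where `f0` is the center frequency of the mother
#' wavelet in cycles/sample. The frequency halves exactly when `j`
#' increments.
#'
#' @param j Octave index (vectorised), `j >= 1`.
#' @param fs Sampling rate in Hz.
#' @param f0 Mother-wavelet center frequency in cycles/sample; by default
#'   measured once from the implemented filter bank
#'   ([wavelet_center_frequency()]).
#' @return Frequency (or frequencies) in Hz.
#' @examples
#' scale_to_frequency(8, fs = 448)
#' @export
scale_to_frequency <- function(j, fs, f0 = wavelet_center_frequency()) {
  if (any(j < 1)) stop("octave index `j` must be >= 1")
  f0 * fs / 2^j
}

#' Center frequency of the implemented complex mother wavelet
#'
#' Measured (once, then cached) from the filter bank as the spectral peak of
#' the level-5 effective complex wavelet, rescaled to cycles/sample at unit
#' scale: if the level-5 response peaks at `p` cycles/sample then
#' `f0 = p * 2^5`. The value depends only on the filter choice and is not
#' hard-coded.
#'
#' @param filter_bank Filter bank from [dtcwt_filter_bank()].
#' @param level Pyramid level at which the peak is measured.
#' @return Center frequency `f0` in cycles/sample, in (0, 1).
#' @export
wavelet_center_frequency <- function(filter_bank = dtcwt_filter_bank(),
                                     level = 5L) {
  key <- sprintf("f0_%s_%d", filter_bank$name, level)
  if (!is.null(.fc_cache[[key]])) return(.fc_cache[[key]])
  resp <- wavelet_band_response(level, filter_bank = filter_bank)
  f0 <- resp$f[which.max(resp$power)] * 2^level
  .fc_cache[[key]] <- f0
  f0
}

#' Squared frequency response of a wavelet octave band
#'
#' Magnitude-squared Fourier transform of the effective complex wavelet
#' filter of octave `j`, on a dense grid of signed frequencies in
#' (-1/2, 1/2\] cycles/sample. This is the weight `|psi~(2^j f)|^2` that the
#' wavelet spectrum applies to the true spectral density.
#'
#' @param j Octave.
#' @param nfft Grid size (power of two).
#' @param filter_bank Filter bank from [dtcwt_filter_bank()].
#' @return A list with `f` (frequencies in cycles/sample) and `power`
#'   (squared modulus response, normalized to unit sum times grid step).
#' @export
wavelet_band_response <- function(j, nfft = 2^15,
                                  filter_bank = dtcwt_filter_bank()) {
  fb <- filter_bank
  eff <- effective_complex_wavelet(fb, j)
  psi <- eff$fA + 1i * fb$sign * eff$fB
  if (length(psi) > nfft) nfft <- 2^ceiling(log2(length(psi)))
  spec <- Mod(stats::fft(c(psi, rep(0 + 0i, nfft - length(psi)))))^2
  f <- seq(0, nfft - 1) / nfft
  f[f >= 0.5] <- f[f >= 0.5] - 1
  ord <- order(f)
  list(f = f[ord], power = spec[ord] / 2^j)
}
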