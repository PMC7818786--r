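#' Specification of one synthetic bivariate scale-free scenario
#'
#' Describes a pair of coupled scale-free signals: each component is either
#' fractional Gaussian noise (`"fGn"`, stationary) or fractional Brownian
#' motion (`"fBm"`, the running sum of fGn increments), the underlying fGn
#' pair has pointwise correlation `rho`, and the second component is delayed
#' by `delta` samples. An optional additive trend and the random seed complete
#' the description.
#'
#' @param kind1,kind2 `"fGn"` or `"fBm"` for each component.
#' @param H1,H2 Hurst exponents in (0, 1).
#' @param rho Pointwise correlation of the underlying fGn pair, in \[-1, 1\].
#' @param delta Non-negative integer delay of component 2, in samples.
#' @param n Number of samples (at least 64).
#' @param fs Sampling rate in Hz attached to the synthesized series.
#' @param trend Optional [trend_spec()] added to both channels after
#'   synthesis.
#' @param seed Optional integer seed; when set, synthesis is reproducible.
#' @return An object of class `bivariate_fractal_spec`.
#' @seealso [synthesize_bivariate()]
#' @export
bivariate_fractal_spec <- function(kind1 = "fGn", kind2 = "fGn",
                                   H1 = 0.7, H2 = 0.8, rho = 0, delta = 0L,
                                   n = 2^14, fs = 1, trend = NULL,
                                   seed = NULL) {
  kind1 <- match.arg(kind1, c("fGn", "fBm"))
  kind2 <- match.arg(kind2, c("fGn", "fBm"))
  check_hurst(H1)
  check_hurst(H2)
  if (!is.numeric(rho) || length(rho) != 1L || abs(rho) > 1) {
    stop("`rho` must be a single value in [-1, 1]")
  }
  delta <- as.integer(delta)
  if (is.na(delta) || delta < 0L) stop("`delta` must be a non-negative integer")
  n <- as.integer(n)
  if (is.na(n) || n < 64L) stop("`n` must be an integer >= 64 (2^6)")
  if (!is.null(trend) && !inherits(trend, "trend_spec")) {
    stop("`trend` must be NULL or a trend_spec object")
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(kind1 = kind1, kind2 = kind2, H1 = H1, H2 = H2, rho = rho,
         delta = delta, n = n, fs = fs, trend = trend, seed = seed),
    class = "bivariate_fractal_spec"
  )
}

#' @export
print.bivariate_fractal_spec <- function(x, ...) {
  cat(sprintf(
    "<bivariate_fractal_spec> %s(H=%.3g) / %s(H=%.3g), rho=%.3g, delta=%d, n=%d\n",
    x$kind1, x$H1, x$kind2, x$H2, x$rho, x$delta, x$n))
  if (!is.null(x$trend)) cat("  + trend:", x$trend$trend_kind, "\n")
  invisible(x)
}

#' Additive trend specification
#'
#' Slow deterministic or stochastic contaminants added on top of scale-free
#' components: a random polynomial, a sinusoid with random phase, or an
#' independent smooth fBm path. The trend is rescaled per channel so that its
#' standard deviation equals `amplitude` times the channel's standard
#' deviation.
#'
#' @param trend_kind `"polynomial"`, `"sinusoid"` or `"fbm"`.
#' @param amplitude Non-negative trend amplitude in units of the channel
#'   standard deviation.
#' @param order Polynomial order (1--3), for `"polynomial"`.
#' @param period Period in samples, for `"sinusoid"`.
#' @param hurst Hurst exponent in (0, 1), for `"fbm"` trends (small values
#'   give very smooth, slowly wandering paths).
#' @param seed Optional integer seed for the trend's own randomness.
#' @return An object of class `trend_spec`.
#' @export
trend_spec <- function(trend_kind = c("polynomial", "sinusoid", "fbm"),
                       amplitude = 1, order = 2L, period = NULL,
                       hurst = 0.2, seed = NULL) {
  trend_kind <- match.arg(trend_kind)
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0) {
    stop("`amplitude` must be a single non-negative value")
  }
  order <- as.integer(order)
  if (trend_kind == "polynomial" && (order < 1L || order > 3L)) {
    stop("polynomial trend order must be between 1 and 3")
  }
  if (trend_kind == "fbm") check_hurst(hurst)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(trend_kind = trend_kind, amplitude = amplitude, order = order,
         period = period, hurst = hurst, seed = seed),
    class = "trend_spec"
  )
}

# ---- circulant embedding of the joint bivariate fGn law -------------------

# Precompute the per-frequency matrix square roots of the circulant embedding
# of the joint covariance of a correlated fGn pair. The embedding is exact:
# if any spectral 2x2 matrix fails positive semidefiniteness beyond numerical
# tolerance, synthesis is refused rather than approximated.
bfgn_embedding <- function(H1, H2, rho, n) {
  m <- 2^ceiling(log2(2 * n))
  lag <- c(0:(m / 2), (m / 2 - 1):1)
  g11 <- Re(stats::fft(fgn_covariance(H1, lag)))
  g22 <- Re(stats::fft(fgn_covariance(H2, lag)))
  g12 <- Re(stats::fft(bfgn_cross_covariance(H1, H2, rho, lag)))
  tol <- 1e-9 * max(g11, g22)
  lam_min <- (g11 + g22) / 2 - sqrt(((g11 - g22) / 2)^2 + g12^2)
  if (min(g11) < -tol || min(g22) < -tol || min(lam_min) < -tol) {
    stop(sprintf(
      "circulant embedding of the joint fGn covariance is not positive semidefinite for (H1=%g, H2=%g, rho=%g)",
      H1, H2, rho))
  }
  g11 <- pmax(g11, 0)
  g22 <- pmax(g22, 0)
  det <- pmax(g11 * g22 - g12^2, 0)
  tr <- g11 + g22
  # sqrt of a 2x2 PSD matrix A: (A + sqrt(det) I) / sqrt(tr + 2 sqrt(det))
  sq <- sqrt(det)
  den <- sqrt(tr + 2 * sq)
  den[den == 0] <- 1
  scale <- 1 / (den * sqrt(m))
  list(m = m, n = n,
       b11 = (g11 + sq) * scale,
       b22 = (g22 + sq) * scale,
       b12 = g12 * scale)
}

# Draw one exact realization (2 x n matrix) of the correlated fGn pair from a
# precomputed embedding. Consumes 4*m standard normals.
bfgn_draw <- function(emb) {
  m <- emb$m
  z1 <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  z2 <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  y <- cbind(emb$b11 * z1 + emb$b12 * z2,
             emb$b12 * z1 + emb$b22 * z2)
  x <- Re(stats::mvfft(y))
  t(x[seq_len(emb$n), , drop = FALSE])
}

#' Synthesize correlated, delayed bivariate fGn/fBm
#'
#' Exact synthesis by circulant embedding of the joint covariance of the
#' correlated fGn pair. Correlation is imposed instantaneously (the lag-zero
#' correlation of the underlying fGn components equals `rho`), then the
#' second component is delayed by `delta` samples: `n + delta` samples are
#' synthesized, component 2 is shifted, and both are cropped to `n`.
#' Components declared `"fBm"` are cumulative sums of their (already delayed)
#' fGn increments; the trend, if any, is added last.
#'
#' @param spec A [bivariate_fractal_spec()].
#' @return A [time_series_set()] with 2 channels and `spec$n` samples; the
#'   spec is attached as provenance.
#' @examples
#' spec <- bivariate_fractal_spec(H1 = 0.7, H2 = 0.8, rho = 0.6, n = 256,
#'                                seed = 1)
#' ts <- synthesize_bivariate(spec)
#' cor(ts$data[1, ], ts$data[2, ])
#' @export
synthesize_bivariate <- function(spec) {
  if (!inherits(spec, "bivariate_fractal_spec")) {
    stop("`spec` must be a bivariate_fractal_spec")
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  emb <- bfgn_embedding(spec$H1, spec$H2, spec$rho, spec$n + spec$delta)
  x <- synthesize_from_embedding(spec, emb)
  if (!is.null(spec$trend)) x <- add_trend(x, spec$trend)
  x
}

# Core synthesis given a precomputed embedding; used by the Monte-Carlo
# harness to amortize the embedding across realizations.
synthesize_from_embedding <- function(spec, emb) {
  n <- spec$n
  d <- spec$delta
  z <- bfgn_draw(emb)
  x1 <- z[1, (d + 1):(d + n)]
  x2 <- z[2, 1:n]
  if (spec$kind1 == "fBm") x1 <- cumsum(x1)
  if (spec$kind2 == "fBm") x2 <- cumsum(x2)
  time_series_set(rbind(x1, x2), fs = spec$fs,
                  labels = c("x1", "x2"), provenance = spec)
}

# ---- trends ---------------------------------------------------------------

generate_trend <- function(trend, n) {
  t01 <- seq(-1, 1, length.out = n)
  switch(trend$trend_kind,
    polynomial = {
      coefs <- stats::rnorm(trend$order)
      drop(outer(t01, seq_len(trend$order), `^`) %*% coefs)
    },
    sinusoid = {
      period <- if (is.null(trend$period)) n / 2 else trend$period
      phase <- stats::runif(1, 0, 2 * pi)
      sin(2 * pi * seq_len(n) / period + phase)
    },
    fbm = {
      emb <- bfgn_embedding(trend$hurst, trend$hurst, 0, n)
      cumsum(bfgn_draw(emb)[1, ])
    },
    stop("unknown trend_kind: ", trend$trend_kind)
  )
}

#' Add an independent slow trend to each channel
#'
#' Each channel receives an independently generated trend of the requested
#' kind, rescaled so that the trend standard deviation equals
#' `trend$amplitude` times the channel standard deviation. The input object
#' is not modified.
#'
#' @param ts A [time_series_set()].
#' @param trend A [trend_spec()].
#' @return A new `time_series_set` with the trends added.
#' @export
add_trend <- function(ts, trend) {
  if (!inherits(ts, "time_series_set")) stop("`ts` must be a time_series_set")
  if (!inherits(trend, "trend_spec")) stop("`trend` must be a trend_spec")
  if (trend$amplitude == 0) return(ts)
  if (!is.null(trend$seed)) set.seed(trend$seed)
  n <- n_samples(ts)
  out <- ts$data
  for (ch in seq_len(nrow(out))) {
    tr <- generate_trend(trend, n)
    s <- stats::sd(tr)
    if (s == 0) next
    tr <- tr / s * trend$amplitude * stats::sd(out[ch, ])
    out[ch, ] <- out[ch, ] + tr
  }
  time_series_set(out, fs = ts$fs, labels = ts$labels,
                  provenance = ts$provenance)
}

# ---- multichannel network datasets ----------------------------------------

#' Generate a multichannel dataset with a planted connectivity structure
#'
#' Channels referenced by an edge are synthesized jointly as an exact
#' correlated, delayed bivariate fGn/fBm pair with the edge's `(rho, delta)`;
#' all remaining channels are mutually independent fGn/fBm. Each channel may
#' participate in at most one edge (disjoint-pair construction; the model has
#' no notion of overlapping joint laws).
#'
#' @param M Number of channels.
#' @param edges List of edges, each a list or vector with elements
#'   `a`, `b` (1-based channel indices), `rho` and `delta`.
#' @param H Per-channel Hurst exponents (recycled if scalar).
#' @param n Samples per channel.
#' @param fs Sampling rate in Hz.
#' @param kind `"fGn"` or `"fBm"` for all channels.
#' @param seed Optional integer seed.
#' @return A [time_series_set()] with `M` channels.
#' @export
generate_network_dataset <- function(M, edges = list(), H = 0.8, n = 2^12,
                                     fs = 1, kind = "fGn", seed = NULL) {
  M <- as.integer(M)
  if (M < 1L) stop("`M` must be at least 1")
  kind <- match.arg(kind, c("fGn", "fBm"))
  H <- rep_len(H, M)
  for (h in H) check_hurst(h)
  if (!is.null(seed)) set.seed(as.integer(seed))
  touched <- integer(0)
  for (e in edges) {
    e <- as.list(e)
    a <- as.integer(e$a); b <- as.integer(e$b)
    if (is.na(a) || is.na(b) || a < 1L || b < 1L || a > M || b > M || a == b) {
      stop("edge must reference two distinct valid channels")
    }
    if (a %in% touched || b %in% touched) {
      stop("overlapping edges: each channel may appear in at most one edge ",
           "(disjoint-pair construction)")
    }
    touched <- c(touched, a, b)
  }
  data <- matrix(0, nrow = M, ncol = n)
  for (e in edges) {
    e <- as.list(e)
    a <- as.integer(e$a); b <- as.integer(e$b)
    spec <- bivariate_fractal_spec(kind1 = kind, kind2 = kind,
                                   H1 = H[a], H2 = H[b],
                                   rho = e$rho, delta = e$delta,
                                   n = n, fs = fs)
    emb <- bfgn_embedding(spec$H1, spec$H2, spec$rho, n + spec$delta)
    pair <- synthesize_from_embedding(spec, emb)
    data[a, ] <- pair$data[1, ]
    data[b, ] <- pair$data[2, ]
  }
  free <- setdiff(seq_len(M), touched)
  for (ch in free) {
    emb <- bfgn_embedding(H[ch], H[ch], 0, n)
    x <- bfgn_draw(emb)[1, ]
    if (kind == "fBm") x <- cumsum(x)
    data[ch, ] <- x
  }
  time_series_set(data, fs = fs,
                  provenance = list(M = M, edges = edges, H = H, kind = kind,
                                    seed = seed))
}
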