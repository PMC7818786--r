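# Shared fixtures: everything is generated in code at test time.

# warm the cached filter bank / center frequency once per session
fb_default <- dtcwt_filter_bank()
f0_default <- wavelet_center_frequency()

# draw one unit-variance fGn path (no delay machinery)
draw_fgn <- function(H, n) {
  emb <- fractalconn:::bfgn_embedding(H, H, 0, n)
  fractalconn:::bfgn_draw(emb)[1, ]
}

# wavelet index profiles for a 2-channel time_series_set
pair_profiles <- function(ts, J) {
  a <- dtcwt_forward(ts$data[1, ], J = J)
  b <- dtcwt_forward(ts$data[2, ], J = J)
  Saa <- wavelet_cross_spectrum(a)
  Sbb <- wavelet_cross_spectrum(b)
  Sab <- wavelet_cross_spectrum(a, b)
  list(coh = w_coh(Saa, Sbb, Sab), icoh = w_icoh(Saa, Sbb, Sab),
       wpli = w_wpli(a, b), a = a, b = b)
}

# sample cross-correlation of x against y at lags -L..L, defined as
# cor(x[t], y[t + lag])
xcorr_lags <- function(x, y, L) {
  n <- length(x)
  vapply(-L:L, function(k) {
    if (k >= 0) stats::cor(x[1:(n - k)], y[(1 + k):n]) else
      stats::cor(x[(1 - k):n], y[1:(n + k)])
  }, numeric(1))
}
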