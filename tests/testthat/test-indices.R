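test_that("self-channel identities and Hermitian symmetry hold exactly", {
  set.seed(41)
  x <- rnorm(1024)
  y <- rnorm(1024)
  a <- dtcwt_forward(x, J = 5)
  b <- dtcwt_forward(y, J = 5)
  Saa <- wavelet_cross_spectrum(a)
  Sbb <- wavelet_cross_spectrum(b)
  Sab <- wavelet_cross_spectrum(a, b)
  Sba <- wavelet_cross_spectrum(b, a)

  # auto-spectra are real and nonnegative
  expect_lt(max(abs(Im(Saa$S))), 1e-12 * max(Mod(Saa$S)))
  expect_true(all(Re(Saa$S) >= 0))
  # swap gives the exact conjugate
  expect_identical(Sab$S, Conj(Sba$S))

  expect_equal(Mod(w_coh(Saa, Saa, Saa)$values), rep(1, 5))
  expect_equal(w_icoh(Saa, Saa, Saa)$values, rep(0, 5))
  wself <- w_wpli(a, a)
  expect_equal(wself$values, rep(0, 5))
  expect_true(all(wself$flagged))

  # antisymmetry under swap; coherence modulus swap-invariant
  expect_equal(w_icoh(Saa, Sbb, Sab)$values,
               -w_icoh(Sbb, Saa, Sba)$values)
  expect_equal(w_wpli(a, b)$values, -w_wpli(b, a)$values)
  expect_equal(Mod(w_coh(Saa, Sbb, Sab)$values),
               Mod(w_coh(Sbb, Saa, Sba)$values))
  # bounds
  expect_true(all(Mod(w_coh(Saa, Sbb, Sab)$values) <= 1 + 1e-10))
  expect_true(all(abs(w_wpli(a, b)$values) <= 1))
})

test_that("spectrum and wPLI match a naive double-loop recomputation", {
  set.seed(42)
  for (n in c(64L, 512L)) {
    a <- dtcwt_forward(rnorm(n))
    b <- dtcwt_forward(rnorm(n))
    Sab <- wavelet_cross_spectrum(a, b)
    wp <- w_wpli(a, b)
    for (j in seq_len(a$J)) {
      keep <- which(!(a$boundary[[j]] | b$boundary[[j]]))
      acc <- 0 + 0i
      num <- den <- 0
      for (k in keep) {
        pr <- a$d[[j]][k] * Conj(b$d[[j]][k])
        acc <- acc + pr
        num <- num + Im(pr)
        den <- den + abs(Im(pr))
      }
      if (length(keep)) {
        expect_lt(Mod(Sab$S[j] - acc / length(keep)), 1e-12 * Mod(Sab$S[j]))
        expect_lt(abs(wp$values[j] - num / den), 1e-12)
      }
    }
  }
})

test_that("mismatched decompositions are rejected", {
  a <- dtcwt_forward(rnorm(512), J = 4)
  b <- dtcwt_forward(rnorm(512), J = 3)
  expect_error(wavelet_cross_spectrum(a, b), "mismatch")
  expect_error(w_wpli(a, b), "mismatch")
})

test_that("band averaging takes the mean of absolute values", {
  p <- fractalconn:::new_profile("ICOH", "wavelet",
                                 c(0.1, -0.2, 0.4, -0.6, 0.3),
                                 flagged = rep(FALSE, 5), octaves = 1:5)
  expect_equal(band_average(p, scale_band(2, 4)), 0.4)
  expect_equal(band_average(fractalconn:::new_profile(
    "ICOH", "wavelet", rep(0, 5), rep(FALSE, 5), octaves = 1:5),
    scale_band(1, 5)), 0)
  # flagged octaves are excluded, never silently included
  p$flagged[3] <- TRUE
  expect_equal(band_average(p, scale_band(2, 4)), 0.4)
  p$flagged[] <- TRUE
  expect_error(band_average(p, scale_band(2, 4)), "unflagged")
  expect_error(band_average(p, scale_band(2, 9)), "support")
})

test_that("delayed correlated pairs produce interior-octave responses", {
  set.seed(43)
  spec <- bivariate_fractal_spec(H1 = 0.7, H2 = 0.8, rho = 0.9, delta = 8,
                                 n = 2^13)
  emb <- fractalconn:::bfgn_embedding(0.7, 0.8, 0.9, 2^13 + 8)
  J <- 8
  icoh <- matrix(0, 50, J)
  for (r in 1:50) {
    ts <- fractalconn:::synthesize_from_embedding(spec, emb)
    icoh[r, ] <- pair_profiles(ts, J)$icoh$values
  }
  m <- abs(colMeans(icoh))
  jstar <- which.max(m)
  expect_gt(jstar, 1)
  expect_lt(jstar, J)

  # doubling the delay moves the response coarser
  spec2 <- bivariate_fractal_spec(H1 = 0.7, H2 = 0.8, rho = 0.9,
                                  delta = 16, n = 2^13)
  emb2 <- fractalconn:::bfgn_embedding(0.7, 0.8, 0.9, 2^13 + 16)
  icoh2 <- matrix(0, 50, J)
  for (r in 1:50) {
    ts <- fractalconn:::synthesize_from_embedding(spec2, emb2)
    icoh2[r, ] <- pair_profiles(ts, J)$icoh$values
  }
  expect_gt(which.max(abs(colMeans(icoh2))), jstar)
})

test_that("the Hurst estimator recovers known exponents", {
  set.seed(44)
  # white noise: flat spectrum, H = 0.5
  a <- dtcwt_forward(rnorm(2^14), J = 9)
  h <- estimate_hurst(wavelet_cross_spectrum(a), scale_band(2, 9), "fGn")
  expect_lt(abs(h$H - 0.5), 0.05)
  expect_gt(h$se, 0)

  # fBm analyzed in the fBm class: slope ~ 2H + 1
  hs <- replicate(25, {
    x <- integrate_to_fbm(draw_fgn(0.7, 2^13))
    a <- dtcwt_forward(x, J = 8)
    est <- estimate_hurst(wavelet_cross_spectrum(a), scale_band(3, 8),
                          "fBm")
    c(est$H, est$zeta)
  })
  expect_lt(abs(mean(hs[1, ]) - 0.7), 0.05)
  expect_lt(abs(mean(hs[2, ]) - 2.4), 0.1)

  expect_error(estimate_hurst(wavelet_cross_spectrum(a),
                              scale_band(3, 4), "fGn"), "3 octaves")
})
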