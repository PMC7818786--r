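test_that("spec constructors validate their inputs", {
  expect_s3_class(bivariate_fractal_spec(), "bivariate_fractal_spec")
  expect_error(bivariate_fractal_spec(H1 = 1.1), "Hurst")
  expect_error(bivariate_fractal_spec(rho = 2), "rho")
  expect_error(bivariate_fractal_spec(delta = -1), "delta")
  expect_error(bivariate_fractal_spec(n = 32), "64")
  expect_error(trend_spec("polynomial", order = 5), "order")
  expect_error(trend_spec("fbm", hurst = 1.5), "Hurst")
  expect_error(trend_spec("polynomial", amplitude = -1), "amplitude")
})

test_that("synthesized fGn reproduces the model autocovariance", {
  set.seed(11)
  H <- 0.7
  n <- 2^11
  reps <- 300
  lags <- 0:16
  acc <- matrix(0, reps, length(lags))
  for (r in seq_len(reps)) {
    x <- draw_fgn(H, n)
    acc[r, ] <- vapply(lags, function(k) {
      mean(x[1:(n - k)] * x[(1 + k):n])
    }, numeric(1))
  }
  emp <- colMeans(acc)
  se <- apply(acc, 2, sd) / sqrt(reps)
  expect_true(all(abs(emp - fgn_covariance(H, lags)) < 3 * se + 1e-12))
})

test_that("lag-zero correlation of the pair equals rho before delaying", {
  # uncentered cross-moment: the process is zero-mean by construction, and
  # the Pearson statistic carries a small-sample bias under long memory
  set.seed(12)
  for (rho in c(0, 0.3, 0.9)) {
    emb <- fractalconn:::bfgn_embedding(0.7, 0.8, rho, 2^11)
    cc <- replicate(150, {
      z <- fractalconn:::bfgn_draw(emb)
      mean(z[1, ] * z[2, ])
    })
    expect_lt(abs(mean(cc) - rho), 3 * sd(cc) / sqrt(length(cc)) + 1e-12)
  }
})

test_that("the delayed component peaks the cross-correlation at the delay", {
  set.seed(13)
  spec <- bivariate_fractal_spec(H1 = 0.7, H2 = 0.8, rho = 0.6,
                                 delta = 8, n = 2^11)
  emb <- fractalconn:::bfgn_embedding(0.7, 0.8, 0.6, 2^11 + 8)
  peaks <- replicate(60, {
    ts <- fractalconn:::synthesize_from_embedding(spec, emb)
    cc <- xcorr_lags(ts$data[1, ], ts$data[2, ], 32)
    (-32:32)[which.max(cc)]
  })
  expect_equal(as.integer(names(which.max(table(peaks)))), 8L)
  # majority, not mere plurality
  expect_gt(mean(peaks == 8), 0.5)
})

test_that("identical seeds reproduce bit-identical output", {
  spec <- bivariate_fractal_spec(H1 = 0.7, H2 = 0.8, rho = 0.5, delta = 4,
                                 n = 2^10, seed = 99)
  a <- synthesize_bivariate(spec)
  b <- synthesize_bivariate(spec)
  expect_identical(a$data, b$data)
  spec2 <- bivariate_fractal_spec(H1 = 0.7, H2 = 0.8, rho = 0.5, delta = 4,
                                  n = 2^10, seed = 100)
  expect_false(identical(synthesize_bivariate(spec2)$data, a$data))
})

test_that("invalid joint covariances are refused, naming the parameters", {
  # rho close to 1 with very different Hurst exponents breaks positive
  # semidefiniteness of the joint law
  expect_error(synthesize_bivariate(
    bivariate_fractal_spec(H1 = 0.05, H2 = 0.95, rho = 0.99, n = 2^10)),
    "H1=0.05")
})

test_that("trends are added per channel at the requested amplitude", {
  set.seed(14)
  ts <- synthesize_bivariate(bivariate_fractal_spec(n = 2^10, seed = 3))
  expect_identical(add_trend(ts, trend_spec(amplitude = 0))$data, ts$data)

  tr <- trend_spec("polynomial", amplitude = 1, order = 1, seed = 5)
  out <- add_trend(ts, tr)
  for (ch in 1:2) {
    d <- out$data[ch, ] - ts$data[ch, ]
    # exactly affine in t
    fit <- lm(d ~ seq_along(d))
    expect_lt(max(abs(residuals(fit))), 1e-8 * max(abs(d)))
    expect_equal(sd(d), sd(ts$data[ch, ]), tolerance = 1e-10)
  }

  # smooth fBm trends load the coarsest octaves of the wavelet spectrum
  set.seed(15)
  n <- 2^11
  J <- 6
  d_oct <- matrix(0, 40, J)
  for (r in 1:40) {
    base <- time_series_set(draw_fgn(0.8, n), fs = 1)
    tsr <- add_trend(base, trend_spec("fbm", amplitude = 1, hurst = 0.2))
    e0 <- vapply(seq_len(J), function(j) {
      co <- dtcwt_forward(base$data[1, ], J = J)
      mean(Mod(co$d[[j]][!co$boundary[[j]]])^2)
    }, numeric(1))
    e1 <- vapply(seq_len(J), function(j) {
      co <- dtcwt_forward(tsr$data[1, ], J = J)
      mean(Mod(co$d[[j]][!co$boundary[[j]]])^2)
    }, numeric(1))
    d_oct[r, ] <- log2(e1) - log2(e0)
  }
  dm <- colMeans(d_oct)
  expect_equal(which.max(dm), J)
  expect_gt(dm[J], dm[2])
})

test_that("network datasets plant dependence only on the declared edges", {
  set.seed(16)
  expect_error(generate_network_dataset(
    4, edges = list(list(a = 1, b = 2, rho = 0.5, delta = 0),
                    list(a = 2, b = 3, rho = 0.5, delta = 0))),
    "overlapping")
  expect_error(generate_network_dataset(
    3, edges = list(list(a = 1, b = 4, rho = 0.5, delta = 0))),
    "valid")

  ts <- generate_network_dataset(
    4, edges = list(list(a = 1, b = 3, rho = 0.8, delta = 0)),
    H = 0.8, n = 2^11, seed = 21)
  C <- cor(t(ts$data))
  expect_gt(C[1, 3], 0.6)
  off <- abs(C[upper.tri(C)])
  expect_lt(sort(off, decreasing = TRUE)[2], 0.2)
})
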