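test_that("reference values honor the zero cases exactly", {
  sp0 <- bivariate_fractal_spec(H1 = 0.7, H2 = 0.8, rho = 0, delta = 8,
                                n = 2^10)
  expect_equal(reference_value(sp0, "ICOH", 3:5)$values, rep(0, 3))
  spd0 <- bivariate_fractal_spec(H1 = 0.7, H2 = 0.8, rho = 0.7, delta = 0,
                                 n = 2^10)
  expect_equal(reference_value(spd0, "ICOH", 3:5)$values, rep(0, 3),
               tolerance = 1e-12)
  # coherence at delta = 0 is positive and increases with rho
  r1 <- reference_value(bivariate_fractal_spec(rho = 0.3, n = 2^10),
                        "COH", 4)$values
  r2 <- reference_value(bivariate_fractal_spec(rho = 0.8, n = 2^10),
                        "COH", 4)$values
  expect_gt(r2, r1)
  expect_error(reference_value(sp0, "wPLI", 3, method = "integral"),
               "empirical")
})

test_that("the spectral-integral and long-run empirical oracles agree", {
  set.seed(61)
  sp <- bivariate_fractal_spec(H1 = 0.7, H2 = 0.8, rho = 0.6, delta = 8,
                               n = 2^13)
  ri <- reference_value(sp, "ICOH", 4)
  re <- reference_value(sp, "ICOH", 4, method = "empirical",
                        n_long = 2^13, N_long = 60)
  expect_false(ri$values == 0)
  expect_lt(abs(ri$values - re$values),
            max(3 * re$se, 0.03 * abs(re$values)))
})

test_that("grids are reproducible and degenerate cases are flagged", {
  tpl <- bivariate_fractal_spec(H1 = 0.7, H2 = 0.8, n = 2^10)
  g1 <- run_grid(tpl, c(0, 0.5), 0, N = 4, estimators = "W-ICOH",
                 band = scale_band(2, 4), master_seed = 7)
  g2 <- run_grid(tpl, c(0, 0.5), 0, N = 4, estimators = "W-ICOH",
                 band = scale_band(2, 4), master_seed = 7)
  expect_identical(g1$band_stats, g2$band_stats)
  expect_identical(g1$octave_stats, g2$octave_stats)

  gN1 <- run_grid(tpl, 0.5, 0, N = 1, estimators = "W-ICOH",
                  band = scale_band(2, 4), master_seed = 7)
  expect_true(is.na(gN1$band_stats$sd))
  expect_equal(gN1$band_stats$mean, gN1$band_stats$m1)

  # reordering the axes permutes, but does not change, cell results
  g3 <- run_grid(tpl, c(0.5, 0), 0, N = 4, estimators = "W-ICOH",
                 band = scale_band(2, 4), master_seed = 7)
  r1 <- g1$band_stats[g1$band_stats$rho == 0.5, ]
  r3 <- g3$band_stats[g3$band_stats$rho == 0.5, ]
  expect_equal(r1$N, r3$N)
})

test_that("summaries implement bias and RMSE from the raw moments", {
  # estimates {0.1, 0.3} against reference 0.2: bias 0, RMSE 0.1
  grid <- structure(list(band_stats = data.frame(
    rho = 0.5, delta = 0, estimator = "W-ICOH", N = 2L,
    mean = 0.2, sd = sd(c(0.1, 0.3)),
    m1 = mean(c(0.1, 0.3)), m2 = mean(c(0.1, 0.3)^2),
    seed = 1L, failed = FALSE)), class = "mc_grid")
  s <- summarize_grid(grid, 0.2)
  expect_equal(s$bias, 0)
  expect_equal(s$rmse, 0.1)
  # estimator constantly equal to the reference: bias and RMSE zero
  grid$band_stats$m1 <- 0.2
  grid$band_stats$m2 <- 0.04
  s0 <- summarize_grid(grid, 0.2)
  expect_equal(s0$bias, 0)
  expect_equal(s0$rmse, 0)
  refs <- data.frame(rho = 0.9, delta = 0, index = "ICOH", reference = 0.1)
  expect_error(summarize_grid(grid, refs), "missing reference")
})

test_that("RMSE ratios are elementwise with flagged zero denominators", {
  tab <- data.frame(rho = c(0, 0.5), delta = 8, estimator = "X",
                    rmse = c(0.2, 0.4))
  expect_equal(rmse_ratio(tab, tab)$ratio, c(1, 1))
  den <- tab
  den$rmse <- c(0, 0.2)
  expect_true(is.na(rmse_ratio(tab, den)$ratio[1]))
  expect_equal(rmse_ratio(tab, den)$ratio[2], 2)
  expect_error(rmse_ratio(tab, tab[1, ]), "do not match")
})
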