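# Monte-Carlo benchmarking of the connectivity estimators over (rho, delta)
# grids: per-octave means and confidence intervals, band-averaged bias and
# RMSE against model-based references, and RMSE-ratio surfaces.

all_estimators <- c("W-COH", "W-ICOH", "W-wPLI", "F-COH", "F-ICOH", "F-wPLI")

#' Model-based reference value of a connectivity index
#'
#' For coherence and imaginary coherence the reference is the model-spectrum
#' integral: the true cross-spectral density of the correlated, delayed
#' pair (fGn: exact aliased power-law density; fBm: generalized power-law
#' spectrum) is integrated against the squared frequency response of the
#' wavelet octave band, and the index is formed from the integrated
#' spectra. For the weighted phase lag index no closed form is available
#' and a long-run empirical oracle (large `n`, many realizations) is used,
#' reporting its Monte-Carlo standard error.
#'
#' @param spec A [bivariate_fractal_spec()] (its `n` and `seed` are ignored
#'   by the integral method).
#' @param index_kind `"COH"`, `"ICOH"` or `"wPLI"`.
#' @param octaves Octaves at which to evaluate the reference.
#' @param method `"integral"` (COH/ICOH) or `"empirical"` (forced for
#'   wPLI).
#' @param n_long,N_long Problem size for the empirical oracle.
#' @param filter_bank Filter bank whose band responses weight the integral.
#' @return An object of class `reference_value`: per-octave values, the
#'   method used, and (for the empirical method) standard errors.
#' @export
reference_value <- function(spec, index_kind = c("COH", "ICOH", "wPLI"),
                            octaves, method = NULL,
                            n_long = 2^16, N_long = 200,
                            filter_bank = dtcwt_filter_bank()) {
  index_kind <- match.arg(index_kind)
  if (is.null(method)) {
    method <- if (index_kind == "wPLI") "empirical" else "integral"
  }
  method <- match.arg(method, c("integral", "empirical"))
  if (index_kind == "wPLI" && method == "integral") {
    stop("no spectral-integral reference exists for the wPLI; use the empirical method")
  }
  if (method == "integral") {
    vals <- vapply(octaves, function(j) {
      reference_integral(spec, index_kind, j, filter_bank)
    }, numeric(1))
    structure(list(index = index_kind, octaves = octaves, values = vals,
                   method = "model-spectrum integral", se = NULL),
              class = "reference_value")
  } else {
    est <- matrix(NA_real_, nrow = N_long, ncol = length(octaves))
    long <- bivariate_fractal_spec(spec$kind1, spec$kind2, spec$H1, spec$H2,
                                   spec$rho, spec$delta, n = n_long,
                                   fs = spec$fs)
    emb <- bfgn_embedding(spec$H1, spec$H2, spec$rho, n_long + spec$delta)
    J <- max(octaves)
    for (r in seq_len(N_long)) {
      ts <- synthesize_from_embedding(long, emb)
      a <- dtcwt_forward(ts$data[1, ], J = J, filter_bank = filter_bank)
      b <- dtcwt_forward(ts$data[2, ], J = J, filter_bank = filter_bank)
      p <- switch(index_kind,
        wPLI = w_wpli(a, b),
        ICOH = w_icoh(wavelet_cross_spectrum(a), wavelet_cross_spectrum(b),
                      wavelet_cross_spectrum(a, b)),
        COH = w_coh(wavelet_cross_spectrum(a), wavelet_cross_spectrum(b),
                    wavelet_cross_spectrum(a, b)))
      est[r, ] <- if (index_kind == "COH") Mod(p$values[octaves]) else
        Re(p$values[octaves])
    }
    structure(list(index = index_kind, octaves = octaves,
                   values = colMeans(est),
                   method = "long-run empirical",
                   se = apply(est, 2, stats::sd) / sqrt(N_long)),
              class = "reference_value")
  }
}

# integral of the model spectra against the octave-band response
reference_integral <- function(spec, index_kind, j, filter_bank) {
  resp <- wavelet_band_response(j, filter_bank = filter_bank)
  f <- resp$f
  keep <- f != 0
  f <- f[keep]; wgt <- resp$power[keep]
  if (spec$kind1 == "fGn" && spec$kind2 == "fGn") {
    S11 <- fgn_spectral_density(f, spec$H1)
    S22 <- fgn_spectral_density(f, spec$H2)
    S12 <- bfgn_cross_spectral_density(f, spec$H1, spec$H2, spec$rho,
                                       spec$delta)
  } else if (spec$kind1 == "fBm" && spec$kind2 == "fBm") {
    S11 <- fbm_generalized_spectrum(f, spec$H1)
    S22 <- fbm_generalized_spectrum(f, spec$H2)
    S12 <- bfbm_cross_generalized_spectrum(f, spec$H1, spec$H2, spec$rho,
                                           spec$delta)
  } else {
    # mixed pair: generalized spectra, the fGn component keeping its exact
    # density
    S11 <- if (spec$kind1 == "fGn") fgn_spectral_density(f, spec$H1) else
      fbm_generalized_spectrum(f, spec$H1)
    S22 <- if (spec$kind2 == "fGn") fgn_spectral_density(f, spec$H2) else
      fbm_generalized_spectrum(f, spec$H2)
    S12 <- bfbm_cross_generalized_spectrum(f, spec$H1, spec$H2, spec$rho,
                                           spec$delta)
  }
  I12 <- sum(S12 * wgt)
  I11 <- sum(S11 * wgt)
  I22 <- sum(S22 * wgt)
  val <- I12 / sqrt(I11 * I22)
  if (index_kind == "COH") Mod(val) else Im(val)
}

#' Run a Monte-Carlo grid of connectivity-estimator experiments
#'
#' For every `(rho, delta)` cell, synthesizes `N` independent realizations
#' of the scenario and computes the requested per-octave indices and their
#' band averages. Per-octave means, standard deviations and normal 95%
#' confidence intervals are accumulated, as are the first two moments of
#' the band-averaged estimates (enough to recover bias and RMSE against any
#' reference). Each cell draws its own sub-seed from `master_seed` by a
#' counter scheme so any cell is reproducible in isolation; a synthesis
#' failure marks the cell failed and the run continues.
#'
#' @param template A [bivariate_fractal_spec()] whose `rho` and `delta` are
#'   overridden per cell.
#' @param rho_grid,delta_grid Numeric grids.
#' @param N Realizations per cell (at least 2 for dispersion estimates; with
#'   `N = 1` the SD is flagged undefined).
#' @param estimators Subset of `r paste(all_estimators, collapse=", ")`.
#' @param band A [scale_band()] for the band averages.
#' @param master_seed Integer master seed.
#' @param J Octave count for the wavelet transforms (defaults to the
#'   band's upper octave plus two, capped by feasibility).
#' @return An object of class `mc_grid` with data frames `octave_stats`
#'   (per cell, estimator, octave) and `band_stats` (per cell and
#'   estimator: mean, sd, and raw moments of the band average), plus the
#'   run metadata.
#' @export
run_grid <- function(template, rho_grid, delta_grid, N,
                     estimators = c("W-ICOH", "W-wPLI"),
                     band = scale_band(3, 7, template$fs),
                     master_seed = 1L, J = NULL) {
  estimators <- match.arg(estimators, all_estimators, several.ok = TRUE)
  N <- as.integer(N)
  if (N < 1L) stop("`N` must be at least 1")
  fb <- dtcwt_filter_bank()
  J_max <- floor(log2(template$n / fb$Lq))
  if (is.null(J)) J <- min(band$j2 + 2L, J_max)
  if (J < band$j2) stop("band exceeds the requested octave count")
  need_w <- any(startsWith(estimators, "W-"))
  need_f <- any(startsWith(estimators, "F-"))
  f_oct <- band$j1:band$j2
  oct_rows <- list()
  band_rows <- list()
  cell_idx <- 0L
  for (delta in delta_grid) {
    for (rho in rho_grid) {
      cell_idx <- cell_idx + 1L
      seed <- cell_seed(master_seed, cell_idx)
      spec <- bivariate_fractal_spec(template$kind1, template$kind2,
                                     template$H1, template$H2, rho,
                                     delta, template$n, template$fs,
                                     template$trend)
      emb_c <- tryCatch(
        bfgn_embedding(spec$H1, spec$H2, rho, spec$n + delta),
        error = function(e) NULL)
      if (is.null(emb_c)) {
        band_rows[[length(band_rows) + 1L]] <- data.frame(
          rho = rho, delta = delta, estimator = estimators, N = 0L,
          mean = NA_real_, sd = NA_real_, m1 = NA_real_, m2 = NA_real_,
          seed = seed, failed = TRUE)
        next
      }
      set.seed(seed)
      acc_oct <- array(0, dim = c(length(estimators), J, 2))
      acc_band <- matrix(0, nrow = length(estimators), ncol = 2)
      for (r in seq_len(N)) {
        ts <- synthesize_from_embedding(spec, emb_c)
        if (!is.null(spec$trend)) ts <- add_trend(ts, spec$trend)
        vals_oct <- matrix(NA_real_, length(estimators), J)
        vals_band <- numeric(length(estimators))
        if (need_w) {
          a <- dtcwt_forward(ts$data[1, ], J = J, filter_bank = fb)
          b <- dtcwt_forward(ts$data[2, ], J = J, filter_bank = fb)
          Saa <- Sbb <- Sab <- NULL
          if (any(estimators %in% c("W-COH", "W-ICOH"))) {
            Saa <- wavelet_cross_spectrum(a)
            Sbb <- wavelet_cross_spectrum(b)
            Sab <- wavelet_cross_spectrum(a, b)
          }
          for (ei in seq_along(estimators)) {
            p <- switch(estimators[ei],
              "W-COH" = w_coh(Saa, Sbb, Sab),
              "W-ICOH" = w_icoh(Saa, Sbb, Sab),
              "W-wPLI" = w_wpli(a, b),
              NULL)
            if (!is.null(p)) {
              vals_oct[ei, ] <- ifelse(p$flagged, NA,
                                       if (estimators[ei] == "W-COH")
                                         Mod(p$values) else Re(p$values))
              vals_band[ei] <- band_average(p, band)
            }
          }
        }
        if (need_f) {
          fo <- fourier_octave_indices(ts$data[1, ], ts$data[2, ],
                                       fs = spec$fs, octaves = f_oct,
                                       f0 = band$f0)
          for (ei in seq_along(estimators)) {
            p <- switch(estimators[ei],
              "F-COH" = fo$coh, "F-ICOH" = fo$icoh, "F-wPLI" = fo$wpli,
              NULL)
            if (!is.null(p)) {
              vals_oct[ei, f_oct] <- ifelse(p$flagged, NA, Re(p$values))
              vals_band[ei] <- band_average(p, band)
            }
          }
        }
        acc_oct[, , 1] <- acc_oct[, , 1] + ifelse(is.na(vals_oct), 0,
                                                  vals_oct)
        acc_oct[, , 2] <- acc_oct[, , 2] + ifelse(is.na(vals_oct), 0,
                                                  vals_oct^2)
        acc_band[, 1] <- acc_band[, 1] + vals_band
        acc_band[, 2] <- acc_band[, 2] + vals_band^2
      }
      m1o <- acc_oct[, , 1, drop = FALSE] / N
      sdo <- if (N > 1) {
        varo <- (acc_oct[, , 2, drop = FALSE] - N * m1o^2) / (N - 1)
        varo[varo < 0] <- 0
        sqrt(varo)
      } else {
        array(NA_real_, dim = dim(m1o))
      }
      for (ei in seq_along(estimators)) {
        octs <- if (startsWith(estimators[ei], "F-")) f_oct else 1:J
        oct_rows[[length(oct_rows) + 1L]] <- data.frame(
          rho = rho, delta = delta, estimator = estimators[ei],
          octave = octs, N = N,
          mean = m1o[ei, octs, 1], sd = sdo[ei, octs, 1],
          ci_lo = m1o[ei, octs, 1] - 1.96 * sdo[ei, octs, 1] / sqrt(N),
          ci_hi = m1o[ei, octs, 1] + 1.96 * sdo[ei, octs, 1] / sqrt(N),
          seed = seed)
      }
      m1 <- acc_band[, 1] / N
      m2 <- acc_band[, 2] / N
      band_rows[[length(band_rows) + 1L]] <- data.frame(
        rho = rho, delta = delta, estimator = estimators, N = N,
        mean = m1,
        sd = if (N > 1) sqrt(pmax(0, (m2 - m1^2) * N / (N - 1))) else
          NA_real_,
        m1 = m1, m2 = m2, seed = seed, failed = FALSE)
    }
  }
  structure(
    list(octave_stats = do.call(rbind, oct_rows),
         band_stats = do.call(rbind, band_rows),
         template = template, band = band, N = N, J = J,
         estimators = estimators, master_seed = master_seed),
    class = "mc_grid"
  )
}

cell_seed <- function(master_seed, cell_idx) {
  as.integer((as.numeric(master_seed) * 100003 + cell_idx * 7919) %%
               2147483647)
}

#' @export
print.mc_grid <- function(x, ...) {
  cat(sprintf("<mc_grid> %d cells x %d realizations, estimators: %s\n",
              nrow(x$band_stats) / length(x$estimators), x$N,
              paste(x$estimators, collapse = ", ")))
  invisible(x)
}

#' Bias and RMSE of band-averaged estimates against references
#'
#' For each grid cell and estimator, computes `bias = mean - reference` and
#' `RMSE = sqrt(mean((estimate - reference)^2))` over realizations, from
#' the accumulated first two moments of the band-averaged estimates.
#' References are supplied per cell as a data frame with columns `rho`,
#' `delta`, `index` (`COH`/`ICOH`/`wPLI`) and `reference` (the band-averaged
#' reference value); a missing reference for any cell is an error.
#'
#' @param grid An [run_grid()] result.
#' @param references Data frame as described above, or a single number
#'   applied everywhere (e.g. 0 for null scenarios).
#' @return Data frame with `rho`, `delta`, `estimator`, `bias`, `rmse`.
#' @export
summarize_grid <- function(grid, references) {
  bs <- grid$band_stats[!grid$band_stats$failed, ]
  if (is.numeric(references) && length(references) == 1L) {
    refs <- references
    bs$reference <- refs
  } else {
    bs$index <- sub("^[WF]-", "", bs$estimator)
    key <- paste(bs$rho, bs$delta, bs$index)
    rkey <- paste(references$rho, references$delta, references$index)
    m <- match(key, rkey)
    if (anyNA(m)) {
      miss <- unique(key[is.na(m)])
      stop("missing reference for cell(s): ", paste(miss, collapse = "; "))
    }
    bs$reference <- references$reference[m]
  }
  data.frame(
    rho = bs$rho, delta = bs$delta, estimator = bs$estimator,
    reference = bs$reference,
    bias = bs$m1 - bs$reference,
    rmse = sqrt(pmax(0, bs$m2 - 2 * bs$reference * bs$m1 + bs$reference^2))
  )
}

#' Elementwise RMSE-ratio surface
#'
#' Ratio of the RMSE of one estimator to another over a common
#' `(rho, delta)` grid (e.g. Fourier over wavelet imaginary coherence).
#' Cells with a zero denominator are flagged `NA`.
#'
#' @param num,den Data frames from [summarize_grid()], filtered to one
#'   estimator each.
#' @return Data frame with `rho`, `delta`, `ratio`.
#' @export
rmse_ratio <- function(num, den) {
  key_n <- paste(num$rho, num$delta)
  key_d <- paste(den$rho, den$delta)
  if (!identical(sort(key_n), sort(key_d))) {
    stop("grids do not match between numerator and denominator tables")
  }
  m <- match(key_n, key_d)
  ratio <- ifelse(den$rmse[m] == 0, NA_real_, num$rmse / den$rmse[m])
  data.frame(rho = num$rho, delta = num$delta, ratio = ratio)
}
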