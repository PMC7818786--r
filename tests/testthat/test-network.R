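test_that("pairwise matrices are symmetric with self-coherence one", {
  set.seed(71)
  x <- draw_fgn(0.8, 2^10)
  ts <- time_series_set(rbind(x, x), fs = 1, labels = c("a", "b"))
  cm <- pairwise_band_indices(ts, "COH", "wavelet", scale_band(2, 4))
  expect_equal(cm$values[1, 2], 1, tolerance = 1e-10)
  expect_true(is.na(cm$values[1, 1]))

  ts4 <- generate_network_dataset(4, H = 0.8, n = 2^10, seed = 5)
  cm4 <- pairwise_band_indices(ts4, "wPLI", "wavelet", scale_band(2, 4))
  expect_equal(cm4$values, t(cm4$values))
  # channel reordering permutes the matrix accordingly
  perm <- c(3, 1, 4, 2)
  tsp <- time_series_set(ts4$data[perm, ], fs = 1,
                         labels = ts4$labels[perm])
  cmp <- pairwise_band_indices(tsp, "wPLI", "wavelet", scale_band(2, 4))
  expect_equal(cmp$values, cm4$values[perm, perm])
  expect_error(pairwise_band_indices(ts4, "wPLI", "wavelet",
                                     scale_band(2, 9)), "infeasible")
})

test_that("a planted edge dominates the wPLI matrix", {
  set.seed(72)
  hits <- 0L
  for (r in 1:20) {
    ts <- generate_network_dataset(
      4, edges = list(list(a = 1, b = 2, rho = 0.8, delta = 8)),
      H = 0.8, n = 2^11)
    cm <- pairwise_band_indices(ts, "wPLI", "wavelet", scale_band(2, 5))
    v <- cm$values
    if (v[1, 2] >= max(v[upper.tri(v)])) hits <- hits + 1L
  }
  expect_gte(hits, 17L)
})

test_that("the efficiency-cost filter recovers planted structure", {
  set.seed(73)
  M <- 10
  V <- matrix(abs(rnorm(M * M, 0.05, 0.01)), M)
  V <- (V + t(V)) / 2
  diag(V) <- 0
  planted <- rbind(c(1, 2), c(3, 4), c(5, 6))
  for (i in seq_len(nrow(planted))) {
    V[planted[i, 1], planted[i, 2]] <- 0.6
    V[planted[i, 2], planted[i, 1]] <- 0.6
  }
  net <- eco_filter(V)
  for (i in seq_len(nrow(planted))) {
    expect_equal(net$adjacency[planted[i, 1], planted[i, 2]], 1L)
  }

  # all-equal weights carry no information: the result is deterministic
  # (tie-break by index order) and sparse relative to the sweep maximum
  Veq <- matrix(1, M, M)
  diag(Veq) <- 0
  e1 <- eco_filter(Veq)
  e2 <- eco_filter(Veq)
  expect_identical(e1$adjacency, e2$adjacency)
  expect_lte(e1$density, 0.5)

  expect_warning(net0 <- eco_filter(matrix(0, M, M)), "all-zero")
  expect_equal(sum(net0$adjacency), 0)

  # node relabeling leaves the objective sweep invariant
  perm <- sample(M)
  net_p <- eco_filter(V[perm, perm])
  expect_equal(net_p$sweep$J, net$sweep$J, tolerance = 1e-12)
  expect_lte(net$density, 0.5)
})

test_that("random matrices select networks with average degree near 3", {
  set.seed(74)
  degs <- replicate(60, {
    M <- 20
    V <- matrix(runif(M * M), M)
    V <- (V + t(V)) / 2
    diag(V) <- 0
    average_degree(eco_filter(V))
  })
  expect_gt(median(degs), 1.5)
  expect_lt(median(degs), 5)
})

test_that("average degree follows both conventions", {
  M <- 4
  full <- matrix(1, M, M) - diag(M)
  expect_equal(average_degree(full), 3)
  expect_equal(average_degree(full, "normalized"), 1)
  expect_equal(average_degree(matrix(0, 3, 3)), 0)
  adj28 <- matrix(0L, 28, 28)
  adj28[1, 2] <- adj28[2, 1] <- 1L
  adj28[3, 4] <- adj28[4, 3] <- 1L
  adj28[5, 6] <- adj28[6, 5] <- 1L
  expect_equal(average_degree(adj28), 3 * 2 / 28)
  bad <- matrix(0, 3, 3)
  bad[1, 2] <- 1
  expect_error(average_degree(bad), "symmetric")
})

test_that("paired contrasts control false discoveries and find real shifts", {
  set.seed(75)
  M <- 8
  rand_cm <- function(shift_edge = NULL, shift = 0) {
    v <- matrix(rnorm(M * M, 0.3, 0.05), M)
    v <- (v + t(v)) / 2
    diag(v) <- NA
    if (!is.null(shift_edge)) {
      v[shift_edge[1], shift_edge[2]] <- v[shift_edge[1], shift_edge[2]] +
        shift
      v[shift_edge[2], shift_edge[1]] <- v[shift_edge[1], shift_edge[2]]
    }
    v
  }
  # identical conditions: zero rejections
  A <- replicate(12, rand_cm(), simplify = FALSE)
  gc0 <- paired_group_contrast(A, A, alpha = 0.01)
  expect_equal(sum(gc0$edges$significant), 0L)
  expect_equal(nrow(gc0$edges), M * (M - 1) / 2)

  # one edge shifted by +0.15 (sd 0.05): detected, null edges quiet
  power_hits <- null_rejects <- 0L
  reps <- 30
  for (r in seq_len(reps)) {
    A <- replicate(20, rand_cm(), simplify = FALSE)
    # paired: B shares A's noise plus the shift on the target edge
    B <- lapply(seq_len(20), function(i) {
      v <- A[[i]]
      v[2, 5] <- v[2, 5] + rnorm(1, 0.15, 0.05)
      v[5, 2] <- v[2, 5]
      v
    })
    gc1 <- paired_group_contrast(A, B, alpha = 0.01)
    target <- gc1$edges$a == 2 & gc1$edges$b == 5
    power_hits <- power_hits + gc1$edges$significant[target]
    null_rejects <- null_rejects + sum(gc1$edges$significant[!target])
  }
  expect_gte(power_hits, reps - 1)
  expect_lte(null_rejects / (reps * (M * (M - 1) / 2 - 1)), 0.01 + 0.01)

  # degenerate zero-variance edges are flagged
  A <- replicate(5, rand_cm(), simplify = FALSE)
  gc2 <- paired_group_contrast(A, A, alpha = 0.01)
  expect_true(all(is.na(gc2$edges$t)))
})

test_that("delta correlations use the Pearson t transform", {
  u <- c(1, 2, 3, 5, 8, 13)
  expect_equal(correlate_deltas(u, u)$r, 1)
  expect_equal(correlate_deltas(u, -2 * u + 3)$r, -1)
  expect_error(correlate_deltas(u, rep(1, 6)), "variance")
  expect_error(correlate_deltas(u, u[-1]), "length")

  # sampling experiment: r recovers a population correlation of -0.33
  set.seed(76)
  rs <- replicate(1000, {
    z <- rnorm(36)
    u <- -0.33 * z + sqrt(1 - 0.33^2) * rnorm(36)
    cor(z, u)
  })
  expect_lt(abs(mean(rs) + 0.33), 0.03)
})
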