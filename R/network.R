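# Channel-pair connectivity matrices, density-based network filtering,
# degree metrics and group-level contrasts.

#' Pairwise band-averaged connectivity matrix
#'
#' Computes the requested index for every channel pair and band-averages it
#' (absolute values), yielding a symmetric `M x M` matrix with an undefined
#' (NA) diagonal. Wavelet transforms are computed once per channel.
#'
#' @param ts A [time_series_set()] with at least 2 channels.
#' @param index_kind `"COH"`, `"ICOH"` or `"wPLI"`.
#' @param basis `"wavelet"` or `"fourier"` (octave-matched Welch).
#' @param band A [scale_band()].
#' @return An object of class `connectivity_matrix`: the matrix `values`
#'   (labelled, diagonal `NA`), `index`, `basis`, `band`.
#' @export
pairwise_band_indices <- function(ts, index_kind = c("wPLI", "COH", "ICOH"),
                                  basis = c("wavelet", "fourier"), band) {
  index_kind <- match.arg(index_kind)
  basis <- match.arg(basis)
  if (!inherits(ts, "time_series_set")) stop("`ts` must be a time_series_set")
  M <- n_channels(ts)
  if (M < 2L) stop("need at least 2 channels")
  fb <- dtcwt_filter_bank()
  J_max <- floor(log2(n_samples(ts) / fb$Lq))
  if (band$j2 > J_max) {
    stop(sprintf("band octave %d infeasible for n = %d (max %d)",
                 band$j2, n_samples(ts), J_max))
  }
  vals <- matrix(NA_real_, M, M, dimnames = list(ts$labels, ts$labels))
  if (basis == "wavelet") {
    J <- band$j2
    co <- lapply(seq_len(M), function(m) {
      dtcwt_forward(ts$data[m, ], J = J, filter_bank = fb)
    })
    auto <- if (index_kind != "wPLI") {
      lapply(co, wavelet_cross_spectrum)
    }
    for (m in seq_len(M - 1L)) {
      for (mp in (m + 1L):M) {
        p <- if (index_kind == "wPLI") {
          w_wpli(co[[m]], co[[mp]])
        } else {
          Sab <- wavelet_cross_spectrum(co[[m]], co[[mp]])
          if (index_kind == "COH") w_coh(auto[[m]], auto[[mp]], Sab) else
            w_icoh(auto[[m]], auto[[mp]], Sab)
        }
        vals[m, mp] <- vals[mp, m] <- band_average(p, band)
      }
    }
  } else {
    key <- c(COH = "coh", ICOH = "icoh", wPLI = "wpli")[[index_kind]]
    for (m in seq_len(M - 1L)) {
      for (mp in (m + 1L):M) {
        fo <- fourier_octave_indices(ts$data[m, ], ts$data[mp, ],
                                     fs = ts$fs, octaves = band$j1:band$j2,
                                     f0 = band$f0)
        vals[m, mp] <- vals[mp, m] <- band_average(fo[[key]], band)
      }
    }
  }
  structure(
    list(values = vals, index = index_kind, basis = basis, band = band,
         labels = ts$labels),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d, %s (%s basis), octaves %d..%d\n",
              nrow(x$values), ncol(x$values), x$index, x$basis,
              x$band$j1, x$band$j2))
  invisible(x)
}

as_conn_matrix <- function(x) {
  if (inherits(x, "connectivity_matrix")) return(x$values)
  if (is.matrix(x)) return(x)
  stop("expected a connectivity_matrix or a numeric matrix")
}

#' Efficiency-cost-optimized density filtering
#'
#' Sweeps network densities, thresholding the connectivity matrix to keep
#' its strongest edges at each density `d`, and retains the density
#' maximizing the efficiency-cost objective
#' \deqn{J(d) = (E_{global} + E_{local}) / d,}
#' with global and local efficiency computed on the unweighted thresholded
#' graph. Ties resolve toward the sparser network. For random matrices the
#' selected networks concentrate around an average degree of about 3.
#'
#' @param cm A `connectivity_matrix` or symmetric numeric matrix
#'   (absolute values are used; the diagonal is ignored).
#' @param densities Densities to sweep; default `2/M, 4/M, ...` up to 0.5.
#' @return An object of class `eco_network`: binary `adjacency`, chosen
#'   `density`, the objective `sweep` table, and the retained edge list.
#' @export
eco_filter <- function(cm, densities = NULL) {
  V <- abs(as_conn_matrix(cm))
  M <- nrow(V)
  diag(V) <- 0
  if (is.null(densities)) {
    densities <- seq(2 / M, 0.5, by = 2 / M)
  }
  n_edges_tot <- M * (M - 1) / 2
  ut <- which(upper.tri(V), arr.ind = TRUE)
  wts <- V[upper.tri(V)]
  if (all(wts == 0)) {
    warning("all-zero connectivity matrix: returning the empty network")
    adj <- matrix(0L, M, M, dimnames = dimnames(V))
    return(structure(list(adjacency = adj, density = 0,
                          sweep = NULL, edges = NULL),
                     class = "eco_network"))
  }
  # deterministic edge ranking: weight desc, then row/col index
  ord <- order(-wts, ut[, 1], ut[, 2])
  sweep_rows <- list()
  best <- NULL
  for (d in densities) {
    E <- max(1L, round(d * n_edges_tot))
    keep <- ord[seq_len(min(E, n_edges_tot))]
    g <- igraph::graph_from_edgelist(cbind(ut[keep, 1], ut[keep, 2]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, M - igraph::vcount(g)))
    eg <- igraph::global_efficiency(g)
    el <- igraph::average_local_efficiency(g)
    Jval <- (eg + el) / d
    sweep_rows[[length(sweep_rows) + 1L]] <- data.frame(
      density = d, n_edges = length(keep), E_global = eg, E_local = el,
      J = Jval)
    if (is.null(best) || Jval > best$J + 1e-12) {
      best <- list(J = Jval, d = d, keep = keep)
    }
  }
  adj <- matrix(0L, M, M, dimnames = dimnames(V))
  adj[ut[best$keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  structure(
    list(adjacency = adj, density = best$d,
         sweep = do.call(rbind, sweep_rows),
         edges = data.frame(a = ut[best$keep, 1], b = ut[best$keep, 2],
                            weight = wts[best$keep])),
    class = "eco_network"
  )
}

#' @export
print.eco_network <- function(x, ...) {
  cat(sprintf("<eco_network> %d nodes, %d edges (density %.3f)\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$density))
  invisible(x)
}

#' Average degree of a binary network
#'
#' Mean number of connections per node, `2 E / M`. A per-node normalized
#' variant (`2 E / (M (M - 1))`, the edge density) is also available since
#' reported average-degree scales differ between conventions.
#'
#' @param adj Binary adjacency matrix (square, symmetric, zero diagonal) or
#'   an `eco_network`.
#' @param convention `"mean"` (default, `2E/M`) or `"normalized"`
#'   (`2E/(M(M-1))`).
#' @return Scalar average degree.
#' @export
average_degree <- function(adj, convention = c("mean", "normalized")) {
  convention <- match.arg(convention)
  if (inherits(adj, "eco_network")) adj <- adj$adjacency
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) {
    stop("`adj` must be a square matrix")
  }
  if (!isTRUE(all.equal(adj, t(adj)))) stop("`adj` must be symmetric")
  if (any(diag(adj) != 0)) stop("`adj` must have a zero diagonal")
  M <- nrow(adj)
  E <- sum(adj != 0) / 2
  switch(convention, mean = 2 * E / M, normalized = 2 * E / (M * (M - 1)))
}

#' Paired group-level contrast of connectivity matrices
#'
#' Edgewise paired t-tests of condition B minus condition A across
#' subjects, with Benjamini-Hochberg false-discovery-rate adjustment across
#' the `M (M - 1) / 2` edges and decisions at level `alpha`. Edges with
#' zero difference variance are flagged (`NA` statistics, no decision).
#'
#' @param condA,condB Subject-aligned lists of `connectivity_matrix`
#'   objects (or plain matrices), equal length `>= 3`.
#' @param alpha Significance level after FDR adjustment (default 0.01).
#' @return An object of class `group_contrast`: data frame `edges` with
#'   per-edge `t`, `p`, `p_adj`, `significant`, plus `n_subjects`, `alpha`.
#' @export
paired_group_contrast <- function(condA, condB, alpha = 0.01) {
  if (length(condA) != length(condB)) {
    stop("conditions must have the same number of subjects")
  }
  N <- length(condA)
  if (N < 3L) stop("need at least 3 subjects")
  A <- vapply(condA, function(x) as_conn_matrix(x)[upper.tri(as_conn_matrix(x))],
              numeric(sum(upper.tri(as_conn_matrix(condA[[1]])))))
  B <- vapply(condB, function(x) as_conn_matrix(x)[upper.tri(as_conn_matrix(x))],
              numeric(nrow(A)))
  D <- B - A
  mbar <- rowMeans(D)
  sdv <- apply(D, 1, stats::sd)
  tstat <- ifelse(sdv == 0, NA_real_, mbar / (sdv / sqrt(N)))
  p <- 2 * stats::pt(abs(tstat), df = N - 1, lower.tail = FALSE)
  p_adj <- stats::p.adjust(p, method = "BH")
  M <- nrow(as_conn_matrix(condA[[1]]))
  idx <- which(upper.tri(matrix(0, M, M)), arr.ind = TRUE)
  structure(
    list(edges = data.frame(a = idx[, 1], b = idx[, 2],
                            mean_diff = mbar, t = tstat, p = p,
                            p_adj = p_adj,
                            significant = !is.na(p_adj) & p_adj < alpha),
         n_subjects = N, alpha = alpha, M = M),
    class = "group_contrast"
  )
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("<group_contrast> %d subjects, %d edges, %d significant at FDR alpha=%.3g\n",
              x$n_subjects, nrow(x$edges), sum(x$edges$significant),
              x$alpha))
  invisible(x)
}

#' Pearson correlation of per-subject differences
#'
#' Relates two per-subject quantities (e.g. the change in the Hurst
#' exponent against the change in a band-averaged connectivity index across
#' conditions) by the standard Pearson correlation with a two-sided p-value
#' from the t transform.
#'
#' @param u,v Equal-length numeric vectors (`length >= 3`), finite, with
#'   nonzero variance.
#' @return List with `r`, `p`, `n`.
#' @export
correlate_deltas <- function(u, v) {
  if (length(u) != length(v)) stop("`u` and `v` must have equal length")
  if (length(u) < 3L) stop("need at least 3 observations")
  if (!all(is.finite(u)) || !all(is.finite(v))) stop("inputs must be finite")
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(u, v, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(u))
}
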