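# Plain-text I/O: TSV time series (with a sampling-rate header), long-format
# connectivity tables and square connectivity matrices.

#' Write a time-series set as TSV
#'
#' Format: a first comment line `# fs=<Hz>`, a header row of channel
#' labels, then one row per sample with one column per channel, at full
#' (15+ significant digit) precision.
#'
#' @param ts A [time_series_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  if (!inherits(ts, "time_series_set")) stop("`ts` must be a time_series_set")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.15g", ts$fs), con)
  writeLines(paste(ts$labels, collapse = "\t"), con)
  m <- t(ts$data)
  lines <- apply(m, 1, function(r) {
    paste(sprintf("%.17g", r), collapse = "\t")
  })
  writeLines(lines, con)
  invisible(path)
}

#' Read a time-series set from TSV
#'
#' Expects the dialect written by [write_timeseries()]: a `# fs=` header
#' line, a label row, then one column per channel. Ragged rows and a
#' missing sampling-rate header are errors.
#'
#' @param path Input file path.
#' @return A [time_series_set()].
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*fs=([0-9.eE+-]+)\\s*$", first))[[1]]
  if (length(m) < 2L) {
    stop("missing sampling-rate header: first line must be `# fs=<Hz>`")
  }
  fs <- as.numeric(m[2])
  nf <- utils::count.fields(path, sep = "\t", skip = 1L)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    stop("ragged row in ", path, ": line ", bad + 1L, " has ", nf[bad],
         " fields, expected ", nf[1])
  }
  tab <- utils::read.table(path, sep = "\t", skip = 1L, header = TRUE,
                           check.names = FALSE,
                           colClasses = "numeric")
  time_series_set(t(as.matrix(tab)), fs = fs, labels = colnames(tab))
}

#' Write connectivity results as TSV
#'
#' Two layouts: a list of `connectivity_profile` objects becomes a
#' long-format table (`pair`, `basis`, `index`, `octave_or_frequency`,
#' `value`, `flagged`), with complex coherence values serialized as R
#' complex literals; a `connectivity_matrix` becomes a square labelled TSV
#' (re-serialization is byte-identical). Flagged entries are marked, never
#' dropped.
#'
#' @param x A `connectivity_matrix`, a single `connectivity_profile`, or a
#'   (possibly named) list of profiles.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(x, path) {
  if (inherits(x, "connectivity_matrix")) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("label", x$labels), collapse = "\t"), con)
    for (i in seq_len(nrow(x$values))) {
      writeLines(paste(c(x$labels[i], sprintf("%.17g", x$values[i, ])),
                       collapse = "\t"), con)
    }
    return(invisible(path))
  }
  if (inherits(x, "connectivity_profile")) x <- list(x)
  rows <- lapply(x, function(p) {
    axis <- if (!is.null(p$octaves)) p$octaves else p$freq
    data.frame(
      pair = if (is.null(p$pair)) "" else paste(p$pair, collapse = ":"),
      basis = p$basis, index = p$index,
      octave_or_frequency = axis,
      value = vapply(p$values, function(v) {
        if (is.complex(v)) format(v, digits = 17) else sprintf("%.17g", v)
      }, character(1)),
      flagged = p$flagged
    )
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a square connectivity matrix written by [write_connectivity()]
#'
#' @param path Input file path.
#' @param index,basis,band Metadata to attach (optional).
#' @return A `connectivity_matrix`.
#' @export
read_connectivity_matrix <- function(path, index = "unknown",
                                     basis = "unknown", band = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  labels <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(vals) <- list(labels, labels)
  structure(list(values = vals, index = index, basis = basis, band = band,
                 labels = labels),
            class = "connectivity_matrix")
}
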