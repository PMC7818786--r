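#' Multichannel time-series container
#'
#' The universal analysis input: `M` channels by `n` samples of real values,
#' a sampling rate and channel labels. Rows of `data` are channels.
#'
#' @param data Numeric matrix, channels in rows (a vector is treated as one
#'   channel).
#' @param fs Sampling rate in Hz.
#' @param labels Character vector of unique channel names; defaults to
#'   `ch1, ch2, ...`.
#' @param provenance Optional record of the generating specification.
#' @return An object of class `time_series_set` with fields `data`, `fs`,
#'   `labels`, `provenance`.
#' @export
time_series_set <- function(data, fs, labels = NULL, provenance = NULL) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix (channels x samples)")
  }
  if (!all(is.finite(data))) stop("`data` must contain only finite values")
  if (nrow(data) < 1L || ncol(data) < 1L) stop("`data` must be non-empty")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive sampling rate in Hz")
  }
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data)) {
    stop("need one label per channel: ", nrow(data), " channels, ",
         length(labels), " labels")
  }
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = labels, provenance = provenance),
    class = "time_series_set"
  )
}

#' @export
print.time_series_set <- function(x, ...) {
  cat(sprintf("<time_series_set> %d channel(s) x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$fs))
  cat("  channels:", paste(utils::head(x$labels, 8L), collapse = ", "),
      if (length(x$labels) > 8L) "..." else "", "\n")
  if (!is.null(x$provenance)) cat("  provenance: attached\n")
  invisible(x)
}

n_samples <- function(ts) ncol(ts$data)
n_channels <- function(ts) nrow(ts$data)
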