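#' Binned spike raster
#'
#' Container for a binary spike raster: `M` trials by `N` time bins at bin
#' width `dt` (seconds). The per-bin last-spike lag map `l(m, n)` (time since
#' the most recent spike strictly before bin `n`, in bins; 0 before a trial's
#' first spike) is computed on construction and kept consistent with the
#' spike matrix.
#'
#' @param y integer/numeric matrix of 0/1 spike indicators, trials in rows.
#' @param dt bin width in seconds.
#' @param trial_labels optional per-trial labels (e.g. ground-truth
#'   modulation class for mixture scenarios).
#' @return An object of class `spike_raster` with elements `y`, `dt`,
#'   `last_spike_lag`, `trial_labels`.
#' @export
spike_raster <- function(y, dt, trial_labels = NULL) {
  y <- as.matrix(y)
  if (!dt > 0) stop("dt must be positive")
  bad <- which(!(y %in% c(0L, 1L)))
  if (length(bad)) {
    i <- bad[1L]
    stop(sprintf("non-binary entry %s at trial %d, bin %d",
                 format(y[i]), row(y)[i], col(y)[i]))
  }
  storage.mode(y) <- "integer"
  if (!is.null(trial_labels) && length(trial_labels) != nrow(y))
    stop("trial_labels length must equal number of trials")
  structure(
    list(y = y, dt = dt, last_spike_lag = .last_spike_lag(y),
         trial_labels = trial_labels),
    class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d trials x %d bins, dt = %g s, rate %.1f Hz\n",
              nrow(x$y), ncol(x$y), x$dt, mean(x$y) / x$dt))
  invisible(x)
}

#' @export
dim.spike_raster <- function(x) dim(x$y)

#' Interspike intervals of a raster
#'
#' @param raster a [spike_raster()].
#' @param units `"s"` or `"bins"`.
#' @return numeric vector of ISIs pooled across trials.
#' @export
isi <- function(raster, units = c("s", "bins")) {
  units <- match.arg(units)
  out <- unlist(lapply(seq_len(nrow(raster$y)), function(m) {
    diff(which(raster$y[m, ] == 1L))
  }), use.names = FALSE)
  if (units == "s") out * raster$dt else out
}

#' Empirical PSTH (trial-averaged firing rate)
#'
#' @param raster a [spike_raster()].
#' @param smooth_sd Gaussian smoothing kernel SD in seconds (0 = none).
#' @return numeric vector of length `N`, in Hz.
#' @export
psth <- function(raster, smooth_sd = 0) {
  r <- colMeans(raster$y) / raster$dt
  if (smooth_sd > 0) r <- gauss_smooth(r, smooth_sd / raster$dt)
  r
}

# centered Gaussian kernel smoothing with edge renormalisation
gauss_smooth <- function(x, sd_bins) {
  h <- ceiling(4 * sd_bins)
  k <- dnorm(seq(-h, h), sd = sd_bins)
  n <- length(x)
  xp <- c(rep(NA_real_, h), x, rep(NA_real_, h))
  vapply(seq_len(n), function(i) {
    w <- xp[i:(i + 2 * h)]
    ok <- !is.na(w)
    sum(w[ok] * k[ok]) / sum(k[ok])
  }, numeric(1))
}

#' @method as_tibble spike_raster
#' @export
as_tibble.spike_raster <- function(x, ...) {
  M <- nrow(x$y); N <- ncol(x$y)
  tibble::tibble(
    trial = rep(seq_len(M), times = N),
    time = rep((seq_len(N) - 1) * x$dt, each = M),
    spike = as.integer(x$y))
}

#' Write / read a raster as plain text
#'
#' One trial per line, space-separated 0/1, preceded by `#`-prefixed header
#' lines carrying `dt` and optional trial labels. The round trip is lossless.
#'
#' @param raster a [spike_raster()].
#' @param path file path.
#' @export
write_raster <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt %.17g", raster$dt), con)
  if (!is.null(raster$trial_labels))
    writeLines(paste("# labels", paste(raster$trial_labels, collapse = " ")), con)
  apply(raster$y, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' @rdname write_raster
#' @param path file path.
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  dt <- NA_real_; labels <- NULL
  for (h in lines[hdr]) {
    tok <- strsplit(trimws(sub("^#\\s*", "", h)), "\\s+")[[1L]]
    if (tok[1L] == "dt") dt <- as.numeric(tok[2L])
    if (tok[1L] == "labels") labels <- tok[-1L]
  }
  if (is.na(dt)) stop("raster file lacks a dt header")
  body <- lines[!hdr & nzchar(trimws(lines))]
  rows <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
  n <- unique(lengths(rows))
  if (length(n) != 1L) stop("ragged raster: trials have differing bin counts")
  y <- do.call(rbind, rows)
  for (m in seq_len(nrow(y))) {
    bad <- which(!(y[m, ] %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("non-binary entry '%s' at trial %d, bin %d",
                   format(y[m, bad[1L]]), m, bad[1L]))
  }
  spike_raster(y, dt, trial_labels = labels)
}

#' Write an oscillation (or any trial-by-bin signal) as CSV
#'
#' Long format with columns `trial`, `bin`, `value`.
#' @param w matrix, trials in rows.
#' @param path file path.
#' @export
write_signal_csv <- function(w, path) {
  df <- data.frame(trial = as.integer(row(w)), bin = as.integer(col(w)),
                   value = as.numeric(w))
  df <- df[order(df$trial, df$bin), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  df <- utils::read.csv(path)
  M <- max(df$trial); N <- max(df$bin)
  w <- matrix(NA_real_, M, N)
  w[cbind(df$trial, df$bin)] <- df$value
  w
}
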