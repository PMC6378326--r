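#' Multichannel time series
#'
#' Container for continuous extracellular data: a samples matrix (rows =
#' samples, columns = channels, amplitudes in microvolts), the sampling rate,
#' the start time and a channel table carrying region / depth / montage
#' metadata for a linear probe.
#'
#' @param samples numeric vector (one channel) or matrix with one column per
#'   channel.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 start time of the first sample, in seconds.
#' @param channels optional data.frame with columns `id`, `region`
#'   (one of `"FC"`, `"LH"`, `"RH"`, `"other"`), `depth_um` and `montage`
#'   (`"monopolar"` or `"bipolar"`). Defaults are generated when omitted.
#'
#' @return An object of class `time_series`.
#' @export
time_series <- function(samples, fs, t0 = 0, channels = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric vector or matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar")
  nc <- ncol(samples)
  if (is.null(channels)) {
    channels <- data.frame(
      id = paste0("ch", seq_len(nc)),
      region = rep("other", nc),
      depth_um = 50 * (seq_len(nc) - 1L),
      montage = rep("monopolar", nc),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(channels) != nc)
    stop("channel table has ", nrow(channels), " rows but samples has ",
         nc, " columns")
  stopifnot(all(c("id", "region", "depth_um", "montage") %in% names(channels)))
  structure(
    list(samples = samples, fs = as.numeric(fs), t0 = as.numeric(t0),
         channels = channels),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d channels x %d samples @ %g Hz (%.3f s), t0 = %g s\n",
              ncol(x$samples), nrow(x$samples), x$fs,
              nrow(x$samples) / x$fs, x$t0))
  reg <- table(x$channels$region)
  cat("  regions:", paste(names(reg), reg, sep = ":", collapse = " "),
      " montage:", paste(unique(x$channels$montage), collapse = "/"), "\n")
  invisible(x)
}

n_samples <- function(ts) nrow(ts$samples)

#' Time axis of a time series
#' @param ts a `time_series`.
#' @return numeric vector of sample times in seconds.
#' @export
ts_times <- function(ts) ts$t0 + (seq_len(n_samples(ts)) - 1L) / ts$fs

#' Select channels of a time series
#'
#' @param ts a `time_series`.
#' @param idx integer/logical column index, or a region name
#'   (`"FC"`, `"LH"`, `"RH"`) which selects all channels of that region.
#' @return a `time_series` with the selected channels.
#' @export
ts_channels <- function(ts, idx) {
  if (is.character(idx) && length(idx) >= 1L &&
      all(idx %in% ts$channels$region)) {
    idx <- which(ts$channels$region %in% idx)
  }
  time_series(ts$samples[, idx, drop = FALSE], ts$fs, ts$t0,
              ts$channels[idx, , drop = FALSE])
}

#' Analytic (Hilbert) phase and envelope
#'
#' @param phase matrix/vector of instantaneous phase in radians, (-pi, pi].
#' @param amplitude matrix/vector of the non-negative Hilbert envelope.
#' @param band the band limits (Hz) of the filtered source signal.
#' @param fs sampling rate (Hz).
#' @param t0 start time (s).
#' @return An object of class `analytic_signal`.
#' @export
analytic_signal <- function(phase, amplitude, band, fs, t0 = 0) {
  if (is.vector(phase)) phase <- matrix(phase, ncol = 1L)
  if (is.vector(amplitude)) amplitude <- matrix(amplitude, ncol = 1L)
  stopifnot(all(dim(phase) == dim(amplitude)), all(amplitude >= 0))
  structure(list(phase = phase, amplitude = amplitude,
                 band = as.numeric(band), fs = fs, t0 = t0),
            class = "analytic_signal")
}

#' @export
print.analytic_signal <- function(x, ...) {
  cat(sprintf("<analytic_signal> band %g-%g Hz, %d x %d samples @ %g Hz\n",
              x$band[1], x$band[2], nrow(x$phase), ncol(x$phase), x$fs))
  invisible(x)
}

#' Time-frequency map
#'
#' @param values complex or real matrix, rows = frequency bins, columns =
#'   time frames.
#' @param freqs strictly increasing frequency axis (Hz).
#' @param times time axis (s).
#' @param kind one of `"stockwell"`, `"morlet"`, `"zscore"`.
#' @return An object of class `tf_map`.
#' @export
tf_map <- function(values, freqs, times, kind = c("stockwell", "morlet", "zscore")) {
  kind <- match.arg(kind)
  stopifnot(nrow(values) == length(freqs), ncol(values) == length(times))
  if (length(freqs) > 1L && any(diff(freqs) <= 0))
    stop("`freqs` must be strictly increasing")
  structure(list(values = values, freqs = as.numeric(freqs),
                 times = as.numeric(times), kind = kind),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map:%s> %d freqs (%g-%g Hz) x %d frames (%g-%g s)\n",
              x$kind, length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

## row indices of a tf_map falling inside a band (inclusive)
tf_band_rows <- function(map, band) {
  which(map$freqs >= band[1] & map$freqs <= band[2])
}
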