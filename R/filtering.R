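#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel with an order-`order` Butterworth band-pass applied
#' forward and backward (zero net phase), the convention used throughout the
#' package because all downstream analyses are phase-sensitive.
#'
#' @param ts a [time_series()].
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi < fs/2`.
#' @param order filter order (default 2, the classic fast-ripple detector
#'   setting; the forward-backward pass doubles the effective order).
#' @return a `time_series` of identical shape and metadata.
#' @export
bandpass_filter <- function(ts, f_lo, f_hi, order = 2L) {
  check_band(c(f_lo, f_hi), ts$fs)
  if (n_samples(ts) <= 12L * order)
    stop("signal too short for filter warm-up (", n_samples(ts), " samples)")
  bf <- signal::butter(order, c(f_lo, f_hi) / (ts$fs / 2), type = "pass")
  out <- apply(ts$samples, 2L, function(x) signal::filtfilt(bf, x))
  if (!is.matrix(out)) out <- matrix(out, ncol = ncol(ts$samples))
  time_series(out, ts$fs, ts$t0, ts$channels)
}

check_band <- function(band, fs) {
  if (length(band) != 2L || !is.numeric(band) ||
      band[1] <= 0 || band[2] <= band[1] || band[2] >= fs / 2)
    stop("invalid band [", paste(band, collapse = ", "),
         "] Hz for fs = ", fs, " Hz (need 0 < f_lo < f_hi < fs/2)")
  invisible(band)
}

## squared magnitude response of a forward-backward Butterworth band-pass,
## evaluated analytically -- used as the closed-form oracle in tests
butter_bandpass_gain2 <- function(f, f_lo, f_hi, fs, order = 2L) {
  bf <- signal::butter(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
  w <- 2 * pi * f / fs
  z <- exp(-1i * outer(w, seq_along(bf$b) - 1))
  h <- as.vector(z %*% bf$b) / as.vector(z %*% bf$a)
  Mod(h)^2
}

#' Bipolar montage from successive probe contacts
#'
#' Re-references a monopolar linear-probe recording to the difference of each
#' pair of successive contacts (ordered by depth), removing any common
#' reference contribution. Channels are processed per region (one probe per
#' region); an N-contact probe yields N-1 bipolar channels.
#'
#' @param ts a monopolar `time_series` with at least two contacts per probe.
#' @return a `time_series` in bipolar montage; each bipolar channel id
#'   records the ordered source pair and its depth is the pair midpoint.
#' @export
bipolar_montage <- function(ts) {
  groups <- split(seq_len(ncol(ts$samples)), ts$channels$region)
  out <- list(); meta <- list()
  for (g in groups) {
    g <- g[order(ts$channels$depth_um[g])]
    if (length(g) < 2L)
      stop("montage error: probe with a single contact (region ",
           ts$channels$region[g[1]], ")")
    for (k in seq_len(length(g) - 1L)) {
      i <- g[k]; j <- g[k + 1L]
      out[[length(out) + 1L]] <- ts$samples[, i] - ts$samples[, j]
      meta[[length(meta) + 1L]] <- data.frame(
        id = paste0(ts$channels$id[i], "-", ts$channels$id[j]),
        region = ts$channels$region[i],
        depth_um = (ts$channels$depth_um[i] + ts$channels$depth_um[j]) / 2,
        montage = "bipolar", stringsAsFactors = FALSE)
    }
  }
  time_series(do.call(cbind, out), ts$fs, ts$t0, do.call(rbind, meta))
}

## analytic signal of a real vector via the FFT half-spectrum method
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase and envelope of a band-limited signal
#'
#' Band-pass filters the signal (zero-phase Butterworth) and applies a Hilbert
#' transform. Phase follows the cosine convention: 0 rad at local maxima of
#' the band-limited signal.
#'
#' @param ts a [time_series()].
#' @param band `c(f_lo, f_hi)` in Hz.
#' @param order filter order passed to [bandpass_filter()].
#' @return an [analytic_signal()] with per-sample phase (radians, (-pi, pi])
#'   and envelope (same units as the input).
#' @export
analytic_phase_amplitude <- function(ts, band, order = 2L) {
  filt <- bandpass_filter(ts, band[1], band[2], order = order)
  ph <- matrix(0, n_samples(ts), ncol(ts$samples))
  am <- ph
  for (j in seq_len(ncol(ts$samples))) {
    a <- hilbert_analytic(filt$samples[, j])
    ph[, j] <- Arg(a)
    am[, j] <- Mod(a)
  }
  analytic_signal(ph, am, band, ts$fs, ts$t0)
}

#' Decimate a recording to a lower analysis rate
#'
#' Anti-alias filters (8th-order Chebyshev type I low-pass, via
#' [signal::decimate()]) and subsamples each channel by an integer factor.
#' Connectivity analyses run at 1 kHz by default for tractability.
#'
#' @param ts a `time_series`.
#' @param fs_new target rate; `fs/fs_new` must be an integer.
#' @return a `time_series` at `fs_new`.
#' @export
decimate_ts <- function(ts, fs_new) {
  q <- ts$fs / fs_new
  if (abs(q - round(q)) > 1e-9)
    stop("fs_new must divide fs (fs = ", ts$fs, ", fs_new = ", fs_new, ")")
  q <- as.integer(round(q))
  if (q == 1L) return(ts)
  out <- apply(ts$samples, 2L, function(x) signal::decimate(x, q))
  if (!is.matrix(out)) out <- matrix(out, ncol = ncol(ts$samples))
  time_series(out, fs_new, ts$t0, ts$channels)
}

#' Extract equal-length epochs around event onsets
#'
#' Slices `[onset + w_lo, onset + w_hi)` (half-open, in samples) around each
#' onset, the onset being mapped to the nearest sample at or before the event
#' time, so every epoch has exactly `round((w_hi - w_lo) * fs)` samples with
#' t = 0 at the onset sample. Epochs that would cross the recording bounds
#' are dropped and reported in the `"dropped"` attribute.
#'
#' @param ts a `time_series`.
#' @param onsets event times in seconds.
#' @param window `c(w_lo, w_hi)` in seconds relative to the onset, e.g. the
#'   period of interest `c(-0.2, 0.6)`.
#' @return list of `time_series` epochs (each with `t0 = w_lo`); attribute
#'   `"dropped"` holds the out-of-bounds onset times, attribute `"onsets"`
#'   the retained ones.
#' @export
extract_epochs <- function(ts, onsets, window) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  n <- n_samples(ts)
  lo <- as.integer(round(window[1] * ts$fs))
  len <- as.integer(round((window[2] - window[1]) * ts$fs))
  out <- list(); kept <- numeric(0); dropped <- numeric(0)
  for (on in onsets) {
    i0 <- floor((on - ts$t0) * ts$fs) + 1L      # nearest sample at/before
    a <- i0 + lo
    b <- a + len - 1L
    if (a < 1L || b > n) {
      dropped <- c(dropped, on)
      next
    }
    out[[length(out) + 1L]] <- time_series(
      ts$samples[a:b, , drop = FALSE], ts$fs, t0 = window[1],
      channels = ts$channels)
    kept <- c(kept, on)
  }
  if (length(dropped))
    message(length(dropped), " epoch(s) dropped (window out of bounds)")
  attr(out, "dropped") <- dropped
  attr(out, "onsets") <- kept
  out
}
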