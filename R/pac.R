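#' Mean amplitude per phase bin
#'
#' Bins the amplitude envelope as a function of the slow-oscillation phase
#' over `n_bins` equal half-open, left-closed bins covering (-pi, pi], and
#' returns the mean amplitude per bin. Empty bins are set to 0 and flagged
#' in the `"empty"` attribute.
#'
#' @param phase instantaneous phase (radians), an [analytic_signal()] or
#'   numeric vector.
#' @param amp amplitude envelope, an [analytic_signal()] or numeric vector,
#'   aligned sample by sample with `phase`.
#' @param n_bins number of phase bins (default 18, matching the log(18)
#'   modulation-index normaliser).
#' @return numeric vector of `n_bins` bin means; attribute `"empty"` marks
#'   bins that received no samples.
#' @export
amplitude_by_phase <- function(phase, amp, n_bins = 18L) {
  if (inherits(phase, "analytic_signal")) phase <- phase$phase[, 1]
  if (inherits(amp, "analytic_signal")) amp <- amp$amplitude[, 1]
  if (length(phase) != length(amp)) stop("phase and amp are not aligned")
  bin <- pmin(n_bins, floor((phase + pi) / (2 * pi / n_bins)) + 1L)
  bin <- pmax(1L, bin)
  means <- rep(0, n_bins)
  m <- tapply(amp, factor(bin, levels = seq_len(n_bins)), mean)
  empty <- is.na(m)
  means[!empty] <- m[!empty]
  attr(means, "empty") <- which(empty)
  means
}

#' Kullback-Leibler modulation index
#'
#' Normalises the amplitude-by-phase bin means to a probability vector p and
#' returns the KL distance of p from the uniform distribution divided by
#' log(n_bins), giving a modulation index in [0, 1]: 0 for a uniform
#' distribution, 1 when all mass falls in a single bin. Zero bins contribute
#' 0 (the 0 log 0 = 0 convention), so both bounds are attained exactly.
#'
#' @param bin_means non-negative amplitude means per phase bin, not all 0.
#' @return modulation index in [0, 1].
#' @export
modulation_index <- function(bin_means) {
  if (any(bin_means < 0)) stop("bin means must be non-negative")
  s <- sum(bin_means)
  if (s <= 0) stop("invalid input: all phase bins are zero")
  p <- bin_means / s
  nb <- length(p)
  nz <- p > 0
  kl <- sum(p[nz] * log(p[nz] * nb))
  kl / log(nb)
}

#' Phase-amplitude comodulogram
#'
#' The five-step KL modulation-index procedure on event-locked windows:
#' (1) Hilbert phase of the low-frequency components and Hilbert envelope of
#' the high-frequency components of the band-filtered signal (filters run on
#' the continuous recording, then the event windows are sliced out);
#' (2) envelope binned as a function of phase; (3) mean amplitude per phase
#' bin per event; (4) KL distance to the uniform distribution;
#' (5) division by log(n_bins). The MI is computed per event and averaged
#' (`average = "pooled"` instead pools all window samples first).
#'
#' @param ts single-channel [time_series()].
#' @param onsets event times (s); for a baseline comodulogram pass baseline
#'   onsets.
#' @param window analysis window around each onset (s), default the period
#'   of interest `c(-0.2, 0.6)`.
#' @param phase_freqs low-frequency (phase) grid centres, Hz; default
#'   2-20 Hz in 0.5 Hz steps.
#' @param amp_freqs high-frequency (amplitude) grid centres, Hz; default
#'   2-98 Hz in 1 Hz steps.
#' @param bw phase-filter bandwidth, Hz (default 3).
#' @param amp_bw amplitude-filter bandwidth, Hz. The default (`NULL`) adapts
#'   it to `max(bw, 2 * f_phase + 2)` (quantised to 2 Hz steps): an
#'   amplitude filter must pass the modulation sidebands at
#'   `f_amp +/- f_phase`, so a bandwidth below twice the phase frequency
#'   cannot see the coupling. Pass a scalar to force a fixed bandwidth.
#' @param n_bins phase bins (default 18).
#' @param average `"per_event"` (default) or `"pooled"`.
#' @param condition label stored in the result (`"poi"` or `"baseline"`).
#' @return object of class `comodulogram`: `mi` (phase x amplitude matrix in
#'   [0, 1]), `phase_freqs`, `amp_freqs`, `peak` (grid location of max MI),
#'   `n_events`, `condition`.
#' @export
comodulogram <- function(ts, onsets, window = c(-0.2, 0.6),
                         phase_freqs = seq(2, 20, by = 0.5),
                         amp_freqs = seq(2, 98, by = 1), bw = 3,
                         amp_bw = NULL, n_bins = 18L,
                         average = c("per_event", "pooled"),
                         condition = "poi") {
  average <- match.arg(average)
  if (ncol(ts$samples) != 1L) stop("comodulogram expects one channel")
  if (max(phase_freqs, amp_freqs) + bw / 2 >= ts$fs / 2)
    stop("frequency grid reaches above Nyquist")
  if (diff(window) < 3 / min(phase_freqs))
    warning("window covers fewer than 3 cycles of the lowest phase frequency")
  fs <- ts$fs
  lo <- as.integer(round(window[1] * fs))
  len <- as.integer(round(diff(window) * fs))
  idx <- lapply(onsets, function(on) {
    i0 <- floor((on - ts$t0) * fs) + 1L + lo
    if (i0 < 1L || i0 + len - 1L > n_samples(ts)) return(NULL)
    i0:(i0 + len - 1L)
  })
  idx <- idx[!vapply(idx, is.null, logical(1))]
  if (!length(idx)) stop("no in-bounds events")
  if (average == "pooled") idx <- list(unlist(idx))

  ph <- matrix(NA_real_, n_samples(ts), length(phase_freqs))
  for (i in seq_along(phase_freqs)) {
    band <- c(max(0.25, phase_freqs[i] - bw / 2), phase_freqs[i] + bw / 2)
    ph[, i] <- analytic_phase_amplitude(ts, band)$phase[, 1]
  }
  ## amplitude bandwidth per phase frequency (sidebands at f_amp +/- f_phase
  ## must pass); envelopes cached per (width, amp frequency)
  widths <- if (is.null(amp_bw))
    2 * ceiling(pmax(bw, 2 * phase_freqs + 2) / 2) else
    rep(amp_bw, length(phase_freqs))
  amp_cache <- new.env(parent = emptyenv())
  get_amp <- function(w, fa) {
    key <- paste0(w, "_", fa)
    if (is.null(amp_cache[[key]])) {
      band <- c(max(0.25, fa - w / 2), min(fa + w / 2, ts$fs / 2 * 0.98))
      am <- analytic_phase_amplitude(ts, band)$amplitude[, 1]
      if (all(am == 0)) stop("zero-amplitude band at ", fa, " Hz")
      amp_cache[[key]] <- am
    }
    amp_cache[[key]]
  }
  mi <- matrix(0, length(phase_freqs), length(amp_freqs))
  for (i in seq_along(phase_freqs)) {
    for (j in seq_along(amp_freqs)) {
      am <- get_amp(widths[i], amp_freqs[j])
      vals <- vapply(idx, function(ii)
        modulation_index(amplitude_by_phase(ph[ii, i], am[ii], n_bins)),
        numeric(1))
      mi[i, j] <- mean(vals)
    }
  }
  pk <- arrayInd(which.max(mi), dim(mi))
  structure(list(mi = mi, phase_freqs = phase_freqs, amp_freqs = amp_freqs,
                 peak = c(f_phase = phase_freqs[pk[1]],
                          f_amp = amp_freqs[pk[2]]),
                 n_events = length(idx), condition = condition),
            class = "comodulogram")
}

#' @export
print.comodulogram <- function(x, ...) {
  cat(sprintf("<comodulogram:%s> %d x %d grid, %d events, peak MI %.4g at (%g Hz phase, %g Hz amp)\n",
              x$condition, nrow(x$mi), ncol(x$mi), x$n_events, max(x$mi),
              x$peak[1], x$peak[2]))
  invisible(x)
}

#' Ratio of modulation indices (period of interest / baseline)
#'
#' @param poi,baseline `comodulogram` objects on identical grids.
#' @param baseline_floor baseline MI values below this are floored before
#'   division and flagged (default 1e-6).
#' @return list with `ratio` (matrix), `peak` (grid location and value of
#'   the maximal ratio), `floored` (indices of floored baseline cells).
#' @export
mi_ratio <- function(poi, baseline, baseline_floor = 1e-6) {
  if (!identical(poi$phase_freqs, baseline$phase_freqs) ||
      !identical(poi$amp_freqs, baseline$amp_freqs))
    stop("comodulogram grids do not match")
  floored <- which(baseline$mi < baseline_floor)
  den <- pmax(baseline$mi, baseline_floor)
  ratio <- poi$mi / den
  pk <- arrayInd(which.max(ratio), dim(ratio))
  list(ratio = ratio,
       peak = list(f_phase = poi$phase_freqs[pk[1]],
                   f_amp = poi$amp_freqs[pk[2]],
                   value = max(ratio)),
       floored = floored)
}
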