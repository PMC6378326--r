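#' Detect fast ripples (200-550 Hz high-frequency oscillations)
#'
#' Band-pass filters each channel with an order-2 zero-phase Butterworth
#' filter and flags events showing at least `min_cycles` negative plus
#' `min_cycles` positive peaks whose amplitude exceeds `threshold_sd` times
#' the SD of the +/-250 ms surrounding baseline (candidate samples excluded
#' from their own baseline). Detections closer than `merge_gap` are merged.
#' All criteria are ratios to the baseline SD, so the detector is invariant
#' to signal scaling.
#'
#' @param ts a [time_series()].
#' @param band fast-ripple band in Hz, default `c(200, 550)`.
#' @param threshold_sd peak amplitude criterion in baseline SDs (default 3).
#' @param min_cycles minimum number of suprathreshold positive (and
#'   negative) peaks (default 4).
#' @param merge_gap events closer than this (s) are merged (default 10 ms).
#' @param baseline_halfwidth half-width (s) of the surrounding baseline used
#'   for the local SD (default 250 ms).
#' @param order Butterworth order (default 2).
#' @return data.frame event catalog: `onset_s` (time of the first
#'   suprathreshold peak), `channel`, `region`, `peak_freq_hz`, `n_cycles`,
#'   `amp_ratio`, `type = "fast_ripple"`.
#' @export
detect_fast_ripples <- function(ts, band = c(200, 550), threshold_sd = 3,
                                min_cycles = 4L, merge_gap = 0.010,
                                baseline_halfwidth = 0.250, order = 2L) {
  if (ts$fs <= 2 * band[2]) stop("invalid band: fs must exceed 2 * f_hi")
  check_band(band, ts$fs)
  filt <- bandpass_filter(ts, band[1], band[2], order = order)
  out <- list()
  for (j in seq_len(ncol(ts$samples))) {
    ev <- fr_detect_channel(filt$samples[, j], ts$fs, threshold_sd,
                            min_cycles, merge_gap, baseline_halfwidth)
    if (nrow(ev)) {
      ev$onset_s <- ev$onset_s + ts$t0
      ev$channel <- ts$channels$id[j]
      ev$region <- ts$channels$region[j]
      out[[length(out) + 1L]] <- ev
    }
  }
  if (!length(out))
    return(data.frame(onset_s = numeric(0), channel = character(0),
                      region = character(0), peak_freq_hz = numeric(0),
                      n_cycles = integer(0), amp_ratio = numeric(0),
                      type = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$type <- "fast_ripple"
  res[order(res$onset_s),
      c("onset_s", "channel", "region", "peak_freq_hz", "n_cycles",
        "amp_ratio", "type")]
}

## single-channel detector core on the band-filtered trace
fr_detect_channel <- function(x, fs, threshold_sd, min_cycles, merge_gap,
                              baseline_halfwidth) {
  empty <- data.frame(onset_s = numeric(0), peak_freq_hz = numeric(0),
                      n_cycles = integer(0), amp_ratio = numeric(0))
  n <- length(x)
  sigma_g <- stats::median(abs(x)) / 0.6745
  if (sigma_g <= 0) return(empty)
  ## candidate segments: envelope above a liberal global threshold
  env <- Mod(hilbert_analytic(x))
  above <- env > 2.5 * sigma_g
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  ## heal brief envelope dips within a burst (2 ms), qualification first;
  ## qualified events are merged over merge_gap afterwards
  heal <- as.integer(round(0.002 * fs))
  merged <- list(seg[1, ])
  if (nrow(seg) > 1) for (k in 2:nrow(seg)) {
    last <- merged[[length(merged)]]
    if (seg[k, 1] - last[2] <= heal)
      merged[[length(merged)]] <- c(last[1], seg[k, 2])
    else merged[[length(merged) + 1L]] <- seg[k, ]
  }
  seg <- do.call(rbind, merged)
  bh <- as.integer(round(baseline_halfwidth * fs))
  in_any_seg <- logical(n)
  for (k in seq_len(nrow(seg))) in_any_seg[seg[k, 1]:seg[k, 2]] <- TRUE
  res <- empty
  for (k in seq_len(nrow(seg))) {
    a <- seg[k, 1]; b <- seg[k, 2]
    ## baseline SD: +/- baseline_halfwidth around the candidate, candidate
    ## samples (of any segment) excluded so events cannot inflate it
    lo <- max(1L, a - bh); hi <- min(n, b + bh)
    base <- x[lo:hi][!in_any_seg[lo:hi]]
    if (length(base) < 10L) next
    thr <- threshold_sd * stats::sd(base)
    pk <- local_peaks(x, a, b)
    if (length(pk$idx) < 2L) next
    ## a cycle = adjacent suprathreshold negative + positive peak pair;
    ## isolated suprathreshold noise peaks do not form cycles
    supra <- abs(pk$val) > thr
    paired <- rep(FALSE, length(pk$idx))
    adj <- supra[-length(supra)] & supra[-1] &
      sign(pk$val[-length(pk$val)]) != sign(pk$val[-1])
    paired[which(adj)] <- TRUE
    paired[which(adj) + 1L] <- TRUE
    pos <- pk$idx[paired & pk$val > 0]
    neg <- pk$idx[paired & pk$val < 0]
    if (length(pos) >= min_cycles && length(neg) >= min_cycles) {
      onset <- (min(pk$idx[paired]) - 1L) / fs
      same_sign <- sort(pos)
      f_hat <- if (length(same_sign) >= 2L)
        fs / stats::median(diff(same_sign)) else NA_real_
      res <- rbind(res, data.frame(
        onset_s = onset, peak_freq_hz = f_hat,
        n_cycles = min(length(pos), length(neg)),
        amp_ratio = max(abs(x[a:b])) / stats::sd(base)))
    }
  }
  ## merge qualified events closer than merge_gap (earliest onset kept)
  if (nrow(res) > 1L) {
    res <- res[order(res$onset_s), ]
    keep <- rep(TRUE, nrow(res))
    for (k in 2:nrow(res)) {
      prev <- max(which(keep[1:(k - 1L)]))
      if (res$onset_s[k] - res$onset_s[prev] <= merge_gap) {
        keep[k] <- FALSE
        res$n_cycles[prev] <- max(res$n_cycles[prev], res$n_cycles[k])
        res$amp_ratio[prev] <- max(res$amp_ratio[prev], res$amp_ratio[k])
      }
    }
    res <- res[keep, , drop = FALSE]
  }
  res
}

## local extrema (derivative sign changes) of x within [a, b]
local_peaks <- function(x, a, b) {
  a <- max(a, 2L); b <- min(b, length(x) - 1L)
  if (b <= a) return(list(idx = integer(0), val = numeric(0)))
  seg <- x[(a - 1L):(b + 1L)]
  d <- diff(seg)
  ip <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L   # maxima
  im <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L   # minima
  idx <- sort(c(ip, im)) + a - 2L
  list(idx = idx, val = x[idx])
}

#' Detect multiunit spikes by robust median thresholding
#'
#' Filters the wideband signal into the multiunit band and applies the
#' unsupervised threshold `4 * median(|x| / 0.6745)` (four times the robust
#' SD estimate of the band-filtered signal `x`). Suprathreshold excursions
#' separated by at least `dead_time` are reported at the time of their
#' absolute extremum.
#'
#' @param ts_wideband a [time_series()] at full acquisition rate.
#' @param band multiunit band in Hz, default `c(300, 6000)` (requires
#'   fs >= 12 kHz; reduced-rate profiles must pass a proportionally reduced
#'   band, which is flagged in the result).
#' @param dead_time refractory period between detections, s (default 1 ms).
#' @param threshold_factor multiplier of the robust SD (default 4).
#' @param order Butterworth order (default 2).
#' @return data.frame with `time_s`, `channel`, `polarity` (+1/-1);
#'   attributes `threshold` (per channel), `band`, and `band_reduced`
#'   (TRUE when `band[2] < 6000`).
#' @export
detect_mua_spikes <- function(ts_wideband, band = c(300, 6000),
                              dead_time = 0.001, threshold_factor = 4,
                              order = 2L) {
  fs <- ts_wideband$fs
  if (band[2] >= fs / 2) {
    fallback <- c(band[1], floor(0.95 * fs / 2))
    stop("multiunit band [", band[1], ", ", band[2], "] Hz infeasible at fs = ",
         fs, " Hz; pass a reduced band such as c(", fallback[1], ", ",
         fallback[2], ")")
  }
  filt <- bandpass_filter(ts_wideband, band[1], band[2], order = order)
  dead <- as.integer(round(dead_time * fs))
  out <- list(); thr_all <- numeric(0)
  for (j in seq_len(ncol(filt$samples))) {
    x <- filt$samples[, j]
    thr <- threshold_factor * stats::median(abs(x) / 0.6745)
    thr_all <- c(thr_all, thr)
    if (thr <= 0) next
    above <- abs(x) > thr
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    seg <- cbind(starts[r$values], ends[r$values])
    ## one spike waveform can cross several times: merge excursions closer
    ## than the dead time into one cluster
    if (nrow(seg) > 1L) {
      merged <- list(seg[1, ])
      for (k in 2:nrow(seg)) {
        last_seg <- merged[[length(merged)]]
        if (seg[k, 1] - last_seg[2] < dead)
          merged[[length(merged)]] <- c(last_seg[1], seg[k, 2])
        else merged[[length(merged) + 1L]] <- seg[k, ]
      }
      seg <- do.call(rbind, merged)
    }
    times <- integer(0); pol <- integer(0); last <- -Inf
    for (k in seq_len(nrow(seg))) {
      i <- seg[k, 1]:seg[k, 2]
      pk <- i[which.max(abs(x[i]))]
      if (pk - last < dead) next
      last <- pk
      times <- c(times, pk)
      pol <- c(pol, sign(x[pk]))
    }
    if (length(times))
      out[[length(out) + 1L]] <- data.frame(
        time_s = ts_wideband$t0 + (times - 1L) / fs,
        channel = ts_wideband$channels$id[j], polarity = pol,
        stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(time_s = numeric(0), channel = character(0),
               polarity = integer(0), stringsAsFactors = FALSE)
  res <- res[order(res$time_s), , drop = FALSE]
  attr(res, "threshold") <- thr_all
  attr(res, "band") <- band
  attr(res, "band_reduced") <- band[2] < 6000
  res
}

#' Classify an event as IED-associated from its z-scored spectrogram
#'
#' An event is associated with an interictal discharge when the maximal
#' z-score within the IED band (20-30 Hz) exceeds `z_threshold`. By default
#' the maximum is taken over frequency rows of the time-averaged z within
#' the window (`reduce = "band_mean"`): the per-cell maximum over all
#' time-frequency points (`reduce = "cell_max"`, the literal reading) has
#' essentially no specificity, because the maximum over hundreds of
#' baseline-distributed cells exceeds 2 almost surely.
#'
#' @param z_map a [tf_map()] of kind `"zscore"` covering the IED band.
#' @param band IED band, default `c(20, 30)` Hz.
#' @param z_threshold default 2.
#' @param reduce `"band_mean"` (default) or `"cell_max"`.
#' @return list with `associated` (logical) and `max_z`.
#' @export
classify_ied_association <- function(z_map, band = c(20, 30),
                                     z_threshold = 2,
                                     reduce = c("band_mean", "cell_max")) {
  reduce <- match.arg(reduce)
  rows <- tf_band_rows(z_map, band)
  if (!length(rows))
    stop("z_map does not cover the ", band[1], "-", band[2], " Hz band")
  v <- Re(z_map$values[rows, , drop = FALSE])
  mz <- if (reduce == "band_mean") max(rowMeans(v)) else max(v)
  list(associated = mz > z_threshold, max_z = mz)
}

#' Median-based band onset across events
#'
#' For each time frame, takes the median across events of the mean z-score
#' within a frequency band; the onset is the earliest frame at which this
#' across-event median exceeds `z_threshold` (default 5, the conservative
#' criterion used for slow-oscillation onsets).
#'
#' @param z_maps list of z-scored [tf_map()]s, one per event, on a common
#'   grid.
#' @param band frequency band `c(f_lo, f_hi)` in Hz.
#' @param z_threshold default 5.
#' @return list with `onset` (s; `NA` when the threshold is never exceeded),
#'   `median_z` (per-frame median series) and `times`.
#' @export
band_onset <- function(z_maps, band, z_threshold = 5) {
  stopifnot(length(z_maps) >= 1L)
  rows <- tf_band_rows(z_maps[[1]], band)
  if (!length(rows)) stop("maps do not cover the requested band")
  series <- sapply(z_maps, function(m)
    colMeans(Re(m$values[rows, , drop = FALSE])))
  med <- apply(series, 1L, stats::median)
  times <- z_maps[[1]]$times
  i <- which(med > z_threshold)
  list(onset = if (length(i)) times[min(i)] else NA_real_,
       median_z = med, times = times)
}

#' Write an event catalog to CSV
#' @param catalog data.frame as returned by [detect_fast_ripples()] or
#'   assembled by [run_pipeline()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_event_catalog <- function(catalog, path) {
  utils::write.csv(catalog, path, row.names = FALSE)
  invisible(path)
}
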