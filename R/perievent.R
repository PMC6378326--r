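#' Peri-event time histogram
#'
#' Spike counts per bin, pooled over all event windows.
#'
#' @param spikes spike times in seconds (pooled over channels or a single
#'   channel).
#' @param event_onsets event times (s).
#' @param window `c(w_lo, w_hi)` around each event (s).
#' @param bin_width bin width in seconds; must divide the window length.
#' @param rate if TRUE, counts are converted to rates
#'   (spikes / s / event).
#' @return list with `edges`, `centers`, `counts` (or `rate`), `n_events`.
#' @export
psth <- function(spikes, event_onsets, window, bin_width, rate = FALSE) {
  if (!length(event_onsets)) stop("zero events")
  nb <- diff(window) / bin_width
  if (abs(nb - round(nb)) > 1e-9) stop("bin_width must divide the window")
  nb <- as.integer(round(nb))
  edges <- window[1] + bin_width * (0:nb)
  counts <- integer(nb)
  for (on in event_onsets) {
    rel <- spikes[spikes >= on + window[1] & spikes < on + window[2]] - on
    if (length(rel)) {
      b <- pmin(nb, floor((rel - window[1]) / bin_width) + 1L)
      tb <- tabulate(b, nb)
      counts <- counts + tb
    }
  }
  out <- list(edges = edges, centers = edges[-1] - bin_width / 2,
              counts = counts, n_events = length(event_onsets))
  if (rate) out$rate <- counts / (bin_width * length(event_onsets))
  out
}

#' Laminar firing ratios in the down-state and fast-ripple windows
#'
#' Per channel, pools spikes over all events and normalises the firing rate
#' in the down-state window (-180 to -30 ms before onset) and the
#' fast-ripple window (-30 to +20 ms) over the rate in the preceding
#' baseline window. Channels with no baseline spikes are flagged and
#' excluded (`NA` ratios).
#'
#' @param spike_times list of spike-time vectors, one per channel.
#' @param onsets event times (s).
#' @param down_window default `c(-0.180, -0.030)` s.
#' @param fr_window default `c(-0.030, 0.020)` s.
#' @param baseline_window default `c(-0.5, -0.2)` s.
#' @param depths channel depths in micrometres (for across-depth ranking).
#' @return data.frame: `channel`, `depth_um`, `down_ratio`, `fr_ratio`,
#'   `baseline_rate`, `excluded`.
#' @export
laminar_rate_ratio <- function(spike_times, onsets,
                               down_window = c(-0.180, -0.030),
                               fr_window = c(-0.030, 0.020),
                               baseline_window = c(-0.5, -0.2),
                               depths = NULL) {
  if (!length(onsets)) stop("zero events")
  nch <- length(spike_times)
  if (is.null(depths)) depths <- 50 * (seq_len(nch) - 1L)
  win_rate <- function(st, win)
    sum(vapply(onsets, function(on)
      sum(st >= on + win[1] & st < on + win[2]), numeric(1))) /
      (diff(win) * length(onsets))
  out <- data.frame(channel = seq_len(nch), depth_um = depths,
                    down_ratio = NA_real_, fr_ratio = NA_real_,
                    baseline_rate = NA_real_, excluded = FALSE)
  for (j in seq_len(nch)) {
    st <- spike_times[[j]]
    base <- win_rate(st, baseline_window)
    out$baseline_rate[j] <- base
    if (base <= 0) { out$excluded[j] <- TRUE; next }
    out$down_ratio[j] <- win_rate(st, down_window) / base
    out$fr_ratio[j] <- win_rate(st, fr_window) / base
  }
  out
}

#' Laminar chronology of multiunit onsets around fast ripples
#'
#' Per channel, builds the across-event average of the binary spike train
#' (sampled at `fs_analysis`), smooths it with a unit-area Hanning window
#' (`hanning_ms`), and sets the onset as the first time within
#' `search` around the event at which the smoothed trace exceeds the
#' preceding-baseline mean by `threshold_sd` baseline SDs. Channels that
#' never cross are excluded from the ranking (`NA` onset). A common time
#' shift of all channels leaves the ranking unchanged.
#'
#' @param spike_times list of spike-time vectors per channel.
#' @param onsets event times (s).
#' @param fs_analysis binary-train sampling rate, Hz (default 1000).
#' @param search onset search window, default `c(-0.030, 0.030)` s.
#' @param baseline_window baseline segment of each epoch for the threshold,
#'   default `c(-0.5, -0.2)` s.
#' @param hanning_ms Hanning window length in ms (default 10).
#' @param threshold_sd threshold in baseline SDs (default 3).
#' @param depths channel depths in micrometres.
#' @return data.frame ordered by onset: `channel`, `depth_um`, `onset_s`,
#'   `rank` (ties share ranks; `NA` = no onset).
#' @export
laminar_onset_chronology <- function(spike_times, onsets, fs_analysis = 1000,
                                     search = c(-0.030, 0.030),
                                     baseline_window = c(-0.5, -0.2),
                                     hanning_ms = 10, threshold_sd = 3,
                                     depths = NULL) {
  if (!length(onsets)) stop("zero events")
  nch <- length(spike_times)
  if (is.null(depths)) depths <- 50 * (seq_len(nch) - 1L)
  w0 <- min(baseline_window[1], search[1])
  w1 <- max(search[2], 0.05)
  nb <- as.integer(round((w1 - w0) * fs_analysis))
  tt <- w0 + (seq_len(nb) - 0.5) / fs_analysis
  nh <- max(3L, as.integer(round(hanning_ms / 1000 * fs_analysis)))
  if (nh %% 2 == 0) nh <- nh + 1L
  han <- 0.5 * (1 - cos(2 * pi * (seq_len(nh) - 1L) / (nh - 1L)))
  han <- han / sum(han)
  onset <- rep(NA_real_, nch)
  for (j in seq_len(nch)) {
    acc <- numeric(nb)
    for (on in onsets) {
      rel <- spike_times[[j]] - on
      rel <- rel[rel >= w0 & rel < w1]
      if (length(rel))
        acc <- acc + tabulate(floor((rel - w0) * fs_analysis) + 1L, nb)
    }
    acc <- acc / length(onsets)
    sm <- as.numeric(stats::filter(acc, han, sides = 2))
    sm[is.na(sm)] <- 0
    ib <- tt >= baseline_window[1] & tt < baseline_window[2]
    mu <- mean(sm[ib]); sdv <- stats::sd(sm[ib])
    if (!is.finite(sdv) || sdv <= 0) next
    is <- which(tt >= search[1] & tt < search[2] &
                sm > mu + threshold_sd * sdv)
    if (length(is)) onset[j] <- tt[min(is)]
  }
  out <- data.frame(channel = seq_len(nch), depth_um = depths,
                    onset_s = onset)
  out$rank <- rank(out$onset_s, ties.method = "min", na.last = "keep")
  out[order(out$onset_s, na.last = TRUE), ]
}

#' Cross-regional event precedence
#'
#' For each non-reference region, the fraction of reference events preceded
#' by at least one event of that region within a short (10 ms) and a long
#' (500 ms) window, compared against a matched-length baseline window
#' (-1000 to -500 ms) with a paired rank test on the per-event indicators.
#'
#' @param catalog data.frame with `onset_s` and `region`.
#' @param reference_region reference events (default `"FC"`).
#' @param other_regions regions tested for precedence
#'   (default `c("LH", "RH")`).
#' @param short,long window lengths in seconds (defaults 0.010 and 0.500).
#' @param baseline_window default `c(-1.0, -0.5)` s relative to each
#'   reference event.
#' @return data.frame: `region`, `frac_short`, `frac_long`,
#'   `frac_baseline`, `p_long_vs_baseline` (paired Wilcoxon signed-rank on
#'   the per-event indicators).
#' @export
precedence_analysis <- function(catalog, reference_region = "FC",
                                other_regions = c("LH", "RH"),
                                short = 0.010, long = 0.500,
                                baseline_window = c(-1.0, -0.5)) {
  ref <- catalog$onset_s[catalog$region == reference_region]
  if (!length(ref)) stop("no reference events in region ", reference_region)
  rows <- lapply(other_regions, function(r) {
    ot <- catalog$onset_s[catalog$region == r]
    ind <- function(w_lo, w_hi) vapply(ref, function(t0)
      any(ot >= t0 + w_lo & ot < t0 + w_hi), logical(1))
    s <- ind(-short, 0); l <- ind(-long, 0)
    b <- ind(baseline_window[1], baseline_window[2])
    p <- if (all(l == b)) 1 else
      suppressWarnings(stats::wilcox.test(as.numeric(l), as.numeric(b),
                                          paired = TRUE)$p.value)
    data.frame(region = r, frac_short = mean(s), frac_long = mean(l),
               frac_baseline = mean(b), p_long_vs_baseline = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
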