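#' Sample baseline epochs outside catalogued events
#'
#' Draws `n` epochs of the same duration as the analysis window, with start
#' times uniform over the parts of the recording that stay clear of every
#' event window plus a guard margin. Seeded and reproducible.
#'
#' @param ts a [time_series()].
#' @param events numeric vector of event times, or a data.frame with
#'   `start` / `end` columns (e.g. complex windows). Instant events are
#'   treated as zero-length intervals.
#' @param n number of baseline epochs.
#' @param window `c(w_lo, w_hi)` epoch window in seconds (matching the
#'   event-locked analysis window).
#' @param guard extra clearance around each event, s (default 1).
#' @param seed integer seed (default 1).
#' @return list of `time_series` epochs with attribute `"onsets"`.
#' @export
sample_baseline_epochs <- function(ts, events, n, window, guard = 1,
                                   seed = 1L) {
  set.seed(seed)
  if (is.data.frame(events)) {
    iv <- cbind(events$start - guard, events$end + guard)
  } else if (length(events)) {
    iv <- cbind(events - guard, events + guard)
  } else iv <- matrix(numeric(0), 0, 2)
  t_start <- ts$t0 - window[1]                       # earliest feasible onset
  t_end <- ts$t0 + n_samples(ts) / ts$fs - window[2]
  ## candidate onset grid at 1 ms, marked clean when the whole epoch clears
  grid <- seq(t_start, t_end, by = 0.001)
  ok <- rep(TRUE, length(grid))
  for (k in seq_len(nrow(iv)))
    ok <- ok & (grid + window[2] <= iv[k, 1] | grid + window[1] >= iv[k, 2])
  if (sum(ok) < 10L)
    stop("insufficient clean signal: only ", sum(ok) / 1000,
         " s of event-free onsets available for ", n, " baseline epochs")
  pick <- sample(which(ok), n, replace = TRUE)
  onsets <- grid[pick] + stats::runif(n, 0, 0.001)
  onsets <- pmin(onsets, t_end)
  ep <- extract_epochs(ts, onsets, window)
  ep
}

#' Baseline time-frequency statistics
#'
#' Computes the Stockwell amplitude spectrogram of each baseline epoch and
#' returns the per-cell mean and SD (per frequency bin and time frame, the
#' time-resolved rule; `time_resolved = FALSE` collapses time so each
#' frequency bin has a single mean/SD). SDs are floored at 1e-12.
#'
#' @param epochs list of single-channel `time_series` (e.g. from
#'   [sample_baseline_epochs()]).
#' @param f_max top frequency of the spectrograms (Hz).
#' @param time_resolved logical, default TRUE.
#' @param channel channel index used when epochs are multichannel.
#' @return object of class `baseline_stats`: `mean`, `sd` (freq x time),
#'   `freqs`, `times`, `n`, `time_resolved`.
#' @export
baseline_stats <- function(epochs, f_max, time_resolved = TRUE, channel = 1L) {
  stopifnot(length(epochs) >= 2L)
  acc <- NULL; acc2 <- NULL
  for (ep in epochs) {
    s <- stockwell_transform(ts_channels(ep, channel), f_max)
    a <- Mod(s$values)
    if (is.null(acc)) {
      acc <- a; acc2 <- a^2
      freqs <- s$freqs; times <- s$times
    } else {
      acc <- acc + a; acc2 <- acc2 + a^2
    }
  }
  n <- length(epochs)
  mu <- acc / n
  sdv <- sqrt(pmax(acc2 / n - mu^2, 0) * n / (n - 1))
  if (!time_resolved) {
    mu <- matrix(rowMeans(mu), nrow(mu), ncol(mu))
    sdv <- matrix(sqrt(rowMeans(sdv^2)), nrow(sdv), ncol(sdv))
  }
  structure(list(mean = mu, sd = pmax(sdv, 1e-12), freqs = freqs,
                 times = times, n = n, time_resolved = time_resolved),
            class = "baseline_stats")
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat(sprintf("<baseline_stats> %d epochs, %d freqs x %d frames, %s\n",
              x$n, length(x$freqs), length(x$times),
              if (x$time_resolved) "time-resolved" else "time-collapsed"))
  invisible(x)
}

#' Z-score an event spectrogram against baseline statistics
#'
#' `(|S| - mean) / sd` elementwise, using the baseline mean and SD per
#' frequency bin (and time frame).
#'
#' @param epoch a single-channel `time_series` epoch, or a `tf_map` of kind
#'   `"stockwell"` already computed on the same grid.
#' @param baseline a [baseline_stats()] object.
#' @param channel channel index used when the epoch is multichannel.
#' @return a [tf_map()] of kind `"zscore"`.
#' @export
zscore_spectrogram <- function(epoch, baseline, channel = 1L) {
  s <- if (inherits(epoch, "tf_map")) epoch else
    stockwell_transform(ts_channels(epoch, channel),
                        max(baseline$freqs))
  if (length(s$freqs) != length(baseline$freqs) ||
      length(s$times) != length(baseline$times))
    stop("spectrogram axes do not match the baseline statistics")
  tf_map((Mod(s$values) - baseline$mean) / baseline$sd,
         baseline$freqs, s$times, kind = "zscore")
}

#' Across-event average z-scored spectrogram with significance contour
#'
#' @param epochs list of single-channel epochs (or z-scored `tf_map`s).
#' @param baseline a [baseline_stats()]; ignored when `epochs` are already
#'   z-scored maps.
#' @param z_threshold significance threshold on the average map (default 5).
#' @param channel channel index for multichannel epochs.
#' @return list with `map` (average [tf_map()], kind `"zscore"`) and `mask`
#'   (logical matrix, TRUE where the average z exceeds `z_threshold`).
#' @export
average_spectrogram <- function(epochs, baseline = NULL, z_threshold = 5,
                                channel = 1L) {
  stopifnot(length(epochs) >= 1L)
  zs <- lapply(epochs, function(e)
    if (inherits(e, "tf_map") && e$kind == "zscore") e
    else zscore_spectrogram(e, baseline, channel))
  avg <- Reduce(`+`, lapply(zs, function(z) Re(z$values))) / length(zs)
  map <- tf_map(avg, zs[[1]]$freqs, zs[[1]]$times, kind = "zscore")
  list(map = map, mask = avg > z_threshold)
}
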