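## build a tapered high-frequency burst inside coloured noise
burst_in_noise <- function(n_cycles, f_burst, snr, fs = 4000, dur = 4,
                           seed = 1) {
  set.seed(seed)
  x <- fripple:::one_over_f(dur * fs, fs, 1)
  d <- n_cycles / f_burst
  i0 <- round(dur / 2 * fs)
  idx <- i0:(i0 + round(d * fs) - 1L)
  tau <- (idx - i0) / fs
  x[idx] <- x[idx] + snr * fripple:::tukey_window(length(idx), 0.1) *
    cos(2 * pi * f_burst * tau)
  list(ts = time_series(x, fs), onset = (i0 - 1) / fs)
}

test_that("the fast-ripple detector enforces the cycle and amplitude criteria", {
  fs <- 4000
  ## zero signal: no events
  expect_equal(nrow(detect_fast_ripples(time_series(rep(0, fs * 2), fs))), 0L)
  ## a 3-cycle burst at 10x SD is rejected (at least four oscillations rule)
  b3 <- burst_in_noise(3, 450, 10, seed = 5)
  expect_equal(nrow(detect_fast_ripples(b3$ts)), 0L)
  ## an 8-cycle 450 Hz burst at 5x SD yields exactly one event with an
  ## accurate onset, across seeded trials
  for (sd in 1:20) {
    b8 <- burst_in_noise(8, 450, 5, seed = 100 + sd)
    det <- detect_fast_ripples(b8$ts)
    expect_equal(nrow(det), 1L)
    expect_lt(abs(det$onset_s[1] - b8$onset), 0.002)
    expect_gte(det$n_cycles[1], 4L)
    expect_gt(det$amp_ratio[1], 3)
  }
})

test_that("fast-ripple detection is invariant to signal scaling", {
  b <- burst_in_noise(8, 450, 5, seed = 9)
  d1 <- detect_fast_ripples(b$ts)
  d2 <- detect_fast_ripples(time_series(b$ts$samples * 1000, b$ts$fs))
  expect_equal(d1$onset_s, d2$onset_s)
  expect_equal(d1$n_cycles, d2$n_cycles)
  expect_equal(d1$amp_ratio, d2$amp_ratio, tolerance = 1e-9)
})

test_that("false-positive rate on pure 1/f noise is below 0.1 per minute", {
  n_fp <- 0L
  minutes <- 0
  for (sd in 1:8) {
    set.seed(400 + sd)
    x <- fripple:::one_over_f(60 * 4000, 4000, 1)
    n_fp <- n_fp + nrow(detect_fast_ripples(time_series(x, 4000)))
    minutes <- minutes + 1
  }
  expect_lt(n_fp / minutes, 0.1)
})

test_that("multiunit threshold follows the robust-median formula", {
  fs <- 16000
  ## constant |x| = c: threshold = 4c / 0.6745 (checked via the formula on
  ## the already-filtered trace)
  x <- rep(c(2, -2), fs / 2)
  expect_equal(4 * median(abs(x) / 0.6745), 4 * 2 / 0.6745)
  ## unit Gaussian: threshold 4.0 +- 0.02 SD units (median |N(0,1)| = 0.6745)
  set.seed(2)
  g <- rnorm(1e6)
  expect_equal(4 * median(abs(g) / 0.6745), 4, tolerance = 0.02 / 4)
  ## infeasible band names a fallback
  expect_error(detect_mua_spikes(time_series(rnorm(4000), 4000)),
               "reduced band")
})

test_that("an inserted large biphasic spike is detected at its time", {
  fs <- 16000
  set.seed(11)
  x <- rnorm(fs %/% 2)   # 0.5 s: keeps expected chance crossings << 1
  kern <- fripple:::spike_kernel(fs)
  sigma_band <- sd(bandpass_filter(time_series(x, fs), 300,
                                   6000)$samples[, 1])
  t_spk <- 0.25
  off <- which.min(kern) - 1L
  i0 <- round(t_spk * fs) + 1L - off
  x[i0:(i0 + length(kern) - 1L)] <- x[i0:(i0 + length(kern) - 1L)] +
    10 * sigma_band * kern
  det <- detect_mua_spikes(time_series(x, fs))
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$time_s[1] - t_spk), 5e-4)
  expect_true(isTRUE(attr(det, "band_reduced")) == FALSE)
})

test_that("spike trains injected by the generator are recovered", {
  g <- desk_fixture()
  fc <- ts_channels(g$recording, "FC")
  mua <- detect_mua_spikes(fc, band = c(300, 1900))
  expect_true(attr(mua, "band_reduced"))
  m2 <- mua$time_s[mua$channel == "FC2"]
  tr <- g$truth$spike_times[[2]]
  err <- vapply(tr, function(x) min(abs(m2 - x)), numeric(1))
  expect_gt(mean(err < 5e-4), 0.9)
  ## refractory period holds
  expect_true(all(diff(sort(m2)) >= 0.001 - 1e-9))
})

test_that("IED association is a threshold on the 20-30 Hz z-score", {
  z0 <- tf_map(matrix(0, 30, 10), freqs = seq(2, 60, 2), times = 1:10 / 10,
               kind = "zscore")
  expect_false(classify_ied_association(z0)$associated)
  v <- matrix(0, 30, 10); v[13, 4] <- 2.5   # 26 Hz
  z1 <- tf_map(v, freqs = seq(2, 60, 2), times = 1:10 / 10, kind = "zscore")
  ## the literal per-cell reading flags a single suprathreshold cell
  r <- classify_ied_association(z1, reduce = "cell_max")
  expect_true(r$associated)
  expect_equal(r$max_z, 2.5)
  ## the default band-mean reduction requires sustained band power
  expect_false(classify_ied_association(z1)$associated)
  v2 <- v; v2[13, ] <- 2.5
  z2 <- tf_map(v2, freqs = seq(2, 60, 2), times = 1:10 / 10, kind = "zscore")
  expect_true(classify_ied_association(z2)$associated)
  zbad <- tf_map(matrix(0, 5, 10), freqs = 1:5, times = 1:10 / 10,
                 kind = "zscore")
  expect_error(classify_ied_association(zbad), "cover")
})

test_that("generated complexes classify as IED-associated, noise does not", {
  g <- desk_fixture()
  lfp <- desk_lfp_fc()
  on <- fc_fr_onsets()
  cw <- fc_complex_windows()
  win <- c(-0.5, 0.5)
  bep <- sample_baseline_epochs(lfp, cw, 30, win, guard = 0.25, seed = 3)
  bs <- baseline_stats(bep, 60)
  zm <- lapply(extract_epochs(lfp, on, win), zscore_spectrogram,
               baseline = bs)
  assoc <- vapply(zm, function(z) classify_ied_association(z)$associated,
                  logical(1))
  expect_gte(mean(assoc), 0.95)
  ## baseline epochs themselves are mostly not associated
  zb <- lapply(bep[1:20], zscore_spectrogram, baseline = bs)
  assoc_b <- vapply(zb, function(z) classify_ied_association(z)$associated,
                    logical(1))
  expect_lt(mean(assoc_b), 0.4)
})

test_that("band onset finds a step and returns the no-onset sentinel", {
  mk_z <- function(vals) {
    m <- matrix(0, 10, length(vals))
    m[4:6, ] <- rep(vals, each = 3)
    tf_map(m, freqs = seq(1, 10), times = seq(-0.5, 0.5,
                                              length.out = length(vals)),
           kind = "zscore")
  }
  ## all-baseline epochs: no onset
  flat <- replicate(5, mk_z(rep(0, 101)), simplify = FALSE)
  expect_true(is.na(band_onset(flat, c(4, 6))$onset))
  ## common step from 0 to 10 at t = -0.4
  vals <- ifelse(seq(-0.5, 0.5, length.out = 101) >= -0.4, 10, 0)
  stepped <- replicate(5, mk_z(vals), simplify = FALSE)
  bo <- band_onset(stepped, c(4, 6))
  expect_equal(bo$onset, -0.4, tolerance = 0.02)
})

test_that("regional slow-band onsets recover the built-in lead", {
  ## exaggerated 160 ms LH lead, enough events to stabilise the median
  cfg <- desk_profile(seed = 55, duration = 500, n_complexes = 150,
                      n_channels = 2, lag_LH_FC = 0.16, lag_RH_FC = 0.05,
                      drive_gain = 0, mua_rate = 5)
  g <- generate_recording(cfg)
  on <- g$truth$fr_onsets$onset_s[g$truth$fr_onsets$region == "FC"]
  cw <- g$truth$complex_windows[g$truth$complex_windows$region == "FC",
                                c("start", "end")]
  win <- c(-0.9, 0.8)
  onset_of <- function(r) {
    ch <- decimate_ts(ts_channels(ts_channels(g$recording, r), 1L), 1000)
    bs <- baseline_stats(sample_baseline_epochs(ch, cw, 120, win,
                                                guard = 0.5, seed = 2), 40)
    zm <- lapply(extract_epochs(ch, on, win), zscore_spectrogram,
                 baseline = bs)
    band_onset(zm, c(3, 5))$onset
  }
  d <- onset_of("LH") - onset_of("FC")
  expect_equal(d, -0.16, tolerance = 0.025 / 0.16)
})
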