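test_that("band-pass filter matches the analytic forward-backward Butterworth response", {
  fs <- 16000
  ## passband tone: amplitude within 1% of the closed-form |H|^2
  ts400 <- sine_ts(400, fs, 10)
  out <- bandpass_filter(ts400, 200, 550)
  amp <- max(out$samples[40000:120000, 1])
  expect_equal(amp, fripple:::butter_bandpass_gain2(400, 200, 550, fs),
               tolerance = 0.01)
  ## stopband tone bounded by the analytic stopband gain
  ts50 <- sine_ts(50, fs, 10)
  out50 <- bandpass_filter(ts50, 200, 550)
  expect_lt(max(abs(out50$samples[40000:120000, 1])),
            1.05 * fripple:::butter_bandpass_gain2(50, 200, 550, fs))
  ## linearity: zero in, zero out
  expect_equal(bandpass_filter(time_series(rep(0, 4000), fs), 200, 550)$samples,
               matrix(0, 4000, 1))
  ## errors
  expect_error(bandpass_filter(ts400, 300, 9000), "invalid band")
  expect_error(bandpass_filter(time_series(rnorm(10), fs), 200, 550),
               "too short")
})

test_that("passband filtering is nearly idempotent", {
  fs <- 16000
  ts <- sine_ts(400, fs, 5)
  once <- bandpass_filter(ts, 200, 550)
  twice <- bandpass_filter(once, 200, 550)
  g2 <- fripple:::butter_bandpass_gain2(400, 200, 550, fs)
  mid <- 30000:50000
  ratio <- max(twice$samples[mid, 1]) / max(once$samples[mid, 1])
  expect_equal(ratio, g2, tolerance = 0.01)
})

test_that("bipolar montage differences successive contacts per probe", {
  n <- 1000
  ## two identical channels cancel
  m <- matrix(rnorm(n), n, 2)
  ts <- time_series(m, 1000)
  bip <- bipolar_montage(ts)
  expect_equal(ncol(bip$samples), 1L)
  expect_equal(bip$samples[, 1], rep(0, n))
  expect_equal(unique(bip$channels$montage), "bipolar")
  ## constant channels [c, 0] -> bipolar = c
  ts2 <- time_series(cbind(rep(3, n), rep(0, n)), 1000)
  expect_equal(bipolar_montage(ts2)$samples[, 1], rep(3, n))
  ## 16 contacts -> 15 bipolar channels equal to direct subtraction
  m16 <- matrix(rnorm(n * 16), n, 16)
  bip16 <- bipolar_montage(time_series(m16, 1000))
  expect_equal(ncol(bip16$samples), 15L)
  for (k in 1:15)
    expect_equal(bip16$samples[, k], m16[, k] - m16[, k + 1])
  ## single contact errors
  expect_error(bipolar_montage(time_series(rnorm(n), 1000)), "montage")
})

test_that("analytic signal uses the cosine phase convention", {
  fs <- 1000
  ts <- sine_ts(4, fs, 10, amp = 2.5)
  ap <- analytic_phase_amplitude(ts, c(3, 5))
  ## phase ~ 0 at signal peaks
  pk <- which(diff(sign(diff(ts$samples[, 1]))) < 0) + 1L
  pk <- pk[pk > 2000 & pk < 8000]
  expect_lt(max(abs(ap$phase[pk, 1])), 0.06)
  ## envelope ~ amplitude away from edges
  expect_equal(mean(ap$amplitude[2000:8000, 1]), 2.5, tolerance = 0.01)
  ## unwrapped phase slope = 2 pi f
  ph <- ap$phase[2000:8000, 1]
  up <- cumsum(c(ph[1], wrap_pi(diff(ph))))
  slope <- stats::coef(stats::lm(up ~ seq_along(up)))[2] * fs
  expect_equal(as.numeric(slope), 2 * pi * 4, tolerance = 0.01 * 2 * pi * 4)
})

test_that("AM envelope is recovered by the analytic amplitude", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  env <- 1 + 0.5 * cos(2 * pi * 4 * t)
  ts <- time_series(env * cos(2 * pi * 27 * t), fs)
  ap <- analytic_phase_amplitude(ts, c(24, 30))
  expect_gt(stats::cor(ap$amplitude[2000:8000, 1], env[2000:8000]), 0.99)
})

test_that("phase of -x is the phase of x shifted by pi", {
  fs <- 500
  ts <- time_series(rnorm(4000), fs)
  p1 <- analytic_phase_amplitude(ts, c(5, 15))$phase[500:3500, 1]
  tsn <- time_series(-ts$samples[, 1], fs)
  p2 <- analytic_phase_amplitude(tsn, c(5, 15))$phase[500:3500, 1]
  d <- wrap_pi(p1 - p2)
  expect_lt(max(abs(abs(d) - pi)), 1e-6)
})

test_that("Stockwell transform equals the brute-force definition", {
  set.seed(42)
  N <- 128; fs <- 128
  x <- rnorm(N)
  S <- stockwell_transform(time_series(x, fs), 60, pad = "none")
  ## direct DFT, no FFT
  X <- sapply(0:(N - 1), function(k)
    sum(x * exp(-2i * pi * (0:(N - 1)) * k / N))) / N
  n_max <- floor(60 * N / fs)
  m <- 0:(N - 1)
  mm <- ifelse(m < N / 2, m, m - N)
  Sb <- matrix(0 + 0i, n_max + 1, N)
  Sb[1, ] <- mean(x)
  for (v in 1:n_max) {
    G <- exp(-2 * pi^2 * mm^2 / v^2)
    Xs <- X[(m + v) %% N + 1]
    for (tau in 0:(N - 1))
      Sb[v + 1, tau + 1] <- sum(Xs * G * exp(2i * pi * m * tau / N))
  }
  expect_lt(max(abs(S$values - Sb)), 1e-9)
  ## spectral-marginal consistency: the time average of each row recovers
  ## the DFT coefficient
  expect_lt(max(abs(rowMeans(S$values)[-1] - X[2:(n_max + 1)])), 1e-9)
})

test_that("Stockwell transform localises tones and DC", {
  ## constant signal: all energy in the 0 Hz row
  Sc <- stockwell_transform(time_series(rep(2, 256), 256), 50, pad = "none")
  expect_equal(Re(Sc$values[1, ]), rep(2, 256))
  expect_lt(max(Mod(Sc$values[-1, ])), 1e-8)
  ## 10 Hz unit sine: row of maximal mean magnitude is the 10 Hz row
  S10 <- stockwell_transform(sine_ts(10, 1000, 1), 50)
  expect_equal(S10$freqs[which.max(rowMeans(Mod(S10$values)))], 10)
  expect_error(stockwell_transform(sine_ts(10, 1000, 1), 600), "invalid")
})

test_that("Morlet transform equals direct convolution with the sampled wavelet", {
  set.seed(7)
  fs <- 1000
  x <- rnorm(400)
  M <- morlet_transform(time_series(x, fs), freqs = 20, pad = "none")
  k <- fripple:::morlet_wavelet(20, fs, 7)
  h <- (length(k) - 1L) / 2L
  direct <- sapply(seq_len(400), function(tt) {
    s <- seq_len(400)
    w <- h + 1L + (tt - s)
    ok <- w >= 1 & w <= length(k)
    sum(x[s[ok]] * k[w[ok]])
  })
  expect_lt(max(abs(M$values[1, ] - direct)), 1e-9)
})

test_that("Morlet transform localises tones and vanishes on zero input", {
  fs <- 500
  M <- morlet_transform(sine_ts(12, fs, 2), freqs = seq(2, 40, 2))
  mid <- 400:600
  expect_equal(M$freqs[which.max(rowMeans(Mod(M$values[, mid])))], 12)
  Z <- morlet_transform(time_series(rep(0, 1000), fs), freqs = c(5, 10))
  expect_equal(max(Mod(Z$values)), 0)
  expect_error(morlet_transform(sine_ts(12, fs, 2), freqs = numeric(0)),
               "empty")
})

test_that("epoch extraction follows the half-open onset-at-or-before convention", {
  fs <- 1000
  ts <- time_series(seq_len(3000), fs)   # sample value = 1-based index
  ep <- extract_epochs(ts, 1.0, c(-0.2, 0.6))
  expect_length(ep, 1L)
  expect_equal(nrow(ep[[1]]$samples), 800L)
  ## onset 1.0 s -> sample index 1001 (1-based); epoch starts at 801
  expect_equal(ep[[1]]$samples[1, 1], 801)
  expect_equal(ep[[1]]$t0, -0.2)
  ## out-of-bounds onset dropped and reported
  ep2 <- suppressMessages(extract_epochs(ts, c(0.05, 1.0), c(-0.2, 0.6)))
  expect_length(ep2, 1L)
  expect_equal(attr(ep2, "dropped"), 0.05)
  ## empty onset list -> empty result
  expect_length(extract_epochs(ts, numeric(0), c(-0.2, 0.6)), 0L)
  ## epochs are bit-identical to direct slices
  set.seed(1)
  tsr <- time_series(rnorm(3000), fs)
  ons <- runif(10, 0.5, 2.2)
  eps <- extract_epochs(tsr, ons, c(-0.1, 0.1))
  for (k in seq_along(ons)) {
    i0 <- floor(ons[k] * fs) + 1L
    expect_identical(eps[[k]]$samples[, 1],
                     tsr$samples[(i0 - 100):(i0 + 99), 1])
  }
})

test_that("recordings round-trip through the flat-binary + JSON dialect", {
  g <- desk_fixture()
  rec <- ts_channels(g$recording, "LH")
  rec$samples <- rec$samples[1:2000, , drop = FALSE]
  path <- file.path(tempdir(), "rec_test")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$channels$region, rec$channels$region)
  ## float32 storage: read-back equals the float32 cast, and a second
  ## round trip is bit-identical
  write_recording(back, path)
  back2 <- read_recording(path)
  expect_identical(back$samples, back2$samples)
  expect_lt(max(abs(back$samples - rec$samples)), 1e-3 * max(abs(rec$samples)))
  expect_error(read_recording(file.path(tempdir(), "nope")), "sidecar")
})
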