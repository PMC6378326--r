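## simulate a stationary bivariate VAR(1)
sim_var1 <- function(A, n, seed) {
  set.seed(seed)
  y <- matrix(0, n, 2)
  for (t in 2:n) y[t, ] <- A %*% y[t - 1, ] + rnorm(2)
  y
}

test_that("Kalman-TVAR time averages converge to the OLS VAR solution", {
  A <- matrix(c(0.5, 0, 0.3, 0.4), 2, 2, byrow = TRUE)
  y <- sim_var1(A, 10000, seed = 3)
  m <- fit_tvar_kalman(time_series(y, 100), order = 1, rate = 0.001)
  est <- t(apply(m$coef[, , 5000:10000], c(1, 2), mean))
  X <- y[1:9999, ]; Y <- y[2:10000, ]
  ols <- t(solve(t(X) %*% X, t(X) %*% Y))
  expect_lt(max(abs(est - ols)), 0.05)
  expect_lt(max(abs(est - A)), 0.05)
  expect_true(m$stable)
  ## smaller rates get closer to OLS on stationary data
  devs <- vapply(c(0.05, 0.01, 0.001), function(rate) {
    mm <- fit_tvar_kalman(time_series(y, 100), order = 1, rate = rate)
    max(abs(t(apply(mm$coef[, , 5000:10000], c(1, 2), mean)) - ols))
  }, numeric(1))
  expect_true(devs[3] < devs[1])
})

test_that("independent white channels give near-zero cross coefficients", {
  set.seed(6)
  y <- matrix(rnorm(2 * 16000), ncol = 2)
  m <- fit_tvar_kalman(time_series(y, 100), order = 1, rate = 0.001)
  cross <- apply(m$coef[, , 8000:16000], c(1, 2), mean)
  ## coef[(j-1)p+m, i]: off-diagonal entries are (source 2, sink 1) and
  ## (source 1, sink 2)
  expect_lt(abs(cross[2, 1]), 0.02)
  expect_lt(abs(cross[1, 2]), 0.02)
})

test_that("faster adaptation tracks a coefficient switch sooner", {
  set.seed(8)
  n <- 6000
  y <- matrix(0, n, 2)
  for (t in 2:n) {
    a <- if (t <= n / 2) 0.8 else -0.5
    y[t, 1] <- a * y[t - 1, 1] + rnorm(1)
    y[t, 2] <- 0.3 * y[t - 1, 2] + rnorm(1)
  }
  settle <- vapply(c(0.002, 0.01, 0.05), function(rate) {
    m <- fit_tvar_kalman(time_series(y, 100), order = 1, rate = rate)
    a11 <- m$coef[1, 1, (n / 2 + 1):n]
    which(a11 < -0.3)[1]
  }, numeric(1))
  expect_true(all(diff(settle) < 0))
})

test_that("APDC respects structure and its normalisation identity", {
  ## hand-built diagonal model: no cross flows
  K <- 3; p <- 2; nt <- 20
  coef <- array(0, c(K * p, K, nt))
  for (i in 1:K) coef[(i - 1) * p + 1, i, ] <- 0.5
  model <- structure(list(coef = coef, order = p, rate = 0, fs = 100,
                          K = K, resid_var = rep(1, K),
                          ridge_flagged = FALSE, stable = TRUE,
                          channels = c("a", "b", "c")),
                     class = "tvar_model")
  ap <- apdc_spectrum(model, freqs = c(2, 10), t_idx = c(5, 10))
  off <- ap$apdc2
  for (i in 1:K) off[i, i, , ] <- 0
  expect_equal(max(off), 0)
  ## sink normalisation: sum over sources = 1 at every (f, t)
  expect_equal(max(abs(apply(ap$apdc2, c(1, 3, 4), sum) - 1)), 0,
               tolerance = 1e-12)
  ## source normalisation: sum over sinks = 1
  aps <- apdc_spectrum(model, freqs = c(2, 10), t_idx = c(5, 10),
                       normalization = "source")
  expect_equal(max(abs(apply(aps$apdc2, c(2, 3, 4), sum) - 1)), 0,
               tolerance = 1e-12)
  expect_error(apdc_spectrum(model, freqs = 60), "invalid")
})

test_that("band integration averages the normalised quantity", {
  K <- 2; p <- 1; nt <- 4
  coef <- array(0.2, c(K * p, K, nt))
  model <- structure(list(coef = coef, order = p, rate = 0, fs = 100,
                          K = K, resid_var = rep(1, K),
                          ridge_flagged = FALSE, stable = TRUE,
                          channels = c("a", "b")),
                     class = "tvar_model")
  ap <- apdc_spectrum(model, freqs = c(3, 4, 5), t_idx = 1:nt)
  ia <- iapdc_band(ap, 3, 5)
  ## averaging identity: mean over the grid of the per-bin values
  expect_equal(ia[2, 1, 1], mean(ap$apdc2[2, 1, , 1]))
  ## a one-bin band equals that bin
  ia1 <- iapdc_band(ap, 4, 4.4)
  expect_equal(ia1[2, 1, 1], ap$apdc2[2, 1, 2, 1])
  expect_error(iapdc_band(ap, 7, 9), "empty")
})

test_that("directed flow is attributed to the resonant driver", {
  fs <- 100; n <- 6000
  r <- 0.95; om <- 2 * pi * 4 / fs
  wins <- 0L
  for (sd in 1:15) {
    set.seed(sd)
    x <- numeric(n); y <- numeric(n)
    for (t in 3:n) {
      x[t] <- 2 * r * cos(om) * x[t - 1] - r^2 * x[t - 2] + rnorm(1)
      y[t] <- 0.5 * y[t - 1] + 0.4 * x[t - 1] + rnorm(1)
    }
    m <- fit_tvar_kalman(time_series(cbind(x, y), fs), order = 2,
                         rate = 0.002)
    ap <- apdc_spectrum(m, freqs = seq(3.5, 4.5, 0.25),
                        t_idx = seq(2000, n, by = 40),
                        normalization = "source")
    ia <- iapdc_band(ap, 3.5, 4.5)
    wins <- wins + (median(ia[2, 1, ]) > median(ia[1, 2, ]))
  }
  expect_gte(wins, 14L)
})

test_that("cross-correlation lags follow the stated sign convention", {
  fs <- 1000
  set.seed(2)
  sig <- as.numeric(stats::filter(rnorm(6000), rep(1, 20), sides = 2))
  sig[is.na(sig)] <- 0
  a <- time_series(sig[65:4564], fs)
  b <- time_series(sig[1:4500], fs)        # b delayed by 64 ms
  lg <- bandlimited_crosscorr_lag(a, b, c(3, 5), 0.2)
  expect_equal(lg$lag_s, -0.064)
  ## identical signals: zero lag; antisymmetry
  expect_equal(bandlimited_crosscorr_lag(a, a, c(3, 5), 0.2)$lag_s, 0)
  lg2 <- bandlimited_crosscorr_lag(b, a, c(3, 5), 0.2)
  expect_equal(lg2$lag_s, -lg$lag_s)
  expect_error(bandlimited_crosscorr_lag(a, b, c(3, 5), 3), "max_lag")
  ## coupled signals correlate better than independent ones
  set.seed(7)
  ind <- bandlimited_crosscorr_lag(time_series(rnorm(4500), fs),
                                   time_series(rnorm(4500), fs),
                                   c(3, 5), 0.2)
  expect_gt(lg$r_max, ind$r_max)
})

test_that("increasing the generator drive raises hippocampus-to-cortex flow only", {
  iapdc_at <- function(sd, gain) {
    g <- generate_recording(desk_profile(
      seed = sd, duration = 90, n_complexes = 25, drive_gain = gain))
    lfp <- decimate_ts(decimate_ts(g$recording, 200), 50)
    mm <- sapply(c("LH", "RH", "FC"), function(rg)
      rowMeans(ts_channels(lfp, rg)$samples))
    m <- fit_tvar_kalman(time_series(mm, 50), order = 5, rate = 0.02)
    fw <- g$truth$complex_windows[g$truth$complex_windows$region == "FC", ]
    poi <- unique(unlist(lapply(seq_len(nrow(fw)), function(k)
      seq(round(fw$start[k] * 50), round(fw$end[k] * 50)))))
    poi <- poi[poi > 5 & poi <= dim(m$coef)[3]]
    ap <- apdc_spectrum(m, freqs = seq(3, 5, 0.5), t_idx = poi,
                        normalization = "source")
    ia <- iapdc_band(ap, 3, 5)
    c(lhfc = median(ia[3, 1, ]), fclh = median(ia[1, 3, ]))
  }
  seeds <- 1:6
  g0 <- t(vapply(seeds, iapdc_at, numeric(2), gain = 0))
  g1 <- t(vapply(seeds, iapdc_at, numeric(2), gain = 0.5))
  expect_gte(mean(g1[, "lhfc"] > g0[, "lhfc"]), 5 / 6)
  expect_gt(mean(g1[, "lhfc"] - g0[, "lhfc"]), 0)
  expect_lte(mean(g1[, "fclh"] - g0[, "fclh"]), 0.01)
})

test_that("condition comparisons report medians, percent change and rank p", {
  set.seed(5)
  K <- 2
  poi <- array(runif(K * K * 60), c(K, K, 60))
  ## identical conditions: 0% difference, non-significant
  d0 <- directed_comparison(poi, poi, labels = c("LH", "FC"))
  expect_equal(d0$diff_percent, rep(0, 2))
  expect_true(all(d0$p > 0.9))
  ## a location shift is detected with the right sign
  shift <- poi + 0.3
  d1 <- directed_comparison(shift, poi, labels = c("LH", "FC"))
  expect_true(all(d1$diff_percent > 0))
  expect_true(all(d1$p < 0.01))
  expect_error(directed_comparison(poi, array(0, c(3, 3, 60))), "unmatched")
})
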