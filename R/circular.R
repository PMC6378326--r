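#' Circular mean, resultant length and von Mises concentration
#'
#' Standard directional-statistics estimators: the circular mean is the
#' argument of the mean resultant vector, the concentration kappa is the
#' maximum-likelihood inverse of the mean resultant length R (Fisher's
#' piecewise approximation, with the usual small-sample correction for
#' n < 15).
#'
#' @param angles radians.
#' @param weights optional non-negative weights.
#' @return list with `mu` (radians in (-pi, pi]), `R` (mean resultant
#'   length in [0, 1]), `kappa` (>= 0) and `n`.
#' @export
circ_mean_kappa <- function(angles, weights = NULL) {
  n <- length(angles)
  if (n < 1L) stop("empty circular sample")
  if (is.null(weights)) weights <- rep(1, n)
  z <- sum(weights * exp(1i * angles)) / sum(weights)
  R <- Mod(z)
  list(mu = Arg(z), R = R, kappa = kappa_from_R(R, n), n = n)
}

## ML inverse of the mean resultant length (Fisher 1993), with the standard
## small-sample bias correction for n < 15
kappa_from_R <- function(R, n = Inf) {
  if (R < 1e-12) return(0)
  k <- if (R < 0.53) 2 * R + R^3 + 5 * R^5 / 6
       else if (R < 0.85) -0.4 + 1.39 * R + 0.43 / (1 - R)
       else 1 / (R^3 - 4 * R^2 + 3 * R)
  if (is.finite(n) && n < 15) {
    k <- if (k < 2) max(k - 2 / (n * k), 0) else k * (n - 1)^3 / (n^3 + n)
  }
  k
}

#' Draw from the von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` returns uniform angles.
#'
#' @param n sample size.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0).
#' @return radians in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa < 1e-9) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r0 <- (1 + b^2) / (2 * b)
  out <- numeric(n); got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r0 * z) / (r0 + z)
    c0 <- kappa * (r0 - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    if (any(ok)) {
      th <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
      take <- min(length(th), n - got)
      out[(got + 1L):(got + take)] <- th[seq_len(take)]
      got <- got + take
    }
  }
  wrap_pi(out + mu)
}

## wrap angles to (-pi, pi]
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Rayleigh test for circular nonuniformity
#'
#' Tests uniformity against a unimodal alternative with the statistic
#' Z = n R^2 and the standard finite-n corrected p-value.
#'
#' @param angles radians.
#' @return list with `Z`, `p`, `n`, `R` and `small_n` (TRUE when n < 5,
#'   where the approximation is unreliable).
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 1L) stop("empty sample")
  R <- Mod(mean(exp(1i * angles)))
  Z <- n * R^2
  Rn <- n * R
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  list(Z = Z, p = min(1, p), n = n, R = R, small_n = n < 5)
}

#' Watson-Williams test for equal circular means
#'
#' One-way F-test for the equality of two mean directions, with the
#' concentration-based correction factor 1 + 3/(8 kappa). Nominally valid
#' for pooled mean resultant length above ~0.45 (kappa above ~1); the
#' result carries a `valid` flag.
#'
#' @param a,b circular samples (radians).
#' @return list with `F`, `p`, `df`, `valid`, plus the per-sample and
#'   pooled resultant lengths.
#' @export
watson_williams_test <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  stopifnot(n1 >= 2L, n2 >= 2L)
  R1 <- n1 * Mod(mean(exp(1i * a)))
  R2 <- n2 * Mod(mean(exp(1i * b)))
  R <- Mod(sum(exp(1i * c(a, b))))
  rw <- (R1 + R2) / n
  kk <- kappa_from_R(rw)
  corr <- 1 + 3 / (8 * max(kk, 1e-12))
  denom <- n - R1 - R2
  Fst <- if (denom <= 0) 0 else corr * ((n - 2) * (R1 + R2 - R)) / denom
  Fst <- max(Fst, 0)
  p <- stats::pf(Fst, 1, n - 2, lower.tail = FALSE)
  list(F = Fst, p = p, df = c(1, n - 2), valid = rw >= 0.45,
       R1 = R1 / n1, R2 = R2 / n2, rw = rw)
}

#' Test for equal von Mises concentration parameters
#'
#' Fisher's concentrated-case two-sample F-test on the dispersions
#' (n - R): F = [(n2 - 1)(n1 - R1)] / [(n1 - 1)(n2 - R2)], compared to
#' F(n1 - 1, n2 - 1), two-sided. Nominally valid when the pooled mean
#' resultant length exceeds 0.7; the result carries a `valid` flag.
#'
#' @param a,b circular samples (radians).
#' @return list with `F`, `p`, `df`, `valid`, and the per-sample kappas.
#' @export
equal_kappa_test <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 2L, n2 >= 2L)
  R1 <- n1 * Mod(mean(exp(1i * a)))
  R2 <- n2 * Mod(mean(exp(1i * b)))
  rbar <- (R1 + R2) / (n1 + n2)
  f <- ((n2 - 1) * (n1 - R1)) / ((n1 - 1) * (n2 - R2))
  if (f >= 1) {
    p <- 2 * stats::pf(f, n1 - 1, n2 - 1, lower.tail = FALSE)
    df <- c(n1 - 1, n2 - 1)
  } else {
    p <- 2 * stats::pf(1 / f, n2 - 1, n1 - 1, lower.tail = FALSE)
    df <- c(n2 - 1, n1 - 1)
  }
  list(F = f, p = min(1, p), df = df, valid = rbar >= 0.7,
       kappa1 = kappa_from_R(R1 / n1, n1), kappa2 = kappa_from_R(R2 / n2, n2))
}

#' Phase locking of events on a band-limited oscillation
#'
#' Collects the instantaneous phase at each event time and reports the
#' circular mean, concentration and Rayleigh test.
#'
#' @param phase an [analytic_signal()] (first channel used).
#' @param event_times event times in seconds.
#' @return list with `angles`, `mu`, `R`, `kappa`, `p` (Rayleigh), `n`.
#' @export
event_phase_locking <- function(phase, event_times) {
  if (!length(event_times)) stop("empty event list")
  n <- nrow(phase$phase)
  idx <- floor((event_times - phase$t0) * phase$fs) + 1L
  if (any(idx < 1L | idx > n)) stop("events outside phase coverage")
  ang <- phase$phase[idx, 1]
  ck <- circ_mean_kappa(ang)
  rt <- rayleigh_test(ang)
  list(angles = ang, mu = ck$mu, R = ck$R, kappa = ck$kappa, p = rt$p,
       n = length(ang))
}

#' Phase-locking factor across events with phase-randomised control
#'
#' For each frequency bin and time frame, PLF(f, t) is the magnitude of the
#' across-event mean of unit phasors of the Morlet phase. A control matrix
#' is built per event and frequency bin by shuffling phases along time
#' (seeded permutation); an equal-concentration test between observed and
#' control phases is computed per (f, t) and Bonferroni-masked at
#' `alpha / (n_t * n_f)`.
#'
#' @param epochs list of >= 10 single-channel `time_series` epochs of equal
#'   length.
#' @param freqs Morlet centre frequencies, default [default_morlet_freqs()].
#' @param width Morlet width in cycles (default 7).
#' @param alpha uncorrected significance level (default 0.05).
#' @param seed seed for the control permutations.
#' @param channel channel index for multichannel epochs.
#' @return list with `plf` (freq x time), `plf_control`, `p` (equal-kappa
#'   p-values), `mask` (Bonferroni-significant cells where locking exceeds
#'   control), `freqs`, `times`, `n_events`, `valid` (FALSE when fewer than
#'   10 epochs).
#' @export
phase_locking_factor <- function(epochs, freqs = default_morlet_freqs(),
                                 width = 7, alpha = 0.05, seed = 1L,
                                 channel = 1L) {
  n_ev <- length(epochs)
  set.seed(seed)
  ph <- lapply(epochs, function(e)
    Arg(morlet_transform(ts_channels(e, channel), freqs, width)$values))
  nf <- nrow(ph[[1]]); nt <- ncol(ph[[1]])
  zsum <- matrix(0 + 0i, nf, nt); zsum_c <- zsum
  cos_o <- matrix(0, nf, nt); cos_c <- cos_o     # for dispersion later
  ctrl <- vector("list", n_ev)
  for (e in seq_len(n_ev)) {
    p_obs <- ph[[e]]
    p_ctl <- t(apply(p_obs, 1L, sample))         # shuffle along time per bin
    ctrl[[e]] <- p_ctl
    zsum <- zsum + exp(1i * p_obs)
    zsum_c <- zsum_c + exp(1i * p_ctl)
  }
  plf <- Mod(zsum) / n_ev
  plf_c <- Mod(zsum_c) / n_ev
  ## vectorised equal-kappa F-test across events per cell
  R1 <- n_ev * plf; R2 <- n_ev * plf_c
  f <- ((n_ev - 1) * (n_ev - R1)) / ((n_ev - 1) * (n_ev - R2))
  p <- ifelse(f >= 1,
              2 * stats::pf(f, n_ev - 1, n_ev - 1, lower.tail = FALSE),
              2 * stats::pf(1 / f, n_ev - 1, n_ev - 1, lower.tail = FALSE))
  p <- pmin(p, 1)
  alpha_corr <- alpha / (nf * nt)
  mask <- (p < alpha_corr) & (plf > plf_c)
  list(plf = plf, plf_control = plf_c, p = p, mask = mask, freqs = freqs,
       times = ts_times(epochs[[1]]), n_events = n_ev,
       alpha_corrected = alpha_corr, valid = n_ev >= 10)
}

#' Inter-regional phase-synchrony scan
#'
#' For each centre frequency (3 Hz bandwidth, 1 Hz step by default), filters
#' both signals, takes the Hilbert phase difference, and compares its von
#' Mises concentration pooled over all period-of-interest frames against the
#' concentration over baseline frames (kappa ratio, with an equal-kappa test
#' per bin). Inputs must be bipolar-montage channels (reference effects
#' confound phase differences) unless `allow_monopolar = TRUE`.
#'
#' @param ts_a,ts_b single-channel `time_series` on a common clock.
#' @param poi_onsets,baseline_onsets event / baseline onset times (s).
#' @param window analysis window around each onset, default
#'   `c(-0.2, 0.6)`.
#' @param freqs centre frequencies in Hz (default 1:100).
#' @param bw bandwidth in Hz (default 3).
#' @param allow_monopolar set TRUE to override the bipolar-montage check.
#' @return data.frame per bin: `freq`, `kappa_poi`, `kappa_baseline`,
#'   `ratio`, `p` (equal-kappa test).
#' @export
phase_synchrony_scan <- function(ts_a, ts_b, poi_onsets, baseline_onsets,
                                 window = c(-0.2, 0.6), freqs = 1:100,
                                 bw = 3, allow_monopolar = FALSE) {
  stopifnot(ts_a$fs == ts_b$fs, n_samples(ts_a) == n_samples(ts_b))
  if (!allow_monopolar &&
      (any(ts_a$channels$montage != "bipolar") ||
       any(ts_b$channels$montage != "bipolar")))
    stop("phase_synchrony_scan requires bipolar-montage inputs ",
         "(set allow_monopolar = TRUE to override)")
  fs <- ts_a$fs
  idx_of <- function(onsets) {
    lo <- as.integer(round(window[1] * fs))
    len <- as.integer(round(diff(window) * fs))
    unlist(lapply(onsets, function(on) {
      i0 <- floor((on - ts_a$t0) * fs) + 1L + lo
      if (i0 < 1L || i0 + len - 1L > n_samples(ts_a)) return(integer(0))
      i0:(i0 + len - 1L)
    }))
  }
  ip <- idx_of(poi_onsets); ib <- idx_of(baseline_onsets)
  if (!length(ip) || !length(ib)) stop("no in-bounds POI/baseline frames")
  out <- data.frame(freq = freqs, kappa_poi = NA_real_,
                    kappa_baseline = NA_real_, ratio = NA_real_,
                    p = NA_real_)
  for (k in seq_along(freqs)) {
    f0 <- freqs[k]
    band <- c(max(0.25, f0 - bw / 2), min(f0 + bw / 2, fs / 2 * 0.98))
    pa <- analytic_phase_amplitude(ts_a, band)$phase[, 1]
    pb <- analytic_phase_amplitude(ts_b, band)$phase[, 1]
    dphi <- wrap_pi(pa - pb)
    kp <- circ_mean_kappa(dphi[ip])$kappa
    kb <- circ_mean_kappa(dphi[ib])$kappa
    ## the equal-kappa test assumes independent angles: phase differences
    ## decorrelate over ~1/bw s, so the test uses frames subsampled at that
    ## interval (kappas above still use all frames)
    stride <- max(1L, as.integer(round(fs / bw)))
    tst <- equal_kappa_test(dphi[ip[seq(1, length(ip), by = stride)]],
                            dphi[ib[seq(1, length(ib), by = stride)]])
    out$kappa_poi[k] <- kp
    out$kappa_baseline[k] <- kb
    out$ratio[k] <- kp / max(kb, 1e-12)
    out$p[k] <- tst$p
  }
  out
}
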