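#' Fit a time-varying autoregressive model by Kalman filtering
#'
#' Estimates per-sample multivariate AR coefficients with a linear
#' state-space recursion: the state is the stacked coefficient vector of
#' each sink channel, the observation equation regresses the current sample
#' on the `order` past samples of all channels, and a random-walk state
#' model (covariance inflation with rate `rate`) lets the coefficients
#' drift. As `rate` tends to 0 the time-averaged estimates converge to the
#' ordinary least-squares VAR solution; larger rates track changes faster.
#'
#' @param ts a multichannel [time_series()] (K >= 2 channels), typically
#'   decimated to ~1 kHz first (see [decimate_ts()]).
#' @param order AR model order p (default 5).
#' @param rate adaptation (update) coefficient in [0, 1) (default 0.02).
#' @return object of class `tvar_model`: `coef` array of dim
#'   `(K*p, K, n)` (column i of slice t = sink i's coefficients, ordered
#'   source-major by lag), `order`, `rate`, `fs`, `K`, `resid_var`,
#'   `ridge_flagged`, `stable` (companion spectral radius <= 1 + tol at
#'   sampled frames), `channels`.
#' @export
fit_tvar_kalman <- function(ts, order = 5L, rate = 0.02) {
  K <- ncol(ts$samples)
  if (K < 2L) stop("need at least two channels")
  fit <- kalman_tvar_cpp(ts$samples, as.integer(order), rate)
  model <- structure(
    list(coef = fit$coef, order = as.integer(order), rate = rate,
         fs = ts$fs, K = K, resid_var = as.numeric(fit$resid_var),
         ridge_flagged = fit$flagged, channels = ts$channels$id),
    class = "tvar_model")
  model$stable <- tvar_stability(model)
  model
}

#' @export
print.tvar_model <- function(x, ...) {
  cat(sprintf("<tvar_model> K=%d, order=%d, rate=%g, %d frames @ %g Hz, %s\n",
              x$K, x$order, x$rate, dim(x$coef)[3], x$fs,
              if (x$stable) "stable" else "UNSTABLE (flagged)"))
  invisible(x)
}

## coefficient matrices A_m(t) (K x K, rows = sink, cols = source) at frame t;
## coef[(j-1)*p + m, i, t] holds sink i <- source j at lag m
tvar_lag_matrices <- function(model, t) {
  p <- model$order; K <- model$K
  sl <- model$coef[, , t]                 # d x K, column = sink
  lapply(seq_len(p), function(m)
    t(sl[(seq_len(K) - 1L) * p + m, , drop = FALSE]))
}

## max companion-form spectral radius over sampled frames
tvar_stability <- function(model, n_check = 20L, tol = 0.05) {
  nt <- dim(model$coef)[3]
  p <- model$order; K <- model$K
  rad <- 0
  for (t in unique(as.integer(seq(p + 1L, nt, length.out = n_check)))) {
    A <- tvar_lag_matrices(model, t)
    C <- matrix(0, K * p, K * p)
    for (m in seq_len(p)) C[seq_len(K), (m - 1L) * K + seq_len(K)] <- A[[m]]
    if (p > 1L)
      C[K + seq_len(K * (p - 1L)), seq_len(K * (p - 1L))] <-
        diag(K * (p - 1L))
    rad <- max(rad, max(Mod(eigen(C, only.values = TRUE)$values)))
  }
  rad <= 1 + tol
}

#' Adaptive partial directed coherence spectrum
#'
#' Transforms the time-varying AR coefficients to the spectral domain,
#' \eqn{\bar A(f,t) = I - \sum_m A_m(t) e^{-i 2 \pi f m / fs}}, and forms
#' the squared adaptive PDC
#' \eqn{APDC_{ij}^2(f,t) = |\bar A_{ij}(f,t)|^2 / \sum_k |\bar A_{ik}(f,t)|^2}.
#' The default denominator sums over sources k for a fixed sink i (row
#' normalisation, the printed convention of the method this package
#' follows); `normalization = "source"` gives the standard PDC column
#' normalisation over sinks for a fixed source. `include_identity = FALSE`
#' uses the bare Fourier transform of the coefficients without the leading
#' identity term.
#'
#' @param model a [fit_tvar_kalman()] result.
#' @param freqs frequencies in Hz (all < fs/2).
#' @param t_idx time indices at which to evaluate (default: up to 400
#'   frames evenly spanning the recording).
#' @param normalization `"sink"` (default, printed convention) or
#'   `"source"` (standard PDC).
#' @param include_identity include the leading identity term (default TRUE).
#' @return object of class `apdc_result`: `apdc2` array of dim
#'   `(K, K, n_freq, n_t)` with `apdc2[i, j, , ]` the flow j -> i, `freqs`,
#'   `t_idx`, `times` (s), `normalization`, `fs`.
#' @export
apdc_spectrum <- function(model, freqs, t_idx = NULL,
                          normalization = c("sink", "source"),
                          include_identity = TRUE) {
  normalization <- match.arg(normalization)
  if (any(freqs >= model$fs / 2)) stop("invalid frequency above Nyquist")
  nt_all <- dim(model$coef)[3]
  if (is.null(t_idx))
    t_idx <- unique(as.integer(seq(model$order + 1L, nt_all,
                                   length.out = min(400L, nt_all))))
  K <- model$K; p <- model$order
  nf <- length(freqs); nt <- length(t_idx)
  E <- exp(-2i * pi * outer(seq_len(p), freqs) / model$fs)   # p x nf
  apdc2 <- array(0, c(K, K, nf, nt))
  for (u in seq_len(nt)) {
    A <- tvar_lag_matrices(model, t_idx[u])
    for (v in seq_len(nf)) {
      Af <- if (include_identity) diag(K) + 0i else matrix(0 + 0i, K, K)
      for (m in seq_len(p))
        Af <- Af - A[[m]] * E[m, v]
      M <- Mod(Af)^2
      den <- if (normalization == "sink") rowSums(M) else colSums(M)
      den[den < 1e-300] <- 1e-300
      apdc2[, , v, u] <- if (normalization == "sink") M / den
                         else sweep(M, 2L, den, "/")
    }
  }
  structure(list(apdc2 = apdc2, freqs = freqs, t_idx = t_idx,
                 times = (t_idx - 1L) / model$fs, fs = model$fs,
                 normalization = normalization,
                 channels = model$channels),
            class = "apdc_result")
}

#' Band-integrated adaptive partial directed coherence
#'
#' Averages the normalised squared APDC over the discrete frequency grid
#' within `[f1, f2]`, per directed pair and time frame:
#' \eqn{iAPDC_{ij}(t) = \frac{1}{n_f}\sum_{f \in [f_1,f_2]}
#' \frac{|\bar A_{ij}(f,t)|^2}{\sum_k |\bar A_{ik}(f,t)|^2}}.
#'
#' @param result an [apdc_spectrum()] result.
#' @param f1,f2 band edges in Hz, `f1 < f2`, within the computed grid.
#' @return array of dim `(K, K, n_t)`; `[i, j, ]` is the flow j -> i.
#' @export
iapdc_band <- function(result, f1, f2) {
  sel <- which(result$freqs >= f1 & result$freqs <= f2)
  if (f1 >= f2 || !length(sel)) stop("empty frequency band [", f1, ", ", f2, "]")
  out <- apply(result$apdc2[, , sel, , drop = FALSE], c(1, 2, 4), mean)
  dimnames(out) <- list(result$channels, result$channels, NULL)
  out
}

#' Band-limited cross-correlation lag
#'
#' Filters both signals into `band`, slides the first signal over the
#' second and reports the lag maximising the Pearson correlation. The sign
#' convention: a negative lag indicates that the second signal is delayed
#' with respect to the first.
#'
#' @param ts_a,ts_b single-channel `time_series` of equal length and rate.
#' @param band frequency band in Hz, default `c(3, 5)`.
#' @param max_lag maximum |lag| in seconds (must be < length / 2).
#' @return list with `lag_s` (lag at the correlation maximum), `profile`
#'   (data.frame: `lag_s`, `r`), `r_max`.
#' @export
bandlimited_crosscorr_lag <- function(ts_a, ts_b, band = c(3, 5), max_lag) {
  stopifnot(ts_a$fs == ts_b$fs, n_samples(ts_a) == n_samples(ts_b))
  fs <- ts_a$fs; n <- n_samples(ts_a)
  L <- as.integer(round(max_lag * fs))
  if (L >= n / 2) stop("max_lag must be below half the signal length")
  a <- bandpass_filter(ts_a, band[1], band[2])$samples[, 1]
  b <- bandpass_filter(ts_b, band[1], band[2])$samples[, 1]
  lags <- -L:L
  r <- vapply(lags, function(l) {
    ## r(l) = cor(a(t + l), b(t)): peak at l < 0 when b lags a
    if (l >= 0) stats::cor(a[(1 + l):n], b[1:(n - l)])
    else stats::cor(a[1:(n + l)], b[(1 - l):n])
  }, numeric(1))
  i <- which.max(r)
  list(lag_s = lags[i] / fs, profile = data.frame(lag_s = lags / fs, r = r),
       r_max = r[i])
}

#' Compare directed connectivity between conditions
#'
#' Thin contract wrapper: per directed pair, the median band-integrated
#' APDC during the period of interest and during baseline, the percent
#' difference, and a Kruskal-Wallis rank test between the two sets of time
#' frames.
#'
#' @param iapdc_poi,iapdc_baseline arrays from [iapdc_band()] computed on
#'   matched frame counts for the two conditions.
#' @param labels channel/region names (defaults to the array dimnames).
#' @return data.frame: `from`, `to`, `median_baseline`, `median_poi`,
#'   `diff_percent`, `p`.
#' @export
directed_comparison <- function(iapdc_poi, iapdc_baseline, labels = NULL) {
  if (!all(dim(iapdc_poi)[1:2] == dim(iapdc_baseline)[1:2]))
    stop("unmatched condition arrays")
  K <- dim(iapdc_poi)[1]
  if (is.null(labels)) labels <- dimnames(iapdc_poi)[[1]]
  if (is.null(labels)) labels <- paste0("ch", seq_len(K))
  rows <- list()
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    x <- iapdc_poi[i, j, ]; y <- iapdc_baseline[i, j, ]
    med_p <- stats::median(x); med_b <- stats::median(y)
    p <- if (stats::sd(c(x, y)) == 0) 1 else
      stats::kruskal.test(list(x, y))$p.value
    rows[[length(rows) + 1L]] <- data.frame(
      from = labels[j], to = labels[i],
      median_baseline = med_b, median_poi = med_p,
      diff_percent = 100 * (med_p - med_b) / max(med_b, 1e-300), p = p,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
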