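#' Stockwell transform
#'
#' Discrete S-transform in the classic formulation: a frequency-dependent
#' Gaussian window of scale sigma(f) = 1/f, computed row by row from the
#' shifted FFT spectrum. Row 0 carries the signal mean.
#'
#' @param ts single-channel [time_series()].
#' @param f_max highest frequency row to return (Hz, < fs/2).
#' @param pad `"reflect"` (default) mirrors the signal by one window length
#'   on each side and discards the pad, limiting edge ringing on short
#'   event-locked windows; `"none"` computes on the raw samples (the form
#'   matched by the brute-force definition).
#' @return a [tf_map()] of complex coefficients, `kind = "stockwell"`;
#'   frequency resolution is fs / n where n is the (padded) length.
#' @export
stockwell_transform <- function(ts, f_max, pad = c("reflect", "none")) {
  pad <- match.arg(pad)
  if (ncol(ts$samples) != 1L) stop("stockwell_transform expects one channel")
  if (f_max >= ts$fs / 2) stop("invalid f_max: ", f_max, " >= Nyquist")
  x <- as.numeric(ts$samples[, 1])
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  n0 <- length(x)
  if (pad == "reflect") {
    x <- c(rev(x), x, rev(x))
    keep <- n0 + seq_len(n0)
  } else keep <- seq_len(n0)
  N <- length(x)
  X <- stats::fft(x) / N
  n_max <- floor(f_max * N / ts$fs)
  m <- 0:(N - 1)
  mm <- ifelse(m < N / 2, m, m - N)            # wrapped frequency offsets
  S <- matrix(0 + 0i, n_max + 1L, N)
  S[1L, ] <- mean(x)
  for (v in seq_len(n_max)) {
    G <- exp(-2 * pi^2 * mm^2 / v^2)
    Xs <- X[(m + v) %% N + 1L]
    S[v + 1L, ] <- stats::fft(Xs * G, inverse = TRUE)
  }
  tf_map(S[, keep, drop = FALSE],
         freqs = (0:n_max) * ts$fs / N,
         times = ts$t0 + (seq_along(keep) - 1L) / ts$fs,
         kind = "stockwell")
}

#' Default Morlet frequency grid: 199 bins between 1 and 100 Hz
#' @return numeric vector of centre frequencies (Hz).
#' @export
default_morlet_freqs <- function() seq(1, 100, by = 0.5)

## centred FFT convolution, 'same' alignment; k must have odd length
fft_conv_same <- function(x, k) {
  n <- length(x); m <- length(k); h <- (m - 1L) / 2L
  L <- n + m - 1L
  full <- stats::fft(stats::fft(c(x, rep(0, L - n))) *
                     stats::fft(c(k, rep(0, L - m))), inverse = TRUE) / L
  full[(h + 1L):(h + n)]
}

#' Complex Morlet wavelet transform
#'
#' Convolves a single-channel signal with complex Morlet wavelets
#' (width `width` cycles, energy-normalised) at each requested frequency.
#'
#' @param ts single-channel [time_series()].
#' @param freqs centre frequencies in Hz (default [default_morlet_freqs()]),
#'   all within (0, fs/2).
#' @param width wavelet width in cycles (default 7).
#' @param pad `"reflect"` (default) or `"none"`, as in
#'   [stockwell_transform()].
#' @return a [tf_map()] of complex coefficients, `kind = "morlet"`.
#' @export
morlet_transform <- function(ts, freqs = default_morlet_freqs(), width = 7,
                             pad = c("reflect", "none")) {
  pad <- match.arg(pad)
  if (ncol(ts$samples) != 1L) stop("morlet_transform expects one channel")
  if (length(freqs) == 0L) stop("empty frequency grid")
  if (any(freqs <= 0 | freqs >= ts$fs / 2)) stop("freqs outside (0, fs/2)")
  x <- as.numeric(ts$samples[, 1])
  n0 <- length(x)
  if (pad == "reflect") {
    x <- c(rev(x), x, rev(x))
    keep <- n0 + seq_len(n0)
  } else keep <- seq_len(n0)
  out <- matrix(0 + 0i, length(freqs), n0)
  for (i in seq_along(freqs)) {
    k <- morlet_wavelet(freqs[i], ts$fs, width)
    out[i, ] <- fft_conv_same(x, k)[keep]
  }
  tf_map(out, freqs = freqs,
         times = ts$t0 + (seq_len(n0) - 1L) / ts$fs, kind = "morlet")
}

## sampled complex Morlet wavelet, unit L2 energy, odd length (+-4 sigma_t)
morlet_wavelet <- function(f, fs, width = 7) {
  sigma_t <- width / (2 * pi * f)
  hw <- ceiling(4 * sigma_t * fs)
  tt <- (-hw:hw) / fs
  w <- exp(-tt^2 / (2 * sigma_t^2)) * exp(2i * pi * f * tt)
  w / sqrt(sum(Mod(w)^2))
}
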