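#' Configuration for the synthetic multichannel recording generator
#'
#' Defines the study conditions the generator emulates: three regions (left
#' hippocampus LH, right hippocampus RH, frontal cortex FC), each recorded by
#' a 16-contact linear probe at 16 kHz, with transient ~800 ms epileptic
#' complexes containing (i) a 3-5 Hz slow oscillation, (ii) a 20-30 Hz
#' interictal-discharge (IED) burst whose amplitude follows the slow-phase
#' (phase-amplitude coupling), (iii) one fast-ripple (FR) burst locked to a
#' preferred slow phase, plus von Mises phase-locked multiunit spikes,
#' inter-regional lags (hippocampi leading the frontal cortex) and a directed
#' hippocampus-to-cortex drive in the slow band.
#'
#' @param fs sampling rate in Hz (16000 in the emulated study).
#' @param duration recording length in seconds.
#' @param n_complexes number of epileptic complexes to place.
#' @param n_channels contacts per probe (per region).
#' @param slow_freq slow-oscillation frequency in Hz (3-5 Hz band).
#' @param complex_duration length of one complex in seconds.
#' @param pac_phase_freq frequency (Hz) whose phase modulates the IED
#'   amplitude; defaults to `slow_freq` so the complex carries one coherent
#'   slow oscillation and the ground-truth coupling pair is
#'   (`slow_freq`, `pac_amp_freq`).
#' @param pac_amp_freq IED carrier frequency in Hz (amplitude frequency of
#'   the coupling; 27 Hz emulates the study's comodulogram peak).
#' @param pac_depth modulation depth of the IED envelope in [0, 1].
#' @param fr_band fast-ripple band in Hz.
#' @param fr_freq fast-ripple carrier frequency in Hz (inside `fr_band`).
#' @param fr_cycles number of carrier cycles per FR burst (>= 4).
#' @param fr_snr FR peak amplitude as a multiple of the broadband
#'   background SD (absolute FR amplitudes are defined relative to the
#'   background because the emulated study reports none in microvolts).
#' @param mua_rate mean multiunit firing rate per channel, Hz.
#' @param kappa_event,kappa_baseline von Mises concentrations of spike
#'   phase locking inside complexes / at baseline (1.08 and 0.32).
#' @param mu_event,mu_baseline preferred spike phases in radians
#'   (0.56 and 0.18).
#' @param mu_fr slow-oscillation phase at FR onset, radians (1.57).
#' @param lag_LH_FC,lag_RH_FC inter-regional lags in seconds: LH (and RH)
#'   activity leads the FC copy of each complex by these amounts
#'   (64 and 52 ms).
#' @param drive_gain gain (x `slow_amp` x background SD) of the directed
#'   component: the LH-specific stochastic slow activity, shaped by an
#'   AR(2) resonator at `slow_freq`, is added to the FC channels during
#'   complexes. 0 disables it.
#' @param drive_lag transmission delay (s) of the directed LH -> FC
#'   component; keep it within the span of the connectivity model
#'   (order / analysis rate) for the drive to be recoverable.
#' @param background_sd broadband background SD in microvolts.
#' @param background_alpha spectral exponent of the 1/f^alpha background.
#' @param common_mode weight (0-1) of a probe-wide common-mode background
#'   term shared by all contacts of one probe.
#' @param baseline_slow_amp amplitude (x background SD) of the continuous
#'   region-specific narrowband 3-5 Hz component that carries baseline
#'   spike phase locking.
#' @param slow_amp,ied_amp amplitudes (x background SD) of the complex's
#'   slow-oscillation and IED components.
#' @param mua_amp spike waveform peak amplitude (x background SD).
#' @param depth_gradient linear depth gradient of the deterministic LFP
#'   components along each probe (per-contact gain
#'   `1 + depth_gradient * (0.5 - depth_fraction)`): laminar amplitude
#'   gradients are what the bipolar montage measures, so 0 would make the
#'   slow oscillation invisible to bipolar phase analyses.
#' @param laminar_down depth-graded suppression of firing in the down-state
#'   window (-180 to -30 ms before FR onset); 0-1, deepest contact most
#'   suppressed.
#' @param laminar_lead extra lead (s) of the deepest contact's peri-FR
#'   firing increase over the most superficial one.
#' @param seed integer; fully determines the generated recording.
#' @return a `synth_config` list, validated.
#' @export
synth_config <- function(fs = 16000, duration = 60, n_complexes = 30,
                         n_channels = 16, slow_freq = 4,
                         complex_duration = 0.8,
                         pac_phase_freq = slow_freq, pac_amp_freq = 27,
                         pac_depth = 0.8, fr_band = c(200, 550),
                         fr_freq = 450, fr_cycles = 8, fr_snr = 5,
                         mua_rate = 20, kappa_event = 1.08,
                         kappa_baseline = 0.32, mu_event = 0.56,
                         mu_baseline = 0.18, mu_fr = 1.57,
                         lag_LH_FC = 0.064, lag_RH_FC = 0.052,
                         drive_gain = 0.3, drive_lag = 0.040,
                         background_sd = 20,
                         background_alpha = 1, common_mode = 0.2,
                         baseline_slow_amp = 0.8, slow_amp = 8,
                         ied_amp = 3, mua_amp = 10, depth_gradient = 1,
                         laminar_down = 0.8, laminar_lead = 0.005,
                         seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    stopifnot(fs > 0, duration > 0, n_complexes >= 0, n_channels >= 1)
    if (duration * fs > 2^31 - 1) stop("duration * fs overflows sample index")
    for (f in c(slow_freq, pac_phase_freq, pac_amp_freq, fr_freq, fr_band))
      if (f >= fs / 2) stop("frequency ", f, " Hz not below Nyquist (fs = ",
                            fs, ")")
    if (fr_freq < fr_band[1] || fr_freq > fr_band[2])
      stop("fr_freq outside fr_band")
    stopifnot(kappa_event >= 0, kappa_baseline >= 0,
              lag_LH_FC >= 0, lag_RH_FC >= 0,
              pac_depth >= 0, pac_depth <= 1, fr_cycles >= 4)
    if (complex_duration < 2 / slow_freq)
      stop("complex_duration must cover >= 2 slow-oscillation cycles")
  })
  invisible(cfg)
}

#' Reduced "desk" profile of the generator
#'
#' Same structure as the full 16 kHz study profile but at 4 kHz (the lowest
#' rate at which the 200-550 Hz fast-ripple band keeps a Nyquist margin) and
#' 4 contacts per probe, for fast test-suite and example runs. The multiunit
#' band is reduced to 300-1900 Hz at this rate and flagged downstream.
#'
#' @param ... overrides passed to [synth_config()].
#' @return a `synth_config`.
#' @export
desk_profile <- function(...) {
  args <- list(...)
  defaults <- list(fs = 4000, duration = 60, n_complexes = 30,
                   n_channels = 4)
  cfg <- do.call(synth_config, utils::modifyList(defaults, args))
  cfg
}

#' 1/f^alpha Gaussian background
#'
#' Per-channel independent spectrally shaped Gaussian noise plus a
#' common-mode term shared by all channels, each channel normalised to
#' `background_sd`.
#'
#' @param cfg a [synth_config()].
#' @param n_channels number of channels to generate.
#' @param duration length in seconds (defaults to `cfg$duration`).
#' @param seed integer seed, or NULL to use the current RNG state (as when
#'   called from [generate_recording()]).
#' @return a [time_series()].
#' @export
generate_background <- function(cfg, n_channels, duration = cfg$duration,
                                seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration * cfg$fs))
  cm <- one_over_f(n, cfg$fs, cfg$background_alpha)
  w <- cfg$common_mode
  out <- matrix(0, n, n_channels)
  for (j in seq_len(n_channels)) {
    x <- sqrt(1 - w^2) * one_over_f(n, cfg$fs, cfg$background_alpha) + w * cm
    out[, j] <- x / stats::sd(x) * cfg$background_sd
  }
  time_series(out, cfg$fs)
}

## single channel of 1/f^alpha noise, unit SD, via FFT spectral shaping
one_over_f <- function(n, fs, alpha) {
  x <- stats::rnorm(n)
  if (alpha == 0) return(x)
  X <- stats::fft(x)
  f <- c(0, seq_len(n - 1)) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]        # mirror negative frequencies
  g <- c(0, f[-1]^(-alpha / 2))              # kill DC
  y <- Re(stats::fft(X * g, inverse = TRUE) / n)
  y / stats::sd(y)
}

## cosine-tapered (Tukey) window, taper fraction a of each half
tukey_window <- function(n, a = 0.25) {
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < a
  hi <- x > 1 - a
  w[lo] <- 0.5 * (1 - cos(pi * x[lo] / a))
  w[hi] <- 0.5 * (1 - cos(pi * (1 - x[hi]) / a))
  w
}

#' One epileptic complex with ground truth
#'
#' Builds the deterministic waveform of a single complex: a Hann-enveloped
#' slow oscillation, an IED burst whose envelope is
#' `(1 + pac_depth * cos(phi_slow - phi_pref)) / 2`, and one fast-ripple
#' burst whose onset falls at slow phase `mu_fr`. Amplitudes are in units of
#' `background_sd`.
#'
#' @param cfg a [synth_config()].
#' @return list with `wave` (numeric vector, length
#'   `round(complex_duration * fs)`), and `truth`: `fr_onset` (s, relative
#'   to complex start), `slow_freq`, `f_phase`, `f_amp`, `phase_fun`
#'   (function mapping relative time to slow phase).
#' @export
generate_complex <- function(cfg) {
  validate_synth_config(cfg)
  fs <- cfg$fs
  L <- as.integer(round(cfg$complex_duration * fs))
  tau <- (seq_len(L) - 1L) / fs
  tc <- cfg$complex_duration / 2
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1L) / (L - 1L)))
  sd0 <- cfg$background_sd
  phase_fun <- function(t) 2 * pi * cfg$slow_freq * (t - tc)
  slow <- cfg$slow_amp * sd0 * hann * cos(phase_fun(tau))
  env <- (1 + cfg$pac_depth * cos(phase_fun(tau))) / 2
  ied <- cfg$ied_amp * sd0 * hann * env * cos(2 * pi * cfg$pac_amp_freq * (tau - tc))
  ## FR onset at slow phase mu_fr, on the cycle nearest the first quarter of
  ## the complex (so the -200..+600 ms period of interest around the FR
  ## covers the complex, as in the emulated study geometry)
  d_fr <- cfg$fr_cycles / cfg$fr_freq
  n_cyc <- ceiling(cfg$complex_duration * cfg$slow_freq)
  cand <- tc + cfg$mu_fr / (2 * pi * cfg$slow_freq) +
    seq(-n_cyc, n_cyc) / cfg$slow_freq
  cand <- cand[cand >= 0.02 & cand + d_fr <= cfg$complex_duration - 0.02]
  t_on <- cand[which.min(abs(cand - cfg$complex_duration / 4))]
  fr <- numeric(L)
  idx <- which(tau >= t_on & tau < t_on + d_fr)
  fr[idx] <- cfg$fr_snr * sd0 * tukey_window(length(idx), 0.1) *
    cos(2 * pi * cfg$fr_freq * (tau[idx] - t_on))
  list(wave = slow + ied + fr, base = slow + ied, fr = fr,
       truth = list(fr_onset = t_on, slow_freq = cfg$slow_freq,
                    f_phase = cfg$slow_freq, f_amp = cfg$pac_amp_freq,
                    phase_fun = phase_fun))
}

#' Von Mises phase-locked Poisson spike train
#'
#' Inhomogeneous Poisson process with intensity
#' `lambda(t) = mua_rate * exp(kappa * cos(phi(t) - mu)) / I0(kappa)`,
#' i.e. von Mises phase modulation normalised to mean rate `mua_rate`,
#' sampled by thinning.
#'
#' @param cfg a [synth_config()].
#' @param phase an [analytic_signal()] (first channel used) or a numeric
#'   vector of instantaneous phase in radians sampled at `fs`.
#' @param state `"event"` (kappa_event, mu_event) or `"baseline"`.
#' @param fs sampling rate of `phase` when given as a plain vector.
#' @param seed integer seed or NULL (use current RNG state).
#' @return numeric vector of spike times in seconds (relative to the start
#'   of the phase signal).
#' @export
generate_spike_train <- function(cfg, phase, state = c("event", "baseline"),
                                 fs = cfg$fs, seed = cfg$seed) {
  state <- match.arg(state)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(phase, "analytic_signal")) {
    fs <- phase$fs
    phase <- phase$phase[, 1]
  }
  stopifnot(cfg$mua_rate > 0)
  kappa <- if (state == "event") cfg$kappa_event else cfg$kappa_baseline
  mu <- if (state == "event") cfg$mu_event else cfg$mu_baseline
  dur <- length(phase) / fs
  i0 <- besselI(kappa, 0)
  lambda_max <- cfg$mua_rate * exp(kappa) / i0
  n_cand <- stats::rpois(1L, lambda_max * dur)
  if (n_cand == 0L) return(numeric(0))
  t_cand <- sort(stats::runif(n_cand, 0, dur))
  idx <- pmin(length(phase), floor(t_cand * fs) + 1L)
  lam <- cfg$mua_rate * exp(kappa * cos(phase[idx] - mu)) / i0
  t_cand[stats::runif(n_cand) < lam / lambda_max]
}

## biphasic extracellular spike kernel, ~0.8 ms, unit peak amplitude
spike_kernel <- function(fs) {
  dur <- 0.0008
  n <- max(5L, as.integer(round(dur * fs)))
  tt <- seq_len(n) - 1L
  w <- -sin(2 * pi * tt / n) * 0.5 * (1 - cos(2 * pi * tt / (n - 1)))
  w / max(abs(w))
}

#' Generate a full synthetic three-region recording with ground truth
#'
#' Assembles background, per-region complex trains with inter-regional lags
#' (each complex appears first in LH, then RH, then FC), the directed
#' AR(2)-resonator component from the LH complex train into FC, and
#' von Mises phase-locked multiunit spikes on the FC channels (with a
#' depth-graded down state before each FR and a depth-graded peri-FR onset
#' lead). Fully determined by `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return list with `recording` (a [time_series()], channels grouped
#'   LH / RH / FC) and `truth`, a list holding `fr_onsets` (data.frame:
#'   onset_s, region), `ied_times`, `complex_windows` (data.frame: region,
#'   start, end), `spike_times` (list per FC channel), `lags`, `coupling`
#'   (`f_phase`, `f_amp`), `mu_fr` and the generating config.
#' @export
generate_recording <- function(cfg) {
  validate_synth_config(cfg)
  set.seed(cfg$seed)
  fs <- cfg$fs
  n <- as.integer(round(cfg$duration * fs))
  regions <- c("LH", "RH", "FC")
  lag <- c(LH = 0, RH = cfg$lag_LH_FC - cfg$lag_RH_FC, FC = cfg$lag_LH_FC)

  ## complex start times (LH reference), jittered grid with margins
  margin <- 1.2
  usable <- cfg$duration - 2 * margin - max(lag) - cfg$complex_duration
  if (cfg$n_complexes > 0 && usable <= 0)
    stop("duration too short for the requested complexes")
  starts <- numeric(0)
  if (cfg$n_complexes > 0) {
    slot <- usable / cfg$n_complexes
    jit_max <- max(0, slot - cfg$complex_duration - 0.3)
    starts <- margin + (seq_len(cfg$n_complexes) - 1L) * slot +
      stats::runif(cfg$n_complexes, 0, min(slot * 0.3, jit_max))
  }

  cx <- generate_complex(cfg)
  L <- length(cx$wave)

  sig <- vector("list", 3L); names(sig) <- regions
  chan <- list()
  slow_bg_phase <- list()
  nb_store <- list()
  bflt <- signal::butter(2, c(max(0.5, cfg$slow_freq - 1),
                              cfg$slow_freq + 1) / (fs / 2), type = "pass")
  dfrac <- if (cfg$n_channels > 1)
    (seq_len(cfg$n_channels) - 1L) / (cfg$n_channels - 1L) else 0.5
  gvec <- 1 + cfg$depth_gradient * (0.5 - dfrac)   # laminar LFP gradient
  for (r in regions) {
    bg <- generate_background(cfg, cfg$n_channels, seed = NULL)
    ## continuous region-specific narrowband slow component (baseline locking)
    nb <- signal::filtfilt(bflt, one_over_f(n, fs, 0))
    nb <- nb / stats::sd(nb) * cfg$baseline_slow_amp * cfg$background_sd
    nb_store[[r]] <- nb
    m <- bg$samples + outer(nb, gvec)
    ## add the lagged complex train (depth-graded); on the FC probe the
    ## fast-ripple component goes only to the designated (spike-free) LFP
    ## contact, its laminar profile not being modelled
    for (s in starts) {
      i0 <- as.integer(round((s + lag[[r]]) * fs)) + 1L
      ii <- i0:(i0 + L - 1L)
      if (r == "FC" && cfg$n_channels > 1L) {
        m[ii, ] <- m[ii, ] + outer(cx$base, gvec)
        m[ii, 1L] <- m[ii, 1L] + cx$fr * gvec[1L]
      } else {
        m[ii, ] <- m[ii, ] + outer(cx$wave, gvec)
      }
    }
    sig[[r]] <- m
    slow_bg_phase[[r]] <- Arg(hilbert_analytic(nb))
    chan[[r]] <- data.frame(
      id = paste0(r, seq_len(cfg$n_channels)),
      region = r, depth_um = 50 * (seq_len(cfg$n_channels) - 1L),
      montage = "monopolar", stringsAsFactors = FALSE)
  }

  ## directed LH -> FC drive: the LH-specific stochastic slow component,
  ## passed through a lightly damped AR(2) resonator at slow_freq and
  ## delayed by drive_lag, enters the FC channels during complexes (Hann
  ## gate). Being stochastic and observable in LH first, it carries genuine
  ## Granger-causal LH -> FC structure; the deterministic complex train
  ## alone would not (a noiseless waveform is equally predictable from any
  ## region's own past).
  if (cfg$drive_gain > 0 && length(starts)) {
    dlag <- max(1L, as.integer(round(cfg$drive_lag * fs)))
    u <- c(rep(0, dlag), nb_store$LH[seq_len(n - dlag)])
    r_pole <- 0.9
    om <- 2 * pi * cfg$slow_freq / fs
    y <- as.numeric(stats::filter(u, c(2 * r_pole * cos(om), -r_pole^2),
                                  method = "recursive"))
    y <- y / stats::sd(y)
    gate <- numeric(n)
    hannL <- 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1L) / (L - 1L)))
    for (s in starts) {
      i0 <- as.integer(round((s + lag[["FC"]]) * fs)) + 1L
      gate[i0:(i0 + L - 1L)] <- pmax(gate[i0:(i0 + L - 1L)], hannL)
    }
    sig$FC <- sig$FC +
      cfg$drive_gain * cfg$slow_amp * cfg$background_sd * y * gate
  }

  ## multiunit spikes on FC channels
  kern <- spike_kernel(fs)
  spike_times <- vector("list", cfg$n_channels)
  t_axis_complexes <- starts + lag[["FC"]]
  fr_on_fc <- t_axis_complexes + cx$truth$fr_onset
  depth_frac <- if (cfg$n_channels > 1)
    (seq_len(cfg$n_channels) - 1L) / (cfg$n_channels - 1L) else 0
  ## the most superficial FC contact is the spike-free LFP contact used for
  ## FR detection and spectrograms; spike waveforms (broadband clicks) go on
  ## the deeper wideband contacts
  spike_channels <- if (cfg$n_channels > 1) 2:cfg$n_channels else 1L
  for (j in spike_channels) {
    d <- depth_frac[j]
    ## baseline spikes over the whole recording
    st <- generate_spike_train(cfg, slow_bg_phase$FC, "baseline",
                               fs = fs, seed = NULL)
    ## remove baseline spikes inside complexes, replace with event spikes
    in_cx <- rep(FALSE, length(st))
    for (s in t_axis_complexes)
      in_cx <- in_cx | (st >= s & st < s + cfg$complex_duration)
    st <- st[!in_cx]
    for (k in seq_along(t_axis_complexes)) {
      s <- t_axis_complexes[k]
      ph <- cx$truth$phase_fun((seq_len(L) - 1L) / fs)
      ev <- generate_spike_train(cfg, ph, "event", fs = fs, seed = NULL) + s
      ## depth-graded down state before the FR, graded peri-FR onset lead
      fr_t <- fr_on_fc[k]
      down <- ev >= fr_t - 0.180 & ev < fr_t - 0.030
      keep <- !(down & stats::runif(length(ev)) < cfg$laminar_down * d)
      lead <- cfg$laminar_lead * (1 - d)       # superficial starts later
      burst <- ev >= fr_t - 0.030 & ev < fr_t - 0.030 + lead
      keep <- keep & !burst
      st <- c(st, ev[keep])
    }
    st <- sort(st[st > 0.002 & st < cfg$duration - 0.002])
    spike_times[[j]] <- st
    off <- which.min(kern) - 1L           # negative peak sits at spike time
    idx <- as.integer(round(st * fs)) + 1L - off
    for (i in idx) {
      ii <- i:(i + length(kern) - 1L)
      sig$FC[ii, j] <- sig$FC[ii, j] + cfg$mua_amp * cfg$background_sd * kern
    }
  }

  for (j in setdiff(seq_len(cfg$n_channels), spike_channels))
    spike_times[[j]] <- numeric(0)

  samples <- cbind(sig$LH, sig$RH, sig$FC)
  channels <- rbind(chan$LH, chan$RH, chan$FC)
  rec <- time_series(samples, fs, 0, channels)

  fr_onsets <- do.call(rbind, lapply(regions, function(r)
    data.frame(onset_s = starts + lag[[r]] + cx$truth$fr_onset,
               region = rep(r, length(starts)),
               stringsAsFactors = FALSE)))
  cw <- do.call(rbind, lapply(regions, function(r)
    data.frame(region = rep(r, length(starts)),
               start = starts + lag[[r]],
               end = starts + lag[[r]] + cfg$complex_duration,
               stringsAsFactors = FALSE)))
  truth <- list(
    fr_onsets = fr_onsets,
    ied_times = t_axis_complexes + cfg$complex_duration / 2,
    complex_windows = cw,
    spike_times = spike_times,
    lags = c(LH_FC = cfg$lag_LH_FC, RH_FC = cfg$lag_RH_FC),
    coupling = c(f_phase = cfg$slow_freq, f_amp = cfg$pac_amp_freq),
    mu_fr = cfg$mu_fr,
    config = cfg)
  list(recording = rec, truth = truth)
}

#' Write generator ground truth as CSV event tables plus a JSON manifest
#'
#' Event-level truth (fast-ripple onsets, IED times, spikes) goes to
#' `events.csv` with columns onset_s, region, channel, type; complex
#' windows to `complex_windows.csv`; scalar truth (lags, coupling
#' frequencies, locking phase, config) to `truth.json`.
#'
#' @param truth the `truth` element of [generate_recording()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fr <- data.frame(onset_s = truth$fr_onsets$onset_s,
                   region = truth$fr_onsets$region,
                   channel = NA_integer_, type = "fast_ripple",
                   stringsAsFactors = FALSE)
  ied <- data.frame(onset_s = truth$ied_times, region = "FC",
                    channel = NA_integer_, type = "ied",
                    stringsAsFactors = FALSE)
  spikes <- do.call(rbind, lapply(seq_along(truth$spike_times), function(j)
    if (length(truth$spike_times[[j]]))
      data.frame(onset_s = truth$spike_times[[j]], region = "FC",
                 channel = j, type = "mua_spike",
                 stringsAsFactors = FALSE)))
  ev <- rbind(fr, ied, spikes)
  ev <- ev[order(ev$onset_s), ]
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(truth$complex_windows,
                   file.path(dir, "complex_windows.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(lags = as.list(truth$lags), coupling = as.list(truth$coupling),
         mu_fr = truth$mu_fr, config = unclass(truth$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
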