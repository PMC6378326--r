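#' Pipeline configuration
#'
#' Aggregates the analysis constants: the period of interest, the frequency
#' bands, the detection thresholds, the analysis rate and the seeds. The
#' defaults are the package's canonical values; any override is recorded in
#' the provenance manifest of [run_pipeline()].
#'
#' @param poi_window period of interest around each frontal-cortex FR
#'   onset, default `c(-0.2, 0.6)` s.
#' @param fr_band fast-ripple band, default `c(200, 550)` Hz.
#' @param ied_band interictal-discharge band, default `c(20, 30)` Hz.
#' @param slow_band slow-oscillation band, default `c(3, 5)` Hz.
#' @param mua_band multiunit band, default `c(300, 6000)` Hz (reduce at
#'   low sampling rates).
#' @param fr_threshold_sd fast-ripple amplitude criterion (default 3).
#' @param ied_z IED association z-threshold (default 2).
#' @param onset_z band-onset z-threshold (default 5).
#' @param analysis_fs decimated LFP analysis rate (default 1000 Hz).
#' @param f_max_spectrogram top spectrogram frequency (default 100 Hz).
#' @param n_baseline number of baseline epochs (default 60).
#' @param guard guard margin around events for baseline sampling, s
#'   (default 1; reduce for short densely-evented recordings).
#' @param pac_phase_freqs,pac_amp_freqs comodulogram grids (defaults
#'   2-20 by 0.5 and 2-98 by 1 Hz).
#' @param synchrony_freqs synchrony-scan centre frequencies (default
#'   1:100 Hz).
#' @param tvar_order,tvar_rate Kalman-TVAR settings (defaults 5, 0.02).
#' @param connectivity_fs analysis rate for the slow-band directed
#'   connectivity stage (default 50 Hz): a VAR of order `tvar_order` can
#'   only attribute a lagged 3-5 Hz drive when its span
#'   (`tvar_order / rate`) is commensurate with the band's innovation
#'   timescale.
#' @param max_lag cross-correlation maximum lag, s (default 0.25).
#' @param seed integer seed for all stochastic stages (default 1).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(poi_window = c(-0.2, 0.6),
                            fr_band = c(200, 550), ied_band = c(20, 30),
                            slow_band = c(3, 5), mua_band = c(300, 6000),
                            fr_threshold_sd = 3, ied_z = 2, onset_z = 5,
                            analysis_fs = 1000, f_max_spectrogram = 100,
                            n_baseline = 60, guard = 1,
                            pac_phase_freqs = seq(2, 20, 0.5),
                            pac_amp_freqs = seq(2, 98, 1),
                            synchrony_freqs = 1:100,
                            tvar_order = 5L, tvar_rate = 0.02,
                            connectivity_fs = 50,
                            max_lag = 0.25, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full event-locked analysis pipeline
#'
#' Sequences the analyses end-to-end on a recording: fast-ripple detection
#' in the frontal cortex, multiunit detection, period-of-interest epoching,
#' baseline-normalised Stockwell spectrograms with IED association and band
#' onsets, slow-oscillation phase locking of FR onsets and multiunit
#' spikes, the phase-amplitude comodulogram (period of interest vs
#' baseline), the inter-regional phase-synchrony scan and band-limited
#' lags, Kalman-TVAR directed connectivity, and the peri-event spike
#' analyses. Any stage failure aborts with the stage named; completed
#' stages are retained in the error's `partial` field.
#'
#' @param rec a [time_series()] recording with FC/LH/RH channel metadata,
#'   or a [synth_config()] (the recording is generated first).
#' @param config a [pipeline_config()].
#' @return a result bundle (list) with elements `catalog`, `mua`,
#'   `spectrograms`, `onsets`, `locking`, `pac`, `synchrony`, `lags`,
#'   `connectivity`, `perievent`, `truth` (when synthetic) and
#'   `provenance`.
#' @export
run_pipeline <- function(rec, config = pipeline_config()) {
  truth <- NULL
  if (inherits(rec, "synth_config")) {
    g <- generate_recording(rec)
    truth <- g$truth
    rec <- g$recording
  }
  stopifnot(inherits(rec, "time_series"))
  bundle <- list(truth = truth)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      err <- simpleError(paste0("pipeline stage '", name, "' failed: ",
                                conditionMessage(e)))
      err$partial <- bundle
      stop(err)
    })
  }
  set.seed(config$seed)
  fc <- ts_channels(rec, "FC")

  ## -- detection ----------------------------------------------------------
  bundle$catalog <- stage("detect_fast_ripples", {
    cat_all <- detect_fast_ripples(rec, config$fr_band,
                                   threshold_sd = config$fr_threshold_sd)
    cat_all
  })
  fc_fr <- bundle$catalog[bundle$catalog$region == "FC" &
                            bundle$catalog$channel ==
                              fc$channels$id[1], , drop = FALSE]
  if (nrow(fc_fr) == 0L)
    warning("no frontal-cortex fast ripples detected; ",
            "downstream tables will be empty")
  bundle$mua <- stage("detect_mua_spikes",
                      detect_mua_spikes(fc, config$mua_band))

  ## -- decimated LFP ------------------------------------------------------
  lfp <- stage("decimate", decimate_ts(rec, config$analysis_fs))
  lfp_fc <- ts_channels(lfp, "FC")

  ## -- spectrograms -------------------------------------------------------
  bundle$spectrograms <- stage("spectrograms", {
    if (nrow(fc_fr) == 0L) list(empty = TRUE) else {
      onsets <- fc_fr$onset_s
      win <- c(-0.5, 0.5)                      # 1 s Stockwell windows
      base_ep <- sample_baseline_epochs(lfp_fc, onsets, config$n_baseline,
                                        win, guard = config$guard,
                                        seed = config$seed)
      bstats <- baseline_stats(base_ep, config$f_max_spectrogram)
      poi_ep <- extract_epochs(lfp_fc, onsets, win)
      zmaps <- lapply(poi_ep, zscore_spectrogram, baseline = bstats)
      assoc <- vapply(zmaps, function(z)
        classify_ied_association(z, config$ied_band,
                                 config$ied_z)$associated, logical(1))
      avg <- average_spectrogram(zmaps, z_threshold = config$onset_z)
      list(baseline = bstats, zmaps = zmaps, average = avg,
           ied_associated = assoc, fraction_ied = mean(assoc),
           onsets_used = attr(poi_ep, "onsets"))
    }
  })

  ## -- band onsets per region --------------------------------------------
  bundle$onsets <- stage("band_onsets", {
    if (nrow(fc_fr) == 0L) NULL else {
      onsets <- fc_fr$onset_s
      win <- c(-0.75, 0.45)
      per_region <- lapply(c(FC = "FC", LH = "LH", RH = "RH"), function(r) {
        ch <- ts_channels(lfp, r)
        ch1 <- ts_channels(ch, 1L)
        base_ep <- sample_baseline_epochs(ch1, onsets, config$n_baseline,
                                          win, guard = config$guard,
                                          seed = config$seed + 1L)
        bstats <- baseline_stats(base_ep, 40)
        ep <- extract_epochs(ch1, onsets, win)
        zm <- lapply(ep, zscore_spectrogram, baseline = bstats)
        list(slow = band_onset(zm, config$slow_band, config$onset_z),
             ied = band_onset(zm, config$ied_band, config$onset_z))
      })
      per_region
    }
  })

  ## -- phase locking ------------------------------------------------------
  bundle$locking <- stage("phase_locking", {
    if (nrow(fc_fr) == 0L) NULL else {
      bip <- bipolar_montage(lfp_fc)
      ph <- analytic_phase_amplitude(ts_channels(bip, 1L), config$slow_band)
      fr_lock <- event_phase_locking(ph, fc_fr$onset_s)
      mua_fc <- bundle$mua                   # pooled over FC contacts
      in_poi <- rep(FALSE, nrow(mua_fc))
      for (on in fc_fr$onset_s)
        in_poi <- in_poi | (mua_fc$time_s >= on + config$poi_window[1] &
                            mua_fc$time_s < on + config$poi_window[2])
      mua_poi <- event_phase_locking(ph, mua_fc$time_s[in_poi])
      mua_base <- event_phase_locking(ph, mua_fc$time_s[!in_poi])
      list(fr = fr_lock, mua_poi = mua_poi, mua_baseline = mua_base,
           ww = watson_williams_test(mua_poi$angles, mua_base$angles),
           kappa_test = equal_kappa_test(mua_poi$angles, mua_base$angles))
    }
  })

  ## -- phase-amplitude coupling ------------------------------------------
  bundle$pac <- stage("pac", {
    if (nrow(fc_fr) == 0L) NULL else {
      ch1 <- ts_channels(lfp_fc, 1L)
      base_ep <- sample_baseline_epochs(ch1, fc_fr$onset_s,
                                        max(20L, min(config$n_baseline,
                                                     nrow(fc_fr))),
                                        config$poi_window,
                                        guard = config$guard,
                                        seed = config$seed + 2L)
      poi <- comodulogram(ch1, fc_fr$onset_s, config$poi_window,
                          config$pac_phase_freqs, config$pac_amp_freqs,
                          condition = "poi")
      base <- comodulogram(ch1, attr(base_ep, "onsets"), config$poi_window,
                           config$pac_phase_freqs, config$pac_amp_freqs,
                           condition = "baseline")
      list(poi = poi, baseline = base, ratio = mi_ratio(poi, base))
    }
  })

  ## -- synchrony + lags ---------------------------------------------------
  bundle$synchrony <- stage("synchrony", {
    if (nrow(fc_fr) == 0L) NULL else {
      bip_fc <- ts_channels(bipolar_montage(lfp_fc), 1L)
      bip_lh <- ts_channels(bipolar_montage(ts_channels(lfp, "LH")), 1L)
      ch1 <- ts_channels(lfp_fc, 1L)
      base_ep <- sample_baseline_epochs(ch1, fc_fr$onset_s,
                                        length(fc_fr$onset_s),
                                        config$poi_window,
                                        guard = config$guard,
                                        seed = config$seed + 3L)
      phase_synchrony_scan(bip_lh, bip_fc, fc_fr$onset_s,
                           attr(base_ep, "onsets"), config$poi_window,
                           freqs = config$synchrony_freqs)
    }
  })
  bundle$lags <- stage("lags", {
    mean_of <- function(r) time_series(rowMeans(ts_channels(lfp, r)$samples),
                                       lfp$fs, lfp$t0)
    lh <- mean_of("LH"); rh <- mean_of("RH"); fcm <- mean_of("FC")
    list(LH_FC = bandlimited_crosscorr_lag(lh, fcm, config$slow_band,
                                           config$max_lag),
         RH_FC = bandlimited_crosscorr_lag(rh, fcm, config$slow_band,
                                           config$max_lag))
  })

  ## -- directed connectivity ---------------------------------------------
  bundle$connectivity <- stage("connectivity", {
    regions <- c("LH", "RH", "FC")
    ## further decimation: the slow-band VAR span must cover the drive lag
    clfp <- lfp
    while (clfp$fs > config$connectivity_fs) {
      q <- min(10, clfp$fs / config$connectivity_fs)
      clfp <- decimate_ts(clfp, clfp$fs / q)
    }
    m <- sapply(regions, function(r)
      rowMeans(ts_channels(clfp, r)$samples))
    reg_ts <- time_series(m, clfp$fs, clfp$t0,
                          data.frame(id = regions, region = regions,
                                     depth_um = 0, montage = "monopolar",
                                     stringsAsFactors = FALSE))
    model <- fit_tvar_kalman(reg_ts, config$tvar_order, config$tvar_rate)
    frame_of <- function(t) pmax(1L, pmin(dim(model$coef)[3],
                                          as.integer(round(t * clfp$fs))))
    if (nrow(fc_fr) == 0L) list(model = model) else {
    poi_frames <- unique(unlist(lapply(fc_fr$onset_s, function(on)
      frame_of(seq(on + config$poi_window[1], on + config$poi_window[2],
                   by = 0.01)))))
    base_onsets <- attr(sample_baseline_epochs(
      ts_channels(lfp_fc, 1L), fc_fr$onset_s, length(fc_fr$onset_s),
      config$poi_window, guard = config$guard,
      seed = config$seed + 4L), "onsets")
    base_frames <- unique(unlist(lapply(base_onsets, function(on)
      frame_of(seq(on + config$poi_window[1], on + config$poi_window[2],
                   by = 0.01)))))
    fgrid <- seq(config$slow_band[1], config$slow_band[2], by = 0.5)
    ap_poi <- apdc_spectrum(model, fgrid, t_idx = poi_frames)
    ap_base <- apdc_spectrum(model, fgrid, t_idx = base_frames)
    ia_poi <- iapdc_band(ap_poi, config$slow_band[1], config$slow_band[2])
    ia_base <- iapdc_band(ap_base, config$slow_band[1], config$slow_band[2])
    list(model = model, iapdc_poi = ia_poi, iapdc_baseline = ia_base,
         comparison = directed_comparison(ia_poi, ia_base, regions))
    }
  })

  ## -- peri-event spike analyses -----------------------------------------
  bundle$perievent <- stage("perievent", {
    if (nrow(fc_fr) == 0L) NULL else {
      mua_by_ch <- split(bundle$mua$time_s, bundle$mua$channel)
      ids <- fc$channels$id
      trains <- lapply(ids, function(id)
        if (id %in% names(mua_by_ch)) mua_by_ch[[id]] else numeric(0))
      pooled <- sort(unlist(trains))
      list(psth = psth(pooled, fc_fr$onset_s, c(-1, 1), 0.01),
           laminar = laminar_rate_ratio(trains, fc_fr$onset_s,
                                        depths = fc$channels$depth_um),
           chronology = laminar_onset_chronology(
             trains, fc_fr$onset_s, depths = fc$channels$depth_um),
           precedence = precedence_analysis(bundle$catalog))
    }
  })

  bundle$provenance <- list(
    seed = config$seed, config = unclass(config),
    package_version = as.character(utils::packageVersion("fripple")),
    n_channels = ncol(rec$samples), fs = rec$fs,
    config_hash = config_hash(config))
  bundle
}

## deterministic md5 of a configuration (via serialisation to a temp file)
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(cfg), f, version = 2)
  unname(tools::md5sum(f))
}

#' Write / read a recording as flat binary plus JSON sidecar
#'
#' The samples are stored channel-major as little-endian float32 in
#' `<path>.bin`; sampling rate, start time and the channel table go to
#' `<path>.json`. Reading restores the `time_series` (samples at float32
#' precision).
#'
#' @param ts a [time_series()].
#' @param path base path (without extension).
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `time_series`.
#' @export
write_recording <- function(ts, path) {
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(ts$samples), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(fs = ts$fs, t0 = ts$t0, n_samples = n_samples(ts),
         n_channels = ncol(ts$samples), order = "channel-major",
         dtype = "float32", channels = ts$channels),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing sidecar file: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("fs", "n_samples", "n_channels", "channels"))
    if (is.null(meta[[f]])) stop("sidecar is missing field '", f, "'")
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = meta$n_samples * meta$n_channels,
               size = 4L, endian = "little")
  time_series(matrix(x, meta$n_samples, meta$n_channels), meta$fs,
              if (is.null(meta$t0)) 0 else meta$t0,
              as.data.frame(meta$channels))
}

#' Write the main pipeline tables to a directory
#'
#' Event catalog, multiunit spikes, synchrony scan, connectivity comparison
#' and precedence tables as CSV; scalar summaries and provenance as JSON.
#'
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$catalog, file.path(dir, "event_catalog.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$mua))
    utils::write.csv(bundle$mua, file.path(dir, "mua_spikes.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$synchrony))
    utils::write.csv(bundle$synchrony, file.path(dir, "synchrony_scan.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$connectivity$comparison))
    utils::write.csv(bundle$connectivity$comparison,
                     file.path(dir, "connectivity_comparison.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$perievent$precedence))
    utils::write.csv(bundle$perievent$precedence,
                     file.path(dir, "precedence.csv"), row.names = FALSE)
  summary <- list(
    n_fast_ripples = nrow(bundle$catalog),
    fraction_ied_associated = bundle$spectrograms$fraction_ied,
    lag_LH_FC_s = bundle$lags$LH_FC$lag_s,
    lag_RH_FC_s = bundle$lags$RH_FC$lag_s,
    provenance = bundle$provenance)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
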