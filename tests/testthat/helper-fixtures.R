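## shared fixtures, generated once per test run and memoised

.fixture_env <- new.env(parent = emptyenv())

## desk-profile recording with ground truth, shared across test files
desk_fixture <- function() {
  if (is.null(.fixture_env$desk)) {
    .fixture_env$desk <- generate_recording(desk_profile(seed = 101))
  }
  .fixture_env$desk
}

## decimated single FC LFP channel of the desk fixture
desk_lfp_fc <- function() {
  if (is.null(.fixture_env$lfp_fc)) {
    g <- desk_fixture()
    .fixture_env$lfp_fc <-
      decimate_ts(ts_channels(ts_channels(g$recording, "FC"), 1L), 1000)
  }
  .fixture_env$lfp_fc
}

fc_fr_onsets <- function() {
  tr <- desk_fixture()$truth$fr_onsets
  tr$onset_s[tr$region == "FC"]
}

fc_complex_windows <- function() {
  cw <- desk_fixture()$truth$complex_windows
  cw[cw$region == "FC", c("start", "end")]
}

## single-channel sine helper
sine_ts <- function(f, fs, dur, amp = 1, phase = 0) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  time_series(amp * cos(2 * pi * f * t + phase), fs)
}
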