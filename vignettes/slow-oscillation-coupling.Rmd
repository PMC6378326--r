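---
title: "Methods: event-locked analysis of fast ripples and slow-oscillation coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-locked analysis of fast ripples and slow-oscillation coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fripple` implements an event-locked analysis chain for multichannel
extracellular recordings in which pathologic fast ripples (FRs,
200–550 Hz) ride on interictal discharges (IEDs, 20–30 Hz spectral
signature) that are themselves nested in a transient large-scale 3–5 Hz
slow oscillation. This vignette documents the models, the parameters that
matter, the numerical choices, what the synthetic-data generator does and
does not emulate, and the known limitations. Everything quantitative
stated here is computed by the test suite or the acceptance script; the
vignette adds the reasoning.

## Signal model and conventions

A recording is a `time_series`: a samples matrix (µV), sampling rate,
start time, and a channel table (id, region ∈ {FC, LH, RH, other}, depth
in µm along a linear probe, montage). All filtering is zero-phase
(order-2 Butterworth applied forward and backward) because every analysis
downstream is phase-sensitive; the forward-backward pass squares the
magnitude response, and the closed-form squared response is the oracle the
tests compare against. Phase follows the cosine convention — 0 rad at
local maxima of the band-limited signal — via the FFT Hilbert transform.

Epoching uses a half-open convention: the onset is mapped to the nearest
sample at or before the event time and the epoch covers
`[onset + w_lo, onset + w_hi)` in samples, so all epochs have identical
length and t = 0 is the onset sample. The period of interest (POI) is
−200 to +600 ms around each frontal-cortex FR onset.

The Stockwell transform uses the classic frequency-dependent Gaussian
window, scale σ(f) = 1/f, in the frequency-domain formulation; the Morlet
transform uses width 7 cycles (exposed as `width`; the reference the
width follows gives no alternative default). Both transforms reflect-pad
the input by one window length and discard the pad: event windows are
short (≈1 s) and reflection keeps edge ringing out of the analysis
interval. The brute-force oracles in the tests therefore use
`pad = "none"`; note that a naive *non-periodised* time-domain Gaussian
sum is **not** equivalent to the discrete frequency-domain definition at
the 1e−9 level (the window aliases at low rows), so the oracle is a
direct, FFT-free evaluation of the discrete definition itself.

## Detection

**Fast ripples.** The trace is filtered to 200–550 Hz; candidate segments
are excursions of the Hilbert envelope above 2.5× the robust global SD
(median(|x|)/0.6745), healed over 2 ms dips. A candidate qualifies when
it contains at least four positive and four negative *paired*
suprathreshold peaks — a cycle is an adjacent suprathreshold
negative+positive peak pair — with the threshold set to 3× the SD of the
±250 ms surrounding baseline, candidate samples excluded so events cannot
inflate their own baseline. The onset is the first peak belonging to such
a pair: requiring the pair (rather than any lone suprathreshold peak)
matters, because isolated 3σ noise peaks otherwise chain into the event
via the 10 ms merge gap and advance onsets by 10–20 ms. Qualified events
closer than 10 ms are merged. Because every criterion is a ratio to a
baseline SD, detection is invariant to signal scaling. There is no manual
review stage; the detector is validated against generator ground truth
instead.

**Multiunit spikes.** The wideband trace is filtered to 300–6000 Hz
(proportionally reduced and flagged at low sampling rates) and
thresholded at `4 · median(|x| / 0.6745)` — four robust SDs; the robust
estimate is used because the spikes themselves inflate a plain SD.
Suprathreshold excursions closer than the 1 ms dead time are merged (one
waveform crosses several times) and reported at their absolute extremum
with its polarity.

**IED association.** An event is IED-associated when the maximal z-score
in the 20–30 Hz band of its baseline-normalised spectrogram exceeds 2.
The default takes the maximum over frequency rows of the *time-averaged*
z within the window: the maximum over every individual time–frequency
cell (`reduce = "cell_max"`, also provided) exceeds 2 almost surely even
for pure baseline — the max of hundreds of roughly standard-normal cells
— and therefore cannot discriminate at all. The band-mean reading keeps
the stated threshold meaningful; with it, generator complexes classify
correctly and baseline epochs rarely do.

**Band onsets.** For each region the per-event z-spectrograms are reduced
to a band series (mean z over the band's rows per frame); the onset is
the earliest frame at which the *median across events* exceeds z = 5
(a deliberately conservative threshold for onsets), with `NA` as the
explicit no-onset sentinel. Onset differences between regions recover a
constructed inter-regional lead, but only once both regions' complexes
sit well inside the analysis window: a spectral peak within one Stockwell
window width (σ = 1/f, i.e. 0.25 s at 4 Hz) of the epoch edge is
attenuated and biases the crossing time.

## Baseline normalisation

Baseline epochs are sampled uniformly outside all catalogued events plus
a guard margin (default 1 s; dense short recordings need a smaller guard
or a longer recording — the desk-scale tests use 0.25–0.5 s), seeded for
reproducibility. The per-cell baseline mean and SD (per frequency bin and
time frame; a time-collapsed option exists because the time-resolved
choice is a genuine judgement call) z-score each event spectrogram, with
an SD floor of 1e−12 against empty bins. Z maps are invariant to global
rescaling of the recording since the baseline is recomputed on the scaled
data.

## Circular statistics

κ is estimated from the mean resultant length R by Fisher's piecewise
maximum-likelihood approximation with the usual small-sample correction
below n = 15. Rayleigh uses Z = nR² with the standard finite-n corrected
p-value. Watson–Williams uses the F statistic with the 1 + 3/(8κ̂)
correction; the equal-concentration test is the concentrated-case
two-sample F test on dispersions (n − R), with textbook n − 1 degrees of
freedom. Both carry `valid` flags (pooled R̄ ≥ 0.45 and ≥ 0.7
respectively); the κ = 1.08 vs 0.32 comparison the package is typically
used for sits outside the equal-κ test's nominal validity and is flagged
as such, while remaining decisively significant at realistic sample
sizes. Calibration (type-I error within [0.04, 0.06] at α = 0.05, 2000
Monte-Carlo draws) is asserted inside each test's validity regime.

The phase-locking factor is PLF(f, t) = |mean over events of unit phasors
of the Morlet phase|; the control matrix shuffles each event's phases
along time per frequency bin (seeded), and each cell gets an
equal-concentration test against control, Bonferroni-corrected at
α / (n_t · n_f). Under the null the expected PLF is ≈ n^−1/2.

The synchrony scan filters both (bipolar; monopolar inputs are refused
without an explicit override, because reference effects masquerade as
synchrony) signals at 1 Hz-stepped, 3 Hz-wide bands, pools the Hilbert
phase differences over all POI frames, and compares κ against baseline
frames. Phase differences decorrelate over roughly 1/bandwidth seconds,
so the equal-κ *test* uses frames subsampled at that interval — feeding
every autocorrelated frame into a test that assumes independence produces
wholesale false positives; the κ estimates themselves use all frames.

## Phase–amplitude coupling

The five-step modulation-index procedure: Hilbert phase of the
low-frequency components (2–20 Hz grid, 0.5 Hz step, 3 Hz bandwidth) and
Hilbert envelope of the high-frequency components (2–98 Hz grid, 1 Hz
step); envelope binned over 18 half-open phase bins; mean amplitude per
bin per event; Kullback–Leibler distance of the normalised bin
distribution from uniform; division by log(18). Filters run on the
continuous recording and the event windows are sliced afterwards —
band-pass filtering an isolated 800 ms window at 2 Hz is dominated by
transients. MI is computed per event and averaged (a pooled option
exists; the per-event reading matches "per bin of phase for each event").

Two numerical choices matter:

- **Exact bounds.** Zero bins follow the 0·log 0 = 0 convention, so
  MI(uniform) = 0 and MI(single bin) = 1 hold exactly rather than to
  within an ε-regularisation; an additive ε would make the bounds
  approximate for no benefit, since empty bins are already flagged by
  `amplitude_by_phase()`.
- **Adaptive amplitude bandwidth.** Amplitude modulation of a carrier at
  f_amp by a phase frequency f_phase lives in sidebands at
  f_amp ± f_phase. A fixed 3 Hz-wide amplitude filter is physically
  unable to pass those sidebands for any f_phase above ≈1.5 Hz, and the
  measured envelope is then flat regardless of true coupling. The
  default amplitude bandwidth is therefore max(bw, 2·f_phase + 2)
  (quantised to 2 Hz for filter caching), the field's standard remedy; a
  scalar `amp_bw` forces a fixed bandwidth for strict replication.

On short Hann-windowed transients the MI phase-frequency peak is biased
upward by ~0.5–1 Hz (off-centre phase filters produce nonuniform phase
occupancy and occasional empty bins, which inflate KL). Since adjacent
0.5 Hz-stepped bands of a 3 Hz filter bank overlap by over 80 %, peak
localisation below 1 Hz is not meaningful there; recovery of the
generator's coupling pair is asserted at 1 Hz resolution.

## Directed connectivity

A Kalman-filtered TVAR model estimates per-sample AR coefficients: per
sink channel, the state is the stacked coefficient vector over all
sources and lags, the observation regresses the current sample on the
`order` past samples, and the random-walk state model is implemented as
covariance inflation P ← P/(1 − c) (the exponential-forgetting form);
c → 0 recovers the ordinary least-squares VAR solution and larger c
tracks faster — both limits are asserted in tests. The recursion is
compiled (RcppArmadillo); channels are jointly rescaled (coefficients are
invariant to a common scale), P is re-symmetrised each step and its trace
capped, and the innovation-variance estimate floored — without these
guards the multiplicative inflation diverges on oversampled, strongly
collinear regressors.

The spectrum uses Ā(f, t) = I − Σ_m A_m(t) e^{−i2πfm/fs} (the leading
identity term included by default; the bare transform is a flag) and

APDC²_ij(f, t) = |Ā_ij|² / Σ_k |Ā_ik|².

The default denominator sums over **sources k for a fixed sink i** (row
normalisation), following the printed form of the method this package
implements; the standard PDC column normalisation (over sinks for a fixed
source) is `normalization = "source"`. The two differ materially: on a
resonant driver the sink-normalised ratio degenerates (the driver's own
diagonal term vanishes at its resonance, inflating the reverse
direction), so directionality *inference* should use the source
normalisation — which is what the static-PDC oracle in the acceptance
tests computes — while the sink form is retained as the printed default
for replication. iAPDC is the mean of APDC² over the discrete frequency
grid in [f1, f2].

Sampling rate matters more than anything else here: the one-step
innovation of a 3–5 Hz process at 1 kHz is negligible, so a genuinely
lagged slow drive is information-theoretically invisible to a low-order
VAR at that rate. General decimation in the package targets 1 kHz, but
the slow-band connectivity stage decimates further to
`connectivity_fs = 50` Hz so that the model span (order/rate = 100 ms)
covers physiologic transmission lags; the drive-gain contrast is decisive
at 50 Hz and flat at 200 Hz–1 kHz.

Cross-correlation lags are computed on band-filtered signals over integer
sample shifts; the sign convention is fixed by construction tests: a
second signal delayed by 64 ms reports a lag of −64 ms, and the estimator
is antisymmetric.

## Peri-event spike analyses

PSTHs pool counts over events (bin width must divide the window).
Laminar ratios normalise firing in the down-state (−180 to −30 ms) and FR
(−30 to +20 ms) windows over the preceding baseline, taken as the
−500 to −200 ms segment of each epoch (the method's "preceding baseline"
is otherwise unspecified); channels with zero baseline spikes are flagged
and excluded. Onset chronology smooths the across-event average binary
train with a unit-area 10 ms Hanning window — unit area makes the trace a
local rate estimate — and takes the first crossing of baseline mean + 3
baseline SD within ±30 ms, per channel independently (a common threshold
across channels would conflate rate differences with latency
differences); channels that never cross are excluded from the ranking,
and ties share ranks. Precedence fractions count reference events
preceded by another region's event within 10 ms / 500 ms windows against
a matched −1000 to −500 ms baseline window, compared by a paired rank
test on the per-event indicators.

## The synthetic-data generator

`generate_recording()` is first-class, tested code; its defaults *are*
the study conditions the package emulates: 16 kHz, three regions ×
16-contact probes, ~800 ms complexes, slow oscillation at 4 Hz, IED
carrier at 27 Hz with envelope (1 + pac_depth·cos φ)/2 (depth 0.8), one
FR burst (450 Hz, 8 cycles, 5× background SD) whose onset falls at slow
phase 1.57 rad, von Mises spike locking κ = 1.08/μ = 0.56 in events vs
κ = 0.32/μ = 0.18 at baseline, LH/RH leading FC by 64/52 ms, and a
directed LH→FC slow-band drive. `desk_profile()` (4 kHz — the lowest rate
keeping the FR band under Nyquist with margin — 60 s, 30 complexes, 4
contacts) is the test-scale variant; the test suite and acceptance checks
run at desk scale.

Structural choices worth knowing:

- The complex carries **one coherent slow oscillation**; the coupling
  phase frequency defaults to the slow frequency itself, so ground-truth
  coupling is (slow_freq, 27 Hz). Two incommensurate "slow" frequencies
  in one complex would make the truth labels ambiguous.
- The FR sits on the slow-oscillation cycle nearest the first quarter of
  the complex, so the −200/+600 ms POI around the FR covers the complex —
  the geometry the analyses assume.
- Deterministic LFP components carry a linear **depth gradient** along
  each probe (gain 1 + depth_gradient·(0.5 − depth fraction)): laminar
  gradients are precisely what the bipolar montage measures, and with a
  flat profile the montage would cancel the oscillation entirely.
- Spike waveforms (broadband clicks) go on the deeper "wideband"
  contacts; the most superficial FC contact is the spike-free LFP contact
  carrying the FR waveform. Without this separation the two detectors
  contaminate each other with click/carrier artifacts — the real study
  handled such artifacts by visual review, which the package replaces
  with ground-truth validation.
- The directed drive is the **LH-specific stochastic** narrowband slow
  component, AR(2)-resonator shaped, delayed by `drive_lag` (40 ms) and
  Hann-gated into FC during complexes. A deterministic waveform cannot
  carry attributable directed structure — it is predicted equally well by
  any region's own past — and the inter-regional POI coherence induced by
  the shared complexes raises *both* directions relative to baseline, so
  the decisive directed contrast is drive_gain > 0 vs drive_gain = 0.
- Background is Gaussian 1/f^α (α = 1) with a probe-wide common-mode
  term; amplitudes (slow 8×, IED 3×, FR 5×, spikes 10× background SD) are
  realism calibrations chosen once — absolute amplitudes are not reported
  by the emulated study, so everything is defined relative to the
  background SD.

What the generator does **not** emulate: biophysical (conductance-based)
dynamics, seizures, artifacts and line noise, FR laminar profiles,
spatially realistic volume conduction, animal-to-animal variability, or
event-rate nonstationarity. Passing recovery tests on this generator
therefore demonstrates correctness of the estimators under the stated
signal model, not robustness to everything real data can do.

## Problem sizes and runtime choices

The suite runs the desk profile (60 s at 4 kHz) for detection and
locking; 90 s profiles for the PAC and directed-drive recoveries; a
500 s, 2-contact profile for the regional-onset chronology (median-based
onsets need ~150 events and generous clean baseline); and 100-seed VAR
simulations (n = 8000 at 100 Hz) for directionality. These sizes were
chosen so each recovery is decisive under its Monte-Carlo noise while the
whole suite stays comfortably runnable on a laptop.

## Known limitations

- The equal-concentration and Watson–Williams tests are approximations
  whose nominal level holds only in their concentrated regimes; outside
  them results carry validity flags rather than corrected p-values.
- The IED-association and band-onset criteria inherit the arbitrariness
  of fixed z thresholds; regional comparisons of onsets are sensitive to
  baseline-SD estimation error (≈ tens of ms at desk scale).
- Kalman-TVAR directionality is meaningful only when the analysis rate,
  model order and expected lags are commensurate; the package picks safe
  defaults but cannot validate a user's choice against unknown true lags.
- The flat-binary recording format stores float32 samples; round trips
  are exact after the first write but quantise doubles on the way in.
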