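---
title: "Methods: models, parameters and design choices in hippoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in hippoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

hippoquant implements the quantitative stages of a hippocampal-inhibition
study as a reusable pipeline: sIPSC detection from voltage-clamp traces,
sharp-wave-ripple (SWR) detection and power, theta/gamma spectral analysis,
isosbestic-corrected fiber photometry with locomotion coupling,
novel-object-location (NOL) scoring, and staining quantification. Because
each stage is ordinarily validated against data that no public archive
holds, every stage ships with a seeded generator that produces realistic
inputs *with ground truth*, and the test suite scores each detector against
its generator. This vignette explains the models, the tunable parameters,
and the design decisions taken where the underlying procedures are
conventionally under-specified.

## Time, intervals and units

All signals are uniformly sampled (`uniform_signal`): sample `i` (0-based)
owns the half-open slot `[t0 + i/rate, t0 + (i+1)/rate)`. Behavioral and
analytic states are half-open interval sets (`interval_set`), so adjacent
intervals tile time without double-counting a sample; `restrict()` evaluates
`start <= t < end` on exact sample timestamps. Seconds everywhere; LFP in
mV, currents in pA, fluorescence in arbitrary units.

## Sharp-wave ripples

The detector band-passes the pyramidal-layer LFP to 70–250 Hz, rectifies,
and smooths with a Gaussian kernel to form an envelope; the envelope is
standardized against its mean and SD during immobility, and events are
maximal runs above 3 SD.

Choices the procedure leaves open, and what we chose:

* **Envelope definition.** A band-passed oscillation smooths toward zero,
  so "filtered and smoothed" is read as Gaussian smoothing of the
  *rectified* (absolute-value) filtered signal — the minimal reading under
  which thresholding is meaningful. The kernel SD is 4 ms, about half a
  ripple cycle at 150 Hz: long enough to bridge rectification troughs,
  short enough to track the ripple's ~20 ms amplitude envelope.
* **Filter.** Zero-phase filtering is required so event times are unbiased.
  We filter in the frequency domain with a cosine-tapered transfer function
  that reaches full rejection at 0.8x the lower and 1.2x the upper band
  edge (the test suite verifies > 40 dB at both points). Before padding,
  the line through the record's endpoints is removed and the first/last
  0.25 s cosine-tapered: an edge discontinuity — large when the signal has
  strong low-frequency content — would otherwise leak slowly decaying
  ringing into the band deep inside the record.
* **Event criteria.** Candidates above 3 SD closer than 15 ms are merged;
  the 20–250 ms duration window is applied to the *supra-threshold core*.
  Brief noise excursions cross a 3-SD threshold routinely, but only a
  genuine ripple holds it for tens of milliseconds, so a core minimum
  duration is what replaces the visual validation step with a deterministic
  criterion. Each surviving event is then extended to the 1 SD crossings,
  which define its reported onset and offset; `mean_power_sd` is the mean
  standardized envelope over that extent and `max_power_sd` its peak.
* **Rate denominator.** SWRs are immobility events; `swr_rate()` counts
  events whose peak lies in immobility and divides by immobility time
  (total recording time available by flag).
* **Baseline.** Single-pass estimation over immobility; no iterative
  re-estimation excluding detected events. With ripples occupying a few
  percent of immobility this deflates SD-unit powers by roughly 5–10%,
  uniformly across conditions.
* **Common threshold.** For longitudinal comparisons,
  `detect_swr_common_threshold()` pools the immobility-restricted envelopes
  of all sessions, computes one mean/SD, and detects per session with the
  shared statistics — removing any between-session threshold difference.

### The LFP generator and its calibration

`simulate_lfp()` builds 1/f background noise (spectral exponent 2 by
default, matching the steep spectral decay of pyramidal-layer LFP), adds a
theta–gamma complex during mobility only (8 Hz theta with a co-varying
4 Hz slow component at 0.35 relative amplitude, plus 30–90 Hz band-limited
gamma), and inserts Gaussian-enveloped 150 Hz ripples at Poisson times
during immobility, thinned to a 200 ms refractory spacing. Ripple amplitude
is specified in *analysis-envelope SD units*: for each event the generator
solves (by a local root search against the same envelope definition the
detector uses) for the raw amplitude at which the envelope of
background-plus-ripple peaks at exactly `mu + amp_sd * sd`. The 3-SD
criterion can therefore be exercised directly: an event programmed at 6 SD
is measured by the detector at 6 SD up to the baseline shift caused by the
events themselves.

Two numerical points deserve mention. First, the background exponent: with
exponent 1 the ripple-band envelope of the background decorrelates within
~5 ms, which narrows the effective supra-threshold core of
moderate-amplitude calibrated events below the 20 ms minimum; exponent 2
gives the envelope a correlation time comparable to the ripple envelope and
is also the more realistic LFP spectrum. Second, the 4 Hz theta component
is tied to the theta amplitude so that the 8 Hz / 4 Hz power ratio is a
waveform property: reducing oscillation amplitude (the "blockade"
condition) lowers theta and gamma power but leaves the ratio unchanged,
which is exactly the dissociation the spectral stage is meant to resolve.

## Spectral analysis

`power_spectrum()` is a Welch estimate: Hamming-windowed one-sided
periodograms on 50%-overlapping segments of length `1/resolution_hz`
(2 s at the default 0.5 Hz), normalized so the integral of the density
equals the signal variance (verified against Parseval on white noise).
Band powers sum density over half-open bands, so slow gamma (30–60) and
fast gamma (60–90) add exactly to gamma (30–90). Line noise at 50 Hz and
harmonics is removed by replacing +/-2 Hz around each harmonic with linear
interpolation *of log-power* between the nearest untouched bins — linear
interpolation in log space respects the 1/f background. The 8/4 Hz theta
ratio reads the single 0.5 Hz bins at 8.0 and 4.0 Hz (a +/-0.25 Hz band
mode is available). Theta segments are a declared stand-in for
"spectral criteria": 2 s windows stepping 1 s, theta (4–10 Hz) over
reference (1–4 Hz) power ratio above 2, unions of consecutive windows kept
if at least 3 s — the defaults recover programmed mobility with Jaccard
overlap above 0.8 in simulation. No detrending is applied by default.

## Spontaneous IPSCs

Detection works on a differentiated copy of the trace: the first difference
times the rate (pA/ms), boxcar-smoothed (1 ms default), must exceed a
threshold (12 pA/ms default) continuously for a minimum trigger duration
(0.4 ms default). These are exactly the two per-cell criteria an
electrophysiologist adjusts; the defaults were characterized on simulated
trains (5 Hz, 50 pA, 5 pA noise at 20 kHz: recall above 0.95 at precision
1.0) and are recorded in the output's provenance attribute. The onset is
the first supra-threshold sample; the peak is searched 10 ms after onset;
the amplitude is peak minus the *median* of the 5 ms pre-onset baseline
(robust to overlapping decay tails). One deliberate deviation from the
naive reading: amplitude is measured on the boxcar-smoothed copy of the
trace, because the raw maximum over a 10 ms window carries an
order-statistic bias of about two noise SDs (+20% at 5 pA noise on 50 pA
events), while 1 ms smoothing attenuates the biexponential peak
(rise 0.5 ms, decay 10 ms) by under 0.3%. Re-triggers within 2 ms of an
onset are ignored; overlapping events otherwise stay separate rows — no
deconvolution, since the downstream statistics are counts and amplitudes.

The generator sums unit-peak-normalized biexponential kernels
`exp(-t/tau_d) - exp(-t/tau_r)` at Poisson onsets with log-normal
amplitudes, over a slow sinusoidal drift and Gaussian noise; outward
polarity by default, matching recordings clamped at 0 mV.

## Fiber photometry

`isosbestic_dff()` fits the 405 nm channel onto the 465 nm channel with a
whole-session least-squares affine map and reports
`100 * (F465 - fit(F405)) / fit(F405)`. Bleaching and motion artifacts
shared by the channels cancel; the session mean of dF/F is ~0 by
construction. The generator treats the motion artifact as *fractional*
(multiplicative) — motion perturbs light collection proportionally in both
channels — which is also why the affine fit removes it.

Mobility segmentation thresholds track speed at 0.02 m/s, drops runs
shorter than 1 s, then bridges gaps shorter than 0.5 s; mobility and
immobility partition the span. Transition-triggered averages z-score the
signal per session, align snippets at the transition, and report pointwise
mean and SEM (dropped transitions are counted; a zero-variance signal is
flagged rather than divided by zero).

For coupling analysis the dF/F is *downsampled* to the 15 frames/s
tracking timebase by windowed means — we do not invent sub-frame
kinematics. Instantaneous speed is the frame displacement times the frame
rate passed through a 3-frame median (tracking jitter), and acceleration
its centered difference. The acceleration-response curve bins the
(acceleration, z-dF/F) pairs into equal-count bins separately for positive
and negative acceleration; massive ties at zero acceleration (immobility)
can collapse bins on one side, and the returned table reports the bins
actually formed. The **acceleration modulation index** is defined from the
least-squares quadratic `y = a2 x^2 + a1 x + a0`: with `a_ref` the 95th
percentile of |acceleration|, `index = yhat(+a_ref) - yhat(-a_ref)
= 2 a1 a_ref`. The underlying procedure says only "quadratic fitting", so
this is a declared definition, not a reconstruction: it summarizes the
acceleration-vs-deceleration asymmetry the response curves display, and the
raw coefficients are returned so alternative summaries can be formed. The
index is antisymmetric in the coupling and zero in distribution under a
sign-permutation null. The photometry acquisition rate is not fixed by the
procedure; the generator defaults to 1 kHz and the analyses are
rate-agnostic.

## Behavior (NOL)

Exploration is time in the half-open annulus `[r, r + 0.02 m)` around each
object center — the 2 cm perimetral zone; a mouse cannot occupy the object
footprint, so the zone is an annulus, not a disk. Entries (first frame of
each in-zone run) are reported separately; the discrimination index
`(displaced - familiar) / (displaced + familiar)` uses time, the quantity
zone-based trackers score; zero total exploration flags the index undefined
rather than zero. The track generator is a reflected correlated random
walk in the 0.35 x 0.24 m arena whose `bias` adds an attraction step
toward the displaced object within 10 cm; its ground truth applies the
scorer's own membership rule frame by frame, so scorer and truth agree
exactly by construction — what the round trip tests is the geometry, not
the rule. Unbiased walks mix slowly (single-session zone-time ratios
scatter widely), so the symmetry property is tested on zone time pooled
across seeds.

## Histology

ROI intensity is measured on *equally thresholded* images: one common
threshold per channel per batch, sub-threshold pixels zeroed, mean over all
ROI pixels (a suprathreshold-pixels-only mode is available by flag, since
the phrase is ambiguous). The perineuronal ring is the set of pixels
outside the cell within 3.8 um of it, computed from the Euclidean distance
transform — the exact geometry the procedure leaves open. mRNA "dot surface
density" is read as connected-component count per ROI area after
binarization, with a minimum dot area; the suprathreshold area fraction is
reported alongside. Chance colocalization mirror-flips the signal channel
left-right while leaving ROI masks in place (the source describes this
variously as flipping or rotation; flipping is primary and 180-degree
rotation available as an option). Cumulative distributions are computed per
animal on a common 18-bin grid spanning the pooled range and averaged
pointwise across animals, so every animal contributes equally; the bin
count is configurable, 18 being consistent with the degrees of freedom of
the distribution-level comparisons this analysis feeds.

The stain generator places non-overlapping somata with graded intensities,
rings on a Bernoulli fraction of cells, and Poisson dot counts inside and
outside cells; dots within a soma are kept apart so each remains one
component, which is what makes noise-free dot counts exactly recoverable.

## What the simulations do and do not show

The generators are pure functions of (config, seed) and their ground truth
suffices to score every detector without reference to the rendered signal.
They emulate the *structure* of the real data — event statistics, band
composition, shared-artifact photometry, zone geometry, staining layout —
not its full richness: no electrode drift or unit activity in the LFP, no
seal instability in voltage clamp, no hemodynamic contamination in
photometry, no segmentation errors in histology (ROIs are inputs there, as
in the original procedure). Passing the recovery tests therefore
demonstrates that the implementations measure what they claim under known
conditions; it does not certify performance on pathological recordings.

## Problem sizes and tolerances

The validation suite runs LFP sessions of 120–600 s at 1250 Hz (the ripple
band needs only 500 Hz of bandwidth; results are rate-agnostic and the
generator default remains 20 kHz), voltage-clamp traces of 120 s at 20 kHz,
photometry sessions of 300–600 s at 250 Hz, and 180 x 180 um images at
0.5 um/px — sizes at which every stochastic check (detector recall and
precision, direction analogues across 20 seeds, enrichment tests) is
stable. Numerical identities (scale invariance, half-open additivity,
double-flip involution) are asserted at 1e-6 to 1e-12; statistical
recoveries at the 2–10% level appropriate to their estimator variance.

## Known limitations

* The envelope baseline includes detected events (single-pass); an
  iterative mode is deliberately not implemented.
* The spectral stage offers no time-frequency analysis; theta segments are
  window-resolution (1 s) objects.
* The IPSC stage performs no template matching or deconvolution, so
  near-coincident events (within the refractory window) merge.
* `resample_linear` is linear interpolation: band-limited signals near the
  source Nyquist rate carry the textbook h^2/8 curvature error (2.2% of
  amplitude for 1 Hz sampled at 15 Hz).
* Histology assumes ROI masks are given; no cell segmentation is provided.
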