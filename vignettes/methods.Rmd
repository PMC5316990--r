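---
title: "Detecting and quantifying sparse dentate granule cell activation from population calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying sparse dentate granule cell activation from population calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific setting

Dentate granule cells (DGCs) form the input gate of the hippocampus and are
famous for how rarely they fire: under afferent (perforant-path) stimulation
only a few percent of them generate action potentials. Multicellular calcium
imaging (MCI) makes this population property measurable: somata bulk-loaded
with a calcium indicator (e.g. OGB-1) produce a fluorescence transient when
— and only when — a cell spikes, so the fraction of imaged regions of
interest (ROIs) with a stimulus-locked transient estimates the fraction of
cells recruited by the stimulus. In epilepsy models this sparse recruitment
collapses and recovers in characteristic phases, which is precisely the kind
of effect that lives or dies by the reliability of transient detection and
the downstream filtering rules.

`sparsegate` implements that measurement chain as reusable, tested code:

1. a **synthetic-data generator** that produces ROI fluorescence traces,
   whole populations across slices and pharmacological conditions, and
   juxtacellular voltage traces — all with ground truth;
2. a **transient detector** (the scientific core of the package);
3. **population statistics**: viability filtering, slice exclusion,
   proportional activation, amplitude distributions, granule-cell-layer
   (GCL) position analysis;
4. **electrophysiology helpers**: AP latency measurement and effect sizes
   computed from published summary statistics;
5. the **statistical battery** used for group comparisons.

## The transient detector

Traces are converted to percent dF/F0 with F0 the mean of a pre-stimulus
baseline (all frames before the first stimulus, capped at 1 s; the first 1 s
when no stimulus schedule is attached). The trace is smoothed with a
Savitzky–Golay filter (window 11 frames ≈ 200 ms at 55 frames/s, order 3)
and differentiated by central differences.

Detection then applies two thresholds:

* **Initial (derivative) threshold.** Candidate events are local maxima of
  the derivative exceeding `k_d` × the robust noise scale of the derivative,
  with scale = 1.4826 × MAD over the whole trace and `k_d = 3` by default.
  The MAD scale is what makes the threshold estimable "from the entire
  trace": a transient of the control amplitude scale shifts it by only a few
  percent, where a plain SD would inflate far more. Robustness is relative,
  not absolute — a large, slow transient occupying a sizable fraction of a
  short trace can still shift the MAD scale by ~10%.
* **AUC (second) threshold.** Each candidate is bracketed by the derivative
  zero crossings around its maximum; its onset is the preceding zero
  crossing. The event window runs from onset until the smoothed trace first
  returns to the event's baseline level, capped at the next candidate's
  onset. The area under the smoothed dF/F0 above that level is compared to
  `k_a × σ_s × median(event duration)`, with `k_a = 2` and σ_s the noise SD
  of the *smoothed* trace, estimated robustly as
  1.4826 · MAD(Δ raw)/√2 × (the filter's noise gain). A candidate whose
  integral cannot beat what noise of that scale would accumulate over a
  typical event duration is discarded.

Three numerical details matter and were chosen deliberately:

* **Event baseline level.** The derivative zero crossing that defines the
  onset sits, by construction, at a local minimum of the smoothed trace.
  Using that sample as the event's baseline makes noise excursions
  effectively unbounded (the trace rarely returns *below* a local minimum),
  which inflates noise AUCs catastrophically. The baseline is therefore the
  median of up to 1 s of pre-onset smoothed trace, floored at the global
  trace median. With this definition the false-call rate on flat noisy
  traces is below 1% per 10 s trace at default parameters.
* **Filter edges.** Savitzky–Golay edge projections produce spurious, very
  large derivative values in the first and last window of a trace; one
  window length at each end is excluded from threshold estimation and
  candidate search.
* **Peak amplitude estimator.** The peak is measured on the *unsmoothed*
  dF/F0 as the maximum of a 3-frame boxcar within the event window. A bare
  single-frame maximum is biased upward by order +1% dF/F0 under 1%
  frame noise (the maximum of several near-peak noisy samples); the
  smoothed-trace maximum overshoots sharp peaks by ~4% (order-3 polynomial
  ringing). The boxcar estimator stays within one frame's kernel change of
  the true peak on clean data and within a few percent of the median under
  noise.

Characterization reports onset, peak time/amplitude, AUC, the 90%-decay
time (first linearly interpolated crossing of baseline + 0.1 × (peak −
baseline) after the peak) and a decay constant from a log-linear
least-squares fit between peak and 90% decay. For a clean exponential decay
the 90%-decay interval equals τ·ln 10; the package recovers this within one
frame.

**Onset convention.** Smoothing advances the apparent onset (the derivative
zero crossing) by up to half a filter window, ~90 ms at the defaults. The
reported `onset_time` is the zero crossing itself; when events are assigned
to stimuli the half-window advance is compensated, so an event evoked 30 ms
after a stimulus is correctly attributed even though its reported onset
precedes the stimulus slightly. Stimulus assignment uses a 500 ms
post-stimulus response window; events matching no stimulus are labelled
spontaneous.

**Detection floor.** At 1% noise the two thresholds make transients below
roughly 4% dF/F0 undetectable (by design — they are indistinguishable from
noise at single-trial resolution). Consequently the *detected* amplitude
distribution of a group whose true median sits near the floor is
right-censored, and detected activation probabilities are the generator
probability × detection sensitivity. Tests that quantify measurement
accuracy therefore use amplitudes above the floor.

## The synthetic generator

The generator emulates OGB-loaded DGC somata at 55 frames/s:

* **Transient shape**: difference of exponentials normalized to its peak,
  τ_rise = 20 ms, τ_decay = 500 ms — typical somatic OGB kinetics. Traces
  are built as F0·(1 + drift·t)·(1 + Σ kernels/100) + Gaussian noise
  (default SD 1% of F0, drift 0). Recording noise, bleaching and kinetics
  are stand-ins chosen once at these values; all are exposed in
  `acquisition_config()` / `group_profile()`.
* **Amplitudes**: log-normal with the group's published median (medians and
  right-skewed distributions are what the study reports), dispersion 0.4
  log-units by default. Multi-spike responses are modelled purely as larger
  amplitude draws; single-trial spike counts are not simulated (the imaging
  modality itself cannot separate spike count from indicator/buffering
  changes).
* **Group profiles** (`dgc_group_profiles()`): activation probabilities per
  stimulus intensity (100/400 µA), amplitude medians, and AP latency
  distributions for the five experimental groups of the epileptogenesis
  time course, taken from the published values (4/21, 57/82, 13/43, 54/81,
  54/91% activation; amplitude medians 5.2/6.6 … 10.1/19.7% dF/F0;
  latencies 7.28, 5.82, 6.94, 5.65 ms). Latency SDs are reconstructed from
  the printed SEMs and cell counts; no latency was published for the
  >6-month group, which reuses the 2–3-month value. The saturating
  picrotoxin (PTX) viability condition activates cells with probability
  0.95 and draws amplitudes from the strongest-intensity median (tetanic
  stimulation).
* **Positions**: GCL positions are uniform on [0, 100]% (inner→outer
  border), matching the near-uniform spread of active-cell locations.
* **Juxtacellular traces**: 20 kHz, a biphasic stimulus artifact, and one
  stereotyped AP waveform that is exactly zero before its onset, so
  ground-truth latency is unambiguous.

What passing tests on these data do *not* show: real recordings have
correlated noise, baseline drift that is not linear, neuropil contamination,
movement, and overlapping ROIs. The generator's simple noise model is
sufficient to exercise thresholds and calibration, not to certify
performance on any specific microscope.

## Population rules

* **Viability**: cells inactive in every condition including saturating PTX
  are removed (deafferented or dead by assumption).
* **Slice exclusion**: a slice with ≥ 70% of ROIs inactive under PTX is
  excluded. The published sentence is ambiguous about strictness at exactly
  70%; the strict-≥ reading is used and the boundary is a parameter.
* **Proportional activation** is computed per slice over viable cells, and
  per-slice percentages (not pooled cells) are the unit of analysis for
  group comparisons, matching how the study reports its sample sizes.
* **Position analysis**: active-vs-all position distributions are compared
  with a two-sample KS test; inner/outer (boundary 50%) membership across
  groups with Fisher's exact test.

## Statistics

Normality is screened per group with a KS test against a fitted normal
(note: with estimated parameters this screen is conservative); non-normal
data go to Kruskal–Wallis with Dunn's rank post hoc (Bonferroni family
correction by default — the convention of the commercial software implied by
the study's figure legends; switchable). Normal data are screened for equal
variances with Brown–Forsythe (ANOVA on |x − group median|); unequal
variances trigger a log(value + 1) transform before one-way ANOVA with
Dunnett's (via `multcomp`, i.e. multivariate-t critical values) or Tukey's
post hoc. This decision pipeline is packaged as `auto_compare_groups()`,
whose null rejection rate at α = 0.05 is verified to lie in [0.03, 0.07].

The robust outlier rule (`rout_outliers()`) implements the
one-sample/constant-fit case of FDR-based robust outlier elimination:
residuals from the median, scale = 68.27th percentile of |residuals| with an
n/(n−1) correction, and a step-down test of the largest residuals against
t-tail probabilities at FDR boundary q·(n−i+1)/n (q = 1% by default). The
full robust-regression variant is intentionally out of scope. The "no flags
as q → 0" limit holds once q falls below the largest residual's tail
probability — with a gross outlier planted at 100× the scale that is
~5·10⁻²⁰, not machine zero.

Fisher's exact test, KS tests, Kruskal–Wallis H, ANOVA and Tukey HSD are
delegated to base R / `car` / `multcomp`; each is validated in the test
suite against an independently written brute-force oracle (exhaustive
hypergeometric enumeration for every 2×2 table with N ≤ 40, first-principles
rank and sum-of-squares arithmetic for the others).

One published worked example is *not* reproducible from its printed inputs:
the inner-GCL localization counts 33/34 vs 327/373 give a two-sided Fisher
p ≈ 0.156, not the printed 0.7099. The package reports the computed value.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on synthetic data:
500-transient detector round trips, 6 slices × 60 cells per group for
activation recovery, 2000-replicate null simulations for type-I error, and
exhaustive 2×2 enumeration to N = 40. These sizes give binomial/Monte-Carlo
error well inside the asserted tolerances while keeping a full run in a few
minutes on one core. Every stochastic step takes an explicit integer seed;
`run_pipeline()` embeds its seed and resolved configuration in its report,
so a run is reproducible from the report alone.

## Known limitations

* Detection assumes positive-going transients with fast rise and slow
  decay; inhibitory or biphasic signals are out of scope.
* The onset estimate inherits a systematic half-window advance from
  smoothing (documented above) rather than a per-event model-based
  correction.
* The amplitude floor (~4% dF/F0 at 1% noise) censors small events; group
  comparisons of detected amplitudes near the floor inherit that censoring.
* `ks_normality` with estimated parameters is anti-conservative as a
  goodness-of-fit test (it under-rejects); it is used as a routing screen,
  and its effect on the driver's type-I error is tested, not assumed.
* No motion correction, ROI segmentation, neuropil subtraction or spike
  inference.
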