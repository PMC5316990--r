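# sparsegate

Calcium-transient detection and population-activation analysis for
multicellular calcium imaging (MCI) of hippocampal dentate granule cells
(DGCs).

## The problem

The dentate gyrus gates cortical input to the hippocampus through the
extremely sparse firing of its granule cells: under perforant-path
stimulation only ~4–21 % of DGCs spike in healthy tissue, and this fraction
explodes 10–20-fold during epilepsy development. Measuring that collapse
from population imaging requires a reliable chain of steps — somatic ROI
fluorescence → ΔF/F₀ → transient detection → viability filtering →
per-slice activation percentages → group statistics — each of which
contributes thresholds and exclusion rules that shape the result.

`sparsegate` packages that chain for anyone analyzing stimulus-evoked
somatic calcium transients in ROI trace tables (one column per ROI, 55
frames/s by default), together with a calibrated synthetic-data generator
so every stage is testable against ground truth without raw recordings.

## The core method

A trace is converted to %ΔF/F₀ (F₀ = pre-stimulus baseline mean), smoothed
with a Savitzky–Golay filter (11 frames, order 3) and differentiated.
Detection applies two thresholds:

1. **derivative threshold** — candidate events are local maxima of the
   derivative above `k_d · 1.4826 · MAD(derivative)` (`k_d = 3`), each
   bracketed by its flanking derivative zero crossings (the preceding one
   is the onset);
2. **AUC threshold** — the integral of smoothed ΔF/F₀ above the event's
   baseline, from onset to return-to-baseline, must exceed
   `k_a · σ_s · median(event duration)` (`k_a = 2`, σ_s = robust noise SD
   of the smoothed trace).

Accepted events are characterized by onset, peak amplitude and time, AUC,
90 %-decay time (for an exponential decay this interval is τ·ln 10) and a
fitted decay constant, then assigned to stimuli within a 500 ms response
window. Downstream, cells inactive even under saturating picrotoxin (PTX)
are excluded as non-viable, slices with ≥ 70 % PTX-inactive ROIs are
dropped, and proportional activation (% of viable cells responding) is
computed per slice and compared across groups with the appropriate
nonparametric or parametric battery (Kruskal–Wallis + Dunn, ANOVA +
Dunnett/Tukey, Brown–Forsythe screening, log(x+1) stabilization, Fisher
exact, robust FDR outlier removal).

## Worked example

Simulate one early-post-insult ROI responding to two stimuli and detect its
transients:

```r
library(sparsegate)
acq  <- acquisition_config(n_frames = 550, stimulus_times = c(2, 6),
                           noise_sd = 0.01)
prof <- dgc_group_profiles()$se_3_7d
g  <- generate_trace(prof, acq, respond = c(TRUE, TRUE),
                     intensity = "100uA", roi_id = "roi01", seed = 42)
ev <- detect_events(g$trace)
ev[, c("peak_id", "onset_time", "peak_dff", "decay90_time", "decay_tau",
       "evoking_stimulus_index")]
#>   peak_id onset_time peak_dff decay90_time decay_tau evoking_stimulus_index
#> 1       1   1.927273 17.33344     3.152572 0.4817091                      1
#> 2       2   5.927273 11.01674     7.207968 0.5057187                      2
g$ground_truth[, c("true_onset", "true_amplitude")]
#>   true_onset true_amplitude
#> 1   2.005197       16.95844
#> 2   6.006518       11.33204
```

Both injected transients (17.0 and 11.3 %ΔF/F₀, onsets ~5–7 ms after the
stimuli) are recovered: amplitudes within ~3 %, decay constants within ~4 %
of the generator's 0.5 s, and each event attributed to its stimulus. The
reported onset precedes the stimulus because smoothing advances the
derivative zero crossing by up to half a filter window (~90 ms); stimulus
attribution compensates for this (see the methods vignette).

The full pipeline — simulate, detect, filter, summarize, test — in one
call:

```r
rep <- run_pipeline(groups = dgc_group_profiles()[c("control", "se_3_7d")],
                    n_slices = 3, n_cells_per_slice = 12,
                    conditions = c("400uA", "PTX"), seed = 1)
rep
#> Pipeline report: 2 group(s), seed 1
#>     group condition pct_active
#> 1 control     400uA   18.77104
#> 2 se_3_7d     400uA   77.77778
#> 3 control       PTX  100.00000
#> 4 se_3_7d       PTX   91.66667
rep$tests$activation_400uA
#> Kruskal-Wallis: statistic(1) = 3.857, p = 0.04953
```

Control slices sit near the configured 21 % activation, the early
post-insult group near 82 %, and PTX activates nearly every viable cell —
the detected percentages are the generator's probabilities filtered through
the detector's sensitivity.

A thin command-line wrapper for shell use lives at
`inst/cli/sparsegate.R` (`simulate`, `detect`, `latency`, `report`
subcommands, optional YAML config).

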