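---
title: "Methods: PRF-tuning analysis of ultrasound neuromodulation calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PRF-tuning analysis of ultrasound neuromodulation calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`usprf` implements a single-cell analysis pipeline for transcranial ultrasound
(US) neuromodulation experiments in which neurons are imaged with a genetically
encoded calcium indicator (GCaMP7f, 20 Hz frame rate) while 1 s trains of US
are delivered at physiologic pulse repetition frequencies (PRFs; 10, 40 and
140 Hz). The question the pipeline answers is whether individual neurons are
activated by US, whether that activation is specific to one PRF, how it
changes pairwise network synchrony, and what the evoked responses look like —
plus a companion module for single-cell RNA expression heterogeneity of
mechanosensitive channels. This vignette explains the models, the tunable
parameters and their defaults, the numerical choices, and what the synthetic
generator does and does not emulate.

## Experimental structure assumed

Two trial protocols are supported, encoded by `session_config()`:

* **single PRF** — 20 trials of 50 s (10 s pre-US, 1 s US, 39 s recovery),
  one PRF throughout;
* **alternating** — 25 blocks, each a random permutation of one 21 s trial
  per PRF (10 s pre, 1 s US, 10 s post), i.e. 75 trials, 25 per PRF.

A 0.5 s pause separates trials. In real recordings the pause creates missing
frames that are filled by shape-preserving interpolation; the trace-level
generator produces the continuous uniform 20 Hz grid directly, which is what
that interpolation yields on-grid. All times are in seconds, windows are
half-open `[start, end)`, and sample `i` (1-based) covers
`[(i-1)/fs, i/fs)`.

## The synthetic generator

`simulate_session()` draws, per neuron, spontaneous calcium events as a
homogeneous Poisson process at `baseline_rate` (default 3.10 events/min, the
rate observed in motor cortex with GCaMP7f). Each event is a linear rise of
duration `Normal(1.11, 0.67)` s truncated above 0.15 s (the empirical
rising-phase distribution) followed by an exponential decay with
`decay_tau_s = 0.7` s, a GCaMP7f-like value chosen once since indicator
kinetics are not part of the reported analysis. Event amplitudes are
`Normal(1, 0.15)` truncated above 0.5 in dF/F units and the additive Gaussian
noise SD is 0.1, i.e. a typical amplitude-to-noise ratio of 10 (transients in
awake-mouse GCaMP7f imaging are conspicuous; the detector's own criterion only
requires 2.5x). A fraction `frac_modulated` (default 0.15 per PRF) of neurons
is assigned a preferred PRF and additionally fires an evoked event with
probability `p_evoked` (default 0.5) at a uniform latency of 0–0.3 s after
each onset of that PRF, consistent with a ~200 ms population response latency.
`simulate_sham_session()` keeps the identical trial structure and omits every
evoked component, emulating stimulation without acoustic coupling gel.

What the generator does **not** emulate: slow baseline drift and
photobleaching beyond a global linear trend, motion artefacts, correlated
(shared) spontaneous activity between neurons, bursting/refractory deviations
from Poisson timing, and amplitude attenuation for deep cells. Passing the
recovery tests therefore shows the pipeline is correct under the stated
statistical structure, not that it is robust to every artefact of real
recordings.

`simulate_movie()` renders traces into pixel movies (circular ROIs on a
spatially smooth, slowly drifting background, plus pixel noise) so the
extraction path can be tested end-to-end, and `simulate_umi_counts()` plants
population differences in single-cell UMI counts using a zero-truncated
negative binomial for the expressing fraction — zero-truncated so the planted
`frac_expressing` equals the expected observed nonzero fraction.

## Trace extraction and dF/F

`extract_traces()` computes, per frame, the mean intensity of each ROI minus
the mean of its surrounding donut (annulus from 15 to 50 px around the ROI
centroid, excluding pixels of *any* ROI), removing local background; a
spatially uniform offset cancels exactly. `preprocess_traces()` then applies a
fixed four-step pipeline: (1) shape-preserving piecewise-cubic (PCHIP)
interpolation onto a uniform 20 Hz grid; (2) linear detrend; (3) min–max
normalization to [0, 1]; (4) per-trial subtraction of the mean over the 10 s
pre-US window, so every trial's pre-onset baseline averages exactly zero. The
result is called dF/F throughout even though the ordering (normalize, then
baseline-subtract) differs from the classical dF/F ratio — the printed order
is implemented verbatim. Constant traces cannot be min–max normalized and are
dropped; dropped neurons are absent from all downstream tables rather than
carried as NA rows. PV labels come from `match_pv()`: a GCaMP ROI is
PV-positive when strictly more than 50% of its pixels fall in any
tdTomato ROI after an optional precomputed projective warp.

## Event detection

`detect_events()` finds calcium events by their spectral signature. The trace
is analysed with a sliding multitaper spectrogram (1 s window, NW = 2, K = 3
Slepian tapers, computed from the tridiagonal eigenproblem) and the power in
the 0.2–2 Hz band — where a 0.3–2 s rise concentrates its energy — is
normalized by the total non-DC power of the window. Candidate peaks are local
maxima of a lightly smoothed trace (0.25 s moving mean) whose normalized band
power exceeds its median over the recording. Each candidate's rise onset is
searched within 3 s before the peak; events must have a rise time strictly
greater than 100 ms and an amplitude strictly greater than 2.5x the pre-event
SD (2 s of clean raw trace before the onset; the robust first-difference SD,
`mad(diff(x))/sqrt(2)`, when less than 0.5 s is clean).

Three numerical choices deserve explanation because a literal implementation
fails on noisy data:

* **Onset localisation.** The "minimum of the trace within 3 s before the
  peak" is ill-posed under noise: on a flat baseline the argmin is an extreme
  statistic that lands uniformly anywhere in the flat region, inflating rise
  times by up to a second. The onset is instead the *last* pre-peak timepoint
  at which the trace sits within `rise_frac` (default 0.1) of the window's
  robust floor (10th percentile), relative to the peak excursion. On
  noise-free transients this reproduces the constructed rise times exactly;
  under 10:1 signal-to-noise the mean bias is below 0.05 s.
* **Consecutive events.** When the 3 s window reaches back across a preceding
  event, the onset search restarts at the *separating trough*: the latest
  point the trace never undercuts again before the peak, that is a local
  minimum of its trailing 0.25 s, and whose flanking drop and rise both exceed
  2.5x the noise SD. Without this rule a follower's onset lands before its
  predecessor and the two merge. Events overlapping in their rise intervals
  after this are genuinely compound and are merged, keeping the higher peak.
* **False-positive control.** Candidates rising straight from baseline must
  also clear the amplitude criterion on the heavily smoothed (1 s) trace,
  whose residual noise is far below threshold; a candidate behind a credited
  separating trough has already demonstrated two noise-impossible excursions.
  On pure noise the detector reports no events over 1000 s.

Measured on the default generator, sensitivity is ≈ 0.92 at 10:1 amplitude
(≈ 0.998 for well-separated events) with essentially zero false discoveries.
The residual misses are *fused* events — a second event starting during
another's rise, or less than about a second into its decay, produces a single
compound maximum that no peak-based detector can split (deconvolution is out
of scope). Because spontaneous events are Poisson at 3.10/min with ~1.1 s
rises, roughly 8–10% of generated events fuse, so the detected spontaneous
rate settles near 2.8 events/min for a planted 3.10 — the recovery analysis
reports this honestly rather than compensating for it.

A neuron with no events anywhere in the recording is flagged and removed from
further analysis. Detected rising phases are binarized (ones over
`[rise start, peak]`) into the event trains used by everything downstream.

## Modulation inference

For each neuron, `shuffle_baseline()` builds the null distribution of the
stimulation-window statistic: 1000 iterations, each averaging the event
density of `n_windows` one-second windows (20 for the single-PRF protocol,
25 per PRF in the alternating protocol) drawn uniformly with replacement from
the baseline — the whole recording excluding the 5 s after *every* onset.
Windows are aligned to the sample grid and must lie wholly in the baseline.
One distribution per neuron per session is reused across PRFs; the per-neuron
seed is the session seed plus the neuron index. Drawing without replacement
within an iteration is available behind a flag (`replace = FALSE`), since
either reading of "sampled with replacement" is defensible; the default is
with replacement.

`classify_modulation()` deems a neuron modulated by a PRF when its mean event
density during the 1 s stimulation windows of that PRF strictly exceeds the
95th percentile of its shuffle distribution — a one-sided permutation test at
a nominal 5% level — *unless* its density in the 1 s before onset already
exceeds that percentile (rising phases last ~1.1 s, so an event starting just
before stimulation would otherwise be credited to it; such neuron-PRF pairs
are excluded). No multiple-comparison correction is applied across neurons,
matching the original procedure; the sham analysis quantifies the resulting
false-positive rate (~4.5%, bounded by the nominal 5% and shrunk slightly by
the exclusion rule). `classify_specificity()` labels neurons modulated by
exactly one PRF "specific", by two or more "non-specific", otherwise
non-responders; `response_significance()` is `(observed - p95)/p95`, with an
infinite sentinel when p95 is zero and the observation positive (reported,
excluded from rank tests).

## Network synchrony (ACC)

The asymmetric correlation coefficient of two binary event trains is

$$\mathrm{ACC}_{A,B} = \tfrac12\left(\frac{\sum A \cap B}{\sum A} +
\frac{\sum B \cap A}{\sum B}\right),$$

the proportion of co-occurring event samples averaged over the two
directions; it is symmetric, lies in [0, 1], and equals 1 for identical
nonzero trains. Pairs (or bins) where either train has no events are
undefined and excluded from group averages rather than set to zero, which
would bias group means downward. For independent trains with rising-phase
densities $p_A, p_B$ its expectation is $(p_A + p_B)/2$, so the baseline ACC
of unconnected neurons is small but positive.

`sustained_acc()` evaluates the full recording for all unordered pairs, with
pair groups (Mod:Mod, Mod:Non, Non:Non — per PRF condition in the alternating
protocol) from the modulation flags. `transient_acc()` evaluates 1 s bins on
a grid anchored at the trial start, pooling each bin's samples across the
selected trials before computing the ACC. Pooling is a deliberate choice:
computing the ACC within single trial-bins and averaging conditions on both
neurons firing in the same trial-bin (rare at baseline, ~25% of pairs per
bin), leaves most baseline bins undefined, and — because it conditions on
joint firing — erases the stimulation-locked rate information entirely. With
pooled bins the baseline sits near the independent-train expectation (~0.06
on the default generator) and the stimulation bin rises several-fold for
modulated pairs, reproducing the expected pattern: an increase confined to
the 0–1 s bin for Mod:Mod and Mod:Non pairs, nothing for Non:Non or sham.
`transient_acc_conditions()` collapses the first 8 s of the trial into the
baseline condition "BL" for the repeated-measures comparison
(Friedman + Nemenyi across sessions).

## Evoked response shape and the GLM

`response_profile()` characterizes a trial-averaged trace aligned to onset:
the peak is the maximum after onset (profiles whose maximum falls beyond 5 s
are invalid and excluded); amplitude is peak minus the pre-peak minimum;
FWHM is the total — possibly non-contiguous — time above the pre-peak minimum
plus half the amplitude within the 5 s window (referencing the half-max to
the pre-peak minimum keeps it consistent with the amplitude definition);
AUC is the trapezoidal integral over exactly 5 s. `population_latency()` is
the first post-onset time the population mean exceeds its 10 s pre-onset
baseline by two baseline SDs.

`glm_compare()` fits `value ~ PRF + cell type + PRF:cell type` and compares
it to the intercept-only model with a deviance test. The family and link are
configurable; the Gaussian/identity default uses an F test (exact level for
Gaussian errors with unknown dispersion; non-Gaussian families use the
likelihood-ratio chi-square). Coefficients are only reported when the
omnibus deviance test is significant at `alpha`.

## Nonparametric testing layer

`fisher_2x2()` (two-sided exact, hypergeometric), `rank_sum_test()` and
`signed_rank_test()` (normal approximation with tie and continuity
corrections), `kruskal_dunn_sidak()` (Kruskal–Wallis with Dunn's pairwise
rank tests, Sidak-adjusted, reported only after a significant omnibus test)
and `friedman_nemenyi()` wrap the standard tests behind a uniform result
type. The Nemenyi critical difference uses the studentized-range form
$CD = q_{\alpha}/\sqrt2 \cdot \sqrt{k(k+1)/(6n)}$ at infinite degrees of
freedom, the variant conventional for post-Friedman comparisons; the
chi-square variant would be slightly more conservative and the choice is
noted rather than claimed to match the original. Alpha is 0.05 throughout.

## Expression heterogeneity

`normalize_umi()` maps UMI counts to `log2(count / cell_total * 1e5 + 1)`.
`cliffs_delta()` computes $\delta = [\#(x>y) - \#(x<y)]/(nm)$ in
O((n+m) log(n+m)) via midranks (ties contribute zero net) and classifies
|δ| by the conventional thresholds 0.147 / 0.330 / 0.474. In
`expression_summary()` the effect size is computed on expressing (nonzero)
cells only by default — matching distribution comparisons that condition on
detection — with `nonzero_only = FALSE` available since the original
computation is only partly specified; the fraction of expressing cells per
population is reported separately, and a Wilcoxon rank-sum p-value
accompanies the effect size without ever substituting for it. The exceedance
interpretation $P(X>Y) \approx (\delta+1)/2$ is included for readability.

## Acoustic intensity utilities

`isppa()` implements the plane-wave closed form $I_{SPPA} = p^2/(2Z)$
(converted to W/cm²; water impedance $Z = 1.5\times10^6$ Rayls by default)
and `ispta()` multiplies by the duty cycle. For a 522 kPa peak pressure the
closed form gives 9.08 W/cm²; the slightly different figure sometimes quoted
for that pressure (9.11) presumably reflects an unrounded pressure or
impedance, and no constant here is adjusted to match it.

## Problem sizes and reproducibility

The test suite and the acceptance analysis regenerate everything from seeds:
recovery analyses use 12 single-PRF sessions of 20–40 neurons (rate and
rise-time recovery), 2000 sham neurons (false-positive control), 12
alternating sessions of 32 neurons plus 10 sham sessions (transient
synchrony), and 16 sessions of 33 PRF-preferring neurons (specificity),
sizes at which the Monte-Carlo error of each checked quantity is well inside
its tolerance. All generators and the shuffle test take explicit integer
seeds and are bit-reproducible given the seed.

## Known limitations

* Detected spontaneous rates under-count fused events by ~8–10% at
  3.10 events/min with ~1.1 s rises (see the event-detection section); all
  rate recoveries inherit this floor.
* The multitaper configuration (window, NW, K, band) is a declared default
  validated by recovery, not a claim about any particular legacy toolbox
  configuration.
* Manual quality-control of events is replaced by the zero-event removal
  rule; no curation step is reproduced.
* The expression module compares two populations at a time; multi-population
  contrasts are run pairwise by the caller.
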