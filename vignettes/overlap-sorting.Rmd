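---
title: "Resolving overlapping spike waveforms: the model and its knobs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving overlapping spike waveforms: the model and its knobs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overlapsort)
```

## The problem

When two nearby neurons fire within about a millisecond of each other, their
extracellular action potentials superimpose on the electrode. The recorded
snippet looks like neither unit's canonical waveform, so conventional
clustering either discards it into a multi-unit pool or, worse, assigns it
to a spurious cluster. For analyses that depend on precise coincident
spiking — correlation, latency, response variability — losing exactly the
coincident spikes is the worst possible failure mode.

`overlapsort` implements a template-superposition approach: if units A and B
are well characterized in isolation, then every waveform that an A+B
coincidence can produce is (to linear superposition accuracy) the sum of the
two templates at some relative phase shift. Enumerating those sums gives a
finite bank of *synthetic waveforms*; recognizing an overlap reduces to
finding its nearest synthetic waveform, which carries its parent pair and
phase shift as labels.

## The pipeline

1. **Detection.** The trace is high-pass filtered (4th-order Butterworth,
   300 Hz corner, zero phase via a forward-backward pass) and every strict
   local minimum at or below −(threshold) is extracted as a 32-sample
   window: 10 samples before the trough, the trough (local sample 11), and
   21 after — about 1 ms at 30 kHz. The threshold is `k` times the
   background-noise SD with `k = 4` by default; the noise SD is the robust
   estimate `median(|x|)/0.6745`, which is insensitive to the spikes
   themselves. On tetrodes each channel is thresholded separately and
   candidate events within 10 samples across channels merge into one event
   triggered by the deepest trough.
2. **First clustering pass.** Shape features (see below) are z-scored and
   clustered with a classification-EM (CEM) mixture of Gaussians: a hard
   assignment step between the E and M steps, empty clusters deleted,
   model selection by penalized likelihood (BIC for electrode data, AIC for
   tetrode data) over a sweep of candidate cluster counts with k-means++
   restarts.
3. **Template construction.** Clusters pass safety screens — at most 1% of
   inter-spike intervals under 1 ms (a contaminated cluster is a mixture),
   mean trough at least 1.5× the detection threshold (small-amplitude
   clusters are multi-unit activity), and no statistically significant
   feature drift — then near-identical clusters (mean-waveform Pearson
   r ≥ 0.95) merge greedily as long as the merged ISI fraction stays clean.
   Groups that remain large and isolated become single units; their mean
   waveforms are the templates. `include`/`exclude` arguments reproduce
   fully manual curation when wanted. On tetrode data the member list is
   then trimmed: members whose waveform correlation with the unit mean
   falls more than five MADs below the cluster median move to the joint
   pool, and the template is re-averaged. This matters on tetrodes because
   the cross-channel merge rule can fold a partner unit's trough into a
   single detected event that then hides inside a template cluster;
   trimming hands such members to the overlap machinery, and any trimmed
   spike the resolver cannot place returns to its source unit at its
   trigger time, so trimming is speculative rather than destructive. On
   single-channel data every qualifying trough is its own detection, so
   trimming is off by default there.
4. **Synthetic bank.** For each unordered template pair, the two templates
   are summed point by point at every phase shift (one leading by 0–31
   samples, the other by 1–31; 63 superpositions per pair, lengths 32–63
   samples), and 32-point synthetic waveforms are re-extracted from each
   superposition with the *same* thresholding rule as real spikes. Each
   synthetic records where its two parent triggers fall relative to its own
   window.
5. **Joint re-clustering and matching.** All spikes outside the template
   clusters are pooled with the bank (each synthetic exactly once), features
   are recomputed on the union so normalization and the principal-component
   axis are shared, and the union is re-clustered. Within every cluster that
   contains both kinds, each real spike takes the co-clustered synthetic
   with the highest Pearson correlation of the concatenated channel samples.
   No minimum correlation is imposed: cluster co-membership — which uses
   amplitude as well as shape — is the gate, not a similarity threshold.
6. **Assignment.** Where the matched synthetic's parent triggers fall
   decides the conversion to unit spikes. One parent inside the 32-sample
   window: the spike belongs to that unit alone (Scenario 1). Both inside
   and a single threshold-crossing minimum in the real waveform: the spikes
   fused, and both units receive a spike at the times implied by the parent
   offsets (Scenario 2). Both inside with two minima: the partner trough was
   extracted as its own spike, so the waveform goes only to the unit whose
   trigger sits nearer the synthetic's trigger (Scenario 3). Three
   consistency guards temper these rules, each using only quantities the
   method already defines. Minima are counted across channels with the same
   merge rule as detection, and a Scenario-3 reading is kept only when a
   separately extracted partner spike actually exists within the window -
   when detection merged both troughs into one event there is no separate
   partner, and the waveform must carry both units. A Scenario-2 reading is
   rejected when the matched noise-free synthetic itself shows two
   threshold-crossing minima while the recorded waveform shows one (fused
   single-trough superpositions only arise at small phase shifts). And each
   Scenario-2 constituent is corroborated against the recording: the voltage
   at that unit's reconstructed trough position, on the channel where its
   template is deepest, must reach the extraction threshold - the same
   criterion that admits spikes in the first place; an uncorroborated
   constituent is dropped and the assignment becomes single-unit. A
   Scenario-1 assignment, which claims the spike is a slightly distorted
   member of one unit, is demoted to the multi-unit pool when its waveform
   is essentially uncorrelated (r < 0.5) with that unit's mean - such events
   are threshold-crossing noise that drifted into a mixed cluster.
7. **Refractory cleanup.** Within each unit, whenever two spikes are closer
   than 1 ms the one correlating less with the unit mean is demoted to the
   multi-unit pool, rescanning until clean. After this step no unit contains
   a sub-refractory interval — asserted on every run.

## Features

Named shape descriptors (`feature_spec()`): `area` Σ|v| (absolute values so
biphasic waveforms do not cancel), `trigger_value` v[11], `peak` max(v),
`width` argmax − argmin in samples, `energy` Σv², `fft` the magnitudes of
the first three non-DC Fourier bins (a compact smoothness/shape descriptor;
the count is configurable), `pc1` the first principal component score of the
mean-centered concatenated waveform, and `wavelet` Haar coefficients. The
electrode preset is {area, trigger value, FFT, pc1}; the tetrode preset adds
width and peak, computed per channel and concatenated (29 columns on four
channels).

The wavelet path computes the full 32-coefficient Haar decomposition and
ranks coefficients by the dip statistic of their across-spike distribution —
multimodal coefficients are the ones that separate units — keeping the top
four by default. The dip is computed by the convex-minorant /
concave-majorant envelope decomposition: for every candidate mode the best
sup-norm unimodal approximation error is half the larger envelope gap, and
the dip is the minimum over modes. This construction is used for *ranking*
only, where ordinal behaviour is what matters; an explicit coefficient list
overrides it, mirroring the manual selection this replaces.

## Clustering engine choices

CEM rather than soft EM because hard assignments are what the downstream
stages consume, and the classification likelihood is monotone under the
E/C/M iteration (tracked and tested). Initialization is k-means++ from the
configured seed; ties in the C-step break toward the lowest cluster index;
singular covariances are ridged with escalating ε·I (warning once).
Covariance is full up to 8 feature dimensions, diagonal above — tetrode
feature spaces are too wide for stable full covariances at realistic cluster
sizes. Every cluster's variance is floored at a small fraction (1% by
default) of the data's global variance per dimension: without a floor,
clusters of noise-free synthetic waveforms collapse into needle-thin
components whose likelihood no recorded spike can reach, which silently
disables the joint matching. Penalized scores use the standard mixture
parameter count. The exact
printed presets (electrode min 5 / max 30 / BIC; tetrode min 30 / max 100 /
AIC) are exported; the pipeline defaults sweep smaller ranges (5–12 and
6–14) because the bundled simulations contain two or three units, not the
dozens a 30-minute tetrode recording can hold.

The joint pass sizes its own sweep from the bank: on electrode data the
minimum is about one eighth and the maximum about one quarter of the number
of synthetic waveforms (clusters of roughly 4–8 synthetics), with a stride
so at most seven candidate counts are fitted. A single cluster holding half
the bank would let the scale-invariant correlation match a small waveform
to a deep synthetic, which is exactly what co-clustering is supposed to
prevent. The tetrode joint pool is dominated by threshold-crossing noise
events and lives in a much wider feature space, so it uses broader clusters
(8–16 synthetics each) and a larger variance floor (5%) to keep noisy real
overlap waveforms attached to their noise-free synthetics; the assignment
guards above then carry the burden of rejecting the spurious attachments
this breadth admits.

## The simulator

`simulate_recording()` builds datasets with known ground truth. Each unit's
spike train is a homogeneous candidate process at a free rate drawn
uniformly from [0, 20] spikes/s, thinned by a sigmoid recovery function of
the time since the last accepted spike — probability
`1/(1 + exp(−(Δ − 2 ms)/1 ms))`, hard zero below 1 ms — which produces
realistic relative-refractory statistics rather than Poisson trains. Spikes
are rendered by adding the unit's template with its trough at the spike
sample; overlaps add linearly.

Noise is built the same way the signal is: 1000 surrogate trains with free
rates uniform on [0, 200] spikes/s, each event replaced by a waveform drawn
from a pool of spike shapes (the templates plus attenuated and
pairwise-summed variants, standing in for the single-unit, multi-unit and
overlapping waveforms of a real recording), summed, mean-subtracted,
normalized to a maximum amplitude of exactly 1 μV, then amplified to the
target noise SD. The presets set that SD to one tenth of the smallest
unit's trough depth (trough-SNR 10).

Templates come from a parametric factory: a difference of Gaussians with a
trough exactly at sample 11, configurable depth, width, afterpotential and
per-channel amplitude profile. The electrode preset has two units (150 and
100 μV nominal depth, different widths); the tetrode preset three units with
distinct channel profiles. Spike times are integer samples (no sub-sample
jitter).

What the simulator deliberately does **not** model: electrode drift,
bursting amplitude decrement, correlated non-spike noise, and overlaps of
more than two units. Passing the bundled benchmarks therefore demonstrates
the overlap-resolution machinery under stationary, linear-superposition
conditions; it does not certify behaviour on drifting or bursting real
recordings, where template stability screening and manual curation carry
more of the load.

## Evaluation conventions

A reported spike is correct when a ground-truth spike of the same unit lies
within ±15 samples (0.5 ms at 30 kHz — half the refractory period, which
prevents double matching); matching is greedy one-to-one. A truth spike is
an *overlap* when any other unit fired within strictly less than 1 ms.
Percentages report sorted/total, the same restricted to overlaps, and false
positives over total truth spikes; tabulated values are integer-truncated
(87.7 prints as 87%) with the false-positive rate at two decimals. When unit
numbering differs between result and truth, the correspondence maximizing
total matches is found exhaustively (up to six units; greedily above) before
scoring.

## Numerical and degenerate-input choices

* Zero-phase filtering uses steady-state initial conditions and reflective
  padding, so constant offsets produce no startup transient.
* Synthetic windows that extend past their superposition are zero-padded
  (the superposition is embedded in a zero baseline); this changes feature
  values of edge synthetics and is therefore stated, not silent.
* Duplicate synthetics within a pair (identical waveforms from different
  shifts) are removed keeping the lowest id; correlation ties in matching
  also break toward the lowest id.
* Scenario-3 ties (parent triggers equidistant from the synthetic trigger)
  go to the deeper-trough template.
* Scenario-2 spike times are `trigger_time + (parent offset − 11)` per
  assigned unit, which reconstructs each constituent trough's position.
* A zero-variance waveform correlates as 0 (with a warning) rather than NA.
* The drift screen requires both a large normalized trend (more than one
  feature SD over the recording) and Bonferroni-corrected significance at
  the 1% level; small clusters' sampling noise would otherwise masquerade
  as electrode drift.
* The refractory cleanup scans chronologically and rescans after each
  demotion; on instances small enough to enumerate, it removes at most one
  spike more than the optimal demotion set (tested by brute force).

## Problem sizes

The bundled benchmark runs four single-electrode and four tetrode datasets
of 5 minutes each at 30 kHz — about 9 million samples per channel, 2,000 to
7,000 true spikes and tens to hundreds of true overlap events per dataset —
which exercises every stage at full fidelity while keeping a complete
benchmark under a few minutes per configuration on one core. Unit tests use
smaller fixtures (tens of seconds) built by the same generator.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_recording(sim_config("electrode", duration_s = 300, seed = 1))
res <- run_sort(sim$recording, run_config("electrode", seed = 1))
score_sort(match_to_truth(res, sim$truth))
```

## Limitations

Pairwise superpositions only: three-way coincidences are not representable
in the bank and fall to the multi-unit pool or to a two-unit approximation.
Template quality bounds everything downstream — a missed unit cannot be
resolved in overlaps, and the automated selection criteria, while
override-able, encode one reasonable operating point rather than a universal
one. Spike-shaped background noise that crosses the detection threshold
adjacent to a real spike is indistinguishable in principle from a genuine
two-unit overlap and is the dominant residual source of false positives.
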