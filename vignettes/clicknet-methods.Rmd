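---
title: "Click-type discovery by weighted-network clustering: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Click-type discovery by weighted-network clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clicknet)
```

## The problem

Delphinid echolocation clicks are impulsive, broadband signals whose
spectral shape and inter-click interval (ICI) statistics differ between
species, but which vary enormously click-to-click with beam aspect,
range and behavior. Long-term seafloor recorders sampling at 200 kHz
collect millions of detections with no labels. clicknet treats
classification the way an analyst does: not click by click, but by
looking for *persistent* structure across many detections — first within
short time windows, then across an entire multi-site archive.

## Detection model

Audio is band-pass filtered to the 10–90 kHz analysis band with a
linear-phase FIR filter applied forward and backward, so the filter is
zero-phase and detection times carry no group-delay bias. Click
boundaries are the first and last instants at which a 50 µs moving
average of calibrated instantaneous energy exceeds a boundary threshold
(default 95 dB re 1 µPa); crossings closer than 100 µs are merged so
that a single click is never split by an envelope ripple. Each snippet
keeps 20 samples of context on both sides, is Hann-weighted, zero-padded
to 400 points and transformed with a 400-point DFT. At the nominal
200 kHz sampling rate this fixes the bin spacing at
200 kHz / 400 = 500 Hz, giving 121 bins on the 10–70 kHz grid that all
downstream stages share; snippets longer than 400 samples are truncated
about the peak of their Hilbert envelope, since the DFT length is fixed
and clicks are impulsive.

Quality control retains detections with peak frequency in 15–85 kHz,
received level above 120 dB peak-to-peak re 1 µPa, and high-energy
envelope duration — the time the Hilbert envelope spends above 50% of
its maximum — below 1 ms. The 1 ms default deserves a note: genuinely
sub-10-µs bounds would be unmeasurable at 200 kHz (two samples) and are
physically implausible for recorded delphinid clicks once multipath is
considered, whereas 1 ms comfortably passes real clicks while rejecting
tonal and ship transients. The bound is configurable
(`detector_config(max_envelope_duration =)`).

## Similarity model

Spectra are min–max normalized, `u_n = (u − min u)/(max u − min u)`, so
that only shape survives; similarity is computed on the *first
differences* of `u_n` across frequency bins with the correlation
distance `D = 1 − corr(Δu_n, Δv_n)` and mapped to
`S_SPEC = exp(−D) ∈ [e⁻², 1]`. Differencing makes the measure sensitive
to the positions of peaks and notches and invariant to any affine
transform of the raw levels. Constant spectra and spectra with
zero-variance differences have no defined correlation; they are dropped
with a warning rather than imputed.

Modal-ICI similarity uses the same exponential map on the Euclidean
distance in seconds, `S_ICI = exp(−|a − b|)`; over the working ICI range
(0.01–0.5 s) this yields values in `[exp(−0.49), 1]`. The two scores are
fused by multiplication, `S2 = S_ICI · S_SPEC`: a pair scores high only
when *both* lines of evidence agree, mirroring how analysts require both
spectral and ICI support. No rescaling is applied before the product —
the two factors deliberately do not have identical distributions, and
transforming either would silently change its influence; hooks exist in
user code by transforming inputs, but the default is identity.

## Pruning

Networks are pruned by removing the weakest `p_e` fraction of edges —
a percentile computed per network, not an absolute weight threshold, so
strongly and weakly interrelated networks lose the same share of edges
and rare-but-coherent types at quiet sites are preserved. Two
edge-counting conventions coexist: the package stores distinct unordered
pairs (`n(n−1)/2` for a complete network) and uses that count for the
default retention quota `round((1 − p_e) · E)`; the self-inclusive
halved count `n²/2` often quoted for complete networks (5,000 nodes →
12.5 million edges → 625,000 retained at `p_e = 0.95`) is exposed on
every `pruned_network` and selectable via `quota = "square_half"`. Ties
at the cut are broken by a stable sort on (weight, node pair), making
pruning deterministic, and `p_e` grids therefore produce nested edge
sets. `pe_sweep()` reports clusters, isolation and cluster-purity
diagnostics over a `p_e` grid; 0.95 is the default operating point for
both clustering phases, with 0.90 for classification where keeping more
edges lets poor-quality test nodes still find their template.

## Clustering and consensus

Chinese Whispers is used exactly because it is simple, linear in the
node count, and indifferent to cluster-size imbalance: every connected
node starts as its own cluster; each pass visits nodes in a fresh random
permutation and a node adopts the label with the maximum summed incident
edge weight among its neighbors, ties broken uniformly at random;
updates are asynchronous; iteration stops at a fixed point or after 20
passes. The algorithm is non-deterministic by construction, so Phase 2
runs it 20 times and keeps the partition with the highest mean pairwise
normalized mutual information against the others ("Best of K"). NMI is
evaluated from the contingency table,

NMI(P_a, P_b) = −2 Σ_ij n_ij log(n_ij n / n_i n_j) /
\[Σ_i n_i log(n_i/n) + Σ_j n_j log(n_j/n)\],

with natural logarithms (the base cancels). The 0/0 form that arises
when both partitions are a single all-node cluster is resolved to 1 —
the partitions are identical — and clusters below the retention size
(20 nodes in Phase 2) are dropped *before* comparison, with pairwise NMI
computed over nodes labeled in both partitions of each pair. The
consensus output is always one of the candidate partitions, never a
synthesized merge.

Per-bin Phase 1 clustering keeps clusters of ≥ 100 clicks and condenses
each to a summary node: the mean of member *dB* spectra (normalization
is deferred to comparison time, so the stored spectrum keeps its level
information for reporting), the ICI histogram of time-sorted member
clicks on the fixed 0.01–0.5 s grid, and the modal ICI. Dense multi-animal
clicking inflates the lowest ICI bins; saturation is declared when the
histogram's global maximum sits in the lowest three bins with counts
declining monotonically across them, in which case the mode is taken as
the first bin strictly greater than both neighbors — the first peak
attributable to an individual's click train — falling back to the global
argmax when no such bin exists. Ties always resolve to the lower bin
center.

Template labels (`A`, `B`, …) are assigned by descending modal ICI, then
descending peak frequency — an arbitrary but stable, human-readable
ordering.

## Classification and certainty

A test summary node is scored by `S2` against every member node of every
template; the *pooled* score set is pruned of its weakest 90% (one
percentile computation per test node, mirroring the per-network dynamic
pruning used everywhere else), each template then averages its surviving
scores (a template with no survivors scores 0 and cannot win), and the
argmax wins with the winning mean as certainty. Certainties below 0.3
become `Unknown`. Survivors-only means are used deliberately: dividing
by the pre-pruning count would conflate template size with match
quality. Because `S_SPEC` is bounded below by `e⁻² ≈ 0.135`, certainty
scores have a soft floor; genuinely alien inputs still land near
0.1–0.25 and fall under the threshold. `certainty_accuracy_curve()`
gives the operator the agreement-versus-certainty diagnostic from which
such a threshold is chosen.

## Synthetic data: what it does and does not emulate

The generator works at two levels. *Audio level*
(`synth_audio_bin()`): Gaussian-enveloped tone bursts (plus secondary
bursts for side peaks) placed as jittered click trains on Gaussian
noise, with calibrated levels, optional snapping-shrimp-like transients
(≈ 35 µs bursts with energy concentrated above the 70 kHz band edge, so
their in-band spectral peak falls above the 85 kHz QC bound), and a
truth table of every planted signal. *Detection level*
(`synth_detection_dataset()`): per-click spectra drawn as
type template + smooth per-bin offset + smooth-plus-white per-click
noise, with timestamps forming jittered trains at the type's modal ICI —
this path scales to 10⁵ clicks in seconds and is the primary test
vehicle for the clustering and classification stages.

The per-bin smooth offset (`bin_noise_db`, default 2.5 dB) matters: it
emulates encounter-level effects — group orientation, range-dependent
attenuation — that are shared by the clicks of one bin and therefore do
*not* average out of bin mean spectra. Without it, summary spectra are
unrealistically clean and uniform, and percentile pruning behaves
pathologically (whole types isolate). The white component of per-click
noise, by contrast, averages down by √n in a 100+ click bin, as it does
in field data, so bin-level draws are smooth-only.

The seven presets of `gom_click_types()` span the peak-frequency
(22–42 kHz) and modal-ICI (0.035–0.165 s) ranges reported for Gulf of
Mexico delphinid click types and carry the qualitative features that
distinguish them (narrow side peaks, banded structure, low-frequency
cut-offs, broad plateaus). They are stylized: within-type variability is
reduced to smooth spectral perturbations and ICI jitter, and the
distinguishing features are crisp. Passing the planted-recovery tests
therefore shows that the pipeline separates types *whose differences are
of the documented kind and scale*; it does not show robustness to
phenomena the generator omits — off-axis beam distortion, propagation
filtering, overlapping multi-species encounters beyond simple two-type
mixtures, or false-positive contamination of summary spectra.

## Numerical and degenerate-input choices

* Filtering: FIR order 128, applied forward–backward; measured stopband
  loss at 5 kHz and 95 kHz exceeds 40 dB by a wide margin, passband
  ripple ≪ 1 dB.
* Zero DFT magnitudes are floored at the smallest positive double before
  the log, so silent bins yield finite (very negative) levels.
* `assemble_bins()` aligns bins to wall-clock 300 s boundaries; trailing
  partial bins participate if they contain ≥ 100 clicks. Subsampling to
  5,000 clicks is uniform, seeded and order-preserving.
* Encounters split on gaps of ≥ 15 minutes (a gap of exactly 15 minutes
  splits).
* All randomness — subsampling, node sampling, label propagation —
  derives from explicit seeds; fixed seeds make every stage
  bit-reproducible, and `with_seed` scoping leaves the caller's RNG
  stream untouched.
* Time columns in detection and summary-node files are written as
  17-significant-digit text (with a derived ISO 8601 display column), so
  write → read → write cycles are byte-stable.
* Empty inputs: an empty detection table yields an empty bin list; a bin
  whose clusters all fall below 100 clicks contributes no summary node;
  an empty similarity matrix prunes to an empty network; classifying
  zero nodes returns an empty, correctly-typed table.

## Problem sizes used by the test and validation suites

The validation suites run the full pipeline at desk scale: seven planted
types × five sites × 9 bins ≈ 58,000 clicks → ≈ 300 summary nodes for
type recovery; 6-second 200 kHz audio scenes for detector recall; toy
two-type sets of 150–250 nodes per type for consensus and classification
properties. These sizes were chosen so that each network is large enough
for the default operating point (`p_e = 0.95`, minimum cluster size 20)
to be meaningful — percentile pruning on networks of only a few dozen
nodes leaves mean degree below what label propagation needs, which is a
genuine small-sample property of the method, not an implementation
artifact. Two consequences are documented rather than hidden: consensus
NMI on 300–500-node toy networks sits around 0.85–0.97 (not 1), and
homogeneous single-type networks are only guaranteed to coalesce to one
cluster at milder pruning.

## Known limitations

* No click-train tracking: interleaved trains are handled only through
  the first-peak modal-ICI rule, and very dense multi-animal encounters
  can still bias modal ICI.
* Similar types with shared ICI (e.g. two mid-band types 2 kHz apart)
  merge or split depending on how pronounced their secondary spectral
  structure is; a multi-pass strategy with increasing thresholds would
  be the natural extension.
* The correlation distance weights all frequency bins equally; no
  perceptual or attenuation-aware weighting is applied.
* Absolute detector thresholds presume calibrated input; uncalibrated
  audio must supply a sensible `cal_db` or override the thresholds.
* Chinese Whispers has no objective function; stability is addressed by
  consensus over 20 runs, not guaranteed.
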