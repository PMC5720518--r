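# clicknet

Unsupervised, network-based discovery and classification of delphinid
echolocation click types in wideband passive acoustic recordings.

Dolphins produce enormous numbers of short (tens of microseconds),
broadband (10–100+ kHz) echolocation clicks. A few species can be
identified from click spectra by trained analysts, but single clicks are
too variable — beam aspect, range-dependent attenuation, source-level
changes — to classify in isolation, and long-term seafloor recorders
yield millions of unlabeled detections. clicknet is aimed at passive
acoustic monitoring analysts who need to (1) find the recurrent click
*types* hiding in such archives without knowing them in advance, and
(2) label novel recordings against those types automatically.

## The method

Clicks (and later, per-bin summaries) are nodes of a weighted network
whose edges encode similarity; clusters of the network are click types.

**Spectral similarity.** Each click spectrum `u` (dB, 10–70 kHz, 500 Hz
bins) is min–max normalized,

    u_n = (u − min u) / max(u − min u),

and compared through the correlation distance between first differences
across frequency bins,

    D = 1 − corr(Δu_n, Δv_n),      S_SPEC = exp(−D) ∈ [e⁻², 1].

**Two-phase clustering.**

* *Phase 1 (within 5-minute bins).* Every click-positive bin (≥ 100
  clicks, subsampled to 5,000) becomes a complete `S_SPEC` network; the
  weakest fraction `p_e = 0.95` of edges is pruned (a per-network
  percentile, not an absolute threshold) and the remainder partitioned
  with Chinese Whispers label propagation (≤ 20 iterations). Clusters of
  ≥ 100 clicks are condensed to **summary nodes**: mean dB spectrum,
  inter-click-interval (ICI) histogram (0.01–0.5 s, 10 ms bins) and
  modal ICI (first-peak rule under train-overlap saturation).
* *Phase 2 (across bins and sites).* 1,000 summary nodes per site are
  sampled and connected by the combined similarity
  `S2 = S_ICI · S_SPEC` with `S_ICI = exp(−|ICI_a − ICI_b|)`, pruned at
  `p_e = 0.95` and clustered 20 times. The partition with the highest
  mean pairwise normalized mutual information (NMI) against the others
  is kept — *Best-of-K* consensus — and its clusters of ≥ 20 nodes
  become **click-type templates**.

**Classification.** A novel summary node is compared (`S2`) against every
training node of every template; the pooled score set is pruned at
`p_e = 0.90`, each template scores the mean of its surviving
similarities, and the node takes the best-scoring label with that score
as its *certainty* — or `Unknown` below a certainty of 0.3.

A synthetic-data module generates calibrated audio scenes and
detection-level datasets with per-click ground truth (type-specific
spectral shapes, modal ICIs, level distributions, snapping-shrimp-like
false positives), so every stage is testable end to end. The click
detector (95 dB re 1 µPa boundary threshold on a 50 µs smoothed energy
trace, Hann-windowed 400-point DFT spectra, peak-frequency /
received-level / envelope-duration QC) handles calibrated single-channel
WAV input.

## Worked example

Simulate seven planted click types at five sites, rediscover them, and
classify fresh data:

```r
library(clicknet)

spec <- synthetic_dataset_spec(bins_per_type_per_site = 9,
                               clicks_per_bin = c(120, 250), rng_seed = 42)
ds <- synth_detection_dataset(spec)
nrow(ds$detections)
#> [1] 57446

nodes <- phase1(ds$detections, rng_seed = 7)       # 5-min bins -> summary nodes
nrow(nodes)
#> [1] 301

res <- discover_types(nodes, phase2_config(rng_seed = 11))
res$bundle
#> <click_type_bundle> 7 click types (A, B, C, D, E, F, G), 278 member nodes
round(res$diagnostics$mean_nmi[res$diagnostics$best_index], 3)
#> [1] 0.997
round(res$diagnostics$isolated_fraction, 3)
#> [1] 0.01

ds2 <- synth_detection_dataset(synthetic_dataset_spec(
  bins_per_type_per_site = 2, clicks_per_bin = c(120, 250), rng_seed = 99))
test_nodes <- phase1(ds2$detections, rng_seed = 8)
cls <- classify_nodes(test_nodes, res$bundle)
table(cls$label)
#>  A  B  C  D  E  F  G
#> 10  9 10  8  9 10 10
summary(cls$certainty)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.7931  0.8863  0.9143  0.9072  0.9320  0.9630
```

All seven planted types are recovered (the winning consensus run has
mean pairwise NMI 0.997 with 1% of nodes isolated), and every test bin
classifies back to its planted type with certainty far above the 0.3
Unknown threshold. `export_cluster_report()` writes per-type spectra
(mean and quartile curves), concatenated member-spectrum matrices and
ICI histograms as tables and figures.

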