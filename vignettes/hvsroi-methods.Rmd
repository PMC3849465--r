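---
title: "hvsroi: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hvsroi: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`hvsroi` extracts candidate carcinoma regions from H&E histopathology
fields by chaining four stages that mirror the ventral visual pathway:
bottom-up saliency, region formation, disorder-regulated attention, and
exemplar-based recognition with similarity propagation. The design
assumption throughout is that carcinoma-like tissue differs from stroma in
a small set of low-level statistics — intensity (hematoxylin-dense regions
are darker), colour opponency (basophilic vs eosinophilic staining),
oriented energy, and local structural disorder — and that those statistics
are stable enough within one field to let a single detected exemplar
recruit its peers.

### Bottom-up saliency

The saliency stage is the classical centre–surround architecture.
Intensity is the per-pixel channel mean; colour uses the four
half-rectified broadly-tuned opponent planes; orientation uses quadrature
Gabor energy (9×9 kernels, σ = 2.5 px, λ = 5 px, isotropic envelope; the
angle names the *edge* orientation the filter prefers). Nine-level
Gaussian pyramids (5-tap binomial smoothing) feed across-scale differences
with centres c ∈ {2,3,4} and surrounds s = c + δ, δ ∈ {3,4}; maps are
summed at working scale 4 (1/16 resolution) and promoted with the
local-maxima operator N(·). The final map is the unweighted mean of the
three promoted conspicuity channels, upsampled bilinearly and min-max
rescaled to [0,1]. Equal channel weights are the conventional default; the
weights are exposed in `saliency_params()` because nothing in the source
material fixes them.

### Regions, disorder and attention

Segmentation is a deterministic SLIC-style superpixel clustering in
(r, g, b, row, col) with grid seeding, ten assignment/update sweeps, and
connectivity enforcement (fragments below a quarter of the nominal cell
area merge into their dominant neighbour). It satisfies the stated
criteria — proximity and similarity between pixels — while remaining fully
reproducible. Structural disorder is the windowed Shannon entropy (bits)
of the binned intensity histogram. Region attention is
`mean_saliency × H/log2(bins)`: disorder *regulates* saliency
multiplicatively, so a perfectly ordered region (H = 0) can never attract
the search regardless of contrast. Additive and exponent-weighted variants
are available (`attention_scores(form = ...)`) since the regulation form
is not pinned down by the source material.

### Recognition and propagation

Textons are 32×32 patches reduced to the feature vector (I, O, C, H) and
classified by Euclidean kNN in the database's z-normalised space. Regions
are examined strictly in decreasing attention order; the first region
whose texton vote reaches the threshold is the target; every region within
feature distance `df ≤` threshold of the target joins the RoI.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| pyramid depth | 9 levels | — | classical scale set; truncated for small images |
| (c, s) pairs | c ∈ {2,3,4}, δ ∈ {3,4} | pyramid levels | classical centre–surround set |
| working scale | 4 | pyramid level | conspicuity summation grid |
| `target_n` | 200 | regions | sized for 1280×1024 fields (≈ 80 px cells); scale proportionally to pixel count, keeping cells ≳ 1.5 texton widths |
| `compactness` | 0.2 | colour units | colours live in [0,1]; 0.2 balances adherence and regularity |
| entropy window / bins | 9 px / 32 | — | window must stay below the 32 px texton; 32 grey bins resolve H&E contrast |
| `knn_k` | 5 | neighbours | small odd k; majority robust to single outliers |
| `textons_per_region` (m) | 20 | patches | vote variance ≈ p(1−p)/20 ≤ 0.012 |
| `vote_threshold` | 0.5 | fraction | simple majority; ties resolved toward background to favour specificity |
| `df_threshold` | 2.0 | scaled units | see below |
| `df_features` | I, O, C, H | — | the four-feature superset; a mask can drop O |

**Why `df_threshold = 2`.** Distances are scaled per feature by the sd of
that feature across the image's regions, so thresholds are comparable
across magnifications. In that space, an average discrepancy of one sd per
feature corresponds to `df = sqrt(4) = 2`; same-tissue regions in any
plausible two-class field sit well below one total-sd per feature while
the opposite class sits far above. A fixed threshold of 1.0 was considered
and rejected: it corresponds to only half an sd per feature, which is
inside the within-class spread of region summaries whenever a lesion spans
several superpixels, so it rejects true fellow-target regions essentially
everywhere. The unscaled-distance variant remains available by passing
explicit `scales`.

**Texton entropy vs region entropy.** A texton's H is the histogram
entropy of its own 1024 intensities (this makes the closed-form two-tone
check exact); a region's H is the mean of the windowed entropy map over
its pixels. Both are in bits on the same [0, log2(bins)] range; the
distinction is deliberate and documented here because the two definitions
coincide only asymptotically.

## Numerical choices

- **Decimation.** Pyramid levels are smoothed then reduced by 2×2 block
  means with ceiling dimensions (a trailing odd row/col averages with
  itself). Single-phase subsampling (every 2nd pixel) was rejected because
  it is not equivariant under horizontal flips for even dimensions, and
  flip equivariance of the whole saliency stage is an asserted invariant.
- **Resampling.** All resizing is bilinear with pixel-centre alignment
  (`src = (i − 0.5)·n_in/n_out + 0.5`), which is symmetric under flips and
  identical in the implementation and the test oracles.
- **Borders.** Convolutions and the entropy window use edge-inclusive
  symmetric reflection; with a unit-sum kernel this conserves total mass,
  which underpins the energy-monotonicity invariant.
- **Degenerate maps.** Min-max rescaling treats a plane whose range is at
  floating round-off scale (≤ 1e−12 relative) as constant and returns
  zeros; otherwise 1-ulp smoothing noise on flat images would be amplified
  into a full-range "saliency" map.
- **Local maxima.** The promotion operator uses strict 8-neighbourhood
  maxima; plateaus (connected equal-value components) count once and only
  when every outside neighbour is strictly smaller; one instance of the
  global maximum is excluded from m̄. All choices are forced by the need
  for a deterministic exhaustive-scan oracle.
- **Even entropy windows.** The window is nominally odd (default 9). Even
  windows are additionally supported (anchored half a pixel up-left)
  because an odd window contains an odd number of pixels and therefore can
  *never* realise the exact 1-bit balanced two-tone value; the closed-form
  check uses window 4.
- **Ties.** Attention ordering: larger area first, then lower region id.
  kNN distance ties: database insertion order. Vote ties: background.
  Accepted-region ordering: target first, then ascending df, then lower id.
- **Determinism.** Every sampling step (texton extraction, per-region
  patch choice, fixture synthesis) runs under a saved-and-restored RNG
  seeded from the configuration; per-region seeds are decorrelated by
  region id. Two runs with identical config and database are
  byte-identical, which the acceptance suite asserts on file hashes.

## The synthetic world

The generator emulates exactly the statistics the pipeline consumes: a
pinkish smooth "stroma" with gentle fibre texture (low entropy), and
purple-blue blobs densely seeded with dark elliptical nuclei (high
entropy, strong blue opponency), plus Gaussian pixel noise (sd 0.02).
Magnification presets `mag4`–`mag40` sweep blob and nucleus scales the way
higher magnification enlarges lesion cross-sections and nuclei at fixed
sensor resolution. Defaults (256×256, two blobs of radius 40–70 px,
nucleus density 0.02 px⁻², radius 2–4 px) were chosen once as a plausible
mid-magnification field and then frozen.

What the fixtures do *not* model: stain variation, scanner artefacts,
nuclear pleomorphism, palisading and other true BCC morphology, or
ambiguous transitional tissue. A green end-to-end test therefore
establishes that the implementation is internally correct and that the
method recovers planted two-class structure; it does not estimate clinical
sensitivity or specificity, which in the source study were measured on
non-deposited patient images and are explicitly out of scope here.

The frozen evaluation suite uses 20 test fields and a database from 20
training fields (10 textons per class each, disjoint seed schedule), with
`target_n = 24` at 256×256 so that a region spans roughly two texton
widths — the direct scale-down of 200 regions on a 1280×1024 field, kept
above the 32 px texton bounding-box requirement.

## Known limitations

- Conspicuity maps are contrast-normalised per image, so the O and C
  features of a *background-only* field are relative quantities; with a
  very small texton database this can produce spurious target votes. The
  packaged protocol (≥ 200 exemplars per class) classifies such fields as
  target-free, and the no-target path (all-zero mask, flag) is tested.
- The search examines regions serially with early stopping; it finds one
  target and recruits similar regions, so two visually dissimilar lesions
  in one field would need the second to resemble the first. Iterative
  re-seeding is deliberately out of scope.
- TIFF input is not supported (no TIFF codec among the package's
  dependencies); PNG and JPEG cover the reference acquisition format.
- Runtime is pure R; a 256×256 field takes a few seconds end to end on one
  CPU. Fields at 1280×1024 are supported but proportionally slower.
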