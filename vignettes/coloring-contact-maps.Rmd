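---
title: "Coloring chromatin contact maps by 1D signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coloring chromatin contact maps by 1D signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicstain)
```

## The problem and the model

Contact maps from Hi-C-family assays are square matrices of interaction
frequencies over genomic bins. Questions like "does this loop anchor
carry CTCF?" or "is this compartment active or Polycomb-repressed?" are
usually answered by placing 1D ChIP-seq tracks next to the heatmap and
eyeballing the alignment. `hicstain` replaces the juxtaposition with a
joint statistic per pixel.

For a region of $n$ bins at resolution $r$, with a 1D track scaled to a
unit signal $s \in [0,1]^n$ and the unit-scaled contact map
$c \in [0,1]^{n \times n}$:

$$m_{ij} = s_i \, s_j, \qquad h_{ij} = m_{ij} \, c_{ij} \cdot 255 .$$

$h$ is the 8-bit opacity of a constant-hue layer: a pixel lights up only
when *both* anchors carry signal and the contact is strong. The key
assumption is multiplicative independence of the two anchors — a deliberate
simplification that makes the image interpretable (opacity factorizes into
"signal here", "signal there", "they touch"). Its known blind spot is an
interaction with signal at only one anchor, which the *vs* mode
($m_{ij} = s^{(1)}_i s^{(2)}_j$) addresses by coloring rows and columns
with different tracks.

Layers for several tracks combine by alpha-weighted linear interpolation.
With layer alphas $\alpha_b$ at a pixel and total
$T=\sum_b \alpha_b$:

$$\text{rgb}_{\text{mix}} = \sum_b \text{rgb}_b \frac{\alpha_b}{T},
  \qquad \alpha_{\text{mix}} = \min(T, 255).$$

Mixing is done in linear RGB on the 0–255 integers, with no gamma
correction: fidelity to the arithmetic above is preferred over perceptual
uniformity, because the quantification layer (below) reads the same alpha
values the image shows.

## Normalization chain

The contact matrix passes through up to three steps, in a fixed order:

1. **Balancing** (optional, cooler sources): stored matrix-balancing
   weights are applied; bins with no weight become missing and render
   transparent.
2. **Distance normalization** (optional):
   $(o_{ij}+1)/(e_{|i-j|}+1)$, where $e_d$ is the mean of non-missing
   observed values at diagonal offset $d$. The $+1$ pseudocount keeps
   empty pixels finite and shrinks noisy long-range diagonals toward 1.
   The expected profile is computed within the displayed region, so the
   result is self-contained and reproducible from the extracted
   submatrix alone; a chromosome-wide expected would differ slightly near
   strong local structure.
3. **Unit scaling** (always, last): min–max over non-missing entries.
   Scaling whatever matrix is being displayed — i.e. *after* distance
   normalization when both are requested — keeps the color range fully
   used in either view.

## Scaling rules and degenerate inputs

- 1D signals are scaled to the **local** minimum and maximum of the
  displayed region. This emphasizes local enrichment; a region with no
  real peaks will amplify noise, which is why `scale_unit()` accepts an
  optional clamp (absolute bounds or quantile probabilities) and an
  optional `log1p`.
- The log transform is `log1p`, not `log`: it keeps zero coverage finite,
  preserves order, and needs no arbitrary pseudocount choice.
- **Flat input** (max = min) scales to all zeros, i.e. a fully
  transparent layer. The alternative — mapping a flat track to full
  saturation — would paint the whole map in the absence of any local
  enrichment; transparency is the conservative reading.
- **Missing values** never participate in min/max and poison any product
  they enter: a pixel with a missing factor has alpha 0. Coverage gaps in
  bigWig/bedGraph are missing; uncovered bases in a BED peak file are 0
  (a peak file asserts absence elsewhere). Consequently a BED-derived bin
  value is the covered fraction of the bin, which is also why
  `bed_to_track` and `read_track`-on-a-value-1-bedGraph agree exactly only
  where coverage is bin-aligned.
- Binning of interval tracks uses the **coverage-weighted mean**, matching
  bigWig summary semantics and keeping BED tracks within [0, 1]. The
  aggregation statistic is this package's choice; sum or max would
  overweight fragmented intervals.

## Signed tracks (compartment eigenvector mode)

Negative values are meaningful in compartment-score tracks. The track is
split into a positive and a negated-negative branch *before* any log
transform; each branch is scaled to [0, 1] independently, so a weak B
compartment remains visible next to a strong A. Each branch gets its own
color and outer-product layer. Because a branch zeroes the other sign's
bins, a pixel whose anchors disagree in sign is transparent in both
layers — it is neither an A–A nor a B–B interaction, which is exactly the
visual distinction the mode exists for.

## chromHMM mode

A BED9 segmentation assigns each bin to the state covering most of its
bases (ties break to the state seen first in the file, making the
assignment deterministic). Each selected state becomes a *binary*
membership signal rendered with the state's own `itemRgb` color. The
membership vector is used as-is, not re-min-max-scaled: rescaling a
segmentation that covers the whole region would hit the flat-input rule
and erase the layer. Per-state layers are built first and then blended;
for non-overlapping states this is equivalent to blending per-bin state
colors directly, and it additionally allows rendering a 2–3 state subset,
which in practice is where the mode is legible (blending 15 state colors
mostly distinguishes heterochromatin from everything else).

## Quantifying mark separation

`classify_bins()` turns "bins with high levels of mark M" into a rule:
value at or above M's own top-quantile threshold (default $q = 0.9$),
*exclusively* — a bin high for two marks is unassigned. The quantile and
the exclusivity are this package's operationalization; no universal
threshold exists for "high". `quantify_overlap()` then collects each
layer's alpha over the pixels whose two bins share a class (unordered
pairs counted once, diagonal included — diagonal pixels are genuine
same-bin interactions and excluding them would discard the strongest
short-range signal) and compares the matched layer against each other
layer with a two-sided Wilcoxon rank-sum test (normal approximation with
tie correction by default; the exact distribution is available for small
samples). Alphas are heavily tied integers, so a rank test with tie
correction is the right default; the test-suite checks it against a
Monte-Carlo permutation reference at small sample sizes.

## The synthetic scene generator

`scene_spec()`/`make_scene()` produce the fixture that stands in for real
data everywhere in the tests:

- **Contacts**: mean model
  $\mu_{ij} = \beta\,(|i-j|+1)^{-\gamma}\, A(z_i, z_j)$ with base scale
  $\beta = 100$, decay exponent $\gamma = 1$ (a standard power-law
  contact decay), state vector $z$ and affinity matrix $A$; optional
  Gaussian loop boosts; counts drawn negative-binomially
  (gamma-mixed Poisson, dispersion 0.05) to mimic Hi-C overdispersion.
  Dispersion 0 returns the exact mean model, which the tests exploit.
- **States**: 200 bins at 10 kb; three mark flavors (A = active/H3K27ac,
  B = heterochromatin/H3K9me3, P = Polycomb/H3K27me3) each occupying two
  10-bin domains — 10% of bins per mark — in a neutral background. The
  10% share is deliberate: it equals the tail mass of the default
  top-decile classification rule, so the planted domains are exactly
  recoverable, and a majority of unassigned neutral chromatin mirrors the
  fact that most of a real chromosome is neither a strong peak of one
  mark nor cleanly A/B.
- **Affinities**: same-flavor contact is strong (3× background decay);
  A–B contact is strongly depleted (0.1); neutral chromatin mixes more
  readily with A (0.9) than with B (0.3), with P in between (0.6). The
  A/B asymmetry makes the leading eigenvector of the
  distance-normalized correlation matrix align with the planted A/B
  axis, as it does in real maps; with fully symmetric flavors the leading
  eigenvector can rotate toward any of the three plaid contrasts.
- **Tracks**: mark emission is bimodal (mean 10 on own-state bins, 0.5
  elsewhere) with lognormal noise (sd 0.25 on the log scale) — clear but
  not noiseless separation. The signed compartment-score track is +1 on
  A bins, −1 on B bins, near zero elsewhere (sd 0.05), emulating an
  eigenvector that fails to assign the third flavor.

What the generator does **not** emulate: genome-scale maps, TADs and
corner peaks, balancing artifacts, copy-number effects, mappability gaps,
antibody-dependent ChIP background, or inter-chromosomal contacts. A
passing test suite therefore shows the *computational* pipeline is exact
and self-consistent, not that any particular biological claim holds on
real data.

## Numerical choices

- 8-bit conversion rounds **half away from zero**, applied once in
  `compose_layer()`. Blending then works with a single integer numerator
  $\sum_b \text{rgb}_b \alpha_b$ and one exact division per channel, so
  the result is independent of layer order even at exact-half rounding
  boundaries, and a naive per-pixel reference reproduces it bit for bit.
- Zero-total-alpha pixels take a white background when flattened to PNG
  and stay transparent in SVG.
- PNG output is the bare flattened pixel matrix written without
  timestamps or metadata: rendering the same specification twice is
  byte-identical. The SVG export carries one `<g>` per layer (each an
  embedded lossless raster) plus genomic coordinate labels on both axes.
- Coordinates are 0-based half-open throughout (BED convention); readers
  snap requested regions to the bin grid (start floored, end ceiled) and
  report the snapped region rather than using it silently.

## Problem sizes

The test suite and the acceptance script run on the 200-bin default scene
and on random instances up to 32×32 with at most 5 layers; oracle
comparisons (per-base binning, per-diagonal expected values, per-pixel
blending, Monte-Carlo permutation tests) are exhaustive at these sizes.

## Limitations

- Opacity conflates signal strength and contact strength by design;
  a dim pixel is ambiguous between "weak signal" and "weak contact".
- Local min–max scaling makes images comparable only within one region
  and one scale choice.
- Color mixing in linear RGB can pass through muddy intermediate hues for
  more than three layers; palette choice is left to the user.
- The cooler reader supports single-resolution files over one chromosome
  window through a bundled Python helper; multi-chromosome trans matrices
  and URL streaming are out of scope.
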