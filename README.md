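# hicstain

Color chromatin contact maps by 1D genomic signals.

Chromatin contact maps (Hi-C, Micro-C) are usually shown as standalone 2D
heatmaps with ChIP-seq tracks juxtaposed alongside, leaving the reader to
align 1D peaks with 2D features by eye. `hicstain` paints the 1D data into
the map itself, so that a pixel is visible exactly where both of its
anchor bins carry signal *and* the two loci actually interact. It is aimed
at anyone studying 3D genome organization — compartments, CTCF/cohesin
loops, Polycomb domains — who wants a precise, quantifiable picture of
where a factor sits relative to contact-map features.

## Model

For a user-selected region binned at resolution *r*:

- a 1D track *s* (bigWig, bedGraph, BED peaks, or a signed compartment
  eigenvector) is optionally `log1p`-transformed and min-max scaled to
  [0, 1] over the region's non-missing bins (local scaling, to emphasize
  local enrichment);
- the scaled signal is lifted to a signal matrix
  `m[i,j] = s[i] * s[j]` (or `m[i,j] = s1[i] * s2[j]` in "vs" mode, to
  color rows and columns by different factors);
- the contact matrix *c* — optionally balanced and/or distance-normalized
  as `(observed + 1) / (expected + 1)` with the expected value being the
  per-diagonal mean — is min-max scaled to [0, 1];
- per-pixel opacity is the 8-bit product `h = (m * c) * 255`, and each
  track contributes one constant-hue RGBA layer;
- multiple layers blend by alpha-weighted linear color interpolation:
  per pixel, `total_alpha = sum(alpha_b)`, each layer's blend ratio is
  `alpha_b / total_alpha`, mixed channels are the ratio-weighted sums of
  the layer colors, and the final alpha is `clip(total_alpha, 0, 255)`.

Signed tracks (compartment eigenvectors) split into independently scaled
positive and negative branches rendered in two colors, so A–A and B–B
interactions are visually distinct and cross-compartment pixels stay
transparent. chromHMM BED9 segmentations paint each state with its own
file-specified color. The `quantify_overlap()` routine classifies bins by
their dominant mark (exclusive top-quantile rule) and tests, with
two-sided Wilcoxon rank-sum tests, whether each mark's layer dominates the
interactions among its own bins — the numerical counterpart of "these
marks form distinct compartments".

## Worked example

The package ships a synthetic-scene generator used throughout the test
suite: a 200-bin, 10-kb-resolution region with three planted chromatin
flavors (active / heterochromatin / Polycomb, 10% of bins each), a plaid
contact matrix with power-law distance decay and negative-binomial noise,
matching mark tracks, a signed compartment-score track, and a chromHMM
segmentation.

```r
library(hicstain)

scene <- make_scene(scene_spec(seed = 42), dir = "demo")
cm <- read_contact_matrix(scene$files$cool, scene$region)
cm
#> <contact_matrix> chrS:0-2000000, 200 x 200, raw; 0 NA entries

cs <- scale_contacts(distance_normalize(cm))
cols <- c(H3K27ac = "#1B9E77", H3K9me3 = "#7570B3", H3K27me3 = "#D95F02")
layers <- lapply(names(scene$tracks), function(mk) {
  s <- scale_unit(scene$tracks[[mk]], use_log = TRUE)
  compose_layer(signal_matrix(s), cs, cols[mk])
})

cls <- classify_bins(scene$tracks, quantile = 0.9)
cls
#> <bin_classification> chrS:0-2000000; exclusive top-quantile (q = 0.9) per mark
#>  H3K27ac H3K27me3  H3K9me3     <NA>
#>       20       20       20      140

quantify_overlap(cls, layers)
#> <overlap_quant> per-class layer alpha medians:
#>     class    layer   n median
#>   H3K27ac  H3K27ac 210   42.0
#>   H3K27ac  H3K9me3 210    0.0
#>   H3K27ac H3K27me3 210    0.0
#>   H3K9me3  H3K27ac 210    0.0
#>   H3K9me3  H3K9me3 210   49.5
#>   ...
#> rank-sum tests (matched vs other layer within class):
#>     class matched_layer other_layer n_matched n_other statistic            p
#>   H3K27ac       H3K27ac     H3K9me3       210     210     44100 4.331957e-76
#>   ...
```

Reading the output: each mark's own layer has a clearly positive median
opacity over the interactions among that mark's bins (42–50 of 255),
while every other mark's layer is dark there (median 0) — the three
flavors form mutually exclusive compartment interactions, and all six
matched-vs-other rank-sum tests confirm the separation.

Rendering the blended image (or a two-color eigenvector view) to disk:

```r
render(render_spec(
  region = scene$region, matrix_source = scene$files$cool,
  tracks = list(list(path = scene$files$eigen, color = "#E41A1C",
                     signed = TRUE)),
  mode = "eigen", distnorm = TRUE, out = "compartments.svg"))
```

The same pipeline is scriptable from a shell via the wrapper in
`inst/cli/hicstain` (subcommands `render`, `quantify`, `simulate`).

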