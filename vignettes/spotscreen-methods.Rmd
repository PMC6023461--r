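---
title: "spotscreen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spotscreen: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotscreen)
```

## What the package computes

spotscreen re-implements the image-analysis and statistics chain of a
high-content RNAi screening comparison between reverse-transfection cell
arrays (printed 300-µm siRNA spots on a slide) and multi-well plates. The
chain has five analysis stages and one generator stage:

1. **Nuclei segmentation** — rolling-ball background subtraction (radius
   50 px), a global Otsu threshold ANDed with a local-mean threshold,
   binary opening, hole filling, a minimum-area filter, and
   connected-component labelling.
2. **Per-nucleus features** — area ("Num Pix"), extent ("Extend" =
   area / bounding-box area), crack-length perimeter, circularity
   $4\pi A/P^2$, moment eccentricity, intensity mean / s.d. / entropy,
   and the pixel centroid (0-based coordinates).
3. **Phenotype classification** — each nucleus is scored as *normal*
   (interphase), *spindle* (mitotic arrest with a monopolar spindle:
   condensed, compact, bright) or *cytokinesis* (multi-/binucleated,
   multi-lobed footprint). The per-spot / per-well *fraction of phenotypic
   nuclei* is the screen readout.
4. **Perinuclear EGF quantification** — each nucleus footprint is extended
   morphologically into a surrounding ring in which the mean EGF-cargo
   intensity is measured per cell; spot/well readouts are cell-weighted
   means.
5. **Heteroscedastic statistics** — Welch's one-way ANOVA, the
   Games–Howell post-hoc test on an internally implemented studentized
   range distribution, Pearson correlation between replicates, Bartlett
   and F variance tests, intra-plate variance, and the
   replicate-equivalence calculation $n_a = (\mathrm{Var}_a /
   \mathrm{Var}_w)\, n_w$.

Because the original raw microscope images were never deposited, stage 0 is
a **synthetic image generator** with full ground truth; every downstream
stage is validated by parameter recovery against that truth and by
brute-force oracles.

## The synthetic generator: what it emulates, and what it does not

`scene_spec()` + `render_field()` draw a Poisson number of cells, assign
each a class from the phenotype mixture, place them by reject-and-resample
so that no two footprints touch, and render three channels: nuclei
(Hoechst-like), spot marker (Cy3-labelled siRNA disk; array platform only)
and EGF cargo. Noise is applied in a fixed order — background plane, object
rendering, optional Poisson shot noise, Gaussian read noise, clipping to
[0, 65535] and rounding — so a fixed seed yields bit-identical 16-bit
images.

Default study conditions mirror the emulated screen: ~156 cells per
300-µm array spot (one image per spot; cell-cycle assay), ~93 cells/spot
for the EGF assay, 9 spots per siRNA and 3 replicas on arrays, 9
subpositions per 384-well (6 wells/siRNA, 54 images/siRNA/plate), 25 per
96-well, and an EGF-uptake reduction of 60–70% under receptor knockdown.
The negative-control mixture defaults to 9.7% spindle and 8% cytokinesis
nuclei, the cell-array values of the emulated study (whose running text
swaps the 8.6%/9.7% spindle pair relative to its own summary table; we
follow the table).

Numbers chosen by this package where the source is silent:

* **Pixel size 0.65 µm/px** — typical 20x objective sampling on a
  scientific CMOS camera; a free configuration parameter, not a measured
  value. A 512 × 512 field then just contains a whole 300-µm spot.
* **Nucleus geometry** — normal-class ellipse semi-axes sampled around
  6.5 × 4.5 µm (a ~13 × 9 µm interphase HeLa nucleus). This keeps the
  in-spot areal coverage at 156 cells/spot near 20%. Substantially larger
  nuclei (e.g. 10 × 7 µm semi-axes) would push non-overlapping coverage
  towards the random-sequential-adsorption jamming regime (~55%), where
  non-touching placement stalls; the chosen size is at the lower end of
  the realistic range and leaves placement, and hence the Poisson cell
  count, essentially unbiased.
* **Photometry** — normal nuclei at base intensity 8000 counts with
  Gaussian chromatin texture (s.d. 500); the spindle class is ~60% of the
  normal area, near-circular, and 1.8x brighter (condensed chromatin);
  the cytokinesis class is one connected 2–4-lobed footprint of 1.5–2x
  the normal area. These choices make the area/extent/intensity feature
  separation of the three classes realizable, which is precisely what the
  original classifier exploited.
* **Cargo model** — per-cell true ring intensity ~ N(3000, 450²) counts
  painted as a 10-px annulus hugging the nucleus, plus a few punctate
  granules at 1.5x the ring intensity (endosomal clusters); background
  150 counts. Knockdown multiplies the ring mean.

What the generator does **not** emulate: optics (no PSF, no chromatic
effects), cytoplasm or membrane signal, uneven illumination beyond a
linear plane, cell debris and mitotic shake-off, touching/overlapping
nuclei (by default), and focus drift. Consequently, green recovery tests
show that the *analysis chain is correct and unbiased under its own
assumptions* — they do not certify performance on real micrographs, where
touching nuclei and texture would dominate the error budget.

## Segmentation: numerical choices

* **Rolling ball** is implemented exactly as a grayscale opening with a
  non-flat ball-top structuring element (height $\sqrt{r^2 - d^2}$ over
  the disc $d^2 \le r^2$), radius 50 px by default. Out-of-bounds
  neighbours are skipped, so a constant image maps to zero everywhere,
  borders included. The compiled kernel processes one output column at a
  time over contiguous column segments (about 2 s for a 512² field at
  radius 50 on one core).
* **Threshold combination** is a logical AND of the global Otsu mask and
  the local-mean mask (window 51 px, offset 0): the local mask suppresses
  the dim halo the global threshold admits around bright nuclei, and the
  global mask suppresses background speckle from the local one. The
  original description lists both thresholds but not the combinator.
* **Cleanup order** is opening (disc radius 2 px) → hole filling →
  minimum area (40 px). Filling before opening is unsafe: on an
  object-free field the AND mask is near-critical speckle, and filling
  its enclosed pockets first welds blobs that survive the opening. Hole
  filling traverses the background 8-connected (the dual of the
  8-connected foreground) for the same reason. Solid nuclei are
  indifferent to both choices.
* **Otsu** maximises between-class variance over a 256-bin histogram of
  the image's value range and returns the bin boundary; foreground is
  *strictly greater than* the threshold. A constant image is a
  "degenerate histogram" error.
* **No watershed**: touching nuclei are not split (the emulated pipeline
  had no splitting step either); the generator's non-touching default
  makes this a documented limitation rather than a hidden error source.
  Nuclei touching the field border are excluded by default
  (`exclude_border = FALSE` keeps them).

## Phenotype classifier

The default classifier is a Gaussian class-conditional (quadratic
discriminant) model on standardised features `num_pix`, `extend`,
`circularity`, `mean_intensity` — the minimal model matching "classified
based on the feature distribution of training data", trainable from tens
of examples, and fully auditable (its JSON serialisation is the complete
model). Numerical details:

* all moments are maximum-likelihood (divide-by-*n*), so duplicating a
  training set leaves the model bit-identical;
* each class covariance is ridge-regularised by $\varepsilon\,
  \mathrm{tr}(S)/d$ on the diagonal, $\varepsilon = 10^{-6}$;
* posterior ties break in class order (normal < spindle < cytokinesis);
* standardisation makes classification invariant under any affine
  rescaling of raw intensities applied consistently to training and test
  data.

Texture features are excluded from the default subset because the
generator's texture is simplistic white noise; with real training data the
subset is configurable. A rule-based fallback (`classifier = "rules"`)
thresholds area, extent and intensity at class-mean midpoints, mimicking a
manual two-feature gate.

The bundled training fixture
(`inst/extdata/training_features_synthetic.csv`, 485 labelled nuclei) is
produced by the generator itself — segmented features matched to
ground-truth classes — because the original labelled training images are
unavailable; user-labelled CSVs can be supplied instead.

## Perinuclear rings

The ring of nucleus *k* is its footprint dilated by the digital disc of
radius $w + 0.5$ (so a width-1 ring around a single pixel is its
8-neighbourhood), minus every nucleus footprint, with contested pixels
assigned to the nearer nucleus centroid — a Voronoi-style partition that
prevents double counting. The default width of 8 px (~5 µm at 0.65 µm/px)
is the single most result-sensitive free parameter of the EGF readout and
should always be reported alongside results. Granules inside the ring are
simply part of the mean, matching a mean-intensity readout. EGF readouts
are normalised per replicate to the negative control by default
(`percent_of_nc`); the raw means are always carried too, since the
original percentage baseline is not defined anywhere.

## Statistics layer

Statistics operate on **position-level readouts** (one value per spot or
well, fractions pooled cell-weighted over subpositions), not on replicate
means — with 9–54 positions per condition this is the granularity at which
post-hoc p-values of the magnitude reported in such screens are
attainable. The observation unit behind the original tables is not stated;
position level is this package's documented choice.

* `welch_anova()` implements the Welch (1951) statistic; it matches
  `stats::oneway.test` to 12 digits and reduces exactly to the squared
  Welch t at k = 2. Note that under an exactly balanced homoscedastic
  design Welch's F equals the classical ANOVA F only up to the
  small-sample correction factor $1 + \frac{2(k-2)}{k^2-1}\Lambda$ (the
  two converge as n grows); the tests assert that exact relationship.
* `studentized_range_cdf()` integrates the scale (chi) distribution with
  Gauss–Legendre panels around a normal-range inner integral, doubling
  the panel count until successive refinements agree to 1e-8 (absolute
  accuracy ~1e-12 in practice against independent references).
* `games_howell()` uses unequal-variance standard errors,
  Welch–Satterthwaite degrees of freedom per pair, $q = \sqrt{2}\,
  |\bar{x}_i - \bar{x}_j| / SE$, and the studentized range with k = total
  number of groups. The test is family-adjusted by construction; no
  further multiplicity correction is applied. Under a heteroscedastic
  null (k = 4, n = 10) its simulated family-wise error sits at the
  nominal 5%.
* Bartlett and F variance tests delegate to `stats::bartlett.test` and
  `stats::var.test` — the exact tools named by the emulated analysis —
  behind a thin validating surface.
* `replicates_needed()` is the planning identity $n_a = (\mathrm{Var}_a /
  \mathrm{Var}_w)\, n_w$, reported exactly and as a ceiling. With the
  published spindle-phenotype standard deviations (7.4 on arrays vs 5.3
  on plates, 3 plate replicates) it gives 5.85, i.e. 6 array replicates.

## Problem sizes used in tests and the reproduction script

Recovery runs use the study's own design sizes: 9 spots × 3 replicas at
~156 cells/spot for the spindle and density studies (27 fields of
512 × 512 px) and 5 spots × 3 replicas × 2 conditions at ~93 cells/spot
for the EGF study. Oracle-equivalence checks run on small rasters (9–64 px
across) where brute-force references are exact; distributional checks use
10⁶ Monte-Carlo draws and 2000 simulated screens. These sizes give
sampling error well inside the assertion bands while keeping a full run on
one core in the minutes range.

## Known limitations

* No splitting of touching nuclei; crowded real images will undercount.
* The classifier is only as good as its training features; the bundled
  fixture is synthetic and should be replaced with labelled real data for
  any real analysis.
* Ring width, local-threshold window and minimum area are
  resolution-dependent; defaults assume ~0.65 µm/px and must be rescaled
  for other optics (the CLI exposes all of them).
* `FieldImage` rasters live in memory; screens of thousands of
  2048² fields would need a streaming layer.
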