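---
title: "Methods: from raw hyperspectral streams to heritable hyper-traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw hyperspectral streams to heritable hyper-traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperphen)
```

This vignette explains the models and procedures behind `hyperphen`, the
assumptions they rest on, the numerical choices made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate.

## The imaging model

A pushbroom hyperspectral camera records one scan line at a time; each
frame holds all spectral bands for the pixels across that line.
Concatenated over lines this is the band-interleaved-by-line (BIL) layout,
and a full acquisition of the reference instrument is a
`1,004 × 250 × 900` block (pixels across the line × bands × lines) of
unsigned 16-bit little-endian samples. `reorganize_stream()` assumes BIL
by default because that is the native order of a line-scan instrument;
BSQ and BIP are selectable for data that has already been rearranged. The
exact byte layout of any particular instrument is configuration, not a
discovery the package can make: the `sample_type` argument covers the
common unsigned 8/16-bit cases.

Radiometric calibration is the standard two-point model
`r = (I − I_dark) / (I_ref − I_dark)`, with the dark-current frame
`I_dark` and white-reference frame `I_ref` taken under the acquisition's
own illumination. Consequences built into `calibrate_reflectance()`:

* pixels where `I_ref = I_dark` carry no calibration information and
  become `NA` rather than infinities;
* small negative reflectances are sensor noise around the dark level and
  are clipped at 0 (disable with `clip_negative = FALSE`);
* values above 1.2 are physically suspect for vegetation (specular
  glints) and are counted in the `n_flagged` attribute but not altered —
  flagging is cheap, silent alteration is not.

The band grid is linear: `λ(i) = 400 + (i − 1) · 600/249` nm, a step of
about 2.41 nm. The mapping is validated in the test suite against the
band/wavelength pairs that are known for the reference instrument
(band 106 ↔ 653 nm, 53 ↔ 525, 136 ↔ 725, 124 ↔ 696). One known label
(band 210, 903 nm) sits 0.6 nm off the linear grid; labels are therefore
treated with a ±1 nm tolerance, which is below half the band spacing.
Repeated scans of the same plant, when supplied as a list of streams, are
averaged sample-by-sample before calibration to improve the
signal-to-noise ratio.

Cubes are stored as an ENVI-style header/data pair with 64-bit floats so
the reflectance and wavelength round trip is lossless. The header parser
is deliberately minimal (the fields the package writes); it is not a
general ENVI reader.

## Segmentation

Healthy vegetation has a deep chlorophyll absorption near 670 nm and a
high near-infrared plateau near 800 nm; background, soil and pot are
spectrally flat. `segment_plant()` exploits this with a
normalized-difference ratio `(NIR − red)/(NIR + red)` from the bands
nearest 800 and 670 nm — maximal contrast across the red edge — followed
by:

1. an Otsu split of the ratio image, with a hard floor `ndvi_min = 0.2`.
   The floor matters for degenerate scenes: Otsu always finds *some*
   split, so a plant-free image would otherwise be bisected into a
   spurious "plant". Vegetation sits well above 0.2, flat materials near
   0, so the floor costs nothing on real scenes;
2. *opening by reconstruction* with a 3 × 3 box: the plain opening is
   used only as a marker, and the surviving connected components of the
   raw threshold mask are restored in full. A plain opening erases
   isolated noise pixels but also clips leaf tips one or two pixels
   wide; reconstruction keeps the silhouette intact while still removing
   speckle, which is what lets pixel precision and recall against the
   generator's ground truth stay above 0.99;
3. removal of connected components smaller than 50 px — smaller blobs at
   this working distance are debris, not plants. Multiple genuine plant
   blobs are retained.

Because the ratio is invariant to a common illumination gain, the
projected area S (the count of mask pixels) does not depend on absolute
reflectance scaling. Plants are imaged from two angles (0° and 90°);
`combine_views()` averages the two views' index vectors and projected
areas.

## The index catalog

Eight families total exactly 1,540 indices; with S the plant is described
by 1,541 variables. `T_i` is the sum of reflectance over plant pixels at
band *i* and `A_i = T_i / S`, so `A_i · S = T_i` is an identity the test
suite enforces on every cube. Derivatives are taken with respect to
wavelength (per nm), not band index, so values are comparable across
instruments with different band spacings. Three-point Lagrange stencils
are used: central at interior bands, one-sided at the two spectral ends,
which keeps each derivative family at the full 250 bands — the only
arithmetic under which six band-wise families and two 20-slot
characteristic families total 1,540. The first-derivative stencil is
exact for quadratics; the second-difference stencil is exact for cubics
on the uniform grid at interior bands.

The 20 characteristic slots are a versioned registry
(`characteristic_registry()`), computed identically from the T spectrum
(CPT) and the A spectrum (CPA): positions, amplitudes and trapezoid areas
of the first derivative over the blue (490–530 nm), yellow (560–640) and
red (680–760) edges; green-peak position/height (510–560); red-valley
position/depth (640–700); NIR plateau mean (780–1000); visible mean
(400–760); and five ratio / normalized-difference combinations. Slot 9 is
pinned to the red-edge area. The registry is a deliberate design point:
the exact historical definitions of such catalogs vary between
instruments, so the slots are named, documented and re-bindable rather
than hard-coded anonymously. The yellow edge is a falling flank, so its
extremum is located on |d1| and its amplitude keeps the (negative) sign.
Ratio slots return `NA` on a zero denominator (flat spectra) rather than
infinities.

## Trait models

With 1,541 candidate predictors and at most a few hundred plants, model
selection is unavoidable. `stepwise_lsr()` is classic bidirectional
stepwise regression on partial-F p-values with `alpha_enter = 0.05` and
`alpha_remove = 0.10` — the long-standing defaults, with removal looser
than entry so the procedure cannot cycle. Determinism is guaranteed by
the tie-break rule (smallest p-value, then lexicographically smallest
feature name), which also makes the selection invariant to column order.
Numerical guards: candidates whose addition makes the design
rank-deficient are skipped; when the residual sum of squares reaches the
working tolerance (`1e-10` of the total sum of squares) entry stops, so
an exact fit does not trigger spurious 0/0 F-statistics.

`kfold_cv()` assigns samples to folds by a seeded uniform permutation
(reproducible, documented by the stored seed and assignment) and reports
per-fold held-out R², `MAPE = 100/n · Σ |(Y_i − y_i)/Y_i|` and the
standard deviation of the per-sample absolute percentage errors
(SD\_APE). Samples with `Y_i = 0` are excluded from percentage errors
with a warning, since the ratio is undefined. MAPE is scale-invariant by
construction, which the tests verify.

`correlation_screen()` uses the absolute Pearson correlation against its
threshold (default 0.3): strong negative correlations are as informative
as positive ones for wavelength-frequency summaries. Band-family indices
are tallied at their band wavelength; characteristic indices at their
registry window centre (combination slots at the centre of their primary
window).

`discriminant_classify()` selects features by stepwise Wilks' lambda
partial-F tests and classifies with a linear discriminant
(`MASS::lda`), reporting the cross-validated confusion matrix and
correct rate. Features with a singular within-class scatter given the
current set are skipped. A caveat the test suite documents: under a
permutation null, cross-validated discriminant accuracy sits slightly
*below* chance at small n (the anti-learning effect of selection plus
LDA on noise); at n ≈ 100 the bias shrinks to a few percent.

## Variance components and hyper-traits

Heritability and genetic correlation come from the bivariate model

y_t = μ_t + u_t + e_t,  Var(u) = G ⊗ K,  Var(e) = E ⊗ I,

with K the genomic relationship matrix from standardized dosages
(`Z Z′ / m`). The restricted likelihood is maximized *exactly*: K is
eigendecomposed once, both traits are rotated into its eigenbasis where
the model decouples into independent 2 × 2 blocks, and the REML
criterion — including the `log |X′V⁻¹X|` term — is evaluated in O(n) per
iteration and maximized by L-BFGS-B on a log-Cholesky parameterization
of G and E. The parameterization keeps both covariance matrices positive
definite throughout, which is simpler and more robust near the boundary
than EM-style component updates; variance components are floored at
1e-8 and convergence is declared on a relative likelihood change of
1e-8. Traits are standardized internally, so heritabilities are
variance fractions and the scale of the components is benign for the
optimizer. Estimates of r_g within 0.001 of ±1 are reported as exactly
±1 with `boundary = TRUE` (a duplicated trait is the canonical case);
standard errors come from the inverse numerical Hessian with a delta
method and are `NA` at boundaries, where the quadratic approximation is
invalid.

Sampling properties worth knowing: the SD of a GRM-based h² estimate is
roughly `√(2m)/n` for an unstructured panel of m SNPs and n accessions,
so single-panel estimates at n = 500, m = 2,000 scatter by about ±0.13.
The package's recovery checks therefore average 20 independent panels,
and under a true h² of zero individual estimates follow a
boundary-truncated half-normal — some exceed 0.1 even though their
location is at zero.

An index qualifies as a *hyper-trait* when it is phenotypically and
genetically tied to an agronomic trait and highly heritable:
`|r_p| ≥ 0.5`, `|r_g| ≥ 0.5`, `h² ≥ 0.5`. Both correlations enter in
absolute value — a strongly negatively correlated index is exactly as
useful a proxy.

## GWAS post-processing

The association scan supplied with the package is a plain per-SNP linear
regression (slope t-test). That is deliberate plumbing: it lets the
post-processing chain run end to end on synthetic data, but it does not
correct for population structure or kinship the way a mixed-model scan
would, and its P-values should not be interpreted on structured panels.

The post-processing rules are:

* **thresholds** — suggestive `1/N`, significant `0.05/N`, with the
  effective number of independent SNPs N supplied by the user (its
  estimation is a separate concern); the ratio is exactly 0.05 for any N;
* **clumping** — greedy by ascending P among SNPs below the suggestive
  threshold; each retained lead removes all remaining candidates with
  `r² > 0.25` to it; finally, leads in LD with fewer than 5 SNPs at
  `P < 1e-4` are dropped — an isolated significant SNP with no associated
  neighborhood is more likely artifact than signal. LD r² is the squared
  Pearson correlation of dosages (the composite estimator standard for
  summary-level work). Sorting happens internally, so the result does
  not depend on input row order;
* **loci** — single-linkage merge of associated SNPs whose adjacent
  distance is under 300 kb, so distinct loci on a chromosome are at
  least 300 kb apart; the lead of a locus is its lowest-P member, ties
  broken by the smaller position. The merge is applied to whatever SNP
  set the caller passes — all suggestive SNPs or clumped leads — since
  either convention appears in practice;
* **candidate windows** — genes (from GFF3 via `rtracklayer`)
  overlapping ±100 kb of a lead SNP, reported with their distance;
* **haplotypes** — accessions grouped by identical multi-SNP genotype
  strings at the significant SNPs; groups under 30 accessions are set
  aside and the two largest are contrasted with a Welch t-test (no
  equal-variance assumption).

SNP filters follow common panel practice: minor allele frequency ≥ 0.05
and at least 6 accessions carrying the minor allele, applied after
orienting dosages to the minor allele.

## What the generator emulates — and what it does not

`simulate_cube()` builds plant spectra as a visible base plus a Gaussian
green peak (550 nm), a Gaussian chlorophyll absorption (680 nm) whose
depth grows with a latent chlorophyll level, and a logistic red edge
whose inflection shifts from 700 to 720 nm with that same level, capped
by a NIR plateau scaled by a latent biomass level. This is the simplest
shape that reproduces the qualitative canopy-reflectance features the
pipeline keys on, and the monotone chlorophyll effects are verified by
test. The sensor model inverts the calibration equation exactly — a dark
level with a mild spatial pattern, a halogen-shaped lamp spectrum with a
quadratic vignette — and quantizes to 16-bit integers, so calibrating
the emitted stream recovers the simulated reflectance to quantization
precision (about 5 × 10⁻⁵ against the ≥ 18,000-count dynamic range).
The plant shape is a rosette of tapering strokes several pixels wide,
matching the apparent leaf width of a potted plant at this working
distance.

Not emulated: radiative-transfer realism (no PROSPECT/SAIL physics, no
specular effects, no mutual shading), organ-level structure, and any
spatial correlation of the noise. Passing the segmentation and recovery
tests therefore shows the pipeline is *correct*, not that it is robust
to every field artifact.

`simulate_population()` draws SNPs with uniform MAF in [0.05, 0.5],
optionally with AR(1) LD along each chromosome via a latent Gaussian
haplotype field (`ld_rho` is the per-adjacent-SNP latent correlation; 0
gives linkage equilibrium). Phenotypes follow the additive model the
REML machinery assumes: per-SNP weights correlated at r_g across the two
traits, an optional planted-QTL layer carrying a stated fraction of the
genetic variance, and residuals orthogonalized against the genetic
values so the realized variance fractions match the requested h²
closely (the tests verify recovery of the configured h² to within 0.02
on average). Epistasis, dominance, G×E and population structure are not
simulated — which is precisely why the plain association scan is
adequate plumbing here.

## Problem sizes and runtime choices

The test suite and the acceptance script run at sizes chosen to make the
statistical checks meaningful while keeping a full run in the minutes
range on one CPU: cubes of 250 × 80 × 80 (one full-size
1,004 × 250 × 900 stream is reorganized to verify the instrument
geometry), REML recovery on 20 independent panels of n = 500 accessions
× 2,000 SNPs, segmentation against ground truth on 50 seeded cubes,
locus-set invariants on 1,000 random instances, and clumping equivalence
against a from-scratch oracle on 200-SNP panels. All randomness is
seeded; the same seed yields bit-identical generator output.

## Known limitations

* The characteristic-index registry is a reasoned standard catalog, not
  a reconstruction of any particular instrument's historical slot list;
  CPT/CPA are strictly T-derived and A-derived respectively.
* The ENVI reader handles the package's own headers only.
* `association_scan()` is unadjusted for structure/kinship by design.
* REML standard errors are asymptotic and unavailable at boundaries.
* The generator's spectra are qualitative, not radiometric; absolute
  reflectance levels should not be compared against field instruments.
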