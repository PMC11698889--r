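---
title: "Quantitative LA-ICP-ToF-MS bioimaging: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative LA-ICP-ToF-MS bioimaging: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`laquant` implements an analysis chain for multi-element tissue images from
laser-ablation ICP-ToF-MS: despiking, per-element background masking,
external calibration, response-factor normalization, and nonparametric
region/group statistics, together with a ground-truthed phantom generator
used to validate every stage. This vignette records the models, the
parameter choices that matter, and what the validation does and does not
establish.

## The processing model

An acquisition produces one 2-D intensity map per isotope on a common pixel
grid (rows are laser lines, columns positions along a line; 35 µm square
pixels by default). All maps of a section travel together as an
`image_stack`; the processing order is fixed: despike, convert to
concentration, mask, summarise.

### Despiking

`rolling_median_filter()` implements a robust outlier rule: for each pixel,
the median $m$ and scaled median absolute deviation
$s = 1.4826 \cdot \mathrm{MAD}$ are computed over the surrounding
$\text{size} \times \text{size}$ window, and the pixel is replaced by $m$
only if $|x - m| > k\,s$. Defaults are size 5 and $k = 3.0$. Two choices
are deliberate:

* **Deviation measure.** The scaled MAD is used rather than a windowed
  standard deviation: it is itself insensitive to the spikes being removed,
  and the 1.4826 factor makes $s$ estimate the standard deviation under
  normality, so $k$ keeps its familiar "3 sigma" reading.
* **Edges.** Windows are truncated at the image border rather than padded;
  padding would manufacture data. Non-outlier pixels pass through
  bit-identical.

### Background masking

Glass-slide pixels (and any tissue of no interest) contaminate region
medians downward. `kmeans_threshold()` clusters the flattened intensities
of one element with 1-D $k$-means ($k = 3$ by default), sorts clusters by
centroid, and masks every pixel in clusters below index $t$ ($t = 1$:
remove only the lowest cluster). The mask is reproducible from a single
scalar — the smallest intensity assigned to cluster $t$ — and ties at the
threshold are retained. Masking is monotone in $t$ by construction, and the
algorithm runs per element: elements differ in contrast, so a shared mask
would impose one element's background structure on another.

The solver is Lloyd's algorithm with k-means++ initialization (10 restarts,
seed 0, tolerance $10^{-8}$), followed by a deterministic boundary
refinement: in one dimension every optimal clustering is contiguous in
sorted order, so the solution is fully described by $k-1$ split points, and
coordinate descent over those split points removes the boundary-misplacement
local optima that Lloyd alone can converge to. In testing against an exact
dynamic-programming solution, plain restarted Lloyd missed the global
optimum on a few percent of random overlapping-mode instances; with the
refinement it matched it on 100/100.

Masking serves the *whole-tissue* (epithelial) group medians. Compartment
comparisons — adipose vs epithelium, tumor niche vs stroma — are computed
directly on the histology-annotated pixels without the k-means mask: those
regions are already delimited by the annotation, and re-masking them would
conflate segmentation behavior with the biological contrast.

### Calibration and LOQ

`fit_calibration()` averages each gelatine standard's intensity over all
its line pixels (5 lines × 200 pixels by default) and fits ordinary least
squares of mean intensity against the standard's *independently measured*
concentration — the cross-quantified value, not the nominal spike, because
spiking is less accurate than digestion-based re-measurement. The blank
standard deviation pools all blank pixels, and
$\mathrm{LOQ} = 10\,\sigma_{\text{blank}} / \text{slope}$. Curves with
$R^2 < 0.98$ trigger a warning (matrix-matched gelatine standards normally
do much better). `apply_calibration()` inverts the affine response per
pixel; sub-LOQ pixels are *flagged, not censored*, and negative
concentrations are *retained, not clipped* — both choices avoid biasing
low-concentration medians upward, at the cost of occasionally reporting a
small negative median for an element whose tissue levels sit near the
calibration noise floor (see Limitations).

Elements without their own standards are converted by
`normalize_by_standard()`: intensity × (reference concentration /
reference-standard mean intensity). This is a single-point response factor,
reported in reference-element-equivalent µg g⁻¹; it assumes proportional
response through the origin and is not a matrix-matched calibration. The
mean (not median) standard intensity is used, mirroring how the calibration
curve itself averages standard intensities.

### Region statistics

The statistical unit is the **per-sample region median** — never pooled
pixels, which would pseudo-replicate massively. Quantiles use the
linear-interpolation convention (R type 7) throughout, pinned for
reproducibility.

* Group contrasts (healthy vs non-metastatic vs metastatic) use the
  one-tailed Mann–Whitney U test with the later-stage group as the
  "greater" alternative: the scientific question is elevation in cancer.
  The p-value is exact for combined $n \le 20$ without ties, otherwise a
  normal approximation with tie and continuity corrections.
* Paired region contrasts use the two-tailed Wilcoxon signed-rank test.
  Zero differences are dropped. For up to 25 pairs the p-value comes from
  the exact sign-flip permutation distribution computed with average ranks
  — tied absolute differences therefore remain exact (a constant shift
  across six pairs yields exactly $2/2^6 = 0.03125$); this coincides with
  the classical signed-rank distribution when ranks are distinct.
* Sr–Ba colocalization is the Spearman rank correlation over masked
  epithelial pixels, classified strong ($\rho \ge 0.8$), moderate
  ($0.4 \le \rho < 0.8$) or weak. The moderate threshold is set at 0.4 so
  that coefficients from 0.46 upward count as at least moderate, consistent
  with how such coefficients are counted in this field's reports; both
  thresholds are arguments of `classify_correlation()`.
* No multiple-testing correction is applied by default, matching standard
  practice for these exploratory panels; the report tables carry raw
  p-values so any correction can be applied downstream.

Samples lacking a stroma region (widespread cancer) are excluded from the
niche/stroma comparison and counted in the report.

## The phantom generator

`generate_tissue_phantom()` builds what the validation needs: known truth
with the statistical structure the analysis assumes.

* **Geometry** is procedurally simple — an elliptical tissue section on
  glass, disc-shaped adipose inclusions, disc-union tumor niche inside the
  epithelium, remainder stroma. The pipeline consumes labels, not
  morphology, so histological realism buys nothing here.
* **Concentration fields** are lognormal: concentrations are positive and
  right-skewed, and the lognormal is the simplest law parameterised by a
  median and quartile spread, via
  $\sigma_{\log} = \ln(q_3/q_1) / (2\,z_{0.75})$ (exact for the
  lognormal). A lognormal matches the median and the quartile *ratio*;
  printed quartile pairs that are asymmetric about the median in log space
  cannot both be hit, and the ratio is what is matched.
* **Two variance levels.** Each sample draws its epithelial median from the
  group-level lognormal (the printed group median and quartiles), then its
  pixel field around that median with a within-sample quartile ratio of
  2.0. Published pooled quartiles conflate within- and between-sample
  variance — using them directly as pixel-field spread (for tissue or for
  adipose) makes single sections far more heterogeneous than the per-sample
  histograms such instruments produce, and in early testing it also let the
  adipose tail hijack the k-means clustering. The 2.0 ratio is a fixed
  modeling choice consistent with unimodal, moderately skewed per-section
  histograms.
* **Spatial structure.** Latent standard-normal fields are smoothed with a
  separable Gaussian kernel (σ = 2.5 px) and rescaled to exact unit
  marginal variance, so marginal laws and copulas are untouched while
  concentrations vary over a realistic correlation length instead of pixel
  to pixel. This matters: on spatially white fields the size-5 despike
  window reads genuine lognormal tails as spikes, biasing medians by
  several percent and visibly attenuating rank correlations — an artifact
  of the phantom, not a property of the method.
* **Sr–Ba coupling** is a Gaussian copula: the latent Pearson correlation
  is set to $r = 2\sin(\pi\rho_s/6)$ so the copula's population Spearman
  coefficient equals the target $\rho_s$ (0.90 by default) exactly, and
  monotone marginal transforms preserve it.
* **Detector model.** Expected signal is slope·conc + intercept in cps;
  counts are Poisson over an effective per-pixel integration time of 0.1 s
  and converted back to cps, so SNR grows with concentration as in real
  ablation data. Sparse salt spikes (probability 0.002, factor 20) exercise
  the despiker. Glass background contributes 0.5% of the epithelial median
  signal plus the instrument intercept. Sensitivities (Fe 1000, Cu 20000,
  Zn 5000, Sr 10⁴, Ba 10⁴ cps per µg g⁻¹) are fixed, realistic ToF-scale
  responses; no instrument values are published to match.
* **Cohort structure.** Default sizes 4 healthy / 7 non-metastatic / 11
  metastatic; per-sample seeds derive deterministically from the master
  seed; 2 NM and 3 M samples lack a stroma region by default (the tumor
  fills the epithelium), leaving 5 and 8 for stroma analysis; metastatic
  samples receive Fe hot spots (3 discs, amplitude ×10).

What the phantoms do **not** emulate: washout effects of fixation and
deparaffination, spectral interferences, detector drift, duty-cycle
effects, or histologically realistic morphology. Passing recovery tests on
phantoms shows the *pipeline* is correct and unbiased under its stated
noise model — it does not certify accuracy on real FFPE tissue, where
sample preparation adds biases no software stage can remove.

## Numerical choices and degenerate inputs

* Quantiles: type 7 everywhere; k-means ties at the threshold retained;
  exact-vs-approximate switchovers for the rank tests as stated above.
* `kmeans_1d` refuses inputs with fewer distinct values than clusters;
  `kmeans_threshold` refuses constant images (no threshold exists).
* Wilcoxon pairing with all-zero differences is an error ("degenerate
  pairing"), as is a constant map in Spearman colocalization
  ("rank-degenerate").
* NaN cells in input CSVs are zero-filled and counted (never silently
  dropped) so masks and grids stay congruent; incongruent shapes are hard
  errors everywhere — nothing broadcasts.
* All stochastic stages run under private, restorable RNG streams keyed by
  explicit seeds; a fixed master seed reproduces a cohort bit for bit.

## Problem sizes used in validation

The test suite runs phantoms of 60×80 to 120×160 pixels and cohorts up to
22 samples; filter and clustering oracles use 50 random 64×64 images and
100 instances of up to 200 values; rank tests are enumerated exhaustively
up to sizes (5,5) / n = 10, with 500 null simulations at the cohort's group
sizes for the type-I-error check; calibration recovery uses 100 seeded
standard sets of 5 lines × 200 pixels. These sizes make the full validation
run in a few minutes while keeping every estimate's Monte-Carlo error well
inside the asserted tolerances.

## Known limitations

* **Low-concentration elements near the calibration floor.** With
  unweighted OLS and a realistic 2% cross-quantification error on standards
  up to 19 µg g⁻¹, the calibration intercept carries an uncertainty of
  order 0.05–0.1 µg g⁻¹ (in concentration units). For an element like Cu,
  whose tissue medians are 0.03–0.07 µg g⁻¹, recovered medians can come
  out slightly negative — retained by design rather than clipped. Weighted
  regression would mitigate this but is out of scope; the below-LOQ flags
  and negative-value counts make the situation auditable.
* **Masked medians are conditional medians.** The k-means mask removes the
  lowest intensity cluster; when tissue heterogeneity is large the
  threshold can sit inside the tissue distribution and shift the masked
  median upward relative to the unmasked tissue median. This is inherent to
  intensity thresholding, not an implementation artifact; the threshold and
  centroids are logged per element and sample.
* **Group-comparison power at these cohort sizes is modest.** With 4
  healthy samples and the configured between-sample spreads, individual
  cohort draws can fail to reach significance for the weakly separated
  elements (Fe, Cu) — as the real cohort's own p-values (0.015–0.066)
  already suggest.
* The response-factor pseudo-concentration for Ba inherits any matrix
  difference between gelatine and tissue and has no LOQ of its own.
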