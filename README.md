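# laquant

Quantitative analysis of multi-element tissue images from LA-ICP-ToF-MS
(laser-ablation inductively-coupled-plasma time-of-flight mass
spectrometry) bioimaging.

## The problem

LA-ICP-ToF-MS rasters a laser over a tissue section and records a full
elemental mass spectrum in every pixel, yielding one intensity map per
isotope (here ⁵⁶Fe, ⁶³Cu, ⁶⁶Zn, ⁸⁸Sr, ¹³⁸Ba). Turning those raw maps into
biological conclusions — e.g. whether trace metals are elevated in breast
tumor tissue relative to healthy tissue, or whether Sr and Ba colocalize in
the epithelium — requires a chain of processing steps, each of which can
bias the result if done carelessly:

1. **Despiking** — isolated detector spikes are removed with a rolling
   median filter: a pixel deviating from its 5×5-window median by more than
   *k* = 3.0 scaled median absolute deviations (1.4826·MAD) is replaced by
   that median.
2. **Background masking** — glass-slide and irrelevant low-signal tissue
   pixels would drag region medians down. Per element, a 1-D *k*-means
   (*k* = 3, *t* = 1) clusters the pixel intensities; the lowest cluster is
   masked, with the threshold defined as the smallest intensity in cluster
   *t*.
3. **Calibration** — matrix-matched gelatine standards (5 ablated lines ×
   200 pixels each, spanning 0–33 µg g⁻¹ for Fe and 0–19 µg g⁻¹ for
   Cu/Zn/Sr) give per-element curves by ordinary least squares of mean
   intensity against independently cross-quantified concentration. The
   limit of quantification is LOQ = 10·SD(blank)/slope. Elements without
   their own standards (Ba) are converted to pseudo-concentrations by a
   response factor from a spiked Sr standard (1.31 µg g⁻¹).
4. **Region statistics** — per sample, the median (with Q1–Q3) of each
   element is computed per region (whole epithelium on masked pixels;
   adipose, tumor niche and stroma on H&E-annotation pixels). Groups
   (healthy / non-metastatic / metastatic) are compared by one-tailed
   Mann–Whitney U on per-sample medians; paired region contrasts use the
   two-tailed Wilcoxon signed-rank test (exact sign-flip distribution up to
   25 pairs); Sr–Ba colocalization is the Spearman rank correlation over
   epithelial pixels, classified weak / moderate / strong.

Because the underlying clinical images are not public, the package includes
a ground-truthed **synthetic phantom generator**: procedural tissue
sections (glass background, adipose blobs, epithelial compartment with an
optional tumor-niche/stroma split, Fe hot spots in metastatic samples) with
lognormal concentration fields, a Gaussian copula linking Sr and Ba at a
configurable rank correlation, Poisson counting noise and sparse spikes.
Every stage of the pipeline is validated against this ground truth and
against independent oracles (brute-force filtering, exact dynamic
programming clustering, exhaustive rank-test enumeration).

## Worked example

```r
library(laquant)

cfg <- phantom_config()                  # study-condition defaults
out <- run_pipeline(cfg, run_config(seed = 42))   # 4 H + 7 NM + 11 M samples
```

The Sr calibration curve fitted from the synthetic gelatine standards:

```
<calibration_curve> 88Sr: slope 9983, intercept -428.4, R2 0.9991, LOQ 0.009804 ug/g (range 0-18.8 ug/g)
```

The slope is the detector response (cps per µg g⁻¹); the LOQ of ~0.01 µg g⁻¹
says concentrations below that are indistinguishable from the blank.
Group-level epithelial Sr medians (µg g⁻¹, median of per-sample medians with
quartiles) and the one-tailed Mann–Whitney comparisons:

```
  element     region group n_samples group_median group_q1 group_q3
1    88Sr epithelial     H         4        0.778    0.614    0.909
2    88Sr epithelial     M        11        1.761    1.202    3.045
3    88Sr epithelial    NM         7        1.237    1.116    2.612

  comparison statistic p_value significant
1    H_vs_NM        25  0.0212        TRUE
2     H_vs_M        38  0.0198        TRUE
3    NM_vs_M        43  0.3621       FALSE
```

Healthy tissue carries ~2–3× less Sr than either cancer group (significant
at α = 0.05), while the two cancer groups do not differ — the pattern the
phantoms are configured to exhibit. Per-sample Sr–Ba colocalization on the
masked epithelium is moderate to strong:

```
  sample_id   elements   rho n_pixels strength
1     S01_H 88Sr-138Ba 0.814     8157   strong
2     S02_H 88Sr-138Ba 0.837     8766   strong
3     S03_H 88Sr-138Ba 0.686     8016 moderate
```

and the paired contrasts show adipose ≪ epithelium for every element
(e.g. ⁵⁶Fe: Wilcoxon p = 4.8×10⁻⁷ over 22 pairs) and tumor niche > stroma
(p = 4.9×10⁻⁴ over the 13 samples that retain a stroma region).

A thin command-line wrapper over the same functions lives at
`inst/scripts/laquant-cli.R`:

```sh
Rscript inst/scripts/laquant-cli.R all --out run1 --seed 42
```

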