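---
title: "Methods: models, estimators and design choices in airmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in airmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airmorph)
```

`airmorph` bundles the bespoke computations of a COPD-like lesion study —
airspace morphometry, epithelium-height measurement, pressure–volume curve
fitting, a cohort regression pipeline, RFLP genotyping, and small assay
calculators — together with seeded synthetic generators for every input.
This vignette explains each model, the parameters that matter, the
numerical choices made where the procedure was genuinely open, and what the
synthetic data do and do not establish about real data.

## Airspace morphometry

### Segmentation

Micrographs are interpreted in HSB space. The saturation channel separates
stained tissue (saturated pink/purple) from airspace (near-white):
`S = (max(R,G,B) − min(R,G,B)) / max(R,G,B)`, with `S = 0` for black
pixels. Pixels with `S` strictly below a threshold are air. Because no
universal numeric threshold exists across stains and scanners, the default
is `"auto"`: Otsu's criterion on the saturation histogram. A constant
saturation channel has no Otsu optimum; `"auto"` then falls back to 0.5.
On noiseless synthetic fields the segmentation reproduces the generator's
ground-truth mask pixel for pixel, for fixed thresholds between the two
class saturations and for `"auto"` alike.

### Particle statistics

Air components are labelled **8-connected** — diagonal air continuity is
real in parenchyma, and this matches the behaviour of the common
particle-analysis tools. Implementation detail: components are first
labelled 4-connected (EBImage), then diagonally adjacent labels are merged
by union–find; the result is exactly 8-connectivity.

Measurements are reported in physical units via the pixel size (µm/px):

* area = pixel count × (pixel size)²;
* perimeter by exposed-edge counting: each air-pixel edge facing
  background (or the image border) contributes one pixel-size length. This
  is exact for axis-aligned rectangles and slightly overestimates smooth
  curves (a known property of edge counting; we document rather than
  correct it, since the generating macro-style procedure does the same);
* equivalent circular diameter `2·sqrt(area/π)`, the shape-agnostic
  reading of "diameter". The minimum-diameter filter (default 5 µm)
  discards particles **strictly below** the cutoff, so a particle exactly
  at 5 µm is kept. The filter applies to particle statistics only — never
  to MLI chords, which are taken from the unfiltered binary image (a
  separate `min_chord_um` is available, default 0).

Border-touching airspaces are **included** by default in both particle
statistics and chords; `exclude_border = TRUE` is available because field
selection practices differ.

### Mean linear intercept

Every image row is scanned at a 1-pixel step; each maximal run of air
pixels contributes one horizontal chord (its width × pixel size); every
column likewise contributes vertical chords; the MLI is the arithmetic mean
of **all** chords from both orientations. Two consequences follow directly
and are used as oracles in the test suite: a single square of side *s*
yields MLI = *s* exactly (all chords equal *s*), and a disc of diameter *d*
yields the analytic mean chord π·d/4 — the rasterised value converges
within 2 % for *d* ≥ 50 px. On masks up to 32 × 32 the chord inventory is
checked exactly against an independent per-pixel exhaustive scan. The MLI
is scale-equivariant in the pixel size and invariant under 90° rotation
(the orientation chord sets swap).

## Epithelium mean height

The basal pole arrives as an ordered polyline in µm (at least two points,
positive arc length). The apical boundary is not drawn by the user: the
region of interest is the union of contiguous tissue components
(8-connected) touched by the rasterised basal line or its immediate
neighbourhood, i.e. morphological reachability from the basal line through
tissue. Mean height = ROI area / basal arc length. A rectangular band of
height *h* returns *h* exactly; a wedge ramping 0 → *h* returns *h*/2
within rasterisation tolerance (1 % at the fixture sizes used). A basal
line not adjacent to any tissue is an error, not a zero.

The band generator offsets each polyline segment along its normal and
rasterises the resulting quadrilaterals by pixel-centre classification;
its ground-truth mean height is the trapezoid rule on the height profile,
`Σ Lᵢ(hᵢ + hᵢ₊₁)/2 / Σ Lᵢ`. Sharp polyline bends can leave sub-pixel
slivers at quad joins; the shipped fixtures use straight or gently bent
basal lines, which is also the realistic acquisition geometry.

## Pressure–volume mechanics

The deflation limb is modelled as the exponential
`V(P) = A − B·exp(−K·P)` — A (mL) the asymptotic volume and estimate of
inspiratory capacity, B (mL) the volume span, K (1/cmH₂O) the shape
constant. The limb is isolated from a full loop as the samples from the
turning point (last sample at peak pressure, so a shared inflation/deflation
peak sample is not duplicated) to the end, ordered by decreasing pressure;
a record that only rises has no deflation limb and errors.

Fitting is unweighted nonlinear least squares (Levenberg–Marquardt,
`minpack.lm`, K bounded above 0), with data-driven starts:
`A₀ = max V`, `B₀ = A₀ − min V`, and `K₀` from the slope of
`log(A₀ + ε − V)` against `P` with `ε = 1e-9·B₀` guarding `log(0)`. No
weighting is applied because none is stated for this class of manoeuvre.
Noiseless curves are recovered to relative error below 1e-6 whenever the
pressure span covers ≥ 3/K; at 1 % noise (SD = 1 % of B) the mean of 200
seeded replicate fits recovers A and K within 2 %. Failures (degenerate,
e.g. perfectly linear, data) are flagged via `converged`, never silently
returned.

**Static compliance.** Commercial ventilator software does not publish its
Cst algorithm. The only definition expressible from the stated model is
the derivative of the fitted curve, so `Cst = B·K·exp(−K·P)` evaluated at
a configurable pressure, default 5 cmH₂O — roughly the mid-range of the
quasi-linear deflation region in mice. This is a declared definition, not
a claim of identity with any instrument's output.

## Cohort pipeline

The analysis of the nasal-polyp cohort is reproduced as four composable
stages:

1. **Exclusions**, in stated order: records with epithelial abrasion
   **strictly** above 70 % first, then smokers among the remainder. The
   counts per reason are therefore disjoint and additive (a record both
   abraded and smoking counts as abraded), which is the only reading
   consistent with the arithmetic 213 − 64 − 26 = 123 of the motivating
   design. Abrasion exactly at 70 % is retained.
2. **Binarization**: inflammation high for scores 2–3; secretory-cell
   hyperplasia high at ≥ 10 %; normal-epithelium proportion high at
   ≥ 50 %. Boundary percentages fall on the high side; a score outside
   0–3 is an error.
3. **Univariate screen**: Pearson χ² without continuity correction for
   categorical covariates (genotype enters here as one 3-level factor),
   two-sided equal-variance Student t for age. No Yates correction because
   the genotype table is 3 × 2 (the correction is a 2 × 2 device) and the
   uncorrected statistic equals the hand-computable `Σ(O−E)²/E`, which the
   tests exploit; a `correct` switch is deliberately not exposed to keep
   the screen identical to its oracle. Degenerate tables (zero margins,
   classes with < 2 records for the t-test) yield flagged `NA`s.
4. **Gate and fit**: covariates with p **strictly** below 0.1 enter the
   multivariate logistic regression (genotype now as HT and HO indicators
   against the WT reference). The fit is IRLS maximum likelihood
   (`stats::glm`); odds ratios are `exp(β)` with Wald 95 % intervals
   `exp(β ± 1.959964·SE)` and two-sided Wald p-values. Wald rather than
   profile intervals because the reported intervals in this literature are
   symmetric on the log-odds scale. Reference levels are reported with OR
   ≡ 1. Missing values are rejected, not imputed. Perfect separation and
   non-convergence are flagged; a constant outcome is an immediate error.

The logistic route is validated against an independent oracle: the
hand-written log-likelihood maximized by `optim` agrees with the package's
estimates to ~3 decimals in β on small two-covariate problems.

## Synthetic cohort generator

Records carry genotype (default frequencies WT/HT/HO = 0.60/0.33/0.07 —
plausible European-ancestry values for a minor-allele frequency near 0.24;
the real cohort's frequencies are not published in the main text, so these
are declared defaults, not inferences), age ~ N(45, 15²) truncated at 18,
gender Bernoulli(0.5), allergy/asthma Bernoulli(0.3), and independent
exclusion flags (abrasion ~ Uniform(0, 100), smoker probability
configurable, default 0.15). Each binary outcome is drawn from
`Bernoulli(logistic(β₀ + Σ log-OR·x))`; the intercept may be given
directly or solved by `uniroot` so the realized mean probability hits a
target prevalence (default 40 %, the mid-range that keeps both outcome
classes well populated). The generator then maps each binary outcome back
to the raw readout the pipeline consumes (a 0–3 score, a percentage), so
binarization inverts it exactly and the generating odds ratios are the
ground truth for the full pipeline round trip. The default effect sizes
are the package's reference odds ratios (inflammation HT 3.5, HO 6.47,
age 0.97/yr; secretory HT 5.18, HO 9.62), and at n = 50,000 the pipeline
recovers each within 15 % on the OR scale.

What the generator does **not** emulate: covariate correlation (age and
genotype are independent here), inter-rater variability of the underlying
histology scores, and any real linkage between smoking and outcomes —
exclusion flags are independent of everything by design. Passing tests
therefore establish the estimator's correctness, not robustness to
real-world confounding.

One printed reference row (HO against normal epithelium, OR 0.2 with CI
0.53–0.74) is internally inconsistent — the point estimate lies outside
its interval, presumably a typesetting slip — so the normal-epithelium
outcome is not used as a default recovery target.

## Genotyping and assay calculators

* **TaqI digestion** cuts at every 5′-TCGA-3′ occurrence between T and C
  (the enzyme's canonical T^CGA offset; the recognition sequence alone
  does not fix the cut position, so the canonical offset is a declared
  choice). Fragments concatenate back to the input — a tested invariant.
* **Genotype calls**: the restriction site is present only on the G (WT)
  allele. Per sample, both allele amplicons are digested and the pooled
  **unique** fragment lengths are the gel bands (equal-length fragments
  co-migrate). Both alleles cut → WT (2 bands), neither → HO (1 band),
  exactly one → HT (3 bands, given the default asymmetric site position at
  40 % of the amplicon — a centred site would merge the two WT fragments
  into one band). An allele with ≥ 2 sites contradicts the assay design
  and is flagged ambiguous rather than called. The amplicon generator
  scrubs accidental TCGA occurrences from its random backbone so the
  engineered site is the only signal; WT and SNP alleles differ at exactly
  one position.
* **Calcium F/Fmax**: baseline is the **mean** of the baseline epoch (the
  protocol names "baseline fluorescence" without an estimator; the mean is
  the low-variance choice), F is the agonist-epoch peak minus baseline,
  Fmax the ionomycin-epoch peak **without** background subtraction — so a
  constant offset moves Fmax but not F, an asserted property. Negative F
  is reported as-is. The trace generator samples at 200 ms over a
  1 min baseline + 5 min agonist + 10 s ionomycin protocol, placing
  transient peaks exactly on sample points so noiseless ratios are exact.
* **2^−ΔΔCT**: `ΔCt = Ct_target − Ct_reference` per condition,
  `ΔΔCt = ΔCt_sample − ΔCt_control`, fold `= 2^−ΔΔCt`; swapping sample
  and control inverts the fold exactly.
* **Proliferation index**: OLS slope of OD₅₆₀ against day (≥ 2 distinct
  days). **Protein normalization**: analyte/protein with protein > 0
  enforced. **Dose–response**: mean ± SEM (sd/√n) per dose; a
  single-observation dose reports SEM 0 with an explicit
  `sem_defined = FALSE` flag.

## Pipeline runner and reproducibility

`run_pipeline()` executes the simulate → analyze stages from a YAML or
list configuration validated against an explicit schema (unknown stages or
keys, out-of-range values and a missing seed are reported before anything
runs). One caveat of YAML 1.1 steered a naming choice: a bare key `n`
parses as a boolean, so the cohort size key is `n_patients`. Per-stage
seeds are derived deterministically from the single top-level seed, all
generators are pure functions of their seed (they restore the caller's RNG
state), and the report carries the configuration hash, so identical
configurations produce identical reports. Stage results are identical to
calling the module functions directly — the runner adds no hidden state.

## Problem sizes and tolerances used by the shipped tests

Chosen as the smallest sizes at which each statistical claim is stable:
cohort recovery at n = 50,000 (tolerance 15 % on the OR scale; the rarest
cell, HO at 7 %, still holds ~3,500 records); PV recovery over 200
replicates of 30-point limbs at 1 % noise (2 % bias tolerance); disc-MLI
within 2 % for diameters ≥ 50 px; 1,000 random ≤ 32 × 32 masks checked
exactly against the exhaustive chord scan; 100 random amplicon backbones ×
3 genotypes called 300/300. Rasterisation fixtures use 1 µm/px so pixel
counts read directly in µm².

## Known limitations

* Segmentation is saturation-only; stain deconvolution, vessel or
  bronchiole exclusion and 3-D stereology are out of scope (field
  selection is assumed done upstream).
* Perimeter by edge counting is biased upward for smooth boundaries;
  comparisons should stay within the package.
* The epithelium ROI detection assumes the epithelial band is the tissue
  component adjacent to the basal line; touching non-epithelial tissue
  would be absorbed into the ROI.
* Wald intervals degrade near separation; the flags should be consulted
  before interpreting ORs from small or quasi-separated cohorts.
* The synthetic cohort's independence assumptions (see above) make it a
  correctness harness, not an epidemiological simulation.
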