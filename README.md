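# airmorph

Quantification of COPD-like airway lesions, and the statistics that go with
it, in one tidyverse-native R package.

Chronic obstructive pulmonary disease (COPD) studies that work with airway
tissue keep re-implementing the same small set of bespoke computations:
segmenting enlarged airspaces on lung-parenchyma micrographs and summarising
them stereologically, measuring epithelium thickness over a hand-drawn basal
line, extracting mechanics parameters from pressure–volume manoeuvres,
running a cohort's exclusion/binarization/logistic-regression analysis, and
genotyping the *CHRNA5* rs16969968 polymorphism by restriction digestion.
`airmorph` packages those computations with tested, seeded synthetic-data
generators for every input, so the whole pipeline is reproducible without
raw images, physiology traces or patient data.

## What it computes

* **Airspace morphometry / emphysema.** RGB micrographs are converted to
  HSB; pixels with saturation below a threshold (fixed, or Otsu on the
  saturation channel) are air. 8-connected air particles are counted and
  measured (mean surface, perimeter, count per image), ignoring particles
  with equivalent circular diameter 2·√(area/π) below 5 µm. The **mean
  linear intercept** scans the binarized image row by row and column by
  column (step: 1 pixel); every maximal air run is a chord, and
  MLI = mean of all chords.
* **Epithelium height.** Mean height = ROI area / basal polyline length,
  with the ROI grown automatically from the basal line through contiguous
  tissue to the apical side.
* **Lung mechanics.** The deflation limb of a PV loop is fitted with the
  Salazar–Knowles exponential *V(P) = A − B·e^(−K·P)* (A estimates
  inspiratory capacity, K is the shape constant); static compliance is the
  fitted slope *B·K·e^(−K·P)* at a configurable pressure (default 5 cmH₂O).
* **Cohort analysis.** Exclusions (abrasion > 70 %, then smokers), outcome
  binarization (inflammation high for scores 2–3; secretory hyperplasia
  high ≥ 10 %; normal epithelium high ≥ 50 %), univariate χ²/Student-t
  screen, a strict p < 0.1 gate, then multivariate logistic regression
  reporting OR = e^β with Wald 95 % CIs.
* **Molecular assays.** In-silico TaqI digestion (T^CGA) and WT/HT/HO
  genotype calls from band patterns; calcium F/Fmax normalization; 2^−ΔΔCT
  fold changes; MTT proliferation index (OLS slope of OD₅₆₀ vs day);
  protein-normalized cytokines; dose–response mean ± SEM aggregation.

Every generator (`sim_*`) emits ground truth next to the artifact, and every
analysis function takes a data frame (or a small S3 container for images)
and returns a tibble; fitted objects support `tidy()`, `glance()` and
`autoplot()`.

## Worked example

```r
library(airmorph)

# a parenchyma field with 10 airspaces, 1 µm/px, and its morphometry
sp   <- random_airspaces(10, 300, 300, c(25, 70), seed = 42)
sim  <- sim_parenchyma(300, 300, pixel_size_um = 1, sp)
mask <- binarize_airspace(sim, "auto")
analyze_airspaces(mask, min_diameter_um = 5)
#>   count mean_area_um2 mean_perimeter_um min_diameter_um
#> 1    10         1910.              188.               5
mean_linear_intercept(mask)
#>   mli_um n_chords n_horizontal n_vertical
#> 1   40.6      941          471        470

# pressure–volume mechanics
loop <- sim_pv_loop(A = 1.2, B = 1.0, K = 0.12, noise_sd = 0.01, seed = 42)
fit  <- loop |> extract_deflation_limb() |> fit_salazar_knowles()
#> <sk_fit> V(P) = A - B * exp(-K * P)
#>   A = 1.1996 mL, B = 1.0122 mL, K = 0.12059 /cmH2O  (n = 20, RSS = 0.0021)
static_compliance(fit, 5)
#> [1] 0.06679391
```

The ten simulated airspaces are all recovered (count 10); their MLI of
~41 µm reflects the 25–70 µm diameter range; and the fitted (A, B, K) sit on
the generating values (1.2, 1.0, 0.12) to within the 1 % noise. On a
simulated cohort, `run_cohort_pipeline()` prints the exclusion log and a
tabular odds-ratio report per outcome:

```r
co <- sim_cohort(2000, seed = 42)
run_cohort_pipeline(co)
#> <cohort_report> n = 1166 retained of 2000
#> ...
#> -- inflammation: gate p < 0.1 kept [genotype, gender, age]
#> genotypeHT  4.24 [3.22–5.58]   genotypeHO  5.17 [3.17–8.44]   age 0.972
```

The genotype odds ratios recover the generator's truth (HT 3.5, HO 6.47,
age 0.97 per year) within the sampling noise of ~1,200 retained records.

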