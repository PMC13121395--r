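# lesionadapt

Lesion-adaptive PET segmentation and method selection for FDG-avid lymphoma.

## The problem

Metabolic tumour volume (MTV) in diffuse large B-cell lymphoma is usually
measured with a single semi-automatic segmentation method — most often an
absolute SUV 4.0 threshold — applied to every lesion. That works well on
high-contrast baseline scans but degrades at interim and end-of-treatment
PET, where residual uptake is faint and heterogeneous: a fixed SUV4.0
threshold under-segments or misses low-uptake lesions, while permissive
thresholds flood into surrounding tissue. No single method delineates every
lesion well, so the practical question is *which method to use for which
lesion*.

`lesionadapt` implements a complete, testable version of a lesion-adaptive
answer to that question:

- **Six seeded segmentation operators** on SUV volumes: absolute thresholds
  SUV2.5 and SUV4.0, a relative threshold at 41% of lesion SUVmax, a
  background-adapted iterative threshold at 50% of SUVpeak (A50peak,
  `T = BG + 0.5·(SUVpeak − BG)`), and majority-vote fusions MV2/MV3 that
  keep voxels selected by ≥2 or ≥3 of the four threshold methods. Every
  mask is the 26-connected component containing the lesion seed.
- **Lesion-level features**: SUVpeak (maximum 1 mL-sphere mean inside the
  mask), local background SUVbg (mean in the 10–15 mm shell around the
  contour), TBRpeak = SUVpeak/SUVbg, and MTV.
- **An exhaustive decision-rule search.** A rule is a prioritised
  two-condition classifier, e.g. *"if SUVpeak > 8 use SUV4.0; else if
  SUVbg > 0.8 use MV3; else use MV2"* (the shipped default). The engine
  enumerates every rule over a threshold grid (861,120 rules with the
  default grids under the distinct-method convention), scores each as the
  fraction of lesions whose selected method was quality-rated 3
  ("preferred"), and estimates accuracy with 50 repetitions of 5-fold
  cross-validation. Because rules are predefined there is no fitting — the
  search is a pure, fully vectorised evaluation that runs in about a minute
  on one CPU for the full grid.
- **ML selector baselines** (multinomial logistic, tree, random forest,
  SVM, XGBoost) with highest-probability selection, for comparison with
  the rule.
- **Agreement analysis** of any selection strategy against the
  preferred-rating reference (mean MTV of rate-3 segmentations): Spearman
  correlations at lesion and scan (TMTV) level, 10%/3 mL discrepancy
  fractions, signed over/under-segmentation counts.
- **Synthetic generators**: blurred-lesion SUV phantoms with known ground
  truth, and simulated rated cohorts built from a planted selection rule,
  so the whole pipeline can be exercised and verified without patient data.
- Scan quality control (liver SUVmean 1.3–3.0, glucose < 11 mmol/L,
  image activity 50–80% of injected), NIfTI-1 and CSV I/O, and a thin CLI
  (`inst/cli/lesionadapt`).

## Worked example

```r
library(lesionadapt)

## a blurred 9 mm lesion (peak SUV 8) in background 0.6, 2 mm voxels
g <- generate_volume(phantom_spec(
  grid_shape = 40, spacing = 2, background_suv = 0.6, noise_sd = 0.1,
  psf_fwhm = 6,
  lesions = list(lesion_spec(center = c(40, 40, 40), radius = 9, peak_suv = 8)),
  rng_seed = 1))
segment_all(g$volume, as.integer(g$seeds[1, c("i", "j", "k")]))
#> Six-method lesion segmentation at seed (21, 21, 21)
#>    method threshold_used n_voxels mtv_ml suvmax converged
#> 1  SUV2.5          2.500      517  4.136  8.073      TRUE
#> 2  SUV4.0          4.000      338  2.704  8.073      TRUE
#> 3   41max          3.310      422  3.376  8.073      TRUE
#> 4 A50peak          3.886      347  2.776  8.073      TRUE
#> 5     MV2             NA      422  3.376  8.073      TRUE
#> 6     MV3             NA      347  2.776  8.073      TRUE
```

The permissive SUV2.5 mask (4.1 mL) floods into blurred background; SUV4.0
is tightest (2.7 mL); the majority votes land in between, which is exactly
the behaviour the adaptive rule exploits.

```r
## a simulated 598-lesion rated cohort (409/67/122 across timepoints),
## generated by the shipped rule with 10% rating noise, then searched
tab <- simulate_rating_table(rating_sim_spec(rating_noise = 0.1, rng_seed = 1))
fit <- rule_search(tab, n_iterations = 50, rng_seed = 1)
fit
#> Decision-rule search: 861120 rules on 598 lesions (5-fold CV x 50 iterations)
#> Best rule: if SUVpeak > 8 use SUV4.0; else if SUVbg > 0.8 use MV3; else use MV2
#>   mean accuracy 0.8896 (SD 0.0243 across 250 held-out folds)

strategy_report(tab, coef(fit))
#> Agreement report (decision_rule strategy), 574 lesions (24 without reference excluded)
#>   lesion-level Spearman rho = 0.993; scan-level (TMTV) rho = 0.998
#>   > 10% deviation: 25.8% of lesions; > 3 mL: 0.9%
#>   over-estimated: 181 lesions, under-estimated: 200

strategy_report(tab, "SUV4.0")
#> Agreement report (SUV4.0 strategy), 574 lesions (24 without reference excluded)
#>   lesion-level Spearman rho = 0.828; scan-level (TMTV) rho = 0.964
#>   > 10% deviation: 63.6% of lesions; > 3 mL: 11.3%
#>   over-estimated: 107 lesions, under-estimated: 399
```

The search recovers the planted rule as the top-ranked rule with
cross-validated accuracy ≈ 0.89 (≈ 1 − the 10% rating noise), and the
adaptive rule agrees far better with the preferred-rating reference than
the one-size-fits-all SUV4.0 benchmark, which systematically
under-segments (399 of 574 lesions under-estimated).

## Package shape

`rule_search()` is the central fitting-style function and returns a classed
object with `print`, `summary`, `coef` (the winning `decision_rule`),
`predict` (apply the winner to new lesions) and `plot` methods;
`decision_rule` and `method_selector` objects have `predict` methods of
their own. The methods vignette (`vignettes/lesion-adaptive-rules.Rmd`)
documents the model, the conventions behind every operator, the synthetic
generators and the package's numerical choices.
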