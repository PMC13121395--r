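---
title: "Lesion-adaptive segmentation rules: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-adaptive segmentation rules: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionadapt)
```

## Why lesion-adaptive selection

Semi-automatic PET segmentation methods trade off sensitivity against
flooding. An absolute SUV 4.0 threshold is reliable for hot, high-contrast
lesions but misses or truncates faint ones; SUV 2.5 catches faint lesions
but floods into physiological uptake; relative thresholds (41% of SUVmax,
background-adapted 50% of SUVpeak) adapt to lesion intensity but become
unstable at low tumour-to-background contrast; majority votes of the four
threshold methods (MV2, MV3) hedge between them. Which method delineates a
given lesion best is predictable from a handful of uptake features — the
lesion's SUVpeak, its local background SUVbg, and their ratio TBRpeak —
which is what a prioritised decision rule exploits:

> if SUVpeak > 8, use SUV4.0; else if SUVbg > 0.8, use MV3; else use MV2

This shipped default (`default_decision_rule()`) reads naturally: hot
lesions are safely segmented by the strict absolute threshold; for cooler
lesions the choice between the two majority votes hinges on how warm the
surroundings are, with the stricter MV3 guarding against flooding when the
background is warm and the more permissive MV2 recovering signal when both
lesion and background are faint.

## Segmentation operators and their conventions

All operators act on an `suv_volume` (a 3-D SUV grid with physical voxel
spacing) and a seed voxel — the reader's click on the hottest voxel of the
lesion. Several conventions are not fixed by common usage, so the package
pins them down explicitly; each is an argument where a user might
reasonably want to vary it.

* **Connectivity.** A lesion mask is the 26-connected component of
  supra-threshold voxels containing the seed. 26-connectivity is the most
  permissive standard 3-D neighbourhood and avoids splitting blurred
  lesions across face-diagonal gaps.
* **Closed thresholds.** Voxels with SUV exactly equal to the threshold are
  included (`>= T`). Any fixed convention works; a closed one makes the
  uniform-block examples exact.
* **41%max scouting.** The "lesion SUVmax" of the relative method needs a
  lesion extent before the lesion is segmented. The operator scouts the
  seed's component at SUV 2.5 — the most permissive absolute threshold in
  the pool — and takes its maximum, falling back to the seed voxel when
  even 2.5 exceeds the seed. The scouting threshold is an argument.
* **A50peak iteration.** The background-adapted operator starts from the
  SUV 2.5 scouting component and iterates: compute the current mask's
  SUVpeak and its shell background `BG`, set `T = BG + 0.5 (SUVpeak − BG)`,
  regrow the seeded component at `T`. It stops when `T` moves by less than
  0.01 SUV or after 10 iterations (then flagged non-converged, last mask
  returned). The returned threshold is always the one that grew the
  returned mask, so the mask can be reproduced by a single flood fill at
  the reported value. All constants are arguments.
* **Majority votes.** MV2/MV3 count voxel-wise agreement among the four
  threshold masks and are then restricted to the seeded component, so every
  method yields a single lesion region, as the per-lesion rating protocol
  assumes. Empty masks are legal outputs (a failed delineation, MTV 0).

## Features

* **SUVpeak** is the maximum, over sphere centres inside the mask, of the
  mean SUV in a 1.0 mL sphere (diameter ≈ 12.4 mm). Centres are restricted
  to mask voxels but the sphere may extend outside the mask; out-of-grid
  voxels are excluded from the mean. This is the usual "peak" construction
  when no scanner-specific definition is mandated.
* **SUVbg** is the mean SUV in the shell of voxels 10–15 mm (closed bounds)
  from the mask surface, measured with true Euclidean distance honouring
  anisotropic spacing, with other lesions excludable. The same shell serves
  the A50peak background estimate; a shell is a generic, organ-agnostic
  background model and is documented as such a limitation below.
* **TBRpeak** = SUVpeak / SUVbg (undefined at SUVbg ≤ 0, which errors).
* **MTV** is voxel count × voxel volume; **TMTV** sums lesion MTVs per scan.

When ratings are available, lesion features are computed from the rate-3
method(s) — averaged when several methods are preferred; prospectively
(no ratings) the MV2 mask is the default substrate, being the single most
reliable method overall.

## The rule space and its grids

A rule combines two conditions on *distinct* features (ordered pairs from
SUVpeak, TBRpeak, SUVbg), strict `>` or `<` comparators, grid thresholds,
and an ordered triple of distinct methods. The default grids are 1–12 in
steps of 0.5 for SUVpeak and TBRpeak (23 values each) and steps of 0.2
within 0.5–2 for SUVbg. The SUVbg grid is anchored at its upper end
(0.6, 0.8, …, 2.0; 8 values) so that the shipped rule's threshold of 0.8 is
itself a grid point — a 0.5-anchored grid in 0.2 steps could never produce
it, and a search grid should contain its own winner. With the
distinct-method convention the space holds

\[(2\cdot23\cdot23 + 4\cdot23\cdot8)\times 4 \times (6\cdot5\cdot4) = 861{,}120\]

rules (`count_rules()`); allowing repeated method triples would give
1,550,016. Both conventions and all grids are exposed as arguments.

## Accuracy estimation

A rule's accuracy on a rated table is the fraction of lesions whose
selected method is rated 3; lesions with no preferred method at all count
as failures, because the denominator is "lesions in the held-out fold",
not "lesions with a reference". `rule_search()` estimates accuracy with 50
iterations of shuffled 5-fold cross-validation. Since rules are predefined
there is no fitting, and with equal fold sizes the across-fold mean equals
the full-table accuracy exactly — the tests assert this identity, and the
CV machinery's real value is the dispersion estimate. Two dispersions are
reported, because "SD across the 5 folds, compiled across 50 iterations"
is ambiguous: `accuracy_sd` pools all 250 held-out evaluations, while
`accuracy_sd_within` averages the per-iteration across-fold SDs. Ranking
uses mean accuracy, then smaller pooled SD, then enumeration order, making
the search fully deterministic given its seed (one seed governs all
iterations).

The engine is vectorised by a branch decomposition: for any lesion subset,
a rule's correct-selection count is
`#(C1 ∧ r3[m1]) + #(¬C1 ∧ C2 ∧ r3[m2]) + #(¬C1 ∧ ¬C2 ∧ r3[m3])`,
where all pairwise condition × rated-3 contingency tables are precomputed
with two matrix products per fold. Each of the 861,120 rules then costs a
few vectorised gathers, so the full default grid with 250 fold evaluations
runs in about a minute on one CPU. A per-rule scalar path
(`rule_accuracy()`) is kept as the reference implementation and the two are
tested for bit-identical results.

## ML selectors

The selector module wraps five generic classifier families (multinomial
logistic regression, decision tree, random forest, SVM, XGBoost) behind a
registry. Training needs a single label per lesion although several
methods may be acceptable; the label is the rate-3 method of highest
priority (MV2 > MV3 > SUV4.0 > A50peak > 41%max > SUV2.5 — overall
reliability order), and lesions with no rate-3 method are excluded from
training. Evaluation deliberately does *not* use that label: a selection
counts as correct when the chosen method is rated 3, the same semantics as
the rule search, so rules and classifiers are compared on an equal
footing. Prediction is highest-probability with exact ties broken by the
same priority order. Family defaults are used; no hyper-parameter search
is performed.

## Agreement analysis

The reference standard for volumes is the mean MTV of the segmentations
rated 3; lesions without any rate-3 method have no reference, are excluded
from agreement, and are counted transparently. `strategy_report()`
evaluates any strategy — a fixed single method, a decision rule, a trained
selector, or the rate-3 "oracle" — via Spearman correlation (average ranks
for ties) at lesion and scan level, overall and per timepoint, and flags
volumes deviating from the reference by more than 10% (relative, with the
reference as denominator) or 3 mL (absolute), with signed
over/under-estimation counts. Scan-level TMTV is reported both pooled and
per timepoint since either stratification can be of interest.

## What the synthetic generators emulate — and what they do not

**Phantoms** (`phantom_spec()`/`generate_volume()`) plant spheres or
ellipsoids at a chosen peak SUV in a uniform background, blur the lesion
excess with an isotropic Gaussian PSF parameterised by FWHM (the standard
PET resolution model), and add truncated Gaussian noise. Blurring only the
lesion excess keeps the background exactly uniform and conserves lesion
activity away from grid edges; the blurred peak approaches the nominal
peak as the radius grows beyond the PSF width (within 2% for a 10 mm
radius at 6 mm FWHM; at smaller radii partial-volume attenuation is real
physics, and the generator does not hide it by rescaling). Seeds are the
hottest pre-noise voxel per lesion, mirroring a reader's click.
Overlapping lesions are rejected by name. These phantoms exercise every
operator code path but are *not* anthropomorphic: no organs, no
respiratory motion, no scanner-specific reconstruction, no heterogeneous
lesion texture — so passing tests demonstrate correctness of the
operators, not clinical segmentation quality.

**Rated cohorts** (`rating_sim_spec()`/`simulate_rating_table()`) default
to the 409/67/122 baseline/interim/end-of-treatment split (598 lesions
over 33 patients, 99 scans). SUVpeak is log-uniform on [2, 20] and SUVbg
uniform on [0.3, 2.5] — deliberately broad, spanning the feature ranges at
which different methods win; real cohorts report only medians and IQRs, so
these are stand-ins exposed as configuration rather than estimates. The
planted rule's method is rated 3; other methods are co-acceptable (also 3)
with probability 0.2 by default, and otherwise rated on the
under-estimation side (1–2) when their nominal strictness exceeds the
planted method's and the over-estimation side (4–5) when more permissive,
reproducing the semantics of the 5-point scale (strictness order used:
SUV2.5 < 41%max < MV2 < MV3 < A50peak < SUV4.0). Rating noise flips the
planted method's rating to 2 or 4 with the configured probability, so the
best achievable selection accuracy is 1 − noise. Per-method MTVs come from
a log-normal true volume (median 3 mL) with rating-dependent bias —
preferred methods scatter ~15% around truth, rating 1 shrinks to 5–50%,
rating 5 inflates 2–8× ("flooding") — enough structure for the agreement
stage to discriminate strategies, but not a physical model of any scanner.

## Numerical choices and degenerate inputs

* Distances to a mask are exact Euclidean distances to its 6-surface
  (the nearest mask voxel to any exterior point provably lies there),
  computed pairwise within a padded bounding box; no chamfer
  approximation.
* The A50peak background falls back to 0 when the shell is empty (tiny
  grids), which degrades gracefully to the pure 50%-of-peak form.
* Empty masks: MTV 0; SUVpeak and SUVbg error (undefined), as does TBR at
  SUVbg ≤ 0. Shell errors distinguish "out of bounds" from "fully
  excluded".
* Constant inputs to the Spearman correlation are flagged
  (`constant = TRUE`, `rho = NA`) rather than silently returned.
* Seeds: every stochastic entry point takes an explicit integer seed and
  is bit-reproducible given it. Operators themselves use no randomness.

## Problem sizes used by the test suite

The suite verifies the operators against scalar brute-force oracles
(flood fill, per-voxel tallies, all-pairs distances, explicit rank
formulae) on 100+ random phantoms of 16³–20³ voxels, segments a full
598-lesion phantom cohort (3,588 records), and runs the complete 861,120
rule search with 50×5-fold cross-validation on a 2,000-lesion noisy
planted-rule cohort, recovering the planted rule in the top tie-group.
These sizes keep the whole suite within a few minutes while leaving every
code path at full production scale (the rule search runs on its complete
default grid, not a subset).

## Known limitations

* The SUVbg shell is organ-agnostic; near liver, kidney or myocardium a
  generic shell cannot represent organ-specific background, and flooding
  into physiological uptake remains the main practical failure mode that
  still needs human supervision.
* The A50peak literature leaves the background estimator's exact geometry
  open; the shell convention here mirrors the quantification shell and is
  an approximation.
* The simulated rating tables assume conditional independence of
  co-acceptability across methods given the planted choice; real observer
  ratings are correlated across methods in ways the simulator does not
  model.
* Rules are limited to two prioritised conditions and three output
  methods; richer rule shapes, continuous threshold optimisation, and
  per-timepoint rules are out of scope.
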