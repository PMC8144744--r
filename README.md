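# phase4d

Respiratory-phase selection and stability assessment for 4D-CT radiomics.

4D-CT planning scans of lung cancer patients are sorted into ten
respiratory bins (phases 0%–90%, 0% = peak inhale). Radiomic features of
the tumour and the peritumoural band vary across phases through motion and
sporadic artifacts, and every radiomics study must decide which phase data
to analyse. `phase4d` implements a data-driven framework for that decision
and measures what each choice is worth in a survival model, for
researchers building prognostic imaging biomarkers (the motivating setting
is distant-failure prediction after stereotactic ablative radiotherapy).

The core is the *personalised most-stable-phase* rule. For feature
$X_{F,n,Ph}$ (feature $F$, patient $n$, phase $Ph$), the cyclic
neighbour-phase difference

$$\Delta X_{F,n,Ph} = |X_{F,n,Ph} - X_{F,n,Ph-1}| + |X_{F,n,Ph} - X_{F,n,Ph+1}|$$

(0% wraps to 90%) scores each phase; each feature votes for its argmin,
and the patient's most stable phase is the modal vote. Around this the
package provides:

* four single-feature-set constructions: mean, median, 50% phase,
  personalised;
* four stability-assessment regimes: none, ICC(A,1)-stability across 10
  phases, across the 3 neighbour phases, and neighbour-phase averaging —
  twelve valid set–assessment combinations in total;
* ICC(A,1) (two-way mixed effects, absolute agreement, single measurement)
  with McGraw–Wong confidence intervals; a feature is stable when the 95%
  CI lower bound is at least 0.85;
* ROI geometry: 3 mm peritumoural band by Euclidean distance transform,
  nearest-voxel mask translation, high-density correction, 64-voxel
  minimum, motion amplitude;
* an IBSI-style extraction pipeline (93 first-order/texture features per
  image type per ROI; original + Laplacian-of-Gaussian σ = 1.5 mm; fixed
  25 HU bins anchored at the ROI minimum; 372 features per phase);
* unsupervised filters (|Spearman ρ| ≤ 0.5 to tumour volume; within-ROI
  redundancy elimination at |Pearson r| ≤ 0.5) and standardisation;
* three supervised selectors (univariable Cox, likelihood ratio over a
  clinical base model, survival MRMR) inside 40×5 event-matched stratified
  cross-validation, selector ranking by `C_test − |C_test − C_train|`, and
  occurrence-ranked signatures of median size;
* clinical-radiomics Cox comparison: 500-bootstrap c-index and the
  fraction of new information `1 − LR_C / LR_CR`;
* synthetic generators — phase-feature cohorts with designed stable
  phases, artifacts, correlation blocks and planted prognostic features;
  survival outcomes; and a moving-sphere 4D CT phantom — so the whole
  pipeline is testable without any data download.

## Worked example

```r
library(phase4d)

design <- simulation_design(n_patients = 120, n_features = 60, seed = 1)
gen <- gen_phase_features(design)            # phase table + ground truth
stable <- select_stable_phase(gen$table)     # per-patient most stable phase
mean(stable$selected == gen$truth$designed_phase)
#> [1] 1

table(stable$selected_label)
#> 0% 10% 20% 30% 40% 50% 60% 70% 80% 90%
#>  2   1   6  10  18  33  30  13   5   2

m <- build_feature_set(gen$table, "personalised", stable = stable)
out <- gen_outcomes(m, design, planted = gen$truth$planted,
                    volume = gen$truth$volume)
res <- run_model_comparison(gen$table, out$clinical, out$outcomes,
                            stable = stable, selector = "univariable",
                            repeats = 5, folds = 5, B = 100, seed = 1)
res[c(1, 2), c("model", "cindex_median", "fraction_new")]
#>               model cindex_median fraction_new
#> 1          clinical         0.667           NA
#> 2 personalised+none         0.877        0.795
```

The selection histogram shows the exhale-biased designed phases the
generator planted (about a third at 50%), all recovered. In the comparison
table, the clinical baseline's bootstrap median c-index is modest, the
personalised clinical-radiomics model finds the planted prognostic
features, and `fraction_new` says what share of the combined model's
explained variation (likelihood-ratio χ²) the radiomic signature
contributes beyond the clinical covariates.

A thin command-line wrapper over the same functions is installed at
`inst/cli/phase4d.R` (`select-phase`, `build-sets`, `stability`,
`simulate`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline from scratch against the installed package: it
builds a 10-phase moving-sphere phantom and extracts the fixed 372-feature
configuration, then generates a seeded synthetic cohort, runs personalised
phase selection, and executes the full 13-model comparison (12 Table-style
combinations plus the clinical baseline), logging per-model bootstrap
c-indices and fractions of new information before writing the JSON report.
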