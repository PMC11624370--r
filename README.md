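# mefeval

Genomic evaluation of methane efficiency in dairy cattle, end to end: from
milk mid-infrared (MIR) spectra to relative breeding values for a methane
trait that is genetically independent of production.

Routine milk recording produces MIR spectra for millions of cows. Because
milk composition (notably fatty acids) reflects rumen fermentation, daily
methane production (g/d) can be predicted from those spectra, turning an
expensive trait measured on a few hundred cows into a population-scale
phenotype. `mefeval` implements the full evaluation chain a genetics
program needs on top of that idea, with a synthetic-data generator carrying
known ground truth so every stage is testable without proprietary data:

* **Spectral phenotyping** — informative-region selection (FOSS pins
  260–402, 442–472, 701–767; 241 points), piecewise standardization with
  PCA-based subset detection, Mahalanobis quality control (χ², *P* <
  0.001), Savitzky–Golay smoothing (order 3, width 11), weekly averaging
  of daily methane with edits (first lactation, 5–305 DIM, ≥ 2 daily
  records, 3.5 SD), 11-day spectrum matching, and a Bayesian-regularized
  neural network (2 tanh neurons, 100 epochs) for prediction.
* **Relationship matrices** — pedigree `A` and its sparse inverse
  (Meuwissen–Luo inbreeding, Henderson's rules), VanRaden genomic `G`
  with tuning and blending to `A22`, and the single-step
  `H⁻¹ = A⁻¹ + [0 0; 0 G*⁻¹ − A22⁻¹]`.
* **Mixed models** — the four-trait herd-test-day animal model

  `y = Xb + Z₁htd + Z₂a + Z₃p + e`,

  with covariance structure `var(htd) = HTD ⊗ I`, `var(a) = G ⊗ A` (or
  `G ⊗ H` in single-step form), `var(p) = P ⊗ I`, `var(e) = R ⊗ I`, for
  traits CH4 (MIR-predicted methane), milk, fat and protein yield.
  Sparse Henderson equations, direct and conjugate-gradient solvers,
  multi-trait AI-REML (EM-warmed, average-information updates, trace
  terms from a blockwise Takahashi selected inverse written in C++), and
  exact PEV reliabilities.
* **Methane efficiency (MEF)** — the genetic residual of methane on the
  production traits, `raw = EBV_CH4 − b′(EBV_MY, EBV_FY, EBV_PY)` with
  `b = G_pp⁻¹ g_p`, sign-reversed so higher = less methane, expressed as
  a relative breeding value (mean 100, SD 5 in base bulls), with
  selection-index reliabilities, the 80:20 genomic reliability blend,
  and the official-status rule (≥ 20 daughters, ≥ 5 herds, ≥ 70%
  reliability).
* **Reporting** — RBV class summaries (low < 95, medium 95–105,
  high > 105), daughter-average regression translating RBV points into
  g/d of methane, and proof-correlation tables.

Everything is tidyverse-native: functions take data frames, return
tibbles, and fitted objects have `tidy()`, `glance()` and `autoplot()`
methods.

## Worked example

Simulate a small genotyped population with known (co)variances, estimate
the components by REML, run a single-step evaluation and derive MEF:

```r
library(mefeval)

cfg <- sim_config(n_founders = 80, n_founder_males = 16,
                  n_generations = 1, n_offspring_per_gen = 400,
                  female_fraction = 1, n_herds = 10, n_snps = 500,
                  genotyped_fraction = 0.3, seed = 42)
pop <- simulate_population(cfg)

fit <- reml_estimate(pop$records, pop$pedigree)
fit
#> <reml_fit> ai | traits: CH4, MY, FY, PY
#> records: 800 | converged: TRUE after 7 iterations | logL = -2293.200
#> heritabilities: CH4=0.254, MY=0.229, FY=0.333, PY=0.243
```

The simulation truth sets heritabilities 0.23/0.38/0.27/0.28; with only
400 cows the estimates above carry visible sampling noise (the
acceptance study below averages 10 replicates of 1,500 cows). Continue to
the single-step evaluation:

```r
des  <- build_design(pop$records, pop$pedigree)
ped  <- des$pedigree
gids <- as.character(ped$animal[ped$genotyped])
A22  <- numerator_relationship(ped)[gids, gids]
G    <- genomic_relationship(pop$genotypes[gids, ], A22 = A22)
Hinv <- h_inverse(numerator_relationship_inverse(ped), A22, G, gids)
sol  <- solve_mme(assemble_mme(des, fit$components, Hinv))

rel  <- pev_reliability(sol)
relw <- tidyr::pivot_wider(rel[, c("animal", "trait", "reliability")],
                           names_from = trait, values_from = reliability)
ev   <- mef_evaluation(sol$ebv, relw, fit$components$G, ped,
                       records = pop$records)
head(ev, 4)
#> # A tibble: 4 x 9
#>   animal raw_mef mef_index   rbv reliability n_daughters n_daughter_herds
#> 1 1        25.9     -25.9   94.1       0.782          30                9
#> 2 2        17.2     -17.2   95.7       0.751          25               10
#> 3 3       -32.7      32.7  105.        0.705          21                7
#> 4 4         6.03     -6.03  97.7       0.717          22                9
```

`raw_mef` is residual genetic methane in g/d (lower is better); `rbv`
re-expresses the reversed index on the 100/5 scale of the base bulls, so
sire 3 (RBV ≈ 105) transmits genetically lower methane at unchanged
production. `autoplot(ev)` draws the RBV distribution;
`rbv_class_summary()` and `daughter_regression()` reproduce the standard
validation summaries.

## Limitations

The prediction accuracies of the real spectral calibration (r = 0.70,
RMSE = 58.62 g/d on station data) depend on proprietary milk-recording
data and are not reproducible here; the synthetic spectra are calibrated
so a linear oracle reaches a comparable accuracy, and the pipeline is
validated for recovery of its own ground truth. See the methods vignette
(`vignettes/methane-efficiency.Rmd`) for the model, the generator's
assumptions and all numerical choices.
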