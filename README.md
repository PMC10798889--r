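# csfsubtypes

Molecular subtyping of Alzheimer's disease (AD) from cerebrospinal fluid
(CSF) tandem-mass-tag (TMT) proteomics.

AD is molecularly heterogeneous: amyloid-positive patients differ in which
processes dominate their CSF proteome (neuronal hyperplasticity, innate
immune activation, RNA dysregulation, choroid plexus dysfunction,
blood–brain barrier impairment). This package is for proteomics and
neurology researchers who want to run — and stress-test — the full
subtype-discovery pipeline on such data:

1. **Normalization** — two-step internal reference scaling (IRS), adapted to
   the median, for 16-channel TMT plexes (14 samples + 2 pooled reference
   channels): within-plex channel medians are matched to the reference
   channels, then per-protein factors `G / r_p` (G = geometric mean of the
   pooled-reference level across plexes) remove batch effects exactly;
   then log2 + z-scaling to controls.
2. **Screening** — Kruskal–Wallis tests of AD vs control, overall and
   stratified by cognitive state and tau status; union of any-stratum
   significance.
3. **Subtyping** — consensus non-negative matrix factorization
   (`X ≈ W·H`, generalized KL, multiplicative updates, 30 seeded restarts)
   with rank selection balancing the cophenetic coefficient, a silhouette
   > 0.5, and a twofold fit improvement over a randomized reference:
   `rho(k) = [fit(k−1) − fit(k)] / [fit_rand(k−1) − fit_rand(k)] ≥ 2`.
   Patients and proteins are dual-clustered by the argmax of `H` and `W`.
4. **Robustness** — Louvain communities (resolution 1.15) on the weighted
   protein coexpression network, matched to the NMF protein clusters by
   exact maximum-weight assignment.
5. **Profiling** — per-protein linear models vs controls with estimated
   marginal means (optional age/sex adjustment, ≥ 5 observations per group),
   plus one-sided hypergeometric term-set enrichment with BH-FDR.
6. **Transfer** — nested protein panels matched to replication cohorts,
   SCUT/SMOTE class balancing, random forests (1,000 trees, 100 repeated
   80/20 splits), mean vote-fraction probabilities, max-probability labels.

Real CSF TMT cohorts are access-controlled, so the package includes a
synthetic cohort generator (`generate_cohort`) that plants subtypes,
signatures, plex batch effects, reference channels and missing blocks — the
entire test suite and the acceptance benchmarks run on it.

## Worked example

```r
library(csfsubtypes)

cfg <- synthetic_config(n_controls = 40, n_ad = 90, k_true = 3,
                        subtype_proportions = c(0.4, 0.35, 0.25),
                        n_proteins = 120, signature_size = 25,
                        effect_size = 2, noise_sd = 0.3,
                        missing_plex_fraction = 0.02, seed = 42)
cohort <- generate_cohort(cfg)
res <- run_discovery_pipeline(cohort$intensity, cohort$metadata,
                              k_range = 2:5, n_runs = 8, seed = 42)
print(res$model)
#> subtype_model
#>   k   fit fit_rand cophenetic silhouette improvement_ratio
#> 1 2 55.22    77.67     0.9686     0.9051             5.778
#> 2 3 44.16    73.66     0.9760     0.8461             2.760
#> 3 4 41.49    69.73     0.9720     0.6149             0.677
#> 4 5 39.26    66.13     0.9421     0.4841             0.620
#> selected k: 3

truth <- cohort$truth$subtype
ad <- names(truth)[!is.na(truth)]
adjusted_rand_index(res$model$patient_labels[ad], truth[ad])
#> [1] 0.9707871
```

Reading the table: the fit improvement from 2 to 3 components is 2.76× the
improvement on permuted data and the consensus silhouette is 0.85, so k = 3
is admissible; k = 4 and 5 fail the twofold gate (0.68, 0.62 — they would be
fitting noise). Among admissible ranks, k = 3 has the highest cophenetic
coefficient (0.976): three subtypes, matching the planted truth, and the
per-patient labels agree with the planted assignment (adjusted Rand index
0.97; 1 = identical, 0 = chance).

The robustness check and transfer follow the same objects:

```r
rob <- coexpression_robustness(res$norm, res$model, cohort$metadata, seed = 1)
rob$overlap_percent          # % agreement of Louvain vs NMF protein clusters
```

A command-line interface covers the same stages
(`simulate`, `normalize`, `select`, `subtype`, `robustness`, `profile`,
`transfer train|predict`); every stage is bit-reproducible given `--seed`:

```sh
Rscript inst/cli/csfsubtypes simulate --out sim/ --seed 7 --n-proteins 200
```

## Known red benchmark

On the strong-separation synthetic benchmark (five planted subtypes at
prevalences 32.7/29.6/5.7/18.6/13.4%, shift = 2 control-s.d.), the
cophenetic coefficient peaks at k = 5 and the k = 5 solution recovers the
planted labels (ARI 0.94), but the twofold fit gate measures
`rho(5) ≈ 1.3 < 2`: the marginal fit gain of a ~6%-prevalence subtype is
smaller than what NMF gains per rank on permuted data. The acceptance test
asserting that the full rule selects k = 5 is therefore left failing, with
a passing companion test documenting the consensus-statistics evidence. The
methods vignette (`vignettes/csf-subtyping-methods.Rmd`) analyzes this in
detail — read `model$metrics` rather than trusting the gate when a small
subtype is plausible.
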