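# snfsubtypes

Multi-omics patient subtyping by similarity network fusion (SNF) and
consensus spectral clustering, with clinical and molecular
characterization of the discovered subtypes.

## What problem this solves

Idiopathic pulmonary fibrosis (IPF) is clinically heterogeneous:
patients with similar lung function at enrollment progress at very
different rates. One route to better prognostication is *endotyping* —
grouping patients by blood molecular profiles rather than by clinical
variables — and then asking whether the molecular groups differ in
outcome. `snfsubtypes` implements that analysis for three blood
modalities (plasma proteins, plasma miRNAs, whole-blood total RNA) as a
reusable, tested R pipeline:

1. **Fusion.** Per-modality patient-similarity networks built with a
   scaled exponential kernel,
   `W(i,j) = exp(-d(i,j)^2 / (mu * eps(i,j)))`, are merged by SNF
   cross-diffusion (`P_v <- S_v %*% mean(P_-v) %*% t(S_v)`, T iterations).
2. **Clustering.** Spectral clustering of the fused network, stabilized
   by consensus over 100 random 80% subsamples; the number of clusters
   (2–10) is chosen by the mean silhouette of each k's consensus matrix.
3. **Clinical characterization.** Composite endpoints (transplant-free
   and progression-free survival, the latter adding a >= 10
   percentage-point absolute FVC decline), Kaplan-Meier/log-rank, Cox
   models unadjusted and adjusted for CPI
   (`91 - 0.65*DLco% - 0.53*FVC% + 0.34*FEV1%`) and antifibrotic use,
   baseline comparison tables, and Cohen's kappa against an external
   risk grouping.
4. **Molecular characterization.** Per-modality contribution by
   normalized mutual information, a 5-fold cross-validated random-forest
   classifier with a >= 3-of-5 feature-selection ledger, per-feature
   linear-model differential expression with BH-FDR, miRNA target-gene
   expansion, and hypergeometric pathway over-representation on GMT
   collections.

Because the motivating registry data are restricted, the package ships a
first-class synthetic-data generator (`sim_config()`, `simulate_study()`)
whose defaults plant the assumed structure: 232 subjects, two subtypes
(45/55), signal in the protein and miRNA blocks but not in toRNA, and
subtype- and severity-dependent censored survival.

## Worked example

```r
library(snfsubtypes)

study <- simulate_study(sim_config(seed = 11))
blocks <- list(study$blocks$protein, study$blocks$mirna,
               variance_filter(study$blocks$torna, 0.10))
ds    <- align_subjects(lapply(blocks, standardize_features))
fused <- snf(ds, snf_params())                       # K=20, mu=0.5, T=20
prof  <- silhouette_profile(fused$W, 2:10, iterations = 100,
                            ratio = 0.8, seed = 3)
print(prof)
#>      2      3      4      5      6      7      8      9     10
#> 1.0000 0.8660 0.7070 0.6340 0.5810 0.5920 0.5310 0.5270 0.4830
#> selected k: 2

k   <- select_k(prof)                                # 2
lab <- prof$runs[[as.character(k)]]$assignment
table(lab$labels)
#>   1   2
#> 102 130
adjusted_rand(lab$labels, study$true_labels[names(lab$labels)])
#> [1] 1

modality_contribution(ds, lab, k, iterations = 100, seed = 5)
#> protein   mirna   torna
#>       1       1       0
```

The silhouette profile peaks at k = 2 and the recovered subtypes match
the planted ones exactly (adjusted Rand index 1). The contribution NMIs
say the protein and miRNA networks each reproduce the fused clustering
on their own while the toRNA network carries none of it — the expected
pattern, since the generator plants no toRNA signal. Downstream,
`derive_progression_outcome()` / `cox_fit()` quantify the survival
separation of the subtypes, `run_cv_classifier()` builds the
protein+miRNA subtype classifier, and `differential_expression()` /
`ora_hypergeometric()` characterize the molecular differences.

The same analysis runs as a staged pipeline with one YAML config and a
run manifest:

```r
run_pipeline(default_config(n_subjects = 232, seed = 1),
             outdir = "run", stage = "all")
```

or from a shell via the thin wrapper `inst/cli/snfsubtypes`
(`snfsubtypes all --config cfg.yaml --outdir run`).

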