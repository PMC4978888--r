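# germpred

Genomic prediction for germplasm collections.

Seed banks hold tens of thousands of accessions that are expensive to
phenotype but increasingly cheap to genotype. When historical field-trial
records exist for part of a collection, whole-genome regression models
trained on those records can predict the genetic merit of every genotyped
accession — including the never-phenotyped ones — and so guide which
accessions are worth growing out. `germpred` implements that workflow for a
soybean-style collection: inbred accessions evaluated across many trials,
blocked by maturity group (MG), with seed oil, protein and machine-harvest
yield as the target traits and lodging/shattering scores (1–5) as
harvest-loss covariates.

## The models

All models share the record-level linear predictor

    y_ijk = mu + e_j + m_k(j) + g_i + eps_ijk

with trial effects `e_j`, maturity-group-within-trial effects `m_k(j)`
(flat-prior/fixed), the additive genetic value `g_i` of accession `i`, and
iid normal residuals. The genetic term is modelled three ways:

* **G-BLUP** — `g ~ MVN(0, G sigma2_g)` with the per-marker-standardized
  genomic relationship matrix
  `G_ii' = p^-1 sum_l (x_il - 2 theta_l)(x_i'l - 2 theta_l) / (2 theta_l (1 - theta_l))`;
  the shrinkage ratio `lambda = sigma2_e / sigma2_g` is estimated by REML,
  profiled on the eigendecomposition of the record-mapped `G`, and the BLUP
  is computed by the inversion-free form `G Z'(Z G Z' + lambda I)^-1 y_adj`.
* **Bayes B** — marker effects from the mixture
  `pi * delta_0 + (1 - pi) * N(0, sigma2_bl)`, scaled inverse chi-squared
  priors on the per-marker variances, a beta prior on the null proportion
  `pi`; Gibbs sampling with per-marker inclusion indicators (compiled in
  C++).
* **Bayesian LASSO** — double-exponential marginal prior via iid exponential
  marker variances, with the standard inverse-Gaussian / gamma augmentation
  updates.

Around the models the package provides marker QC (missingness > 0.80 or
MAF < 0.01 removed), mean imputation, phenotype adjustment for trial and MG
effects (optionally lodging/shattering covariates), entry-mean heritability,
four cross-validation schemes (One/Group, One/All, Group/All, Group/Group)
over trial, state or genetic-cluster groupings with a strict leakage rule —
every record of a validation accession is removed from training — Pearson
predictive ability with 10,000-replicate bootstrap CIs, top-10 % selection
enrichment, and a synthetic collection generator (Balding–Nichols cluster
structure, fully inbred dosages, MG-banded trial design, penalty-linked
lodging/shattering) so the whole pipeline runs without any external data.

## Worked example

```r
library(germpred)

col <- simulate_collection(sim_config(n_accessions = 800, p_markers = 800,
                                      n_trials = 10, seed = 1))
geno <- impute_missing(filter_markers(col$genotypes)$genotypes)
K    <- compute_grm(geno)
mean(diag(K$G))
#> [1] 2                 # fully inbred panel: diagonal ~ 1 + F = 2

grouping <- cv_grouping(col$phenotypes, "trial")
report <- run_scheme("group_all", grouping, col$phenotypes,
                     wgr_spec("gblup", trait = "oil"),
                     kinship = K, boot_reps = 2000, seed = 1)
glance(report)
#> # A tibble: 1 × 8
#>   scheme    criterion n_groups n_defined mean_r median_r min_r max_r
#>   <chr>     <chr>        <int>     <int>  <dbl>    <dbl> <dbl> <dbl>
#> 1 group_all trial           10        10  0.469    0.478 0.348 0.553
```

`mean_r` is the average predictive ability: the Pearson correlation, within
each left-out trial, between genomic predictions and phenotypes adjusted for
trial and MG effects. Selecting the top 10 % of accessions per trial on
these predictions:

```r
enrichment_by_group(report) |> tail(1)
#> # A tibble: 1 × 4
#>   group n_selected pct_gt_mean pct_bottom
#>   <chr>      <dbl>       <dbl>      <dbl>
#> 1 Mean          96        85.4          0
```

— on average 85 % of the selected accessions beat their trial mean for oil
and none fall in the observed bottom decile, which is the practical payoff
of genomic selection on a collection.

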