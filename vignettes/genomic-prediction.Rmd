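---
title: "Genomic prediction for germplasm collections: models, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction for germplasm collections: models, design and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germpred)
```

## The problem

A germplasm collection is phenotyped opportunistically: different accessions
are grown in different trials, in different states, in different decades,
and trials are blocked by maturity group (MG) because a late-maturing
soybean cannot be evaluated meaningfully in a northern state. The question
this package answers is whether genome-wide markers plus those heterogeneous
historical records are enough to rank accessions on genetic merit — and how
the composition of the training set (same trial, same state, same genetic
cluster, or everything available) changes the answer.

## The linear predictor and its pieces

Every model works on record-level data

$$y_{ijk} = \mu + e_j + m_{k(j)} + g_i + \varepsilon_{ijk},$$

where $e_j$ is the effect of trial $j$, $m_{k(j)}$ the effect of maturity
group $k$ nested in trial $j$, $g_i$ the additive genetic value of accession
$i$, and $\varepsilon_{ijk} \sim N(0, \sigma^2_\varepsilon)$ iid. MG effects
are nested because maturity adaptation depends on trial latitude — MG III
means something different in Minnesota and Mississippi. Trial and MG effects
are treated as ordinary fixed effects (flat priors in the samplers);
identifiability uses sum-to-zero constraints, a choice that cannot affect
anything downstream because only the *adjusted* phenotypes
$\tilde y = y - \hat e_j - \hat m_{k(j)}$ are consumed.

An accession evaluated in several trials contributes several records to one
$g_i$ through an incidence mapping; this holds in all three models.

### Genomic relationship matrix

`compute_grm()` evaluates

$$G_{ii'} = \frac1p \sum_{l=1}^p
  \frac{(x_{il} - 2\theta_l)(x_{i'l} - 2\theta_l)}{2\theta_l(1-\theta_l)},$$

the per-marker-standardized form: each marker is centered at its mean dosage
$2\theta_l$ and scaled by its binomial variance before averaging, so rare
and common markers contribute equally (this is *not* the pooled
$\sum 2\theta(1-\theta)$ variant). Two exact identities make good tests and
are asserted in the suite: with in-sample $\theta$ every row of $G$ sums to
zero, and $G = WW'/p$ for the standardized score matrix $W$, which makes
G-BLUP algebraically identical to ridge regression on $W$ with penalty
$\lambda p$. For a fully inbred panel the expected diagonal is
$1 + F = 2$; an outbred Hardy–Weinberg simulation mode exists purely to
check that the diagonal drops to 1.

Markers are filtered before any of this: missingness strictly greater than
0.80 or MAF strictly below 0.01 removes a marker (boundary values are
kept — the literal reading of the rule), and remaining missing calls are
imputed to the marker mean $2\theta_l$, which preserves $\theta$ exactly.
The allele frequency used by the GRM is frozen at imputation time so a
single definition of $\theta$ flows through the pipeline.

### G-BLUP

With $g \sim MVN(0, G\sigma^2_g)$ the BLUP is
$\hat g = [I + \lambda G^{-1}]^{-1}\tilde y$ where
$\lambda = \sigma^2_\varepsilon/\sigma^2_g$. The implementation uses the
equivalent inversion-free form
$\hat g = G Z'(Z G Z' + \lambda I)^{-1}(y - F\hat\alpha)$, which is defined
for singular $G$ (no jitter is ever added) and yields predictions for new
accessions by the same weight vector: $\hat g_{new} = G_{no}\,v$. REML for
$\lambda$ profiles the restricted likelihood on the eigendecomposition of
the record-mapped relationship matrix $ZGZ'$, so each candidate $\lambda$
costs $O(Nq^2)$ after one $O(N^3)$ decomposition; the 1-D maximization runs
to tolerance $10^{-8}$ on $\log\lambda \in [-12, 12]$.

Two fitting paths exist and matter. The *joint* path (give `fit_gblup()` the
raw record table) estimates fixed effects and $g$ together, exactly as the
linear predictor is written. The *two-stage* path (adjust first, then fit on
per-accession means) is what the cross-validation engine uses, because it
makes the validation observations — adjusted phenotypes — explicit and
identical across models. The difference matters for variance components at
small cell sizes: with only a few records per (trial, MG) cell, estimated
cell means absorb genuine genetic variance (MG correlates with genetic
cluster in any structured collection), and a two-stage heritability estimate
is biased down. Parameter-recovery checks therefore use the joint fit.

Reported genomic heritability is
$\hat\sigma^2_g \cdot \overline{G_{ii}} / (\hat\sigma^2_g \cdot
\overline{G_{ii}} + \hat\sigma^2_\varepsilon)$: the genomic variance of an
accession under this GRM is $\sigma^2_g G_{ii}$, and with
$\overline{G_{ii}} \approx 2$ on inbreds the naive ratio would
underestimate badly.

### Bayes B and the Bayesian LASSO

Both marker models regress on dosages centered by $2\theta_l$, so an
accession sitting at the training mean for every marker predicts exactly
$\mu$ — the centering constant is absorbed into the intercept and
predictions are reported on the trait scale as
$\mu + \sum_l (x_{il} - 2\theta_l)\hat b_l$.

Bayes B places the spike-and-slab prior
$p(b_l) = \pi\,\delta_0 + (1-\pi)\,N(0, \sigma^2_{b_l})$ with
$\sigma^2_{b_l} \sim \chi^{-2}(df_b, S_b)$ and a beta prior on $\pi$. The
beta prior's published notation is ambiguous about its parameterization; it
is resolved here as mean $\pi_0$ and concentration $p_0$
(`shape1 = pi0*p0`, `shape2 = (1-pi0)*p0`), defaults $\pi_0 = 0.5$,
$p_0 = 10$ — weakly informative, letting the data decide sparsity. The
sampler draws each inclusion indicator from its marginal odds (with $b_l$
integrated out), then the effect from its conjugate slab, then the marker
variance, $\pi$, and $\sigma^2_\varepsilon$.

The Bayesian LASSO uses $b_l \mid \tau^2_l \sim N(0, \tau^2_l
\sigma^2_\varepsilon)$ with $\tau^2_l$ iid exponential, giving the double
exponential marginal; updates are the standard inverse-Gaussian draw for
$1/\tau^2_l$ and a gamma draw for the regularization parameter $\lambda^2$.

Hyperparameters follow a variance-partition rule with prior $R^2 = 0.5$:
$df_\varepsilon = 5$ and $S_\varepsilon$ chosen so the prior mode of
$\sigma^2_\varepsilon$ is $(1-R^2)\,\mathrm{var}(\tilde y)$; for Bayes B,
$S_b$ matched so the slab mode is
$R^2\,\mathrm{var}(\tilde y)/((1-\pi_0)\,MS_x)$ with
$MS_x = \sum_l 2\theta_l(1-\theta_l)$; for the LASSO the prior mode of
$\lambda^2$ is $2\,MS_x\,(1-R^2)/R^2$. All are overridable in `wgr_spec()`.
Scaled inverse chi-squared is parameterized so that $\chi^{-2}(df, S)$ is
sampled as $S/\chi^2_{df}$ with prior mode $S/(df+2)$.

Both samplers are compiled (RcppArmadillo), use R's RNG so a seed makes runs
bit-identical, and default to 12,000 iterations, 2,000 burn-in, thinning 5.
The test suite uses shorter chains sized to its small problems; mixing is
unproblematic there because single-site updates of weakly correlated
markers mix fast at $n$ in the hundreds.

## Cross-validation design

Groupings: by trial, by state, or by genetic cluster (accessions assigned by
maximum membership probability, ties to the lowest index; the number of
clusters for an external ancestry run would be chosen where the CV-error
improvement plateaus, `select_k_plateau()`). Four schemes, all mimicking the
prediction of accessions with no data:

* **One/Group** — within each group, accessions predicted from the rest of
  the same group;
* **One/All** — same validation folds, training on all groups;
* **Group/All** — each whole group predicted from all other groups;
* **Group/Group** — every ordered pair: train on one group, validate on
  another.

The leakage rule is absolute and asserted per fold: every record of every
validation accession is removed from training (an accession grown in two
trials disappears from both). Leave-one-accession-out is executed as
accession-level k-fold (default 10) — thousands of refits per scheme would
add nothing statistically — with exact LOO available by raising `folds` to
the group size.

Validation observations are adjusted phenotypes aggregated per accession
*within the scored group*, with the adjustment design fitted on all records
of the trait. Adjusting validation data with training-only effect estimates
was considered and rejected: the adjustment is a preprocessing of
observations, predictions never feed into it, and all-data adjustment keeps
the observation vector identical across schemes so their abilities are
comparable. Fold predictions are compiled as genomic value plus the all-data
intercept; a fold-specific intercept would add noise that is exactly
anti-correlated with the held-out fold mean (in a small group where REML
finds no genetic signal, predictions would collapse to training means and
the compiled correlation to $-1$), while the within-group Pearson
correlation is invariant to any common shift.

Predictive ability is the plain Pearson correlation — deliberately *not*
divided by $\sqrt{h^2}$, so it is a conservative lower bound on accuracy
against true breeding values. Confidence intervals are percentile bootstrap
(10,000 paired resamples by default; percentile rather than BCa for
determinism and simplicity), with degenerate resamples redrawn and counted.

Enrichment takes the top `top_frac` (default 10 %) of accessions by
prediction, ties broken by stable order, and reports the share observed
above the group mean and the share at or below the empirical `top_frac`
quantile (type 7, ties included). It is computed per trial on raw
(uncorrected) values by default — a breeder selecting for machine-harvest
yield wants exactly the raw trait.

## The synthetic collection

The generator exists so every stage runs and is testable with no download.
What it emulates, and the defaults chosen:

* **Structure** — 9 clusters of fully inbred lines ($x \in \{0, 2\}$) under
  a Balding–Nichols model: ancestral frequencies Uniform(0.05, 0.95),
  cluster frequencies Beta-distributed around them with differentiation
  $F_{st} = 0.15$ (moderate differentiation, typical of distinct landrace
  groups), cluster-dominant Dirichlet admixture emitted as a membership
  table.
* **Trial design** — 25 trials in 3 states by default; states occupy
  overlapping maturity bands (early MGs north, late MGs south), MG is drawn
  around cluster-specific means so structure and maturity are confounded as
  they are in a real collection; 85 % of accessions are evaluated in one
  trial, 15 % in two.
* **Traits** — oil, protein (record-level $h^2$ 0.6) and yield ($h^2$ 0.4),
  simulated on a standardized scale (trial effects SD 0.5, MG-in-trial SD
  0.3, trial-by-accession G×E SD 0.2) and mapped to field units (oil 19.5 %
  ± 1.2, protein 41 % ± 1.8, yield 2.5 Mg/ha ± 0.45). Marker effects are
  infinitesimal by default or confined to `n_qtl` markers, rescaled so the
  realized genetic variance matches $h^2$ exactly in sample.
* **Harvest losses** — lodging and shattering arise from heritable latent
  scores (latent $h^2$ 0.8 — harvest-loss traits are genetically much
  simpler than yield, which is what makes raw machine-harvest yield
  prediction partly score prediction) cut into five equiprobable classes (the observed scale is 1–5 and
  nothing more is specified by the data-generating tradition, so
  equiprobable thresholds are the neutral choice). Machine-harvest yield is
  yield potential minus $\gamma_L(\text{lodging}-1) +
  \gamma_S(\text{shattering}-1)$ plus residual noise; the defaults
  $\gamma_L = 0.165$, $\gamma_S = 0.21$ were calibrated once so pooled
  within-trial correlations of yield with the two scores land near $-0.21$
  and $-0.27$.

What it does **not** emulate: linkage disequilibrium (markers are
independent given cluster frequencies, so marker-density effects and
LD-decay across clusters are absent), pedigree relatedness within cluster,
year effects, spatial field trend, genotype-by-year interaction, and
selection history. Passing tests on this generator therefore demonstrate
that the estimators and the CV machinery are correct and well-calibrated
under the assumed model — not that any particular predictive ability will
be attained on real collection data, where LD structure typically helps
and heterogeneous data quality hurts.

## Numerical choices and degenerate inputs

* Monomorphic markers make the GRM denominator zero and raise an error
  naming the marker — MAF filtering is the supported path.
* All-missing markers are removed by the missingness rule; imputing one is
  an error.
* Eigenvalues of $ZGZ'$ are clipped at zero before adding $\lambda$;
  $\lambda$ itself is searched on $[-12, 12]$ in log space, covering
  effectively-zero to effectively-infinite shrinkage.
* Validation groups with fewer than 3 accessions, or zero variance on
  either side, report `NA` ability with the group's counts rather than
  failing the whole scheme.
* Divergent chains (non-finite residual variance) abort with the iteration
  index.
* `entry_mean_heritability()` uses REML (lme4) and falls back to the
  method-of-moments ANOVA estimator when the REML fit degenerates (e.g.
  zero residual variance); negative component estimates truncate at zero.

## Problem sizes

The shipped tests and the acceptance script run at deliberately desk-scale
sizes — collections of 250–1000 accessions, 200–2000 markers, 5–25 trials,
bootstrap coverage at 200×2000 resamples — chosen so the whole suite
completes in a few minutes while every statistical claim retains enough
replication to be meaningful. All sizes scale up by configuration only.
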