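---
title: "Models and methods for paired two-timepoint transcriptome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for paired two-timepoint transcriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longage)
```

## Setting

`longage` analyses cohorts in which the same individuals are RNA-sequenced
at two ages (the motivating design is whole blood at ages 70 and 80, 65
individuals, 130 samples). The paired structure changes almost every
statistical step: expression comparisons become within-individual
contrasts, QTL scans can be replicated across ages within the same people,
heritability becomes a bivariate problem with a cross-age genetic
correlation, and allele-specific expression can be compared within an
individual's own heterozygous sites. The package implements each stage and
a synthetic-cohort generator that emulates all the required inputs, so the
entire pipeline is testable end to end without controlled-access genotype
or sequence data.

Age is coded 0/1 (0 = first age, 1 = second) in every model.

## The synthetic cohort

`sim_config()` fixes the study conditions; `simulate_cohort()` draws one
cohort. The generator's defaults are the cohort the analyses assume:

* 65 individuals, each with exactly two samples;
* cis-heritabilities averaging 0.18 / 0.17 at the two ages with cross-age
  genetic correlation 0.96, realized through a shared causal SNP (weight
  $\sqrt{\rho_g}$) and age-specific causal SNPs (weight $\sqrt{1-\rho_g}$)
  among the ~20 simulated cis SNPs per gene, drawn under Hardy–Weinberg
  equilibrium at MAFs uniform on [0.05, 0.5]. Per-gene heritability is the
  per-age mean times a unit-mean Gamma(1.2) multiplier (capped at 0.8):
  real cis-h² distributions are strongly right-skewed, and it is that
  upper tail that supplies discoverable eGenes at n = 63;
* 8% of genes differentially expressed, effect magnitude 0.5 on the log2
  scale. (The real study's per-gene age effects are weaker — age explained
  about 1.5% of expression variance there — but at desk-scale gene counts
  a 0.5 log2 effect gives the power regime in which the machinery, rather
  than the sample size, is being exercised.)
* a compound-symmetric individual random effect (30% of latent variance),
  hidden technical factors (10%) of which the first is correlated with age
  at −0.46, emulating the RIN/concentration confounding reported for
  cohorts of this design, and negative-binomial read noise with lognormal
  gene-level dispersions around median 0.1;
* beta-binomial allele-specific counts with latent phase
  $\phi_i \in \{-1,+1\}$ (prior 0.5), concentration 50, lognormal depths,
  and a global 2.7% inflation of logit-scale allelic effects at the later
  age (the study's observed median allelic-imbalance increase);
* Dirichlet-multinomial intron-cluster counts (concentration 30, totals
  lognormal around 150), with 5% of clusters shifting the first intron's
  usage by 0.8 logit units with age.

What the generator deliberately does **not** emulate: read-level
artefacts (mapping bias, GC effects), linkage disequilibrium between cis
SNPs, multi-tissue structure, non-linear age trajectories, and library
batch structure beyond the hidden factors. Tests passing on this
generator therefore demonstrate the correctness and calibration of the
statistical machinery under its stated model, not robustness to every
failure mode of real sequencing data.

Determinism: the full cohort is a deterministic function of the
configuration, including its seed; the pipeline derives per-stage child
seeds as `(seed * 101 + stage index) mod (2^31 - 1)`.

## Preprocessing

Genes are kept when, within each age separately, the mean count is at
least 5 and no more than 20% of individuals have a zero count. The
zero-count rule is evaluated per age (pooling ages is the other defensible
reading; per age is stricter and symmetric). Normalization is
median-of-ratios size factors followed by `log2(x + 1)`; a `transform`
hook accepts a variance-stabilizing alternative, and downstream models are
transform-robust in the sense that all of them act on the normalized
matrix, whatever produced it.

The number of hidden factors is estimated by permutation parallel
analysis: the matrix is residualized on age and measured covariates, rows
standardized, and the singular-value variance shares compared with B = 20
row-wise permutations at α = 0.05; the count is the leading run of
components exceeding the permutation 95th percentile. Stopping at the
first non-significant component keeps the null calibration clean (counting
all significant components individually inflates the count by ~α per
component). Factor extraction itself delegates to surrogate variable
analysis (`sva`); by default the factors may correlate with age, matching
the analysis design this package targets, and `protect_age = TRUE`
residualizes them on age instead.

Sample-clustering concordance is the fraction of samples whose sibling
branch at their first merge in the complete-linkage, Euclidean-distance
dendrogram contains their same-individual other-age sample. When the
sibling branch has several leaves they are all cophenetically equidistant,
so membership of the pair in the sibling set is the exact
"nearest dendrogram neighbour" criterion.

## Differential expression

Each gene is fit with a paired linear mixed model: age (fixed) +
hidden factors and measured covariates (fixed) + individual (random
intercept). Because every individual contributes exactly one sample per
age, the model is solved by an orthonormal within-pair rotation into
independent "sum" and "difference" rows with two variance components
$\sigma^2(1\pm\rho)$; REML profiles the intra-class correlation on
$(-1+\varepsilon, 1-\varepsilon)$ (tolerance 1e-10) and the solution is
polished by Fisher scoring on the two rotated variances until the REML
score vanishes. This exactness matters: without covariates the fit
reproduces the paired t-test to machine precision, with Satterthwaite
denominator degrees of freedom n − 1, and the test suite holds it to that
oracle at 1e-8. Satterthwaite df come from the REML information of the
two variance components via the delta method on
$\mathrm{Var}(\hat\beta_{\mathrm{age}})$.

Multiplicity uses Storey q-values: $\pi_0$ estimated on the λ-grid
0.05–0.95 (step 0.05) with a cubic smoothing spline extrapolated to
λ = 1; with $\pi_0$ pinned to 1 the q-values equal Benjamini–Hochberg
adjusted p-values exactly.

Variance explained by age is a semi-partial R²: expression is centered
within individual, and the drop in residual sum of squares from adding age
to the covariate-only model is divided by the total centered variance.
The estimator is one of several defensible choices (the quantity is
under-determined by a verbal description alone); it is labelled as such in
the output.

Age-trajectory outliers: per gene, within-individual changes
$\Delta = E_{80} - E_{70}$ are compared with fences
$(Q_1 - 3\,\mathrm{IQR},\ Q_3 + 3\,\mathrm{IQR})$ using type-7
(linear-interpolation) quantiles. By default the scan runs on
hidden-factor-corrected values restricted to individuals that pass
clustering concordance; with fewer than 10 such individuals the fences are
unstable and the pipeline falls back to the full cohort.

## cis-QTL mapping and cross-age stability

Phenotype and genotype are residualized on covariates, then each
phenotype–SNP pair within the cis window (1 Mb of the TSS for expression,
100 kb for intron usage) is tested by OLS with t degrees of freedom
n − k − 2, the convention that counts the k projected-out covariates.
Gene-level evidence is Simes' rule over the pair p-values. The two-level
hierarchy is Benjamini–Hochberg on Simes p-values at the phenotype level,
then within-phenotype BH at `q_within · R/M` (the selected-fraction budget
adjustment); plain within-family BH is available by flag since the choice
of level-2 budget is a policy, not a theorem, at this package's scale.

The pipeline's eQTL stage selects, separately for each age, the number of
leading hidden factors (grid 0, 5, 10, 15) that maximizes eGene discovery
at the 1% hierarchical FDR — correcting for too many pooled factors costs
residual degrees of freedom and can absorb genetic signal, and the
discovery-maximizing count is the natural per-age operating point for
this design.

Cross-age stability uses three instruments: a two-step replication FDR
(discover at 1%, re-test the discovered set in the other age at 10%), an
exact McNemar test on the discordant discovery flags
($OR = c/b$, $p = 2P(\mathrm{Bin}(b+c, 1/2) \le \min(b,c))$ capped at 1),
and the Spearman correlation of per-phenotype top-SNP effects.

## cis-heritability

The GRM is $Z Z^\top / m$ over standardized cis dosages. Univariate REML
profiles $h^2$ on the GRM eigenbasis (1-D bounded optimization, tolerance
1e-10, SE from the observed information of the profile). Internally $h^2$
is clamped to $[10^{-6}, 1-10^{-6}]$ and boundary estimates are flagged;
the clamped estimator is necessarily positively biased at $h^2 = 0$, so
bias assessments in the tests pass unconstrained bounds through the
`bounds` argument. The bivariate model has six parameters (two genetic
and two residual variances, genetic and residual cross-age correlations),
optimized by BFGS on log-variances and atanh-correlations using the
shared eigenbasis for O(n) likelihood evaluations, with random restarts.

The heritability-by-age trend is a maximum-likelihood beta regression
with logit mean link and common precision,
$\mathrm{logit}(h^2) = \alpha + \beta\,\mathrm{age}$, optionally weighted
by inverse squared standard errors normalized to mean 1. The pipeline
floors the SEs at 0.05 before weighting because boundary fits report
near-zero SEs that would otherwise dominate the fit. The paired Wilcoxon
test of $h^2_{80} - h^2_{70}$ uses the exact sign-permutation distribution
(subset-sum convolution over doubled midranks, so ties are exact) for up
to 25 non-zero differences and the tie-corrected normal approximation
beyond.

## Allele-specific expression

Filters: records with reference proportion outside [0.1, 0.9] are removed
(mono-allelic or error-dominated sites; the rule is stated disjunctively
in some descriptions, which is vacuous — the interval reading is the
operative one). Depth thresholds per analysis: 100 reads at each age
(global AI and cross-age correlation), 50 (individual-level tests), 20 in
at least 20 heterozygous individuals (population-level tests).

Global allelic imbalance: per individual, the per-age median of
$\phi = |\pi - 0.5|$ across qualifying sites and the ratio
$\phi^{80}/\phi^{70}$; the increase-with-age test is a one-sided
signed-rank test of the log ratios against zero.

The local models treat the phase between the unobserved cis-regulatory
variant and the measured exonic site as a latent sign:

$$y_{it} \sim \mathrm{BB}\big(n_{it},\ \sigma(\phi_i \beta_t + u_i),\ c\big),
\qquad \phi_i \in \{-1, +1\},\ u_i \sim N(0, v),$$

with $\beta_t = b_0 + b_1 \mathbf{1}[t = 80]$ and the likelihood-ratio
test on $b_1$ (1 df). The marginal likelihood sums over $\phi_i$ with a
learned prior; it is exactly invariant to relabelling ref/alt alleles.
The concentration $c$ carries a Gamma(1.0001, 1e-4) prior (MAP).

*Individual-level* tests have only two observations per unit, which
cannot identify $c$; a free $c$ makes the LRT grossly anticonservative.
The scan therefore learns $c$ per site by pooling the other heterozygous
individuals (leave-one-out, so a genuinely differential individual does
not inflate the dispersion it is tested against) and tests each
individual with $c$ fixed. Under this scheme the null LRT is calibrated
(checked against uniformity at c = 50).

*Population-level* tests include the per-individual random effect $u_i$
and are fit by variational Bayes EM: Gaussian posteriors per $u_i$
(expectations by 20-node Gauss–Hermite quadrature), exact discrete
updates per $\phi_i$, closed-form M-steps for the phase prior and $v$,
and accept-if-improve quasi-Newton M-steps for $\beta$ and $c$. Every
update maximizes the same evidence lower bound, so the ELBO is
non-decreasing by construction (asserted at every iteration in the test
suite); convergence is declared at an ELBO change below 1e-8 (at most
500 iterations). On small instances the ELBO sits within half a nat of
an exact quadrature evaluation of the marginal likelihood.

## Alternative splicing

Intron clusters are filtered in sequence: more than 10 introns → drop;
an intron is active when it carries ≥ 10% of its cluster's reads in
≥ 25% of samples, each age evaluated separately (an intron must qualify
at both ages); fewer than 2 active introns → drop; mean-over-samples
Hellinger distance between each sample's usage vector and the cluster
mean below 1% → drop (the maximum over samples is available by flag; the
mean is the default because a single outlying sample should not rescue an
otherwise invariant cluster).

Differential splicing is a Dirichlet-multinomial GLM per cluster:
softmax-linked per-intron linear predictors with intercepts, age
coefficients (alternative model) and per-intron covariate coefficients,
the last intron fixed at zero for identifiability, and one cluster-level
concentration (capped at $e^{15}$, beyond which the DM is numerically
indistinguishable from its multinomial limit and the log-gamma difference
terms lose all precision). The LRT has (active introns − 1) df. Covariates
enter standardized (a pure optimizer conditioning step; the likelihood is
unchanged). The paired structure is deliberately not modelled here — the
DM GLM treats samples as independent given covariates — and that is a
known statistical limitation of this stage. Gene-level evidence is Simes
over the gene's clusters, with the same two-level FDR machinery as the
QTL stage at 5%/5%. sQTL mapping reuses `map_cis_qtl` on (optionally
rank-normalized) usage ratios with a 100 kb window.

## Pipeline and reporting

`run_pipeline()` executes the stages in dependency order with per-stage
child seeds, returns a manifest (config snapshot, seeds, stage statuses,
summary metrics, file checksums), and `acceptance_report()` tabulates
false-discovery proportions, power, and parameter recovery against the
planted truth. Problem sizes in the shipped tests and in
`scripts/acceptance.R` are desk-scale (hundreds of genes, tens of
clusters, 100-gene heritability scans, 20–25 sites in the VB-EM scan):
large enough to exercise every code path and the calibration claims,
small enough to re-run routinely. The global-AI power check uses a cohort
of 5000 sites (~500–700 qualifying per individual), the per-individual
median precision implied by the study's reported test sensitivity.

## Known limitations

* The DM GLM ignores the pairing of samples within individuals.
* The VB-EM reports a lower bound, not the exact marginal likelihood;
  LRT p-values at the population level inherit that approximation.
* The constrained univariate REML estimator is positively biased near
  $h^2 = 0$; use unconstrained bounds when bias matters.
* The surrogate-variable step follows the `sva` implementation, not any
  particular re-derivation of it; factor counts on real data depend on
  that choice.
* The generator plants single-SNP genetic architectures without LD;
  fine-mapping behaviour is out of scope.
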