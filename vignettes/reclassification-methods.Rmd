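---
title: "Genotype-driven reclassification: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-driven reclassification: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snplca)
```

## The problem

Complex diseases such as Crohn's disease are clinically heterogeneous, yet the
standard subphenotyping schemes (location, behavior, age at onset) map poorly
onto genetic risk. snplca implements the opposite direction: it asks whether a
panel of disease-associated SNPs, by itself, partitions a patient cohort into
molecular subgroups — and only afterwards asks whether those subgroups relate
to the clinical labels. The same machinery is run on healthy controls as a
negative control: if the patient clusters were generic population structure,
the controls should produce the same ones.

## The latent class model

Genotypes are additively coded per SNP: 0 (major-allele homozygote),
1 (heterozygote), 2 (minor-allele homozygote), with the minor allele defined
in the *control* group (`orient_to_control_minor()`). A cohort of $n$
individuals over $m$ SNPs is modelled as a finite mixture of $K$ latent
classes: class $k$ has weight $\pi_k$ and, independently at each SNP $j$, a
category distribution $\theta_{kjg}$ over $g \in \{0,1,2\}$. The likelihood of
individual $i$ is

$$ L_i = \sum_{k=1}^{K} \pi_k \prod_{j \in \mathrm{obs}(i)} \theta_{k j g_{ij}}, $$

where the product runs over the individual's *observed* genotypes only:
missing calls are marginalised out (a missing-at-random assumption), so every
individual — including those with missing genotypes — contributes to the fit,
and an individual with no observed genotypes contributes
$\log \sum_k \pi_k = 0$.

`lca_fit()` maximises this by EM. The E-step computes responsibilities by
Bayes' rule over observed entries; the M-step sets $\pi_k$ to mean
responsibility and $\theta_{kj\cdot}$ to responsibility-weighted category
frequencies among individuals observed at SNP $j$. All per-individual
products are accumulated in log space (46 SNPs would underflow otherwise);
the inner loop is compiled (RcppArmadillo), making a $K=6$ fit on an
875 × 46 cohort a sub-second operation.

Numerical choices:

* **Initialisation.** Two start families, `n_starts = 20` in total by
  default. Half are random responsibility matrices with Dirichlet(1,…,1)
  rows; half are *genotype-exemplar* starts — `k` individuals are chosen by a
  farthest-point (k-means++-like) rule on genotype agreement, and everyone is
  softly assigned by agreement with them. Exemplar starts locate
  block-structured classes (including small ones) far more reliably than
  random responsibilities: on a 6-class, 875 × 46 cohort, six mixed starts
  match a 30-start random-only fit to within a few log-likelihood units,
  where random-only starts can lag by over 100. Starts run in an emEM-style
  schedule — a short EM burst each, then the most promising are run to
  convergence — with survivors chosen *per family*, because exemplar starts
  converge faster and would otherwise crowd out slower random starts heading
  to better optima. Deterministic given `seed`, and computed in a canonical
  row/column order so the result cannot depend on how the input file happened
  to be sorted.
* **Convergence.** Relative log-likelihood change below `tol = 1e-8`, cap
  2000 iterations. The monotonicity of EM is asserted in the test suite on
  every fit.
* **Smoothing.** `eps = 1e-10` is added to M-step category counts so no
  fitted probability is exactly zero; without it, bootstrap replicates can
  otherwise hit $-\infty$ likelihoods on categories unseen in the original
  sample.
* **Ties.** Hard assignment takes the posterior argmax, ties broken toward
  the lowest class index.

Continuous covariates (which general latent-class software also accepts) are
out of scope: every input here is a 3-category genotype.

## How many classes? The parametric bootstrap LRT

`select_num_classes()` steps $k = 1, 2, \dots$ and tests $k$ vs $k+1$ classes
with `bootstrap_lrt()`, stopping at the first non-significant test
($\alpha = 0.05$). Because the null hypothesis lies on the boundary of the
parameter space, the usual $\chi^2$ asymptotics fail; the reference
distribution is instead simulated: each of `B = 20` replicates draws $n$
individuals from the *fitted null model*, re-imposes missing calls per SNP at
the original per-SNP rates (missing-completely-at-random), refits both models,
and records its LR statistic. The p-value is the add-one estimator
$(1 + \#\{LR_b \ge LR_{obs}\})/(B+1)$, so its smallest attainable value with
$B = 20$ is $1/21 \approx 0.048$ — just under the default $\alpha$, meaning a
rejection requires the observed statistic to exceed *every* replicate.

Three choices deserve emphasis:

* **"Bootstrap" means parametric here.** Replicates are draws under the
  fitted null hypothesis, not resamples of individuals; that is what makes
  the test a null-calibrated LRT rather than a variance estimate.
* **Symmetric optimization budgets.** Observed data and replicates are fitted
  with the *same* multi-start budget (`boot_n_starts = n_starts` by default),
  and the $k{+}1$ fit additionally seeds candidate starts by splitting each
  class of the fitted $k$-class model, on observed and replicate data alike.
  We found the tempting economy of cheaper replicate refits to be
  anti-conservative: with 46 SNPs the $k{+}1$-class fit on the observed data,
  given more starts, finds systematically larger spurious improvements than
  the replicates it is compared against, and the selection then overshoots
  the true $k$. A cheaper replicate budget remains available as an explicit
  argument, with this caveat documented.
* **Replicates carry parameter uncertainty.** Each replicate's generating
  parameters are drawn from the Dirichlet posterior implied by the null
  model's responsibility-weighted counts (Jeffreys 1/2 prior), not fixed at
  the point estimate. With ~460 parameters fitted to a few hundred
  individuals, plug-in replicates are visibly too tame: on a planted 5-class,
  367-individual, 46-SNP cohort we measured the true-data LR distribution at
  median 129 (range 112–150 over 20 draws) against a plug-in replicate
  distribution at median 119 (max 131) — so the observed statistic beat every
  one of 20 plug-in replicates about a quarter of the time even though the
  null was true. Posterior-drawn replicates reproduce the true distribution
  (median 129, range 115–154) and restore the nominal rejection rate.
  `replicate_params = "plugin"` gives the classical behavior.

`cluster_flow()` cross-tabulates assignments between the successive models
$k$ and $k+1$, reproducing both models' cluster sizes as its margins;
`autoplot()` renders the familiar band diagram.

## Explaining clusters: trees and forests

`grow_tree()` re-derives the clusters from individual SNPs with CART-style
recursive partitioning: genotypes are *unordered* categories, every split
sends a subset of {0,1,2} left (all three bipartitions are searched
exhaustively — exactness is cheap with three categories), and the split
maximising the count-weighted Gini impurity decrease wins. A split must
reduce impurity by at least `cp = 0.01` of the root impurity and nodes below
`min_split = 20` are not split — common CART practice. There are deliberately
**no surrogate splits**: an individual missing the genotype at a decision SNP
is *unallocated* (`drop_down()`), because the unallocated count — individuals
a SNP-rule cannot place — is itself a reported quantity of the analysis
(`drop_down_report()`). During growth, individuals missing at the evaluated
SNP are excluded from that split's evaluation and take no further part in the
branch.

`fit_forest()` (Breiman–Cutler random forest via the randomForest package)
asks the complementary question — can *clinical* variables predict the
genetic clusters? It reports the out-of-bag error and both importance
measures (raw permutation mean decrease in accuracy, and mean decrease in
Gini impurity), which need not agree; their disagreement on clinical
predictors is itself informative.

## Comparing case and control geometry

`fit_cda()` performs canonical discriminant analysis on the coded genotypes
with cluster labels as groups: the generalized eigenproblem of between-group
vs within-group scatter. Missing genotypes are mean-imputed per SNP *for this
analysis only* (the LCA needs no imputation). Scores are centered at the
derivation-sample mean — canonical means are therefore zero to floating-point
precision (~1e-16, matching the magnitude such software prints) — and scaled
to unit pooled within-group variance, so between-group separation shows up as
total SDs above 1. A ridge of $10^{-8}\,\mathrm{tr}(W)/m$ handles collinear
panels, with a warning.

`project_cda()` applies one group's discriminant rule — centering,
imputation values and coefficients unchanged — to the other group. If the
case clusters reflected generic structure, case-derived axes would separate
control clusters equally well; `manova_wilks()` formalises the comparison of
the projected means with Wilks' lambda (Rao's F, exact for two groups; base
R's `manova` is the engine, and the two-group case is verified against the
Hotelling $T^2$ closed form in the tests). When a group has fewer than three
clusters the discriminant rule has fewer than two axes; the pipeline then
substitutes the leading two principal components of the case genotypes as the
projection rule so the cross-group comparison still runs — a documented
degenerate-path convention, not a claim about the standard analysis.

## Cluster-phenotype association

`two_by_two()` tests one cluster against all others for a binary phenotype:
individuals with missing phenotype are excluded (and counted — necessary to
reproduce published odds ratios from cohort tables with footnoted missing
values), the odds ratio gets a Woolf interval
$\exp(\ln \mathrm{OR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$ (the method that
exactly reproduces the published intervals; Haldane–Anscombe +0.5 on zero
cells), the chi-square is Pearson's without continuity correction, and a
Fisher exact p is added whenever an expected cell count is below 5.
`logistic_backward()` implements the backward-elimination logistic regression
(removal threshold 0.10, the conventional default; the univariate screen the
published analyses describe also used 0.1). No multiple-testing correction is
applied to the association table, deliberately — such exploratory differences
are modest and would not survive correction, which the reporting should make
visible rather than hide; a Bonferroni-adjusted column is trivial to add from
the tidy output.

## The synthetic cohort generator

`simulate_cohort()` draws each individual's class from the group's mixing
proportions, genotypes independently per SNP from the class's category
profile (optionally Hardy–Weinberg from per-class allele frequencies,
`profiles_from_mafs()`), masks calls MCAR at per-SNP rates, and draws binary
phenotypes from class-conditional prevalences (phenotypes are independent of
genotype given class). `paper_scale_design()` is the shipped preset at the
scale of the motivating study: 875 cases in 6 classes with mixing proportions
302/96/62/117/59/239, 367 controls in 5 equal classes, 46 SNPs, 2% missing
calls per SNP, and case phenotype prevalences varying moderately by class.
Each class carries an elevated counted-allele frequency (0.45 vs a 0.10
background) on its own block of SNPs — separation strong enough that the
class structure is recoverable at these sample sizes, while profiles still
overlap. The preset mirrors the *structure* of the real cohort, not its
data: no LD between SNPs, no population stratification, no genotyping-error
model, no informative missingness, and phenotype-class links that are
conditionally independent by construction. Passing tests on this generator
demonstrate correctness of the machinery, not that any real cohort has six
clusters.

Test problem sizes are deliberate: parameter recovery uses a 3-class, 2000
case cohort with near-fixed within-class allele frequencies (0.9 vs 0.05 —
pooled frequency 1/3, still minor overall) so that every category probability
sits far from 1/2 and estimates concentrate well inside the 0.05 sup-norm
asserted; LRT calibration uses 20 independent 500 × 10 null cohorts at the
default B = 20; the end-to-end check runs the full pipeline on the
cohort-scale preset for 10 seeds and requires the planted 6/5 class counts in
at least 8. The 8-of-10 (not 10-of-10) bar reflects two irreducible sources
of miss: the add-one p-value floor of 1/21 sits just under α, so even a
perfectly calibrated step false-rejects with probability ~5% whenever the
observed statistic beats all twenty replicates; and occasional cohort draws
genuinely contain extra-class structure — one of the ten preset seeds
produces a control sample whose 6-class improvement (LR ≈ 173) exceeds the
entire measured true-null LR distribution (102–150), and a correctly
calibrated test rightly rejects there.

## Known limitations

* SNP independence within class is the model; cohorts with strong LD will
  see LD blocks absorbed into extra classes.
* The MCAR missingness treatment (fitting and replicates) is weaker than the
  MAR marginalisation the likelihood tolerates; informative missingness
  (e.g. assay failure correlated with genotype) would bias profiles.
* With B = 20 bootstrap replicates the p-value granularity is 1/21; finer
  decisions near the threshold need a larger B.
* Backward elimination inherits all the usual caveats of stepwise selection;
  it is provided for comparability with the published analysis style, not as
  a recommended inferential tool.
* CDA consumes additively coded genotypes as quantitative variables
  (mean-imputed); an alternative — running it on latent-class membership
  probabilities — is available by passing the membership columns instead, and
  neither is claimed to be canonical.
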