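---
title: "Methods: ROI burden collapsing and case/control modelling"
author: "roiburden authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROI burden collapsing and case/control modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roiburden)
```

## The model

Gene-panel sequencing of a disease cohort yields, per individual, a set of
rare variants. Single-variant association is underpowered at panel scale,
so the package collapses variants into per-individual *mutational load*
scores over four region-of-interest (ROI) axes:

* **genes** — the panel genes themselves;
* **domains** — protein-domain intervals nested in the genes;
* **pathways** — gene sets; a pathway's score collapses variants from all
  member genes;
* **PPI neighbourhoods** — features named by an *interactor* protein,
  collapsing variants from the panel genes that physically interact with
  it. A variant never contributes to a PPI feature named after its own
  gene; the fan-out of a variant in a gene with one overlapping domain,
  two pathway memberships and two interactors is therefore exactly six
  features (1 gene + 1 domain + 2 pathways + 2 PPI).

Each variant allele contributes

$$ v = \sigma \times P \times \left(-\log_{10} \max(F, f_0)\right) $$

where $\sigma \in \{0,1,2\}$ is the allele copy count (zygosity),
$P \in [0,1]$ the predicted deleteriousness of the variant (consumed as an
input annotation column), $F$ its population allele frequency and
$f_0$ a frequency floor. An ROI score is the sum of $v$ over all variants
whose fan-out includes that ROI. The $-\log_{10} F$ weight penalizes
common variants (the contribution is strictly decreasing in $F$ and
vanishes at $F = 1$), while $P$ damps rare-but-tolerated alleles.

Two numerical conventions are ours and are deliberate:

* **Sign and base of the log.** The collapsing rule is stated with
  $\log F$, which is negative for $F < 1$; we report
  $\sigma P(-\log_{10} F) \ge 0$ so that scores grow with rarity. This is
  a strictly monotone relabeling: rank-based tests, AUC and tree
  ensembles are unchanged by it.
* **Frequency floor.** Novel alleles ($F$ missing or 0) have an undefined
  log. We substitute $f_0 = 1/5008$ — one allele among the $2 \times
  2504$ haplotypes of the reference population panel — the usual
  pseudo-frequency for an unobserved allele. It is exposed as
  `scoring_config(freq_floor = )`. Whether to floor or drop such variants
  was an open choice; flooring retains exactly the variants a rare-variant
  analysis cares about most.

Variant-to-gene assignment comes from the annotation table (the upstream
annotator's call), never re-derived from intervals; gene intervals are used
for validation and synthetic data generation only. VCF positions are
1-based, interval files BED-style 0-based half-open; the overlap test
converts accordingly. Variants without a deleteriousness score are dropped
with a logged count.

With four axes there are $2^4 - 1 = 15$ non-empty axis combinations, each
defining one dataset; at the annotation sizes typical for a ~109-gene
panel (129 gene features including isoforms, 252 domains, 130 pathways,
569 interactors) the full combination carries $252+129+130+569 = 1080$
features.

## Univariate association

Each feature is tested case versus control with a normality gate:
Shapiro-Wilk per group at $\alpha = 0.05$ (the gate level is
configurable; no specific normality test was prescribed, Shapiro-Wilk is
the standard small-sample choice), then a two-sided Welch $t$-test when
both groups look Gaussian, otherwise a two-sided Wilcoxon rank-sum test.
Burden scores are zero-inflated and right-skewed, so the rank-sum branch
dominates in practice. Two deliberate interpretations:

* The unpaired **rank-sum (Mann-Whitney)** test is used where a "signed
  rank" test is sometimes named in this setting: the two cohort arms are
  independent samples of different sizes, for which the signed-rank test
  is not defined.
* **Welch** rather than pooled-variance $t$: the arms differ in size and
  provenance, so equal variances are not assumed.

Multiplicity is controlled per axis with Bonferroni
($p_{\mathrm{adj}} = \min(1, m\,p)$, $m$ = features on the axis), because
each axis is reported as its own family; a switch collapses all axes into
one family if wanted. Significant features are assembled into a
containment graph (domain → gene, gene → pathway, gene → PPI) written as
DOT; a significant domain whose owning gene is not significant simply has
no outgoing edge.

## Stochastic feature search

For the multivariate models, features are ranked by posterior inclusion
probability from a Markov-chain Monte-Carlo stochastic search over binary
inclusion vectors (the binary-outcome stochastic search family). The
published interface of that family — prior model size 20 with variance 10,
100 000 iterations with 10 000 burn-in, ranking by inclusion probability —
is kept; its internals are not specified at this level, so the package
fixes a concrete, reproducible and oracle-checkable chain:

* **Model score.** A model (included subset $S$) is scored by the BIC of
  the linear-probability fit of the 0/1 outcome on the standardized
  columns of $S$, used as a marginal-likelihood approximation:
  $\log \pi(S) \propto -\mathrm{BIC}(S)/2 + \log p(|S|)$.
* **Size prior.** Beta-Binomial with the requested mean and variance when
  that pair is feasible; the prior degrades to Binomial when the requested
  variance is below the Binomial's (which happens at the published
  20/10 setting for $d = 1080$: the Binomial variance is already 19.6).
  When the prior mean exceeds the feature count (tuning grids hit small
  axes routinely), the mean is clamped to $\lfloor d/2 \rfloor$ with a
  message rather than refusing to run.
* **Proposals.** Toggle one feature, or swap an included with an excluded
  feature, chosen with equal probability; an infeasible swap (empty or
  full model) is treated as a rejected no-op so the kernel stays symmetric
  at the boundaries — without this the chain would not match exact
  enumeration at small $d$.
* **Degeneracies.** Constant columns are excluded from proposals and
  reported; a singular included subset (e.g. duplicated columns) scores
  $-\infty$ and is never accepted.

Columns are standardized on the rows the search sees (training rows only,
inside cross-validation), making the search scale-invariant. The test
suite checks the chain against exhaustive enumeration of all $2^{10}$
models at $d = 10$, $n = 60$ (maximum marginal error < 0.05), and
bit-reproducibility under a fixed seed.

## Evaluation protocol

Per dataset: repeat 10 times {stratified 70/30 train/test split; 5-fold
stratified cross-validation on the training set over the grid (features
$\in \{5, 10, 25, 50, 100, \text{all}\}$) × (trees
$\in \{5, 10, 50, \dots, 500\}$), with the feature ranking recomputed
inside every fold so validation rows never inform selection; refit on the
whole training set with the winning pair; score the held-out test set with
AUC and MCC}. Random-forest parameters other than tree count stay at
library defaults. Design choices that were genuinely open:

* **CV selection metric**: AUC (MCC is reported alongside and can be
  selected instead); the tuned metric was not named in the protocol's
  source description.
* **Stratification**: splits and folds are stratified because an 85/61
  imbalance makes unstratified 5-fold folds occasionally lose a class.
* **Final refit**: the test-time model uses a whole-training-set ranking
  with the tuned $k$; per-fold rankings exist only to score the grid.
* **"Unselected features"**: implemented as the $k=\text{all}$ slice of
  the same grid, sharing the tuned tree count search.
* **Seeds**: repetition $r$ uses `seed + r`, each repetition independently
  reproducible.

AUC is computed rank-based (Mann-Whitney with midranks); MCC uses the
standard formula with the convention that a zero marginal gives 0.

## Power analyses

**Univariate.** For a feature with observed class summaries
$(\bar x_1, s_1, n_1)$ and $(\bar x_0, s_0, n_0)$: draw `n_sim` paired
cohorts from the two normal distributions (the normal family is the one
fully parameterized by mean, standard deviation and count), report
Cohen's $d$ with pooled standard deviation, and the power as the fraction
of two-sided rank-sum rejections at $\alpha$. Degenerate inputs (both
spreads zero, equal means) report power $= \alpha$ and are flagged.

**Multivariate (learning curves).** Power is read as *sensitivity*
(recall on cases). For each size $s$ in a grid up to the cohort size:
repeatedly subsample $s$ individuals stratified, run 5-fold CV of a
random forest with *fixed* parameters — the feature subset and tree count
retained by the evaluation protocol, nothing re-optimized inside the
curve — and pool out-of-fold predictions. The curve reports mean
sensitivity with a normal-approximation 95% half-width over the repeats
and the plateau size: the smallest $s$ whose interval reaches the curve's
maximum. Passing the retained feature *subset* (rather than re-running
the MCMC ranking inside each of the grid-size × repeats × folds fits)
keeps the curve computable at the published scale of one hundred 5-fold
CVs per grid point.

## Synthetic cohorts

No cohort is distributed with the package; the generator produces the
study conditions in which everything is tested: 85 cases and 61 controls
over a 109-gene panel by default, with axis sizes shaped like a real
annotation of such a panel (about 2.3 domains per gene, 130 pathways, 569
interactors).

* **Background.** Variant counts are Poisson per gene (mean 8);
  population frequencies are log-uniform on $[1/5008, 0.5]$ with a 15%
  point mass of common variants; deleteriousness is a Beta mixture
  (30% damaging near 1, 70% tolerated near 0); genotypes are
  Hardy-Weinberg draws at each variant's frequency, identically in both
  arms — the simplest defensible population model, stated explicitly
  because none is prescribed for this design. There is no linkage
  disequilibrium, population structure or sequencing-error model, so
  passing tests demonstrate correctness of the collapsing and inference
  machinery, not robustness to those real-data complications.
* **Planted signal.** A planted ROI receives novel (frequency-floored)
  damaging variants in its member genes. Cases carry them by *balanced
  allele allocation*: every case carries $\lfloor m \rfloor$ or
  $\lceil m \rceil$ planted alleles, with $m$ chosen so the expected
  added case burden equals the requested effect (in score units,
  i.e. downstream of the collapsing formula — so tests control Cohen's
  $d$ directly rather than through variant-level knobs). Controls carry
  the planted alleles only at Hardy-Weinberg floor frequency. Balanced
  allocation keeps the realized $d$ tight around its target; independent
  Bernoulli carriage would add case-side variance of the same order as
  the shift and make calibration unstable.
* **Calibration.** `calibrate_effect()` finds the effect realizing a
  target $d$ by fixed-point iteration on pilot simulations (realized $d$
  is mildly nonlinear in the effect because planting still adds some
  case-side variance). The truth record stores the realized $d$ of every
  planted ROI computed from the emitted score matrix, plus per-variant
  provenance.

## Problem sizes used by the test-suite and acceptance script

Oracle-equivalence tests run at deliberately small sizes where exhaustive
computation is feasible: burden matrices against a naive triple loop on
1000 random 5-sample cohorts; the rank-sum test against all
$\binom{8}{4}$ relabelings; the MCMC search against all $2^{10}$ models;
the CV grid against brute-force evaluation of each pair. Calibration
checks use the full 85/61 cohort shape with 2000 null simulations for the
type-I error, 25 planted-cohort replicates for recovery after Bonferroni,
and 10 protocol repetitions for the null-AUC band; the acceptance script
repeats these from scratch at comparable sizes, which keep the whole
suite within a few minutes on one core while leaving Monte-Carlo error
well inside the asserted tolerances.

## Known limitations

* The deleteriousness score and population frequency are consumed as
  annotation inputs; variants without a score are dropped, which mirrors
  coding-region-only predictors and undercounts non-coding burden.
* PPI neighbourhood features share member genes heavily; their scores are
  strongly correlated with the gene axis, and the search treats them as
  exchangeable features with no structural prior.
* Bonferroni within axes is conservative under correlated burden scores;
  no FDR or permutation alternative is provided by design.
* The synthetic generator's independence assumptions (no LD, no
  structure) make planted-signal recovery an upper bound on real-data
  performance.
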