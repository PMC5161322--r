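# roiburden

Rare-variant burden collapsing over four region-of-interest (ROI) axes —
genes, protein domains, pathways and protein–protein-interaction (PPI)
neighbourhoods — with univariate association, stochastic-search feature
ranking, a repeated random-forest case/control evaluation protocol, and
simulation-based power analyses. It is written for analysts of gene-panel
sequencing studies (on the order of a hundred genes, a few hundred
individuals) where single-variant association is hopeless and signal must
be aggregated across variants, and across annotation layers, to become
testable.

## The score

Each variant allele contributes

    v = sigma × P × (−log10 max(F, f0))

to every ROI it maps to, where `sigma ∈ {0,1,2}` is the allele copy count,
`P ∈ [0,1]` the predicted deleteriousness (an input annotation column),
`F` the population allele frequency and `f0 = 1/5008` the novel-allele
floor. An individual's score for an ROI is the sum of `v` over the ROI's
variants: rare, damaging, homozygous alleles dominate; common or tolerated
ones contribute little. A variant fans out to several ROIs at once — its
gene, any overlapping domain, every pathway containing the gene and every
interactor the gene's protein binds (a variant in a gene with one
overlapping domain, two pathways and two interactors feeds exactly 6
features). Combining the four axes gives `2^4 − 1 = 15` datasets per
cohort; at typical panel annotation sizes (129 gene features, 252 domains,
130 pathways, 569 interactors) the full combination has 1080 features.

On top of the matrices the package provides:

* `associate()` — per-feature case/control tests (Shapiro-Wilk-gated
  Welch *t* or Wilcoxon rank-sum), Bonferroni-corrected per axis, plus a
  containment graph of significant ROIs (`overlap_report()`);
* `rank_features()` — MCMC stochastic search over feature-inclusion
  vectors (BIC-scored linear-probability models, Beta-Binomial model-size
  prior), ranking features by posterior inclusion probability;
* `run_protocol()` — repeated stratified 70/30 splits with 5-fold
  cross-validated grid search over (selected features × forest size),
  per-fold feature selection, and held-out AUC/MCC averaged over
  repetitions;
* `univariate_power()` / `learning_curve()` — simulation-based power per
  feature, and sensitivity-versus-sample-size curves with confidence
  bands;
* `generate_topology()` / `generate_cohort()` — a fully synthetic cohort
  generator with planted high-burden ROIs and a truth record of realized
  effect sizes, so every analysis step is testable without patient data.

## Worked example

```r
library(roiburden)

cfg <- sim_config(n_cases = 85, n_controls = 61, n_genes = 30,
                  n_pathways = 10, n_interactors = 12,
                  variants_per_gene = 8, seed = 2024)
reg <- generate_topology(cfg)
eff <- calibrate_effect(reg, cfg, "gene", "G007", target_d = 1.5)
cfg$planted_rois <- list(list(roi_type = "gene", roi_id = "G007",
                              effect = eff))
sim <- generate_cohort(reg, cfg)
sim$cohort
#> ROI cohort: 146 samples (85 cases / 61 controls), 250 variants
round(sim$truth$planted$realized_d, 2)
#> [1] 1.31
```

The planted gene carries a realized standardized case excess of d ≈ 1.3.
Univariate association on the gene+pathway dataset recovers it, and the
pathways containing it, after Bonferroni correction within each axis:

```r
m <- build_score_matrix(sim$cohort, reg, c("gene", "pathway"))
res <- associate(m, sim$cohort$labels)
head(res[order(res$p_adjusted), ], 5)
#>    roi_type roi_id test_used    p_raw p_adjusted significant
#> 34  pathway  PW004   ranksum 6.91e-09   6.91e-08        TRUE
#> 31  pathway  PW001   ranksum 1.08e-06   1.08e-05        TRUE
#> 7      gene   G007   ranksum 3.79e-07   1.14e-05        TRUE
#> 37  pathway  PW007   ranksum 4.76e-06   4.76e-05        TRUE
#> 35  pathway  PW005         t 7.06e-06   7.06e-05        TRUE
```

`p_adjusted` is the raw p times the axis size (10 pathways, 30 genes),
capped at 1; `test_used` shows the normality gate in action. The
multivariate protocol on the same dataset:

```r
ec <- eval_config(repetitions = 3, feature_grid = list(5, "all"),
                  tree_grid = c(50, 100), seed = 9,
                  search = search_config(prior_model_size = 4,
                                         prior_variance = 2,
                                         iterations = 2000, burn_in = 400))
run_protocol(sim$cohort, reg, list(c("gene", "pathway")), ec)[[1]]
#> Evaluation report [gene+pathway]: mean AUC 0.730, mean MCC 0.420 over 3 repetitions
```

Held-out test AUC of 0.73 from a single planted gene: the burden signal
generalizes to unseen individuals, well above the ~0.5 a label-permuted
or unplanted cohort yields.

A thin command-line wrapper over the same functions ships in
`exec/roiburden` (subcommands `simulate`, `score`, `assoc`, `select`,
`train`, `power`); after installation:

```sh
RB=$(Rscript -e 'cat(system.file("exec", "roiburden", package = "roiburden"))')
Rscript "$RB" simulate --out demo --seed 5 --plant gene:G003:4
Rscript "$RB" score --vcf demo/cohort.vcf --annot demo/annotation.tsv \
    --labels demo/labels.tsv --rois demo --combo gene,pathway --out demo/m.tsv
Rscript "$RB" assoc --matrix demo/m.tsv --labels demo/labels.tsv --out demo/assoc.tsv
```

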