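test_that("generated topologies satisfy the registry contracts", {
  cfg <- sim_config(n_genes = 20, domains_per_gene = 2, n_pathways = 6,
                    n_interactors = 10, seed = 51)
  reg <- generate_topology(cfg)
  expect_s3_class(reg, "roi_registry")
  g <- reg$genes
  expect_false(is.unsorted(GenomicRanges::start(g)))
  expect_true(all(GenomicRanges::start(g)[-1] >
                    GenomicRanges::end(g)[-length(g)]))  # non-overlapping
  d <- reg$domains
  own <- match(S4Vectors::mcols(d)$gene_id, S4Vectors::mcols(g)$gene_id)
  expect_true(all(GenomicRanges::start(d) >= GenomicRanges::start(g)[own]))
  expect_true(all(GenomicRanges::end(d) <= GenomicRanges::end(g)[own]))
  expect_false(anyDuplicated(S4Vectors::mcols(d)$domain_id) > 0)
  expect_true(all(unlist(reg$pathways) %in% S4Vectors::mcols(g)$gene_id))
})

test_that("empty axes are honoured by fan-out", {
  cfg <- sim_config(n_genes = 5, n_pathways = 0, n_interactors = 3,
                    variants_per_gene = 3, n_cases = 4, n_controls = 3,
                    seed = 52)
  reg <- generate_topology(cfg)
  expect_equal(unname(axis_sizes(reg)["pathway"]), 0L)
  sim <- generate_cohort(reg, cfg)
  for (vi in seq_len(min(5, nrow(sim$cohort$variants)))) {
    rois <- map_variant_to_rois(sim$cohort$variants[vi, ], reg)
    expect_false("pathway" %in% rois$roi_type)
  }
})

test_that("the whole artifact set is deterministic under a fixed seed", {
  cfg <- small_sim_config(seed = 53)
  reg1 <- generate_topology(cfg)
  reg2 <- generate_topology(cfg)
  d <- withr::local_tempdir()
  pa <- file.path(d, c("g1.bed", "d1.bed", "p1.tsv", "i1.tsv"))
  pb <- file.path(d, c("g2.bed", "d2.bed", "p2.tsv", "i2.tsv"))
  write_roi_registry(reg1, pa[1], pa[2], pa[3], pa[4])
  write_roi_registry(reg2, pb[1], pb[2], pb[3], pb[4])
  for (i in 1:4) expect_identical(readLines(pa[i]), readLines(pb[i]))
  sim1 <- generate_cohort(reg1, cfg)
  sim2 <- generate_cohort(reg2, cfg)
  expect_identical(sim1$cohort, sim2$cohort)
  expect_identical(sim1$truth$planted, sim2$truth$planted)
})

test_that("background genotypes follow Hardy-Weinberg at the variant frequency", {
  cfg <- sim_config(n_cases = 300, n_controls = 300, n_genes = 6,
                    variants_per_gene = 20, common_mass = 0.5, seed = 54)
  reg <- generate_topology(cfg)
  co <- generate_cohort(reg, cfg)$cohort
  pick <- which(co$variants$F > 0.05 & co$variants$F < 0.45)
  expect_gt(length(pick), 5)
  fr <- co$variants$F[pick]
  het_obs <- rowMeans(co$geno[pick, , drop = FALSE] == 1L)
  het_exp <- 2 * fr * (1 - fr)
  se <- sqrt(het_exp * (1 - het_exp) / ncol(co$geno))
  expect_true(all(abs(het_obs - het_exp) < 4 * se))
})

test_that("unplanted cohorts carry no class signal", {
  cfg <- sim_config(n_cases = 60, n_controls = 60, n_genes = 12,
                    n_pathways = 4, n_interactors = 6, variants_per_gene = 6,
                    seed = 55)
  reg <- generate_topology(cfg)
  co <- generate_cohort(reg, cfg)$cohort
  m <- build_score_matrix(co, reg)
  z <- apply(m, 2, function(col) {
    x1 <- col[co$labels == 1L]; x0 <- col[co$labels == 0L]
    se <- sqrt(var(x1) / length(x1) + var(x0) / length(x0))
    if (se == 0) 0 else (mean(x1) - mean(x0)) / se
  })
  expect_true(all(abs(z) < 3.5))
  expect_gt(mean(abs(z) < 3), 0.95)
})

test_that("planted effects reach the requested standardized size", {
  cfg <- sim_config(n_cases = 85, n_controls = 61, n_genes = 15,
                    n_pathways = 5, n_interactors = 8, variants_per_gene = 8,
                    seed = 56)
  reg <- generate_topology(cfg)
  eff <- calibrate_effect(reg, cfg, "gene", "G005", target_d = 1.5)
  ds <- vapply(1:12, function(s) {
    cfg_s <- cfg
    cfg_s$seed <- 600 + s
    cfg_s$planted_rois <- list(list(roi_type = "gene", roi_id = "G005",
                                    effect = eff))
    generate_cohort(reg, cfg_s)$truth$planted$realized_d[1]
  }, numeric(1))
  expect_true(all(ds > 1.2 & ds < 1.8))
})

test_that("a gene-level plant propagates along the fan-out", {
  cfg <- sim_config(n_cases = 50, n_controls = 40, n_genes = 8,
                    n_pathways = 4, pathway_size = 3, n_interactors = 5,
                    variants_per_gene = 5, seed = 57)
  reg <- generate_topology(cfg)
  cfg$planted_rois <- list(list(roi_type = "gene", roi_id = "G003",
                                effect = 8))
  co <- generate_cohort(reg, cfg)$cohort
  m <- build_score_matrix(co, reg)
  probe <- list(chrom = "1",
                pos = GenomicRanges::start(reg$genes)[3] + 1,
                gene_id = "G003")
  downstream <- scan_variant_rois(probe, reg)
  downstream <- downstream[downstream$roi_type != "domain", ]
  for (i in seq_len(nrow(downstream))) {
    col <- m[, paste0(downstream$roi_type[i], ":", downstream$roi_id[i])]
    diff <- mean(col[co$labels == 1L]) - mean(col[co$labels == 0L])
    expect_gt(diff, 0)
  }
})

test_that("unreachable planted effects fail loudly", {
  cfg <- sim_config(n_cases = 10, n_controls = 8, n_genes = 4,
                    variants_per_gene = 2, n_pathways = 2,
                    n_interactors = 2, seed = 58)
  reg <- generate_topology(cfg)
  cfg$planted_rois <- list(list(roi_type = "gene", roi_id = "G001",
                                effect = 500))
  expect_error(generate_cohort(reg, cfg), "unreachable")
})
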