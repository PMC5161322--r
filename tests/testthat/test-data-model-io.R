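test_that("a cohort round-trips losslessly through VCF, annotation and labels", {
  cfg <- small_sim_config(seed = 11)
  reg <- generate_topology(cfg)
  sim <- generate_cohort(reg, cfg)
  d <- withr::local_tempdir()
  paths <- file.path(d, c("c.vcf", "a.tsv", "l.tsv"))
  write_cohort(sim$cohort, paths[1], paths[2], paths[3])
  co2 <- read_cohort(paths[1], paths[2], paths[3])
  expect_identical(co2$samples, sim$cohort$samples)
  expect_identical(co2$labels, sim$cohort$labels)
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt)
  o1 <- order(key(sim$cohort$variants))
  o2 <- order(key(co2$variants))
  expect_equal(co2$variants[o2, c("gene_id", "P", "F")],
               sim$cohort$variants[o1, c("gene_id", "P", "F")],
               ignore_attr = TRUE)
  expect_equal(unname(co2$geno[o2, ]), unname(sim$cohort$geno[o1, ]))
})

test_that("multi-allelic records split into per-allele copy counts", {
  # all diploid genotype combinations over REF/ALT1/ALT2, plus a missing
  # call; expected counts enumerated by hand
  gts <- c("0/0", "0/1", "0/2", "1/1", "1/2", "2/2", "./.")
  sigma_alt1 <- c(0, 1, 0, 2, 1, 0, 0)
  sigma_alt2 <- c(0, 0, 1, 0, 1, 2, 0)
  d <- withr::local_tempdir()
  samples <- sprintf("s%d", seq_along(gts))
  vcf <- file.path(d, "m.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "FORMAT",
            samples), collapse = "\t"),
    paste(c("1", "150", ".", "A", "C,T", ".", "PASS", "GT", gts),
          collapse = "\t")), vcf)
  ann <- file.path(d, "a.tsv")
  write.table(data.frame(chrom = "1", pos = 150, ref = "A", alt = c("C", "T"),
                         gene = "A", score = 0.8, freq = 0.01),
              ann, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- file.path(d, "l.tsv")
  write.table(data.frame(sample = samples,
                         label = rep(c("case", "control"), c(4, 3))),
              lab, sep = "\t", quote = FALSE, row.names = FALSE)
  co <- read_cohort(vcf, ann, lab)
  expect_equal(nrow(co$variants), 2)
  expect_equal(unname(co$geno[co$variants$alt == "C", ]), sigma_alt1)
  expect_equal(unname(co$geno[co$variants$alt == "T", ]), sigma_alt2)
})

test_that("unannotated variants are dropped with a count and bad labels are hard errors", {
  cfg <- small_sim_config(seed = 12)
  reg <- generate_topology(cfg)
  sim <- generate_cohort(reg, cfg)
  d <- withr::local_tempdir()
  paths <- file.path(d, c("c.vcf", "a.tsv", "l.tsv"))
  write_cohort(sim$cohort, paths[1], paths[2], paths[3])
  ann <- read.delim(paths[2])
  write.table(ann[-1, ], paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(co <- read_cohort(paths[1], paths[2], paths[3]),
                 "dropped 1 ")
  expect_equal(nrow(co$variants), nrow(sim$cohort$variants) - 1)

  lab <- read.delim(paths[3])
  lab$sample[1] <- "ghost"
  write.table(lab, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cohort(paths[1], paths[2], paths[3]), "ghost")
  names(lab)[2] <- "phenotype"
  write.table(lab, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cohort(paths[1], paths[2], paths[3]), "label")
})

test_that("registry reader validates intervals and flags odd members", {
  d <- withr::local_tempdir()
  gene_bed <- file.path(d, "g.bed"); dom_bed <- file.path(d, "d.bed")
  pw <- file.path(d, "p.tsv"); pp <- file.path(d, "i.tsv")
  writeLines(c("1\t100\t200\tA", "1\t300\t400\tB"), gene_bed)
  writeLines("1\t150\t170\tDOM\tA", dom_bed)
  writeLines(c("P1\tA", "P1\tOFFPANEL"), pw)
  writeLines("X1\tB", pp)
  reg <- suppressMessages(read_roi_registry(gene_bed, dom_bed, pw, pp))
  expect_equal(unname(axis_sizes(reg)), c(2, 1, 1, 1))
  expect_equal(reg$off_panel_members, 1)

  writeLines("1\t500\t400\tBAD", file.path(d, "bad.bed"))
  expect_error(
    suppressMessages(read_roi_registry(file.path(d, "bad.bed"), dom_bed, pw, pp)),
    "line 1")
  # domain hanging outside its owning gene: kept, but warned about
  writeLines("1\t150\t250\tDOM\tA", dom_bed)
  expect_warning(
    reg2 <- suppressMessages(read_roi_registry(gene_bed, dom_bed, pw, pp)),
    "outside")
  expect_equal(length(reg2$domains), 1)
})

test_that("variant fan-out reproduces the six-feature worked example", {
  reg <- tiny_registry()
  v <- list(chrom = "1", pos = 160, gene_id = "A")
  rois <- map_variant_to_rois(v, reg)
  expect_equal(nrow(rois), 6)
  expect_equal(rois$roi_id[rois$roi_type == "gene"], "A")
  expect_equal(rois$roi_id[rois$roi_type == "domain"], "DOM")
  expect_setequal(rois$roi_id[rois$roi_type == "pathway"], c("P1", "P2"))
  expect_setequal(rois$roi_id[rois$roi_type == "ppi"], c("B", "C"))
  # an isolated gene maps to its own gene ROI and nothing else
  v_iso <- list(chrom = "1", pos = 750, gene_id = "ISO")
  expect_equal(map_variant_to_rois(v_iso, reg),
               data.frame(roi_type = "gene", roi_id = "ISO"))
  expect_error(map_variant_to_rois(list(chrom = "1", pos = 1, gene_id = "ZZ"),
                                   reg), "panel")
})

test_that("fan-out agrees with the exhaustive membership scan", {
  set.seed(42)
  for (s in 1:25) {
    cfg <- small_sim_config(seed = 100 + s)
    reg <- generate_topology(cfg)
    sim <- generate_cohort(reg, cfg)
    vs <- sim$cohort$variants
    for (vi in sample(nrow(vs), min(8, nrow(vs)))) {
      v <- vs[vi, ]
      expect_equal(map_variant_to_rois(v, reg), scan_variant_rois(v, reg))
    }
  }
})

test_that("adding a pathway containing the gene grows fan-out by exactly one", {
  reg <- tiny_registry()
  v <- list(chrom = "1", pos = 160, gene_id = "A")
  base <- map_variant_to_rois(v, reg)
  reg2 <- reg
  reg2$pathways$PNEW <- c("A", "ISO")
  grown <- map_variant_to_rois(v, reg2)
  expect_equal(nrow(grown), nrow(base) + 1)
  expect_true(all(paste(base$roi_type, base$roi_id) %in%
                    paste(grown$roi_type, grown$roi_id)))
  expect_true("PNEW" %in% grown$roi_id)
})

test_that("a registry round-trips through its four files", {
  cfg <- small_sim_config(seed = 13)
  reg <- generate_topology(cfg)
  d <- withr::local_tempdir()
  p <- file.path(d, c("g.bed", "d.bed", "p.tsv", "i.tsv"))
  write_roi_registry(reg, p[1], p[2], p[3], p[4])
  reg2 <- suppressMessages(read_roi_registry(p[1], p[2], p[3], p[4]))
  expect_equal(axis_sizes(reg2), axis_sizes(reg))
  expect_equal(S4Vectors::mcols(reg2$genes)$gene_id,
               S4Vectors::mcols(reg$genes)$gene_id)
  expect_equal(GenomicRanges::start(reg2$genes), GenomicRanges::start(reg$genes))
  expect_equal(GenomicRanges::end(reg2$domains), GenomicRanges::end(reg$domains))
  expect_equal(reg2$pathways[order(names(reg2$pathways))],
               reg$pathways[order(names(reg$pathways))])
  expect_equal(reg2$ppi[order(names(reg2$ppi))],
               reg$ppi[order(names(reg$ppi))])
})
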