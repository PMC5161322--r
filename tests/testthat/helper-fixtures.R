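# Hand-built registry realizing the canonical fan-out situation: a variant
# in gene A inside domain DOM, with A in two pathways and adjacent to two
# interactors.
tiny_registry <- function() {
  genes <- GenomicRanges::GRanges("1",
    IRanges::IRanges(start = c(101, 301, 501, 701),
                     end = c(200, 400, 600, 800)),
    gene_id = c("A", "B", "C", "ISO"))
  domains <- GenomicRanges::GRanges("1",
    IRanges::IRanges(start = 151, end = 170),
    domain_id = "DOM", gene_id = "A")
  roi_registry(genes, domains,
               pathways = list(P1 = c("A", "B"), P2 = c("A", "C")),
               ppi = list(B = "A", C = "A"))
}

small_sim_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_cases = 6, n_controls = 5, n_genes = 4, domains_per_gene = 1,
         n_pathways = 2, pathway_size = 2, n_interactors = 3,
         ppi_degree = 1.5, variants_per_gene = 3, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# Exhaustive membership scan, written directly against the registry
# internals: the independent oracle for fan-out and for burden matrices.
scan_variant_rois <- function(variant, registry) {
  out <- data.frame(roi_type = character(), roi_id = character(),
                    stringsAsFactors = FALSE)
  gmc <- S4Vectors::mcols(registry$genes)
  for (i in seq_along(registry$genes))
    if (gmc$gene_id[i] == variant$gene_id)
      out <- rbind(out, data.frame(roi_type = "gene", roi_id = gmc$gene_id[i]))
  dmc <- S4Vectors::mcols(registry$domains)
  for (i in seq_along(registry$domains)) {
    same_chrom <- as.character(GenomicRanges::seqnames(registry$domains))[i] ==
      as.character(variant$chrom)
    if (same_chrom &&
        variant$pos >= GenomicRanges::start(registry$domains)[i] &&
        variant$pos <= GenomicRanges::end(registry$domains)[i])
      out <- rbind(out, data.frame(roi_type = "domain", roi_id = dmc$domain_id[i]))
  }
  for (pw in names(registry$pathways))
    if (variant$gene_id %in% registry$pathways[[pw]])
      out <- rbind(out, data.frame(roi_type = "pathway", roi_id = pw))
  for (px in names(registry$ppi))
    if (variant$gene_id %in% registry$ppi[[px]])
      out <- rbind(out, data.frame(roi_type = "ppi", roi_id = px))
  out <- out[order(match(out$roi_type, c("gene", "domain", "pathway", "ppi")),
                   out$roi_id, method = "radix"), ]
  rownames(out) <- NULL
  out
}

# Naive triple loop over (sample, feature, variant): the burden-matrix
# oracle, computing the score arithmetic directly.
naive_score_matrix <- function(cohort, registry, combo, freq_floor = 1 / 5008) {
  feat <- list()
  for (ax in c("gene", "domain", "pathway", "ppi")) {
    if (!ax %in% combo) next
    ids <- switch(ax,
      gene = S4Vectors::mcols(registry$genes)$gene_id,
      domain = S4Vectors::mcols(registry$domains)$domain_id,
      pathway = names(registry$pathways),
      ppi = names(registry$ppi))
    for (id in sort(as.character(ids), method = "radix"))
      feat[[length(feat) + 1]] <- c(ax, id)
  }
  m <- matrix(0, length(cohort$samples), length(feat),
              dimnames = list(cohort$samples,
                              vapply(feat, function(f) paste0(f[1], ":", f[2]),
                                     character(1))))
  rois_by_variant <- lapply(seq_len(nrow(cohort$variants)), function(vi)
    scan_variant_rois(cohort$variants[vi, ], registry))
  for (si in seq_along(cohort$samples)) {
    for (fi in seq_along(feat)) {
      total <- 0
      for (vi in seq_len(nrow(cohort$variants))) {
        v <- cohort$variants[vi, ]
        rois <- rois_by_variant[[vi]]
        hit <- any(rois$roi_type == feat[[fi]][1] & rois$roi_id == feat[[fi]][2])
        if (hit) {
          f <- if (is.na(v$F)) freq_floor else max(v$F, freq_floor)
          total <- total + cohort$geno[vi, si] * v$P * (-log10(f))
        }
      }
      m[si, fi] <- total
    }
  }
  m
}

# registry with exact axis sizes (gene/domain/pathway/ppi), domains spread
# round-robin over genes
make_registry_of_sizes <- function(n_gene, n_domain, n_pathway, n_ppi) {
  gene_ids <- sprintf("G%03d", seq_len(n_gene))
  start0 <- (seq_len(n_gene) - 1) * 10000
  genes <- GenomicRanges::GRanges("1",
    IRanges::IRanges(start = start0 + 1, end = start0 + 5000),
    gene_id = gene_ids)
  own <- rep_len(seq_len(n_gene), n_domain)
  occ <- stats::ave(own, own, FUN = seq_along)
  domains <- GenomicRanges::GRanges("1",
    IRanges::IRanges(start = start0[own] + occ * 300 + 1,
                     end = start0[own] + occ * 300 + 100),
    domain_id = sprintf("D%04d", seq_len(n_domain)),
    gene_id = gene_ids[own])
  pw <- lapply(seq_len(n_pathway), function(i)
    gene_ids[(seq(i, i + 2) - 1) %% n_gene + 1])
  names(pw) <- sprintf("PW%03d", seq_len(n_pathway))
  ppi <- lapply(seq_len(n_ppi), function(i)
    gene_ids[(seq(i, i + 1) - 1) %% n_gene + 1])
  names(ppi) <- sprintf("X%03d", seq_len(n_ppi))
  roi_registry(genes, domains, pw, ppi)
}

pooled_d <- function(x1, x0) {
  sp <- sqrt(((length(x1) - 1) * var(x1) + (length(x0) - 1) * var(x0)) /
               (length(x1) + length(x0) - 2))
  (mean(x1) - mean(x0)) / sp
}
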