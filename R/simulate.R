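#' Configuration of the synthetic cohort generator
#'
#' The generator emulates a two-class gene-panel sequencing study: by
#' default 85 cases and 61 controls genotyped over a 109-gene panel, with
#' domain, pathway and PPI axes sized like a typical annotation of such a
#' panel (about 2.3 domains per gene, 130 pathways, 569 interactors).
#' Population allele frequencies are log-uniform between the novel-allele
#' floor and 0.5 with a point mass of common variants; deleteriousness
#' scores are a mixture of near-zero (tolerated) and near-one (damaging)
#' Beta draws; genotypes are Hardy-Weinberg at each variant's frequency.
#' Case/control signal is planted per ROI as an added expected burden (in
#' score units) carried by cases through extra rare damaging alleles in
#' the ROI's member genes.
#'
#' @param n_cases,n_controls cohort arm sizes.
#' @param n_genes panel size.
#' @param domains_per_gene mean domains per gene (Poisson).
#' @param n_pathways,pathway_size number of pathways and mean members.
#' @param n_interactors,ppi_degree number of PPI interactors and mean panel
#'   genes adjacent to each.
#' @param variants_per_gene mean background variants per gene (Poisson).
#' @param common_mass fraction of variants redrawn as common (frequency
#'   0.2-0.5).
#' @param p_deleterious fraction of variants drawn from the damaging
#'   (near-1) deleteriousness component.
#' @param planted_rois list of `list(roi_type, roi_id, effect)` entries;
#'   `effect` is the added expected case burden in score units.
#' @param freq_floor novel-allele frequency floor (matches
#'   [scoring_config()]).
#' @param seed RNG seed; topology and cohort are deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 85, n_controls = 61, n_genes = 109,
                       domains_per_gene = 2.3, n_pathways = 130,
                       pathway_size = 8, n_interactors = 569,
                       ppi_degree = 2, variants_per_gene = 8,
                       common_mass = 0.15, p_deleterious = 0.3,
                       planted_rois = list(), freq_floor = 1 / 5008,
                       seed = 1) {
  stopifnot(n_cases >= 2, n_controls >= 2, n_genes >= 1,
            variants_per_gene > 0, freq_floor > 0, freq_floor < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic ROI topology
#'
#' Panel genes get non-overlapping intervals on one chromosome; domains are
#' nested inside their owning genes (a sampled domain longer than its gene
#' is resampled); pathway memberships and interactor adjacencies are
#' sampled uniformly over panel genes with Poisson sizes. Deterministic
#' given the config seed.
#'
#' @param config a [sim_config()].
#' @return A [roi_registry()].
#' @export
generate_topology <- function(config = sim_config()) {
  with_seed(config$seed, {
    gene_ids <- sprintf("G%03d", seq_len(config$n_genes))
    len <- sample(2000:6000, config$n_genes, replace = TRUE)
    start0 <- cumsum(c(0, head(len, -1) + 1000L))
    genes <- GenomicRanges::GRanges("1",
      IRanges::IRanges(start = start0 + 1L, end = start0 + len),
      gene_id = gene_ids)
    doms <- list()
    n_dom <- rpois(config$n_genes, config$domains_per_gene)
    for (i in seq_len(config$n_genes)) {
      for (k in seq_len(n_dom[i])) {
        dlen <- sample(100:2000, 1)
        while (dlen >= len[i]) dlen <- sample(100:2000, 1)
        ds <- start0[i] + sample.int(len[i] - dlen, 1)
        doms[[length(doms) + 1]] <- c(ds, ds + dlen, i)
      }
    }
    domains <- if (length(doms)) {
      dm <- do.call(rbind, doms)
      GenomicRanges::GRanges("1",
        IRanges::IRanges(start = dm[, 1] + 1L, end = dm[, 2]),
        domain_id = sprintf("D%04d", seq_len(nrow(dm))),
        gene_id = gene_ids[dm[, 3]])
    } else {
      g0 <- GenomicRanges::GRanges()
      S4Vectors::mcols(g0)$domain_id <- character(0)
      S4Vectors::mcols(g0)$gene_id <- character(0)
      g0
    }
    pw <- lapply(seq_len(config$n_pathways), function(i)
      sample(gene_ids, min(config$n_genes,
                           1 + rpois(1, config$pathway_size - 1))))
    names(pw) <- sprintf("PW%03d", seq_along(pw))
    ppi <- lapply(seq_len(config$n_interactors), function(i)
      sample(gene_ids, min(config$n_genes,
                           1 + rpois(1, config$ppi_degree - 1))))
    names(ppi) <- sprintf("X%03d", seq_along(ppi))
    roi_registry(genes, domains, pw, ppi)
  })
}

#' Generate a synthetic case/control cohort over a topology
#'
#' Background variants are Poisson per gene, with log-uniform population
#' frequencies, mixture deleteriousness and Hardy-Weinberg genotypes (the
#' same process in both arms, so an unplanted ROI carries no signal).
#' Each planted ROI receives novel (frequency-floored) damaging variants in
#' its member genes; cases carry each with probability `q` chosen so the
#' expected added case burden equals the requested effect, while controls
#' carry them only at Hardy-Weinberg floor frequency. The truth record
#' reports, per planted ROI, the Cohen's d realized in the emitted score
#' matrix, plus per-variant provenance.
#'
#' @param registry a [roi_registry()] from [generate_topology()].
#' @param config the same [sim_config()].
#' @return List with `cohort` (a [roi_cohort()]) and `truth` (list with
#'   `planted` data.frame carrying `realized_d`, and `provenance`).
#' @export
generate_cohort <- function(registry, config = sim_config()) {
  panel <- S4Vectors::mcols(registry$genes)$gene_id
  n <- config$n_cases + config$n_controls
  samples <- c(sprintf("case%03d", seq_len(config$n_cases)),
               sprintf("ctrl%03d", seq_len(config$n_controls)))
  labels <- setNames(rep(c(1L, 0L), c(config$n_cases, config$n_controls)),
                     samples)
  is_case <- labels == 1L
  bases <- c("A", "C", "G", "T")

  out <- with_seed(config$seed + 1L, {
    used <- new.env(hash = TRUE)
    draw_pos <- function(lo, hi) {
      repeat {
        p <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        key <- as.character(p)
        if (is.null(used[[key]])) { used[[key]] <- TRUE; return(p) }
      }
    }
    n_bg <- rpois(config$n_genes, config$variants_per_gene)
    gidx <- rep(seq_len(config$n_genes), n_bg)
    nv <- length(gidx)
    pos <- vapply(gidx, function(i)
      draw_pos(GenomicRanges::start(registry$genes)[i],
               GenomicRanges::end(registry$genes)[i]), integer(1))
    F_bg <- 10^runif(nv, log10(config$freq_floor), log10(0.5))
    common <- runif(nv) < config$common_mass
    F_bg[common] <- runif(sum(common), 0.2, 0.5)
    del <- runif(nv) < config$p_deleterious
    P_bg <- ifelse(del, rbeta(nv, 6, 1), rbeta(nv, 1, 6))
    ref <- sample(bases, nv, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    geno <- matrix(rbinom(nv * n, 2L, rep(F_bg, n)), nrow = nv, ncol = n,
                   dimnames = list(NULL, samples))
    variants <- data.frame(chrom = rep("1", nv), pos = pos, ref = ref,
                           alt = alt, gene_id = panel[gidx], P = P_bg,
                           F = F_bg, stringsAsFactors = FALSE)
    provenance <- rep("background", nv)

    for (pl in config$planted_rois) {
      member <- intersect(feature_gene_set(registry, pl$roi_type, pl$roi_id),
                          panel)
      if (length(member) == 0)
        stop(sprintf("planted ROI %s:%s has no panel member genes",
                     pl$roi_type, pl$roi_id))
      w_one <- 0.95 * (-log10(config$freq_floor))  # expected planted weight
      m_alleles <- pl$effect / w_one      # mean planted alleles per case
      n_pl <- max(3L, ceiling(m_alleles))
      budget <- ceiling(length(member) * config$variants_per_gene)
      n_pl <- min(n_pl, max(budget, 3L))
      if (m_alleles > 2 * n_pl)
        stop(sprintf(paste("planted effect %.2f for %s:%s is unreachable;",
                           "increase variants_per_gene or add member genes"),
                     pl$effect, pl$roi_type, pl$roi_id))
      P_pl <- runif(n_pl, 0.9, 1)
      w <- P_pl * (-log10(config$freq_floor))
      mi <- match(rep_len(member, n_pl), panel)
      pos_pl <- vapply(seq_len(n_pl), function(k) {
        if (pl$roi_type == "domain") {
          di <- which(S4Vectors::mcols(registry$domains)$domain_id == pl$roi_id)
          draw_pos(GenomicRanges::start(registry$domains)[di],
                   GenomicRanges::end(registry$domains)[di])
        } else {
          draw_pos(GenomicRanges::start(registry$genes)[mi[k]],
                   GenomicRanges::end(registry$genes)[mi[k]])
        }
      }, integer(1))
      ref_pl <- sample(bases, n_pl, replace = TRUE)
      alt_pl <- vapply(ref_pl, function(b) sample(setdiff(bases, b), 1),
                       character(1))
      # balanced allele allocation: every case carries floor(m) or ceil(m)
      # planted alleles (which variants randomized), so the added case
      # burden is tight around the requested effect; controls carry the
      # alleles only at Hardy-Weinberg floor frequency
      n_case <- sum(is_case)
      m_adj <- pl$effect / mean(w)
      cnt <- rep(floor(m_adj), n_case)
      extra <- round((m_adj - floor(m_adj)) * n_case)
      if (extra > 0) cnt[sample.int(n_case, extra)] <- cnt[1] + 1L
      g_pl <- matrix(0L, n_pl, n, dimnames = list(NULL, samples))
      case_cols <- which(is_case)
      for (ci in seq_len(n_case)) {
        k <- cnt[ci]
        if (k == 0) next
        hom <- max(0L, k - n_pl)            # overflow becomes hom-alt calls
        carried <- sample.int(n_pl, min(k, n_pl))
        g_pl[carried, case_cols[ci]] <- 1L
        if (hom > 0)
          g_pl[carried[seq_len(hom)], case_cols[ci]] <- 2L
      }
      g_pl[, !is_case] <- rbinom(n_pl * sum(!is_case), 2L,
                                 config$freq_floor)
      gene_pl <- if (pl$roi_type == "domain")
        rep(feature_gene_set(registry, "domain", pl$roi_id)[1], n_pl)
        else panel[mi]
      variants <- rbind(variants,
                        data.frame(chrom = "1", pos = pos_pl, ref = ref_pl,
                                   alt = alt_pl, gene_id = gene_pl,
                                   P = P_pl, F = NA_real_,
                                   stringsAsFactors = FALSE))
      geno <- rbind(geno, g_pl)
      provenance <- c(provenance, rep("planted", n_pl))
    }
    list(variants = variants, geno = geno, provenance = provenance)
  })

  cohort <- roi_cohort(samples, labels, out$variants, out$geno)
  truth <- list(provenance = out$provenance,
                planted = planted_truth(cohort, registry, config))
  list(cohort = cohort, truth = truth)
}

# realized standardized effect of each planted ROI in the emitted scores
planted_truth <- function(cohort, registry, config) {
  if (length(config$planted_rois) == 0)
    return(data.frame(roi_type = character(), roi_id = character(),
                      effect = numeric(), realized_d = numeric(),
                      stringsAsFactors = FALSE))
  sc <- scoring_config(config$freq_floor)
  do.call(rbind, lapply(config$planted_rois, function(pl) {
    m <- build_score_matrix(cohort, registry, pl$roi_type, sc)
    col <- m[, paste0(pl$roi_type, ":", pl$roi_id)]
    x1 <- col[cohort$labels == 1L]; x0 <- col[cohort$labels == 0L]
    sp <- sqrt(((length(x1) - 1) * var(x1) + (length(x0) - 1) * var(x0)) /
                 (length(x1) + length(x0) - 2))
    data.frame(roi_type = pl$roi_type, roi_id = pl$roi_id,
               effect = pl$effect,
               realized_d = if (sp == 0) NA_real_ else (mean(x1) - mean(x0)) / sp,
               stringsAsFactors = FALSE)
  }))
}

#' Calibrate a planted effect to a target Cohen's d
#'
#' Finds the effect (in burden-score units) whose realized standardized
#' case-control difference matches `target_d`, by simulation: starting from
#' `target_d` times the background spread of the target ROI score, the
#' effect is rescaled by `target_d / mean realized d` over `n_pilot` pilot
#' cohorts per iteration. The realized d is a mildly nonlinear function of
#' the effect (planting also adds some case-side variance), so a couple of
#' fixed-point iterations suffice.
#'
#' @param registry a [roi_registry()].
#' @param config a [sim_config()] (its `planted_rois` are ignored).
#' @param roi_type,roi_id the target feature.
#' @param target_d desired standardized case-control effect.
#' @param n_pilot pilot cohorts per iteration.
#' @param iterations fixed-point iterations.
#' @return Effect in burden-score units to pass in `planted_rois`.
#' @export
calibrate_effect <- function(registry, config, roi_type, roi_id, target_d,
                             n_pilot = 4, iterations = 4) {
  col <- paste0(roi_type, ":", roi_id)
  s0 <- mean(vapply(seq_len(n_pilot), function(i) {
    cfg0 <- config
    cfg0$planted_rois <- list()
    cfg0$seed <- config$seed + 1000 * i
    pilot <- generate_cohort(registry, cfg0)
    m <- build_score_matrix(pilot$cohort, registry, roi_type,
                            scoring_config(config$freq_floor))
    stats::sd(m[, col])
  }, numeric(1)))
  # when the background burden is nearly empty the carriage noise of the
  # planted alleles dominates the spread; start from that floor instead of
  # target_d * s0 so the fixed point is reached in few iterations
  w_one <- 0.95 * (-log10(config$freq_floor))
  eff <- max(target_d * s0, target_d^2 * w_one / 4)
  for (it in seq_len(iterations)) {
    d_bar <- mean(vapply(seq_len(n_pilot), function(i) {
      cfg1 <- config
      cfg1$seed <- config$seed + 1000 * it + 100 * i
      cfg1$planted_rois <- list(list(roi_type = roi_type, roi_id = roi_id,
                                     effect = eff))
      generate_cohort(registry, cfg1)$truth$planted$realized_d[1]
    }, numeric(1)))
    if (!is.finite(d_bar) || d_bar <= 0) break
    eff <- eff * min(max(target_d / d_bar, 1 / 3), 3)
  }
  eff
}
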