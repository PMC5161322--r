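#' ROI registries: the four region-of-interest axes
#'
#' A `roi_registry` holds the four axes over which variants are collapsed:
#' \describe{
#'   \item{genes}{`GRanges` of panel gene intervals, metadata column
#'     `gene_id`.}
#'   \item{domains}{`GRanges` of protein-domain intervals, metadata columns
#'     `domain_id` and `gene_id` (owning gene).}
#'   \item{pathways}{named list, pathway id -> character vector of member
#'     gene ids.}
#'   \item{ppi}{named list, interactor id -> character vector of panel genes
#'     physically interacting with that protein. A PPI feature is named by
#'     the \emph{interactor}; its burden collapses variants from the
#'     adjacent panel genes, never from a gene of the same name.}
#' }
#'
#' @param genes,domains `GRanges` as described above.
#' @param pathways,ppi named lists of character vectors.
#' @return An object of class `roi_registry`.
#' @export
roi_registry <- function(genes, domains, pathways, ppi) {
  stopifnot(methods::is(genes, "GRanges"), methods::is(domains, "GRanges"),
            is.list(pathways), is.list(ppi))
  if (anyDuplicated(S4Vectors::mcols(genes)$gene_id))
    stop("duplicate gene_id in gene intervals")
  if (anyDuplicated(S4Vectors::mcols(domains)$domain_id))
    stop("duplicate domain_id in domain intervals")
  if (anyDuplicated(names(pathways))) stop("duplicate pathway ids")
  if (anyDuplicated(names(ppi))) stop("duplicate interactor ids")
  panel <- S4Vectors::mcols(genes)$gene_id
  # members outside the panel are kept (they can never receive variants)
  # but counted so users see them
  off_panel <- sum(!unlist(pathways, use.names = FALSE) %in% panel) +
    sum(!unlist(ppi, use.names = FALSE) %in% panel)
  structure(
    list(genes = genes, domains = domains, pathways = pathways, ppi = ppi,
         off_panel_members = off_panel),
    class = "roi_registry")
}

#' @exportS3Method base::print
print.roi_registry <- function(x, ...) {
  cat("ROI registry\n")
  cat(sprintf("  genes:    %d intervals\n", length(x$genes)))
  cat(sprintf("  domains:  %d intervals\n", length(x$domains)))
  cat(sprintf("  pathways: %d gene sets\n", length(x$pathways)))
  cat(sprintf("  ppi:      %d interactor neighbourhoods\n", length(x$ppi)))
  if (x$off_panel_members > 0)
    cat(sprintf("  (%d pathway/PPI member genes are off-panel)\n",
                x$off_panel_members))
  invisible(x)
}

#' Number of features on each ROI axis
#' @param registry a `roi_registry`.
#' @return named integer vector over `gene`, `domain`, `pathway`, `ppi`.
#' @export
axis_sizes <- function(registry) {
  c(gene = length(registry$genes), domain = length(registry$domains),
    pathway = length(registry$pathways), ppi = length(registry$ppi))
}

read_bed3 <- function(path, n_extra, what) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 3 + n_extra)
    stop(sprintf("%s: expected at least %d columns in %s", what,
                 3 + n_extra, path))
  bad <- which(df[[3]] <= df[[2]])
  if (length(bad))
    stop(sprintf("%s: malformed interval (end <= start) at line %d of %s",
                 what, bad[1], path))
  df
}

read_membership_tsv <- function(path, what) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 2)
    stop(sprintf("%s: expected 2 columns (id, gene) in %s", what, path))
  split(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read the four ROI definition files
#'
#' Interval files follow the BED convention (0-based, half-open). The gene
#' file carries the gene id in column 4; the domain file carries the domain
#' id in column 4 and the owning gene id in column 5. Pathway membership and
#' PPI edges are two-column TSVs (`pathway_id<TAB>gene_id`,
#' `interactor_id<TAB>gene_id`), without header.
#'
#' Domain intervals falling outside their owning gene raise a warning but
#' are kept; pathway/PPI members that match no panel gene are retained and
#' counted (they can never receive variants).
#'
#' @param gene_bed,domain_bed paths to BED-like interval files.
#' @param pathway_tsv,ppi_tsv paths to two-column membership TSVs.
#' @return A [roi_registry()].
#' @export
read_roi_registry <- function(gene_bed, domain_bed, pathway_tsv, ppi_tsv) {
  g <- read_bed3(gene_bed, 1, "gene intervals")
  genes <- GenomicRanges::GRanges(
    seqnames = as.character(g[[1]]),
    ranges = IRanges::IRanges(start = g[[2]] + 1L, end = g[[3]]),
    gene_id = as.character(g[[4]]))
  d <- read_bed3(domain_bed, 2, "domain intervals")
  domains <- GenomicRanges::GRanges(
    seqnames = as.character(d[[1]]),
    ranges = IRanges::IRanges(start = d[[2]] + 1L, end = d[[3]]),
    domain_id = as.character(d[[4]]), gene_id = as.character(d[[5]]))
  check_domain_nesting(genes, domains)
  reg <- roi_registry(genes, domains,
                      read_membership_tsv(pathway_tsv, "pathway membership"),
                      read_membership_tsv(ppi_tsv, "PPI edges"))
  sz <- axis_sizes(reg)
  message(sprintf("ROI registry: %d genes, %d domains, %d pathways, %d interactors",
                  sz["gene"], sz["domain"], sz["pathway"], sz["ppi"]))
  reg
}

check_domain_nesting <- function(genes, domains) {
  if (length(domains) == 0) return(invisible())
  own <- match(S4Vectors::mcols(domains)$gene_id,
               S4Vectors::mcols(genes)$gene_id)
  for (i in seq_along(domains)) {
    if (is.na(own[i])) {
      warning(sprintf("domain %s owned by unknown gene %s",
                      S4Vectors::mcols(domains)$domain_id[i],
                      S4Vectors::mcols(domains)$gene_id[i]))
      next
    }
    gi <- genes[own[i]]
    if (as.character(GenomicRanges::seqnames(domains[i])) !=
          as.character(GenomicRanges::seqnames(gi)) ||
        GenomicRanges::start(domains[i]) < GenomicRanges::start(gi) ||
        GenomicRanges::end(domains[i]) > GenomicRanges::end(gi))
      warning(sprintf("domain %s lies outside its owning gene %s (kept)",
                      S4Vectors::mcols(domains)$domain_id[i],
                      S4Vectors::mcols(domains)$gene_id[i]))
  }
  invisible()
}

#' Write a registry back to its four flat files
#'
#' Inverse of [read_roi_registry()]; intervals are emitted 0-based
#' half-open.
#'
#' @param registry a `roi_registry`.
#' @param gene_bed,domain_bed,pathway_tsv,ppi_tsv output paths.
#' @return Invisibly, the registry.
#' @export
write_roi_registry <- function(registry, gene_bed, domain_bed, pathway_tsv,
                               ppi_tsv) {
  g <- registry$genes
  utils::write.table(
    data.frame(as.character(GenomicRanges::seqnames(g)),
               GenomicRanges::start(g) - 1L, GenomicRanges::end(g),
               S4Vectors::mcols(g)$gene_id),
    gene_bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  d <- registry$domains
  utils::write.table(
    data.frame(as.character(GenomicRanges::seqnames(d)),
               GenomicRanges::start(d) - 1L, GenomicRanges::end(d),
               S4Vectors::mcols(d)$domain_id, S4Vectors::mcols(d)$gene_id),
    domain_bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_membership <- function(lst, path) {
    df <- data.frame(id = rep(names(lst), lengths(lst)),
                     gene = unlist(lst, use.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_membership(registry$pathways, pathway_tsv)
  write_membership(registry$ppi, ppi_tsv)
  invisible(registry)
}

#' Map one variant to every ROI feature it contributes to
#'
#' The fan-out of a variant is: the gene ROI of its owning gene, every
#' domain ROI whose interval overlaps the position, every pathway ROI whose
#' gene set contains the gene, and every PPI ROI whose interactor
#' neighbourhood contains the gene. A variant never contributes to a PPI
#' feature named after its own gene: PPI features are named by the
#' interactor, and collapse variants of the adjacent panel genes.
#'
#' @param variant a list or one-row data.frame with `chrom`, `pos` (1-based)
#'   and `gene_id`.
#' @param registry a [roi_registry()].
#' @return A data.frame with columns `roi_type` and `roi_id`, ordered
#'   gene < domain < pathway < ppi then lexicographically by id.
#' @export
map_variant_to_rois <- function(variant, registry) {
  gid <- as.character(variant$gene_id)
  if (!gid %in% S4Vectors::mcols(registry$genes)$gene_id)
    stop(sprintf("variant gene %s is not in the registry gene panel", gid))
  pos <- GenomicRanges::GRanges(as.character(variant$chrom),
                                IRanges::IRanges(variant$pos, variant$pos))
  hit <- GenomicRanges::findOverlaps(pos, registry$domains)
  dom <- S4Vectors::mcols(registry$domains)$domain_id[S4Vectors::subjectHits(hit)]
  pw <- names(registry$pathways)[vapply(registry$pathways,
                                        function(m) gid %in% m, logical(1))]
  pp <- names(registry$ppi)[vapply(registry$ppi,
                                   function(m) gid %in% m, logical(1))]
  out <- data.frame(
    roi_type = c("gene", rep("domain", length(dom)),
                 rep("pathway", length(pw)), rep("ppi", length(pp))),
    roi_id = c(gid, dom, pw, pp),
    stringsAsFactors = FALSE)
  out <- out[order(match(out$roi_type, ROI_TYPES), out$roi_id,
                   method = "radix"), ]
  rownames(out) <- NULL
  out
}

# variant x feature membership indicator for one axis, vectorized over a
# cohort's variant table; used by build_score_matrix and kept consistent
# with map_variant_to_rois (tested against it)
axis_membership <- function(variants, registry, roi_type) {
  ids <- axis_feature_ids(registry, roi_type)
  n <- nrow(variants)
  m <- matrix(FALSE, n, length(ids), dimnames = list(NULL, ids))
  if (n == 0 || length(ids) == 0) return(m)
  if (roi_type == "gene") {
    j <- match(variants$gene_id, ids)
    ok <- !is.na(j)
    m[cbind(which(ok), j[ok])] <- TRUE
  } else if (roi_type == "domain") {
    vr <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos, variants$pos))
    hit <- GenomicRanges::findOverlaps(vr, registry$domains)
    j <- match(S4Vectors::mcols(registry$domains)$domain_id[S4Vectors::subjectHits(hit)], ids)
    m[cbind(S4Vectors::queryHits(hit), j)] <- TRUE
  } else {
    sets <- if (roi_type == "pathway") registry$pathways else registry$ppi
    for (id in ids) m[, id] <- variants$gene_id %in% sets[[id]]
  }
  m
}

axis_feature_ids <- function(registry, roi_type) {
  ids <- switch(roi_type,
    gene = S4Vectors::mcols(registry$genes)$gene_id,
    domain = S4Vectors::mcols(registry$domains)$domain_id,
    pathway = names(registry$pathways),
    ppi = names(registry$ppi),
    stop("unknown ROI type: ", roi_type))
  lex_sort(as.character(ids))
}

# gene set backing a feature: used for planted effects and overlap reports
feature_gene_set <- function(registry, roi_type, roi_id) {
  switch(roi_type,
    gene = roi_id,
    domain = S4Vectors::mcols(registry$domains)$gene_id[
      S4Vectors::mcols(registry$domains)$domain_id == roi_id],
    pathway = registry$pathways[[roi_id]],
    ppi = registry$ppi[[roi_id]],
    stop("unknown ROI type: ", roi_type))
}
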