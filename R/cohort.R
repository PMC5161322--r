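#' Cohorts: samples, labels and annotated variants
#'
#' A `roi_cohort` bundles an ordered sample vector, binary phenotype labels
#' (case = 1, control = 0), a variant table and a genotype matrix:
#' \describe{
#'   \item{samples}{character vector, the label-file order.}
#'   \item{labels}{named integer vector over `samples`, values 0/1.}
#'   \item{variants}{data.frame with `chrom`, `pos` (1-based), `ref`, `alt`,
#'     `gene_id`, `P` (deleteriousness in \[0,1\]) and `F` (population
#'     allele frequency; `NA` for novel alleles, floored at scoring time).}
#'   \item{geno}{integer matrix, variants x samples, allele-copy counts
#'     (zygosity) in \{0,1,2\}.}
#' }
#'
#' @param samples,labels,variants,geno components as described above.
#' @return An object of class `roi_cohort`.
#' @export
roi_cohort <- function(samples, labels, variants, geno) {
  samples <- as.character(samples)
  labels <- as.integer(labels[samples])
  names(labels) <- samples
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1 and cover every sample")
  if (sum(labels == 1L) < 1 || sum(labels == 0L) < 1)
    stop("cohort needs at least one case and one control")
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(variants) || ncol(geno) != length(samples))
    stop("genotype matrix must be variants x samples")
  if (!all(geno %in% c(0L, 1L, 2L)))
    stop("allele copy counts must be 0, 1 or 2")
  if (any(variants$P < 0 | variants$P > 1, na.rm = TRUE))
    stop("deleteriousness scores P must lie in [0, 1]")
  bad_f <- !is.na(variants$F) & (variants$F < 0 | variants$F > 1)
  if (any(bad_f)) stop("population frequencies F must lie in [0, 1] or be NA")
  colnames(geno) <- samples
  rownames(variants) <- NULL
  structure(list(samples = samples, labels = labels,
                 variants = variants, geno = geno),
            class = "roi_cohort")
}

#' @exportS3Method base::print
print.roi_cohort <- function(x, ...) {
  cat(sprintf("ROI cohort: %d samples (%d cases / %d controls), %d variants\n",
              length(x$samples), sum(x$labels == 1L), sum(x$labels == 0L),
              nrow(x$variants)))
  invisible(x)
}

# allele-copy count of alt allele `a` (1-based in the ALT list) from VCF GT
# strings; missing calls count as reference
gt_allele_counts <- function(gt, alt_index) {
  gt[is.na(gt)] <- "."           # missing calls count as reference
  gt <- sub(":.*", "", gt)
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(al) sum(al == as.character(alt_index)), integer(1))
}

#' Read a cohort from VCF, annotation table and label file
#'
#' Genotypes come from the VCF; `P` (deleteriousness), `F` (population
#' frequency) and the owning `gene_id` are joined from the annotation table,
#' keyed by `(chrom, pos, ref, alt)`. Variant-to-gene assignment is taken
#' from the annotation (the upstream annotator's call), never re-derived
#' from intervals. Variants missing from the annotation table, or annotated
#' without a usable deleteriousness score, are dropped with a logged count.
#' Multi-allelic records are split into one variant per alternate allele,
#' each with that allele's copy count.
#'
#' @param vcf_path VCF (v4.x) with GT genotypes for at least the labelled
#'   samples.
#' @param annotation_table_path TSV with header columns
#'   `chrom,pos,ref,alt,gene,score,freq`.
#' @param labels_path two-column TSV with header `sample,label`; labels are
#'   `case`/`control` or 1/0.
#' @return A [roi_cohort()] whose samples are the label-file samples, in
#'   label-file order.
#' @export
read_cohort <- function(vcf_path, annotation_table_path, labels_path) {
  lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "label") %in% names(lab)))
    stop("label file must have columns 'sample' and 'label'")
  labels <- parse_labels(lab$label)
  names(labels) <- as.character(lab$sample)

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt_raw <- vcf@gt
  if (ncol(gt_raw) && colnames(gt_raw)[1] == "FORMAT")
    gt_raw <- gt_raw[, -1, drop = FALSE]
  missing_samples <- setdiff(names(labels), colnames(gt_raw))
  if (length(missing_samples))
    stop("labelled sample(s) absent from VCF: ",
         paste(missing_samples, collapse = ", "))
  gt_raw <- gt_raw[, names(labels), drop = FALSE]

  # split multi-allelic records: one row per alternate allele
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  rec <- rep(seq_len(nrow(fix)), lengths(alts))
  aidx <- unlist(lapply(lengths(alts), seq_len), use.names = FALSE)
  variants <- data.frame(chrom = fix$CHROM[rec],
                         pos = as.integer(fix$POS[rec]),
                         ref = fix$REF[rec],
                         alt = unlist(alts, use.names = FALSE),
                         stringsAsFactors = FALSE)
  geno <- matrix(0L, nrow(variants), ncol(gt_raw),
                 dimnames = list(NULL, colnames(gt_raw)))
  for (i in seq_len(nrow(variants)))
    geno[i, ] <- gt_allele_counts(gt_raw[rec[i], ], aidx[i])

  ann <- utils::read.delim(annotation_table_path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "gene", "score", "freq")
  if (!all(need %in% names(ann)))
    stop("annotation table must have columns ",
         paste(need, collapse = ","))
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  j <- match(key(variants), key(ann))
  keep <- !is.na(j) & !is.na(ann$score[j]) & !is.na(ann$gene[j])
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("read_cohort: dropped %d unannotated or unscored variant allele(s)",
                    n_drop))
  variants <- variants[keep, , drop = FALSE]
  j <- j[keep]
  variants$gene_id <- as.character(ann$gene[j])
  variants$P <- as.numeric(ann$score[j])
  variants$F <- as.numeric(ann$freq[j])
  variants$F[!is.na(variants$F) & variants$F == 0] <- NA_real_
  roi_cohort(names(labels), labels, variants,
             geno[keep, , drop = FALSE])
}

parse_labels <- function(x) {
  x <- tolower(as.character(x))
  out <- ifelse(x %in% c("case", "1"), 1L,
                ifelse(x %in% c("control", "0"), 0L, NA_integer_))
  if (anyNA(out))
    stop("labels must be 'case'/'control' or 1/0; offending value: ",
         x[which(is.na(out))[1]])
  out
}

#' Write a cohort to VCF, annotation table and label file
#'
#' Emits exactly the formats [read_cohort()] consumes, so a cohort can make
#' a lossless round trip through the three files.
#'
#' @param cohort a [roi_cohort()].
#' @param vcf_path,annotation_table_path,labels_path output paths.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, vcf_path, annotation_table_path,
                         labels_path) {
  v <- cohort$variants
  gt <- matrix(c("0/0", "0/1", "1/1")[cohort$geno + 1L],
               nrow = nrow(v), dimnames = dimnames(cohort$geno))
  con <- file(vcf_path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "FORMAT", cohort$samples), collapse = "\t")), con)
  if (nrow(v) > 0) {
    body <- cbind(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", "GT", gt)
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  ann <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                    gene = v$gene_id, score = v$P, freq = v$F)
  utils::write.table(ann, annotation_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lab <- data.frame(sample = cohort$samples,
                    label = ifelse(cohort$labels == 1L, "case", "control"))
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(cohort)
}
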