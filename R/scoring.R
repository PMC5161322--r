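#' Scoring configuration for burden collapsing
#'
#' Each variant allele contributes
#' \deqn{v = \sigma \times P \times (-\log_{10} \max(F, f_0))}
#' to every ROI it maps to, where \eqn{\sigma \in \{0,1,2\}} is the allele
#' copy count, \eqn{P \in [0,1]} the predicted deleteriousness, \eqn{F} the
#' population allele frequency and \eqn{f_0} the frequency floor substituted
#' for missing or zero frequencies. The \eqn{-\log_{10}} weight penalizes
#' common variants: a fixed-\eqn{\sigma,P} contribution is strictly
#' decreasing in \eqn{F}, and vanishes at \eqn{F = 1}. Scores are reported
#' on the nonnegative scale (rarer = larger), a monotone relabeling of the
#' signed log that leaves rank-based tests and tree ensembles unchanged.
#'
#' @param freq_floor frequency substituted for missing/zero `F`. The default
#'   `1/5008` is one allele among the 2 x 2504 reference-panel haplotypes —
#'   the usual pseudo-frequency for an allele unobserved in the population
#'   panel.
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(freq_floor = 1 / 5008) {
  stopifnot(is.numeric(freq_floor), freq_floor > 0, freq_floor < 1)
  structure(list(freq_floor = freq_floor, log_base = 10), class = "scoring_config")
}

#' Per-variant burden contribution
#'
#' @param sigma allele copy count(s) in \{0,1,2\}.
#' @param P deleteriousness score(s) in \[0,1\].
#' @param F population allele frequency in \[0,1\], or `NA` for novel
#'   alleles (floored).
#' @param config a [scoring_config()].
#' @return `sigma * P * (-log10(max(F, freq_floor)))`, vectorized; zero iff
#'   `sigma = 0`, `P = 0` or `F = 1`.
#' @export
variant_score <- function(sigma, P, F, config = scoring_config()) {
  if (any(P < 0 | P > 1, na.rm = TRUE))
    stop("deleteriousness score P outside [0, 1]")
  stopifnot(all(sigma %in% c(0, 1, 2)))
  f <- pmax(ifelse(is.na(F), config$freq_floor, F), config$freq_floor)
  sigma * P * (-log10(f))
}

# per-variant weights (score of one copy) for a cohort's variant table
variant_weights <- function(variants, config) {
  variant_score(1, variants$P, variants$F, config)
}

#' Enumerate ROI-type combinations
#'
#' All non-empty subsets of the given ROI axes, in deterministic order
#' (by subset size, then by the canonical axis order
#' gene < domain < pathway < ppi). Four axes yield 15 combinations, one
#' dataset each.
#'
#' @param roi_types character vector of axis names (default all four).
#' @return List of character vectors.
#' @export
enumerate_combos <- function(roi_types = ROI_TYPES) {
  stopifnot(length(roi_types) >= 1, !anyDuplicated(roi_types),
            all(roi_types %in% ROI_TYPES))
  roi_types <- ROI_TYPES[ROI_TYPES %in% roi_types]
  out <- list()
  for (k in seq_along(roi_types))
    out <- c(out, utils::combn(roi_types, k, simplify = FALSE))
  out
}

combo_name <- function(combo) paste(combo, collapse = "+")

#' Build an individuals x ROI-features burden matrix
#'
#' Collapses every cohort variant into the features of the requested ROI
#' axes: the score of sample `i` for feature `j` is the sum of
#' [variant_score()] over all variants whose fan-out
#' ([map_variant_to_rois()]) includes `j`, with that sample's allele copy
#' counts. Features are ordered by axis (gene < domain < pathway < ppi)
#' then lexicographically by id, and named `"type:id"`. Columns of a
#' multi-axis matrix equal the column-concatenation of the single-axis
#' matrices.
#'
#' @param cohort a [roi_cohort()].
#' @param registry a [roi_registry()].
#' @param combo non-empty subset of `c("gene","domain","pathway","ppi")`.
#' @param config a [scoring_config()].
#' @return A `score_matrix`: numeric samples x features matrix with
#'   attributes `features` (data.frame `roi_type`, `roi_id`), `combo` and
#'   `config`.
#' @export
build_score_matrix <- function(cohort, registry, combo = ROI_TYPES,
                               config = scoring_config()) {
  if (length(combo) == 0) stop("combo must name at least one ROI axis")
  stopifnot(all(combo %in% ROI_TYPES))
  combo <- ROI_TYPES[ROI_TYPES %in% combo]
  w <- variant_weights(cohort$variants, config)
  contrib <- cohort$geno * w                     # variants x samples
  blocks <- lapply(combo, function(ax) {
    memb <- axis_membership(cohort$variants, registry, ax)
    scores <- t(crossprod(memb, contrib))        # samples x features
    if (ncol(memb))                              # paste0 pads empty axes
      colnames(scores) <- paste0(ax, ":", colnames(memb))
    scores
  })
  m <- do.call(cbind, blocks)
  rownames(m) <- cohort$samples
  feats <- data.frame(
    roi_type = sub(":.*", "", colnames(m)),
    roi_id = sub("^[a-z]+:", "", colnames(m)),
    stringsAsFactors = FALSE)
  structure(m, features = feats, combo = combo, config = config,
            class = c("score_matrix", "matrix", "array"))
}

#' Burden score of one sample for one ROI feature
#'
#' Scalar convenience wrapper around the same collapsing rule as
#' [build_score_matrix()].
#'
#' @param sample sample id.
#' @param roi_type,roi_id the feature.
#' @inheritParams build_score_matrix
#' @return A single burden score.
#' @export
roi_score <- function(sample, roi_type, roi_id, cohort, registry,
                      config = scoring_config()) {
  if (!roi_id %in% axis_feature_ids(registry, roi_type))
    stop(sprintf("unknown %s feature: %s", roi_type, roi_id))
  memb <- axis_membership(cohort$variants, registry, roi_type)[, roi_id]
  w <- variant_weights(cohort$variants, config)
  sum(w[memb] * cohort$geno[memb, sample])
}

#' Write / read a score matrix as TSV plus JSON sidecar
#'
#' The TSV has a `sample` first column and `type:id` feature headers; the
#' sidecar records the ROI combination, scoring configuration and axis
#' sizes so a matrix round-trips exactly.
#'
#' @param m a `score_matrix`.
#' @param tsv_path output TSV; the sidecar is written at
#'   `paste0(tsv_path, ".json")`.
#' @return Invisibly, the matrix.
#' @export
write_score_matrix <- function(m, tsv_path) {
  df <- data.frame(sample = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sizes <- table(attr(m, "features")$roi_type)
  jsonlite::write_json(
    list(combo = attr(m, "combo"),
         freq_floor = attr(m, "config")$freq_floor,
         axis_sizes = as.list(sizes)),
    paste0(tsv_path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(m)
}

#' @rdname write_score_matrix
#' @export
read_score_matrix <- function(tsv_path) {
  df <- utils::read.delim(tsv_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(tsv_path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample
  feats <- data.frame(roi_type = sub(":.*", "", colnames(m)),
                      roi_id = sub("^[a-z]+:", "", colnames(m)),
                      stringsAsFactors = FALSE)
  structure(m, features = feats, combo = side$combo,
            config = scoring_config(side$freq_floor),
            class = c("score_matrix", "matrix", "array"))
}
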