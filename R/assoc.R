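#' Two-group association test for one ROI feature
#'
#' The test is chosen by a per-group normality gate: Shapiro-Wilk is run on
#' each group, and only when both groups look Gaussian at `normality_alpha`
#' is a two-sided Welch t-test used; otherwise a two-sided Wilcoxon
#' rank-sum (Mann-Whitney) test. Groups with fewer than three distinct
#' observations, or constant groups, cannot pass the gate and fall through
#' to the rank-sum test. Burden score distributions are typically
#' zero-inflated and right-skewed, so the rank-sum branch is the common
#' path in practice.
#'
#' When both groups are constant and equal there is no signal of any kind;
#' the result carries `p_raw = 1` and is flagged degenerate.
#'
#' @param case_scores,control_scores numeric burden scores per group
#'   (each of length >= 2).
#' @param normality_alpha level of the Shapiro-Wilk gate.
#' @return List with `test_used` ("t" or "ranksum"), `statistic`, `p_raw`
#'   and `degenerate`.
#' @export
test_feature <- function(case_scores, control_scores,
                         normality_alpha = 0.05) {
  stopifnot(length(case_scores) >= 2, length(control_scores) >= 2)
  if (var(case_scores) == 0 && var(control_scores) == 0 &&
      case_scores[1] == control_scores[1])
    return(list(test_used = "ranksum", statistic = 0, p_raw = 1,
                degenerate = TRUE))
  gaussian <- function(x) {
    if (length(unique(x)) < 3 || length(x) < 3 || length(x) > 5000)
      return(FALSE)
    stats::shapiro.test(x)$p.value > normality_alpha
  }
  if (gaussian(case_scores) && gaussian(control_scores)) {
    ht <- stats::t.test(case_scores, control_scores)
    list(test_used = "t", statistic = unname(ht$statistic),
         p_raw = ht$p.value, degenerate = FALSE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(case_scores, control_scores))
    list(test_used = "ranksum", statistic = unname(ht$statistic),
         p_raw = ht$p.value, degenerate = FALSE)
  }
}

#' Bonferroni adjustment within one ROI axis
#'
#' Multiplies each raw p-value by the number of features tested on the
#' axis, capped at 1, and flags significance at `alpha`. Results must all
#' belong to a single axis: the multiplicity family is the axis, not the
#' pooled feature set.
#'
#' @param results data.frame of per-feature results sharing one `roi_type`.
#' @param alpha familywise significance level.
#' @return `results` with `p_adjusted` and `significant` columns.
#' @export
adjust_axis <- function(results, alpha = 0.05) {
  if (length(unique(results$roi_type)) > 1)
    stop("adjust_axis expects results from a single ROI axis")
  m <- nrow(results)
  results$p_adjusted <- pmin(1, results$p_raw * m)
  results$significant <- results$p_adjusted < alpha
  results
}

#' Per-ROI univariate association over a score matrix
#'
#' Runs [test_feature()] on every column of the matrix and applies
#' Bonferroni correction per ROI axis (or across all features when
#' `per_axis = FALSE`).
#'
#' @param m a `score_matrix` from [build_score_matrix()].
#' @param labels named 0/1 vector over the matrix rows (1 = case).
#' @param alpha familywise significance level.
#' @param normality_alpha level of the Shapiro-Wilk gate in
#'   [test_feature()].
#' @param per_axis whether the Bonferroni family is each axis (default) or
#'   the whole matrix.
#' @param registry optional [roi_registry()]; when given, each row carries
#'   `related_genes`, the comma-joined panel gene set backing the feature.
#' @return An `association_table`: data.frame with one row per feature
#'   (`roi_type`, `roi_id`, `test_used`, `statistic`, `p_raw`,
#'   `p_adjusted`, `significant`, `degenerate`, optionally
#'   `related_genes`).
#' @export
associate <- function(m, labels, alpha = 0.05, normality_alpha = 0.05,
                      per_axis = TRUE, registry = NULL) {
  labels <- labels[rownames(m)]
  if (anyNA(labels)) stop("labels must cover every matrix row")
  feats <- attr(m, "features")
  res <- lapply(seq_len(ncol(m)), function(j) {
    r <- test_feature(m[labels == 1L, j], m[labels == 0L, j],
                      normality_alpha)
    data.frame(roi_type = feats$roi_type[j], roi_id = feats$roi_id[j],
               test_used = r$test_used, statistic = r$statistic,
               p_raw = r$p_raw, degenerate = r$degenerate,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (per_axis) {
    parts <- split(res, res$roi_type)
    res <- do.call(rbind, lapply(parts, adjust_axis, alpha = alpha))
  } else {
    res$p_adjusted <- pmin(1, res$p_raw * nrow(res))
    res$significant <- res$p_adjusted < alpha
  }
  res <- res[order(match(res$roi_type, ROI_TYPES), res$roi_id,
                   method = "radix"), ]
  rownames(res) <- NULL
  if (!is.null(registry))
    res$related_genes <- mapply(function(ty, id)
      paste(lex_sort(unique(feature_gene_set(registry, ty, id))),
            collapse = ","),
      res$roi_type, res$roi_id, USE.NAMES = FALSE)
  class(res) <- c("association_table", "data.frame")
  res
}

#' Containment graph of significant ROIs
#'
#' Builds the directed overlap graph of significant features: an edge
#' `x -> y` means the gene set of `x` is contained in the member set of
#' `y`. Domains point at their (significant) owning genes, genes at
#' (significant) pathways containing them and at (significant) PPI
#' neighbourhoods they belong to. A significant domain whose owning gene
#' is not itself significant simply has no outgoing gene edge.
#'
#' @param results an `association_table` (only rows with
#'   `significant == TRUE` are used).
#' @param registry the [roi_registry()] the scores were built from.
#' @return data.frame edge list with columns `from`, `from_type`, `to`,
#'   `to_type`.
#' @export
overlap_report <- function(results, registry) {
  sig <- results[results$significant, , drop = FALSE]
  edges <- list()
  contained <- function(x_genes, y_genes)
    length(x_genes) > 0 && all(x_genes %in% y_genes)
  add <- function(from_row, to_row) {
    data.frame(from = from_row$roi_id, from_type = from_row$roi_type,
               to = to_row$roi_id, to_type = to_row$roi_type,
               stringsAsFactors = FALSE)
  }
  pairs <- list(c("domain", "gene"), c("gene", "pathway"), c("gene", "ppi"))
  for (p in pairs) {
    xs <- sig[sig$roi_type == p[1], , drop = FALSE]
    ys <- sig[sig$roi_type == p[2], , drop = FALSE]
    for (i in seq_len(nrow(xs))) for (j in seq_len(nrow(ys))) {
      xg <- feature_gene_set(registry, p[1], xs$roi_id[i])
      yg <- feature_gene_set(registry, p[2], ys$roi_id[j])
      if (contained(xg, yg)) edges[[length(edges) + 1]] <- add(xs[i, ], ys[j, ])
    }
  }
  if (length(edges) == 0)
    return(data.frame(from = character(), from_type = character(),
                      to = character(), to_type = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, edges)
}

#' Write an overlap graph in DOT format
#'
#' @param edges edge list from [overlap_report()].
#' @param path output `.dot` file.
#' @return Invisibly, the path.
#' @export
write_overlap_dot <- function(edges, path) {
  lines <- c("digraph roi_overlap {",
             sprintf('  "%s:%s" -> "%s:%s";', edges$from_type, edges$from,
                     edges$to_type, edges$to),
             "}")
  writeLines(lines, path)
  invisible(path)
}
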