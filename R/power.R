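#' Simulation-based univariate power for one ROI feature
#'
#' Mirrors the per-feature power recipe used for burden scores: (i) draw
#' case and control samples from normal distributions with the observed
#' class-wise mean, standard deviation and size; (ii) report the
#' standardized effect as Cohen's d with pooled standard deviation;
#' (iii) run a two-sided Wilcoxon rank-sum test on every draw and report
#' power as the rejection fraction at `alpha`. The normal family is the
#' distribution fully parameterized by the three observed summaries.
#'
#' When both groups are degenerate (zero spread, equal means) the test has
#' no information; power is reported as `alpha` by convention and flagged.
#'
#' @param mean_case,sd_case,n_case observed case summaries.
#' @param mean_ctrl,sd_ctrl,n_ctrl observed control summaries.
#' @param alpha test level.
#' @param n_sim number of simulated cohorts (>= 100).
#' @param seed RNG seed.
#' @return List with `cohens_d`, `power`, `n_sim`, `alpha`, `degenerate`.
#' @export
univariate_power <- function(mean_case, sd_case, n_case,
                             mean_ctrl, sd_ctrl, n_ctrl,
                             alpha = 0.05, n_sim = 2000, seed = 1) {
  stopifnot(sd_case >= 0, sd_ctrl >= 0, n_case >= 2, n_ctrl >= 2,
            n_sim >= 100)
  sd_pooled <- sqrt(((n_case - 1) * sd_case^2 + (n_ctrl - 1) * sd_ctrl^2) /
                      (n_case + n_ctrl - 2))
  if (sd_pooled == 0 && mean_case == mean_ctrl)
    return(list(cohens_d = 0, power = alpha, n_sim = n_sim, alpha = alpha,
                degenerate = TRUE))
  d <- if (sd_pooled == 0) Inf else (mean_case - mean_ctrl) / sd_pooled
  rej <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      x1 <- rnorm(n_case, mean_case, sd_case)
      x0 <- rnorm(n_ctrl, mean_ctrl, sd_ctrl)
      suppressWarnings(stats::wilcox.test(x1, x0)$p.value) < alpha
    }, logical(1))
  })
  list(cohens_d = d, power = mean(rej), n_sim = n_sim, alpha = alpha,
       degenerate = FALSE)
}

#' Learning curve: sensitivity versus cohort size
#'
#' Empirical power analysis of the multivariate model: for each size `s` in
#' the grid, repeatedly draw a stratified subsample of `s` individuals, run
#' `folds`-fold cross-validation of a random forest with \emph{fixed}
#' parameters (the feature set and tree count retained by the evaluation
#' protocol — nothing is re-optimized inside the curve), and record the
#' sensitivity (recall on cases) of the pooled out-of-fold predictions.
#' The curve reports the mean sensitivity per size with a 95% normal
#' confidence half-width over the repeats, and the plateau size: the
#' smallest size whose confidence interval reaches the maximum of the mean
#' curve.
#'
#' @param m samples x features score matrix.
#' @param labels named 0/1 vector over the matrix rows.
#' @param fixed_params list with `features` (character vector of matrix
#'   columns, or `"all"`) and `n_trees`.
#' @param sample_grid cohort sizes to evaluate; sizes below `folds` are
#'   skipped with a warning, sizes above the cohort are an error.
#' @param repeats subsample/CV repetitions per size.
#' @param folds cross-validation folds.
#' @param seed base seed; each (size, repeat) gets its own derived stream.
#' @return A `learning_curve` data.frame (`size`, `sensitivity`, `ci95`)
#'   with attribute `plateau_size`.
#' @export
learning_curve <- function(m, labels, fixed_params,
                           sample_grid = c(5, 6, 7, 8, 9, 10, seq(20, 140, 10),
                                           145, nrow(m)),
                           repeats = 100, folds = 5, seed = 1) {
  labels <- labels[rownames(m)]
  sample_grid <- sort(unique(pmin(sample_grid, nrow(m))))
  if (any(sample_grid < folds)) {
    warning("sizes below the fold count skipped")
    sample_grid <- sample_grid[sample_grid >= folds]
  }
  feats <- fixed_params$features
  if (identical(feats, "all")) feats <- colnames(m)
  x <- m[, feats, drop = FALSE]
  rows <- lapply(seq_along(sample_grid), function(si) {
    s <- sample_grid[si]
    sens <- vapply(seq_len(repeats), function(r) {
      sub <- stratified_subsample(labels, s, seed + si * 10000 + r)
      cv_sensitivity(x[sub, , drop = FALSE], labels[sub],
                     fixed_params$n_trees, folds,
                     seed + si * 10000 + r)
    }, numeric(1))
    data.frame(size = s, sensitivity = mean(sens),
               ci95 = 1.96 * stats::sd(sens) / sqrt(repeats))
  })
  out <- do.call(rbind, rows)
  peak <- max(out$sensitivity)
  reach <- out$sensitivity + out$ci95 >= peak
  attr(out, "plateau_size") <- out$size[which(reach)[1]]
  class(out) <- c("learning_curve", "data.frame")
  out
}

# stratified subsample of size s preserving class proportions; redraws via
# complement when rounding strips a class entirely
stratified_subsample <- function(labels, s, seed) {
  with_seed(seed, {
    n <- length(labels)
    idx_by_class <- split(seq_len(n), labels)
    take <- round(s * lengths(idx_by_class) / n)
    # keep at least one member of each class and exactly s in total
    take <- pmax(take, 1L)
    while (sum(take) != s) {
      i <- which.max(lengths(idx_by_class) - take)
      if (sum(take) < s) take[i] <- take[i] + 1L
      else {
        i <- which.max(take)
        take[i] <- take[i] - 1L
      }
    }
    sort(unlist(mapply(function(idx, k) sample(idx, k), idx_by_class, take,
                       SIMPLIFY = FALSE), use.names = FALSE))
  })
}

cv_sensitivity <- function(x, y, n_trees, folds, seed) {
  y <- as.integer(y)
  fold <- stratified_folds(y, folds, seed)
  pred <- rep(NA_integer_, length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f; va <- fold == f
    if (!any(va)) next
    if (length(unique(y[tr])) < 2) next
    fit <- with_seed(seed * 53 + f,
                     rf_fit(x[tr, , drop = FALSE], y[tr], n_trees))
    pred[va] <- as.integer(rf_prob(fit, x[va, , drop = FALSE]) >= 0.5)
  }
  ok <- !is.na(pred) & y == 1L
  if (!any(ok)) return(NA_real_)
  mean(pred[ok] == 1L)
}
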