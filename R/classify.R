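#' Configuration of the multivariate evaluation protocol
#'
#' The protocol, per dataset (ROI combination): repeat `repetitions` times
#' {stratified 70/30 train/test split; grid search over (number of selected
#' features) x (number of trees) by stratified `folds`-fold cross-validation
#' on the training set, with feature ranking re-run inside every fold so
#' the validation rows never inform the selection; refit on the whole
#' training set with the winning pair (ranking recomputed on the whole
#' training set); score the held-out test set}. AUC and the Matthews
#' correlation coefficient are reported per repetition and averaged.
#'
#' @param train_frac training fraction of the split.
#' @param folds cross-validation folds.
#' @param repetitions number of independent split/tune/test repetitions.
#' @param feature_grid numbers of selected features to try; the string
#'   `"all"` means no selection.
#' @param tree_grid numbers of random-forest trees to try. All other forest
#'   parameters stay at the library defaults.
#' @param cv_metric metric maximized in the grid search: `"auc"` (default)
#'   or `"mcc"`.
#' @param seed base seed; repetition r uses `seed + r` so every repetition
#'   is independently reproducible.
#' @param search a [search_config()] for the per-fold feature ranking.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(train_frac = 0.7, folds = 5, repetitions = 10,
                        feature_grid = list(5, 10, 25, 50, 100, "all"),
                        tree_grid = c(5, 10, 50, 100, 150, 200, 250, 300,
                                      350, 400, 450, 500),
                        cv_metric = c("auc", "mcc"), seed = 1,
                        search = search_config()) {
  stopifnot(train_frac > 0, train_frac < 1, folds >= 2, repetitions >= 1,
            length(feature_grid) >= 1, length(tree_grid) >= 1)
  structure(list(train_frac = train_frac, folds = as.integer(folds),
                 repetitions = as.integer(repetitions),
                 feature_grid = as.list(feature_grid),
                 tree_grid = tree_grid, cv_metric = match.arg(cv_metric),
                 seed = seed, search = search),
            class = "eval_config")
}

#' Matthews correlation coefficient from confusion counts
#'
#' @param tp,fp,tn,fn nonnegative confusion-matrix counts.
#' @return MCC in \[-1, 1\]; by convention 0 when any marginal is zero.
#' @export
mcc <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

#' Rank-based AUC (Mann-Whitney, midranks for ties)
#'
#' @param scores numeric classifier scores, larger = more case-like.
#' @param labels 0/1 vector, 1 = case.
#' @return AUC in \[0, 1\]; 0.5 when all scores tie.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified train/test split
#'
#' Samples `round(train_frac * n_class)` members of each class into the
#' training set, so class proportions are preserved within rounding; the
#' split is disjoint, exhaustive and a deterministic function of the seed.
#'
#' @param labels named 0/1 vector.
#' @param train_frac training fraction.
#' @param seed RNG seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_cohort <- function(labels, train_frac = 0.7, seed = 1) {
  classes <- split(seq_along(labels), labels)
  if (any(lengths(classes) < 2))
    stop("each class needs at least 2 samples to split")
  with_seed(seed, {
    train <- unlist(lapply(classes, function(idx) {
      n_tr <- round(length(idx) * train_frac)
      sample(idx, n_tr)
    }), use.names = FALSE)
    list(train = sort(train),
         test = sort(setdiff(seq_along(labels), train)))
  })
}

# per-class round-robin fold assignment after shuffling; every fold gets
# within-1 balanced class counts, so a fold can miss a class only when the
# class itself has fewer members than folds
stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (idx in split(seq_along(labels), labels))
      fold[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    fold
  })
}

rf_fit <- function(x, y, ntree) {
  randomForest::randomForest(x = as.data.frame(x),
                             y = factor(y, levels = c(0, 1)),
                             ntree = ntree)
}

rf_prob <- function(fit, x) {
  unname(stats::predict(fit, as.data.frame(x), type = "prob")[, "1"])
}

eval_metric <- function(prob, y, metric) {
  if (metric == "auc") return(auc(prob, y))
  pred <- as.integer(prob >= 0.5)
  mcc(sum(pred == 1 & y == 1), sum(pred == 1 & y == 0),
      sum(pred == 0 & y == 0), sum(pred == 0 & y == 1))
}

#' Cross-validated grid search over (feature count, tree count)
#'
#' For each fold, features are ranked on the fold's training portion only;
#' each `(k, n_trees)` pair is then fit on the fold-train top-`k` columns
#' and scored on the fold's validation portion. The winning pair maximizes
#' the mean validation metric; ties prefer fewer features, then fewer
#' trees. Folds whose validation part lacks a class are skipped with a
#' message (only possible when a class has fewer members than folds).
#'
#' @param m training samples x features matrix.
#' @param labels named 0/1 vector over the matrix rows.
#' @param config an [eval_config()].
#' @return List with `best_k` (grid label), `best_trees` and the full
#'   `cv_results` data.frame (`k`, `n_trees`, `mean_metric`).
#' @export
tune <- function(m, labels, config = eval_config()) {
  labels <- as.integer(labels[rownames(m)])
  fold <- stratified_folds(labels, config$folds, config$seed)
  ks <- config$feature_grid
  grid <- expand.grid(ki = seq_along(ks),
                      n_trees = config$tree_grid)
  acc <- matrix(NA_real_, nrow(grid), config$folds)
  need_ranking <- !all(vapply(ks, identical, logical(1), "all"))
  for (f in seq_len(config$folds)) {
    tr <- fold != f; va <- fold == f
    if (length(unique(labels[va])) < 2 || length(unique(labels[tr])) < 2) {
      message(sprintf("tune: fold %d lacks a class in train or validation; skipped", f))
      next
    }
    ranking <- if (need_ranking)
      rank_features(m[tr, , drop = FALSE], setNames(labels, rownames(m))[tr],
                    modifyList(config$search,
                               list(seed = (config$search$seed %||% config$seed) + f)))
    for (gi in seq_len(nrow(grid))) {
      k <- ks[[grid$ki[gi]]]
      feats <- if (identical(k, "all")) colnames(m)
               else suppressWarnings(select_top(ranking, k))
      fit <- with_seed(config$seed * 131 + f,
                       rf_fit(m[tr, feats, drop = FALSE], labels[tr],
                              grid$n_trees[gi]))
      prob <- rf_prob(fit, m[va, feats, drop = FALSE])
      acc[gi, f] <- eval_metric(prob, labels[va], config$cv_metric)
    }
  }
  mean_metric <- rowMeans(acc, na.rm = TRUE)
  k_size <- vapply(seq_along(ks), function(i)
    if (identical(ks[[i]], "all")) ncol(m) + 1 else as.numeric(ks[[i]]),
    numeric(1))
  ord <- order(-mean_metric, k_size[grid$ki], grid$n_trees)
  best <- grid[ord[1], ]
  list(best_k = ks[[best$ki]], best_trees = best$n_trees,
       cv_results = data.frame(
         k = vapply(grid$ki, function(i) as.character(ks[[i]]), character(1)),
         n_trees = grid$n_trees, mean_metric = mean_metric))
}

#' Run the full multivariate evaluation protocol
#'
#' Builds the burden matrix for each requested ROI combination and runs the
#' repeated split / tune / refit / test protocol described in
#' [eval_config()]. The refit on the whole training set recomputes the
#' feature ranking on all training rows and keeps the tuned `k` and tree
#' count; the test rows never enter ranking, tuning or fitting.
#'
#' @param cohort a [roi_cohort()].
#' @param registry a [roi_registry()].
#' @param combos list of ROI-type subsets (default: all 15).
#' @param config an [eval_config()].
#' @param scoring a [scoring_config()].
#' @return A named list (one entry per combination) of
#'   `evaluation_report`s: `combo`, `per_rep` (seed, best_k, best_trees,
#'   auc, mcc), `mean_auc`, `mean_mcc`.
#' @export
run_protocol <- function(cohort, registry, combos = enumerate_combos(),
                         config = eval_config(),
                         scoring = scoring_config()) {
  reports <- lapply(combos, function(combo) {
    m <- build_score_matrix(cohort, registry, combo, scoring)
    labels <- cohort$labels
    per_rep <- lapply(seq_len(config$repetitions), function(r) {
      rep_seed <- config$seed + r
      sp <- split_cohort(labels, config$train_frac, rep_seed)
      m_tr <- m[sp$train, , drop = FALSE]
      y_tr <- labels[sp$train]
      rep_cfg <- config
      rep_cfg$seed <- rep_seed
      tuned <- tune(m_tr, y_tr, rep_cfg)
      feats <- if (identical(tuned$best_k, "all")) colnames(m) else {
        ranking <- rank_features(m_tr, y_tr,
                                 modifyList(config$search,
                                            list(seed = rep_seed * 17)))
        suppressWarnings(select_top(ranking, tuned$best_k))
      }
      fit <- with_seed(rep_seed * 29,
                       rf_fit(m_tr[, feats, drop = FALSE], y_tr,
                              tuned$best_trees))
      prob <- rf_prob(fit, m[sp$test, feats, drop = FALSE])
      y_te <- labels[sp$test]
      pred <- as.integer(prob >= 0.5)
      data.frame(seed = rep_seed, best_k = as.character(tuned$best_k),
                 best_trees = tuned$best_trees,
                 auc = auc(prob, y_te),
                 mcc = mcc(sum(pred == 1 & y_te == 1),
                           sum(pred == 1 & y_te == 0),
                           sum(pred == 0 & y_te == 0),
                           sum(pred == 0 & y_te == 1)),
                 stringsAsFactors = FALSE)
    })
    per_rep <- do.call(rbind, per_rep)
    structure(list(combo = combo, per_rep = per_rep,
                   mean_auc = mean(per_rep$auc),
                   mean_mcc = mean(per_rep$mcc)),
              class = "evaluation_report")
  })
  names(reports) <- vapply(combos, combo_name, character(1))
  reports
}

#' @exportS3Method base::print
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation report [%s]: mean AUC %.3f, mean MCC %.3f over %d repetitions\n",
              combo_name(x$combo), x$mean_auc, x$mean_mcc, nrow(x$per_rep)))
  invisible(x)
}

#' Summarize evaluation reports across datasets
#'
#' @param reports list of `evaluation_report`s from [run_protocol()].
#' @return data.frame with one row per ROI combination and its averaged
#'   test AUC and MCC.
#' @export
report_summary <- function(reports) {
  do.call(rbind, lapply(reports, function(r)
    data.frame(combo = combo_name(r$combo), mean_auc = r$mean_auc,
               mean_mcc = r$mean_mcc, stringsAsFactors = FALSE)))
}
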