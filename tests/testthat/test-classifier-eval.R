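test_that("MCC follows the confusion-matrix formula with the zero-marginal convention", {
  expect_equal(mcc(10, 0, 10, 0), 1)
  expect_equal(mcc(0, 10, 0, 10), -1)
  expect_equal(mcc(6, 2, 5, 3), 0.38, tolerance = 0.005 / 0.38)
  expect_equal(mcc(6, 2, 5, 3),
               (6 * 5 - 2 * 3) / sqrt(8 * 9 * 7 * 8))
  expect_equal(mcc(5, 5, 0, 0), 0)  # a zero marginal
})

test_that("AUC is the Mann-Whitney statistic with midranks", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
  # exhaustive pair-counting oracle, including a tie
  s <- c(0.9, 0.7, 0.7, 0.4, 0.3, 0.1)
  y <- c(1, 1, 0, 1, 0, 0)
  pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
  oracle <- mean(ifelse(s[pairs$i] > s[pairs$j], 1,
                        ifelse(s[pairs$i] == s[pairs$j], 0.5, 0)))
  expect_equal(auc(s, y), oracle)
})

test_that("splits are stratified, exhaustive and seed-deterministic", {
  y <- setNames(rep(c(1L, 0L), each = 50), sprintf("s%03d", 1:100))
  sp <- split_cohort(y, 0.7, seed = 4)
  expect_length(sp$train, 70)
  expect_length(sp$test, 30)
  expect_equal(sum(y[sp$train]), 35)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_identical(sp, split_cohort(y, 0.7, seed = 4))

  y2 <- setNames(rep(c(1L, 0L), c(85, 61)), sprintf("s%03d", 1:146))
  sp2 <- split_cohort(y2, 0.7, seed = 5)
  n_tr <- length(sp2$train)
  expect_lte(abs(n_tr - 102), 1)
  case_frac <- sum(y2[sp2$train]) / n_tr
  expect_lte(abs(case_frac - 85 / 146) * n_tr, 1)
  expect_error(split_cohort(setNames(c(1L, 0L, 0L), letters[1:3])), "at least 2")
})

sep_matrix <- function(n = 40, d = 6, gap = 3, seed = 81) {
  set.seed(seed)
  y <- setNames(rep(c(1L, 0L), each = n / 2), sprintf("s%03d", seq_len(n)))
  m <- matrix(rnorm(n * d), n, d,
              dimnames = list(names(y), sprintf("f%02d", seq_len(d))))
  m[, 1] <- m[, 1] + gap * y
  list(m = m, y = y)
}

small_eval <- function(feature_grid, tree_grid, seed = 1)
  eval_config(repetitions = 1, feature_grid = feature_grid,
              tree_grid = tree_grid, seed = seed,
              search = search_config(prior_model_size = 2, prior_variance = 1,
                                     iterations = 2000, burn_in = 400))

test_that("tuning returns the single grid point unchanged and finds separable data", {
  fx <- sep_matrix()
  t1 <- tune(fx$m, fx$y, small_eval(list(2), c(40)))
  expect_equal(t1$best_k, 2)
  expect_equal(t1$best_trees, 40)
  fx_wide <- sep_matrix(gap = 8)
  t2 <- tune(fx_wide$m, fx_wide$y, small_eval(list(2, "all"), c(30, 60)))
  expect_equal(max(t2$cv_results$mean_metric), 1)
})

test_that("grid search equals brute-force evaluation of every pair", {
  fx <- sep_matrix(gap = 0.8, seed = 82)
  grid_k <- list(2, "all"); grid_t <- c(25, 60)
  full <- tune(fx$m, fx$y, small_eval(grid_k, grid_t, seed = 7))
  # oracle: score each (k, trees) pair on its own and pick the best with
  # the smaller-k / fewer-trees tie rule
  singles <- expand.grid(ki = 1:2, ti = 1:2)
  vals <- mapply(function(ki, ti)
    tune(fx$m, fx$y, small_eval(grid_k[ki], grid_t[ti], seed = 7))$cv_results$mean_metric,
    singles$ki, singles$ti)
  ksize <- c(2, ncol(fx$m) + 1)[singles$ki]
  best <- order(-vals, ksize, grid_t[singles$ti])[1]
  expect_equal(as.character(full$best_k),
               as.character(grid_k[[singles$ki[best]]]))
  expect_equal(full$best_trees, grid_t[singles$ti[best]])
  # and the full cv table contains exactly those four means
  expect_equal(sort(full$cv_results$mean_metric), sort(vals))
})

test_that("tuned parameters never depend on test rows", {
  fx <- sep_matrix(gap = 1, seed = 83)
  sp <- split_cohort(fx$y, 0.7, seed = 2)
  cfg <- small_eval(list(2, "all"), c(30), seed = 3)
  t_ref <- tune(fx$m[sp$train, ], fx$y[sp$train], cfg)
  m_pert <- fx$m
  m_pert[sp$test, ] <- m_pert[sp$test, ] + matrix(rnorm(length(sp$test) * ncol(fx$m), sd = 10),
                                                  length(sp$test))
  t_pert <- tune(m_pert[sp$train, ], fx$y[sp$train], cfg)
  expect_identical(t_ref, t_pert)
})

test_that("the full protocol is deterministic and keeps honest books", {
  cfg <- small_sim_config(seed = 41, n_cases = 18, n_controls = 14)
  reg <- generate_topology(cfg)
  co <- generate_cohort(reg, cfg)$cohort
  ec <- eval_config(repetitions = 2, feature_grid = list(2, "all"),
                    tree_grid = c(30), seed = 11,
                    search = search_config(prior_model_size = 2,
                                           prior_variance = 1,
                                           iterations = 1500, burn_in = 300))
  r1 <- run_protocol(co, reg, list("gene", c("gene", "pathway")), ec)
  r2 <- run_protocol(co, reg, list("gene", c("gene", "pathway")), ec)
  expect_identical(r1, r2)
  expect_named(r1, c("gene", "gene+pathway"))
  for (rep in r1) {
    expect_equal(rep$mean_auc, mean(rep$per_rep$auc))
    expect_equal(rep$mean_mcc, mean(rep$per_rep$mcc))
    expect_true(all(rep$per_rep$auc >= 0 & rep$per_rep$auc <= 1))
    expect_true(all(rep$per_rep$mcc >= -1 & rep$per_rep$mcc <= 1))
  }
  smry <- report_summary(r1)
  expect_equal(smry$mean_auc, vapply(r1, `[[`, numeric(1), "mean_auc"),
               ignore_attr = TRUE)
})
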