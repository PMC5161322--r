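#' Configuration of the stochastic feature search
#'
#' The search is a Metropolis-Hastings chain over binary feature-inclusion
#' vectors. A model (an included subset) is scored by the BIC of the
#' linear-probability fit of the 0/1 outcome on the standardized included
#' columns, used as a marginal-likelihood approximation, plus a model-size
#' prior. The size prior is Beta-Binomial with the requested mean and
#' variance when that pair is feasible, degrading to Binomial when the
#' requested variance is below the Binomial's. Features are ranked by their
#' posterior inclusion probability, the post-burn-in frequency with which
#' the chain includes them.
#'
#' @param prior_model_size expected number of included features.
#' @param prior_variance variance of the model-size prior.
#' @param iterations total MCMC sweeps.
#' @param burn_in sweeps discarded before inclusion frequencies are
#'   accumulated.
#' @param seed RNG seed; the ranking is bit-reproducible given the seed.
#' @return An object of class `search_config`.
#' @export
search_config <- function(prior_model_size = 20, prior_variance = 10,
                          iterations = 100000, burn_in = 10000,
                          seed = NULL) {
  stopifnot(prior_model_size >= 1, prior_variance > 0,
            burn_in < iterations)
  structure(list(prior_model_size = prior_model_size,
                 prior_variance = prior_variance,
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), seed = seed),
            class = "search_config")
}

# run expr under a deterministic RNG stream without disturbing the caller's
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# log prior of an inclusion vector of size k among d features
size_log_prior <- function(d, mu, v) {
  mu <- min(mu, max(1, floor(d / 2)))
  p <- mu / d
  c_binom <- d * p * (1 - p)
  if (v > c_binom && v < c_binom * d) {
    s <- (c_binom * d - v) / (v - c_binom)
    a <- p * s; b <- (1 - p) * s
    function(k) lbeta(a + k, b + d - k) - lbeta(a, b)
  } else {
    function(k) k * log(p) + (d - k) * log(1 - p)
  }
}

# scorer over inclusion index vectors: BIC-based log posterior of the
# linear-probability model plus the size prior
make_model_scorer <- function(x, y, config) {
  n <- nrow(x); d <- ncol(x)
  xs <- scale(x)
  y0 <- y - mean(y)
  xtx <- crossprod(xs)
  xty <- drop(crossprod(xs, y0))
  syy <- sum(y0^2)
  lprior <- size_log_prior(d, config$prior_model_size, config$prior_variance)
  function(idx) {
    k <- length(idx)
    if (k >= n - 2) return(-Inf)
    rss <- if (k == 0) syy else {
      b <- tryCatch(solve(xtx[idx, idx, drop = FALSE], xty[idx]),
                    error = function(e) NULL)
      if (is.null(b)) return(-Inf)
      max(syy - sum(b * xty[idx]), 1e-12)
    }
    bic <- n * log(rss / n) + (k + 1) * log(n)
    -bic / 2 + lprior(k)
  }
}

#' Rank features by posterior inclusion probability
#'
#' Runs the Metropolis-Hastings stochastic search described in
#' [search_config()] over the columns of a score matrix. Proposals toggle
#' one feature or swap an included feature with an excluded one (both
#' symmetric). Constant (zero-variance) columns are excluded from the
#' search and reported with inclusion probability zero.
#'
#' @param m numeric samples x features matrix (e.g. a `score_matrix`).
#' @param labels named 0/1 vector over the matrix rows.
#' @param config a [search_config()].
#' @return A `boss_ranking` data.frame: `feature`, `inclusion_prob`,
#'   `rank`, `constant`; sorted by descending inclusion probability with
#'   lexicographic id tie-break. Attribute `visited_models` counts the
#'   distinct models visited after burn-in.
#' @export
rank_features <- function(m, labels, config = search_config()) {
  labels <- labels[rownames(m)]
  if (anyNA(labels)) stop("labels must cover every matrix row")
  if (ncol(m) < 2) stop("need at least two features to rank")
  const <- apply(m, 2, function(col) var(col) == 0)
  if (any(const))
    message(sprintf("rank_features: %d constant feature(s) excluded",
                    sum(const)))
  active <- which(!const)
  x <- m[, active, drop = FALSE]
  d <- ncol(x)
  scorer <- make_model_scorer(x, as.numeric(labels), config)
  counts <- numeric(d)
  n_keep <- config$iterations - config$burn_in
  visited <- new.env(hash = TRUE)
  with_seed(config$seed, {
    incl <- logical(d)
    lp <- scorer(integer(0))
    for (it in seq_len(config$iterations)) {
      k <- sum(incl)
      do_swap <- runif(1) < 0.5
      # an infeasible swap (empty or full model) is a rejected no-op so the
      # proposal kernel stays symmetric at the boundaries
      if (!do_swap || (k > 0 && k < d)) {
        prop <- incl
        if (do_swap) {
          ins <- which(incl); outs <- which(!incl)
          prop[ins[sample.int(length(ins), 1)]] <- FALSE
          prop[outs[sample.int(length(outs), 1)]] <- TRUE
        } else {
          j <- sample.int(d, 1)
          prop[j] <- !prop[j]
        }
        lp_prop <- scorer(which(prop))
        if (log(runif(1)) < lp_prop - lp) {
          incl <- prop
          lp <- lp_prop
        }
      }
      if (it > config$burn_in) {
        counts[incl] <- counts[incl] + 1
        key <- paste0("m", paste(which(incl), collapse = ","))
        if (is.null(visited[[key]])) visited[[key]] <- TRUE
      }
    }
  })
  prob <- numeric(ncol(m))
  prob[active] <- counts / n_keep
  out <- data.frame(feature = colnames(m), inclusion_prob = prob,
                    constant = const, stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[order(-out$inclusion_prob, out$feature, method = "radix"), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "visited_models") <- length(ls(visited))
  class(out) <- c("boss_ranking", "data.frame")
  out
}

#' Select the top-k features of a ranking
#'
#' @param ranking a `boss_ranking` from [rank_features()].
#' @param k number of features, or `"all"`. `k` larger than the number of
#'   ranked features returns all of them with a warning (grids applied to
#'   small axes hit this routinely).
#' @return Character vector of feature names, in ranking order (descending
#'   inclusion probability, lexicographic tie-break).
#' @export
select_top <- function(ranking, k) {
  d <- nrow(ranking)
  if (identical(k, "all")) return(ranking$feature)
  k <- as.integer(k)
  stopifnot(k >= 1)
  if (k > d) {
    warning(sprintf("k = %d exceeds the %d ranked features; returning all",
                    k, d))
    k <- d
  }
  ranking$feature[seq_len(k)]
}
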