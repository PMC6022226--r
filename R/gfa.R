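# Genetic function approximation: a seeded genetic algorithm over
# descriptor subsets, each individual fitted by OLS and scored by
# Friedman's lack-of-fit (a size-penalized mean squared error), with
# tournament selection, single-point crossover, add/remove-term mutation
# and elitism.

#' Friedman lack-of-fit score
#'
#' `LOF = (SSE/m) / (1 - (c + d p)/m)^2` with `m` samples, `c` basis
#' functions, `p` total terms and smoothing parameter `d`.  For the linear
#' models evolved here the convention is `c = p = ` number of descriptors
#' plus one, counting the intercept as a basis function.
#'
#' @param sse residual sum of squares.
#' @param m number of samples.
#' @param c number of basis functions.
#' @param p total number of model terms.
#' @param d smoothing parameter (default 1).
#' @return the LOF score (>= SSE/m).
#' @export
#' @examples
#' gfa_lof(1, m = 10, c = 2, p = 2)  # 0.1 / 0.36 = 0.2778
gfa_lof <- function(sse, m, c, p, d = 1) {
  pen <- 1 - (c + d * p) / m
  if (pen <= 0)
    stop("model too large for sample size: c + d*p = ", c + d * p,
         " >= m = ", m)
  (sse / m) / pen^2
}

#' GFA configuration
#'
#' @param population_size number of individuals (>= 2).
#' @param generations number of GA generations.
#' @param mutation_probability per-offspring mutation probability.
#' @param d LOF smoothing parameter.
#' @param max_terms,min_terms subset size bounds.
#' @param rng_seed integer seed; the whole run is reproducible from it.
#' @return list of class `gfa_config`.
#' @export
gfa_config <- function(population_size = 100, generations = 500,
                       mutation_probability = 0.1, d = 1.0,
                       max_terms = 5, min_terms = 1, rng_seed = 1L) {
  stopifnot(population_size >= 2, generations >= 1,
            mutation_probability >= 0, mutation_probability <= 1,
            min_terms >= 1, max_terms >= min_terms)
  structure(list(population_size = population_size,
                 generations = generations,
                 mutation_probability = mutation_probability,
                 d = d, max_terms = max_terms, min_terms = min_terms,
                 rng_seed = as.integer(rng_seed)),
            class = "gfa_config")
}

# fit one subset, returning NULL for rank-deficient candidates
gfa_score <- function(X, y, subset, d) {
  fit <- tryCatch(fit_mlr(X[, subset, drop = FALSE], y),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  m <- length(y)
  cp <- length(subset) + 1  # intercept counts as a basis function
  lof <- tryCatch(gfa_lof(fit$stats$sse, m, cp, cp, d),
                  error = function(e) NULL)
  if (is.null(lof)) return(NULL)
  list(subset = sort(subset), fit = fit, lof = lof)
}

#' Evolve descriptor subsets by genetic function approximation
#'
#' Seeded, fully reproducible GA over subsets of the descriptor pool.
#' Individuals are descriptor-name sets within the configured size bounds;
#' every individual is refit by OLS ([fit_mlr()]) and ranked by
#' [gfa_lof()].  Selection is tournament (size 2), recombination is
#' single-point crossover over term lists with duplicate collapse,
#' mutation adds, removes or swaps one term, and the best individual is
#' carried over unchanged (elitism), so the best LOF is non-increasing
#' across generations.
#'
#' @param X descriptor matrix or data frame (named columns).
#' @param y activity vector.
#' @param config a [gfa_config()].
#' @param top_k number of distinct top models to return.
#' @return list of class `gfa_result`: `models` (list of candidate models,
#'   best first, each with `subset`, `model`, `stats`, `lof`), `config`,
#'   and `lof_trace` (best LOF per generation).
#' @export
gfa_evolve <- function(X, y, config = gfa_config(), top_k = 10) {
  X <- as.data.frame(X)
  pool <- colnames(X)
  stopifnot(length(pool) >= config$min_terms, length(y) == nrow(X))
  if (config$max_terms >= length(y) - 1)
    stop("max_terms must be below n_samples - 1")
  Xm <- as.matrix(X)

  runif(1)  # ensure RNG exists
  old <- .Random.seed
  on.exit(.Random.seed <<- old)
  set.seed(config$rng_seed)

  rand_subset <- function() {
    k <- sample(config$min_terms:config$max_terms, 1)
    sample(pool, min(k, length(pool)))
  }
  score_cache <- new.env(parent = emptyenv())
  score <- function(subset) {
    key <- paste(sort(subset), collapse = "|")
    if (!is.null(sc <- score_cache[[key]])) return(sc)
    sc <- gfa_score(Xm, y, sort(subset), config$d)
    score_cache[[key]] <- if (is.null(sc)) list(NULL) else sc
    score_cache[[key]]
  }
  lof_of <- function(sc) if (is.null(sc$subset)) Inf else sc$lof

  pop <- replicate(config$population_size, rand_subset(), simplify = FALSE)
  scores <- lapply(pop, score)
  if (all(!is.finite(vapply(scores, lof_of, 0))))
    stop("no rank-sufficient candidate model could be fit")
  trace <- numeric(config$generations)

  clamp <- function(s) {
    s <- unique(s)
    if (length(s) > config$max_terms)
      s <- sample(s, config$max_terms)
    while (length(s) < config$min_terms)
      s <- unique(c(s, sample(pool, 1)))
    s
  }
  mutate <- function(s) {
    op <- sample(c("add", "drop", "swap"), 1)
    if (op == "add" && length(s) < config$max_terms &&
        length(setdiff(pool, s)))
      s <- c(s, sample(setdiff(pool, s), 1))
    else if (op == "drop" && length(s) > config$min_terms)
      s <- sample(s, length(s) - 1)
    else if (length(setdiff(pool, s)))
      s[sample(length(s), 1)] <- sample(setdiff(pool, s), 1)
    clamp(s)
  }

  for (g in seq_len(config$generations)) {
    lofs <- vapply(scores, lof_of, 0)
    best <- which.min(lofs)
    nxt <- list(pop[[best]])  # elitism
    while (length(nxt) < config$population_size) {
      pick <- function() {
        c2 <- sample(config$population_size, 2)
        pop[[c2[which.min(lofs[c2])]]]
      }
      p1 <- pick(); p2 <- pick()
      cut1 <- sample(0:length(p1), 1)
      child <- clamp(c(head(p1, cut1), setdiff(p2, head(p1, cut1))))
      if (runif(1) < config$mutation_probability) child <- mutate(child)
      nxt[[length(nxt) + 1]] <- child
    }
    pop <- nxt
    scores <- lapply(pop, score)
    trace[g] <- min(vapply(scores, lof_of, 0))
  }

  # rank all distinct evaluated subsets
  all_sc <- Filter(function(s) !is.null(s$subset),
                   as.list(score_cache, all.names = TRUE))
  ord <- order(vapply(all_sc, `[[`, 0, "lof"))
  models <- lapply(all_sc[head(ord, top_k)], function(sc)
    list(subset = sc$subset, model = sc$fit$model, stats = sc$fit$stats,
         lof = sc$lof))
  structure(list(models = models, config = config, lof_trace = trace),
            class = "gfa_result")
}

#' @export
print.gfa_result <- function(x, ...) {
  cat(sprintf("<gfa_result> %d ranked models (seed %d)\n",
              length(x$models), x$config$rng_seed))
  for (k in seq_len(min(5, length(x$models)))) {
    m <- x$models[[k]]
    cat(sprintf("  %d. LOF %.4g r2 %.3f q2 %.3f: %s\n", k, m$lof,
                m$stats$r2, m$stats$q2_loo,
                paste(m$subset, collapse = " + ")))
  }
  invisible(x)
}

#' Ranked models as a data frame
#'
#' @param result a `gfa_result`.
#' @return data frame with `subset`, `lof`, `r2`, `r2_adj`, `q2_loo`.
#' @export
gfa_ranking <- function(result) {
  do.call(rbind, lapply(result$models, function(m)
    data.frame(subset = paste(m$subset, collapse = "+"), lof = m$lof,
               r2 = m$stats$r2, r2_adj = m$stats$r2_adj,
               q2_loo = m$stats$q2_loo)))
}
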