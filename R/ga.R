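# Genetic-algorithm wrapper selection of a fixed-size gene panel.
# Individuals are panel_size-subsets of the candidate pool; fitness is the
# LOOCV accuracy of the SVM restricted to the subset. The search keeps a
# global elitist memory, so the reported best panel is the best individual
# ever evaluated and the best-so-far fitness is non-decreasing.

#' Genetic-algorithm configuration
#'
#' Operator defaults: fitness-proportional (roulette) parent selection,
#' single-point crossover on the gene list followed by repair of duplicate
#' genes (duplicates are replaced by uniform draws from the unused pool),
#' per-position mutation that swaps a gene for an unused one, and one elite
#' individual copied unchanged per generation. Ten generations suffice for
#' the fitness to plateau on problems of the intended scale (a few hundred
#' pool genes, tens of samples).
#'
#' @param population_size Number of individuals per generation.
#' @param generations Number of generations, counting the random initial
#'   population as the first.
#' @param crossover_rate Probability that a selected parent pair is
#'   recombined rather than copied.
#' @param mutation_rate Per-position probability of mutating a gene.
#' @param elitism_count Individuals carried over unchanged each generation;
#'   must be smaller than `population_size`.
#' @param rng_seed Optional integer seed making the run exactly
#'   reproducible.
#' @return A list of class `"ga_control"`.
#' @export
ga_control <- function(population_size = 100L, generations = 10L,
                       crossover_rate = 0.8, mutation_rate = 0.05,
                       elitism_count = 1L, rng_seed = NULL) {
  population_size <- as.integer(population_size)
  generations <- as.integer(generations)
  elitism_count <- as.integer(elitism_count)
  stopifnot(population_size >= 2L, generations >= 1L,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elitism_count >= 0L, elitism_count < population_size)
  structure(list(population_size = population_size,
                 generations = generations,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism_count = elitism_count,
                 rng_seed = rng_seed),
            class = "ga_control")
}

#' Select a gene panel by genetic-algorithm wrapper search
#'
#' Searches the `panel_size`-subsets of `pool` for the subset maximizing
#' [loocv_accuracy()] of the configured classifier on the grouped training
#' samples. Fitness evaluations are memoized, so re-encountered panels cost
#' nothing.
#'
#' @param pool Character vector of candidate gene ids (typically the
#'   Kruskal-Wallis-significant genes), all present in `x`.
#' @param x Gene x sample expression matrix on the standardized scale.
#' @param groups Factor of response labels named by sample id.
#' @param control A [ga_control()] configuration.
#' @param panel_size Number of genes to select (default 10).
#' @param classifier An [svm_control()] configuration.
#' @return A list of class `"ga_result"` with elements `panel` (character
#'   vector of `panel_size` gene ids), `fitness` (its LOOCV accuracy),
#'   `history` (best-so-far fitness after each generation, non-decreasing),
#'   and `n_evaluated` (distinct panels scored).
#' @export
ga_select <- function(pool, x, groups, control = ga_control(),
                      panel_size = 10L, classifier = svm_control()) {
  pool <- unique(as.character(pool))
  panel_size <- as.integer(panel_size)
  if (!inherits(control, "ga_control")) {
    stop("'control' must come from ga_control()", call. = FALSE)
  }
  if (length(pool) < panel_size) {
    stop(sprintf("pool has %d genes but panel_size is %d",
                 length(pool), panel_size), call. = FALSE)
  }
  npool <- length(pool)

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  fitness_of <- function(idx) {
    key <- paste(sort.int(idx), collapse = ".")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    f <- loocv_accuracy(pool[idx], x, groups, classifier)
    cache[[key]] <- f
    n_eval <<- n_eval + 1L
    f
  }

  if (npool == panel_size) { # a single candidate exists
    f <- fitness_of(seq_len(npool))
    return(structure(list(panel = pool, fitness = f, history = f,
                          n_evaluated = 1L, control = control),
                     class = "ga_result"))
  }

  with_seed(control$rng_seed, {
    pop <- replicate(control$population_size,
                     sample.int(npool, panel_size), simplify = FALSE)
    best_idx <- NULL
    best_fit <- -Inf
    history <- numeric(control$generations)

    repair <- function(idx) {
      idx <- unique(idx)
      if (length(idx) < panel_size) {
        free <- setdiff(seq_len(npool), idx)
        idx <- c(idx, sample(free, panel_size - length(idx)))
      }
      idx
    }
    mutate <- function(idx) {
      hit <- stats::runif(panel_size) < control$mutation_rate
      if (any(hit)) {
        free <- setdiff(seq_len(npool), idx)
        k <- min(sum(hit), length(free))
        if (k > 0L) idx[which(hit)[seq_len(k)]] <- sample(free, k)
      }
      idx
    }

    for (gen in seq_len(control$generations)) {
      fits <- vapply(pop, fitness_of, numeric(1L))
      gen_best <- which.max(fits)
      if (fits[gen_best] > best_fit) {
        best_fit <- fits[gen_best]
        best_idx <- pop[[gen_best]]
      }
      history[gen] <- best_fit
      if (gen == control$generations) break

      # breed the next generation
      nxt <- vector("list", control$population_size)
      if (control$elitism_count > 0L) {
        elite <- order(fits, decreasing = TRUE)[seq_len(control$elitism_count)]
        nxt[seq_along(elite)] <- pop[elite]
      }
      filled <- control$elitism_count
      w <- if (all(fits <= 0)) rep(1, length(fits)) else fits
      while (filled < control$population_size) {
        par <- sample.int(length(pop), 2L, replace = TRUE, prob = w)
        a <- pop[[par[1L]]]
        b <- pop[[par[2L]]]
        if (stats::runif(1L) < control$crossover_rate) {
          cut <- sample.int(panel_size - 1L, 1L)
          child1 <- repair(c(a[seq_len(cut)], b[-seq_len(cut)]))
          child2 <- repair(c(b[seq_len(cut)], a[-seq_len(cut)]))
        } else {
          child1 <- a
          child2 <- b
        }
        for (child in list(child1, child2)) {
          if (filled >= control$population_size) break
          filled <- filled + 1L
          nxt[[filled]] <- mutate(child)
        }
      }
      pop <- nxt
    }

    structure(list(panel = pool[sort.int(best_idx)], fitness = best_fit,
                   history = history, n_evaluated = n_eval,
                   control = control),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("GA panel selection: %d genes, LOOCV accuracy %.3f (%d panels evaluated)\n",
              length(x$panel), x$fitness, x$n_evaluated))
  cat("  panel:", paste(x$panel, collapse = ", "), "\n")
  invisible(x)
}
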