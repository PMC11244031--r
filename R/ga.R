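#' Configure the genetic-algorithm feature selector
#'
#' Wrapper selection over binary chromosomes (1 = feature kept). Defaults
#' follow common wrapper-GA practice for this problem: population 50,
#' crossover probability 0.9, mutation probability 0.2, 20 generations,
#' chromosome length equal to the feature count. Fitness is the mean
#' stratified k-fold cross-validated overall accuracy of `fitness_classifier`
#' restricted to the masked features. The mutation probability is applied
#' per individual (one uniformly chosen bit flips); a per-bit reading of 0.2
#' would rerandomize a fifth of all genes every generation and prevent
#' convergence within 20 generations — `mutation_mode = "per_bit"` is
#' available for that interpretation.
#'
#' @param population_size even integer (default 50).
#' @param crossover_prob uniform-crossover probability per pair (default 0.9).
#' @param mutation_prob mutation probability (default 0.2).
#' @param mutation_mode `"per_individual"` (default) or `"per_bit"`.
#' @param generations number of generations (default 20).
#' @param fitness_folds stratified CV folds inside the fitness function
#'   (default 5; lighter than the 10-fold used for final model assessment).
#' @param fitness_classifier a [classifier_spec()]; default KNN with k = 5,
#'   chosen for tractability inside the GA loop.
#' @param elitism number of best individuals copied unchanged (default 1).
#' @param seed integer seed.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 50, crossover_prob = 0.9,
                      mutation_prob = 0.2,
                      mutation_mode = c("per_individual", "per_bit"),
                      generations = 20, fitness_folds = 5,
                      fitness_classifier = classifier_spec("knn", k = 5),
                      elitism = 1, seed = 1) {
  stop_if_not(population_size %% 2 == 0, "population_size must be even")
  stop_if_not(crossover_prob >= 0 && crossover_prob <= 1,
              "crossover_prob must be in [0, 1]")
  stop_if_not(mutation_prob >= 0 && mutation_prob <= 1,
              "mutation_prob must be in [0, 1]")
  stop_if_not(generations >= 0, "generations must be >= 0")
  structure(list(population_size = as.integer(population_size),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 mutation_mode = match.arg(mutation_mode),
                 generations = as.integer(generations),
                 fitness_folds = as.integer(fitness_folds),
                 fitness_classifier = fitness_classifier,
                 elitism = as.integer(elitism), seed = as.integer(seed)),
            class = "ga_config")
}

#' Genetic-algorithm wrapper feature selection
#'
#' Evolves binary feature masks by tournament selection (k = 2), uniform
#' crossover, mutation and elitism; fitness is stratified CV overall
#' accuracy of the configured classifier on the masked feature table. Empty
#' masks are repaired by activating one random bit. Fitness evaluations are
#' memoized by mask, and the best mask ever seen is returned. Deterministic
#' given the seed.
#'
#' @param table a feature table: data.frame with feature columns and a
#'   `label` column (see [build_feature_families()]).
#' @param config a [ga_config()].
#' @return An object of class `ga_result`: list with `mask` (0/1 integer
#'   vector named by feature columns), `best_fitness_history` (length
#'   generations + 1), `selected` (count) and `feature_names`.
#' @export
ga_select <- function(table, config = ga_config()) {
  stop_if_not(inherits(config, "ga_config"), "`config` must be ga_config")
  feats <- feature_columns(table)
  stop_if_not(length(feats) >= 2, "need >= 2 features")
  stop_if_not(length(unique(table$label)) >= 2, "need >= 2 classes")
  x <- as.matrix(table[, feats, drop = FALSE])
  y <- table$label
  len <- length(feats)
  cache <- new.env(parent = emptyenv())
  fitness <- function(mask) {
    key <- paste(mask, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    sub <- data.frame(x[, mask == 1L, drop = FALSE], label = y,
                      check.names = FALSE)
    val <- cross_validate(sub, config$fitness_classifier,
                          folds = config$fitness_folds,
                          seed = config$seed)$oa
    cache[[key]] <- val
    val
  }
  with_seed(config$seed, {
    repair <- function(mask) {
      if (sum(mask) == 0L) mask[sample.int(len, 1)] <- 1L
      mask
    }
    pop <- lapply(seq_len(config$population_size), function(i)
      repair(as.integer(stats::runif(len) < 0.5)))
    fit <- vapply(pop, fitness, numeric(1))
    best_i <- which.max(fit)
    best_mask <- pop[[best_i]]; best_fit <- fit[best_i]
    history <- best_fit
    if (config$generations > 0) for (g in seq_len(config$generations)) {
      tournament <- function() {
        ij <- sample.int(config$population_size, 2)
        if (fit[ij[1]] >= fit[ij[2]]) pop[[ij[1]]] else pop[[ij[2]]]
      }
      newpop <- vector("list", config$population_size)
      i <- 1L
      while (i < config$population_size) {
        p1 <- tournament(); p2 <- tournament()
        if (stats::runif(1) < config$crossover_prob) {
          swap <- stats::runif(len) < 0.5
          c1 <- ifelse(swap, p2, p1); c2 <- ifelse(swap, p1, p2)
        } else { c1 <- p1; c2 <- p2 }
        mutate <- function(m) {
          if (config$mutation_mode == "per_individual") {
            if (stats::runif(1) < config$mutation_prob) {
              b <- sample.int(len, 1); m[b] <- 1L - m[b]
            }
          } else {
            flip <- stats::runif(len) < config$mutation_prob
            m[flip] <- 1L - m[flip]
          }
          m
        }
        newpop[[i]] <- repair(as.integer(mutate(c1)))
        newpop[[i + 1L]] <- repair(as.integer(mutate(c2)))
        i <- i + 2L
      }
      # elitism: best individuals survive unchanged
      if (config$elitism > 0) {
        elite <- order(fit, decreasing = TRUE)[seq_len(config$elitism)]
        for (e in seq_along(elite)) newpop[[e]] <- pop[[elite[e]]]
      }
      pop <- newpop
      fit <- vapply(pop, fitness, numeric(1))
      gi <- which.max(fit)
      if (fit[gi] > best_fit) { best_fit <- fit[gi]; best_mask <- pop[[gi]] }
      history <- c(history, best_fit)
    }
    structure(list(mask = stats::setNames(best_mask, feats),
                   best_fitness_history = history,
                   selected = sum(best_mask), feature_names = feats),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> %d / %d features selected, best fitness %.4f\n",
              x$selected, length(x$mask), max(x$best_fitness_history)))
  invisible(x)
}

#' Apply a binary feature mask to a feature table
#'
#' @param table feature table (data.frame with feature columns, optional
#'   `sample_id` and `label`).
#' @param mask 0/1 integer vector, one entry per feature column, order
#'   preserved.
#' @return The table restricted to masked-in feature columns; `sample_id`
#'   and `label` untouched.
#' @export
apply_mask <- function(table, mask) {
  feats <- feature_columns(table)
  stop_if_not(length(mask) == length(feats),
              "mask length must equal the number of feature columns")
  if (sum(mask) == 0) stop("all-zero mask", call. = FALSE)
  drop_cols <- feats[mask == 0L]
  table[, !(names(table) %in% drop_cols), drop = FALSE]
}

# feature columns = everything except bookkeeping columns
feature_columns <- function(table) {
  setdiff(names(table), c("sample_id", "label"))
}
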