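#' Genetic algorithm configuration
#'
#' Controls the multi-objective evolution of [detector_genome()] populations.
#' Selection is by Pareto rank (non-dominated sorting over sensitivity,
#' specificity and accuracy) with crowding-distance tie-breaks; variation is
#' uniform crossover plus per-gene mutation; the running non-dominated
#' archive is elitist. Evolution stops after `n_generations`, or earlier
#' once `stopping_patience` consecutive generations add nothing new to the
#' Pareto archive.
#'
#' @param population_size Genomes per generation (default 40).
#' @param n_generations Maximum generations (default 30).
#' @param crossover_prob Probability an offspring is produced by uniform
#'   crossover rather than cloning (default 0.9).
#' @param mutation_prob_per_gene Per-gene mutation probability (default 0.15).
#' @param tournament_size Tournament size for parent selection (default 3).
#' @param elitism_count Archive members re-injected each generation
#'   (default 4; must be below `population_size`).
#' @param stopping_patience Generations without Pareto improvement before
#'   stopping early (default 10).
#' @param k_max Largest neighbourhood size searched (default 25, clipped to
#'   the retained item count minus one).
#' @param allow_even_k Search even `k` too? Default FALSE (odd `k` reduces
#'   vote ties in binary tasks).
#' @param seed Integer seed making the whole run reproducible.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 40, n_generations = 30,
                      crossover_prob = 0.9, mutation_prob_per_gene = 0.15,
                      tournament_size = 3, elitism_count = 4,
                      stopping_patience = 10, k_max = 25,
                      allow_even_k = FALSE, seed = 1) {
  cfg <- list(population_size = as.integer(population_size),
              n_generations = as.integer(n_generations),
              crossover_prob = crossover_prob,
              mutation_prob_per_gene = mutation_prob_per_gene,
              tournament_size = as.integer(tournament_size),
              elitism_count = as.integer(elitism_count),
              stopping_patience = as.integer(stopping_patience),
              k_max = as.integer(k_max),
              allow_even_k = isTRUE(allow_even_k),
              seed = as.integer(seed))
  assert_that(is_count(cfg$population_size), "population_size must be positive")
  assert_that(is_count(cfg$n_generations), "n_generations must be positive")
  for (p in c("crossover_prob", "mutation_prob_per_gene"))
    assert_that(cfg[[p]] >= 0 && cfg[[p]] <= 1, paste(p, "must lie in [0, 1]"))
  assert_that(cfg$tournament_size >= 1 &&
                cfg$tournament_size <= cfg$population_size,
              "tournament_size must not exceed population_size")
  assert_that(cfg$elitism_count >= 0 &&
                cfg$elitism_count < cfg$population_size,
              "elitism_count must be below population_size")
  assert_that(cfg$stopping_patience >= 1, "stopping_patience must be >= 1")
  structure(cfg, class = "ga_config")
}

#' LOOCV fitness of one genome
#'
#' The fitness triple is computed from a single leave-one-out
#' cross-validation run: sensitivity and specificity from the binary
#' injury-present collapse of the confusion counts (see
#' [confusion_metrics()]) and accuracy as the exact-match fraction (these
#' coincide for binary tasks).
#'
#' @param genome A [detector_genome()].
#' @param dataset A [featurize_study()] result.
#' @param task A [classification_task()].
#' @param cache Optional environment memoising fitness by genome, so
#'   re-evaluating an unchanged genome inside a GA run costs nothing.
#' @return Named numeric vector `sensitivity`, `specificity`, `accuracy` (%).
#' @export
fitness <- function(genome, dataset, task, cache = NULL) {
  validate_genome(genome)
  key <- genome_key(genome)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  cv <- loocv(dataset, genome, task)
  metrics <- confusion_metrics(cv$counts)
  out <- c(sensitivity = unname(metrics["sensitivity"]),
           specificity = unname(metrics["specificity"]),
           accuracy = cv$accuracy)
  if (!is.null(cache)) cache[[key]] <- out
  out
}

# a dominates b: no objective worse, at least one strictly better
dominates <- function(a, b) all(a >= b) && any(a > b)

# Indices of the non-dominated rows of a fitness matrix.
nondominated_indices <- function(fits) {
  n <- nrow(fits)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (i != j && keep[j] && dominates(fits[j, ], fits[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  which(keep)
}

# Non-dominated sorting: Pareto rank (1 = front) per row.
pareto_ranks <- function(fits) {
  n <- nrow(fits)
  rank <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  r <- 0L
  while (length(remaining)) {
    r <- r + 1L
    front <- remaining[nondominated_indices(fits[remaining, , drop = FALSE])]
    rank[front] <- r
    remaining <- setdiff(remaining, front)
  }
  rank
}

# Crowding distance within each Pareto front.
crowding_distances <- function(fits, ranks) {
  n <- nrow(fits)
  cd <- numeric(n)
  for (r in unique(ranks)) {
    idx <- which(ranks == r)
    if (length(idx) <= 2) { cd[idx] <- Inf; next }
    for (obj in seq_len(ncol(fits))) {
      o <- idx[order(fits[idx, obj])]
      cd[o[1]] <- cd[o[length(o)]] <- Inf
      span <- fits[o[length(o)], obj] - fits[o[1], obj]
      if (span > 0) {
        mid <- 2:(length(o) - 1)
        cd[o[mid]] <- cd[o[mid]] +
          (fits[o[mid + 1], obj] - fits[o[mid - 1], obj]) / span
      }
    }
  }
  cd
}

# --- variation operators -----------------------------------------------------

random_genome <- function(n_features, k_max, allow_even_k) {
  ks <- if (allow_even_k) seq_len(k_max) else seq(1, k_max, by = 2)
  mask <- runif(n_features) < 0.7
  if (!any(mask)) mask[sample.int(n_features, 1)] <- TRUE
  detector_genome(k = sample(ks, 1), feature_mask = mask,
                  feature_weights = exp(rnorm(n_features, sd = 0.2)),
                  distance_exponent = sample(c(1, 2), 1))
}

mutate_genome <- function(g, prob, k_max, allow_even_k) {
  if (runif(1) < prob) {
    step <- if (allow_even_k) sample(c(-2L, -1L, 1L, 2L), 1) else
      sample(c(-2L, 2L), 1)  # +/-2 keeps k odd
    g$k <- min(max(g$k + step, 1L), k_max)
  }
  flip <- runif(length(g$feature_mask)) < prob
  g$feature_mask <- xor(g$feature_mask, flip)
  if (!any(g$feature_mask))
    g$feature_mask[sample.int(length(g$feature_mask), 1)] <- TRUE
  jitter <- runif(length(g$feature_weights)) < prob
  if (any(jitter))
    g$feature_weights[jitter] <- g$feature_weights[jitter] *
      exp(rnorm(sum(jitter), sd = 0.3))
  if (runif(1) < prob) g$distance_exponent <- sample(c(1, 2), 1)
  g
}

crossover_genomes <- function(a, b) {
  nf <- length(a$feature_mask)
  pick <- runif(nf) < 0.5
  mask <- ifelse(pick, a$feature_mask, b$feature_mask)
  if (!any(mask)) mask <- a$feature_mask
  detector_genome(
    k = if (runif(1) < 0.5) a$k else b$k,
    feature_mask = mask,
    feature_weights = ifelse(runif(nf) < 0.5, a$feature_weights,
                             b$feature_weights),
    distance_exponent = if (runif(1) < 0.5) a$distance_exponent
                        else b$distance_exponent)
}

#' Evolve a KNN detector by a multi-objective genetic algorithm
#'
#' Maximises LOOCV sensitivity, specificity and accuracy jointly over the
#' detector parameter space (neighbourhood size, feature mask, feature
#' weights, distance exponent). The algorithm is NSGA-II-flavoured:
#' non-dominated sorting assigns Pareto ranks, crowding distance breaks
#' rank ties, parents are chosen by tournament on (rank, crowding),
#' offspring arise by uniform crossover and per-gene mutation, and an
#' elitist archive of all non-dominated genomes found so far is maintained
#' and partially re-injected each generation. Because the archive is
#' elitist, its best accuracy never decreases across generations.
#'
#' "Pareto improvement" (for the `stopping_patience` rule) means the set of
#' objective vectors represented on the archive changed; once the front's
#' objective values are stable for `stopping_patience` generations the run
#' stops early. The archive is capped at 150 genomes by crowding distance
#' to keep dominance bookkeeping cheap on tasks where many genomes tie.
#'
#' @param dataset A [featurize_study()] result.
#' @param task A [classification_task()].
#' @param ga A [ga_config()].
#' @param initial_population Optional list of [detector_genome()]s seeding
#'   the first generation (recycled/truncated to `population_size`); by
#'   default one all-features genome plus random genomes.
#' @return An object of class `evolution_result`: `best_genome` (archive
#'   member with maximal accuracy, ties broken by sensitivity then
#'   specificity), `best_fitness`, `pareto_front` (list of genomes) and
#'   `pareto_fitness` (matrix), `history` (one row per generation:
#'   best/mean of each objective and archive size), `n_evaluated` (distinct
#'   genomes scored), and the `ga` config echo.
#' @export
evolve <- function(dataset, task, ga = ga_config(),
                   initial_population = NULL) {
  assert_that(inherits(ga, "ga_config"), "ga must be a ga_config()")
  cls <- apply_task(task, dataset$labels)
  n_retained <- sum(!is.na(cls))
  assert_that(n_retained >= 3, "dataset retains too few items")
  nf <- ncol(dataset$features)
  k_max <- max(1L, min(ga$k_max, n_retained - 2L))
  cache <- new.env(parent = emptyenv())
  eval_pop <- function(pop) {
    t(vapply(pop, fitness, numeric(3), dataset = dataset, task = task,
             cache = cache))
  }
  with_seed(ga$seed, {
    pop <- if (is.null(initial_population)) {
      c(list(detector_genome(k = min(5L, k_max),
                             feature_mask = rep(TRUE, nf))),
        replicate(ga$population_size - 1,
                  random_genome(nf, k_max, ga$allow_even_k),
                  simplify = FALSE))
    } else {
      rep_len(initial_population, ga$population_size)
    }
    archive <- list(); arch_fits <- NULL; front_sig <- ""
    history <- vector("list", ga$n_generations)
    stale <- 0L
    for (gen in seq_len(ga$n_generations)) {
      fits <- eval_pop(pop)
      # elitist archive update (dedupe by canonical genome serialization)
      cand <- c(archive, pop)
      cand_fits <- rbind(arch_fits, fits)
      keys <- vapply(cand, genome_key, character(1))
      first <- !duplicated(keys)
      cand <- cand[first]; cand_fits <- cand_fits[first, , drop = FALSE]
      nd <- nondominated_indices(cand_fits)
      archive <- cand[nd]
      arch_fits <- cand_fits[nd, , drop = FALSE]
      if (length(archive) > 150L) {
        r <- rep(1L, length(archive))
        keep <- order(-crowding_distances(arch_fits, r))[seq_len(150L)]
        archive <- archive[keep]
        arch_fits <- arch_fits[keep, , drop = FALSE]
      }
      sig <- paste(sort(unique(apply(round(arch_fits, 9), 1, paste,
                                     collapse = ","))), collapse = ";")
      improved <- !identical(sig, front_sig)
      front_sig <- sig
      stale <- if (improved) 0L else stale + 1L
      history[[gen]] <- data.frame(
        generation = gen,
        best_sensitivity = max(arch_fits[, "sensitivity"]),
        best_specificity = max(arch_fits[, "specificity"]),
        best_accuracy = max(arch_fits[, "accuracy"]),
        mean_sensitivity = mean(fits[, "sensitivity"]),
        mean_specificity = mean(fits[, "specificity"]),
        mean_accuracy = mean(fits[, "accuracy"]),
        archive_size = length(archive))
      if (gen == ga$n_generations || stale >= ga$stopping_patience) break
      # selection: tournament on (Pareto rank, crowding) in the current pop
      ranks <- pareto_ranks(fits)
      crowd <- crowding_distances(fits, ranks)
      pick_parent <- function() {
        cand <- sample.int(length(pop), ga$tournament_size)
        cand[order(ranks[cand], -crowd[cand])][1]
      }
      n_elite <- min(ga$elitism_count, length(archive))
      elites <- if (n_elite > 0) {
        ord <- order(-arch_fits[, "accuracy"], -arch_fits[, "sensitivity"],
                     -arch_fits[, "specificity"])
        archive[ord[seq_len(n_elite)]]
      } else list()
      offspring <- lapply(seq_len(ga$population_size - length(elites)),
                          function(i) {
        p1 <- pop[[pick_parent()]]
        child <- if (runif(1) < ga$crossover_prob)
          crossover_genomes(p1, pop[[pick_parent()]]) else p1
        child$k <- min(child$k, k_max)
        mutate_genome(child, ga$mutation_prob_per_gene, k_max,
                      ga$allow_even_k)
      })
      pop <- c(elites, offspring)
    }
    history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
    best_ord <- order(-arch_fits[, "accuracy"], -arch_fits[, "sensitivity"],
                      -arch_fits[, "specificity"])
    structure(list(best_genome = archive[[best_ord[1]]],
                   best_fitness = arch_fits[best_ord[1], ],
                   pareto_front = archive,
                   pareto_fitness = arch_fits,
                   history = history,
                   n_evaluated = length(ls(cache)),
                   ga = ga, task = task$name),
              class = "evolution_result")
  })
}

#' @export
print.evolution_result <- function(x, ...) {
  cat(sprintf("<evolution_result> task %s: %d generation(s), %d genomes scored\n",
              x$task, nrow(x$history), x$n_evaluated))
  cat(sprintf("  best: sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%% (Pareto size %d)\n",
              x$best_fitness["sensitivity"], x$best_fitness["specificity"],
              x$best_fitness["accuracy"], length(x$pareto_front)))
  invisible(x)
}
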