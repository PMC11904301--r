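#' Real-coded genetic algorithm with Nelder-Mead sub-optimization
#'
#' Refines the weight and curve parameters of the enabled features of `init`
#' by maximizing mean MAP. The genome is the concatenated (weight, curve)
#' vector; the population is seeded with the incoming vector plus Gaussian
#' jitter. Each generation applies tournament selection, uniform crossover,
#' Gaussian mutation clipped to the bounds, and elitism (the best individual
#' always survives, so the best-so-far trace is non-decreasing and the final
#' MAP can never fall below the initial one). Every `nm_every` generations
#' the best individual is refined by [nelder_mead_maximize()]; the refined
#' vector replaces it only if the relative improvement is at least
#' `nm_improve_threshold` (default 1e-3, i.e. 0.1\%). All randomness derives
#' from `seed`; identical seeds give bit-identical results.
#'
#' @param projects List of [tr_project()]s.
#' @param init Catalog carrying the starting weights/curves (e.g. the SFS
#'   result's catalog); only enabled rows are optimized.
#' @param population Population size (>= 2).
#' @param generations Number of generations.
#' @param mutation_sd Mutation standard deviation as a fraction of each
#'   bound's width.
#' @param mutation_rate Per-gene mutation probability.
#' @param crossover_rate Probability of uniform crossover per offspring.
#' @param tournament Tournament size for selection.
#' @param elitism Number of elite individuals copied unchanged.
#' @param nm_every Generations between Nelder-Mead refinements (0 disables).
#' @param nm_improve_threshold Relative improvement needed to accept a
#'   refinement.
#' @param weight_bounds,curve_bounds Box bounds for the genome.
#' @param seed Integer seed for all GA randomness.
#' @return A `tr_optimization` with the best catalog, per-generation
#'   best-so-far trace and method log.
#' @export
ga_optimize <- function(projects, init = default_catalog(),
                        population = 40, generations = 60,
                        mutation_sd = 0.1, mutation_rate = 0.15,
                        crossover_rate = 0.9, tournament = 3, elitism = 1,
                        nm_every = 10, nm_improve_threshold = 1e-3,
                        weight_bounds = c(-10, 10), curve_bounds = c(-3, 3),
                        seed = 1) {
  stopifnot(population >= 2, generations >= 1, length(projects) >= 1)
  validate_catalog(init)
  compiled <- lapply(projects, compile_project, catalog = init)
  feat_names <- colnames(compiled[[1]]$M)
  on_idx <- match(feat_names, init$name)
  k <- length(feat_names)
  lower <- c(rep(weight_bounds[1], k), rep(curve_bounds[1], k))
  upper <- c(rep(weight_bounds[2], k), rep(curve_bounds[2], k))
  width <- upper - lower
  clip <- function(g) pmin(pmax(g, lower), upper)

  cache <- new.env(parent = emptyenv())
  fitness <- function(g) {
    key <- paste(sprintf("%.17g", g), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- compiled_objective(compiled, g[seq_len(k)], g[k + seq_len(k)])
    cache[[key]] <- val
    val
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))

  g0 <- c(init$weight[on_idx], init$curve[on_idx])
  g0 <- clip(g0)
  pop <- matrix(0, population, 2 * k)
  pop[1, ] <- g0
  for (i in seq_len(population)[-1]) {
    pop[i, ] <- clip(g0 + stats::rnorm(2 * k, 0, mutation_sd * width))
  }
  fit <- apply(pop, 1, fitness)
  best_g <- pop[which.max(fit), ]
  best_f <- max(fit)
  init_f <- fitness(g0)
  trace0 <- best_f
  trace <- numeric(generations)
  log <- sprintf("generation 0: best %.6f (init %.6f)", best_f, init_f)

  for (gen in seq_len(generations)) {
    elite_ord <- order(fit, decreasing = TRUE)
    newpop <- matrix(0, population, 2 * k)
    n_elite <- min(elitism, population)
    newpop[seq_len(n_elite), ] <- pop[elite_ord[seq_len(n_elite)], , drop = FALSE]
    for (i in seq(n_elite + 1, population)) {
      pick <- function() {
        idx <- sample.int(population, tournament, replace = TRUE)
        pop[idx[which.max(fit[idx])], ]
      }
      p1 <- pick()
      child <- if (stats::runif(1) < crossover_rate) {
        p2 <- pick()
        mask <- stats::runif(2 * k) < 0.5
        ifelse(mask, p1, p2)
      } else p1
      mut <- stats::runif(2 * k) < mutation_rate
      if (any(mut)) {
        child[mut] <- child[mut] +
          stats::rnorm(sum(mut), 0, mutation_sd * width[mut])
      }
      newpop[i, ] <- clip(child)
    }
    pop <- newpop
    fit <- apply(pop, 1, fitness)
    if (max(fit) > best_f) {
      best_f <- max(fit)
      best_g <- pop[which.max(fit), ]
    }
    if (nm_every > 0 && gen %% nm_every == 0) {
      ref <- nelder_mead_maximize(fitness, best_g, lower, upper)
      rel <- (ref$max - best_f) / max(abs(best_f), .Machine$double.eps)
      if (rel >= nm_improve_threshold) {
        best_g <- clip(ref$argmax)
        best_f <- fitness(best_g)
        i_worst <- which.min(fit)
        pop[i_worst, ] <- best_g
        fit[i_worst] <- best_f
        log <- c(log, sprintf("generation %d: nelder-mead refinement accepted: %.6f",
                              gen, best_f))
      }
    }
    trace[gen] <- best_f
  }

  out_cat <- init
  out_cat$weight[on_idx] <- best_g[seq_len(k)]
  out_cat$curve[on_idx] <- best_g[k + seq_len(k)]
  log <- c(log, sprintf("final best: %.6f", best_f))
  structure(list(catalog = out_cat,
                 selected = feat_names,
                 trace = c(trace0, trace),
                 initial_map = init_f,
                 final_map = best_f,
                 method = "ga_nm",
                 seed = seed,
                 log = log),
            class = "tr_optimization")
}
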