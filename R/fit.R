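#' Control parameters for [tr_fit()]
#'
#' @param sfs_threshold Relative MAP improvement required for SFS inclusion
#'   (default 1e-4, i.e. 0.01\%).
#' @param population,generations GA budget.
#' @param mutation_sd,mutation_rate,crossover_rate,tournament,elitism GA
#'   operators, see [ga_optimize()].
#' @param nm_every,nm_improve_threshold Nelder-Mead refinement cadence and
#'   acceptance threshold (default 1e-3, i.e. 0.1\%).
#' @param weight_bounds,curve_bounds Parameter boxes.
#' @return A list of control values.
#' @export
tr_control <- function(sfs_threshold = 1e-4,
                       population = 40, generations = 60,
                       mutation_sd = 0.1, mutation_rate = 0.15,
                       crossover_rate = 0.9, tournament = 3, elitism = 1,
                       nm_every = 10, nm_improve_threshold = 1e-3,
                       weight_bounds = c(-10, 10), curve_bounds = c(-3, 3)) {
  stopifnot(sfs_threshold >= 0, nm_improve_threshold >= 0,
            all(is.finite(weight_bounds)), all(is.finite(curve_bounds)),
            weight_bounds[1] <= 0, weight_bounds[2] >= 0,
            curve_bounds[1] <= 0, curve_bounds[2] >= 0)
  as.list(environment())
}

#' Fit feature weights and curves by maximizing mean average precision
#'
#' The model: each gene's score is the normalized weighted average of its
#' curved, rescaled feature values, and the fitted parameters are the signed
#' weight and curve of every feature. Fitting maximizes mean MAP of the
#' known-positive targets over the supplied projects in two stages, mirroring
#' the exploratory-then-local optimization stack:
#' \enumerate{
#'   \item [sfs_optimize()] — sequential forward selection of the feature
#'     subset, each inclusion refined one coordinate at a time by Brent
#'     search;
#'   \item [ga_optimize()] — a seeded real-coded genetic algorithm over the
#'     selected features' weights and curves, with periodic Nelder-Mead
#'     sub-optimization of the best individual.
#' }
#' `strategy = "multi_cancer"` fits one parameter vector against the mean
#' MAP of all projects; `"phenotype_specific"` requires a single project.
#' With one project the two strategies coincide.
#'
#' @param projects List of [tr_project()]s (or a single project).
#' @param catalog Starting feature catalog (defaults, bounds, methods).
#' @param strategy "multi_cancer" or "phenotype_specific".
#' @param seed Integer seed driving all stochastic optimization.
#' @param control A [tr_control()] list.
#' @return An object of class `tr_fit` with components `catalog` (fitted
#'   parameters), `sfs`, `ga` (stage results), `trace`, `initial_map`,
#'   `final_map`, `strategy`, `seed` and `log`.
#' @seealso [coef.tr_fit()], [predict.tr_fit()], [plot.tr_fit()]
#' @export
tr_fit <- function(projects, catalog = default_catalog(),
                   strategy = c("multi_cancer", "phenotype_specific"),
                   seed = 1, control = tr_control()) {
  strategy <- match.arg(strategy)
  if (inherits(projects, "tr_project")) projects <- list(projects)
  stopifnot(length(projects) >= 1)
  if (strategy == "phenotype_specific" && length(projects) != 1L) {
    stop("phenotype_specific strategy takes exactly one project")
  }
  sfs <- sfs_optimize(projects, catalog,
                      improve_threshold = control$sfs_threshold,
                      weight_bounds = control$weight_bounds,
                      curve_bounds = control$curve_bounds)
  ga <- ga_optimize(projects, init = sfs$catalog,
                    population = control$population,
                    generations = control$generations,
                    mutation_sd = control$mutation_sd,
                    mutation_rate = control$mutation_rate,
                    crossover_rate = control$crossover_rate,
                    tournament = control$tournament,
                    elitism = control$elitism,
                    nm_every = control$nm_every,
                    nm_improve_threshold = control$nm_improve_threshold,
                    weight_bounds = control$weight_bounds,
                    curve_bounds = control$curve_bounds,
                    seed = seed)
  structure(list(catalog = ga$catalog,
                 sfs = sfs, ga = ga,
                 trace = c(sfs$trace, ga$trace),
                 initial_map = sfs$initial_map,
                 final_map = ga$final_map,
                 strategy = strategy,
                 seed = seed,
                 phenotypes = vapply(projects, `[[`, "", "phenotype"),
                 log = c(sfs$log, ga$log)),
            class = "tr_fit")
}

#' @export
print.tr_fit <- function(x, ...) {
  cat(sprintf("<tr_fit> %s over %d project(s) [%s], seed %d\n",
              x$strategy, length(x$phenotypes),
              paste(x$phenotypes, collapse = ", "), x$seed))
  cat(sprintf("  MAP: default %.4f -> SFS %.4f -> GA %.4f\n",
              x$initial_map, x$sfs$final_map, x$final_map))
  cat("  selected features:",
      paste(x$catalog$name[x$catalog$enabled], collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.tr_fit <- function(object, ...) {
  cat_on <- object$catalog[object$catalog$enabled, , drop = FALSE]
  out <- list(fit = object,
              params = cat_on[, c("name", "category", "weight", "curve")])
  class(out) <- "summary.tr_fit"
  out
}

#' @export
print.summary.tr_fit <- function(x, ...) {
  print(x$fit)
  cat("\nFitted parameters:\n")
  print(x$params, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Fitted weights and curves as a named vector
#' @param object A `tr_fit`.
#' @param ... Unused.
#' @export
coef.tr_fit <- function(object, ...) {
  cat_on <- object$catalog[object$catalog$enabled, , drop = FALSE]
  stats::setNames(c(cat_on$weight, cat_on$curve),
                  c(paste0("weight.", cat_on$name),
                    paste0("curve.", cat_on$name)))
}

#' Score a new feature matrix or project with the fitted parameters
#'
#' @param object A `tr_fit`.
#' @param newdata A `feature_matrix` or a [tr_project()] (whose labels then
#'   yield a MAP on the report).
#' @param ... Passed to [score_genes()].
#' @return A `tr_report`.
#' @export
predict.tr_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "tr_project")) {
    score_genes(newdata$fm, catalog = object$catalog,
                labels = newdata$labels, ...)
  } else {
    score_genes(newdata, catalog = object$catalog, ...)
  }
}

#' Plot the optimization trace of a fit
#'
#' Best-so-far mean MAP across SFS steps and GA generations.
#' @param x A `tr_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tr_fit <- function(x, ...) {
  n_sfs <- length(x$sfs$trace)
  graphics::plot(seq_along(x$trace), x$trace, type = "s",
                 xlab = "optimization step (SFS steps, then GA generations)",
                 ylab = "best-so-far mean MAP", ...)
  graphics::abline(v = n_sfs + 0.5, lty = 2, col = "grey50")
  graphics::mtext(c("SFS+Brent", "GA+NM"), side = 3,
                  at = c(n_sfs / 2, n_sfs + length(x$ga$trace) / 2),
                  cex = 0.8)
  invisible(x)
}
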