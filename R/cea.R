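#' Evaluate a cost-effectiveness model
#'
#' The main entry point: rolls the decision tree back to per-strategy
#' expected costs and QALYs and derives the comparison table (ICER versus
#' the lowest-cost reference, net monetary benefit at the willingness-to-pay
#' threshold, dominance flags, ranks). The returned object supports
#' \code{print()}, \code{summary()}, \code{predict()} (re-evaluation at new
#' parameter values), \code{simulate()} (probabilistic sensitivity
#' analysis) and \code{plot()} (cost-effectiveness plane).
#'
#' @param model A [cea_model()].
#' @param wtp Willingness-to-pay threshold in cost units per QALY
#'   (default 30,000).
#' @return Object of class \code{cea_fit} with elements \code{model},
#'   \code{wtp}, \code{outcomes} ([rollback()] result) and \code{table}
#'   ([rank_strategies()] result).
#' @examples
#' fit <- cea(phalanx_model(), wtp = 30000)
#' fit
#' summary(fit)
#' predict(fit, newdata = list(prevalence = 0.25))
#' @export
cea <- function(model, wtp = 30000) {
  stopifnot(inherits(model, "cea_model"))
  outcomes <- rollback(model)
  structure(list(model = model, wtp = wtp, outcomes = outcomes,
                 table = rank_strategies(outcomes, wtp)),
            class = "cea_fit")
}

#' @export
print.cea_fit <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' @export
summary.cea_fit <- function(object, ...) {
  structure(list(table = object$table,
                 frontier = frontier(object$outcomes),
                 wtp = object$wtp,
                 name = object$model$name),
            class = "summary.cea_fit")
}

#' @export
print.summary.cea_fit <- function(x, ...) {
  if (!is.null(x$name)) cat("Model:", x$name, "\n")
  print(x$table)
  opt <- x$table$strategy[x$table$rank == 1L]
  cat(sprintf("\nOptimal strategy at wtp %g: %s\n", x$wtp, opt))
  dom <- x$table$strategy[x$table$dominated]
  if (length(dom) > 0L)
    cat("Dominated:", paste(dom, collapse = ", "), "\n")
  cat("Frontier:", paste(x$frontier$strategy, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
coef.cea_fit <- function(object, ...) {
  stats::setNames(vapply(object$model$parameters, `[[`, numeric(1L),
                         "point_estimate"),
                  names(object$model$parameters))
}

#' Re-evaluate a fitted model at new parameter values
#'
#' @param object A [cea()] fit.
#' @param newdata Named list of parameter values overriding the point
#'   estimates (all other parameters unchanged).
#' @param ... Unused.
#' @return A [rank_strategies()] table at the fit's threshold.
#' @export
predict.cea_fit <- function(object, newdata = NULL, ...) {
  rank_strategies(rollback(object$model, newdata), object$wtp)
}

#' Simulate from a fitted model (probabilistic sensitivity analysis)
#'
#' \code{simulate()} on a [cea()] fit runs [run_psa()]: \code{nsim} joint
#' parameter draws propagated through the tree.
#'
#' @param object A [cea()] fit.
#' @param nsim Number of PSA iterations (default 1000).
#' @param seed Integer seed (required, for reproducibility).
#' @param ... Unused.
#' @return A [run_psa()] result.
#' @export
simulate.cea_fit <- function(object, nsim = 1000, seed = NULL, ...) {
  if (is.null(seed))
    stop("simulate.cea_fit requires an explicit `seed`", call. = FALSE)
  run_psa(object$model, n = nsim, seed = seed)
}

#' Plot a fitted model on the cost-effectiveness plane
#'
#' Expected cost against expected QALYs per strategy, with the efficiency
#' frontier drawn through the non-dominated strategies.
#'
#' @param x A [cea()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cea_fit <- function(x, ...) {
  oc <- x$outcomes
  fr <- frontier(oc)
  graphics::plot(oc$qaly, oc$cost, pch = 19,
                 xlab = "Expected QALYs", ylab = "Expected cost",
                 main = "Cost-effectiveness plane", ...)
  graphics::lines(fr$qaly, fr$cost, lty = 2, col = "grey40")
  graphics::text(oc$qaly, oc$cost, oc$strategy, pos = 3, cex = 0.8)
  invisible(x)
}
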