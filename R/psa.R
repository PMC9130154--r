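# Probabilistic sensitivity analysis: moment-matched samplers, Monte-Carlo
# propagation, acceptability curves, incremental scatter.

#' Fit a second-order distribution to a parameter
#'
#' Moment-matches the parameter's distribution family to its point estimate
#' \eqn{m} and standard deviation \eqn{s = dispersion \cdot m}:
#' \itemize{
#'   \item beta: \eqn{\alpha = m(m(1-m)/s^2 - 1)},
#'     \eqn{\beta = (1-m)(m(1-m)/s^2 - 1)}; requires \eqn{s^2 < m(1-m)}.
#'   \item gamma: shape \eqn{1/dispersion^2}, scale
#'     \eqn{m \cdot dispersion^2}.
#'   \item fixed: degenerate at \eqn{m}.
#' }
#'
#' @param spec A [cea_parameter()].
#' @return Object of class \code{cea_sampler}: a list with \code{family},
#'   \code{pars} and a \code{sample(n)} function drawing from the fitted
#'   distribution via the current RNG stream.
#' @examples
#' s <- fit_distribution(cea_parameter("u", 0.5, role = "utility",
#'   dist_family = "beta", dispersion = 0.2))
#' s$pars  # alpha = beta = 12
#' @export
fit_distribution <- function(spec) {
  stopifnot(inherits(spec, "cea_parameter"))
  m <- spec$point_estimate
  out <- switch(spec$dist_family,
    fixed = list(family = "fixed", pars = c(value = m),
                 sample = function(n) rep(m, n)),
    beta = {
      s2 <- (spec$dispersion * m)^2
      if (m <= 0 || m >= 1)
        stop("parameter ", sQuote(spec$name),
             ": beta requires a mean strictly inside (0, 1)", call. = FALSE)
      if (s2 >= m * (1 - m))
        stop("parameter ", sQuote(spec$name),
             ": infeasible dispersion for a beta distribution ",
             "(s^2 >= m(1-m))", call. = FALSE)
      nu <- m * (1 - m) / s2 - 1
      a <- m * nu; b <- (1 - m) * nu
      list(family = "beta", pars = c(shape1 = a, shape2 = b),
           sample = function(n) stats::rbeta(n, a, b))
    },
    gamma = {
      if (m <= 0)
        stop("parameter ", sQuote(spec$name),
             ": gamma requires a positive mean", call. = FALSE)
      shape <- 1 / spec$dispersion^2
      scale <- m * spec$dispersion^2
      list(family = "gamma", pars = c(shape = shape, scale = scale),
           sample = function(n) stats::rgamma(n, shape = shape,
                                              scale = scale))
    })
  structure(c(out, list(name = spec$name)), class = "cea_sampler")
}

#' @export
print.cea_sampler <- function(x, ...) {
  cat(sprintf("<cea_sampler> %s ~ %s(%s)\n", x$name, x$family,
              paste(sprintf("%s = %g", names(x$pars), x$pars),
                    collapse = ", ")))
  invisible(x)
}

#' Run a probabilistic sensitivity analysis
#'
#' Draws \code{n} independent joint parameter vectors from the fitted
#' second-order distributions (parameters with \code{dist_family =
#' "fixed"} are held at their point estimates) and rolls the tree back
#' once per draw. Draws are taken parameter by parameter in the order the
#' parameters are declared, so the full output is reproducible bit-for-bit
#' from \code{(seed, n)}. A draw under which any chance-node branch
#' probability leaves \code{[0, 1]} is rejected and redrawn; the count of
#' rejected draws is recorded.
#'
#' @param model A [cea_model()].
#' @param n Number of iterations.
#' @param seed Integer seed for the RNG stream.
#' @return Object of class \code{cea_psa}: \code{n}, \code{seed},
#'   \code{draws} (n-row data frame of sampled parameter values),
#'   \code{cost} and \code{qaly} (n-by-strategy matrices),
#'   \code{strategies}, \code{rejections}.
#' @examples
#' psa <- run_psa(phalanx_model(), n = 200, seed = 1)
#' psa
#' @export
run_psa <- function(model, n, seed) {
  stopifnot(inherits(model, "cea_model"),
            is.numeric(n), length(n) == 1L, n >= 1,
            is.numeric(seed), length(seed) == 1L)
  n <- as.integer(n)
  samplers <- lapply(model$parameters, fit_distribution)

  set.seed(as.integer(seed))
  draw_rows <- function(k) {
    d <- lapply(samplers, function(s) s$sample(k))
    as.data.frame(d, optional = TRUE)
  }
  draws <- draw_rows(n)

  # Collect chance-node probability expressions once.
  prob_exprs <- list()
  walk_nodes(model$root, function(node, path) {
    if (node$kind == "chance")
      for (b in node$branches)
        prob_exprs[[length(prob_exprs) + 1L]] <<- b$probability
  })
  invalid_rows <- function(d) {
    bad <- rep(FALSE, nrow(d))
    env <- as.list(d)
    for (ex in prob_exprs) {
      p <- rep_len(eval_cea_expr(ex, env), nrow(d))
      bad <- bad | p < 0 | p > 1
    }
    which(bad)
  }

  rejections <- 0L
  bad <- invalid_rows(draws)
  tries <- 0L
  while (length(bad) > 0L) {
    tries <- tries + 1L
    if (tries > 1000L)
      stop("rejection resampling did not terminate; the sampled ",
           "distributions are incompatible with the tree's probability ",
           "expressions", call. = FALSE)
    rejections <- rejections + length(bad)
    draws[bad, ] <- draw_rows(length(bad))
    bad <- bad[invalid_rows(draws[bad, , drop = FALSE])]
  }

  ev <- lapply(model$root$branches, eval_node, env = as.list(draws))
  cost <- vapply(model$strategies,
                 function(s) rep_len(ev[[s]]$cost, n), numeric(n))
  qaly <- vapply(model$strategies,
                 function(s) rep_len(ev[[s]]$qaly, n), numeric(n))
  if (n == 1L) {  # vapply returns vectors for n = 1
    cost <- matrix(cost, nrow = 1L, dimnames = list(NULL, model$strategies))
    qaly <- matrix(qaly, nrow = 1L, dimnames = list(NULL, model$strategies))
  }
  structure(list(n = n, seed = as.integer(seed), draws = draws,
                 cost = cost, qaly = qaly,
                 strategies = model$strategies, rejections = rejections),
            class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf(
    "Probabilistic sensitivity analysis: %d iterations (seed %d, %d rejected draws)\n",
    x$n, x$seed, x$rejections))
  cat("Mean outcomes:\n")
  print(data.frame(strategy = x$strategies,
                   cost = colMeans(x$cost),
                   qaly = colMeans(x$qaly), row.names = NULL))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value on a grid, the fraction of PSA
#' iterations in which each strategy attains the maximal net monetary
#' benefit. All grid values reuse the same draws (no re-sampling across
#' the grid), so the curves are smooth functions of the threshold. NMB
#' ties within an iteration split the probability mass equally, keeping
#' the probabilities an exact partition of 1 at every threshold.
#'
#' @param result A [run_psa()] result.
#' @param wtp_grid Numeric vector of strictly positive thresholds; default
#'   500 to 50,000 in steps of 500.
#' @return Data frame of class \code{cea_ceac} with columns \code{wtp},
#'   \code{strategy}, \code{probability}.
#' @examples
#' psa <- run_psa(phalanx_model(), n = 200, seed = 1)
#' head(ceac(psa, wtp_grid = c(10000, 30000)))
#' @export
ceac <- function(result, wtp_grid = seq(500, 50000, by = 500)) {
  stopifnot(inherits(result, "cea_psa"), is.numeric(wtp_grid),
            length(wtp_grid) >= 1L, all(wtp_grid > 0))
  S <- length(result$strategies)
  rows <- lapply(wtp_grid, function(l) {
    nb <- result$qaly - result$cost / l
    mx <- nb[cbind(seq_len(result$n), max.col(nb, ties.method = "first"))]
    win <- nb == mx
    w <- win / rowSums(win)
    data.frame(wtp = l, strategy = result$strategies,
               probability = colSums(w) / result$n, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cea_ceac", "data.frame")
  out
}

#' @export
plot.cea_ceac <- function(x, ...) {
  strategies <- unique(x$strategy)
  cols <- grDevices::hcl.colors(max(3L, length(strategies)), "Dark 3")
  graphics::plot(NULL, xlim = range(x$wtp), ylim = c(0, 1),
                 xlab = "Willingness to pay (per QALY)",
                 ylab = "Probability cost-effective",
                 main = "Cost-effectiveness acceptability curves", ...)
  for (i in seq_along(strategies)) {
    d <- x[x$strategy == strategies[i], ]
    graphics::lines(d$wtp, d$probability, col = cols[i], lwd = 2)
  }
  graphics::legend("right", legend = strategies,
                   col = cols[seq_along(strategies)], lwd = 2, bty = "n")
  invisible(x)
}

#' Incremental cost-effectiveness scatter
#'
#' Per-iteration incremental (QALY, cost) pairs of every non-reference
#' strategy against a reference strategy — the point cloud plotted on the
#' cost-effectiveness plane.
#'
#' @param result A [run_psa()] result.
#' @param reference Name of the reference strategy.
#' @return Data frame with columns \code{strategy}, \code{iteration},
#'   \code{delta_qaly}, \code{delta_cost}.
#' @export
incremental_scatter <- function(result, reference) {
  stopifnot(inherits(result, "cea_psa"))
  if (!reference %in% result$strategies)
    stop("unknown reference strategy: ", sQuote(reference), call. = FALSE)
  others <- setdiff(result$strategies, reference)
  do.call(rbind, lapply(others, function(s)
    data.frame(strategy = s, iteration = seq_len(result$n),
               delta_qaly = result$qaly[, s] - result$qaly[, reference],
               delta_cost = result$cost[, s] - result$cost[, reference])))
}
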