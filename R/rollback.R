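#' Expected-value rollback of the decision tree
#'
#' Evaluates the tree from the leaves up: at a terminal the payoffs are the
#' evaluated cost and QALY expressions; at a chance node they are the
#' probability-weighted sums over branches; at the root decision node each
#' strategy branch yields its own expected (cost, QALY) pair. The whole
#' cohort is thereby distributed over the terminal health states and each
#' strategy summarised by one expected cost and one expected QALY per
#' patient.
#'
#' @param model A [cea_model()].
#' @param assignment Optional named list (or vector) of parameter values
#'   overriding point estimates. Values may be equal-length numeric vectors,
#'   in which case the rollback is evaluated element-wise (used internally
#'   by the PSA).
#' @return A data frame of class \code{cea_outcomes} with columns
#'   \code{strategy}, \code{cost}, \code{qaly} (one row per strategy; with
#'   vector assignments, one row per strategy and assignment, with an
#'   \code{draw} index column).
#' @examples
#' rollback(phalanx_model())
#' @export
rollback <- function(model, assignment = NULL) {
  stopifnot(inherits(model, "cea_model"))
  env <- point_estimates(model$parameters)
  if (!is.null(assignment)) {
    assignment <- as.list(assignment)
    if (is.null(names(assignment)) || any(!nzchar(names(assignment))))
      stop("assignment must be named", call. = FALSE)
    unknown <- setdiff(names(assignment), names(env))
    if (length(unknown) > 0L)
      stop("unbound parameter name(s) in assignment: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    env[names(assignment)] <- assignment
  }
  missing <- setdiff(node_vars(model$root), names(env))
  if (length(missing) > 0L)
    stop("unbound parameter name(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  per_strategy <- lapply(model$root$branches, eval_node, env = env)
  lens <- vapply(per_strategy, function(x) length(x$cost), integer(1L))
  n <- max(lens, 1L)
  out <- do.call(rbind, lapply(model$strategies, function(s) {
    ev <- per_strategy[[s]]
    data.frame(strategy = s,
               draw = seq_len(n),
               cost = rep_len(ev$cost, n),
               qaly = rep_len(ev$qaly, n))
  }))
  if (n == 1L) out$draw <- NULL
  rownames(out) <- NULL
  class(out) <- c("cea_outcomes", "data.frame")
  out
}

# Recursive expected-value evaluation; vectorises over parameter vectors.
eval_node <- function(node, env) {
  switch(node$kind,
    terminal = list(cost = eval_cea_expr(node$cost, env),
                    qaly = eval_cea_expr(node$qaly, env)),
    chance = {
      cost <- 0; qaly <- 0
      for (b in node$branches) {
        p <- eval_cea_expr(b$probability, env)
        sub <- eval_node(b$node, env)
        cost <- cost + p * sub$cost
        qaly <- qaly + p * sub$qaly
      }
      list(cost = cost, qaly = qaly)
    },
    decision = stop("decision node below the root", call. = FALSE))
}

#' @export
print.cea_outcomes <- function(x, digits = 4, ...) {
  cat("Per-strategy expected outcomes (rollback)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
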