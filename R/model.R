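#' Assemble a cost-effectiveness decision model
#'
#' Binds a decision tree (a root [decision_node()] whose branches are the
#' strategies under comparison) to its parameter set. The model is the
#' object every analysis operation consumes: [rollback()], [cea()],
#' [one_way()], [tornado()], [run_psa()], [microsimulate()].
#'
#' @param root The root node; must be a decision node, and the only
#'   decision node in the tree (one-period model).
#' @param parameters List of [cea_parameter()] objects covering every name
#'   referenced by tree expressions.
#' @param name Optional model name.
#' @param calibration Optional calibration block (see
#'   [calibrate_endpoints()]); retained through serialisation.
#' @param validate Validate on construction (default \code{TRUE}); a
#'   violation raises an error.
#' @return An object of class \code{cea_model} with elements \code{root},
#'   \code{parameters} (named list), \code{strategies} (character, report
#'   order = branch order) and \code{name}.
#' @examples
#' m <- cea_model(
#'   decision_node(list(
#'     A = terminal_node("c_a", "q_a"),
#'     B = terminal_node("c_b", "q_b"))),
#'   parameters = list(
#'     cea_parameter("c_a", 10, role = "cost"),
#'     cea_parameter("q_a", 0.9, role = "utility"),
#'     cea_parameter("c_b", 25, role = "cost"),
#'     cea_parameter("q_b", 0.95, role = "utility")))
#' rollback(m)
#' @export
cea_model <- function(root, parameters, name = NULL, calibration = NULL,
                      validate = TRUE) {
  stopifnot(inherits(root, "cea_node"))
  model <- structure(
    list(name = name,
         root = root,
         parameters = as_parameter_set(parameters),
         strategies = names(root$branches),
         calibration = calibration),
    class = "cea_model")
  if (validate) {
    v <- validate_tree(model)
    if (length(v) > 0L)
      stop("invalid model:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  }
  model
}

#' @export
print.cea_model <- function(x, ...) {
  cat("Decision-tree cost-effectiveness model",
      if (!is.null(x$name)) paste0(" '", x$name, "'"), "\n", sep = "")
  cat("  strategies: ", paste(x$strategies, collapse = ", "), "\n", sep = "")
  cat("  parameters: ", length(x$parameters), "\n", sep = "")
  n_term <- 0L
  walk_nodes(x$root, function(node, path)
    if (node$kind == "terminal") n_term <<- n_term + 1L)
  cat("  terminal nodes: ", n_term, "\n", sep = "")
  invisible(x)
}

#' Validate model structure
#'
#' Reports (rather than raises) structural violations: the root must be the
#' single decision node; chance-node branch probabilities must sum to 1
#' within 1e-9 at the point estimates; every referenced name must exist in
#' the parameter set. Violations at chance nodes are hard modelling errors,
#' not candidates for silent renormalisation.
#'
#' @param model A [cea_model()] (constructed with \code{validate = FALSE}
#'   if you expect violations).
#' @param assignment Optional named parameter assignment at which to check
#'   probability sums; defaults to the point estimates.
#' @return Character vector of human-readable violations; empty if the
#'   model is valid.
#' @export
validate_tree <- function(model, assignment = NULL) {
  stopifnot(inherits(model, "cea_model"))
  violations <- character(0L)
  if (model$root$kind != "decision")
    violations <- c(violations, "root node is not a decision node")

  known <- names(model$parameters)
  unbound <- setdiff(node_vars(model$root), known)
  if (length(unbound) > 0L)
    violations <- c(violations,
                    paste0("unbound parameter name(s): ",
                           paste(sort(unbound), collapse = ", ")))

  if (is.null(assignment)) assignment <- point_estimates(model$parameters)

  walk_nodes(model$root, function(node, path) {
    where <- if (length(path) == 0L) "root" else paste(path, collapse = "/")
    if (node$kind == "decision" && length(path) > 0L)
      violations <<- c(violations,
                       paste0("decision node below the root at ", where,
                              " (one-period model allows exactly one)"))
    if (node$kind == "chance") {
      ok <- all(unlist(lapply(node$branches, function(b)
        all(expr_vars(b$probability) %in% known))))
      if (ok) {
        p <- vapply(node$branches, function(b)
          eval_cea_expr(b$probability, assignment), numeric(1L))
        if (any(p < -1e-9) || any(p > 1 + 1e-9))
          violations <<- c(violations,
                           paste0("branch probability outside [0, 1] at ",
                                  where))
        if (abs(sum(p) - 1) > 1e-9)
          violations <<- c(violations,
                           sprintf("probabilities sum to %.10g at %s",
                                   sum(p), where))
      }
    }
  })
  violations
}

#' Joint probabilities of diagnostic outcomes
#'
#' The four cells of the disease-by-test cross-classification implied by a
#' pretest probability and the test's operating characteristics:
#' TP = prevalence * sensitivity, FN = prevalence * (1 - sensitivity),
#' FP = (1 - prevalence) * (1 - specificity),
#' TN = (1 - prevalence) * specificity. These are the branch weights of a
#' diagnostic chance-node pair and always sum to 1.
#'
#' @param prevalence,sensitivity,specificity Probabilities in \code{[0, 1]}.
#' @return Named numeric vector \code{c(TP, FN, FP, TN)}.
#' @examples
#' diagnostic_joint_probabilities(0.18, 0.96, 0.90)
#' @export
diagnostic_joint_probabilities <- function(prevalence, sensitivity,
                                           specificity) {
  for (v in c(prevalence, sensitivity, specificity))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("prevalence, sensitivity and specificity must be single ",
           "probabilities in [0, 1]", call. = FALSE)
  c(TP = prevalence * sensitivity,
    FN = prevalence * (1 - sensitivity),
    FP = (1 - prevalence) * (1 - specificity),
    TN = (1 - prevalence) * specificity)
}
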