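# Node constructors and the restricted expression language.
#
# Probability and payoff expressions are limited to sums, differences and
# products of parameter references, numeric literals and parentheses.
# No division, no function calls: every expression stays a polynomial in
# the parameters and can be audited by eye. Expressions are stored both as
# the original string (for serialisation) and as a parsed language object
# (for evaluation).

parse_cea_expr <- function(text) {
  stopifnot(is.character(text) || is.numeric(text), length(text) == 1L)
  if (is.numeric(text)) return(list(src = as.character(text), lang = text))
  lang <- tryCatch(str2lang(text), error = function(e)
    stop("cannot parse expression: ", sQuote(text), call. = FALSE))
  check_cea_expr(lang, text)
  list(src = text, lang = lang)
}

check_cea_expr <- function(e, src) {
  if (is.numeric(e) || is.symbol(e)) return(invisible(TRUE))
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op %in% c("+", "-", "*", "(")) {
      for (i in seq_along(e)[-1L]) check_cea_expr(e[[i]], src)
      return(invisible(TRUE))
    }
  }
  stop("expression ", sQuote(src),
       " uses a construct outside the model language ",
       "(allowed: + - * parentheses, numbers, parameter names)",
       call. = FALSE)
}

eval_cea_expr <- function(expr, assignment) {
  if (is.numeric(expr$lang)) return(expr$lang)
  eval(expr$lang, envir = assignment, enclos = baseenv())
}

expr_vars <- function(expr) {
  if (is.numeric(expr$lang)) character(0L) else all.vars(expr$lang)
}

#' Decision-tree node constructors
#'
#' A one-period decision tree is built from three node kinds.
#' \code{decision_node()} sits at the root and carries one named branch per
#' strategy. \code{chance_node()} branches carry probability expressions over
#' parameter names; at any admissible parameter assignment the branch
#' probabilities must sum to 1 (checked by [validate_tree()] to 1e-9).
#' \code{terminal_node()} holds the cost (currency units) and QALY payoff
#' expressions accrued by patients reaching that leaf.
#'
#' Expressions are strings in a deliberately small language: sums,
#' differences and products of parameter names, numeric literals and
#' parentheses (e.g. \code{"(1 - prevalence) * spec_cbct"}).
#'
#' @param branches For \code{decision_node()}, a named list of nodes, one
#'   per strategy (names are the strategy labels). For \code{chance_node()},
#'   an unnamed list of branches created by \code{chance_branch()}.
#' @param probability Probability expression for a chance branch.
#' @param node Child node of a chance branch.
#' @param cost,qaly Payoff expressions of a terminal node.
#' @param label Optional terminal label (e.g. \code{"TP:arthritis"},
#'   \code{"FN"}); used by [microsimulate()] to annotate patient records.
#' @return A node object of class \code{cea_node}.
#' @examples
#' tn <- terminal_node(cost = "32", qaly = "q_healthy")
#' cn <- chance_node(list(
#'   chance_branch("prevalence", tn),
#'   chance_branch("1 - prevalence", tn)))
#' decision_node(list(CR = cn))
#' @name tree-nodes
NULL

#' @rdname tree-nodes
#' @export
decision_node <- function(branches) {
  stopifnot(is.list(branches), length(branches) >= 1L)
  if (is.null(names(branches)) || any(!nzchar(names(branches))))
    stop("decision branches must be named by strategy", call. = FALSE)
  if (anyDuplicated(names(branches)))
    stop("duplicate strategy names", call. = FALSE)
  for (b in branches) stopifnot(inherits(b, "cea_node"))
  structure(list(kind = "decision", branches = branches),
            class = "cea_node")
}

#' @rdname tree-nodes
#' @export
chance_node <- function(branches) {
  stopifnot(is.list(branches), length(branches) >= 1L)
  for (b in branches)
    if (!is.list(b) || is.null(b$probability) || is.null(b$node))
      stop("chance branches must be built with chance_branch()",
           call. = FALSE)
  structure(list(kind = "chance", branches = branches), class = "cea_node")
}

#' @rdname tree-nodes
#' @export
chance_branch <- function(probability, node) {
  stopifnot(inherits(node, "cea_node"))
  list(probability = parse_cea_expr(probability), node = node)
}

#' @rdname tree-nodes
#' @export
terminal_node <- function(cost, qaly, label = NULL) {
  structure(list(kind = "terminal",
                 cost = parse_cea_expr(cost),
                 qaly = parse_cea_expr(qaly),
                 label = label),
            class = "cea_node")
}

#' @export
print.cea_node <- function(x, ...) {
  cat(format_node(x), sep = "\n")
  invisible(x)
}

format_node <- function(node, indent = 0L) {
  pad <- strrep("  ", indent)
  switch(node$kind,
    decision = c(paste0(pad, "decision"),
                 unlist(lapply(names(node$branches), function(nm)
                   c(paste0(pad, "  [", nm, "]"),
                     format_node(node$branches[[nm]], indent + 2L))))),
    chance = c(paste0(pad, "chance"),
               unlist(lapply(node$branches, function(b)
                 c(paste0(pad, "  p = ", b$probability$src),
                   format_node(b$node, indent + 2L))))),
    terminal = paste0(pad, "terminal(cost = ", node$cost$src,
                      ", qaly = ", node$qaly$src,
                      if (!is.null(node$label)) paste0(", ", node$label),
                      ")"))
}

# All parameter names referenced anywhere below `node`.
node_vars <- function(node) {
  switch(node$kind,
    terminal = c(expr_vars(node$cost), expr_vars(node$qaly)),
    chance = unique(unlist(lapply(node$branches, function(b)
      c(expr_vars(b$probability), node_vars(b$node))))),
    decision = unique(unlist(lapply(node$branches, node_vars))))
}

# Apply FUN to every node (pre-order); used by validation.
walk_nodes <- function(node, fun, path = character(0L)) {
  fun(node, path)
  if (node$kind == "decision")
    for (nm in names(node$branches))
      walk_nodes(node$branches[[nm]], fun, c(path, nm))
  if (node$kind == "chance")
    for (i in seq_along(node$branches))
      walk_nodes(node$branches[[i]]$node, fun,
                 c(path, paste0("branch", i)))
  invisible(NULL)
}
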