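# Independent oracles and generators shared across tests.

# Brute-force path enumeration: collect every root-to-leaf path of a
# strategy's subtree as a product of probability expressions, evaluate each
# product, and sum probability-weighted payoffs. Independent of the
# package's recursive rollback.
enum_paths <- function(node, prob_exprs = character(0L)) {
  if (node$kind == "terminal")
    return(list(list(probs = prob_exprs, cost = node$cost$src,
                     qaly = node$qaly$src)))
  stopifnot(node$kind == "chance")
  out <- list()
  for (b in node$branches)
    out <- c(out, enum_paths(b$node, c(prob_exprs, b$probability$src)))
  out
}

path_enum_outcomes <- function(model, assignment = NULL) {
  env <- lapply(model$parameters, function(p) p$point_estimate)
  if (!is.null(assignment)) env[names(assignment)] <- assignment
  ev <- function(src) eval(parse(text = src)[[1L]], envir = env,
                           enclos = baseenv())
  do.call(rbind, lapply(model$strategies, function(s) {
    paths <- enum_paths(model$root$branches[[s]])
    cost <- 0; qaly <- 0
    for (p in paths) {
      w <- prod(vapply(p$probs, ev, numeric(1L)))
      cost <- cost + w * ev(p$cost)
      qaly <- qaly + w * ev(p$qaly)
    }
    data.frame(strategy = s, cost = cost, qaly = qaly)
  }))
}

fmt_num <- function(x) sprintf("%.17g", x)

# Random valid tree: chance nodes built from bare parameters and their
# complements so branch probabilities always sum to 1; terminals carry
# literal payoffs. Returns a cea_model. Call under a set seed.
random_model <- function(max_depth = 3L, n_strategies = NULL) {
  params <- list()
  new_prob <- function() {
    nm <- sprintf("p%d", length(params) + 1L)
    params[[length(params) + 1L]] <<- ceatree::cea_parameter(
      nm, stats::runif(1L, 0.05, 0.95), role = "probability",
      dist_family = "beta", dispersion = 0.1)
    nm
  }
  random_node <- function(depth) {
    if (depth <= 0L || stats::runif(1L) < 0.35)
      return(ceatree::terminal_node(cost = fmt_num(stats::runif(1L, 0, 200)),
                                    qaly = fmt_num(stats::runif(1L, 0, 10))))
    if (stats::runif(1L) < 0.5) {
      p <- new_prob()
      ceatree::chance_node(list(
        ceatree::chance_branch(p, random_node(depth - 1L)),
        ceatree::chance_branch(paste0("1 - ", p), random_node(depth - 1L))))
    } else {
      p <- new_prob(); q <- new_prob()
      ceatree::chance_node(list(
        ceatree::chance_branch(paste0(p, " * ", q),
                               random_node(depth - 1L)),
        ceatree::chance_branch(paste0(p, " * (1 - ", q, ")"),
                               random_node(depth - 1L)),
        ceatree::chance_branch(paste0("1 - ", p),
                               random_node(depth - 1L))))
    }
  }
  if (is.null(n_strategies)) n_strategies <- sample(2:3, 1L)
  branches <- lapply(seq_len(n_strategies), function(i) {
    p <- new_prob()  # force at least one chance level per strategy
    ceatree::chance_node(list(
      ceatree::chance_branch(p, random_node(max_depth - 1L)),
      ceatree::chance_branch(paste0("1 - ", p),
                             random_node(max_depth - 1L))))
  })
  names(branches) <- paste0("S", seq_len(n_strategies))
  ceatree::cea_model(ceatree::decision_node(branches), params,
                     name = "random")
}

# Printed per-strategy summary pairs of the bundled comparison (reference
# values used across tests).
table2_outcomes <- function() {
  data.frame(strategy = c("CR", "CBCT", "MSCT"),
             cost = c(32, 67.33, 106.23),
             qaly = c(7.9, 9.08, 8.18))
}

# Conditional expected QALY of a strategy given disease status, via a
# one-way prevalence evaluation at 0 or 1.
conditional_qaly <- function(model, strategy, status) {
  v <- if (status == "present") 1 else 0
  oc <- ceatree::rollback(model, list(prevalence = v))
  oc$qaly[oc$strategy == strategy]
}

# Copy of a model with every parameter held fixed (degenerate PSA).
all_fixed <- function(model) {
  model$parameters <- lapply(model$parameters, function(p) {
    p$dist_family <- "fixed"
    p
  })
  model
}

# Frontier walk-up decision rule: climb the cost-sorted frontier while the
# ICER against the previous member stays at or below the threshold.
walkup_optimal <- function(outcomes, wtp) {
  fr <- ceatree::frontier(outcomes)
  fr <- fr[!fr$tie | !duplicated(paste(fr$cost, fr$qaly)), , drop = FALSE]
  pick <- 1L
  for (i in seq_len(nrow(fr))[-1L])
    if (!is.na(fr$icer_vs_previous[i]) && fr$icer_vs_previous[i] <= wtp)
      pick <- i
  fr$strategy[pick]
}
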