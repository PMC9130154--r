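# JSON (de)serialisation of model configurations.
#
# Schema: an object with `name`, `strategies` (report order), `parameters`
# (array of parameter records), `tree` (nested node objects with `kind`,
# `branches`, `probability`, `cost`, `qaly`, `label`) and an optional
# `calibration` block consumed by calibrate_endpoints().

#' Read a model configuration from JSON
#'
#' @param path Path to a model JSON file.
#' @param validate Validate the model after construction (default
#'   \code{TRUE}).
#' @return A [cea_model()].
#' @seealso [write_cea_model()], [phalanx_model()]
#' @export
read_cea_model <- function(path, validate = TRUE) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  params <- lapply(raw$parameters, function(p)
    cea_parameter(p$name, p$point_estimate,
                  low = p$low %||% p$point_estimate,
                  high = p$high %||% p$point_estimate,
                  role = p$role %||% "other",
                  dist_family = p$dist_family %||% "fixed",
                  dispersion = p$dispersion %||% 0.10,
                  description = p$description))
  root <- node_from_list(raw$tree)
  model <- cea_model(root, params, name = raw$name,
                     calibration = raw$calibration, validate = validate)
  if (!is.null(raw$strategies)) {
    want <- unlist(raw$strategies)
    if (!setequal(want, model$strategies))
      stop("strategies field does not match the decision node's branches",
           call. = FALSE)
    model$strategies <- want
  }
  model
}

node_from_list <- function(x) {
  kind <- x$kind %||% stop("node without a 'kind' field", call. = FALSE)
  switch(kind,
    decision = {
      brs <- lapply(x$branches, function(b) node_from_list(b$node))
      names(brs) <- vapply(x$branches, function(b)
        b$name %||% stop("decision branch without a name", call. = FALSE),
        character(1L))
      decision_node(brs)
    },
    chance = chance_node(lapply(x$branches, function(b)
      chance_branch(b$probability, node_from_list(b$node)))),
    terminal = terminal_node(x$cost, x$qaly, label = x$label),
    stop("unknown node kind: ", sQuote(kind), call. = FALSE))
}

#' Write a model configuration to JSON
#'
#' Serialises a model to the same JSON schema [read_cea_model()] consumes;
#' reading the file back reproduces the model (expressions are stored as
#' their source strings).
#'
#' @param model A [cea_model()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_cea_model <- function(model, path) {
  stopifnot(inherits(model, "cea_model"))
  obj <- list(
    name = model$name,
    strategies = as.list(model$strategies),
    parameters = lapply(unname(model$parameters), function(p)
      drop_null(list(name = p$name, point_estimate = p$point_estimate,
                     low = p$low, high = p$high, role = p$role,
                     dist_family = p$dist_family, dispersion = p$dispersion,
                     description = p$description))),
    tree = node_to_list(model$root),
    calibration = model$calibration)
  jsonlite::write_json(drop_null(obj), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

node_to_list <- function(node) {
  switch(node$kind,
    decision = list(kind = "decision",
                    branches = lapply(names(node$branches), function(nm)
                      list(name = nm,
                           node = node_to_list(node$branches[[nm]])))),
    chance = list(kind = "chance",
                  branches = lapply(node$branches, function(b)
                    list(probability = b$probability$src,
                         node = node_to_list(b$node)))),
    terminal = drop_null(list(kind = "terminal", cost = node$cost$src,
                              qaly = node$qaly$src, label = node$label)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

drop_null <- function(x) x[!vapply(x, is.null, logical(1L))]
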