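#' Define a model parameter
#'
#' A parameter couples a point estimate with a plausible range and the
#' second-order distribution used during probabilistic sensitivity analysis.
#' Probabilities and utilities live on \code{[0, 1]} and are sampled from
#' beta distributions; costs are non-negative and sampled from gamma
#' distributions; \code{"fixed"} parameters are held at their point estimate
#' everywhere (the convention for quantities treated as deterministic, such
#' as test characteristics established from the literature).
#'
#' @param name Parameter name. Must be a syntactically valid identifier;
#'   node expressions refer to parameters by this name.
#' @param point_estimate Base-case value.
#' @param low,high Plausible range used by deterministic sensitivity
#'   analysis. Defaults to the point estimate (a degenerate range).
#' @param role One of \code{"probability"}, \code{"utility"}, \code{"cost"},
#'   \code{"other"}. Probabilities and utilities must lie in \code{[0, 1]}
#'   and use beta (or fixed) distributions; costs must be non-negative and
#'   use gamma (or fixed) distributions.
#' @param dist_family One of \code{"fixed"}, \code{"beta"}, \code{"gamma"}.
#' @param dispersion Relative standard error (standard deviation divided by
#'   the mean, dimensionless) used when moment-matching the PSA
#'   distribution. Ignored when \code{dist_family = "fixed"}. Default 0.10.
#' @param description Optional free-text annotation carried through
#'   serialisation.
#' @return An object of class \code{cea_parameter}.
#' @seealso [fit_distribution()], [cea_model()]
#' @examples
#' cea_parameter("prevalence", 0.18, 0.10, 0.25,
#'   role = "probability", dist_family = "beta")
#' @export
cea_parameter <- function(name, point_estimate, low = point_estimate,
                          high = point_estimate,
                          role = c("probability", "utility", "cost", "other"),
                          dist_family = c("fixed", "beta", "gamma"),
                          dispersion = 0.10, description = NULL) {
  role <- match.arg(role)
  dist_family <- match.arg(dist_family)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(point_estimate), length(point_estimate) == 1L,
            is.finite(point_estimate),
            is.numeric(low), is.numeric(high),
            is.numeric(dispersion), length(dispersion) == 1L)
  if (make.names(name) != name)
    stop("parameter name ", sQuote(name), " is not a valid identifier",
         call. = FALSE)
  if (low > point_estimate || point_estimate > high)
    stop("parameter ", sQuote(name),
         ": requires low <= point_estimate <= high", call. = FALSE)
  if (role %in% c("probability", "utility")) {
    if (point_estimate < 0 || point_estimate > 1)
      stop("parameter ", sQuote(name), ": role ", sQuote(role),
           " requires a point estimate in [0, 1]", call. = FALSE)
    if (!dist_family %in% c("beta", "fixed"))
      stop("parameter ", sQuote(name), ": role ", sQuote(role),
           " requires dist_family 'beta' or 'fixed'", call. = FALSE)
  }
  if (role == "cost") {
    if (point_estimate < 0)
      stop("parameter ", sQuote(name),
           ": costs must be non-negative", call. = FALSE)
    if (!dist_family %in% c("gamma", "fixed"))
      stop("parameter ", sQuote(name),
           ": role 'cost' requires dist_family 'gamma' or 'fixed'",
           call. = FALSE)
  }
  if (dist_family != "fixed" && !(is.finite(dispersion) && dispersion > 0))
    stop("parameter ", sQuote(name),
         ": dispersion must be positive for sampled parameters",
         call. = FALSE)
  structure(
    list(name = name, point_estimate = point_estimate,
         low = low, high = high, role = role,
         dist_family = dist_family, dispersion = dispersion,
         description = description),
    class = "cea_parameter")
}

#' @export
print.cea_parameter <- function(x, ...) {
  cat(sprintf("<cea_parameter> %s = %g [%g, %g] (%s, %s%s)\n",
              x$name, x$point_estimate, x$low, x$high, x$role,
              x$dist_family,
              if (x$dist_family == "fixed") ""
              else sprintf(", rse %g", x$dispersion)))
  invisible(x)
}

# Named list of parameters, keyed by name; input may be a single parameter
# or an unnamed list of cea_parameter objects.
as_parameter_set <- function(parameters) {
  if (inherits(parameters, "cea_parameter")) parameters <- list(parameters)
  stopifnot(is.list(parameters))
  for (p in parameters)
    if (!inherits(p, "cea_parameter"))
      stop("parameters must be cea_parameter objects", call. = FALSE)
  nms <- vapply(parameters, `[[`, character(1L), "name")
  if (anyDuplicated(nms))
    stop("duplicate parameter names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(parameters) <- nms
  parameters
}

# Point-estimate assignment (named list) for a parameter set.
point_estimates <- function(parameters) {
  lapply(parameters, `[[`, "point_estimate")
}
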