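# Deterministic sensitivity analysis: one-way sweeps, tornado summaries,
# strategy-switch thresholds.

#' One-way parameter sweep
#'
#' Re-evaluates the model over a grid of values for a single parameter,
#' holding every other parameter at its point estimate. For each grid value
#' the per-strategy expected cost, expected QALYs and lambda-scaled NMB are
#' reported, together with a flag marking the NMB-optimal strategy at that
#' value.
#'
#' @param model A [cea_model()].
#' @param parameter Name of the parameter to sweep.
#' @param grid Numeric vector of values. By default values must lie within
#'   the parameter's \code{[low, high]} range; set \code{force = TRUE} to
#'   sweep beyond it (e.g. a prevalence swept over the full \code{[0, 1]}
#'   axis).
#' @param wtp Willingness-to-pay threshold used for the NMB column.
#' @param force Allow grid values outside the parameter's plausible range.
#' @return Data frame with columns \code{value}, \code{strategy},
#'   \code{cost}, \code{qaly}, \code{nmb}, \code{optimal}.
#' @examples
#' m <- phalanx_model()
#' one_way(m, "prevalence", grid = c(0, 0.18, 1), wtp = 30000, force = TRUE)
#' @export
one_way <- function(model, parameter, grid, wtp = 30000, force = FALSE) {
  stopifnot(inherits(model, "cea_model"), is.numeric(grid),
            length(grid) >= 1L)
  p <- model$parameters[[parameter]]
  if (is.null(p))
    stop("unknown parameter: ", sQuote(parameter), call. = FALSE)
  if (!force && any(grid < p$low | grid > p$high))
    stop("grid values outside [", p$low, ", ", p$high, "] for ",
         sQuote(parameter), "; use force = TRUE to sweep beyond the ",
         "plausible range", call. = FALSE)
  out <- do.call(rbind, lapply(grid, function(v) {
    oc <- rollback(model, stats::setNames(list(v), parameter))
    oc$value <- v
    oc$nmb <- nmb(oc$cost, oc$qaly, wtp)$qaly_scaled
    oc$optimal <- seq_len(nrow(oc)) ==
      order(-oc$nmb, oc$strategy)[1L]
    oc
  }))
  rownames(out) <- NULL
  out <- out[, c("value", "strategy", "cost", "qaly", "nmb", "optimal")]
  attr(out, "parameter") <- parameter
  attr(out, "wtp") <- wtp
  out
}

#' Tornado analysis
#'
#' Sweeps each parameter to the endpoints of its plausible range, all other
#' parameters held at point estimates, and summarises the impact on a
#' scalar outcome: by default the lambda-scaled NMB of the base-case
#' optimal strategy, alternatively that strategy's expected QALYs. Entries
#' are sorted by decreasing width (the absolute difference between the
#' outcome at the high and low endpoints), the order in which a tornado
#' diagram stacks its bars.
#'
#' @param model A [cea_model()].
#' @param ranges Optional named list of \code{c(low, high)} ranges
#'   overriding the parameter set's own ranges. Parameters with degenerate
#'   ranges (low = high = point estimate) are widened to ±20% of the point
#'   estimate (clamped to \code{[0, 1]} for probabilities/utilities), the
#'   documented default for inputs whose plausible range is not stated.
#' @param wtp Willingness-to-pay threshold.
#' @param outcome \code{"nmb"} (default) or \code{"qaly"}.
#' @return Data frame of class \code{cea_tornado}: \code{parameter},
#'   \code{low}, \code{high}, \code{outcome_at_low}, \code{outcome_at_high},
#'   \code{width}, sorted by decreasing width; attributes \code{baseline}
#'   (base-case outcome value) and \code{strategy}.
#' @export
tornado <- function(model, ranges = NULL, wtp = 30000,
                    outcome = c("nmb", "qaly")) {
  stopifnot(inherits(model, "cea_model"))
  outcome <- match.arg(outcome)

  base <- rollback(model)
  base$nmb <- nmb(base$cost, base$qaly, wtp)$qaly_scaled
  opt <- base$strategy[order(-base$nmb, base$strategy)[1L]]
  value_of <- function(oc) {
    row <- oc[oc$strategy == opt, ]
    if (outcome == "nmb") nmb(row$cost, row$qaly, wtp)$qaly_scaled
    else row$qaly
  }

  nms <- names(model$parameters)
  rows <- lapply(nms, function(nm) {
    p <- model$parameters[[nm]]
    rg <- if (!is.null(ranges) && !is.null(ranges[[nm]])) ranges[[nm]]
          else c(p$low, p$high)
    if (rg[1L] == rg[2L]) rg <- default_range(p)
    lo <- value_of(rollback(model, stats::setNames(list(rg[1L]), nm)))
    hi <- value_of(rollback(model, stats::setNames(list(rg[2L]), nm)))
    data.frame(parameter = nm, low = rg[1L], high = rg[2L],
               outcome_at_low = lo, outcome_at_high = hi,
               width = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width, out$parameter), ]
  rownames(out) <- NULL
  attr(out, "baseline") <- value_of(base)
  attr(out, "strategy") <- opt
  attr(out, "wtp") <- wtp
  class(out) <- c("cea_tornado", "data.frame")
  out
}

# ±20% default range for a parameter without a stated plausible range,
# clamped to the role's natural domain.
default_range <- function(p) {
  rg <- p$point_estimate * c(0.8, 1.2)
  if (p$role %in% c("probability", "utility"))
    rg <- pmin(1, pmax(0, rg))
  if (p$role == "cost") rg <- pmax(0, rg)
  sort(rg)
}

#' @export
print.cea_tornado <- function(x, digits = 4, ...) {
  cat(sprintf("Tornado analysis of %s (baseline %.6g, wtp %g)\n",
              attr(x, "strategy"), attr(x, "baseline"), attr(x, "wtp")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Strategy-switch threshold of a parameter
#'
#' Finds the parameter value at which the base-case optimal strategy loses
#' its rank-1 position, i.e. the root of the leading NMB gap (optimal
#' strategy's NMB minus the best competitor's) over the parameter's range.
#' When the gap is affine in the parameter (the common case for a
#' probability entering each path once) the crossing is solved in closed
#' form; otherwise it is located by bisection to an absolute tolerance of
#' 1e-9. If the gap does not change sign over the range, there is no
#' switch and \code{NA} is returned.
#'
#' @param model A [cea_model()].
#' @param parameter Parameter name.
#' @param wtp Willingness-to-pay threshold.
#' @param range Optional \code{c(low, high)} overriding the parameter's own
#'   range.
#' @return The switch value, or \code{NA_real_} if the optimum never
#'   changes over the range.
#' @export
switch_threshold <- function(model, parameter, wtp = 30000, range = NULL) {
  stopifnot(inherits(model, "cea_model"))
  p <- model$parameters[[parameter]]
  if (is.null(p))
    stop("unknown parameter: ", sQuote(parameter), call. = FALSE)
  rg <- if (!is.null(range)) sort(as.numeric(range)) else c(p$low, p$high)
  if (rg[1L] == rg[2L]) return(NA_real_)

  base <- rollback(model)
  base$nmb <- nmb(base$cost, base$qaly, wtp)$qaly_scaled
  opt <- base$strategy[order(-base$nmb, base$strategy)[1L]]

  gap <- function(v) {
    oc <- rollback(model, stats::setNames(list(v), parameter))
    nb <- nmb(oc$cost, oc$qaly, wtp)$qaly_scaled
    nb[oc$strategy == opt] - max(nb[oc$strategy != opt])
  }

  g_lo <- gap(rg[1L]); g_hi <- gap(rg[2L])
  if (sign(g_lo) == sign(g_hi) || (g_lo == 0 && g_hi == 0))
    return(NA_real_)

  # Closed form when the gap is affine over the range (3-point check).
  mid <- mean(rg)
  g_mid <- gap(mid)
  lin <- g_lo + (g_hi - g_lo) * (mid - rg[1L]) / (rg[2L] - rg[1L])
  if (abs(g_mid - lin) <= 1e-9 * max(1, abs(g_lo), abs(g_hi)))
    return(rg[1L] - g_lo * (rg[2L] - rg[1L]) / (g_hi - g_lo))

  lo <- rg[1L]; hi <- rg[2L]
  while (hi - lo > 1e-9) {
    m <- (lo + hi) / 2
    if (sign(gap(m)) == sign(g_lo)) lo <- m else hi <- m
  }
  (lo + hi) / 2
}
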