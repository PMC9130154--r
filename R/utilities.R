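# Health-utility machinery: DASH -> EQ-5D mapping, utility trajectories,
# QALY accumulation, life-table lookup.

#' Coefficients of a DASH to EQ-5D mapping function
#'
#' A linear mapping predicting the EQ-5D utility index from hand-function
#' outcomes: pre-injury EQ-5D score, the DASH pain component, the EQ-5D
#' function component, and the pain-by-function product term.
#'
#' The package bundles a coefficient set
#' (\code{dash_eq5d_coefficients_synthetic.json} under \code{extdata})
#' that is explicitly synthetic: it has the qualitative structure of a
#' mapping estimated on an upper-limb fracture population (pain worsens,
#' better function and pre-injury health improve the predicted index) but
#' its values are placeholders, not estimates from any published
#' regression. Supply your own coefficients for substantive work.
#'
#' @param intercept,beta_eq5d_pre,beta_dash_pain,beta_eq5d_function,beta_interaction
#'   Finite regression coefficients; \code{beta_interaction} multiplies the
#'   product of the DASH pain and EQ-5D function components.
#' @param provenance Character string recording where the coefficients come
#'   from (required; use it honestly).
#' @return Object of class \code{eq5d_mapping}.
#' @examples
#' mapping_coefficients(0.2, 0.3, -0.004, 0.5, 0.001, provenance = "example")
#' @export
mapping_coefficients <- function(intercept, beta_eq5d_pre, beta_dash_pain,
                                 beta_eq5d_function, beta_interaction,
                                 provenance) {
  co <- c(intercept = intercept, beta_eq5d_pre = beta_eq5d_pre,
          beta_dash_pain = beta_dash_pain,
          beta_eq5d_function = beta_eq5d_function,
          beta_interaction = beta_interaction)
  stopifnot(is.numeric(co), all(is.finite(co)),
            is.character(provenance), length(provenance) == 1L)
  structure(list(coefficients = co, provenance = provenance),
            class = "eq5d_mapping")
}

#' @export
print.eq5d_mapping <- function(x, ...) {
  cat("DASH -> EQ-5D linear mapping (", x$provenance, ")\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Predict an EQ-5D utility index from DASH-related components
#'
#' Evaluates the linear predictor
#' \code{intercept + b1 * eq5d_pre + b2 * dash_pain + b3 * eq5d_function +
#' b4 * dash_pain * eq5d_function} and clamps the result to \code{[0, 1]}
#' (the EQ-5D index anchors 0 = dead, 1 = full health; states worse than
#' dead are outside this model's scope).
#'
#' @param eq5d_pre Pre-injury EQ-5D index.
#' @param dash_pain DASH pain component score.
#' @param eq5d_function EQ-5D function component score.
#' @param coefficients An [mapping_coefficients()] object.
#' @return Predicted utility in \code{[0, 1]} (vectorised over inputs).
#' @export
map_dash_to_eq5d <- function(eq5d_pre, dash_pain, eq5d_function,
                             coefficients) {
  stopifnot(inherits(coefficients, "eq5d_mapping"),
            is.numeric(eq5d_pre), is.numeric(dash_pain),
            is.numeric(eq5d_function),
            all(is.finite(eq5d_pre)), all(is.finite(dash_pain)),
            all(is.finite(eq5d_function)))
  co <- coefficients$coefficients
  eta <- co[["intercept"]] +
    co[["beta_eq5d_pre"]] * eq5d_pre +
    co[["beta_dash_pain"]] * dash_pain +
    co[["beta_eq5d_function"]] * eq5d_function +
    co[["beta_interaction"]] * dash_pain * eq5d_function
  pmin(1, pmax(0, eta))
}

#' Utility trajectory over a time horizon
#'
#' An ordered sequence of health-state segments, each a utility weight held
#' for a duration in years. QALYs accrue as utility times duration.
#'
#' @param utility Numeric vector of utilities in \code{[0, 1]}.
#' @param duration Numeric vector of strictly positive durations (years).
#' @return Data frame of class \code{utility_trajectory}.
#' @examples
#' tr <- utility_trajectory(c(0.759, 0.93), c(0.25, 0.75))
#' qalys(tr)
#' @export
utility_trajectory <- function(utility, duration) {
  stopifnot(is.numeric(utility), is.numeric(duration),
            length(utility) == length(duration))
  if (length(utility) > 0L) {
    stopifnot(all(is.finite(utility)), all(is.finite(duration)))
    if (any(utility < 0 | utility > 1))
      stop("utilities must lie in [0, 1]", call. = FALSE)
    if (any(duration <= 0))
      stop("durations must be positive", call. = FALSE)
  }
  structure(data.frame(utility = utility, duration = duration),
            class = c("utility_trajectory", "data.frame"))
}

#' Quality-adjusted life years of a trajectory
#'
#' Sums utility times duration over the segments of a trajectory. With a
#' positive annual discount rate, each segment contributes its
#' continuously-discounted integral
#' \eqn{u (e^{-r t_0} - e^{-r t_1}) / r} instead; the default rate is 0
#' (no discounting).
#'
#' @param trajectory A [utility_trajectory()] (or data frame with columns
#'   \code{utility}, \code{duration}).
#' @param discount_rate Annual discount rate, default 0.
#' @return QALYs (a single number; 0 for an empty trajectory).
#' @export
qalys <- function(trajectory, discount_rate = 0) {
  tr <- as.data.frame(trajectory)
  if (nrow(tr) == 0L) return(0)
  stopifnot(all(c("utility", "duration") %in% names(tr)),
            is.numeric(discount_rate), length(discount_rate) == 1L,
            discount_rate >= 0)
  if (discount_rate == 0) return(sum(tr$utility * tr$duration))
  t1 <- cumsum(tr$duration)
  t0 <- c(0, t1[-length(t1)])
  r <- discount_rate
  sum(tr$utility * (exp(-r * t0) - exp(-r * t1)) / r)
}

#' Remaining life expectancy from a life table
#'
#' Looks up remaining years of life at a given age, interpolating linearly
#' between tabulated ages. The bundled table
#' (\code{life_table_synthetic.json} under \code{extdata}) is a synthetic
#' period life table shaped like European population statistics; it passes
#' through 49.87 remaining years at age 30 and 45 remaining years at age
#' 35 (a mean age at death of 80 for the modelled cohort).
#'
#' @param age Age in years (vectorised); must lie within the table's domain.
#' @param life_table Data frame with numeric columns \code{age} and
#'   \code{remaining}; default the bundled synthetic table.
#' @return Remaining life expectancy in years.
#' @examples
#' remaining_years(30)
#' remaining_years(35)
#' @export
remaining_years <- function(age, life_table = read_life_table()) {
  stopifnot(is.numeric(age),
            is.data.frame(life_table),
            all(c("age", "remaining") %in% names(life_table)))
  lt <- life_table[order(life_table$age), ]
  if (any(age < min(lt$age) | age > max(lt$age)))
    stop("age outside the life table domain [",
         min(lt$age), ", ", max(lt$age), "]", call. = FALSE)
  stats::approx(lt$age, lt$remaining, xout = age, method = "linear",
                ties = "ordered")$y
}

#' Read a life table from JSON
#'
#' @param path Path to a JSON file with fields \code{age} and
#'   \code{remaining} (equal-length numeric arrays); defaults to the
#'   bundled synthetic table.
#' @return Data frame with columns \code{age}, \code{remaining}.
#' @export
read_life_table <- function(path = system.file("extdata",
                                               "life_table_synthetic.json",
                                               package = "ceatree")) {
  raw <- jsonlite::fromJSON(path)
  data.frame(age = as.numeric(raw$age), remaining = as.numeric(raw$remaining))
}

#' Read DASH to EQ-5D mapping coefficients from JSON
#'
#' @param path Path to a JSON file with the five coefficient fields and a
#'   \code{provenance} string; defaults to the bundled synthetic set.
#' @return An [mapping_coefficients()] object.
#' @export
read_mapping_coefficients <- function(path = system.file(
    "extdata", "dash_eq5d_coefficients_synthetic.json", package = "ceatree")) {
  raw <- jsonlite::fromJSON(path)
  mapping_coefficients(raw$intercept, raw$beta_eq5d_pre, raw$beta_dash_pain,
                       raw$beta_eq5d_function, raw$beta_interaction,
                       provenance = raw$provenance)
}
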