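# Comparison statistics: ICER, NMB, ranking, dominance, frontier.

# Truncation (not rounding) to 2 decimals: the reporting convention for NMB
# in lambda-scaled QALY units. A 1e-9 guard absorbs binary representation
# error so that values stored as e.g. 9.0799999... truncate as 9.08.
truncate2 <- function(x) trunc(x * 100 + sign(x) * 1e-9) / 100

#' Incremental cost-effectiveness ratio
#'
#' Difference in expected cost between two strategies divided by the
#' difference in expected QALYs, \eqn{(C_c - C_r) / (E_c - E_r)}. The sign
#' is preserved as computed; a negative ICER accompanies dominance (one
#' strategy cheaper and more effective) and should be read together with
#' the dominance flags of [rank_strategies()]. When the QALY difference is
#' zero the ratio is undefined and \code{NA} is returned.
#'
#' @param reference,comparator Strategy outcomes: any list or one-row data
#'   frame with elements/columns \code{cost} and \code{qaly} (a row of a
#'   [rollback()] result works directly).
#' @return The ICER in cost units per QALY, or \code{NA_real_} when the
#'   strategies have equal expected QALYs.
#' @examples
#' icer(list(cost = 32, qaly = 7.9), list(cost = 67.33, qaly = 9.08))
#' @export
icer <- function(reference, comparator) {
  r <- as.list(reference); c_ <- as.list(comparator)
  stopifnot(is.numeric(r$cost), is.numeric(r$qaly),
            is.numeric(c_$cost), is.numeric(c_$qaly))
  dq <- c_$qaly - r$qaly
  if (dq == 0) return(NA_real_)
  (c_$cost - r$cost) / dq
}

#' Net monetary benefit
#'
#' Values a strategy's expected QALYs at the willingness-to-pay threshold
#' \eqn{\lambda} and subtracts its cost. Two equivalent forms are returned:
#' the monetary form \eqn{E \lambda - C} (currency units) and the
#' lambda-scaled form \eqn{E - C / \lambda} (QALY units). Reported values
#' follow the lambda-scaled form truncated to 2 decimals; full-precision
#' values are retained for ranking and tie-breaking.
#'
#' @param cost,qaly Expected cost and expected QALYs (vectors recycle).
#' @param wtp Willingness-to-pay threshold (cost per QALY), strictly
#'   positive.
#' @return Data frame with columns \code{monetary}, \code{qaly_scaled},
#'   \code{reported}.
#' @examples
#' nmb(67.33, 9.08, wtp = 30000)
#' @export
nmb <- function(cost, qaly, wtp) {
  stopifnot(is.numeric(cost), is.numeric(qaly),
            is.numeric(wtp), length(wtp) == 1L)
  if (!is.finite(wtp) || wtp <= 0)
    stop("wtp must be a positive willingness-to-pay threshold",
         call. = FALSE)
  scaled <- qaly - cost / wtp
  data.frame(monetary = qaly * wtp - cost,
             qaly_scaled = scaled,
             reported = truncate2(scaled))
}

#' Rank strategies at a willingness-to-pay threshold
#'
#' Builds the full comparison table: per-strategy expected cost and QALYs,
#' ICER against the reference strategy (the lowest-cost strategy; ties
#' broken by name), lambda-scaled NMB, incremental NMB versus the
#' reference, strict-dominance flags, and rank by decreasing NMB (NMB ties
#' broken deterministically by strategy name). Rank 1 is the optimal
#' strategy at the threshold.
#'
#' @param outcomes A \code{cea_outcomes} data frame ([rollback()]) or any
#'   data frame with columns \code{strategy}, \code{cost}, \code{qaly}.
#' @param wtp Willingness-to-pay threshold (cost per QALY).
#' @return A data frame of class \code{cea_table} with columns
#'   \code{strategy}, \code{cost}, \code{qaly}, \code{icer},
#'   \code{reference}, \code{nmb}, \code{nmb_reported},
#'   \code{incremental_nmb}, \code{incremental_nmb_reported},
#'   \code{dominated}, \code{rank}; attribute \code{wtp}.
#' @examples
#' tab <- rank_strategies(rollback(phalanx_model()), wtp = 30000)
#' tab
#' @export
rank_strategies <- function(outcomes, wtp) {
  outcomes <- as.data.frame(outcomes)
  stopifnot(all(c("strategy", "cost", "qaly") %in% names(outcomes)),
            nrow(outcomes) >= 2L)
  if (anyDuplicated(outcomes$strategy))
    stop("duplicate strategy names in outcomes", call. = FALSE)
  nb <- nmb(outcomes$cost, outcomes$qaly, wtp)

  ref_i <- order(outcomes$cost, outcomes$strategy)[1L]
  icers <- vapply(seq_len(nrow(outcomes)), function(i) {
    if (i == ref_i) NA_real_
    else icer(outcomes[ref_i, ], outcomes[i, ])
  }, numeric(1L))

  dominated <- vapply(seq_len(nrow(outcomes)), function(i)
    any(outcomes$cost < outcomes$cost[i] & outcomes$qaly > outcomes$qaly[i]),
    logical(1L))

  rank <- integer(nrow(outcomes))
  rank[order(-nb$qaly_scaled, outcomes$strategy)] <- seq_len(nrow(outcomes))

  inc <- nb$qaly_scaled - nb$qaly_scaled[ref_i]
  tab <- data.frame(strategy = outcomes$strategy,
                    cost = outcomes$cost,
                    qaly = outcomes$qaly,
                    icer = icers,
                    reference = seq_len(nrow(outcomes)) == ref_i,
                    nmb = nb$qaly_scaled,
                    nmb_reported = nb$reported,
                    incremental_nmb = inc,
                    incremental_nmb_reported = truncate2(inc),
                    dominated = dominated,
                    rank = rank)
  attr(tab, "wtp") <- wtp
  class(tab) <- c("cea_table", "data.frame")
  tab
}

#' @export
print.cea_table <- function(x, digits = 4, ...) {
  cat(sprintf("Cost-effectiveness comparison at wtp = %g per QALY\n",
              attr(x, "wtp")))
  df <- as.data.frame(x)
  df$icer <- ifelse(df$reference, "reference",
                    formatC(df$icer, format = "f", digits = 2))
  print.data.frame(df[order(df$rank),
                      c("strategy", "cost", "qaly", "icer", "nmb_reported",
                        "incremental_nmb_reported", "dominated", "rank")],
                   digits = digits, row.names = FALSE)
  invisible(x)
}

#' Cost-effectiveness frontier
#'
#' The efficient subset of strategies: those excluded neither by strict
#' dominance (another strategy is cheaper with more QALYs) nor by extended
#' dominance (a convex combination of two other frontier strategies is
#' better). The frontier is returned sorted by increasing cost, with the
#' ICER of each strategy against its frontier predecessor; these ICERs are
#' increasing along the frontier. Strategies with identical (cost, QALY)
#' pairs are all retained and flagged as ties.
#'
#' @param outcomes Data frame with columns \code{strategy}, \code{cost},
#'   \code{qaly}.
#' @return Data frame with the frontier strategies (columns as input plus
#'   \code{icer_vs_previous} and logical \code{tie}), sorted by cost.
#' @examples
#' frontier(rollback(phalanx_model()))
#' @export
frontier <- function(outcomes) {
  outcomes <- as.data.frame(outcomes)
  stopifnot(all(c("strategy", "cost", "qaly") %in% names(outcomes)),
            nrow(outcomes) >= 1L)
  keep <- vapply(seq_len(nrow(outcomes)), function(i)
    !any(outcomes$cost < outcomes$cost[i] &
           outcomes$qaly > outcomes$qaly[i]),
    logical(1L))
  fr <- outcomes[keep, , drop = FALSE]
  fr <- fr[order(fr$cost, -fr$qaly, fr$strategy), , drop = FALSE]

  # Extended dominance: drop interior strategies whose ICER against the
  # previous frontier member exceeds the next member's; repeat to fixpoint.
  # Tied (cost, qaly) duplicates are exempt and retained.
  dup_key <- paste(fr$cost, fr$qaly)
  tie <- duplicated(dup_key) | duplicated(dup_key, fromLast = TRUE)
  repeat {
    active <- which(!tie | !duplicated(paste(fr$cost, fr$qaly)))
    if (length(active) < 3L) break
    ic <- diff(fr$cost[active]) / diff(fr$qaly[active])
    bad <- which(diff(ic) < 0)
    if (length(bad) == 0L) break
    drop_row <- active[bad[1L] + 1L]
    tie <- tie[-drop_row]
    fr <- fr[-drop_row, , drop = FALSE]
  }
  active <- which(!tie | !duplicated(paste(fr$cost, fr$qaly)))
  fr$icer_vs_previous <- NA_real_
  if (length(active) > 1L)
    fr$icer_vs_previous[active[-1L]] <-
      diff(fr$cost[active]) / diff(fr$qaly[active])
  fr$tie <- tie
  rownames(fr) <- NULL
  fr
}
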