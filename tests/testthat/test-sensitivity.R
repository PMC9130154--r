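test_that("a one-point sweep at the point estimate is the base case", {
  m <- phalanx_model()
  base <- rollback(m)
  ow <- one_way(m, "prevalence", grid = 0.18, wtp = 30000)
  expect_equal(ow$cost, base$cost, tolerance = 1e-15)
  expect_equal(ow$qaly, base$qaly, tolerance = 1e-15)
})

test_that("sweeping prevalence across the disease axis hits the endpoints", {
  m <- phalanx_model()
  ow <- one_way(m, "prevalence", grid = c(0, 1), wtp = 30000, force = TRUE)
  q <- function(v, s) ow$qaly[ow$value == v & ow$strategy == s]
  expect_equal(q(0, "CBCT"), 8.8, tolerance = 1e-9)
  expect_equal(q(0, "MSCT"), 7.9, tolerance = 1e-9)
  expect_equal(q(1, "CBCT"), 9.08, tolerance = 1e-9)
  expect_equal(q(1, "MSCT"), 8.18, tolerance = 1e-9)
  expect_true(all(ow$optimal[ow$strategy == "CBCT"]))
})

test_that("grids outside the plausible range require force", {
  m <- phalanx_model()
  expect_error(one_way(m, "prevalence", grid = c(0, 1), wtp = 30000),
               "force = TRUE")
  expect_error(one_way(m, "nonesuch", grid = 0.5), "unknown parameter")
})

test_that("one-way outputs are affine in a linear-entry parameter", {
  m <- phalanx_model()
  ow <- one_way(m, "prevalence", grid = c(0.10, 0.175, 0.25), wtp = 30000)
  for (s in m$strategies) {
    y <- ow$nmb[ow$strategy == s]
    expect_equal(y[2], (y[1] + y[3]) / 2, tolerance = 1e-9)
  }
})

test_that("tornado widths match an independent two-rollback oracle", {
  m <- phalanx_model()
  tor <- tornado(m, wtp = 30000)
  base <- rollback(m)
  base$nmb <- nmb(base$cost, base$qaly, 30000)$qaly_scaled
  opt <- base$strategy[which.max(base$nmb)]
  for (i in seq_len(nrow(tor))) {
    nm <- tor$parameter[i]
    ev <- function(v) {
      oc <- rollback(m, stats::setNames(list(v), nm))
      row <- oc[oc$strategy == opt, ]
      nmb(row$cost, row$qaly, 30000)$qaly_scaled
    }
    expect_equal(tor$width[i],
                 abs(ev(tor$high[i]) - ev(tor$low[i])),
                 tolerance = 1e-12, info = nm)
  }
  expect_equal(tor$width, sort(tor$width, decreasing = TRUE))
})

test_that("an unreferenced parameter has zero tornado width and sorts last", {
  tor <- tornado(phalanx_model(), wtp = 30000)
  expect_equal(tor$width[tor$parameter == "pretest_probability"], 0)
  # sorts after every parameter with leverage on the optimal strategy
  expect_gt(match("pretest_probability", tor$parameter),
            max(which(tor$width > 0)))
})

test_that("tornado widths are invariant to sweep direction", {
  m <- phalanx_model()
  fwd <- tornado(m, wtp = 30000)
  swapped <- lapply(stats::setNames(nm = fwd$parameter), function(nm) {
    i <- match(nm, fwd$parameter)
    c(fwd$high[i], fwd$low[i])
  })
  # ranges are re-sorted internally; widths must match regardless
  rev <- tornado(m, ranges = lapply(swapped, sort), wtp = 30000)
  expect_equal(fwd$width[order(fwd$parameter)],
               rev$width[order(rev$parameter)], tolerance = 1e-12)
})

test_that("a parameter without leverage yields no switch threshold", {
  expect_true(is.na(switch_threshold(phalanx_model(),
                                     "pretest_probability", wtp = 30000)))
})

test_that("an affine NMB gap is solved to its analytic root", {
  m <- cea_model(
    decision_node(list(
      A = chance_node(list(
        chance_branch("p", terminal_node("0", "1")),
        chance_branch("1 - p", terminal_node("0", "0")))),
      B = chance_node(list(
        chance_branch("0.5", terminal_node("0", "1")),
        chance_branch("0.5", terminal_node("0", "0")))))),
    parameters = list(cea_parameter("p", 0.7, 0, 1,
                                    role = "probability",
                                    dist_family = "beta")))
  # E[A] = p, E[B] = 0.5: the optimum switches exactly at p = 0.5
  expect_equal(switch_threshold(m, "p", wtp = 30000), 0.5,
               tolerance = 1e-9)
})

test_that("the CBCT cost break-even matches the closed-form NMB equality", {
  m <- phalanx_model()
  base <- rollback(m)
  nb <- nmb(base$cost, base$qaly, 30000)$qaly_scaled
  others <- base$strategy != "CBCT"
  cstar <- min(base$cost[others] +
                 30000 * (base$qaly[base$strategy == "CBCT"] -
                            base$qaly[others]))
  got <- switch_threshold(m, "cost_cbct", wtp = 30000,
                          range = c(53.864, 40000))
  expect_equal(got, cstar, tolerance = 1e-6)
})
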