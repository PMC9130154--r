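test_that("moment matching recovers the stated beta and gamma forms", {
  b <- fit_distribution(cea_parameter("u", 0.5, role = "utility",
                                      dist_family = "beta",
                                      dispersion = 0.2))  # s = 0.1
  expect_equal(unname(b$pars), c(12, 12), tolerance = 1e-12)

  g <- fit_distribution(cea_parameter("c", 67.33, role = "cost",
                                      dist_family = "gamma",
                                      dispersion = 0.1))
  expect_equal(unname(g$pars["shape"]), 100, tolerance = 1e-12)
  expect_equal(unname(g$pars["scale"]), 0.6733, tolerance = 1e-12)

  f <- fit_distribution(cea_parameter("prev", 0.18, role = "probability",
                                      dist_family = "fixed"))
  expect_equal(f$sample(5), rep(0.18, 5))

  expect_error(
    fit_distribution(cea_parameter("u", 0.5, role = "utility",
                                   dist_family = "beta",
                                   dispersion = 1.2)),
    "infeasible dispersion")
})

test_that("fitted samplers reproduce their first two moments", {
  set.seed(99)
  b <- fit_distribution(cea_parameter("u", 0.759, role = "utility",
                                      dist_family = "beta",
                                      dispersion = 0.1))
  x <- b$sample(50000)
  expect_equal(mean(x), 0.759, tolerance = 0.02)
  expect_equal(sd(x), 0.0759, tolerance = 0.02)
  g <- fit_distribution(cea_parameter("c", 106.23, role = "cost",
                                      dist_family = "gamma",
                                      dispersion = 0.1))
  y <- g$sample(50000)
  expect_equal(mean(y), 106.23, tolerance = 0.02)
  expect_equal(sd(y), 10.623, tolerance = 0.02)
})

test_that("a degenerate all-fixed PSA reproduces the base-case rollback", {
  m <- all_fixed(phalanx_model())
  res <- run_psa(m, n = 1, seed = 4)
  base <- rollback(m)
  expect_equal(as.vector(res$cost[1, ]), base$cost, tolerance = 1e-15)
  expect_equal(as.vector(res$qaly[1, ]), base$qaly, tolerance = 1e-15)
  expect_equal(res$rejections, 0L)
})

test_that("the PSA is bit-for-bit reproducible from (seed, n)", {
  m <- phalanx_model()
  a <- run_psa(m, n = 300, seed = 123)
  b <- run_psa(m, n = 300, seed = 123)
  expect_identical(a$draws, b$draws)
  expect_identical(a$cost, b$cost)
  expect_identical(a$qaly, b$qaly)
  c_ <- run_psa(m, n = 300, seed = 124)
  expect_false(identical(a$draws, c_$draws))
})

test_that("Monte-Carlo means stay within sampling error of the rollback", {
  m <- phalanx_model()
  res <- run_psa(m, n = 4000, seed = 21)
  base <- rollback(m)
  for (s in m$strategies) {
    se <- sd(res$cost[, s]) / sqrt(res$n)
    expect_lt(abs(mean(res$cost[, s]) - base$cost[base$strategy == s]),
              3 * se + 1e-12)
  }
})

test_that("draws pushing a branch probability outside [0, 1] are rejected", {
  m <- cea_model(
    decision_node(list(A = chance_node(list(
      chance_branch("p1 + 0.2", terminal_node("1", "1")),
      chance_branch("0.8 - p1", terminal_node("2", "2")))))),
    parameters = list(cea_parameter("p1", 0.6, role = "probability",
                                    dist_family = "beta",
                                    dispersion = 0.25)))
  res <- run_psa(m, n = 2000, seed = 8)
  expect_gt(res$rejections, 0L)
  expect_true(all(res$draws$p1 <= 0.8))
  res2 <- run_psa(m, n = 2000, seed = 8)
  expect_identical(res$draws, res2$draws)  # rejection path is seeded too
})

test_that("acceptability probabilities partition 1 and reuse the draws", {
  m <- phalanx_model()
  res <- run_psa(m, n = 500, seed = 14)
  grid <- c(1000, 7500, 30000)
  cc <- ceac(res, grid)
  for (l in grid)
    expect_equal(sum(cc$probability[cc$wtp == l]), 1, tolerance = 1e-12)
  expect_identical(cc, ceac(res, grid))
})

test_that("the acceptability of the dominant strategy rises to 1 as
           dispersions shrink", {
  m <- phalanx_model()
  tighten <- function(model, f) {
    model$parameters <- lapply(model$parameters, function(p) {
      p$dispersion <- p$dispersion * f
      p
    })
    model
  }
  prob_cbct <- vapply(c(1, 0.2), function(f) {
    res <- run_psa(tighten(m, f), n = 400, seed = 9)
    cc <- ceac(res, 30000)
    cc$probability[cc$strategy == "CBCT"]
  }, numeric(1L))
  expect_true(prob_cbct[2] >= prob_cbct[1] - 0.02)
  res0 <- run_psa(all_fixed(m), n = 50, seed = 2)
  cc0 <- ceac(res0, 30000)
  expect_equal(cc0$probability[cc0$strategy == "CBCT"], 1)
})

test_that("incremental scatter reflects base-case increments", {
  m <- phalanx_model()
  res0 <- run_psa(all_fixed(m), n = 3, seed = 5)
  sc0 <- incremental_scatter(res0, "CR")
  base <- rollback(m)
  d <- function(s, col) base[[col]][base$strategy == s] -
    base[[col]][base$strategy == "CR"]
  expect_equal(unique(sc0$delta_cost[sc0$strategy == "CBCT"]),
               d("CBCT", "cost"), tolerance = 1e-12)
  expect_equal(unique(sc0$delta_qaly[sc0$strategy == "CBCT"]),
               d("CBCT", "qaly"), tolerance = 1e-12)

  res <- run_psa(m, n = 4000, seed = 77)
  sc <- incremental_scatter(res, "CR")
  dc <- sc$delta_cost[sc$strategy == "CBCT"]
  dq <- sc$delta_qaly[sc$strategy == "CBCT"]
  expect_lt(abs(mean(dc) - d("CBCT", "cost")),
            3 * sd(dc) / sqrt(length(dc)) + 1e-12)
  expect_lt(abs(mean(dq) - d("CBCT", "qaly")),
            3 * sd(dq) / sqrt(length(dq)) + 1e-12)

  # MSCT relative to CBCT sits in the dominated quadrant on average
  sc2 <- incremental_scatter(res, "CBCT")
  expect_gt(mean(sc2$delta_cost[sc2$strategy == "MSCT"]), 0)
  expect_lt(mean(sc2$delta_qaly[sc2$strategy == "MSCT"]), 0)
})
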