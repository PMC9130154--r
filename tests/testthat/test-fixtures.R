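test_that("the bundled model is valid and carries the expected schema", {
  m <- phalanx_model()
  expect_length(validate_tree(m), 0L)
  expect_equal(m$strategies, c("CR", "CBCT", "MSCT"))
  expect_setequal(
    names(m$parameters),
    c("prevalence", "pretest_probability",
      "sens_cr", "spec_cr", "sens_cbct", "spec_cbct",
      "sens_msct", "spec_msct",
      "p_displacement", "p_nonunion", "p_arthritis",
      "cost_cr", "cost_cbct", "cost_msct",
      "u_population", "u_base", "u_immobilization", "u_symptom_dec",
      "age_injury", "age_death",
      "q_cr_absent", "q_cr_present", "q_cbct_absent", "q_cbct_present",
      "q_msct_absent", "q_msct_present"))
})

test_that("rollback preserves the unit costs of each strategy exactly", {
  oc <- rollback(phalanx_model())
  expect_equal(oc$cost, c(32, 67.33, 106.23), tolerance = 1e-12)
  oc0 <- rollback(phalanx_model(), list(prevalence = 0))
  expect_equal(oc0$qaly[oc0$strategy == "CR"], 7.9, tolerance = 1e-9)
})

test_that("calibration reproduces every conditional QALY endpoint", {
  m <- phalanx_model()
  targets <- list(CR = c(absent = 7.9, present = 7.9),
                  CBCT = c(absent = 8.8, present = 9.08),
                  MSCT = c(absent = 7.9, present = 8.18))
  for (s in names(targets))
    for (st in c("absent", "present"))
      expect_equal(conditional_qaly(m, s, st), unname(targets[[s]][st]),
                   tolerance = 1e-9, info = paste(s, st))
  # linear interpolation between the endpoints at the base-case prevalence
  oc <- rollback(m)
  expect_equal(oc$qaly[oc$strategy == "CBCT"], 8.8 + 0.18 * 0.28,
               tolerance = 1e-9)
})

test_that("equal endpoint targets make a strategy prevalence-invariant", {
  m <- phalanx_model()
  ow <- one_way(m, "prevalence", grid = c(0, 0.5, 1), wtp = 30000,
                force = TRUE)
  cr <- ow$qaly[ow$strategy == "CR"]
  expect_equal(cr, rep(7.9, 3), tolerance = 1e-9)
})

test_that("targets that would force negative leaf payoffs are rejected", {
  m <- phalanx_model(calibrate = FALSE)
  bad <- m$calibration$targets
  bad[[4]]$target <- 0.5  # CBCT present, below the complication decrements
  expect_error(calibrate_endpoints(m, targets = bad),
               "infeasible calibration")
})

test_that("calibration demands an additive single-use anchor", {
  m <- phalanx_model(calibrate = FALSE)
  tg <- list(list(strategy = "CBCT", status = "present",
                  anchor = "u_symptom_dec", target = 9.08))
  expect_error(calibrate_endpoints(m, targets = tg),
               "additively exactly once")
})

test_that("microsimulation means converge to the rollback expectations", {
  m <- phalanx_model()
  ms <- microsimulate(m, n = 20000, seed = 6)
  base <- rollback(m)
  for (s in m$strategies) {
    qs <- ms$records$qaly[ms$records$strategy == s]
    se <- sd(qs) / sqrt(length(qs))
    expect_lt(abs(mean(qs) - base$qaly[base$strategy == s]), 3 * se + 1e-12)
  }
  expect_equal(nrow(ms$summary), length(m$strategies))
})

test_that("microsimulation records realise consistent paths", {
  m <- phalanx_model()
  ms <- microsimulate(m, n = 2000, seed = 10)
  r <- ms$records
  expect_equal(nrow(r), 2000 * 3)
  # accrued cost equals the strategy's terminal (unit) cost on every path
  unit <- c(CR = 32, CBCT = 67.33, MSCT = 106.23)
  expect_equal(r$cost, unname(unit[r$strategy]), tolerance = 1e-12)
  # complication labels occur exactly on treated true-positive paths
  expect_true(all(!is.na(r$complication) ==
                    (r$true_fracture & r$test_result)))
  expect_true(all(r$complication[!is.na(r$complication)] %in%
                    c("displacement", "non-union", "arthritis", "none")))
  # a positive test in a fracture-free patient is an FP path
  fp <- !r$true_fracture & r$test_result
  expect_true(all(is.na(r$complication[fp])))
  # sex is metadata at roughly the assumed 2:1 ratio
  expect_equal(mean(r$sex == "male"), 2 / 3, tolerance = 0.05)
  expect_identical(ms$records,
                   microsimulate(m, n = 2000, seed = 10)$records)
})

test_that("a degenerate tree yields identical records for every patient", {
  m <- cea_model(decision_node(list(only = terminal_node("10", "1",
                                                         label = "TN"))),
                 parameters = list(cea_parameter("dummy", 1,
                                                 role = "other")))
  ms <- microsimulate(m, n = 50, seed = 1)
  expect_equal(unique(ms$records$cost), 10)
  expect_equal(unique(ms$records$qaly), 1)
  expect_true(all(ms$records$true_fracture == FALSE))
})

test_that("microsimulation agrees with rollback on random trees", {
  set.seed(404)
  for (i in 1:3) {
    rm <- random_model(max_depth = 2L)
    base <- rollback(rm)
    oracle <- path_enum_outcomes(rm)
    expect_equal(base$qaly, oracle$qaly, tolerance = 1e-12)
    ms <- microsimulate(rm, n = 20000, seed = 1000 + i)
    for (s in rm$strategies) {
      qs <- ms$records$qaly[ms$records$strategy == s]
      se <- sd(qs) / sqrt(length(qs))
      expect_lt(abs(mean(qs) - base$qaly[base$strategy == s]),
                3 * se + 1e-9)
    }
  }
})
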