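make_manual_trials <- function() {
  rec <- forest_record(fig_forest())
  data.frame(participant = "a", session = 1, forest = 1,
             day = c(1, 2, 1, 2), weather = c(2, 1, 2, 2),
             energy = c(2, 3, 2, 1), choice = c(1, 0, 0, 1),
             outcome = c(1, -1, -1, 1), energy_after = c(3, 2, 1, 2),
             valid = TRUE, rec[rep(1, 4), ], row.names = NULL)
}

test_that("heuristic variables match their worked definitions", {
  h <- compute_heuristics(make_manual_trials())
  # p = 0.6, g = 1 gives EV -0.2 (good weather of the example forest)
  expect_equal(h$p_success, c(0.6, 0.1, 0.6, 0.6))
  expect_equal(h$ev[1], -0.2)
  expect_equal(h$ev, h$p_success * h$gain - (1 - h$p_success) * 2)
  # binary energy state flags only sure-death-by-waiting states
  expect_equal(h$energy_bin, c(0, 0, 0, 1))
  expect_equal(h$energy_bin, as.integer(h$energy_cont == 1))
  expect_equal(h$days_past, h$day)
  # previous energy 2 -> 3 means delta +1 and WSLS 1; first trial missing
  expect_equal(h$delta_energy, c(NA, 1, -1, -1))
  expect_equal(h$wsls, c(NA, 1, 0, 0))
  expect_equal(h$wsls[-1], as.integer(h$delta_energy[-1] > 0))
})

test_that("the expected value of waiting is -1 in every grid cell", {
  for (p in seq(0.1, 0.9, 0.1)) for (g in 0:4)
    expect_identical(expected_values(weather(p, g))$wait, -1)
})

test_that("dq columns agree with the value-difference series", {
  h <- compute_heuristics(make_manual_trials())
  tab <- optimal_values(fig_forest(), 5)
  expect_equal(h$dq_h5, value_difference_series(tab, 5, h))
  expect_equal(h$dq_h1, value_difference_series(tab, 1, h))
})

test_that("energy-0 rows and missing columns are rejected", {
  tr <- make_manual_trials()
  tr$energy[2] <- 0
  expect_error(compute_heuristics(tr), "energy-0")
  expect_error(compute_heuristics(tr[, -4]), "missing columns")
})

test_that("shared variance behaves as a squared correlation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(shared_variance(x, x), 1)
  expect_equal(shared_variance(x, 2 - 3 * x), 1)
  y <- c(1, -1, 0, -1, 1) # orthogonal to x by construction
  expect_equal(shared_variance(x, y), 0, tolerance = 1e-12)
  expect_error(shared_variance(x, rep(2, 5)), "constant")
})

test_that("momentary option variables share the most variance with the optimal policy", {
  tr <- study_ds()$trials
  tr <- tr[tr$valid, ]
  m <- shared_variance_matrix(tr)
  expect_equal(dim(m), c(11, 11))
  # the momentary foraging-option variables overlap substantially with
  # the optimal policy, while the history heuristics carry little of it
  expect_gt(m["dq_h5", "p_success"], 0.15)
  expect_gt(m["dq_h5", "ev"], 0.15)
  expect_gt(m["dq_h5", "weather"], 0.15)
  for (v in c("wsls", "delta_energy", "days_past"))
    expect_lt(m["dq_h5", v], 0.1)
})
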