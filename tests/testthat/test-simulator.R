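test_that("forest sets are deterministic under a seed and span the grid", {
  fs1 <- generate_forest_set(30, seed = 5)
  fs2 <- generate_forest_set(30, seed = 5)
  expect_identical(lapply(fs1, forest_record), lapply(fs2, forest_record))
  fs3 <- generate_forest_set(30, seed = 6)
  expect_false(identical(lapply(fs1, forest_record),
                         lapply(fs3, forest_record)))
  # 9 x 5 grid: 45 weather cells, 990 pairs, 3 start energies
  expect_error(generate_forest_set(2971), "at most 2970")
  recs <- do.call(rbind, lapply(generate_forest_set(240, seed = 1),
                                forest_record))
  expect_equal(nrow(unique(recs)), 240)
  expect_true(all(recs$start_energy %in% 2:4))
})

test_that("episode lengths honor the binding session totals", {
  for (s in 1:5) {
    lens <- sample_episode_lengths(24, 40, seed = s)
    expect_length(lens, 24)
    expect_equal(sum(lens), 40)
    expect_true(all(lens %in% 1:5))
  }
  expect_identical(sample_episode_lengths(seed = 3),
                   sample_episode_lengths(seed = 3))
  # single-day forests dominate once the totals bind (mean 40/24 < 2)
  many <- unlist(lapply(1:40, function(s)
    sample_episode_lengths(seed = 100 + s)))
  expect_equal(which.max(tabulate(many, 5)), 1)
})

test_that("an always-waiting agent starves on schedule", {
  f <- fig_forest() # start energy 2
  ep <- simulate_episode(f, function(ctx) 0, n_days = 5,
                         start_energy = 3, seed = 1)
  expect_equal(ep$energy[1:3], c(3, 2, 1))
  expect_equal(ep$energy_after[3], 0)
  # post-starvation days are marker rows without choices
  expect_false(any(ep$valid[4:5]))
  expect_true(all(is.na(ep$choice[4:5])))
})

test_that("foraging with near-certain success never starves", {
  f <- forest(weather(1 - 1e-9, 2), weather(1 - 1e-9, 1))
  for (s in 1:20) {
    ep <- simulate_episode(f, function(ctx) 1, n_days = 5, seed = s)
    expect_true(all(ep$energy_after >= 1))
  }
})

test_that("energy bookkeeping matches the transition rules", {
  tr <- small_ds()$trials
  ok <- !is.na(tr$outcome)
  expect_equal(tr$energy_after[ok], tr$energy[ok] + tr$outcome[ok])
  expect_true(all(tr$energy >= 1)) # markers were filtered upstream
  expect_true(all(tr$energy_after >= 0 & tr$energy_after <= 5))
  forage <- ok & tr$choice %in% 1
  expect_true(all(tr$outcome[forage] %in% c(-2, -1, 0, 1, 2, 3, 4)))
  wait <- ok & tr$choice %in% 0
  expect_true(all(tr$outcome[wait] == -1))
})

test_that("invalid agents are rejected", {
  expect_error(simulate_episode(fig_forest(), function(ctx) 2, seed = 1),
               "invalid forage probability")
  expect_error(simulate_episode(fig_forest(), function(ctx) NA, seed = 1),
               "invalid forage probability")
})

test_that("payoff pays CHF 1.50 per surviving selected forest", {
  expect_equal(payoff(rep(TRUE, 10)), 15)
  expect_equal(payoff(rep(FALSE, 10)), 0)
  expect_equal(payoff(c(TRUE, FALSE, TRUE)), 3)
})
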