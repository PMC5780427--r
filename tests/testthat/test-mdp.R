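test_that("transition matrices implement the clip rules and absorb starvation", {
  tm <- transition_model(fig_forest())
  for (w in tm) for (M in w) {
    expect_equal(unname(rowSums(M)), rep(1, 6), tolerance = 1e-12)
    expect_equal(unname(M[1, ]), c(1, 0, 0, 0, 0, 0)) # state 0 absorbing
  }
  # good weather p = 0.6, g = 1: forage from 3 goes to 4 or 1
  expect_equal(unname(tm$good$forage["3", c("4", "1")]), c(0.6, 0.4))
  # waiting from state 1 starves with certainty
  expect_equal(unname(tm$bad$wait["1", "0"]), 1)
  expect_equal(unname(tm$good$wait["1", "0"]), 1)
  # energy cap: forage at the ceiling with a big gain stays at 5
  tm2 <- transition_model(forest(weather(0.3, 4), weather(0.7, 4)))
  expect_equal(unname(tm2$good$forage["5", c("5", "3")]), c(0.7, 0.3))
})

test_that("good/bad weather ordering follows implied starvation probability", {
  f <- forest(weather(0.1, 1), weather(0.6, 1))
  expect_equal(f$weather_good$p, 0.6)
  # tie in starvation risk resolved by higher p, then higher g
  f2 <- forest(weather(0.5, 3), weather(0.5, 2))
  expect_equal(f2$weather_good$g, 3)
})

test_that("backward induction matches the worked indifference and sure-death cases", {
  for (f in list(fig_forest(), forest(weather(0.2, 3), weather(0.8, 0)))) {
    tab <- optimal_values(f, 5)
    # energy 4, one day left: starvation unreachable, indifferent
    expect_identical(unname(tab$dq[4, , 1]), c(0, 0))
    expect_identical(unname(tab$dq[5, , 1]), c(0, 0))
    # energy 1: waiting is sure death, so forage whenever p > 0
    expect_true(all(tab$dq[1, , ] > 0))
    expect_true(all(tab$q_forage >= 0 & tab$q_forage <= 1))
    expect_true(all(tab$q_wait >= 0 & tab$q_wait <= 1))
  }
})

test_that("dq is exactly zero wherever starvation is unreachable", {
  set.seed(1)
  for (rep in 1:10) {
    f <- forest(weather(sample(1:9, 1) / 10, sample(0:4, 1)),
                weather(sample(1:9, 1) / 10, sample(0:4, 1)))
    tab <- optimal_values(f, 5)
    for (t in 1:5) for (s in 1:5)
      if (s > 2 * t) # max loss is 2 per day
        expect_identical(unname(tab$dq[s, , t]), c(0, 0))
  }
})

test_that("p_starve is non-increasing in the energy state", {
  set.seed(2)
  for (rep in 1:10) {
    f <- forest(weather(sample(1:9, 1) / 10, sample(0:4, 1)),
                weather(sample(1:9, 1) / 10, sample(0:4, 1)))
    tab <- optimal_values(f, 5)
    for (w in 1:2) for (t in 1:5)
      expect_true(all(diff(tab$p_starve[, w, t]) <= 1e-12))
  }
})

test_that("backward-induction values equal brute-force enumeration (spot check)", {
  f <- forest(weather(0.4, 2), weather(0.7, 1))
  tab <- optimal_values(f, 5)
  pol <- optimal_policy(tab)
  for (s in 1:5) for (w in 1:2) for (h in c(1, 3, 5)) {
    bf <- brute_force_survival(f, h, pol, start_energy = s,
                               first_weather = w)
    expect_equal(bf, tab$v[s, w, h], tolerance = 1e-12)
  }
})

test_that("brute-force enumeration handles deterministic policies exactly", {
  f <- fig_forest()
  wait <- function(s, w, t) 0
  expect_identical(brute_force_survival(f, 5, wait, start_energy = 3), 0)
  expect_identical(brute_force_survival(f, 3, wait, start_energy = 4), 1)
  expect_error(brute_force_survival(f, 6, wait), "enumeration")
})

test_that("no deterministic policy beats the backward-induction policy", {
  for (f in list(forest(weather(0.5, 1), weather(0.8, 2), 2),
                 forest(weather(0.2, 2), weather(0.6, 0), 2))) {
    tab <- optimal_values(f, 2)
    v_opt <- 0.5 * (tab$v[2, 1, 2] + tab$v[2, 2, 2])
    expect_lte(best_exhaustive_survival(f, 2, 2), v_opt + 1e-12)
    expect_equal(best_exhaustive_survival(f, 2, 2), v_opt,
                 tolerance = 1e-12)
  }
  f <- forest(weather(0.5, 1), weather(0.8, 1), 2)
  tab <- optimal_values(f, 3)
  v_opt <- 0.5 * (tab$v[2, 1, 3] + tab$v[2, 2, 3])
  expect_equal(best_exhaustive_survival(f, 3, 2), v_opt,
               tolerance = 1e-12)
})

test_that("the horizon-decrement rule governs the value-difference series", {
  f <- fig_forest()
  tab <- optimal_values(f, 5)
  trials <- data.frame(energy = c(3, 3, 2), weather = c(1, 2, 2),
                       day = c(1, 5, 3))
  dq5 <- value_difference_series(tab, 5, trials)
  # day 5 of a horizon-5 forest uses the one-step table
  expect_identical(dq5[2], tab$dq[3, 2, 1])
  # horizon floors at 1: horizon-1 on day 1 equals the final step
  dq1 <- value_difference_series(tab, 1, trials)
  expect_identical(dq1[1], tab$dq[3, 1, 1])
  expect_error(value_difference_series(
    tab, 5, data.frame(energy = 0, weather = 1, day = 1)), "energy")
})

test_that("horizon-5 and horizon-1 policies disagree somewhere on the grid", {
  found <- FALSE
  for (p in seq(0.1, 0.9, 0.2)) for (g in 0:4) {
    f <- forest(weather(p, g), weather(0.5, 2))
    tab <- optimal_values(f, 5)
    if (any(sign(tab$dq[, , 5]) * sign(tab$dq[, , 1]) < 0)) {
      found <- TRUE
      break
    }
    if (found) break
  }
  expect_true(found)
})

test_that("value tables export to a tidy long format", {
  tab <- optimal_values(fig_forest(), 3)
  df <- as.data.frame(tab)
  expect_equal(nrow(df), 5 * 2 * 3)
  expect_true(all(c("horizon", "state", "weather", "day", "q_forage",
                    "q_wait", "dq") %in% names(df)))
  expect_equal(df$dq, df$q_forage - df$q_wait)
})
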