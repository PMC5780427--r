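test_that("choice uncertainty is the normalized logistic derivative", {
  r <- unit_ref(0, 1)
  expect_equal(choice_uncertainty(0, r), 1) # DV = 0: maximal
  expect_lt(choice_uncertainty(20, r), 1e-6) # certain regimes vanish
  expect_lt(choice_uncertainty(-20, r), 1e-6)
  x <- seq(-3, 3, 0.5)
  expect_equal(choice_uncertainty(x, r), choice_uncertainty(-x, r))
  expect_true(all(choice_uncertainty(x, r) <= 1))
})

test_that("discrepancy is the absolute gap in predicted choice probabilities", {
  rp <- unit_ref(0, 1)
  expect_equal(policy_discrepancy(0.3, 0.3, rp, rp), 0)
  expect_gt(policy_discrepancy(20, -20, rp, rp), 1 - 1e-6)
  # invariant to which policy is considered first
  d1 <- policy_discrepancy(1.2, -0.4, rp, unit_ref(0.5, 2))
  d2 <- abs(plogis(0.5 + 2 * -0.4) - plogis(1.2))
  expect_equal(d1, d2)
})

test_that("opposing-trial selection is symmetric and midpoint-exclusive", {
  tr <- data.frame(participant = rep("a", 4), valid = TRUE,
                   pred_p = c(0.8, 0.3, 0.5, 0.6),
                   pred_dq = c(0.2, 0.7, 0.9, 0.9))
  sel <- opposing_trials(tr)
  expect_equal(sel$index, c(TRUE, TRUE, FALSE, FALSE)) # 0.5 excluded
  swapped <- tr
  names(swapped)[3:4] <- c("pred_dq", "pred_p")
  expect_equal(opposing_trials(swapped)$index, sel$index)
  same <- tr
  same$pred_dq <- same$pred_p
  expect_false(any(opposing_trials(same)$index))
})

test_that("study-scale data yield tens of opposing trials per participant", {
  tr <- study_ds()$trials
  sel <- opposing_trials(tr)
  counts <- tapply(sel$index[tr$valid], tr$participant[tr$valid], sum)
  expect_true(all(counts > 5))
  expect_true(mean(counts) > 20 && mean(counts) < 250)
})

test_that("always waiting starves in every episode", {
  fs <- generate_forest_set(10, seed = 2)
  res <- policy_starvation(function(ctx) 0, fs,
                           episodes_per_forest = 20, seed = 3)
  expect_equal(res$rate, 1) # five waits from start energy <= 4
})

test_that("the optimal policy starves less than heuristic policies", {
  fs <- generate_forest_set(20, seed = 4)
  refs <- behavioral_refs()
  r_opt <- policy_starvation(optimal_agent(), fs, 150, seed = 5)
  r_p <- policy_starvation(heuristic_agent("p_success", refs$p, 1),
                           fs, 150, seed = 5)
  r_forage <- policy_starvation(function(ctx) 1, fs, 150, seed = 5)
  margin <- 3 * sqrt(r_opt$se^2 + r_p$se^2)
  expect_lt(r_opt$rate + margin, r_p$rate)
  expect_lt(r_opt$rate + margin, r_forage$rate)
  # reproducible under the seed
  expect_equal(policy_starvation(optimal_agent(), fs, 150, seed = 5)$rate,
               r_opt$rate)
})

test_that("horizon contrasts separate deep and myopic agents", {
  refs <- behavioral_refs()
  base <- generative_params(n_participants = 8, n_sessions = 4)
  # agents driven by the h-5 value difference
  p5 <- base; p5$choice_beta <- c(0, 0, 5); p5$choice_sd <- c(0.2, 0, 1)
  d5 <- generate_dataset(p5, seed = 61, refs = refs)
  h5 <- horizon_contrast(d5$trials, 1)
  expect_gt(mean(h5$proportion), 0.5)
  # myopic agents driven by the one-step value difference
  agent_pool <- generate_forest_set(60, seed = 62)
  tr1 <- do.call(rbind, lapply(1:8, function(i) {
    cbind(participant = paste0("m", i),
          simulate_participant(agent_pool,
            function(ctx) plogis(5 * ctx$dq_h1),
            n_sessions = 4, seed = 70 + i))
  }))
  tr1 <- compute_heuristics(tr1[tr1$energy > 0, ])
  h1 <- horizon_contrast(tr1, 1)
  expect_lt(mean(h1$proportion), 0.5)
  # random agents sit at the midpoint
  tr0 <- do.call(rbind, lapply(1:8, function(i) {
    cbind(participant = paste0("r", i),
          simulate_participant(agent_pool, function(ctx) 0.5,
                               n_sessions = 4, seed = 80 + i))
  }))
  tr0 <- compute_heuristics(tr0[tr0$energy > 0, ])
  h0 <- horizon_contrast(tr0, 1)
  expect_lt(abs(mean(h0$proportion) - 0.5), 0.1)
})
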