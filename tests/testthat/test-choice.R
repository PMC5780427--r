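test_that("the intercept-only fit on balanced choices has its closed form", {
  d <- data.frame(choice = rep(0:1, 50))
  f <- fit_choice(d, character(0))
  expect_equal(unname(coef(f)), 0, tolerance = 1e-8)
  expect_equal(f$logLik, 100 * log(0.5), tolerance = 1e-10)
  expect_equal(f$bic, 1 * log(100) - 2 * f$logLik)
})

test_that("the BIC identity holds for every fit", {
  tr <- small_ds()$trials
  ev <- fit_choice_models(tr, choice_model_space("single"),
                          keep_fits = TRUE)
  for (pf in ev$fits) for (f in pf) {
    expect_equal(f$bic, f$k * log(f$n) - 2 * f$logLik)
    expect_true(all(is.finite(coef(f))))
  }
  expect_equal(ev$log_evidence, -ev$bic / 2)
})

test_that("coefficients are recovered from model-generated data", {
  set.seed(42)
  n <- 1000
  x <- rnorm(n)
  z <- rnorm(n)
  d <- data.frame(x = x, z = z,
                  choice = rbinom(n, 1, plogis(0.5 + 2 * x - z)))
  f <- fit_choice(d, c("x", "z"), standardize = FALSE)
  expect_equal(unname(coef(f)), c(0.5, 2, -1), tolerance = 0.2)
  expect_false(f$separation)
})

test_that("adding a predictor never decreases the likelihood", {
  tr <- small_ds()$trials
  d <- tr[tr$participant == tr$participant[1] & tr$valid, ]
  f1 <- fit_choice(d, "p_success")
  f2 <- fit_choice(d, c("p_success", "energy_cont"))
  expect_gte(f2$logLik, f1$logLik - 1e-8)
})

test_that("complete separation is flagged and still yields finite evidence", {
  set.seed(1)
  x <- c(rnorm(30, -2), rnorm(30, 2))
  d <- data.frame(x = x, choice = as.integer(x > 0))
  f <- fit_choice(d, "x", standardize = FALSE)
  expect_true(f$separation)
  expect_true(is.finite(f$bic))
})

test_that("the model space has the documented sizes", {
  expect_length(choice_model_space("single"), 11)
  expect_length(choice_model_space("second_given_p"), 10)
  expect_length(choice_model_space("all_pairs"), 55)
  expect_length(choice_model_space("triples"), 9)
  expect_length(choice_model_space("interactions"), 5)
  # every pair is distinct and references candidate variables
  prs <- choice_model_space("all_pairs")
  expect_equal(anyDuplicated(sapply(prs, paste, collapse = "+")), 0)
  expect_true(all(unlist(prs) %in% candidate_variables()))
})

test_that("interaction predictors derive from uncertainties and discrepancy", {
  tr <- small_ds()$trials
  tr <- add_policy_interactions(tr)
  expect_equal(tr$p_x_cert, tr$p_success * (1 - tr$unc_p))
  expect_equal(tr$dq_x_disc, tr$dq_h5 * tr$discrepancy)
  ev <- fit_choice_models(tr, choice_model_space("interactions"))
  expect_equal(dim(ev$bic), c(6, 5))
  expect_true(all(is.finite(ev$bic)))
})

test_that("posterior predictive checks are self-consistent", {
  tr <- small_ds()$trials
  ev <- fit_choice_models(tr, list(pdq = c("p_success", "dq_h5"),
                                   null = character(0)),
                          keep_fits = TRUE)
  ppc <- posterior_predictive(ev, tr, "p_success", model = "pdq")
  # a well-specified fitted model tracks its own data across bins
  expect_true(all(abs(ppc$observed - ppc$predicted) <
                    pmax(4 * ppc$obs_sem, 0.1)))
  expect_gt(cor(ppc$bin, ppc$predicted), 0) # forage rises with p
  flat <- posterior_predictive(ev, tr, "p_success", model = "null")
  expect_lt(diff(range(flat$predicted)), 0.02) # intercept-only is flat
})
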