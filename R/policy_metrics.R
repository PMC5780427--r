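# Choice uncertainty, policy discrepancy, opposing-prescription trial
# selection, horizon contrasts, and Monte-Carlo starvation-rate
# benchmarks of candidate policies.

#' Reference logistic policy from an independent sample
#'
#' Fits a single-variable logistic choice model per participant and
#' averages the coefficients — the reference logistic function through
#' which uncertainties, discrepancies and prescriptions are computed on
#' a second, independent sample.
#'
#' @param trials trial table of the reference sample (valid trials,
#'   with \code{participant}, \code{choice} and the variable column).
#' @param variable predictor column name (e.g. \code{"p_success"} or
#'   \code{"dq_h5"}).
#' @return object of class \code{"ref_policy"}: list with \code{beta0},
#'   \code{beta1}, the variable name and provenance info.
#' @export
fit_reference_policy <- function(trials, variable) {
  trials <- trials[trials$valid %in% TRUE, ]
  ids <- unique(trials$participant)
  cf <- t(vapply(ids, function(id) {
    f <- fit_choice(trials[trials$participant == id, ], variable,
                    standardize = FALSE)
    f$coefficients
  }, numeric(2)))
  structure(list(beta0 = mean(cf[, 1]), beta1 = mean(cf[, 2]),
                 variable = variable, n_participants = length(ids),
                 provenance = "mean per-participant ML estimates"),
            class = "ref_policy")
}

#' @export
print.ref_policy <- function(x, ...) {
  cat(sprintf("reference policy on %s: DV = %.3f + %.3f x (n = %d)\n",
              x$variable, x$beta0, x$beta1, x$n_participants))
  invisible(x)
}

ref_dv <- function(x, ref) ref$beta0 + ref$beta1 * x

#' Choice uncertainty of a logistic policy
#'
#' The derivative-based indecision index of a logistic policy:
#' \code{sigma(DV) (1 - sigma(DV))} with \code{DV = beta0 + beta1 x},
#' normalized to a maximum of 1 (division by 0.25). Maximal where the
#' predicted choice probability is 0.5, vanishing where the policy is
#' certain.
#'
#' @param x variable values.
#' @param ref a \code{\link{fit_reference_policy}} object (or any list
#'   with \code{beta0}, \code{beta1}).
#' @return uncertainties in (0, 1].
#' @export
choice_uncertainty <- function(x, ref) {
  s <- stats::plogis(ref_dv(x, ref))
  4 * s * (1 - s)
}

#' Discrepancy between heuristic and optimal policy prescriptions
#'
#' Absolute difference between the choice probabilities predicted by the
#' heuristic reference policy (on the probability of foraging success)
#' and the optimal-policy reference (on the h-5 value difference).
#'
#' @param p_trial probability of foraging success per trial.
#' @param dq_trial h-5 value difference per trial.
#' @param ref_p,ref_dq reference policies for the two variables.
#' @return discrepancies in [0, 1].
#' @export
policy_discrepancy <- function(p_trial, dq_trial, ref_p, ref_dq) {
  abs(stats::plogis(ref_dv(p_trial, ref_p)) -
        stats::plogis(ref_dv(dq_trial, ref_dq)))
}

#' Append uncertainty/discrepancy columns to a trial table
#'
#' @param trials trial table with \code{p_success} and \code{dq_h5}.
#' @param ref_p,ref_dq reference policies.
#' @return the table with columns \code{pred_p, pred_dq} (predicted
#'   forage probabilities under the two reference policies),
#'   \code{unc_p, unc_dq} (normalized choice uncertainties) and
#'   \code{discrepancy}.
#' @export
add_policy_metrics <- function(trials, ref_p, ref_dq) {
  trials$pred_p <- stats::plogis(ref_dv(trials$p_success, ref_p))
  trials$pred_dq <- stats::plogis(ref_dv(trials$dq_h5, ref_dq))
  trials$unc_p <- choice_uncertainty(trials$p_success, ref_p)
  trials$unc_dq <- choice_uncertainty(trials$dq_h5, ref_dq)
  trials$discrepancy <- abs(trials$pred_p - trials$pred_dq)
  trials
}

#' Trials on which the two policies make opposing prescriptions
#'
#' Binarizes the predicted choice probabilities of the heuristic and the
#' optimal reference policies at the midpoint 0.5 and selects the trials
#' on which exactly one exceeds it (exact 0.5 is excluded).
#'
#' @param trials trial table carrying \code{pred_p} and \code{pred_dq}
#'   (see \code{\link{add_policy_metrics}}).
#' @return list with \code{index} (logical row selector) and
#'   \code{proportion} (per-participant proportion of opposing trials).
#' @export
opposing_trials <- function(trials) {
  stopifnot(all(c("pred_p", "pred_dq") %in% names(trials)))
  opp <- (trials$pred_p - 0.5) * (trials$pred_dq - 0.5) < 0 &
    trials$valid %in% TRUE
  prop <- tapply(opp[trials$valid %in% TRUE],
                 trials$participant[trials$valid %in% TRUE], mean)
  list(index = opp, proportion = prop)
}

#' Horizon contrast on opposing-prescription trials
#'
#' For a horizon k != 5, selects the trials on which the h-5 and h-k
#' optimal policies prescribe opposite actions (opposite dq signs; ties
#' excluded), computes each participant's proportion of h-5-consistent
#' choices, and tests the proportions against the 0.5 midpoint.
#'
#' @param trials trial table with \code{dq_h5}, \code{dq_h<k>},
#'   \code{choice}, \code{participant}, \code{valid}.
#' @param horizon the competing horizon k.
#' @return list with the per-participant proportions, trial counts, and
#'   the one-sample t-test versus 0.5 (\code{NULL} with a message
#'   element when the contrast set is empty).
#' @export
horizon_contrast <- function(trials, horizon = 1) {
  col <- paste0("dq_h", horizon)
  stopifnot(col %in% names(trials), "dq_h5" %in% names(trials))
  ok <- trials$valid %in% TRUE & !is.na(trials$choice)
  opp <- ok & trials$dq_h5 * trials[[col]] < 0
  if (!any(opp))
    return(list(proportion = numeric(0), n = integer(0), test = NULL,
                message = "no opposing trials for this contrast"))
  consistent <- (trials$choice == 1) == (trials$dq_h5 > 0)
  prop <- tapply(consistent[opp], trials$participant[opp], mean)
  n <- tapply(opp, trials$participant, sum)
  test <- if (length(prop) >= 2 && stats::sd(prop) > 0)
    stats::t.test(prop, mu = 0.5) else NULL
  list(proportion = prop, n = n, test = test, horizon = horizon)
}

#' Monte-Carlo starvation rate of a policy
#'
#' Simulates full five-day episodes across a forest set, with starting
#' energies drawn uniformly from {2, 3, 4}, and reports the frequency of
#' starvation (energy 0 on or before day five) with its Monte-Carlo
#' standard error.
#'
#' @param agent agent function (see \code{\link{simulate_episode}}).
#' @param forest_set list of forests.
#' @param episodes_per_forest episodes simulated per forest.
#' @param seed RNG seed.
#' @return list with \code{rate}, \code{se} and \code{n_episodes}.
#' @export
policy_starvation <- function(agent, forest_set,
                              episodes_per_forest = 100, seed = NULL) {
  tabs <- attr(forest_set, "tabs")
  if (is.null(tabs)) tabs <- lapply(forest_set, optimal_values, horizon = 5)
  with_seed(seed, {
    starved <- 0L
    total <- 0L
    for (i in seq_along(forest_set)) {
      s0s <- sample(2:4, episodes_per_forest, replace = TRUE)
      for (e in seq_len(episodes_per_forest)) {
        ep <- episode_core(forest_set[[i]], tabs[[i]], agent, n_days = 5,
                           start_energy = s0s[e], prev_delta = 0)
        starved <- starved + as.integer(ep$energy_after[5] == 0)
        total <- total + 1L
      }
    }
    rate <- starved / total
    list(rate = rate, se = sqrt(rate * (1 - rate) / total),
         n_episodes = total)
  })
}

#' Agent following a single-variable logistic policy
#'
#' Builds an agent that forages with probability \code{sigma((beta0 +
#' beta1 x) / temperature)}, where x is one of the candidate decision
#' variables evaluated from the trial context. At \code{temperature = 0}
#' the policy is thresholded (deterministic).
#'
#' @param variable candidate variable name (see
#'   \code{\link{candidate_variables}}).
#' @param ref reference policy providing \code{beta0}, \code{beta1}.
#' @param temperature softmax temperature (> 0, or 0 for thresholding).
#' @return an agent function.
#' @export
heuristic_agent <- function(variable, ref, temperature = 1) {
  getter <- switch(variable,
    p_success = function(ctx) ctx$p,
    gain = function(ctx) ctx$g,
    ev = function(ctx) ctx$p * ctx$g - (1 - ctx$p) * 2,
    energy_cont = function(ctx) ctx$energy,
    energy_bin = function(ctx) as.numeric(ctx$energy == 1),
    weather = function(ctx) ctx$weather,
    days_past = function(ctx) ctx$day,
    delta_energy = function(ctx) ctx$delta_energy,
    wsls = function(ctx) as.numeric(ctx$delta_energy > 0),
    dq_h1 = function(ctx) ctx$dq_h1,
    dq_h5 = function(ctx) ctx$dq_h5,
    stop("unknown variable: ", variable))
  function(ctx) {
    dv <- ref$beta0 + ref$beta1 * getter(ctx)
    if (temperature == 0) {
      if (dv > 0) 1 else if (dv < 0) 0 else 0.5
    } else stats::plogis(dv / temperature)
  }
}

#' Agent playing the exact optimal policy
#'
#' Forages where the h-5 backward-induction value difference is
#' positive, waits where it is negative, and chooses each option with
#' probability 0.5 at exact indifference.
#'
#' @return an agent function.
#' @export
optimal_agent <- function() {
  function(ctx) {
    if (ctx$dq_h5 > 0) 1 else if (ctx$dq_h5 < 0) 0 else 0.5
  }
}

#' Starvation-rate benchmark of candidate policies
#'
#' Evaluates the Monte-Carlo starvation rate of single-variable logistic
#' policies (one per heuristic variable, under a common temperature
#' sweep) and of the exact h-5 optimal policy, on a common forest set
#' with shared seeds.
#'
#' @param forest_set list of forests.
#' @param refs named list of reference policies, one per variable (see
#'   \code{\link{fit_reference_policy}}).
#' @param temperatures temperature sweep.
#' @param episodes_per_forest episodes per forest and policy.
#' @param seed RNG seed (one stream per policy x temperature, derived).
#' @return data frame with columns \code{policy, temperature, rate, se}.
#' @export
starvation_benchmark <- function(forest_set, refs,
                                 temperatures = c(0.5, 1, 2),
                                 episodes_per_forest = 100,
                                 seed = NULL) {
  if (is.null(attr(forest_set, "tabs")))
    attr(forest_set, "tabs") <- lapply(forest_set, optimal_values,
                                       horizon = 5)
  rows <- list()
  k <- 0L
  for (v in names(refs)) {
    for (tau in temperatures) {
      k <- k + 1L
      res <- policy_starvation(
        heuristic_agent(v, refs[[v]], tau), forest_set,
        episodes_per_forest,
        seed = if (is.null(seed)) NULL else seed + k)
      rows[[k]] <- data.frame(policy = v, temperature = tau,
                              rate = res$rate, se = res$se)
    }
  }
  k <- k + 1L
  res <- policy_starvation(optimal_agent(), forest_set,
                           episodes_per_forest,
                           seed = if (is.null(seed)) NULL else seed + k)
  rows[[k]] <- data.frame(policy = "optimal_h5", temperature = NA,
                          rate = res$rate, se = res$se)
  do.call(rbind, rows)
}
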