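# Synthetic-participant generator: closed-loop simulation of choices
# from a logistic policy on (p_success, h-5 dq) and of log reaction
# times from the five-predictor linear model, with participant-level
# random effects and known ground truth.

#' Generative parameters for synthetic datasets
#'
#' Defaults reproduce the study's structure: 28 participants, 10
#' sessions of 24 forests / 40 days drawn from 240 forest types, a
#' ~1.6% non-response rate (which together with starvation leaves ~370
#' valid trials of 400), choices from \code{DV = b0 + b1 (p - 0.5) + b2
#' dq}, and log RTs (seconds) linear in the five RT predictors with
#' independent normal participant-level random effects.
#'
#' @param n_participants number of synthetic participants.
#' @param n_sessions,forests_per_session,days_per_session session
#'   structure.
#' @param n_forest_types size of the forest-type pool.
#' @param choice_beta group-mean choice coefficients (intercept, p
#'   centered at 0.5, h-5 dq).
#' @param choice_sd between-participant SDs of the choice coefficients.
#' @param rt_beta group-mean log-RT coefficients (intercept, p - 0.5,
#'   dq, uncertainty of p, uncertainty of dq, discrepancy).
#' @param rt_sd between-participant SDs of the RT coefficients.
#' @param rt_sigma residual SD of log RT.
#' @param nonresponse_rate probability a trial is marked invalid
#'   (no response).
#' @param optimal_latency_penalty_ms extra latency (ms) added on
#'   opposing-prescription trials whose choice follows the optimal
#'   policy (0 = off; used for injection/recovery studies).
#' @return a list of class \code{"generative_params"}.
#' @export
generative_params <- function(n_participants = 28,
                              n_sessions = 10,
                              forests_per_session = 24,
                              days_per_session = 40,
                              n_forest_types = 240,
                              choice_beta = c(0.3, 6, 2.5),
                              choice_sd = c(0.3, 1.5, 0.8),
                              rt_beta = c(-0.29, -0.08, -0.03,
                                          0.12, 0.04, 0.10),
                              rt_sd = c(0.15, 0.04, 0.02,
                                        0.05, 0.02, 0.04),
                              rt_sigma = 0.25,
                              nonresponse_rate = 0.016,
                              optimal_latency_penalty_ms = 0) {
  stopifnot(n_participants >= 1, all(choice_sd >= 0), all(rt_sd >= 0),
            rt_sigma >= 0, nonresponse_rate >= 0, nonresponse_rate < 1)
  structure(list(n_participants = n_participants,
                 n_sessions = n_sessions,
                 forests_per_session = forests_per_session,
                 days_per_session = days_per_session,
                 n_forest_types = n_forest_types,
                 choice_beta = choice_beta, choice_sd = choice_sd,
                 rt_beta = rt_beta, rt_sd = rt_sd, rt_sigma = rt_sigma,
                 nonresponse_rate = nonresponse_rate,
                 optimal_latency_penalty_ms = optimal_latency_penalty_ms),
            class = "generative_params")
}

# simulate choices for a set of participants; returns trial table with
# per-participant generative coefficients attached as attribute
simulate_choice_sample <- function(params, forest_set, tabs, ids) {
  attr(forest_set, "tabs") <- tabs
  coefs <- matrix(stats::rnorm(length(ids) * 3,
                               mean = rep(params$choice_beta, each = length(ids)),
                               sd = rep(params$choice_sd, each = length(ids))),
                  length(ids), 3)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    b <- coefs[i, ]
    agent <- function(ctx)
      stats::plogis(b[1] + b[2] * (ctx$p - 0.5) + b[3] * ctx$dq_h5)
    tr <- simulate_participant(forest_set, agent,
                               n_sessions = params$n_sessions,
                               forests_per_session = params$forests_per_session,
                               days_per_session = params$days_per_session)
    out[[i]] <- cbind(participant = ids[i], tr)
  }
  trials <- do.call(rbind, out)
  attr(trials, "choice_coefs") <- coefs
  trials
}

#' Generate a synthetic dataset with known ground truth
#'
#' Closed-loop simulation: each synthetic participant's choice on each
#' trial is drawn from their logistic policy given that trial's
#' predictors, and the energy state evolves accordingly; log RTs are
#' drawn from the five-predictor linear model with participant random
#' effects and residual noise; a fraction of trials is marked invalid
#' (non-response) and excluded from analyses, as starvation days already
#' are.
#'
#' If no reference policies are supplied, an independent "behavioral
#' sample" of 21 participants is generated first (with the same
#' generative parameters) and its mean single-variable fits provide the
#' reference logistic functions for the uncertainty and discrepancy
#' predictors — mirroring the independence logic of the study design.
#'
#' @param params a \code{\link{generative_params}} list.
#' @param seed RNG seed for the whole generation.
#' @param refs optional list with elements \code{p} and \code{dq}
#'   (\code{ref_policy} objects).
#' @param n_reference_participants size of the internal reference
#'   sample when \code{refs} is \code{NULL}.
#' @return an object of class \code{"synth_data"}: list with
#'   \code{trials} (full trial table incl. heuristic, uncertainty and
#'   RT columns), \code{truth} (generative parameters and
#'   per-participant coefficients), \code{refs}, and
#'   \code{forest_set}.
#' @export
generate_dataset <- function(params = generative_params(), seed = NULL,
                             refs = NULL,
                             n_reference_participants = 21) {
  with_seed(seed, {
    forest_set <- generate_forest_set(params$n_forest_types)
    tabs <- lapply(forest_set, optimal_values, horizon = 5)
    if (is.null(refs)) {
      rp <- params
      rp$n_participants <- n_reference_participants
      ref_trials <- simulate_choice_sample(rp, forest_set, tabs,
                                           paste0("ref", seq_len(rp$n_participants)))
      ref_trials <- compute_heuristics(ref_trials[ref_trials$valid, ])
      refs <- list(p = fit_reference_policy(ref_trials, "p_success"),
                   dq = fit_reference_policy(ref_trials, "dq_h5"))
    }
    ids <- sprintf("s%02d", seq_len(params$n_participants))
    trials <- simulate_choice_sample(params, forest_set, tabs, ids)
    choice_coefs <- attr(trials, "choice_coefs")
    # non-response exclusions on choice trials
    nr <- stats::runif(nrow(trials)) < params$nonresponse_rate &
      trials$valid
    trials$valid[nr] <- FALSE
    keep <- trials$energy > 0
    full <- trials
    trials <- compute_heuristics(trials[keep, ])
    trials <- add_policy_metrics(trials, refs$p, refs$dq)
    # log RTs from the five-predictor linear model
    nid <- params$n_participants
    rt_coefs <- matrix(stats::rnorm(nid * 6,
                                    mean = rep(params$rt_beta, each = nid),
                                    sd = rep(params$rt_sd, each = nid)),
                       nid, 6, dimnames = list(ids, NULL))
    ri <- match(trials$participant, ids)
    B <- rt_coefs[ri, , drop = FALSE]
    lrt <- B[, 1] + B[, 2] * (trials$p_success - 0.5) +
      B[, 3] * trials$dq_h5 + B[, 4] * trials$unc_p +
      B[, 5] * trials$unc_dq + B[, 6] * trials$discrepancy +
      stats::rnorm(nrow(trials), 0, params$rt_sigma)
    rt <- exp(lrt)
    if (params$optimal_latency_penalty_ms > 0) {
      opp <- (trials$pred_p - 0.5) * (trials$pred_dq - 0.5) < 0
      followed_opt <- opp & !is.na(trials$choice) &
        ((trials$choice == 1) == (trials$pred_dq > 0.5))
      rt[followed_opt] <- rt[followed_opt] +
        params$optimal_latency_penalty_ms / 1000
    }
    trials$rt <- ifelse(trials$valid, rt, NA_real_)
    trials$choice[!trials$valid] <- NA_integer_
    structure(list(trials = trials,
                   truth = list(params = params,
                                choice_coefs = choice_coefs,
                                rt_coefs = rt_coefs,
                                starvation_days = sum(!keep)),
                   refs = refs, forest_set = forest_set),
              class = "synth_data")
  })
}

#' @export
print.synth_data <- function(x, ...) {
  tr <- x$trials
  nv <- tapply(tr$valid, tr$participant, sum)
  cat(sprintf(paste0(
    "synthetic dataset: %d participants, %.1f +/- %.1f valid trials",
    " (of %d days each; %d starvation days overall)\n"),
    length(nv), mean(nv), stats::sd(nv),
    x$truth$params$n_sessions * x$truth$params$days_per_session,
    x$truth$starvation_days))
  invisible(x)
}
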