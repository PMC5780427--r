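# Exact representation of the foraging MDP and backward-induction solver.
#
# Internal convention: energy states are 0..5 (0 absorbing starvation);
# transition matrices are 6x6 with rows = state before, cols = state
# after. Weather index 1 = bad, 2 = good. Backward induction is carried
# out on starvation probabilities so that states from which starvation is
# unreachable have a value of exactly 0 (and hence dq exactly 0) in
# floating point.

#' Per-weather, per-action transition matrices
#'
#' Builds the one-step energy transition matrices of the foraging MDP.
#' Waiting moves energy down by 1 (floored at 0); foraging moves energy
#' to \code{min(s + g, 5)} with probability \code{p} and to
#' \code{max(s - 2, 0)} with probability \code{q = 1 - p}. State 0
#' (starvation) is absorbing.
#'
#' @param f a \code{\link{forest}}.
#' @return a list of class \code{"transition_model"} with elements
#'   \code{bad} and \code{good}, each a list of 6x6 matrices
#'   \code{forage} and \code{wait} (rows/columns are energy states
#'   0--5).
#' @examples
#' tm <- transition_model(forest(weather(0.6, 1), weather(0.1, 1)))
#' tm$good$forage["3", ]  # 0.6 mass on state 4, 0.4 on state 1
#' @export
transition_model <- function(f) {
  stopifnot(is.forest(f))
  one <- function(w) {
    states <- 0:5
    forage <- matrix(0, 6, 6, dimnames = list(states, states))
    wait <- forage
    forage[1, 1] <- 1
    wait[1, 1] <- 1
    for (s in 1:5) {
      up <- min(s + w$g, 5L)
      down <- max(s - w$c_f, 0L)
      forage[s + 1, up + 1] <- forage[s + 1, up + 1] + w$p
      forage[s + 1, down + 1] <- forage[s + 1, down + 1] + w$q
      wait[s + 1, max(s - 1L, 0L) + 1] <- 1
    }
    list(forage = forage, wait = wait)
  }
  structure(list(bad = one(f$weather_bad), good = one(f$weather_good)),
            class = "transition_model")
}

#' Optimal action values by backward induction
#'
#' Solves the finite-horizon foraging MDP exactly. For each energy state
#' \code{s} (1--5), weather type (bad/good) and number of days still to
#' go \code{t} (1..horizon), the table holds the survival probabilities
#' \code{q_forage} and \code{q_wait} of taking that action now and
#' playing optimally afterwards, their difference \code{dq}, the optimal
#' value \code{v = max(q_forage, q_wait)} and the starvation probability
#' \code{p_starve = 1 - v}. On the final day the value of an action is
#' simply the probability of being alive after it; earlier values
#' propagate the max-action continuation value through the transition
#' model and the fair 0.5/0.5 weather draw of the next day.
#'
#' @param f a \code{\link{forest}}.
#' @param horizon integer number of days, 1--7.
#' @return an object of class \code{"value_table"}: a list with arrays
#'   \code{q_forage}, \code{q_wait}, \code{dq}, \code{v},
#'   \code{p_starve}, each of dimension \code{5 x 2 x horizon}
#'   (state 1--5, weather bad/good, days-to-go 1..horizon), plus the
#'   forest and horizon.
#' @examples
#' tab <- optimal_values(forest(weather(0.6, 1), weather(0.1, 1)), 5)
#' tab$dq[4, , 1]  # energy 4, one day left: indifferent (0, 0)
#' @export
optimal_values <- function(f, horizon = 5) {
  stopifnot(is.forest(f))
  if (!(is.numeric(horizon) && length(horizon) == 1L &&
        horizon == round(horizon) && horizon >= 1 && horizon <= 7))
    stop("'horizon' must be an integer between 1 and 7")
  horizon <- as.integer(horizon)
  tm <- transition_model(f)
  dn <- list(state = 1:5, weather = c("bad", "good"), t = seq_len(horizon))
  qf <- array(NA_real_, c(5, 2, horizon), dimnames = dn)
  qw <- qf
  # starve[s'] for s' = 0..5: starvation probability from the start of a
  # day with t - 1 days to go, before the weather draw
  starve_next <- c(1, rep(0, 5))
  for (t in seq_len(horizon)) {
    sf <- matrix(NA_real_, 5, 2) # starvation prob of forage, by s, w
    sw <- sf
    for (w in 1:2) {
      P <- tm[[c("bad", "good")[w]]]
      sf[, w] <- (P$forage %*% starve_next)[2:6]
      sw[, w] <- (P$wait %*% starve_next)[2:6]
    }
    qf[, , t] <- 1 - sf
    qw[, , t] <- 1 - sw
    best <- pmin(sf, sw) # minimal starvation probability per (s, w)
    starve_next <- c(1, 0.5 * (best[, 1] + best[, 2]))
  }
  dq <- qf - qw
  v <- pmax(qf, qw)
  structure(list(q_forage = qf, q_wait = qw, dq = dq, v = v,
                 p_starve = 1 - v, forest = f, horizon = horizon),
            class = "value_table")
}

#' @export
print.value_table <- function(x, ...) {
  cat(sprintf("optimal value table, horizon %d\n", x$horizon))
  print(x$forest)
  cat("dq (forage - wait) at the first day:\n")
  print(round(x$dq[, , x$horizon], 4))
  invisible(x)
}

#' @export
as.data.frame.value_table <- function(x, ...) {
  g <- expand.grid(state = 1:5, weather = c("bad", "good"),
                   t = seq_len(x$horizon), stringsAsFactors = FALSE)
  data.frame(horizon = x$horizon, state = g$state, weather = g$weather,
             day = x$horizon - g$t + 1,
             q_forage = as.vector(x$q_forage),
             q_wait = as.vector(x$q_wait),
             dq = as.vector(x$dq),
             p_starve = as.vector(x$p_starve))
}

#' Optimal policy as a function
#'
#' Extracts the deterministic optimal policy from a value table as a
#' function returning the probability of foraging: 1 where foraging is
#' strictly better, 0 where waiting is strictly better, and 0.5 at exact
#' indifference (dq = 0).
#'
#' @param tab a \code{\link{optimal_values}} table.
#' @return a function \code{(s, w, t)} of energy state 1--5, weather
#'   index (1 bad, 2 good) and days-to-go, returning the forage
#'   probability.
#' @export
optimal_policy <- function(tab) {
  stopifnot(inherits(tab, "value_table"))
  dq <- tab$dq
  function(s, w, t) {
    d <- dq[s, w, t]
    if (d > 0) 1 else if (d < 0) 0 else 0.5
  }
}

#' Exact survival probability of a policy by tree enumeration
#'
#' Independent oracle for the backward-induction solver: enumerates every
#' weather sequence and foraging-outcome branch of an episode explicitly
#' and sums the probabilities of the branches in which the agent is alive
#' after \code{horizon} days.
#'
#' @param f a \code{\link{forest}}.
#' @param horizon number of days; enumeration is exponential, so a
#'   configurable limit applies.
#' @param policy function \code{(s, w, t)} returning the probability of
#'   foraging (0/1 for deterministic policies) given energy state
#'   \code{s}, weather index \code{w} (1 bad, 2 good) and days-to-go
#'   \code{t}.
#' @param start_energy starting energy state (default: the forest's).
#' @param first_weather optional weather index of the first day; if
#'   \code{NULL} the first day's weather is averaged 0.5/0.5 like all
#'   later days.
#' @param max_horizon enumeration guard (default 5).
#' @return survival probability (numeric scalar).
#' @examples
#' f <- forest(weather(0.5, 2), weather(0.8, 1))
#' brute_force_survival(f, 3, function(s, w, t) 0, start_energy = 4) # 1
#' @export
brute_force_survival <- function(f, horizon, policy,
                                 start_energy = f$start_energy,
                                 first_weather = NULL, max_horizon = 5) {
  stopifnot(is.forest(f), start_energy >= 1, start_energy <= 5)
  if (horizon > max_horizon)
    stop("horizon too large for explicit enumeration")
  gs <- c(f$weather_bad$g, f$weather_good$g)
  ps <- c(f$weather_bad$p, f$weather_good$p)
  # survival from state s at the start of a day with weather w and t
  # days (including this one) to go
  surv_day <- function(s, w, t) {
    if (s == 0) return(0)
    fp <- policy(s, w, t)
    stopifnot(fp >= 0, fp <= 1)
    res <- 0
    if (fp > 0) { # forage branch
      up <- min(s + gs[w], 5)
      down <- max(s - 2, 0)
      res <- res + fp * (ps[w] * surv_next(up, t - 1) +
                         (1 - ps[w]) * surv_next(down, t - 1))
    }
    if (fp < 1) # wait branch
      res <- res + (1 - fp) * surv_next(max(s - 1, 0), t - 1)
    res
  }
  # survival from state s with t days to go, before the weather draw
  surv_next <- function(s, t) {
    if (s == 0) return(0)
    if (t == 0) return(1)
    0.5 * surv_day(s, 1, t) + 0.5 * surv_day(s, 2, t)
  }
  if (is.null(first_weather)) surv_next(start_energy, horizon)
  else surv_day(start_energy, first_weather, horizon)
}

#' Value differences for a sequence of trials
#'
#' Looks up the optimal-policy value difference (forage minus wait
#' survival probability) for each trial under the horizon-decrement rule:
#' a forest entered with horizon \code{n} uses \code{n} days-to-go on day
#' 1, \code{n - 1} on day 2, ..., floored at 1.
#'
#' @param f a \code{\link{forest}} or a precomputed
#'   \code{\link{optimal_values}} table of that forest.
#' @param horizon the horizon with which the forest is entered (1--7).
#' @param trials data frame with columns \code{energy} (state 1--5),
#'   \code{weather} (1 bad, 2 good) and \code{day} (1--5).
#' @return numeric vector of dq values, one per trial.
#' @export
value_difference_series <- function(f, horizon, trials) {
  tab <- if (inherits(f, "value_table")) f else optimal_values(f, horizon)
  stopifnot(tab$horizon >= horizon,
            all(c("energy", "weather", "day") %in% names(trials)))
  if (any(trials$energy < 1 | trials$energy > 5))
    stop("no choice exists at energy state 0 (or states above 5)")
  if (any(!trials$weather %in% 1:2)) stop("weather must be coded 1/2")
  t_togo <- pmax(horizon - trials$day + 1, 1)
  tab$dq[cbind(trials$energy, trials$weather, t_togo)]
}
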