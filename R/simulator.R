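# Task simulator: forest sets, episodes, sessions, payoffs.
#
# An agent is a function(ctx) returning the probability of foraging,
# where ctx is a list with elements energy, weather (1 bad / 2 good),
# day, p, g, delta_energy (energy change realized on the previous
# choice, 0 before the first), dq_h5, dq_h1 (optimal value differences
# under the horizon-decrement rule).

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a set of forest types
#'
#' Samples distinct forest types from the task grid: weather cells are
#' all combinations of p in \code{p_grid} and g in \code{g_grid} (the
#' task uses 9 x 5 = 45 cells), forests pair two distinct cells plus a
#' starting energy. Sampling is deterministic under \code{seed}.
#'
#' @param n_forests number of distinct forest types (study default 240).
#' @param p_grid grid of success probabilities.
#' @param g_grid grid of gain magnitudes.
#' @param start_energies candidate starting energies.
#' @param seed RNG seed (\code{NULL} to use the current RNG state).
#' @return a list of \code{\link{forest}} objects of length
#'   \code{n_forests}.
#' @export
generate_forest_set <- function(n_forests = 240,
                                p_grid = seq(0.1, 0.9, by = 0.1),
                                g_grid = 0:4,
                                start_energies = 2:4,
                                seed = NULL) {
  stopifnot(length(p_grid) >= 1, length(g_grid) >= 1,
            all(p_grid > 0 & p_grid < 1), all(g_grid %in% 0:4))
  cells <- expand.grid(p = p_grid, g = g_grid)
  pairs <- utils::combn(nrow(cells), 2)
  types <- expand.grid(pair = seq_len(ncol(pairs)), s0 = start_energies)
  if (n_forests > nrow(types))
    stop("grid supports at most ", nrow(types), " distinct forest types")
  with_seed(seed, {
    pick <- sample.int(nrow(types), n_forests)
    lapply(pick, function(i) {
      ij <- pairs[, types$pair[i]]
      forest(weather(cells$p[ij[1]], cells$g[ij[1]]),
             weather(cells$p[ij[2]], cells$g[ij[2]]),
             start_energy = types$s0[i])
    })
  })
}

#' Simulate one episode (forest visit)
#'
#' Draws the weather fairly on each day, queries the agent for a forage
#' probability, draws the choice and the foraging outcome, and updates
#' the energy state under the transition rules. Once the agent starves,
#' the remaining days of the episode are emitted as starvation marker
#' records (no choices), mirroring the task's trial accounting.
#'
#' @param f a \code{\link{forest}}.
#' @param agent function(ctx) -> forage probability; see file header for
#'   the ctx fields.
#' @param n_days episode length, 1--5.
#' @param tab optional precomputed \code{\link{optimal_values}} table of
#'   \code{f} with horizon >= 5 (computed if \code{NULL}).
#' @param start_energy starting energy (default: the forest's).
#' @param prev_delta energy change carried in from the previous episode
#'   (0 at the start of an experiment).
#' @param seed RNG seed (\code{NULL} to use the current RNG state).
#' @return a data frame with one row per day: \code{day, weather, p, g,
#'   energy, choice, outcome, energy_after, valid} (\code{valid} is
#'   \code{FALSE} on starvation marker rows).
#' @export
simulate_episode <- function(f, agent, n_days = 5, tab = NULL,
                             start_energy = f$start_energy,
                             prev_delta = 0, seed = NULL) {
  stopifnot(is.forest(f), n_days >= 1, n_days <= 5)
  if (is.null(tab)) tab <- optimal_values(f, 5)
  with_seed(seed,
    as.data.frame(episode_core(f, tab, agent, n_days, start_energy,
                               prev_delta)))
}

# inner episode loop on preallocated vectors (shared by
# simulate_episode and simulate_participant); uses the current RNG
episode_core <- function(f, tab, agent, n_days, start_energy,
                         prev_delta) {
  ps <- c(f$weather_bad$p, f$weather_good$p)
  gs <- c(f$weather_bad$g, f$weather_good$g)
  dq <- tab$dq
  weather <- sample.int(2L, n_days, replace = TRUE)
  energy <- choice <- outcome <- energy_after <- integer(n_days)
  choice[] <- outcome[] <- NA_integer_
  valid <- logical(n_days)
  s <- start_energy
  delta <- prev_delta
  u <- stats::runif(2L * n_days) # choice draw, outcome draw per day
  for (day in seq_len(n_days)) {
    w <- weather[day]
    energy[day] <- s
    if (s == 0L) next # starvation marker row
    t5 <- max(5L - day + 1L, 1L)
    fp <- agent(list(energy = s, weather = w, day = day, p = ps[w],
                     g = gs[w], delta_energy = delta,
                     dq_h5 = dq[s, w, t5], dq_h1 = dq[s, w, 1]))
    if (!is.numeric(fp) || is.na(fp) || fp < 0 || fp > 1)
      stop("agent returned an invalid forage probability")
    ch <- as.integer(u[2L * day - 1L] < fp)
    s_after <- if (ch == 1L) {
      if (u[2L * day] < ps[w]) min(s + gs[w], 5L) else max(s - 2L, 0L)
    } else max(s - 1L, 0L)
    choice[day] <- ch
    outcome[day] <- s_after - s
    energy_after[day] <- s_after
    valid[day] <- TRUE
    delta <- outcome[day]
    s <- s_after
  }
  list(day = seq_len(n_days), weather = weather, p = ps[weather],
       g = gs[weather], energy = energy, choice = choice,
       outcome = outcome, energy_after = energy_after, valid = valid)
}

# P(ceil(Exp(mean)) = l) for l = 1..max_days, all mass above clipped up
episode_length_probs <- function(mean = 2.5, max_days = 5) {
  l <- seq_len(max_days - 1)
  p <- exp(-(l - 1) / mean) - exp(-l / mean)
  c(p, exp(-(max_days - 1) / mean))
}

#' Sample episode lengths conditional on a session total
#'
#' Episode lengths follow a truncated exponential (mean 2.5 days, ceiled
#' and clipped to 1--5), but each session comprises exactly
#' \code{n} forests totalling \code{total} days. Lengths are therefore
#' drawn from the exact conditional distribution of \code{n} i.i.d.
#' truncated-exponential lengths given their sum, by sequential sampling
#' from a convolution table.
#'
#' @param n number of forests per session (study: 24).
#' @param total total days per session (study: 40).
#' @param probs unconditional length distribution over 1..length(probs).
#' @param seed RNG seed (\code{NULL} to use the current RNG state).
#' @return integer vector of \code{n} lengths summing to \code{total}.
#' @export
sample_episode_lengths <- function(n = 24, total = 40,
                                   probs = episode_length_probs(),
                                   seed = NULL) {
  L <- length(probs)
  stopifnot(total >= n, total <= n * L)
  # conv[k + 1, s + 1] = P(sum of k draws = s)
  conv <- matrix(0, n + 1, total + 1)
  conv[1, 1] <- 1
  for (k in seq_len(n))
    for (s in k:min(total, k * L))
      conv[k + 1, s + 1] <- sum(probs[seq_len(min(L, s))] *
                                conv[k, s - seq_len(min(L, s)) + 1])
  if (conv[n + 1, total + 1] <= 0) stop("infeasible length constraint")
  with_seed(seed, {
    lens <- integer(n)
    rem <- total
    for (j in seq_len(n)) {
      k_left <- n - j
      cand <- seq_len(min(L, rem))
      wgt <- probs[cand] * conv[k_left + 1, rem - cand + 1]
      lens[j] <- sample(cand, 1, prob = wgt)
      rem <- rem - lens[j]
    }
    lens
  })
}

#' Simulate a full participant
#'
#' Runs \code{n_sessions} sessions of \code{forests_per_session} forests
#' (sampled from \code{forest_set}) totalling \code{days_per_session}
#' days each, with the given agent. Energy change carries across forest
#' boundaries into the agent context (for WSLS-type agents).
#'
#' @param forest_set list of \code{\link{forest}} objects (with an
#'   optional attribute \code{"tabs"} of precomputed value tables).
#' @param agent agent function; see \code{\link{simulate_episode}}.
#' @param n_sessions,forests_per_session,days_per_session session
#'   structure (study defaults 10, 24, 40).
#' @param seed RNG seed.
#' @return a data frame of trial records with columns \code{session,
#'   forest, day, weather, p, g, energy, choice, outcome, energy_after,
#'   valid} plus the forest record columns (\code{p_bad, g_bad, p_good,
#'   g_good, start_energy}).
#' @export
simulate_participant <- function(forest_set, agent, n_sessions = 10,
                                 forests_per_session = 24,
                                 days_per_session = 40, seed = NULL) {
  tabs <- attr(forest_set, "tabs")
  if (is.null(tabs)) tabs <- lapply(forest_set, optimal_values, horizon = 5)
  recs <- do.call(rbind, lapply(forest_set, forest_record))
  with_seed(seed, {
    eps <- vector("list", n_sessions * forests_per_session)
    sess_id <- forest_id <- integer(length(eps))
    delta <- 0
    k <- 0L
    for (sess in seq_len(n_sessions)) {
      idx <- sample.int(length(forest_set), forests_per_session,
                        replace = forests_per_session > length(forest_set))
      lens <- sample_episode_lengths(forests_per_session, days_per_session)
      for (j in seq_along(idx)) {
        fi <- idx[j]
        ep <- episode_core(forest_set[[fi]], tabs[[fi]], agent,
                           n_days = lens[j],
                           start_energy = forest_set[[fi]]$start_energy,
                           prev_delta = delta)
        last_out <- ep$outcome[ep$valid]
        if (length(last_out)) delta <- last_out[length(last_out)]
        k <- k + 1L
        eps[[k]] <- ep
        sess_id[k] <- sess
        forest_id[k] <- fi
      }
    }
    nd <- vapply(eps, function(e) length(e$day), 0L)
    flat <- function(field) unlist(lapply(eps, `[[`, field),
                                   use.names = FALSE)
    fid <- rep(forest_id, nd)
    data.frame(session = rep(sess_id, nd), forest = fid,
               day = flat("day"), weather = flat("weather"),
               p = flat("p"), g = flat("g"), energy = flat("energy"),
               choice = flat("choice"), outcome = flat("outcome"),
               energy_after = flat("energy_after"), valid = flat("valid"),
               recs[fid, ], row.names = NULL)
  })
}

#' Session payoff
#'
#' One randomly selected forest per session is completed to day five;
#' each selected forest survived (energy above zero at day five,
#' regardless of the precise level) pays CHF 1.50.
#'
#' @param survived logical vector, one entry per selected forest.
#' @param per_forest payout per surviving forest (CHF).
#' @return total payoff in CHF.
#' @examples
#' payoff(rep(TRUE, 10))  # 15
#' @export
payoff <- function(survived, per_forest = 1.5) {
  stopifnot(is.logical(survived))
  per_forest * sum(survived)
}
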