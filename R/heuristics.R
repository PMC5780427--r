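# Trial-by-trial heuristic decision variables and the optimal-policy
# value differences used as candidate predictors of choice.

#' Names of the eleven candidate decision variables
#'
#' The ten heuristic variables plus the horizon-5 optimal-policy value
#' difference, in the conventional model-numbering order: optimal policy
#' (h-5), probability of foraging success, gain magnitude, expected
#' value, continuous energy state, binary energy state, weather type,
#' days past in the forest, change in energy states, win-stay-lose-shift,
#' and the myopic horizon-1 policy.
#'
#' @return character vector of column names as produced by
#'   \code{\link{compute_heuristics}}.
#' @export
candidate_variables <- function() {
  c("dq_h5", "p_success", "gain", "ev", "energy_cont", "energy_bin",
    "weather", "days_past", "delta_energy", "wsls", "dq_h1")
}

#' Compute heuristic variables for a trial table
#'
#' Appends, per trial: \code{p_success} and \code{gain} of the realized
#' weather; the momentary expected value \code{ev = p g - (1 - p) 2} (the
#' expected value of waiting is always -1); the continuous energy state
#' and its binarization (\code{energy_bin = 1} iff energy is 1, where
#' waiting means sure death); the weather code (1 bad, 2 good); the day
#' within the forest; the change in energy states relative to the
#' previous trial (within and across forests; missing on each
#' participant's first trial); the win-stay-lose-shift indicator
#' (1 iff the energy state increased); and the optimal-policy value
#' differences for horizons 5 and 1 under the horizon-decrement rule.
#'
#' @param trials a trial table ordered chronologically within
#'   participant, containing columns \code{participant, day, weather,
#'   energy, outcome} and the forest record columns \code{p_bad, g_bad,
#'   p_good, g_good}; rows with energy 0 must be pre-filtered.
#' @param horizons integer horizons for which to add \code{dq_h<k>}
#'   columns (default 5 and 1).
#' @return the trial table with the heuristic columns appended.
#' @export
compute_heuristics <- function(trials, horizons = c(5L, 1L)) {
  need <- c("participant", "day", "weather", "energy", "outcome",
            "p_bad", "g_bad", "p_good", "g_good", "start_energy")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(trials$energy == 0))
    stop("energy-0 rows present; filter starvation markers first")
  if (any(!trials$weather %in% 1:2)) stop("weather must be coded 1/2")
  good <- trials$weather == 2L
  trials$p_success <- ifelse(good, trials$p_good, trials$p_bad)
  trials$gain <- ifelse(good, trials$g_good, trials$g_bad)
  trials$ev <- trials$p_success * trials$gain -
    (1 - trials$p_success) * 2
  trials$energy_cont <- trials$energy
  trials$energy_bin <- as.integer(trials$energy == 1L)
  trials$days_past <- trials$day
  first <- !duplicated(trials$participant)
  prev_outcome <- c(NA_integer_, trials$outcome[-nrow(trials)])
  prev_outcome[first] <- NA_integer_
  trials$delta_energy <- prev_outcome
  trials$wsls <- as.integer(trials$delta_energy > 0)
  # optimal-policy value differences, one table per unique forest
  key <- paste(trials$p_bad, trials$g_bad, trials$p_good, trials$g_good,
               trials$start_energy)
  hmax <- max(horizons)
  for (h in horizons) trials[[paste0("dq_h", h)]] <- NA_real_
  for (k in unique(key)) {
    i <- which(key == k)
    f <- forest_from_record(trials[i[1], ])
    tab <- optimal_values(f, hmax)
    for (h in horizons)
      trials[[paste0("dq_h", h)]][i] <-
        value_difference_series(tab, h, trials[i, ])
  }
  trials
}

#' Shared variance between two trial series
#'
#' Squared Pearson correlation; the trial-by-trial measure used to ask
#' how much of the optimal policy a heuristic carries.
#'
#' @param x,y numeric vectors of equal length.
#' @return proportion of shared variance in [0, 1].
#' @export
shared_variance <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("shared variance undefined for a constant series")
  stats::cor(x, y)^2
}

#' Pairwise shared-variance matrix of the candidate variables
#'
#' @param trials a trial table with the columns of
#'   \code{\link{candidate_variables}} (see
#'   \code{\link{compute_heuristics}}).
#' @param vars variable names (default: all eleven candidates).
#' @return symmetric matrix of squared pairwise Pearson correlations
#'   (pairwise complete observations).
#' @export
shared_variance_matrix <- function(trials, vars = candidate_variables()) {
  m <- as.matrix(trials[, vars])
  stats::cor(m, use = "pairwise.complete.obs")^2
}
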