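# Shared fixtures, memoized so expensive simulations run once per suite.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# the example forest of the task figure: good weather p = 0.6, g = 1;
# bad weather p = 0.1, g = 1; start energy 2
fig_forest <- function() forest(weather(0.6, 1), weather(0.1, 1), 2)

# trivial reference policies for metric plumbing tests
unit_ref <- function(beta0 = 0, beta1 = 1)
  structure(list(beta0 = beta0, beta1 = beta1, variable = "x",
                 n_participants = 0), class = "ref_policy")

# reference logistic policies fitted on an independent 21-participant
# sample at study scale (the "behavioral sample" role)
behavioral_refs <- function() memo("refs21", {
  ds <- generate_dataset(generative_params(n_participants = 21),
                         seed = 9000,
                         refs = list(p = unit_ref(), dq = unit_ref()))
  tr <- ds$trials[ds$trials$valid, ]
  list(p = fit_reference_policy(tr, "p_success"),
       dq = fit_reference_policy(tr, "dq_h5"))
})

# one study-scale synthetic dataset (28 participants, 400 days each)
study_ds <- function() memo("study_ds",
  generate_dataset(generative_params(), seed = 7100,
                   refs = behavioral_refs()))

# a small dataset for cheap unit tests
small_ds <- function() memo("small_ds",
  generate_dataset(generative_params(n_participants = 6, n_sessions = 3),
                   seed = 7200, refs = behavioral_refs()))

# all (s, weather, day) decision points reachable with positive
# probability under some policy, for exhaustive policy search
reachable_points <- function(f, horizon, start) {
  gs <- c(f$weather_bad$g, f$weather_good$g)
  states <- start
  pts <- list()
  for (day in seq_len(horizon)) {
    for (s in states) for (w in 1:2)
      pts[[length(pts) + 1L]] <- c(s = s, w = w, t = horizon - day + 1L)
    nxt <- integer(0)
    for (s in states) for (w in 1:2)
      nxt <- c(nxt, max(s - 1L, 0L), min(s + gs[w], 5L), max(s - 2L, 0L))
    states <- setdiff(unique(nxt), 0L)
    if (!length(states)) break
  }
  do.call(rbind, pts)
}

# best survival over every deterministic policy on the reachable points
best_exhaustive_survival <- function(f, horizon, start) {
  pts <- reachable_points(f, horizon, start)
  n <- nrow(pts)
  stopifnot(n <= 14) # 2^14 policies at most
  key <- paste(pts[, 1], pts[, 2], pts[, 3])
  best <- -Inf
  for (mask in 0:(2^n - 1)) {
    acts <- as.integer(intToBits(mask))[seq_len(n)]
    pol <- function(s, w, t) acts[match(paste(s, w, t), key)]
    sv <- brute_force_survival(f, horizon, pol, start_energy = start)
    if (sv > best) best <- sv
  }
  best
}

# sample skewness
skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}
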