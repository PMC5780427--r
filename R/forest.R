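#' Weather type specification
#'
#' A weather type is one of the two foraging environments that define a
#' forest. It is fully described by the probability of foraging success
#' \code{p} and the gain magnitude \code{g}; unsuccessful foraging always
#' costs 2 energy points.
#'
#' @param p probability of foraging success; on the task grid this is
#'   0.1--0.9 in steps of 0.1, but any value in (0, 1) is accepted.
#' @param g integer gain magnitude in energy points, 0--4.
#' @return an object of class \code{"weather"}: a list with elements
#'   \code{p}, \code{q = 1 - p}, \code{g} and the fixed foraging loss
#'   \code{c_f = 2}.
#' @examples
#' weather(0.6, 1)
#' @export
weather <- function(p, g) {
  stopifnot(is.numeric(p), length(p) == 1L, p > 0, p < 1,
            is.numeric(g), length(g) == 1L, g %in% 0:4)
  structure(list(p = p, q = 1 - p, g = as.integer(g), c_f = 2L),
            class = "weather")
}

#' @export
print.weather <- function(x, ...) {
  cat(sprintf("weather: p = %.2f, g = %d (loss %d)\n", x$p, x$g, x$c_f))
  invisible(x)
}

#' Forest specification
#'
#' A forest is a mini-block of up to five days defined by two weather
#' types (each drawn independently with probability 0.5 on every day) and
#' a starting energy state. The two weathers are stored ordered so that
#' \code{weather_good} is the one with the lower implied starvation
#' probability (horizon-5 optimal play in a single-weather world starting
#' from energy 3); ties are broken by higher \code{p}, then higher
#' \code{g}.
#'
#' @param w1,w2 \code{\link{weather}} objects (order irrelevant).
#' @param start_energy starting energy state, one of 2, 3, 4.
#' @return an object of class \code{"forest"}: a list with elements
#'   \code{weather_bad}, \code{weather_good}, \code{start_energy} and the
#'   fixed waiting loss \code{c_w = 1}.
#' @examples
#' f <- forest(weather(0.6, 1), weather(0.1, 1), start_energy = 2)
#' f$weather_good$p  # 0.6
#' @export
forest <- function(w1, w2, start_energy = 3) {
  stopifnot(inherits(w1, "weather"), inherits(w2, "weather"),
            start_energy %in% 2:4)
  s1 <- weather_starvation(w1)
  s2 <- weather_starvation(w2)
  key1 <- c(-s1, w1$p, w1$g)
  key2 <- c(-s2, w2$p, w2$g)
  # lexicographic: lower starvation wins, then higher p, then higher g
  first_is_good <- {
    d <- key1 - key2
    i <- which(abs(d) > 1e-12)[1]
    if (is.na(i)) TRUE else d[i] > 0
  }
  good <- if (first_is_good) w1 else w2
  bad <- if (first_is_good) w2 else w1
  structure(list(weather_bad = bad, weather_good = good,
                 start_energy = as.integer(start_energy), c_w = 1L),
            class = "forest")
}

# implied starvation probability of a single weather type: horizon-5
# optimal play when that weather occurs every day, starting at energy 3
weather_starvation <- function(w) {
  f <- structure(list(weather_bad = w, weather_good = w,
                      start_energy = 3L, c_w = 1L), class = "forest")
  tab <- optimal_values(f, horizon = 5)
  1 - tab$v[3, 1, 5]
}

#' @export
print.forest <- function(x, ...) {
  cat(sprintf(
    "forest: bad (p = %.2f, g = %d), good (p = %.2f, g = %d), start energy %d\n",
    x$weather_bad$p, x$weather_bad$g,
    x$weather_good$p, x$weather_good$g, x$start_energy))
  invisible(x)
}

#' @rdname forest
#' @param x an object to test or convert.
#' @export
is.forest <- function(x) inherits(x, "forest")

#' Serialize forests to and from plain records
#'
#' Forests round-trip through flat records \code{(p_bad, g_bad, p_good,
#' g_good, start_energy)}, the JSON/CSV interchange form.
#'
#' @param f a forest, or for \code{forest_from_record} a list/1-row data
#'   frame with fields \code{p_bad, g_bad, p_good, g_good, start_energy}.
#' @return \code{forest_record}: a one-row data frame;
#'   \code{forest_from_record}: a \code{\link{forest}}.
#' @export
forest_record <- function(f) {
  stopifnot(is.forest(f))
  data.frame(p_bad = f$weather_bad$p, g_bad = f$weather_bad$g,
             p_good = f$weather_good$p, g_good = f$weather_good$g,
             start_energy = f$start_energy)
}

#' @rdname forest_record
#' @export
forest_from_record <- function(f) {
  forest(weather(f$p_bad[[1]], f$g_bad[[1]]),
         weather(f$p_good[[1]], f$g_good[[1]]),
         start_energy = f$start_energy[[1]])
}

#' Expected one-day values of the two choice options
#'
#' The momentary (myopic) expected value of foraging under a weather type
#' is \eqn{p g - (1-p) \cdot 2}; the expected value of waiting is always
#' \eqn{-1} (the sure waiting loss), independent of the forest.
#'
#' @param w a \code{\link{weather}} object.
#' @return a list with elements \code{forage} and \code{wait} (energy
#'   points).
#' @examples
#' expected_values(weather(0.6, 1))$forage  # -0.2
#' @export
expected_values <- function(w) {
  stopifnot(inherits(w, "weather"))
  list(forage = w$p * w$g - w$q * w$c_f, wait = -1)
}
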