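# Hierarchical regression of log reaction times on the five policy
# predictors, with per-predictor likelihood-ratio tests, posterior
# predictive checks, and the opposing-trial RT contrast.

rt_predictors_default <- c("p_success", "dq_h5", "unc_p", "unc_dq",
                           "discrepancy")

#' Fit the hierarchical log-RT model
#'
#' Fits \code{log(rt) ~ predictors + (1 + predictors | participant)} by
#' maximum likelihood (lme4). The random-effects structure falls back
#' from the full (unstructured covariance) model to independent
#' (diagonal) random slopes and finally to a random intercept only if a
#' fit fails, does not converge, or is singular; the structure actually
#' used is recorded. Fixed-effect significance is assessed by
#' likelihood-ratio tests of the full model against models dropping
#' each predictor's fixed effect.
#'
#' @param trials trial table with \code{rt} (seconds), the predictor
#'   columns, \code{participant} and \code{valid}.
#' @param predictors predictor column names (default: probability of
#'   foraging success, h-5 value difference, the two choice
#'   uncertainties, and the discrepancy).
#' @param re_structure first structure to try: \code{"full"},
#'   \code{"diagonal"} or \code{"intercept"}; fallback proceeds down
#'   that list.
#' @param standardize z-score predictors within participant before
#'   fitting (default \code{TRUE}).
#' @param lrt compute per-predictor likelihood-ratio tests (refits the
#'   model once per predictor).
#' @return object of class \code{"rt_fit"}: list with the lme4 fit
#'   (\code{model}), fixed effects (\code{coefficients}), the structure
#'   used, the LRT table, and scaling metadata.
#' @export
fit_rt <- function(trials, predictors = rt_predictors_default,
                   re_structure = c("full", "diagonal", "intercept"),
                   standardize = TRUE, lrt = TRUE) {
  re_structure <- match.arg(re_structure)
  d <- trials[trials$valid %in% TRUE & !is.na(trials$rt), ]
  stopifnot(all(predictors %in% names(d)), all(d$rt > 0),
            length(unique(d$participant)) >= 2)
  d$log_rt <- log(d$rt)
  if (standardize) {
    for (v in predictors) {
      d[[v]] <- stats::ave(d[[v]], d$participant, FUN = function(x) {
        s <- stats::sd(x)
        if (s == 0) x * 0 else (x - mean(x)) / s
      })
    }
  }
  px <- paste(predictors, collapse = " + ")
  forms <- list(
    full = stats::as.formula(sprintf(
      "log_rt ~ %s + (1 + %s | participant)", px, px)),
    diagonal = stats::as.formula(sprintf(
      "log_rt ~ %s + (1 + %s || participant)", px, px)),
    intercept = stats::as.formula(sprintf(
      "log_rt ~ %s + (1 | participant)", px)))
  order <- c("full", "diagonal", "intercept")
  order <- order[match(re_structure, order):3]
  fit <- NULL
  used <- NULL
  notes <- character()
  for (st in order) {
    f <- tryCatch(
      suppressWarnings(lme4::lmer(forms[[st]], data = d, REML = FALSE)),
      error = function(e) NULL)
    bad <- is.null(f) || lme4::isSingular(f, tol = 1e-5) ||
      length(f@optinfo$conv$lme4$messages) > 0
    if (!bad) { fit <- f; used <- st; break }
    notes <- c(notes, sprintf("structure '%s' failed or was singular", st))
    if (is.null(fit) && st == order[length(order)]) { fit <- f; used <- st }
  }
  if (is.null(fit)) stop("all random-effects structures failed to fit")
  lrt_tab <- NULL
  if (lrt) {
    lrt_tab <- do.call(rbind, lapply(predictors, function(v) {
      red <- stats::update(stats::formula(fit),
                           stats::as.formula(paste(". ~ . -", v)))
      rf <- suppressWarnings(lme4::lmer(red, data = d, REML = FALSE))
      chisq <- max(0, 2 * (as.numeric(stats::logLik(fit)) -
                             as.numeric(stats::logLik(rf))))
      data.frame(predictor = v, chisq = chisq, df = 1,
                 p = stats::pchisq(chisq, 1, lower.tail = FALSE))
    }))
  }
  structure(list(model = fit, coefficients = lme4::fixef(fit),
                 re_structure = used, notes = notes, lrt = lrt_tab,
                 predictors = predictors, standardize = standardize,
                 n = nrow(d), data = d),
            class = "rt_fit")
}

#' @export
print.rt_fit <- function(x, ...) {
  cat(sprintf("log-RT mixed model (%d trials, random effects: %s)\n",
              x$n, x$re_structure))
  print(round(x$coefficients, 4))
  if (!is.null(x$lrt)) {
    cat("likelihood-ratio tests (full vs without predictor):\n")
    print(x$lrt, row.names = FALSE, digits = 3)
  }
  if (length(x$notes)) cat(paste0("note: ", x$notes, "\n"))
  invisible(x)
}

#' @export
coef.rt_fit <- function(object, ...) object$coefficients

#' @export
summary.rt_fit <- function(object, ...) summary(object$model)

#' @export
residuals.rt_fit <- function(object, ...) stats::residuals(object$model)

#' Binned posterior predictive check of the RT model
#'
#' Compares observed and model-predicted mean log RT across bins of one
#' predictor (predictions are the participant-conditional fitted values
#' of the mixed model, averaged per bin across participants).
#'
#' @param fit an \code{\link{fit_rt}} object.
#' @param bin_variable predictor to bin by (on the scale used in the
#'   fit).
#' @param n_bins number of bins.
#' @return object of class \code{"rt_ppc"}: data frame of bin
#'   midpoints, observed and predicted means with SEM and counts.
#' @export
rt_posterior_predictive <- function(fit, bin_variable, n_bins = 7) {
  d <- fit$data
  x <- d[[bin_variable]]
  ux <- sort(unique(x))
  if (length(ux) <= n_bins) {
    bin <- match(x, ux)
    mids <- ux
  } else {
    br <- unique(stats::quantile(x, seq(0, 1, length.out = n_bins + 1)))
    bin <- cut(x, br, include.lowest = TRUE, labels = FALSE)
    mids <- (br[-1] + br[-length(br)]) / 2
  }
  pred <- stats::fitted(fit$model)
  agg <- function(v) {
    pm <- tapply(v, list(d$participant, bin), mean)
    list(mean = colMeans(pm, na.rm = TRUE),
         sem = apply(pm, 2, stats::sd, na.rm = TRUE) /
           sqrt(colSums(!is.na(pm))))
  }
  o <- agg(d$log_rt); p <- agg(pred)
  keep <- as.integer(names(o$mean))
  out <- data.frame(bin = mids[keep], observed = o$mean,
                    obs_sem = o$sem, predicted = p$mean,
                    pred_sem = p$sem,
                    n = as.vector(table(factor(bin, levels = keep))))
  structure(out, class = c("rt_ppc", "data.frame"),
            bin_variable = bin_variable)
}

#' @export
plot.rt_ppc <- function(x, ...) {
  rng <- range(c(x$observed - x$obs_sem, x$observed + x$obs_sem,
                 x$predicted))
  graphics::plot(x$bin, x$observed, ylim = rng, pch = 19,
                 xlab = attr(x, "bin_variable"),
                 ylab = "mean log RT", ...)
  graphics::arrows(x$bin, x$observed - x$obs_sem, x$bin,
                   x$observed + x$obs_sem, angle = 90, code = 3,
                   length = 0.03)
  graphics::lines(x$bin, x$predicted, col = "red3")
  graphics::points(x$bin, x$predicted, col = "red3", pch = 4)
  invisible(x)
}

#' RT contrast between heuristic- and optimal-consistent choices
#'
#' On opposing-prescription trials, each choice follows exactly one of
#' the two policies. Computes per-participant mean RTs for
#' heuristic-followed and optimal-followed trials and the paired t-test
#' of their difference (optimal minus heuristic, in ms).
#'
#' @param trials trial table carrying \code{rt}, \code{choice},
#'   \code{pred_p}, \code{pred_dq}, \code{valid} (see
#'   \code{\link{add_policy_metrics}}).
#' @return list with the per-participant table, mean and SD of the
#'   paired difference (ms), and the paired t-test; participants with
#'   an empty cell are excluded (and counted in \code{n_excluded}).
#' @export
rt_opposing_contrast <- function(trials) {
  stopifnot(all(c("pred_p", "pred_dq", "rt", "choice") %in% names(trials)))
  ok <- trials$valid %in% TRUE & !is.na(trials$rt) & !is.na(trials$choice)
  opp <- ok & (trials$pred_p - 0.5) * (trials$pred_dq - 0.5) < 0
  d <- trials[opp, ]
  followed_opt <- (d$choice == 1) == (d$pred_dq > 0.5)
  per <- do.call(rbind, lapply(split(seq_len(nrow(d)), d$participant),
    function(i) {
      fo <- followed_opt[i]
      data.frame(rt_heuristic = mean(d$rt[i][!fo]),
                 rt_optimal = mean(d$rt[i][fo]),
                 n_heuristic = sum(!fo), n_optimal = sum(fo))
    }))
  per$participant <- rownames(per)
  complete <- per$n_heuristic > 0 & per$n_optimal > 0
  diff_ms <- (per$rt_optimal - per$rt_heuristic)[complete] * 1000
  test <- if (sum(complete) >= 2) stats::t.test(diff_ms) else NULL
  list(per_participant = per, mean_diff_ms = mean(diff_ms),
       sd_diff_ms = stats::sd(diff_ms), test = test,
       n_excluded = sum(!complete))
}
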