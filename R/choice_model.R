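# Logistic choice models: per-participant maximum-likelihood fits,
# BIC-based model evidence, the model-space generator, and posterior
# predictive checks.
#
# The choice model is p(forage) = 1 / (1 + exp(-DV)) with
# DV = b0 + b1 x1 + ... The likelihood is maximised with stats::glm;
# complete separation is caught and refit with a tiny ridge penalty
# (flagged), so that every model yields a finite BIC.

#' Fit a logistic choice model for one participant
#'
#' @param data trials of a single participant: a data frame with a
#'   binary \code{choice} column (1 forage, 0 wait) and the predictor
#'   columns named in \code{predictors}.
#' @param predictors character vector of predictor column names; rows
#'   with missing predictors or choices are dropped (complete-case).
#' @param standardize z-score the predictors within the participant
#'   before fitting (default \code{TRUE}); constant predictors are set
#'   to zero and flagged.
#' @param ridge ridge penalty used only in the separation fallback.
#' @return an object of class \code{"choice_fit"} with the coefficient
#'   vector, maximized log-likelihood, \code{n}, \code{k}, \code{bic},
#'   and \code{converged}/\code{separation} flags. \code{BIC = k log n -
#'   2 logLik} holds exactly.
#' @export
fit_choice <- function(data, predictors, standardize = TRUE,
                       ridge = 1e-6) {
  stopifnot("choice" %in% names(data),
            all(predictors %in% names(data)))
  X <- as.matrix(data[, predictors, drop = FALSE])
  y <- data$choice
  ok <- stats::complete.cases(X, y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  n <- length(y)
  if (n < 2) stop("not enough trials to fit")
  centers <- rep(0, ncol(X)); scales <- rep(1, ncol(X))
  constant <- logical(ncol(X))
  if (standardize && ncol(X) > 0) {
    centers <- colMeans(X)
    scales <- apply(X, 2, stats::sd)
    constant <- scales == 0
    scales[constant] <- 1
    X <- sweep(sweep(X, 2, centers), 2, scales, "/")
    X[, constant] <- 0
  }
  names(centers) <- names(scales) <- names(constant) <- predictors
  Xd <- cbind(`(Intercept)` = 1, X)
  loglik <- function(beta) {
    eta <- drop(Xd %*% beta)
    # log(1 + e^eta) computed overflow-safely
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  fit <- suppressWarnings(
    stats::glm.fit(Xd, y, family = stats::binomial()))
  beta <- fit$coefficients
  separation <- !fit$converged || anyNA(beta) || any(abs(beta) > 15)
  if (separation) {
    beta0 <- rep(0, ncol(Xd))
    obj <- function(b) -loglik(b) + ridge * sum(b^2)
    grad <- function(b) {
      mu <- stats::plogis(drop(Xd %*% b))
      -drop(crossprod(Xd, y - mu)) + 2 * ridge * b
    }
    opt <- stats::optim(beta0, obj, grad, method = "BFGS",
                        control = list(maxit = 500))
    beta <- opt$par
    names(beta) <- colnames(Xd)
  }
  ll <- loglik(beta)
  k <- length(beta)
  structure(list(coefficients = beta, logLik = ll, n = n, k = k,
                 bic = k * log(n) - 2 * ll,
                 converged = fit$converged || separation,
                 separation = separation,
                 predictors = predictors, standardize = standardize,
                 centers = centers, scales = scales, constant = constant),
            class = "choice_fit")
}

#' @export
print.choice_fit <- function(x, ...) {
  cat(sprintf("logistic choice model (%d trials, %d parameters)\n",
              x$n, x$k))
  print(round(x$coefficients, 4))
  cat(sprintf("logLik %.3f, BIC %.3f%s\n", x$logLik, x$bic,
              if (x$separation) " [separation: ridge fallback]" else ""))
  invisible(x)
}

#' @export
coef.choice_fit <- function(object, ...) object$coefficients

#' @export
logLik.choice_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n,
            class = "logLik")
}

#' @export
predict.choice_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$predictors, drop = FALSE])
  X <- sweep(sweep(X, 2, object$centers), 2, object$scales, "/")
  X[, object$constant] <- 0
  stats::plogis(drop(cbind(1, X) %*% object$coefficients))
}

#' @export
simulate.choice_fit <- function(object, nsim = 1, seed = NULL,
                                newdata, ...) {
  pr <- predict.choice_fit(object, newdata)
  with_seed(seed, {
    matrix(stats::rbinom(length(pr) * nsim, 1, rep(pr, nsim)),
           ncol = nsim)
  })
}

#' Enumerate the logistic model space
#'
#' Stages: \code{"single"} (each of the eleven candidate variables
#' alone), \code{"second_given_p"} (p_success plus each remaining
#' variable; 10 models), \code{"all_pairs"} (all 55 unordered pairs),
#' \code{"triples"} (all triples containing p_success and the h-5
#' optimal policy), and \code{"interactions"} (the five interaction
#' forms, expressed over derived columns; see
#' \code{\link{add_policy_interactions}}).
#'
#' @param stage model-space stage.
#' @param candidates candidate variable names.
#' @return a named list of character vectors of predictor names.
#' @export
choice_model_space <- function(stage = c("single", "second_given_p",
                                         "all_pairs", "triples",
                                         "interactions"),
                               candidates = candidate_variables()) {
  stage <- match.arg(stage)
  specs <- switch(stage,
    single = as.list(candidates),
    second_given_p = lapply(setdiff(candidates, "p_success"),
                            function(v) c("p_success", v)),
    all_pairs = utils::combn(candidates, 2, simplify = FALSE),
    triples = lapply(setdiff(candidates, c("p_success", "dq_h5")),
                     function(v) c("p_success", "dq_h5", v)),
    interactions = list(
      c("p_x_cert", "dq_h5"),
      c("p_success", "dq_x_cert"),
      c("p_x_cert", "dq_x_cert"),
      c("p_x_disc", "dq_h5"),
      c("p_success", "dq_x_disc")))
  names(specs) <- vapply(specs, paste, "", collapse = "+")
  specs
}

#' Derived interaction predictors
#'
#' Adds the columns used by the interaction model stage:
#' \code{p_x_cert = p_success * (1 - unc_p)}, \code{dq_x_cert = dq_h5 *
#' (1 - unc_dq)}, \code{p_x_disc = p_success * discrepancy},
#' \code{dq_x_disc = dq_h5 * discrepancy}. Requires the uncertainty and
#' discrepancy columns from \code{\link{add_policy_metrics}}.
#'
#' @param trials trial table with \code{p_success, dq_h5, unc_p,
#'   unc_dq, discrepancy}.
#' @return the table with the four derived columns appended.
#' @export
add_policy_interactions <- function(trials) {
  need <- c("p_success", "dq_h5", "unc_p", "unc_dq", "discrepancy")
  stopifnot(all(need %in% names(trials)))
  trials$p_x_cert <- trials$p_success * (1 - trials$unc_p)
  trials$dq_x_cert <- trials$dq_h5 * (1 - trials$unc_dq)
  trials$p_x_disc <- trials$p_success * trials$discrepancy
  trials$dq_x_disc <- trials$dq_h5 * trials$discrepancy
  trials
}

#' Fit a model space across participants
#'
#' Fits every model in \code{specs} separately to every participant's
#' valid trials and collects the per-participant BIC evidence matrix —
#' the interchange format consumed by \code{\link{bms}} and
#' \code{\link{lgbf}}.
#'
#' @param trials trial table with a \code{participant} column, a binary
#'   \code{choice} and the predictor columns.
#' @param specs list of predictor-name vectors (see
#'   \code{\link{choice_model_space}}).
#' @param standardize,ridge passed to \code{\link{fit_choice}}.
#' @param keep_fits keep the individual \code{choice_fit} objects.
#' @return an object of class \code{"choice_evidence"}: a list with the
#'   BIC matrix \code{bic} (participants x models), the matching
#'   log-evidence approximation \code{log_evidence = -bic / 2}, specs,
#'   and (optionally) fits.
#' @export
fit_choice_models <- function(trials, specs, standardize = TRUE,
                              ridge = 1e-6, keep_fits = FALSE) {
  if (!is.list(specs)) specs <- list(specs)
  ids <- unique(trials$participant)
  bic <- matrix(NA_real_, length(ids), length(specs),
                dimnames = list(ids, names(specs)))
  fits <- if (keep_fits) vector("list", length(ids)) else NULL
  for (i in seq_along(ids)) {
    d <- trials[trials$participant == ids[i] & trials$valid %in% TRUE, ]
    pf <- lapply(specs, function(sp)
      fit_choice(d, sp, standardize = standardize, ridge = ridge))
    bic[i, ] <- vapply(pf, function(f) f$bic, 0)
    if (keep_fits) fits[[i]] <- pf
  }
  if (keep_fits) names(fits) <- ids
  structure(list(bic = bic, log_evidence = -bic / 2, specs = specs,
                 participants = ids, fits = fits),
            class = "choice_evidence")
}

#' @export
print.choice_evidence <- function(x, ...) {
  cat(sprintf("choice-model evidence: %d participants x %d models\n",
              nrow(x$bic), ncol(x$bic)))
  s <- colSums(x$bic)
  best <- which.min(s)
  cat(sprintf("lowest group BIC: %s\n", colnames(x$bic)[best]))
  invisible(x)
}

#' Posterior predictive check of choice models
#'
#' Bins the trials by one variable and compares, per bin, the observed
#' proportion of forage choices with the model-predicted proportion
#' (each participant's predicted choice probabilities under their own
#' fit, averaged across participants — the exact expectation of the
#' simulation-based check).
#'
#' @param fits named list (by participant) of \code{choice_fit} objects
#'   for one model, or a \code{choice_evidence} with \code{keep_fits}
#'   and a \code{model} name/index.
#' @param trials trial table (valid trials).
#' @param bin_variable column to bin by.
#' @param n_bins number of bins; if the variable has at most
#'   \code{n_bins} distinct values its values are used directly.
#' @param model model name or index when \code{fits} is a
#'   \code{choice_evidence}.
#' @return an object of class \code{"choice_ppc"}: a data frame with
#'   per-bin midpoints, observed and predicted forage proportions, SEM
#'   over participants and trial counts.
#' @export
posterior_predictive <- function(fits, trials, bin_variable,
                                 n_bins = 9, model = 1) {
  if (inherits(fits, "choice_evidence")) {
    stopifnot(!is.null(fits$fits))
    fits <- lapply(fits$fits, `[[`, model)
  }
  trials <- trials[trials$valid %in% TRUE, ]
  x <- trials[[bin_variable]]
  ux <- sort(unique(x[!is.na(x)]))
  if (length(ux) <= n_bins) {
    bin <- match(x, ux)
    mids <- ux
  } else {
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out =
                                                  n_bins + 1), na.rm = TRUE))
    bin <- cut(x, br, include.lowest = TRUE, labels = FALSE)
    mids <- (br[-1] + br[-length(br)]) / 2
  }
  pred <- rep(NA_real_, nrow(trials))
  for (id in names(fits)) {
    i <- trials$participant == id
    if (any(i)) pred[i] <- predict(fits[[id]], trials[i, , drop = FALSE])
  }
  agg <- function(v) {
    pm <- tapply(v, list(trials$participant, bin), mean, na.rm = TRUE)
    list(mean = colMeans(pm, na.rm = TRUE),
         sem = apply(pm, 2, stats::sd, na.rm = TRUE) /
           sqrt(colSums(!is.na(pm))))
  }
  o <- agg(trials$choice)
  p <- agg(pred)
  keep <- as.integer(names(o$mean))
  out <- data.frame(bin = mids[keep], observed = o$mean,
                    obs_sem = o$sem, predicted = p$mean,
                    pred_sem = p$sem,
                    n = as.vector(table(factor(bin, levels = keep))))
  structure(out, class = c("choice_ppc", "data.frame"),
            bin_variable = bin_variable)
}

#' @export
plot.choice_ppc <- function(x, ...) {
  graphics::plot(x$bin, x$observed, ylim = c(0, 1), pch = 19,
                 xlab = attr(x, "bin_variable"),
                 ylab = "proportion forage", ...)
  graphics::arrows(x$bin, x$observed - x$obs_sem,
                   x$bin, x$observed + x$obs_sem,
                   angle = 90, code = 3, length = 0.03)
  graphics::lines(x$bin, x$predicted, col = "red3")
  graphics::points(x$bin, x$predicted, col = "red3", pch = 4)
  invisible(x)
}
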