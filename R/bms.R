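# Group-level model comparison: fixed-effects log group Bayes factors
# and random-effects Bayesian model selection (variational Dirichlet
# scheme) with exceedance probabilities, Bayesian omnibus risk and
# protected exceedance probabilities.

#' Fixed-effects log group Bayes factors
#'
#' Per-model log group Bayes factor relative to a reference model,
#' approximating each participant-level log evidence by -BIC/2 and
#' summing across participants: \code{LGBF_m = 0.5 * sum_i(BIC_ref,i -
#' BIC_m,i)}.
#'
#' @param bic participants x models BIC matrix (or a
#'   \code{choice_evidence}).
#' @param ref reference model index or name (default the first column).
#' @return named numeric vector of log group Bayes factors; attribute
#'   \code{"decisive"} is \code{TRUE} when the best model beats the
#'   second-best by more than 3.
#' @export
lgbf <- function(bic, ref = 1) {
  if (inherits(bic, "choice_evidence")) bic <- bic$bic
  stopifnot(is.matrix(bic), !anyNA(bic))
  out <- 0.5 * colSums(bic[, ref] - bic)
  s <- sort(out, decreasing = TRUE)
  attr(out, "decisive") <- length(s) >= 2 && (s[1] - s[2]) > 3
  out
}

#' Random-effects Bayesian model selection
#'
#' Estimates the population frequencies of K candidate models from a
#' participants x models evidence matrix under a Dirichlet prior,
#' using the standard variational scheme: iterate model
#' responsibilities \code{u_ik ~ exp(logev_ik + digamma(alpha_k) -
#' digamma(sum alpha))} (normalized per participant) and \code{alpha_k =
#' alpha0 + sum_i u_ik} to convergence. Exceedance probabilities (EP)
#' are computed by Monte-Carlo sampling of the Dirichlet posterior; the
#' Bayesian omnibus risk (BOR) compares the variational free energy of
#' the frequency model against the equal-frequency null; protected
#' exceedance probabilities follow the identity \code{PEP_k = EP_k (1 -
#' BOR) + BOR / K}.
#'
#' @param evidence participants x models matrix of log model evidences,
#'   a BIC matrix with \code{type = "bic"} (converted as -BIC/2), or a
#'   \code{choice_evidence} object.
#' @param type \code{"logev"} or \code{"bic"}.
#' @param alpha0 Dirichlet prior count (default 1, uniform).
#' @param n_samples Monte-Carlo samples for the EPs (default 1e6,
#'   drawn in bounded-memory chunks).
#' @param tol convergence tolerance on the alpha vector.
#' @param max_iter iteration cap; non-convergence is flagged.
#' @param seed RNG seed for the Monte-Carlo step.
#' @return an object of class \code{"bms"} with \code{alpha} (Dirichlet
#'   posterior), \code{exp_r} (expected frequencies), \code{ep},
#'   \code{bor}, \code{pep}, \code{u} (responsibilities), free energies
#'   \code{F1}/\code{F0}, and a convergence flag.
#' @export
bms <- function(evidence, type = c("logev", "bic"), alpha0 = 1,
                n_samples = 1e6, tol = 1e-8, max_iter = 500,
                seed = NULL) {
  type <- match.arg(type)
  if (inherits(evidence, "choice_evidence")) {
    evidence <- evidence$log_evidence
    type <- "logev"
  }
  stopifnot(is.matrix(evidence), !anyNA(evidence), ncol(evidence) >= 2)
  L <- if (type == "bic") -evidence / 2 else evidence
  N <- nrow(L); K <- ncol(L)
  L <- L - apply(L, 1, max) # per-participant shift, cancels in u
  alpha <- rep(alpha0, K)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lw <- sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lw <- lw - apply(lw, 1, max)
    u <- exp(lw)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  names(alpha) <- colnames(L)
  ep <- dirichlet_exceedance(alpha, n_samples, seed = seed)
  # variational free energy of the random-effects model
  elog_r <- digamma(alpha) - digamma(sum(alpha))
  F1 <- sum(u * L) + sum(u %*% elog_r) +
    (lgamma(K * alpha0) - K * lgamma(alpha0) +
       sum((alpha0 - 1) * elog_r)) -
    (lgamma(sum(alpha)) - sum(lgamma(alpha)) +
       sum((alpha - 1) * elog_r)) -
    sum(u * log(pmax(u, 1e-300)))
  # null model: fixed equal frequencies 1/K
  F0 <- sum(apply(L, 1, function(l) log(mean(exp(l)))))
  bor <- 1 / (1 + exp(F1 - F0))
  pep <- ep * (1 - bor) + bor / K
  structure(list(alpha = alpha, exp_r = alpha / sum(alpha), ep = ep,
                 bor = bor, pep = pep, u = u, F1 = F1, F0 = F0,
                 K = K, n = N, alpha0 = alpha0, converged = converged,
                 n_samples = n_samples, seed = seed),
            class = "bms")
}

# Monte-Carlo exceedance probabilities of a Dirichlet distribution,
# sampled in chunks to bound memory at large K * n_samples
dirichlet_exceedance <- function(alpha, n_samples = 1e6,
                                 chunk = 1e5, seed = NULL) {
  K <- length(alpha)
  with_seed(seed, {
    wins <- numeric(K)
    done <- 0
    while (done < n_samples) {
      m <- min(chunk, n_samples - done)
      g <- matrix(stats::rgamma(m * K, shape = rep(alpha, each = m)),
                  m, K)
      w <- max.col(g)
      wins <- wins + tabulate(w, K)
      done <- done + m
    }
    stats::setNames(wins / n_samples, names(alpha))
  })
}

#' @export
print.bms <- function(x, ...) {
  cat(sprintf(
    "random-effects BMS: %d models, %d participants (BOR %.3f)\n",
    x$K, x$n, x$bor))
  tab <- rbind(`expected freq` = x$exp_r, EP = x$ep, PEP = x$pep)
  print(round(tab, 3))
  if (!x$converged) cat("warning: variational update did not converge\n")
  invisible(x)
}

#' @export
summary.bms <- function(object, ...) {
  best <- which.max(object$pep)
  cat(sprintf("winning model: %s (PEP = %.3f, EP = %.3f, BOR = %.3f)\n",
              names(object$alpha)[best] %||% best,
              object$pep[best], object$ep[best], object$bor))
  invisible(object)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
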