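# Conditional logistic likelihood machinery for 1:1 matched strata.
#
# With each stratum reduced to its case-minus-control difference z_i, the
# conditional log-likelihood is
#   l(beta) = sum_i w_i [ z_i beta - log(1 + exp(z_i beta)) ]
# with per-stratum importance weights w_i (all 1 for an unweighted fit).
# mu_i = plogis(z_i beta) is the fitted probability of observing the case
# pattern in stratum i; the score is Z' diag(w) (1 - mu) and the Hessian
# -Z' diag(w * mu(1-mu)) Z.

#' Conditional logistic log-likelihood
#'
#' @param diff a [diff_data()] object (or a vector/matrix of differences).
#' @param beta coefficient vector, length `ncol(z)`.
#' @param weights optional nonnegative per-stratum importance weights.
#' @return The (weighted) conditional log-likelihood.
#' @export
clr_loglik <- function(diff, beta, weights = NULL) {
  diff <- as_diff(diff)
  z <- diff$z
  if (length(beta) != ncol(z))
    stop("beta has length ", length(beta), " but z has ", ncol(z), " column(s)")
  w <- check_weights(weights, nrow(z))
  eta <- drop(z %*% beta)
  # log(1+exp(eta)) via log1p, guarded against overflow for large |eta|
  sum(w * (eta - softplus(eta)))
}

softplus <- function(eta) {
  out <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
  out
}

check_weights <- function(weights, n) {
  if (is.null(weights)) return(rep(1, n))
  if (length(weights) != n) stop("weights length must equal the number of strata")
  if (any(weights < 0)) stop("weights must be nonnegative")
  as.numeric(weights)
}

#' Score and Hessian of the conditional likelihood
#'
#' @inheritParams clr_loglik
#' @return A `clr_workspace` list: `mu` (per-stratum case-pattern
#'   probability), `w` (`mu * (1 - mu)`, the diagonal of W), `score`,
#'   `hessian` and `loglik`, all at `beta`.
#' @export
clr_score_hessian <- function(diff, beta, weights = NULL) {
  diff <- as_diff(diff)
  z <- diff$z
  if (length(beta) != ncol(z))
    stop("beta has length ", length(beta), " but z has ", ncol(z), " column(s)")
  if (any(!is.finite(beta))) stop("non-finite beta")
  wts <- check_weights(weights, nrow(z))
  eta <- drop(z %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  score <- drop(crossprod(z, wts * (1 - mu)))
  hessian <- -crossprod(z, (wts * w) * z)
  structure(list(mu = mu, w = w, score = score, hessian = hessian,
                 loglik = sum(wts * (eta - softplus(eta)))),
            class = "clr_workspace")
}

#' Fit conditional logistic regression by Newton-Raphson
#'
#' Maximizes the (weighted) conditional log-likelihood with step-halving.
#' Convergence is declared when the log-likelihood changes by less than
#' `tol`. A fit drifting beyond `|beta| > beta_bound` while the likelihood is
#' still improving is flagged as non-converged (quasi-separation: the
#' conditional likelihood has no finite maximum when all nonzero differences
#' share a sign).
#'
#' @inheritParams clr_loglik
#' @param tol absolute log-likelihood convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @param beta_init starting value (default 0).
#' @param beta_bound separation guard on each coefficient.
#' @return A `clr_fit`: `beta`, `se` (from the observed information),
#'   `loglik`, `iterations`, `converged`, `p_wald`, plus the final `hessian`.
#' @export
fit_clr <- function(diff, weights = NULL, tol = 1e-10, max_iter = 50,
                    beta_init = NULL, beta_bound = 15) {
  diff <- as_diff(diff)
  z <- diff$z
  p <- ncol(z)
  wts <- check_weights(weights, nrow(z))
  active <- wts > 0
  if (all(z[active, , drop = FALSE] == 0))
    stop("degenerate input: all case-control differences are zero")
  beta <- if (is.null(beta_init)) rep(0, p) else rep_len(beta_init, p)
  ws <- clr_score_hessian(diff, beta, wts)
  ll <- ws$loglik
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(ws$hessian, ws$score),
                     error = function(e) NULL)
    if (is.null(step)) break  # singular information
    step <- -step
    # step-halving on the likelihood
    lambda <- 1
    for (h in seq_len(21)) {
      cand <- beta + lambda * step
      ws_new <- clr_score_hessian(diff, cand, wts)
      if (is.finite(ws_new$loglik) && ws_new$loglik >= ll - 1e-14) break
      lambda <- lambda / 2
    }
    delta <- ws_new$loglik - ll
    beta <- cand
    ws <- ws_new
    ll <- ws_new$loglik
    if (any(abs(beta) > beta_bound)) break  # separation guard
    if (abs(delta) < tol) {
      converged <- TRUE
      break
    }
  }
  info <- -ws$hessian
  se <- rep(NA_real_, p)
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (!is.null(cov)) se <- sqrt(pmax(diag(as.matrix(cov)), 0))
  fit <- structure(list(beta = beta, se = se, loglik = ll,
                        iterations = iter, converged = converged,
                        hessian = ws$hessian, n0 = nrow(z)),
                   class = "clr_fit")
  fit$p_wald <- if (converged && all(is.finite(se)) && all(se > 0))
    wald_p(fit) else NA_real_
  fit
}

#' @method print clr_fit
#' @export
print.clr_fit <- function(x, ...) {
  cat("clr_fit:", x$n0, "strata; beta =", format(x$beta, digits = 4),
      "(se", format(x$se, digits = 4), ")",
      if (x$converged) "" else "[NOT CONVERGED]", "\n")
  cat("  loglik =", format(x$loglik, digits = 8),
      " Wald p =", format(x$p_wald, digits = 4), "\n")
  invisible(x)
}

#' Two-sided Wald p-value
#'
#' `p = 2 * (1 - Phi(|beta / se|))`, the large-sample normal reference.
#'
#' @param fit a `clr_fit` (or any list with `beta` and `se`).
#' @return p-value(s) in \[0, 1\], one per coefficient.
#' @export
wald_p <- function(fit) {
  if (any(!is.finite(fit$se)) || any(fit$se <= 0))
    stop("standard error must be positive and finite")
  2 * stats::pnorm(-abs(fit$beta / fit$se))
}

#' Relevance p-value of an external dataset
#'
#' Homogeneity likelihood-ratio test of a common coefficient across the local
#' and one external dataset:
#' `LRT = 2 * (l_loc(b_loc) + l_ext(b_ext) - [l_loc + l_ext](b_pooled))`,
#' referred to a chi-squared distribution with `ncol(z)` degrees of freedom.
#' Large q (no detectable heterogeneity) marks a relevant external dataset.
#'
#' @param local,external [diff_data()] objects with the same covariates.
#' @param ... passed to [fit_clr()].
#' @return Upper-tail p-value q in \[0, 1\].
#' @export
relevance_pvalue <- function(local, external, ...) {
  local <- as_diff(local); external <- as_diff(external)
  if (ncol(local$z) != ncol(external$z)) stop("covariate dimension mismatch")
  f_loc <- fit_clr(local, ...)
  f_ext <- fit_clr(external, ...)
  pooled <- diff_data(rbind(local$z, external$z))
  f_pool <- fit_clr(pooled, ...)
  if (!f_loc$converged || !f_ext$converged || !f_pool$converged)
    stop("relevance test requires converged fits (separation in a dataset?)")
  lrt <- 2 * (f_loc$loglik + f_ext$loglik - f_pool$loglik)
  lrt <- max(lrt, 0)
  stats::pchisq(lrt, df = ncol(local$z), lower.tail = FALSE)
}
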