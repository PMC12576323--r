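# Asymmetric integration of auxiliary matched cohorts into a local
# conditional logistic fit.
#
# Each external dataset k receives a weight omega_k in [0,1]; the weighted
# fit maximizes l_0(beta) + sum_k omega_k l_k(beta). Rather than optimizing
# all K weights, per-dataset relevance p-values q_k are mapped to weights
# through a two-knot piecewise-linear map (qa, qb), and the pair (qa, qb) is
# chosen to minimize the local leave-one-stratum-out cross-validated
# negative log-likelihood, approximated by a one-step Newton update.

#' Piecewise-linear weight map
#'
#' Maps relevance p-values q to integration weights:
#' `0` for `q <= qa`, `(q - qa)/(qb - qa)` for `qa < q <= qb`, `1` for
#' `q > qb`. The degenerate knot `qa == qb` acts as the step `1{q > qa}`.
#'
#' @param q vector of relevance p-values in \[0, 1\].
#' @param qa,qb knots with `0 <= qa <= qb <= 1`.
#' @return Weight vector omega, elementwise in \[0, 1\].
#' @export
map_weights <- function(q, qa, qb) {
  if (!(is.finite(qa) && is.finite(qb) && qa >= 0 && qa <= qb && qb <= 1))
    stop("invalid weight map: need 0 <= qa <= qb <= 1")
  if (any(q < 0 | q > 1)) stop("relevance p-values must lie in [0, 1]")
  omega <- numeric(length(q))
  omega[q > qb] <- 1
  mid <- q > qa & q <= qb
  if (qb > qa) omega[mid] <- (q[mid] - qa) / (qb - qa)
  omega
}

#' Weighted conditional logistic fit across cohorts
#'
#' Maximizes `l_local(beta) + sum_k omega_k * l_k(beta)`. Local strata always
#' carry weight 1; with all `omega = 0` this is exactly the local fit, and
#' with all `omega = 1` the pooled fit.
#'
#' @param local [diff_data()] for the primary cohort.
#' @param externals list of [diff_data()] for the auxiliary cohorts.
#' @param omega weights, one per external, each in \[0, 1\].
#' @param ... passed to [fit_clr()].
#' @return A `clr_fit` for the integrated estimate.
#' @export
weighted_fit <- function(local, externals = list(), omega = numeric(0), ...) {
  local <- as_diff(local)
  externals <- lapply(externals, as_diff)
  if (length(omega) != length(externals))
    stop("need one weight per external dataset")
  if (any(omega < 0 | omega > 1)) stop("weights must lie in [0, 1]")
  # zero-weight externals contribute nothing; dropping them keeps the
  # omega = 0 case bit-identical to the local-only fit
  keep <- omega > 0
  externals <- externals[keep]
  omega <- omega[keep]
  z <- do.call(rbind, c(list(local$z), lapply(externals, `[[`, "z")))
  w <- c(rep(1, local$n0),
         unlist(mapply(function(d, o) rep(o, d$n0), externals, omega,
                       SIMPLIFY = FALSE), use.names = FALSE))
  fit <- fit_clr(diff_data(z), weights = w, ...)
  fit$n_local <- local$n0
  fit
}

#' One-step leave-one-stratum-out estimates
#'
#' For each local stratum j, approximates the estimate refitted without that
#' stratum by a single Newton step from the full weighted fit:
#' `beta_loo_j = beta_hat - A^{-1} z_j' (1 - mu_j) / (1 - v_jj)` where
#' `A = Z0'W0Z0 + sum_k omega_k Zk'WkZk` is the weighted observed information
#' and `v_jj` the j-th diagonal of the hat-type matrix
#' `W0^{1/2} Z0 A^{-1} Z0' W0^{1/2}` (the stratum's leverage).
#'
#' @inheritParams weighted_fit
#' @param fit the converged `clr_fit` from [weighted_fit()].
#' @return A `loo_state` list: `v_diag` (leverages, each in \[0, 1)) and
#'   `beta_loo` (n0 x p matrix of one-step leave-one-out estimates).
#' @export
loo_onestep <- function(local, externals = list(), omega = numeric(0), fit) {
  local <- as_diff(local)
  externals <- lapply(externals, as_diff)
  if (!isTRUE(fit$converged)) stop("one-step LOO requires a converged fit")
  beta <- fit$beta
  z0 <- local$z
  ws0 <- clr_score_hessian(local, beta)
  a_mat <- -ws0$hessian
  if (length(externals)) {
    for (k in seq_along(externals)) {
      if (omega[k] == 0) next
      a_mat <- a_mat - omega[k] * clr_score_hessian(externals[[k]], beta)$hessian
    }
  }
  a_inv <- solve(a_mat)
  za <- z0 %*% a_inv                      # n0 x p
  v_diag <- ws0$w * rowSums(za * z0)      # w_j * z_j A^-1 z_j'
  if (any(v_diag >= 1))
    stop("leverage >= 1: stratum ", which(v_diag >= 1)[1],
         " dominates the weighted fit")
  resid <- (1 - ws0$mu) / (1 - v_diag)
  beta_loo <- matrix(beta, nrow = nrow(z0), ncol = length(beta), byrow = TRUE) -
    za * resid
  structure(list(v_diag = v_diag, beta_loo = beta_loo),
            class = "loo_state")
}

# Exact leave-one-out refits (n0 x p matrix); test/reference path for the
# one-step formula.
loo_exact <- function(local, externals = list(), omega = numeric(0), ...) {
  local <- as_diff(local)
  p <- ncol(local$z)
  out <- vapply(seq_len(local$n0), function(j) {
    loc_j <- diff_data(local$z[-j, , drop = FALSE])
    weighted_fit(loc_j, externals, omega, ...)$beta
  }, numeric(p))
  if (p == 1) matrix(out, ncol = 1) else t(out)
}

#' Negative LOOCV log-likelihood of a weight map
#'
#' Applies the (qa, qb) map to the relevance p-values, refits the weighted
#' model, and returns `-sum_j l_j(beta_loo_j)`: each local stratum's
#' conditional log-likelihood contribution evaluated at the estimate fitted
#' (one-step-approximately, or exactly with `exact = TRUE`) without it.
#'
#' @inheritParams weighted_fit
#' @param q relevance p-values, one per external.
#' @param qa,qb weight-map knots, `0 <= qa <= qb <= 1`.
#' @param exact use exact per-stratum refits instead of the one-step
#'   approximation (slow; reference mode).
#' @return The objective value, with the weighted `clr_fit` attached as
#'   attribute `"fit"` and the weights as `"omega"`.
#' @export
cv_objective <- function(local, externals = list(), q = numeric(0), qa, qb,
                         exact = FALSE, ...) {
  local <- as_diff(local)
  omega <- map_weights(q, qa, qb)
  fit <- weighted_fit(local, externals, omega, ...)
  if (!fit$converged) return(structure(Inf, fit = fit, omega = omega))
  beta_loo <- if (exact) loo_exact(local, externals, omega, ...)
  else loo_onestep(local, externals, omega, fit)$beta_loo
  eta <- rowSums(local$z * beta_loo)
  obj <- -sum(eta - softplus(eta))
  structure(obj, fit = fit, omega = omega)
}

#' Choose the weight map by LOOCV
#'
#' Minimizes [cv_objective()] over the knots under `0 <= qa <= qb <= 1`,
#' using the smooth reparameterization `qa = a`, `qb = a + (1 - a) b` with
#' `(a, b)` in the unit box, L-BFGS-B with forward-difference gradients, and
#' multiple starts on a 3x3 grid plus the all-weights-zero corner `(1, 1)`
#' (so the selected objective never exceeds the local-only objective among
#' evaluated candidates).
#'
#' @inheritParams cv_objective
#' @param starts matrix of (a, b) starting points; default
#'   `{0.05, 0.5, 0.95}^2` plus `(1, 1)`.
#' @return An `integration_result`: `q`, `qa`, `qb`, `omega`, `fit` (the
#'   weighted `clr_fit`), `cv_objective`, `p_integrated`.
#' @export
optimize_map <- function(local, externals = list(), q = numeric(0),
                         starts = NULL, ...) {
  local <- as_diff(local)
  if (length(q) != length(externals))
    stop("need one relevance p-value per external dataset")
  if (length(externals) == 0) {
    obj <- cv_objective(local, qa = 1, qb = 1, ...)
    fit <- attr(obj, "fit")
    return(structure(list(q = q, qa = 1, qb = 1, omega = numeric(0),
                          fit = fit, cv_objective = as.numeric(obj),
                          p_integrated = fit$p_wald),
                     class = "integration_result"))
  }
  if (is.null(starts)) {
    g <- c(0.05, 0.5, 0.95)
    starts <- rbind(as.matrix(expand.grid(a = g, b = g)), c(1, 1))
  }
  # many (qa, qb) induce the same omega; cache objective values by omega
  cache <- new.env(parent = emptyenv())
  eval_omega <- function(omega) {
    key <- paste(signif(omega, 12), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    fit <- weighted_fit(local, externals, omega, ...)
    val <- if (!fit$converged) Inf else {
      beta_loo <- loo_onestep(local, externals, omega, fit)$beta_loo
      eta <- rowSums(local$z * beta_loo)
      -sum(eta - softplus(eta))
    }
    out <- list(value = val, fit = fit, omega = omega)
    cache[[key]] <- out
    out
  }
  fn <- function(par) {
    a <- min(max(par[1], 0), 1); b <- min(max(par[2], 0), 1)
    eval_omega(map_weights(q, a, a + (1 - a) * b))$value
  }
  best <- NULL
  failures <- character(0)
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[s, ], fn, method = "L-BFGS-B", lower = 0, upper = 1,
                   control = list(ndeps = c(1e-4, 1e-4))),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
      next
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("weight-map optimization failed from every start: ",
         paste(unique(failures), collapse = "; "))
  a <- min(max(best$par[1], 0), 1); b <- min(max(best$par[2], 0), 1)
  qa <- a; qb <- a + (1 - a) * b
  sel <- eval_omega(map_weights(q, qa, qb))
  structure(list(q = q, qa = qa, qb = qb, omega = sel$omega, fit = sel$fit,
                 cv_objective = sel$value, p_integrated = sel$fit$p_wald),
            class = "integration_result")
}

#' @method print integration_result
#' @export
print.integration_result <- function(x, ...) {
  cat("integration_result: K =", length(x$omega), "externals\n")
  cat("  knots (qa, qb) = (", format(x$qa, digits = 4), ",",
      format(x$qb, digits = 4), ")\n")
  if (length(x$omega))
    cat("  omega =", paste(format(x$omega, digits = 3), collapse = " "), "\n")
  cat("  beta_int =", format(x$fit$beta, digits = 4),
      " p_int =", format(x$p_integrated, digits = 4),
      " LOOCV objective =", format(x$cv_objective, digits = 8), "\n")
  invisible(x)
}

#' Per-variant association with optional integration
#'
#' The per-variant pipeline: fit the non-integrated local conditional
#' logistic model; when its Wald p-value passes the prescreen
#' (`p < prescreen_alpha`), compute a relevance p-value against every other
#' cohort, optimize the weight map, and record the integrated fit. Variants
#' failing the prescreen keep their local result with integration skipped.
#'
#' @param variant variant column index or id.
#' @param cohorts named list of [matched_cohort()] objects.
#' @param local_label name of the primary cohort within `cohorts`.
#' @param dosages [dosage_matrix()] holding every sample.
#' @param prescreen_alpha integration prescreen level on the local Wald p.
#' @param ... passed to [fit_clr()].
#' @return One-row data frame: variant annotation, local fit
#'   (`beta_local`, `se_local`, `p_local`), `skipped`, knots, one
#'   `omega_<cohort>` column per external, and the integrated fit
#'   (`beta_int`, `se_int`, `p_int`). Local separation yields `NA` p-values
#'   and `failed = TRUE` (excluded from downstream FDR input).
#' @export
integrate_variant <- function(variant, cohorts, local_label, dosages,
                              prescreen_alpha = 0.05, ...) {
  if (!local_label %in% names(cohorts))
    stop("unknown local cohort: ", local_label)
  ext_labels <- setdiff(names(cohorts), local_label)
  vrec <- dosages$variants[match_variant(dosages, variant), ]
  base <- data.frame(variant_id = vrec$id, chrom = vrec$chrom, pos = vrec$pos,
                     maf = vrec$maf, stringsAsFactors = FALSE)
  empty_int <- function(skipped, failed = FALSE, beta = NA_real_,
                        se = NA_real_, p = NA_real_, qa = NA_real_,
                        qb = NA_real_, omega = rep(NA_real_, length(ext_labels)),
                        cvo = NA_real_) {
    out <- data.frame(skipped = skipped, failed = failed, qa = qa, qb = qb,
                      beta_int = beta, se_int = se, p_int = p,
                      cv_objective = cvo)
    for (i in seq_along(ext_labels))
      out[[paste0("omega_", ext_labels[i])]] <- omega[i]
    out
  }
  local <- build_differences(cohorts[[local_label]], dosages, variant)
  f_loc <- tryCatch(fit_clr(local, ...), error = function(e) NULL)
  if (is.null(f_loc) || !f_loc$converged)
    return(cbind(base, beta_local = NA_real_, se_local = NA_real_,
                 p_local = NA_real_, empty_int(TRUE, failed = TRUE)))
  loc_cols <- data.frame(beta_local = f_loc$beta, se_local = f_loc$se,
                         p_local = f_loc$p_wald)
  if (f_loc$p_wald >= prescreen_alpha)
    return(cbind(base, loc_cols, empty_int(TRUE)))
  externals <- list(); q <- numeric(0); kept <- character(0)
  for (lab in ext_labels) {
    ext <- build_differences(cohorts[[lab]], dosages, variant)
    qk <- tryCatch(relevance_pvalue(local, ext, ...), error = function(e) NA_real_)
    if (is.na(qk)) next  # external unusable (separation): force omega 0
    externals <- c(externals, list(ext)); q <- c(q, qk); kept <- c(kept, lab)
  }
  res <- optimize_map(local, externals, q, ...)
  omega_full <- rep(0, length(ext_labels))
  names(omega_full) <- ext_labels
  omega_full[kept] <- res$omega
  cbind(base, loc_cols,
        empty_int(FALSE, beta = res$fit$beta, se = res$fit$se,
                  p = res$p_integrated, qa = res$qa, qb = res$qb,
                  omega = omega_full, cvo = res$cv_objective))
}

match_variant <- function(dosages, variant) {
  if (is.character(variant)) {
    i <- match(variant, dosages$variants$id)
    if (is.na(i)) stop("unknown variant: ", variant)
    i
  } else as.integer(variant)
}
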