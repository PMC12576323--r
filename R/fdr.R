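# Permutation-based FDR control.
#
# Adaptive integration weights make the integrated Wald p-values
# anti-conservative under the null, and linkage disequilibrium correlates
# the tests, so rank-based procedures such as Benjamini-Hochberg do not
# apply. Instead, case-control labels are swapped within each stratum with
# probability 1/2 under ONE genome-wide plan per cohort (preserving the LD
# structure of the permuted statistics), the whole pipeline is re-run, and
# exceedance counts of observed versus permuted p-values give the FDR
# estimate.

#' Draw a within-stratum label-swap plan
#'
#' Each stratum is independently flagged for a case/control label exchange
#' with probability exactly 1/2, reproducibly from `seed`. Applying the plan
#' to difference data negates `z` exactly at the swapped strata.
#'
#' @param cohort a [matched_cohort()].
#' @param seed integer seed (mandatory; plans must be reproducible).
#' @return A `permutation_plan`: `seed` and logical `swap` of length `n0`.
#' @export
make_permutation <- function(cohort, seed) {
  stopifnot(inherits(cohort, "matched_cohort"), is.numeric(seed))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  swap <- stats::runif(cohort$n0) < 0.5
  structure(list(seed = as.integer(seed), swap = swap),
            class = "permutation_plan")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Apply a swap plan to a cohort
#'
#' @param cohort a [matched_cohort()].
#' @param plan a [make_permutation()] plan for this cohort.
#' @return A [matched_cohort()] with case and control labels exchanged at
#'   the flagged strata.
#' @export
apply_permutation <- function(cohort, plan) {
  stopifnot(inherits(cohort, "matched_cohort"),
            inherits(plan, "permutation_plan"),
            length(plan$swap) == cohort$n0)
  st <- cohort$strata
  sw <- plan$swap
  tmp <- st$case[sw]
  st$case[sw] <- st$control[sw]
  st$control[sw] <- tmp
  matched_cohort(cohort$label, st)
}

#' Permuted per-variant p-values
#'
#' Re-runs the identical per-variant pipeline (prescreen on the permuted
#' non-integrated p-value, relevance tests, weight optimization) after
#' applying one fixed swap plan per cohort. The plans are drawn once and
#' shared across all variants so the permuted statistics keep the
#' between-variant LD structure.
#'
#' @param variants vector of variant indices or ids to analyze.
#' @param cohorts named list of [matched_cohort()] objects.
#' @param plans named list of [make_permutation()] plans, one per cohort.
#' @param local_label the primary cohort.
#' @param dosages [dosage_matrix()].
#' @param ... passed to [integrate_variant()].
#' @return The per-variant results table of [integrate_variant()], computed
#'   on the permuted labels.
#' @export
permuted_pvalues <- function(variants, cohorts, plans, local_label, dosages,
                             ...) {
  if (!all(names(cohorts) %in% names(plans)))
    stop("need one permutation plan per cohort")
  perm <- lapply(names(cohorts), function(lab)
    apply_permutation(cohorts[[lab]], plans[[lab]]))
  names(perm) <- names(cohorts)
  do.call(rbind, lapply(variants, integrate_variant, cohorts = perm,
                        local_label = local_label, dosages = dosages, ...))
}

#' Single-iteration permutation FDR estimates
#'
#' With observed p-values sorted ascending (p_1 <= p_2 <= ...), let
#' `m_i = #\{p in observed : p <= p_i\}` and
#' `m_i* = #\{p* in permuted : p* <= p_i\}`; the raw estimate is
#' `min(m_i*/m_i, 1)`, made monotone nondecreasing in i by replacing it with
#' the minimum over all larger thresholds (`min over j >= i`). Ties are
#' counted with `<=` on both sets. FDR is estimated within one cohort's
#' result set at a time; never pool across local cohorts.
#'
#' @param observed,permuted nonempty numeric p-value vectors; `observed` may
#'   be named by variant.
#' @return An `fdr_table` data frame sorted by p: `variant_id` (names, if
#'   any), `p`, `m`, `m_star`, `fdr_raw`, `fdr`.
#' @export
estimate_fdr <- function(observed, permuted) {
  estimate_fdr_multi(observed, list(permuted))
}

#' Multi-iteration permutation FDR estimates
#'
#' As [estimate_fdr()] but with the permuted exceedance count `m_i*`
#' replaced by its average over `B` independent permuted sets, which
#' stabilizes the estimate (single-iteration FDR control is liberal).
#'
#' @param observed nonempty numeric p-value vector, optionally named.
#' @param permuted_sets list of `B >= 1` permuted p-value vectors.
#' @return An `fdr_table` data frame; see [estimate_fdr()].
#' @export
estimate_fdr_multi <- function(observed, permuted_sets) {
  observed <- observed[!is.na(observed)]
  if (!length(observed)) stop("no observed p-values")
  if (!is.list(permuted_sets) || !length(permuted_sets))
    stop("need at least one permuted p-value set")
  permuted_sets <- lapply(permuted_sets, function(p) sort(p[!is.na(p)]))
  if (any(!lengths(permuted_sets))) stop("empty permuted p-value set")
  ord <- order(observed)
  p_sorted <- observed[ord]
  n <- length(p_sorted)
  m <- findInterval(p_sorted, p_sorted)          # ties counted with <=
  m_star <- rowMeans(vapply(permuted_sets, function(ps)
    as.numeric(findInterval(p_sorted, ps)), numeric(n)))
  fdr_raw <- pmin(m_star / m, 1)
  fdr <- rev(cummin(rev(fdr_raw)))
  ids <- names(p_sorted)
  if (is.null(ids)) ids <- as.character(ord)
  structure(data.frame(variant_id = ids, p = as.numeric(p_sorted), m = m,
                       m_star = m_star, fdr_raw = fdr_raw, fdr = fdr,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("fdr_table", "data.frame"))
}
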