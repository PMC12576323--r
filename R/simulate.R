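# Multi-cohort matched case-control dosage simulator.
#
# Dosages are Binomial(2, f) allele counts plus truncated Gaussian
# imputation noise clipped to [0, 2] (well-imputed dosages cluster near
# 0/1/2). Within each stratum with member genotypes (g1, g2) and cohort
# effect beta, member 1 is labeled the case with probability
# exp(g1*beta) / (exp(g1*beta) + exp(g2*beta)) -- exactly the conditional
# likelihood's kernel, so the fitted CLR coefficient is consistent for the
# generating value. Effects may be shared across cohorts, heterogeneous, or
# null, one value per (variant, cohort).

# Stratum counts of the default cohort template (14 cancer-type-sized
# cohorts, 71--1964 strata).
DEFAULT_STRATA <- c(bladder = 554, brain = 334, breast = 1964,
                    esophageal = 168, head_neck = 670, kidney = 680,
                    leukemia = 71, liver = 260, lung = 394, ovarian = 158,
                    pancreatic = 233, prostate = 1079, sarcoma = 654,
                    stomach = 76)

#' Simulation configuration
#'
#' @param strata_per_cohort named integer vector of stratum counts, one per
#'   cohort; the default mirrors a 14-cohort cancer-registry template
#'   (71 to 1964 strata per cohort).
#' @param n_variants number of variants to simulate.
#' @param maf_range allele-frequency range; per-variant frequency is drawn
#'   uniformly from it (default (0.05, 0.5\], the common-variant range).
#' @param effects `n_variants x n_cohorts` matrix of true per-cohort
#'   log-odds ratios (rows may be constant for shared effects, varying for
#'   heterogeneous ones, zero for null). A scalar recycles; default 0.
#' @param dosage_noise_sd sd of the truncated Gaussian imputation noise
#'   added to the integer allele counts (default 0.05).
#' @param seed mandatory integer seed.
#' @return A `sim_config` list; `rng_kind` records the pinned generator.
#' @export
sim_config <- function(strata_per_cohort = DEFAULT_STRATA,
                       n_variants = 100,
                       maf_range = c(0.05, 0.5),
                       effects = 0,
                       dosage_noise_sd = 0.05,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is.null(names(strata_per_cohort)))
    names(strata_per_cohort) <- paste0("cohort", seq_along(strata_per_cohort))
  if (any(strata_per_cohort < 1)) stop("every cohort needs >= 1 stratum")
  if (!(maf_range[1] > 0 && maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2]))
    stop("maf_range must lie within (0, 0.5]")
  k <- length(strata_per_cohort)
  if (is.matrix(effects)) {
    if (!all(dim(effects) == c(n_variants, k)))
      stop("effects must be n_variants x n_cohorts")
  } else {
    effects <- matrix(effects, n_variants, k)
  }
  colnames(effects) <- names(strata_per_cohort)
  if (dosage_noise_sd < 0) stop("dosage_noise_sd must be >= 0")
  structure(list(strata_per_cohort = strata_per_cohort,
                 n_variants = as.integer(n_variants), maf_range = maf_range,
                 effects = effects, dosage_noise_sd = dosage_noise_sd,
                 seed = as.integer(seed),
                 rng_kind = c("Mersenne-Twister", "Inversion", "Rejection")),
            class = "sim_config")
}

#' Simulate matched multi-cohort dosage data
#'
#' @param config a [sim_config()].
#' @return List: `dosages` (a [dosage_matrix()]), `cohorts` (named list of
#'   [matched_cohort()]), `truth` (data frame `variant`, `cohort`,
#'   `beta_true`).
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  do.call(RNGkind, as.list(config$rng_kind))
  set.seed(config$seed)

  labels <- names(config$strata_per_cohort)
  n_str <- config$strata_per_cohort
  nv <- config$n_variants
  member_a <- unlist(lapply(labels, function(l)
    sprintf("%s_s%d_a", l, seq_len(n_str[[l]]))), use.names = FALSE)
  member_b <- sub("_a$", "_b", member_a)
  samples <- as.vector(rbind(member_a, member_b))
  n <- length(samples)

  f <- stats::runif(nv, config$maf_range[1], config$maf_range[2])
  values <- vapply(f, function(fj) stats::rbinom(n, 2, fj), numeric(n))
  if (config$dosage_noise_sd > 0)
    values <- values + matrix(stats::rnorm(n * nv, 0, config$dosage_noise_sd),
                              n, nv)
  values <- pmin(pmax(values, 0), 2)
  variants <- data.frame(chrom = "1",
                         pos = seq(1e5, by = 1e5, length.out = nv),
                         id = sprintf("v%d", seq_len(nv)),
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  rownames(values) <- samples
  colnames(values) <- variants$id
  dosages <- dosage_matrix(values, variants = variants)

  cohorts <- vector("list", length(labels))
  names(cohorts) <- labels
  offset <- 0L
  for (ci in seq_along(labels)) {
    ns <- n_str[[ci]]
    a_idx <- offset + 2L * seq_len(ns) - 1L
    b_idx <- a_idx + 1L
    # conditional-likelihood kernel on the (noisy) dosages actually analyzed
    lp <- drop((values[a_idx, , drop = FALSE] -
                  values[b_idx, , drop = FALSE]) %*% config$effects[, ci])
    a_is_case <- stats::runif(ns) < stats::plogis(lp)
    cohorts[[ci]] <- matched_cohort(labels[ci], data.frame(
      stratum_id = sprintf("%s_s%04d", labels[ci], seq_len(ns)),
      case = ifelse(a_is_case, samples[a_idx], samples[b_idx]),
      control = ifelse(a_is_case, samples[b_idx], samples[a_idx]),
      stringsAsFactors = FALSE))
    offset <- offset + 2L * ns
  }
  truth <- data.frame(variant = rep(variants$id, times = length(labels)),
                      cohort = rep(labels, each = nv),
                      beta_true = as.vector(config$effects),
                      stringsAsFactors = FALSE)
  list(dosages = dosages, cohorts = cohorts, truth = truth)
}

#' Simulate a global-null panel
#'
#' [simulate_cohorts()] with every effect forced to zero; used for size and
#' FDR-calibration checks.
#'
#' @param config a [sim_config()]; its `effects` are ignored.
#' @return As [simulate_cohorts()].
#' @export
simulate_null_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$effects[] <- 0
  simulate_cohorts(config)
}

#' Write a simulated dataset in the exchange formats the readers consume
#'
#' @param sim result of [simulate_cohorts()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written (`dosages`, `strata`,
#'   `truth`).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(dosages = file.path(dir, "dosages.vcf"),
             dosages_tsv = file.path(dir, "dosages.tsv"),
             strata = file.path(dir, "strata.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_dosages_vcf(sim$dosages, paths[["dosages"]])
  write_dosages_tsv(sim$dosages, paths[["dosages_tsv"]])
  write_strata(sim$cohorts, paths[["strata"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
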