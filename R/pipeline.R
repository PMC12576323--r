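# Whole-genome wiring: MAF filter -> per-variant CLR -> prescreened
# integration -> genome-wide permutation -> FDR -> clumping -> TSS
# enrichment.

#' Per-variant association scan for one local cohort
#'
#' Applies the common-variant filter, then runs [integrate_variant()] on
#' every retained variant with the remaining cohorts as auxiliaries.
#'
#' @param dosages [dosage_matrix()].
#' @param cohorts named list of [matched_cohort()] objects.
#' @param local_label the primary cohort.
#' @param maf_threshold common-variant MAF cutoff (strict `>`).
#' @param prescreen_alpha integration prescreen on the local Wald p.
#' @param ... passed to [fit_clr()].
#' @return Data frame with one row per common variant (see
#'   [integrate_variant()]).
#' @export
run_association <- function(dosages, cohorts, local_label,
                            maf_threshold = 0.05, prescreen_alpha = 0.05,
                            ...) {
  common <- filter_common(dosages, maf_threshold)
  if (nrow(common$variants) == 0)
    stop("no variant passes the MAF filter at ", maf_threshold)
  out <- do.call(rbind, lapply(seq_len(nrow(common$variants)),
                               integrate_variant, cohorts = cohorts,
                               local_label = local_label, dosages = common,
                               prescreen_alpha = prescreen_alpha, ...))
  rownames(out) <- NULL
  out
}

#' Permutation plans for every cohort
#'
#' One genome-wide plan per cohort (shared across variants, preserving LD in
#' the permuted statistics), with per-cohort seeds derived deterministically
#' from `seed`.
#'
#' @param cohorts named list of [matched_cohort()] objects.
#' @param seed base integer seed.
#' @param iteration permutation iteration index (1-based), offsetting the
#'   derived seeds so multi-iteration runs get independent plans.
#' @return Named list of [make_permutation()] plans.
#' @export
make_permutation_plans <- function(cohorts, seed, iteration = 1) {
  plans <- lapply(seq_along(cohorts), function(i)
    make_permutation(cohorts[[i]],
                     (seed + 7919L * iteration + i) %% .Machine$integer.max))
  names(plans) <- names(cohorts)
  plans
}

#' Permutation FDR for one association scan
#'
#' Runs `B` permuted replicates of the identical pipeline and estimates FDR
#' separately for the integrated p-values (prescreened variants only; these
#' p-values are anti-conservative and need the permutation reference) and
#' the non-integrated p-values (all variants), within this local cohort
#' only.
#'
#' @param observed result of [run_association()].
#' @param dosages,cohorts,local_label as in [run_association()].
#' @param seed base seed for the permutation plans.
#' @param B number of permutation iterations (default 1, the
#'   single-iteration procedure; larger B gives the more robust
#'   multi-iteration estimate).
#' @param maf_threshold,prescreen_alpha,... as in [run_association()].
#' @return List: `fdr_integrated` and `fdr_nonintegrated` ([estimate_fdr()]
#'   tables) and `permuted` (list of B permuted result tables).
#' @export
run_permutation_fdr <- function(observed, dosages, cohorts, local_label,
                                seed, B = 1, maf_threshold = 0.05,
                                prescreen_alpha = 0.05, ...) {
  common <- filter_common(dosages, maf_threshold)
  permuted <- lapply(seq_len(B), function(b) {
    plans <- make_permutation_plans(cohorts, seed, iteration = b)
    res <- permuted_pvalues(seq_len(nrow(common$variants)), cohorts, plans,
                            local_label, common,
                            prescreen_alpha = prescreen_alpha, ...)
    rownames(res) <- NULL
    res
  })
  pull <- function(res, col) stats::setNames(res[[col]], res$variant_id)
  obs_int <- pull(observed[!observed$skipped & !is.na(observed$p_int), ], "p_int")
  perm_int <- lapply(permuted, function(r)
    r$p_int[!r$skipped & !is.na(r$p_int)])
  obs_non <- pull(observed[!is.na(observed$p_local), ], "p_local")
  perm_non <- lapply(permuted, function(r) r$p_local[!is.na(r$p_local)])
  fdr_int <- if (length(obs_int) && all(lengths(perm_int) > 0))
    estimate_fdr_multi(obs_int, perm_int) else NULL
  fdr_non <- estimate_fdr_multi(obs_non, perm_non)
  list(fdr_integrated = fdr_int, fdr_nonintegrated = fdr_non,
       permuted = permuted)
}

#' Run configuration
#'
#' Reads a YAML run configuration, fills defaults, and applies overrides
#' (e.g. command-line flags). Threshold defaults: MAF 0.05, prescreen 0.05,
#' FDR report levels 0.05 and 0.1, clump r-squared 0.5, clump and TSS
#' windows 250 kb, one permutation iteration. `seed` has no default: every
#' stochastic run must name one.
#'
#' @param path YAML file, or `NULL` to start from defaults only.
#' @param overrides named list overriding file values.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(dosages = NULL, strata = NULL, tss = NULL, out_dir = ".",
              local = NULL, maf_threshold = 0.05, prescreen_alpha = 0.05,
              fdr_levels = c(0.05, 0.1), clump_r2 = 0.5,
              clump_window = 250000, tss_window = 250000,
              n_reference = 1000, permutations = 1, seed = NULL)
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    unknown <- setdiff(names(file_cfg), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(file_cfg)] <- file_cfg
  }
  overrides <- overrides[!vapply(overrides, is.null, TRUE)]
  cfg[names(overrides)] <- overrides
  stopifnot(cfg$maf_threshold > 0, cfg$maf_threshold < 1,
            cfg$prescreen_alpha > 0, cfg$prescreen_alpha < 1,
            all(cfg$fdr_levels > 0 & cfg$fdr_levels < 1),
            cfg$clump_r2 > 0, cfg$clump_r2 < 1,
            cfg$clump_window >= 1, cfg$tss_window >= 1,
            cfg$permutations >= 1)
  structure(cfg, class = "run_config")
}

#' Full analysis pipeline for one local cohort
#'
#' Chains the stages in order: read inputs, MAF filter, per-variant CLR with
#' prescreened integration, genome-wide permutation(s), per-cohort FDR for
#' integrated and non-integrated p-values, LD clumping of the significant
#' variants at each FDR report level, and (when a TSS annotation is given)
#' TSS-proximity enrichment of the significant integrated set. Writes
#' tab-separated outputs plus a manifest that suffices to reproduce the run.
#'
#' @param config a [read_run_config()] object with `dosages`, `strata`,
#'   `local` and `seed` set.
#' @return Invisibly, a list with every intermediate result and
#'   `files` (the paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$seed)) stop("config$seed is required")
  if (is.null(config$local)) stop("config$local (local cohort label) is required")
  dosages <- read_dosages(config$dosages)
  cohorts <- read_strata(config$strata, dosages)
  run_pipeline_objects(dosages, cohorts, config)
}

#' @rdname run_pipeline
#' @param dosages,cohorts in-memory inputs (bypassing the file readers).
#' @export
run_pipeline_objects <- function(dosages, cohorts, config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$seed)) stop("config$seed is required")
  local_label <- config$local
  if (!local_label %in% names(cohorts))
    stop("local cohort '", local_label, "' not in strata file")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(tab, name) {
    path <- file.path(config$out_dir, name)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[[name]] <<- path
    path
  }

  common <- filter_common(dosages, config$maf_threshold)
  observed <- run_association(dosages, cohorts, local_label,
                              maf_threshold = config$maf_threshold,
                              prescreen_alpha = config$prescreen_alpha)
  emit(observed, "results.tsv")
  counts <- c(total = nrow(dosages$variants), common = nrow(common$variants),
              prescreened = sum(!observed$skipped),
              failed = sum(observed$failed))

  fdr <- run_permutation_fdr(observed, dosages, cohorts, local_label,
                             seed = config$seed, B = config$permutations,
                             maf_threshold = config$maf_threshold,
                             prescreen_alpha = config$prescreen_alpha)
  for (b in seq_along(fdr$permuted))
    emit(fdr$permuted[[b]], sprintf("permuted_%d.tsv", b))
  long_fdr <- function(tab, method) if (!is.null(tab))
    data.frame(variant_id = tab$variant_id, p = tab$p, fdr = tab$fdr,
               method = method, cohort = local_label,
               stringsAsFactors = FALSE)
  fdr_long <- rbind(long_fdr(fdr$fdr_integrated, "integrated"),
                    long_fdr(fdr$fdr_nonintegrated, "non-integrated"))
  emit(fdr_long, "fdr.tsv")

  clumped <- list()
  can_clump <- !anyNA(common$variants$chrom) && !anyNA(common$variants$pos)
  if (!can_clump)
    message("no chrom/pos annotation (bare TSV input): reporting ",
            "significant variants without LD clumping")
  for (lev in config$fdr_levels) {
    for (method in c("integrated", "non-integrated")) {
      tab <- fdr_long[fdr_long$method == method & fdr_long$fdr <= lev, ,
                      drop = FALSE]
      if (!nrow(tab)) next
      hits <- merge(tab, observed[, c("variant_id", "chrom", "pos")],
                    by = "variant_id")
      cl <- if (can_clump)
        ld_clump(hits, common, r2_threshold = config$clump_r2,
                 window = config$clump_window)
      else hits[order(hits$p), , drop = FALSE]
      clumped[[paste(method, lev, sep = "_")]] <- cl
      emit(cl, sprintf("significant_%s_fdr%s.tsv", method, lev))
    }
  }

  enrichment <- NULL
  if (!is.null(config$tss)) {
    ann <- read_tss_bed(config$tss)
    key <- paste("integrated", max(config$fdr_levels), sep = "_")
    sig <- clumped[[key]]
    if (!is.null(sig) && nrow(sig) > 0) {
      enrichment <- tss_enrichment_analysis(
        sig, common, ann, n_reference = min(config$n_reference,
                                            nrow(common$variants)),
        seed = config$seed, window = config$tss_window)
      emit(data.frame(statistic = enrichment$statistic,
                      p_value = enrichment$p_value,
                      within_identified = enrichment$table[1, 1],
                      beyond_identified = enrichment$table[1, 2],
                      within_reference = enrichment$table[2, 1],
                      beyond_reference = enrichment$table[2, 2]),
           "tss_enrichment.tsv")
    }
  }

  manifest <- list(package = "asymclr",
                   version = as.character(utils::packageVersion("asymclr")),
                   r_version = R.version.string,
                   config = unclass(config),
                   counts = as.list(counts))
  manifest_path <- file.path(config$out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  files[["manifest.yaml"]] <- manifest_path

  message(sprintf(
    "[%s] variants: %d total, %d common, %d prescreened, %d failed",
    local_label, counts["total"], counts["common"], counts["prescreened"],
    counts["failed"]))
  invisible(list(observed = observed, fdr = fdr, fdr_long = fdr_long,
                 clumped = clumped, enrichment = enrichment,
                 counts = counts, files = files))
}
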