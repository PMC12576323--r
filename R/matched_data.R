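# Readers, validators and the case-minus-control difference representation
# consumed by the conditional likelihood.

DOSAGE_TOL <- 1e-6

#' Construct a dosage matrix
#'
#' A `dosage_matrix` bundles a numeric sample-by-variant grid of alternative
#' allele dosages (each value in \[0, 2\]) with its variant annotation.
#' Minor-allele frequencies are computed from the dosages on construction.
#'
#' @param values numeric matrix, samples in rows, variants in columns.
#' @param samples character vector of unique sample identifiers (defaults to
#'   `rownames(values)`).
#' @param variants data frame with one row per variant and columns
#'   `chrom`, `pos`, `id`, `ref`, `alt` (defaults are synthesised from
#'   `colnames(values)` when absent).
#' @return An object of class `dosage_matrix` with elements `values`,
#'   `samples` and `variants` (the latter gains a `maf` column).
#' @export
dosage_matrix <- function(values, samples = rownames(values), variants = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(samples)) stop("sample identifiers are required")
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicated sample identifiers")
  if (length(samples) != nrow(values)) stop("samples must match rows of `values`")
  if (is.null(variants)) {
    ids <- colnames(values)
    if (is.null(ids)) ids <- paste0("v", seq_len(ncol(values)))
    variants <- data.frame(chrom = NA_character_, pos = NA_integer_, id = ids,
                           ref = NA_character_, alt = NA_character_,
                           stringsAsFactors = FALSE)
  }
  variants <- as.data.frame(variants)
  if (anyDuplicated(variants$id)) stop("duplicated variant identifiers")
  if (nrow(variants) != ncol(values)) stop("variants must match columns of `values`")
  if (anyNA(values)) stop("missing dosage values are not supported; remove or re-impute them upstream")
  if (any(values < -DOSAGE_TOL | values > 2 + DOSAGE_TOL))
    stop("dosage outside [0, 2]: range observed [",
         format(min(values)), ", ", format(max(values)), "]")
  values <- pmin(pmax(values, 0), 2)
  dimnames(values) <- list(samples, variants$id)
  x <- structure(list(values = values, samples = samples, variants = variants),
                 class = "dosage_matrix")
  x$variants$maf <- vapply(seq_len(ncol(values)), function(j) compute_maf(x, j), 0)
  x
}

#' @method print dosage_matrix
#' @export
print.dosage_matrix <- function(x, ...) {
  cat("dosage_matrix:", length(x$samples), "samples x", nrow(x$variants),
      "variants\n")
  invisible(x)
}

#' @method dim dosage_matrix
#' @export
dim.dosage_matrix <- function(x) dim(x$values)

#' Read allele dosages from VCF or TSV
#'
#' VCF input uses the per-genotype `DS` FORMAT field when present; otherwise
#' hard `GT` calls are converted to alternative-allele counts 0/1/2.
#' Multi-allelic records are rejected. The TSV dialect is: first column the
#' sample id, header row of variant ids, tab separated.
#'
#' @param path input file.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by file extension).
#' @return A [dosage_matrix()] in file variant order.
#' @export
read_dosages <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") read_dosages_vcf(path) else read_dosages_tsv(path)
}

read_dosages_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("dosage TSV needs a sample column plus >=1 variant column: ", path)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(tab[-1], is.numeric, TRUE))[1]
    stop("non-numeric dosage column '", colnames(tab)[bad + 1], "' in ", path)
  }
  rownames(vals) <- as.character(tab[[1]])
  dosage_matrix(vals)
}

read_dosages_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi))
    stop("multi-allelic record(s) at ", paste(utils::head(
      paste0(fix$CHROM[multi], ":", fix$POS[multi]), 3), collapse = ", "),
      "; split to biallelic records first")
  fmt <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  if (is.null(fmt) || all(is.na(fmt))) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    if (is.null(gt)) stop("VCF has neither DS nor GT genotype fields: ", path)
    fmt <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  if (anyNA(fmt)) {
    bad <- which(is.na(fmt), arr.ind = TRUE)[1, ]
    stop("missing dosage for sample '", colnames(fmt)[bad[2]], "' at record ",
         rownames(fmt)[bad[1]], " in ", path)
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), id = ids,
                         ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  dosage_matrix(t(fmt), samples = colnames(fmt), variants = variants)
}

#' Write a dosage matrix in the TSV dialect
#'
#' @param x a [dosage_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dosages_tsv <- function(x, path) {
  stopifnot(inherits(x, "dosage_matrix"))
  tab <- data.frame(sample = x$samples, x$values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a dosage matrix as a biallelic VCF with a DS FORMAT field
#'
#' Requires complete variant annotation (`chrom`, `pos`, `ref`, `alt`);
#' dosages are written with six decimals.
#'
#' @param x a [dosage_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dosages_vcf <- function(x, path) {
  stopifnot(inherits(x, "dosage_matrix"))
  v <- x$variants
  if (anyNA(v$chrom) || anyNA(v$pos))
    stop("VCF output needs chrom and pos for every variant")
  ref <- ifelse(is.na(v$ref), "A", v$ref)
  alt <- ifelse(is.na(v$alt), "G", v$alt)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternative allele dosage\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", x$samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(j)
    paste(c(v$chrom[j], v$pos[j], v$id[j], ref[j], alt[j], ".", ".", ".",
            "DS", sprintf("%.6f", x$values[, j])), collapse = "\t"),
    character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Minor-allele frequency of one variant
#'
#' Alternative-allele frequency is `sum(dosage) / (2 * n_samples)`; the MAF
#' folds it onto \[0, 0.5\].
#'
#' @param dosages a [dosage_matrix()].
#' @param variant variant column index or id.
#' @return MAF in \[0, 0.5\].
#' @export
compute_maf <- function(dosages, variant) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  n <- length(dosages$samples)
  if (n == 0) stop("cannot compute an allele frequency with no samples")
  f <- sum(dosages$values[, variant]) / (2 * n)
  min(f, 1 - f)
}

#' Keep common variants
#'
#' Retains variants with MAF strictly greater than `threshold` (default 5%,
#' the usual common-variant cutoff), preserving order.
#'
#' @param dosages a [dosage_matrix()].
#' @param threshold MAF cutoff; variants with `maf > threshold` are kept.
#' @return A [dosage_matrix()] restricted to the retained variants.
#' @export
filter_common <- function(dosages, threshold = 0.05) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  keep <- which(dosages$variants$maf > threshold)
  subset_variants(dosages, keep)
}

subset_variants <- function(dosages, idx) {
  structure(list(values = dosages$values[, idx, drop = FALSE],
                 samples = dosages$samples,
                 variants = dosages$variants[idx, , drop = FALSE]),
            class = "dosage_matrix")
}

#' Construct a matched cohort
#'
#' One cohort's 1:1 matched strata: each stratum pairs one case with one
#' control sample. Samples may appear in at most one stratum.
#'
#' @param label cohort name (e.g. a cancer type).
#' @param strata data frame with columns `stratum_id`, `case`, `control`.
#' @return An object of class `matched_cohort` with elements `label`,
#'   `strata` (sorted by `stratum_id`) and `n0` (number of strata).
#' @export
matched_cohort <- function(label, strata) {
  strata <- as.data.frame(strata, stringsAsFactors = FALSE)
  need <- c("stratum_id", "case", "control")
  if (!all(need %in% names(strata)))
    stop("strata need columns: ", paste(need, collapse = ", "))
  if (any(strata$case == strata$control))
    stop("case and control coincide in stratum ",
         strata$stratum_id[strata$case == strata$control][1])
  ids <- c(strata$case, strata$control)
  if (anyDuplicated(ids))
    stop("sample(s) in more than one stratum: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  strata <- strata[order(strata$stratum_id), need, drop = FALSE]
  rownames(strata) <- NULL
  structure(list(label = label, strata = strata, n0 = nrow(strata)),
            class = "matched_cohort")
}

#' @method print matched_cohort
#' @export
print.matched_cohort <- function(x, ...) {
  cat("matched_cohort '", x$label, "': ", x$n0, " case-control strata\n",
      sep = "")
  invisible(x)
}

#' Read stratum definitions
#'
#' Expects a tab-separated file with header
#' `stratum_id  cohort  case_sample  control_sample`. Every referenced sample
#' must exist in `dosages`.
#'
#' @param path strata file.
#' @param dosages the [dosage_matrix()] the samples live in.
#' @return Named list of [matched_cohort()] objects, one per cohort label.
#' @export
read_strata <- function(path, dosages) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("stratum_id", "cohort", "case_sample", "control_sample")
  if (!all(need %in% names(tab)))
    stop("strata file needs columns: ", paste(need, collapse = ", "))
  miss <- setdiff(c(tab$case_sample, tab$control_sample), dosages$samples)
  if (length(miss))
    stop("sample(s) absent from dosages: ",
         paste(utils::head(miss, 5), collapse = ", "))
  out <- lapply(split(tab, tab$cohort), function(g)
    matched_cohort(g$cohort[1],
                   data.frame(stratum_id = g$stratum_id, case = g$case_sample,
                              control = g$control_sample,
                              stringsAsFactors = FALSE)))
  out[unique(tab$cohort)]
}

#' Write stratum definitions
#'
#' @param cohorts list of [matched_cohort()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_strata <- function(cohorts, path) {
  rows <- do.call(rbind, lapply(cohorts, function(co)
    data.frame(stratum_id = co$strata$stratum_id, cohort = co$label,
               case_sample = co$strata$case,
               control_sample = co$strata$control,
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Case-minus-control dosage differences
#'
#' For 1:1 matched pairs the conditional likelihood depends on the data only
#' through the within-stratum covariate difference `Z = X_case - X_control`
#' with an all-ones working response. Swapping case and control labels in a
#' stratum negates its row of `z`.
#'
#' @param cohort a [matched_cohort()].
#' @param dosages a [dosage_matrix()] containing every cohort sample.
#' @param variant variant column index/id (may be a vector).
#' @return An object of class `diff_data`: list with `z` (n0 x p matrix),
#'   `ystar` (all ones) and `stratum_id`.
#' @export
build_differences <- function(cohort, dosages, variant) {
  stopifnot(inherits(cohort, "matched_cohort"), inherits(dosages, "dosage_matrix"))
  miss <- setdiff(c(cohort$strata$case, cohort$strata$control), dosages$samples)
  if (length(miss))
    stop("sample(s) absent from dosages: ", paste(utils::head(miss, 5), collapse = ", "))
  z <- dosages$values[cohort$strata$case, variant, drop = FALSE] -
    dosages$values[cohort$strata$control, variant, drop = FALSE]
  rownames(z) <- cohort$strata$stratum_id
  diff_data(z, stratum_id = cohort$strata$stratum_id)
}

#' Construct difference data directly
#'
#' @param z numeric vector or n0 x p matrix of per-stratum differences.
#' @param stratum_id optional identifiers.
#' @return A `diff_data` object.
#' @export
diff_data <- function(z, stratum_id = NULL) {
  z <- as.matrix(z)
  storage.mode(z) <- "double"
  if (anyNA(z)) stop("missing values in difference data")
  if (is.null(stratum_id)) stratum_id <- seq_len(nrow(z))
  structure(list(z = z, ystar = rep(1, nrow(z)), stratum_id = stratum_id,
                 n0 = nrow(z)),
            class = "diff_data")
}

#' @method print diff_data
#' @export
print.diff_data <- function(x, ...) {
  cat("diff_data:", nrow(x$z), "strata,", ncol(x$z), "covariate(s)\n")
  invisible(x)
}

as_diff <- function(x) {
  if (inherits(x, "diff_data")) x else diff_data(x)
}
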