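# LD clumping of significant variants and TSS-proximity enrichment.

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the two dosage vectors across samples.
#' A reference panel may be supplied as `dosages` in place of the study data.
#'
#' @param dosages a [dosage_matrix()].
#' @param v1,v2 variant indices or ids.
#' @return r-squared in \[0, 1\].
#' @export
pairwise_r2 <- function(dosages, v1, v2) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  x <- dosages$values[, match_variant(dosages, v1)]
  y <- dosages$values[, match_variant(dosages, v2)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero dosage variance; r-squared undefined")
  stats::cor(x, y)^2
}

#' Greedy LD clumping
#'
#' Sorts records by ascending p-value, keeps the most significant variant,
#' and drops any later variant on the same chromosome that lies within
#' `window` base pairs of an already-kept variant AND is in LD with it
#' (`r^2 > r2_threshold`); both conditions must hold for removal.
#'
#' @param results data frame with columns `variant_id`, `chrom`, `pos` and a
#'   p-value column.
#' @param dosages [dosage_matrix()] used for the r-squared computation (the
#'   study data or an external reference panel).
#' @param r2_threshold LD cutoff (default 0.5).
#' @param window positional cutoff in bp (default 250 kb, strict `<`).
#' @param p_col name of the p-value column.
#' @return The retained rows of `results`, sorted by p-value. Always a
#'   subset of the input containing its minimum-p variant.
#' @export
ld_clump <- function(results, dosages, r2_threshold = 0.5, window = 250000,
                     p_col = "p") {
  stopifnot(all(c("variant_id", "chrom", "pos", p_col) %in% names(results)))
  if (anyNA(results$chrom) || anyNA(results$pos))
    stop("clumping needs chrom and pos for every record (VCF input carries ",
         "them; the bare dosage TSV does not)")
  miss <- setdiff(results$variant_id, dosages$variants$id)
  if (length(miss))
    stop("no genotypes for variant(s): ", paste(utils::head(miss, 5), collapse = ", "))
  res <- results[order(results[[p_col]]), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(res))) {
    drop_it <- FALSE
    for (k in kept) {
      if (res$chrom[i] != res$chrom[k]) next
      if (abs(res$pos[i] - res$pos[k]) >= window) next
      if (pairwise_r2(dosages, res$variant_id[i], res$variant_id[k]) >
          r2_threshold) {
        drop_it <- TRUE
        break
      }
    }
    if (!drop_it) kept <- c(kept, i)
  }
  out <- res[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read TSS annotation from BED6
#'
#' BED is 0-based half-open; the transcription start site is `start + 1`
#' (1-based) for `+` strand genes and `end` for `-` strand genes.
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @return A `tss_annotation` data frame: `chrom`, `tss` (1-based),
#'   `strand`, `gene`, in file order.
#' @export
read_tss_bed <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 6) stop("TSS annotation must be BED6: ", path)
  names(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (!all(bed$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  tss_annotation(bed$chrom, ifelse(bed$strand == "+", bed$start + 1, bed$end),
                 bed$strand, bed$name)
}

#' Construct a TSS annotation
#'
#' @param chrom chromosome labels.
#' @param tss 1-based TSS positions.
#' @param strand `"+"` or `"-"` per gene.
#' @param gene gene names.
#' @return A `tss_annotation` data frame.
#' @export
tss_annotation <- function(chrom, tss, strand, gene) {
  if (any(tss < 1)) stop("TSS positions are 1-based and must be >= 1")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  structure(data.frame(chrom = chrom, tss = as.integer(tss), strand = strand,
                       gene = gene, stringsAsFactors = FALSE),
            class = c("tss_annotation", "data.frame"))
}

#' Signed distance to the nearest TSS
#'
#' Chooses the TSS minimizing the absolute distance (ties broken by
#' annotation order) and signs the distance so that upstream of the gene is
#' negative: on the `+` strand `pos_snp - pos_tss`, on the `-` strand
#' `pos_tss - pos_snp`.
#'
#' @param chrom,pos SNP location (1-based).
#' @param ann a [tss_annotation()].
#' @return List with `distance` (signed bp) and `gene`; `distance` is `NA`
#'   when the annotation has no TSS on the SNP's chromosome.
#' @export
nearest_tss <- function(chrom, pos, ann) {
  on_chr <- which(ann$chrom == chrom)
  if (!length(on_chr)) return(list(distance = NA_real_, gene = NA_character_))
  d_abs <- abs(ann$tss[on_chr] - pos)
  i <- on_chr[which.min(d_abs)]  # which.min takes the first on ties
  d <- if (ann$strand[i] == "+") pos - ann$tss[i] else ann$tss[i] - pos
  list(distance = d, gene = ann$gene[i])
}

#' TSS-window enrichment test
#'
#' Pearson chi-squared test with Yates continuity correction on the 2x2
#' table of SNP set (identified vs reference) against TSS proximity (within
#' vs beyond the window), 1 df, upper tail.
#'
#' @param tab 2x2 matrix of nonnegative counts: rows = SNP sets, columns =
#'   within / beyond the window.
#' @return List with `statistic` and `p_value`.
#' @export
tss_enrichment <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0))
    stop("need a 2x2 table of nonnegative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in the contingency table")
  ct <- stats::chisq.test(tab, correct = TRUE)
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value))
}

#' Annotate variants with their nearest TSS and test enrichment
#'
#' Convenience wrapper: computes signed nearest-TSS distances for an
#' identified SNP set and a seeded random reference set, forms the
#' within/beyond `window` 2x2 table and applies [tss_enrichment()].
#'
#' @param identified data frame with `chrom` and `pos` of identified SNPs.
#' @param dosages [dosage_matrix()] providing the reference pool.
#' @param ann a [tss_annotation()].
#' @param n_reference reference SNPs to sample (default 1000).
#' @param seed seed for the reference sample.
#' @param window half-width in bp; "within" means absolute distance
#'   strictly `< window`.
#' @return List: `distances` (identified), `ref_distances`, `table`,
#'   `statistic`, `p_value`. SNPs with no TSS on their chromosome are
#'   excluded from the table.
#' @export
tss_enrichment_analysis <- function(identified, dosages, ann,
                                    n_reference = 1000, seed,
                                    window = 250000) {
  dist_of <- function(chrom, pos) vapply(seq_along(pos), function(i)
    nearest_tss(chrom[i], pos[i], ann)$distance, 0)
  d_id <- dist_of(identified$chrom, identified$pos)
  ref_idx <- sample_reference_snps(dosages, n_reference, seed)
  ref <- dosages$variants[ref_idx, ]
  d_ref <- dist_of(ref$chrom, ref$pos)
  within <- function(d) {
    d <- d[!is.na(d)]
    c(sum(abs(d) < window), sum(abs(d) >= window))
  }
  tab <- rbind(identified = within(d_id), reference = within(d_ref))
  colnames(tab) <- c("within", "beyond")
  test <- tss_enrichment(tab)
  list(distances = d_id, ref_distances = d_ref, table = tab,
       statistic = test$statistic, p_value = test$p_value)
}

#' Sample a reference SNP set
#'
#' Uniform sample of variant indices without replacement, reproducible from
#' `seed`.
#'
#' @param dosages a [dosage_matrix()].
#' @param n number of variants to draw.
#' @param seed integer seed.
#' @return Integer vector of variant indices.
#' @export
sample_reference_snps <- function(dosages, n = 1000, seed) {
  total <- nrow(dosages$variants)
  if (n > total) stop("cannot sample ", n, " of ", total, " variants")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sort(sample.int(total, n))
}
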