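# LD clumping and TSS-proximity enrichment.

test_that("r-squared identities: self, allele flip, independence", {
  set.seed(91)
  v1 <- rbinom(10000, 2, 0.3) + rnorm(10000, 0, 0.01)
  v1 <- pmin(pmax(v1, 0), 2)
  v3 <- pmin(pmax(rbinom(10000, 2, 0.4) + rnorm(10000, 0, 0.01), 0), 2)
  d <- dosage_matrix(cbind(a = v1, b = 2 - v1, c = v3),
                     samples = sprintf("s%05d", 1:10000))
  expect_equal(pairwise_r2(d, "a", "a"), 1)
  expect_equal(pairwise_r2(d, "a", "b"), 1)        # allele flip
  expect_lt(pairwise_r2(d, "a", "c"), 0.01)        # independent variants
  d0 <- dosage_matrix(cbind(a = v1[1:5], z = rep(1, 5)),
                      samples = paste0("s", 1:5))
  expect_error(pairwise_r2(d0, "a", "z"), "variance")
})

# Three variants engineered so r2(1,2) is high at 10 kb and r2(1,3) low.
clump_fixture <- function() {
  set.seed(101)
  g1 <- rbinom(400, 2, 0.3)
  g2 <- ifelse(runif(400) < 0.95, g1, rbinom(400, 2, 0.3))  # high LD with g1
  g3 <- rbinom(400, 2, 0.3)
  d <- dosage_matrix(cbind(v1 = g1, v2 = g2, v3 = g3),
                     samples = sprintf("s%03d", 1:400),
                     variants = data.frame(
                       chrom = "2", pos = c(1e6, 1e6 + 1e4, 1e6 + 2e4),
                       id = c("v1", "v2", "v3"), ref = "A", alt = "G"))
  res <- data.frame(variant_id = c("v1", "v2", "v3"), chrom = "2",
                    pos = d$variants$pos, p = c(1e-8, 1e-6, 1e-4),
                    stringsAsFactors = FALSE)
  list(d = d, res = res)
}

test_that("clumping drops the correlated nearby variant only", {
  fx <- clump_fixture()
  expect_gt(pairwise_r2(fx$d, "v1", "v2"), 0.5)
  expect_lt(pairwise_r2(fx$d, "v1", "v3"), 0.5)
  kept <- ld_clump(fx$res, fx$d)
  expect_identical(kept$variant_id, c("v1", "v3"))
  expect_identical(kept$variant_id[1],
                   fx$res$variant_id[which.min(fx$res$p)])
})

test_that("clumping requires both the window and the LD condition", {
  fx <- clump_fixture()
  fx$res$pos[2] <- fx$res$pos[1] + 3e5  # correlated but 300 kb away
  fx$d$variants$pos[2] <- fx$res$pos[2]
  kept <- ld_clump(fx$res, fx$d)
  expect_identical(kept$variant_id, c("v1", "v2", "v3"))
  # independent variants all survive
  set.seed(111)
  d_ind <- dosage_matrix(matrix(rbinom(400 * 3, 2, 0.4), 400, 3,
                                dimnames = list(sprintf("s%03d", 1:400),
                                                c("v1", "v2", "v3"))),
                         variants = fx$d$variants)
  expect_equal(nrow(ld_clump(fx$res, d_ind)), 3)
})

test_that("nearest TSS distance follows the strand sign convention", {
  ann <- tss_annotation(chrom = c("1", "1"), tss = c(1500, 500),
                        strand = c("+", "-"), gene = c("gpos", "gneg"))
  r1 <- nearest_tss("1", 1000, tss_annotation("1", 1500, "+", "g"))
  expect_equal(r1$distance, -500)  # upstream of a + gene is negative
  r2 <- nearest_tss("1", 1000, tss_annotation("1", 500, "-", "g"))
  expect_equal(r2$distance, -500)  # upstream of a - gene is also negative
  # |distance| is strand-invariant
  r3 <- nearest_tss("1", 1000, tss_annotation("1", 500, "+", "g"))
  expect_equal(abs(r3$distance), abs(r2$distance))
  expect_equal(r3$distance, 500)
  # equidistant tie -> first gene in annotation order
  tie <- nearest_tss("1", 1000, ann)
  expect_equal(tie$gene, "gpos")
  # chromosome with no TSS
  expect_true(is.na(nearest_tss("7", 1000, ann)$distance))
})

test_that("BED6 TSS conversion is strand-aware and 1-based", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t999\t2000\tgeneA\t0\t+", "1\t4999\t6000\tgeneB\t0\t-"),
             path)
  ann <- read_tss_bed(path)
  expect_equal(ann$tss, c(1000L, 6000L))  # start+1 for +, end for -
})

test_that("enrichment chi-squared reproduces the corrected statistic", {
  tab <- rbind(c(72, 1), c(829, 171))
  out <- tss_enrichment(tab)
  expect_equal(out$statistic, 11.36, tolerance = 0.005)
  expect_lt(out$p_value, 0.001)
  # identical row proportions: corrected statistic is essentially zero
  flat <- tss_enrichment(rbind(c(50, 50), c(500, 500)))
  expect_lt(flat$statistic, 0.1)
  # doubling all cells strengthens the signal
  expect_gt(tss_enrichment(2 * tab)$statistic, out$statistic)
  # Yates statistic never exceeds uncorrected Pearson
  set.seed(121)
  for (i in 1:10) {
    t2 <- matrix(rpois(4, 50) + 1, 2, 2)
    expect_lte(tss_enrichment(t2)$statistic,
               suppressWarnings(chisq.test(t2, correct = FALSE)$statistic))
  }
  expect_error(tss_enrichment(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("reference SNP sampling is seeded and exhaustive at full n", {
  d <- dosage_matrix(matrix(runif(40, 0, 2), 4, 10,
                            dimnames = list(paste0("s", 1:4),
                                            paste0("v", 1:10))))
  s1 <- sample_reference_snps(d, 5, seed = 7)
  expect_identical(s1, sample_reference_snps(d, 5, seed = 7))
  expect_identical(sample_reference_snps(d, 10, seed = 1), 1:10)
  expect_error(sample_reference_snps(d, 11, seed = 1), "cannot sample")
  expect_false(identical(sample_reference_snps(d, 5, seed = 8), s1))
})

test_that("enrichment analysis wrapper builds the within/beyond table", {
  set.seed(131)
  nv <- 30
  d <- dosage_matrix(matrix(runif(10 * nv, 0, 2), 10, nv,
                            dimnames = list(paste0("s", 1:10),
                                            paste0("v", 1:nv))),
                     variants = data.frame(chrom = "1",
                                           pos = seq(1e5, by = 5e5,
                                                     length.out = nv),
                                           id = paste0("v", 1:nv),
                                           ref = "A", alt = "G"))
  ann <- tss_annotation("1", c(1e5 + 1000, 2.1e6), c("+", "-"),
                        c("g1", "g2"))
  hits <- data.frame(chrom = "1", pos = c(1e5, 2.0e6))
  out <- suppressWarnings(  # tiny expected counts in this toy table
    tss_enrichment_analysis(hits, d, ann, n_reference = 20, seed = 3))
  expect_equal(sum(out$table["identified", ]), 2)
  expect_equal(sum(out$table["reference", ]), 20)
  expect_equal(out$table["identified", "within"], 2)  # both within 250 kb
})
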