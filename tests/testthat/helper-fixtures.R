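# Shared fixtures: small in-code datasets and independent oracles.

# Random difference data with a known coefficient dimension.
random_diff <- function(n0, p = 1, sd = 1) {
  diff_data(matrix(rnorm(n0 * p, sd = sd), n0, p))
}

# Independent maximizer of the (weighted) conditional likelihood, written
# from the likelihood definition only (never touches the package's Newton
# path).
oracle_clr_beta <- function(z, weights = NULL, start = NULL) {
  z <- as.matrix(z)
  if (is.null(weights)) weights <- rep(1, nrow(z))
  nll <- function(b) {
    eta <- drop(z %*% b)
    -sum(weights * (eta - ifelse(eta > 0, eta + log1p(exp(-eta)),
                                 log1p(exp(eta)))))
  }
  p <- ncol(z)
  if (is.null(start)) start <- rep(0, p)
  if (p == 1) stats::optimize(function(b) nll(b), c(-10, 10),
                              tol = 1e-12)$minimum
  else stats::optim(start, nll, method = "BFGS",
                    control = list(reltol = 1e-15, maxit = 2000))$par
}

# A small two-cohort simulated dataset reused across tests.
tiny_sim <- function(seed = 101, effects = 0) {
  simulate_cohorts(sim_config(
    strata_per_cohort = c(alpha = 40, beta_cohort = 60),
    n_variants = 4, effects = effects, dosage_noise_sd = 0.05, seed = seed))
}

# Minimal VCF text with a DS FORMAT field.
write_fixture_vcf <- function(path, ds = rbind(c(0.0, 1.97)),
                              samples = c("s1", "s2"),
                              chrom = "1", pos = 100, id = "rs1",
                              ref = "A", alt = "G") {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(ds)), function(i)
    paste(c(chrom[min(i, length(chrom))], pos[min(i, length(pos))],
            id[min(i, length(id))], ref[min(i, length(ref))],
            alt[min(i, length(alt))], ".", "PASS", ".", "DS",
            format(ds[i, ], trim = TRUE)), collapse = "\t"),
    character(1))
  writeLines(c(header, body), path)
  path
}
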