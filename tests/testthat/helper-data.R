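# Shared fixture builders: everything is generated in code at test time.

# random genotype_matrix with optional missing entries
random_genotypes <- function(n, p, missing_rate = 0, seed = 1) {
  set.seed(seed)
  d <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
  if (missing_rate > 0 && n * p > 0) {
    d[runif(n * p) < missing_rate] <- NA_integer_
  }
  meta <- data.frame(chrom = as.character(sample(1:3, p, replace = TRUE)),
                     id = if (p) paste0("rs", seq_len(p)) else character(),
                     cm = round(runif(p), 4),
                     pos = if (p) sort(sample.int(1e6, p)) else integer(),
                     a1 = sample(c("A", "C", "G", "T"), p, replace = TRUE),
                     a2 = sample(c("A", "C", "G", "T"), p, replace = TRUE))
  genotype_matrix(d, snp_meta = meta)
}

# tiny filtered dataset with a planted single-SNP signal
planted_signal_data <- function(n = 80, p = 40, snp = 5, noise = 0.05,
                                seed = 42) {
  set.seed(seed)
  g <- random_genotypes(n, p, seed = seed)
  y <- g$dosages[, snp] + rnorm(n, sd = noise)
  list(genotypes = g, phenotype = y, snp = snp)
}

# brute-force per-SNP regression oracle via stats::lm
lm_scan_oracle <- function(g, y, idx = seq_along(y)) {
  vapply(seq_len(ncol(g$dosages)), function(j) {
    x <- g$dosages[idx, j]
    if (var(x) == 0) return(1)
    summary(lm(y[idx] ~ x))$coefficients[2, 4]
  }, numeric(1))
}
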