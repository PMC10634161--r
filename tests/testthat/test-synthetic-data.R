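test_that("simulation is a deterministic function of its configuration", {
  a <- simulate_dataset(50, 80, n_causal = 5, heritability = 0.4,
                        missing_rate = 0.05, seed = 9)
  b <- simulate_dataset(50, 80, n_causal = 5, heritability = 0.4,
                        missing_rate = 0.05, seed = 9)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$causal_indices, b$causal_indices)

  c <- simulate_dataset(50, 80, n_causal = 5, heritability = 0.4,
                        missing_rate = 0.05, seed = 10)
  expect_false(identical(a$phenotype, c$phenotype))
})

test_that("phenotype decomposes exactly into additive score plus recorded noise", {
  sim <- simulate_dataset(120, 150, n_causal = 12, heritability = 0.5,
                          seed = 4)
  score <- as.numeric(
    sim$genotypes$dosages[, sim$causal_indices] %*% sim$effects)
  expect_equal(sim$phenotype, score + sim$noise, tolerance = 1e-12)
  # noise is independent Gaussian with the variance implied by h2
  expect_lt(abs(cor(score, sim$noise)), 0.3)
})

test_that("realized heritability is recorded near its target", {
  sim <- simulate_dataset(400, 2000, n_causal = 20, heritability = 0.6,
                          seed = 1)
  expect_lt(abs(sim$realized_h2 - 0.6), 0.15)
  expect_equal(sim$realized_h2,
               var(sim$genetic_values) / var(sim$phenotype))

  null <- simulate_dataset(100, 50, n_causal = 0, heritability = 0, seed = 2)
  expect_identical(null$realized_h2, 0)
  expect_identical(null$genetic_values, numeric(100))
})

test_that("empirical allele frequencies track the drawn frequencies", {
  sim <- simulate_dataset(400, 300, n_causal = 0, heritability = 0, seed = 6)
  emp <- colMeans(sim$genotypes$dosages) / 2
  se <- sqrt(sim$allele_freqs * (1 - sim$allele_freqs) / (2 * 400))
  # per-SNP binomial check: ~0.3% of 300 SNPs may legitimately sit outside
  # the 3-SE band, so allow a handful of exceedances but no systematic drift
  expect_lte(sum(abs(emp - sim$allele_freqs) > 3 * se), 6)
  expect_lt(abs(mean(emp - sim$allele_freqs)), 0.01)
})

test_that("epistatic terms add products of centered dosages for causal pairs", {
  sim <- simulate_dataset(150, 100, n_causal = 10, heritability = 0.8,
                          n_epistatic_pairs = 3, seed = 5)
  expect_equal(dim(sim$epistatic_pairs), c(3, 2))
  expect_true(all(sim$epistatic_pairs %in% sim$causal_indices))
  X <- sim$genotypes$dosages
  score <- as.numeric(X[, sim$causal_indices] %*% sim$effects)
  for (k in 1:3) {
    i <- sim$epistatic_pairs[k, 1]; j <- sim$epistatic_pairs[k, 2]
    score <- score + sim$epistatic_effects[k] *
      (X[, i] - mean(X[, i])) * (X[, j] - mean(X[, j]))
  }
  expect_equal(sim$genetic_values, score, tolerance = 1e-10)
})

test_that("invalid configurations are rejected", {
  expect_error(simulate_dataset(10, 5, n_causal = 6), "n_causal")
  expect_error(simulate_dataset(10, 5, n_causal = 2, n_epistatic_pairs = 2))
  expect_error(simulate_dataset(10, 5, n_causal = 0, heritability = 1),
               "n_causal")
  expect_error(simulate_dataset(10, 5, maf_range = c(0, 0.5)))
})

test_that("block-correlated mode induces LD within blocks, none across", {
  sim <- simulate_dataset(500, 40, n_causal = 0, heritability = 0,
                          maf_range = c(0.3, 0.5), ld_block_size = 10,
                          ld_rho = 0.9, seed = 8)
  X <- sim$genotypes$dosages
  within <- cor(X[, 1], X[, 2])
  across <- cor(X[, 10], X[, 11])  # block boundary
  expect_gt(within, 0.5)
  expect_lt(abs(across), 0.2)
  # marginals stay binomial: frequencies still track their draws
  emp <- colMeans(X) / 2
  expect_lt(max(abs(emp - sim$allele_freqs)), 0.1)
})

test_that("fixtures round-trip through the PLINK codec with a faithful truth sidecar", {
  sim <- simulate_dataset(30, 25, n_causal = 4, heritability = 0.5,
                          n_epistatic_pairs = 1, seed = 11)
  prefix <- tempfile()
  write_fixture(sim, prefix)
  rt <- read_plink(prefix)
  expect_identical(rt$genotypes$dosages, sim$genotypes$dosages)
  expect_equal(rt$phenotype, sim$phenotype)

  truth <- read.table(paste0(prefix, ".truth.tsv"), header = TRUE, sep = "\t")
  expect_equal(truth$snp_index, sim$causal_indices)
  expect_equal(truth$effect, sim$effects, tolerance = 1e-15)
  expect_equal(sum(truth$in_epistatic_pair), 2)

  # same config twice -> byte-identical files
  prefix2 <- tempfile()
  write_fixture(simulate_dataset(30, 25, n_causal = 4, heritability = 0.5,
                                 n_epistatic_pairs = 1, seed = 11), prefix2)
  for (ext in c(".bed", ".bim", ".fam", ".truth.tsv")) {
    expect_identical(readBin(paste0(prefix, ext), "raw", 1e6),
                     readBin(paste0(prefix2, ext), "raw", 1e6))
  }
})
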