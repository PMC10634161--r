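# Synthetic genotype-phenotype datasets with known causal architecture.

#' Simulate a genotype-phenotype dataset
#'
#' Draws biallelic SNP dosages per SNP as Binomial(2, f) with allele
#' frequency f uniform in `maf_range` (independent SNPs by default; see
#' `ld_block_size` for a block-correlated mode), assigns effects to
#' `n_causal` SNPs, optionally adds pairwise epistatic terms as products of
#' centered dosages for pairs of causal SNPs, and adds Gaussian noise scaled
#' so that the genetic fraction of phenotypic variance equals `heritability`
#' in expectation. The realized variance ratio is recorded, not assumed.
#'
#' With `heritability = 0` or `n_causal = 0` the phenotype is pure standard
#' normal noise (requesting `heritability = 1` with no causal SNPs is an
#' error). Missing genotypes are inserted completely at random at
#' `missing_rate`.
#'
#' @param n_individuals,n_snps Dataset dimensions.
#' @param n_causal Number of causal SNPs (`<= n_snps`).
#' @param heritability Target ratio var(genetic)/var(phenotype), in `[0, 1]`.
#' @param maf_range Length-2 vector of allele-frequency bounds in `(0, 0.5]`.
#' @param n_epistatic_pairs Number of causal-SNP pairs contributing a
#'   product-of-centered-dosages interaction (`2 * n_epistatic_pairs <=
#'   n_causal`).
#' @param effect_distribution `"gaussian"` or `"laplace"` marker effects.
#' @param missing_rate Fraction of genotype entries set missing, in `[0, 1)`.
#' @param ld_block_size If `> 1`, SNPs are simulated in blocks of this size
#'   with an AR(1) correlation `ld_rho` between the latent allele draws of
#'   adjacent SNPs, giving linkage-disequilibrium-like marker correlation.
#' @param ld_rho AR(1) latent correlation within blocks.
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   arguments.
#' @return An object of class `ifs_simulation`: list with `genotypes`
#'   ([genotype_matrix]), `phenotype`, `causal_indices`, `effects`
#'   (additive, aligned with `causal_indices`), `epistatic_pairs` (2-column
#'   matrix of SNP indices), `epistatic_effects`, `genetic_values`,
#'   `noise`, `realized_h2` and the call's configuration.
#' @export
simulate_dataset <- function(n_individuals, n_snps, n_causal = 0,
                             heritability = 0.5, maf_range = c(0.05, 0.5),
                             n_epistatic_pairs = 0,
                             effect_distribution = c("gaussian", "laplace"),
                             missing_rate = 0, ld_block_size = 1,
                             ld_rho = 0.8, seed = 1) {
  effect_distribution <- match.arg(effect_distribution)
  stopifnot(n_individuals >= 1, n_snps >= 1, n_causal >= 0,
            n_causal <= n_snps, 2 * n_epistatic_pairs <= n_causal,
            heritability >= 0, heritability <= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            missing_rate >= 0, missing_rate < 1)
  if (heritability > 0 && n_causal == 0) {
    stop("heritability > 0 requires n_causal > 0 (no genetic variance otherwise)")
  }

  old_seed <- .GlobalEnv$.Random.seed
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = .GlobalEnv))
  set.seed(seed)

  n <- n_individuals
  p <- n_snps
  freqs <- stats::runif(p, maf_range[1], maf_range[2])
  if (ld_block_size > 1) {
    X <- .simulate_ld_dosages(n, freqs, ld_block_size, ld_rho)
  } else {
    X <- matrix(stats::rbinom(n * p, 2L, rep(freqs, each = n)), n, p)
  }

  causal <- sort(sample.int(p, n_causal))
  effects <- switch(effect_distribution,
    gaussian = stats::rnorm(n_causal),
    laplace = stats::rexp(n_causal) * sample(c(-1, 1), n_causal, TRUE))

  genetic <- if (n_causal > 0) {
    as.numeric(X[, causal, drop = FALSE] %*% effects)
  } else {
    numeric(n)
  }
  pairs <- matrix(integer(), 0L, 2L)
  epi_effects <- numeric(0)
  if (n_epistatic_pairs > 0) {
    chosen <- sample(causal, 2L * n_epistatic_pairs)
    pairs <- matrix(chosen, ncol = 2L, byrow = TRUE)
    epi_effects <- stats::rnorm(n_epistatic_pairs)
    Xc <- scale(X[, chosen, drop = FALSE], scale = FALSE)
    for (k in seq_len(n_epistatic_pairs)) {
      genetic <- genetic + epi_effects[k] * Xc[, 2L * k - 1L] * Xc[, 2L * k]
    }
  }

  var_g <- stats::var(genetic)
  if (heritability == 0 || var_g == 0) {
    noise <- stats::rnorm(n)
    genetic <- numeric(n)
  } else {
    sigma_e <- sqrt(var_g * (1 - heritability) / heritability)
    noise <- stats::rnorm(n, sd = sigma_e)
  }
  y <- genetic + noise

  if (missing_rate > 0) {
    miss <- which(stats::runif(n * p) < missing_rate)
    X[miss] <- NA_integer_
  }

  g <- genotype_matrix(X)
  realized <- if (stats::var(y) > 0) stats::var(genetic) / stats::var(y) else NA_real_
  structure(list(genotypes = g, phenotype = y,
                 causal_indices = causal, effects = effects,
                 epistatic_pairs = pairs, epistatic_effects = epi_effects,
                 genetic_values = genetic, noise = noise,
                 realized_h2 = realized, allele_freqs = freqs,
                 config = list(n_individuals = n, n_snps = p,
                               n_causal = n_causal,
                               heritability = heritability,
                               maf_range = maf_range,
                               n_epistatic_pairs = n_epistatic_pairs,
                               effect_distribution = effect_distribution,
                               missing_rate = missing_rate,
                               ld_block_size = ld_block_size,
                               ld_rho = ld_rho, seed = seed)),
            class = "ifs_simulation")
}

# Block-correlated dosages: per block, each of the two allele draws of SNP j
# shares its latent uniform with SNP j-1 with probability ld_rho, otherwise
# refreshes it (AR(1)-style latent persistence), then thresholds at the SNP's
# own frequency. Marginals stay Binomial(2, f_j).
.simulate_ld_dosages <- function(n, freqs, block_size, rho) {
  p <- length(freqs)
  X <- matrix(0L, n, p)
  starts <- seq(1L, p, by = block_size)
  for (s in starts) {
    idx <- s:min(s + block_size - 1L, p)
    u1 <- stats::runif(n)
    u2 <- stats::runif(n)
    for (j in idx) {
      if (j > s) {
        refresh1 <- stats::runif(n) > rho
        refresh2 <- stats::runif(n) > rho
        u1[refresh1] <- stats::runif(sum(refresh1))
        u2[refresh2] <- stats::runif(sum(refresh2))
      }
      X[, j] <- (u1 < freqs[j]) + (u2 < freqs[j])
    }
  }
  X
}

#' @export
print.ifs_simulation <- function(x, ...) {
  cfg <- x$config
  cat("ifs_simulation:", cfg$n_individuals, "individuals x", cfg$n_snps,
      "SNPs;", cfg$n_causal, "causal;",
      "target h2 =", cfg$heritability,
      "(realized", round(x$realized_h2, 3), ")\n")
  invisible(x)
}

#' Write a simulated dataset as a PLINK fileset plus truth sidecar
#'
#' Serializes genotypes and phenotype via [write_plink] and writes
#' `prefix.truth.tsv` with columns `snp_index`, `effect`,
#' `in_epistatic_pair`, one row per causal SNP, so tests can reconstruct the
#' genetic architecture.
#'
#' @param sim An `ifs_simulation`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(sim, prefix) {
  stopifnot(inherits(sim, "ifs_simulation"))
  paths <- write_plink(sim$genotypes, sim$phenotype, prefix)
  truth <- data.frame(snp_index = sim$causal_indices,
                      effect = sim$effects,
                      in_epistatic_pair =
                        sim$causal_indices %in% as.vector(sim$epistatic_pairs))
  truth_path <- paste0(prefix, ".truth.tsv")
  utils::write.table(format(truth, digits = 17, trim = TRUE), truth_path,
                     quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(c(paths, truth_path))
}
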