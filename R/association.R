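# Single-marker association scan and deterministic p-value ranking.

#' Single-marker GWAS scan on a training subset
#'
#' For each SNP fits the simple linear regression
#' `phenotype ~ intercept + dosage` on the training individuals only and
#' reports the two-sided Wald t-test p-value on the slope with
#' `length(train_idx) - 2` degrees of freedom — the quantitative-trait
#' linear association test without covariates. SNPs with zero dosage
#' variance on the training set (monomorphic there) get `p = 1`,
#' `slope = 0`. The whole scan is computed with closed-form column
#' operations, so it scales to hundreds of thousands of markers.
#'
#' @param g A [genotype_matrix] with no missing dosages on `train_idx`.
#' @param phenotype Numeric phenotype aligned with `g`.
#' @param train_idx Integer indices of the training individuals (>= 3);
#'   defaults to all individuals.
#' @return An object of class `ifs_assoc`: list with `p_values`, `slopes`,
#'   and `snp_meta` (carrying the (chromosome, position) tie-break key).
#' @export
gwas_scan <- function(g, phenotype, train_idx = seq_along(phenotype)) {
  stopifnot(inherits(g, "genotype_matrix"),
            length(phenotype) == nrow(g$dosages))
  train_idx <- as.integer(train_idx)
  m <- length(train_idx)
  if (m < 3) stop("need at least 3 training individuals for the t-test")
  X <- g$dosages[train_idx, , drop = FALSE]
  if (anyNA(X)) stop("missing dosages in training submatrix; run filter_missing first")
  y <- phenotype[train_idx]
  if (anyNA(y)) stop("missing phenotypes in training subset")
  p <- ncol(X)

  storage.mode(X) <- "double"
  yc <- y - mean(y)
  sxx <- colSums(X^2) - colSums(X)^2 / m      # m * var_x (biased scale)
  sxy <- as.numeric(crossprod(X, yc))          # sum (x - xbar)(y - ybar)
  syy <- sum(yc^2)

  pvals <- rep(1, p)
  slopes <- rep(0, p)
  poly <- sxx > 0
  if (syy == 0) {
    warning("constant phenotype on training set: all association p-values are 1")
  } else if (any(poly)) {
    b <- sxy[poly] / sxx[poly]
    ss_res <- pmax(syy - b * sxy[poly], 0)
    df <- m - 2L
    se <- sqrt(ss_res / (df * sxx[poly]))
    tval <- ifelse(se > 0, b / se, Inf * sign(b))
    pv <- 2 * stats::pt(-abs(tval), df)
    pv[se == 0 & b == 0] <- 1  # flat fit with zero residual: no evidence
    pvals[poly] <- pv
    slopes[poly] <- b
  }
  structure(list(p_values = pvals, slopes = slopes, snp_meta = g$snp_meta,
                 n_train = m),
            class = "ifs_assoc")
}

#' @export
print.ifs_assoc <- function(x, ...) {
  cat("ifs_assoc:", length(x$p_values), "SNPs scanned on", x$n_train,
      "training individuals; min p =", format(min(x$p_values)), "\n")
  invisible(x)
}

#' Rank SNPs by association strength
#'
#' Stable ascending sort on p-value; ties are broken by genomic coordinates
#' (chromosome, then base-pair position) so the ranking is deterministic
#' across runs and platforms. Raw p-values are used purely as an ordering —
#' no multiple-testing correction is applied or needed.
#'
#' @param assoc An `ifs_assoc` from [gwas_scan].
#' @return Integer vector: a permutation of `1..n_snps`, most strongly
#'   associated SNP first.
#' @export
rank_snps <- function(assoc) {
  stopifnot(inherits(assoc, "ifs_assoc"))
  order(assoc$p_values, assoc$snp_meta$chrom, assoc$snp_meta$pos)
}

#' Export an association scan as TSV
#'
#' Columns `snp_id`, `chrom`, `pos`, `slope`, `p_value`, mirroring the shape
#' of standard GWAS tool output.
#'
#' @param assoc An `ifs_assoc`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_assoc <- function(assoc, path) {
  stopifnot(inherits(assoc, "ifs_assoc"))
  out <- data.frame(snp_id = assoc$snp_meta$id,
                    chrom = assoc$snp_meta$chrom,
                    pos = assoc$snp_meta$pos,
                    slope = assoc$slopes,
                    p_value = assoc$p_values)
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
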