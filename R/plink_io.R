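# PLINK 1.x binary I/O: .bed/.bim/.fam triplets, 2-bit SNP-major codec.

BED_MAGIC <- as.raw(c(0x6c, 0x1b))
BED_SNP_MAJOR <- as.raw(0x01)

#' Construct a genotype matrix
#'
#' Bundles a dosage matrix with per-individual and per-SNP metadata. Dosages
#' count copies of a designated allele per diploid individual, so values are
#' 0, 1, 2 or `NA` for missing genotypes.
#'
#' @param dosages Integer matrix, individuals in rows, SNPs in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param sample_ids Data frame with columns `fid` (family id) and `iid`
#'   (individual id), one row per individual. Defaults to
#'   `F1..Fn` / `I1..In`.
#' @param snp_meta Data frame with columns `chrom`, `id`, `cm` (genetic
#'   distance), `pos` (bp), `a1`, `a2`, one row per SNP. Defaults to
#'   chromosome `"1"`, ids `snp1..snpp`, positions `1000·j`, alleles A/B.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, sample_ids = NULL, snp_meta = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  n <- nrow(dosages)
  p <- ncol(dosages)
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad)) {
    stop("dosages must be 0, 1, 2 or NA; found ", dosages[which(bad)[1]])
  }
  if (is.null(sample_ids)) {
    sample_ids <- data.frame(fid = paste0("F", seq_len(n)),
                             iid = paste0("I", seq_len(n)))
  }
  if (is.null(snp_meta)) {
    snp_meta <- data.frame(chrom = rep("1", p),
                           id = if (p) paste0("snp", seq_len(p)) else character(),
                           cm = numeric(p),
                           pos = if (p) 1000L * seq_len(p) else integer(),
                           a1 = rep("A", p), a2 = rep("B", p))
  }
  sample_ids <- as.data.frame(sample_ids, stringsAsFactors = FALSE)
  snp_meta <- as.data.frame(snp_meta, stringsAsFactors = FALSE)
  stopifnot(nrow(sample_ids) == n, nrow(snp_meta) == p,
            all(c("fid", "iid") %in% names(sample_ids)),
            all(c("chrom", "id", "cm", "pos", "a1", "a2") %in% names(snp_meta)))
  structure(list(dosages = dosages, sample_ids = sample_ids,
                 snp_meta = snp_meta),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "SNPs;",
      sum(is.na(x$dosages)), "missing genotypes\n")
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x A `genotype_matrix`.
#' @param i Individual (row) indices; missing keeps all.
#' @param j SNP (column) indices; missing keeps all.
#' @param ... Ignored.
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  genotype_matrix(x$dosages[i, j, drop = FALSE],
                  x$sample_ids[i, , drop = FALSE],
                  x$snp_meta[j, , drop = FALSE])
}

# 2-bit genotype codes, SNP-major, lowest bits first within a byte:
#   00 = homozygous A1, 01 = missing, 10 = heterozygous, 11 = homozygous A2.
# Counting A1 copies: 00 -> 2, 10 -> 1, 11 -> 0, 01 -> NA.
.code_to_dosage_a1 <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)

# 256 x 4 lookup: byte value -> dosages of the four packed genotypes
.bed_decode_table <- local({
  tab <- matrix(NA_integer_, 256L, 4L)
  for (b in 0:255) {
    v <- b
    for (k in 1:4) {
      tab[b + 1L, k] <- .code_to_dosage_a1[[as.character(v %% 4L)]]
      v <- v %/% 4L
    }
  }
  tab
})

.read_bim <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), id = character(), cm = numeric(),
                      pos = integer(), a1 = character(), a2 = character()))
  }
  bim <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  bim
}

.read_fam <- function(path) {
  fam <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "character",
                                          "character", "character", "numeric"))
  names(fam) <- c("fid", "iid", "pid", "mid", "sex", "pheno")
  fam
}

#' Read a PLINK 1.x binary fileset
#'
#' Decodes `prefix.bed`/`prefix.bim`/`prefix.fam` into a [genotype_matrix]
#' and a phenotype vector. The `.bed` must be in SNP-major mode. By default
#' dosages count copies of the `.bim` A1 allele (so an individual homozygous
#' for A2 has dosage 0); set `count_allele = "a2"` to flip. The phenotype is
#' `.fam` column 6 with `-9` and `0` treated as missing, unless a separate
#' phenotype file (whitespace-delimited `FID IID VALUE`, header optional) is
#' supplied, which then takes precedence.
#'
#' @param prefix Path prefix of the fileset (without extension).
#' @param pheno_file Optional path to a phenotype file overriding `.fam`.
#' @param count_allele `"a1"` (default) or `"a2"`: which allele dosages count.
#' @return A list with elements `genotypes` ([genotype_matrix]) and
#'   `phenotype` (numeric vector with `NA` for missing values).
#' @export
read_plink <- function(prefix, pheno_file = NULL,
                       count_allele = c("a1", "a2")) {
  count_allele <- match.arg(count_allele)
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    stop("missing PLINK file(s): ", paste(missing_files, collapse = ", "))
  }
  bim <- .read_bim(paths[2])
  fam <- .read_fam(paths[3])
  n <- nrow(fam)
  p <- nrow(bim)

  raw <- readBin(paths[1], "raw", n = file.info(paths[1])$size)
  if (length(raw) < 3L || !identical(raw[1:2], BED_MAGIC)) {
    stop("not a PLINK 1.x .bed file (bad magic bytes): ", paths[1])
  }
  if (!identical(raw[3], BED_SNP_MAJOR)) {
    stop(".bed is not in SNP-major mode; re-export with a modern PLINK")
  }
  bytes_per_snp <- ceiling(n / 4)
  expected <- 3L + bytes_per_snp * p
  if (length(raw) != expected) {
    stop(".bed size (", length(raw), " bytes) inconsistent with .bim/.fam (",
         "expected ", expected, " for ", n, " individuals x ", p, " SNPs)")
  }

  dosages <- matrix(NA_integer_, n, p)
  if (p > 0L && n > 0L) {
    body <- as.integer(raw[-(1:3)])
    # decode all packed genotypes at once, then trim the per-SNP padding
    decoded <- .bed_decode_table[body + 1L, , drop = FALSE]
    decoded <- matrix(t(decoded), nrow = 4L * bytes_per_snp, ncol = p)
    dosages <- decoded[seq_len(n), , drop = FALSE]
  }
  if (count_allele == "a2") dosages <- 2L - dosages

  g <- genotype_matrix(dosages, fam[, c("fid", "iid")], bim)
  pheno <- fam$pheno
  pheno[!is.na(pheno) & (pheno == -9 | pheno == 0)] <- NA_real_
  if (!is.null(pheno_file)) {
    pheno <- read_phenotype(pheno_file, g$sample_ids)
  }
  list(genotypes = g, phenotype = as.numeric(pheno))
}

#' Read a separate phenotype file
#'
#' Whitespace-delimited `FID IID VALUE`; a header row is detected by a
#' non-numeric third field. Values `-9` and `0` are kept as given (only the
#' `.fam` sentinel convention maps them to missing); `NA` strings become
#' missing. Individuals absent from the file get `NA`.
#'
#' @param path Phenotype file path.
#' @param sample_ids Data frame with `fid`, `iid` giving the required order.
#' @return Numeric vector aligned with `sample_ids`.
#' @export
read_phenotype <- function(path, sample_ids) {
  first <- strsplit(trimws(readLines(path, n = 1L)), "\\s+")[[1]]
  skip <- if (length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3])))) 1L else 0L
  tab <- utils::read.table(path, header = FALSE, skip = skip,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric"))
  key <- paste(tab[[1]], tab[[2]], sep = "\r")
  want <- paste(sample_ids$fid, sample_ids$iid, sep = "\r")
  as.numeric(tab[[3]][match(want, key)])
}

#' Write a PLINK 1.x binary fileset
#'
#' Inverse of [read_plink] under the same allele-counting convention:
#' `write_plink` followed by `read_plink` reproduces dosages, metadata and
#' phenotype exactly. The `.bed` is SNP-major with each SNP's genotypes
#' packed 4 per byte, padded with zero bits to a whole byte.
#'
#' @param g A [genotype_matrix].
#' @param phenotype Numeric phenotype vector (`NA` written as `-9`).
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_plink <- function(g, phenotype, prefix) {
  stopifnot(inherits(g, "genotype_matrix"),
            length(phenotype) == nrow(g$dosages))
  n <- nrow(g$dosages)
  p <- ncol(g$dosages)
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))

  # dosage -> 2-bit code (A1-counting): 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code_of <- c(`0` = 3L, `1` = 2L, `2` = 0L)
  bytes_per_snp <- ceiling(n / 4)
  codes <- matrix(0L, 4L * bytes_per_snp, p)  # zero bits pad the tail
  if (n > 0L && p > 0L) {
    d <- g$dosages
    cc <- matrix(1L, n, p)  # missing code
    ok <- !is.na(d)
    cc[ok] <- code_of[as.character(d[ok])]
    codes[seq_len(n), ] <- cc
  }
  weights <- c(1L, 4L, 16L, 64L)
  byte_vals <- vapply(seq_len(bytes_per_snp), function(b) {
    rows <- (4L * (b - 1L) + 1L):(4L * b)
    as.integer(weights %*% codes[rows, , drop = FALSE])
  }, integer(p))
  # vapply returns p x bytes_per_snp; transpose to SNP-major byte stream
  stream <- if (p > 0L) as.vector(t(matrix(byte_vals, nrow = p))) else integer()
  con <- file(paths[1], "wb")
  on.exit(close(con))
  writeBin(c(BED_MAGIC, BED_SNP_MAJOR, as.raw(stream)), con)

  bim <- g$snp_meta
  bim$cm <- sprintf("%.17g", bim$cm)  # full precision so round-trips are exact
  utils::write.table(bim[, c("chrom", "id", "cm", "pos", "a1", "a2")],
                     paths[2], quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  ph <- ifelse(is.na(phenotype), "-9", sprintf("%.17g", phenotype))
  fam <- data.frame(g$sample_ids$fid, g$sample_ids$iid, 0L, 0L, 0L, ph)
  utils::write.table(fam, paths[3], quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

#' Remove individuals and SNPs with missing values
#'
#' Individuals with a missing phenotype are dropped first; then SNPs with
#' any missing genotype among the remaining individuals are dropped. This is
#' strict removal, not imputation. Counts removed are reported via
#' `message()` so the filtering can be audited.
#'
#' @param g A [genotype_matrix].
#' @param phenotype Numeric phenotype vector aligned with `g`.
#' @return List with filtered `genotypes` and `phenotype`.
#' @export
filter_missing <- function(g, phenotype) {
  stopifnot(inherits(g, "genotype_matrix"),
            length(phenotype) == nrow(g$dosages))
  keep_ind <- !is.na(phenotype)
  if (!any(keep_ind)) stop("all individuals removed: no non-missing phenotypes")
  d <- g$dosages[keep_ind, , drop = FALSE]
  keep_snp <- colSums(is.na(d)) == 0L
  message("filter_missing: removed ", sum(!keep_ind),
          " individual(s) with missing phenotype, then ",
          sum(!keep_snp), " SNP(s) with missing genotypes")
  list(genotypes = g[keep_ind, keep_snp],
       phenotype = phenotype[keep_ind])
}
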