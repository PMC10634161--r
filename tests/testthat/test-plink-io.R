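test_that("hand-packed .bed bytes decode to the documented dosages", {
  # 4 individuals, 2 SNPs, codes packed lowest-bits-first:
  # SNP1: hom A1 (00), het (10), hom A2 (11), missing (01) -> byte 0x78
  # SNP2: all hom A1 (00) -> byte 0x00
  prefix <- tempfile()
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x78, 0x00)), paste0(prefix, ".bed"))
  writeLines(c("1\trs1\t0\t100\tA\tG", "1\trs2\t0\t200\tC\tT"),
             paste0(prefix, ".bim"))
  writeLines(sprintf("F%d\tI%d\t0\t0\t0\t%s", 1:4, 1:4,
                     c("1.5", "-9", "0", "2.25")),
             paste0(prefix, ".fam"))

  d <- read_plink(prefix)
  expect_equal(d$genotypes$dosages[, 1], c(2L, 1L, 0L, NA_integer_))
  expect_equal(d$genotypes$dosages[, 2], rep(2L, 4))
  # .fam column 6: -9 and 0 are the missing sentinels
  expect_equal(is.na(d$phenotype), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(d$phenotype[c(1, 4)], c(1.5, 2.25))

  # writing the same matrix back reproduces the byte stream exactly
  out <- tempfile()
  write_plink(d$genotypes, d$phenotype, out)
  expect_identical(readBin(paste0(out, ".bed"), "raw", 10),
                   as.raw(c(0x6c, 0x1b, 0x01, 0x78, 0x00)))

  # allele-2 counting flips the dosages
  flipped <- read_plink(prefix, count_allele = "a2")
  expect_equal(flipped$genotypes$dosages[, 1], c(0L, 1L, 2L, NA_integer_))
})

test_that("an individual homozygous for allele2 has dosage 0 under A1 counting", {
  g <- genotype_matrix(matrix(0L, 1, 1))
  prefix <- tempfile()
  write_plink(g, 1.0, prefix)
  # dosage 0 = hom A2 = code 11 -> byte 0x03
  expect_identical(readBin(paste0(prefix, ".bed"), "raw", 4)[4], as.raw(0x03))
  expect_equal(read_plink(prefix)$genotypes$dosages, matrix(0L, 1, 1))
})

test_that("round-trip is bit-exact across sizes that exercise byte padding", {
  for (n in c(1:7, 100)) {
    for (p in c(0, 1, 63, 64, 65)) {
      g <- random_genotypes(n, p, missing_rate = 0.1, seed = n * 1000 + p)
      set.seed(n + p)
      y <- rnorm(n)
      y[sample.int(n, 1)] <- NA
      prefix <- tempfile()
      write_plink(g, y, prefix)
      rt <- read_plink(prefix)
      expect_identical(rt$genotypes$dosages, g$dosages)
      expect_equal(rt$genotypes$snp_meta, g$snp_meta,
                   ignore_attr = TRUE, tolerance = 0)
      expect_identical(rt$genotypes$sample_ids$iid, g$sample_ids$iid)
      expect_identical(rt$phenotype, y)
      # SNP-major packing: each SNP occupies ceiling(n/4) bytes after the magic
      expect_identical(file.size(paste0(prefix, ".bed")),
                       3 + ceiling(n / 4) * p)
    }
  }
})

test_that("empty-SNP matrix writes a .bed of exactly the 3 magic bytes", {
  g <- random_genotypes(5, 0)
  prefix <- tempfile()
  write_plink(g, rnorm(5), prefix)
  expect_identical(readBin(paste0(prefix, ".bed"), "raw", 10),
                   as.raw(c(0x6c, 0x1b, 0x01)))
})

test_that("malformed filesets are rejected with informative errors", {
  g <- random_genotypes(6, 4)
  prefix <- tempfile()
  write_plink(g, rnorm(6), prefix)

  expect_error(read_plink(tempfile()), "missing PLINK file")

  bad <- tempfile()
  file.copy(paste0(prefix, c(".bim", ".fam")), paste0(bad, c(".bim", ".fam")))
  writeBin(as.raw(c(0xde, 0xad, 0x01, 0x00)), paste0(bad, ".bed"))
  expect_error(read_plink(bad), "magic")

  raw <- readBin(paste0(prefix, ".bed"), "raw", file.size(paste0(prefix, ".bed")))
  raw[3] <- as.raw(0x00)  # individual-major mode
  writeBin(raw, paste0(bad, ".bed"))
  expect_error(read_plink(bad), "SNP-major")

  full <- readBin(paste0(prefix, ".bed"), "raw",
                  file.size(paste0(prefix, ".bed")))
  writeBin(c(full, as.raw(0)), paste0(bad, ".bed"))
  expect_error(read_plink(bad), "inconsistent")
})

test_that("separate phenotype file overrides .fam column 6", {
  g <- random_genotypes(4, 3)
  prefix <- tempfile()
  write_plink(g, c(1, 2, 3, 4), prefix)
  ph <- tempfile()
  writeLines(c("FID IID TRAIT",
               sprintf("%s %s %s", g$sample_ids$fid[c(3, 1, 2)],
                       g$sample_ids$iid[c(3, 1, 2)], c("30", "10", "20"))),
             ph)
  d <- read_plink(prefix, pheno_file = ph)
  # matched by FID/IID, not file order; absent individual 4 -> NA
  expect_equal(d$phenotype, c(10, 20, 30, NA))
})

test_that("filter_missing drops phenotype-missing individuals first, then missing SNPs", {
  d <- matrix(0:2, 4, 3)
  d[2, 1] <- NA_integer_  # SNP 1 missing only in individual 2
  d[3, 2] <- NA_integer_  # SNP 2 missing in a phenotyped individual
  g <- genotype_matrix(d)
  y <- c(1.2, NA, 0.7, 0.3)

  res <- suppressMessages(filter_missing(g, y))
  # individual 2 dropped => SNP 1 retained; SNP 2 dropped
  expect_equal(nrow(res$genotypes$dosages), 3)
  expect_equal(res$genotypes$snp_meta$id, c("snp1", "snp3"))
  expect_equal(res$phenotype, c(1.2, 0.7, 0.3))
  expect_false(anyNA(res$genotypes$dosages))

  # identity on clean data, and idempotent
  clean <- random_genotypes(10, 6)
  yc <- rnorm(10)
  r1 <- suppressMessages(filter_missing(clean, yc))
  expect_identical(r1$genotypes$dosages, clean$dosages)
  r2 <- suppressMessages(filter_missing(r1$genotypes, r1$phenotype))
  expect_identical(r2$genotypes$dosages, r1$genotypes$dosages)
  expect_identical(r2$phenotype, r1$phenotype)

  expect_error(suppressMessages(filter_missing(g, c(NA, NA, NA, NA))),
               "all individuals removed")
})
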