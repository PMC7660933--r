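test_that("summary-stats parsing is an identity on well-formed input and honors column maps", {
  df <- make_sumstats_df(3)
  f1 <- tempfile(fileext = ".tsv")
  write.table(df, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_summary_stats(f1)
  expect_s3_class(tab, "summary_stats")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$beta, df$BETA)
  expect_equal(tab$snp_id, df$SNP)
  expect_equal(attr(tab, "n_dropped"), 0)

  # shuffled column order with nonstandard names, mapped back
  df2 <- df[, c("P", "BETA", "SNP", "SE", "EAF", "N", "A2", "A1", "BP", "CHR")]
  names(df2) <- c("pv", "eff", "marker", "stderr", "freq", "nn", "ref", "alt",
                  "position", "chrom")
  f2 <- tempfile(fileext = ".tsv")
  write.table(df2, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  tab2 <- read_summary_stats(f2, column_map = c(
    snp_id = "marker", chrom = "chrom", pos = "position",
    effect_allele = "alt", other_allele = "ref", beta = "eff", se = "stderr",
    n = "nn", eaf = "freq", pval = "pv"))
  expect_equal(tab2, tab, ignore_attr = TRUE)

  expect_error(read_summary_stats(f2), "missing mandatory column")
})

test_that("invariant-violating rows are dropped with a warning count", {
  df <- make_sumstats_df(4)
  df$SE[2] <- 0
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(tab <- read_summary_stats(f), "1 row")
  expect_equal(nrow(tab), 3)
  expect_equal(attr(tab, "n_dropped"), 1)
  expect_false("rs2" %in% tab$snp_id)

  df$SE <- 0
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressWarnings(read_summary_stats(f)), "no valid rows")
})

test_that("write/read round trip preserves all numeric fields exactly", {
  set.seed(7)
  df <- make_sumstats_df(5)
  df$BETA <- rnorm(5) / 3        # full-precision doubles
  df$SE <- runif(5, 0.001, 0.01)
  df$P <- runif(5) * 1e-9
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE,
              # high precision on the way in so the oracle is the df itself
              )
  tab <- read_summary_stats(f)
  f2 <- tempfile(fileext = ".tsv")
  write_summary_stats(tab, f2)
  tab2 <- read_summary_stats(f2)
  expect_identical(tab2$beta, tab$beta)
  expect_identical(tab2$se, tab$se)
  expect_identical(tab2$eaf, tab$eaf)
  expect_identical(tab2$pval, tab$pval)
})

test_that("estimate_ld matches a brute-force two-pass Pearson oracle", {
  set.seed(11)
  n <- 50; m <- 6
  dos <- matrix(sample(0:2, n * m, replace = TRUE, prob = c(.4, .4, .2)), n, m)
  colnames(dos) <- paste0("v", 1:m)
  dos[, 4] <- dos[, 2]                      # exact copy
  panel <- as_reference_panel(dos)
  ld <- estimate_ld(panel)
  expect_equal(diag(ld$sigma), rep(1, m), ignore_attr = TRUE)
  expect_equal(ld$sigma["v2", "v4"], 1.0)
  for (i in 1:m) for (j in 1:m) {
    expect_equal(ld$sigma[i, j], pearson_brute(dos[, i], dos[, j]),
                 tolerance = 1e-12)
  }
  # shrinkage pulls off-diagonals toward zero, keeps unit diagonal
  lds <- estimate_ld(panel, lambda = 0.5)
  expect_equal(lds$sigma[1, 2], 0.5 * ld$sigma[1, 2], tolerance = 1e-12)
  expect_equal(diag(lds$sigma), rep(1, m), ignore_attr = TRUE)
})

test_that("monomorphic SNPs are rejected by name and missing dosages mean-imputed", {
  dos <- cbind(a = c(1, 1, 1, 1), b = c(0, 1, 2, 1))
  expect_error(as_reference_panel(dos), "monomorphic.*a")
  dos2 <- cbind(a = c(0, NA, 2, 1), b = c(0, 1, 2, 1))
  p <- as_reference_panel(dos2)
  expect_equal(unname(p$dosages[2, "a"]), 1)   # mean of 0,2,1
})

test_that("VCF panels load with GT converted to ALT dosage", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tI1\tI2\tI3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0|1\t1|1\t0|0",
    "1\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t./.\t0/1\t1/1"
  )
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  p <- read_reference_panel(f)
  expect_equal(p$snp_ids, c("rs1", "rs2", "rs3"))
  expect_equal(unname(p$dosages[, "rs1"]), c(0, 1, 2))
  expect_equal(unname(p$dosages[, "rs2"]), c(1, 2, 0))
  # missing genotype mean-imputed from the observed 1 and 2
  expect_equal(unname(p$dosages[, "rs3"]), c(1.5, 1, 2))
})

test_that("harmonize flips swapped alleles, drops palindromes/mismatches, and is idempotent", {
  X <- as_ss(make_sumstats_df(4))
  Y <- X
  # rs2: swapped alleles in Y; rs3: irreconcilable alleles
  Y$effect_allele[2] <- X$other_allele[2]; Y$other_allele[2] <- X$effect_allele[2]
  Y$beta[2] <- X$beta[2] * 1.1   # value itself arbitrary
  Y$effect_allele[3] <- "T"; Y$other_allele[3] <- "C"
  hp <- harmonize(X, Y)
  expect_setequal(hp$snp_ids, c("rs1", "rs2", "rs4"))
  expect_equal(hp$statsY$beta[hp$snp_ids == "rs2"], -X$beta[2] * 1.1)
  expect_equal(hp$statsY$eaf[hp$snp_ids == "rs2"], 1 - Y$eaf[2])
  expect_equal(hp$flip_log$action[hp$flip_log$snp_id == "rs2"], "flip_beta_Y")
  expect_equal(hp$flip_log$action[hp$flip_log$snp_id == "rs3"],
               "drop_allele_mismatch")

  # idempotent: harmonizing the harmonized pair changes nothing
  hp2 <- harmonize(hp$statsX, hp$statsY)
  expect_equal(hp2$statsX$beta, hp$statsX$beta)
  expect_equal(hp2$statsY$beta, hp$statsY$beta)
  expect_equal(nrow(hp2$flip_log), 0)

  # identical coding: empty flip log
  hp3 <- harmonize(X, X)
  expect_equal(nrow(hp3$flip_log), 0)
  expect_equal(hp3$statsY$beta, hp3$statsX$beta)
})

test_that("palindromic SNPs are dropped by default and kept on request", {
  X <- as_ss(make_sumstats_df(3))
  X$effect_allele[1] <- "A"; X$other_allele[1] <- "T"
  Y <- X
  hp <- harmonize(X, Y)
  expect_false("rs1" %in% hp$snp_ids)
  expect_true("drop_palindromic" %in% hp$flip_log$action)
  hp2 <- harmonize(X, Y, strict_palindromes = FALSE)
  expect_true("rs1" %in% hp2$snp_ids)

  Z <- X; Z$snp_id <- paste0("other", 1:3)
  expect_error(harmonize(X, Z), "no shared SNPs")
})

test_that("BED loci convert to 1-based inclusive coordinates", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("1\t0\t1000\t7", "2\t5000\t6000\t8"), f)
  loci <- read_loci(f)
  expect_equal(loci$start, c(1L, 5001L))
  expect_equal(loci$end, c(1000L, 6000L))
  expect_equal(loci$locus_id, c(7L, 8L))
})
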