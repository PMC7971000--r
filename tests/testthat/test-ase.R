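test_that("SNP discovery reports differing columns in X coordinates", {
  s <- snps_from_alignment("ACGT", "ACTT")
  expect_equal(s$orf_position, 3)
  expect_equal(s$x_base, "G")
  expect_equal(s$y_base, "T")
  expect_equal(nrow(snps_from_alignment("ACGT", "ACGT")), 0)
  # gap and ambiguity columns are never SNPs
  expect_equal(nrow(snps_from_alignment("AC-GT", "ACAGT")), 0)
  expect_equal(nrow(snps_from_alignment("ACNGT", "ACAGT")), 0)
  expect_error(snps_from_alignment("ACG", "AC"), "length")
})

test_that("gap insertion leaves ungapped X coordinates unchanged", {
  x <- "ACGTACGT"; y <- "ACTTACGA"
  base <- snps_from_alignment(x, y)
  # pad both sequences with aligned gap columns
  xg <- "AC--GTACGT"; yg <- "AC--TTACGA"
  expect_equal(snps_from_alignment(xg, yg)$orf_position,
               base$orf_position)
  # a gap in X only shifts alignment columns, not X coordinates
  xg2 <- "ACGTAC-GT"; yg2 <- "ACTTACAGA"
  s2 <- snps_from_alignment(xg2, yg2)
  expect_true(all(s2$orf_position <= nchar(x)))
})

test_that("genotype validation demands hom-ref females and het males", {
  snps <- data.frame(gene_id = "g1", pos = c(10, 20, 30, 40))
  gt <- expand.grid(pos = c(10, 20, 30), sample = c("f1", "f2", "m1", "m2"),
                    stringsAsFactors = FALSE)
  gt$gene_id <- "g1"
  female <- grepl("^f", gt$sample)
  gt$gt <- ifelse(female, "0/0", "0/1")
  # site 20: one female het; site 30: one male hom
  gt$gt[gt$pos == 20 & gt$sample == "f2"] <- "0/1"
  gt$gt[gt$pos == 30 & gt$sample == "m1"] <- "0/0"
  sex <- c(f1 = "female", f2 = "female", m1 = "male", m2 = "male")
  v <- validate_snps(snps, gt, sex)
  expect_equal(v$valid, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(v$reason,
               c("ok", "female_not_hom_ref", "male_not_het", "missing"))
})

test_that("allele read counting sums valid in-ORF depths per gene", {
  annot <- data.frame(gene_id = "g1", orf_start = 101, orf_end = 400)
  rec <- data.frame(
    gene_id = "g1",
    pos = c(150, 250, 350, 500),      # 500 lies outside the ORF
    sample = "m1",
    ref_depth = c(10, 8, 5, 99),
    alt_depth = c(2, 4, 1, 99),
    valid = c(TRUE, TRUE, FALSE, TRUE))  # 350 failed validation
  out <- count_allele_reads(rec, annot)
  expect_equal(out$table$x_reads, 18)
  expect_equal(out$table$y_reads, 6)
  expect_equal(out$table$n_snps, 2L)

  # all-zero depths: gene retained with zero counts
  rec0 <- data.frame(gene_id = "g1", pos = 150, sample = "m1",
                     ref_depth = 0, alt_depth = 0, valid = TRUE)
  out0 <- count_allele_reads(rec0, annot)
  expect_equal(out0$table$x_reads, 0)
  expect_equal(length(out0$excluded), 0)

  # no valid in-ORF SNP at all: gene excluded and listed
  rec1 <- data.frame(gene_id = "g1", pos = 500, sample = "m1",
                     ref_depth = 3, alt_depth = 1, valid = TRUE)
  out1 <- count_allele_reads(rec1, annot)
  expect_identical(out1$excluded, "g1")
})

test_that("TMM factors are 1 for identical or rescaled libraries", {
  set.seed(6)
  m <- matrix(rnbinom(40, mu = 100, size = 5), 20, 2)
  m[, 2] <- m[, 1]
  expect_equal(unname(tmm_factors(m)), c(1, 1))
  # pure depth change, composition unchanged: the library-size term absorbs
  # the constant and the factors stay 1
  m2 <- cbind(m[, 1], m[, 1] * 4)
  expect_equal(unname(tmm_factors(m2)), c(1, 1), tolerance = 1e-12)
  expect_error(tmm_factors(cbind(m[, 1], 0)), "all-zero")
  expect_error(tmm_factors(m[, 1, drop = FALSE]), "2 libraries")
})

test_that("TMM matches a step-by-step trimmed-mean oracle on 6 genes", {
  counts <- matrix(c(100, 200, 300, 400, 500, 50,
                     80, 400, 290, 410, 1000, 45), 6, 2,
                   dimnames = list(paste0("g", 1:6), c("L1", "L2")))
  lib <- colSums(counts)
  ## independent hand computation of the trimmed mean of M-values -------
  uq <- apply(counts, 2, quantile, 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))          # reference library
  j <- if (ref == 1) 2 else 1                   # the other library
  p_obs <- counts[, j] / lib[j]; p_ref <- counts[, ref] / lib[ref]
  m <- log2(p_obs / p_ref); a <- 0.5 * log2(p_obs * p_ref)
  n <- 6
  keep <- rank(m) >= floor(n * 0.3) + 1 & rank(m) <= n - floor(n * 0.3) &
    rank(a) >= floor(n * 0.05) + 1 & rank(a) <= n - floor(n * 0.05)
  w <- 1 / ((lib[j] - counts[, j]) / (lib[j] * counts[, j]) +
              (lib[ref] - counts[, ref]) / (lib[ref] * counts[, ref]))
  f_other <- 2^(sum(m[keep] * w[keep]) / sum(w[keep]))
  expected <- c(1, 1); expected[j] <- f_other
  expected <- expected / exp(mean(log(expected)))
  ## --------------------------------------------------------------------
  expect_equal(unname(tmm_factors(counts)), unname(expected),
               tolerance = 1e-12)
})

test_that("TMM agrees with the reference Bioconductor implementation", {
  skip_if_not_installed("edgeR")
  set.seed(8)
  for (i in 1:3) {
    m <- matrix(rnbinom(200, mu = 150, size = 2) + 1, 50, 4)
    mine <- tmm_factors(m)
    theirs <- edgeR::calcNormFactors(m, method = "TMM")
    expect_equal(unname(mine), unname(theirs), tolerance = 1e-10)
  }
})

test_that("normalization arithmetic and scaling behave as documented", {
  tab <- data.frame(gene_id = "g1", sample = "m1",
                    x_reads = 100, y_reads = 40, n_snps = 4L)
  out <- normalize_allele_expression(tab, c(m1 = 1e6))
  expect_equal(out$ref_expr, 25)
  expect_equal(out$alt_expr, 10)
  out2 <- normalize_allele_expression(tab, c(m1 = 2e6))
  expect_equal(out2$ref_expr, 12.5)
  expect_error(normalize_allele_expression(tab, c(m1 = 0)), "positive")
  # un-normalized by SNP count, expression is additive over disjoint
  # SNP subsets
  tab_a <- data.frame(gene_id = "g1", sample = "m1",
                      x_reads = 60, y_reads = 30, n_snps = 3L)
  tab_b <- data.frame(gene_id = "g1", sample = "m1",
                      x_reads = 40, y_reads = 10, n_snps = 1L)
  oa <- normalize_allele_expression(tab_a, c(m1 = 1e6))
  ob <- normalize_allele_expression(tab_b, c(m1 = 1e6))
  expect_equal(oa$ref_expr * 3 + ob$ref_expr * 1, out$ref_expr * 4)
})
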