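test_that("the expression filter uses a strict per-sample threshold", {
  m <- rbind(low_in_one = c(1.2, 0, 0),
             exactly_one = c(1, 1, 1),
             zero = c(0, 0, 0),
             high = c(5, 8, 2))
  x <- make_expr(m)
  kept <- filter_expressed(x, 1)
  expect_identical(rownames(kept$values), c("low_in_one", "high"))
  # idempotent and monotone in the threshold
  expect_identical(filter_expressed(kept, 1)$values, kept$values)
  stricter <- filter_expressed(x, 4)
  expect_true(all(rownames(stricter$values) %in% rownames(kept$values)))
  # empty matrix passes through
  empty <- subset_expr(x, genes = integer(0))
  expect_identical(nrow(filter_expressed(empty)$values), 0L)
})

test_that("outgroup calibration divides by the matched-tissue ortholog", {
  foc <- make_expr(matrix(c(4, 6, 8, 10), 2, byrow = TRUE,
                          dimnames = list(c("g1", "g2"), NULL)),
                   sex = "male")
  og <- make_expr(matrix(c(2, 1), 2,
                         dimnames = list(c("o1", "o2"), "out_leaf")),
                  sex = "monoecious", species = "outgroup")
  map <- data.frame(focal_gene_id = c("g1", "g2"),
                    outgroup_gene_id = c("o1", "o2"))
  cal <- calibrate_by_outgroup(foc, og, map)
  expect_equal(unname(cal$calibrated$values["g1", ]), c(2, 3))
  expect_equal(unname(cal$calibrated$values["g2", ]), c(8, 10))
  expect_equal(nrow(cal$excluded), 0)

  # zero outgroup denominator: the gene is excluded and reported
  og0 <- make_expr(matrix(c(2, 0), 2,
                          dimnames = list(c("o1", "o2"), "out_leaf")),
                   sex = "monoecious", species = "outgroup")
  cal0 <- calibrate_by_outgroup(foc, og0, map)
  expect_identical(cal0$excluded$gene_id, "g2")
  expect_identical(cal0$excluded$reason, "low_outgroup")

  # genes absent from the map are flagged, not silently dropped
  cal1 <- calibrate_by_outgroup(foc, og, map[1, , drop = FALSE])
  expect_identical(cal1$excluded$reason, "no_ortholog")

  # missing outgroup tissue errors and names the tissue
  foc2 <- make_expr(matrix(1:2, 1, dimnames = list("g1", NULL)),
                    tissue = c("leaf", "flower"))
  expect_error(calibrate_by_outgroup(foc2, og, map), "flower")
})

test_that("calibration is scale-equivariant in the focal sample", {
  set.seed(1)
  foc <- make_expr(matrix(runif(20, 1, 10), 10,
                          dimnames = list(paste0("g", 1:10), NULL)))
  og <- make_expr(matrix(runif(10, 1, 5), 10,
                         dimnames = list(paste0("o", 1:10), "out_leaf")),
                  species = "outgroup", sex = "monoecious")
  map <- data.frame(focal_gene_id = paste0("g", 1:10),
                    outgroup_gene_id = paste0("o", 1:10))
  base <- calibrate_by_outgroup(foc, og, map)$calibrated$values
  foc2 <- foc
  foc2$values[, 1] <- foc2$values[, 1] * 3
  scaled <- calibrate_by_outgroup(foc2, og, map)$calibrated$values
  expect_equal(scaled[, 1], base[, 1] * 3)
  expect_equal(scaled[, 2], base[, 2])
})

test_that("region summary reports ratio-of-aggregates and a rank-sum test", {
  set.seed(4)
  vals <- matrix(rlnorm(60), 60, 1, dimnames = list(paste0("g", 1:60), "s1"))
  x <- make_expr(vals)
  annot <- data.frame(gene_id = paste0("g", 1:60),
                      class = rep(c("XY-paired", "autosome"), each = 30))
  rs <- region_summary(x, annot, "s1")
  expect_equal(rs$ratio_of_medians,
               rs$median_sex_specific / rs$median_autosome)
  expect_equal(rs$ratio_of_means, rs$mean_sex_specific / rs$mean_autosome)
  expect_gte(rs$W, 0)

  # identical gene sets: both ratios 1 and a null rank-sum p
  vals2 <- matrix(rep(rlnorm(30), 2), 60, 1,
                  dimnames = list(paste0("g", 1:60), "s1"))
  rs2 <- region_summary(make_expr(vals2), annot, "s1")
  expect_equal(rs2$ratio_of_medians, 1)
  expect_equal(rs2$ratio_of_means, 1)
  expect_gt(rs2$p, 0.9)
})

test_that("percent reduction is the relative drop of the male ratio", {
  expect_equal(percent_reduction(0.7, 0.7), 0)
  expect_equal(percent_reduction(0.5, 1.0), 50)
  expect_error(percent_reduction(0.5, 0), "positive")
})

test_that("global correlations match direct computation on small vectors", {
  # monotone transform: spearman rho exactly 1
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(global_correlation(x, 2 * x, "spearman")$coefficient, 1)
  # 5-gene toy: rho from the rank formula 1 - 6*sum(d^2)/(n(n^2-1))
  y <- c(2, 7, 1, 8, 3)
  d <- rank(x) - rank(y)
  rho_formula <- 1 - 6 * sum(d^2) / (5 * (25 - 1))
  expect_equal(global_correlation(x, y, "spearman")$coefficient,
               rho_formula)
  # pearson on log10 scale equals cor() of the transformed values
  r <- global_correlation(x, y, "pearson_log10", pseudocount = 0.01)
  expect_equal(r$coefficient, cor(log10(x + 0.01), log10(y + 0.01)))
  expect_error(global_correlation(1:2, 2:3), "at least 3")
})

test_that("a random permutation decorrelates large vectors", {
  set.seed(11)
  x <- rlnorm(1000)
  y <- sample(x)
  expect_lt(abs(global_correlation(x, y, "spearman")$coefficient), 0.1)
})

test_that("rank-sum p-values behave at the symmetric and extreme ends", {
  a <- c(1, 5, 3, 7, 9, 2)
  w <- rank_sum_test(a, a)
  expect_gt(w$p_two_sided, 0.9)
  # complete separation gives the minimal exact p for the sizes
  lo <- 1:5; hi <- 11:15
  w2 <- rank_sum_test(hi, lo)
  expect_equal(w2$W, 25)
  expect_equal(w2$p_two_sided, 2 / choose(10, 5))
  # all values identical: defined degenerate answer
  expect_equal(rank_sum_test(rep(2, 4), rep(2, 6))$p_two_sided, 1)
})

test_that("rank-sum p matches exhaustive enumeration on 5-vs-5 toys", {
  set.seed(2)
  for (i in 1:5) {
    v <- sample(1:40, 10)
    a <- v[1:5]; b <- v[6:10]
    expect_equal(rank_sum_test(a, b)$p_two_sided, enum_rank_sum(a, b))
  }
})

test_that("null region summaries give uniform rank-sum p across seeds", {
  # sex-specific and autosomal genes drawn from the same law
  set.seed(99)
  ps <- replicate(200, {
    vals <- matrix(rlnorm(80), 80, 1,
                   dimnames = list(paste0("g", 1:80), "s1"))
    annot <- data.frame(gene_id = paste0("g", 1:80),
                        class = rep(c("XY-paired", "autosome"), c(20, 60)))
    region_summary(make_expr(vals), annot, "s1")$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
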