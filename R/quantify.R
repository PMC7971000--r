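#' Keep genes expressed above a TPM threshold in at least one sample
#'
#' A gene is retained when its value is strictly greater than `threshold`
#' in one or more samples; row order is preserved. The default of 1 TPM is
#' the usual expressed-gene cutoff for bulk RNA-Seq.
#'
#' @param x an [expr_set()].
#' @param threshold non-negative expression cutoff (strict inequality).
#' @return An `expr_set` with the retained genes.
#' @export
filter_expressed <- function(x, threshold = 1) {
  stopifnot(inherits(x, "expr_set"), threshold >= 0)
  if (nrow(x$values) == 0) return(x)
  keep <- apply(x$values > threshold, 1, any)
  subset_expr(x, genes = which(keep))
}

#' Calibrate focal expression by the outgroup ortholog
#'
#' Divides each focal gene's expression by the expression of its ortholog
#' in a relative species without sex chromosomes, removing gene-specific
#' expression-level effects so sex-linked and autosomal genes become
#' comparable. Each focal sample is calibrated against the outgroup library
#' of the same tissue (outgroup replicates for a tissue are averaged).
#' Genes with no ortholog, or whose outgroup expression falls at or below
#' `outgroup_min` in the matched tissue, are excluded.
#'
#' @param focal,outgroup [expr_set()] objects; every focal tissue must be
#'   present among the outgroup samples.
#' @param map ortholog data.frame (focal_gene_id, outgroup_gene_id), 1:1.
#' @param outgroup_min outgroup expression at or below this is treated as an
#'   unusable denominator (default 0: exclude only exact zeros).
#' @return A list: `calibrated` (expr_set in ratio units), `excluded`
#'   (data.frame gene_id, reason: "no_ortholog" / "low_outgroup").
#' @export
calibrate_by_outgroup <- function(focal, outgroup, map, outgroup_min = 0) {
  stopifnot(inherits(focal, "expr_set"), inherits(outgroup, "expr_set"))
  if (anyDuplicated(map$focal_gene_id) || anyDuplicated(map$outgroup_gene_id))
    stop("ortholog map must be one-to-one")
  tissues <- unique(focal$samples$tissue)
  missing_t <- setdiff(tissues, outgroup$samples$tissue)
  if (length(missing_t) > 0) {
    stop("no outgroup sample for tissue(s): ",
         paste(missing_t, collapse = ", "))
  }
  ## per-tissue outgroup expression (mean across outgroup replicates)
  og_tissue <- vapply(tissues, function(tt) {
    cols <- which(outgroup$samples$tissue == tt)
    rowMeans(outgroup$values[, cols, drop = FALSE])
  }, numeric(nrow(outgroup$values)))
  rownames(og_tissue) <- rownames(outgroup$values)

  idx <- match(rownames(focal$values), map$focal_gene_id)
  og_id <- map$outgroup_gene_id[idx]
  has_map <- !is.na(og_id) & og_id %in% rownames(og_tissue)

  og_vals <- matrix(NA_real_, nrow(focal$values), length(tissues),
                    dimnames = list(rownames(focal$values), tissues))
  og_vals[has_map, ] <- og_tissue[og_id[has_map], , drop = FALSE]
  usable <- has_map & apply(og_vals > outgroup_min, 1, all)
  usable[is.na(usable)] <- FALSE

  excluded <- data.frame(
    gene_id = rownames(focal$values)[!usable],
    reason = ifelse(has_map[!usable], "low_outgroup", "no_ortholog"),
    stringsAsFactors = FALSE)

  vals <- focal$values[usable, , drop = FALSE]
  denom <- og_vals[usable, match(focal$samples$tissue, tissues),
                   drop = FALSE]
  calibrated <- expr_set(vals / denom, focal$samples)
  list(calibrated = calibrated, excluded = excluded)
}

#' Summarize sex-specific-region vs autosomal expression for one sample
#'
#' Computes, over calibrated expression in one library, the median and mean
#' of sex-specific-region genes (X/Y pairs and X-specific genes of the
#' non-recombining region) and of autosomal genes, the ratios of those
#' aggregates (median/median, mean/mean), and a Wilcoxon rank-sum test of
#' the two gene sets (sex-specific ranked first).
#'
#' @param calibrated an [expr_set()] in calibrated units.
#' @param annot annotation data.frame with gene_id and class.
#' @param sample sample id (one column of `calibrated`).
#' @return data.frame with one row: sample, n_sex_specific, n_autosome,
#'   median_sex_specific, mean_sex_specific, median_autosome, mean_autosome,
#'   ratio_of_medians, ratio_of_means, W, p.
#' @export
region_summary <- function(calibrated, annot, sample) {
  stopifnot(inherits(calibrated, "expr_set"))
  if (!sample %in% colnames(calibrated$values)) {
    stop("unknown sample: ", sample)
  }
  cls <- annot$class[match(rownames(calibrated$values), annot$gene_id)]
  v <- calibrated$values[, sample]
  sex_specific <- v[cls %in% c("XY-paired", "X-specific", "Y-specific")]
  autosome <- v[cls %in% "autosome"]
  if (length(sex_specific) < 2 || length(autosome) < 2) {
    stop("need at least 2 genes in each of the sex-specific and ",
         "autosome classes")
  }
  w <- rank_sum_test(sex_specific, autosome)
  data.frame(
    sample = sample,
    n_sex_specific = length(sex_specific),
    n_autosome = length(autosome),
    median_sex_specific = stats::median(sex_specific),
    mean_sex_specific = mean(sex_specific),
    median_autosome = stats::median(autosome),
    mean_autosome = mean(autosome),
    ratio_of_medians = stats::median(sex_specific) / stats::median(autosome),
    ratio_of_means = mean(sex_specific) / mean(autosome),
    W = w$W, p = w$p_two_sided,
    stringsAsFactors = FALSE)
}

#' Percent reduction of a male ratio relative to the female ratio
#'
#' Expresses how much lower the male sex-specific/autosome expression ratio
#' is than the female one: `100 * (1 - male_ratio / female_ratio)`. A value
#' below 50 for an uncompensated X-linked complement indicates partial
#' compensation or compensation of some genes.
#'
#' @param male_ratio,female_ratio aggregate expression ratios;
#'   `female_ratio` must be positive.
#' @return Percent reduction (can be negative when male exceeds female).
#' @export
percent_reduction <- function(male_ratio, female_ratio) {
  if (!is.finite(female_ratio) || female_ratio <= 0) {
    stop("female_ratio must be positive")
  }
  100 * (1 - male_ratio / female_ratio)
}

#' Correlation between two expression vectors
#'
#' `pearson_log10` applies log10 after adding `pseudocount` (to rescue
#' zeros) and computes Pearson's r, matching the usual log-scale expression
#' scatter; `spearman` ranks the raw values.
#'
#' @param x,y aligned expression vectors over shared genes, length >= 3.
#' @param method "pearson_log10" or "spearman".
#' @param pseudocount added before log10 for the Pearson variant.
#' @return list(coefficient, n, p).
#' @export
global_correlation <- function(x, y, method = c("pearson_log10", "spearman"),
                               pseudocount = 0.01) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must be aligned")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (method == "pearson_log10") {
    ct <- stats::cor.test(log10(x + pseudocount), log10(y + pseudocount),
                          method = "pearson")
  } else {
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
  }
  list(coefficient = unname(ct$estimate), n = length(x), p = ct$p.value)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Reports the rank-sum statistic W for the first argument and a two-sided
#' p-value: exact enumeration when both groups together hold at most 20
#' observations and there are no ties, otherwise the normal approximation
#' with tie and continuity correction.
#'
#' @param a,b numeric vectors (each non-empty).
#' @return list(W, p_two_sided).
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("both groups must be non-empty")
  if (length(unique(c(a, b))) == 1) {
    # degenerate: every value identical across both groups
    return(list(W = length(a) * length(b) / 2, p_two_sided = 1))
  }
  exact <- (length(a) + length(b)) <= 20
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(W = unname(wt$statistic), p_two_sided = wt$p.value)
}
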