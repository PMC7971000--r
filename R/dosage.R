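#' Per-gene expression ratios between alleles and sexes
#'
#' From per-tissue mX, mY and fXX, derives the ratios used to read dosage
#' compensation: mX/fXX (male X vs the female two-X total; 0.5 under the
#' no-compensation null where each allele transcribes at the same
#' per-allele rate), mY/mX (Y-allele decay), and mXY/fXX (total male vs
#' female, (mX+mY)/fXX, 1 under the null). log2 forms are added where the
#' ratio is positive; ratios are undefined (NA) when their denominator is
#' zero or missing. A per-gene summary `median_mx_fxx` takes the median of
#' mX/fXX over tissues where it is defined.
#'
#' @param abt data.frame from [allele_expression_by_tissue()] (gene_id,
#'   tissue, mX, mY, fXX).
#' @param annot optional annotation (gene_id, region, ks) merged onto the
#'   output.
#' @return list(`per_tissue`: gene_id, tissue, mX, mY, fXX, mx_fxx, my_mx,
#'   mxy_fxx and log2 columns; `per_gene`: gene_id, median_mx_fxx,
#'   median_my_mx, median_mxy_fxx, n_tissues, plus region/ks when
#'   annotated).
#' @export
compute_ratios <- function(abt, annot = NULL) {
  r <- abt
  div <- function(num, den) ifelse(!is.na(den) & den > 0, num / den, NA)
  r$mx_fxx <- div(r$mX, r$fXX)
  r$my_mx <- div(r$mY, r$mX)
  r$mxy_fxx <- div(r$mX + r$mY, r$fXX)
  lg <- function(x) ifelse(!is.na(x) & x > 0, log2(x), NA)
  r$log2_mx_fxx <- lg(r$mx_fxx)
  r$log2_my_mx <- lg(r$my_mx)
  r$log2_mxy_fxx <- lg(r$mxy_fxx)

  med <- function(col) {
    as.numeric(tapply(r[[col]], r$gene_id, function(v)
      if (all(is.na(v))) NA else stats::median(v, na.rm = TRUE)))
  }
  genes <- sort(unique(r$gene_id))
  per_gene <- data.frame(
    gene_id = genes,
    median_mx_fxx = med("mx_fxx"),
    median_my_mx = med("my_mx"),
    median_mxy_fxx = med("mxy_fxx"),
    n_tissues = as.integer(tapply(!is.na(r$mx_fxx), r$gene_id, sum)),
    stringsAsFactors = FALSE)
  if (!is.null(annot)) {
    keep <- intersect(c("region", "ks"), names(annot))
    per_gene <- cbind(per_gene,
                      annot[match(genes, annot$gene_id), keep, drop = FALSE])
    rownames(per_gene) <- NULL
  }
  list(per_tissue = r, per_gene = per_gene)
}

#' Kernel-density peaks of a ratio distribution
#'
#' Estimates a Gaussian kernel density of the ratios on `[0, max_ratio_clip]`
#' (values above the clip are discarded as outliers, matching how ratio
#' histograms are usually truncated) and reports the strict local maxima of
#' the density, rounded to the histogram bin resolution and ordered by
#' density, highest first. The bandwidth defaults to Silverman's
#' rule-of-thumb on the clipped data.
#'
#' @param ratios numeric vector; at least 20 finite values are required for
#'   a stable density.
#' @param bandwidth kernel bandwidth; `NULL` for Silverman's rule.
#' @param bin_width resolution at which peak locations are reported.
#' @param max_ratio_clip upper clip of the support.
#' @return list(peaks: data.frame(location, density), bandwidth, bin_width,
#'   n, density: the `stats::density` object).
#' @export
ratio_density_peaks <- function(ratios, bandwidth = NULL, bin_width = 0.1,
                                max_ratio_clip = 2.0) {
  x <- ratios[is.finite(ratios) & ratios >= 0 & ratios <= max_ratio_clip]
  if (length(x) < 20) {
    stop("need at least 20 finite ratios in [0, clip]; got ", length(x))
  }
  round_bin <- function(v) round(v / bin_width) * bin_width
  if (length(unique(x)) == 1) {
    # degenerate point mass: the mode is the value itself
    pk <- data.frame(location = round_bin(x[1]), density = Inf)
    return(list(peaks = pk, bandwidth = 0, bin_width = bin_width,
                n = length(x), density = NULL))
  }
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(x)
  d <- stats::density(x, bw = bandwidth, from = 0, to = max_ratio_clip,
                      n = 512)
  y <- d$y
  is_peak <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                 y[2:(length(y) - 1)] > y[3:length(y)], FALSE)
  # boundary maxima count too (a mode pushed against 0 or the clip)
  if (y[1] > y[2]) is_peak[1] <- TRUE
  if (y[length(y)] > y[length(y) - 1]) is_peak[length(y)] <- TRUE
  pk <- data.frame(location = round_bin(d$x[is_peak]),
                   density = y[is_peak])
  # several grid maxima can round to the same bin: keep the densest
  pk <- pk[order(-pk$density), ]
  pk <- pk[!duplicated(pk$location), ]
  rownames(pk) <- NULL
  list(peaks = pk, bandwidth = bandwidth, bin_width = bin_width,
       n = length(x), density = d)
}

#' Classify a gene's dosage-compensation status
#'
#' Uses the per-gene median mX/fXX across tissues: at or above
#' `full_threshold` the male X allele has been up-regulated to (near) the
#' female two-allele level ("compensated"); at or above `partial_threshold`
#' but below full, "partial"; otherwise "uncompensated" (the null sits at
#' 0.5). Genes whose ratio is undefined in every tissue are "unexpressed".
#'
#' @param median_mx_fxx per-gene median mX/fXX (NA allowed).
#' @param full_threshold,partial_threshold classification cutoffs
#'   (inclusive); `partial_threshold` must not exceed `full_threshold`.
#' @return Character vector of labels.
#' @export
classify_gene <- function(median_mx_fxx, full_threshold = 0.9,
                          partial_threshold = 0.75) {
  if (partial_threshold > full_threshold) {
    stop("partial_threshold must be <= full_threshold")
  }
  ifelse(is.na(median_mx_fxx), "unexpressed",
  ifelse(median_mx_fxx >= full_threshold, "compensated",
  ifelse(median_mx_fxx >= partial_threshold, "partial", "uncompensated")))
}

#' Compare a log2 ratio metric between evolutionary strata
#'
#' Summarizes a log2 ratio per region of the non-recombining region
#' (inversion 1 = older stratum, inversion 2 = younger, collinear) and runs
#' pairwise two-sided Mann-Whitney tests between regions. Genes whose
#' metric is undefined (e.g. log2 of a zero ratio) are excluded and
#' counted. Unadjusted p-values carry significance stars (* < 0.05,
#' ** < 0.01); a Holm-adjusted column is reported alongside.
#'
#' @param per_gene data.frame with gene_id, region and the metric column.
#' @param metric name of the metric column, e.g. "median_log2_mxy_fxx".
#' @param regions regions to compare.
#' @return list(`summary`: per-region n, median, mean; `tests`: pairwise
#'   region_a, region_b, W, p, p_holm, stars; `n_excluded`).
#' @export
strata_compare <- function(per_gene, metric,
                           regions = c("inversion1", "inversion2",
                                       "collinear")) {
  v <- per_gene[[metric]]
  if (is.null(v)) stop("no such metric column: ", metric)
  ok <- !is.na(v) & per_gene$region %in% regions
  n_excluded <- sum(per_gene$region %in% regions) - sum(ok)
  d <- data.frame(region = per_gene$region[ok], value = v[ok])
  summ <- do.call(rbind, lapply(regions, function(r) {
    vv <- d$value[d$region == r]
    data.frame(region = r, n = length(vv),
               median = if (length(vv)) stats::median(vv) else NA,
               mean = if (length(vv)) mean(vv) else NA)
  }))
  pairs <- utils::combn(regions, 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- d$value[d$region == pairs[1, k]]
    b <- d$value[d$region == pairs[2, k]]
    if (length(a) < 3 || length(b) < 3) {
      warning("fewer than 3 genes in ", pairs[1, k], " or ", pairs[2, k],
              "; pair skipped")
      return(NULL)
    }
    w <- rank_sum_test(a, b)
    data.frame(region_a = pairs[1, k], region_b = pairs[2, k],
               W = w$W, p = w$p_two_sided, stringsAsFactors = FALSE)
  }))
  if (!is.null(tests) && nrow(tests) > 0) {
    tests$p_holm <- stats::p.adjust(tests$p, method = "holm")
    tests$stars <- ifelse(tests$p < 0.01, "**",
                   ifelse(tests$p < 0.05, "*", "ns"))
  }
  list(summary = summ, tests = tests, n_excluded = n_excluded)
}

#' Correlation of Y/X expression decay with synonymous divergence
#'
#' Spearman rank correlation between per-gene mY/mX and Ks (synonymous
#' X-Y divergence, a proxy for time since recombination arrest). A
#' negative coefficient indicates that older gene pairs have lost more Y
#' expression.
#'
#' @param my_mx per-gene mY/mX values.
#' @param ks matching Ks values.
#' @return list(rho, p, n) over pairs where both are defined (n >= 3).
#' @export
ks_correlation <- function(my_mx, ks) {
  if (length(my_mx) != length(ks)) stop("inputs must be aligned")
  ok <- is.finite(my_mx) & is.finite(ks)
  if (sum(ok) < 3) stop("need at least 3 genes with both mY/mX and Ks")
  ct <- suppressWarnings(
    stats::cor.test(my_mx[ok], ks[ok], method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Fraction of hemizygous X-specific genes that are silenced
#'
#' A gene counts as silenced when its expression never exceeds `threshold`
#' in any sample. High silenced fractions among hemizygous genes suggest
#' gene silencing as a route to transcriptional balance between the sexes.
#'
#' @param x an [expr_set()] restricted to X-specific genes.
#' @param threshold expression cutoff (strict; a gene at exactly the
#'   threshold everywhere is silenced).
#' @return list(n_silenced, n_total, percent) with percent to 1 decimal.
#' @export
silenced_fraction <- function(x, threshold = 1) {
  stopifnot(inherits(x, "expr_set"))
  n_total <- nrow(x$values)
  if (n_total == 0) stop("no X-specific genes supplied")
  silenced <- !apply(x$values > threshold, 1, any)
  n_sil <- sum(silenced)
  list(n_silenced = n_sil, n_total = n_total,
       percent = round(100 * n_sil / n_total, 1))
}

#' Histogram plus kernel density of an expression-ratio distribution
#'
#' @param ratios numeric ratios.
#' @param peaks optional result of [ratio_density_peaks()]; its peaks are
#'   marked with arrows.
#' @param bin_width histogram bin width.
#' @param max_ratio_clip upper plotting limit.
#' @param main plot title.
#' @return Invisibly, the peak set used.
#' @export
plot_ratio_distribution <- function(ratios, peaks = NULL, bin_width = 0.1,
                                    max_ratio_clip = 2.0,
                                    main = "expression ratio") {
  x <- ratios[is.finite(ratios) & ratios >= 0 & ratios <= max_ratio_clip]
  if (is.null(peaks)) {
    peaks <- ratio_density_peaks(x, bin_width = bin_width,
                                 max_ratio_clip = max_ratio_clip)
  }
  graphics::hist(x, breaks = seq(0, max_ratio_clip, by = bin_width),
                 freq = FALSE, main = main, xlab = "ratio",
                 col = "grey85", border = "white")
  if (!is.null(peaks$density)) {
    graphics::lines(peaks$density, col = "red", lwd = 2)
    graphics::points(peaks$peaks$location, peaks$peaks$density,
                     pch = 25, bg = "red", col = "red")
  }
  invisible(peaks)
}
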