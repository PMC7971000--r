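#' Diagnostic SNPs from an aligned X/Y allele pair
#'
#' Scans two aligned sequences of equal length and reports every column
#' where both alleles carry a plain, differing nucleotide (A/C/G/T,
#' case-insensitive). Columns containing a gap or an ambiguity code are
#' never called. Positions are reported in ungapped X-allele coordinates,
#' 1-based, so they stay stable if the alignment is padded with gaps.
#'
#' @param x_seq,y_seq aligned sequences (character scalars, equal length).
#' @param gene_id optional gene id carried into the output.
#' @return data.frame: gene_id, orf_position (ungapped X coordinate),
#'   x_base, y_base.
#' @export
snps_from_alignment <- function(x_seq, y_seq, gene_id = NA_character_) {
  x <- strsplit(toupper(x_seq), "")[[1]]
  y <- strsplit(toupper(y_seq), "")[[1]]
  if (length(x) != length(y)) {
    stop("aligned sequences differ in length (", length(x), " vs ",
         length(y), ")")
  }
  plain <- c("A", "C", "G", "T")
  x_pos <- cumsum(x != "-")          # ungapped X coordinate per column
  is_snp <- x %in% plain & y %in% plain & x != y
  data.frame(gene_id = rep(gene_id, sum(is_snp)),
             orf_position = x_pos[is_snp],
             x_base = x[is_snp], y_base = y[is_snp],
             stringsAsFactors = FALSE)
}

.gt_alleles <- function(gt) {
  # "0/1", "0|1", "1/1" ... -> integer alleles; NA for missing
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(c(NA, NA))
  as.integer(strsplit(gt, "[/|]")[[1]])
}

#' Validate candidate diagnostic SNPs against observed genotypes
#'
#' A site separates the X and Y alleles only when every female plant is
#' homozygous for the reference (X) base and every male plant is
#' heterozygous. Sites failing the criterion, or lacking a genotype record
#' in either sex, are retained with `valid = FALSE` and a reason, never
#' silently dropped.
#'
#' @param snps data.frame with gene_id and pos (one row per candidate
#'   site; positions on the same axis as the genotype records).
#' @param genotypes long data.frame with gene_id, pos, sample, gt
#'   (VCF-style genotype strings), e.g. from [read_allele_vcf()].
#' @param sample_sex named character vector mapping sample id to
#'   "male"/"female".
#' @return `snps` with columns valid (logical) and reason
#'   ("ok", "female_not_hom_ref", "male_not_het", "missing").
#' @export
validate_snps <- function(snps, genotypes, sample_sex) {
  key_g <- paste(genotypes$gene_id, genotypes$pos)
  sex <- sample_sex[genotypes$sample]
  valid <- logical(nrow(snps))
  reason <- character(nrow(snps))
  for (i in seq_len(nrow(snps))) {
    rows <- which(key_g == paste(snps$gene_id[i], snps$pos[i]))
    f_gt <- genotypes$gt[rows][sex[rows] == "female"]
    m_gt <- genotypes$gt[rows][sex[rows] == "male"]
    if (length(f_gt) == 0 || length(m_gt) == 0 ||
        anyNA(f_gt) || anyNA(m_gt)) {
      reason[i] <- "missing"
      next
    }
    f_ok <- all(vapply(f_gt, function(g)
      identical(.gt_alleles(g), c(0L, 0L)), TRUE))
    m_ok <- all(vapply(m_gt, function(g) {
      al <- .gt_alleles(g)
      !anyNA(al) && length(unique(al)) == 2
    }, TRUE))
    if (!f_ok) reason[i] <- "female_not_hom_ref"
    else if (!m_ok) reason[i] <- "male_not_het"
    else { valid[i] <- TRUE; reason[i] <- "ok" }
  }
  snps$valid <- valid
  snps$reason <- reason
  snps
}

#' Aggregate allele read counts over valid in-ORF SNPs
#'
#' For every gene and library, sums the reference-base depths (the X
#' allele; females are homozygous reference so their total is the two-X
#' depth) and alternate-base depths (the Y allele) over the validated SNPs
#' falling within the gene's open reading frame. Genes without any valid
#' in-ORF SNP are excluded and listed.
#'
#' @param records long data.frame with gene_id, pos, sample, ref_depth,
#'   alt_depth and a logical `valid` column (from [validate_snps()],
#'   joined back onto the depth records; an absent column means all valid).
#' @param annot annotation data.frame with gene_id, orf_start, orf_end on
#'   the same position axis as `pos`.
#' @return list(`table`: data.frame gene_id, sample, x_reads, y_reads,
#'   n_snps; `excluded`: character vector of gene ids with no valid
#'   in-ORF SNP).
#' @export
count_allele_reads <- function(records, annot) {
  if (is.null(records$valid)) records$valid <- TRUE
  a <- annot[match(records$gene_id, annot$gene_id), ]
  in_orf <- !is.na(a$orf_start) & records$pos >= a$orf_start &
    records$pos <= a$orf_end
  use <- records$valid & in_orf
  all_genes <- unique(records$gene_id)
  kept <- records[use, , drop = FALSE]
  if (nrow(kept) == 0) {
    return(list(table = data.frame(gene_id = character(0),
                                   sample = character(0),
                                   x_reads = numeric(0),
                                   y_reads = numeric(0),
                                   n_snps = integer(0)),
                excluded = all_genes))
  }
  key <- interaction(kept$gene_id, kept$sample, drop = TRUE)
  tab <- data.frame(
    gene_id = as.character(tapply(kept$gene_id, key, `[`, 1)),
    sample = as.character(tapply(kept$sample, key, `[`, 1)),
    x_reads = as.numeric(tapply(kept$ref_depth, key, sum)),
    y_reads = as.numeric(tapply(kept$alt_depth, key, sum)),
    n_snps = as.integer(tapply(kept$pos, key, function(p)
      length(unique(p)))),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab[order(tab$gene_id, tab$sample), ],
       excluded = setdiff(all_genes, kept$gene_id))
}

#' Trimmed-mean-of-M-values (TMM) library scaling factors
#'
#' Computes between-library scaling factors robust to composition effects.
#' The reference library is the one whose 75th percentile of
#' counts-per-library-size is closest to the mean 75th percentile. For each
#' library, per-gene log2 expression ratios against the reference (M) and
#' average log2 abundances (A) are formed over genes with non-zero counts
#' in both libraries; the most extreme 30% of M (two-sided) and 5% of A
#' (two-sided) are trimmed, and the factor is 2 to the precision-weighted
#' mean of the remaining M values. Factors are rescaled so their geometric
#' mean is 1.
#'
#' @param counts gene x library count matrix (>= 2 libraries).
#' @param lib_sizes library sizes; default column sums.
#' @param logratio_trim,abundance_trim two-sided trim fractions on M and A.
#' @param do_weighting weight M values by inverse binomial variance (the
#'   standard choice); unweighted otherwise.
#' @return Named numeric vector of factors, one per library.
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts),
                        logratio_trim = 0.30, abundance_trim = 0.05,
                        do_weighting = TRUE) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 libraries")
  if (any(colSums(counts) == 0)) stop("a library has all-zero counts")
  ## reference: upper quartile of scaled counts closest to the mean
  uq <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib_sizes
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], counts[, ref], lib_sizes[j], lib_sizes[ref],
              logratio_trim, abundance_trim, do_weighting)
  }, 0)
  f <- f / exp(mean(log(f)))          # geometric mean 1
  stats::setNames(f, colnames(counts))
}

# one library against the reference
.tmm_pair <- function(obs, ref, n_obs, n_ref, lt, at, weighted) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  p_obs <- obs / n_obs; p_ref <- ref / n_ref
  m <- log2(p_obs / p_ref)
  a <- 0.5 * log2(p_obs * p_ref)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * lt) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * at) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) return(1)
  if (weighted) {
    w <- 1 / ((n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref))
    f <- sum(m[keep2] * w[keep2]) / sum(w[keep2])
  } else {
    f <- mean(m[keep2])
  }
  if (!is.finite(f)) f <- 0
  2^f
}

#' Normalize allele read counts to per-SNP, per-million expression
#'
#' Divides each gene's summed allele reads by its number of contributing
#' SNPs (removing gene-length/divergence effects) and by the effective
#' library size (library size times TMM factor), scaled to reads per
#' million. For male libraries the reference-base value is the X-allele
#' expression (mX) and the alternate-base value the Y-allele expression
#' (mY); for female libraries the reference-base value is the two-X total
#' (fXX).
#'
#' @param table data.frame from [count_allele_reads()] (gene_id, sample,
#'   x_reads, y_reads, n_snps).
#' @param library_sizes named vector of per-library totals (> 0).
#' @param factors named vector of TMM factors (default 1 for every
#'   library).
#' @return The table with columns norm_factor, ref_expr and alt_expr added
#'   (reads per SNP per million effective library reads).
#' @export
normalize_allele_expression <- function(table, library_sizes,
                                        factors = NULL) {
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (is.null(factors)) {
    factors <- stats::setNames(rep(1, length(library_sizes)),
                               names(library_sizes))
  }
  if (any(table$n_snps < 1)) stop("every gene needs at least one SNP")
  lib <- library_sizes[table$sample]
  fac <- factors[table$sample]
  if (anyNA(lib) || anyNA(fac)) {
    stop("library sizes / factors missing for some samples")
  }
  eff <- lib * fac
  table$norm_factor <- unname(fac)
  table$ref_expr <- (table$x_reads / table$n_snps) / eff * 1e6
  table$alt_expr <- (table$y_reads / table$n_snps) / eff * 1e6
  table
}

#' Per-gene, per-tissue mX, mY and fXX from normalized allele expression
#'
#' Averages the normalized allele expression over replicate libraries
#' within each sex x tissue: male reference-base expression becomes mX,
#' male alternate-base expression mY, and female reference-base expression
#' fXX (the two X alleles), all measured at the same validated SNP sites.
#'
#' @param norm_table output of [normalize_allele_expression()].
#' @param samples sample metadata (sample, sex, tissue).
#' @return data.frame: gene_id, tissue, mX, mY, fXX.
#' @export
allele_expression_by_tissue <- function(norm_table, samples) {
  sx <- stats::setNames(samples$sex, samples$sample)
  ts <- stats::setNames(samples$tissue, samples$sample)
  norm_table$sex <- sx[norm_table$sample]
  norm_table$tissue <- ts[norm_table$sample]
  if (anyNA(norm_table$sex)) stop("samples missing from metadata")
  key <- interaction(norm_table$gene_id, norm_table$tissue, drop = TRUE)
  agg <- function(v, sel) {
    out <- tapply(ifelse(sel, v, NA), key, mean, na.rm = TRUE)
    out[is.nan(out)] <- NA
    out
  }
  male <- norm_table$sex == "male"
  res <- data.frame(
    gene_id = as.character(tapply(norm_table$gene_id, key, `[`, 1)),
    tissue = as.character(tapply(norm_table$tissue, key, `[`, 1)),
    mX = as.numeric(agg(norm_table$ref_expr, male)),
    mY = as.numeric(agg(norm_table$alt_expr, male)),
    fXX = as.numeric(agg(norm_table$ref_expr, !male)),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res[order(res$gene_id, res$tissue), ]
}
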