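#' Load a dataset written by [write_fixture()] from disk
#'
#' @param directory directory holding the fixture files.
#' @return A list shaped like the output of [simulate_dataset()] (without
#'   sequences-derived extras that the files do not carry).
#' @export
read_dataset <- function(directory) {
  p <- function(f) {
    fp <- file.path(directory, f)
    if (!file.exists(fp)) stop("missing input file: ", fp)
    fp
  }
  focal <- read_expression_tsv(p("focal_tpm.tsv"), p("focal_samples.tsv"))
  outgroup <- read_expression_tsv(p("outgroup_tpm.tsv"),
                                  p("outgroup_samples.tsv"))
  cts <- utils::read.delim(p("focal_counts.tsv"), check.names = FALSE)
  counts <- as.matrix(cts[, -1, drop = FALSE])
  rownames(counts) <- cts[[1]]
  libs <- utils::read.delim(p("library_sizes.tsv"))
  library_sizes <- stats::setNames(libs$library_size, libs$sample)
  vcf <- read_allele_vcf(p("snps.vcf"))
  list(focal = focal, focal_counts = counts, outgroup = outgroup,
       vcf_records = vcf,
       annotation = read_annotation_tsv(p("annotation.tsv")),
       orthologs = read_orthologs_tsv(p("orthologs.tsv")),
       library_sizes = library_sizes)
}

# allele-depth records with genotypes, on the gene position axis, straight
# from an in-memory simulated dataset (equivalent to writing + re-reading
# the VCF)
.records_from_dataset <- function(dataset) {
  ac <- dataset$allele_counts
  orf_start <- stats::setNames(dataset$annotation$orf_start,
                               dataset$annotation$gene_id)
  sex <- stats::setNames(dataset$focal$samples$sex,
                         dataset$focal$samples$sample)
  snp <- dataset$snps
  base_key <- paste(snp$gene_id, snp$orf_position)
  ref <- stats::setNames(snp$x_base, base_key)
  alt <- stats::setNames(snp$y_base, base_key)
  k <- paste(ac$gene_id, ac$orf_position)
  data.frame(
    gene_id = ac$gene_id,
    pos = unname(orf_start[ac$gene_id]) + ac$orf_position - 1L,
    ref = unname(ref[k]), alt = unname(alt[k]),
    sample = ac$sample,
    gt = ifelse(sex[ac$sample] == "male", "0/1", "0/0"),
    ref_depth = ac$ref_depth, alt_depth = ac$alt_depth,
    stringsAsFactors = FALSE)
}

#' Run the full dosage-compensation analysis
#'
#' Orchestrates the stages end to end: expression filtering, outgroup
#' calibration and region summaries with male-vs-female reduction
#' percentages; diagnostic-SNP validation, allele read counting, TMM
#' normalization and per-gene mX / mY / fXX; ratio distributions with
#' density peaks; per-gene compensation classification; strata
#' comparisons; the Ks correlation; and the silenced fraction of
#' X-specific genes.
#'
#' @param dataset an in-memory dataset from [simulate_dataset()], or `NULL`
#'   to read `input_dir`.
#' @param input_dir directory of fixture files (used when `dataset` is
#'   `NULL`).
#' @param out_dir optional output directory; when given, result tables are
#'   written as TSV and the summary as JSON.
#' @param tpm_min expression filter threshold.
#' @param outgroup_min minimum usable outgroup denominator.
#' @param full_threshold,partial_threshold classification cutoffs.
#' @param per_gene_median if `TRUE` (default) the ratio distributions use
#'   one value per gene (median across tissues); otherwise per-tissue
#'   ratios are pooled.
#' @param bin_width peak-reporting resolution.
#' @param max_ratio_clip upper clip of the ratio densities.
#' @return A list of stage results (`region_summaries`, `reduction`,
#'   `ase`, `ratios`, `classification`, `peaks`, `strata`,
#'   `ks_correlation`, `silenced`, `correlations`, `log`).
#' @export
run_pipeline <- function(dataset = NULL, input_dir = NULL, out_dir = NULL,
                         tpm_min = 1, outgroup_min = 0,
                         full_threshold = 0.9, partial_threshold = 0.75,
                         per_gene_median = TRUE, bin_width = 0.1,
                         max_ratio_clip = 2.0) {
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.null(dataset)) {
    if (is.null(input_dir)) stop("supply a dataset or an input_dir")
    dataset <- stage("load", read_dataset(input_dir))
    records <- dataset$vcf_records
  } else {
    records <- stage("load", .records_from_dataset(dataset))
  }
  annot <- dataset$annotation
  samples <- dataset$focal$samples
  note("samples: ", nrow(samples), "; genes: ", nrow(dataset$focal$values))

  ## ---- expression filter + calibration + region summaries ------------
  expressed <- stage("filter", filter_expressed(dataset$focal, tpm_min))
  note("expressed genes (> ", tpm_min, " in >=1 sample): ",
       nrow(expressed$values))
  cal <- stage("calibrate", calibrate_by_outgroup(
    expressed, dataset$outgroup, dataset$orthologs, outgroup_min))
  note("calibration excluded ", nrow(cal$excluded), " genes")

  region_summaries <- stage("region_summary", do.call(rbind, lapply(
    samples$sample, function(s)
      region_summary(cal$calibrated, annot, s))))
  rs <- merge(region_summaries, samples, by = "sample")

  ## male-vs-female percent reduction of the mean-ratio per tissue
  reduction <- stage("reduction", do.call(rbind, lapply(
    unique(samples$tissue), function(tt) {
      m <- mean(rs$ratio_of_means[rs$tissue == tt & rs$sex == "male"])
      f <- mean(rs$ratio_of_means[rs$tissue == tt & rs$sex == "female"])
      data.frame(tissue = tt, male_ratio_of_means = m,
                 female_ratio_of_means = f,
                 percent_reduction = percent_reduction(m, f))
    })))

  ## male-vs-female global expression correlation per tissue
  correlations <- stage("correlation", do.call(rbind, lapply(
    unique(samples$tissue), function(tt) {
      ms <- samples$sample[samples$tissue == tt & samples$sex == "male"]
      fs <- samples$sample[samples$tissue == tt & samples$sex == "female"]
      x <- rowMeans(dataset$focal$values[, ms, drop = FALSE])
      y <- rowMeans(dataset$focal$values[, fs, drop = FALSE])
      sp <- global_correlation(x, y, "spearman")
      pe <- global_correlation(x, y, "pearson_log10")
      data.frame(tissue = tt, spearman_rho = sp$coefficient,
                 pearson_log10_r = pe$coefficient, n = sp$n)
    })))

  ## ---- allele-specific expression ------------------------------------
  sample_sex <- stats::setNames(samples$sex, samples$sample)
  sites <- unique(records[, c("gene_id", "pos")])
  sites <- stage("validate", validate_snps(sites, records, sample_sex))
  note("diagnostic SNP sites: ", nrow(sites), " (valid: ",
       sum(sites$valid), ")")
  vkey <- paste(sites$gene_id, sites$pos)
  records$valid <- sites$valid[match(paste(records$gene_id, records$pos),
                                     vkey)]
  counted <- stage("count", count_allele_reads(records, annot))
  note("genes without a valid in-ORF SNP: ", length(counted$excluded))

  factors <- stage("tmm", tmm_factors(dataset$focal_counts,
                                      dataset$library_sizes))
  norm <- stage("normalize", normalize_allele_expression(
    counted$table, dataset$library_sizes, factors))
  abt <- allele_expression_by_tissue(norm, samples)

  ## ---- ratios, peaks, classification, strata, Ks ---------------------
  ratios <- stage("ratios", compute_ratios(abt, annot))
  pg <- ratios$per_gene
  pg$label <- classify_gene(pg$median_mx_fxx, full_threshold,
                            partial_threshold)

  mx_vals <- if (per_gene_median) pg$median_mx_fxx else
    ratios$per_tissue$mx_fxx
  my_fxx_tissue <- with(ratios$per_tissue,
                        ifelse(!is.na(fXX) & fXX > 0, mY / fXX, NA))
  my_vals <- if (per_gene_median) {
    as.numeric(tapply(my_fxx_tissue, ratios$per_tissue$gene_id,
                      stats::median, na.rm = TRUE))
  } else my_fxx_tissue
  peaks <- stage("peaks", list(
    mx_fxx = ratio_density_peaks(mx_vals, bin_width = bin_width,
                                 max_ratio_clip = max_ratio_clip),
    my_fxx = ratio_density_peaks(my_vals, bin_width = bin_width,
                                 max_ratio_clip = max_ratio_clip)))

  ## per-gene median log2 metrics for the strata boxplots
  lg_med <- function(col) as.numeric(
    tapply(ratios$per_tissue[[col]], ratios$per_tissue$gene_id,
           function(v) if (all(is.na(v))) NA else
             stats::median(v, na.rm = TRUE)))
  pg$median_log2_mx_fxx <- lg_med("log2_mx_fxx")
  pg$median_log2_mxy_fxx <- lg_med("log2_mxy_fxx")
  strata <- stage("strata", list(
    log2_mx_fxx = strata_compare(pg, "median_log2_mx_fxx"),
    log2_mxy_fxx = strata_compare(pg, "median_log2_mxy_fxx")))

  ks_res <- if (sum(is.finite(pg$median_my_mx) & is.finite(pg$ks)) >= 3) {
    stage("ks", ks_correlation(pg$median_my_mx, pg$ks))
  } else NULL

  xs_genes <- annot$gene_id[annot$class == "X-specific"]
  silenced <- if (length(xs_genes) > 0) {
    stage("silenced", silenced_fraction(
      subset_expr(dataset$focal,
                  genes = intersect(xs_genes,
                                    rownames(dataset$focal$values))),
      tpm_min))
  } else NULL

  result <- list(
    region_summaries = rs, reduction = reduction,
    correlations = correlations,
    ase = norm, ratios = ratios, classification = pg,
    peaks = peaks, strata = strata, ks_correlation = ks_res,
    silenced = silenced,
    thresholds = list(tpm_min = tpm_min, outgroup_min = outgroup_min,
                      full_threshold = full_threshold,
                      partial_threshold = partial_threshold),
    log = log_lines)

  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  result
}

.write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  w(result$region_summaries, "region_summaries.tsv")
  w(result$reduction, "reduction.tsv")
  w(result$ase, "allele_expression.tsv")
  w(result$ratios$per_tissue, "ratios_per_tissue.tsv")
  w(result$classification, "classification.tsv")
  if (!is.null(result$strata$log2_mxy_fxx$tests)) {
    w(result$strata$log2_mxy_fxx$tests, "strata_tests_log2_mxy_fxx.tsv")
  }
  summary <- list(
    reduction = result$reduction,
    peaks_mx_fxx = result$peaks$mx_fxx$peaks,
    peaks_my_fxx = result$peaks$my_fxx$peaks,
    classification_counts =
      as.list(table(result$classification$label)),
    ks_correlation = result$ks_correlation,
    silenced = result$silenced,
    thresholds = result$thresholds)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  writeLines(result$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
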