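#' Read an expression matrix and its sample metadata from TSV
#'
#' The matrix file is genes x samples with a header row of sample ids and
#' gene ids in the first column; the samples file has one row per sample.
#'
#' @param values_path TSV of expression values.
#' @param samples_path TSV of sample metadata (sample, species, sex, tissue,
#'   replicate).
#' @return An [expr_set()].
#' @export
read_expression_tsv <- function(values_path, samples_path) {
  v <- utils::read.delim(values_path, check.names = FALSE)
  m <- as.matrix(v[, -1, drop = FALSE])
  rownames(m) <- v[[1]]
  s <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  expr_set(m, s)
}

#' Write an expression set to a pair of TSV files
#' @param x an `expr_set`.
#' @param values_path,samples_path output paths.
#' @export
write_expression_tsv <- function(x, values_path, samples_path) {
  stopifnot(inherits(x, "expr_set"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(values_path, samples_path))
}

#' Read a gene annotation table
#'
#' Expects columns gene_id, class (autosome / XY-paired / X-specific /
#' Y-specific), region (autosomal / inversion1 / inversion2 / collinear),
#' orf_start, orf_end and optionally ks.
#' @param path annotation TSV.
#' @return data.frame.
#' @export
read_annotation_tsv <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "class", "region", "orf_start", "orf_end")
  miss <- setdiff(req, names(a))
  if (length(miss) > 0) {
    stop("annotation missing columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(a$gene_id)) stop("duplicate gene ids in annotation")
  a
}

#' Read a focal-to-outgroup ortholog map
#' @param path TSV with columns focal_gene_id, outgroup_gene_id.
#' @return data.frame; the map must be 1:1 in both directions.
#' @export
read_orthologs_tsv <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("focal_gene_id", "outgroup_gene_id") %in% names(m))) {
    stop("ortholog map needs focal_gene_id and outgroup_gene_id columns")
  }
  if (anyDuplicated(m$focal_gene_id) || anyDuplicated(m$outgroup_gene_id)) {
    stop("ortholog map must be one-to-one")
  }
  m
}

#' Read aligned X/Y allele sequence pairs from FASTA
#'
#' Each gene contributes two records named `<gene>_X` and `<gene>_Y`,
#' aligned to equal length (gaps as `-`).
#' @param path FASTA file.
#' @return Named list: per gene, a list with `x` and `y` aligned sequences
#'   (character scalars).
#' @export
read_aligned_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- names(ss)
  gene <- sub("_[XY]$", "", nm)
  allele <- sub("^.*_([XY])$", "\\1", nm)
  out <- list()
  for (g in unique(gene)) {
    xi <- which(gene == g & allele == "X")
    yi <- which(gene == g & allele == "Y")
    if (length(xi) != 1 || length(yi) != 1) {
      stop("gene ", g, " does not have exactly one _X and one _Y record")
    }
    out[[g]] <- list(x = as.character(ss[[xi]]), y = as.character(ss[[yi]]))
  }
  out
}

#' Read per-sample genotypes and allele depths from a VCF
#'
#' Consumes a VCF 4.x with GT and AD FORMAT fields; one biallelic SNP per
#' record, CHROM holding the gene id and POS the position on the gene (the
#' annotation's ORF coordinates are on the same axis).
#'
#' @param path VCF file (plain text or gzipped).
#' @return A long data.frame: gene_id, pos, ref, alt, sample, gt,
#'   ref_depth, alt_depth.
#' @export
read_allele_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  n_samp <- ncol(gt)
  ref_d <- apply(ad, 2, function(col)
    as.numeric(vapply(strsplit(col, ","), `[`, "", 1)))
  alt_d <- apply(ad, 2, function(col)
    as.numeric(vapply(strsplit(col, ","), `[`, "", 2)))
  data.frame(
    gene_id = rep(fix[, "CHROM"], n_samp),
    pos = rep(as.integer(fix[, "POS"]), n_samp),
    ref = rep(fix[, "REF"], n_samp),
    alt = rep(fix[, "ALT"], n_samp),
    sample = rep(colnames(gt), each = nrow(gt)),
    gt = as.vector(gt),
    ref_depth = as.vector(ref_d),
    alt_depth = as.vector(alt_d),
    stringsAsFactors = FALSE)
}

#' Write a simulated dataset to disk as standard flat files
#'
#' Produces TSV expression matrices and metadata, an annotation TSV, an
#' ortholog TSV, a truth TSV, aligned X/Y FASTA, and a VCF (GT:AD) with one
#' record per diagnostic SNP: females genotyped 0/0 (X base is REF), males
#' 0/1, allele depths from the simulated per-SNP counts. Files round-trip
#' through the package readers.
#'
#' @param dataset output of [simulate_dataset()].
#' @param directory output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture <- function(dataset, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory ", directory)
  }
  p <- function(f) file.path(directory, f)
  write_expression_tsv(dataset$focal, p("focal_tpm.tsv"),
                       p("focal_samples.tsv"))
  write_expression_tsv(dataset$outgroup, p("outgroup_tpm.tsv"),
                       p("outgroup_samples.tsv"))
  utils::write.table(dataset$annotation, p("annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$orthologs, p("orthologs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth, p("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cts <- data.frame(gene_id = rownames(dataset$focal_counts),
                    dataset$focal_counts, check.names = FALSE)
  utils::write.table(cts, p("focal_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  libs <- data.frame(sample = names(dataset$library_sizes),
                     library_size = as.numeric(dataset$library_sizes))
  utils::write.table(libs, p("library_sizes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  if (length(dataset$sequences) > 0) {
    writeLines(paste0(">", names(dataset$sequences), "\n",
                      dataset$sequences), p("alleles.fasta"))
  }
  .write_snp_vcf(dataset, p("snps.vcf"))
  invisible(vapply(c("focal_tpm.tsv", "focal_samples.tsv",
                     "outgroup_tpm.tsv", "outgroup_samples.tsv",
                     "annotation.tsv", "orthologs.tsv", "truth.tsv",
                     "focal_counts.tsv", "library_sizes.tsv",
                     "alleles.fasta", "snps.vcf"), p, ""))
}

# One VCF record per simulated diagnostic SNP. CHROM = gene id, POS = the
# SNP's position on the gene axis (orf_start + within-ORF offset), REF = X
# base, ALT = Y base; GT:AD per focal sample.
.write_snp_vcf <- function(dataset, path) {
  snps <- dataset$snps
  ac <- dataset$allele_counts
  samp <- dataset$focal$samples
  orf_start <- stats::setNames(dataset$annotation$orf_start,
                               dataset$annotation$gene_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=dosecomp-simulate",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allele depths (ref,alt)\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samp$sample), collapse = "\t")), con)
  if (nrow(snps) == 0) return(invisible(path))
  is_male <- stats::setNames(samp$sex == "male", samp$sample)
  key_ac <- paste(ac$gene_id, ac$orf_position, ac$sample)
  depth <- stats::setNames(
    paste0(round(ac$ref_depth), ",", round(ac$alt_depth)), key_ac)
  for (r in seq_len(nrow(snps))) {
    g <- snps$gene_id[r]
    pos <- snps$orf_position[r]
    cells <- vapply(samp$sample, function(s) {
      ad <- depth[paste(g, pos, s)]
      if (is.na(ad)) ad <- "0,0"
      paste0(if (is_male[s]) "0/1" else "0/0", ":", ad)
    }, "")
    writeLines(paste(c(g, orf_start[g] + pos - 1L, ".", snps$x_base[r],
                       snps$y_base[r], ".", "PASS", ".", "GT:AD", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}
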