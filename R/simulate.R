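#' Configuration for the synthetic dosage-compensation dataset
#'
#' Builds and validates the parameter set for [simulate_dataset()]. The
#' generator emulates a two-sex, multi-tissue RNA-Seq study of a species
#' with young sex chromosomes plus a monoecious outgroup: X/Y gene pairs in
#' three compartments of the non-recombining region (two inversion strata
#' and the collinear region), hemizygous X-specific genes, autosomal genes,
#' and per-gene diagnostic SNPs between the X and Y alleles.
#'
#' Per-gene per-allele transcription rates are drawn log-normally. A male
#' X/Y pair expresses its X allele at rate `lambda * compensation_factor`
#' (if the pair is compensated) or `lambda`, and its Y allele at
#' `lambda * y_decay[region]`; a female expresses two X alleles at `lambda`
#' each. By construction the expected male-X to female-XX ratio is 0.5 for
#' an uncompensated pair and `0.5 * compensation_factor` for a compensated
#' one, and the expected male Y/X ratio equals `y_decay[region]` divided by
#' the X up-regulation factor.
#'
#' @param n_autosomal number of autosomal genes. The default keeps the
#'   autosomal background large relative to the sex-linked complement, as
#'   in a real transcriptome, so that between-library TMM scaling (which
#'   assumes most genes unchanged between libraries) is well-posed.
#' @param n_xy_pairs named integer vector: X/Y pairs per region
#'   (`inversion1`, `inversion2`, `collinear`).
#' @param n_x_specific number of hemizygous X-specific genes.
#' @param frac_silenced_x_specific fraction of X-specific genes that are
#'   transcriptionally silenced (rate 0) in all samples.
#' @param y_decay named numeric vector, multiplicative Y per-allele rate
#'   factor per region, in `[0, Inf)`.
#' @param compensation_frac named numeric vector, fraction of X/Y pairs per
#'   region whose male X allele is up-regulated.
#' @param compensation_factor multiplicative male-X up-regulation applied to
#'   compensated pairs.
#' @param base_meanlog,base_sdlog log-normal parameters of the per-gene
#'   per-allele transcription rate (interpreted on the TPM scale at the
#'   default library size).
#' @param nb_dispersion negative-binomial dispersion; variance is
#'   `mu + mu^2 * dispersion`. Zero degenerates to Poisson.
#' @param noiseless if `TRUE`, counts are the negative-binomial means
#'   themselves (no sampling); used for exact-arithmetic checks.
#' @param snps_per_gene mean of the (zero-truncated) Poisson number of
#'   diagnostic SNPs per X/Y pair.
#' @param library_size per-sample sequencing depth; a scalar recycled over
#'   samples or a vector named by sample id.
#' @param tissues character vector of tissue names shared by both sexes;
#'   the outgroup contributes one library per tissue.
#' @param replicates libraries per sex x tissue combination.
#' @param seed integer seed; a fixed seed makes the output byte-identical.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_autosomal = 2000,
                       n_xy_pairs = c(inversion1 = 18, inversion2 = 16,
                                      collinear = 11),
                       n_x_specific = 34,
                       frac_silenced_x_specific = 32 / 34,
                       y_decay = c(inversion1 = 0.8, inversion2 = 1.1,
                                   collinear = 1.0),
                       compensation_frac = c(inversion1 = 0.05,
                                             inversion2 = 0.25,
                                             collinear = 0.18),
                       compensation_factor = 1.8,
                       base_meanlog = log(30),
                       base_sdlog = 1,
                       nb_dispersion = 0.1,
                       noiseless = FALSE,
                       snps_per_gene = 10,
                       library_size = 1e6,
                       tissues = c("leaf", "flower"),
                       replicates = 4,
                       seed = 1L) {
  regions <- c("inversion1", "inversion2", "collinear")
  n_xy_pairs <- .complete_by_region(n_xy_pairs, regions, 0)
  y_decay <- .complete_by_region(y_decay, regions, 1)
  compensation_frac <- .complete_by_region(compensation_frac, regions, 0)

  stopifnot(n_autosomal >= 1, n_x_specific >= 0,
            all(n_xy_pairs >= 0), all(y_decay >= 0),
            compensation_factor >= 0,
            frac_silenced_x_specific >= 0, frac_silenced_x_specific <= 1,
            all(compensation_frac >= 0), all(compensation_frac <= 1),
            nb_dispersion >= 0, snps_per_gene > 0,
            replicates >= 1, length(tissues) >= 1)
  if (any(library_size <= 0)) stop("library_size must be positive")

  structure(list(
    n_autosomal = as.integer(n_autosomal),
    n_xy_pairs = n_xy_pairs,
    n_x_specific = as.integer(n_x_specific),
    frac_silenced_x_specific = frac_silenced_x_specific,
    y_decay = y_decay,
    compensation_frac = compensation_frac,
    compensation_factor = compensation_factor,
    base_meanlog = base_meanlog,
    base_sdlog = base_sdlog,
    nb_dispersion = nb_dispersion,
    noiseless = noiseless,
    snps_per_gene = snps_per_gene,
    library_size = library_size,
    tissues = tissues,
    replicates = as.integer(replicates),
    seed = as.integer(seed)
  ), class = "sim_config")
}

.complete_by_region <- function(x, regions, default) {
  if (is.null(names(x))) {
    if (length(x) == 1) x <- stats::setNames(rep(x, 3), regions)
    else if (length(x) == 3) names(x) <- regions
    else stop("region vector must be named or length 1/3")
  }
  out <- stats::setNames(rep(default, length(regions)), regions)
  out[names(x)] <- x
  out
}

# NB draw parameterized by mean and dispersion (var = mu + mu^2 * disp);
# disp 0 is Poisson, noiseless returns the means.
.rcounts <- function(n, mu, disp, noiseless) {
  if (noiseless) return(rep_len(unname(mu), n))
  if (disp <= 0) return(stats::rpois(n, lambda = mu))
  stats::rnbinom(n, mu = mu, size = 1 / disp)
}

#' Simulate a complete dosage-compensation study with ground truth
#'
#' Draws a full synthetic dataset under `config`: focal-species TPM-scale
#' expression for male and female libraries across tissues and replicates,
#' outgroup expression from the same per-gene base rates (two alleles, no
#' sex chromosomes, so outgroup calibration is well-posed), per-SNP allele
#' depths for every X/Y pair in every library, a gene annotation table, a
#' 1:1 ortholog map, aligned X/Y sequences, and a truth table holding each
#' sex-linked gene's expected ratios.
#'
#' Counts are negative-binomial with mean
#' `per-allele rate x allele copies x library_size / 1e6`; expression values
#' are counts rescaled to reads-per-million of the nominal library size.
#' Allele depths at each diagnostic SNP are drawn per allele with the same
#' law; the female depth at a site is the sum of two independent X-allele
#' draws, and female alternate (Y-base) depth is zero.
#'
#' @param config a [sim_config()].
#' @return A list with elements `focal` (expr_set, TPM scale), `focal_counts`
#'   (matrix), `outgroup` (expr_set), `allele_counts` (data.frame: gene_id,
#'   orf_position, sample, ref_depth, alt_depth), `annotation`, `orthologs`,
#'   `snps`, `sequences` (named character, `<gene>_X` / `<gene>_Y`),
#'   `truth`, `library_sizes` (named vector), and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  regions <- names(config$n_xy_pairs)

  ## --- gene table -----------------------------------------------------
  auto_ids <- sprintf("AUTO%04d", seq_len(config$n_autosomal))
  xy_ids <- unlist(lapply(regions, function(r) {
    n <- config$n_xy_pairs[[r]]
    if (n == 0) return(character(0))
    sprintf("XY_%s_%03d", sub("inversion", "inv", r), seq_len(n))
  }))
  xy_region <- rep(regions, times = config$n_xy_pairs)
  xs_ids <- if (config$n_x_specific > 0) {
    sprintf("XSP%03d", seq_len(config$n_x_specific))
  } else character(0)
  xs_region <- if (length(xs_ids) > 0) {
    rep(c("inversion1", "inversion2"), length.out = length(xs_ids))
  } else character(0)

  gene_id <- c(auto_ids, xy_ids, xs_ids)
  class <- c(rep("autosome", length(auto_ids)),
             rep("XY-paired", length(xy_ids)),
             rep("X-specific", length(xs_ids)))
  region <- c(rep("autosomal", length(auto_ids)), xy_region, xs_region)

  n_genes <- length(gene_id)
  lambda <- stats::rlnorm(n_genes, config$base_meanlog, config$base_sdlog)

  ## silenced X-specific genes: rate zero everywhere
  silenced <- rep(NA, n_genes)
  if (length(xs_ids) > 0) {
    xs_idx <- which(class == "X-specific")
    n_sil <- round(config$frac_silenced_x_specific * length(xs_idx))
    sil <- rep(FALSE, length(xs_idx))
    sil[sample(seq_along(xs_idx), n_sil)] <- TRUE
    lambda[xs_idx[sil]] <- 0
    silenced[xs_idx] <- sil
  }

  ## compensation status and allele rates for X/Y pairs
  compensated <- rep(NA, n_genes)
  y_factor <- rep(NA_real_, n_genes)
  xy_idx <- which(class == "XY-paired")
  if (length(xy_idx) > 0) {
    comp <- stats::runif(length(xy_idx)) <
      config$compensation_frac[region[xy_idx]]
    compensated[xy_idx] <- comp
    y_factor[xy_idx] <- config$y_decay[region[xy_idx]]
  }
  x_rate <- lambda
  x_rate[xy_idx] <- lambda[xy_idx] *
    ifelse(compensated[xy_idx], config$compensation_factor, 1)
  y_rate <- rep(0, n_genes)
  y_rate[xy_idx] <- lambda[xy_idx] * y_factor[xy_idx]

  ## per-sex total rates (allele copies included)
  male_rate <- ifelse(class == "autosome", 2 * lambda,
               ifelse(class == "XY-paired", x_rate + y_rate, x_rate))
  female_rate <- ifelse(class == "autosome", 2 * lambda, 2 * lambda)
  # female X-specific also 2 alleles (or 0 if silenced): covered by 2*lambda

  ## --- samples --------------------------------------------------------
  grid <- expand.grid(replicate = seq_len(config$replicates),
                      tissue = config$tissues,
                      sex = c("male", "female"),
                      stringsAsFactors = FALSE)
  grid$sample <- sprintf("%s_%s_%d", grid$sex, grid$tissue, grid$replicate)
  grid$species <- "focal"
  samples <- grid[, c("sample", "species", "sex", "tissue", "replicate")]

  lib <- config$library_size
  if (length(lib) == 1) {
    lib <- stats::setNames(rep(lib, nrow(samples)), samples$sample)
  } else {
    if (is.null(names(lib))) stop("vector library_size must be named")
    if (!all(samples$sample %in% names(lib))) {
      stop("library_size names must cover all focal samples")
    }
    lib <- lib[samples$sample]
  }

  disp <- config$nb_dispersion
  nl <- config$noiseless
  counts <- matrix(0, n_genes, nrow(samples),
                   dimnames = list(gene_id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    rate <- if (samples$sex[j] == "male") male_rate else female_rate
    mu <- rate * lib[j] / 1e6
    counts[, j] <- .rcounts(n_genes, mu, disp, nl)
  }
  tpm <- sweep(counts, 2, lib / 1e6, "/")
  focal <- expr_set(tpm, samples)

  ## --- outgroup: two alleles of the same base rate, no sex chromosome --
  out_ids <- paste0("OG_", gene_id)
  out_samples <- data.frame(
    sample = paste0("outgroup_", config$tissues),
    species = "outgroup", sex = "monoecious",
    tissue = config$tissues, replicate = 1L,
    stringsAsFactors = FALSE)
  out_lib <- rep(if (length(config$library_size) == 1)
    config$library_size else 1e6, nrow(out_samples))
  names(out_lib) <- out_samples$sample
  out_counts <- matrix(0, n_genes, nrow(out_samples),
                       dimnames = list(out_ids, out_samples$sample))
  for (j in seq_len(nrow(out_samples))) {
    mu <- 2 * lambda * out_lib[j] / 1e6
    out_counts[, j] <- .rcounts(n_genes, mu, disp, nl)
  }
  out_tpm <- sweep(out_counts, 2, out_lib / 1e6, "/")
  outgroup <- expr_set(out_tpm, out_samples)

  orthologs <- data.frame(focal_gene_id = gene_id,
                          outgroup_gene_id = out_ids,
                          stringsAsFactors = FALSE)

  ## --- ORFs, diagnostic SNPs, sequences, allele depths ----------------
  orf_len <- 3 * (100 + stats::rpois(n_genes, 200))
  orf_start <- rep(101L, n_genes)
  orf_end <- orf_start + orf_len - 1L
  ks_mean <- c(inversion1 = 0.15, inversion2 = 0.05, collinear = 0.02)
  ks <- rep(NA_real_, n_genes)
  ks[xy_idx] <- stats::rgamma(length(xy_idx), shape = 4,
                              rate = 4 / ks_mean[region[xy_idx]])

  annotation <- data.frame(gene_id = gene_id, class = class, region = region,
                           orf_start = orf_start, orf_end = orf_end,
                           ks = round(ks, 4), stringsAsFactors = FALSE)

  bases <- c("A", "C", "G", "T")
  snp_list <- vector("list", length(xy_idx))
  seqs <- character(0)
  ac_list <- list()
  male_rows <- which(samples$sex == "male")
  female_rows <- which(samples$sex == "female")
  for (k in seq_along(xy_idx)) {
    i <- xy_idx[k]
    n_snp <- .rpois_trunc1(1, config$snps_per_gene)
    pos <- sort(sample.int(orf_len[i], n_snp))
    x_seq <- sample(bases, orf_len[i], replace = TRUE)
    y_seq <- x_seq
    y_seq[pos] <- vapply(x_seq[pos],
                         function(b) sample(setdiff(bases, b), 1), "")
    seqs[paste0(gene_id[i], "_X")] <- paste(x_seq, collapse = "")
    seqs[paste0(gene_id[i], "_Y")] <- paste(y_seq, collapse = "")
    snp_list[[k]] <- data.frame(gene_id = gene_id[i], orf_position = pos,
                                x_base = x_seq[pos], y_base = y_seq[pos],
                                stringsAsFactors = FALSE)

    ## per-SNP per-allele depths in every focal library
    n_m <- length(male_rows); n_f <- length(female_rows)
    for (j in male_rows) {
      sc <- lib[j] / 1e6
      ac_list[[length(ac_list) + 1]] <- data.frame(
        gene_id = gene_id[i], orf_position = pos,
        sample = samples$sample[j],
        ref_depth = .rcounts(n_snp, x_rate[i] * sc, disp, nl),
        alt_depth = .rcounts(n_snp, y_rate[i] * sc, disp, nl),
        stringsAsFactors = FALSE)
    }
    for (j in female_rows) {
      sc <- lib[j] / 1e6
      two_x <- .rcounts(n_snp, lambda[i] * sc, disp, nl) +
        .rcounts(n_snp, lambda[i] * sc, disp, nl)
      ac_list[[length(ac_list) + 1]] <- data.frame(
        gene_id = gene_id[i], orf_position = pos,
        sample = samples$sample[j],
        ref_depth = two_x, alt_depth = 0,
        stringsAsFactors = FALSE)
    }
  }
  snps <- if (length(snp_list) > 0) do.call(rbind, snp_list) else
    data.frame(gene_id = character(0), orf_position = integer(0),
               x_base = character(0), y_base = character(0))
  allele_counts <- if (length(ac_list) > 0) do.call(rbind, ac_list) else
    data.frame(gene_id = character(0), orf_position = integer(0),
               sample = character(0), ref_depth = numeric(0),
               alt_depth = numeric(0))
  rownames(allele_counts) <- NULL

  ## --- truth table for sex-linked genes --------------------------------
  sl_idx <- c(xy_idx, which(class == "X-specific"))
  cf <- ifelse(!is.na(compensated[sl_idx]) & compensated[sl_idx],
               config$compensation_factor, 1)
  truth <- data.frame(
    gene_id = gene_id[sl_idx],
    region = region[sl_idx],
    compensated = compensated[sl_idx],
    y_factor = y_factor[sl_idx],
    expected_mx_fxx = ifelse(class[sl_idx] == "XY-paired", 0.5 * cf, NA),
    expected_my_mx = ifelse(class[sl_idx] == "XY-paired",
                            y_factor[sl_idx] / cf, NA),
    silenced = silenced[sl_idx],
    stringsAsFactors = FALSE)

  list(focal = focal, focal_counts = counts, outgroup = outgroup,
       allele_counts = allele_counts, annotation = annotation,
       orthologs = orthologs, snps = snps, sequences = seqs,
       truth = truth, library_sizes = lib, config = config)
}

# zero-truncated Poisson: every analyzable X/Y pair has at least one SNP
.rpois_trunc1 <- function(n, mean) {
  x <- stats::rpois(n, mean)
  while (any(x == 0)) x[x == 0] <- stats::rpois(sum(x == 0), mean)
  x
}
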