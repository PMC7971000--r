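# Small builders shared across the suite.

# minimal expression set: one matrix, auto-filled metadata
make_expr <- function(values, sex = "female", tissue = "leaf",
                      species = "focal") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  n <- ncol(values)
  expr_set(values, data.frame(
    sample = colnames(values),
    species = rep_len(species, n),
    sex = rep_len(sex, n),
    tissue = rep_len(tissue, n),
    replicate = seq_len(n)))
}

# small, fast simulation config for structural tests
small_config <- function(...) {
  defaults <- list(
    n_autosomal = 40,
    n_xy_pairs = c(inversion1 = 8, inversion2 = 8, collinear = 6),
    n_x_specific = 10, frac_silenced_x_specific = 0.5,
    replicates = 2)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# exhaustive two-sided Mann-Whitney p-value by enumerating every assignment
# of the pooled values into groups of the observed sizes (no-tie inputs)
enum_rank_sum <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(n, na)
  u_all <- apply(sets, 2, function(idx) {
    sum(r[idx]) - na * (na + 1) / 2
  })
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}
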