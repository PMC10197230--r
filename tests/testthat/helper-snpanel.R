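# Shared fixtures, built once per test run.

# A small 4-species hybrid-zone dataset (46 samples, 400 markers).
small_sim <- simulate_dataset(
  sim_config(n_markers = 400L, n_contigs = 10L, samples_per_pop = 2L),
  seed = 7
)

# A random genotype matrix with missingness, for property tests.
random_genotypes <- function(m, n, miss = 0.1, seed = 1) {
  set.seed(seed)
  g <- matrix(sample(0:2, m * n, replace = TRUE), m, n)
  g[matrix(runif(m * n) < miss, m, n)] <- NA_integer_
  genotype_matrix(g, paste0("mk", seq_len(m)), paste0("s", seq_len(n)))
}

# Align an admixture fit's clusters to a truth Q and return the relabelled Q.
aligned_q <- function(fit, Q_true) {
  perm <- align_clusters(fit$Q, Q_true)
  Q <- fit$Q[, perm, drop = FALSE]
  colnames(Q) <- colnames(Q_true)
  Q
}

# One-hot ancestry matrix for n_per samples in each of K clusters.
one_hot_q <- function(n_per, K) {
  Q <- matrix(0, n_per * K, K)
  for (k in seq_len(K)) Q[((k - 1) * n_per + 1):(k * n_per), k] <- 1
  Q
}

# Hudson-style two-population differentiation over a marker set
# (independent check used for the divergence-monotonicity property).
hudson_fst <- function(g, samples1, samples2) {
  p1 <- rowSums(unclass(g)[, samples1], na.rm = TRUE) /
    (2 * rowSums(!is.na(unclass(g)[, samples1])))
  p2 <- rowSums(unclass(g)[, samples2], na.rm = TRUE) /
    (2 * rowSums(!is.na(unclass(g)[, samples2])))
  n1 <- length(samples1); n2 <- length(samples2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (2 * n1 - 1) - p2 * (1 - p2) / (2 * n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num, na.rm = TRUE) / sum(den, na.rm = TRUE)
}

# Write a minimal VCF by hand (for parser edge cases).
write_raw_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="qd">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    lines
  ), path)
  path
}
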