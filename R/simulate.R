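#' Balding-Nichols species allele frequencies
#'
#' Draws per-species allele frequencies around ancestral frequencies
#' `p_anc` under the Balding-Nichols model: for species k with
#' divergence F_k, `f_kj ~ Beta(p_j (1 - F_k) / F_k, (1 - p_j)(1 - F_k) / F_k)`,
#' so E[f_kj] = p_j and divergence grows with F_k.
#'
#' @param p_anc ancestral allele frequencies, all strictly in (0, 1).
#' @param F per-species divergence parameters, strictly in (0, 1).
#' @param seed RNG seed.
#' @return list of class `frequency_model`: `p_anc`, `F`, and `f`
#'   (K x m species-frequency matrix, rows named by `names(F)`).
#' @export
simulate_species_frequencies <- function(p_anc, F, seed = 1) {
  if (any(p_anc <= 0 | p_anc >= 1)) stop("ancestral frequencies must lie in (0, 1)")
  if (any(F <= 0 | F >= 1)) stop("divergence parameters must lie in (0, 1)")
  set.seed(seed)
  m <- length(p_anc)
  K <- length(F)
  f <- matrix(NA_real_, K, m)
  for (k in seq_len(K)) {
    a <- p_anc * (1 - F[k]) / F[k]
    b <- (1 - p_anc) * (1 - F[k]) / F[k]
    f[k, ] <- stats::rbeta(m, a, b)
  }
  rownames(f) <- names(F)
  structure(list(p_anc = p_anc, F = F, f = f), class = "frequency_model")
}

#' Sample genotypes under an admixture model
#'
#' Each genotype is binomial:
#' `g_ij ~ Binomial(2, pi_ij)`, `pi_ij = sum_k Q_ik f_kj` — i.e. each of
#' an individual's two allele copies descends from cluster k with
#' probability Q_ik and is then the alt allele with probability f_kj.
#'
#' @param freq a `frequency_model` (or any list with element `f`).
#' @param Q n x K ancestry proportions, rows summing to 1.
#' @param seed RNG seed.
#' @param marker_ids,sample_ids optional ids for the result.
#' @return a `genotype_matrix` (m markers x n samples, no missingness).
#' @export
sample_genotypes <- function(freq, Q, seed = 1, marker_ids = NULL,
                             sample_ids = NULL) {
  f <- freq$f
  Q <- as.matrix(Q)
  if (ncol(Q) != nrow(f)) stop("Q and f disagree on the number of clusters")
  if (any(abs(rowSums(Q) - 1) > 1e-8) || any(Q < 0)) {
    stop("each row of Q must be non-negative and sum to 1")
  }
  set.seed(seed)
  pi <- Q %*% f                     # n x m
  n <- nrow(Q); m <- ncol(f)
  g <- matrix(stats::rbinom(n * m, 2L, t(pi)), nrow = m, ncol = n)
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(m))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  genotype_matrix(g, marker_ids = marker_ids, sample_ids = sample_ids)
}

#' Platform degradation model
#'
#' @param miss_rate per-genotype missing probability; scalar or one value
#'   per sample.
#' @param err_rate per-called-genotype error probability.
#' @param het_hom_bias multiplier (>= 1) on the error rate for
#'   heterozygous genotypes, which then flip to a homozygote; emulates
#'   hemizygosity-driven het-to-hom miscalls.  1 = symmetric model.
#' @param miss_site_sd standard deviation (logit scale) of a shared
#'   per-site missingness effect.  0 (default) gives genotype-independent
#'   MCAR missingness; positive values emulate depth-linked low-coverage
#'   patchiness, where well-covered sites are called in almost every
#'   sample while poorly covered sites are missing almost everywhere.
#' @return list of class `platform_model`.
#' @export
platform_model <- function(miss_rate = 0, err_rate = 0, het_hom_bias = 1,
                           miss_site_sd = 0) {
  stopifnot(all(miss_rate >= 0 & miss_rate <= 1), err_rate >= 0, err_rate <= 1,
            het_hom_bias >= 1, miss_site_sd >= 0)
  structure(list(miss_rate = miss_rate, err_rate = err_rate,
                 het_hom_bias = het_hom_bias, miss_site_sd = miss_site_sd),
            class = "platform_model")
}

#' Degrade a clean genotype matrix with platform missingness and error
#'
#' Each entry is independently set missing with the platform
#' `miss_rate`; each surviving entry is flipped with probability
#' `err_rate` to one of the other two dosage states, chosen uniformly
#' (symmetric model).  With `het_hom_bias > 1`, heterozygotes instead
#' flip with probability `min(1, err_rate * het_hom_bias)` and always to
#' a homozygote.  The true flip mask is attached as attribute
#' `error_mask`.
#'
#' @param g a `genotype_matrix`.
#' @param platform a `platform_model`.
#' @param seed RNG seed.
#' @return degraded `genotype_matrix`.
#' @export
degrade <- function(g, platform, seed = 1) {
  set.seed(seed)
  gm <- unclass(g)
  m <- nrow(gm); n <- ncol(gm)
  miss <- rep(platform$miss_rate, length.out = n)
  p_miss <- matrix(miss, m, n, byrow = TRUE)
  sd_site <- platform$miss_site_sd %||% 0
  if (sd_site > 0) {
    site_eff <- stats::rnorm(m, 0, sd_site)
    inner <- p_miss > 0 & p_miss < 1
    p_miss[inner] <- stats::plogis(stats::qlogis(p_miss[inner]) +
                                     site_eff[row(p_miss)[inner]])
  }
  miss_mask <- matrix(stats::runif(m * n), m, n) < p_miss
  err_p <- matrix(platform$err_rate, m, n)
  if (platform$het_hom_bias > 1) {
    err_p[gm == 1L] <- pmin(1, platform$err_rate * platform$het_hom_bias)
  }
  err_mask <- matrix(stats::runif(m * n) < err_p, m, n) & !miss_mask & !is.na(gm)
  out <- gm
  if (any(err_mask)) {
    cur <- gm[err_mask]
    u <- stats::runif(sum(err_mask))
    flipped <- integer(length(cur))
    for (v in 0:2) {
      others <- setdiff(0:2, v)
      sel <- cur == v
      # a flipped het lands on a homozygote either way, so the biased
      # mode only changes the het flip *probability*, handled above
      flipped[sel] <- ifelse(u[sel] < 0.5, others[1], others[2])
    }
    out[err_mask] <- flipped
  }
  out[miss_mask] <- NA_integer_
  out <- genotype_matrix(out, rownames(gm), colnames(gm))
  attr(out, "error_mask") <- err_mask
  out
}

#' Default simulation configuration
#'
#' The bundled study conditions: K = 4 diverged species, 23 populations
#' of 6 individuals (n = 138), three of the populations admixed with
#' 50:50 hybrids, 60 contigs of 12 kb, 3,000 markers placed with a
#' minimum spacing of 200 bp, Balding-Nichols divergence
#' F = (0.20, 0.20, 0.25, 0.30), lcWGS-style missingness drawn per
#' species in [0.60, 0.77] with genotype error 0.05, array-style
#' missingness in [0.00, 0.02] with error 0.005.
#'
#' @param ... named overrides of any config entry.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(...) {
  species <- c("edulis", "galloprovincialis", "trossulus", "chilensis")
  cfg <- list(
    species = species,
    F = stats::setNames(c(0.20, 0.20, 0.25, 0.30), species),
    # population -> species; "a+b" denotes an admixed population whose
    # individuals are 50:50 hybrids of species a and b
    populations = c(
      rep("edulis", 6), rep("galloprovincialis", 6),
      rep("chilensis", 6), rep("trossulus", 2),
      "edulis+trossulus", "edulis+trossulus", "galloprovincialis+trossulus"
    ),
    samples_per_pop = 6L,
    n_markers = 3000L,
    n_contigs = 60L,
    contig_length = 12000L,
    min_spacing = 200L,
    p_anc_range = c(0.10, 0.90),
    lcwgs_miss_range = c(0.60, 0.77),
    array_miss_range = c(0.00, 0.02),
    lcwgs_err = 0.05,
    array_err = 0.005,
    lcwgs_miss_site_sd = 0,
    array_miss_site_sd = 0,
    hybrid_q = 0.5
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg$populations <- as.character(cfg$populations)
  class(cfg) <- c("sim_config", "list")
  cfg
}

# Place n_markers variant positions over contigs with a minimum spacing,
# keeping a full flank inside the contig.  Returns data.frame(contig, pos).
place_markers <- function(n_markers, n_contigs, contig_length, min_spacing,
                          flank = 35L) {
  per <- ceiling(n_markers / n_contigs)
  lo <- flank + 1L
  hi <- contig_length - flank
  cap <- floor((hi - lo) / max(min_spacing, 1L)) + 1L
  if (per > cap) {
    stop("marker density incompatible with contig lengths: need ", per,
         " markers per contig but spacing allows at most ", cap)
  }
  out <- vector("list", n_contigs)
  placed <- 0L
  for (c in seq_len(n_contigs)) {
    k <- min(per, n_markers - placed)
    if (k <= 0) break
    # jittered grid: guarantees >= min_spacing between neighbours
    slack <- (hi - lo) - (k - 1L) * min_spacing
    offsets <- sort(sample.int(slack + 1L, k, replace = TRUE)) - 1L
    pos <- lo + (seq_len(k) - 1L) * min_spacing + offsets
    out[[c]] <- data.frame(contig = sprintf("ctg%03d", c), pos = pos,
                           stringsAsFactors = FALSE)
    placed <- placed + k
  }
  do.call(rbind, out)
}

#' Simulate a full multi-species array-design fixture
#'
#' Generates a reference FASTA (random sequence with variants planted at
#' a configurable minimum spacing), a clean genotype matrix under the
#' Balding-Nichols + admixture model, lcWGS- and array-degraded copies,
#' a sample sheet and a truth list.  When `out_dir` is given the bundle
#' is written to disk (ref.fasta, lcwgs.vcf, array_genotypes.tsv,
#' samples.tsv, truth.json).
#'
#' @param config a `sim_config`.
#' @param seed RNG seed; all outputs are reproducible under
#'   (config, seed).
#' @param out_dir optional output directory.
#' @return list: `variants`, `ref`, `g_clean`, `g_lcwgs`, `g_array`,
#'   `sheet`, `contig_info`, `truth`, and `paths` when written.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1, out_dir = NULL) {
  set.seed(seed)
  cfg <- config
  K <- length(cfg$species)

  loc <- place_markers(cfg$n_markers, cfg$n_contigs, cfg$contig_length,
                       cfg$min_spacing)
  m <- nrow(loc)

  # reference sequence and alleles
  bases <- c("A", "C", "G", "T")
  ref_seqs <- vapply(seq_len(cfg$n_contigs), function(i) {
    paste(sample(bases, cfg$contig_length, replace = TRUE), collapse = "")
  }, character(1))
  names(ref_seqs) <- sprintf("ctg%03d", seq_len(cfg$n_contigs))
  ref_allele <- vapply(seq_len(m), function(i) {
    substr(ref_seqs[[loc$contig[i]]], loc$pos[i], loc$pos[i])
  }, character(1))
  alt_allele <- vapply(ref_allele, function(b) sample(setdiff(bases, b), 1),
                       character(1))

  # frequencies and ancestry
  p_anc <- stats::runif(m, cfg$p_anc_range[1], cfg$p_anc_range[2])
  freq <- simulate_species_frequencies(p_anc, cfg$F,
                                       seed = seed + 101L)
  pops <- cfg$populations
  n <- length(pops) * cfg$samples_per_pop
  pop_of <- rep(paste0("pop", sprintf("%02d", seq_along(pops))),
                each = cfg$samples_per_pop)
  sample_ids <- paste0(pop_of, "_", rep(seq_len(cfg$samples_per_pop),
                                        times = length(pops)))
  Q <- matrix(0, n, K, dimnames = list(sample_ids, cfg$species))
  species_of <- character(n)
  for (p in seq_along(pops)) {
    rows <- ((p - 1) * cfg$samples_per_pop + 1):(p * cfg$samples_per_pop)
    spec <- strsplit(pops[p], "+", fixed = TRUE)[[1]]
    if (length(spec) == 1) {
      Q[rows, spec] <- 1
      species_of[rows] <- spec
    } else {
      Q[rows, spec[1]] <- cfg$hybrid_q
      Q[rows, spec[2]] <- 1 - cfg$hybrid_q
      species_of[rows] <- "hybrid"
    }
  }

  ids <- marker_id(loc$contig, loc$pos, ref_allele, alt_allele)
  g_clean <- sample_genotypes(freq, Q, seed = seed + 202L,
                              marker_ids = ids, sample_ids = sample_ids)

  # per-species platform missingness
  miss_lcwgs_sp <- stats::setNames(
    stats::runif(K, cfg$lcwgs_miss_range[1], cfg$lcwgs_miss_range[2]),
    cfg$species)
  miss_array_sp <- stats::setNames(
    stats::runif(K, cfg$array_miss_range[1], cfg$array_miss_range[2]),
    cfg$species)
  dominant <- cfg$species[max.col(Q)]
  pm_lcwgs <- platform_model(miss_rate = unname(miss_lcwgs_sp[dominant]),
                             err_rate = cfg$lcwgs_err,
                             miss_site_sd = cfg$lcwgs_miss_site_sd)
  pm_array <- platform_model(miss_rate = unname(miss_array_sp[dominant]),
                             err_rate = cfg$array_err,
                             miss_site_sd = cfg$array_miss_site_sd)
  g_lcwgs <- degrade(g_clean, pm_lcwgs, seed = seed + 303L)
  g_array <- degrade(g_clean, pm_array, seed = seed + 404L)

  # benign caller annotations (all sites pass default filters)
  vt <- variant_table(
    contig = loc$contig, pos = loc$pos, ref = ref_allele, alt = alt_allele,
    QD = stats::runif(m, 5, 30), FS = stats::runif(m, 0, 10),
    MQ = stats::runif(m, 50, 60), HaplotypeScore = stats::runif(m, 0, 5),
    MQRankSum = stats::rnorm(m, 0, 2),
    mean_depth = stats::runif(m, 4, 10)
  )
  ord <- match(vt$id, ids)
  g_clean <- subset_g(g_clean, vt$id)
  g_lcwgs2 <- subset_g(g_lcwgs, vt$id)
  attr(g_lcwgs2, "error_mask") <- attr(g_lcwgs, "error_mask")[ord, , drop = FALSE]
  g_lcwgs <- g_lcwgs2
  g_array2 <- subset_g(g_array, vt$id)
  attr(g_array2, "error_mask") <- attr(g_array, "error_mask")[ord, , drop = FALSE]
  g_array <- g_array2

  sheet <- sample_sheet(sample_ids, pop_of, species = species_of,
                        platform = "lcWGS")
  contig_info <- data.frame(
    contig = names(ref_seqs),
    length = nchar(ref_seqs),
    mean_coverage = stats::runif(cfg$n_contigs, 5, 15),
    stringsAsFactors = FALSE
  )
  truth <- list(
    seed = seed, K = K, species = cfg$species, F = as.list(cfg$F),
    Q_true = Q[match(sample_ids, rownames(Q)), , drop = FALSE],
    species_of_sample = stats::setNames(species_of, sample_ids),
    miss_lcwgs = as.list(miss_lcwgs_sp), miss_array = as.list(miss_array_sp),
    err_lcwgs = cfg$lcwgs_err, err_array = cfg$array_err,
    min_spacing = cfg$min_spacing, n_markers = m,
    note = "synthetic dataset; error rates are order-of-magnitude emulations"
  )

  out <- list(variants = vt, ref = ref_seqs, g_clean = g_clean,
              g_lcwgs = g_lcwgs, g_array = g_array, sheet = sheet,
              contig_info = contig_info, truth = truth, config = cfg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(out_dir, "ref.fasta"),
      vcf = file.path(out_dir, "lcwgs.vcf"),
      array = file.path(out_dir, "array_genotypes.tsv"),
      sheet = file.path(out_dir, "samples.tsv"),
      contigs = file.path(out_dir, "contigs.tsv"),
      truth = file.path(out_dir, "truth.json")
    )
    write_fasta(ref_seqs, paths$fasta)
    write_vcf(vt, g_lcwgs, paths$vcf,
              contig_lengths = stats::setNames(contig_info$length,
                                               contig_info$contig))
    write_genotype_table(g_array, paths$array)
    write_sample_sheet(sheet, paths$sheet)
    utils::write.table(contig_info, paths$contigs, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truth_json <- truth
    truth_json$Q_true <- as.data.frame(truth$Q_true)
    jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                         digits = NA)
    out$paths <- paths
  }
  out
}

#' Synthesize a prior-marker table on a reference
#'
#' Expands per-category counts into concrete prior markers placed at
#' probe-safe positions on the supplied reference contigs (used to
#' emulate an externally provided table of previously published SNPs —
#' e.g. the 810-SNP pool of the blue-mussel array: 12 species_id + 140
#' sex + 301 cancer1 + 35 cancer2 + 113 + 113 structure + 96
#' structure_chilensis).
#'
#' @param counts named integer vector: category -> number of markers.
#' @param ref named character vector of contig sequences.
#' @param seed RNG seed.
#' @param flank_bp flank kept clear of the contig edge.
#' @return a `prior_marker_set`.
#' @export
synthesize_prior_markers <- function(counts, ref, seed = 1, flank_bp = 35L) {
  set.seed(seed)
  total <- sum(counts)
  bases <- c("A", "C", "G", "T")
  contigs <- sort(sample(names(ref), total, replace = TRUE))
  pos <- integer(total)
  for (ctg in unique(contigs)) {
    sel <- contigs == ctg
    # without replacement: coordinates stay unique within a contig
    pos[sel] <- sample((flank_bp + 1L):(nchar(ref[[ctg]]) - flank_bp),
                       sum(sel))
  }
  refa <- vapply(seq_len(total), function(i) {
    substr(ref[[contigs[i]]], pos[i], pos[i])
  }, character(1))
  alta <- vapply(refa, function(b) sample(setdiff(bases, b), 1L), character(1))
  df <- data.frame(
    contig = contigs, pos = pos, ref = refa, alt = alta,
    category = rep(names(counts), times = counts),
    source = "synthetic", stringsAsFactors = FALSE
  )
  # drop accidental coordinate duplicates deterministically
  df <- df[!duplicated(marker_id(df$contig, df$pos, df$ref, df$alt)), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("prior_marker_set", "data.frame")
  df
}
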