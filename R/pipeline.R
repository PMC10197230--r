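#' Load a pipeline configuration
#'
#' Configurations are plain named lists; YAML files are accepted
#' anywhere a config is expected.
#'
#' @param config a named list or path to a YAML file.
#' @return named list.
#' @export
load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  config
}

cfg_get <- function(cfg, key, default = NULL, required = FALSE) {
  if (!is.null(cfg[[key]])) return(cfg[[key]])
  if (required) stop("config key missing: ", key)
  default
}

#' Simulate-subcommand driver
#'
#' Writes a full synthetic fixture bundle (reference FASTA, lcWGS-style
#' VCF, array genotype table, sample sheet, contig table, truth JSON)
#' to `out_dir`.  Byte-identical across reruns with the same
#' (config, seed).
#'
#' @param config list or YAML path; keys: `out_dir` (required), `seed`
#'   (default 1), plus any [sim_config()] override under `sim`.
#' @return the [simulate_dataset()] bundle, invisibly.
#' @export
cmd_simulate <- function(config) {
  cfg <- load_config(config)
  out_dir <- cfg_get(cfg, "out_dir", required = TRUE)
  seed <- cfg_get(cfg, "seed", 1L)
  sim_over <- cfg_get(cfg, "sim", list())
  sc <- do.call(sim_config, sim_over)
  invisible(simulate_dataset(sc, seed = seed, out_dir = out_dir))
}

#' Design-subcommand driver
#'
#' Runs the full array-design workflow: read inputs, hard filters,
#' depth/contig eligibility, per-population missingness, global MAF,
#' flanking-monomorphism screen plus probe extraction and design
#' scoring, species assignment (taken from the sample sheet when
#' present, otherwise inferred by admixture), within-species MAF pass
#' sets, sharing-tier classification, quota-thinned panel assembly and
#' prior-marker merge.  Writes the panel file (+BED), composition
#' report, tier/UpSet table and a machine-readable funnel log of marker
#' counts surviving every stage.
#'
#' @param config list or YAML path; keys: `vcf`, `fasta`, `sample_sheet`,
#'   `out_dir` (required); optional `priors`, `contig_info`, `seed`,
#'   `thresholds` (named overrides), `exclusive_quota`, `K`,
#'   `species_labels`, `q_min`, `ld_prune` (logical, default FALSE for
#'   the design branch).
#' @return list with `panel`, `composition`, `funnel`; files under
#'   `out_dir`.
#' @export
cmd_design <- function(config) {
  cfg <- load_config(config)
  out_dir <- cfg_get(cfg, "out_dir", required = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg_get(cfg, "seed", 1L)
  th <- do.call(filter_thresholds, cfg_get(cfg, "thresholds", list()))

  sheet <- read_sample_sheet(cfg_get(cfg, "sample_sheet", required = TRUE))
  vcf <- read_vcf(cfg_get(cfg, "vcf", required = TRUE), sheet)
  vt <- vcf$variants
  g <- vcf$genotypes
  ref <- read_fasta(cfg_get(cfg, "fasta", required = TRUE))
  contig_path <- cfg_get(cfg, "contig_info")
  contig_info <- if (!is.null(contig_path)) {
    utils::read.delim(contig_path, stringsAsFactors = FALSE)
  } else {
    data.frame(contig = names(ref), length = nchar(ref),
               stringsAsFactors = FALSE)
  }

  funnel <- list(called = nrow(vt))
  full_vt <- vt  # full called set: screen flanks against it

  m_hard <- hard_filter(vt, th)
  m_depth <- depth_contig_filter(vt, contig_info, th)
  m_pop <- pop_missingness_filter(g, sheet, th$pop_missing_max)
  m_maf <- maf_filter(g, min_maf = th$maf_global_min)
  mask <- combine_masks(m_hard, m_depth, m_pop, m_maf)
  funnel$hard_filtered <- sum(m_hard$pass)
  funnel$depth_contig <- sum(m_hard$pass & m_depth$pass)
  funnel$pop_missing <- sum(m_hard$pass & m_depth$pass & m_pop$pass)
  funnel$maf_global <- sum(mask$pass)

  keep <- mask$pass
  vt <- vt[keep, , drop = FALSE]
  g <- subset_g(g, vt$id)

  m_flank <- flanking_monomorphic_mask(vt, screen_vt = full_vt)
  vt <- vt[m_flank$pass, , drop = FALSE]
  g <- subset_g(g, vt$id)
  funnel$flank_monomorphic <- nrow(vt)

  cand <- probe_candidates(vt, ref, screen_vt = full_vt)
  cand_ok <- cand[cand$recommended, , drop = FALSE]
  funnel$probe_recommended <- nrow(cand_ok)
  g_ok <- subset_g(g, cand_ok$id)

  # species groups: sheet labels if present, else admixture assignment
  have_labels <- !all(is.na(sheet$species))
  if (have_labels) {
    groups <- species_groups(sheet)
  } else {
    K <- cfg_get(cfg, "K", required = TRUE)
    labels <- cfg_get(cfg, "species_labels", paste0("cluster", seq_len(K)))
    fit <- admixture_em(g_ok, K, seed = seed)
    assigned <- assign_species(fit, labels, q_min = cfg_get(cfg, "q_min", 0.8))
    sheet$species <- assigned[sheet$sample_id]
    groups <- species_groups(sheet)
  }

  pass_sets <- species_pass_masks(g_ok, groups, maf_min = th$maf_species_min)
  tiers <- classify_sharing_tiers(pass_sets)
  funnel$tiered <- nrow(tiers)

  panel <- select_panel(tiers, cand_ok,
                        exclusive_quota = cfg_get(cfg, "exclusive_quota", 2500L),
                        seed = seed)
  funnel$panel_discovery <- nrow(panel)

  priors_path <- cfg_get(cfg, "priors")
  if (!is.null(priors_path)) {
    priors <- read_prior_markers(priors_path)
    panel <- merge_prior_markers(panel, priors, ref)
    funnel$priors_supplied <- nrow(priors)
    funnel$priors_rejected <- nrow(attr(panel, "rejected"))
  }
  funnel$panel_total <- nrow(panel)

  comp <- panel_composition(panel)
  write_panel(panel, file.path(out_dir, "panel.tsv"))
  utils::write.table(comp, file.path(out_dir, "composition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(attr(tiers, "upset"), file.path(out_dir, "upset.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(funnel, file.path(out_dir, "design_log.json"),
                       auto_unbox = TRUE, digits = NA)
  list(panel = panel, composition = comp, funnel = funnel)
}

#' Validate-subcommand driver
#'
#' Computes the call-rate scenario table, the within-species
#' polymorphism report and the cross-platform concordance report for a
#' pair of genotype datasets over the same marker key space.
#'
#' @param config list or YAML path; keys: `genotypes_a` (e.g. the array
#'   table), `genotypes_b` (e.g. an lcWGS VCF or genotype table),
#'   `sample_sheet`, `out_dir` (required); optional `pairing` (TSV with
#'   sample_a, sample_b, group; defaults to identical ids for samples
#'   shared by the two datasets), `cr_min` (default 0.95),
#'   `cr_thresholds`.
#' @return list with `scenarios`, `polymorphism`, `concordance`.
#' @export
cmd_validate <- function(config) {
  cfg <- load_config(config)
  out_dir <- cfg_get(cfg, "out_dir", required = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sheet <- read_sample_sheet(cfg_get(cfg, "sample_sheet", required = TRUE))
  read_geno <- function(path) {
    if (grepl("\\.vcf(\\.gz)?$", path)) read_vcf(path)$genotypes
    else read_genotype_table(path)
  }
  gA <- read_geno(cfg_get(cfg, "genotypes_a", required = TRUE))
  gB <- read_geno(cfg_get(cfg, "genotypes_b", required = TRUE))

  groups <- species_groups(sheet)
  groups <- lapply(groups, intersect, colnames(gA))
  groups <- groups[vapply(groups, length, 1L) > 0]
  groupings <- c(list(ALL = colnames(gA)), groups)

  thresholds <- cfg_get(cfg, "cr_thresholds", seq(0.90, 0.96, by = 0.01))
  scen <- cr_scenario_table(gA, groupings, thresholds)
  poly <- polymorphism_report(gA, groups, cr_min = cfg_get(cfg, "cr_min", 0.95))

  pairing_path <- cfg_get(cfg, "pairing")
  if (!is.null(pairing_path)) {
    pairing <- utils::read.delim(pairing_path, stringsAsFactors = FALSE)
  } else {
    shared <- intersect(colnames(gA), colnames(gB))
    unpaired <- setdiff(union(colnames(gA), colnames(gB)), shared)
    if (length(unpaired)) {
      message("cmd_validate: ", length(unpaired),
              " unpaired sample(s) skipped: ",
              paste(utils::head(unpaired, 5), collapse = ", "))
    }
    idx <- match(shared, sheet$sample_id)
    pairing <- data.frame(sample_a = shared, sample_b = shared,
                          group = ifelse(is.na(idx), "unassigned",
                                         sheet$species[idx]),
                          stringsAsFactors = FALSE)
  }
  conc <- genotype_concordance(gA, gB, pairing)

  utils::write.table(scen, file.path(out_dir, "cr_scenarios.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(poly, file.path(out_dir, "polymorphism.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(conc$individuals,
                     file.path(out_dir, "concordance_individuals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(conc$groups, file.path(out_dir, "concordance_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(scenarios = scen, polymorphism = poly, concordance = conc)
}
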