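#' Within-species MAF pass sets
#'
#' For each species group, the set of markers with within-species minor
#' allele frequency at or above `maf_min` (computed over called
#' genotypes of that species' samples; markers with no calls in a
#' species are not in its set).
#'
#' @param g a `genotype_matrix` (normally restricted to probe-QC-passed
#'   candidates).
#' @param groups named list of sample-id vectors, one per species; each
#'   group needs at least 2 samples.
#' @param maf_min within-species MAF threshold.
#' @return named list of marker-id character vectors.
#' @export
species_pass_masks <- function(g, groups, maf_min = 0.02) {
  if (length(groups) < 1) stop("no species groups supplied")
  lapply(groups, function(smp) {
    if (length(smp) < 2) stop("species group with fewer than 2 samples")
    p <- alt_freq(g, smp)
    maf <- pmin(p, 1 - p)
    rownames(g)[!is.na(maf) & maf >= maf_min]
  })
}

#' Classify markers into sharing tiers
#'
#' A marker's tier is the number of species in whose pass set it
#' appears: present in all K sets = `shared_all`, in 3 = `shared_3`, in
#' 2 = `shared_2`, in exactly one = `exclusive:<species>`.  Markers in
#' no set are dropped.  An UpSet-style intersection count table over
#' species combinations is attached as attribute `upset`.
#'
#' @param pass_sets named list of marker-id vectors from
#'   [species_pass_masks()] (>= 2 species).
#' @return data.frame (id, n_species, tier) with attribute `upset`.
#' @export
classify_sharing_tiers <- function(pass_sets) {
  if (length(pass_sets) < 2) stop("need at least 2 species sets")
  K <- length(pass_sets)
  sp <- names(pass_sets)
  all_ids <- sort(unique(unlist(pass_sets)))
  member <- vapply(pass_sets, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  if (length(all_ids) == 1L) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, sp))
  n_sp <- rowSums(member)
  tier <- character(length(all_ids))
  tier[n_sp == K] <- "shared_all"
  mid <- n_sp > 1 & n_sp < K
  tier[mid] <- paste0("shared_", n_sp[mid])
  excl <- n_sp == 1
  tier[excl] <- paste0("exclusive:", sp[max.col(member[excl, , drop = FALSE])])
  combo <- apply(member, 1, function(r) paste(sp[r], collapse = "+"))
  upset <- as.data.frame(table(combo), stringsAsFactors = FALSE)
  names(upset) <- c("species_set", "n_markers")
  structure(data.frame(id = all_ids, n_species = n_sp, tier = tier,
                       stringsAsFactors = FALSE),
            upset = upset)
}

#' Assemble the discovery panel from sharing tiers
#'
#' All markers shared by two or more species are included; from each
#' species-exclusive pool, `min(quota, pool size)` markers are drawn
#' uniformly without replacement (over sorted marker ids, under `seed`,
#' so selection is bit-reproducible).  Pools smaller than their quota
#' are kept whole and the shortfall logged.
#'
#' @param tiers output of [classify_sharing_tiers()].
#' @param candidates a `probe_candidates` table carrying probe sequences
#'   for (at least) the tiered markers.
#' @param exclusive_quota per-species quota for exclusive markers.
#' @param seed RNG seed for the random thinning.
#' @return data.frame of class `panel_design` (id, contig, pos, ref,
#'   alt, probe_seq, tier, provenance) with attribute `shortfalls`.
#' @export
select_panel <- function(tiers, candidates, exclusive_quota = 2500L, seed = 1) {
  set.seed(seed)
  shared <- tiers[!startsWith(tiers$tier, "exclusive:"), , drop = FALSE]
  chosen <- shared
  shortfalls <- list()
  for (t in sort(unique(tiers$tier[startsWith(tiers$tier, "exclusive:")]))) {
    pool <- sort(tiers$id[tiers$tier == t])
    take <- min(exclusive_quota, length(pool))
    if (take < exclusive_quota) {
      shortfalls[[t]] <- exclusive_quota - take
      message("select_panel: ", t, " pool (", length(pool),
              ") below quota ", exclusive_quota)
    }
    sel <- sort(sample(pool, take))
    chosen <- rbind(chosen, tiers[match(sel, tiers$id), , drop = FALSE])
  }
  idx <- match(chosen$id, candidates$id)
  if (anyNA(idx)) stop("tiered marker(s) missing from candidate table")
  panel <- data.frame(
    id = chosen$id, contig = candidates$contig[idx],
    pos = candidates$pos[idx], ref = candidates$ref[idx],
    alt = candidates$alt[idx], probe_seq = candidates$probe_seq[idx],
    tier = chosen$tier, provenance = "discovery",
    stringsAsFactors = FALSE
  )
  panel <- panel[order(panel$contig, panel$pos, panel$id), , drop = FALSE]
  rownames(panel) <- NULL
  class(panel) <- c("panel_design", "data.frame")
  attr(panel, "shortfalls") <- shortfalls
  panel
}

#' Merge prior published markers into a panel
#'
#' Prior markers are screened like any candidate: probe extraction from
#' the reference (contig edge or unknown contig rejects the row) and the
#' design-score requirement of `Recommended` on both flanks.  Accepted
#' priors are appended with tier `prior:<category>`; a prior duplicating
#' an existing panel entry (same contig:pos:ref:alt) replaces it, i.e.
#' the prior provenance label wins.  Rejections and their reasons are
#' attached as attribute `rejected` — this is how attrition of a prior
#' pool (e.g. 810 supplied, fewer designable) stays visible.
#'
#' @param panel a `panel_design`.
#' @param priors a `prior_marker_set`.
#' @param ref reference sequences.
#' @param flank_bp flank size.
#' @param scorer probe scorer, default [score_probe()].
#' @return updated `panel_design` with attribute `rejected`.
#' @export
merge_prior_markers <- function(panel, priors, ref, flank_bp = 35L,
                                scorer = score_probe) {
  if (nrow(priors) == 0) {
    attr(panel, "rejected") <- data.frame(id = character(0), reason = character(0))
    return(panel)
  }
  pid <- marker_id(priors$contig, priors$pos, priors$ref, priors$alt)
  probe <- rep(NA_character_, nrow(priors))
  reason <- rep(NA_character_, nrow(priors))
  for (i in seq_len(nrow(priors))) {
    if (!priors$contig[i] %in% names(ref)) {
      reason[i] <- "unknown_contig"
      next
    }
    probe[i] <- tryCatch(
      extract_probe_sequence(ref, priors$contig[i], priors$pos[i], flank_bp,
                             ref_allele = priors$ref[i]),
      error = function(e) NA_character_)
    if (is.na(probe[i])) {
      reason[i] <- "flank_truncated"
      next
    }
    qc <- scorer(probe[i], flank_bp)
    if (!all(qc == "Recommended")) reason[i] <- "probe_qc"
  }
  ok <- is.na(reason)
  rejected <- data.frame(id = pid[!ok], reason = reason[!ok],
                         stringsAsFactors = FALSE)
  if (nrow(rejected) > 0) {
    message("merge_prior_markers: rejected ", nrow(rejected), " prior(s)")
  }
  add <- data.frame(
    id = pid[ok], contig = priors$contig[ok], pos = priors$pos[ok],
    ref = priors$ref[ok], alt = priors$alt[ok], probe_seq = probe[ok],
    tier = paste0("prior:", priors$category[ok]), provenance = "prior",
    stringsAsFactors = FALSE
  )
  out <- panel[!panel$id %in% add$id, , drop = FALSE]  # prior label wins
  out <- rbind(out, add)
  out <- out[order(out$contig, out$pos, out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("panel_design", "data.frame")
  attr(out, "shortfalls") <- attr(panel, "shortfalls")
  attr(out, "rejected") <- rejected
  out
}

#' Panel composition report
#'
#' Per-tier marker counts in the layout of a published array design
#' table: one line per sharing tier and per-species exclusive class,
#' prior markers aggregated on a single line, and a total that equals
#' the panel size by construction.
#'
#' @param panel a `panel_design`.
#' @return data.frame (category, n_markers) whose last row is the total.
#' @export
panel_composition <- function(panel) {
  tier <- ifelse(startsWith(panel$tier, "prior:"), "prior", panel$tier)
  shared <- grep("^shared_", unique(tier), value = TRUE)
  order_cats <- c("shared_all", sort(setdiff(shared, "shared_all"),
                                     decreasing = TRUE),
                  sort(grep("^exclusive:", unique(tier), value = TRUE)),
                  "prior")
  cats <- order_cats[order_cats %in% tier]
  counts <- vapply(cats, function(ct) sum(tier == ct), integer(1))
  out <- data.frame(category = c(cats, "total"),
                    n_markers = c(unname(counts), nrow(panel)),
                    stringsAsFactors = FALSE)
  stopifnot(sum(counts) == nrow(panel))
  out
}

#' Read and validate a panel composition table
#'
#' Reads a tab-delimited composition report (category, n_markers whose
#' last row is the total) and checks the structural identity that the
#' per-category counts sum to the stated total.
#'
#' @param path composition TSV.
#' @return the composition data.frame; attribute `total` carries the
#'   validated panel size.
#' @export
read_panel_composition <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("category", "n_markers") %in% names(df)))
  total_row <- df$category == "total"
  if (sum(total_row) != 1) stop("composition table needs exactly one total row")
  total <- df$n_markers[total_row]
  if (sum(df$n_markers[!total_row]) != total) {
    stop("composition counts do not sum to the stated total")
  }
  attr(df, "total") <- total
  df
}
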