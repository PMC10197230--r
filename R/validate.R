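#' Per-marker call rate within a sample grouping
#'
#' @param g a `genotype_matrix`.
#' @param samples non-empty sample-id vector defining the grouping.
#' @return numeric vector in [0, 1], named by marker id: the fraction of
#'   grouping samples with a non-missing call.
#' @export
marker_call_rate <- function(g, samples = colnames(g)) {
  if (length(samples) == 0) stop("empty sample grouping")
  missing <- setdiff(samples, colnames(g))
  if (length(missing)) stop("unknown sample(s): ", paste(missing, collapse = ", "))
  rowMeans(!is.na(unclass(g)[, samples, drop = FALSE]))
}

#' Call-rate scenario table
#'
#' For each grouping and each CR threshold, the number of markers whose
#' call rate within the grouping is at or above the threshold — the
#' retained-marker scenario table used to compare running all samples
#' combined against per-species runs.
#'
#' @param g a `genotype_matrix`.
#' @param groupings named list of sample-id vectors (e.g. `ALL` plus one
#'   entry per species).
#' @param thresholds ascending CR thresholds (default 0.90 to 0.96).
#' @return data.frame with column `cr` plus one retained-count column
#'   per grouping; counts are non-increasing down each column.
#' @export
cr_scenario_table <- function(g, groupings, thresholds = seq(0.90, 0.96, by = 0.01)) {
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  cr <- lapply(groupings, function(s) marker_call_rate(g, s))
  out <- data.frame(cr = thresholds)
  for (grp in names(groupings)) {
    # small tolerance so 0.93 from seq() matches a call rate of exactly 93/100
    out[[grp]] <- vapply(thresholds,
                         function(t) sum(cr[[grp]] >= t - 1e-9), integer(1))
  }
  out
}

#' Within-group polymorphism report
#'
#' Among the markers reaching call rate `cr_min` within a grouping, a
#' marker is monomorphic iff exactly one allele is observed across the
#' called genotypes (all hom-ref or all hom-alt; any heterozygote shows
#' both alleles), polymorphic otherwise, and uniquely polymorphic when
#' no other grouping's polymorphic set contains it.  Monomorphic +
#' polymorphic = total holds for every grouping by construction.
#'
#' @param g a `genotype_matrix`.
#' @param groupings named list of per-species sample-id vectors.
#' @param cr_min call-rate threshold for a marker to enter a grouping's
#'   report.
#' @return data.frame (grouping, total, monomorphic, polymorphic,
#'   unique_polymorphic); attribute `polymorphic_sets` holds the marker
#'   ids per grouping and `upset` their intersection counts.
#' @export
polymorphism_report <- function(g, groupings, cr_min = 0.95) {
  gm <- unclass(g)
  per <- lapply(names(groupings), function(grp) {
    smp <- groupings[[grp]]
    cr <- marker_call_rate(g, smp)
    keep <- cr >= cr_min
    sub <- gm[keep, smp, drop = FALSE]
    has_ref <- rowSums(sub < 2, na.rm = TRUE) > 0   # 0 or 1 shows ref
    has_alt <- rowSums(sub > 0, na.rm = TRUE) > 0   # 1 or 2 shows alt
    called <- rowSums(!is.na(sub)) > 0
    poly <- called & has_ref & has_alt
    list(total = sum(keep), ids = rownames(sub), poly_ids = rownames(sub)[poly])
  })
  names(per) <- names(groupings)
  poly_sets <- lapply(per, `[[`, "poly_ids")
  rows <- lapply(names(per), function(grp) {
    others <- unique(unlist(poly_sets[setdiff(names(per), grp)]))
    npoly <- length(poly_sets[[grp]])
    data.frame(grouping = grp, total = per[[grp]]$total,
               monomorphic = per[[grp]]$total - npoly,
               polymorphic = npoly,
               unique_polymorphic = sum(!poly_sets[[grp]] %in% others),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  all_ids <- sort(unique(unlist(poly_sets)))
  if (length(all_ids)) {
    member <- vapply(poly_sets, function(s) all_ids %in% s,
                     logical(length(all_ids)))
    if (length(all_ids) == 1L) member <- matrix(member, nrow = 1)
    combo <- apply(member, 1, function(r) paste(names(poly_sets)[r], collapse = "+"))
    upset <- as.data.frame(table(combo), stringsAsFactors = FALSE)
    names(upset) <- c("grouping_set", "n_markers")
  } else {
    upset <- data.frame(grouping_set = character(0), n_markers = integer(0))
  }
  attr(out, "polymorphic_sets") <- poly_sets
  attr(out, "upset") <- upset
  out
}

#' Cross-platform genotype concordance
#'
#' For each paired individual, comparisons are restricted to the markers
#' called in BOTH datasets (on the shared marker ids, matched by the
#' contig:pos:ref:alt key so allele orientation is identical); the
#' concordance is `100 * n_equal / n_compared`.  Group summaries are
#' mean +/- standard error over individuals (individuals with
#' `n_compared = 0` are reported but excluded from the mean).  Each
#' individual's missingness within each dataset (over the shared
#' markers) is reported alongside.
#'
#' @param gA,gB two `genotype_matrix` objects with overlapping marker ids.
#' @param pairing data.frame with columns `sample_a`, `sample_b` and
#'   optionally `group`.
#' @return list of class `concordance_report`: `individuals`
#'   (per-individual table) and `groups` (mean +/- SE per group,
#'   including missingness summaries).
#' @export
genotype_concordance <- function(gA, gB, pairing) {
  stopifnot(all(c("sample_a", "sample_b") %in% names(pairing)))
  common <- intersect(rownames(gA), rownames(gB))
  if (length(common) == 0) stop("no shared markers between datasets")
  A <- unclass(gA)[common, , drop = FALSE]
  B <- unclass(gB)[common, , drop = FALSE]
  grp <- if ("group" %in% names(pairing)) pairing$group else "all"
  ind <- lapply(seq_len(nrow(pairing)), function(i) {
    a <- A[, pairing$sample_a[i]]
    b <- B[, pairing$sample_b[i]]
    both <- !is.na(a) & !is.na(b)
    n <- sum(both)
    data.frame(
      sample_a = pairing$sample_a[i], sample_b = pairing$sample_b[i],
      group = grp[min(i, length(grp))],
      n_markers = length(common), n_compared = n,
      n_equal = sum(a[both] == b[both]),
      pct_concordant = if (n > 0) 100 * sum(a[both] == b[both]) / n else NA_real_,
      miss_a = mean(is.na(a)), miss_b = mean(is.na(b)),
      stringsAsFactors = FALSE
    )
  })
  ind <- do.call(rbind, ind)
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  groups <- do.call(rbind, lapply(split(ind, ind$group), function(d) {
    ok <- !is.na(d$pct_concordant)
    data.frame(
      group = d$group[1], n_individuals = sum(ok),
      mean_pct = mean(d$pct_concordant[ok]), se_pct = se(d$pct_concordant[ok]),
      mean_miss_a = mean(d$miss_a), se_miss_a = se(d$miss_a),
      mean_miss_b = mean(d$miss_b), se_miss_b = se(d$miss_b),
      stringsAsFactors = FALSE
    )
  }))
  rownames(groups) <- NULL
  structure(list(individuals = ind, groups = groups),
            class = "concordance_report")
}
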