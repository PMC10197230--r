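#' Default variant-filter thresholds
#'
#' Bundles the hard-filter, depth/contig, frequency, missingness and LD
#' pruning thresholds used across the filtering ladder.  Defaults follow
#' the GATK-style hard-filter convention plus the settings used to build
#' the blue-mussel 60 K class array: QD < 2, FS > 60, MQ < 40,
#' HaplotypeScore > 13, MQRankSum < -13 fail; site mean depth outside
#' [4, 10] fails; contigs must be > 10 kb with mean coverage < 20x;
#' global MAF >= 0.01 and within-species MAF >= 0.02; markers missing in
#' > 50\% of any population fail; LD pruning at 50 kb windows, 10 kb
#' step, r^2 > 0.1.
#'
#' Note the MQRankSum bound: hard-filter write-ups occasionally print the
#' threshold without its sign; a positive bound would fail essentially
#' every site, so the default is -13 and the value is configurable.
#'
#' @param ... named overrides of any threshold.
#' @return list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(...) {
  th <- list(
    qd_min = 2.0, fs_max = 60.0, mq_min = 40.0,
    haplotype_score_max = 13.0, mqranksum_min = -13.0,
    depth_min = 4, depth_max = 10,
    contig_min_len = 10000L, contig_max_mean_cov = 20,
    maf_global_min = 0.01, maf_species_min = 0.02,
    pop_missing_max = 0.50,
    ld_window = 50000L, ld_step = 10000L, ld_r2_max = 0.1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(th))
  if (length(unknown)) stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
  th[names(over)] <- over
  class(th) <- "filter_thresholds"
  th
}

# A filter mask: per-marker PASS/FAIL with the first failing rule as tag.
new_filter_mask <- function(id, pass, tag) {
  stopifnot(length(id) == length(pass), length(tag) == length(pass))
  tag[pass] <- ""
  if (any(!pass & tag == "")) stop("failing markers must carry a tag")
  structure(data.frame(id = id, pass = pass, tag = tag,
                       stringsAsFactors = FALSE),
            class = c("filter_mask", "data.frame"))
}

#' Combine filter masks by AND
#'
#' @param ... `filter_mask` objects over the same marker ids.
#' @return a `filter_mask`; a marker fails if it fails any input mask,
#'   tagged with the first mask (in argument order) that fails it.
#' @export
combine_masks <- function(...) {
  masks <- list(...)
  stopifnot(length(masks) >= 1)
  id <- masks[[1]]$id
  pass <- rep(TRUE, length(id))
  tag <- rep("", length(id))
  for (m in masks) {
    stopifnot(identical(m$id, id))
    newfail <- pass & !m$pass
    tag[newfail] <- m$tag[newfail]
    pass <- pass & m$pass
  }
  new_filter_mask(id, pass, tag)
}

#' GATK-style hard filter on caller annotations
#'
#' FAIL iff QD < qd_min, FS > fs_max, MQ < mq_min,
#' HaplotypeScore > haplotype_score_max or MQRankSum < mqranksum_min.
#' Sites at exactly a threshold boundary pass (strict inequalities).  A
#' missing required annotation fails conservatively with tag
#' `"missing_annot"`.
#'
#' @param vt a `variant_table`.
#' @param th a `filter_thresholds`.
#' @return a `filter_mask`.
#' @export
hard_filter <- function(vt, th = filter_thresholds()) {
  ann <- cbind(vt$QD, vt$FS, vt$MQ, vt$HaplotypeScore, vt$MQRankSum)
  has_na <- rowSums(is.na(ann)) > 0
  fails <- cbind(
    QD = vt$QD < th$qd_min,
    FS = vt$FS > th$fs_max,
    MQ = vt$MQ < th$mq_min,
    HaplotypeScore = vt$HaplotypeScore > th$haplotype_score_max,
    MQRankSum = vt$MQRankSum < th$mqranksum_min
  )
  rule <- colnames(fails)
  first_fail <- apply(fails, 1, function(r) {
    i <- which(r)
    if (length(i)) rule[i[1]] else ""
  })
  tag <- ifelse(has_na, "missing_annot", first_fail)
  pass <- !has_na & first_fail == ""
  new_filter_mask(vt$id, pass, tag)
}

#' Depth and contig eligibility filter
#'
#' FAIL iff the contig is not longer than `contig_min_len`, the contig
#' mean coverage is at or above `contig_max_mean_cov`, or the site mean
#' depth lies outside `[depth_min, depth_max]` (inclusive bounds pass).
#'
#' @param vt a `variant_table` with `mean_depth` populated.
#' @param contig_info data.frame with columns contig, length and
#'   optionally mean_coverage; every variant contig must appear.
#' @param th a `filter_thresholds`.
#' @return a `filter_mask` with tags `contig_len`, `contig_cov`,
#'   `depth_low`, `depth_high` or `missing_depth`.
#' @export
depth_contig_filter <- function(vt, contig_info, th = filter_thresholds()) {
  idx <- match(vt$contig, contig_info$contig)
  if (anyNA(idx)) {
    stop("unknown contig(s): ",
         paste(unique(vt$contig[is.na(idx)]), collapse = ", "))
  }
  len <- contig_info$length[idx]
  cov <- if ("mean_coverage" %in% names(contig_info)) {
    contig_info$mean_coverage[idx]
  } else rep(NA_real_, length(idx))
  tag <- character(nrow(vt))
  tag[is.na(vt$mean_depth)] <- "missing_depth"
  tag[tag == "" & len <= th$contig_min_len] <- "contig_len"
  tag[tag == "" & !is.na(cov) & cov >= th$contig_max_mean_cov] <- "contig_cov"
  tag[tag == "" & vt$mean_depth < th$depth_min] <- "depth_low"
  tag[tag == "" & vt$mean_depth > th$depth_max] <- "depth_high"
  new_filter_mask(vt$id, tag == "", tag)
}

# Allele frequency of the alt allele among called genotypes; NA if none.
alt_freq <- function(g, samples = colnames(g)) {
  sub <- unclass(g)[, samples, drop = FALSE]
  called <- rowSums(!is.na(sub))
  p <- rowSums(sub, na.rm = TRUE) / (2 * called)
  p[called == 0] <- NA_real_
  p
}

#' Minor allele frequency filter
#'
#' MAF is computed from called genotypes only:
#' `p = sum(dosage) / (2 * n_called)`, MAF = min(p, 1 - p).  FAIL iff
#' MAF < `min_maf` within the given sample group; markers with zero
#' called genotypes fail with tag `"no_calls"`.
#'
#' @param g a `genotype_matrix`.
#' @param samples sample ids defining the group (default: all samples).
#' @param min_maf minimum minor allele frequency.
#' @return a `filter_mask`.
#' @export
maf_filter <- function(g, samples = colnames(g), min_maf = 0.01) {
  if (length(samples) == 0) stop("empty sample group")
  p <- alt_freq(g, samples)
  maf <- pmin(p, 1 - p)
  tag <- character(nrow(g))
  tag[is.na(p)] <- "no_calls"
  tag[tag == "" & maf < min_maf] <- "maf"
  new_filter_mask(rownames(g), tag == "", tag)
}

#' Per-population missingness filter
#'
#' FAIL iff the missing fraction exceeds `max_frac` (strict inequality)
#' in any population: a 6-sample population with exactly 3 missing
#' genotypes (50\%) passes at the default 0.5.
#'
#' @param g a `genotype_matrix`.
#' @param sheet a `sample_sheet` mapping every sample of `g` to a
#'   population.
#' @param max_frac maximum tolerated missing fraction per population.
#' @return a `filter_mask` with tag `"pop_missing"`.
#' @export
pop_missingness_filter <- function(g, sheet, max_frac = 0.5) {
  idx <- match(colnames(g), sheet$sample_id)
  if (anyNA(idx)) {
    stop("samples absent from sheet: ",
         paste(colnames(g)[is.na(idx)], collapse = ", "))
  }
  pops <- split(colnames(g), sheet$population[idx])
  fail <- rep(FALSE, nrow(g))
  for (p in pops) {
    frac <- rowMeans(is.na(unclass(g)[, p, drop = FALSE]))
    fail <- fail | frac > max_frac
  }
  new_filter_mask(rownames(g), !fail, ifelse(fail, "pop_missing", ""))
}

#' Sliding-window LD pruning
#'
#' Greedy pruning of linked markers: windows of `window_bp` advance by
#' `step_bp` along each contig; within a window markers are scanned in
#' position order and a marker is removed when its r^2 (squared Pearson
#' correlation of dosage vectors over pairwise-complete samples) with any
#' retained earlier marker exceeds `r2_max`.  Deterministic; the `seed`
#' argument is reserved and unused.
#'
#' @param g a `genotype_matrix` aligned to `vt`.
#' @param vt a `variant_table` sorted by (contig, pos).
#' @param window_bp,step_bp window and step sizes in bp (window >= step).
#' @param r2_max r^2 threshold above which one of a pair is removed.
#' @param seed reserved.
#' @return character vector of retained marker ids, in input order.
#' @export
ld_prune <- function(g, vt, window_bp = 50000L, step_bp = 10000L,
                     r2_max = 0.1, seed = NULL) {
  if (window_bp < step_bp) stop("window must be >= step")
  stopifnot(identical(rownames(g), vt$id))
  keep <- rep(TRUE, nrow(vt))
  gm <- unclass(g)
  for (ctg in unique(vt$contig)) {
    rows <- which(vt$contig == ctg)
    pos <- vt$pos[rows]
    starts <- seq(min(pos), max(pos), by = step_bp)
    for (ws in starts) {
      inw <- rows[pos >= ws & pos < ws + window_bp & keep[rows]]
      if (length(inw) < 2) next
      cc <- suppressWarnings(
        stats::cor(t(gm[inw, , drop = FALSE]), use = "pairwise.complete.obs"))
      r2 <- cc^2
      retained <- integer(0)
      for (j in seq_along(inw)) {
        if (length(retained) > 0) {
          r2j <- r2[j, retained]
          if (any(!is.na(r2j) & r2j > r2_max)) {
            keep[inw[j]] <- FALSE
            next
          }
        }
        retained <- c(retained, j)
      }
    }
  }
  vt$id[keep]
}
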