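#' Flanking-monomorphism screen
#'
#' A marker passes iff no other variant in the supplied list lies on the
#' same contig within `flank_bp` of its position (boundary inclusive:
#' two variants exactly `flank_bp` apart disqualify each other).  Array
#' probes interrogate the 35 bp either side of the variant, so any
#' polymorphism in that window can disrupt hybridization; the screen is
#' normally run against the *full* called variant list, before other
#' filters discard sites, since unseen flanking polymorphism is the main
#' cause of probe failure.
#'
#' @param vt a `variant_table`, sorted by (contig, pos).
#' @param flank_bp flank size either side of the variant (default 35).
#' @param screen_vt optional larger `variant_table` to screen against
#'   (defaults to `vt` itself); disqualification is symmetric within it.
#' @return a `filter_mask` over `vt$id` with tag `"flank_polymorphic"`.
#' @export
flanking_monomorphic_mask <- function(vt, flank_bp = 35L, screen_vt = vt) {
  # for each variant the nearest other variant on the contig decides
  fail <- logical(nrow(vt))
  for (ctg in unique(vt$contig)) {
    rows <- which(vt$contig == ctg)
    pos <- vt$pos[rows]
    spos <- sort(screen_vt$pos[screen_vt$contig == ctg])
    if (length(spos) == 0) next
    # distance to nearest screen variant that is not the site itself
    idx <- findInterval(pos, spos)
    near <- rep(Inf, length(pos))
    for (i in seq_along(pos)) {
      cand <- spos[max(1L, idx[i] - 1L):min(length(spos), idx[i] + 1L)]
      cand <- cand[cand != pos[i]]
      # handle duplicated positions in the screen list
      if (sum(spos == pos[i]) > 1L) cand <- c(cand, pos[i])
      if (length(cand)) near[i] <- min(abs(cand - pos[i]))
    }
    fail[rows] <- near <= flank_bp
  }
  new_filter_mask(vt$id, !fail, ifelse(fail, "flank_polymorphic", ""))
}

#' Extract the 71-mer reference probe sequence around a variant
#'
#' @param ref named character vector of contig sequences (see
#'   [read_fasta()]).
#' @param contig,pos variant coordinates (1-based).
#' @param flank_bp flank size; the probe is `2 * flank_bp + 1` nt with
#'   the variant base at position `flank_bp + 1`.
#' @param ref_allele when given, the extracted center base must equal
#'   it, otherwise a reference-mismatch error is raised.
#' @return the probe sequence (uppercase character scalar).
#' @export
extract_probe_sequence <- function(ref, contig, pos, flank_bp = 35L,
                                   ref_allele = NULL) {
  if (!contig %in% names(ref)) stop("unknown contig: ", contig)
  seq <- ref[[contig]]
  if (pos - flank_bp < 1L || pos + flank_bp > nchar(seq)) {
    stop("flank truncated: position ", pos, " on ", contig,
         " leaves less than ", flank_bp, " bp of flank")
  }
  probe <- substr(seq, pos - flank_bp, pos + flank_bp)
  if (!is.null(ref_allele)) {
    center <- substr(probe, flank_bp + 1L, flank_bp + 1L)
    if (center != ref_allele) {
      stop("reference mismatch at ", contig, ":", pos, " (", center,
           " != ", ref_allele, ")")
    }
  }
  probe
}

# Longest homopolymer run in a sequence.
max_homopolymer <- function(seq) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  max(r$lengths)
}

#' Heuristic probe design score
#'
#' Stand-in classifier for vendor per-flank probe design scores, with
#' the same four classes.  Per flank: `NotPossible` if it contains a
#' non-ACGT base; `NotRecommended` if GC content falls outside
#' [0.25, 0.75] or it contains a homopolymer of 8+; `Neutral` for a
#' homopolymer of 6-7; else `Recommended`.  Vendor scores can be
#' substituted wherever a scorer function is accepted (signature:
#' 71-mer in, `c(left=, right=)` classes out).
#'
#' @param probe_seq 71-mer (or `2 * flank_bp + 1`-mer) probe sequence.
#' @param flank_bp flank size.
#' @return named character vector `c(left = class, right = class)`.
#' @export
score_probe <- function(probe_seq, flank_bp = 35L) {
  score_flank <- function(fl) {
    if (grepl("[^ACGT]", fl)) return("NotPossible")
    gc <- nchar(gsub("[AT]", "", fl)) / nchar(fl)
    hp <- max_homopolymer(fl)
    if (gc < 0.25 || gc > 0.75 || hp >= 8) return("NotRecommended")
    if (hp >= 6) return("Neutral")
    "Recommended"
  }
  left <- substr(probe_seq, 1L, flank_bp)
  right <- substr(probe_seq, flank_bp + 2L, 2L * flank_bp + 1L)
  c(left = score_flank(left), right = score_flank(right))
}

#' Build probe candidates for a variant set
#'
#' Combines probe extraction, the flanking-monomorphism screen and
#' per-flank design scoring into one candidate table.  Markers whose
#' probe cannot be extracted (contig edge) get `NA` probe and class
#' `NotPossible`.
#'
#' @param vt a `variant_table` of candidate markers.
#' @param ref reference sequences (named character vector).
#' @param screen_vt variant list for the monomorphism screen (default:
#'   `vt`; pass the full pre-filter list when available).
#' @param flank_bp flank size.
#' @param scorer scoring function, default [score_probe()].
#' @return data.frame of class `probe_candidates`: id, contig, pos, ref,
#'   alt, probe_seq, flank_clean, qc_left, qc_right, recommended.
#' @export
probe_candidates <- function(vt, ref, screen_vt = vt, flank_bp = 35L,
                             scorer = score_probe) {
  mask <- flanking_monomorphic_mask(vt, flank_bp, screen_vt)
  probe <- rep(NA_character_, nrow(vt))
  for (i in seq_len(nrow(vt))) {
    probe[i] <- tryCatch(
      extract_probe_sequence(ref, vt$contig[i], vt$pos[i], flank_bp,
                             ref_allele = vt$ref[i]),
      error = function(e) NA_character_)
  }
  qc <- t(vapply(probe, function(p) {
    if (is.na(p)) c(left = "NotPossible", right = "NotPossible")
    else scorer(p, flank_bp)
  }, c(left = "", right = "")))
  out <- data.frame(
    id = vt$id, contig = vt$contig, pos = vt$pos, ref = vt$ref, alt = vt$alt,
    probe_seq = probe, flank_clean = mask$pass,
    qc_left = qc[, "left"], qc_right = qc[, "right"],
    stringsAsFactors = FALSE
  )
  out$recommended <- out$qc_left == "Recommended" & out$qc_right == "Recommended"
  rownames(out) <- NULL
  class(out) <- c("probe_candidates", "data.frame")
  out
}

#' Import vendor probe scores
#'
#' Tab-delimited file with columns id, qc_left, qc_right using the four
#' design classes; returns a scorer-compatible lookup applied by id.
#'
#' @param path score file.
#' @param candidates a `probe_candidates` table to annotate.
#' @return `candidates` with qc_left/qc_right/recommended replaced by
#'   the vendor classes (markers absent from the file keep their
#'   heuristic classes).
#' @export
apply_vendor_scores <- function(candidates, path) {
  sc <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "qc_left", "qc_right") %in% names(sc)))
  classes <- c("Recommended", "Neutral", "NotRecommended", "NotPossible")
  if (!all(sc$qc_left %in% classes) || !all(sc$qc_right %in% classes)) {
    stop("unknown probe QC class in vendor file")
  }
  idx <- match(candidates$id, sc$id)
  hit <- !is.na(idx)
  candidates$qc_left[hit] <- sc$qc_left[idx[hit]]
  candidates$qc_right[hit] <- sc$qc_right[idx[hit]]
  candidates$recommended <- candidates$qc_left == "Recommended" &
    candidates$qc_right == "Recommended"
  candidates
}
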