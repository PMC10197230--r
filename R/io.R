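#' Read a multi-sample VCF into a variant table and genotype matrix
#'
#' Keeps biallelic SNP records only; multiallelic and non-SNP records are
#' dropped with a logged count (attribute `dropped`).  `./.` genotypes
#' become `NA`; phase separators `/` and `|` are treated identically.
#' Caller annotations (QD, FS, MQ, HaplotypeScore, MQRankSum) are taken
#' from INFO when present and left `NA` otherwise; per-site mean depth is
#' the mean FORMAT/DP across samples when available, else INFO/DP divided
#' by the sample count.
#'
#' @param path VCF or VCF.gz file with GT fields.
#' @param sheet optional `sample_sheet`; every VCF sample must appear in
#'   it, otherwise an error lists the offenders.
#' @return list with `variants` (variant_table) and `genotypes`
#'   (genotype_matrix); attribute `dropped` counts excluded records.
#' @export
read_vcf <- function(path, sheet = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (nrow(fix) == 0L) stop("VCF contains no records: ", path)
  samples <- colnames(vcf@gt)[-1]
  if (!is.null(sheet)) {
    missing <- setdiff(samples, sheet$sample_id)
    if (length(missing) > 0) {
      stop("VCF samples absent from sample sheet: ", paste(missing, collapse = ", "))
    }
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!is_snp)
  if (n_drop > 0) {
    message("read_vcf: dropped ", n_drop, " non-biallelic-SNP record(s)")
  }
  if (!any(is_snp)) stop("no biallelic SNP records in ", path)

  info_num <- function(key) {
    out <- suppressWarnings(vcfR::extract.info(vcf, element = key, as.numeric = TRUE))
    if (is.null(out)) rep(NA_real_, nrow(fix)) else as.numeric(out)
  }
  dp_fmt <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  if (!is.null(dp_fmt) && !all(is.na(dp_fmt))) {
    mean_depth <- rowMeans(dp_fmt, na.rm = TRUE)
    mean_depth[is.nan(mean_depth)] <- NA_real_
  } else {
    mean_depth <- info_num("DP") / length(samples)
  }

  vt <- variant_table(
    contig = fix[is_snp, "CHROM"], pos = as.integer(fix[is_snp, "POS"]),
    ref = ref[is_snp], alt = alt[is_snp],
    QD = info_num("QD")[is_snp], FS = info_num("FS")[is_snp],
    MQ = info_num("MQ")[is_snp],
    HaplotypeScore = info_num("HaplotypeScore")[is_snp],
    MQRankSum = info_num("MQRankSum")[is_snp],
    mean_depth = mean_depth[is_snp]
  )

  gt <- vcfR::extract.gt(vcf, element = "GT")[is_snp, , drop = FALSE]
  dos <- gt_to_dosage(gt)
  # variant_table() sorts by (contig, pos); align genotype rows to it
  raw_ids <- marker_id(fix[is_snp, "CHROM"], as.integer(fix[is_snp, "POS"]),
                       ref[is_snp], alt[is_snp])
  rownames(dos) <- raw_ids
  dos <- dos[vt$id, , drop = FALSE]
  g <- genotype_matrix(dos, marker_ids = vt$id, sample_ids = samples)
  structure(list(variants = vt, genotypes = g), dropped = n_drop)
}

# GT strings ("0/1", "1|0", "./.", ".") -> dosage 0/1/2/NA
gt_to_dosage <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  out[gt %in% "0/0"] <- 0L
  out[gt %in% c("0/1", "1/0")] <- 1L
  out[gt %in% "1/1"] <- 2L
  bad <- !is.na(gt) & !(gt %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".", "././.")) &
    !grepl("\\.", gt)
  if (any(bad)) {
    stop("unparseable GT value(s), e.g. ", gt[which(bad)[1]],
         " (only biallelic diploid calls are supported)")
  }
  out
}

#' Write a variant table and genotype matrix as VCF 4.2
#'
#' Emits GT-only genotype columns plus the caller annotations carried by
#' the variant table (QD, FS, MQ, HaplotypeScore, MQRankSum and total DP)
#' in INFO.  `read_vcf(write_vcf(...))` round-trips the genotype matrix
#' bit-exactly.
#'
#' @param vt a `variant_table`.
#' @param g a `genotype_matrix` aligned to `vt$id`.
#' @param path output file.
#' @param contig_lengths optional named vector for ##contig header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, g, path, contig_lengths = NULL) {
  stopifnot(identical(rownames(g), vt$id))
  n <- ncol(g)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=snpanel",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias (phred)">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=HaplotypeScore,Number=1,Type=Float,Description="Haplotype score">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping quality rank-sum">',
    '##INFO=<ID=DP,Number=1,Type=Float,Description="Total depth across samples">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", colnames(g)), collapse = "\t"))
  fmt1 <- function(key, x) ifelse(is.na(x), NA, paste0(key, "=", format(x, digits = 10, trim = TRUE, scientific = FALSE)))
  info_parts <- cbind(
    fmt1("QD", vt$QD), fmt1("FS", vt$FS), fmt1("MQ", vt$MQ),
    fmt1("HaplotypeScore", vt$HaplotypeScore), fmt1("MQRankSum", vt$MQRankSum),
    fmt1("DP", vt$mean_depth * n)
  )
  info <- apply(info_parts, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) "." else paste(r, collapse = ";")
  })
  gt_chr <- matrix("./.", nrow(g), ncol(g))
  gt_chr[which(unclass(g) == 0L)] <- "0/0"
  gt_chr[which(unclass(g) == 1L)] <- "0/1"
  gt_chr[which(unclass(g) == 2L)] <- "1/1"
  body <- cbind(vt$contig, vt$pos, vt$id, vt$ref, vt$alt, ".", "PASS", info,
                "GT", gt_chr)
  lines <- c(hdr, apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a (multi-)FASTA reference
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences, one per contig;
#'   duplicate contig names or an empty file are errors.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate contig names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  out <- toupper(as.character(seqs))
  names(out) <- nm
  out
}

#' Write a named set of sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a prior (previously published) marker table
#'
#' Tab-delimited table with columns contig, pos, ref, alt, category and
#' optionally source.  Rows duplicated on (contig, pos, ref, alt) are kept
#' once with a logged count; categories outside the declared vocabulary
#' are an error naming the offending row.
#'
#' @param path delimited file.
#' @param categories allowed category vocabulary.
#' @return data.frame of class `prior_marker_set`; attributes
#'   `category_counts` and `n_dedup`.
#' @export
read_prior_markers <- function(path,
                               categories = c("species_id", "sex", "cancer1",
                                              "cancer2", "structure",
                                              "structure_fluidigm",
                                              "structure_chilensis")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("contig", "pos", "ref", "alt", "category")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("prior marker table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"source" %in% names(df)) df$source <- NA_character_
  if (nrow(df) > 0) {
    bad <- which(!(df$category %in% categories))
    if (length(bad)) {
      stop("unknown prior-marker category '", df$category[bad[1]],
           "' at row ", bad[1])
    }
  }
  key <- marker_id(df$contig, df$pos, df$ref, df$alt)
  dup <- duplicated(key)
  n_dedup <- sum(dup)
  if (n_dedup > 0) message("read_prior_markers: ", n_dedup, " duplicate row(s) removed")
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("prior_marker_set", "data.frame")
  attr(df, "category_counts") <- table(df$category)
  attr(df, "n_dedup") <- n_dedup
  df
}

#' Write a panel submission file and BED sidecar
#'
#' One tab-delimited data row per marker: id, contig, 1-based position,
#' the 71-mer with the variant written as bracketed alleles
#' (`[REF/ALT]` at probe position 36), sharing tier and provenance.  A
#' BED (0-based half-open) sidecar records the 71 bp probe footprints.
#' Markers whose probe could not be extracted (contig edge) are rejected
#' with a reason, returned in the `rejected` attribute.
#'
#' @param panel a `panel_design` (see [select_panel()]).
#' @param path output TSV; the BED sidecar is written to `paste0(path, ".bed")`.
#' @param flank_bp flank length either side of the variant (default 35).
#' @return `path` invisibly; attribute `rejected` is a data.frame of
#'   excluded rows with reasons.
#' @export
write_panel <- function(panel, path, flank_bp = 35L) {
  stopifnot(is.data.frame(panel))
  ok <- !is.na(panel$probe_seq) & nchar(panel$probe_seq) == 2L * flank_bp + 1L
  rejected <- data.frame(id = panel$id[!ok],
                         reason = rep("flank_truncated", sum(!ok)),
                         stringsAsFactors = FALSE)
  kept <- panel[ok, , drop = FALSE]
  if (anyDuplicated(kept$id)) stop("duplicate marker ids in panel")
  left <- substr(kept$probe_seq, 1L, flank_bp)
  right <- substr(kept$probe_seq, flank_bp + 2L, 2L * flank_bp + 1L)
  probe <- paste0(left, "[", kept$ref, "/", kept$alt, "]", right)
  out <- data.frame(id = kept$id, contig = kept$contig, pos = kept$pos,
                    probe = probe, tier = kept$tier,
                    provenance = kept$provenance, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- data.frame(contig = kept$contig,
                    start = kept$pos - flank_bp - 1L,  # 0-based
                    end = kept$pos + flank_bp,
                    id = kept$id, stringsAsFactors = FALSE)
  utils::write.table(bed, paste0(path, ".bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (nrow(rejected) > 0) {
    message("write_panel: rejected ", nrow(rejected), " marker(s) (flank_truncated)")
  }
  structure(invisible(path), rejected = rejected)
}

#' Read / write a plain genotype dosage table
#'
#' Tab-delimited markers x samples table with a leading `marker_id`
#' column; missing genotypes written as `NA`.
#'
#' @param g a `genotype_matrix` (for writing).
#' @param path file path.
#' @return [read_genotype_table()] returns a `genotype_matrix`.
#' @export
write_genotype_table <- function(g, path) {
  df <- data.frame(marker_id = rownames(g), unclass(g), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_table
#' @export
read_genotype_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  genotype_matrix(m, marker_ids = df$marker_id, sample_ids = colnames(m))
}

#' Read / write a sample sheet
#'
#' @param sheet a `sample_sheet` (for writing).
#' @param path tab-delimited file with columns sample_id, population and
#'   optionally species, platform.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sample_sheet(df$sample_id, df$population,
               species = if ("species" %in% names(df)) df$species else NA,
               platform = if ("platform" %in% names(df)) df$platform else "lcWGS")
}
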