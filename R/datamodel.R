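#' Construct a variant table
#'
#' A `variant_table` is a data.frame with one row per biallelic SNP,
#' sorted by (contig, pos), carrying the caller annotations consumed by
#' the hard filters.  Marker ids are the stable key `contig:pos:ref:alt`.
#'
#' @param contig character vector of contig names.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-nucleotide reference / alternate alleles.
#' @param QD,FS,MQ,HaplotypeScore,MQRankSum numeric caller annotations
#'   (NA when absent from the source VCF).
#' @param mean_depth numeric mean read depth per site across samples.
#' @return a data.frame of class `variant_table` with an `id` column.
#' @export
variant_table <- function(contig, pos, ref, alt,
                          QD = NA_real_, FS = NA_real_, MQ = NA_real_,
                          HaplotypeScore = NA_real_, MQRankSum = NA_real_,
                          mean_depth = NA_real_) {
  n <- max(length(contig), length(pos), length(ref), length(alt))
  for (len in c(length(contig), length(pos), length(ref), length(alt))) {
    if (!len %in% c(1L, n)) stop("coordinate/allele lengths must be 1 or ", n)
  }
  contig <- rep_len(contig, n); pos <- rep_len(pos, n)
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop("variant positions must be >= 1")
  ref <- toupper(ref); alt <- toupper(alt)
  bases <- c("A", "C", "G", "T")
  if (!all(ref %in% bases) || !all(alt %in% bases)) {
    stop("ref/alt alleles must be single bases in {A,C,G,T}")
  }
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  vt <- data.frame(
    contig = as.character(contig), pos = pos, ref = ref, alt = alt,
    QD = rep_len(as.numeric(QD), n), FS = rep_len(as.numeric(FS), n),
    MQ = rep_len(as.numeric(MQ), n),
    HaplotypeScore = rep_len(as.numeric(HaplotypeScore), n),
    MQRankSum = rep_len(as.numeric(MQRankSum), n),
    mean_depth = rep_len(as.numeric(mean_depth), n),
    stringsAsFactors = FALSE
  )
  vt$id <- marker_id(vt$contig, vt$pos, vt$ref, vt$alt)
  if (anyDuplicated(vt$id)) {
    stop("duplicate marker ids: ", paste(utils::head(vt$id[duplicated(vt$id)], 3), collapse = ", "))
  }
  vt <- vt[order(vt$contig, vt$pos), , drop = FALSE]
  rownames(vt) <- NULL
  class(vt) <- c("variant_table", "data.frame")
  vt
}

#' Stable marker key
#'
#' @param contig,pos,ref,alt variant coordinates and alleles.
#' @return character vector `"contig:pos:ref:alt"`.
#' @export
marker_id <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

#' Construct a genotype matrix
#'
#' Markers x samples matrix of alt-allele dosages 0/1/2, with `NA` as the
#' missing-genotype sentinel (never conflated with dosage 0).
#'
#' @param values numeric/integer matrix, entries in \{0, 1, 2, NA\}.
#' @param marker_ids,sample_ids row / column ids; defaults to dimnames.
#' @return integer matrix of class `genotype_matrix` with dimnames set.
#' @export
genotype_matrix <- function(values, marker_ids = rownames(values),
                            sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  ok <- is.na(values) | values %in% 0:2
  if (!all(ok)) stop("genotype values must be 0, 1, 2 or NA")
  # empty dimensions legitimately carry no dimnames
  if (is.null(marker_ids) && nrow(values) == 0L) marker_ids <- character(0)
  if (is.null(sample_ids) && ncol(values) == 0L) sample_ids <- character(0)
  if (is.null(marker_ids) || is.null(sample_ids)) {
    stop("genotype_matrix requires marker and sample ids")
  }
  if (length(marker_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("id lengths do not match matrix dimensions")
  }
  if (anyDuplicated(marker_ids)) stop("duplicate marker ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  dimnames(values) <- list(marker_ids, sample_ids)
  class(values) <- c("genotype_matrix", class(values))
  values
}

#' Construct a sample sheet
#'
#' @param sample_id unique sample identifiers.
#' @param population population label per sample (non-empty).
#' @param species optional species label (`NA` = unassigned).
#' @param platform genotyping platform, `"lcWGS"` or `"array"`.
#' @return data.frame of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, population,
                         species = NA_character_, platform = "lcWGS") {
  n <- length(sample_id)
  if (anyDuplicated(sample_id)) stop("sample ids must be unique")
  population <- rep_len(as.character(population), n)
  if (any(is.na(population) | population == "")) stop("every population must be non-empty")
  sh <- data.frame(
    sample_id = as.character(sample_id),
    population = population,
    species = rep_len(as.character(species), n),
    platform = rep_len(as.character(platform), n),
    stringsAsFactors = FALSE
  )
  class(sh) <- c("sample_sheet", "data.frame")
  sh
}

#' Species sample groups from a sample sheet
#'
#' @param sheet a `sample_sheet` with species labels filled in.
#' @param drop_unassigned drop samples labelled NA / "unassigned" / "hybrid".
#' @return named list of sample-id character vectors, one per species.
#' @export
species_groups <- function(sheet, drop_unassigned = TRUE) {
  sp <- sheet$species
  if (drop_unassigned) {
    keep <- !is.na(sp) & !(sp %in% c("unassigned", "hybrid", "hybrid/unassigned"))
  } else {
    keep <- !is.na(sp)
  }
  split(sheet$sample_id[keep], sp[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal: subset a genotype matrix keeping its class.
subset_g <- function(g, markers = rownames(g), samples = colnames(g)) {
  out <- unclass(g)[markers, samples, drop = FALSE]
  genotype_matrix(out)
}
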