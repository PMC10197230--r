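test_that("variant_table validates and sorts", {
  vt <- variant_table(c("c2", "c1"), c(5L, 9L), c("A", "C"), c("G", "T"))
  expect_equal(vt$contig, c("c1", "c2"))
  expect_equal(vt$id, c("c1:9:C:T", "c2:5:A:G"))
  expect_error(variant_table("c1", 0L, "A", "G"), ">= 1")
  expect_error(variant_table("c1", 1L, "A", "A"), "differ")
  expect_error(variant_table("c1", 1L, "N", "A"), "A,C,G,T")
})

test_that("genotype_matrix rejects bad dosages and keeps NA distinct from 0", {
  g <- genotype_matrix(matrix(c(0L, NA, 2L, 1L), 2, 2),
                       c("m1", "m2"), c("s1", "s2"))
  expect_true(is.na(g["m2", "s1"]))
  expect_false(is.na(g["m1", "s1"]))
  expect_error(genotype_matrix(matrix(3L, 1, 1), "m", "s"), "0, 1, 2 or NA")
})

test_that("non-SNP and multiallelic records are dropped with a count, dosages coded", {
  path <- write_raw_vcf(c(
    "c1\t100\t.\tA\tG\t.\tPASS\tQD=5\tGT\t0/1\t1|1",
    "c1\t200\t.\tAT\tA\t.\tPASS\t.\tGT\t0/1\t0/0",   # indel
    "c1\t300\t.\tC\tT,G\t.\tPASS\t.\tGT\t0/1\t0/0",  # multiallelic
    "c1\t400\t.\tC\tT\t.\tPASS\t.\tGT\t./.\t0/0"
  ))
  res <- read_vcf(path)
  expect_equal(attr(res, "dropped"), 2L)
  expect_equal(nrow(res$variants), 2L)
  g <- res$genotypes
  expect_equal(unname(g["c1:100:A:G", ]), c(1L, 2L))   # phased == unphased
  expect_true(is.na(g["c1:400:C:T", "S1"]))
  expect_equal(unname(g["c1:400:C:T", "S2"]), 0L)
})

test_that("VCF sample ids must all appear in the sample sheet", {
  path <- write_raw_vcf("c1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1")
  sheet <- sample_sheet("S1", "p1")
  expect_error(read_vcf(path, sheet), "S2")
})

test_that("write_vcf / read_vcf round-trips the genotype matrix bit-exactly", {
  d <- small_sim
  path <- tempfile(fileext = ".vcf")
  write_vcf(d$variants, d$g_lcwgs, path)
  back <- read_vcf(path, d$sheet)
  expect_equal(attr(back, "dropped"), 0L)
  a <- unclass(back$genotypes)
  b <- unclass(d$g_lcwgs); attr(b, "error_mask") <- NULL
  expect_identical(a, b)
  expect_equal(back$variants$id, d$variants$id)
  expect_equal(back$variants$QD, d$variants$QD, tolerance = 1e-6)
  expect_equal(back$variants$mean_depth, d$variants$mean_depth, tolerance = 1e-6)
})

test_that("read_fasta uppercases, keeps lengths, rejects duplicates and empties", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "acgt"), p)
  r <- read_fasta(p)
  expect_equal(r, c(c1 = "ACGT"))
  expect_equal(nchar(r[["c1"]]), 4L)

  writeLines(c(">c1", "acgt", ">c1", "tttt"), p)
  expect_error(read_fasta(p), "duplicate")

  writeLines(character(0), p)
  expect_error(read_fasta(p), "empty")
})

test_that("a many-contig synthetic reference is fully retrievable by name", {
  d <- simulate_dataset(sim_config(n_markers = 50L, n_contigs = 40L,
                                   contig_length = 500L, min_spacing = 80L,
                                   samples_per_pop = 1L),
                        seed = 3, out_dir = tempfile())
  ref <- read_fasta(d$paths$fasta)
  expect_length(ref, 40L)
  expect_setequal(names(ref), d$contig_info$contig)
  expect_true(all(nchar(ref[d$contig_info$contig]) == d$contig_info$length))
})

test_that("prior marker tables validate categories, dedupe, and count per category", {
  counts <- c(species_id = 12, sex = 140, cancer1 = 301, cancer2 = 35,
              structure = 113, structure_fluidigm = 113,
              structure_chilensis = 96)
  pri <- synthesize_prior_markers(counts, small_sim$ref, seed = 5)
  expect_equal(nrow(pri), 810L)
  path <- tempfile(fileext = ".tsv")
  write.table(pri, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_prior_markers(path)
  expect_equal(nrow(back), 810L)
  expect_equal(as.vector(attr(back, "category_counts")[names(counts)]),
               unname(counts))

  # duplicated rows are kept once
  dup <- rbind(pri, pri[1, ])
  write.table(dup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(back2 <- read_prior_markers(path), "1 duplicate")
  expect_equal(nrow(back2), 810L)

  # empty table -> empty set
  write.table(pri[0, ], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_prior_markers(path)), 0L)

  # unknown category names the row
  bad <- pri; bad$category[3] <- "mystery"
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_prior_markers(path), "mystery")
})

test_that("write_panel emits 71-mers with bracketed alleles and a BED sidecar", {
  ref <- c(c1 = paste(rep("ACGT", 25), collapse = ""))  # 100 nt
  panel <- data.frame(
    id = c("c1:36:T:A", "c1:10:C:G"), contig = "c1", pos = c(36L, 10L),
    ref = c("T", "C"), alt = c("A", "G"),
    probe_seq = c(extract_probe_sequence(ref, "c1", 36), NA),
    tier = "shared_all", provenance = "discovery", stringsAsFactors = FALSE
  )
  path <- tempfile(fileext = ".tsv")
  expect_message(res <- write_panel(panel, path), "rejected 1")
  expect_equal(attr(res, "rejected")$reason, "flank_truncated")
  out <- read.delim(path)
  expect_equal(nrow(out), 1L)
  expect_match(out$probe, "^[ACGT]{35}\\[T/A\\][ACGT]{35}$")
  bed <- read.delim(paste0(path, ".bed"), header = FALSE)
  expect_equal(bed$V3 - bed$V2, 71L)
  expect_equal(bed$V2, 0L)  # probe spans the contig start (0-based)
})

test_that("panel files contain one row per marker (length conservation)", {
  d <- small_sim
  cand <- probe_candidates(d$variants, d$ref)
  ok <- cand[cand$recommended & cand$flank_clean, ]
  panel <- data.frame(ok[, c("id", "contig", "pos", "ref", "alt", "probe_seq")],
                      tier = "shared_all", provenance = "discovery")
  path <- tempfile(fileext = ".tsv")
  write_panel(panel, path)
  out <- read.delim(path)
  expect_equal(nrow(out), nrow(panel))
  expect_false(anyDuplicated(out$id) > 0)
  bed <- read.delim(paste0(path, ".bed"), header = FALSE)
  expect_true(all(bed$V3 - bed$V2 == 71L))
})
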