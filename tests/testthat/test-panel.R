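# minimal candidate table for markers that only need panel metadata
fake_candidates <- function(ids) {
  parts <- strsplit(ids, ":", fixed = TRUE)
  data.frame(
    id = ids,
    contig = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    ref = vapply(parts, `[`, "", 3),
    alt = vapply(parts, `[`, "", 4),
    probe_seq = strrep("ACGT", 18) |> substr(1, 71),
    stringsAsFactors = FALSE
  )
}

test_that("within-species MAF pass sets match per-group recomputation", {
  g <- genotype_matrix(
    rbind(fixedA = c(0L, 0L, 0L, 1L, 1L, 2L),
          common = c(0L, 1L, 1L, 1L, 0L, 1L)),
    c("fixedA", "common"), paste0("s", 1:6))
  groups <- list(A = paste0("s", 1:3), B = paste0("s", 4:6))
  sets <- species_pass_masks(g, groups, maf_min = 0.02)
  expect_equal(sets$A, "common")              # fixedA monomorphic in A
  expect_setequal(sets$B, c("fixedA", "common"))

  # identical groups give identical sets
  sets2 <- species_pass_masks(g, list(X = groups$A, Y = groups$A), 0.02)
  expect_identical(sets2$X, sets2$Y)
  expect_error(species_pass_masks(g, list(A = "s1"), 0.02), "fewer than 2")

  # brute-force oracle on a random fixture
  gr <- random_genotypes(1000, 24, miss = 0.2, seed = 51)
  grp <- split(colnames(gr), rep(c("a", "b", "c"), each = 8))
  sets3 <- species_pass_masks(gr, grp, maf_min = 0.05)
  for (s in names(grp)) {
    brute <- vapply(rownames(gr), function(mk) {
      x <- unclass(gr)[mk, grp[[s]]]
      x <- x[!is.na(x)]
      if (length(x) == 0) return(FALSE)
      p <- sum(x) / (2 * length(x))
      min(p, 1 - p) >= 0.05
    }, logical(1))
    expect_setequal(sets3[[s]], rownames(gr)[brute])
  }
})

test_that("sharing tiers count set membership and the UpSet table is conservative", {
  sets <- list(
    edulis = c("m1", "m2", "m3", "m4"),
    gallo = c("m1", "m2", "m3"),
    tros = c("m1", "m2"),
    chil = c("m1", "m5")
  )
  tiers <- classify_sharing_tiers(sets)
  tt <- setNames(tiers$tier, tiers$id)
  expect_equal(unname(tt["m1"]), "shared_all")
  expect_equal(unname(tt["m2"]), "shared_3")
  expect_equal(unname(tt["m3"]), "shared_2")
  expect_equal(unname(tt["m4"]), "exclusive:edulis")
  expect_equal(unname(tt["m5"]), "exclusive:chil")

  up <- attr(tiers, "upset")
  for (s in names(sets)) {
    in_s <- grepl(paste0("(^|\\+)", s, "(\\+|$)"), up$species_set)
    expect_equal(sum(up$n_markers[in_s]), length(sets[[s]]))
  }
})

test_that("panel selection keeps all shared markers and thins exclusives to quota", {
  set.seed(1)
  ids_shared <- paste0("c1:", (1:100) * 1000, ":A:G")
  ids_exclA <- paste0("c2:", (1:5000) * 100, ":A:G")
  ids_exclB <- paste0("c3:", (1:1000) * 100, ":A:G")
  tiers <- data.frame(
    id = c(ids_shared, ids_exclA, ids_exclB),
    n_species = c(rep(2L, 100), rep(1L, 6000)),
    tier = c(rep("shared_2", 100), rep("exclusive:A", 5000),
             rep("exclusive:B", 1000)),
    stringsAsFactors = FALSE
  )
  cand <- fake_candidates(tiers$id)
  expect_message(panel <- select_panel(tiers, cand, exclusive_quota = 2500L,
                                       seed = 10),
                 "below quota")
  expect_equal(sum(panel$tier == "shared_2"), 100L)
  expect_equal(sum(panel$tier == "exclusive:A"), 2500L)
  expect_equal(sum(panel$tier == "exclusive:B"), 1000L)  # short pool kept whole
  expect_equal(nrow(panel), 100L + 2500L + 1000L)        # conservation
  expect_equal(attr(panel, "shortfalls")$`exclusive:B`, 1500L)

  # bit-reproducible under the same seed
  panel2 <- suppressMessages(select_panel(tiers, cand, 2500L, seed = 10))
  expect_identical(panel$id, panel2$id)
  panel3 <- suppressMessages(select_panel(tiers, cand, 2500L, seed = 11))
  expect_false(identical(panel$id, panel3$id))
})

test_that("prior markers are screened, deduplicated and reported as one line", {
  d <- small_sim
  cand <- probe_candidates(d$variants, d$ref)
  cand_ok <- cand[cand$recommended & cand$flank_clean, ]
  tiers <- data.frame(id = cand_ok$id, n_species = 2L, tier = "shared_2",
                      stringsAsFactors = FALSE)
  panel <- select_panel(tiers, cand_ok, seed = 1)

  pri <- synthesize_prior_markers(c(species_id = 5, sex = 5), d$ref, seed = 9)
  # plant one prior duplicating a panel marker and one at a contig edge
  pri[1, c("contig", "pos", "ref", "alt")] <-
    panel[1, c("contig", "pos", "ref", "alt")]
  pri$pos[2] <- 10L
  pri$ref[2] <- substr(d$ref[[pri$contig[2]]], 10, 10)
  pri[3, "contig"] <- "nowhere"

  merged <- suppressMessages(merge_prior_markers(panel, pri, d$ref))
  rej <- attr(merged, "rejected")
  expect_true("flank_truncated" %in% rej$reason)
  expect_true("unknown_contig" %in% rej$reason)
  # duplicate resolves to a single entry carrying the prior label
  expect_equal(sum(merged$id == panel$id[1]), 1L)
  expect_equal(merged$tier[merged$id == panel$id[1]], "prior:species_id")
  expect_false(anyDuplicated(merged$id) > 0)

  comp <- panel_composition(merged)
  n_prior <- sum(startsWith(merged$tier, "prior:"))
  expect_equal(comp$n_markers[comp$category == "prior"], n_prior)
  expect_equal(comp$n_markers[comp$category == "total"], nrow(merged))
  expect_equal(sum(comp$n_markers[comp$category != "total"]), nrow(merged))
})

test_that("composition reports validate their additivity on reading", {
  path <- tempfile(fileext = ".tsv")
  good <- data.frame(category = c("shared_2", "prior", "total"),
                     n_markers = c(10L, 2L, 12L))
  write.table(good, path, sep = "\t", quote = FALSE, row.names = FALSE)
  comp <- read_panel_composition(path)
  expect_equal(attr(comp, "total"), 12L)

  bad <- good; bad$n_markers[3] <- 13L
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_panel_composition(path), "do not sum")
})
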