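th <- filter_thresholds()

test_that("hard filter boundaries are strict and tags name the first failing rule", {
  vt <- variant_table(
    contig = rep("c1", 3), pos = c(100L, 200L, 300L),
    ref = "A", alt = "G",
    QD = c(1.5, 2.0, 25), FS = c(5, 60.0, 5), MQ = c(55, 40.0, 55),
    HaplotypeScore = c(1, 13.0, 1), MQRankSum = c(0, -13.0, 0),
    mean_depth = 6
  )
  mask <- hard_filter(vt, th)
  expect_equal(mask$pass, c(FALSE, TRUE, TRUE))
  expect_equal(mask$tag, c("QD", "", ""))

  # missing required annotation fails conservatively
  vt$MQ[3] <- NA
  mask2 <- hard_filter(vt, th)
  expect_false(mask2$pass[3])
  expect_equal(mask2$tag[3], "missing_annot")
})

test_that("hard filter equals brute-force row-wise evaluation on random sites", {
  set.seed(42)
  n <- 1000
  vt <- variant_table(
    contig = "c1", pos = seq_len(n) * 100L, ref = "A", alt = "C",
    QD = ifelse(runif(n) < 0.05, NA, runif(n, 0, 10)),
    FS = runif(n, 0, 120), MQ = runif(n, 20, 60),
    HaplotypeScore = runif(n, 0, 26), MQRankSum = runif(n, -26, 5),
    mean_depth = runif(n, 2, 12)
  )
  mask <- hard_filter(vt, th)
  brute <- vapply(seq_len(n), function(i) {
    a <- vt[i, ]
    if (anyNA(a[c("QD", "FS", "MQ", "HaplotypeScore", "MQRankSum")])) return(FALSE)
    !(a$QD < 2 || a$FS > 60 || a$MQ < 40 || a$HaplotypeScore > 13 ||
        a$MQRankSum < -13)
  }, logical(1))
  expect_identical(mask$pass, brute)
})

test_that("depth/contig filter applies inclusive depth bounds and partitions failures", {
  vt <- variant_table(
    contig = c("big", "big", "big", "small", "cov"),
    pos = c(100L, 200L, 300L, 100L, 100L),
    ref = "A", alt = "G", QD = 10, FS = 1, MQ = 50, HaplotypeScore = 1,
    MQRankSum = 0, mean_depth = c(4, 10, 3.9, 6, 6)
  )
  info <- data.frame(contig = c("big", "small", "cov"),
                     length = c(11000L, 9000L, 11000L),
                     mean_coverage = c(15, 15, 20))
  mask <- depth_contig_filter(vt, info, th)
  got <- setNames(mask$tag, vt$id)
  expect_equal(unname(got[c("big:100:A:G", "big:200:A:G")]), c("", ""))
  expect_equal(unname(got["big:300:A:G"]), "depth_low")
  expect_equal(unname(got["small:100:A:G"]), "contig_len")
  expect_equal(unname(got["cov:100:A:G"]), "contig_cov")
  # tag counts partition the failures
  expect_equal(sum(table(mask$tag[mask$tag != ""])), sum(!mask$pass))
  expect_error(depth_contig_filter(vt, info[-1, ], th), "unknown contig")
})

test_that("MAF is computed over called genotypes only", {
  g <- genotype_matrix(
    rbind(mono = c(0L, 0L, 0L, 0L, 0L, 0L),
          rare = c(0L, 0L, 0L, 1L, NA, NA),
          none = rep(NA_integer_, 6)),
    c("mono", "rare", "none"), paste0("s", 1:6))
  mask <- maf_filter(g, min_maf = 0.01)
  expect_equal(setNames(mask$pass, mask$id),
               c(mono = FALSE, rare = TRUE, none = FALSE))
  expect_equal(mask$tag[mask$id == "none"], "no_calls")
  # hand count: (0,0,0,1) over 4 called -> MAF 1/8
  expect_false(maf_filter(g, min_maf = 0.2)$pass[2])
  expect_error(maf_filter(g, samples = character(0)), "empty")
})

test_that("population missingness uses strict > max_frac in any population", {
  sheet <- sample_sheet(paste0("s", 1:12), rep(c("p1", "p2"), each = 6))
  base <- matrix(0L, 2, 12, dimnames = list(c("m1", "m2"), paste0("s", 1:12)))
  base["m1", 1:3] <- NA        # 3/6 = 50% in p1: boundary, passes
  base["m2", 1:4] <- NA        # 4/6 > 50% in p1: fails even though p2 clean
  g <- genotype_matrix(base)
  mask <- pop_missingness_filter(g, sheet, 0.5)
  expect_equal(setNames(mask$pass, mask$id), c(m1 = TRUE, m2 = FALSE))
  expect_equal(mask$tag[2], "pop_missing")
})

test_that("LD pruning drops one of a duplicated pair and respects window bounds", {
  set.seed(8)
  base <- sample(0:2, 200, replace = TRUE)
  g <- genotype_matrix(rbind(a = base, b = base),
                       c("c1:1000:A:G", "c1:2000:A:G"), paste0("s", 1:200))
  vt <- variant_table(c("c1", "c1"), c(1000L, 2000L), "A", "G", mean_depth = 6)
  kept <- ld_prune(g, vt)
  expect_length(kept, 1L)
  expect_equal(kept, "c1:1000:A:G")  # greedy keep-first

  # a perfectly linked pair 60 kb apart is never co-windowed at 50 kb
  vt2 <- variant_table(c("c1", "c1"), c(1000L, 61000L), "A", "G", mean_depth = 6)
  g2 <- genotype_matrix(rbind(base, base), vt2$id, paste0("s", 1:200))
  expect_length(ld_prune(g2, vt2), 2L)

  expect_error(ld_prune(g, vt, window_bp = 5000L, step_bp = 10000L), ">= step")
})

test_that("independent markers all survive LD pruning", {
  set.seed(9)
  m <- 30
  g <- genotype_matrix(matrix(sample(0:2, m * 200, replace = TRUE), m, 200),
                       paste0("c1:", seq_len(m) * 1000, ":A:G"),
                       paste0("s", 1:200))
  vt <- variant_table(rep("c1", m), seq_len(m) * 1000L, "A", "G", mean_depth = 6)
  expect_length(ld_prune(g, vt), m)
})

test_that("per-marker filters compose order-invariantly via AND", {
  d <- small_sim
  vt <- d$variants
  vt$QD[1:40] <- 1.0                       # planted hard-filter failures
  g <- d$g_lcwgs
  m1 <- hard_filter(vt, th)
  m2 <- maf_filter(g, min_maf = 0.05)
  m3 <- pop_missingness_filter(g, d$sheet, 0.5)
  ab <- combine_masks(m1, m2, m3)
  ba <- combine_masks(m3, m2, m1)
  expect_identical(ab$pass, ba$pass)
  # sequential application equals the combined mask
  seq_pass <- m1$pass & m2$pass & m3$pass
  expect_identical(ab$pass, seq_pass)
})

test_that("planted single-rule failures are recalled with the right tag", {
  vt <- variant_table(
    contig = "c1", pos = (1:6) * 1000L, ref = "A", alt = "G",
    QD = c(1, 10, 10, 10, 10, 10), FS = c(1, 70, 1, 1, 1, 1),
    MQ = c(50, 50, 30, 50, 50, 50), HaplotypeScore = c(1, 1, 1, 20, 1, 1),
    MQRankSum = c(0, 0, 0, 0, -20, 0), mean_depth = 6
  )
  vt$QD[6] <- NA
  mask <- hard_filter(vt, th)
  expect_equal(mask$tag,
               c("QD", "FS", "MQ", "HaplotypeScore", "MQRankSum", "missing_annot"))
})
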