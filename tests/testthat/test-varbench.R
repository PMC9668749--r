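# Haplotype-to-reference alignment, phased variant calling (with GAP2
# promotion) and the benchmarking metric formulas.

test_that("anchored alignment recovers simple edits", {
  ref <- random_seq(30000, seed = 61)
  # identical sequences: one all-match run
  a0 <- align_haplotype(ref, ref)
  expect_identical(a0$ops$op, "=")
  expect_equal(a0$ops$len, 30000)
  # a single 100-bp insertion appears as one I op of length 100
  ins <- random_seq(100, seed = 62)
  qry <- paste0(substring(ref, 1, 15000), ins, substring(ref, 15001, 30000))
  a1 <- align_haplotype(qry, ref)
  expect_identical(a1$ops$op[a1$ops$op != "="], "I")
  expect_equal(a1$ops$len[a1$ops$op == "I"], 100)
  # a single deletion appears as one D op
  qry2 <- paste0(substring(ref, 1, 10000), substring(ref, 10081, 30000))
  a2 <- align_haplotype(qry2, ref)
  expect_identical(a2$ops$op[a2$ops$op != "="], "D")
  expect_equal(a2$ops$len[a2$ops$op == "D"], 80)
})

test_that("variant calling round-trips synthetic truth exactly", {
  trio <- gen_trio(trio_config(seed = 63, chrom_lengths = 1e5,
                               snv_rate = 0.002, indel_rate = 2e-4,
                               sv_rate = 2e-5, sv_types = c("ins", "del")))
  ref <- trio$ancestor[[1]]
  pat <- trio$sequences$child_pat[[1]]
  mat <- trio$sequences$child_mat[[1]]
  cv <- call_variants(align_haplotype(pat, ref), align_haplotype(mat, ref),
                      pat, mat, ref, chrom = "chr1")
  tv <- truth_variants(trio)
  cnt <- compare_to_truth(cv$variants, tv, cv$conf_regions)
  met <- benchmark_metrics(cnt)
  expect_equal(met$SNP.F1, 1.0)
  expect_equal(met$INDEL.F1, 1.0)
  expect_equal(met$SNP.Recall, 1.0)
  expect_true(met$qv_infinite)
  # phasing convention: hap1 (paternal) occupies the first genotype field
  pat_only <- tv[tv$gt == "1|0" & tv$class == "SNP", ]
  called <- cv$variants
  key <- paste(called$pos, called$ref, called$alt)
  m <- match(paste(pat_only$pos, pat_only$ref, pat_only$alt), key)
  expect_true(all(called$gt[m] == "1|0"))
})

test_that("single-haplotype coverage yields GAP2 with promoted genotype", {
  ref <- random_seq(40000, seed = 64)
  # hap2 covers only the first half; hap1 carries a variant in the second
  hap2 <- substring(ref, 1, 20000)
  hap1 <- ref
  substring(hap1, 30000, 30000) <- if (substring(ref, 30000, 30000) == "A") "G" else "A"
  cv <- call_variants(align_haplotype(hap1, ref), align_haplotype(hap2, ref),
                      hap1, hap2, ref, chrom = "r")
  v <- cv$variants[cv$variants$pos == 29999, ]
  expect_identical(v$filter, "GAP2")
  expect_identical(v$gt, "1|1")
  # confident regions are the doubly-covered intersection
  expect_lte(cv$conf_regions$end, 20000)
})

test_that("comparison counts match a brute-force per-site oracle", {
  trio <- gen_trio(trio_config(seed = 65, chrom_lengths = 5e4,
                               snv_rate = 0.003, indel_rate = 3e-4, sv_rate = 0))
  tv <- truth_variants(trio)
  conf <- data.frame(chrom = "chr1", start = 0, end = 5e4)
  # query == truth: everything TP
  c0 <- compare_to_truth(tv, tv, conf)
  expect_identical(c0[["SNP.TRUTH.TP"]], c0[["SNP.TRUTH.TOTAL"]])
  expect_identical(c0[["SNP.QUERY.FP"]], 0L)
  expect_identical(c0[["INDEL.TRUTH.FN"]], 0L)
  # perturb: flip some genotypes, drop some records, add novel ones
  withr::with_seed(66, {
    q <- tv
    flip <- sample(which(q$gt == "0|1" & q$class == "SNP"), 5)
    q$gt[flip] <- "1|1"
    dropped <- sample(setdiff(seq_len(nrow(q)), flip), 7)
    q <- q[-dropped, ]
    novel <- data.frame(chrom = "chr1", pos = c(101, 202, 303) + 0.0,
                        ref = c("A", "C", "G"), alt = c("T", "A", "C"),
                        gt = "1|1", class = "SNP")
    q <- rbind(q, novel)
    q <- q[order(q$pos), ]
  })
  cnt <- compare_to_truth(q, tv, conf)
  # independent per-site oracle
  kq <- paste(q$pos, q$ref, q$alt)
  kt <- paste(tv$pos, tv$ref, tv$alt)
  gt_norm <- function(g) vapply(strsplit(g, "|", fixed = TRUE),
                                function(x) paste(sort(x), collapse = "/"), "")
  for (cls in c("SNP", "INDEL")) {
    t_i <- which(tv$class == cls)
    tp <- fp_gt <- fn <- 0L
    for (i in t_i) {
      j <- match(kt[i], kq)
      if (is.na(j)) fn <- fn + 1L
      else if (gt_norm(tv$gt[i]) == gt_norm(q$gt[j])) tp <- tp + 1L
      else fp_gt <- fp_gt + 1L
    }
    expect_identical(cnt[[paste0(cls, ".TRUTH.TP")]], tp)
    expect_identical(cnt[[paste0(cls, ".FP.gt")]], fp_gt)
    expect_identical(cnt[[paste0(cls, ".TRUTH.FN")]], fn)
    qfp <- sum(!(kq[q$class == cls] %in% kt))
    expect_identical(cnt[[paste0(cls, ".QUERY.FP")]], qfp)
  }
  # a flipped genotype counts in FP.gt, not in plain FP
  expect_gte(cnt[["SNP.FP.gt"]], 5L)
  met <- benchmark_metrics(cnt)
  expect_gte(met$SNP.Recall_ignoreGT, met$SNP.Recall)
})

test_that("metric formulas match their closed forms", {
  counts <- structure(list(
    SNP.TRUTH.TOTAL = 100L, SNP.TRUTH.TP = 90L, SNP.FP.gt = 5L,
    SNP.TRUTH.FN = 5L, SNP.QUERY.TOTAL = 96L, SNP.QUERY.FP = 1L,
    INDEL.TRUTH.TOTAL = 10L, INDEL.TRUTH.TP = 10L, INDEL.FP.gt = 0L,
    INDEL.TRUTH.FN = 0L, INDEL.QUERY.TOTAL = 11L, INDEL.QUERY.FP = 1L,
    Subset.IS_CONF.Size = 1e6), class = "benchmark_counts")
  met <- benchmark_metrics(counts)
  expect_equal(met$SNP.Recall, 0.90)
  expect_equal(met$SNP.Recall_ignoreGT, 0.95)
  # 2 FP over 2x1 Mb confident bp: QV_dip = -10*log10(2/2e6) = 60
  expect_equal(met$QV_dip_snp_indel, 60)
  # log-linearity: 10x the false positives costs exactly 10 QV
  counts10 <- counts
  counts10$SNP.QUERY.FP <- 10L
  counts10$INDEL.QUERY.FP <- 10L
  expect_equal(benchmark_metrics(counts10)$QV_dip_snp_indel, 50)
  # zero FP: infinite sentinel
  counts0 <- counts
  counts0$SNP.QUERY.FP <- 0L
  counts0$INDEL.QUERY.FP <- 0L
  m0 <- benchmark_metrics(counts0)
  expect_true(m0$qv_infinite)
  expect_identical(m0$QV_dip_snp_indel, Inf)
})
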