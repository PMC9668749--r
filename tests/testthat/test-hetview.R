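# Haplotype-vs-haplotype diversity catalogs, window densities, coding
# classification, heterozygosity percentages and heteroplasmy.

test_that("catalogs classify at the 50-bp boundary and match diff oracles", {
  # identical haplotypes: empty catalog
  s <- random_seq(30000, seed = 71)
  expect_identical(nrow(hap_vs_hap(c(a = s), c(b = s))), 0L)
  # 49-bp vs 50-bp deletions straddle the small/SV boundary
  h2 <- random_seq(24000, seed = 72)
  h1 <- paste0(substring(h2, 1, 8000), substring(h2, 8050, 24000))
  h1 <- paste0(substring(h1, 1, 16000), substring(h1, 16051, nchar(h1)))
  cb <- hap_vs_hap(c(a = h1), c(b = h2))
  expect_identical(cb$size_class[order(cb$len)], c("small_indel", "sv"))
  expect_equal(cb$len[order(cb$len)], c(49, 50))
  # SNV-only trio: catalog equals the brute-force character diff
  trio <- gen_trio(trio_config(seed = 73, chrom_lengths = 5e4,
                               snv_rate = 0.002, indel_rate = 0, sv_rate = 0))
  m <- trio$sequences$child_mat[[1]]
  p <- trio$sequences$child_pat[[1]]
  cat_df <- hap_vs_hap(c(mat = m), c(pat = p))
  diff_pos <- which(charToRaw(m) != charToRaw(p)) - 1
  expect_setequal(cat_df$pos[cat_df$class == "SNV"], diff_pos)
  # label symmetry: swapping haplotypes inverts polarity, preserves totals
  cat_sw <- hap_vs_hap(c(pat = p), c(mat = m))
  expect_identical(nrow(cat_sw), nrow(cat_df))
})

test_that("inversions are recognized as reverse-complement block replacements", {
  h2 <- random_seq(40000, seed = 74)
  seg <- substring(h2, 20001, 20400)
  inv <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
  h1 <- paste0(substring(h2, 1, 20000), inv, substring(h2, 20401, 40000))
  cat_df <- hap_vs_hap(c(a = h1), c(b = h2))
  expect_true("INV" %in% cat_df$class)
  iv <- cat_df[cat_df$class == "INV", ]
  expect_lte(abs(iv$len[1] - 400), 45)  # anchors may trim palindromic ends
})

test_that("window densities equal brute-force per-window counts", {
  cat1 <- data.frame(chrom = "c", pos = 0, class = "SNV", len = 1,
                     ref = "A", alt = "T")
  wd <- window_density(cat1, c(c = 1e6), snv_window = 5e5)
  expect_equal(wd$snv$count, c(1L, 0L))
  withr::with_seed(75, {
    pos <- sort(sample(0:999999, 300))
    cls <- sample(c("SNV", "INS", "DEL"), 300, TRUE)
  })
  cat_r <- data.frame(chrom = "c", pos = pos, class = cls,
                      len = ifelse(cls == "SNV", 1, 10), ref = "", alt = "")
  wd_r <- window_density(cat_r, c(c = 1e6), snv_window = 2.5e5,
                         indel_window = 2e5)
  oracle_snv <- vapply(seq(0, 75e4, by = 25e4), function(s)
    sum(pos >= s & pos < s + 25e4 & cls == "SNV"), 0L)
  expect_equal(wd_r$snv$count, oracle_snv)
  oracle_ind <- vapply(seq(0, 8e5, by = 2e5), function(s)
    sum(pos >= s & pos < s + 2e5 & cls %in% c("INS", "DEL")), 0L)
  expect_equal(wd_r$indel$count, oracle_ind)
  # SNV percentage is count over window bp
  expect_equal(wd_r$snv$pct, 100 * oracle_snv / 2.5e5)
})

test_that("coding classification translates codons on both strands", {
  genome <- c(chr1 = "AAAGGAGGATTTCCTCCTTT")
  cds <- data.frame(chrom = "chr1", start = c(3, 12), end = c(9, 18),
                    strand = c("+", "-"), gene = c("gplus", "gminus"),
                    stringsAsFactors = FALSE)
  snvs <- data.frame(chrom = "chr1",
                     pos = c(5, 4, 13),
                     ref = c("A", "G", "C"),
                     alt = c("G", "A", "T"))
  # gplus codons GGA GGA: GGA->GGG synonymous (Gly), GGA->GAA non-syn (Glu)
  # gminus coding strand is AGGAGG...: pos 13 C->T on - strand = G->A
  cc <- classify_coding(snvs, cds, genome)
  eff <- cc$effects
  expect_identical(eff$effect[eff$variant == "chr1:5"], "synonymous")
  expect_identical(eff$effect[eff$variant == "chr1:4"], "non-synonymous")
  expect_identical(nrow(eff), 3L)
  s <- cc$summary
  expect_equal(s$pct_synonymous + s$pct_non_synonymous, 100, tolerance = 0.11)
  # frame violation: gene skipped and logged
  bad <- data.frame(chrom = "chr1", start = 3, end = 10, strand = "+",
                    gene = "gbad")
  expect_identical(classify_coding(snvs, bad, genome)$skipped_genes, "gbad")
  # printed-scale arithmetic: 6,397 synonymous of 12,241 is 52.3%
  eff_big <- data.frame(
    effect = rep(c("synonymous", "non-synonymous"), c(6397, 5844)),
    gene = "g")
  sm <- coding_effect_summary(eff_big)
  expect_identical(sm$pct_synonymous, 52.3)
  expect_identical(sm$pct_non_synonymous, 47.7)
})

test_that("per-gene rollup counts exclusively non-synonymous genes", {
  eff <- data.frame(effect = c("synonymous", "non-synonymous",
                               "non-synonymous", "non-synonymous"),
                    gene = c("g1", "g1", "g2", "g2"))
  sm <- coding_effect_summary(eff)
  expect_identical(sm$genes_exclusively_non_synonymous, 1L)
  expect_identical(sm$genes_non_synonymous, 2L)
})

test_that("heterozygosity summary tallies affected bp over the denominator", {
  empty <- data.frame(chrom = character(0), pos = numeric(0),
                      class = character(0), len = numeric(0),
                      ref = character(0), alt = character(0))
  expect_equal(het_summary(empty, 1e5)$pct, 0)
  one_ins <- data.frame(chrom = "c", pos = 500, class = "INS", len = 1000,
                        ref = "", alt = strrep("A", 1000))
  expect_equal(het_summary(one_ins, 1e5)$pct, 1.0)
  # brute-force bp tally on a mixed catalog
  cat_df <- data.frame(chrom = "c", pos = c(10, 200, 3000, 7000),
                       class = c("SNV", "DEL", "INS", "INV"),
                       len = c(1, 30, 200, 500), ref = "", alt = "")
  hs <- het_summary(cat_df, 1e5)
  expect_equal(hs$het_bp, 1 + 30 + 200 + 500)
  # exclusion: records inside excluded regions leave the numerator and
  # excluded bp leave the denominator
  excl <- data.frame(chrom = "c", start = 0, end = 5000)
  hs_e <- het_summary(cat_df, 1e5, exclude = excl)
  expect_equal(hs_e$het_bp, 500)
  expect_equal(hs_e$denominator_bp, 95000)
  expect_error(het_summary(cat_df, 1e5,
                           exclude = data.frame(chrom = "c", start = 0,
                                                end = 2e5)),
               "exceed")
})

test_that("heteroplasmy reports minor alleles strictly above the error floor", {
  # printed worked example: major T 8,033 (4,186+/3,847-), minor C 202
  # (94+/108-) is a 2% minor allele
  mt <- data.frame(chrom = "MT", pos = 3243, A = 0, C = 202, G = 0, T = 8033,
                   A_fwd = 0, A_rev = 0, C_fwd = 94, C_rev = 108,
                   G_fwd = 0, G_rev = 0, T_fwd = 4186, T_rev = 3847)
  hp <- heteroplasmy(mt)
  expect_identical(nrow(hp), 1L)
  expect_identical(hp$allele, "C")
  expect_identical(hp$pct, 2)
  expect_identical(hp$fwd, 94)
  expect_identical(hp$rev, 108)
  expect_identical(hp$major_allele, "T")
  # a 50/50 site reports both alleles in the record
  half <- data.frame(chrom = "MT", pos = 1, A = 500, C = 0, G = 500, T = 0)
  hh <- heteroplasmy(half)
  expect_identical(nrow(hh), 1L)
  expect_setequal(c(hh$allele, hh$major_allele), c("A", "G"))
  expect_identical(hh$pct, 50)
  # a minor allele at exactly 1.0% is not reported (strict threshold)
  edge <- data.frame(chrom = "MT", pos = 2, A = 990, C = 10, G = 0, T = 0)
  expect_identical(nrow(heteroplasmy(edge)), 0L)
  # zero-coverage sites are skipped
  zero <- data.frame(chrom = "MT", pos = 3, A = 0, C = 0, G = 0, T = 0)
  expect_identical(nrow(heteroplasmy(zero)), 0L)
})
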