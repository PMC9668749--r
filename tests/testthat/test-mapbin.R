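# Optical-map digestion, molecule alignment, trio binning and the allele
# cross-check.

test_that("in-silico digestion equals a regex-scan oracle on both strands", {
  m <- digest_to_map("AAGATCAA", "GATC")
  expect_equal(m$labels, 2)
  expect_length(digest_to_map(strrep("AC", 100), "GATC")$labels, 0L)
  s <- random_seq(1e5, seed = 41)
  got <- digest_to_map(s, "CTTAAG")$labels
  fwd <- unlist(gregexpr("CTTAAG", s, fixed = TRUE))
  rev_pat <- as.character(Biostrings::reverseComplement(Biostrings::DNAString("CTTAAG")))
  rev <- unlist(gregexpr(rev_pat, s, fixed = TRUE))
  expected <- sort(unique(c(fwd[fwd > 0], rev[rev > 0]))) - 1
  expect_equal(got, expected)
  # degenerate motifs digest through their IUPAC expansion
  s2 <- "AAGACTCAAGAGTCAA"
  expect_equal(digest_to_map(s2, "GANTC")$labels, c(2, 9))
})

test_that("molecule alignment is exact at zero noise and robust to label dropout", {
  hap <- setNames(random_seq(8e5, seed = 43), "h")
  map <- digest_to_map(hap, "CTTAAG", "h")
  m0 <- sim_molecules(hap, "CTTAAG", coverage = 3, sizing_cv = 0,
                      fp_rate = 0, fn_rate = 0, seed = 44)
  ok_offset <- 0L
  n_checked <- 0L
  for (i in seq_len(nrow(m0$molecules))) {
    if (m0$molecules$n_labels[i] < 9) next
    al <- align_molecule(m0$labels[[i]], map,
                         mol_len = m0$molecules$length[i])
    n_checked <- n_checked + 1L
    expect_equal(al$confidence, 1.0)
    truth_start <- m0$molecules$origin_start[i]
    # offset maps the first matched label back to the source coordinate
    if (abs(al$offset - truth_start) < 10) ok_offset <- ok_offset + 1L
  }
  expect_gt(n_checked, 3)
  expect_equal(ok_offset, n_checked)
  # 10% dropped labels: confidence stays >= 0.8 on the correct target
  mfn <- sim_molecules(hap, "CTTAAG", coverage = 1, sizing_cv = 0.02,
                       fp_rate = 0, fn_rate = 0.1, seed = 45)
  confs <- c()
  for (i in seq_len(nrow(mfn$molecules))) {
    if (mfn$molecules$n_labels[i] < 9) next
    al <- align_molecule(mfn$labels[[i]], map,
                         mol_len = mfn$molecules$length[i])
    expect_identical(al$target, "h")
    confs <- c(confs, al$confidence)
  }
  expect_gte(mean(confs >= 0.8), 0.9)
  # a molecule from an unrelated sequence does not align
  other <- setNames(random_seq(4e5, seed = 46), "x")
  mo <- sim_molecules(other, "CTTAAG", coverage = 0.3, sizing_cv = 0,
                      fp_rate = 0, fn_rate = 0, seed = 47)
  neg <- align_molecule(mo$labels[[1]], map, mol_len = mo$molecules$length[1])
  expect_true(is.null(neg) || neg$confidence < 0.5)
  # too few labels: unalignable
  expect_null(align_molecule(c(100, 5000), map, mol_len = 10000))
})

test_that("alignment score is invariant under joint reverse-complement", {
  hap <- random_seq(6e5, seed = 48)
  map_f <- digest_to_map(hap, "CTTAAG", "f")
  map_r <- digest_to_map(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(hap))),
    "CTTAAG", "r")
  mols <- sim_molecules(setNames(hap, "h"), "CTTAAG", coverage = 0.5,
                        sizing_cv = 0.01, fp_rate = 0, fn_rate = 0.05,
                        seed = 49)
  i <- which(mols$molecules$n_labels >= 9)[1]
  af <- align_molecule(mols$labels[[i]], map_f, mol_len = mols$molecules$length[i])
  ar <- align_molecule(mols$labels[[i]], map_r, mol_len = mols$molecules$length[i])
  expect_equal(af$score, ar$score)
  expect_false(af$orientation == ar$orientation)
})

test_that("molecule trio binning follows confidence with seeded tie splitting", {
  withr::with_seed(51, {
    base <- random_seq(8e5)
    # father carries three 8-kb deletions: discriminative SV sites
    del <- function(s, at, len)
      paste0(substring(s, 1, at), substring(s, at + len + 1, nchar(s)))
    father <- del(del(del(base, 1e5, 8000), 3e5, 8000), 5e5, 8000)
  })
  fmap <- digest_to_map(father, "CTTAAG", "father")
  mmap <- digest_to_map(base, "CTTAAG", "mother")
  mols <- sim_molecules(setNames(base, "mat"), "CTTAAG", coverage = 3,
                        sizing_cv = 0.02, fp_rate = 0.01, fn_rate = 0.05,
                        seed = 52)
  bm <- bin_molecules(mols, list(fmap), list(mmap), seed = 2)
  asg <- bm$report[bm$report$reason == "assigned", ]
  # maternal molecules overlapping a father-specific SV bin maternal
  expect_gte(mean(asg$bin == "maternal"), 0.95)
  expect_gt(nrow(asg), 0)
  # ties and unaligned molecules are split into equal halves
  rest <- bm$report[bm$report$reason != "assigned", ]
  expect_lte(abs(sum(rest$bin == "maternal") - sum(rest$bin == "paternal")), 1L)
  # swapping the parents swaps the confidently assigned bins
  bm_sw <- bin_molecules(mols, list(mmap), list(fmap), seed = 2)
  asg_sw <- bm_sw$report[bm_sw$report$reason == "assigned", ]
  expect_identical(sort(asg_sw$id), sort(asg$id))
  expect_true(all(asg_sw$bin[match(asg$id, asg_sw$id)] !=
                  asg$bin))
  # determinism of the seeded split
  bm2 <- bin_molecules(mols, list(fmap), list(mmap), seed = 2)
  expect_identical(bm$report, bm2$report)
})

test_that("cross-check recovers mis-binned alleles without false breaks", {
  n_win <- 62L
  het_windows <- 2L + seq_len(58L)          # 58 informative loci, windows 3..60
  misbinned <- het_windows[c(4, 11, 19, 25, 33, 41, 49, 56)]  # 8 implanted
  consistent <- setdiff(het_windows, misbinned)[1:50]
  f1 <- make_label_map("f1", n_win)
  f2 <- make_label_map("f2", n_win)                    # father AA everywhere
  m1 <- make_label_map("m1", n_win)                    # mother allele A
  m2 <- make_label_map("m2", n_win, het_windows)       # mother allele B
  child_pat <- make_label_map("cp", n_win, misbinned)  # wrongly carries B
  child_mat <- make_label_map("cm", n_win, consistent) # B where truth says so
  res <- cross_check(list(mat = child_mat, pat = child_pat),
                     list(f1, f2), list(m1, m2))
  expect_gte(sum(res$breaks$window %in% misbinned), 7L)
  expect_identical(sum(res$loci$verdict == "break" &
                       !(res$loci$window %in% misbinned)), 0L)
  expect_gte(sum(res$loci$verdict == "consistent"), 50L)
  # breaking splits the maternal child map into one extra piece per break
  expect_identical(length(res$child_maps_broken$mat), nrow(res$breaks) + 1L)
  # a fully consistent trio yields zero breaks
  res0 <- cross_check(list(mat = make_label_map("cm", n_win, het_windows),
                           pat = make_label_map("cp", n_win)),
                      list(f1, f2), list(m1, m2))
  expect_identical(nrow(res0$breaks), 0L)
})
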