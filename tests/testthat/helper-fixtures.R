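# Shared fixtures and independent oracles. Fixtures are generated in code
# (no files); the trio fixture is cached per session because several test
# files reuse it.

.fixture_env <- new.env(parent = emptyenv())

# Small trio: one 200-kb chromosome, SNVs + small indels, no SVs.
fixture_trio <- function() {
  if (is.null(.fixture_env$trio)) {
    .fixture_env$trio <- gen_trio(trio_config(
      seed = 101, chrom_lengths = 2e5, snv_rate = 0.001,
      indel_rate = 1e-4, sv_rate = 0))
  }
  .fixture_env$trio
}

fixture_hapmers <- function(reliable_min = 1L) {
  key <- paste0("hapmers", reliable_min)
  if (is.null(.fixture_env[[key]])) {
    sq <- fixture_trio()$sequences
    .fixture_env[[key]] <- hapmer_sets(
      count_kmers(c(sq$mother_hap1, sq$mother_hap2), 21, "mat"),
      count_kmers(c(sq$father_hap1, sq$father_hap2), 21, "pat"),
      count_kmers(c(sq$child_mat, sq$child_pat), 21, "child"),
      reliable_min = reliable_min)
  }
  .fixture_env[[key]]
}

random_seq <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Naive O(n*k) canonical k-mer oracle (pure R, independent of the package's
# compiled path).
naive_kmer_table <- function(seqs, k) {
  all <- unlist(lapply(seqs, function(s) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) return(character(0))
    km <- substring(s, 1:(n - k + 1), k:n)
    km[!grepl("[^ACGT]", km)]
  }))
  if (length(all) == 0L) return(table(character(0)))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(all)))
  table(pmin(all, rc))
}

# Brute-force NG50: scan every candidate length by definition.
brute_ng50 <- function(lengths, G) {
  best <- 0
  for (L in sort(unique(lengths))) {
    if (sum(lengths[lengths >= L]) >= G / 2 && L > best) best <- L
  }
  best
}

# Label tracks for optical-map cross-check fixtures: n_windows blocks of
# `lpw` labels at `spacing` bp; windows listed in b_windows carry allele B
# (one inner interval stretched well beyond sizing tolerance).
make_label_map <- function(id, n_windows, b_windows = integer(0),
                           lpw = 10L, spacing = 5000) {
  n_lab <- n_windows * lpw
  gaps <- rep(spacing, n_lab)        # gaps[i] precedes label i (first = offset)
  for (w in b_windows) {
    i <- (w - 1L) * lpw + 4L         # an interval interior to window w
    gaps[i] <- spacing * 1.6
  }
  labels <- cumsum(gaps)
  optical_map(id, labels[n_lab] + spacing, labels)
}
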