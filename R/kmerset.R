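# Canonical k-mer multisets and the k-mer based assembly metrics: consensus
# quality (QV), completeness, haplotype-specific marker (hapmer) extraction
# and false-duplication estimation. Exact counting (no sketches): the test
# suite relies on oracle equality.

#' Count canonical k-mers
#'
#' Every k-mer is stored as the lexicographic minimum of itself and its
#' reverse complement; k-mers containing non-ACGT characters (gaps, N) are
#' skipped.
#'
#' @param seqs character vector or DNAStringSet of sequences
#' @param k odd k-mer size (default 21)
#' @param source free-text label (reads, assembly, parent, ...)
#' @return a \code{kmer_set}: fields \code{k}, \code{key} (opaque sorted
#'   encoding), \code{count}, \code{source}
#' @export
count_kmers <- function(seqs, k = 21L, source = "reads") {
  seqs <- as_char_seqs(seqs)
  k <- as.integer(k)
  if (k < 3L || k > 31L || k %% 2L == 0L)
    stop("k must be odd and between 3 and 31")
  res <- cpp_count_kmers(seqs, k)
  structure(list(k = k, key = res$key, count = res$count, source = source),
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat("kmer_set: k =", x$k, "|", length(x$key), "distinct,",
      format(sum(as.numeric(x$count)), big.mark = ","), "total instances",
      "| source:", x$source, "\n")
  invisible(x)
}

#' Distinct k-mers of a set as strings (small sets / testing)
#' @param ks a [kmer_set] or a Hapmers component
#' @return character vector of canonical k-mers
#' @export
kmer_strings <- function(ks) cpp_decode_kmers(ks$key, ks$k)

# Instance counts of ks_a's keys inside ks_b (0 where absent).
kmer_counts_in <- function(keys, ks) {
  idx <- cpp_key_match(keys, ks$key)
  out <- integer(length(keys))
  out[idx > 0] <- ks$count[idx[idx > 0]]
  out
}

#' Extract haplotype-specific marker k-mers (hapmers)
#'
#' Maternal hapmers are k-mers present in the maternal read set but not the
#' paternal one, and inherited by the child; paternal hapmers symmetric.
#' Both are restricted to counts of at least \code{reliable_min} in the
#' contributing parent and in the child, to exclude singleton error k-mers.
#'
#' @param mat_reads,pat_reads,child_reads [kmer_set]s with identical k
#' @param reliable_min minimum count in parent and child (default 2; use 1
#'   for error-free, genome-derived sets)
#' @return a \code{hapmers} object with \code{$maternal} and \code{$paternal}
#'   [kmer_set]s (counts are the child counts); the two sets are disjoint
#' @export
hapmer_sets <- function(mat_reads, pat_reads, child_reads, reliable_min = 2L) {
  if (mat_reads$k != pat_reads$k || mat_reads$k != child_reads$k)
    stop("k-mer sizes differ between input sets")
  stopifnot(reliable_min >= 1)
  k <- mat_reads$k
  one_side <- function(own, other) {
    keys <- own$key[own$count >= reliable_min]
    keys <- keys[cpp_key_match(keys, other$key) == 0L]
    child_cnt <- kmer_counts_in(keys, child_reads)
    keep <- child_cnt >= reliable_min
    structure(list(k = k, key = keys[keep], count = child_cnt[keep],
                   source = "hapmer"), class = "kmer_set")
  }
  structure(list(k = k,
                 maternal = one_side(mat_reads, pat_reads),
                 paternal = one_side(pat_reads, mat_reads)),
            class = "hapmers")
}

#' @export
print.hapmers <- function(x, ...) {
  cat("hapmers: k =", x$k, "| maternal:", length(x$maternal$key),
      "| paternal:", length(x$paternal$key), "\n")
  invisible(x)
}

#' Estimate consensus quality (QV) from k-mer read support
#'
#' Counts assembly k-mer instances absent from the read k-mer set
#' (\code{k_err} of \code{k_total}), converts to a per-base error
#' probability \code{E = 1 - (1 - k_err/k_total)^(1/k)} and reports
#' \code{QV = -10*log10(E)}. A QV of 60 corresponds to about one error per
#' megabase. When no instance is unsupported the report is flagged infinite
#' and \code{qv} carries the sentinel \code{Inf}.
#'
#' @param asm assembly sequences (character vector or DNAStringSet)
#' @param read_kmers [kmer_set] built from reads
#' @param k k-mer size (defaults to that of \code{read_kmers})
#' @return a \code{qv_report}: k_total, k_err, err_rate, qv, infinite flag
#' @export
estimate_qv <- function(asm, read_kmers, k = read_kmers$k) {
  asm <- as_char_seqs(asm)
  if (length(read_kmers$key) == 0L) stop("read k-mer set is empty")
  if (k != read_kmers$k) stop("k does not match read_kmers")
  inst <- cpp_kmer_instances(asm, k, read_kmers$key)
  if (inst[1] == 0) stop("assembly shorter than k: no k-mer instances")
  k_total <- inst[1]; k_err <- inst[2]
  if (k_err == 0) {
    rep <- list(k = k, k_total = k_total, k_err = 0, err_rate = 0,
                qv = Inf, infinite = TRUE)
  } else {
    E <- 1 - (1 - k_err / k_total)^(1 / k)
    rep <- list(k = k, k_total = k_total, k_err = k_err, err_rate = E,
                qv = -10 * log10(E), infinite = FALSE)
  }
  structure(rep, class = "qv_report")
}

#' @export
print.qv_report <- function(x, ...) {
  if (x$infinite)
    cat(sprintf("QV: inf (no unsupported k-mers; %s instances)\n",
                format(x$k_total, big.mark = ",")))
  else
    cat(sprintf("QV: %.1f (error rate %.3g; %s of %s instances unsupported)\n",
                x$qv, x$err_rate, format(x$k_err, big.mark = ","),
                format(x$k_total, big.mark = ",")))
  invisible(x)
}

#' K-mer completeness of an assembly
#'
#' Fraction of reliable read k-mers (count at least \code{reliable_min})
#' present in the assembly.
#'
#' @param asm_kmers [kmer_set] from the assembly
#' @param read_kmers [kmer_set] from reads
#' @param reliable_min reliability floor on read counts
#' @return fraction in [0, 1]
#' @export
completeness <- function(asm_kmers, read_kmers, reliable_min = 2L) {
  if (asm_kmers$k != read_kmers$k) stop("k-mer sizes differ")
  rel <- read_kmers$key[read_kmers$count >= reliable_min]
  if (length(rel) == 0L)
    stop("no reliable read k-mers at reliable_min = ", reliable_min)
  mean(cpp_key_match(rel, asm_kmers$key) > 0L)
}

#' Estimate the haploid depth peak of a read k-mer spectrum
#'
#' The mode of the count histogram above the reliability floor. On strongly
#' homozygous diploids the mode sits at the 2-copy peak; pass an explicit
#' peak to [false_duplication()] when that is known.
#'
#' @param read_kmers [kmer_set] from reads
#' @param reliable_min counts below this are treated as error k-mers
#' @return modal multiplicity (integer)
#' @export
haploid_peak <- function(read_kmers, reliable_min = 2L) {
  cnt <- read_kmers$count[read_kmers$count >= reliable_min]
  if (length(cnt) == 0L) stop("flat spectrum: no counts above reliable_min")
  tab <- table(cnt)
  if (length(tab) == 1L && as.integer(names(tab))[1] == reliable_min)
    warning("spectrum has a single multiplicity; peak estimate is degenerate")
  as.integer(names(tab)[which.max(tab)])
}

#' False-duplication estimate from k-mer copy numbers
#'
#' Flags assembly k-mers whose assembly copy number exceeds the copy number
#' implied by read multiplicity, \code{round(read_count / peak)} (floored at
#' one for read-supported k-mers). Each excess instance is counted as one
#' duplicated bp; the result is a percentage of assembly bp. Unsupported
#' (zero-read-count) k-mers are consensus errors, not duplications, and are
#' ignored here.
#'
#' @param asm_kmers [kmer_set] from the assembly
#' @param read_kmers [kmer_set] from reads
#' @param peak haploid-depth peak; estimated with [haploid_peak()] when NULL
#' @param reliable_min reliability floor used for peak estimation
#' @return list: percent, excess_bp, assembly_bp, peak
#' @export
false_duplication <- function(asm_kmers, read_kmers, peak = NULL,
                              reliable_min = 2L) {
  if (asm_kmers$k != read_kmers$k) stop("k-mer sizes differ")
  if (is.null(peak)) peak <- haploid_peak(read_kmers, reliable_min)
  stopifnot(peak > 0)
  rc <- kmer_counts_in(asm_kmers$key, read_kmers)
  supported <- rc > 0
  expected <- pmax(1, round(rc[supported] / peak))
  excess <- pmax(0, asm_kmers$count[supported] - expected)
  asm_bp <- sum(as.numeric(asm_kmers$count))
  list(percent = 100 * sum(excess) / asm_bp,
       excess_bp = sum(excess), assembly_bp = asm_bp, peak = peak)
}
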