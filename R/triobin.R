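# Trio binning of child reads by hapmer content, and haplotype filtering of
# linked read pairs against the other haplotype's hapmers.

#' Bin long reads into parental haplotypes by hapmer hits
#'
#' A read is assigned maternal when it carries at least \code{min_hits}
#' maternal hapmer instances and strictly more maternal than paternal ones;
#' paternal symmetric; everything else (including exact ties) is UNKNOWN.
#' Reads shorter than \code{min_len} are excluded and reported separately.
#'
#' @param reads a \code{read_set} (see [sim_long_reads()]) or a named
#'   character vector of read sequences
#' @param hapmers a \code{hapmers} object (see [hapmer_sets()])
#' @param min_len minimum read length in bp (default 1000)
#' @param min_hits minimum hapmer instances required for assignment
#' @return a \code{bin_result}: \code{$assignments} data frame (id, length,
#'   n_mat, n_pat, bin), \code{$excluded} short-read ids, \code{$summary}
#' @export
bin_long_reads <- function(reads, hapmers, min_len = 1000, min_hits = 2L) {
  if (is.character(reads)) {
    ids <- names(reads) %||% sprintf("read%06d", seq_along(reads))
    reads <- data.frame(id = ids, seq = unname(reads),
                        length = nchar(reads), stringsAsFactors = FALSE)
  }
  n_hap <- length(hapmers$maternal$key) + length(hapmers$paternal$key)
  long <- reads$length >= min_len
  excluded <- reads$id[!long]
  r <- reads[long, , drop = FALSE]
  if (n_hap == 0L) {
    warning("both hapmer sets are empty: all reads UNKNOWN")
    hits <- matrix(0L, nrow(r), 2)
  } else {
    hits <- cpp_seq_hits(r$seq, hapmers$k,
                         hapmers$maternal$key, hapmers$paternal$key)
  }
  n_mat <- hits[, 1]; n_pat <- hits[, 2]
  bin <- rep("UNKNOWN", nrow(r))
  bin[n_mat >= min_hits & n_mat > n_pat] <- "MAT"
  bin[n_pat >= min_hits & n_pat > n_mat] <- "PAT"
  asg <- data.frame(id = r$id, length = r$length, n_mat = n_mat,
                    n_pat = n_pat, bin = bin, stringsAsFactors = FALSE)
  if (!is.null(r$origin)) asg$origin <- r$origin
  structure(list(assignments = asg, excluded = excluded,
                 summary = c(table(factor(bin, c("MAT", "PAT", "UNKNOWN"))))),
            class = "bin_result")
}

#' @export
print.bin_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("trio binning: %d MAT / %d PAT / %d UNKNOWN (%d excluded < min_len)\n",
              s[["MAT"]], s[["PAT"]], s[["UNKNOWN"]], length(x$excluded)))
  invisible(x)
}

#' Split unclassified reads into two equal bins
#'
#' Deterministic under \code{seed}; bin sizes differ by at most one.
#'
#' @param ids read identifiers
#' @param seed RNG seed
#' @return list with \code{bin1} and \code{bin2} id vectors
#' @export
split_unknowns <- function(ids, seed) {
  with_seed(seed, {
    perm <- sample(ids)
    n1 <- ceiling(length(ids) / 2)
    list(bin1 = perm[seq_len(n1)],
         bin2 = if (length(ids) > n1) perm[(n1 + 1):length(ids)] else character(0))
  })
}

#' Filter linked read pairs against the other haplotype's hapmers
#'
#' A pair is dropped when either mate contains one or more k-mers from the
#' other-haplotype hapmer set; kept pairs pass through unchanged.
#'
#' @param pairs data frame with columns \code{pair_id}, \code{seq1},
#'   \code{seq2}
#' @param other_hapmers [kmer_set] of the other haplotype's hapmers
#' @return list: \code{kept} (pairs), \code{dropped} (pair_id, hits1, hits2)
#' @export
filter_linked_pairs <- function(pairs, other_hapmers) {
  need <- c("pair_id", "seq1", "seq2")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns pair_id, seq1, seq2")
  bad <- is.na(pairs$seq1) | is.na(pairs$seq2) |
    !nzchar(pairs$seq1) | !nzchar(pairs$seq2)
  if (any(bad))
    stop("orphan mates for pair id(s): ",
         paste(pairs$pair_id[bad], collapse = ", "))
  empty <- numeric(0)
  h1 <- cpp_seq_hits(pairs$seq1, other_hapmers$k, other_hapmers$key, empty)[, 1]
  h2 <- cpp_seq_hits(pairs$seq2, other_hapmers$k, other_hapmers$key, empty)[, 1]
  drop <- h1 > 0 | h2 > 0
  list(kept = pairs[!drop, , drop = FALSE],
       dropped = data.frame(pair_id = pairs$pair_id[drop],
                            hits1 = h1[drop], hits2 = h2[drop],
                            stringsAsFactors = FALSE))
}
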