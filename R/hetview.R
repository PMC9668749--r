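# Haplotype-versus-haplotype diversity: variant catalogs at the 50-bp SV
# boundary, window densities, synonymous/non-synonymous classification,
# heterozygosity percentages and mitochondrial heteroplasmy calling.

#' Catalog differences between two haploid assemblies
#'
#' Aligns haplotype 1 contigs against haplotype 2 (used as the reference for
#' coordinates) and classifies differences at the 50-bp boundary: SNVs,
#' small indels (<50 bp) and large SVs (insertions, deletions, inversions;
#' >=50 bp). Block replacements whose two sides are reverse complements (at
#' 90 percent identity or better) are classified as inversions. Features in
#' which more than half the bases are gaps (N) are excluded. When both
#' inputs hold multiple contigs, contig pairs are used only if they
#' reciprocally share the best alignment (mutual-best rule).
#'
#' @param h1,h2 named character vectors of haploid assemblies
#' @param sv_min SV size boundary in bp (50)
#' @param anchor_k anchor k-mer size for the aligner
#' @return a \code{het_catalog} data frame: chrom (h2 contig), pos, class
#'   (SNV, INS, DEL, INV), len, ref, alt; attribute \code{aligned_bp}
#' @export
hap_vs_hap <- function(h1, h2, sv_min = 50, anchor_k = 21L) {
  h1 <- as_char_seqs(h1); h2 <- as_char_seqs(h2)
  if (is.null(names(h1))) names(h1) <- paste0("h1_", seq_along(h1))
  if (is.null(names(h2))) names(h2) <- paste0("h2_", seq_along(h2))
  # mutual-best contig pairing by shared unique-anchor count
  pair_score <- matrix(0, length(h1), length(h2),
                       dimnames = list(names(h1), names(h2)))
  ks2 <- lapply(h2, count_kmers, k = anchor_k)
  for (i in seq_along(h1)) {
    k1 <- count_kmers(h1[[i]], anchor_k)
    u1 <- k1$key[k1$count == 1L]
    for (j in seq_along(h2)) {
      u2 <- ks2[[j]]$key[ks2[[j]]$count == 1L]
      pair_score[i, j] <- sum(cpp_key_match(u1, u2) > 0L)
    }
  }
  records <- list()
  aligned_bp <- 0
  unaligned <- character(0)
  for (i in seq_along(h1)) {
    j <- which.max(pair_score[i, ])
    mutual <- which.max(pair_score[, j]) == i && pair_score[i, j] > 0
    if (!mutual) { unaligned <- c(unaligned, names(h1)[i]); next }
    aln <- align_haplotype(h1[[i]], h2[[j]], anchor_k = anchor_k)
    if (is.null(aln)) { unaligned <- c(unaligned, names(h1)[i]); next }
    aligned_bp <- aligned_bp + (aln$ref_end - aln$ref_start)
    records[[length(records) + 1L]] <-
      catalog_from_ops(aln, h1[[i]], h2[[j]], names(h2)[j], sv_min)
  }
  cat_df <- if (length(records)) do.call(rbind, records) else
    data.frame(chrom = character(0), pos = numeric(0), class = character(0),
               len = numeric(0), ref = character(0), alt = character(0),
               stringsAsFactors = FALSE)
  cat_df <- cat_df[order(cat_df$chrom, cat_df$pos), , drop = FALSE]
  rownames(cat_df) <- NULL
  # size classification at the SV boundary: small indels < sv_min bp,
  # large SVs (including inversions) >= sv_min bp
  cat_df$size_class <- ifelse(cat_df$class == "SNV", "snv",
                       ifelse(cat_df$len < sv_min, "small_indel", "sv"))
  structure(cat_df, aligned_bp = aligned_bp, unaligned = unaligned,
            class = c("het_catalog", "data.frame"))
}

gap_majority <- function(...) {
  seqs <- c(...)
  n_bases <- sum(nchar(seqs))
  if (n_bases == 0) return(FALSE)
  n_gap <- sum(vapply(seqs, function(s)
    lengths(regmatches(s, gregexpr("N", s, fixed = TRUE))), 0L))
  n_gap > n_bases / 2
}

# Collapse alignment ops into maximal difference blocks (runs of non-match
# ops) and classify each block: pure substitutions decompose into SNVs,
# one-sided blocks are insertions/deletions, and two-sided replacements
# whose sides are reverse complements are inversions.
catalog_from_ops <- function(aln, qry, refseq, chrom, sv_min) {
  out <- list()
  emit <- function(rec) out[[length(out) + 1L]] <<- rec
  ops <- aln$ops
  r <- aln$ref_start; h <- 0
  emit_block <- function(r0, h0, rlen, hlen) {
    rseq <- if (rlen > 0) substring(refseq, r0 + 1, r0 + rlen) else ""
    qseq <- if (hlen > 0) substring(qry, h0 + 1, h0 + hlen) else ""
    if (gap_majority(rseq, qseq)) return(invisible())
    if (rlen > 0 && hlen > 0 &&
        min(rlen, hlen) >= sv_min && rc_identity(rseq, qseq) >= 0.9) {
      emit(data.frame(chrom = chrom, pos = r0, class = "INV", len = rlen,
                      ref = "", alt = "", stringsAsFactors = FALSE))
    } else if (rlen == hlen) {
      for (j in seq_len(rlen)) {
        rb <- substring(rseq, j, j); qb <- substring(qseq, j, j)
        if (rb != qb && rb != "N" && qb != "N")
          emit(data.frame(chrom = chrom, pos = r0 + j - 1, class = "SNV",
                          len = 1, ref = rb, alt = qb,
                          stringsAsFactors = FALSE))
      }
    } else {
      # general replacement: trim the common substituted prefix into SNVs,
      # then record the length difference as an indel
      common <- min(rlen, hlen)
      for (j in seq_len(common)) {
        rb <- substring(rseq, j, j); qb <- substring(qseq, j, j)
        if (rb != qb && rb != "N" && qb != "N")
          emit(data.frame(chrom = chrom, pos = r0 + j - 1, class = "SNV",
                          len = 1, ref = rb, alt = qb,
                          stringsAsFactors = FALSE))
      }
      if (rlen > hlen) {
        nv <- left_normalize(refseq, r0 + common,
                             substring(refseq, r0 + common + 1, r0 + rlen), "")
        emit(data.frame(chrom = chrom, pos = nv$pos, class = "DEL",
                        len = rlen - hlen, ref = nv$ref, alt = "",
                        stringsAsFactors = FALSE))
      } else {
        nv <- left_normalize(refseq, r0 + common, "",
                             substring(qry, h0 + common + 1, h0 + hlen))
        emit(data.frame(chrom = chrom, pos = nv$pos, class = "INS",
                        len = hlen - rlen, ref = "", alt = nv$alt,
                        stringsAsFactors = FALSE))
      }
    }
    invisible()
  }
  # match runs shorter than merge_gap do not close a difference block:
  # dissimilar replaced regions (inversions in particular) align with short
  # chance matches that would otherwise shatter the block
  merge_gap <- 25L
  i <- 1L
  n <- nrow(ops)
  while (i <= n) {
    if (ops$op[i] == "=") {
      r <- r + ops$len[i]; h <- h + ops$len[i]; i <- i + 1L; next
    }
    j <- i
    rlen <- 0; hlen <- 0
    while (j <= n) {
      if (ops$op[j] == "=") {
        # close unless this is a short chance match with more differences after
        if (ops$len[j] >= merge_gap || j == n || ops$op[j + 1L] == "=") break
      }
      if (ops$op[j] != "I") rlen <- rlen + ops$len[j]
      if (ops$op[j] != "D") hlen <- hlen + ops$len[j]
      j <- j + 1L
    }
    emit_block(r, h, rlen, hlen)
    r <- r + rlen; h <- h + hlen
    i <- j
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), pos = numeric(0), class = character(0),
               len = numeric(0), ref = character(0), alt = character(0),
               stringsAsFactors = FALSE)
}

rc_identity <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) return(0)
  if (abs(nchar(a) - nchar(b)) > 0.1 * max(nchar(a), nchar(b))) return(0)
  n <- min(nchar(a), nchar(b))
  ra <- substring(rev_comp(a), 1, n)
  1 - str_mismatches(ra, substring(b, 1, n)) / n
}

#' Window densities of a diversity catalog
#'
#' SNV counts (and percentages of window bp) in \code{snv_window} tiles and
#' indel/SV counts in \code{indel_window} tiles; the last window of each
#' chromosome is truncated.
#'
#' @param catalog a [hap_vs_hap()] catalog (or compatible frame)
#' @param chrom_lengths named vector of reference (h2) contig lengths
#' @param snv_window SNV window size in bp (500 kb)
#' @param indel_window indel/SV window size in bp (1 Mb)
#' @return list of data frames: \code{snv} (chrom, start, end, count, pct),
#'   \code{indel} and \code{sv} (chrom, start, end, count)
#' @export
window_density <- function(catalog, chrom_lengths, snv_window = 5e5,
                           indel_window = 1e6) {
  tile_counts <- function(classes, window, with_pct = FALSE) {
    sub <- catalog[catalog$class %in% classes, , drop = FALSE]
    out <- lapply(names(chrom_lengths), function(ch) {
      L <- chrom_lengths[[ch]]
      starts <- seq(0, max(0, L - 1), by = window)
      ends <- pmin(starts + window, L)
      p <- sub$pos[sub$chrom == ch]
      count <- vapply(seq_along(starts), function(i)
        sum(p >= starts[i] & p < ends[i]), 0L)
      df <- data.frame(chrom = ch, start = starts, end = ends, count = count,
                       stringsAsFactors = FALSE)
      if (with_pct) df$pct <- 100 * count / (ends - starts)
      df
    })
    do.call(rbind, out)
  }
  list(snv = tile_counts("SNV", snv_window, with_pct = TRUE),
       indel = tile_counts(c("INS", "DEL"), indel_window),
       sv = tile_counts(c("INV"), indel_window))
}

#' Classify coding SNVs as synonymous or non-synonymous
#'
#' Translates the affected codon before and after each SNV using the given
#' codon table; genes whose concatenated CDS length is not a multiple of
#' three are skipped and logged.
#'
#' @param snvs SNV records (chrom, pos, ref, alt), 0-based
#' @param cds CDS annotation frame: chrom, start, end (0-based half-open),
#'   strand (+/-), gene
#' @param genome named character vector of the sequences the CDS refer to
#' @return list: \code{effects} (variant, gene, effect), \code{summary}
#'   from [coding_effect_summary()], \code{skipped_genes}
#' @export
classify_coding <- function(snvs, cds, genome) {
  effects <- list()
  skipped <- character(0)
  for (g in unique(cds$gene)) {
    gc <- cds[cds$gene == g, , drop = FALSE]
    gc <- gc[order(gc$start), , drop = FALSE]
    strand <- gc$strand[1]
    ch <- gc$chrom[1]
    cds_len <- sum(gc$end - gc$start)
    if (cds_len %% 3 != 0) { skipped <- c(skipped, g); next }
    # genomic offset -> CDS coordinate (5'->3' on the coding strand)
    seg_starts <- gc$start; seg_ends <- gc$end
    hit <- snvs$chrom == ch &
      in_regions(snvs$chrom, snvs$pos, data.frame(chrom = ch,
                                                  start = gc$start,
                                                  end = gc$end))
    for (vi in which(hit)) {
      p <- snvs$pos[vi]
      seg <- which(p >= seg_starts & p < seg_ends)
      off_plus <- sum((seg_ends - seg_starts)[seq_len(seg - 1)]) +
        (p - seg_starts[seg])
      cds_pos <- if (strand == "+") off_plus else cds_len - 1 - off_plus
      codon_i <- cds_pos %/% 3
      within <- cds_pos %% 3
      # pull the codon's genomic bases
      cds_seq <- paste(substring(genome[[ch]], seg_starts + 1, seg_ends),
                       collapse = "")
      if (strand == "-") cds_seq <- rev_comp(cds_seq)
      codon <- substring(cds_seq, codon_i * 3 + 1, codon_i * 3 + 3)
      ref_b <- snvs$ref[vi]; alt_b <- snvs$alt[vi]
      if (strand == "-") {
        ref_b <- rev_comp(ref_b); alt_b <- rev_comp(alt_b)
      }
      if (substring(codon, within + 1, within + 1) != ref_b) next  # stale ref
      alt_codon <- codon
      substring(alt_codon, within + 1, within + 1) <- alt_b
      aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(codon)))
      aa_alt <- as.character(Biostrings::translate(Biostrings::DNAString(alt_codon)))
      effects[[length(effects) + 1L]] <- data.frame(
        variant = paste0(ch, ":", p), gene = g,
        effect = if (aa_ref == aa_alt) "synonymous" else "non-synonymous",
        stringsAsFactors = FALSE)
    }
  }
  eff <- if (length(effects)) do.call(rbind, effects) else
    data.frame(variant = character(0), gene = character(0),
               effect = character(0), stringsAsFactors = FALSE)
  list(effects = eff, summary = coding_effect_summary(eff),
       skipped_genes = skipped)
}

#' Summarize coding effects with one-decimal percentages
#'
#' Counts synonymous and non-synonymous SNVs and the genes they affect,
#' including the per-gene rollup of genes whose coding SNVs are exclusively
#' non-synonymous. Percentages are reported to one decimal.
#'
#' @param effects data frame with columns \code{effect} ("synonymous" /
#'   "non-synonymous") and optionally \code{gene}
#' @return list: n_total, n_synonymous, n_non_synonymous, pct_synonymous,
#'   pct_non_synonymous, gene counts when genes are present
#' @export
coding_effect_summary <- function(effects) {
  n <- nrow(effects)
  n_syn <- sum(effects$effect == "synonymous")
  n_non <- sum(effects$effect == "non-synonymous")
  out <- list(n_total = n, n_synonymous = n_syn, n_non_synonymous = n_non,
              pct_synonymous = if (n > 0) round(100 * n_syn / n, 1) else NA_real_,
              pct_non_synonymous = if (n > 0) round(100 * n_non / n, 1) else NA_real_)
  if (!is.null(effects$gene) && n > 0) {
    out$genes_synonymous <- length(unique(effects$gene[effects$effect == "synonymous"]))
    out$genes_non_synonymous <- length(unique(effects$gene[effects$effect == "non-synonymous"]))
    per_gene <- tapply(effects$effect, effects$gene,
                       function(e) all(e == "non-synonymous"))
    out$genes_exclusively_non_synonymous <- sum(per_gene)
  }
  out
}

#' Heterozygosity summary of a diversity catalog
#'
#' Heterozygous bp are summed per record (SNV = 1 bp; insertion/deletion =
#' length change; inversion = span) and expressed as a percentage of the
#' genome after subtracting any excluded regions (records inside excluded
#' regions are dropped from the numerator). When the catalog carries an
#' \code{aligned_bp} attribute the percentage over aligned bp is reported
#' alongside the genome-bp percentage.
#'
#' @param catalog a [hap_vs_hap()] catalog
#' @param genome_bp total genome size used as denominator
#' @param exclude optional BED frame of regions to exclude (e.g. centromeres)
#' @return list: het_bp, denominator_bp, pct, per_class bp totals, and
#'   pct_aligned when available
#' @export
het_summary <- function(catalog, genome_bp, exclude = NULL) {
  stopifnot(genome_bp > 0)
  cat_df <- catalog
  excl_bp <- 0
  if (!is.null(exclude) && nrow(exclude) > 0) {
    excl_bp <- sum(exclude$end - exclude$start)
    if (excl_bp >= genome_bp) stop("exclusion regions exceed the genome")
    drop <- in_regions(cat_df$chrom, cat_df$pos, exclude)
    cat_df <- cat_df[!drop, , drop = FALSE]
  }
  bp_of <- function(df) {
    if (nrow(df) == 0L) return(0)
    sum(ifelse(df$class == "SNV", 1, df$len))
  }
  per_class <- vapply(c(SNV = "SNV", INS = "INS", DEL = "DEL", INV = "INV"),
                      function(cl) bp_of(cat_df[cat_df$class == cl, , drop = FALSE]),
                      0)
  het_bp <- sum(per_class)
  denom <- genome_bp - excl_bp
  out <- list(het_bp = het_bp, denominator_bp = denom,
              pct = 100 * het_bp / denom, per_class_bp = per_class,
              n_records = nrow(cat_df))
  ab <- attr(catalog, "aligned_bp")
  if (!is.null(ab) && ab > 0) out$pct_aligned <- 100 * het_bp / ab
  out
}

#' Call heteroplasmic minor alleles from per-site base counts
#'
#' Reports minor alleles whose frequency (over all counted bases at the
#' site) strictly exceeds \code{min_frac}, with integer-rounded percentage
#' and per-strand counts when stranded columns (e.g. \code{A_fwd},
#' \code{A_rev}) are provided. Zero-coverage sites are skipped.
#'
#' @param site_counts data frame with columns chrom, pos and base counts
#'   A, C, G, T (optionally \code{<base>_fwd} / \code{<base>_rev})
#' @param min_frac minor-allele frequency threshold (default 0.01, i.e.
#'   above a 1 percent read error rate)
#' @return data frame: chrom, pos, allele, count, major_allele, major_count,
#'   freq, pct (nearest integer), plus fwd/rev counts when stranded
#' @export
heteroplasmy <- function(site_counts, min_frac = 0.01) {
  bases <- c("A", "C", "G", "T")
  stopifnot(all(bases %in% names(site_counts)))
  stranded <- all(paste0(bases, "_fwd") %in% names(site_counts))
  out <- list()
  for (i in seq_len(nrow(site_counts))) {
    cnt <- as.numeric(site_counts[i, bases])
    total <- sum(cnt)
    if (total == 0) next
    maj <- which.max(cnt)
    for (b in seq_along(bases)) {
      if (b == maj || cnt[b] == 0) next
      freq <- cnt[b] / total
      if (freq > min_frac) {
        rec <- data.frame(chrom = site_counts$chrom[i],
                          pos = site_counts$pos[i],
                          allele = bases[b], count = cnt[b],
                          major_allele = bases[maj], major_count = cnt[maj],
                          freq = freq, pct = round(100 * freq),
                          stringsAsFactors = FALSE)
        if (stranded) {
          rec$fwd <- site_counts[i, paste0(bases[b], "_fwd")]
          rec$rev <- site_counts[i, paste0(bases[b], "_rev")]
        }
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), pos = numeric(0), allele = character(0),
               count = numeric(0), major_allele = character(0),
               major_count = numeric(0), freq = numeric(0), pct = numeric(0),
               stringsAsFactors = FALSE)
}
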