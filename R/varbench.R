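# Assembly-based small-variant calling and benchmarking on desk-scale
# genomes: anchored global alignment of each haplotype to a reference,
# phased variant derivation with single-haplotype (GAP2) handling, and the
# genotype-aware recall / Phred-scaled error metrics.

# --- alignment ------------------------------------------------------------

# Longest strictly-increasing subsequence (indices), patience algorithm.
lis_idx <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  tails <- integer(0)  # indices of smallest tail per length
  prev <- integer(n)
  for (i in seq_len(n)) {
    lo <- 1L; hi <- length(tails) + 1L
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (x[tails[mid]] < x[i]) lo <- mid + 1L else hi <- mid
    }
    prev[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    tails[lo] <- i
  }
  out <- integer(length(tails))
  j <- tails[length(tails)]
  for (p in rev(seq_along(tails))) { out[p] <- j; j <- prev[j] }
  out
}

#' Align a haplotype contig to a reference sequence
#'
#' Anchored global alignment for desk-scale contigs: k-mers unique in both
#' sequences serve as colinear anchors (longest increasing chain), and the
#' segments between anchors are aligned with banded affine-gap dynamic
#' programming. Inter-anchor segments too large for base-level alignment
#' are emitted as block replacements.
#'
#' @param contig single haplotype contig sequence
#' @param ref single reference sequence
#' @param anchor_k anchor k-mer size (default 21)
#' @param max_cells cell guard for inter-anchor dynamic programming
#' @return a \code{hap_alignment}: \code{$ops} data frame of run-length
#'   operations (=, X, I, D), \code{$ref_start}, \code{$ref_end} (0-based
#'   half-open reference coverage), or NULL when no anchors are found
#' @export
align_haplotype <- function(contig, ref, anchor_k = 21L, max_cells = 2.5e7) {
  contig <- as_char_seqs(contig)[[1]]
  ref <- as_char_seqs(ref)[[1]]
  ks_r <- count_kmers(ref, anchor_k, "ref")
  ks_h <- count_kmers(contig, anchor_k, "hap")
  uniq_r <- ks_r$key[ks_r$count == 1L]
  shared <- uniq_r[cpp_key_match(
    uniq_r, ks_h$key[ks_h$count == 1L]) > 0L]
  if (length(shared) == 0L) return(NULL)
  ar <- cpp_anchor_positions(ref, anchor_k, shared)
  ah <- cpp_anchor_positions(contig, anchor_k, shared)
  # keys are unique in both sequences, so match pairs anchors one-to-one
  m <- match(ar$key, ah$key)
  ok <- !is.na(m)
  rpos <- ar$pos[ok]; hpos <- ah$pos[m[ok]]
  o <- order(rpos)
  rpos <- rpos[o]; hpos <- hpos[o]
  keep <- lis_idx(hpos)
  rpos <- rpos[keep]; hpos <- hpos[keep]
  # forward-strand verification (canonical k-mers also match reverse hits)
  fwd <- substring(ref, rpos + 1, rpos + anchor_k) ==
         substring(contig, hpos + 1, hpos + anchor_k)
  rpos <- rpos[fwd]; hpos <- hpos[fwd]
  if (length(rpos) == 0L) return(NULL)
  # thin to non-overlapping anchors
  sel <- 1L
  for (i in seq_along(rpos)[-1]) {
    j <- sel[length(sel)]
    if (rpos[i] >= rpos[j] + anchor_k && hpos[i] >= hpos[j] + anchor_k)
      sel <- c(sel, i)
  }
  rpos <- rpos[sel]; hpos <- hpos[sel]
  n_a <- length(rpos)
  ops <- list()
  push <- function(res) if (length(res$op)) ops[[length(ops) + 1L]] <<-
    data.frame(op = res$op, len = res$len, stringsAsFactors = FALSE)
  seg <- function(r0, r1, h0, h1)  # 0-based half-open on both sides
    cpp_nw_ops(substring(ref, r0 + 1, r1), substring(contig, h0 + 1, h1),
               1L, -4L, -6L, -1L, max_cells)
  head_h <- hpos[1]
  ref_start <- max(0, rpos[1] - head_h)
  push(seg(ref_start, rpos[1], 0, head_h))
  for (i in seq_len(n_a)) {
    push(list(op = "=", len = anchor_k))
    if (i < n_a)
      push(seg(rpos[i] + anchor_k, rpos[i + 1],
               hpos[i] + anchor_k, hpos[i + 1]))
  }
  tail_h <- nchar(contig) - (hpos[n_a] + anchor_k)
  ref_end <- min(nchar(ref), rpos[n_a] + anchor_k + tail_h)
  push(seg(rpos[n_a] + anchor_k, ref_end,
           hpos[n_a] + anchor_k, nchar(contig)))
  runs <- do.call(rbind, ops)
  # merge adjacent identical ops
  same <- c(FALSE, runs$op[-1] == runs$op[-nrow(runs)])
  grp <- cumsum(!same)
  runs <- data.frame(op = runs$op[!same],
                     len = as.vector(tapply(runs$len, grp, sum)),
                     stringsAsFactors = FALSE)
  structure(list(ops = runs, ref_start = ref_start, ref_end = ref_end,
                 contig_len = nchar(contig)),
            class = "hap_alignment")
}

# --- variant derivation ---------------------------------------------------

# Left-align one indel against the reference string. pos is 0-based; for
# insertions `alt` holds the inserted bases (ref allele empty); for
# deletions `ref_allele` holds the deleted bases (alt empty).
left_normalize <- function(refseq, pos, ref_allele, alt) {
  moving <- if (nchar(ref_allele) > 0) ref_allele else alt
  while (pos > 0) {
    prev <- substring(refseq, pos, pos)  # base at 0-based pos-1
    last <- substring(moving, nchar(moving), nchar(moving))
    if (prev != last) break
    moving <- paste0(prev, substring(moving, 1, nchar(moving) - 1))
    pos <- pos - 1
  }
  if (nchar(ref_allele) > 0) list(pos = pos, ref = moving, alt = "")
  else list(pos = pos, ref = "", alt = moving)
}

# Walk alignment ops into per-haplotype variant records.
ops_to_variants <- function(aln, contig, refseq, chrom) {
  vars <- list()
  r <- aln$ref_start  # 0-based ref cursor
  h <- 0
  for (i in seq_len(nrow(aln$ops))) {
    op <- aln$ops$op[i]; len <- aln$ops$len[i]
    if (op == "=") { r <- r + len; h <- h + len }
    else if (op == "X") {
      for (j in seq_len(len))
        vars[[length(vars) + 1L]] <- list(
          pos = r + j - 1,
          ref = substring(refseq, r + j, r + j),
          alt = substring(contig, h + j, h + j))
      r <- r + len; h <- h + len
    } else if (op == "D") {
      nv <- left_normalize(refseq, r, substring(refseq, r + 1, r + len), "")
      vars[[length(vars) + 1L]] <- nv
      r <- r + len
    } else {  # I
      nv <- left_normalize(refseq, r, "", substring(contig, h + 1, h + len))
      vars[[length(vars) + 1L]] <- nv
      h <- h + len
    }
  }
  if (!length(vars))
    return(data.frame(chrom = character(0), pos = numeric(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  data.frame(chrom = chrom,
             pos = vapply(vars, `[[`, 0, "pos"),
             ref = vapply(vars, `[[`, "", "ref"),
             alt = vapply(vars, `[[`, "", "alt"),
             stringsAsFactors = FALSE)
}

#' Call phased variants from two haplotype alignments
#'
#' Produces decomposed, left-normalized records with phased genotypes
#' (haplotype 1, by convention paternal, in the first field). Sites covered
#' by only one haplotype alignment receive the GAP2 filter and their
#' genotype is promoted from half-calls to homozygous (1|. to 1|1),
#' following the single-haplotype handling of assembly-based calling.
#'
#' @param aln_hap1,aln_hap2 [align_haplotype()] results (hap1 = paternal);
#'   either may be NULL (uncovered haplotype)
#' @param contig1,contig2 the contig sequences that were aligned
#' @param ref single reference sequence
#' @param chrom reference name for the records
#' @return list: \code{$variants} (chrom, pos, ref, alt, gt, filter, class),
#'   \code{$conf_regions} BED-like frame covered by both haplotypes
#' @export
call_variants <- function(aln_hap1, aln_hap2, contig1, contig2, ref,
                          chrom = "ref") {
  ref <- as_char_seqs(ref)[[1]]
  v1 <- if (!is.null(aln_hap1))
    ops_to_variants(aln_hap1, as_char_seqs(contig1)[[1]], ref, chrom)
  else NULL
  v2 <- if (!is.null(aln_hap2))
    ops_to_variants(aln_hap2, as_char_seqs(contig2)[[1]], ref, chrom)
  else NULL
  cov1 <- if (!is.null(aln_hap1)) c(aln_hap1$ref_start, aln_hap1$ref_end) else NULL
  cov2 <- if (!is.null(aln_hap2)) c(aln_hap2$ref_start, aln_hap2$ref_end) else NULL
  keyof <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  k1 <- if (!is.null(v1)) keyof(v1) else character(0)
  k2 <- if (!is.null(v2)) keyof(v2) else character(0)
  allv <- rbind(v1, v2)
  if (is.null(allv) || nrow(allv) == 0L) {
    variants <- data.frame(chrom = character(0), pos = numeric(0),
                           ref = character(0), alt = character(0),
                           gt = character(0), filter = character(0),
                           class = character(0), stringsAsFactors = FALSE)
  } else {
    allv <- allv[!duplicated(keyof(allv)), , drop = FALSE]
    allv <- allv[order(allv$pos), , drop = FALSE]
    keys <- keyof(allv)
    in1 <- keys %in% k1
    in2 <- keys %in% k2
    covered1 <- !is.null(cov1) & allv$pos >= (cov1[1] %||% Inf) &
      allv$pos < (cov1[2] %||% -Inf)
    covered2 <- !is.null(cov2) & allv$pos >= (cov2[1] %||% Inf) &
      allv$pos < (cov2[2] %||% -Inf)
    gt <- paste0(as.integer(in1), "|", as.integer(in2))
    filter <- rep("PASS", nrow(allv))
    single <- xor(covered1, covered2)
    if (any(single)) {
      filter[single] <- "GAP2"
      gt[single] <- "1|1"  # 1|. promoted to homozygous
    }
    variants <- data.frame(allv, gt = gt, filter = filter,
                           class = ifelse(nchar(allv$ref) == 1 &
                                          nchar(allv$alt) == 1, "SNP", "INDEL"),
                           stringsAsFactors = FALSE)
    rownames(variants) <- NULL
  }
  conf <- if (!is.null(cov1) && !is.null(cov2)) {
    s <- max(cov1[1], cov2[1]); e <- min(cov1[2], cov2[2])
    if (e > s) data.frame(chrom = chrom, start = s, end = e) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  } else data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  list(variants = variants, conf_regions = conf)
}

#' Phased truth variants of a synthetic trio child, caller-normalized
#'
#' Converts the child's event-level truth (against the ancestor) into the
#' decomposed left-normalized records [call_variants()] emits, so the two
#' can be compared exactly. Inversion events are excluded (they are block
#' rearrangements, not small variants).
#'
#' @param trio a \code{trio_truth} (see [gen_trio()])
#' @return variant data frame (chrom, pos, ref, alt, gt, class)
#' @export
truth_variants <- function(trio) {
  tv <- trio$child_variants
  tv <- tv[tv$type != "inv", , drop = FALSE]
  if (nrow(tv) == 0L)
    return(data.frame(chrom = character(0), pos = numeric(0),
                      ref = character(0), alt = character(0),
                      gt = character(0), class = character(0)))
  out <- lapply(seq_len(nrow(tv)), function(i) {
    anc <- trio$ancestor[[tv$chrom[i]]]
    if (tv$type[i] == "snv") {
      list(pos = tv$pos[i],
           ref = substring(anc, tv$pos[i] + 1, tv$pos[i] + 1),
           alt = tv$alt[i])
    } else if (tv$type[i] == "del") {
      left_normalize(anc, tv$pos[i],
                     substring(anc, tv$pos[i] + 1, tv$pos[i] + tv$len[i]), "")
    } else {
      left_normalize(anc, tv$pos[i], "", tv$alt[i])
    }
  })
  res <- data.frame(chrom = tv$chrom,
                    pos = vapply(out, `[[`, 0, "pos"),
                    ref = vapply(out, `[[`, "", "ref"),
                    alt = vapply(out, `[[`, "", "alt"),
                    gt = tv$gt,
                    stringsAsFactors = FALSE)
  res$class <- ifelse(nchar(res$ref) == 1 & nchar(res$alt) == 1, "SNP", "INDEL")
  res[order(res$chrom, res$pos), , drop = FALSE]
}

# --- benchmarking ---------------------------------------------------------

in_regions <- function(chrom, pos, bed) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    b <- bed[bed$chrom == ch, , drop = FALSE]
    idx <- which(chrom == ch)
    if (nrow(b) == 0L) next
    for (j in seq_len(nrow(b)))
      out[idx] <- out[idx] | (pos[idx] >= b$start[j] & pos[idx] < b$end[j])
  }
  out
}

gt_equal <- function(a, b) {
  sa <- vapply(strsplit(a, "|", fixed = TRUE), function(x)
    paste(sort(x), collapse = "/"), "")
  sb <- vapply(strsplit(b, "|", fixed = TRUE), function(x)
    paste(sort(x), collapse = "/"), "")
  sa == sb
}

#' Compare a query variant set to truth inside confident regions
#'
#' Matching is exact on normalized decomposed alleles: a truth record is TP
#' when its allele and (unphased) genotype are both matched; an allele match
#' with a genotype mismatch is counted in FP.gt; unmatched truth records are
#' FN and unmatched query records FP.
#'
#' @param query,truth variant data frames (chrom, pos, ref, alt, gt, class)
#' @param conf_regions confident-region BED frame (chrom, start, end)
#' @param strata optional named list of BED frames for stratified counts
#' @return a \code{benchmark_counts} list: per-type TRUTH.TOTAL, TRUTH.TP,
#'   FP.gt, TRUTH.FN, QUERY.FP, QUERY.TOTAL; Subset.IS_CONF.Size; and
#'   \code{$strata} when requested
#' @export
compare_to_truth <- function(query, truth, conf_regions, strata = NULL) {
  if (is.unsorted(truth$pos[truth$chrom == truth$chrom[1]]) ||
      is.unsorted(query$pos[query$chrom == query$chrom[1]]))
    stop("variant sets must be position-sorted")
  count_one <- function(regions) {
    q <- query[in_regions(query$chrom, query$pos, regions), , drop = FALSE]
    t <- truth[in_regions(truth$chrom, truth$pos, regions), , drop = FALSE]
    kq <- paste(q$chrom, q$pos, q$ref, q$alt, sep = ":")
    kt <- paste(t$chrom, t$pos, t$ref, t$alt, sep = ":")
    res <- list()
    for (cls in c("SNP", "INDEL")) {
      ti <- t$class == cls
      qi <- q$class == cls
      m <- match(kt[ti], kq)
      matched <- !is.na(m)
      gt_ok <- matched
      gt_ok[matched] <- gt_equal(t$gt[ti][matched], q$gt[m[matched]])
      res[[paste0(cls, ".TRUTH.TOTAL")]] <- sum(ti)
      res[[paste0(cls, ".TRUTH.TP")]] <- sum(gt_ok)
      res[[paste0(cls, ".FP.gt")]] <- sum(matched & !gt_ok)
      res[[paste0(cls, ".TRUTH.FN")]] <- sum(!matched)
      res[[paste0(cls, ".QUERY.TOTAL")]] <- sum(qi)
      res[[paste0(cls, ".QUERY.FP")]] <- sum(!(kq[qi] %in% kt))
    }
    res
  }
  out <- count_one(conf_regions)
  out[["Subset.IS_CONF.Size"]] <- sum(conf_regions$end - conf_regions$start)
  if (!is.null(strata)) {
    out$strata <- lapply(strata, function(bed) {
      inter <- intersect_beds(conf_regions, bed)
      c(count_one(inter),
        list(Subset.IS_CONF.Size = sum(inter$end - inter$start)))
    })
  }
  structure(out, class = "benchmark_counts")
}

intersect_beds <- function(a, b) {
  out <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ra <- IRanges::IRanges(a$start[a$chrom == ch] + 1L, a$end[a$chrom == ch])
    rb <- IRanges::IRanges(b$start[b$chrom == ch] + 1L, b$end[b$chrom == ch])
    ov <- IRanges::intersect(IRanges::reduce(ra), IRanges::reduce(rb))
    if (length(ov))
      out[[ch]] <- data.frame(chrom = ch, start = IRanges::start(ov) - 1L,
                              end = IRanges::end(ov), stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
}

#' Benchmark metric table from comparison counts
#'
#' Implements the printed metric definitions: SNP.Recall_ignoreGT =
#' (SNP.TRUTH.TP + SNP.FP.gt) / SNP.TRUTH.TOTAL; SNP.Recall =
#' SNP.TRUTH.TP / SNP.TRUTH.TOTAL; QV_dip_snp_indel =
#' -10 * log10((SNP.QUERY.FP + INDEL.QUERY.FP) / (Subset.IS_CONF.Size * 2)).
#' Zero false positives yield the infinite-QV sentinel with a flag.
#' Precision/recall/F1 per type are included for round-trip checking.
#'
#' @param counts a \code{benchmark_counts} (see [compare_to_truth()])
#' @return list of metrics (class \code{benchmark_metrics})
#' @export
benchmark_metrics <- function(counts) {
  stopifnot(counts[["Subset.IS_CONF.Size"]] > 0)
  fp <- counts[["SNP.QUERY.FP"]] + counts[["INDEL.QUERY.FP"]]
  qv <- if (fp == 0) Inf else
    -10 * log10(fp / (counts[["Subset.IS_CONF.Size"]] * 2))
  prf <- function(cls) {
    tp <- counts[[paste0(cls, ".TRUTH.TP")]]
    tot <- counts[[paste0(cls, ".TRUTH.TOTAL")]]
    qtot <- counts[[paste0(cls, ".QUERY.TOTAL")]]
    qfp <- counts[[paste0(cls, ".QUERY.FP")]]
    recall <- if (tot > 0) tp / tot else NA_real_
    precision <- if (qtot > 0) (qtot - qfp) / qtot else NA_real_
    f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    list(recall = recall, precision = precision, f1 = f1)
  }
  snp <- prf("SNP"); indel <- prf("INDEL")
  structure(list(
    SNP.Recall = snp$recall,
    SNP.Recall_ignoreGT = if (counts[["SNP.TRUTH.TOTAL"]] > 0)
      (counts[["SNP.TRUTH.TP"]] + counts[["SNP.FP.gt"]]) /
        counts[["SNP.TRUTH.TOTAL"]] else NA_real_,
    INDEL.Recall = indel$recall,
    SNP.Precision = snp$precision, INDEL.Precision = indel$precision,
    SNP.F1 = snp$f1, INDEL.F1 = indel$f1,
    QV_dip_snp_indel = qv, qv_infinite = !is.finite(qv)),
    class = "benchmark_metrics")
}

#' @export
print.benchmark_metrics <- function(x, ...) {
  cat(sprintf("SNP recall %.4f (ignoreGT %.4f), indel recall %.4f\n",
              x$SNP.Recall, x$SNP.Recall_ignoreGT, x$INDEL.Recall))
  cat(sprintf("QV_dip_snp_indel: %s\n",
              if (x$qv_infinite) "inf (no false positives)"
              else sprintf("%.2f", x$QV_dip_snp_indel)))
  invisible(x)
}
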