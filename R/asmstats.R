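# Continuity statistics (all N bases count as gaps), telomere scanning and
# conservative gap patching from donor contigs.

#' Assembly continuity statistics
#'
#' Contigs are maximal N-free runs: any run of one or more N splits a
#' scaffold. NG50 values are computed against the assumed genome size
#' \code{G} (3 Gb for human).
#'
#' @param asm named character vector (or DNAStringSet) of scaffolds
#' @param G assumed genome size in bp
#' @return a \code{continuity_report}: n_scaffolds, n_contigs, total_bp,
#'   total_N, max_scaffold, scaffold_NG50, contig_NG50, gaps_per_scaffold
#' @export
continuity_stats <- function(asm, G = 3e9) {
  asm <- toupper(as_char_seqs(asm))
  if (length(asm) == 0L || all(nchar(asm) == 0L)) stop("empty assembly")
  scaf_len <- nchar(asm)
  contig_runs <- gregexpr("[^N]+", asm)
  contig_lens <- unlist(lapply(contig_runs, function(m)
    if (m[1] == -1) integer(0) else attr(m, "match.length")))
  gaps <- vapply(seq_along(asm), function(i) {
    m <- contig_runs[[i]]
    n_runs <- if (m[1] == -1) 0L else length(m)
    # N-runs = interior separators plus leading/trailing N blocks
    covered <- if (n_runs == 0L) 0L else sum(attr(m, "match.length"))
    n_bp <- scaf_len[i] - covered
    if (n_bp == 0L) return(0L)
    # count maximal N runs directly
    nm <- gregexpr("N+", asm[i])[[1]]
    if (nm[1] == -1) 0L else length(nm)
  }, 0L)
  sng <- ng50(scaf_len, G)
  cng <- ng50(contig_lens, G)
  structure(list(n_scaffolds = length(asm),
                 n_contigs = length(contig_lens),
                 total_bp = sum(as.numeric(scaf_len)),
                 total_N = sum(as.numeric(scaf_len)) - sum(as.numeric(contig_lens)),
                 max_scaffold = max(scaf_len),
                 scaffold_NG50 = as.numeric(sng),
                 contig_NG50 = as.numeric(cng),
                 ng50_short = attr(sng, "short") || attr(cng, "short"),
                 gaps_per_scaffold = gaps, G = G),
            class = "continuity_report")
}

#' @export
print.continuity_report <- function(x, ...) {
  cat(sprintf(paste0("continuity: %d scaffold(s), %d contig(s), %s bp ",
                     "(%s N)\n  scaffold NG50 %s | contig NG50 %s | gaps %d\n"),
              x$n_scaffolds, x$n_contigs,
              format(x$total_bp, big.mark = ","),
              format(x$total_N, big.mark = ","),
              format(x$scaffold_NG50, big.mark = ","),
              format(x$contig_NG50, big.mark = ","),
              sum(x$gaps_per_scaffold)))
  invisible(x)
}

#' Scan contig ends for telomeric repeat
#'
#' An end is called telomeric when the fraction of its terminal window
#' covered by the tandem motif reaches \code{min_frac} (closed threshold).
#' By the strand convention the q end (3') is scanned for the motif itself
#' and the p end (5') for its reverse complement.
#'
#' @param asm named character vector (or DNAStringSet) of contigs
#' @param motif canonical telomere repeat (vertebrate TTAGGG)
#' @param window terminal window in bp
#' @param min_frac minimum covered fraction of the window
#' @return data frame: contig, p_frac, q_frac, p_telomere, q_telomere
#' @export
telomere_scan <- function(asm, motif = "TTAGGG", window = 1000,
                          min_frac = 0.4) {
  asm <- as_char_seqs(asm)
  if (any(nchar(asm) < window)) stop("window exceeds a contig length")
  rc <- rev_comp(motif)
  covered_frac <- function(seqs, pat) {
    vapply(seqs, function(s) {
      m <- Biostrings::matchPattern(pat, Biostrings::DNAString(s))
      if (length(m) == 0L) return(0)
      sum(IRanges::width(IRanges::reduce(as(m, "IRanges")))) / nchar(s)
    }, 0, USE.NAMES = FALSE)
  }
  p_win <- substring(asm, 1, window)
  q_win <- substring(asm, nchar(asm) - window + 1, nchar(asm))
  p_frac <- covered_frac(p_win, rc)
  q_frac <- covered_frac(q_win, motif)
  data.frame(contig = names(asm) %||% paste0("contig", seq_along(asm)),
             p_frac = p_frac, q_frac = q_frac,
             p_telomere = p_frac >= min_frac,
             q_telomere = q_frac >= min_frac,
             stringsAsFactors = FALSE)
}

# Locate one flank in the donor set: exact seed next to the gap, then full
# flank verification within the mismatch budget. Returns a data frame of
# candidate placements (donor, orientation, start/end of the flank match in
# forward donor coordinates, 1-based inclusive).
locate_flank <- function(flank, donors, side, max_mm, seed_len) {
  hits <- list()
  seed <- if (side == "left") substring(flank, nchar(flank) - seed_len + 1,
                                        nchar(flank))
          else substring(flank, 1, seed_len)
  for (d in names(donors)) {
    for (ori in c("+", "-")) {
      dseq <- if (ori == "+") donors[[d]] else rev_comp(donors[[d]])
      at <- gregexpr(seed, dseq, fixed = TRUE)[[1]]
      if (at[1] == -1) next
      for (p in as.integer(at)) {
        # p = 1-based seed start in dseq
        fl_start <- if (side == "left") p + seed_len - nchar(flank) else p
        fl_end <- fl_start + nchar(flank) - 1
        if (fl_start < 1 || fl_end > nchar(dseq)) next
        mm <- str_mismatches(substring(dseq, fl_start, fl_end), flank)
        if (mm <= max_mm)
          hits[[length(hits) + 1L]] <- data.frame(
            donor = d, orientation = ori, start = fl_start, end = fl_end,
            mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else NULL
}

#' Patch scaffold gaps with donor contigs
#'
#' A gap (N-run) is replaced only when a single donor contig aligns to both
#' flanks with at least \code{anchor} bp each, at most
#' \code{max_mismatch_frac} mismatches, consistent orientation and ordering.
#' Ambiguous (multi-donor or multi-placement) support leaves the gap
#' unpatched and logs a conflict.
#'
#' @param scaffolds named character vector of scaffolds containing N-runs
#' @param donors named character vector of gap-free donor contigs
#' @param anchor flank anchor length in bp
#' @param max_mismatch_frac maximum mismatch fraction per flank
#' @param seed_len exact seed length used to locate flanks
#' @return list: \code{assembly} (patched scaffolds), \code{patches} and
#'   \code{conflicts} data frames
#' @export
patch_gaps <- function(scaffolds, donors, anchor = 10000,
                       max_mismatch_frac = 0.01, seed_len = 64L) {
  scaffolds <- as_char_seqs(scaffolds)
  donors <- as_char_seqs(donors)
  if (any(grepl("N", donors, fixed = TRUE))) stop("donor contigs must be gap-free")
  patches <- list(); conflicts <- list()
  out <- scaffolds
  max_mm <- floor(anchor * max_mismatch_frac)
  for (sc in names(out)) {
    repeat {
      gaps <- gregexpr("N+", out[[sc]])[[1]]
      if (gaps[1] == -1) break
      done_any <- FALSE
      glens <- attr(gaps, "match.length")
      for (gi in seq_along(gaps)) {
        g1 <- as.integer(gaps[gi]); glen <- glens[gi]   # 1-based N-run
        if (g1 - anchor < 1 || g1 + glen + anchor - 1 > nchar(out[[sc]])) next
        left <- substring(out[[sc]], g1 - anchor, g1 - 1)
        right <- substring(out[[sc]], g1 + glen, g1 + glen + anchor - 1)
        if (grepl("N", left, fixed = TRUE) || grepl("N", right, fixed = TRUE)) next
        lh <- locate_flank(left, donors, "left", max_mm, seed_len)
        rh <- locate_flank(right, donors, "right", max_mm, seed_len)
        if (is.null(lh) || is.null(rh)) next
        cand <- merge(lh, rh, by = c("donor", "orientation"),
                      suffixes = c("_l", "_r"))
        cand <- cand[cand$end_l < cand$start_r, , drop = FALSE]
        if (nrow(cand) == 0L) next
        fills <- vapply(seq_len(nrow(cand)), function(ci) {
          dseq <- if (cand$orientation[ci] == "+") donors[[cand$donor[ci]]]
                  else rev_comp(donors[[cand$donor[ci]]])
          substring(dseq, cand$end_l[ci] + 1, cand$start_r[ci] - 1)
        }, "")
        # unanimity: multiple placements are acceptable only when they
        # propose the identical fill sequence
        if (length(unique(fills)) > 1L) {
          conflicts[[length(conflicts) + 1L]] <- data.frame(
            scaffold = sc, gap_start = g1 - 1, gap_end = g1 - 1 + glen,
            n_candidates = nrow(cand), stringsAsFactors = FALSE)
          next
        }
        d <- cand$donor[1]
        fill <- fills[1]
        patches[[length(patches) + 1L]] <- data.frame(
          scaffold = sc, gap_start = g1 - 1, gap_end = g1 - 1 + glen,
          donor = d, donor_start = cand$end_l[1], donor_end = cand$start_r[1] - 1,
          orientation = cand$orientation[1], filled_len = nchar(fill),
          stringsAsFactors = FALSE)
        out[[sc]] <- paste0(substring(out[[sc]], 1, g1 - 1), fill,
                            substring(out[[sc]], g1 + glen, nchar(out[[sc]])))
        done_any <- TRUE
        break  # gap coordinates shifted; rescan this scaffold
      }
      if (!done_any) break
    }
  }
  list(assembly = out,
       patches = if (length(patches)) do.call(rbind, patches) else
         data.frame(scaffold = character(0)),
       conflicts = if (length(conflicts)) do.call(rbind, conflicts) else
         data.frame(scaffold = character(0)))
}
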