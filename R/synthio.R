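# Synthetic diploid trio generator. An ancestral sequence (i.i.d. uniform
# ACGT) is mutated independently into the four founder haplotypes (two per
# parent); each child haplotype is a crossover mosaic of one parent's two
# haplotypes, expressed as a selection of mutation events in ancestor
# coordinates. Because every event is recorded, ground truth (haplotype
# origin of reads, phased variants against the ancestor, heterozygous sites
# between the child haplotypes) is exact and re-derivable.

#' Configuration for a synthetic trio
#'
#' @param seed integer; fully determines all generator output
#' @param chrom_lengths chromosome lengths in bp
#' @param snv_rate expected heterozygous SNVs per bp between the two child
#'   haplotypes. Each founder haplotype diverges from the ancestor at half
#'   this rate, so two random haplotypes differ at approximately the full
#'   rate.
#' @param indel_rate per-bp rate of small indels (1-49 bp, geometric lengths
#'   with mean 3)
#' @param sv_rate per-bp rate of structural variants (50 bp or more)
#' @param sv_types SV types to draw from: insertion, deletion, inversion
#' @param sv_max maximum SV length in bp
#' @param recombination crossovers per chromosome per meiosis
#' @param k k-mer size the downstream analyses will use (validation only)
#' @return a \code{trio_config} object
#' @export
trio_config <- function(seed = 1L, chrom_lengths = 1e6, snv_rate = 0.001,
                        indel_rate = 1e-4, sv_rate = 0,
                        sv_types = c("ins", "del", "inv"), sv_max = 5000,
                        recombination = 1L, k = 21L) {
  rates <- c(snv_rate, indel_rate, sv_rate)
  if (any(rates < 0 | rates >= 1)) stop("rates must lie in [0, 1)")
  if (any(chrom_lengths < 10 * k))
    stop("chromosome length < 10*k: too short for k-mer analyses")
  stopifnot(all(sv_types %in% c("ins", "del", "inv")), recombination >= 0)
  structure(list(seed = as.integer(seed),
                 chrom_lengths = as.numeric(chrom_lengths),
                 snv_rate = snv_rate, indel_rate = indel_rate,
                 sv_rate = sv_rate, sv_types = sv_types, sv_max = sv_max,
                 recombination = as.integer(recombination), k = as.integer(k)),
            class = "trio_config")
}

# Draw non-overlapping mutation events for one haplotype of one chromosome,
# in 0-based ancestor coordinates. Event fields:
#   pos  0-based; for ins, the insertion point (before pos)
#   type snv | ins | del | inv
#   len  event length on the ancestor (snv 1, ins 0, del/inv span)
#   alt  replacement sequence (snv alt base, ins inserted bases, else "")
sample_events <- function(L, cfg) {
  margin <- 2L * cfg$k  # keep chromosome ends event-free for k-mer tests
  lo <- margin
  hi <- L - margin
  if (hi <= lo) return(empty_events())
  span <- hi - lo
  draw_pos <- function(n) sort(lo + sample.int(span, n))
  ev <- list()
  n_snv <- rbinom(1L, span, cfg$snv_rate / 2)
  if (n_snv > 0)
    ev$snv <- data.frame(pos = draw_pos(n_snv), type = "snv", len = 1,
                         alt = "", stringsAsFactors = FALSE)
  n_ind <- rbinom(1L, span, cfg$indel_rate / 2)
  if (n_ind > 0) {
    lens <- pmin(rgeom_mean3(n_ind), 49L)
    is_ins <- runif(n_ind) < 0.5
    ev$ind <- data.frame(pos = draw_pos(n_ind),
                         type = ifelse(is_ins, "ins", "del"),
                         len = ifelse(is_ins, 0L, lens), alt = "",
                         stringsAsFactors = FALSE)
    ev$ind$ins_len <- ifelse(is_ins, lens, 0L)
  }
  n_sv <- rbinom(1L, span, cfg$sv_rate / 2)
  if (n_sv > 0) {
    lens <- floor(runif(n_sv, 50, cfg$sv_max + 1))
    types <- sample(cfg$sv_types, n_sv, replace = TRUE)
    ev$sv <- data.frame(pos = draw_pos(n_sv), type = types,
                        len = ifelse(types == "ins", 0L, lens), alt = "",
                        stringsAsFactors = FALSE)
    ev$sv$ins_len <- ifelse(types == "ins", lens, 0L)
  }
  if (length(ev) == 0L) return(empty_events())
  for (nm in names(ev)) if (is.null(ev[[nm]]$ins_len)) ev[[nm]]$ins_len <- 0L
  ev <- do.call(rbind, ev)
  ev <- ev[order(ev$pos), , drop = FALSE]
  # greedy drop of events overlapping the previous kept footprint (+1 bp
  # guard so adjacent indels stay separable after normalization)
  keep <- logical(nrow(ev))
  last_end <- -1
  for (i in seq_len(nrow(ev))) {
    if (ev$pos[i] > last_end) {
      keep[i] <- TRUE
      last_end <- ev$pos[i] + max(ev$len[i], 1L)
    }
  }
  ev <- ev[keep & ev$pos + ev$len <= hi, , drop = FALSE]
  # fill alt sequences now so an event is fully determined at draw time
  n <- nrow(ev)
  if (n) {
    ins_idx <- which(ev$type == "ins")
    if (length(ins_idx))
      ev$alt[ins_idx] <- random_dna(ev$ins_len[ins_idx])
  }
  ev$ins_len <- NULL
  rownames(ev) <- NULL
  ev
}

empty_events <- function() {
  data.frame(pos = numeric(0), type = character(0), len = numeric(0),
             alt = character(0), stringsAsFactors = FALSE)
}

rgeom_mean3 <- function(n) rgeom(n, 1 / 3) + 1L

# SNV alt bases depend on the ancestor, so they are assigned against it.
finalize_snv_alts <- function(ev, anc) {
  idx <- which(ev$type == "snv")
  if (!length(idx)) return(ev)
  refs <- substring(anc, ev$pos[idx] + 1, ev$pos[idx] + 1)
  others <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
  pick <- floor(runif(length(idx)) * 3) + 1
  ev$alt[idx] <- mapply(function(r, p) others[[r]][p], refs, pick)
  ev
}

# Apply events (ancestor coordinates, non-overlapping, sorted) to a sequence.
apply_events <- function(anc, ev) {
  if (nrow(ev) == 0L) return(anc)
  L <- nchar(anc)
  p1 <- ev$pos + 1  # 1-based event start
  consumed <- ev$len
  keep_start <- c(1, p1 + consumed)
  keep_end <- c(p1 - 1, L)
  repl <- character(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    repl[i] <- switch(ev$type[i],
      snv = ev$alt[i],
      ins = ev$alt[i],
      del = "",
      inv = rev_comp(substring(anc, p1[i], p1[i] + ev$len[i] - 1)))
  }
  keeps <- substring(anc, keep_start, keep_end)
  pieces <- character(2L * nrow(ev) + 1L)
  pieces[seq(1, length(pieces), by = 2)] <- keeps
  pieces[seq(2, length(pieces), by = 2)] <- repl
  paste(pieces, collapse = "")
}

# Recombine two parental haplotype event lists into one gamete: crossover
# points are uniform on the chromosome; events are assigned to segments by
# their start position. Returns the selected event data frame.
recombine_events <- function(ev1, ev2, L, n_cross) {
  start_hap <- if (runif(1) < 0.5) 1L else 2L
  cuts <- if (n_cross > 0) sort(runif(n_cross, 0, L)) else numeric(0)
  bounds <- c(0, cuts, L)
  segs <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
  segs$hap <- rep(c(start_hap, 3L - start_hap),
                  length.out = nrow(segs))
  pick <- function(ev, hap_id) {
    s <- segs[segs$hap == hap_id, , drop = FALSE]
    sel <- rep(FALSE, nrow(ev))
    for (i in seq_len(nrow(s)))
      sel <- sel | (ev$pos >= s$start[i] & ev$pos < s$end[i])
    ev[sel, , drop = FALSE]
  }
  out <- rbind(pick(ev1, 1L), pick(ev2, 2L))
  out <- out[order(out$pos), , drop = FALSE]
  # crossovers cannot split an event here (assignment is by start position),
  # but two events from different haplotypes may overlap across a boundary;
  # keep the first of any overlapping pair
  if (nrow(out) > 1L) {
    keep <- logical(nrow(out))
    last_end <- -1
    for (i in seq_len(nrow(out))) {
      if (out$pos[i] > last_end) {
        keep[i] <- TRUE
        last_end <- out$pos[i] + max(out$len[i], 1L)
      }
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Generate a synthetic parent-parent-child trio with ground truth
#'
#' @param config a [trio_config()]
#' @return a \code{trio_truth} object: \code{$sequences} (named list with
#'   father_hap1/2, mother_hap1/2, child_mat, child_pat), \code{$ancestor},
#'   per-haplotype event tables in ancestor coordinates (\code{$events}),
#'   the phased child variant truth against the ancestor
#'   (\code{$child_variants}, 0-based, GT over \code{child_pat|child_mat})
#'   and the count of heterozygous SNV sites between the child haplotypes
#'   (\code{$het_snv_count}).
#' @export
gen_trio <- function(config) {
  stopifnot(inherits(config, "trio_config"))
  with_seed(config$seed, {
    n_chr <- length(config$chrom_lengths)
    chroms <- paste0("chr", seq_len(n_chr))
    ancestor <- setNames(random_dna(config$chrom_lengths), chroms)
    hap_names <- c("father_hap1", "father_hap2", "mother_hap1", "mother_hap2")
    events <- list()
    for (h in hap_names) {
      events[[h]] <- setNames(lapply(seq_len(n_chr), function(ci) {
        ev <- sample_events(config$chrom_lengths[ci], config)
        finalize_snv_alts(ev, ancestor[[ci]])
      }), chroms)
    }
    events$child_pat <- setNames(lapply(seq_len(n_chr), function(ci)
      recombine_events(events$father_hap1[[ci]], events$father_hap2[[ci]],
                       config$chrom_lengths[ci], config$recombination)), chroms)
    events$child_mat <- setNames(lapply(seq_len(n_chr), function(ci)
      recombine_events(events$mother_hap1[[ci]], events$mother_hap2[[ci]],
                       config$chrom_lengths[ci], config$recombination)), chroms)
    seqs <- lapply(events, function(evs)
      setNames(vapply(chroms, function(ch)
        apply_events(ancestor[[ch]], evs[[ch]]), ""), chroms))
    truth <- child_variant_truth(events$child_pat, events$child_mat, chroms)
    het <- truth[truth$gt %in% c("0|1", "1|0", "1|2"), , drop = FALSE]
    structure(list(config = config, ancestor = ancestor,
                   sequences = seqs, events = events,
                   child_variants = truth,
                   het_snv_count = sum(het$class == "SNV")),
              class = "trio_truth")
  })
}

# Merge the two child haplotype event lists into phased variant records
# against the ancestor. GT convention: paternal|maternal.
child_variant_truth <- function(pat_events, mat_events, chroms) {
  out <- list()
  for (ch in chroms) {
    p <- pat_events[[ch]]
    m <- mat_events[[ch]]
    keyify <- function(e) paste(e$pos, e$type, e$len, e$alt, sep = ":")
    pk <- keyify(p); mk <- keyify(m)
    allk <- union(pk, mk)
    if (!length(allk)) next
    src <- rbind(p, m)
    src <- src[!duplicated(keyify(src)), , drop = FALSE]
    src_keys <- keyify(src)
    gt <- paste0(as.integer(src_keys %in% pk), "|",
                 as.integer(src_keys %in% mk))
    # distinct alleles at the same position become a multi-allelic 1|2
    dup_pos <- src$pos[duplicated(src$pos)]
    cls <- ifelse(src$type == "snv", "SNV",
           ifelse(pmax(src$len, nchar(src$alt)) >= 50, "SV", "INDEL"))
    out[[ch]] <- data.frame(chrom = ch, pos = src$pos, type = src$type,
                            len = src$len, alt = src$alt, gt = gt,
                            class = cls, multi = src$pos %in% dup_pos,
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), pos = numeric(0),
                      type = character(0), len = numeric(0),
                      alt = character(0), gt = character(0),
                      class = character(0), multi = logical(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  # multi-allelic sites stay decomposed: one record per distinct allele,
  # genotype 1|0 / 0|1 per carrying haplotype (1|1 when shared)
  rownames(res) <- NULL
  res
}

#' @export
print.trio_truth <- function(x, ...) {
  cat("Synthetic trio:", length(x$ancestor), "chromosome(s),",
      format(sum(nchar(x$ancestor)), big.mark = ","), "bp ancestor\n")
  cat("  child het SNV sites:", x$het_snv_count, "\n")
  cat("  truth variant records:", nrow(x$child_variants), "\n")
  invisible(x)
}

#' Simulate long reads from a haplotype set
#'
#' Emulates a HiFi-like regime: read lengths normal around \code{mean_len},
#' substitution-dominated errors at \code{err_rate}, reads drawn from the
#' supplied haplotypes proportional to length. The truth origin of each read
#' (haplotype, position, strand) is recorded in the read name after the
#' reserved token \code{|origin=}.
#'
#' @param haps named character vector of haplotype sequences; names carrying
#'   \code{mat}/\code{pat} determine the recorded MAT/PAT origin label
#' @param coverage target fold-coverage of the summed haplotype length
#' @param mean_len mean read length (bp)
#' @param err_rate per-base error rate (80\% substitutions, 20\% 1-bp indels)
#' @param seed RNG seed
#' @param sd_len read-length SD (bp)
#' @return a \code{read_set} data frame: id, seq, origin, hap, strand,
#'   start (0-based), length
#' @export
sim_long_reads <- function(haps, coverage, mean_len = 15000, err_rate = 0,
                           seed = 1L, sd_len = mean_len * 0.1) {
  haps <- as_char_seqs(haps)
  stopifnot(coverage > 0, !is.null(names(haps)))
  with_seed(seed, {
    lens_h <- nchar(haps)
    total <- sum(lens_h)
    n <- max(1L, round(total * coverage / mean_len))
    rl <- pmax(100, round(rnorm(n, mean_len, sd_len)))
    src <- sample(seq_along(haps), n, replace = TRUE, prob = lens_h)
    too_long <- rl > lens_h[src]
    if (any(too_long)) {
      warning(sum(too_long), " read(s) truncated to chromosome length")
      rl[too_long] <- lens_h[src][too_long]
    }
    start0 <- floor(runif(n) * (lens_h[src] - rl + 1))
    strand <- ifelse(runif(n) < 0.5, "+", "-")
    seqs <- character(n)
    for (h in seq_along(haps)) {
      idx <- which(src == h)
      if (length(idx))
        seqs[idx] <- substring(haps[h], start0[idx] + 1, start0[idx] + rl[idx])
    }
    neg <- which(strand == "-")
    if (length(neg)) seqs[neg] <- rev_comp(seqs[neg])
    if (err_rate > 0) seqs <- cpp_mutate_seqs(seqs, err_rate, 0.8)
    hap_name <- names(haps)[src]
    origin <- ifelse(grepl("mat", hap_name, ignore.case = TRUE), "MAT",
              ifelse(grepl("pat|father", hap_name, ignore.case = TRUE),
                     "PAT", "UNK"))
    ids <- sprintf("read%06d|origin=%s|%s|%s|%d", seq_len(n), origin,
                   hap_name, strand, start0)
    structure(
      data.frame(id = ids, seq = seqs, origin = origin, hap = hap_name,
                 strand = strand, start = start0, length = nchar(seqs),
                 stringsAsFactors = FALSE),
      class = c("read_set", "data.frame"))
  })
}

#' Simulate optical-map molecules from a haplotype
#'
#' Molecules emulate DLE1-style single-molecule maps: each molecule is a
#' random interval of at least \code{min_len} bp; its labels are the
#' in-silico digestion sites of that interval with Gaussian sizing noise on
#' inter-label distances (SD = \code{sizing_cv} times the distance), labels
#' dropped at \code{fn_rate} and spurious labels added at \code{fp_rate} per
#' true label. Molecules without any label are emitted and flagged.
#'
#' @param haps named character vector of source sequences
#' @param motif recognition motif (IUPAC allowed)
#' @param coverage fold-coverage of the summed sequence length
#' @param min_len minimum molecule length (bp; default 150 kb)
#' @param mean_len mean molecule length (bp)
#' @param sizing_cv coefficient of variation of inter-label sizing noise
#' @param fp_rate expected spurious labels per true label
#' @param fn_rate probability a true label is missed
#' @param seed RNG seed
#' @return a \code{molecule_set}: \code{$molecules} data frame (id, length,
#'   n_labels, origin_hap, origin_start, strand, zero_label flag) and
#'   \code{$labels}, a list of ascending label-position vectors
#' @export
sim_molecules <- function(haps, motif = "CTTAAG", coverage = 1,
                          min_len = 150000, mean_len = 250000,
                          sizing_cv = 0.02, fp_rate = 0.01, fn_rate = 0.05,
                          seed = 1L) {
  haps <- as_char_seqs(haps)
  stopifnot(nchar(motif) >= 4)
  with_seed(seed, {
    site_map <- lapply(haps, function(s) digest_to_map(s, motif)$labels)
    lens_h <- nchar(haps)
    if (any(lens_h < min_len))
      stop("source sequence shorter than min_len")
    n <- max(1L, round(sum(lens_h) * coverage / mean_len))
    src <- sample(seq_along(haps), n, replace = TRUE, prob = lens_h)
    ml <- floor(pmin(min_len + rexp(n, 1 / max(1, mean_len - min_len)),
                     lens_h[src]))
    start0 <- floor(runif(n) * (lens_h[src] - ml + 1))
    strand <- ifelse(runif(n) < 0.5, "+", "-")
    labels <- vector("list", n)
    for (i in seq_len(n)) {
      sites <- site_map[[src[i]]]
      lab <- sites[sites >= start0[i] & sites < start0[i] + ml[i]] - start0[i]
      if (strand[i] == "-") lab <- sort(ml[i] - 1 - lab)
      if (length(lab) && fn_rate > 0) lab <- lab[runif(length(lab)) >= fn_rate]
      if (length(lab) >= 2 && sizing_cv > 0) {
        d <- diff(lab)
        d <- pmax(1, d + rnorm(length(d), 0, sizing_cv * d))
        lab <- lab[1] + c(0, cumsum(d))
      }
      n_fp <- if (fp_rate > 0) rpois(1, fp_rate * max(1, length(lab))) else 0L
      if (n_fp > 0) lab <- c(lab, runif(n_fp, 0, ml[i]))
      lab <- sort(unique(pmin(pmax(lab, 0), ml[i] - 1)))
      labels[[i]] <- lab
    }
    mols <- data.frame(
      id = sprintf("mol%06d", seq_len(n)), length = ml,
      n_labels = vapply(labels, length, 0L),
      origin_hap = names(haps)[src], origin_start = start0, strand = strand,
      stringsAsFactors = FALSE)
    mols$zero_label <- mols$n_labels == 0L
    if (any(mols$zero_label))
      warning(sum(mols$zero_label), " molecule(s) carry no label")
    structure(list(molecules = mols, labels = labels, motif = motif),
              class = "molecule_set")
  })
}

#' Expand degenerate DNA motifs into all concrete sequences
#'
#' @param motifs character vector of motifs over the IUPAC alphabet
#' @return character vector of distinct concrete expansions
#' @examples
#' expand_motif(c("GATC", "GANTC", "CTNAG", "TTAA"))  # 10 cut sites
#' @export
expand_motif <- function(motifs) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  expand_one <- function(m) {
    chars <- strsplit(toupper(m), "")[[1L]]
    if (!all(chars %in% names(iupac)))
      stop("invalid character in motif: ", m)
    opts <- lapply(chars, function(c) iupac[[c]])
    grid <- expand.grid(rev(opts), stringsAsFactors = FALSE)
    apply(grid[, rev(seq_along(opts)), drop = FALSE], 1, paste, collapse = "")
  }
  unique(unlist(lapply(motifs, expand_one), use.names = FALSE))
}

#' Simulate a binned read-depth track with implanted collapses
#'
#' Per-bin depth is Normal(\code{mean_depth}, \code{noise_sd}) multiplied by
#' the copy number of any overlapping \code{collapse_truth} interval;
#' negative draws are clipped to zero.
#'
#' @param asm named character vector of sequences, or a named numeric vector
#'   of sequence lengths
#' @param mean_depth mean depth outside collapsed regions
#' @param collapse_truth data frame (chrom, start, end, copies) or NULL
#' @param bin bin width in bp
#' @param noise_sd per-bin depth SD
#' @param seed RNG seed
#' @return coverage track data frame (chrom, start, end, depth)
#' @export
sim_coverage <- function(asm, mean_depth, collapse_truth = NULL, bin = 1000,
                         noise_sd = 0, seed = 1L) {
  stopifnot(mean_depth > 0)
  lens <- if (is.numeric(asm)) asm else nchar(as_char_seqs(asm))
  stopifnot(!is.null(names(lens)))
  with_seed(seed, {
    out <- lapply(names(lens), function(ch) {
      starts <- seq(0, lens[[ch]] - 1, by = bin)
      ends <- pmin(starts + bin, lens[[ch]])
      depth <- rnorm(length(starts), mean_depth, noise_sd)
      if (!is.null(collapse_truth)) {
        ct <- collapse_truth[collapse_truth$chrom == ch, , drop = FALSE]
        for (i in seq_len(nrow(ct))) {
          hit <- starts < ct$end[i] & ends > ct$start[i]
          depth[hit] <- depth[hit] * ct$copies[i]
        }
      }
      data.frame(chrom = ch, start = starts, end = ends,
                 depth = pmax(depth, 0), stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
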