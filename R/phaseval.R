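# Phasing evaluation: hapmer marker tracks along contigs, phase blocks with
# a short-range switch tolerance, switch-error rates and phase-block NG
# statistics.

#' Hapmer marker track of a contig
#'
#' One marker per hapmer occurrence (canonical match), labeled by parent of
#' origin, positions 0-based and strictly increasing.
#'
#' @param contig single contig sequence (character)
#' @param hapmers a \code{hapmers} object
#' @param name contig name for reporting
#' @return a \code{marker_track} data frame (pos, label MAT/PAT) with
#'   attributes \code{contig}, \code{contig_len} and \code{k}
#' @export
marker_track <- function(contig, hapmers, name = "contig") {
  contig <- as_char_seqs(contig)
  stopifnot(length(contig) == 1L)
  res <- cpp_marker_positions(contig, hapmers$k,
                              hapmers$maternal$key, hapmers$paternal$key)
  structure(
    data.frame(pos = res$pos, label = c("MAT", "PAT")[res$label],
               stringsAsFactors = FALSE),
    contig = name, contig_len = nchar(contig), k = hapmers$k,
    class = c("marker_track", "data.frame"))
}

#' Phase blocks and switch statistics of a marker track
#'
#' Blocks are maximal runs of one majority parental label. A run of
#' opposite-label markers inside a block is tolerated as short-range
#' switching while it spans at most \code{max_switches} markers and
#' \code{within} bp; exceeding either terminates the block at the last
#' same-label marker, and a new block starts at the head of the opposite
#' run. The switch rate is the fraction of adjacent marker pairs with
#' differing labels.
#'
#' @param track a [marker_track()]
#' @param max_switches marker-count tolerance for short-range switches
#' @param within bp tolerance window for short-range switches
#' @return a \code{phase_blocks} object: \code{$blocks} data frame (contig,
#'   start, end, label, n_markers, n_switches_internal), \code{$switch_rate},
#'   \code{$n_adjacent}, \code{$rate_defined}
#' @export
phase_blocks <- function(track, max_switches = 100L, within = 20000) {
  k <- attr(track, "k") %||% 21L
  contig <- attr(track, "contig") %||% "contig"
  n <- nrow(track)
  empty <- data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0), label = character(0),
                      n_markers = integer(0), n_switches_internal = integer(0),
                      stringsAsFactors = FALSE)
  if (n == 0L)
    return(structure(list(blocks = empty, switch_rate = 0,
                          n_adjacent = 0L, rate_defined = FALSE),
                     class = "phase_blocks"))
  pos <- track$pos
  lab <- track$label
  switch_pairs <- if (n >= 2L) sum(lab[-1] != lab[-n]) else 0L
  blocks <- list()
  bstart <- 1L          # index of first marker of current block
  blabel <- lab[1L]
  blast_same <- 1L      # last marker carrying the block label
  bswitch <- 0L         # adjacent differing pairs inside the block
  opp_head <- NA_integer_  # head of the current opposite run
  flush_block <- function(from, to, label, nsw) {
    data.frame(contig = contig, start = pos[from], end = pos[to] + k,
               label = label, n_markers = to - from + 1L,
               n_switches_internal = nsw, stringsAsFactors = FALSE)
  }
  i <- 2L
  while (i <= n) {
    if (lab[i] == blabel) {
      if (!is.na(opp_head)) bswitch <- bswitch + 2L
      opp_head <- NA_integer_
      blast_same <- i
    } else {
      if (is.na(opp_head)) opp_head <- i
      run_len <- i - opp_head + 1L
      run_span <- pos[i] - pos[opp_head]
      if (run_len > max_switches || run_span > within) {
        blocks[[length(blocks) + 1L]] <-
          flush_block(bstart, blast_same, blabel, bswitch)
        bstart <- opp_head
        blabel <- lab[i]
        blast_same <- i
        bswitch <- 0L
        opp_head <- NA_integer_
      }
    }
    i <- i + 1L
  }
  blocks[[length(blocks) + 1L]] <- flush_block(bstart, blast_same, blabel, bswitch)
  structure(list(blocks = do.call(rbind, blocks),
                 switch_rate = if (n >= 2L) switch_pairs / (n - 1L) else 0,
                 n_adjacent = max(0L, n - 1L),
                 rate_defined = n >= 2L),
            class = "phase_blocks")
}

#' @export
print.phase_blocks <- function(x, ...) {
  cat(sprintf("phase blocks: %d block(s), switch rate %.4g%s\n",
              nrow(x$blocks), x$switch_rate,
              if (x$rate_defined) "" else " (undefined: <2 markers)"))
  invisible(x)
}

#' Phase-block NG50 and NG curve
#'
#' @param blocks a \code{phase_blocks} object, its \code{$blocks} data
#'   frame, or a numeric vector of block lengths
#' @param G assumed genome size in bp (the continuity convention is 3 Gb
#'   for human)
#' @return list: \code{ng50}, \code{curve} (data frame cum_bp, length),
#'   \code{short} flag (TRUE when blocks sum to less than G/2, NG50 = 0)
#' @export
block_ng <- function(blocks, G) {
  stopifnot(G > 0)
  lens <- if (is.numeric(blocks)) blocks
          else if (inherits(blocks, "phase_blocks")) blocks$blocks$end - blocks$blocks$start
          else blocks$end - blocks$start
  lens <- sort(as.numeric(lens), decreasing = TRUE)
  v <- ng50(lens, G)
  list(ng50 = as.numeric(v), short = attr(v, "short"),
       curve = data.frame(cum_bp = cumsum(lens), length = lens))
}
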