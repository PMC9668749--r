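# Read-depth based detection of collapsed repeats, the common-repeat content
# filter, and the expandable-sequence estimate.

#' Detect collapsed regions from a coverage track
#'
#' Background mean and SD are computed over non-zero bins after trimming the
#' top and bottom 1 percent (robustness against the collapses themselves and
#' against gaps). Collapsed regions are maximal runs of bins with depth above
#' mean + z*SD, merged across single-bin dips, and at least \code{min_len}
#' bp long.
#'
#' @param track coverage track data frame (chrom, start, end, depth)
#' @param z number of SDs above the mean (default 3)
#' @param min_len minimum region length in bp (default 15 kb)
#' @return a \code{collapse_regions} data frame (chrom, start, end,
#'   mean_depth) with attributes \code{background_mean}, \code{background_sd}
#'   and \code{threshold}
#' @export
detect_collapses <- function(track, z = 3, min_len = 15000) {
  d <- track$depth
  nz <- d[d > 0]
  if (length(nz) == 0L) stop("all-zero coverage track")
  qs <- quantile(nz, c(0.01, 0.99), names = FALSE)
  core <- nz[nz >= qs[1] & nz <= qs[2]]
  if (length(core) < 2L) core <- nz
  mu <- mean(core); sdv <- sd(core)
  if (is.na(sdv)) sdv <- 0
  thr <- mu + z * sdv
  regions <- list()
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, , drop = FALSE]
    hot <- t$depth > thr
    # merge across single-bin dips
    if (length(hot) >= 3L) {
      dip <- which(!hot[-c(1, length(hot))] & hot[-(1:2)] &
                     hot[-c(length(hot) - 1, length(hot))]) + 1L
      hot[dip] <- TRUE
    }
    r <- rle(hot)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    for (j in which(r$values)) {
      s <- t$start[starts_idx[j]]; e <- t$end[ends_idx[j]]
      if (e - s >= min_len)
        regions[[length(regions) + 1L]] <- data.frame(
          chrom = ch, start = s, end = e,
          mean_depth = mean(t$depth[starts_idx[j]:ends_idx[j]]),
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               mean_depth = numeric(0), stringsAsFactors = FALSE)
  structure(out, background_mean = mu, background_sd = sdv, threshold = thr,
            class = c("collapse_regions", "data.frame"))
}

#' Drop collapse calls dominated by common repeats
#'
#' Removes regions whose overlap with the repeat annotation exceeds
#' \code{max_repeat_frac} of their length; the overlap fraction is added to
#' the surviving records.
#'
#' @param regions [detect_collapses()] output (or any chrom/start/end frame)
#' @param repeat_bed repeat annotation data frame (chrom, start, end)
#' @param max_repeat_frac maximum tolerated repeat fraction (default 0.75)
#' @return filtered regions with a \code{repeat_frac} column
#' @export
filter_repeat_collapses <- function(regions, repeat_bed,
                                    max_repeat_frac = 0.75) {
  if (nrow(regions) == 0L) {
    regions$repeat_frac <- numeric(0)
    return(regions)
  }
  frac <- vapply(seq_len(nrow(regions)), function(i) {
    rb <- repeat_bed[repeat_bed$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(rb) == 0L) return(0)
    reg <- IRanges::IRanges(regions$start[i] + 1L, regions$end[i])
    rep_r <- IRanges::reduce(IRanges::IRanges(rb$start + 1L, rb$end))
    ov <- IRanges::intersect(reg, rep_r)
    sum(IRanges::width(ov)) / (regions$end[i] - regions$start[i])
  }, 0)
  regions$repeat_frac <- frac
  regions[frac <= max_repeat_frac, , drop = FALSE]
}

#' Expandable sequence implied by collapsed regions
#'
#' Each collapse contributes its length multiplied by its read depth over
#' the average genome coverage: the amount of sequence the region would
#' occupy had its copies been assembled separately.
#'
#' @param regions collapse regions with a \code{mean_depth} column
#' @param avg_cov average genome-wide coverage
#' @return list: \code{total_bp} and per-region \code{expandable_bp} vector
#' @export
expandable_bp <- function(regions, avg_cov) {
  stopifnot(avg_cov > 0)
  per <- (regions$end - regions$start) * regions$mean_depth / avg_cov
  list(total_bp = sum(per), expandable_bp = per)
}
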