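# Plain-text readers/writers for the formats the toolkit exchanges:
# FASTA/FASTQ (via Biostrings), BED, a minimal phased-VCF subset, coverage
# tracks in BED-graph dialect, and TSV molecule/map files
# (id, length, comma-separated ascending label positions).

#' Read a FASTA file into a named character vector
#' @param path file path
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  as_char_seqs(Biostrings::readDNAStringSet(path))
}

#' Write sequences to FASTA
#' @param seqs named character vector
#' @param path output path
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a read set to FASTQ
#'
#' Read names carry the truth origin after the reserved token
#' \code{|origin=}, so no side file is needed to recover it.
#' @param reads a \code{read_set} (see [sim_long_reads()])
#' @param path output path
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' Read a FASTQ file into a read set
#' @param path file path
#' @return a \code{read_set} data frame (origin parsed from names when present)
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- names(x)
  origin <- rep(NA_character_, length(ids))
  tok <- regmatches(ids, regexpr("\\|origin=[A-Z]+", ids))
  has <- grepl("\\|origin=", ids)
  origin[has] <- sub("\\|origin=", "", tok)
  structure(
    data.frame(id = ids, seq = as.character(x), origin = origin,
               length = Biostrings::width(x), stringsAsFactors = FALSE),
    class = c("read_set", "data.frame"))
}

#' Read a BED file (0-based half-open intervals)
#' @param path file path
#' @return data frame with chrom, start, end and any extra columns
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df
}

#' Write intervals to BED
#' @param df data frame whose first three columns are chrom, start, end
#' @param path output path
#' @export
write_bed <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a minimal phased VCF (CHROM POS REF ALT FILTER GT)
#'
#' Positions are converted from the toolkit's 0-based convention to VCF's
#' 1-based; empty-allele indels are anchored on the preceding base.
#' @param variants variant data frame (chrom, pos, ref, alt, gt, filter)
#' @param genome named character vector of reference sequences (for anchors)
#' @param path output path
#' @export
write_vcf <- function(variants, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE"), con)
  if (nrow(variants)) {
    v <- variants
    v$filter <- if (is.null(v$filter)) "PASS" else v$filter
    for (i in seq_len(nrow(v))) {
      ref <- v$ref[i]; alt <- v$alt[i]; pos1 <- v$pos[i] + 1L
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        # anchor indel on preceding base
        anchor <- substring(genome[[v$chrom[i]]], v$pos[i], v$pos[i])
        ref <- paste0(anchor, ref); alt <- paste0(anchor, alt)
        pos1 <- v$pos[i]  # anchor base position, 1-based
      }
      writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.\tGT\t%s",
                         v$chrom[i], pos1, ref, alt, v$filter[i], v$gt[i]), con)
    }
  }
  invisible(path)
}

#' Write a coverage track as BED-graph
#' @param track coverage track data frame (chrom, start, end, depth)
#' @param path output path
#' @export
write_bedgraph <- function(track, path) {
  write.table(track[, c("chrom", "start", "end", "depth")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED-graph coverage track
#' @param path file path
#' @return coverage track data frame (chrom, start, end, depth)
#' @export
read_bedgraph <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "depth")[seq_len(ncol(df))]
  df
}

#' Write optical molecules or maps to TSV
#'
#' Columns: id, length, comma-separated ascending label positions (bp).
#' A text stand-in for the BNX/CMAP concepts of molecule and consensus map.
#' @param x a \code{molecule_set} or list of \code{optical_map}s
#' @param path output path
#' @export
write_molecules_tsv <- function(x, path) {
  if (inherits(x, "molecule_set")) {
    ids <- x$molecules$id
    lens <- x$molecules$length
    labs <- x$labels
  } else {
    ids <- vapply(x, function(m) m$id, "")
    lens <- vapply(x, function(m) m$length, 0)
    labs <- lapply(x, function(m) m$labels)
  }
  lines <- vapply(seq_along(ids), function(i)
    sprintf("%s\t%.0f\t%s", ids[i], lens[i],
            paste(format(labs[[i]], scientific = FALSE, trim = TRUE),
                  collapse = ",")), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read optical molecules/maps from TSV
#' @param path file path
#' @return list of \code{optical_map} objects
#' @export
read_molecules_tsv <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    labs <- if (length(f) >= 3 && nzchar(f[3]))
      as.numeric(strsplit(f[3], ",", fixed = TRUE)[[1L]]) else numeric(0)
    optical_map(f[1], as.numeric(f[2]), labs)
  })
}

#' Serialize a k-mer set to sorted TSV (kmer, count)
#' @param ks a [kmer_set]
#' @param path output path
#' @export
write_kmer_tsv <- function(ks, path) {
  km <- cpp_decode_kmers(ks$key, ks$k)
  o <- order(km)
  write.table(data.frame(kmer = km[o], count = ks$count[o]), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
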