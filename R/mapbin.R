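# Optical-map trio binning: in-silico digestion, molecule-to-map alignment
# over label coordinates, confidence-based haplotype assignment with equal
# splitting of ties, and the allele-consistency cross-check.

#' Construct an optical map
#' @param id contig id
#' @param length sequence length in bp
#' @param labels ascending 0-based label positions
#' @return an \code{optical_map} object
#' @export
optical_map <- function(id, length, labels) {
  labels <- as.numeric(labels)
  if (length(labels) && (is.unsorted(labels, strictly = TRUE) ||
                         labels[1] < 0 || labels[length(labels)] >= length))
    stop("labels must be strictly increasing within [0, length)")
  structure(list(id = id, length = as.numeric(length), labels = labels),
            class = "optical_map")
}

#' @export
print.optical_map <- function(x, ...) {
  cat(sprintf("optical_map %s: %s bp, %d label(s)\n", x$id,
              format(x$length, big.mark = ","), length(x$labels)))
  invisible(x)
}

#' In-silico digestion of a sequence into an optical map
#'
#' Labels at every motif occurrence on either strand, collapsed to the
#' 0-based site start on the forward strand. IUPAC codes in the motif are
#' honored.
#'
#' @param seq single sequence (character or DNAString)
#' @param motif recognition motif
#' @param id map id
#' @return an [optical_map()]
#' @export
digest_to_map <- function(seq, motif, id = "map") {
  s <- Biostrings::DNAString(as_char_seqs(seq)[[1]])
  pos <- Biostrings::start(Biostrings::matchPattern(motif, s, fixed = FALSE))
  rc <- rev_comp(motif)
  if (rc != toupper(motif))
    pos <- c(pos, Biostrings::start(Biostrings::matchPattern(rc, s, fixed = FALSE)))
  optical_map(id, length(s), sort(unique(pos)) - 1)
}

#' Align an optical molecule to assembly maps
#'
#' Dynamic programming over label-interval matching: consecutive interval
#' runs match when their summed lengths agree within \code{sizing_tol}
#' (relative to the map side); the score is the number of matched labels
#' minus \code{miss_penalty} per skipped label. Both orientations and all
#' target maps are searched; confidence is the score over the molecule
#' label count, clamped to [0, 1].
#'
#' @param mol numeric vector of molecule label positions, or one row of a
#'   \code{molecule_set} via \code{mol_labels}
#' @param maps an [optical_map()] or list of them
#' @param mol_len molecule length in bp (for orientation flips); defaults to
#'   just past the last label
#' @param sizing_tol relative sizing tolerance (default 0.1)
#' @param miss_penalty score penalty per skipped label
#' @param min_labels minimum labels required to attempt alignment
#' @param max_skip maximum consecutive skipped labels on either side
#' @param min_conf alignments below this confidence are discarded
#' @return a \code{map_alignment} (target, orientation, offset, score,
#'   n_matched, confidence) or NULL when unalignable
#' @export
align_molecule <- function(mol, maps, mol_len = NULL, sizing_tol = 0.1,
                           miss_penalty = 0.3, min_labels = 9L,
                           max_skip = 5L, min_conf = 0.25) {
  if (inherits(maps, "optical_map")) maps <- list(maps)
  mol <- as.numeric(mol)
  if (length(mol) < min_labels) return(NULL)
  mol_len <- mol_len %||% (mol[length(mol)] + 1)
  best <- NULL
  for (m in maps) {
    for (ori in c("+", "-")) {
      lab <- if (ori == "+") mol else sort(mol_len - 1 - mol)
      res <- cpp_map_align(lab, m$labels, sizing_tol, miss_penalty, max_skip)
      if (!is.finite(res$score)) next
      conf <- min(1, max(0, res$score / length(mol)))
      if (is.null(best) || res$score > best$score) {
        i1 <- res$mol_idx[1]; j1 <- res$map_idx[1]
        best <- structure(list(target = m$id, orientation = ori,
                               offset = m$labels[j1] - lab[i1],
                               score = res$score, n_matched = res$n_matched,
                               confidence = conf,
                               mol_idx = res$mol_idx, map_idx = res$map_idx),
                          class = "map_alignment")
      }
    }
  }
  if (is.null(best) || best$confidence < min_conf) return(NULL)
  best
}

#' Bin optical molecules into parental haplotypes
#'
#' Each molecule is aligned to the father and the mother assembly maps and
#' assigned to the bin with higher alignment confidence. Molecules aligning
#' equally well (confidence difference at most \code{tie_eps}) and molecules
#' aligning to neither parent are split into two equal clusters
#' (deterministically under \code{seed}).
#'
#' @param mols a \code{molecule_set} (see [sim_molecules()])
#' @param father_maps,mother_maps [optical_map()] lists for the parents
#' @param tie_eps confidence-difference threshold for ties (default 1e-2)
#' @param seed RNG seed for the equal split
#' @param ... passed to [align_molecule()]
#' @return a \code{mapbin_result}: \code{$report} data frame (id, conf_father,
#'   conf_mother, bin, reason), \code{$paternal}, \code{$maternal} id vectors
#' @export
bin_molecules <- function(mols, father_maps, mother_maps, tie_eps = 1e-2,
                          seed = 1L, ...) {
  n <- nrow(mols$molecules)
  conf_f <- conf_m <- numeric(n)
  for (i in seq_len(n)) {
    af <- align_molecule(mols$labels[[i]], father_maps,
                         mol_len = mols$molecules$length[i], ...)
    am <- align_molecule(mols$labels[[i]], mother_maps,
                         mol_len = mols$molecules$length[i], ...)
    conf_f[i] <- if (is.null(af)) NA_real_ else af$confidence
    conf_m[i] <- if (is.null(am)) NA_real_ else am$confidence
  }
  bin <- rep(NA_character_, n)
  reason <- rep("assigned", n)
  unaligned <- is.na(conf_f) & is.na(conf_m)
  cf <- ifelse(is.na(conf_f), -Inf, conf_f)
  cm <- ifelse(is.na(conf_m), -Inf, conf_m)
  tie <- !unaligned & abs(cf - cm) <= tie_eps
  bin[!unaligned & !tie & cf > cm] <- "paternal"
  bin[!unaligned & !tie & cm > cf] <- "maternal"
  reason[tie] <- "tie"
  reason[unaligned] <- "unaligned"
  to_split <- which(is.na(bin))
  if (length(to_split)) {
    halves <- split_unknowns(to_split, seed)
    bin[halves$bin1] <- "paternal"
    bin[halves$bin2] <- "maternal"
  }
  report <- data.frame(id = mols$molecules$id, conf_father = conf_f,
                       conf_mother = conf_m, bin = bin, reason = reason,
                       stringsAsFactors = FALSE)
  structure(list(report = report,
                 paternal = report$id[report$bin == "paternal"],
                 maternal = report$id[report$bin == "maternal"]),
            class = "mapbin_result")
}

#' @export
print.mapbin_result <- function(x, ...) {
  t <- table(x$report$reason)
  cat(sprintf("molecule binning: %d paternal / %d maternal (%d tie, %d unaligned, split equally)\n",
              length(x$paternal), length(x$maternal),
              if ("tie" %in% names(t)) t[["tie"]] else 0L,
              if ("unaligned" %in% names(t)) t[["unaligned"]] else 0L))
  invisible(x)
}

# Interval signature of window w (1-based label-block index).
window_signature <- function(map, w, labels_per_window) {
  i0 <- (w - 1L) * labels_per_window + 1L
  i1 <- min(i0 + labels_per_window - 1L, length(map$labels))
  if (i1 - i0 + 1L < 2L) return(NULL)
  diff(map$labels[i0:i1])
}

same_allele <- function(a, b, sizing_tol) {
  if (is.null(a) || is.null(b) || length(a) != length(b)) return(FALSE)
  all(abs(a - b) <= sizing_tol * pmax(a, b))
}

#' Allele cross-check of trio-binned optical maps
#'
#' Scans homologous maps in windows of \code{labels_per_window} labels. At a
#' reportable locus exactly one parent is heterozygous (its two haplotype
#' maps carry distinct label-interval alleles A and B) while the homozygous
#' parent shares allele A. The child haplotype inherited from the
#' heterozygous parent must then carry B whenever B is present in the child;
#' if it instead carries A while the other child haplotype carries B, the
#' allele was mis-binned and the het-parent child map is broken at the locus
#' midpoint.
#'
#' All six maps must be digested with the same motif and colinear (equal
#' label counts up to the compared prefix); the windowed label-index
#' formalization is this package's reconstruction of the consistency check.
#'
#' @param child_maps list with \code{mat} and \code{pat} [optical_map()]s
#' @param father_maps,mother_maps lists of the two haplotype maps per parent
#' @param labels_per_window labels per locus window (default 10)
#' @param sizing_tol relative interval tolerance for allele identity
#' @return list: \code{loci} data frame (window, start, end, het_parent,
#'   verdict), \code{breaks} subset with verdict "break", and
#'   \code{child_maps_broken} with the broken maps
#' @export
cross_check <- function(child_maps, father_maps, mother_maps,
                        labels_per_window = 10L, sizing_tol = 0.1) {
  all_maps <- c(father_maps, mother_maps, child_maps)
  n_lab <- min(vapply(all_maps, function(m) length(m$labels), 0L))
  n_win <- n_lab %/% labels_per_window
  loci <- list()
  breaks_at <- list(mat = numeric(0), pat = numeric(0))
  for (w in seq_len(n_win)) {
    sig <- lapply(all_maps, window_signature, w = w,
                  labels_per_window = labels_per_window)
    names(sig) <- c("f1", "f2", "m1", "m2", names(child_maps))
    f_hom <- same_allele(sig$f1, sig$f2, sizing_tol)
    m_hom <- same_allele(sig$m1, sig$m2, sizing_tol)
    if (f_hom == m_hom) next                     # zero or two hets: no signal
    if (f_hom) {
      hom_allele <- sig$f1
      het_pair <- list(sig$m1, sig$m2)
      het_parent <- "mother"; child_het <- "mat"; child_other <- "pat"
    } else {
      hom_allele <- sig$m1
      het_pair <- list(sig$f1, sig$f2)
      het_parent <- "father"; child_het <- "pat"; child_other <- "mat"
    }
    shares <- vapply(het_pair, same_allele, TRUE, b = hom_allele,
                     sizing_tol = sizing_tol)
    if (sum(shares) != 1L) next                  # need a shared allele A and a distinct B
    allele_a <- hom_allele
    allele_b <- het_pair[[which(!shares)]]
    ch_het <- sig[[child_het]]
    ch_other <- sig[[child_other]]
    verdict <- "consistent"
    if (same_allele(ch_het, allele_a, sizing_tol) &&
        same_allele(ch_other, allele_b, sizing_tol)) {
      verdict <- "break"
      i0 <- (w - 1L) * labels_per_window + 1L
      i1 <- i0 + labels_per_window - 1L
      lab <- child_maps[[child_het]]$labels
      breaks_at[[child_het]] <- c(breaks_at[[child_het]],
                                  (lab[i0] + lab[min(i1, length(lab))]) / 2)
    }
    i0 <- (w - 1L) * labels_per_window + 1L
    lab <- child_maps[[child_het]]$labels
    loci[[length(loci) + 1L]] <- data.frame(
      window = w, start = lab[i0],
      end = lab[min(i0 + labels_per_window - 1L, length(lab))],
      het_parent = het_parent, verdict = verdict, stringsAsFactors = FALSE)
  }
  loci <- if (length(loci)) do.call(rbind, loci) else
    data.frame(window = integer(0), start = numeric(0), end = numeric(0),
               het_parent = character(0), verdict = character(0))
  broken <- child_maps
  for (h in names(breaks_at)) {
    cuts <- sort(breaks_at[[h]])
    if (!length(cuts)) next
    m <- child_maps[[h]]
    bounds <- c(0, cuts, m$length)
    pieces <- list()
    for (i in seq_len(length(bounds) - 1L)) {
      sel <- m$labels >= bounds[i] & m$labels < bounds[i + 1L]
      pieces[[i]] <- optical_map(paste0(m$id, "_part", i),
                                 bounds[i + 1L] - bounds[i],
                                 m$labels[sel] - bounds[i])
    }
    broken[[h]] <- pieces
  }
  list(loci = loci,
       breaks = loci[loci$verdict == "break", , drop = FALSE],
       child_maps_broken = broken)
}
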