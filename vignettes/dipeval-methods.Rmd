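---
title: "Evaluating trio-phased diploid assemblies with dipeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating trio-phased diploid assemblies with dipeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipeval)
```

## The problem

A diploid genome assembly represents the two parental haplotypes of an
individual as two separate sequence sets. Evaluating such an assembly asks
several distinct questions: how accurate is the consensus (base-level
quality), how complete is it, how cleanly are the haplotypes separated
(phasing), how contiguous is it, where has it collapsed repeats into too few
copies, and how faithfully does it represent the individual's variation
against a reference. When parental sequencing data exist, k-mers carried by
exactly one parent and inherited by the child — *hapmers* — provide
haplotype-of-origin markers that make phasing directly measurable, and they
also drive trio binning: partitioning child reads, linked read pairs and
optical-map molecules into maternal and paternal sets before or after
assembly.

dipeval implements this evaluation suite end to end on desk-scale data,
together with a synthetic diploid-trio generator whose complete ground truth
makes every metric testable without any external download.

## The synthetic trio and what it does (and does not) emulate

`gen_trio()` draws an ancestral sequence i.i.d. uniform over ACGT, mutates
it independently into the four founder haplotypes (two per parent), and
builds each child haplotype as a crossover mosaic of one parent's pair
(default one crossover per chromosome, uniform position). Every mutation
event is recorded in ancestor coordinates, so the phased variant truth, the
haplotype of origin of every simulated read and molecule, and the
heterozygous-site count between the child haplotypes are exact and
re-derivable by brute force — the test suite does exactly that.

Parameter conventions:

* `snv_rate` is the expected heterozygous SNV density **between the child
  haplotypes**; each founder haplotype diverges from the ancestor at half
  that rate. The default 0.001 (0.1%) is the SNV heterozygosity scale of a
  human genome; the headline multi-percent total-bp diversity of real
  haplotype pairs is dominated by centromeric structural variation, which an
  i.i.d. ancestor deliberately does not model.
* Small indels use geometric lengths (mean 3 bp, capped at 49 bp);
  structural variants are uniform on 50 bp to `sv_max`, exercising the
  50-bp boundary that separates small indels from SVs everywhere in the
  toolkit.
* Long reads emulate a HiFi-like regime: normal lengths around 15 kb and a
  low, substitution-dominated error rate (80% substitutions, 20% 1-bp
  indels). No base-caller-specific error profile is modeled.
* Optical molecules emulate direct-label chemistry: molecules of at least
  150 kb, labels at motif digestion sites with Gaussian sizing noise
  proportional to inter-label distance, dropped labels (molecule side) and
  spurious labels.
* Coverage tracks are Normal per bin around the target depth, multiplied by
  copy number inside implanted collapse intervals.

Because the ancestor is i.i.d. uniform, k-mers are almost surely unique at
the scales used, GC skew and repeat families are absent, and alignment is
unambiguous. Passing tests therefore demonstrate the correctness of the
computations, not robustness to repeat-rich real genomes — the one caveat
that matters when transferring conclusions to real data.

## K-mer metrics

All k-mer work uses canonical k-mers (the lexicographic minimum of a k-mer
and its reverse complement) with exact counts; k defaults to 21 and k-mers
containing N are skipped. Exactness is a requirement, not an optimization
target: the tests compare against a naive sliding-window oracle.

* **QV.** With `k_err` of `k_total` assembly k-mer instances unsupported by
  the read set, the per-base error probability is
  `E = 1 - (1 - k_err/k_total)^(1/k)` and `QV = -10*log10(E)`. One
  substitution in a megabase damages 21 k-mers and lands at QV 60 — about
  one error per megabase. A fully supported assembly reports an explicit
  infinite flag with an `Inf` sentinel rather than a fabricated number.
* **Completeness.** The fraction of reliable read k-mers (count at least
  `reliable_min`, default 2 to exclude singleton sequencing-error k-mers)
  present in the assembly.
* **Hapmers.** Maternal hapmers are maternal-read k-mers absent from the
  paternal set and inherited by the child, with the same reliability floor
  on both sides. For error-free genome-derived sets (as in the synthetic
  benchmarks) every count is 1 and `reliable_min = 1` is the correct
  setting.
* **False duplication.** Assembly k-mers whose copy number exceeds
  `round(read_count / haploid_peak)` contribute their excess instances as
  duplicated bp, reported as a percentage of assembly bp. The instance-based
  accounting (rather than distinct k-mers) is a documented choice. The
  haploid peak can be estimated as the spectrum mode, but on strongly
  homozygous diploids the mode sits at the two-copy peak — pass the known
  peak when you have it.

## Trio binning and phasing evaluation

`bin_long_reads()` assigns a read maternal when it carries at least
`min_hits` maternal hapmer instances and strictly more maternal than
paternal instances (paternal symmetric); exact ties go to UNKNOWN, never to
an arbitrary side, and `split_unknowns()` later divides them into two equal
seeded halves, preserving auditability. `min_hits` defaults to 2 because
singleton hits are error-prone; the upstream splitters pass an undocumented
per-parent threshold, so the knob is exposed. Hit counts are not normalized
by hapmer set size (a documented simplification; parental coverage
asymmetry is not modeled). Linked read pairs are filtered by the simpler
published rule: a pair is dropped when either mate contains any k-mer from
the other haplotype's hapmer set.

`marker_track()` places one marker per hapmer occurrence along a contig;
`phase_blocks()` forms maximal single-label runs, tolerating opposite-label
runs of at most 100 markers spanning at most 20 kb (the upstream
convention; the source publications print no tolerance, so both knobs are
exposed and results at other settings are not bit-comparable). The switch
rate is the fraction of adjacent marker pairs with differing labels. Phase
block NG50 uses the standard NG definition against an assumed genome size
(3 Gb for human); block extents run between their terminal markers, so
unmarked terminal sequence does not inflate block lengths.

## Continuity, telomeres, gap patching

Contigs are maximal N-free runs — every N base counts as gap. The telomere
scan calls an end telomeric when the tandem canonical repeat (TTAGGG;
reverse complement at the 5' end) covers at least `min_frac = 0.4` of the
terminal 1-kb window, a closed threshold; window and threshold are
configurable because no printed values exist. Gap patching is deliberately
conservative: a gap is filled only when donor flank matches of at least
`anchor` bp (default 10 kb, at most 1% mismatches, exact seed plus
verification) exist on both sides in a consistent orientation and order,
and all candidate placements propose the identical fill; disagreeing
candidates leave the gap unpatched with a logged conflict.

## Collapse detection

Collapsed repeats appear as excess read depth: regions of bins above
`mean + 3*SD`, at least 15 kb long. Background mean and SD are computed
over non-zero bins after trimming the top and bottom 1% — robust to both
gaps and the collapses themselves. Super-threshold runs are merged across
single-bin dips (whether the original analyses merged nearby runs is
unstated; this is the documented choice), the bin defaults to 1 kb (also
unprinted), and regions more than 75% covered by a supplied common-repeat
annotation can be filtered out. Expandable sequence is
`length * depth / average coverage` per region — the amount of sequence the
collapse would occupy if correctly expanded.

## Optical-map binning and cross-checking

Molecule-to-map alignment is dynamic programming over label intervals: two
interval runs match when their summed lengths agree within `sizing_tol`
(default 0.1, relative to the map side); the score is matched labels minus
a penalty (default 0.3) per skipped label, maximized over both orientations
and all target maps. Confidence is the score over the molecule's label
count, clamped to [0, 1] — a documented, monotone stand-in for the
proprietary aligner's confidence, which is not published. Molecules with
fewer than 9 labels are unalignable (a typical molecule filter). Binning
assigns each child molecule to the parent with higher confidence; molecules
within `tie_eps = 1e-2` of equal confidence, and molecules aligning to
neither parent, are split into two equal seeded clusters.

The allele cross-check scans colinear maps in windows of 10 labels. A locus
is reportable when exactly one parent is heterozygous (its two haplotype
maps carry distinct interval signatures A and B — differing label count or
any interval beyond `sizing_tol`) and the homozygous parent shares allele
A. If the child haplotype inherited from the heterozygous parent carries A
while the other child haplotype carries B, the B allele was mis-binned and
the map is broken at the locus midpoint. The label-index windowing assumes
colinear maps with equal label counts (interval-changing, label-preserving
SVs); it is this package's reconstruction of an unpublished consistency
check, and real pipelines anchor loci by alignment instead.

## Variant benchmarking

`align_haplotype()` chains k-mers unique to both contig and reference into
a colinear anchor set (longest increasing subsequence, forward-strand
verified) and closes inter-anchor segments with affine-gap dynamic
programming (match +1, mismatch -4, gap open -6, extend -1; segments beyond
the cell guard become block replacements). Variants are decomposed and
left-aligned with parsimony — the standard VCF normalization — and phased
with haplotype 1 (paternal by convention, configurable by argument order)
in the first genotype field. Sites covered by exactly one haplotype
alignment receive the GAP2 filter with the genotype promoted from a half
call to homozygous (1|. to 1|1), mirroring assembly-based calling in
homozygous regions with a missing alternate contig. Comparison to truth is
exact on normalized alleles: a genotype-correct allele match is TP, an
allele match with wrong genotype counts in FP.gt, and the metric table
implements the printed definitions, including
`Recall_ignoreGT = (TP + FP.gt)/TOTAL` and
`QV_dip = -10*log10((SNP.FP + INDEL.FP)/(2*confident bp))`. The
haplotype-graph matching of full benchmarking engines (equivalent complex
representations, FP.al leniency) is out of scope; exact normalized matching
is sufficient for the synthetic round trips, where error-free calling must
— and does — reproduce the truth set with F1 = 1.

## Haplotype diversity

`hap_vs_hap()` aligns one haploid assembly against the other (mutual-best
contig pairing) and collapses alignment differences into blocks: pure
substitution blocks decompose into SNVs, one-sided blocks are insertions or
deletions classified at the 50-bp boundary, and two-sided replacements
whose sides are reverse complements (at 90% identity or better) are
inversions. Match runs shorter than 25 bp do not close a block — chance
micro-matches inside dissimilar replaced regions would otherwise shatter
them. Features that are more than half gap (N) are excluded.
`het_summary()` reports heterozygous bp (SNV = 1 bp, indels = length
change, inversions = span) as a percentage of a caller-supplied genome
size, optionally after excluding regions (e.g. centromeres); because the
natural denominator is ambiguous (assembly bp vs aligned bp), the aligned-bp
percentage is reported alongside whenever available. Coding SNVs are
classified by codon translation on the annotated strand; per-gene rollups
count genes whose coding SNVs are exclusively non-synonymous; percentages
are reported to one decimal. Heteroplasmy calling reports minor alleles
strictly above a 1% frequency floor (the read-error rate), with per-strand
counts and integer-rounded percentages; frequencies use all counted bases
at the site, which is why a published 97%/2% pair need not sum to 100%.

## Numerical and scale choices

All coordinates are 0-based half-open. Every generator is a pure function
of its configuration and seed: functions seed a local RNG and restore the
caller's state. K-mer keys are 2-bit packed 64-bit integers carried
opaquely through R; set algebra happens on sorted keys in compiled code.
The shipped tests run the full pipeline at reduced scale — a 5-Mb
chromosome with 30-fold read coverage for the trio-binning benchmark,
50-400 kb sequences elsewhere — sizes chosen so that exact oracles
(exhaustive diffs, naive counting, per-base interval arithmetic) remain
feasible while preserving each method's operating regime.

## Known limitations

* The synthetic genome has no repeat structure; k-mer uniqueness and
  alignment unambiguity are optimistic relative to real assemblies.
* The anchored aligner is for desk-scale, mostly colinear sequences; it is
  not a replacement for a production long-sequence aligner.
* Optical-map cross-checking assumes label-count-preserving alleles;
  label-gain/loss alleles reduce its sensitivity.
* Variant comparison is exact-match after normalization; complex
  overlapping representations that a haplotype-graph engine would reconcile
  are counted as FP/FN.
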