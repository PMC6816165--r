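---
title: "Reference-guided scaffolding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided scaffolding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A long-read draft assembly of a eukaryotic genome typically arrives as
hundreds to thousands of contigs. When a chromosome-scale reference of the
same or a closely related species exists, its large-scale structure can be
used the way a genetic map would be: contigs are aligned to the reference
and then *clustered* to chromosomes, *ordered* along them, and *oriented*,
yielding chromosome-length pseudomolecules. refscaf implements this method
around whole-genome alignments in PAF format (produced internally with
minimap2, k-mer and window size 19, or supplied precomputed), together
with the surrounding machinery a real scaffolding run needs: confidence
scores, chimeric-contig correction, assembly-based structural-variant
(SV) calling, multi-sample SV merging, and a simulation benchmark.

The guiding principle is that scaffolding must never edit the assembly:
contigs are only arranged (and optionally split at putative misassembly
junctions), with fixed-size N padding between them. Every output base is
an input base, up to reverse complement.

## The core method

After dropping alignments shorter than `min_aln_len` (default 1 kbp,
measured on the PAF alignment block length):

1. **Clustering.** Each contig is assigned to the reference chromosome it
   *covers* the most, where coverage is the size of the union of the
   reference intervals hit by at least one alignment. The *clustering
   confidence* is covered bp on the assigned chromosome divided by the
   total covered bp in the whole reference, so the per-chromosome
   fractions of a contig sum to one. Contigs with no alignments, with
   confidence below `min_cluster_confidence` (default 0.2), or explicitly
   skipped are pooled in the unlocalized group `Chr0`.
2. **Ordering.** Within a chromosome group, each contig is anchored by
   its *primary* alignment — the longest one to the assigned chromosome —
   and contigs are sorted by that alignment's reference start, then end.
   The *location confidence* is the covered fraction of the reference
   range spanned by the contig's alignments to its chromosome: a contig
   whose alignments are scattered across a wide, sparsely covered range
   scores low.
3. **Orienting.** Every alignment to the assigned chromosome casts a
   vote, weighted by its block length, for its strand; the majority wins
   and the *orientation confidence* is the winning vote share.

Pseudomolecules are the ordered, oriented contigs concatenated with
`pad_size` N characters between neighbours (default 100 bp; zero for the
simulation benchmark, where the partition is exact). Output names are
`<chromosome>_pseudomolecule`; placements are serialized as AGP v2.1 —
the only place where coordinates become 1-based inclusive, everything
internal being 0-based half-open like PAF and BED.

### Numerical choices and tie-breaks

The method is deterministic: identical inputs give byte-identical
outputs. Where the formulation leaves ties open we fix them explicitly:
chromosome-assignment ties go to the lexicographically smallest reference
id, ordering ties to the smaller contig id, orientation ties to `+`.
"Longest alignment" always means the PAF block length (column 11), which
is strand-neutral and dialect-stable, rather than the query or reference
span. A contig with a single short alignment has location confidence 1.0
by the formula; we accept this formula-faithful behaviour rather than
special-casing it. Clustering confidence is computed from the same
post-length-filter alignment set as its numerator, and location
confidence from all post-filter alignments (not only unique anchors);
both are defensible readings and these were fixed once.

## Chimeric-contig correction

Assemblies sometimes join sequence from two chromosomes
(interchromosomal chimera) or from distant loci of one chromosome
(intrachromosomal). An optional pre-pass detects both from discordant
alignments. Alignments under 10 kbp are removed and the rest
unique-anchor filtered at 10 kbp: alignments are visited longest first
and kept only if they contribute at least the threshold of novel query
bp. A contig is interchromosomally chimeric when at least two
chromosomes each hold at least 5% of its total alignment length *and*
at least 100 kbp of covered span; the break goes where the
query-sorted alignments first transition between qualifying chromosomes,
at the end of the earlier alignment (the transition is explicit there,
so no midpoint guessing is needed). Intrachromosomal detection sorts the
dominant chromosome's alignments by reference position and breaks at the
midpoint of the unaligned query interval between the first consecutive
pair whose reference gap or absolute query gap exceeds the distance
thresholds — neither flank is preferred, hence the midpoint. The
defaults for those thresholds are 2 Mbp: deliberately large, so that
ordinary structural variants are not mistaken for misassemblies;
correction should only run when large structural differences are more
plausibly assembly errors than biology.

Breaking conserves sequence exactly: fragments
`<id>_chimera_broken:<start>-<end>` concatenate back to the original
contig. At most one break of each kind happens per contig per round, so
nested chimeras need additional rounds with realignment in between.
Gene loci supplied as GFF3 intervals are *protected*: a breakpoint
falling inside one suppresses the break entirely (rather than shifting
it, which could silently split a neighbouring feature). As a
diagnostic, the mean clustering confidence can be compared before and
after correction — alignments should become less ambiguous, never more.

## Structural variants

After scaffolding, the pseudomolecules are realigned to the reference
and SVs of 20 bp–100 kbp are read off in two ways. *Within-alignment*
calls take insertion/deletion operations directly from the base-level
alignment (the `cg:Z` CIGAR tag); on minus-strand alignments query
coordinates walk backwards from the alignment's query end.
*Between-alignment* calls consider consecutive unique-anchored
alignments of one query on the same chromosome and strand: the
discrepancy between the query-side and (strand-adjusted) reference-side
gap is the variant size, and the sign pattern of the two gaps classifies
it — insertion/deletion when neither side overlaps, tandem
expansion/contraction when exactly one does, repeat
expansion/contraction when both do. The classification is total: every
in-range gap pair maps to exactly one type.

Because alignments may traverse sequencing gaps, each variant is
annotated with the fraction of its span overlapping N-runs — the
reference span for deletions and contractions, the query span for
insertions and expansions (the span where the affected sequence
actually lives) — and variants above 10% gap overlap can be excluded.

Merging across samples links variants of the same type, chromosome, and
(optionally) strand whose start and end breakpoints both lie within
1 kbp, without any size-similarity requirement; merged variants are the
connected components of this relation, verified in the tests against a
brute-force component oracle. A minimum support of 1 gives the union of
call sets, support equal to the sample count their intersection. The
representative coordinates are those of the largest member (a simple,
deterministic choice). Presence/absence of each merged variant per
sample feeds pan-genome analyses, and per-gene counts intersect variant
spans with gene intervals extended by 2 kbp flanks, reported raw and
normalized by gene length.

## The simulation benchmark

The generator partitions any reference into scaffolds whose lengths are
drawn from an empirical length distribution — in practice the observed
contig lengths of a real long-read assembly; when no empirical sample
is supplied, a log-normal with median 100 kbp (sdlog 1) stands in at
desk scale. Scaffolds more than 50% N are dropped, half of the rest is
randomly reverse complemented, and the output order is shuffled; the
truth table records chromosome, order, orientation, and source interval
of every kept scaffold. Contigs are derived by splitting at N-runs of
20 bp or more, discarding the gap sequence and any piece under 10 kbp
(such pieces leave the truth denominator as well — they are removed
from the simulated assembly, not merely ignored).

The "hard" variant adds variation before splitting: indel events
(20 bp–10 kbp, insertions and deletions equally likely, positions
uniform over non-N bases, events non-overlapping so the log is
invertible) and SNPs at 1% per non-N base. The canonical event count is
10,000 on a ~762 Mbp scaffold set; smaller genomes scale the count by
length so the per-bp event rate is preserved. The mutation log doubles
as ground truth for the SV caller, which closes the loop: planted
indels must be recovered with matching type and size.

Scoring follows four metrics. Clustering and orientation accuracy are
the fractions of localized contigs with the correct chromosome and
orientation. Ordering is scored per chromosome by the token edit
distance between true and predicted contig order, normalized by the
true contig count (capped at 2, since spurious extra pieces can push
the raw distance past the truth length), and by the fraction of correct
*directed* adjacent pairs — directedness penalizes local order
inversions, consistent with the edit-distance companion. Localization
is reported over contigs and over bases. A truth orientation is the
extraction orientation: predicting `-` for a forward-extracted piece is
wrong even if the position is right.

### What the synthetic benchmark does and does not show

Test genomes are uniform random sequence: alignment is unambiguous, so
near-perfect scores demonstrate the correctness of the bookkeeping
(coordinates, strand handling, ordering, conservation), not robustness
to repeats, segmental duplications, or true inter-sample structural
divergence. Real references also have non-uniform gap structure and
the draft/reference pair differs biologically; localization and
confidence distributions on real data are correspondingly lower, which
is exactly what the confidence scores are for. The benchmark sizes used
in the test-suite and acceptance runs (five 2 Mbp chromosomes, ~100
scaffolds, hundreds of planted variants) were chosen as the smallest
instances on which every property is still exercised, including
multi-chromosome clustering and scale-matched mutation rates.

## Known limitations

* One reference at a time; no reconciliation of multiple references.
* Gap sizes between contigs are a fixed pad, not estimated.
* The SV type system covers indels and tandem/repeat copy-number
  changes; inversions and translocations are out of scope.
* Chimera detection is alignment-based only; coverage- or Hi-C-based
  misassembly signals are not consulted.
* Merged-variant representatives are a heuristic; member records are
  retained so downstream consumers can re-derive their own.
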