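---
title: "Transcript-seeded genome walking: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcript-seeded genome walking: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Large repeat-rich genomes often cannot be assembled from low-coverage short
reads: the reads exist (say 20x of 2x100 bp pairs), but whole-genome
assembly collapses on the repeat content. Most downstream uses, however,
need only the *genic* fraction: exon/intron structures, promoter-proximal
flanks, intron sequence for probe or guide design. `genewalker` recovers
exactly that fraction by local assembly. Starting from a known transcript,
it recruits the genomic reads that overlap its exons, assembles them,
and then walks outward: each iteration queries the growing contig ends
against the read set, recruits what overlaps, reassembles, and stops when
nothing extends any more. One scaffold per gene is produced, with exons
ordered along the transcript and unbridged introns represented by fixed
runs of 500 `N`.

## Pipeline stages and their parameters

### Repeat depletion

Every read pair is scored by the *median canonical 31-mer coverage* of
each mate: the median, over all 31-base windows of the read, of that
window's multiplicity in the entire read set. Reads from an L-copy repeat
family have roughly L-fold inflated medians, so removing pairs with median
coverage > 40 (at nominal 20x) deletes high-copy repeat sequence from the
walk's universe; removing pairs with median <= 1 deletes sequencing-error
singletons and trace contaminants. Pairs containing `N` are also removed.
Both cutoffs are configurable (`depletion_config`); the defaults are the
published operating point. Two bookkeeping choices are ours: the median of
an even-sized multiset is the *lower* middle element (keeps the statistic
integral, as k-mer tools conventionally do), and windows containing `N`
contribute count 0 (so ambiguity depresses coverage; moot while
`drop_ambiguous = TRUE`). Counting is exact (a hash table), not a
probabilistic sketch: desk-scale inputs fit in memory, and exactness makes
the brute-force oracle in the test suite meaningful. The counter packs a
k-mer in 64 bits, so k <= 32; every operating point here uses k = 31.

### Read recruitment

The *reads* are indexed, not a reference. Every 20-mer of every mate goes
into a sorted array; a query samples its own seeds at a stride such that
any maximal exact match (MEM) of at least the match threshold must contain
a sampled seed, then extends each hit to maximality. Recall is therefore
complete by construction and independent of the seed length. Recruitment
thresholds: 40 bp exact match against the whole transcript when seeding,
60 bp against the terminal 600 bp of each contig end when extending. The
stricter extension threshold is what keeps walks from leaking across
diverged repeat copies. We recruit on MEMs rather than strict SMEMs
(maximality among overlapping query positions): for a recruit/no-recruit
decision the two differ only when a read has stacked matches, which cannot
change set membership.

### Local assembly

Recruited reads are assembled by a canonical de Bruijn unitigger at
k = 63: k-mers below a coverage floor (default 2, absorbing scattered
sequencing errors; set 1 for error-free input) are dropped, dead-end tips
shorter than 2k are clipped, and maximal non-branching paths are reported
in strand-canonical lexicographic order, making assembly fully
deterministic. One unitigger stands in for the published union of two
assemblers, because the consumer of that redundancy is the merge step that
follows either way.

Contig sets are combined by greedy overlap-layout-consensus. An overlap is
accepted at >= 30 bases and >= 75% identity, with unaligned overhang
adjacent to the overlap tolerated up to 80% of the overlap length and then
clipped (the "permissive" profile, mirroring an overhang-tolerant
assembler configuration); elongation of a contig by raw reads uses a
"strict" profile (40 bases, 90%). Three choices are this package's own:

* *Arrangement selection.* A pair of contigs can merge as containment or
  as either dovetail; we evaluate all arrangements consistent with the
  overhang budget and keep the one that loses the least sequence. (Naively
  treating any small-flanked alignment as containment silently discards
  real extensions; the test suite pins this.)
* *Consensus ties.* The majority base is taken per column; with two
  sequences every disagreement is a tie, resolved toward the
  higher-coverage contig, with contig length as the coverage proxy. In
  practice the overlap region is therefore taken from the longer contig.
* *Merge order.* Pairs merge by descending overlap score
  (identity x length), ties by contig id — deterministic layout without a
  full overlap graph.

The aligner behind all of this is an ungapped seed-and-extend HSP finder
(x-drop extension from exact 11-mers). Indels are not modelled anywhere:
the sequences this pipeline compares diverge by scattered substitutions
(sequencing error, repeat-copy divergence), and an ungapped model keeps
every consensus step coordinate-exact.

### The walk

Each iteration: recruit from end windows, assemble the *new* pairs,
elongate carried-over contigs, merge everything permissively, classify
exon-containing contigs, and retain neighbours linked by read pairs.
Classification aligns the transcript to each contig (blocks >= 40 bases,
>= 90% identity — our quantification of an aligner's defaults) and applies
a culling rule: a block enveloped by 2 higher-scoring blocks from other
contigs is discarded, so at most two contigs can claim the same exon
interval. A few bases of slack absorb x-drop jitter at block edges.
"Sufficient paired-end linkage" for keeping a non-exon neighbour contig is
quantified as >= 3 pairs with one mate on the neighbour (>= 95% identity
over >= 90% of the mate) and the other on an exon contig; 3 resists a
single chimeric pair.

Progress rules: continue while the maximum or summed contig length grows;
drop the transcript when its contig count reaches 500 or triples within
one iteration (runaway repeat recruitment); otherwise finish. The default
30 iterations extend each contig end by roughly the fragment length minus
the end window's reach per round — a few hundred bases per iteration on
the synthetic data.

### Finishing and scaffolding

Per transcript: contigs carrying the same exon sequence twice are
chimera candidates; their support is re-measured as *perfect proper-pair
coverage* (both mates full-length, zero mismatches, convergent, insert
within [0.5x, 2x] the median — the published rule fixes only "100%
identity", so the pairing window is ours). Internal regions with zero
coverage, or never straddled by a pair, are excised; terminal runs are
never excised. Contigs are then oriented by their best transcript block,
near-identical alternative assemblies (>= 200 bases at >= 95%, our
quantification of "large regions of similarity") collapse to a
column-majority consensus anchored on the longest member, and the
survivors are ordered by transcript coordinate and joined: a detectable
end overlap (>= 30 bases, >= 90%) fuses, anything else gets a fixed
500-`N` spacer.

### Redundancy merge

Transcripts are mapped back to scaffolds as chains of alignment blocks
with monotone transcript and scaffold coordinates. This replaces
splice-site-aware cDNA alignment; it is adequate because each scaffold was
built around its own transcript, so near-exact blocks exist — base-pair
precision at intron boundaries is explicitly not claimed. Contigs no block
touches are removed (gap-delimited), then scaffolds are grouped longest
first: a candidate joins when *all* of its exon blocks lie inside
scaffold-to-scaffold alignments of >= 95% identity and at least one lies
inside an alignment of >= 99% — the published two-tier rule. Groups merge
by pooling contigs through the same permissive merge and consensus
machinery, ordered by the longest member transcript.

## The synthetic world

`sim_config()` defaults state the testing world: a 1 Mb genome, 10 genes
of 3–8 exons (exons 120–400 bases — typical vertebrate exon sizes — and
introns 200–3000 bases), one 2 kb repeat family at 100 copies with 2%
per-copy divergence, and 20x coverage of 2x100 bp pairs at 0.1%
substitution error with 300 +/- 30 insert. Reads are uniform over the
genome (no GC bias), errors are substitution-only — the chimera machinery
and the exactness oracles are cleaner to validate without indels, and an
indel mode would exercise no additional code path in an ungapped pipeline.
What a green test therefore establishes: the method's mechanics (depletion
arithmetic, recruitment recall, assembly/merge correctness, stop rules,
scaffolding bookkeeping) on data whose statistical shape matches the
published input regime. What it does not establish: behaviour under real
error profiles, indels, GC bias, or a realistic repeat landscape with many
interleaved families.

Repeat divergence interacts with depletion in a way worth stating
explicitly. Median-coverage filtering removes a read only when more than
half of its 31-mers are family-wide; a copy diverged by ~2% gives most of
its reads at least one private mutation, whose overlapping 31-mers are
low-count and pull the median down — so those reads survive and the walk
can cross the copy. This is by design (the published analysis likewise
walks through diverged repeats), and it means the repeat-*stop* behaviour
is a property of young, homogeneous families. The repeat-stop acceptance
test therefore plants a 0%-divergence family; the general-purpose default
family diverges at 2% per copy, which exercises the walk-through regime.

One deliberate divergence in the repeat-stop analysis: the contig-end
classification (`end_status_report`) takes its coverage read set as an
argument, and the acceptance test passes the *pre-depletion* reads. In the
published data depletion is imperfect, so diverged repeat copies keep
stopped ends visibly high-coverage even in the depleted alignment; in the
synthetic world depletion is nearly complete over the planted family,
which would erase the signal being classified. Using all simulated reads
reproduces the mechanism being tested — high underlying copy number at
stopped ends. The "mode of extending-end medians" threshold is computed on
integer-binned medians (bin width 1x), our operationalisation of a
histogram-derived threshold.

## Numerical and degenerate-input choices

* All intervals are 0-based half-open; strand is `+`/`-`. Lowercase input
  is uppercased; FASTQ qualities are parsed and discarded.
* Reads shorter than k are "uncounted" and treated as coverage 0 by the
  depletion filter (hence removed by the low cutoff).
* A transcript shorter than the seeding threshold, or recruiting nothing,
  fails to seed with an explicit reason; one transcript's failure never
  aborts a batch.
* Ordering ties (two contigs claiming one transcript position) break by
  contig length then id, with a warning.
* `max_iterations = 0` is a seed-only run. A walk still extending at the
  iteration cap keeps status `"extending"`, which is what the end-status
  report keys on.
* The contig-count cap is checked before the quadratic merge so a runaway
  transcript is dropped cheaply.

## Known limitations

* Ungapped alignment throughout: true indel polymorphism between repeat
  copies or alleles fragments blocks instead of gapping them.
* The k-mer counter is exact and in-memory; billions of reads would need
  the counting-sketch backend the design leaves as an extension point.
* Splice-aware mapping is approximated by block chaining; intron
  boundaries can be off by a few bases where exons end in short repeats.
* The simulator does not model quality scores, indels, GC bias, or a
  realistic repeat taxonomy.
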