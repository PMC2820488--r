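---
title: "Characterizing tandem repeat families from c0t-1 clone libraries"
author: "cotrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing tandem repeat families from c0t-1 clone libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

A c0t-1 library is a physical enrichment experiment: denatured genomic
fragments are allowed to reassociate for a fixed time, and only
double-stranded molecules are cloned. Because second-order renaturation is
driven by the concentration of complementary strands, a fragment whose
sequence occurs N times in the genome re-anneals roughly N times faster than
single-copy DNA, so the library over-represents repeats in proportion to
their abundance. `cotrep` implements both sides of this experiment: a
simulator that plants a repeat landscape in a synthetic genome and samples a
library under these kinetics, and an analysis pipeline that classifies the
clones, discovers tandem repeat families de novo, characterizes their array
architecture and extrapolates genomic copy numbers.

The retained fraction of a sequence with copy number N is modeled as the
equilibrium of second-order kinetics,

    f(N) = k N C0t / (1 + k N C0t),

which is proportional to N when rare and saturates at 1 (`retentionProbability`).
The per-copy rate constant defaults to k = 0.01 so that a 1000-copy family is
at least 90% retained at C0t = 1; single-copy background then retains at
about 1%, reproducing the strong enrichment that makes these libraries
useful.

One modeling decision deserves emphasis. For a **tandem** family the
kinetically relevant copy number of a cloned fragment is not the monomer
count: a fragment-sized piece of a satellite array finds complementary
partners at every fragment-sized window of that family genome-wide, so the
sampler uses `total_family_bp / mean_insert_length` as the kinetic copy
number of tandem (and organellar) families, and the element count for
dispersed families. A 10 bp minisatellite with 1000 monomer copies occupies
10 kb and renatures like a ~30-copy fragment family, not like a 1000-copy
one. The abundance rank correlation reported by `evaluateRecovery` is
therefore computed against these kinetic copy numbers.

## Alignment conventions

All alignment-based operations share one scoring scheme: match +1,
mismatch -1, linear gap -2, and N never matches anything, including another
N. Coordinates are 0-based half-open everywhere, including the TSV/BED-style
outputs.

* `globalIdentity` is an ends-free global alignment; identity is
  matches / alignment columns x 100 over the aligned region. Co-optimal
  ends-free alignments can differ between argument orders, so the pair is
  canonically ordered internally to make the measure exactly symmetric.
* `seededLocalAlign` screens targets for an exact shared k-mer (default
  k = 11, both strands) and then computes a full local alignment for each
  candidate pair. Acceptance requires aligned length >= 50 bp, identity
  >= 70% and score >= 30. These three thresholds are the package's
  stand-in for a database-search e-value cutoff: e-values depend on
  database size and composition, which are meaningless for a small
  synthetic target set, while a length/identity/score floor is portable.
  All three are exposed as parameters.
* `rotationIdentity` compares tandem-repeat consensi, whose start point is
  arbitrary: the shorter sequence is aligned globally within the doubled
  longer sequence, on both strands.

## Tandem detection

`detectTandem` is a two-stage period finder:

1. **Candidate periods** are the distances between successive identical
   k-mers (default k = 5), together with all divisors >= 2 of those
   distances. Distances seen at least twice are preferred; divisors matter
   because in a mutated array the surviving exact k-mer pairs are often one
   or more periods apart.
2. **Verification** compares the sequence with its own p-shifted copy. Each
   position contributes +((100 - c)/100) when it matches and -(c/100)
   otherwise, where c is the conformity floor (default 80%); all maximal
   positive-sum segments (Ruzzo-Tompa) whose span is at least 20 bp, whose
   copy number (span / p) is at least 2.5 and whose conformity is at least
   the floor become arrays.

Periods are scanned smallest-first, so an array is reported at the smallest
period that explains it at the floor; a candidate overlapped more than 50%
by an already accepted smaller-period array is dropped. The conformity floor
is also what separates higher-order repeats from their base motif: a 30 bp
monomer built from degenerate 5 bp motifs agrees with its own 5 bp shift at
only ~50% of positions and is rejected at p = 5, while p = 30 verifies
cleanly. Periods below 2 are never reported: homopolymer runs are not
treated as tandem arrays, matching the 2 bp lower bound of microsatellite
motifs. Array boundaries carry an intrinsic +-1 bp ambiguity when a flank
base happens to continue the periodic pattern; boundaries are reported at
the maximal periodic extent.

Monomer decomposition cuts the array substring at phase, phase + p, ...;
the concatenation of the returned monomers always reconstructs the substring
exactly, and this invariant is property-tested. Consensus building is
per-column majority over full monomers with alphabetical tie-break, then
rotation to the lexicographically minimal form, so that the reported
consensus does not depend on where an array happened to start.

Family statistics follow the reporting conventions of classical satellite
tables: G/C content and the min/max pairwise identity over a seeded random
sample of at most 20 monomers (`monomerStats`; seed 1763 by default, a
mnemonic for a typical library size). Because arrays are cut at arbitrary
phase and strand, members of a family are strand-oriented and re-phased to
the family representative before the statistics are computed; without this,
identity ranges would measure cutting artifacts rather than sequence
divergence.

## Family grouping

`clusterFamilies` performs single-linkage clustering of tandem-bearing
sequences at >= 70% rotation/strand-tolerant consensus identity. Two
consensi whose periods differ by more than 30% are never linked directly
(size-variable families remain connected through intermediate members; the
30% allowance comfortably covers a 32-39 bp monomer range). Edges within an
already-merged component are skipped, which is exact for single linkage and
keeps the pass near-linear in practice. The identity threshold is a genuine
design choice: planted families diverge by a few percent within and by
> 40% between, so any threshold between roughly 60% and 85% produces the
same grouping on realistic inputs; 70% is kept as a round default. Family
monomer size is the modal member period (reported as a range when members
differ), the family's library hits are its distinct member clones, and the
representative monomer is the consensus of the largest member array.
Size classes follow the standard convention: 2-5 bp microsatellite, 6-100 bp
minisatellite, > 100 bp satellite.

## Classification

`classifyLibrary` assigns every clone to exactly one of known_repeat,
chloroplast, telomere, microsatellite or novel. Precedence is
known_repeat > chloroplast > telomere > microsatellite > novel: specific
homology to a curated panel entry beats generic motif content, and among
panel hits the highest-scoring acceptable alignment decides (an
organellar-class best hit yields chloroplast). Telomere detection looks for
>= 3 tandem copies of TTTAGGG on either strand with at most one mismatch
per copy; the copy threshold is a design choice — two copies of a 7-mer are
too common in AT-rich background. Microsatellite detection reuses the
shifted-self machinery at motif lengths 2-5 with a 90% conformity floor and
a 20 bp minimum span, reports motifs in canonical rotation and excludes
homopolymers.

The pipeline scans both the novel **and** the microsatellite fraction for
tandem arrays. This matters for microsatellite-derived minisatellites: a
clone filled with a 5 bp motif and its degenerate variants is, correctly,
classified as microsatellite, yet its higher-order 30 bp periodicity is what
defines the family. Percentages in the composition report are count/total x
100 rounded half-up to one decimal, the convention that reproduces printed
survey tables exactly; base R's round-half-even would not.

## Assembly

`greedyAssemble` is a deliberately simple overlap-layout-consensus
assembler for short clone reads: candidate relative offsets come from shared
k-mers, overlaps are gapless (substitutions only) and scored by identity,
and the best overlap (longest, then highest identity, then lexicographic id)
is merged first, with the consensus recomputed as a per-column majority over
member reads. The gapless model is appropriate for the substitution-only
error process of the simulator and for the highly similar reads the pipeline
feeds it; reads requiring indel-tolerant overlaps stay singletons rather
than being misassembled. Orientation is normalized during merging and each
contig is anchored to the strand of its first member in input order, which
makes the output invariant (up to global reverse complement) under
reverse-complementing any input read. Assembly of tandem-repeat reads is
inherently ambiguous modulo the period; contigs from such reads are
consensus-accurate but their length is not a copy-number estimate.

## Array architecture

**Higher-order structure.** `detectHOR` decomposes an array into
base-motif-sized units, labels units by greedy clustering at <= 1 mismatch,
and reports the smallest label period covering >= 80% of unit positions.
Unit variants two or more substitutions apart always receive distinct
labels; a variant one substitution away from the base motif may share its
label, which is harmless because the reported unit pattern is the modal
unit sequence per pattern position, and the exact-base count is computed on
those sequences, not on labels. Arrays whose units do not recur (less than
60% of units in recurring variants) and label sequences without periodicity
return nothing — under an i.i.d. null the false-positive rate is below 5%.
The pipeline additionally requires a candidate base motif to dominate the
monomer (>= 1/3 of its frames) before accepting a higher-order call, which
rejects the degenerate "every monomer is a pattern of dinucleotides"
decomposition.

**Head-to-head junctions.** `detectInvertedJunction` tiles the sequence
with monomer-sized windows and scores each against the consensus and its
reverse complement, rotation-tolerantly, assigning the better orientation
when it reaches 70% identity. Blocks of >= 2 consistent monomers on each
side with an orientation switch between them are junctions; the boundary is
refined at single-base resolution by maximizing window identity, ties
resolved away from the junction. The junction position is the start of the
first opposite-orientation monomer. When the terminal base of one array is
coincidentally consistent with the other orientation the position is
ambiguous by that base; fixtures show this shifts a minority of calls by
< 1 monomer. A gap allowance (default 60 bp) lets a conserved spacer or
flank sit inside the junction.

**Flanks and palindromes.** `extractFlankMotif` builds a majority consensus
over fixed-length flanks of several loci and reports the pairwise identity
range. `findImperfectPalindromes` scans all (center, spacer) placements,
extends arms maximally under a per-arm mismatch budget of
floor(0.25 x arm), and merges hits sharing an axis (centers within 2 bp)
to the highest-scoring one. Hits with distinct axes are kept even when
their intervals overlap — biologically real palindromic motifs can overlap
each other, and collapsing them would hide one. The 25% budget is the
smallest round fraction that tolerates the arm-interior substitutions seen
in real conserved flanks while leaving random sequence mostly empty at the
default 6 bp minimum arm.

## Abundance

`countHits` counts genome-sample records (not alignments) with at least one
acceptable hit; `binHits` reports <= 10 as low, 11-300 as mid and > 300 as
high (10 goes to low, preserving the conventional mid-bin lower edge of
11); `estimateCopies` extrapolates through the sampled coverage fraction,
est = hits / coverage. This estimator is calibrated for dispersed elements
about as long as, or shorter than, a sample record, where one copy meets
about `coverage` records. For tandem families it deliberately measures
something else — array loci, since hundreds of monomers share a record — so
the package evaluates copy-number recovery on dispersed families and uses
truth-labeled clone counts, not hit counts, to check the abundance ranking
of tandem families. The pipeline queries the sample with each family's
largest tandem-bearing clone rather than the bare monomer, since a 10 bp
monomer cannot reach the 50 bp acceptance length.

## The synthetic landscape

`referenceCotSpec` defines the validation conditions: a 2 Mb genome at 35%
background G/C, ~64% repetitive, with three known high-copy satellites
(160/170/330 bp monomers in large arrays), dispersed LTR-retroelement-,
MITE- and SINE-like families, a plastid-like organellar block (concatenated
lightly mutated copies of a 2 kb module, so one panel entry classifies all
of it), telomere-like and microsatellite arrays, and twelve novel tandem
families: three satellites (130 bp G/C-rich, 173 bp, 325 bp) and nine
minisatellites (10-96 bp) including a higher-order family whose 30 bp
monomer is GAAAA-AATAA-GTTCA followed by three GATCA units, and a 21 bp
family with half of its arrays built head-to-head around a conserved 51 bp
palindromic flank. Minisatellite arrays span ~0.5-1 kb, satellite arrays
several kb to tens of kb. Family genomic footprints span a ~9x range and
were sized so that each novel family expects at least ~15 library clones at
2000 clones; per-copy mutation rates are 2-5% substitutions.

Default study sizes, chosen once for desk-scale validation: 2 Mb genome,
2000 clones (inserts uniform 100-600 bp, < 50 bp discarded), genome sample
of 4000 x 250 bp records (coverage 0.5, so hit counts carry ~5% relative
error). The whole pipeline runs in a few minutes on one core at these
sizes.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: indels and sequencing error (the mutation model
is substitution-only, which the gapless assembler and exact monomer
reconstruction exploit); nested or interleaved repeats and
repeat-within-repeat structures; chromosome-scale organization
(centromeric clustering, subtelomeric position); satellite library bias
beyond reassociation kinetics (e.g. hairpin self-annealing of inverted
elements, which real libraries under-sample); and genome-scale copy
numbers, which are scaled down ~100-fold. One planted family (the 325 bp
satellite) is intentionally unrecoverable by per-clone tandem detection:
2.5 copies of its monomer do not fit in a 600 bp insert, so it surfaces
through assembled contigs instead — the recovery target (>= 10 of 12
families) budgets for exactly this class of miss.

## Degenerate inputs and tie-breaks

Empty libraries, empty panels and empty tandem sets raise informative
errors or return typed empty results as documented per function. All
majority votes break ties alphabetically; all sorts have total,
deterministic keys (score, then id, then position). Every stochastic
component takes an explicit seed and restores the caller's RNG state, so
identical inputs and seeds give byte-identical reports.
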