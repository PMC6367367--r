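---
title: "Methods: inventorying the mPing/Ping/Pong element family from short reads"
author: "mpingr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inventorying the mPing/Ping/Pong element family from short reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological problem

mPing is a rice miniature inverted-repeat transposable element (MITE): a
430-bp nonautonomous DNA transposon with 15-bp terminal inverted repeats
(TIRs) that is mobilized in trans by the transposase of its autonomous
partner, Ping. Ping itself is an internal-deletion ancestor/partner
relationship with mPing: the two are identical over both termini, and the
Ping-only interior (positions 253-5164 in our coordinates) is therefore the
only sequence that distinguishes a Ping insertion from an mPing insertion in
short-read data. Pong is a related autonomous element with its own
diagnostic interior (23-5320). Two Ping variants segregate in rice,
distinguished by a single G/A SNP at element position 16, immediately 3' of
the 5' TIR: Ping16G (the ancestral state, shared with mPing) and Ping16A. A
particular nested structure, Ping16A inserted after position 305 of a 770-bp
Stowaway element, defines the Ping16A_Stow locus associated with mPing
copy-number bursts.

`mpingr` implements the computational inventory of this family from
paired-end short reads: insertion discovery and element discrimination,
window read-depth copy-number estimation, junction-read detection of the
nested locus, +16 genotyping, subtype classification of assembled mPing
sequences, and the cohort statistics tying Ping variants to mPing load —
together with a synthetic-data generator that provides ground truth for
every stage.

## Element templates

Real mPing/Ping/Pong sequences are not bundled; `build_default_elements()`
generates parametric stand-ins from a fixed internal seed so that every
structural relationship the pipeline exploits holds by construction:

* Ping16G: 5341 bp, 15-bp TIRs, `G` at position 16.
* mPing: Ping16G positions 1-252 joined to 5164-5341 (430 bp), so the two
  elements share both termini exactly and the diagnostic interior is
  precisely the Ping-only sequence.
* Ping16A: Ping16G with the single G->A change at position 16.
* Pong: an independent 5341-bp TIR element (interior 23-5320).
* Stowaway: 770 bp. The flank arithmetic used for the nested pseudogenome
  (1-305 upstream, 306-770 downstream) requires a 770-bp element; a 769-bp
  length is sometimes quoted for this family, and we adopt 770 so the
  internal coordinates are addressable.

A user-supplied FASTA can replace all five sequences; templates are
validated against the TIR, length and internal-region invariants on load.

Canonical mPing subtypes (mPingA-D) are modelled as four internal-deletion
derivatives of Ping16G, each removing 4911 bp so all are 430 bp long, with
deletion starts staggered by 18 bp (217, 235, 253, 271). The true canonical
breakpoints are not published at base resolution, so these are configurable
placeholders; the 18-bp stagger guarantees any two canonical subtypes differ
by well over the 4-difference graph threshold, and mPingC coincides with the
default mPing template. Each subtype records its breakpoint (the last base
before the deletion, in derived coordinates) for read-level detection.

## Synthetic data: what it emulates, and what it does not

`simulate_genome()` draws i.i.d. bases at a target GC content (0.44,
rice-like). `insert_elements()` places element copies after uniformly
sampled positions (or positions weighted by the AT fraction of the
surrounding 9 bp, with a bonus for TTA/TAA target sites, mirroring the
family's AT-rich preference), duplicating the preceding bases as a
target-site duplication — 3 bp for the mPing/Ping/Pong family, 2 bp for
Stowaway. Insertion strand is Bernoulli(1/2). Insertion points are kept at
least 200 bp apart (configurable): the discovery and genotyping protocols
assume loci are separable at the library insert-size scale, and the real
analyses carry the same assumption.

`insert_nested()` builds the Ping16A_Stow structure as
`Stow[1..305] + Ping16A + Stow[303..305] + Stow[306..770]`: a transposition
duplicates its 3-bp target site once, on the 3' side of the insert.

`simulate_reads()` draws `round(coverage x genome_length / (2 x
read_length))` fragments with normal insert sizes (default 500 +/- 50 bp,
the study's library geometry), emits 100-bp mate pairs in FR orientation
with random mate labelling, and applies i.i.d. substitution errors (default
0.1%; the sequencing-error profile of the original simulator is not
published, so a flat substitution rate is our choice). Base qualities are
constant Q30 — nothing downstream uses qualities. The generator does not
model indel errors, GC-coverage bias, PCR duplicates, or real repeat
landscapes; passing tests therefore demonstrate correctness of the
algorithms under the stated library geometry, not robustness to every
artefact of real data.

`simulate_cohort()` drives per-accession configurations (mPing/Ping/Pong
copies, Ping variant, Ping16A_Stow status, coverage) over one shared
reference with a fixed shared Stowaway host locus, and emits FASTQ plus
truth TSVs.

## Read placement and pileups

Placement is ungapped seed-and-extend, written in C++: exact k-mer seeds at
pigeonhole offsets (k chosen so that more than `max_mismatch` disjoint seeds
fit in the read; k = 31 for 100-bp reads at the pipeline's <= 2 mismatch
filter) guarantee every placement with at most `max_mismatch` substitutions
is found. A placement is *unique* when it is the single best and beats the
second best by at least one mismatch; ties are non-unique, which is what
makes reads inside multi-copy elements behave correctly. Gapped placements
are not attempted; the mismatch filter counts substitutions only.

For element profiles the aligner runs in clipped mode: the read may overhang
either template end, mismatches are counted on the overlap (>= 20 bp), and
the best overlap wins. This mirrors soft-clipping in the original BWA-based
protocol and removes the depth bias at element termini that full-length
placement would cause — junction-crossing reads contribute their
element-matching part to the pileup. Pileup depth is capped at 8000 per
position by default (the protocol's cap); the simulation-grid evaluation
raises the cap, as the original validation did.

`genome_mean_depth()` is the aligned-base total over the genome length. For
libraries beyond 200k reads the aligned fraction is measured on a
deterministic systematic subsample and scaled — the induced error is far
below depth noise.

## Insertion discovery and discrimination

A junction read matches an element terminus with at least 10 bp
(`len_cut_trim = 10`, the discovery parameter of the original tooling) and
carries a remainder of at least 15 bp that places uniquely on the reference.
The junction coordinate gives the duplicated target site exactly: the 3 bp
ending at the left junction equal the 3 bp starting at the right junction.
Junction evidence is clustered with 2 bp of slop; a locus needs 3 supporting
reads with both sides represented at >= 10x coverage (2 reads below that) —
the original pipeline delegates this threshold to its discovery tool without
printing it, so it is our choice, balanced for the study's 14x libraries.

Discrimination uses mate pairs: a pair whose one mate lies fully inside the
Ping interior 253-5164 while the other anchors uniquely near the locus marks
a Ping insertion; Pong analogously with 23-5320. Because mPing shares both
Ping termini, every Ping locus also appears in the mPing query run; loci
classed Ping or Pong are subtracted from the mPing set. Loci with support
from both interiors are contradictions, excluded and logged. When the
library insert is too short for mate discrimination
(`insert_mean < 2 x read_length + 30`), only family-level calls are made and
genotyping switches to pooled mode.

Presence calls use covered fraction of the element: >= 70% present, < 10%
absent, otherwise partial — the signature of a deletion derivative.

## Copy number

The element's comparable region (mPing 1-430; Ping/Pong 260-3260, the
region unique to the autonomous elements) is tiled with 50-bp windows
stepping by 10 bp. If the stepping grid does not reach the region end, one
extra end-anchored window is appended so every position is covered — how the
remainder of 260-3260 is handled is not specified in the source protocol,
and this choice keeps the tiling exhaustive. Window copy number is mean
window depth over genome mean depth; the element estimate is the mean over
windows, reported as a float and as an integer rounded half away from zero.
A two-sided one-sample t-test compares window depths with the genome mean
(the protocol states depths, not ratios; the two give identical tests up to
scaling). Zero-variance windows short-circuit to t = +/-Inf, p = 0 (or
t = 0, p = 1 when the mean equals the reference), logged as degenerate.

`evaluate_simulation_grid()` re-runs the validation design — copies
{1, 10, 100, 1000} x depths {1, 2, 3, 4, 5, 10, 20, 40} x 3 replicates. The
desk-scale configuration used by the test suite and the acceptance script
is a 1-Mb single-chromosome reference with copies {1, 10, 100} and depths
{2, 5, 10, 20, 40}; the statistics of the estimator are governed by reads
per element, so the reduced genome leaves accuracy representative while
keeping the run in minutes on one CPU.

## Ping16A_Stow detection

Two pseudogenomes per accession: the Stowaway in its 2-kb genomic flanks,
and Ping16A flanked by Stowaway 1-305 (plus genomic context) upstream and
the duplicated target plus Stowaway 306-770 downstream. Junction support
counts reads spanning a flank/insert boundary with >= 10 matched bases on
each side; presence needs >= 2 spanning reads with both junctions seen —
the two-read threshold is by analogy with the protocol's pervasive two-read
rules, which do not state a junction-specific value. The decision is
two-stage: no Stowaway junctions -> none; Stowaway without nested junctions
-> stowaway_only; both -> ping16A_stow; nested support without Stowaway
support is an impossible structure and raises an error.

## +16 G/A genotyping

Locus-specific reads (mates anchored within insert_mean + 4 sd of the
locus) are clip-aligned to the Ping template and the base counts at element
position 16 follow the two-read rule: >= 2 G and < 2 A -> Ping16G;
>= 2 A and < 2 G -> Ping16A; both >= 2 -> "both"; otherwise undetermined.
Minus-strand reads are complemented by the aligner before counting. In
pooled mode all family reads are counted together and the result is
accession-level.

A "both" call triggers shared-allele resolution: every read covering
position 16 with a G or A, plus its mate, is aligned to pseudogenomes of
all candidate loci — assembled consensus for mPing-sized loci (preserving
locus-private variants such as an mPing copy carrying A at 16), oriented
Ping template for loci discriminated as Ping (a full-length Ping cannot be
tiled by locus reads, and a "complete" assembly there would be a chimera
through the shared termini). Pairs uniquely assigned to an mPing locus are
removed from the allele counts and the rule is re-applied; pairs assigned
to a Ping locus, or tied between pseudogenomes, keep contributing (ties are
warned about), so a genuine second Ping allele survives as "both". Loci
that fail resolution are reported as "both" and excluded from variant
tallies.

## Subtype classification

Locus consensus sequences are rebuilt by greedy maximal-overlap merging
(exact overlaps >= 20 bp, both read orientations), a deliberate stand-in
for a de Bruijn assembler that is exact for error-free desk-scale data; an
externally assembled FASTA can be supplied instead. Flanks are trimmed with
20-bp reference anchors bounding the duplicated target site; a consensus
missing either anchor (a coverage gap) is incomplete and excluded from
graphs.

`pairwise_distance()` is an optimal global alignment under unit mismatch
and unit gap-column costs, so the total equals the Levenshtein distance; a
3-bp indel counts as 3 gap columns. Whether "number of gaps" should count
gap columns or gap runs is ambiguous in the field's phrasing; we take the
conservative column reading (configurable in principle via the scoring).
Edges connect sequences with mismatches + gap columns <= 4; connected
components (via igraph) are the subtypes, transitively: members of one
component may be more than 4 apart. Component representatives are the
lexicographically smallest member sequences.

Canonical labels are assigned by aligning the consensus and each canonical
subtype to the parent with affine gap costs (so each excised interval stays
one contiguous gap) and comparing the observed deletion intervals — mapping
both sides through the same aligner makes breakpoint comparisons robust to
homology at the deletion boundaries. Ties go to the fewest total
differences, persistent ties to "ambiguous". The read-level mode reports a
subtype present when >= 2 reads span its breakpoint with >= 10 bp on each
side under the <= 2 mismatch filter.

## Cohort statistics

Pearson correlation (via `cor.test`) compares discovery counts with depth
estimates. The Ping16A_Stow association uses a two-tailed
Wilcoxon-Mann-Whitney rank-sum test: exact enumeration of all rank splits
for combined n <= 16 (midranks make it valid under ties, which the standard
exact implementation refuses), normal approximation with tie and continuity
correction above. One-way ANOVA and Tukey HSD go through `aov` and
`TukeyHSD`, with the all-constant degenerate case short-circuited to F = 0.
Yeast transposition rates divide selective-plate colonies by total plated
cells back-calculated from the reference plate at its dilution (default
1e-4), reported per million and normalized to the control construct; the
control itself is normalized by the control mean. Report percentages are
printed to one decimal under both half-away-from-zero and half-toward-zero
conventions, flagged when they differ — published figures are not uniform
in this respect (43.75% printed as 43.7 implies the toward-zero side).

## Problem sizes and limitations

The bundled checks run on one CPU in minutes: the copy-number grid on a
1-Mb reference (45 simulated libraries), a 30-accession discrimination and
genotyping cohort and a 20-accession Ping16A_Stow cohort on 120-kb genomes
at 14x, and statistical-engine oracles at enumeration scale.

Known limitations: ungapped placement means indel polymorphisms in real
elements degrade alignment rather than being modelled; the greedy assembler
assumes error-free tiling reads; nearby family insertions (within the
locus-read window) can force a locus genotype to "both" until resolution,
and two insertions closer than the junction slop would merge; the nested
pseudogenome construction assumes the host Stowaway orientation is known;
and the synthetic reference has no repeat structure beyond the inserted
elements, so mappability effects of real genomes are untested.
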