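---
title: "Methods behind trimscape: structural discovery and characterization of miniature LTR retrotransposons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind trimscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trimscape)
```

## The problem

Terminal-repeat retrotransposons in miniature (TRIMs) are small
(< 1,500 bp) non-autonomous LTR retroelements: two short long terminal
repeats (LTRs, 30-500 bp) flank an internal region (30-2,000 bp) with no
coding capacity, and insertion leaves a 4-6 bp target-site duplication
(TSD) on either side. Their small size and lack of conserved protein
domains make them invisible to most repeat annotators, which key on
reverse-transcriptase homology or on primer-binding-site/polypurine-tract
features that diverged TRIMs often lack. `trimscape` implements a
structural pipeline for these elements end to end: de novo candidate
detection, the three TRIM-defining filters, subfamily/family clustering
under the 80/80 rule, library masking with copy-number summaries,
tandem-array structure typing, genic-context and gene-capture analyses
with a Nei-Gojobori Ka/Ks estimator, methylation and small-RNA profiling,
and comparative analyses (autonomous partners, deletion breakpoints,
insertion polymorphisms between assemblies).

Because genome-scale re-analysis of dozens of plant assemblies is not
reproducible on a desktop, every stage is validated against synthetic
genomes with complete ground truth, generated by the package itself.

## The synthetic-data generator

`simulate_genome()` builds an i.i.d. background of configurable GC
content (default 0.45, a typical plant euchromatic value) and implants
elements the way retroelements integrate: the target site is duplicated,
so a complete insertion reads `TSD + LTR + internal + LTR' + TSD`, both
TSD copies identical, and the pre-insertion haplotype retains a single
copy of the site. The 3' LTR is a point-substitution copy of the 5' LTR
at the configured divergence (substitutions only; the package's alignment
machinery is likewise gapless, see below). Implanted LTRs start `TG` and
end `CA`, the canonical retroviral/retrotransposon terminus, which real
TRIM families overwhelmingly show; boundary refinement exploits this the
way a human curator would.

Defaults mirror the size envelope of the elements under study: LTRs
80-300 bp, internal regions 100-800 bp, TSDs 4-6 bp, divergence 0.02
(recently amplified families), uniform placement away from sequence ends.
Deviations are options, not defaults: decoy microsatellite arrays (to
exercise false-positive rejection), intron-biased or large-gene-biased
placement (to exercise the gene-context statistics), a large "partner"
element with a derived miniature copy, and paired genomes sharing a
configurable fraction of insertions (for polymorphism calling; these use
5-bp TSDs, the length observed for polymorphic elements).

What the simulator does *not* model: indels, nested insertions,
population structure, or read-level bisulfite data (methylomes are
emitted as per-cytosine count tables directly). Passing tests therefore
demonstrate correctness of the algorithms under a substitution-dominated
divergence model, not robustness to assembly gaps or structural noise in
real genomes.

Two generator choices exist purely so that planted truth is *uniquely
identifiable*, and are worth stating. First, in the partner construct the
bases immediately flanking the two copies of the duplicated internal
sequence are forced to differ between copies, and the copy junction bases
stay exact while only the copy interior diverges: otherwise a chance
agreement of one flanking base makes a 26-bp interpretation of a 25-bp
duplication equally parsimonious, and no algorithm (or reviewer) could
recover "the" truth. Second, the reconstruction invariant -- deleting
every implanted element plus one TSD copy restores the background byte
for byte -- is tested directly.

## The structural scanner

`scan_genome()` finds candidate elements as pairs of nearby direct
repeats. Exact 12-mers recurring at a start-to-start distance compatible
with the length bounds (LTR 30-500 bp, spacing 30-2,000 bp) seed the
search; seeds at one distance are chained, extended by an X-drop walk
(+1 match / -3 mismatch, drop 12) along the single alignment diagonal,
and trimmed to a clean terminus (no mismatch within the outermost six
columns). The clean-terminus rule makes boundaries of exact repeats
*maximal exact runs*, which is what the brute-force shift-and-compare
oracle in the test suite enumerates; at 12-mer seeding the scanner is
sensitive down to roughly 10 % LTR divergence, beyond which exact seeds
become sparse in short LTRs.

Boundary determination is where miniature elements are genuinely hard.
The raw repeat boundary wobbles by a few bases at realistic divergence,
and pseudo-TSDs -- the true TSD plus one or two coincidentally matching
bases of element or background -- are common (a quarter of elements at a
minimum). The TSD snap therefore scores candidate boundary shifts of up
to ±12 bp lexicographically: first by how many of the four canonical
terminus signals are present (`TG` at the element start and at the 3'
LTR start, `CA` at the element end and at the 5' LTR end -- the paired
copy rescues a mutated edge), then by smallest shift, then by longest
exact TSD. Overlapping candidates resolve by identity, then length, then
position. This post-processing is one shared function applied equally to
scanner output and to the oracle's enumeration so the two stay
comparable.

Residual boundary ambiguity is real, not algorithmic: when the same edge
base is mutated in both LTR copies (the 3' LTR is copied from the 5'
one, so an early mutation propagates), or when the TSD sits in a
homopolymer run, the sequence admits two equally parsimonious
interpretations. At 3 % divergence this affects roughly 2-7 % of
elements; the recovery suite (100 elements in 2 Mb) measures recall and
precision at 1.00, boundaries within ±5 bp for ≥ 95 % and exact TSDs for
≥ 95 % of detections under those conditions.

`refine_boundaries()` exposes the same logic as a standalone
coordinate-descent search (±15 bp per boundary, identity-maximizing,
ties broken toward canonical termini, longer LTRs, leftmost start) for
candidates produced elsewhere.

## The TRIM-defining filters

`apply_trim_criteria()` implements the three defining criteria: (1) the
element is shorter than 1,500 bp and contains no N ("without gaps"; the
scanner already refuses N inside LTRs, the filter extends this to the
whole span); (2) the genome contains at least two complete copies of the
provisional subfamily flanked by *different* TSD sequences, or one
complete copy plus one solo LTR; (3) no retrotransposase coding
capacity. Copies with identical TSDs are conservatively counted as one
supporting copy, since a segmental duplication moves an element together
with its flanks. Provisional subfamilies for criterion 2 use the same
80/80 predicate as the clustering module; solo LTRs are genomic matches
of the subfamily LTR (identity ≥ 0.80 over ≥ 80 % of its length, a
choice made by analogy with the clustering rule, since no canonical
threshold exists) that are not part of any candidate's LTR pair. Coding
capacity means a six-frame, stop-free translation segment of ≥ 100 aa
aligning to a supplied retroelement protein at ≥ 50 % identity over
≥ 80 aa -- an identity-based stand-in for an E-value cutoff, since no
external search engine is invoked. The filter returns the rejected set
with per-candidate reasons; input always equals retained plus rejected.

## Clustering and conservation labels

Subfamilies are single-linkage clusters within one genome under
identity ≥ 0.80 AND coverage ≥ 0.80 of the shorter element, computed
from the best local alignment (match 2 / mismatch -2, gap 6/2).
Consensus building uses a star alignment onto a reference member -- the
member of modal length rather than simply the longest, because a tandem
array that clusters into its parent subfamily would otherwise become the
reference and inflate the consensus past the unit element. Families
link subfamily consensuses across genomes when the best local alignment
spans ≥ 50 bp and ≥ 5 % of the query consensus at ≥ 70 % identity
(identity again replacing an E-value; the linking alignment is scored
match 2 / mismatch -4 so that it does not drift into unrelated sequence
and dilute its own identity). Conservation labels follow directly from a
genome-to-plant-family taxonomy table: shared between plant families,
family-specific, or species-specific.

## Library masking and summaries

`mask_genome()` aligns each consensus to both strands through the same
seed-and-extend engine, scoring match +1 / mismatch -1 scaled by ten to
approximate the masking-score convention, with defaults score > 250 and
hit length > 50 bp. The engine is gapless -- on substitution-dominated
divergence the gap penalties of a full alignment would never fire -- so
a hit lives on one diagonal; this is a stated limitation for real
genomes with indel-rich histories. Overlapping hits resolve by score,
then length, then position. Completeness is an operational definition
(no published rule exists): complete iff the alignment covers ≥ 80 % of
the consensus including both terminal 20-bp ends; solo LTR iff confined
to an LTR interval covering ≥ 80 % of the LTR; else fragmented. Summaries
count copies by class and measure masked base pairs on the interval
union (verified against a per-base bitmap), with the genome fraction as
a percentage; on synthetic genomes at ≤ 5 % divergence the estimated
fraction sits within one percentage point of truth.

## Tandem arrays

Tandemly arrayed elements are runs of ≥ 3 LTR segments with interleaved
internal segments, annotated by masking the LTR and internal consensus
separately (`annotate_segments()`) and merging adjacent segments within
a 10-bp gap tolerance (a default; no published adjacency tolerance
exists). Structure strings count segments (`L3I2`, `L5I4`, ...);
`inverted` flags strand changes within a run (two tail-to-tail
elements read `L4I2` inverted); runs that start or end with an internal
segment are flagged non-canonical rather than rejected. A whole-array
TSD is looked up on the full span and reported but not used as a filter,
since published arrays list one TSD per array without stating it as a
requirement.

## Genic context, gene capture, Ka/Ks

Insertions get exactly one positional category with precedence
exon > intron > upstream (1.5 kb, strand-aware) > intergenic, so a hit
spanning an exon/intron or upstream/exon boundary counts once -- the
dedup rule. Downstream proximity is intergenic by design ("near genes"
means upstream only). A hit inside two genes goes to the gene whose exon
it touches, else the longer gene. Element-bearing genes (TRGs) are
compared to the rest with two-sample t-tests on log-transformed exon
counts, exon sizes and intron sizes. Size-class densities rank genes by
length, take the bottom/top 20 % as small/large, and report insertions
per gene (two decimals) and per kb (four decimals); the arithmetic core
(`density_from_counts()`) is exposed so published per-class counts can
be fed through the identical code path.

Gene capture aligns element internal regions to spliced transcripts
(≥ 70 % identity over ≥ 50 bp). A capture is exon-only iff it aligns no
further along the *unspliced* gene than along the transcript: a fragment
carrying an intron aligns further on the unspliced gene, a spliced
capture does not.

Ka/Ks uses the Nei-Gojobori (1986) estimator with Jukes-Cantor
correction: per-codon synonymous site fractions, pathway-averaged
difference counts (pathways through stop codons are excluded, falling
back to all pathways if none avoids a stop; mutations *to* stops count
as nonsynonymous in site counting), and NA on saturation or when a site
class is empty. The test suite checks every sense-codon pair against an
independent exhaustive pathway enumerator. This estimator stands in for
a maximum-likelihood codon model by explicit design choice: it is exact,
dependency-free and auditable, at the cost of ignoring
transition/transversion bias and codon frequencies.

## Methylation and small RNAs

Methylation arrives as per-cytosine counts (chrom, position, strand,
context, methylated reads, total reads). Methylated positions are called
by the one-sided binomial tail against the bisulfite non-conversion rate
with Benjamini-Hochberg correction; region levels are *weighted*
(summed methylated over summed total counts), which is invariant to
splitting a region and recombining with count weights. Metaprofiles
rescale bodies to 20 bins with fixed-width flank bins, pooling counts
before dividing.

Small-RNA abundance counts overlapping reads by length (21/24 nt),
weights a read at k loci by 1/k, and normalizes to transcripts per
million of the input. Family epigenetic types are a numeric calibration
of qualitative class definitions, with every threshold exposed: Type I
(RNA-directed DNA methylation of the element body) requires 24-nt body
abundance ≥ 5 TPM, body CHH ≥ 0.10 and a summed body-minus-flank
contrast ≥ 0.10; Type III requires low 24-nt abundance with CG-only body
methylation (CG ≥ 0.40, CHG < 0.10, CHH < 0.10); everything else is
Type II (CG+CHG in body and flanks without borders). Gene bodies
classify as C-methylated (non-CG level ≥ 0.05 and binomially enriched
over a 0.05 background), CG-body-methylated (CG ≥ 0.20 and enriched), or
unmethylated; genes below five reads per context are uncallable. The
simulated sRNA background avoids element bodies because at simulated
depths a single stray read dominates a small element's TPM -- a
simulator simplification, stated here, not a property of real data.

## Comparative analyses

Partner search looks for genomic LTR pairs matching a miniature
element's LTR at ≥ 0.79 identity whose span is ≥ 3,000 bp and whose
internal region shares ≥ 100 aligned bp with the element's internal
region; among chained or nested pairings the tightest valid span wins
(a partner's 5' LTR would otherwise pair with a *related element's*
3' LTR further downstream). Breakpoint location decomposes the
miniature element into a 5' and a 3' block against the partner. Because
divergence is substitution-dominated, the deletion length is the exact
difference of the two block diagonals; a split-point scan then maximizes
total matches of the two-block interpretation, and the rightmost
maximum of its plateau is the breakpoint, putting the duplicated
internal sequence immediately 5' of it, matching the published
convention. The duplication itself is found between the two
junction-anchored windows by alignment score (match +1 / mismatch -3;
ties to the longer copy) over lengths 8-60 bp at ≥ 0.90 identity.
Autonomy requires a stop-free six-frame ORF of ≥ 900 aa (a configurable
floor separating ~1,200-1,600 aa full retrotransposases from ~400 aa
truncations) *and* coding capacity against the protein set.

Polymorphism calling maps each annotated element's 500-bp flanks onto
the second assembly. A call is polymorphic iff both flanks place
uniquely (≥ 0.90 identity; a near-best secondary locus marks the element
ambiguous) and their projected inner edges overlap by up to a TSD length
or gap by at most 2 bp -- the single target-site copy of the empty
site, which is reported as the TSD. Inner gaps near the element length
mean the insertion is shared. Calls are symmetric between genomes by
construction.

## Numerical choices and problem sizes

All internal coordinates are 1-based inclusive, the natural convention
of the R/Bioconductor interval stack this package is built on; GFF3
output is 1-based inclusive as the format requires, and exported TSVs
state their convention. Determinism: all generators take explicit seeds;
derived seeds stay below 2^31.

The test suite and the acceptance script run everything at sizes a
laptop handles in minutes, chosen as the smallest scales at which the
measured quantities are stable: the scanner oracle on twenty 12-kb
genomes; scanner recovery on one 2-Mb genome with 100 implants at 3 %
divergence; clustering oracles on 50 elements; masking on 400 kb with 25
elements at 4 % divergence; epigenetic typing on 50 single-element
families; polymorphism calling on ten insertions per genome.

## Known limitations

Gapless homology throughout (indel-divergent copies fragment into
multiple hits); k-mer seeding bounds sensitivity at roughly 10 %
divergence for short LTRs; no nested-element resolution; no
phylogenetic dating; tandem arrays sharing internal LTRs are reported
once as arrays, not as overlapping elements; syntenic-ortholog analyses
consume a user-supplied pair table rather than computing synteny; and
boundary calls on elements whose terminal motifs are mutated in both
LTR copies, or whose TSD sits in a homopolymer, are reported at one of
the equally parsimonious interpretations.
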