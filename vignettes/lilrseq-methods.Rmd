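---
title: "Methods: models, simulator and design choices in lilrseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulator and design choices in lilrseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lilrseq)
```

`lilrseq` analyzes barcoded long-read (CCS) amplicon data from the highly
polymorphic inhibitory receptor genes *LILRB1* and *LILRB2*. This
vignette is the package's own account of the underlying models, the
synthetic-data generator that stands in for real sequencing data, the
numerical conventions, and the design decisions that were genuinely open.

## The gene model

A `gene_model` records ordered exon spans on a genomic allele, which
exons form the mature mRNA, where translation starts and stops, and the
structural region each exon encodes. The canonical *LILRB1* layout is:
16 exons, mature mRNA from 14 of them, start codon in exon 3, stop codon
147 bp into exon 16; exons 5–8 encode the Ig-like domains D1–D4, exons
9–10 the stem, exon 11 the transmembrane segment and exons 12–16 the
cytoplasmic tail. For *LILRB2*, exon 1 and intron 1 cannot be resolved in
public assemblies, so `lilrb2_model()` starts at exon 2 while keeping the
genomic exon numbering; all statements such as "exon 9" or "exon 15" use
that frame throughout the package.

**Coordinates.** All intervals are 1-based and inclusive, both
internally and in reports. This is the native R and IRanges convention;
using a single convention end to end removes the internal/external
translation step where off-by-one errors in retention arithmetic would
otherwise live.

**ITIM counting.** The sources that count "three to four" ITIMs never
state the motif definition, so the classical consensus
`(S/I/V/L)-x-Y-x-x-(I/V/L)` is used, scanned with overlaps over the
translated product and attributed to the exon encoding the motif's first
residue. This is an assumption, not an inference: it is the only
defensible default, and it is encoded in one place (`count_itims()`).

**Exon 15 length.** Published descriptions are ambiguous between a
126-bp and a 156-bp canonical exon 15 (the latter arising from a ~30-bp
partial intron retention). The canonical fixture uses 126 bp, so that the
retention isoform annotates as 156 bp; the choice is surfaced here rather
than buried in the fixture.

## The synthetic generator: what it emulates, what it does not

The package ships no real data. `lilrb1_fixture()` deterministically
constructs a canonical genomic allele that satisfies every structural
statement of the model above, including four ITIMs with exactly one in
exon 15, a GT/AG intron set, and engineered intron ends: intron 9 ends in
`GCA` so that a 3-bp alternative 3' splice site at exon 10 inserts an
alanine, and intron 14 ends in `CAG` so the analogous event at exon 15
inserts a glutamine. (No alanine codon ends in `AG`, so a codon-aligned
3-bp acceptor retention encoding alanine cannot leave a canonical `AG`
acceptor; the fixture accepts the non-canonical acceptor at intron 9 and
keeps the canonical one at intron 14.) The first five codons of exon 10
are fixed so that 1–2-bp acceptor micro-insertions put a stop codon
inside exon 10 in the shifted frame, reproducing the premature-stop
isoforms; the first 30 bp of intron 15 are stop-free in frame so the
156-bp retention isoform stays translatable.

`simulate_allele_set()` uses a star-within-star process: one ancestor,
`n_lineages` founders mutated at the inter-lineage divergence, and
alleles mutated from their founder at the intra-lineage divergence. This
reproduces the cluster structure that lineage assignment relies on, and
nothing more — it is not a coalescent and makes no claim about realistic
genealogies, recombination, or gene conversion. Substitutions never touch
splice-site dinucleotides, the engineered intron heads/tails, or the
start/stop codons, and never create an internal stop, so every simulated
allele satisfies its gene model by construction. Lineage-level structural
features mirror observed alleles: a 21-bp in-frame exon-9 insertion
encoding the stem extension PTTGPTS (the peptide is fixed; the codons are
a seeded choice among synonymous options), a GT-to-GC donor mutation of
intron 15, and a cryptic stop codon 3 nt into the intron after the stem
region.

Key defaults, chosen once as the conditions the analysis assumes:

| parameter | default | rationale |
|---|---|---|
| lineages × alleles | 3 × 4 | enough structure for lineage recovery at desk scale |
| inter-lineage divergence | 0.05 subst/site | cross-lineage distances (~0.10) sit well above the 0.04 lineage ceiling, as real LILRB lineages do |
| intra-lineage divergence | 0.002 subst/site | a few substitutions per 2.3-kb transcript; inter/intra ratio 25 |
| samples / reads | 20 samples × 500 reads | desk-scale version of a multiplexed SMRT cell |
| isoform mixture | canonical weight 0.15 | non-canonical transcripts dominate, led by the exon-10 alt-3'ss and exon-15 skipping |
| CCS error rate | 0.001 subst/base | high-accuracy consensus reads; substitutions only |
| barcodes | 16 bp, dual, distance-checked | the assay's sample tagging |
| read quality | 90% with rq ≥ 0.99 | the filtering stage has something to remove |

The error model is substitutions-only: CCS indel rates are far below
substitution rates at this accuracy, and the downstream matching stage is
exact-match, so indel noise would only exercise code paths the
contracts do not define. Consequently, reads from one isoform share a
length, which the clustering stage exploits. What passing tests on this
generator do **not** show: robustness to chimeric PCR products, indel
sequencing errors, barcode hopping, or expression-level differences
between alleles — none of which the generator emulates.

## Read processing

Reads with read quality below 0.99 are removed (the threshold is a
parameter; 0.99 is the conventional CCS high-quality cutoff). Demultiplexing tries both
orientations of each read, scores the 16-bp barcode at each end against
every sample's pair, and assigns a read to the unique sample matching
within `max_mismatch` (default 1) at *both* ends; joint-score ties leave
the read unassigned. The manifest is rejected unless every pair of
samples has joint barcode distance above `2 * max_mismatch`, which makes
the assignment unambiguous by construction. The 1-mismatch default is a
choice (the sources are silent); 16-bp PacBio barcode sets tolerate it
without collisions.

## Allele discovery

Matching is deliberately strict: a read is assigned only on a
zero-mismatch alignment covering the full shorter sequence with at least
400 bp of overlap and at most one ambiguous base. The implementation
anchors a read's leading 32-mer in an index over the reference library
and verifies containment exactly; this changes nothing about the
contract, only the cost.

Unassigned reads are clustered per sample, stratified by length
(substitution-only errors preserve length), with single-linkage greedy
clustering at 99.5% identity (Hamming). Within a cluster, every exact
haplotype supported by at least three identical reads becomes its own
candidate — several byte-identical full-length CCS copies cannot be
independent error artifacts, and this keeps same-lineage alleles, which
can sit within the 0.5% radius of each other, from collapsing into one
contig. Remaining error-bearing reads attach to their nearest candidate
as support; a cluster with no anchored haplotype falls back to a
majority-rule column consensus (so three reads with one scattered error
each still yield the true sequence). The three-reads-per-contig cutoff
applies to candidates.

A candidate is *confirmed* when its consensus is identified in two
independent runs for one individual or in at least two individuals — run
and sample identity being the machine-readable proxy for "two independent
PCRs and PacBio runs". Confirmed transcripts are reconciled against the
genomic allele set: a transcript links to a genomic allele iff the
spliced aligner derives it exactly under some splice signature. Linked
transcripts enter the reference library as named splice variants of their
parent allele; unlinkable ones are retained as transcript-only novelties.
The library grows and matching repeats until no new sequence is confirmed
(at most 5 iterations — the cap mirrors the "iterate up to 5 times"
setting of the original mapping tool, whose precise meaning is
undocumented; in practice closure occurs in 2–3).

A consequence worth knowing: an isoform whose supporting reads occur in
only one individual and one run can never be confirmed, so its reads
remain unassigned at closure. That is the confirmation rule working as
specified, not a missed assignment; the per-sample allele calls are
unaffected because canonical-isoform reads always match the base library.

## Splice annotation

`align_transcript()` decomposes a transcript into maximal exact blocks
mapped co-linearly onto the genomic allele (20-mer seeding, leftmost
maximal extension). Junctions are then normalized: boundary bases that
match on both sides of a junction are slid left until a block boundary
lands on an annotated exon end or the next block starts on an exon start.
This left-alignment is a deterministic canonical form for the inherent
ambiguity of indels in repeated sequence — e.g. a 30-bp retention whose
last base equals the first base of the next exon is always reported as
`ret15+30`, never `ret15+31` plus a 1-bp acceptor truncation.

Classification compares the chain with the mature exon spans. The
conventions, chosen to match the field's vocabulary:

* missing exon → `exon_skip`;
* acceptor-side gain of 1–2 bp → `micro_insertion` (the premature-stop
  generator at exon 10), 3–50 bp → `alt_3ss` (+k), larger → retention;
  acceptor-side losses → `alt_3ss` (−k);
* donor-side gains of any size → `intron_retention` (the ~30-bp exon-15
  extensions are called "partial intron retention", not alt-5'ss);
  donor-side losses → `alt_5ss` (−k).

The 50-bp alt-ss bound is configurable; it only disambiguates
acceptor-side gains, and the observed events sit far from it (3 bp vs
~30 bp). Signatures are validated: at most one acceptor-side and one
donor-side event per exon, no boundary events on skipped exons.

`annotate_protein()` rebuilds the isoform, translates from the start
codon, and reports frame status, premature stops (and whether they fall
upstream of the TM segment — the soluble-receptor candidates), residues
inserted relative to the allele's own canonical protein, and the ITIM
count of the product. `detect_splice_motifs()` reports donor/acceptor
dinucleotides, flags non-GT donors, and checks the intron after the stem
region for an in-frame stop codon starting 3 nt after the donor.

The shared-event catalog keeps events — identified allele-agnostically by
(kind, exon, delta) — observed in at least two individuals *and* two or
more species; this is the filter behind the cross-species event counts.

## Distances, trees, lineages, names

Jukes–Cantor, Tamura–Nei (TN93) and the Nei–Gojobori nonsynonymous
distance are implemented from their closed forms with pairwise deletion
of gap/ambiguous columns; the first two are cross-checked in the tests
against an independent implementation, and the pathway-averaging core of
Nei–Gojobori against exhaustive enumeration over all sense-codon pairs
with up to two differences. Saturated pairs (p ≥ 3/4, or a logarithm
domain violation) are flagged rather than silently clamped; tree building
refuses saturated matrices. Mutational pathways through stop codons are
excluded from the Nei–Gojobori average unless every pathway is blocked,
and changes *to* stop codons count as nonsynonymous in site counting.

Trees are neighbor-joining (Saitou–Nei agglomeration); negative branch
lengths, an artifact of NJ on noisy matrices, are clamped to zero with
the deficit moved to the sister branch so path lengths stay consistent.
Bootstrap support resamples alignment columns with replacement, rebuilds
the tree per replicate, and counts clade recurrence (seeded, hence
reproducible; the conventional 1,000 replicates is the default).

Lineages are the maximal clades, on the midpoint-rooted supported tree,
whose support meets `min_support` (default 70%) and whose internal
divergence stays within `max_intra` (default 0.04 substitutions/site).
Both thresholds are exposed because no authoritative values exist;
singleton lineages are allowed, as observed in real data. Ids are
assigned in discovery order unless a legacy map pins specific alleles to
specific ids.

Names follow `Mamu-LILRB1*001:01:01:01`: four-letter taxon prefix (first
two letters of the genus plus the first two of the species — the
published examples Mamu, Mafa and Paha all follow this pattern, even
though one textual description says "last two"), gene, a 3-digit lineage
field, and up to three 2-digit fields. Because the field-assignment
algorithm is not specified anywhere, new alleles are classified against
their lineage's first allele: any nonsynonymous coding difference opens a
new field-2 value; otherwise a synonymous coding difference opens
field 3; otherwise (non-coding differences only) field 4. The `Sp`
suffix marks alleles described from splice-variant transcripts. The
grammar is a strict bijection (`format_name()`/`parse_name()`).

## Diversity statistics

The variability profile counts unique residues per alignment column,
excluding gap states by default (it counts amino acids, not indels).
S/NS mutation density classifies, per variable codon column, each
observed alternative codon against the column's majority codon —
consensus-relative because no reference allele is designated anywhere —
and normalizes per-exon counts by exon coding length. A codon changed at
several positions counts once, by its net residue effect, to avoid double
counting. Domain-sharing groups partition alleles by exact deduced
peptide over D1, D2 or D1+D2. Residue frequency tables per position
back the stacked-bar views and report invariant positions.

## Numerical choices and degenerate inputs

* Ties in clustering consensus go to the lexicographically first base;
  ties in demultiplexing leave reads unassigned; NJ inherits its
  deterministic agglomeration order from the distance matrix.
* `align_transcript()` requires internal blocks of ≥ 12 bp and seeds of
  20 bp; transcripts that cannot be derived exactly raise a typed
  no-derivation error rather than returning a partial chain.
* Distance functions abort on empty comparable columns; Nei–Gojobori
  aborts on internal stop codons and frame violations.
* Sequence sets of unequal length (indel-bearing alleles) are aligned
  with the system `mafft`; equal-length sets pass through unchanged.
* All stochastic stages take explicit seeds; `run_pipeline()` derives
  every stream from the single configured seed, and identical
  config + seed give identical reports.

## Problem sizes used by the tests

The test suite runs the full pipeline at the generator's default scale
(3 lineages × 4 alleles, 20 samples × 500 reads) under both error-free
and 0.001-error conditions, with 100 bootstrap replicates in the
phylogeny stage of those end-to-end runs and the default 1,000 available
for analyses where bootstrap precision matters. Property suites
(round-trip of the event catalog and its pairwise combinations,
codon-pair enumeration, quartet topologies) are exhaustive at their
natural sizes.

## Known limitations

* Exact-match assignment cannot rescue reads whose every copy carries an
  error; allele-level calls are robust (clean canonical reads are
  plentiful at CCS accuracy) but per-read assignment rates drop with the
  error rate.
* The clustering radius (99.5%) cannot separate two alleles whose reads
  are closer than the radius *and* have no error-free copies; the exact
  haplotype anchoring removes this failure mode for clean reads only.
* Lineage assignment assumes lineages are monophyletic on the NJ tree;
  recombinant alleles would violate this silently.
* The pipeline's external-input mode (FASTQ + FASTA + barcode TSV) runs
  filtering, demultiplexing and exact-match calling, but library growth
  requires genomic alleles with models, which external callers must
  supply through the simulation-free API (`reconcile_cdna_gdna()`).
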