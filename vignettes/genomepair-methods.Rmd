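---
title: "Methods: classifying and triaging gene differences between paired assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and triaging gene differences between paired assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomepair)
```

## The problem

Two high-quality assemblies of the same species, one annotated by lifting
the other's annotation across, share gene and transcript identifiers. Most
genes will be identical or nearly so; the scientifically interesting residue
is the small set of genes whose protein products genuinely differ between
the two individuals, and the assembly-level features (donor-filled sequence,
mitochondrial insertions, ribosomal DNA arrays, paralog copy-number
changes) that contextualise them. `genomepair` implements that comparison
as a deterministic, testable pipeline over standard files (FASTA, GFF3,
VCF, PAF, BED).

All internal coordinates are 0-based half-open; GFF3 and VCF are converted
at the boundary and an interval printed as start–end spans `end - start`
bases. Lowercase in FASTA is meaningful (donor provenance) and is never
normalised on read.

## Effect classification

For each shared transcript the two CDS are extracted (spliced in
transcription order, minus strand reverse-complemented) and compared:

1. Byte-identical CDS → `identical`.
2. Identical translations → `synonymous`.
3. Otherwise, features are detected on a global DNA alignment and the most
   severe one wins.

Alignment uses Needleman–Wunsch with affine gaps. The scoring parameters
are conventional rather than derived: DNA match +2 / mismatch −3, gap open
5 / extend 2; proteins BLOSUM62 with open 11 / extend 1. A gap of length L
costs `open + L·extend`. Identity is matching columns over *all* alignment
columns, terminal gaps included, so a missing terminus depresses identity
rather than being silently clipped. All scores are overridable per call.

Feature definitions:

* **Truncation (5′/3′)** — a terminal alignment gap in the subject that
  removes the reference terminus including the whole start (or stop) codon.
  Because gap placement inside repeats is ambiguous, a deletion run counts
  as terminal when it is *shiftable* to the terminus (deleting `ref[i..j]`
  equals a 5′-terminal deletion iff `ref[1..i−1] == ref[j−i+2..j]`), not
  only when the aligner happened to put it there. Truncation gaps are
  excluded from the frameshift test.
* **Frameshift** — any remaining single indel whose length is not a
  multiple of 3. We considered triggering on the *net* indel instead; the
  per-indel rule is stricter and matches the definition of a frameshift as
  a reading-frame disruption, so it is the default (the net is still
  computed and used for the in-frame direction).
* **Stop gained** — a premature stop codon in the subject translation
  (a stop before the final complete codon).
* **Start lost** — the subject's first codon is not ATG *and* is aligned to
  the reference start (no 5′ terminal gap). The ordering matters: every 5′
  truncation also removes the ATG, so a naive "first codon ≠ ATG" test
  would shadow all truncations. Detection therefore separates substitution
  at the start (start loss) from loss of the start (truncation); the
  severity order between the two remains configurable.
* **In-frame insertion/deletion** — indels all multiples of 3, direction by
  the sign of the net length difference.
* **Nonsynonymous** — at least one substituted aligned position; also the
  fallback when nothing else fires.

When several features co-occur the default severity order is
`frameshift > stop_gained > start_lost > truncation_5p > truncation_3p >
inframe_* > nonsynonymous` — most protein-disruptive first. The order is a
parameter of `classify_cds()`/`classify_transcripts()` because no single
ordering is canonical.

Transcripts without CDS in either annotation are compared on spliced exon
sequence and receive a DNA identity only (category `NA`). A transcript
coding on one side only is treated as a structural annotation defect and
raises an error, distinct from an unmapped transcript (absent from the
join, counted in an attribute).

Degenerate inputs: empty sequences are rejected before alignment; proteins
that translate to the empty string (immediate stop) get amino-acid identity
0 rather than an alignment error; ambiguity codons translate to `X`.

## Gene rollup, summary and zygosity rescue

A gene's representative transcript is its isoform with the highest protein
identity to its counterpart, ties broken by smallest transcript id — so an
intact isoform "rescues" a gene at the isoform level before any variant
logic runs. The category summary counts conserved genes
(`identical + synonymous`), rounds the conserved fraction half-up to a
whole percent (matching how such tables are printed), and totals the
deleterious classes (start loss, stop gain, truncations, frameshift).

Zygosity rescue then asks whether each candidate's damage is real on both
haplotypes: variants are filtered to homozygous and non-SNP (a SNP cannot
shift a reading frame; note an equal-length multi-base substitution counts
as non-SNP), intersected with the union of CDS exons over *all* transcripts
of the gene in the coordinate system the variants were called in, and
deduplicated by (sequence, position, ref, alt) within the gene so exon
sharing between isoforms does not inflate site counts. A gene survives iff
at least one distinct site remains. The original analysis also used manual
inspection at this step; the package deliberately replaces that with the
deterministic rule above, so its funnel is reproducible but slightly more
permissive than a curated one.

## Assembly-level features

* **Provenance**: donor bases are exactly the lowercase residues; uppercase
  `N` is counted as non-donor because provenance is purely case-driven.
  Ratios round half-even (R's `round()`) to 4 decimals; the total row sums
  bases before dividing.
* **NUMT validation**: supporting reads are primary alignments containing
  the whole insertion with at least `flank_bp` (default 500, inclusive —
  exactly 500 passes) on both sides. Support is monotone non-increasing in
  the flank requirement.
* **rDNA units**: candidate array alignments are filtered strictly
  (> 1,000 bp and > 98.5 % identity — boundary values fail) and merged into
  approximate loci for masking. Labeled subunit placements are grouped
  greedily left-to-right per sequence and strand; three consecutive
  placements labeled 18S, 5.8S, 28S in transcription order (mirrored on the
  minus strand) within `max_unit_span` form a valid unit. The span default
  (45 kb) is the scale of one human rDNA repeat unit; "same locus" is not
  given a distance anywhere authoritative, so this is a package choice and
  configurable. Strict adjacency is assumed: an intervening placement
  breaks the unit. Leftover placements are rejected with a reason
  (`order`, `span`, or `incomplete`), and an audit lists any unit that
  overlaps a gene of the main annotation.

## Paralog clusters

Genes cluster by single linkage over the relation "global identity ≥ 0.9
and aligned (both-non-gap) columns cover ≥ 0.9 of *both* sequences". Both
choices are the stricter reading of the underlying criterion: identity is
per alignment column (not per shorter sequence), and coverage is required
bidirectionally (configurable). Single linkage is used because membership
requires similarity "to at least one other member". Cluster ids are
deterministic (numbered by smallest member label). Because identity and
coverage are both bounded above by `min(len)/max(len)`, pairs failing that
bound are never aligned — an exact pruning, not a heuristic. Copy-number
classes per cluster: `none`, `lost_one` (one fewer subject member),
`lost_multiple`, `absent_in_subject`, `gained`.

## What the simulator emulates — and what it does not

`simulate_genome_pair()` builds a reference chromosome of multi-exon
protein-coding genes (ATG start, terminal stop, no internal stop, CDS a
multiple of 3), plants exactly one effect per gene according to a category
plan, and derives the subject chromosome, lifted annotation, and VCF from
the same edits, so classification, rescue, and the file round-trips can be
checked against exact truth. Default study conditions: 50 genes covering
all ten categories (the mix leans towards `identical` as real genomes do),
2–4 exons per gene, CDS 150–300 bp, one isoform per gene; deleterious edits
are heterozygous with probability 0.4 (benign 0.5); five rDNA units with
wrong-order/incomplete/short/low-identity decoys; one 13,781 bp NUMT with
26 spanning reads and 10 decoys; 500 bp donor patches lowercased at each
sequence start. One effect per gene keeps category recovery unambiguous;
feature co-occurrence is tested separately at the CDS level.

Planting choices worth knowing: deleterious edits are deliberately non-SNP
(frameshifts are 2-bp deletions, start losses and stop gains whole-codon
replacements, truncations multiple-of-3 terminal deletions that include the
start/stop codon) so that every homozygous deleterious gene is recoverable
by the rescue rule; truncations are genomic deletions rather than
annotation-only edits so they carry a VCF record. A configurable fraction
of heterozygous genes keeps the intact haplotype in the subject sequence,
emulating an assembly that collapsed to the undamaged copy (those genes
classify as identical while their variant stays in the VCF).

The simulator does *not* emulate: sequencing error or read-length
distributions (NUMT reads are PAF records, not sequences), UTRs or
alternative isoforms, compound effects on one gene, diploid output, rDNA
morphotype structure, or alignment noise in the lift-over itself (subject
annotations are derived exactly). Passing the closed loop therefore shows
the *logic* is correct under clean inputs, not that the pipeline is robust
to noisy alignments or mis-lifted annotations.

## Numerical choices and test design

* Rounding: protein length ratios and identities print to 3 decimals,
  provenance ratios to 4 (half-even), conserved percent to a whole percent
  (half-up). Identity comparisons in tests use exact equality of doubles
  derived from integer counts.
* The alignment oracle in the tests is an independent Gotoh DP. Optimal
  alignments can tie with different match/column counts, so the oracle
  enumerates the identities of *all* optimal alignments and requires the
  implementation's identity to be a member of that set; a single-traceback
  oracle would intermittently disagree for reasons that are not errors.
* Problem sizes: unit tests run the simulator at 10–20 genes, the
  closed-loop and acceptance runs at the default 50 genes, 200 random
  pairs for the alignment oracle, 25 sequences for the clustering oracle,
  and a 203-unit rDNA layout for the subunit accounting. These sizes were
  chosen to exercise every code path with comfortable margins on a single
  CPU.
* Determinism: a single integer seed drives every simulation draw; the
  pipeline itself uses no randomness, writes tables with fixed column
  order and formatting, and its JSON summary omits wall-clock timings so
  reruns are byte-identical.

## Known limitations

* The ten-category scheme assigns one label per transcript; a gene both
  frameshifted and truncated reports only the more severe label (the
  severity order is configurable but single-valued).
* Exhaustive pairwise clustering is quadratic and intended for desk-scale
  inputs (hundreds to a few thousand sequences), not whole-proteome runs —
  there is no k-mer prefilter beyond the exact length-ratio bound.
* `start_lost` is defined against the standard ATG start; non-AUG
  initiation and alternative genetic codes are out of scope, as are
  selenocysteine recoding and codon-aware alignment.
* The VCF reader handles single-sample files and takes the first non-ref
  allele of a genotype; multi-sample semantics are out of scope.
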