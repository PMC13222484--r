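---
title: "Haplotype-aware annotation refinement: models, rules and design choices"
author: "haprefine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-aware annotation refinement: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haprefine)
```

## The problem

When a heterozygous diploid genome is assembled into two phased haplotypes
and each haplotype is annotated independently, the two annotations disagree
far more than the underlying sequences do. A gene model present on one
haplotype and missing on the other may reflect real biology — the locus was
deleted, or a variant destroyed the reading frame — but much more often it is
an annotation artifact: the gene predictor simply missed the second copy, or
fragmented it into pieces, or fused it with a neighbour. These artifacts
inflate the apparent count of haplotype-specific genes and contaminate every
downstream comparison of allelic sequence and expression.

`haprefine` implements a haplotype-aware refinement of such paired
annotations. The core idea is to treat the two haplotypes as mutual evidence:
a gene called on haplotype 1 whose counterpart region on haplotype 2 is
intact should also yield a gene there, and when it does not, the package
either finds disabling evidence (making the gene a credible
haplotype-specific call) or repairs the annotation.

## The refinement procedure

The pipeline (`runRefinement()`) runs a fixed stage order; every gene added
or removed is recorded in an audit log and the gene counts are reconciled
exactly at the end.

1. **Cross-haplotype protein matching.** Peptides of the representative
   (longest) transcript of every gene are aligned across haplotypes with
   local alignment (BLOSUM62, affine gap open 10 / extend 0.5). Rather than
   an all-vs-all scan, candidate pairs are pre-screened by projecting each
   gene span through the synteny blocks and collecting genes within a 20 kb
   window on the other haplotype; for collinear gene pairs this is equivalent
   to a nucleotide-level pre-alignment of gene sequences against the other
   genome, done through one mechanism instead of two. Hits with identity or
   coverage below 80% are discarded for the one-to-one screen; coverage for
   that screen is the larger of the query- and subject-side coverages, and
   the per-side values are kept because split fragments by nature cover only
   part of their counterpart.
2. **Clustering.** Single-linkage clusters over the retained-hit graph.
   A cluster containing genes of only one haplotype marks those genes as
   *candidate haplotype-specific*.
3. **Validation of candidates.** Each candidate is tested, in order, against
   three kinds of disabling evidence at its counterpart locus:
   (i) a HIGH-impact variant (start loss, premature stop, frameshift,
   splice-site loss) called by the built-in consequence engine;
   (ii) structural-variant evidence — a deletion (≥ 50 bp) removing the
   whole gene or at least 50% of its coding bases, a long insertion anchored
   inside coding sequence, or an inversion touching coding sequence;
   (iii) residence in an unaligned region. Candidates with any evidence are
   *high-confidence haplotype-specific*; the remainder are *candidate
   unannotated* genes — putative annotation errors.
4. **Rescue.** Candidate unannotated genes are projected through the synteny
   blocks onto the other haplotype. A projection is accepted only when every
   projected intron has intact GT..AG dinucleotides, the projected ORF is
   intact (ATG start, no internal stop, terminal stop, length divisible
   by 3), the target region carries no existing model, and — when
   splice-junction hints are supplied — every projected intron matches a
   hinted junction. Rejected candidates stay in a report; nothing is dropped
   silently.
5. **Split/merge repair.** One source protein aligning to two or more
   adjacent target genes whose hit intervals tile near-disjoint parts
   (< 20% pairwise overlap) of the source is a *split* call; the symmetric
   pattern is a *merge*. "Adjacent" means the same sequence, at most 10 kb
   apart, with no intervening gene. Repairs project the source model(s) over
   the fragment/fusion models under the same gates as rescue; failures leave
   the original models in place, flagged unrepaired.
6. **Filters.** Genes whose span is covered by annotated transposable
   elements for strictly more than 30% are removed. A gene is a putative
   false positive only when it simultaneously is mono-exonic and shorter
   than 300 bp, lacks any protein domain, has zero expression in every
   sample, and has no homology hit at the 80/80 level; a missing evidence
   table leaves its criterion unmet, so genes are never removed for lack of
   input data.

After refinement the specificity analysis (steps 1–3) is re-derived on the
refined annotations, so the before/after reduction of candidate unannotated
genes is measured by the same instrument.

### The variant-consequence engine

`classifyVariantEffect()` assigns exactly one consequence per
(variant, transcript) by editing the coding sequence in CDS coordinates and
re-translating, plus positional splice checks on the first and last two
bases of each intron. The fixed severity order is start_lost > stop_gained >
splice_donor/acceptor_lost > frameshift > stop_lost > inframe_indel >
missense > synonymous; the first six are HIGH impact. Conventions worth
stating: a stop is *gained* only when the edit introduces an internal stop
codon the original CDS lacked (an in-frame deletion that merely brings the
terminal stop closer is an in-frame indel); indels are classified by their
most severe overlapping consequence when they span an exon–intron boundary;
an insertion anchored exactly on an exon edge falls on the intron side;
effects are evaluated on the representative transcript only, and variants
are applied independently of one another. A stop gained in the final
stretch of the peptide is still HIGH — no attenuation rule is applied.
The test suite holds this engine against an independent oracle that rebuilds
the mutated locus genomically, remaps the exon boundaries, re-extracts and
re-translates; the two routes must agree on 1000 random cases.

### Coordinate liftover

Internally all intervals are 0-based half-open; GFF3, VCF and synteny I/O
use the 1-based inclusive conventions of those formats. Liftover is
piecewise-linear within two-sided blocks (SYN, INV, TRANS, DUP); INV blocks
reverse coordinates and flip strand; NOTAL regions and one-sided INS/DEL
records are unmapped and reduce the mapped fraction. Where a DUP block
overlaps a non-duplicated block on the source side, the non-DUP block wins,
so duplicated regions map deterministically to their primary copy. A
projection with under 50% of exonic bases mapped fails outright; exons that
do not map fully and contiguously are dropped, which downstream gates then
catch via the ORF check.

## Allelic analysis

Bi-allelic pairs require shared cluster membership *and* lifted-span
overlap; among multiple candidates the pair with the greatest lifted overlap
wins (ties: alignment score, then lexicographic id). Pairs never expressed in
any tissue, and pairs with byte-identical coding sequences, are removed
before expression states are assigned — identical alleles cannot be
distinguished by allele-specific quantification, so classifying them would
be vacuous.

Per tissue, the observed TPM pair is normalized to proportions and assigned
to the category whose ideal vector is nearest in Euclidean distance:
Balanced (0.5, 0.5), H1_dominant (1, 0), H2_dominant (0, 1). The vectors are
a design choice (the category names and the minimum-distance criterion are
standard; the vectors themselves are not dictated by any formula), and their
consequence is transparent: a pair is dominant exactly when one allele's
share exceeds 0.75, the midpoint between 0.5 and 1. Before any distance is
computed, a tissue with summed TPM below the expression floor (default
0.5 TPM) is NE; the floor is applied per tissue, before normalization, since
proportions of near-zero counts are noise. Ties resolve toward Balanced.

The tissue-specificity index is
$\tau = \sum_i (1 - x_i/x_{\max})/(n-1)$ on the max-normalized profile:
0 for uniform expression, 1 for single-tissue expression, undefined (NA) for
an all-zero profile, and invariant to uniform scaling. A transcript is
called tissue-specific when its highest-to-second-highest TPM ratio strictly
exceeds 3 (with a zero second-highest and positive maximum counting as
specific); an alternative highest-to-lowest rule is exposed as
`rule = "lowest"` because both definitions circulate and they disagree on
profiles with a long low tail — the top-two rule is the default as the more
conservative reading. Candidate non-coding transcripts under 200 bp are
rejected; the rest are intergenic only with zero overlap with any
protein-coding gene span (strand-agnostic), and a transcript is
TE-associated when TE intervals cover strictly more than half of its span.

## The synthetic diploid generator

`simulateHaplotypePair()` builds the fixture world every claim in this
package is tested against. Haplotype 1 carries simulated protein-coding
genes — 1 to 6 exons, 100–400 codons, canonical GT..AG introns, ATG start
and terminal stop — placed with at least 2 kb of intergenic space on
chromosomes of configurable length. Haplotype 2 is derived by planting:

* SNPs at 7.6/kb and 1–10 bp indels at 2.1/kb, the small-variant densities
  typical of a heterozygous diploid crop genome. Indels are intergenic;
  random SNPs avoid exons and splice dinucleotides so that unbroken genes
  stay coding-identical, while each gene carried by both haplotypes receives
  2–4 planted *synonymous* third-position SNPs so allelic coding sequences
  differ without changing any peptide.
* Structural events — deletions, insertions, inversions, tandem
  duplications, translocations and unalignable (NOTAL) replacement
  segments — in intergenic space, plus whole-gene deletions for hemizygous
  genes. Every event is emitted both as anchored VCF records (inversions,
  duplications, translocations and NOTAL segments decompose into co-located
  deletion+insertion records) and as synteny blocks, and the haplotype-2
  sequence is assembled by an independent segment walk, so "apply the VCF to
  haplotype 1 and obtain haplotype 2 byte-exactly" is a real cross-check of
  two code paths, not a tautology.
* Annotation errors with recorded truth: dropped models (sequence intact,
  model absent), split models (one gene annotated as two in-frame
  fragments), merged models (two adjacent same-strand genes fused into one),
  spurious mono-exonic models of 150–280 bp with no expression, no domains
  and no homolog, genes disabled by exactly one uniformly chosen HIGH
  variant, and hemizygous genes under whole-gene deletions.
* Expression tables with planted per-tissue allelic categories. Each
  bi-allelic pair draws a base category (Balanced 60%, each dominant 15%,
  NE 10%); a third of expressed pairs get one tissue switched to a different
  category, emulating the roughly one-third of bi-alleles with divergent
  cross-tissue allelic patterns seen in real diploid crops. Dominant shares
  are drawn at 0.92 ± 0.02 (clamped to ≥ 0.85), balanced shares at
  0.5 ± 0.02, so planted categories sit well inside the classifier's
  decision regions at the default dispersion.

One seed drives a single RNG stream; identical seeds give byte-identical
fixture files.

**What the generator does not emulate** — and hence what green tests do
*not* establish about real data: sequencing or assembly error, alternative
isoforms and UTRs (models are CDS-exact), TE sequence content (intervals
only), genes overlapping structural-variant breakpoints in complex nested
arrangements, mapping noise in expression quantification, and annotation
errors correlated with repeat content. Performance on the battery is an
upper bound: it shows the machinery is correct where the planted truth is
unambiguous, not that real annotations are this recoverable.

## Numerical and procedural choices

* **Problem sizes.** The default battery is 500 genes on two 2.5 Mb
  chromosomes with 5% dropped, 3% split, 2% merged, 5% spurious, 5%
  disabled and 2% hemizygous genes — large enough that every planted error
  class appears tens of times, small enough to simulate and refine in about
  a minute.
* **Thresholds** (80/80 retention, 50 bp SV floor, 50% coding deletion,
  30% TE overlap, 300 bp / four-criteria false-positive rule, 200 bp
  lincRNA floor, 50% TE association, ratio-3 tissue specificity) are strict
  or non-strict exactly as their source wording implies ("more than 30%"
  removes 0.31 and keeps 0.30; "at least 50%" keeps 0.50 in); boundary
  behaviour is pinned by tests.
* **Determinism.** Refinement contains no randomness; ties in the longest
  transcript, effective-allele choice and feature ordering are broken
  lexicographically, so two runs on identical inputs are byte-identical.
* **Direction of repair.** Split/merge correction treats haplotype 1 as the
  source and rewrites haplotype 2 by default (configurable). A fusion on one
  haplotype versus a genuine pair on the other is not distinguishable from
  protein alignment alone; junction hints arbitrate, and without hints the
  projection gates (splice/ORF) still have to pass before anything is
  rewritten.
* **Degenerate inputs.** Empty model lists, empty variant sets and silent
  simulator configurations (all rates zero) are legal and covered by tests;
  an all-zero expression profile yields NA for τ and "not specific".

## Limitations

Only diploids are handled (no polyploid generalization); compound effects of
multiple variants on one codon are not modelled; liftover has no chain/net
support and maps duplications to a single primary copy; rescue emits
CDS+exon models without UTRs; coding-potential assessment of non-coding
transcripts is out of scope (the positional lincRNA rules assume candidate
non-coding input). The protein aligner is exact dynamic programming, sized
for desk-scale proteomes reached through the synteny pre-screen; genuinely
unplaceable genes (no synteny context at all) are only compared within
their homology cluster.
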