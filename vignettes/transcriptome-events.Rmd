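---
title: "Methods: chimeric RNAs, SNPs and allele-specific expression from RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chimeric RNAs, SNPs and allele-specific expression from RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txevents)
```

This vignette documents the models and procedures the package implements,
the tunable parameters and their defaults, the design choices taken where
the methods literature leaves the decision open, what the synthetic-data
generator does and does not emulate, and the package's numerical
conventions and known limitations.

## Coordinate and sequence conventions

All internal coordinates are 1-based inclusive, the GTF/VCF convention;
BED-style inputs are shifted on read (`start + 1`) and back on write. A
genomic interval has length `end - start + 1`. Sequence extraction is
strand-aware: for a minus-strand interval the reverse complement of the
forward-strand substring is returned, so extracted sequence always reads
in transcription direction. Only biallelic single-nucleotide variants are
analysed; multi-allelic VCF records and indels are skipped with a logged
count.

## Expression quantification

RPKM is computed as $10^9 \, C / (N \cdot L)$ per gene, where $C$ is the
gene's read count, $N$ the library-level number of mapped reads and $L$
the *union* of the gene's exons across all its transcripts. The union
(rather than the longest transcript) is the standard gene-level reading of
"per kilobase of exon per gene"; it never double-counts overlapping
exons. Whether $N$ counts all mapped or uniquely mapped reads is a
property of the upstream counting step; the package takes $N$ as an
explicit argument and documents it as "mapped reads".

Detection is strict (`RPKM > 0.1`), so a gene at exactly the threshold is
not detected. Bin edges follow the usual reporting conventions: weak
`< 5`, abundant `≥ 100` (inclusive), highly expressed `> 1000`
(exclusive). Percentages are over detected genes and printed to one
decimal. The bins partition the detected set and the highly-expressed
genes are a subset of the abundant bin; both properties are tested.

## Chimeric RNA analysis

**Consensus.** Fusion callers disagree on breakpoint bases far more often
than on partner genes, so two callers' candidate lists are intersected by
*unordered gene pair*; breakpoint agreement within a tolerance (default
10 bases) is recorded but not required. Coordinates of a consensus row
come from the first caller (first-caller precedence). Matching by gene
pair rather than junction coordinate is a design choice: the alternative
(coordinate matching) would make the consensus fragile to one-base caller
disagreements, and the tolerance remains exposed for users who want it
stricter.

**Structural classification** is total and ordered, most specific rule
first:

1. different chromosomes → interchromosomal;
2. partners sharing an exon with identical coordinates → adjacent /
   overlapping (overlap is checked before the orientation rules because
   overlapping genes also satisfy them);
3. partners whose spans overlap or lie within `adjacency_max_gap` bases
   (default 100,000) with **no third gene wholly inside the gap** →
   adjacent: same strand → read-through; opposite strands with the 5′
   ends facing the gap → divergent, with the 3′ ends facing → convergent;
4. otherwise → intrachromosomal.

"Adjacent" has no standard quantitative definition; the 100-kb default
with the no-intervening-gene condition captures "neighbouring genes"
while remaining configurable. For opposite-strand pairs the facing ends
are determined purely from strand and relative order: if the left-hand
gene is on the minus strand both 5′ ends point into the gap (divergent),
otherwise both 3′ ends do (convergent).

**Canonical splice check.** A junction is canonical when the strand-aware
genomic dinucleotide immediately downstream of the 5′ breakpoint is `GT`
(donor) and the one immediately upstream of the 3′ breakpoint is `AG`
(acceptor); minus-strand partners step toward decreasing coordinates with
complemented bases. Breakpoints within 2 nt of a chromosome end are
reported non-canonical with an `splice_undetermined` flag rather than
guessed.

**Junction-spanning reads** are counted by exact substring search: the
probe is the last `probe_flank` transcribed nucleotides of the 5′ segment
joined to the first `probe_flank` of the 3′ segment (default 20 + 20),
and a read matches if it contains the probe or its reverse complement;
each read counts at most once. This is the in-silico analogue of grepping
the FASTQ and is deliberately alignment-free.

**Cross-species homology filter.** Alignment itself (BLAST against
another species' chimera catalogue) is out of scope; the package consumes
tabular hits with query coordinates relative to the junction and accepts
a hit only when ≥ 20 nt are mapped on *both* sides. Coordinates use
negative positions for the 5′ side and positive for the 3′ side, with no
position zero.

## SNP filtering and annotation

Filtering removes, in order: (1) variants on excluded chromosomes
(configurable name patterns, default scaffold-like prefixes and `MT`);
(2) hard-filter failures `FS > 30.0`, `QD < 2.0`, `DP < 5` — strict
inequalities, so boundary values are retained, and missing values fail;
(3) clusters: among the per-chromosome sorted survivors, any 3
consecutive variants spanning ≤ 35 bases (inclusive span) are all
removed, with overlapping windows unioned. Each removal is attributed to
exactly one rule (first failing, in the order above) so per-rule counts
plus retained records always sum to the input — a tested invariant.

Consequence annotation re-translates codons: for a coding position the
reference codon is read strand-aware from the genome using the
transcript's CDS coordinate map, the alternate base is substituted
(complemented on the minus strand), and the amino acids compared —
identical → synonymous, different → nonsynonymous, stop gained or lost →
stop-affecting. Intronic positions within `splice_region_window` nt of an
exon–intron boundary (default 8, a common annotator convention) are
splice-region; exonic non-CDS positions are 5′/3′ UTR by transcription
direction; positions within `flank_window` nt of a gene span (default
5,000) are upstream/downstream relative to the gene's strand. When a
variant touches several transcripts or genes the most severe class wins,
with the total order stop-affecting > nonsynonymous > synonymous >
splice-region > 5′ UTR > 3′ UTR > intron > upstream > downstream >
intergenic. The UTR-vs-UTR and upstream-vs-downstream order is arbitrary
(the classes are disjoint within one transcript); it exists only to make
the precedence total. Exonic positions of a transcript without CDS
records fall back to intron severity. The annotator is tested for
equivalence against an independent oracle that rebuilds each spliced CDS,
substitutes the base and re-translates the whole protein.

Summaries: the six unordered substitution types, transition
(`A/G`, `C/T`) and transversion counts, Ts/Tv ratio (two decimals; an
all-transition input is reported with an infinite flag rather than a
number); per-gene SNP counts where a SNP increments *every* gene whose
span contains it (overlapping genes each counted) with histogram bins
< 10, 10–25, > 25; known/novel partition against a catalogue, requiring
allele-pair agreement at the matched position by default (position-only
matching is a flag) to avoid false "known" calls; QTL overlap with
inclusive boundaries, per-trait counts using set semantics (a SNP in
three regions of two traits counts once per trait and once overall).

## Allele-specific expression

Eligibility requires each allele ≥ 3 reads and total depth ≥ 10
(boundaries inclusive). The allelic ratio is the alternate count over
total. The binomial null success probability is fixed at 0.5; no
reference-mapping-bias correction is applied, matching the upstream
procedure the package mirrors, but `ase_bias_diagnostics()` reports the
global alternate fraction so users can see systematic bias. The test is
two-sided by doubling the smaller tail, capped at 1 — the simplest
defensible two-sided definition, chosen over the minimum-likelihood
method used by `binom.test()` and verified against tail enumeration in
the tests. BH correction runs across all eligible (post-filter) sites —
not all input sites — because tests are only performed there. A site is
called when its ratio is above 0.65 or below 0.35 (strict) and its
q-value is below 0.05. Nonsynonymous enrichment among ASE calls uses the
two-sided Fisher exact test on the 2×2 ASE × nonsynonymous table; an
empty margin returns p = 1 with a degenerate flag.

## The synthetic-data generator

The generator is first-class, tested code: its purpose is to produce
inputs whose correct answers are known *by construction*, so that every
downstream stage can be verified exactly.

* **Genome and annotation.** Two 600-kb chromosomes carry designed
  adjacent gene pairs in every orientation the fusion plan needs,
  exon-sharing (overlapping) pairs, and background genes used to form
  intrachromosomal pairs (two genes with a third wholly between them) and
  interchromosomal pairs; a gene-free 10-kb scaffold and 5-kb MT
  contig exercise the chromosome-exclusion filter. Genes have 3–5 exons
  of 120–240 nt with 300–900-nt introns and a CDS whose length is a
  multiple of three.
* **Fusions.** For each planned candidate the generator plants the
  donor/acceptor dinucleotides in the genome (GT/AG for canonical
  candidates — the planted fraction defaults to 154/163 — and a
  non-canonical dinucleotide otherwise), then emits two caller tables
  whose intersection is exactly the planned consensus set plus
  caller-specific extras, and 90-nt junction reads embedding each
  candidate's probe at a random offset, half reverse-complemented. The
  first candidate always receives exactly 37 spanning reads as a fixed
  worked-example fixture.
* **Variants.** Consequence classes are realised by construction: coding
  substitutions are chosen by enumerating the reference codon's nine
  substitutions and picking one with the intended effect; non-coding
  classes are placed in the appropriate compartment with clearance rules
  (flank positions > 5 kb from any other gene, intron positions > 8 nt
  from any exon boundary, nothing inside another gene's exons) so the
  most-severe rule cannot reassign them. Positions are kept ≥ 36 bases
  apart except in designed clusters (3 SNPs spanning 25 bases).
  Transitions are preferred with probability 0.7 where the class allows a
  choice, giving a realistically transition-heavy spectrum.
* **Allele counts.** 5,000 sites, 20% truly allele-specific with
  alternate-allele probability 0.8 and the rest at 0.5, with Poisson
  depths around 100 — the regime in which the caller's operating
  characteristics are assessed (sensitivity > 0.9, realised
  false-discovery proportion ≤ 0.10 in the tests). Nonsynonymous labels
  are drawn with probability 0.12 at true-ASE sites versus 0.04
  elsewhere, giving the enrichment test real signal.
* **Catalogue and QTL.** The known-SNP catalogue covers 93.6% of the
  variants planned to survive filtering, plus catalogue-only entries and
  same-position/different-allele decoys that must *not* match under
  allele-aware comparison. QTL regions (default 24 of 20–60 kb) are
  non-overlapping within each of eight production-trait labels.

Each artifact draws from its own random stream derived from the master
seed, so regenerating one artifact never perturbs the others, and a
given seed/configuration yields byte-identical files.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: read alignment and its biases (the allele
counts are drawn directly, with no reference-mapping bias), sequencing
error, caller-specific evidence models (support counts are Poisson, not
ChimeraScan/FusionMap scores), overdispersed allelic counts
(beta-binomial behaviour of real ASE data), linkage between nearby sites,
and realistic gene density or chromosome-scale structure. Results on the
synthetic data certify the *logic* of each stage, not the error rates to
expect on a sequencing run.

## Numerical choices and degenerate inputs

Percentages are rounded to the precision used in reporting: one decimal
for expression bins, chimera classes and the dbSNP partition; two
decimals for QTL overlap, the substitution spectrum and Ts/Tv. Ties in
the top-expression table break by gene identifier. Empty inputs return
empty summaries with a warning rather than errors; an all-transversion
(or all-transition) spectrum and an empty Fisher margin are flagged
rather than silently divided. q-values from BH are returned in the
original input order and are permutation-invariant, which is tested.

Problem sizes in the tests and the acceptance script were chosen so the
complete run stays comfortably interactive: ~60 genes on two 600-kb
chromosomes, ~320 variants, 27 consensus fusion candidates with ~600
junction reads, and 5,000 allele-count sites.

## Known limitations

* Only biallelic SNVs; no indels or structural variants.
* GTF parsing covers the gene/transcript/exon/CDS feature set; GFF3
  nesting beyond that is out of scope.
* No de novo fusion discovery from reads, no caller score reproduction,
  no chimera ORF prediction; the homology step consumes precomputed
  alignment hits.
* No haplotype- or gene-level ASE aggregation and no overdispersion
  model; the binomial test is anti-conservative when counts are
  overdispersed, which the bias diagnostics cannot fix, only reveal.
* The consequence annotator assigns one class per variant (most severe);
  per-transcript annotation tables are not produced.
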