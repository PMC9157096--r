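---
title: "Classifying transcriptional vs post-transcriptional regulation from intron signal"
author: "intronDE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying transcriptional vs post-transcriptional regulation from intron signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronDE)
library(SummarizedExperiment)
```

## The model

In a total-RNA, rRNA-depleted library the read population is a mixture of
mature mRNA (exons only) and nascent pre-mRNA (exons *and* introns). Writing
$\tau_{gc}$ for the transcription rate of gene $g$ in condition $c$ and
$s_{gc}$ for the net mRNA stability (everything post-transcriptional folded
into one multiplier), the expected coverage decomposes as

$$
\mathbb{E}[\text{intron counts}] \propto \tau_{gc}, \qquad
\mathbb{E}[\text{exon counts}] \propto \tau_{gc}\, s_{gc}.
$$

A change in transcription moves both signals; a change in stability moves
only the exon signal. Testing the two count tables independently for
differential abundance and intersecting the outcomes therefore separates
the two regulatory levels — with the caveat that a single-exon gene has no
intron, so for it the intron test is undefined and an exon-only change is
*inconclusive*, not evidence of post-transcriptional regulation.

This decomposition is exactly what the synthetic-data generator emulates
(`simulateCounts()`): negative-binomial counts whose intron mean is
$\tau$-driven and whose exon mean is $\tau\,s$-driven, with transcriptional
differential expression multiplying $\tau$ by $2^{\mathrm{lfc}}$ in the up
tissue and post-transcriptional differential expression multiplying $s$
only.

## The feature catalog

`buildFeatureCatalog()` flattens an annotation to one exon set and one
intron set per gene:

1. exon segments = union of all the gene's isoforms' exons, merged — an
   exon skipped by one isoform but retained by another stays exonic, so
   alternative splicing can never masquerade as intron signal;
2. intron segments = gene span (min start to max end over transcripts)
   minus the exon union;
3. genome-wide purge: any intron region overlapping *any* gene's exon
   segment is trimmed away. Exon evidence wins because an exonic base is
   unambiguous transcript evidence for its own gene, and counting it as
   intronic for a host gene (a nested gene inside another's intron is
   common) would contaminate the nascent-transcription readout.

Two genes' *introns* over the same bases are attributed to both genes:
there is no exon evidence to arbitrate, and a read there is ambiguous at
counting time anyway (it touches two genes and is discarded as such), so
removing the region would only lose bookkeeping information.

The purge is strand-blind by default — a base under an exon on either
strand is never intronic. With `stranded = TRUE` only same-strand conflicts
are purged; that variant suits a strictly strand-resolved counting mode but
weakens the guarantee that intron counts are exon-free, which is why it is
not the default.

Coordinates are held as `GRanges` (1-based closed) throughout and converted
at the BED boundary (0-based half-open). Segments of any width are kept
(`minSegmentWidth = 1`): short intron slivers are rare, harmless to the
counting rule, and dropping them would silently shrink the intron universe.

The whole construction is checked against an independent brute-force
oracle: on random ≤ 10 kb genomes with nesting and isoforms, a per-base
labeler that applies the same three rules by explicit set arithmetic must
reproduce the interval implementation base-for-base (it does, on 200
genomes per run).

## Read counting

A read (all its aligned blocks, summed) is assigned by majority
overlapping-base count to a single (gene, class), with two guards:

- touching features of more than one gene → `ambiguous_multi_gene`,
  discarded but counted;
- exon/intron tie within one gene → exon, consistent with exon precedence
  and robust to one-base boundary jitter.

Uniqueness filtering keeps `NH == 1` reads when the tag exists, else
`MAPQ >= 20`; multimapped reads are poison for intron attribution because
intronic repeats are common. Strandedness defaults to reverse (dUTP
libraries: read antisense to the gene) and is configurable; in the wrong
sense a read is *unassigned*, never miscounted. The six disposition
counters sum to the record total by construction, and the suite checks this
conservation plus exact agreement between counting a simulated SAM and the
simulator's placement record.

## The differential test

Each feature class is tested separately (the two result tables are also
adjusted separately, since they are filtered separately downstream):

- **Normalization** — median-of-ratios: factor$_j$ = median over genes with
  a positive geometric mean of $k_{gj}/\mathrm{geomean}_g$, rescaled to
  geometric mean 1. The median is taken in linear space; DESeq2's log-space
  variant agrees up to the averaging of the two middle genes and is used as
  an independent cross-check in the tests.
- **Dispersion** — per-gene method-of-moments
  $\hat\alpha_g = \max\{0, (s^2_g - \bar\mu_g)/\bar\mu_g^2\}$ with the
  variance pooled within conditions; a trend $\alpha(\mu) = a_0/\mu + a_1$
  fitted by least squares over genes with $\hat\alpha_g > 0$; final value
  $w\hat\alpha_g + (1-w)\alpha(\bar\mu_g)$ with $w = n/(n+4)$ (so 3
  replicates put 4/7 of the weight on the trend), floored at $10^{-8}$.
- **Test** — Wald statistic $\log_2(\hat\mu_A/\hat\mu_B)/\mathrm{SE}$ with
  the delta-method SE from the NB variance $(\mu + \alpha\mu^2)/n$ of each
  condition's mean of normalized counts; two-sided normal p-value;
  Benjamini–Hochberg within the table over tested genes. The variance is
  written purely in terms of normalized counts, which buys exact scale
  invariance (scaling a column together with its size factor changes
  nothing). The reported fold-change adds a pseudo-count of 0.5 to each
  mean so it stays finite; the statistic never uses the pseudo-count.
- **Floor** — genes with mean normalized count `< 1` are marked untested
  (`NA` p-values) rather than dropped, so tables stay one-row-per-gene.

With three replicates and a plug-in dispersion the normal-quantile Wald
test is known to run slightly hot; in the package's null simulations
(2,000 genes, NB $\alpha = 0.05$, 3 vs 3) the raw false-positive rate at
$p < 0.05$ sits around 0.05–0.065 for exon-scale means (500) and around
0.04–0.06 for intron-scale means (50). That is the cost of the simple,
fully specified estimator; a shrunken-LFC or t-calibrated engine is out of
scope.

## Classification

Per class and tissue, a gene is significant when tested,
`p_adjusted < 0.05`, and `log2_fc > 1` (tissue A) or `< -1` (tissue B) —
strict inequalities. Evidence per tissue is the set of tables significant
there: intron-only or both → transcriptional; exon-only and multi-exon →
post-transcriptional; exon-only and single-exon → inconclusive. A gene
significant for opposite tissues in the two tables gets *two* calls, both
conflict-flagged — the intron-side call is transcriptional (intron evidence
is the transcription readout), and each call participates in its own
tissue's downstream sets. Keeping both flagged calls mirrors the
dual-category bookkeeping of published summary tables and preserves
auditability; collapsing to one call would hide a biologically interesting
discordance.

"Intron only / exon only / both" is deliberately interpreted on the
*significance status in the two result tables*, not on raw read presence:
the thresholds are applied to the output files first, and the sorting
operates on what survives them.

## Downstream joins and enrichment

All overlap tables reduce to numerator/denominator/percentage triples
(`overlapSummary()`), with the percentage rounded at each table's printed
precision (1 decimal, 2 for the subgenome table) so printed arithmetic is
reproduced bit-for-bit. Enhancer lists are purged of single-exon genes
before joining, and their denominators count only genes the pipeline
actually classified. TF-target coverage defines the active TF set per
tissue as transcriptional calls annotated with TF activity and pools their
network targets. Term enrichment is the one-sided Fisher exact test
(hypergeometric upper tail $P[X \ge k]$) over terms with at least 10
background genes, adjusted with Benjamini–Yekutieli — valid under arbitrary
dependence, which nested ontology terms violate wholesale — and flagged at
FDR < 0.01. The background defaults to all genes supplied by the caller (in
practice: all genes with at least one term); it is a parameter, because no
single background is canonical. One-sided is the standard enrichment
choice; a two-sided variant would also flag depletion, which the summary
tables never report.

## The generator, and what passing tests do not show

Defaults encode the emulated study design: 2 conditions × 3 replicates,
10% transcriptional and 5% post-transcriptional DE genes per tissue at
|log2FC| = 2, exon mean 500, intron:exon ratio 0.1 (nascent pre-mRNA is
scarce), shared NB dispersion 0.05, 15% single-exon genes, exon counts
uniform on 2–20 otherwise, nesting and second isoforms at 10%/20%, 100 bp
single-end reverse-stranded reads. The intron:exon ratio is a free
parameter no study quantifies precisely; 0.1 is a realistic order of
magnitude for total-RNA libraries. Per-gene means are held at the
configured values rather than scaled by feature length — lengths matter
only to read placement in `simulateAlignments()` — because the recovery
conditions are stated directly in count space; a length-proportional
variant would only relabel which genes sit at which depth. Auxiliary tables
are enriched for the true classes with configurable odds (default 8;
odds 1 gives class-independent tables, which the suite verifies).

Everything is seeded and byte-reproducible. `simulateAlignments()` places
reads only inside segment regions covered by exactly one gene's segments,
so counting its output must reproduce its placement record *exactly* — an
identity, not a statistical check. Consequently the generator does not
exercise ambiguous reads; those are covered separately by randomized
block-level tests against a base-counting oracle.

What the simulations do **not** model: sequencing error and mappability,
multimapping structure, fragment-length effects, length-dependent counting
efficiency, batch effects, and dispersion that varies with expression.
Passing recovery tests therefore demonstrates the pipeline's logic is
correct under its own generative assumptions, not that real tissues will
yield 84% sensitivity. On real data the intron signal is weaker and
noisier; the structural ceiling remains though: with 15% single-exon genes,
at most ~85% of true transcriptional genes are recoverable, and observed
sensitivity (~84% at the defaults) is essentially at that ceiling.

## Problem sizes and numerical choices

The test suite and acceptance script run: 200 random ≤ 10 kb genomes (≤ 20
genes each) for the catalog oracle; 2,000-gene count simulations for null
calibration and recovery; 1,000-gene simulations for enrichment spiking;
50-gene genomes for SAM-level checks. These sizes give stable Monte Carlo
estimates (binomial SE ≈ 0.005 on a 2,000-gene false-positive rate) while
keeping a full run under a couple of minutes. Ties in the Wald statistic,
zero-mean genes (p = 1), one-sided zero means (p → 0), and zero-width
purge remnants are all handled explicitly; degenerate inputs (no gene
positive in all samples, fewer than 2 replicates, study genes outside the
background) raise errors naming the remedy.
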