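# intronDE

Intron-signal classification of transcriptional vs post-transcriptional
differential expression from total-RNA RNA-seq.

## The problem

Standard RNA-seq compares steady-state transcript abundance and cannot tell
*why* a gene's mRNA level differs between two tissues: more transcription, or
slower mRNA decay? In total-RNA (rRNA-depleted, not poly-A-selected)
libraries, a fraction of reads falls inside introns. Those reads come from
nascent, unspliced pre-mRNA, so intron coverage tracks ongoing transcription
while exon coverage tracks the mature transcript pool. Testing intron and
exon counts *separately* for differential abundance between two conditions
partitions differentially expressed genes:

- **intron signal moved** (alone or with the exon signal) → the gene is
  *transcriptionally* differentially expressed;
- **only the exon signal moved**, and the gene has ≥ 2 exons (hence at least
  one intron that could have responded) → *post-transcriptionally*
  differentially expressed;
- **only the exon signal moved** but the gene has a single exon → the test
  is undefined, the gene is *inconclusive*.

`intronDE` implements this strategy end to end for any pair of conditions
with replicated single-end stranded libraries:

1. **`parseGeneModels()` / `buildFeatureCatalog()`** — flatten a GFF3
   annotation into per-gene union-exon segments and intron segments (gene
   span minus the exon union), then purge genome-wide so that no base is
   simultaneously exonic and intronic for *any* pair of genes. Exons win:
   an exonic base of one gene is never intronic evidence for another, which
   keeps the nascent-transcription signal uncontaminated by overlapping or
   nested gene models and by alternative splicing.
2. **`countReads()`** — assign each uniquely mapped read (SAM/BAM) to at
   most one (gene, exon|intron) by majority block overlap, with exon
   tie-break, honouring library strandedness (reverse/dUTP by default); a
   per-sample disposition summary always sums to the number of records.
3. **`nbWaldTest()` / `testDifferential()`** — a self-contained
   negative-binomial Wald test per feature class: median-of-ratios size
   factors, method-of-moments dispersions shrunk toward an `a0/mu + a1`
   trend with weight `n/(n+4)`, delta-method standard error of the log2
   mean ratio, Benjamini–Hochberg adjustment within each class.
4. **`classifyRegulation()` / `summarizeCategories()`** — apply the
   thresholds `p_adj < 0.05` and `|log2FC| > 1` (strict) per class, combine
   the intron/exon evidence into the three categories above per tissue, and
   flag genes called in opposite tissues by the two classes.
5. **`enhancerOverlap()`, `tfTargetCoverage()`, `subgenomeBreakdown()`,
   `grnTargetSummary()`, `termEnrichment()`** — join calls against
   enhancer-linked gene lists, TF→target networks, subgenome assignments
   and GO maps; enrichment uses the one-sided Fisher (hypergeometric upper
   tail) with Benjamini–Yekutieli FDR, a 0.01 significance level and a
   minimum of 10 mapped genes per term.
6. **`simulationConfig()` / `simulateAnnotation()` / `simulateCounts()` /
   `simulateAlignments()` / `simulateAuxiliary()`** — a ground-truth
   generator (gene models with 1–20 exons, nested genes, isoforms; NB
   counts where transcriptional effects move intron *and* exon abundance
   and post-transcriptional effects move exon abundance only; SAM reads;
   enriched auxiliary tables) so every stage is testable without any
   external data.

## Worked example

Simulate a 300-gene genome, build the catalog, simulate counts under the
default design (two conditions × 3 replicates, 10% transcriptionally and 5%
post-transcriptionally DE genes per tissue at |log2FC| = 2), test, classify:

```r
library(intronDE)
cfg <- simulationConfig(n_genes = 300, seed = 42)
ann <- simulateAnnotation(cfg)
gff <- tempfile(fileext = ".gff3"); writeLines(ann$gff3, gff)
catalog <- buildFeatureCatalog(parseGeneModels(gff))
catalog
#> FeatureCatalog with 300 genes
#>   exon segments:  2867 (544732 bp)
#>   intron segments:2573 (713817 bp)
#>   single-exon genes: 44

sim   <- simulateCounts(cfg, catalog, ann$truth)
de    <- testDifferential(sim$counts)
calls <- classifyRegulation(de$intron, de$exon, catalog)
summarizeCategories(calls)
#> Regulatory category summary
#>                                 A  B total
#> transcriptional                26 25    51
#> post_transcriptional_multiexon 14 13    27
#> inconclusive_single_exon        5  7    12
#> calls: 90  unique genes: 90  multi-category genes: 0
#> exon-only share: 43%
```

The simulator planted 30 transcriptional and 15 post-transcriptional genes
per tissue; the pipeline recovers 85% of the true transcriptional genes in
the correct tissue (single-exon transcriptional genes are structurally
unrecoverable — they have no introns — which caps sensitivity near 85% when
15% of genes are single-exon). The `inconclusive_single_exon` rows are
exactly those casualties, kept visible rather than silently dropped.

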