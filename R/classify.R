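#' Classify genes as transcriptionally or post-transcriptionally regulated
#'
#' Applies the intron-evidence rules to the two per-feature-class DE tables.
#' A gene is *significant for tissue A* in a table when it is tested,
#' `p_adjusted < padjMax` and `log2_fc > lfcMinAbs` (strict inequalities),
#' and for tissue B when `log2_fc < -lfcMinAbs`. Per tissue, the evidence is
#' the set of tables in which the gene is significant:
#' \describe{
#'   \item{intron only or both}{`transcriptional` -- the nascent (intron)
#'     signal moved, so transcription itself changed}
#'   \item{exon only, multi-exon gene}{`post_transcriptional_multiexon` --
#'     mature transcript abundance moved without an intron signal}
#'   \item{exon only, single-exon gene}{`inconclusive_single_exon` -- the
#'     gene has no intron, so the intron test is undefined}
#' }
#' A gene significant for one tissue in one table and the other tissue in
#' the other table receives two calls, each flagged as a conflict (mirroring
#' dual-category bookkeeping).
#'
#' @param intronDE,exonDE DE `DataFrame`s from [nbWaldTest()] over the same
#'   design.
#' @param catalog a [FeatureCatalog-class] supplying `exon_count` (or a named
#'   integer vector of exon counts); every gene appearing in the DE tables
#'   must be present.
#' @param padjMax,lfcMinAbs classification thresholds (defaults 0.05 and 1).
#' @param tissueLabels length-2 character naming the up-tissues; defaults to
#'   the DE tables' condition levels.
#' @return `DataFrame` of calls: `gene_id`, `tissue`, `category`, `evidence`
#'   (`intron_only` / `exon_only` / `both`), `exon_count`, `conflict`.
#' @export
classifyRegulation <- function(intronDE, exonDE, catalog,
                               padjMax = 0.05, lfcMinAbs = 1,
                               tissueLabels = NULL) {
    stopifnot(padjMax > 0, padjMax <= 1, lfcMinAbs > 0)
    if (is.null(tissueLabels))
        tissueLabels <- metadata(exonDE)$conditionLevels %||% c("A", "B")
    genes <- union(intronDE$gene_id, exonDE$gene_id)
    exonN <- if (is(catalog, "FeatureCatalog")) exonCount(catalog)
             else catalog
    bad <- setdiff(genes, names(exonN))
    if (length(bad))
        stop("genes present in DE tables but absent from catalog: ",
             paste(utils::head(bad, 10), collapse = ", "))

    sig <- function(de, dir) {
        ok <- de$tested & !is.na(de$p_adjusted) & de$p_adjusted < padjMax &
            (if (dir > 0) de$log2_fc > lfcMinAbs else de$log2_fc < -lfcMinAbs)
        de$gene_id[ok]
    }
    calls <- list()
    for (t in 1:2) {
        dir <- if (t == 1L) 1 else -1
        inI <- sig(intronDE, dir)
        inE <- sig(exonDE, dir)
        g <- union(inI, inE)
        if (!length(g)) next
        evidence <- ifelse(g %in% inI & g %in% inE, "both",
                    ifelse(g %in% inI, "intron_only", "exon_only"))
        ec <- unname(exonN[g])
        category <- ifelse(evidence != "exon_only", "transcriptional",
                    ifelse(ec >= 2L, "post_transcriptional_multiexon",
                           "inconclusive_single_exon"))
        calls[[t]] <- data.frame(gene_id = g, tissue = tissueLabels[t],
                                 category = category, evidence = evidence,
                                 exon_count = ec, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, calls)
    if (is.null(out))
        out <- data.frame(gene_id = character(), tissue = character(),
                          category = character(), evidence = character(),
                          exon_count = integer())
    dup <- out$gene_id[duplicated(out$gene_id)]
    out$conflict <- out$gene_id %in% dup
    res <- S4Vectors::DataFrame(out)
    metadata(res) <- list(padjMax = padjMax, lfcMinAbs = lfcMinAbs,
                          tissueLabels = tissueLabels)
    res
}

#' Summarize regulatory calls per tissue and category
#'
#' Aggregates [classifyRegulation()] calls into the per-tissue category
#' counts with row totals, plus the reconciliation numbers: total calls,
#' genes appearing in more than one category (dual-tissue conflicts), the
#' deduplicated unique-gene total, and the percentage of unique genes whose
#' evidence was exon-only.
#'
#' @param calls a calls `DataFrame` (or data.frame) with columns `gene_id`,
#'   `tissue`, `category`.
#' @param tissueLabels optional ordering of the two tissue columns.
#' @return list of class `CategorySummary`: `counts` (data.frame category x
#'   tissue with `total` column), `total_calls`, `multi_category_genes`,
#'   `unique_genes`, `exon_only_percent`.
#' @export
summarizeCategories <- function(calls, tissueLabels = NULL) {
    calls <- as.data.frame(calls)
    cats <- c("transcriptional", "post_transcriptional_multiexon",
              "inconclusive_single_exon")
    if (is.null(tissueLabels)) tissueLabels <- sort(unique(calls$tissue))
    tab <- table(factor(calls$category, levels = cats),
                 factor(calls$tissue, levels = tissueLabels))
    counts <- as.data.frame.matrix(tab)
    counts$total <- rowSums(counts)
    nMulti <- sum(table(calls$gene_id) > 1L)
    uniqueGenes <- length(unique(calls$gene_id))
    exonOnly <- counts["post_transcriptional_multiexon", "total"] +
        counts["inconclusive_single_exon", "total"]
    structure(list(
        counts = counts,
        total_calls = nrow(calls),
        multi_category_genes = nMulti,
        unique_genes = uniqueGenes,
        exon_only_percent = if (uniqueGenes)
            100 * exonOnly / uniqueGenes else NA_real_
    ), class = "CategorySummary")
}

#' @export
print.CategorySummary <- function(x, ...) {
    cat("Regulatory category summary\n")
    print(x$counts)
    cat("calls:", x$total_calls,
        " unique genes:", x$unique_genes,
        " multi-category genes:", x$multi_category_genes, "\n")
    if (!is.na(x$exon_only_percent))
        cat(sprintf("exon-only share: %.0f%%\n", x$exon_only_percent))
    invisible(x)
}

#' Write regulatory calls as TSV
#' @param calls calls `DataFrame` from [classifyRegulation()].
#' @param path output path.
#' @export
writeCalls <- function(calls, path) {
    utils::write.table(as.data.frame(calls), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
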