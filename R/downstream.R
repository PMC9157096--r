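#' Overlap summary: counts and printed-precision percentage
#'
#' Small helper shared by all downstream join operations: a numerator /
#' denominator pair with its percentage rounded to the precision the
#' corresponding summary table prints (1 decimal by default). A zero
#' denominator yields an undefined (`NA`) percentage, never 0%.
#'
#' @param numerator,denominator non-negative counts (vectorized).
#' @param digits decimals for the percentage (default 1).
#' @return data.frame with columns `numerator`, `denominator`, `percentage`.
#' @examples
#' overlapSummary(25, 31)           # 80.6
#' overlapSummary(1415, 2573, 2)    # 54.99
#' @export
overlapSummary <- function(numerator, denominator, digits = 1) {
    stopifnot(all(numerator >= 0), all(denominator >= 0),
              all(numerator <= denominator | denominator == 0))
    pct <- ifelse(denominator > 0,
                  round(100 * numerator / denominator, digits), NA_real_)
    data.frame(numerator = numerator, denominator = denominator,
               percentage = pct)
}

.callSets <- function(calls) {
    calls <- as.data.frame(calls)
    list(
        trans = split(calls$gene_id[calls$category == "transcriptional"],
                      calls$tissue[calls$category == "transcriptional"]),
        post = split(calls$gene_id[calls$category == "post_transcriptional_multiexon"],
                     calls$tissue[calls$category == "post_transcriptional_multiexon"]),
        transAll = unique(calls$gene_id[calls$category == "transcriptional"]),
        postAll = unique(calls$gene_id[calls$category == "post_transcriptional_multiexon"])
    )
}

#' Enhancer-linked gene overlap with regulatory classes
#'
#' For each tissue, takes the list of genes previously linked to
#' tissue-specific enhancers, removes single-exon genes (they carry no
#' intron and cannot be classified), and reports how many of the remainder
#' were called transcriptional vs multi-exon post-transcriptional in that
#' tissue. The denominator is the number of enhancer-linked genes found in
#' either class (genes the pipeline did not call are not included).
#'
#' @param calls calls from [classifyRegulation()].
#' @param enhancers data.frame with columns `gene_id`, `tissue`.
#' @param catalog [FeatureCatalog-class] (or named exon-count vector) used
#'   for the single-exon purge.
#' @return data.frame: `tissue`, `category`, `numerator`, `denominator`,
#'   `percentage` (1 decimal).
#' @export
enhancerOverlap <- function(calls, enhancers, catalog) {
    sets <- .callSets(calls)
    exonN <- if (is(catalog, "FeatureCatalog")) exonCount(catalog)
             else catalog
    enhancers <- enhancers[enhancers$gene_id %in% names(exonN)[exonN >= 2L], ,
                           drop = FALSE]
    out <- lapply(unique(enhancers$tissue), function(t) {
        g <- unique(enhancers$gene_id[enhancers$tissue == t])
        nT <- sum(g %in% sets$trans[[t]])
        nP <- sum(g %in% sets$post[[t]])
        den <- nT + nP
        cbind(tissue = t, category = c("transcriptional",
                                       "post_transcriptional_multiexon"),
              overlapSummary(c(nT, nP), c(den, den)))
    })
    do.call(rbind, out)
}

#' Transcription-factor target coverage of regulatory classes
#'
#' Per tissue, the active TF set is the transcriptional calls flagged as
#' transcription factors; the target pool is the union of those TFs' targets
#' in the network. Coverage is the fraction of each class (transcriptional;
#' multi-exon post-transcriptional) in the tissue that falls in the pool.
#'
#' @param calls calls from [classifyRegulation()].
#' @param network data.frame of directed edges `tf_id`, `target_id`.
#' @param tfGenes character vector of gene ids annotated with
#'   transcription-factor activity (e.g. membership in GO:0003700).
#' @return data.frame: `tissue`, `category`, `n_tfs`, `numerator`,
#'   `denominator`, `percentage` (1 decimal).
#' @export
tfTargetCoverage <- function(calls, network, tfGenes) {
    sets <- .callSets(calls)
    tissues <- sort(unique(as.data.frame(calls)$tissue))
    out <- lapply(tissues, function(t) {
        trans <- unique(sets$trans[[t]])
        post <- unique(sets$post[[t]])
        tfs <- intersect(trans, tfGenes)
        pool <- unique(network$target_id[network$tf_id %in% tfs])
        s <- overlapSummary(c(sum(trans %in% pool), sum(post %in% pool)),
                            c(length(trans), length(post)))
        cbind(tissue = t, category = c("transcriptional",
                                       "post_transcriptional_multiexon"),
              n_tfs = length(tfs), s)
    })
    do.call(rbind, out)
}

#' Subgenome breakdown of regulatory classes
#'
#' Splits each tissue x category class by subgenome assignment (the two
#' retained subgenomes of the ancient tetraploidy, plus unassigned genes).
#' The three percentages per class sum to 100 up to rounding.
#'
#' @param calls calls from [classifyRegulation()].
#' @param subgenomes data.frame with columns `gene_id`, `label`; genes
#'   absent from the table count as `"none"`.
#' @param labels the two subgenome label values (default
#'   `c("Maize1", "Maize2")`).
#' @param digits percentage decimals (default 2, the printed precision).
#' @return data.frame: `tissue`, `category`, `subgenome`, `numerator`,
#'   `denominator`, `percentage`.
#' @export
subgenomeBreakdown <- function(calls, subgenomes,
                               labels = c("Maize1", "Maize2"), digits = 2) {
    calls <- as.data.frame(calls)
    lut <- stats::setNames(subgenomes$label, subgenomes$gene_id)
    cats <- c("transcriptional", "post_transcriptional_multiexon")
    out <- list()
    for (t in sort(unique(calls$tissue))) for (cl in cats) {
        g <- unique(calls$gene_id[calls$tissue == t & calls$category == cl])
        lab <- lut[g]
        lab[is.na(lab) | !(lab %in% labels)] <- "none"
        n <- vapply(c(labels, "none"), function(l) sum(lab == l), integer(1))
        out[[paste(t, cl)]] <- cbind(
            tissue = t, category = cl, subgenome = c(labels, "none"),
            overlapSummary(unname(n), rep(length(g), 3L), digits = digits))
    }
    do.call(rbind, out)
}

#' Per-TF regulatory-target summary
#'
#' For each named transcription factor, splits its network targets that are
#' differentially expressed into the transcriptional and multi-exon
#' post-transcriptional classes (any tissue); percentages are over the
#' differentially expressed total. A TF with no DE targets gets undefined
#' percentages.
#'
#' @param targetsByTF named list: TF id -> character vector of target ids.
#' @param calls calls from [classifyRegulation()].
#' @return data.frame: `tf`, `n_targets`, `transcriptional`,
#'   `post_transcriptional`, `de_total`, `pct_transcriptional`,
#'   `pct_post_transcriptional` (1 decimal).
#' @export
grnTargetSummary <- function(targetsByTF, calls) {
    sets <- .callSets(calls)
    rows <- lapply(names(targetsByTF), function(tf) {
        tg <- unique(targetsByTF[[tf]])
        nT <- sum(tg %in% sets$transAll)
        nP <- sum(tg %in% sets$postAll)
        de <- nT + nP
        data.frame(tf = tf, n_targets = length(tg),
                   transcriptional = nT, post_transcriptional = nP,
                   de_total = de,
                   pct_transcriptional = overlapSummary(nT, de)$percentage,
                   pct_post_transcriptional = overlapSummary(nP, de)$percentage)
    })
    do.call(rbind, rows)
}

#' Gene-set term enrichment (one-sided Fisher, Benjamini-Yekutieli)
#'
#' For every term mapped to at least `minEntries` background genes, tests
#' over-representation in the study set with the one-sided Fisher exact test
#' (hypergeometric upper tail, `P[X >= k]`) and adjusts across terms with
#' the Benjamini-Yekutieli procedure (FDR valid under arbitrary dependence,
#' appropriate for nested ontology terms).
#'
#' @param study character vector of study gene ids; must be a subset of
#'   `background`.
#' @param background character vector of background gene ids.
#' @param goMap data.frame with columns `gene_id`, `term`.
#' @param alpha significance level on the adjusted value (default 0.01).
#' @param minEntries minimum background genes mapped to a term for the term
#'   to be tested (default 10).
#' @return data.frame sorted by p: `term`, `k` (study hits), `K` (study
#'   size), `m` (background hits), `N` (background size), `p`, `fdr`,
#'   `significant`.
#' @export
termEnrichment <- function(study, background, goMap,
                           alpha = 0.01, minEntries = 10L) {
    study <- unique(study)
    background <- unique(background)
    if (!all(study %in% background))
        stop("study genes absent from background: ",
             paste(utils::head(setdiff(study, background), 5), collapse = ", "))
    goMap <- unique(goMap[goMap$gene_id %in% background, c("gene_id", "term")])
    mTab <- table(goMap$term)
    terms <- names(mTab)[mTab >= minEntries]
    N <- length(background)
    K <- length(study)
    if (!length(terms))
        return(data.frame(term = character(), k = integer(), K = integer(),
                          m = integer(), N = integer(), p = numeric(),
                          fdr = numeric(), significant = logical()))
    kTab <- table(factor(goMap$term[goMap$gene_id %in% study], levels = terms))
    m <- as.integer(mTab[terms])
    k <- as.integer(kTab)
    p <- stats::phyper(k - 1L, m, N - m, K, lower.tail = FALSE)
    fdr <- stats::p.adjust(p, method = "BY")
    out <- data.frame(term = terms, k = k, K = K, m = m, N = N,
                      p = p, fdr = fdr, significant = fdr < alpha)
    out[order(out$p), , drop = FALSE]
}

#' Translate gene ids through a synonym table
#'
#' Applies a two-column synonym table (e.g. annotation-version id pairs) at
#' load time; ids without a synonym pass through unchanged. No remote
#' lookups, so results are deterministic offline.
#'
#' @param ids character vector of gene ids.
#' @param synonyms data.frame with columns `from`, `to`.
#' @return translated character vector, same length as `ids`.
#' @export
translateGeneIds <- function(ids, synonyms) {
    lut <- stats::setNames(as.character(synonyms$to), synonyms$from)
    hit <- ids %in% names(lut)
    ids[hit] <- unname(lut[ids[hit]])
    ids
}
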