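#' Median-of-ratios size factors
#'
#' For each sample j, the factor is the median over genes (restricted to
#' genes with a positive geometric mean across samples) of
#' `count[g, j] / geomean(count[g, ])`. Factors are then rescaled to have
#' geometric mean 1, so normalized counts live on a common scale.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return positive numeric vector of per-sample factors (geometric mean 1).
#' @export
medianRatioSizeFactors <- function(counts) {
    counts <- as.matrix(counts)
    logGeo <- rowMeans(log(counts))            # -Inf when any zero in the row
    use <- is.finite(logGeo)
    if (!any(use))
        stop("no gene has positive counts in every sample; ",
             "consider a pseudo-reference fallback")
    ratios <- counts[use, , drop = FALSE] / exp(logGeo[use])
    f <- apply(ratios, 2L, stats::median)
    f / exp(mean(log(f)))
}

#' Method-of-moments NB dispersions with trend shrinkage
#'
#' Per gene, a method-of-moments dispersion `max(0, (s2 - m) / m^2)` is
#' computed from normalized counts, with the variance pooled within
#' conditions (so true fold-changes do not inflate it) and `m` the grand mean
#' of normalized counts. A mean-dispersion trend `a0/m + a1` is fitted by
#' least squares over genes with positive raw dispersion, and the final
#' per-gene value is the weighted combination
#' `w * raw + (1 - w) * trend(m)` with `w = n_reps / (n_reps + 4)`, floored
#' at 1e-8. With few replicates the per-gene estimate is noisy, so most of
#' the weight sits on the trend.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param condition two-level factor over samples, at least two replicates
#'   per level.
#' @param sizeFactors per-sample factors; computed by
#'   [medianRatioSizeFactors()] when `NULL`.
#' @return numeric vector of final dispersions with attributes `raw`
#'   (method-of-moments values) and `trend` (coefficients `a0`, `a1`).
#' @export
momDispersions <- function(counts, condition, sizeFactors = NULL) {
    counts <- as.matrix(counts)
    condition <- as.factor(condition)
    if (any(table(condition) < 2L))
        stop("at least 2 replicates per condition are required ",
             "to estimate within-condition variance")
    if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(counts)
    norm <- sweep(counts, 2L, sizeFactors, "/")

    grandMean <- rowMeans(norm)
    lev <- levels(condition)
    ## df-weighted pooled within-condition variance
    ssq <- 0
    df <- 0
    for (l in lev) {
        sub <- norm[, condition == l, drop = FALSE]
        n <- ncol(sub)
        ssq <- ssq + rowSums((sub - rowMeans(sub))^2)
        df <- df + (n - 1L)
    }
    s2 <- ssq / df
    raw <- pmax(0, (s2 - grandMean) / grandMean^2)
    raw[!is.finite(raw)] <- 0

    fitOn <- raw > 0 & grandMean > 0
    if (sum(fitOn) >= 2L) {
        fit <- stats::lm.fit(cbind(a0 = 1 / grandMean[fitOn], a1 = 1),
                             raw[fitOn])
        co <- pmax(fit$coefficients, 0)   # a negative trend piece is meaningless
    } else {
        co <- c(a0 = 0, a1 = stats::median(raw))
    }
    trend <- co[1L] / grandMean + co[2L]
    trend[!is.finite(trend)] <- co[2L]

    nReps <- min(table(condition))
    w <- nReps / (nReps + 4)
    final <- pmax(w * raw + (1 - w) * trend, 1e-8)
    attr(final, "raw") <- raw
    attr(final, "trend") <- co
    final
}

#' Negative-binomial Wald test for differential abundance
#'
#' Per gene, condition means of normalized counts are compared on the log2
#' scale. The reported fold-change uses a pseudo-count of 0.5 on each mean
#' (display only, to keep it finite); the Wald statistic divides the raw
#' log2 mean ratio by a delta-method standard error derived from the NB
#' variance `mu + alpha * mu^2` of each sample's fitted mean, and a two-sided
#' p-value comes from the standard normal. Benjamini-Hochberg adjustment is
#' applied over tested genes only; genes whose mean normalized count falls
#' below `expressionFloor` are marked untested (NA p-values), never dropped.
#'
#' @param counts raw non-negative integer matrix, genes x samples.
#' @param condition two-level factor over samples; the *first* level is the
#'   numerator of the fold-change.
#' @param sizeFactors,dispersions optional; computed with
#'   [medianRatioSizeFactors()] / [momDispersions()] when `NULL`.
#' @param expressionFloor minimum mean normalized count for testing
#'   (default 1).
#' @param featureClass optional label ("exon"/"intron") stored in the result
#'   metadata.
#' @return a [S4Vectors::DataFrame] with one row per gene: `gene_id`,
#'   `base_mean`, `log2_fc`, `se`, `stat`, `p_value`, `p_adjusted`, `tested`.
#'   `metadata()` carries `sizeFactors`, `dispersions`, `conditionLevels`
#'   and `featureClass`.
#' @export
nbWaldTest <- function(counts, condition, sizeFactors = NULL,
                       dispersions = NULL, expressionFloor = 1,
                       featureClass = NA_character_) {
    counts <- as.matrix(counts)
    if (any(counts != round(counts)) || any(counts < 0))
        stop("counts must be raw non-negative integers")
    condition <- as.factor(condition)
    if (nlevels(condition) != 2L)
        stop("exactly two conditions are required")
    if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(counts)
    if (is.null(dispersions))
        dispersions <- momDispersions(counts, condition, sizeFactors)

    norm <- sweep(counts, 2L, sizeFactors, "/")
    lev <- levels(condition)
    aIdx <- condition == lev[1L]
    bIdx <- condition == lev[2L]
    muA <- rowMeans(norm[, aIdx, drop = FALSE])
    muB <- rowMeans(norm[, bIdx, drop = FALSE])
    baseMean <- rowMeans(norm)
    tested <- baseMean >= expressionFloor

    log2fc <- log2(muA + 0.5) - log2(muB + 0.5)

    ## delta-method variance of log2 of a mean of normalized NB counts,
    ## Var = (mu + alpha*mu^2)/n on the normalized scale, so the statistic
    ## depends on the data only through the normalized counts
    varLog2Mean <- function(mu, n, alpha) {
        ((mu + alpha * mu^2) / n) / (mu^2 * log(2)^2)
    }
    vA <- varLog2Mean(muA, sum(aIdx), dispersions)
    vB <- varLog2Mean(muB, sum(bIdx), dispersions)
    se <- sqrt(vA + vB)

    rawLfc <- log2(muA) - log2(muB)       # no pseudo-count in the statistic
    stat <- ifelse(muA == 0 & muB == 0, 0, rawLfc / se)
    stat[muA == 0 & muB > 0] <- -Inf
    stat[muB == 0 & muA > 0] <- Inf
    p <- ifelse(muA == 0 & muB == 0, 1, 2 * stats::pnorm(-abs(stat)))
    p <- pmin(p, 1)

    p[!tested] <- NA_real_
    padj <- rep(NA_real_, length(p))
    padj[tested] <- stats::p.adjust(p[tested], method = "BH")

    res <- S4Vectors::DataFrame(
        gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
        base_mean = unname(baseMean),
        log2_fc = unname(log2fc),
        se = unname(se),
        stat = unname(stat),
        p_value = unname(p),
        p_adjusted = unname(padj),
        tested = unname(tested))
    metadata(res) <- list(sizeFactors = sizeFactors,
                          dispersions = as.numeric(dispersions),
                          conditionLevels = lev,
                          featureClass = featureClass)
    res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the two differential tests of an intron/exon count object
#'
#' Convenience wrapper: runs [nbWaldTest()] on the exon and intron assays of
#' an [IntronExonCounts-class] independently (each feature class gets its own
#' size factors, dispersions and BH adjustment).
#'
#' @param counts an [IntronExonCounts-class].
#' @param expressionFloor passed to [nbWaldTest()].
#' @return named list with elements `exon` and `intron`, each a DE
#'   `DataFrame`.
#' @export
testDifferential <- function(counts, expressionFloor = 1) {
    stopifnot(is(counts, "IntronExonCounts"))
    condition <- SummarizedExperiment::colData(counts)$condition
    lapply(stats::setNames(c("exon", "intron"), c("exon", "intron")),
           function(cls) {
        m <- SummarizedExperiment::assay(counts, cls)
        nbWaldTest(m, condition, expressionFloor = expressionFloor,
                   featureClass = cls)
    })
}

#' Write a DE table as TSV
#' @param de a DE `DataFrame` from [nbWaldTest()].
#' @param path output path.
#' @export
writeDETable <- function(de, path) {
    utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
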