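#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @import GenomicRanges
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
NULL

#' FeatureCatalog: genome-wide disjoint exon and intron segments
#'
#' A `FeatureCatalog` holds, per gene, the merged union-exon segments and the
#' intron segments (gene span minus the exon union), after a genome-wide purge
#' that removes any intron base overlapped by *any* gene's exon segment. The
#' purge makes the exon and intron sets disjoint at the base level across the
#' whole genome, so that a read overlapping an exon base can never be counted
#' as intronic evidence for another gene. Exon segments take precedence over
#' introns because exon coverage is unambiguous transcript evidence, while the
#' intron (nascent-transcription) signal must not be contaminated by mature
#' mRNA from overlapping gene models.
#'
#' @slot exons [GenomicRanges::GRanges] of exon segments; `mcols()$gene_id`
#'   assigns each segment to a gene. Sorted, and disjoint within a gene.
#' @slot introns [GenomicRanges::GRanges] of intron segments, same layout.
#' @slot geneInfo [S4Vectors::DataFrame] with one row per gene (rownames are
#'   gene ids) and columns `chrom`, `strand`, `span_start`, `span_end`,
#'   `exon_count` (number of merged exon segments).
#' @slot provenance list recording the annotation source and build parameters.
#'
#' @seealso [buildFeatureCatalog()], [parseGeneModels()]
#' @export
setClass("FeatureCatalog",
    representation(
        exons = "GRanges",
        introns = "GRanges",
        geneInfo = "DataFrame",
        provenance = "list"
    )
)

.validFeatureCatalog <- function(object) {
    msg <- character()
    gi <- object@geneInfo
    ex <- object@exons
    it <- object@introns
    need <- c("chrom", "strand", "span_start", "span_end", "exon_count")
    if (!all(need %in% colnames(gi)))
        return(paste("geneInfo must have columns:", paste(need, collapse = ", ")))
    if (length(ex) && !all(mcols(ex)$gene_id %in% rownames(gi)))
        msg <- c(msg, "exon segment with gene_id missing from geneInfo")
    if (length(it) && !all(mcols(it)$gene_id %in% rownames(gi)))
        msg <- c(msg, "intron segment with gene_id missing from geneInfo")
    ## per-gene segments sorted, non-overlapping, non-adjacent
    for (gr in list(ex, it)) {
        if (!length(gr)) next
        byg <- split(gr, mcols(gr)$gene_id)
        red <- GenomicRanges::reduce(byg, min.gapwidth = 1L)
        if (!identical(sum(BiocGenerics::width(byg)), sum(BiocGenerics::width(red))) ||
            !identical(lengths(byg), lengths(red)))
            msg <- c(msg, "segments within a gene must be sorted, disjoint and merged")
    }
    ## genome-wide exon/intron disjointness (strand-blind unless stranded build)
    strandBlind <- !isTRUE(object@provenance$stranded)
    if (length(ex) && length(it)) {
        ov <- GenomicRanges::findOverlaps(ex, it, ignore.strand = strandBlind)
        if (length(ov))
            msg <- c(msg, "an exon segment overlaps an intron segment")
    }
    ## introns inside gene span; single-exon genes intron-free
    if (length(it)) {
        g <- as.character(mcols(it)$gene_id)
        bad <- BiocGenerics::start(it) < gi[g, "span_start"] |
            BiocGenerics::end(it) > gi[g, "span_end"]
        if (any(bad))
            msg <- c(msg, "intron segment outside its gene span")
        if (any(gi[g, "exon_count"] == 1L))
            msg <- c(msg, "single-exon gene has intron segments")
    }
    if (length(msg)) msg else TRUE
}
setValidity("FeatureCatalog", .validFeatureCatalog)

#' @describeIn FeatureCatalog-class compact display
#' @param object a `FeatureCatalog`
#' @export
setMethod("show", "FeatureCatalog", function(object) {
    gi <- object@geneInfo
    cat("FeatureCatalog with", nrow(gi), "genes\n")
    cat("  exon segments:  ", length(object@exons),
        " (", sum(BiocGenerics::width(object@exons)), " bp)\n", sep = "")
    cat("  intron segments:", length(object@introns),
        " (", sum(BiocGenerics::width(object@introns)), " bp)\n", sep = "")
    cat("  single-exon genes:", sum(gi$exon_count == 1L), "\n")
    if (!is.null(object@provenance$source))
        cat("  source:", object@provenance$source, "\n")
})

#' @rdname FeatureCatalog-class
#' @param x a `FeatureCatalog`
#' @export
exonSegments <- function(x) {
    stopifnot(is(x, "FeatureCatalog"))
    x@exons
}

#' @rdname FeatureCatalog-class
#' @export
intronSegments <- function(x) {
    stopifnot(is(x, "FeatureCatalog"))
    x@introns
}

#' @rdname FeatureCatalog-class
#' @export
geneInfo <- function(x) {
    stopifnot(is(x, "FeatureCatalog"))
    x@geneInfo
}

#' @rdname FeatureCatalog-class
#' @return `exonCount()`: named integer vector of merged exon segment counts.
#' @export
exonCount <- function(x) {
    gi <- geneInfo(x)
    stats::setNames(gi$exon_count, rownames(gi))
}

#' IntronExonCounts: paired exon/intron count matrices
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding the two
#' per-gene count matrices produced by [countReads()] (assays `"exon"` and
#' `"intron"`), the sample design in `colData` (column `condition`), and the
#' per-sample read-disposition summary in `metadata()$summary`.
#'
#' @export
setClass("IntronExonCounts", contains = "SummarizedExperiment")

.validIntronExonCounts <- function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("exon", "intron") %in% an))
        return("assays must include 'exon' and 'intron'")
    for (nm in c("exon", "intron")) {
        a <- SummarizedExperiment::assay(object, nm)
        if (any(a < 0) || any(a != round(a)))
            msg <- c(msg, sprintf("assay '%s' must hold non-negative integers", nm))
    }
    if (!"condition" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must have a 'condition' column")
    if (length(msg)) msg else TRUE
}
setValidity("IntronExonCounts", .validIntronExonCounts)

#' Construct an IntronExonCounts object
#'
#' @param exon,intron integer matrices, genes x samples, identical dimnames.
#' @param condition factor or character of per-sample conditions (two levels;
#'   the first level is the fold-change numerator).
#' @param summary optional per-sample read-disposition `DataFrame`.
#' @return an [IntronExonCounts-class] object.
#' @export
IntronExonCounts <- function(exon, intron, condition, summary = NULL) {
    stopifnot(identical(dim(exon), dim(intron)),
              identical(dimnames(exon), dimnames(intron)))
    condition <- as.factor(condition)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exon = exon, intron = intron),
        colData = S4Vectors::DataFrame(condition = condition,
                                       row.names = colnames(exon))
    )
    obj <- new("IntronExonCounts", se)
    if (!is.null(summary)) metadata(obj)$summary <- summary
    validObject(obj)
    obj
}
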