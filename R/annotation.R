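#' Parse gene models from a GFF3 annotation
#'
#' Reads a GFF3 file and assembles gene models: one record per gene, its
#' transcripts, and each transcript's exons linked through `Parent`
#' attributes. Both `mRNA` and `transcript` feature types are accepted as
#' transcript rows. The gene span is the minimum start to maximum end over the
#' gene's transcript exons.
#'
#' Exons lacking a `Parent` attribute abort the parse (orphan features);
#' exons or transcripts whose `Parent` id is not present in the file are
#' reported with a warning, returned in the `orphans` element, and excluded
#' from the models.
#'
#' @param gff3 path to a GFF3 file.
#' @return a list of class `GeneModels` with elements
#'   \describe{
#'     \item{genes}{`GRanges` of gene spans with `mcols()$gene_id`}
#'     \item{transcripts}{`DataFrame` mapping `tx_id` to `gene_id`}
#'     \item{exonsByTx}{`GRangesList` of exons, named by transcript id,
#'       sorted by start within each transcript}
#'     \item{orphans}{character vector of feature ids with unknown parents}
#'   }
#' @examples
#' gff <- system.file("extdata", "toy_models.gff3", package = "intronDE")
#' models <- parseGeneModels(gff)
#' models$genes
#' @export
parseGeneModels <- function(gff3) {
    gr <- tryCatch(
        rtracklayer::import(gff3, format = "gff3"),
        error = function(e) stop("GFF3 parse error in '", gff3, "': ",
                                 conditionMessage(e), call. = FALSE)
    )
    type <- as.character(gr$type)
    tx <- gr[type %in% c("mRNA", "transcript")]
    exons <- gr[type == "exon"]

    txParent <- .firstParent(tx)
    if (anyNA(txParent))
        stop("orphan-feature error: transcript(s) without a Parent attribute: ",
             paste(utils::head(tx$ID[is.na(txParent)], 5), collapse = ", "),
             call. = FALSE)
    exParent <- .firstParent(exons)
    if (anyNA(exParent))
        stop("orphan-feature error: exon(s) without a Parent attribute",
             call. = FALSE)

    geneIds <- unique(if (any(type == "gene")) {
        as.character(gr$ID[type == "gene"])
    } else character())
    orphans <- character()

    knownGene <- txParent %in% geneIds
    if (length(geneIds) && !all(knownGene)) {
        orphans <- c(orphans, as.character(tx$ID[!knownGene]))
        tx <- tx[knownGene]
        txParent <- txParent[knownGene]
    } else if (!length(geneIds)) {
        ## annotation without explicit gene rows: transcript parents act as genes
        geneIds <- unique(txParent)
    }
    txIds <- as.character(tx$ID)

    knownTx <- exParent %in% txIds
    if (!all(knownTx)) {
        orphans <- c(orphans, unique(exParent[!knownTx]))
        exons <- exons[knownTx]
        exParent <- exParent[knownTx]
    }
    if (length(orphans))
        warning("features with unknown parents excluded: ",
                paste(utils::head(unique(orphans), 10), collapse = ", "))

    exonsByTx <- GenomicRanges::sort(
        GenomicRanges::split(GenomicRanges::granges(exons),
                             factor(exParent, levels = txIds)))
    ## drop transcripts with no exons
    keep <- lengths(exonsByTx) > 0L
    exonsByTx <- exonsByTx[keep]
    txIds <- txIds[keep]
    txParent <- txParent[keep]

    spans <- unlist(range(exonsByTx), use.names = FALSE)
    geneOf <- factor(txParent, levels = unique(txParent))
    geneSpan <- unlist(range(GenomicRanges::split(spans, geneOf)),
                       use.names = FALSE)
    mcols(geneSpan)$gene_id <- levels(geneOf)

    structure(list(
        genes = geneSpan,
        transcripts = S4Vectors::DataFrame(tx_id = txIds, gene_id = txParent),
        exonsByTx = exonsByTx,
        orphans = unique(orphans)
    ), class = "GeneModels")
}

.firstParent <- function(gr) {
    if (!length(gr)) return(character())
    p <- gr$Parent
    vapply(as.list(p), function(x) {
        if (length(x)) as.character(x[[1]]) else NA_character_
    }, character(1))
}

#' @export
print.GeneModels <- function(x, ...) {
    cat("GeneModels:", length(x$genes), "genes,",
        nrow(x$transcripts), "transcripts\n")
    invisible(x)
}

#' Build a genome-wide disjoint exon/intron feature catalog
#'
#' Per gene, the exon segments are the merged union of all its transcripts'
#' exons (so an exon skipped by one isoform but present in another stays
#' exonic), and the intron segments are the gene span minus that union. A
#' genome-wide purge then trims away any intron region that overlaps *any*
#' gene's exon segment, so no base is simultaneously exonic and intronic
#' anywhere in the catalog. Regions where two genes' introns overlap are
#' attributed to both genes.
#'
#' @param models a `GeneModels` object from [parseGeneModels()], or an
#'   existing [FeatureCatalog-class] (whose segments are re-derived, useful
#'   for idempotence checks).
#' @param stranded if `TRUE`, the purge only removes same-strand conflicts;
#'   the default (`FALSE`) is strand-blind: a base covered by an exon on
#'   either strand is never intronic.
#' @param minSegmentWidth drop segments narrower than this many bases
#'   (default 1, i.e. keep everything).
#' @return a [FeatureCatalog-class].
#' @examples
#' gff <- system.file("extdata", "toy_models.gff3", package = "intronDE")
#' cat <- buildFeatureCatalog(parseGeneModels(gff))
#' cat
#' @export
buildFeatureCatalog <- function(models, stranded = FALSE, minSegmentWidth = 1L) {
    if (is(models, "FeatureCatalog"))
        models <- .modelsFromCatalog(models)
    stopifnot(inherits(models, "GeneModels"))
    geneIds <- as.character(mcols(models$genes)$gene_id)

    if (!length(geneIds)) {
        empty <- GenomicRanges::GRanges()
        mcols(empty)$gene_id <- character()
        return(S4Vectors::new2("FeatureCatalog", exons = empty, introns = empty,
                   geneInfo = S4Vectors::DataFrame(
                       chrom = character(), strand = character(),
                       span_start = integer(), span_end = integer(),
                       exon_count = integer(), row.names = character()),
                   provenance = list(stranded = stranded,
                                     min_segment_width = minSegmentWidth),
                   check = FALSE))
    }

    txGene <- as.character(models$transcripts$gene_id)
    exAll <- unlist(models$exonsByTx, use.names = FALSE)
    exGene <- rep(txGene, lengths(models$exonsByTx))
    exByGene <- GenomicRanges::reduce(
        GenomicRanges::split(exAll, factor(exGene, levels = geneIds)))

    spanByGene <- GenomicRanges::split(models$genes,
                                       factor(geneIds, levels = geneIds))
    intByGene <- GenomicRanges::psetdiff(
        unlist(range(spanByGene), use.names = FALSE), exByGene)

    ## genome-wide purge: intron bases overlapped by ANY exon are removed
    exonPool <- GenomicRanges::reduce(unlist(exByGene, use.names = FALSE),
                                      ignore.strand = !stranded)
    intFlat <- unlist(intByGene, use.names = FALSE)
    intGene <- rep(geneIds, lengths(intByGene))
    if (length(intFlat)) {
        purged <- GenomicRanges::subtract(intFlat, exonPool,
                                          ignore.strand = !stranded)
        intFlat <- unlist(purged, use.names = FALSE)
        intGene <- rep(intGene, lengths(purged))
    }

    exFlat <- unlist(exByGene, use.names = FALSE)
    exGeneFlat <- rep(geneIds, lengths(exByGene))

    keepE <- BiocGenerics::width(exFlat) >= minSegmentWidth
    keepI <- if (length(intFlat)) BiocGenerics::width(intFlat) >= minSegmentWidth
             else logical()
    exFlat <- exFlat[keepE]; exGeneFlat <- exGeneFlat[keepE]
    intFlat <- intFlat[keepI]; intGene <- intGene[keepI]
    mcols(exFlat) <- S4Vectors::DataFrame(gene_id = exGeneFlat)
    mcols(intFlat) <- S4Vectors::DataFrame(gene_id = intGene)

    exCount <- table(factor(exGeneFlat, levels = geneIds))
    gi <- S4Vectors::DataFrame(
        chrom = as.character(GenomicRanges::seqnames(models$genes)),
        strand = as.character(BiocGenerics::strand(models$genes)),
        span_start = BiocGenerics::start(models$genes),
        span_end = BiocGenerics::end(models$genes),
        exon_count = as.integer(exCount[geneIds]),
        row.names = geneIds)

    ## a single-exon gene cannot carry intron evidence even if purge left slivers
    if (length(intFlat)) {
        single <- rownames(gi)[gi$exon_count <= 1L]
        drop <- mcols(intFlat)$gene_id %in% single
        intFlat <- intFlat[!drop]
    }

    ## construction guarantees the invariants; skip the (expensive) validity
    ## re-check here, tests exercise validObject() explicitly
    S4Vectors::new2("FeatureCatalog",
        exons = GenomicRanges::sort(exFlat, ignore.strand = TRUE),
        introns = GenomicRanges::sort(intFlat, ignore.strand = TRUE),
        geneInfo = gi,
        provenance = list(stranded = stranded,
                          min_segment_width = minSegmentWidth),
        check = FALSE)
}

## rebuild GeneModels treating each gene's exon segments as one transcript
.modelsFromCatalog <- function(catalog) {
    gi <- geneInfo(catalog)
    geneIds <- rownames(gi)
    ex <- exonSegments(catalog)
    exonsByTx <- GenomicRanges::split(
        GenomicRanges::granges(ex),
        factor(mcols(ex)$gene_id, levels = geneIds))
    names(exonsByTx) <- paste0(geneIds, "_t1")
    genes <- unlist(range(exonsByTx), use.names = FALSE)
    mcols(genes)$gene_id <- geneIds
    structure(list(
        genes = genes,
        transcripts = S4Vectors::DataFrame(tx_id = names(exonsByTx),
                                           gene_id = geneIds),
        exonsByTx = exonsByTx,
        orphans = character()
    ), class = "GeneModels")
}

#' Write / read a feature catalog as BED + sidecar TSV
#'
#' The BED file (0-based half-open) carries one row per segment with
#' `name = <gene_id>|<exon|intron>`; the sidecar TSV carries per-gene
#' `gene_id`, `exon_count`, `total_exon_bp`, `total_intron_bp`.
#'
#' @param catalog a [FeatureCatalog-class].
#' @param prefix output path prefix; writes `<prefix>.bed` and
#'   `<prefix>.genes.tsv`.
#' @return `writeCatalogBED()` returns the BED path invisibly;
#'   `readCatalogBED()` returns a rebuilt [FeatureCatalog-class].
#' @export
writeCatalogBED <- function(catalog, prefix) {
    grs <- list(exon = exonSegments(catalog), intron = intronSegments(catalog))
    rows <- lapply(names(grs), function(cls) {
        gr <- grs[[cls]]
        if (!length(gr)) return(NULL)
        data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,  # BED is 0-based
                   end = BiocGenerics::end(gr),
                   name = paste(mcols(gr)$gene_id, cls, sep = "|"),
                   score = 0L,
                   strand = as.character(BiocGenerics::strand(gr)))
    })
    bed <- do.call(rbind, rows)
    bedPath <- paste0(prefix, ".bed")
    utils::write.table(bed, bedPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    gi <- geneInfo(catalog)
    side <- data.frame(
        gene_id = rownames(gi),
        exon_count = gi$exon_count,
        total_exon_bp = vapply(rownames(gi), function(g)
            sum(BiocGenerics::width(grs$exon[mcols(grs$exon)$gene_id == g])),
            numeric(1)),
        total_intron_bp = vapply(rownames(gi), function(g)
            sum(BiocGenerics::width(grs$intron[mcols(grs$intron)$gene_id == g])),
            numeric(1)))
    utils::write.table(side, paste0(prefix, ".genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(bedPath)
}

#' @rdname writeCatalogBED
#' @export
readCatalogBED <- function(prefix) {
    bed <- utils::read.table(paste0(prefix, ".bed"), sep = "\t",
                             col.names = c("chrom", "start", "end", "name",
                                           "score", "strand"),
                             colClasses = c("character", "integer", "integer",
                                            "character", "integer", "character"))
    parts <- strsplit(bed$name, "|", fixed = TRUE)
    gene <- vapply(parts, `[`, character(1), 1L)
    cls <- vapply(parts, `[`, character(1), 2L)
    gr <- GenomicRanges::GRanges(bed$chrom,
                                 IRanges(bed$start + 1L, bed$end),
                                 strand = bed$strand)
    mcols(gr)$gene_id <- gene
    side <- utils::read.table(paste0(prefix, ".genes.tsv"), sep = "\t",
                              header = TRUE, colClasses = c("character",
                              "integer", "numeric", "numeric"))
    ex <- gr[cls == "exon"]
    it <- gr[cls == "intron"]
    spans <- range(GenomicRanges::split(
        c(GenomicRanges::granges(ex), GenomicRanges::granges(it)),
        factor(c(mcols(ex)$gene_id, mcols(it)$gene_id),
               levels = side$gene_id)))
    spanFlat <- unlist(spans, use.names = FALSE)
    gi <- S4Vectors::DataFrame(
        chrom = as.character(GenomicRanges::seqnames(spanFlat)),
        strand = as.character(BiocGenerics::strand(spanFlat)),
        span_start = BiocGenerics::start(spanFlat),
        span_end = BiocGenerics::end(spanFlat),
        exon_count = side$exon_count,
        row.names = side$gene_id)
    S4Vectors::new2("FeatureCatalog",
        exons = GenomicRanges::sort(ex, ignore.strand = TRUE),
        introns = GenomicRanges::sort(it, ignore.strand = TRUE),
        geneInfo = gi,
        provenance = list(stranded = FALSE, source = paste0(prefix, ".bed")),
        check = FALSE)
}
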