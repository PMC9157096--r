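#' Resolve the feature-class disposition of one read
#'
#' Given the per-(gene, class) overlap base counts of a single read's aligned
#' blocks against a [FeatureCatalog-class], decide its disposition: a read
#' touching features of more than one gene is ambiguous; otherwise it is
#' assigned to the class (exon or intron) with the larger overlapping base
#' count, with ties broken in favour of exon. Majority overlap is robust to
#' one-base boundary jitter between an alignment block and a segment edge.
#'
#' @param overlaps data.frame with columns `gene_id`, `class`
#'   (`"exon"`/`"intron"`) and `width` (overlapping bases), one row per
#'   touched (gene, class); zero rows mean the read touched no feature.
#' @return list with `disposition` (one of `"assigned_exon"`,
#'   `"assigned_intron"`, `"ambiguous_multi_gene"`, `"unassigned_no_feature"`)
#'   and, when assigned, `gene_id`.
#' @examples
#' resolveReadClass(data.frame(gene_id = "g1",
#'                             class = c("exon", "intron"),
#'                             width = c(80, 20)))
#' @export
resolveReadClass <- function(overlaps) {
    overlaps <- overlaps[overlaps$width > 0, , drop = FALSE]
    if (nrow(overlaps) == 0L)
        return(list(disposition = "unassigned_no_feature", gene_id = NA_character_))
    genes <- unique(overlaps$gene_id)
    if (length(genes) > 1L)
        return(list(disposition = "ambiguous_multi_gene", gene_id = NA_character_))
    wExon <- sum(overlaps$width[overlaps$class == "exon"])
    wIntron <- sum(overlaps$width[overlaps$class == "intron"])
    cls <- if (wIntron > wExon) "intron" else "exon"  # tie goes to exon
    list(disposition = paste0("assigned_", cls), gene_id = genes)
}

#' Count reads into per-gene exon and intron features
#'
#' Assigns each retained alignment to at most one (gene, feature-class) by
#' majority block overlap against the catalog segments (see
#' [resolveReadClass()]), producing one exon and one intron count matrix plus
#' a per-sample disposition summary whose six counters always sum to the
#' number of input records.
#'
#' Alignment filtering follows the uniquely-mapped-reads convention of
#' stranded total-RNA libraries: when the `NH` tag is present, only reads
#' with `NH == 1` are kept; otherwise a MAPQ threshold stands in. Gapped
#' (spliced) alignments contribute each block independently, summed per
#' (gene, class).
#'
#' @param files named character vector of SAM or BAM paths; names are sample
#'   ids. SAM text is converted on the fly with [Rsamtools::asBam()].
#' @param catalog a [FeatureCatalog-class].
#' @param condition per-sample condition labels parallel to `files` (two
#'   levels; first level is the downstream fold-change numerator).
#' @param strandedness `"reverse"` (default; read antisense to the gene, the
#'   dUTP convention), `"forward"`, or `"unstranded"`.
#' @param uniqueOnly keep only uniquely mapped reads (default `TRUE`).
#' @param mapqMin MAPQ threshold used when the `NH` tag is absent
#'   (default 20).
#' @return an [IntronExonCounts-class] with assays `exon` and `intron`
#'   (genes x samples) and the disposition summary in `metadata()$summary`.
#' @export
countReads <- function(files, catalog, condition,
                       strandedness = c("reverse", "forward", "unstranded"),
                       uniqueOnly = TRUE, mapqMin = 20L) {
    strandedness <- match.arg(strandedness)
    stopifnot(length(files) >= 1L, length(condition) == length(files))
    if (is.null(names(files)))
        names(files) <- paste0("sample", seq_along(files))

    segs <- .catalogSegments(catalog)
    geneIds <- rownames(geneInfo(catalog))
    exon <- intron <- matrix(0L, nrow = length(geneIds), ncol = length(files),
                             dimnames = list(geneIds, names(files)))
    summ <- vector("list", length(files))
    for (j in seq_along(files)) {
        one <- .countOneSample(files[[j]], segs, geneIds, strandedness,
                               uniqueOnly, mapqMin)
        exon[, j] <- one$exon
        intron[, j] <- one$intron
        summ[[j]] <- one$summary
    }
    summary <- S4Vectors::DataFrame(do.call(rbind, summ),
                                    row.names = names(files))
    IntronExonCounts(exon, intron, condition, summary = summary)
}

.catalogSegments <- function(catalog) {
    ex <- exonSegments(catalog)
    it <- intronSegments(catalog)
    segs <- c(GenomicRanges::granges(ex), GenomicRanges::granges(it))
    mcols(segs)$gene_id <- c(as.character(mcols(ex)$gene_id),
                             as.character(mcols(it)$gene_id))
    mcols(segs)$class <- rep(c("exon", "intron"), c(length(ex), length(it)))
    segs
}

.countOneSample <- function(file, segs, geneIds, strandedness,
                            uniqueOnly, mapqMin) {
    bam <- .ensureBam(file)
    param <- Rsamtools::ScanBamParam(what = c("mapq"), tag = "NH")
    gal <- GenomicAlignments::readGAlignments(bam, param = param)
    total <- length(gal)

    nh <- mcols(gal)$NH
    mapq <- mcols(gal)$mapq
    discardedNonUnique <- 0L
    discardedLowMapq <- 0L
    keep <- rep(TRUE, total)
    if (uniqueOnly && total) {
        hasNH <- !is.na(nh)
        nonUnique <- hasNH & nh > 1L
        lowMapq <- !hasNH & (is.na(mapq) | mapq < mapqMin)
        discardedNonUnique <- sum(nonUnique)
        discardedLowMapq <- sum(lowMapq)
        keep <- !(nonUnique | lowMapq)
    }
    galk <- gal[keep]
    nKeep <- length(galk)

    exonCounts <- intronCounts <- stats::setNames(integer(length(geneIds)),
                                                  geneIds)
    nExon <- nIntron <- nAmbig <- nUnassigned <- 0L
    if (nKeep) {
        missingChrom <- setdiff(as.character(GenomicRanges::seqnames(galk)),
                                as.character(GenomicRanges::seqnames(segs)))
        for (chr in unique(missingChrom))
            message("chromosome '", chr,
                    "' present in alignments but absent from catalog; ",
                    "its reads are unassigned")

        blocks <- GenomicAlignments::grglist(galk)
        flat <- unlist(blocks, use.names = FALSE)
        readIdx <- rep(seq_len(nKeep), lengths(blocks))
        hits <- GenomicRanges::findOverlaps(flat, segs, ignore.strand = TRUE)
        if (length(hits)) {
            q <- S4Vectors::queryHits(hits)
            s <- S4Vectors::subjectHits(hits)
            w <- BiocGenerics::width(GenomicRanges::pintersect(
                flat[q], segs[s], ignore.strand = TRUE))
            rd <- readIdx[q]
            geneStrand <- as.character(BiocGenerics::strand(segs))[s]
            readStrand <- as.character(BiocGenerics::strand(galk))[rd]
            ok <- switch(strandedness,
                unstranded = rep(TRUE, length(q)),
                forward = geneStrand == "*" | readStrand == geneStrand,
                reverse = geneStrand == "*" | readStrand != geneStrand)
            ok <- ok & w > 0L
            rd <- rd[ok]; s <- s[ok]; w <- w[ok]
            if (length(rd)) {
                gene <- as.character(mcols(segs)$gene_id)[s]
                cls <- mcols(segs)$class[s]
                key <- paste(rd, gene, cls, sep = "\r")
                agg <- rowsum(w, key)
                kk <- strsplit(rownames(agg), "\r", fixed = TRUE)
                aggRead <- as.integer(vapply(kk, `[`, character(1), 1L))
                aggGene <- vapply(kk, `[`, character(1), 2L)
                aggCls <- vapply(kk, `[`, character(1), 3L)
                aggW <- agg[, 1L]

                genesPerRead <- vapply(split(aggGene, aggRead),
                                       function(g) length(unique(g)), integer(1))
                readsTouched <- as.integer(names(genesPerRead))
                ambig <- readsTouched[genesPerRead > 1L]
                uniqReads <- readsTouched[genesPerRead == 1L]
                nAmbig <- length(ambig)
                if (length(uniqReads)) {
                    sel <- aggRead %in% uniqReads
                    selRead <- aggRead[sel]; selGene <- aggGene[sel]
                    selCls <- aggCls[sel]; selW <- aggW[sel]
                    wE <- rowsum(ifelse(selCls == "exon", selW, 0), selRead)
                    wI <- rowsum(ifelse(selCls == "intron", selW, 0), selRead)
                    geneOf <- vapply(split(selGene, selRead), `[`, character(1), 1L)
                    isIntron <- wI[, 1L] > wE[, 1L]  # tie -> exon
                    tabE <- table(factor(geneOf[!isIntron], levels = geneIds))
                    tabI <- table(factor(geneOf[isIntron], levels = geneIds))
                    exonCounts <- exonCounts + as.integer(tabE)
                    intronCounts <- intronCounts + as.integer(tabI)
                    nExon <- sum(!isIntron)
                    nIntron <- sum(isIntron)
                }
            }
        }
        nUnassigned <- nKeep - nExon - nIntron - nAmbig
    }
    list(exon = exonCounts, intron = intronCounts,
         summary = data.frame(
             total = total,
             discarded_non_unique = discardedNonUnique,
             discarded_low_mapq = discardedLowMapq,
             assigned_exon = nExon,
             assigned_intron = nIntron,
             ambiguous_multi_gene = nAmbig,
             unassigned_no_feature = nUnassigned))
}

.ensureBam <- function(file) {
    if (grepl("\\.sam$", file, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        Rsamtools::asBam(file, destination = dest, overwrite = TRUE,
                         indexDestination = TRUE)
    } else file
}

#' Write an IntronExonCounts object as TSV files
#'
#' Emits `<prefix>_counts_exon.tsv` and `<prefix>_counts_intron.tsv`
#' (gene_id plus one column per sample), `<prefix>_design.tsv`
#' (sample_id, condition) and, when present, `<prefix>_summary.tsv`
#' (per-sample read dispositions).
#'
#' @param counts an [IntronExonCounts-class].
#' @param prefix output path prefix.
#' @return the paths written, invisibly.
#' @export
writeCounts <- function(counts, prefix) {
    stopifnot(is(counts, "IntronExonCounts"))
    paths <- character()
    for (cls in c("exon", "intron")) {
        m <- SummarizedExperiment::assay(counts, cls)
        df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
        p <- paste0(prefix, "_counts_", cls, ".tsv")
        utils::write.table(df, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths <- c(paths, p)
    }
    cd <- SummarizedExperiment::colData(counts)
    p <- paste0(prefix, "_design.tsv")
    utils::write.table(data.frame(sample_id = rownames(cd),
                                  condition = cd$condition),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    if (!is.null(metadata(counts)$summary)) {
        p <- paste0(prefix, "_summary.tsv")
        s <- as.data.frame(metadata(counts)$summary)
        utils::write.table(data.frame(sample_id = rownames(s), s),
                           p, sep = "\t", quote = FALSE, row.names = FALSE)
        paths <- c(paths, p)
    }
    invisible(paths)
}
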