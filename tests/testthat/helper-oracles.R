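## Independent oracles and random-fixture builders used across the suite.

## --- brute-force per-base genome labeler ---------------------------------
## Labels every base of a small genome per gene as exon/intron by direct set
## arithmetic on base positions, applying the same semantics the catalog is
## supposed to implement: exon = union over transcripts; intron = span minus
## exon union; then any intron base covered by ANY gene's exon base (strand-
## blind) is removed. Returns per gene a list(exon=, intron=) of sorted base
## positions, keyed "chrom:base".
## These fixtures live on a single chromosome, so bases are plain integer
## positions; set arithmetic on integers keeps the oracle fast enough for a
## few hundred genomes.
bruteForceLabels <- function(models) {
    geneIds <- as.character(S4Vectors::mcols(models$genes)$gene_id)
    stopifnot(length(unique(as.character(
        GenomicRanges::seqnames(models$genes)))) <= 1L)
    txGene <- as.character(models$transcripts$gene_id)
    exonBases <- list()
    for (g in geneIds) {
        txs <- models$transcripts$tx_id[txGene == g]
        bases <- integer()
        for (t in txs) {
            ex <- models$exonsByTx[[t]]
            for (i in seq_along(ex))
                bases <- union(bases,
                               seq.int(BiocGenerics::start(ex)[i],
                                       BiocGenerics::end(ex)[i]))
        }
        exonBases[[g]] <- sort(bases)
    }
    allExon <- unique(unlist(exonBases, use.names = FALSE))
    out <- list()
    for (g in geneIds) {
        b <- exonBases[[g]]
        span <- seq.int(min(b), max(b))
        intron <- setdiff(setdiff(span, b), allExon)  # genome-wide purge
        ## a gene whose exon bases form one contiguous run carries no introns
        if (all(diff(b) == 1L)) intron <- integer()
        out[[g]] <- list(exon = b, intron = sort(intron))
    }
    out
}

## base set covered by a gene's segments of one class in a catalog;
## plain-vector extraction once, then per-gene integer expansion
catalogBases <- function(catalog, cls) {
    gr <- if (cls == "exon") exonSegments(catalog) else intronSegments(catalog)
    st <- BiocGenerics::start(gr); en <- BiocGenerics::end(gr)
    gid <- as.character(S4Vectors::mcols(gr)$gene_id)
    out <- list()
    for (i in seq_along(gid))
        out[[gid[i]]] <- c(out[[gid[i]]], seq.int(st[i], en[i]))
    lapply(out, sort)
}

## merge several independent GeneModels (each on its own chromosome set)
## into one, so a single catalog build covers many genomes at once
mergeGeneModels <- function(modelList) {
    ## c()-ing ranges from unrelated genomes merges disjoint seqinfos, which
    ## GenomeInfoDb flags; that is exactly what we want here
    genes <- suppressWarnings(unlist(GenomicRanges::GRangesList(
        lapply(modelList, function(m) {
            g <- m$genes
            S4Vectors::mcols(g) <- NULL
            g
        })), use.names = FALSE))
    S4Vectors::mcols(genes)$gene_id <- unlist(lapply(modelList, function(m)
        as.character(S4Vectors::mcols(m$genes)$gene_id)))
    tx <- do.call(rbind, lapply(modelList, function(m)
        as.data.frame(m$transcripts)))
    exonsByTx <- suppressWarnings(
        do.call(c, lapply(modelList, function(m) m$exonsByTx)))
    structure(list(genes = genes,
                   transcripts = S4Vectors::DataFrame(tx),
                   exonsByTx = exonsByTx,
                   orphans = character()),
              class = "GeneModels")
}

## --- random small gene models (messy overlaps, isoforms) -----------------
## Genomes <= 10 kb, <= maxGenes genes; genes placed independently so
## overlap/nesting arises naturally; some genes get a second isoform that
## skips one exon.
randomGeneModels <- function(seed, maxGenes = 20L, genomeLen = 10000L,
                             tag = "") {
    set.seed(seed)
    chromName <- paste0(tag, "chr1")
    nGenes <- sample.int(maxGenes, 1L)
    exS <- exE <- integer(); exTx <- character()
    txId <- txGene <- txStrand <- character()
    gS <- gEnd <- integer(); gId <- gStrand <- character()
    for (i in seq_len(nGenes)) {
        gid <- sprintf("%sg%02d", tag, i)
        strand <- sample(c("+", "-"), 1L)
        nExon <- sample(1:6, 1L)
        exLen <- sample(20:120, nExon, replace = TRUE)
        inLen <- if (nExon > 1L) sample(30:400, nExon - 1L, replace = TRUE)
                 else integer()
        glen <- sum(exLen) + sum(inLen)
        gstart <- sample.int(max(1L, genomeLen - glen), 1L)
        exStart <- gstart + c(0L, cumsum(exLen + c(inLen, 0L))[-nExon])
        exEnd <- exStart + exLen - 1L
        mk <- function(keep, tid) {
            exS <<- c(exS, exStart[keep]); exE <<- c(exE, exEnd[keep])
            exTx <<- c(exTx, rep(tid, length(keep)))
            txId <<- c(txId, tid); txGene <<- c(txGene, gid)
            txStrand <<- c(txStrand, strand)
        }
        mk(seq_len(nExon), paste0(gid, "_t1"))
        if (nExon >= 3L && runif(1) < 0.3)
            mk(setdiff(seq_len(nExon), sample(2:(nExon - 1L), 1L)),
               paste0(gid, "_t2"))
        gS <- c(gS, gstart); gEnd <- c(gEnd, gstart + glen - 1L)
        gId <- c(gId, gid); gStrand <- c(gStrand, strand)
    }
    exGr <- GenomicRanges::GRanges(chromName, IRanges::IRanges(exS, exE),
        strand = txStrand[match(exTx, txId)])
    genes <- GenomicRanges::GRanges(chromName, IRanges::IRanges(gS, gEnd),
                                    strand = gStrand)
    S4Vectors::mcols(genes)$gene_id <- gId
    structure(list(genes = genes,
                   transcripts = S4Vectors::DataFrame(tx_id = txId,
                                                      gene_id = txGene),
                   exonsByTx = GenomicRanges::split(exGr,
                       factor(exTx, levels = txId)),
                   orphans = character()),
              class = "GeneModels")
}

## --- brute-force read disposition ----------------------------------------
## Counts overlapping bases of a read's blocks against every catalog segment
## by explicit base enumeration, then applies the documented rule.
bruteDisposition <- function(blocks, catalog) {
    segs <- list(exon = exonSegments(catalog), intron = intronSegments(catalog))
    readBases <- unlist(lapply(seq_along(blocks), function(i)
        paste0(as.character(GenomicRanges::seqnames(blocks))[i], ":",
               seq(BiocGenerics::start(blocks)[i], BiocGenerics::end(blocks)[i]))))
    rows <- list()
    for (cls in names(segs)) {
        gr <- segs[[cls]]
        for (i in seq_along(gr)) {
            b <- paste0(as.character(GenomicRanges::seqnames(gr))[i], ":",
                        seq(BiocGenerics::start(gr)[i], BiocGenerics::end(gr)[i]))
            ov <- length(intersect(readBases, b))
            if (ov > 0)
                rows[[length(rows) + 1L]] <- data.frame(
                    gene_id = S4Vectors::mcols(gr)$gene_id[i],
                    class = cls, width = ov)
        }
    }
    if (!length(rows))
        return(list(disposition = "unassigned_no_feature",
                    gene_id = NA_character_))
    df <- do.call(rbind, rows)
    agg <- aggregate(width ~ gene_id + class, df, sum)
    if (length(unique(agg$gene_id)) > 1L)
        return(list(disposition = "ambiguous_multi_gene",
                    gene_id = NA_character_))
    wE <- sum(agg$width[agg$class == "exon"])
    wI <- sum(agg$width[agg$class == "intron"])
    list(disposition = if (wI > wE) "assigned_intron" else "assigned_exon",
         gene_id = unique(agg$gene_id))
}

## --- exact hypergeometric upper tail --------------------------------------
## P[X >= k] by direct enumeration of the hypergeometric pmf with choose().
exactHyperTail <- function(k, K, m, N) {
    kk <- k:min(K, m)
    sum(choose(m, kk) * choose(N - m, K - kk)) / choose(N, K)
}

## --- tiny GFF3 writer for hand-built fixtures ------------------------------
writeToyGFF3 <- function(lines, path = tempfile(fileext = ".gff3")) {
    writeLines(c("##gff-version 3", lines), path)
    path
}
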