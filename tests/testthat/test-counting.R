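## shared small genome + catalog for the counting tests
mkCountingFixture <- function(seed = 7L, nGenes = 40L) {
    cfg <- simulationConfig(n_genes = nGenes, seed = seed)
    ann <- simulateAnnotation(cfg)
    p <- tempfile(fileext = ".gff3")
    writeLines(ann$gff3, p)
    list(cfg = cfg, catalog = buildFeatureCatalog(parseGeneModels(p)),
         truth = ann$truth)
}

test_that("read-class resolution follows majority overlap with exon tie-break", {
    one <- function(...) resolveReadClass(data.frame(...))
    expect_equal(one(gene_id = "g", class = c("exon", "intron"),
                     width = c(80, 20))$disposition, "assigned_exon")
    expect_equal(one(gene_id = "g", class = c("exon", "intron"),
                     width = c(20, 80))$disposition, "assigned_intron")
    expect_equal(one(gene_id = "g", class = c("exon", "intron"),
                     width = c(50, 50))$disposition, "assigned_exon")
    expect_equal(one(gene_id = c("g1", "g2"), class = c("exon", "exon"),
                     width = c(60, 40))$disposition, "ambiguous_multi_gene")
    expect_equal(resolveReadClass(
        data.frame(gene_id = character(), class = character(),
                   width = numeric()))$disposition, "unassigned_no_feature")
})

test_that("random block sets match the exhaustive base-count oracle", {
    fx <- mkCountingFixture(seed = 11L, nGenes = 15L)
    segs <- intronDE:::.catalogSegments(fx$catalog)
    set.seed(42)
    for (i in 1:60) {
        chrom <- sample(unique(as.character(seqnames(segs))), 1)
        lo <- sample(2000:20000, 1)
        nb <- sample(1:3, 1)
        starts <- sort(sample(lo:(lo + 400), nb))
        blocks <- GRanges(chrom, IRanges(starts, width = sample(20:80, nb,
                                                                replace = TRUE)))
        blocks <- reduce(blocks)  # guarantee sorted non-overlapping blocks
        oracle <- bruteDisposition(blocks, fx$catalog)
        hits <- findOverlaps(blocks, segs, ignore.strand = TRUE)
        ov <- data.frame(
            gene_id = S4Vectors::mcols(segs)$gene_id[subjectHits(hits)],
            class = S4Vectors::mcols(segs)$class[subjectHits(hits)],
            width = width(pintersect(blocks[queryHits(hits)],
                                     segs[subjectHits(hits)],
                                     ignore.strand = TRUE)))
        got <- resolveReadClass(ov)
        expect_identical(got, oracle, label = paste("case", i))
    }
})

test_that("counting a simulated SAM reproduces the placement record exactly", {
    fx <- mkCountingFixture()
    genes <- rownames(geneInfo(fx$catalog))
    set.seed(5)
    tallies <- data.frame(
        gene_id = rep(genes, each = 2),
        class = rep(c("exon", "intron"), length(genes)),
        n = sample(0:30, 2 * length(genes), replace = TRUE))
    al <- simulateAlignments(fx$catalog, tallies, seed = 9L)
    sam <- tempfile(fileext = ".sam")
    writeLines(al$sam, sam)
    cc <- countReads(c(s1 = sam), fx$catalog, condition = "A")
    pl <- al$placements
    for (cls in c("exon", "intron")) {
        want <- tapply(pl$n_placed[pl$class == cls],
                       pl$gene_id[pl$class == cls], sum)
        got <- assay(cc, cls)[names(want), 1]
        expect_equal(unname(got), as.integer(want), label = cls)
    }
    ## conservation: dispositions sum to record total
    s <- as.data.frame(metadata(cc)$summary)
    expect_equal(s$total,
                 s$discarded_non_unique + s$discarded_low_mapq +
                 s$assigned_exon + s$assigned_intron +
                 s$ambiguous_multi_gene + s$unassigned_no_feature)
    expect_equal(s$total, sum(pl$n_placed))
})

test_that("strand mode, uniqueness filter and off-catalog reads behave as documented", {
    fx <- mkCountingFixture(seed = 13L, nGenes = 10L)
    genes <- rownames(geneInfo(fx$catalog))
    tallies <- data.frame(gene_id = genes[1:5], class = "exon", n = 4L)
    al <- simulateAlignments(fx$catalog, tallies, seed = 2L)

    ## flipping every read's strand and the mode's sense leaves counts unchanged
    flip <- function(lines) {
        vapply(lines, function(l) {
            if (grepl("^@", l)) return(l)
            f <- strsplit(l, "\t")[[1]]
            f[2] <- ifelse(f[2] == "16", "0", "16")
            paste(f, collapse = "\t")
        }, character(1), USE.NAMES = FALSE)
    }
    s1 <- tempfile(fileext = ".sam"); writeLines(al$sam, s1)
    s2 <- tempfile(fileext = ".sam"); writeLines(flip(al$sam), s2)
    c1 <- countReads(c(a = s1), fx$catalog, condition = "A",
                     strandedness = "reverse")
    c2 <- countReads(c(a = s2), fx$catalog, condition = "A",
                     strandedness = "forward")
    expect_equal(assay(c1, "exon"), assay(c2, "exon"))
    expect_equal(assay(c1, "intron"), assay(c2, "intron"))
    ## in the wrong sense the reads are unassigned, not miscounted
    c3 <- countReads(c(a = s1), fx$catalog, condition = "A",
                     strandedness = "forward")
    expect_equal(sum(assay(c3, "exon")), 0L)
    expect_equal(as.data.frame(metadata(c3)$summary)$unassigned_no_feature,
                 sum(al$placements$n_placed))

    ## multimappers (NH > 1) are discarded under the unique filter
    bump <- sub("NH:i:1", "NH:i:3", al$sam)
    s4 <- tempfile(fileext = ".sam"); writeLines(bump, s4)
    c4 <- countReads(c(a = s4), fx$catalog, condition = "A")
    expect_equal(sum(assay(c4, "exon")) + sum(assay(c4, "intron")), 0L)
    expect_equal(as.data.frame(metadata(c4)$summary)$discarded_non_unique,
                 sum(al$placements$n_placed))

    ## chromosome absent from the catalog -> unassigned plus a message
    extra <- c(al$sam[grepl("^@", al$sam)],
               "@SQ\tSN:chrZ\tLN:5000",
               sub("^(\\S+\t\\S+\t)\\S+", "\\1chrZ",
                   al$sam[!grepl("^@", al$sam)][1]))
    s5 <- tempfile(fileext = ".sam"); writeLines(extra, s5)
    expect_message(
        c5 <- countReads(c(a = s5), fx$catalog, condition = "A"),
        "absent from catalog")
    expect_equal(as.data.frame(metadata(c5)$summary)$unassigned_no_feature, 1L)
})

test_that("counting is monotone: adding reads never decreases a count", {
    fx <- mkCountingFixture(seed = 21L, nGenes = 8L)
    genes <- rownames(geneInfo(fx$catalog))
    t1 <- data.frame(gene_id = genes, class = "exon", n = 3L)
    t2 <- rbind(t1, data.frame(gene_id = genes, class = "intron", n = 2L))
    a1 <- simulateAlignments(fx$catalog, t1, seed = 4L)
    a2 <- simulateAlignments(fx$catalog, t2, seed = 4L)
    s1 <- tempfile(fileext = ".sam"); writeLines(a1$sam, s1)
    s2 <- tempfile(fileext = ".sam"); writeLines(a2$sam, s2)
    c1 <- countReads(c(a = s1), fx$catalog, condition = "A")
    c2 <- countReads(c(a = s2), fx$catalog, condition = "A")
    expect_true(all(assay(c2, "exon") >= assay(c1, "exon")))
    expect_true(all(assay(c2, "intron") >= assay(c1, "intron")))
})

test_that("counts round-trip through the TSV writer", {
    m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
    cc <- IntronExonCounts(m, m * 0L, condition = c("A", "B"))
    prefix <- tempfile()
    writeCounts(cc, prefix)
    back <- read.delim(paste0(prefix, "_counts_exon.tsv"), check.names = FALSE)
    expect_equal(as.matrix(back[, -1]),
                 matrix(1:6, 3, 2, dimnames = list(NULL, c("s1", "s2"))))
    des <- read.delim(paste0(prefix, "_design.tsv"))
    expect_equal(des$condition, c("A", "B"))
})
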