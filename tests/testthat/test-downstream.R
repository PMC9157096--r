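test_that("overlap summaries reproduce printed-table arithmetic", {
    ## enhancer-style: 25 of 31 -> 80.6%, 179 of 225 -> 79.6%
    expect_equal(overlapSummary(c(25, 179), c(31, 225))$percentage,
                 c(80.6, 79.6))
    ## TF-coverage style: 2,554 of 2,768 -> 92.3%; 1,185 of 1,379 -> 85.9%
    expect_equal(overlapSummary(c(2554, 1185), c(2768, 1379))$percentage,
                 c(92.3, 85.9))
    ## subgenome style at 2 decimals: 1,415 of 2,573 -> 54.99%
    expect_equal(overlapSummary(1415, 2573, digits = 2)$percentage, 54.99)
    expect_equal(overlapSummary(893, 2768, digits = 2)$percentage, 32.26)
    ## per-TF style: 847 and 315 of 1,162 -> 72.9% / 27.1%
    expect_equal(overlapSummary(c(847, 315), c(1162, 1162))$percentage,
                 c(72.9, 27.1))
    expect_equal(overlapSummary(c(50, 28), c(78, 78))$percentage,
                 c(64.1, 35.9))
    ## zero denominator is undefined, not 0%
    expect_true(is.na(overlapSummary(0, 0)$percentage))
})

## small synthetic calls + annotations used by the join operations
mkJoinFixture <- function(seed = 3L) {
    cfg <- simulationConfig(n_genes = 400L, seed = seed)
    sim <- simulateCounts(cfg, NULL, simulateTruthSkeleton(cfg))
    de <- testDifferential(sim$counts)
    exonN <- setNames(sim$truth$exon_count, sim$truth$gene_id)
    calls <- classifyRegulation(de$intron, de$exon, exonN)
    aux <- simulateAuxiliary(cfg, sim$truth)
    list(cfg = cfg, sim = sim, calls = calls, aux = aux, exonN = exonN)
}

test_that("enhancer overlap purges single-exon genes and splits by class", {
    fx <- mkJoinFixture()
    ov <- enhancerOverlap(fx$calls, fx$aux$enhancers, fx$exonN)
    expect_setequal(unique(ov$tissue), fx$cfg$conditions)
    ## numerators sum to the denominator within a tissue
    for (t in unique(ov$tissue)) {
        sub <- ov[ov$tissue == t, ]
        expect_equal(sum(sub$numerator), sub$denominator[1])
        if (sub$denominator[1] > 0)
            expect_equal(sum(sub$percentage), 100, tolerance = 0.2)
    }
    ## enhancer lists enriched for true transcriptional genes -> the
    ## transcriptional share clearly dominates
    tshare <- ov$numerator[ov$category == "transcriptional"]
    pshare <- ov$numerator[ov$category == "post_transcriptional_multiexon"]
    expect_gt(sum(tshare), sum(pshare))
    ## single-exon genes never enter
    enhSingle <- data.frame(gene_id = names(fx$exonN)[fx$exonN == 1][1],
                            tissue = fx$cfg$conditions[1])
    ov2 <- enhancerOverlap(fx$calls, enhSingle, fx$exonN)
    expect_true(is.null(ov2) || all(ov2$denominator == 0))
    ## empty list -> undefined, not 0%
    ovE <- enhancerOverlap(fx$calls,
                           data.frame(gene_id = character(),
                                      tissue = character()), fx$exonN)
    expect_true(is.null(ovE) || all(is.na(ovE$percentage)))
})

test_that("enhancerOverlap and exonCount also accept a real catalog", {
    cfg <- simulationConfig(n_genes = 30L, seed = 9L)
    ann <- simulateAnnotation(cfg)
    p <- tempfile(fileext = ".gff3"); writeLines(ann$gff3, p)
    catg <- buildFeatureCatalog(parseGeneModels(p))
    calls <- S4Vectors::DataFrame(
        gene_id = ann$truth$gene_id[1:4], tissue = "A",
        category = "transcriptional", evidence = "both",
        exon_count = ann$truth$exon_count[1:4], conflict = FALSE)
    enh <- data.frame(gene_id = ann$truth$gene_id[1:4], tissue = "A")
    ov <- enhancerOverlap(calls, enh, catg)
    expect_true(all(ov$denominator <= 4))
})

test_that("TF target coverage counts class members inside the active-TF target pool", {
    fx <- mkJoinFixture()
    cov <- tfTargetCoverage(fx$calls, fx$aux$network, fx$aux$tfGenes)
    expect_true(all(cov$numerator <= cov$denominator))
    ## empty network -> 0% with nonzero denominator
    cov0 <- tfTargetCoverage(fx$calls,
                             data.frame(tf_id = character(),
                                        target_id = character()),
                             fx$aux$tfGenes)
    expect_true(all(cov0$numerator == 0))
    expect_true(any(cov0$denominator > 0))
    expect_true(all(cov0$percentage[cov0$denominator > 0] == 0))
})

test_that("subgenome breakdown partitions each class and sums to 100%", {
    fx <- mkJoinFixture()
    br <- subgenomeBreakdown(fx$calls, fx$aux$subgenomes)
    for (key in unique(paste(br$tissue, br$category))) {
        sub <- br[paste(br$tissue, br$category) == key, ]
        expect_equal(nrow(sub), 3L)
        if (sub$denominator[1] > 0) {
            expect_equal(sum(sub$numerator), sub$denominator[1])
            expect_equal(sum(sub$percentage), 100, tolerance = 0.05)
        }
    }
    ## unlabeled genes all fall into 'none'
    br0 <- subgenomeBreakdown(fx$calls,
                              data.frame(gene_id = character(),
                                         label = character()))
    none <- br0[br0$subgenome == "none" & br0$denominator > 0, ]
    expect_true(all(none$percentage == 100))
})

test_that("per-TF target summaries split DE targets by regulatory class", {
    fx <- mkJoinFixture()
    net <- fx$aux$network
    targets <- split(net$target_id, net$tf_id)
    gs <- grnTargetSummary(targets, fx$calls)
    expect_equal(gs$de_total, gs$transcriptional + gs$post_transcriptional)
    ok <- gs$de_total > 0
    expect_equal(gs$pct_transcriptional[ok] + gs$pct_post_transcriptional[ok],
                 rep(100, sum(ok)), tolerance = 0.2)
    ## a TF with no DE targets reports undefined percentages
    gs0 <- grnTargetSummary(list(tfX = "no_such_gene"), fx$calls)
    expect_true(is.na(gs0$pct_transcriptional))
})

test_that("Fisher enrichment matches exhaustive hypergeometric enumeration", {
    ## worked single table: k=5, K=10, m=5, N=20
    p <- termEnrichment(paste0("s", 1:10), paste0("s", 1:20),
                        data.frame(gene_id = paste0("s", 1:5), term = "T"),
                        minEntries = 5L)
    expect_equal(p$p, choose(15, 5) / choose(20, 10), tolerance = 1e-12)
    expect_equal(p$p, 0.01625387, tolerance = 1e-7)
    expect_equal(p$p, exactHyperTail(5, 10, 5, 20), tolerance = 1e-12)

    ## random tables with N <= 60: implementation vs enumeration
    set.seed(31)
    for (i in 1:50) {
        N <- sample(10:60, 1)
        K <- sample(1:N, 1)
        m <- sample(1:N, 1)
        bg <- paste0("g", seq_len(N))
        study <- sample(bg, K)
        mapped <- sample(bg, m)
        res <- termEnrichment(study, bg,
                              data.frame(gene_id = mapped, term = "T"),
                              minEntries = 1L)
        k <- sum(study %in% mapped)
        expect_equal(res$p, exactHyperTail(k, K, m, N), tolerance = 1e-10,
                     label = sprintf("N=%d K=%d m=%d", N, K, m))
    }

    ## study == background -> p = 1 for every term
    bg <- paste0("g", 1:30)
    gm <- data.frame(gene_id = rep(bg, 2),
                     term = rep(c("T1", "T2"), each = 30))
    resAll <- termEnrichment(bg, bg, gm)
    expect_true(all(resAll$p == 1))
    ## study must be inside the background
    expect_error(termEnrichment(c(bg, "alien"), bg, gm), "absent")
})

test_that("BY dominates BH dominates raw p, and uses the harmonic factor", {
    set.seed(8)
    p <- runif(40)^2
    by <- p.adjust(p, "BY"); bh <- p.adjust(p, "BH")
    expect_true(all(by >= bh - 1e-15))
    expect_true(all(bh >= p - 1e-15))
    ## n = 3: the BY inflation factor is 1 + 1/2 + 1/3 = 11/6; apply the
    ## step-up rule by hand and compare
    p3 <- c(0.01, 0.2, 0.9)
    h <- 11 / 6
    raw <- pmin(1, sort(p3) * h * 3 / (1:3))
    oracle <- rev(cummin(rev(raw)))
    expect_equal(sort(p.adjust(p3, "BY")), oracle, tolerance = 1e-12)
})

test_that("a spiked GO term is detected below the configured FDR", {
    fx <- mkJoinFixture(seed = 6L)
    tru <- fx$sim$truth
    study <- tru$gene_id[tru$true_class == "transcriptional"]
    res <- termEnrichment(study, tru$gene_id, fx$aux$goMap)
    spike <- res[res$term == fx$aux$spikedTerm, ]
    expect_equal(nrow(spike), 1L)
    expect_lt(spike$fdr, 0.01)
    expect_true(spike$significant)
    ## background terms are not flagged wholesale
    expect_lt(mean(res$significant), 0.5)
})

test_that("gene ids pass through a synonym table", {
    syn <- data.frame(from = c("v4_1", "v4_2"), to = c("v3_1", "v3_2"))
    expect_equal(translateGeneIds(c("v4_1", "x", "v4_2"), syn),
                 c("v3_1", "x", "v3_2"))
})
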