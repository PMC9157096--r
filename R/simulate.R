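#' Simulation configuration
#'
#' Collects the parameters of the synthetic-data generator. The defaults
#' emulate the study design the pipeline is built for: two conditions with
#' three replicates each, negative-binomial counts in which transcriptional
#' effects move intron and exon abundance jointly while post-transcriptional
#' effects move exon abundance only, gene models with 1-20 exons including
#' single-exon genes, genes nested inside other genes' introns, and
#' alternative isoforms.
#'
#' @param n_genes number of genes (default 200).
#' @param single_exon_prob probability a gene has exactly one exon
#'   (default 0.15); otherwise the exon count is uniform on
#'   `multi_exon_range`.
#' @param multi_exon_range inclusive exon-count range for multi-exon genes
#'   (default 2:20).
#' @param nested_rate probability a gene is placed inside a previously
#'   placed gene's intron when one is large enough (default 0.1).
#' @param isoform_rate probability a gene with >= 3 exons gets a second
#'   isoform skipping one internal exon (default 0.2).
#' @param exon_len_range,intron_len_range,gap_range inclusive bp ranges for
#'   exon lengths, intron lengths and intergenic gaps.
#' @param n_chrom chromosomes genes are spread over (default 2).
#' @param reps replicates per condition (default 3).
#' @param conditions the two condition labels; the first is the fold-change
#'   numerator (default `c("A", "B")`).
#' @param frac_transcriptional fraction of genes transcriptionally DE *per
#'   tissue* (default 0.1 each).
#' @param frac_post fraction post-transcriptionally DE per tissue
#'   (default 0.05 each).
#' @param lfc absolute true log2 fold-change of DE genes (default 2).
#' @param exon_mean baseline exon-count mean per gene (default 500).
#' @param intron_ratio intron:exon abundance ratio, reflecting the scarcity
#'   of the nascent pre-mRNA fraction (default 0.1, i.e. intron mean 50).
#' @param alpha NB dispersion shared by both feature classes (default 0.05).
#' @param read_length simulated read length in bp (default 100).
#' @param enhancer_n enhancer-linked genes sampled per tissue (default 40).
#' @param enhancer_odds odds multiplier favouring true transcriptional genes
#'   of the matching tissue in enhancer lists (default 8; 1 = no
#'   enrichment).
#' @param tf_per_tissue simulated active TFs per tissue (default 5).
#' @param targets_per_tf network targets drawn per TF (default 40).
#' @param target_odds odds multiplier favouring DE genes among network
#'   targets (default 8).
#' @param subgenome_probs probabilities of the Maize1-like / Maize2-like /
#'   unassigned labels (default `c(0.5, 0.3, 0.2)`).
#' @param go_terms_n background GO terms (default 20); one extra spiked
#'   term is planted in true transcriptional genes.
#' @param seed mandatory RNG seed; every generator output is byte-identical
#'   given the same config.
#' @return list of class `SimulationConfig`.
#' @export
simulationConfig <- function(n_genes = 200L,
                             single_exon_prob = 0.15,
                             multi_exon_range = c(2L, 20L),
                             nested_rate = 0.1,
                             isoform_rate = 0.2,
                             exon_len_range = c(80L, 300L),
                             intron_len_range = c(60L, 500L),
                             gap_range = c(200L, 1000L),
                             n_chrom = 2L,
                             reps = 3L,
                             conditions = c("A", "B"),
                             frac_transcriptional = 0.1,
                             frac_post = 0.05,
                             lfc = 2,
                             exon_mean = 500,
                             intron_ratio = 0.1,
                             alpha = 0.05,
                             read_length = 100L,
                             enhancer_n = 40L,
                             enhancer_odds = 8,
                             tf_per_tissue = 5L,
                             targets_per_tf = 40L,
                             target_odds = 8,
                             subgenome_probs = c(0.5, 0.3, 0.2),
                             go_terms_n = 20L,
                             seed = 1L) {
    stopifnot(2 * frac_transcriptional + 2 * frac_post <= 1,
              intron_ratio > 0, alpha >= 0, reps >= 2L,
              length(conditions) == 2L, !is.null(seed))
    cfg <- as.list(environment())
    class(cfg) <- "SimulationConfig"
    cfg
}

.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(list = ".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

.runif_int <- function(n, range) {
    as.integer(floor(stats::runif(n, range[1], range[2] + 1)))
}

#' Simulate a GFF3 genome annotation with ground truth
#'
#' Generates gene models with the configured single-exon probability,
#' nesting (a gene dropped whole into an earlier gene's intron) and
#' alternative isoforms (a second transcript skipping one internal exon).
#' The emitted text is valid GFF3 that round-trips through
#' [parseGeneModels()], byte-identical for a fixed config.
#'
#' @param config a [simulationConfig()].
#' @return list with `gff3` (character vector of lines) and `truth`
#'   (data.frame: `gene_id`, `chrom`, `strand`, `exon_count`, `nested`,
#'   `n_isoforms`).
#' @export
simulateAnnotation <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    .withSeed(config$seed, {
        n <- config$n_genes
        lines <- "##gff-version 3"
        truth <- data.frame(gene_id = character(n), chrom = character(n),
                            strand = character(n), exon_count = integer(n),
                            nested = logical(n), n_isoforms = integer(n))
        if (n == 0L) return(list(gff3 = lines, truth = truth))

        cursor <- stats::setNames(rep(1L, config$n_chrom),
                                  paste0("chr", seq_len(config$n_chrom)))
        ## host introns available for nesting: chrom, start, end (exclusive bounds)
        hosts <- data.frame(chrom = character(), start = integer(),
                            end = integer())
        for (i in seq_len(n)) {
            gid <- sprintf("gene%03d", i)
            nExon <- if (stats::runif(1) < config$single_exon_prob) 1L
                     else .runif_int(1, config$multi_exon_range)
            exLen <- .runif_int(nExon, config$exon_len_range)
            inLen <- if (nExon > 1L) .runif_int(nExon - 1L,
                                                config$intron_len_range)
                     else integer()
            glen <- sum(exLen) + sum(inLen)
            strand <- sample(c("+", "-"), 1L)

            nested <- FALSE
            fit <- which(hosts$end - hosts$start + 1L >= glen + 2L)
            if (length(fit) && stats::runif(1) < config$nested_rate) {
                h <- fit[1L]
                chrom <- hosts$chrom[h]
                gstart <- hosts$start[h] + 1L
                hosts <- hosts[-h, , drop = FALSE]
                nested <- TRUE
            } else {
                chrom <- names(cursor)[which.min(cursor)]
                gstart <- cursor[[chrom]] + .runif_int(1, config$gap_range)
                cursor[[chrom]] <- gstart + glen
            }
            gend <- gstart + glen - 1L

            exStart <- gstart + c(0L, cumsum(exLen + c(inLen, 0L))[-nExon])
            exEnd <- exStart + exLen - 1L
            if (nExon > 1L && !nested) {
                iS <- exEnd[-nExon] + 1L
                iE <- exStart[-1L] - 1L
                big <- which(iE - iS + 1L >= 50L)
                if (length(big))
                    hosts <- rbind(hosts, data.frame(chrom = chrom,
                                                     start = iS[big],
                                                     end = iE[big]))
            }

            nIso <- 1L
            skip <- NA_integer_
            if (nExon >= 3L && stats::runif(1) < config$isoform_rate) {
                nIso <- 2L
                skip <- .runif_int(1, c(2L, nExon - 1L))
            }

            lines <- c(lines, sprintf(
                "%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s", chrom, gstart,
                gend, strand, gid))
            for (iso in seq_len(nIso)) {
                tid <- sprintf("%s_t%d", gid, iso)
                keep <- if (iso == 2L) setdiff(seq_len(nExon), skip)
                        else seq_len(nExon)
                lines <- c(lines, sprintf(
                    "%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                    chrom, min(exStart[keep]), max(exEnd[keep]), strand,
                    tid, gid))
                lines <- c(lines, sprintf(
                    "%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                    chrom, exStart[keep], exEnd[keep], strand, tid,
                    seq_along(keep), tid))
            }
            truth[i, ] <- list(gid, chrom, strand, nExon, nested, nIso)
        }
        list(gff3 = lines, truth = truth)
    })
}

#' Simulate exon and intron count tables with known regulatory classes
#'
#' Generative model per gene and condition: a transcription rate sets the
#' shared scale of the nascent (intron) and mature (exon) signal, and an
#' mRNA-stability term multiplies the exon signal only. Transcriptional DE
#' multiplies the transcription rate by `2^lfc` in the up tissue (moving
#' intron *and* exon counts); post-transcriptional DE multiplies stability
#' only (exon moves, intron does not). Counts are NB with the configured
#' dispersion; genes whose catalog has no intron segment get zero intron
#' counts.
#'
#' @param config a [simulationConfig()].
#' @param catalog a [FeatureCatalog-class] built from
#'   [simulateAnnotation()] output, or `NULL` to take intron presence from
#'   `truth$exon_count` (multi-exon genes carry introns) for count-level
#'   simulations that skip the annotation stage.
#' @param truth the truth data.frame from [simulateAnnotation()].
#' @return list with `counts` (an [IntronExonCounts-class]), `truth`
#'   (augmented with `true_class`, `true_tissue`, `true_lfc`) and `design`
#'   (data.frame `sample_id`, `condition`, `replicate`).
#' @export
simulateCounts <- function(config, catalog, truth) {
    stopifnot(inherits(config, "SimulationConfig"))
    .withSeed(config$seed + 1L, {
        genes <- truth$gene_id
        n <- length(genes)
        nT <- round(config$frac_transcriptional * n)
        nP <- round(config$frac_post * n)
        shuffled <- sample(genes)
        cls <- rep("null", n)
        tis <- rep(NA_character_, n)
        names(cls) <- names(tis) <- shuffled
        idx <- 1L
        for (t in config$conditions) {
            take <- shuffled[seq.int(idx, length.out = nT)]
            cls[take] <- "transcriptional"; tis[take] <- t
            idx <- idx + nT
            take <- shuffled[seq.int(idx, length.out = nP)]
            cls[take] <- "post_transcriptional"; tis[take] <- t
            idx <- idx + nP
        }
        cls <- cls[genes]; tis <- tis[genes]
        lfc <- ifelse(cls == "null", 0, config$lfc)

        hasIntron <- if (is.null(catalog)) truth$exon_count >= 2L
            else genes %in% unique(
                as.character(mcols(intronSegments(catalog))$gene_id))
        exonBase <- rep(config$exon_mean, n)
        intronBase <- ifelse(hasIntron, config$exon_mean * config$intron_ratio, 0)

        mult <- function(condition) {
            up <- !is.na(tis) & tis == condition
            tau <- ifelse(up & cls == "transcriptional", 2^lfc, 1)
            stab <- ifelse(up & cls == "post_transcriptional", 2^lfc, 1)
            list(exon = tau * stab, intron = tau)
        }
        rnb <- function(mu) {
            out <- integer(length(mu))
            pos <- mu > 0
            out[pos] <- if (config$alpha < 1e-12)
                stats::rpois(sum(pos), mu[pos])
            else stats::rnbinom(sum(pos), mu = mu[pos],
                                size = 1 / config$alpha)
            out
        }
        sampleIds <- paste0(rep(config$conditions, each = config$reps),
                            "_rep", rep(seq_len(config$reps), 2L))
        condition <- rep(config$conditions, each = config$reps)
        exon <- intron <- matrix(0L, n, length(sampleIds),
                                 dimnames = list(genes, sampleIds))
        for (j in seq_along(sampleIds)) {
            m <- mult(condition[j])
            exon[, j] <- rnb(exonBase * m$exon)
            intron[, j] <- rnb(intronBase * m$intron)
        }
        truth$true_class <- unname(cls)
        truth$true_tissue <- unname(tis)
        truth$true_lfc <- unname(lfc)
        design <- data.frame(sample_id = sampleIds, condition = condition,
                             replicate = rep(seq_len(config$reps), 2L))
        list(counts = IntronExonCounts(exon, intron, condition),
             truth = truth, design = design)
    })
}

#' Simulate single-end aligned reads as SAM text
#'
#' Places reads wholly inside catalog segments according to the requested
#' per-(gene, class) tallies, reverse-stranded (read antisense to its gene,
#' the dUTP library convention). Reads are only placed in segment regions
#' not shared with any other gene's segments, so counting the emitted SAM
#' with [countReads()] reproduces the placement record exactly. A (gene,
#' class) with no usable region gets zero placements, recorded as such.
#'
#' @param catalog a [FeatureCatalog-class].
#' @param tallies data.frame with columns `gene_id`, `class`
#'   (`"exon"`/`"intron"`), `n` (reads requested).
#' @param readLength read length in bp (default 100); shrinks to fit short
#'   segments.
#' @param seed RNG seed.
#' @return list with `sam` (character vector of SAM lines) and `placements`
#'   (the tallies with an `n_placed` column).
#' @export
simulateAlignments <- function(catalog, tallies, readLength = 100L, seed = 1L) {
    segs <- .catalogSegments(catalog)
    ## regions covered by exactly one segment are safe for unambiguous reads
    dj <- GenomicRanges::disjoin(segs, ignore.strand = TRUE)
    cov <- GenomicRanges::countOverlaps(dj, segs, ignore.strand = TRUE)
    uniqRegion <- dj[cov == 1L]
    hit <- GenomicRanges::findOverlaps(segs, uniqRegion, ignore.strand = TRUE)
    safe <- GenomicRanges::pintersect(
        segs[S4Vectors::queryHits(hit)],
        uniqRegion[S4Vectors::subjectHits(hit)],
        ignore.strand = TRUE)
    mcols(safe) <- mcols(segs)[S4Vectors::queryHits(hit), ]

    gi <- geneInfo(catalog)
    chroms <- sort(unique(gi$chrom))
    chromLen <- vapply(chroms, function(ch)
        max(gi$span_end[gi$chrom == ch]) + 1000L, numeric(1))

    .withSeed(seed, {
        header <- c("@HD\tVN:1.6\tSO:unknown",
                    sprintf("@SQ\tSN:%s\tLN:%d", chroms,
                            as.integer(chromLen)))
        recs <- character()
        tallies$n_placed <- 0L
        ctr <- 0L
        for (r in seq_len(nrow(tallies))) {
            nReq <- tallies$n[r]
            if (nReq <= 0L) next
            cand <- safe[mcols(safe)$gene_id == tallies$gene_id[r] &
                         mcols(safe)$class == tallies$class[r]]
            if (!length(cand)) next
            w <- BiocGenerics::width(cand)
            rl <- min(readLength, max(w))
            cand <- cand[w >= rl]
            w <- BiocGenerics::width(cand)
            pick <- sample.int(length(cand), nReq, replace = TRUE,
                               prob = w - rl + 1L)
            off <- floor(stats::runif(nReq) * (w[pick] - rl + 1L))
            pos <- BiocGenerics::start(cand)[pick] + as.integer(off)
            geneStrand <- gi[tallies$gene_id[r], "strand"]
            flag <- if (geneStrand == "+") 16L else 0L  # antisense read
            recs <- c(recs, sprintf(
                "read%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNH:i:1",
                ctr + seq_len(nReq), flag,
                as.character(GenomicRanges::seqnames(cand))[pick], pos, rl,
                strrep("A", rl)))
            ctr <- ctr + nReq
            tallies$n_placed[r] <- nReq
        }
        list(sam = c(header, recs), placements = tallies)
    })
}

#' Simulate auxiliary annotation tables enriched for the true classes
#'
#' Emits the downstream-integration inputs with configurable enrichment:
#' enhancer-linked gene lists preferentially sampling true transcriptional
#' genes of the matching tissue, a TF-target network whose targets
#' preferentially sample DE genes, subgenome labels, and a GO map with one
#' spiked term planted in true transcriptional genes (for
#' enrichment-detection checks).
#'
#' @param config a [simulationConfig()].
#' @param truth truth data.frame from [simulateCounts()] (with
#'   `true_class` / `true_tissue`).
#' @return list with data.frames `enhancers` (`gene_id`, `tissue`),
#'   `network` (`tf_id`, `target_id`), `subgenomes` (`gene_id`, `label`),
#'   `goMap` (`gene_id`, `term`), plus `tfGenes` and `spikedTerm`.
#' @export
simulateAuxiliary <- function(config, truth) {
    stopifnot(inherits(config, "SimulationConfig"),
              "true_class" %in% names(truth))
    .withSeed(config$seed + 2L, {
        genes <- truth$gene_id
        n <- length(genes)
        if (n == 0L)
            return(list(enhancers = data.frame(gene_id = character(),
                                               tissue = character()),
                        network = data.frame(tf_id = character(),
                                             target_id = character()),
                        subgenomes = data.frame(gene_id = character(),
                                                label = character()),
                        goMap = data.frame(gene_id = character(),
                                           term = character()),
                        tfGenes = character(), spikedTerm = NA_character_))
        isDE <- truth$true_class != "null"

        enh <- lapply(config$conditions, function(t) {
            w <- ifelse(truth$true_class == "transcriptional" &
                        truth$true_tissue == t & !is.na(truth$true_tissue),
                        config$enhancer_odds, 1)
            k <- min(config$enhancer_n, n)
            data.frame(gene_id = sample(genes, k, prob = w), tissue = t)
        })
        enhancers <- do.call(rbind, enh)

        tfGenes <- unlist(lapply(config$conditions, function(t) {
            pool <- genes[truth$true_class == "transcriptional" &
                          truth$true_tissue == t & !is.na(truth$true_tissue)]
            sample(pool, min(config$tf_per_tissue, length(pool)))
        }))
        wTarget <- ifelse(isDE, config$target_odds, 1)
        network <- do.call(rbind, lapply(tfGenes, function(tf) {
            k <- min(config$targets_per_tf, n - 1L)
            data.frame(tf_id = tf,
                       target_id = sample(setdiff(genes, tf), k,
                                          prob = wTarget[genes != tf]))
        }))

        subgenomes <- data.frame(
            gene_id = genes,
            label = sample(c("Maize1", "Maize2", "none"), n, replace = TRUE,
                           prob = config$subgenome_probs))
        subgenomes <- subgenomes[subgenomes$label != "none", , drop = FALSE]

        terms <- sprintf("GO:%07d", seq_len(config$go_terms_n))
        nAssign <- stats::rpois(n, 3) + 1L
        goMap <- data.frame(
            gene_id = rep(genes, nAssign),
            term = unlist(lapply(nAssign, function(k)
                sample(terms, k, replace = FALSE))))
        spikedTerm <- "GO:9999999"
        spikeGenes <- genes[truth$true_class == "transcriptional"]
        if (length(spikeGenes) >= 2L)
            goMap <- rbind(goMap, data.frame(gene_id = spikeGenes,
                                             term = spikedTerm))
        goMap <- unique(goMap)
        list(enhancers = enhancers, network = network,
             subgenomes = subgenomes, goMap = goMap,
             tfGenes = tfGenes, spikedTerm = spikedTerm)
    })
}

#' Draw a gene-truth skeleton without genomic coordinates
#'
#' For count-level simulations that do not need an annotation, draws per-gene
#' exon counts from the configured distribution (single-exon probability,
#' uniform multi-exon range) and returns the same truth layout as
#' [simulateAnnotation()], with placeholder coordinates.
#'
#' @param config a [simulationConfig()].
#' @return data.frame with `gene_id`, `chrom`, `strand`, `exon_count`,
#'   `nested`, `n_isoforms`.
#' @export
simulateTruthSkeleton <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    .withSeed(config$seed, {
        n <- config$n_genes
        single <- stats::runif(n) < config$single_exon_prob
        nExon <- ifelse(single, 1L,
                        .runif_int(n, config$multi_exon_range))
        data.frame(gene_id = sprintf("gene%05d", seq_len(n)),
                   chrom = rep("chr1", n), strand = rep("+", n),
                   exon_count = as.integer(nExon),
                   nested = rep(FALSE, n), n_isoforms = rep(1L, n))
    })
}
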