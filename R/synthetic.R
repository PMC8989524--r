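## Ground-truthed synthetic data: a miniature two-sex genome with six
## histone marks, replicated ChIP read tracks, count tables, a DE table and
## recorded truth, emulating the structure of the real inputs (near-isogenic
## male/female lines, PAR/SDR sex chromosome, TE and gene-age labels,
## expression coupled to chromatin class, a minority of sex-biased genes).

SEXES <- c("female", "male")

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe the study conditions the generator emulates: 4 autosomes
#' of 400 kb plus a 400 kb sex chromosome (PAR 0-320 kb, female SDR
#' 320-360 kb, male SDR 360-400 kb), 200-bp bins, a 12-state true model whose
#' emission profiles follow the five state groups, class-dependent log-normal
#' expression, region-dependent TE/young-gene prevalence, and a small
#' sex-biased gene fraction with planted chromatin transitions.
#'
#' @param seed RNG seed; the whole dataset is deterministic given the
#'   config.
#' @param autosomes number of autosomes.
#' @param chromLength chromosome length in bp.
#' @param parEnd,sdrFemale,sdrMale sex-chromosome intervals (0-based
#'   half-open bp): PAR is `[0, parEnd)`.
#' @param binSize bin width in bp.
#' @param geneLengthBins range of gene lengths in bins (uniform).
#' @param gapMeanBins mean extra intergenic gap in bins beyond the minimum
#'   of 2.
#' @param classProbs 4 x 4 matrix of signature-class probabilities
#'   (rows AUTOSOME/PAR/SDR_FEMALE/SDR_MALE, columns
#'   ACTIVATION/MIXED/REPRESSION/NULL).
#' @param teProb,youngProb named per-region probabilities of TE overlap and
#'   YOUNG age class.
#' @param sexBiasedFraction fraction of non-SDR genes with planted sex bias.
#' @param biasLog2FCRange range of planted |log2 fold changes|.
#' @param pTransBiased probability that a biased gene's disfavoured sex
#'   carries a repression/mixed signature instead of the favoured sex's.
#' @param pTransUnbiased,pTransPar probability that an unbiased gene's male
#'   signature is redrawn (autosomes resp. PAR).
#' @param depthEnriched,depthBackground mean ChIP reads per bin in fully
#'   enriched resp. background states.
#' @param readLength read length in bp for the emitted intervals.
#' @param exprMeanLog named per-class mean of `log(expression)`.
#' @param exprSdLog log-normal spread of expression.
#' @param countDepth expected counts per expression unit per kb.
#' @return a list of class `chromsig_config`.
#' @export
syntheticConfig <- function(seed = 1L,
                            autosomes = 4L,
                            chromLength = 400000L,
                            parEnd = 320000L,
                            sdrFemale = c(320000L, 360000L),
                            sdrMale = c(360000L, 400000L),
                            binSize = 200L,
                            geneLengthBins = c(4L, 8L),
                            gapMeanBins = 2,
                            classProbs = rbind(
                                AUTOSOME   = c(0.45, 0.30, 0.17, 0.08),
                                PAR        = c(0.20, 0.28, 0.40, 0.12),
                                SDR_FEMALE = c(0.05, 0.10, 0.70, 0.15),
                                SDR_MALE   = c(0.20, 0.27, 0.40, 0.13)),
                            teProb = c(AUTOSOME = 0.36, PAR = 0.80,
                                       SDR_FEMALE = 0.50, SDR_MALE = 0.50),
                            youngProb = c(AUTOSOME = 0.22, PAR = 0.53,
                                          SDR_FEMALE = 0.30, SDR_MALE = 0.30),
                            sexBiasedFraction = 0.015,
                            biasLog2FCRange = c(2, 4),
                            pTransBiased = 0.40,
                            pTransUnbiased = 0.10,
                            pTransPar = 0.32,
                            depthEnriched = 24,
                            depthBackground = 1,
                            readLength = 50L,
                            exprMeanLog = c(ACTIVATION = log(60),
                                            MIXED = log(8),
                                            REPRESSION = log(1.2),
                                            "NULL" = log(0.4)),
                            exprSdLog = 0.8,
                            countDepth = 2) {
    if (sdrFemale[2L] > chromLength || sdrMale[2L] > chromLength)
        stop("SDR extends beyond the sex chromosome")
    colnames(classProbs) <- SIGNATURE_CLASSES
    stopifnot(all(abs(rowSums(classProbs) - 1) < 1e-8),
              all(classProbs >= 0), all(classProbs <= 1))
    cfg <- as.list(environment())
    class(cfg) <- "chromsig_config"
    cfg
}

## True 12-state emission matrix over the six marks, following the five
## state groups (three TSS-activation states, two H3K36me3 states, three
## mixed, three silent, one null).
trueEmissionMatrix <- function(hi = 0.9, lo = 0.04) {
    on <- list(E1 = c("H3K4me3", "H3K9ac"),
               E2 = c("H3K9ac", "H3K27ac"),
               E3 = c("H3K4me3", "H3K9ac", "H3K27ac"),
               E4 = "H3K36me3",
               E5 = "H3K36me3",
               E6 = c("H3K4me3", "H3K79me2"),
               E7 = c("H3K36me3", "H4K20me3"),
               E8 = c("H3K27ac", "H3K79me2", "H4K20me3"),
               E9 = "H3K79me2",
               E10 = "H4K20me3",
               E11 = c("H3K79me2", "H4K20me3"),
               E12 = character(0))
    E <- matrix(lo, 12L, length(DEFAULT_MARKS),
                dimnames = list(names(on), DEFAULT_MARKS))
    for (k in names(on)) E[k, on[[k]]] <- hi
    E
}

## States of each group under the true model layout.
TRUE_GROUP_STATES <- list(PERMISSIVE1 = 1:3, PERMISSIVE2 = 4:5,
                          MIXED = 6:8, SILENT = 9:11)

maskGroups <- function(mask) STATE_GROUPS[bitwAnd(mask, GROUP_BITS[STATE_GROUPS]) > 0L]

CLASS_MASKS <- list(ACTIVATION = c(1L, 2L, 3L),
                    MIXED = c(5L, 6L, 7L, 9L, 10L, 11L, 13L, 14L, 15L),
                    REPRESSION = c(4L, 8L, 12L),
                    "NULL" = 0L)

#' Generate a complete synthetic dataset with recorded ground truth
#'
#' Writes, under `outDir`: the layout YAML, gene models (GFF3), a TE BED, a
#' gene-age TSV, per-sex per-mark per-replicate ChIP read BEDs plus per-sex
#' control tracks (reads Poisson-sampled at a rate interpolating between the
#' background and enriched depths by the true state emission), replicated
#' count tables, a DE table written from the planted fold changes, per-sex
#' true bin-state tables, a per-gene truth table and a file manifest.
#'
#' @param config a [syntheticConfig()] list.
#' @param outDir output directory (created if needed).
#' @return invisibly, the truth bundle: a list with the config, layout,
#'   genes, true emission matrix, per-sex true bin states, the per-gene
#'   truth table and the manifest.
#' @export
generateDataset <- function(config = syntheticConfig(), outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(outDir, "chip"), showWarnings = FALSE)
    dir.create(file.path(outDir, "truth"), showWarnings = FALSE)
    truth <- withSeed(config$seed, buildTruth(config))
    writeDataset(truth, config, outDir)
}

buildTruth <- function(cfg) {
    ## layout
    sl <- stats::setNames(rep(cfg$chromLength, cfg$autosomes + 1L),
                          c(sprintf("chr%02d", seq_len(cfg$autosomes)),
                            "chrUV"))
    layout <- makeGenomeLayout(sl, data.frame(
        chromosome = "chrUV",
        start = c(0L, cfg$sdrFemale[1L], cfg$sdrMale[1L]),
        end = c(cfg$parEnd, cfg$sdrFemale[2L], cfg$sdrMale[2L]),
        region_class = c("PAR", "SDR_FEMALE", "SDR_MALE")))

    ## bin-aligned, non-overlapping genes with >= 1 null bin between them
    bs <- cfg$binSize
    geneRows <- list()
    gi <- 0L
    for (chrom in names(sl)) {
        nb <- nBins(sl[[chrom]], bs)
        pos <- 0L
        repeat {
            gap <- 2L + stats::rpois(1L, cfg$gapMeanBins)
            len <- sample(seq(cfg$geneLengthBins[1L], cfg$geneLengthBins[2L]),
                          1L)
            startBin <- pos + gap
            endBin <- startBin + len
            if (endBin >= nb) break
            gi <- gi + 1L
            geneRows[[gi]] <- data.frame(chrom = chrom, startBin = startBin,
                                         endBin = endBin)
            pos <- endBin
        }
    }
    gdf <- do.call(rbind, geneRows)
    gdf$gene_id <- sprintf("G%04d", seq_len(nrow(gdf)))
    genes <- GRanges(gdf$chrom,
                     IRanges(start = gdf$startBin * bs + 1L,
                             end = gdf$endBin * bs),
                     strand = sample(c("+", "-"), nrow(gdf), replace = TRUE))
    mcols(genes)$gene_id <- gdf$gene_id
    mid0 <- floor(((start(genes) - 1L) + end(genes)) / 2)
    region <- regionClassAt(layout, gdf$chrom, mid0)
    n <- nrow(gdf)

    te <- stats::runif(n) < cfg$teProb[region]
    age <- ifelse(stats::runif(n) < cfg$youngProb[region], "YOUNG",
                  "CONSERVED")

    ## per-gene signature masks for each sex (0 = null signature)
    drawMask <- function(regions) {
        vapply(regions, function(r) {
            cls <- sample(SIGNATURE_CLASSES, 1L,
                          prob = cfg$classProbs[r, ])
            m <- CLASS_MASKS[[cls]]
            if (length(m) > 1L) sample(m, 1L) else m
        }, 0L)
    }
    maskF <- drawMask(region)
    maskM <- maskF

    ## sex-biased genes (non-SDR only): favoured sex active, disfavoured sex
    ## optionally transitioned to a mixed/repressive signature
    shared <- which(!region %in% c("SDR_FEMALE", "SDR_MALE"))
    nBiased <- round(cfg$sexBiasedFraction * length(shared))
    biasedIdx <- sample(shared, nBiased)
    biasDir <- sample(c("MALE_BIASED", "FEMALE_BIASED"), nBiased,
                      replace = TRUE)
    bias <- rep("UNBIASED", n)
    bias[biasedIdx] <- biasDir
    l2fc <- numeric(n)
    mag <- stats::runif(nBiased, cfg$biasLog2FCRange[1L],
                        cfg$biasLog2FCRange[2L])
    l2fc[biasedIdx] <- ifelse(biasDir == "MALE_BIASED", mag, -mag)
    for (i in seq_along(biasedIdx)) {
        g <- biasedIdx[i]
        act <- sample(CLASS_MASKS$ACTIVATION, 1L)
        off <- if (stats::runif(1) < cfg$pTransBiased)
            sample(c(CLASS_MASKS$MIXED, CLASS_MASKS$REPRESSION), 1L) else act
        if (biasDir[i] == "MALE_BIASED") { maskM[g] <- act; maskF[g] <- off }
        else { maskF[g] <- act; maskM[g] <- off }
    }
    ## unbiased genes: sex-dependent chromatin transitions, more frequent on
    ## the PAR, mostly without expression change
    unb <- setdiff(shared, biasedIdx)
    pTrans <- ifelse(region[unb] == "PAR", cfg$pTransPar, cfg$pTransUnbiased)
    redraw <- unb[stats::runif(length(unb)) < pTrans]
    maskM[redraw] <- drawMask(region[redraw])
    ## SDR genes exist in one sex only: the other sex's line lacks that
    ## chromosome region, so its signal is background and its signature null
    maskM[region == "SDR_FEMALE"] <- 0L
    maskF[region == "SDR_MALE"] <- 0L

    ## paint true per-bin states per sex: contiguous chunk per group inside
    ## each gene body, E12 elsewhere
    states <- list()
    for (sex in SEXES) {
        mask <- if (sex == "female") maskF else maskM
        st <- lapply(sl, function(L) rep(12L, nBins(L, bs)))
        for (g in seq_len(n)) {
            if (mask[g] == 0L) next
            grp <- maskGroups(mask[g])
            bins <- (gdf$startBin[g] + 1L):gdf$endBin[g]  # 1-based bin idx
            chunks <- split(bins, ceiling(seq_along(bins) * length(grp) /
                                              length(bins)))
            for (j in seq_along(grp)) {
                s <- TRUE_GROUP_STATES[[grp[j]]]
                s <- if (length(s) > 1L) sample(s, 1L) else s
                st[[gdf$chrom[g]]][chunks[[j]]] <- s
            }
        }
        states[[sex]] <- st
    }

    ## expression: class-driven log-normal, equal between sexes unless a
    ## bias is planted; SDR genes silent in the other sex
    classOf <- function(mask) {
        ifelse(mask == 0L, "NULL", defaultSignatureClassTable()[
            paste0("S", pmax(mask, 1L))])
    }
    clsF <- classOf(maskF); clsM <- classOf(maskM)
    base <- stats::rlnorm(n, cfg$exprMeanLog[clsF], cfg$exprSdLog)
    exprF <- base; exprM <- base
    isB <- bias != "UNBIASED"
    exprM[isB] <- base[isB] * 2^(l2fc[isB] / 2)
    exprF[isB] <- base[isB] * 2^(-l2fc[isB] / 2)
    exprM[region == "SDR_FEMALE"] <- 0
    exprF[region == "SDR_MALE"] <- 0

    lenBp <- width(genes)
    counts <- sapply(c("female_rep1", "female_rep2", "male_rep1",
                       "male_rep2"), function(sm) {
        e <- if (startsWith(sm, "female")) exprF else exprM
        stats::rpois(n, e * lenBp / 1000 * cfg$countDepth)
    })
    rownames(counts) <- gdf$gene_id

    de <- data.frame(gene_id = gdf$gene_id[shared],
                     log2FC = l2fc[shared] + stats::rnorm(length(shared), 0, 0.1),
                     padj = ifelse(bias[shared] != "UNBIASED",
                                   stats::runif(length(shared), 1e-8, 1e-3),
                                   stats::runif(length(shared), 0.2, 1)))

    geneTruth <- data.frame(
        gene_id = gdf$gene_id, chrom = gdf$chrom,
        start = gdf$startBin * bs, end = gdf$endBin * bs,
        region_class = region, te_overlap = te, age_class = age,
        signature_female = ifelse(maskF == 0L, "S16", paste0("S", maskF)),
        signature_male = ifelse(maskM == 0L, "S16", paste0("S", maskM)),
        class_female = clsF, class_male = clsM,
        bias = bias, log2FC = l2fc,
        expr_female = exprF, expr_male = exprM)

    list(config = cfg, layout = layout, genes = genes,
         emission = trueEmissionMatrix(), states = states,
         geneTruth = geneTruth, counts = counts, de = de)
}

## Poisson read sampling for one sex/mark/replicate given true bin states.
sampleReads <- function(statesByChrom, emissionCol, cfg) {
    rows <- lapply(names(statesByChrom), function(chrom) {
        st <- statesByChrom[[chrom]]
        rate <- cfg$depthBackground +
            emissionCol[st] * (cfg$depthEnriched - cfg$depthBackground)
        nReads <- stats::rpois(length(st), rate)
        tot <- sum(nReads)
        if (tot == 0L) return(NULL)
        binIdx <- rep(seq_along(st) - 1L, nReads)
        start0 <- binIdx * cfg$binSize +
            sample.int(cfg$binSize, tot, replace = TRUE) - 1L
        data.frame(chrom = chrom, start = start0,
                   end = start0 + cfg$readLength)
    })
    do.call(rbind, rows)
}

writeBed3 <- function(df, path) {
    if (is.null(df)) df <- data.frame(chrom = character(0),
                                      start = integer(0), end = integer(0))
    utils::write.table(df[order(df$chrom, df$start), ], path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

writeDataset <- function(truth, cfg, outDir) {
    files <- character(0)
    put <- function(rel) { files <<- c(files, rel); file.path(outDir, rel) }

    writeGenomeLayout(truth$layout, put("layout.yaml"))
    writeGeneModelsGFF3(truth$genes, put("genes.gff3"))

    gt <- truth$geneTruth
    teRows <- gt[gt$te_overlap, ]
    third <- floor((teRows$end - teRows$start) / 3)
    writeBed3(data.frame(chrom = teRows$chrom,
                         start = teRows$start + third,
                         end = teRows$end - third),
              put("te.bed"))
    utils::write.table(gt[, c("gene_id", "age_class")], put("age.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    reads <- withSeed(cfg$seed + 1L, {
        out <- list()
        for (sex in SEXES) {
            for (mark in DEFAULT_MARKS) {
                for (rep_ in 1:2) {
                    key <- sprintf("chip/%s_%s_rep%d.bed", sex, mark, rep_)
                    out[[key]] <- sampleReads(truth$states[[sex]],
                                              truth$emission[, mark], cfg)
                }
            }
            key <- sprintf("chip/%s_control.bed", sex)
            flat <- lapply(truth$states[[sex]], function(st) rep(12L, length(st)))
            ctl <- cfg
            ctl$depthEnriched <- cfg$depthBackground
            out[[key]] <- sampleReads(flat, truth$emission[, 1L], ctl)
        }
        out
    })
    for (key in names(reads)) writeBed3(reads[[key]], put(key))

    counts <- data.frame(gene_id = gt$gene_id, length = gt$end - gt$start,
                         truth$counts, check.names = FALSE)
    utils::write.table(counts, put("counts.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(truth$de, put("de.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)

    for (sex in SEXES) {
        st <- truth$states[[sex]]
        df <- do.call(rbind, lapply(names(st), function(chrom)
            data.frame(chrom = chrom, bin = seq_along(st[[chrom]]) - 1L,
                       state = paste0("E", st[[chrom]]))))
        utils::write.table(df, put(sprintf("truth/states_%s.tsv", sex)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(gt, put("truth/genes.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- data.frame(file = files)
    utils::write.table(manifest, file.path(outDir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth$files <- files
    truth$dir <- outDir
    class(truth) <- "chromsig_truth"
    invisible(truth)
}

#' Simulate a BinaryMatrix directly from a BernoulliHMM
#'
#' Draws hidden state paths per chromosome from the model's Markov chain and
#' emits marks independently per bin; used for parameter-recovery checks.
#'
#' @param model a [BernoulliHMM-class].
#' @param layout a [GenomeLayout-class].
#' @param binSize bin width in bp.
#' @param seed RNG seed.
#' @param sample sample label.
#' @return list with `bm` (a [BinaryMatrix-class]) and `states` (true
#'   per-bin state indices, in row order).
#' @export
simulateBinaryMatrix <- function(model, layout, binSize = 200L, seed = 1L,
                                 sample = "sim") {
    sl <- chromLengths(layout)
    K <- nStates(model)
    withSeed(seed, {
        cols <- NULL
        statesAll <- integer(0)
        dat <- NULL
        for (chrom in names(sl)) {
            nb <- nBins(sl[[chrom]], binSize)
            st <- integer(nb)
            st[1L] <- sample.int(K, 1L, prob = initialProbs(model))
            if (nb > 1L) for (t in 2:nb)
                st[t] <- sample.int(K, 1L,
                                    prob = transitionProbs(model)[st[t - 1L], ])
            X <- matrix(stats::rbinom(nb * length(marks(model)), 1L,
                                      emissionProbs(model)[st, ]),
                        nb, length(marks(model)))
            statesAll <- c(statesAll, st)
            dat <- rbind(dat, X)
        }
        colnames(dat) <- marks(model)
        cols <- lapply(seq_len(ncol(dat)), function(j) {
            v <- dat[, j]
            lens <- nBins(sl, binSize)
            split(v, rep(seq_along(lens), lens)) |>
                stats::setNames(names(sl))
        })
        names(cols) <- marks(model)
        bm <- makeBinaryMatrix(cols, layout, binSize = binSize,
                               sample = sample)
        list(bm = bm, states = statesAll)
    })
}

#' Score pipeline outputs against the recorded truth
#'
#' @param truth a truth bundle from [generateDataset()].
#' @param model fitted [BernoulliHMM-class] (for state matching), or `NULL`.
#' @param segmentations named list (`female`, `male`) of
#'   [Segmentation-class] objects, or `NULL`.
#' @param signatures named list (`female`, `male`) of
#'   [GeneSignatureTable-class] objects, or `NULL`.
#' @param bias data.frame with `gene_id`, `bias` (predicted labels), or
#'   `NULL`.
#' @return list of scores in `[0, 1]`: per-sex `state_accuracy` (after
#'   matching fitted states to true states by maximal emission correlation),
#'   per-sex `signature_agreement`, and `bias_confusion` (a matrix).
#' @export
evaluateAgainstTruth <- function(truth, model = NULL, segmentations = NULL,
                                 signatures = NULL, bias = NULL) {
    out <- list()
    if (!is.null(segmentations)) {
        if (is.null(model)) stop("state scoring needs the fitted model")
        trueModel <- new("BernoulliHMM", K = 12L,
                         emission = clipEmission(truth$emission),
                         transition = matrix(1 / 12, 12L, 12L),
                         initial = rep(1 / 12, 12L),
                         marks = colnames(truth$emission), metadata = list())
        ## match by maximal emission correlation; near-constant emission rows
        ## have no defined correlation, so fall back to minimal distance
        Ef <- emissionProbs(model)
        Et <- clipEmission(truth$emission)
        toTrue <- stats::setNames(vapply(seq_len(nrow(Ef)), function(i) {
            dists <- rowMeans(abs(sweep(Et, 2L, Ef[i, ])))
            if (diff(range(Ef[i, ])) < 0.2) return(which.min(dists))
            cors <- vapply(seq_len(nrow(Et)), function(j) {
                if (diff(range(Et[j, ])) < 0.2) return(0)
                stats::cor(Ef[i, ], Et[j, ])
            }, 0)
            if (max(cors) > 0) which.max(cors) else which.min(dists)
        }, 0L), paste0("E", seq_len(nrow(Ef))))
        out$state_accuracy <- vapply(SEXES, function(sex) {
            seg <- segmentations[[sex]]
            if (is.null(seg)) return(NA_real_)
            pred <- integer(0); tru <- integer(0)
            gr <- tiles(seg)
            bs <- binSize(seg)
            for (chrom in names(truth$states[[sex]])) {
                tchrom <- truth$states[[sex]][[chrom]]
                sub <- gr[as.character(seqnames(gr)) == chrom]
                p <- integer(length(tchrom))
                for (i in seq_along(sub)) {
                    b0 <- (start(sub)[i] - 1L) %/% bs + 1L
                    b1 <- (end(sub)[i] - 1L) %/% bs + 1L
                    p[b0:b1] <- toTrue[[mcols(sub)$state[i]]]
                }
                pred <- c(pred, p); tru <- c(tru, tchrom)
            }
            mean(pred == tru)
        }, 0)
    }
    if (!is.null(signatures)) {
        gt <- truth$geneTruth
        out$signature_agreement <- vapply(SEXES, function(sex) {
            gst <- signatures[[sex]]
            if (is.null(gst)) return(NA_real_)
            tb <- signatureTable(gst)
            truthSig <- gt[[paste0("signature_", sex)]][
                match(tb$gene_id, gt$gene_id)]
            mean(tb$signature == truthSig)
        }, 0)
    }
    if (!is.null(bias)) {
        gt <- truth$geneTruth
        lev <- c("FEMALE_BIASED", "MALE_BIASED", "UNBIASED")
        idx <- match(bias$gene_id, gt$gene_id)
        out$bias_confusion <- table(truth = factor(gt$bias[idx], lev),
                                    predicted = factor(bias$bias, lev))
    }
    out
}
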