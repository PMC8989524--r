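## End-to-end orchestration: binarized tracks -> joint HMM -> per-sex
## segmentations -> gene signatures -> expression integration -> comparative
## and permutation reports.

#' Build a pipeline run configuration
#'
#' Collects input paths and parameters for [runPipeline()].  `dataDir` is a
#' directory laid out as written by [generateDataset()]; individual paths may
#' be overridden.
#'
#' @param dataDir input directory.
#' @param outDir output directory.
#' @param marks mark names (column order of the binary matrices).
#' @param binSize bin width in bp.
#' @param pThreshold Poisson binarization threshold.
#' @param replicateRule how replicate binary calls combine (`"or"`/`"and"`).
#' @param K number of HMM states; when `NULL`, chosen by
#'   [selectStateCount()] between `kMin` and `kMax`.
#' @param kMin,kMax state-count range for model selection.
#' @param maxIter,tol EM settings.
#' @param init EM initialisation strategy (see [fitHMM()]); the pipeline
#'   defaults to the pattern-based initialisation, which is markedly more
#'   stable for combinatorial chromatin states.
#' @param nPerm permutations for the matched tests.
#' @param exprWindow expression-matching window (fraction of target median).
#' @param seed seed governing fitting and permutation draws.
#' @return a config list of class `chromsig_run_config`.
#' @export
runConfig <- function(dataDir, outDir, marks = DEFAULT_MARKS,
                      binSize = 200L, pThreshold = 1e-4,
                      replicateRule = "or", K = 12L, kMin = 8L, kMax = 17L,
                      maxIter = 200L, tol = 1e-4, init = "patterns",
                      nPerm = 100000L, exprWindow = 0.25, seed = 1L) {
    cfg <- list(
        dataDir = dataDir, outDir = outDir, marks = marks,
        binSize = as.integer(binSize), pThreshold = pThreshold,
        replicateRule = replicateRule, K = K, kMin = kMin, kMax = kMax,
        maxIter = as.integer(maxIter), tol = tol, init = init,
        nPerm = as.integer(nPerm),
        exprWindow = exprWindow, seed = as.integer(seed),
        layout = file.path(dataDir, "layout.yaml"),
        genes = file.path(dataDir, "genes.gff3"),
        te = file.path(dataDir, "te.bed"),
        age = file.path(dataDir, "age.tsv"),
        counts = file.path(dataDir, "counts.tsv"),
        de = file.path(dataDir, "de.tsv"),
        chipDir = file.path(dataDir, "chip"))
    class(cfg) <- "chromsig_run_config"
    cfg
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys are [runConfig()] arguments plus
#'   optional explicit input paths.
#' @return a config list.
#' @export
loadRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    args <- y[intersect(names(y), names(formals(runConfig)))]
    cfg <- do.call(runConfig, args)
    for (k in intersect(names(y), c("layout", "genes", "te", "age",
                                    "counts", "de", "chipDir")))
        cfg[[k]] <- y[[k]]
    cfg
}

pipelineLog <- function(logCon, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    message(msg)
    if (!is.null(logCon)) writeLines(msg, logCon)
}

#' Run the full chromatin-signature analysis
#'
#' One command from read tracks to reports: binarized per-sex matrices, the
#' joint model (and, optionally, the state-count similarity curve), per-sex
#' segmentations and gene-signature tables, expression categories and
#' sex-bias calls, signature-proportion tables overall / by expression
#' category / by bias group / by genome region, male-female transition
#' tables, per-mark region coverage, matched permutation tests (PAR and SDR
#' against autosomes, young against conserved expression-matched autosomal
#' genes) and the signature-by-location expression model.  All tables are
#' tab-separated with a header comment naming the producing stage and the
#' config hash; a `run.log` records progress and the seed.
#'
#' @param config a [runConfig()] list (or path to a YAML accepted by
#'   [loadRunConfig()]).
#' @return invisibly, a list with the fitted objects and all result tables.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- loadRunConfig(config)
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    hash <- configHash(config[!names(config) %in% c("outDir")])
    logCon <- file(file.path(config$outDir, "run.log"), "w")
    on.exit(close(logCon))
    pipelineLog(logCon, sprintf("chromsig %s | R %s | seed %d | config %s",
                                as.character(utils::packageVersion("chromsig")),
                                getRversion(), config$seed, hash))
    stage <- function(name, expr) {
        pipelineLog(logCon, "stage ", name)
        tryCatch(expr, error = function(e) {
            writeLines(sprintf("FAILED at stage %s: %s", name,
                               conditionMessage(e)),
                       file.path(config$outDir, "FAILED"))
            stop(sprintf("stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE)
        })
    }
    put <- function(df, name, stageName) {
        writeStageTable(df, file.path(config$outDir, name), stageName, hash)
    }
    res <- list(config = config, hash = hash)

    stage("inputs", {
        res$layout <- loadGenomeLayout(config$layout)
        res$genes <- loadGeneModels(config$genes, res$layout,
                                    tePath = config$te, agePath = config$age)
    })

    stage("binarize", {
        res$binary <- lapply(stats::setNames(SEXES, SEXES), function(sex) {
            ctlPath <- file.path(config$chipDir,
                                 sprintf("%s_control.bed", sex))
            control <- binSignal(rtracklayer::import(ctlPath, format = "bed"),
                                 res$layout, config$binSize,
                                 mark = "control", sample = sex)
            mats <- lapply(1:2, function(rep_) {
                cols <- lapply(stats::setNames(config$marks, config$marks),
                               function(mark) {
                    p <- file.path(config$chipDir,
                                   sprintf("%s_%s_rep%d.bed", sex, mark, rep_))
                    ip <- binSignal(rtracklayer::import(p, format = "bed"),
                                    res$layout, config$binSize, mark = mark,
                                    sample = sex)
                    binarizeTrack(ip, control, pThreshold = config$pThreshold)
                })
                makeBinaryMatrix(cols, res$layout, config$binSize,
                                 sample = sex)
            })
            combineReplicates(mats[[1L]], mats[[2L]],
                              rule = config$replicateRule)
        })
    })

    stage("fit", {
        if (is.null(config$K)) {
            sel <- selectStateCount(res$binary, kMax = config$kMax,
                                    kMin = config$kMin, seed = config$seed,
                                    maxIter = config$maxIter,
                                    tol = config$tol, init = config$init)
            res$selection <- sel
            put(sel$curve, "state_count_similarity.tsv", "fit")
            config$K <- sel$K
        }
        res$model <- fitHMM(res$binary, K = config$K, seed = config$seed,
                            maxIter = config$maxIter, tol = config$tol,
                            init = config$init)
        writeHMM(res$model, file.path(config$outDir, "model.tsv"))
        res$groupMap <- inferStateGroups(res$model)
        writeStateGroupMap(res$groupMap,
                           file.path(config$outDir, "state_groups.tsv"))
    })

    stage("decode", {
        res$segmentation <- lapply(res$binary, function(bm)
            decodeStates(res$model, bm))
        for (sex in SEXES)
            writeSegmentation(res$segmentation[[sex]],
                              file.path(config$outDir,
                                        sprintf("segmentation_%s.bed", sex)))
    })

    stage("signatures", {
        res$signatures <- lapply(stats::setNames(SEXES, SEXES), function(sex) {
            sets <- intersectStatesWithGenes(res$segmentation[[sex]],
                                             res$genes)
            assignSignatures(sets, res$groupMap, sample = sex)
        })
        for (sex in SEXES) {
            tb <- signatureTable(res$signatures[[sex]])
            put(data.frame(gene_id = tb$gene_id,
                           states = unname(vapply(tb$states, paste,
                                                  "", collapse = ",")),
                           groups = unname(vapply(tb$groups, paste,
                                                  "", collapse = ",")),
                           signature = tb$signature, class = tb$class,
                           sex = sex),
                sprintf("signatures_%s.tsv", sex), "signatures")
        }
    })

    stage("expression", {
        cnt <- readStageTable(config$counts)
        mat <- as.matrix(cnt[, !(colnames(cnt) %in% c("gene_id", "length"))])
        rownames(mat) <- cnt$gene_id
        res$tpm <- computeTPM(mat, cnt$length)
        sexOfSample <- ifelse(startsWith(colnames(res$tpm), "female"),
                              "female", "male")
        res$expressed <- callExpressed(res$tpm)
        res$tau <- computeTau(res$tpm)
        de <- readStageTable(config$de)
        res$bias <- callSexBias(de, res$tpm, sexOfSample)
        res$meanTPM <- vapply(stats::setNames(SEXES, SEXES), function(sex)
            rowMeans(res$tpm[, sexOfSample == sex, drop = FALSE]),
            numeric(nrow(res$tpm)))
        put(data.frame(gene_id = rownames(res$tpm), res$tpm,
                       expressed = res$expressed, tau = res$tau$tau,
                       breadth = res$tau$breadth,
                       tpm_female = res$meanTPM[, "female"],
                       tpm_male = res$meanTPM[, "male"],
                       check.names = FALSE),
            "expression_categories.tsv", "expression")
        put(res$bias, "sex_bias.tsv", "expression")
    })

    stage("report_tables", {
        ids <- mcols(res$genes)$gene_id
        region <- stats::setNames(mcols(res$genes)$region_class, ids)
        ## genome-wide signature proportions per sex (gene-set shares)
        prop <- do.call(rbind, lapply(SEXES, function(sex) {
            p <- signatureProportions(res$signatures[[sex]])
            p$sex <- sex
            p
        }))
        put(prop, "signature_proportions.tsv", "report_tables")
        ## proportions within expression categories
        categories <- list(
            transcribed = function(sex) ids[res$meanTPM[ids, sex] >= 1],
            silent = function(sex) ids[res$meanTPM[ids, sex] < 1],
            housekeeping = function(sex) {
                tau <- stats::setNames(res$tau$tau, res$tau$gene_id)[ids]
                ids[!is.na(tau) & tau < 0.25]
            },
            narrow = function(sex) {
                tau <- stats::setNames(res$tau$tau, res$tau$gene_id)[ids]
                ids[!is.na(tau) & tau > 0.75]
            })
        catTab <- do.call(rbind, lapply(SEXES, function(sex) {
            do.call(rbind, lapply(names(categories), function(catName) {
                sub <- categories[[catName]](sex)
                if (length(sub) == 0L) return(NULL)
                p <- signatureProportions(res$signatures[[sex]], sub)
                p$sex <- sex; p$category <- catName; p$n_genes <- length(sub)
                p
            }))
        }))
        put(catTab, "signature_by_expression_category.tsv", "report_tables")
        ## expression by signature
        exprSig <- do.call(rbind, lapply(SEXES, function(sex) {
            tb <- signatureTable(res$signatures[[sex]])
            l2 <- log2(res$meanTPM[tb$gene_id, sex] + 1)
            stats::aggregate(
                data.frame(mean_log2_tpm1 = l2),
                by = list(signature = tb$signature), FUN = mean) |>
                transform(n = as.integer(table(tb$signature)[signature]),
                          sex = sex)
        }))
        put(exprSig, "expression_by_signature.tsv", "report_tables")
        ## bias x signature and transitions
        biasOf <- stats::setNames(res$bias$bias, res$bias$gene_id)[ids]
        biasOf[is.na(biasOf)] <- "UNBIASED"
        biasTab <- do.call(rbind, lapply(SEXES, function(sex) {
            do.call(rbind, lapply(unique(biasOf), function(b) {
                sub <- ids[biasOf == b]
                p <- signatureProportions(res$signatures[[sex]], sub)
                p$sex <- sex; p$bias <- b; p$n_genes <- length(sub)
                p
            }))
        }))
        put(biasTab, "signature_by_bias.tsv", "report_tables")
        res$transitions <- list(
            all = signatureTransitions(res$signatures$female,
                                       res$signatures$male),
            male_biased = signatureTransitions(
                res$signatures$female, res$signatures$male,
                ids[biasOf == "MALE_BIASED"]),
            female_biased = signatureTransitions(
                res$signatures$female, res$signatures$male,
                ids[biasOf == "FEMALE_BIASED"]),
            unbiased = signatureTransitions(
                res$signatures$female, res$signatures$male,
                ids[biasOf == "UNBIASED"]),
            par = signatureTransitions(
                res$signatures$female, res$signatures$male,
                ids[region[ids] == "PAR"]))
        summ <- data.frame(
            subset = names(res$transitions),
            n_genes = vapply(res$transitions, `[[`, 0, "n"),
            fraction_changed = vapply(res$transitions, `[[`, 0,
                                      "fraction_changed"))
        put(summ, "transition_summary.tsv", "report_tables")
        put(transitionEdgeList(res$transitions$all),
            "transition_edges.tsv", "report_tables")
        ## region x signature and coverage
        regTab <- do.call(rbind, lapply(SEXES, function(sex) {
            do.call(rbind, lapply(unique(region), function(r) {
                sub <- ids[region[ids] == r]
                if (length(sub) == 0L) return(NULL)
                p <- signatureProportions(res$signatures[[sex]], sub)
                p$sex <- sex; p$region <- r; p$n_genes <- length(sub)
                p
            }))
        }))
        put(regTab, "signature_by_region.tsv", "report_tables")
        cov <- do.call(rbind, lapply(SEXES, function(sex) {
            do.call(rbind, lapply(config$marks, function(mark) {
                cv <- coverageByRegion(markFootprint(res$binary[[sex]], mark),
                                       res$layout)
                cv$mark <- mark; cv$sex <- sex
                cv
            }))
        }))
        put(cov, "mark_coverage_by_region.tsv", "report_tables")
    })

    stage("stats", {
        ids <- mcols(res$genes)$gene_id
        region <- stats::setNames(mcols(res$genes)$region_class, ids)
        teFlags <- stats::setNames(mcols(res$genes)$te_overlap, ids)
        ageOf <- stats::setNames(mcols(res$genes)$age_class, ids)
        meanExpr <- rowMeans(res$meanTPM)[ids]
        auto <- ids[region == "AUTOSOME"]
        permRows <- list()
        res$permutations <- list()
        runTest <- function(name, sex, target, pool, matching) {
            if (length(target) < 2L || length(pool) <= length(target))
                return(NULL)
            pr <- tryCatch(matchedPermutationTest(
                target, pool, res$signatures[[sex]], nPerm = config$nPerm,
                matching = matching, teFlags = teFlags,
                expression = meanExpr, window = config$exprWindow,
                seed = config$seed), error = function(e) e)
            if (inherits(pr, "error")) {
                pipelineLog(logCon, sprintf("  test %s (%s) skipped: %s",
                                            name, sex, conditionMessage(pr)))
                return(NULL)
            }
            res$permutations[[paste(name, sex, sep = "_")]] <<- pr
            data.frame(test = name, sex = sex, matching = matching,
                       n_target = length(target), n_pool = length(pool),
                       observed = observedStat(pr), p_value = pValue(pr),
                       n_perm = pr@nPerm)
        }
        for (sex in SEXES) {
            permRows <- c(permRows, list(
                runTest("par_vs_autosome", sex, ids[region == "PAR"], auto,
                        "NONE"),
                runTest("par_vs_autosome_te_matched", sex,
                        ids[region == "PAR"], auto, "TE_PREVALENCE"),
                runTest("sdr_vs_autosome", sex,
                        ids[region == paste0("SDR_",
                                             toupper(sex))], auto, "NONE"),
                runTest("young_vs_conserved_expr_matched", sex,
                        ids[ageOf == "YOUNG" & region == "AUTOSOME"],
                        ids[ageOf == "CONSERVED" & region == "AUTOSOME"],
                        "EXPRESSION_WINDOW")))
        }
        put(do.call(rbind, permRows), "permutation_tests.tsv", "stats")
        ## signature x location model of log2(TPM+1)
        modRows <- do.call(rbind, lapply(SEXES, function(sex) {
            keep <- ids[region %in% c("AUTOSOME", "PAR")]
            tb <- signatureTable(res$signatures[[sex]])
            sig <- stats::setNames(tb$signature, tb$gene_id)
            expr <- stats::setNames(log2(res$meanTPM[keep, sex] + 1), keep)
            fit <- signatureExpressionModel(expr, sig[keep], region[keep])
            cf <- fit$coefficients
            cf$sex <- sex
            res$models[[sex]] <<- fit
            cf
        }))
        put(modRows, "signature_location_model.tsv", "stats")
    })

    pipelineLog(logCon, "done")
    invisible(res)
}
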