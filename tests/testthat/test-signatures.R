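test_that("state-gene intersection follows the half-open >= minOverlap rule", {
    seg <- segFromTiles(c(0, 200, 400), c(200, 400, 600),
                        c("E3", "E12", "E9"))
    genes <- genesAt(c(100, 100, 400), c(300, 500, 600),
                     ids = c("inside", "spanning", "abutting"))
    sets <- intersectStatesWithGenes(seg, genes)
    expect_identical(sets$inside, c("E12", "E3"))
    expect_identical(sets$spanning, c("E12", "E3", "E9"))
    ## gene [400,600) abuts tile [200,400) with zero overlap
    expect_identical(sets$abutting, "E9")

    whole <- segFromTiles(0, 600, "E3")
    expect_identical(intersectStatesWithGenes(whole,
                                              genesAt(100, 300))$g01, "E3")
    expect_error(intersectStatesWithGenes(
        seg, genesAt(0, 100, chrom = "chrZ")), "absent from the segmentation")
})

test_that("signature assignment implements the null rule and bitmask ids", {
    map <- defaultStateGroupMap()
    gst <- assignSignatures(list(
        nullOnly = "E12",                 # nothing but the null state
        s3 = c("E1", "E4"),               # both permissive groups
        silentPlusNull = c("E9", "E12"),  # null dropped when others exist
        s1 = c("E2", "E3", "E12")), map)
    tb <- signatureTable(gst)
    sig <- stats::setNames(tb$signature, tb$gene_id)
    expect_identical(unname(sig[c("nullOnly", "s3", "silentPlusNull", "s1")]),
                     c("S16", "S3", "S8", "S1"))
    expect_identical(as.character(tb$class[tb$gene_id == "nullOnly"]), "NULL")
    expect_identical(unname(unlist(tb$groups[tb$gene_id == "silentPlusNull"])),
                     "SILENT")
    expect_error(assignSignatures(list(g = "E99"), map), "E99")
})

test_that("a custom subset-to-id table overrides the bitmask order", {
    map <- defaultStateGroupMap()
    idTable <- stats::setNames(c("S9", "S16"), c("PERMISSIVE1", ""))
    gst <- assignSignatures(list(a = "E1", b = "E12"), map,
                            idTable = idTable)
    expect_identical(unname(signatureTable(gst)$signature), c("S9", "S16"))
    expect_error(assignSignatures(list(a = "E9"), map, idTable = idTable),
                 "missing from idTable")
})

test_that("signature classes follow the permissive/heavy split", {
    ct <- defaultSignatureClassTable()
    expect_identical(unname(ct[c("S1", "S2", "S3")]), rep("ACTIVATION", 3))
    expect_identical(unname(ct[c("S4", "S8", "S12")]), rep("REPRESSION", 3))
    expect_identical(unname(ct["S16"]), "NULL")
    expect_identical(sum(ct == "MIXED"), 9L)
})

test_that("signature proportions count, sum to one, and recombine by weight", {
    map <- defaultStateGroupMap()
    gst <- assignSignatures(list(a = c("E1", "E4"), b = c("E1", "E4"),
                                 c = "E12", d = c("E1", "E4", "E9")), map)
    pr <- signatureProportions(gst)
    expect_equal(sum(pr$proportion), 1, tolerance = 1e-12)
    expect_equal(pr$proportion[pr$signature == "S3"], 0.5)
    expect_equal(pr$proportion[pr$signature == "S16"], 0.25)
    expect_equal(pr$proportion[pr$signature == "S11"], 0.25)

    p1 <- signatureProportions(gst, c("a", "b"))
    p2 <- signatureProportions(gst, c("c", "d"))
    expect_equal(0.5 * p1$proportion + 0.5 * p2$proportion, pr$proportion)
    expect_error(signatureProportions(gst, character(0)), "empty")
    expect_error(signatureProportions(gst, "zz"), "absent")
})

test_that("assignment equals the brute-force overlap oracle on random genomes", {
    map <- defaultStateGroupMap()
    set.seed(42)
    for (rep_ in 1:25) {
        nbins <- sample(30:80, 1)
        lay <- tinyLayout(nbins * 200L)
        states <- paste0("E", sample(1:12, nbins, replace = TRUE))
        seg <- binStatesToSegmentationForTest(states, nbins)
        ng <- sample(5:40, 1)
        starts <- sort(sample(0:(nbins * 200L - 401L), ng))
        ends <- pmin(starts + sample(100:2000, ng, replace = TRUE),
                     nbins * 200L)
        genes <- genesAt(starts, ends, ids = sprintf("g%03d", seq_len(ng)))
        gst <- assignSignatures(intersectStatesWithGenes(seg, genes), map)
        got <- stats::setNames(signatureTable(gst)$signature,
                               signatureTable(gst)$gene_id)
        oracle <- bruteForceSignatures(seg, genes, map)
        expect_identical(got[names(oracle)], oracle)
    }
})

test_that("assignment is invariant to fragmenting tiles into same-state pieces", {
    map <- defaultStateGroupMap()
    seg <- segFromTiles(c(0, 600, 1200), c(600, 1200, 1600),
                        c("E3", "E9", "E12"))
    frag <- segFromTiles(c(0, 200, 400, 600, 1200, 1400),
                         c(200, 400, 600, 1200, 1400, 1600),
                         c("E3", "E3", "E3", "E9", "E12", "E12"))
    genes <- genesAt(c(100, 500, 700, 1300), c(300, 700, 1100, 1500))
    a <- signatureTable(assignSignatures(intersectStatesWithGenes(seg, genes), map))
    b <- signatureTable(assignSignatures(intersectStatesWithGenes(frag, genes), map))
    expect_identical(a$signature, b$signature)
})

test_that("inferStateGroups classifies emission archetypes and always keeps a null state", {
    E <- rbind(c(0.9, 0.8, 0.7, 0.05, 0.02, 0.02),   # TSS marks
               c(0.1, 0.05, 0.1, 0.9, 0.02, 0.02),   # gene-body mark
               c(0.8, 0.1, 0.1, 0.05, 0.9, 0.02),    # activation + repressive
               c(0.05, 0.05, 0.05, 0.05, 0.9, 0.8),  # repressive only
               c(0.02, 0.02, 0.02, 0.02, 0.02, 0.02))
    m <- new("BernoulliHMM", K = 5L,
             emission = pmin(pmax(E, 1e-6), 1 - 1e-6),
             transition = matrix(0.2, 5, 5), initial = rep(0.2, 5),
             marks = c("H3K4me3", "H3K9ac", "H3K27ac", "H3K36me3",
                       "H3K79me2", "H4K20me3"),
             metadata = list())
    expect_identical(unname(inferStateGroups(m)),
                     c("PERMISSIVE1", "PERMISSIVE2", "MIXED", "SILENT",
                       "NULL"))
    ## no all-low state: the flattest one is forced NULL
    m2 <- new("BernoulliHMM", K = 2L,
              emission = pmin(pmax(E[c(1, 4), ], 1e-6), 1 - 1e-6),
              transition = matrix(0.5, 2, 2), initial = c(0.5, 0.5),
              marks = marks(m), metadata = list())
    expect_true("NULL" %in% inferStateGroups(m2))
})

test_that("state-group maps round-trip as TSV and demand a null state", {
    map <- defaultStateGroupMap()
    path <- withr::local_tempfile(fileext = ".tsv")
    writeStateGroupMap(map, path)
    expect_identical(readStateGroupMap(path), map)
    bad <- map
    bad["E12"] <- "SILENT"
    writeStateGroupMap(bad, path)
    expect_error(readStateGroupMap(path), "NULL")
})
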