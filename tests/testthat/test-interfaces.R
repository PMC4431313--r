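test_that("docking table I/O round-trips and enforces the format", {
    rec <- data.frame(molecule_id = c("m1", "m1", "m2"),
                      target_id = c("t1", "t2", "t1"),
                      score = c(6.5, 5.9, 7.1),
                      reference_score = c(6.2, 5.0, 6.0),
                      stringsAsFactors = FALSE)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeDockingTable(rec, path)
    back <- readDockingTable(path)
    expect_equal(back, rec)

    bad <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("molecule_id\ttarget_id\tscore", "m\tt\t6.5"), bad)
    expect_error(readDockingTable(bad), "reference_score")

    nonnum <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("molecule_id\ttarget_id\tscore\treference_score",
                 "m\tt\t6.5\t6.0", "m\tt2\toops\t6.0"), nonnum)
    expect_error(readDockingTable(nonnum), "line 2")
})

test_that("target metadata round-trips including empty pathway lists", {
    meta <- data.frame(target_id = c("t1", "t2"),
                       organism = c("human", "mouse"),
                       pathways = I(list(c("P1", "P2"), character())),
                       stringsAsFactors = FALSE)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeTargetMeta(meta, path)
    back <- readTargetMeta(path)
    expect_equal(back$target_id, meta$target_id)
    expect_equal(back$organism, meta$organism)
    expect_equal(unclass(back$pathways), unclass(meta$pathways),
                 ignore_attr = TRUE)
})

test_that("GMT-style maps round-trip on the data model", {
    map <- annotationMap(list(P1 = c("d1", "d2"), P2 = "d3"), "pd")
    path <- withr::local_tempfile(fileext = ".gmt")
    writeAnnotationGmt(map, path)
    back <- readAnnotationGmt(path, "pd")
    expect_equal(forwardMap(back), forwardMap(map))
    expect_equal(reverseMap(back)$d2, "P1")

    zl <- zhengLabelSet(c("d1", "d2"), list("Cold", c("Cold", "Hot")))
    zpath <- withr::local_tempfile(fileext = ".gmt")
    writeZhengLabels(zl, zpath)
    zback <- readZhengLabels(zpath)
    expect_equal(zback@disease, zl@disease)
    expect_equal(zback@labels, zl@labels)

    writeLines("d1\tna\tWarm", zpath)
    expect_error(readZhengLabels(zpath), "Cold, Hot")
})

test_that("network export formats behave per contract", {
    net <- buildBipartite(data.frame(left = "a", right = "b"))
    sif <- withr::local_tempfile(fileext = ".sif")
    writeNetwork(net, sif, "SIF", relation = "binds")
    expect_identical(readLines(sif), "a\tbinds\tb")

    expect_error(writeNetwork(net, sif, "DOT"), "unknown network format")

    empty <- buildBipartite(data.frame(left = character(),
                                       right = character()))
    writeNetwork(empty, sif, "SIF")
    expect_length(readLines(sif), 0L)
    gml0 <- withr::local_tempfile(fileext = ".graphml")
    writeNetwork(empty, gml0, "GraphML")
    expect_equal(edgeCount(readNetworkGraphML(gml0)), 0L)

    ## GraphML round-trip preserves nodes, sides, edges and weights
    wnet <- buildBipartite(data.frame(left = c("d1", "d1", "d2"),
                                      right = c("p1", "p2", "p1")),
                           weights = c(2L, 1L, 3L),
                           rightNodes = "p9")
    gml <- withr::local_tempfile(fileext = ".graphml")
    writeNetwork(wnet, gml, "GraphML")
    back <- readNetworkGraphML(gml)
    expect_equal(leftNodes(back), leftNodes(wnet))
    expect_equal(rightNodes(back), rightNodes(wnet))
    expect_equal(edgeTable(back), edgeTable(wnet))
})

test_that("profile and signature tables round-trip", {
    spec <- tinySpec(seed = 4)
    sig <- generateSignature(spec)
    prof <- generateProfiles(spec, sig)
    ppath <- withr::local_tempfile(fileext = ".tsv")
    spath <- withr::local_tempfile(fileext = ".tsv")
    writeProfiles(prof, ppath)
    writeSignature(sig, spath)
    pback <- readProfiles(ppath)
    expect_equal(rankingMatrix(pback), rankingMatrix(prof))
    expect_equal(instanceInfo(pback), instanceInfo(prof))
    sback <- readSignature(spath)
    expect_equal(upTags(sback), upTags(sig))
    expect_equal(downTags(sback), downTags(sig))
})

test_that("flat YAML config parsing honours values and invariants", {
    dir <- withr::local_tempdir()
    cfg <- file.path(dir, "config.yaml")
    writeLines(c("# pipeline settings",
                 "score_threshold: 6.5",
                 "strata_bounds: [5, 12]",
                 "n_permutations: 7",
                 "seed: 42",
                 "organism: Human",
                 "docking: docking.tsv",
                 "target_meta: meta.tsv",
                 "pathway_disease: pd.gmt",
                 "disease_category: dc.gmt",
                 "disease_symptom: ds.gmt",
                 "zheng: z.gmt",
                 "out_dir: out"), cfg)
    conf <- readPipelineConfig(cfg)
    expect_equal(conf@scoreThreshold, 6.5)
    expect_equal(conf@strataBounds, c(5L, 12L))
    expect_equal(conf@nPermutations, 7L)
    expect_equal(conf@seed, 42L)
    expect_true(is.na(conf@profilesPath))
    expect_equal(conf@dockingPath,
                 file.path(normalizePath(dir), "docking.tsv"))

    expect_error(pipelineConfig("a", "b", "c", "d", "e", "f", "out",
                                strataBounds = c(30L, 10L)),
                 "strictly increasing")
    expect_error(pipelineConfig("a", "b", "c", "d", "e", "f", "out",
                                nPermutations = 0L), "nPermutations")
})

test_that("the command-line wrapper drives the package", {
    cli <- system.file("scripts", "netpharm-cli.R", package = "netPharm")
    expect_true(nzchar(cli))
    dir <- withr::local_tempdir()
    rscript <- file.path(R.home("bin"), "Rscript")
    status <- system2(rscript, c(cli, "simulate", "--dir", dir,
                                 "--seed", "2"),
                      stdout = TRUE, stderr = TRUE,
                      env = paste0("R_LIBS=",
                                   paste(.libPaths(), collapse = ":")))
    expect_null(attr(status, "status"))
    expect_true(file.exists(file.path(dir, "docking.tsv")))
    expect_true(file.exists(file.path(dir, "config.yaml")))
})
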