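test_that("buildBipartite counts nodes/edges and rejects collisions", {
    net <- buildBipartite(data.frame(left = c("d1", "d1"),
                                     right = c("t1", "t2")))
    expect_equal(nodeCount(net), 3L)
    expect_equal(edgeCount(net), 2L)

    empty <- buildBipartite(data.frame(left = character(),
                                       right = character()))
    expect_equal(nodeCount(empty), 0L)
    expect_equal(edgeCount(empty), 0L)

    expect_error(buildBipartite(data.frame(left = "x", right = "x")),
                 "namespace collision")

    ## parallel edges collapse
    dup <- buildBipartite(data.frame(left = c("a", "a"),
                                     right = c("b", "b")))
    expect_equal(edgeCount(dup), 1L)

    ## counting oracle on a synthetic pair list
    set.seed(5)
    pairs <- unique(data.frame(
        left = sample(sprintf("d%03d", 1:57), 600, replace = TRUE),
        right = sample(sprintf("t%03d", 1:271), 600, replace = TRUE),
        stringsAsFactors = FALSE))
    big <- buildBipartite(pairs)
    expect_equal(edgeCount(big), nrow(pairs))
    expect_equal(nodeCount(big),
                 length(unique(pairs$left)) + length(unique(pairs$right)))
})

test_that("degrees satisfy examples and the handshake identity", {
    star <- buildBipartite(data.frame(left = "hub",
                                      right = sprintf("t%d", 1:5)))
    expect_equal(nodeDegrees(star)[["hub"]], 5L)

    iso <- buildBipartite(data.frame(left = "a", right = "b"),
                          rightNodes = "lonely")
    expect_equal(nodeDegrees(iso)[["lonely"]], 0L)

    set.seed(11)
    for (i in 1:5) {
        net <- randomBipartiteNet()
        deg <- nodeDegrees(net)
        e <- edgeTable(net)
        ## brute-force recount from the adjacency list
        recount <- vapply(names(deg), function(v)
            sum(e$left == v) + sum(e$right == v), numeric(1))
        expect_equal(as.numeric(deg), as.numeric(recount))
        expect_equal(sum(nodeDegrees(net, "left")), edgeCount(net))
        expect_equal(sum(nodeDegrees(net, "right")), edgeCount(net))
        expect_equal(sum(deg), 2L * edgeCount(net))
    }
})

test_that("betweenness matches hand-derived values", {
    path <- buildBipartite(data.frame(left = c("A", "C"),
                                      right = c("B", "B")))
    b <- betweennessCentrality(path)
    expect_equal(b[["B"]], 1.0)  # the single A-C geodesic runs through B
    expect_equal(b[["A"]], 0)

    ## 4-cycle: each node mediates one of two geodesics for the opposite
    ## pair -> raw 1/2, normalized by (4-1)(4-2)/2 = 3 -> 1/6
    cyc <- buildBipartite(data.frame(left = c("L1", "L1", "L2", "L2"),
                                     right = c("R1", "R2", "R1", "R2")))
    expect_equal(unname(betweennessCentrality(cyc)), rep(1 / 6, 4))

    ## any degree-1 node of a tree has betweenness 0 (path A-B-C-D)
    tree <- buildBipartite(data.frame(left = c("A", "C", "C"),
                                      right = c("B", "B", "D")))
    expect_equal(betweennessCentrality(tree)[["A"]], 0)
    expect_equal(betweennessCentrality(tree)[["D"]], 0)
})

test_that("betweenness equals the exhaustive path-enumeration oracle", {
    set.seed(42)
    for (i in 1:10) {
        net <- randomBipartiteNet()
        expect_equal(betweennessCentrality(net, normalized = TRUE),
                     bruteBetweenness(net, normalized = TRUE),
                     tolerance = 1e-12)
        expect_equal(betweennessCentrality(net, normalized = FALSE),
                     bruteBetweenness(net, normalized = FALSE),
                     tolerance = 1e-12)
    }
})

test_that("degree stratification uses the published bounds", {
    degrees <- c(62, 40, 34, 32, 22, 18, 16, 16, 14, 12, 10)
    ## build molecules with exactly these degrees over disjoint targets
    pairs <- do.call(rbind, lapply(seq_along(degrees), function(i)
        data.frame(left = sprintf("mol%02d", i),
                   right = sprintf("t%02d_%02d", i, seq_len(degrees[i])),
                   stringsAsFactors = FALSE)))
    net <- buildBipartite(pairs)
    strata <- stratifyByDegree(net, "left", bounds = c(10L, 30L))
    counts <- table(strata)
    expect_equal(as.integer(counts[c("high", "middle", "low")]),
                 c(4L, 6L, 1L))
    expect_equal(as.character(strata[["mol01"]]), "high")   # degree 62
    expect_equal(as.character(strata[["mol02"]]), "high")   # degree 40
    expect_equal(as.character(strata[["mol11"]]), "low")    # degree 10

    ## boundary: 10 -> low, 11 -> middle
    bnet <- buildBipartite(data.frame(
        left = rep(c("m10", "m11"), times = c(10, 11)),
        right = c(sprintf("a%02d", 1:10), sprintf("b%02d", 1:11))))
    bstrata <- stratifyByDegree(bnet, "left")
    expect_equal(as.character(bstrata[["m10"]]), "low")
    expect_equal(as.character(bstrata[["m11"]]), "middle")

    ## degree-0 nodes are excluded with a notice
    inet <- buildBipartite(data.frame(left = "m", right = "t"),
                           leftNodes = "isolated")
    expect_message(s <- stratifyByDegree(inet, "left"), "degree-0")
    expect_false("isolated" %in% names(s))
})

test_that("pathway relevance scores are triple-count frequencies", {
    tp <- annotationMap(list(t1 = "P1", t2 = c("P1", "P2")), "tp")
    hits <- data.frame(molecule_id = c("m1", "m1", "m2"),
                       target_id = c("t1", "t2", "t1"))
    sc <- pathwayRelevanceScore(hits, tp)
    ## triples: (m1,t1,P1) (m1,t2,P1) (m1,t2,P2) (m2,t1,P1) -> 3:1
    expect_equal(sc[["P1"]], 0.75)
    expect_equal(sc[["P2"]], 0.25)
    expect_equal(sum(sc), 1.0)

    ## single pathway covering all targets scores 1
    one <- pathwayRelevanceScore(
        data.frame(m = c("a", "b"), t = c("t1", "t1")),
        annotationMap(list(t1 = "Only"), "tp"))
    expect_equal(unname(one), 1.0)

    ## invariance under molecule relabeling
    hits2 <- hits
    hits2$molecule_id <- paste0("relabeled_", hits2$molecule_id)
    expect_equal(pathwayRelevanceScore(hits2, tp), sc)

    expect_error(pathwayRelevanceScore(hits[0, ], tp),
                 "no interactions in stratum")
})

test_that("merging strata mixes relevance scores by triple counts", {
    set.seed(9)
    tp <- annotationMap(
        structure(lapply(1:12, function(i)
            sample(sprintf("P%d", 1:5), sample(1:3, 1))),
            names = sprintf("t%02d", 1:12)), "tp")
    hitsA <- data.frame(m = sample(sprintf("a%d", 1:4), 15, TRUE),
                        t = sample(sprintf("t%02d", 1:12), 15, TRUE))
    hitsB <- data.frame(m = sample(sprintf("b%d", 1:4), 10, TRUE),
                        t = sample(sprintf("t%02d", 1:12), 10, TRUE))
    hitsA <- unique(hitsA)
    hitsB <- unique(hitsB)
    nT <- function(h) sum(lengths(forwardMap(tp)[h$t]))
    scA <- pathwayRelevanceScore(hitsA, tp)
    scB <- pathwayRelevanceScore(hitsB, tp)
    merged <- pathwayRelevanceScore(rbind(hitsA, hitsB), tp)
    wA <- nT(hitsA) / (nT(hitsA) + nT(hitsB))
    pw <- names(merged)
    mix <- wA * ifelse(pw %in% names(scA), scA[pw], 0) +
        (1 - wA) * ifelse(pw %in% names(scB), scB[pw], 0)
    expect_equal(as.numeric(merged), as.numeric(mix), tolerance = 1e-12)
})

test_that("node attribute tables are ordered by decreasing degree", {
    net <- buildBipartite(data.frame(
        left = c("m1", "m1", "m1", "m2"),
        right = c("t1", "t2", "t3", "t1")))
    tab <- nodeAttributes(net)
    expect_equal(names(tab), c("node", "side", "degree", "betweenness"))
    expect_equal(tab$node[1L], "m1")
    expect_true(all(diff(tab$degree) <= 0))
    expect_true(all(tab$betweenness >= 0 & tab$betweenness <= 1))
})
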