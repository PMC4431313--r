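test_that("drug-pathway projection composes layers through shared targets", {
    dt <- buildBipartite(data.frame(left = "d", right = c("t1", "t2")))
    tp <- buildBipartite(data.frame(left = c("t1", "t2"), right = "p"))
    dp <- projectDrugPathway(dt, tp)
    expect_equal(edgeCount(dp), 1L)
    expect_equal(edgeTable(dp)$weight, 2L)      # two shared targets
    expect_equal(nodeDegrees(dp)[["d"]], 1L)    # unweighted degree

    ## single-target chain
    dt1 <- buildBipartite(data.frame(left = "d", right = "t"))
    tp1 <- buildBipartite(data.frame(left = "t", right = "p"))
    dp1 <- projectDrugPathway(dt1, tp1)
    expect_equal(edgeTable(dp1),
                 data.frame(left = "d", right = "p", weight = 1L))

    ## no shared targets -> no edge
    tp2 <- buildBipartite(data.frame(left = "tOther", right = "p"))
    expect_warning(dp2 <- projectDrugPathway(dt1, tp2), "disjoint")
    expect_equal(edgeCount(dp2), 0L)
})

test_that("projection conserves (drug, target, pathway) triple counts", {
    set.seed(33)
    for (i in 1:20) {
        nT <- sample(3:8, 1)
        tgts <- sprintf("t%02d", seq_len(nT))
        dt <- buildBipartite(expand.grid(
            left = sprintf("d%d", 1:4), right = tgts,
            stringsAsFactors = FALSE)[runif(4 * nT) < 0.4, ])
        tp <- buildBipartite(expand.grid(
            left = tgts, right = sprintf("p%d", 1:5),
            stringsAsFactors = FALSE)[runif(5 * nT) < 0.4, ])
        if (!edgeCount(dt) || !edgeCount(tp)) next
        dte <- edgeTable(dt)
        tpe <- edgeTable(tp)
        triples <- 0L
        for (r in seq_len(nrow(dte)))
            triples <- triples + sum(tpe$left == dte$right[r])
        dp <- suppressWarnings(projectDrugPathway(dt, tp))
        expect_equal(sum(edgeTable(dp)$weight), triples)
    }
})

test_that("projection is monotone under edge addition", {
    dt <- buildBipartite(data.frame(left = c("d1", "d2"),
                                    right = c("t1", "t2")))
    tp <- buildBipartite(data.frame(left = c("t1", "t2"),
                                    right = c("p1", "p2")))
    before <- edgeTable(projectDrugPathway(dt, tp))
    dt2 <- buildBipartite(rbind(edgeTable(dt)[, 1:2],
                                data.frame(left = "d1", right = "t2")))
    after <- edgeTable(projectDrugPathway(dt2, tp))
    expect_true(all(paste(before$left, before$right) %in%
                        paste(after$left, after$right)))
})

test_that("pathway-disease network mirrors the annotation map", {
    pd <- annotationMap(list(P1 = c("d1", "d2", "d3"), P2 = "d2"), "pd")
    star <- buildPathwayDisease("P1", pd)
    expect_equal(edgeCount(star), 3L)
    expect_equal(nodeDegrees(star)[["P1"]], 3L)

    both <- buildPathwayDisease(c("P1", "P2"), pd)
    expect_equal(nodeDegrees(both)[["d2"]], 2L)  # shared disease

    ## degrees equal per-key set sizes on a synthetic map
    set.seed(21)
    fwd <- structure(lapply(1:8, function(i)
        sample(sprintf("d%02d", 1:20), sample(1:5, 1))),
        names = sprintf("P%02d", 1:8))
    net <- buildPathwayDisease(names(fwd), annotationMap(fwd, "pd"))
    deg <- nodeDegrees(net, "left")
    expect_equal(as.integer(deg[names(fwd)]), unname(lengths(fwd)))

    ## disease-free pathways appear only when asked
    pd2 <- annotationMap(list(P1 = "d1"), "pd")
    expect_false("P9" %in% leftNodes(buildPathwayDisease(c("P1", "P9"), pd2)))
    withIso <- buildPathwayDisease(c("P1", "P9"), pd2, keepIsolated = TRUE)
    expect_true("P9" %in% leftNodes(withIso))
    expect_equal(nodeDegrees(withIso)[["P9"]], 0L)
})

test_that("bipartite mean degrees follow the arithmetic definition", {
    k13 <- buildBipartite(data.frame(left = "c", right = sprintf("t%d", 1:3)))
    expect_equal(bipartiteMeanDegrees(k13), c(left = 3, right = 1))

    empty <- buildBipartite(data.frame(left = character(),
                                       right = character()))
    expect_true(all(is.na(bipartiteMeanDegrees(empty))))

    set.seed(8)
    for (i in 1:5) {
        net <- randomBipartiteNet()
        md <- bipartiteMeanDegrees(net)
        expect_equal(md[["left"]], mean(nodeDegrees(net, "left")))
        expect_equal(md[["right"]], mean(nodeDegrees(net, "right")))
        expect_equal(md[["left"]] * length(leftNodes(net)), edgeCount(net))
        expect_equal(md[["right"]] * length(rightNodes(net)),
                     edgeCount(net))
    }
})

test_that("mechanism subnetworks contain exactly the in-pathway hits", {
    dt <- buildBipartite(data.frame(
        left = c("d1", "d1", "d2", "d2"),
        right = c("t1", "t3", "t2", "t3")))
    tp <- buildBipartite(data.frame(
        left = c("t1", "t2", "tNoHit"), right = "pwy"))
    sub <- extractMechanism(dt, tp, "pwy")
    ## t3 is off-pathway, tNoHit has no drug -> 2 drugs x 2 targets
    expect_setequal(leftNodes(sub), c("d1", "d2"))
    expect_setequal(rightNodes(sub), c("t1", "t2"))
    expect_equal(edgeCount(sub), 2L)
    expect_true(all(paste(edgeTable(sub)$left, edgeTable(sub)$right) %in%
                        paste(edgeTable(dt)$left, edgeTable(dt)$right)))
    expect_true(all(rightNodes(sub) %in%
                        edgeTable(tp)$left[edgeTable(tp)$right == "pwy"]))

    ## annotated targets but no drug hits -> empty subnetwork
    tpOnly <- buildBipartite(data.frame(left = "tNoHit", right = "lonely"))
    expect_equal(nodeCount(extractMechanism(dt, tpOnly, "lonely")), 0L)

    expect_error(extractMechanism(dt, tp, "missing"),
                 "unknown pathway id: missing")

    summ <- mechanismSummary(dt, tp, "pwy")
    expect_equal(summ$n_molecules, 2L)
    expect_equal(summ$n_targets, 2L)
})
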