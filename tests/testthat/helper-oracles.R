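# Shared fixtures and independent oracles. The betweenness oracle below is a
# literal BFS + shortest-path enumeration, written without igraph so it can
# cross-check the package implementation.

bruteBetweenness <- function(net, normalized = TRUE) {
    nodes <- c(leftNodes(net), rightNodes(net))
    n <- length(nodes)
    btw <- structure(numeric(n), names = nodes)
    if (n < 3L) return(btw)
    e <- edgeTable(net)
    adj <- structure(vector("list", n), names = nodes)
    for (i in seq_len(nrow(e))) {
        adj[[e$left[i]]] <- c(adj[[e$left[i]]], e$right[i])
        adj[[e$right[i]]] <- c(adj[[e$right[i]]], e$left[i])
    }
    distFrom <- function(s) {
        d <- structure(rep(Inf, n), names = nodes)
        d[s] <- 0
        queue <- s
        while (length(queue)) {
            v <- queue[1L]
            queue <- queue[-1L]
            for (w in adj[[v]]) if (!is.finite(d[w])) {
                d[w] <- d[v] + 1
                queue <- c(queue, w)
            }
        }
        d
    }
    dmat <- vapply(nodes, distFrom, numeric(n))  # dmat[w, s]
    allPaths <- function(s, t, d) {
        if (s == t) return(list(s))
        res <- list()
        for (w in adj[[t]]) if (is.finite(d[w]) && d[w] == d[t] - 1)
            res <- c(res, lapply(allPaths(s, w, d), function(p) c(p, t)))
        res
    }
    for (si in seq_len(n - 1L)) for (ti in seq(si + 1L, n)) {
        s <- nodes[si]
        t <- nodes[ti]
        d <- dmat[, s]
        if (!is.finite(d[t])) next
        paths <- allPaths(s, t, d)
        for (p in paths) {
            inner <- p[-c(1L, length(p))]
            if (length(inner))
                btw[inner] <- btw[inner] + 1 / length(paths)
        }
    }
    if (normalized) {
        csize <- vapply(nodes, function(s) sum(is.finite(dmat[, s])),
                        numeric(1))
        denom <- (csize - 1) * (csize - 2) / 2
        btw <- ifelse(denom > 0, btw / denom, 0)
        names(btw) <- nodes
    }
    btw
}

# Random bipartite network with <= maxPerSide nodes per side.
randomBipartiteNet <- function(nl = sample(2:6, 1), nr = sample(2:6, 1),
                               p = 0.4) {
    left <- sprintf("L%02d", seq_len(nl))
    right <- sprintf("R%02d", seq_len(nr))
    grid <- expand.grid(left = left, right = right,
                        stringsAsFactors = FALSE)
    keep <- runif(nrow(grid)) < p
    buildBipartite(grid[keep, , drop = FALSE],
                   leftNodes = left, rightNodes = right)
}

# Literal, loop-based transcription of the one-sided KS statistic, used as
# the exhaustive-argmax oracle for ksEnrichment.
ksOracle <- function(ranks, n) {
    V <- sort(ranks)
    t <- length(V)
    a <- -Inf
    b <- -Inf
    for (j in seq_len(t)) {
        a <- max(a, j / t - V[j] / n)
        b <- max(b, V[j] / n - (j - 1) / t)
    }
    if (a > b) a else -b
}

# Raw connectivity score of one instance computed from the oracle above.
rawScoreOracle <- function(sig, profiles, j) {
    rk <- rankingMatrix(profiles)
    n <- nrow(rk)
    up <- upTags(sig)
    down <- downTags(sig)
    ksU <- if (length(up)) ksOracle(rk[up, j], n) else NULL
    ksD <- if (length(down)) ksOracle(rk[down, j], n) else NULL
    if (is.null(ksD)) return(ksU)
    if (is.null(ksU)) return(-ksD)
    if (ksU * ksD > 0) 0 else ksU - ksD
}

# A tiny hand-checkable annotation world used across tests.
toyAnnotations <- function() {
    list(
        targetPathway = annotationMap(
            list(t1 = "P1", t2 = c("P1", "P2"), t3 = "P2"),
            "target_pathway"),
        pathwayDisease = annotationMap(
            list(P1 = c("d1", "d2"), P2 = "d2"), "pathway_disease"))
}

# Small spec for fast end-to-end runs.
tinySpec <- function(seed = 1, ...) {
    simulationSpec(nMolecules = 20, nTargets = 60, nPathways = 10,
                   nDiseases = 30, nSymptoms = 15, hitFraction = 0.05,
                   hubSpec = data.frame(molecule = 1, degree = 35),
                   meanPathwaysPerTarget = 2.5, meanDiseasesPerPathway = 3,
                   meanSymptomsPerDisease = 5, nPerturbagens = 5,
                   nInstances = 2, nTags = 100, nUpTags = 8, nDownTags = 8,
                   seed = seed, ...)
}
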