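## Bipartite network construction and the node statistics reported for every
## layer: degree, per-component normalized betweenness, degree strata and the
## stratum-wise pathway relevance-frequency score.

#' Build a bipartite network from (left, right) pairs
#'
#' Constructs a simple undirected two-sided network whose node sets are the
#' edge endpoints (plus any explicitly declared isolated nodes). Parallel
#' input pairs collapse to a single edge, so each interaction pair is counted
#' once, as in a docking-derived drug-target layer.
#'
#' @param pairs data.frame (or 2-column matrix) whose first two columns hold
#'   left- and right-side identifiers; may be empty.
#' @param weights optional positive integer edge weights parallel to `pairs`
#'   (duplicated pairs keep the first weight).
#' @param leftNodes,rightNodes optional additional identifiers declared as
#'   isolated nodes of the respective side.
#' @return a [BipartiteNetwork-class].
#' @examples
#' net <- buildBipartite(data.frame(left = c("d1", "d1"),
#'                                  right = c("t1", "t2")))
#' nodeCount(net)  # 3
#' edgeCount(net)  # 2
#' @export
buildBipartite <- function(pairs, weights = NULL, leftNodes = character(),
                           rightNodes = character()) {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    if (ncol(pairs) && nrow(pairs)) {
        left <- as.character(pairs[[1L]])
        right <- as.character(pairs[[2L]])
    } else {
        left <- right <- character()
    }
    clash <- left == right
    if (any(clash))
        stop("namespace collision: pair with identical left and right id '",
             left[which(clash)[1L]], "'")
    w <- if (is.null(weights)) rep(1L, length(left)) else as.integer(weights)
    if (length(w) != length(left))
        stop("weights must be parallel to pairs")
    keep <- if (length(left))
        !duplicated(paste0(left, "\r", right)) else logical()
    edges <- data.frame(left = left[keep], right = right[keep],
                        weight = w[keep], stringsAsFactors = FALSE)
    edges <- edges[order(edges$left, edges$right), , drop = FALSE]
    rownames(edges) <- NULL
    ln <- sort(unique(c(edges$left, as.character(leftNodes))))
    rn <- sort(unique(c(edges$right, as.character(rightNodes))))
    new("BipartiteNetwork", leftNodes = ln, rightNodes = rn, edges = edges)
}

#' Convert a BipartiteNetwork to an igraph graph
#'
#' The resulting undirected graph carries a `side` vertex attribute
#' (`"left"`/`"right"`) and a `weight` edge attribute, which is also how
#' [writeNetwork()] serializes GraphML.
#'
#' @param net a [BipartiteNetwork-class].
#' @return an [igraph::igraph] object.
#' @export
asIgraph <- function(net) {
    stopifnot(is(net, "BipartiteNetwork"))
    vertices <- data.frame(
        name = c(net@leftNodes, net@rightNodes),
        side = c(rep("left", length(net@leftNodes)),
                 rep("right", length(net@rightNodes))),
        stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(
        d = net@edges[, c("left", "right", "weight")],
        directed = FALSE, vertices = vertices)
}

#' Node degrees of a bipartite network
#'
#' Neighbour counts per declared node; isolated declared nodes report 0. The
#' handshake identity holds: each side's degrees sum to the edge count.
#'
#' @param net a [BipartiteNetwork-class].
#' @param side `"both"` (default), `"left"` or `"right"`.
#' @return named integer vector of degrees.
#' @export
nodeDegrees <- function(net, side = c("both", "left", "right")) {
    side <- match.arg(side)
    e <- net@edges
    degL <- structure(integer(length(net@leftNodes)), names = net@leftNodes)
    degR <- structure(integer(length(net@rightNodes)), names = net@rightNodes)
    if (nrow(e)) {
        tl <- table(e$left)
        tr <- table(e$right)
        degL[names(tl)] <- as.integer(tl)
        degR[names(tr)] <- as.integer(tr)
    }
    switch(side, both = c(degL, degR), left = degL, right = degR)
}

#' Shortest-path betweenness centrality
#'
#' Betweenness with fractional credit over equally short paths, computed on
#' the bipartite graph itself. When `normalized = TRUE` each node's value is
#' divided by `(n - 1) * (n - 2) / 2` with `n` the size of the node's
#' connected component (the undirected convention used by Cytoscape's
#' NetworkAnalyzer), so values lie in `[0, 1]`; nodes in components of size
#' below 3 score 0.
#'
#' @param net a [BipartiteNetwork-class].
#' @param normalized divide by the per-component pair count? Default `TRUE`.
#' @return named numeric vector over all declared nodes.
#' @examples
#' path <- buildBipartite(data.frame(l = c("A", "C"), r = c("B", "B")))
#' betweennessCentrality(path)[["B"]]  # 1: the only A-C path runs through B
#' @export
betweennessCentrality <- function(net, normalized = TRUE) {
    stopifnot(is(net, "BipartiteNetwork"))
    nodes <- c(net@leftNodes, net@rightNodes)
    if (!length(nodes)) return(structure(numeric(), names = character()))
    g <- asIgraph(net)
    btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
    out <- structure(as.numeric(btw), names = igraph::V(g)$name)
    if (normalized) {
        comp <- igraph::components(g)
        csize <- comp$csize[comp$membership]
        denom <- (csize - 1) * (csize - 2) / 2
        out <- ifelse(denom > 0, out / denom, 0)
        names(out) <- igraph::V(g)$name
    }
    out[nodes]
}

#' Node attribute table (degree and betweenness)
#'
#' One row per declared node with its side, degree and (normalized)
#' betweenness, ordered by decreasing degree then node id -- the layout used
#' for reporting each network layer.
#'
#' @param net a [BipartiteNetwork-class].
#' @param normalized passed to [betweennessCentrality()].
#' @return data.frame with columns `node`, `side`, `degree`, `betweenness`.
#' @export
nodeAttributes <- function(net, normalized = TRUE) {
    deg <- nodeDegrees(net)
    btw <- betweennessCentrality(net, normalized = normalized)
    side <- c(rep("left", length(net@leftNodes)),
              rep("right", length(net@rightNodes)))
    nodes <- if (is.null(names(deg))) character() else names(deg)
    out <- data.frame(node = nodes, side = side,
                      degree = as.integer(deg),
                      betweenness = as.numeric(btw[nodes]),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$degree, out$node), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Stratify one side of a network by degree
#'
#' Partitions the degree >= 1 nodes of the chosen side into `low` (degree in
#' `[1, c1]`), `middle` (`[c1 + 1, c2]`) and `high` (`[c2 + 1, Inf)`) strata.
#' The default cut points 10 and 30 reproduce the published molecule
#' classification (low 1-10, middle 11-30, high 31+). Degree-0 nodes are
#' excluded with a notice.
#'
#' @param net a [BipartiteNetwork-class].
#' @param side `"left"` or `"right"`; the molecule side of a drug-target
#'   layer in the canonical use.
#' @param bounds two strictly increasing integer cut points `(c1, c2)`.
#' @return named factor with levels `low`, `middle`, `high` over the
#'   degree >= 1 nodes of the side.
#' @export
stratifyByDegree <- function(net, side = c("left", "right"),
                             bounds = c(10L, 30L)) {
    side <- match.arg(side)
    bounds <- as.integer(bounds)
    if (length(bounds) != 2L || any(bounds < 1L) || bounds[1L] >= bounds[2L])
        stop("bounds must be two strictly increasing cut points >= 1")
    deg <- nodeDegrees(net, side)
    isolated <- names(deg)[deg == 0L]
    if (length(isolated))
        message("stratifyByDegree: excluding ", length(isolated),
                " degree-0 node(s): ",
                paste(utils::head(isolated, 5L), collapse = ", "))
    deg <- deg[deg > 0L]
    stratum <- cut(deg, breaks = c(0L, bounds, Inf),
                   labels = c("low", "middle", "high"), right = TRUE)
    structure(stratum, names = names(deg))
}

#' Pathway relevance-frequency score
#'
#' For the drug-target interactions of one degree stratum, scores each
#' pathway by its share of (molecule, target, pathway) incidence triples:
#' `score(p) = N(p) / sum_q N(q)` with `N(p)` the number of stratum
#' interactions whose target is annotated to `p`. Scores form a probability
#' vector over the pathways touched by the stratum and measure the impact of
#' the stratum's molecules on each pathway.
#'
#' @param hits data.frame of interaction pairs whose first two columns are
#'   molecule and target ids (e.g. [selectHits()] output restricted to one
#'   stratum's molecules).
#' @param targetPathway an [AnnotationMap-class] from target ids to pathway
#'   ids.
#' @return named numeric vector of scores, decreasing; sums to 1.
#' @examples
#' hits <- data.frame(molecule_id = c("m1", "m1", "m2"),
#'                    target_id = c("t1", "t2", "t1"))
#' tp <- annotationMap(list(t1 = "P1", t2 = c("P1", "P2")))
#' pathwayRelevanceScore(hits, tp)  # P1 0.75, P2 0.25
#' @export
pathwayRelevanceScore <- function(hits, targetPathway) {
    stopifnot(is(targetPathway, "AnnotationMap"))
    hits <- as.data.frame(hits, stringsAsFactors = FALSE)
    if (!nrow(hits))
        stop("no interactions in stratum")
    fwd <- forwardMap(targetPathway)
    pw <- fwd[as.character(hits[[2L]])]
    counts <- table(unlist(pw, use.names = FALSE))
    if (!length(counts))
        stop("no interactions in stratum")
    score <- as.numeric(counts) / sum(counts)
    names(score) <- names(counts)
    score[order(-score, names(score))]
}
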