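## Network composition across scales: drug-pathway by shared targets,
## pathway-disease from annotation, per-side mean degrees, and mechanism
## subnetwork extraction for a single disease pathway.

#' Project drug-pathway interactions through shared targets
#'
#' Composes the drug-target and target-pathway layers: an edge (drug,
#' pathway) exists iff some target is hit by the drug and annotated to the
#' pathway. The edge weight records the number of such shared targets, so
#' total edge weight equals the number of (drug, target, pathway) triples;
#' degrees are reported on the unweighted projection (a drug's degree is the
#' number of distinct pathways it reaches).
#'
#' @param dt drug-target [BipartiteNetwork-class] (targets on the right).
#' @param tp target-pathway [BipartiteNetwork-class] (targets on the left).
#' @return a weighted drug-pathway `BipartiteNetwork`. When the two layers
#'   share no target id the result is empty and a warning is raised.
#' @export
projectDrugPathway <- function(dt, tp) {
    stopifnot(is(dt, "BipartiteNetwork"), is(tp, "BipartiteNetwork"))
    shared <- intersect(rightNodes(dt), leftNodes(tp))
    if (!length(shared)) {
        warning("projectDrugPathway: disjoint target namespaces, ",
                "empty projection")
        return(buildBipartite(data.frame(left = character(),
                                         right = character())))
    }
    dte <- edgeTable(dt)
    tpe <- edgeTable(tp)
    m <- merge(dte[, c("left", "right")], tpe[, c("left", "right")],
               by.x = "right", by.y = "left")
    ## columns: right = target, left = drug, right.y = pathway
    names(m) <- c("target", "drug", "pathway")
    if (!nrow(m))
        return(buildBipartite(data.frame(left = character(),
                                         right = character())))
    key <- paste0(m$drug, "\r", m$pathway)
    w <- table(key)
    parts <- strsplit(names(w), "\r", fixed = TRUE)
    buildBipartite(
        data.frame(left = vapply(parts, `[[`, character(1), 1L),
                   right = vapply(parts, `[[`, character(1), 2L),
                   stringsAsFactors = FALSE),
        weights = as.integer(w))
}

#' Build the pathway-disease layer
#'
#' One edge per (pathway, disease) annotation, restricted to the supplied
#' pathway set. Pathways without any disease annotation are included as
#' isolated nodes only on request.
#'
#' @param pathways character vector of pathway ids.
#' @param pathwayDisease an [AnnotationMap-class] from pathway to disease ids.
#' @param keepIsolated declare disease-free pathways as isolated nodes?
#'   Default `FALSE`.
#' @return a pathway-disease [BipartiteNetwork-class].
#' @export
buildPathwayDisease <- function(pathways, pathwayDisease,
                                keepIsolated = FALSE) {
    stopifnot(is(pathwayDisease, "AnnotationMap"))
    pathways <- unique(as.character(pathways))
    fwd <- forwardMap(pathwayDisease)
    sets <- fwd[intersect(pathways, names(fwd))]
    pairs <- data.frame(left = rep(names(sets), lengths(sets)),
                        right = unlist(sets, use.names = FALSE),
                        stringsAsFactors = FALSE)
    iso <- if (keepIsolated) setdiff(pathways, names(sets)) else character()
    buildBipartite(pairs, leftNodes = iso)
}

#' Per-side mean degrees
#'
#' Arithmetic mean degree of each side over all declared nodes (isolates
#' included). With no declared isolates the identity
#' `left_mean * |left| = right_mean * |right| = |edges|` holds. An empty side
#' has no mean and reports `NA`.
#'
#' @param net a [BipartiteNetwork-class].
#' @return named numeric `c(left = , right = )`.
#' @export
bipartiteMeanDegrees <- function(net) {
    stopifnot(is(net, "BipartiteNetwork"))
    meanOf <- function(side) {
        deg <- nodeDegrees(net, side)
        if (!length(deg)) NA_real_ else mean(deg)
    }
    c(left = meanOf("left"), right = meanOf("right"))
}

#' Extract the mechanism subnetwork of one pathway
#'
#' For a disease pathway of interest, returns the drug-target subnetwork
#' containing exactly the targets annotated to that pathway that have at
#' least one drug hit, the drugs hitting them, and those drug-target edges --
#' the molecules and key proteins through which the formula can act on the
#' disease.
#'
#' @param dt drug-target [BipartiteNetwork-class].
#' @param tp target-pathway [BipartiteNetwork-class] (targets left,
#'   pathways right).
#' @param pathwayId a pathway id present in `tp`.
#' @return a drug-target `BipartiteNetwork`; empty when no annotated target
#'   has a drug hit.
#' @export
extractMechanism <- function(dt, tp, pathwayId) {
    stopifnot(is(dt, "BipartiteNetwork"), is(tp, "BipartiteNetwork"))
    pathwayId <- as.character(pathwayId)
    if (!(pathwayId %in% rightNodes(tp)))
        stop("unknown pathway id: ", pathwayId)
    tpe <- edgeTable(tp)
    inPathway <- unique(tpe$left[tpe$right == pathwayId])
    dte <- edgeTable(dt)
    sub <- dte[dte$right %in% inPathway, , drop = FALSE]
    buildBipartite(sub[, c("left", "right")], weights = sub$weight)
}

#' Summarize a mechanism subnetwork
#'
#' Molecule and target counts for one pathway's mechanism subnetwork, with an
#' optional shared-target comparison against a second pathway (diseases with
#' overlapping mechanism proteins tend to share clinical symptoms).
#'
#' @param dt,tp as in [extractMechanism()].
#' @param pathwayId pathway of interest.
#' @param comparePathway optional second pathway id; when given, the targets
#'   common to both mechanism subnetworks are reported.
#' @return data.frame with columns `pathway`, `n_molecules`, `n_targets`,
#'   `shared_with`, `shared_targets` (semicolon-joined, `""` when not asked).
#' @export
mechanismSummary <- function(dt, tp, pathwayId, comparePathway = NULL) {
    sub <- extractMechanism(dt, tp, pathwayId)
    shared <- ""
    compareLab <- ""
    if (!is.null(comparePathway)) {
        other <- extractMechanism(dt, tp, comparePathway)
        compareLab <- as.character(comparePathway)
        shared <- paste(sort(intersect(rightNodes(sub), rightNodes(other))),
                        collapse = ";")
    }
    data.frame(pathway = as.character(pathwayId),
               n_molecules = length(leftNodes(sub)),
               n_targets = length(rightNodes(sub)),
               shared_with = compareLab, shared_targets = shared,
               stringsAsFactors = FALSE)
}
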