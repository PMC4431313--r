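## Generics, constructors, accessors and show methods for the S4 containers.

#' @importFrom methods new validObject is setValidity slot
#' @importFrom stats rnorm rpois rexp runif
#' @importFrom utils read.delim write.table head tail
NULL

## ---- generics ---------------------------------------------------------------

#' @export
setGeneric("leftNodes", function(x) standardGeneric("leftNodes"))
#' @export
setGeneric("rightNodes", function(x) standardGeneric("rightNodes"))
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))
#' @export
setGeneric("mapName", function(x) standardGeneric("mapName"))
#' @export
setGeneric("forwardMap", function(x) standardGeneric("forwardMap"))
#' @export
setGeneric("reverseMap", function(x) standardGeneric("reverseMap"))
#' @export
setGeneric("upTags", function(x) standardGeneric("upTags"))
#' @export
setGeneric("downTags", function(x) standardGeneric("downTags"))
#' @export
setGeneric("rankingMatrix", function(x) standardGeneric("rankingMatrix"))
#' @export
setGeneric("instanceInfo", function(x) standardGeneric("instanceInfo"))
#' @export
setGeneric("tagUniverse", function(x) standardGeneric("tagUniverse"))

## ---- BipartiteNetwork accessors --------------------------------------------

#' Accessors for BipartiteNetwork
#'
#' `leftNodes()`/`rightNodes()` return the declared node identifiers of each
#' side, `edgeTable()` the edge data.frame (`left`, `right`, `weight`),
#' `edgeCount()` the number of edges and `nodeCount()` the number of declared
#' nodes over both sides.
#'
#' @param x a [BipartiteNetwork-class] object.
#' @return character vectors, a data.frame, or integer counts as described.
#' @examples
#' net <- buildBipartite(data.frame(left = "d1", right = c("t1", "t2")))
#' leftNodes(net)
#' edgeCount(net)
#' @name BipartiteNetwork-accessors
#' @aliases leftNodes rightNodes edgeTable edgeCount nodeCount
NULL

#' @rdname BipartiteNetwork-accessors
#' @export
setMethod("leftNodes", "BipartiteNetwork", function(x) x@leftNodes)

#' @rdname BipartiteNetwork-accessors
#' @export
setMethod("rightNodes", "BipartiteNetwork", function(x) x@rightNodes)

#' @rdname BipartiteNetwork-accessors
#' @export
setMethod("edgeTable", "BipartiteNetwork", function(x) x@edges)

#' @rdname BipartiteNetwork-accessors
#' @export
setMethod("edgeCount", "BipartiteNetwork", function(x) nrow(x@edges))

#' @rdname BipartiteNetwork-accessors
#' @export
setMethod("nodeCount", "BipartiteNetwork",
          function(x) length(x@leftNodes) + length(x@rightNodes))

setMethod("show", "BipartiteNetwork", function(object) {
    cat("BipartiteNetwork:", length(object@leftNodes), "left x",
        length(object@rightNodes), "right nodes,",
        nrow(object@edges), "edges\n")
    if (nrow(object@edges)) {
        w <- object@edges$weight
        if (any(w != 1L))
            cat("  weighted; total weight", sum(w), "\n")
    }
    invisible(NULL)
})

## ---- AnnotationMap ----------------------------------------------------------

#' Construct an AnnotationMap
#'
#' @param forward named list mapping key ids to character vectors of value
#'   ids. Duplicate values within a set are dropped; empty sets are removed.
#' @param name label for the map.
#' @return an [AnnotationMap-class] object.
#' @examples
#' tp <- annotationMap(list(T1 = c("P1", "P2"), T2 = "P1"), "target_pathway")
#' forwardMap(tp)$T1
#' reverseMap(tp)$P1
#' @export
annotationMap <- function(forward, name = "") {
    stopifnot(is.list(forward))
    forward <- lapply(forward, function(v) unique(as.character(v)))
    forward <- forward[lengths(forward) > 0L]
    new("AnnotationMap", name = as.character(name), forward = forward)
}

#' Accessors for AnnotationMap
#'
#' `forwardMap()` returns the stored key -> value-set list, `reverseMap()`
#' the derived value -> key-set list (consistent with the forward view by
#' construction), and `mapName()` the label.
#'
#' @param x an [AnnotationMap-class] object.
#' @name AnnotationMap-accessors
#' @aliases mapName forwardMap reverseMap
NULL

#' @rdname AnnotationMap-accessors
#' @export
setMethod("mapName", "AnnotationMap", function(x) x@name)

#' @rdname AnnotationMap-accessors
#' @export
setMethod("forwardMap", "AnnotationMap", function(x) x@forward)

#' @rdname AnnotationMap-accessors
#' @export
setMethod("reverseMap", "AnnotationMap", function(x) {
    f <- x@forward
    if (!length(f)) return(structure(list(), names = character()))
    key <- rep(names(f), lengths(f))
    val <- unlist(f, use.names = FALSE)
    lapply(split(key, val), unique)
})

#' @describeIn AnnotationMap-accessors number of stored keys.
#' @export
setMethod("length", "AnnotationMap", function(x) length(x@forward))

setMethod("show", "AnnotationMap", function(object) {
    cat("AnnotationMap", if (nzchar(object@name))
        paste0("'", object@name, "'") else "", ": ",
        length(object@forward), " keys -> ",
        length(unique(unlist(object@forward, use.names = FALSE))),
        " values (", sum(lengths(object@forward)), " assignments)\n", sep = "")
    invisible(NULL)
})

## ---- ZhengLabelSet ----------------------------------------------------------

#' Construct a ZhengLabelSet
#'
#' @param disease character vector of disease ids.
#' @param labels list of label sets parallel to `disease`; each a nonempty
#'   subset of `c("Cold", "Hot")`.
#' @return a [ZhengLabelSet-class] object.
#' @examples
#' z <- zhengLabelSet(c("d1", "d2", "d3"),
#'                    list("Cold", c("Cold", "Hot"), "Hot"))
#' classifyZheng(z)$summary
#' @export
zhengLabelSet <- function(disease, labels) {
    new("ZhengLabelSet", disease = as.character(disease),
        labels = lapply(labels, function(l) unique(as.character(l))))
}

#' @describeIn zhengLabelSet number of labelled diseases.
#' @param x a `ZhengLabelSet`.
#' @export
setMethod("length", "ZhengLabelSet", function(x) length(x@disease))

setMethod("show", "ZhengLabelSet", function(object) {
    cat("ZhengLabelSet:", length(object@disease), "labelled diseases\n")
    invisible(NULL)
})

#' Restrict a ZhengLabelSet to a disease set
#'
#' @param x a [ZhengLabelSet-class] object.
#' @param diseases character vector of disease ids to keep.
#' @return a `ZhengLabelSet` containing only the requested diseases.
#' @export
subsetZheng <- function(x, diseases) {
    stopifnot(is(x, "ZhengLabelSet"))
    keep <- x@disease %in% diseases
    new("ZhengLabelSet", disease = x@disease[keep], labels = x@labels[keep])
}

## ---- TagSignature -----------------------------------------------------------

#' Construct a TagSignature
#'
#' @param up,down character vectors of up- and down-regulated tags. They must
#'   be disjoint and at least one must be nonempty (a one-sided signature is
#'   allowed).
#' @return a [TagSignature-class] object.
#' @examples
#' sig <- tagSignature(up = c("g1", "g2"), down = "g9")
#' upTags(sig)
#' @export
tagSignature <- function(up = character(), down = character()) {
    new("TagSignature", up = as.character(up), down = as.character(down))
}

#' @rdname tagSignature
#' @param x a `TagSignature`.
#' @export
setMethod("upTags", "TagSignature", function(x) x@up)

#' @rdname tagSignature
#' @export
setMethod("downTags", "TagSignature", function(x) x@down)

setMethod("show", "TagSignature", function(object) {
    cat("TagSignature:", length(object@up), "up /",
        length(object@down), "down tags\n")
    invisible(NULL)
})

## ---- RankedProfileSet -------------------------------------------------------

#' Construct a RankedProfileSet
#'
#' @param rankings integer matrix (tags x instances) with tag rownames; each
#'   column a permutation of `1:nrow(rankings)`, rank 1 = most up-regulated.
#' @param instances data.frame with columns `instance`, `perturbagen`,
#'   `cell_line` describing each column.
#' @return a [RankedProfileSet-class] object.
#' @export
rankedProfileSet <- function(rankings, instances) {
    storage.mode(rankings) <- "integer"
    instances <- as.data.frame(instances, stringsAsFactors = FALSE)
    new("RankedProfileSet", rankings = rankings, instances = instances)
}

#' Accessors for RankedProfileSet
#'
#' `rankingMatrix()` returns the tags x instances rank matrix,
#' `instanceInfo()` the instance annotation table and `tagUniverse()` the tag
#' identifiers.
#'
#' @param x a [RankedProfileSet-class] object.
#' @name RankedProfileSet-accessors
#' @aliases rankingMatrix instanceInfo tagUniverse
NULL

#' @rdname RankedProfileSet-accessors
#' @export
setMethod("rankingMatrix", "RankedProfileSet", function(x) x@rankings)

#' @rdname RankedProfileSet-accessors
#' @export
setMethod("instanceInfo", "RankedProfileSet", function(x) x@instances)

#' @rdname RankedProfileSet-accessors
#' @export
setMethod("tagUniverse", "RankedProfileSet", function(x) rownames(x@rankings))

setMethod("show", "RankedProfileSet", function(object) {
    cat("RankedProfileSet:", nrow(object@rankings), "tags x",
        ncol(object@rankings), "instances;",
        length(unique(object@instances$perturbagen)), "perturbagens,",
        length(unique(object@instances$cell_line)), "cell line(s)\n")
    invisible(NULL)
})

## ---- SimulationSpec ---------------------------------------------------------

#' Create a synthetic-world specification
#'
#' Returns a [SimulationSpec-class] whose defaults state the emulated world:
#' 90 ingredient molecules docked against 270 targets with an overall planted
#' hit fraction of 0.018 (matching the source system's drug-target edge
#' density), hub molecules planted at post-filter degrees 62, 40 and 34, a
#' 1-truncated-Poisson annotation structure with on average 4.6 pathways per
#' target and 3 diseases per pathway, a dominant first pathway, ZHENG label
#' proportions (Cold 0.25, Hot 0.80, both 0.05) over 17.5% of diseases, and a
#' connectivity reference of 22 perturbagens (a planted mimic, a planted
#' reverser and 20 nulls) with 2 instances each over a 500-tag universe.
#'
#' @param nMolecules,nTargets,nPathways,nDiseases,nSymptoms entity counts.
#' @param hitFraction planted hit probability for non-hub pairs, in `[0, 1)`.
#' @param hubSpec data.frame (`molecule`, `degree`): planted hub degrees.
#' @param meanPathwaysPerTarget,meanDiseasesPerPathway,meanSymptomsPerDisease
#'   means of the 1-truncated Poisson set sizes (all >= 1).
#' @param dominantPathwayBoost sampling-weight multiplier for pathway 1.
#' @param zhengProportions named `(cold, hot, both)` inclusive proportions.
#' @param zhengFraction fraction of diseases receiving a ZHENG label.
#' @param nPerturbagens,nInstances,nTags,nUpTags,nDownTags,mimicStrength,cellLines
#'   connectivity-reference settings (see [SimulationSpec-class]).
#' @param seed master seed.
#' @return a validated `SimulationSpec`.
#' @examples
#' spec <- simulationSpec(seed = 7)
#' spec
#' @export
simulationSpec <- function(nMolecules = 90, nTargets = 270, nPathways = 40,
                           nDiseases = 130, nSymptoms = 50,
                           hitFraction = 0.018,
                           hubSpec = data.frame(molecule = 1:3,
                                                degree = c(62L, 40L, 34L)),
                           meanPathwaysPerTarget = 4.6,
                           meanDiseasesPerPathway = 3,
                           meanSymptomsPerDisease = 19,
                           dominantPathwayBoost = 8,
                           zhengProportions = c(cold = 0.25, hot = 0.80,
                                                both = 0.05),
                           zhengFraction = 0.175,
                           nPerturbagens = 22, nInstances = 2, nTags = 500,
                           nUpTags = 20, nDownTags = 20, mimicStrength = 3,
                           cellLines = "MCF7", seed = 1) {
    new("SimulationSpec",
        nMolecules = as.integer(nMolecules), nTargets = as.integer(nTargets),
        nPathways = as.integer(nPathways), nDiseases = as.integer(nDiseases),
        nSymptoms = as.integer(nSymptoms), hitFraction = as.numeric(hitFraction),
        hubSpec = as.data.frame(hubSpec),
        meanPathwaysPerTarget = as.numeric(meanPathwaysPerTarget),
        meanDiseasesPerPathway = as.numeric(meanDiseasesPerPathway),
        meanSymptomsPerDisease = as.numeric(meanSymptomsPerDisease),
        dominantPathwayBoost = as.numeric(dominantPathwayBoost),
        zhengProportions = zhengProportions,
        zhengFraction = as.numeric(zhengFraction),
        nPerturbagens = as.integer(nPerturbagens),
        nInstances = as.integer(nInstances), nTags = as.integer(nTags),
        nUpTags = as.integer(nUpTags), nDownTags = as.integer(nDownTags),
        mimicStrength = as.numeric(mimicStrength),
        cellLines = as.character(cellLines), seed = as.integer(seed))
}

setMethod("show", "SimulationSpec", function(object) {
    cat("SimulationSpec:", object@nMolecules, "molecules x", object@nTargets,
        "targets;", object@nPathways, "pathways,", object@nDiseases,
        "diseases,", object@nSymptoms, "symptoms\n")
    cat("  hit fraction", object@hitFraction, "with",
        nrow(object@hubSpec), "planted hub(s); seed", object@seed, "\n")
    invisible(NULL)
})

## ---- PipelineConfig ---------------------------------------------------------

#' Create a pipeline configuration
#'
#' @param dockingPath,targetMetaPath,pathwayDiseasePath,diseaseCategoryPath,diseaseSymptomPath,zhengPath
#'   input file locations.
#' @param outDir output directory (created if missing).
#' @param scoreThreshold docking-score cutoff (default 6.0).
#' @param strataBounds degree-stratum cut points (default `c(10, 30)`).
#' @param nPermutations connectivity permutation count.
#' @param seed integer seed.
#' @param organism eligible organism label (case-insensitive).
#' @param profilesPath,signaturePath optional connectivity inputs; leave `NA`
#'   to skip the connectivity stage.
#' @return a validated [PipelineConfig-class].
#' @seealso [runPipeline()], [readPipelineConfig()]
#' @export
pipelineConfig <- function(dockingPath, targetMetaPath, pathwayDiseasePath,
                           diseaseCategoryPath, diseaseSymptomPath, zhengPath,
                           outDir, scoreThreshold = 6.0,
                           strataBounds = c(10L, 30L), nPermutations = 100L,
                           seed = 1L, organism = "human",
                           profilesPath = NA_character_,
                           signaturePath = NA_character_) {
    new("PipelineConfig", scoreThreshold = as.numeric(scoreThreshold),
        strataBounds = as.integer(strataBounds),
        nPermutations = as.integer(nPermutations), seed = as.integer(seed),
        organism = as.character(organism),
        dockingPath = as.character(dockingPath),
        targetMetaPath = as.character(targetMetaPath),
        pathwayDiseasePath = as.character(pathwayDiseasePath),
        diseaseCategoryPath = as.character(diseaseCategoryPath),
        diseaseSymptomPath = as.character(diseaseSymptomPath),
        zhengPath = as.character(zhengPath),
        profilesPath = as.character(profilesPath),
        signaturePath = as.character(signaturePath),
        outDir = as.character(outDir))
}

setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig: threshold", object@scoreThreshold,
        "| strata cuts", paste(object@strataBounds, collapse = "/"),
        "| permutations", object@nPermutations,
        "| seed", object@seed, "\n")
    cat("  out:", object@outDir, "\n")
    invisible(NULL)
})
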