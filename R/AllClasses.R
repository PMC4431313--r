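## S4 containers for the multiscale pipeline:
## drug ingredients -> protein targets -> pathways -> diseases -> symptoms/ZHENG.

.emptyEdges <- function() {
    data.frame(left = character(), right = character(), weight = integer(),
               stringsAsFactors = FALSE)
}

#' Two-sided (bipartite) interaction network
#'
#' Carrier for every network layer in the pipeline: drug-target,
#' target-pathway, drug-pathway and pathway-disease. Nodes live on a declared
#' `left` or `right` side; edges are undirected, simple (parallel edges
#' collapsed) and may carry a positive integer weight (used by the
#' drug-pathway projection to record shared-target counts). Declared nodes
#' without incident edges are allowed and count as isolates.
#'
#' @slot leftNodes character vector of left-side node identifiers.
#' @slot rightNodes character vector of right-side node identifiers.
#' @slot edges data.frame with columns `left`, `right`, `weight`.
#'
#' @seealso [buildBipartite()] for the user-facing constructor.
#' @export
setClass("BipartiteNetwork",
    slots = c(leftNodes = "character", rightNodes = "character",
              edges = "data.frame"),
    prototype = list(leftNodes = character(), rightNodes = character(),
                     edges = .emptyEdges()))

setValidity("BipartiteNetwork", function(object) {
    msg <- character()
    e <- object@edges
    if (!all(c("left", "right", "weight") %in% names(e)))
        return("edges must have columns 'left', 'right', 'weight'")
    if (anyDuplicated(object@leftNodes) || anyDuplicated(object@rightNodes))
        msg <- c(msg, "duplicated node identifiers within a side")
    overlap <- intersect(object@leftNodes, object@rightNodes)
    if (length(overlap))
        msg <- c(msg, paste0("node id in both sides (namespace collision): ",
                             overlap[1L]))
    if (nrow(e)) {
        if (!all(e$left %in% object@leftNodes))
            msg <- c(msg, "edge with undeclared left endpoint")
        if (!all(e$right %in% object@rightNodes))
            msg <- c(msg, "edge with undeclared right endpoint")
        if (anyDuplicated(paste0(e$left, "\r", e$right)))
            msg <- c(msg, "parallel edges are not allowed")
        if (any(!is.finite(e$weight)) || any(e$weight < 1))
            msg <- c(msg, "edge weights must be positive")
    }
    if (length(msg)) msg else TRUE
})

#' Named many-to-many identifier mapping
#'
#' A named family of identifier sets: target -> pathways, pathway -> diseases,
#' disease -> symptoms, disease -> categories. Stored keys always map to
#' nonempty, duplicate-free value sets; the reverse view is derived on demand.
#'
#' @slot name single string labelling the map (e.g. `"pathway_disease"`).
#' @slot forward named list; each element a character vector of value ids.
#'
#' @seealso [annotationMap()], [forwardMap()], [reverseMap()]
#' @export
setClass("AnnotationMap",
    slots = c(name = "character", forward = "list"),
    prototype = list(name = "", forward = structure(list(), names = character())))

setValidity("AnnotationMap", function(object) {
    msg <- character()
    if (length(object@name) != 1L)
        msg <- c(msg, "name must be a single string")
    f <- object@forward
    if (length(f)) {
        if (is.null(names(f)) || any(!nzchar(names(f))) || anyDuplicated(names(f)))
            msg <- c(msg, "forward map keys must be unique nonempty strings")
        sizes <- lengths(f)
        if (any(sizes == 0L))
            msg <- c(msg, "stored keys must map to nonempty value sets")
        if (!all(vapply(f, is.character, logical(1))))
            msg <- c(msg, "value sets must be character vectors")
        if (any(vapply(f, anyDuplicated, integer(1)) > 0L))
            msg <- c(msg, "value sets must be duplicate-free")
    }
    if (length(msg)) msg else TRUE
})

#' Cold/Hot ZHENG labels per disease
#'
#' Per-disease nonempty subsets of \{Cold, Hot\}, the traditional Chinese
#' medicine syndrome dichotomy. Diseases without a label are simply absent.
#'
#' @slot disease character vector of disease identifiers (unique).
#' @slot labels list parallel to `disease`; each element a nonempty subset of
#'   `c("Cold", "Hot")`.
#'
#' @seealso [zhengLabelSet()], [classifyZheng()]
#' @export
setClass("ZhengLabelSet",
    slots = c(disease = "character", labels = "list"),
    prototype = list(disease = character(), labels = list()))

setValidity("ZhengLabelSet", function(object) {
    msg <- character()
    if (length(object@disease) != length(object@labels))
        msg <- c(msg, "disease and labels must have equal length")
    if (anyDuplicated(object@disease))
        msg <- c(msg, "disease ids must be unique")
    ok <- vapply(object@labels, function(l)
        is.character(l) && length(l) >= 1L && all(l %in% c("Cold", "Hot")) &&
            !anyDuplicated(l), logical(1))
    if (!all(ok))
        msg <- c(msg, "each label set must be a nonempty subset of {Cold, Hot}")
    if (length(msg)) msg else TRUE
})

#' Up/down expression tag signature
#'
#' A query signature for connectivity scoring: an up-regulated and a
#' down-regulated tag list. The two lists are disjoint and at least one is
#' nonempty (an up-only query is supported).
#'
#' @slot up character vector of up-regulated tags.
#' @slot down character vector of down-regulated tags.
#'
#' @seealso [tagSignature()], [instanceScores()]
#' @export
setClass("TagSignature",
    slots = c(up = "character", down = "character"),
    prototype = list(up = character(), down = character()))

setValidity("TagSignature", function(object) {
    msg <- character()
    if (length(object@up) + length(object@down) == 0L)
        msg <- c(msg, "at least one of up/down must be nonempty")
    if (anyDuplicated(object@up) || anyDuplicated(object@down))
        msg <- c(msg, "tag lists must be duplicate-free")
    if (length(intersect(object@up, object@down)))
        msg <- c(msg, "up and down tag lists must be disjoint")
    if (length(msg)) msg else TRUE
})

#' Reference set of rank-ordered expression instances
#'
#' The reference side of connectivity scoring: a tag universe and, per
#' instance (one treatment of one perturbagen in one cell line), a complete
#' ranking of the universe, rank 1 = most up-regulated.
#'
#' @slot rankings integer matrix, tags x instances; column j holds the rank of
#'   every tag in instance j and is a permutation of `1:nrow`.
#' @slot instances data.frame with columns `instance`, `perturbagen`,
#'   `cell_line`, one row per column of `rankings`.
#'
#' @seealso [rankedProfileSet()], [meanScoresWithPvalues()]
#' @export
setClass("RankedProfileSet",
    slots = c(rankings = "matrix", instances = "data.frame"),
    prototype = list(
        rankings = matrix(integer(), 0L, 0L),
        instances = data.frame(instance = character(), perturbagen = character(),
                               cell_line = character(), stringsAsFactors = FALSE)))

setValidity("RankedProfileSet", function(object) {
    msg <- character()
    rk <- object@rankings
    info <- object@instances
    if (!all(c("instance", "perturbagen", "cell_line") %in% names(info)))
        return("instances needs columns instance, perturbagen, cell_line")
    if (ncol(rk) != nrow(info))
        msg <- c(msg, "one instances row per rankings column required")
    if (nrow(rk) && is.null(rownames(rk)))
        msg <- c(msg, "rankings must carry tag rownames")
    if (nrow(rk) && anyDuplicated(rownames(rk)))
        msg <- c(msg, "tag ids must be unique")
    n <- nrow(rk)
    if (n && ncol(rk)) {
        perm <- apply(rk, 2L, function(col) identical(sort(as.integer(col)),
                                                      seq_len(n)))
        if (!all(perm))
            msg <- c(msg, "every column must be a permutation of 1..n_tags")
    }
    if (anyDuplicated(info$instance))
        msg <- c(msg, "instance ids must be unique")
    if (length(msg)) msg else TRUE
})

#' Synthetic-world specification
#'
#' All knobs of the seeded synthetic-data generators. Defaults state the
#' emulated world once: magnitudes follow the source system scaled to desk
#' size (90 ingredient molecules, 270 targets, 40 pathways, 130 diseases),
#' hub molecules planted at the observed top drug-target degrees (62, 40, 34),
#' pathway multiplicities around the observed network densities, and ZHENG
#' proportions (Cold 0.25, Hot 0.80, both 0.05) matching the published
#' 28/94/5 split of 117 labelled diseases.
#'
#' @slot nMolecules,nTargets,nPathways,nDiseases,nSymptoms positive counts.
#' @slot hitFraction probability that a non-hub (molecule, target) pair is a
#'   planted docking hit.
#' @slot hubSpec data.frame with columns `molecule` (index) and `degree`:
#'   molecules planted to reach exactly that post-filter degree.
#' @slot meanPathwaysPerTarget,meanDiseasesPerPathway,meanSymptomsPerDisease
#'   means of the 1-truncated Poisson set sizes.
#' @slot dominantPathwayBoost sampling-weight multiplier for the first
#'   pathway, planting a dominant pathway recoverable by the relevance score.
#' @slot zhengProportions named numeric `(cold, hot, both)`; inclusive
#'   probabilities among labelled diseases.
#' @slot zhengFraction fraction of diseases that carry a ZHENG label.
#' @slot nPerturbagens,nInstances,nTags,nUpTags,nDownTags,mimicStrength
#'   connectivity-reference settings: perturbagen count (the first is a
#'   planted mimic, the second a planted reverser), instances per perturbagen,
#'   tag-universe size, signature sizes, and the mean shift (in SD units of
#'   the latent tag score) applied to signature tags in the planted profiles.
#' @slot cellLines character vector of cell-line labels cycled over instances.
#' @slot seed integer master seed; all generators are deterministic given it.
#'
#' @seealso [simulationSpec()], [simulateAll()]
#' @export
setClass("SimulationSpec",
    slots = c(nMolecules = "integer", nTargets = "integer",
              nPathways = "integer", nDiseases = "integer",
              nSymptoms = "integer", hitFraction = "numeric",
              hubSpec = "data.frame", meanPathwaysPerTarget = "numeric",
              meanDiseasesPerPathway = "numeric",
              meanSymptomsPerDisease = "numeric",
              dominantPathwayBoost = "numeric",
              zhengProportions = "numeric", zhengFraction = "numeric",
              nPerturbagens = "integer", nInstances = "integer",
              nTags = "integer", nUpTags = "integer", nDownTags = "integer",
              mimicStrength = "numeric", cellLines = "character",
              seed = "integer"))

setValidity("SimulationSpec", function(object) {
    msg <- character()
    counts <- c(object@nMolecules, object@nTargets, object@nPathways,
                object@nDiseases, object@nSymptoms, object@nPerturbagens,
                object@nInstances, object@nTags)
    if (any(counts < 1L)) msg <- c(msg, "all counts must be >= 1")
    if (!(object@hitFraction >= 0 && object@hitFraction < 1))
        msg <- c(msg, "hitFraction must lie in [0, 1)")
    hs <- object@hubSpec
    if (!all(c("molecule", "degree") %in% names(hs)))
        msg <- c(msg, "hubSpec needs columns molecule, degree")
    else {
        if (any(hs$degree > object@nTargets))
            msg <- c(msg, "planted hub degree exceeds n_targets")
        if (any(hs$molecule < 1L | hs$molecule > object@nMolecules))
            msg <- c(msg, "hub molecule index out of range")
        if (anyDuplicated(hs$molecule))
            msg <- c(msg, "duplicate hub molecule index")
    }
    zp <- object@zhengProportions
    if (!all(c("cold", "hot", "both") %in% names(zp)))
        msg <- c(msg, "zhengProportions needs names cold, hot, both")
    else {
        if (any(zp < 0 | zp > 1)) msg <- c(msg, "zheng proportions in [0,1]")
        if (zp["both"] > min(zp["cold"], zp["hot"]))
            msg <- c(msg, "both-proportion cannot exceed cold or hot")
    }
    if (!(object@zhengFraction >= 0 && object@zhengFraction <= 1))
        msg <- c(msg, "zhengFraction in [0, 1]")
    means <- c(object@meanPathwaysPerTarget, object@meanDiseasesPerPathway,
               object@meanSymptomsPerDisease)
    if (any(means < 1)) msg <- c(msg, "mean set sizes must be >= 1")
    if (object@nUpTags + object@nDownTags > object@nTags)
        msg <- c(msg, "signature larger than tag universe")
    if (object@nUpTags + object@nDownTags < 1L)
        msg <- c(msg, "signature must have at least one tag")
    if (object@mimicStrength < 0) msg <- c(msg, "mimicStrength must be >= 0")
    if (object@nPerturbagens < 3L)
        msg <- c(msg, "need >= 3 perturbagens (mimic, reverser, >=1 null)")
    if (length(msg)) msg else TRUE
})

#' Pipeline configuration
#'
#' Parameters and file locations for [runPipeline()]. The docking-score
#' cutoff defaults to 6.0 and the degree-stratum cut points to 10 and 30
#' (low 1-10, middle 11-30, high 31+), the published operating point.
#'
#' @slot scoreThreshold docking-score cutoff; a pair is a hit only if its best
#'   score strictly exceeds both this and the target's reference-ligand score.
#' @slot strataBounds two strictly increasing integer cut points `(c1, c2)`.
#' @slot nPermutations permutation count for connectivity p-values.
#' @slot seed integer seed for every stochastic stage.
#' @slot organism organism label accepted by the eligibility filter
#'   (case-insensitive).
#' @slot dockingPath,targetMetaPath,pathwayDiseasePath,diseaseCategoryPath,diseaseSymptomPath,zhengPath
#'   input file locations (TSV / GMT-style dialects, see the I/O help pages).
#' @slot profilesPath,signaturePath optional connectivity inputs (`NA` to
#'   skip the connectivity stage).
#' @slot outDir directory receiving every artifact.
#'
#' @seealso [pipelineConfig()], [readPipelineConfig()], [runPipeline()]
#' @export
setClass("PipelineConfig",
    slots = c(scoreThreshold = "numeric", strataBounds = "integer",
              nPermutations = "integer", seed = "integer",
              organism = "character",
              dockingPath = "character", targetMetaPath = "character",
              pathwayDiseasePath = "character",
              diseaseCategoryPath = "character",
              diseaseSymptomPath = "character", zhengPath = "character",
              profilesPath = "character", signaturePath = "character",
              outDir = "character"))

setValidity("PipelineConfig", function(object) {
    msg <- character()
    if (!is.finite(object@scoreThreshold))
        msg <- c(msg, "scoreThreshold must be finite")
    b <- object@strataBounds
    if (length(b) != 2L || any(b < 1L) || b[1L] >= b[2L])
        msg <- c(msg, "strataBounds must be two strictly increasing cut points >= 1")
    if (object@nPermutations < 1L)
        msg <- c(msg, "nPermutations must be >= 1")
    if (length(msg)) msg else TRUE
})
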