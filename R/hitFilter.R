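## Virtual-screening hit selection and target eligibility. These two rules
## define the edge set of the drug-target layer: a (molecule, target) pair is
## a hit only if its docking score strictly beats both the target's original
## co-crystal ligand and the global cutoff (6.0), and a target survives only
## if it is human, pathway-annotated, and at least one of its pathways has a
## disease annotation.

#' Select docking hits
#'
#' A (molecule, target) pair is retained iff its docking score strictly
#' exceeds the target's reference-ligand score *and* strictly exceeds
#' `threshold` (default 6.0; "higher than" is read literally, so ties are
#' excluded). Scores follow the higher-is-stronger convention; flip signs at
#' ingest if your docking engine reports energies. Multiple records for the
#' same pair collapse to the pair's best score, compared against the
#' target's minimum reference score over all its records (the most
#' permissive composition across alternative crystal structures).
#'
#' @param records data.frame with columns `molecule_id`, `target_id`,
#'   `score`, `reference_score` (see [readDockingTable()]).
#' @param threshold finite docking-score cutoff.
#' @return data.frame of unique hit pairs with columns `molecule_id`,
#'   `target_id`, `score` (pair best) and `reference_score` (target minimum),
#'   sorted by molecule then target; zero rows when nothing passes.
#' @examples
#' rec <- data.frame(molecule_id = "m", target_id = "t",
#'                   score = 6.5, reference_score = 6.2)
#' nrow(selectHits(rec))            # 1: 6.5 > 6.2 and 6.5 > 6.0
#' nrow(selectHits(rec, threshold = 6.5))  # 0: strict inequality
#' @export
selectHits <- function(records, threshold = 6.0) {
    if (!is.finite(threshold)) stop("threshold must be finite")
    records <- as.data.frame(records, stringsAsFactors = FALSE)
    need <- c("molecule_id", "target_id", "score", "reference_score")
    miss <- setdiff(need, names(records))
    if (length(miss))
        stop("records is missing column(s): ", paste(miss, collapse = ", "))
    empty <- data.frame(molecule_id = character(), target_id = character(),
                        score = numeric(), reference_score = numeric(),
                        stringsAsFactors = FALSE)
    if (!nrow(records)) return(empty)
    if (any(!is.finite(records$score)) || any(!is.finite(records$reference_score)))
        stop("non-finite score in records; reject such rows at read time")
    ## per-target minimum reference, per-pair best score
    refMin <- tapply(records$reference_score, records$target_id, min)
    key <- paste0(records$molecule_id, "\r", records$target_id)
    best <- tapply(records$score, key, max)
    pairKey <- names(best)
    parts <- strsplit(pairKey, "\r", fixed = TRUE)
    mol <- vapply(parts, `[[`, character(1), 1L)
    tgt <- vapply(parts, `[[`, character(1), 2L)
    score <- as.numeric(best)
    ref <- as.numeric(refMin[tgt])
    keep <- score > ref & score > threshold
    out <- data.frame(molecule_id = mol[keep], target_id = tgt[keep],
                      score = score[keep], reference_score = ref[keep],
                      stringsAsFactors = FALSE)
    out <- out[order(out$molecule_id, out$target_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Targets eligible for network construction
#'
#' Applies the three eligibility criteria to annotated targets: (a) the
#' source organism matches `organism` (case-insensitive), (b) the target has
#' at least one pathway annotation, and (c) at least one of its pathways has
#' at least one disease annotation. Pathway ids absent from the
#' pathway-disease map simply contribute no disease.
#'
#' @param targets data.frame with columns `target_id`, `organism` and a list
#'   column `pathways` (see [readTargetMeta()]).
#' @param pathwayDisease an [AnnotationMap-class] from pathway ids to disease
#'   ids.
#' @param organism accepted organism label, default `"human"`.
#' @return character vector of eligible target ids (sorted).
#' @export
eligibleTargets <- function(targets, pathwayDisease, organism = "human") {
    stopifnot(is(pathwayDisease, "AnnotationMap"))
    targets <- as.data.frame(targets, stringsAsFactors = FALSE)
    need <- c("target_id", "organism", "pathways")
    miss <- setdiff(need, names(targets))
    if (length(miss))
        stop("targets is missing column(s): ", paste(miss, collapse = ", "))
    if (!nrow(targets)) return(character())
    fwd <- forwardMap(pathwayDisease)
    isHuman <- tolower(targets$organism) == tolower(organism)
    hasPathway <- lengths(targets$pathways) > 0L
    hasDisease <- vapply(targets$pathways, function(pw)
        any(lengths(fwd[as.character(pw)]) > 0L), logical(1))
    sort(unique(targets$target_id[isHuman & hasPathway & hasDisease]))
}

#' Restrict hits to eligible targets
#'
#' Keeps exactly the hit rows whose target is in `keptTargets`; molecules
#' whose hits all disappear drop out of the downstream network.
#'
#' @param hits data.frame of hit pairs (first two columns molecule, target),
#'   as returned by [selectHits()].
#' @param keptTargets character vector of target ids to keep.
#' @return the filtered hits data.frame (possibly zero rows).
#' @export
restrictHits <- function(hits, keptTargets) {
    hits <- as.data.frame(hits, stringsAsFactors = FALSE)
    if (!nrow(hits)) return(hits)
    out <- hits[hits[[2L]] %in% keptTargets, , drop = FALSE]
    rownames(out) <- NULL
    out
}
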