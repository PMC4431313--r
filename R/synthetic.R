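## Seeded generators for every pipeline input, with planted structure:
## a known hit fraction and hub degrees in the docking table, a dominant
## pathway in the annotation layer, stated ZHENG proportions, and planted
## mimic/reverser perturbagens in the expression reference.

.molIds <- function(n) sprintf("MOL%03d", seq_len(n))
.tgtIds <- function(n) sprintf("TGT%03d", seq_len(n))
.pwyIds <- function(n) sprintf("PWY%03d", seq_len(n))
.disIds <- function(n) sprintf("DIS%03d", seq_len(n))
.symIds <- function(n) sprintf("SYM%03d", seq_len(n))

## 1-truncated Poisson sizes with exact mean `mean` (>= 1), capped at `cap`.
.truncPoisSizes <- function(n, mean, cap) {
    pmin(1L + stats::rpois(n, mean - 1), cap)
}

.categoryVocab <- c(
    "Inherited metabolic disease", "Cancer", "Nervous system disease",
    "Developmental disorder", "Hematologic disease", "Skeletal dysplasia",
    "Infectious disease", "Skin and connective tissue disease",
    "Primary immunodeficiency", "Immune system disease",
    "Neurodegenerative disease", "Endocrine disease", "Kidney disease",
    "Cardiovascular disease", "Eye disease")

#' Generate a synthetic docking-score table
#'
#' Emits one record per (molecule, target) pair of the spec's world. Each
#' target's reference-ligand score is drawn around the 6.0 operating
#' threshold; planted hits score strictly above `max(reference, 6) + 0.5`
#' and everything else strictly below `max(reference, 6)`, so
#' [selectHits()] at threshold 6 recovers exactly the planted pairs. Hub
#' molecules listed in `hubSpec` receive exactly their intended number of
#' hits (their remaining pairs are forced misses); every other pair is a hit
#' independently with probability `hitFraction`.
#'
#' @param spec a [SimulationSpec-class].
#' @return data.frame with columns `molecule_id`, `target_id`, `score`,
#'   `reference_score`.
#' @examples
#' spec <- simulationSpec(nMolecules = 5, nTargets = 70, hitFraction = 0.05,
#'                        hubSpec = data.frame(molecule = 1, degree = 62),
#'                        seed = 1)
#' hits <- selectHits(generateDockingTable(spec))
#' sum(hits$molecule_id == "MOL001")  # exactly 62
#' @export
generateDockingTable <- function(spec) {
    stopifnot(is(spec, "SimulationSpec"))
    validObject(spec)
    set.seed(spec@seed)
    nm <- spec@nMolecules
    nt <- spec@nTargets
    mols <- .molIds(nm)
    tgts <- .tgtIds(nt)
    refScore <- stats::rnorm(nt, mean = 6.0, sd = 0.4)
    df <- data.frame(
        molecule_id = rep(mols, each = nt),
        target_id = rep(tgts, times = nm),
        reference_score = rep(refScore, times = nm),
        stringsAsFactors = FALSE)
    isHub <- rep(FALSE, nrow(df))
    hit <- stats::runif(nrow(df)) < spec@hitFraction
    hs <- spec@hubSpec
    for (i in seq_len(nrow(hs))) {
        rows <- which(df$molecule_id == mols[hs$molecule[i]])
        hit[rows] <- FALSE
        hit[rows[sample.int(nt, hs$degree[i])]] <- TRUE
        isHub[rows] <- TRUE
    }
    ceiling6 <- pmax(df$reference_score, 6.0)
    df$score <- ifelse(hit,
                       ceiling6 + 0.5 + stats::rexp(nrow(df), rate = 2),
                       ceiling6 - stats::rexp(nrow(df), rate = 0.8))
    df[, c("molecule_id", "target_id", "score", "reference_score")]
}

#' Generate synthetic annotation layers
#'
#' Draws the four annotation maps and the ZHENG labels of the world. Set
#' sizes are 1-truncated Poisson around the spec means, so every target has
#' at least one pathway and every pathway at least one disease (making the
#' eligibility criteria satisfiable); pathway memberships are sampled with
#' the first pathway's weight multiplied by `dominantPathwayBoost`, planting
#' a dominant pathway that the relevance-frequency score should rank first.
#' ZHENG labels are drawn for a `zhengFraction` share of diseases with the
#' inclusive (cold, hot, both) proportions of the spec. All targets are
#' labelled with organism `"human"` so planted hub degrees survive the
#' eligibility restriction exactly.
#'
#' @param spec a [SimulationSpec-class].
#' @return list with elements `targetMeta` (data.frame `target_id`,
#'   `organism`, list column `pathways`), `targetPathway`, `pathwayDisease`,
#'   `diseaseSymptom`, `diseaseCategory` ([AnnotationMap-class]) and `zheng`
#'   ([ZhengLabelSet-class]).
#' @export
generateAnnotations <- function(spec) {
    stopifnot(is(spec, "SimulationSpec"))
    validObject(spec)
    set.seed(spec@seed + 1L)
    tgts <- .tgtIds(spec@nTargets)
    pwys <- .pwyIds(spec@nPathways)
    diss <- .disIds(spec@nDiseases)
    syms <- .symIds(spec@nSymptoms)

    pwWeights <- rep(1, spec@nPathways)
    pwWeights[1L] <- spec@dominantPathwayBoost
    sizes <- .truncPoisSizes(spec@nTargets, spec@meanPathwaysPerTarget,
                             spec@nPathways)
    tpList <- lapply(sizes, function(k)
        sample(pwys, k, prob = pwWeights))
    names(tpList) <- tgts

    sizes <- .truncPoisSizes(spec@nPathways, spec@meanDiseasesPerPathway,
                             spec@nDiseases)
    pdList <- lapply(sizes, function(k) sample(diss, k))
    names(pdList) <- pwys

    sizes <- .truncPoisSizes(spec@nDiseases, spec@meanSymptomsPerDisease,
                             spec@nSymptoms)
    dsList <- lapply(sizes, function(k) sample(syms, k))
    names(dsList) <- diss

    nCat <- 1L + (stats::runif(spec@nDiseases) < 0.15)
    dcList <- lapply(nCat, function(k) sample(.categoryVocab, k))
    names(dcList) <- diss

    nLabelled <- round(spec@zhengFraction * spec@nDiseases)
    labelled <- sort(sample(diss, nLabelled))
    zp <- spec@zhengProportions
    pExcl <- c(cold = unname(zp["cold"] - zp["both"]),
               hot = unname(zp["hot"] - zp["both"]),
               both = unname(zp["both"]))
    if (sum(pExcl) <= 0) {
        labelled <- character(0)
    } else {
        pExcl <- pExcl / sum(pExcl)
    }
    draw <- if (length(labelled))
        sample(c("cold", "hot", "both"), length(labelled), replace = TRUE,
               prob = pExcl) else character()
    zlabels <- lapply(draw, function(d)
        switch(d, cold = "Cold", hot = "Hot", both = c("Cold", "Hot")))

    list(targetMeta = data.frame(target_id = tgts,
                                 organism = rep("human", spec@nTargets),
                                 pathways = I(tpList),
                                 stringsAsFactors = FALSE),
         targetPathway = annotationMap(tpList, "target_pathway"),
         pathwayDisease = annotationMap(pdList, "pathway_disease"),
         diseaseSymptom = annotationMap(dsList, "disease_symptom"),
         diseaseCategory = annotationMap(dcList, "disease_category"),
         zheng = zhengLabelSet(labelled, zlabels))
}

#' Generate a query signature for the synthetic world
#'
#' Samples `nUpTags` up- and `nDownTags` down-regulated tags (disjoint) from
#' the spec's tag universe.
#'
#' @param spec a [SimulationSpec-class].
#' @return a [TagSignature-class].
#' @export
generateSignature <- function(spec) {
    stopifnot(is(spec, "SimulationSpec"))
    set.seed(spec@seed + 2L)
    tags <- sprintf("TAG%04d", seq_len(spec@nTags))
    drawn <- sample(tags, spec@nUpTags + spec@nDownTags)
    tagSignature(up = drawn[seq_len(spec@nUpTags)],
                 down = drawn[seq_len(spec@nDownTags) + spec@nUpTags])
}

#' Generate a reference set of ranked expression instances
#'
#' Builds `nPerturbagens * nInstances` instances over the spec's tag
#' universe. Each instance ranks a latent standard-normal tag score,
#' decreasing (rank 1 = most up-regulated). The first perturbagen
#' (`"mimic"`) has the signature's up tags shifted up and down tags shifted
#' down by `mimicStrength` latent-score units; the second (`"reverser"`) has
#' the opposite shift; the remaining (`"null01"`, ...) perturbagens rank
#' pure noise. Cell-line labels cycle over `spec@cellLines`.
#'
#' @param spec a [SimulationSpec-class].
#' @param sig the query [TagSignature-class] to plant (tags must be in the
#'   spec universe), e.g. from [generateSignature()].
#' @return a [RankedProfileSet-class].
#' @export
generateProfiles <- function(spec, sig) {
    stopifnot(is(spec, "SimulationSpec"), is(sig, "TagSignature"))
    validObject(spec)
    set.seed(spec@seed + 3L)
    tags <- sprintf("TAG%04d", seq_len(spec@nTags))
    upIdx <- .resolveTags(upTags(sig), tags)
    downIdx <- .resolveTags(downTags(sig), tags)
    nP <- spec@nPerturbagens
    perts <- c("mimic", "reverser",
               sprintf("null%02d", seq_len(max(0L, nP - 2L))))
    nInst <- spec@nInstances
    m <- nP * nInst
    rk <- matrix(0L, nrow = spec@nTags, ncol = m, dimnames = list(tags, NULL))
    pert <- character(m)
    cell <- character(m)
    inst <- character(m)
    k <- 0L
    for (p in seq_len(nP)) {
        for (i in seq_len(nInst)) {
            k <- k + 1L
            z <- stats::rnorm(spec@nTags)
            if (p == 1L) {
                z[upIdx] <- z[upIdx] + spec@mimicStrength
                z[downIdx] <- z[downIdx] - spec@mimicStrength
            } else if (p == 2L) {
                z[upIdx] <- z[upIdx] - spec@mimicStrength
                z[downIdx] <- z[downIdx] + spec@mimicStrength
            }
            rk[, k] <- rank(-z, ties.method = "first")
            pert[k] <- perts[p]
            cell[k] <- spec@cellLines[(k - 1L) %% length(spec@cellLines) + 1L]
            inst[k] <- sprintf("INST%04d", k)
        }
    }
    colnames(rk) <- inst
    rankedProfileSet(rk, data.frame(instance = inst, perturbagen = pert,
                                    cell_line = cell,
                                    stringsAsFactors = FALSE))
}

#' Materialize a complete synthetic fixture directory
#'
#' Writes every pipeline input of the spec's world into `dir` in the exact
#' dialects the readers consume, plus a ready-to-run flat YAML config:
#' `docking.tsv`, `target_meta.tsv`, `pathway_disease.gmt`,
#' `disease_category.gmt`, `disease_symptom.gmt`, `zheng.gmt`,
#' `profiles.tsv`, `signature.tsv`, `config.yaml`.
#'
#' @param spec a [SimulationSpec-class].
#' @param dir directory to create/populate.
#' @param outDir pipeline output directory recorded in the config (default
#'   `file.path(dir, "out")`).
#' @param nPermutations,scoreThreshold,strataBounds config values copied
#'   into `config.yaml`.
#' @return (invisibly) a list with the generated objects and a `files`
#'   character vector of the written paths.
#' @export
simulateAll <- function(spec, dir, outDir = file.path(dir, "out"),
                        nPermutations = 100L, scoreThreshold = 6.0,
                        strataBounds = c(10L, 30L)) {
    stopifnot(is(spec, "SimulationSpec"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    docking <- generateDockingTable(spec)
    ann <- generateAnnotations(spec)
    sig <- generateSignature(spec)
    profiles <- generateProfiles(spec, sig)

    files <- c(
        docking = file.path(dir, "docking.tsv"),
        target_meta = file.path(dir, "target_meta.tsv"),
        pathway_disease = file.path(dir, "pathway_disease.gmt"),
        disease_category = file.path(dir, "disease_category.gmt"),
        disease_symptom = file.path(dir, "disease_symptom.gmt"),
        zheng = file.path(dir, "zheng.gmt"),
        profiles = file.path(dir, "profiles.tsv"),
        signature = file.path(dir, "signature.tsv"),
        config = file.path(dir, "config.yaml"))
    writeDockingTable(docking, files[["docking"]])
    writeTargetMeta(ann$targetMeta, files[["target_meta"]])
    writeAnnotationGmt(ann$pathwayDisease, files[["pathway_disease"]])
    writeAnnotationGmt(ann$diseaseCategory, files[["disease_category"]])
    writeAnnotationGmt(ann$diseaseSymptom, files[["disease_symptom"]])
    writeZhengLabels(ann$zheng, files[["zheng"]])
    writeProfiles(profiles, files[["profiles"]])
    writeSignature(sig, files[["signature"]])

    cfg <- c(
        paste0("score_threshold: ", scoreThreshold),
        paste0("strata_bounds: [", strataBounds[1L], ", ",
               strataBounds[2L], "]"),
        paste0("n_permutations: ", as.integer(nPermutations)),
        paste0("seed: ", spec@seed),
        "organism: human",
        paste0("docking: ", files[["docking"]]),
        paste0("target_meta: ", files[["target_meta"]]),
        paste0("pathway_disease: ", files[["pathway_disease"]]),
        paste0("disease_category: ", files[["disease_category"]]),
        paste0("disease_symptom: ", files[["disease_symptom"]]),
        paste0("zheng: ", files[["zheng"]]),
        paste0("profiles: ", files[["profiles"]]),
        paste0("signature: ", files[["signature"]]),
        paste0("out_dir: ", outDir))
    writeLines(cfg, files[["config"]])

    invisible(list(spec = spec, docking = docking, annotations = ann,
                   signature = sig, profiles = profiles, files = files))
}
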