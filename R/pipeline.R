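## End-to-end orchestration of the multiscale stages, in order: hit filter,
## drug-target network, target-pathway network, degree strata + pathway
## relevance scores, drug-pathway projection, pathway-disease network,
## phenotype tables, ZHENG partition, optional connectivity scoring.

.stageLine <- function(stage, ...) {
    kv <- c(...)
    paste(c(stage, paste0(names(kv), "=", unname(kv))), collapse = "\t")
}

#' Run the full multiscale pipeline
#'
#' Executes every stage on the configured inputs and writes all artifacts
#' into `config@outDir`: `hits.tsv`; `drug_target.sif` / `.graphml` and
#' `drug_target_attributes.tsv`; `target_pathway.sif` and
#' `target_pathway_attributes.tsv`; `pathway_scores.tsv` (stratum-wise
#' relevance-frequency scores); `drug_pathway.sif` and
#' `drug_pathway_attributes.tsv`; `pathway_disease.sif`;
#' `disease_categories.tsv`; `symptom_counts.tsv`; `zheng_partition.tsv` and
#' `zheng_summary.tsv`; `connectivity.tsv` (when profile and signature paths
#' are configured); and `pipeline.log` with one `stage<TAB>key=value` line
#' per logged count. A stage failure aborts with the stage name and cause.
#' Runs are deterministic: identical inputs and seed give byte-identical
#' tables.
#'
#' @param config a [PipelineConfig-class].
#' @param verbose emit log lines as messages too? Default `FALSE`.
#' @return (invisibly) a list bundle with the in-memory objects (`hits`,
#'   `drugTarget`, `targetPathway`, `strata`, `pathwayScores`,
#'   `drugPathway`, `pathwayDisease`, `categories`, `symptoms`, `zheng`,
#'   `connectivity` or `NULL`), the log lines and a named `files` vector.
#' @export
runPipeline <- function(config, verbose = FALSE) {
    stopifnot(is(config, "PipelineConfig"))
    validObject(config)
    logLines <- character()
    note <- function(stage, ...) {
        line <- .stageLine(stage, ...)
        logLines <<- c(logLines, line)
        if (verbose) message(line)
    }
    run <- function(stage, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", stage, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    out <- config@outDir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    files <- c()
    emit <- function(key, filename) {
        path <- file.path(out, filename)
        files[[key]] <<- path
        path
    }

    ## -- inputs
    docking <- run("read_inputs", readDockingTable(config@dockingPath))
    meta <- run("read_inputs", readTargetMeta(config@targetMetaPath))
    pd <- run("read_inputs",
              readAnnotationGmt(config@pathwayDiseasePath, "pathway_disease"))
    dc <- run("read_inputs",
              readAnnotationGmt(config@diseaseCategoryPath, "disease_category"))
    ds <- run("read_inputs",
              readAnnotationGmt(config@diseaseSymptomPath, "disease_symptom"))
    zheng <- run("read_inputs", readZhengLabels(config@zhengPath))
    note("read_inputs", c(docking_rows = nrow(docking),
                          targets = nrow(meta),
                          pathway_sets = length(pd)))

    ## -- hit filter
    hits <- run("hit_filter", {
        h <- selectHits(docking, config@scoreThreshold)
        kept <- eligibleTargets(meta, pd, config@organism)
        restrictHits(h, kept)
    })
    writeDockingTable(hits, emit("hits", "hits.tsv"))
    note("hit_filter", c(hits = nrow(hits),
                         molecules = length(unique(hits$molecule_id)),
                         targets = length(unique(hits$target_id))))

    ## -- drug-target network
    dt <- run("drug_target_network",
              buildBipartite(hits[, c("molecule_id", "target_id")]))
    writeNetwork(dt, emit("drug_target_sif", "drug_target.sif"),
                 "SIF", relation = "binds")
    writeNetwork(dt, emit("drug_target_graphml", "drug_target.graphml"),
                 "GraphML")
    writeNodeAttributes(dt, emit("drug_target_attributes",
                                 "drug_target_attributes.tsv"))
    note("drug_target_network", c(nodes = nodeCount(dt),
                                  edges = edgeCount(dt)))

    ## -- target-pathway network (targets with a drug hit only)
    tpMap <- annotationMap(
        structure(meta$pathways, names = meta$target_id), "target_pathway")
    tp <- run("target_pathway_network", {
        fwd <- forwardMap(tpMap)
        sets <- fwd[intersect(rightNodes(dt), names(fwd))]
        buildBipartite(data.frame(
            left = rep(names(sets), lengths(sets)),
            right = unlist(sets, use.names = FALSE),
            stringsAsFactors = FALSE))
    })
    writeNetwork(tp, emit("target_pathway_sif", "target_pathway.sif"),
                 "SIF", relation = "member_of")
    writeNodeAttributes(tp, emit("target_pathway_attributes",
                                 "target_pathway_attributes.tsv"))
    note("target_pathway_network", c(nodes = nodeCount(tp),
                                     edges = edgeCount(tp)))

    ## -- degree strata + pathway relevance scores
    scoresTab <- run("pathway_scores", {
        strata <- if (edgeCount(dt))
            stratifyByDegree(dt, "left", config@strataBounds)
        else structure(factor(character(),
                              levels = c("low", "middle", "high")),
                       names = character())
        rows <- lapply(levels(strata), function(s) {
            mols <- names(strata)[strata == s]
            sub <- hits[hits$molecule_id %in% mols, , drop = FALSE]
            if (!nrow(sub)) return(NULL)
            sc <- pathwayRelevanceScore(sub, tpMap)
            data.frame(stratum = s, pathway = names(sc),
                       score = as.numeric(sc), stringsAsFactors = FALSE)
        })
        list(strata = strata, table = do.call(rbind, c(rows,
            list(data.frame(stratum = character(), pathway = character(),
                            score = numeric(), stringsAsFactors = FALSE)))))
    })
    .writeTsv(scoresTab$table, emit("pathway_scores", "pathway_scores.tsv"))
    note("pathway_scores",
         c(strata = length(unique(scoresTab$table$stratum)),
           rows = nrow(scoresTab$table)))

    ## -- drug-pathway projection
    dp <- run("drug_pathway_network", {
        if (edgeCount(dt) && edgeCount(tp)) projectDrugPathway(dt, tp)
        else buildBipartite(data.frame(left = character(),
                                       right = character()))
    })
    writeNetwork(dp, emit("drug_pathway_sif", "drug_pathway.sif"),
                 "SIF", relation = "perturbs")
    writeNodeAttributes(dp, emit("drug_pathway_attributes",
                                 "drug_pathway_attributes.tsv"))
    note("drug_pathway_network", c(nodes = nodeCount(dp),
                                   edges = edgeCount(dp),
                                   total_weight = sum(edgeTable(dp)$weight)))

    ## -- pathway-disease network
    pdNet <- run("pathway_disease_network",
                 buildPathwayDisease(rightNodes(tp), pd))
    writeNetwork(pdNet, emit("pathway_disease_sif", "pathway_disease.sif"),
                 "SIF", relation = "associated_with")
    md <- bipartiteMeanDegrees(pdNet)
    note("pathway_disease_network",
         c(nodes = nodeCount(pdNet), edges = edgeCount(pdNet),
           mean_diseases_per_pathway = signif(md[["left"]], 4),
           mean_pathways_per_disease = signif(md[["right"]], 4)))

    ## -- phenotype tables
    diseases <- rightNodes(pdNet)
    categories <- run("phenotype", categoryProportions(dc, diseases))
    symptoms <- run("phenotype", symptomCounts(ds, diseases))
    .writeTsv(categories, emit("disease_categories",
                               "disease_categories.tsv"))
    .writeTsv(symptoms, emit("symptom_counts", "symptom_counts.tsv"))
    note("phenotype", c(diseases = length(diseases),
                        categories = nrow(categories),
                        symptoms = nrow(symptoms)))

    ## -- ZHENG partition
    zres <- run("zheng", classifyZheng(subsetZheng(zheng, diseases)))
    part <- data.frame(
        disease = c(zres$coldOnly, zres$hotOnly, zres$both),
        stratum = c(rep("cold_only", length(zres$coldOnly)),
                    rep("hot_only", length(zres$hotOnly)),
                    rep("both", length(zres$both))),
        stringsAsFactors = FALSE)
    part <- part[order(part$disease), , drop = FALSE]
    .writeTsv(part, emit("zheng_partition", "zheng_partition.tsv"))
    .writeTsv(data.frame(measure = names(zres$summary),
                         count = as.integer(zres$summary),
                         stringsAsFactors = FALSE),
              emit("zheng_summary", "zheng_summary.tsv"))
    note("zheng", zres$summary)

    ## -- optional connectivity stage
    connectivity <- NULL
    if (!is.na(config@profilesPath) && !is.na(config@signaturePath)) {
        connectivity <- run("connectivity", {
            profiles <- readProfiles(config@profilesPath)
            sig <- readSignature(config@signaturePath)
            meanScoresWithPvalues(sig, profiles, config@nPermutations,
                                  seed = config@seed)
        })
        .writeTsv(connectivity, emit("connectivity", "connectivity.tsv"))
        note("connectivity",
             c(combinations = nrow(connectivity),
               top = connectivity$perturbagen[1L]))
    }

    logPath <- emit("log", "pipeline.log")
    writeLines(logLines, logPath)
    invisible(list(hits = hits, drugTarget = dt, targetPathway = tp,
                   strata = scoresTab$strata,
                   pathwayScores = scoresTab$table, drugPathway = dp,
                   pathwayDisease = pdNet, categories = categories,
                   symptoms = symptoms, zheng = zres,
                   connectivity = connectivity, log = logLines,
                   files = unlist(files)))
}
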