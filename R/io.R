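## Readers and writers for every external dialect: docking TSV, target-meta
## TSV, GMT-style set maps, SIF and GraphML network exports, long-format
## profile/signature TSVs, and the flat-YAML pipeline config.

.readTsv <- function(path) {
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character")
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

.requireCols <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
        stop("format error in ", what, ": missing column(s) ",
             paste(miss, collapse = ", "))
}

.numericCol <- function(x, col, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
        stop("non-numeric or non-finite ", col, " in ", what,
             " at data line ", bad[1L])
    v
}

## ---- docking table ----------------------------------------------------------

#' Read and write docking-score tables
#'
#' Tab-separated, UTF-8, header row with columns `molecule_id`, `target_id`,
#' `score`, `reference_score`. Duplicate (molecule, target) rows are
#' preserved on read; [selectHits()] resolves them. A missing column raises
#' a format error naming the column; a non-numeric score raises a row-level
#' error with the data line number.
#'
#' @param path file path.
#' @param records data.frame with the four columns above.
#' @return `readDockingTable()` returns the parsed data.frame;
#'   `writeDockingTable()` returns the path invisibly.
#' @export
readDockingTable <- function(path) {
    df <- .readTsv(path)
    .requireCols(df, c("molecule_id", "target_id", "score",
                       "reference_score"), "docking table")
    df$score <- .numericCol(df$score, "score", "docking table")
    df$reference_score <- .numericCol(df$reference_score, "reference_score",
                                      "docking table")
    df[, c("molecule_id", "target_id", "score", "reference_score")]
}

#' @rdname readDockingTable
#' @export
writeDockingTable <- function(records, path) {
    .requireCols(records, c("molecule_id", "target_id", "score",
                            "reference_score"), "docking table")
    .writeTsv(records[, c("molecule_id", "target_id", "score",
                          "reference_score")], path)
}

## ---- target metadata --------------------------------------------------------

#' Read and write target annotation tables
#'
#' TSV with columns `target_id`, `organism`, `pathway_ids`; `pathway_ids`
#' holds a semicolon-joined (possibly empty) pathway list. In memory the
#' pathway lists live in a list column `pathways`.
#'
#' @param path file path.
#' @param targets data.frame with columns `target_id`, `organism` and list
#'   column `pathways`.
#' @return `readTargetMeta()` returns the data.frame with the `pathways`
#'   list column; `writeTargetMeta()` the path, invisibly.
#' @export
readTargetMeta <- function(path) {
    df <- .readTsv(path)
    .requireCols(df, c("target_id", "organism", "pathway_ids"),
                 "target metadata")
    pathways <- lapply(strsplit(df$pathway_ids, ";", fixed = TRUE),
                       function(v) v[nzchar(v)])
    data.frame(target_id = df$target_id, organism = df$organism,
               pathways = I(pathways), stringsAsFactors = FALSE)
}

#' @rdname readTargetMeta
#' @export
writeTargetMeta <- function(targets, path) {
    .requireCols(targets, c("target_id", "organism", "pathways"),
                 "target metadata")
    out <- data.frame(
        target_id = targets$target_id, organism = targets$organism,
        pathway_ids = vapply(targets$pathways, paste, character(1),
                             collapse = ";"),
        stringsAsFactors = FALSE)
    .writeTsv(out, path)
}

## ---- GMT-style set maps -----------------------------------------------------

#' Read and write GMT-style annotation maps
#'
#' One line per set: `set_id<TAB>description<TAB>member1<TAB>member2...`.
#' All four annotation maps (target-pathway, pathway-disease,
#' disease-symptom, disease-category) use this one dialect. Lines with no
#' members are dropped with a warning on read; descriptions are not
#' retained (`"na"` is written).
#'
#' @param path file path.
#' @param name map label for the returned object.
#' @param map an [AnnotationMap-class].
#' @return `readAnnotationGmt()` returns an [AnnotationMap-class];
#'   `writeAnnotationGmt()` the path, invisibly.
#' @export
readAnnotationGmt <- function(path, name = "") {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- vapply(fields, length, integer(1)) < 2L
    if (any(short))
        stop("format error in GMT file: line ", which(short)[1L],
             " has fewer than 2 fields")
    keys <- vapply(fields, `[[`, character(1), 1L)
    members <- lapply(fields, function(f) unique(f[-(1:2)]))
    empty <- lengths(members) == 0L
    if (any(empty)) {
        warning("dropping ", sum(empty), " GMT set(s) with no members")
        keys <- keys[!empty]
        members <- members[!empty]
    }
    names(members) <- keys
    annotationMap(members, name = name)
}

#' @rdname readAnnotationGmt
#' @export
writeAnnotationGmt <- function(map, path) {
    stopifnot(is(map, "AnnotationMap"))
    fwd <- forwardMap(map)
    lines <- vapply(names(fwd), function(k)
        paste(c(k, "na", fwd[[k]]), collapse = "\t"), character(1))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

#' Read and write ZHENG label sets
#'
#' GMT-style lines keyed by disease id with members drawn from
#' `{Cold, Hot}`. A disease line with an empty or invalid label set is
#' rejected at read time.
#'
#' @param path file path.
#' @param labels a [ZhengLabelSet-class].
#' @return `readZhengLabels()` returns a [ZhengLabelSet-class];
#'   `writeZhengLabels()` the path, invisibly.
#' @export
readZhengLabels <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    keys <- vapply(fields, `[[`, character(1), 1L)
    members <- lapply(fields, function(f) unique(f[-(1:2)]))
    bad <- which(lengths(members) == 0L |
                 !vapply(members, function(m) all(m %in% c("Cold", "Hot")),
                         logical(1)))
    if (length(bad))
        stop("invalid ZHENG label set at line ", bad[1L],
             " (must be a nonempty subset of {Cold, Hot})")
    zhengLabelSet(keys, members)
}

#' @rdname readZhengLabels
#' @export
writeZhengLabels <- function(labels, path) {
    stopifnot(is(labels, "ZhengLabelSet"))
    lines <- vapply(seq_along(labels@disease), function(i)
        paste(c(labels@disease[i], "na", labels@labels[[i]]),
              collapse = "\t"), character(1))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

## ---- networks ---------------------------------------------------------------

#' Write a network as SIF or GraphML
#'
#' SIF emits one `nodeA<TAB>relation<TAB>nodeB` line per edge (no lines for
#' an empty network; isolated nodes are not representable in SIF). GraphML
#' (via igraph) carries the `side` node attribute and `weight` edge
#' attribute, so [readNetworkGraphML()] round-trips the full data model.
#'
#' @param net a [BipartiteNetwork-class].
#' @param path file path.
#' @param format `"SIF"` or `"GraphML"` (case-insensitive).
#' @param relation relation token written in SIF lines.
#' @return the path, invisibly.
#' @export
writeNetwork <- function(net, path, format = c("SIF", "GraphML"),
                         relation = "interacts") {
    stopifnot(is(net, "BipartiteNetwork"))
    fmt <- tolower(as.character(format)[1L])
    if (!fmt %in% c("sif", "graphml"))
        stop("unknown network format: ", format[1L],
             " (use 'SIF' or 'GraphML')")
    if (fmt == "sif") {
        e <- edgeTable(net)
        lines <- if (nrow(e))
            paste(e$left, relation, e$right, sep = "\t") else character()
        writeLines(lines, path, useBytes = TRUE)
    } else {
        igraph::write_graph(asIgraph(net), path, format = "graphml")
    }
    invisible(path)
}

#' Read a SIF edge list
#'
#' @param path file path.
#' @return data.frame (`left`, `relation`, `right`); zero rows for an empty
#'   file. SIF carries no side or weight information, so only the edge set
#'   round-trips.
#' @export
readNetworkSIF <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(data.frame(left = character(), relation = character(),
                          right = character(), stringsAsFactors = FALSE))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(vapply(fields, length, integer(1)) < 3L))
        stop("format error in SIF file: line with fewer than 3 fields")
    data.frame(left = vapply(fields, `[[`, character(1), 1L),
               relation = vapply(fields, `[[`, character(1), 2L),
               right = vapply(fields, `[[`, character(1), 3L),
               stringsAsFactors = FALSE)
}

#' Read a GraphML network written by [writeNetwork()]
#'
#' @param path file path.
#' @return a [BipartiteNetwork-class] reconstructed from the `side` and
#'   `weight` attributes.
#' @export
readNetworkGraphML <- function(path) {
    g <- igraph::read_graph(path, format = "graphml")
    name <- igraph::V(g)$name
    side <- igraph::V(g)$side
    el <- igraph::as_edgelist(g, names = TRUE)
    w <- if ("weight" %in% igraph::edge_attr_names(g))
        as.integer(igraph::E(g)$weight) else rep(1L, nrow(el))
    if (nrow(el)) {
        ## orient every edge left -> right
        flip <- side[match(el[, 1L], name)] == "right"
        el[flip, ] <- el[flip, c(2L, 1L)]
    }
    buildBipartite(data.frame(left = el[, 1L], right = el[, 2L],
                              stringsAsFactors = FALSE),
                   weights = w,
                   leftNodes = name[side == "left"],
                   rightNodes = name[side == "right"])
}

#' Write a node attribute table
#'
#' TSV with columns `node`, `side`, `degree`, `betweenness`, ordered by
#' decreasing degree then node id.
#'
#' @param net a [BipartiteNetwork-class].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeNodeAttributes <- function(net, path) {
    .writeTsv(nodeAttributes(net), path)
}

## ---- profiles and signatures ------------------------------------------------

#' Read and write ranked profile sets
#'
#' Long-format TSV with columns `instance`, `perturbagen`, `cell_line`,
#' `tag`, `rank`; each instance must cover the whole tag universe exactly
#' once.
#'
#' @param path file path.
#' @param profiles a [RankedProfileSet-class].
#' @return `readProfiles()` returns a [RankedProfileSet-class];
#'   `writeProfiles()` the path, invisibly.
#' @export
readProfiles <- function(path) {
    df <- .readTsv(path)
    .requireCols(df, c("instance", "perturbagen", "cell_line", "tag",
                       "rank"), "profiles table")
    df$rank <- as.integer(.numericCol(df$rank, "rank", "profiles table"))
    tags <- sort(unique(df$tag))
    insts <- unique(df$instance)
    rk <- matrix(NA_integer_, nrow = length(tags), ncol = length(insts),
                 dimnames = list(tags, insts))
    rk[cbind(match(df$tag, tags), match(df$instance, insts))] <- df$rank
    if (anyNA(rk))
        stop("profiles table: every instance must rank every tag")
    info <- unique(df[, c("instance", "perturbagen", "cell_line")])
    info <- info[match(insts, info$instance), , drop = FALSE]
    rownames(info) <- NULL
    rankedProfileSet(rk, info)
}

#' @rdname readProfiles
#' @export
writeProfiles <- function(profiles, path) {
    stopifnot(is(profiles, "RankedProfileSet"))
    rk <- rankingMatrix(profiles)
    info <- instanceInfo(profiles)
    idx <- rep(seq_len(ncol(rk)), each = nrow(rk))
    out <- data.frame(instance = info$instance[idx],
                      perturbagen = info$perturbagen[idx],
                      cell_line = info$cell_line[idx],
                      tag = rep(rownames(rk), times = ncol(rk)),
                      rank = as.integer(rk[cbind(
                          rep(seq_len(nrow(rk)), times = ncol(rk)),
                          idx)]),
                      stringsAsFactors = FALSE)
    .writeTsv(out, path)
}

#' Read and write tag signatures
#'
#' Two-column TSV `tag`, `direction` with direction in `{up, down}`.
#'
#' @param path file path.
#' @param sig a [TagSignature-class].
#' @return `readSignature()` returns a [TagSignature-class];
#'   `writeSignature()` the path, invisibly.
#' @export
readSignature <- function(path) {
    df <- .readTsv(path)
    .requireCols(df, c("tag", "direction"), "signature table")
    bad <- !df$direction %in% c("up", "down")
    if (any(bad))
        stop("signature table: invalid direction at data line ",
             which(bad)[1L], " (must be 'up' or 'down')")
    tagSignature(up = df$tag[df$direction == "up"],
                 down = df$tag[df$direction == "down"])
}

#' @rdname readSignature
#' @export
writeSignature <- function(sig, path) {
    stopifnot(is(sig, "TagSignature"))
    out <- data.frame(tag = c(upTags(sig), downTags(sig)),
                      direction = c(rep("up", length(upTags(sig))),
                                    rep("down", length(downTags(sig)))),
                      stringsAsFactors = FALSE)
    .writeTsv(out, path)
}

## ---- configuration ----------------------------------------------------------

#' Read a flat YAML pipeline configuration
#'
#' Parses the flat `key: value` YAML subset (scalars and `[a, b]` flow
#' lists; `#` comments and blank lines ignored) and returns a validated
#' [PipelineConfig-class]. Recognized keys: `score_threshold`,
#' `strata_bounds`, `n_permutations`, `seed`, `organism`, `docking`,
#' `target_meta`, `pathway_disease`, `disease_category`, `disease_symptom`,
#' `zheng`, `profiles`, `signature`, `out_dir`. Relative paths are resolved
#' against the config file's directory.
#'
#' @param path config file path.
#' @return a [PipelineConfig-class].
#' @seealso [pipelineConfig()] for programmatic construction,
#'   [simulateAll()] which writes such a config.
#' @export
readPipelineConfig <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    m <- regmatches(lines, regexec("^([A-Za-z0-9_.]+):[[:space:]]*(.*)$",
                                   lines))
    bad <- vapply(m, length, integer(1)) != 3L
    if (any(bad))
        stop("config parse error at line: ", lines[which(bad)[1L]])
    kv <- structure(vapply(m, `[[`, character(1), 3L),
                    names = vapply(m, `[[`, character(1), 2L))
    kv <- trimws(gsub("^['\"]|['\"]$", "", kv))
    getKey <- function(key, default = NULL) {
        if (key %in% names(kv)) kv[[key]] else default
    }
    parseList <- function(x) {
        x <- gsub("^\\[|\\]$", "", x)
        as.numeric(trimws(strsplit(x, ",", fixed = TRUE)[[1L]]))
    }
    base <- dirname(normalizePath(path))
    resolve <- function(p) {
        if (is.null(p) || is.na(p) || !nzchar(p)) return(NA_character_)
        if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
    }
    bounds <- getKey("strata_bounds", "10, 30")
    pipelineConfig(
        dockingPath = resolve(getKey("docking")),
        targetMetaPath = resolve(getKey("target_meta")),
        pathwayDiseasePath = resolve(getKey("pathway_disease")),
        diseaseCategoryPath = resolve(getKey("disease_category")),
        diseaseSymptomPath = resolve(getKey("disease_symptom")),
        zhengPath = resolve(getKey("zheng")),
        profilesPath = resolve(getKey("profiles", NA_character_)),
        signaturePath = resolve(getKey("signature", NA_character_)),
        outDir = resolve(getKey("out_dir", "out")),
        scoreThreshold = as.numeric(getKey("score_threshold", "6.0")),
        strataBounds = as.integer(parseList(bounds)),
        nPermutations = as.integer(getKey("n_permutations", "100")),
        seed = as.integer(getKey("seed", "1")),
        organism = getKey("organism", "human"))
}
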