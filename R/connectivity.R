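## Rank-based Kolmogorov-Smirnov connectivity scoring of an up/down tag
## signature against a reference set of rank-ordered expression instances,
## with per-(perturbagen, cell line) mean scores and permutation p-values.

## Core KS statistic for one tag set against one ranking.
## V: sorted ascending ranks of the tags; t tags in a universe of n.
## a = max_j (j/t - V_j/n), b = max_j (V_j/n - (j-1)/t); return a if a > b
## else -b. Positive = tags concentrated at the top of the ranking.
.ksFromSorted <- function(V, n) {
    t <- length(V)
    j <- seq_len(t)
    a <- max(j / t - V / n)
    b <- max(V / n - (j - 1) / t)
    if (a > b) a else -b
}

## Column-wise KS for a t x m matrix of tag ranks (columns = instances).
.ksCols <- function(R, n) {
    t <- nrow(R)
    m <- ncol(R)
    if (t == 0L) return(numeric(m))
    V <- matrix(apply(R, 2L, sort), nrow = t)
    j <- seq_len(t)
    a <- apply(j / t - V / n, 2L, max)
    b <- apply(V / n - (j - 1) / t, 2L, max)
    ifelse(a > b, a, -b)
}

## Raw (unscaled) instance scores for up/down index vectors into the rank
## matrix rk. Sign rule: 0 when both one-sided statistics share a sign,
## otherwise ks_up - ks_down; one-sided signatures use the available side.
.rawScores <- function(rk, upIdx, downIdx) {
    n <- nrow(rk)
    m <- ncol(rk)
    ksU <- if (length(upIdx)) .ksCols(rk[upIdx, , drop = FALSE], n) else NULL
    ksD <- if (length(downIdx)) .ksCols(rk[downIdx, , drop = FALSE], n) else NULL
    if (is.null(ksD)) return(ksU)
    if (is.null(ksU)) return(-ksD)
    ifelse(ksU * ksD > 0, 0, ksU - ksD)
}

.resolveTags <- function(tags, universe) {
    idx <- match(tags, universe)
    if (anyNA(idx))
        stop("tag not in ranking universe: ", tags[which(is.na(idx))[1L]])
    idx
}

#' KS enrichment of a tag set in one ranking
#'
#' The one-sided building block of the connectivity score. With `V(j)` the
#' ascending ranks of the `t` tags in a universe of `n`, computes
#' `a = max_j (j/t - V(j)/n)` and `b = max_j (V(j)/n - (j-1)/t)` and returns
#' `a` if `a > b`, else `-b`. Values near +1 mean the tags sit at the top of
#' the ranking (most up-regulated), near -1 at the bottom.
#'
#' @param tags character vector of tags (all must be in the universe).
#' @param ranking named integer vector: a permutation of `1:n` named by the
#'   tag universe (rank 1 = most up-regulated), e.g. one column of a
#'   [RankedProfileSet-class] turned into a named vector.
#' @return a single number in `[-1, 1]`.
#' @examples
#' ranking <- structure(1:10, names = paste0("g", 1:10))
#' ksEnrichment(c("g1", "g2"), ranking)   # 0.8
#' ksEnrichment(c("g9", "g10"), ranking)  # -0.9
#' @export
ksEnrichment <- function(tags, ranking) {
    tags <- as.character(tags)
    if (!length(tags)) stop("empty tag set")
    if (is.null(names(ranking))) stop("ranking must be a named permutation")
    idx <- .resolveTags(tags, names(ranking))
    .ksFromSorted(sort(as.numeric(ranking[idx])), length(ranking))
}

#' Batch instance connectivity scores
#'
#' Scores every instance of a reference set against a query signature. The
#' raw score is 0 when the up- and down-tag KS statistics share a sign and
#' `ks_up - ks_down` otherwise; raw scores are then scaled by the batch
#' maximum absolute raw score into `[-1, 1]`, so in every batch with a
#' nonzero score at least one instance attains |score| = 1. Swapping the up
#' and down lists negates every raw score exactly.
#'
#' @param sig a [TagSignature-class]; tags must all be in the profile
#'   universe.
#' @param profiles a [RankedProfileSet-class] with at least one instance.
#' @return data.frame (`instance`, `perturbagen`, `cell_line`, `raw`,
#'   `scaled`), one row per instance in storage order.
#' @export
instanceScores <- function(sig, profiles) {
    stopifnot(is(sig, "TagSignature"), is(profiles, "RankedProfileSet"))
    rk <- rankingMatrix(profiles)
    if (!ncol(rk)) stop("empty batch: profile set has no instances")
    universe <- tagUniverse(profiles)
    upIdx <- .resolveTags(upTags(sig), universe)
    downIdx <- .resolveTags(downTags(sig), universe)
    raw <- .rawScores(rk, upIdx, downIdx)
    M <- max(abs(raw))
    scaled <- if (M > 0) raw / M else raw
    info <- instanceInfo(profiles)
    data.frame(instance = info$instance, perturbagen = info$perturbagen,
               cell_line = info$cell_line, raw = raw, scaled = scaled,
               stringsAsFactors = FALSE)
}

#' Mean connectivity scores with permutation p-values
#'
#' Aggregates scaled instance scores to one mean score per (perturbagen,
#' cell line) combination and attaches a permutation p-value: the signature's
#' tags are redrawn uniformly without replacement from the universe (sizes
#' preserved, up/down kept disjoint) `nPerm` times, and
#' `p = (1 + #\{permuted |mean| >= observed |mean|\}) / (1 + nPerm)`
#' (add-one estimator, so p is never 0). The comparison uses raw means,
#' which is equivalent to scaling every permutation by the observed batch
#' maximum. A high positive mean score marks a perturbagen that induces
#' expression changes similar to the query; a strongly negative one, a
#' reverser.
#'
#' @param sig a [TagSignature-class].
#' @param profiles a [RankedProfileSet-class].
#' @param nPerm number of permutations (>= 1).
#' @param seed optional integer; when supplied the permutation stream is
#'   seeded and the caller's RNG state is restored on exit.
#' @return data.frame (`perturbagen`, `cell_line`, `meanScore`, `pValue`,
#'   `nInstances`) sorted by decreasing mean score.
#' @export
meanScoresWithPvalues <- function(sig, profiles, nPerm = 1000L, seed = NULL) {
    stopifnot(is(sig, "TagSignature"), is(profiles, "RankedProfileSet"))
    nPerm <- as.integer(nPerm)
    if (is.na(nPerm) || nPerm < 1L) stop("nPerm must be >= 1")
    rk <- rankingMatrix(profiles)
    if (!ncol(rk)) stop("empty batch: profile set has no instances")
    universe <- tagUniverse(profiles)
    upIdx <- .resolveTags(upTags(sig), universe)
    downIdx <- .resolveTags(downTags(sig), universe)
    info <- instanceInfo(profiles)
    combo <- factor(paste(info$perturbagen, info$cell_line, sep = "\r"))
    counts <- as.integer(table(combo))

    raw <- .rawScores(rk, upIdx, downIdx)
    M <- max(abs(raw))
    scaled <- if (M > 0) raw / M else raw
    meanScaled <- as.numeric(rowsum(scaled, combo) / counts)
    obsAbs <- abs(as.numeric(rowsum(raw, combo) / counts))

    if (!is.null(seed)) {
        if (exists(".Random.seed", envir = globalenv())) {
            old <- get(".Random.seed", envir = globalenv())
            on.exit(assign(".Random.seed", old, envir = globalenv()))
        }
        set.seed(as.integer(seed))
    }
    tU <- length(upIdx)
    tD <- length(downIdx)
    geq <- integer(nlevels(combo))
    for (b in seq_len(nPerm)) {
        drawn <- sample.int(length(universe), tU + tD)
        praw <- .rawScores(rk, drawn[seq_len(tU)],
                           drawn[seq_len(tD) + tU])
        pAbs <- abs(as.numeric(rowsum(praw, combo) / counts))
        geq <- geq + (pAbs >= obsAbs)
    }
    pval <- (1 + geq) / (1 + nPerm)

    parts <- strsplit(levels(combo), "\r", fixed = TRUE)
    out <- data.frame(
        perturbagen = vapply(parts, `[[`, character(1), 1L),
        cell_line = vapply(parts, `[[`, character(1), 2L),
        meanScore = meanScaled, pValue = pval, nInstances = counts,
        stringsAsFactors = FALSE)
    out <- out[order(-out$meanScore, out$perturbagen, out$cell_line), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}
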