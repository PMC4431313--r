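## Phenotype layer: disease-category proportions, symptom frequencies, and
## the Cold/Hot ZHENG inclusion-exclusion partition.

#' Disease-category proportions
#'
#' Counts (disease, category) assignments over a disease set. A disease with
#' several categories ("Metabolic disease; Endocrine disease" style records)
#' contributes one assignment per category; percentages are shares of all
#' assignments, reported to two decimals, and sum to 100 up to rounding.
#'
#' @param diseaseCategories an [AnnotationMap-class] from disease ids to
#'   category labels.
#' @param diseases character vector of disease ids to summarize.
#' @return data.frame (`category`, `count`, `percentage`) sorted by
#'   decreasing count then category.
#' @export
categoryProportions <- function(diseaseCategories, diseases) {
    stopifnot(is(diseaseCategories, "AnnotationMap"))
    fwd <- forwardMap(diseaseCategories)
    sets <- fwd[intersect(unique(as.character(diseases)), names(fwd))]
    empty <- data.frame(category = character(), count = integer(),
                        percentage = numeric(), stringsAsFactors = FALSE)
    if (!length(sets)) return(empty)
    counts <- table(unlist(sets, use.names = FALSE))
    out <- data.frame(category = names(counts), count = as.integer(counts),
                      percentage = round(100 * as.integer(counts) /
                                             sum(counts), 2L),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$category), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Symptom frequencies across a disease set
#'
#' For each symptom, the number of distinct diseases in the set exhibiting
#' it (a symptom repeated within one disease record counts once).
#'
#' @param diseaseSymptoms an [AnnotationMap-class] from disease ids to
#'   symptom labels.
#' @param diseases character vector of disease ids.
#' @return data.frame (`symptom`, `n_diseases`) sorted by decreasing count
#'   then symptom.
#' @export
symptomCounts <- function(diseaseSymptoms, diseases) {
    stopifnot(is(diseaseSymptoms, "AnnotationMap"))
    fwd <- forwardMap(diseaseSymptoms)
    sets <- fwd[intersect(unique(as.character(diseases)), names(fwd))]
    empty <- data.frame(symptom = character(), n_diseases = integer(),
                        stringsAsFactors = FALSE)
    if (!length(sets)) return(empty)
    counts <- table(unlist(sets, use.names = FALSE))  # sets are deduplicated
    out <- data.frame(symptom = names(counts), n_diseases = as.integer(counts),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$n_diseases, out$symptom), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Cold/Hot ZHENG partition
#'
#' Partitions labelled diseases into `coldOnly`, `hotOnly` and `both` by
#' inclusion-exclusion. Summary counts are inclusive: `cold` and `hot` each
#' count the dual-labelled diseases too, so
#' `total = cold + hot - both` -- the reading under which the published
#' 28 Cold + 94 Hot - 5 dual = 117 labelled diseases is consistent.
#'
#' @param labels a [ZhengLabelSet-class].
#' @return list with sorted character vectors `coldOnly`, `hotOnly`, `both`
#'   and an integer `summary` `c(cold, hot, both, total)`.
#' @examples
#' z <- zhengLabelSet(c("a", "b", "c"), list("Cold", c("Cold", "Hot"), "Hot"))
#' classifyZheng(z)$summary  # cold 2, hot 2, both 1, total 3
#' @export
classifyZheng <- function(labels) {
    stopifnot(is(labels, "ZhengLabelSet"))
    hasCold <- vapply(labels@labels, function(l) "Cold" %in% l, logical(1))
    hasHot <- vapply(labels@labels, function(l) "Hot" %in% l, logical(1))
    d <- labels@disease
    both <- sort(d[hasCold & hasHot])
    coldOnly <- sort(d[hasCold & !hasHot])
    hotOnly <- sort(d[hasHot & !hasCold])
    list(coldOnly = coldOnly, hotOnly = hotOnly, both = both,
         summary = c(cold = length(coldOnly) + length(both),
                     hot = length(hotOnly) + length(both),
                     both = length(both),
                     total = length(d)))
}
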