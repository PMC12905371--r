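#' Accessors for leakSplit classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x a leakSplit object.
#' @param ... unused.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("entityIds", function(x, ...) standardGeneric("entityIds"))
#' @rdname accessors
#' @export
setGeneric("similarityValues", function(x, ...) standardGeneric("similarityValues"))
#' @rdname accessors
#' @export
setGeneric("entityWeights", function(x, ...) standardGeneric("entityWeights"))
#' @rdname accessors
#' @export
setGeneric("metricName", function(x, ...) standardGeneric("metricName"))
#' @rdname accessors
#' @export
setGeneric("clusters", function(x, ...) standardGeneric("clusters"))
#' @rdname accessors
#' @export
setGeneric("clusterWeights", function(x, ...) standardGeneric("clusterWeights"))
#' @rdname accessors
#' @export
setGeneric("clusterSimilarity", function(x, ...) standardGeneric("clusterSimilarity"))
#' @rdname accessors
#' @export
setGeneric("splitNames", function(x, ...) standardGeneric("splitNames"))
#' @rdname accessors
#' @export
setGeneric("splitFractions", function(x, ...) standardGeneric("splitFractions"))
#' @rdname accessors
#' @export
setGeneric("assignment", function(x, ...) standardGeneric("assignment"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x, ...) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("scaledTotal", function(x, ...) standardGeneric("scaledTotal"))
#' @rdname accessors
#' @export
setGeneric("maxSingleLeak", function(x, ...) standardGeneric("maxSingleLeak"))
#' @rdname accessors
#' @export
setGeneric("perPairLeak", function(x, ...) standardGeneric("perPairLeak"))
#' @rdname accessors
#' @export
setGeneric("assignedFraction", function(x, ...) standardGeneric("assignedFraction"))

#' @rdname accessors
setMethod("entityIds", "SimilarityMatrix", function(x, ...) x@ids)
#' @rdname accessors
setMethod("similarityValues", "SimilarityMatrix", function(x, ...) x@values)
#' @rdname accessors
setMethod("entityWeights", "SimilarityMatrix", function(x, ...)
  setNames(x@weights, x@ids))
#' @rdname accessors
setMethod("metricName", "SimilarityMatrix", function(x, ...) x@metricName)

#' @rdname accessors
setMethod("clusters", "ClusterSet", function(x, ...) x@clusters)
#' @rdname accessors
setMethod("clusterWeights", "ClusterSet", function(x, ...) x@clusterWeights)
#' @rdname accessors
setMethod("clusterSimilarity", "ClusterSet", function(x, ...) x@clusterSimilarity)
#' @rdname accessors
setMethod("entityIds", "ClusterSet", function(x, ...)
  unlist(x@clusters, use.names = FALSE))

#' @rdname accessors
setMethod("splitNames", "SplitSpec", function(x, ...) x@splitNames)
#' @rdname accessors
setMethod("splitFractions", "SplitSpec", function(x, ...)
  setNames(x@fractions, x@splitNames))

#' @rdname accessors
setMethod("splitNames", "SplitAssignment", function(x, ...) x@splitNames)
#' @rdname accessors
setMethod("assignment", "SplitAssignment", function(x, ...) x@assignment)
#' @rdname accessors
setMethod("provenance", "SplitAssignment", function(x, ...) x@provenance)
#' @rdname accessors
setMethod("entityIds", "SplitAssignment", function(x, ...) names(x@assignment))

#' @rdname accessors
setMethod("scaledTotal", "LeakageReport", function(x, ...) x@scaledTotal)
#' @rdname accessors
setMethod("maxSingleLeak", "LeakageReport", function(x, ...) x@maxSingleLeak)
#' @rdname accessors
setMethod("perPairLeak", "LeakageReport", function(x, ...) x@perPair)
#' @rdname accessors
setMethod("assignedFraction", "LeakageReport", function(x, ...) x@assignedFraction)

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix: %d entities, metric '%s'\n",
              length(object@ids), object@metricName))
  if (length(object@ids) > 1) {
    off <- object@values[upper.tri(object@values)]
    cat(sprintf("  off-diagonal similarity: min %.3f, mean %.3f, max %.3f\n",
                min(off), mean(off), max(off)))
  }
  if (!all(object@weights == 1))
    cat(sprintf("  weighted (total weight %.3g)\n", sum(object@weights)))
})

setMethod("show", "ClusterSet", function(object) {
  sizes <- lengths(object@clusters)
  cat(sprintf("ClusterSet: %d clusters over %d entities (threshold %.3g, %s linkage aggregation)\n",
              length(sizes), sum(sizes), object@threshold, object@aggregation))
  cat(sprintf("  cluster sizes: %s%s\n",
              paste(utils::head(sizes, 10), collapse = ", "),
              if (length(sizes) > 10) ", ..." else ""))
})

setMethod("show", "SplitSpec", function(object) {
  cat(sprintf("SplitSpec: %s (epsilon %.3g, objective '%s'%s, seed %d)\n",
              paste(sprintf("%s=%.3g", object@splitNames, object@fractions),
                    collapse = ", "),
              object@epsilon, object@objective,
              if (nzchar(object@stratifyOn))
                sprintf(", stratified on '%s'", object@stratifyOn) else "",
              object@seed))
})

setMethod("show", "SplitAssignment", function(object) {
  tab <- table(factor(object@assignment,
                      levels = c(object@splitNames, UNASSIGNED)))
  cat(sprintf("SplitAssignment: %d entities -> %s\n",
              length(object@assignment),
              paste(sprintf("%s:%d", names(tab), tab), collapse = ", ")))
  if (length(object@provenance))
    cat("  provenance:",
        paste(sprintf("%s=%s", names(object@provenance),
                      vapply(object@provenance, format, "")), collapse = ", "),
        "\n")
})

setMethod("show", "LeakageReport", function(object) {
  cat(sprintf("LeakageReport: scaled total leakage %.4f, max single leak %.4f\n",
              object@scaledTotal, object@maxSingleLeak))
  cat(sprintf("  assigned fraction: %.3f\n", object@assignedFraction))
  if (nrow(object@perPair)) {
    cat("  leaked mass per split pair:\n")
    for (i in seq_len(nrow(object@perPair)))
      cat(sprintf("    %s ~ %s: %.4g\n", object@perPair$split_a[i],
                  object@perPair$split_b[i], object@perPair$leaked_mass[i]))
  }
})
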