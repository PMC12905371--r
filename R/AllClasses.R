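#' @import methods
#' @importFrom stats setNames runif
#' @importFrom utils read.delim write.table head
NULL

#' SimilarityMatrix: validated pairwise entity similarity
#'
#' Symmetric entity-by-entity similarity with values in \[0, 1\], a unit
#' diagonal, and optional per-entity weights. This is the object every
#' downstream step (clustering, leakage scoring, solving) consumes.
#'
#' @slot ids ordered character vector of entity ids (matrix dimension order).
#' @slot values square numeric matrix of similarities in \[0, 1\].
#' @slot metricName character scalar naming the metric that produced the
#'   matrix (e.g. `"nw-identity"`, `"ecfp4-tanimoto"`, `"precomputed"`).
#' @slot weights non-negative per-entity weights; uniform weights cancel in
#'   the scaled leakage score. For interaction datasets reduced to one
#'   dimension, the weight is the number of interactions the entity
#'   participates in.
#'
#' @examples
#' m <- SimilarityMatrix(ids = c("a", "b"),
#'                       values = matrix(c(1, .3, .3, 1), 2),
#'                       metricName = "precomputed")
#' similarityValues(m)
#' @export
setClass("SimilarityMatrix",
  representation(ids = "character", values = "matrix",
                 metricName = "character", weights = "numeric"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  n <- length(object@ids)
  msg <- character()
  if (any(!nzchar(object@ids))) msg <- c(msg, "ids must be non-empty strings")
  if (anyDuplicated(object@ids))
    msg <- c(msg, sprintf("duplicate ids: %s",
                          paste(unique(object@ids[duplicated(object@ids)]), collapse = ", ")))
  if (nrow(v) != n || ncol(v) != n)
    msg <- c(msg, sprintf("values must be %d x %d to match ids", n, n))
  else {
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      msg <- c(msg, "similarities must be finite and in [0, 1]")
    else {
      if (max(abs(v - t(v))) > 1e-9) msg <- c(msg, "matrix not symmetric within 1e-9")
      if (n > 0 && max(abs(diag(v) - 1)) > 1e-9) msg <- c(msg, "diagonal must equal 1.0")
    }
  }
  if (length(object@weights) != n) msg <- c(msg, "weights length must match ids")
  else if (any(!is.finite(object@weights)) || any(object@weights < 0))
    msg <- c(msg, "weights must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname SimilarityMatrix-class
#' @param ids,values,metricName,weights see slots.
#' @export
SimilarityMatrix <- function(ids, values, metricName = "precomputed",
                             weights = rep(1, length(ids))) {
  dimnames(values) <- list(ids, ids)
  new("SimilarityMatrix", ids = as.character(ids), values = values,
      metricName = metricName, weights = as.numeric(weights))
}

#' ClusterSet: similarity clusters acting as atomic split units
#'
#' A partition of the entities of a [SimilarityMatrix] into clusters. The
#' solver assigns whole clusters to splits so that no pair of entities more
#' similar than the clustering threshold ever straddles a split boundary.
#' Clusters are ordered by decreasing weight (ties by smallest member id)
#' so solver runs are reproducible.
#'
#' @slot clusters list of character vectors of entity ids (disjoint, covering).
#' @slot clusterWeights per-cluster sums of member weights.
#' @slot clusterSimilarity square inter-cluster similarity matrix in \[0, 1\]
#'   with unit diagonal; the off-diagonal aggregation (max by default,
#'   pessimistic leak bound) is recorded in `aggregation`.
#' @slot aggregation `"max"` or `"mean"`.
#' @slot threshold the clustering threshold used.
#' @export
setClass("ClusterSet",
  representation(clusters = "list", clusterWeights = "numeric",
                 clusterSimilarity = "matrix", aggregation = "character",
                 threshold = "numeric"))

setValidity("ClusterSet", function(object) {
  msg <- character()
  ids <- unlist(object@clusters, use.names = FALSE)
  if (anyDuplicated(ids)) msg <- c(msg, "clusters must be disjoint")
  k <- length(object@clusters)
  if (length(object@clusterWeights) != k)
    msg <- c(msg, "clusterWeights length must equal number of clusters")
  cs <- object@clusterSimilarity
  if (nrow(cs) != k || ncol(cs) != k)
    msg <- c(msg, "clusterSimilarity must be k x k")
  else if (k > 0) {
    if (max(abs(cs - t(cs))) > 1e-9) msg <- c(msg, "clusterSimilarity not symmetric")
    if (max(abs(diag(cs) - 1)) > 1e-9) msg <- c(msg, "clusterSimilarity diagonal must be 1")
  }
  if (length(msg)) msg else TRUE
})

#' SplitSpec: named splits, target fractions and solver settings
#'
#' @slot splitNames ordered character vector (>= 2 names).
#' @slot fractions positive target weight fractions summing to 1.
#' @slot epsilon allowed absolute deviation of each split's realized weight
#'   fraction from its target; in (0, 0.5).
#' @slot objective `"total"` (minimize total leaked similarity mass) or
#'   `"max"` (minimize the largest single inter-split similarity).
#' @slot stratifyOn optional label column name ("" = none).
#' @slot stratifyTolerance allowed per-split deviation of each label's share
#'   from its global share.
#' @slot seed integer seed driving all solver randomness.
#' @export
setClass("SplitSpec",
  representation(splitNames = "character", fractions = "numeric",
                 epsilon = "numeric", objective = "character",
                 stratifyOn = "character", stratifyTolerance = "numeric",
                 seed = "integer"))

setValidity("SplitSpec", function(object) {
  msg <- character()
  n <- length(object@splitNames)
  if (n < 2) msg <- c(msg, "need at least 2 splits")
  if (anyDuplicated(object@splitNames)) msg <- c(msg, "split names must be unique")
  if (length(object@fractions) != n) msg <- c(msg, "one fraction per split required")
  else {
    if (any(object@fractions <= 0)) msg <- c(msg, "fractions must be positive")
    if (abs(sum(object@fractions) - 1) > 1e-9) msg <- c(msg, "fractions must sum to 1")
  }
  if (object@epsilon <= 0 || object@epsilon >= 0.5)
    msg <- c(msg, "epsilon must lie in (0, 0.5)")
  if (!object@objective %in% c("total", "max"))
    msg <- c(msg, "objective must be 'total' or 'max'")
  if (length(msg)) msg else TRUE
})

#' @rdname SplitSpec-class
#' @param splitNames,fractions,epsilon,objective,stratifyOn,stratifyTolerance,seed
#'   see slots.
#' @examples
#' splitSpec(c(train = 0.8, val = 0.1, test = 0.1))
#' @export
splitSpec <- function(fractions, splitNames = names(fractions),
                      epsilon = 0.05, objective = c("total", "max"),
                      stratifyOn = "", stratifyTolerance = 0.1,
                      seed = 1L) {
  objective <- match.arg(objective)
  if (is.null(splitNames))
    splitNames <- paste0("split", seq_along(fractions))
  new("SplitSpec", splitNames = as.character(splitNames),
      fractions = as.numeric(fractions), epsilon = as.numeric(epsilon),
      objective = objective, stratifyOn = as.character(stratifyOn),
      stratifyTolerance = as.numeric(stratifyTolerance),
      seed = as.integer(seed))
}

#' SplitAssignment: the split each entity belongs to
#'
#' Maps every entity id to a split name or to `"UNASSIGNED"`. Unassigned
#' entities are excluded from leakage scoring (numerator and denominator);
#' the scored fraction is surfaced in the [LeakageReport].
#'
#' @slot assignment named character vector: entity id -> split name.
#' @slot splitNames ordered character vector of legal split names.
#' @slot provenance named list of free-text metadata (tool, seed, objective).
#' @export
setClass("SplitAssignment",
  representation(assignment = "character", splitNames = "character",
                 provenance = "list"))

#' @rdname SplitAssignment-class
#' @param assignment,splitNames,provenance see slots.
#' @export
SplitAssignment <- function(assignment, splitNames, provenance = list()) {
  new("SplitAssignment", assignment = assignment,
      splitNames = as.character(splitNames), provenance = provenance)
}

UNASSIGNED <- "UNASSIGNED"

setValidity("SplitAssignment", function(object) {
  msg <- character()
  if (is.null(names(object@assignment)) || any(!nzchar(names(object@assignment))))
    msg <- c(msg, "assignment must be a named character vector of entity ids")
  bad <- setdiff(unique(object@assignment), c(object@splitNames, UNASSIGNED))
  if (length(bad))
    msg <- c(msg, sprintf("assigned names not in splitNames: %s",
                          paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' LeakageReport: scaled leakage of a split assignment
#'
#' @slot scaledTotal cross-split weighted similarity mass divided by total
#'   weighted similarity mass over assigned entities; in \[0, 1\].
#' @slot maxSingleLeak largest single similarity between entities of two
#'   different splits (0 when no cross pair exists).
#' @slot perPair data.frame with columns `split_a`, `split_b`, `leaked_mass`
#'   (raw weighted similarity mass per unordered split pair).
#' @slot assignedFraction fraction of scored-dataset entities that carried a
#'   split label.
#' @export
setClass("LeakageReport",
  representation(scaledTotal = "numeric", maxSingleLeak = "numeric",
                 perPair = "data.frame", assignedFraction = "numeric"))

setValidity("LeakageReport", function(object) {
  msg <- character()
  if (object@scaledTotal < -1e-12 || object@scaledTotal > 1 + 1e-12)
    msg <- c(msg, "scaledTotal must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
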