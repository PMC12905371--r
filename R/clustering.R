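#' Single-linkage similarity clustering at a threshold
#'
#' Builds the graph with an edge between two entities whenever their
#' similarity is at or above `threshold`, and returns its connected
#' components as a [ClusterSet-class]. Single linkage guarantees that no
#' pair of entities in *different* clusters reaches the threshold -- the
#' leak being controlled -- which is why it is the default; `"complete"`
#' linkage (hclust-based) is available as an alternative.
#'
#' Inter-cluster similarity is aggregated pessimistically by the maximum
#' over cross pairs (a bound on the single largest leak); `aggregation =
#' "mean"` is available for the total-leak objective.
#'
#' Clusters are ordered by decreasing weight, ties broken by the smallest
#' member id, so downstream solver runs are reproducible.
#'
#' @param matrix a [SimilarityMatrix-class].
#' @param threshold similarity threshold in \[0, 1\]. At 0 every pair is
#'   connected (one cluster); similarities of exactly 0 still count as
#'   edges at threshold 0.
#' @param aggregation `"max"` (default) or `"mean"` inter-cluster
#'   similarity aggregation.
#' @param linkage `"single"` (default, connected components) or
#'   `"complete"`.
#' @return a [ClusterSet-class].
#' @examples
#' m <- SimilarityMatrix(letters[1:3],
#'   matrix(c(1, .9, 0, .9, 1, .9, 0, .9, 1), 3), "precomputed")
#' length(clusters(clusterByThreshold(m, 0.8)))  # 1: a-b-c chain
#' @export
clusterByThreshold <- function(matrix, threshold,
                               aggregation = c("max", "mean"),
                               linkage = c("single", "complete")) {
  aggregation <- match.arg(aggregation)
  linkage <- match.arg(linkage)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1)
    invalidInput("threshold must lie in [0, 1]")
  methods::validObject(matrix)
  ids <- entityIds(matrix)
  v <- similarityValues(matrix)
  n <- length(ids)

  if (linkage == "single") {
    adj <- v >= threshold
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    member <- igraph::components(g)$membership
  } else {
    d <- stats::as.dist(1 - v)
    hc <- stats::hclust(d, method = "complete")
    member <- stats::cutree(hc, h = 1 - threshold)
  }
  clusterList <- split(ids, member)
  names(clusterList) <- NULL
  .makeClusterSet(clusterList, matrix, aggregation, threshold)
}

.makeClusterSet <- function(clusterList, matrix, aggregation, threshold) {
  ids <- entityIds(matrix)
  v <- similarityValues(matrix)
  w <- entityWeights(matrix)
  k <- length(clusterList)
  cw <- vapply(clusterList, function(cl) sum(w[cl]), 0)
  ord <- order(-cw, vapply(clusterList, function(cl) min(cl), ""))
  clusterList <- clusterList[ord]
  cw <- cw[ord]
  cs <- diag(1, k)
  if (k > 1) {
    aggFun <- if (aggregation == "max") max else mean
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      cs[i, j] <- cs[j, i] <-
        aggFun(v[clusterList[[i]], clusterList[[j]], drop = FALSE])
  }
  names(cw) <- paste0("cluster", seq_len(k))
  new("ClusterSet", clusters = clusterList, clusterWeights = unname(cw),
      clusterSimilarity = cs, aggregation = aggregation,
      threshold = as.numeric(threshold))
}

#' Recompute cluster weights from entity weights
#'
#' Resets each cluster's weight to the sum of its members' weights (total
#' weight is conserved). Used when entity weights change after clustering,
#' e.g. when proteins are re-weighted by the number of interactions they
#' participate in.
#'
#' @param clusterSet a [ClusterSet-class].
#' @param entities an [entityTable()] whose ids exactly cover the clusters.
#' @return the updated [ClusterSet-class].
#' @export
aggregateWeights <- function(clusterSet, entities) {
  entities <- checkEntityTable(entities)
  ids <- entityIds(clusterSet)
  miss <- setdiff(entities$id, ids)
  if (length(miss))
    consistencyError(sprintf("entities missing from clusters: %s",
                             paste(miss, collapse = ", ")))
  miss2 <- setdiff(ids, entities$id)
  if (length(miss2))
    consistencyError(sprintf("clustered ids missing from entities: %s",
                             paste(miss2, collapse = ", ")))
  w <- setNames(entities$weight, entities$id)
  cw <- vapply(clusters(clusterSet), function(cl) sum(w[cl]), 0)
  methods::initialize(clusterSet, clusterWeights = unname(cw))
}

#' Export a clustering as an entity-to-cluster table
#'
#' @param clusterSet a [ClusterSet-class].
#' @return data.frame with columns `entity_id`, `cluster_id`.
#' @export
clustersAsTable <- function(clusterSet) {
  cl <- clusters(clusterSet)
  data.frame(
    entity_id = unlist(cl, use.names = FALSE),
    cluster_id = rep(paste0("cluster", seq_along(cl)), lengths(cl)),
    stringsAsFactors = FALSE)
}
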