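#' Scaled leakage score of a split assignment
#'
#' The comparison statistic for split quality: the fraction of the
#' weighted pairwise similarity mass that crosses a split boundary,
#' \deqn{L = \frac{\sum_{i<j,\ \pi(i)\ne\pi(j)} w_i w_j s_{ij}}
#'              {\sum_{i<j} w_i w_j s_{ij}},}
#' over the assigned entities. It is scale-free in \[0, 1\]: 0 means no
#' similarity mass is shared between splits, 1 means all of it is. A
#' random 80/10/10 split of a homogeneous dataset scores about
#' 1 - (0.8^2 + 0.1^2 + 0.1^2) = 0.34 for large n. Self pairs (the
#' diagonal) never count, and unordered pairs are used (for a symmetric
#' similarity the ratio is identical either way). When the total mass is 0
#' the score is 0 by convention.
#'
#' The formula lives only in this function so an alternative normalization
#' or weighting can be swapped in at a single point.
#'
#' Entities labelled `"UNASSIGNED"` are excluded from numerator and
#' denominator; the fraction that was assigned is reported so information
#' discarded by a splitter stays visible.
#'
#' @param matrix a [SimilarityMatrix-class] covering all scored entities.
#' @param assignment a [SplitAssignment-class]; every assigned id must
#'   appear in the matrix.
#' @return a [LeakageReport-class] with the scaled total, the maximum
#'   single inter-split similarity, the raw leaked mass per unordered
#'   split pair, and the assigned fraction.
#' @examples
#' m <- SimilarityMatrix(c("a", "b"), matrix(c(1, 1, 1, 1), 2), "precomputed")
#' a <- SplitAssignment(c(a = "train", b = "test"), c("train", "test"))
#' scaledTotal(scaledLeakage(m, a))  # 1: all similarity mass crosses
#' @export
scaledLeakage <- function(matrix, assignment) {
  methods::validObject(matrix)
  methods::validObject(assignment)
  asg <- assignment(assignment)
  unknown <- setdiff(names(asg), entityIds(matrix))
  if (length(unknown))
    consistencyError(sprintf("assignment references ids absent from matrix: %s",
                             paste(unknown, collapse = ", ")))
  scored <- names(asg)[asg != UNASSIGNED]
  if (!length(scored))
    invalidInput("all entities are unassigned; nothing to score")
  assignedFraction <- length(scored) / length(asg)

  v <- similarityValues(matrix)[scored, scored, drop = FALSE]
  w <- entityWeights(matrix)[scored]
  lab <- asg[scored]
  mass <- outer(w, w) * v
  ut <- upper.tri(v)
  total <- sum(mass[ut])
  cross <- outer(lab, lab, "!=")
  crossMass <- sum(mass[ut & cross])
  scaled <- if (total > 0) crossMass / total else 0

  maxLeak <- if (any(ut & cross)) max(v[ut & cross]) else 0

  sn <- splitNames(assignment)
  present <- sn[sn %in% lab]
  perPair <- data.frame(split_a = character(), split_b = character(),
                        leaked_mass = numeric(), stringsAsFactors = FALSE)
  if (length(present) > 1) {
    combs <- utils::combn(present, 2)
    perPair <- data.frame(
      split_a = combs[1, ], split_b = combs[2, ],
      leaked_mass = apply(combs, 2, function(p)
        sum(mass[lab == p[1], lab == p[2], drop = FALSE])),
      stringsAsFactors = FALSE)
  }
  new("LeakageReport", scaledTotal = scaled, maxSingleLeak = maxLeak,
      perPair = perPair, assignedFraction = assignedFraction)
}

#' Largest similarity between two splits
#'
#' The constraint-style split-quality check: the maximum pairwise
#' similarity between any entity of one split and any entity of another
#' (e.g. "at most 50% sequence identity between training and any other
#' split").
#'
#' @param matrix a [SimilarityMatrix-class].
#' @param assignment a [SplitAssignment-class].
#' @param splitA,splitB names of two non-empty splits.
#' @return the maximum similarity in \[0, 1\].
#' @export
maxInterSplitSimilarity <- function(matrix, assignment, splitA, splitB) {
  methods::validObject(matrix)
  asg <- assignment(assignment)
  unknown <- setdiff(names(asg), entityIds(matrix))
  if (length(unknown))
    consistencyError(sprintf("assignment references ids absent from matrix: %s",
                             paste(unknown, collapse = ", ")))
  idsA <- names(asg)[asg == splitA]
  idsB <- names(asg)[asg == splitB]
  if (!length(idsA)) invalidInput(sprintf("split '%s' is empty", splitA))
  if (!length(idsB)) invalidInput(sprintf("split '%s' is empty", splitB))
  max(similarityValues(matrix)[idsA, idsB, drop = FALSE])
}
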