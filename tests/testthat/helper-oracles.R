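# Independent oracles: deliberately naive implementations used only to
# check the package's optimized code paths.

# Double-loop scaled leakage: cross-split weighted similarity mass over
# total weighted similarity mass, unordered entity pairs, no diagonal.
oracleScaledLeakage <- function(values, weights, splits) {
  n <- length(splits)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m <- weights[i] * weights[j] * values[i, j]
    den <- den + m
    if (splits[i] != splits[j]) num <- num + m
  }
  if (den > 0) num / den else 0
}

# Full-table Needleman-Wunsch score (no traceback), linear gaps.
oracleNwScore <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)
  M[1, ] <- gap * (0:m); M[, 1] <- gap * (0:n)
  for (i in seq_len(n)) for (j in seq_len(m))
    M[i + 1, j + 1] <- max(
      M[i, j] + if (a[i] == b[j]) match else mismatch,
      M[i, j + 1] + gap,
      M[i + 1, j] + gap)
  M[n + 1, m + 1]
}

# Exhaustive-enumeration minimum of the cluster-assignment problem,
# vectorized over the full assignment grid (still a plain enumeration,
# independent of the package's branch-and-bound). Returns NULL when no
# assignment is feasible.
oracleBestAssignment <- function(mass, sim, w, fractions, epsilon,
                                 objective = "total",
                                 labcnt = NULL, stratTol = Inf) {
  nc <- length(w); ns <- length(fractions)
  W <- sum(w)
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), nc)))
  nr <- nrow(grid)

  feasible <- rep(TRUE, nr)
  for (s in seq_len(ns)) {
    frac <- as.vector((grid == s) %*% w) / W
    feasible <- feasible & abs(frac - fractions[s]) <= epsilon + 1e-9
  }
  if (!is.null(labcnt)) {
    gshare <- colSums(labcnt) / sum(labcnt)
    for (s in seq_len(ns)) {
      inS <- (grid == s) * 1
      tot <- as.vector(inS %*% rowSums(labcnt))
      for (l in seq_len(ncol(labcnt))) {
        share <- as.vector(inS %*% labcnt[, l]) / pmax(tot, 1)
        feasible <- feasible &
          (tot == 0 | abs(share - gshare[l]) <= stratTol + 1e-9)
      }
    }
  }
  if (!any(feasible)) return(NULL)

  obj <- numeric(nr)
  if (objective == "max") objMax <- numeric(nr)
  for (i in seq_len(nc - 1)) for (j in (i + 1):nc) {
    cross <- grid[, i] != grid[, j]
    if (objective == "total") obj <- obj + cross * mass[i, j]
    else objMax <- pmax(objMax, cross * sim[i, j])
  }
  if (objective == "total") {
    tot <- sum(mass[upper.tri(mass)])
    obj <- if (tot > 0) obj / tot else obj * 0
  } else obj <- objMax
  min(obj[feasible])
}

# Random valid similarity matrix on n entities.
randomSimilarityMatrix <- function(n, weights = rep(1, n),
                                   ids = sprintf("e%02d", seq_len(n))) {
  v <- matrix(runif(n * n), n, n)
  v <- (v + t(v)) / 2
  diag(v) <- 1
  SimilarityMatrix(ids, v, metricName = "precomputed", weights = weights)
}

# Random cluster-level instance for solver tests: singleton clusters over a
# random matrix, so cluster structure equals entity structure.
randomClusterInstance <- function(nc, weights = rep(1, nc)) {
  m <- randomSimilarityMatrix(nc, weights)
  clusterByThreshold(m, 1)  # off-diagonal similarities are < 1 a.s.
}

# ClusterSet built directly from a matrix at a threshold.
makeInstance <- function(n, threshold = 2) {
  m <- randomSimilarityMatrix(n)
  list(matrix = m,
       clusters = clusterByThreshold(m, min(threshold, 1)))
}
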