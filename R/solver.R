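#' Construct a validated interaction table
#'
#' Two-dimensional datasets (drug-target, protein-protein) are tables of
#' entity pairs with a binary interaction label.
#'
#' @param idA,idB character vectors of entity ids (one row per pair).
#' @param label vector coercible to character; conventionally "1"
#'   (positive) / "0" (negative).
#' @return data.frame with columns `id_a`, `id_b`, `label`.
#' @export
interactionTable <- function(idA, idB, label = "1") {
  idA <- as.character(idA); idB <- as.character(idB)
  label <- rep_len(as.character(label), length(idA))
  if (length(idA) != length(idB))
    invalidInput("idA and idB must have the same length")
  if (any(!nzchar(idA)) || any(!nzchar(idB)))
    invalidInput("interaction ids must be non-empty")
  key <- paste(idA, idB, label, sep = "\r")
  if (anyDuplicated(key))
    invalidInput("duplicate (id_a, id_b, label) rows")
  data.frame(id_a = idA, id_b = idB, label = label, stringsAsFactors = FALSE)
}

checkInteractionTable <- function(interactions) {
  if (!is.data.frame(interactions) ||
      !all(c("id_a", "id_b", "label") %in% names(interactions)))
    invalidInput("interactions must have columns id_a, id_b, label")
  interactionTable(interactions$id_a, interactions$id_b, interactions$label)
}

# Pairwise leaked-mass matrix at cluster level: W_c * W_d * S_cd, zero diagonal.
.clusterPairMass <- function(clusterSet) {
  w <- clusterWeights(clusterSet)
  m <- outer(w, w) * clusterSimilarity(clusterSet)
  diag(m) <- 0
  m
}

# Scaled cluster-level leakage of an assignment index vector (1-based splits).
.clusterObjective <- function(assignIdx, mass, sim, objective) {
  ut <- upper.tri(mass)
  cross <- outer(assignIdx, assignIdx, "!=") & ut
  if (objective == "total") {
    tot <- sum(mass[ut])
    if (tot > 0) sum(mass[cross]) / tot else 0
  } else {
    if (any(cross)) max(sim[cross]) else 0
  }
}

.clusterLabelCounts <- function(clusterSet, entities, labelColumn) {
  if (!labelColumn %in% names(entities))
    invalidInput(sprintf("entities lack stratification column '%s'", labelColumn))
  lab <- setNames(as.character(entities[[labelColumn]]), entities$id)
  if (anyNA(lab)) invalidInput("stratification labels must not be NA")
  levs <- sort(unique(lab))
  cnt <- t(vapply(clusters(clusterSet), function(cl)
    as.integer(table(factor(lab[cl], levels = levs))),
    integer(length(levs))))
  if (length(levs) == 1) cnt <- matrix(cnt, ncol = 1)
  colnames(cnt) <- levs
  cnt
}

.checkFractionWindows <- function(assignIdx, w, spec) {
  W <- sum(w)
  frac <- vapply(seq_along(spec@splitNames), function(s)
    sum(w[assignIdx == s]) / W, 0)
  dev <- abs(frac - spec@fractions)
  if (any(dev > spec@epsilon + 1e-9))
    infeasibleError(sprintf(
      "solver output violates the fraction window: split '%s' realized %.4f vs target %.4f (epsilon %.3g)",
      spec@splitNames[which.max(dev)], frac[which.max(dev)],
      spec@fractions[which.max(dev)], spec@epsilon))
  invisible(frac)
}

.checkStratification <- function(assignIdx, labcnt, spec) {
  if (is.null(labcnt)) return(invisible(NULL))
  gshare <- colSums(labcnt) / sum(labcnt)
  for (s in seq_along(spec@splitNames)) {
    inS <- labcnt[assignIdx == s, , drop = FALSE]
    tot <- sum(inS)
    if (tot == 0) next
    dev <- abs(colSums(inS) / tot - gshare)
    if (any(dev > spec@stratifyTolerance + 1e-9))
      infeasibleError(sprintf(
        "label '%s' cannot be balanced in split '%s' (share deviates by %.3f > tolerance %.3g)",
        colnames(labcnt)[which.max(dev)], spec@splitNames[s],
        max(dev), spec@stratifyTolerance))
  }
  invisible(NULL)
}

.singleClusterCapacityCheck <- function(clusterSet, spec) {
  w <- clusterWeights(clusterSet)
  W <- sum(w)
  if (W <= 0) invalidInput("total cluster weight must be positive")
  cap <- max(spec@fractions + spec@epsilon) * W
  heavy <- which(w > cap + 1e-9)
  if (length(heavy)) {
    members <- clusters(clusterSet)[[heavy[1]]]
    infeasibleError(sprintf(
      "cluster %d (weight %.3g, first member '%s') exceeds every split capacity (max %.3g); raise epsilon or the largest fraction",
      heavy[1], w[heavy[1]], members[1], cap))
  }
  invisible(NULL)
}

# Greedy seeding + steepest-descent single-cluster moves on a penalized
# objective; deterministic under the spec seed via seeded restart orders.
.heuristicAssign <- function(mass, sim, w, spec, labcnt = NULL,
                             nRestarts = 10) {
  ns <- length(spec@fractions)
  nc <- length(w)
  W <- sum(w)
  targets <- spec@fractions * W
  penalty <- 1e3 * (1 + sum(mass))

  penalized <- function(assignIdx) {
    frac <- vapply(seq_len(ns), function(s) sum(w[assignIdx == s]), 0) / W
    viol <- sum(pmax(0, abs(frac - spec@fractions) - spec@epsilon))
    sviol <- 0
    if (!is.null(labcnt)) {
      gshare <- colSums(labcnt) / sum(labcnt)
      for (s in seq_len(ns)) {
        inS <- labcnt[assignIdx == s, , drop = FALSE]
        tot <- sum(inS)
        if (tot > 0)
          sviol <- sviol +
            sum(pmax(0, abs(colSums(inS) / tot - gshare) - spec@stratifyTolerance))
      }
    }
    .clusterObjective(assignIdx, mass, sim, spec@objective) +
      penalty * (viol + sviol)
  }

  descend <- function(assignIdx) {
    obj <- penalized(assignIdx)
    repeat {
      bestMove <- NULL
      bestObj <- obj
      for (i in seq_len(nc)) for (s in seq_len(ns)) {
        if (assignIdx[i] == s) next
        cand <- assignIdx
        cand[i] <- s
        o <- penalized(cand)
        if (o < bestObj - 1e-12) { bestObj <- o; bestMove <- c(i, s) }
      }
      if (is.null(bestMove)) break
      assignIdx[bestMove[1]] <- bestMove[2]
      obj <- bestObj
    }
    list(assign = assignIdx, obj = obj)
  }

  greedySeed <- function(ord) {
    assignIdx <- integer(nc)
    got <- numeric(ns)
    for (i in ord) {
      s <- which.max(targets - got)
      assignIdx[i] <- s
      got[s] <- got[s] + w[i]
    }
    assignIdx
  }

  best <- NULL
  withLocalSeed(spec@seed, {
    for (r in seq_len(nRestarts)) {
      ord <- if (r == 1) order(-w, seq_len(nc)) else sample.int(nc)
      res <- descend(greedySeed(ord))
      if (is.null(best) || res$obj < best$obj - 1e-12) best <- res
    }
  })
  if (best$obj >= penalty / 2)
    infeasibleError(
      "no feasible cluster-to-split assignment found (heuristic search); relax epsilon or the stratification tolerance")
  best$assign
}

.entityAssignment <- function(clusterSet, assignIdx, spec, provenance) {
  cl <- clusters(clusterSet)
  asg <- setNames(rep(spec@splitNames[1], length(unlist(cl))),
                  unlist(cl, use.names = FALSE))
  for (k in seq_along(cl))
    asg[cl[[k]]] <- spec@splitNames[assignIdx[k]]
  SplitAssignment(asg, spec@splitNames, provenance)
}

#' Leakage-minimizing one-dimensional split (S1)
#'
#' Assigns whole similarity clusters to the named splits so that each
#' split's realized weight fraction lies within `epsilon` of its target
#' and the leakage objective is minimized: either the total cross-split
#' weighted similarity mass (`objective = "total"`, reported scaled to
#' \[0, 1\]) or the largest single inter-split cluster similarity
#' (`objective = "max"`).
#'
#' Up to `exactNodes` candidate assignments the solver is exact: a
#' branch-and-bound enumeration whose result is the true minimum, with
#' ties broken lexicographically (cluster order, then split order).
#' Larger instances fall back to a deterministic seeded heuristic: greedy
#' seeding (largest cluster into the split with the largest remaining
#' target weight) followed by steepest-descent single-cluster moves with
#' random restarts. Fraction windows (and stratification, when requested)
#' are re-checked on the returned assignment, not trusted from the search.
#'
#' @param clusterSet a [ClusterSet-class] (see [clusterByThreshold()]).
#' @param spec a [splitSpec()].
#' @param entities optional [entityTable()]; required when
#'   `spec` stratifies on a label column.
#' @param exactNodes search-space bound (number of split^cluster
#'   combinations) up to which the exact path is used. Default 2^21.
#' @return a [SplitAssignment-class]; provenance records the solver path,
#'   seed, objective, and the achieved cluster-level objective value.
#' @examples
#' m <- SimilarityMatrix(c("a", "b", "c", "d"),
#'   {v <- diag(1, 4); v[1, 2] <- v[2, 1] <- 0.9; v}, "precomputed")
#' cs <- clusterByThreshold(m, 0.5)
#' solveS1(cs, splitSpec(c(train = 0.5, test = 0.5), epsilon = 0.26))
#' @export
solveS1 <- function(clusterSet, spec, entities = NULL, exactNodes = 2^21) {
  methods::validObject(clusterSet)
  methods::validObject(spec)
  .singleClusterCapacityCheck(clusterSet, spec)
  w <- clusterWeights(clusterSet)
  nc <- length(w)
  ns <- length(spec@splitNames)
  mass <- .clusterPairMass(clusterSet)
  sim <- clusterSimilarity(clusterSet)

  labcnt <- NULL
  if (nzchar(spec@stratifyOn)) {
    if (is.null(entities))
      invalidInput("stratified solving requires the entities table")
    entities <- checkEntityTable(entities)
    labcnt <- .clusterLabelCounts(clusterSet, entities, spec@stratifyOn)
  }

  exact <- ns^nc <= exactNodes
  if (exact) {
    res <- .s1_exact_cpp(mass, sim, w, spec@fractions, spec@epsilon,
                         if (spec@objective == "total") 0L else 1L,
                         if (is.null(labcnt)) matrix(0L, nc, 0) else labcnt,
                         spec@stratifyTolerance)
    if (!res$found) .reportInfeasible(clusterSet, spec, labcnt)
    assignIdx <- res$assignment + 1L
  } else {
    assignIdx <- .heuristicAssign(mass, sim, w, spec, labcnt)
  }

  .checkFractionWindows(assignIdx, w, spec)
  .checkStratification(assignIdx, labcnt, spec)
  objVal <- .clusterObjective(assignIdx, mass, sim, spec@objective)
  .entityAssignment(clusterSet, assignIdx, spec, list(
    tool = "leakSplit::solveS1", solver = if (exact) "exact" else "heuristic",
    objective = spec@objective, objective_value = objVal, seed = spec@seed))
}

.reportInfeasible <- function(clusterSet, spec, labcnt) {
  if (!is.null(labcnt)) {
    # a label confined to one cluster can never reach every split
    for (l in seq_len(ncol(labcnt))) {
      inCl <- which(labcnt[, l] > 0)
      if (length(inCl) == 1)
        infeasibleError(sprintf(
          "stratification infeasible: label '%s' occurs only in cluster %d and cannot be balanced across %d splits",
          colnames(labcnt)[l], inCl, length(spec@splitNames)))
    }
    infeasibleError(sprintf(
      "no assignment satisfies both the fraction windows (epsilon %.3g) and stratification (tolerance %.3g)",
      spec@epsilon, spec@stratifyTolerance))
  }
  # tightest split: largest lower weight bound relative to cluster granularity
  tight <- which.max(spec@fractions)
  infeasibleError(sprintf(
    "no cluster-to-split assignment puts every split within epsilon %.3g of its target; tightest split '%s' (target %.3g); relax epsilon or lower the clustering threshold",
    spec@epsilon, spec@splitNames[tight], spec@fractions[tight]))
}

#' @rdname solveS1
#' @details `solveS1Stratified` is `solveS1` with a mandatory
#'   stratification column: per split, each label's share must fall within
#'   `stratifyTolerance` of its global share (e.g. keeping positive and
#'   negative interactions balanced in every split).
#' @param stratifyOn label column; overrides the one in `spec` when given.
#' @export
solveS1Stratified <- function(clusterSet, entities, spec, stratifyOn = NULL,
                              exactNodes = 2^21) {
  if (!is.null(stratifyOn)) spec@stratifyOn <- stratifyOn
  if (!nzchar(spec@stratifyOn))
    invalidInput("spec must name a stratifyOn label column")
  solveS1(clusterSet, spec, entities = entities, exactNodes = exactNodes)
}

#' Assign interactions to splits induced by entity assignments
#'
#' An interaction belongs to split S if and only if both its endpoints are
#' assigned to S; every other interaction (cross-split or touching an
#' unassigned entity) is returned as discarded, never silently dropped.
#'
#' @param assignment a [SplitAssignment-class] covering every endpoint id
#'   (entities of both interaction dimensions combined).
#' @param interactions an [interactionTable()].
#' @return a list with `bySplit` (named list of interaction data.frames,
#'   one per split) and `discarded` (data.frame of the remaining rows).
#' @export
induceInteractionSplit <- function(assignment, interactions) {
  interactions <- checkInteractionTable(interactions)
  asg <- assignment(assignment)
  unknown <- setdiff(unique(c(interactions$id_a, interactions$id_b)),
                     names(asg))
  if (length(unknown))
    consistencyError(sprintf("interaction endpoints missing from assignment: %s",
                             paste(unknown, collapse = ", ")))
  sa <- asg[interactions$id_a]
  sb <- asg[interactions$id_b]
  same <- sa == sb & sa != UNASSIGNED
  bySplit <- lapply(setNames(nm = splitNames(assignment)), function(s)
    interactions[same & sa == s, , drop = FALSE])
  list(bySplit = bySplit,
       discarded = interactions[!same, , drop = FALSE])
}

#' Reduce an interaction table to one weighted entity set
#'
#' Pools the entities of both interaction dimensions into a single set,
#' weighting each entity by the number of interaction rows that mention it
#' (an entity appearing on both sides of different rows is counted once
#' per mention). This is the reduction that lets a one-dimensional S1
#' split drive a two-dimensional interaction dataset, as used for
#' protein-protein interaction data. Payloads are not recoverable from an
#' interaction table, so the id is carried as the payload placeholder.
#'
#' @param interactions an [interactionTable()].
#' @return an [entityTable()] with one row per distinct entity, in order
#'   of first appearance, `weight` = mention count.
#' @examples
#' it <- interactionTable(c("p1", "p1"), c("p2", "p3"))
#' weightedUnionReduction(it)$weight  # 2, 1, 1
#' @export
weightedUnionReduction <- function(interactions) {
  interactions <- checkInteractionTable(interactions)
  if (!nrow(interactions)) invalidInput("interaction table is empty")
  mentions <- c(rbind(interactions$id_a, interactions$id_b))
  ids <- unique(mentions)
  cnt <- table(factor(mentions, levels = ids))
  entityTable(ids, ids, weight = as.numeric(cnt))
}

#' Leakage-minimizing two-dimensional split (S2)
#'
#' Jointly assigns the clusters of both interacting dimensions (e.g.
#' proteins and ligands) to splits. The objective is the sum of the two
#' dimensions' scaled cluster-level leakages (equal weighting by default,
#' `dimWeights` exposes the balance). An interaction is kept in split S
#' iff both endpoints land in S; per-split kept-interaction fractions must
#' lie within `epsilon` of the targets, and no split may end up without
#' interactions.
#'
#' Exact joint enumeration is used while the joint search space
#' (splits^(clustersA + clustersB)) stays within `exactNodes`; beyond
#' that a seeded penalized local search over the joint assignment runs.
#'
#' @param clustersA,clustersB [ClusterSet-class] objects for the two
#'   dimensions; their entity ids must cover the interaction endpoints.
#' @param interactions an [interactionTable()].
#' @param spec a [splitSpec()]; fraction targets are measured in kept
#'   interaction rows (what downstream training consumes), not entity
#'   weight.
#' @param dimWeights length-2 positive weights on the two dimensions'
#'   leakage terms.
#' @param exactNodes joint search-space bound for the exact path.
#' @return list with `assignmentA`, `assignmentB` ([SplitAssignment-class])
#'   and `interactions` (the [induceInteractionSplit()] result).
#' @export
solveS2 <- function(clustersA, clustersB, interactions, spec,
                    dimWeights = c(1, 1), exactNodes = 2^22) {
  methods::validObject(clustersA); methods::validObject(clustersB)
  methods::validObject(spec)
  interactions <- checkInteractionTable(interactions)
  idsA <- entityIds(clustersA); idsB <- entityIds(clustersB)
  missA <- setdiff(unique(interactions$id_a), idsA)
  missB <- setdiff(unique(interactions$id_b), idsB)
  if (length(missA) || length(missB))
    consistencyError(sprintf("interaction endpoints not covered by clusters: %s",
                             paste(c(missA, missB), collapse = ", ")))
  if (any(dimWeights <= 0) || length(dimWeights) != 2)
    invalidInput("dimWeights must be two positive numbers")

  ncA <- length(clusters(clustersA)); ncB <- length(clusters(clustersB))
  ns <- length(spec@splitNames)
  clusterOf <- function(cs) {
    cl <- clusters(cs)
    setNames(rep(seq_along(cl), lengths(cl)), unlist(cl, use.names = FALSE))
  }
  cA <- clusterOf(clustersA); cB <- clusterOf(clustersB)
  N <- matrix(0, ncA, ncB)
  tab <- table(cA[interactions$id_a], cB[interactions$id_b])
  N[cbind(as.integer(rownames(tab))[row(tab)],
          as.integer(colnames(tab))[col(tab)])] <- as.vector(tab)
  nRows <- nrow(interactions)

  massA <- .clusterPairMass(clustersA); simA <- clusterSimilarity(clustersA)
  massB <- .clusterPairMass(clustersB); simB <- clusterSimilarity(clustersB)

  if (ns^(ncA + ncB) <= exactNodes) {
    sol <- .s2Exact(massA, simA, massB, simB, N, spec, dimWeights)
  } else {
    sol <- .s2Heuristic(massA, simA, massB, simB, N, spec, dimWeights)
  }
  if (is.null(sol))
    infeasibleError(sprintf(
      "no joint assignment keeps every split's interaction fraction within epsilon %.3g (and non-empty); relax epsilon or lower the clustering thresholds",
      spec@epsilon))

  provA <- list(tool = "leakSplit::solveS2", dimension = "A",
                objective = "total", seed = spec@seed,
                objective_value = sol$obj)
  provB <- provA; provB$dimension <- "B"
  aA <- .entityAssignment(clustersA, sol$assignA, spec, provA)
  aB <- .entityAssignment(clustersB, sol$assignB, spec, provB)
  combined <- SplitAssignment(c(assignment(aA), assignment(aB)),
                              spec@splitNames)
  induced <- induceInteractionSplit(combined, interactions)
  kept <- vapply(induced$bySplit, nrow, 0L)
  if (any(kept == 0))
    infeasibleError(sprintf("induced split leaves split '%s' empty of interactions",
                            spec@splitNames[which(kept == 0)[1]]))
  list(assignmentA = aA, assignmentB = aB, interactions = induced)
}

# All joint assignments, vectorized: rows of EA / EB are assignments in
# lexicographic order (first cluster most significant, split order within).
.enumAssignments <- function(nc, ns) {
  grid <- rev(expand.grid(rev(lapply(seq_len(nc), function(i) seq_len(ns)))))
  as.matrix(unname(grid))
}

.s2Exact <- function(massA, simA, massB, simB, N, spec, dimWeights) {
  ns <- length(spec@splitNames)
  EA <- .enumAssignments(nrow(massA), ns)
  EB <- .enumAssignments(nrow(massB), ns)
  leakA <- apply(EA, 1, .clusterObjective, massA, simA, "total")
  leakB <- apply(EB, 1, .clusterObjective, massB, simB, "total")
  obj <- dimWeights[1] * outer(leakA, rep(1, length(leakB))) +
         dimWeights[2] * outer(rep(1, length(leakA)), leakB)
  kept <- matrix(0, nrow(EA), nrow(EB))
  feas <- matrix(TRUE, nrow(EA), nrow(EB))
  counts <- vector("list", ns)
  for (s in seq_len(ns)) {
    MA <- (EA == s) * 1
    MB <- (EB == s) * 1
    counts[[s]] <- MA %*% N %*% t(MB)
    kept <- kept + counts[[s]]
    feas <- feas & counts[[s]] >= 1
  }
  for (s in seq_len(ns))
    feas <- feas & kept > 0 &
      abs(counts[[s]] / pmax(kept, 1) - spec@fractions[s]) <= spec@epsilon + 1e-9
  if (!any(feas)) return(NULL)
  obj[!feas] <- Inf
  best <- min(obj)
  # lexicographic tie-break: smallest A index, then smallest B index
  hits <- which(obj <= best + 1e-12, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  list(assignA = EA[hits[1, 1], ], assignB = EB[hits[1, 2], ], obj = best)
}

.s2Heuristic <- function(massA, simA, massB, simB, N, spec, dimWeights,
                         nRestarts = 10) {
  ns <- length(spec@splitNames)
  ncA <- nrow(massA); ncB <- nrow(massB)
  nRows <- sum(N)
  penalty <- 1e3 * (dimWeights[1] + dimWeights[2] + 1)

  penalized <- function(aA, aB) {
    cnt <- vapply(seq_len(ns), function(s)
      sum(N[aA == s, aB == s, drop = FALSE]), 0)
    kept <- sum(cnt)
    viol <- if (kept == 0) ns else
      sum(pmax(0, abs(cnt / kept - spec@fractions) - spec@epsilon)) +
      sum(cnt == 0)
    dimWeights[1] * .clusterObjective(aA, massA, simA, "total") +
      dimWeights[2] * .clusterObjective(aB, massB, simB, "total") +
      penalty * viol
  }

  descend <- function(aA, aB) {
    obj <- penalized(aA, aB)
    repeat {
      bestObj <- obj; bestMove <- NULL
      for (i in seq_len(ncA)) for (s in seq_len(ns)) {
        if (aA[i] == s) next
        cand <- aA; cand[i] <- s
        o <- penalized(cand, aB)
        if (o < bestObj - 1e-12) { bestObj <- o; bestMove <- list("A", i, s) }
      }
      for (i in seq_len(ncB)) for (s in seq_len(ns)) {
        if (aB[i] == s) next
        cand <- aB; cand[i] <- s
        o <- penalized(aA, cand)
        if (o < bestObj - 1e-12) { bestObj <- o; bestMove <- list("B", i, s) }
      }
      if (is.null(bestMove)) break
      if (bestMove[[1]] == "A") aA[bestMove[[2]]] <- bestMove[[3]]
      else aB[bestMove[[2]]] <- bestMove[[3]]
      obj <- bestObj
    }
    list(aA = aA, aB = aB, obj = obj)
  }

  best <- NULL
  withLocalSeed(spec@seed, {
    for (r in seq_len(nRestarts)) {
      aA <- sample.int(ns, ncA, replace = TRUE)
      aB <- sample.int(ns, ncB, replace = TRUE)
      res <- descend(aA, aB)
      if (is.null(best) || res$obj < best$obj - 1e-12) best <- res
    }
  })
  if (best$obj >= penalty / 2) return(NULL)
  list(assignA = best$aA, assignB = best$aB, obj = best$obj)
}
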