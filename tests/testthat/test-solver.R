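test_that("two independent equal clusters split with zero leakage", {
  ids <- c("a1", "a2", "b1", "b2")
  v <- diag(1, 4)
  v[1, 2] <- v[2, 1] <- 0.9
  v[3, 4] <- v[4, 3] <- 0.9
  m <- SimilarityMatrix(ids, v, "precomputed")
  cs <- clusterByThreshold(m, 0.8)
  expect_length(clusters(cs), 2)
  asg <- solveS1(cs, splitSpec(c(train = 0.5, test = 0.5), epsilon = 0.05))
  expect_equal(provenance(asg)$objective_value, 0)
  expect_equal(scaledTotal(scaledLeakage(m, asg)), 0)
})

test_that("uniform similarity makes every feasible assignment equivalent", {
  n <- 6
  ids <- paste0("e", 1:n)
  v <- matrix(0.5, n, n); diag(v) <- 1
  m <- SimilarityMatrix(ids, v, "precomputed")
  cs <- clusterByThreshold(m, 0.9)  # singletons
  spec <- splitSpec(c(train = 0.5, test = 0.5), epsilon = 0.05)
  asg <- solveS1(cs, spec)
  mass <- outer(clusterWeights(cs), clusterWeights(cs)) *
    clusterSimilarity(cs); diag(mass) <- 0
  best <- oracleBestAssignment(mass, clusterSimilarity(cs),
                               clusterWeights(cs), spec@fractions,
                               spec@epsilon)
  expect_equal(provenance(asg)$objective_value, best, tolerance = 1e-9)
})

test_that("exact solver matches exhaustive enumeration (both objectives)", {
  set.seed(29)
  for (k in 1:12) {
    nc <- sample(5:9, 1)
    w <- runif(nc, 0.5, 2)
    cs <- randomClusterInstance(nc, weights = w)
    ns <- sample(2:3, 1)
    fr <- if (ns == 2) c(0.7, 0.3) else c(0.6, 0.2, 0.2)
    names(fr) <- paste0("s", seq_len(ns))
    for (objective in c("total", "max")) {
      spec <- splitSpec(fr, epsilon = 0.25, objective = objective, seed = k)
      mass <- outer(clusterWeights(cs), clusterWeights(cs)) *
        clusterSimilarity(cs); diag(mass) <- 0
      oracle <- oracleBestAssignment(mass, clusterSimilarity(cs),
                                     clusterWeights(cs), spec@fractions,
                                     spec@epsilon, objective)
      if (is.null(oracle)) {
        expect_error(solveS1(cs, spec), class = "leakSplit_infeasible_error")
      } else {
        asg <- solveS1(cs, spec)
        expect_equal(provenance(asg)$objective_value, oracle,
                     tolerance = 1e-9,
                     info = sprintf("instance %d objective %s", k, objective))
      }
    }
  }
})

test_that("solver respects fraction windows and reports infeasibility", {
  # a cluster heavier than any split capacity is named
  ids <- paste0("e", 1:4)
  v <- diag(1, 4); v[1, 2] <- v[2, 1] <- v[1, 3] <- v[3, 1] <- v[2, 3] <- v[3, 2] <- 0.95
  m <- SimilarityMatrix(ids, v, "precomputed")
  cs <- clusterByThreshold(m, 0.9)  # one 3-cluster + singleton
  expect_error(solveS1(cs, splitSpec(c(a = 0.5, b = 0.5), epsilon = 0.05)),
               "capacity", class = "leakSplit_infeasible_error")

  # feasible case: realized fractions within epsilon (checked post-hoc)
  set.seed(17)
  for (k in 1:10) {
    nc <- sample(6:10, 1)
    w <- runif(nc, 0.5, 1.5)
    cs <- randomClusterInstance(nc, weights = w)
    spec <- splitSpec(c(train = 0.75, test = 0.25), epsilon = 0.15, seed = k)
    asg <- solveS1(cs, spec)
    wById <- setNames(rep(clusterWeights(cs), lengths(clusters(cs))),
                      unlist(clusters(cs)))
    tab <- tapply(wById[names(assignment(asg))], assignment(asg), sum)
    frac <- tab[c("train", "test")] / sum(w)
    expect_true(all(abs(frac - c(0.75, 0.25)) <= 0.15 + 1e-9))
  }
})

test_that("solver is deterministic and beats random cluster splits", {
  set.seed(41)
  for (k in 1:5) {
    cs <- randomClusterInstance(8)
    spec <- splitSpec(c(train = 0.75, test = 0.25), epsilon = 0.13, seed = 7)
    a1 <- solveS1(cs, spec)
    a2 <- solveS1(cs, spec)
    expect_identical(assignment(a1), assignment(a2))
  }
})

test_that("heuristic path also returns feasible low-leak assignments", {
  set.seed(61)
  cs <- randomClusterInstance(12)
  spec <- splitSpec(c(train = 0.8, test = 0.2), epsilon = 0.1, seed = 3)
  # force the heuristic by shrinking the exact-search budget
  asgH <- solveS1(cs, spec, exactNodes = 2)
  expect_identical(provenance(asgH)$solver, "heuristic")
  asgE <- solveS1(cs, spec)
  expect_identical(provenance(asgE)$solver, "exact")
  w <- clusterWeights(cs)
  tab <- table(assignment(asgH))
  expect_true(all(abs(tab[c("train", "test")] / 12 - c(0.8, 0.2)) <= 0.1 + 1e-9))
  # heuristic never beats the exact optimum
  expect_gte(provenance(asgH)$objective_value + 1e-9,
             provenance(asgE)$objective_value)
})

test_that("stratified solving balances labels or explains failure", {
  # labels balanced inside each cluster: plain solution already satisfies it
  ids <- paste0("e", 1:8)
  m <- SimilarityMatrix(ids, diag(1, 8), "precomputed")
  cs <- clusterByThreshold(m, 0.5)
  ent <- entityTable(ids, rep("ACD", 8), lab = rep(c("pos", "neg"), 4))
  spec <- splitSpec(c(train = 0.5, test = 0.5), epsilon = 0.05,
                    stratifyOn = "lab", stratifyTolerance = 0.05)
  asg <- solveS1Stratified(cs, ent, spec)
  for (s in c("train", "test")) {
    inS <- ent$lab[assignment(asg)[ent$id] == s]
    expect_equal(mean(inS == "pos"), 0.5)
  }

  # a label confined to one cluster cannot reach both splits
  v <- diag(1, 8)
  v[1, 2] <- v[2, 1] <- 0.99
  m2 <- SimilarityMatrix(ids, v, "precomputed")
  cs2 <- clusterByThreshold(m2, 0.9)
  ent2 <- entityTable(ids, rep("ACD", 8),
                      lab = c("rare", "rare", rep("common", 6)))
  spec2 <- splitSpec(c(train = 0.5, test = 0.5), epsilon = 0.2,
                     stratifyOn = "lab", stratifyTolerance = 0.05)
  expect_error(solveS1Stratified(cs2, ent2, spec2),
               "rare", class = "leakSplit_infeasible_error")

  # synthetic 12-cluster instance: shares verified by direct counting
  set.seed(71)
  ids3 <- paste0("e", 1:12)
  m3 <- SimilarityMatrix(ids3, diag(1, 12), "precomputed")
  cs3 <- clusterByThreshold(m3, 0.5)
  ent3 <- entityTable(ids3, rep("ACD", 12),
                      lab = rep(c("pos", "neg"), 6))
  spec3 <- splitSpec(c(train = 2 / 3, test = 1 / 3), epsilon = 0.1,
                     stratifyOn = "lab", stratifyTolerance = 0.1, seed = 2)
  asg3 <- solveS1Stratified(cs3, ent3, spec3)
  glob <- mean(ent3$lab == "pos")
  for (s in c("train", "test")) {
    inS <- ent3$lab[assignment(asg3)[ent3$id] == s]
    expect_lte(abs(mean(inS == "pos") - glob), 0.1 + 1e-9)
  }
})

test_that("interaction induction follows the both-endpoints rule", {
  asg <- SplitAssignment(c(p1 = "train", p2 = "train", p3 = "test",
                           p4 = "UNASSIGNED"),
                         c("train", "test"))
  it <- interactionTable(c("p1", "p1", "p3", "p1"),
                         c("p2", "p3", "p3", "p4"),
                         c("1", "1", "0", "1"))
  res <- induceInteractionSplit(asg, it)
  expect_equal(nrow(res$bySplit$train), 1)   # (p1,p2) both in train
  expect_equal(nrow(res$bySplit$test), 1)    # (p3,p3) both in test
  expect_equal(nrow(res$discarded), 2)       # cross-split and unassigned
  expect_equal(nrow(res$bySplit$train) + nrow(res$bySplit$test) +
               nrow(res$discarded), nrow(it))

  empty <- interactionTable(character(), character(), character())
  res0 <- induceInteractionSplit(asg, empty)
  expect_equal(nrow(res0$discarded), 0)
  expect_equal(sum(vapply(res0$bySplit, nrow, 0L)), 0)

  bad <- interactionTable("p1", "zz")
  expect_error(induceInteractionSplit(asg, bad),
               class = "leakSplit_consistency_error")
})

test_that("induced splits partition the rows on random instances", {
  set.seed(83)
  for (k in 1:20) {
    nA <- sample(4:10, 1); nB <- sample(4:10, 1)
    idsA <- paste0("a", seq_len(nA)); idsB <- paste0("b", seq_len(nB))
    pairs <- expand.grid(a = idsA, b = idsB, stringsAsFactors = FALSE)
    pairs <- pairs[sample(nrow(pairs), sample(5:15, 1)), ]
    it <- interactionTable(pairs$a, pairs$b)
    asg <- SplitAssignment(
      setNames(sample(c("train", "test", "UNASSIGNED"), nA + nB, TRUE),
               c(idsA, idsB)),
      c("train", "test"))
    res <- induceInteractionSplit(asg, it)
    kept <- do.call(rbind, res$bySplit)
    expect_equal(nrow(kept) + nrow(res$discarded), nrow(it))
    # a kept row's endpoints share its split; across splits rows are disjoint
    for (s in c("train", "test")) {
      d <- res$bySplit[[s]]
      if (nrow(d)) {
        expect_true(all(assignment(asg)[d$id_a] == s))
        expect_true(all(assignment(asg)[d$id_b] == s))
      }
    }
  }
})

test_that("weighted union reduction counts interaction mentions", {
  it <- interactionTable(c("p1", "p1"), c("p2", "p3"))
  red <- weightedUnionReduction(it)
  expect_equal(setNames(red$weight, red$id),
               c(p1 = 2, p2 = 1, p3 = 1))
  one <- weightedUnionReduction(interactionTable("a", "b"))
  expect_equal(setNames(one$weight, one$id), c(a = 1, b = 1))
  # entity on both sides of different rows: one mention per row
  toy <- interactionTable(c("x", "y", "z", "w", "x"),
                          c("y", "z", "x", "x", "q"))
  redt <- weightedUnionReduction(toy)
  mentions <- table(c(toy$id_a, toy$id_b))
  expect_equal(unname(setNames(redt$weight, redt$id)[names(mentions)]),
               unname(as.numeric(mentions)))
})

test_that("S2 sends disjoint interaction blocks to different splits", {
  # proteins x ligands with interactions only inside two blocks
  idsA <- paste0("p", 1:4); idsB <- paste0("l", 1:4)
  vA <- diag(1, 4); vA[1, 2] <- vA[2, 1] <- 0.9; vA[3, 4] <- vA[4, 3] <- 0.9
  vB <- vA
  mA <- SimilarityMatrix(idsA, vA, "precomputed")
  mB <- SimilarityMatrix(idsB, vB, "precomputed")
  csA <- clusterByThreshold(mA, 0.8); csB <- clusterByThreshold(mB, 0.8)
  it <- interactionTable(c("p1", "p2", "p3", "p4"),
                         c("l1", "l2", "l3", "l4"))
  sol <- solveS2(csA, csB, it, splitSpec(c(train = 0.5, test = 0.5),
                                         epsilon = 0.05))
  expect_equal(nrow(sol$interactions$discarded), 0)
  expect_equal(provenance(sol$assignmentA)$objective_value, 0)
  # each block is wholly inside one split
  aA <- assignment(sol$assignmentA)
  expect_equal(aA[["p1"]], aA[["p2"]])
  expect_equal(aA[["p3"]], aA[["p4"]])
  expect_false(aA[["p1"]] == aA[["p3"]])
})

test_that("S2 exact objective matches joint enumeration", {
  set.seed(101)
  for (k in 1:4) {
    nA <- sample(3:5, 1); nB <- sample(3:5, 1)
    mA <- randomSimilarityMatrix(nA, ids = paste0("p", seq_len(nA)))
    mB <- randomSimilarityMatrix(nB, ids = paste0("l", seq_len(nB)))
    csA <- clusterByThreshold(mA, 1); csB <- clusterByThreshold(mB, 1)
    pairs <- expand.grid(a = entityIds(mA), b = entityIds(mB),
                         stringsAsFactors = FALSE)
    it <- interactionTable(pairs$a, pairs$b)
    spec <- splitSpec(c(train = 0.7, test = 0.3), epsilon = 0.2, seed = k)
    sol <- tryCatch(solveS2(csA, csB, it, spec),
                    leakSplit_infeasible_error = function(e) NULL)

    # independent joint enumeration
    wA <- clusterWeights(csA); wB <- clusterWeights(csB)
    mmA <- outer(wA, wA) * clusterSimilarity(csA); diag(mmA) <- 0
    mmB <- outer(wB, wB) * clusterSimilarity(csB); diag(mmB) <- 0
    N <- matrix(0, length(wA), length(wB))
    ia <- match(it$id_a, entityIds(csA)); ib <- match(it$id_b, entityIds(csB))
    # singleton clusters: entity index == cluster index
    for (r in seq_len(nrow(it))) N[ia[r], ib[r]] <- N[ia[r], ib[r]] + 1
    gridA <- as.matrix(expand.grid(rep(list(1:2), length(wA))))
    gridB <- as.matrix(expand.grid(rep(list(1:2), length(wB))))
    best <- Inf
    scaled <- function(asg, mm) {
      ut <- upper.tri(mm); tot <- sum(mm[ut])
      cr <- outer(asg, asg, "!=") & ut
      if (tot > 0) sum(mm[cr]) / tot else 0
    }
    for (ra in seq_len(nrow(gridA))) for (rb in seq_len(nrow(gridB))) {
      aA <- gridA[ra, ]; aB <- gridB[rb, ]
      cnt <- vapply(1:2, function(s) sum(N[aA == s, aB == s, drop = FALSE]), 0)
      kept <- sum(cnt)
      if (kept == 0 || any(cnt < 1)) next
      if (any(abs(cnt / kept - c(0.7, 0.3)) > 0.2 + 1e-9)) next
      best <- min(best, scaled(aA, mmA) + scaled(aB, mmB))
    }
    if (is.null(sol)) {
      expect_identical(best, Inf)
    } else {
      expect_equal(provenance(sol$assignmentA)$objective_value, best,
                   tolerance = 1e-9, info = sprintf("instance %d", k))
    }
  }
})
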