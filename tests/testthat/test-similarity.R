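test_that("global alignment identity matches hand-checkable cases", {
  expect_equal(alignIdentity("ACDEFG", "ACDEFG"), 1.0)
  expect_equal(alignIdentity("AAAA", "WWWW"), 0.0)
  # frozen from the DP oracle: ungapped alignment, 3 matches over length 7
  expect_equal(alignIdentity("GATTACA", "GCATGCT"), 3 / 7)
})

test_that("alignment scores agree with a naive DP table and with Biostrings", {
  skip_if_not_installed("Biostrings")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mat <- matrix(-1, 20, 20, dimnames = list(aa, aa)); diag(mat) <- 1
  set.seed(42)
  for (k in 1:20) {
    a <- paste(sample(aa, sample(5:30, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(5:30, 1), replace = TRUE), collapse = "")
    res <- alignGlobal(a, b)
    expect_equal(res$score, oracleNwScore(a, b), info = paste(a, b))
    pa <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2)
    expect_equal(res$score, Biostrings::score(pa), info = paste(a, b))
    # symmetry under the symmetric default scoring
    expect_equal(res$identity, alignGlobal(b, a)$identity)
  }
})

test_that("alignment rejects empty sequences and illegal characters", {
  expect_error(alignIdentity("", "ACD"), class = "leakSplit_invalid_input")
  expect_error(alignIdentity("ACD", "AZD"), "Z",
               class = "leakSplit_invalid_input")
  expect_equal(alignIdentity("AXA", "AXA"), 1.0)  # X is a legal residue
})

test_that("Morgan fingerprints are deterministic and canonical", {
  fp <- morganFingerprint("C", radius = 2, nBits = 2048)
  expect_s4_class(fp, "Fingerprint")
  expect_gt(length(onBits(fp)), 0)
  expect_identical(onBits(morganFingerprint("CCO")),
                   onBits(morganFingerprint("CCO")))
  # two spellings of ethanol give identical bit sets
  expect_identical(onBits(morganFingerprint("CCO")),
                   onBits(morganFingerprint("OCC")))
  expect_true(all(onBits(morganFingerprint("c1ccccc1CCO", nBits = 64)) < 64))
  expect_error(morganFingerprint("not a smiles(("),
               class = "leakSplit_parse_error")
  expect_error(morganFingerprint("CCO", radius = 4),
               class = "leakSplit_invalid_input")
})

test_that("dice and tanimoto follow set arithmetic and t = d/(2-d)", {
  a <- Fingerprint(c(1, 2, 3), 64)
  b <- Fingerprint(c(2, 3, 4), 64)
  expect_equal(diceSim(a, b), 2 * 2 / (3 + 3))
  expect_equal(tanimotoSim(a, b), 2 / 4)
  expect_equal(diceSim(a, a), 1.0)
  disjoint <- Fingerprint(c(10, 11), 64)
  expect_equal(diceSim(a, disjoint), 0.0)
  expect_equal(tanimotoSim(a, disjoint), 0.0)
  # empty-set conventions
  e <- Fingerprint(integer(), 64)
  expect_equal(diceSim(e, e), 1.0)
  expect_equal(tanimotoSim(e, e), 1.0)
  expect_equal(diceSim(e, a), 0.0)
  expect_error(diceSim(a, Fingerprint(1, 128)),
               class = "leakSplit_invalid_input")
  # identity t = d/(2-d) on random fingerprints, so tanimoto <= dice
  set.seed(7)
  for (k in 1:25) {
    x <- Fingerprint(sample(0:63, sample(0:20, 1)), 64)
    y <- Fingerprint(sample(0:63, sample(1:20, 1)), 64)
    d <- diceSim(x, y); t <- tanimotoSim(x, y)
    expect_equal(t, d / (2 - d))
    expect_lte(t, d + 1e-12)
    expect_equal(d, diceSim(y, x))
  }
})

test_that("buildSimilarityMatrix satisfies its invariants on random data", {
  set.seed(11)
  for (k in 1:100) {
    n <- sample(2:8, 1)
    ent <- generateSequenceFamilies(1, n, withinDivergence = runif(1, 0, 0.5),
                                    length = 30, seed = k)
    m <- buildSimilarityMatrix(ent, "nw-identity")
    expect_true(methods::validObject(m))
    expect_identical(entityIds(m), ent$id)
  }
})

test_that("matrix entries equal pairwise alignment calls", {
  seqs <- c("ACDEFGHIK", "ACDEFGHIW", "WWWWYYYY")
  ent <- entityTable(c("s1", "s2", "s3"), seqs)
  m <- buildSimilarityMatrix(ent, "nw-identity")
  v <- similarityValues(m)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(v[i, j], alignIdentity(seqs[i], seqs[j]))
  expect_equal(unname(diag(v)), rep(1, 3))
})

test_that("duplicate ids and bad precomputed matrices are rejected", {
  expect_error(entityTable(c("a", "a"), c("ACD", "ACE")),
               "duplicate", class = "leakSplit_invalid_input")
  ent <- entityTable(c("a", "b"), c("ACD", "ACE"))
  bad <- matrix(c(1, 0.4, 0.6, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(buildSimilarityMatrix(ent, "precomputed", precomputed = bad),
               "asymmetric", class = "leakSplit_validation_error")
  oor <- matrix(c(1, 1.2, 1.2, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(buildSimilarityMatrix(ent, "precomputed", precomputed = oor),
               class = "leakSplit_validation_error")
  # tiny excursions within 1e-6 are clipped, not rejected
  tiny <- matrix(c(1, 1 + 1e-8, 1 + 1e-8, 1), 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
  m <- buildSimilarityMatrix(ent, "precomputed", precomputed = tiny)
  expect_equal(max(similarityValues(m)), 1)
})

test_that("redundancy filter removes all pairs at or above the threshold", {
  # two identical sequences: exactly one survives
  ent <- entityTable(c("a", "b"), c("ACDEFG", "ACDEFG"))
  m <- buildSimilarityMatrix(ent, "nw-identity")
  expect_equal(nrow(redundancyFilter(ent, m, 0.4)), 1)

  # orthogonal entities: all survive
  ids <- letters[1:4]
  m0 <- SimilarityMatrix(ids, diag(1, 4), "precomputed")
  e0 <- entityTable(ids, rep("ACDE", 4))
  expect_equal(nrow(redundancyFilter(e0, m0, 0.4)), 4)

  expect_error(redundancyFilter(e0, m0, 0), class = "leakSplit_invalid_input")
  expect_error(redundancyFilter(e0, m0, 1.5), class = "leakSplit_invalid_input")

  # hand-written 5-entity instance checked against the exhaustive property
  ids <- paste0("x", 1:5)
  v <- diag(1, 5)
  dimnames(v) <- list(ids, ids)
  v[1, 2] <- v[2, 1] <- 0.9; v[2, 3] <- v[3, 2] <- 0.6
  v[4, 5] <- v[5, 4] <- 0.55; v[1, 5] <- v[5, 1] <- 0.2
  m5 <- SimilarityMatrix(ids, v, "precomputed")
  e5 <- entityTable(ids, c("AAAAAA", "AAAAA", "AAAA", "AAA", "AA"))
  kept <- redundancyFilter(e5, m5, 0.5)
  keptIds <- kept$id
  expect_true(all(v[keptIds, keptIds][upper.tri(diag(length(keptIds)))] < 0.5))
  for (dropped in setdiff(ids, keptIds))
    expect_true(any(v[dropped, keptIds] >= 0.5))
})

test_that("redundancy filter output never contains a pair above threshold", {
  set.seed(23)
  for (k in 1:20) {
    n <- sample(4:12, 1)
    m <- randomSimilarityMatrix(n)
    ent <- entityTable(entityIds(m),
                       vapply(seq_len(n), function(i)
                         paste(rep("A", sample(3:10, 1)), collapse = ""), ""))
    thr <- runif(1, 0.3, 0.9)
    kept <- redundancyFilter(ent, m, thr)$id
    if (length(kept) > 1) {
      sub <- similarityValues(m)[kept, kept]
      expect_lt(max(sub[upper.tri(sub)]), thr)
    }
  }
})
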