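#' Synthetic datasets with controlled leakage structure
#'
#' Generators that emulate the structure of the benchmark inputs this
#' package targets -- clustered protein families, clustered molecule
#' families sharing a scaffold, and bipartite interaction networks with
#' degree-preserving negatives -- so every splitting and scoring operation
#' is testable without external downloads.
#'
#' `generateSequenceFamilies` plants `nClusters` families: each family has
#' one random ancestor of length `length` drawn from a family-specific
#' sub-alphabet (sub-alphabets are disjoint across families while the
#' 20-letter amino-acid alphabet allows, making the ground-truth partition
#' unambiguous at moderate divergence), and `clusterSize` copies in which
#' every position is independently substituted with probability
#' `withinDivergence` (substitutions drawn uniformly from the 19 other
#' residues). No indels are introduced, mirroring the mutation model's
#' focus on identity structure rather than realistic evolution.
#'
#' @param nClusters number of families (>= 1).
#' @param clusterSize members per family (scalar or per-family vector).
#' @param withinDivergence per-position substitution probability in \[0, 1\].
#' @param length ancestor sequence length.
#' @param seed integer seed; output is a deterministic function of the
#'   arguments.
#' @return an [entityTable()] with a ground-truth `family` label column.
#' @examples
#' fam <- generateSequenceFamilies(3, 4, withinDivergence = 0.05, seed = 7)
#' table(fam$family)
#' @export
generateSequenceFamilies <- function(nClusters, clusterSize,
                                     withinDivergence = 0.05,
                                     length = 120, seed = 1) {
  if (nClusters < 1) invalidInput("nClusters must be >= 1")
  clusterSize <- rep_len(as.integer(clusterSize), nClusters)
  if (any(clusterSize < 1)) invalidInput("clusterSize must be >= 1")
  if (withinDivergence < 0 || withinDivergence > 1)
    invalidInput("withinDivergence must lie in [0, 1]")
  aa <- aminoAlphabet()
  withLocalSeed(seed, {
    subSize <- max(2L, length(aa) %/% nClusters)
    pool <- sample(aa)
    ids <- character(); seqs <- character(); fams <- integer()
    for (f in seq_len(nClusters)) {
      # disjoint sub-alphabets while 20 letters allow; wrap around beyond
      start <- ((f - 1) * subSize) %% length(aa)
      sub <- pool[(start + seq_len(subSize) - 1) %% length(aa) + 1]
      anc <- sample(sub, length, replace = TRUE)
      for (m in seq_len(clusterSize[f])) {
        s <- anc
        mut <- runif(length) < withinDivergence
        if (any(mut))
          s[mut] <- vapply(s[mut], function(res)
            sample(setdiff(aa, res), 1), "")
        ids <- c(ids, sprintf("fam%02d_seq%02d", f, m))
        seqs <- c(seqs, paste(s, collapse = ""))
        fams <- c(fams, f)
      }
    }
    entityTable(ids, seqs, family = sprintf("fam%02d", fams))
  })
}

# Hand-written valid scaffold SMILES. Multi-ring systems are used so the
# scaffold dominates the fingerprint bit set and families form real
# similarity clusters. Appending a substituent chain extends the last atom
# (always a ring carbon) and is pruned away by Murcko reduction, so
# decorated members keep their family's scaffold.
.builtinScaffolds <- c(
  "c1ccc2ccccc2c1",               # naphthalene
  "c1ccc2ncccc2c1",               # quinoline
  "c1ccc2[nH]ccc2c1",             # indole
  "c1ccc2occc2c1",                # benzofuran
  "c1ccc2sccc2c1",                # benzothiophene
  "c1ccc2cc3ccccc3cc2c1",         # anthracene
  "C1CCC2CCCCC2C1",               # decalin
  "C1CCc2ccccc2C1",               # tetralin
  "C1CCC2(CC1)CCCCC2",            # spiro[5.5]undecane
  "c1ccc2c(c1)OCO2",              # benzodioxole
  "c1ccc(cc1)c1ccccc1",           # biphenyl
  "c1ccc(cc1)Cc1ccccc1",          # diphenylmethane
  "c1ccc(cc1)CCc1ccccc1",         # bibenzyl
  "c1ccc(cc1)Oc1ccccc1",          # diphenyl ether
  "c1ccc(cc1)Nc1ccccc1",          # diphenylamine
  "c1ccc(cc1)C(=O)c1ccccc1",      # benzophenone
  "c1ccc(cc1)S(=O)(=O)c1ccccc1",  # diphenyl sulfone
  "c1ccc(cc1)c1ccncc1",           # phenylpyridine
  "C1CN(CCN1)c1ccccc1",           # phenylpiperazine
  "c1csc(n1)c1ccccc1",            # phenylthiazole
  "c1ccc(cc1)c1sccc1",            # phenylthiophene (ends on a ring carbon)
  "c1ccc(cc1)c1occc1",            # phenylfuran (ends on a ring carbon)
  "c1ccc(cc1)C2CCCCC2",           # phenylcyclohexane
  "c1ccc(cc1)N2CCCCC2"            # phenylpiperidine
)

# Substituents are concatenated into one linear chain appended to the
# scaffold SMILES. Chain-extendable fragments may appear anywhere; fragments
# ending in a terminal group (halogen, nitrile) must come last.
.chainSubstituents <- c("C", "CC", "CCC", "C(C)C", "CO", "CN", "CC=C")
.terminalSubstituents <- c("C", "CC", "CCC", "CO", "CCO", "CN",
                           "CF", "CCl", "CBr", "C(F)(F)F", "CC#N")

#' @rdname generateSequenceFamilies
#' @details `generateMoleculeFamilies` draws one scaffold per family from a
#'   built-in list of 24 hand-written valid ring
#'   systems and decorates each member with 1-3 random small substituent
#'   chains appended to the SMILES, so family members share their
#'   scaffold's Bemis-Murcko key while differing in side chains.
#' @return `generateMoleculeFamilies`: an [entityTable()] of SMILES with a
#'   `family` label column.
#' @export
generateMoleculeFamilies <- function(nClusters, clusterSize, seed = 1) {
  if (nClusters < 1) invalidInput("nClusters must be >= 1")
  if (nClusters > length(.builtinScaffolds))
    invalidInput(sprintf("at most %d molecule families supported (built-in scaffolds)",
                         length(.builtinScaffolds)))
  clusterSize <- rep_len(as.integer(clusterSize), nClusters)
  if (any(clusterSize < 1)) invalidInput("clusterSize must be >= 1")
  withLocalSeed(seed, {
    scaffolds <- sample(.builtinScaffolds, nClusters)
    ids <- character(); smiles <- character(); fams <- integer()
    for (f in seq_len(nClusters)) {
      for (m in seq_len(clusterSize[f])) {
        nsub <- sample(1:2, 1)
        deco <- paste0(
          paste(sample(.chainSubstituents, nsub - 1, replace = TRUE),
                collapse = ""),
          sample(.terminalSubstituents, 1))
        ids <- c(ids, sprintf("fam%02d_mol%02d", f, m))
        smiles <- c(smiles, paste0(scaffolds[f], deco))
        fams <- c(fams, f)
      }
    }
    entityTable(ids, smiles, family = sprintf("fam%02d", fams))
  })
}

#' Bipartite interaction network with degree-preserving negatives
#'
#' Samples positive interactions uniformly at the requested density, then
#' draws an equal number of negatives by configuration-model stub
#' matching: every entity receives exactly as many negative interactions
#' as it has positive ones. Collisions (a negative duplicating a positive
#' pair or an earlier negative) are rejected and the matching pass
#' restarts; a positive draw that admits no simple degree-preserving
#' negative set (a hub interacting with almost every counterpart) is
#' itself redrawn, still uniformly at the same density. All restarts count
#' against one retry cap, after which the generator errors and suggests
#' lowering the density. The exact two-sided degree preservation fixes the
#' positive:negative ratio at 1:1.
#'
#' @param entitiesA,entitiesB [entityTable()]s for the two dimensions.
#' @param density fraction of all A x B pairs drawn as positives, in (0, 1\].
#' @param seed integer seed; output is deterministic.
#' @param maxRetries cap on collision-resolution swaps (default 10000).
#' @return an [interactionTable()] with labels "1" (positive) / "0"
#'   (negative).
#' @examples
#' a <- entityTable(paste0("a", 1:6), rep("ACDEFG", 6))
#' b <- entityTable(paste0("b", 1:6), rep("ACDEFG", 6))
#' net <- generateInteractionNetwork(a, b, density = 0.3, seed = 3)
#' table(net$label)
#' @export
generateInteractionNetwork <- function(entitiesA, entitiesB, density,
                                       seed = 1, maxRetries = 10000) {
  entitiesA <- checkEntityTable(entitiesA)
  entitiesB <- checkEntityTable(entitiesB)
  if (!is.numeric(density) || length(density) != 1 ||
      density <= 0 || density > 1)
    invalidInput("density must lie in (0, 1]")
  nA <- nrow(entitiesA); nB <- nrow(entitiesB)
  withLocalSeed(seed, {
    nPos <- max(1L, round(density * nA * nB))
    tries <- 0L
    repeat {
      # uniform positive draw; redrawn when it admits no simple
      # degree-preserving negative set (a hub with positive degree above
      # the number of available non-partners makes one impossible)
      pos <- sample.int(nA * nB, nPos)
      posA <- (pos - 1L) %% nA + 1L
      posB <- (pos - 1L) %/% nA + 1L
      posKey <- paste(posA, posB)

      # configuration model: one stub per positive endpoint on each side;
      # A-stubs are matched to B-stubs one by one, rejecting collisions
      # (duplicate of a positive pair or of an earlier negative); dead ends
      # restart the pass, all counted against the retry cap
      stubsA <- posA
      stubsB <- posB
      negB <- NULL
      for (pass in seq_len(25L)) {
        tries <- tries + 1L
        if (tries > maxRetries)
          infeasibleError(
            "could not realize a degree-preserving negative set; lower the density")
        ordA <- sample(length(stubsA))
        remB <- sample(length(stubsB))
        cand_negB <- integer(length(stubsA))
        drawn <- character()
        ok <- TRUE
        for (i in ordA) {
          cand <- remB[!paste(stubsA[i], stubsB[remB]) %in% c(posKey, drawn)]
          if (!length(cand)) { ok <- FALSE; break }
          pick <- cand[1]
          cand_negB[i] <- stubsB[pick]
          drawn <- c(drawn, paste(stubsA[i], stubsB[pick]))
          remB <- remB[remB != pick]
        }
        if (ok) { negB <- cand_negB; break }
      }
      if (!is.null(negB)) break
    }
    interactionTable(
      c(entitiesA$id[posA], entitiesA$id[stubsA]),
      c(entitiesB$id[posB], entitiesB$id[negB]),
      rep(c("1", "0"), each = nPos))
  })
}
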