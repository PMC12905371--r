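#' Fingerprint: hashed circular (Morgan/ECFP) substructure bit set
#'
#' Stores the on-bit indices (0-based) of a folded binary fingerprint.
#'
#' @slot onBits sorted integer vector of 0-based on-bit indices.
#' @slot nBits total bit-vector length; every on-bit index is < nBits.
#' @export
setClass("Fingerprint",
  representation(onBits = "integer", nBits = "integer"))

setValidity("Fingerprint", function(object) {
  msg <- character()
  if (object@nBits < 1) msg <- c(msg, "nBits must be positive")
  if (length(object@onBits) &&
      (min(object@onBits) < 0 || max(object@onBits) >= object@nBits))
    msg <- c(msg, "every on-bit index must lie in [0, nBits)")
  if (anyDuplicated(object@onBits)) msg <- c(msg, "onBits must be unique")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Fingerprint", function(object) {
  cat(sprintf("Fingerprint: %d/%d bits set\n",
              length(object@onBits), object@nBits))
})

#' @rdname Fingerprint-class
#' @param onBits,nBits see slots.
#' @export
Fingerprint <- function(onBits, nBits) {
  new("Fingerprint", onBits = sort(unique(as.integer(onBits))),
      nBits = as.integer(nBits))
}

#' @rdname accessors
#' @export
setGeneric("onBits", function(x, ...) standardGeneric("onBits"))
#' @rdname accessors
setMethod("onBits", "Fingerprint", function(x, ...) x@onBits)
#' @rdname accessors
#' @export
setGeneric("nBits", function(x, ...) standardGeneric("nBits"))
#' @rdname accessors
setMethod("nBits", "Fingerprint", function(x, ...) x@nBits)

#' Alignment scoring configuration
#'
#' Defaults: match +1, mismatch -1, linear gap -2, identity denominator =
#' alignment length. A deliberately simple published-style scheme whose DP
#' table can be checked by hand; substitution-matrix scoring is outside the
#' intended scope.
#'
#' @param match,mismatch,gap numeric scores (gap per position, linear).
#' @return a list with components `match`, `mismatch`, `gap`.
#' @export
alignmentScoring <- function(match = 1, mismatch = -1, gap = -2) {
  list(match = as.numeric(match), mismatch = as.numeric(mismatch),
       gap = as.numeric(gap))
}

#' Global alignment identity between two amino-acid sequences
#'
#' Needleman-Wunsch global alignment under a linear gap penalty; the
#' percentage of matching residues is the number of identical aligned
#' residue pairs divided by the alignment length (gap columns included).
#' Exactly one optimal alignment is reported: the DP traceback prefers
#' diagonal over up over left, so tied optima resolve deterministically
#' (ties can correspond to different identities; the reported value always
#' comes from this one alignment).
#'
#' @param seqA,seqB non-empty strings over the 20 amino acids plus X.
#' @param scoring an [alignmentScoring()] configuration.
#' @return `alignIdentity`: identity in \[0, 1\]. `alignGlobal`: a list with
#'   `score`, `identity`, `matches`, `length`, `aligned_a`, `aligned_b`.
#' @examples
#' alignIdentity("ACDEFG", "ACDEFG")  # 1
#' alignGlobal("GATTACA", "GCATGCT")$identity
#' @export
alignIdentity <- function(seqA, seqB, scoring = alignmentScoring()) {
  alignGlobal(seqA, seqB, scoring)$identity
}

#' @rdname alignIdentity
#' @export
alignGlobal <- function(seqA, seqB, scoring = alignmentScoring()) {
  checkSequencePayload(seqA, "first sequence")
  checkSequencePayload(seqB, "second sequence")
  .nw_align_cpp(seqA, seqB, scoring$match, scoring$mismatch, scoring$gap)
}

# OpenBabel hashes extended-connectivity fingerprints at fixed diameters;
# radius r maps to ECFP(2r).
.ecfpName <- c(`0` = "ECFP0", `1` = "ECFP2", `2` = "ECFP4", `3` = "ECFP6",
               `5` = "ECFP10")

#' Morgan (extended-connectivity) fingerprint of a molecule
#'
#' Computes a hashed circular fingerprint via OpenBabel (ChemmineOB) and
#' folds it to `nBits` by taking each on-bit index modulo `nBits`. ECFP4
#' corresponds to `radius = 2`, the default. OpenBabel provides fingerprints
#' at diameters 0/2/4/6/10, so the supported radii are 0, 1, 2, 3 and 5.
#' The binary (not count) variant is used.
#'
#' @param smiles a single SMILES string.
#' @param radius neighborhood radius; one of 0, 1, 2, 3, 5 (default 2).
#' @param nBits folded fingerprint length, >= 16 (default 2048).
#' @return a [Fingerprint-class] object.
#' @examples
#' fp <- morganFingerprint("CCO")
#' length(onBits(fp)) > 0
#' @export
morganFingerprint <- function(smiles, radius = 2, nBits = 2048) {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(smiles))
    invalidInput("smiles must be a single non-empty string")
  if (!as.character(radius) %in% names(.ecfpName))
    invalidInput(sprintf(
      "radius %s unsupported: OpenBabel circular fingerprints exist for radii %s",
      format(radius), paste(names(.ecfpName), collapse = ", ")))
  if (nBits < 16) invalidInput("nBits must be >= 16")
  bits <- .obFingerprintBits(smiles, .ecfpName[[as.character(radius)]])
  Fingerprint(unique(bits %% as.integer(nBits)), nBits)
}

# Raw 0-based on-bit indices of the 4096-bit OpenBabel fingerprint.
.obFingerprintBits <- function(smiles, fpName) {
  mol <- .parseSmilesOB(smiles)
  v <- ChemmineOB::fingerprint_OB(mol, fpName)
  which(v != 0) - 1L
}

.parseSmilesOB <- function(smiles) {
  res <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", smiles, identity)),
    error = function(e) NULL)
  if (is.null(res))
    parseError(sprintf("unparsable SMILES: '%s'", smiles))
  res
}

.pairCoef <- function(a, b, f) {
  if (!methods::is(a, "Fingerprint") || !methods::is(b, "Fingerprint"))
    invalidInput("both arguments must be Fingerprint objects")
  if (a@nBits != b@nBits)
    invalidInput(sprintf("fingerprint lengths differ (%d vs %d)",
                         a@nBits, b@nBits))
  ni <- length(intersect(a@onBits, b@onBits))
  f(ni, length(a@onBits), length(b@onBits))
}

#' Dice and Tanimoto similarity of two fingerprints
#'
#' `diceSim` returns 2|A&B| / (|A| + |B|); `tanimotoSim` returns
#' |A&B| / |A|B|. Two empty bit sets compare as identical (similarity 1);
#' empty versus non-empty gives 0. For any pair,
#' `tanimotoSim = diceSim / (2 - diceSim)`, hence Tanimoto <= Dice.
#'
#' @param a,b [Fingerprint-class] objects with equal `nBits`.
#' @return similarity in \[0, 1\].
#' @examples
#' a <- Fingerprint(c(1, 2, 3), 64); b <- Fingerprint(c(2, 3, 4), 64)
#' diceSim(a, b)      # 2*2/(3+3)
#' tanimotoSim(a, b)  # 2/4
#' @export
diceSim <- function(a, b) {
  .pairCoef(a, b, function(ni, na, nb) {
    if (na + nb == 0) 1.0 else 2 * ni / (na + nb)
  })
}

#' @rdname diceSim
#' @export
tanimotoSim <- function(a, b) {
  .pairCoef(a, b, function(ni, na, nb) {
    nu <- na + nb - ni
    if (nu == 0) 1.0 else ni / nu
  })
}

#' Assemble a validated similarity matrix over a dataset
#'
#' Computes all pairwise similarities under the chosen metric (or validates
#' a precomputed matrix) and returns a [SimilarityMatrix-class] whose row
#' order matches the input entity order.
#'
#' Metrics: `"nw-identity"` (Needleman-Wunsch identity on sequences,
#' [alignIdentity()]), `"morgan-dice"` (Dice on Morgan fingerprints),
#' `"ecfp4-tanimoto"` (Tanimoto on radius-2 fingerprints), and
#' `"precomputed"`. Precomputed values are clipped into \[0, 1\] only when
#' within 1e-6 of the range and the diagonal is snapped to 1 under the same
#' tolerance; larger violations are rejected so data errors are not
#' silently hidden.
#'
#' @param entities an [entityTable()] (>= 2 rows).
#' @param metric one of the four metric names above.
#' @param precomputed for `metric = "precomputed"`: a square numeric matrix
#'   with entity ids as dimnames, or the path of a TSV file whose first row
#'   and column hold the ids.
#' @param scoring alignment scoring for `"nw-identity"`.
#' @param radius,nBits fingerprint parameters for the fingerprint metrics.
#' @return a [SimilarityMatrix-class].
#' @examples
#' ent <- entityTable(c("a", "b"), c("ACDEFG", "ACDEFG"))
#' buildSimilarityMatrix(ent, "nw-identity")
#' @export
buildSimilarityMatrix <- function(entities,
                                  metric = c("nw-identity", "morgan-dice",
                                             "ecfp4-tanimoto", "precomputed"),
                                  precomputed = NULL,
                                  scoring = alignmentScoring(),
                                  radius = 2, nBits = 2048) {
  metric <- match.arg(metric)
  entities <- checkEntityTable(entities)
  n <- nrow(entities)
  if (n < 2) invalidInput("need at least 2 entities")
  ids <- entities$id

  if (metric == "precomputed") {
    if (is.null(precomputed))
      invalidInput("metric 'precomputed' requires a matrix or a TSV path")
    if (is.character(precomputed) && length(precomputed) == 1)
      precomputed <- readSimilarityTsv(precomputed, validate = FALSE)
    if (methods::is(precomputed, "SimilarityMatrix"))
      precomputed <- similarityValues(precomputed)
    miss <- setdiff(ids, rownames(precomputed))
    if (length(miss))
      validationError(sprintf("precomputed matrix missing ids: %s",
                              paste(miss, collapse = ", ")))
    v <- .validatePrecomputed(precomputed[ids, ids, drop = FALSE])
  } else if (metric == "nw-identity") {
    for (i in seq_len(n)) checkSequencePayload(entities$payload[i],
                                               sprintf("sequence '%s'", ids[i]))
    v <- diag(1, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      v[i, j] <- v[j, i] <- alignIdentity(entities$payload[i],
                                          entities$payload[j], scoring)
  } else {
    if (metric == "ecfp4-tanimoto") radius <- 2
    fps <- lapply(entities$payload, morganFingerprint,
                  radius = radius, nBits = nBits)
    simFun <- if (metric == "morgan-dice") diceSim else tanimotoSim
    v <- diag(1, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      v[i, j] <- v[j, i] <- simFun(fps[[i]], fps[[j]])
  }
  SimilarityMatrix(ids, v, metricName = metric, weights = entities$weight)
}

.validatePrecomputed <- function(v, tol = 1e-6) {
  v <- as.matrix(v)
  if (nrow(v) != ncol(v)) validationError("precomputed matrix must be square")
  if (any(!is.finite(v))) validationError("precomputed matrix has non-finite values")
  if (min(v) < -tol || max(v) > 1 + tol)
    validationError(sprintf(
      "precomputed similarities outside [0, 1] beyond tolerance %g (range %g..%g)",
      tol, min(v), max(v)))
  v <- pmin(pmax(v, 0), 1)
  if (max(abs(v - t(v))) > 1e-9) {
    if (max(abs(v - t(v))) > tol)
      validationError("precomputed matrix asymmetric beyond tolerance")
    v <- (v + t(v)) / 2
  }
  if (max(abs(diag(v) - 1)) > tol)
    validationError("precomputed matrix diagonal must equal 1")
  diag(v) <- 1
  v
}

#' Greedy redundancy filter (CD-HIT-style)
#'
#' Removes near-duplicate entities so that no retained pair has similarity
#' at or above `threshold`. Entities are visited by decreasing payload
#' length (ties by id, ascending) and retained iff their similarity to
#' every already-retained entity is below the threshold -- the greedy
#' incremental scheme used by sequence-redundancy tools such as CD-HIT
#' (e.g. a 40% identity cutoff).
#'
#' @param entities an [entityTable()].
#' @param matrix a [SimilarityMatrix-class] covering all entity ids.
#' @param threshold similarity cutoff in (0, 1\].
#' @return the retained rows of `entities`, in original row order.
#' @export
redundancyFilter <- function(entities, matrix, threshold) {
  entities <- checkEntityTable(entities)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1)
    invalidInput("threshold must lie in (0, 1]")
  miss <- setdiff(entities$id, entityIds(matrix))
  if (length(miss))
    consistencyError(sprintf("matrix does not cover ids: %s",
                             paste(miss, collapse = ", ")))
  v <- similarityValues(matrix)
  ord <- order(-nchar(entities$payload), entities$id)
  retained <- character()
  for (i in ord) {
    id <- entities$id[i]
    if (!length(retained) || all(v[id, retained] < threshold))
      retained <- c(retained, id)
  }
  entities[entities$id %in% retained, , drop = FALSE]
}
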