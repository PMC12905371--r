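#' Baseline reference splitters: random, stratified, scaffold
#'
#' The three splitting techniques recommended by MoleculeNet-style
#' benchmarks, implemented deterministically so that optimized splits can
#' be compared against them on the same similarity matrix.
#'
#' `randomSplit` deals entities to splits after a seeded uniform shuffle;
#' split sizes follow largest-remainder rounding of the target fractions
#' (ties in the remainders broken in split order).
#'
#' `stratifiedSplit` applies `randomSplit` independently within each level
#' of the stratification label, so each split's label composition matches
#' the global one up to rounding. A stratum smaller than the number of
#' splits triggers a warning and a best-effort allocation (some splits
#' receive none of that stratum).
#'
#' `scaffoldSplit` groups molecules by Bemis-Murcko scaffold
#' ([murckoScaffoldKey()]; acyclic molecules form one shared empty-scaffold
#' group), sorts groups by size descending (ties by scaffold key), and
#' fills the splits in spec order: groups go to the first split until its
#' largest-remainder count target is reached, then to the next. No
#' scaffold group ever straddles two splits; a single indivisible group
#' can therefore leave later splits empty (warned).
#'
#' @param entities an [entityTable()]; for `scaffoldSplit` the payloads
#'   must be valid SMILES, for `stratifiedSplit` the `spec`'s
#'   `stratifyOn` column must be present.
#' @param spec a [splitSpec()]; `seed` drives the shuffle.
#' @return a [SplitAssignment-class].
#' @examples
#' ent <- entityTable(paste0("m", 1:10), rep("CCO", 10))
#' randomSplit(ent, splitSpec(c(train = 0.8, test = 0.2)))
#' @name baselines
NULL

#' @rdname baselines
#' @export
randomSplit <- function(entities, spec) {
  entities <- checkEntityTable(entities)
  methods::validObject(spec)
  n <- nrow(entities)
  ns <- length(spec@splitNames)
  if (n < ns)
    infeasibleError(sprintf("%d entities cannot fill %d splits", n, ns))
  counts <- largestRemainder(n, spec@fractions)
  perm <- withLocalSeed(spec@seed, sample.int(n))
  # shuffled entities are dealt block-wise to the splits
  asg <- setNames(rep(spec@splitNames, counts), entities$id[perm])
  asg <- asg[entities$id]
  SplitAssignment(asg, spec@splitNames,
                  list(tool = "leakSplit::randomSplit", seed = spec@seed))
}

#' @rdname baselines
#' @export
stratifiedSplit <- function(entities, spec) {
  entities <- checkEntityTable(entities)
  methods::validObject(spec)
  if (!nzchar(spec@stratifyOn))
    invalidInput("spec must name a stratifyOn label column")
  if (!spec@stratifyOn %in% names(entities))
    invalidInput(sprintf("entities lack stratification column '%s'",
                         spec@stratifyOn))
  lab <- as.character(entities[[spec@stratifyOn]])
  if (anyNA(lab)) invalidInput("stratification labels must not be NA")
  ns <- length(spec@splitNames)
  asg <- character(nrow(entities))
  names(asg) <- entities$id
  withLocalSeed(spec@seed, {
    for (lev in sort(unique(lab))) {
      idx <- which(lab == lev)
      if (length(idx) < ns)
        warning(sprintf(
          "stratum '%s' has %d entities for %d splits; best-effort allocation",
          lev, length(idx), ns))
      counts <- largestRemainder(length(idx), spec@fractions)
      perm <- sample.int(length(idx))
      asg[idx[perm]] <- rep(spec@splitNames, counts)
    }
  })
  SplitAssignment(asg, spec@splitNames,
                  list(tool = "leakSplit::stratifiedSplit", seed = spec@seed,
                       stratify_on = spec@stratifyOn))
}

#' @rdname baselines
#' @export
scaffoldSplit <- function(entities, spec) {
  entities <- checkEntityTable(entities)
  methods::validObject(spec)
  keys <- vapply(seq_len(nrow(entities)), function(i) {
    tryCatch(murckoScaffoldKey(entities$payload[i]),
             leakSplit_parse_error = function(e)
               parseError(sprintf("row %d (id '%s'): %s", i, entities$id[i],
                                  conditionMessage(e))))
  }, "")
  groups <- split(seq_len(nrow(entities)), keys)
  ord <- order(-lengths(groups), names(groups))
  groups <- groups[ord]

  n <- nrow(entities)
  targets <- largestRemainder(n, spec@fractions)
  ns <- length(spec@splitNames)
  asg <- character(n)
  names(asg) <- entities$id
  s <- 1L
  filled <- 0L
  for (g in groups) {
    while (s < ns && filled >= targets[s]) { s <- s + 1L; filled <- 0L }
    asg[g] <- spec@splitNames[s]
    filled <- filled + length(g)
  }
  empty <- setdiff(spec@splitNames, unique(asg))
  if (length(empty))
    warning(sprintf("indivisible scaffold groups left split(s) empty: %s",
                    paste(empty, collapse = ", ")))
  SplitAssignment(asg, spec@splitNames,
                  list(tool = "leakSplit::scaffoldSplit", seed = spec@seed,
                       n_scaffold_groups = length(groups)))
}
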