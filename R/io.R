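#' Readers and writers for the standard on-disk formats
#'
#' FASTA sequence sets, SMILES CSV tables, interaction TSVs, precomputed
#' similarity-matrix TSVs, split-assignment TSVs and JSON leakage reports.
#' Every writer round-trips through its reader.
#'
#' @name leakSplit-io
NULL

#' @rdname leakSplit-io
#' @param path file path.
#' @details `readFastaEntities` reads a multi-record FASTA (wrapped lines,
#'   `>` headers) via Biostrings; the first whitespace-delimited header
#'   token becomes the entity id.
#' @return `readFastaEntities`: an [entityTable()] of sequences.
#' @export
readFastaEntities <- function(path) {
  if (!file.exists(path)) invalidInput(sprintf("file not found: %s", path))
  seqs <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e)
                     parseError(sprintf("cannot parse FASTA '%s': %s",
                                        path, conditionMessage(e))))
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1)
  entityTable(ids, as.character(seqs))
}

#' @rdname leakSplit-io
#' @param entities an [entityTable()].
#' @export
writeFastaEntities <- function(entities, path) {
  entities <- checkEntityTable(entities)
  x <- Biostrings::AAStringSet(setNames(entities$payload, entities$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname leakSplit-io
#' @param idColumn,smilesColumn CSV column names holding the id and the
#'   SMILES string; all other columns are kept as labels.
#' @return `readSmilesCsv`: an [entityTable()] of molecules with label
#'   columns.
#' @export
readSmilesCsv <- function(path, idColumn = "id", smilesColumn = "smiles") {
  if (!file.exists(path)) invalidInput(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(idColumn, smilesColumn))
    if (!col %in% names(df))
      parseError(sprintf("CSV '%s' lacks column '%s'", path, col))
  labels <- df[, setdiff(names(df), c(idColumn, smilesColumn)), drop = FALSE]
  out <- entityTable(df[[idColumn]], df[[smilesColumn]])
  cbind(out, labels)
}

#' @rdname leakSplit-io
#' @export
writeSmilesCsv <- function(entities, path) {
  entities <- checkEntityTable(entities)
  df <- data.frame(id = entities$id, smiles = entities$payload,
                   entities[, setdiff(names(entities),
                                      c("id", "payload", "weight")),
                            drop = FALSE],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname leakSplit-io
#' @param positiveLabel,negativeLabel strings encoding the interaction
#'   label in the TSV (defaults "1"/"0").
#' @return `readInteractionTsv`: an [interactionTable()].
#' @export
readInteractionTsv <- function(path, positiveLabel = "1",
                               negativeLabel = "0") {
  if (!file.exists(path)) invalidInput(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, header = TRUE,
                          check.names = FALSE)
  if (ncol(df) < 3)
    parseError(sprintf("interaction TSV '%s' needs 3 columns (id_a, id_b, label)",
                       path))
  lab <- as.character(df[[3]])
  bad <- which(!lab %in% c(positiveLabel, negativeLabel))
  if (length(bad))
    parseError(sprintf("interaction TSV '%s' line %d: unknown label '%s'",
                       path, bad[1] + 1L, lab[bad[1]]))
  interactionTable(df[[1]], df[[2]],
                   ifelse(lab == positiveLabel, "1", "0"))
}

#' @rdname leakSplit-io
#' @param interactions an [interactionTable()], optionally with a `split`
#'   column.
#' @export
writeInteractionTsv <- function(interactions, path) {
  utils::write.table(interactions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname leakSplit-io
#' @param validate validate the matrix invariants on read (default TRUE).
#' @return `readSimilarityTsv`: a numeric matrix with id dimnames (or a
#'   [SimilarityMatrix-class] when `validate = TRUE`).
#' @details The similarity-matrix TSV holds ids in the first row and first
#'   column and similarities in the cells.
#' @export
readSimilarityTsv <- function(path, validate = TRUE) {
  if (!file.exists(path)) invalidInput(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          row.names = 1)
  m <- as.matrix(df)
  if (!is.numeric(m))
    parseError(sprintf("similarity TSV '%s' has non-numeric cells", path))
  if (!validate) return(m)
  v <- .validatePrecomputed(m)
  SimilarityMatrix(rownames(m), v, metricName = "precomputed")
}

#' @rdname leakSplit-io
#' @param matrix a [SimilarityMatrix-class] or numeric matrix with dimnames.
#' @export
writeSimilarityTsv <- function(matrix, path) {
  if (methods::is(matrix, "SimilarityMatrix"))
    matrix <- similarityValues(matrix)
  utils::write.table(matrix, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname leakSplit-io
#' @param splitNames optional ordered split names; defaults to order of
#'   first appearance in the file.
#' @details The split-assignment TSV has two columns `id<TAB>split`; a
#'   header line is detected (first line equal to `id<TAB>split`) and
#'   optional.
#' @return `readAssignmentTsv`: a [SplitAssignment-class].
#' @export
readAssignmentTsv <- function(path, splitNames = NULL) {
  if (!file.exists(path)) invalidInput(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lineNo <- which(nzchar(lines))
  lines <- lines[lineNo]
  if (!length(lines)) parseError(sprintf("assignment TSV '%s' is empty", path))
  if (identical(tolower(lines[1]), "id\tsplit")) {
    lines <- lines[-1]; lineNo <- lineNo[-1]
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  badLen <- which(lengths(parts) != 2)
  if (length(badLen))
    parseError(sprintf("assignment TSV '%s' line %d: expected 'id<TAB>split'",
                       path, lineNo[badLen[1]]))
  ids <- vapply(parts, `[`, "", 1)
  splits <- vapply(parts, `[`, "", 2)
  if (anyDuplicated(ids))
    parseError(sprintf("assignment TSV '%s': duplicate id '%s'",
                       path, ids[duplicated(ids)][1]))
  if (is.null(splitNames))
    splitNames <- setdiff(unique(splits), UNASSIGNED)
  SplitAssignment(setNames(splits, ids), splitNames,
                  list(source = path))
}

#' @rdname leakSplit-io
#' @param x a [SplitAssignment-class] (writer) or [LeakageReport-class]
#'   (report writer).
#' @export
writeAssignmentTsv <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("id\tsplit", con)
  writeLines(paste(names(assignment(x)), assignment(x), sep = "\t"), con)
  invisible(path)
}

#' @rdname leakSplit-io
#' @export
writeLeakageJson <- function(x, path) {
  pp <- perPairLeak(x)
  perPair <- setNames(as.list(pp$leaked_mass),
                      paste(pp$split_a, pp$split_b, sep = "~"))
  jsonlite::write_json(
    list(scaled_total = scaledTotal(x),
         max_single_leak = maxSingleLeak(x),
         per_pair = perPair,
         assigned_fraction = assignedFraction(x)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
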