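# Classed conditions so callers (and the CLI exit-code mapping) can
# distinguish bad input (2) from infeasible optimization problems (1).
lsError <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "leakSplit_error"),
                      call = call))
}
invalidInput <- function(msg) lsError(msg, "leakSplit_invalid_input")
parseError <- function(msg) lsError(msg, "leakSplit_parse_error")
consistencyError <- function(msg) lsError(msg, "leakSplit_consistency_error")
infeasibleError <- function(msg) lsError(msg, "leakSplit_infeasible_error")
validationError <- function(msg) lsError(msg, "leakSplit_validation_error")

# Run code under a given seed without disturbing the caller's RNG stream.
withLocalSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Construct a validated entity table
#'
#' The in-memory representation of a dataset to be split: one row per
#' entity with a unique `id`, a `payload` (SMILES string or amino-acid
#' sequence), a non-negative `weight` (default 1), and any further columns
#' kept as labels (used e.g. for stratification).
#'
#' @param id character vector of unique, non-empty entity ids.
#' @param payload character vector of SMILES strings or sequences.
#' @param weight non-negative numeric weights, recycled if scalar.
#' @param ... further equal-length label columns.
#' @return a `data.frame` with columns `id`, `payload`, `weight`, then labels.
#' @examples
#' entityTable(id = c("p1", "p2"), payload = c("ACDEF", "ACDEG"))
#' @export
entityTable <- function(id, payload, weight = 1, ...) {
  id <- as.character(id)
  payload <- as.character(payload)
  if (length(id) != length(payload))
    invalidInput("id and payload must have the same length")
  if (any(!nzchar(id)) || anyNA(id)) invalidInput("entity ids must be non-empty")
  if (anyDuplicated(id))
    invalidInput(sprintf("duplicate entity ids: %s",
                         paste(unique(id[duplicated(id)]), collapse = ", ")))
  if (any(!nzchar(payload)) || anyNA(payload))
    invalidInput("entity payloads must be non-empty")
  weight <- rep_len(as.numeric(weight), length(id))
  if (any(!is.finite(weight)) || any(weight < 0))
    invalidInput("weights must be finite and >= 0")
  data.frame(id = id, payload = payload, weight = weight, ...,
             stringsAsFactors = FALSE)
}

checkEntityTable <- function(entities) {
  if (!is.data.frame(entities) ||
      !all(c("id", "payload") %in% names(entities)))
    invalidInput("entities must be a data.frame with 'id' and 'payload' columns")
  if (!"weight" %in% names(entities)) entities$weight <- 1
  entityTable(entities$id, entities$payload, entities$weight)
  entities
}

# Largest-remainder apportionment of n items to target fractions.
# Ties in the fractional remainders are broken in split order.
largestRemainder <- function(n, fractions) {
  exact <- n * fractions
  counts <- floor(exact)
  rem <- exact - counts
  short <- n - sum(counts)
  if (short > 0) {
    ord <- order(-rem, seq_along(fractions))
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

aminoAlphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

checkSequencePayload <- function(seq, what = "sequence") {
  if (!nzchar(seq)) invalidInput(sprintf("empty %s", what))
  ok <- c(aminoAlphabet(), "X")
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), ok)
  if (length(bad))
    invalidInput(sprintf("illegal character '%s' in %s (alphabet: 20 amino acids plus X)",
                         bad[[1]], what))
  invisible(seq)
}
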