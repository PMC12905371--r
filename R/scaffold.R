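# Bemis-Murcko scaffold extraction on the OpenBabel-parsed molecular graph.
#
# The scaffold is the ring systems plus the linkers connecting them: side
# chains are removed by iteratively deleting degree-1 atoms. Acyclic
# molecules reduce to the empty scaffold. The scaffold *key* is a canonical
# string of the vertex-colored scaffold graph (element symbols as vertex
# colors; bond orders encoded as colored subdivision vertices) obtained via
# igraph's BLISS canonical permutation, so two molecules share a key iff
# their scaffold graphs are isomorphic as colored graphs.

.molGraph <- function(smiles) {
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e)
                    parseError(sprintf("unparsable SMILES: '%s'", smiles)))
  sdf <- sdf[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_\\d+$", "", rownames(ab))
  if (length(elements) == 0)
    parseError(sprintf("SMILES parses to an empty molecule: '%s'", smiles))
  edges <- if (is.null(bb) || nrow(bb) == 0) {
    matrix(integer(), ncol = 2)
  } else {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  }
  orders <- if (is.null(bb) || nrow(bb) == 0) integer()
            else as.integer(bb[, 3])
  list(elements = elements, edges = edges, orders = orders)
}

# Indices of scaffold atoms: iteratively strip degree-1 vertices.
.scaffoldAtoms <- function(g) {
  n <- length(g$elements)
  keep <- rep(TRUE, n)
  if (nrow(g$edges) == 0) return(integer())
  repeat {
    deg <- integer(n)
    for (k in seq_len(nrow(g$edges))) {
      i <- g$edges[k, 1]; j <- g$edges[k, 2]
      if (keep[i] && keep[j]) { deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L }
    }
    drop <- keep & deg <= 1
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  which(keep)
}

#' Canonical Bemis-Murcko scaffold key of a molecule
#'
#' Reduces a molecule to its Bemis-Murcko scaffold (ring systems plus
#' linkers; side chains pruned) and returns a canonical string key:
#' molecules receive the same key iff their scaffold graphs are identical
#' as element- and bond-order-colored graphs. Acyclic molecules share the
#' empty-scaffold key `""` (one common group, matching the usual
#' scaffold-split convention).
#'
#' @param smiles a single SMILES string.
#' @return a character scaffold key.
#' @examples
#' murckoScaffoldKey("c1ccccc1CC") == murckoScaffoldKey("c1ccccc1CCO")
#' murckoScaffoldKey("CCO")  # ""
#' @export
murckoScaffoldKey <- function(smiles) {
  g <- .molGraph(smiles)
  atoms <- .scaffoldAtoms(g)
  if (length(atoms) == 0) return("")
  sel <- g$edges[, 1] %in% atoms & g$edges[, 2] %in% atoms
  edges <- g$edges[sel, , drop = FALSE]
  orders <- g$orders[sel]
  idx <- match(seq_along(g$elements), atoms)  # old -> new vertex index
  elements <- g$elements[atoms]

  # Colored graph: scaffold atoms colored by element, each bond replaced by
  # a subdivision vertex colored by bond order (keeps colors on vertices,
  # which is what BLISS canonicalization supports).
  nAtoms <- length(atoms)
  nBonds <- nrow(edges)
  colorNames <- c(sort(unique(elements)),
                  paste0("bond", sort(unique(orders))))
  vcolor <- c(match(elements, colorNames),
              match(paste0("bond", orders), colorNames))
  el <- matrix(0L, nrow = 2 * nBonds, ncol = 2)
  for (k in seq_len(nBonds)) {
    bv <- nAtoms + k
    el[2 * k - 1, ] <- c(idx[edges[k, 1]], bv)
    el[2 * k, ] <- c(idx[edges[k, 2]], bv)
  }
  gr <- igraph::make_graph(t(el), n = nAtoms + nBonds, directed = FALSE)
  perm <- igraph::canonical_permutation(gr, colors = vcolor)$labeling
  grc <- igraph::permute(gr, perm)
  colc <- integer(length(vcolor))
  colc[perm] <- vcolor
  em <- igraph::as_edgelist(grc)
  em <- t(apply(em, 1, sort))
  em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
  paste0("v:", paste(colorNames[colc], collapse = ","),
         ";e:", paste(em[, 1], em[, 2], sep = "-", collapse = ","))
}
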