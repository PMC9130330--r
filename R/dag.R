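#' Construct a directed acyclic graph over named nodes
#'
#' The graph is held as a named list of parent sets. Acyclicity is checked
#' on construction and on every mutation.
#'
#' @param nodes Character vector of node names (declaration order is kept
#'   and used for deterministic tie-breaking everywhere).
#' @param arcs Two-column character matrix (or data frame) of
#'   `(parent, child)` pairs; may be empty.
#' @return An object of class `"dag"`.
#' @export
#' @examples
#' dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
dag <- function(nodes, arcs = NULL) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes))
  parents <- stats::setNames(rep(list(character()), length(nodes)), nodes)
  g <- structure(list(nodes = nodes, parents = parents), class = "dag")
  if (!is.null(arcs) && NROW(arcs) > 0L) {
    arcs <- as.matrix(arcs)
    for (i in seq_len(nrow(arcs)))
      g <- add_arc(g, arcs[i, 1L], arcs[i, 2L])
  }
  g
}

#' @export
print.dag <- function(x, ...) {
  a <- arcs(x)
  cat(sprintf("dag: %d nodes, %d arcs\n", length(x$nodes), nrow(a)))
  if (nrow(a))
    cat(paste(sprintf("  %s -> %s", a[, 1L], a[, 2L]), collapse = "\n"), "\n")
  invisible(x)
}

#' Arc set of a DAG
#' @param g A `dag`.
#' @return Two-column character matrix `(parent, child)`, ordered by child
#'   then parent in node declaration order.
#' @export
arcs <- function(g) {
  out <- matrix(character(), 0L, 2L,
                dimnames = list(NULL, c("from", "to")))
  for (child in g$nodes)
    for (p in g$parents[[child]])
      out <- rbind(out, c(p, child))
  out
}

# TRUE iff a directed path from -> ... -> to exists.
has_path <- function(g, from, to) {
  if (from == to) return(TRUE)
  children <- lapply(g$parents, identity)
  stack <- from
  seen <- character()
  while (length(stack)) {
    cur <- stack[[1L]]; stack <- stack[-1L]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    kids <- g$nodes[vapply(g$nodes, function(n) cur %in% g$parents[[n]],
                           FALSE)]
    if (to %in% kids) return(TRUE)
    stack <- c(stack, kids)
  }
  FALSE
}

#' Add an arc, refusing cycles
#' @param g A `dag`.
#' @param from,to Parent and child node names.
#' @return The modified `dag`.
#' @export
add_arc <- function(g, from, to) {
  stopifnot(from %in% g$nodes, to %in% g$nodes, from != to)
  if (from %in% g$parents[[to]]) return(g)
  if (has_path(g, to, from))
    stop("adding ", from, " -> ", to, " would create a cycle")
  g$parents[[to]] <- c(g$parents[[to]], from)
  g
}

#' Remove an arc
#' @inheritParams add_arc
#' @return The modified `dag`.
#' @export
remove_arc <- function(g, from, to) {
  g$parents[[to]] <- setdiff(g$parents[[to]], from)
  g
}

#' Topological order of a DAG
#'
#' Kahn's algorithm, stable with respect to node declaration order: among
#' the nodes whose parents have all been emitted, the one declared first is
#' emitted first, so the forward-sampling order (roots down to leaves) is
#' deterministic.
#'
#' @param g A `dag`.
#' @return Character vector of node names, every parent before its children.
#' @export
topological_order <- function(g) {
  remaining <- g$nodes
  parents <- g$parents
  out <- character()
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(n)
      length(intersect(parents[[n]], remaining)) == 0L, FALSE)]
    if (!length(ready)) stop("cycle detected: no topological order exists")
    nxt <- ready[[1L]]
    out <- c(out, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  out
}

#' Export a DAG in DOT format
#' @param g A `dag`.
#' @param path Optional file; if `NULL` the DOT text is returned.
#' @return DOT source, invisibly when written to file.
#' @export
dag_to_dot <- function(g, path = NULL) {
  a <- arcs(g)
  body <- c(sprintf("  \"%s\";", g$nodes),
            if (nrow(a)) sprintf("  \"%s\" -> \"%s\";", a[, 1L], a[, 2L]))
  txt <- paste(c("digraph bn {", body, "}"), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
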