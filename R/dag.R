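#' Construct a directed acyclic graph over named variables
#'
#' @param nodes character vector of unique node names.
#' @param edges edge set: a 2-column character matrix or data frame with
#'   columns (from, to), a character vector of `"from->to"` strings, or
#'   `NULL` for the empty graph.
#' @return an object of class `dag`: list with `nodes` and `edges` (a
#'   2-column character matrix).  Construction fails on self-loops,
#'   unknown endpoints, duplicate edges, or directed cycles.
#' @examples
#' dag_structure(c("X", "Y", "Z"), c("X->Y", "Y->Z"))
#' @export
dag_structure <- function(nodes, edges = NULL) {
  if (!is.character(nodes) || !length(nodes) || anyDuplicated(nodes))
    stop("`nodes` must be a character vector of unique names")
  em <- as_edge_matrix(edges)
  if (nrow(em)) {
    unknown <- setdiff(c(em), nodes)
    if (length(unknown))
      stop("edge endpoint(s) not in nodes: ", paste(unknown, collapse = ", "))
    if (any(em[, 1L] == em[, 2L])) stop("self-loops are not allowed")
    if (anyDuplicated(paste(em[, 1L], em[, 2L]))) stop("duplicate edges")
  }
  g <- structure(list(nodes = nodes, edges = em), class = "dag")
  if (is.null(topological_sort(g)))
    stop("edge set contains a directed cycle")
  g
}

# normalize the accepted edge representations to a (from,to) matrix
as_edge_matrix <- function(edges) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0L) ||
      length(edges) == 0L)
    return(matrix(character(0), 0L, 2L,
                  dimnames = list(NULL, c("from", "to"))))
  if (is.character(edges) && !is.matrix(edges)) {
    parts <- strsplit(edges, "->", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("edge strings must look like 'from->to'")
    edges <- do.call(rbind, parts)
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (!is.matrix(edges) || ncol(edges) != 2L)
    stop("`edges` must have two columns (from, to)")
  edges <- matrix(trimws(as.character(edges)), ncol = 2L,
                  dimnames = list(NULL, c("from", "to")))
  edges
}

#' @export
print.dag <- function(x, ...) {
  cat("dag:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges))
    cat(paste(" ", x$edges[, 1L], "->", x$edges[, 2L]), sep = "\n")
  invisible(x)
}

#' Edges of a DAG as "from->to" strings
#' @param dag a [dag_structure()].
#' @return character vector, one string per edge.
#' @export
dag_edge_strings <- function(dag) {
  if (!nrow(dag$edges)) return(character(0))
  paste0(dag$edges[, 1L], "->", dag$edges[, 2L])
}

#' Parents of a node
#' @param dag a [dag_structure()].
#' @param node node name.
#' @return character vector of parent names (possibly empty).
#' @export
dag_parents <- function(dag, node) {
  unname(dag$edges[dag$edges[, 2L] == node, 1L])
}

#' Children of a node
#' @param dag a [dag_structure()].
#' @param node node name.
#' @return character vector of child names.
#' @export
dag_children <- function(dag, node) {
  unname(dag$edges[dag$edges[, 1L] == node, 2L])
}

#' Topological order of a DAG
#'
#' Kahn's algorithm with deterministic (node-list order) tie-breaking.
#'
#' @param dag a [dag_structure()] (or the list form used internally).
#' @return character vector of nodes in topological order, or `NULL` if
#'   the edge set is cyclic.
#' @export
topological_sort <- function(dag) {
  nodes <- dag$nodes
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(dag$edges)) {
    tab <- table(dag$edges[, 2L])
    indeg[names(tab)] <- as.integer(tab)
  }
  order <- character(0)
  avail <- nodes[indeg == 0L]
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    order <- c(order, v)
    for (ch in dag_children(dag, v)) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) avail <- c(avail, ch)
    }
  }
  if (length(order) != length(nodes)) NULL else order
}

# directed reachability from -> to, DFS on the out-adjacency
dag_reachable <- function(dag, from, to) {
  if (from == to) return(TRUE)
  seen <- character(0)
  stack <- from
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v %in% seen) next
    seen <- c(seen, v)
    ch <- dag_children(dag, v)
    if (to %in% ch) return(TRUE)
    stack <- c(stack, ch)
  }
  FALSE
}

# mutation helpers used by the search; they validate acyclicity the cheap
# way (adding u->v is safe iff v cannot already reach u)
dag_add_edge <- function(dag, from, to, check = TRUE) {
  if (check && dag_reachable(dag, to, from))
    stop("adding ", from, "->", to, " would create a cycle")
  dag$edges <- rbind(dag$edges, c(from, to))
  dag
}

dag_remove_edge <- function(dag, from, to) {
  keep <- !(dag$edges[, 1L] == from & dag$edges[, 2L] == to)
  if (all(keep)) stop("no such edge: ", from, "->", to)
  dag$edges <- dag$edges[keep, , drop = FALSE]
  dag
}

dag_reverse_edge <- function(dag, from, to, check = TRUE) {
  g <- dag_remove_edge(dag, from, to)
  dag_add_edge(g, to, from, check = check)
}

#' Convert a DAG to an igraph object
#' @param dag a [dag_structure()].
#' @return an [igraph::graph] with the same nodes and directed edges.
#' @export
as_igraph <- function(dag) {
  stopifnot(inherits(dag, "dag"))
  igraph::graph_from_data_frame(
    as.data.frame(dag$edges, stringsAsFactors = FALSE),
    directed = TRUE, vertices = dag$nodes)
}

#' Export a DAG to DOT, GraphML or TSV edge-list
#'
#' @param dag a [dag_structure()].
#' @param path destination file.
#' @param format `"dot"`, `"graphml"` or `"tsv"`; default inferred from
#'   the file extension.
#' @return `path`, invisibly.
#' @export
write_dag <- function(dag, path, format = NULL) {
  stopifnot(inherits(dag, "dag"))
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)),
                     dot = "dot", gv = "dot", graphml = "graphml",
                     tsv = "tsv", "tsv")
  if (format == "tsv") {
    utils::write.table(
      data.frame(parent = dag$edges[, 1L], child = dag$edges[, 2L]),
      path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    igraph::write_graph(as_igraph(dag), path, format = format)
  }
  invisible(path)
}
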