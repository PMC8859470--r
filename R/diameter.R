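#' Graph diameter (exact, all-pairs BFS)
#'
#' Maximum over vertex pairs of the unweighted shortest-path length,
#' computed exactly by breadth-first search from every vertex (igraph's C
#' implementation). The diameter of a disconnected graph is infinite.
#'
#' @param x an `mpsn_graph` (union of all pathways), an igraph object, or a
#'   symmetric binary adjacency matrix.
#' @param directed treat the input as directed (only meaningful for igraph
#'   or matrix input).
#' @param find_pair also locate one eccentric vertex pair (a second
#'   all-pairs sweep; off by default).
#' @return object of class `mpsn_diameter`: list with `value` (integer or
#'   `Inf`), `is_connected`, and `extremal` (ids of one eccentric pair when
#'   requested, else `NULL`).
#' @export
mpsn_diameter <- function(x, directed = FALSE, find_pair = FALSE) {
  ig <- if (inherits(x, "mpsn_graph")) as_union_igraph(x)
        else if (inherits(x, "igraph")) x
        else adjacency_to_igraph(x)
  conn <- igraph::is_connected(ig, mode = if (directed) "strong" else "weak")
  if (!conn) {
    return(structure(list(value = Inf, is_connected = FALSE, extremal = NULL),
                     class = "mpsn_diameter"))
  }
  d <- igraph::diameter(ig, directed = directed, unconnected = FALSE)
  ext <- if (find_pair)
    as.integer(igraph::farthest_vertices(ig, directed = directed)$vertices)
  else NULL
  structure(list(value = as.integer(d), is_connected = TRUE,
                 extremal = ext),
            class = "mpsn_diameter")
}

#' @export
print.mpsn_diameter <- function(x, ...) {
  cat(sprintf("diameter: %s (%sconnected)\n",
              format(x$value), if (x$is_connected) "" else "not "))
  invisible(x)
}

#' t-th power of a graph
#'
#' Joins every pair of distinct vertices at BFS distance between 1 and `t`.
#' `t = 1` returns a graph with the same edge set.
#'
#' @param x igraph object or symmetric binary adjacency matrix.
#' @param t positive integer.
#' @return an igraph object on the same vertex set.
#' @export
graph_power <- function(x, t) {
  if (!is.numeric(t) || length(t) != 1L || t < 1) stop("t must be >= 1")
  t <- floor(t)
  ig <- if (inherits(x, "igraph")) x else adjacency_to_igraph(x)
  D <- igraph::distances(ig)
  A <- (D >= 1) & (D <= t)
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
}
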