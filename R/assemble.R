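#' Assemble a multi-pathway spatial network
#'
#' Builds the full labeled multigraph: the lattice, the locality partition,
#' and the three pathway layers (short-range `S`, intra-locality `L`,
#' long-distance `LD`). The result is a pure function of the parameters and
#' seed: identical inputs give byte-identical edge tables.
#'
#' @param params an [mpsn_params()] object; must validate.
#' @param template optional [build_template()] object; defaults to the
#'   template named by `params$template_kind` (required for `"custom"`).
#' @param f_ld optional [interlocality_graph()]; when `NULL` it is sampled
#'   with [sample_interlocality()] from the network stream derived from
#'   `params$rng_seed`.
#' @param ld_variant `"definitional"` (the model definition; default) or
#'   `"kronecker"` (exact Kronecker-product layer).
#' @return An object of class `mpsn_graph`: list with `vertices`, `edges`
#'   (columns `src`, `dst`, `pathway`, `weight`; `src < dst`), `locality_map`,
#'   `template`, `f_ld`, `params`, `ld_variant`.
#' @export
#' @examples
#' g <- assemble_mpsn(mpsn_params(n = 144, r = 1, k = 9, s = 4, epsilon = 1))
#' g
assemble_mpsn <- function(params, template = NULL, f_ld = NULL,
                          ld_variant = c("definitional", "kronecker")) {
  ld_variant <- match.arg(ld_variant)
  stop_if_invalid(params)
  vertices <- make_lattice(params$n)
  lmap <- assign_localities(params$n, params$k, params$s)
  if (is.null(template)) {
    if (params$template_kind == "custom")
      stop("template_kind 'custom' requires an explicit template")
    template <- build_template(params$template_kind, params$s)
  }
  if (template$s != params$s) stop("template size does not match params$s")
  if (is.null(f_ld)) {
    f_ld <- sample_interlocality(params$k, params$epsilon,
                                 derive_seed(params$rng_seed, "network"))
  }
  e_s <- build_short_range(vertices, params$r)
  e_l <- build_intra_locality(lmap, template)
  e_ld <- build_long_distance(lmap, f_ld, ld_variant)
  edges <- rbind(e_s, e_l, e_ld)
  rownames(edges) <- NULL
  structure(list(vertices = vertices, edges = edges, locality_map = lmap,
                 template = template, f_ld = f_ld, params = params,
                 ld_variant = ld_variant),
            class = "mpsn_graph")
}

#' @export
print.mpsn_graph <- function(x, ...) {
  cnt <- table(factor(x$edges$pathway, levels = c("S", "L", "LD")))
  cat(sprintf("MPSN graph: %d vertices; edges S=%d L=%d LD=%d (%s LD variant)\n",
              nrow(x$vertices), cnt[["S"]], cnt[["L"]], cnt[["LD"]],
              x$ld_variant))
  print(x$params)
  invisible(x)
}

#' Pathway layer adjacency matrix
#'
#' Sparse symmetric adjacency of one pathway layer, binary by default
#' (`weighted = TRUE` uses flow weights, relevant for `LD`).
#'
#' @param g an `mpsn_graph`.
#' @param pathway `"S"`, `"L"`, or `"LD"`.
#' @param weighted logical; use stored edge weights.
#' @return a `dgCMatrix` of dimension n x n.
#' @export
layer_adjacency <- function(g, pathway, weighted = FALSE) {
  e <- g$edges[g$edges$pathway == pathway, , drop = FALSE]
  n <- nrow(g$vertices)
  w <- if (weighted) e$weight else rep(1, nrow(e))
  Matrix::sparseMatrix(i = c(e$src, e$dst), j = c(e$dst, e$src),
                       x = c(w, w), dims = c(n, n))
}

#' Simple-graph union adjacency
#'
#' Binary symmetric adjacency of the union of all three pathway layers: an
#' entry is 1 iff at least one pathway connects the pair (union semantics:
#' a pair linked by several pathways still contributes a single 1). The
#' diagonal is zero. Structural metrics (spectral radius, diameter) run on
#' this simple graph; the simulator keeps the labeled multigraph.
#'
#' @param g an `mpsn_graph`.
#' @return a binary `dgCMatrix` of dimension n x n.
#' @export
union_adjacency <- function(g) {
  n <- nrow(g$vertices)
  e <- g$edges
  A <- Matrix::sparseMatrix(i = c(e$src, e$dst), j = c(e$dst, e$src),
                            x = rep(1, 2 * nrow(e)), dims = c(n, n))
  A@x[] <- 1  # collapse multi-pathway multiplicities to 1
  A
}

# igraph view of the union graph (used for diameter / BFS work); parallel
# pathway edges are kept — they do not affect unweighted distances
as_union_igraph <- function(g) {
  igraph::make_graph(rbind(g$edges$src, g$edges$dst),
                     n = nrow(g$vertices), directed = FALSE)
}

# igraph from any (sparse or dense) symmetric binary adjacency
adjacency_to_igraph <- function(A) {
  igraph::graph_from_adjacency_matrix(methods::as(A, "CsparseMatrix"),
                                      mode = "undirected", diag = FALSE)
}
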