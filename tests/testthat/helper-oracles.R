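# Independent oracles used across the suite. These deliberately use naive
# O(n^2) / dense / BFS routes, never the package's production code paths.

# all-pairs enumeration of lattice pairs within Euclidean range r
brute_short_range <- function(m, r) {
  coords <- expand.grid(i = 0:(m - 1), j = 0:(m - 1))
  coords <- coords[order(coords$i, coords$j), ]
  n <- m * m
  out <- list()
  for (a in 1:(n - 1)) {
    d2 <- (coords$i[(a + 1):n] - coords$i[a])^2 +
          (coords$j[(a + 1):n] - coords$j[a])^2
    hit <- which(d2 <= r * r)
    if (length(hit)) out[[length(out) + 1L]] <- cbind(a, a + hit)
  }
  if (length(out) == 0L) return(matrix(integer(), ncol = 2))
  do.call(rbind, out)
}

# dense adjacency from an edge data.frame
edges_to_dense <- function(edges, n, weighted = FALSE) {
  A <- matrix(0, n, n)
  if (nrow(edges)) {
    w <- if (weighted) edges$weight else 1
    A[cbind(edges$src, edges$dst)] <- w
    A[cbind(edges$dst, edges$src)] <- w
  }
  A
}

# largest eigenvalue by the dense symmetric solver
dense_lambda1 <- function(A) {
  max(eigen(as.matrix(A), symmetric = TRUE, only.values = TRUE)$values, 0)
}

# BFS ball: vertices within graph distance t of any seed (union graph)
bfs_ball <- function(g, seeds, t) {
  ig <- igraph::make_graph(as.vector(t(as.matrix(
    unique(g$edges[, c("src", "dst")])))), n = nrow(g$vertices),
    directed = FALSE)
  d <- igraph::distances(ig, v = seeds)
  which(apply(d, 2, min) <= t)
}

# a small reference instance: 12x12 lattice, 9 regions, K4 localities, r=1
make_fig_instance <- function(epsilon = 1, rng_seed = 11L,
                              ld_variant = "definitional") {
  assemble_mpsn(mpsn_params(n = 144, r = 1, k = 9, s = 4,
                            epsilon = epsilon, rng_seed = rng_seed),
                ld_variant = ld_variant)
}
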