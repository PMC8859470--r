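#' Synthesize a temporal commodity-flow network
#'
#' Generates a *synthetic* stand-in for temporal directed weighted
#' commodity-flow networks: nodes on a jittered lattice, spatial groups
#' (localities) around cluster centres, seasonally varying node infectivity
#' `rho(v, m) = base + amplitude * max(0, sin(2*pi*(m - phase)/12))` on a
#' configurable fraction of "production" nodes, and directed inter-group
#' flows concentrated on a few source ("hub") groups — emulating landscapes
#' where a small number of production areas send commodity to many areas of
#' consumption. Deterministic under the seed.
#'
#' @param n_nodes number of nodes.
#' @param n_groups number of groups (localities), `<= n_nodes`.
#' @param seasonality seasonal amplitude of production-node infectivity
#'   (0 = all months identical).
#' @param hub_concentration in `[0, 1]`; 1 means all inter-group flows
#'   originate from a single group.
#' @param rng_seed integer seed.
#' @param base_rho baseline infectivity of every node.
#' @param production_fraction fraction of nodes with a seasonal component.
#' @param group_edge_density probability that a hub sends flow to another
#'   group.
#' @param name tag stored on the object.
#' @return object of class `temporal_flow_network`: list with `name`,
#'   `nodes` (`id`, `x`, `y`, `group`), `rho` (`n x 12` matrix), `flows`
#'   (`src_group`, `dst_group`, `month`, `F`), `period = 12`.
#' @export
synth_temporal_flow <- function(n_nodes = 120, n_groups = 5,
                                seasonality = 0.8, hub_concentration = 0.5,
                                rng_seed = 1L, base_rho = 0.2,
                                production_fraction = 0.3,
                                group_edge_density = 0.5,
                                name = "synthetic") {
  stopifnot(n_groups <= n_nodes, n_groups >= 1,
            hub_concentration >= 0, hub_concentration <= 1)
  with_seed(derive_seed(rng_seed, "network"), {
    side <- ceiling(sqrt(n_nodes))
    ii <- (seq_len(n_nodes) - 1L) %/% side
    jj <- (seq_len(n_nodes) - 1L) %% side
    x <- ii + runif(n_nodes, -0.25, 0.25)
    y <- jj + runif(n_nodes, -0.25, 0.25)
    centres <- sample.int(n_nodes, n_groups)
    d2 <- outer(x, x[centres], `-`)^2 + outer(y, y[centres], `-`)^2
    group <- max.col(-d2)  # nearest centre
    nodes <- data.frame(id = seq_len(n_nodes), x = x, y = y, group = group)

    production <- runif(n_nodes) < production_fraction
    phase <- sample.int(12, n_groups, replace = TRUE)[group]
    rho <- matrix(base_rho, n_nodes, 12)
    for (m in 1:12) {
      seas <- seasonality * pmax(0, sin(2 * pi * (m - phase) / 12))
      rho[, m] <- base_rho + ifelse(production, seas, 0)
    }

    n_hubs <- max(1L, ceiling((1 - hub_concentration) * n_groups))
    hubs <- sample.int(n_groups, n_hubs)
    fl <- list()
    for (h in hubs) {
      targets <- setdiff(seq_len(n_groups), h)
      targets <- targets[runif(length(targets)) < group_edge_density]
      for (tg in targets) {
        w0 <- runif(1, 1, 5)
        # flow tracks the hub's seasonal production level
        hub_rho <- colMeans(rho[group == h, , drop = FALSE])
        fl[[length(fl) + 1L]] <-
          data.frame(src_group = h, dst_group = tg, month = 1:12,
                     F = w0 * hub_rho / max(hub_rho))
      }
    }
    flows <- if (length(fl)) do.call(rbind, fl)
             else data.frame(src_group = integer(), dst_group = integer(),
                             month = integer(), F = numeric())
    structure(list(name = name, nodes = nodes, rho = rho, flows = flows,
                   edges = NULL, period = 12L),
              class = "temporal_flow_network")
  })
}

#' @export
print.temporal_flow_network <- function(x, ...) {
  cat(sprintf("temporal flow network '%s': %d nodes, %d groups, %d group-flow records over %d months\n",
              x$name, nrow(x$nodes), length(unique(x$nodes$group)),
              nrow(x$flows), x$period))
  invisible(x)
}

#' Write a temporal flow network to TSV files
#'
#' Dialect: `<prefix>_nodes.tsv` (`id`, `x`, `y`, `group`),
#' `<prefix>_rho.tsv` (`id`, `month`, `rho`), `<prefix>_flows.tsv`
#' (`src_group`, `dst_group`, `month`, `F`), and — when explicit monthly
#' edges are attached — `<prefix>_edges.tsv` in long format
#' (`src`, `dst`, `pathway`, `weight`, `month`).
#'
#' @param net a `temporal_flow_network`.
#' @param prefix path prefix.
#' @return invisibly, the file paths written.
#' @export
write_temporal_network <- function(net, prefix) {
  paths <- paste0(prefix, c("_nodes.tsv", "_rho.tsv", "_flows.tsv"))
  nd <- net$nodes; nd$id <- nd$id - 1L; nd$group <- nd$group - 1L
  write.table(nd, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  rho_long <- data.frame(id = rep(net$nodes$id - 1L, times = 12),
                         month = rep(1:12, each = nrow(net$nodes)),
                         rho = as.vector(net$rho))
  write.table(rho_long, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  fl <- net$flows
  fl$src_group <- fl$src_group - 1L; fl$dst_group <- fl$dst_group - 1L
  write.table(fl, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(net$edges)) {
    ep <- paste0(prefix, "_edges.tsv")
    ed <- net$edges; ed$src <- ed$src - 1L; ed$dst <- ed$dst - 1L
    write.table(ed, ep, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, ep)
  }
  invisible(paths)
}

#' Load a temporal flow network from TSV files
#'
#' Reads the dialect of [write_temporal_network()]; the rho table is
#' optional (constant 1 when absent), as is the long-format monthly edge
#' table (when present, explicit edges are used by [monthly_matrices()]
#' instead of being derived from coordinates and groups). Reports the node
#' count, per-month and union-over-months edge counts, the group count and
#' the group-edge count (distinct ordered group pairs over all months).
#'
#' @param prefix path prefix.
#' @param name tag for the loaded network.
#' @return a `temporal_flow_network` with attribute `counts`.
#' @export
load_temporal_network <- function(prefix, name = basename(prefix)) {
  nodes <- read.delim(paste0(prefix, "_nodes.tsv"))
  if (!all(c("id", "x", "y", "group") %in% names(nodes)))
    stop("node table must have columns id, x, y, group")
  nodes$id <- nodes$id + 1L
  nodes$group <- nodes$group + 1L
  n <- nrow(nodes)
  if (any(sort(nodes$id) != seq_len(n)))
    stop("node ids must be 0..n-1 without gaps")

  rho_path <- paste0(prefix, "_rho.tsv")
  rho <- matrix(1, n, 12)
  if (file.exists(rho_path)) {
    rl <- read.delim(rho_path)
    if (any(rl$month < 1 | rl$month > 12)) stop("rho month outside 1..12")
    rho[cbind(rl$id + 1L, rl$month)] <- rl$rho
  }
  fl <- read.delim(paste0(prefix, "_flows.tsv"))
  if (!all(c("src_group", "dst_group", "month", "F") %in% names(fl)))
    stop("flow table must have columns src_group, dst_group, month, F")
  fl$src_group <- fl$src_group + 1L; fl$dst_group <- fl$dst_group + 1L
  if (nrow(fl) > 0 && any(fl$F < 0)) stop("negative flow weight")
  edges <- NULL
  ep <- paste0(prefix, "_edges.tsv")
  if (file.exists(ep)) {
    edges <- read.delim(ep)
    edges$src <- edges$src + 1L; edges$dst <- edges$dst + 1L
    if (any(edges$src < 1 | edges$src > n | edges$dst < 1 | edges$dst > n))
      stop("edge references undeclared node")
    if (!all(edges$pathway %in% c("S", "L", "LD")))
      stop("unknown pathway label in edge table")
    if (length(setdiff(1:12, unique(edges$month))) > 0)
      stop("edge table missing months")
  }
  net <- structure(list(name = name, nodes = nodes, rho = rho, flows = fl,
                        edges = edges, period = 12L),
                   class = "temporal_flow_network")
  gp <- unique(fl[, c("src_group", "dst_group")])
  per_month_edges <- if (!is.null(edges)) table(factor(edges$month, 1:12))
                     else NULL
  attr(net, "counts") <- list(
    n_nodes = n,
    n_groups = length(unique(nodes$group)),
    n_group_edges = nrow(gp),
    n_edges_union = if (!is.null(edges))
      nrow(unique(edges[, c("src", "dst", "pathway")])) else NA_integer_,
    n_edges_per_month = per_month_edges)
  net
}

#' Monthly weighted and unweighted adjacency matrices
#'
#' Builds the directed month-`m` snapshot: short-range edges between nodes
#' at Euclidean distance at most `r` and intra-group edges between all
#' same-group pairs, both directions, with weight `rho(source, m)`;
#' long-distance edges from every node of a flow's source group to every
#' node of its destination group with weight `rho(source, m) * F`. The
#' three weighted adjacencies are summed; the unweighted variant binarizes
#' the support. Months are 12-periodic (month 13 equals month 1). When the
#' network carries explicit monthly edge lists, those are used instead of
#' the derived short-range/intra-group layers (stored weight times
#' `rho(source, m)`, and additionally times `F` is already in the stored
#' LD weight).
#'
#' @param net a `temporal_flow_network`.
#' @param month month index (any positive integer; reduced mod 12).
#' @param r range for the derived short-range layer.
#' @return object of class `monthly_matrices`: list with `weighted`,
#'   `unweighted` (`dgCMatrix`), `month`, `r`.
#' @export
monthly_matrices <- function(net, month, r = 1) {
  m <- ((month - 1L) %% net$period) + 1L
  n <- nrow(net$nodes)
  rho_m <- net$rho[, m]
  src <- integer(0); dst <- integer(0); w <- numeric(0)

  if (!is.null(net$edges)) {
    ed <- net$edges[net$edges$month == m, , drop = FALSE]
    src <- ed$src; dst <- ed$dst
    w <- ed$weight * rho_m[ed$src]
  } else {
    xy <- cbind(net$nodes$x, net$nodes$y)
    d2 <- as.matrix(stats::dist(xy))^2
    near <- which(d2 <= r * r & upper.tri(d2), arr.ind = TRUE)
    same <- which(outer(net$nodes$group, net$nodes$group, `==`) &
                    upper.tri(d2), arr.ind = TRUE)
    a <- c(near[, 1], same[, 1]); b <- c(near[, 2], same[, 2])
    src <- c(src, a, b); dst <- c(dst, b, a)
    w <- c(w, rho_m[a], rho_m[b])
    fl <- net$flows[net$flows$month == m & net$flows$F > 0, , drop = FALSE]
    if (nrow(fl) > 0) {
      for (e in seq_len(nrow(fl))) {
        su <- net$nodes$id[net$nodes$group == fl$src_group[e]]
        sv <- net$nodes$id[net$nodes$group == fl$dst_group[e]]
        if (length(su) == 0L || length(sv) == 0L) next
        es <- rep(su, times = length(sv)); et <- rep(sv, each = length(su))
        src <- c(src, es); dst <- c(dst, et)
        w <- c(w, rho_m[es] * fl$F[e])
      }
    }
  }
  keep <- src != dst
  W <- Matrix::sparseMatrix(i = src[keep], j = dst[keep], x = w[keep],
                            dims = c(n, n))
  U <- W
  if (length(U@x)) U@x[] <- as.numeric(U@x > 0)
  U <- Matrix::drop0(U)
  structure(list(weighted = W, unweighted = U, month = m, r = r),
            class = "monthly_matrices")
}

#' Per-month spectral and diameter profile
#'
#' For every month and range value: the weighted spectral radius (Perron
#' root of the summed weighted directed adjacency, by nonnegative power
#' iteration), the unweighted spectral radius, and the diameter of the
#' unweighted snapshot. The diameter is computed on the underlying
#' undirected version of the support by default (`directed = TRUE` gives
#' the strict directed eccentricity); a disconnected snapshot reports `Inf`
#' plus the largest weakly connected component's diameter.
#'
#' @param net a `temporal_flow_network`.
#' @param r_values numeric vector of range values.
#' @param directed compute the directed diameter instead.
#' @param tol eigensolver tolerance.
#' @return data.frame with one row per (r, month).
#' @export
temporal_profile <- function(net, r_values = c(1, 2), directed = FALSE,
                             tol = 1e-8) {
  rows <- list()
  for (r in r_values) {
    for (m in 1:12) {
      mm <- monthly_matrices(net, m, r)
      lw <- as.numeric(spectral_radius(mm$weighted, tol = tol,
                                       symmetric = FALSE))
      lu <- as.numeric(spectral_radius(mm$unweighted, tol = tol,
                                       symmetric = FALSE))
      ig <- igraph::graph_from_adjacency_matrix(mm$unweighted,
                                                mode = if (directed) "directed"
                                                       else "max",
                                                weighted = NULL, diag = FALSE)
      conn <- igraph::is_connected(ig, mode = if (directed) "strong"
                                              else "weak")
      dm <- if (conn) igraph::diameter(ig, directed = directed,
                                       unconnected = FALSE) else Inf
      comp <- igraph::components(ig, mode = "weak")
      big <- which.max(comp$csize)
      sub <- igraph::induced_subgraph(ig, which(comp$membership == big))
      dm_big <- igraph::diameter(sub, directed = directed, unconnected = TRUE)
      rows[[length(rows) + 1L]] <-
        data.frame(r = r, month = m, lambda_weighted = lw,
                   lambda_unweighted = lu, diam = dm,
                   diam_largest_component = dm_big)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
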