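#' Short-range (self-mediated) pathway edges
#'
#' Connects every pair of lattice points at Euclidean distance at most `r`.
#' Membership is decided by the exact integer comparison
#' `di^2 + dj^2 <= r^2`; the left side is an integer, so there is no
#' floating-point ambiguity for any `r`. Edges are enumerated by coordinate
#' offset, so construction is O(n * |offsets|) rather than all-pairs.
#'
#' @param vertices lattice data.frame from [make_lattice()].
#' @param r dispersal range (> 0).
#' @return data.frame with columns `src`, `dst` (1-based ids, `src < dst`),
#'   `pathway = "S"`, `weight = 1`.
#' @export
build_short_range <- function(vertices, r) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0) stop("r must be positive")
  n <- nrow(vertices)
  m <- as.integer(round(sqrt(n)))
  fr <- as.integer(floor(r))
  if (fr < 1) {
    return(data.frame(src = integer(), dst = integer(),
                      pathway = character(), weight = numeric()))
  }
  offs <- expand.grid(di = 0:fr, dj = -fr:fr)
  offs <- offs[(offs$di > 0 | (offs$di == 0 & offs$dj > 0)) &
                 (offs$di^2 + offs$dj^2) <= r * r, , drop = FALSE]
  src <- integer(0); dst <- integer(0)
  for (o in seq_len(nrow(offs))) {
    di <- offs$di[o]; dj <- offs$dj[o]
    is <- 0:(m - 1L - di)
    js <- if (dj >= 0) 0:(m - 1L - dj) else (-dj):(m - 1L)
    if (length(is) == 0L || length(js) == 0L) next
    ii <- rep(is, each = length(js)); jj <- rep(js, times = length(is))
    src <- c(src, ii * m + jj + 1L)
    dst <- c(dst, (ii + di) * m + (jj + dj) + 1L)
  }
  a <- pmin(src, dst); b <- pmax(src, dst)
  ord <- order(a, b)
  data.frame(src = a[ord], dst = b[ord],
             pathway = rep("S", length(a)), weight = rep(1, length(a)))
}

#' Intra-locality template graph
#'
#' The template `H_L` lives on a `sqrt(s) x sqrt(s)` grid of `s` vertices
#' (1-based row-major indices); every locality carries an isomorphic copy.
#' `"complete"` joins all pairs; `"star"` joins the hub (row-major index 1)
#' to every other vertex; `"custom"` takes a caller-supplied simple edge
#' list.
#'
#' @param kind one of `"complete"`, `"star"`, `"custom"`.
#' @param s template size, a perfect square.
#' @param edges for `kind = "custom"`: 2-column matrix of vertex index pairs.
#' @return object of class `mpsn_template` with fields `kind`, `s`, `edges`.
#' @export
build_template <- function(kind = c("complete", "star", "custom"), s, edges = NULL) {
  kind <- match.arg(kind)
  if (!is_perfect_square(s)) stop("template size s must be a perfect square")
  if (kind == "complete") {
    e <- if (s >= 2) t(combn(s, 2)) else matrix(integer(), ncol = 2)
  } else if (kind == "star") {
    e <- if (s >= 2) cbind(1L, 2:s) else matrix(integer(), ncol = 2)
  } else {
    if (is.null(edges)) edges <- matrix(integer(), ncol = 2)
    e <- matrix(as.integer(edges), ncol = 2)
    if (nrow(e) > 0) {
      if (any(e < 1 | e > s)) stop("custom template edge references index outside 1..s")
      if (any(e[, 1] == e[, 2])) stop("custom template contains a self-loop")
      a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
      if (anyDuplicated(paste(a, b))) stop("custom template contains a duplicate edge")
      e <- cbind(a, b)[order(a, b), , drop = FALSE]
    }
  }
  colnames(e) <- c("a", "b")
  structure(list(kind = kind, s = as.integer(s), edges = e),
            class = "mpsn_template")
}

#' @export
print.mpsn_template <- function(x, ...) {
  cat(sprintf("intra-locality template: %s on %d vertices, %d edges\n",
              x$kind, x$s, nrow(x$edges)))
  invisible(x)
}

# dense adjacency of a template (s x s); used for exact small spectra
template_adjacency <- function(template) {
  s <- template$s
  A <- matrix(0, s, s)
  if (nrow(template$edges) > 0) {
    A[template$edges] <- 1
    A[template$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  A
}

#' Intra-locality pathway edges
#'
#' Places one copy of the template in every locality through the row-major
#' bijection between template indices and locality members.
#'
#' @param locality_map from [assign_localities()].
#' @param template from [build_template()]; its size must equal `s`.
#' @return data.frame of `L`-labeled edges (`src < dst`, weight 1).
#' @export
build_intra_locality <- function(locality_map, template) {
  if (template$s != locality_map$s)
    stop(sprintf("template size %d does not match locality size %d",
                 template$s, locality_map$s))
  te <- template$edges
  if (nrow(te) == 0L || locality_map$k == 0L) {
    return(data.frame(src = integer(), dst = integer(),
                      pathway = character(), weight = numeric()))
  }
  srcs <- vector("list", locality_map$k)
  dsts <- vector("list", locality_map$k)
  for (g in seq_len(locality_map$k)) {
    mem <- locality_map$members[[g]]
    srcs[[g]] <- mem[te[, 1]]
    dsts[[g]] <- mem[te[, 2]]
  }
  src <- unlist(srcs); dst <- unlist(dsts)
  a <- pmin(src, dst); b <- pmax(src, dst)
  ord <- order(a, b)
  data.frame(src = a[ord], dst = b[ord],
             pathway = rep("L", length(a)), weight = rep(1, length(a)))
}

#' Inter-locality graph constructor
#'
#' A simple graph on the `k` localities; each edge optionally carries a
#' nonnegative flow weight (default 1) which long-distance edges inherit.
#'
#' @param k number of localities.
#' @param edges 2-column matrix/data.frame of locality index pairs (1-based).
#' @param weights numeric vector of nonnegative flow weights, recycled.
#' @return object of class `mpsn_interlocality`.
#' @export
interlocality_graph <- function(k, edges = NULL, weights = 1) {
  if (is.null(edges) || NROW(edges) == 0L) {
    ed <- data.frame(u = integer(), v = integer(), weight = numeric())
  } else {
    e <- as.matrix(edges)[, 1:2, drop = FALSE]
    if (any(e < 1 | e > k)) stop("locality index outside 1..k in inter-locality edges")
    if (any(e[, 1] == e[, 2])) stop("inter-locality self-loop")
    a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
    if (anyDuplicated(paste(a, b))) stop("duplicate inter-locality edge")
    w <- rep_len(as.numeric(weights), length(a))
    if (any(w < 0)) stop("negative inter-locality weight")
    ord <- order(a, b)
    ed <- data.frame(u = as.integer(a[ord]), v = as.integer(b[ord]),
                     weight = w[ord])
  }
  structure(list(k = as.integer(k), edges = ed), class = "mpsn_interlocality")
}

#' @export
print.mpsn_interlocality <- function(x, ...) {
  cat(sprintf("inter-locality graph: k=%d localities, %d edges\n",
              x$k, nrow(x$edges)))
  invisible(x)
}

# dense k x k adjacency with flow weights
interlocality_adjacency <- function(f_ld, weighted = TRUE) {
  A <- matrix(0, f_ld$k, f_ld$k)
  e <- f_ld$edges
  if (nrow(e) > 0) {
    w <- if (weighted) e$weight else 1
    A[cbind(e$u, e$v)] <- w
    A[cbind(e$v, e$u)] <- w
  }
  A
}

#' Sample an Erdos-Renyi inter-locality graph
#'
#' Each of the `choose(k, 2)` locality pairs is included independently with
#' probability `min(1, epsilon/k)`. Pairs are visited in lexicographic order
#' with exactly one uniform draw each, so the result is a deterministic
#' function of `(k, epsilon, rng_seed)`. All weights are 1.
#'
#' @param k number of localities.
#' @param epsilon edge-probability factor (>= 0); probability `epsilon/k`,
#'   clamped at 1.
#' @param rng_seed integer seed (network stream).
#' @return an [interlocality_graph()] object.
#' @export
sample_interlocality <- function(k, epsilon, rng_seed) {
  if (k < 1) stop("k must be >= 1")
  if (epsilon < 0) stop("epsilon must be nonnegative")
  p <- min(1, epsilon / k)
  if (k < 2 || p == 0) return(interlocality_graph(k))
  u <- rep(seq_len(k - 1L), times = (k - 1L):1L)
  v <- unlist(lapply(seq_len(k - 1L), function(a) (a + 1L):k))
  draws <- with_seed(rng_seed, runif(length(u)))
  keep <- draws < p
  interlocality_graph(k, cbind(u[keep], v[keep]), weights = 1)
}

#' Long-distance pathway edges
#'
#' For every inter-locality edge `(u, v)` the `"definitional"` variant joins
#' all `s^2` cross pairs `L_u x L_v`; the `"kronecker"` variant joins only
#' cross pairs whose row-major template indices differ (`s^2 - s` pairs),
#' which makes the layer the Kronecker product of `F_LD` with the complete
#' graph on `s` vertices and gives spectral radius `(s-1) * lambda1(F_LD)`
#' exactly (the definitional layer has `s * lambda1(F_LD)`). Each edge
#' inherits the inter-locality edge's flow weight.
#'
#' @param locality_map from [assign_localities()].
#' @param f_ld an [interlocality_graph()]; indices must lie in `1..k`.
#' @param variant `"definitional"` (default) or `"kronecker"`.
#' @return data.frame of `LD`-labeled edges (`src < dst`).
#' @export
build_long_distance <- function(locality_map, f_ld,
                                variant = c("definitional", "kronecker")) {
  variant <- match.arg(variant)
  ed <- f_ld$edges
  if (nrow(ed) > 0 && (max(ed$u, ed$v) > locality_map$k || min(ed$u, ed$v) < 1))
    stop("locality index in inter-locality graph outside 1..k")
  if (nrow(ed) == 0L) {
    return(data.frame(src = integer(), dst = integer(),
                      pathway = character(), weight = numeric()))
  }
  s <- locality_map$s
  ia <- rep(seq_len(s), times = s)   # template index in L_u
  ib <- rep(seq_len(s), each = s)    # template index in L_v
  if (variant == "kronecker") {
    keep <- ia != ib
    ia <- ia[keep]; ib <- ib[keep]
  }
  srcs <- vector("list", nrow(ed)); dsts <- srcs; ws <- srcs
  for (e in seq_len(nrow(ed))) {
    mu <- locality_map$members[[ed$u[e]]]
    mv <- locality_map$members[[ed$v[e]]]
    srcs[[e]] <- mu[ia]; dsts[[e]] <- mv[ib]
    ws[[e]] <- rep(ed$weight[e], length(ia))
  }
  src <- unlist(srcs); dst <- unlist(dsts); w <- unlist(ws)
  a <- pmin(src, dst); b <- pmax(src, dst)
  ord <- order(a, b)
  data.frame(src = a[ord], dst = b[ord],
             pathway = rep("LD", length(a)), weight = w[ord])
}
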