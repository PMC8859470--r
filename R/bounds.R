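# canonical integer keys for an edge set of an igraph on n vertices
edge_keys <- function(ig, n) {
  e <- igraph::as_edgelist(ig, names = FALSE)
  if (nrow(e) == 0L) return(numeric(0))
  a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
  a * (n + 1) + b
}

#' Short-range layer sandwich and degree-bound check
#'
#' Verifies, on a concrete `sqrt(n) x sqrt(n)` lattice, that the edge set of
#' the short-range layer with range `r` is sandwiched between the
#' `floor(r)`-th graph powers of the 4-neighbour grid `H1` and the
#' 8-neighbour (king-move) grid `H2`; that the minimum degree of
#' `H1^floor(r)` is at least `floor(r)(floor(r)+1)/2` and the maximum
#' degree of `H2^floor(r)` at most the Chebyshev-ball count
#' `4 floor(r)^2 + 4 floor(r)` (the variant form `4(floor(r)-1)^2 +
#' 4 floor(r)` undercounts and is reported, not asserted); and that the
#' layer's spectral radius is bracketed by its minimum and maximum degree.
#'
#' @param n lattice size (perfect square, `n >= 9`).
#' @param r dispersal range (`r >= 1`, so the powers are defined).
#' @return list with the three logical verdicts (`sandwich`, `degree_bounds`,
#'   `lambda_bracket`) plus the measured quantities.
#' @export
sandwich_check <- function(n, r) {
  if (n < 9) stop("check requires n >= 9")
  if (r < 1) stop("check requires r >= 1")
  lat <- make_lattice(n)
  fr <- floor(r)
  gs_edges <- build_short_range(lat, r)
  gs_keys <- gs_edges$src * (n + 1) + gs_edges$dst
  h1 <- as_layer_igraph(build_short_range(lat, 1), n)
  h2 <- as_layer_igraph(build_short_range(lat, 1.5), n)  # orth + diag moves
  h1p <- graph_power(h1, fr)
  h2p <- graph_power(h2, fr)
  k1 <- edge_keys(h1p, n); k2 <- edge_keys(h2p, n)

  sandwich_lower <- all(k1 %in% gs_keys)
  sandwich_upper <- all(gs_keys %in% k2)

  deg1 <- igraph::degree(h1p); deg2 <- igraph::degree(h2p)
  bound_min <- fr * (fr + 1) / 2
  # Chebyshev-ball count: an interior vertex of the king-move power has
  # exactly (2*fr+1)^2 - 1 = 4*fr^2 + 4*fr neighbours; that is the valid
  # O(r^2) cap. The historically printed form 4*(fr-1)^2 + 4*fr undercounts
  # (it is below the true maximum degree already at fr = 1) and is recorded
  # for reference only.
  bound_max <- 4 * fr^2 + 4 * fr
  bound_max_printed <- 4 * (fr - 1)^2 + 4 * fr
  degree_bounds <- min(deg1) >= bound_min && max(deg2) <= bound_max

  A <- Matrix::sparseMatrix(i = c(gs_edges$src, gs_edges$dst),
                            j = c(gs_edges$dst, gs_edges$src),
                            x = 1, dims = c(n, n))
  lam <- as.numeric(spectral_radius(A, symmetric = TRUE))
  degs <- as.numeric(Matrix::rowSums(A))
  lambda_bracket <- min(degs) <= lam + 1e-8 && lam <= max(degs) + 1e-8

  list(sandwich = sandwich_lower && sandwich_upper,
       sandwich_lower = sandwich_lower, sandwich_upper = sandwich_upper,
       degree_bounds = degree_bounds,
       min_deg_h1p = min(deg1), bound_min_deg = bound_min,
       max_deg_h2p = max(deg2), bound_max_deg = bound_max,
       bound_max_deg_printed = bound_max_printed,
       printed_max_bound_holds = max(deg2) <= bound_max_printed,
       lambda_bracket = lambda_bracket,
       lambda_s = lam, min_deg_s = min(degs), max_deg_s = max(degs))
}

as_layer_igraph <- function(edges, n) {
  igraph::make_graph(as.vector(t(as.matrix(edges[, c("src", "dst")]))),
                     n = n, directed = FALSE)
}

#' Spectral-radius bound report
#'
#' Measures the spectral radius of the union graph and of each pathway
#' layer, and compares the union value against the model's sandwich bounds:
#' lower `max(r^2/2, lambda1(H_L), (s-1) lambda1(F_LD))` and upper
#' `4 r^2 + lambda1(H_L) + (s-1) lambda1(F_LD)`. Those printed bounds are
#' *reported*, never asserted — for the definitional LD variant the layer's
#' spectral radius is `s * lambda1(F_LD)`, which can exceed the `(s-1)`
#' coefficient of the printed bound in extreme regimes. The safe bounds
#' (every layer's radius is at most the union's; the union's is at most the
#' sum over layers) follow from subgraph monotonicity and subadditivity of
#' `lambda1` for symmetric nonnegative matrices and *are* asserted: their
#' violation indicates a solver failure and raises an error.
#'
#' The floor-based alternative lower-bound term
#' `floor(r)(floor(r)+1)/2` (which differs from `r^2/2` for non-integer `r`)
#' is recorded alongside.
#'
#' @param g an `mpsn_graph` carrying its parameters.
#' @param tol solver tolerance forwarded to [spectral_radius()].
#' @param lambda_layers optional named list (`S`, `L`, `LD`) of precomputed
#'   layer spectral radii (e.g. cached across replicates); missing entries
#'   are measured.
#' @return object of class `mpsn_bound_report`.
#' @export
spectral_bound_report <- function(g, tol = 1e-8, lambda_layers = list()) {
  p <- g$params
  lam_layer <- function(pw) {
    if (!is.null(lambda_layers[[pw]])) return(as.numeric(lambda_layers[[pw]]))
    as.numeric(spectral_radius(layer_adjacency(g, pw), tol = tol,
                               symmetric = TRUE))
  }
  lam_u <- as.numeric(spectral_radius(union_adjacency(g), tol = tol,
                                      symmetric = TRUE))
  lam_s <- lam_layer("S"); lam_l <- lam_layer("L"); lam_ld <- lam_layer("LD")
  lam_hl <- max(eigen(template_adjacency(g$template), symmetric = TRUE,
                      only.values = TRUE)$values, 0)
  lam_f <- max(eigen(interlocality_adjacency(g$f_ld, weighted = FALSE),
                     symmetric = TRUE, only.values = TRUE)$values, 0)

  lower_terms <- c(r_sq_half = p$r^2 / 2, lambda_hl = lam_hl,
                   ld = (p$s - 1) * lam_f)
  lower_floor_term <- floor(p$r) * (floor(p$r) + 1) / 2
  upper <- 4 * p$r^2 + lam_hl + (p$s - 1) * lam_f

  slack <- max(1e-6, tol * 100)
  safe_lower <- max(lam_s, lam_l, lam_ld) <= lam_u + slack
  safe_upper <- lam_u <= lam_s + lam_l + lam_ld + slack
  if (!safe_lower || !safe_upper)
    stop("safe spectral bounds violated; eigensolver failure suspected")

  structure(list(
    lambda_union = lam_u,
    lambda_layers = c(S = lam_s, L = lam_l, LD = lam_ld),
    lambda_template = lam_hl, lambda_fld = lam_f,
    lower_terms = lower_terms, lower_floor_term = lower_floor_term,
    lower_bound = max(lower_terms), upper_bound = upper,
    satisfied_lower = lam_u >= max(lower_terms) - slack,
    satisfied_upper = lam_u <= upper + slack,
    satisfied_safe_lower = safe_lower, satisfied_safe_upper = safe_upper,
    ld_variant = g$ld_variant,
    params = p), class = "mpsn_bound_report")
}

#' @export
print.mpsn_bound_report <- function(x, ...) {
  cat(sprintf("spectral bound report (%s LD variant)\n", x$ld_variant))
  cat(sprintf("  lambda1(G) = %.6f; layers S=%.6f L=%.6f LD=%.6f\n",
              x$lambda_union, x$lambda_layers["S"], x$lambda_layers["L"],
              x$lambda_layers["LD"]))
  cat(sprintf("  printed bounds: %.4f <= lambda1 <= %.4f  [lower %s, upper %s]\n",
              x$lower_bound, x$upper_bound,
              if (x$satisfied_lower) "ok" else "VIOLATED",
              if (x$satisfied_upper) "ok" else "VIOLATED"))
  cat(sprintf("  safe bounds: max layer <= lambda1 <= sum layers  [ok]\n"))
  invisible(x)
}

#' Diameter scaling table
#'
#' For a list of MPSN instances, verifies on each that the short-range
#' layer's diameter is at least `ceiling(sqrt(n)/r)` (the explicit finite
#' form of the lower-bound argument, valid for `n >= 9`) and that adding
#' locality and long-distance edges never increases the diameter. Emits the
#' scaling ratios against `sqrt(n)/r` and `(sqrt(n)/sqrt(k)) log k` for
#' inspection; no asymptotic claim is asserted.
#'
#' @param instances list of `mpsn_graph` objects.
#' @return data.frame with one row per instance.
#' @export
diameter_scaling_check <- function(instances) {
  rows <- lapply(instances, function(g) {
    p <- g$params
    n <- p$n
    ds <- mpsn_diameter(adjacency_to_igraph(layer_adjacency(g, "S")))$value
    du <- mpsn_diameter(g)$value
    bound_s <- ceiling(sqrt(n) / p$r)
    kb <- if (p$k > 1) (sqrt(n) / sqrt(p$k)) * log(p$k) else NA_real_
    data.frame(n = n, r = p$r, k = p$k,
               diam_s = ds, bound_s = bound_s,
               ok_lower = is.infinite(ds) || n < 9 || ds >= bound_s,
               diam_union = du, ok_monotone = du <= ds,
               ratio_s = ds / (sqrt(n) / p$r), k_term = kb,
               ratio_union = du / kb)
  })
  do.call(rbind, rows)
}
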