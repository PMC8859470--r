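test_that("spectral radius agrees with closed forms on both solver paths", {
  K4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(as.numeric(spectral_radius(K4)), 3, tolerance = 1e-10)
  edge <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(as.numeric(spectral_radius(edge)), 1, tolerance = 1e-10)

  # 12x12 grid: lambda1 = 4 cos(pi/13) (Cartesian product of two paths)
  g <- make_fig_instance(epsilon = 0)
  A <- layer_adjacency(g, "S")
  closed <- 4 * cos(pi / 13)
  expect_equal(as.numeric(spectral_radius(A)), closed, tolerance = 1e-8)
  # force the power-iteration path and compare against the dense path
  expect_equal(as.numeric(spectral_radius(A, dense_cap = 1L)), closed,
               tolerance = 1e-7)
  # bipartite layer (complete bipartite block): shift makes power iteration
  # land on the Perron root, not the -lambda1 twin
  lm <- assign_localities(64, 4, 4)
  B <- edges_to_dense(build_long_distance(lm, interlocality_graph(4, cbind(1, 2))), 64)
  expect_equal(as.numeric(spectral_radius(B, dense_cap = 1L)), 4,
               tolerance = 1e-7)
})

test_that("full spectrum is sorted, complete, and cap-guarded", {
  K4 <- matrix(1, 4, 4) - diag(4)
  sp <- graph_spectrum(K4)
  expect_equal(sp$values, c(3, -1, -1, -1), tolerance = 1e-10)
  expect_equal(graph_spectrum(matrix(0, 5, 5))$values, rep(0, 5))
  expect_error(graph_spectrum(Matrix::Diagonal(10), dense_cap = 5), "cap")
})

test_that("union adjacency collapses multi-pathway pairs to one entry", {
  # locality pairs at lattice distance 1 are linked by both S and L
  g <- make_fig_instance()
  A <- union_adjacency(g)
  expect_true(all(A@x == 1))
  expect_true(Matrix::isSymmetric(A))
  expect_equal(Matrix::diag(A), rep(0, 144))
  # row sums bounded by the degree bookkeeping of the three layers
  degs <- Matrix::rowSums(A)
  expect_true(all(degs >= 2))
  per_layer_max <- sapply(c("S", "L", "LD"), function(p)
    max(Matrix::rowSums(layer_adjacency(g, p))))
  expect_true(max(degs) <= sum(per_layer_max))
})

test_that("diameter is exact, with the infinite convention when disconnected", {
  K4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(mpsn_diameter(K4)$value, 1)
  two <- matrix(0, 2, 2)
  d <- mpsn_diameter(two)
  expect_identical(d$value, Inf)
  expect_false(d$is_connected)
  # 12x12 grid: 2(sqrt(n)-1) = 22
  g <- make_fig_instance(epsilon = 0)
  dS <- mpsn_diameter(mpsn:::adjacency_to_igraph(layer_adjacency(g, "S")))
  expect_equal(dS$value, 22L)
})

test_that("graph powers follow BFS distance", {
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  p2 <- graph_power(path3, 2)
  expect_equal(igraph::ecount(p2), 3)  # triangle
  p1 <- graph_power(path3, 1)
  expect_equal(igraph::ecount(p1), 2)
  # 6x6 four-neighbour grid squared: corner degree is the true minimum (5),
  # above the t(t+1)/2 = 3 lower bound
  h1 <- edges_to_dense(build_short_range(make_lattice(36), 1), 36)
  h1p2 <- graph_power(h1, 2)
  degs <- igraph::degree(h1p2)
  expect_equal(min(degs), 5)
  expect_gte(min(degs), 3)
  expect_error(graph_power(path3, 0), ">= 1")
})

test_that("short-range sandwich and degree checks pass on the 12x12 lattice", {
  for (r in c(1, 2)) {
    sc <- sandwich_check(144, r)
    expect_true(sc$sandwich, label = sprintf("sandwich r=%s", r))
    expect_true(sc$degree_bounds, label = sprintf("degrees r=%s", r))
    expect_true(sc$lambda_bracket, label = sprintf("bracket r=%s", r))
  }
  # r=1: the lower power equals the layer exactly
  sc1 <- sandwich_check(144, 1)
  expect_equal(sc1$min_deg_h1p, sc1$min_deg_s)
  # corrected Chebyshev cap for r=2 is 24; the printed variant (12) fails
  sc2 <- sandwich_check(144, 2)
  expect_equal(sc2$bound_max_deg, 24)
  expect_equal(sc2$bound_max_deg_printed, 12)
  expect_false(sc2$printed_max_bound_holds)
})

test_that("bound report: safe bounds hold and layer identities are exact", {
  for (variant in c("definitional", "kronecker")) {
    g <- make_fig_instance(epsilon = 5, rng_seed = 3L, ld_variant = variant)
    rep <- spectral_bound_report(g)
    expect_true(rep$satisfied_safe_lower)
    expect_true(rep$satisfied_safe_upper)
    expect_equal(rep$ld_variant, variant)
    lam_f <- rep$lambda_fld
    want <- if (variant == "kronecker") 3 * lam_f else 4 * lam_f
    expect_equal(unname(rep$lambda_layers["LD"]), want, tolerance = 1e-8)
    # block-diagonal layer identity: lambda1(G_L) = lambda1(H_L)
    expect_equal(unname(rep$lambda_layers["L"]), rep$lambda_template,
                 tolerance = 1e-8)
  }
  # kronecker variant satisfies the printed bounds
  gk <- make_fig_instance(epsilon = 5, rng_seed = 3L, ld_variant = "kronecker")
  rk <- spectral_bound_report(gk)
  expect_true(rk$satisfied_lower)
  expect_true(rk$satisfied_upper)
})

test_that("spectral invariants hold across random instances", {
  for (seed in 1:5) {
    g <- assemble_mpsn(mpsn_params(n = 64, r = 1.5, k = 4, s = 4,
                                   epsilon = 2, rng_seed = seed))
    lu <- dense_lambda1(as.matrix(union_adjacency(g)))
    lams <- sapply(c("S", "L", "LD"), function(p)
      dense_lambda1(as.matrix(layer_adjacency(g, p))))
    expect_gte(lu, max(lams) - 1e-10)   # subgraph monotonicity
    expect_lte(lu, sum(lams) + 1e-10)   # subadditivity
  }
})

test_that("diameter scaling check verifies the finite lower bound", {
  gs <- lapply(c(1, 2), function(r)
    assemble_mpsn(mpsn_params(n = 256, r = r, k = 4, s = 4, epsilon = 1,
                              rng_seed = 2L)))
  tab <- diameter_scaling_check(gs)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$ok_lower))
  expect_true(all(tab$ok_monotone))
  expect_equal(tab$diam_s[1], 30)          # 2(sqrt(n)-1) at r=1
  expect_equal(tab$bound_s, c(16, 8))
})
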