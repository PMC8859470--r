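test_that("synthetic temporal networks honour their stated structure", {
  net <- synth_temporal_flow(n_nodes = 80, n_groups = 4, rng_seed = 3)
  expect_s3_class(net, "temporal_flow_network")
  expect_equal(nrow(net$nodes), 80)
  expect_equal(ncol(net$rho), 12)
  expect_true(all(net$rho >= 0))
  # determinism
  net2 <- synth_temporal_flow(n_nodes = 80, n_groups = 4, rng_seed = 3)
  expect_identical(net$nodes, net2$nodes)
  expect_identical(net$flows, net2$flows)

  # zero seasonality: every month identical
  flat <- synth_temporal_flow(n_nodes = 40, n_groups = 3, seasonality = 0,
                              rng_seed = 1)
  expect_true(all(flat$rho == flat$rho[, 1]))
  prof <- temporal_profile(flat, r_values = 1)
  expect_equal(length(unique(round(prof$lambda_weighted, 9))), 1)

  # full hub concentration: all flows from one source group
  hub <- synth_temporal_flow(n_nodes = 60, n_groups = 5,
                             hub_concentration = 1, rng_seed = 2,
                             group_edge_density = 1)
  expect_equal(length(unique(hub$flows$src_group)), 1)
})

test_that("monthly matrices: weights, periodicity and homogeneity in rho", {
  net <- synth_temporal_flow(n_nodes = 50, n_groups = 3, rng_seed = 5)
  m1 <- monthly_matrices(net, 1, r = 1)
  m13 <- monthly_matrices(net, 13, r = 1)
  expect_equal(m1$weighted, m13$weighted)   # 12-periodicity

  # weighted support equals unweighted support; binary entries
  expect_true(all(m1$unweighted@x == 1))
  expect_equal(Matrix::nnzero(m1$weighted > 0), Matrix::nnzero(m1$unweighted))

  # scaling all rho by c scales the weighted matrix and its Perron root by c
  net3 <- net; net3$rho <- net$rho * 3
  m3 <- monthly_matrices(net3, 1, r = 1)
  expect_equal(m3$weighted, m1$weighted * 3, tolerance = 1e-12)
  l1 <- as.numeric(spectral_radius(m1$weighted, symmetric = FALSE))
  l3 <- as.numeric(spectral_radius(m3$weighted, symmetric = FALSE))
  expect_equal(l3, 3 * l1, tolerance = 1e-6)

  # rho identically zero in a month: zero matrix
  net0 <- net; net0$rho[] <- 0
  expect_equal(Matrix::nnzero(monthly_matrices(net0, 2, 1)$weighted), 0)
})

test_that("temporal profiles behave under range and season changes", {
  net <- synth_temporal_flow(n_nodes = 60, n_groups = 4, rng_seed = 7,
                             seasonality = 1, production_fraction = 1)
  p1 <- temporal_profile(net, r_values = c(1, 2))
  # increasing range never decreases either spectral radius
  a <- p1[p1$r == 1, ]; b <- p1[p1$r == 2, ]
  expect_true(all(b$lambda_weighted >= a$lambda_weighted - 1e-9))
  expect_true(all(b$lambda_unweighted >= a$lambda_unweighted - 1e-9))
  # unweighted radius is rho-invariant while support is unchanged
  expect_equal(length(unique(round(a$lambda_unweighted, 8))), 1)
  # offseason months have strictly lower weighted radius than peak months
  expect_gt(max(a$lambda_weighted), min(a$lambda_weighted))
})

test_that("temporal round trip and loader counts are self-consistent", {
  net <- synth_temporal_flow(n_nodes = 40, n_groups = 3, rng_seed = 9)
  prefix <- file.path(withr::local_tempdir(), "tf")
  write_temporal_network(net, prefix)
  got <- load_temporal_network(prefix)
  expect_equal(got$nodes$group, net$nodes$group)
  expect_equal(got$rho, net$rho, ignore_attr = TRUE)
  expect_equal(got$flows$F, net$flows$F)
  cnt <- attr(got, "counts")
  expect_equal(cnt$n_nodes, 40)
  expect_equal(cnt$n_groups, 3)
  expect_equal(cnt$n_group_edges,
               nrow(unique(net$flows[, c("src_group", "dst_group")])))
  # matrices from the reloaded network match the original
  expect_equal(monthly_matrices(got, 4, 1)$weighted,
               monthly_matrices(net, 4, 1)$weighted, tolerance = 1e-12)

  # two groups, one directed flow: group-edge count 1
  tiny <- synth_temporal_flow(n_nodes = 10, n_groups = 2,
                              hub_concentration = 1, group_edge_density = 1,
                              rng_seed = 1)
  expect_equal(nrow(unique(tiny$flows[, c("src_group", "dst_group")])), 1)
})

test_that("removing inter-group flows cannot raise the weighted radius", {
  net <- synth_temporal_flow(n_nodes = 50, n_groups = 4, rng_seed = 11,
                             group_edge_density = 1)
  cut <- net; cut$flows <- cut$flows[cut$flows$month != 3, ]
  l_full <- as.numeric(spectral_radius(monthly_matrices(net, 3, 1)$weighted,
                                       symmetric = FALSE))
  l_cut <- as.numeric(spectral_radius(monthly_matrices(cut, 3, 1)$weighted,
                                      symmetric = FALSE))
  expect_lte(l_cut, l_full + 1e-9)
})
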