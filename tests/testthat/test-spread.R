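test_that("edge probabilities follow the negative-exponential closed form", {
  expect_equal(edge_probability("S", 0, 5), 0)
  expect_equal(edge_probability("S", 0.01, 1), 1 - exp(-0.01))
  expect_equal(edge_probability("LD", 0.005, 1, 2), 1 - exp(-0.01))
  # flow weight ignored for S and L
  expect_equal(edge_probability("S", 0.01, 1, 7), 1 - exp(-0.01))
  expect_equal(edge_probability("L", 0.01, 2), 1 - exp(-0.02))
  expect_error(edge_probability("S", -1, 1), "nonnegative")
})

test_that("seed selection is exact-count, uniform and deterministic", {
  g <- make_fig_instance()
  s1 <- select_seeds(g, 0.05, 42)
  expect_length(s1, floor(0.05 * 144))
  expect_identical(s1, select_seeds(g, 0.05, 42))
  expect_length(select_seeds(g, 1, 1), 144)
  expect_error(select_seeds(g, 0.001, 1), "zero seed")
})

test_that("latency semantics: exposed at t, infectious at t + latency", {
  # single edge, probability 1
  g <- make_fig_instance(epsilon = 0)
  g$edges <- data.frame(src = 1L, dst = 2L, pathway = "S", weight = 1)
  p <- spread_params(alpha_s = 1e9, latency = 3L, seed_fraction = 0.01,
                     horizons = c(1L, 3L, 4L), rng_seed = 1L)
  traj <- spread_run(g, p, seeds = 1L)
  # v exposed during step 0 (visible at t=1); promoted during step 3
  # (exposure age 3 >= latency), so infectious from t=4 onwards
  expect_equal(traj$E[traj$t == 1], 1)
  expect_equal(traj$E[traj$t == 3], 1)
  expect_equal(traj$I[traj$t == 4], 2)
  expect_equal(traj$E[traj$t == 4], 0)
  expect_equal(traj$cum_infected[traj$t == 1], 2)
})

test_that("deterministic front on the 5x5 grid matches the BFS ball", {
  g <- assemble_mpsn(mpsn_params(n = 25, r = 1, k = 1, s = 1, epsilon = 0))
  p <- spread_params(alpha_s = 1e9, latency = 0L, horizons = c(2L),
                     rng_seed = 1L)
  centre <- 13L
  traj <- spread_run(g, p, seeds = centre)
  expect_equal(traj$cum_infected[traj$t == 2], 13)  # |{|x|+|y| <= 2}|
})

test_that("probability-1 spread equals the t-hop BFS ball on random instances", {
  for (seed in 1:6) {
    set.seed(seed)
    n_side <- sample(c(5, 7, 9), 1)  # odd side: single trivial locality fits
    prm <- mpsn_params(n = n_side^2, r = sample(c(1, 1.5, 2), 1), k = 1,
                       s = 1, epsilon = 0, rng_seed = seed)
    g <- assemble_mpsn(prm)
    seeds <- select_seeds(g, 0.2, seed)
    p <- spread_params(alpha_s = 1e9, alpha_l = 1e9, alpha_ld = 1e9,
                       latency = 0L, horizons = c(1L, 3L), rng_seed = seed)
    traj <- spread_run(g, p, seeds = seeds)
    for (t in c(1L, 3L)) {
      expect_equal(traj$cum_infected[traj$t == t],
                   length(bfs_ball(g, seeds, t)),
                   label = sprintf("seed=%d t=%d", seed, t))
    }
  }
})

test_that("all-zero rates freeze the process at the seed count", {
  g <- make_fig_instance()
  p <- spread_params(horizons = c(6L, 12L), rng_seed = 9L)
  traj <- spread_run(g, p)
  expect_true(all(traj$cum_infected == floor(0.05 * 144)))
})

test_that("conservation, monotonicity and determinism hold on every run", {
  g <- make_fig_instance(epsilon = 3)
  p <- spread_params(alpha_s = 0.1, alpha_l = 0.2, alpha_ld = 0.05,
                     latency = 1L, horizons = c(8L), rng_seed = 31L)
  t1 <- spread_run(g, p)
  t2 <- spread_run(g, p)
  expect_identical(t1, t2)
  expect_true(all(t1$S + t1$E + t1$I == 144))
  expect_true(all(diff(t1$cum_infected) >= 0))
  expect_true(all(diff(t1$S) <= 0))
})

test_that("ensembles summarize runs; deterministic dynamics give zero variance", {
  g <- make_fig_instance(epsilon = 0)
  p <- spread_params(alpha_s = 1e9, latency = 0L, horizons = c(2L, 4L),
                     rng_seed = 5L, seed_fraction = 1)
  ens <- run_ensemble(g, p, n_runs = 4)
  expect_equal(ens$n_runs, 4)
  expect_equal(unname(ens$var), c(0, 0))
  expect_equal(unname(ens$mean), c(144, 144))
  # means always within [seed count, n]
  p2 <- spread_params(alpha_s = 0.3, horizons = c(4L), rng_seed = 5L)
  e2 <- run_ensemble(g, p2, n_runs = 10)
  expect_gte(min(e2$cum_infected), floor(0.05 * 144))
  expect_lte(max(e2$cum_infected), 144)
})

test_that("pathway unraveling is nested and monotone under common draws", {
  g <- assemble_mpsn(mpsn_params(n = 144, r = 1, k = 9, s = 4, epsilon = 5,
                                 rng_seed = 4L))
  res <- pathway_unravel(g, 0.2, horizons = c(2L, 4L, 6L), n_runs = 15,
                         rng_seed = 8L)
  expect_named(res, c("grid", "grid_local", "grid_local_ld"))
  # exact CRN coupling: monotone run by run, not just in the mean
  expect_true(all(res$grid$cum_infected <= res$grid_local$cum_infected))
  expect_true(all(res$grid_local$cum_infected <=
                    res$grid_local_ld$cum_infected))

  res0 <- pathway_unravel(g, 0, horizons = c(2L), n_runs = 3, rng_seed = 8L)
  expect_equal(unname(res0$grid$mean), unname(res0$grid_local_ld$mean))
  expect_equal(unname(res0$grid$mean), floor(0.05 * 144))
})

test_that("infection counts increase with a pathway rate (common seeds)", {
  g <- make_fig_instance(epsilon = 5)
  means <- sapply(c(0, 0.05, 0.5), function(a) {
    p <- spread_params(alpha_s = a, horizons = c(6L), rng_seed = 77L)
    mean(run_ensemble(g, p, n_runs = 20, crn = TRUE)$cum_infected)
  })
  expect_true(all(diff(means) > 0))
})
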