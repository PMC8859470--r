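test_that("short-range layer matches the brute-force all-pairs oracle", {
  lat12 <- make_lattice(144)
  e <- build_short_range(lat12, 1)
  expect_equal(nrow(e), 264)  # 2 * 12 * 11 orthogonal grid edges
  expect_equal(nrow(build_short_range(make_lattice(9), 1.5)), 20)
  expect_equal(nrow(build_short_range(make_lattice(25), 0.5)), 0)

  for (r in c(1, 1.5, 2, 2.5, 3.2)) {
    got <- build_short_range(make_lattice(49), r)
    want <- brute_short_range(7, r)
    expect_equal(cbind(got$src, got$dst), unname(want),
                 label = sprintf("r=%s", r))
  }
})

test_that("short-range membership uses the exact integer comparison", {
  # r = sqrt(2): diagonal (1,1) with d^2 = 2 must be included exactly
  e <- build_short_range(make_lattice(9), sqrt(2))
  expect_equal(nrow(e), 20)
  # just under: excluded
  e2 <- build_short_range(make_lattice(9), sqrt(2) - 1e-12)
  expect_equal(nrow(e2), 12)
})

test_that("templates have the expected sizes and spectra", {
  k4 <- build_template("complete", 4)
  expect_equal(nrow(k4$edges), 6)
  expect_equal(dense_lambda1(mpsn:::template_adjacency(k4)), 3)
  k16 <- build_template("complete", 16)
  expect_equal(nrow(k16$edges), 120)
  expect_equal(dense_lambda1(mpsn:::template_adjacency(k16)), 15)
  st16 <- build_template("star", 16)
  expect_equal(nrow(st16$edges), 15)
  expect_equal(st16$edges[, 1], rep(1L, 15))  # hub at row-major index 0
  expect_equal(dense_lambda1(mpsn:::template_adjacency(st16)), sqrt(15))
  expect_error(build_template("custom", 4, cbind(1, 5)), "outside")
  expect_error(build_template("custom", 4, rbind(c(1, 2), c(2, 1))), "duplicate")
})

test_that("intra-locality layer is k disjoint template copies", {
  lm <- assign_localities(144, 9, 4)
  e <- build_intra_locality(lm, build_template("complete", 4))
  expect_equal(nrow(e), 9 * 6)
  # each edge joins two vertices of the same locality
  expect_true(all(lm$locality[e$src] == lm$locality[e$dst]))
  # spectrum = 9 concatenated copies of spectrum(K4) = {3, -1, -1, -1}
  A <- edges_to_dense(e, 144)
  vals <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
  want <- sort(c(rep(c(3, -1, -1, -1), 9), rep(0, 144 - 36)),
               decreasing = TRUE)
  expect_equal(vals, want, tolerance = 1e-10)

  empty <- build_template("custom", 4, NULL)
  expect_equal(nrow(build_intra_locality(lm, empty)), 0)
  expect_error(build_intra_locality(lm, build_template("complete", 16)),
               "does not match")
})

test_that("inter-locality sampling is seeded, clamped, and calibrated", {
  expect_equal(nrow(sample_interlocality(16, 0, 1)$edges), 0)
  # clamp: epsilon/k = 10/4 > 1 includes all 6 pairs
  f <- sample_interlocality(4, 10, 99)
  expect_equal(nrow(f$edges), 6)
  # determinism
  expect_identical(sample_interlocality(16, 1, 5)$edges,
                   sample_interlocality(16, 1, 5)$edges)
  # binomial calibration: k=64, eps=1 -> mean C(64,2)/64 = 31.5
  counts <- vapply(1:200, function(s)
    nrow(sample_interlocality(64, 1, s)$edges), numeric(1))
  p <- 1 / 64; npairs <- choose(64, 2)
  se <- sqrt(npairs * p * (1 - p) / 200)
  expect_lt(abs(mean(counts) - npairs * p), 3 * se)
})

test_that("long-distance variants differ by the equal-index cross pairs", {
  lm <- assign_localities(64, 4, 4)   # 4 regions of side 4, 2x2 localities
  f <- interlocality_graph(4, cbind(1, 2))
  def <- build_long_distance(lm, f, "definitional")
  kro <- build_long_distance(lm, f, "kronecker")
  expect_equal(nrow(def), 16)
  expect_equal(nrow(kro), 12)
  expect_equal(dense_lambda1(edges_to_dense(def, 64)), 4, tolerance = 1e-10)
  expect_equal(dense_lambda1(edges_to_dense(kro, 64)), 3, tolerance = 1e-10)
  # the definitional extra edges are exactly the s equal-index pairs
  key <- function(e) paste(e$src, e$dst)
  expect_length(setdiff(key(def), key(kro)), 4)
  expect_length(setdiff(key(kro), key(def)), 0)

  expect_equal(nrow(build_long_distance(lm, interlocality_graph(4))), 0)
  expect_error(build_long_distance(lm, interlocality_graph(9, cbind(1, 9))),
               "outside")
})

test_that("long-distance edges inherit inter-locality flow weights", {
  lm <- assign_localities(64, 4, 4)
  f <- interlocality_graph(4, rbind(c(1, 2), c(3, 4)), weights = c(2, 5))
  e <- build_long_distance(lm, f)
  expect_setequal(unique(e$weight), c(2, 5))
  expect_equal(sum(e$weight == 2), 16)
})
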