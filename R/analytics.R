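#' Default full-factorial network parameter grids
#'
#' The value grids of the model study: `k` in {4, 16, 64}, `r` from 1 to 4
#' in steps of 0.5, `s` in {4, 16, 64}, complete and star templates, and
#' `epsilon` in {0.1, 0.5, 1, 5, 10}, at a fixed lattice size (4096 for the
#' full study; pass a smaller `n` for reduced sweeps).
#'
#' @param n lattice size.
#' @return named list of value vectors for [factorial_design()].
#' @export
default_network_grids <- function(n = 4096) {
  list(n = n, k = c(4, 16, 64), r = seq(1, 4, by = 0.5), s = c(4, 16, 64),
       template = c("complete", "star"), epsilon = c(0.1, 0.5, 1, 5, 10))
}

#' Reduced network grids of the dynamics study
#'
#' `n = 4096`, `k = 16`, `r` in {1, 2, 3}, `s` in {4, 16}, complete
#' template, `epsilon` in {0.1, 1, 10}: 18 network combinations.
#'
#' @param n lattice size.
#' @export
dynamics_network_grids <- function(n = 4096) {
  list(n = n, k = 16, r = c(1, 2, 3), s = c(4, 16),
       template = "complete", epsilon = c(0.1, 1, 10))
}

#' Default SEI pathway parameter grids
#'
#' Each pathway rate ranges over {0, 0.001, 0.005, 0.01, 0.015, 0.02}
#' (the progression in steps of 0.005 above 0.001).
#'
#' @export
default_spread_grids <- function() {
  a <- c(0, 0.001, 0.005, 0.01, 0.015, 0.02)
  list(alpha_s = a, alpha_l = a, alpha_ld = a)
}

#' Full-factorial design with validity filtering and replicates
#'
#' Takes the Cartesian product of the value grids, drops parameter
#' combinations that fail [validate_params()] (e.g. localities larger than
#' their region), and expands each valid combination into `n_replicates`
#' design points with deterministic per-point network seeds derived from
#' `master_seed`. The same grids and master seed always give an identical
#' design.
#'
#' @param grids named list with entries `n`, `k`, `r`, `s`, `template`,
#'   `epsilon` (vectors of values).
#' @param n_replicates replicates per valid combination (default 10).
#' @param master_seed integer master seed.
#' @return data.frame of design points (`point_id`, parameter columns,
#'   `replicate`, `net_seed`) with attribute `n_valid_combinations`.
#' @export
factorial_design <- function(grids, n_replicates = 10L, master_seed = 1L) {
  combos <- expand.grid(n = grids$n, k = grids$k, r = grids$r, s = grids$s,
                        template = grids$template, epsilon = grids$epsilon,
                        stringsAsFactors = FALSE)
  ok <- vapply(seq_len(nrow(combos)), function(i) {
    validate_params(mpsn_params(n = combos$n[i], r = combos$r[i],
                                k = combos$k[i], s = combos$s[i],
                                epsilon = combos$epsilon[i]))$valid
  }, logical(1))
  combos <- combos[ok, , drop = FALSE]
  if (nrow(combos) == 0L) stop("no valid parameter combination in the grids")
  combos$point_id <- seq_len(nrow(combos))
  design <- combos[rep(seq_len(nrow(combos)), each = n_replicates), ]
  design$replicate <- rep(seq_len(n_replicates), times = nrow(combos))
  design$net_seed <- vapply(seq_len(nrow(design)), function(i) {
    derive_seed(master_seed, "network",
                design$point_id[i] * 1000 + design$replicate[i])
  }, integer(1))
  rownames(design) <- NULL
  attr(design, "n_valid_combinations") <- nrow(combos)
  design
}

#' Structural sweep over a factorial design
#'
#' For every design point: assembles the network, measures the spectral
#' radius of the union graph, obtains the layer spectral radii, and computes
#' the diameter. With `fast_layers = TRUE` (default) the layer values use
#' exact structural identities — `lambda1(G_L) = lambda1(H_L)` (the layer is
#' k disjoint template copies), `lambda1(G_LD) = s * lambda1(F_LD)`
#' (definitional variant) or `(s-1) * lambda1(F_LD)` (kronecker) — with the
#' small template / inter-locality matrices solved densely, and the
#' short-range value cached per `(n, r)`; these identities are verified by
#' the package's structure tests. `fast_layers = FALSE` measures every layer
#' on the full instance. The union value is always measured. Per-point
#' failures are recorded in the `status` column and the sweep continues.
#'
#' @param design data.frame from [factorial_design()].
#' @param ld_variant long-distance layer variant.
#' @param fast_layers use exact layer identities (default TRUE).
#' @param compute_diameter logical.
#' @param tol eigensolver tolerance.
#' @return data.frame: design columns plus `lambda1`, `lambda_s`,
#'   `lambda_l`, `lambda_ld`, `diam`, `safe_ok`, `status`.
#' @export
structural_sweep <- function(design, ld_variant = "definitional",
                             fast_layers = TRUE, compute_diameter = TRUE,
                             tol = 1e-8) {
  cache_s <- new.env(parent = emptyenv())
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    res <- tryCatch({
      p <- mpsn_params(n = row$n, r = row$r, k = row$k, s = row$s,
                       template_kind = row$template, epsilon = row$epsilon,
                       rng_seed = row$net_seed)
      f_ld <- sample_interlocality(p$k, p$epsilon,
                                   derive_seed(p$rng_seed, "network"))
      g <- assemble_mpsn(p, f_ld = f_ld, ld_variant = ld_variant)
      key <- paste(row$n, row$r, sep = "_")
      if (is.null(cache_s[[key]]))
        cache_s[[key]] <- as.numeric(
          spectral_radius(layer_adjacency(g, "S"), tol = tol, symmetric = TRUE))
      lam_s <- cache_s[[key]]
      if (fast_layers) {
        lam_l <- max(eigen(template_adjacency(g$template), symmetric = TRUE,
                           only.values = TRUE)$values, 0)
        lam_f <- max(eigen(interlocality_adjacency(f_ld, weighted = FALSE),
                           symmetric = TRUE, only.values = TRUE)$values, 0)
        lam_ld <- if (ld_variant == "kronecker") (p$s - 1) * lam_f
                  else p$s * lam_f
        if (nrow(f_ld$edges) == 0L) lam_ld <- 0
      } else {
        lam_l <- as.numeric(spectral_radius(layer_adjacency(g, "L"),
                                            tol = tol, symmetric = TRUE))
        lam_ld <- as.numeric(spectral_radius(layer_adjacency(g, "LD"),
                                             tol = tol, symmetric = TRUE))
      }
      lam_u <- as.numeric(spectral_radius(union_adjacency(g), tol = tol,
                                          symmetric = TRUE))
      dm <- if (compute_diameter) mpsn_diameter(g)$value else NA_real_
      slack <- 1e-6
      data.frame(lambda1 = lam_u, lambda_s = lam_s, lambda_l = lam_l,
                 lambda_ld = lam_ld, diam = as.numeric(dm),
                 safe_ok = max(lam_s, lam_l, lam_ld) <= lam_u + slack &&
                           lam_u <= lam_s + lam_l + lam_ld + slack,
                 status = "ok")
    }, error = function(e) {
      data.frame(lambda1 = NA_real_, lambda_s = NA_real_, lambda_l = NA_real_,
                 lambda_ld = NA_real_, diam = NA_real_, safe_ok = NA,
                 status = conditionMessage(e))
    })
    out[[i]] <- cbind(design[i, , drop = FALSE], res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Dynamics sweep: SEI ensembles over network x pathway-parameter grids
#'
#' For every network design point and every combination of the pathway
#' rates, runs an ensemble of `n_runs` SEI simulations and records the mean
#' cumulative infections at each horizon (long format: one row per network
#' point x rate combination x horizon).
#'
#' @param design network design from [factorial_design()].
#' @param spread_grids named list with `alpha_s`, `alpha_l`, `alpha_ld`
#'   value vectors ([default_spread_grids()] for the full study).
#' @param n_runs simulation instances per combination (study value: 100).
#' @param horizons observation steps (default `c(6, 12, 18, 24)`).
#' @param seed_fraction seeded fraction (default 0.05).
#' @param master_seed simulation master seed.
#' @param ld_variant long-distance layer variant.
#' @return data.frame with design columns, `alpha_s`, `alpha_l`, `alpha_ld`,
#'   `T`, `mean_infected`, `var_infected`, `n_runs`, `status`.
#' @export
dynamics_sweep <- function(design, spread_grids = default_spread_grids(),
                           n_runs = 100L, horizons = c(6L, 12L, 18L, 24L),
                           seed_fraction = 0.05, master_seed = 1L,
                           ld_variant = "definitional") {
  alphas <- expand.grid(alpha_s = spread_grids$alpha_s,
                        alpha_l = spread_grids$alpha_l,
                        alpha_ld = spread_grids$alpha_ld)
  out <- list()
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    p <- mpsn_params(n = row$n, r = row$r, k = row$k, s = row$s,
                     template_kind = row$template, epsilon = row$epsilon,
                     rng_seed = row$net_seed)
    g <- assemble_mpsn(p, ld_variant = ld_variant)
    for (a in seq_len(nrow(alphas))) {
      res <- tryCatch({
        sp <- spread_params(alpha_s = alphas$alpha_s[a],
                            alpha_l = alphas$alpha_l[a],
                            alpha_ld = alphas$alpha_ld[a],
                            seed_fraction = seed_fraction,
                            horizons = horizons,
                            rng_seed = derive_seed(master_seed, "simulation",
                                                   i * 10000 + a))
        ens <- run_ensemble(g, sp, n_runs = n_runs)
        data.frame(alpha_s = alphas$alpha_s[a], alpha_l = alphas$alpha_l[a],
                   alpha_ld = alphas$alpha_ld[a], T = horizons,
                   mean_infected = as.numeric(ens$mean),
                   var_infected = as.numeric(ens$var),
                   n_runs = n_runs, status = "ok")
      }, error = function(e) {
        data.frame(alpha_s = alphas$alpha_s[a], alpha_l = alphas$alpha_l[a],
                   alpha_ld = alphas$alpha_ld[a], T = horizons,
                   mean_infected = NA_real_, var_infected = NA_real_,
                   n_runs = n_runs, status = conditionMessage(e))
      })
      out[[length(out) + 1L]] <-
        cbind(design[i, , drop = FALSE], res, row.names = NULL)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# one-hot encode a feature frame to a numeric matrix; returns the matrix and
# a map from encoded column -> original feature name
encode_features <- function(data, features) {
  cols <- list(); owner <- character(0)
  for (f in features) {
    x <- data[[f]]
    if (is.numeric(x)) {
      cols[[f]] <- as.numeric(x); owner <- c(owner, f)
    } else {
      lv <- sort(unique(as.character(x)))
      for (l in lv) {
        nm <- paste0(f, "_", l)
        cols[[nm]] <- as.numeric(as.character(x) == l)
        owner <- c(owner, f)
      }
    }
  }
  X <- do.call(cbind, cols)
  list(X = X, owner = owner)
}

#' Feature importance by regression tree or random forest
#'
#' Fits a CART regression tree (deterministic, exhaustive splits; rendered
#' as text) or a bagged random forest (per-split feature subsampling) of the
#' measured outputs on the design parameters and returns impurity
#' importances: the per-feature decrease in residual sum of squares,
#' normalized to sum to 1. Categorical features are one-hot encoded and the
#' encoded columns' importances are summed back into their parent feature.
#' A constant target is flagged degenerate with all-zero importances, never
#' an error.
#'
#' @param data data.frame of a sweep result.
#' @param target name of the output column.
#' @param features feature column names (default: the design parameters
#'   present among `k`, `r`, `s`, `template`, `epsilon`, `alpha_s`,
#'   `alpha_l`, `alpha_ld`, `T`).
#' @param method `"cart"` or `"random_forest"`.
#' @param max_depth tree depth (default 3 for `cart` — a renderable tree —
#'   and 12 within the forest).
#' @param n_trees forest size (default 500).
#' @param min_split minimum node size to attempt a split.
#' @param min_bucket minimum leaf size.
#' @param mtry features tried per split in the forest (default `p/3`).
#' @param rng_seed forest resampling seed.
#' @return object of class `mpsn_importance`: `method`, `hyperparams`,
#'   `importance` (named, sums to 1), `rank` (1 = most important),
#'   `degenerate` flag, and `tree_text` (cart only).
#' @export
fit_importance <- function(data, target,
                           features = intersect(c("k", "r", "s", "template",
                                                  "epsilon", "alpha_s",
                                                  "alpha_l", "alpha_ld", "T"),
                                                names(data)),
                           method = c("cart", "random_forest"),
                           max_depth = NULL, n_trees = 500L, min_split = 10L,
                           min_bucket = NULL, mtry = NULL, rng_seed = 1L) {
  method <- match.arg(method)
  if (nrow(data) < 20L) stop("need at least 20 rows to fit importances")
  keep <- stats::complete.cases(data[, c(features, target)])
  data <- data[keep, , drop = FALSE]
  y <- as.numeric(data[[target]])
  finite <- is.finite(y)
  data <- data[finite, , drop = FALSE]; y <- y[finite]
  enc <- encode_features(data, features)
  p <- ncol(enc$X)
  if (is.null(mtry)) mtry <- max(1L, p %/% 3L)
  if (is.null(min_bucket)) min_bucket <- max(1L, min_split %/% 3L)

  degenerate <- length(unique(y)) <= 1L
  tree_text <- NULL
  if (degenerate) {
    raw <- numeric(p)
  } else if (method == "cart") {
    if (is.null(max_depth)) max_depth <- 3L
    tr <- grow_tree(enc$X, y, max_depth = max_depth, min_split = min_split,
                    min_bucket = min_bucket, mtry = p)
    raw <- tree_importance_raw(tr)
    tree_text <- render_tree(tr, colnames(enc$X))
  } else {
    if (is.null(max_depth)) max_depth <- 12L
    fo <- grow_forest(enc$X, y, n_trees = n_trees, mtry = mtry,
                      max_depth = max_depth, min_split = min_split,
                      min_bucket = min_bucket, rng_seed = rng_seed)
    raw <- fo$importance_raw
  }
  # fold encoded columns back into their parent features
  imp <- vapply(split(raw, enc$owner), sum, numeric(1))[unique(enc$owner)]
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot else degenerate <- TRUE
  rk <- setNames(rank(-imp, ties.method = "first"), names(imp))
  structure(list(method = method,
                 hyperparams = list(max_depth = max_depth, n_trees = n_trees,
                                    min_split = min_split,
                                    min_bucket = min_bucket, mtry = mtry),
                 importance = imp, rank = rk, degenerate = degenerate,
                 target = target, tree_text = tree_text),
            class = "mpsn_importance")
}

#' @export
print.mpsn_importance <- function(x, ...) {
  cat(sprintf("%s importance for target '%s'%s\n", x$method, x$target,
              if (x$degenerate) " [degenerate: constant target]" else ""))
  ord <- order(x$rank)
  print(round(x$importance[ord], 4))
  if (!is.null(x$tree_text)) cat(x$tree_text, "\n")
  invisible(x)
}

#' Hyperparameter robustness scan of forest importances
#'
#' Refits the random-forest importances over a grid of forest sizes and
#' node sizes and summarizes whether the top-ranked feature is invariant
#' across the grid.
#'
#' @param data,target,features as in [fit_importance()].
#' @param n_trees_grid forest sizes (default `c(100, 300, 500)`).
#' @param min_bucket_grid node sizes (default `c(2, 5)`).
#' @param rng_seed resampling seed.
#' @return list with `results` (one `mpsn_importance` per grid cell),
#'   `grid`, `top_feature` per cell, and `stable_top1` (logical).
#' @export
robustness_scan <- function(data, target,
                            features = intersect(c("k", "r", "s", "template",
                                                   "epsilon", "alpha_s",
                                                   "alpha_l", "alpha_ld", "T"),
                                                 names(data)),
                            n_trees_grid = c(100L, 300L, 500L),
                            min_bucket_grid = c(2L, 5L), rng_seed = 1L) {
  grid <- expand.grid(n_trees = n_trees_grid, min_bucket = min_bucket_grid)
  results <- vector("list", nrow(grid))
  top <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    results[[i]] <- fit_importance(data, target, features,
                                   method = "random_forest",
                                   n_trees = grid$n_trees[i],
                                   min_bucket = grid$min_bucket[i],
                                   rng_seed = rng_seed)
    top[i] <- names(which.min(results[[i]]$rank))
  }
  list(results = results, grid = grid, top_feature = top,
       stable_top1 = length(unique(top)) == 1L)
}
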