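# Regression-tree engine (CART-style, variance-reduction splits) and a
# bagged forest with per-split feature subsampling. Implemented here because
# the target environment ships no tree package; the engine is deliberately
# small: numeric features only (categoricals are one-hot encoded upstream),
# exhaustive midpoint split search, impurity importances = summed decrease
# in residual sum of squares per feature.

# Best split of (x, y): returns list(threshold, decrease) or NULL.
best_split_feature <- function(x, y, min_bucket) {
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  n <- length(ys)
  cut_ok <- which(xs[-n] != xs[-1])          # split between pos and pos+1
  cut_ok <- cut_ok[cut_ok >= min_bucket & (n - cut_ok) >= min_bucket]
  if (length(cut_ok) == 0L) return(NULL)
  cl <- cumsum(ys)
  tot <- cl[n]
  nl <- cut_ok
  sl <- cl[cut_ok]
  # between-group sum of squares = decrease in SSE
  dec <- sl^2 / nl + (tot - sl)^2 / (n - nl) - tot^2 / n
  b <- which.max(dec)
  if (dec[b] <= 0) return(NULL)
  list(threshold = (xs[cut_ok[b]] + xs[cut_ok[b] + 1L]) / 2,
       decrease = dec[b])
}

# Grow one regression tree. X numeric matrix, y numeric. mtry features are
# sampled per split (set mtry = ncol(X) for deterministic CART). Consumes
# the current RNG stream only when mtry < ncol(X).
grow_tree <- function(X, y, max_depth = 30L, min_split = 10L,
                      min_bucket = max(1L, min_split %/% 3L),
                      mtry = ncol(X)) {
  p <- ncol(X)
  nodes <- list()
  new_node <- function() length(nodes) + 1L
  # stack of (row index set, depth, parent slot writer)
  grow <- function(idx, depth) {
    id <- new_node()
    yv <- y[idx]
    node <- list(id = id, n = length(idx), value = mean(yv),
                 feature = NA_integer_, threshold = NA_real_,
                 decrease = 0, left = NA_integer_, right = NA_integer_)
    nodes[[id]] <<- node
    if (depth >= max_depth || length(idx) < min_split ||
        length(unique(yv)) == 1L)
      return(id)
    feats <- if (mtry >= p) seq_len(p) else sort(sample.int(p, mtry))
    best <- NULL; best_f <- NA_integer_
    for (f in feats) {
      sp <- best_split_feature(X[idx, f], yv, min_bucket)
      if (!is.null(sp) && (is.null(best) || sp$decrease > best$decrease)) {
        best <- sp; best_f <- f
      }
    }
    if (is.null(best)) return(id)
    go_left <- X[idx, best_f] <= best$threshold
    lid <- grow(idx[go_left], depth + 1L)
    rid <- grow(idx[!go_left], depth + 1L)
    nodes[[id]]$feature <<- best_f
    nodes[[id]]$threshold <<- best$threshold
    nodes[[id]]$decrease <<- best$decrease
    nodes[[id]]$left <<- lid
    nodes[[id]]$right <<- rid
    id
  }
  grow(seq_along(y), 0L)
  structure(list(nodes = nodes, p = p), class = "mpsn_tree")
}

predict_tree <- function(tree, X) {
  X <- as.matrix(X)
  out <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    id <- 1L
    repeat {
      nd <- tree$nodes[[id]]
      if (is.na(nd$feature)) { out[i] <- nd$value; break }
      id <- if (X[i, nd$feature] <= nd$threshold) nd$left else nd$right
    }
  }
  out
}

tree_importance_raw <- function(tree) {
  imp <- numeric(tree$p)
  for (nd in tree$nodes)
    if (!is.na(nd$feature)) imp[nd$feature] <- imp[nd$feature] + nd$decrease
  imp
}

render_tree <- function(tree, feature_names, digits = 4) {
  lines <- character(0)
  walk <- function(id, prefix, label) {
    nd <- tree$nodes[[id]]
    if (is.na(nd$feature)) {
      lines <<- c(lines, sprintf("%s%s -> %s (n=%d)", prefix, label,
                                 format(nd$value, digits = digits), nd$n))
    } else {
      lines <<- c(lines, sprintf("%s%s [%s <= %s] (n=%d, mean=%s)", prefix,
                                 label, feature_names[nd$feature],
                                 format(nd$threshold, digits = digits), nd$n,
                                 format(nd$value, digits = digits)))
      walk(nd$left, paste0(prefix, "  "), "yes:")
      walk(nd$right, paste0(prefix, "  "), "no: ")
    }
  }
  walk(1L, "", "root")
  paste(lines, collapse = "\n")
}

# Bagged forest. Rows are canonicalized (lexicographic sort over features
# then target) before resampling so results are invariant to input row
# order. Returns raw (unnormalized) importances plus the trees' count.
grow_forest <- function(X, y, n_trees = 500L, mtry = max(1L, ncol(X) %/% 3L),
                        max_depth = 30L, min_split = 5L,
                        min_bucket = 2L, rng_seed = 1L) {
  ord <- do.call(order, c(as.data.frame(X), list(y)))
  X <- X[ord, , drop = FALSE]; y <- y[ord]
  n <- length(y)
  imp <- numeric(ncol(X))
  with_seed(derive_seed(rng_seed, "forest"), {
    for (b in seq_len(n_trees)) {
      boot <- sample.int(n, n, replace = TRUE)
      tr <- grow_tree(X[boot, , drop = FALSE], y[boot],
                      max_depth = max_depth, min_split = min_split,
                      min_bucket = min_bucket, mtry = mtry)
      imp <- imp + tree_importance_raw(tr)
    }
  })
  list(importance_raw = imp, n_trees = n_trees)
}
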