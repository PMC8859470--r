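#' SEI diffusion parameters
#'
#' Configuration of the discrete-time SEI process over a multi-pathway
#' graph. Each pathway has its own tunable rate: an infectious node attacks
#' a susceptible neighbour across a labeled edge with probability
#' `1 - exp(-alpha * rho)` (short-range and intra-locality) or
#' `1 - exp(-alpha * F * rho)` (long-distance, `F` the inter-locality flow
#' weight). Exposed nodes become infectious after `latency` steps.
#'
#' @param alpha_s,alpha_l,alpha_ld nonnegative pathway parameters.
#' @param latency nonnegative integer latency (exposure at step t makes the
#'   node infectious at step `t + latency`; 0 means the node is promoted in
#'   the same step and first transmits at the next one).
#' @param seed_fraction fraction of vertices seeded infectious (default 0.05).
#' @param horizons strictly increasing positive integer observation steps.
#' @param rng_seed integer seed for the simulation stream.
#' @return object of class `spread_params`.
#' @export
spread_params <- function(alpha_s = 0, alpha_l = 0, alpha_ld = 0,
                          latency = 0L, seed_fraction = 0.05,
                          horizons = c(6L, 12L, 18L, 24L), rng_seed = 1L) {
  stopifnot(alpha_s >= 0, alpha_l >= 0, alpha_ld >= 0, latency >= 0,
            seed_fraction >= 0, seed_fraction <= 1)
  horizons <- as.integer(horizons)
  if (length(horizons) == 0L || any(horizons <= 0L) ||
      any(diff(horizons) <= 0L))
    stop("horizons must be strictly increasing positive integers")
  structure(list(alpha_s = alpha_s, alpha_l = alpha_l, alpha_ld = alpha_ld,
                 latency = as.integer(latency), seed_fraction = seed_fraction,
                 horizons = horizons, rng_seed = as.integer(rng_seed)),
            class = "spread_params")
}

#' Periodic node infectivity schedule
#'
#' Infectivity `rho(v, t)` scales a node's outgoing infection probabilities
#' and is periodic in `t` (default period 12, one phase per month). The
#' default is the constant 1 for all nodes and phases.
#'
#' @param n number of vertices.
#' @param period positive integer period.
#' @param values `NULL` (constant 1), a scalar, a length-`n` vector
#'   (constant in time), or an `n x period` matrix.
#' @return object of class `infectivity_schedule` (an `n x period` matrix).
#' @export
infectivity_schedule <- function(n, period = 12L, values = NULL) {
  period <- as.integer(period)
  if (period < 1L) stop("period must be positive")
  M <- if (is.null(values)) matrix(1, n, period)
       else if (is.matrix(values)) {
         if (!all(dim(values) == c(n, period))) stop("values must be n x period")
         values
       } else matrix(rep_len(as.numeric(values), n), n, period)
  if (any(M < 0)) stop("infectivity must be nonnegative")
  structure(M, class = c("infectivity_schedule", "matrix"))
}

# rho values for all nodes at (0-based) step t
schedule_at <- function(schedule, t) {
  schedule[, (t %% ncol(schedule)) + 1L]
}

#' Per-edge infection probability
#'
#' Closed form of the pathway transmission probabilities:
#' `1 - exp(-alpha * rho)` for pathways `S` and `L` (the flow weight is
#' ignored, i.e. treated as 1) and `1 - exp(-alpha * flow_weight * rho)`
#' for `LD`. Vectorized over `rho` and `flow_weight`.
#'
#' @param pathway `"S"`, `"L"`, or `"LD"` (vectorized).
#' @param alpha nonnegative pathway parameter.
#' @param rho nonnegative infectivity of the transmitting node.
#' @param flow_weight nonnegative inter-locality flow weight.
#' @return probability in `[0, 1]`.
#' @export
#' @examples
#' edge_probability("S", 0.01, 1)          # 1 - exp(-0.01)
#' edge_probability("LD", 0.005, 1, 2)     # same value
edge_probability <- function(pathway, alpha, rho = 1, flow_weight = 1) {
  if (any(alpha < 0) || any(rho < 0) || any(flow_weight < 0))
    stop("alpha, rho and flow_weight must be nonnegative")
  f <- ifelse(pathway == "LD", flow_weight, 1)
  1 - exp(-alpha * f * rho)
}

#' Select initial infectious seeds
#'
#' Exactly `floor(seed_fraction * n)` distinct vertices, uniformly at random
#' without replacement from the simulation stream; deterministic under a
#' fixed seed.
#'
#' @param g an `mpsn_graph`.
#' @param seed_fraction fraction in `(0, 1]`.
#' @param rng_seed integer seed.
#' @return integer vector of vertex ids.
#' @export
select_seeds <- function(g, seed_fraction, rng_seed) {
  n <- nrow(g$vertices)
  m <- floor(seed_fraction * n)
  if (m < 1) stop("seed_fraction yields zero seed vertices")
  sort(with_seed(rng_seed, sample.int(n, m)))
}

# Directed expansion of the labeled edge multiset with per-edge alpha and
# flow weight; infection probability additionally needs rho(from, t).
directed_edges <- function(g, params) {
  e <- g$edges
  alpha <- c(S = params$alpha_s, L = params$alpha_l, LD = params$alpha_ld)
  a <- alpha[e$pathway]
  f <- ifelse(e$pathway == "LD", e$weight, 1)
  list(from = c(e$src, e$dst), to = c(e$dst, e$src),
       rate = c(a * f, a * f))  # probability = 1 - exp(-rate * rho(from, t))
}

# One synchronous SEI step (0-based step index t). States: 0=S, 1=E, 2=I.
# de: directed_edges() output; u: optional pre-drawn uniforms, one per
# directed edge in fixed order (common-random-numbers coupling).
sei_step <- function(state, exposure, de, schedule, latency, t, u = NULL) {
  cand <- which(state[de$from] == 2L & state[de$to] == 0L)
  if (length(cand)) {
    rho <- schedule_at(schedule, t)[de$from[cand]]
    p <- 1 - exp(-de$rate[cand] * rho)
    draws <- if (is.null(u)) runif(length(cand)) else u[cand]
    hit <- unique(de$to[cand[draws < p]])
    if (length(hit)) {
      state[hit] <- 1L
      exposure[hit] <- t
    }
  }
  promote <- which(state == 1L & (t - exposure) >= latency)
  if (length(promote)) state[promote] <- 2L
  list(state = state, exposure = exposure)
}

#' Run one SEI trajectory
#'
#' Executes `max(horizons)` synchronous steps. Time origin `t = 0` holds the
#' seeded state; row `t + 1` of the trajectory records the state after `t`
#' completed steps. Within a step, infectious nodes (as of the step's start)
#' attack their susceptible neighbours with one independent Bernoulli draw
#' per labeled edge (a pair linked by two pathways gets two draws); exposed
#' nodes whose latency has elapsed are then promoted. Newly exposed nodes
#' never transmit within the same step.
#'
#' @param g an `mpsn_graph`.
#' @param params a [spread_params()] object.
#' @param schedule optional [infectivity_schedule()]; default constant 1.
#' @param seeds optional explicit seed set (overrides `seed_fraction`).
#' @param crn logical; when `TRUE`, one uniform is drawn for every directed
#'   labeled edge at every step in a fixed order, giving exact
#'   common-random-numbers coupling across parameter configurations sharing
#'   a seed (costlier; default `FALSE` draws only for active edges).
#' @return object of class `spread_trajectory`: data.frame with columns
#'   `t`, `S`, `E`, `I`, `cum_infected` (vertices ever exposed or
#'   infectious, seeds included), plus attributes `seeds` and `rng_seed`.
#' @export
spread_run <- function(g, params, schedule = NULL, seeds = NULL, crn = FALSE) {
  n <- nrow(g$vertices)
  if (is.null(schedule)) schedule <- infectivity_schedule(n)
  if (is.null(seeds))
    seeds <- select_seeds(g, params$seed_fraction,
                          derive_seed(params$rng_seed, "simulation"))
  tmax <- max(params$horizons)
  de <- directed_edges(g, params)
  state <- integer(n)      # 0 = S
  exposure <- rep(NA_integer_, n)
  state[seeds] <- 2L       # seeded infectious

  counts <- matrix(0L, tmax + 1L, 3L)
  counts[1L, ] <- c(sum(state == 0L), sum(state == 1L), sum(state == 2L))
  with_seed(derive_seed(params$rng_seed, "simulation-draws"), {
    n_dir <- length(de$from)
    for (t in 0:(tmax - 1L)) {
      u <- if (crn) runif(n_dir) else NULL
      st <- sei_step(state, exposure, de, schedule, params$latency, t, u)
      state <- st$state; exposure <- st$exposure
      counts[t + 2L, ] <- c(sum(state == 0L), sum(state == 1L),
                            sum(state == 2L))
    }
  })
  traj <- data.frame(t = 0:tmax, S = counts[, 1], E = counts[, 2],
                     I = counts[, 3], cum_infected = n - counts[, 1])
  attr(traj, "seeds") <- seeds
  attr(traj, "rng_seed") <- params$rng_seed
  class(traj) <- c("spread_trajectory", "data.frame")
  traj
}

#' Run an ensemble of SEI trajectories
#'
#' `n_runs` independent runs whose per-run seeds are derived from
#' `(params$rng_seed, run index)`; the seed *set* and the Bernoulli draws
#' both vary across runs but are reproducible.
#'
#' @inheritParams spread_run
#' @param n_runs number of simulation instances (model studies use 100).
#' @return object of class `spread_ensemble`: list with `horizons`, `mean`,
#'   `var`, `n_runs`, and the per-run matrix `cum_infected`
#'   (`n_runs x length(horizons)`).
#' @export
run_ensemble <- function(g, params, schedule = NULL, n_runs = 100L,
                         crn = FALSE) {
  stopifnot(n_runs >= 1)
  hz <- params$horizons
  cum <- matrix(0, n_runs, length(hz),
                dimnames = list(NULL, paste0("T", hz)))
  for (run in seq_len(n_runs)) {
    rp <- params
    rp$rng_seed <- derive_seed(params$rng_seed, "run", run)
    traj <- spread_run(g, rp, schedule = schedule, crn = crn)
    cum[run, ] <- traj$cum_infected[hz + 1L]
  }
  structure(list(horizons = hz,
                 mean = colMeans(cum),
                 var = apply(cum, 2, var),
                 n_runs = n_runs,
                 cum_infected = cum),
            class = "spread_ensemble")
}

#' @export
print.spread_ensemble <- function(x, ...) {
  cat(sprintf("SEI ensemble of %d runs\n", x$n_runs))
  print(data.frame(T = x$horizons, mean = x$mean, var = x$var))
  invisible(x)
}

#' Pathway unraveling experiment
#'
#' Runs the three nested configurations `(c, 0, 0)`, `(c, c, 0)`,
#' `(c, c, c)` of the pathway parameters on a common network with a common
#' seeding policy and exact common-random-numbers coupling (one uniform per
#' directed edge per step shared across configurations), so cumulative
#' infections are monotone in the unraveled edge set run by run.
#'
#' @param g an `mpsn_graph`.
#' @param c shared pathway parameter value, `0 <= c < 1`.
#' @param horizons observation steps.
#' @param n_runs runs per configuration.
#' @param seed_fraction seeded fraction (default 0.05).
#' @param rng_seed master simulation seed.
#' @return named list of three `spread_ensemble` objects
#'   (`grid`, `grid_local`, `grid_local_ld`), in unravel order.
#' @export
pathway_unravel <- function(g, c, horizons = c(6L, 12L, 18L, 24L),
                            n_runs = 100L, seed_fraction = 0.05,
                            rng_seed = 1L) {
  stopifnot(c >= 0, c < 1)
  cfgs <- list(grid = c(c, 0, 0), grid_local = c(c, c, 0),
               grid_local_ld = c(c, c, c))
  lapply(cfgs, function(al) {
    p <- spread_params(alpha_s = al[1], alpha_l = al[2], alpha_ld = al[3],
                       latency = 0L, seed_fraction = seed_fraction,
                       horizons = horizons, rng_seed = rng_seed)
    run_ensemble(g, p, n_runs = n_runs, crn = TRUE)
  })
}
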