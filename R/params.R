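#' MPSN parameter set
#'
#' Bundles the parameters of the multi-pathway spatial network model
#' MPSN(n, r, k, s, H_L, F_LD): `n` lattice vertices, dispersal range `r`,
#' `k` regions each holding one locality of `s` vertices, an intra-locality
#' template graph kind, and the Erdos-Renyi factor `epsilon` from which the
#' inter-locality graph is sampled with edge probability `min(1, epsilon/k)`.
#'
#' @param n vertex count; must be a positive perfect square.
#' @param r dispersal range in lattice units (> 0). Two lattice points are
#'   short-range neighbours iff their Euclidean distance is at most `r`.
#' @param k number of regions; a perfect square whose root divides `sqrt(n)`.
#' @param s locality size in vertices; a perfect square with
#'   `sqrt(s) <= sqrt(n/k)` and `sqrt(s)` of the same parity as `sqrt(n/k)`
#'   (so the locality subgrid centres exactly in its region).
#' @param template_kind intra-locality template: `"complete"`, `"star"`, or
#'   `"custom"`.
#' @param epsilon inter-locality edge-probability factor (>= 0); realized
#'   Bernoulli probability is `min(1, epsilon/k)`.
#' @param rng_seed integer seed for the network random stream.
#' @return An object of class `mpsn_params`.
#' @seealso [validate_params()], [assemble_mpsn()]
#' @export
#' @examples
#' p <- mpsn_params(n = 144, r = 1, k = 9, s = 4)
#' validate_params(p)
mpsn_params <- function(n, r = 1, k = 1, s = 1,
                        template_kind = c("complete", "star", "custom"),
                        epsilon = 0, rng_seed = 1L) {
  template_kind <- match.arg(template_kind)
  structure(
    list(n = n, r = r, k = k, s = s, template_kind = template_kind,
         epsilon = epsilon, rng_seed = as.integer(rng_seed)),
    class = "mpsn_params"
  )
}

#' Validate an MPSN parameter set
#'
#' Checks every structural invariant of the model parameters and returns a
#' verdict object; it never throws. Invalid verdicts enumerate all violated
#' rules, not just the first.
#'
#' @param p an [mpsn_params()] object (or a bare list with the same fields).
#' @return A list of class `mpsn_validation` with elements `valid` (logical)
#'   and `reasons` (character vector, empty when valid).
#' @export
validate_params <- function(p) {
  reasons <- character()
  num_ok <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

  if (!num_ok(p$n) || !is_perfect_square(p$n))
    reasons <- c(reasons, "n must be a positive perfect square")
  if (!num_ok(p$r) || p$r <= 0)
    reasons <- c(reasons, "range r must be positive")
  if (!num_ok(p$k) || !is_perfect_square(p$k))
    reasons <- c(reasons, "k must be a positive perfect square")
  if (!num_ok(p$s) || !is_perfect_square(p$s))
    reasons <- c(reasons, "s must be a positive perfect square")
  if (!num_ok(p$epsilon) || p$epsilon < 0)
    reasons <- c(reasons, "epsilon must be nonnegative")

  if (num_ok(p$n) && num_ok(p$k) &&
      is_perfect_square(p$n) && is_perfect_square(p$k)) {
    rn <- round(sqrt(p$n)); rk <- round(sqrt(p$k))
    if (rn %% rk != 0) {
      reasons <- c(reasons,
                   sprintf("sqrt(k) = %d must divide sqrt(n) = %d", rk, rn))
    } else if (num_ok(p$s) && is_perfect_square(p$s)) {
      side <- rn %/% rk            # region side length
      rs <- round(sqrt(p$s))       # locality side length
      if (rs > side)
        reasons <- c(reasons,
                     sprintf("locality side %d exceeds region side %d", rs, side))
      if (rs <= side && (rs %% 2L) != (side %% 2L))
        reasons <- c(reasons,
                     sprintf("locality side %d and region side %d have unequal parity (centering offset non-integral)",
                             rs, side))
    }
  }

  structure(list(valid = length(reasons) == 0L, reasons = reasons),
            class = "mpsn_validation")
}

#' @export
print.mpsn_validation <- function(x, ...) {
  if (x$valid) cat("valid MPSN parameters\n")
  else cat("invalid MPSN parameters:\n", paste0("  - ", x$reasons, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.mpsn_params <- function(x, ...) {
  cat(sprintf("MPSN parameters: n=%s r=%s k=%s s=%s template=%s epsilon=%s seed=%d\n",
              x$n, x$r, x$k, x$s, x$template_kind, x$epsilon, x$rng_seed))
  invisible(x)
}

stop_if_invalid <- function(p) {
  v <- validate_params(p)
  if (!v$valid)
    stop("invalid MPSN parameters: ", paste(v$reasons, collapse = "; "),
         call. = FALSE)
  invisible(TRUE)
}
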