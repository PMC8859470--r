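#' Build the vertex lattice
#'
#' Vertices are the points of a `sqrt(n) x sqrt(n)` square lattice with
#' integer coordinates `(i, j)`, `i, j` in `0 .. sqrt(n)-1`, listed in
#' row-major order. Internal vertex ids are 1-based (`id = i*sqrt(n) + j + 1`);
#' file interfaces use 0-based ids.
#'
#' @param n vertex count, a positive perfect square.
#' @return data.frame with columns `id`, `i`, `j`.
#' @export
#' @examples
#' make_lattice(4)
make_lattice <- function(n) {
  if (!is_perfect_square(n)) stop("n must be a positive perfect square")
  m <- as.integer(round(sqrt(n)))
  i <- rep(0:(m - 1L), each = m)
  j <- rep(0:(m - 1L), times = m)
  data.frame(id = seq_len(m * m), i = i, j = j)
}

#' Partition the lattice into regions and centred localities
#'
#' The lattice is tiled row-major into `k` square regions of side
#' `sqrt(n/k)`; each region holds one `sqrt(s) x sqrt(s)` locality subgrid
#' placed at offset `(side - sqrt(s))/2` from the region's top-left corner,
#' i.e. centred (the parity invariant of [validate_params()] makes the
#' offset integral). Locality members are ordered row-major within the
#' subgrid; this ordering is the bijection onto template-graph vertices.
#'
#' @param n,k,s see [mpsn_params()]; the triple must validate.
#' @return A list of class `mpsn_locality_map`:
#'   \describe{
#'     \item{region}{integer vector, region index (1..k) per vertex}
#'     \item{locality}{integer vector, locality index (1..k) or `NA` per vertex}
#'     \item{members}{list of k integer vectors, vertex ids in template order}
#'     \item{n, k, s}{the generating parameters}
#'   }
#' @export
assign_localities <- function(n, k, s) {
  stop_if_invalid(mpsn_params(n = n, k = k, s = s))
  m <- as.integer(round(sqrt(n)))
  rk <- as.integer(round(sqrt(k)))
  rs <- as.integer(round(sqrt(s)))
  side <- m %/% rk
  off <- (side - rs) %/% 2L

  lat <- make_lattice(n)
  rr <- lat$i %/% side; rc <- lat$j %/% side
  region <- rr * rk + rc + 1L
  li <- lat$i %% side; lj <- lat$j %% side
  in_loc <- li >= off & li < off + rs & lj >= off & lj < off + rs
  locality <- ifelse(in_loc, region, NA_integer_)

  members <- vector("list", k)
  idx <- which(in_loc)
  # template index: row-major within the locality subgrid
  tpos <- (li[idx] - off) * rs + (lj[idx] - off) + 1L
  for (v in seq_along(idx)) {
    g <- region[idx[v]]
    if (is.null(members[[g]])) members[[g]] <- integer(s)
    members[[g]][tpos[v]] <- idx[v]
  }
  structure(list(region = as.integer(region), locality = as.integer(locality),
                 members = members, n = as.integer(n), k = as.integer(k),
                 s = as.integer(s)),
            class = "mpsn_locality_map")
}

#' @export
print.mpsn_locality_map <- function(x, ...) {
  cat(sprintf("locality map: n=%d, k=%d regions, localities of s=%d (%d locality vertices)\n",
              x$n, x$k, x$s, x$k * x$s))
  invisible(x)
}
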