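#' Write an MPSN graph to TSV files
#'
#' Writes `<prefix>_nodes.tsv` (columns `id`, `i`, `j`, `region`,
#' `locality`; ids and region/locality indices 0-based, locality -1 for
#' non-locality vertices), `<prefix>_edges.tsv` (columns `src`, `dst`,
#' `pathway`, `weight`; undirected edges once with `src < dst`, 0-based,
#' canonical src-then-dst ascending order), and `<prefix>_meta.json`
#' (parameters, template and LD variant needed for a lossless round trip).
#'
#' @param g an `mpsn_graph`.
#' @param prefix path prefix for the three files.
#' @return invisibly, the vector of file paths written.
#' @export
write_graph <- function(g, prefix) {
  lm <- g$locality_map
  nodes <- data.frame(id = g$vertices$id - 1L, i = g$vertices$i,
                      j = g$vertices$j, region = lm$region - 1L,
                      locality = ifelse(is.na(lm$locality), -1L,
                                        lm$locality - 1L))
  e <- g$edges[order(g$edges$src, g$edges$dst), ]
  edges <- data.frame(src = e$src - 1L, dst = e$dst - 1L,
                      pathway = e$pathway, weight = e$weight)
  paths <- paste0(prefix, c("_nodes.tsv", "_edges.tsv", "_meta.json"))
  write.table(nodes, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(edges, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(params = unclass(g$params), ld_variant = g$ld_variant,
               template = list(kind = g$template$kind, s = g$template$s,
                               edges = g$template$edges),
               f_ld = list(k = g$f_ld$k, edges = g$f_ld$edges))
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read an MPSN graph written by [write_graph()]
#'
#' Malformed rows (wrong arity, unknown pathway label, negative weight,
#' out-of-range vertex id) raise an error naming the offending line number.
#' An empty edge file yields an edgeless graph, not an error.
#'
#' @param prefix path prefix used at write time.
#' @return an `mpsn_graph`.
#' @export
read_graph <- function(prefix) {
  npath <- paste0(prefix, "_nodes.tsv")
  epath <- paste0(prefix, "_edges.tsv")
  mpath <- paste0(prefix, "_meta.json")
  nodes <- read.delim(npath, colClasses = c("integer", "integer", "integer",
                                            "integer", "integer"))
  if (!identical(names(nodes), c("id", "i", "j", "region", "locality")))
    stop("node table must have columns id, i, j, region, locality")
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  p <- do.call(mpsn_params, as.list(meta$params))
  stop_if_invalid(p)

  raw <- readLines(epath)
  header <- strsplit(raw[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("src", "dst", "pathway", "weight")))
    stop("edge table must have columns src, dst, pathway, weight")
  n <- nrow(nodes)
  if (length(raw) > 1L) {
    fields <- strsplit(raw[-1], "\t", fixed = TRUE)
    for (ln in seq_along(fields)) {
      f <- fields[[ln]]
      line_no <- ln + 1L
      if (length(f) != 4L)
        stop(sprintf("edge file line %d: expected 4 fields, found %d",
                     line_no, length(f)))
      if (!f[3] %in% c("S", "L", "LD"))
        stop(sprintf("edge file line %d: unknown pathway label '%s'",
                     line_no, f[3]))
      w <- suppressWarnings(as.numeric(f[4]))
      if (is.na(w) || w < 0)
        stop(sprintf("edge file line %d: invalid or negative weight '%s'",
                     line_no, f[4]))
      sd <- suppressWarnings(as.integer(f[1:2]))
      if (any(is.na(sd)) || any(sd < 0) || any(sd >= n))
        stop(sprintf("edge file line %d: vertex id outside 0..%d",
                     line_no, n - 1L))
    }
    edges <- data.frame(
      src = vapply(fields, function(f) as.integer(f[1]), integer(1)) + 1L,
      dst = vapply(fields, function(f) as.integer(f[2]), integer(1)) + 1L,
      pathway = vapply(fields, `[`, character(1), 3L),
      weight = vapply(fields, function(f) as.numeric(f[4]), numeric(1)))
  } else {
    edges <- data.frame(src = integer(), dst = integer(),
                        pathway = character(), weight = numeric())
  }

  template_edges <- if (!is.null(meta$template$edges) &&
                        NROW(meta$template$edges) > 0)
    matrix(as.integer(as.matrix(meta$template$edges)), ncol = 2) else NULL
  template <- build_template(meta$template$kind, meta$template$s,
                             edges = template_edges)
  f_edges <- if (!is.null(meta$f_ld$edges) && NROW(meta$f_ld$edges) > 0)
    as.data.frame(meta$f_ld$edges) else NULL
  f_ld <- if (is.null(f_edges)) interlocality_graph(meta$f_ld$k)
          else interlocality_graph(meta$f_ld$k, cbind(f_edges$u, f_edges$v),
                                   weights = f_edges$weight)

  lmap <- assign_localities(p$n, p$k, p$s)
  # order edges in the assembler's canonical order (pathway blocks S, L, LD)
  blocks <- lapply(c("S", "L", "LD"), function(pw) {
    b <- edges[edges$pathway == pw, , drop = FALSE]
    b[order(b$src, b$dst), , drop = FALSE]
  })
  edges <- do.call(rbind, blocks)
  rownames(edges) <- NULL
  structure(list(vertices = make_lattice(p$n), edges = edges,
                 locality_map = lmap, template = template, f_ld = f_ld,
                 params = p, ld_variant = meta$ld_variant),
            class = "mpsn_graph")
}
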