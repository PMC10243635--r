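#' Construct an undirected graph
#'
#' Creates a simple undirected graph over nodes `0 .. n_nodes-1`. Edges are
#' canonicalized (smaller id first, sorted, deduplicated); self-loops and
#' out-of-range endpoints are rejected.
#'
#' @param n_nodes Number of nodes (integer >= 1).
#' @param edges Two-column integer matrix of node-id pairs (0-based). May be
#'   empty (0 rows).
#' @param coords Optional numeric matrix with `n_nodes` rows and 3 columns of
#'   node positions (arbitrary length units).
#' @return An object of class `ugraph` with fields `n_nodes`, `edges`
#'   (canonical two-column matrix) and `coords` (or `NULL`).
#' @examples
#' g <- ugraph(3, rbind(c(0, 1), c(1, 2), c(2, 0)))
#' mean_degree(g)
#' @export
ugraph <- function(n_nodes, edges, coords = NULL) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(length(n_nodes) == 1L, n_nodes >= 1L)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (anyNA(edges)) stop("edge list contains missing values")
    if (min(edges) < 0L || max(edges) >= n_nodes) {
      stop("edge endpoint outside 0..n_nodes-1")
    }
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    edges <- canonical_edges(edges)
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == n_nodes, ncol(coords) == 3L)
    dimnames(coords) <- NULL
  }
  structure(list(n_nodes = n_nodes, edges = edges, coords = coords),
            class = "ugraph")
}

# smaller endpoint first, lexicographic order, duplicates collapsed
canonical_edges <- function(edges) {
  lo <- pmin(edges[, 1L], edges[, 2L])
  hi <- pmax(edges[, 1L], edges[, 2L])
  key <- as.numeric(lo) * (max(hi) + 1) + as.numeric(hi)
  keep <- !duplicated(key)
  lo <- lo[keep]; hi <- hi[keep]; key <- key[keep]
  ord <- order(key)
  cbind(lo[ord], hi[ord], deparse.level = 0L)
}

#' @export
print.ugraph <- function(x, ...) {
  cat(sprintf("ugraph: %d nodes, %d edges, mean degree %.4f%s\n",
              x$n_nodes, nrow(x$edges), mean_degree(x),
              if (is.null(x$coords)) "" else ", with 3D coordinates"))
  invisible(x)
}

#' Node degrees
#'
#' @param g A `ugraph`.
#' @return Integer vector of length `n_nodes`.
#' @export
degrees <- function(g) {
  tabulate(c(g$edges[, 1L], g$edges[, 2L]) + 1L, nbins = g$n_nodes)
}

#' Mean degree
#'
#' Mean degree `2 |E| / N` of a graph.
#'
#' @param g A `ugraph`.
#' @return A number.
#' @export
mean_degree <- function(g) 2 * nrow(g$edges) / g$n_nodes

#' Read an undirected graph from an edge-list file
#'
#' One edge per line, two whitespace-separated integer node ids. Duplicate
#' lines (in either orientation) collapse to one edge; self-loops are dropped
#' with a warning. Node ids are compacted to `0..N-1` in order of first
#' appearance (ids already forming `0..N-1` are kept unchanged, so reading
#' back a written file is the identity); the old-to-new map is attached as
#' attribute `id_map`.
#'
#' @param path Edge-list file path.
#' @param coords_path Optional companion coordinates CSV with header
#'   `id,x,y,z` (ids in the original numbering).
#' @return A `ugraph`, with attribute `id_map` (data.frame `old_id,new_id`).
#' @export
read_edge_list <- function(path, coords_path = NULL) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop(sprintf("empty edge-list file: %s", path))
  lineno <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- which(vapply(toks, function(tk) {
    length(tk) != 2L || !all(grepl("^[-+]?[0-9]+$", tk))
  }, logical(1L)))
  if (length(bad)) {
    stop(sprintf("malformed edge-list line %d: '%s'",
                 lineno[bad[1L]], lines[lineno[bad[1L]]]))
  }
  m <- matrix(as.integer(unlist(toks)), ncol = 2L, byrow = TRUE)
  loops <- m[, 1L] == m[, 2L]
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    m <- m[!loops, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("edge list contains no usable edges")
  old_ids <- unique(as.integer(t(m)))  # order of first appearance
  if (identical(sort(old_ids), seq_along(old_ids) - 1L)) {
    old_ids <- sort(old_ids)           # already compact: keep ids as-is
  }
  new_of <- match(m, old_ids) - 1L
  g <- ugraph(length(old_ids), matrix(new_of, ncol = 2L))
  if (!is.null(coords_path)) {
    cc <- utils::read.csv(coords_path)
    stopifnot(all(c("id", "x", "y", "z") %in% names(cc)))
    idx <- match(old_ids, cc$id)
    if (anyNA(idx)) stop("coordinates file is missing some node ids")
    g$coords <- as.matrix(cc[idx, c("x", "y", "z")])
    dimnames(g$coords) <- NULL
  }
  attr(g, "id_map") <- data.frame(old_id = old_ids,
                                  new_id = seq_along(old_ids) - 1L)
  g
}

#' Write an edge list (and optional coordinates / id map)
#'
#' Mirrors the input dialect of [read_edge_list()]: tab-separated 0-based ids,
#' each undirected edge listed once with the smaller id first, in canonical
#' order, so write-then-read is the identity on canonical edge sets.
#'
#' @param g A `ugraph`.
#' @param path Output path for the edge list.
#' @param coords_path Optional output path for a coordinates CSV (`id,x,y,z`).
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(g, path, coords_path = NULL) {
  writeLines(paste(g$edges[, 1L], g$edges[, 2L], sep = "\t"), path)
  if (!is.null(coords_path)) {
    if (is.null(g$coords)) stop("graph has no coordinates to write")
    df <- data.frame(id = seq_len(g$n_nodes) - 1L,
                     x = g$coords[, 1L], y = g$coords[, 2L], z = g$coords[, 3L])
    utils::write.csv(df, coords_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Restrict a graph to its largest connected component
#'
#' The spectral workflow (relaxation time in particular) is only defined on
#' connected graphs, so generators and the pipeline route every graph through
#' this step. Ties between equally large components are broken toward the
#' component containing the smallest node id. Node ids are recompacted to
#' `0..N'-1` preserving ascending original order.
#'
#' @param g A `ugraph`.
#' @return A `ugraph` with attributes `retained_fraction` and `id_map`.
#' @export
largest_component <- function(g) {
  ig <- igraph::make_empty_graph(n = g$n_nodes, directed = FALSE)
  if (nrow(g$edges) > 0L) {
    ig <- igraph::add_edges(ig, as.vector(t(g$edges)) + 1L)
  }
  comp <- igraph::components(ig)
  big <- max(comp$csize)
  # first node (in id order) whose component has maximal size
  cid <- comp$membership[which(comp$csize[comp$membership] == big)[1L]]
  keep_old <- which(comp$membership == cid) - 1L  # ascending old ids
  new_of <- rep(NA_integer_, g$n_nodes)
  new_of[keep_old + 1L] <- seq_along(keep_old) - 1L
  e <- g$edges
  in_comp <- !is.na(new_of[e[, 1L] + 1L]) & !is.na(new_of[e[, 2L] + 1L])
  e <- cbind(new_of[e[in_comp, 1L] + 1L], new_of[e[in_comp, 2L] + 1L])
  out <- ugraph(length(keep_old), e,
                coords = if (is.null(g$coords)) NULL else
                  g$coords[keep_old + 1L, , drop = FALSE])
  attr(out, "retained_fraction") <- length(keep_old) / g$n_nodes
  attr(out, "id_map") <- data.frame(old_id = keep_old,
                                    new_id = seq_along(keep_old) - 1L)
  out
}

#' Random-walk transition matrix T = D^-1 A
#'
#' Row-stochastic one-step transition matrix of the simple random walk:
#' `T[i, j] = 1/d_i` iff `{i, j}` is an edge. Requires every node to have
#' degree at least 1.
#'
#' @param g A connected `ugraph` with no isolated nodes.
#' @return Object of class `transition_matrix`: fields `Tm` (sparse
#'   `dgCMatrix`), `d` (degree vector), `E` (edge count), `n`.
#' @export
transition_matrix <- function(g) {
  d <- degrees(g)
  if (any(d == 0L)) {
    stop("graph has isolated node(s); run largest_component() first")
  }
  i <- c(g$edges[, 1L], g$edges[, 2L]) + 1L
  j <- c(g$edges[, 2L], g$edges[, 1L]) + 1L
  Tm <- Matrix::sparseMatrix(i = i, j = j, x = 1 / d[i],
                             dims = c(g$n_nodes, g$n_nodes))
  structure(list(Tm = Tm, d = d, E = nrow(g$edges), n = g$n_nodes),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("transition_matrix: %d x %d, %d edges (volume 2E = %d)\n",
              x$n, x$n, x$E, 2L * x$E))
  invisible(x)
}

#' Thin a graph to a target mean degree
#'
#' Removes uniformly random edges one at a time until the mean degree first
#' crosses (falls to or below) `target`. The node count is unchanged, so
#' isolated nodes may appear; downstream callers apply [largest_component()].
#' Removal order is reproducible from `seed`.
#'
#' @param g A `ugraph`.
#' @param target Target mean degree (0 < target <= current mean degree).
#' @param seed Integer RNG seed.
#' @return A thinned `ugraph`.
#' @export
thin_to_mean_degree <- function(g, target, seed = 1L) {
  stopifnot(target > 0)
  if (target > mean_degree(g) + 1e-12) {
    stop(sprintf("target mean degree %.4f exceeds current %.4f",
                 target, mean_degree(g)))
  }
  e_final <- floor(target * g$n_nodes / 2 + 1e-9)
  n_remove <- nrow(g$edges) - e_final
  if (n_remove <= 0L) return(g)
  drop_idx <- withr::with_seed(seed, sample.int(nrow(g$edges), n_remove))
  ugraph(g$n_nodes, g$edges[-drop_idx, , drop = FALSE], coords = g$coords)
}
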