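#' Voronoi vertex graph of a 3D seed-point cloud
#'
#' Builds the graph whose nodes are the finite Voronoi vertices of the seed
#' points and whose edges are the finite Voronoi ridge segments between
#' them (equivalently: circumcenters of Delaunay tetrahedra, joined when two
#' tetrahedra share a triangular face). The tessellation is delegated to
#' qhull through `scipy.spatial`, invoked via the system `python`.
#'
#' @param points Numeric matrix (>= 5 rows, 3 columns) of seed coordinates
#'   in generic position (add jitter to regular lattices).
#' @return A `ugraph` with node coordinates (the Voronoi vertex positions).
#' @export
voronoi_graph <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, nrow(points) >= 5L)
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no 'python' interpreter found on PATH")
  script <- system.file("python", "voronoi_graph.py", package = "diffcomm",
                        mustWork = TRUE)
  f_pts <- tempfile("vorpts", fileext = ".txt")
  f_vert <- tempfile("vorvert", fileext = ".csv")
  f_edge <- tempfile("voredge", fileext = ".tsv")
  on.exit(unlink(c(f_pts, f_vert, f_edge)), add = TRUE)
  writeLines(apply(points, 1L, function(r) paste(sprintf("%.17g", r),
                                                 collapse = " ")), f_pts)
  out <- suppressWarnings(system2(py, c(script, f_pts, f_vert, f_edge),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop(paste0("Voronoi tessellation failed (degenerate seed geometry? ",
                "use noise > 0): ", paste(out, collapse = "; ")))
  }
  vert <- as.matrix(utils::read.csv(f_vert, header = FALSE))
  e <- utils::read.table(f_edge, header = FALSE,
                         colClasses = c("integer", "integer"))
  ugraph(nrow(vert), as.matrix(e), coords = vert)
}

#' Homogeneous Voronoi null network (HVor)
#'
#' Spatially uniform quasi-regular network: (1) an integer lattice of
#' `grid_side^3` points centered at the origin; (2) keep the `sphere_keep`
#' points closest to the center (rank-based sphere filter, boundary ties
#' broken by lexicographic coordinate order); (3) add seeded uniform jitter
#' of amplitude `noise` to every coordinate so the tessellation is generic
#' (on a perfect lattice Voronoi vertices degenerate toward degree 6 instead
#' of the generic 4); (4) Voronoi vertex graph; (5) thin to the target mean
#' degree; (6) largest connected component.
#'
#' Defaults reproduce the reference recipe: a 31x31x31 grid filtered to 5185
#' in-sphere seeds and thinned to mean degree 2.8, yielding a network of
#' roughly 2e5 nodes.
#'
#' @param grid_side Lattice side length (>= 3).
#' @param noise Uniform jitter amplitude in lattice units (`+/- noise`).
#' @param sphere_keep Number of seed points kept inside the sphere.
#' @param target_mean_degree Mean degree to thin to, or `NULL` to skip
#'   thinning.
#' @param seed Integer RNG seed (drives jitter and thinning).
#' @return A connected `ugraph` with coordinates.
#' @export
homogeneous_voronoi <- function(grid_side = 31L, noise = 0.2,
                                sphere_keep = 5185L,
                                target_mean_degree = 2.8, seed = 1L) {
  stopifnot(grid_side >= 3L, sphere_keep >= 5L,
            sphere_keep <= grid_side^3, noise >= 0)
  ax <- seq_len(grid_side) - (grid_side + 1) / 2
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  dimnames(pts) <- NULL
  r2 <- rowSums(pts^2)
  ord <- order(r2, pts[, 1L], pts[, 2L], pts[, 3L])
  pts <- pts[ord[seq_len(sphere_keep)], , drop = FALSE]
  seeds <- derive_seeds(seed, 2L)
  pts <- pts + withr::with_seed(
    seeds[1L], matrix(stats::runif(length(pts), -noise, noise), nrow(pts)))
  finish_null_model(voronoi_graph(pts), target_mean_degree, seeds[2L])
}

#' Polar Voronoi null network (PVor)
#'
#' Voronoi vertex graph of seeds drawn from the union of two isotropic 3D
#' Gaussians — a broad one and a dense compact one — producing a network with
#' a strong density gradient (a "polarized" counterpart of
#' [homogeneous_voronoi()]). Defaults follow the reference recipe:
#' `n1 = 10000` seeds around the origin with sd 5 plus `n2 = 18752` seeds
#' around (5,5,5) with sd 1, thinned to mean degree 2.8.
#'
#' @param n1,n2 Seed counts of the two Gaussians (`n2 = 0` degenerates to a
#'   single isotropic cloud).
#' @param center1,center2 Length-3 centers.
#' @param sd1,sd2 Isotropic standard deviations.
#' @inheritParams homogeneous_voronoi
#' @return A connected `ugraph` with coordinates.
#' @export
polar_voronoi <- function(n1 = 10000L, center1 = c(0, 0, 0), sd1 = 5,
                          n2 = 18752L, center2 = c(5, 5, 5), sd2 = 1,
                          target_mean_degree = 2.8, seed = 1L) {
  stopifnot(n1 >= 5L, n2 >= 0L, sd1 > 0, sd2 > 0)
  seeds <- derive_seeds(seed, 2L)
  pts <- withr::with_seed(seeds[1L], {
    p1 <- matrix(stats::rnorm(3L * n1, sd = sd1), ncol = 3L, byrow = TRUE)
    p1 <- sweep(p1, 2L, center1, "+")
    if (n2 > 0L) {
      p2 <- matrix(stats::rnorm(3L * n2, sd = sd2), ncol = 3L, byrow = TRUE)
      rbind(p1, sweep(p2, 2L, center2, "+"))
    } else p1
  })
  finish_null_model(voronoi_graph(pts), target_mean_degree, seeds[2L])
}

#' Configuration-model random null network
#'
#' Stub-matching configuration model on the constant degree sequence
#' `rep(degree, n)` (the degree sequence of a `degree`-regular graph),
#' simplified (self-loops and multi-edges removed), thinned to the target
#' mean degree and restricted to the largest component.
#'
#' @param n Number of nodes; `n * degree` must be even.
#' @param degree Target degree of the sequence (default 3).
#' @inheritParams homogeneous_voronoi
#' @return A connected `ugraph` (no coordinates).
#' @export
random_configuration <- function(n, degree = 3L, target_mean_degree = 2.8,
                                 seed = 1L) {
  stopifnot(n >= 2L, degree >= 1L)
  if ((as.numeric(n) * degree) %% 2 != 0) {
    stop("n * degree must be even (handshake parity)")
  }
  seeds <- derive_seeds(seed, 2L)
  ig <- withr::with_seed(
    seeds[1L],
    igraph::sample_degseq(rep(degree, n), method = "configuration"))
  ig <- igraph::simplify(ig)
  e <- igraph::as_edgelist(ig, names = FALSE) - 1L
  g <- ugraph(n, e)
  finish_null_model(g, target_mean_degree, seeds[2L])
}

finish_null_model <- function(g, target_mean_degree, thin_seed) {
  if (!is.null(target_mean_degree) &&
      target_mean_degree < mean_degree(g)) {
    g <- thin_to_mean_degree(g, target_mean_degree, seed = thin_seed)
  }
  largest_component(g)
}

# independent sub-streams derived from one user-facing seed
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Degree-preserving rewiring by double edge swaps
#'
#' Performs `ceiling(fraction * |E| / 2)` successful double edge swaps
#' (each swap replaces edges `(a,b), (c,d)` by `(a,d), (c,b)`, so a fraction
#' `fraction` of edges is rewired), rejecting candidate swaps that would
#' create a self-loop or a duplicate edge. The degree sequence, node count
#' and edge count are exactly preserved. Attempts are capped at 100x the
#' requested swap count.
#'
#' @param g A `ugraph` with at least 2 edges.
#' @param fraction Fraction of edges to rewire, in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return A rewired `ugraph` (coordinates carried over unchanged).
#' @export
rewire <- function(g, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1, nrow(g$edges) >= 2L)
  n_swaps <- ceiling(fraction * nrow(g$edges) / 2)
  if (n_swaps == 0) return(g)
  edges <- g$edges
  ne <- nrow(edges)
  key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  present <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(ne)) assign(key(edges[r, 1L], edges[r, 2L]), TRUE,
                                envir = present)
  done <- 0L
  attempts <- 0L
  max_attempts <- 100 * n_swaps
  withr::with_seed(seed, {
    while (done < n_swaps) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop(sprintf("rewiring stalled: %d of %d swaps after %d attempts",
                     done, n_swaps, attempts - 1L))
      }
      idx <- sample.int(ne, 2L)
      a <- edges[idx[1L], 1L]; b <- edges[idx[1L], 2L]
      c_ <- edges[idx[2L], 1L]; d_ <- edges[idx[2L], 2L]
      if (stats::runif(1L) < 0.5) { tmp <- c_; c_ <- d_; d_ <- tmp }
      if (a == d_ || c_ == b) next
      k1 <- key(a, d_); k2 <- key(c_, b)
      if (k1 == k2) next
      if (exists(k1, envir = present) || exists(k2, envir = present)) next
      rm(list = c(key(a, b), key(c_, d_)), envir = present)
      assign(k1, TRUE, envir = present)
      assign(k2, TRUE, envir = present)
      edges[idx[1L], ] <- c(min(a, d_), max(a, d_))
      edges[idx[2L], ] <- c(min(c_, b), max(c_, b))
      done <- done + 1L
    }
  })
  ugraph(g$n_nodes, edges, coords = g$coords)
}

#' Generate a null network from a declarative recipe
#'
#' Dispatches on `spec$generator` (`"hvor"`, `"pvor"`, `"random"`,
#' `"rewired"`) with the remaining list entries as generator arguments; for
#' `"rewired"`, `spec$base` is itself a recipe and `spec$fraction` the
#' rewired edge fraction. Used by the workflow front-end so fixtures and
#' paper-scale networks come from the same code path.
#'
#' @param spec Named list: `generator`, generator parameters, `seed`.
#' @return A `ugraph`.
#' @export
generate_null_model <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$generator))
  gen <- spec$generator
  args <- spec[setdiff(names(spec), "generator")]
  switch(gen,
    hvor = do.call(homogeneous_voronoi, args),
    pvor = do.call(polar_voronoi, args),
    random = do.call(random_configuration, args),
    rewired = {
      base <- generate_null_model(args$base)
      rewire(base, args$fraction,
             seed = if (is.null(args$seed)) 1L else args$seed)
    },
    stop(sprintf("unknown generator '%s'", gen))
  )
}
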