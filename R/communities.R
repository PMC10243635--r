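#' Diffusion-community detection by k-means at a walk time
#'
#' Clusters the rows of the diffusion embedding `X(t) = Psi Lambda^t` (with
#' the constant mode-0 column dropped) into `k` communities with Lloyd
#' k-means: k-means++ seeded initialization, `nstart` restarts, relative
#' inertia tolerance 1e-6, nearest-centroid ties broken toward the lowest
#' community id, and empty clusters repaired by re-seeding from the point
#' farthest from its assigned centroid. `t` defaults to the floored
#' relaxation time; at that horizon most coordinates have underflowed to 0
#' and clustering acts on the few surviving slow modes, which is the intended
#' long-time structure.
#'
#' @param m A `spectral_model`.
#' @param k Number of communities, `1 <= k <= N`.
#' @param t Integer embedding time (default `floor(relaxation_time(m))`).
#' @param seed Integer RNG seed driving initialization of all restarts.
#' @param nstart Number of k-means restarts (best inertia wins, first on tie).
#' @param max_iter Maximum Lloyd iterations per restart.
#' @return Object of class `community_partition`: `labels` (0-based, length
#'   N), `k`, `t_embed`, `seed`.
#' @export
detect_communities <- function(m, k, t = NULL, seed = 1L, nstart = 10L,
                               max_iter = 100L) {
  n <- m$n
  k <- as.integer(k)
  if (k < 1L || k > n) stop(sprintf("k must be in 1..N (N = %d)", n))
  if (is.null(t)) t <- floor(relaxation_time(m))
  if (t < 0) stop("t must be a nonnegative integer")
  if (k == n) {
    labels <- seq_len(n) - 1L            # degenerate: every node its own
  } else if (k == 1L) {
    labels <- rep(0L, n)
  } else {
    X <- diffusion_coordinates(m, t)[, -1L, drop = FALSE]
    labels <- withr::with_seed(seed, {
      best <- NULL
      for (r in seq_len(nstart)) {
        fit <- lloyd_kmeans(X, k, max_iter = max_iter, tol = 1e-6)
        if (is.null(best) || fit$inertia < best$inertia) best <- fit
      }
      best$labels - 1L
    })
  }
  structure(list(labels = labels, k = k, t_embed = t, seed = seed),
            class = "community_partition")
}

# squared Euclidean distances points x centers
dist2_to_centers <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
  pmax(d2, 0)
}

kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2L, X[idx[1L], ], "-")^2)
  for (j in seq(2L, length.out = k - 1L)) {
    tot <- sum(d2)
    idx[j] <- if (tot <= 0) {
      # all remaining points coincide with a center: pick uniformly
      sample.int(n, 1L)
    } else {
      sample.int(n, 1L, prob = d2 / tot)
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[idx[j], ], "-")^2))
  }
  X[idx, , drop = FALSE]
}

lloyd_kmeans <- function(X, k, max_iter = 100L, tol = 1e-6) {
  n <- nrow(X)
  C <- kmeanspp_centers(X, k)
  labels <- integer(n)
  inertia <- Inf
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(X, C)
    labels <- max.col(-d2, ties.method = "first")  # lowest id on ties
    # repair empty clusters from the farthest point (deterministic)
    repair <- 0L
    repeat {
      sizes <- tabulate(labels, nbins = k)
      empty <- which(sizes == 0L)
      if (!length(empty) || repair >= 2L * k) break
      dmin <- d2[cbind(seq_len(n), labels)]
      far <- which.max(dmin)
      C[empty[1L], ] <- X[far, ]
      d2[, empty[1L]] <- rowSums(sweep(X, 2L, C[empty[1L], ], "-")^2)
      labels <- max.col(-d2, ties.method = "first")
      repair <- repair + 1L
    }
    if (any(tabulate(labels, nbins = k) == 0L)) {
      # pathological duplicate-heavy input: deterministically split the
      # largest cluster by node order until every community is populated
      labels <- fill_empty_clusters(labels, k)
      d2min <- rowSums((X - C[labels, , drop = FALSE])^2)
      inertia <- sum(d2min)
      break
    }
    new_inertia <- sum(d2[cbind(seq_len(n), labels)])
    C <- apply_center_update(X, labels, k, C)
    if (is.finite(inertia) &&
        (inertia - new_inertia) <= tol * max(new_inertia, .Machine$double.eps)) {
      inertia <- new_inertia
      break
    }
    inertia <- new_inertia
  }
  list(labels = labels, centers = C, inertia = inertia)
}

apply_center_update <- function(X, labels, k, C_old) {
  sums <- rowsum(X, group = factor(labels, levels = seq_len(k)))
  sizes <- tabulate(labels, nbins = k)
  C <- C_old
  ok <- sizes > 0L
  C[ok, ] <- sums[ok, , drop = FALSE] / sizes[ok]
  C
}

fill_empty_clusters <- function(labels, k) {
  repeat {
    sizes <- tabulate(labels, nbins = k)
    empty <- which(sizes == 0L)
    if (!length(empty)) return(labels)
    donor <- which.max(sizes)
    member <- which(labels == donor)[1L]
    labels[member] <- empty[1L]
  }
}

#' @export
print.community_partition <- function(x, ...) {
  s <- community_sizes(x)
  cat(sprintf(
    "community_partition: k = %d, t_embed = %d, sizes %d..%d (mean %.1f)\n",
    x$k, x$t_embed, min(s), max(s), mean(s)))
  invisible(x)
}

#' Community sizes
#'
#' Node counts per community (indexed by community id `0..k-1`); they always
#' sum to `N`.
#'
#' @param p A `community_partition`.
#' @return Integer vector of length `k`.
#' @export
community_sizes <- function(p) {
  tabulate(p$labels + 1L, nbins = p$k)
}
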