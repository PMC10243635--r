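# Small named graphs used across the suite (0-based ids).

g_triangle <- function() ugraph(3, rbind(c(0, 1), c(1, 2), c(0, 2)))
g_k4 <- function() ugraph(4, t(utils::combn(0:3, 2)))
g_p4 <- function() ugraph(4, rbind(c(0, 1), c(1, 2), c(2, 3)))
# triangle 0-1-2 plus pendant edge 2-3
g_lollipop <- function() ugraph(4, rbind(c(0, 1), c(1, 2), c(0, 2), c(2, 3)))
# two triangles joined by a bridge 2-3
g_dumbbell <- function() {
  ugraph(6, rbind(c(0, 1), c(1, 2), c(0, 2),
                  c(3, 4), c(4, 5), c(3, 5), c(2, 3)))
}
g_petersen <- function() {
  outer <- cbind(0:4, c(1:4, 0))
  inner <- cbind(5:9, 5 + (0:4 + 2) %% 5)
  spokes <- cbind(0:4, 5:9)
  ugraph(10, rbind(outer, inner, spokes))
}
# ring of n nodes with +/-1 and +/-2 chords: connected, 4-regular, odd cycles
g_circulant <- function(n) {
  e1 <- cbind(0:(n - 1), (1:n) %% n)
  e2 <- cbind(0:(n - 1), (2:(n + 1)) %% n)
  ugraph(n, rbind(e1, e2))
}

# random connected graph: random attachment tree + extra G(n,p) edges;
# an explicit triangle guarantees an odd cycle (non-bipartite)
random_connected_graph <- function(n, extra = n, seed = 1L,
                                   odd_cycle = TRUE) {
  withr::with_seed(seed, {
    tree <- cbind(1:(n - 1), vapply(1:(n - 1), function(i) {
      sample.int(i, 1L) - 1L
    }, integer(1L)))
    ex <- cbind(sample.int(n, extra, replace = TRUE),
                sample.int(n, extra, replace = TRUE)) - 1L
    ex <- ex[ex[, 1L] != ex[, 2L], , drop = FALSE]
    e <- rbind(tree, ex)
    if (odd_cycle && n >= 3) e <- rbind(e, c(0, 1), c(1, 2), c(0, 2))
    ugraph(n, unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))))
  })
}

# ---- independent oracles (kept free of the package's internal paths) ----

dense_T <- function(g) {
  n <- g$n_nodes
  A <- matrix(0, n, n)
  A[g$edges + 1L] <- 1
  A[g$edges[, 2:1, drop = FALSE] + 1L] <- 1
  A / rowSums(A)
}

# plain repeated multiplication, independent of the package's squaring code
dense_T_power <- function(Tm, t) {
  P <- diag(nrow(Tm))
  for (i in seq_len(t)) P <- P %*% Tm
  P
}

# mean entry/exit probabilities by direct averaging of T^t entries
oracle_pin_pout <- function(Tt, members) {
  n_in <- sum(members)
  n_out <- sum(!members)
  c(pin = sum(Tt[!members, members]) / (n_in * n_out),
    pout = sum(Tt[members, !members]) / (n_in * n_out))
}

# connected components by hand-rolled BFS
bfs_components <- function(g) {
  n <- g$n_nodes
  adj <- vector("list", n)
  for (r in seq_len(nrow(g$edges))) {
    i <- g$edges[r, 1L] + 1L; j <- g$edges[r, 2L] + 1L
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]]
      new <- nb[is.na(comp[nb])]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  comp
}

# weighted-l2 diffusion distance straight from the defining formula
oracle_diffusion_distance <- function(g, i0, i1, t) {
  Tm <- dense_T(g)
  Tt <- dense_T_power(Tm, t)
  d <- degrees(g)
  w <- 2 * nrow(g$edges) / d
  sqrt(sum((Tt[i0 + 1L, ] - Tt[i1 + 1L, ])^2 * w))
}

# exhaustive best 2-partition under the k-means objective
oracle_best_2partition <- function(X) {
  n <- nrow(X)
  best <- NULL
  best_cost <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    members <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (!any(members) || all(members)) next
    c1 <- colMeans(X[members, , drop = FALSE])
    c2 <- colMeans(X[!members, , drop = FALSE])
    cost <- sum(sweep(X[members, , drop = FALSE], 2L, c1)^2) +
      sum(sweep(X[!members, , drop = FALSE], 2L, c2)^2)
    if (cost < best_cost) {
      best_cost <- cost
      best <- members
    }
  }
  list(members = best, cost = best_cost)
}

full_model <- function(g) spectral_decomposition(transition_matrix(g), g$n_nodes)

partition_of <- function(labels, k, t = 0L, seed = 0L) {
  structure(list(labels = as.integer(labels), k = as.integer(k),
                 t_embed = t, seed = seed),
            class = "community_partition")
}
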