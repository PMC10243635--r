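#' Cheeger mixing index of one community
#'
#' `h(C) = cut(C, C-bar) / min(vol(C), vol(C-bar))`: the number of edges
#' leaving the community divided by the smaller of the two degree volumes.
#' Low values mean the community forms a compact neighbourhood in the graph
#' (high spatial coherence); values near 1 mean its nodes are scattered.
#'
#' @param g The `ugraph` the partition was computed on.
#' @param p A `community_partition`.
#' @param c Community id (0-based). Must be non-empty and proper.
#' @return A number in (0, 1] for any proper community of a connected graph.
#' @export
cheeger_index <- function(g, p, c) {
  members <- p$labels == c
  if (!any(members)) stop(sprintf("community %d is empty", c))
  if (all(members)) stop("community equals the whole node set (C-bar empty)")
  d <- degrees(g)
  in1 <- members[g$edges[, 1L] + 1L]
  in2 <- members[g$edges[, 2L] + 1L]
  cut <- sum(xor(in1, in2))
  vol_c <- sum(d[members])
  cut / min(vol_c, sum(d) - vol_c)
}

#' Mean Cheeger mixing index
#'
#' Unweighted arithmetic mean of [cheeger_index()] over all communities of a
#' partition; the headline spatial-coherence score of a network.
#'
#' @inheritParams cheeger_index
#' @return A number.
#' @export
mean_cheeger <- function(g, p) {
  if (p$k < 2L) stop("mean Cheeger index needs at least 2 communities")
  mean(vapply(seq_len(p$k) - 1L, function(c) cheeger_index(g, p, c),
              numeric(1L)))
}

# Per-community sums of the left/right eigenvector entries: the O(K*N)
# reduction that makes entry/exit probabilities tractable without T^t.
community_spectral_sums <- function(m, p) {
  sizes <- community_sizes(p)
  if (any(sizes == 0L)) stop("partition has empty communities")
  # reorder = TRUE sorts rows by community id 0..k-1
  list(SPsi = rowsum(m$Psi, p$labels, reorder = TRUE),   # k x K
       SPhi = rowsum(m$Phi, p$labels, reorder = TRUE),
       SPsi_tot = colSums(m$Psi),
       SPhi_tot = colSums(m$Phi),
       sizes = sizes)
}

#' Mean entry and exit probabilities for all communities over a time grid
#'
#' For each community `C` and time `t`,
#' `p_in  = mean over (source not in C, target in C) of p(target, t | source)`
#' `p_out = mean over (source in C, target not in C) of p(target, t | source)`
#' evaluated through the truncated spectrum via per-community eigenvector
#' sums (cost `O(k K)` per time), never via a dense `T^t`.
#'
#' @param m A `spectral_model`.
#' @param p A `community_partition` with `k >= 2`.
#' @param times Vector of nonnegative integer walk times.
#' @return List with matrices `pin` and `pout` (`k` rows, one column per
#'   time) and the `times` vector.
#' @export
community_probabilities <- function(m, p, times) {
  stopifnot(p$k >= 2L, all(times >= 0))
  cs <- community_spectral_sums(m, p)
  n <- m$n
  k <- p$k
  nc <- cs$sizes
  pairs <- nc * (n - nc)
  psi_out <- sweep(-cs$SPsi, 2L, cs$SPsi_tot, "+")  # sums over complement
  phi_out <- sweep(-cs$SPhi, 2L, cs$SPhi_tot, "+")
  pin <- matrix(NA_real_, k, length(times))
  pout <- matrix(NA_real_, k, length(times))
  for (j in seq_along(times)) {
    lt <- lambda_power(m$lambdas, times[j])
    ltm <- matrix(lt, k, m$K, byrow = TRUE)
    pin[, j] <- rowSums(psi_out * ltm * cs$SPhi) / pairs
    pout[, j] <- rowSums(cs$SPsi * ltm * phi_out) / pairs
  }
  list(pin = pin, pout = pout, times = times)
}

#' Mean entry probability of one community at one time
#'
#' @inheritParams community_probabilities
#' @param c Community id (0-based); must be proper.
#' @param t Nonnegative integer walk time.
#' @return A number (in `[0, 1]` at full rank; truncated values may deviate
#'   by the truncation error).
#' @export
entry_probability <- function(m, p, c, t) {
  if (all(p$labels == c)) stop("community equals the whole node set")
  community_probabilities(m, p, t)$pin[c + 1L, 1L]
}

#' Mean exit probability of one community at one time
#'
#' @inheritParams entry_probability
#' @return A number.
#' @export
exit_probability <- function(m, p, c, t) {
  if (all(p$labels == c)) stop("community equals the whole node set")
  community_probabilities(m, p, t)$pout[c + 1L, 1L]
}

#' Default logarithmic time grid around the relaxation time
#'
#' About `n_points` logarithmically spaced integer times from 1 to
#' `2 * floor(tau)`, always including `floor(tau)` (marked by the
#' `tau_index` attribute).
#'
#' @param tau Relaxation time (>= 1).
#' @param n_points Approximate grid size.
#' @return Increasing integer vector with attribute `tau_index`.
#' @export
time_grid <- function(tau, n_points = 12L) {
  stopifnot(tau >= 1)
  ft <- floor(tau)
  pts <- unique(round(exp(seq(0, log(max(2 * ft, 2)), length.out = n_points))))
  pts <- sort(unique(c(pts, ft)))
  pts <- pts[pts >= 1]
  attr(pts, "tau_index") <- match(ft, pts)
  pts
}

#' Across-community heterogeneity of entry/exit probabilities
#'
#' For every time in `grid`, the spread of `p_in` (and `p_out`) across the
#' `k` communities is summarized by the population standard deviation
#' (divisor `k`); the maxima over the grid, `max_t SD_C(p_in)` and
#' `max_t SD_C(p_out)`, are the network's heterogeneity statistics.
#'
#' @param m A `spectral_model`.
#' @param p A `community_partition` with `k >= 2`.
#' @param grid Increasing vector of positive integer times (see
#'   [time_grid()]).
#' @return List of class `heterogeneity`: `grid`, `sd_pin`, `sd_pout`
#'   (per-time vectors), `max_sd_pin`, `max_sd_pout`, and the underlying
#'   `pin`/`pout` matrices.
#' @export
heterogeneity <- function(m, p, grid) {
  stopifnot(length(grid) >= 1L)
  cp <- community_probabilities(m, p, grid)
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  sd_pin <- apply(cp$pin, 2L, sd_pop)
  sd_pout <- apply(cp$pout, 2L, sd_pop)
  structure(list(grid = grid, sd_pin = sd_pin, sd_pout = sd_pout,
                 max_sd_pin = max(sd_pin), max_sd_pout = max(sd_pout),
                 pin = cp$pin, pout = cp$pout),
            class = "heterogeneity")
}

#' @export
print.heterogeneity <- function(x, ...) {
  cat(sprintf("heterogeneity over %d times: max SD(p_in) = %.3g, max SD(p_out) = %.3g\n",
              length(x$grid), x$max_sd_pin, x$max_sd_pout))
  invisible(x)
}

#' Rank communities by a feature and extract the extremes
#'
#' Returns the `m` communities with the lowest (or highest) feature values,
#' sorted by value, optionally with values expressed as a percentage of the
#' mean across all communities (the convention used to single out remote
#' regions).
#'
#' @param values Numeric vector of one feature per community (index = id).
#' @param m Number of extreme communities to return (`m <= k`).
#' @param direction `"lowest"` or `"highest"`.
#' @param percent If `TRUE`, add `pct_of_mean = 100 * value / mean(values)`.
#' @return data.frame with columns `community`, `value` (and `pct_of_mean`).
#' @export
rank_communities <- function(values, m, direction = c("lowest", "highest"),
                             percent = FALSE) {
  direction <- match.arg(direction)
  stopifnot(m >= 1L, m <= length(values))
  ord <- if (direction == "lowest") order(values) else order(-values)
  sel <- ord[seq_len(m)]
  out <- data.frame(community = sel - 1L, value = values[sel])
  if (percent) out$pct_of_mean <- 100 * out$value / mean(values)
  out
}

#' Convert a biological residence time to random-walk steps
#'
#' One walk step corresponds to traversing one edge: the per-step duration is
#' `edge_length / speed`, rounded to 2 decimal places (minutes), and the step
#' count is `floor(residence / per-step duration)`. With a 12 h residence,
#' 13 um/min cell speed and 10 um edges this gives 935 steps (0.77 min per
#' step).
#'
#' @param residence Residence time in minutes.
#' @param speed Migration speed in um/min.
#' @param edge_length Mean edge length in um.
#' @return Integer number of steps.
#' @export
scan_steps <- function(residence, speed, edge_length) {
  if (residence <= 0 || speed <= 0 || edge_length <= 0) {
    stop("residence, speed and edge_length must all be positive")
  }
  step_min <- round(edge_length / speed, 2L)
  as.integer(floor(residence / step_min + 1e-9))
}

#' Per-community feature table
#'
#' One row per community: size, mean degree, Cheeger mixing index, and
#' `p_in`/`p_out` sampled on a time grid (columns `pin_t<t>`/`pout_t<t>`).
#'
#' @param g The `ugraph` of the analysis.
#' @param m Its `spectral_model`.
#' @param p A `community_partition` with `k >= 2`.
#' @param grid Integer time grid (see [time_grid()]).
#' @return data.frame with `k` rows.
#' @export
feature_table <- function(g, m, p, grid) {
  d <- degrees(g)
  sizes <- community_sizes(p)
  mean_deg <- as.numeric(rowsum(d, p$labels, reorder = TRUE)) / sizes
  ch <- vapply(seq_len(p$k) - 1L, function(c) cheeger_index(g, p, c),
               numeric(1L))
  cp <- community_probabilities(m, p, grid)
  out <- data.frame(community = seq_len(p$k) - 1L, n_nodes = sizes,
                    mean_degree = mean_deg, cheeger = ch)
  pin <- as.data.frame(cp$pin)
  names(pin) <- paste0("pin_t", grid)
  pout <- as.data.frame(cp$pout)
  names(pout) <- paste0("pout_t", grid)
  cbind(out, pin, pout)
}
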