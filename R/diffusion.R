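#' Truncated biorthogonal spectral decomposition of the transition matrix
#'
#' Computes the `K` largest-magnitude eigenpairs of the symmetrized walk
#' matrix `S = D^-1/2 A D^-1/2` (which shares its spectrum with
#' `T = D^-1 A`), then maps the orthonormal eigenvectors `v_k` to the
#' biorthogonal eigensystem of `T`:
#' `psi_k = sqrt(2E) D^-1/2 v_k` (right), `phi_k = D^1/2 v_k / sqrt(2E)`
#' (left), so that `T = Psi Lambda Phi^T`, `Phi^T Psi = I`, `psi_0 == 1`
#' and `phi_0 = d/(2E)` (the stationary distribution).
#'
#' Eigenvalues are ordered by decreasing magnitude with `lambda_0 = 1` first;
#' each `v_k` is sign-fixed so its largest-magnitude entry is positive. Small
#' problems (or `K` close to `N`) use a dense symmetric solver; larger ones
#' use ARPACK (via igraph) with a seeded start vector so repeated runs agree.
#'
#' @param tm A `transition_matrix` from a connected graph.
#' @param K Truncation order, `1 <= K <= N`.
#' @return Object of class `spectral_model`: `K`, `lambdas`, `Psi` (N x K),
#'   `Phi` (N x K), `d`, `E`, `n`.
#' @export
spectral_decomposition <- function(tm, K) {
  n <- tm$n
  K <- as.integer(K)
  if (K < 1L || K > n) stop(sprintf("K must be in 1..N (N = %d)", n))
  sq <- sqrt(tm$d)
  S <- Matrix::Diagonal(x = sq) %*% tm$Tm %*% Matrix::Diagonal(x = 1 / sq)
  S <- Matrix::forceSymmetric((S + Matrix::t(S)) / 2)
  if (n <= 600L || K > n - 2L) {
    ev <- eigen(as.matrix(S), symmetric = TRUE)
    ord <- order(-abs(ev$values), -ev$values)[seq_len(K)]
    vals <- ev$values[ord]
    vecs <- ev$vectors[, ord, drop = FALSE]
  } else {
    mult <- function(x, extra) as.numeric(S %*% x)
    opts <- list(n = n, nev = K, ncv = min(n, max(2L * K + 1L, 20L)),
                 which = "LM", maxiter = 5000L)
    res <- withr::with_seed(20230524L, igraph::arpack(mult, sym = TRUE,
                                                      options = opts))
    if (length(res$values) < K) {
      stop(sprintf("eigen-solver returned %d of %d requested pairs (ARPACK)",
                   length(res$values), K))
    }
    ord <- order(-abs(res$values), -res$values)
    vals <- res$values[ord]
    vecs <- matrix(res$vectors, nrow = n)[, ord, drop = FALSE]
  }
  if (abs(vals[1L] - 1) > 1e-6) {
    stop("leading eigenvalue is not 1; is the graph connected?")
  }
  vals[1L] <- 1
  # sign convention: largest-magnitude entry of each orthonormal vector > 0
  for (k in seq_len(K)) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  s2E <- sqrt(2 * tm$E)
  Psi <- (s2E / sq) * vecs
  Phi <- (sq / s2E) * vecs
  structure(list(K = K, lambdas = vals, Psi = Psi, Phi = Phi,
                 d = tm$d, E = tm$E, n = n),
            class = "spectral_model")
}

#' @export
print.spectral_model <- function(x, ...) {
  cat(sprintf("spectral_model: N = %d, K = %d, |lambda_1| = %.6f\n",
              x$n, x$K, if (x$K >= 2L) abs(x$lambdas[2L]) else NA_real_))
  invisible(x)
}

# lambda^t with sign handled explicitly and graceful underflow to 0,
# stable for very large integer t (computed as exp(t*log|lambda|))
lambda_power <- function(lambda, t) {
  if (t == 0) return(rep(1, length(lambda)))
  mag <- abs(lambda)
  out <- numeric(length(lambda))
  pos <- mag > 0
  out[pos] <- exp(t * log(mag[pos]))
  neg_odd <- lambda < 0 & (t %% 2 == 1)
  out[neg_odd] <- -out[neg_odd]
  out
}

#' Diffusion coordinates X(t) = Psi Lambda^t
#'
#' Embedding of every node at walk time `t`. Column 1 (mode 0) is constant 1
#' for every `t`; coordinates whose magnitude underflows double precision
#' flush to 0.
#'
#' @param m A `spectral_model`.
#' @param t Nonnegative integer walk time.
#' @return N x K numeric matrix.
#' @export
diffusion_coordinates <- function(m, t) {
  if (t < 0) stop("t must be a nonnegative integer")
  lp <- lambda_power(m$lambdas, t)
  m$Psi %*% diag(lp, nrow = m$K)
}

#' Diffusion distance between two nodes
#'
#' `D_t(i0, i1) = sqrt(sum_{k>=1} lambda_k^{2t} (psi_k(i0) - psi_k(i1))^2)`.
#' With `K = N` this equals the degree-weighted l2 distance between the
#' t-step presence fields started at `i0` and `i1` (weights `w(j) = 2E/d_j`).
#'
#' @param m A `spectral_model`.
#' @param i0,i1 Node ids (0-based).
#' @param t Nonnegative integer walk time.
#' @return Nonnegative number.
#' @export
diffusion_distance <- function(m, i0, i1, t) {
  stopifnot(i0 >= 0, i0 < m$n, i1 >= 0, i1 < m$n, t >= 0)
  if (i0 == i1) return(0)
  dpsi <- m$Psi[i0 + 1L, ] - m$Psi[i1 + 1L, ]
  lp2 <- lambda_power(abs(m$lambdas), 2 * t)  # lambda^(2t) >= 0
  sqrt(sum(lp2[-1L] * dpsi[-1L]^2))
}

#' Presence field of a random walker
#'
#' Probability `p(j, t | i)` of finding at time `t` a walker that started at
#' node `i`, reconstructed through the truncated spectrum:
#' `p(j, t | i) = sum_k psi_k(i) lambda_k^t phi_k(j)`. With `K = N` this is
#' exactly row `i` of `T^t`; with `K < N` the total reconstructed mass (which
#' deviates from 1 by the truncation error) is attached as attribute `mass`.
#'
#' @param m A `spectral_model`.
#' @param i Source node id (0-based).
#' @param t Nonnegative integer walk time.
#' @return Numeric vector over nodes, with attribute `mass`.
#' @export
presence_field <- function(m, i, t) {
  stopifnot(i >= 0, i < m$n, t >= 0)
  coef <- m$Psi[i + 1L, ] * lambda_power(m$lambdas, t)
  p <- as.numeric(m$Phi %*% coef)
  attr(p, "mass") <- sum(p)
  p
}

#' Relaxation time of the random walk
#'
#' `tau = 1 / (1 - |lambda_1|)` where `|lambda_1|` is the second-largest
#' eigenvalue magnitude: the characteristic number of steps for the walk to
#' approach stationarity. Undefined when `|lambda_1| = 1` (bipartite or
#' disconnected graph).
#'
#' @param m A `spectral_model` with `K >= 2`.
#' @return Positive number (not floored; callers floor when a step count is
#'   needed).
#' @export
relaxation_time <- function(m) {
  if (m$K < 2L) stop("relaxation time needs at least K = 2 eigenvalues")
  l1 <- abs(m$lambdas[2L])
  if (1 - l1 < 1e-9) {
    stop(paste("relaxation time undefined: |lambda_1| = 1,",
               "the graph is bipartite or disconnected"))
  }
  1 / (1 - l1)
}

# dense matrix power by repeated squaring (reference computations only)
dense_matrix_power <- function(M, t) {
  n <- nrow(M)
  out <- diag(n)
  P <- M
  while (t > 0) {
    if (t %% 2 == 1) out <- out %*% P
    t <- t %/% 2
    if (t > 0) P <- P %*% P
  }
  out
}

#' Relative truncation error of the spectral approximation
#'
#' Relative spectral-norm error `||T^t - That_K^t||_2 / ||T^t||_2` between the
#' exact dense `t`-step propagator and its rank-`K` spectral reconstruction.
#' Exact dense computation is used as the reference, so the graph size is
#' capped (`n_cap`, default 2000 nodes).
#'
#' @param tm A `transition_matrix`.
#' @param K Truncation order.
#' @param t Nonnegative integer walk time.
#' @param model Optional precomputed full-rank (`K = N`) `spectral_model`,
#'   reused across calls; the truncation takes its first `K` modes.
#' @param n_cap Maximum graph size for the dense reference.
#' @return Nonnegative number.
#' @export
truncation_error <- function(tm, K, t, model = NULL, n_cap = 2000L) {
  if (tm$n > n_cap) {
    stop(sprintf("N = %d exceeds the dense cap (%d); use a smaller fixture",
                 tm$n, n_cap))
  }
  if (is.null(model)) model <- spectral_decomposition(tm, tm$n)
  stopifnot(model$n == tm$n, model$K >= K)
  Tt <- dense_matrix_power(as.matrix(tm$Tm), t)
  lp <- lambda_power(model$lambdas[seq_len(K)], t)
  That <- model$Psi[, seq_len(K), drop = FALSE] %*%
    (lp * t(model$Phi[, seq_len(K), drop = FALSE]))
  norm(Tt - That, type = "2") / norm(Tt, type = "2")
}

#' Restrict a spectral model to its first K modes
#'
#' Returns the rank-`K` truncation of an existing decomposition (its `K`
#' largest-magnitude modes), so one expensive full or high-rank
#' decomposition can serve both a low-rank clustering embedding and
#' high-accuracy feature evaluation.
#'
#' @param m A `spectral_model`.
#' @param K New truncation order, `1 <= K <= m$K`.
#' @return A `spectral_model` of rank `K`.
#' @export
truncate_model <- function(m, K) {
  K <- as.integer(K)
  if (K < 1L || K > m$K) stop(sprintf("K must be in 1..%d", m$K))
  structure(list(K = K, lambdas = m$lambdas[seq_len(K)],
                 Psi = m$Psi[, seq_len(K), drop = FALSE],
                 Phi = m$Phi[, seq_len(K), drop = FALSE],
                 d = m$d, E = m$E, n = m$n),
            class = "spectral_model")
}

#' Save / load a spectral model
#'
#' The decomposition is the expensive step of the workflow, so it can be
#' serialized once and reused. The container stores the eigensystem arrays
#' together with `K`, `E` and a checksum of the degree sequence used to guard
#' against pairing a model with the wrong graph.
#'
#' @param m A `spectral_model`.
#' @param path File path (`.rds` container).
#' @return `save_spectral_model`: invisibly, `path`. `load_spectral_model`:
#'   the restored `spectral_model`.
#' @export
save_spectral_model <- function(m, path) {
  stopifnot(inherits(m, "spectral_model"))
  payload <- unclass(m)
  payload$degree_checksum <- degree_checksum(m$d)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_spectral_model
#' @param g Optional `ugraph` to validate the model against on load.
#' @export
load_spectral_model <- function(path, g = NULL) {
  payload <- readRDS(path)
  if (!is.null(g) && degree_checksum(degrees(g)) != payload$degree_checksum) {
    stop("spectral model does not match this graph (degree checksum differs)")
  }
  payload$degree_checksum <- NULL
  structure(payload, class = "spectral_model")
}

degree_checksum <- function(d) {
  sum(as.numeric(d) * (seq_along(d) %% 97 + 1))
}
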