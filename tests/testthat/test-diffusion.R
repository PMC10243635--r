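test_that("closed-form spectra are recovered", {
  m3 <- full_model(g_triangle())
  expect_equal(m3$lambdas, c(1, -0.5, -0.5), tolerance = 1e-10)
  mp4 <- full_model(g_p4())
  expect_equal(sort(mp4$lambdas), c(-1, -0.5, 0.5, 1), tolerance = 1e-10)
  # magnitude ordering puts -1 second
  expect_equal(abs(mp4$lambdas[2]), 1, tolerance = 1e-10)
})

test_that("biorthogonality and stationary-mode invariants hold", {
  for (s in 1:5) {
    g <- random_connected_graph(40, seed = s)
    m <- full_model(g)
    expect_lt(max(abs(crossprod(m$Phi, m$Psi) - diag(m$K))), 1e-8)
    expect_equal(m$Psi[, 1], rep(1, g$n_nodes), tolerance = 1e-8)
    expect_equal(m$Phi[, 1], degrees(g) / (2 * nrow(g$edges)),
                 tolerance = 1e-8)
    expect_true(all(abs(m$lambdas) <= 1 + 1e-10))
    # eigen relation T Psi = Psi Lambda, column by column
    Tm <- dense_T(g)
    expect_lt(max(abs(Tm %*% m$Psi - m$Psi %*% diag(m$lambdas))), 1e-8)
  }
})

test_that("ARPACK and dense paths agree on eigenvalues", {
  g <- random_connected_graph(700, extra = 1200, seed = 2)
  tm <- transition_matrix(g)
  K <- 12L
  m_arpack <- spectral_decomposition(tm, K)        # N > 600: iterative path
  dense <- eigen(as.matrix(
    diag(sqrt(tm$d)) %*% as.matrix(tm$Tm) %*% diag(1 / sqrt(tm$d))),
    symmetric = TRUE, only.values = TRUE)$values
  dense <- dense[order(-abs(dense))][seq_len(K)]
  expect_equal(m_arpack$lambdas, dense, tolerance = 1e-8)
  expect_lt(max(abs(crossprod(m_arpack$Phi, m_arpack$Psi) - diag(K))), 1e-8)
})

test_that("diffusion coordinates: X(0) = Psi, constant first column, mixing", {
  m <- full_model(g_triangle())
  expect_equal(diffusion_coordinates(m, 0), m$Psi)
  for (t in c(1, 7, 100)) {
    expect_equal(diffusion_coordinates(m, t)[, 1], rep(1, 3))
  }
  X <- diffusion_coordinates(m, 1e6)
  expect_equal(X, cbind(1, 0, 0) %x% rep(1, 3), ignore_attr = TRUE)
  expect_error(diffusion_coordinates(m, -1), "nonnegative")
})

test_that("diffusion distance matches the weighted-l2 definition at K = N", {
  m3 <- full_model(g_triangle())
  expect_equal(diffusion_distance(m3, 0, 0, 3), 0)
  expect_equal(diffusion_distance(m3, 0, 1, 1), sqrt(1.5), tolerance = 1e-10)
  # vertex transitivity of K3
  for (t in 0:3) {
    d01 <- diffusion_distance(m3, 0, 1, t)
    expect_equal(diffusion_distance(m3, 0, 2, t), d01, tolerance = 1e-12)
    expect_equal(diffusion_distance(m3, 1, 2, t), d01, tolerance = 1e-12)
  }
  for (s in 1:5) {
    g <- random_connected_graph(30, seed = s + 50)
    m <- full_model(g)
    for (t in c(1, 3, 8)) {
      expect_equal(diffusion_distance(m, 0, 5, t),
                   oracle_diffusion_distance(g, 0, 5, t), tolerance = 1e-8)
    }
  }
})

test_that("presence fields reproduce dense walk enumeration", {
  mp4 <- full_model(g_p4())
  expect_equal(as.numeric(presence_field(mp4, 0, 1)), c(0, 1, 0, 0),
               tolerance = 1e-10)
  expect_equal(as.numeric(presence_field(mp4, 0, 2)), c(0.5, 0, 0.5, 0),
               tolerance = 1e-10)
  ml <- full_model(g_lollipop())
  for (i in 0:3) {
    expect_equal(as.numeric(presence_field(ml, i, 1e6)),
                 c(1, 1, 1.5, 0.5) / 4, tolerance = 1e-9)
  }
})

test_that("truncated mass converges to 1 as K grows to N", {
  g <- random_connected_graph(40, seed = 3)
  tm <- transition_matrix(g)
  mass_err <- vapply(c(5L, 20L, 40L), function(K) {
    m <- spectral_decomposition(tm, K)
    abs(attr(presence_field(m, 0, 3), "mass") - 1)
  }, numeric(1))
  expect_lt(mass_err[3], 1e-8)
  expect_true(mass_err[3] <= mass_err[1] + 1e-12)
})

test_that("relaxation time follows the spectral gap and flags bipartiteness", {
  expect_equal(relaxation_time(full_model(g_triangle())), 2)
  expect_equal(relaxation_time(full_model(g_k4())), 1.5)
  expect_error(relaxation_time(full_model(g_p4())), "bipartite")
})

test_that("lambda powers underflow gracefully at huge times", {
  lp <- diffcomm:::lambda_power(c(1, 0.9999, -0.5, 0), 1e6)
  expect_equal(lp[1], 1)
  expect_gt(lp[2], 0)
  expect_equal(lp[3], 0)
  expect_equal(lp[4], 0)
  # odd power keeps the sign of a negative eigenvalue
  expect_lt(diffcomm:::lambda_power(-0.5, 3), 0)
  expect_equal(diffcomm:::lambda_power(c(-0.5, 0.25), 0), c(1, 1))
})

test_that("truncation error: zero at full rank, monotone in K, decaying in t", {
  g <- random_connected_graph(80, seed = 6)
  tm <- transition_matrix(g)
  mod <- spectral_decomposition(tm, tm$n)
  expect_lt(truncation_error(tm, tm$n, 3, model = mod), 1e-10)
  errs_K <- vapply(c(10L, 30L, 60L, 80L), function(K) {
    truncation_error(tm, K, 3, model = mod)
  }, numeric(1))
  expect_true(all(diff(errs_K) <= 1e-10))
  errs_t <- vapply(c(1L, 3L, 8L, 20L), function(t) {
    truncation_error(tm, 20L, t, model = mod)
  }, numeric(1))
  expect_true(all(diff(errs_t) <= 1e-10))
  expect_error(truncation_error(tm, 10, 1, n_cap = 50), "cap")
})

test_that("model truncation preserves the leading modes and invariants", {
  g <- random_connected_graph(40, seed = 12)
  tm <- transition_matrix(g)
  mF <- full_model(g)
  m10 <- truncate_model(mF, 10)
  expect_equal(m10$lambdas, mF$lambdas[1:10])
  expect_equal(m10$Psi, mF$Psi[, 1:10])
  expect_equal(presence_field(m10, 0, 4),
               presence_field(spectral_decomposition(tm, 10), 0, 4),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(truncate_model(m10, 11), "K must be")
})

test_that("spectral model serialization round-trips with a graph guard", {
  g <- random_connected_graph(25, seed = 9)
  m <- full_model(g)
  f <- withr::local_tempfile(fileext = ".rds")
  save_spectral_model(m, f)
  m2 <- load_spectral_model(f, g = g)
  expect_equal(m2$lambdas, m$lambdas)
  expect_equal(m2$Psi, m$Psi)
  other <- random_connected_graph(26, seed = 10)
  expect_error(load_spectral_model(f, g = other), "checksum")
})

test_that("decomposition rejects invalid truncation orders", {
  tm <- transition_matrix(g_triangle())
  expect_error(spectral_decomposition(tm, 0), "K must be")
  expect_error(spectral_decomposition(tm, 4), "K must be")
})
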