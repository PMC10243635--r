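test_that("Cheeger mixing index matches hand-counted cuts and volumes", {
  p4 <- g_p4()
  part <- partition_of(c(0, 0, 1, 1), 2)
  expect_equal(cheeger_index(p4, part, 0), 1 / 3)
  k4 <- g_k4()
  expect_equal(cheeger_index(k4, partition_of(c(0, 0, 1, 1), 2), 0), 2 / 3)
  single <- partition_of(c(0, 1, 1, 1), 2)
  expect_equal(cheeger_index(p4, single, 0), 1)
  expect_error(cheeger_index(p4, partition_of(c(0, 0, 0, 0), 1), 0),
               "whole node set")
  expect_error(cheeger_index(p4, partition_of(c(0, 0, 0, 1), 3), 2), "empty")
})

test_that("mean Cheeger index averages per-community values", {
  k4 <- g_k4()
  expect_equal(mean_cheeger(k4, partition_of(c(0, 0, 1, 1), 2)), 2 / 3)
  p4 <- g_p4()
  expect_equal(mean_cheeger(p4, partition_of(c(0, 0, 1, 1), 2)), 1 / 3)
  g <- random_connected_graph(30, seed = 2)
  m <- full_model(g)
  p <- detect_communities(m, 4, t = 3, seed = 1)
  hs <- vapply(0:3, function(c) cheeger_index(g, p, c), numeric(1))
  expect_equal(mean_cheeger(g, p), mean(hs))
  expect_error(mean_cheeger(g, partition_of(rep(0, 30), 1)), "at least 2")
})

test_that("entry/exit probabilities match closed-form examples and limits", {
  m4 <- full_model(g_k4())
  p <- partition_of(c(0, 1, 1, 1), 2)
  expect_equal(entry_probability(m4, p, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(exit_probability(m4, p, 0, 1), 1 / 3, tolerance = 1e-12)
  ml <- full_model(g_lollipop())
  pl <- partition_of(c(0, 0, 0, 1), 2)
  # stationary limits: mean degree of C (resp. C-bar) over the volume 2E
  expect_equal(entry_probability(ml, pl, 1, 1e6), 1 / 8, tolerance = 1e-9)
  expect_equal(exit_probability(ml, pl, 1, 1e6), 7 / 24, tolerance = 1e-9)
  expect_error(entry_probability(ml, partition_of(rep(0, 4), 1), 0, 1),
               "whole node set")
})

test_that("entry/exit equal dense T^t averaging on random fixtures", {
  for (s in 1:4) {
    g <- random_connected_graph(35, seed = s + 200)
    m <- full_model(g)
    p <- detect_communities(m, 3, t = 2, seed = s)
    Tm <- dense_T(g)
    for (t in c(1, 4, 9)) {
      Tt <- dense_T_power(Tm, t)
      cp <- community_probabilities(m, p, t)
      for (c in 0:2) {
        oracle <- oracle_pin_pout(Tt, p$labels == c)
        expect_equal(cp$pin[c + 1, 1], unname(oracle["pin"]),
                     tolerance = 1e-8)
        expect_equal(cp$pout[c + 1, 1], unname(oracle["pout"]),
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("regular graphs have identical entry and exit probabilities", {
  for (g in list(g_k4(), g_petersen(), g_circulant(12))) {
    m <- full_model(g)
    p <- detect_communities(m, 3, t = 1, seed = 1)
    for (t in c(0, 1, 5, 20)) {
      cp <- community_probabilities(m, p, t)
      expect_equal(cp$pin, cp$pout, tolerance = 1e-10)
    }
  }
})

test_that("heterogeneity is zero under exact symmetry and obeys the grid", {
  m4 <- full_model(g_k4())
  p <- partition_of(c(0, 0, 1, 1), 2)
  h <- heterogeneity(m4, p, c(1, 2, 5, 10))
  expect_equal(h$max_sd_pin, 0, tolerance = 1e-12)
  expect_equal(h$max_sd_pout, 0, tolerance = 1e-12)
  # a singleton grid's maximum is that time's SD
  g <- random_connected_graph(30, seed = 5)
  m <- full_model(g)
  pp <- detect_communities(m, 4, t = 2, seed = 2)
  h1 <- heterogeneity(m, pp, 3)
  expect_equal(h1$max_sd_pin, h1$sd_pin[1])
  # population SD definition (divisor k)
  cp <- community_probabilities(m, pp, 3)
  expect_equal(h1$sd_pin[1], sqrt(mean((cp$pin - mean(cp$pin))^2)))
})

test_that("community ranking orders, truncates and reports percentages", {
  r <- rank_communities(c(0.1, 0.5, 0.3), 1, "lowest")
  expect_equal(r$community, 0L)
  r2 <- rank_communities(c(0.1, 0.5, 0.3), 3, "lowest")
  expect_equal(r2$community, c(0L, 2L, 1L))
  r3 <- rank_communities(c(0.1, 0.5, 0.3), 2, "highest")
  expect_equal(r3$community, c(1L, 2L))
  r4 <- rank_communities(c(1, 2, 3), 3, "lowest", percent = TRUE)
  expect_equal(r4$pct_of_mean, c(50, 100, 150))
})

test_that("scan-time conversion rounds the per-step duration first", {
  expect_identical(scan_steps(720, 13, 10), 935L)
  expect_identical(scan_steps(720, 10, 10), 720L)
  expect_identical(scan_steps(0.77, 13, 10), 1L)
  expect_error(scan_steps(0, 13, 10), "positive")
  expect_error(scan_steps(720, -1, 10), "positive")
})

test_that("default time grid is sorted, unique and anchored at floor(tau)", {
  for (tau in c(1.2, 7.9, 293.4, 17797.4)) {
    tg <- time_grid(tau)
    expect_true(all(diff(tg) > 0))
    expect_true(all(tg >= 1))
    expect_true(floor(tau) %in% tg)
    expect_equal(tg[attr(tg, "tau_index")], floor(tau))
    expect_lte(max(tg), max(2 * floor(tau), 2))
  }
})

test_that("feature table carries sizes, degrees, Cheeger and probabilities", {
  g <- random_connected_graph(40, seed = 8)
  m <- full_model(g)
  p <- detect_communities(m, 4, t = 2, seed = 3)
  ft <- feature_table(g, m, p, c(1, 5))
  expect_equal(nrow(ft), 4L)
  expect_named(ft, c("community", "n_nodes", "mean_degree", "cheeger",
                     "pin_t1", "pin_t5", "pout_t1", "pout_t5"))
  expect_equal(sum(ft$n_nodes), 40L)
  expect_equal(ft$cheeger[1], cheeger_index(g, p, 0))
  expect_equal(ft$pin_t5[2], entry_probability(m, p, 1, 5), tolerance = 1e-12)
  # weighted mean of community mean degrees recovers the global mean degree
  expect_equal(sum(ft$mean_degree * ft$n_nodes) / 40, mean_degree(g))
})

test_that("features are invariant to community relabelling", {
  g <- random_connected_graph(30, seed = 14)
  m <- full_model(g)
  p <- detect_communities(m, 3, t = 2, seed = 1)
  perm <- c(2L, 0L, 1L)
  q <- partition_of(perm[p$labels + 1L], 3)
  expect_equal(mean_cheeger(g, p), mean_cheeger(g, q))
  hp <- heterogeneity(m, p, c(1, 3))
  hq <- heterogeneity(m, q, c(1, 3))
  expect_equal(hp$max_sd_pin, hq$max_sd_pin)
  expect_equal(sort(community_sizes(p)), sort(community_sizes(q)))
})
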