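test_that("full connection probability gives the complete digraph", {
  cfg <- network_config(N = 3, N_E = 2, N_I = 1, Q = 1, f = 1,
                        p_EE = 1, p_EI = 1, p_IE = 1, p_II = 1)
  edges <- build_connectivity(cfg)
  expect_equal(nrow(edges), 6L)  # 3 * 2 directed pairs, no self-loops
  expect_false(any(edges$pre == edges$post))
})

test_that("edge counts follow the binomial law of the connection draw", {
  cfg <- network_config(N = 1000, seed = 5)
  counts <- vapply(1:8, function(s) {
    e <- build_connectivity(cfg, seed = s)
    sum(e$pre <= 800 & e$post <= 800)
  }, numeric(1))
  n_pairs <- 800 * 799
  expect_lt(abs(mean(counts) - 0.2 * n_pairs),
            3 * sqrt(0.2 * 0.8 * n_pairs / 8))
})

test_that("Dale's law holds at construction and weights carry the right sign", {
  edges <- build_connectivity(tiny_cfg())
  E_rows <- edges$pre <= 80
  expect_true(all(edges$w[E_rows] >= 0))
  expect_true(all(edges$w[!E_rows] <= 0))
  expect_true(all(edges$plastic == (edges$pre <= 80 & edges$post <= 80)))
})

test_that("construction is reproducible from the seed", {
  cfg <- tiny_cfg(seed = 123L)
  expect_identical(build_network(cfg)$edges, build_network(cfg)$edges)
  expect_identical(build_network(cfg)$clusters$eta,
                   build_network(cfg)$clusters$eta)
})

test_that("cluster membership statistics match the Bernoulli closed forms", {
  # f = 0.1, Q = 10, N_E = 800: non-responsive fraction (1-f)^Q ~ 0.3487,
  # P(>= 2 stimuli) ~ 0.2639, responsive-in->=2 ~ 0.6126, mean size 80.
  stats <- purrr::map_dfr(1:400, function(s)
    cluster_stats(assign_clusters(800, 10, 0.1, seed = s)))
  n <- nrow(stats) * 800
  p0 <- (1 - 0.1)^10
  se0 <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(mean(stats$frac_nonresponsive) - p0), 3 * se0)
  expect_lt(abs(mean(stats$frac_responsive) - (1 - p0)), 3 * se0)
  pg2 <- 1 - p0 - 10 * 0.1 * 0.9^9
  expect_lt(abs(mean(stats$frac_ge2) - pg2),
            3 * sqrt(pg2 * (1 - pg2) / n))
  # membership-weighted multi-cluster fraction: 1 - (1-f)^(Q-1)
  pov <- 1 - (1 - 0.1)^9
  expect_equal(mean(stats$frac_multi), pov, tolerance = 0.01)
  expect_equal(mean(stats$mean_size), 80, tolerance = 0.01)
  expect_equal(mean(stats$sd_size), sqrt(0.1 * 0.9 * 800), tolerance = 0.05)
})

test_that("degenerate coding levels behave as stated", {
  cl <- assign_clusters(50, 3, 1, seed = 1)
  expect_true(all(cl$eta == 1L))
  expect_error(assign_clusters(50, 3, 0, seed = 1), "f must be")
})

test_that("network scaling regimes reproduce the published sizes", {
  lin <- scale_network(5000, "linear")
  expect_equal(lin$N_E, 4000)
  expect_equal(lin$Q, 50)
  expect_equal(lin$f, 0.02)
  expect_equal(lin$mean_cluster_size, 80)
  expect_equal(scale_network(10000, "linear")$Q, 100)
  # sqrt regime agrees with the basic network at N = 1000
  expect_equal(scale_network(1000, "sqrt")$Q, 10)
  expect_equal(scale_network(1000, "sqrt")$f, 0.1)
  expect_equal(scale_network(5000, "sqrt")$Q, 22)
  expect_equal(scale_network(10000, "sqrt")$Q, 32)
  expect_equal(scale_network(15000, "sqrt")$Q, 39)
  expect_equal(scale_network(20000, "sqrt")$Q, 45)
  expect_error(scale_network(5000, "cubic"))
})

test_that("configuration invariants are enforced", {
  expect_error(network_config(p_EE = 1.5), "probabilities")
  expect_error(network_config(f = 0), "coding level")
  expect_error(network_config(N_E = 700, N_I = 200), "N_E \\+ N_I")
  expect_error(network_config(w_EI = 0.1), "inhibitory")
  expect_error(neuron_params(V_T = 30, V_peak = 25), "V_r <= V_L")
  expect_error(plasticity_params(tau_v = -1), "time constants")
})
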