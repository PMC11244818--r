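test_that("rate estimation: boxcar counts over the causal window", {
  empty <- tibble::tibble(time = numeric(), neuron = integer())
  r0 <- estimate_rates(empty, 5, 0, 1000)
  expect_true(all(r0$rates == 0))
  # one spike inside a 50 ms window reads 20 spikes/s
  sp <- tibble::tibble(time = 95, neuron = 2L)
  r1 <- estimate_rates(sp, 3, 0, 200, window_ms = 50, grid_ms = 10)
  expect_equal(max(r1$rates[2, ]), 20)
  expect_equal(sum(r1$rates[2, ] == 20), 5)  # covered by 5 grid points
  expect_true(all(r1$rates[c(1, 3), ] == 0))
})

test_that("rate estimation is unbiased for a Poisson train", {
  set.seed(31)
  rate <- 20
  spikes <- tibble::tibble(time = sort(runif(rate * 100, 0, 100000)),
                           neuron = 1L)
  r <- estimate_rates(spikes, 1, 0, 100000)
  n <- rate * 100
  expect_lt(abs(mean(r$rates) - rate), 3 * sqrt(n) / 100)
})

test_that("overlaps follow the rate-weighted definition and conventions", {
  cl <- structure(list(eta = rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)),
                       Q = 2, N_E = 4, f = 0.5),
                  class = "plastnet_clusters")
  # only cluster-1 neurons fire -> m_1 = 1, m_2 = 0
  sp <- tibble::tibble(time = rep(c(60, 70, 80), 2),
                       neuron = rep(1:2, each = 3))
  ov <- overlaps(estimate_rates(sp, 4, 0, 100), cl)
  at_peak <- ov[ov$time == 90, ]
  expect_equal(at_peak$m[at_peak$cluster == 1], 1)
  expect_equal(at_peak$m[at_peak$cluster == 2], 0)
  # silence -> all overlaps 0 by convention
  empty <- tibble::tibble(time = numeric(), neuron = integer())
  ov0 <- overlaps(estimate_rates(empty, 4, 0, 100), cl)
  expect_true(all(ov0$m == 0))
  # non-overlapping clusters covering all neurons: sum_q m_q = 1 wherever
  # there is any activity
  set.seed(7)
  sp2 <- tibble::tibble(time = sort(runif(400, 0, 1000)),
                        neuron = sample(1:4, 400, TRUE))
  ov2 <- overlaps(estimate_rates(sp2, 4, 0, 1000), cl)
  sums <- tapply(ov2$m, ov2$time, sum)
  expect_true(all(abs(sums - 1) < 1e-12 | sums == 0))
  expect_true(all(ov2$m >= 0 & ov2$m <= 1))
})

test_that("state detection: strict threshold, maximal runs, disjointness", {
  grid <- seq(10, 1000, by = 10)
  ov <- tibble::tibble(time = rep(grid, 2),
                       cluster = rep(1:2, each = length(grid)),
                       m = c(rep(0.6, length(grid)), rep(0.2, length(grid))))
  ov <- structure(ov, grid_ms = 10,
                  class = c("plastnet_overlaps", class(ov)))
  st <- detect_states(ov)
  expect_equal(nrow(st), 1L)
  expect_equal(st$duration, 1000)
  expect_false(st$complete)  # touches both boundaries
  # exactly at threshold: no state (strict inequality)
  ov$m[ov$cluster == 1] <- 0.5
  expect_equal(nrow(detect_states(ov)), 0L)
  # alternating clusters: segments never overlap in time
  m1 <- rep(c(0.9, 0.1), length.out = length(grid))
  ov$m <- c(m1, 1 - m1)
  st2 <- detect_states(ov)
  st2 <- st2[order(st2$onset), ]
  expect_true(all(st2$onset[-1] >= st2$offset[-nrow(st2)] - 1e-9))
})

test_that("duration statistics and the exponentiality diagnostic", {
  segs <- tibble::tibble(cluster = 1L, onset = c(0, 500, 1000),
                         offset = c(100, 700, 1300),
                         duration = c(100, 200, 300),
                         complete = TRUE)
  ds <- duration_stats(segs)
  expect_equal(ds$mean_ms, 200)
  expect_equal(ds$sd_ms, 100)
  # exponential dwell times have sd/mean ~ 1
  set.seed(11)
  d <- rexp(10000, 1 / 250)
  segs2 <- tibble::tibble(cluster = 1L, onset = 0, offset = d, duration = d,
                          complete = TRUE)
  ds2 <- duration_stats(segs2)
  expect_lt(ds2$exp_diagnostic, 3 / sqrt(10000) * sqrt(8))
  # single segment: sd flagged undefined; none complete: explicit NA marker
  expect_true(is.na(duration_stats(segs[1, ])$sd_ms))
  segs$complete <- FALSE
  expect_true(is.na(duration_stats(segs)$mean_ms))
  expect_equal(duration_stats(segs)$n_complete, 0L)
})

test_that("weight classes: partition, means, and relabeling invariance", {
  net <- build_network(tiny_cfg(seed = 14))
  wc <- mean_weights_by_class(net)
  expect_equal(wc$n0 + wc$n1, sum(net$edges$plastic))
  # uniform pre-training weights: w0 = w1 = w_EE
  expect_equal(wc$w0, 0.005)
  expect_equal(wc$w1, 0.005)
  # relabeling neurons leaves the class means unchanged
  set.seed(2)
  perm <- sample(80)
  net2 <- net
  pl <- net2$edges$plastic
  net2$edges$pre[pl] <- perm[net2$edges$pre[pl]]
  net2$edges$post[pl] <- perm[net2$edges$post[pl]]
  net2$clusters$eta <- net2$clusters$eta[, order(perm)]
  set.seed(3)
  net$edges$w[pl] <- runif(sum(pl))
  net2$edges$w[pl] <- net$edges$w[pl]
  wc1 <- mean_weights_by_class(net, net$clusters)
  wc2 <- mean_weights_by_class(net2, net2$clusters)
  expect_equal(wc1$w0, wc2$w0)
  expect_equal(wc1$w1, wc2$w1)
})

test_that("size-scaled weight drift collapses for synthetic 1/N series", {
  tser <- seq(0, 10000, by = 1000)
  mk <- function(N) tibble::tibble(time = tser, N = N,
                                   w0 = 0.005 + 0.2 * tser / N,
                                   w1 = 1 - 0.5 * tser / N)
  series <- dplyr::bind_rows(mk(1000), mk(5000), mk(20000))
  rates <- weight_change_rate(series)
  al <- scaling_alignment(rates)
  expect_lt(max(al$max_gap), 1e-12)
  expect_equal(unique(round(rates$N_dw_dt[rates$class == "w0"], 10)), 0.2)
  # constant snapshots -> zero drift
  flat <- tibble::tibble(time = tser, N = 1000, w0 = 0.3, w1 = 0.7)
  expect_true(all(weight_change_rate(flat)$dw_dt == 0))
  # non-monotone snapshot times are rejected
  bad <- flat; bad$time[3] <- bad$time[2]
  expect_error(weight_change_rate(bad), "increasing")
})
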