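pp <- plasticity_params()

test_that("filters relax to their fixed points", {
  np <- neuron_params()
  # constant V -> v_tilde converges to the exponential term
  V <- 18
  target <- np$Delta_T * exp((V - np$V_T) / np$Delta_T)
  st <- list(v_tilde = 0, s_tilde = 0)
  for (k in 1:40000)
    st <- filter_step(st$v_tilde, st$s_tilde, V, FALSE, np, pp, dt = 0.05)
  expect_equal(st$v_tilde, target, tolerance = 1e-6)
  # no spikes -> pure exponential decay of s_tilde
  s <- 0.02
  for (k in 1:2000)
    s <- filter_step(0, s, 0, FALSE, np, pp, dt = 0.5)$s_tilde
  expect_equal(s, 0.02 * exp(-1000 / pp$tau_s), tolerance = 1e-12)
})

test_that("s_tilde tracks the firing rate under periodic spiking", {
  np <- neuron_params()
  dt <- 0.05
  r <- 0.02  # spikes/ms = 20 spikes/s; r * tau_s = 20 >> 1
  period <- round(1 / r / dt)  # steps between spikes
  s <- 0
  for (k in 1:(400 * period)) {
    s <- filter_step(0, s, 0, spiked = (k %% period == 0), np, pp,
                     dt = dt)$s_tilde
  }
  expect_equal(s, r, tolerance = 0.05)
})

test_that("the threshold fixed point is v_tilde + gamma * s_tilde", {
  th <- 0.7; vt <- 0.5; st <- (0.7 - 0.5) / pp$gamma
  expect_equal(threshold_step(th, vt, st, pp, dt = 0.05), th)
})

test_that("t_half matches direct ODE integration over Delta in [0.01, 10]", {
  for (delta in c(0.01, 0.05, 0.3, 1, 3, 5, 10)) {
    expect_lt(abs(t_half(delta, 1) - ode_t_half(delta)) / ode_t_half(delta),
              0.01)
  }
})

test_that("t_half limits: ln 2 for small Delta, Delta/2 for large", {
  expect_equal(t_half(1e-4, 500) / 500, log(2), tolerance = 1e-4)
  expect_equal(t_half(3, 500) / 500, log(sinh(3) / sinh(1.5)),
               tolerance = 1e-12)
  expect_equal(t_half(8, 500) / 500, 4, tolerance = 0.01)
  # monotone nondecreasing
  d <- seq(0.01, 10, length.out = 200)
  expect_true(all(diff(t_half(d, 500)) >= 0))
  expect_error(t_half(0), "delta must be > 0")
})

test_that("single-spike weight update follows the rule exactly", {
  # balanced filters: no change
  expect_equal(apply_presynaptic_spike(0.2, 1, 1, pp), 0.2)
  # pure LTP at w = 0 with unit drive: Delta w = A_LTP
  expect_equal(apply_presynaptic_spike(0, 1, 0, pp), pp$A_LTP)
  expect_equal(pp$A_LTP, 0.005)
  # pure LTD from a small weight clamps at zero
  expect_equal(apply_presynaptic_spike(0.01, 0, 1, pp), 0)
  expect_equal(pp$A_LTD, 0.015)
  # LTP attenuation: ratio of increments is exp(-beta (w_b^2 - w_a^2))
  inc <- function(w) apply_presynaptic_spike(w, 2, 1, pp) - w
  # tolerance limited by cancellation in w + dw - w at w = 10
  expect_equal(inc(10) / inc(1), exp(-pp$beta * (100 - 1)),
               tolerance = 1e-6)
  # hand-set general case
  w <- 0.8; vt <- 1.3; th <- 0.6
  expect_equal(apply_presynaptic_spike(w, vt, th, pp),
               w + pp$A_LTP * exp(-pp$beta * w^2) * (vt - th))
})

test_that("weights stay nonnegative under a million random updates", {
  set.seed(99)
  w <- runif(1000, 0, 2)
  for (k in 1:1000) {
    vt <- runif(1000, 0, 3)
    th <- runif(1000, 0, 3)
    w <- apply_presynaptic_spike(w, vt, th, pp)
    if (k %% 100 == 0) expect_true(all(w >= 0))
  }
  expect_true(all(w >= 0))
})

test_that("an isolated postsynaptic spike opens an LTP window, then LTD,
          with near-zero integrated weight change", {
  np <- neuron_params()
  dt <- 0.05
  # quiescent neuron at the leak potential fires once
  vt <- 0; s <- 0; th <- 0
  kernel <- numeric(0)
  for (k in 1:40000) {  # 2 s
    V <- if (k == 2000) 25 else 0
    f <- filter_step(vt, s, V, spiked = (k == 2000), np, pp, dt)
    vt <- f$v_tilde; s <- f$s_tilde
    th <- threshold_step(th, vt, s, pp, dt)
    kernel <- c(kernel, vt - th)
  }
  post <- kernel[2001:40000]
  expect_gt(max(post), 0)   # transient LTP window ...
  expect_lt(min(post), 0)   # ... followed by LTD
  # the sign change is LTP-first
  first_neg <- which(post < 0)[1]
  expect_true(all(post[1:5] > 0))
  expect_gt(first_neg, 5)
  # an occasional spike produces no meaningful change: the mean weight
  # update a random presynaptic spike would sample over this window is
  # orders of magnitude below the trained-weight scale (~1 mV)
  drive <- pp$A_LTP * pmax(post, 0) - pp$A_LTD * pmax(-post, 0)
  expect_lt(abs(mean(drive)), 1e-3)
})

test_that("sustained firing turns potentiation into depression", {
  np <- neuron_params()
  dt <- 0.05
  vt <- 0; s <- 0; th <- 0
  period <- 500  # a spike every 25 ms: 40 spikes/s
  sgn <- numeric(0)
  for (k in 1:200000) {  # 10 s of sustained firing
    spike <- (k %% period == 0)
    V <- if (spike) 25 else 10
    f <- filter_step(vt, s, V, spike, np, pp, dt)
    vt <- f$v_tilde; s <- f$s_tilde
    th <- threshold_step(th, vt, s, pp, dt)
    sgn <- c(sgn, vt - th)
  }
  expect_gt(max(sgn[1:40000]), 0)          # early LTP
  expect_lt(mean(sgn[150000:200000]), 0)   # late LTD: theta above v_tilde
})
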