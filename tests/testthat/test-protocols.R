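test_that("training schedule: one presentation per period, uniform stimuli", {
  cl <- assign_clusters(800, 10, 0.1, seed = 4)
  sched <- training_schedule(cl, session_ms = 600000, period_ms = 2000,
                             stim_ms = 500, seed = 8)
  expect_equal(nrow(sched), 300L)        # 10 min / 2 s
  expect_true(all(sched$duration == 500))
  expect_equal(mean(table(sched$stimulus)), 30)  # ~30 presentations each
  expect_true(all(sort(unique(sched$stimulus)) %in% 1:10))
  # targets are exactly the cluster members
  k <- 17
  expect_equal(sched$targets[[k]], which(cl$eta[sched$stimulus[k], ] == 1))
  # default session length scales linearly with Q
  cl4 <- assign_clusters(800, 20, 0.05, seed = 4)
  expect_equal(attr(training_schedule(cl4, seed = 1), "session_ms"), 1200000)
  expect_error(training_schedule(cl, stim_ms = 2500), "stim_ms")
})

test_that("perturbation schedules implement the three scenarios", {
  set2 <- assign_clusters(800, 10, 0.1, seed = 21)
  # Poisson onsets: ~360 events per hour at 10 s mean interval
  n_ev <- vapply(1:6, function(s)
    nrow(perturbation_schedule("random", 800, 0.1, 3600000, seed = s)),
    numeric(1))
  expect_lt(abs(mean(n_ev) - 360), 3 * sqrt(360 / 6))
  sched <- perturbation_schedule("novel", 800, 0.1, 600000, set2 = set2,
                                 seed = 3)
  expect_true(all(sched$duration == 200))
  expect_true(all(sched$stimulus %in% 1:10))
  for (k in seq_len(nrow(sched)))
    expect_equal(sched$targets[[k]],
                 which(set2$eta[sched$stimulus[k], ] == 1))
  mixed <- perturbation_schedule("mixed", 800, 0.1, 1200000, set2 = set2,
                                 seed = 5)
  expect_true(any(is.na(mixed$stimulus)) && any(!is.na(mixed$stimulus)))
  expect_error(perturbation_schedule("novel", 800, 0.1, 1e5), "set2")
})

test_that("stimulus drive raises firing only in targets during the event", {
  cfg <- tiny_cfg(seed = 9)
  net <- build_network(cfg)
  targets <- 1:20
  sched <- tibble::tibble(
    onset = 200, duration = 300, stimulus = 1L, amplitude = 0.5,
    targets = list(targets))
  sched <- plastnet:::new_schedule(sched, 1000, "training")
  ses <- run_session(net, sched, plasticity = FALSE)
  during <- ses$spikes[ses$spikes$time > 200 & ses$spikes$time <= 500, ]
  before <- ses$spikes[ses$spikes$time <= 200, ]
  rate_t <- sum(during$neuron %in% targets) / length(targets) / 0.3
  rate_nt <- sum(!during$neuron %in% targets &
                   during$neuron <= 80) / (80 - length(targets)) / 0.3
  rate_pre <- sum(before$neuron %in% targets) / length(targets) / 0.2
  expect_gt(rate_t, 2 * rate_nt)   # drive is restricted to the targets
  expect_gt(rate_t, 2 * rate_pre)  # and to the presentation window
})

test_that("with plasticity off the synaptic matrix is untouched", {
  net <- build_network(tiny_cfg(seed = 10))
  ses <- run_session(net, empty_schedule(2000), plasticity = FALSE)
  expect_identical(ses$network$edges$w, net$edges$w)
})

test_that("sessions resume exactly and record weight-class series", {
  net <- build_network(tiny_cfg(seed = 12))
  s1 <- run_session(net, empty_schedule(500), class_interval_ms = 100)
  s2 <- run_session(s1$network, empty_schedule(500), resume = s1,
                    class_interval_ms = 100)
  expect_equal(s2$t0, 500)
  expect_equal(s2$t_end, 1000)
  # one continuous run gives the same final state as two chained halves
  s12 <- run_session(net, empty_schedule(1000), class_interval_ms = 100)
  expect_equal(s2$state$V, s12$state$V, tolerance = 1e-12)
  expect_equal(s2$network$edges$w, s12$network$edges$w)
  expect_equal(s12$class_series$time, seq(0, 1000, by = 100))
  expect_true(all(diff(s12$snapshots$time) > 0) || nrow(s12$snapshots) <= 1)
})

test_that("schedules beyond the session or with bad targets are rejected", {
  net <- build_network(tiny_cfg())
  sched <- plastnet:::new_schedule(
    tibble::tibble(onset = 900, duration = 300, stimulus = 1L,
                   amplitude = 0.5, targets = list(1:5)), 1000, "training")
  expect_error(run_session(net, sched), "beyond the session")
  bad <- plastnet:::new_schedule(
    tibble::tibble(onset = 0, duration = 100, stimulus = 1L,
                   amplitude = 0.5, targets = list(c(1L, 95L))),
    1000, "training")
  expect_error(run_session(net, bad), "excitatory")
})
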