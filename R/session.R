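#' Run a simulation session
#'
#' Integrates the full network for the duration of `schedule` (or
#' `duration_ms`), applying the stimulus drive `h_st` to each event's targets
#' during its presentation window and — when `plasticity` is on — updating
#' every plastic synapse at each presynaptic spike arrival. The integration
#' is forward Euler at step `dt` with exact exponential decay of the synaptic
#' and spike-trace filters; spikes detected at the end of a step are
#' delivered one step later. Given identical inputs and seeds, a session is
#' bit-reproducible.
#'
#' Initial membrane potentials are drawn uniformly from `[V_r, V_T)` (seeded
#' `init_v` substream) and the plasticity filters start from zero, unless
#' `resume` passes the final state of a previous session, in which case the
#' session continues exactly where that one ended.
#'
#' @param network A [build_network()] object (or the `network` of a previous
#'   session result).
#' @param schedule A `plastnet_schedule`; default no stimulation.
#' @param duration_ms Session length, ms; defaults to the schedule's
#'   `session_ms`.
#' @param plasticity Logical; apply the plasticity rule? With `FALSE` the
#'   synaptic matrix is returned bit-identical to the input.
#' @param dt Integration step, ms (default from the config).
#' @param resume A previous `plastnet_session` to continue from.
#' @param class_interval_ms Cadence of the per-class (`w0`, `w1`) weight
#'   averages, ms; 0 disables.
#' @param snapshot_times Absolute times (ms) at which to store full copies of
#'   the plastic weights.
#' @param record_spikes Keep the spike table (disable for long throwaway
#'   runs).
#'
#' @return A `plastnet_session`: list with `spikes` (tibble `time`, `neuron`,
#'   1-based, sorted by time), `network` (input network with updated
#'   weights), `class_series` (tibble `time`, `w0`, `w1`), `snapshots`
#'   (tibble `time`, list-column `w`), `state` (final membrane, filter and
#'   threshold values), and the timing metadata.
#' @export
#' @examples
#' cfg <- network_config(N = 60, N_E = 48, N_I = 12, Q = 2, seed = 1)
#' net <- build_network(cfg)
#' ses <- run_session(net, empty_schedule(200))
#' nrow(ses$spikes)
run_session <- function(network, schedule = NULL, duration_ms = NULL,
                        plasticity = TRUE, dt = network$cfg$dt,
                        resume = NULL, class_interval_ms = 1000,
                        snapshot_times = numeric(0), record_spikes = TRUE) {
  stopifnot(inherits(network, "plastnet_network"))
  cfg <- network$cfg
  if (is.null(schedule)) {
    if (is.null(duration_ms))
      stop("run_session: give a schedule or duration_ms", call. = FALSE)
    schedule <- empty_schedule(duration_ms)
  }
  if (is.null(duration_ms)) duration_ms <- attr(schedule, "session_ms")
  if (nrow(schedule) > 0 &&
      max(schedule$onset + schedule$duration) > duration_ms + 1e-9)
    stop("run_session: schedule extends beyond the session duration",
         call. = FALSE)
  bad <- vapply(schedule$targets,
                function(tg) length(tg) > 0 && max(tg) > cfg$N_E,
                logical(1))
  if (any(bad))
    stop("run_session: stimulus targets must be excitatory neurons",
         call. = FALSE)

  edges <- network$edges
  n <- cfg$N; n_e <- cfg$N_E
  h_ext <- c(rep(cfg$h_ext_E, n_e), rep(cfg$h_ext_I, n - n_e))

  if (is.null(resume)) {
    t0 <- 0
    V0 <- with_seed(substream_seed(cfg$seed, "init_v"),
                    runif(n, cfg$neuron$V_r, cfg$neuron$V_T))
    init_plast <- list()
  } else {
    stopifnot(inherits(resume, "plastnet_session"))
    t0 <- resume$t_end
    V0 <- resume$state$V
    init_plast <- resume$state[c("v_tilde", "s_tilde", "theta", "h_E",
                                 "h_I", "pending")]
  }

  n_ev <- nrow(schedule)
  tg_len <- vapply(schedule$targets, length, integer(1))
  ev_ptr <- c(0L, cumsum(tg_len))
  ev_targets <- if (n_ev) unlist(schedule$targets, use.names = FALSE) else
    integer(0)

  cls <- edges$class
  cls[is.na(cls)] <- -1L

  out <- simulate_network_cpp(
    edge_pre = edges$pre - 1L, edge_post = edges$post - 1L,
    edge_w = edges$w, edge_class = cls, n = n, n_e = n_e,
    neuron = unclass(cfg$neuron), plast = unclass(cfg$plasticity),
    plasticity_on = plasticity, V0 = V0, h_ext = h_ext,
    t0 = t0, duration = duration_ms, dt = dt,
    ev_onset = t0 + schedule$onset,
    ev_offset = t0 + schedule$onset + schedule$duration,
    ev_amp = schedule$amplitude,
    ev_ptr = ev_ptr, ev_targets = as.integer(ev_targets) - 1L,
    class_interval = class_interval_ms,
    snapshot_times = sort(snapshot_times), init_plast = init_plast,
    record_spikes = record_spikes)

  if (any(!is.finite(out$w)))
    stop("run_session: non-finite synaptic weight after integration",
         call. = FALSE)

  network$edges$w <- out$w
  structure(list(
    spikes = tibble::tibble(time = out$spike_t, neuron = out$spike_id + 1L),
    network = network,
    class_series = tibble::tibble(time = out$class_t, w0 = out$class_w0,
                                  w1 = out$class_w1),
    snapshots = tibble::tibble(time = out$snapshot_t,
                               w = lapply(out$snapshots, identity)),
    state = list(V = out$V, h_E = out$h_E, h_I = out$h_I,
                 v_tilde = out$v_tilde, s_tilde = out$s_tilde,
                 theta = out$theta, pending = out$pending),
    t0 = t0, t_end = out$t_end, dt = dt, plasticity_on = plasticity,
    scenario = attr(schedule, "scenario")),
    class = "plastnet_session")
}

#' @export
print.plastnet_session <- function(x, ...) {
  cat("<plastnet_session> [", x$t0, ",", x$t_end, "] ms, dt =", x$dt,
      "ms, plasticity", if (x$plasticity_on) "ON" else "OFF", "\n")
  cat("  spikes:", nrow(x$spikes), " scenario:", x$scenario, "\n")
  invisible(x)
}
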