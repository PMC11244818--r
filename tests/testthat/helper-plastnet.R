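# Small fixtures shared across the suite; everything is generated in code.

tiny_cfg <- function(seed = 42L, ...) {
  network_config(N = 100, N_E = 80, N_I = 20, Q = 4, f = 0.1, seed = seed,
                 ...)
}

# Single-neuron "network" for membrane-level checks.
one_neuron_cfg <- function(h_ext_E = 0, seed = 1L) {
  network_config(N = 1, N_E = 1, N_I = 0, Q = 1, f = 1, h_ext_E = h_ext_E,
                 seed = seed)
}

# Direct engine call for a network with no synapses and a prescribed V0.
run_engine_plain <- function(V0, n_e = length(V0), h_ext = 0, duration = 1,
                             dt = 0.05, neuron = neuron_params(),
                             plasticity = plasticity_params()) {
  n <- length(V0)
  plastnet:::simulate_network_cpp(
    edge_pre = integer(0), edge_post = integer(0), edge_w = numeric(0),
    edge_class = integer(0), n = n, n_e = n_e, neuron = unclass(neuron),
    plast = unclass(plasticity), plasticity_on = TRUE, V0 = V0,
    h_ext = rep_len(h_ext, n), t0 = 0, duration = duration, dt = dt,
    ev_onset = numeric(0), ev_offset = numeric(0), ev_amp = numeric(0),
    ev_ptr = 0L, ev_targets = integer(0), class_interval = 0,
    snapshot_times = numeric(0), init_plast = list())
}

# Fine-dt Euler integration of the normalised threshold ODE
# tau * theta' = tanh(delta - theta); returns time to reach delta/2.
ode_t_half <- function(delta, tau = 1, dt = 1e-4) {
  theta <- 0; t <- 0
  target <- delta / 2
  while (theta < target) {
    theta <- theta + dt / tau * tanh(delta - theta)
    t <- t + dt
    if (t > 100 * tau) stop("ode_t_half: no crossing")
  }
  t
}
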