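#' One step of the postsynaptic plasticity filters
#'
#' Advances the two low-pass filters feeding the plasticity rule by one Euler
#' step of length `dt`: the voltage trace \eqn{\tilde v} relaxes toward the
#' exponential voltage term \eqn{\Delta_T e^{(V - V_T)/\Delta_T}} (with `V`
#' clipped at `V_peak`) with time constant `tau_v`, and the spike trace
#' \eqn{\tilde s} decays with `tau_s` and jumps by `1/tau_s` at each
#' postsynaptic spike (delta-train integration).
#'
#' These vectorised reference kernels mirror, step for step, what the compiled
#' network engine does for its excitatory neurons; they are exported so single
#' synapses can be studied (and the engine cross-checked) without running a
#' network.
#'
#' @param v_tilde,s_tilde Current filter values (mV and 1/ms).
#' @param V Membrane potential(s), mV.
#' @param spiked Logical; TRUE where the neuron spiked in this step.
#' @param neuron A [neuron_params()].
#' @param plasticity A [plasticity_params()].
#' @param dt Step, ms.
#'
#' @return A list with updated `v_tilde` and `s_tilde`.
#' @export
#' @examples
#' filter_step(0, 0, V = 25, spiked = TRUE, neuron_params(),
#'             plasticity_params(), dt = 0.05)
filter_step <- function(v_tilde, s_tilde, V, spiked, neuron, plasticity, dt) {
  stopifnot(dt > 0)
  u <- exp_voltage_term(V, neuron)
  v_tilde <- v_tilde + dt / plasticity$tau_v * (-v_tilde + u)
  s_tilde <- s_tilde * exp(-dt / plasticity$tau_s) +
    ifelse(spiked, 1 / plasticity$tau_s, 0)
  list(v_tilde = v_tilde, s_tilde = s_tilde)
}

# Exponential spike-initiation term with overflow guard (V clipped at V_peak,
# bounding the term at Delta_T * exp((V_peak - V_T)/Delta_T)).
exp_voltage_term <- function(V, neuron) {
  Vc <- pmin(V, neuron$V_peak)
  neuron$Delta_T * exp((Vc - neuron$V_T) / neuron$Delta_T)
}

#' One step of the adaptive plasticity threshold
#'
#' Euler step of
#' \eqn{\tau_\theta\dot\theta =
#'   \theta_a\tanh[g(-\theta + \tilde v + \gamma\tilde s)]}.
#' The fixed point is \eqn{\theta = \tilde v + \gamma\tilde s}: for a silent
#' neuron \eqn{\theta} tracks \eqn{\tilde v} and no net plasticity ensues,
#' while sustained firing pushes the fixed point above \eqn{\tilde v}
#' (through \eqn{\gamma\tilde s}), turning potentiation into depression.
#'
#' @inheritParams filter_step
#' @param theta Current threshold(s), mV.
#' @return Updated `theta`.
#' @export
threshold_step <- function(theta, v_tilde, s_tilde, plasticity, dt) {
  stopifnot(dt > 0)
  theta + dt / plasticity$tau_theta * plasticity$theta_a *
    tanh(plasticity$g * (-theta + v_tilde + plasticity$gamma * s_tilde))
}

#' Threshold half-rise time
#'
#' For the normalised threshold equation \eqn{\tau_\theta\dot\theta =
#' \tanh(-\theta + \Delta)} with \eqn{\theta(0) = 0}, the time for
#' \eqn{\theta} to reach \eqn{\Delta/2} has the closed form
#' \deqn{T_{1/2}(\Delta) =
#'   \tau_\theta\,\ln\frac{\sinh\Delta}{\sinh(\Delta/2)},}
#' which tends to \eqn{\tau_\theta\ln 2} for \eqn{\Delta \ll 1} and grows
#' linearly, \eqn{\approx \tau_\theta\Delta/2}, for \eqn{\Delta > 3}. This is
#' the sense in which the tanh threshold adapts its own time scale: small
#' excursions of the drive are tracked quickly, large ones (spikes, sustained
#' firing) slowly, opening the transient LTP window.
#'
#' @param delta Drive step \eqn{\Delta > 0} (mV, in units of the threshold
#'   amplitude).
#' @param tau_theta Threshold time constant, ms.
#' @return Half-rise time in ms (vectorised over `delta`).
#' @export
#' @examples
#' t_half(0.001, 500) / 500 # ~ log(2)
#' t_half(5, 500) / 500     # ~ 2.5
t_half <- function(delta, tau_theta = 500) {
  if (any(delta <= 0)) stop("t_half: delta must be > 0", call. = FALSE)
  # log(sinh(d)) computed stably for large d: d + log1p(-exp(-2d)) - log 2
  lsinh <- function(d) d + log1p(-exp(-2 * d)) - log(2)
  tau_theta * (lsinh(delta) - lsinh(delta / 2))
}

#' Weight change triggered by one presynaptic spike
#'
#' Applies the plasticity rule of a single presynaptic spike to an E-to-E
#' synapse:
#' \deqn{\Delta w = A_{LTP} e^{-\beta w^2} [\tilde v - \theta]_+
#'   - A_{LTD} [\theta - \tilde v]_+,}
#' after which the weight is clamped at zero from below. Exactly one of the
#' two terms is nonzero. The rule is fully local: it reads only the weight
#' itself and the postsynaptic filter state.
#'
#' @param w Current weight(s), mV (>= 0).
#' @param v_tilde_post Postsynaptic voltage trace, mV.
#' @param theta_post Postsynaptic adaptive threshold, mV.
#' @param plasticity A [plasticity_params()].
#' @return Updated weight(s), never negative. Vectorised over all arguments.
#' @export
#' @examples
#' apply_presynaptic_spike(0, v_tilde_post = 1.5, theta_post = 0.5,
#'                         plasticity_params())
apply_presynaptic_spike <- function(w, v_tilde_post, theta_post, plasticity) {
  if (any(w < 0)) stop("apply_presynaptic_spike: w must be >= 0",
                       call. = FALSE)
  d <- v_tilde_post - theta_post
  dw <- ifelse(d > 0,
               plasticity$A_LTP * exp(-plasticity$beta * w^2) * d,
               plasticity$A_LTD * d)
  pmax(w + dw, 0)
}
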