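#' One forward-Euler step of the EIF membrane equation
#'
#' Advances the membrane potentials by one explicit step of the exponential
#' integrate-and-fire equation. The exponential spike-initiation term is
#' evaluated with `V` clipped at `V_peak` (overflow guard, bounding it at
#' \eqn{\Delta_T e^{(V_{peak}-V_T)/\Delta_T}}); neurons whose updated
#' potential reaches `V_peak` are flagged as spiking — the spike time is the
#' end of the step — and reset to `V_r`.
#'
#' This is the vectorised reference kernel for the per-step arithmetic of
#' the compiled network engine; the two are interchangeable for a single
#' step.
#'
#' @param V Membrane potential(s), mV; must be `< V_peak` on entry.
#' @param drive Total input current `h_E + h_I + h_st + h_ext`, mV/ms
#'   (recycled).
#' @param neuron A [neuron_params()].
#' @param dt Step, ms.
#' @param excitatory Logical (recycled): selects `tau_m_E` or `tau_m_I`.
#' @return A list with updated `V` and logical `spiked`.
#' @export
#' @examples
#' membrane_step(V = 25, drive = 0, neuron_params(), dt = 0.05)
membrane_step <- function(V, drive, neuron, dt, excitatory = TRUE) {
  stopifnot(dt > 0)
  tau_m <- ifelse(excitatory, neuron$tau_m_E, neuron$tau_m_I)
  Vn <- V + dt * ((-(V - neuron$V_L) + exp_voltage_term(V, neuron)) / tau_m +
                    drive)
  if (any(!is.finite(Vn))) {
    bad <- which(!is.finite(Vn))[1]
    stop("membrane_step: non-finite potential for neuron ", bad,
         " (dt = ", dt, " ms)", call. = FALSE)
  }
  spiked <- Vn >= neuron$V_peak
  Vn[spiked] <- neuron$V_r
  list(V = Vn, spiked = spiked)
}

#' One step of the exponential synaptic filter
#'
#' The recurrent synaptic input obeys
#' \eqn{\tau_{syn}\dot h = -h + \sum_j w_j \sum_k \delta(t - t_j^{(k)})}:
#' between spikes `h` decays exponentially, and each arriving spike of
#' weight `w` adds a jump `w / tau_syn` (additive across simultaneous
#' arrivals, as integrating the delta forces).
#'
#' @param h Current filtered input, mV/ms.
#' @param tau_syn Synaptic time constant, ms.
#' @param arriving_weight_sum Summed weight of spikes arriving in this step,
#'   mV.
#' @param dt Step, ms.
#' @return Updated filtered input, mV/ms.
#' @export
#' @examples
#' synaptic_filter_step(1, tau_syn = 3, arriving_weight_sum = 0, dt = 3)
synaptic_filter_step <- function(h, tau_syn, arriving_weight_sum = 0, dt) {
  stopifnot(tau_syn > 0, dt > 0)
  h * exp(-dt / tau_syn) + arriving_weight_sum / tau_syn
}
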