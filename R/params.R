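#' Single-neuron parameters of the exponential integrate-and-fire model
#'
#' The membrane potential of each neuron follows
#' \deqn{\dot V = \frac{-(V - V_L) + \Delta_T e^{(V - V_T)/\Delta_T}}{\tau_m}
#'   + h^{E,syn} + h^{I,syn} + h^{st} + h^{ext},}
#' with a spike emitted when \eqn{V \ge V_{peak}}, after which \eqn{V} is reset
#' to \eqn{V_r}. Defaults are the reference parameter set used throughout the
#' package.
#'
#' @param V_L Leak (resting) potential, mV.
#' @param V_T Soft spiking threshold, mV.
#' @param Delta_T Spike-initiation sharpness, mV.
#' @param V_peak Spike cut-off potential, mV; must exceed `V_T`.
#' @param V_r Reset potential, mV.
#' @param tau_m_E,tau_m_I Membrane time constants of excitatory and inhibitory
#'   neurons, ms.
#' @param tau_syn_E,tau_syn_I Synaptic filter time constants of excitatory and
#'   inhibitory inputs, ms.
#'
#' @return A validated list of class `plastnet_neuron_params`.
#' @export
#' @examples
#' neuron_params()
neuron_params <- function(V_L = 0, V_T = 20, Delta_T = 1, V_peak = 25,
                          V_r = 0, tau_m_E = 15, tau_m_I = 10,
                          tau_syn_E = 3, tau_syn_I = 2) {
  p <- list(V_L = V_L, V_T = V_T, Delta_T = Delta_T, V_peak = V_peak,
            V_r = V_r, tau_m_E = tau_m_E, tau_m_I = tau_m_I,
            tau_syn_E = tau_syn_E, tau_syn_I = tau_syn_I)
  stopifnot(vapply(p, is.numeric, logical(1)),
            vapply(p, length, integer(1)) == 1L)
  if (!(V_r <= V_L && V_L < V_T && V_T < V_peak))
    stop("neuron_params: need V_r <= V_L < V_T < V_peak", call. = FALSE)
  if (Delta_T <= 0 || tau_m_E <= 0 || tau_m_I <= 0 ||
      tau_syn_E <= 0 || tau_syn_I <= 0)
    stop("neuron_params: Delta_T and all time constants must be > 0",
         call. = FALSE)
  structure(p, class = "plastnet_neuron_params")
}

#' Parameters of the local voltage-based plasticity rule
#'
#' An E-to-E synapse \eqn{w_{ij}} changes only when a presynaptic spike
#' arrives:
#' \deqn{\Delta w_{ij} = A_{LTP} e^{-\beta w_{ij}^2}[\tilde v_i - \theta_i]_+
#'   - A_{LTD}[\theta_i - \tilde v_i]_+,}
#' where \eqn{\tilde v_i} is the low-pass filtered exponential voltage term of
#' the postsynaptic neuron and \eqn{\theta_i} an adaptive threshold obeying
#' \deqn{\tau_\theta\dot\theta_i =
#'   \theta_a \tanh[g(-\theta_i + \tilde v_i + \gamma\tilde s_i)],}
#' with \eqn{\tilde s_i} the low-pass filtered postsynaptic spike train.
#' Weights are clamped at zero from below (Dale's law).
#'
#' @param A_LTP,A_LTD Potentiation / depression strengths (dimensionless).
#' @param beta LTP attenuation factor, mV^-2; suppresses growth of already
#'   strong synapses via \eqn{e^{-\beta w^2}}.
#' @param tau_v Filter time constant of the voltage trace \eqn{\tilde v}, ms.
#' @param tau_s Filter time constant of the spike trace \eqn{\tilde s}, ms.
#' @param tau_theta Threshold time constant, ms.
#' @param theta_a Threshold amplitude, mV.
#' @param g Threshold gain, mV^-1.
#' @param gamma Spiking contribution to the threshold, mV ms.
#'
#' @return A validated list of class `plastnet_plasticity_params`.
#' @export
#' @examples
#' plasticity_params()
plasticity_params <- function(A_LTP = 0.005, A_LTD = 0.015, beta = 0.1,
                              tau_v = 50, tau_s = 1000, tau_theta = 500,
                              theta_a = 1, g = 5, gamma = 50) {
  p <- list(A_LTP = A_LTP, A_LTD = A_LTD, beta = beta, tau_v = tau_v,
            tau_s = tau_s, tau_theta = tau_theta, theta_a = theta_a,
            g = g, gamma = gamma)
  stopifnot(vapply(p, is.numeric, logical(1)),
            vapply(p, length, integer(1)) == 1L)
  if (tau_v <= 0 || tau_s <= 0 || tau_theta <= 0)
    stop("plasticity_params: time constants must be > 0", call. = FALSE)
  if (A_LTP < 0 || A_LTD < 0 || beta < 0 || g < 0 || gamma < 0)
    stop("plasticity_params: A_LTP, A_LTD, beta, g, gamma must be >= 0",
         call. = FALSE)
  structure(p, class = "plastnet_plasticity_params")
}

#' Network configuration
#'
#' Bundles the population sizes, connectivity statistics, initial efficacies,
#' external drives and stimulus statistics of a clustered E/I network,
#' together with the neuron and plasticity parameter sets, the integration
#' step and the master seed. Defaults give the "basic" network: 800
#' excitatory and 200 inhibitory neurons, Q = 10 stimuli at coding level
#' f = 0.1.
#'
#' @param N Total number of neurons.
#' @param N_E,N_I Population sizes; default 4:1 excitatory to inhibitory.
#' @param Q Number of training stimuli.
#' @param f Coding level: probability that an excitatory neuron is targeted by
#'   a given stimulus.
#' @param p_EE,p_EI,p_IE,p_II Connection probabilities by population pair
#'   (first index = postsynaptic type).
#' @param w_EE,w_EI,w_IE,w_II Initial synaptic efficacies, mV. Excitatory rows
#'   must be nonnegative, inhibitory rows nonpositive.
#' @param h_ext_E,h_ext_I Constant external drives, mV/ms.
#' @param h_st Stimulus drive added to targeted neurons during presentations,
#'   mV/ms.
#' @param dt Integration step, ms.
#' @param seed Master seed; all random substreams (connectivity, cluster
#'   membership, initial voltages, schedules) are derived from it.
#' @param neuron A [neuron_params()] object.
#' @param plasticity A [plasticity_params()] object.
#'
#' @return A validated list of class `plastnet_config`.
#' @export
#' @examples
#' cfg <- network_config(seed = 1)
#' cfg$Q
network_config <- function(N = 1000, N_E = round(0.8 * N), N_I = N - N_E,
                           Q = 10, f = 0.1, p_EE = 0.2, p_EI = 0.5,
                           p_IE = 0.5, p_II = 0.5, w_EE = 0.005,
                           w_EI = -0.34, w_IE = 0.54, w_II = -0.46,
                           h_ext_E = 1.5, h_ext_I = 2.19, h_st = 0.5,
                           dt = 0.05, seed = 1L,
                           neuron = neuron_params(),
                           plasticity = plasticity_params()) {
  cfg <- list(N = N, N_E = N_E, N_I = N_I, Q = Q, f = f, p_EE = p_EE,
              p_EI = p_EI, p_IE = p_IE, p_II = p_II, w_EE = w_EE,
              w_EI = w_EI, w_IE = w_IE, w_II = w_II, h_ext_E = h_ext_E,
              h_ext_I = h_ext_I, h_st = h_st, dt = dt, seed = as.integer(seed),
              neuron = neuron, plasticity = plasticity)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  with(cfg, {
    if (N_E + N_I != N)
      stop("network_config: N_E + N_I must equal N", call. = FALSE)
    probs <- c(p_EE = p_EE, p_EI = p_EI, p_IE = p_IE, p_II = p_II)
    bad <- names(probs)[probs < 0 | probs > 1]
    if (length(bad))
      stop("network_config: probabilities outside [0, 1]: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (f <= 0 || f > 1)
      stop("network_config: coding level f must be in (0, 1]", call. = FALSE)
    if (Q < 1) stop("network_config: Q must be >= 1", call. = FALSE)
    if (w_EE < 0 || w_IE < 0)
      stop("network_config: excitatory efficacies must be >= 0",
           call. = FALSE)
    if (w_EI > 0 || w_II > 0)
      stop("network_config: inhibitory efficacies must be <= 0",
           call. = FALSE)
    if (dt <= 0) stop("network_config: dt must be > 0", call. = FALSE)
  })
  if (!inherits(cfg$neuron, "plastnet_neuron_params"))
    cfg$neuron <- do.call(neuron_params, cfg$neuron)
  if (!inherits(cfg$plasticity, "plastnet_plasticity_params"))
    cfg$plasticity <- do.call(plasticity_params, cfg$plasticity)
  structure(cfg, class = "plastnet_config")
}

#' Scale the clustered network to a different size
#'
#' Two scaling regimes are supported. In the `"linear"` regime the number of
#' clusters grows in proportion to the network, `Q = N/100` with coding level
#' `f = 1/Q`, so the mean cluster size stays fixed at `f * N_E = 80` neurons.
#' In the `"sqrt"` regime `Q = round(sqrt(N/10))` and `f = 1/Q`, so both the
#' number and the size of clusters grow. Both regimes coincide with the basic
#' network (`Q = 10`, `f = 0.1`) at `N = 1000`.
#'
#' @param N Total number of neurons (>= 1000).
#' @param regime `"linear"` or `"sqrt"`.
#'
#' @return A tibble with one row: `N`, `N_E`, `N_I`, `Q`, `f`,
#'   `mean_cluster_size`.
#' @export
#' @examples
#' scale_network(5000, "linear")
#' scale_network(5000, "sqrt")
scale_network <- function(N, regime = c("linear", "sqrt")) {
  regime <- match.arg(regime)
  if (N < 1000) stop("scale_network: N must be >= 1000", call. = FALSE)
  N_E <- round(0.8 * N)
  Q <- switch(regime,
              linear = round(N / 100),
              sqrt = round(sqrt(N / 10)))
  f <- 1 / Q
  tibble::tibble(N = N, N_E = N_E, N_I = N - N_E, Q = Q, f = f,
                 mean_cluster_size = f * N_E, regime = regime)
}

# Named seed substreams derived from one master seed, so one component
# (connectivity, clusters, schedule, ...) can be varied holding others fixed.
.substreams <- c(connectivity = 1L, clusters = 2L, init_v = 3L,
                 schedule = 4L, perturbation = 5L, extra = 6L)

#' Derive a named seed substream from a master seed
#'
#' Connectivity, cluster membership, initial voltages and schedules each use
#' their own substream of the master seed, so one component can be re-drawn
#' while the others are held fixed (e.g. the same network under a different
#' training order).
#'
#' @param seed Master seed (integer).
#' @param stream One of `"connectivity"`, `"clusters"`, `"init_v"`,
#'   `"schedule"`, `"perturbation"`, `"extra"`.
#' @return An integer seed.
#' @export
#' @examples
#' substream_seed(1, "schedule")
substream_seed <- function(seed, stream) {
  off <- .substreams[[stream]]
  as.integer((as.double(seed) * 48271 + 7919 * off) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
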