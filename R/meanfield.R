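#' Configuration of the simplified clustered network for mean-field analysis
#'
#' The mean-field description uses a reduced network: `N_E` excitatory
#' neurons uniformly partitioned into `Q` non-overlapping clusters of size
#' `N_E/Q`, plus `N_I` inhibitory neurons, with the same quenched random
#' connectivity as the simulations. Synapses within a cluster ("w+") are
#' independent samples from a distribution with mean `mu_plus`, standard
#' deviation `sigma_plus` and support in `[0, w_max]`; synapses between
#' clusters are fixed at the small constant `w_minus`. For a given mean the
#' spread is bounded by \eqn{\sigma_{max}(\mu) = \sqrt{w_{max}\mu - \mu^2}}
#' (attained by the two-point distribution on \{0, w_max\}); pairs above
#' that curve are not realisable.
#'
#' @param N_E,N_I,Q Population sizes and number of clusters.
#' @param mu_plus,sigma_plus Mean and sd of intra-cluster weights, mV.
#' @param w_minus Inter-cluster E-to-E efficacy, mV (defaults to the
#'   pre-training `w_EE`).
#' @param w_max Upper support bound of the intra-cluster weights, mV.
#' @param p_EE,p_EI,p_IE,p_II Connection probabilities.
#' @param w_EI,w_IE,w_II Fixed efficacies of the other population pairs, mV.
#' @param h_ext_E,h_ext_I External drives, mV/ms.
#' @param neuron A [neuron_params()].
#'
#' @return A validated list of class `plastnet_mf_config`.
#' @export
#' @examples
#' meanfield_config(mu_plus = 1, sigma_plus = 0.5)
meanfield_config <- function(N_E = 4000, N_I = 1000, Q = 50, mu_plus = 0.005,
                             sigma_plus = 0, w_minus = 0.005, w_max = 4,
                             p_EE = 0.2, p_EI = 0.5, p_IE = 0.5, p_II = 0.5,
                             w_EI = -0.34, w_IE = 0.54, w_II = -0.46,
                             h_ext_E = 1.5, h_ext_I = 2.19,
                             neuron = neuron_params()) {
  if (mu_plus < 0 || mu_plus > w_max)
    stop("meanfield_config: need 0 <= mu_plus <= w_max", call. = FALSE)
  if (sigma_plus < 0 ||
      sigma_plus > sigma_max(mu_plus, w_max) + 1e-12)
    stop("meanfield_config: sigma_plus exceeds sigma_max(mu_plus)",
         call. = FALSE)
  structure(list(N_E = N_E, N_I = N_I, Q = Q, mu_plus = mu_plus,
                 sigma_plus = sigma_plus, w_minus = w_minus, w_max = w_max,
                 p_EE = p_EE, p_EI = p_EI, p_IE = p_IE, p_II = p_II,
                 w_EI = w_EI, w_IE = w_IE, w_II = w_II,
                 h_ext_E = h_ext_E, h_ext_I = h_ext_I, neuron = neuron),
            class = "plastnet_mf_config")
}

#' Accessibility bound on the intra-cluster weight spread
#'
#' \eqn{\sigma_{max}(\mu) = \sqrt{w_{max}\mu - \mu^2}}: the largest standard
#' deviation a distribution with mean \eqn{\mu} and support `[0, w_max]` can
#' have, saturated by the two-point distribution
#' \eqn{P(w_{max}) = \mu/w_{max}}, \eqn{P(0) = 1 - \mu/w_{max}}.
#'
#' @param mu Mean weight(s), mV, in `[0, w_max]`.
#' @param w_max Support bound, mV.
#' @return Standard-deviation bound(s), mV.
#' @export
#' @examples
#' sigma_max(2, 4) # = 2
sigma_max <- function(mu, w_max = 4) {
  if (any(mu < 0 | mu > w_max))
    stop("sigma_max: mu must lie in [0, w_max]", call. = FALSE)
  sqrt(w_max * mu - mu^2)
}

#' Solver settings for the Fokker-Planck transfer function and the
#' self-consistency iteration
#'
#' @param V_lb Lower bound of the voltage grid, mV (well below reset).
#' @param dV Voltage grid step, mV.
#' @param damping Relaxation factor of the fixed-point iteration in (0, 1].
#' @param tol Rate convergence tolerance, spikes/s.
#' @param max_iter Iteration cap.
#' @param rate_cap Ceiling on iterated rates, spikes/s. The EIF model here
#'   has no refractory period, so at strong self-excitation the only fixed
#'   point can run away; iterations pinned at the cap mark that regime.
#' @return A list of class `plastnet_solver_settings`.
#' @export
solver_settings <- function(V_lb = -30, dV = 0.01, damping = 0.1,
                            tol = 1e-6, max_iter = 10000, rate_cap = 1e4) {
  stopifnot(dV > 0, damping > 0, damping <= 1, tol > 0, max_iter >= 1,
            rate_cap > 0)
  structure(list(V_lb = V_lb, dV = dV, damping = damping, tol = tol,
                 max_iter = max_iter, rate_cap = rate_cap),
            class = "plastnet_solver_settings")
}

#' EIF transfer function from the stationary Fokker-Planck equation
#'
#' Stationary firing rate of an exponential integrate-and-fire neuron driven
#' by white noise with infinitesimal mean `mu` (mV/ms) and variance `s`
#' (mV^2/ms), computed by backward threshold integration of the stationary
#' flux equations from `V_peak` down to `V_lb` with reinjection at `V_r`;
#' the rate is the inverse of the probability normalisation.
#'
#' @param mu,s Input moments (vectorised; recycled to a common length).
#' @param neuron A [neuron_params()].
#' @param tau_m Membrane time constant to use, ms (excitatory by default).
#' @param settings A [solver_settings()] (grid bounds and step).
#' @return Firing rate(s), spikes/s.
#' @export
#' @examples
#' eif_rate_fp(1.5, 1)
eif_rate_fp <- function(mu, s, neuron = neuron_params(),
                        tau_m = neuron$tau_m_E,
                        settings = solver_settings()) {
  k <- max(length(mu), length(s))
  mu <- rep_len(mu, k); s <- rep_len(s, k)
  if (any(s <= 0)) stop("eif_rate_fp: s must be > 0", call. = FALSE)
  eif_fp_rate_cpp(mu, s, neuron$V_L, neuron$V_T, neuron$Delta_T,
                  neuron$V_peak, neuron$V_r, tau_m,
                  settings$V_lb, settings$dV)
}

#' Monte-Carlo estimate of the EIF stationary rate
#'
#' Euler-Maruyama integration of the white-noise-driven EIF neuron:
#' `n_rep` independent neurons, each simulated for `burn_ms + T_ms`, spikes
#' counted after the burn-in. This is the independent cross-check of
#' [eif_rate_fp()].
#'
#' @inheritParams eif_rate_fp
#' @param T_ms Counting time per repetition, ms.
#' @param dt Integration step, ms.
#' @param n_rep Independent repetitions averaged.
#' @param burn_ms Discarded transient, ms.
#' @param seed Optional seed.
#' @return Firing rate, spikes/s.
#' @export
eif_rate_mc <- function(mu, s, neuron = neuron_params(),
                        tau_m = neuron$tau_m_E, T_ms = 100000, dt = 0.01,
                        n_rep = 1, burn_ms = 1000, seed = NULL) {
  run <- function() eif_mc_rate_cpp(mu, s, neuron$V_L, neuron$V_T,
                                    neuron$Delta_T, neuron$V_peak,
                                    neuron$V_r, tau_m, T_ms, dt, n_rep,
                                    burn_ms)
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Input moments of every population from the rate vector
#'
#' Under the diffusion approximation the synaptic input to a neuron of
#' cluster `k` has infinitesimal mean and variance
#' \deqn{\mu_E^{(k)} = \tfrac{N_E}{Q} p_{EE} E[w_+]\,\nu_E^{(k)}
#'  + \tfrac{N_E}{Q} p_{EE} E[w_-] \sum_{j \ne k} \nu_E^{(j)}
#'  + N_I p_{EI} w_{EI}\, \nu_I + h^{ext}_E,}
#' \deqn{s_E^{(k)} = \tfrac{N_E}{Q} p_{EE} E[w_+^2]\,\nu_E^{(k)}
#'  + \tfrac{N_E}{Q} p_{EE} E[w_-^2] \sum_{j \ne k} \nu_E^{(j)}
#'  + N_I p_{EI} w_{EI}^2\, \nu_I,}
#' and analogously for the inhibitory population with `w_IE`, `w_II` and
#' `h_ext_I`. `E[w+] = mu_plus`, `E[w+^2] = mu_plus^2 + sigma_plus^2`.
#' Synapses are treated as instantaneous (delta) for these moments.
#'
#' @param nu Rate vector `c(nu_E_1, ..., nu_E_Q, nu_I)` in spikes/s.
#' @param cfg A [meanfield_config()].
#' @return Tibble with one row per population (`cluster_1..Q`, `I`): the
#'   moments `mu` (mV/ms) and `s` (mV^2/ms), and the four separate
#'   contributions `own`, `other`, `inhibition`, `external` to `mu`.
#' @export
population_inputs <- function(nu, cfg) {
  stopifnot(inherits(cfg, "plastnet_mf_config"))
  Q <- cfg$Q
  if (length(nu) != Q + 1)
    stop("population_inputs: nu must have length Q + 1", call. = FALSE)
  if (any(nu < 0))
    stop("population_inputs: rates must be nonnegative", call. = FALSE)
  nE <- nu[seq_len(Q)] / 1000  # spikes/ms
  nI <- nu[Q + 1] / 1000
  KE <- cfg$N_E / Q * cfg$p_EE
  Ew1 <- cfg$mu_plus; Ew2 <- cfg$mu_plus^2 + cfg$sigma_plus^2
  wm1 <- cfg$w_minus; wm2 <- cfg$w_minus^2
  other_sum <- sum(nE) - nE
  mu_own <- KE * Ew1 * nE
  mu_other <- KE * wm1 * other_sum
  mu_inh <- cfg$N_I * cfg$p_EI * cfg$w_EI * nI
  s_E <- KE * Ew2 * nE + KE * wm2 * other_sum +
    cfg$N_I * cfg$p_EI * cfg$w_EI^2 * nI
  KI <- cfg$N_E / Q * cfg$p_IE
  mu_I_own <- KI * cfg$w_IE * sum(nE)
  mu_I_inh <- cfg$N_I * cfg$p_II * cfg$w_II * nI
  s_I <- KI * cfg$w_IE^2 * sum(nE) + cfg$N_I * cfg$p_II * cfg$w_II^2 * nI
  tibble::tibble(
    population = c(paste0("cluster_", seq_len(Q)), "I"),
    mu = c(mu_own + mu_other + mu_inh + cfg$h_ext_E,
           mu_I_own + mu_I_inh + cfg$h_ext_I),
    s = c(s_E, s_I),
    own = c(mu_own, mu_I_own),
    other = c(mu_other, 0),
    inhibition = c(rep(mu_inh, Q), mu_I_inh),
    external = c(rep(cfg$h_ext_E, Q), cfg$h_ext_I))
}

# Reduced moment computation for the two ansatzes; nu in spikes/s.
# uniform: nu = (nu_E, nu_I); one_active: nu = (nu_a, nu_in, nu_I).
mf_moments <- function(nu, cfg, ansatz) {
  full <- if (ansatz == "uniform") c(rep(nu[1], cfg$Q), nu[2]) else
    c(nu[1], rep(nu[2], cfg$Q - 1), nu[3])
  pi <- population_inputs(full, cfg)
  if (ansatz == "uniform") pi[c(1, cfg$Q + 1), ] else
    pi[c(1, min(2, cfg$Q + 1), cfg$Q + 1), ]
}

#' Self-consistent population rates of the clustered network
#'
#' Solves \eqn{\nu_\alpha = F_\alpha(\mu_\alpha(\nu), s_\alpha(\nu))} by a
#' damped fixed-point iteration
#' \eqn{\nu \leftarrow (1 - d)\nu + d\,F(\mu(\nu), s(\nu))}. Two ansatzes:
#' `"uniform"` treats all clusters as identical (two unknown rates), while
#' `"one_active"` allows a single active cluster against `Q - 1` identical
#' inactive ones (three unknowns) — the configuration relevant for
#' metastability, where at most one memory is reactivated at a time.
#'
#' @param cfg A [meanfield_config()].
#' @param settings A [solver_settings()].
#' @param ansatz `"uniform"` or `"one_active"`.
#' @param init Initial rates, spikes/s (length 2 or 3 to match the ansatz).
#' @return A `plastnet_rate_solution`: list with the converged rates `nu`
#'   (named, spikes/s), input moments, `converged`, `residual` (spikes/s)
#'   and `iterations`.
#' @export
#' @examples
#' sol <- solve_rates(meanfield_config(), ansatz = "uniform")
#' sol$nu
solve_rates <- function(cfg, settings = solver_settings(),
                        ansatz = c("uniform", "one_active"), init = NULL) {
  ansatz <- match.arg(ansatz)
  k <- if (ansatz == "uniform") 2L else 3L
  nu <- if (is.null(init)) rep(2, k) else rep_len(init, k)
  neuron <- cfg$neuron
  tau <- c(rep(neuron$tau_m_E, k - 1), neuron$tau_m_I)
  res <- Inf; it <- 0L
  F_nu <- nu
  while (it < settings$max_iter) {
    it <- it + 1L
    mom <- mf_moments(nu, cfg, ansatz)
    s <- pmax(mom$s, 1e-9)
    F_nu <- vapply(seq_len(k), function(i)
      eif_rate_fp(mom$mu[i], s[i], neuron, tau_m = tau[i],
                  settings = settings), numeric(1))
    F_nu <- pmin(F_nu, settings$rate_cap)
    res <- max(abs(F_nu - nu))
    nu <- (1 - settings$damping) * nu + settings$damping * F_nu
    if (res < settings$tol) break
  }
  names(nu) <- if (ansatz == "uniform") c("E", "I") else
    c("active", "inactive", "I")
  mom <- mf_moments(nu, cfg, ansatz)
  structure(list(ansatz = ansatz, nu = nu, moments = mom,
                 converged = res < settings$tol, residual = res,
                 iterations = it, cfg = cfg, settings = settings),
            class = "plastnet_rate_solution")
}

#' @export
print.plastnet_rate_solution <- function(x, ...) {
  cat("<plastnet_rate_solution> ansatz:", x$ansatz,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(round(x$nu, 3))
  invisible(x)
}

# Probe a landscape point from low and high initial active-cluster rates.
solve_point <- function(cfg, settings, init_low = c(1, 1, 5),
                        init_high = c(50, 2, 10), active_gap = 0.5) {
  lo <- solve_rates(cfg, settings, "one_active", init = init_low)
  hi <- solve_rates(cfg, settings, "one_active", init = init_high)
  pick <- if (hi$converged) hi else lo
  active <- hi$converged &&
    (hi$nu[["active"]] - hi$nu[["inactive"]]) > active_gap
  list(low = lo, high = hi,
       active = active,
       active_rate = if (active) hi$nu[["active"]] else NA_real_,
       inactive_rate = pick$nu[["inactive"]],
       converged = lo$converged || hi$converged)
}

#' Mean-field landscape over the intra-cluster weight moments
#'
#' Solves the one-active-cluster self-consistency problem on a grid of
#' intra-cluster weight mean `mu` and spread `sigma`. Cells with
#' `sigma > sigma_max(mu)` are masked as forbidden (no weight distribution
#' on `[0, w_max]` realises them). Each admissible cell is probed from a low
#' and a high initial active-cluster rate; a cell is in the active phase
#' when a converged solution has the active cluster faster than the
#' inactive ones by more than `active_gap`. The instability line — the
#' boundary between the phases, where metastable switching lives — is the
#' lowest `mu` of the active phase at each `sigma`.
#'
#' @param mu_grid,sigma_grid Grid values, mV.
#' @param cfg A [meanfield_config()] (its `mu_plus`/`sigma_plus` are
#'   overridden cell by cell).
#' @param settings A [solver_settings()].
#' @param active_gap Rate difference (spikes/s) above which a cell counts as
#'   active phase.
#' @return A `plastnet_landscape` tibble: `mu`, `sigma`, `forbidden`,
#'   `converged`, `active`, `active_rate`, `inactive_rate`; the phase
#'   boundary is in `attr(, "boundary")`.
#' @export
mf_landscape <- function(mu_grid, sigma_grid, cfg = meanfield_config(),
                         settings = solver_settings(), active_gap = 0.5) {
  grid <- tidyr::expand_grid(mu = mu_grid, sigma = sigma_grid)
  rows <- purrr::pmap_dfr(grid, function(mu, sigma) {
    if (mu > cfg$w_max || sigma > sigma_max(min(mu, cfg$w_max), cfg$w_max) +
          1e-12)
      return(tibble::tibble(mu = mu, sigma = sigma, forbidden = TRUE,
                            converged = NA, active = NA,
                            active_rate = NA_real_,
                            inactive_rate = NA_real_))
    cfg_pt <- cfg
    cfg_pt$mu_plus <- mu; cfg_pt$sigma_plus <- sigma
    pt <- solve_point(cfg_pt, settings, active_gap = active_gap)
    tibble::tibble(mu = mu, sigma = sigma, forbidden = FALSE,
                   converged = pt$converged, active = pt$active,
                   active_rate = pt$active_rate,
                   inactive_rate = pt$inactive_rate)
  })
  act <- dplyr::filter(rows, !.data$forbidden, !is.na(.data$active),
                       .data$active)
  boundary <- if (nrow(act) == 0) {
    tibble::tibble(sigma = numeric(), mu_c = numeric())
  } else {
    act |>
      dplyr::group_by(.data$sigma) |>
      dplyr::summarise(mu_c = min(.data$mu), .groups = "drop")
  }
  structure(rows, boundary = boundary, cfg = cfg,
            class = c("plastnet_landscape", class(rows)))
}
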