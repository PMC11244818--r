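#' Instantaneous firing-rate estimates from a spike table
#'
#' Causal boxcar estimator: for each neuron and each point of a regular time
#' grid, the spike count in the window `(t - window_ms, t]` divided by the
#' window, in spikes/s. The 50 ms default window resolves state durations of
#' a few hundred ms while smoothing over single spikes; both knobs are
#' exposed.
#'
#' @param spikes Tibble with columns `time` (ms) and `neuron` (1-based), as
#'   produced by [run_session()].
#' @param n_neurons Number of neurons the rate matrix should cover (rows
#'   `1..n_neurons`; pass `N_E` to restrict to excitatory neurons).
#' @param t_start,t_end Analysis interval, ms.
#' @param window_ms Boxcar width, ms.
#' @param grid_ms Grid spacing, ms.
#'
#' @return A `plastnet_rates` object: list with `times` (ms), the
#'   `n_neurons x length(times)` matrix `rates` (spikes/s) and the estimator
#'   settings. An empty spike table gives all-zero rates.
#' @export
estimate_rates <- function(spikes, n_neurons, t_start, t_end,
                           window_ms = 50, grid_ms = 10) {
  stopifnot(window_ms > 0, grid_ms > 0, t_end > t_start)
  times <- seq(t_start + window_ms, t_end, by = grid_ms)
  rates <- matrix(0, nrow = n_neurons, ncol = length(times))
  sp <- spikes[spikes$neuron <= n_neurons &
                 spikes$time > t_start & spikes$time <= t_end, ]
  if (nrow(sp) > 0) {
    by_neuron <- split(sp$time, factor(sp$neuron, levels = seq_len(n_neurons)))
    for (i in seq_len(n_neurons)) {
      st <- by_neuron[[i]]
      if (is.null(st) || !length(st)) next
      st <- sort(st)
      rates[i, ] <- (findInterval(times, st) -
                       findInterval(times - window_ms, st)) /
        (window_ms / 1000)
    }
  }
  structure(list(times = times, rates = rates, window_ms = window_ms,
                 grid_ms = grid_ms), class = "plastnet_rates")
}

#' Overlap of network activity with each stimulus cluster
#'
#' The overlap of stimulus `q` at time `t` is the rate-weighted fraction of
#' excitatory activity carried by that stimulus' cluster,
#' \deqn{m_q(t) = \frac{\sum_i \eta_{q,i}\,\nu_i(t)}{\sum_i \nu_i(t)},}
#' so \eqn{0 \le m_q \le 1}; it approaches 1 when only neurons of cluster
#' `q` are active. When the network is completely silent (zero denominator)
#' the overlap is defined as 0.
#'
#' @param rates A [estimate_rates()] result covering the excitatory neurons.
#' @param clusters The [assign_clusters()] map used in training.
#'
#' @return A `plastnet_overlaps` tibble: columns `time` (ms), `cluster`
#'   and `m`, on the rate grid.
#' @export
overlaps <- function(rates, clusters) {
  stopifnot(inherits(rates, "plastnet_rates"))
  eta <- clusters$eta
  if (ncol(eta) != nrow(rates$rates))
    stop("overlaps: rate matrix must cover exactly the excitatory neurons",
         call. = FALSE)
  num <- eta %*% rates$rates              # Q x T
  den <- colSums(rates$rates)
  m <- sweep(num, 2, ifelse(den > 0, den, Inf), "/")
  out <- tibble::tibble(
    time = rep(rates$times, each = nrow(eta)),
    cluster = rep(seq_len(nrow(eta)), times = length(rates$times)),
    m = as.vector(m))
  structure(out, grid_ms = rates$grid_ms,
            class = c("plastnet_overlaps", class(out)))
}

#' Overlap time series straight from a spike table
#'
#' Convenience wrapper around [estimate_rates()] + [overlaps()] that
#' processes the time grid in chunks, so long recordings do not materialise
#' the full neuron-by-time rate matrix.
#'
#' @inheritParams estimate_rates
#' @inheritParams overlaps
#' @param chunk_s Chunk length for the internal rate matrices, s.
#' @return A `plastnet_overlaps` tibble (see [overlaps()]).
#' @export
overlap_series <- function(spikes, clusters, t_start, t_end,
                           window_ms = 50, grid_ms = 10, chunk_s = 50) {
  n_e <- clusters$N_E
  breaks <- seq(t_start, t_end, by = chunk_s * 1000)
  if (breaks[length(breaks)] < t_end) breaks <- c(breaks, t_end)
  parts <- vector("list", length(breaks) - 1)
  for (k in seq_len(length(breaks) - 1)) {
    # extend left so the causal window of the first grid point is covered
    r <- estimate_rates(spikes, n_e, breaks[k], breaks[k + 1],
                        window_ms = window_ms, grid_ms = grid_ms)
    parts[[k]] <- overlaps(r, clusters)
  }
  out <- dplyr::bind_rows(parts)
  structure(out, grid_ms = grid_ms,
            class = c("plastnet_overlaps", class(tibble::tibble())))
}

#' Segment metastable states from overlap series
#'
#' A memory state for stimulus `q` is active while `m_q > threshold`
#' (strictly). Maximal runs of consecutive grid samples above threshold
#' become segments; no smoothing or debouncing is applied. Segments touching
#' the recording boundaries are flagged incomplete (their true duration is
#' censored).
#'
#' @param ov A `plastnet_overlaps` tibble on a regular grid.
#' @param threshold Activation threshold (default 0.5; since the overlaps sum
#'   to about one, at most one cluster can exceed it at a time).
#'
#' @return A `plastnet_states` tibble: `cluster`, `onset`, `offset`,
#'   `duration` (ms) and `complete`.
#' @export
detect_states <- function(ov, threshold = 0.5) {
  grid_ms <- attr(ov, "grid_ms") %||%
    min(diff(sort(unique(ov$time))))
  t_min <- min(ov$time); t_max <- max(ov$time)
  if (!any(ov$m > threshold)) {
    segs <- tibble::tibble(cluster = integer(), onset = numeric(),
                           offset = numeric(), duration = numeric(),
                           complete = logical())
    return(structure(segs, threshold = threshold, grid_ms = grid_ms,
                     class = c("plastnet_states", class(segs))))
  }
  segs <- ov |>
    dplyr::group_by(.data$cluster) |>
    dplyr::arrange(.data$time, .by_group = TRUE) |>
    dplyr::mutate(active = .data$m > threshold,
                  run = cumsum(.data$active &
                                 !dplyr::lag(.data$active, default = FALSE))) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$active) |>
    dplyr::group_by(.data$cluster, .data$run) |>
    dplyr::summarise(onset = min(.data$time),
                     offset = max(.data$time) + grid_ms, .groups = "drop") |>
    dplyr::mutate(duration = .data$offset - .data$onset,
                  complete = .data$onset > t_min &
                    (.data$offset - grid_ms) < t_max) |>
    dplyr::select("cluster", "onset", "offset", "duration", "complete") |>
    dplyr::arrange(.data$onset)
  structure(segs, threshold = threshold, grid_ms = grid_ms,
            class = c("plastnet_states", class(segs)))
}

#' Dwell-time statistics of metastable states
#'
#' Mean, standard deviation and an exponentiality diagnostic of the
#' state durations. Only complete (non-censored) segments enter the
#' statistics; boundary segments would bias the mean. For an exponential
#' dwell-time distribution the standard deviation equals the mean, so
#' `exp_diagnostic = |sd/mean - 1|` is near zero.
#'
#' @param segments A [detect_states()] tibble.
#' @return A one-row tibble: `n_segments`, `n_complete`, `mean_ms`, `sd_ms`,
#'   `cv` (sd/mean) and `exp_diagnostic`. With no complete segment all
#'   statistics are `NA` (explicit empty marker); with one, `sd_ms` is `NA`.
#' @export
duration_stats <- function(segments) {
  d <- segments$duration[segments$complete]
  tibble::tibble(
    n_segments = nrow(segments),
    n_complete = length(d),
    mean_ms = if (length(d)) mean(d) else NA_real_,
    sd_ms = if (length(d) > 1) sd(d) else NA_real_,
    cv = if (length(d) > 1) sd(d) / mean(d) else NA_real_,
    exp_diagnostic = if (length(d) > 1) abs(sd(d) / mean(d) - 1) else NA_real_)
}

#' Mean plastic weight by class (w0 / w1)
#'
#' Partitions the plastic (E-to-E) synapses into class 1 — the two neurons
#' share at least one stimulus — and class 0 — they share none — and returns
#' the mean efficacy of each class. Training drives `w1` up relative to
#' `w0`; their post-training relaxation tracks the stability of the learned
#' clusters.
#'
#' @param network A `plastnet_network` (possibly after sessions).
#' @param clusters Optional cluster map to classify against; defaults to the
#'   map stored at construction, so post-remapping bookkeeping against a new
#'   stimulus set is explicit, not automatic.
#' @return A one-row tibble: `w0`, `w1` (mV; `NA` when a class is empty),
#'   `n0`, `n1`.
#' @export
mean_weights_by_class <- function(network, clusters = NULL) {
  edges <- network$edges
  pl <- edges[edges$plastic, ]
  if (nrow(pl) == 0)
    stop("mean_weights_by_class: network has no plastic synapses",
         call. = FALSE)
  cls <- if (is.null(clusters)) pl$class else
    edge_classes(clusters$eta, pl$pre, pl$post)
  tibble::tibble(
    w0 = if (any(cls == 0)) mean(pl$w[cls == 0]) else NA_real_,
    w1 = if (any(cls == 1)) mean(pl$w[cls == 1]) else NA_real_,
    n0 = sum(cls == 0), n1 = sum(cls == 1))
}

#' Mean and spread of intra-cluster weights over time
#'
#' For each stored weight snapshot of a session, the mean and standard
#' deviation of the class-1 (shared-stimulus) plastic weights — the
#' trajectory that can be overlaid on the mean-field landscape.
#'
#' @param session A `plastnet_session` with snapshots.
#' @return Tibble: `time`, `mean_w1`, `sd_w1`.
#' @export
weight_moments <- function(session) {
  edges <- session$network$edges
  idx <- which(edges$plastic & edges$class == 1L)
  purrr::map2_dfr(session$snapshots$time, session$snapshots$w,
                  function(tm, w) tibble::tibble(
                    time = tm, mean_w1 = mean(w[idx]), sd_w1 = sd(w[idx])))
}

#' Size-scaled rate of change of the weight classes
#'
#' Finite differences of the class-averaged weights over snapshot intervals,
#' multiplied by the network size `N`. If the per-synapse drift scales as
#' `1/N`, the `N * dw/dt` curves of different network sizes collapse onto a
#' common master curve.
#'
#' @param series Tibble with columns `time` (ms), `w0`, `w1` and `N` (one
#'   value of `N` per network; bind several networks' [run_session()]
#'   `class_series` together, adding their `N`).
#' @return Tibble with `N`, `time` (interval midpoint, ms), `class`
#'   (`"w0"`/`"w1"`), `dw_dt` (mV/ms) and `N_dw_dt`.
#' @export
weight_change_rate <- function(series) {
  stopifnot(all(c("time", "w0", "w1", "N") %in% names(series)))
  series |>
    tidyr::pivot_longer(c("w0", "w1"), names_to = "class",
                        values_to = "w") |>
    dplyr::group_by(.data$N, .data$class) |>
    dplyr::arrange(.data$time, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      if (any(diff(d$time) <= 0))
        stop("weight_change_rate: snapshot times must be increasing",
             call. = FALSE)
      tibble::tibble(time = (d$time[-1] + d$time[-nrow(d)]) / 2,
                     dw_dt = diff(d$w) / diff(d$time))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(N_dw_dt = .data$N * .data$dw_dt)
}

#' Alignment of size-scaled weight-drift curves
#'
#' Maximum pairwise gap, over a common time grid, between the `N * dw/dt`
#' curves of different network sizes — small gaps mean the `1/N` drift law
#' holds.
#'
#' @param rates A [weight_change_rate()] result with several `N`.
#' @return Tibble per `class`: `max_gap` and the across-`N` spread summary.
#' @export
scaling_alignment <- function(rates) {
  rates |>
    dplyr::group_by(.data$class, .data$time) |>
    dplyr::summarise(gap = max(.data$N_dw_dt) - min(.data$N_dw_dt),
                     .groups = "drop_last") |>
    dplyr::summarise(max_gap = max(.data$gap), mean_gap = mean(.data$gap),
                     .groups = "drop")
}
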