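#' Training schedule: periodic presentation of the stimulus set
#'
#' One stimulus, drawn uniformly from the `Q` clusters, is presented in every
#' period. Presentations last `stim_ms` and start at the beginning of each
#' period (or at exponentially distributed random times when
#' `random_intervals = TRUE`; the fixed-period default and random intervals
#' give equivalent training outcomes). The default session length scales
#' linearly with `Q` (one simulated minute per 10 presentations), so every
#' stimulus is presented about 30 times regardless of network size.
#'
#' @param clusters A [assign_clusters()] map; event targets are the cluster
#'   members.
#' @param session_ms Session duration, ms. Default `60000 * Q`
#'   (10 minutes for Q = 10, i.e. about 30 presentations per stimulus at the
#'   2 s period; doubled clusters double the training time).
#' @param period_ms Presentation period, ms.
#' @param stim_ms Stimulus duration, ms; must be < `period_ms`.
#' @param amplitude Stimulus drive `h_st`, mV/ms.
#' @param seed Integer seed for the stimulus order.
#' @param random_intervals Draw inter-presentation onsets from an exponential
#'   distribution with mean `period_ms` instead of a fixed period.
#'
#' @return A `plastnet_schedule`: tibble with columns `onset`, `duration`,
#'   `stimulus`, `amplitude` and list-column `targets`, sorted by onset;
#'   attributes `session_ms` and `scenario = "training"`.
#' @export
#' @examples
#' cl <- assign_clusters(80, 4, 0.1, seed = 2)
#' sched <- training_schedule(cl, session_ms = 20000, seed = 1)
#' nrow(sched)
training_schedule <- function(clusters, session_ms = 60000 * clusters$Q,
                              period_ms = 2000, stim_ms = 500,
                              amplitude = 0.5, seed = 1L,
                              random_intervals = FALSE) {
  if (stim_ms >= period_ms)
    stop("training_schedule: stim_ms must be < period_ms", call. = FALSE)
  Q <- clusters$Q
  with_seed(seed, {
    if (random_intervals) {
      onsets <- cumsum(rexp(ceiling(4 * session_ms / period_ms),
                            rate = 1 / period_ms))
      onsets <- onsets[onsets + stim_ms <= session_ms]
    } else {
      onsets <- seq(0, session_ms - period_ms, by = period_ms)
    }
    ids <- sample.int(Q, length(onsets), replace = TRUE)
  })
  sched <- tibble::tibble(
    onset = onsets, duration = stim_ms, stimulus = ids,
    amplitude = amplitude,
    targets = lapply(ids, function(q) which(clusters$eta[q, ] == 1L)))
  new_schedule(sched, session_ms, "training")
}

#' Perturbation schedules: random, mixed, or novel stimuli after training
#'
#' Events occur at random times with exponentially distributed inter-event
#' intervals (a Poisson process). Three scenarios are supported:
#' * `"random"` — every event targets a fresh, independently drawn
#'   Bernoulli(`f`) subset of excitatory neurons (a purely noisy
#'   environment);
#' * `"mixed"` — each event is, with probability 1/2, such a fresh random
#'   set, and otherwise a stimulus drawn uniformly (with replacement) from
#'   the predefined second set `set2`;
#' * `"novel"` — all events are drawn uniformly from `set2` (retraining with
#'   a new stimulus set).
#'
#' @param scenario One of `"random"`, `"mixed"`, `"novel"`.
#' @param N_E Number of excitatory neurons (targets are sampled among these).
#' @param f Coding level of the freshly sampled random stimuli.
#' @param session_ms Session duration, ms.
#' @param set2 A [assign_clusters()] map holding the second stimulus set;
#'   required for scenarios `"mixed"` and `"novel"`.
#' @param mean_interval_ms Mean inter-event interval, ms (default 10 s).
#' @param stim_ms Event duration, ms (default 200 ms).
#' @param amplitude Stimulus drive, mV/ms.
#' @param seed Integer seed.
#'
#' @return A `plastnet_schedule` tibble (see [training_schedule()]);
#'   `stimulus` is the index into `set2` for set-2 events and `NA` for fresh
#'   random events.
#' @export
perturbation_schedule <- function(scenario = c("random", "mixed", "novel"),
                                  N_E, f, session_ms, set2 = NULL,
                                  mean_interval_ms = 10000, stim_ms = 200,
                                  amplitude = 0.5, seed = 1L) {
  scenario <- match.arg(scenario)
  if (scenario != "random" && is.null(set2))
    stop("perturbation_schedule: set2 is required for scenario '", scenario,
         "'", call. = FALSE)
  with_seed(seed, {
    n_guess <- ceiling(3 * session_ms / mean_interval_ms) + 20
    onsets <- cumsum(rexp(n_guess, rate = 1 / mean_interval_ms))
    onsets <- onsets[onsets + stim_ms <= session_ms]
    n_ev <- length(onsets)
    fresh <- switch(scenario,
                    random = rep(TRUE, n_ev),
                    mixed = runif(n_ev) < 0.5,
                    novel = rep(FALSE, n_ev))
    ids <- rep(NA_integer_, n_ev)
    if (any(!fresh)) ids[!fresh] <- sample.int(set2$Q, sum(!fresh),
                                               replace = TRUE)
    targets <- vector("list", n_ev)
    for (k in seq_len(n_ev)) {
      targets[[k]] <- if (fresh[k]) which(runif(N_E) < f)
                      else which(set2$eta[ids[k], ] == 1L)
    }
  })
  sched <- tibble::tibble(onset = onsets, duration = stim_ms,
                          stimulus = ids, amplitude = amplitude,
                          targets = targets)
  new_schedule(sched, session_ms, scenario)
}

#' An empty schedule (ongoing activity, no stimulation)
#'
#' @param session_ms Session duration, ms.
#' @return A `plastnet_schedule` with zero events.
#' @export
empty_schedule <- function(session_ms) {
  sched <- tibble::tibble(onset = numeric(), duration = numeric(),
                          stimulus = integer(), amplitude = numeric(),
                          targets = list())
  new_schedule(sched, session_ms, "none")
}

new_schedule <- function(sched, session_ms, scenario) {
  sched <- dplyr::arrange(sched, .data$onset)
  structure(sched, session_ms = session_ms, scenario = scenario,
            class = c("plastnet_schedule", class(sched)))
}
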