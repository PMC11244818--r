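#' Write / read a spike table
#'
#' Plain-text format: comment header lines (`#`) carrying `N`, `N_E`, `dt`
#' and the seed, then a tab-separated table with `time_ms` (3 decimals) and
#' `neuron` (0-based in the file, converted to 1-based on read), sorted by
#' time.
#'
#' @param session A `plastnet_session` (or a tibble with `time`, `neuron`).
#' @param path Output file.
#' @param meta Optional named list overriding the header metadata.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(session, path, meta = NULL) {
  if (inherits(session, "plastnet_session")) {
    spikes <- session$spikes
    cfg <- session$network$cfg
    meta <- meta %||% list(N = cfg$N, N_E = cfg$N_E, dt = session$dt,
                           seed = cfg$seed)
  } else {
    spikes <- session
    meta <- meta %||% list()
  }
  hdr <- c("# plastnet spike table v1",
           paste0("# ", paste(names(meta), unlist(meta), sep = "=",
                              collapse = " ")),
           "time_ms\tneuron")
  body <- sprintf("%.3f\t%d", spikes$time, spikes$neuron - 1L)
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  tb <- readr::read_tsv(path, comment = "#",
                        col_types = readr::cols(
                          time_ms = readr::col_double(),
                          neuron = readr::col_integer()))
  tibble::tibble(time = tb$time_ms, neuron = tb$neuron + 1L)
}

#' Write / read a weight snapshot
#'
#' Versioned plain-text edge list: header comments with `N`, `N_E`, the
#' snapshot time and seed provenance, then tab-separated `pre`, `post`
#' (1-based), `w` at full double precision — the round trip is lossless.
#'
#' @param network A `plastnet_network`.
#' @param path Output file.
#' @param time_ms Snapshot time stamp, ms.
#' @return `path` invisibly; `read_weights()` returns a
#'   `plastnet_network`-shaped list with `edges` and header metadata (the
#'   cluster map is not stored here — rebuild it from the seed, or keep the
#'   built network object).
#' @export
write_weights <- function(network, path, time_ms = NA) {
  cfg <- network$cfg
  hdr <- c("# plastnet weights v1",
           sprintf("# N=%d N_E=%d time_ms=%s seed=%d", cfg$N, cfg$N_E,
                   format(time_ms), cfg$seed),
           "pre\tpost\tw")
  e <- network$edges
  body <- sprintf("%d\t%d\t%.17g", e$pre, e$post, e$w)
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  hdr <- readr::read_lines(path, n_max = 2)
  kv <- strsplit(sub("^# ", "", hdr[2]), " ")[[1]]
  meta <- as.list(setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv)))
  tb <- readr::read_tsv(path, comment = "#",
                        col_types = readr::cols(
                          pre = readr::col_integer(),
                          post = readr::col_integer(),
                          w = readr::col_character()))
  # strtod via as.numeric: correctly rounded, so %.17g round-trips exactly
  tb$w <- as.numeric(tb$w)
  edges <- tibble::as_tibble(tb)
  edges$plastic <- edges$pre <= meta$N_E & edges$post <= meta$N_E
  list(edges = edges, meta = meta)
}

#' Write / read a session's plasticity-state snapshot
#'
#' Per-excitatory-neuron `v_tilde`, `s_tilde` and `theta` in a plain TSV.
#'
#' @param session A `plastnet_session`.
#' @param path Output file.
#' @export
write_plasticity_state <- function(session, path) {
  st <- session$state
  tb <- tibble::tibble(neuron = seq_along(st$v_tilde),
                       v_tilde = st$v_tilde, s_tilde = st$s_tilde,
                       theta = st$theta)
  readr::write_tsv(tb, path)
  invisible(path)
}

#' @rdname write_plasticity_state
#' @export
read_plasticity_state <- function(path) {
  readr::read_tsv(path, col_types = readr::cols())
}

#' Save / load an experiment configuration as YAML
#'
#' Every model parameter is serialised by name; reading an empty or partial
#' file fills the remaining fields with the package defaults, and unknown
#' keys are an error (they usually indicate a typo in a parameter name).
#'
#' @param cfg A [network_config()].
#' @param path YAML file.
#' @return `path` invisibly; `read_config()` returns a validated
#'   [network_config()].
#' @export
write_config <- function(cfg, path) {
  lst <- unclass(cfg)
  lst$neuron <- unclass(lst$neuron)
  lst$plasticity <- unclass(lst$plasticity)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- unclass(network_config())
  known <- names(defaults)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("read_config: unknown keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (blk in c("neuron", "plasticity")) {
    if (!is.null(raw[[blk]])) {
      unknown <- setdiff(names(raw[[blk]]), names(unclass(defaults[[blk]])))
      if (length(unknown))
        stop("read_config: unknown keys in ", blk, ": ",
             paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  args <- utils::modifyList(list(), raw)
  if (!is.null(args$neuron)) args$neuron <- do.call(neuron_params, args$neuron)
  if (!is.null(args$plasticity))
    args$plasticity <- do.call(plasticity_params, args$plasticity)
  # N_E/N_I defaults follow a supplied N unless given explicitly
  do.call(network_config, args)
}
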