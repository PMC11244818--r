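#' Draw the random connectivity of a clustered E/I network
#'
#' Every ordered pair of distinct neurons is connected independently with the
#' probability of its population pair (`p_EE`, `p_EI`, `p_IE`, `p_II`; first
#' index postsynaptic), and each existing connection starts at the constant
#' efficacy of its type. Neurons `1..N_E` are excitatory, `(N_E+1)..N`
#' inhibitory; weights from excitatory neurons are nonnegative and weights
#' from inhibitory neurons nonpositive (Dale's law), which plasticity later
#' preserves because only E-to-E synapses are plastic and they are clamped at
#' zero. Self-connections are excluded.
#'
#' @param cfg A [network_config()].
#' @param seed Seed for the connectivity draw; defaults to the `connectivity`
#'   substream of `cfg$seed`.
#'
#' @return A tibble of directed edges with columns `pre`, `post` (1-based),
#'   `w` (mV) and `plastic` (TRUE exactly for E-to-E edges), sorted by
#'   `pre`, `post`.
#' @export
#' @examples
#' edges <- build_connectivity(network_config(N = 50, N_E = 40, N_I = 10))
#' nrow(edges)
build_connectivity <- function(cfg,
                               seed = substream_seed(cfg$seed, "connectivity")) {
  stopifnot(inherits(cfg, "plastnet_config"))
  n <- cfg$N; n_e <- cfg$N_E
  p_of <- function(post_E, pre_E) {
    if (pre_E) { if (post_E) cfg$p_EE else cfg$p_IE }
    else       { if (post_E) cfg$p_EI else cfg$p_II }
  }
  w_of <- function(post_E, pre_E) {
    if (pre_E) { if (post_E) cfg$w_EE else cfg$w_IE }
    else       { if (post_E) cfg$w_EI else cfg$w_II }
  }
  with_seed(seed, {
    chunks <- split(seq_len(n), ceiling(seq_len(n) / 500))
    parts <- lapply(chunks, function(pres) {
      res <- vector("list", length(pres))
      for (k in seq_along(pres)) {
        j <- pres[k]
        pre_E <- j <= n_e
        # posts are all other neurons; two probability blocks (E posts, I posts)
        pE <- p_of(TRUE, pre_E); pI <- p_of(FALSE, pre_E)
        uE <- runif(n_e) < pE
        uI <- runif(n - n_e) < pI
        hit <- c(uE, uI)
        hit[j] <- FALSE
        post <- which(hit)
        if (!length(post)) next
        res[[k]] <- tibble::tibble(
          pre = j, post = post,
          w = ifelse(post <= n_e, w_of(TRUE, pre_E), w_of(FALSE, pre_E)))
      }
      dplyr::bind_rows(res)
    })
    edges <- dplyr::bind_rows(parts)
  })
  edges$plastic <- edges$pre <= n_e & edges$post <= n_e
  dplyr::arrange(edges, .data$pre, .data$post)
}

#' Assign overlapping stimulus clusters
#'
#' Each of `Q` stimuli targets every excitatory neuron independently with
#' probability `f` (the coding level). The targeted subpopulation of a
#' stimulus is its cluster; clusters overlap, and a fraction of about
#' `(1 - f)^Q` of neurons responds to no stimulus.
#'
#' @param N_E Number of excitatory neurons.
#' @param Q Number of stimuli.
#' @param f Coding level in (0, 1].
#' @param seed Integer seed.
#'
#' @return An object of class `plastnet_clusters`: a list with the binary
#'   `Q x N_E` membership matrix `eta` and the draw parameters.
#' @export
#' @examples
#' cl <- assign_clusters(800, 10, 0.1, seed = 1)
#' cluster_stats(cl)
assign_clusters <- function(N_E, Q, f, seed = 1L) {
  if (f <= 0 || f > 1) stop("assign_clusters: f must be in (0, 1]",
                            call. = FALSE)
  if (Q < 1) stop("assign_clusters: Q must be >= 1", call. = FALSE)
  eta <- with_seed(seed, matrix(as.integer(runif(Q * N_E) < f), nrow = Q))
  structure(list(eta = eta, Q = Q, N_E = N_E, f = f, seed = seed),
            class = "plastnet_clusters")
}

#' @export
print.plastnet_clusters <- function(x, ...) {
  cat("<plastnet_clusters> Q =", x$Q, " N_E =", x$N_E, " f =", x$f, "\n")
  invisible(x)
}

#' Summary statistics of a cluster assignment
#'
#' @param clusters A [assign_clusters()] result.
#' @return A one-row tibble: mean and sd of cluster sizes, fraction of
#'   excitatory neurons responsive to no stimulus (`frac_nonresponsive`),
#'   fraction responsive to at least two (`frac_ge2`), and `frac_multi` —
#'   the fraction of cluster memberships whose neuron also belongs to other
#'   clusters, i.e. the probability that a neuron of a given cluster
#'   responds to further stimuli (expectation `1 - (1 - f)^(Q - 1)`).
#' @export
cluster_stats <- function(clusters) {
  eta <- clusters$eta
  sizes <- rowSums(eta)
  memb <- colSums(eta)
  tibble::tibble(
    Q = clusters$Q, N_E = clusters$N_E, f = clusters$f,
    mean_size = mean(sizes), sd_size = sd(sizes),
    frac_nonresponsive = mean(memb == 0),
    frac_responsive = mean(memb > 0),
    frac_ge2 = mean(memb >= 2),
    frac_multi = if (any(memb > 0)) sum(memb[memb >= 2]) / sum(memb)
                 else NA_real_)
}

# Class of each plastic synapse: 1 if pre and post share >= 1 stimulus,
# 0 otherwise. Chunked so the Q x n_edges intermediate stays small.
edge_classes <- function(eta, pre, post, chunk = 100000L) {
  n <- length(pre)
  out <- integer(n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    idx <- lo:hi
    out[idx] <- as.integer(
      colSums(eta[, pre[idx], drop = FALSE] *
              eta[, post[idx], drop = FALSE]) > 0)
  }
  out
}

#' Build a complete network: connectivity plus stimulus clusters
#'
#' Draws the quenched random connectivity and the stimulus cluster map from
#' independent substreams of the master seed, and labels each plastic (E-to-E)
#' synapse by weight class: class 1 if its two neurons share at least one
#' stimulus, class 0 otherwise.
#'
#' @param cfg A [network_config()].
#' @return An object of class `plastnet_network`: list with `cfg`, the edge
#'   tibble `edges` (columns `pre`, `post`, `w`, `plastic`, `class`), and the
#'   cluster map `clusters`.
#' @export
#' @examples
#' net <- build_network(network_config(N = 100, N_E = 80, N_I = 20, Q = 4))
#' net
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "plastnet_config"))
  edges <- build_connectivity(cfg)
  clusters <- assign_clusters(cfg$N_E, cfg$Q, cfg$f,
                              seed = substream_seed(cfg$seed, "clusters"))
  edges$class <- NA_integer_
  pl <- which(edges$plastic)
  edges$class[pl] <- edge_classes(clusters$eta, edges$pre[pl], edges$post[pl])
  structure(list(cfg = cfg, edges = edges, clusters = clusters),
            class = "plastnet_network")
}

#' @export
print.plastnet_network <- function(x, ...) {
  cat("<plastnet_network> N =", x$cfg$N, "(", x$cfg$N_E, "E /", x$cfg$N_I,
      "I ), Q =", x$cfg$Q, ", f =", x$cfg$f, "\n")
  cat("  edges:", nrow(x$edges), " plastic:", sum(x$edges$plastic), "\n")
  invisible(x)
}
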