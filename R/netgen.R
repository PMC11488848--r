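#' Number of excitatory cells implied by a configuration
#' @param config a [ppn_config()].
#' @return integer count of excitatory neurons.
#' @export
n_excitatory <- function(config) {
  as.integer(round(config$network$n * config$network$excit_fraction))
}

#' Within-cluster connection probability
#'
#' E-to-E connections exist only between cells sharing a cluster, so the
#' within-cluster probability must exceed the global target `pc` to realize
#' the desired total number of connections. With `Ctot = nE (nE - 1)`
#' ordered pairs overall and `Cclust = nEclust (nEclust - 1) nc` ordered
#' within-cluster pairs (using the real-valued cluster size
#' `nEclust = nE mu_c / nc`), the within-cluster probability is
#' `pc * Ctot / Cclust`.
#'
#' Values above 1 mark an infeasible geometry: the clusters do not contain
#' enough pairs to reach the global connection density.
#'
#' @param config a [ppn_config()].
#' @return the within-cluster connection probability (may exceed 1, in
#'   which case the configuration cannot be realized).
#' @export
within_cluster_probability <- function(config) {
  nw <- config$network
  n_e <- n_excitatory(config)
  n_clust <- n_e * nw$cluster_participation / nw$n_clusters
  c_tot <- n_e * (n_e - 1)
  c_clust <- n_clust * (n_clust - 1) * nw$n_clusters
  nw$p_ee * c_tot / c_clust
}

#' Is a cluster geometry feasible?
#'
#' @param config a [ppn_config()].
#' @return `TRUE` if the within-cluster probability is at most 1 and the
#'   participation does not exceed the cluster count.
#' @export
config_feasible <- function(config) {
  nw <- config$network
  nw$cluster_participation <= nw$n_clusters &&
    within_cluster_probability(config) <= 1
}

#' Assign excitatory cells to overlapping clusters
#'
#' Every excitatory cell is first given exactly one cluster (round-robin
#' over a random ordering of cells, so base sizes are balanced), then each
#' cluster is topped up with randomly selected additional cells - sampled
#' without replacement from cells not already in it - until all clusters
#' reach the identical target size `round(nE mu_c / nc)`.
#'
#' @param config a [ppn_config()].
#' @param seed optional integer seed; defaults to the `"clusters"`
#'   sub-stream of the master seed.
#' @return an object of class `cluster_membership`: a list with `membership`
#'   (logical `nE x nc` matrix), `cluster_size`, and the realized mean
#'   participation.
#' @export
assign_clusters <- function(config, seed = NULL) {
  nw <- config$network
  n_e <- n_excitatory(config)
  nc <- nw$n_clusters
  mu <- nw$cluster_participation
  if (mu > nc)
    stop("cluster participation cannot exceed the number of clusters")
  size <- as.integer(round(n_e * mu / nc))
  if (size > n_e)
    stop("required cluster size exceeds the number of excitatory cells")
  if (is.null(seed)) seed <- substream_seed(config$seed, "clusters")
  membership <- with_stream(seed, {
    m <- matrix(FALSE, n_e, nc)
    first <- rep_len(seq_len(nc), n_e)[sample.int(n_e)]
    m[cbind(seq_len(n_e), first)] <- TRUE
    for (k in seq_len(nc)) {
      need <- size - sum(m[, k])
      if (need > 0) {
        pool <- which(!m[, k])
        m[pool[sample.int(length(pool), need)], k] <- TRUE
      }
    }
    m
  })
  structure(list(membership = membership,
                 cluster_size = as.integer(colSums(membership)),
                 mean_participation = mean(rowSums(membership))),
            class = "cluster_membership")
}

#' @export
print.cluster_membership <- function(x, ...) {
  cat(sprintf("Cluster membership: %d E cells, %d clusters of size %d, mean participation %.3f\n",
              nrow(x$membership), ncol(x$membership), x$cluster_size[1L],
              x$mean_participation))
  invisible(x)
}

#' Build the directed connectivity of one network realization
#'
#' E-to-E connections are drawn cluster-wise: within every cluster, each
#' ordered pair of member cells receives an independent Bernoulli trial
#' at the within-cluster probability
#' ([within_cluster_probability()]), and the adjacency is the union over
#' clusters (a pair sharing several clusters gets several chances, which
#' is what makes the expected global density exactly `p_ee`); pairs
#' sharing no cluster are never connected. E-to-I and I-to-E connections
#' are cluster-independent with probability `p_ei_ie`. There are no
#' I-to-I connections and no self-connections.
#'
#' @param members a [assign_clusters()] result.
#' @param config a [ppn_config()].
#' @param seed optional seed; defaults to the `"connectivity"` sub-stream.
#' @return an object of class `connectivity`: logical matrices `ee`
#'   (`nE x nE`), `ei` (`nE x nI`), `ie` (`nI x nE`).
#' @export
build_connectivity <- function(members, config, seed = NULL) {
  nw <- config$network
  n_e <- nrow(members$membership)
  n_i <- nw$n - n_e
  # calibrate against the realized integer cluster sizes so the expected
  # number of connections is pc * nE (nE - 1)
  sizes <- members$cluster_size
  c_clust <- sum(sizes * (sizes - 1))
  p_within <- nw$p_ee * n_e * (n_e - 1) / c_clust
  if (p_within > 1 || within_cluster_probability(config) > 1)
    stop("infeasible geometry: within-cluster connection probability ",
         sprintf("%.3f", p_within), " exceeds 1")
  if (is.null(seed)) seed <- substream_seed(config$seed, "connectivity")
  with_stream(seed, {
    ee <- matrix(FALSE, n_e, n_e)
    for (k in seq_len(ncol(members$membership))) {
      idx <- which(members$membership[, k])
      m_k <- length(idx)
      block <- matrix(stats::runif(m_k * m_k) < p_within, m_k, m_k)
      diag(block) <- FALSE
      ee[idx, idx] <- ee[idx, idx] | block
    }
    ei <- matrix(stats::runif(n_e * n_i) < nw$p_ei_ie, n_e, n_i)
    ie <- matrix(stats::runif(n_i * n_e) < nw$p_ei_ie, n_i, n_e)
    structure(list(ee = ee, ei = ei, ie = ie, n_e = n_e, n_i = n_i),
              class = "connectivity")
  })
}

#' @export
print.connectivity <- function(x, ...) {
  cat(sprintf("Connectivity: %d E, %d I; E-to-E density %.4f (%d connections)\n",
              x$n_e, x$n_i, mean(x$ee[!diag(nrow(x$ee))]), sum(x$ee)))
  invisible(x)
}

#' Define an environment by a cluster-rank permutation
#'
#' Each environment randomly orders the clusters and assigns them evenly
#' spaced rank-bias values from -1 (first cluster: rightward cue
#' preference) to +1 (last: leftward preference). A cell's location-cue
#' bias is the mean bias of its clusters times `sigma_bias`.
#'
#' @param config a [ppn_config()].
#' @param env_id integer environment label.
#' @param seed optional seed; defaults to the `("environment", env_id)`
#'   sub-stream.
#' @return class `environment_spec`: `env_id`, `cluster_order` (the random
#'   shuffle), and `cluster_bias` (per-cluster bias value in `[-1, 1]`).
#' @export
environment_spec <- function(config, env_id = 1L, seed = NULL) {
  nc <- config$network$n_clusters
  if (is.null(seed)) seed <- substream_seed(config$seed, "environment", env_id)
  ord <- with_stream(seed, sample.int(nc))
  bias <- numeric(nc)
  bias[ord] <- if (nc > 1) seq(-1, 1, length.out = nc) else 0
  structure(list(env_id = env_id, cluster_order = ord, cluster_bias = bias),
            class = "environment_spec")
}

# Moment-matched log-normal draws with mean mu and standard deviation sigma.
rlnorm_meansd <- function(n, mu, sigma) {
  if (sigma == 0) return(rep(mu, n))
  meanlog <- log(mu^2 / sqrt(sigma^2 + mu^2))
  sdlog <- sqrt(log(1 + sigma^2 / mu^2))
  stats::rlnorm(n, meanlog, sdlog)
}

#' Draw feed-forward input weights for one environment
#'
#' Location-cue weights (excitatory cells only) and context-cue weights
#' (all cells) are drawn from a log-normal distribution with mean `w_in`
#' and standard deviation `sigma_in` (location) or `sigma_context`
#' (context), parameterized by moment matching. Each excitatory cell's
#' bias, `sigma_bias` times the mean rank bias of its clusters, then
#' scales the left-cue weight by `(1 + bias)` and the right-cue weight by
#' `(1 - bias)`.
#'
#' Context weights are unique per environment; the sleep session draws its
#' own context weights via [draw_context_weights()].
#'
#' @param members a [assign_clusters()] result.
#' @param env an [environment_spec()].
#' @param config a [ppn_config()].
#' @param seed optional seed; defaults to the `("weights", env_id)`
#'   sub-stream.
#' @return class `input_weights`: `w_left`, `w_right` (pS, length `nE`),
#'   `w_context` (pS, length `n`: E cells first, then I), and `bias`
#'   (length `nE`, in `[-1, 1]` before the `sigma_bias` scaling).
#' @export
generate_input_weights <- function(members, env, config, seed = NULL) {
  inp <- config$inputs
  n_e <- nrow(members$membership)
  n <- config$network$n
  if (is.null(seed)) seed <- substream_seed(config$seed, "weights", env$env_id)
  with_stream(seed, {
    raw_left <- rlnorm_meansd(n_e, inp$w_in, inp$sigma_in)
    raw_right <- rlnorm_meansd(n_e, inp$w_in, inp$sigma_in)
    w_context <- rlnorm_meansd(n, inp$w_in, inp$sigma_context)
    rank_bias <- members$membership %*% env$cluster_bias / rowSums(members$membership)
    bias <- as.numeric(rank_bias)
    scaled_bias <- inp$sigma_bias * bias
    structure(list(w_left = raw_left * (1 + scaled_bias),
                   w_right = raw_right * (1 - scaled_bias),
                   w_context = w_context,
                   bias = bias,
                   env_id = env$env_id),
              class = "input_weights")
  })
}

#' Draw context-cue weights for a sleep session
#'
#' @param config a [ppn_config()].
#' @param label stream label (default `"sleep"`).
#' @return numeric vector of context weights (pS) for all `n` neurons.
#' @export
draw_context_weights <- function(config, label = "sleep") {
  with_stream(substream_seed(config$seed, "context", label),
              rlnorm_meansd(config$network$n, config$inputs$w_in,
                            config$inputs$sigma_context))
}

#' Build a complete clustered network realization
#'
#' Assembles cluster membership, directed connectivity, the requested
#' number of environments (cluster-rank permutations plus input weights),
#' and sleep context weights, all from named sub-streams of the master
#' seed.
#'
#' @param config a [ppn_config()].
#' @param n_env number of environments to define.
#' @return class `clustered_network` with elements `config`, `members`,
#'   `conn`, `envs` (list of `environment_spec`), `weights` (list of
#'   `input_weights` per environment), `w_context_sleep`, and `is_excit`.
#' @export
build_network <- function(config, n_env = 1L) {
  members <- assign_clusters(config)
  conn <- build_connectivity(members, config)
  envs <- lapply(seq_len(n_env), function(e) environment_spec(config, e))
  weights <- lapply(envs, function(e)
    generate_input_weights(members, e, config))
  n_e <- conn$n_e
  structure(list(config = config,
                 members = members,
                 conn = conn,
                 envs = envs,
                 weights = weights,
                 w_context_sleep = draw_context_weights(config),
                 is_excit = c(rep(TRUE, n_e), rep(FALSE, conn$n_i))),
            class = "clustered_network")
}

#' @export
print.clustered_network <- function(x, ...) {
  print(x$config)
  print(x$members)
  print(x$conn)
  cat(sprintf("  %d environment(s) defined\n", length(x$envs)))
  invisible(x)
}
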