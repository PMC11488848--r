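# Shared fixtures. Expensive ensembles are computed once per test session
# and memoized here; everything is generated from fixed seeds in code.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Tiny network configuration for fast dynamical tests.
tiny_config <- function(seed = 11, ...) {
  ppn_config(seed = seed,
             network.n = 60, network.n_clusters = 4,
             network.cluster_participation = 1.25,
             session.sleep_s = 5, ...)
}

# Hand-built spike record (constant-speed run session by default).
make_spike_record <- function(neuron, time, n = 10L, n_e = 10L,
                              session = "run", duration = 10,
                              direction = "right", n_laps = 5L,
                              lap_s = 2, env = 1L, speed = 1) {
  ord <- order(time, neuron)
  structure(list(spikes = data.frame(neuron = as.integer(neuron[ord]),
                                     time = as.numeric(time[ord])),
                 duration = duration, n = as.integer(n),
                 n_e = as.integer(n_e),
                 meta = list(session = session, env = env,
                             direction = direction, speed = speed,
                             n_laps = n_laps, lap_s = lap_s,
                             label = "fixture", seed = NA)),
            class = "spike_record")
}

# Hand-built posterior object compatible with the decoder statistics.
make_posterior <- function(post, tau = 0.01) {
  post <- sweep(post, 2, colSums(post), "/")
  structure(list(post = post, counts = NULL, tau = tau,
                 t_centers = (seq_len(ncol(post)) - 0.5) * tau,
                 x_centers = (seq_len(nrow(post)) - 0.5) / nrow(post),
                 event = list(start = 0, end = ncol(post) * tau)),
            class = "posterior_matrix")
}

# Point-mass posterior marching along given bins.
marching_posterior <- function(bins, n_bins = 50L) {
  p <- matrix(0, n_bins, length(bins))
  p[cbind(bins, seq_along(bins))] <- 1
  make_posterior(p)
}

# Fiducial ensemble shared by the acceptance tests: 10 networks at the
# fiducial parameter point, 120 s sleep each (the event count the headline
# ensemble statistics are defined over).
fiducial_ensemble <- function() {
  cached("fiducial_ensemble", {
    run_fiducial(ppn_config(seed = 1), n_networks = 10L, keep_spikes = TRUE)
  })
}

# Reduced parameter grid at three connection probabilities for the
# small-world correlation analysis.
swi_grid <- function() {
  cached("swi_grid", {
    run_grid(ppn_config(seed = 1), nc_values = c(8L, 15L),
             mu_values = c(1.25, 2), pc_values = c(0.04, 0.08, 0.12),
             n_networks = 3L, sleep_s = 60)
  })
}

# Two-network, two-environment remapping bundle.
remap_bundle <- function() {
  cached("remap_bundle", {
    run_multi_environment(ppn_config(seed = 1), n_networks = 2L)
  })
}

# Active-cluster counts per decoded event of the fiducial ensemble.
fiducial_active_counts <- function() {
  cached("fiducial_active_counts", {
    ens <- fiducial_ensemble()
    cfg <- ppn_config(seed = 1)
    unlist(lapply(ens$networks, function(b) {
      if (is.null(b$preplay) || nrow(b$preplay$stats) == 0) return(integer())
      vapply(seq_len(nrow(b$preplay$stats)), function(e)
        active_clusters(b$sleep, b$preplay$stats[e, ],
                        b$network$members, cfg)$n_active, integer(1))
    }))
  })
}

# Literal triple-enumeration oracle for the directed (total) clustering
# coefficient: multiplicity-weighted triangles over possible triplets.
brute_clustering <- function(a, type = "global") {
  a <- (a != 0) * 1; diag(a) <- 0
  n <- nrow(a)
  tri <- numeric(n); poss <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i) next
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        mi_j <- a[i, j] + a[j, i]
        mi_k <- a[i, k] + a[k, i]
        tri[i] <- tri[i] + mi_j * mi_k * (a[j, k] + a[k, j]) / 2
        poss[i] <- poss[i] + mi_j * mi_k
      }
    }
  }
  if (type == "global") sum(tri) / sum(poss)
  else mean((tri / poss)[poss > 0])
}

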