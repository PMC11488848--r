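#' Build, simulate and analyze one network realization
#'
#' Runs the full single-network pipeline: network construction, run
#' sessions for every environment and direction, place-field maps and
#' statistics, a sleep session with population-burst detection, Bayesian
#' decoding of decodable events against the designated trajectory (or all
#' trajectories), and the small-world summary of the E-to-E graph.
#'
#' @param config a [ppn_config()]; the master seed identifies the
#'   network.
#' @param n_env number of environments to simulate.
#' @param sleep_s sleep duration (s); defaults to the configuration.
#' @param decode_env,decode_direction designated decoding trajectory for
#'   the headline statistics.
#' @param all_trajectories decode every environment x direction.
#' @param keep_spikes retain the raw spike records in the result.
#' @return class `network_analysis`: `network`, `maps` and `stats`
#'   (nested `[[env]][[direction]]`), `sleep` (optional), `trace_summary`,
#'   `pbes`, `preplay` (a `preplay_events`, or a list per trajectory),
#'   `graph`.
#' @export
analyze_network <- function(config, n_env = 1L, sleep_s = NULL,
                            decode_env = 1L, decode_direction = "left",
                            all_trajectories = FALSE, keep_spikes = FALSE) {
  net <- build_network(config, n_env = n_env)
  directions <- c("right", "left")
  maps <- list(); stats_out <- list()
  for (e in seq_len(n_env)) {
    maps[[e]] <- list(); stats_out[[e]] <- list()
    for (d in directions) {
      rec <- simulate_session(net, "run", env = e, direction = d)
      maps[[e]][[d]] <- compute_rate_map(rec, config)
      stats_out[[e]][[d]] <- place_field_stats(maps[[e]][[d]], config)
    }
  }
  sleep <- simulate_session(net, "sleep", duration_s = sleep_s)
  trace <- population_rate(sleep, config)
  pbes <- detect_pbes(trace, sleep, config)
  decode_one <- function(e, d)
    decode_events(sleep, pbes, maps[[e]][[d]], config,
                  seed = substream_seed(config$seed, "shuffles", e, d))
  preplay <- if (all_trajectories) {
    out <- list()
    for (e in seq_len(n_env))
      for (d in directions)
        out[[paste0("env", e, "_", d)]] <- decode_one(e, d)
    out
  } else if (sum(pbes$decodable) > 0) {
    decode_one(decode_env, decode_direction)
  } else {
    NULL
  }
  structure(list(network = net, maps = maps, stats = stats_out,
                 sleep = if (keep_spikes) sleep else NULL,
                 trace_summary = list(mean = trace$mean, sd = trace$sd),
                 pbes = pbes, preplay = preplay,
                 graph = graph_summary(net),
                 decode_env = decode_env,
                 decode_direction = decode_direction),
            class = "network_analysis")
}

# Per-network configs for an ensemble: one distinct sub-seed each.
ensemble_configs <- function(config, n_networks) {
  lapply(seq_len(n_networks), function(i) {
    cfg <- config
    cfg$seed <- substream_seed(config$seed, "network", i)
    cfg
  })
}

#' Fiducial-style ensemble run
#'
#' Simulates `n_networks` independent network realizations at one
#' parameter set, pools all decoded events, and evaluates ensemble
#' preplay significance (KS test against pooled shuffles, median shift,
#' threshold-grid bootstrap, per-event p-values).
#'
#' @param config a [ppn_config()].
#' @param n_networks networks to simulate.
#' @param sleep_s sleep duration per network (s).
#' @param keep_spikes retain sleep spike records per network.
#' @return class `ensemble_result`: `networks` (list of
#'   `network_analysis`), `events` (combined `preplay_events`),
#'   `significance` (a `preplay_significance`), `per_network`
#'   (data.frame: `swi`, `median_shift`, `n_events`).
#' @export
run_fiducial <- function(config, n_networks = 5L, sleep_s = NULL,
                         keep_spikes = FALSE) {
  cfgs <- ensemble_configs(config, n_networks)
  nets <- lapply(cfgs, analyze_network, sleep_s = sleep_s,
                 keep_spikes = keep_spikes)
  has_events <- vapply(nets, function(b) !is.null(b$preplay) &&
                         nrow(b$preplay$stats) > 0, logical(1))
  events <- combine_preplay_events(lapply(nets[has_events], `[[`, "preplay"))
  sig <- if (nrow(events$stats) > 0) preplay_significance(events, config)
         else NULL
  per_network <- data.frame(
    network = seq_len(n_networks),
    swi = vapply(nets, function(b) b$graph$swi, numeric(1)),
    median_shift = vapply(nets, function(b) {
      if (is.null(b$preplay) || nrow(b$preplay$stats) == 0) return(NA_real_)
      stats::median(abs(b$preplay$stats$r)) -
        stats::median(abs(b$preplay$shuffle_r))
    }, numeric(1)),
    n_events = vapply(nets, function(b)
      if (is.null(b$preplay)) 0L else nrow(b$preplay$stats), integer(1)))
  structure(list(networks = nets, events = events, significance = sig,
                 per_network = per_network, config = config),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("Ensemble of %d networks: %d decoded events\n",
              nrow(x$per_network), nrow(x$events$stats)))
  if (!is.null(x$significance)) print(x$significance)
  invisible(x)
}

#' Parameter-grid sweep
#'
#' Sweeps the (number of clusters) x (cluster participation) grid at one
#' or more global E-to-E connection probabilities, rescaling the E-to-E
#' conductance step inversely with `pc` so total recurrent drive stays
#' constant. Infeasible grid points (within-cluster probability above 1
#' or participation above the cluster count) are skipped and reported.
#'
#' @param config base [ppn_config()].
#' @param nc_values,mu_values,pc_values grid axes.
#' @param n_networks networks per grid point.
#' @param sleep_s sleep duration per network (s).
#' @return class `grid_result`: `points` (one row per grid point:
#'   parameters, feasibility, event counts, KS statistic and p, median
#'   shift, mean SWI, mean place-field statistics, mean active-cluster
#'   count) and `per_network` (per-network SWI and median shift, for
#'   rank-correlation analyses).
#' @export
run_grid <- function(config, nc_values = c(8L, 15L, 30L),
                     mu_values = c(1.1, 1.25, 2),
                     pc_values = 0.08,
                     n_networks = 3L, sleep_s = 60) {
  w_ee_base <- config$network$w_ee
  pc_base <- config$network$p_ee
  rows <- list(); pernet <- list()
  for (pc in pc_values) for (nc in nc_values) for (mu in mu_values) {
    cfg <- tryCatch(
      modify_config(config, list(network.n_clusters = nc,
                                 network.cluster_participation = mu,
                                 network.p_ee = pc,
                                 network.w_ee = w_ee_base * pc_base / pc)),
      error = function(e) NULL)
    feasible <- !is.null(cfg) && config_feasible(cfg)
    if (!feasible) {
      rows[[length(rows) + 1L]] <- data.frame(
        pc = pc, n_clusters = nc, participation = mu, feasible = FALSE,
        n_events = NA, ks_statistic = NA, ks_p = NA, median_shift = NA,
        swi = NA, peak_rate = NA, spatial_info = NA, specificity = NA,
        kl_divergence = NA, mean_active_clusters = NA)
      next
    }
    ens <- run_fiducial(cfg, n_networks = n_networks, sleep_s = sleep_s,
                        keep_spikes = TRUE)
    sig <- ens$significance
    pf <- lapply(ens$networks, function(b) b$stats[[1L]][["left"]])
    mean_stat <- function(field) mean(unlist(lapply(pf, function(s)
      s[[field]][s$place_cell])), na.rm = TRUE)
    n_active <- unlist(lapply(ens$networks, function(b) {
      if (is.null(b$preplay) || nrow(b$preplay$stats) == 0) return(numeric())
      vapply(seq_len(nrow(b$preplay$stats)), function(e)
        active_clusters(b$sleep, b$preplay$stats[e, ],
                        b$network$members, cfg)$n_active, integer(1))
    }))
    rows[[length(rows) + 1L]] <- data.frame(
      pc = pc, n_clusters = nc, participation = mu, feasible = TRUE,
      n_events = nrow(ens$events$stats),
      ks_statistic = if (is.null(sig)) NA else sig$ks_statistic,
      ks_p = if (is.null(sig)) NA else sig$ks_p,
      median_shift = if (is.null(sig)) NA else sig$median_shift,
      swi = mean(ens$per_network$swi),
      peak_rate = mean_stat("peak_rate"),
      spatial_info = mean_stat("spatial_information"),
      specificity = mean_stat("specificity"),
      kl_divergence = mean(vapply(pf, `[[`, numeric(1), "kl_divergence")),
      mean_active_clusters = if (length(n_active)) mean(n_active) else NA)
    pn <- ens$per_network
    pn$pc <- pc; pn$n_clusters <- nc; pn$participation <- mu
    pernet[[length(pernet) + 1L]] <- pn
  }
  structure(list(points = do.call(rbind, rows),
                 per_network = do.call(rbind, pernet)),
            class = "grid_result")
}

#' Rank correlation between small-world index and preplay quality
#'
#' Spearman correlation between per-network SWI and the per-network
#' median shift in absolute weighted correlation over shuffles, computed
#' within each connection probability of a [run_grid()] result.
#'
#' @param grid a `grid_result`.
#' @return data.frame with one row per `pc`: `rho`, `p_value`, `n`.
#' @export
swi_preplay_correlation <- function(grid) {
  pn <- grid$per_network
  pn <- pn[!is.na(pn$median_shift) & !is.na(pn$swi), , drop = FALSE]
  do.call(rbind, lapply(split(pn, pn$pc), function(d) {
    ct <- suppressWarnings(stats::cor.test(d$swi, d$median_shift,
                                           method = "spearman"))
    data.frame(pc = d$pc[1L], rho = unname(ct$estimate),
               p_value = ct$p.value, n = nrow(d))
  }))
}

#' Multi-environment remapping protocol
#'
#' Simulates each network in two environments (distinct cluster-rank
#' permutations and context weights), computes the four place-field maps
#' (2 environments x 2 directions) and their pairwise map correlations,
#' and decodes the same sleep events with each of the four maps.
#'
#' @param config a [ppn_config()].
#' @param n_networks networks to simulate.
#' @param sleep_s sleep duration per network (s).
#' @return class `remap_result`: `within_corr` and `across_corr` (map
#'   correlations pooled over networks), `events_by_traj` (combined
#'   `preplay_events` per trajectory), `significance_by_traj`.
#' @export
run_multi_environment <- function(config, n_networks = 2L, sleep_s = NULL) {
  cfgs <- ensemble_configs(config, n_networks)
  nets <- lapply(cfgs, analyze_network, n_env = 2L, sleep_s = sleep_s,
                 all_trajectories = TRUE)
  within <- c(); across <- c()
  for (b in nets) {
    within <- c(within,
                map_correlation(b$maps[[1]][["left"]], b$maps[[1]][["right"]]),
                map_correlation(b$maps[[2]][["left"]], b$maps[[2]][["right"]]))
    for (d1 in c("left", "right")) for (d2 in c("left", "right"))
      across <- c(across,
                  map_correlation(b$maps[[1]][[d1]], b$maps[[2]][[d2]]))
  }
  trajs <- names(nets[[1L]]$preplay)
  events_by_traj <- lapply(trajs, function(tr)
    combine_preplay_events(lapply(nets, function(b) b$preplay[[tr]])))
  names(events_by_traj) <- trajs
  significance_by_traj <- lapply(events_by_traj, function(ev)
    if (nrow(ev$stats) > 0) preplay_significance(ev, config) else NULL)
  structure(list(within_corr = within, across_corr = across,
                 events_by_traj = events_by_traj,
                 significance_by_traj = significance_by_traj,
                 networks = nets),
            class = "remap_result")
}

#' @export
print.remap_result <- function(x, ...) {
  cat(sprintf("Remapping: within-environment map correlation %.3f, across %.3f (%d / %d pairs)\n",
              mean(x$within_corr), mean(x$across_corr),
              length(x$within_corr), length(x$across_corr)))
  for (tr in names(x$significance_by_traj)) {
    s <- x$significance_by_traj[[tr]]
    if (!is.null(s))
      cat(sprintf("  %s: KS %.3f (p = %.2g), median shift %+.3f\n",
                  tr, s$ks_statistic, s$ks_p, s$median_shift))
  }
  invisible(x)
}

#' Place versus time coding comparison
#'
#' Simulates extra traversals at twice the base speed, pools both speed
#' conditions, and contrasts each place cell's spatial information (50
#' spatial bins) with its temporal information (fifty 40 ms bins over the
#' first two seconds of each traversal).
#'
#' @param config a [ppn_config()].
#' @param env environment index.
#' @param direction trajectory direction.
#' @return list with per-cell `place_info` and `time_info` (place cells
#'   only) and their means.
#' @export
place_vs_time <- function(config, env = 1L, direction = "left") {
  net <- build_network(config, n_env = env)
  rec1 <- simulate_session(net, "run", env = env, direction = direction,
                           speed = 1, label = "pvt1")
  rec2 <- simulate_session(net, "run", env = env, direction = direction,
                           speed = 2, label = "pvt2")
  pmap <- compute_rate_map(list(rec1, rec2), config)
  tmap <- compute_time_fields(list(rec1, rec2), config)
  mask <- apply(pmap$rates, 1L, max) > config$analysis$place_peak_hz &
    rowSums(tmap$raw) > 0
  p_info <- vapply(which(mask), function(i)
    spatial_information(pmap$rates[i, ], pmap$occupancy), numeric(1))
  t_info <- vapply(which(mask), function(i)
    spatial_information(tmap$rates[i, ], tmap$occupancy), numeric(1))
  list(place_info = p_info, time_info = t_info,
       mean_place = mean(p_info), mean_time = mean(t_info),
       n_cells = sum(mask))
}
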