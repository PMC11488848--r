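#' Smoothed per-cluster firing-rate curves over an event window
#'
#' Mean firing rate of each cluster's member cells on a fine time grid
#' within the event, smoothed with a Gaussian kernel (15 ms SD). Cells in
#' multiple clusters contribute to every curve they belong to.
#'
#' @param record sleep `spike_record`.
#' @param event list or row with `start`, `end` (s).
#' @param members a [assign_clusters()] result.
#' @param config a [ppn_config()].
#' @param grid_dt_ms time grid step within the window.
#' @return list with `time` (s) and `rate` (clusters x time, Hz per
#'   member cell).
#' @export
cluster_rate_curves <- function(record, event, members, config,
                                grid_dt_ms = 1) {
  sd_ms <- config$analysis$cluster_kernel_ms
  pad_s <- 4 * sd_ms / 1000
  t0 <- event$start - pad_s
  t1 <- event$end + pad_s
  dt_s <- grid_dt_ms / 1000
  n_steps <- max(1L, as.integer(ceiling((t1 - t0) / dt_s)))
  m <- members$membership
  nc <- ncol(m)
  sp <- record$spikes[record$spikes$neuron <= nrow(m) &
                        record$spikes$time >= t0 &
                        record$spikes$time <= t1, , drop = FALSE]
  idx <- pmin(pmax(ceiling((sp$time - t0) / dt_s), 1L), n_steps)
  sd_steps <- sd_ms / grid_dt_ms
  half <- ceiling(4 * sd_steps)
  kern <- exp(-(seq(-half, half))^2 / (2 * sd_steps^2))
  kern <- kern / sum(kern)
  rate <- matrix(0, nc, n_steps)
  for (k in seq_len(nc)) {
    cells <- which(m[, k])
    counts <- tabulate(idx[sp$neuron %in% cells], nbins = n_steps)
    r <- counts / (length(cells) * dt_s)
    smoothed <- stats::convolve(r, rev(kern), type = "open")
    rate[k, ] <- pmax(smoothed[(half + 1):(half + n_steps)], 0)
  }
  times <- t0 + (seq_len(n_steps) - 0.5) * dt_s
  inside <- times >= event$start & times <= event$end
  list(time = times[inside], rate = rate[, inside, drop = FALSE],
       dt = dt_s)
}

#' Active clusters of one population burst event
#'
#' A cluster is active if at any instant within the event its population
#' rate exceeds twice that of every other cluster. The sequence is
#' ordered by the first time each active cluster becomes the most active
#' one, and each activation duration is the total time that cluster
#' remains the most active.
#'
#' @inheritParams cluster_rate_curves
#' @param curves optionally a precomputed [cluster_rate_curves()] result.
#' @return class `active_cluster_sequence`: `clusters` (ordered ids,
#'   possibly empty), `durations` (s), `n_active`.
#' @export
active_clusters <- function(record, event, members, config, curves = NULL) {
  if (is.null(curves))
    curves <- cluster_rate_curves(record, event, members, config)
  r <- curves$rate
  nc <- nrow(r)
  if (ncol(r) == 0L)
    return(structure(list(clusters = integer(), durations = numeric(),
                          n_active = 0L), class = "active_cluster_sequence"))
  n_t <- ncol(r)
  max1 <- apply(r, 2L, max)
  arg1 <- apply(r, 2L, which.max)
  max2 <- vapply(seq_len(n_t), function(t)
    if (nc > 1) max(r[-arg1[t], t]) else 0, numeric(1))
  active <- vapply(seq_len(nc), function(k) {
    other <- ifelse(arg1 == k, max2, max1)
    any(r[k, ] > 2 * other)
  }, logical(1))
  if (!any(active))
    return(structure(list(clusters = integer(), durations = numeric(),
                          n_active = 0L), class = "active_cluster_sequence"))
  winner <- apply(r, 2L, which.max)
  ids <- which(active)
  first_win <- vapply(ids, function(k) {
    w <- which(winner == k)
    if (length(w)) w[1L] else NA_integer_
  }, integer(1))
  ord <- order(first_win)
  ids <- ids[ord]
  durations <- vapply(ids, function(k) sum(winner == k) * curves$dt,
                      numeric(1))
  structure(list(clusters = ids, durations = durations,
                 n_active = length(ids)),
            class = "active_cluster_sequence")
}

#' @export
print.active_cluster_sequence <- function(x, ...) {
  cat(sprintf("Active clusters: %s (durations %s ms)\n",
              paste(x$clusters, collapse = " -> "),
              paste(round(1000 * x$durations), collapse = ", ")))
  invisible(x)
}

#' Does the cluster-activation order match the track order?
#'
#' Among events with exactly three active clusters, the fraction whose
#' activation sequence is monotone in the clusters' track rank bias (in
#' either direction) is compared with the distribution expected from
#' randomly sampling sequences of three distinct clusters without
#' replacement (null probability of a monotone triple: 1/3).
#'
#' @param sequences list of `active_cluster_sequence` objects (only those
#'   with `n_active == 3` are used).
#' @param cluster_bias per-cluster rank bias values (an
#'   [environment_spec()]'s `cluster_bias`).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return list with `fraction`, `n_events`, `null_fraction` (1/3), and
#'   bootstrap `p_value` (probability of a null fraction at least as
#'   large).
#' @export
sequence_match_test <- function(sequences, cluster_bias, n_boot = 2000L,
                                seed = NULL) {
  trips <- Filter(function(s) s$n_active == 3L, sequences)
  if (length(trips) == 0L) stop("no events with exactly three active clusters")
  monotone <- function(b) all(diff(b) > 0) || all(diff(b) < 0)
  obs <- vapply(trips, function(s) monotone(cluster_bias[s$clusters]),
                logical(1))
  frac <- mean(obs)
  nc <- length(cluster_bias)
  n_ev <- length(trips)
  boot <- function() {
    vapply(seq_len(n_boot), function(b)
      mean(vapply(seq_len(n_ev), function(e)
        monotone(cluster_bias[sample.int(nc, 3L)]), logical(1))),
      numeric(1))
  }
  null_frac <- if (is.null(seed)) boot() else with_stream(seed, boot())
  list(fraction = frac, n_events = n_ev, null_fraction = 1 / 3,
       p_value = mean(null_frac >= frac))
}

#' Preplay quality versus number of active clusters
#'
#' Z-scores each event's absolute weighted correlation against the pooled
#' shuffle correlations of all events with the same active-cluster count,
#' then computes Spearman's rank correlation between the count and the
#' z-score.
#'
#' @param events a `preplay_events` object.
#' @param n_active integer vector of active-cluster counts, one per
#'   decoded event (rows of `events$stats`).
#' @return list with `rho`, `p_value`, `n_events`, and the per-event
#'   z-scores.
#' @export
active_cluster_count_correlation <- function(events, n_active) {
  st <- events$stats
  stopifnot(length(n_active) == nrow(st))
  if (length(unique(n_active)) < 2L)
    stop("active-cluster count is constant; correlation undefined")
  z <- rep(NA_real_, nrow(st))
  for (cnt in unique(n_active)) {
    rows <- which(n_active == cnt)
    pool <- abs(events$shuffle_r[rows, , drop = FALSE])
    mu <- mean(pool); sdev <- stats::sd(as.numeric(pool))
    if (is.na(sdev) || sdev == 0) next
    z[rows] <- (abs(st$r[rows]) - mu) / sdev
  }
  ok <- !is.na(z)
  ct <- suppressWarnings(stats::cor.test(n_active[ok], z[ok],
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_events = sum(ok), z = z)
}

#' Cell-identity shuffles
#'
#' Permutations of excitatory cell identity used as decoding controls:
#' `"across"` permutes all E cells uniformly; `"within_cluster"` composes
#' many random transpositions of cells that share membership in at least
#' one cluster; `"within_single_cluster"` permutes only cells belonging
#' to exactly one cluster, within that cluster (multi-cluster cells are
#' fixed points).
#'
#' @param members a [assign_clusters()] result.
#' @param mode shuffle mode.
#' @param seed integer seed.
#' @param n_swaps transposition count for the within-cluster mode
#'   (default `10 nE`).
#' @return integer permutation `perm` of `1..nE`: the cell recorded as
#'   `i` is relabeled `perm[i]`.
#' @export
shuffle_identities <- function(members,
                               mode = c("across", "within_cluster",
                                        "within_single_cluster"),
                               seed = NULL, n_swaps = NULL) {
  mode <- match.arg(mode)
  m <- members$membership
  n_e <- nrow(m)
  body <- function() {
    perm <- seq_len(n_e)
    if (mode == "across") {
      perm <- sample.int(n_e)
    } else if (mode == "within_cluster") {
      share <- tcrossprod(m * 1L) > 0
      diag(share) <- TRUE
      partners <- lapply(seq_len(n_e), function(i) which(share[i, ]))
      if (is.null(n_swaps)) n_swaps <- 10L * n_e
      # random transpositions accepted only while every cell keeps an
      # identity it shares a cluster with, so labels cannot migrate
      # across the membership graph
      for (s in seq_len(n_swaps)) {
        i <- sample.int(n_e, 1L)
        js <- partners[[i]]
        j <- js[sample.int(length(js), 1L)]
        if (i == j) next
        if (share[j, perm[i]] && share[i, perm[j]]) {
          tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
        }
      }
    } else {
      single <- rowSums(m) == 1L
      for (k in seq_len(ncol(m))) {
        cells <- which(m[, k] & single)
        if (length(cells) > 1L) perm[cells] <- cells[sample.int(length(cells))]
      }
    }
    perm
  }
  if (is.null(seed)) body() else with_stream(seed, body())
}

#' Relabel excitatory cells of a spike record
#'
#' @param record a `spike_record`.
#' @param perm permutation from [shuffle_identities()].
#' @return the record with excitatory spike ids mapped through `perm`.
#' @export
apply_identity_shuffle <- function(record, perm) {
  e <- record$spikes$neuron <= length(perm)
  record$spikes$neuron[e] <- perm[record$spikes$neuron[e]]
  ord <- order(record$spikes$time, record$spikes$neuron)
  record$spikes <- record$spikes[ord, , drop = FALSE]
  rownames(record$spikes) <- NULL
  record
}

#' Mean relative spike rank versus place-field location
#'
#' For each decoded event, participating excitatory cells are ranked by
#' their mean spike time within the event and the rank is normalized to
#' `[0, 1]`. With direction correction, ranks are inverted in events
#' whose decoded trajectory slopes negatively (sign of the weighted
#' correlation), so forward and reverse sequences align. Each cell's
#' ranks are averaged over events and regressed against the cell's mean
#' place-field density location (the center of mass of its smoothed
#' field, as a track fraction); under the `"cluster"` scope a cell is
#' ranked only among co-participating cells that share at least one of
#' its clusters.
#'
#' @param record sleep `spike_record` (optionally identity-shuffled).
#' @param events a `preplay_events` for that record (event windows and
#'   decoded slopes).
#' @param members a [assign_clusters()] result.
#' @param map the trajectory `place_field_map` providing field locations.
#' @param config a [ppn_config()].
#' @param scope `"network"` or `"cluster"`.
#' @param direction_correct invert ranks in negative-slope events.
#' @param rank_stat per-event rank key: `"mean"` (default) or
#'   `"median"` spike time.
#' @return class `rank_analysis`: per-cell data.frame (`cell`,
#'   `mean_rank`, `n_events`, `field_location`), regression `slope`,
#'   `intercept`, `r_squared`.
#' @export
mean_relative_rank <- function(record, events, members, map, config,
                               scope = c("network", "cluster"),
                               direction_correct = TRUE,
                               rank_stat = c("mean", "median")) {
  scope <- match.arg(scope)
  rank_stat <- match.arg(rank_stat)
  m <- members$membership
  n_e <- nrow(m)
  share <- tcrossprod(m * 1L) > 0
  diag(share) <- TRUE
  st <- events$stats
  rank_sum <- numeric(n_e)
  rank_n <- integer(n_e)
  sp_all <- record$spikes[record$spikes$neuron <= n_e, , drop = FALSE]
  key_fun <- if (rank_stat == "mean") mean else stats::median
  for (e in seq_len(nrow(st))) {
    sp <- sp_all[sp_all$time >= st$start[e] & sp_all$time <= st$end[e], ,
                 drop = FALSE]
    if (nrow(sp) == 0L) next
    key <- tapply(sp$time, sp$neuron, key_fun)
    cells <- as.integer(names(key))
    if (length(cells) < 2L) next
    invert <- direction_correct && !is.na(st$r[e]) && st$r[e] < 0
    if (scope == "network") {
      rk <- (rank(key, ties.method = "average") - 1) / (length(key) - 1)
      if (invert) rk <- 1 - rk
      rank_sum[cells] <- rank_sum[cells] + rk
      rank_n[cells] <- rank_n[cells] + 1L
    } else {
      for (ci in seq_along(cells)) {
        grp <- which(share[cells[ci], cells])
        if (length(grp) < 2L) next
        rk <- (rank(key[grp], ties.method = "average") - 1) /
          (length(grp) - 1)
        r1 <- rk[match(ci, grp)]
        if (invert) r1 <- 1 - r1
        rank_sum[cells[ci]] <- rank_sum[cells[ci]] + r1
        rank_n[cells[ci]] <- rank_n[cells[ci]] + 1L
      }
    }
  }
  x_centers <- (seq_len(ncol(map$rates)) - 0.5) / ncol(map$rates)
  com <- as.numeric(map$rates %*% x_centers) / rowSums(map$rates)
  place <- apply(map$rates, 1L, max) > config$analysis$place_peak_hz
  use <- rank_n > 0 & place
  tab <- data.frame(cell = which(use),
                    mean_rank = rank_sum[use] / rank_n[use],
                    n_events = rank_n[use],
                    field_location = com[use])
  fit <- if (nrow(tab) >= 3L)
    stats::lm(mean_rank ~ field_location, data = tab) else NULL
  structure(list(cells = tab,
                 slope = if (is.null(fit)) NA_real_ else unname(stats::coef(fit)[2L]),
                 intercept = if (is.null(fit)) NA_real_ else unname(stats::coef(fit)[1L]),
                 r_squared = if (is.null(fit)) NA_real_ else summary(fit)$r.squared,
                 scope = scope, direction_correct = direction_correct),
            class = "rank_analysis")
}

#' @export
print.rank_analysis <- function(x, ...) {
  cat(sprintf("Mean relative spike rank (%s scope%s): %d cells, regression slope %.3f (R^2 %.3f)\n",
              x$scope,
              if (x$direction_correct) ", direction-corrected" else "",
              nrow(x$cells), x$slope, x$r_squared))
  invisible(x)
}
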