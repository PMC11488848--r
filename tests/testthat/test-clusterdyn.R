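cfg <- ppn_config()

toy_members <- function(membership) {
  structure(list(membership = membership,
                 cluster_size = as.integer(colSums(membership)),
                 mean_participation = mean(rowSums(membership))),
            class = "cluster_membership")
}

# Inject hand-built cluster rate curves into the activity test.
make_curves <- function(rate, dt = 1e-3) {
  list(time = (seq_len(ncol(rate)) - 0.5) * dt, rate = rate, dt = dt)
}

test_that("cluster rate curves average member cells and conserve spike mass", {
  m <- matrix(FALSE, 4, 2); m[1:2, 1] <- TRUE; m[2:4, 2] <- TRUE
  members <- toy_members(m)
  rec <- make_spike_record(neuron = c(1, 2, 2, 3),
                           time = c(0.10, 0.11, 0.12, 0.11),
                           n = 4, n_e = 4, session = "sleep", duration = 1)
  cur <- cluster_rate_curves(rec, list(start = 0.05, end = 0.2),
                             members, cfg)
  # integral of each curve = member spikes / member count
  expect_equal(sum(cur$rate[1, ]) * cur$dt, 3 / 2, tolerance = 0.01)
  expect_equal(sum(cur$rate[2, ]) * cur$dt, 3 / 3, tolerance = 0.01)
  # cells in both clusters contribute to both curves
  expect_gt(max(cur$rate[1, ]), 0)
  expect_gt(max(cur$rate[2, ]), 0)
})

test_that("active clusters follow the 2x dominance rule in sequence", {
  m <- diag(3) > 0
  members <- toy_members(m)
  # constructed curves: A dominant 0-30 ms, B 30-80 ms
  a <- c(rep(10, 30), rep(1, 50))
  b <- c(rep(1, 30), rep(10, 50))
  c_ <- rep(0.5, 80)
  seq_ab <- active_clusters(NULL, NULL, members, cfg,
                            curves = make_curves(rbind(a, b, c_)))
  expect_equal(seq_ab$clusters, c(1L, 2L))
  expect_equal(seq_ab$durations, c(0.030, 0.050), tolerance = 1e-9)
  expect_equal(seq_ab$n_active, 2L)

  # two identical curves: neither exceeds twice the other
  same <- rbind(c_, c_, rep(0.01, 80))
  seq0 <- active_clusters(NULL, NULL, members, cfg,
                          curves = make_curves(same))
  expect_equal(seq0$n_active, 0L)

  # only one cluster's members spike
  solo <- rbind(rep(4, 80), rep(0, 80), rep(0, 80))
  seq1 <- active_clusters(NULL, NULL, members, cfg,
                          curves = make_curves(solo))
  expect_equal(seq1$clusters, 1L)
  expect_equal(seq1$durations, 0.080, tolerance = 1e-9)
})

test_that("three-cluster sequences are tested against the sampling null", {
  bias <- seq(-1, 1, length.out = 10)
  mk_seq <- function(cl) structure(list(clusters = cl, durations = rep(0.02, 3),
                                        n_active = 3L),
                                   class = "active_cluster_sequence")
  # all monotone: fraction 1, p near 0
  mono <- lapply(1:30, function(i) mk_seq(c(1L, 5L, 9L)))
  res <- sequence_match_test(mono, bias, n_boot = 500, seed = 2)
  expect_equal(res$fraction, 1)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$null_fraction, 1 / 3)

  # sequences at exactly the null fraction 1/3: p is central
  third <- lapply(1:120, function(i)
    if (i <= 40) mk_seq(c(1L, 5L, 9L)) else mk_seq(c(1L, 9L, 5L)))
  res2 <- sequence_match_test(third, bias, n_boot = 500, seed = 3)
  expect_equal(res2$fraction, 1 / 3)
  expect_gt(res2$p_value, 0.2); expect_lt(res2$p_value, 0.8)

  # non-monotone-only events: fraction 0
  flat <- lapply(1:10, function(i) mk_seq(c(1L, 9L, 5L)))
  expect_equal(sequence_match_test(flat, bias, n_boot = 100,
                                   seed = 4)$fraction, 0)
})

test_that("the count correlation z-scores against count-matched shuffles", {
  # synthetic: z strictly decreasing in count -> rho = -1
  n <- 40
  counts <- rep(1:4, each = 10)
  shuffle_r <- matrix(rep(0.3, n * 20), n, 20)
  r <- 0.3 + (5 - counts) * 0.1   # higher |r| for fewer clusters
  ev <- structure(list(stats = data.frame(r = r, jd = runif(n)),
                       shuffle_r = shuffle_r + matrix(rnorm(n * 20, 0, 0.02), n, 20)),
                  class = "preplay_events")
  set.seed(8)
  res <- active_cluster_count_correlation(ev, counts)
  expect_lt(res$rho, -0.9)

  # shuffled pairing decorrelates
  ev2 <- ev
  ev2$stats$r <- sample(ev$stats$r)
  res2 <- active_cluster_count_correlation(ev2, counts)
  expect_lt(abs(res2$rho), 0.5)
  expect_error(active_cluster_count_correlation(ev, rep(2L, n)), "constant")
})

test_that("identity shuffles respect their membership constraints", {
  cfg4 <- ppn_config(seed = 17, network.n = 120, network.n_clusters = 5,
                     network.cluster_participation = 1.4)
  members <- assign_clusters(cfg4)
  m <- members$membership
  share <- tcrossprod(m * 1L) > 0; diag(share) <- TRUE
  n_e <- nrow(m)

  perm_a <- shuffle_identities(members, "across", seed = 1)
  expect_equal(sort(perm_a), seq_len(n_e))
  expect_gt(sum(perm_a != seq_len(n_e)), n_e * 0.9)

  perm_w <- shuffle_identities(members, "within_cluster", seed = 2)
  expect_equal(sort(perm_w), seq_len(n_e))
  # every relabeled cell keeps an identity sharing a cluster with it
  expect_true(all(share[cbind(seq_len(n_e), perm_w)]))
  expect_gt(sum(perm_w != seq_len(n_e)), n_e * 0.5)

  perm_s <- shuffle_identities(members, "within_single_cluster", seed = 3)
  expect_equal(sort(perm_s), seq_len(n_e))
  multi <- rowSums(m) > 1
  expect_true(all(perm_s[multi] == which(multi)))
  single <- !multi
  same_cluster <- vapply(which(single), function(i)
    any(m[i, ] & m[perm_s[i], ]), logical(1))
  expect_true(all(same_cluster))

  # the identity permutation leaves a record untouched
  rec <- make_spike_record(neuron = sample.int(n_e, 50, TRUE),
                           time = sort(runif(50, 0, 2)), n = 160,
                           n_e = n_e, session = "sleep", duration = 2)
  expect_identical(apply_identity_shuffle(rec, seq_len(n_e))$spikes,
                   rec$spikes)
})

test_that("mean relative rank matches hand enumeration on a toy ensemble", {
  m <- matrix(TRUE, 3, 1)
  members <- toy_members(m)
  rates <- rbind(c(rep(8, 10), rep(0.1, 40)),
                 c(rep(0.1, 20), rep(8, 10), rep(0.1, 20)),
                 c(rep(0.1, 40), rep(8, 10)))
  map <- structure(list(rates = rates, raw = rates,
                        occupancy = rep(1 / 50, 50), env = 1,
                        direction = "left"),
                   class = "place_field_map")
  # event 1 (slope +): order 1,2,3; event 2 (slope -): order 1,3,2
  rec <- make_spike_record(neuron = c(1, 2, 3, 1, 3, 2),
                           time = c(0.10, 0.12, 0.14, 0.50, 0.52, 0.54),
                           n = 3, n_e = 3, session = "sleep", duration = 1)
  ev <- structure(list(stats = data.frame(event = 1:2,
                                          start = c(0.09, 0.49),
                                          end = c(0.15, 0.55),
                                          n_t = c(6L, 6L),
                                          r = c(0.9, -0.9),
                                          jd = c(0.1, 0.1),
                                          entropy = c(1, 1),
                                          p_value = c(0, 0))),
                  class = "preplay_events")
  ra <- mean_relative_rank(rec, ev, members, map, cfg, scope = "network",
                           direction_correct = TRUE)
  # event 1 ranks: 0, 1/2, 1; event 2 ranks 0, 1, 1/2 inverted -> 1, 0, 1/2
  expect_equal(ra$cells$mean_rank[ra$cells$cell == 1], mean(c(0, 1)))
  expect_equal(ra$cells$mean_rank[ra$cells$cell == 2], mean(c(0.5, 0)))
  expect_equal(ra$cells$mean_rank[ra$cells$cell == 3], mean(c(1, 0.5)))
  ra2 <- mean_relative_rank(rec, ev, members, map, cfg,
                            direction_correct = FALSE)
  expect_equal(ra2$cells$mean_rank, c(0, 0.75, 0.75))
})

test_that("direction-corrected rank correlates with field location in simulation", {
  ens <- fiducial_ensemble()
  b <- ens$networks[[1]]
  map <- b$maps[[1]][["left"]]
  ra_corr <- mean_relative_rank(b$sleep, b$preplay, b$network$members,
                                map, ppn_config(seed = 1),
                                scope = "network", direction_correct = TRUE)
  ra_raw <- mean_relative_rank(b$sleep, b$preplay, b$network$members,
                               map, ppn_config(seed = 1),
                               scope = "network", direction_correct = FALSE)
  expect_gt(ra_corr$slope, 0.2)
  expect_lt(abs(ra_raw$slope), 0.15)
  # shuffling identities across the network abolishes the correlation
  perm <- shuffle_identities(b$network$members, "across", seed = 44)
  ra_sh <- mean_relative_rank(apply_identity_shuffle(b$sleep, perm),
                              b$preplay, b$network$members, map,
                              ppn_config(seed = 1))
  expect_lt(abs(ra_sh$slope), ra_corr$slope / 2)
  # cluster-scope correlation is positive as well
  ra_cl <- mean_relative_rank(b$sleep, b$preplay, b$network$members,
                              map, ppn_config(seed = 1), scope = "cluster")
  expect_gt(ra_cl$slope, 0.05)
})
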