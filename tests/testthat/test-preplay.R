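test_that("time-bin shuffles are uniform permutations with exact statistics", {
  # T = 2: each shuffle is identity or swap, about half each
  post <- marching_posterior(c(10, 40))
  sh <- shuffle_event(post, n = 400, seed = 1)
  expect_equal(nrow(sh), 400L)
  expect_true(all(abs(abs(sh$r) - 1) < 1e-9))
  frac_swap <- mean(sh$r < 0) # swapped order reverses the slope
  expect_gt(frac_swap, 0.4); expect_lt(frac_swap, 0.6)

  # a time-independent posterior shuffles to r = 0 always
  flat <- make_posterior(matrix(rexp(50), 50, 5))
  sh2 <- shuffle_event(flat, n = 50, seed = 2)
  expect_equal(sh2$r, rep(0, 50))

  # T = 3 diagonal point mass: shuffle statistics live on the exact
  # 6-permutation support computed by brute force
  post3 <- marching_posterior(c(10, 25, 40))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  exact <- vapply(perms, function(p) {
    reordered <- post3$post[, p, drop = FALSE]
    weighted_correlation(make_posterior(reordered))
  }, numeric(1))
  sh3 <- shuffle_event(post3, n = 300, seed = 3)
  expect_true(all(vapply(sh3$r, function(r)
    any(abs(r - exact) < 1e-9), logical(1))))
  # each permutation appears with roughly uniform frequency
  counts <- table(vapply(sh3$r, function(r) which.min(abs(exact - r)),
                         integer(1)))
  expect_true(all(counts > 20))
})

test_that("per-event p-values count strictly better shuffles", {
  expect_equal(per_event_pvalue(0.9, seq(0, 0.8, length.out = 100)), 0)
  expect_equal(per_event_pvalue(0.1, seq(0.2, 0.9, length.out = 100)), 1)
  shuf <- c(rep(0.4, 93), rep(0.6, 7))
  expect_equal(per_event_pvalue(0.5, shuf), 0.07)
  # sign is ignored on both sides
  expect_equal(per_event_pvalue(-0.5, shuf), 0.07)
})

test_that("the ensemble KS test behaves at its limits", {
  set.seed(8)
  x <- runif(300)
  same <- ks_preplay_test(x, x)
  expect_lt(same$statistic, 1e-9)
  expect_equal(same$median_shift, 0)
  far <- ks_preplay_test(x + 5, x)
  expect_equal(far$statistic, 1)
  expect_lt(far$p_value, 1e-10)
  expect_equal(far$median_shift, 5, tolerance = 0.2)
})

test_that("the threshold grid never flags the all-pass corner and matches enumeration", {
  # three events with 2 shuffles each: exhaustive oracle over the 8
  # equally likely shuffle data sets
  ev <- list(stats = data.frame(r = c(0.9, 0.5, 0.2), jd = c(0.1, 0.3, 0.6)),
             shuffle_r = rbind(c(0.3, 0.95), c(0.1, 0.6), c(0.4, 0.1)),
             shuffle_jd = rbind(c(0.2, 0.1), c(0.5, 0.2), c(0.3, 0.8)))
  class(ev) <- "preplay_events"
  r_thr <- c(0, 0.4, 0.8); jd_thr <- c(0.2, 1)
  grid <- threshold_grid_bootstrap(ev, r_thr, jd_thr,
                                   n_datasets = 4000L, seed = 5)
  # all-pass corner: every event passes in actual and all shuffle sets
  expect_equal(grid$actual_fraction["0", "1"], 1)
  expect_equal(grid$p["0", "1"], 1)
  # exact p by enumerating all 2^3 shuffle data sets
  enum_p <- function(rmin, jdmax) {
    actual <- mean(abs(ev$stats$r) >= rmin & ev$stats$jd <= jdmax)
    combos <- expand.grid(1:2, 1:2, 1:2)
    hit <- apply(combos, 1, function(pick) {
      rs <- ev$shuffle_r[cbind(1:3, pick)]
      js <- ev$shuffle_jd[cbind(1:3, pick)]
      mean(abs(rs) >= rmin & js <= jdmax) >= actual
    })
    mean(hit)
  }
  for (ri in seq_along(r_thr)) for (ji in seq_along(jd_thr)) {
    expect_equal(grid$p[ri, ji], enum_p(r_thr[ri], jd_thr[ji]),
                 tolerance = 0.05)
  }
})

test_that("perfect events dominate mediocre shuffles at strict thresholds", {
  n_ev <- 8
  ev <- list(stats = data.frame(r = rep(1, n_ev), jd = rep(1 / 50, n_ev)),
             shuffle_r = matrix(runif(n_ev * 30, 0, 0.5), n_ev, 30),
             shuffle_jd = matrix(runif(n_ev * 30, 0.3, 1), n_ev, 30))
  class(ev) <- "preplay_events"
  grid <- threshold_grid_bootstrap(ev, r_thresholds = c(0, 0.9),
                                   jd_thresholds = c(0.1, 1),
                                   n_datasets = 200L, seed = 6)
  expect_equal(grid$p["0.9", "0.1"], 0)
  expect_equal(grid$p["0", "1"], 1)
})

test_that("per-event p-values are uniform under a permutation null", {
  # events that are themselves random permutations of a template: their
  # shuffle p-values must be uniform on the achievable grid
  set.seed(13)
  base <- marching_posterior(sample.int(50, 8))
  pvals <- vapply(1:150, function(i) {
    perm <- sample.int(8)
    ev_post <- make_posterior(base$post[, perm])
    sh <- shuffle_event(ev_post, n = 60)
    per_event_pvalue(weighted_correlation(ev_post), sh$r)
  }, numeric(1))
  expect_gt(mean(pvals), 0.40); expect_lt(mean(pvals), 0.60)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("combining preplay events preserves rows and network labels", {
  mk <- function(n, off = 0) {
    structure(list(stats = data.frame(event = 1:n, start = 1:n, end = 1:n + 0.1,
                                      n_t = rep(5L, n), r = runif(n),
                                      jd = runif(n), entropy = runif(n),
                                      p_value = runif(n)),
                   shuffle_r = matrix(runif(n * 10), n, 10),
                   shuffle_jd = matrix(runif(n * 10), n, 10),
                   n_dropped = 1L, posteriors = NULL),
              class = "preplay_events")
  }
  set.seed(3)
  comb <- combine_preplay_events(list(mk(4), mk(6)))
  expect_equal(nrow(comb$stats), 10L)
  expect_equal(comb$stats$network, rep(1:2, c(4, 6)))
  expect_equal(dim(comb$shuffle_r), c(10L, 10L))
  expect_equal(comb$n_dropped, 2L)
})
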