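cfg50 <- ppn_config()

test_that("rate maps are occupancy-discounted, trial-averaged and smoothed", {
  # 1 trial, 2 s lap, 3 spikes in one bin: pre-smoothing rate 3 / (2/50)
  rec <- make_spike_record(neuron = c(1, 1, 1),
                           time = c(0.500, 0.504, 0.508),  # x in bin 13
                           n_e = 2, duration = 2, n_laps = 1)
  map <- compute_rate_map(rec, cfg50)
  bin <- floor(0.25 * 50) + 1   # x = 0.25 at t = 0.5 s, rightward
  expect_equal(map$raw[1, bin], 3 / (2 / 50))
  expect_equal(sum(map$raw[1, ]), 3 / (2 / 50))
  expect_equal(sum(map$raw[2, ]), 0)

  # smoothing preserves a constant map exactly
  k <- preplaynet:::smoothing_matrix(50, 2)
  expect_equal(as.numeric(rep(5, 50) %*% k), rep(5, 50))

  # a single-bin impulse becomes a discrete Gaussian bump (SD 2 bins)
  imp <- numeric(50); imp[25] <- 1
  sm <- as.numeric(imp %*% k)
  expect_equal(which.max(sm), 25)
  ratio <- sm[27] / sm[25]
  expect_equal(ratio, exp(-4 / (2 * 4)), tolerance = 1e-6)

  # homogeneous Poisson cell: flat map close to its rate
  set.seed(3)
  tt <- sort(runif(2000, 0, 40))   # 5 Hz for 20 x 2 s laps... 2000/40 = 50
  rec2 <- make_spike_record(neuron = rep(1, 2000), time = tt, n_e = 1,
                            duration = 40, n_laps = 20)
  map2 <- compute_rate_map(rec2, cfg50)
  expect_lt(max(abs(map2$rates[1, ] - 50)), 10)
})

test_that("specificity follows the quarter-max bin-count definition", {
  r <- numeric(50); r[1:10] <- 10; r[11:50] <- 1   # 10 bins above 2.5
  expect_equal(specificity(r), 0.8)
  expect_equal(specificity(rep(4, 50)), 0)
  single <- numeric(50); single[7] <- 3
  expect_equal(specificity(single), 1 - 1 / 50)
  expect_equal(specificity(2 * r), specificity(r))  # scale invariance
  expect_error(specificity(numeric(50)), "all-zero")
})

test_that("spatial information reproduces the worked analytic values", {
  half <- c(rep(2, 25), rep(0, 25))
  expect_equal(spatial_information(half), 1)
  single <- numeric(50); single[13] <- 4
  expect_equal(spatial_information(single), log2(50))
  expect_equal(spatial_information(rep(3, 50)), 0)
  # bounded on arbitrary non-negative inputs
  set.seed(1)
  for (i in 1:20) {
    r <- rexp(50) * rbinom(50, 1, 0.7)
    if (sum(r) == 0) next
    si <- spatial_information(r)
    expect_gte(si, -1e-12); expect_lte(si, log2(50) + 1e-12)
  }
})

test_that("peak-distribution divergence reproduces the worked analytic values", {
  expect_equal(peak_distribution_kl(rep(1:25, each = 4), 50), 1)
  expect_equal(peak_distribution_kl(rep(1:50, 3), 50), 0)
  expect_equal(peak_distribution_kl(rep(9, 12), 50), log2(50))
  set.seed(2)
  for (i in 1:20) {
    peaks <- sample.int(50, 30, replace = TRUE)
    d <- peak_distribution_kl(peaks, 50)
    expect_gte(d, -1e-12); expect_lte(d, log2(50) + 1e-12)
  }
})

test_that("central-third fraction uses bins 17-33 of 50", {
  expect_equal(central_third_fraction(1:50), 17 / 50)
  expect_equal(central_third_fraction(c(1, 1, 50, 50)), 0)
  expect_equal(central_third_fraction(c(25, 25, 25, 2)), 0.75)
  expect_equal(central_third_fraction(c(16, 17, 33, 34)), 0.5)
})

test_that("map correlation is a mean of per-bin population-vector correlations", {
  set.seed(5)
  a <- matrix(rexp(200 * 50), 200, 50)
  expect_equal(as.numeric(map_correlation(a, a)), 1)
  # symmetric
  b <- matrix(rexp(200 * 50), 200, 50)
  expect_equal(as.numeric(map_correlation(a, b)),
               as.numeric(map_correlation(b, a)))
  # independent random maps decorrelate (Monte-Carlo null)
  expect_lt(abs(as.numeric(map_correlation(a, b))), 0.05)
  # invariant to a consistent relabeling of cells
  perm <- sample.int(200)
  expect_equal(as.numeric(map_correlation(a[perm, ], b[perm, ])),
               as.numeric(map_correlation(a, b)))
  # zero-variance bins are skipped and counted
  a2 <- a; b2 <- b
  a2[, 3] <- 1
  mc <- map_correlation(a2, b2, normalize = FALSE)
  expect_equal(attr(mc, "n_skipped"), 1L)
  # peak normalization discounts per-cell excitability: a map scaled by
  # random per-cell gains still correlates perfectly with itself
  gains <- rexp(200) + 0.1
  expect_equal(as.numeric(map_correlation(a * gains, a)), 1)
})

test_that("time fields separate place-locked from time-locked firing", {
  # spikes at fixed position x = 0.5 on every lap, for 1x and 2x speeds
  lap_times <- function(lap_s, n_laps, frac) (seq_len(n_laps) - 1 + frac) * lap_s
  r1 <- make_spike_record(neuron = rep(1, 10),
                          time = lap_times(2, 10, 0.5), n_e = 1,
                          duration = 20, n_laps = 10, lap_s = 2)
  r2 <- make_spike_record(neuron = rep(1, 10),
                          time = lap_times(1, 10, 0.5), n_e = 1,
                          duration = 10, n_laps = 10, lap_s = 1, speed = 2)
  pmap <- compute_rate_map(list(r1, r2), cfg50)
  tmap <- compute_time_fields(list(r1, r2), cfg50)
  p_info <- spatial_information(pmap$rates[1, ], pmap$occupancy)
  t_info <- spatial_information(tmap$rates[1, ], tmap$occupancy)
  expect_gt(p_info, t_info)

  # spikes at a fixed latency of 0.5 s regardless of speed: time-locked
  r3 <- make_spike_record(neuron = rep(1, 10),
                          time = lap_times(2, 10, 0.25), n_e = 1,
                          duration = 20, n_laps = 10, lap_s = 2)
  r4 <- make_spike_record(neuron = rep(1, 10),
                          time = lap_times(1, 10, 0.5), n_e = 1,
                          duration = 10, n_laps = 10, lap_s = 1, speed = 2)
  pmap2 <- compute_rate_map(list(r3, r4), cfg50)
  tmap2 <- compute_time_fields(list(r3, r4), cfg50)
  expect_gt(spatial_information(tmap2$rates[1, ], tmap2$occupancy),
            spatial_information(pmap2$rates[1, ], pmap2$occupancy))
})

test_that("place-field statistics apply the 3 Hz place-cell threshold", {
  rates <- rbind(c(rep(0, 24), 10, rep(0, 25)),  # sharp cell, peak bin 25
                 rep(2, 50),                      # below threshold
                 c(rep(5, 10), rep(0.1, 40)))     # broad cell, peak bin 1
  map <- structure(list(rates = rates, raw = rates,
                        occupancy = rep(1 / 50, 50),
                        env = 1, direction = "right"),
                   class = "place_field_map")
  st <- place_field_stats(map, cfg50)
  expect_equal(st$place_cell, c(TRUE, FALSE, TRUE))
  expect_equal(st$n_place_cells, 2L)
  expect_true(is.na(st$spatial_information[2]))
  expect_equal(st$peak_bin[1], 25L)
  expect_equal(st$central_third, 0.5)   # peaks 25 and 1
})
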