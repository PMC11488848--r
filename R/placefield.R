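#' Gaussian spatial smoothing matrix
#'
#' Kernel matrix for smoothing binned rate maps: column `j` holds the
#' truncated, renormalized Gaussian centered on bin `j`, so smoothing
#' preserves constants exactly and no rate mass leaks off the track.
#'
#' @param n_bins number of bins.
#' @param sd_bins kernel standard deviation in bins.
#' @return an `n_bins x n_bins` matrix; smooth a row-per-cell rate matrix
#'   `R` as `R %*% K`.
#' @keywords internal
smoothing_matrix <- function(n_bins, sd_bins) {
  d <- outer(seq_len(n_bins), seq_len(n_bins), "-")
  k <- exp(-d^2 / (2 * sd_bins^2))
  sweep(k, 2, colSums(k), "/")
}

# Map spike times of one constant-speed run session to spatial bins.
# Returns integer bins in 1..n_bins (lap position folded by direction).
spike_position_bins <- function(times, lap_s, direction, n_bins) {
  frac <- times / lap_s - floor(times / lap_s)
  x <- if (direction == "right") frac else 1 - frac
  # epsilon guards against representation jitter for spikes that fall
  # exactly on a bin boundary
  pmin(floor(x * n_bins + 1e-9) + 1L, n_bins)
}

#' Trial-averaged, smoothed place-field rate maps
#'
#' Computes for every excitatory cell its occupancy-discounted firing rate
#' in each 2 cm bin of the 1 m track, averaged over the session's
#' constant-speed traversals, then smoothed with a Gaussian kernel (4 cm
#' SD). Under constant speed the occupancy is uniform (`lap_s / n_bins`
#' per traversal), so the discounting is a constant factor.
#'
#' @param record a run-session `spike_record` from [simulate_session()]
#'   (or a list of them sharing one trajectory, pooled as repeated
#'   trials).
#' @param config a [ppn_config()].
#' @return class `place_field_map`: list with `rates` (`nE x n_bins`
#'   matrix, Hz), `raw` (pre-smoothing), `occupancy` (per-bin probability),
#'   and the trajectory metadata.
#' @export
compute_rate_map <- function(record, config) {
  records <- if (inherits(record, "spike_record")) list(record) else record
  an <- config$analysis
  n_bins <- an$n_bins
  n_e <- records[[1L]]$n_e
  counts <- matrix(0, n_e, n_bins)
  total_time_per_bin <- 0
  direction <- records[[1L]]$meta$direction
  for (rec in records) {
    stopifnot(rec$meta$session == "run")
    if (!identical(rec$meta$direction, direction))
      stop("all trials must share one trajectory")
    sp <- rec$spikes[rec$spikes$neuron <= n_e, , drop = FALSE]
    bins <- spike_position_bins(sp$time, rec$meta$lap_s, direction, n_bins)
    if (nrow(sp))
      counts <- counts + unclass(table(factor(sp$neuron, levels = seq_len(n_e)),
                                       factor(bins, levels = seq_len(n_bins))))
    total_time_per_bin <- total_time_per_bin +
      rec$meta$n_laps * rec$meta$lap_s / n_bins
  }
  if (total_time_per_bin <= 0) stop("zero occupancy")
  raw <- counts / total_time_per_bin
  sd_bins <- an$smooth_sd_cm / (an$track_cm / n_bins)
  rates <- raw %*% smoothing_matrix(n_bins, sd_bins)
  structure(list(rates = rates, raw = raw,
                 occupancy = rep(1 / n_bins, n_bins),
                 env = records[[1L]]$meta$env, direction = direction),
            class = "place_field_map")
}

#' @export
print.place_field_map <- function(x, ...) {
  pk <- apply(x$rates, 1, max)
  cat(sprintf("Place-field map (env %s, %s): %d cells x %d bins, %d place cells (peak > 3 Hz)\n",
              x$env, x$direction, nrow(x$rates), ncol(x$rates), sum(pk > 3)))
  invisible(x)
}

#' Place-field specificity
#'
#' One minus the fraction of spatial bins in which the field's rate
#' exceeds 25% of its maximum: 0 for a uniform field, close to 1 for a
#' single sharp peak.
#'
#' @param rate numeric rate vector over bins (peak must be positive).
#' @return specificity in `[0, 1 - 1/n_bins]`.
#' @export
specificity <- function(rate) {
  m <- max(rate)
  if (m <= 0) stop("specificity undefined for an all-zero field")
  1 - mean(rate > 0.25 * m)
}

#' Spatial information of a place field
#'
#' `sum_i p_i (r_i / rbar) log2(r_i / rbar)` in bits per spike, where
#' `p_i` is the occupancy probability of bin `i`, `r_i` the field's rate
#' there, and `rbar = sum_i p_i r_i` its mean rate. Zero-rate bins
#' contribute nothing (the `x log x -> 0` limit). Ranges from 0 (uniform
#' firing) to `log2(n_bins)` (all firing in a single bin).
#'
#' @param rate numeric rate vector over bins.
#' @param occupancy occupancy probabilities (default uniform).
#' @return bits per spike.
#' @export
spatial_information <- function(rate,
                                occupancy = rep(1 / length(rate), length(rate))) {
  rbar <- sum(occupancy * rate)
  if (rbar <= 0) stop("spatial information undefined for an all-zero field")
  pos <- rate > 0
  sum(occupancy[pos] * (rate[pos] / rbar) * log2(rate[pos] / rbar))
}

#' Peak bin of each place field
#'
#' @param rates rate matrix (cells x bins). Ties take the leftmost bin.
#' @return integer vector of peak bins.
#' @export
peak_bins <- function(rates) {
  apply(rates, 1L, which.max)
}

#' Divergence of the place-field peak distribution from uniform
#'
#' Kullback-Leibler divergence (bits) of the empirical distribution of
#' peak bins from the uniform distribution over bins:
#' `-sum_i p_i^data log2(p_i^uniform / p_i^data)`. Zero for perfectly
#' uniform peaks, `log2(n_bins)` if all peaks share one bin.
#'
#' @param peaks integer vector of peak bins.
#' @param n_bins number of spatial bins.
#' @return divergence in bits.
#' @export
peak_distribution_kl <- function(peaks, n_bins = 50L) {
  p_data <- tabulate(peaks, nbins = n_bins) / length(peaks)
  pos <- p_data > 0
  -sum(p_data[pos] * log2((1 / n_bins) / p_data[pos]))
}

#' Fraction of place-field peaks in the central third of the track
#'
#' The central third is bins 17-33 (1-based) of the 50-bin track: the
#' middle 17 bins. The location cues peak at the track ends, so this
#' region is the most depleted of input drive.
#'
#' @param peaks integer vector of peak bins.
#' @param n_bins number of spatial bins.
#' @return fraction in `[0, 1]`.
#' @export
central_third_fraction <- function(peaks, n_bins = 50L) {
  lo <- floor(n_bins / 3) + 1L      # 17 for 50 bins
  hi <- 2L * floor(n_bins / 3) + 1L # 33 for 50 bins
  mean(peaks >= lo & peaks <= hi)
}

#' Population-vector correlation between two place-field maps
#'
#' For each spatial bin, the Pearson correlation between the two maps'
#' population rate vectors; the map correlation is the mean over bins.
#' By default each cell's field is normalized by its peak rate first, so
#' the correlation reflects where cells fire rather than how much: maps
#' of the same environment then correlate strongly while remapped
#' environments fall to zero even though per-cell excitability persists
#' across environments. Bins where either population vector has zero
#' variance are skipped (and counted in the `n_skipped` attribute).
#'
#' @param map_a,map_b `place_field_map` objects or rate matrices with the
#'   same cells and bins.
#' @param normalize divide each cell's field by its peak before
#'   correlating.
#' @return mean per-bin correlation, with attribute `n_skipped`.
#' @export
map_correlation <- function(map_a, map_b, normalize = TRUE) {
  a <- if (inherits(map_a, "place_field_map")) map_a$rates else map_a
  b <- if (inherits(map_b, "place_field_map")) map_b$rates else map_b
  stopifnot(identical(dim(a), dim(b)))
  if (normalize) {
    a <- a / pmax(apply(a, 1L, max), .Machine$double.eps)
    b <- b / pmax(apply(b, 1L, max), .Machine$double.eps)
  }
  vals <- vapply(seq_len(ncol(a)), function(j) {
    if (stats::sd(a[, j]) == 0 || stats::sd(b[, j]) == 0) NA_real_
    else stats::cor(a[, j], b[, j])
  }, numeric(1))
  structure(mean(vals, na.rm = TRUE), n_skipped = sum(is.na(vals)))
}

#' Per-cell and per-map place-field statistics
#'
#' @param map a [compute_rate_map()] result.
#' @param config a [ppn_config()].
#' @return class `place_field_stats`: per-cell `peak_rate`, `peak_bin`,
#'   `specificity`, `spatial_information` (place cells only; `NA`
#'   elsewhere), the logical `place_cell` mask (peak above the 3 Hz
#'   threshold), and per-map `kl_divergence` and `central_third` over
#'   place-cell peaks.
#' @export
place_field_stats <- function(map, config) {
  an <- config$analysis
  rates <- map$rates
  pk_rate <- apply(rates, 1L, max)
  pk_bin <- peak_bins(rates)
  mask <- pk_rate > an$place_peak_hz
  spec <- si <- rep(NA_real_, nrow(rates))
  for (i in which(mask)) {
    spec[i] <- specificity(rates[i, ])
    si[i] <- spatial_information(rates[i, ], map$occupancy)
  }
  structure(list(peak_rate = pk_rate, peak_bin = pk_bin,
                 specificity = spec, spatial_information = si,
                 place_cell = mask,
                 n_place_cells = sum(mask),
                 kl_divergence = if (any(mask))
                   peak_distribution_kl(pk_bin[mask], an$n_bins) else NA_real_,
                 central_third = if (any(mask))
                   central_third_fraction(pk_bin[mask], an$n_bins) else NA_real_),
            class = "place_field_stats")
}

#' @export
print.place_field_stats <- function(x, ...) {
  cat(sprintf("Place-field stats: %d place cells; median peak %.2f Hz, specificity %.2f, info %.2f bits/spike; KL %.2f bits, central third %.2f\n",
              x$n_place_cells, stats::median(x$peak_rate[x$place_cell]),
              stats::median(x$specificity, na.rm = TRUE),
              stats::median(x$spatial_information, na.rm = TRUE),
              x$kl_divergence, x$central_third))
  invisible(x)
}

#' Time-field maps from mixed-speed traversals
#'
#' Same estimator as [compute_rate_map()] but binned in elapsed time from
#' traversal onset: fifty 40 ms bins across the initial two seconds.
#' Traversals shorter than 2 s (higher speeds) contribute occupancy only
#' to the bins they cover, so rates stay occupancy-discounted.
#'
#' @param records list of run-session `spike_record`s (possibly at
#'   different speeds, same trajectory).
#' @param config a [ppn_config()].
#' @return class `place_field_map` (time interpreted as the bin axis,
#'   occupancy reflecting traversal coverage).
#' @export
compute_time_fields <- function(records, config) {
  an <- config$analysis
  n_bins <- an$n_bins
  bin_s <- 2 / n_bins   # 40 ms bins over the first two seconds
  n_e <- records[[1L]]$n_e
  counts <- matrix(0, n_e, n_bins)
  occ_time <- numeric(n_bins)
  for (rec in records) {
    stopifnot(rec$meta$session == "run")
    lap_s <- rec$meta$lap_s
    sp <- rec$spikes[rec$spikes$neuron <= n_e, , drop = FALSE]
    t_in_lap <- sp$time - floor(sp$time / lap_s) * lap_s
    keep <- t_in_lap < 2
    bins <- pmin(floor(t_in_lap[keep] / bin_s + 1e-9) + 1L, n_bins)
    if (any(keep))
      counts <- counts + unclass(table(factor(sp$neuron[keep], levels = seq_len(n_e)),
                                       factor(bins, levels = seq_len(n_bins))))
    covered <- pmin(pmax(lap_s, 0), 2) / bin_s   # bins covered per lap
    full <- floor(covered + 1e-9)
    add <- c(rep(bin_s, full), rep(0, n_bins - full))
    occ_time <- occ_time + rec$meta$n_laps * add
  }
  if (all(occ_time <= 0)) stop("zero occupancy")
  raw <- sweep(counts, 2, pmax(occ_time, .Machine$double.eps), "/")
  raw[, occ_time <= 0] <- 0
  sd_bins <- an$smooth_sd_cm / (an$track_cm / n_bins)
  rates <- raw %*% smoothing_matrix(n_bins, sd_bins)
  occupancy <- occ_time / sum(occ_time)
  structure(list(rates = rates, raw = raw, occupancy = occupancy,
                 env = records[[1L]]$meta$env,
                 direction = records[[1L]]$meta$direction),
            class = "place_field_map")
}
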