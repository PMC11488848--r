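#' Smoothed excitatory population rate
#'
#' Bins all excitatory spikes on the simulation time grid, converts to a
#' per-cell rate in Hz, and smooths with a Gaussian kernel (15 ms SD,
#' truncated at 4 SD) via FFT convolution. The trace's session mean and
#' standard deviation define the event-detection threshold.
#'
#' @param record a sleep-session `spike_record`.
#' @param config a [ppn_config()].
#' @param grid_dt_ms analysis grid step; defaults to the simulation `dt`.
#' @return class `population_rate`: `time` (s), `rate` (Hz per cell),
#'   `mean`, `sd`, `dt` (s).
#' @export
population_rate <- function(record, config, grid_dt_ms = config$cells$dt) {
  dt_s <- grid_dt_ms / 1000
  n_steps <- as.integer(round(record$duration / dt_s))
  sp <- record$spikes[record$spikes$neuron <= record$n_e, , drop = FALSE]
  idx <- pmin(pmax(ceiling(sp$time / dt_s), 1L), n_steps)
  counts <- tabulate(idx, nbins = n_steps)
  rate <- counts / (record$n_e * dt_s)
  sd_steps <- config$analysis$pbe_kernel_ms / grid_dt_ms
  half <- ceiling(4 * sd_steps)
  kern <- exp(-(seq(-half, half))^2 / (2 * sd_steps^2))
  kern <- kern / sum(kern)
  sm <- stats::convolve(rate, rev(kern), type = "open")
  sm <- sm[(half + 1):(half + n_steps)]
  sm[sm < 0] <- 0   # FFT round-off
  structure(list(time = (seq_len(n_steps) - 0.5) * dt_s, rate = sm,
                 mean = mean(sm), sd = stats::sd(sm), dt = dt_s),
            class = "population_rate")
}

#' @export
print.population_rate <- function(x, ...) {
  cat(sprintf("Population rate trace: %.1f s, mean %.3f Hz, SD %.3f Hz\n",
              length(x$rate) * x$dt, x$mean, x$sd))
  invisible(x)
}

#' Detect population burst events
#'
#' PBEs are periods where the smoothed excitatory population rate exceeds
#' one standard deviation above its session mean for at least 30 ms and
#' reaches a peak of at least 0.5 Hz. Events whose boundaries are
#' separated by less than 10 ms are merged. An event is flagged
#' `decodable` when it lasts at least 50 ms and at least 5 excitatory
#' cells spike within it.
#'
#' @param trace a [population_rate()] result computed over the full
#'   session.
#' @param record the same session's `spike_record`.
#' @param config a [ppn_config()].
#' @return class `pbe_list`: data.frame with `start`, `end`, `duration`
#'   (s), `n_cells`, `peak_rate` (Hz), `decodable`.
#' @export
detect_pbes <- function(trace, record, config) {
  an <- config$analysis
  thr <- trace$mean + trace$sd
  above <- trace$rate > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  ev_start <- trace$time[starts[keep]] - trace$dt / 2
  ev_end <- trace$time[ends[keep]] + trace$dt / 2
  dur <- ev_end - ev_start
  peak <- vapply(which(keep), function(k)
    max(trace$rate[starts[k]:ends[k]]), numeric(1))
  ok <- dur >= an$pbe_min_ms / 1000 & peak >= an$pbe_peak_hz
  ev_start <- ev_start[ok]; ev_end <- ev_end[ok]; peak <- peak[ok]
  out <- empty_pbe_frame()
  if (length(ev_start)) {
    # merge events separated by less than the gap threshold
    gap_s <- an$pbe_gap_ms / 1000
    ms <- ev_start[1L]; me <- ev_end[1L]; mp <- peak[1L]
    rows <- list()
    if (length(ev_start) > 1) {
      for (i in 2:length(ev_start)) {
        if (ev_start[i] - me < gap_s) {
          me <- ev_end[i]; mp <- max(mp, peak[i])
        } else {
          rows[[length(rows) + 1L]] <- c(ms, me, mp)
          ms <- ev_start[i]; me <- ev_end[i]; mp <- peak[i]
        }
      }
    }
    rows[[length(rows) + 1L]] <- c(ms, me, mp)
    m <- do.call(rbind, rows)
    sp <- record$spikes[record$spikes$neuron <= record$n_e, , drop = FALSE]
    n_cells <- vapply(seq_len(nrow(m)), function(i)
      length(unique(sp$neuron[sp$time >= m[i, 1] & sp$time <= m[i, 2]])),
      integer(1))
    out <- data.frame(start = m[, 1], end = m[, 2],
                      duration = m[, 2] - m[, 1],
                      n_cells = n_cells, peak_rate = m[, 3])
    out$decodable <- out$n_cells >= an$decode_min_cells &
      out$duration >= an$decode_min_ms / 1000
  }
  structure(out, class = c("pbe_list", "data.frame"))
}

empty_pbe_frame <- function() {
  data.frame(start = numeric(), end = numeric(), duration = numeric(),
             n_cells = integer(), peak_rate = numeric(),
             decodable = logical())
}

#' @export
print.pbe_list <- function(x, ...) {
  cat(sprintf("PBEs: %d events (%d decodable); median duration %.0f ms, median participation %d cells\n",
              nrow(x), sum(x$decodable),
              if (nrow(x)) 1000 * stats::median(x$duration) else NA,
              if (nrow(x)) as.integer(stats::median(x$n_cells)) else NA))
  invisible(x)
}
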