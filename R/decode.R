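#' Memoryless Bayesian decoding of one population burst event
#'
#' Bins the event's spikes into 10 ms windows from event start (a final
#' partial window is dropped) and computes, per window, the posterior over
#' the 50 spatial bins under independent-Poisson place-field likelihoods
#' and a uniform position prior:
#' `P(x | s) ~ prod_i r_i(x)^(s_i) * exp(-tau * sum_i r_i(x))`.
#' Only cells whose place-field peak exceeds the 3 Hz threshold enter the
#' decoder; their rates are floored at 0.01 Hz so no position has zero
#' likelihood. Windows without spikes are retained (the likelihood is the
#' no-spike Poisson term alone).
#'
#' @param record the sleep `spike_record` containing the event.
#' @param event one row of a [detect_pbes()] frame (list or data.frame
#'   row with `start` and `end`).
#' @param map a `place_field_map` for the decoding trajectory.
#' @param config a [ppn_config()].
#' @param place_cells optional logical mask of cells to use; defaults to
#'   peak rate above the configured threshold.
#' @return class `posterior_matrix`: `post` (`n_bins x T`, columns sum to
#'   1), `counts` (place cells x T spike counts), `tau` (s), `t_centers`
#'   (s, event-relative), `x_centers` (track fraction).
#' @export
decode_event <- function(record, event, map, config, place_cells = NULL) {
  an <- config$analysis
  tau <- an$decode_bin_ms / 1000
  if (is.null(place_cells))
    place_cells <- apply(map$rates, 1L, max) > an$place_peak_hz
  rates <- pmax(map$rates[place_cells, , drop = FALSE], an$rate_floor_hz)
  n_t <- floor((event$end - event$start) / tau + 1e-9)
  if (n_t < 1) stop("event shorter than one decoding window")
  ids <- which(place_cells)
  sp <- record$spikes
  sel <- sp$time >= event$start & sp$time < event$start + n_t * tau &
    sp$neuron %in% ids
  sp <- sp[sel, , drop = FALSE]
  tbin <- pmin(floor((sp$time - event$start) / tau) + 1L, n_t)
  counts <- unclass(table(factor(match(sp$neuron, ids),
                                 levels = seq_along(ids)),
                          factor(tbin, levels = seq_len(n_t))))
  log_r <- log(rates)
  loglik <- crossprod(log_r, counts) - tau * colSums(rates)  # n_bins x T
  post <- apply(loglik, 2L, function(col) {
    p <- exp(col - max(col))
    p / sum(p)
  })
  post <- matrix(post, nrow = ncol(map$rates))
  n_bins <- nrow(post)
  structure(list(post = post, counts = counts, tau = tau,
                 t_centers = (seq_len(n_t) - 0.5) * tau,
                 x_centers = (seq_len(n_bins) - 0.5) / n_bins,
                 event = list(start = event$start, end = event$end)),
            class = "posterior_matrix")
}

#' @export
print.posterior_matrix <- function(x, ...) {
  cat(sprintf("Decoded event: %d spatial bins x %d time bins (tau = %g ms); |r| = %.3f, jd = %.2f, H = %.2f bits\n",
              nrow(x$post), ncol(x$post), 1000 * x$tau,
              abs(weighted_correlation(x)), max_jump(x), event_entropy(x)))
  invisible(x)
}

#' Probability-weighted space-time correlation of a decoded event
#'
#' Pearson correlation between position (bin centers, track fraction) and
#' time (bin centers, seconds) over the event's space-time grid, with the
#' decoded probability in each 10 ms by 2 cm bin as the weight. The
#' absolute value measures how linear the decoded trajectory is; the sign
#' gives its direction.
#'
#' @param post a [decode_event()] result, or a bare posterior matrix
#'   (columns normalized over space).
#' @return the signed weighted correlation, or `NA` if the weighted
#'   variance of position or time vanishes.
#' @export
weighted_correlation <- function(post) {
  p <- if (inherits(post, "posterior_matrix")) post$post else post
  n_bins <- nrow(p); n_t <- ncol(p)
  if (n_t < 2) stop("need at least 2 time bins")
  x <- if (inherits(post, "posterior_matrix")) post$x_centers
       else (seq_len(n_bins) - 0.5) / n_bins
  t <- if (inherits(post, "posterior_matrix")) post$t_centers
       else seq_len(n_t) - 0.5
  w <- sum(p)
  ex <- sum(rowSums(p) * x) / w
  et <- sum(colSums(p) * t) / w
  vx <- sum(rowSums(p) * (x - ex)^2) / w
  vt <- sum(colSums(p) * (t - et)^2) / w
  if (vx <= 0 || vt <= 0) return(NA_real_)
  cxt <- sum(p * outer(x - ex, t - et)) / w
  cxt / sqrt(vx * vt)
}

#' Maximum jump of the decoded peak position
#'
#' Largest displacement of the posterior's argmax between adjacent time
#' bins, as a fraction of the track length. Argmax ties take the lowest
#' bin.
#'
#' @param post a [decode_event()] result or posterior matrix.
#' @return jump distance in `[0, 1 - 1/n_bins]`; 0 for a single-bin
#'   event.
#' @export
max_jump <- function(post) {
  p <- if (inherits(post, "posterior_matrix")) post$post else post
  peaks <- apply(p, 2L, which.max)
  if (length(peaks) < 2) return(0)
  max(abs(diff(peaks))) / nrow(p)
}

#' Mean spatial entropy of a decoded event
#'
#' Mean over time bins of the entropy (bits) of the decoded position
#' distribution: `log2(n_bins)` for uniform columns, 0 for point masses.
#'
#' @param post a [decode_event()] result or posterior matrix.
#' @return mean entropy in bits.
#' @export
event_entropy <- function(post) {
  p <- if (inherits(post, "posterior_matrix")) post$post else post
  h <- apply(p, 2L, function(col) {
    pos <- col > 0
    -sum(col[pos] * log2(col[pos]))
  })
  mean(h)
}
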