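# Sufficient statistics of a posterior for fast column-permutation
# statistics: per-column weighted mean/second moment of position and the
# per-column argmax. Column masses are all 1, so only the pairing of time
# coordinates with columns changes under a shuffle.
posterior_suffstats <- function(post) {
  p <- post$post
  x <- post$x_centers
  t <- post$t_centers
  mu <- colSums(p * x)
  s2 <- colSums(p * x^2)
  n_t <- ncol(p)
  ex <- sum(mu) / n_t
  vx <- sum(s2) / n_t - ex^2
  et <- mean(t)
  vt <- mean((t - et)^2)
  list(mu = mu, peaks = apply(p, 2L, which.max), n_bins = nrow(p),
       t = t, ex = ex, vx = vx, et = et, vt = vt, n_t = n_t)
}

wcorr_from_suffstats <- function(ss, perm) {
  if (ss$vx <= 0 || ss$vt <= 0) return(NA_real_)
  cxt <- sum(ss$t * ss$mu[perm]) / ss$n_t - ss$ex * ss$et
  cxt / sqrt(ss$vx * ss$vt)
}

#' Time-bin shuffles of a decoded event
#'
#' Generates uniformly random permutations of the event's 10 ms time bins
#' (applied to the posterior's columns, which is equivalent to shuffling
#' the binned spike vectors because the decoder is memoryless) and
#' recomputes the weighted correlation and maximum jump distance of each
#' shuffled event.
#'
#' @param post a [decode_event()] result with at least 2 time bins.
#' @param n number of shuffles (100 in the standard analysis).
#' @param seed integer seed for the event's shuffle stream.
#' @return data.frame with columns `r` (signed weighted correlation) and
#'   `jd`, one row per shuffle.
#' @export
shuffle_event <- function(post, n = 100L, seed = NULL) {
  ss <- posterior_suffstats(post)
  if (ss$n_t < 2) stop("cannot shuffle an event with fewer than 2 time bins")
  draw <- function() {
    r <- numeric(n); jd <- numeric(n)
    for (k in seq_len(n)) {
      perm <- sample.int(ss$n_t)
      r[k] <- wcorr_from_suffstats(ss, perm)
      jd[k] <- max(abs(diff(ss$peaks[perm]))) / ss$n_bins
    }
    data.frame(r = r, jd = jd)
  }
  if (is.null(seed)) draw() else with_stream(seed, draw())
}

#' Per-event shuffle p-value
#'
#' Fraction of the event's own time-bin shuffles whose absolute weighted
#' correlation exceeds the event's.
#'
#' @param r_actual the event's signed weighted correlation.
#' @param shuffle_r the shuffles' signed weighted correlations.
#' @return p-value on the grid `0, 1/n, ..., 1`.
#' @export
per_event_pvalue <- function(r_actual, shuffle_r) {
  mean(abs(shuffle_r) > abs(r_actual))
}

#' Decode and shuffle all decodable events of a sleep session
#'
#' Runs [decode_event()] on every decodable PBE, computes per-event
#' statistics (weighted correlation, maximum jump, mean entropy, shuffle
#' p-value), and attaches each event's time-bin shuffles. Events whose
#' weighted correlation is undefined (zero weighted variance) or that
#' span fewer than two decoding windows are dropped and counted.
#'
#' @param record sleep `spike_record`.
#' @param pbes a [detect_pbes()] frame.
#' @param map the decoding trajectory's `place_field_map`.
#' @param config a [ppn_config()].
#' @param seed base seed for the shuffle streams (keyed per event).
#' @param keep_posteriors retain the posterior matrices (memory permitting).
#' @return class `preplay_events`: list with `stats` (data.frame per
#'   event: `event`, `start`, `end`, `n_t`, `r`, `jd`, `entropy`,
#'   `p_value`), `shuffle_r`, `shuffle_jd` (events x n_shuffles matrices),
#'   `n_dropped`, and optionally `posteriors`.
#' @export
decode_events <- function(record, pbes, map, config,
                          seed = substream_seed(config$seed, "shuffles"),
                          keep_posteriors = FALSE) {
  an <- config$analysis
  idx <- which(pbes$decodable)
  stats_rows <- list(); shr <- list(); shjd <- list(); posts <- list()
  n_dropped <- 0L
  for (e in idx) {
    post <- decode_event(record, pbes[e, ], map, config)
    if (ncol(post$post) < 2) { n_dropped <- n_dropped + 1L; next }
    r <- weighted_correlation(post)
    if (is.na(r)) { n_dropped <- n_dropped + 1L; next }
    sh <- shuffle_event(post, an$n_shuffles,
                        seed = substream_seed(seed, "event", e))
    stats_rows[[length(stats_rows) + 1L]] <- data.frame(
      event = e, start = pbes$start[e], end = pbes$end[e],
      n_t = ncol(post$post), r = r, jd = max_jump(post),
      entropy = event_entropy(post),
      p_value = per_event_pvalue(r, sh$r))
    shr[[length(shr) + 1L]] <- sh$r
    shjd[[length(shjd) + 1L]] <- sh$jd
    if (keep_posteriors) posts[[length(posts) + 1L]] <- post
  }
  stats <- if (length(stats_rows)) do.call(rbind, stats_rows) else
    data.frame(event = integer(), start = numeric(), end = numeric(),
               n_t = integer(), r = numeric(), jd = numeric(),
               entropy = numeric(), p_value = numeric())
  structure(list(stats = stats,
                 shuffle_r = if (length(shr)) do.call(rbind, shr) else
                   matrix(numeric(), 0, an$n_shuffles),
                 shuffle_jd = if (length(shjd)) do.call(rbind, shjd) else
                   matrix(numeric(), 0, an$n_shuffles),
                 n_dropped = n_dropped,
                 posteriors = if (keep_posteriors) posts else NULL),
            class = "preplay_events")
}

#' @export
print.preplay_events <- function(x, ...) {
  cat(sprintf("Decoded events: %d (dropped %d); median |r| = %.3f, median jd = %.2f\n",
              nrow(x$stats), x$n_dropped,
              stats::median(abs(x$stats$r)), stats::median(x$stats$jd)))
  invisible(x)
}

#' Combine decoded events across networks
#'
#' @param ... `preplay_events` objects (or one list of them).
#' @return a single `preplay_events` with a `network` column in `stats`.
#' @export
combine_preplay_events <- function(...) {
  objs <- list(...)
  if (length(objs) == 1L && !inherits(objs[[1L]], "preplay_events"))
    objs <- objs[[1L]]
  if (length(objs) == 0L)
    return(structure(list(stats = data.frame(), shuffle_r = NULL,
                          shuffle_jd = NULL, n_dropped = 0L,
                          posteriors = NULL), class = "preplay_events"))
  stats <- do.call(rbind, lapply(seq_along(objs), function(i) {
    s <- objs[[i]]$stats
    if (nrow(s)) s$network <- i
    s
  }))
  structure(list(stats = stats,
                 shuffle_r = do.call(rbind, lapply(objs, `[[`, "shuffle_r")),
                 shuffle_jd = do.call(rbind, lapply(objs, `[[`, "shuffle_jd")),
                 n_dropped = sum(vapply(objs, `[[`, integer(1), "n_dropped")),
                 posteriors = NULL),
            class = "preplay_events")
}

#' Ensemble Kolmogorov-Smirnov preplay test
#'
#' Two-sample KS test comparing the absolute weighted correlations of the
#' actual events with those of all their pooled time-bin shuffles.
#'
#' @param actual_r signed (or absolute) weighted correlations of actual
#'   events.
#' @param shuffle_r pooled shuffle correlations.
#' @return list with `statistic`, `p_value`, and `median_shift`
#'   (median |r| actual minus median |r| shuffled).
#' @export
ks_preplay_test <- function(actual_r, shuffle_r) {
  a <- abs(actual_r); s <- abs(shuffle_r)
  kt <- suppressWarnings(stats::ks.test(a, s))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value),
       median_shift = stats::median(a) - stats::median(s))
}

#' Threshold-grid bootstrap significance of preplay
#'
#' For each pair of thresholds (minimum absolute weighted correlation,
#' maximum jump distance), computes the fraction of actual events passing
#' both gates and compares it against 100 shuffled data sets, each formed
#' by drawing one time-bin shuffle per event. The cell's p-value is the
#' fraction of shuffled data sets whose passing fraction is at least the
#' actual one (ties count, so the all-pass corner - r threshold 0, jump
#' threshold 1 - always has p = 1 and can never be significant); cells
#' that no event (actual or shuffled) passes are flagged empty.
#'
#' @param events a `preplay_events` object.
#' @param r_thresholds,jd_thresholds gate grids.
#' @param n_datasets number of shuffled data sets.
#' @param seed integer seed.
#' @return class `threshold_grid`: list with `p` (r x jd matrix),
#'   `actual_fraction`, `empty` (logical matrix), and the grids.
#' @export
threshold_grid_bootstrap <- function(events,
                                     r_thresholds = seq(0, 0.9, by = 0.1),
                                     jd_thresholds = seq(0.1, 1, by = 0.1),
                                     n_datasets = 100L,
                                     seed = NULL) {
  st <- events$stats
  n_ev <- nrow(st)
  if (n_ev == 0L) stop("no decoded events")
  n_sh <- ncol(events$shuffle_r)
  frac_grid <- function(r, jd) {
    vapply(jd_thresholds, function(dj)
      vapply(r_thresholds, function(ri) mean(abs(r) >= ri & jd <= dj),
             numeric(1)),
      numeric(length(r_thresholds)))
  }
  actual <- frac_grid(st$r, st$jd)
  run <- function() {
    higher <- array(0, dim(actual))
    any_pass <- actual > 0
    for (d in seq_len(n_datasets)) {
      pick <- sample.int(n_sh, n_ev, replace = TRUE)
      rs <- events$shuffle_r[cbind(seq_len(n_ev), pick)]
      js <- events$shuffle_jd[cbind(seq_len(n_ev), pick)]
      f <- frac_grid(rs, js)
      # ties count toward p, so the all-pass corner (every event passes
      # in every data set) can never be significant
      higher <- higher + (f >= actual)
      any_pass <- any_pass | f > 0
    }
    list(p = higher / n_datasets, empty = !any_pass)
  }
  res <- if (is.null(seed)) run() else with_stream(seed, run())
  dimnames(res$p) <- dimnames(actual) <-
    list(r_min = r_thresholds, jd_max = jd_thresholds)
  structure(list(p = res$p, actual_fraction = actual, empty = res$empty,
                 r_thresholds = r_thresholds, jd_thresholds = jd_thresholds,
                 n_datasets = n_datasets),
            class = "threshold_grid")
}

#' @export
print.threshold_grid <- function(x, ...) {
  n_cells <- sum(!x$empty)
  cat(sprintf("Threshold-grid bootstrap: %d x %d cells (%d non-empty), %d significant at p < 0.05\n",
              nrow(x$p), ncol(x$p), n_cells, sum(x$p < 0.05 & !x$empty)))
  invisible(x)
}

#' Full preplay significance report for an event ensemble
#'
#' @param events a `preplay_events` (typically combined across networks).
#' @param config a [ppn_config()] (for the bootstrap seed).
#' @param ... passed to [threshold_grid_bootstrap()].
#' @return class `preplay_significance`: the KS test, median shift,
#'   threshold grid, per-event p-values, and the fraction of individually
#'   significant events (p < 0.05).
#' @export
preplay_significance <- function(events, config, ...) {
  ks <- ks_preplay_test(events$stats$r, events$shuffle_r)
  grid <- threshold_grid_bootstrap(events, ...,
                                   seed = substream_seed(config$seed,
                                                         "grid_bootstrap"))
  structure(list(ks_statistic = ks$statistic, ks_p = ks$p_value,
                 median_shift = ks$median_shift, grid = grid,
                 event_p = events$stats$p_value,
                 frac_significant = mean(events$stats$p_value < 0.05),
                 n_events = nrow(events$stats)),
            class = "preplay_significance")
}

#' @export
print.preplay_significance <- function(x, ...) {
  cat(sprintf("Preplay significance over %d events:\n", x$n_events))
  cat(sprintf("  KS statistic %.3f (p = %.3g), median |r| shift %+.3f\n",
              x$ks_statistic, x$ks_p, x$median_shift))
  cat(sprintf("  fraction of individually significant events: %.2f\n",
              x$frac_significant))
  print(x$grid)
  invisible(x)
}
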