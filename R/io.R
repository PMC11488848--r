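#' Write a spike record as a columnar text table
#'
#' Tab-separated columns `session_id`, `neuron_id`, `t_seconds`, sorted
#' by time, preceded by `#`-prefixed metadata lines (session kind,
#' duration, counts, trajectory, seed) so the record round-trips
#' losslessly.
#'
#' @param record a `spike_record`.
#' @param path output path.
#' @param session_id label written in the first column.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(record, path, session_id = NULL) {
  if (is.null(session_id))
    session_id <- paste0(record$meta$session,
                         if (record$meta$session == "run")
                           paste0("_env", record$meta$env, "_",
                                  record$meta$direction) else "")
  meta <- record$meta
  hdr <- c(sprintf("# session=%s", meta$session),
           sprintf("# duration=%.9g", record$duration),
           sprintf("# n=%d", record$n),
           sprintf("# n_e=%d", record$n_e),
           sprintf("# env=%s", meta$env),
           sprintf("# direction=%s", meta$direction),
           sprintf("# speed=%.9g", meta$speed),
           sprintf("# n_laps=%s", meta$n_laps),
           sprintf("# lap_s=%.9g", meta$lap_s),
           sprintf("# seed=%s", meta$seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("session_id\tneuron_id\tt_seconds", con)
  if (nrow(record$spikes))
    writeLines(sprintf("%s\t%d\t%.9f", session_id, record$spikes$neuron,
                       record$spikes$time), con)
  invisible(path)
}

#' Read a spike record written by [write_spike_table()]
#'
#' Externally produced tables are accepted if they provide the three
#' columns and the metadata header; times must be sorted and
#' non-negative.
#'
#' @param path input path.
#' @return a `spike_record`.
#' @export
read_spike_table <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[kv[1L]]] <- kv[2L]
  }
  required <- c("session", "duration", "n", "n_e")
  if (!all(required %in% names(meta)))
    stop("spike table is missing metadata header(s): ",
         paste(setdiff(required, names(meta)), collapse = ", "))
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("session_id", "neuron_id", "t_seconds") %in% names(tab)))
    stop("spike table must have columns session_id, neuron_id, t_seconds")
  if (nrow(tab)) {
    if (any(tab$t_seconds < 0))
      stop("negative spike time at line ",
           which(tab$t_seconds < 0)[1L] + length(meta_lines) + 1L)
    if (is.unsorted(tab$t_seconds))
      stop("spike times must be sorted at line ",
           which(diff(tab$t_seconds) < 0)[1L] + length(meta_lines) + 2L)
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  structure(list(spikes = data.frame(neuron = as.integer(tab$neuron_id),
                                     time = as.numeric(tab$t_seconds)),
                 duration = as.numeric(meta$duration),
                 n = as.integer(meta$n), n_e = as.integer(meta$n_e),
                 meta = list(session = meta$session,
                             env = num_or_na(meta$env),
                             direction = meta$direction,
                             speed = num_or_na(meta$speed),
                             n_laps = num_or_na(meta$n_laps),
                             lap_s = num_or_na(meta$lap_s),
                             seed = num_or_na(meta$seed))),
            class = "spike_record")
}

#' Export a rate map as a delimited matrix
#'
#' One row per cell; the header row holds the spatial bin centers in cm.
#'
#' @param map a `place_field_map`.
#' @param path output path.
#' @param config a [ppn_config()] (bin geometry).
#' @return `path`, invisibly.
#' @export
write_rate_map <- function(map, path, config = ppn_config()) {
  an <- config$analysis
  centers <- (seq_len(an$n_bins) - 0.5) * an$track_cm / an$n_bins
  out <- as.data.frame(map$rates)
  names(out) <- sprintf("%.1f", centers)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a rate map written by [write_rate_map()]
#' @param path input path.
#' @return a `place_field_map` (rates only; uniform occupancy).
#' @export
read_rate_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  rates <- as.matrix(tab)
  dimnames(rates) <- NULL
  structure(list(rates = rates, raw = NULL,
                 occupancy = rep(1 / ncol(rates), ncol(rates)),
                 env = NA, direction = NA),
            class = "place_field_map")
}

#' Export a detected-event table
#' @param pbes a [detect_pbes()] frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(pbes, path) {
  utils::write.table(as.data.frame(pbes), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event table
#' @param path input path.
#' @return a `pbe_list` data.frame.
#' @export
read_event_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(tab, class = c("pbe_list", "data.frame"))
}
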