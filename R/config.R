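#' Fiducial model configuration
#'
#' Returns the full parameter tree of the clustered-network model with every
#' parameter at its fiducial value: the neuron model (conductance-based LIF
#' with spike-rate adaptation), the network structure (randomly overlapping
#' clusters of excitatory cells), the feed-forward inputs (two linear
#' location cues plus a context cue, log-normal synaptic weights), the
#' session protocol (five 2 s track traversals per trajectory; 120 s sleep),
#' and the analysis settings (spatial binning, smoothing kernels, event
#' detection thresholds, decoder settings, shuffle counts).
#'
#' Units are stated per field: conductances in pS, times in ms unless the
#' name says otherwise, rates in Hz, potentials in mV.
#'
#' @param seed master seed; all randomness in the package flows from named
#'   sub-streams derived from it (see [substream_seed()]).
#' @param ... named overrides as `section.key = value`, e.g.
#'   `network.n_clusters = 8` or a nested list per section.
#' @return a list of class `ppn_config`.
#' @export
ppn_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    network = list(
      n = 500L,                    # total neurons
      excit_fraction = 0.75,       # fraction excitatory
      n_clusters = 15L,
      cluster_participation = 1.25,# mean clusters per E cell
      p_ee = 0.08,                 # global E-to-E connection probability
      p_ei_ie = 0.25,              # E-to-I and I-to-E probability
      w_ee = 220,                  # pS, E-to-E conductance step
      w_ei = 400,                  # pS, E-to-I
      w_ie = 400                   # pS, I-to-E
    ),
    cells = list(
      tau_m = 40,     # ms, membrane time constant (= c_m / g_l)
      c_m = 0.4,      # nF
      g_l = 10,       # nS
      e_l = -70,      # mV
      e_e = 0,        # mV, excitatory (and external-input) reversal
      e_i = -70,      # mV
      e_sra = -80,    # mV
      v_th = -50,     # mV
      v_reset = -70,  # mV
      tau_e = 10,     # ms
      tau_i = 3,      # ms
      tau_sra = 30,   # ms
      delta_sra = 3,  # pS, SRA conductance step per own spike
      dt = 0.1        # ms, integration step
    ),
    inputs = list(
      r_g = 5000,          # Hz, peak Poisson input rate
      input_dt = 0.1,      # ms, input-process grid (fixed across dt)
      w_in = 72,           # pS, mean input synaptic strength
      sigma_in = 5,        # pS, SD of location-cue weights
      sigma_context = 1.25,# pS, SD of context-cue weights
      sigma_bias = 0.04,   # location-cue cluster bias scale
      f_e_awake = 0.1,     # E-cell context scaling, awake
      f_e_sleep = 1,       # E-cell context scaling, sleep
      f_i_awake = 1,       # I-cell context scaling, awake
      f_i_sleep = 0.75     # I-cell context scaling, sleep
    ),
    session = list(
      lap_s = 2,       # s per 1 m traversal at 1x speed
      n_laps = 5L,
      sleep_s = 120
    ),
    analysis = list(
      n_bins = 50L,          # spatial bins over the 1 m track (2 cm each)
      track_cm = 100,
      smooth_sd_cm = 4,      # place-field Gaussian kernel SD
      place_peak_hz = 3,     # place-cell inclusion threshold
      pbe_kernel_ms = 15,    # population-rate smoothing SD
      pbe_min_ms = 30,       # minimum supra-threshold duration
      pbe_gap_ms = 10,       # merge events separated by less than this
      pbe_peak_hz = 0.5,     # minimum peak population rate
      decode_bin_ms = 10,    # decoder time bin
      decode_min_ms = 50,    # minimum decodable event duration
      decode_min_cells = 5L, # minimum participating cells
      rate_floor_hz = 0.01,  # decoder place-field rate floor
      n_shuffles = 100L,     # time-bin shuffles per event
      cluster_kernel_ms = 15 # cluster-rate smoothing SD
    )
  )
  class(cfg) <- "ppn_config"
  cfg <- modify_config(cfg, list(...))
  validate_config(cfg)
}

#' @export
print.ppn_config <- function(x, ...) {
  cat("Clustered-network model configuration (seed ", x$seed, ")\n", sep = "")
  nw <- x$network
  cat(sprintf("  network: n=%d (%.0f%% E), %d clusters, participation %.2f, pc=%.3g\n",
              nw$n, 100 * nw$excit_fraction, nw$n_clusters,
              nw$cluster_participation, nw$p_ee))
  cat(sprintf("  within-cluster connection probability: %.3f\n",
              within_cluster_probability(x)))
  cat(sprintf("  sessions: %d laps x %g s run; %g s sleep; dt = %g ms\n",
              x$session$n_laps, x$session$lap_s, x$session$sleep_s,
              x$cells$dt))
  invisible(x)
}

modify_config <- function(cfg, dots) {
  if (length(dots) == 0L) return(cfg)
  nms <- names(dots)
  if (is.null(nms) || any(nms == ""))
    stop("config overrides must be named")
  for (i in seq_along(dots)) {
    key <- strsplit(nms[i], ".", fixed = TRUE)[[1L]]
    if (length(key) == 1L && is.list(dots[[i]])) {
      for (sub in names(dots[[i]]))
        cfg <- assign_config_key(cfg, c(key, sub), dots[[i]][[sub]])
    } else {
      cfg <- assign_config_key(cfg, key, dots[[i]])
    }
  }
  cfg
}

assign_config_key <- function(cfg, key, value) {
  if (length(key) == 1L && key == "seed") {
    cfg$seed <- as.integer(value)
    return(cfg)
  }
  if (length(key) != 2L || is.null(cfg[[key[1L]]]) ||
      !(key[2L] %in% names(cfg[[key[1L]]])))
    stop("unknown configuration key: ", paste(key, collapse = "."))
  mode_old <- storage.mode(cfg[[key[1L]]][[key[2L]]])
  cfg[[key[1L]]][[key[2L]]] <- if (mode_old == "integer")
    as.integer(value) else as.numeric(value)
  cfg
}

validate_config <- function(cfg) {
  nw <- cfg$network
  if (nw$cluster_participation < 1)
    stop("cluster participation must be at least 1")
  if (nw$cluster_participation > nw$n_clusters)
    stop("cluster participation cannot exceed the number of clusters")
  if (nw$p_ee <= 0 || nw$p_ee >= 1 || nw$p_ei_ie <= 0 || nw$p_ei_ie >= 1)
    stop("connection probabilities must lie strictly in (0, 1)")
  if (abs(cfg$cells$tau_m - cfg$cells$c_m / cfg$cells$g_l * 1000) > 1e-6)
    stop("tau_m must equal c_m / g_l")
  if (cfg$inputs$r_g * cfg$inputs$input_dt / 1000 > 1)
    stop("input rate times the input grid step exceeds 1")
  ratio <- cfg$inputs$input_dt / cfg$cells$dt
  if (ratio < 1 - 1e-9 || abs(round(ratio) - ratio) > 1e-9)
    stop("dt must evenly divide the input grid step")
  cfg
}

#' Load a configuration file
#'
#' Reads a YAML parameter file and merges it over the fiducial defaults.
#' Unknown keys are rejected with the offending key named. An empty file
#' yields the full fiducial configuration.
#'
#' @param path path to a YAML file whose top level mirrors the sections of
#'   [ppn_config()] (`seed`, `network`, `cells`, `inputs`, `session`,
#'   `analysis`).
#' @return a validated `ppn_config`.
#' @export
load_config <- function(path) {
  # keep YAML-1.1 boolean-like scalars (n, y, yes, no) as literal strings:
  # `n` is a parameter name here, not a boolean
  keep <- function(x) x
  raw <- yaml::read_yaml(path, handlers = list("bool#yes" = keep,
                                               "bool#no" = keep))
  if (is.null(raw)) raw <- list()
  cfg <- ppn_config()
  if (!is.null(raw$seed)) {
    cfg$seed <- as.integer(raw$seed)
    raw$seed <- NULL
  }
  for (section in names(raw)) {
    entries <- raw[[section]]
    if (!is.list(entries))
      stop("top-level key '", section, "' must be a section of named values")
    for (key in names(entries))
      cfg <- assign_config_key(cfg, c(section, key), entries[[key]])
  }
  validate_config(cfg)
}

#' Derive a named sub-stream seed
#'
#' Hashes the master seed together with a path of names (e.g.
#' `"clusters"`, `c("weights", "env1")`) into a 31-bit integer seed, so each
#' module draws from an independently reproducible stream.
#'
#' @param seed master integer seed.
#' @param ... name components identifying the stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(c(format(seed), unlist(list(...))), collapse = "/")
  h <- 5381
  for (ch in utf8ToInt(key)) h <- (h * 33 + ch) %% 2147483629
  as.integer(h)
}

# Evaluate `code` under a given seed, restoring the caller's RNG state.
with_stream <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
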