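#' Location-cue input rates at a track position
#'
#' The two spatially modulated Poisson inputs peak at opposite ends of the
#' 1 m track and vary linearly to zero at the far end, so their rates sum
#' to the peak rate everywhere. The left cue peaks at `x = 0`.
#'
#' @param x track fraction(s) in `[0, 1]`.
#' @param r_g peak Poisson rate (Hz).
#' @return a matrix with columns `left` and `right` (Hz).
#' @export
location_cue_rates <- function(x, r_g = 5000) {
  if (any(x < 0 | x > 1)) stop("track fraction must lie in [0, 1]")
  cbind(left = r_g * (1 - x), right = r_g * x)
}

# Steady-state-approximating initial feed-forward conductance: per active
# input, a Gaussian draw with mean w * rate * tauE and shot-noise SD
# w * sqrt(rate * tauE / 2); summed over inputs and truncated at zero.
# `w_list` holds per-neuron weight vectors (nS), `rates` the matching
# per-input rates (Hz). Uses the current RNG state.
initial_input_conductance <- function(w_list, rates, tau_e_ms) {
  n <- length(w_list[[1L]])
  tau_s <- tau_e_ms / 1000
  g <- numeric(n)
  for (k in seq_along(w_list)) {
    rate <- rates[[k]]
    if (rate <= 0) next
    w <- w_list[[k]]
    g <- g + pmax(0, stats::rnorm(n, w * rate * tau_s,
                                  w * sqrt(rate * tau_s / 2)))
  }
  g
}

cell_param_vector <- function(cells) {
  # capacitance in pF so that (nS * mV) * ms / pF = mV
  c(cells$g_l, cells$e_l, cells$e_e, cells$e_i, cells$e_sra, cells$v_th,
    cells$v_reset, cells$c_m * 1000, cells$tau_e, cells$tau_i, cells$tau_sra,
    cells$delta_sra / 1000)
}

# Outgoing adjacency lists (1-based targets, conductance steps in nS) for
# the C++ integrator. E cells project to E and I targets; I cells to E.
conn_adjacency <- function(conn, network_cfg) {
  n_e <- conn$n_e
  n_i <- conn$n_i
  w_ee <- network_cfg$w_ee / 1000
  w_ei <- network_cfg$w_ei / 1000
  w_ie <- network_cfg$w_ie / 1000
  targets <- vector("list", n_e + n_i)
  target_w <- vector("list", n_e + n_i)
  for (i in seq_len(n_e)) {
    te <- which(conn$ee[i, ])
    ti <- which(conn$ei[i, ])
    targets[[i]] <- c(te, n_e + ti)
    target_w[[i]] <- c(rep(w_ee, length(te)), rep(w_ei, length(ti)))
  }
  for (j in seq_len(n_i)) {
    te <- which(conn$ie[j, ])
    targets[[n_e + j]] <- te
    target_w[[n_e + j]] <- rep(w_ie, length(te))
  }
  list(targets = targets, target_w = target_w)
}

#' Low-level LIF network integration
#'
#' Direct access to the forward-Euler integrator for arbitrary hand-built
#' networks and inputs; [simulate_session()] is the session-level
#' interface. All conductance arguments are in nS, times in seconds.
#' Feed-forward Poisson inputs are realized as Bernoulli events on a
#' fixed input grid (probability `rate * input_dt` per 0.1 ms tick); the
#' grid is decoupled from the integration step, so refining `dt` leaves
#' the input realization statistics unchanged.
#'
#' @param config a [ppn_config()] supplying the cell parameters and `dt`.
#' @param n neuron count.
#' @param is_excit logical vector; inhibitory spikes step `gI`, excitatory
#'   spikes step `gE` of their targets.
#' @param targets,target_w outgoing adjacency lists (1-based indices,
#'   conductance steps in nS); `NULL` for an unconnected population.
#' @param w_left,w_right,w_context per-neuron feed-forward conductance
#'   steps (nS) for the three inputs.
#' @param duration_s simulated time (s).
#' @param session `"sleep"` (location cues silent) or `"run"`.
#' @param direction `+1` for x: 0 to 1 within a lap, `-1` reversed.
#' @param lap_s traversal duration (s).
#' @param r_g peak Poisson rate (Hz); 0 silences all inputs.
#' @param v0 initial membrane potentials (mV; default leak reversal).
#' @param gext0 initial feed-forward conductances (nS; default 0).
#' @param record_idx neuron indices whose membrane potential to record.
#' @param record_every record every this many steps.
#' @param seed integer seed (set immediately before integration).
#' @return list with `neuron`, `time` (s), `v_final`, and optionally
#'   `v_trace`.
#' @export
lif_integrate <- function(config, n, is_excit = rep(TRUE, n),
                          targets = NULL, target_w = NULL,
                          w_left = numeric(n), w_right = numeric(n),
                          w_context = numeric(n),
                          duration_s, session = "sleep", direction = 1L,
                          lap_s = 2, r_g = 0,
                          v0 = NULL, gext0 = NULL,
                          record_idx = integer(), record_every = 10L,
                          seed = NULL) {
  if (is.null(targets)) {
    targets <- rep(list(integer()), n)
    target_w <- rep(list(numeric()), n)
  }
  if (is.null(v0)) v0 <- rep(config$cells$e_l, n)
  if (is.null(gext0)) gext0 <- numeric(n)
  kind <- match.arg(session, c("sleep", "run"))
  run_body <- function() {
    lif_simulate_cpp(as.integer(n), is_excit, targets, target_w,
                     as.numeric(w_left), as.numeric(w_right),
                     as.numeric(w_context),
                     duration_s, config$cells$dt,
                     if (kind == "run") 1L else 0L,
                     as.integer(direction), lap_s, r_g,
                     cell_param_vector(config$cells),
                     config$inputs$input_dt,
                     as.numeric(v0), as.numeric(gext0),
                     as.integer(record_idx), as.integer(record_every))
  }
  if (is.null(seed)) run_body() else with_stream(seed, run_body())
}

#' Simulate one session of a clustered network
#'
#' Runs the conductance-based LIF dynamics of a [build_network()]
#' realization for either a linear-track run session (five constant-speed
#' traversals by default, location cues active, context cue scaled by
#' `f_e_awake` / `f_i_awake`) or a sleep session (location cues silent,
#' context cue scaled by `f_e_sleep` / `f_i_sleep`, sleep-specific context
#' weights). Feed-forward conductances start at Gaussian approximations of
#' their steady state; recurrent and adaptation conductances start at zero
#' and membrane potentials at the leak reversal.
#'
#' @param network a [build_network()] object.
#' @param session `"run"` or `"sleep"`.
#' @param env environment index (run sessions).
#' @param direction `"right"` (x: 0 to 1; the left cue decreases along the
#'   lap) or `"left"` (x: 1 to 0).
#' @param speed traversal speed multiplier (run sessions; `2` halves the
#'   lap duration).
#' @param n_laps number of traversals (default from the configuration).
#' @param duration_s sleep duration override (s).
#' @param label extra seed label so repeated sessions get independent
#'   noise.
#' @param seed explicit integer seed (overrides the derived sub-stream).
#' @return class `spike_record`: list with `spikes` (data.frame `neuron`,
#'   `time` in s, sorted by time), `duration`, `n`, `n_e`, and `meta`.
#' @export
simulate_session <- function(network, session = c("run", "sleep"),
                             env = 1L, direction = c("right", "left"),
                             speed = 1, n_laps = NULL, duration_s = NULL,
                             label = "", seed = NULL) {
  session <- match.arg(session)
  direction <- match.arg(direction)
  config <- network$config
  inp <- config$inputs
  n <- config$network$n
  n_e <- network$conn$n_e
  adj <- conn_adjacency(network$conn, config$network)
  zeros <- numeric(n)
  if (session == "run") {
    wset <- network$weights[[env]]
    w_left <- c(wset$w_left, numeric(n - n_e)) / 1000
    w_right <- c(wset$w_right, numeric(n - n_e)) / 1000
    scale <- ifelse(network$is_excit, inp$f_e_awake, inp$f_i_awake)
    w_context <- wset$w_context * scale / 1000
    if (is.null(n_laps)) n_laps <- config$session$n_laps
    lap_s <- config$session$lap_s / speed
    duration_s <- n_laps * lap_s
    dir_sign <- if (direction == "right") 1L else -1L
    x0 <- if (direction == "right") 0 else 1
    rates0 <- location_cue_rates(x0, inp$r_g)
    w_list <- list(w_left, w_right, w_context)
    rates <- c(rates0[1, "left"], rates0[1, "right"], inp$r_g)
  } else {
    w_left <- zeros; w_right <- zeros
    scale <- ifelse(network$is_excit, inp$f_e_sleep, inp$f_i_sleep)
    w_context <- network$w_context_sleep * scale / 1000
    if (is.null(duration_s)) duration_s <- config$session$sleep_s
    lap_s <- config$session$lap_s
    dir_sign <- 1L
    w_list <- list(w_context)
    rates <- inp$r_g
  }
  if (is.null(seed))
    seed <- substream_seed(config$seed, "sim", session, env, direction,
                           speed, label)
  res <- with_stream(seed, {
    gext0 <- initial_input_conductance(w_list, rates, config$cells$tau_e)
    lif_integrate(config, n, network$is_excit, adj$targets, adj$target_w,
                  w_left, w_right, w_context, duration_s,
                  session = if (session == "run") "run" else "sleep",
                  direction = dir_sign, lap_s = lap_s, r_g = inp$r_g,
                  gext0 = gext0)
  })
  spikes <- data.frame(neuron = res$neuron, time = res$time)
  spikes <- spikes[order(spikes$time, spikes$neuron), , drop = FALSE]
  rownames(spikes) <- NULL
  structure(list(spikes = spikes, duration = duration_s, n = n, n_e = n_e,
                 meta = list(session = session, env = env,
                             direction = direction, speed = speed,
                             n_laps = if (session == "run") n_laps else NA,
                             lap_s = lap_s, label = label, seed = seed)),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  e_rate <- sum(x$spikes$neuron <= x$n_e) / x$n_e / x$duration
  cat(sprintf("Spike record: %s session, %.1f s, %d spikes (E-cell mean rate %.2f Hz)\n",
              x$meta$session, x$duration, nrow(x$spikes), e_rate))
  invisible(x)
}

#' Mean firing rates of a spike record
#' @param record a `spike_record`.
#' @return numeric vector of per-neuron rates (Hz), length `n`.
#' @export
mean_rates <- function(record) {
  tabulate(record$spikes$neuron, nbins = record$n) / record$duration
}
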