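#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Conductance-based LIF network integrator (forward Euler).
// Units: mV, nS, pF, ms internally; spike times returned in seconds.
// params vector layout (all scalars):
//  0 gL, 1 EL, 2 EE, 3 EI, 4 ESRA, 5 Vth, 6 Vreset, 7 Cm,
//  8 tauE, 9 tauI, 10 tauSRA, 11 deltaSRA
// session_kind: 0 = sleep (location cues silent), 1 = run.
// direction: +1 position goes 0 -> 1 within a lap, -1 reversed.
// Feed-forward inputs are independent per-neuron Poisson trains realized as
// Bernoulli events on a fixed input grid (probability rate * input_dt per
// grid tick). The input grid is decoupled from the integration step, so
// refining dt leaves the input process statistics unchanged.
// [[Rcpp::export]]
List lif_simulate_cpp(int n,
                      LogicalVector is_excit,
                      List targets,      // per-neuron outgoing target indices (1-based)
                      List target_w,     // matching conductance steps (nS)
                      NumericVector w_left,
                      NumericVector w_right,
                      NumericVector w_context,
                      double duration_s,
                      double dt_ms,
                      int session_kind,
                      int direction,
                      double lap_s,
                      double rG_hz,
                      NumericVector params,
                      double input_dt_ms,
                      NumericVector v0,
                      NumericVector gext0,
                      IntegerVector record_idx,
                      int record_every) {
  const double gL = params[0], EL = params[1], EE = params[2], EI = params[3],
               ESRA = params[4], Vth = params[5], Vreset = params[6],
               Cm = params[7], tauE = params[8], tauI = params[9],
               tauSRA = params[10], dSRA = params[11];
  const double dt_s = dt_ms / 1000.0;
  const long nsteps = (long)std::floor(duration_s / dt_s + 0.5);
  const double decE = std::exp(-dt_ms / tauE);
  const double decI = std::exp(-dt_ms / tauI);
  const double decS = std::exp(-dt_ms / tauSRA);
  const int sub = (int)std::floor(input_dt_ms / dt_ms + 0.5);
  if (sub < 1 || std::fabs(sub * dt_ms - input_dt_ms) > 1e-9)
    stop("integration step must evenly divide the input grid step");
  const double input_dt_s = input_dt_ms / 1000.0;
  const double p_ctx = rG_hz * input_dt_s;
  const bool run = (session_kind == 1);

  std::vector<double> V(v0.begin(), v0.end());
  std::vector<double> gE(n, 0.0), gI(n, 0.0), gS(n, 0.0);
  std::vector<double> gX(gext0.begin(), gext0.end());

  // flatten adjacency for speed
  std::vector< std::vector<int> > tg(n);
  std::vector< std::vector<double> > tw(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector ti = targets[i];
    NumericVector wi = target_w[i];
    tg[i].assign(ti.begin(), ti.end());
    tw[i].assign(wi.begin(), wi.end());
  }

  std::vector<int> spk_id; std::vector<double> spk_t;
  spk_id.reserve(1 << 16); spk_t.reserve(1 << 16);
  std::vector<int> spikers; spikers.reserve(64);

  const int nrec = record_idx.size();
  long nrec_steps = (nrec > 0) ? (nsteps / record_every + 1) : 0;
  NumericMatrix vrec(nrec > 0 ? nrec : 1, nrec > 0 ? nrec_steps : 1);
  long rec_col = 0;
  if (nrec > 0) {
    for (int r = 0; r < nrec; ++r) vrec(r, 0) = V[record_idx[r] - 1];
    rec_col = 1;
  }

  RNGScope scope;
  for (long step = 0; step < nsteps; ++step) {
    const bool input_tick = (step % sub == 0);
    double p_left = 0.0, p_right = 0.0;
    if (run && input_tick) {
      double laps_done = step * dt_s / lap_s;
      double frac = laps_done - std::floor(laps_done);
      double x = (direction > 0) ? frac : 1.0 - frac;
      p_left = rG_hz * (1.0 - x) * input_dt_s;
      p_right = rG_hz * x * input_dt_s;
    }
    spikers.clear();
    for (int i = 0; i < n; ++i) {
      gE[i] *= decE; gI[i] *= decI; gS[i] *= decS; gX[i] *= decE;
      if (input_tick) {
        if (run && is_excit[i]) {
          if (unif_rand() < p_left)  gX[i] += w_left[i];
          if (unif_rand() < p_right) gX[i] += w_right[i];
        }
        if (p_ctx > 0.0 && unif_rand() < p_ctx) gX[i] += w_context[i];
      }
      double v = V[i];
      double dv = (-gL * (v - EL) - gE[i] * (v - EE) - gI[i] * (v - EI)
                   - gS[i] * (v - ESRA) - gX[i] * (v - EE)) * (dt_ms / Cm);
      v += dv;
      if (v >= Vth) {
        spk_id.push_back(i + 1);
        spk_t.push_back((step + 1) * dt_s);
        v = Vreset;
        gS[i] += dSRA;
        spikers.push_back(i);
      }
      V[i] = v;
      if (v > 100.0 || v < -200.0)
        stop("membrane potential diverged (neuron %d, t = %f s)", i + 1,
             step * dt_s);
    }
    for (size_t s = 0; s < spikers.size(); ++s) {
      int i = spikers[s];
      bool exc = is_excit[i];
      const std::vector<int>& ti = tg[i];
      const std::vector<double>& wi = tw[i];
      for (size_t j = 0; j < ti.size(); ++j) {
        if (exc) gE[ti[j] - 1] += wi[j]; else gI[ti[j] - 1] += wi[j];
      }
    }
    if (nrec > 0 && ((step + 1) % record_every == 0) && rec_col < nrec_steps) {
      for (int r = 0; r < nrec; ++r) vrec(r, rec_col) = V[record_idx[r] - 1];
      ++rec_col;
    }
  }

  List out = List::create(
    _["neuron"] = wrap(spk_id),
    _["time"] = wrap(spk_t),
    _["v_final"] = wrap(V));
  if (nrec > 0) out["v_trace"] = vrec;
  return out;
}

// Mean shortest directed path length over all ordered pairs (BFS from each
// node). Returns c(mean over reachable pairs, n reachable, n ordered pairs).
// [[Rcpp::export]]
NumericVector bfs_mean_path_cpp(List adj, int n) {
  std::vector< std::vector<int> > tg(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector ti = adj[i];
    tg[i].assign(ti.begin(), ti.end());
  }
  double total = 0.0; double nreach = 0.0;
  std::vector<int> dist(n);
  std::queue<int> q;
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      const std::vector<int>& ti = tg[u];
      for (size_t j = 0; j < ti.size(); ++j) {
        int v = ti[j] - 1;
        if (dist[v] < 0) { dist[v] = dist[u] + 1; q.push(v); }
      }
    }
    for (int v = 0; v < n; ++v) {
      if (v != s && dist[v] > 0) { total += dist[v]; nreach += 1.0; }
    }
  }
  double npairs = (double)n * (n - 1);
  return NumericVector::create(nreach > 0 ? total / nreach : NA_REAL,
                               nreach, npairs);
}
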