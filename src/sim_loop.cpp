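#include <Rcpp.h>
using namespace Rcpp;

// Symmetry measure on the current weights; pairs with u = 0 are excluded.
static double s_measure(const NumericMatrix& w) {
  int n = w.nrow();
  double acc = 0.0;
  int cnt = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double u = w(i, j) + w(j, i);
      if (u > 0.0) {
        acc += std::fabs(w(i, j) - w(j, i)) / u;
        ++cnt;
      }
    }
  }
  if (cnt == 0) return NA_REAL;
  return 1.0 - acc / cnt;
}

// Leaky integrate-and-fire network with escape noise and triplet STDP.
//
// W0: initial weights, w(i, j) = connection from presynaptic j onto
// postsynaptic i. mask: true entries are permanently disconnected and are
// never updated. extSteps: per neuron, sorted 1-based step indices of
// external events (duplicates = multiple events in one step).
//
// Per step: traces and membrane decay by their exact exponential factors;
// synaptic impulses from spikes delaySteps ago and external impulses are
// added; spikes are drawn from the escape-noise probability; the triplet
// STDP update reads the trace values before this step's increments; spiked
// neurons' traces are then incremented (reset-to-1 or +1) and their
// membrane reset.
// [[Rcpp::export]]
List sim_loop_cpp(NumericMatrix W0, LogicalMatrix mask, List extSteps,
                  int nSteps, double dt, double tauM, double vRest,
                  double vTheta, double jSyn, double jExt, double escapeRate,
                  double deltaU, int delaySteps, double tauR1, double tauR2,
                  double tauO1, double tauO2, double a2p, double a3p,
                  double a2m, double a3m, double eta, double wMin,
                  double wMax, bool resetTraces, int recordEvery) {
  int n = W0.nrow();
  NumericMatrix w = clone(W0);

  double decayM = std::exp(-dt / tauM);
  double dR1 = std::exp(-dt / tauR1), dR2 = std::exp(-dt / tauR2);
  double dO1 = std::exp(-dt / tauO1), dO2 = std::exp(-dt / tauO2);

  std::vector<double> V(n, vRest), r1(n, 0.0), r2(n, 0.0), o1(n, 0.0),
      o2(n, 0.0);

  // ring buffer of spike flags for the synaptic delivery delay
  int ring = delaySteps + 1;
  std::vector<std::vector<int> > spikeBuf(ring, std::vector<int>(n, 0));

  // per-neuron cursors into the external event lists
  std::vector<IntegerVector> ext(n);
  std::vector<int> cursor(n, 0);
  for (int i = 0; i < n; ++i) ext[i] = as<IntegerVector>(extSteps[i]);

  std::vector<std::vector<int> > raster(n);
  std::vector<int> recSteps;
  std::vector<double> recS;
  recSteps.push_back(0);
  recS.push_back(s_measure(w));

  std::vector<int> spiked(n, 0);

  for (int t = 1; t <= nSteps; ++t) {
    // exponential decay of traces and membrane
    for (int i = 0; i < n; ++i) {
      r1[i] *= dR1;
      r2[i] *= dR2;
      o1[i] *= dO1;
      o2[i] *= dO2;
      V[i] = vRest + (V[i] - vRest) * decayM;
    }

    // synaptic impulses from spikes delaySteps ago
    const std::vector<int>& delayed = spikeBuf[(t - delaySteps) % ring < 0
        ? ((t - delaySteps) % ring + ring) : (t - delaySteps) % ring];
    for (int j = 0; j < n; ++j) {
      if (delayed[j]) {
        for (int i = 0; i < n; ++i) {
          if (i != j && w(i, j) > 0.0) V[i] += jSyn * w(i, j);
        }
      }
    }

    // external impulses
    for (int i = 0; i < n; ++i) {
      while (cursor[i] < ext[i].size() && ext[i][cursor[i]] == t) {
        V[i] += jExt;
        ++cursor[i];
      }
    }

    // escape-noise spike generation
    int any = 0;
    for (int i = 0; i < n; ++i) {
      double arg = (V[i] - vTheta) / deltaU;
      if (arg > 30.0) arg = 30.0;
      double rate = escapeRate * std::exp(arg);
      double pfire = 1.0 - std::exp(-rate * dt);
      spiked[i] = (unif_rand() < pfire) ? 1 : 0;
      any += spiked[i];
    }

    if (any > 0 && eta != 0.0) {
      // triplet STDP, reading traces before this step's increments
      for (int k = 0; k < n; ++k) {
        if (!spiked[k]) continue;
        double ltpGain = eta * (a2p + a3p * o2[k]);
        double ltdGain = eta * (a2m + a3m * r2[k]);
        for (int j = 0; j < n; ++j) {
          if (j == k) continue;
          if (!mask(k, j)) {  // potentiate incoming j -> k
            double nw = w(k, j) + r1[j] * ltpGain;
            w(k, j) = nw > wMax ? wMax : nw;
          }
          if (!mask(j, k)) {  // depress outgoing k -> j
            double nw = w(j, k) - o1[j] * ltdGain;
            w(j, k) = nw < wMin ? wMin : nw;
          }
        }
      }
    }

    // trace increments, membrane reset, raster
    std::vector<int>& slot = spikeBuf[t % ring];
    for (int i = 0; i < n; ++i) {
      slot[i] = spiked[i];
      if (spiked[i]) {
        if (resetTraces) {
          r1[i] = 1.0; r2[i] = 1.0; o1[i] = 1.0; o2[i] = 1.0;
        } else {
          r1[i] += 1.0; r2[i] += 1.0; o1[i] += 1.0; o2[i] += 1.0;
        }
        V[i] = vRest;
        raster[i].push_back(t);
      }
    }

    if (t % recordEvery == 0 || t == nSteps) {
      recSteps.push_back(t);
      recS.push_back(s_measure(w));
    }
  }

  List rasterOut(n);
  for (int i = 0; i < n; ++i) rasterOut[i] = wrap(raster[i]);

  return List::create(_["steps"] = wrap(recSteps), _["s"] = wrap(recS),
                      _["weights"] = w, _["raster"] = rasterOut);
}
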