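#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler simulation of a leaky integrate-and-fire network driven by
// piecewise-constant generating currents at electrode-mapped neurons.
// Weights arrive as the CSC slots of the *transposed* weight matrix, so a
// column holds the outgoing synapses of one presynaptic neuron. Synapses
// are delta-current: a presynaptic spike deflects each target membrane by
// w * q / Cm (mV) after a uniform conduction delay.
//
// [[Rcpp::export(name = ".lifSimulate")]]
List lifSimulate(NumericVector v0, NumericVector refrac0,
                 IntegerVector Wtp, IntegerVector Wti, NumericVector Wtx,
                 NumericMatrix featCur, IntegerVector elecMap,
                 double dtFeat, double duration,
                 double vTh, double eL, double vReset, double tauM,
                 double cM, double tRef, double dt,
                 double delay, double synapticCharge) {
  const int n = v0.size();
  const int nFeat = featCur.ncol();
  const int nSteps = (int)std::lround(duration / dt);
  const int delaySteps = std::max(0, (int)std::lround(delay / dt));
  const int bufLen = delaySteps + 1;

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> refrac(refrac0.begin(), refrac0.end());
  std::vector<double> pending((size_t)bufLen * n, 0.0);
  std::vector<double> inj(n, 0.0);
  std::vector<int> spikeNeuron;
  std::vector<double> spikeTime;

  const double leak = dt / tauM;
  int lastFeat = -1;
  for (int s = 0; s < nSteps; ++s) {
    const double t = s * dt;
    int fIdx = (int)(t / dtFeat);
    if (fIdx >= nFeat) fIdx = nFeat - 1;
    if (fIdx != lastFeat) {
      std::fill(inj.begin(), inj.end(), 0.0);
      for (int k = 0; k < elecMap.size(); ++k)
        inj[elecMap[k] - 1] += featCur(k, fIdx);
      lastFeat = fIdx;
    }
    double *slot = &pending[(size_t)(s % bufLen) * n];
    for (int i = 0; i < n; ++i) {
      if (refrac[i] > 0.0) {
        refrac[i] -= dt;
        v[i] = vReset;
        slot[i] = 0.0;
        continue;
      }
      v[i] += slot[i];                       // delayed synaptic charge (mV)
      slot[i] = 0.0;
      v[i] += -(v[i] - eL) * leak + inj[i] / cM * dt;
      if (v[i] >= vTh) {
        spikeNeuron.push_back(i + 1);
        spikeTime.push_back(t);
        v[i] = vReset;
        refrac[i] = tRef;
        const int dslot = (s + delaySteps) % bufLen;
        double *target = &pending[(size_t)dslot * n];
        for (int p = Wtp[i]; p < Wtp[i + 1]; ++p)
          target[Wti[p]] += Wtx[p] * synapticCharge / cM;
      }
    }
  }
  return List::create(_["neuron"] = wrap(spikeNeuron),
                      _["time"] = wrap(spikeTime),
                      _["v"] = wrap(v), _["refrac"] = wrap(refrac));
}

// Additive nearest-neighbour pair-based STDP over one window's spikes.
// Weights arrive as the CSC slots of W[pre, post] (columns = postsynaptic
// neuron). spikes/offsets hold the concatenated sorted per-neuron spike
// times: neuron i's spikes occupy [offsets[i-1], offsets[i]) (0-based).
//
// [[Rcpp::export(name = ".stdpUpdate")]]
NumericVector stdpUpdate(IntegerVector Wp, IntegerVector Wi, NumericVector Wx,
                         NumericVector spikes, IntegerVector offsets,
                         double lambdaRate, double tauPlus, double tauMinus,
                         double asymmetry, double wMax) {
  const int nPost = Wp.size() - 1;
  NumericVector out = clone(Wx);
  for (int post = 0; post < nPost; ++post) {
    const int sPost0 = offsets[post], sPost1 = offsets[post + 1];
    if (sPost1 == sPost0) {
      // no post spikes: only depression of pre spikes is possible, and it
      // needs a preceding post spike, so nothing changes on this column
      // unless pre spikes exist with post spikes — none here.
      continue;
    }
    for (int p = Wp[post]; p < Wp[post + 1]; ++p) {
      const int pre = Wi[p];
      const int sPre0 = offsets[pre], sPre1 = offsets[pre + 1];
      if (sPre1 == sPre0) continue;
      double dw = 0.0;
      // potentiation: each post spike pairs with the nearest earlier pre
      int j = sPre0;
      for (int k = sPost0; k < sPost1; ++k) {
        const double tp = spikes[k];
        while (j < sPre1 && spikes[j] < tp) ++j;
        if (j > sPre0) dw += lambdaRate * wMax *
          std::exp(-(tp - spikes[j - 1]) / tauPlus);
      }
      // depression: each pre spike pairs with the nearest earlier post
      j = sPost0;
      for (int k = sPre0; k < sPre1; ++k) {
        const double tp = spikes[k];
        while (j < sPost1 && spikes[j] < tp) ++j;
        if (j > sPost0) dw -= asymmetry * lambdaRate * wMax *
          std::exp(-(tp - spikes[j - 1]) / tauMinus);
      }
      double w = out[p] + dw;
      if (w < 0.0) w = 0.0;
      if (w > wMax) w = wMax;
      out[p] = w;
    }
  }
  return out;
}
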