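// Exact piecewise-exponential gate trajectories under piecewise-constant
// voltage commands, with reverse-mode sensitivity coefficients for the
// per-segment steady states and time constants.
//
// Within a segment the command voltage is constant, so each gate obeys
//   m(t) = a_s + (M_s - a_s) * exp(-(t - t_s)/tau_s)
// where a_s = m_inf of the segment, M_s the gate value at the segment start.
// The observable is scale_s * prod_i m_i^{n_i}.

#include <Rcpp.h>
using namespace Rcpp;

static inline double safe_pow(double x, int p) {
  if (p == 0) return 1.0;
  if (p == 1) return x;
  return std::pow(x, p);
}

// [[Rcpp::export]]
List sweep_kernel_cpp(NumericVector seg_start, NumericVector seg_dur,
                      NumericVector scale, NumericMatrix minf,
                      NumericMatrix tau, IntegerVector powers,
                      NumericVector obs_t, IntegerVector obs_seg,
                      NumericVector obs_y, bool want_grad) {
  const int S = seg_start.size();
  const int G = minf.ncol();
  const int n = obs_t.size();

  // forward: gate values at observation points and segment starts
  NumericMatrix m_obs(n, G);
  NumericMatrix M(S, G);            // gate value at segment start
  for (int g = 0; g < G; ++g) {
    double Mcur = minf(0, g);
    for (int s = 0; s < S; ++s) {
      M(s, g) = Mcur;
      Mcur = minf(s, g) + (Mcur - minf(s, g)) * std::exp(-seg_dur[s] / tau(s, g));
    }
  }
  for (int p = 0; p < n; ++p) {
    int s = obs_seg[p] - 1;
    for (int g = 0; g < G; ++g) {
      double a = minf(s, g);
      double e = std::exp(-(obs_t[p] - seg_start[s]) / tau(s, g));
      m_obs(p, g) = a + (M(s, g) - a) * e;
    }
  }

  NumericVector pred(n), resid(n);
  double ssr = 0.0;
  for (int p = 0; p < n; ++p) {
    int s = obs_seg[p] - 1;
    double prod = 1.0;
    for (int g = 0; g < G; ++g) prod *= safe_pow(m_obs(p, g), powers[g]);
    pred[p] = scale[s] * prod;
    double r = obs_y[p] - pred[p];
    resid[p] = r;
    ssr += r * r;
  }

  if (!want_grad) {
    return List::create(_["pred"] = pred, _["resid"] = resid, _["ssr"] = ssr,
                        _["gating"] = m_obs);
  }

  // reverse pass: A(g,s) = d(0.5*ssr)/d minf(s,g); B(g,s) likewise for tau
  NumericMatrix A(G, S), B(G, S);
  std::vector<double> D(S), E(S);   // dM_s/da_q, dM_s/dtau_q for q <= s
  for (int g = 0; g < G; ++g) {
    std::fill(D.begin(), D.end(), 0.0);
    std::fill(E.begin(), E.end(), 0.0);
    D[0] = 1.0;                     // M_1 = a_1 (steady state at the holding level)
    int p = 0;
    for (int s = 0; s < S; ++s) {
      double a = minf(s, g), tg = tau(s, g);
      double sum_e = 0.0, dirA = 0.0, dirB = 0.0;
      // observations are ordered by time, hence by segment
      while (p < n && obs_seg[p] - 1 == s) {
        double dt = obs_t[p] - seg_start[s];
        double e = std::exp(-dt / tg);
        // d(0.5 ssr)/dm = -r * scale * n_g * m^{n_g-1} * prod_others
        double others = 1.0;
        for (int h = 0; h < G; ++h)
          if (h != g) others *= safe_pow(m_obs(p, h), powers[h]);
        double gp = -resid[p] * scale[s] * powers[g] *
                    safe_pow(m_obs(p, g), powers[g] - 1) * others;
        dirA += gp * (1.0 - e);
        dirB += gp * (M(s, g) - a) * e * dt / (tg * tg);
        sum_e += gp * e;
        ++p;
      }
      A(g, s) += dirA;
      B(g, s) += dirB;
      for (int q = 0; q <= s; ++q) {
        A(g, q) += sum_e * D[q];
        B(g, q) += sum_e * E[q];
      }
      // propagate dM/d(params) to the next segment start
      double e_end = std::exp(-seg_dur[s] / tg);
      for (int q = 0; q <= s; ++q) { D[q] *= e_end; E[q] *= e_end; }
      E[s] += (M(s, g) - a) * e_end * seg_dur[s] / (tg * tg);
      D[s] += (1.0 - e_end);
    }
    // reset observation pointer for the next gate
    p = 0;
  }

  return List::create(_["pred"] = pred, _["resid"] = resid, _["ssr"] = ssr,
                      _["A"] = A, _["B"] = B, _["gating"] = m_obs);
}
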