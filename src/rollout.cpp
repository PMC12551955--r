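#include <Rcpp.h>
using namespace Rcpp;

// Explicit-Euler rollout of the stage/genotype-structured dynamics.
// This is the single implementation of the discrete update used both by
// rollout_discrete() and inside the decision-model objective, so the
// direct-transcription consistency check is exact by construction.
//
// State layout per node (length S = 4G + G^2):
//   E[0..G), L[G..2G), P[2G..3G), M[3G..4G), F[4G..4G+G^2)
// with mated females F column-major: F[gf + G*gm] (own genotype gf, mate gm).
//
// rates[[n]] : n_days x 8 matrix, columns (nu, thE, muE, thL, muL, thP, muP, muA)
// probs      : G*G*G inheritance array, probs[gf + G*gm + G*G*go]
// releases[[n]] : n_days x G matrix of adult-male impulses (start of day)
//
// Reported state at day t includes that day's release impulse.
// [[Rcpp::export]]
List rollout_core(NumericVector init, int n_days, int n_sub, int G,
                  List rates, NumericVector probs,
                  NumericVector s_f, NumericVector s_m,
                  NumericVector eta, NumericVector beta,
                  NumericVector K, NumericMatrix mig,
                  List releases) {
  const int n_nodes = rates.size();
  const int S = 4 * G + G * G;
  const double dt = 1.0 / n_sub;
  std::vector<double> y(init.begin(), init.end());
  std::vector<double> dy(y.size());
  NumericMatrix out(n_days, n_nodes * S);
  std::vector<NumericMatrix> rt, rel;
  for (int n = 0; n < n_nodes; ++n) {
    rt.push_back(as<NumericMatrix>(rates[n]));
    rel.push_back(as<NumericMatrix>(releases[n]));
  }
  double minstate = 0.0, maxabs = 0.0;
  std::vector<double> B(G), em(G), mf(G);

  for (int t = 0; t < n_days; ++t) {
    for (int n = 0; n < n_nodes; ++n)
      for (int g = 0; g < G; ++g)
        y[n * S + 3 * G + g] += rel[n](t, g);
    for (int i = 0; i < (int)y.size(); ++i) out(t, i) = y[i];
    if (t == n_days - 1) break;

    for (int sub = 0; sub < n_sub; ++sub) {
      std::fill(dy.begin(), dy.end(), 0.0);
      for (int n = 0; n < n_nodes; ++n) {
        const double nu = rt[n](t, 0), thE = rt[n](t, 1), muE = rt[n](t, 2),
                     thL = rt[n](t, 3), muL = rt[n](t, 4), thP = rt[n](t, 5),
                     muP = rt[n](t, 6), muA = rt[n](t, 7);
        double *E = &y[n * S], *L = E + G, *P = L + G, *M = P + G, *F = M + G;
        double *dE = &dy[n * S], *dL = dE + G, *dP = dL + G, *dM = dP + G,
               *dF = dM + G;
        double Ltot = 0.0, denom = 0.0;
        for (int g = 0; g < G; ++g) { Ltot += L[g]; denom += eta[g] * M[g]; }
        // no males -> no new mated females (mating fraction 0)
        for (int g = 0; g < G; ++g)
          mf[g] = denom > 0.0 ? eta[g] * M[g] / denom : 0.0;
        for (int g = 0; g < G; ++g) em[g] = 0.5 * thP * P[g];
        for (int go = 0; go < G; ++go) {
          double b = 0.0;
          for (int gm = 0; gm < G; ++gm)
            for (int gf = 0; gf < G; ++gf)
              b += beta[gf] * F[gf + G * gm] * probs[gf + G * gm + G * G * go];
          B[go] = nu * b;
        }
        const double dd = muL * (1.0 + Ltot / K[n]);
        for (int g = 0; g < G; ++g) {
          dE[g] += B[g] - (thE + muE) * E[g];
          dL[g] += thE * E[g] - (thL + dd) * L[g];
          dP[g] += thL * L[g] - (thP + muP) * P[g];
          dM[g] += s_m[g] * em[g] - muA * M[g];
        }
        for (int gm = 0; gm < G; ++gm)
          for (int gf = 0; gf < G; ++gf)
            dF[gf + G * gm] += s_f[gf] * em[gf] * mf[gm] - muA * F[gf + G * gm];
      }
      // adult-only migration (M and F states); juveniles do not move
      if (n_nodes > 1) {
        for (int a = 0; a < n_nodes; ++a)
          for (int b = 0; b < n_nodes; ++b) {
            if (a == b) continue;
            const double m = mig(a, b);
            if (m <= 0.0) continue;
            for (int g = 0; g < G; ++g) {
              const double fl = m * y[a * S + 3 * G + g];
              dy[a * S + 3 * G + g] -= fl;
              dy[b * S + 3 * G + g] += fl;
            }
            for (int q = 0; q < G * G; ++q) {
              const double fl = m * y[a * S + 4 * G + q];
              dy[a * S + 4 * G + q] -= fl;
              dy[b * S + 4 * G + q] += fl;
            }
          }
      }
      for (int i = 0; i < (int)y.size(); ++i) {
        y[i] += dt * dy[i];
        if (y[i] < minstate) minstate = y[i];
        const double a = std::fabs(y[i]);
        if (a > maxabs) maxabs = a;
      }
    }
  }
  return List::create(_["states"] = out, _["min_state"] = minstate,
                      _["max_abs"] = maxabs);
}

// Forward rollout + discrete-adjoint gradient of the tracking objective
//   J_track = alpha_F * sum_{t in win} sum_{g in wild} (W_g(x_t) - psi W_g(x_1))^2
// with W_g(x) = total mated females of own genotype g (all mates, all nodes),
// differentiated with respect to every possible male release impulse
// (day, node, genotype). Exact reverse-mode differentiation of the Euler
// update above (including the dependence of the target on the day-1 state).
// [[Rcpp::export]]
List rollout_adjoint_core(NumericVector init, int n_days, int n_sub, int G,
                          List rates, NumericVector probs,
                          NumericVector s_f, NumericVector s_m,
                          NumericVector eta, NumericVector beta,
                          NumericVector K, NumericMatrix mig,
                          List releases,
                          IntegerVector win, double psi, double alpha_F,
                          IntegerVector wild_idx) {
  const int n_nodes = rates.size();
  const int S = 4 * G + G * G;
  const int dim = n_nodes * S;
  const double dt = 1.0 / n_sub;
  std::vector<NumericMatrix> rt, rel;
  for (int n = 0; n < n_nodes; ++n) {
    rt.push_back(as<NumericMatrix>(rates[n]));
    rel.push_back(as<NumericMatrix>(releases[n]));
  }
  std::vector<double> y(init.begin(), init.end());
  NumericMatrix out(n_days, dim);
  std::vector<double> store((size_t)(n_days - 1) * n_sub * dim);
  std::vector<double> dy(dim);
  std::vector<double> B(G), em(G), mf(G);
  std::vector<bool> inwin(n_days + 1, false);
  for (int i = 0; i < win.size(); ++i) inwin[win[i]] = true;
  const int n_wild = wild_idx.size();

  // ---- forward sweep, storing every substep start state ----
  double minstate = 0.0, maxabs = 0.0;
  for (int t = 0; t < n_days; ++t) {
    for (int n = 0; n < n_nodes; ++n)
      for (int g = 0; g < G; ++g) y[n * S + 3 * G + g] += rel[n](t, g);
    for (int i = 0; i < dim; ++i) out(t, i) = y[i];
    if (t == n_days - 1) break;
    for (int sub = 0; sub < n_sub; ++sub) {
      double *st = &store[((size_t)t * n_sub + sub) * dim];
      std::copy(y.begin(), y.end(), st);
      std::fill(dy.begin(), dy.end(), 0.0);
      for (int n = 0; n < n_nodes; ++n) {
        const double nu = rt[n](t, 0), thE = rt[n](t, 1), muE = rt[n](t, 2),
                     thL = rt[n](t, 3), muL = rt[n](t, 4), thP = rt[n](t, 5),
                     muP = rt[n](t, 6), muA = rt[n](t, 7);
        double *E = &y[n * S], *L = E + G, *P = L + G, *M = P + G, *F = M + G;
        double *dE = &dy[n * S], *dL = dE + G, *dP = dL + G, *dM = dP + G,
               *dF = dM + G;
        double Ltot = 0.0, denom = 0.0;
        for (int g = 0; g < G; ++g) { Ltot += L[g]; denom += eta[g] * M[g]; }
        for (int g = 0; g < G; ++g)
          mf[g] = denom > 0.0 ? eta[g] * M[g] / denom : 0.0;
        for (int g = 0; g < G; ++g) em[g] = 0.5 * thP * P[g];
        for (int go = 0; go < G; ++go) {
          double b = 0.0;
          for (int gm = 0; gm < G; ++gm)
            for (int gf = 0; gf < G; ++gf)
              b += beta[gf] * F[gf + G * gm] * probs[gf + G * gm + G * G * go];
          B[go] = nu * b;
        }
        const double dd = muL * (1.0 + Ltot / K[n]);
        for (int g = 0; g < G; ++g) {
          dE[g] += B[g] - (thE + muE) * E[g];
          dL[g] += thE * E[g] - (thL + dd) * L[g];
          dP[g] += thL * L[g] - (thP + muP) * P[g];
          dM[g] += s_m[g] * em[g] - muA * M[g];
        }
        for (int gm = 0; gm < G; ++gm)
          for (int gf = 0; gf < G; ++gf)
            dF[gf + G * gm] += s_f[gf] * em[gf] * mf[gm] - muA * F[gf + G * gm];
      }
      if (n_nodes > 1) {
        for (int a = 0; a < n_nodes; ++a)
          for (int b = 0; b < n_nodes; ++b) {
            if (a == b) continue;
            const double m = mig(a, b);
            if (m <= 0.0) continue;
            for (int q = 3 * G; q < S; ++q) {
              const double fl = m * y[a * S + q];
              dy[a * S + q] -= fl;
              dy[b * S + q] += fl;
            }
          }
      }
      for (int i = 0; i < dim; ++i) {
        y[i] += dt * dy[i];
        if (y[i] < minstate) minstate = y[i];
        const double a = std::fabs(y[i]);
        if (a > maxabs) maxabs = a;
      }
    }
  }

  // wild female totals per day / wild genotype, target, tracking value
  NumericMatrix Wt(n_days, n_wild);
  for (int t = 0; t < n_days; ++t)
    for (int j = 0; j < n_wild; ++j) {
      const int gf = wild_idx[j] - 1;
      double w = 0.0;
      for (int n = 0; n < n_nodes; ++n)
        for (int gm = 0; gm < G; ++gm)
          w += out(t, n * S + 4 * G + gf + G * gm);
      Wt(t, j) = w;
    }
  std::vector<double> target(n_wild);
  for (int j = 0; j < n_wild; ++j) target[j] = psi * Wt(0, j);
  double value = 0.0;
  for (int t = 1; t <= n_days; ++t)
    if (inwin[t])
      for (int j = 0; j < n_wild; ++j) {
        const double d = Wt(t - 1, j) - target[j];
        value += alpha_F * d * d;
      }

  // ---- backward sweep ----
  std::vector<double> lam(dim, 0.0), gadj(dim);
  std::vector<double> tgt_adj(n_wild, 0.0);  // d J / d W_g(x_1) via target
  List grad(n_nodes);
  std::vector<NumericMatrix> gr;
  for (int n = 0; n < n_nodes; ++n) {
    gr.push_back(NumericMatrix(n_days, G));
    grad[n] = gr[n];
  }
  std::vector<double> Sadj(G);
  for (int t = n_days; t >= 1; --t) {
    if (inwin[t])
      for (int j = 0; j < n_wild; ++j) {
        const int gf = wild_idx[j] - 1;
        const double r = 2.0 * alpha_F * (Wt(t - 1, j) - target[j]);
        tgt_adj[j] -= psi * r;
        for (int n = 0; n < n_nodes; ++n)
          for (int gm = 0; gm < G; ++gm)
            lam[n * S + 4 * G + gf + G * gm] += r;
      }
    if (t == 1)
      for (int j = 0; j < n_wild; ++j) {
        const int gf = wild_idx[j] - 1;
        for (int n = 0; n < n_nodes; ++n)
          for (int gm = 0; gm < G; ++gm)
            lam[n * S + 4 * G + gf + G * gm] += tgt_adj[j];
      }
    for (int n = 0; n < n_nodes; ++n)
      for (int g = 0; g < G; ++g)
        gr[n](t - 1, g) = lam[n * S + 3 * G + g];
    if (t == 1) break;
    const int td = t - 2;  // rate row of the day whose substeps produced x_t
    for (int sub = n_sub - 1; sub >= 0; --sub) {
      const double *st = &store[((size_t)td * n_sub + sub) * dim];
      std::fill(gadj.begin(), gadj.end(), 0.0);
      for (int n = 0; n < n_nodes; ++n) {
        const double nu = rt[n](td, 0), thE = rt[n](td, 1), muE = rt[n](td, 2),
                     thL = rt[n](td, 3), muL = rt[n](td, 4), thP = rt[n](td, 5),
                     muP = rt[n](td, 6), muA = rt[n](td, 7);
        const double *E = st + n * S, *L = E + G, *P = L + G, *M = P + G,
                     *F = M + G;
        (void)E; (void)F;
        const double *aE = &lam[n * S], *aL = aE + G, *aP = aL + G,
                     *aM = aP + G, *aF = aM + G;
        double *gE = &gadj[n * S], *gL = gE + G, *gP = gL + G, *gM = gP + G,
               *gF = gM + G;
        double Ltot = 0.0, denom = 0.0;
        for (int g = 0; g < G; ++g) { Ltot += L[g]; denom += eta[g] * M[g]; }
        for (int g = 0; g < G; ++g)
          mf[g] = denom > 0.0 ? eta[g] * M[g] / denom : 0.0;
        for (int g = 0; g < G; ++g) em[g] = 0.5 * thP * P[g];
        const double dd = muL * (1.0 + Ltot / K[n]);
        double aLL = 0.0;  // sum_g aL_g L_g (density-dependence coupling)
        for (int g = 0; g < G; ++g) aLL += aL[g] * L[g];
        // S_gm = sum_gf aF[gf,gm] s_f_gf em_gf ; and their mf-weighted sum
        double Smf = 0.0;
        for (int gm = 0; gm < G; ++gm) {
          double s = 0.0;
          for (int gf = 0; gf < G; ++gf)
            s += aF[gf + G * gm] * s_f[gf] * em[gf];
          Sadj[gm] = s;
          Smf += mf[gm] * s;
        }
        for (int g = 0; g < G; ++g) {
          gE[g] += -(thE + muE) * aE[g] + thE * aL[g];
          gL[g] += -(thL + dd) * aL[g] - (muL / K[n]) * aLL + thL * aP[g];
          double fsum = 0.0;
          for (int gm = 0; gm < G; ++gm) fsum += mf[gm] * aF[g + G * gm];
          gP[g] += -(thP + muP) * aP[g] +
                   0.5 * thP * (s_m[g] * aM[g] + s_f[g] * fsum);
          gM[g] += -muA * aM[g];
          if (denom > 0.0)
            gM[g] += (eta[g] / denom) * (Sadj[g] - Smf);
        }
        for (int gm = 0; gm < G; ++gm)
          for (int gf = 0; gf < G; ++gf) {
            double bsum = 0.0;
            for (int go = 0; go < G; ++go)
              bsum += probs[gf + G * gm + G * G * go] * aE[go];
            gF[gf + G * gm] += -muA * aF[gf + G * gm] + nu * beta[gf] * bsum;
          }
      }
      if (n_nodes > 1) {
        for (int a = 0; a < n_nodes; ++a)
          for (int b = 0; b < n_nodes; ++b) {
            if (a == b) continue;
            const double m = mig(a, b);
            if (m <= 0.0) continue;
            for (int q = 3 * G; q < S; ++q)
              gadj[a * S + q] += m * (lam[b * S + q] - lam[a * S + q]);
          }
      }
      for (int i = 0; i < dim; ++i) lam[i] += dt * gadj[i];
    }
  }
  return List::create(_["states"] = out, _["value_track"] = value,
                      _["grad"] = grad, _["wild_females"] = Wt,
                      _["min_state"] = minstate, _["max_abs"] = maxabs);
}
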