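#include <Rcpp.h>
using namespace Rcpp;

// Direct-method stochastic simulation of a reaction system with
// structurally encoded propensities.
//
// Reaction j has a base rate constant rate[j], a kinetic order
// (0 = constant, 1 = unimolecular in species s1, 2 = bimolecular in
// s1, s2) and an optional state-dependent modifier:
//   mod 0: none
//   mod 1: Hill activation  X^n / (X^n + K^n)      (mp1 = K, mp2 = n)
//   mod 2: repression       r / (r + X)            (mp1 = r)
//   mod 3: saturating       S / (1 + B X)          (mp1 = B, mp2 = S)
// evaluated on species modsp[j].
//
// Piecewise-constant parameter changes (stress windows) are passed as
// segment boundaries seg_start (first must be 0) with one multiplier per
// reaction per segment. When a waiting time crosses a segment boundary
// the clock is advanced to the boundary and redrawn, which is exact for
// exponential waiting times at piecewise-constant rates.

static double propensity(int j, const std::vector<double>& X,
                         const NumericVector& rate,
                         const IntegerVector& order,
                         const IntegerVector& s1, const IntegerVector& s2,
                         const IntegerVector& mod,
                         const IntegerVector& modsp,
                         const NumericVector& mp1,
                         const NumericVector& mp2, double mult) {
  double a = rate[j] * mult;
  if (order[j] >= 1) a *= X[s1[j]];
  if (order[j] == 2) a *= X[s2[j]];
  if (mod[j] != 0) {
    double Xm = X[modsp[j]];
    if (mod[j] == 1) {
      double xn = std::pow(Xm, mp2[j]);
      double kn = std::pow(mp1[j], mp2[j]);
      a *= (xn + kn) > 0 ? xn / (xn + kn) : 0.0;
    } else if (mod[j] == 2) {
      a *= mp1[j] / (mp1[j] + Xm);
    } else if (mod[j] == 3) {
      a *= mp2[j] / (1.0 + mp1[j] * Xm);
    }
  }
  return a > 0 ? a : 0.0;
}

// [[Rcpp::export(name = ".ssa_run")]]
List ssa_run(IntegerMatrix stoich,      // n_species x n_reactions
             NumericVector rate,
             IntegerVector order,
             IntegerVector s1,
             IntegerVector s2,
             IntegerVector mod,
             IntegerVector modsp,
             NumericVector mp1,
             NumericVector mp2,
             NumericVector init,
             NumericVector sample_times,
             NumericVector seg_start,    // first element 0
             NumericMatrix seg_mult,     // n_segments x n_reactions
             double max_steps) {
  const int nS = stoich.nrow();
  const int nR = stoich.ncol();
  const int nT = sample_times.size();
  const int nSeg = seg_start.size();
  std::vector<double> X(init.begin(), init.end());
  NumericMatrix out(nT, nS);
  double t = 0.0;
  const double t_end = sample_times[nT - 1];
  int next_sample = 0;
  int seg = 0;
  double steps = 0.0;
  double n_events = 0.0;
  bool exhausted = false;

  std::vector<double> a(nR);
  while (t < t_end) {
    if (steps++ > max_steps) {
      stop("maximum number of SSA steps exceeded (%g)", max_steps);
    }
    while (seg + 1 < nSeg && t >= seg_start[seg + 1]) seg++;
    double seg_end = (seg + 1 < nSeg) ? seg_start[seg + 1] : t_end;
    double a0 = 0.0;
    for (int j = 0; j < nR; ++j) {
      a[j] = propensity(j, X, rate, order, s1, s2, mod, modsp, mp1, mp2,
                        seg_mult(seg, j));
      a0 += a[j];
    }
    if (a0 <= 0.0) {
      // no reaction can fire in this segment; jump to its end
      if (seg + 1 < nSeg) { t = seg_end; continue; }
      exhausted = true;
      break;
    }
    double tau = R::rexp(1.0 / a0);
    if (t + tau > seg_end) {
      // boundary crossed: move to the boundary and redraw (memoryless)
      t = seg_end;
      continue;
    }
    t += tau;
    while (next_sample < nT && sample_times[next_sample] <= t) {
      for (int i = 0; i < nS; ++i) out(next_sample, i) = X[i];
      next_sample++;
    }
    double u = unif_rand() * a0;
    int pick = nR - 1;
    double cum = 0.0;
    for (int j = 0; j < nR; ++j) {
      cum += a[j];
      if (u <= cum) { pick = j; break; }
    }
    for (int i = 0; i < nS; ++i) {
      X[i] += stoich(i, pick);
      if (X[i] < 0) stop("species %d became negative", i + 1);
    }
    n_events += 1.0;
  }
  // trailing samples hold the final (possibly absorbed) state
  while (next_sample < nT) {
    for (int i = 0; i < nS; ++i) out(next_sample, i) = X[i];
    next_sample++;
  }
  return List::create(_["counts"] = out,
                      _["n_events"] = n_events,
                      _["absorbed"] = exhausted,
                      _["t_final"] = t);
}
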