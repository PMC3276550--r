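#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Poisson draw using R's RNG; inversion for small means (the common case at
// microsecond leaps), R::rpois otherwise.
static inline int rpois_fast(double m) {
  if (m <= 0.0) return 0;
  if (m < 5.0) {
    double u = unif_rand();
    double p = std::exp(-m), cum = p;
    int k = 0;
    while (u > cum && k < 1000) {
      ++k;
      p *= m / k;
      cum += p;
    }
    return k;
  }
  return (int) R::rpois(m);
}

static inline int rbinom_fast(int n, double p) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  double m = n * p;
  if (m < 0.02) {
    // almost always 0; exact inversion through the first terms
    double u = unif_rand();
    double q = std::pow(1.0 - p, n), cum = q;
    int k = 0;
    while (u > cum && k < n) {
      ++k;
      q *= ((double)(n - k + 1) / k) * (p / (1.0 - p));
      cum += q;
    }
    return k;
  }
  return (int) R::rbinom((double) n, p);
}

struct ReactionSet {
  IntegerVector r1, r2, need1, need2;
  LogicalVector selfPair;
  IntegerVector sPtr, sIdx;
  NumericVector sVal;
  NumericMatrix cmat;  // nsub x nreact propensity constants
  int nreact;
  // per-subvolume active reaction lists (reactions whose reactants can
  // ever be present there); CSR over subvolumes
  IntegerVector actPtr, actIdx;
};

// n: contiguous species vector of one subvolume
static inline double propensity(const ReactionSet& R_, int sub,
                                const double* n, int r) {
  double c = R_.cmat(sub, r);
  if (c == 0.0) return 0.0;
  double n1 = n[R_.r1[r]];
  if (n1 < R_.need1[r]) return 0.0;
  if (R_.r2[r] < 0) return c * n1;
  if (R_.selfPair[r]) return 0.5 * c * n1 * (n1 - 1.0);
  double n2 = n[R_.r2[r]];
  if (n2 < R_.need2[r]) return 0.0;
  return c * n1 * n2;
}

// exact SSA within one subvolume for duration dt (negativity fallback)
static void ssa_sub(const ReactionSet& R_, int sub, double* n, double dt) {
  double t = 0.0;
  int lo = R_.actPtr[sub], hi = R_.actPtr[sub + 1];
  std::vector<double> a(hi - lo);
  for (int iter = 0; iter < 100000; ++iter) {
    double atot = 0.0;
    for (int q = lo; q < hi; ++q) {
      a[q - lo] = propensity(R_, sub, n, R_.actIdx[q]);
      atot += a[q - lo];
    }
    if (atot <= 0.0) return;
    t += R::rexp(1.0 / atot);
    if (t >= dt) return;
    double u = unif_rand() * atot, cum = 0.0;
    int pick = R_.actIdx[hi - 1];
    for (int q = lo; q < hi; ++q) {
      cum += a[q - lo];
      if (u <= cum) { pick = R_.actIdx[q]; break; }
    }
    for (int q = R_.sPtr[pick]; q < R_.sPtr[pick + 1]; ++q)
      n[R_.sIdx[q]] += R_.sVal[q];
  }
}

// tau-leap over one subvolume; on negativity, halve dt locally (<=5 deep),
static void leap_sub(const ReactionSet& R_, int sub, double* n, double dt,
                     int depth, std::vector<double>& dn,
                     std::vector<int>& touched) {
  touched.clear();
  for (int q0 = R_.actPtr[sub]; q0 < R_.actPtr[sub + 1]; ++q0) {
    int r = R_.actIdx[q0];
    double a = propensity(R_, sub, n, r);
    if (a <= 0.0) continue;
    int k = rpois_fast(a * dt);
    if (k == 0) continue;
    for (int q = R_.sPtr[r]; q < R_.sPtr[r + 1]; ++q) {
      int sp = R_.sIdx[q];
      if (dn[sp] == 0.0) touched.push_back(sp);
      dn[sp] += R_.sVal[q] * k;
    }
  }
  bool neg = false;
  for (size_t i = 0; i < touched.size(); ++i) {
    int sp = touched[i];
    if (n[sp] + dn[sp] < 0.0) { neg = true; break; }
  }
  if (!neg) {
    for (size_t i = 0; i < touched.size(); ++i) {
      n[touched[i]] += dn[touched[i]];
      dn[touched[i]] = 0.0;
    }
    return;
  }
  for (size_t i = 0; i < touched.size(); ++i) dn[touched[i]] = 0.0;
  if (depth < 5) {
    leap_sub(R_, sub, n, dt * 0.5, depth + 1, dn, touched);
    leap_sub(R_, sub, n, dt * 0.5, depth + 1, dn, touched);
  } else {
    ssa_sub(R_, sub, n, dt);
  }
}

// counts0 is species x subvolume so that each subvolume's species vector is
// a contiguous column.
// [[Rcpp::export]]
List cpp_tauleap(NumericMatrix counts0,
                 IntegerVector r1, IntegerVector r2,
                 IntegerVector need1, IntegerVector need2,
                 LogicalVector selfPair,
                 IntegerVector sPtr, IntegerVector sIdx, NumericVector sVal,
                 NumericMatrix cmat,
                 IntegerVector actPtr, IntegerVector actIdx,
                 IntegerVector nbrPtr, IntegerVector nbrIdx,
                 NumericVector nbrG,
                 IntegerVector dSpec, NumericVector dRate,
                 IntegerVector dSubsteps,
                 IntegerVector injSpec, IntegerVector injPtr,
                 IntegerVector injSub, NumericVector injRate,
                 NumericVector injOn, NumericVector injOff,
                 IntegerVector injPulsePtr,
                 IntegerVector clSpec, IntegerVector clPtr,
                 IntegerVector clSub, NumericVector clCount,
                 NumericVector clOn, NumericVector clOff,
                 IntegerVector clPulsePtr,
                 double dt, double T, NumericVector recTimes,
                 IntegerVector groupOf, int ngroup,
                 bool adaptive, double eps, double dtMin, double dtMax) {
  int nspec = counts0.nrow(), nsub = counts0.ncol();
  NumericMatrix counts = clone(counts0);

  ReactionSet RS{r1, r2, need1, need2, selfPair, sPtr, sIdx, sVal, cmat,
                 (int) r1.size(), actPtr, actIdx};

  int nrec = recTimes.size();
  NumericVector rec(Dimension(nrec, ngroup, nspec));
  int recIdx = 0;

  std::vector<double> dn(nspec, 0.0);
  std::vector<int> touched;
  std::vector<double> tmp(nsub), inflow(nsub);

  RNGScope scope;
  double t = 0.0;
  int nDiff = dSpec.size();
  long step = 0;

  auto record = [&](double tcur) {
    while (recIdx < nrec && tcur >= recTimes[recIdx] - 1e-12) {
      for (int v = 0; v < nsub; ++v) {
        int g = groupOf[v];
        for (int s = 0; s < nspec; ++s)
          rec[recIdx + (size_t) nrec * (g + (size_t) ngroup * s)] +=
            counts(s, v);
      }
      ++recIdx;
    }
  };
  record(0.0);

  double curDt = dt;
  while (t < T - 1e-12 && recIdx < nrec) {
    if (adaptive && (step % 25 == 0)) {
      // bound the expected relative change of every species count
      double lim = dtMax;
      for (int v = 0; v < nsub; ++v) {
        double* nv = &counts(0, v);
        for (int q0 = actPtr[v]; q0 < actPtr[v + 1]; ++q0) {
          int r = actIdx[q0];
          double a = propensity(RS, v, nv, r);
          if (a <= 0.0) continue;
          for (int q = sPtr[r]; q < sPtr[r + 1]; ++q)
            dn[sIdx[q]] += sVal[q] * a;
        }
        for (int s = 0; s < nspec; ++s) {
          double drift = std::fabs(dn[s]);
          dn[s] = 0.0;
          if (drift > 0.0) {
            double nref = std::max(nv[s], 10.0);
            double cand = eps * nref / drift;
            if (cand < lim) lim = cand;
          }
        }
      }
      curDt = std::max(dtMin, lim);
    }
    double stepDt = std::min(curDt, T - t);

    // clamps applied at the start of each step
    for (int c = 0; c < clSpec.size(); ++c) {
      bool active = false;
      for (int p = clPulsePtr[c]; p < clPulsePtr[c + 1]; ++p)
        if (t >= clOn[p] - 1e-12 && t < clOff[p]) { active = true; break; }
      if (!active) continue;
      int s = clSpec[c];
      for (int q = clPtr[c]; q < clPtr[c + 1]; ++q)
        counts(s, clSub[q]) = clCount[q];
    }

    // reactions
    for (int v = 0; v < nsub; ++v)
      leap_sub(RS, v, &counts(0, v), stepDt, 0, dn, touched);

    // diffusion: multinomial across neighbors, optional substeps
    for (int di = 0; di < nDiff; ++di) {
      int s = dSpec[di];
      double D = dRate[di];
      int L = dSubsteps[di];
      double subDt = stepDt / L;
      for (int l = 0; l < L; ++l) {
        for (int v = 0; v < nsub; ++v) {
          tmp[v] = counts(s, v);
          inflow[v] = 0.0;
        }
        for (int v = 0; v < nsub; ++v) {
          int n = (int) tmp[v];
          if (n <= 0) continue;
          int rem = n;
          double cum = 0.0;
          for (int q = nbrPtr[v]; q < nbrPtr[v + 1] && rem > 0; ++q) {
            double p = D * nbrG[q] * subDt;
            double pc = p / (1.0 - cum);
            if (pc > 1.0) pc = 1.0;
            int x = rbinom_fast(rem, pc);
            if (x > 0) { inflow[nbrIdx[q]] += x; rem -= x; }
            cum += p;
          }
          if (rem != n) counts(s, v) = rem;
        }
        for (int v = 0; v < nsub; ++v)
          if (inflow[v] > 0.0) counts(s, v) += inflow[v];
      }
    }

    // injections
    for (int c = 0; c < injSpec.size(); ++c) {
      double overlap = 0.0;
      for (int p = injPulsePtr[c]; p < injPulsePtr[c + 1]; ++p) {
        double lo = std::max(t, injOn[p]);
        double hi = std::min(t + stepDt, injOff[p]);
        if (hi > lo) overlap += hi - lo;
      }
      if (overlap <= 0.0) continue;
      int s = injSpec[c];
      for (int q = injPtr[c]; q < injPtr[c + 1]; ++q)
        counts(s, injSub[q]) += rpois_fast(injRate[q] * overlap);
    }

    t += stepDt;
    ++step;
    record(t);
  }

  return List::create(_["counts"] = counts, _["rec"] = rec,
                      _["steps"] = (double) step, _["t"] = t);
}

// Mass-action right-hand side for the deterministic engine.
// y: concentrations (nM), compartment-major layout (index v + ncomp*s).
// [[Rcpp::export]]
NumericVector cpp_rhs(NumericVector y, int ncomp, int nspec,
                      IntegerVector r1, IntegerVector r2,
                      IntegerVector sPtr, IntegerVector sIdx,
                      NumericVector sVal, NumericVector kvec,
                           IntegerVector cpA, IntegerVector cpB,
                      NumericVector gOverVa, NumericVector gOverVb,
                      IntegerVector dSpec, NumericVector dRate,
                      NumericVector source,
                      IntegerVector clampIdx) {
  int nreact = r1.size();
  NumericVector dy(y.size());
  for (int v = 0; v < ncomp; ++v) {
    for (int r = 0; r < nreact; ++r) {
      double rate = kvec[r] * y[v + (size_t) ncomp * r1[r]];
      if (rate == 0.0) continue;
      if (r2[r] >= 0)
        rate *= y[v + (size_t) ncomp * r2[r]];
      if (rate == 0.0) continue;
      for (int q = sPtr[r]; q < sPtr[r + 1]; ++q)
        dy[v + (size_t) ncomp * sIdx[q]] += sVal[q] * rate;
    }
  }
  int ncp = cpA.size();
  for (int di = 0; di < dSpec.size(); ++di) {
    size_t off = (size_t) ncomp * dSpec[di];
    double D = dRate[di];
    if (D == 0.0) continue;
    for (int m = 0; m < ncp; ++m) {
      double grad = y[off + cpA[m]] - y[off + cpB[m]];
      if (grad == 0.0) continue;
      dy[off + cpA[m]] -= D * gOverVa[m] * grad;
      dy[off + cpB[m]] += D * gOverVb[m] * grad;
    }
  }
  if (source.size() == y.size())
    for (int i = 0; i < y.size(); ++i) dy[i] += source[i];
  for (int i = 0; i < clampIdx.size(); ++i) dy[clampIdx[i]] = 0.0;
  return dy;
}
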