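// Discrete-time synchronous stepping kernels for the network simulators.
//
// All randomness goes through R's RNG (unif_rand), so runs are fully
// reproducible under set.seed().  Roles are integer-coded:
//   ISVOR:    0=I 1=S 2=V 3=O 4=R
//   SIR:      0=S 1=I 2=R
//   SEIR:     0=S 1=E 2=I 3=R
//   Twin-SIR: 0=susceptible 1=S1 (rumor) 2=S2 (dispeller) 3=R
//
// Per-node rule: candidate transitions are evaluated sequentially with
// short-circuit (first success wins); contact-driven trials precede
// spontaneous ones.  For nodes facing two competing contact types the
// contact order is randomized per node per step (a shuffle is skipped
// when only one type is present -- the outcome distribution is
// unchanged and baseline reductions stay bit-identical).
//
// Contact-driven trials come in three modes (mode argument):
//   0 maki_thompson (default): ignorants feel one independent trial per
//     spreading neighbour (receiver-side infection pressure), while each
//     ACTIVE node keys its own contact-driven transitions (stifling,
//     variation conversion) on ONE uniformly sampled neighbour per step,
//     as in classic Maki-Thompson rumor dynamics;
//   1 per_step: one Bernoulli trial per contact CLASS, performed only
//     when at least one neighbour of that class is present (per-step
//     conditional probabilities; no degree saturation);
//   2 per_contact: one independent trial per neighbour of the class,
//     the discrete counterpart of the degree-multiplied mass-action
//     terms.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int runif_int(int n) {
  // uniform integer on 0..n-1
  double u = unif_rand();
  int k = (int)(u * n);
  return k >= n ? n - 1 : k;
}

// ISVOR transition indices in the per-step log
// 0:I->S 1:I->V 2:I->R 3:S->V 4:S->O 5:S->R 6:V->O 7:V->R 8:O->S 9:O->V 10:O->R
static void isvor_step_core(const int* roles, int* nxt, int n,
                            const int* off, const int* nb,
                            double alpha, double eps, double lam,
                            double mu1, double mu2, double gam, double eta,
                            double xi1, double xi2, double theta,
                            double beta1, double beta2,
                            bool inc_eps, bool theta_contact,
                            bool lam_fraction, int mode,
                            int* trans, std::vector<int>& buf) {
  const bool per_step = (mode == 1);
  const bool sampled = (mode == 0);
  for (int v = 0; v < n; ++v) {
    int r = roles[v];
    int out = r;
    int d0 = off[v], d1 = off[v + 1];
    if (r == 4) { nxt[v] = 4; continue; }
    if (r == 0) {                       // ignorant
      buf.clear();
      bool sawS = false, sawV = false;
      for (int j = d0; j < d1; ++j) {
        int rr = roles[nb[j]];
        if (rr == 1 && !(per_step && sawS)) { buf.push_back(1); sawS = true; }
        else if (rr == 2 && !lam_fraction && !(per_step && sawV)) {
          buf.push_back(2); sawV = true;
        }
      }
      int m = (int)buf.size();
      if (sawS && sawV)                 // randomized contact order
        for (int i = m - 1; i > 0; --i) {
          int k = runif_int(i + 1);
          int tmp = buf[i]; buf[i] = buf[k]; buf[k] = tmp;
        }
      for (int i = 0; i < m && out == 0; ++i) {
        if (buf[i] == 1) {              // spreader contact
          if (inc_eps && unif_rand() < eps) { out = 4; trans[2]++; }
          else if (unif_rand() < alpha) {
            if (lam_fraction && unif_rand() < lam) { out = 2; trans[1]++; }
            else { out = 1; trans[0]++; }
          }
        } else {                        // variation contact
          if (unif_rand() < lam) { out = 2; trans[1]++; }
        }
      }
    } else if (r == 1) {                // spreader
      if (sampled) {                    // one sampled discussion partner
        if (d1 > d0) {
          int partner = roles[nb[d0 + runif_int(d1 - d0)]];
          if (partner != 0 && unif_rand() < mu1) { out = 4; trans[5]++; }
          if (out == 1 && partner == 2 && unif_rand() < eta) {
            out = 2; trans[3]++;
          }
        }
      } else {
        int nNonI = 0, nV = 0;
        for (int j = d0; j < d1; ++j) {
          int rr = roles[nb[j]];
          if (rr != 0) nNonI++;
          if (rr == 2) nV++;
        }
        if (per_step) { nNonI = nNonI > 0; nV = nV > 0; }
        for (int i = 0; i < nNonI && out == 1; ++i)
          if (unif_rand() < mu1) { out = 4; trans[5]++; }
        for (int i = 0; i < nV && out == 1; ++i)
          if (unif_rand() < eta) { out = 2; trans[3]++; }
      }
      if (out == 1 && unif_rand() < gam) { out = 2; trans[3]++; }
      if (out == 1 && unif_rand() < xi1) { out = 3; trans[4]++; }
    } else if (r == 2) {                // variation
      if (sampled) {
        if (d1 > d0) {
          int partner = roles[nb[d0 + runif_int(d1 - d0)]];
          if (partner != 0 && unif_rand() < mu2) { out = 4; trans[7]++; }
        }
      } else {
        int nNonI = 0;
        for (int j = d0; j < d1; ++j) if (roles[nb[j]] != 0) nNonI++;
        if (per_step) nNonI = nNonI > 0;
        for (int i = 0; i < nNonI && out == 2; ++i)
          if (unif_rand() < mu2) { out = 4; trans[7]++; }
      }
      if (out == 2 && unif_rand() < xi2) { out = 3; trans[6]++; }
    } else {                            // oyster
      if (theta_contact) {
        if (sampled) {
          if (d1 > d0 && roles[nb[d0 + runif_int(d1 - d0)]] != 0 &&
              unif_rand() < theta) { out = 4; trans[10]++; }
        } else {
          int nNonI = 0;
          for (int j = d0; j < d1; ++j) if (roles[nb[j]] != 0) nNonI++;
          if (per_step) nNonI = nNonI > 0;
          for (int i = 0; i < nNonI && out == 3; ++i)
            if (unif_rand() < theta) { out = 4; trans[10]++; }
        }
      } else {
        if (unif_rand() < theta) { out = 4; trans[10]++; }
      }
      if (out == 3 && unif_rand() < beta1) { out = 1; trans[8]++; }
      if (out == 3 && unif_rand() < beta2) { out = 2; trans[9]++; }
    }
    nxt[v] = out;
  }
}

// [[Rcpp::export]]
List isvor_step_cpp(IntegerVector roles, IntegerVector off, IntegerVector nb,
                    NumericVector par, IntegerVector flags) {
  int n = roles.size();
  IntegerVector nxt(n);
  IntegerVector trans(11);
  std::vector<int> buf;
  isvor_step_core(roles.begin(), nxt.begin(), n, off.begin(), nb.begin(),
                  par[0], par[1], par[2], par[3], par[4], par[5], par[6],
                  par[7], par[8], par[9], par[10], par[11],
                  flags[0] != 0, flags[1] != 0, flags[2] != 0, flags[3],
                  trans.begin(), buf);
  return List::create(_["roles"] = nxt, _["transitions"] = trans);
}

// [[Rcpp::export]]
List isvor_run_cpp(IntegerVector roles0, IntegerVector off, IntegerVector nb,
                   NumericVector par, IntegerVector flags, int t_max) {
  int n = roles0.size();
  std::vector<int> cur(roles0.begin(), roles0.end());
  std::vector<int> nxt(n);
  std::vector<int> buf;
  IntegerMatrix counts(t_max + 1, 5);
  IntegerMatrix trans(t_max, 11);
  int absorbed = -1;
  int t = 0;
  for (int v = 0; v < n; ++v) counts(0, cur[v])++;
  for (t = 0; t < t_max; ++t) {
    // absorbing: no spreader, variation or oyster left
    if (counts(t, 1) == 0 && counts(t, 2) == 0 && counts(t, 3) == 0) {
      absorbed = t;
      break;
    }
    int tr[11] = {0};
    isvor_step_core(cur.data(), nxt.data(), n, off.begin(), nb.begin(),
                    par[0], par[1], par[2], par[3], par[4], par[5], par[6],
                    par[7], par[8], par[9], par[10], par[11],
                    flags[0] != 0, flags[1] != 0, flags[2] != 0, flags[3],
                    tr, buf);
    for (int j = 0; j < 11; ++j) trans(t, j) = tr[j];
    std::swap(cur, nxt);
    for (int v = 0; v < n; ++v) counts(t + 1, cur[v])++;
  }
  if (absorbed < 0 && counts(t, 1) == 0 && counts(t, 2) == 0 &&
      counts(t, 3) == 0)
    absorbed = t;
  int len = (absorbed >= 0 ? absorbed : t_max);
  return List::create(
    _["counts"] = counts(Range(0, len), _),
    _["transitions"] = (len > 0 ? trans(Range(0, len - 1), _)
                                : IntegerMatrix(0, 11)),
    _["absorbed_at"] = absorbed,
    _["final_roles"] = IntegerVector(cur.begin(), cur.end()));
}

// ---- SIR baseline: 0=S 1=I 2=R ------------------------------------------
// S: per I-neighbour Bernoulli(alpha) -> I.  I: spontaneous mu1 -> R.
static inline int count_role(const int* roles, const int* nb, int d0,
                             int d1, int role, bool per_step) {
  int c = 0;
  for (int j = d0; j < d1; ++j) if (roles[nb[j]] == role) c++;
  return per_step ? (c > 0) : c;
}

static void sir_step_core(const int* roles, int* nxt, int n,
                          const int* off, const int* nb,
                          double alpha, double mu1, bool per_step) {
  for (int v = 0; v < n; ++v) {
    int r = roles[v], out = r;
    if (r == 0) {
      int c = count_role(roles, nb, off[v], off[v + 1], 1, per_step);
      for (int i = 0; i < c && out == 0; ++i)
        if (unif_rand() < alpha) out = 1;
    } else if (r == 1) {
      if (unif_rand() < mu1) out = 2;
    }
    nxt[v] = out;
  }
}

// [[Rcpp::export]]
List sir_run_cpp(IntegerVector roles0, IntegerVector off, IntegerVector nb,
                 double alpha, double mu1, int t_max, bool per_step) {
  int n = roles0.size();
  std::vector<int> cur(roles0.begin(), roles0.end()), nxt(n);
  IntegerMatrix counts(t_max + 1, 3);
  int absorbed = -1, t;
  for (int v = 0; v < n; ++v) counts(0, cur[v])++;
  for (t = 0; t < t_max; ++t) {
    if (counts(t, 1) == 0) { absorbed = t; break; }
    sir_step_core(cur.data(), nxt.data(), n, off.begin(), nb.begin(),
                  alpha, mu1, per_step);
    std::swap(cur, nxt);
    for (int v = 0; v < n; ++v) counts(t + 1, cur[v])++;
  }
  if (absorbed < 0 && counts(t, 1) == 0) absorbed = t;
  int len = (absorbed >= 0 ? absorbed : t_max);
  return List::create(_["counts"] = counts(Range(0, len), _),
                      _["absorbed_at"] = absorbed);
}

// ---- SEIR baseline: 0=S 1=E 2=I 3=R --------------------------------------
static void seir_step_core(const int* roles, int* nxt, int n,
                           const int* off, const int* nb,
                           double alpha, double incub, double mu1,
                           bool per_step) {
  for (int v = 0; v < n; ++v) {
    int r = roles[v], out = r;
    if (r == 0) {
      int c = count_role(roles, nb, off[v], off[v + 1], 2, per_step);
      for (int i = 0; i < c && out == 0; ++i)
        if (unif_rand() < alpha) out = 1;
    } else if (r == 1) {
      if (unif_rand() < incub) out = 2;
    } else if (r == 2) {
      if (unif_rand() < mu1) out = 3;
    }
    nxt[v] = out;
  }
}

// [[Rcpp::export]]
List seir_run_cpp(IntegerVector roles0, IntegerVector off, IntegerVector nb,
                  double alpha, double incub, double mu1, int t_max,
                  bool per_step) {
  int n = roles0.size();
  std::vector<int> cur(roles0.begin(), roles0.end()), nxt(n);
  IntegerMatrix counts(t_max + 1, 4);
  int absorbed = -1, t;
  for (int v = 0; v < n; ++v) counts(0, cur[v])++;
  for (t = 0; t < t_max; ++t) {
    if (counts(t, 1) == 0 && counts(t, 2) == 0) { absorbed = t; break; }
    seir_step_core(cur.data(), nxt.data(), n, off.begin(), nb.begin(),
                   alpha, incub, mu1, per_step);
    std::swap(cur, nxt);
    for (int v = 0; v < n; ++v) counts(t + 1, cur[v])++;
  }
  if (absorbed < 0 && counts(t, 1) == 0 && counts(t, 2) == 0) absorbed = t;
  int len = (absorbed >= 0 ? absorbed : t_max);
  return List::create(_["counts"] = counts(Range(0, len), _),
                      _["absorbed_at"] = absorbed);
}

// ---- Twin-SIR baseline: 0=sus 1=S1 2=S2 3=R -------------------------------
// sus: randomized order over S1 contacts (alpha -> S1) and S2 contacts
// (dispel -> S2), first success wins.  S1: per S2-neighbour
// Bernoulli(dispel) -> S2, then spontaneous mu1 -> R.  S2: spontaneous
// rec2 -> R.  n_disp dispellers are seeded among susceptibles at step
// `delay`.
static void twinsir_step_core(const int* roles, int* nxt, int n,
                              const int* off, const int* nb,
                              double alpha, double mu1, double dispel,
                              double rec2, int mode,
                              std::vector<int>& buf) {
  const bool per_step = (mode == 1);
  // under the sampled-partner mode the dispel machinery consumes RNG
  // only when a dispeller exists, so a dispeller-free run reduces to SIR
  bool any_s2 = false;
  for (int v = 0; v < n && !any_s2; ++v) any_s2 = roles[v] == 2;
  for (int v = 0; v < n; ++v) {
    int r = roles[v], out = r;
    if (r == 0) {
      buf.clear();
      bool saw1 = false, saw2 = false;
      for (int j = off[v]; j < off[v + 1]; ++j) {
        int rr = roles[nb[j]];
        if (rr == 1 && !(per_step && saw1)) { buf.push_back(1); saw1 = true; }
        else if (rr == 2 && !(per_step && saw2)) {
          buf.push_back(2); saw2 = true;
        }
      }
      int m = (int)buf.size();
      if (saw1 && saw2)
        for (int i = m - 1; i > 0; --i) {
          int k = runif_int(i + 1);
          int tmp = buf[i]; buf[i] = buf[k]; buf[k] = tmp;
        }
      for (int i = 0; i < m && out == 0; ++i) {
        if (buf[i] == 1) { if (unif_rand() < alpha) out = 1; }
        else             { if (unif_rand() < dispel) out = 2; }
      }
    } else if (r == 1) {
      if (mode == 0) {
        if (any_s2 && off[v + 1] > off[v]) {
          int partner = roles[nb[off[v] + runif_int(off[v + 1] - off[v])]];
          if (partner == 2 && unif_rand() < dispel) out = 2;
        }
      } else {
        int c = count_role(roles, nb, off[v], off[v + 1], 2, per_step);
        for (int i = 0; i < c && out == 1; ++i)
          if (unif_rand() < dispel) out = 2;
      }
      if (out == 1 && unif_rand() < mu1) out = 3;
    } else if (r == 2) {
      if (unif_rand() < rec2) out = 3;
    }
    nxt[v] = out;
  }
}

// [[Rcpp::export]]
List twinsir_run_cpp(IntegerVector roles0, IntegerVector off,
                     IntegerVector nb, double alpha, double mu1,
                     double dispel, double rec2, int delay, int n_disp,
                     int t_max, int mode) {
  int n = roles0.size();
  std::vector<int> cur(roles0.begin(), roles0.end()), nxt(n);
  std::vector<int> buf;
  IntegerMatrix counts(t_max + 1, 4);
  int absorbed = -1, t;
  for (int v = 0; v < n; ++v) counts(0, cur[v])++;
  for (t = 0; t < t_max; ++t) {
    if (t == delay && n_disp > 0) {
      // seed dispellers among the remaining susceptibles
      std::vector<int> sus;
      for (int v = 0; v < n; ++v) if (cur[v] == 0) sus.push_back(v);
      int take = n_disp < (int)sus.size() ? n_disp : (int)sus.size();
      for (int i = 0; i < take; ++i) {
        int k = i + runif_int((int)sus.size() - i);
        int tmp = sus[i]; sus[i] = sus[k]; sus[k] = tmp;
        cur[sus[i]] = 2;
      }
      counts(t, _) = IntegerVector(4);
      for (int v = 0; v < n; ++v) counts(t, cur[v])++;
    }
    if (counts(t, 1) == 0 && counts(t, 2) == 0 &&
        (t > delay || n_disp == 0)) {
      absorbed = t;
      break;
    }
    twinsir_step_core(cur.data(), nxt.data(), n, off.begin(), nb.begin(),
                      alpha, mu1, dispel, rec2, mode, buf);
    std::swap(cur, nxt);
    for (int v = 0; v < n; ++v) counts(t + 1, cur[v])++;
  }
  if (absorbed < 0 && counts(t, 1) == 0 && counts(t, 2) == 0) absorbed = t;
  int len = (absorbed >= 0 ? absorbed : t_max);
  return List::create(_["counts"] = counts(Range(0, len), _),
                      _["absorbed_at"] = absorbed);
}
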