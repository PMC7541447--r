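// Self-contained RNA secondary-structure engine used as the package's
// deterministic fallback backend: Nussinov-style MFE (score = -1 per pair),
// McCaskill-style partition function / pair probabilities under the same
// score model, and a simplified kinetic Monte-Carlo folding simulator
// (move set = add/remove one base pair, Metropolis acceptance).
//
// Sequences arrive as integer vectors: 0 = A, 1 = C, 2 = G, 3 = U.
// Pairing rule: Watson-Crick (AU, GC) plus wobble (GU), both orientations.
// Minimum hairpin loop length (unpaired nt enclosed by a pair) is a parameter,
// default 3 at the R level.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline bool pair_ok(int a, int b) {
  // AU/UA, GC/CG, GU/UG
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return true;
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return true;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return true;
  return false;
}

// ---------------------------------------------------------------------------
// Nussinov maximum base-pairing DP with traceback.
// ---------------------------------------------------------------------------

static void traceback(int i, int j,
                      const std::vector<std::vector<int> > &M,
                      const IntegerVector &s, int min_loop,
                      std::vector<char> &db) {
  if (j - i <= min_loop) return;
  if (M[i][j] == M[i][j - 1]) {
    traceback(i, j - 1, M, s, min_loop, db);
    return;
  }
  for (int k = i; k <= j - min_loop - 1; ++k) {
    if (!pair_ok(s[k], s[j])) continue;
    int left = (k > i) ? M[i][k - 1] : 0;
    int inside = (j - k > min_loop + 1) ? M[k + 1][j - 1] : 0;
    if (M[i][j] == left + inside + 1) {
      db[k] = '(';
      db[j] = ')';
      if (k > i) traceback(i, k - 1, M, s, min_loop, db);
      if (j - k > min_loop + 1) traceback(k + 1, j - 1, M, s, min_loop, db);
      return;
    }
  }
  // should not be reached
  stop("internal error: Nussinov traceback failed");
}

// [[Rcpp::export]]
List cpp_nussinov(IntegerVector s, int min_loop) {
  int n = s.size();
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[i][j - 1];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (!pair_ok(s[k], s[j])) continue;
        int left = (k > i) ? M[i][k - 1] : 0;
        int inside = (j - k > min_loop + 1) ? M[k + 1][j - 1] : 0;
        if (left + inside + 1 > best) best = left + inside + 1;
      }
      M[i][j] = best;
    }
  }
  std::vector<char> db(n, '.');
  if (n > min_loop + 1) traceback(0, n - 1, M, s, min_loop, db);
  int npairs = (n > 0) ? M[0][n - 1] : 0;
  return List::create(_["n_pairs"] = npairs,
                      _["structure"] = std::string(db.begin(), db.end()));
}

// ---------------------------------------------------------------------------
// Stacking-score DP: a base pair contributes -1 only when stacked on the
// adjacent pair (helix of length h scores -(h-1)), so isolated pairs are
// free and the optimum concentrates on contiguous helices. Two-state DP:
// S[i][j] = best stacks in [i, j]; P[i][j] = best stacks given (i, j) paired.
// ---------------------------------------------------------------------------

static const int NEG = -1000000;

static void stack_traceback_S(int i, int j,
                              const std::vector<std::vector<int> > &S,
                              const std::vector<std::vector<int> > &P,
                              const IntegerVector &s, int min_loop,
                              std::vector<char> &db);

static void stack_traceback_P(int i, int j,
                              const std::vector<std::vector<int> > &S,
                              const std::vector<std::vector<int> > &P,
                              const IntegerVector &s, int min_loop,
                              std::vector<char> &db) {
  db[i] = '('; db[j] = ')';
  int span = j - i;
  if (span >= min_loop + 3 && pair_ok(s[i + 1], s[j - 1]) &&
      P[i + 1][j - 1] > NEG && P[i][j] == P[i + 1][j - 1] + 1) {
    stack_traceback_P(i + 1, j - 1, S, P, s, min_loop, db);
    return;
  }
  if (span >= 2) stack_traceback_S(i + 1, j - 1, S, P, s, min_loop, db);
}

static void stack_traceback_S(int i, int j,
                              const std::vector<std::vector<int> > &S,
                              const std::vector<std::vector<int> > &P,
                              const IntegerVector &s, int min_loop,
                              std::vector<char> &db) {
  if (j - i <= min_loop) return;
  if (S[i][j] == S[i][j - 1]) {
    stack_traceback_S(i, j - 1, S, P, s, min_loop, db);
    return;
  }
  for (int k = i; k <= j - min_loop - 1; ++k) {
    if (!pair_ok(s[k], s[j]) || P[k][j] <= NEG) continue;
    int left = (k > i) ? S[i][k - 1] : 0;
    if (S[i][j] == left + P[k][j]) {
      stack_traceback_P(k, j, S, P, s, min_loop, db);
      if (k > i) stack_traceback_S(i, k - 1, S, P, s, min_loop, db);
      return;
    }
  }
  stop("internal error: stacking traceback failed");
}

// [[Rcpp::export]]
List cpp_stack_mfe(IntegerVector s, int min_loop) {
  int n = s.size();
  std::vector<std::vector<int> > S(n, std::vector<int>(n, 0));
  std::vector<std::vector<int> > P(n, std::vector<int>(n, NEG));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      if (pair_ok(s[i], s[j])) {
        int inner = NEG;
        if (span >= min_loop + 3 && pair_ok(s[i + 1], s[j - 1]) &&
            P[i + 1][j - 1] > NEG) {
          inner = P[i + 1][j - 1] + 1;
        }
        int open = (span >= 2) ? S[i + 1][j - 1] : 0;
        P[i][j] = std::max(inner, open);
      }
      int best = S[i][j - 1];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (!pair_ok(s[k], s[j]) || P[k][j] <= NEG) continue;
        int left = (k > i) ? S[i][k - 1] : 0;
        if (left + P[k][j] > best) best = left + P[k][j];
      }
      S[i][j] = best;
    }
  }
  std::vector<char> db(n, '.');
  if (n > min_loop + 1 && S[0][n - 1] > 0) {
    stack_traceback_S(0, n - 1, S, P, s, min_loop, db);
  }
  return List::create(_["n_stacks"] = (n > 0 ? S[0][n - 1] : 0),
                      _["structure"] = std::string(db.begin(), db.end()));
}

// ---------------------------------------------------------------------------
// Partition function and base-pair probabilities.
// Boltzmann weight of a structure = w^(number of pairs), w = exp(beta)
// (score model: -1 per pair, kT = 1/beta in score units).
// Interior: Q[i][j] over [i, j]; exterior recursion over immediately
// enclosing pairs (O(n^4), fine for the construct-scale lengths used here).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_partition(IntegerVector s, int min_loop, double beta) {
  int n = s.size();
  double w = std::exp(beta);
  // Q[i][j], 0-based, Q over empty/invalid = 1; pad handled via helper lambda.
  std::vector<std::vector<double> > Q(n + 1, std::vector<double>(n + 1, 1.0));
  // Q stored with offset: access q(i, j) for -1 <= i, j <= n
  auto q = [&](int i, int j) -> double {
    if (i > j) return 1.0;
    return Q[i][j];
  };
  for (int span = 0; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      if (span <= min_loop) { Q[i][j] = 1.0; continue; }
      double tot = q(i, j - 1);
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (!pair_ok(s[k], s[j])) continue;
        tot += q(i, k - 1) * w * q(k + 1, j - 1);
      }
      Q[i][j] = tot;
    }
  }
  double Z = (n > 0) ? Q[0][n - 1] : 1.0;

  // ext(i, j) = exterior weight of pair (i, j) = P(i,j) / Qb(i,j)
  NumericMatrix P(n, n);
  std::vector<std::vector<double> > ext(n, std::vector<double>(n, 0.0));
  // iterate spans from largest to smallest so enclosing pairs are ready
  for (int span = n - 1; span >= min_loop + 1; --span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      if (!pair_ok(s[i], s[j])) continue;
      double e = q(0, i - 1) * q(j + 1, n - 1) / Z;
      for (int k = 0; k < i; ++k) {
        for (int l = j + 1; l < n; ++l) {
          if (!pair_ok(s[k], s[l])) continue;
          if (ext[k][l] == 0.0) continue;
          e += ext[k][l] * w * q(k + 1, i - 1) * q(j + 1, l - 1);
        }
      }
      ext[i][j] = e;
      double qb = w * q(i + 1, j - 1);
      double p = qb * e;
      P(i, j) = p;
      P(j, i) = p;
    }
  }
  return List::create(_["Z"] = Z, _["p"] = P);
}

// ---------------------------------------------------------------------------
// Kinetic Monte-Carlo folding.
// Candidate moves: for every complementary (i, j) with j - i > min_loop,
// either add the pair (if both free and non-crossing) or remove it (if
// currently formed). Attempts pick a candidate uniformly; Metropolis
// acceptance min(1, exp(-beta * dE)) with dE in score units (-1 per pair).
// Time advances by an Exp(rate = n_candidates) increment per attempt
// (unit attempt frequency per candidate move), giving a Gillespie-like
// rejection clock in dimensionless arbitrary units.
// Uses R's RNG so R-level set.seed() controls reproducibility.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_kinetic(IntegerVector s, int min_loop, double beta, double t_max,
                 int mfe_pairs, int record_limit) {
  int n = s.size();
  std::vector<std::pair<int, int> > cand;
  for (int i = 0; i < n; ++i)
    for (int j = i + min_loop + 1; j < n; ++j)
      if (pair_ok(s[i], s[j])) cand.push_back(std::make_pair(i, j));
  int ncand = (int)cand.size();

  std::vector<double> times;
  std::vector<double> energies;
  times.push_back(0.0);
  energies.push_back(0.0);

  double mfe_energy = -(double)mfe_pairs;
  bool reached = (mfe_pairs == 0);
  double t_reach = reached ? 0.0 : NA_REAL;
  double integral = 0.0;

  if (ncand == 0 || reached) {
    // no possible pairs (or trivially at MFE): flat trajectory at 0
    return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                        _["energies"] = NumericVector(energies.begin(), energies.end()),
                        _["avg_energy"] = 0.0,
                        _["reached_mfe"] = reached,
                        _["t_reach"] = t_reach,
                        _["truncated"] = false);
  }

  std::vector<int> partner(n, -1);
  double t = 0.0;
  double e_cur = 0.0;
  double p_rem = std::exp(-beta);  // acceptance of a pair removal (dE = +1)
  bool truncated = false;

  RNGScope scope;
  while (t < t_max) {
    double dt = R::exp_rand() / (double)ncand;
    if (t + dt >= t_max) { t = t_max; break; }
    t += dt;
    int idx = (int)std::floor(R::unif_rand() * ncand);
    if (idx >= ncand) idx = ncand - 1;
    int i = cand[idx].first, j = cand[idx].second;
    bool moved = false;
    if (partner[i] == j) {
      // removal, dE = +1
      if (R::unif_rand() < p_rem) {
        partner[i] = -1; partner[j] = -1;
        e_cur += 1.0;
        moved = true;
      }
    } else if (partner[i] < 0 && partner[j] < 0) {
      // addition, dE = -1, always accepted; must be non-crossing
      bool crossing = false;
      for (int k = i + 1; k < j; ++k) {
        int pk = partner[k];
        if (pk >= 0 && (pk < i || pk > j)) { crossing = true; break; }
      }
      if (!crossing) {
        partner[i] = j; partner[j] = i;
        e_cur -= 1.0;
        moved = true;
      }
    }
    if (moved) {
      // accumulate the step-function integral up to this event
      double t_prev = times.empty() ? 0.0 : times.back();
      double e_prev = energies.empty() ? 0.0 : energies.back();
      integral += e_prev * (t - t_prev);
      if ((int)times.size() < record_limit) {
        times.push_back(t);
        energies.push_back(e_cur);
      } else {
        truncated = true;
        times.back() = t;
        energies.back() = e_cur;
      }
      if (e_cur <= mfe_energy + 1e-9) {
        reached = true;
        t_reach = t;
        break;
      }
    }
  }

  // close the integral: remain at the last energy (clamped to MFE if reached)
  double t_last = times.back();
  double e_last = energies.back();
  if (reached) e_last = mfe_energy;
  integral += e_last * (t_max - t_last);
  double avg_energy = integral / t_max;

  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["energies"] = NumericVector(energies.begin(), energies.end()),
                      _["avg_energy"] = avg_energy,
                      _["reached_mfe"] = reached,
                      _["t_reach"] = t_reach,
                      _["truncated"] = truncated);
}
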