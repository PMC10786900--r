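#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// All stochastic kernels use an explicit std::mt19937 seed so results are
// reproducible across platforms independently of R's RNG state.

// ---------------------------------------------------------------------------
// NODF
// ---------------------------------------------------------------------------

// Pairwise overlap/decreasing-fill score summed over all unordered pairs of
// one guild. Score for a pair is 0 when marginal totals are equal or the
// poorer total is 0, else 100 * shared / poorer-total.
static void nodf_axis(const IntegerMatrix& B, bool rows, double* sum_out,
                      int* npairs_out) {
  const int n = rows ? B.nrow() : B.ncol();
  const int m = rows ? B.ncol() : B.nrow();
  std::vector<int> fill(n, 0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < m; ++k) fill[i] += rows ? B(i, k) : B(k, i);
  double s = 0.0;
  int np = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      ++np;
      const int fi = fill[i], fj = fill[j];
      if (fi == fj) continue;
      const int lo = std::min(fi, fj);
      if (lo == 0) continue;
      int ov = 0;
      for (int k = 0; k < m; ++k) {
        const int a = rows ? B(i, k) : B(k, i);
        const int b = rows ? B(j, k) : B(k, j);
        if (a && b) ++ov;
      }
      s += 100.0 * ov / lo;
    }
  }
  *sum_out = s;
  *npairs_out = np;
}

// [[Rcpp::export]]
NumericVector nodf_cpp(IntegerMatrix B) {
  double sr, sc;
  int nr, nc;
  nodf_axis(B, true, &sr, &nr);   // row (plant) pairs
  nodf_axis(B, false, &sc, &nc);  // column (animal) pairs
  const double rows = nr > 0 ? sr / nr : 0.0;
  const double cols = nc > 0 ? sc / nc : 0.0;
  const double tot = (nr + nc) > 0 ? (sr + sc) / (nr + nc) : 0.0;
  return NumericVector::create(_["rows"] = rows, _["cols"] = cols,
                               _["total"] = tot);
}

// ---------------------------------------------------------------------------
// Barber bipartite modularity
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double barber_q_cpp(IntegerMatrix B, IntegerVector rmod, IntegerVector cmod) {
  const int P = B.nrow(), A = B.ncol();
  double E = 0.0;
  std::vector<double> kr(P, 0.0), kc(A, 0.0);
  for (int i = 0; i < P; ++i)
    for (int j = 0; j < A; ++j) {
      kr[i] += B(i, j);
      kc[j] += B(i, j);
      E += B(i, j);
    }
  if (E <= 0) return 0.0;
  double q = 0.0;
  for (int i = 0; i < P; ++i)
    for (int j = 0; j < A; ++j)
      if (rmod[i] == cmod[j]) q += B(i, j) - kr[i] * kc[j] / E;
  return q / E;
}

// Internal state for the label-propagation optimizer.
struct LPAState {
  int P, A, N;
  double E;
  std::vector<double> M;  // modularity matrix B - k k'/E, row-major P x A
  std::vector<int> lab;   // labels, plants then animals
  // scratch for sweep(): per-label gain accumulator with a stamp marker
  std::vector<double> gain;
  std::vector<int> stamp, seen;
  int tick = 0;

  inline double m_at(int i, int j) const { return M[i * A + j]; }

  double qval() const {
    double q = 0.0;
    for (int i = 0; i < P; ++i)
      for (int j = 0; j < A; ++j)
        if (lab[i] == lab[P + j]) q += m_at(i, j);
    return q / E;
  }

  // One asynchronous sweep in the given node order; returns number of moves.
  int sweep(const std::vector<int>& order) {
    int moves = 0;
    if ((int)gain.size() < N + 1) {
      gain.assign(N + 1, 0.0);
      stamp.assign(N + 1, -1);
    }
    for (int v : order) {
      ++tick;
      seen.clear();
      const bool is_plant = v < P;
      if (is_plant) {
        const double* row = &M[v * A];
        for (int j = 0; j < A; ++j) {
          const int c = lab[P + j];
          if (stamp[c] != tick) {
            stamp[c] = tick;
            gain[c] = 0.0;
            seen.push_back(c);
          }
          gain[c] += row[j];
        }
      } else {
        const int j = v - P;
        for (int i = 0; i < P; ++i) {
          const int c = lab[i];
          if (stamp[c] != tick) {
            stamp[c] = tick;
            gain[c] = 0.0;
            seen.push_back(c);
          }
          gain[c] += m_at(i, j);
        }
      }
      const int cur = lab[v];
      const double gcur = (stamp[cur] == tick) ? gain[cur] : 0.0;
      int best = cur;
      double gbest = gcur;
      for (int c : seen) {
        // strict improvement required; first-seen label wins ties
        if (gain[c] > gbest + 1e-12) {
          best = c;
          gbest = gain[c];
        }
      }
      if (best != cur && gbest > gcur + 1e-12) {
        lab[v] = best;
        ++moves;
      }
    }
    return moves;
  }

  // Relabel to contiguous 0..K-1; returns K.
  int compress() {
    std::vector<int> map(N + 1, -1);
    int k = 0;
    for (int v = 0; v < N; ++v) {
      if (map[lab[v]] < 0) map[lab[v]] = k++;
      lab[v] = map[lab[v]];
    }
    return k;
  }

  // Greedy pairwise module merging while it improves Q.
  void merge_pass() {
    int K = compress();
    if (K <= 1) return;
    // S[c][d] = sum over plants in c, animals in d of M
    std::vector<std::vector<double>> S(K, std::vector<double>(K, 0.0));
    for (int i = 0; i < P; ++i)
      for (int j = 0; j < A; ++j) S[lab[i]][lab[P + j]] += m_at(i, j);
    std::vector<bool> alive(K, true);
    bool improved = true;
    while (improved) {
      improved = false;
      int bc = -1, bd = -1;
      double bg = 1e-12;
      for (int c = 0; c < K; ++c) {
        if (!alive[c]) continue;
        for (int d = c + 1; d < K; ++d) {
          if (!alive[d]) continue;
          const double g = S[c][d] + S[d][c];
          if (g > bg) {
            bg = g;
            bc = c;
            bd = d;
          }
        }
      }
      if (bc >= 0) {
        for (int e = 0; e < K; ++e) {
          S[bc][e] += S[bd][e];
          S[bd][e] = 0.0;
        }
        for (int e = 0; e < K; ++e) {
          S[e][bc] += S[e][bd];
          S[e][bd] = 0.0;
        }
        alive[bd] = false;
        for (int v = 0; v < N; ++v)
          if (lab[v] == bd) lab[v] = bc;
        improved = true;
      }
    }
    compress();
  }

  void run_to_convergence(std::mt19937& rng, int max_sweeps) {
    std::vector<int> order(N);
    for (int v = 0; v < N; ++v) order[v] = v;
    for (;;) {
      int sweeps = 0;
      while (sweeps < max_sweeps) {
        std::shuffle(order.begin(), order.end(), rng);
        if (sweep(order) == 0) break;
        ++sweeps;
      }
      const double before = qval();
      merge_pass();
      // after merging, labels may admit further single-node moves
      std::shuffle(order.begin(), order.end(), rng);
      if (sweep(order) == 0) break;
      if (qval() <= before + 1e-12) break;
    }
    compress();
  }
};

// Multi-start label propagation with greedy merging and perturbation
// restarts around the incumbent (DIRTLPAwb+-style search).
// [[Rcpp::export]]
List lpa_modules_cpp(IntegerMatrix B, int n_starts, int seed,
                     int max_sweeps = 200) {
  LPAState st;
  st.P = B.nrow();
  st.A = B.ncol();
  st.N = st.P + st.A;
  st.E = 0.0;
  std::vector<double> kr(st.P, 0.0), kc(st.A, 0.0);
  for (int i = 0; i < st.P; ++i)
    for (int j = 0; j < st.A; ++j) {
      kr[i] += B(i, j);
      kc[j] += B(i, j);
      st.E += B(i, j);
    }
  st.M.assign(static_cast<size_t>(st.P) * st.A, 0.0);
  for (int i = 0; i < st.P; ++i)
    for (int j = 0; j < st.A; ++j)
      st.M[i * st.A + j] = B(i, j) - kr[i] * kc[j] / st.E;
  st.lab.assign(st.N, 0);

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::vector<int> best_lab;
  double best_q = -1e18;

  for (int s = 0; s < std::max(1, n_starts); ++s) {
    for (int v = 0; v < st.N; ++v) st.lab[v] = v;  // singleton start
    st.run_to_convergence(rng, max_sweeps);
    const double q = st.qval();
    if (q > best_q) {
      best_q = q;
      best_lab = st.lab;
    }
  }

  // Perturbation phase: jitter the incumbent and re-optimize.
  const int n_perturb = std::max(2, n_starts / 2);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  for (int s = 0; s < n_perturb; ++s) {
    st.lab = best_lab;
    int K = st.compress();
    std::uniform_int_distribution<int> pick(0, std::max(0, K - 1));
    for (int v = 0; v < st.N; ++v)
      if (unif(rng) < 0.25) st.lab[v] = pick(rng);
    st.run_to_convergence(rng, max_sweeps);
    const double q = st.qval();
    if (q > best_q) {
      best_q = q;
      best_lab = st.lab;
    }
  }

  st.lab = best_lab;
  // no modular structure above the one-module baseline: return one module
  if (best_q < 1e-12) {
    for (int v = 0; v < st.N; ++v) st.lab[v] = 0;
    best_q = st.qval();
  }
  const int K = st.compress();
  IntegerVector rmod(st.P), cmod(st.A);
  for (int i = 0; i < st.P; ++i) rmod[i] = st.lab[i];
  for (int j = 0; j < st.A; ++j) cmod[j] = st.lab[st.P + j];
  return List::create(_["row_modules"] = rmod, _["col_modules"] = cmod,
                      _["Q"] = st.qval(), _["n_modules"] = K);
}

// ---------------------------------------------------------------------------
// Curveball fixed-fixed randomization
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix curveball_cpp(IntegerMatrix B, int n_trades, int seed) {
  const int P = B.nrow(), A = B.ncol();
  std::vector<std::vector<int>> rows(P);
  for (int i = 0; i < P; ++i)
    for (int j = 0; j < A; ++j)
      if (B(i, j)) rows[i].push_back(j);
  std::mt19937 rng(static_cast<unsigned int>(seed));
  if (P >= 2) {
    std::uniform_int_distribution<int> pickrow(0, P - 1);
    std::vector<char> in1(A, 0), in2(A, 0);
    for (int t = 0; t < n_trades; ++t) {
      int r1 = pickrow(rng), r2 = pickrow(rng);
      if (r1 == r2) continue;
      for (int j : rows[r1]) in1[j] = 1;
      for (int j : rows[r2]) in2[j] = 1;
      std::vector<int> only1, only2;
      for (int j : rows[r1])
        if (!in2[j]) only1.push_back(j);
      for (int j : rows[r2])
        if (!in1[j]) only2.push_back(j);
      const int n1 = static_cast<int>(only1.size());
      const int n2 = static_cast<int>(only2.size());
      if (n1 > 0 && n2 > 0) {
        std::vector<int> pool(only1);
        pool.insert(pool.end(), only2.begin(), only2.end());
        std::shuffle(pool.begin(), pool.end(), rng);
        std::vector<int> nr1, nr2;
        for (int j : rows[r1])
          if (in2[j]) nr1.push_back(j);
        for (int j : rows[r2])
          if (in1[j]) nr2.push_back(j);
        nr1.insert(nr1.end(), pool.begin(), pool.begin() + n1);
        nr2.insert(nr2.end(), pool.begin() + n1, pool.end());
        rows[r1].swap(nr1);
        rows[r2].swap(nr2);
      }
      for (int j = 0; j < A; ++j) {
        in1[j] = 0;
        in2[j] = 0;
      }
    }
  }
  IntegerMatrix out(P, A);
  for (int i = 0; i < P; ++i)
    for (int j : rows[i]) out(i, j) = 1;
  out.attr("dimnames") = B.attr("dimnames");
  return out;
}

// ---------------------------------------------------------------------------
// Random primary-extinction simulation
// ---------------------------------------------------------------------------

// Removes rows of B one at a time in uniformly random order; counts partner
// columns whose remaining degree hits zero. Returns an n_reps x nrow matrix
// of cumulative secondary-extinction counts. Transpose B to remove columns.
// [[Rcpp::export]]
IntegerMatrix extinction_runs_cpp(IntegerMatrix B, int n_reps, int seed) {
  const int G = B.nrow(), Ap = B.ncol();
  std::vector<std::vector<int>> adj(G);
  std::vector<int> deg0(Ap, 0);
  for (int i = 0; i < G; ++i)
    for (int j = 0; j < Ap; ++j)
      if (B(i, j)) {
        adj[i].push_back(j);
        ++deg0[j];
      }
  std::mt19937 rng(static_cast<unsigned int>(seed));
  IntegerMatrix out(n_reps, G);
  std::vector<int> order(G), deg(Ap);
  for (int r = 0; r < n_reps; ++r) {
    for (int i = 0; i < G; ++i) order[i] = i;
    std::shuffle(order.begin(), order.end(), rng);
    deg = deg0;
    int cum = 0;
    for (int s = 0; s < G; ++s) {
      const int v = order[s];
      for (int j : adj[v])
        if (--deg[j] == 0) ++cum;
      out(r, s) = cum;
    }
  }
  return out;
}
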