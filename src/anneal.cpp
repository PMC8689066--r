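// Simulated-annealing maximization of Barber bipartite modularity.
//
// Q_B = (1/L) * sum_{i in rows, j in cols} (A_ij - k_i * d_j / L) *
//       delta(g_i, g_j)
//
// Moves: single-node reassignments plus occasional whole-module merges and
// random bisection splits, all accepted by the Metropolis rule on dQ at the
// current temperature. Uses R's RNG so runs are reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct State {
  int P, M, L, K;                 // rows, cols, links, label space
  std::vector<std::vector<int>> adj_row;  // col neighbours of each row
  std::vector<std::vector<int>> adj_col;  // row neighbours of each col
  std::vector<int> krow, kcol;    // degrees
  std::vector<int> grow, gcol;    // module labels (0..K-1)
  std::vector<double> srow, scol; // total degree of rows / cols per module

  // edges from row i into module m (counting column neighbours)
  double erow(int i, int m) const {
    int e = 0;
    for (int j : adj_row[i]) if (gcol[j] == m) ++e;
    return e;
  }
  double ecol(int j, int m) const {
    int e = 0;
    for (int i : adj_col[j]) if (grow[i] == m) ++e;
    return e;
  }

  double q() const {
    double within = 0.0, expct = 0.0;
    for (int i = 0; i < P; ++i) within += erow(i, grow[i]);
    for (int m = 0; m < K; ++m) expct += srow[m] * scol[m];
    return within / L - expct / ((double)L * L);
  }

  double dq_move_row(int i, int b) const {
    int a = grow[i];
    if (a == b) return 0.0;
    return (erow(i, b) - erow(i, a)) / L -
           krow[i] * (scol[b] - scol[a]) / ((double)L * L);
  }
  double dq_move_col(int j, int b) const {
    int a = gcol[j];
    if (a == b) return 0.0;
    return (ecol(j, b) - ecol(j, a)) / L -
           kcol[j] * (srow[b] - srow[a]) / ((double)L * L);
  }
  void move_row(int i, int b) {
    srow[grow[i]] -= krow[i];
    srow[b] += krow[i];
    grow[i] = b;
  }
  void move_col(int j, int b) {
    scol[gcol[j]] -= kcol[j];
    scol[b] += kcol[j];
    gcol[j] = b;
  }
};

int runif_int(int n) {  // uniform on 0..n-1
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

}  // namespace

// [[Rcpp::export(name = ".anneal_cpp")]]
List anneal_cpp(IntegerMatrix A, double t0, double cooling, int c_moves,
                double t_min, int stale_stages) {
  State st;
  st.P = A.nrow(); st.M = A.ncol();
  st.K = st.P + st.M;
  st.adj_row.assign(st.P, {});
  st.adj_col.assign(st.M, {});
  st.L = 0;
  for (int i = 0; i < st.P; ++i)
    for (int j = 0; j < st.M; ++j)
      if (A(i, j) > 0) {
        st.adj_row[i].push_back(j);
        st.adj_col[j].push_back(i);
        ++st.L;
      }
  if (st.L == 0) stop("empty network");
  st.krow.resize(st.P); st.kcol.resize(st.M);
  for (int i = 0; i < st.P; ++i) st.krow[i] = st.adj_row[i].size();
  for (int j = 0; j < st.M; ++j) st.kcol[j] = st.adj_col[j].size();
  // start: every node in its own module
  st.grow.resize(st.P); st.gcol.resize(st.M);
  st.srow.assign(st.K, 0.0); st.scol.assign(st.K, 0.0);
  for (int i = 0; i < st.P; ++i) { st.grow[i] = i; st.srow[i] = st.krow[i]; }
  for (int j = 0; j < st.M; ++j) {
    st.gcol[j] = st.P + j;
    st.scol[st.P + j] = st.kcol[j];
  }

  double q = st.q();
  double best_q = q;
  std::vector<int> best_grow = st.grow, best_gcol = st.gcol;

  int n_nodes = st.P + st.M;
  int moves_per_stage = c_moves * n_nodes;
  double T = t0;
  int stale = 0;
  std::vector<double> trace_t, trace_q;

  auto metropolis = [&](double dq) {
    return dq > 0 || unif_rand() < std::exp(dq / T);
  };
  auto remember = [&]() {
    if (q > best_q) {
      best_q = q;
      best_grow = st.grow;
      best_gcol = st.gcol;
    }
  };

  while (T > t_min) {
    int accepted = 0;
    for (int s = 0; s < moves_per_stage; ++s) {
      int node = runif_int(n_nodes);
      int b = runif_int(st.K);
      if (node < st.P) {
        double dq = st.dq_move_row(node, b);
        if (st.grow[node] != b && metropolis(dq)) {
          st.move_row(node, b);
          q += dq; ++accepted; remember();
        }
      } else {
        int j = node - st.P;
        double dq = st.dq_move_col(j, b);
        if (st.gcol[j] != b && metropolis(dq)) {
          st.move_col(j, b);
          q += dq; ++accepted; remember();
        }
      }
    }
    // collective moves: a few merge and split proposals per stage
    for (int s = 0; s < c_moves; ++s) {
      // occupied modules
      std::vector<int> occ;
      std::vector<char> used(st.K, 0);
      for (int i = 0; i < st.P; ++i) used[st.grow[i]] = 1;
      for (int j = 0; j < st.M; ++j) used[st.gcol[j]] = 1;
      for (int m = 0; m < st.K; ++m) if (used[m]) occ.push_back(m);
      if (unif_rand() < 0.5 && occ.size() >= 2) {
        // merge module a into b, node by node, tracking exact dQ
        int a = occ[runif_int(occ.size())], b;
        do { b = occ[runif_int(occ.size())]; } while (b == a);
        std::vector<int> rows_a, cols_a;
        for (int i = 0; i < st.P; ++i) if (st.grow[i] == a) rows_a.push_back(i);
        for (int j = 0; j < st.M; ++j) if (st.gcol[j] == a) cols_a.push_back(j);
        double dq_total = 0.0;
        for (int i : rows_a) { dq_total += st.dq_move_row(i, b); st.move_row(i, b); }
        for (int j : cols_a) { dq_total += st.dq_move_col(j, b); st.move_col(j, b); }
        if (metropolis(dq_total)) {
          q += dq_total; ++accepted; remember();
        } else {  // revert
          for (int i : rows_a) st.move_row(i, a);
          for (int j : cols_a) st.move_col(j, a);
        }
      } else if (!occ.empty()) {
        // split: send a random half of module a to an empty label
        int a = occ[runif_int(occ.size())];
        int empty = -1;
        for (int m = 0; m < st.K; ++m) if (!used[m]) { empty = m; break; }
        if (empty < 0) continue;
        std::vector<int> moved_rows, moved_cols;
        double dq_total = 0.0;
        for (int i = 0; i < st.P; ++i)
          if (st.grow[i] == a && unif_rand() < 0.5) {
            dq_total += st.dq_move_row(i, empty);
            st.move_row(i, empty);
            moved_rows.push_back(i);
          }
        for (int j = 0; j < st.M; ++j)
          if (st.gcol[j] == a && unif_rand() < 0.5) {
            dq_total += st.dq_move_col(j, empty);
            st.move_col(j, empty);
            moved_cols.push_back(j);
          }
        if (moved_rows.empty() && moved_cols.empty()) continue;
        if (metropolis(dq_total)) {
          q += dq_total; ++accepted; remember();
        } else {
          for (int i : moved_rows) st.move_row(i, a);
          for (int j : moved_cols) st.move_col(j, a);
        }
      }
    }
    trace_t.push_back(T);
    trace_q.push_back(best_q);
    stale = (accepted == 0) ? stale + 1 : 0;
    if (stale >= stale_stages) break;
    T *= cooling;
  }

  return List::create(_["row_modules"] = IntegerVector(best_grow.begin(),
                                                       best_grow.end()),
                      _["col_modules"] = IntegerVector(best_gcol.begin(),
                                                       best_gcol.end()),
                      _["q"] = best_q,
                      _["trace_t"] = NumericVector(trace_t.begin(),
                                                   trace_t.end()),
                      _["trace_q"] = NumericVector(trace_q.begin(),
                                                   trace_q.end()));
}
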