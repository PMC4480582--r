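// Core numerics for the mixture-of-Gaussian-Bayesian-networks sampler:
//  - closed-form Normal-Wishart (BGe-type) marginal likelihood of a DAG,
//  - single-edge structure moves,
//  - Gibbs reallocation of observations,
//  - trans-dimensional eject/absorb moves on the number of components.
// All randomness goes through R's RNG so set.seed() gives bit-identical runs.

#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Prior {
  int d;
  double am;       // scalar weight on the prior precision of the mean
  double aw;       // Wishart degrees of freedom
  arma::mat T;     // prior precision (parametric) matrix
  arma::vec mu0;   // prior mean
  bool prior_only = false;  // diagnostic: score as if the data were empty
};

struct Stats {
  double n;
  arma::vec s;     // column sums
  arma::mat M;     // raw scatter  sum_i x_i x_i'
};

struct Component {
  Stats st;
  arma::imat adj;              // d x d, adj(i,j)=1 means i -> j
  arma::vec fam;               // per-node family score under adj
  double score;                // sum(fam)
};

double lmvgamma(double a, int k) {
  double r = 0.25 * k * (k - 1) * std::log(M_PI);
  for (int i = 1; i <= k; ++i) r += std::lgamma(a + 0.5 * (1.0 - i));
  return r;
}

// log marginal likelihood of the columns in S under the projected
// Normal-Wishart prior (subset degrees of freedom aw - d + |S|).
double subset_logml(const Stats& st, const std::vector<int>& S, const Prior& pr) {
  const int k = (int)S.size();
  if (pr.prior_only || k == 0 || st.n <= 0.0) return 0.0;
  const double n = st.n;
  const double awk = pr.aw - pr.d + k;
  arma::uvec idx(k);
  for (int i = 0; i < k; ++i) idx[i] = (arma::uword)S[i];
  arma::vec xbar = st.s.elem(idx) / n;
  arma::mat TS = pr.T.submat(idx, idx);
  arma::mat C = st.M.submat(idx, idx) - n * (xbar * xbar.t());
  arma::vec dv = xbar - pr.mu0.elem(idx);
  arma::mat R = TS + C + (pr.am * n / (pr.am + n)) * (dv * dv.t());
  double ldT, ldR, sgn;
  arma::log_det(ldT, sgn, TS);
  arma::log_det(ldR, sgn, arma::symmatu(R));
  return -0.5 * n * k * std::log(M_PI)
       + 0.5 * k * (std::log(pr.am) - std::log(pr.am + n))
       + 0.5 * awk * ldT - 0.5 * (awk + n) * ldR
       + lmvgamma(0.5 * (awk + n), k) - lmvgamma(0.5 * awk, k);
}

std::vector<int> parents_of(const arma::imat& adj, int j) {
  std::vector<int> P;
  for (int i = 0; i < (int)adj.n_rows; ++i) if (adj(i, j) == 1) P.push_back(i);
  return P;
}

double family_score(const Stats& st, const arma::imat& adj, int j, const Prior& pr) {
  std::vector<int> P = parents_of(adj, j);
  std::vector<int> Pj = P;
  Pj.push_back(j);
  std::sort(Pj.begin(), Pj.end());
  return subset_logml(st, Pj, pr) - subset_logml(st, P, pr);
}

arma::vec all_family_scores(const Stats& st, const arma::imat& adj, const Prior& pr) {
  arma::vec f(pr.d);
  for (int j = 0; j < pr.d; ++j) f[j] = family_score(st, adj, j, pr);
  return f;
}

// Kahn's algorithm.
bool acyclic(const arma::imat& adj) {
  const int d = adj.n_rows;
  std::vector<int> indeg(d, 0);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < d; ++i) indeg[j] += (adj(i, j) != 0);
  std::vector<int> q;
  for (int j = 0; j < d; ++j) if (indeg[j] == 0) q.push_back(j);
  int seen = 0;
  while (!q.empty()) {
    int u = q.back(); q.pop_back(); ++seen;
    for (int v = 0; v < d; ++v)
      if (adj(u, v) != 0 && --indeg[v] == 0) q.push_back(v);
  }
  return seen == d;
}

// Normalizing constant of the cardinality-uniform structure prior:
// Z_d = sum over DAGs of prod_j 1/C(d-1, |pa_j|), via weighted
// inclusion-exclusion over sink sets (Robinson-style recursion with the
// per-node weight W(m) = sum_p C(m, p)/C(d-1, p) for parents drawn from a
// pool of m nodes).
double log_dag_prior_normconst(int d) {
  static std::map<int, double> cache;
  auto it = cache.find(d);
  if (it != cache.end()) return it->second;
  auto lchoose = [](int a, int b) {
    return std::lgamma(a + 1.0) - std::lgamma(b + 1.0) - std::lgamma(a - b + 1.0);
  };
  std::vector<double> W(d, 0.0);
  for (int m = 0; m < d; ++m)
    for (int p = 0; p <= m; ++p)
      W[m] += std::exp(lchoose(m, p) - lchoose(d - 1, p));
  std::vector<double> A(d + 1);
  A[0] = 1.0;
  for (int nn = 1; nn <= d; ++nn) {
    double s = 0.0;
    for (int k = 1; k <= nn; ++k) {
      double term = std::exp(lchoose(nn, k)) * std::pow(W[nn - k], k) * A[nn - k];
      s += (k % 2 == 1) ? term : -term;
    }
    A[nn] = s;
  }
  double v = std::log(A[d]);
  cache[d] = v;
  return v;
}

// uniform over parent-set cardinalities, normalized over all DAGs:
// log p(G) = -sum_j log C(d-1, |pa_j|) - log Z_d
double log_dag_prior(const arma::imat& adj) {
  const int d = adj.n_rows;
  double lp = -log_dag_prior_normconst(d);
  for (int j = 0; j < d; ++j) {
    int p = 0;
    for (int i = 0; i < d; ++i) p += (adj(i, j) != 0);
    lp -= std::lgamma(d) - std::lgamma(p + 1) - std::lgamma(d - p);  // log C(d-1, p)
  }
  return lp;
}

struct EdgeOp { int i, j, type; };  // type: 0 add, 1 delete, 2 reverse

std::vector<EdgeOp> valid_edge_ops(const arma::imat& adj, int max_parents) {
  const int d = adj.n_rows;
  std::vector<EdgeOp> ops;
  arma::imat a = adj;
  std::vector<int> npar(d, 0);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < d; ++i) npar[j] += (adj(i, j) != 0);
  for (int i = 0; i < d; ++i) for (int j = 0; j < d; ++j) {
    if (i == j) continue;
    if (adj(i, j) == 1) {
      ops.push_back({i, j, 1});                       // delete: always acyclic
      if (npar[i] < max_parents) {
        a(i, j) = 0; a(j, i) = 1;                     // reverse
        if (acyclic(a)) ops.push_back({i, j, 2});
        a(i, j) = 1; a(j, i) = 0;
      }
    } else if (adj(j, i) == 0 && npar[j] < max_parents) {
      a(i, j) = 1;                                    // add
      if (acyclic(a)) ops.push_back({i, j, 0});
      a(i, j) = 0;
    }
  }
  return ops;
}

void apply_edge_op(arma::imat& adj, const EdgeOp& op) {
  if (op.type == 0) adj(op.i, op.j) = 1;
  else if (op.type == 1) adj(op.i, op.j) = 0;
  else { adj(op.i, op.j) = 0; adj(op.j, op.i) = 1; }
}

// number of labelled DAGs on d nodes (Robinson's recurrence)
double count_dags(int d) {
  std::vector<double> a(d + 1);
  a[0] = 1.0;
  for (int n = 1; n <= d; ++n) {
    double s = 0.0;
    for (int k = 1; k <= n; ++k) {
      double c = std::exp(std::lgamma(n + 1) - std::lgamma(k + 1) - std::lgamma(n - k + 1));
      double term = c * std::pow(2.0, (double)k * (n - k)) * a[n - k];
      s += (k % 2 == 1) ? term : -term;
    }
    a[n] = s;
  }
  return a[d];
}

arma::imat random_uniform_dag(int d) {
  arma::imat a(d, d);
  for (;;) {
    a.zeros();
    for (int i = 0; i < d; ++i)
      for (int j = 0; j < d; ++j)
        if (i != j && unif_rand() < 0.5) a(i, j) = 1;
    if (acyclic(a)) return a;
  }
}

int sample_categorical_log(const arma::vec& logw) {
  double m = logw.max();
  arma::vec w = arma::exp(logw - m);
  double tot = arma::accu(w);
  double u = unif_rand() * tot, c = 0.0;
  for (arma::uword h = 0; h < w.n_elem; ++h) {
    c += w[h];
    if (u <= c) return (int)h;
  }
  return (int)w.n_elem - 1;
}

void stats_add(Stats& st, const arma::rowvec& x) {
  st.n += 1.0;
  st.s += x.t();
  st.M += x.t() * x;
}

void stats_remove(Stats& st, const arma::rowvec& x) {
  st.n -= 1.0;
  st.s -= x.t();
  st.M -= x.t() * x;
}

Stats stats_of(const arma::mat& X, const std::vector<int>& rows) {
  Stats st;
  const int d = X.n_cols;
  st.n = 0.0;
  st.s = arma::zeros<arma::vec>(d);
  st.M = arma::zeros<arma::mat>(d, d);
  for (int r : rows) stats_add(st, X.row(r));
  return st;
}

double log_alloc_ratio_split(int N, double alpha, int n1, int n2, int n) {
  // p_{N+1}(m') / p_N(m) for splitting a block of n1 + n2 = nb
  const int nb = n1 + n2;
  return std::lgamma((N + 1) * alpha) - std::lgamma(N * alpha)
       + std::lgamma(n + N * alpha) - std::lgamma(n + (N + 1) * alpha)
       + std::lgamma(n1 + alpha) + std::lgamma(n2 + alpha)
       - std::lgamma(alpha) - std::lgamma(nb + alpha);
}

}  // namespace

// [[Rcpp::export]]
bool cpp_is_acyclic(const arma::imat& adj) { return acyclic(adj); }

// [[Rcpp::export]]
double cpp_count_dags(int d) { return count_dags(d); }

// [[Rcpp::export]]
double cpp_log_dag_prior(const arma::imat& adj) { return log_dag_prior(adj); }

// [[Rcpp::export]]
double cpp_log_dag_prior_normconst(int d) { return log_dag_prior_normconst(d); }

// [[Rcpp::export]]
double cpp_gbn_logml(const arma::mat& X, const arma::imat& adj,
                     double am, double aw, const arma::mat& T, const arma::vec& mu0) {
  Prior pr{(int)X.n_cols, am, aw, T, mu0};
  if (X.n_rows == 0) return 0.0;
  std::vector<int> rows(X.n_rows);
  for (arma::uword i = 0; i < X.n_rows; ++i) rows[i] = (int)i;
  Stats st = stats_of(X, rows);
  return arma::accu(all_family_scores(st, adj, pr));
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_family_scores(const arma::mat& X, const arma::imat& adj,
                                      double am, double aw, const arma::mat& T,
                                      const arma::vec& mu0) {
  Prior pr{(int)X.n_cols, am, aw, T, mu0};
  if (X.n_rows == 0) return Rcpp::NumericVector(X.n_cols);
  std::vector<int> rows(X.n_rows);
  for (arma::uword i = 0; i < X.n_rows; ++i) rows[i] = (int)i;
  Stats st = stats_of(X, rows);
  return Rcpp::wrap(all_family_scores(st, adj, pr));
}

// Marginal likelihood of a column subset (0-based indices) under the
// projected prior; the node-j family score is subset(P+j) - subset(P).
// [[Rcpp::export]]
double cpp_subset_logml(const arma::mat& X, const arma::ivec& subset,
                        double am, double aw, const arma::mat& T,
                        const arma::vec& mu0) {
  Prior pr{(int)X.n_cols, am, aw, T, mu0};
  if (X.n_rows == 0 || subset.n_elem == 0) return 0.0;
  std::vector<int> rows(X.n_rows);
  for (arma::uword i = 0; i < X.n_rows; ++i) rows[i] = (int)i;
  Stats st = stats_of(X, rows);
  std::vector<int> S(subset.begin(), subset.end());
  return subset_logml(st, S, pr);
}

// [[Rcpp::export]]
Rcpp::List cpp_dag_neighbors(const arma::imat& adj, int max_parents) {
  std::vector<EdgeOp> ops = valid_edge_ops(adj, max_parents);
  Rcpp::List out(ops.size());
  Rcpp::CharacterVector kind(ops.size());
  const char* nm[3] = {"add", "delete", "reverse"};
  for (size_t t = 0; t < ops.size(); ++t) {
    arma::imat a = adj;
    apply_edge_op(a, ops[t]);
    out[t] = Rcpp::wrap(a);
    kind[t] = nm[ops[t].type];
  }
  out.attr("kind") = kind;
  return out;
}

// Full-conditional log weights for reallocating observation i (1-based) among
// the current components: predictive likelihood contribution + log(n_h^{-i} + alpha).
// [[Rcpp::export]]
arma::vec cpp_gibbs_logweights(const arma::mat& X, const arma::ivec& labels,
                               const Rcpp::List& dags, int i, double am, double aw,
                               const arma::mat& T, const arma::vec& mu0, double alpha) {
  Prior pr{(int)X.n_cols, am, aw, T, mu0};
  const int N = dags.size();
  const int i0 = i - 1;
  arma::vec lw(N);
  for (int h = 0; h < N; ++h) {
    arma::imat adj = Rcpp::as<arma::imat>(dags[h]);
    std::vector<int> rows;
    for (arma::uword r = 0; r < X.n_rows; ++r)
      if (labels[r] == h + 1 && (int)r != i0) rows.push_back((int)r);
    Stats st = stats_of(X, rows);
    double base = arma::accu(all_family_scores(st, adj, pr));
    stats_add(st, X.row(i0));
    double with = arma::accu(all_family_scores(st, adj, pr));
    lw[h] = (with - base) + std::log((double)rows.size() + alpha);
  }
  return lw;
}

// [[Rcpp::export]]
Rcpp::List cpp_run_mcmc(const arma::mat& X, double am, double aw,
                        const arma::mat& T, const arma::vec& mu0,
                        int n_iterations, int burn_in, int thinning,
                        double alpha, double lambda,
                        const arma::vec& move_probs,  // edge, gibbs, eject, absorb
                        int max_parents, bool prior_only) {
  const int n = X.n_rows, d = X.n_cols;
  Prior pr{d, am, aw, T, mu0, prior_only};
  const double log_u_dag = -std::log(count_dags(d));

  // initial state: one component, empty DAG
  std::vector<int> lab(n, 0);
  std::vector<Component> comp;
  {
    Component c;
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = i;
    c.st = stats_of(X, rows);
    c.adj = arma::zeros<arma::imat>(d, d);
    c.fam = all_family_scores(c.st, c.adj, pr);
    c.score = arma::accu(c.fam);
    comp.push_back(c);
  }

  const int r_expected = (n_iterations - burn_in) / thinning;
  Rcpp::List samples(std::max(r_expected, 0));
  int kept = 0;
  // move bookkeeping: proposals / acceptances per move type
  arma::ivec prop(4, arma::fill::zeros), acc(4, arma::fill::zeros);

  arma::vec mp = move_probs / arma::accu(move_probs);

  for (int it = 1; it <= n_iterations; ++it) {
    if (it % 4096 == 0) Rcpp::checkUserInterrupt();
    double u = unif_rand();
    int move = 0;
    {
      double c0 = mp[0], c1 = c0 + mp[1], c2 = c1 + mp[2];
      move = (u < c0) ? 0 : (u < c1) ? 1 : (u < c2) ? 2 : 3;
    }
    const int N = (int)comp.size();

    if (move == 0 && d > 1) {
      // one Metropolis-Hastings single-edge move per component
      for (int h = 0; h < N; ++h) {
        prop[0]++;
        std::vector<EdgeOp> ops = valid_edge_ops(comp[h].adj, max_parents);
        if (ops.empty()) continue;
        int pick = (int)std::floor(unif_rand() * ops.size());
        if (pick >= (int)ops.size()) pick = (int)ops.size() - 1;
        arma::imat prop_adj = comp[h].adj;
        apply_edge_op(prop_adj, ops[pick]);
        arma::vec fam2 = comp[h].fam;
        // only touched families change
        fam2[ops[pick].j] = family_score(comp[h].st, prop_adj, ops[pick].j, pr);
        if (ops[pick].type == 2)
          fam2[ops[pick].i] = family_score(comp[h].st, prop_adj, ops[pick].i, pr);
        double score2 = arma::accu(fam2);
        size_t k2 = valid_edge_ops(prop_adj, max_parents).size();
        double logA = (score2 + log_dag_prior(prop_adj))
                    - (comp[h].score + log_dag_prior(comp[h].adj))
                    + std::log((double)ops.size()) - std::log((double)k2);
        if (std::log(unif_rand()) < logA) {
          comp[h].adj = prop_adj;
          comp[h].fam = fam2;
          comp[h].score = score2;
          acc[0]++;
        }
      }
    } else if (move == 1 || (move == 0 && d == 1)) {
      // Gibbs reallocation pass; singleton components may not be emptied
      prop[1]++;
      if (N >= 2) {
        for (int i = 0; i < n; ++i) {
          int c = lab[i];
          if (comp[c].st.n <= 1.0) continue;
          Stats st_minus = comp[c].st;
          stats_remove(st_minus, X.row(i));
          double score_c_minus = arma::accu(all_family_scores(st_minus, comp[c].adj, pr));
          arma::vec lw(N);
          std::vector<double> plus_score(N);
          for (int h = 0; h < N; ++h) {
            double nm_h, delta;
            if (h == c) {
              nm_h = comp[c].st.n - 1.0;
              delta = comp[c].score - score_c_minus;
              plus_score[h] = comp[c].score;
            } else {
              nm_h = comp[h].st.n;
              Stats st_plus = comp[h].st;
              stats_add(st_plus, X.row(i));
              plus_score[h] = arma::accu(all_family_scores(st_plus, comp[h].adj, pr));
              delta = plus_score[h] - comp[h].score;
            }
            lw[h] = delta + std::log(nm_h + alpha);
          }
          int hnew = sample_categorical_log(lw);
          if (hnew != c) {
            stats_remove(comp[c].st, X.row(i));
            comp[c].fam = all_family_scores(comp[c].st, comp[c].adj, pr);
            comp[c].score = arma::accu(comp[c].fam);
            stats_add(comp[hnew].st, X.row(i));
            comp[hnew].fam = all_family_scores(comp[hnew].st, comp[hnew].adj, pr);
            comp[hnew].score = plus_score[hnew];
            lab[i] = hnew;
          }
        }
      }
      acc[1]++;
    } else {
      // Anchored split-merge (eject/absorb) with restricted-Gibbs launch:
      // draw an ordered pair of observations (i, j); if they share a
      // component the component is split (side of i keeps the component's
      // DAG, side of j gets a uniformly drawn DAG, members are allocated by
      // a restricted Gibbs scan from a launch state); otherwise their two
      // components are merged (keeping the DAG of i's component). The
      // final-scan probability and the DAG-draw density enter the
      // acceptance ratio, so the pair of moves is reversible.
      int ai = 0, aj = 0;
      if (n >= 2) {
        ai = (int)std::floor(unif_rand() * n);
        if (ai >= n) ai = n - 1;
        aj = (int)std::floor(unif_rand() * (n - 1));
        if (aj >= n - 1) aj = n - 2;
        if (aj >= ai) aj += 1;
      }
      const int t_scans = 3;

      if (n < 2) {
        // a single observation admits no component change
      } else if (lab[ai] == lab[aj]) {
        // SPLIT
        prop[2]++;
        int h = lab[ai];
        std::vector<int> S;
        for (int i = 0; i < n; ++i)
          if (lab[i] == h && i != ai && i != aj) S.push_back(i);
        arma::imat Gnew = random_uniform_dag(d);
        // side 0: keeps comp h's dag; side 1: new dag
        Stats st0, st1;
        st0.n = 0; st0.s = arma::zeros<arma::vec>(d);
        st0.M = arma::zeros<arma::mat>(d, d);
        st1 = st0;
        stats_add(st0, X.row(ai));
        stats_add(st1, X.row(aj));
        std::vector<int> z(S.size());
        for (size_t m = 0; m < S.size(); ++m) {
          z[m] = (unif_rand() < 0.5) ? 0 : 1;
          stats_add(z[m] == 0 ? st0 : st1, X.row(S[m]));
        }
        double sc0 = arma::accu(all_family_scores(st0, comp[h].adj, pr));
        double sc1 = arma::accu(all_family_scores(st1, Gnew, pr));
        double logq_final = 0.0;
        for (int scan = 0; scan <= t_scans; ++scan) {
          bool record = (scan == t_scans);
          for (size_t m = 0; m < S.size(); ++m) {
            Stats& cur = (z[m] == 0) ? st0 : st1;
            double& cursc = (z[m] == 0) ? sc0 : sc1;
            stats_remove(cur, X.row(S[m]));
            cursc = arma::accu(all_family_scores(
                cur, (z[m] == 0) ? comp[h].adj : Gnew, pr));
            Stats tr0 = st0; stats_add(tr0, X.row(S[m]));
            double with0 = arma::accu(all_family_scores(tr0, comp[h].adj, pr));
            Stats tr1 = st1; stats_add(tr1, X.row(S[m]));
            double with1 = arma::accu(all_family_scores(tr1, Gnew, pr));
            double lw0 = (with0 - sc0) + std::log(st0.n + alpha);
            double lw1 = (with1 - sc1) + std::log(st1.n + alpha);
            double mx = std::max(lw0, lw1);
            double p0 = std::exp(lw0 - mx), p1 = std::exp(lw1 - mx);
            int pick = (unif_rand() * (p0 + p1) <= p0) ? 0 : 1;
            if (record)
              logq_final += (pick == 0 ? lw0 : lw1) - mx - std::log(p0 + p1);
            z[m] = pick;
            if (pick == 0) { st0 = tr0; sc0 = with0; }
            else           { st1 = tr1; sc1 = with1; }
          }
        }
        int n0 = (int)st0.n, n1s = (int)st1.n;
        double dlp = sc0 + sc1 - comp[h].score + log_dag_prior(Gnew)
                   + log_alloc_ratio_split(N, alpha, n0, n1s, n)
                   + std::log(lambda);
        if (std::log(unif_rand()) < dlp - (log_u_dag + logq_final)) {
          Component cnew;
          cnew.st = st1; cnew.adj = Gnew;
          cnew.fam = all_family_scores(st1, Gnew, pr); cnew.score = sc1;
          comp[h].st = st0;
          comp[h].fam = all_family_scores(st0, comp[h].adj, pr);
          comp[h].score = sc0;
          lab[aj] = N;
          for (size_t m = 0; m < S.size(); ++m)
            lab[S[m]] = (z[m] == 0) ? h : N;
          comp.push_back(cnew);
          acc[2]++;
        }
      } else {
        // MERGE (components of i and j; the merged block keeps i's DAG)
        prop[3]++;
        int c1 = lab[ai], c2 = lab[aj];
        std::vector<int> S;
        for (int i = 0; i < n; ++i)
          if ((lab[i] == c1 || lab[i] == c2) && i != ai && i != aj)
            S.push_back(i);
        int n1 = (int)comp[c1].st.n, n2 = (int)comp[c2].st.n;
        // launch state for the hypothetical reverse split
        Stats st0, st1;
        st0.n = 0; st0.s = arma::zeros<arma::vec>(d);
        st0.M = arma::zeros<arma::mat>(d, d);
        st1 = st0;
        stats_add(st0, X.row(ai));
        stats_add(st1, X.row(aj));
        std::vector<int> z(S.size());
        for (size_t m = 0; m < S.size(); ++m) {
          z[m] = (unif_rand() < 0.5) ? 0 : 1;
          stats_add(z[m] == 0 ? st0 : st1, X.row(S[m]));
        }
        double sc0 = arma::accu(all_family_scores(st0, comp[c1].adj, pr));
        double sc1 = arma::accu(all_family_scores(st1, comp[c2].adj, pr));
        double logq_rev = 0.0;
        for (int scan = 0; scan <= t_scans; ++scan) {
          bool final_scan = (scan == t_scans);
          for (size_t m = 0; m < S.size(); ++m) {
            Stats& cur = (z[m] == 0) ? st0 : st1;
            stats_remove(cur, X.row(S[m]));
            if (z[m] == 0)
              sc0 = arma::accu(all_family_scores(st0, comp[c1].adj, pr));
            else
              sc1 = arma::accu(all_family_scores(st1, comp[c2].adj, pr));
            Stats tr0 = st0; stats_add(tr0, X.row(S[m]));
            double with0 = arma::accu(all_family_scores(tr0, comp[c1].adj, pr));
            Stats tr1 = st1; stats_add(tr1, X.row(S[m]));
            double with1 = arma::accu(all_family_scores(tr1, comp[c2].adj, pr));
            double lw0 = (with0 - sc0) + std::log(st0.n + alpha);
            double lw1 = (with1 - sc1) + std::log(st1.n + alpha);
            double mx = std::max(lw0, lw1);
            double p0 = std::exp(lw0 - mx), p1 = std::exp(lw1 - mx);
            int pick;
            if (final_scan) {
              pick = (lab[S[m]] == c1) ? 0 : 1;  // the actual assignment
              logq_rev += (pick == 0 ? lw0 : lw1) - mx - std::log(p0 + p1);
            } else {
              pick = (unif_rand() * (p0 + p1) <= p0) ? 0 : 1;
            }
            z[m] = pick;
            if (pick == 0) { st0 = tr0; sc0 = with0; }
            else           { st1 = tr1; sc1 = with1; }
          }
        }
        Stats stm = comp[c1].st;
        stm.n += comp[c2].st.n; stm.s += comp[c2].st.s;
        stm.M += comp[c2].st.M;
        arma::vec famm = all_family_scores(stm, comp[c1].adj, pr);
        double sm = arma::accu(famm);
        double dlp = sm - comp[c1].score - comp[c2].score
                   - log_dag_prior(comp[c2].adj)
                   - log_alloc_ratio_split(N - 1, alpha, n1, n2, n)
                   - std::log(lambda);
        if (std::log(unif_rand()) < dlp + log_u_dag + logq_rev) {
          int lo = std::min(c1, c2), hi = std::max(c1, c2);
          Component merged;
          merged.st = stm; merged.adj = comp[c1].adj;
          merged.fam = famm; merged.score = sm;
          comp[lo] = merged;
          comp.erase(comp.begin() + hi);
          for (int i = 0; i < n; ++i) {
            if (lab[i] == hi) lab[i] = lo;
            else if (lab[i] > hi) lab[i] -= 1;
          }
          acc[3]++;
        }
      }
    }

    if (it > burn_in && (it - burn_in) % thinning == 0 && kept < r_expected) {
      // refresh sufficient statistics from scratch to stop rounding drift
      const int Nc = (int)comp.size();
      double logpost = 0.0;
      Rcpp::List dags(Nc);
      Rcpp::IntegerVector sizes(Nc);
      for (int h = 0; h < Nc; ++h) {
        std::vector<int> rows;
        for (int i = 0; i < n; ++i) if (lab[i] == h) rows.push_back(i);
        comp[h].st = stats_of(X, rows);
        comp[h].fam = all_family_scores(comp[h].st, comp[h].adj, pr);
        comp[h].score = arma::accu(comp[h].fam);
        logpost += comp[h].score + log_dag_prior(comp[h].adj);
        sizes[h] = (int)rows.size();
        dags[h] = Rcpp::wrap(comp[h].adj);
      }
      logpost += std::lgamma(Nc * alpha) - std::lgamma(n + Nc * alpha);
      for (int h = 0; h < Nc; ++h)
        logpost += std::lgamma(sizes[h] + alpha) - std::lgamma(alpha);
      logpost += Nc * std::log(lambda) - std::lgamma(Nc + 1.0)
               - std::log(std::expm1(lambda));
      Rcpp::IntegerVector lab1(n);
      for (int i = 0; i < n; ++i) lab1[i] = lab[i] + 1;
      samples[kept] = Rcpp::List::create(
          Rcpp::Named("iteration") = it,
          Rcpp::Named("n_components") = Nc,
          Rcpp::Named("allocation") = lab1,
          Rcpp::Named("component_sizes") = sizes,
          Rcpp::Named("dags") = dags,
          Rcpp::Named("log_posterior") = logpost);
      kept++;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("samples") = samples,
      Rcpp::Named("proposed") = Rcpp::wrap(prop),
      Rcpp::Named("accepted") = Rcpp::wrap(acc));
}
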