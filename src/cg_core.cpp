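// Conditional-Gaussian network scoring and search.
//
// Discrete nodes: multinomial likelihood with a symmetric Dirichlet prior,
// integrated in closed form per discrete-parent configuration.
// Continuous nodes: linear-Gaussian likelihood on (intercept, continuous
// parents) with a normal-inverse-gamma prior, integrated in closed form per
// discrete-parent configuration (a multivariate Student-t predictive).
//
// Structures are held as per-node parent bitmasks (<= 30 nodes).  Local
// scores are memoised on (node, parent mask), which makes exhaustive
// enumeration and hill-climbing cheap: most structures share parent sets.

#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Per-node hyperparameters (vectors aligned with the data columns).
struct CGPrior {
  std::vector<double> dir;     // Dirichlet pseudo-count per cell
  std::vector<double> mu;      // prior mean for the node's intercept
  std::vector<double> mucoef;  // prior mean for regression coefficients
  std::vector<double> tau;     // prior precision scale on coefficients
  std::vector<double> rho;     // inverse-gamma shape (variance ~ IG(rho/2, phi/2))
  std::vector<double> phi;     // inverse-gamma scale
};

class CGScorer {
public:
  const arma::mat& X;                // n x p data, discrete columns coded 0..levels-1
  const std::vector<int>& disc;      // 1 if discrete
  const std::vector<int>& levels;
  CGPrior pr;
  int n, p;
  std::unordered_map<uint64_t, double> cache;

  CGScorer(const arma::mat& X_, const std::vector<int>& disc_,
           const std::vector<int>& levels_, const CGPrior& pr_)
    : X(X_), disc(disc_), levels(levels_), pr(pr_) {
    n = X.n_rows;
    p = X.n_cols;
  }

  double local(int node, uint32_t pmask) {
    uint64_t key = (static_cast<uint64_t>(node) << 32) | pmask;
    auto it = cache.find(key);
    if (it != cache.end()) return it->second;
    double v = compute_local(node, pmask);
    cache.emplace(key, v);
    return v;
  }

  double struct_score(const std::vector<uint32_t>& pm) {
    double s = 0.0;
    for (int i = 0; i < p; ++i) s += local(i, pm[i]);
    return s;
  }

  // score of the null network: every edge incident to node d removed
  double null_score(const std::vector<uint32_t>& pm, int d) {
    double s = 0.0;
    uint32_t dbit = 1u << d;
    for (int i = 0; i < p; ++i)
      s += local(i, i == d ? 0u : (pm[i] & ~dbit));
    return s;
  }

private:
  double compute_local(int node, uint32_t pmask) {
    std::vector<int> dp, cp;
    for (int j = 0; j < p; ++j) {
      if (pmask >> j & 1u) {
        if (disc[j]) dp.push_back(j); else cp.push_back(j);
      }
    }
    if (disc[node] && !cp.empty())
      stop("continuous parent of a discrete node violates the CG restriction");

    long ncfg = 1;
    for (int j : dp) ncfg *= levels[j];
    if (ncfg > 59049)  // 3^10 guard on the configuration table
      stop("too many discrete-parent configurations");

    std::vector<int> cfg(n, 0);
    {
      long radix = 1;
      for (int j : dp) {
        for (int i = 0; i < n; ++i)
          cfg[i] += static_cast<int>(radix * static_cast<long>(X(i, j)));
        radix *= levels[j];
      }
    }

    if (disc[node]) {
      const int L = levels[node];
      std::vector<double> cnt(static_cast<size_t>(ncfg) * L, 0.0);
      std::vector<double> tot(ncfg, 0.0);
      for (int i = 0; i < n; ++i) {
        cnt[static_cast<size_t>(cfg[i]) * L + static_cast<int>(X(i, node))] += 1.0;
        tot[cfg[i]] += 1.0;
      }
      const double a = pr.dir[node];
      double out = 0.0;
      for (long c = 0; c < ncfg; ++c) {
        if (tot[c] == 0.0) continue;
        out += std::lgamma(L * a) - std::lgamma(L * a + tot[c]);
        for (int k = 0; k < L; ++k)
          out += std::lgamma(a + cnt[static_cast<size_t>(c) * L + k]) - std::lgamma(a);
      }
      return out;
    }

    // continuous node: NIG marginal per discrete-parent configuration
    const int q = static_cast<int>(cp.size()) + 1;  // intercept + cont parents
    std::vector<std::vector<int>> rows(ncfg);
    for (int i = 0; i < n; ++i) rows[cfg[i]].push_back(i);

    const double tau = pr.tau[node];
    const double a0 = pr.rho[node] / 2.0, b0 = pr.phi[node] / 2.0;
    arma::vec m0(q);
    m0(0) = pr.mu[node];
    for (int k = 1; k < q; ++k) m0(k) = pr.mucoef[node];
    double out = 0.0;
    for (long c = 0; c < ncfg; ++c) {
      const int nj = static_cast<int>(rows[c].size());
      if (nj == 0) continue;
      arma::mat Z(nj, q);
      arma::vec y(nj);
      for (int r = 0; r < nj; ++r) {
        const int i = rows[c][r];
        Z(r, 0) = 1.0;
        for (size_t k = 0; k < cp.size(); ++k) Z(r, k + 1) = X(i, cp[k]);
        y(r) = X(i, node);
      }
      arma::mat Ln = tau * arma::eye(q, q) + Z.t() * Z;
      arma::vec rhs = tau * m0 + Z.t() * y;
      arma::vec mun;
      double ldet;
      bool ok = arma::solve(mun, Ln, rhs, arma::solve_opts::likely_sympd);
      if (ok) {
        double sign;
        ok = arma::log_det(ldet, sign, Ln) && sign > 0.0;
      }
      if (!ok) stop("singular posterior precision in continuous local score");
      const double an = a0 + nj / 2.0;
      const double bn = b0 + 0.5 * (arma::dot(y, y)
                                    + tau * arma::dot(m0, m0)
                                    - arma::dot(mun, Ln * mun));
      if (bn <= 0.0) stop("non-positive posterior scale in continuous local score");
      out += -0.5 * nj * std::log(2.0 * M_PI)
             + 0.5 * (q * std::log(tau) - ldet)
             + a0 * std::log(b0) - an * std::log(bn)
             + std::lgamma(an) - std::lgamma(a0);
    }
    return out;
  }
};

bool acyclic(const std::vector<uint32_t>& pm, int p) {
  uint32_t removed = 0;
  const uint32_t all = (p >= 32) ? ~0u : ((1u << p) - 1u);
  bool progress = true;
  while (progress) {
    progress = false;
    for (int i = 0; i < p; ++i) {
      if (removed >> i & 1u) continue;
      if ((pm[i] & ~removed) == 0u) {
        removed |= 1u << i;
        progress = true;
      }
    }
  }
  return removed == all;
}

// lexicographic order of edge sets represented as sorted candidate-index lists
bool lex_less(uint32_t a, uint32_t b, int m) {
  for (int k = 0; k < m; ++k) {
    const bool ia = a >> k & 1u, ib = b >> k & 1u;
    if (ia == ib) continue;
    if (ia) {
      // a's next element is k; b's next is larger or absent
      return (b >> k) != 0u ? true : false;
    } else {
      return (a >> k) != 0u ? false : true;
    }
  }
  return false;
}

// prior arrives as a list of per-node numeric vectors, aligned with columns
CGPrior as_prior(const List& prior) {
  CGPrior pr;
  pr.dir    = as<std::vector<double>>(prior["dirichlet"]);
  pr.mu     = as<std::vector<double>>(prior["mu"]);
  pr.mucoef = as<std::vector<double>>(prior["mucoef"]);
  pr.tau    = as<std::vector<double>>(prior["tau"]);
  pr.rho    = as<std::vector<double>>(prior["rho"]);
  pr.phi    = as<std::vector<double>>(prior["phi"]);
  return pr;
}

std::vector<int> as_int_vec(const IntegerVector& v) {
  return std::vector<int>(v.begin(), v.end());
}

}  // namespace

// [[Rcpp::export]]
double cpp_local_score(const arma::mat& X, IntegerVector disc, IntegerVector levels,
                       int node, IntegerVector parents, List prior) {
  std::vector<int> d = as_int_vec(disc), l = as_int_vec(levels);
  CGScorer sc(X, d, l, as_prior(prior));
  uint32_t pmask = 0;
  for (int j : parents) pmask |= 1u << j;
  return sc.local(node, pmask);
}

// [[Rcpp::export]]
List cpp_network_score(const arma::mat& X, IntegerVector disc, IntegerVector levels,
                       IntegerVector parent_masks, int d_index, List prior) {
  std::vector<int> d = as_int_vec(disc), l = as_int_vec(levels);
  CGScorer sc(X, d, l, as_prior(prior));
  std::vector<uint32_t> pm(parent_masks.begin(), parent_masks.end());
  const double S = sc.struct_score(pm);
  double S0 = NA_REAL;
  if (d_index >= 0) S0 = sc.null_score(pm, d_index);
  return List::create(_["S"] = S, _["S0"] = S0);
}

// Enumerate every acyclic subset of the admissible candidate edges on the
// given node set and return the structure maximizing the objective (network
// score S or the average network improvement score phi).  Ties are broken by
// the canonically earlier edge set.
// [[Rcpp::export]]
List cpp_best_structure(const arma::mat& X, IntegerVector disc, IntegerVector levels,
                        IntegerVector allowed, int d_index, List prior,
                        double lambda, double alpha, std::string objective,
                        bool return_all = false) {
  std::vector<int> d = as_int_vec(disc), l = as_int_vec(levels);
  CGScorer sc(X, d, l, as_prior(prior));
  const int p = X.n_cols;

  std::vector<std::pair<int,int>> cand;  // (parent, child), parent-major order
  for (int u = 0; u < p; ++u)
    for (int v = 0; v < p; ++v)
      if (allowed[v] >> u & 1) cand.push_back({u, v});
  const int m = static_cast<int>(cand.size());
  if (m > 25) stop("candidate edge set too large for exhaustive enumeration");

  std::vector<uint32_t> pm(p);
  uint32_t best_mask = 0;
  double best_obj = -std::numeric_limits<double>::infinity();
  double best_S = NA_REAL, best_S0 = NA_REAL, best_phi = NA_REAL;
  long n_struct = 0;

  std::vector<double> all_S, all_S0, all_phi;
  std::vector<uint32_t> all_mask;

  const uint32_t top = 1u << m;
  for (uint32_t mask = 0; mask < top; ++mask) {
    std::fill(pm.begin(), pm.end(), 0u);
    for (int k = 0; k < m; ++k)
      if (mask >> k & 1u) pm[cand[k].second] |= 1u << cand[k].first;
    if (!acyclic(pm, p)) continue;
    ++n_struct;
    const double S = sc.struct_score(pm);
    const double S0 = sc.null_score(pm, d_index);
    const double ph = (lambda * (S - S0) + (1.0 - lambda) * S) / alpha;
    const double obj = (objective == "S") ? S : ph;
    if (obj > best_obj ||
        (obj == best_obj && lex_less(mask, best_mask, m))) {
      best_obj = obj; best_mask = mask;
      best_S = S; best_S0 = S0; best_phi = ph;
    }
    if (return_all) {
      all_mask.push_back(mask);
      all_S.push_back(S); all_S0.push_back(S0); all_phi.push_back(ph);
    }
  }

  std::vector<int> eu, ev;
  for (int k = 0; k < m; ++k)
    if (best_mask >> k & 1u) { eu.push_back(cand[k].first + 1); ev.push_back(cand[k].second + 1); }

  IntegerMatrix edges(eu.size(), 2);
  for (size_t k = 0; k < eu.size(); ++k) { edges(k, 0) = eu[k]; edges(k, 1) = ev[k]; }

  List out = List::create(
    _["edges"] = edges, _["S"] = best_S, _["S0"] = best_S0, _["phi"] = best_phi,
    _["objective"] = best_obj, _["n_structures"] = static_cast<double>(n_struct));
  if (return_all) {
    IntegerMatrix cm(m, 2);
    for (int k = 0; k < m; ++k) { cm(k, 0) = cand[k].first + 1; cm(k, 1) = cand[k].second + 1; }
    out["all"] = DataFrame::create(
      _["mask"] = IntegerVector(all_mask.begin(), all_mask.end()),
      _["S"] = NumericVector(all_S.begin(), all_S.end()),
      _["S0"] = NumericVector(all_S0.begin(), all_S0.end()),
      _["phi"] = NumericVector(all_phi.begin(), all_phi.end()));
    out["candidates"] = cm;
  }
  return out;
}

namespace {

int active_nodes(const std::vector<uint32_t>& pm, int p) {
  uint32_t act = 0;
  for (int i = 0; i < p; ++i) {
    if (pm[i]) { act |= 1u << i; act |= pm[i]; }
  }
  int c = 0;
  for (int i = 0; i < p; ++i) c += (act >> i) & 1u;
  return c;
}

}  // namespace

// Greedy hill-climbing with random restarts over admissible structures.
// One iteration = one accepted single-edge modification (add/delete/reverse);
// the search stops when no move strictly improves the objective or when
// max_iter accepted moves have been made.  Uses R's RNG (seed via set.seed).
// [[Rcpp::export]]
List cpp_greedy(const arma::mat& X, IntegerVector disc, IntegerVector levels,
                IntegerVector allowed, int d_index, List prior,
                double lambda, std::string objective,
                int restarts, int max_iter, int node_cap, double init_prob) {
  std::vector<int> d = as_int_vec(disc), l = as_int_vec(levels);
  CGScorer sc(X, d, l, as_prior(prior));
  const int p = X.n_cols;
  const double alpha = static_cast<double>(p);

  std::vector<uint32_t> best_pm(p, 0u);
  double best_obj = -std::numeric_limits<double>::infinity();
  NumericMatrix log(restarts, 2);

  for (int rs = 0; rs < restarts; ++rs) {
    // random topological order (Fisher-Yates), then sparse random edges
    std::vector<int> perm(p);
    for (int i = 0; i < p; ++i) perm[i] = i;
    for (int i = p - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    std::vector<uint32_t> pm(p, 0u);
    for (int a = 0; a < p; ++a) {
      for (int b = a + 1; b < p; ++b) {
        const int u = perm[a], v = perm[b];
        if (!(allowed[v] >> u & 1)) continue;
        if (unif_rand() >= init_prob) continue;
        pm[v] |= 1u << u;
        if (node_cap > 0 && active_nodes(pm, p) > node_cap) pm[v] &= ~(1u << u);
      }
    }

    auto obj_of = [&](const std::vector<uint32_t>& s) {
      const double S = sc.struct_score(s);
      if (objective == "S") return S;
      const double S0 = sc.null_score(s, d_index);
      return (lambda * (S - S0) + (1.0 - lambda) * S) / alpha;
    };

    double cur = obj_of(pm);
    int iters = 0;
    while (iters < max_iter) {
      double cand_best = cur;
      int mu = -1, mv = -1, mtype = -1;  // 0 add, 1 delete, 2 reverse
      std::vector<uint32_t> tmp = pm;

      for (int u = 0; u < p; ++u) {
        for (int v = 0; v < p; ++v) {
          if (u == v) continue;
          const bool present = pm[v] >> u & 1u;
          // add
          if (!present && (allowed[v] >> u & 1)) {
            tmp[v] = pm[v] | (1u << u);
            bool ok = acyclic(tmp, p);
            if (ok && node_cap > 0 && active_nodes(tmp, p) > node_cap) ok = false;
            if (ok) {
              const double o = obj_of(tmp);
              if (o > cand_best) { cand_best = o; mu = u; mv = v; mtype = 0; }
            }
            tmp[v] = pm[v];
          }
          // delete
          if (present) {
            tmp[v] = pm[v] & ~(1u << u);
            const double o = obj_of(tmp);
            if (o > cand_best) { cand_best = o; mu = u; mv = v; mtype = 1; }
            tmp[v] = pm[v];
          }
          // reverse u->v into v->u
          if (present && (allowed[u] >> v & 1)) {
            tmp[v] = pm[v] & ~(1u << u);
            tmp[u] = pm[u] | (1u << v);
            if (acyclic(tmp, p)) {
              const double o = obj_of(tmp);
              if (o > cand_best) { cand_best = o; mu = u; mv = v; mtype = 2; }
            }
            tmp[v] = pm[v]; tmp[u] = pm[u];
          }
        }
      }

      if (mtype < 0) break;  // local optimum
      if (mtype == 0) pm[mv] |= 1u << mu;
      else if (mtype == 1) pm[mv] &= ~(1u << mu);
      else { pm[mv] &= ~(1u << mu); pm[mu] |= 1u << mv; }
      cur = cand_best;
      ++iters;
    }

    log(rs, 0) = iters;
    log(rs, 1) = cur;
    if (cur > best_obj) { best_obj = cur; best_pm = pm; }
  }

  const double S = sc.struct_score(best_pm);
  const double S0 = sc.null_score(best_pm, d_index);
  const double ph = (lambda * (S - S0) + (1.0 - lambda) * S) / alpha;
  colnames(log) = CharacterVector::create("iterations", "objective");
  return List::create(
    _["parent_masks"] = IntegerVector(best_pm.begin(), best_pm.end()),
    _["S"] = S, _["S0"] = S0, _["phi"] = ph, _["objective"] = best_obj,
    _["restart_log"] = log);
}
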