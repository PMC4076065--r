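// Goldman-Yang (1994) codon-model likelihood core.
//
// The Felsenstein pruning over 61 sense-codon states is the hot path of the
// site-model fits (called thousands of times per optimisation; the replicate
// studies fit hundreds of datasets), so it lives here rather than in R.
// Everything model-facing (parameterisation, optimisation, beta
// discretisation) stays on the R side.

#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// single-nucleotide codon change bookkeeping, built once per genetic code
struct PairTable {
  std::vector<int> i, j;        // 0-based codon indices
  std::vector<char> ts, nonsyn; // transition / nonsynonymous flags
  bool ready = false;
};
static PairTable g_pairs;

static void build_pairs(const IntegerMatrix& codonNuc, const IntegerVector& codonAA) {
  if (g_pairs.ready) return;
  const int n = codonNuc.nrow();
  for (int a = 0; a < n; ++a) {
    for (int b = 0; b < n; ++b) {
      if (a == b) continue;
      int ndiff = 0, pos = -1;
      for (int p = 0; p < 3; ++p)
        if (codonNuc(a, p) != codonNuc(b, p)) { ++ndiff; pos = p; }
      if (ndiff != 1) continue;
      const int x = codonNuc(a, pos), y = codonNuc(b, pos);
      g_pairs.i.push_back(a);
      g_pairs.j.push_back(b);
      // transitions are A<->G (codes 0,2) and C<->T (codes 1,3)
      g_pairs.ts.push_back((x + y == 2) || (x + y == 4));
      g_pairs.nonsyn.push_back(codonAA[a] != codonAA[b]);
    }
  }
  g_pairs.ready = true;
}

// unscaled GY94 generator: rate i->j = pi_j * kappa^[ts] * omega^[nonsyn]
static void gy94_fill_Q(const arma::vec& pi, double kappa, double omega, arma::mat& Q) {
  Q.zeros();
  for (size_t k = 0; k < g_pairs.i.size(); ++k) {
    double r = pi(g_pairs.j[k]);
    if (g_pairs.ts[k]) r *= kappa;
    if (g_pairs.nonsyn[k]) r *= omega;
    Q(g_pairs.i[k], g_pairs.j[k]) = r;
  }
  for (arma::uword i = 0; i < Q.n_rows; ++i) Q(i, i) = -arma::accu(Q.row(i));
}

// symmetrised eigendecomposition of the reversible generator:
// P(t) = D^{-1/2} V exp(L t) V' D^{1/2}, D = diag(pi)
struct QEigen {
  arma::mat V;
  arma::vec lambda;
};

// small cache keyed by (pi checksum, kappa, omega); within an optimisation
// only a handful of distinct generators recur (e.g. scale-only line searches)
static std::map<std::tuple<double, double, double>, QEigen> g_eig_cache;

static const QEigen& gy94_eigen_cached(const arma::vec& pi, double pisum,
                                       double kappa, double omega,
                                       const arma::vec& dpos, const arma::vec& dinv) {
  auto key = std::make_tuple(pisum, kappa, omega);
  auto it = g_eig_cache.find(key);
  if (it != g_eig_cache.end()) return it->second;
  if (g_eig_cache.size() > 4096) g_eig_cache.clear();
  arma::mat Q(pi.n_elem, pi.n_elem);
  gy94_fill_Q(pi, kappa, omega, Q);
  arma::mat S = Q;
  S.each_col() %= dpos;
  S.each_row() %= dinv.t();
  S = 0.5 * (S + S.t());
  QEigen e;
  arma::eig_sym(e.lambda, e.V, S, "dc");
  return g_eig_cache.emplace(key, std::move(e)).first->second;
}

// mixture normalisation: expected substitutions per codon per unit branch
static double mixture_rate(const arma::vec& pi, double kappa,
                           const NumericVector& classWeights,
                           const NumericVector& classOmegas) {
  // rate = sum_k w_k sum_pairs pi_i q_ij(omega_k); linear in omega
  double syn = 0.0, nonsyn = 0.0;
  for (size_t k = 0; k < g_pairs.i.size(); ++k) {
    double r = pi(g_pairs.i[k]) * pi(g_pairs.j[k]);
    if (g_pairs.ts[k]) r *= kappa;
    if (g_pairs.nonsyn[k]) nonsyn += r; else syn += r;
  }
  double wbar = 0.0;
  for (int k = 0; k < classWeights.size(); ++k) wbar += classWeights[k] * classOmegas[k];
  return syn + wbar * nonsyn;
}

// Log-likelihood of a codon alignment under a mixture of omega site classes.
// tipStates: nTip x nPat 0-based codon states (-1 = missing); edge: (parent,
// child) 0-based in postorder (children before parents, tips 0..nTip-1).
// Optionally returns per-pattern posterior class weights (naive empirical
// Bayes).
// [[Rcpp::export]]
List gy94_loglik_cpp(IntegerMatrix tipStates, NumericVector patWeights,
                     IntegerMatrix edge, NumericVector edgeLen,
                     int nTip, int nNode, int rootNode,
                     NumericVector pi_, double kappa,
                     NumericVector classWeights, NumericVector classOmegas,
                     IntegerMatrix codonNuc, IntegerVector codonAA,
                     bool posterior = false) {
  build_pairs(codonNuc, codonAA);
  const int nState = pi_.size();
  const int nPat = tipStates.ncol();
  const int nClass = classWeights.size();
  const int nEdge = edge.nrow();
  arma::vec pi(pi_.begin(), nState);
  const arma::vec dpos = arma::sqrt(pi);
  const arma::vec dinv = 1.0 / dpos;
  // cheap fingerprint of pi for the eigen cache key
  double pisum = 0.0;
  for (int i = 0; i < nState; ++i) pisum += pi(i) * (i + 1) * 0.01371;

  const double rate = mixture_rate(pi, kappa, classWeights, classOmegas);
  if (rate <= 0.0) stop("degenerate rate matrix (all rates zero)");

  // per-class pattern likelihoods depend only on (data, pi, kappa, omega_k,
  // scaled branch lengths); across optimizer evaluations many classes recur
  // unchanged (e.g. the beta classes while only the selection class moves),
  // so they are cached
  static std::map<std::tuple<double, double, double, double>, arma::rowvec> lik_cache;
  double datahash = nPat * 1.0;
  for (int i = 0; i < nTip; ++i)
    for (int s = 0; s < nPat; ++s) datahash += tipStates(i, s) * ((i + 2.0) * 0.001 + (s + 1.0) * 1e-6);
  double lenhash = 0.0;
  for (int ei = 0; ei < nEdge; ++ei) lenhash += edgeLen[ei] * (ei + 1.0) * 0.0137;
  const double base_key = pisum * 1e3 + datahash + lenhash / rate;

  arma::mat classLik(nClass, nPat, arma::fill::zeros);
  std::vector<arma::mat> part(nNode);
  std::vector<char> seen(nNode);
  arma::mat P(nState, nState), W(nState, nState), contrib(nState, nPat);

  for (int k = 0; k < nClass; ++k) {
    auto key = std::make_tuple(base_key, lenhash / rate, kappa, classOmegas[k]);
    auto it = lik_cache.find(key);
    if (it != lik_cache.end()) { classLik.row(k) = it->second; continue; }
    const QEigen& e = gy94_eigen_cached(pi, pisum, kappa, classOmegas[k], dpos, dinv);
    std::fill(seen.begin(), seen.end(), 0);
    for (int ei = 0; ei < nEdge; ++ei) {
      const int par = edge(ei, 0), ch = edge(ei, 1);
      const double t = edgeLen[ei] / rate;
      W = e.V;
      W.each_row() %= arma::exp(e.lambda * t).t();
      P = W * e.V.t();
      P.each_col() %= dinv;
      P.each_row() %= dpos.t();
      P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
      if (ch < nTip) {
        for (int s = 0; s < nPat; ++s) {
          const int st = tipStates(ch, s);
          if (st >= 0) contrib.col(s) = P.col(st);
          else contrib.col(s).ones();
        }
      } else {
        contrib = P * part[ch];
      }
      if (!seen[par]) { part[par] = contrib; seen[par] = 1; }
      else part[par] %= contrib;
    }
    if (lik_cache.size() > 20000) lik_cache.clear();
    classLik.row(k) = pi.t() * part[rootNode];
    lik_cache.emplace(key, classLik.row(k));
  }

  arma::vec w(classWeights.begin(), nClass);
  arma::rowvec site = w.t() * classLik;
  double ll = 0.0;
  for (int s = 0; s < nPat; ++s) {
    if (site(s) <= 0.0) return List::create(_["loglik"] = R_NegInf);
    ll += patWeights[s] * std::log(site(s));
  }

  List out = List::create(_["loglik"] = ll);
  if (posterior) {
    arma::mat post = classLik;
    post.each_col() %= w;
    post.each_row() /= site;
    out["posterior"] = wrap(post);
  }
  return out;
}

// Transition-probability matrix for one omega class under the mixture
// normalisation given by (classWeights, classOmegas); used by tests.
// [[Rcpp::export]]
NumericMatrix gy94_pmat_cpp(NumericVector pi_, double kappa, double omega, double t,
                            NumericVector classWeights, NumericVector classOmegas,
                            IntegerMatrix codonNuc, IntegerVector codonAA) {
  build_pairs(codonNuc, codonAA);
  const int nState = pi_.size();
  arma::vec pi(pi_.begin(), nState);
  const double rate = mixture_rate(pi, kappa, classWeights, classOmegas);
  arma::mat Q(nState, nState);
  gy94_fill_Q(pi, kappa, omega, Q);
  Q /= rate;
  const arma::vec dpos = arma::sqrt(pi), dinv = 1.0 / dpos;
  arma::mat S = Q;
  S.each_col() %= dpos;
  S.each_row() %= dinv.t();
  S = 0.5 * (S + S.t());
  arma::vec lam; arma::mat V;
  arma::eig_sym(lam, V, S, "dc");
  arma::mat W = V;
  W.each_row() %= arma::exp(lam * t).t();
  arma::mat P = W * V.t();
  P.each_col() %= dinv;
  P.each_row() %= dpos.t();
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return wrap(P);
}

// Simulate codon states along a tree under GY94 with site-wise omega.
// edge: (parent, child) 0-based rows in preorder (parents before children);
// edgeLen already on the unscaled-generator time scale. Uses R's RNG, so
// results are reproducible under set.seed(). Returns nNode x nSites states
// (0-based); tip rows are 0..nTip-1.
// [[Rcpp::export]]
IntegerMatrix gy94_sim_cpp(IntegerMatrix edge, NumericVector edgeLen,
                           int nTip, int nNode, int rootNode,
                           NumericVector pi_, double kappa,
                           NumericVector siteOmega,
                           IntegerMatrix codonNuc, IntegerVector codonAA) {
  build_pairs(codonNuc, codonAA);
  const int nState = pi_.size();
  const int nSites = siteOmega.size();
  arma::vec pi(pi_.begin(), nState);
  const arma::vec dpos = arma::sqrt(pi), dinv = 1.0 / dpos;

  // group sites by omega value
  std::map<double, std::vector<int>> groups;
  for (int s = 0; s < nSites; ++s) groups[siteOmega[s]].push_back(s);
  std::map<double, QEigen> eigs;
  for (auto& g : groups) {
    arma::mat Q(nState, nState);
    gy94_fill_Q(pi, kappa, g.first, Q);
    arma::mat S = Q;
    S.each_col() %= dpos;
    S.each_row() %= dinv.t();
    S = 0.5 * (S + S.t());
    QEigen e;
    arma::eig_sym(e.lambda, e.V, S, "dc");
    eigs.emplace(g.first, std::move(e));
  }

  IntegerMatrix states(nNode, nSites);
  // root states from pi
  arma::vec cpi = arma::cumsum(pi);
  for (int s = 0; s < nSites; ++s) {
    const double u = unif_rand() * cpi(nState - 1);
    int st = 0;
    while (st < nState - 1 && u > cpi(st)) ++st;
    states(rootNode, s) = st;
  }
  for (int ei = 0; ei < edge.nrow(); ++ei) {
    const int par = edge(ei, 0), ch = edge(ei, 1);
    const double t = edgeLen[ei];
    if (t <= 0.0) {
      for (int s = 0; s < nSites; ++s) states(ch, s) = states(par, s);
      continue;
    }
    for (auto& g : groups) {
      const QEigen& e = eigs[g.first];
      const arma::vec el = arma::exp(e.lambda * t);
      // sites per omega group are few (often one), so build only the P rows
      // actually needed: P(ps, .) = dinv[ps] * ((V[ps,] % el) * V') % dpos'
      std::map<int, arma::rowvec> rows;
      for (int s : g.second) {
        const int ps = states(par, s);
        auto rit = rows.find(ps);
        if (rit == rows.end()) {
          arma::rowvec w = e.V.row(ps) % el.t();
          arma::rowvec rp = (w * e.V.t()) % dpos.t() * dinv(ps);
          rp.transform([](double x) { return x < 0.0 ? 0.0 : x; });
          rit = rows.emplace(ps, arma::cumsum(rp)).first;
        }
        const arma::rowvec& C = rit->second;
        const double u = unif_rand() * C(nState - 1);
        int st = 0;
        while (st < nState - 1 && u > C(st)) ++st;
        states(ch, s) = st;
      }
    }
  }
  return states;
}

// Tally per-pair column classes (0 identical, 1 transition, 2 transversion,
// 3 excluded) over a bootstrap resample of columns; fast path for
// bootstrap_nj.
// [[Rcpp::export]]
IntegerMatrix count_pair_classes_cpp(IntegerMatrix colClass, IntegerVector idx) {
  const int nPair = colClass.nrow();
  IntegerMatrix out(nPair, 4);
  for (int c = 0; c < idx.size(); ++c) {
    const int col = idx[c];
    for (int p = 0; p < nPair; ++p) out(p, colClass(p, col)) += 1;
  }
  return out;
}
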