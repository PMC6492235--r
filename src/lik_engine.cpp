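// Felsenstein pruning engine for amino-acid likelihoods on a fixed rooted
// binary topology. Per-edge "messages" (P(edge) %*% subtree partial) are
// cached so that single-parameter MCMC moves only recompute the path from
// the touched edges up to the root. Messages are double-buffered: a
// proposal writes into the inactive buffer and an accept flips it, so
// reject/accept cost no copying of likelihood state. Numerical underflow
// is handled by per-node, per-pattern rescaling with the log scalers
// accumulated into the final log-likelihood.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int NS = 20;

struct LikEngine {
  int ntip, nnode, npat, ncat, root;
  std::vector<int> parent;              // 0-based, -1 at root
  std::vector<std::vector<int>> children;
  std::vector<int> postpos, postorder;
  std::vector<std::vector<int>> tipstate; // per tip: npat states, 20 = missing
  arma::vec weights;
  arma::mat U, Uinv;
  arma::vec lam, pi;
  arma::vec lengths, catr;
  std::vector<arma::cube> buf0, buf1;   // NS x npat x ncat message buffers
  std::vector<char> act, pend;          // active / pending buffer per node
  arma::mat ownlog;                     // npat x nnode
  arma::vec sitelik;
  double loglik;
  // workspaces
  arma::mat P, W1;
  arma::cube part;
  // small-state backup for reject
  std::vector<int> bk_nodes;
  std::vector<arma::vec> bk_ownlog;
  arma::vec bk_sitelik, bk_lengths, bk_catr;
  double bk_loglik;
  bool have_backup = false;

  arma::cube &pendmsg(int j) { return pend[j] ? buf1[j] : buf0[j]; }

  void pmat(double d) {
    for (int i = 0; i < NS; ++i) {
      double e = std::exp(lam[i] * d);
      for (int r = 0; r < NS; ++r) W1(r, i) = U(r, i) * e;
    }
    P = W1 * Uinv;
    double *p = P.memptr();
    for (int i = 0; i < NS * NS; ++i) if (p[i] < 0) p[i] = 0;
  }

  // children product (pending buffers) into this->part, rescaled, with
  // the log scaler written to ownlog column j
  void build_partial(int j) {
    const std::vector<int> &ch = children[j];
    std::memcpy(part.memptr(), pendmsg(ch[0]).memptr(),
                sizeof(double) * part.n_elem);
    for (size_t k = 1; k < ch.size(); ++k) {
      const double *src = pendmsg(ch[k]).memptr();
      double *dst = part.memptr();
      const size_t n = part.n_elem;
      for (size_t i = 0; i < n; ++i) dst[i] *= src[i];
    }
    double *ol = ownlog.colptr(j);
    for (int p = 0; p < npat; ++p) {
      double m = 0.0;
      for (int c = 0; c < ncat; ++c) {
        const double *col = part.slice_colptr(c, p);
        for (int s = 0; s < NS; ++s) if (col[s] > m) m = col[s];
      }
      if (m <= 0.0) m = 1e-300;
      double inv = 1.0 / m;
      for (int c = 0; c < ncat; ++c) {
        double *col = part.slice_colptr(c, p);
        for (int s = 0; s < NS; ++s) col[s] *= inv;
      }
      ol[p] = std::log(m);
    }
  }

  void compute_msg(int j) {
    pend[j] = 1 - act[j];
    arma::cube &M = pendmsg(j);
    if (j < ntip) {
      const std::vector<int> &st = tipstate[j];
      for (int c = 0; c < ncat; ++c) {
        pmat(lengths[j] * catr[c]);
        for (int p = 0; p < npat; ++p) {
          double *col = M.slice_colptr(c, p);
          int s = st[p];
          if (s < NS) std::memcpy(col, P.colptr(s), sizeof(double) * NS);
          else for (int i = 0; i < NS; ++i) col[i] = 1.0;
        }
      }
    } else {
      build_partial(j);
      for (int c = 0; c < ncat; ++c) {
        pmat(lengths[j] * catr[c]);
        arma::mat dst(M.slice_memptr(c), NS, npat, false, true);
        arma::mat src(part.slice_memptr(c), NS, npat, false, true);
        dst = P * src;
      }
    }
  }

  void compute_root() {
    build_partial(root);
    sitelik.zeros();
    for (int c = 0; c < ncat; ++c) {
      const double *pp = part.slice_memptr(c);
      for (int p = 0; p < npat; ++p) {
        double s = 0.0;
        const double *col = pp + (size_t)p * NS;
        for (int i = 0; i < NS; ++i) s += pi[i] * col[i];
        sitelik[p] += s;
      }
    }
    sitelik /= (double)ncat;
  }

  void total() {
    arma::vec persite = arma::log(sitelik) + arma::sum(ownlog, 1);
    loglik = arma::dot(weights, persite);
  }

  arma::vec pattern_loglik() const {
    return arma::log(sitelik) + arma::sum(ownlog, 1);
  }

  void recompute(std::vector<int> dirty) {
    std::sort(dirty.begin(), dirty.end(),
              [this](int a, int b) { return postpos[a] < postpos[b]; });
    for (int j : dirty) {
      if (j == root) compute_root();
      else compute_msg(j);
    }
    total();
  }

  std::vector<int> closure(const std::vector<int> &touched) {
    std::vector<int> out;
    std::vector<char> seen(nnode, 0);
    for (int j : touched) {
      int k = j;
      while (k >= 0 && !seen[k]) {
        seen[k] = 1;
        out.push_back(k);
        k = parent[k];
      }
    }
    return out;
  }

  void take_backup(const std::vector<int> &dirty) {
    bk_nodes = dirty;
    for (int j : dirty)
      std::memcpy(bk_ownlog[j].memptr(), ownlog.colptr(j),
                  sizeof(double) * npat);
    bk_sitelik = sitelik;
    bk_lengths = lengths;
    bk_catr = catr;
    bk_loglik = loglik;
    have_backup = true;
  }

  void commit() {
    for (int j : bk_nodes) act[j] = pend[j];
    have_backup = false;
  }

  void rollback() {
    if (!have_backup) return;
    for (int j : bk_nodes) {
      pend[j] = act[j];
      std::memcpy(ownlog.colptr(j), bk_ownlog[j].memptr(),
                  sizeof(double) * npat);
    }
    sitelik = bk_sitelik;
    lengths = bk_lengths;
    catr = bk_catr;
    loglik = bk_loglik;
    have_backup = false;
  }
};

// [[Rcpp::export(name = ".le_create")]]
SEXP le_create(int ntip, IntegerVector parent, IntegerMatrix tipstate,
               NumericVector weights, int ncat) {
  LikEngine *e = new LikEngine();
  e->ntip = ntip;
  e->nnode = parent.size();
  e->npat = tipstate.nrow();
  e->ncat = ncat;
  e->parent.resize(e->nnode);
  e->children.assign(e->nnode, {});
  e->root = -1;
  for (int j = 0; j < e->nnode; ++j) {
    e->parent[j] = parent[j];
    if (parent[j] < 0) e->root = j;
    else e->children[parent[j]].push_back(j);
  }
  std::vector<int> stack = {e->root}, order;
  while (!stack.empty()) {
    int j = stack.back(); stack.pop_back();
    order.push_back(j);
    for (int c : e->children[j]) stack.push_back(c);
  }
  e->postorder.assign(order.rbegin(), order.rend());
  e->postpos.assign(e->nnode, 0);
  for (int i = 0; i < e->nnode; ++i) e->postpos[e->postorder[i]] = i;
  e->tipstate.assign(ntip, std::vector<int>(e->npat));
  for (int t = 0; t < ntip; ++t)
    for (int p = 0; p < e->npat; ++p) e->tipstate[t][p] = tipstate(p, t);
  e->weights = as<arma::vec>(weights);
  e->lengths = arma::zeros(e->nnode);
  e->catr = arma::ones(e->ncat);
  e->buf0.assign(e->nnode, arma::cube(NS, e->npat, e->ncat, arma::fill::ones));
  e->buf1.assign(e->nnode, arma::cube(NS, e->npat, e->ncat, arma::fill::ones));
  e->act.assign(e->nnode, 0);
  e->pend.assign(e->nnode, 0);
  e->ownlog = arma::zeros(e->npat, e->nnode);
  e->sitelik = arma::ones(e->npat);
  e->P.set_size(NS, NS);
  e->W1.set_size(NS, NS);
  e->part.set_size(NS, e->npat, e->ncat);
  e->bk_ownlog.assign(e->nnode, arma::vec(e->npat));
  XPtr<LikEngine> p(e, true);
  return p;
}

// [[Rcpp::export(name = ".le_set_model")]]
void le_set_model(SEXP ptr, NumericMatrix U, NumericMatrix Uinv,
                  NumericVector lam, NumericVector pi) {
  XPtr<LikEngine> e(ptr);
  e->U = as<arma::mat>(U);
  e->Uinv = as<arma::mat>(Uinv);
  e->lam = as<arma::vec>(lam);
  e->pi = as<arma::vec>(pi);
}

// full recompute; defines the reference state
// [[Rcpp::export(name = ".le_full")]]
double le_full(SEXP ptr, NumericVector lengths, NumericVector catr) {
  XPtr<LikEngine> e(ptr);
  e->lengths = as<arma::vec>(lengths);
  e->catr = as<arma::vec>(catr);
  e->recompute(e->postorder);
  for (int j = 0; j < e->nnode; ++j) e->act[j] = e->pend[j];
  e->have_backup = false;
  return e->loglik;
}

// propose new lengths on the edges above `touched` (1-based node ids);
// if catr differs everything is recomputed
// [[Rcpp::export(name = ".le_propose")]]
double le_propose(SEXP ptr, IntegerVector touched, NumericVector lengths,
                  NumericVector catr) {
  XPtr<LikEngine> e(ptr);
  arma::vec newcat = as<arma::vec>(catr);
  std::vector<int> dirty;
  if (arma::any(arma::abs(newcat - e->catr) > 0)) {
    dirty = e->postorder;
  } else {
    std::vector<int> t0;
    for (int i = 0; i < touched.size(); ++i) t0.push_back(touched[i] - 1);
    dirty = e->closure(t0);
  }
  e->take_backup(dirty);
  e->lengths = as<arma::vec>(lengths);
  e->catr = newcat;
  e->recompute(dirty);
  return e->loglik;
}

// [[Rcpp::export(name = ".le_accept")]]
void le_accept(SEXP ptr) {
  XPtr<LikEngine> e(ptr);
  e->commit();
}

// [[Rcpp::export(name = ".le_reject")]]
void le_reject(SEXP ptr) {
  XPtr<LikEngine> e(ptr);
  e->rollback();
}

// [[Rcpp::export(name = ".le_pattern_loglik")]]
NumericVector le_pattern_loglik(SEXP ptr) {
  XPtr<LikEngine> e(ptr);
  return wrap(e->pattern_loglik());
}

// [[Rcpp::export(name = ".le_loglik")]]
double le_loglik(SEXP ptr) {
  XPtr<LikEngine> e(ptr);
  return e->loglik;
}
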