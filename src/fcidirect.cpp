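// Direct-CI Davidson solver for a fixed (n_orb, n_alpha, n_beta) sector.
//
// Spin-free Hamiltonian H = sum h_pq E_pq + 1/2 sum (pq|rs) e_pqrs in
// chemists' convention.  Sigma vectors are built with the one-particle
// coupling formulation:
//   F_pq = k_pq C + 1/2 sum_rs (pq|rs) (E_rs C),  sigma = sum_pq E_pq F_pq
// with k_pq = h_pq - 1/2 sum_r (pr|rq).  Strings are bit masks enumerated in
// increasing numeric order, matching the R-side sector bases.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Excit { int src; int dst; double sign; };

// all k-subsets of n bits, ascending
std::vector<uint32_t> gen_strings(int n, int k) {
  std::vector<uint32_t> out;
  if (k == 0) { out.push_back(0u); return out; }
  uint32_t v = (1u << k) - 1u;
  uint32_t limit = 1u << n;
  while (v < limit) {
    out.push_back(v);
    uint32_t t = v | (v - 1u);
    v = (t + 1u) | (((~t & (t + 1u)) - 1u) >> (__builtin_ctz(v) + 1));
    if (v == 0) break;
  }
  return out;
}

inline int parity_between(uint32_t str, int p, int q) {
  if (p == q) return 1;
  int lo = std::min(p, q), hi = std::max(p, q);
  uint32_t mask = ((1u << hi) - 1u) & ~((1u << (lo + 1)) - 1u);
  return (__builtin_popcount(str & mask) & 1) ? -1 : 1;
}

// excitation lists for E_pq on one spin: tab[p*norb+q] = {(I -> J, sign)}
std::vector<std::vector<Excit>> build_tables(
    const std::vector<uint32_t>& strs, int norb) {
  std::unordered_map<uint32_t, int> index;
  index.reserve(strs.size() * 2);
  for (size_t i = 0; i < strs.size(); ++i) index[strs[i]] = (int)i;
  std::vector<std::vector<Excit>> tab(norb * norb);
  for (size_t i = 0; i < strs.size(); ++i) {
    uint32_t I = strs[i];
    for (int q = 0; q < norb; ++q) {
      if (!((I >> q) & 1u)) continue;
      for (int p = 0; p < norb; ++p) {
        if (p != q && ((I >> p) & 1u)) continue;
        uint32_t J = (I ^ (1u << q)) | (1u << p);
        double s = parity_between(I, p, q);
        tab[p * norb + q].push_back({(int)i, index[J], s});
      }
    }
  }
  return tab;
}

} // namespace

class SectorCI {
public:
  int norb, nsa, nsb;
  arma::uword dim;
  std::vector<uint32_t> sa, sb;
  std::vector<std::vector<Excit>> ta, tb;
  arma::mat h;       // bare one-electron
  arma::mat k1;      // h - 1/2 sum_r (pr|rq)
  const double* g;   // norb^4, column-major (p,q,r,s)

  SectorCI(const arma::mat& h_, const double* g_, int norb_, int na, int nb)
      : norb(norb_), h(h_), g(g_) {
    sa = gen_strings(norb, na);
    sb = gen_strings(norb, nb);
    nsa = (int)sa.size(); nsb = (int)sb.size();
    dim = (arma::uword)nsa * nsb;
    ta = build_tables(sa, norb);
    tb = (na == nb) ? ta : build_tables(sb, norb);
    k1 = h;
    for (int p = 0; p < norb; ++p)
      for (int q = 0; q < norb; ++q) {
        double acc = 0;
        for (int r = 0; r < norb; ++r) acc += gv(p, r, r, q);
        k1(p, q) -= 0.5 * acc;
      }
  }

  inline double gv(int p, int q, int r, int s) const {
    return g[p + norb * (q + norb * (r + norb * s))];
  }

  // E_rs C accumulated into D (both spins), C and D as (nsa x nsb) mats
  void apply_E(int r, int s, const arma::mat& C, arma::mat& D,
               double scale) const {
    for (const Excit& e : ta[r * norb + s])
      D.row(e.dst) += (scale * e.sign) * C.row(e.src);
    for (const Excit& e : tb[r * norb + s])
      D.col(e.dst) += (scale * e.sign) * C.col(e.src);
  }

  arma::vec sigma(const arma::vec& c) const {
    arma::mat C(const_cast<double*>(c.memptr()), nsa, nsb, false, true);
    int npair = norb * (norb + 1) / 2;
    int nsq = norb * norb;
    // D'_rs = E_rs C + E_sr C (r > s), E_rr C on the diagonal
    arma::mat D(dim, npair, arma::fill::zeros);
    int col = 0;
    std::vector<std::pair<int,int>> pairs(npair);
    for (int r = 0; r < norb; ++r)
      for (int s = 0; s <= r; ++s, ++col) {
        pairs[col] = {r, s};
        arma::mat Dm(D.colptr(col), nsa, nsb, false, true);
        apply_E(r, s, C, Dm, 1.0);
        if (r != s) apply_E(s, r, C, Dm, 1.0);
      }
    // W[rs_pair, pq] = 1/2 (pq|rs)
    arma::mat W(npair, nsq);
    for (int c2 = 0; c2 < nsq; ++c2) {
      int p = c2 % norb, q = c2 / norb;      // pq index = q*norb + p
      for (int c1 = 0; c1 < npair; ++c1)
        W(c1, c2) = 0.5 * gv(p, q, pairs[c1].first, pairs[c1].second);
    }
    arma::mat F = D * W;                      // dim x nsq
    D.reset();
    arma::vec out(dim, arma::fill::zeros);
    arma::mat O(out.memptr(), nsa, nsb, false, true);
    for (int q = 0; q < norb; ++q)
      for (int p = 0; p < norb; ++p) {
        int c2 = q * norb + p;
        arma::mat Fm(F.colptr(c2), nsa, nsb, false, true);
        if (k1(p, q) != 0) Fm += k1(p, q) * C;
        apply_E(p, q, Fm, O, 1.0);
      }
    return out;
  }

  arma::vec diagonal() const {
    arma::vec d(dim);
    std::vector<double> hd(norb), jd(norb * norb), kd(norb * norb);
    for (int p = 0; p < norb; ++p) {
      hd[p] = h(p, p);
      for (int q = 0; q < norb; ++q) {
        jd[p * norb + q] = gv(p, p, q, q);
        kd[p * norb + q] = gv(p, q, q, p);
      }
    }
    arma::uword idx = 0;
    for (int ib = 0; ib < nsb; ++ib) {
      uint32_t B = sb[ib];
      for (int ia = 0; ia < nsa; ++ia, ++idx) {
        uint32_t A = sa[ia];
        double e = 0;
        for (int p = 0; p < norb; ++p) {
          int npa = (A >> p) & 1, npb = (B >> p) & 1;
          int np = npa + npb;
          if (!np) continue;
          e += np * hd[p];
          for (int q = 0; q < norb; ++q) {
            int nqa = (A >> q) & 1, nqb = (B >> q) & 1;
            int nq = nqa + nqb;
            if (!nq) continue;
            e += 0.5 * np * nq * jd[p * norb + q];
            e -= 0.5 * (npa * nqa + npb * nqb) * kd[p * norb + q];
          }
        }
        d(idx) = e;
      }
    }
    return d;
  }
};

// [[Rcpp::export]]
List fci_davidson_cpp(NumericMatrix h, NumericVector g, int norb,
                      int na, int nb, int nroots = 1, double tol = 1e-6,
                      int max_iter = 120) {
  arma::mat hm(h.begin(), norb, norb, true);
  SectorCI ci(hm, g.begin(), norb, na, nb);
  arma::uword dim = ci.dim;
  arma::vec hdiag = ci.diagonal();
  const int mmax = std::max(18, 2 * nroots + 10);

  arma::mat conv_vecs(dim, 0);
  arma::vec conv_vals;

  for (int root = 0; root < nroots; ++root) {
    // start vector: lowest diagonal not dominated by converged roots
    arma::vec v(dim, arma::fill::zeros);
    {
      arma::uvec ord = arma::sort_index(hdiag);
      for (arma::uword t = 0; t < dim; ++t) {
        v.zeros(); v(ord(t)) = 1.0;
        for (arma::uword r = 0; r < conv_vecs.n_cols; ++r)
          v -= arma::dot(conv_vecs.col(r), v) * conv_vecs.col(r);
        if (arma::norm(v) > 0.5) { v /= arma::norm(v); break; }
      }
    }
    arma::mat Vb(dim, 0), Sb(dim, 0);
    double theta = 0;
    arma::vec x;
    bool done = false;
    for (int it = 0; it < max_iter && !done; ++it) {
      // orthogonalize v against basis and converged roots, append
      for (int rep = 0; rep < 2; ++rep) {
        for (arma::uword j = 0; j < Vb.n_cols; ++j)
          v -= arma::dot(Vb.col(j), v) * Vb.col(j);
        for (arma::uword r = 0; r < conv_vecs.n_cols; ++r)
          v -= arma::dot(conv_vecs.col(r), v) * conv_vecs.col(r);
      }
      double nv = arma::norm(v);
      if (nv < 1e-10) { done = true; break; }
      v /= nv;
      Vb.insert_cols(Vb.n_cols, v);
      Sb.insert_cols(Sb.n_cols, ci.sigma(v));
      arma::mat Hs = Vb.t() * Sb;
      Hs = 0.5 * (Hs + Hs.t());
      arma::vec evals; arma::mat evecs;
      arma::eig_sym(evals, evecs, Hs);
      theta = evals(0);
      x = Vb * evecs.col(0);
      arma::vec r = Sb * evecs.col(0) - theta * x;
      double rn = arma::norm(r);
      if (rn < tol) { done = true; break; }
      if ((int)Vb.n_cols >= mmax) {   // restart
        arma::vec x2 = Sb * evecs.col(0);
        Vb.set_size(dim, 0); Sb.set_size(dim, 0);
        Vb.insert_cols(0, x);
        Sb.insert_cols(0, x2);
      }
      // diagonal preconditioner
      arma::vec denom = hdiag - theta;
      denom.transform([](double z) {
        return (std::abs(z) < 1e-6) ? ((z < 0) ? -1e-6 : 1e-6) : z; });
      v = -r / denom;
    }
    conv_vecs.insert_cols(conv_vecs.n_cols, x / arma::norm(x));
    arma::vec val1(1); val1(0) = theta;
    conv_vals = arma::join_cols(conv_vals, val1);
  }
  return List::create(Named("values") = NumericVector(conv_vals.begin(),
                                                      conv_vals.end()),
                      Named("vectors") = wrap(conv_vecs));
}
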