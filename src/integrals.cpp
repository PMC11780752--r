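// Gaussian AO integrals (overlap, kinetic, nuclear attraction, two-electron
// repulsion) over contracted Cartesian Gaussian shells, McMurchie-Davidson
// scheme (Hermite expansion coefficients + Boys-function Hermite Coulomb
// recursion).  Angular momenta up to d are exercised; the recursions are
// general.  Contraction coefficients arrive pre-scaled with primitive and
// contracted normalization (see the R basis loader); the per-component
// Cartesian factors sqrt((2l-1)!! / prod (2li-1)!!) are applied here.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>

using namespace Rcpp;

namespace {

const double PI = 3.14159265358979323846;

// Boys function F_0..F_mmax at x (downward recursion from a series top)
void boys(int mmax, double x, double* F) {
  if (x < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2 * m + 1);
    return;
  }
  if (x > 38.0) {
    F[0] = 0.5 * std::sqrt(PI / x);
    for (int m = 1; m <= mmax; ++m)
      F[m] = F[m - 1] * (2 * m - 1) / (2 * x);
    return;
  }
  // series for F_mmax: e^-x * sum_k (2x)^k / (2m+1)(2m+3)...(2m+2k+1)
  double acc = 1.0 / (2 * mmax + 1), term = acc;
  for (int k = 1; k < 300; ++k) {
    term *= 2 * x / (2 * mmax + 2 * k + 1);
    acc += term;
    if (term < 1e-17 * acc) break;
  }
  F[mmax] = std::exp(-x) * acc;
  for (int m = mmax - 1; m >= 0; --m)
    F[m] = (2 * x * F[m + 1] + std::exp(-x)) / (2 * m + 1);
}

// Hermite expansion coefficients E_t^{ij} for one dimension
struct ECoef {
  int la, lb;
  double v[5][5][9];   // [i][j][t]
  void build(int la_, int lb_, double a, double b, double AB) {
    la = la_; lb = lb_;
    double p = a + b, mu = a * b / p;
    double XPA = -b * AB / p, XPB = a * AB / p;   // P - A, P - B with AB = A-B
    for (int i = 0; i <= la; ++i)
      for (int j = 0; j <= lb; ++j)
        for (int t = 0; t <= la + lb; ++t) v[i][j][t] = 0.0;
    v[0][0][0] = std::exp(-mu * AB * AB);
    for (int i = 1; i <= la; ++i)
      for (int t = 0; t <= i; ++t) {
        double acc = XPA * v[i - 1][0][t];
        if (t > 0) acc += v[i - 1][0][t - 1] / (2 * p);
        if (t + 1 <= i - 1) acc += (t + 1) * v[i - 1][0][t + 1];
        v[i][0][t] = acc;
      }
    for (int j = 1; j <= lb; ++j)
      for (int i = 0; i <= la; ++i)
        for (int t = 0; t <= i + j; ++t) {
          double acc = XPB * v[i][j - 1][t];
          if (t > 0) acc += v[i][j - 1][t - 1] / (2 * p);
          if (t + 1 <= i + j - 1) acc += (t + 1) * v[i][j - 1][t + 1];
          v[i][j][t] = acc;
        }
  }
};

// Hermite Coulomb integrals R_{tuv} = R^0_{tuv}(p, PC) for t+u+v <= L
void hermite_R(int L, double p, double X, double Y, double Z,
               std::vector<double>& R, int dim) {
  // R indexed [t][u][v] with stride dim
  double r2 = X * X + Y * Y + Z * Z;
  double F[64];
  boys(L, p * r2, F);
  // work array over n
  std::vector<double> cur((dim) * (dim) * (dim), 0.0),
      nxt(dim * dim * dim, 0.0);
  auto idx = [dim](int t, int u, int v) { return (t * dim + u) * dim + v; };
  // start from n = L down to 0, building R^n for t+u+v <= L-n
  std::vector<std::vector<double>> Rn(L + 1,
      std::vector<double>(dim * dim * dim, 0.0));
  for (int n = L; n >= 0; --n) {
    double f = 1.0;
    for (int k = 0; k < n; ++k) f *= -2.0 * p;
    Rn[n][idx(0, 0, 0)] = f * F[n];
  }
  for (int total = 1; total <= L; ++total)
    for (int n = L - total; n >= 0; --n)
      for (int t = 0; t <= total; ++t)
        for (int u = 0; u <= total - t; ++u) {
          int v = total - t - u;
          double acc = 0;
          if (t > 0) {
            acc = X * Rn[n + 1][idx(t - 1, u, v)];
            if (t > 1) acc += (t - 1) * Rn[n + 1][idx(t - 2, u, v)];
          } else if (u > 0) {
            acc = Y * Rn[n + 1][idx(t, u - 1, v)];
            if (u > 1) acc += (u - 1) * Rn[n + 1][idx(t, u - 2, v)];
          } else {
            acc = Z * Rn[n + 1][idx(t, u, v - 1)];
            if (v > 1) acc += (v - 1) * Rn[n + 1][idx(t, u, v - 2)];
          }
          Rn[n][idx(t, u, v)] = acc;
        }
  R = Rn[0];
}

int dfact(int n) { // (2n-1)!! with n = l
  int r = 1;
  for (int k = 2 * n - 1; k > 1; k -= 2) r *= k;
  return r;
}

struct Shell {
  int l, nprim, off;          // off = first AO index
  std::vector<double> ex, cf;
  double cx, cy, cz;
  int ncart() const { return (l + 1) * (l + 2) / 2; }
};

struct Cart { int lx, ly, lz; double fac; };

std::vector<Cart> cart_list(int l) {
  std::vector<Cart> out;
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly) {
      int lz = l - lx - ly;
      double f = std::sqrt((double)dfact(l) /
                           ((double)dfact(lx) * dfact(ly) * dfact(lz)));
      out.push_back({lx, ly, lz, f});
    }
  return out;
}

} // namespace

// [[Rcpp::export]]
List ao_integrals_cpp(IntegerVector l, IntegerVector nprim,
                      NumericVector exps, NumericVector coefs,
                      NumericMatrix centers, NumericVector Z,
                      NumericMatrix atom_xyz, bool do_eri = true) {
  int nsh = l.size();
  std::vector<Shell> sh(nsh);
  int nao = 0, po = 0;
  for (int i = 0; i < nsh; ++i) {
    sh[i].l = l[i]; sh[i].nprim = nprim[i];
    sh[i].cx = centers(i, 0); sh[i].cy = centers(i, 1);
    sh[i].cz = centers(i, 2);
    sh[i].ex.assign(exps.begin() + po, exps.begin() + po + nprim[i]);
    sh[i].cf.assign(coefs.begin() + po, coefs.begin() + po + nprim[i]);
    po += nprim[i];
    sh[i].off = nao;
    nao += sh[i].ncart();
  }
  std::vector<std::vector<Cart>> carts(3);
  for (int lv = 0; lv <= 2; ++lv) carts[lv] = cart_list(lv);
  auto cl = [&](int lv) -> const std::vector<Cart>& {
    if (lv >= (int)carts.size())
      carts.resize(lv + 1), carts[lv] = cart_list(lv);
    return carts[lv];
  };

  NumericMatrix S(nao, nao), T(nao, nao), V(nao, nao);
  int natom = Z.size();

  for (int i = 0; i < nsh; ++i)
    for (int j = 0; j <= i; ++j) {
      const Shell &A = sh[i], &B = sh[j];
      double ABx = A.cx - B.cx, ABy = A.cy - B.cy, ABz = A.cz - B.cz;
      const std::vector<Cart>& ca = cl(A.l);
      const std::vector<Cart>& cb = cl(B.l);
      int na = ca.size(), nb = cb.size();
      std::vector<double> Sbuf(na * nb, 0.0), Tbuf(na * nb, 0.0),
          Vbuf(na * nb, 0.0);
      for (int pi = 0; pi < A.nprim; ++pi)
        for (int pj = 0; pj < B.nprim; ++pj) {
          double a = A.ex[pi], b = B.ex[pj], p = a + b;
          double cc = A.cf[pi] * B.cf[pj];
          ECoef Ex, Ey, Ez;
          // need up to l+2 on the bra for the kinetic recursion
          Ex.build(A.l + 2, B.l, a, b, ABx);
          Ey.build(A.l + 2, B.l, a, b, ABy);
          Ez.build(A.l + 2, B.l, a, b, ABz);
          double sqp = std::sqrt(PI / p);
          double Px = (a * A.cx + b * B.cx) / p,
                 Py = (a * A.cy + b * B.cy) / p,
                 Pz = (a * A.cz + b * B.cz) / p;
          int Ltot = A.l + B.l;
          int dim = Ltot + 1;
          // nuclear attraction Hermite tables per atom
          std::vector<std::vector<double>> Rat(natom);
          for (int at = 0; at < natom; ++at)
            hermite_R(Ltot, p, Px - atom_xyz(at, 0), Py - atom_xyz(at, 1),
                      Pz - atom_xyz(at, 2), Rat[at], dim);
          for (int ia = 0; ia < na; ++ia)
            for (int ib = 0; ib < nb; ++ib) {
              const Cart &c1 = ca[ia], &c2 = cb[ib];
              double sx = Ex.v[c1.lx][c2.lx][0] * sqp;
              double sy = Ey.v[c1.ly][c2.ly][0] * sqp;
              double sz = Ez.v[c1.lz][c2.lz][0] * sqp;
              double fnorm = cc * c1.fac * c2.fac;
              Sbuf[ia * nb + ib] += fnorm * sx * sy * sz;
              // 1-D kinetic pieces: act with a on the *bra* index
              auto t1d = [&](const ECoef& E, int li, int lj,
                             double s0) -> double {
                double t = a * (2 * li + 1) * s0;
                t -= 2 * a * a * E.v[li + 2][lj][0] * sqp;
                if (li >= 2) t -= 0.5 * li * (li - 1) * E.v[li - 2][lj][0] * sqp;
                return t;
              };
              double tx = t1d(Ex, c1.lx, c2.lx, sx);
              double ty = t1d(Ey, c1.ly, c2.ly, sy);
              double tz = t1d(Ez, c1.lz, c2.lz, sz);
              Tbuf[ia * nb + ib] += fnorm * (tx * sy * sz + sx * ty * sz +
                                             sx * sy * tz);
              double vsum = 0;
              for (int at = 0; at < natom; ++at) {
                double acc = 0;
                for (int t = 0; t <= c1.lx + c2.lx; ++t)
                  for (int u = 0; u <= c1.ly + c2.ly; ++u)
                    for (int v = 0; v <= c1.lz + c2.lz; ++v)
                      acc += Ex.v[c1.lx][c2.lx][t] * Ey.v[c1.ly][c2.ly][u] *
                             Ez.v[c1.lz][c2.lz][v] *
                             Rat[at][(t * dim + u) * dim + v];
                vsum += -Z[at] * acc;
              }
              Vbuf[ia * nb + ib] += fnorm * (2 * PI / p) * vsum;
            }
        }
      for (int ia = 0; ia < na; ++ia)
        for (int ib = 0; ib < nb; ++ib) {
          S(A.off + ia, B.off + ib) = Sbuf[ia * nb + ib];
          S(B.off + ib, A.off + ia) = Sbuf[ia * nb + ib];
          T(A.off + ia, B.off + ib) = Tbuf[ia * nb + ib];
          T(B.off + ib, A.off + ia) = Tbuf[ia * nb + ib];
          V(A.off + ia, B.off + ib) = Vbuf[ia * nb + ib];
          V(B.off + ib, A.off + ia) = Vbuf[ia * nb + ib];
        }
    }

  List out = List::create(Named("S") = S, Named("T") = T, Named("V") = V,
                          Named("nao") = nao);
  if (!do_eri) return out;

  NumericVector eri((R_xlen_t)nao * nao * nao * nao);  // dims set in R
  double* E4 = eri.begin();
  auto eidx = [nao](int p, int q, int r, int s) {
    return ((size_t)s * nao + r) * nao * nao + (size_t)q * nao + p;
  };

  // shell pair list
  struct PairPrim {
    double p, Px, Py, Pz, cc;
    ECoef Ex, Ey, Ez;
  };
  struct ShPair {
    int i, j;
    std::vector<PairPrim> pp;
  };
  std::vector<ShPair> pairs;
  for (int i = 0; i < nsh; ++i)
    for (int j = 0; j <= i; ++j) {
      ShPair sp; sp.i = i; sp.j = j;
      const Shell &A = sh[i], &B = sh[j];
      double ABx = A.cx - B.cx, ABy = A.cy - B.cy, ABz = A.cz - B.cz;
      for (int pi = 0; pi < A.nprim; ++pi)
        for (int pj = 0; pj < B.nprim; ++pj) {
          PairPrim q;
          double a = A.ex[pi], b = B.ex[pj];
          q.p = a + b;
          q.cc = A.cf[pi] * B.cf[pj];
          double mu = a * b / q.p;
          if (q.cc == 0 ||
              std::exp(-mu * (ABx * ABx + ABy * ABy + ABz * ABz)) < 1e-16)
            continue;
          q.Px = (a * A.cx + b * B.cx) / q.p;
          q.Py = (a * A.cy + b * B.cy) / q.p;
          q.Pz = (a * A.cz + b * B.cz) / q.p;
          q.Ex.build(A.l, B.l, a, b, ABx);
          q.Ey.build(A.l, B.l, a, b, ABy);
          q.Ez.build(A.l, B.l, a, b, ABz);
          sp.pp.push_back(q);
        }
      pairs.push_back(sp);
    }

  std::vector<double> R;
  for (size_t ip = 0; ip < pairs.size(); ++ip)
    for (size_t jp = 0; jp <= ip; ++jp) {
      const ShPair &P12 = pairs[ip], &P34 = pairs[jp];
      const Shell &A = sh[P12.i], &B = sh[P12.j],
                  &C = sh[P34.i], &D = sh[P34.j];
      const std::vector<Cart>& ca = cl(A.l);
      const std::vector<Cart>& cb = cl(B.l);
      const std::vector<Cart>& cc_ = cl(C.l);
      const std::vector<Cart>& cd = cl(D.l);
      int na = ca.size(), nb = cb.size(), nc = cc_.size(), nd = cd.size();
      std::vector<double> buf(na * nb * nc * nd, 0.0);
      int L12 = A.l + B.l, L34 = C.l + D.l, Ltot = L12 + L34;
      int dim = Ltot + 1;
      for (const PairPrim& q1 : P12.pp)
        for (const PairPrim& q2 : P34.pp) {
          double alpha = q1.p * q2.p / (q1.p + q2.p);
          double pref = 2 * std::pow(PI, 2.5) /
              (q1.p * q2.p * std::sqrt(q1.p + q2.p)) * q1.cc * q2.cc;
          hermite_R(Ltot, alpha, q1.Px - q2.Px, q1.Py - q2.Py,
                    q1.Pz - q2.Pz, R, dim);
          int bi = 0;
          for (int ia = 0; ia < na; ++ia)
            for (int ib = 0; ib < nb; ++ib)
              for (int ic = 0; ic < nc; ++ic)
                for (int id = 0; id < nd; ++id, ++bi) {
                  const Cart &x1 = ca[ia], &x2 = cb[ib], &x3 = cc_[ic],
                             &x4 = cd[id];
                  double acc = 0;
                  for (int t = 0; t <= x1.lx + x2.lx; ++t)
                    for (int u = 0; u <= x1.ly + x2.ly; ++u)
                      for (int v = 0; v <= x1.lz + x2.lz; ++v) {
                        double e1 = q1.Ex.v[x1.lx][x2.lx][t] *
                                    q1.Ey.v[x1.ly][x2.ly][u] *
                                    q1.Ez.v[x1.lz][x2.lz][v];
                        if (e1 == 0) continue;
                        double inner = 0;
                        for (int tt = 0; tt <= x3.lx + x4.lx; ++tt)
                          for (int uu = 0; uu <= x3.ly + x4.ly; ++uu)
                            for (int vv = 0; vv <= x3.lz + x4.lz; ++vv) {
                              double e2 = q2.Ex.v[x3.lx][x4.lx][tt] *
                                          q2.Ey.v[x3.ly][x4.ly][uu] *
                                          q2.Ez.v[x3.lz][x4.lz][vv];
                              if (e2 == 0) continue;
                              double sgn = ((tt + uu + vv) & 1) ? -1.0 : 1.0;
                              inner += sgn * e2 *
                                  R[((t + tt) * dim + (u + uu)) * dim +
                                    (v + vv)];
                            }
                        acc += e1 * inner;
                      }
                  buf[bi] += pref * acc *
                      x1.fac * x2.fac * x3.fac * x4.fac;
                }
        }
      // scatter with full 8-fold symmetry
      int bi = 0;
      for (int ia = 0; ia < na; ++ia)
        for (int ib = 0; ib < nb; ++ib)
          for (int ic = 0; ic < nc; ++ic)
            for (int id = 0; id < nd; ++id, ++bi) {
              int p = A.off + ia, q = B.off + ib,
                  r = C.off + ic, s = D.off + id;
              double x = buf[bi];
              E4[eidx(p, q, r, s)] = x; E4[eidx(q, p, r, s)] = x;
              E4[eidx(p, q, s, r)] = x; E4[eidx(q, p, s, r)] = x;
              E4[eidx(r, s, p, q)] = x; E4[eidx(s, r, p, q)] = x;
              E4[eidx(r, s, q, p)] = x; E4[eidx(s, r, q, p)] = x;
            }
    }
  out["eri"] = eri;
  return out;
}
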