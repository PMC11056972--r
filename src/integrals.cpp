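// McMurchie-Davidson evaluation of Gaussian integrals over contracted
// Cartesian shells attached to movable centers.  Shells arrive from R as
// lists (center coordinates in Bohr, angular momentum l, primitive exponents,
// contraction coefficients already weighted for primitive normalization).
// Spherical-harmonic transformation and final normalization happen in R.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

const double PI = 3.14159265358979323846;

// ---------------------------------------------------------------------------
// Boys function F_m(x), m = 0..mmax, stable over the whole range.
void boys(int mmax, double x, std::vector<double> &F) {
  F.assign(mmax + 1, 0.0);
  if (x < 1e-14) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (x > 35.0) {
    // upward recursion is stable for large x (exp(-x) negligible)
    F[0] = 0.5 * std::sqrt(PI / x) * std::erf(std::sqrt(x));
    double ex = std::exp(-x);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2.0 * m + 1.0) * F[m] - ex) / (2.0 * x);
    return;
  }
  // series for F_mmax, then downward recursion
  double ex = std::exp(-x);
  double term = 1.0 / (2.0 * mmax + 1.0);
  double sum = term;
  for (int i = 1; i < 300; ++i) {
    term *= 2.0 * x / (2.0 * mmax + 2.0 * i + 1.0);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  F[mmax] = ex * sum;
  for (int m = mmax; m > 0; --m)
    F[m - 1] = (2.0 * x * F[m] + ex) / (2.0 * m - 1.0);
}

// ---------------------------------------------------------------------------
// Hermite expansion coefficients E_t^{ij} for one Cartesian direction.
// Table indexed [i][j][t], i<=imax, j<=jmax, t<=i+j; out-of-range t -> 0.
struct ETable {
  int imax, jmax, tmax;
  std::vector<double> v;
  double at(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(i * (jmax + 1) + j) * (tmax + 1) + t];
  }
  double &ref(int i, int j, int t) {
    return v[(i * (jmax + 1) + j) * (tmax + 1) + t];
  }
};

void build_E(ETable &E, int imax, int jmax, double a, double b, double AB,
             double PA, double PB) {
  E.imax = imax; E.jmax = jmax; E.tmax = imax + jmax;
  E.v.assign((imax + 1) * (jmax + 1) * (E.tmax + 1), 0.0);
  double p = a + b;
  double mu = a * b / p;
  E.ref(0, 0, 0) = std::exp(-mu * AB * AB);
  double oo2p = 0.5 / p;
  for (int i = 0; i <= imax; ++i) {
    for (int j = 0; j <= jmax; ++j) {
      if (i == 0 && j == 0) continue;
      if (j > 0) {
        for (int t = 0; t <= i + j; ++t)
          E.ref(i, j, t) = oo2p * E.at(i, j - 1, t - 1) +
                           PB * E.at(i, j - 1, t) +
                           (t + 1) * E.at(i, j - 1, t + 1);
      } else {
        for (int t = 0; t <= i + j; ++t)
          E.ref(i, j, t) = oo2p * E.at(i - 1, j, t - 1) +
                           PA * E.at(i - 1, j, t) +
                           (t + 1) * E.at(i - 1, j, t + 1);
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Hermite Coulomb integrals R_{tuv} = R^0_{tuv}(p, PC); table up to order L.
struct RTable {
  int L;
  std::vector<double> v; // [t][u][v], t+u+v <= L
  double at(int t, int u, int w) const {
    if (t < 0 || u < 0 || w < 0) return 0.0;
    return v[(t * (L + 1) + u) * (L + 1) + w];
  }
};

void build_R(RTable &R, int L, double p, double X, double Y, double Z) {
  double r2 = X * X + Y * Y + Z * Z;
  std::vector<double> F;
  boys(L, p * r2, F);
  int n1 = L + 1;
  // Rn[n][t][u][v]; fill n descending
  std::vector<double> Rn((L + 1) * n1 * n1 * n1, 0.0);
  auto idx = [n1](int n, int t, int u, int w) {
    return ((n * n1 + t) * n1 + u) * n1 + w;
  };
  for (int n = L; n >= 0; --n) {
    Rn[idx(n, 0, 0, 0)] = std::pow(-2.0 * p, n) * F[n];
    if (n == L) continue;
    for (int t = 0; t <= L - n; ++t)
      for (int u = 0; u <= L - n - t; ++u)
        for (int w = 0; w <= L - n - t - u; ++w) {
          if (t + u + w == 0) continue;
          double val;
          if (t > 0) {
            val = X * Rn[idx(n + 1, t - 1, u, w)];
            if (t > 1) val += (t - 1) * Rn[idx(n + 1, t - 2, u, w)];
          } else if (u > 0) {
            val = Y * Rn[idx(n + 1, t, u - 1, w)];
            if (u > 1) val += (u - 1) * Rn[idx(n + 1, t, u - 2, w)];
          } else {
            val = Z * Rn[idx(n + 1, t, u, w - 1)];
            if (w > 1) val += (w - 1) * Rn[idx(n + 1, t, u, w - 2)];
          }
          Rn[idx(n, t, u, w)] = val;
        }
  }
  R.L = L;
  R.v.assign(n1 * n1 * n1, 0.0);
  for (int t = 0; t <= L; ++t)
    for (int u = 0; u <= L - t; ++u)
      for (int w = 0; w <= L - t - u; ++w)
        R.v[(t * n1 + u) * n1 + w] = Rn[idx(0, t, u, w)];
}

// ---------------------------------------------------------------------------
// Shell container decoded from R.
struct Shell {
  double A[3];
  int l;
  std::vector<double> exps, coefs;
  int ncart() const { return (l + 1) * (l + 2) / 2; }
};

std::vector<Shell> decode_shells(const List &shells) {
  std::vector<Shell> out;
  out.reserve(shells.size());
  for (int s = 0; s < shells.size(); ++s) {
    List sh = shells[s];
    Shell S;
    NumericVector A = sh["center"];
    S.A[0] = A[0]; S.A[1] = A[1]; S.A[2] = A[2];
    S.l = as<int>(sh["l"]);
    NumericVector e = sh["exponents"], c = sh["coefs"];
    S.exps.assign(e.begin(), e.end());
    S.coefs.assign(c.begin(), c.end());
    out.push_back(S);
  }
  return out;
}

// Cartesian component list for angular momentum l: lx descending, then ly.
void cart_components(int l, std::vector<std::array<int, 3>> &comp) {
  comp.clear();
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly)
      comp.push_back({lx, ly, l - lx - ly});
}

} // namespace

// ---------------------------------------------------------------------------
// One-particle matrices over contracted Cartesian functions: overlap, kinetic
// (electron convention, -1/2 del^2), unsigned point-charge attraction kernel
// sum_A Z_A <mu| 1/|r-R_A| |nu>, and Cartesian position matrices.
// [[Rcpp::export(name = ".cpp_one_particle")]]
List cpp_one_particle(List shells_in, NumericMatrix charge_pos,
                      NumericVector charges) {
  std::vector<Shell> shells = decode_shells(shells_in);
  int nsh = shells.size();
  std::vector<int> offset(nsh, 0);
  int nbf = 0;
  for (int s = 0; s < nsh; ++s) { offset[s] = nbf; nbf += shells[s].ncart(); }

  NumericMatrix S(nbf, nbf), T(nbf, nbf), V(nbf, nbf),
      X(nbf, nbf), Y(nbf, nbf), Z(nbf, nbf);
  int nchg = charge_pos.nrow();

  std::vector<std::array<int, 3>> compA, compB;
  for (int sa = 0; sa < nsh; ++sa) {
    const Shell &A = shells[sa];
    cart_components(A.l, compA);
    for (int sb = sa; sb < nsh; ++sb) {
      const Shell &B = shells[sb];
      cart_components(B.l, compB);
      int na = compA.size(), nb = compB.size();
      std::vector<double> bS(na * nb, 0.0), bT(na * nb, 0.0),
          bV(na * nb, 0.0), bX(na * nb, 0.0), bY(na * nb, 0.0),
          bZ(na * nb, 0.0);
      for (size_t ia = 0; ia < A.exps.size(); ++ia) {
        for (size_t ib = 0; ib < B.exps.size(); ++ib) {
          double a = A.exps[ia], b = B.exps[ib];
          double cc = A.coefs[ia] * B.coefs[ib];
          double p = a + b;
          double P[3], PA[3], PB[3], AB[3];
          for (int d = 0; d < 3; ++d) {
            P[d] = (a * A.A[d] + b * B.A[d]) / p;
            PA[d] = P[d] - A.A[d];
            PB[d] = P[d] - B.A[d];
            AB[d] = A.A[d] - B.A[d];
          }
          ETable Ex, Ey, Ez;
          // +2 on ket side for kinetic, +1 reused for dipole
          build_E(Ex, A.l, B.l + 2, a, b, AB[0], PA[0], PB[0]);
          build_E(Ey, A.l, B.l + 2, a, b, AB[1], PA[1], PB[1]);
          build_E(Ez, A.l, B.l + 2, a, b, AB[2], PA[2], PB[2]);
          double pref = std::pow(PI / p, 1.5);
          int L = A.l + B.l;
          // Hermite Coulomb tables per charge
          std::vector<RTable> Rtabs(nchg);
          for (int c = 0; c < nchg; ++c)
            build_R(Rtabs[c], L, p, P[0] - charge_pos(c, 0),
                    P[1] - charge_pos(c, 1), P[2] - charge_pos(c, 2));
          for (int ka = 0; ka < na; ++ka) {
            int ax = compA[ka][0], ay = compA[ka][1], az = compA[ka][2];
            for (int kb = 0; kb < nb; ++kb) {
              int bx = compB[kb][0], by = compB[kb][1], bz = compB[kb][2];
              auto ss = [&](int jx, int jy, int jz) -> double {
                if (jx < 0 || jy < 0 || jz < 0) return 0.0;
                return Ex.at(ax, jx, 0) * Ey.at(ay, jy, 0) *
                       Ez.at(az, jz, 0) * pref;
              };
              double s0 = ss(bx, by, bz);
              int k = ka * nb + kb;
              bS[k] += cc * s0;
              // kinetic via angular-momentum raised/lowered overlaps
              double t = b * (2.0 * (bx + by + bz) + 3.0) * s0 -
                         2.0 * b * b * (ss(bx + 2, by, bz) +
                                        ss(bx, by + 2, bz) +
                                        ss(bx, by, bz + 2));
              if (bx > 1) t -= 0.5 * bx * (bx - 1) * ss(bx - 2, by, bz);
              if (by > 1) t -= 0.5 * by * (by - 1) * ss(bx, by - 2, bz);
              if (bz > 1) t -= 0.5 * bz * (bz - 1) * ss(bx, by, bz - 2);
              bT[k] += cc * t;
              bX[k] += cc * (ss(bx + 1, by, bz) + B.A[0] * s0);
              bY[k] += cc * (ss(bx, by + 1, bz) + B.A[1] * s0);
              bZ[k] += cc * (ss(bx, by, bz + 1) + B.A[2] * s0);
              if (nchg > 0) {
                double v = 0.0;
                for (int c = 0; c < nchg; ++c) {
                  double vc = 0.0;
                  for (int tt = 0; tt <= ax + bx; ++tt)
                    for (int uu = 0; uu <= ay + by; ++uu)
                      for (int ww = 0; ww <= az + bz; ++ww)
                        vc += Ex.at(ax, bx, tt) * Ey.at(ay, by, uu) *
                              Ez.at(az, bz, ww) * Rtabs[c].at(tt, uu, ww);
                  v += charges[c] * vc;
                }
                bV[k] += cc * (2.0 * PI / p) * v;
              }
            }
          }
        }
      }
      for (int ka = 0; ka < na; ++ka)
        for (int kb = 0; kb < nb; ++kb) {
          int i = offset[sa] + ka, j = offset[sb] + kb, k = ka * nb + kb;
          S(i, j) = bS[k]; T(i, j) = bT[k]; V(i, j) = bV[k];
          X(i, j) = bX[k]; Y(i, j) = bY[k]; Z(i, j) = bZ[k];
          if (i != j) {
            S(j, i) = bS[k]; T(j, i) = bT[k]; V(j, i) = bV[k];
            X(j, i) = bX[k]; Y(j, i) = bY[k]; Z(j, i) = bZ[k];
          }
        }
    }
  }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V,
                      _["X"] = X, _["Y"] = Y, _["Z"] = Z);
}

// ---------------------------------------------------------------------------
// Two-particle Coulomb tensor (mu nu | la si) in chemists' notation between a
// bra shell list and a ket shell list (possibly different species).  Returned
// as an (nbra^2 x nket^2) matrix with column-major pair indices (mu,nu).
// [[Rcpp::export(name = ".cpp_eri")]]
NumericMatrix cpp_eri(List bra_in, List ket_in) {
  std::vector<Shell> bra = decode_shells(bra_in);
  std::vector<Shell> ket = decode_shells(ket_in);
  int nshA = bra.size(), nshC = ket.size();
  std::vector<int> offA(nshA, 0), offC(nshC, 0);
  int nA = 0, nC = 0;
  for (int s = 0; s < nshA; ++s) { offA[s] = nA; nA += bra[s].ncart(); }
  for (int s = 0; s < nshC; ++s) { offC[s] = nC; nC += ket[s].ncart(); }

  NumericMatrix G((R_xlen_t)nA * nA, (R_xlen_t)nC * nC);
  double *g = G.begin();
  R_xlen_t nrow = (R_xlen_t)nA * nA;

  std::vector<std::array<int, 3>> cA, cB, cC, cD;
  for (int sa = 0; sa < nshA; ++sa) {
    cart_components(bra[sa].l, cA);
    for (int sb = sa; sb < nshA; ++sb) {
      cart_components(bra[sb].l, cB);
      const Shell &A = bra[sa], &B = bra[sb];
      int na = cA.size(), nb = cB.size();
      for (int sc = 0; sc < nshC; ++sc) {
        cart_components(ket[sc].l, cC);
        for (int sd = sc; sd < nshC; ++sd) {
          cart_components(ket[sd].l, cD);
          const Shell &C = ket[sc], &D = ket[sd];
          int nc = cC.size(), nd = cD.size();
          std::vector<double> blk(na * nb * nc * nd, 0.0);
          int L1 = A.l + B.l, L2 = C.l + D.l, L = L1 + L2;
          for (size_t ia = 0; ia < A.exps.size(); ++ia)
            for (size_t ib = 0; ib < B.exps.size(); ++ib) {
              double a = A.exps[ia], b = B.exps[ib], p = a + b;
              double ccab = A.coefs[ia] * B.coefs[ib];
              double P[3], PA[3], PB[3], AB[3];
              for (int d = 0; d < 3; ++d) {
                P[d] = (a * A.A[d] + b * B.A[d]) / p;
                PA[d] = P[d] - A.A[d];
                PB[d] = P[d] - B.A[d];
                AB[d] = A.A[d] - B.A[d];
              }
              ETable E1x, E1y, E1z;
              build_E(E1x, A.l, B.l, a, b, AB[0], PA[0], PB[0]);
              build_E(E1y, A.l, B.l, a, b, AB[1], PA[1], PB[1]);
              build_E(E1z, A.l, B.l, a, b, AB[2], PA[2], PB[2]);
              for (size_t ic = 0; ic < C.exps.size(); ++ic)
                for (size_t id = 0; id < D.exps.size(); ++id) {
                  double c = C.exps[ic], d0 = D.exps[id], q = c + d0;
                  double cc = ccab * C.coefs[ic] * D.coefs[id];
                  double Q[3], QC[3], QD[3], CD[3];
                  for (int d = 0; d < 3; ++d) {
                    Q[d] = (c * C.A[d] + d0 * D.A[d]) / q;
                    QC[d] = Q[d] - C.A[d];
                    QD[d] = Q[d] - D.A[d];
                    CD[d] = C.A[d] - D.A[d];
                  }
                  ETable E2x, E2y, E2z;
                  build_E(E2x, C.l, D.l, c, d0, CD[0], QC[0], QD[0]);
                  build_E(E2y, C.l, D.l, c, d0, CD[1], QC[1], QD[1]);
                  build_E(E2z, C.l, D.l, c, d0, CD[2], QC[2], QD[2]);
                  double alpha = p * q / (p + q);
                  RTable R;
                  build_R(R, L, alpha, P[0] - Q[0], P[1] - Q[1], P[2] - Q[2]);
                  double pref = 2.0 * std::pow(PI, 2.5) /
                                (p * q * std::sqrt(p + q));
                  for (int ka = 0; ka < na; ++ka)
                    for (int kb = 0; kb < nb; ++kb)
                      for (int kc = 0; kc < nc; ++kc)
                        for (int kd = 0; kd < nd; ++kd) {
                          double val = 0.0;
                          int tx = cA[ka][0] + cB[kb][0],
                              ty = cA[ka][1] + cB[kb][1],
                              tz = cA[ka][2] + cB[kb][2];
                          int sx = cC[kc][0] + cD[kd][0],
                              sy = cC[kc][1] + cD[kd][1],
                              sz = cC[kc][2] + cD[kd][2];
                          for (int t = 0; t <= tx; ++t)
                            for (int u = 0; u <= ty; ++u)
                              for (int w = 0; w <= tz; ++w) {
                                double e1 =
                                    E1x.at(cA[ka][0], cB[kb][0], t) *
                                    E1y.at(cA[ka][1], cB[kb][1], u) *
                                    E1z.at(cA[ka][2], cB[kb][2], w);
                                if (e1 == 0.0) continue;
                                double inner = 0.0;
                                for (int tp = 0; tp <= sx; ++tp)
                                  for (int up = 0; up <= sy; ++up)
                                    for (int wp = 0; wp <= sz; ++wp) {
                                      double e2 =
                                          E2x.at(cC[kc][0], cD[kd][0], tp) *
                                          E2y.at(cC[kc][1], cD[kd][1], up) *
                                          E2z.at(cC[kc][2], cD[kd][2], wp);
                                      if (e2 == 0.0) continue;
                                      double sgn =
                                          ((tp + up + wp) % 2) ? -1.0 : 1.0;
                                      inner += sgn * e2 *
                                               R.at(t + tp, u + up, w + wp);
                                    }
                                val += e1 * inner;
                              }
                          blk[((ka * nb + kb) * nc + kc) * nd + kd] +=
                              cc * pref * val;
                        }
                }
            }
          // scatter with bra (sa<=sb) and ket (sc<=sd) permutational symmetry
          for (int ka = 0; ka < na; ++ka)
            for (int kb = 0; kb < nb; ++kb)
              for (int kc = 0; kc < nc; ++kc)
                for (int kd = 0; kd < nd; ++kd) {
                  double val = blk[((ka * nb + kb) * nc + kc) * nd + kd];
                  int i = offA[sa] + ka, j = offA[sb] + kb;
                  int k = offC[sc] + kc, l = offC[sd] + kd;
                  R_xlen_t r1 = (R_xlen_t)j * nA + i,
                           r2 = (R_xlen_t)i * nA + j;
                  R_xlen_t c1 = (R_xlen_t)l * nC + k,
                           c2 = (R_xlen_t)k * nC + l;
                  g[r1 + nrow * c1] = val;
                  g[r2 + nrow * c1] = val;
                  g[r1 + nrow * c2] = val;
                  g[r2 + nrow * c2] = val;
                }
        }
      }
    }
  }
  return G;
}
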