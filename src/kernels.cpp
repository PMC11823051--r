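#include <Rcpp.h>
#include <cmath>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// Pairwise Euclidean distance matrix for a scalar variable.
// [[Rcpp::export]]
NumericMatrix cpp_dist_vec(NumericVector x) {
  int n = x.size();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = std::fabs(x[i] - x[j]);
      D(i, j) = d;
      D(j, i) = d;
    }
  return D;
}

// Pairwise Euclidean distance matrix for rows of a matrix.
// [[Rcpp::export]]
NumericMatrix cpp_dist_mat(NumericMatrix X) {
  int n = X.nrow(), p = X.ncol();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) {
        double d = X(i, k) - X(j, k);
        s += d * d;
      }
      s = std::sqrt(s);
      D(i, j) = s;
      D(j, i) = s;
    }
  return D;
}

// Double (unweighted) centering: A_ij = d_ij - rowmean_i - colmean_j + grand.
// [[Rcpp::export]]
NumericMatrix cpp_dcenter(NumericMatrix D) {
  int n = D.nrow();
  NumericVector rm(n);
  double gm = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += D(i, j);
    rm[i] = s / n;
    gm += s;
  }
  gm /= (double)n * n;
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      A(i, j) = D(i, j) - rm[i] - rm[j] + gm;
  return A;
}

// Quadratic-form statistics for weighted distance covariance:
// given centered matrices A, B, returns
// (w'(A*B)w, w'(A*A)w, w'(B*B)w) / n^2   (elementwise products).
// [[Rcpp::export]]
NumericVector cpp_wstats(NumericMatrix A, NumericMatrix B, NumericVector w) {
  int n = A.nrow();
  double sab = 0.0, saa = 0.0, sbb = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double ww = w[i] * w[j];
      double a = A(i, j), b = B(i, j);
      sab += ww * a * b;
      saa += ww * a * a;
      sbb += ww * b * b;
    }
  double n2 = (double)n * n;
  return NumericVector::create(sab / n2, saa / n2, sbb / n2);
}

// Weighted distance correlation of each column of Z with t, for several
// weight vectors at once (columns of W, each summing to n).  Uses the
// spec quadratic form: unweighted double centering, weights only in the
// quadratic form.  Returns a p x m matrix.  Heavy products use BLAS.
//
// For a raw symmetric distance matrix D with row means r and grand mean
// g, centered A_ij = D_ij - r_i - r_j + g, and weights w (sum n):
//   w'(A.B)w = w'(D.Dt)w - [2 sum_i w_i r^b_i v^a_i - g_b q_a]
//              - [2 sum_i w_i r^a_i v^b_i - g_a q_b]
//              + 2n sum w r^a r^b + 2 (sum w r^a)(sum w r^b)
//              - 2n g_b sum w r^a - 2n g_a sum w r^b + n^2 g_a g_b
// with v^a = D w, q_a = w'v^a (and symmetrically for Dt).
// [[Rcpp::export]]
NumericMatrix cpp_wdcor_multi(NumericMatrix Z, NumericVector t,
                              NumericMatrix W) {
  int n = Z.nrow(), p = Z.ncol(), m = W.ncol();
  double n2 = (double)n * n;
  const double one = 1.0, zero = 0.0;
  std::vector<double> Dt(n * n), Et(n * n), rb(n);
  double gb = 0.0;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      double d = std::fabs(t[i] - t[j]);
      Dt[j * n + i] = d;
      Et[j * n + i] = d * d;
    }
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += Dt[j * n + i];
    rb[i] = s / n;
    gb += s;
  }
  gb /= n2;
  // per weight column: vb = Dt w, and S_bb
  std::vector<double> VB(n * m), CB(n * m), sbb(m), qb(m), swrb(m);
  F77_CALL(dgemm)("N", "N", &n, &m, &n, &one, Dt.data(), &n, W.begin(),
                  &n, &zero, VB.data(), &n FCONE FCONE);
  F77_CALL(dgemm)("N", "N", &n, &m, &n, &one, Et.data(), &n, W.begin(),
                  &n, &zero, CB.data(), &n FCONE FCONE);
  for (int k = 0; k < m; ++k) {
    double q = 0.0, p2 = 0.0, wv = 0.0, m1 = 0.0, m2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double wi = W(i, k);
      q += wi * VB[k * n + i];
      p2 += wi * CB[k * n + i];
      wv += wi * rb[i] * VB[k * n + i];
      m1 += wi * rb[i];
      m2 += wi * rb[i] * rb[i];
    }
    qb[k] = q;
    swrb[k] = m1;
    sbb[k] = p2 - 2.0 * (2.0 * wv - gb * q) +
      (2.0 * n * m2 + 2.0 * m1 * m1 + n2 * gb * gb - 4.0 * gb * n * m1);
  }
  std::vector<double> D(n * n), E1(n * n), E2(n * n),
    VA(n * m), C1(n * m), C2(n * m), ra(n);
  NumericMatrix out(p, m);
  for (int c = 0; c < p; ++c) {
    double ga = 0.0;
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        double d = std::fabs(Z(i, c) - Z(j, c));
        D[j * n + i] = d;
        E1[j * n + i] = d * Dt[j * n + i];
        E2[j * n + i] = d * d;
      }
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += D[j * n + i];
      ra[i] = s / n;
      ga += s;
    }
    ga /= n2;
    F77_CALL(dgemm)("N", "N", &n, &m, &n, &one, D.data(), &n, W.begin(),
                    &n, &zero, VA.data(), &n FCONE FCONE);
    F77_CALL(dgemm)("N", "N", &n, &m, &n, &one, E1.data(), &n, W.begin(),
                    &n, &zero, C1.data(), &n FCONE FCONE);
    F77_CALL(dgemm)("N", "N", &n, &m, &n, &one, E2.data(), &n, W.begin(),
                    &n, &zero, C2.data(), &n FCONE FCONE);
    for (int k = 0; k < m; ++k) {
      double qa = 0.0, p1 = 0.0, p2 = 0.0, wrbva = 0.0, wrav_b = 0.0,
        wva = 0.0, m1a = 0.0, m2a = 0.0, wrarb = 0.0;
      for (int i = 0; i < n; ++i) {
        double wi = W(i, k);
        qa += wi * VA[k * n + i];
        p1 += wi * C1[k * n + i];
        p2 += wi * C2[k * n + i];
        wrbva += wi * rb[i] * VA[k * n + i];
        wrav_b += wi * ra[i] * VB[k * n + i];
        wva += wi * ra[i] * VA[k * n + i];
        m1a += wi * ra[i];
        m2a += wi * ra[i] * ra[i];
        wrarb += wi * ra[i] * rb[i];
      }
      double sab = p1 - (2.0 * wrbva - gb * qa) - (2.0 * wrav_b - ga * qb[k])
        + 2.0 * n * wrarb + 2.0 * m1a * swrb[k]
        - 2.0 * n * gb * m1a - 2.0 * n * ga * swrb[k] + n2 * ga * gb;
      double saa = p2 - 2.0 * (2.0 * wva - ga * qa) +
        (2.0 * n * m2a + 2.0 * m1a * m1a + n2 * ga * ga
         - 4.0 * ga * n * m1a);
      double denom = std::sqrt(saa * sbb[k]);
      double r2 = (denom > 1e-10 * n2) ? sab / denom : 0.0;
      out(c, k) = (r2 > 0.0) ? std::sqrt(std::min(r2, 1.0)) : 0.0;
    }
  }
  return out;
}

// Kernel-smoothed conditional distance correlation of each column of Z
// with y, given t.  W is an n x m matrix of kernel weights (one column per
// evaluation point, each column summing to n).  Uses weighted double
// centering inside each local statistic, with own-pair (diagonal) terms
// removed from the quadratic sums (partial U-statistic bias correction);
// returns the average over evaluation points for each covariate.
//
// Per evaluation point k with weights w (sum n), writing A, B for the raw
// distance matrices and ma = A w / n, maa = w'ma / n (similarly mb, mbb):
//   S_ab = w'(A.B)w - 2n sum_i w_i ma_i mb_i + n^2 maa mbb
//          - sum_i w_i^2 (maa - 2 ma_i)(mbb - 2 mb_i)
// and S_aa, S_bb analogously; the local dcor is sqrt(S_ab/sqrt(S_aa S_bb)).
// The heavy products are delegated to BLAS dgemm.
// [[Rcpp::export]]
NumericVector cpp_cdcor_multi(NumericMatrix Z, NumericVector y,
                              NumericMatrix W) {
  int n = Z.nrow(), p = Z.ncol(), m = W.ncol();
  double n2 = (double)n * n;
  const double one = 1.0, zero = 0.0;
  std::vector<double> Dy(n * n), Eb(n * n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      double d = std::fabs(y[i] - y[j]);
      Dy[j * n + i] = d;
      Eb[j * n + i] = d * d;
    }
  // MB = Dy W, CB = (Dy.Dy) W
  std::vector<double> MB(n * m), CB(n * m);
  F77_CALL(dgemm)("N", "N", &n, &m, &n, &one, Dy.data(), &n, W.begin(),
                  &n, &zero, MB.data(), &n FCONE FCONE);
  F77_CALL(dgemm)("N", "N", &n, &m, &n, &one, Eb.data(), &n, W.begin(),
                  &n, &zero, CB.data(), &n FCONE FCONE);
  std::vector<double> mbb(m), sbb(m);
  for (int k = 0; k < m; ++k) {
    double g = 0.0, pbb = 0.0, corr = 0.0, cross = 0.0;
    for (int i = 0; i < n; ++i) {
      double wi = W(i, k);
      MB[k * n + i] /= n;
      g += wi * MB[k * n + i];
      pbb += wi * CB[k * n + i];
    }
    g /= n;
    for (int i = 0; i < n; ++i) {
      double wi = W(i, k), mbi = MB[k * n + i];
      cross += wi * mbi * mbi;
      double bcii = g - 2.0 * mbi;
      corr += wi * wi * bcii * bcii;
    }
    mbb[k] = g;
    sbb[k] = (pbb - 2.0 * n * cross + n2 * g * g - corr) / n2;
  }
  std::vector<double> A(n * n), E1(n * n), E2(n * n),
    MA(n * m), C1(n * m), C2(n * m);
  NumericVector out(p);
  for (int c = 0; c < p; ++c) {
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        double a = std::fabs(Z(i, c) - Z(j, c));
        A[j * n + i] = a;
        E1[j * n + i] = a * Dy[j * n + i];
        E2[j * n + i] = a * a;
      }
    F77_CALL(dgemm)("N", "N", &n, &m, &n, &one, A.data(), &n, W.begin(),
                    &n, &zero, MA.data(), &n FCONE FCONE);
    F77_CALL(dgemm)("N", "N", &n, &m, &n, &one, E1.data(), &n, W.begin(),
                    &n, &zero, C1.data(), &n FCONE FCONE);
    F77_CALL(dgemm)("N", "N", &n, &m, &n, &one, E2.data(), &n, W.begin(),
                    &n, &zero, C2.data(), &n FCONE FCONE);
    double acc = 0.0;
    for (int k = 0; k < m; ++k) {
      double maa = 0.0, pab = 0.0, paa = 0.0;
      for (int i = 0; i < n; ++i) {
        double wi = W(i, k);
        MA[k * n + i] /= n;
        maa += wi * MA[k * n + i];
        pab += wi * C1[k * n + i];
        paa += wi * C2[k * n + i];
      }
      maa /= n;
      double cr_ab = 0.0, cr_aa = 0.0, d_ab = 0.0, d_aa = 0.0;
      for (int i = 0; i < n; ++i) {
        double wi = W(i, k), mai = MA[k * n + i], mbi = MB[k * n + i];
        cr_ab += wi * mai * mbi;
        cr_aa += wi * mai * mai;
        double acii = maa - 2.0 * mai, bcii = mbb[k] - 2.0 * mbi;
        d_ab += wi * wi * acii * bcii;
        d_aa += wi * wi * acii * acii;
      }
      double sab = (pab - 2.0 * n * cr_ab + n2 * maa * mbb[k] - d_ab) / n2;
      double saa = (paa - 2.0 * n * cr_aa + n2 * maa * maa - d_aa) / n2;
      double denom = std::sqrt(saa * sbb[k]);
      double r2 = (denom > 1e-14) ? sab / denom : 0.0;
      acc += (r2 > 0.0) ? std::sqrt(std::min(r2, 1.0)) : 0.0;
    }
    out[c] = acc / m;
  }
  return out;
}

// Cyclic coordinate descent for min ||y - X b||^2 + sum_j lam_j |b_j|.
// X and y are expected centered; lam_j combines lambda_n and the adaptive
// penalty weight.  Deterministic cyclic order, warm start b0.
// [[Rcpp::export]]
NumericVector cpp_cd_lasso(NumericMatrix X, NumericVector y,
                           NumericVector lam, NumericVector b0,
                           double tol, int maxit) {
  int n = X.nrow(), p = X.ncol();
  NumericVector b = clone(b0);
  std::vector<double> r(n), ss(p);
  for (int i = 0; i < n; ++i) r[i] = y[i];
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    ss[j] = s;
    if (b[j] != 0.0)
      for (int i = 0; i < n; ++i) r[i] -= X(i, j) * b[j];
  }
  for (int it = 0; it < maxit; ++it) {
    double del = 0.0;
    for (int j = 0; j < p; ++j) {
      if (ss[j] <= 0.0) { b[j] = 0.0; continue; }
      double rho = 0.0;
      for (int i = 0; i < n; ++i) rho += X(i, j) * r[i];
      rho += ss[j] * b[j];
      double th = lam[j] / 2.0;
      double bn;
      if (rho > th) bn = (rho - th) / ss[j];
      else if (rho < -th) bn = (rho + th) / ss[j];
      else bn = 0.0;
      double d = bn - b[j];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= X(i, j) * d;
        b[j] = bn;
        double ad = std::fabs(d);
        if (ad > del) del = ad;
      }
    }
    if (del < tol) break;
  }
  return b;
}
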