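// Electronic amplitude propagation across one nuclear step.
//
// Adiabatic generator:  dc/dt = -i E(t) * c - sigma(t) %*% c
// with E(t) linearly interpolated between the step endpoints and
// sigma(t) = lin(S0, S1)(t) + 6 t (1 - t) * Scorr,
// where Scorr = S_ths - (S0 + S1)/2 reproduces the overlap-derived
// time-integral of the coupling (Tully-Hammes-Schiffer-style treatment:
// a narrow coupling spike between the endpoints still transfers the right
// amplitude). The fewest-switches hop probability out of the active state
// is accumulated substep by substep, so transits faster than the nuclear
// step still yield the correct integrated hop probability.
//
// Diabatic generator (frozen-path re-analysis): dc/dt = -i V(t) %*% c,
// V(t) linear; hop flux 2 V_ja Im(c_j^* c_a).
//
// Fixed-substep classical RK4, atomic units, hbar = 1.

#include <Rcpp.h>
#include <complex>
#include <vector>
using namespace Rcpp;

typedef std::complex<double> cplx;

// [[Rcpp::export]]
List tdse_rk4_adiabatic(ComplexVector c0,
                        NumericVector E0, NumericVector E1,
                        NumericMatrix S0, NumericMatrix S1,
                        NumericMatrix Sths,
                        double dt, int nsub, int active) {
  const int n = c0.size();
  if (nsub < 1) stop("nsub must be >= 1");
  std::vector<cplx> c(n), k1(n), k2(n), k3(n), k4(n), tmp(n);
  for (int i = 0; i < n; ++i) c[i] = cplx(c0[i].r, c0[i].i);
  const double h = dt / nsub;

  std::vector<double> e(n), S((size_t)n * n);
  std::vector<double> s0((size_t)n * n), s1((size_t)n * n), sc((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      size_t k = (size_t)i * n + j;
      s0[k] = S0(i, j);
      s1[k] = S1(i, j);
      sc[k] = Sths(i, j) - 0.5 * (S0(i, j) + S1(i, j));
    }

  auto interp = [&](double f) {
    for (int i = 0; i < n; ++i) e[i] = E0[i] + f * (E1[i] - E0[i]);
    double w = 6.0 * f * (1.0 - f);
    for (size_t k = 0; k < (size_t)n * n; ++k)
      S[k] = s0[k] + f * (s1[k] - s0[k]) + w * sc[k];
  };
  auto df = [&](const std::vector<cplx>& cc, std::vector<cplx>& out) {
    for (int i = 0; i < n; ++i) {
      cplx acc = cplx(0.0, -1.0) * e[i] * cc[i];
      const double* Srow = S.data() + (size_t)i * n;
      for (int j = 0; j < n; ++j) acc -= Srow[j] * cc[j];
      out[i] = acc;
    }
  };

  NumericVector g(n);  // accumulated fewest-switches hop probability
  const int a = active - 1;

  for (int s = 0; s < nsub; ++s) {
    double f0 = (double)s / nsub;
    double fm = (s + 0.5) / nsub;
    double f1 = (double)(s + 1) / nsub;

    interp(f0); df(c, k1);
    for (int i = 0; i < n; ++i) tmp[i] = c[i] + 0.5 * h * k1[i];
    interp(fm); df(tmp, k2);
    for (int i = 0; i < n; ++i) tmp[i] = c[i] + 0.5 * h * k2[i];
    df(tmp, k3);
    // keep midpoint sigma for the hop flux below
    std::vector<double> Smid(S);
    for (int i = 0; i < n; ++i) tmp[i] = c[i] + h * k3[i];
    interp(f1); df(tmp, k4);
    for (int i = 0; i < n; ++i)
      c[i] += (h / 6.0) * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

    if (a >= 0 && a < n) {
      double pa = std::norm(c[a]);
      if (pa > 1e-12) {
        for (int j = 0; j < n; ++j) {
          if (j == a) continue;
          // flux into j out of a: 2 sigma_aj Re(c_j^* c_a)
          double flux = 2.0 * Smid[(size_t)a * n + j] *
            (c[j].real() * c[a].real() + c[j].imag() * c[a].imag());
          g[j] += h * flux / pa;
        }
      }
    }
  }
  // positive part of the net integrated flux per channel
  for (int j = 0; j < n; ++j) if (g[j] < 0) g[j] = 0;

  ComplexVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i].r = c[i].real();
    out[i].i = c[i].imag();
  }
  return List::create(_["c"] = out, _["g"] = g);
}

// [[Rcpp::export]]
List tdse_rk4_diabatic(ComplexVector c0,
                       NumericMatrix V0, NumericMatrix V1,
                       double dt, int nsub, int active) {
  const int n = c0.size();
  if (nsub < 1) stop("nsub must be >= 1");
  std::vector<cplx> c(n), k1(n), k2(n), k3(n), k4(n), tmp(n);
  for (int i = 0; i < n; ++i) c[i] = cplx(c0[i].r, c0[i].i);
  const double h = dt / nsub;

  std::vector<double> V((size_t)n * n), v0((size_t)n * n), v1((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      size_t k = (size_t)i * n + j;
      v0[k] = V0(i, j);
      v1[k] = V1(i, j);
    }
  auto interp = [&](double f) {
    for (size_t k = 0; k < (size_t)n * n; ++k) V[k] = v0[k] + f * (v1[k] - v0[k]);
  };
  auto df = [&](const std::vector<cplx>& cc, std::vector<cplx>& out) {
    for (int i = 0; i < n; ++i) {
      cplx acc(0.0, 0.0);
      const double* Vrow = V.data() + (size_t)i * n;
      for (int j = 0; j < n; ++j) acc += Vrow[j] * cc[j];
      out[i] = cplx(acc.imag(), -acc.real());  // * -i
    }
  };

  NumericVector g(n);
  const int a = active - 1;

  for (int s = 0; s < nsub; ++s) {
    double f0 = (double)s / nsub;
    double fm = (s + 0.5) / nsub;
    double f1 = (double)(s + 1) / nsub;
    interp(f0); df(c, k1);
    for (int i = 0; i < n; ++i) tmp[i] = c[i] + 0.5 * h * k1[i];
    interp(fm); df(tmp, k2);
    for (int i = 0; i < n; ++i) tmp[i] = c[i] + 0.5 * h * k2[i];
    df(tmp, k3);
    std::vector<double> Vmid(V);
    for (int i = 0; i < n; ++i) tmp[i] = c[i] + h * k3[i];
    interp(f1); df(tmp, k4);
    for (int i = 0; i < n; ++i)
      c[i] += (h / 6.0) * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

    if (a >= 0 && a < n) {
      double pa = std::norm(c[a]);
      if (pa > 1e-12) {
        for (int j = 0; j < n; ++j) {
          if (j == a) continue;
          // flux into j: 2 V_ja Im(c_j^* c_a)
          double flux = 2.0 * Vmid[(size_t)j * n + a] *
            (c[j].real() * c[a].imag() - c[j].imag() * c[a].real());
          g[j] += h * flux / pa;
        }
      }
    }
  }
  for (int j = 0; j < n; ++j) if (g[j] < 0) g[j] = 0;

  ComplexVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i].r = c[i].real();
    out[i].i = c[i].imag();
  }
  return List::create(_["c"] = out, _["g"] = g);
}
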