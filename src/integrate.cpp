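// Fixed-step RK4 integration of the STN-GPe ring network.
//
// Implements exactly the model defined by the pure-R functions in
// R/model_core.R (which are the readable reference); kept in C++ because the
// amplitude-by-frequency sweep experiments integrate thousands of
// network-seconds.
//
// State layout for n neurons per population (12 n values):
//   [0,n)    STN v      [5n,6n)  GPe v
//   [n,2n)   STN n      [6n,7n)  GPe n
//   [2n,3n)  STN h      [7n,8n)  GPe h
//   [3n,4n)  STN r      [8n,9n)  GPe r
//   [4n,5n)  STN Ca     [9n,10n) GPe Ca
//   [10n,11n) STN->GPe gates s   [11n,12n) GPe->STN gates s

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sig(double x, double th, double sg) {
  return 1.0 / (1.0 + std::exp(-(x - th) / sg));
}

struct Cell {
  double C, gNa, vNa, gK, vK, gL, vL, gCa, gT, vCa, gAHP, vAHP;
  double k1, eps, kCa, phin, phih, phir, Iapp;
  bool lin_r;  // T-current inactivation: true -> r, false -> b_inf(r)^2
  double thm, sgm, thh, sgh, thn, sgn, thr, sgr, tha, sga, ths, sgs, thb, sgb;
  double tn0, tn1, thnt, sgnt, th0, th1, thht, sght, tr0, tr1, thrt, sgrt;
  double binf0;  // sig(0; thb, sgb), offset making b_inf(0) = 0
};

// Must match pack_cell() in R/parameters.R.
static Cell unpack_cell(const NumericVector& p) {
  Cell c;
  int i = 0;
  c.C = p[i++]; c.gNa = p[i++]; c.vNa = p[i++]; c.gK = p[i++]; c.vK = p[i++];
  c.gL = p[i++]; c.vL = p[i++]; c.gCa = p[i++]; c.gT = p[i++]; c.vCa = p[i++];
  c.gAHP = p[i++]; c.vAHP = p[i++]; c.k1 = p[i++]; c.eps = p[i++]; c.kCa = p[i++];
  c.phin = p[i++]; c.phih = p[i++]; c.phir = p[i++]; c.Iapp = p[i++];
  c.lin_r = p[i++] != 0.0;
  c.thm = p[i++]; c.sgm = p[i++]; c.thh = p[i++]; c.sgh = p[i++];
  c.thn = p[i++]; c.sgn = p[i++]; c.thr = p[i++]; c.sgr = p[i++];
  c.tha = p[i++]; c.sga = p[i++]; c.ths = p[i++]; c.sgs = p[i++];
  c.thb = p[i++]; c.sgb = p[i++];
  c.tn0 = p[i++]; c.tn1 = p[i++]; c.thnt = p[i++]; c.sgnt = p[i++];
  c.th0 = p[i++]; c.th1 = p[i++]; c.thht = p[i++]; c.sght = p[i++];
  c.tr0 = p[i++]; c.tr1 = p[i++]; c.thrt = p[i++]; c.sgrt = p[i++];
  c.binf0 = sig(0.0, c.thb, c.sgb);
  return c;
}

struct Syn {
  double alpha, beta, thg, ThgH, sgH, g, vsyn;
};

static Syn unpack_syn(const NumericVector& p) {
  Syn s;
  s.alpha = p[0]; s.beta = p[1]; s.thg = p[2]; s.ThgH = p[3]; s.sgH = p[4];
  s.g = p[5]; s.vsyn = p[6];
  return s;
}

// Derivative of one neuron's (v, n, h, r, Ca) given total synaptic and
// external currents; writes 5 values through d*.
static inline void cell_deriv(const Cell& c, double v, double nn, double h,
                              double r, double Ca, double isyn, double iext,
                              double* dv, double* dn, double* dh, double* dr,
                              double* dCa) {
  const double minf = sig(v, c.thm, c.sgm);
  const double INa = c.gNa * minf * minf * minf * h * (v - c.vNa);
  const double n2 = nn * nn;
  const double IK = c.gK * n2 * n2 * (v - c.vK);
  const double IL = c.gL * (v - c.vL);
  const double sinf = sig(v, c.ths, c.sgs);
  const double ICa = c.gCa * sinf * sinf * (v - c.vCa);
  const double ainf = sig(v, c.tha, c.sga);
  double tgate;
  if (c.lin_r) {
    tgate = r;
  } else {
    const double b = sig(r, c.thb, c.sgb) - c.binf0;
    tgate = b * b;
  }
  const double IT = c.gT * ainf * ainf * ainf * tgate * (v - c.vCa);
  const double IAHP = c.gAHP * (Ca / (Ca + c.k1)) * (v - c.vAHP);

  *dv = (-INa - IK - IL - ICa - IT - IAHP + c.Iapp - isyn + iext) / c.C;
  *dn = c.phin * (sig(v, c.thn, c.sgn) - nn) /
        (c.tn0 + c.tn1 * sig(v, c.thnt, c.sgnt));
  *dh = c.phih * (sig(v, c.thh, c.sgh) - h) /
        (c.th0 + c.th1 * sig(v, c.thht, c.sght));
  *dr = c.phir * (sig(v, c.thr, c.sgr) - r) /
        (c.tr0 + c.tr1 * sig(v, c.thrt, c.sgrt));
  *dCa = c.eps * (-ICa - IT - c.kCa * Ca);
}

static void rhs(const double* y, double* dy, int n, const Cell& stn,
                const Cell& gpe, const Syn& sg, const Syn& gs, double iext) {
  const double* vS = y;            const double* nS = y + n;
  const double* hS = y + 2 * n;    const double* rS = y + 3 * n;
  const double* CaS = y + 4 * n;
  const double* vG = y + 5 * n;    const double* nG = y + 6 * n;
  const double* hG = y + 7 * n;    const double* rG = y + 8 * n;
  const double* CaG = y + 9 * n;
  const double* sS = y + 10 * n;   const double* sG = y + 11 * n;

  for (int i = 0; i < n; ++i) {
    // GPe -> STN: afferents from GPe i-1, i, i+1 on the ring.
    const int im = (i + n - 1) % n, ip = (i + 1) % n;
    const double gates = sG[im] + sG[i] + sG[ip];
    const double isyn = gs.g * (vS[i] - gs.vsyn) * gates;
    cell_deriv(stn, vS[i], nS[i], hS[i], rS[i], CaS[i], isyn, iext,
               dy + i, dy + n + i, dy + 2 * n + i, dy + 3 * n + i,
               dy + 4 * n + i);
  }
  for (int i = 0; i < n; ++i) {
    // STN -> GPe: single like-indexed afferent.
    const double isyn = sg.g * (vG[i] - sg.vsyn) * sS[i];
    cell_deriv(gpe, vG[i], nG[i], hG[i], rG[i], CaG[i], isyn, 0.0,
               dy + 5 * n + i, dy + 6 * n + i, dy + 7 * n + i, dy + 8 * n + i,
               dy + 9 * n + i);
  }
  for (int i = 0; i < n; ++i) {
    const double H = sig(vS[i] - sg.thg, sg.ThgH, sg.sgH);
    dy[10 * n + i] = sg.alpha * H * (1.0 - sS[i]) - sg.beta * sS[i];
  }
  for (int i = 0; i < n; ++i) {
    const double H = sig(vG[i] - gs.thg, gs.ThgH, gs.sgH);
    dy[11 * n + i] = gs.alpha * H * (1.0 - sG[i]) - gs.beta * sG[i];
  }
}

// External input current applied to STN neurons.
//   mode 0: none; mode 1: A sin(2 pi w0 t / 1000);
//   mode 2: A sin(2 pi w0 t / 1000 + xi[k]) with per-step jitter xi;
//   mode 3: externally supplied series ext[k], zero-order hold over the step.
static inline double input_at(int mode, double t, int k, double A, double w0,
                              const double* xi, const double* ext) {
  const double twopi = 6.283185307179586476925286766559;
  switch (mode) {
    case 1: return A * std::sin(twopi * w0 * t / 1000.0);
    case 2: return A * std::sin(twopi * w0 * t / 1000.0 + xi[k]);
    case 3: return ext[k];
    default: return 0.0;
  }
}

// [[Rcpp::export]]
List rk4_integrate_cpp(NumericVector y0, int n, NumericVector stn_par,
                       NumericVector gpe_par, NumericVector syn_sg,
                       NumericVector syn_gs, double dt, int n_steps,
                       int stride, int input_mode, double A, double omega0,
                       NumericVector xi, NumericVector ext, double t0) {
  const Cell stn = unpack_cell(stn_par), gpe = unpack_cell(gpe_par);
  const Syn sg = unpack_syn(syn_sg), gs = unpack_syn(syn_gs);
  const int dim = 12 * n;
  if (y0.size() != dim) stop("state dimension mismatch: expected %d", dim);
  if (input_mode == 2 && xi.size() < n_steps) stop("jitter series shorter than n_steps");
  if (input_mode == 3 && ext.size() < n_steps) stop("external input series shorter than n_steps");

  const int n_rec = n_steps / stride + 1;
  NumericVector time(n_rec), input_rec(n_rec);
  NumericMatrix v_stn(n_rec, n), v_gpe(n_rec, n), r_stn(n_rec, n),
      ca_stn(n_rec, n), s_stn(n_rec, n), s_gpe(n_rec, n), isyn_stn(n_rec, n);

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(dim), k2(dim), k3(dim), k4(dim), tmp(dim);
  const double* xip = xi.size() ? &xi[0] : nullptr;
  const double* extp = ext.size() ? &ext[0] : nullptr;

  int rec = 0;
  for (int step = 0; step <= n_steps; ++step) {
    const double t = t0 + step * dt;
    if (step % stride == 0) {
      // record, with a finiteness check so blow-ups abort informatively
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(y[i]) || !std::isfinite(y[5 * n + i]))
          stop("non-finite membrane potential at t = %.3f ms", t);
        v_stn(rec, i) = y[i];
        v_gpe(rec, i) = y[5 * n + i];
        r_stn(rec, i) = y[3 * n + i];
        ca_stn(rec, i) = y[4 * n + i];
        s_stn(rec, i) = y[10 * n + i];
        s_gpe(rec, i) = y[11 * n + i];
        const int im = (i + n - 1) % n, ip = (i + 1) % n;
        isyn_stn(rec, i) = gs.g * (y[i] - gs.vsyn) *
                           (y[11 * n + im] + y[11 * n + i] + y[11 * n + ip]);
      }
      const int kk = step < n_steps ? step : n_steps - 1;
      time[rec] = t;
      input_rec[rec] = input_at(input_mode, t, kk, A, omega0, xip, extp);
      ++rec;
    }
    if (step == n_steps) break;

    const double i1 = input_at(input_mode, t, step, A, omega0, xip, extp);
    const double i2 = input_at(input_mode, t + 0.5 * dt, step, A, omega0, xip, extp);
    const double i4 = input_at(input_mode, t + dt, step, A, omega0, xip, extp);

    rhs(y.data(), k1.data(), n, stn, gpe, sg, gs, i1);
    for (int j = 0; j < dim; ++j) tmp[j] = y[j] + 0.5 * dt * k1[j];
    rhs(tmp.data(), k2.data(), n, stn, gpe, sg, gs, i2);
    for (int j = 0; j < dim; ++j) tmp[j] = y[j] + 0.5 * dt * k2[j];
    rhs(tmp.data(), k3.data(), n, stn, gpe, sg, gs, i2);
    for (int j = 0; j < dim; ++j) tmp[j] = y[j] + dt * k3[j];
    rhs(tmp.data(), k4.data(), n, stn, gpe, sg, gs, i4);
    for (int j = 0; j < dim; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
  }

  return List::create(
      _["time"] = time, _["v_stn"] = v_stn, _["v_gpe"] = v_gpe,
      _["r_stn"] = r_stn, _["ca_stn"] = ca_stn, _["s_stn"] = s_stn,
      _["s_gpe"] = s_gpe, _["isyn_stn"] = isyn_stn, _["input"] = input_rec,
      _["state_final"] = NumericVector(y.begin(), y.end()));
}

// Single right-hand-side evaluation; exercised by tests against the pure-R
// network_rhs() to pin the compiled and reference implementations together.
// [[Rcpp::export]]
NumericVector network_rhs_cpp(NumericVector y, int n, NumericVector stn_par,
                              NumericVector gpe_par, NumericVector syn_sg,
                              NumericVector syn_gs, double iext) {
  const Cell stn = unpack_cell(stn_par), gpe = unpack_cell(gpe_par);
  const Syn sg = unpack_syn(syn_sg), gs = unpack_syn(syn_gs);
  if (y.size() != 12 * n) stop("state dimension mismatch");
  NumericVector dy(12 * n);
  rhs(&y[0], &dy[0], n, stn, gpe, sg, gs, iext);
  return dy;
}
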