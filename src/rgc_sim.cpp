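// Fixed-step integration of the RGC model. The right-hand side here mirrors
// the pure-R reference implementation (rgc_rhs); the test suite asserts the
// two agree to machine precision. Forward Euler is the primary method,
// classical RK4 the cross-check/reference.
//
// Gating kinetics: canonical HH (rest -65 mV) with small fitted voltage
// offsets on m and n, Connor-Stevens A-current with inactivation midpoint
// -63 mV, Boltzmann L-type activation. These calibrated constants must stay
// in lock-step with default_kinetics() in R/kinetics.R.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pars {
  double Cm, Vrest;
  double gNa, gKdr, gKA, gCaL, gKCa, gL;
  double ENa, EK, ECa, EL, Eexc;
  double gAMPA, gNMDA, EC50A, EC50N;
  double tauAr, tauAd, tauNr, tauNd;
  double eta, gamma, fCa, kN, kL, Carest, tauCa, Kd;
};

Pars unpack(const List& p) {
  Pars q;
  q.Cm = p["Cm"]; q.Vrest = p["Vrest"];
  q.gNa = p["gNa"]; q.gKdr = p["gKdr"]; q.gKA = p["gKA"];
  q.gCaL = p["gCaL"]; q.gKCa = p["gKCa"]; q.gL = p["gL"];
  q.ENa = p["ENa"]; q.EK = p["EK"]; q.ECa = p["ECa"];
  q.EL = p["EL"]; q.Eexc = p["Eexc"];
  q.gAMPA = p["gAMPA"]; q.gNMDA = p["gNMDA"];
  q.EC50A = p["EC50_AMPA"]; q.EC50N = p["EC50_NMDA"];
  q.tauAr = p["tau_AMPA_rise"]; q.tauAd = p["tau_AMPA_decay"];
  q.tauNr = p["tau_NMDA_rise"]; q.tauNd = p["tau_NMDA_decay"];
  q.eta = p["eta"]; q.gamma = p["gamma"]; q.fCa = p["fCa"];
  q.kN = p["kCa_NMDA"]; q.kL = p["kCa_CaL"];
  q.Carest = p["Ca_rest"]; q.tauCa = p["tau_Ca"]; q.Kd = p["Kd_KCa"];
  return q;
}

// x/(exp(x/y)-1), continuous at x = 0
inline double vtrap(double x, double y) {
  double r = x / y;
  if (std::fabs(r) < 1e-6) return y * (1.0 - 0.5 * r);
  return x / std::expm1(r);
}

// state layout: 0 V, 1 m, 2 h, 3 n, 4 a, 5 b, 6 sCaL, 7 sAMPA, 8 sNMDA, 9 Ca
const char* kStateNames[10] =
  {"V", "m", "h", "n", "a", "b", "sCaL", "sAMPA", "sNMDA", "Ca"};

struct Aux { double IAMPA, INMDA, B; };

inline void derivs(const double* y, double glu, double mg, const Pars& p,
                   double* dy, Aux* aux) {
  const double V = y[0], m = y[1], h = y[2], n = y[3], a = y[4], b = y[5],
    sCaL = y[6], sA = y[7], sN = y[8], Ca = y[9];

  // intrinsic currents
  const double INa  = p.gNa * m * m * m * h * (V - p.ENa);
  const double IKdr = p.gKdr * n * n * n * n * (V - p.EK);
  const double IKA  = p.gKA * a * a * a * b * (V - p.EK);
  const double ICaL = p.gCaL * sCaL * sCaL * (V - p.ECa);
  const double kca  = Ca * Ca / (Ca * Ca + p.Kd * p.Kd);
  const double IKCa = p.gKCa * kca * (V - p.EK);
  const double IL   = p.gL * (V - p.EL);

  // synaptic currents with Jahr-Stevens Mg block
  const double B = 1.0 / (1.0 + p.eta * mg * std::exp(-p.gamma * V));
  const double IAMPA = p.gAMPA * sA * (V - p.Eexc);
  const double INMDA = p.gNMDA * sN * B * (V - p.Eexc);

  dy[0] = -(INa + IKdr + IKA + ICaL + IKCa + IL + IAMPA + INMDA) / p.Cm;

  // HH sodium/potassium gates (rest -65 mV)
  const double Vm = V - 0.17;
  const double am = 0.1 * vtrap(-(Vm + 40.0), 10.0);
  const double bm = 4.0 * std::exp(-(Vm + 65.0) / 18.0);
  const double Vn = V - 1.1;
  const double ah = 0.07 * std::exp(-(V + 65.0) / 20.0);
  const double bh = 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0));
  const double an = 0.01 * vtrap(-(Vn + 55.0), 10.0);
  const double bn = 0.125 * std::exp(-(Vn + 65.0) / 80.0);
  dy[1] = am * (1.0 - m) - bm * m;
  dy[2] = ah * (1.0 - h) - bh * h;
  dy[3] = an * (1.0 - n) - bn * n;

  // Connor-Stevens A-current (inactivation midpoint -63 mV)
  double ainf = std::cbrt(0.0761 * std::exp((V + 94.22) / 31.84) /
                          (1.0 + std::exp((V + 1.17) / 28.93)));
  if (ainf > 1.0) ainf = 1.0;  // CS formula marginally exceeds 1 above ~+55 mV
  const double taua = 0.3632 + 1.158 / (1.0 + std::exp((V + 55.96) / 20.12));
  const double bq = 1.0 / (1.0 + std::exp((V + 63.0) / 14.54));
  const double binf = bq * bq * bq * bq;
  const double taub = 1.24 + 2.678 / (1.0 + std::exp((V + 50.0) / 16.027));
  dy[4] = (ainf - a) / taua;
  dy[5] = (binf - b) / taub;

  // L-type Ca activation (Boltzmann, half-activation -5 mV, tau 1.75 ms)
  const double sinf = 1.0 / (1.0 + std::exp(-(V + 5.0) / 7.0));
  dy[6] = (sinf - sCaL) / 1.75;

  // synaptic gates
  const double actA = glu / (glu + p.EC50A);
  const double actN = glu / (glu + p.EC50N);
  dy[7] = actA * (1.0 - sA) / p.tauAr - sA / p.tauAd;
  dy[8] = actN * (1.0 - sN) / p.tauNr - sN / p.tauNd;

  // calcium pool
  dy[9] = -p.kN * p.fCa * INMDA - p.kL * ICaL - (Ca - p.Carest) / p.tauCa;

  if (aux) { aux->IAMPA = IAMPA; aux->INMDA = INMDA; aux->B = B; }
}

struct Stim {
  double start, end, period, width, amp;
  std::vector<double> mg_t, mg_v;
};

Stim unpack_stim(const List& proto) {
  Stim s;
  s.start = proto["stim_start"]; s.end = proto["stim_end"];
  s.period = proto["period"]; s.width = proto["pulse_width"];
  s.amp = proto["pulse_amp"];
  DataFrame mgs = as<DataFrame>(proto["mg_schedule"]);
  NumericVector mt = mgs["time"], mv = mgs["mg"];
  s.mg_t.assign(mt.begin(), mt.end());
  s.mg_v.assign(mv.begin(), mv.end());
  return s;
}

inline double glu_at(const Stim& s, double t) {
  if (t < s.start || t >= s.end) return 0.0;
  double k = std::floor((t - s.start) / s.period + 1e-9);
  double tk = s.start + k * s.period;
  if ((t - tk) < s.width - 1e-9 && tk + s.width <= s.end + 1e-9) return s.amp;
  return 0.0;
}

inline double mg_at_t(const Stim& s, double t) {
  double v = s.mg_v[0];
  for (size_t i = 1; i < s.mg_t.size(); ++i) {
    if (s.mg_t[i] <= t + 1e-9) v = s.mg_v[i]; else break;
  }
  return v;
}

// clamp gating/synaptic variables to [0,1]; tolerate only tiny overshoot
inline void clamp_gates(double* y, double t) {
  for (int j = 1; j <= 8; ++j) {
    if (y[j] < 0.0) {
      if (y[j] < -1e-6)
        stop("gating variable '%s' left [0,1] by more than 1e-6 at t = %g ms",
             kStateNames[j], t);
      y[j] = 0.0;
    } else if (y[j] > 1.0) {
      if (y[j] > 1.0 + 1e-6)
        stop("gating variable '%s' left [0,1] by more than 1e-6 at t = %g ms",
             kStateNames[j], t);
      y[j] = 1.0;
    }
  }
  if (y[9] < 0.0) y[9] = 0.0;
}

inline void check_blowup(const double* y, double t) {
  for (int j = 0; j < 10; ++j)
    if (!std::isfinite(y[j]))
      stop("numeric blowup: '%s' became non-finite at t = %g ms",
           kStateNames[j], t);
  if (std::fabs(y[0]) > 200.0)
    stop("numeric blowup: |V| > 200 mV at t = %g ms", t);
  if (y[9] > 1000.0)
    stop("numeric blowup: Ca > 1000 uM at t = %g ms", t);
}

} // namespace

// [[Rcpp::export]]
List integrate_cpp(NumericVector init, List pars, List proto,
                   double dt, double t_end, std::string method,
                   int record_stride) {
  if (init.size() != 10) stop("initial state must have 10 elements");
  if (dt <= 0 || t_end <= 0) stop("dt and t_end must be > 0");
  if (record_stride < 1) stop("record_stride must be >= 1");
  const Pars p = unpack(pars);
  const Stim st = unpack_stim(proto);
  const bool rk4 = (method == "rk4");
  if (!rk4 && method != "euler") stop("unknown method '%s'", method.c_str());

  const long nsteps = (long)std::llround(t_end / dt);
  const long nrec = nsteps / record_stride + 1;

  NumericMatrix S(nrec, 10);
  NumericVector tv(nrec), gv(nrec), mv(nrec), ia(nrec), in(nrec), bb(nrec);

  double y[10], k1[10], k2[10], k3[10], k4[10], tmp[10];
  for (int j = 0; j < 10; ++j) y[j] = init[j];

  long r = 0;
  for (long i = 0; i <= nsteps; ++i) {
    const double t = i * dt;
    if (i % record_stride == 0) {
      const double glu = glu_at(st, t), mg = mg_at_t(st, t);
      Aux aux; double dy[10];
      derivs(y, glu, mg, p, dy, &aux);
      tv[r] = t; gv[r] = glu; mv[r] = mg;
      ia[r] = aux.IAMPA; in[r] = aux.INMDA; bb[r] = aux.B;
      for (int j = 0; j < 10; ++j) S(r, j) = y[j];
      ++r;
    }
    if (i == nsteps) break;

    if (!rk4) {
      derivs(y, glu_at(st, t), mg_at_t(st, t), p, k1, nullptr);
      for (int j = 0; j < 10; ++j) y[j] += dt * k1[j];
    } else {
      const double th = t + 0.5 * dt, t1 = t + dt;
      derivs(y, glu_at(st, t), mg_at_t(st, t), p, k1, nullptr);
      for (int j = 0; j < 10; ++j) tmp[j] = y[j] + 0.5 * dt * k1[j];
      derivs(tmp, glu_at(st, th), mg_at_t(st, th), p, k2, nullptr);
      for (int j = 0; j < 10; ++j) tmp[j] = y[j] + 0.5 * dt * k2[j];
      derivs(tmp, glu_at(st, th), mg_at_t(st, th), p, k3, nullptr);
      for (int j = 0; j < 10; ++j) tmp[j] = y[j] + dt * k3[j];
      derivs(tmp, glu_at(st, t1), mg_at_t(st, t1), p, k4, nullptr);
      for (int j = 0; j < 10; ++j)
        y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    }
    clamp_gates(y, t + dt);
    check_blowup(y, t + dt);
    if (i % 50000 == 0) Rcpp::checkUserInterrupt();
  }

  colnames(S) = CharacterVector::create("V", "m", "h", "n", "a", "b",
                                        "sCaL", "sAMPA", "sNMDA", "Ca");
  return List::create(_["time"] = tv, _["state"] = S, _["Glu"] = gv,
                      _["Mg"] = mv, _["IAMPA"] = ia, _["INMDA"] = in,
                      _["B"] = bb);
}

// Single right-hand-side evaluation, exposed for cross-checking the compiled
// model against the pure-R reference implementation.
// [[Rcpp::export]]
List rhs_cpp(NumericVector state, List pars, double glu, double mg) {
  if (state.size() != 10) stop("state must have 10 elements");
  const Pars p = unpack(pars);
  double y[10], dy[10];
  for (int j = 0; j < 10; ++j) y[j] = state[j];
  Aux aux;
  derivs(y, glu, mg, p, dy, &aux);
  NumericVector d(10);
  for (int j = 0; j < 10; ++j) d[j] = dy[j];
  d.names() = CharacterVector::create("V", "m", "h", "n", "a", "b",
                                      "sCaL", "sAMPA", "sNMDA", "Ca");
  return List::create(_["deriv"] = d, _["IAMPA"] = aux.IAMPA,
                      _["INMDA"] = aux.INMDA, _["B"] = aux.B);
}
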