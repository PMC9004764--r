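#include <Rcpp.h>
using namespace Rcpp;

// Death-rate forms for the sensitive compartment.
// 0 = exponential approach to k_d, 1 = linear ramp over t_d, 2 = constant.

static inline double krate(double t, int form, double kd, double td, double g0) {
  switch (form) {
  case 0:
    return kd - (g0 + kd) * std::exp(-t / td);
  case 1:
    return (t < td) ? kd - (g0 + kd) * (1.0 - t / td) : kd;
  default:
    return kd;
  }
}

// Cumulative kill kernel K(t) = int_0^t k(s) ds; analytic for all forms,
// so S(t) = S0 * exp(-K(t)) is evaluated exactly.
static inline double cumk(double t, int form, double kd, double td, double g0) {
  switch (form) {
  case 0:
    return kd * t - (g0 + kd) * td * (1.0 - std::exp(-t / td));
  case 1:
    if (t <= td)
      return kd * t - (g0 + kd) * (t - t * t / (2.0 * td));
    return kd * t - (g0 + kd) * td * 0.5;
  default:
    return kd * t;
  }
}

// [[Rcpp::export(name = ".sim_rs_cpp")]]
NumericMatrix sim_rs_cpp(NumericVector times, double fr, double gr, double tr,
                         double kd, double td, double g0, double Nmax,
                         double N0, int k_form, double hmax) {
  const int n = times.size();
  NumericMatrix out(n, 3); // S, R, N
  const double S0 = (1.0 - fr) * N0;
  double R = fr * N0;
  double tcur = times[0];

  for (int i = 0; i < n; ++i) {
    double tnext = times[i];
    while (tcur < tnext) {
      double tstop = tnext;
      // resolve the Heaviside gate exactly at t_r
      if (tcur < tr && tr < tnext) tstop = tr;
      double span = tstop - tcur;
      int nsub = (int)std::ceil(span / hmax);
      if (nsub < 1) nsub = 1;
      double h = span / nsub;
      for (int j = 0; j < nsub; ++j) {
        double t0 = tcur + j * h;
        if (t0 + h <= tr) { // growth gated off (H(0) = 1, so t >= tr grows)
          continue;
        }
        double S0t = S0 * std::exp(-cumk(t0, k_form, kd, td, g0));
        double Smid = S0 * std::exp(-cumk(t0 + 0.5 * h, k_form, kd, td, g0));
        double S1t = S0 * std::exp(-cumk(t0 + h, k_form, kd, td, g0));
        double k1 = gr * R * (1.0 - (R + S0t) / Nmax);
        double R2 = R + 0.5 * h * k1;
        double k2 = gr * R2 * (1.0 - (R2 + Smid) / Nmax);
        double R3 = R + 0.5 * h * k2;
        double k3 = gr * R3 * (1.0 - (R3 + Smid) / Nmax);
        double R4 = R + h * k3;
        double k4 = gr * R4 * (1.0 - (R4 + S1t) / Nmax);
        R += h / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
        if (R < 0.0) R = 0.0;
      }
      tcur = tstop;
    }
    double S = S0 * std::exp(-cumk(tcur, k_form, kd, td, g0));
    out(i, 0) = S;
    out(i, 1) = R;
    out(i, 2) = S + R;
  }
  return out;
}

// [[Rcpp::export(name = ".death_rate_cpp")]]
NumericVector death_rate_cpp(NumericVector t, double kd, double td, double g0,
                             int k_form) {
  const int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = krate(t[i], k_form, kd, td, g0);
  return out;
}
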