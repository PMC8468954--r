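#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// BAOAB Langevin propagation of the reduced two-bridge model.
// Coordinates: x = (r1, R1, r2, R2) in Angstrom, velocities in A/fs.
// Energies in kcal/mol internally; the conversion to the integrator's
// amu A^2 fs^-2 unit happens through f2a = 4.184e-4.
// Noise is drawn from R's RNG (norm_rand) in the fixed order
// r1, R1, r2, R2 each step, so seeded runs are exactly reproducible.

static const double F2A = 4.184e-4; // kcal/mol -> amu A^2 fs^-2

struct ModelPar {
  double D_d, D_a, a_d, a_a, rho, k_R, R_0, lambda_c, m_H, m_R;
};

static inline void forces(const ModelPar &p, const double *x, double *F,
                          double *energy) {
  double E = 0.0;
  double q[2];
  for (int b = 0; b < 2; ++b) {
    double r = x[2 * b], R = x[2 * b + 1];
    double ed = std::exp(-p.a_d * (r - p.rho));
    double ea = std::exp(-p.a_a * (R - r - p.rho));
    E += p.D_d * (1 - ed) * (1 - ed) + p.D_a * (1 - ea) * (1 - ea)
       + 0.5 * p.k_R * (R - p.R_0) * (R - p.R_0);
    double dVdr = 2 * p.D_d * p.a_d * ed * (1 - ed)
                - 2 * p.D_a * p.a_a * ea * (1 - ea);
    double dVdR = 2 * p.D_a * p.a_a * ea * (1 - ea) + p.k_R * (R - p.R_0);
    F[2 * b] = -dVdr;
    F[2 * b + 1] = -dVdR;
    q[b] = r - R / 2.0;
  }
  E += p.lambda_c * q[0] * q[1];
  // coupling gradients: dq/dr = 1, dq/dR = -1/2
  F[0] += -p.lambda_c * q[1];
  F[1] += 0.5 * p.lambda_c * q[1];
  F[2] += -p.lambda_c * q[0];
  F[3] += 0.5 * p.lambda_c * q[0];
  *energy = E;
}

// [[Rcpp::export]]
List langevin_baoab_cpp(NumericVector state0, List par, int n_equil,
                        int n_prod, int stride, double dt, double gamma,
                        double kT_kcal) {
  ModelPar p;
  p.D_d = par["D_d"]; p.D_a = par["D_a"];
  p.a_d = par["a_d"]; p.a_a = par["a_a"];
  p.rho = par["rho"]; p.k_R = par["k_R"]; p.R_0 = par["R_0"];
  p.lambda_c = par["lambda_c"]; p.m_H = par["m_H"]; p.m_R = par["m_R"];

  const double m[4] = {p.m_H, p.m_R, p.m_H, p.m_R};
  const double kT = kT_kcal * F2A;
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);
  double sig[4];
  for (int i = 0; i < 4; ++i) sig[i] = std::sqrt(kT / m[i]) * c2;

  double x[4], v[4], F[4], E;
  for (int i = 0; i < 4; ++i) { x[i] = state0[i]; v[i] = state0[i + 4]; }
  forces(p, x, F, &E);

  const int n_frames = n_prod / stride + 1;
  NumericMatrix out(n_frames, 8);
  NumericVector time(n_frames);
  int frame = 0;
  const int n_total = n_equil + n_prod;

  // store the state at the start of production (step index n_equil)
  auto maybe_store = [&](int step) {
    if (step >= n_equil && (step - n_equil) % stride == 0 && frame < n_frames) {
      for (int i = 0; i < 4; ++i) {
        out(frame, i) = x[i];
        out(frame, i + 4) = v[i];
      }
      time[frame] = step * dt;
      ++frame;
    }
  };
  if (n_equil == 0) maybe_store(0);

  for (int step = 1; step <= n_total; ++step) {
    // B: half kick
    for (int i = 0; i < 4; ++i) v[i] += 0.5 * dt * F[i] * F2A / m[i];
    // A: half drift
    for (int i = 0; i < 4; ++i) x[i] += 0.5 * dt * v[i];
    // O: Ornstein-Uhlenbeck, exact
    for (int i = 0; i < 4; ++i) v[i] = c1 * v[i] + sig[i] * norm_rand();
    // A: half drift
    for (int i = 0; i < 4; ++i) x[i] += 0.5 * dt * v[i];
    // B: half kick with fresh forces
    forces(p, x, F, &E);
    for (int i = 0; i < 4; ++i) v[i] += 0.5 * dt * F[i] * F2A / m[i];

    bool bad = !std::isfinite(E);
    for (int i = 0; i < 4 && !bad; ++i)
      bad = !std::isfinite(x[i]) || std::fabs(x[i]) > 1e6;
    if (bad)
      return List::create(_["ok"] = false, _["step"] = step);
    maybe_store(step);
  }

  return List::create(_["ok"] = true, _["frames"] = out, _["time"] = time);
}
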