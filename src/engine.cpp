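// Core surface-hopping engine: Langevin (GJF) nuclear integration on the
// active adiabatic surface, substep amplitude propagation with overlap-derived
// couplings, fewest-switches hop selection with parallel velocity rescaling,
// and energy-based decoherence.  Counter-based RNG so any run segment can be
// resumed bit-for-bit from (seed, counter).
//
// Units: reduced model units throughout, kB = hbar = m = 1.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// counter-based RNG (splitmix64 stream)

static inline uint64_t sm64(uint64_t seed, uint64_t n) {
  uint64_t z = seed + (n + 1ULL) * 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double unif01(uint64_t seed, uint64_t n) {
  // in (0, 1), 53-bit resolution
  return ((sm64(seed, n) >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

static inline double gauss1(uint64_t seed, uint64_t n) {
  // one Box-Muller value per counter (consumes counters 2n, 2n+1)
  double u1 = unif01(seed, 2ULL * n);
  double u2 = unif01(seed, 2ULL * n + 1ULL);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

// [[Rcpp::export]]
double cpp_derive_seed(double base, double id) {
  // stable substream derivation (shot id -> child seed), result < 2^53
  uint64_t s = sm64(static_cast<uint64_t>(base), static_cast<uint64_t>(id));
  return static_cast<double>(s >> 11);
}

// ---------------------------------------------------------------------------
// analytic diabatic models (2 states, 3 Cartesian coordinates)

struct ModelP {
  int type;        // 0 = avoided crossing, 1 = conical intersection
  double p[10];
};

// H = {V11, V22, V12}; G[c][i] = d(H[c])/d(r[i])
static inline void eval_diab(const ModelP& m, const double* r,
                             double H[3], double G[3][3]) {
  const double x = r[0], y = r[1], z = r[2];
  if (m.type == 0) {
    const double Vc = m.p[0], x0 = m.p[1], eps = m.p[2], kp = m.p[3];
    const double inv2 = 1.0 / (x0 * x0);
    const double perp = 0.5 * kp * (y * y + z * z);
    H[0] = eps * (x + x0) * (x + x0) * inv2 + perp;
    H[1] = eps * (x - x0) * (x - x0) * inv2 + perp;
    H[2] = Vc;
    G[0][0] = 2.0 * eps * (x + x0) * inv2; G[0][1] = kp * y; G[0][2] = kp * z;
    G[1][0] = 2.0 * eps * (x - x0) * inv2; G[1][1] = kp * y; G[1][2] = kp * z;
    G[2][0] = 0.0; G[2][1] = 0.0; G[2][2] = 0.0;
  } else {
    const double a = m.p[0], b = m.p[1], c = m.p[2], d = m.p[3],
                 e = m.p[4], k = m.p[5], f = m.p[6];
    const double u = x - y, v = x + y, id2 = 1.0 / (d * d);
    H[0] = a * (u - d) * (u - d) * id2 + b * (v - d) * (v - d) * id2 + c * e * z * z;
    H[1] = a * (u + d) * (u + d) * id2 + b * (v + d) * (v + d) * id2 + c * e * z * z;
    const double g = std::exp(f * (1.0 - u * u));
    H[2] = k * v * g;
    const double au1 = 2.0 * a * (u - d) * id2, bv1 = 2.0 * b * (v - d) * id2;
    const double au2 = 2.0 * a * (u + d) * id2, bv2 = 2.0 * b * (v + d) * id2;
    G[0][0] = au1 + bv1;  G[0][1] = -au1 + bv1;  G[0][2] = 2.0 * c * e * z;
    G[1][0] = au2 + bv2;  G[1][1] = -au2 + bv2;  G[1][2] = 2.0 * c * e * z;
    G[2][0] = k * g * (1.0 - 2.0 * f * u * v);
    G[2][1] = k * g * (1.0 + 2.0 * f * u * v);
    G[2][2] = 0.0;
  }
}

// adiabatize a 2x2 symmetric H = [[V11,V12],[V12,V22]]
// E ascending; U columns = eigenvectors, largest-|component| positive.
static inline void adiab2(const double H[3], double E[2], double U[4]) {
  const double mean = 0.5 * (H[0] + H[1]);
  const double delta = 0.5 * (H[0] - H[1]);
  const double w = std::sqrt(delta * delta + H[2] * H[2]);
  E[0] = mean - w;
  E[1] = mean + w;
  if (w < 1e-300) { U[0] = 1.0; U[1] = 0.0; U[2] = 0.0; U[3] = 1.0; return; }
  // lower eigenvector: (-V12, V11 - E0) or (V22 - E0, -V12), whichever larger
  double v1a = -H[2], v2a = H[0] - E[0];
  double v1b = H[1] - E[0], v2b = -H[2];
  double na = v1a * v1a + v2a * v2a, nb = v1b * v1b + v2b * v2b;
  double v1, v2;
  if (na >= nb) { v1 = v1a; v2 = v2a; } else { v1 = v1b; v2 = v2b; }
  const double nn = std::sqrt(v1 * v1 + v2 * v2);
  v1 /= nn; v2 /= nn;
  // sign convention per column
  if (std::fabs(v1) >= std::fabs(v2)) { if (v1 < 0) { v1 = -v1; v2 = -v2; } }
  else                                { if (v2 < 0) { v1 = -v1; v2 = -v2; } }
  U[0] = v1; U[1] = v2;                 // column 1 (lower)
  double u1 = -v2, u2 = v1;             // orthogonal column 2 (upper)
  if (std::fabs(u1) >= std::fabs(u2)) { if (u1 < 0) { u1 = -u1; u2 = -u2; } }
  else                                { if (u2 < 0) { u1 = -u1; u2 = -u2; } }
  U[2] = u1; U[3] = u2;
}

// Hellmann-Feynman adiabatic gradients; falls back to the diabatic diagonal
// gradients within gap < 1e-10 of an exact degeneracy.
static inline void adiab_grads(const double G[3][3], const double U[4],
                               double gap, double F[2][3]) {
  if (gap < 1e-10) {
    for (int i = 0; i < 3; ++i) { F[0][i] = G[0][i]; F[1][i] = G[1][i]; }
    return;
  }
  for (int s = 0; s < 2; ++s) {
    const double a = U[2 * s], b = U[2 * s + 1];
    for (int i = 0; i < 3; ++i)
      F[s][i] = a * a * G[0][i] + b * b * G[1][i] + 2.0 * a * b * G[2][i];
  }
}

// ---------------------------------------------------------------------------
// engine state

struct EngState {
  double x[3], v[3];
  int active;                     // 0-based
  std::complex<double> c[2];
  double time;
  // electronic bookkeeping at the current geometry
  double E[2];                    // adiabatic energies
  double U[4];                    // phase-tracked transformation (col-major)
  double F[2][3];                 // adiabatic gradients (both states)
};

static void refresh_electronic(const ModelP& m, EngState& st, bool keep_phase) {
  double H[3], G[3][3], Unew[4];
  eval_diab(m, st.x, H, G);
  adiab2(H, st.E, Unew);
  if (keep_phase) {
    // align new convention-U with previously tracked U (persistent phases)
    for (int col = 0; col < 2; ++col) {
      double dot = st.U[2 * col] * Unew[2 * col] + st.U[2 * col + 1] * Unew[2 * col + 1];
      if (dot < 0) { Unew[2 * col] = -Unew[2 * col]; Unew[2 * col + 1] = -Unew[2 * col + 1]; }
    }
    // trivial crossing: the aligned overlap can come out improper
    // (det < 0, diagonal ~ 0); flip one column so S is a proper rotation
    // and the overlap-derived coupling performs the full diabatic swap
    double S00 = st.U[0] * Unew[0] + st.U[1] * Unew[1];
    double S01 = st.U[0] * Unew[2] + st.U[1] * Unew[3];
    double S10 = st.U[2] * Unew[0] + st.U[3] * Unew[1];
    double S11 = st.U[2] * Unew[2] + st.U[3] * Unew[3];
    if (S00 * S11 - S01 * S10 < 0) { Unew[2] = -Unew[2]; Unew[3] = -Unew[3]; }
  }
  st.U[0] = Unew[0]; st.U[1] = Unew[1]; st.U[2] = Unew[2]; st.U[3] = Unew[3];
  adiab_grads(G, st.U, st.E[1] - st.E[0], st.F);
}

// export/import amplitudes in the deterministic convention gauge so that a
// resumed segment reproduces the original run exactly
static void gauge_to_convention(const ModelP& m, const EngState& st,
                                std::complex<double> cout[2]) {
  double H[3], G[3][3], E[2], Uc[4];
  eval_diab(m, st.x, H, G);
  adiab2(H, E, Uc);
  for (int col = 0; col < 2; ++col) {
    double dot = st.U[2 * col] * Uc[2 * col] + st.U[2 * col + 1] * Uc[2 * col + 1];
    cout[col] = (dot < 0) ? -st.c[col] : st.c[col];
  }
}

// ---------------------------------------------------------------------------
// event specification (crossings / region entries over a linear collective
// variable cv = w . x, with an allowed electronic-state mask)

struct EventSpec {
  double w[3], level;
  int dir;          // +1: outward/toward-B side is cv increasing
  int mask;         // bit s set => adiabatic state s allowed (0-based)
  int type;         // 0 record crossing, 1 stop on crossing,
                    // 2 stop on region entry, 3 record in-region snapshot
  int every;        // for type 3: sampling period in steps
};

static inline double cvval(const EventSpec& ev, const double* x) {
  return ev.w[0] * x[0] + ev.w[1] * x[1] + ev.w[2] * x[2];
}

static inline bool state_ok(const EventSpec& ev, int s) {
  return (ev.mask >> s) & 1;
}

static inline bool in_region(const EventSpec& ev, const double* x, int s) {
  return ev.dir * (cvval(ev, x) - ev.level) >= 0 && state_ok(ev, s);
}

// ---------------------------------------------------------------------------
// one full TSH step; returns hop record flags via out-params

struct StepDiag {
  double max_norm_err = 0.0;
  long n_acc = 0, n_frust = 0;
};

struct HopRec { long step; double time; int from, to, frustrated; };

static void tsh_step(const ModelP& m, EngState& st,
                     double T, double gamma, double dt, int substeps, double C,
                     bool electronic,
                     uint64_t seed_n, uint64_t& ctr_n,
                     uint64_t seed_h, uint64_t& ctr_h,
                     const double* inj_noise,  // 3 values or nullptr
                     const double* inj_unif,   // 1 value or nullptr
                     StepDiag& diag, std::vector<HopRec>* hops, long step_idx) {
  const double half = 0.5 * gamma * dt;
  const double bcoef = 1.0 / (1.0 + half);
  const double acoef = (1.0 - half) * bcoef;
  const double sig = std::sqrt(2.0 * gamma * T * dt);

  double xi[3];
  for (int i = 0; i < 3; ++i)
    xi[i] = inj_noise ? inj_noise[i] : sig * gauss1(seed_n, ctr_n + i);
  if (!inj_noise) ctr_n += 3;

  const double E_old[2] = { st.E[0], st.E[1] };
  double F0[3] = { -st.F[st.active][0], -st.F[st.active][1], -st.F[st.active][2] };

  // GJF position update
  for (int i = 0; i < 3; ++i)
    st.x[i] += bcoef * dt * st.v[i] + 0.5 * bcoef * dt * dt * F0[i]
             + 0.5 * bcoef * dt * xi[i];

  // electronic structure at the new geometry (overlap sign fix = phase corr.)
  double U_old[4] = { st.U[0], st.U[1], st.U[2], st.U[3] };
  refresh_electronic(m, st, true);

  // GJF velocity update with the force of the (old) active surface
  double F1[3] = { -st.F[st.active][0], -st.F[st.active][1], -st.F[st.active][2] };
  for (int i = 0; i < 3; ++i)
    st.v[i] = acoef * st.v[i] + 0.5 * dt * (acoef * F0[i] + F1[i]) + bcoef * xi[i];

  if (!electronic) { st.time += dt; return; }   // plain adiabatic Langevin

  // overlap and overlap-derived coupling K = logm(S)/dt (2x2 rotation angle)
  double S00 = U_old[0] * st.U[0] + U_old[1] * st.U[1];
  double S01 = U_old[0] * st.U[2] + U_old[1] * st.U[3];
  double S10 = U_old[2] * st.U[0] + U_old[3] * st.U[1];
  double S11 = U_old[2] * st.U[2] + U_old[3] * st.U[3];
  const double theta = std::atan2(S10 - S01, S00 + S11);
  const double kappa = theta / dt;

  // substep propagator: R = prod_j expm((-i diag(H_j) - K) dtau)
  const double dtau = dt / substeps;
  std::complex<double> R00(1, 0), R01(0, 0), R10(0, 0), R11(1, 0);
  const std::complex<double> I(0, 1);
  for (int j = 0; j < substeps; ++j) {
    const double frac = (j + 0.5) / substeps;
    const double h0 = E_old[0] + frac * (st.E[0] - E_old[0]);
    const double h1 = E_old[1] + frac * (st.E[1] - E_old[1]);
    const double mu = 0.5 * (h0 + h1) * dtau;
    const double del = 0.5 * (h0 - h1);
    const double w = std::sqrt(del * del + kappa * kappa);
    const double wt = w * dtau;
    const double cw = std::cos(wt);
    const double sw = (wt < 1e-12) ? dtau : std::sin(wt) / w;  // sin(wt)/w
    const std::complex<double> ph = std::exp(-I * mu);
    // M = ph * (cw*I2 + sw * [[-i del, kappa],[-kappa, i del]])
    const std::complex<double> M00 = ph * (cw - I * del * sw);
    const std::complex<double> M01 = ph * (kappa * sw);
    const std::complex<double> M10 = ph * (-kappa * sw);
    const std::complex<double> M11 = ph * (cw + I * del * sw);
    std::complex<double> N00 = M00 * R00 + M01 * R10;
    std::complex<double> N01 = M00 * R01 + M01 * R11;
    std::complex<double> N10 = M10 * R00 + M11 * R10;
    std::complex<double> N11 = M10 * R01 + M11 * R11;
    R00 = N00; R01 = N01; R10 = N10; R11 = N11;
  }
  const std::complex<double> c_old[2] = { st.c[0], st.c[1] };
  st.c[0] = R00 * c_old[0] + R01 * c_old[1];
  st.c[1] = R10 * c_old[0] + R11 * c_old[1];

  const double norm = std::norm(st.c[0]) + std::norm(st.c[1]);
  const double nerr = std::fabs(norm - 1.0);
  if (nerr > diag.max_norm_err) diag.max_norm_err = nerr;

  // fewest-switches hop probability (active state beta)
  const int beta = st.active;
  const int alpha = 1 - beta;
  const std::complex<double> Rbb = (beta == 0) ? R00 : R11;
  const std::complex<double> Rab = (beta == 0) ? R10 : R01;  // R[alpha,beta]
  double P = 0.0;
  const double pb_old = std::norm(c_old[beta]);
  if (pb_old > 1e-15) {
    const double fac1 = 1.0 - std::norm(st.c[beta]) / pb_old;
    if (fac1 > 0.0) {
      const double num = std::real(st.c[alpha] * std::conj(Rab) * std::conj(c_old[beta]));
      const double den = pb_old - std::real(st.c[beta] * std::conj(Rbb) * std::conj(c_old[beta]));
      if (den > 1e-300) P = fac1 * num / den;
    }
  }
  if (P < 0.0) P = 0.0;
  if (P > 1.0) P = 1.0;

  const double r = inj_unif ? *inj_unif : unif01(seed_h, ctr_h);
  if (!inj_unif) ctr_h += 1;

  if (r < P) {
    // attempt hop beta -> alpha with parallel velocity rescaling
    const double ekin = 0.5 * (st.v[0] * st.v[0] + st.v[1] * st.v[1] + st.v[2] * st.v[2]);
    const double dE = st.E[alpha] - st.E[beta];
    if (ekin + 1e-300 < dE) {
      diag.n_frust++;
      if (hops) hops->push_back({ step_idx, st.time + dt, beta, alpha, 1 });
    } else {
      const double scale = (ekin > 0.0) ? std::sqrt((ekin - dE) / ekin) : 1.0;
      st.v[0] *= scale; st.v[1] *= scale; st.v[2] *= scale;
      st.active = alpha;
      diag.n_acc++;
      if (hops) hops->push_back({ step_idx, st.time + dt, beta, alpha, 0 });
    }
  }

  // energy-based decoherence (after the hop decision)
  const int b2 = st.active;
  const double ekin2 = 0.5 * (st.v[0] * st.v[0] + st.v[1] * st.v[1] + st.v[2] * st.v[2]);
  const int a2 = 1 - b2;
  const double damp = std::exp(-dt * std::fabs(st.E[a2] - st.E[b2]) * ekin2 / (ekin2 + C));
  st.c[a2] *= damp;
  const double pb = std::norm(st.c[b2]);
  if (pb > 1e-15) {
    const double pa = std::norm(st.c[a2]);
    st.c[b2] *= std::sqrt((1.0 - pa) / pb);
  }
  st.time += dt;
}

// ---------------------------------------------------------------------------
// main runner

static ModelP parse_model(const List& model) {
  ModelP m;
  m.type = as<int>(model["type"]);
  NumericVector p = model["params"];
  for (int i = 0; i < 10; ++i) m.p[i] = (i < p.size()) ? p[i] : 0.0;
  return m;
}

// state vector layout (length 11): x,y,z, vx,vy,vz, active(0-based),
// Re c1, Im c1, Re c2, Im c2   (amplitudes in the convention gauge)
// [[Rcpp::export]]
List cpp_run_tsh(NumericVector state, double time0, List model, List thermo,
                 double n_steps, double stride, NumericMatrix events,
                 double max_record, double seed_noise, double seed_hop,
                 double noise_counter, double hop_counter,
                 bool record_hops,
                 Nullable<NumericMatrix> injected_noise = R_NilValue,
                 Nullable<NumericVector> injected_uniforms = R_NilValue) {
  ModelP m = parse_model(model);
  const double T = as<double>(thermo["temperature"]);
  const double gamma = as<double>(thermo["friction"]);
  const double dt = as<double>(thermo["dt"]);
  const int substeps = as<int>(thermo["substeps"]);
  const double C = as<double>(thermo["decoherence"]);
  const bool electronic = thermo.containsElementNamed("hopping")
    ? as<bool>(thermo["hopping"]) : true;

  EngState st;
  for (int i = 0; i < 3; ++i) { st.x[i] = state[i]; st.v[i] = state[3 + i]; }
  st.active = static_cast<int>(state[6]);
  st.c[0] = std::complex<double>(state[7], state[8]);
  st.c[1] = std::complex<double>(state[9], state[10]);
  st.time = time0;
  refresh_electronic(m, st, false);   // convention gauge at segment start

  std::vector<EventSpec> evs;
  for (int i = 0; i < events.nrow(); ++i) {
    EventSpec e;
    e.w[0] = events(i, 0); e.w[1] = events(i, 1); e.w[2] = events(i, 2);
    e.level = events(i, 3);
    e.dir = static_cast<int>(events(i, 4));
    e.mask = static_cast<int>(events(i, 5));
    e.type = static_cast<int>(events(i, 6));
    e.every = events.ncol() > 7 ? static_cast<int>(events(i, 7)) : 1;
    if (e.every < 1) e.every = 1;
    evs.push_back(e);
  }
  const long nev = static_cast<long>(evs.size());
  if (nev > 64) stop("at most 64 event specifications are supported");
  std::vector<long> ev_count(nev, 0);

  const long N = static_cast<long>(n_steps);
  const long strd = stride > 0 ? static_cast<long>(stride) : 0;
  const long maxrec = static_cast<long>(max_record);

  uint64_t sn = static_cast<uint64_t>(seed_noise);
  uint64_t sh = static_cast<uint64_t>(seed_hop);
  uint64_t cn = static_cast<uint64_t>(noise_counter);
  uint64_t ch = static_cast<uint64_t>(hop_counter);

  const NumericMatrix inj_n = injected_noise.isNotNull()
    ? NumericMatrix(injected_noise) : NumericMatrix(0, 0);
  const NumericVector inj_u = injected_uniforms.isNotNull()
    ? NumericVector(injected_uniforms) : NumericVector(0);

  std::vector<double> traj;           // 15 cols
  std::vector<HopRec> hops;
  std::vector<double> recs;           // 14 cols: event idx, step, time, state(11)
  StepDiag diag;

  auto push_snap = [&](long step) {
    std::complex<double> cc[2];
    gauge_to_convention(m, st, cc);
    traj.push_back(static_cast<double>(step)); traj.push_back(st.time);
    for (int i = 0; i < 3; ++i) traj.push_back(st.x[i]);
    for (int i = 0; i < 3; ++i) traj.push_back(st.v[i]);
    traj.push_back(st.active);
    traj.push_back(cc[0].real()); traj.push_back(cc[0].imag());
    traj.push_back(cc[1].real()); traj.push_back(cc[1].imag());
    traj.push_back(st.E[0]); traj.push_back(st.E[1]);
  };
  auto push_rec = [&](long iev, long step) {
    std::complex<double> cc[2];
    gauge_to_convention(m, st, cc);
    recs.push_back(static_cast<double>(iev + 1));
    recs.push_back(static_cast<double>(step)); recs.push_back(st.time);
    for (int i = 0; i < 3; ++i) recs.push_back(st.x[i]);
    for (int i = 0; i < 3; ++i) recs.push_back(st.v[i]);
    recs.push_back(st.active);
    recs.push_back(cc[0].real()); recs.push_back(cc[0].imag());
    recs.push_back(cc[1].real()); recs.push_back(cc[1].imag());
  };

  if (strd > 0) push_snap(0);

  long steps_done = 0;
  int stop_event = 0;
  double cv_prev[64];
  for (long i = 0; i < nev && i < 64; ++i) cv_prev[i] = cvval(evs[i], st.x);

  for (long step = 1; step <= N; ++step) {
    const bool has_n = inj_n.nrow() >= step;
    double nrow[3];
    if (has_n) {
      nrow[0] = inj_n(step - 1, 0); nrow[1] = inj_n(step - 1, 1);
      nrow[2] = inj_n(step - 1, 2);
    }
    const bool has_u = inj_u.size() >= step;
    double uval = has_u ? inj_u[step - 1] : 0.0;

    tsh_step(m, st, T, gamma, dt, substeps, C, electronic, sn, cn, sh, ch,
             has_n ? nrow : nullptr, has_u ? &uval : nullptr, diag,
             record_hops ? &hops : nullptr, step);
    steps_done = step;

    if (strd > 0 && (step % strd == 0)) push_snap(step);

    for (long i = 0; i < nev; ++i) {
      const EventSpec& e = evs[i];
      const double cv = cvval(e, st.x);
      bool fired = false;
      if (e.type == 0 || e.type == 1) {
        const bool was = e.dir * (cv_prev[i] - e.level) < 0;
        const bool now = e.dir * (cv - e.level) >= 0;
        fired = was && now && state_ok(e, st.active);
      } else if (e.type == 2) {
        fired = in_region(e, st.x, st.active);
      } else if (e.type == 3) {
        fired = (step % e.every == 0) && in_region(e, st.x, st.active);
      }
      cv_prev[i] = cv;
      if (!fired) continue;
      ev_count[i]++;
      if ((e.type == 0 || e.type == 3) &&
          static_cast<long>(recs.size() / 14) < maxrec) push_rec(i, step);
      if (e.type == 1 || e.type == 2) { stop_event = static_cast<int>(i + 1); break; }
    }
    if (stop_event) break;
    if (step % 262144 == 0) Rcpp::checkUserInterrupt();
  }

  if (strd > 0 && steps_done % strd != 0) push_snap(steps_done);

  // final state (convention gauge)
  std::complex<double> cc[2];
  gauge_to_convention(m, st, cc);
  NumericVector out_state(11);
  for (int i = 0; i < 3; ++i) { out_state[i] = st.x[i]; out_state[3 + i] = st.v[i]; }
  out_state[6] = st.active;
  out_state[7] = cc[0].real(); out_state[8] = cc[0].imag();
  out_state[9] = cc[1].real(); out_state[10] = cc[1].imag();

  const long ntraj = static_cast<long>(traj.size() / 15);
  NumericMatrix trajm(ntraj, 15);
  for (long i = 0; i < ntraj; ++i)
    for (int j = 0; j < 15; ++j) trajm(i, j) = traj[i * 15 + j];

  const long nhop = static_cast<long>(hops.size());
  NumericMatrix hopm(nhop, 5);
  for (long i = 0; i < nhop; ++i) {
    hopm(i, 0) = hops[i].step; hopm(i, 1) = hops[i].time;
    hopm(i, 2) = hops[i].from; hopm(i, 3) = hops[i].to;
    hopm(i, 4) = hops[i].frustrated;
  }

  const long nrec = static_cast<long>(recs.size() / 14);
  NumericMatrix recm(nrec, 14);
  for (long i = 0; i < nrec; ++i)
    for (int j = 0; j < 14; ++j) recm(i, j) = recs[i * 14 + j];

  NumericVector evcnt(nev);
  for (long i = 0; i < nev; ++i) evcnt[i] = static_cast<double>(ev_count[i]);

  return List::create(
    _["state"] = out_state, _["time"] = st.time,
    _["steps_done"] = static_cast<double>(steps_done),
    _["stop_event"] = stop_event,
    _["trajectory"] = trajm, _["hops"] = hopm,
    _["records"] = recm, _["event_counts"] = evcnt,
    _["energies"] = NumericVector::create(st.E[0], st.E[1]),
    _["max_norm_err"] = diag.max_norm_err,
    _["n_hops"] = static_cast<double>(diag.n_acc),
    _["n_frustrated"] = static_cast<double>(diag.n_frust),
    _["noise_counter"] = static_cast<double>(cn),
    _["hop_counter"] = static_cast<double>(ch));
}

// ---------------------------------------------------------------------------
// vectorized model evaluation helpers (used by the R-level statics)

// [[Rcpp::export]]
List cpp_eval_model(List model, NumericMatrix pos) {
  ModelP m = parse_model(model);
  const int n = pos.nrow();
  NumericMatrix Hm(n, 3), Em(n, 2);
  for (int i = 0; i < n; ++i) {
    double r[3] = { pos(i, 0), pos(i, 1), pos(i, 2) };
    double H[3], G[3][3], E[2], U[4];
    eval_diab(m, r, H, G);
    adiab2(H, E, U);
    Hm(i, 0) = H[0]; Hm(i, 1) = H[1]; Hm(i, 2) = H[2];
    Em(i, 0) = E[0]; Em(i, 1) = E[1];
  }
  return List::create(_["diabatic"] = Hm, _["adiabatic"] = Em);
}
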