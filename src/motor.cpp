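// Core numerics for the reduced Fo motor model: total energy and torque of
// the rigid c10-ring + stator system, the Metropolis proton-transfer sweep,
// and the overdamped Langevin driver.  All angles are in radians, all
// energies in kT, distances in nm.  Randomness comes from R's RNG so that
// set.seed() in R gives bit-reproducible runs.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double LN10 = 2.302585092994046;

struct Model {
  int n;                       // number of c-subunits
  double Rc, Ra;               // ring and stator radii (nm)
  std::vector<double> off;     // c-site angular offsets (rad)
  double ang_e162, ang_r176, ang_e223;
  double window_half;          // a-facing sector half width (rad)
  double edge_scale;           // logistic scale of the membrane edge (rad)
  std::vector<double> A, r0, pka;  // per c-site transfer parameters
  double pka_e223, pka_e162;
  double B, lambda, dfloor, eps_mem;
  double g_theta0, g_sigma;
  double res_weight;
  double pH_ims, pH_mat, dpsi, psi_frac, mv_per_kt;
  double bg_amp; int bg_nfold; double bg_phase;
};

static Model unpack(const List& m) {
  Model M;
  M.n = as<int>(m["n_sites"]);
  M.Rc = as<double>(m["c_radius"]);
  M.Ra = as<double>(m["a_radius"]);
  M.off = as<std::vector<double> >(m["site_offsets"]);
  M.ang_e162 = as<double>(m["ang_e162"]);
  M.ang_r176 = as<double>(m["ang_r176"]);
  M.ang_e223 = as<double>(m["ang_e223"]);
  M.window_half = as<double>(m["window_half"]);
  M.edge_scale = as<double>(m["edge_scale"]);
  M.A = as<std::vector<double> >(m["A"]);
  M.r0 = as<std::vector<double> >(m["r0"]);
  M.pka = as<std::vector<double> >(m["pka"]);
  M.pka_e223 = as<double>(m["pka_e223"]);
  M.pka_e162 = as<double>(m["pka_e162"]);
  M.B = as<double>(m["B"]);
  M.lambda = as<double>(m["lambda_d"]);
  M.dfloor = as<double>(m["dist_floor"]);
  M.eps_mem = as<double>(m["eps_mem"]);
  M.g_theta0 = as<double>(m["g_theta0"]);
  M.g_sigma = as<double>(m["g_sigma"]);
  M.res_weight = as<double>(m["reservoir_weight"]);
  M.pH_ims = as<double>(m["pH_ims"]);
  M.pH_mat = as<double>(m["pH_matrix"]);
  M.dpsi = as<double>(m["delta_psi"]);
  M.psi_frac = as<double>(m["psi_fraction"]);
  M.mv_per_kt = as<double>(m["mv_per_kt"]);
  M.bg_amp = as<double>(m["bg_amp"]);
  M.bg_nfold = as<int>(m["bg_nfold"]);
  M.bg_phase = as<double>(m["bg_phase"]);
  return M;
}

static inline double wrap_pi(double a) {
  double t = (a + M_PI) / (2.0 * M_PI);
  t -= std::floor(t);
  return t * 2.0 * M_PI - M_PI;
}

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Protonation free energy of binding a proton from the IMS reservoir to a
// site with the given pKa sitting at the psi_frac depth of the potential
// drop (IMS side positive).  This is the per-proton term entering V_pKa;
// matrix-side exchange shifts by delta_res (see below).
static inline double pfe_ims(const Model& M, double pka) {
  return LN10 * (M.pH_ims - pka) +
         (M.psi_frac - 1.0) * M.dpsi / M.mv_per_kt;
}
static inline double delta_res(const Model& M) {
  // pfe(matrix) - pfe(IMS): chemical + full-membrane electrical work
  return LN10 * (M.pH_mat - M.pH_ims) + M.dpsi / M.mv_per_kt;
}

// occ layout: [0..n-1] c-sites a..j, [n] aE223, [n+1] aE162
static inline double site_charge(const IntegerVector& occ, int i) {
  return occ[i] ? 0.0 : -1.0;
}

struct Beads {
  // charged beads: positions as angles (c-sites on Rc, stator on Ra)
  std::vector<double> ang_c, q_c;      // deprotonated c-sites
  std::vector<double> ang_s, q_s;      // charged stator beads
  std::vector<int> idx_c;
};

static Beads collect(const Model& M, const IntegerVector& occ, double phi) {
  Beads b;
  for (int i = 0; i < M.n; ++i)
    if (!occ[i]) { b.ang_c.push_back(phi + M.off[i]); b.q_c.push_back(-1.0); b.idx_c.push_back(i); }
  b.ang_s.push_back(M.ang_r176); b.q_s.push_back(1.0);
  if (!occ[M.n])     { b.ang_s.push_back(M.ang_e223); b.q_s.push_back(-1.0); }
  if (!occ[M.n + 1]) { b.ang_s.push_back(M.ang_e162); b.q_s.push_back(-1.0); }
  return b;
}

static inline double pair_dist(double r1, double a1, double r2, double a2) {
  double d2 = r1 * r1 + r2 * r2 - 2.0 * r1 * r2 * std::cos(a1 - a2);
  return std::sqrt(std::max(d2, 0.0));
}

static inline double screened(const Model& M, double q1, double q2, double d) {
  double dd = std::max(d, M.dfloor);
  return q1 * q2 * M.B * std::exp(-d / M.lambda) / dd;
}

static double v_coulomb(const Model& M, const IntegerVector& occ, double phi) {
  Beads b = collect(M, occ, phi);
  double v = 0.0;
  size_t nc = b.ang_c.size(), ns = b.ang_s.size();
  for (size_t i = 0; i < nc; ++i) {
    for (size_t j = i + 1; j < nc; ++j)
      v += screened(M, b.q_c[i], b.q_c[j],
                    pair_dist(M.Rc, b.ang_c[i], M.Rc, b.ang_c[j]));
    for (size_t j = 0; j < ns; ++j)
      v += screened(M, b.q_c[i], b.q_s[j],
                    pair_dist(M.Rc, b.ang_c[i], M.Ra, b.ang_s[j]));
  }
  for (size_t i = 0; i < ns; ++i)
    for (size_t j = i + 1; j < ns; ++j)
      v += screened(M, b.q_s[i], b.q_s[j],
                    pair_dist(M.Ra, b.ang_s[i], M.Ra, b.ang_s[j]));
  return v;
}

static double v_mem(const Model& M, const IntegerVector& occ, double phi) {
  double v = 0.0;
  for (int i = 0; i < M.n; ++i) {
    if (occ[i]) continue;
    double rel = wrap_pi(phi + M.off[i]);
    v += M.eps_mem * logistic((std::fabs(rel) - M.window_half) / M.edge_scale);
  }
  return v;
}

static double v_pka(const Model& M, const IntegerVector& occ) {
  double v = 0.0;
  for (int i = 0; i < M.n; ++i) if (occ[i]) v += pfe_ims(M, M.pka[i]);
  if (occ[M.n])     v += pfe_ims(M, M.pka_e223);
  if (occ[M.n + 1]) v += pfe_ims(M, M.pka_e162);
  return v;
}

static inline double v_bg(const Model& M, double phi) {
  if (M.bg_amp == 0.0) return 0.0;
  return M.bg_amp * std::cos(M.bg_nfold * phi + M.bg_phase);
}

static double v_total(const Model& M, const IntegerVector& occ, double phi) {
  return v_coulomb(M, occ, phi) + v_mem(M, occ, phi) + v_pka(M, occ) +
         v_bg(M, phi);
}

static double torque(const Model& M, const IntegerVector& occ, double phi) {
  // -dV/dphi; only deprotonated c-sites couple the angle to the stator
  double tq = 0.0;
  double stat_ang[3]; double stat_q[3]; int ns = 0;
  stat_ang[ns] = M.ang_r176; stat_q[ns++] = 1.0;
  if (!occ[M.n])     { stat_ang[ns] = M.ang_e223; stat_q[ns++] = -1.0; }
  if (!occ[M.n + 1]) { stat_ang[ns] = M.ang_e162; stat_q[ns++] = -1.0; }
  for (int i = 0; i < M.n; ++i) {
    if (occ[i]) continue;
    double ai = phi + M.off[i];
    for (int j = 0; j < ns; ++j) {
      double d = pair_dist(M.Rc, ai, M.Ra, stat_ang[j]);
      double dd_dphi = M.Rc * M.Ra * std::sin(ai - stat_ang[j]) /
                       std::max(d, 1e-12);
      double qq = -1.0 * stat_q[j] * M.B;
      double dv_dd;
      if (d > M.dfloor)
        dv_dd = -qq * std::exp(-d / M.lambda) *
                (1.0 / (M.lambda * d) + 1.0 / (d * d));
      else
        dv_dd = -qq * std::exp(-d / M.lambda) / (M.lambda * M.dfloor);
      tq -= dv_dd * dd_dphi;
    }
    double rel = wrap_pi(ai);
    double u = (std::fabs(rel) - M.window_half) / M.edge_scale;
    double s = logistic(u);
    double sign = (rel >= 0) ? 1.0 : -1.0;
    tq -= M.eps_mem * s * (1.0 - s) / M.edge_scale * sign;
  }
  if (M.bg_amp != 0.0)
    tq += M.bg_amp * M.bg_nfold * std::sin(M.bg_nfold * phi + M.bg_phase);
  return tq;
}

// transfer attempt weight w = f(r) g(theta) h(R176) for channel c-site i
// <-> relay (relay_code 0 = aE162, 1 = aE223)
static double channel_weight(const Model& M, int i, int relay_code, double phi) {
  double ang_rel = relay_code ? M.ang_e223 : M.ang_e162;
  double ai = phi + M.off[i];
  double rel = wrap_pi(ai - M.ang_r176);
  // hard gate: exchange only on the relay's side of the essential arginine
  bool ok = relay_code ? (rel > 0.0 && rel < M_PI) : (rel < 0.0 && rel > -M_PI);
  if (!ok) return 0.0;
  double r = pair_dist(M.Rc, ai, M.Ra, ang_rel);
  double f = std::exp(-M.A[i] * (r - M.r0[i]));
  if (f > 1.0) f = 1.0;
  // theta: angle between the site's outward radial direction and the
  // site-to-relay direction
  double px = M.Rc * std::cos(ai), py = M.Rc * std::sin(ai);
  double qx = M.Ra * std::cos(ang_rel), qy = M.Ra * std::sin(ang_rel);
  double vx = qx - px, vy = qy - py;
  double vn = std::sqrt(vx * vx + vy * vy);
  double ct = (std::cos(ai) * vx + std::sin(ai) * vy) / std::max(vn, 1e-12);
  if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
  double theta = std::acos(ct);
  double z = (theta - M.g_theta0) / M.g_sigma;
  double g = std::exp(-0.5 * z * z);
  return f * g;
}

struct EventLog {
  std::vector<double> step;
  std::vector<int> kind, subunit, dir, outcome;
  std::vector<double> dv;
  void add(double s, int k, int su, int d, int out, double de) {
    step.push_back(s); kind.push_back(k); subunit.push_back(su);
    dir.push_back(d); outcome.push_back(out); dv.push_back(de);
  }
};

// One Metropolis sweep over all admissible channels in random order.
// Channel kinds: 1 release (c<->aE162), 2 uptake (c<->aE223),
//                3 relay_ims (IMS<->aE223), 4 relay_matrix (aE162<->matrix)
static void sweep(const Model& M, IntegerVector& occ, double phi,
                  double md_step, EventLog& ev,
                  long& ims_in, long& matrix_out) {
  int nch = 2 * M.n + 2;
  std::vector<int> order(nch);
  for (int i = 0; i < nch; ++i) order[i] = i;
  for (int i = nch - 1; i > 0; --i) {       // Fisher-Yates with R's RNG
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(order[i], order[j]);
  }
  int iE223 = M.n, iE162 = M.n + 1;
  double dres = delta_res(M);
  for (int c = 0; c < nch; ++c) {
    int ch = order[c];
    int kind, site = -1, from, to, dir;
    double w, shift = 0.0;
    if (ch < M.n) {                          // release: c-site <-> aE162
      kind = 1; site = ch;
      if (occ[site] && !occ[iE162])      { from = site; to = iE162; dir = 1; }
      else if (occ[iE162] && !occ[site]) { from = iE162; to = site; dir = -1; }
      else continue;
      w = channel_weight(M, site, 0, phi);
    } else if (ch < 2 * M.n) {               // uptake: aE223 <-> c-site
      kind = 2; site = ch - M.n;
      if (occ[iE223] && !occ[site])      { from = iE223; to = site; dir = 1; }
      else if (occ[site] && !occ[iE223]) { from = site; to = iE223; dir = -1; }
      else continue;
      w = channel_weight(M, site, 1, phi);
    } else if (ch == 2 * M.n) {              // IMS <-> aE223
      kind = 3;
      if (!occ[iE223]) { from = -1; to = iE223; dir = 1; }
      else             { from = iE223; to = -1; dir = -1; }
      w = M.res_weight;
    } else {                                 // aE162 <-> matrix
      kind = 4;
      if (occ[iE162]) { from = iE162; to = -1; dir = 1; }
      else            { from = -1; to = iE162; dir = -1; }
      w = M.res_weight;
      shift = (dir == 1) ? -dres : dres;     // matrix-side reference shift
    }
    if (w <= 0.0) continue;
    if (unif_rand() >= w) continue;          // attempt with probability w
    double v0 = v_total(M, occ, phi);
    if (from >= 0) occ[from] = 0;
    if (to >= 0) occ[to] = 1;
    double dv = v_total(M, occ, phi) - v0 + shift;
    ev.add(md_step, kind, site, dir, 0, dv); // trial
    bool accept = (dv <= 0.0) || (unif_rand() < std::exp(-dv));
    if (accept) {
      ev.add(md_step, kind, site, dir, 1, dv);
      if (kind == 3 && dir == 1) ims_in++;
      if (kind == 4 && dir == 1) matrix_out++;
    } else {                                 // revert
      if (from >= 0) occ[from] = 1;
      if (to >= 0) occ[to] = 0;
    }
  }
}

// [[Rcpp::export]]
NumericVector fo_energy_cpp(List model, IntegerVector occ, double phi) {
  Model M = unpack(model);
  double vc = v_coulomb(M, occ, phi), vm = v_mem(M, occ, phi),
         vp = v_pka(M, occ), vb = v_bg(M, phi);
  return NumericVector::create(_["v_coulomb"] = vc, _["v_mem"] = vm,
                               _["v_pka"] = vp, _["v_background"] = vb,
                               _["total"] = vc + vm + vp + vb);
}

// [[Rcpp::export]]
double fo_torque_cpp(List model, IntegerVector occ, double phi) {
  Model M = unpack(model);
  return torque(M, occ, phi);
}

// [[Rcpp::export]]
double fo_weight_cpp(List model, int site, int relay_code, double phi) {
  Model M = unpack(model);
  return channel_weight(M, site, relay_code, phi);
}

static DataFrame events_df(const EventLog& ev) {
  return DataFrame::create(
      _["md_step"] = ev.step, _["kind"] = ev.kind, _["subunit"] = ev.subunit,
      _["direction"] = ev.dir, _["outcome"] = ev.outcome,
      _["delta_energy"] = ev.dv);
}

// [[Rcpp::export]]
List fo_sweep_cpp(List model, IntegerVector occ, double phi, double md_step) {
  Model M = unpack(model);
  IntegerVector o = clone(occ);
  EventLog ev;
  long ii = 0, mo = 0;
  sweep(M, o, phi, md_step, ev, ii, mo);
  return List::create(_["occ"] = o, _["events"] = events_df(ev),
                      _["ims_in"] = (double)ii, _["matrix_out"] = (double)mo);
}

// [[Rcpp::export]]
NumericVector fo_langevin_cpp(List model, IntegerVector occ, double phi,
                              int n_steps, double dt, double d_rot,
                              int record_every) {
  Model M = unpack(model);
  int nrec = n_steps / record_every;
  NumericVector out(nrec);
  double amp = std::sqrt(2.0 * d_rot * dt);
  int k = 0;
  for (int s = 1; s <= n_steps; ++s) {
    phi += d_rot * dt * torque(M, occ, phi) + amp * norm_rand();
    if (s % record_every == 0) out[k++] = phi;
  }
  return out;
}

// Full hybrid MC/MD run: `rounds` cycles of one proton sweep followed by
// `md_steps` Langevin steps; frames sampled every md_steps/frames_per_round.
// [[Rcpp::export]]
List fo_run_cpp(List model, IntegerVector occ0, double phi0, int rounds,
                int md_steps, int frames_per_round, double dt, double d_rot) {
  Model M = unpack(model);
  IntegerVector occ = clone(occ0);
  double phi = phi0;
  EventLog ev;
  long ims_in = 0, matrix_out = 0;
  int frame_int = md_steps / frames_per_round;
  int nframes = rounds * frames_per_round;
  NumericVector f_step(nframes), f_phi(nframes);
  IntegerVector f_ims(nframes), f_mat(nframes);
  IntegerMatrix f_occ(nframes, M.n + 2);
  double amp = std::sqrt(2.0 * d_rot * dt);
  double steps_done = 0.0;
  int k = 0;
  for (int r = 0; r < rounds; ++r) {
    sweep(M, occ, phi, steps_done, ev, ims_in, matrix_out);
    for (int s = 1; s <= md_steps; ++s) {
      phi += d_rot * dt * torque(M, occ, phi) + amp * norm_rand();
      if (s % frame_int == 0) {
        f_step[k] = steps_done + s;
        f_phi[k] = phi;
        f_ims[k] = (int)ims_in;
        f_mat[k] = (int)matrix_out;
        for (int i = 0; i < M.n + 2; ++i) f_occ(k, i) = occ[i];
        ++k;
      }
    }
    steps_done += md_steps;
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["md_step"] = f_step, _["phi"] = f_phi, _["n_ims_in"] = f_ims,
      _["n_matrix_out"] = f_mat, _["occ"] = f_occ,
      _["events"] = events_df(ev), _["occ_final"] = occ,
      _["phi_final"] = phi);
}
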