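#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "model_rates.h"
using namespace Rcpp;

// Hybrid stochastic-deterministic simulation of an IP3R cluster.
//
// Each channel owns a spherically symmetric radial reaction-diffusion
// field for free Ca2+ and free dye on a shared nonuniform finite-volume
// grid (fine near the pore, coarsening geometrically outward).  Diffusion
// is advanced with backward Euler on the tridiagonal radial system
// (unconditionally stable; factorization precomputed since dt is fixed);
// the dye reaction and the point-source term are then applied with a
// positivity-preserving semi-implicit update.  The local Ca2+ at each
// channel is the resting level plus the superposed excess concentrations
// of all channels' fields evaluated at the inter-channel distances (the
// self term at the source shell radius).  Channel gating advances by
// exact exponential-clock jumps of the twelve-state chain with rates
// frozen over one field step.

namespace {

struct Tridiag {
  // backward-Euler factorization for (I - dt*L) x = rhs with Dirichlet
  // outer boundary; precomputed forward-elimination coefficients
  std::vector<double> sub, denom_inv, cp;
  int n;
  void init(const std::vector<double> &nodes, const std::vector<double> &edges,
            double D, double dt) {
    n = (int)nodes.size();
    std::vector<double> diag(n), sup(n);
    sub.assign(n, 0.0); cp.assign(n, 0.0); denom_inv.assign(n, 0.0);
    std::vector<double> W(n + 1, 0.0), V(n);
    for (int i = 1; i < n; ++i) {
      const double A = 2.0 * M_PI * edges[i] * edges[i];  // hemisphere shell
      W[i] = D * A / (nodes[i] - nodes[i - 1]);
    }
    for (int i = 0; i < n; ++i) {
      V[i] = 2.0 * M_PI / 3.0 *
        (edges[i + 1] * edges[i + 1] * edges[i + 1] -
         edges[i] * edges[i] * edges[i]);
      sub[i] = -dt * W[i] / V[i];
      sup[i] = -dt * W[i + 1] / V[i];
      diag[i] = 1.0 + dt * (W[i] + W[i + 1]) / V[i];
    }
    // Dirichlet at the outer node
    sub[n - 1] = 0.0; sup[n - 1] = 0.0; diag[n - 1] = 1.0;
    cp[0] = sup[0] / diag[0];
    denom_inv[0] = 1.0 / diag[0];
    for (int i = 1; i < n; ++i) {
      const double den = diag[i] - sub[i] * cp[i - 1];
      denom_inv[i] = 1.0 / den;
      cp[i] = sup[i] / den;
    }
  }
  void solve(std::vector<double> &x) const {
    x[0] *= denom_inv[0];
    for (int i = 1; i < n; ++i)
      x[i] = (x[i] - sub[i] * x[i - 1]) * denom_inv[i];
    for (int i = n - 2; i >= 0; --i) x[i] -= cp[i] * x[i + 1];
  }
};

struct Field {
  std::vector<double> c, b;  // free Ca2+ (uM), free dye (uM)
  bool active;
  void reset(int n, double crest, double brest) {
    c.assign(n, crest);
    b.assign(n, brest);
    active = false;
  }
};

struct FieldModel {
  std::vector<double> nodes, edges;
  Tridiag tri_c, tri_d;
  double Dc, Dd, Bd, kf, kr, crest, brest;
  double src_rate;      // uM/s deposited in the source cells while open
  int n_src;            // number of innermost cells receiving the source
  double dt;
  int n;

  void init(const NumericVector &nodes_, const NumericVector &edges_,
            double Dc_, double Dd_, double Bd_, double kf_, double kr_,
            double crest_, double src_rate_, int n_src_, double dt_) {
    nodes.assign(nodes_.begin(), nodes_.end());
    edges.assign(edges_.begin(), edges_.end());
    n = (int)nodes.size();
    Dc = Dc_; Dd = Dd_; Bd = Bd_; kf = kf_; kr = kr_; crest = crest_;
    src_rate = src_rate_; n_src = n_src_; dt = dt_;
    brest = (Bd > 0.0) ? Bd * kr / (kr + kf * crest) : 0.0;
    tri_c.init(nodes, edges, Dc, dt);
    if (Bd > 0.0) tri_d.init(nodes, edges, Dd, dt);
  }

  void step(Field &f, bool source_on) const {
    // source enters the backward-Euler right-hand side so the inner-cell
    // balance (source against diffusive outflow) is resolved implicitly
    if (source_on)
      for (int i = 0; i < n_src; ++i) f.c[i] += dt * src_rate;
    tri_c.solve(f.c);
    if (Bd > 0.0) tri_d.solve(f.b);
    for (int i = 0; i < n - 1; ++i) {  // outer node stays clamped at rest
      if (Bd > 0.0) {
        const double bn = (f.b[i] + dt * kr * Bd) /
                          (1.0 + dt * (kr + kf * f.c[i]));
        const double cn = (f.c[i] + dt * kr * (Bd - bn)) /
                          (1.0 + dt * kf * bn);
        f.b[i] = bn;
        f.c[i] = cn;
      }
    }
  }

  // linear interpolation of the excess free Ca2+ at radius r
  double excess_at(const Field &f, int idx, double w) const {
    return (1.0 - w) * (f.c[idx] - crest) + w * (f.c[idx + 1] - crest);
  }
  double dye_excess_at(const Field &f, int idx, double w) const {
    if (Bd <= 0.0) return 0.0;
    return (1.0 - w) * (brest - f.b[idx]) + w * (brest - f.b[idx + 1]);
  }

  double max_excess(const Field &f) const {
    double m = 0.0;
    for (int i = 0; i < n; ++i)
      m = std::max(m, std::fabs(f.c[i] - crest));
    return m;
  }
};

void interp_weights(const std::vector<double> &nodes, double r,
                    int &idx, double &w) {
  const int n = (int)nodes.size();
  if (r <= nodes[0]) { idx = 0; w = 0.0; return; }
  if (r >= nodes[n - 1]) { idx = n - 2; w = 1.0; return; }
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    const int mid = (lo + hi) / 2;
    if (nodes[mid] <= r) lo = mid; else hi = mid;
  }
  idx = lo;
  w = (r - nodes[lo]) / (nodes[hi] - nodes[lo]);
}

}  // namespace

// Deterministic single-channel field driver: advances one radial field
// under a piecewise-constant source schedule (seg_end gives segment end
// times in s, seg_on whether the source is on).  Returns the final
// profiles and a time series of the concentration in the innermost cell.
// Used for steady-state, fixed-point and convergence checks.
// [[Rcpp::export]]
List cpp_single_field(NumericVector nodes, NumericVector edges,
                      double Dc, double Dd, double Bd, double kf, double kr,
                      double crest, double src_rate, int n_src,
                      double dt, NumericVector seg_end, LogicalVector seg_on,
                      double record_dt) {
  FieldModel fm;
  fm.init(nodes, edges, Dc, Dd, Bd, kf, kr, crest, src_rate, n_src, dt);
  Field f;
  f.reset(fm.n, fm.crest, fm.brest);

  std::vector<double> t_rec, c0_rec;
  double t = 0.0, next_rec = 0.0;
  for (int seg = 0; seg < seg_end.size(); ++seg) {
    const bool on = seg_on[seg];
    while (t < seg_end[seg] - 1e-15) {
      fm.step(f, on);
      t += dt;
      if (record_dt > 0 && t >= next_rec - 1e-15) {
        t_rec.push_back(t);
        c0_rec.push_back(f.c[0]);
        next_rec += record_dt;
      }
    }
  }
  return List::create(_["r_um"] = nodes,
                      _["c"] = wrap(f.c), _["b"] = wrap(f.b),
                      _["b_rest"] = fm.brest,
                      _["t_s"] = wrap(t_rec), _["c_inner"] = wrap(c0_rec));
}

// Full cluster run.  dist: n_chan x n_chan inter-channel distances (um)
// with the self-evaluation radius on the diagonal; r_center: distance of
// each channel to the recording point.  init_states are 1-based canonical
// state indices.  Returns decimated time series of the channel states and
// of the superposed concentrations at the recording point.
// [[Rcpp::export]]
List cpp_run_cluster(NumericVector K, NumericVector j, double ip3,
                     NumericMatrix dist, NumericVector r_center,
                     NumericVector nodes, NumericVector edges,
                     double Dc, double Dd, double Bd, double kf, double kr,
                     double crest, double src_rate, int n_src,
                     double duration_s, double dt, double record_dt,
                     IntegerVector init_states) {
  const int nch = dist.nrow();
  if (dist.ncol() != nch || r_center.size() != nch ||
      init_states.size() != nch)
    stop("inconsistent channel geometry inputs");
  if (K.size() != 12 || j.size() != 18) stop("K must have 12 and j 18 entries");

  FieldModel fm;
  fm.init(nodes, edges, Dc, Dd, Bd, kf, kr, crest, src_rate, n_src, dt);

  std::vector<Field> fields(nch);
  for (int i = 0; i < nch; ++i) fields[i].reset(fm.n, fm.crest, fm.brest);

  // interpolation weights for channel-to-channel and channel-to-center
  std::vector<int> widx(nch * nch), cidx(nch);
  std::vector<double> wfrac(nch * nch), cfrac(nch);
  for (int i = 0; i < nch; ++i) {
    for (int jj = 0; jj < nch; ++jj)
      interp_weights(fm.nodes, dist(i, jj), widx[i * nch + jj],
                     wfrac[i * nch + jj]);
    interp_weights(fm.nodes, r_center[i], cidx[i], cfrac[i]);
  }

  std::vector<int> state(nch);
  for (int i = 0; i < nch; ++i) {
    state[i] = init_states[i] - 1;
    if (state[i] < 0 || state[i] > 11) stop("init_states must be in 1..12");
  }

  std::vector<double> Qi(144), Ccache(nch, -1.0);
  std::vector<std::vector<double>> Qch(nch, std::vector<double>(144));

  const long nsteps = (long)std::ceil(duration_s / dt);
  const int rec_every = std::max(1, (int)std::lround(record_dt / dt));
  const long nrec = nsteps / rec_every + 1;

  NumericVector t_out(nrec), ca_center(nrec), dye_center(nrec);
  IntegerMatrix open_out(nrec, nch);
  IntegerVector nopen_out(nrec);

  std::vector<double> Cloc(nch);
  long irec = 0;

  auto record = [&](long step) {
    const double t = step * dt;
    double cc = crest, dd = 0.0;
    for (int jj = 0; jj < nch; ++jj) {
      if (!fields[jj].active) continue;
      cc += fm.excess_at(fields[jj], cidx[jj], cfrac[jj]);
      dd += fm.dye_excess_at(fields[jj], cidx[jj], cfrac[jj]);
    }
    int nop = 0;
    for (int i = 0; i < nch; ++i) {
      const int op = state[i] < 3 ? 1 : 0;  // canonical order: open first
      open_out(irec, i) = op;
      nop += op;
    }
    t_out[irec] = t;
    ca_center[irec] = cc;
    dye_center[irec] = (Bd > 0.0 ? (Bd - fm.brest) : 0.0) + dd;
    nopen_out[irec] = nop;
    ++irec;
  };

  record(0);

  for (long step = 0; step < nsteps; ++step) {
    // local Ca2+ at each channel from superposed field excesses
    for (int i = 0; i < nch; ++i) {
      double ci = crest;
      for (int jj = 0; jj < nch; ++jj) {
        if (!fields[jj].active) continue;
        ci += fm.excess_at(fields[jj], widx[i * nch + jj],
                           wfrac[i * nch + jj]);
      }
      Cloc[i] = std::max(ci, 0.0);
    }

    // gating: exact jumps with rates frozen over this step (Q in ms^-1,
    // clock in s)
    for (int i = 0; i < nch; ++i) {
      if (Ccache[i] < 0.0 ||
          std::fabs(Cloc[i] - Ccache[i]) > 1e-3 * Ccache[i]) {
        ip3r::build_generator(K.begin(), j.begin(), Cloc[i], ip3,
                              Qch[i].data());
        Ccache[i] = Cloc[i];
      }
      const double *Qc = Qch[i].data();
      double remain = dt;
      int s = state[i];
      for (;;) {
        const double exit_s = -Qc[12 * s + s] * 1000.0;
        if (exit_s <= 0.0) break;
        const double tau = exp_rand() / exit_s;
        if (tau > remain) break;
        remain -= tau;
        double u = unif_rand() * (-Qc[12 * s + s]);
        double acc = 0.0;
        int nxt = -1;
        for (int b = 0; b < 12; ++b) {
          if (b == s) continue;
          acc += Qc[12 * s + b];
          if (u <= acc) { nxt = b; break; }
        }
        if (nxt < 0) break;
        s = nxt;
      }
      state[i] = s;
    }

    // fields
    for (int i = 0; i < nch; ++i) {
      const bool on = state[i] < 3;
      if (on) fields[i].active = true;
      if (!fields[i].active) continue;
      fm.step(fields[i], on);
      // retire fields that have relaxed back to rest
      if (!on && (step & 255) == 0 &&
          fm.max_excess(fields[i]) < 1e-8) {
        fields[i].reset(fm.n, fm.crest, fm.brest);
      }
    }

    if ((step + 1) % rec_every == 0 && irec < nrec) record(step + 1);
  }

  return List::create(
      _["t_s"] = t_out[Range(0, irec - 1)],
      _["n_open"] = nopen_out[Range(0, irec - 1)],
      _["open"] = open_out(Range(0, irec - 1), _),
      _["ca_center_uM"] = ca_center[Range(0, irec - 1)],
      _["dye_bound_center_uM"] = dye_center[Range(0, irec - 1)],
      _["final_state"] = wrap(std::vector<int>(state.begin(), state.end())));
}
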