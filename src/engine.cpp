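// Event-driven discrete molecular dynamics core.
//
// Beads move ballistically between events; events are hardcore bounces,
// step-potential shell crossings, bond-wall reflections, hydrogen-bond
// reactions/breaks, Anderson-thermostat velocity reassignments and
// bookkeeping "refresh" events that bound how far a bead may travel before
// its neighbourhood is re-examined (this replaces a cell list: a pair can
// only reach the interaction cutoff after one participant has moved more
// than `delta`, at which point its refresh event has already rescheduled
// it). All collisions conserve linear momentum exactly and change only the
// radial velocity component, so the pair's angular momentum about its
// centre of mass is conserved as well.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <unordered_map>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

const double BTOL = 1e-9;  // "at a boundary" tolerance (Angstrom)

struct Event {
  double t;
  int i, j;          // j = -1 for one-body events
  uint32_t ci, cj;   // bead collision counters at scheduling time
  uint8_t kind;      // 0 pair, 1 thermostat, 2 refresh
  double d;          // boundary radius for pair events
};

struct EventCmp {
  bool operator()(const Event& a, const Event& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.i != b.i) return a.i > b.i;  // lexicographic tie-break
    return a.j > b.j;
  }
};

// deterministic RNG: xoshiro-style splitmix + Box-Muller
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL),
                                have_spare(false), spare(0) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() {  // (0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0) +
           (0.5 / 9007199254740992.0);
  }
  bool have_spare;
  double spare;
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u));
    spare = r * std::sin(2.0 * M_PI * v);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * v);
  }
  double expo(double rate) { return -std::log(unif()) / rate; }
};

struct StepPot {
  std::vector<double> radii;     // ascending; radii[0] = hardcore wall
  std::vector<double> energies;  // energy between radii[k] and radii[k+1]
  double cutoff() const { return radii.empty() ? 0.0 : radii.back(); }
  double energy(double r) const {
    if (radii.empty() || r >= radii.back()) return 0.0;
    if (r <= radii.front()) return R_PosInf;
    for (size_t k = radii.size() - 1; k > 0; --k) {
      if (r > radii[k - 1]) return energies[k - 1];
    }
    return R_PosInf;  // unreachable
  }
};

struct Engine {
  int n;
  std::vector<double> x, v;      // 3n, lazily advanced
  std::vector<double> tlast;     // per-bead last update time
  std::vector<double> mass, invm;
  std::vector<int> iclass, mol, don_cap, acc_cap, is_pep;
  std::vector<int> don_used, acc_used;
  std::vector<uint32_t> cnt;
  double L;
  double t;

  std::vector<StepPot> pots;        // inter-molecular (with dispersion tail)
  std::vector<StepPot> pots_intra;  // same-molecule pairs: tail stripped
  std::vector<int> pt_index;     // nclass x nclass
  std::vector<double> maxcut;       // nclass x nclass conservative reach
  std::vector<double> maxcut_intra;
  int nclass;

  double hb_dmin, hb_dmax, hb_eps;
  bool hb_on;
  // reacted hydrogen-bond pairs, stored per bead as (partner, donor)
  std::vector<std::vector<std::pair<int,int>>> hb_with;

  std::vector<std::vector<int>> bond_partners;
  std::vector<std::vector<std::pair<double,double>>> bond_ranges;
  // cached neighbour lists, rebuilt when the owner has travelled `delta`
  // since the rebuild position (the 2*delta margin in reach2 covers both
  // beads' travel; beads entering range are covered by their own lists)
  std::vector<std::vector<int>> nbrs;
  std::vector<double> xref;  // unwrapped position at last rebuild

  double kTtgt, thermo_rate, delta, horizon;

  std::priority_queue<Event, std::vector<Event>, EventCmp> heap;

  double pe;  // incremental potential energy
  long n_cross = 0, n_reflect = 0, n_hb_form = 0, n_hb_break = 0,
       n_thermo = 0, n_refresh = 0, n_stale = 0, n_heal = 0;

  int64_t pkey(int i, int j) const {
    if (i > j) std::swap(i, j);
    return (int64_t)i * n + j;
  }

  inline double px(int i, int k, double tt) const {
    return x[3 * i + k] + v[3 * i + k] * (tt - tlast[i]);
  }
  inline void advance(int i, double tt) {
    double dt = tt - tlast[i];
    x[3 * i] += v[3 * i] * dt;
    x[3 * i + 1] += v[3 * i + 1] * dt;
    x[3 * i + 2] += v[3 * i + 2] * dt;
    tlast[i] = tt;
  }
  inline double mi(double d) const { return d - L * std::nearbyint(d / L); }

  bool bonded(int i, int j, double* dmin = nullptr,
              double* dmax = nullptr) const {
    const std::vector<int>& bp = bond_partners[i];
    for (size_t k = 0; k < bp.size(); ++k) {
      if (bp[k] == j) {
        if (dmin) { *dmin = bond_ranges[i][k].first;
                    *dmax = bond_ranges[i][k].second; }
        return true;
      }
    }
    return false;
  }

  bool hb_eligible(int i, int j) const {
    if (!hb_on) return false;
    return (don_cap[i] > 0 && acc_cap[j] > 0) ||
           (don_cap[j] > 0 && acc_cap[i] > 0);
  }

  bool is_reacted(int i, int j) const {
    const std::vector<std::pair<int,int>>& w = hb_with[i];
    for (size_t k = 0; k < w.size(); ++k) {
      if (w[k].first == j) return true;
    }
    return false;
  }
  void hb_react(int i, int j, int donor) {
    hb_with[i].push_back({j, donor});
    hb_with[j].push_back({i, donor});
    don_used[donor]++;
    acc_used[donor == i ? j : i]++;
  }
  int hb_unreact(int i, int j) {
    int donor = -1;
    for (size_t k = 0; k < hb_with[i].size(); ++k) {
      if (hb_with[i][k].first == j) {
        donor = hb_with[i][k].second;
        hb_with[i].erase(hb_with[i].begin() + k);
        break;
      }
    }
    for (size_t k = 0; k < hb_with[j].size(); ++k) {
      if (hb_with[j][k].first == i) {
        hb_with[j].erase(hb_with[j].begin() + k);
        break;
      }
    }
    don_used[donor]--;
    acc_used[donor == i ? j : i]--;
    return donor;
  }

  const StepPot* pair_pot(int i, int j) const {
    int idx = pt_index[iclass[i] * nclass + iclass[j]];
    if (idx < 0) return nullptr;
    return (mol[i] == mol[j]) ? &pots_intra[idx] : &pots[idx];
  }
  double reach2(int i, int j) const {
    double c = (mol[i] == mol[j] ? maxcut_intra : maxcut)
                 [iclass[i] * nclass + iclass[j]] + 2.0 * delta;
    return c * c;
  }

  // total pair energy (base + active hydrogen bond) just off a boundary
  double u_tot(const StepPot* pt, double r, bool hb_active) const {
    double u = pt ? pt->energy(r) : 0.0;
    if (hb_active && r < hb_dmax) u += hb_eps;
    return u;
  }

  // predict the next event for pair (i, j); returns false if none.
  // is_bond: the pair is a bond/constraint with walls [bmin, bmax]
  bool predict(int i, int j, double now, double& te, double& dbound,
               bool is_bond = false, double bmin = 0,
               double bmax = 0) const {
    double r[3], vr[3];
    for (int k = 0; k < 3; ++k) {
      r[k] = mi(px(j, k, now) - px(i, k, now));
      vr[k] = v[3 * j + k] - v[3 * i + k];
    }
    double rr2 = r[0] * r[0] + r[1] * r[1] + r[2] * r[2];
    double rr = std::sqrt(rr2);
    double b = r[0] * vr[0] + r[1] * vr[1] + r[2] * vr[2];
    double v2 = vr[0] * vr[0] + vr[1] * vr[1] + vr[2] * vr[2];
    if (v2 <= 0.0) return false;

    // applicable boundaries
    double din = -1.0, dout = R_PosInf;
    if (is_bond) {
      if (bmin < rr - BTOL && bmin > din) din = bmin;
      if (bmax > rr + BTOL && bmax < dout) dout = bmax;
    } else {
      const StepPot* pt = pair_pot(i, j);
      if (pt) {
        for (size_t k = 0; k < pt->radii.size(); ++k) {
          double d = pt->radii[k];
          if (d < rr - BTOL && d > din) din = d;
          if (d > rr + BTOL && d < dout) dout = d;
        }
      }
      if (hb_eligible(i, j)) {
        bool reacted = is_reacted(i, j);
        if (reacted) {
          if (hb_dmin < rr - BTOL && hb_dmin > din) din = hb_dmin;
          if (hb_dmax > rr + BTOL && hb_dmax < dout) dout = hb_dmax;
        } else {
          // unreacted: d_max matters only as an inward (reaction) trigger
          if (hb_dmax < rr - BTOL && hb_dmax > din) din = hb_dmax;
        }
      }
    }

    if (b < 0.0 && din > 0.0) {
      double disc = b * b - v2 * (rr2 - din * din);
      if (disc > 0.0) {
        te = now + (-b - std::sqrt(disc)) / v2;
        dbound = din;
        return te > now;
      }
    }
    if (!std::isfinite(dout)) return false;
    double disc = b * b - v2 * (rr2 - dout * dout);
    if (disc < 0.0) disc = 0.0;
    te = now + (-b + std::sqrt(disc)) / v2;
    dbound = dout;
    return te > now;
  }

  // one-event-per-bead scheduling: each bead owns exactly one live entry,
  // either its earliest pending pair event or a refresh (fires after the
  // bead has travelled `delta`, re-examining its neighbourhood). Any
  // velocity change recomputes the entries of the beads involved; entries
  // referencing a bead whose collision counter has advanced are recomputed
  // lazily when popped.
  void build_nbrs(int i, double now) {
    std::vector<int>& nb = nbrs[i];
    nb.clear();
    double xi[3];
    for (int k = 0; k < 3; ++k) { xi[k] = px(i, k, now); xref[3 * i + k] = xi[k]; }
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double r2lim = reach2(i, j);
      double dx = mi(px(j, 0, now) - xi[0]);
      double dy = mi(px(j, 1, now) - xi[1]);
      double dz = mi(px(j, 2, now) - xi[2]);
      if (dx * dx + dy * dy + dz * dz > r2lim) continue;
      if (bonded(i, j)) continue;  // scheduled separately
      nb.push_back(j);
      // membership must be mutual: after either bead's velocity changes,
      // its own rescan has to see the pair
      std::vector<int>& nbj = nbrs[j];
      bool have = false;
      for (size_t q = 0; q < nbj.size(); ++q) {
        if (nbj[q] == i) { have = true; break; }
      }
      if (!have) nbj.push_back(i);
    }
  }

  void push_next(int i, double now) {
    double sp = std::sqrt(v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                          v[3 * i + 2] * v[3 * i + 2]);
    // remaining travel allowance before the cached list must be rebuilt
    double disp2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      double dk = px(i, k, now) - xref[3 * i + k];
      disp2 += dk * dk;
    }
    double rem = delta - std::sqrt(disp2);
    if (rem <= 1e-12) {
      build_nbrs(i, now);
      rem = delta;
    }
    double tbest = now + ((sp > 0.0) ? std::min(rem / sp, horizon)
                                     : horizon);
    int jbest = -1;
    double dbest = 0.0, te, d;
    const std::vector<int>& bp = bond_partners[i];
    for (size_t k = 0; k < bp.size(); ++k) {
      if (predict(i, bp[k], now, te, d, true, bond_ranges[i][k].first,
                  bond_ranges[i][k].second) && te < tbest) {
        tbest = te; jbest = bp[k]; dbest = d;
      }
    }
    const std::vector<int>& nb = nbrs[i];
    for (size_t k = 0; k < nb.size(); ++k) {
      if (predict(i, nb[k], now, te, d) && te < tbest) {
        tbest = te; jbest = nb[k]; dbest = d;
      }
    }
    heap.push(Event{tbest, i, jbest, cnt[i],
                    jbest >= 0 ? cnt[jbest] : 0u,
                    (uint8_t)(jbest >= 0 ? 0 : 2), dbest});
  }

  void schedule_thermostat(int i, double now, Rng& rng) {
    if (thermo_rate <= 0.0) return;
    heap.push(Event{now + rng.expo(thermo_rate), i, -1, cnt[i], 0, 1, 0.0});
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_run_dmd(NumericMatrix x0, NumericMatrix v0, NumericVector mass,
                 IntegerVector iclass, IntegerVector mol,
                 IntegerVector don_cap, IntegerVector acc_cap,
                 IntegerVector is_pep,
                 double box_edge,
                 List pots_in, IntegerVector pots_tail,
                 IntegerMatrix pt_index_in,
                 double hb_dmin, double hb_dmax, double hb_eps, bool hb_on,
                 IntegerVector bond_i, IntegerVector bond_j,
                 NumericVector bond_dmin, NumericVector bond_dmax,
                 double kT_target, double thermo_rate,
                 double event_budget, double max_time,
                 double emit_every, double emit_dt,
                 double seed, double delta, double horizon,
                 double t0) {
  Engine E;
  E.n = x0.nrow();
  E.L = box_edge;
  E.t = t0;
  E.x.resize(3 * E.n); E.v.resize(3 * E.n);
  for (int i = 0; i < E.n; ++i) {
    for (int k = 0; k < 3; ++k) {
      E.x[3 * i + k] = x0(i, k);
      E.v[3 * i + k] = v0(i, k);
    }
  }
  E.tlast.assign(E.n, t0);
  E.mass.assign(mass.begin(), mass.end());
  E.invm.resize(E.n);
  for (int i = 0; i < E.n; ++i) E.invm[i] = 1.0 / E.mass[i];
  E.iclass.assign(iclass.begin(), iclass.end());
  E.mol.assign(mol.begin(), mol.end());
  E.don_cap.assign(don_cap.begin(), don_cap.end());
  E.acc_cap.assign(acc_cap.begin(), acc_cap.end());
  E.is_pep.assign(is_pep.begin(), is_pep.end());
  E.don_used.assign(E.n, 0);
  E.acc_used.assign(E.n, 0);
  E.hb_with.assign(E.n, {});
  E.cnt.assign(E.n, 0);

  E.nclass = pt_index_in.nrow();
  E.pt_index.resize(E.nclass * E.nclass);
  for (int a = 0; a < E.nclass; ++a)
    for (int b = 0; b < E.nclass; ++b)
      E.pt_index[a * E.nclass + b] = pt_index_in(a, b);
  for (int p = 0; p < pots_in.size(); ++p) {
    List pp = pots_in[p];
    StepPot sp;
    NumericVector rad = pp["radii"], en = pp["energies"];
    sp.radii.assign(rad.begin(), rad.end());
    sp.energies.assign(en.begin(), en.end());
    E.pots.push_back(sp);
    StepPot si = sp;
    if (pots_tail[p] > 0 && (int)si.radii.size() > 1) {
      si.radii.pop_back();
      si.energies.pop_back();
    }
    E.pots_intra.push_back(si);
  }
  E.hb_dmin = hb_dmin; E.hb_dmax = hb_dmax; E.hb_eps = hb_eps;
  E.hb_on = hb_on;
  E.maxcut.resize(E.nclass * E.nclass);
  E.maxcut_intra.resize(E.nclass * E.nclass);
  for (int a = 0; a < E.nclass; ++a) {
    for (int b = 0; b < E.nclass; ++b) {
      int idx = E.pt_index[a * E.nclass + b];
      double cut = idx >= 0 ? E.pots[idx].cutoff() : 0.0;
      double cut_i = idx >= 0 ? E.pots_intra[idx].cutoff() : 0.0;
      if (hb_on) { cut = std::max(cut, hb_dmax); cut_i = std::max(cut_i, hb_dmax); }
      E.maxcut[a * E.nclass + b] = cut;
      E.maxcut_intra[a * E.nclass + b] = cut_i;
    }
  }

  E.bond_partners.assign(E.n, {});
  E.bond_ranges.assign(E.n, {});
  for (int b = 0; b < bond_i.size(); ++b) {
    int i = bond_i[b], j = bond_j[b];
    E.bond_partners[i].push_back(j);
    E.bond_partners[j].push_back(i);
    E.bond_ranges[i].push_back({bond_dmin[b], bond_dmax[b]});
    E.bond_ranges[j].push_back({bond_dmin[b], bond_dmax[b]});
  }

  E.kTtgt = kT_target;
  E.thermo_rate = thermo_rate;
  E.delta = delta;
  E.horizon = horizon;

  Rng rng((uint64_t)seed);

  // ---- initial hydrogen-bond registry (greedy by bead index) and PE ----
  E.pe = 0.0;
  int n_core_overlap = 0;
  for (int i = 0; i < E.n; ++i) {
    for (int j = i + 1; j < E.n; ++j) {
      double r2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = E.mi(E.x[3 * j + k] - E.x[3 * i + k]);
        r2 += d * d;
      }
      double maxreach = (E.mol[i] == E.mol[j] ? E.maxcut_intra : E.maxcut)
                          [E.iclass[i] * E.nclass + E.iclass[j]];
      double bmin, bmax;
      bool isb = E.bonded(i, j, &bmin, &bmax);
      if (!isb && r2 > maxreach * maxreach) continue;
      double r = std::sqrt(r2);
      if (isb) continue;  // bonds carry no potential energy
      const StepPot* pt = E.pair_pot(i, j);
      if (pt) {
        double u = pt->energy(r);
        if (!std::isfinite(u)) {
          // core-overlapped input: book the innermost shell; the healing
          // rule lets the pair escape during the run
          u = pt->energies.empty() ? 0.0 : pt->energies.front();
          n_core_overlap++;
        }
        E.pe += u;
      }
      if (E.hb_eligible(i, j) && r < hb_dmax && r > hb_dmin) {
        int di = -1;
        if (E.don_cap[i] - E.don_used[i] > 0 &&
            E.acc_cap[j] - E.acc_used[j] > 0) di = i;
        else if (E.don_cap[j] - E.don_used[j] > 0 &&
                 E.acc_cap[i] - E.acc_used[i] > 0) di = j;
        if (di >= 0) {
          E.hb_react(i, j, di);
          E.pe += hb_eps;
        }
      }
    }
  }
  if (n_core_overlap > 0) {
    Rcpp::warning("%d bead pair(s) start inside a hardcore; booked as "
                  "innermost shell", n_core_overlap);
  }

  // ---- initial schedule ----
  E.nbrs.assign(E.n, {});
  E.xref.assign(3 * E.n, 0.0);
  for (int i = 0; i < E.n; ++i) {
    E.build_nbrs(i, E.t);
    E.push_next(i, E.t);
    E.schedule_thermostat(i, E.t, rng);
  }

  // ---- frame buffers ----
  std::vector<double> fx, fv, ft, fke, fpe, fhb_pp, fhb_pl, fnev;
  auto kinetic = [&]() {
    double ke = 0.0;
    for (int i = 0; i < E.n; ++i) {
      ke += 0.5 * E.mass[i] * (E.v[3 * i] * E.v[3 * i] +
                               E.v[3 * i + 1] * E.v[3 * i + 1] +
                               E.v[3 * i + 2] * E.v[3 * i + 2]);
    }
    return ke;
  };
  long n_pair_events = 0;
  auto emit_frame = [&](double tt) {
    for (int i = 0; i < E.n; ++i) {
      for (int k = 0; k < 3; ++k) {
        double xx = E.px(i, k, tt);
        xx -= E.L * std::floor(xx / E.L);
        fx.push_back(xx);
        fv.push_back(E.v[3 * i + k]);
      }
    }
    ft.push_back(tt);
    fke.push_back(kinetic());
    fpe.push_back(E.pe);
    int pp = 0, pl = 0;  // inter-molecular hydrogen bonds only
    for (int i = 0; i < E.n; ++i) {
      for (size_t k = 0; k < E.hb_with[i].size(); ++k) {
        int j = E.hb_with[i][k].first;
        if (j <= i || E.mol[i] == E.mol[j]) continue;
        if (E.is_pep[i] && E.is_pep[j]) pp++;
        else if (E.is_pep[i] != E.is_pep[j]) pl++;
      }
    }
    fhb_pp.push_back(pp);
    fhb_pl.push_back(pl);
    fnev.push_back((double)n_pair_events);
  };
  emit_frame(E.t);
  double next_frame_t = std::isfinite(emit_dt) ? E.t + emit_dt : R_PosInf;
  double end_time = std::isfinite(max_time) ? max_time : R_PosInf;

  // ---- main loop ----
  bool done = false;
  while (!done) {
    if (E.heap.empty()) break;  // nothing can ever happen again
    Event ev = E.heap.top();
    E.heap.pop();
    // thermostat events are a Poisson process independent of collisions and
    // are never stale
    if (ev.kind != 1) {
      if (ev.ci != E.cnt[ev.i]) {
        // the owner was rescheduled since; a newer entry exists
        E.n_stale++;
        continue;
      }
      if (ev.j >= 0 && ev.cj != E.cnt[ev.j]) {
        // partner changed course: this entry is void, but it was the
        // owner's only one, so recompute the owner's next event now
        E.n_stale++;
        E.push_next(ev.i, E.t);
        continue;
      }
    }
    // time-based frames due before this event
    while (next_frame_t <= ev.t && next_frame_t <= end_time) {
      emit_frame(next_frame_t);
      next_frame_t += emit_dt;
    }
    if (ev.t > end_time) {
      E.t = end_time;
      break;
    }
    if (ev.t < E.t - 1e-9) stop("event-time regression: internal error");
    E.t = ev.t;

    if (ev.kind == 1) {  // thermostat
      int i = ev.i;
      E.advance(i, E.t);
      double sd = std::sqrt(E.kTtgt * E.invm[i]);
      for (int k = 0; k < 3; ++k) E.v[3 * i + k] = sd * rng.norm();
      E.cnt[i]++;
      E.n_thermo++;
      E.push_next(i, E.t);
      E.schedule_thermostat(i, E.t, rng);
      continue;
    }
    if (ev.kind == 2) {  // refresh: re-examine the neighbourhood
      int i = ev.i;
      E.advance(i, E.t);
      E.n_refresh++;
      E.build_nbrs(i, E.t);
      E.push_next(i, E.t);
      continue;
    }

    // ---- two-body event ----
    int i = ev.i, j = ev.j;
    E.advance(i, E.t);
    E.advance(j, E.t);
    double r[3];
    double rr2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      r[k] = E.mi(E.x[3 * j + k] - E.x[3 * i + k]);
      rr2 += r[k] * r[k];
    }
    double rr = std::sqrt(rr2);
    double d = ev.d;
    double nvec[3] = {r[0] / rr, r[1] / rr, r[2] / rr};
    double vr = 0.0;
    for (int k = 0; k < 3; ++k)
      vr += (E.v[3 * j + k] - E.v[3 * i + k]) * nvec[k];
    double mu = 1.0 / (E.invm[i] + E.invm[j]);
    bool inward = vr < 0.0;

    double bmin, bmax;
    bool isb = E.bonded(i, j, &bmin, &bmax);
    bool reflect;
    double dU = 0.0;
    bool will_react = false, will_break = false;
    int donor = -1;
    if (isb) {
      reflect = true;  // bond walls always reflect
    } else {
      const StepPot* pt = E.pair_pot(i, j);
      bool hard = pt && std::fabs(d - pt->radii.front()) < 1e-7;
      bool elig = E.hb_eligible(i, j);
      bool is_reacted = elig && E.is_reacted(i, j);
      if (hard && !inward) {
        // outward crossing scheduled at the hardcore is only possible for
        // a pair inside its core (an extremely rare scheduling miss lets
        // one through); let it escape freely instead of trapping it
        reflect = false;
        dU = 0.0;
        E.n_heal++;
      } else if (hard || (is_reacted && std::fabs(d - E.hb_dmin) < 1e-7)) {
        reflect = true;
      } else {
        bool at_hb_dmax = E.hb_on && std::fabs(d - E.hb_dmax) < 1e-7;
        if (at_hb_dmax && elig) {
          if (inward && !is_reacted) {
            if (E.don_cap[i] - E.don_used[i] > 0 &&
                E.acc_cap[j] - E.acc_used[j] > 0) { will_react = true; donor = i; }
            else if (E.don_cap[j] - E.don_used[j] > 0 &&
                     E.acc_cap[i] - E.acc_used[i] > 0) { will_react = true; donor = j; }
          } else if (!inward && is_reacted) {
            will_break = true;
          }
        }
        // u_tot applies the hb term only below hb_dmax, so a breaking pair
        // automatically sees the +|eps| escape step
        double h = 1e-6;
        bool hb_active = is_reacted || will_react;
        double u_in = E.u_tot(pt, d - h, hb_active);
        double u_out = E.u_tot(pt, d + h, hb_active);
        // energy on the far side in the direction of motion minus near side
        dU = inward ? (u_in - u_out) : (u_out - u_in);
        double ekin_r = 0.5 * mu * vr * vr;
        reflect = !(ekin_r > dU);
      }
    }

    double vrp;
    if (reflect) {
      vrp = -vr;
      E.n_reflect++;
    } else {
      double s = vr * vr - 2.0 * dU / mu;
      vrp = (inward ? -1.0 : 1.0) * std::sqrt(s);
      E.pe += dU;
      E.n_cross++;
      if (will_react) {
        E.hb_react(i, j, donor);
        E.n_hb_form++;
      } else if (will_break) {
        E.hb_unreact(i, j);
        E.n_hb_break++;
      }
    }
    double dvr = vrp - vr;
    for (int k = 0; k < 3; ++k) {
      E.v[3 * i + k] -= mu * dvr * E.invm[i] * nvec[k];
      E.v[3 * j + k] += mu * dvr * E.invm[j] * nvec[k];
    }
    // park the pair at the boundary radius, biased 1e-8 A onto the side
    // consistent with its outgoing radial motion so the piecewise-constant
    // energy is unambiguous at emitted frames (centre of mass fixed)
    double corr = d - rr + (vrp > 0 ? 1e-8 : -1e-8);
    for (int k = 0; k < 3; ++k) {
      E.x[3 * i + k] -= corr * (mu * E.invm[i]) * nvec[k];
      E.x[3 * j + k] += corr * (mu * E.invm[j]) * nvec[k];
    }
    E.cnt[i]++; E.cnt[j]++;
    E.push_next(i, E.t);
    E.push_next(j, E.t);

    n_pair_events++;
    if (emit_every > 0 &&
        (long)(n_pair_events) % (long)emit_every == 0) emit_frame(E.t);
    if ((double)n_pair_events >= event_budget) done = true;
    if (E.t >= end_time) done = true;
    if (n_pair_events % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  // final frame at the stop time
  if (ft.empty() || ft.back() < E.t - 1e-12) emit_frame(E.t);

  int nf = ft.size();
  // final state (advanced, wrapped)
  NumericMatrix xf(E.n, 3), vf(E.n, 3);
  for (int i = 0; i < E.n; ++i) {
    for (int k = 0; k < 3; ++k) {
      double xx = E.px(i, k, E.t);
      xf(i, k) = xx - E.L * std::floor(xx / E.L);
      vf(i, k) = E.v[3 * i + k];
    }
  }
  std::vector<std::pair<int,int>> reg_rows;
  for (int i = 0; i < E.n; ++i) {
    for (size_t k = 0; k < E.hb_with[i].size(); ++k) {
      int j = E.hb_with[i][k].first;
      if (j <= i) continue;
      int dn = E.hb_with[i][k].second;
      reg_rows.push_back({dn, dn == i ? j : i});
    }
  }
  std::sort(reg_rows.begin(), reg_rows.end());
  IntegerMatrix reg(reg_rows.size(), 2);
  for (size_t r = 0; r < reg_rows.size(); ++r) {
    reg(r, 0) = reg_rows[r].first + 1;  // 1-based for R
    reg(r, 1) = reg_rows[r].second + 1;
  }

  return List::create(
    _["n_frames"] = nf,
    _["frame_x"] = NumericVector(fx.begin(), fx.end()),
    _["frame_v"] = NumericVector(fv.begin(), fv.end()),
    _["frame_time"] = NumericVector(ft.begin(), ft.end()),
    _["frame_ke"] = NumericVector(fke.begin(), fke.end()),
    _["frame_pe"] = NumericVector(fpe.begin(), fpe.end()),
    _["frame_hb_pp"] = NumericVector(fhb_pp.begin(), fhb_pp.end()),
    _["frame_hb_pl"] = NumericVector(fhb_pl.begin(), fhb_pl.end()),
    _["frame_events"] = NumericVector(fnev.begin(), fnev.end()),
    _["x_final"] = xf, _["v_final"] = vf,
    _["time_final"] = E.t,
    _["hb_registry"] = reg,
    _["n_pair_events"] = (double)n_pair_events,
    _["counts"] = NumericVector::create(
      _["cross"] = E.n_cross, _["reflect"] = E.n_reflect,
      _["hb_form"] = E.n_hb_form, _["hb_break"] = E.n_hb_break,
      _["thermostat"] = E.n_thermo, _["refresh"] = E.n_refresh,
      _["stale"] = E.n_stale, _["healed"] = E.n_heal)
  );
}

// Direct O(N^2) energy evaluation; the reference for the engine's
// incremental bookkeeping. `hb_registry` rows are 1-based (donor, acceptor).
// [[Rcpp::export]]
List cpp_total_energy(NumericMatrix x, NumericMatrix v, NumericVector mass,
                      IntegerVector iclass, IntegerVector mol,
                      double box_edge,
                      List pots_in, IntegerVector pots_tail,
                      IntegerMatrix pt_index_in,
                      IntegerVector bond_i, IntegerVector bond_j,
                      IntegerMatrix hb_registry, double hb_eps) {
  int n = x.nrow();
  int nclass = pt_index_in.nrow();
  std::vector<StepPot> pots, pots_intra;
  for (int p = 0; p < pots_in.size(); ++p) {
    List pp = pots_in[p];
    StepPot sp;
    NumericVector rad = pp["radii"], en = pp["energies"];
    sp.radii.assign(rad.begin(), rad.end());
    sp.energies.assign(en.begin(), en.end());
    pots.push_back(sp);
    StepPot si = sp;
    if (pots_tail[p] > 0 && (int)si.radii.size() > 1) {
      si.radii.pop_back();
      si.energies.pop_back();
    }
    pots_intra.push_back(si);
  }
  std::vector<bool> isbond((size_t)n * n, false);
  for (int b = 0; b < bond_i.size(); ++b) {
    int i = bond_i[b], j = bond_j[b];
    isbond[(size_t)i * n + j] = isbond[(size_t)j * n + i] = true;
  }
  double ke = 0.0, pe = 0.0;
  for (int i = 0; i < n; ++i) {
    ke += 0.5 * mass[i] * (v(i, 0) * v(i, 0) + v(i, 1) * v(i, 1) +
                           v(i, 2) * v(i, 2));
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (isbond[(size_t)i * n + j]) continue;
      int idx = pt_index_in(iclass[i], iclass[j]);
      if (idx < 0) continue;
      const StepPot& pt = (mol[i] == mol[j]) ? pots_intra[idx] : pots[idx];
      double r2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = x(j, k) - x(i, k);
        d -= box_edge * std::nearbyint(d / box_edge);
        r2 += d * d;
      }
      double r = std::sqrt(r2);
      if (r < pt.cutoff()) pe += pt.energy(r);
    }
  }
  pe += hb_eps * hb_registry.nrow();
  return List::create(_["kinetic"] = ke, _["potential"] = pe);
}
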