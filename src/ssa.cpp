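// Exact SSA for the reaction-diffusion master equation on a voxel lattice.
//
// Direct-method Gillespie with a two-level channel hierarchy: a Fenwick
// (binary indexed) tree holds one aggregated propensity per voxel; within the
// sampled voxel, channels (reactions, per-direction diffusion hops,
// carrier-facilitated longitudinal transport) are re-enumerated in a fixed
// order. This is exact and O(log n_voxels) per event. Uses R's RNG so that
// set.seed()/.Random.seed give bit-reproducible, checkpointable trajectories.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// neighbor column convention (0-based): 0:+x 1:-x 2:+y 3:-y 4:+z(up) 5:-z(down)
const int DIR_UP = 4;
const int DIR_DOWN = 5;

struct Sim {
  int n_vox, n_sp, n_rx, n_tr;
  std::vector<long long> cnt;          // n_vox * n_sp, voxel-major
  const int* nbr;                      // n_vox x 6, 1-based, 0 = absent
  const int* region;                   // 1 interior, 2 shell
  const int* apex;                     // 0/1
  std::vector<double> D;
  // compact reactions
  std::vector<double> k;
  std::vector<int> restr;              // 0 all, 1 shell, 2 apex
  std::vector<std::vector<int>> rx_sp; // reactant species (0-based)
  std::vector<std::vector<int>> rx_m;  // reactant orders
  std::vector<std::vector<std::pair<int,int>>> rx_delta; // (species, net change)
  // transport rules
  std::vector<int> tr_carrier, tr_cargo, tr_dir; // dir 0 sym, 1 basipetal
  std::vector<double> tr_alpha;
  std::vector<int> diff_sp;            // species with D > 0

  long long& n(int v, int s) { return cnt[(size_t)v * n_sp + s]; }
  long long nn(int v, int s) const { return cnt[(size_t)v * n_sp + s]; }

  bool rx_allowed(int r, int v) const {
    if (restr[r] == 1) return region[v] == 2;
    if (restr[r] == 2) return apex[v] != 0;
    return true;
  }

  double rx_prop(int r, int v) const {
    if (!rx_allowed(r, v)) return 0.0;
    double a = k[r];
    const std::vector<int>& sp = rx_sp[r];
    const std::vector<int>& m = rx_m[r];
    for (size_t i = 0; i < sp.size(); ++i) {
      long long ncount = nn(v, sp[i]);
      for (int j = 0; j < m[i]; ++j) {
        long long f = ncount - j;
        if (f <= 0) return 0.0;
        a *= (double)f;
      }
    }
    return a;
  }

  // facilitated longitudinal propensity of rule t in voxel v toward
  // direction d (DIR_UP or DIR_DOWN); 0 if that neighbor is absent.
  double tr_prop(int t, int v, int d) const {
    if (nbr[(size_t)v + (size_t)d * n_vox] == 0) return 0.0;
    if (tr_dir[t] == 1 && d != DIR_DOWN) return 0.0;
    double share = (tr_dir[t] == 1) ? 1.0 : 0.5;
    return share * tr_alpha[t] * (double)nn(v, tr_carrier[t]) *
           (double)nn(v, tr_cargo[t]);
  }

  double voxel_total(int v) const {
    double a = 0.0;
    for (int r = 0; r < n_rx; ++r) a += rx_prop(r, v);
    for (int s : diff_sp) {
      int deg = 0;
      for (int d = 0; d < 6; ++d)
        if (nbr[(size_t)v + (size_t)d * n_vox] != 0) ++deg;
      a += D[s] * (double)nn(v, s) * deg;
    }
    for (int t = 0; t < n_tr; ++t)
      a += tr_prop(t, v, DIR_UP) + tr_prop(t, v, DIR_DOWN);
    return a;
  }
};

struct Fenwick {
  int n;
  std::vector<double> tree;
  void init(const std::vector<double>& vals) {
    n = (int)vals.size();
    tree.assign(n + 1, 0.0);
    for (int i = 1; i <= n; ++i) {
      tree[i] += vals[i - 1];
      int j = i + (i & -i);
      if (j <= n) tree[j] += tree[i];
    }
  }
  void add(int i, double delta) { // 0-based i
    for (int j = i + 1; j <= n; j += j & -j) tree[j] += delta;
  }
  double total() const {
    double s = 0.0;
    for (int j = n; j > 0; j -= j & -j) s += tree[j];
    return s;
  }
  // largest prefix with cumulative sum < u; returns index (0-based) and
  // leaves the remainder within that element in u.
  int search(double& u) const {
    int pos = 0;
    int logn = 1;
    while ((1 << logn) <= n) ++logn;
    for (int pw = 1 << (logn - 1); pw > 0; pw >>= 1) {
      int next = pos + pw;
      if (next <= n && tree[next] < u) {
        u -= tree[next];
        pos = next;
      }
    }
    return pos < n ? pos : n - 1;
  }
};

} // namespace

// [[Rcpp::export(name = ".ssa_run_cpp")]]
List ssa_run_cpp(IntegerMatrix counts, IntegerMatrix nbr, IntegerVector region,
                 LogicalVector apex, NumericVector D, IntegerMatrix stoich_r,
                 IntegerMatrix stoich_p, NumericVector k, IntegerVector restr,
                 IntegerVector tr_carrier, IntegerVector tr_cargo,
                 NumericVector tr_alpha, IntegerVector tr_dir,
                 double start_time, double start_events, double max_events,
                 double max_time, double snapshot_every, double snapshot_dt,
                 bool log_events, double max_log) {
  Sim S;
  S.n_vox = counts.nrow();
  S.n_sp = counts.ncol();
  S.n_rx = stoich_r.nrow();
  S.n_tr = tr_carrier.size();
  S.cnt.resize((size_t)S.n_vox * S.n_sp);
  for (int v = 0; v < S.n_vox; ++v)
    for (int s = 0; s < S.n_sp; ++s) S.n(v, s) = counts(v, s);
  S.nbr = INTEGER(nbr);
  S.region = INTEGER(region);
  S.apex = LOGICAL(apex);
  S.D.assign(D.begin(), D.end());
  S.k.assign(k.begin(), k.end());
  S.restr.assign(restr.begin(), restr.end());
  S.rx_sp.resize(S.n_rx);
  S.rx_m.resize(S.n_rx);
  S.rx_delta.resize(S.n_rx);
  for (int r = 0; r < S.n_rx; ++r) {
    for (int s = 0; s < S.n_sp; ++s) {
      if (stoich_r(r, s) > 0) {
        S.rx_sp[r].push_back(s);
        S.rx_m[r].push_back(stoich_r(r, s));
      }
      int d = stoich_p(r, s) - stoich_r(r, s);
      if (d != 0) S.rx_delta[r].push_back(std::make_pair(s, d));
    }
  }
  for (int t = 0; t < S.n_tr; ++t) {
    S.tr_carrier.push_back(tr_carrier[t] - 1);
    S.tr_cargo.push_back(tr_cargo[t] - 1);
    S.tr_dir.push_back(tr_dir[t]);
    S.tr_alpha.push_back(tr_alpha[t]);
  }
  for (int s = 0; s < S.n_sp; ++s)
    if (S.D[s] > 0) S.diff_sp.push_back(s);

  std::vector<double> vprop(S.n_vox);
  for (int v = 0; v < S.n_vox; ++v) vprop[v] = S.voxel_total(v);
  Fenwick fw;
  fw.init(vprop);

  double t = start_time;
  double total_events = start_events;
  double events_done = 0.0;

  std::vector<std::vector<int>> snaps;
  std::vector<double> snap_t, snap_ev;
  std::vector<double> log_time;
  std::vector<int> log_vox, log_type, log_idx, log_dir;
  bool log_truncated = false;

  double next_snap_t = (snapshot_dt > 0)
      ? (std::floor(t / snapshot_dt) + 1.0) * snapshot_dt : R_PosInf;
  double next_snap_ev = (snapshot_every > 0)
      ? (std::floor(total_events / snapshot_every) + 1.0) * snapshot_every
      : R_PosInf;

  auto take_snapshot = [&](double at_t) {
    std::vector<int> copy(S.cnt.size());
    for (size_t i = 0; i < S.cnt.size(); ++i) copy[i] = (int)S.cnt[i];
    snaps.push_back(copy);
    snap_t.push_back(at_t);
    snap_ev.push_back(total_events);
  };

  std::string reason = "max_events";
  GetRNGstate();
  long long rebuild_counter = 0;

  while (events_done < max_events) {
    double total = fw.total();
    if (!(total > 0.0)) { reason = "absorbing"; break; }
    double dt = exp_rand() / total;
    double t_new = t + dt;
    while (snapshot_dt > 0 && next_snap_t <= t_new &&
           next_snap_t <= max_time) {
      take_snapshot(next_snap_t);
      next_snap_t += snapshot_dt;
    }
    if (t_new > max_time) { t = max_time; reason = "max_time"; break; }
    t = t_new;

    double u = unif_rand() * total;
    int v = fw.search(u); // u now remainder within voxel v

    // enumerate channels of voxel v in fixed order
    int type = -1, idx = -1, dir = -1;
    double a = 0.0;
    for (int r = 0; r < S.n_rx && type < 0; ++r) {
      a = S.rx_prop(r, v);
      if (a > 0.0 && u < a) { type = 0; idx = r; }
      else u -= a;
    }
    if (type < 0) {
      for (size_t si = 0; si < S.diff_sp.size() && type < 0; ++si) {
        int s = S.diff_sp[si];
        double per = S.D[s] * (double)S.nn(v, s);
        if (per <= 0.0) continue;
        for (int d = 0; d < 6 && type < 0; ++d) {
          if (S.nbr[(size_t)v + (size_t)d * S.n_vox] == 0) continue;
          if (u < per) { type = 1; idx = s; dir = d; }
          else u -= per;
        }
      }
    }
    if (type < 0) {
      for (int tr = 0; tr < S.n_tr && type < 0; ++tr) {
        for (int d = DIR_UP; d <= DIR_DOWN && type < 0; ++d) {
          a = S.tr_prop(tr, v, d);
          if (a <= 0.0) continue;
          if (u < a) { type = 2; idx = tr; dir = d; }
          else u -= a;
        }
      }
    }
    if (type < 0) {
      // floating-point spill past the last channel: take the last positive
      // channel (transport, then diffusion, then reaction order reversed)
      for (int tr = S.n_tr - 1; tr >= 0 && type < 0; --tr)
        for (int d = DIR_DOWN; d >= DIR_UP && type < 0; --d)
          if (S.tr_prop(tr, v, d) > 0.0) { type = 2; idx = tr; dir = d; }
      for (int si = (int)S.diff_sp.size() - 1; si >= 0 && type < 0; --si) {
        int s = S.diff_sp[si];
        if (S.D[s] * (double)S.nn(v, s) <= 0.0) continue;
        for (int d = 5; d >= 0 && type < 0; --d)
          if (S.nbr[(size_t)v + (size_t)d * S.n_vox] != 0) {
            type = 1; idx = s; dir = d;
          }
      }
      for (int r = S.n_rx - 1; r >= 0 && type < 0; --r)
        if (S.rx_prop(r, v) > 0.0) { type = 0; idx = r; }
      if (type < 0) { // voxel propensity was stale zero; rebuild and retry
        for (int w = 0; w < S.n_vox; ++w) vprop[w] = S.voxel_total(w);
        fw.init(vprop);
        continue;
      }
    }

    // apply the event
    if (type == 0) {
      const std::vector<std::pair<int,int>>& del = S.rx_delta[idx];
      for (size_t i = 0; i < del.size(); ++i)
        S.n(v, del[i].first) += del[i].second;
      double np = S.voxel_total(v);
      fw.add(v, np - vprop[v]);
      vprop[v] = np;
    } else {
      int w = S.nbr[(size_t)v + (size_t)dir * S.n_vox] - 1;
      int s = (type == 1) ? idx : S.tr_cargo[idx];
      S.n(v, s) -= 1;
      S.n(w, s) += 1;
      double np = S.voxel_total(v);
      fw.add(v, np - vprop[v]);
      vprop[v] = np;
      np = S.voxel_total(w);
      fw.add(w, np - vprop[w]);
      vprop[w] = np;
    }

    events_done += 1.0;
    total_events += 1.0;

    if (log_events) {
      if ((double)log_time.size() < max_log) {
        log_time.push_back(t);
        log_vox.push_back(v + 1);
        log_type.push_back(type);
        log_idx.push_back(idx + 1);
        log_dir.push_back(dir + 1);
      } else {
        log_truncated = true;
      }
    }
    if (total_events >= next_snap_ev) {
      take_snapshot(t);
      next_snap_ev += snapshot_every;
    }
    if ((++rebuild_counter & 0xFFFFFLL) == 0) { // periodic drift control
      for (int w = 0; w < S.n_vox; ++w) vprop[w] = S.voxel_total(w);
      fw.init(vprop);
    }
    if ((rebuild_counter & 0x3FFFFFLL) == 0) checkUserInterrupt();
  }
  PutRNGstate();

  IntegerMatrix out_counts(S.n_vox, S.n_sp);
  for (int v = 0; v < S.n_vox; ++v)
    for (int s = 0; s < S.n_sp; ++s) out_counts(v, s) = (int)S.nn(v, s);

  List snap_list(snaps.size());
  for (size_t i = 0; i < snaps.size(); ++i) {
    IntegerMatrix m(S.n_vox, S.n_sp);
    for (int v = 0; v < S.n_vox; ++v)
      for (int s = 0; s < S.n_sp; ++s)
        m(v, s) = snaps[i][(size_t)v * S.n_sp + s];
    snap_list[i] = m;
  }

  List log;
  if (log_events) {
    log = List::create(_["time"] = NumericVector(log_time.begin(), log_time.end()),
                       _["voxel"] = IntegerVector(log_vox.begin(), log_vox.end()),
                       _["type"] = IntegerVector(log_type.begin(), log_type.end()),
                       _["index"] = IntegerVector(log_idx.begin(), log_idx.end()),
                       _["dir"] = IntegerVector(log_dir.begin(), log_dir.end()));
  }

  return List::create(
    _["counts"] = out_counts,
    _["time"] = t,
    _["events"] = total_events,
    _["events_done"] = events_done,
    _["reason"] = reason,
    _["snap_times"] = NumericVector(snap_t.begin(), snap_t.end()),
    _["snap_events"] = NumericVector(snap_ev.begin(), snap_ev.end()),
    _["snapshots"] = snap_list,
    _["event_log"] = log,
    _["log_truncated"] = log_truncated
  );
}
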