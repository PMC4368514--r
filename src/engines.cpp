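// Simulation kernels shared by the deterministic and stochastic engines.
//
// A compiled reaction network is passed down from R as flat arrays:
//   rate      R x N matrix of per-subvolume rate constants (already converted
//             to per-event units; position dependence encodes the static Bcd
//             field and the lumped basal activation channel)
//   re1, re2  reactant species indices (0-based; -1 = absent, so zeroth- and
//             first-order channels are expressed by dropping reactants)
//   st_*      flattened stoichiometry (species index + delta per reaction)
//   dif_*     diffusing species and their per-neighbour jump rates
//   nb_*      flattened subvolume neighbour lists (reflecting boundaries are
//             encoded simply by absent neighbours)

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-free splittable RNG: splitmix64 seeding + xoshiro256++ stream.
// One generator per replicate keeps ensembles order-independent.
// ---------------------------------------------------------------------------
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t w = z;
      w = (w ^ (w >> 30)) * 0xbf58476d1ce4e5b9ULL;
      w = (w ^ (w >> 27)) * 0x94d049bb133111ebULL;
      s[i] = w ^ (w >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0,1); never exactly 0 so log() is safe
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double expdraw() { return -std::log(unif()); }
};

// indexed 4-ary min-heap over subvolume next-event times
struct EventHeap {
  std::vector<double> tau;
  std::vector<int> heap, pos;
  int n;
  explicit EventHeap(int N) : tau(N), heap(N), pos(N), n(N) {
    for (int i = 0; i < N; ++i) { heap[i] = i; pos[i] = i; }
  }
  inline void swap_nodes(int a, int b) {
    std::swap(heap[a], heap[b]);
    pos[heap[a]] = a; pos[heap[b]] = b;
  }
  void sift_up(int k) {
    while (k > 0) {
      int p = (k - 1) >> 2;
      if (tau[heap[k]] < tau[heap[p]]) { swap_nodes(k, p); k = p; } else break;
    }
  }
  void sift_down(int k) {
    for (;;) {
      int c0 = 4 * k + 1;
      if (c0 >= n) break;
      int m = k;
      int cend = c0 + 4 < n ? c0 + 4 : n;
      for (int c = c0; c < cend; ++c)
        if (tau[heap[c]] < tau[heap[m]]) m = c;
      if (m == k) break;
      swap_nodes(k, m); k = m;
    }
  }
  void build() { for (int k = n - 1; k >= 0; --k) sift_down(k); }
  inline int top() const { return heap[0]; }
  void update(int i, double t) {
    double old = tau[i]; tau[i] = t;
    if (t < old) sift_up(pos[i]); else sift_down(pos[i]);
  }
};

const double INF = std::numeric_limits<double>::infinity();

} // namespace

// ---------------------------------------------------------------------------
// Next-subvolume method: statistically exact SSA over reaction + diffusion
// events. Snapshots are the state at the last event before each record time.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".nsm_cpp")]]
List nsm_cpp(IntegerMatrix state0, NumericMatrix rate,
             IntegerVector re1, IntegerVector re2,
             IntegerVector st_ptr, IntegerVector st_sp, IntegerVector st_delta,
             IntegerVector dif_sp, NumericVector dif_rate,
             IntegerVector nb_ptr, IntegerVector nb_idx,
             NumericVector record, double seed, int max_log = 0) {
  const int S = state0.nrow(), N = state0.ncol();
  const int R = rate.nrow(), T = record.size(), K = dif_sp.size();
  if (rate.ncol() != N) stop("rate matrix does not match lattice size");

  std::vector<int> x(state0.begin(), state0.end()); // S x N column-major
  std::vector<double> a((size_t)R * N), asum(N, 0.0), dsum(N, 0.0);
  std::vector<int> deg(N);
  for (int i = 0; i < N; ++i) deg[i] = nb_ptr[i + 1] - nb_ptr[i];

  // species -> diffusion channel
  std::vector<int> difmap(S, -1);
  for (int k = 0; k < K; ++k) difmap[dif_sp[k]] = k;

  // species -> dependent reactions (within one subvolume)
  std::vector<std::vector<int>> dep(S);
  for (int r = 0; r < R; ++r) {
    if (re1[r] >= 0) dep[re1[r]].push_back(r);
    if (re2[r] >= 0 && re2[r] != re1[r]) dep[re2[r]].push_back(r);
  }

  const double *ratep = rate.begin();
  auto prop = [&](int r, int i) -> double {
    double v = ratep[(size_t)r + (size_t)R * i];
    if (v == 0.0) return 0.0;
    if (re1[r] >= 0) v *= x[(size_t)re1[r] + (size_t)S * i];
    if (re2[r] >= 0) v *= x[(size_t)re2[r] + (size_t)S * i];
    return v;
  };
  auto refresh = [&](int i) {
    double sa = 0.0;
    for (int r = 0; r < R; ++r) { double v = prop(r, i); a[(size_t)r + (size_t)R * i] = v; sa += v; }
    asum[i] = sa;
    double sd = 0.0;
    for (int k = 0; k < K; ++k) sd += dif_rate[k] * x[(size_t)dif_sp[k] + (size_t)S * i];
    dsum[i] = sd * deg[i];
  };
  for (int i = 0; i < N; ++i) refresh(i);

  Xoshiro rng((uint64_t)seed);
  EventHeap hp(N);
  for (int i = 0; i < N; ++i) {
    double tot = asum[i] + dsum[i];
    hp.tau[i] = (tot > 0.0) ? rng.expdraw() / tot : INF;
  }
  hp.build();

  IntegerVector snaps((R_xlen_t)S * N * T);
  NumericVector evlog(max_log > 0 ? max_log : 0);
  int rec = 0, nlog = 0;
  long long nevents = 0;
  double t = 0.0;

  auto take_snaps_until = [&](double tnext) {
    while (rec < T && record[rec] < tnext) {
      std::copy(x.begin(), x.end(), snaps.begin() + (R_xlen_t)S * N * rec);
      ++rec;
    }
  };

  // helper: after species s changed by delta in subvolume i, update
  // dependent reaction propensities and the diffusion sum
  auto touch = [&](int i, int s, int delta) {
    for (int r : dep[s]) {
      size_t idx = (size_t)r + (size_t)R * i;
      double old = a[idx], nv = prop(r, i);
      a[idx] = nv; asum[i] += nv - old;
    }
    int k = difmap[s];
    if (k >= 0) dsum[i] += dif_rate[k] * deg[i] * delta;
  };

  while (rec < T) {
    int i = hp.top();
    double tnext = hp.tau[i];
    take_snaps_until(tnext);
    if (rec >= T) break;
    if (!std::isfinite(tnext)) { // system exhausted; remaining snaps = current state
      while (rec < T) {
        std::copy(x.begin(), x.end(), snaps.begin() + (R_xlen_t)S * N * rec);
        ++rec;
      }
      break;
    }
    t = tnext;
    ++nevents;
    if (max_log > 0 && nlog < max_log) evlog[nlog++] = t;

    double tot = asum[i] + dsum[i];
    double u = rng.unif() * tot;
    if (u < asum[i] || dsum[i] <= 0.0) {
      // reaction event: linear scan (falls back to last live channel on drift)
      int rsel = -1; double acc = 0.0;
      for (int r = 0; r < R; ++r) {
        double v = a[(size_t)r + (size_t)R * i];
        if (v > 0.0) { acc += v; rsel = r; if (u < acc) break; }
      }
      if (rsel < 0) { refresh(i); double tt = asum[i] + dsum[i];
        hp.update(i, tt > 0 ? t + rng.expdraw() / tt : INF); continue; }
      for (int p = st_ptr[rsel]; p < st_ptr[rsel + 1]; ++p) {
        int s = st_sp[p];
        x[(size_t)s + (size_t)S * i] += st_delta[p];
        if (x[(size_t)s + (size_t)S * i] < 0)
          stop("negative count for species %d in subvolume %d (reaction %d)",
               s + 1, i + 1, rsel + 1);
      }
      for (int p = st_ptr[rsel]; p < st_ptr[rsel + 1]; ++p)
        touch(i, st_sp[p], st_delta[p]);
      double ntot = asum[i] + dsum[i];
      hp.update(i, ntot > 0.0 ? t + rng.expdraw() / ntot : INF);
    } else {
      // diffusion event: pick species by weight, neighbour uniformly
      double v = u - asum[i];
      int ksel = K - 1; double acc = 0.0;
      for (int k = 0; k < K; ++k) {
        double w = dif_rate[k] * x[(size_t)dif_sp[k] + (size_t)S * i] * deg[i];
        acc += w;
        if (v < acc) { ksel = k; break; }
      }
      int s = dif_sp[ksel];
      if (x[(size_t)s + (size_t)S * i] <= 0) { refresh(i);
        double tt = asum[i] + dsum[i];
        hp.update(i, tt > 0 ? t + rng.expdraw() / tt : INF); continue; }
      int j = nb_idx[nb_ptr[i] + (int)(rng.unif() * deg[i]) % deg[i]];
      x[(size_t)s + (size_t)S * i] -= 1;
      x[(size_t)s + (size_t)S * j] += 1;
      touch(i, s, -1);
      double oldj = asum[j] + dsum[j];
      touch(j, s, 1);
      double newj = asum[j] + dsum[j];
      double ntot = asum[i] + dsum[i];
      hp.update(i, ntot > 0.0 ? t + rng.expdraw() / ntot : INF);
      if (oldj > 0.0 && std::isfinite(hp.tau[j]))
        hp.update(j, newj > 0.0 ? t + (hp.tau[j] - t) * oldj / newj : INF);
      else
        hp.update(j, newj > 0.0 ? t + rng.expdraw() / newj : INF);
    }
    // periodic full refresh against floating-point drift in the running sums
    if ((nevents & 0x3FFFFF) == 0) for (int q = 0; q < N; ++q) refresh(q);
  }

  return List::create(_["snapshots"] = snaps,
                      _["n_events"] = (double)nevents,
                      _["event_times"] = evlog,
                      _["n_logged"] = nlog);
}

// ---------------------------------------------------------------------------
// Fixed-step classical RK4 over the mean-field mass-action equations with
// discrete protein diffusion (reflecting ends). Returns status 1 if the
// solution left the admissible region (stiffness guard), letting the R
// wrapper halve dt and retry.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".rk4_cpp")]]
List rk4_cpp(NumericMatrix state0, NumericMatrix rate,
             IntegerVector re1, IntegerVector re2,
             IntegerVector st_ptr, IntegerVector st_sp, IntegerVector st_delta,
             IntegerVector dif_sp, NumericVector dif_rate,
             IntegerVector nb_ptr, IntegerVector nb_idx,
             double t_end, double dt, NumericVector record,
             double neg_tol = 1e-4) {
  const int S = state0.nrow(), N = state0.ncol();
  const int R = rate.nrow(), T = record.size(), K = dif_sp.size();
  const size_t M = (size_t)S * N;

  std::vector<double> x(state0.begin(), state0.end());
  std::vector<double> k1(M), k2(M), k3(M), k4(M), tmp(M);

  // compact per-reaction layout (hoisted out of the Rcpp SEXP wrappers)
  struct Rx { int i1, i2, nst; int sp[4]; double del[4]; };
  std::vector<Rx> rxs(R);
  for (int r = 0; r < R; ++r) {
    Rx &e = rxs[r];
    e.i1 = re1[r]; e.i2 = re2[r];
    e.nst = st_ptr[r + 1] - st_ptr[r];
    if (e.nst > 4) stop("stoichiometry entries per reaction limited to 4");
    for (int p = 0; p < e.nst; ++p) {
      e.sp[p] = st_sp[st_ptr[r] + p];
      e.del[p] = (double)st_delta[st_ptr[r] + p];
    }
  }
  // rate transposed to subvolume-major rows per reaction
  std::vector<double> ratet((size_t)R * N);
  for (int r = 0; r < R; ++r)
    for (int i = 0; i < N; ++i)
      ratet[(size_t)r * N + i] = rate(r, i);
  std::vector<int> nbp(nb_ptr.begin(), nb_ptr.end());
  std::vector<int> nbi(nb_idx.begin(), nb_idx.end());
  std::vector<int> dsp(dif_sp.begin(), dif_sp.end());
  std::vector<double> drt(dif_rate.begin(), dif_rate.end());

  auto rhs = [&](const std::vector<double> &y, std::vector<double> &d) {
    std::fill(d.begin(), d.end(), 0.0);
    const double *yp = y.data();
    double *dp = d.data();
    for (int r = 0; r < R; ++r) {
      const Rx &e = rxs[r];
      const double *rr = &ratet[(size_t)r * N];
      const int i1 = e.i1, i2 = e.i2, nst = e.nst;
      for (int i = 0; i < N; ++i) {
        double v = rr[i];
        if (v == 0.0) continue;
        const double *yi = yp + (size_t)S * i;
        if (i1 >= 0) v *= yi[i1];
        if (i2 >= 0) v *= yi[i2];
        double *di = dp + (size_t)S * i;
        for (int p = 0; p < nst; ++p) di[e.sp[p]] += e.del[p] * v;
      }
    }
    for (int k = 0; k < K; ++k) {
      const int s = dsp[k];
      const double dr = drt[k];
      if (dr == 0.0) continue;
      for (int i = 0; i < N; ++i) {
        const double yi = yp[(size_t)S * i + s];
        double acc = 0.0;
        for (int p = nbp[i]; p < nbp[i + 1]; ++p)
          acc += yp[(size_t)S * nbi[p] + s] - yi;
        dp[(size_t)S * i + s] += dr * acc;
      }
    }
  };

  NumericVector snaps((R_xlen_t)M * T);
  int rec = 0, status = 0;
  const long long nsteps = (long long)std::ceil(t_end / dt - 1e-9);
  long long step = 0;

  auto maybe_record = [&](double tnow) {
    while (rec < T && record[rec] <= tnow + 1e-9) {
      std::copy(x.begin(), x.end(), snaps.begin() + (R_xlen_t)M * rec);
      ++rec;
    }
  };
  maybe_record(0.0);

  for (step = 1; step <= nsteps && rec < T; ++step) {
    rhs(x, k1);
    for (size_t m = 0; m < M; ++m) tmp[m] = x[m] + 0.5 * dt * k1[m];
    rhs(tmp, k2);
    for (size_t m = 0; m < M; ++m) tmp[m] = x[m] + 0.5 * dt * k2[m];
    rhs(tmp, k3);
    for (size_t m = 0; m < M; ++m) tmp[m] = x[m] + dt * k3[m];
    rhs(tmp, k4);
    for (size_t m = 0; m < M; ++m) {
      double v = x[m] + dt / 6.0 * (k1[m] + 2.0 * k2[m] + 2.0 * k3[m] + k4[m]);
      if (v < 0.0) {
        if (v > -neg_tol) v = 0.0; else { status = 1; break; }
      }
      x[m] = v;
    }
    if (status) break;
    if ((step & 0xFF) == 0) {
      for (size_t m = 0; m < M; m += 7)
        if (!std::isfinite(x[m])) { status = 1; break; }
      if (status) break;
    }
    maybe_record((double)step * dt);
  }

  return List::create(_["snapshots"] = snaps, _["status"] = status,
                      _["recorded"] = rec);
}
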