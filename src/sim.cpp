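// Monte Carlo core for the memory-damped Fermi spatial prisoner's dilemma.
//
// Lattice sites are stored 0-based in R's column-major order: site = i + j*L
// for (row i, column j). Strategies are 1 (cooperator) and 0 (defector).
// All randomness is drawn from R's RNG stream via unif_rand(), in a fixed,
// documented order, so trajectories are reproducible from set.seed() and a
// pure-R stepper sharing the stream produces bit-identical lattices.
//
// Draw order per asynchronous elementary update (always three draws):
//   1. u1: focal site  x = floor(u1 * N)
//   2. u2: neighbour   y = neighbours(x)[floor(u2 * k)]   (k = #neighbours,
//          order up, down, left, right)
//   3. u3: accept imitation iff u3 < H * 1/(1 + exp((P_x - P_y)/K))
// Synchronous scheme: agents 0..N-1 in order, two draws each (neighbour,
// accept), payoffs and strategies read from the pre-step lattice.

#include <Rcpp.h>
#include <set>
using namespace Rcpp;

namespace {

struct SimParams {
  double R, S, T, P;       // payoff table (weak dilemma default R=1, P=S=0)
  double K;                // Fermi selection noise, > 0
  double beta;             // memory weight, 0 < beta < 1
  int M;                   // memory length (rounds), >= 0
  double reset_threshold;  // adjacent-switch fraction; >= 1 never resets
  bool periodic;           // periodic vs fixed boundary
  bool stability_self;     // H from the learner (true) or from the model
  bool synchronous;
};

SimParams unpack(const List& p) {
  SimParams s;
  s.R = as<double>(p["R"]);
  s.S = as<double>(p["S"]);
  s.T = as<double>(p["T"]);
  s.P = as<double>(p["P"]);
  s.K = as<double>(p["K"]);
  s.beta = as<double>(p["beta"]);
  s.M = as<int>(p["M"]);
  s.reset_threshold = as<double>(p["reset_threshold"]);
  s.periodic = as<bool>(p["periodic"]);
  s.stability_self = as<bool>(p["stability_self"]);
  s.synchronous = as<bool>(p["synchronous"]);
  return s;
}

inline double pair_payoff(int sx, int sy, const SimParams& pp) {
  if (sx == 1) return (sy == 1) ? pp.R : pp.S;
  return (sy == 1) ? pp.T : pp.P;
}

// von Neumann neighbourhood of (i, j); order up, down, left, right
inline int neighbour_sites(int i, int j, int L, bool periodic, int* out) {
  int cnt = 0;
  if (periodic) {
    out[cnt++] = ((i + L - 1) % L) + j * L;
    out[cnt++] = ((i + 1) % L) + j * L;
    out[cnt++] = i + ((j + L - 1) % L) * L;
    out[cnt++] = i + ((j + 1) % L) * L;
  } else {
    if (i > 0) out[cnt++] = (i - 1) + j * L;
    if (i < L - 1) out[cnt++] = (i + 1) + j * L;
    if (j > 0) out[cnt++] = i + (j - 1) * L;
    if (j < L - 1) out[cnt++] = i + (j + 1) * L;
  }
  return cnt;
}

inline double site_payoff(const IntegerVector& lat, int site, int L,
                          const SimParams& pp) {
  int nb[4];
  int cnt = neighbour_sites(site % L, site / L, L, pp.periodic, nb);
  double tot = 0.0;
  for (int k = 0; k < cnt; ++k) tot += pair_payoff(lat[site], lat[nb[k]], pp);
  return tot;
}

// run length of newest memory entries equal to `cur` (column 0 is newest)
inline int stability_n(const IntegerMatrix& mem, const IntegerVector& len,
                       int agent, int cur) {
  int n = 0, l = len[agent];
  for (int k = 0; k < l; ++k) {
    if (mem(agent, k) == cur) ++n; else break;
  }
  return n;
}

// H = 1 - (1-beta) * n / denom; warm-up denominator is the stored length
// until the buffer is full, so H stays within [beta, 1] from round one.
inline double memory_factor(int n, int eff_len, const SimParams& pp) {
  if (pp.M == 0) return 1.0;
  int denom = (eff_len < pp.M) ? std::max(eff_len, 1) : pp.M;
  return 1.0 - (1.0 - pp.beta) * (double)n / (double)denom;
}

// Fermi acceptance; exp overflow saturates to +Inf giving probability 0
inline double imitation_prob(double px, double py, double H, double K) {
  return H / (1.0 + std::exp((px - py) / K));
}

inline void one_update(IntegerVector& lat, const IntegerMatrix& mem,
                       const IntegerVector& len, int L, int N,
                       const SimParams& pp) {
  int x = (int)(unif_rand() * N);
  if (x >= N) x = N - 1;
  int nb[4];
  int cnt = neighbour_sites(x % L, x / L, L, pp.periodic, nb);
  int k = (int)(unif_rand() * cnt);
  if (k >= cnt) k = cnt - 1;
  int y = nb[k];
  double px = site_payoff(lat, x, L, pp);
  double py = site_payoff(lat, y, L, pp);
  int ref = pp.stability_self ? x : y;
  int n = stability_n(mem, len, ref, lat[ref]);
  double H = memory_factor(n, len[ref], pp);
  double p = imitation_prob(px, py, H, pp.K);
  if (unif_rand() < p) lat[x] = lat[y];
}

void sync_step(IntegerVector& lat, const IntegerMatrix& mem,
               const IntegerVector& len, int L, int N, const SimParams& pp,
               std::vector<double>& pay) {
  for (int s = 0; s < N; ++s) pay[s] = site_payoff(lat, s, L, pp);
  IntegerVector newlat = clone(lat);
  for (int x = 0; x < N; ++x) {
    int nb[4];
    int cnt = neighbour_sites(x % L, x / L, L, pp.periodic, nb);
    int k = (int)(unif_rand() * cnt);
    if (k >= cnt) k = cnt - 1;
    int y = nb[k];
    int ref = pp.stability_self ? x : y;
    int n = stability_n(mem, len, ref, lat[ref]);
    double H = memory_factor(n, len[ref], pp);
    double p = imitation_prob(pay[x], pay[y], H, pp.K);
    if (unif_rand() < p) newlat[x] = lat[y];
  }
  for (int x = 0; x < N; ++x) lat[x] = newlat[x];
}

// push current strategy (newest first), evict oldest, then apply the reset
// policy: clear when adjacent switches exceed reset_threshold * (len - 1)
inline void push_and_reset(IntegerMatrix& mem, IntegerVector& len, int agent,
                           int s, const SimParams& pp) {
  if (pp.M == 0) return;
  int l = std::min(len[agent] + 1, pp.M);
  for (int k = l - 1; k >= 1; --k) mem(agent, k) = mem(agent, k - 1);
  mem(agent, 0) = s;
  len[agent] = l;
  if (l >= 2) {
    int sw = 0;
    for (int k = 0; k + 1 < l; ++k)
      if (mem(agent, k) != mem(agent, k + 1)) ++sw;
    if ((double)sw > pp.reset_threshold * (double)(l - 1)) len[agent] = 0;
  }
}

inline bool homogeneous(const IntegerVector& lat) {
  int s0 = lat[0];
  for (int i = 1; i < lat.size(); ++i)
    if (lat[i] != s0) return false;
  return true;
}

double coop_rate(const IntegerVector& lat) {
  long c = 0;
  for (int i = 0; i < lat.size(); ++i) c += lat[i];
  return (double)c / (double)lat.size();
}

// population mean of n_x / M (the strategy-stability observable; the
// denominator is always M, unlike the memory factor's warm-up rule)
double mean_rho(const IntegerMatrix& mem, const IntegerVector& len,
                const IntegerVector& lat, const SimParams& pp) {
  if (pp.M == 0) return NA_REAL;
  double tot = 0.0;
  int N = lat.size();
  for (int a = 0; a < N; ++a)
    tot += (double)stability_n(mem, len, a, lat[a]) / (double)pp.M;
  return tot / (double)N;
}

void retention(const IntegerVector& prev, const IntegerVector& cur,
               double* pcc, double* pdd) {
  long nc = 0, nd = 0, cc = 0, dd = 0;
  for (int i = 0; i < prev.size(); ++i) {
    if (prev[i] == 1) { ++nc; if (cur[i] == 1) ++cc; }
    else { ++nd; if (cur[i] == 0) ++dd; }
  }
  *pcc = (nc > 0) ? (double)cc / (double)nc : NA_REAL;
  *pdd = (nd > 0) ? (double)dd / (double)nd : NA_REAL;
}

} // namespace

// [[Rcpp::export]]
NumericVector payoffs_cpp(IntegerVector lattice, int L, List params) {
  SimParams pp = unpack(params);
  int N = L * L;
  NumericVector out(N);
  for (int s = 0; s < N; ++s) out[s] = site_payoff(lattice, s, L, pp);
  return out;
}

// [[Rcpp::export]]
IntegerVector elementary_update_cpp(IntegerVector lattice, IntegerMatrix memory,
                                    IntegerVector mem_len, int L, List params) {
  SimParams pp = unpack(params);
  IntegerVector lat = clone(lattice);
  one_update(lat, memory, mem_len, L, L * L, pp);
  return lat;
}

// Runs `steps` Monte Carlo steps; each step is N elementary updates
// (asynchronous) or one simultaneous sweep (synchronous), followed by a
// memory push and reset check for every agent. Observables are recorded
// every `record_every` steps; retention probabilities are lag-1 between
// consecutive recorded lattices. Once the lattice is homogeneous the
// elementary updates are skipped (every update is a guaranteed no-op);
// memory pushes and observables continue so the series stays complete.
// [[Rcpp::export]]
List sim_run_cpp(IntegerVector lattice, IntegerMatrix memory,
                 IntegerVector mem_len, int L, int t0, int steps,
                 int record_every, List params, IntegerVector snapshot_times) {
  SimParams pp = unpack(params);
  int N = L * L;
  IntegerVector lat = clone(lattice);
  IntegerMatrix mem = clone(memory);
  IntegerVector len = clone(mem_len);
  std::vector<double> pay(pp.synchronous ? N : 0);

  int nrec = steps / record_every;
  NumericMatrix series(nrec + 1, 5);
  series(0, 0) = t0;
  series(0, 1) = coop_rate(lat);
  series(0, 2) = mean_rho(mem, len, lat, pp);
  series(0, 3) = NA_REAL;
  series(0, 4) = NA_REAL;

  std::set<int> snap_at(snapshot_times.begin(), snapshot_times.end());
  List snaps;
  CharacterVector snap_names;
  if (snap_at.count(t0)) {
    snaps.push_back(clone(lat));
    snap_names.push_back(std::to_string(t0));
  }

  IntegerVector prev = clone(lat);
  int row = 1;
  for (int s = 1; s <= steps; ++s) {
    if (!homogeneous(lat)) {
      if (pp.synchronous) {
        sync_step(lat, mem, len, L, N, pp, pay);
      } else {
        for (int u = 0; u < N; ++u) one_update(lat, mem, len, L, N, pp);
      }
    }
    for (int a = 0; a < N; ++a) push_and_reset(mem, len, a, lat[a], pp);
    int t = t0 + s;
    if (s % record_every == 0) {
      double pcc, pdd;
      retention(prev, lat, &pcc, &pdd);
      series(row, 0) = t;
      series(row, 1) = coop_rate(lat);
      series(row, 2) = mean_rho(mem, len, lat, pp);
      series(row, 3) = pcc;
      series(row, 4) = pdd;
      prev = clone(lat);
      ++row;
    }
    if (snap_at.count(t)) {
      snaps.push_back(clone(lat));
      snap_names.push_back(std::to_string(t));
    }
    if (s % 200 == 0) Rcpp::checkUserInterrupt();
  }
  snaps.attr("names") = snap_names;
  return List::create(_["lattice"] = lat, _["memory"] = mem, _["len"] = len,
                      _["t"] = t0 + steps, _["series"] = series,
                      _["snapshots"] = snaps);
}
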