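// Event-driven branching-process core.
//
// Each cell carries (alpha, c, s, g): proliferation potential, cycle status
// (0 at birth, +1 division, -1 death), distance in cycle units to the next
// generation boundary, and generation number.  Between generation increments
// the dynamics dalpha/dt = k (alpha_p - alpha) + beta are linear with constant
// coefficients, so alpha(t) and its integral (which drives c and g) have
// closed forms; event times are located by safeguarded Newton on the analytic
// integral.  All randomness flows through one xoshiro256++ stream per clone,
// seeded from (master seed, clone index), so runs are bit-reproducible and
// order-independent across a cohort.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <limits>
#include <queue>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------- RNG -----

struct Rng {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit Rng(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix(seed);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform on (0,1), never exactly 0 or 1
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // Box-Muller (non-caching, deterministic draw order)
  inline double norm() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
};

static inline uint64_t stream_seed(double master, double index) {
  uint64_t x = (uint64_t)(int64_t)master;
  x ^= 0xD1B54A32D192ED03ULL;
  x += (uint64_t)(int64_t)index * 0x9E3779B97F4A7C15ULL;
  return x;
}

// ----------------------------------------------------------- parameters ---

struct Params {
  double g_limit, a_scale;           // programmed proliferation alpha_p
  double kp_sat, kp_rate, kp_lin;    // programmed differentiation k_p
  double beta_mean, beta_sd;         // hormone environment
  int    mut_count;                  // mutations per daughter
  int    mut_family;                 // 0 point-mass, 1 gaussian, 2 mixture
  double mut_value, mut_mean, mut_sd;
  double mix_mean, mix_sd, mix_tail_p, mix_tail_shift, mix_tail_scale;
  double mix_pos_p, mix_pos_shift, mix_pos_scale;
  double inherit_sd, alpha_init;
  double detect, k_floor, max_time;
};

static Params parse_params(const List &par) {
  Params P;
  P.g_limit     = as<double>(par["gLimit"]);
  P.a_scale     = as<double>(par["alphaPScale"]);
  P.kp_sat      = as<double>(par["kpSaturation"]);
  P.kp_rate     = as<double>(par["kpRate"]);
  P.kp_lin      = as<double>(par["kpLinear"]);
  P.beta_mean   = as<double>(par["betaMean"]);
  P.beta_sd     = as<double>(par["betaSd"]);
  P.mut_count   = as<int>(par["mutationsPerDivision"]);
  P.mut_family  = as<int>(par["mutFamily"]);
  P.mut_value   = as<double>(par["mutValue"]);
  P.mut_mean    = as<double>(par["mutMean"]);
  P.mut_sd      = as<double>(par["mutSd"]);
  P.mix_mean    = as<double>(par["mixGaussMean"]);
  P.mix_sd      = as<double>(par["mixGaussSd"]);
  P.mix_tail_p  = as<double>(par["mixTailProb"]);
  P.mix_tail_shift = as<double>(par["mixTailShift"]);
  P.mix_tail_scale = as<double>(par["mixTailScale"]);
  P.mix_pos_p     = as<double>(par["mixPosProb"]);
  P.mix_pos_shift = as<double>(par["mixPosShift"]);
  P.mix_pos_scale = as<double>(par["mixPosScale"]);
  P.inherit_sd  = as<double>(par["inheritanceNoiseSd"]);
  P.alpha_init  = as<double>(par["alphaInitial"]);
  P.detect      = as<double>(par["detectThreshold"]);
  P.k_floor     = as<double>(par["kFloor"]);
  P.max_time    = as<double>(par["maxSimTime"]);
  return P;
}

static inline double alpha_p(int g, const Params &P) {
  return P.a_scale * (P.g_limit - g);
}
static inline double k_p(int g, const Params &P) {
  return P.kp_sat * (1.0 - std::exp(-P.kp_rate * g)) + P.kp_lin * g;
}
static inline double k_of(int g, double msum, const Params &P) {
  double k = k_p(g, P) + msum;
  return (k < P.k_floor) ? P.k_floor : k;
}
static inline double mut_draw(Rng &r, const Params &P) {
  switch (P.mut_family) {
  case 0: return P.mut_value;
  case 1: return P.mut_mean + P.mut_sd * r.norm();
  default: {
    double u = r.unif();
    if (u < P.mix_tail_p)
      return -P.mix_tail_shift + P.mix_tail_scale * std::log(r.unif());
    if (u < P.mix_tail_p + P.mix_pos_p)
      return P.mix_pos_shift - P.mix_pos_scale * std::log(r.unif());
    return P.mix_mean + P.mix_sd * r.norm();
  }
  }
}

// ----------------------------------------------------------- propagation --

// One generation piece: dalpha/dt = k (ap - alpha) + beta with constant k, ap.
struct Piece {
  double a0, astar, k, beta;
  bool k0;
  inline double alpha(double tau) const {
    return k0 ? a0 + beta * tau
              : astar + (a0 - astar) * std::exp(-k * tau);
  }
  inline double integ(double tau) const {   // int_0^tau alpha(u) du
    return k0 ? a0 * tau + 0.5 * beta * tau * tau
              : astar * tau + (a0 - astar) * (1.0 - std::exp(-k * tau)) / k;
  }
};

// Solve integ(tau) = y on [lo, hi] where integ is monotone and the bracket is
// valid; Newton refined, bisection safeguarded.
static double solve_hit(const Piece &pc, double y, double lo, double hi) {
  double flo = pc.integ(lo) - y;
  double x = 0.5 * (lo + hi);
  for (int it = 0; it < 200; ++it) {
    double f = pc.integ(x) - y;
    if ((f < 0) == (flo < 0)) { lo = x; flo = f; } else { hi = x; }
    double d = pc.alpha(x);
    double xn = (d != 0.0) ? x - f / d : 0.5 * (lo + hi);
    if (!(xn > lo && xn < hi)) xn = 0.5 * (lo + hi);
    if (std::fabs(xn - x) < 1e-12 * (1.0 + std::fabs(x))) return xn;
    x = xn;
  }
  return x;
}

struct CellDyn { double t, alpha, c, s; int g; };

// Propagate a live cell to its next fate event or to t_stop.
// Returns 0 censored-at-t_stop, 1 division, 2 death.  st is updated to the
// event state; *k_out (if non-null) receives the k of the piece in force at
// the event.
static int propagate(CellDyn &st, double msum, double beta, const Params &P,
                     double t_stop, double *k_out) {
  for (;;) {
    double tau_max = t_stop - st.t;
    if (tau_max <= 0.0) {
      if (k_out) *k_out = k_of(st.g, msum, P);
      return 0;
    }
    Piece pc;
    pc.k = k_of(st.g, msum, P);
    pc.k0 = (pc.k <= 0.0);
    pc.beta = beta;
    pc.a0 = st.alpha;
    pc.astar = pc.k0 ? 0.0 : alpha_p(st.g, P) + beta / pc.k;

    double ydiv = 1.0 - st.c, ydie = -1.0 - st.c, ybnd = st.s;

    // time at which alpha changes sign (if interior)
    double tz = -1.0;
    if (pc.k0) {
      if (pc.beta != 0.0) {
        double t0 = -pc.a0 / pc.beta;
        if (t0 > 0.0) tz = t0;
      }
    } else {
      double denom = pc.a0 - pc.astar;
      if (denom != 0.0) {
        double ratio = -pc.astar / denom;
        if (ratio > 0.0 && ratio < 1.0) tz = -std::log(ratio) / pc.k;
      }
    }

    double s0 = 0.0;
    int typ = 0;           // 1 div, 2 die, 3 boundary
    double tau = INF, yhit = 0.0;
    int nseg = (tz > 0.0) ? 2 : 1;
    for (int seg = 0; seg < nseg && typ == 0; ++seg) {
      bool last = (seg == nseg - 1);
      double s1 = last ? INF : tz;
      bool inc;
      if (tz > 0.0 && seg == 0) inc = (pc.a0 > 0.0);
      else if (tz > 0.0)        inc = pc.k0 ? (pc.beta > 0.0) : (pc.astar > 0.0);
      else {
        if (pc.a0 != 0.0) inc = (pc.a0 > 0.0);
        else if (pc.k0)   inc = (pc.beta > 0.0);
        else              inc = (pc.astar > 0.0);
      }
      double I0 = pc.integ(s0);
      double L;              // integral value approached at segment end
      if (std::isinf(s1)) {
        if (pc.k0) {
          if (pc.beta != 0.0) L = (pc.beta > 0.0) ? INF : -INF;
          else                L = (pc.a0 > 0.0) ? INF : (pc.a0 < 0.0 ? -INF : I0);
        } else {
          if (pc.astar > 0.0)      L = INF;
          else if (pc.astar < 0.0) L = -INF;
          else                     L = pc.a0 / pc.k;   // finite asymptote
        }
      } else L = pc.integ(s1);

      double y = 0.0; int t_ = 0;
      if (inc) {
        // boundary wins exact ties with division (the new generation begins)
        if (ybnd > I0 && ybnd <= L) { y = ybnd; t_ = 3; }
        if (ydiv > I0 && ydiv <= L && (t_ == 0 || ydiv < y)) { y = ydiv; t_ = 1; }
      } else {
        if (ydie < I0 && ydie >= L) { y = ydie; t_ = 2; }
      }
      if (t_ != 0) {
        double hi = s1;
        if (std::isinf(hi)) {
          double slope = std::max(std::fabs(pc.alpha(s0)), 1e-8);
          hi = s0 + std::max(1e-3, std::fabs(y - I0) / slope);
          int guard = 0;
          while ((inc ? pc.integ(hi) < y : pc.integ(hi) > y) && guard++ < 200)
            hi = s0 + (hi - s0) * 2.0;
        }
        tau = solve_hit(pc, y, s0, hi);
        yhit = y;
        typ = t_;
      }
      s0 = s1;
    }

    if (typ == 0 || tau > tau_max) {   // censored within this piece
      st.alpha = pc.alpha(tau_max);
      st.c += pc.integ(tau_max);
      st.s -= pc.integ(tau_max);
      st.t = t_stop;
      if (k_out) *k_out = pc.k;
      return 0;
    }

    st.t += tau;
    st.alpha = pc.alpha(tau);
    st.c += yhit;
    st.s -= yhit;

    if (typ == 3) {                    // generation boundary
      st.g += 1;
      st.s = 1.0;
      if (st.c >= 1.0) {               // division coincides with the boundary
        st.c = 1.0;
        if (k_out) *k_out = k_of(st.g, msum, P);
        return 1;
      }
      continue;
    }
    if (k_out) *k_out = pc.k;
    if (typ == 1) { st.c = 1.0; return 1; }
    st.c = -1.0; return 2;
  }
}

// ------------------------------------------------------------ clone sim ---

struct QE {                 // queue entry: a cell whose fate is precomputed
  double t;                 // event time
  long   idx;               // creation index (deterministic tie-break)
  int    typ;               // 0 censored, 1 division, 2 death
  double a, s, msum, beta;  // state at the event (inheritable)
  int    g, d;
};
struct QCmp {
  bool operator()(const QE &a, const QE &b) const {
    if (a.t != b.t) return a.t > b.t;
    return a.idx > b.idx;
  }
};

struct CloneOut {
  double peak = 1, lifespan = 0, t_detect = NA_REAL;
  bool tumor = false, censored = false, guard_tripped = false;
  double births = 1, deaths = 0, censored_cells = 0;
  // lineage columns (store mode)
  std::vector<int>    parent, d, g_birth, g_event, fate;
  std::vector<double> t_birth, t_event, a_birth, s_birth, msum, beta,
                      a_event, k_event;
  // N(t) series
  std::vector<double> ser_t, ser_n;
};

static void run_clone(const Params &P, uint64_t rngseed,
                      bool have_phen, double ph_k, double ph_alpha,
                      int ph_g, int ph_d,
                      bool store, bool series, double max_events,
                      double series_budget, CloneOut &out) {
  Rng rng(rngseed);
  std::priority_queue<QE, std::vector<QE>, QCmp> q;
  long n_cells = 0;
  double n_alive = 1;

  auto spawn = [&](long par_idx, int dd, double t0, double a0, double s0,
                   int g0, double ms, double bb) {
    CellDyn st{t0, a0, 0.0, s0, g0};
    double k_ev = NA_REAL;
    int typ = propagate(st, ms, bb, P, P.max_time, &k_ev);
    QE e{st.t, n_cells, typ, st.alpha, st.s, ms, bb, st.g, dd};
    q.push(e);
    if (store) {
      out.parent.push_back((int)(par_idx + 1));   // 1-based, root parent 0
      out.d.push_back(dd);
      out.g_birth.push_back(g0);
      out.g_event.push_back(st.g);
      out.fate.push_back(typ);
      out.t_birth.push_back(t0);
      out.t_event.push_back(st.t);
      out.a_birth.push_back(a0);
      out.s_birth.push_back(s0);
      out.msum.push_back(ms);
      out.beta.push_back(bb);
      out.a_event.push_back(st.alpha);
      out.k_event.push_back(k_ev);
    }
    ++n_cells;
  };

  {
    double beta0 = P.beta_mean + P.beta_sd * rng.norm();
    double a0 = have_phen ? ph_alpha : P.alpha_init;
    int    g0 = have_phen ? ph_g : 1;
    int    d0 = have_phen ? ph_d : 1;
    double ms = have_phen ? (ph_k - k_p(g0, P)) : 0.0;
    spawn(-1, d0, 0.0, a0, 1.0, g0, ms, beta0);
  }
  if (series) { out.ser_t.push_back(0.0); out.ser_n.push_back(1); }
  if (n_alive >= P.detect) {          // degenerate threshold: the root
    out.tumor = true;                  // alone is already a detectable mass
    out.t_detect = 0.0;
    out.lifespan = 0.0;
    return;
  }

  double events = 0, last_t = 0;
  while (!q.empty()) {
    QE e = q.top(); q.pop();
    if (++events > max_events) { out.guard_tripped = true; break; }
    if (e.t > last_t) last_t = e.t;
    if (e.typ == 2) {
      out.deaths += 1; n_alive -= 1;
    } else if (e.typ == 0) {
      out.censored_cells += 1;          // still alive at the time cap
    } else {
      out.births += 2; n_alive += 1;
      for (int i = 0; i < 2; ++i) {
        double a0 = e.a + P.inherit_sd * rng.norm();
        double bb = P.beta_mean + P.beta_sd * rng.norm();
        double ms = e.msum;
        for (int j = 0; j < P.mut_count; ++j) ms += mut_draw(rng, P);
        spawn(e.idx, e.d + 1, e.t, a0, e.s, e.g, ms, bb);
      }
      if (n_alive > out.peak) out.peak = n_alive;
    }
    if (series) {
      if ((double)out.ser_t.size() >= series_budget)
        stop("full N(t) recording refused beyond the series budget of %g "
             "events; use series = FALSE, raise seriesBudget, or "
             "force = TRUE", series_budget);
      out.ser_t.push_back(e.t); out.ser_n.push_back(n_alive);
    }
    if (e.typ == 1 && !out.tumor && n_alive >= P.detect) {
      out.tumor = true;
      out.t_detect = e.t;
      break;                             // mass analyzed at detection
    }
  }
  out.censored = (out.censored_cells > 0) || out.guard_tripped;
  out.lifespan = out.tumor ? out.t_detect
                           : (out.censored ? P.max_time : last_t);
}

// Detection-time phenotypes of all living cells (store mode required).
static void snapshot_cells(const CloneOut &co, const Params &P, double t_ref,
                           std::vector<int> &d, std::vector<int> &g,
                           std::vector<double> &k, std::vector<double> &a) {
  size_t n = co.t_birth.size();
  for (size_t i = 0; i < n; ++i) {
    if (co.t_birth[i] <= t_ref && co.t_event[i] > t_ref) {
      CellDyn st{co.t_birth[i], co.a_birth[i], 0.0, co.s_birth[i],
                 co.g_birth[i]};
      propagate(st, co.msum[i], co.beta[i], P, t_ref, nullptr);
      d.push_back(co.d[i]);
      g.push_back(st.g);
      k.push_back(k_of(st.g, co.msum[i], P));
      a.push_back(st.alpha);
    }
  }
}

static double med(std::vector<double> v) {
  size_t n = v.size();
  if (n == 0) return NA_REAL;
  std::sort(v.begin(), v.end());
  return (n % 2) ? v[n / 2] : 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// ------------------------------------------------------------- exports ----

// [[Rcpp::export]]
List cpp_simulate_clone(List par, double seed, double cloneIndex,
                        Nullable<NumericVector> phenotype,
                        bool series, bool lineage, bool snapshot,
                        double maxEvents, double seriesBudget) {
  Params P = parse_params(par);
  bool have_phen = phenotype.isNotNull();
  double pk = 0, pa = 0; int pg = 1, pd = 1;
  if (have_phen) {
    NumericVector ph(phenotype);
    pk = ph[0]; pa = ph[1]; pg = (int)ph[2]; pd = (int)ph[3];
  }
  bool store = lineage || snapshot;
  CloneOut co;
  run_clone(P, stream_seed(seed, cloneIndex), have_phen, pk, pa, pg, pd,
            store, series, maxEvents, seriesBudget, co);

  List res = List::create(
    _["peak"] = co.peak, _["lifespanMonths"] = co.lifespan,
    _["tumor"] = co.tumor, _["censored"] = co.censored,
    _["guardTripped"] = co.guard_tripped,
    _["timeToDetectionMonths"] = co.t_detect,
    _["births"] = co.births, _["deaths"] = co.deaths,
    _["censoredCells"] = co.censored_cells);
  if (series)
    res["series"] = DataFrame::create(_["time"] = co.ser_t,
                                      _["cells"] = co.ser_n);
  double t_ref = co.tumor ? co.t_detect
                          : (co.censored ? P.max_time : NA_REAL);
  if (snapshot && !ISNA(t_ref)) {
    std::vector<int> sd, sg; std::vector<double> sk, sa;
    snapshot_cells(co, P, t_ref, sd, sg, sk, sa);
    res["snapshot"] = DataFrame::create(_["d"] = sd, _["g"] = sg,
                                        _["k"] = sk, _["alpha"] = sa);
  }
  if (lineage) {
    // alive-in-final-mass flag at t_ref (empty mass for extinct clones)
    size_t n = co.t_birth.size();
    LogicalVector alive(n);
    for (size_t i = 0; i < n; ++i)
      alive[i] = !ISNA(t_ref) && co.t_birth[i] <= t_ref &&
                 co.t_event[i] > t_ref;
    res["lineage"] = List::create(
      _["parent"] = co.parent, _["d"] = co.d,
      _["gBirth"] = co.g_birth, _["gEvent"] = co.g_event,
      _["fate"] = co.fate, _["tBirth"] = co.t_birth,
      _["tEvent"] = co.t_event, _["alphaAtEvent"] = co.a_event,
      _["kAtEvent"] = co.k_event, _["alive"] = alive);
  }
  return res;
}

// [[Rcpp::export]]
List cpp_simulate_cohort(List par, double seed, double n,
                         Nullable<NumericVector> phenotype,
                         bool tumorMedians, double maxEvents) {
  Params P = parse_params(par);
  bool have_phen = phenotype.isNotNull();
  double pk = 0, pa = 0; int pg = 1, pd = 1;
  if (have_phen) {
    NumericVector ph(phenotype);
    pk = ph[0]; pa = ph[1]; pg = (int)ph[2]; pd = (int)ph[3];
  }
  R_xlen_t N = (R_xlen_t)n;
  NumericVector peak(N), life(N), tdet(N), medk(N), meda(N), medd(N),
      stem(N);
  LogicalVector tum(N), cen(N);
  for (R_xlen_t j = 0; j < N; ++j) {
    CloneOut co;
    run_clone(P, stream_seed(seed, (double)(j + 1)), have_phen, pk, pa, pg,
              pd, tumorMedians, false, maxEvents, INF, co);
    peak[j] = co.peak;
    life[j] = co.lifespan;
    tum[j] = co.tumor;
    cen[j] = co.censored;
    tdet[j] = co.t_detect;
    medk[j] = meda[j] = medd[j] = stem[j] = NA_REAL;
    if (tumorMedians && co.tumor) {
      std::vector<int> sd, sg; std::vector<double> sk, sa;
      snapshot_cells(co, P, co.t_detect, sd, sg, sk, sa);
      std::vector<double> dd(sd.begin(), sd.end());
      medk[j] = med(sk);
      meda[j] = med(sa);
      medd[j] = med(dd);
      size_t z = 0;
      for (double v : sk) if (v <= 0.0) ++z;
      stem[j] = sk.empty() ? NA_REAL : (double)z / (double)sk.size();
    }
    if (j % 10000 == 9999) Rcpp::checkUserInterrupt();
  }
  return List::create(_["peak"] = peak, _["lifespanMonths"] = life,
                      _["tumor"] = tum, _["censored"] = cen,
                      _["timeToDetectionMonths"] = tdet,
                      _["medianK"] = medk, _["medianAlpha"] = meda,
                      _["medianD"] = medd, _["stemFraction"] = stem);
}

// Single-cell propagation, exposed for oracle tests and trajectory checks.
// state = c(t, alpha, c, s, g); returns the event and end state.
// [[Rcpp::export]]
List cpp_propagate_cell(List par, NumericVector state, double msum,
                        double beta, double tStop) {
  Params P = parse_params(par);
  CellDyn st{state[0], state[1], state[2], state[3], (int)state[4]};
  double k_ev = NA_REAL;
  int typ = propagate(st, msum, beta, P, tStop, &k_ev);
  return List::create(
    _["event"] = (typ == 1 ? "division" : (typ == 2 ? "death" : "censored")),
    _["t"] = st.t, _["alpha"] = st.alpha, _["c"] = st.c, _["s"] = st.s,
    _["g"] = st.g, _["k"] = k_ev);
}

// [[Rcpp::export]]
NumericVector cpp_draw_environment(double n, double mean, double sd,
                                   double seed) {
  Rng rng(stream_seed(seed, 0));
  R_xlen_t N = (R_xlen_t)n;
  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = mean + sd * rng.norm();
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_draw_mutation_effects(double n, List par, double seed) {
  Params P = parse_params(par);
  Rng rng(stream_seed(seed, 0));
  R_xlen_t N = (R_xlen_t)n;
  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = mut_draw(rng, P);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_perturb_alpha(double parentAlpha, double n, double sd,
                                double seed) {
  Rng rng(stream_seed(seed, 0));
  R_xlen_t N = (R_xlen_t)n;
  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = parentAlpha + sd * rng.norm();
  return out;
}

// Post-order descendant-in-final-mass counts from a parent vector (1-based,
// root parent 0; children always have larger index than their parent).
// [[Rcpp::export]]
IntegerVector cpp_descendant_counts(IntegerVector parent,
                                    LogicalVector alive) {
  R_xlen_t n = parent.size();
  IntegerVector cnt(n);
  for (R_xlen_t i = 0; i < n; ++i) cnt[i] = alive[i] ? 1 : 0;
  for (R_xlen_t i = n - 1; i >= 1; --i) {
    int p = parent[i];
    if (p < 1 || p > i) stop("orphan or out-of-order lineage code at node %d",
                             (int)(i + 1));
    cnt[p - 1] += cnt[i];
  }
  return cnt;
}
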