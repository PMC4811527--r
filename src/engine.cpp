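// Core discrete-time engine for the ductal-epithelium agent-based model.
//
// One C++ implementation backs both the exported per-operation kernels
// (hormone waveform, HGF production, repair, AKT update, division hits,
// damage checkpoint) and the full per-day simulation loop, so the R-level
// module surface and the production engine cannot diverge.

#include <Rcpp.h>
#include <cstdint>
#include <array>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: PCG32 (O'Neill). Small, fast, deterministic across platforms; every
// stochastic draw of one simulation goes through a single stream seeded from
// the run seed.
// ---------------------------------------------------------------------------

struct Pcg32 {
  uint64_t state, inc;
  void seed(uint64_t s) {
    // splitmix64 expansion of the user seed into state/stream
    auto sm = [](uint64_t& x) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      return z ^ (z >> 31);
    };
    uint64_t x = s;
    state = sm(x);
    inc = sm(x) | 1ULL;
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double unif() { return (next() >> 5) * (1.0 / 134217728.0); } // 27-bit mantissa in [0,1)
  int below(int n) { return (int)(unif() * n); }                // n small
};

// ---------------------------------------------------------------------------
// Genes (fixed order, used for reporting)
// ---------------------------------------------------------------------------

enum Gene {
  G_BRCA1 = 0, G_P53, G_HER2, G_TGFB_R, G_EGFR, G_RUNX3,
  G_CMYC, G_ESR1, G_TELOMERASE, G_ECADHERIN, G_MMP3, G_CMET,
  N_GENES = 12
};

// ---------------------------------------------------------------------------
// Parameters
// ---------------------------------------------------------------------------

struct Params {
  // endocrine
  double estrogen_base, estrogen_peak, estrogen_luteal;
  double progesterone_base, progesterone_peak;
  // genome
  bool include_cmet;
  // damage
  double d_max, repair_capacity, deficit_brca1, deficit_p53, het_deficit_brca1;
  bool p53_checkpoint;
  double beta, epsilon, senescence_threshold, apoptosis_threshold, damage_ceiling;
  // cells
  double akt_threshold, akt_decay, basal_inflow;
  double amphi_per_er_cell, hgf_max, hgf_half_sat;
  double mitogen_gain_hgf, mitogen_gain_amphi, amphi_half_sat, tgfb_per_density;
  double tgfb_escapable;
  double cmyc_inflow, v1_amphi, v2_estrogen_gain, her2_activation_prob;
  double her2_multiplier, egfr_multiplier, runx3_multiplier;
  double p_er_daughter, differentiation_prob;
  int telomere_initial;
  double baseline_apoptosis, overflow_apoptosis_factor, senescent_clearance;
  int signal_radius, overflow_capacity;
  double invasion_prob, invaded_brake;
  // engine
  int width, n_days;
  double malignancy_fold, hyperplasia_fold;
  double er_positive_threshold, her2_positive_threshold;
};

static double num(const List& cfg, const char* name) {
  if (!cfg.containsElementNamed(name))
    stop("config parameter '%s' missing", name);
  return as<double>(cfg[name]);
}

static Params read_params(const List& cfg) {
  Params p;
  p.estrogen_base = num(cfg, "estrogen_base");
  p.estrogen_peak = num(cfg, "estrogen_peak");
  p.estrogen_luteal = num(cfg, "estrogen_luteal");
  p.progesterone_base = num(cfg, "progesterone_base");
  p.progesterone_peak = num(cfg, "progesterone_peak");
  p.include_cmet = num(cfg, "include_cmet") != 0;
  p.d_max = num(cfg, "d_max");
  p.repair_capacity = num(cfg, "repair_capacity");
  p.deficit_brca1 = num(cfg, "deficit_brca1");
  p.deficit_p53 = num(cfg, "deficit_p53");
  p.het_deficit_brca1 = num(cfg, "het_deficit_brca1");
  p.p53_checkpoint = num(cfg, "p53_checkpoint") != 0;
  p.beta = num(cfg, "beta");
  p.epsilon = num(cfg, "epsilon");
  p.senescence_threshold = num(cfg, "senescence_threshold");
  p.apoptosis_threshold = num(cfg, "apoptosis_threshold");
  p.damage_ceiling = num(cfg, "damage_ceiling");
  if (p.senescence_threshold >= p.apoptosis_threshold)
    stop("senescence_threshold must be below apoptosis_threshold");
  p.akt_threshold = num(cfg, "akt_threshold");
  p.akt_decay = num(cfg, "akt_decay");
  p.basal_inflow = num(cfg, "basal_inflow");
  p.amphi_per_er_cell = num(cfg, "amphi_per_er_cell");
  p.hgf_max = num(cfg, "hgf_max");
  p.hgf_half_sat = num(cfg, "hgf_half_sat");
  p.mitogen_gain_hgf = num(cfg, "mitogen_gain_hgf");
  p.mitogen_gain_amphi = num(cfg, "mitogen_gain_amphi");
  p.amphi_half_sat = num(cfg, "amphi_half_sat");
  p.tgfb_per_density = num(cfg, "tgfb_per_density");
  p.tgfb_escapable = num(cfg, "tgfb_escapable");
  p.cmyc_inflow = num(cfg, "cmyc_inflow");
  p.v1_amphi = num(cfg, "v1_amphi");
  p.v2_estrogen_gain = num(cfg, "v2_estrogen_gain");
  p.her2_activation_prob = num(cfg, "her2_activation_prob");
  p.her2_multiplier = num(cfg, "her2_multiplier");
  p.egfr_multiplier = num(cfg, "egfr_multiplier");
  p.runx3_multiplier = num(cfg, "runx3_multiplier");
  p.p_er_daughter = num(cfg, "p_er_daughter");
  p.differentiation_prob = num(cfg, "differentiation_prob");
  p.telomere_initial = (int)num(cfg, "telomere_initial");
  p.baseline_apoptosis = num(cfg, "baseline_apoptosis");
  p.overflow_apoptosis_factor = num(cfg, "overflow_apoptosis_factor");
  p.senescent_clearance = num(cfg, "senescent_clearance");
  p.signal_radius = (int)num(cfg, "signal_radius");
  p.overflow_capacity = (int)num(cfg, "overflow_capacity");
  p.invasion_prob = num(cfg, "invasion_prob");
  p.invaded_brake = num(cfg, "invaded_brake");
  p.width = (int)num(cfg, "width");
  if (p.width < 10) stop("lattice width below 10 is degenerate");
  p.n_days = (int)num(cfg, "n_days");
  p.malignancy_fold = num(cfg, "malignancy_fold");
  p.hyperplasia_fold = num(cfg, "hyperplasia_fold");
  p.er_positive_threshold = num(cfg, "er_positive_threshold");
  p.her2_positive_threshold = num(cfg, "her2_positive_threshold");
  return p;
}

// ---------------------------------------------------------------------------
// Hormone waveform: piecewise-linear idealized menstrual profile over 28 days.
// Estrogen: follicular baseline, periovulatory peak at day 12, smaller luteal
// plateau days 17-24. Progesterone: near-baseline in the follicular phase,
// broad luteal peak centred on day 21.
// ---------------------------------------------------------------------------

static double interp_anchors(const double* xs, const double* ys, int n, double x) {
  for (int i = 0; i + 1 < n; ++i) {
    if (x >= xs[i] && x <= xs[i + 1]) {
      double t = (x - xs[i]) / (xs[i + 1] - xs[i]);
      return ys[i] + t * (ys[i + 1] - ys[i]);
    }
  }
  return ys[n - 1];
}

static void hormone_tables(const Params& p, double* etab, double* ptab) {
  const double ex[7] = {0, 7, 12, 14, 17, 24, 28};
  const double ey[7] = {p.estrogen_base, p.estrogen_base, p.estrogen_peak,
                        0.3 * p.estrogen_peak, p.estrogen_luteal,
                        p.estrogen_luteal, p.estrogen_base};
  const double px[7] = {0, 13, 16, 21, 24, 27, 28};
  const double py[7] = {p.progesterone_base, p.progesterone_base,
                        0.6 * p.progesterone_peak, p.progesterone_peak,
                        0.6 * p.progesterone_peak, p.progesterone_base,
                        p.progesterone_base};
  for (int d = 0; d < 28; ++d) {
    etab[d] = interp_anchors(ex, ey, 7, (double)d);
    ptab[d] = interp_anchors(px, py, 7, (double)d);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_hormone_table(List cfg) {
  Params p = read_params(cfg);
  double e[28], pr[28];
  hormone_tables(p, e, pr);
  NumericMatrix out(28, 2);
  for (int d = 0; d < 28; ++d) { out(d, 0) = e[d]; out(d, 1) = pr[d]; }
  colnames(out) = CharacterVector::create("estrogen", "progesterone");
  return out;
}

// ---------------------------------------------------------------------------
// Shared per-operation kernels
// ---------------------------------------------------------------------------

// HGF produced by a fibroblast: saturating (Michaelis) response to local
// amphiregulin; zero at zero input.
static inline double hgf_production(double amphi, double hgf_max, double half_sat) {
  if (amphi <= 0) return 0.0;
  return hgf_max * amphi / (amphi + half_sat);
}

// [[Rcpp::export]]
NumericVector cpp_hgf(NumericVector amphi, double hgf_max, double half_sat) {
  NumericVector out(amphi.size());
  for (R_xlen_t i = 0; i < amphi.size(); ++i)
    out[i] = hgf_production(amphi[i], hgf_max, half_sat);
  return out;
}

// Daily repair: fixed capacity, multiplicatively reduced per lost repair
// gene. A single remaining BRCA1 copy is haploinsufficient: a milder
// multiplier applies in the heterozygous state.
static inline double repair_residual(double damage, int brca1_copies, bool p53_null,
                                     const Params& p) {
  double cap = p.repair_capacity;
  if (brca1_copies == 0) cap *= p.deficit_brca1;
  else if (brca1_copies == 1) cap *= p.het_deficit_brca1;
  if (p53_null) cap *= p.deficit_p53;
  double d = damage - cap;
  return d > 0 ? d : 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_repair(NumericVector damage, int brca1_copies, bool p53_null, List cfg) {
  Params p = read_params(cfg);
  NumericVector out(damage.size());
  for (R_xlen_t i = 0; i < damage.size(); ++i)
    out[i] = repair_residual(damage[i], brca1_copies, p53_null, p);
  return out;
}

// Damage checkpoint: 0 = pass, 1 = senescence, 2 = apoptosis.
// P53-null cells bypass the checkpoint entirely.
static inline int checkpoint_code(double damage, bool p53_null, const Params& p) {
  if (p53_null && p.p53_checkpoint) return 0;
  if (damage > p.apoptosis_threshold) return 2;
  if (damage > p.senescence_threshold) return 1;
  return 0;
}

// [[Rcpp::export]]
IntegerVector cpp_checkpoint(NumericVector damage, bool p53_null, List cfg) {
  Params p = read_params(cfg);
  IntegerVector out(damage.size());
  for (R_xlen_t i = 0; i < damage.size(); ++i)
    out[i] = checkpoint_code(damage[i], p53_null, p);
  return out;
}

// Mutation hits received by one division product: a damage-dependent hit,
// P = min(1, beta * unrepaired damage), plus an independent replication error.
static inline int division_hits(double damage, double beta, double epsilon, Pcg32& rng) {
  int n = 0;
  double pd = beta * damage;
  if (pd > 1.0) pd = 1.0;
  if (pd > 0 && rng.unif() < pd) ++n;
  if (epsilon > 0 && rng.unif() < epsilon) ++n;
  return n;
}

// [[Rcpp::export]]
IntegerVector cpp_division_hits(int n, double damage, double beta, double epsilon,
                                int seed) {
  Pcg32 rng;
  rng.seed((uint64_t)seed);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = division_hits(damage, beta, epsilon, rng);
  return out;
}

// Bounded daily damage increment, uniform on [0, d_max].
// [[Rcpp::export]]
NumericVector cpp_daily_damage(int n, double d_max, int seed) {
  Pcg32 rng;
  rng.seed((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.unif() * d_max;
  return out;
}

// Triangular smoothing kernel over lattice columns (edges clamped).
static void smooth_columns(const std::vector<double>& x, std::vector<double>& out,
                           int radius) {
  int w = (int)x.size();
  out.assign(w, 0.0);
  if (radius <= 0) { out = x; return; }
  double wsum = 0;
  for (int k = -radius; k <= radius; ++k) wsum += (radius + 1 - std::abs(k));
  for (int c = 0; c < w; ++c) {
    double s = 0;
    for (int k = -radius; k <= radius; ++k) {
      int j = c + k;
      if (j < 0) j = 0;
      if (j >= w) j = w - 1;
      s += (radius + 1 - std::abs(k)) * x[j];
    }
    out[c] = s / wsum;
  }
}

// [[Rcpp::export]]
NumericVector cpp_smooth_columns(NumericVector x, int radius) {
  std::vector<double> in(x.begin(), x.end()), out;
  smooth_columns(in, out, radius);
  return NumericVector(out.begin(), out.end());
}

// AKT update for one luminal (or myoepithelial) cell. Returns the new AKT.
// er: expresses ER; copies: 12 gene copy numbers; variant: ESR1 variant tag
// (0 none, 1..3) meaningful only when ESR1 is at 0 copies in an ER+ cell.
static inline double akt_update(double akt, bool er, bool myoep, const int8_t* copies,
                                int variant, bool her2_active, double estrogen,
                                double amphi_bar, double hgf, double density_bar,
                                const Params& p) {
  bool runx3_null = copies[G_RUNX3] == 0;
  bool egfr_null = copies[G_EGFR] == 0;
  bool her2_null = her2_active;
  bool tgfb_null = copies[G_TGFB_R] == 0;
  bool cmyc_null = copies[G_CMYC] == 0;
  bool cmet_null = p.include_cmet && copies[G_CMET] == 0;
  bool esr1_null = copies[G_ESR1] == 0;

  double mit = 0.0;
  if (myoep) {
    mit += p.mitogen_gain_hgf * hgf;
  } else if (er) {
    // EGFR-mediated autocrine response saturates in local amphiregulin
    double resp = amphi_bar / (amphi_bar + p.amphi_half_sat);
    mit += p.mitogen_gain_amphi * resp * (runx3_null ? p.runx3_multiplier : 1.0);
    if (cmet_null) mit += p.mitogen_gain_hgf * hgf;  // ER+ cells normally suppress c-Met
  } else {
    mit += p.mitogen_gain_hgf * hgf;
  }
  if (egfr_null) mit *= p.egfr_multiplier;
  if (her2_null) mit *= p.her2_multiplier;

  double inflow = mit + p.basal_inflow;
  if (cmyc_null) inflow += p.cmyc_inflow;  // hormone-independent growth
  if (er && esr1_null) {
    if (variant == 2) inflow += p.v2_estrogen_gain * estrogen;
    if (variant == 3) inflow += 0.5 * p.v2_estrogen_gain * estrogen;
  }
  double inhib = p.tgfb_per_density * density_bar *
                 (tgfb_null ? (1.0 - p.tgfb_escapable) : 1.0);

  double out = akt * (1.0 - p.akt_decay) + inflow - inhib;
  if (out < 0) out = 0;
  if (out > p.akt_threshold) out = p.akt_threshold;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_akt_update(NumericVector akt, LogicalVector er, LogicalVector myoep,
                             IntegerMatrix copies, IntegerVector variant,
                             LogicalVector her2_active, double estrogen,
                             NumericVector amphi_bar, NumericVector hgf,
                             NumericVector density_bar, List cfg) {
  Params p = read_params(cfg);
  int n = akt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int8_t cp[N_GENES];
    for (int g = 0; g < N_GENES; ++g) cp[g] = (int8_t)copies(i, g);
    out[i] = akt_update(akt[i], er[i], myoep[i], cp, variant[i],
                        her2_active[i], estrogen, amphi_bar[i], hgf[i],
                        density_bar[i], p);
  }
  return out;
}

// Amphiregulin produced by one luminal cell per day.
static inline double amphi_production(bool er, bool senescent, const int8_t* copies,
                                      int variant, double estrogen, const Params& p) {
  if (!er || senescent) return 0.0;
  if (copies[G_ESR1] == 0) {
    if (variant == 1) return p.v1_amphi;               // autonomous, estrogen-independent
    if (variant == 3) return 0.5 * p.v1_amphi;         // moderate autonomous output
  }
  return p.amphi_per_er_cell * estrogen;
}

// [[Rcpp::export]]
NumericVector cpp_amphi(LogicalVector er, LogicalVector senescent, IntegerMatrix copies,
                        IntegerVector variant, double estrogen, List cfg) {
  Params p = read_params(cfg);
  int n = er.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int8_t cp[N_GENES];
    for (int g = 0; g < N_GENES; ++g) cp[g] = (int8_t)copies(i, g);
    out[i] = amphi_production(er[i], senescent[i], cp, variant[i], estrogen, p);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Simulation state
// ---------------------------------------------------------------------------

struct Node {          // one heritable allele-loss event (arena-allocated)
  int32_t parent;      // previous node in the lineage history, -1 at root
  int32_t day;
  int16_t ord;         // 1-based position in the lineage history
  int8_t gene;
  int8_t variant;      // ESR1 variant tag, 0 otherwise
};

struct CellA {
  double akt, damage;
  int32_t hist;        // arena index of latest mutation event, -1 = none
  int16_t col;
  int16_t telomere;
  int16_t nmut;        // history length
  int8_t layer;        // 0 adhered luminal, 1 overflow band, 2 invaded (sub-membrane)
  int8_t variant;
  bool er, senescent, alive, her2_active;
};

struct Simulation {
  Params p;
  Pcg32 rng;
  int group;           // 0 wild-type, 1 BRCA1 carrier
  int seed;
  int day;
  int baseline;
  bool breach;
  bool stopped;        // malignancy declared
  int event_day;       // day malignancy declared (1-based), -1 otherwise
  int census;
  long long total_divisions;
  std::vector<CellA> cells;
  std::vector<Node> arena;
  std::vector<int> adh;          // per-column adhered cell index, -1 free
  std::vector<int> over_count;   // per-column overflow occupancy
  int invaded_count;             // cells below the membrane
  double etab[28], ptab[28];
  // structural layers: inert homeostatic compartments carrying genomes
  int8_t fibro_copies[N_GENES], myo_copies[N_GENES];
  // logging
  bool log_census;
  std::vector<int> log_day, log_n;
  std::vector<double> log_er, log_her2;
  std::vector<int> log_breach;
  bool trace;
  // division trace: day, parent hist before, parent hist after, daughter hist,
  // parent index, parent telomere after, daughter telomere
  std::vector<int> tr_day, tr_pbefore, tr_pafter, tr_dhist, tr_ptel, tr_dtel;
  // reusable per-day buffers
  std::vector<int> order;
  std::vector<double> bufA, bufAbar, bufdens, bufdensbar, bufidens, bufidensbar, bufHGF;
  int n_dead;

  void init(const List& cfg, int group_, int seed_) {
    p = read_params(cfg);
    group = group_;
    seed = seed_;
    rng.seed((uint64_t)(uint32_t)seed_ * 2654435761ULL + 0x1234ABCDULL);
    hormone_tables(p, etab, ptab);
    day = 0;
    breach = false;
    stopped = false;
    event_day = -1;
    total_divisions = 0;
    log_census = false;
    trace = false;
    int w = p.width;
    adh.assign(w, -1);
    over_count.assign(w, 0);
    invaded_count = 0;
    cells.clear();
    cells.reserve(4096);
    arena.clear();
    n_dead = 0;
    for (int g = 0; g < N_GENES; ++g) {
      fibro_copies[g] = 2;
      myo_copies[g] = 2;
    }
    if (group == 1) { fibro_copies[G_BRCA1] = 1; myo_copies[G_BRCA1] = 1; }
    int n_er = 0;
    for (int c = 0; c < w; ++c) {
      CellA cell;
      cell.col = (int16_t)c;
      cell.layer = 0;
      // deterministic even spacing of the initial ER+ complement
      bool er = std::floor((c + 1) * p.p_er_daughter) > std::floor(c * p.p_er_daughter);
      cell.er = er;
      if (er) ++n_er;
      cell.senescent = false;
      cell.alive = true;
      cell.telomere = (int16_t)p.telomere_initial;
      cell.akt = rng.unif() * p.akt_threshold;  // desynchronized start
      cell.damage = 0.0;
      cell.hist = -1;
      cell.nmut = 0;
      cell.variant = 0;
      cell.her2_active = false;
      adh[c] = (int)cells.size();
      cells.push_back(cell);
    }
    baseline = w;
    census = w;
    (void)n_er;
  }

  inline bool gene_null(const CellA& cell, int gene) const {
    return cell_copies(cell, gene) == 0;
  }

  // copy numbers are a pure function of group + lineage history; cache per cell
  // would cost memory churn at division, so each cell stores them directly.
  std::vector<std::array<int8_t, N_GENES>> copies_store;

  // -- copies are stored per cell in a parallel vector ----------------------
  inline int cell_copies(const CellA& cell, int gene) const {
    return copies_store[&cell - cells.data()][gene];
  }

  void init_copies() {
    copies_store.assign(cells.size(), initial_copies());
  }

  std::array<int8_t, N_GENES> initial_copies() const {
    std::array<int8_t, N_GENES> cp;
    cp.fill(2);
    if (group == 1) cp[G_BRCA1] = 1;
    return cp;
  }

  // apply one uniform-gene hit to a cell; absorbed when the gene is already
  // at 0 copies (no functional meaning, not recorded in the lineage history)
  void apply_hit(int idx) {
    int n_target = p.include_cmet ? N_GENES : N_GENES - 1;
    int g = rng.below(n_target);
    auto& cp = copies_store[idx];
    if (cp[g] == 0) return;
    cp[g]--;
    CellA& cell = cells[idx];
    int8_t var = 0;
    if (g == G_ESR1 && cp[g] == 0) {
      double u = rng.unif();
      var = (int8_t)(u < 1.0 / 3 ? 1 : (u < 2.0 / 3 ? 2 : 3));
      cell.variant = var;
    }
    if (g == G_HER2 && cp[g] == 0) {
      if (rng.unif() < p.her2_activation_prob) {
        cell.her2_active = true;
        var = 4;  // activating-variant tag in the event record
      }
    }
    Node nd;
    nd.parent = cell.hist;
    nd.day = day;
    nd.ord = (int16_t)(cell.nmut + 1);
    nd.gene = (int8_t)g;
    nd.variant = var;
    cell.hist = (int32_t)arena.size();
    arena.push_back(nd);
    cell.nmut++;
  }

  // drop dead entries once they dominate the vector (bookkeeping only;
  // the RNG stream and per-day dynamics are unaffected)
  void compact() {
    std::vector<CellA> cells2;
    std::vector<std::array<int8_t, N_GENES>> copies2;
    cells2.reserve(cells.size());
    copies2.reserve(cells.size());
    for (size_t i = 0; i < cells.size(); ++i) {
      if (!cells[i].alive) continue;
      if (cells[i].layer == 0) adh[cells[i].col] = (int)cells2.size();
      cells2.push_back(cells[i]);
      copies2.push_back(copies_store[i]);
    }
    cells.swap(cells2);
    copies_store.swap(copies2);
    n_dead = 0;
  }

  void step() {
    if (stopped || day >= p.n_days) return;
    int w = p.width;
    int cyc = day % 28;
    double E = etab[cyc];

    if (n_dead > 1000 && n_dead > (int)cells.size() / 2) compact();

    // living cell index list, shuffled once per day
    order.clear();
    for (int i = 0; i < (int)cells.size(); ++i)
      if (cells[i].alive) order.push_back(i);
    for (int i = (int)order.size() - 1; i > 0; --i) {
      int j = rng.below(i + 1);
      std::swap(order[i], order[j]);
    }

    // phases 1-2: hormones + signal fields
    std::vector<double>&A = bufA, &Abar = bufAbar, &dens = bufdens,
      &densbar = bufdensbar, &HGF = bufHGF, &idens = bufidens,
      &idensbar = bufidensbar;
    A.assign(w, 0.0); dens.assign(w, 0.0); HGF.assign(w, 0.0); idens.assign(w, 0.0);
    for (int i : order) {
      const CellA& cell = cells[i];
      A[cell.col] += amphi_production(cell.er, cell.senescent,
                                      copies_store[i].data(), cell.variant, E, p);
      if (cell.layer == 2) idens[cell.col] += 1.0;
      else dens[cell.col] += 1.0;
    }
    smooth_columns(A, Abar, p.signal_radius);
    smooth_columns(dens, densbar, p.signal_radius);
    smooth_columns(idens, idensbar, p.signal_radius);
    for (int c = 0; c < w; ++c)
      HGF[c] = hgf_production(Abar[c], p.hgf_max, p.hgf_half_sat);

    // phase 3: damage + repair
    for (int i : order) {
      CellA& cell = cells[i];
      if (p.d_max > 0) cell.damage += rng.unif() * p.d_max;
      if (cell.damage > p.damage_ceiling) cell.damage = p.damage_ceiling;
      cell.damage = repair_residual(cell.damage, cell_copies(cell, G_BRCA1),
                                    gene_null(cell, G_P53), p);
    }

    // phase 4: AKT update
    for (int i : order) {
      CellA& cell = cells[i];
      if (cell.senescent) continue;
      double db = cell.layer == 2 ? p.invaded_brake * idensbar[cell.col]
                                  : densbar[cell.col];
      cell.akt = akt_update(cell.akt, cell.er, false, copies_store[i].data(),
                            cell.variant, cell.her2_active, E, Abar[cell.col],
                            HGF[cell.col], db, p);
    }

    // phase 5: mitosis attempts
    size_t n_before = order.size();
    for (size_t oi = 0; oi < n_before; ++oi) {
      int i = order[oi];
      CellA& cell = cells[i];
      if (!cell.alive || cell.senescent) continue;
      if (cell.akt < p.akt_threshold) continue;
      bool p53n = gene_null(cell, G_P53);
      int chk = checkpoint_code(cell.damage, p53n, p);
      if (chk == 2) { kill(i); continue; }
      if (chk == 1) { cell.senescent = true; continue; }
      bool tel_null = gene_null(cell, G_TELOMERASE);
      if (cell.telomere <= 0 && !tel_null) { cell.senescent = true; continue; }

      // placement: free adhered slot in own/adjacent column first, then the
      // overflow band (anoikis-resistant lineages only survive there)
      int target_col = -1;
      int target_layer = 0;
      int c = cell.col;
      int dir = rng.unif() < 0.5 ? 1 : -1;
      int cand[3] = {c, c + dir, c - dir};
      if (cell.layer == 2) {
        // invaded compartment: no lattice cap; the mass spreads laterally
        // under the membrane (uniform within +/-3 columns)
        int cc = c + rng.below(7) - 3;
        if (cc < 0) cc = 0;
        if (cc >= w) cc = w - 1;
        target_col = cc;
        target_layer = 2;
      } else {
        for (int k = 0; k < 3; ++k) {
          int cc = cand[k];
          if (cc < 0 || cc >= w) continue;
          if (k == 0 && cell.layer == 0) continue;  // own slot occupied by self
          int occ = adh[cc];
          if (occ == -1) { target_col = cc; break; }
          if (cells[occ].senescent) {
            // regenerative displacement of a senescent occupant
            kill(occ);
            adh[cc] = -1;
            target_col = cc;
            break;
          }
        }
        if (target_col == -1 && gene_null(cell, G_ECADHERIN)) {
          for (int k = 0; k < 3; ++k) {
            int cc = cand[k];
            if (cc < 0 || cc >= w) continue;
            if (over_count[cc] < p.overflow_capacity) {
              target_col = cc;
              target_layer = 1;
              break;
            }
          }
        }
        if (target_col == -1) continue;  // contact-inhibited: no room
      }

      // divide
      int32_t pbefore = cell.hist;
      CellA d = cell;
      d.col = (int16_t)target_col;
      d.layer = (int8_t)target_layer;
      d.senescent = false;
      if (!tel_null) { cell.telomere--; d.telomere = cell.telomere; }
      cell.akt = 0.0;
      d.akt = 0.0;
      // daughter cell type: inherited; differentiation (redraw of ER state)
      // occurs only within the organized adhered epithelium — disorganized
      // overflow/invaded growth breeds true
      if (target_layer == 0 && rng.unif() < p.differentiation_prob)
        d.er = rng.unif() < p.p_er_daughter;
      int didx = (int)cells.size();
      cells.push_back(d);
      copies_store.push_back(copies_store[i]);
      if (target_layer == 1) over_count[target_col]++;
      else if (target_layer == 0) adh[target_col] = didx;
      else invaded_count++;
      order.push_back(didx);  // newborn participates in later phases
      total_divisions++;

      // mutation hits, independently per product
      CellA& parent = cells[i];  // re-reference (push_back may reallocate)
      int hp = division_hits(parent.damage, p.beta, p.epsilon, rng);
      for (int h = 0; h < hp; ++h) apply_hit(i);
      int hd = division_hits(cells[didx].damage, p.beta, p.epsilon, rng);
      for (int h = 0; h < hd; ++h) apply_hit(didx);
      // replication dilutes the unrepaired lesion burden between products
      cells[i].damage *= 0.5;
      cells[didx].damage = cells[i].damage;

      if (trace) {
        tr_day.push_back(day);
        tr_pbefore.push_back(pbefore);
        tr_pafter.push_back(cells[i].hist);
        tr_dhist.push_back(cells[didx].hist);
        tr_ptel.push_back(cells[i].telomere);
        tr_dtel.push_back(cells[didx].telomere);
      }
    }

    // phase 6: apoptosis / senescence / anoikis
    for (size_t oi = 0; oi < order.size(); ++oi) {
      int i = order[oi];
      CellA& cell = cells[i];
      if (!cell.alive) continue;
      bool p53n = gene_null(cell, G_P53);
      // anoikis: unadhered cells (overflow band or invaded mass) die unless
      // cell-cell adhesion function is lost
      if (cell.layer >= 1 && !gene_null(cell, G_ECADHERIN)) { kill(i); continue; }
      int chk = checkpoint_code(cell.damage, p53n, p);
      if (chk == 2) { kill(i); continue; }
      if (chk == 1) cell.senescent = true;
      if (cell.senescent) {
        // organized-layer senescent cells persist (they hold their slot until
        // displaced by regeneration); disorganized ones are cleared
        if (cell.layer >= 1 && rng.unif() < p.senescent_clearance) kill(i);
        continue;
      }
      // disorganized masses (overflow band, invaded compartment) have a
      // reduced apoptotic turnover
      double dz = p.baseline_apoptosis *
                  (cell.layer >= 1 ? p.overflow_apoptosis_factor : 1.0);
      if (dz > 0 && rng.unif() < dz) kill(i);
    }

    // phase 7: invasion: capable cells breach the basement membrane and
    // relocate below it; the breach flag is sticky. The invasive mass is
    // founded by the breaching cell(s) of one day and thereafter grows by
    // division - no continued transmigration while it persists.
    if (invaded_count == 0) {
      for (size_t oi = 0; oi < order.size(); ++oi) {
        int i = order[oi];
        CellA& cell = cells[i];
        if (!cell.alive || cell.senescent || cell.layer == 2) continue;
        if (cell_copies(cell, G_MMP3) == 0 && rng.unif() < p.invasion_prob) {
          breach = true;
          if (cell.layer == 0) {
            if (adh[cell.col] == i) adh[cell.col] = -1;
          } else {
            over_count[cell.col]--;
          }
          cell.layer = 2;
          invaded_count++;
        }
      }
    }

    // phase 8: census + malignancy stopping rule
    int n = 0;
    for (size_t oi = 0; oi < order.size(); ++oi)
      if (cells[order[oi]].alive) ++n;
    census = n;
    day++;
    if (log_census) {
      log_day.push_back(day);
      log_n.push_back(n);
      int ner = 0, nher2 = 0;
      for (size_t oi = 0; oi < order.size(); ++oi) {
        const CellA& cell = cells[order[oi]];
        if (!cell.alive) continue;
        if (cell.er) ++ner;
        if (cell.her2_active) ++nher2;
      }
      log_er.push_back(n > 0 ? (double)ner / n : 0.0);
      log_her2.push_back(n > 0 ? (double)nher2 / n : 0.0);
      log_breach.push_back(breach ? 1 : 0);
    }
    if (breach && census > p.malignancy_fold * baseline) {
      stopped = true;
      event_day = day;
    }
  }

  void kill(int i) {
    CellA& cell = cells[i];
    if (!cell.alive) return;
    cell.alive = false;
    n_dead++;
    if (cell.layer == 0) {
      if (adh[cell.col] == i) adh[cell.col] = -1;
    } else if (cell.layer == 1) {
      over_count[cell.col]--;
    } else {
      invaded_count--;
    }
  }

  List result() const {
    int n = 0, ner = 0, nher2 = 0;
    std::unordered_map<int32_t, int> lineage_count;
    for (size_t i = 0; i < cells.size(); ++i) {
      const CellA& cell = cells[i];
      if (!cell.alive) continue;
      ++n;
      if (cell.er) ++ner;
      if (cell.her2_active) ++nher2;
      lineage_count[cell.hist]++;
    }
    // dominant lineage: modal identical-history group, ties to the
    // earliest-created genotype (wild-type root sorts first)
    int32_t best = -1;
    int best_n = -1;
    for (auto& kv : lineage_count) {
      if (kv.second > best_n || (kv.second == best_n && kv.first < best)) {
        best = kv.first;
        best_n = kv.second;
      }
    }
    std::vector<int> h_gene, h_day, h_ord, h_var;
    std::array<int8_t, N_GENES> dom_cp = initial_copies();
    for (int32_t nd = best; nd != -1; nd = arena[nd].parent) {
      h_gene.push_back(arena[nd].gene);
      h_day.push_back(arena[nd].day);
      h_ord.push_back(arena[nd].ord);
      h_var.push_back(arena[nd].variant);
    }
    std::reverse(h_gene.begin(), h_gene.end());
    std::reverse(h_day.begin(), h_day.end());
    std::reverse(h_ord.begin(), h_ord.end());
    std::reverse(h_var.begin(), h_var.end());
    for (int g : h_gene)
      if (dom_cp[g] > 0) dom_cp[g]--;

    int outcome;  // 0 normal, 1 hyperplastic, 2 malignant
    if (stopped) outcome = 2;
    else if (census > p.hyperplasia_fold * baseline) outcome = 1;
    else outcome = 0;

    List out = List::create(
      _["outcome"] = outcome,
      _["event_day"] = event_day,
      _["final_luminal_count"] = census,
      _["baseline_luminal_count"] = baseline,
      _["er_fraction"] = n > 0 ? (double)ner / n : NA_REAL,
      _["her2_fraction"] = n > 0 ? (double)nher2 / n : NA_REAL,
      _["breach"] = breach,
      _["total_mutation_count"] = (int)h_gene.size(),
      _["dominant_lineage_size"] = best_n,
      _["n_events_total"] = (int)arena.size(),
      _["total_divisions"] = (double)total_divisions,
      _["seed"] = seed,
      _["group"] = group,
      _["days_run"] = day,
      _["history_gene"] = IntegerVector(h_gene.begin(), h_gene.end()),
      _["history_day"] = IntegerVector(h_day.begin(), h_day.end()),
      _["history_ordinal"] = IntegerVector(h_ord.begin(), h_ord.end()),
      _["history_variant"] = IntegerVector(h_var.begin(), h_var.end()),
      _["dominant_copies"] = IntegerVector(dom_cp.begin(), dom_cp.end())
    );
    if (log_census) {
      out["census_log"] = List::create(
        _["day"] = IntegerVector(log_day.begin(), log_day.end()),
        _["luminal_count"] = IntegerVector(log_n.begin(), log_n.end()),
        _["er_fraction"] = NumericVector(log_er.begin(), log_er.end()),
        _["her2_fraction"] = NumericVector(log_her2.begin(), log_her2.end()),
        _["breach"] = IntegerVector(log_breach.begin(), log_breach.end())
      );
    }
    if (trace) {
      // full event arena + division log for heritability checks
      int m = (int)arena.size();
      IntegerVector ag(m), ad(m), ao(m), av(m), ap(m);
      for (int i = 0; i < m; ++i) {
        ag[i] = arena[i].gene;
        ad[i] = arena[i].day;
        ao[i] = arena[i].ord;
        av[i] = arena[i].variant;
        ap[i] = arena[i].parent;
      }
      out["arena"] = List::create(_["gene"] = ag, _["day"] = ad, _["ordinal"] = ao,
                                  _["variant"] = av, _["parent"] = ap);
      out["divisions"] = List::create(
        _["day"] = IntegerVector(tr_day.begin(), tr_day.end()),
        _["parent_hist_before"] = IntegerVector(tr_pbefore.begin(), tr_pbefore.end()),
        _["parent_hist_after"] = IntegerVector(tr_pafter.begin(), tr_pafter.end()),
        _["daughter_hist"] = IntegerVector(tr_dhist.begin(), tr_dhist.end()),
        _["parent_telomere"] = IntegerVector(tr_ptel.begin(), tr_ptel.end()),
        _["daughter_telomere"] = IntegerVector(tr_dtel.begin(), tr_dtel.end())
      );
    }
    return out;
  }
};

// ---------------------------------------------------------------------------
// R interface
// ---------------------------------------------------------------------------

static Simulation* make_sim(const List& cfg, int group, int seed) {
  Simulation* s = new Simulation();
  s->init(cfg, group, seed);
  s->init_copies();
  return s;
}

// [[Rcpp::export]]
SEXP ds_sim_new(List cfg, int group, int seed, bool census_log = false,
                bool trace = false) {
  Simulation* s = make_sim(cfg, group, seed);
  s->log_census = census_log;
  s->trace = trace;
  XPtr<Simulation> ptr(s, true);
  return ptr;
}

// [[Rcpp::export]]
int ds_sim_step(SEXP sim, int n_days = 1) {
  XPtr<Simulation> s(sim);
  for (int i = 0; i < n_days && !s->stopped && s->day < s->p.n_days; ++i) s->step();
  return s->day;
}

// [[Rcpp::export]]
List ds_sim_state(SEXP sim) {
  XPtr<Simulation> s(sim);
  return List::create(
    _["day"] = s->day, _["census"] = s->census, _["breach"] = s->breach,
    _["baseline"] = s->baseline, _["stopped"] = s->stopped,
    _["event_day"] = s->event_day, _["n_events_total"] = (int)s->arena.size());
}

// [[Rcpp::export]]
List ds_sim_result(SEXP sim) {
  XPtr<Simulation> s(sim);
  return s->result();
}

// [[Rcpp::export]]
List ds_sim_cells(SEXP sim) {
  XPtr<Simulation> s(sim);
  int n = 0;
  for (const CellA& c : s->cells)
    if (c.alive) ++n;
  IntegerVector col(n), tel(n), nmut(n), layer(n), variant(n);
  NumericVector akt(n), damage(n);
  LogicalVector er(n), sen(n), h2a(n);
  IntegerMatrix copies(n, N_GENES);
  int j = 0;
  for (size_t i = 0; i < s->cells.size(); ++i) {
    const CellA& c = s->cells[i];
    if (!c.alive) continue;
    col[j] = c.col;
    layer[j] = c.layer;
    tel[j] = c.telomere;
    nmut[j] = c.nmut;
    variant[j] = c.variant;
    akt[j] = c.akt;
    damage[j] = c.damage;
    er[j] = c.er;
    sen[j] = c.senescent;
    h2a[j] = c.her2_active;
    for (int g = 0; g < N_GENES; ++g) copies(j, g) = s->copies_store[i][g];
    ++j;
  }
  return List::create(
    _["column"] = col, _["layer"] = layer, _["er"] = er, _["senescent"] = sen,
    _["her2_active"] = h2a, _["telomere"] = tel, _["akt"] = akt,
    _["damage"] = damage, _["n_mutations"] = nmut, _["esr1_variant"] = variant,
    _["copies"] = copies);
}

// [[Rcpp::export]]
List ds_sim_structural(SEXP sim) {
  XPtr<Simulation> s(sim);
  IntegerVector f(N_GENES), m(N_GENES);
  for (int g = 0; g < N_GENES; ++g) {
    f[g] = s->fibro_copies[g];
    m[g] = s->myo_copies[g];
  }
  return List::create(_["fibroblast_copies"] = f, _["myoepithelial_copies"] = m,
                      _["width"] = s->p.width);
}

// Current-day signal fields (recomputed from live occupancy, for inspection
// and locality tests).
// [[Rcpp::export]]
DataFrame ds_sim_signals(SEXP sim) {
  XPtr<Simulation> s(sim);
  int w = s->p.width;
  int cyc = s->day % 28;
  double E = s->etab[cyc];
  std::vector<double> A(w, 0.0), Abar, dens(w, 0.0), densbar;
  for (size_t i = 0; i < s->cells.size(); ++i) {
    const CellA& c = s->cells[i];
    if (!c.alive) continue;
    A[c.col] += amphi_production(c.er, c.senescent, s->copies_store[i].data(),
                                 c.variant, E, s->p);
    dens[c.col] += 1.0;
  }
  smooth_columns(A, Abar, s->p.signal_radius);
  smooth_columns(dens, densbar, s->p.signal_radius);
  NumericVector hgf(w), am(w), ab(w), db(w), tg(w);
  for (int c = 0; c < w; ++c) {
    am[c] = A[c];
    ab[c] = Abar[c];
    hgf[c] = hgf_production(Abar[c], s->p.hgf_max, s->p.hgf_half_sat);
    db[c] = densbar[c];
    tg[c] = s->p.tgfb_per_density * densbar[c];
  }
  return DataFrame::create(_["column"] = seq_len(w) - 1, _["amphiregulin"] = am,
                           _["amphiregulin_smoothed"] = ab, _["hgf"] = hgf,
                           _["density_smoothed"] = db, _["tgfb"] = tg);
}

// [[Rcpp::export]]
List cpp_run_simulation(List cfg, int group, int seed, bool census_log = false,
                        bool trace = false) {
  Simulation s;
  s.init(cfg, group, seed);
  s.init_copies();
  s.log_census = census_log;
  s.trace = trace;
  while (!s.stopped && s.day < s.p.n_days) s.step();
  return s.result();
}
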