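// Stochastic agent-based model of the endothelial-blood interface.
//
// The lattice is a torus of endothelial sites carrying a damage level in
// [0,1] and a non-negative infection level; mobile immune agents
// (macrophages, neutrophils, TH0/TH1/TH2 cells) move over it and fire
// cytokine-production rules whose coefficients come from the Model Rule
// Matrix.  The engine owns its own PRNG (splitmix64) so trajectories are
// bit-reproducible for a given seed independently of R's RNG state and of
// the platform.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// PRNG: splitmix64.  Small, fast, well-distributed, and trivially seedable.
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int randint(int n) { // uniform on 0..n-1
    return (int)(next() % (uint64_t)n);
  }
};

enum Outcome { RUNNING = 0, DIED = 1, HEALED = 2, CENSORED = 3 };

// agent type codes; ENDO fires on damaged lattice sites, not as an agent
enum CellType { MACROPHAGE = 0, NEUTROPHIL = 1, TH0 = 2, TH1 = 3, TH2 = 4,
                N_AGENT_TYPES = 5, ENDOTHELIAL = 5 };

struct Sim {
  int W, H, n, nmed, nrules;
  double step_minutes;

  std::vector<double> damage, infection;
  std::vector<std::vector<double> > fields;       // nmed lattices
  // start-of-step snapshots used as synchronous rule inputs
  std::vector<std::vector<double> > snap_fields;
  std::vector<double> snap_damage, snap_infection;

  std::vector<int> ag_type, ag_pos;

  std::vector<double> M;                 // nrules x (nmed + 2), row-major
  std::vector<int> rule_owner, rule_out;
  std::vector<std::vector<int> > rules_of; // per owner type incl. ENDOTHELIAL

  std::vector<double> diffusion, decay, toxicity, init_fields; // per mediator
  double production_scale, phagocytosis, infection_cap, field_cap;
  int attractant[N_AGENT_TYPES]; // mediator index or -1 (random walk)

  double injury_size, invasiveness, toxigenesis, env_toxicity, resilience;

  double clock_min;
  int outcome;
  double death_min;
  SplitMix rng;

  std::vector<double> traj; // per record: time_h, nmed totals, damage_frac, infection_total

  Sim() : rng(1) {}

  inline int idx(int x, int y) const { return y * W + x; }
  inline void neighbors(int s, int* nb) const {
    int x = s % W, y = s / W;
    nb[0] = idx((x + 1) % W, y);
    nb[1] = idx((x + W - 1) % W, y);
    nb[2] = idx(x, (y + 1) % H);
    nb[3] = idx(x, (y + H - 1) % H);
  }

  double damage_total() const {
    double d = 0; for (int s = 0; s < n; s++) d += damage[s]; return d;
  }
  double infection_total() const {
    double d = 0; for (int s = 0; s < n; s++) d += infection[s]; return d;
  }

  void record() {
    traj.push_back(clock_min / 60.0);
    for (int m = 0; m < nmed; m++) {
      double tot = 0;
      const std::vector<double>& f = fields[m];
      for (int s = 0; s < n; s++) tot += f[s];
      traj.push_back(tot);
    }
    traj.push_back(damage_total() / n);
    traj.push_back(infection_total());
  }

  void check_outcome(double horizon_min) {
    double dfrac = damage_total() / n;
    if (dfrac > 0.8) {
      outcome = DIED; death_min = clock_min;
    } else if (dfrac == 0.0 && infection_total() == 0.0) {
      outcome = HEALED;
    } else if (clock_min >= horizon_min) {
      outcome = CENSORED;
    }
  }

  void snapshot() {
    snap_fields = fields;
    snap_damage = damage;
    snap_infection = infection;
  }

  void step() {
    snapshot();

    // (1) mediator diffusion (4-neighbour) and exponential decay
    int nb[4];
    for (int m = 0; m < nmed; m++) {
      double D = diffusion[m], k = decay[m];
      std::vector<double>& f = fields[m];
      const std::vector<double>& f0 = snap_fields[m];
      for (int s = 0; s < n; s++) {
        neighbors(s, nb);
        double mean4 = 0.25 * (f0[nb[0]] + f0[nb[1]] + f0[nb[2]] + f0[nb[3]]);
        double v = f0[s] + D * (mean4 - f0[s]);
        v *= (1.0 - k);
        f[s] = v > 0 ? v : 0;
      }
    }

    // (2) agent movement: chemotaxis up the attractant gradient, else random
    for (size_t a = 0; a < ag_pos.size(); a++) {
      int s = ag_pos[a], att = attractant[ag_type[a]];
      neighbors(s, nb);
      int target = -1;
      if (att >= 0) {
        const std::vector<double>& f = fields[att];
        double best = f[s];
        int nbest = 0, bests[4];
        for (int j = 0; j < 4; j++) {
          if (f[nb[j]] > best) { best = f[nb[j]]; nbest = 1; bests[0] = nb[j]; }
          else if (nbest > 0 && f[nb[j]] == best) { bests[nbest++] = nb[j]; }
        }
        if (nbest > 0) target = bests[nbest == 1 ? 0 : rng.randint(nbest)];
      }
      if (target < 0) target = nb[rng.randint(4)];
      ag_pos[a] = target;
    }

    // (3) rule firing: rectified linear combination of start-of-step inputs
    //     agents fire their cell type's rules at their site; endothelial
    //     rules fire at every damaged site
    for (size_t a = 0; a < ag_pos.size(); a++) {
      fire_rules(ag_type[a], ag_pos[a]);
    }
    if (!rules_of[ENDOTHELIAL].empty()) {
      for (int s = 0; s < n; s++)
        if (snap_damage[s] > 0) fire_rules(ENDOTHELIAL, s);
    }
    // secretion saturation: concentrations cannot exceed field_cap
    for (int m = 0; m < nmed; m++) {
      std::vector<double>& f = fields[m];
      for (int s = 0; s < n; s++)
        if (f[s] > field_cap) f[s] = field_cap;
    }

    // (4) infection spread, toxigenesis, phagocytosis, cytokine toxicity
    if (invasiveness > 0) {
      for (int s = 0; s < n; s++) {
        neighbors(s, nb);
        double mean4 = 0.25 * (snap_infection[nb[0]] + snap_infection[nb[1]] +
                               snap_infection[nb[2]] + snap_infection[nb[3]]);
        double v = infection[s] + invasiveness * mean4;
        infection[s] = v > infection_cap ? infection_cap : v;
      }
    }
    if (toxigenesis > 0) {
      for (int s = 0; s < n; s++) damage[s] += toxigenesis * infection[s];
    }
    if (phagocytosis > 0) {
      for (size_t a = 0; a < ag_pos.size(); a++) {
        if (ag_type[a] == MACROPHAGE || ag_type[a] == NEUTROPHIL) {
          double v = infection[ag_pos[a]] - phagocytosis;
          infection[ag_pos[a]] = v > 0 ? v : 0;
        }
      }
    }
    // systemic cytokine toxicity: circulating (lattice-mean) levels of the
    // designated toxic mediators damage all tissue uniformly
    for (int m = 0; m < nmed; m++) {
      if (toxicity[m] > 0) {
        const std::vector<double>& f = fields[m];
        double mean = 0;
        for (int s = 0; s < n; s++) mean += f[s];
        mean /= n;
        double inc = toxicity[m] * mean;
        for (int s = 0; s < n; s++) damage[s] += inc;
      }
    }
    for (int s = 0; s < n; s++) {
      if (damage[s] > 1) damage[s] = 1;
      if (damage[s] < 0) damage[s] = 0;
    }

    // (5) repair: damaged-not-dead sites recover at host_resilience; dead
    //     sites regenerate from the frontier (scaled by live 4-neighbours)
    if (resilience > 0) {
      std::vector<char> dead(n);
      for (int s = 0; s < n; s++) dead[s] = damage[s] >= 1.0;
      for (int s = 0; s < n; s++) {
        if (damage[s] <= 0) continue;
        if (!dead[s]) {
          double v = damage[s] - resilience;
          damage[s] = v > 0 ? v : 0;
        } else {
          neighbors(s, nb);
          int live = (!dead[nb[0]]) + (!dead[nb[1]]) + (!dead[nb[2]]) + (!dead[nb[3]]);
          if (live > 0) {
            double v = damage[s] - resilience * live / 4.0;
            damage[s] = v > 0 ? v : 0;
          }
        }
      }
    }

    // (6) environmental re-exposure
    if (env_toxicity > 0 && rng.unif() < env_toxicity) {
      infection[rng.randint(n)] += 1.0;
    }

    clock_min += step_minutes;
    record();
  }

  void fire_rules(int type, int s) {
    const std::vector<int>& rr = rules_of[type];
    for (size_t q = 0; q < rr.size(); q++) {
      int r = rr[q];
      const double* row = &M[(size_t)r * (nmed + 2)];
      double dot = 0;
      for (int m = 0; m < nmed; m++) dot += row[m] * snap_fields[m][s];
      dot += row[nmed] * snap_damage[s];
      dot += row[nmed + 1] * snap_infection[s];
      if (dot > 0) fields[rule_out[r]][s] += dot * production_scale;
    }
  }
};

static Sim* get_sim(SEXP ptr) {
  XPtr<Sim> p(ptr);
  return p.get();
}

// [[Rcpp::export]]
SEXP sim_create(List cfg, NumericMatrix rule_matrix, IntegerVector rule_owner,
                IntegerVector rule_out, List params, int seed) {
  Sim* sim = new Sim();
  sim->W = as<int>(cfg["grid_width"]);
  sim->H = as<int>(cfg["grid_height"]);
  sim->n = sim->W * sim->H;
  sim->step_minutes = as<double>(cfg["step_minutes"]);
  sim->nmed = as<int>(cfg["n_mediators"]);
  sim->nrules = rule_matrix.nrow();

  sim->diffusion = as<std::vector<double> >(cfg["diffusion"]);
  sim->decay = as<std::vector<double> >(cfg["decay"]);
  sim->toxicity = as<std::vector<double> >(cfg["toxicity"]);
  sim->init_fields = as<std::vector<double> >(cfg["init_fields"]);
  sim->production_scale = as<double>(cfg["production_scale"]);
  sim->phagocytosis = as<double>(cfg["phagocytosis"]);
  sim->infection_cap = as<double>(cfg["infection_cap"]);
  sim->field_cap = as<double>(cfg["field_cap"]);
  IntegerVector att = cfg["attractant_index"]; // length 5, 0-based or -1
  for (int i = 0; i < N_AGENT_TYPES; i++) sim->attractant[i] = att[i];

  if (rule_matrix.ncol() != sim->nmed + 2)
    stop("rule matrix must have n_mediators + 2 columns");
  sim->M.assign(rule_matrix.nrow() * rule_matrix.ncol(), 0.0);
  for (int r = 0; r < rule_matrix.nrow(); r++)
    for (int c = 0; c < rule_matrix.ncol(); c++)
      sim->M[(size_t)r * rule_matrix.ncol() + c] = rule_matrix(r, c);
  sim->rule_owner = as<std::vector<int> >(rule_owner);
  sim->rule_out = as<std::vector<int> >(rule_out);
  sim->rules_of.assign(ENDOTHELIAL + 1, std::vector<int>());
  for (int r = 0; r < sim->nrules; r++) {
    int o = sim->rule_owner[r];
    if (o < 0 || o > ENDOTHELIAL) { delete sim; stop("bad rule owner code"); }
    sim->rules_of[o].push_back(r);
  }

  sim->injury_size = as<double>(params["injury_size"]);
  sim->invasiveness = as<double>(params["microbial_invasiveness"]);
  sim->toxigenesis = as<double>(params["microbial_toxigenesis"]);
  sim->env_toxicity = as<double>(params["environmental_toxicity"]);
  sim->resilience = as<double>(params["host_resilience"]);

  sim->rng = SplitMix((uint64_t)(uint32_t)seed * 0x9e3779b97f4a7c15ULL + 0x1234567ULL);

  sim->damage.assign(sim->n, 0.0);
  sim->infection.assign(sim->n, 0.0);
  sim->fields.assign(sim->nmed, std::vector<double>(sim->n, 0.0));
  for (int m = 0; m < sim->nmed; m++)
    if (sim->init_fields[m] != 0)
      std::fill(sim->fields[m].begin(), sim->fields[m].end(), sim->init_fields[m]);

  // contiguous injured patch: sites ranked by squared torus distance from the
  // grid centre (deterministic; ties broken by site index)
  int ninj = (int)std::ceil(sim->injury_size * sim->n);
  if (ninj > sim->n) ninj = sim->n;
  bool infectious = sim->invasiveness > 0 || sim->toxigenesis > 0;
  if (ninj == 0 && infectious)
    { delete sim; stop("infectious injury parameters require a non-empty injured patch"); }
  if (ninj > 0) {
    std::vector<std::pair<double, int> > ord(sim->n);
    double cx = (sim->W - 1) / 2.0, cy = (sim->H - 1) / 2.0;
    for (int s = 0; s < sim->n; s++) {
      double dx = std::fabs(s % sim->W - cx), dy = std::fabs(s / sim->W - cy);
      if (dx > sim->W / 2.0) dx = sim->W - dx;
      if (dy > sim->H / 2.0) dy = sim->H - dy;
      ord[s] = std::make_pair(dx * dx + dy * dy, s);
    }
    std::sort(ord.begin(), ord.end());
    for (int i = 0; i < ninj; i++) {
      sim->damage[ord[i].second] = 1.0;
      if (infectious) sim->infection[ord[i].second] = 1.0;
    }
  }

  // agent placement uniform at random via the seeded stream
  IntegerVector counts = cfg["agent_counts"]; // length 5
  for (int t = 0; t < N_AGENT_TYPES; t++) {
    for (int i = 0; i < counts[t]; i++) {
      sim->ag_type.push_back(t);
      sim->ag_pos.push_back(sim->rng.randint(sim->n));
    }
  }

  sim->clock_min = 0;
  sim->outcome = RUNNING;
  sim->death_min = NA_REAL;
  sim->record();

  XPtr<Sim> ptr(sim, true);
  return ptr;
}

// Pure state advance: outcome/termination rules live in sim_run.
// [[Rcpp::export]]
int sim_step_n(SEXP ptr, int nsteps) {
  Sim* sim = get_sim(ptr);
  for (int i = 0; i < nsteps; i++) sim->step();
  return sim->outcome;
}

// [[Rcpp::export]]
int sim_run(SEXP ptr, double horizon_hours) {
  Sim* sim = get_sim(ptr);
  double horizon_min = horizon_hours * 60.0;
  sim->check_outcome(horizon_min);
  while (sim->outcome == RUNNING) {
    sim->step();
    sim->check_outcome(horizon_min);
  }
  return sim->outcome;
}

// [[Rcpp::export]]
NumericMatrix sim_trajectory(SEXP ptr) {
  Sim* sim = get_sim(ptr);
  int ncol = sim->nmed + 3;
  int nrow = sim->traj.size() / ncol;
  NumericMatrix out(nrow, ncol);
  for (int i = 0; i < nrow; i++)
    for (int j = 0; j < ncol; j++)
      out(i, j) = sim->traj[(size_t)i * ncol + j];
  return out;
}

// [[Rcpp::export]]
List sim_snapshot(SEXP ptr) {
  Sim* sim = get_sim(ptr);
  NumericMatrix dmg(sim->H, sim->W), inf(sim->H, sim->W);
  for (int s = 0; s < sim->n; s++) {
    dmg(s / sim->W, s % sim->W) = sim->damage[s];
    inf(s / sim->W, s % sim->W) = sim->infection[s];
  }
  List flds(sim->nmed);
  for (int m = 0; m < sim->nmed; m++) {
    NumericMatrix f(sim->H, sim->W);
    for (int s = 0; s < sim->n; s++) f(s / sim->W, s % sim->W) = sim->fields[m][s];
    flds[m] = f;
  }
  int na = sim->ag_pos.size();
  IntegerVector atype(na), ax(na), ay(na);
  for (int a = 0; a < na; a++) {
    atype[a] = sim->ag_type[a];
    ax[a] = sim->ag_pos[a] % sim->W;
    ay[a] = sim->ag_pos[a] / sim->W;
  }
  return List::create(
    _["damage"] = dmg, _["infection"] = inf, _["fields"] = flds,
    _["agent_type"] = atype, _["agent_x"] = ax, _["agent_y"] = ay,
    _["clock_hours"] = sim->clock_min / 60.0,
    _["damage_fraction"] = sim->damage_total() / sim->n,
    _["infection_total"] = sim->infection_total(),
    _["outcome"] = sim->outcome,
    _["death_hours"] = ISNA(sim->death_min) ? NA_REAL : sim->death_min / 60.0);
}

// Deterministic integer seed mixing for replicate / candidate streams.
// [[Rcpp::export]]
int hash_seed(int a, int b, int c) {
  SplitMix s(((uint64_t)(uint32_t)a << 40) ^ ((uint64_t)(uint32_t)b << 20) ^
             (uint64_t)(uint32_t)c);
  uint64_t v = s.next();
  return (int)(v % 2147483629ULL) + 1; // in [1, 2^31 - 19]
}
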