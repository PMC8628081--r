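// Individual-based engine: linear genomes of essential genes, transposable
// elements (TEs) and non-coding DNA, evolving on a toroidal grid with an
// extracellular-DNA (eDNA) pool.
//
// Element encoding (one double per genetic element):
//   0            non-coding
//   k in 1..26   essential gene of type k ('a' = 1, ...)
//   v in [-2,-1] TE with transposition rate phi = -v - 1
//
// All randomness is drawn from R's RNG so that set.seed() in R makes every
// run reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

typedef std::vector<double> Gen;

static inline bool el_is_te(double v)  { return v < -0.5; }
static inline bool el_is_ess(double v) { return v > 0.5; }
static inline bool el_is_nc(double v)  { return !el_is_te(v) && !el_is_ess(v); }
static inline double el_phi(double v)  { return -v - 1.0; }
static inline double te_val(double phi){ return -1.0 - phi; }

// uniform integer on 0..(n-1)
static inline int runif_int(int n) {
  int k = (int)(unif_rand() * (double)n);
  return k >= n ? n - 1 : k;
}

struct Rates {
  double single_dup, single_del, inactivation, large_scale, phi_mut, phi_step;
};

static Rates rates_from_list(const List& r) {
  Rates x;
  x.single_dup   = as<double>(r["singleDup"]);
  x.single_del   = as<double>(r["singleDel"]);
  x.inactivation = as<double>(r["inactivation"]);
  x.large_scale  = as<double>(r["largeScale"]);
  x.phi_mut      = as<double>(r["phiMut"]);
  x.phi_step     = as<double>(r["phiStep"]);
  return x;
}

// ---------------------------------------------------------------- fitness

static double fitness_of(const Gen& g, double c, int nfun) {
  int T = 0;
  unsigned seen = 0u;
  for (size_t i = 0; i < g.size(); ++i) {
    double v = g[i];
    if (el_is_te(v)) {
      ++T;
    } else if (el_is_ess(v)) {
      int k = (int)(v + 0.5);
      if (k >= 1 && k <= nfun) seen |= (1u << (k - 1));
    }
  }
  unsigned need = (nfun >= 32) ? ~0u : ((1u << nfun) - 1u);
  if ((seen & need) != need) return 0.0;
  double f = 1.0 - c * (double)T;
  return f < 0.0 ? 0.0 : f;
}

static int te_count(const Gen& g) {
  int T = 0;
  for (size_t i = 0; i < g.size(); ++i) if (el_is_te(g[i])) ++T;
  return T;
}

// ---------------------------------------------------------------- mutation

static double phi_mutate(double phi, double p, double step) {
  if (p > 0.0 && unif_rand() < p) {
    phi += (unif_rand() < 0.5) ? -step : step;
    if (phi < 0.0) phi = 0.0; else if (phi > 1.0) phi = 1.0;
  }
  return phi;
}

// Segment length for large-scale duplication / deletion / inversion:
// uniform integer on [1, max(1, floor(G/2) - 1)], mean G/4 for even G,
// so a single event covers on average a quarter of the genome.
static int seg_len_draw(int G) {
  int m = G / 2 - 1;
  if (m < 1) m = 1;
  return 1 + runif_int(m);
}

// kind: 0 = duplication (tandem), 1 = deletion, 2 = inversion.
// Segment starts at pos (0-based), truncated at the genome end.
static void apply_large(Gen& g, std::vector<char>* skip, int pos, int kind, int L) {
  int G = (int)g.size();
  if (L > G - pos) L = G - pos;
  if (L <= 0) return;
  if (kind == 0) {
    Gen seg(g.begin() + pos, g.begin() + pos + L);
    g.insert(g.begin() + pos + L, seg.begin(), seg.end());
    if (skip) skip->insert(skip->begin() + pos + L, (size_t)L, 1);
  } else if (kind == 1) {
    g.erase(g.begin() + pos, g.begin() + pos + L);
    if (skip) skip->erase(skip->begin() + pos, skip->begin() + pos + L);
  } else {
    std::reverse(g.begin() + pos, g.begin() + pos + L);
    if (skip) std::reverse(skip->begin() + pos, skip->begin() + pos + L);
  }
}

// Replication-time scan: left to right, at most one structural event per
// scanned position (order: large-scale, duplication, deletion, inactivation);
// copies created by duplications are not re-scanned in the same pass.  Every
// surviving TE is offered one phi-mutation (genome replication counts as a
// replication of each TE it carries).
static Gen mutate_gen(const Gen& in, const Rates& r) {
  Gen g(in);
  std::vector<char> skip(g.size(), 0);
  size_t i = 0;
  while (i < g.size()) {
    if (skip[i]) { ++i; continue; }
    bool deleted = false;
    if (r.large_scale > 0.0 && unif_rand() < r.large_scale) {
      int L = seg_len_draw((int)g.size());
      int kind = runif_int(3);
      apply_large(g, &skip, (int)i, kind, L);
      if (kind == 1) deleted = true;
    } else if (r.single_dup > 0.0 && unif_rand() < r.single_dup) {
      double v = g[i];
      g.insert(g.begin() + i + 1, v);
      skip.insert(skip.begin() + i + 1, 1);
    } else if (r.single_del > 0.0 && unif_rand() < r.single_del) {
      g.erase(g.begin() + i);
      skip.erase(skip.begin() + i);
      deleted = true;
    } else if (r.inactivation > 0.0 && unif_rand() < r.inactivation) {
      g[i] = 0.0;
    }
    if (!deleted && i < g.size()) {
      if (el_is_te(g[i]))
        g[i] = te_val(phi_mutate(el_phi(g[i]), r.phi_mut, r.phi_step));
      ++i;
    }
  }
  return g;
}

// ---------------------------------------------------------------- transposition

// Insert a TE at pos (0-based; pos == length appends).  If the displaced
// element is coding (essential gene or TE), it is inactivated with
// probability b.  Returns 0 = no damage, 1 = coding non-essential damaged,
// 2 = essential gene damaged.
static int insert_te_impl(Gen& g, double tev, int pos, double b) {
  int dam = 0;
  bool has_target = pos < (int)g.size();
  double target = has_target ? g[pos] : 0.0;
  g.insert(g.begin() + pos, tev);
  if (has_target && !el_is_nc(target) && b > 0.0 && unif_rand() < b) {
    g[pos + 1] = 0.0;
    dam = el_is_ess(target) ? 2 : 1;
  }
  return dam;
}

// One transposition opportunity per TE present at entry (snapshot of phi
// values), each firing with probability phi * j; copy-and-paste insertion at
// a uniform position, the new copy offered a phi-mutation.
static void lifetime_transposition_impl(Gen& g, double j, double b, const Rates& r) {
  std::vector<double> phis;
  for (size_t k = 0; k < g.size(); ++k)
    if (el_is_te(g[k])) phis.push_back(el_phi(g[k]));
  for (size_t k = 0; k < phis.size(); ++k) {
    double phi = phis[k];
    if (j > 0.0 && phi > 0.0 && unif_rand() < phi * j) {
      double np = phi_mutate(phi, r.phi_mut, r.phi_step);
      int pos = runif_int((int)g.size() + 1);
      insert_te_impl(g, te_val(np), pos, b);
    }
  }
}

// ---------------------------------------------------------------- eDNA

// Fragment a genome left to right into pieces of iid uniform length 3..8;
// a final remainder shorter than the draw is kept as its own fragment.
static void lyse_impl(const Gen& g, std::vector<Gen>& out) {
  size_t i = 0;
  while (i < g.size()) {
    size_t L = (size_t)(3 + runif_int(6));
    if (i + L > g.size()) L = g.size() - i;
    out.push_back(Gen(g.begin() + i, g.begin() + i + L));
    i += L;
  }
}

// Take up one fragment into a genome: each TE it carries integrates with
// probability equal to its own phi, at a uniform position, with insertion
// damage b; integrated copies are offered a phi-mutation.  Non-TE content is
// inert and lost.  Returns number of TEs integrated.
static int integrate_fragment(Gen& g, const Gen& frag, double b, const Rates& r) {
  int n = 0;
  for (size_t k = 0; k < frag.size(); ++k) {
    if (!el_is_te(frag[k])) continue;
    double phi = el_phi(frag[k]);
    if (phi > 0.0 && unif_rand() < phi) {
      double np = phi_mutate(phi, r.phi_mut, r.phi_step);
      int pos = runif_int((int)g.size() + 1);
      insert_te_impl(g, te_val(np), pos, b);
      ++n;
    }
  }
  return n;
}

// ---------------------------------------------------------------- competition

// Fitness-proportional draw among competitors, with probability
// eps / (sum(f) + eps) that nobody wins.  Returns 0-based index or -1.
static int compete_idx(const std::vector<double>& f, double eps) {
  double tot = eps;
  for (size_t k = 0; k < f.size(); ++k) tot += f[k];
  if (tot <= 0.0) return -1;
  double u = unif_rand() * tot;
  double acc = 0.0;
  for (size_t k = 0; k < f.size(); ++k) {
    acc += f[k];
    if (u < acc) return (int)k;
  }
  return -1;
}

// Single cross-over in the middle of both genomes: left floor(L1/2) elements
// of parent 1 + right L2 - floor(L2/2) elements of parent 2.
static Gen crossover_impl(const Gen& a, const Gen& b) {
  Gen c(a.begin(), a.begin() + (a.size() / 2));
  c.insert(c.end(), b.begin() + (b.size() / 2), b.end());
  return c;
}

// ================================================================ exported
// thin wrappers over the same internals the engine uses

// [[Rcpp::export]]
double cpp_fitness(NumericVector genome, double c, int nFunctions) {
  Gen g(genome.begin(), genome.end());
  return fitness_of(g, c, nFunctions);
}

// [[Rcpp::export]]
NumericVector cpp_mutate_genome(NumericVector genome, List rates) {
  Rates r = rates_from_list(rates);
  Gen g(genome.begin(), genome.end());
  Gen out = mutate_gen(g, r);
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
int cpp_draw_segment_length(int genomeLength) {
  return seg_len_draw(genomeLength);
}

// pos 0-based; kind 0 = duplication, 1 = deletion, 2 = inversion;
// segLen < 0 draws the length from the standard distribution
// [[Rcpp::export]]
NumericVector cpp_apply_large_scale(NumericVector genome, int pos, int kind, int segLen) {
  Gen g(genome.begin(), genome.end());
  int L = segLen < 0 ? seg_len_draw((int)g.size()) : segLen;
  apply_large(g, (std::vector<char>*)0, pos, kind, L);
  return NumericVector(g.begin(), g.end());
}

// [[Rcpp::export]]
double cpp_mutate_phi(double phi, double pMut, double step) {
  return phi_mutate(phi, pMut, step);
}

// pos 0-based, pos == length appends
// [[Rcpp::export]]
List cpp_insert_te(NumericVector genome, double phi, int pos, double b) {
  Gen g(genome.begin(), genome.end());
  int dam = insert_te_impl(g, te_val(phi), pos, b);
  return List::create(_["genome"] = NumericVector(g.begin(), g.end()),
                      _["damage"] = dam);
}

// [[Rcpp::export]]
NumericVector cpp_lifetime_transposition(NumericVector genome, double j, double b,
                                         List rates) {
  Rates r = rates_from_list(rates);
  Gen g(genome.begin(), genome.end());
  lifetime_transposition_impl(g, j, b, r);
  return NumericVector(g.begin(), g.end());
}

// [[Rcpp::export]]
List cpp_lyse(NumericVector genome) {
  Gen g(genome.begin(), genome.end());
  std::vector<Gen> frags;
  lyse_impl(g, frags);
  List out(frags.size());
  for (size_t k = 0; k < frags.size(); ++k)
    out[k] = NumericVector(frags[k].begin(), frags[k].end());
  return out;
}

// [[Rcpp::export]]
int cpp_compete(NumericVector fitness, double epsilon) {
  std::vector<double> f(fitness.begin(), fitness.end());
  return compete_idx(f, epsilon);
}

// [[Rcpp::export]]
NumericVector cpp_crossover(NumericVector g1, NumericVector g2) {
  Gen a(g1.begin(), g1.end()), b(g2.begin(), g2.end());
  Gen c = crossover_impl(a, b);
  return NumericVector(c.begin(), c.end());
}

// Diffuse / degrade an eDNA pool: fragments is a list of element vectors,
// sites the matching 1-based site indices on a W x H torus.
// [[Rcpp::export]]
List cpp_step_edna(List fragments, IntegerVector sites, int W, int H,
                   double D, double q) {
  int n = fragments.size();
  std::vector<int> keep_site;
  std::vector<int> keep_idx;
  for (int k = 0; k < n; ++k) {
    if (q > 0.0 && unif_rand() < q) continue;
    int s = sites[k] - 1;
    if (D > 0.0 && unif_rand() < D) {
      int row = s / W, col = s % W;
      int m = runif_int(8);
      // Moore offsets, skipping (0,0)
      static const int dy[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
      static const int dx[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
      int nr = (row + dy[m] + H) % H;
      int nc = (col + dx[m] + W) % W;
      s = nr * W + nc;
    }
    keep_idx.push_back(k);
    keep_site.push_back(s + 1);
  }
  List fr(keep_idx.size());
  for (size_t k = 0; k < keep_idx.size(); ++k) fr[k] = fragments[keep_idx[k]];
  return List::create(_["elements"] = fr,
                      _["site"] = IntegerVector(keep_site.begin(), keep_site.end()));
}

// Uptake of co-located fragments by one cell: each fragment taken up with
// probability u, TEs integrate per their own phi.  Returns the new genome and
// the consumed-fragment flags.
// [[Rcpp::export]]
List cpp_uptake(NumericVector genome, List fragments, double u, double b,
                List rates) {
  Rates r = rates_from_list(rates);
  Gen g(genome.begin(), genome.end());
  int n = fragments.size();
  LogicalVector consumed(n);
  int integrated = 0;
  for (int k = 0; k < n; ++k) {
    if (u > 0.0 && unif_rand() < u) {
      consumed[k] = true;
      NumericVector fv = fragments[k];
      Gen frag(fv.begin(), fv.end());
      integrated += integrate_fragment(g, frag, b, r);
    } else {
      consumed[k] = false;
    }
  }
  return List::create(_["genome"] = NumericVector(g.begin(), g.end()),
                      _["consumed"] = consumed,
                      _["integrated"] = integrated);
}

// ================================================================ engine

struct LinInfo {
  int t_inf;
  int members;
  double te_prod;
  int max_depth;
};

// [[Rcpp::export]]
List cpp_run(List state, List cfg, int nSteps) {
  const int W = as<int>(cfg["width"]);
  const int H = as<int>(cfg["height"]);
  const int nsites = W * H;
  const int nfun = as<int>(cfg["nFunctions"]);
  const double c   = as<double>(cfg["c"]);
  const double d   = as<double>(cfg["d"]);
  const double u   = as<double>(cfg["u"]);
  const double j   = as<double>(cfg["j"]);
  const double Dd  = as<double>(cfg["D"]);
  const double q   = as<double>(cfg["q"]);
  const double b   = as<double>(cfg["b"]);
  const double eps = as<double>(cfg["epsilon"]);
  const int mode   = as<int>(cfg["modeCode"]);   // 0 spatial, 1 mixed_cells, 2 mixed_edna
  const int repro  = as<int>(cfg["reproCode"]);  // 0 asexual_hgt, 1 sexual, 2 clonal
  // 0 per_cell: each living cell draws u once per step and takes up one
  //             uniformly chosen local fragment;
  // 1 per_fragment: every local fragment is offered to the resident cell
  //             with probability u each step;
  // 2 at_birth: as per_fragment, but only for daughters born this step
  const int upMode = as<int>(cfg["uptakeCode"]);
  const int sampleEvery = as<int>(cfg["sampleEvery"]);
  const Rates r = rates_from_list(cfg["rates"]);

  // ---- unpack state
  List cellsIn = state["cells"];
  IntegerVector linIn = state["lineageId"];
  IntegerVector depIn = state["depth"];
  IntegerVector infIn = state["infectedSince"];
  List fragIn = state["fragElements"];
  IntegerVector fragSiteIn = state["fragSite"];
  int t = as<int>(state["t"]);
  int nextLin = as<int>(state["nextLineage"]);

  std::vector<Gen> cell(nsites);
  std::vector<char> occ(nsites, 0);
  std::vector<double> fit(nsites, 0.0);
  std::vector<int> lin(nsites, 0), dep(nsites, 0), infs(nsites, NA_INTEGER);
  for (int s = 0; s < nsites; ++s) {
    RObject g = cellsIn[s];
    if (!g.isNULL()) {
      NumericVector gv(g);
      cell[s].assign(gv.begin(), gv.end());
      occ[s] = 1;
      fit[s] = fitness_of(cell[s], c, nfun);
      lin[s] = linIn[s];
      dep[s] = depIn[s];
      infs[s] = infIn[s];
    }
  }
  std::vector<std::vector<Gen> > frag(nsites);
  for (int k = 0; k < fragIn.size(); ++k) {
    NumericVector fv = fragIn[k];
    frag[fragSiteIn[k] - 1].push_back(Gen(fv.begin(), fv.end()));
  }

  std::unordered_map<int, LinInfo> open;
  {
    List ol = state["openLineages"];
    IntegerVector id = ol["id"], ti = ol["tInfected"], mem = ol["members"],
                  md = ol["maxDepth"];
    NumericVector tp = ol["teProduced"];
    for (int k = 0; k < id.size(); ++k) {
      LinInfo L; L.t_inf = ti[k]; L.members = mem[k]; L.te_prod = tp[k];
      L.max_depth = md[k];
      open[id[k]] = L;
    }
  }
  std::vector<int> cl_id, cl_tinf, cl_text, cl_gen;
  std::vector<double> cl_tp;

  // time-series accumulators
  std::vector<int> ts_t, ts_n, ts_nfrag;
  std::vector<double> ts_ess, ts_te, ts_nc, ts_len, ts_phi, ts_fit, ts_poolte;

  // Moore neighbourhood table
  std::vector<int> nb((size_t)nsites * 8);
  {
    static const int dy[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
    static const int dx[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
    for (int row = 0; row < H; ++row)
      for (int col = 0; col < W; ++col) {
        int s = row * W + col;
        for (int m = 0; m < 8; ++m) {
          int nr = (row + dy[m] + H) % H;
          int nc2 = (col + dx[m] + W) % W;
          nb[(size_t)s * 8 + m] = nr * W + nc2;
        }
      }
  }

  std::vector<char> snap(nsites);
  std::vector<int> nbr_sites(8);
  std::vector<double> nbr_fit(8);

  for (int step = 0; step < nSteps; ++step) {
    int tc = t + step + 1;  // world time once this step completes

    // (1) death & lysis: non-viable cells plus stochastic deaths
    for (int s = 0; s < nsites; ++s) {
      if (!occ[s]) continue;
      bool die = (fit[s] <= 0.0);
      if (!die && d > 0.0 && unif_rand() < d) die = true;
      if (!die) continue;
      if (lin[s] > 0) {
        LinInfo& L = open[lin[s]];
        L.members -= 1;
        L.te_prod += te_count(cell[s]);
        if (L.members <= 0) {
          cl_id.push_back(lin[s]); cl_tinf.push_back(L.t_inf);
          cl_text.push_back(tc); cl_gen.push_back(L.max_depth);
          cl_tp.push_back(L.te_prod);
          open.erase(lin[s]);
        }
      }
      lyse_impl(cell[s], frag[s]);
      cell[s].clear(); occ[s] = 0; fit[s] = 0.0;
      lin[s] = 0; dep[s] = 0; infs[s] = NA_INTEGER;
    }

    // (2) eDNA degradation + diffusion
    if (q > 0.0 || Dd > 0.0) {
      std::vector<std::vector<Gen> > nf(nsites);
      for (int s = 0; s < nsites; ++s) {
        for (size_t k = 0; k < frag[s].size(); ++k) {
          if (q > 0.0 && unif_rand() < q) continue;
          int dest = s;
          if (Dd > 0.0 && unif_rand() < Dd)
            dest = nb[(size_t)s * 8 + runif_int(8)];
          nf[dest].push_back(std::move(frag[s][k]));
        }
      }
      frag.swap(nf);
    }

    // (3) synchronous competition / reproduction for empty sites
    std::vector<char> born(nsites, 0);
    std::copy(occ.begin(), occ.end(), snap.begin());
    std::vector<int> b_site, b_lin, b_dep;
    std::vector<Gen> b_gen;
    for (int s = 0; s < nsites; ++s) {
      if (snap[s]) continue;
      int nlive = 0;
      for (int m = 0; m < 8; ++m) {
        int v = nb[(size_t)s * 8 + m];
        if (snap[v]) { nbr_sites[nlive] = v; nbr_fit[nlive] = fit[v]; ++nlive; }
      }
      if (nlive == 0) continue;
      std::vector<double> f(nbr_fit.begin(), nbr_fit.begin() + nlive);
      int w1 = compete_idx(f, eps);
      if (w1 < 0) continue;
      int p1 = nbr_sites[w1];
      Gen child;
      int plin = lin[p1], pdep = lin[p1] > 0 ? dep[p1] + 1 : 0;
      if (repro == 1 && nlive >= 2) {
        // sexual: second parent drawn from the remaining competitors with the
        // same epsilon rule; an epsilon outcome falls back to clonal copying
        std::vector<double> f2;
        std::vector<int> s2;
        for (int k = 0; k < nlive; ++k)
          if (k != w1) { f2.push_back(nbr_fit[k]); s2.push_back(nbr_sites[k]); }
        int w2 = compete_idx(f2, eps);
        if (w2 >= 0) {
          int p2 = s2[w2];
          Gen cx = crossover_impl(cell[p1], cell[p2]);
          child = mutate_gen(cx, r);
          if (plin == 0 && lin[p2] > 0) { plin = lin[p2]; pdep = dep[p2] + 1; }
        } else {
          child = mutate_gen(cell[p1], r);
        }
      } else {
        child = mutate_gen(cell[p1], r);
      }
      b_site.push_back(s); b_gen.push_back(std::move(child));
      b_lin.push_back(plin); b_dep.push_back(pdep);
    }
    for (size_t k = 0; k < b_site.size(); ++k) {
      int s = b_site[k];
      cell[s] = std::move(b_gen[k]);
      occ[s] = 1;
      born[s] = 1;
      fit[s] = fitness_of(cell[s], c, nfun);
      lin[s] = b_lin[k]; dep[s] = b_dep[k];
      if (lin[s] > 0) {
        LinInfo& L = open[lin[s]];
        L.members += 1;
        if (dep[s] > L.max_depth) L.max_depth = dep[s];
        infs[s] = L.t_inf;
      } else if (te_count(cell[s]) > 0) {
        LinInfo L; L.t_inf = tc; L.members = 1; L.te_prod = 0.0; L.max_depth = 0;
        lin[s] = nextLin++; dep[s] = 0; infs[s] = tc;
        open[lin[s]] = L;
      } else {
        infs[s] = NA_INTEGER;
      }
    }

    // (4) uptake of eDNA + TE integration (HGT mode only)
    if (repro == 0 && u > 0.0) {
      for (int s = 0; s < nsites; ++s) {
        if (!occ[s]) continue;
        int integrated = 0;
        if (upMode == 0) {
          // bounded uptake: the cell's machinery processes at most one
          // fragment per step (probability u), sampled uniformly from the
          // local pool (own site + Moore neighbourhood)
          if (unif_rand() >= u) continue;
          int tot = (int)frag[s].size();
          for (int m = 0; m < 8; ++m) tot += (int)frag[nb[(size_t)s * 8 + m]].size();
          if (tot == 0) continue;
          int k = runif_int(tot);
          int ss = s;
          if (k >= (int)frag[s].size()) {
            k -= (int)frag[s].size();
            for (int m = 0; m < 8; ++m) {
              int v = nb[(size_t)s * 8 + m];
              if (k < (int)frag[v].size()) { ss = v; break; }
              k -= (int)frag[v].size();
            }
          }
          integrated += integrate_fragment(cell[s], frag[ss][k], b, r);
          frag[ss].erase(frag[ss].begin() + k);
        } else {
          if (frag[s].empty()) continue;
          if (upMode == 2 && !born[s]) continue;
          std::vector<Gen> keep;
          for (size_t k = 0; k < frag[s].size(); ++k) {
            if (unif_rand() < u) {
              integrated += integrate_fragment(cell[s], frag[s][k], b, r);
            } else {
              keep.push_back(std::move(frag[s][k]));
            }
          }
          frag[s].swap(keep);
        }
        if (integrated > 0 && lin[s] == 0) {
          LinInfo L; L.t_inf = tc; L.members = 1; L.te_prod = 0.0; L.max_depth = 0;
          lin[s] = nextLin++; dep[s] = 0; infs[s] = tc;
          open[lin[s]] = L;
        }
      }
    }

    // (5) lifetime transposition
    if (j > 0.0) {
      for (int s = 0; s < nsites; ++s) {
        if (!occ[s]) continue;
        lifetime_transposition_impl(cell[s], j, b, r);
      }
    }

    // (6) viability / fitness refresh (inviable cells die next death phase)
    for (int s = 0; s < nsites; ++s)
      if (occ[s]) fit[s] = fitness_of(cell[s], c, nfun);

    // (7) mixing controls
    if (mode == 1) {
      for (int i = nsites - 1; i > 0; --i) {
        int k = runif_int(i + 1);
        if (k == i) continue;
        std::swap(cell[i], cell[k]); std::swap(occ[i], occ[k]);
        std::swap(fit[i], fit[k]); std::swap(lin[i], lin[k]);
        std::swap(dep[i], dep[k]); std::swap(infs[i], infs[k]);
      }
    } else if (mode == 2) {
      std::vector<std::vector<Gen> > nf(nsites);
      for (int s = 0; s < nsites; ++s)
        for (size_t k = 0; k < frag[s].size(); ++k)
          nf[runif_int(nsites)].push_back(std::move(frag[s][k]));
      frag.swap(nf);
    }

    // (8) observers
    if (sampleEvery > 0 && tc % sampleEvery == 0) {
      int n = 0, nfr = 0;
      double se = 0, st = 0, sn = 0, sf = 0, sphi = 0, pool_te = 0;
      long nte = 0;
      for (int s = 0; s < nsites; ++s) {
        if (occ[s]) {
          ++n;
          for (size_t k = 0; k < cell[s].size(); ++k) {
            double v = cell[s][k];
            if (el_is_te(v)) { st += 1; sphi += el_phi(v); ++nte; }
            else if (el_is_ess(v)) se += 1;
            else sn += 1;
          }
          sf += fit[s];
        }
        nfr += (int)frag[s].size();
        for (size_t k = 0; k < frag[s].size(); ++k)
          pool_te += te_count(frag[s][k]);
      }
      ts_t.push_back(tc); ts_n.push_back(n); ts_nfrag.push_back(nfr);
      ts_poolte.push_back(pool_te);
      if (n > 0) {
        ts_ess.push_back(se / n); ts_te.push_back(st / n);
        ts_nc.push_back(sn / n); ts_len.push_back((se + st + sn) / n);
        ts_fit.push_back(sf / n);
      } else {
        ts_ess.push_back(NA_REAL); ts_te.push_back(NA_REAL);
        ts_nc.push_back(NA_REAL); ts_len.push_back(NA_REAL);
        ts_fit.push_back(NA_REAL);
      }
      ts_phi.push_back(nte > 0 ? sphi / (double)nte : NA_REAL);
    }
  }

  // ---- repack state
  List cellsOut(nsites);
  IntegerVector linOut(nsites), depOut(nsites), infOut(nsites);
  for (int s = 0; s < nsites; ++s) {
    if (occ[s]) cellsOut[s] = NumericVector(cell[s].begin(), cell[s].end());
    linOut[s] = lin[s]; depOut[s] = dep[s]; infOut[s] = infs[s];
  }
  int nfrag_tot = 0;
  for (int s = 0; s < nsites; ++s) nfrag_tot += (int)frag[s].size();
  List fragOut(nfrag_tot);
  IntegerVector fragSiteOut(nfrag_tot);
  int idx = 0;
  for (int s = 0; s < nsites; ++s)
    for (size_t k = 0; k < frag[s].size(); ++k) {
      fragOut[idx] = NumericVector(frag[s][k].begin(), frag[s][k].end());
      fragSiteOut[idx] = s + 1;
      ++idx;
    }

  int nopen = (int)open.size();
  IntegerVector o_id(nopen), o_ti(nopen), o_mem(nopen), o_md(nopen);
  NumericVector o_tp(nopen);
  {
    int k = 0;
    for (std::unordered_map<int, LinInfo>::const_iterator it = open.begin();
         it != open.end(); ++it, ++k) {
      o_id[k] = it->first; o_ti[k] = it->second.t_inf;
      o_mem[k] = it->second.members; o_md[k] = it->second.max_depth;
      o_tp[k] = it->second.te_prod;
    }
  }

  return List::create(
    _["cells"] = cellsOut,
    _["lineageId"] = linOut,
    _["depth"] = depOut,
    _["infectedSince"] = infOut,
    _["fragElements"] = fragOut,
    _["fragSite"] = fragSiteOut,
    _["t"] = t + nSteps,
    _["nextLineage"] = nextLin,
    _["openLineages"] = List::create(
      _["id"] = o_id, _["tInfected"] = o_ti, _["members"] = o_mem,
      _["teProduced"] = o_tp, _["maxDepth"] = o_md),
    _["closedLineages"] = List::create(
      _["id"] = IntegerVector(cl_id.begin(), cl_id.end()),
      _["tInfected"] = IntegerVector(cl_tinf.begin(), cl_tinf.end()),
      _["tExtinct"] = IntegerVector(cl_text.begin(), cl_text.end()),
      _["generations"] = IntegerVector(cl_gen.begin(), cl_gen.end()),
      _["teProduced"] = NumericVector(cl_tp.begin(), cl_tp.end())),
    _["timeSeries"] = List::create(
      _["t"] = IntegerVector(ts_t.begin(), ts_t.end()),
      _["nCells"] = IntegerVector(ts_n.begin(), ts_n.end()),
      _["meanEssential"] = NumericVector(ts_ess.begin(), ts_ess.end()),
      _["meanTE"] = NumericVector(ts_te.begin(), ts_te.end()),
      _["meanNonCoding"] = NumericVector(ts_nc.begin(), ts_nc.end()),
      _["meanLength"] = NumericVector(ts_len.begin(), ts_len.end()),
      _["meanPhi"] = NumericVector(ts_phi.begin(), ts_phi.end()),
      _["meanFitness"] = NumericVector(ts_fit.begin(), ts_fit.end()),
      _["nFragments"] = IntegerVector(ts_nfrag.begin(), ts_nfrag.end()),
      _["poolTE"] = NumericVector(ts_poolte.begin(), ts_poolte.end())));
}
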