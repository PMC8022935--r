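// Forward-in-time simulator for multiparental RIL panels.
//
// Haplotypes are founder-of-origin segment lists (end positions in bp plus
// founder ids), so cost scales with realized breakpoints, not marker count.
// All randomness comes from R's RNG: results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Hap {
  std::vector<double> ends;  // segment end positions (bp), last == chrom length
  std::vector<int> fdr;      // founder id per segment (0-based)
};

struct ChromMap {
  double L;                    // physical length (bp)
  std::vector<double> bnd;     // domain boundaries, bnd[0]=0, bnd.back()=L
  std::vector<double> rate;    // cM/Mb per domain
  std::vector<double> gcum;    // cumulative cM at boundaries
  double gtot;                 // total cM
};

typedef std::vector<std::array<Hap, 2> > Ind;  // [chrom][hap]

std::vector<ChromMap> build_maps(const NumericVector &chrom_len,
                                 const IntegerVector &dom_chrom,
                                 const NumericVector &dom_start,
                                 const NumericVector &dom_end,
                                 const NumericVector &dom_rate) {
  int nc = chrom_len.size();
  std::vector<ChromMap> maps(nc);
  for (int c = 0; c < nc; ++c) {
    maps[c].L = chrom_len[c];
    maps[c].bnd.push_back(0.0);
    maps[c].gcum.push_back(0.0);
  }
  // domains assumed sorted by (chrom, start) and tiling each chromosome
  for (int i = 0; i < dom_chrom.size(); ++i) {
    ChromMap &m = maps[dom_chrom[i]];
    m.bnd.push_back(dom_end[i]);
    m.rate.push_back(dom_rate[i]);
    double g = m.gcum.back() + dom_rate[i] * (dom_end[i] - dom_start[i]) / 1e6;
    m.gcum.push_back(g);
  }
  for (int c = 0; c < nc; ++c) maps[c].gtot = maps[c].gcum.back();
  return maps;
}

// invert cumulative genetic position (cM) to physical bp
double gen2phys(const ChromMap &m, double g) {
  int k = 0, K = (int)m.rate.size();
  while (k < K - 1 && g > m.gcum[k + 1]) ++k;
  if (m.rate[k] <= 0.0) return m.bnd[k + 1];
  return m.bnd[k] + (g - m.gcum[k]) / m.rate[k] * 1e6;
}

void emit(Hap &out, double end, int f) {
  if (!out.fdr.empty() && out.fdr.back() == f)
    out.ends.back() = end;
  else {
    out.ends.push_back(end);
    out.fdr.push_back(f);
  }
}

// copy segments of h over the half-open physical interval (from, to]
void copy_until(const Hap &h, double from, double to, Hap &out) {
  size_t i = std::upper_bound(h.ends.begin(), h.ends.end(), from) -
             h.ends.begin();
  if (i >= h.ends.size()) i = h.ends.size() - 1;
  for (; i < h.ends.size(); ++i) {
    double e = std::min(h.ends[i], to);
    if (e > from) emit(out, e, h.fdr[i]);
    if (h.ends[i] >= to) break;
  }
}

// one meiosis on one chromosome: obligate bivalent crossover plus Poisson
// extras from residual bivalent map length (2L - 1 Morgans), each crossover
// transmitted to the sampled chromatid with probability 1/2.
Hap meiose(const Hap &a, const Hap &b, const ChromMap &m) {
  double LM = m.gtot / 100.0;  // Morgans
  int nco = 1 + (int)R::rpois(std::max(0.0, 2.0 * LM - 1.0));
  std::vector<double> xo;
  for (int k = 0; k < nco; ++k)
    if (unif_rand() < 0.5) xo.push_back(gen2phys(m, unif_rand() * m.gtot));
  std::sort(xo.begin(), xo.end());
  int cur = unif_rand() < 0.5 ? 0 : 1;
  if (xo.empty()) return cur == 0 ? a : b;
  Hap out;
  double pos = 0.0;
  for (size_t k = 0; k <= xo.size(); ++k) {
    double to = (k == xo.size()) ? m.L : xo[k];
    if (to > pos) copy_until(cur == 0 ? a : b, pos, to, out);
    pos = to;
    cur = 1 - cur;
  }
  return out;
}

std::vector<Hap> gamete(const Ind &par, const std::vector<ChromMap> &maps) {
  std::vector<Hap> g(maps.size());
  for (size_t c = 0; c < maps.size(); ++c)
    g[c] = meiose(par[c][0], par[c][1], maps[c]);
  return g;
}

Ind make_child(const Ind &p1, const Ind &p2,
               const std::vector<ChromMap> &maps) {
  std::vector<Hap> g1 = gamete(p1, maps), g2 = gamete(p2, maps);
  Ind child(maps.size());
  for (size_t c = 0; c < maps.size(); ++c) {
    child[c][0] = g1[c];
    child[c][1] = g2[c];
  }
  return child;
}

int runif_int(int n) {
  int k = (int)std::floor(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

}  // namespace

namespace {

void evolve(std::vector<Ind> &pop, int generations, double outcross_p,
            const std::vector<ChromMap> &maps) {
  for (int g = 0; g < generations; ++g) {
    int N = (int)pop.size();
    if (N < 2 && outcross_p > 0.0)
      stop("population size < 2 during an outcrossing generation");
    std::vector<Ind> nxt;
    nxt.reserve(N);
    for (int i = 0; i < N; ++i) {
      if (unif_rand() < outcross_p) {
        int a = runif_int(N), b = runif_int(N);
        while (b == a) b = runif_int(N);
        nxt.push_back(make_child(pop[a], pop[b], maps));
      } else {
        int a = runif_int(N);
        nxt.push_back(make_child(pop[a], pop[a], maps));
      }
    }
    pop.swap(nxt);
  }
}

std::vector<Ind> derive_rils(const std::vector<Ind> &pop, int n_lines,
                             int selfing_gens,
                             const std::vector<ChromMap> &maps) {
  if (n_lines > (int)pop.size())
    stop("cannot sample more lines than the final census size");
  int N = (int)pop.size();
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int i = 0; i < n_lines; ++i)
    std::swap(idx[i], idx[i + runif_int(N - i)]);
  std::vector<Ind> lines;
  lines.reserve(n_lines);
  for (int i = 0; i < n_lines; ++i) lines.push_back(pop[idx[i]]);
  for (int s = 0; s < selfing_gens; ++s)
    for (int i = 0; i < n_lines; ++i)
      lines[i] = make_child(lines[i], lines[i], maps);
  return lines;
}

std::vector<Ind> run_funnel(int n_founders, int census,
                            const std::vector<ChromMap> &maps) {
  int nc = (int)maps.size();
  std::vector<std::vector<Ind> > pops(n_founders);
  for (int f = 0; f < n_founders; ++f) {
    Ind ind(nc);
    for (int c = 0; c < nc; ++c) {
      Hap h;
      h.ends.push_back(maps[c].L);
      h.fdr.push_back(f);
      ind[c][0] = h;
      ind[c][1] = h;
    }
    pops[f].push_back(ind);
  }
  // halve the number of subpopulations each generation by pairwise
  // crossing, until a single hybrid population of the full census remains
  while ((int)pops.size() > 1) {
    int npnew = (int)pops.size() / 2;
    int size = std::max(1, census / npnew);
    if (npnew == 1) size = census;
    std::vector<std::vector<Ind> > nxt(npnew);
    for (int j = 0; j < npnew; ++j) {
      std::vector<Ind> &pa = pops[2 * j], &pb = pops[2 * j + 1];
      nxt[j].reserve(size);
      for (int i = 0; i < size; ++i)
        nxt[j].push_back(make_child(pa[runif_int((int)pa.size())],
                                    pb[runif_int((int)pb.size())], maps));
    }
    pops.swap(nxt);
  }
  return pops[0];
}

void flatten_lines(const std::vector<Ind> &lines, int line_offset,
                   std::vector<int> &o_line, std::vector<int> &o_hap,
                   std::vector<int> &o_chrom, std::vector<double> &o_end,
                   std::vector<int> &o_fdr) {
  int nc = lines.empty() ? 0 : (int)lines[0].size();
  for (size_t i = 0; i < lines.size(); ++i)
    for (int c = 0; c < nc; ++c)
      for (int h = 0; h < 2; ++h) {
        const Hap &hp = lines[i][c][h];
        for (size_t s = 0; s < hp.ends.size(); ++s) {
          o_line.push_back(line_offset + (int)i + 1);
          o_hap.push_back(h + 1);
          o_chrom.push_back(c + 1);
          o_end.push_back(hp.ends[s]);
          o_fdr.push_back(hp.fdr[s] + 1);
        }
      }
}

}  // namespace

// [[Rcpp::export]]
List cpp_simulate_panel(NumericVector chrom_len, IntegerVector dom_chrom,
                        NumericVector dom_start, NumericVector dom_end,
                        NumericVector dom_rate, int n_founders, int census,
                        int generations, double outcross_p, int n_lines,
                        int selfing_gens) {
  RNGScope scope;
  std::vector<ChromMap> maps =
      build_maps(chrom_len, dom_chrom, dom_start, dom_end, dom_rate);
  std::vector<Ind> pop = run_funnel(n_founders, census, maps);
  evolve(pop, generations, outcross_p, maps);
  std::vector<Ind> lines = derive_rils(pop, n_lines, selfing_gens, maps);
  std::vector<int> o_line, o_hap, o_chrom, o_fdr;
  std::vector<double> o_end;
  flatten_lines(lines, 0, o_line, o_hap, o_chrom, o_end, o_fdr);
  return List::create(_["line"] = o_line, _["hap"] = o_hap,
                      _["chrom"] = o_chrom, _["end"] = o_end,
                      _["founder"] = o_fdr);
}

// Structured design: a base population (funnel + base generations), then
// derived lineages branching from stored population states.  Lineage i has
// parent[i] (-1 = base population), evolves gens[i] further generations at
// outcross_p[i], and RILs are sampled from its end state (n_lines[i],
// selfing as for the base).  Lineages must appear after their parents.
// [[Rcpp::export]]
List cpp_simulate_structured(NumericVector chrom_len,
                             IntegerVector dom_chrom,
                             NumericVector dom_start, NumericVector dom_end,
                             NumericVector dom_rate, int n_founders,
                             int census, int base_generations,
                             double base_outcross_p, int base_n_lines,
                             IntegerVector parent, IntegerVector gens,
                             NumericVector outcross_p,
                             IntegerVector n_lines, int selfing_gens) {
  RNGScope scope;
  std::vector<ChromMap> maps =
      build_maps(chrom_len, dom_chrom, dom_start, dom_end, dom_rate);
  std::vector<Ind> base = run_funnel(n_founders, census, maps);
  evolve(base, base_generations, base_outcross_p, maps);

  std::vector<int> o_line, o_hap, o_chrom, o_fdr;
  std::vector<double> o_end;
  int offset = 0;
  {
    std::vector<Ind> lines = derive_rils(base, base_n_lines, selfing_gens,
                                         maps);
    flatten_lines(lines, offset, o_line, o_hap, o_chrom, o_end, o_fdr);
    offset += base_n_lines;
  }
  int K = parent.size();
  std::vector<std::vector<Ind> > states(K);
  for (int k = 0; k < K; ++k) {
    if (parent[k] >= k) stop("lineages must appear after their parents");
    std::vector<Ind> pop = parent[k] < 0 ? base : states[parent[k]];
    evolve(pop, gens[k], outcross_p[k], maps);
    std::vector<Ind> lines = derive_rils(pop, n_lines[k], selfing_gens,
                                         maps);
    flatten_lines(lines, offset, o_line, o_hap, o_chrom, o_end, o_fdr);
    offset += n_lines[k];
    states[k] = pop;
  }
  return List::create(_["line"] = o_line, _["hap"] = o_hap,
                      _["chrom"] = o_chrom, _["end"] = o_end,
                      _["founder"] = o_fdr);
}

// [[Rcpp::export]]
List cpp_sim_meioses(NumericVector chrom_len, IntegerVector dom_chrom,
                     NumericVector dom_start, NumericVector dom_end,
                     NumericVector dom_rate, int n) {
  RNGScope scope;
  std::vector<ChromMap> maps =
      build_maps(chrom_len, dom_chrom, dom_start, dom_end, dom_rate);
  int nc = chrom_len.size();
  Ind f1(nc);
  for (int c = 0; c < nc; ++c) {
    Hap h;
    h.ends.push_back(maps[c].L);
    h.fdr.push_back(0);
    f1[c][0] = h;
    h.fdr[0] = 1;
    f1[c][1] = h;
  }
  std::vector<int> o_g, o_chrom, o_fdr;
  std::vector<double> o_end;
  for (int i = 0; i < n; ++i) {
    std::vector<Hap> g = gamete(f1, maps);
    for (int c = 0; c < nc; ++c)
      for (size_t s = 0; s < g[c].ends.size(); ++s) {
        o_g.push_back(i + 1);
        o_chrom.push_back(c + 1);
        o_end.push_back(g[c].ends[s]);
        o_fdr.push_back(g[c].fdr[s] + 1);
      }
  }
  return List::create(_["gamete"] = o_g, _["chrom"] = o_chrom,
                      _["end"] = o_end, _["founder"] = o_fdr);
}

// [[Rcpp::export]]
NumericMatrix cpp_paths_to_geno(IntegerVector seg_line, IntegerVector seg_hap,
                                IntegerVector seg_chrom, NumericVector seg_end,
                                IntegerVector seg_fdr,
                                IntegerMatrix founder_alleles,
                                IntegerVector marker_chrom,
                                NumericVector marker_pos, int n_lines) {
  int m = marker_pos.size();
  // contiguous marker index range per chromosome (markers sorted by chrom,pos)
  int nc = 0;
  for (int j = 0; j < m; ++j) nc = std::max(nc, marker_chrom[j]);
  std::vector<int> lo(nc + 1, m), hi(nc + 1, -1);
  for (int j = 0; j < m; ++j) {
    int c = marker_chrom[j];
    lo[c] = std::min(lo[c], j);
    hi[c] = std::max(hi[c], j);
  }
  NumericMatrix out(n_lines, m);
  int n = seg_line.size();
  int i = 0;
  while (i < n) {
    int line = seg_line[i], hap = seg_hap[i], chrom = seg_chrom[i];
    double prev = 0.0;
    int j = lo[chrom];
    while (i < n && seg_line[i] == line && seg_hap[i] == hap &&
           seg_chrom[i] == chrom) {
      double e = seg_end[i];
      int f = seg_fdr[i] - 1;
      while (j <= hi[chrom] && marker_pos[j] > prev && marker_pos[j] <= e) {
        out(line - 1, j) += 0.5 * founder_alleles(f, j);
        ++j;
      }
      prev = e;
      ++i;
    }
  }
  return out;
}
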