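// Forward-in-time Wright-Fisher core for facultatively clonal diploids.
// Haplotypes are stored as rows of allele codes over the currently
// segregating sites; columns are kept sorted by genomic position and
// monomorphic columns are purged every generation. All randomness comes
// from R's RNG so set.seed() at the R level makes runs reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <unordered_set>
#include <cmath>

using namespace Rcpp;

typedef std::vector<uint8_t> Hap;

namespace {

struct NewCol {
  int pos;
  uint8_t anc;
  double eff;
  // carriers: (haplotype row, allele)
  std::vector<std::pair<int, uint8_t> > carriers;
};

// fitness-weighted parent index from a cumulative-weight vector
inline int wsample(const std::vector<double>& cum) {
  double u = R::unif_rand() * cum.back();
  int i = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
  if (i >= (int)cum.size()) i = (int)cum.size() - 1;
  return i;
}

// one meiotic gamete from haplotype pair (a, b): crossovers Poisson(rec*L)
// within contigs plus independent assortment between contigs (a boundary
// crossover with probability 1/2 at each multiple of clen)
void make_gamete(const Hap& a, const Hap& b, const std::vector<int>& pos,
                 double rec, double L, double clen, Hap& out) {
  const int S = (int)pos.size();
  out.resize(S);
  int k = (rec > 0.0) ? (int)R::rpois(rec * L) : 0;
  std::vector<double> bp(k);
  for (int i = 0; i < k; ++i) bp[i] = R::unif_rand() * L;
  if (clen > 0.0) {
    for (double b0 = clen; b0 < L - 0.5; b0 += clen) {
      if (R::unif_rand() < 0.5) bp.push_back(b0 + 0.5);
    }
  }
  k = (int)bp.size();
  bool use_a = (R::unif_rand() < 0.5);
  if (k == 0) {
    const Hap& src = use_a ? a : b;
    std::copy(src.begin(), src.end(), out.begin());
    return;
  }
  std::sort(bp.begin(), bp.end());
  int j = 0;
  for (int i = 0; i < k; ++i) {
    int stop = (int)(std::lower_bound(pos.begin(), pos.end(), bp[i]) - pos.begin());
    const Hap& src = use_a ? a : b;
    for (; j < stop; ++j) out[j] = src[j];
    use_a = !use_a;
  }
  const Hap& src = use_a ? a : b;
  for (; j < S; ++j) out[j] = src[j];
}

// draw a selection coefficient: 0 (neutral) or -gamma(shape, mean |s_mean|)
inline double draw_effect(double del_frac, double s_mean, double dfe_shape) {
  if (del_frac <= 0.0 || R::unif_rand() >= del_frac) return 0.0;
  double scale = (-s_mean) / dfe_shape;
  return -R::rgamma(dfe_shape, scale);
}

// k distinct indices in [0, n) (Floyd's algorithm); k <= n
void sample_distinct(int n, int k, std::vector<int>& out) {
  out.clear();
  if (k >= n) {
    out.resize(n);
    for (int i = 0; i < n; ++i) out[i] = i;
    return;
  }
  std::unordered_set<int> seen;
  for (int j = n - k; j < n; ++j) {
    int t = (int)(R::unif_rand() * (j + 1));
    if (t > j) t = j;
    if (seen.count(t)) t = j;
    seen.insert(t);
    out.push_back(t);
  }
}

} // namespace

// Run n_gens generations. `state` is a list(haps, pos, anc, eff, fixed_pos,
// fixed_allele, generation) as produced by a previous call, or with a
// 2*Ne x 0 haps matrix for a monomorphic founder population.
// [[Rcpp::export(name = ".simcore_run")]]
List simcore_run(List state, int Ne, double L, double mu, double rec,
                 double c_clone, double alpha, double del_frac,
                 double s_mean, double dfe_shape, int n_gens, bool finite4,
                 double clen) {
  const int H = 2 * Ne;

  IntegerMatrix haps0 = state["haps"];
  if (haps0.nrow() != H) stop("state/pop_size mismatch");
  std::vector<int> pos = as<std::vector<int> >(state["pos"]);
  std::vector<uint8_t> anc;
  {
    IntegerVector a = state["anc"];
    anc.assign(a.begin(), a.end());
  }
  std::vector<double> eff = as<std::vector<double> >(state["eff"]);
  int generation = as<int>(state["generation"]);

  std::unordered_map<int, uint8_t> fixed;
  {
    IntegerVector fp = state["fixed_pos"], fa = state["fixed_allele"];
    for (int i = 0; i < fp.size(); ++i) fixed[fp[i]] = (uint8_t)fa[i];
  }

  int S = (int)pos.size();
  std::vector<Hap> cur(H), nxt(H);
  for (int r = 0; r < H; ++r) {
    cur[r].resize(S);
    for (int j = 0; j < S; ++j) cur[r][j] = (uint8_t)haps0(r, j);
  }

  std::vector<double> cum(Ne), logw(Ne);
  std::vector<int> sel, conv_idx;
  std::vector<NewCol> newcols;
  std::unordered_map<int, int> newmap; // pos -> index into newcols

  for (int g = 0; g < n_gens; ++g) {
    // ---- fitness ----
    sel.clear();
    for (int j = 0; j < S; ++j) if (eff[j] != 0.0) sel.push_back(j);
    bool neutral = sel.empty();
    if (!neutral) {
      const size_t ns = sel.size();
      std::vector<double> l1(ns), l2(ns);
      std::vector<uint8_t> a0(ns);
      for (size_t m = 0; m < ns; ++m) {
        double s = eff[sel[m]];
        l1[m] = (1.0 + 0.5 * s > 0) ? std::log1p(0.5 * s) : R_NegInf;
        l2[m] = (1.0 + s > 0) ? std::log1p(s) : R_NegInf;
        a0[m] = anc[sel[m]];
      }
      for (int i = 0; i < Ne; ++i) {
        const Hap& ha = cur[2 * i];
        const Hap& hb = cur[2 * i + 1];
        double lw = 0.0;
        for (size_t m = 0; m < ns; ++m) {
          int j = sel[m];
          int k = (ha[j] != a0[m]) + (hb[j] != a0[m]);
          if (k == 1) lw += l1[m];
          else if (k == 2) lw += l2[m];
        }
        logw[i] = lw;
      }
      double mx = *std::max_element(logw.begin(), logw.end());
      double acc = 0.0;
      for (int i = 0; i < Ne; ++i) {
        acc += std::exp(logw[i] - mx);
        cum[i] = acc;
      }
    } else {
      for (int i = 0; i < Ne; ++i) cum[i] = i + 1.0;
    }

    // ---- reproduction ----
    for (int i = 0; i < Ne; ++i) {
      if (c_clone > 0.0 && R::unif_rand() < c_clone) {
        int p = wsample(cum);
        nxt[2 * i] = cur[2 * p];
        nxt[2 * i + 1] = cur[2 * p + 1];
      } else {
        int p1 = wsample(cum), p2 = wsample(cum);
        make_gamete(cur[2 * p1], cur[2 * p1 + 1], pos, rec, L, clen, nxt[2 * i]);
        make_gamete(cur[2 * p2], cur[2 * p2 + 1], pos, rec, L, clen, nxt[2 * i + 1]);
      }
    }

    // ---- new mutations ----
    newcols.clear();
    newmap.clear();
    int nm = (mu > 0.0) ? (int)R::rpois((double)H * mu * L) : 0;
    for (int m = 0; m < nm; ++m) {
      int h = (int)(R::unif_rand() * H);
      if (h >= H) h = H - 1;
      for (int attempt = 0; attempt < 1000; ++attempt) {
        int P = 1 + (int)(R::unif_rand() * L);
        if (P > (int)L) P = (int)L;
        std::vector<int>::iterator it = std::lower_bound(pos.begin(), pos.end(), P);
        if (it != pos.end() && *it == P) {
          // position already segregating
          if (finite4) {
            int j = (int)(it - pos.begin());
            uint8_t curA = nxt[h][j];
            uint8_t a;
            do { a = (uint8_t)(R::unif_rand() * 4.0); } while (a == curA || a > 3);
            nxt[h][j] = a;
            break;
          }
          continue; // infinite sites: redraw position
        }
        std::unordered_map<int, int>::iterator nit = newmap.find(P);
        if (nit != newmap.end()) {
          if (finite4) {
            NewCol& nc = newcols[nit->second];
            uint8_t a;
            do { a = (uint8_t)(R::unif_rand() * 4.0); } while (a == nc.anc || a > 3);
            nc.carriers.push_back(std::make_pair(h, a));
            break;
          }
          continue; // infinite sites: redraw
        }
        NewCol nc;
        nc.pos = P;
        std::unordered_map<int, uint8_t>::iterator fit = fixed.find(P);
        nc.anc = (fit != fixed.end()) ? fit->second : 0;
        nc.eff = draw_effect(del_frac, s_mean, dfe_shape);
        uint8_t a;
        if (finite4) {
          do { a = (uint8_t)(R::unif_rand() * 4.0); } while (a == nc.anc || a > 3);
        } else {
          a = 1;
        }
        nc.carriers.push_back(std::make_pair(h, a));
        newmap[P] = (int)newcols.size();
        newcols.push_back(nc);
        break;
      }
    }
    std::sort(newcols.begin(), newcols.end(),
              [](const NewCol& x, const NewCol& y) { return x.pos < y.pos; });

    // ---- merge new columns, purge monomorphic columns ----
    // row-major scan: a column is monomorphic iff no row differs from row 0
    std::vector<char> drop(S, 1);
    {
      const Hap& r0 = nxt[0];
      for (int r = 1; r < H; ++r) {
        const Hap& rr = nxt[r];
        for (int j = 0; j < S; ++j)
          if (rr[j] != r0[j]) drop[j] = 0;
      }
      for (int j = 0; j < S; ++j) {
        if (drop[j]) {
          uint8_t v = nxt[0][j];
          if (v != 0) fixed[pos[j]] = v; else fixed.erase(pos[j]);
        }
      }
    }
    std::vector<int> pos2;
    std::vector<uint8_t> anc2;
    std::vector<double> eff2;
    std::vector<int> src;       // old column index, or -1 for a new column
    std::vector<uint8_t> defv;  // default allele for new columns
    std::vector<int> newat(newcols.size());
    {
      size_t jn = 0;
      for (int j = 0; j <= S; ++j) {
        while (jn < newcols.size() &&
               (j == S || newcols[jn].pos < pos[j])) {
          newat[jn] = (int)pos2.size();
          pos2.push_back(newcols[jn].pos);
          anc2.push_back(newcols[jn].anc);
          eff2.push_back(newcols[jn].eff);
          src.push_back(-1);
          defv.push_back(newcols[jn].anc);
          ++jn;
        }
        if (j == S) break;
        if (!drop[j]) {
          pos2.push_back(pos[j]);
          anc2.push_back(anc[j]);
          eff2.push_back(eff[j]);
          src.push_back(j);
          defv.push_back(0);
        }
      }
    }
    const int S2 = (int)pos2.size();
    for (int r = 0; r < H; ++r) {
      Hap& out = cur[r];
      out.resize(S2);
      const Hap& in = nxt[r];
      for (int j2 = 0; j2 < S2; ++j2)
        out[j2] = (src[j2] >= 0) ? in[src[j2]] : defv[j2];
    }
    for (size_t m = 0; m < newcols.size(); ++m)
      for (size_t q = 0; q < newcols[m].carriers.size(); ++q)
        cur[newcols[m].carriers[q].first][newat[m]] = newcols[m].carriers[q].second;
    pos.swap(pos2);
    anc.swap(anc2);
    eff.swap(eff2);
    S = S2;

    // ---- gene conversion (per segregating site, tract length 1) ----
    if (alpha > 0.0 && S > 0) {
      for (int i = 0; i < Ne; ++i) {
        int k = (alpha >= 1.0) ? S : (int)R::rbinom((double)S, alpha);
        if (k <= 0) continue;
        sample_distinct(S, k, conv_idx);
        Hap& h1 = cur[2 * i];
        Hap& h2 = cur[2 * i + 1];
        for (size_t q = 0; q < conv_idx.size(); ++q) {
          int j = conv_idx[q];
          if (h1[j] != h2[j]) {
            if (R::unif_rand() < 0.5) h2[j] = h1[j]; else h1[j] = h2[j];
          }
        }
      }
    }

    ++generation;
    if ((g & 0x3f) == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix hout(H, S);
  for (int r = 0; r < H; ++r)
    for (int j = 0; j < S; ++j) hout(r, j) = cur[r][j];
  IntegerVector fp(fixed.size()), fa(fixed.size());
  int q = 0;
  for (std::unordered_map<int, uint8_t>::iterator it = fixed.begin();
       it != fixed.end(); ++it, ++q) {
    fp[q] = it->first;
    fa[q] = it->second;
  }
  return List::create(
    _["haps"] = hout,
    _["pos"] = wrap(pos),
    _["anc"] = IntegerVector(anc.begin(), anc.end()),
    _["eff"] = wrap(eff),
    _["fixed_pos"] = fp,
    _["fixed_allele"] = fa,
    _["generation"] = generation);
}

// Vectorised DFE draws for tests and the exported R operation.
// [[Rcpp::export(name = ".simcore_dfe")]]
NumericVector simcore_dfe(int n, double del_frac, double s_mean, double dfe_shape) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = draw_effect(del_frac, s_mean, dfe_shape);
  return out;
}
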