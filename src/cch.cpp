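#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Conflicting homozygosity (CH) at a marker = at least one pair of
// individuals homozygous for opposite alleles (IBS0).  For a subset S this
// reduces to: (some member is HOM_REF) AND (some member is HOM_ALT).
// Genotypes are bit-packed into two planes per chromosome (one bit per
// marker per individual): the HOM_REF plane and the HOM_ALT plane.  The CH
// track of a subset is then OR(ref planes) & OR(alt planes), 32 markers per
// word, which is what makes exhaustive subset scans tractable.

// Pack an m x n genotype matrix (rows = markers, cols = individuals,
// values 0/1/2/NA) into per-chromosome HOM_REF / HOM_ALT bit planes.
// chrom_off / chrom_m give the 0-based start and length of each
// chromosome's marker block.
// [[Rcpp::export]]
List pack_genotypes_cpp(IntegerMatrix geno, IntegerVector chrom_off,
                        IntegerVector chrom_m) {
  const int n = geno.ncol();
  const int nc = chrom_off.size();
  List ref(nc), alt(nc);
  for (int c = 0; c < nc; ++c) {
    const int off = chrom_off[c], m = chrom_m[c];
    const int W = (m + 31) / 32;
    IntegerMatrix pr(W, n), pa(W, n);
    for (int j = 0; j < n; ++j) {
      uint32_t *vr = reinterpret_cast<uint32_t *>(&pr(0, j));
      uint32_t *va = reinterpret_cast<uint32_t *>(&pa(0, j));
      for (int i = 0; i < m; ++i) {
        const int g = geno(off + i, j);
        if (g == NA_INTEGER) continue;
        if (g == 0) vr[i >> 5] |= (1u << (i & 31));
        else if (g == 2) va[i >> 5] |= (1u << (i & 31));
      }
    }
    ref[c] = pr;
    alt[c] = pa;
  }
  return List::create(_["ref"] = ref, _["alt"] = alt,
                      _["chrom_off"] = chrom_off, _["chrom_m"] = chrom_m);
}

namespace {

struct Run {
  int s, e, tol;
};

// Maximal no-CH stretches from sorted CH marker positions, then the
// single-error tolerance rule: two runs separated by exactly one CH marker
// are merged when the merged span (cM of last minus cM of first marker)
// reaches min_cm; a merged run may keep absorbing earlier neighbours
// (stack-based left-to-right pass, equivalent to iterating pairwise merges
// to a fixpoint because eligibility only grows as runs grow).
void build_runs(const std::vector<int> &chpos, int m, const double *cm,
                double min_cm, bool tolerate, std::vector<Run> &out) {
  out.clear();
  std::vector<Run> raw;
  int prev = -1; // index of last CH marker seen
  for (size_t i = 0; i <= chpos.size(); ++i) {
    const int nxt = (i < chpos.size()) ? chpos[i] : m;
    if (nxt - prev > 1) raw.push_back({prev + 1, nxt - 1, 0});
    prev = nxt;
  }
  if (!tolerate) {
    out = raw;
    return;
  }
  for (Run r : raw) {
    while (!out.empty()) {
      const Run &t = out.back();
      if (r.s == t.e + 2 && cm[r.e] - cm[t.s] >= min_cm) {
        r.tol += t.tol + 1;
        r.s = t.s;
        out.pop_back();
      } else
        break;
    }
    out.push_back(r);
  }
}

} // namespace

// Scan a set of subsets (columns of `subsets`, 0-based individual indices)
// against packed genotypes.  Returns one row per reported run.  With
// qualify = TRUE only runs with length_cm >= min_cm and n_snps >= min_snps
// are kept; otherwise all runs with n_snps >= return_min_snps are kept
// (used for null run-length collection).  Marker indices in the output are
// global and 1-based.
// [[Rcpp::export]]
List cch_scan_cpp(List packed, List cm_list, IntegerMatrix subsets,
                  double min_cm, int min_snps, bool tolerate, bool qualify,
                  int return_min_snps) {
  List ref = packed["ref"], alt = packed["alt"];
  IntegerVector chrom_off = packed["chrom_off"], chrom_m = packed["chrom_m"];
  const int nc = ref.size(), k = subsets.nrow(), S = subsets.ncol();

  int Wmax = 0;
  for (int c = 0; c < nc; ++c) {
    const int W = (chrom_m[c] + 31) / 32;
    if (W > Wmax) Wmax = W;
  }
  std::vector<uint32_t> orr(Wmax), ora(Wmax), chw(Wmax);
  std::vector<int> chpos;
  chpos.reserve(32 * Wmax);
  std::vector<Run> runs;

  std::vector<int> o_sub, o_chr, o_s, o_e, o_n, o_tol;
  std::vector<double> o_len, o_scm, o_ecm;

  for (int s = 0; s < S; ++s) {
    if ((s & 1023) == 0) Rcpp::checkUserInterrupt();
    for (int c = 0; c < nc; ++c) {
      const int m = chrom_m[c];
      const int W = (m + 31) / 32;
      IntegerMatrix pr = ref[c], pa = alt[c];
      std::fill(orr.begin(), orr.begin() + W, 0u);
      std::fill(ora.begin(), ora.begin() + W, 0u);
      for (int j = 0; j < k; ++j) {
        const int col = subsets(j, s);
        const uint32_t *vr = reinterpret_cast<const uint32_t *>(&pr(0, col));
        const uint32_t *va = reinterpret_cast<const uint32_t *>(&pa(0, col));
        for (int w = 0; w < W; ++w) {
          orr[w] |= vr[w];
          ora[w] |= va[w];
        }
      }
      for (int w = 0; w < W; ++w) chw[w] = orr[w] & ora[w];
      // Any reportable run of >= 96 markers contains a word-aligned 64-bit
      // window lying fully inside it, within which every CH marker is
      // isolated (no two adjacent set bits).  When the reporting floor
      // guarantees >= 96 markers per run, chromosomes without such a
      // window can be skipped outright -- the common case in exhaustive
      // subset scans, where conflicting homozygosity is dense.
      const int floor_n = qualify ? min_snps : return_min_snps;
      if (floor_n >= 96 && W > 1) {
        bool cand = false;
        for (int w = 0; w + 1 < W; ++w) {
          const uint64_t x =
              (uint64_t)chw[w] | ((uint64_t)chw[w + 1] << 32);
          if ((x & (x >> 1)) == 0) {
            cand = true;
            break;
          }
        }
        if (!cand) continue;
      }
      chpos.clear();
      for (int w = 0; w < W; ++w) {
        uint32_t ch = chw[w];
        while (ch) {
          const int b = __builtin_ctz(ch);
          chpos.push_back((w << 5) + b);
          ch &= ch - 1;
        }
      }
      const NumericVector cmv = cm_list[c];
      const double *cm = REAL(cmv);
      build_runs(chpos, m, cm, min_cm, tolerate, runs);
      for (const Run &r : runs) {
        const int n = r.e - r.s + 1;
        const double len = cm[r.e] - cm[r.s];
        const bool keep = qualify ? (len >= min_cm && n >= min_snps)
                                  : (n >= return_min_snps);
        if (!keep) continue;
        o_sub.push_back(s + 1);
        o_chr.push_back(c + 1);
        o_s.push_back(chrom_off[c] + r.s + 1);
        o_e.push_back(chrom_off[c] + r.e + 1);
        o_n.push_back(n);
        o_len.push_back(len);
        o_scm.push_back(cm[r.s]);
        o_ecm.push_back(cm[r.e]);
        o_tol.push_back(r.tol);
      }
    }
  }
  return List::create(
      _["subset"] = wrap(o_sub), _["chrom"] = wrap(o_chr),
      _["start_idx"] = wrap(o_s), _["end_idx"] = wrap(o_e),
      _["n_snps"] = wrap(o_n), _["length_cm"] = wrap(o_len),
      _["start_cm"] = wrap(o_scm), _["end_cm"] = wrap(o_ecm),
      _["tolerated_ch_count"] = wrap(o_tol));
}
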