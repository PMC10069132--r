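#include <Rcpp.h>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Haplotype-class bookkeeping for site-specific EHH (EHHS).
//
// Haplotypes are partitioned into classes identical over [core..t]; the
// partition is refined marker by marker moving away from the core.  A
// haplotype with a missing allele (< 0) leaves all classes from that marker
// outward (dropped from numerator and denominator).
//
// variant 0 = "tang":   EHHS(t) = sum_k n_k(n_k-1) / sum_a n_a(n_a-1),
//                        a indexing core-allele classes among still-active
//                        haplotypes.
// variant 1 = "sabeti": EHHS(t) = sum_k n_k(n_k-1) / (n(n-1)),
//                        n = active haplotype count.
// Both are defined to equal 1 at the core marker itself.

struct EhhsState {
  std::vector<int> cls;      // class id per haplotype, -1 = dropped
  std::vector<int> core;     // core allele per haplotype
  int n_active;

  void init(const IntegerMatrix &hap, int core_idx) {
    int n = hap.nrow();
    cls.assign(n, -1);
    core.assign(n, -1);
    n_active = 0;
    for (int i = 0; i < n; ++i) {
      int a = hap(i, core_idx);
      if (a >= 0) {
        cls[i] = a;        // classes start split by core allele
        core[i] = a;
        ++n_active;
      }
    }
  }

  // refine partition by the allele at marker t; returns EHHS value
  double step(const IntegerMatrix &hap, int t, int variant) {
    int n = hap.nrow();
    std::unordered_map<long long, int> renum;
    renum.reserve(n * 2);
    int next_id = 0;
    for (int i = 0; i < n; ++i) {
      if (cls[i] < 0) continue;
      int a = hap(i, t);
      if (a < 0) { cls[i] = -1; --n_active; continue; }
      long long key = (long long)cls[i] * 4LL + a;
      auto it = renum.find(key);
      if (it == renum.end()) { renum[key] = next_id; cls[i] = next_id; ++next_id; }
      else cls[i] = it->second;
    }
    return value(variant);
  }

  double value(int variant) const {
    if (n_active < 2) return NA_REAL;
    int n = (int)cls.size();
    std::unordered_map<int, int> cnt, core_cnt;
    for (int i = 0; i < n; ++i) {
      if (cls[i] < 0) continue;
      ++cnt[cls[i]];
      ++core_cnt[core[i]];
    }
    double num = 0.0;
    for (auto &kv : cnt) num += (double)kv.second * (kv.second - 1);
    double den;
    if (variant == 0) {
      den = 0.0;
      for (auto &kv : core_cnt) den += (double)kv.second * (kv.second - 1);
    } else {
      den = (double)n_active * (n_active - 1);
    }
    if (den <= 0.0) return NA_REAL;
    return num / den;
  }
};

// Full EHHS curve around one core marker (no truncation). Returns a vector
// of length m with EHHS at every marker of the chromosome; 1 at the core.
// [[Rcpp::export]]
NumericVector ehhs_curve_cpp(IntegerMatrix hap, int core_idx, int variant) {
  int m = hap.ncol();
  NumericVector out(m, NA_REAL);
  out[core_idx] = 1.0;
  EhhsState st;
  // rightwards
  st.init(hap, core_idx);
  for (int t = core_idx + 1; t < m; ++t) out[t] = st.step(hap, t, variant);
  // leftwards
  st.init(hap, core_idx);
  for (int t = core_idx - 1; t >= 0; --t) out[t] = st.step(hap, t, variant);
  return out;
}

// iES at every marker of one chromosome: trapezoidal integral of EHHS over
// bp, each side truncated at the first marker with EHHS < cutoff (that
// marker included as final endpoint).  If a side reaches the chromosome end
// with EHHS still >= cutoff and discard_at_border is true, iES is NA.
// [[Rcpp::export]]
NumericVector ies_all_cpp(IntegerMatrix hap, NumericVector pos, int variant,
                          double cutoff, bool discard_at_border) {
  int m = hap.ncol();
  NumericVector out(m, NA_REAL);
  EhhsState st;
  for (int c = 0; c < m; ++c) {
    double total = 0.0;
    bool ok = true;
    for (int dir = 0; dir < 2 && ok; ++dir) {
      st.init(hap, c);
      if (st.n_active < 2) { ok = false; break; }
      double prev_e = 1.0, prev_p = pos[c];
      bool closed = false;
      int t = (dir == 0) ? c + 1 : c - 1;
      int stepv = (dir == 0) ? 1 : -1;
      for (; t >= 0 && t < m; t += stepv) {
        double e = st.step(hap, t, variant);
        if (ISNAN(e)) { ok = false; break; }
        total += 0.5 * (prev_e + e) * std::fabs(pos[t] - prev_p);
        prev_e = e; prev_p = pos[t];
        if (e < cutoff) { closed = true; break; }
      }
      if (!closed && discard_at_border) ok = false;
    }
    out[c] = ok ? total : NA_REAL;
  }
  return out;
}
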