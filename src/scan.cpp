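// Windowed u-test scan.
//
// Three structural reductions keep the enumeration tractable:
//   (a) subjects are collapsed to genotype-profile classes over the
//       retained SNP set (the pairwise ordering depends only on the two
//       profiles), so per-pair work scales with the number of distinct
//       profiles, not n^2;
//   (b) candidates from different windows / polarity vectors that share the
//       same retained set (polarity 0 drops a SNP) are grouped: classes and
//       the per-pair comparison signatures are built once per retained set;
//   (c) within a retained set, the window ordering for each sign pattern is
//       memoized per distinct comparison signature, so the lambda chain
//       runs once per signature, not once per class pair.
// Ordering codes: 0 = undecided (?), 1 = lower (<), 2 = higher (>),
// 3 = equal (=).

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cfloat>
#include <cstdint>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

static inline int lam2(int a, int b) {
  if ((a == 1 && b == 2) || (a == 2 && b == 1)) return 0;
  if (a == 1 || b == 1) return 1;
  if (a == 2 || b == 2) return 2;
  if (a == 3 || b == 3) return 3;
  return 0;
}

struct CompStat {
  double ic, z, p, s;
  bool non_informative;
};

struct Candidate {
  int rset;        // index into the center's retained-set list
  int sign_id;     // sign pattern (bit b set = retained SNP b+1 negative)
  int win_start;   // 0-based column of window start
  int win_len;
  int pol_code;    // base-3, digit j (little-endian) = polarity of SNP j + 1
};

// Fenwick tree for the 2-D dominance counts
struct BIT {
  std::vector<int> t;  // 1-based internally
  int n;
  explicit BIT(int n_) : t(n_ + 1, 0), n(n_) {}
  void add(int i) { for (++i; i <= n; i += i & -i) t[i]++; }
  int query(int i) const {  // count of inserted with 0-based rank <= i
    int s = 0;
    for (++i; i > 0; i -= i & -i) s += t[i];
    return s;
  }
};

// dominance score for every candidate: LE - GE where
// LE = #{d : s_d <= s_c, ic_d <= ic_c}, GE = #{d : s_d >= s_c, ic_d >= ic_c}
// (both include c itself; the self terms cancel in the difference)
static std::vector<int> dominance(const std::vector<double> &s,
                                  const std::vector<double> &ic) {
  int k = (int)s.size();
  std::vector<int> score(k, 0);
  if (k == 0) return score;
  std::vector<double> uniq = ic;
  std::sort(uniq.begin(), uniq.end());
  uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
  int nr = (int)uniq.size();
  std::vector<int> icr(k);
  for (int i = 0; i < k; ++i)
    icr[i] = (int)(std::lower_bound(uniq.begin(), uniq.end(), ic[i]) -
                   uniq.begin());
  std::vector<int> idx(k);
  for (int i = 0; i < k; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return s[a] < s[b]; });
  {  // LE sweep: ascending s; a whole tie-group is inserted, then queried
    BIT bit(nr);
    int i = 0;
    while (i < k) {
      int j = i;
      while (j < k && s[idx[j]] == s[idx[i]]) ++j;
      for (int t = i; t < j; ++t) bit.add(icr[idx[t]]);
      for (int t = i; t < j; ++t) score[idx[t]] += bit.query(icr[idx[t]]);
      i = j;
    }
  }
  {  // GE sweep: descending s, ic ranks reversed
    BIT bit(nr);
    int i = k - 1;
    while (i >= 0) {
      int j = i;
      while (j >= 0 && s[idx[j]] == s[idx[i]]) --j;
      for (int t = i; t > j; --t) bit.add(nr - 1 - icr[idx[t]]);
      for (int t = i; t > j; --t)
        score[idx[t]] -= bit.query(nr - 1 - icr[idx[t]]);
      i = j;
    }
  }
  return score;
}

// lexicographic polarity key (first window SNP most significant); for
// tie-breaking only
static double pol_key(int code, int len) {
  int dig[16];
  for (int j = 0; j < len; ++j) { dig[j] = code % 3; code /= 3; }
  double key = 0;
  for (int j = 0; j < len; ++j) key = key * 3 + dig[j];
  return key;
}

// evaluate one retained set for all of its 2^(k-1) sign patterns
static void evaluate_rset(const std::vector<int> &rpos,
                          const std::vector<uint32_t> &subj_code,
                          const IntegerVector &status, int m,
                          std::vector<int> &lookup,
                          std::vector<signed char> &wtab,
                          std::vector<CompStat> &out) {
  const int n = (int)subj_code.size();
  const int k = (int)rpos.size();
  const int n_sign = 1 << (k - 1);
  const double nn1 = (double)n * (n - 1);
  out.resize(n_sign);

  // profile classes over the retained set
  std::vector<int> keys;
  std::vector<int> nvec, mvec;
  std::vector<uint32_t> prof;
  keys.reserve(128);
  for (int i = 0; i < n; ++i) {
    uint32_t key = 0;
    for (int j = 0; j < k; ++j)
      key |= ((subj_code[i] >> (2 * rpos[j])) & 3u) << (2 * j);
    int g = lookup[key];
    if (g < 0) {
      g = (int)keys.size();
      lookup[key] = g;
      keys.push_back((int)key);
      nvec.push_back(0);
      mvec.push_back(0);
      prof.push_back(key);
    }
    nvec[g]++;
    if (status[i] == 1) mvec[g]++;
  }
  const int G = (int)keys.size();
  for (int kk : keys) lookup[kk] = -1;

  // per-pair comparison signatures under all-(+1) signs, plus the class
  // weights feeding the u-score and IC accumulation
  const int npair = G * (G - 1) / 2;
  std::vector<uint16_t> sig_arr(npair);
  std::vector<uint16_t> g_arr(npair), h_arr(npair);
  std::vector<double> wt_h(npair), wt_g(npair), wt_prod(npair);
  {
    int q = 0;
    int av[16];
    for (int g = 0; g < G; ++g) {
      for (int j = 0; j < k; ++j) av[j] = (prof[g] >> (2 * j)) & 3u;
      for (int h = g + 1; h < G; ++h, ++q) {
        int sig = 0;
        for (int j = 0; j < k; ++j) {
          int bj = (prof[h] >> (2 * j)) & 3u;
          int sc = (av[j] == 3 || bj == 3) ? 0
                   : (av[j] == bj ? 3 : (av[j] < bj ? 1 : 2));
          sig |= sc << (2 * j);
        }
        sig_arr[q] = (uint16_t)sig;
        g_arr[q] = (uint16_t)g;
        h_arr[q] = (uint16_t)h;
        wt_h[q] = nvec[h];
        wt_g[q] = nvec[g];
        wt_prod[q] = 2.0 * nvec[g] * nvec[h];
      }
    }
  }

  // within-class pairs: every retained S is "=" or "?"; the pair is
  // decided ("=") unless missing calls blank out every consecutive
  // retained pair; independent of signs
  double decided_self = 0;
  for (int g = 0; g < G; ++g) {
    bool miss[16], dec_self;
    for (int j = 0; j < k; ++j) miss[j] = (((prof[g] >> (2 * j)) & 3u) == 3u);
    if (k == 1) dec_self = !miss[0];
    else {
      dec_self = false;
      for (int r = 0; r < k - 1; ++r)
        if (!miss[r] || !miss[r + 1]) { dec_self = true; break; }
    }
    if (dec_self) decided_self += (double)nvec[g] * (nvec[g] - 1);
  }

  static const double sgn_tab[4] = {0.0, -1.0, 1.0, 0.0};
  static const double dec_tab[4] = {0.0, 1.0, 1.0, 1.0};
  std::vector<double> u(G);
  int scode[16], I[15];
  for (int sid = 0; sid < n_sign; ++sid) {
    std::memset(wtab.data(), -1, (size_t)1 << (2 * k));
    std::fill(u.begin(), u.end(), 0.0);
    double decided = decided_self;
    for (int q = 0; q < npair; ++q) {
      int sig = sig_arr[q];
      int w = wtab[sig];
      if (w < 0) {
        // apply the sign pattern: a negative retained SNP swaps < and >
        for (int j = 0; j < k; ++j) {
          int sc = (sig >> (2 * j)) & 3;
          if (j > 0 && (sid >> (j - 1)) & 1) {
            if (sc == 1) sc = 2;
            else if (sc == 2) sc = 1;
          }
          scode[j] = sc;
        }
        if (k == 1) w = scode[0];
        else {
          for (int r = 0; r < k - 1; ++r)
            I[r] = lam2(scode[r], scode[r + 1]);
          bool lt = false, gt = false, eq = false;
          for (int r = 0; r < k - 1; ++r) {
            if (I[r] == 1) lt = true;
            else if (I[r] == 2) gt = true;
            else if (I[r] == 3) eq = true;
          }
          w = (lt && gt) ? 0 : lt ? 1 : gt ? 2 : eq ? 3 : 0;
        }
        wtab[sig] = (signed char)w;
      }
      const double sg = sgn_tab[w];
      u[g_arr[q]] += sg * wt_h[q];
      u[h_arr[q]] -= sg * wt_g[q];
      decided += dec_tab[w] * wt_prod[q];
    }

    CompStat st;
    st.ic = decided / nn1;
    double T = 0, sum_u2 = 0;
    for (int g = 0; g < G; ++g) {
      T += mvec[g] * u[g];
      sum_u2 += nvec[g] * u[g] * u[g];
    }
    if (sum_u2 <= 0) {
      st.z = 0; st.p = 1; st.s = 0; st.non_informative = true;
    } else {
      double var_t = (double)m * (n - m) / nn1 * sum_u2;
      st.z = T / std::sqrt(var_t);
      double p = 2.0 * R::pnorm(-std::fabs(st.z), 0.0, 1.0, 1, 0);
      if (p < DBL_MIN) p = DBL_MIN;
      st.p = p;
      st.s = -std::log10(p);
      st.non_informative = false;
    }
    out[sid] = st;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_scan_centers(IntegerMatrix dos, IntegerVector run_start,
                               IntegerVector run_end, IntegerVector centers,
                               IntegerVector status, int max_window,
                               double ic_min, bool return_all) {
  if (max_window < 1 || max_window > 8)
    stop("max_window must be between 1 and 8");
  const int n = dos.nrow();
  const int m = Rcpp::sum(status);

  std::vector<int> lookup(1 << (2 * max_window), -1);
  std::vector<signed char> wtab(1 << (2 * max_window));
  std::vector<int> pow3(max_window + 1, 1);
  for (int j = 1; j <= max_window; ++j) pow3[j] = pow3[j - 1] * 3;
  std::vector<std::vector<double>> out_rows;

  for (int ci = 0; ci < centers.size(); ++ci) {
    const int cc = centers[ci] - 1;
    const int lo = std::max(run_start[cc] - 1, cc - (max_window - 1));
    const int hi = std::min(run_end[cc] - 1, cc + (max_window - 1));
    const int width = hi - lo + 1;  // <= 2*max_window - 1 <= 15

    // 2-bit dosage codes over the neighborhood (3 = missing)
    std::vector<uint32_t> subj_code(n, 0u);
    for (int j = 0; j < width; ++j)
      for (int i = 0; i < n; ++i) {
        int v = dos(i, lo + j);
        if (v == NA_INTEGER) v = 3;
        subj_code[i] |= (uint32_t)v << (2 * j);
      }

    // enumerate candidates; group by retained set + sign pattern
    std::unordered_map<uint32_t, int> rset_of;
    std::vector<std::vector<int>> rset_rpos;
    std::vector<Candidate> cand;
    for (int a = std::max(lo, cc - max_window + 1); a <= cc; ++a) {
      for (int b = cc; b <= std::min(hi, a + max_window - 1); ++b) {
        const int L = b - a + 1;
        for (int code = 1; code < pow3[L]; ++code) {
          int c2 = code, first_nz = -1, sign_id = 0, nr = 0;
          bool skip = false;
          uint32_t mem = 0;
          std::vector<int> rpos;
          for (int j = 0; j < L; ++j) {
            int pj = (c2 % 3) - 1;
            c2 /= 3;
            if (pj != 0) {
              if (first_nz < 0) {
                first_nz = j;
                if (pj != 1) { skip = true; break; }  // sign-flip duplicate
              } else if (pj < 0) {
                sign_id |= 1 << (nr - 1);
              }
              mem |= 1u << (a - lo + j);
              rpos.push_back(a - lo + j);
              ++nr;
            }
          }
          if (skip || nr == 0) continue;
          auto it = rset_of.find(mem);
          int id;
          if (it == rset_of.end()) {
            id = (int)rset_rpos.size();
            rset_of.emplace(mem, id);
            rset_rpos.push_back(rpos);
          } else id = it->second;
          Candidate cd;
          cd.rset = id;
          cd.sign_id = sign_id;
          cd.win_start = a;
          cd.win_len = L;
          cd.pol_code = code;
          cand.push_back(cd);
        }
      }
    }

    std::vector<std::vector<CompStat>> stats(rset_rpos.size());
    for (size_t q = 0; q < rset_rpos.size(); ++q)
      evaluate_rset(rset_rpos[q], subj_code, status, m, lookup, wtab,
                    stats[q]);

    // expand, apply the IC floor, rank by dominance
    std::vector<Candidate> keep;
    std::vector<double> s_all, ic_all;
    keep.reserve(cand.size());
    for (const Candidate &cd : cand) {
      const CompStat &st = stats[cd.rset][cd.sign_id];
      if (st.ic < ic_min) continue;
      keep.push_back(cd);
      s_all.push_back(st.s);
      ic_all.push_back(st.ic);
    }
    std::vector<int> dom = dominance(s_all, ic_all);

    if (return_all) {
      for (size_t i = 0; i < keep.size(); ++i) {
        const Candidate &cd = keep[i];
        const CompStat &st = stats[cd.rset][cd.sign_id];
        out_rows.push_back({(double)(cc + 1), (double)(cd.win_start + 1),
                            (double)cd.win_len, (double)cd.pol_code, st.ic,
                            st.z, st.p, st.s, (double)st.non_informative,
                            (double)keep.size(), (double)dom[i]});
      }
    } else if (!keep.empty()) {
      int best = 0;
      for (int i = 1; i < (int)keep.size(); ++i) {
        const Candidate &A = keep[i], &B = keep[best];
        const CompStat &sa = stats[A.rset][A.sign_id];
        const CompStat &sb = stats[B.rset][B.sign_id];
        bool better;
        if (dom[i] != dom[best]) better = dom[i] > dom[best];
        else if (sa.ic != sb.ic) better = sa.ic > sb.ic;
        else if (A.win_len != B.win_len) better = A.win_len < B.win_len;
        else if (pol_key(A.pol_code, A.win_len) !=
                 pol_key(B.pol_code, B.win_len))
          better = pol_key(A.pol_code, A.win_len) <
                   pol_key(B.pol_code, B.win_len);
        else better = A.win_start < B.win_start;
        if (better) best = i;
      }
      const Candidate &cd = keep[best];
      const CompStat &st = stats[cd.rset][cd.sign_id];
      out_rows.push_back({(double)(cc + 1), (double)(cd.win_start + 1),
                          (double)cd.win_len, (double)cd.pol_code, st.ic,
                          st.z, st.p, st.s, (double)st.non_informative,
                          (double)keep.size(), (double)dom[best]});
    }
    if (ci % 64 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix out((int)out_rows.size(), 11);
  for (int i = 0; i < (int)out_rows.size(); ++i)
    for (int j = 0; j < 11; ++j) out(i, j) = out_rows[i][j];
  return out;
}
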