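// Seeded banded local alignment engine and affine-gap dynamic programming.
// One banded DP core serves three callers: full Smith-Waterman (band spans
// the whole matrix), banded local extension of k-mer seed clusters, and
// free-end-gap ("glocal") alignment used for centre-star MSA construction.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const int NEG_INF = -100000000;

static inline char complement_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = complement_base(r[i]);
  return r;
}

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline bool is_transition(char x, char y) {
  return (x == 'A' && y == 'G') || (x == 'G' && y == 'A') ||
         (x == 'C' && y == 'T') || (x == 'T' && y == 'C');
}

struct AlnResult {
  int score;
  int a_start, a_end, b_start, b_end;  // 0-based half-open
  int matches, columns, pairs, ts, tv;
  std::string aa, ab;
  bool found;
  AlnResult() : score(0), a_start(0), a_end(0), b_start(0), b_end(0),
                matches(0), columns(0), pairs(0), ts(0), tv(0), found(false) {}
};

// Banded affine-gap DP. Diagonals d = j - i restricted to [dlo, dhi].
// local = true: Smith-Waterman (max over all cells, paths start at score 0).
// local = false: free-end-gap global (paths start on the i==0 or j==0 edge,
// end on the i==n or j==m edge); aligned strings are padded to full length
// of both inputs so callers can stack rows into an MSA.
// Gap of length L costs gap_open + L * gap_extend.
static AlnResult band_dp(const std::string& a, const std::string& b,
                         int dlo, int dhi, bool local,
                         int match, int mismatch, int gap_open, int gap_extend,
                         bool want_strings) {
  const int n = (int)a.size(), m = (int)b.size();
  AlnResult res;
  if (n == 0 || m == 0) return res;
  if (dlo > dhi) std::swap(dlo, dhi);
  if (dlo < -n) dlo = -n;
  if (dhi > m) dhi = m;
  if (dlo > dhi) return res;
  const int W = dhi - dlo + 1;
  const int go = gap_open, ge = gap_extend;

  std::vector<int> Hprev(W, NEG_INF), Hcur(W, NEG_INF);
  std::vector<int> Fprev(W, NEG_INF), Fcur(W, NEG_INF);
  std::vector<int> Ecur(W, NEG_INF);
  // traceback: tbH 0=start 1=diag 2=E 3=F ; tbE/tbF 1=opened from H
  std::vector<uint8_t> tbH((size_t)(n + 1) * W, 0);
  std::vector<uint8_t> tbE((size_t)(n + 1) * W, 0);
  std::vector<uint8_t> tbF((size_t)(n + 1) * W, 0);

  int best = local ? 0 : NEG_INF;
  int best_i = -1, best_w = -1;

  // row 0
  for (int w = 0; w < W; ++w) {
    int j = 0 + dlo + w;
    if (j < 0 || j > m) continue;
    Hprev[w] = 0;  // both modes: free start on top edge
    if (!local && 0 == n) { /* degenerate, n>0 guaranteed */ }
  }
  if (!local) {
    // glocal end cells on row 0 only matter when n==0 (excluded above)
  }

  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int w = 0; w < W; ++w) {
      int j = i + dlo + w;
      if (j < 0 || j > m) { Hcur[w] = NEG_INF; Ecur[w] = NEG_INF; Fcur[w] = NEG_INF; continue; }
      size_t idx = (size_t)i * W + w;
      if (j == 0) {  // left edge: free start
        Hcur[w] = 0; Ecur[w] = NEG_INF; Fcur[w] = NEG_INF;
        tbH[idx] = 0;
        continue;
      }
      // E: gap in a (consume b), from (i, j-1) = same row, w-1
      int e = NEG_INF; uint8_t te = 0;
      if (w - 1 >= 0) {
        int open_e = (Hcur[w - 1] <= NEG_INF / 2) ? NEG_INF : Hcur[w - 1] - go - ge;
        int ext_e  = (Ecur[w - 1] <= NEG_INF / 2) ? NEG_INF : Ecur[w - 1] - ge;
        if (open_e >= ext_e) { e = open_e; te = 1; } else { e = ext_e; te = 0; }
      }
      // F: gap in b (consume a), from (i-1, j) = prev row, w+1
      int f = NEG_INF; uint8_t tf = 0;
      if (w + 1 < W) {
        int open_f = (Hprev[w + 1] <= NEG_INF / 2) ? NEG_INF : Hprev[w + 1] - go - ge;
        int ext_f  = (Fprev[w + 1] <= NEG_INF / 2) ? NEG_INF : Fprev[w + 1] - ge;
        if (open_f >= ext_f) { f = open_f; tf = 1; } else { f = ext_f; tf = 0; }
      }
      // diag from (i-1, j-1) = prev row, same w
      int d = NEG_INF;
      if (Hprev[w] > NEG_INF / 2) {
        const char bj = b[j - 1];
        int s = (ai == bj && is_acgt(ai)) ? match : mismatch;
        d = Hprev[w] + s;
      }
      int h = d; uint8_t th = 1;
      if (e > h) { h = e; th = 2; }
      if (f > h) { h = f; th = 3; }
      if (local && h < 0) { h = 0; th = 0; }
      if (!local && h < NEG_INF / 2) { h = NEG_INF; th = 0; }
      Hcur[w] = h; Ecur[w] = e; Fcur[w] = f;
      tbH[idx] = th; tbE[idx] = te; tbF[idx] = tf;

      if (local) {
        if (h > best) { best = h; best_i = i; best_w = w; }
      } else if (i == n || j == m) {
        if (h > best) { best = h; best_i = i; best_w = w; }
      }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
    std::fill(Ecur.begin(), Ecur.end(), NEG_INF);
  }

  if (best_i < 0 || (local && best <= 0)) return res;

  // traceback
  int i = best_i, w = best_w;
  int j = i + dlo + w;
  res.a_end = i; res.b_end = j; res.score = best;
  std::string ra, rb;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (true) {
    size_t idx = (size_t)i * W + w;
    if (state == 0) {
      uint8_t t = tbH[idx];
      if (t == 0) break;
      if (t == 1) {
        char ca = a[i - 1], cb = b[j - 1];
        if (want_strings) { ra.push_back(ca); rb.push_back(cb); }
        res.columns++; res.pairs++;
        if (ca == cb && is_acgt(ca)) res.matches++;
        else if (is_transition(ca, cb)) res.ts++;
        else if (is_acgt(ca) && is_acgt(cb)) res.tv++;
        --i; --j;  // w unchanged
      } else if (t == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {  // E: gap in a, consume b
      uint8_t t = tbE[idx];
      if (want_strings) { ra.push_back('-'); rb.push_back(b[j - 1]); }
      res.columns++;
      --j; --w;
      if (t == 1) state = 0;
    } else {  // F: gap in b, consume a
      uint8_t t = tbF[idx];
      if (want_strings) { ra.push_back(a[i - 1]); rb.push_back('-'); }
      res.columns++;
      --i; ++w;
      if (t == 1) state = 0;
    }
  }
  res.a_start = i; res.b_start = j;
  if (want_strings) {
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    if (!local) {
      // pad to full length of both sequences (free end gaps)
      std::string pa, pb;
      if (res.b_start > 0) { pa.append(res.b_start, '-'); pb.append(b, 0, res.b_start); }
      if (res.a_start > 0) { pa.append(a, 0, res.a_start); pb.append(res.a_start, '-'); }
      pa += ra; pb += rb;
      if (res.a_end < n) { pa.append(a, res.a_end, n - res.a_end); pb.append(n - res.a_end, '-'); }
      if (res.b_end < m) { pa.append(m - res.b_end, '-'); pb.append(b, res.b_end, m - res.b_end); }
      ra = pa; rb = pb;
    }
    res.aa = ra; res.ab = rb;
  }
  res.found = true;
  return res;
}

static List aln_to_list(const AlnResult& r) {
  return List::create(
    _["found"] = r.found,
    _["score"] = r.score,
    _["a_start"] = r.a_start, _["a_end"] = r.a_end,
    _["b_start"] = r.b_start, _["b_end"] = r.b_end,
    _["matches"] = r.matches, _["columns"] = r.columns,
    _["pairs"] = r.pairs, _["ts"] = r.ts, _["tv"] = r.tv,
    _["aligned_a"] = r.aa, _["aligned_b"] = r.ab);
}

// [[Rcpp::export]]
List cpp_align(std::string a, std::string b, int dlo, int dhi, bool local,
               int match, int mismatch, int gap_open, int gap_extend,
               bool want_strings) {
  AlnResult r = band_dp(a, b, dlo, dhi, local, match, mismatch,
                        gap_open, gap_extend, want_strings);
  return aln_to_list(r);
}

// ---- seeded search -------------------------------------------------------

struct SeedMatch { int diag; int spos; };

// Find local alignments of query against subject by exact k-mer seeding,
// diagonal clustering, and banded extension. Plus strand only; the caller
// handles reverse-complement searches.
// [[Rcpp::export]]
DataFrame cpp_find_hits(std::string query, std::string subject,
                        int k, int pad,
                        int match, int mismatch, int gap_open, int gap_extend,
                        int max_seed_gap, int min_score, int min_seeds) {
  const int n = (int)query.size(), m = (int)subject.size();
  std::vector<int> qs, qe, ss, se, sc, mt, cl, pr, ts, tv;
  static int8_t code_tab[256];
  static bool code_init = false;
  if (!code_init) {
    for (int i = 0; i < 256; ++i) code_tab[i] = -1;
    code_tab[(unsigned char)'A'] = 0; code_tab[(unsigned char)'C'] = 1;
    code_tab[(unsigned char)'G'] = 2; code_tab[(unsigned char)'T'] = 3;
    code_init = true;
  }
  if (n >= k && m >= k) {
    // index query k-mers in a flat open-addressing table with chained
    // positions (fast misses dominate the subject scan)
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    size_t tsize = 64;
    while (tsize < (size_t)n * 4) tsize <<= 1;
    const uint64_t tmask = tsize - 1;
    std::vector<uint64_t> tkey(tsize, ~0ULL);
    std::vector<int> thead(tsize, -1);
    std::vector<int> tnext(n, -1);
    std::vector<int> tqpos(n, -1);
    int n_entries = 0;
    uint64_t key = 0; int run = 0;
    for (int i = 0; i < n; ++i) {
      int code = code_tab[(unsigned char)query[i]];
      if (code < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)code) & mask;
      if (++run >= k) {
        size_t slot = (key * 0x9E3779B97F4A7C15ULL) & tmask;
        while (tkey[slot] != ~0ULL && tkey[slot] != key)
          slot = (slot + 1) & tmask;
        tkey[slot] = key;
        tqpos[n_entries] = i - k + 1;
        tnext[n_entries] = thead[slot];
        thead[slot] = n_entries;
        ++n_entries;
      }
    }
    // scan subject
    std::vector<SeedMatch> hits;
    key = 0; run = 0;
    for (int j = 0; j < m; ++j) {
      int code = code_tab[(unsigned char)subject[j]];
      if (code < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)code) & mask;
      if (++run >= k) {
        size_t slot = (key * 0x9E3779B97F4A7C15ULL) & tmask;
        while (tkey[slot] != ~0ULL) {
          if (tkey[slot] == key) {
            int sp = j - k + 1;
            for (int e = thead[slot]; e >= 0; e = tnext[e]) {
              SeedMatch sm; sm.diag = sp - tqpos[e]; sm.spos = sp;
              hits.push_back(sm);
            }
            break;
          }
          slot = (slot + 1) & tmask;
        }
      }
    }
    if (!hits.empty()) {
      std::sort(hits.begin(), hits.end(), [](const SeedMatch& x, const SeedMatch& y) {
        if (x.diag != y.diag) return x.diag < y.diag;
        return x.spos < y.spos;
      });
      // cluster by diagonal proximity, then split on subject-position gaps
      std::vector<std::pair<size_t, size_t> > diag_groups;  // [lo, hi) into hits
      size_t lo = 0;
      for (size_t i = 1; i <= hits.size(); ++i) {
        if (i == hits.size() || hits[i].diag - hits[i - 1].diag > pad) {
          diag_groups.push_back(std::make_pair(lo, i));
          lo = i;
        }
      }
      for (size_t g = 0; g < diag_groups.size(); ++g) {
        size_t a0 = diag_groups[g].first, a1 = diag_groups[g].second;
        std::vector<SeedMatch> grp(hits.begin() + a0, hits.begin() + a1);
        std::sort(grp.begin(), grp.end(), [](const SeedMatch& x, const SeedMatch& y) {
          return x.spos < y.spos;
        });
        size_t c0 = 0;
        for (size_t i = 1; i <= grp.size(); ++i) {
          if (i == grp.size() || grp[i].spos - grp[i - 1].spos > max_seed_gap) {
            if ((int)(i - c0) < min_seeds) { c0 = i; continue; }
            int dmin = grp[c0].diag, dmax = grp[c0].diag;
            for (size_t t = c0; t < i; ++t) {
              dmin = std::min(dmin, grp[t].diag);
              dmax = std::max(dmax, grp[t].diag);
            }
            AlnResult r = band_dp(query, subject, dmin - pad, dmax + pad, true,
                                  match, mismatch, gap_open, gap_extend, false);
            if (r.found && r.score >= min_score) {
              qs.push_back(r.a_start); qe.push_back(r.a_end);
              ss.push_back(r.b_start); se.push_back(r.b_end);
              sc.push_back(r.score); mt.push_back(r.matches);
              cl.push_back(r.columns); pr.push_back(r.pairs);
              ts.push_back(r.ts); tv.push_back(r.tv);
            }
            c0 = i;
          }
        }
      }
    }
  }
  return DataFrame::create(
    _["q_start"] = qs, _["q_end"] = qe,
    _["s_start"] = ss, _["s_end"] = se,
    _["score"] = sc, _["matches"] = mt, _["columns"] = cl,
    _["pairs"] = pr, _["ts"] = ts, _["tv"] = tv);
}

// ---- tandem repeat detection --------------------------------------------

// For each candidate period p, score the self-match vector s[i] == s[i+p]
// (+1 match, -3 mismatch, so non-negative segments have >= 75% matches) and
// emit X-drop-delimited maximal segments with net score >= min_net.
// [[Rcpp::export]]
DataFrame cpp_tandem_segments(std::string s, int max_period, int min_net, int xdrop) {
  const int n = (int)s.size();
  std::vector<int> rs, re, rp, rm, rmm;
  int pmax = std::min(max_period, n - 1);
  for (int p = 1; p <= pmax; ++p) {
    const int L = n - p;
    int i = 0;
    while (i < L) {
      // skip leading mismatch
      bool m0 = (s[i] == s[i + p] && is_acgt(s[i]));
      if (!m0) { ++i; continue; }
      int cur = 0, bestv = 0, best_pos = i - 1, start = i;
      int jj = i;
      for (; jj < L; ++jj) {
        bool mm = (s[jj] == s[jj + p] && is_acgt(s[jj]));
        cur += mm ? 1 : -3;
        if (cur > bestv) { bestv = cur; best_pos = jj; }
        if (cur < 0 || bestv - cur > xdrop) break;
      }
      if (bestv >= min_net && best_pos >= start) {
        int mcount = 0, mmcount = 0;
        for (int t = start; t <= best_pos; ++t) {
          if (s[t] == s[t + p] && is_acgt(s[t])) ++mcount; else ++mmcount;
        }
        rs.push_back(start);
        re.push_back(best_pos + 1 + p);
        rp.push_back(p);
        rm.push_back(mcount);
        rmm.push_back(mmcount);
        i = best_pos + 1;
      } else {
        i = (jj >= L) ? L : jj + 1;
      }
    }
  }
  return DataFrame::create(
    _["start"] = rs, _["end"] = re, _["period"] = rp,
    _["m"] = rm, _["mm"] = rmm);
}
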