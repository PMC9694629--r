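#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// DNA seed-and-extend engine and banded aligners used by find_repeats(),
// find_mtpt() and classify_reads(). Sequences arrive as plain ACGTN
// strings oriented by the R layer; all coordinates returned are 1-based
// inclusive on the strings as given.

static inline int basecode(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4;  // N and anything else: never matches
  }
}

static inline bool base_match(char a, char b) {
  // N is a wildcard in neither direction: it always scores as a mismatch
  return a == b && a != 'N' && b != 'N';
}

struct Hsp {
  int qs, qe, ss, se;  // 0-based inclusive
  int score;
};

// ---------------------------------------------------------------------------
// banded affine local alignment (Smith-Waterman) over a window, used to
// refine/merge ungapped seed extensions into the final gapped HSP
// ---------------------------------------------------------------------------

struct RefineResult {
  int qs, qe, ss, se, score;
  int columns, matches, mismatches, gapopens, gapcols;
  bool ok;
};

static RefineResult banded_affine_local(const std::string& q, const std::string& s,
                                        int qw0, int qw1, int sw0, int sw1,
                                        int dlo, int dhi,
                                        int match, int mismatch,
                                        int gap_open, int gap_extend) {
  const int NEG = -1000000000;
  int m = qw1 - qw0 + 1;
  int W = dhi - dlo + 1;
  std::vector<int> H((size_t)(m + 1) * W, NEG), E((size_t)(m + 1) * W, NEG),
      F((size_t)(m + 1) * W, NEG);
  std::vector<uint8_t> tbH((size_t)(m + 1) * W, 0), tbE((size_t)(m + 1) * W, 0),
      tbF((size_t)(m + 1) * W, 0);
  // cell (i, k): i = number of q chars consumed (q index qw0+i-1 is last),
  // j = number of s chars consumed; k = (j - i) - dlo in [0, W)
  // H includes the empty-start option (local alignment: floor at 0).
  auto idx = [&](int i, int k) { return (size_t)i * W + k; };
  int best = 0, bi = -1, bk = -1;
  for (int i = 0; i <= m; ++i) {
    for (int k = 0; k < W; ++k) {
      int j = i + dlo + k;
      if (j < 0 || j > sw1 - sw0 + 1) continue;
      size_t id = idx(i, k);
      // E: gap in q (consume s char j)
      if (j > 0 && k > 0) {
        int fromH = H[idx(i, k - 1)];
        int fromE = E[idx(i, k - 1)];
        int e1 = (fromH > NEG / 2) ? fromH - gap_open - gap_extend : NEG;
        int e2 = (fromE > NEG / 2) ? fromE - gap_extend : NEG;
        if (e1 >= e2) { E[id] = e1; tbE[id] = 0; } else { E[id] = e2; tbE[id] = 1; }
      }
      // F: gap in s (consume q char i)
      if (i > 0 && k < W - 1) {
        int fromH = H[idx(i - 1, k + 1)];
        int fromF = F[idx(i - 1, k + 1)];
        int f1 = (fromH > NEG / 2) ? fromH - gap_open - gap_extend : NEG;
        int f2 = (fromF > NEG / 2) ? fromF - gap_extend : NEG;
        if (f1 >= f2) { F[id] = f1; tbF[id] = 0; } else { F[id] = f2; tbF[id] = 1; }
      }
      int h = 0; uint8_t tb = 0;  // start
      if (i > 0 && j > 0) {
        int dg = H[idx(i - 1, k)];
        if (dg > NEG / 2) {
          int sc = dg + (base_match(q[qw0 + i - 1], s[sw0 + j - 1]) ? match : -mismatch);
          if (sc > h) { h = sc; tb = 1; }
        }
      }
      if (E[id] > h) { h = E[id]; tb = 2; }
      if (F[id] > h) { h = F[id]; tb = 3; }
      H[id] = h; tbH[id] = tb;
      if (h > best) { best = h; bi = i; bk = k; }
    }
  }
  RefineResult r; r.ok = false;
  if (bi < 0) return r;
  // traceback
  int i = bi, k = bk;
  int columns = 0, matches = 0, mismatches = 0, gapopens = 0, gapcols = 0;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  r.qe = qw0 + i - 1; r.se = sw0 + (i + dlo + k) - 1; r.score = best;
  while (true) {
    size_t id = idx(i, k);
    if (state == 0) {
      uint8_t tb = tbH[id];
      if (tb == 0) break;
      if (tb == 1) {
        ++columns;
        if (base_match(q[qw0 + i - 1], s[sw0 + (i + dlo + k) - 1])) ++matches; else ++mismatches;
        i -= 1;  // k unchanged on diagonal move
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {  // E: consumed s char
      ++columns; ++gapcols;
      uint8_t tb = tbE[id];
      k -= 1;
      if (tb == 0) { ++gapopens; state = 0; }
    } else {  // F: consumed q char
      ++columns; ++gapcols;
      uint8_t tb = tbF[id];
      i -= 1; k += 1;
      if (tb == 0) { ++gapopens; state = 0; }
    }
  }
  r.qs = qw0 + i; r.ss = sw0 + (i + dlo + k);
  r.columns = columns; r.matches = matches; r.mismatches = mismatches;
  r.gapopens = gapopens; r.gapcols = gapcols;
  r.ok = best > 0 && columns > 0;
  return r;
}

// ---------------------------------------------------------------------------
// seed-and-extend HSP search
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_find_hsps(std::string q, std::string s,
                        int word, int match, int mismatch,
                        int gap_open, int gap_extend,
                        int xdrop, int min_ungapped,
                        bool same_chrom, int period,
                        int max_chain_gap, int band_pad) {
  int qlen = (int)q.size(), slen = (int)s.size();
  std::vector<Hsp> hsps;
  if (qlen >= word && slen >= word) {
    // index subject k-mers
    uint32_t mask = (word >= 16) ? 0xFFFFFFFFu : ((1u << (2 * word)) - 1u);
    std::vector<int32_t> heads((size_t)1 << (2 * word), -1);
    std::vector<int32_t> nxt(slen, -1);
    {
      uint32_t code = 0; int run = 0;
      for (int j = 0; j < slen; ++j) {
        int b = basecode(s[j]);
        if (b == 4) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint32_t)b) & mask;
        if (++run >= word) {
          int start = j - word + 1;
          nxt[start] = heads[code];
          heads[code] = start;
        }
      }
    }
    std::unordered_map<int64_t, int> reach;  // diag -> rightmost q index covered
    uint32_t code = 0; int run = 0;
    for (int i = 0; i < qlen; ++i) {
      int b = basecode(q[i]);
      if (b == 4) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)b) & mask;
      if (++run < word) continue;
      int qstart = i - word + 1;
      for (int j = heads[code]; j >= 0; j = nxt[j]) {
        int64_t diag = (int64_t)qstart - j;
        if (same_chrom) {
          if (j <= qstart) continue;              // mirror half-plane
          int64_t d = diag % period; if (d < 0) d += period;
          if (d == 0) continue;                   // trivial self / doubled-copy diagonal
        }
        auto it = reach.find(diag);
        if (it != reach.end() && it->second >= qstart) continue;
        // ungapped X-drop extension around the seed
        int score = word * match;
        int qi = qstart + word, sj = j + word;
        int cur = score, bestR = 0, endq = qstart + word - 1;
        while (qi < qlen && sj < slen) {
          cur += base_match(q[qi], s[sj]) ? match : -mismatch;
          int gain = cur - score;
          if (gain > bestR) { bestR = gain; endq = qi; }
          if (bestR - gain > xdrop) break;
          ++qi; ++sj;
        }
        qi = qstart - 1; sj = j - 1;
        cur = score; int bestL = 0, startq = qstart;
        while (qi >= 0 && sj >= 0) {
          cur += base_match(q[qi], s[sj]) ? match : -mismatch;
          int gain = cur - score;
          if (gain > bestL) { bestL = gain; startq = qi; }
          if (bestL - gain > xdrop) break;
          --qi; --sj;
        }
        int total = score + bestR + bestL;
        reach[diag] = endq;
        if (total >= min_ungapped) {
          Hsp h;
          h.qs = startq; h.qe = endq;
          h.ss = (int)(startq - diag); h.se = (int)(endq - diag);
          h.score = total;
          hsps.push_back(h);
        }
      }
    }
  }
  // chain colinear ungapped HSPs that are close on both sequences
  std::sort(hsps.begin(), hsps.end(), [](const Hsp& a, const Hsp& b) {
    return a.qs < b.qs;
  });
  int n = (int)hsps.size();
  std::vector<int> chain_id(n, -1);
  std::vector<std::vector<int>> chains;
  for (int a = 0; a < n; ++a) {
    bool placed = false;
    for (int c = (int)chains.size() - 1; c >= 0 && !placed; --c) {
      const Hsp& last = hsps[chains[c].back()];
      const Hsp& cur = hsps[a];
      int64_t dlast = (int64_t)last.qs - last.ss, dcur = (int64_t)cur.qs - cur.ss;
      if (cur.qs - last.qe <= max_chain_gap && cur.qs - last.qe > -50 &&
          cur.ss - last.se <= max_chain_gap && cur.ss > last.ss &&
          std::llabs(dcur - dlast) <= 50) {
        chains[c].push_back(a);
        placed = true;
      }
    }
    if (!placed) chains.push_back({a});
  }
  // refine each chain with a banded affine local alignment
  std::vector<RefineResult> out;
  for (auto& ch : chains) {
    int qs = qlen, qe = -1, ss = slen, se = -1;
    int64_t dmin = INT64_MAX, dmax = INT64_MIN;
    for (int id : ch) {
      const Hsp& h = hsps[id];
      qs = std::min(qs, h.qs); qe = std::max(qe, h.qe);
      ss = std::min(ss, h.ss); se = std::max(se, h.se);
      int64_t d = (int64_t)h.qs - h.ss;
      dmin = std::min(dmin, d); dmax = std::max(dmax, d);
    }
    int qw0 = std::max(0, qs - band_pad), qw1 = std::min(qlen - 1, qe + band_pad);
    int sw0 = std::max(0, ss - band_pad), sw1 = std::min(slen - 1, se + band_pad);
    // diagonal band relative to the window, with slack for refinement gaps
    int extra = 24;
    int dlo = (int)(dmin - (int64_t)(qw0 - sw0)); // j - i center offsets
    int dhi = (int)(dmax - (int64_t)(qw0 - sw0));
    // convert q-s diagonal to window (j - i): j - i = -(qdiag) + const
    // window diag of a cell aligning q index x to s index y (both window
    // rel., 1-based consumed counts) is (y - x) = (s - q) global + (qw0 - sw0)
    int lo = -(int)(dmax) + (qw0 - sw0) - extra;
    int hi = -(int)(dmin) + (qw0 - sw0) + extra;
    (void)dlo; (void)dhi;
    RefineResult r = banded_affine_local(q, s, qw0, qw1, sw0, sw1, lo, hi,
                                         match, mismatch, gap_open, gap_extend);
    if (r.ok) out.push_back(r);
  }
  int no = (int)out.size();
  IntegerVector rqs(no), rqe(no), rss(no), rse(no), rscore(no), rlen(no),
      rmis(no), rgapo(no), rgapc(no);
  NumericVector rident(no);
  for (int i = 0; i < no; ++i) {
    rqs[i] = out[i].qs + 1; rqe[i] = out[i].qe + 1;
    rss[i] = out[i].ss + 1; rse[i] = out[i].se + 1;
    rscore[i] = out[i].score; rlen[i] = out[i].columns;
    rmis[i] = out[i].mismatches; rgapo[i] = out[i].gapopens;
    rgapc[i] = out[i].gapcols;
    rident[i] = out[i].columns > 0 ? 100.0 * out[i].matches / out[i].columns : 0.0;
  }
  return DataFrame::create(
      _["qstart"] = rqs, _["qend"] = rqe, _["sstart"] = rss, _["send"] = rse,
      _["score"] = rscore, _["length"] = rlen, _["mismatches"] = rmis,
      _["gap_opens"] = rgapo, _["gap_cols"] = rgapc, _["identity"] = rident);
}

// ---------------------------------------------------------------------------
// read classification support: seed diagonal location + banded overlap
// alignment (free end gaps on both sequences; linear gap cost)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_best_diagonal(std::string a, std::string b, int k, int bucket) {
  // locate where pattern `a` sits in text `b` via exact k-mer matches;
  // returns c(count, diag) where diag = b_pos - a_pos (0-based) of the
  // best-supported diagonal bucket, or c(0, 0) when no k-mer is shared
  int alen = (int)a.size(), blen = (int)b.size();
  if (alen < k || blen < k) return IntegerVector::create(0, 0);
  uint32_t mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  std::unordered_map<uint32_t, std::vector<int>> index;
  {
    uint32_t code = 0; int run = 0;
    for (int i = 0; i < alen; ++i) {
      int bb = basecode(a[i]);
      if (bb == 4) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)bb) & mask;
      if (++run >= k) index[code].push_back(i - k + 1);
    }
  }
  std::unordered_map<int, std::pair<int, int64_t>> buckets;  // bucket -> (count, diag sum)
  uint32_t code = 0; int run = 0;
  for (int j = 0; j < blen; ++j) {
    int bb = basecode(b[j]);
    if (bb == 4) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)bb) & mask;
    if (++run < k) continue;
    auto it = index.find(code);
    if (it == index.end()) continue;
    int jstart = j - k + 1;
    for (int i : it->second) {
      int diag = jstart - i;
      int bk = diag >= 0 ? diag / bucket : -(((-diag) + bucket - 1) / bucket);
      auto& e = buckets[bk];
      e.first += 1; e.second += diag;
    }
  }
  if (buckets.empty()) return IntegerVector::create(0, 0);
  int bestc = 0; int64_t bestsum = 0;
  for (auto& kv : buckets) {
    // pool each bucket with its right neighbour so straddled diagonals count
    int c = kv.second.first; int64_t sm = kv.second.second;
    auto nb = buckets.find(kv.first + 1);
    if (nb != buckets.end()) { c += nb->second.first; sm += nb->second.second; }
    if (c > bestc) { bestc = c; bestsum = sm; }
  }
  int diag = (int)(bestsum / bestc);
  return IntegerVector::create(bestc, diag);
}

// [[Rcpp::export]]
List cpp_overlap_align(std::string a, std::string b, int diag_center, int band_w,
                       int match, int mismatch, int gap) {
  // overlap (dovetail/containment) alignment of a against b inside a
  // diagonal band: alignment must start on a boundary (i==0 or j==0) and
  // end on a boundary (i==m or j==n); maximises match/mismatch/gap score
  const int NEG = -1000000000;
  int m = (int)a.size(), n = (int)b.size();
  int W = 2 * band_w + 1;
  std::vector<int> H((size_t)(m + 1) * W, NEG);
  std::vector<uint8_t> tb((size_t)(m + 1) * W, 255);
  auto idx = [&](int i, int k) { return (size_t)i * W + k; };
  auto jof = [&](int i, int k) { return i + diag_center + (k - band_w); };
  int best = NEG, bi = -1, bk = -1;
  for (int i = 0; i <= m; ++i) {
    for (int k = 0; k < W; ++k) {
      int j = jof(i, k);
      if (j < 0 || j > n) continue;
      int h = NEG; uint8_t t = 255;
      if (i == 0 || j == 0) { h = 0; t = 0; }  // free prefix start
      if (i > 0 && j > 0) {
        int dg = H[idx(i - 1, k)];
        if (dg > NEG / 2) {
          int sc = dg + (base_match(a[i - 1], b[j - 1]) ? match : -mismatch);
          if (sc > h) { h = sc; t = 1; }
        }
      }
      if (i > 0 && k < W - 1) {  // consume a char (gap in b)
        int up = H[idx(i - 1, k + 1)];
        if (up > NEG / 2 && up - gap > h) { h = up - gap; t = 2; }
      }
      if (j > 0 && k > 0) {  // consume b char (gap in a)
        int lf = H[idx(i, k - 1)];
        if (lf > NEG / 2 && lf - gap > h) { h = lf - gap; t = 3; }
      }
      H[idx(i, k)] = h; tb[idx(i, k)] = t;
      if ((i == m || j == n) && h > best) { best = h; bi = i; bk = k; }
    }
  }
  if (bi < 0 || best <= NEG / 2)
    return List::create(_["score"] = NA_INTEGER);
  int i = bi, k = bk;
  int columns = 0, matches = 0, mismatches = 0, gapcols = 0;
  int a_end = i, b_end = jof(i, k);
  while (tb[idx(i, k)] != 0) {
    uint8_t t = tb[idx(i, k)];
    if (t == 1) {
      ++columns;
      if (base_match(a[i - 1], b[jof(i, k) - 1])) ++matches; else ++mismatches;
      i -= 1;
    } else if (t == 2) { ++columns; ++gapcols; i -= 1; k += 1; }
    else { ++columns; ++gapcols; k -= 1; }
  }
  return List::create(
      _["score"] = best,
      _["a_start"] = i + 1, _["a_end"] = a_end,
      _["b_start"] = jof(i, k) + 1, _["b_end"] = b_end,
      _["columns"] = columns, _["matches"] = matches,
      _["mismatches"] = mismatches, _["gap_cols"] = gapcols);
}

// ---------------------------------------------------------------------------
// batch read classification: conformations are indexed once, each read is
// scanned on both strands for shared k-mers, and each seeded conformation
// is aligned with a fast banded overlap kernel
// ---------------------------------------------------------------------------

struct BandAln {
  int score, a_start, a_end, columns, mismatches, gapcols;
  bool ok;
};

// banded overlap alignment with rolling score rows and a full traceback
// byte matrix; identical semantics to cpp_overlap_align
static BandAln band_align(const std::string& a, const std::string& b,
                          int diag_center, int band_w,
                          int match, int mismatch, int gap) {
  const int NEG = -1000000000;
  int m = (int)a.size(), n = (int)b.size();
  int W = 2 * band_w + 1;
  static thread_local std::vector<int> prev_v, cur_v;
  static thread_local std::vector<uint8_t> tb_v;
  prev_v.assign(W + 2, NEG); cur_v.assign(W + 2, NEG);
  tb_v.assign((size_t)(m + 1) * W, 255);
  int* prev = prev_v.data() + 1;  // sentinel NEG at k=-1 and k=W
  int* cur = cur_v.data() + 1;
  int best = NEG, bi = -1, bk = -1;
  // row 0
  for (int k = 0; k < W; ++k) {
    int j = diag_center + (k - band_w);
    if (j < 0 || j > n) continue;
    prev[k] = 0; tb_v[k] = 0;
    if (j == n && 0 > best) { best = 0; bi = 0; bk = k; }
  }
  for (int i = 1; i <= m; ++i) {
    int base_j = i + diag_center - band_w;  // j at k = 0
    uint8_t* tbrow = tb_v.data() + (size_t)i * W;
    for (int k = 0; k < W; ++k) cur[k] = NEG;
    int klo = std::max(0, -base_j);
    int khi = std::min(W - 1, n - base_j);
    const char ai = a[i - 1];
    if (klo <= khi && base_j + klo == 0) {
      // j == 0 boundary: free start of the read
      int u = prev[klo + 1] - gap;
      if (u > 0) { cur[klo] = u; tbrow[klo] = 2; }
      else { cur[klo] = 0; tbrow[klo] = 0; }
      ++klo;
    }
    const char* bj = b.data() + base_j - 1;
    for (int k = klo; k <= khi; ++k) {
      char bc = bj[k];
      int h = prev[k] + ((bc == ai && ai != 'N') ? match : -mismatch);
      uint8_t t = 1;
      int u = prev[k + 1] - gap;
      if (u > h) { h = u; t = 2; }
      int l = cur[k - 1] - gap;
      if (l > h) { h = l; t = 3; }
      cur[k] = h; tbrow[k] = t;
    }
    if (i == m) {
      for (int k = std::max(0, -base_j); k <= khi; ++k)
        if (cur[k] > best) { best = cur[k]; bi = i; bk = k; }
    } else if (n - base_j <= khi && n - base_j >= 0 && cur[n - base_j] > best) {
      best = cur[n - base_j]; bi = i; bk = n - base_j;
    }
    std::swap_ranges(prev_v.begin(), prev_v.end(), cur_v.begin());
  }
  BandAln r; r.ok = false;
  if (bi < 0 || best <= 0) return r;
  int i = bi, k = bk;
  r.score = best; r.a_end = i;
  int columns = 0, matches = 0, mismatches_n = 0, gapcols = 0;
  while (true) {
    uint8_t t = tb_v[(size_t)i * W + k];
    if (t == 0 || t == 255) break;
    if (t == 1) {
      ++columns;
      int j = i + diag_center + (k - band_w);
      if (base_match(a[i - 1], b[j - 1])) ++matches; else ++mismatches_n;
      i -= 1;
    } else if (t == 2) { ++columns; ++gapcols; i -= 1; k += 1; }
    else { ++columns; ++gapcols; k -= 1; }
  }
  r.a_start = i + 1;
  r.columns = columns; r.mismatches = mismatches_n; r.gapcols = gapcols;
  r.ok = columns > 0;
  return r;
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[s.size() - 1 - i];
    switch (c) {
      case 'A': out[i] = 'T'; break;
      case 'C': out[i] = 'G'; break;
      case 'G': out[i] = 'C'; break;
      case 'T': out[i] = 'A'; break;
      default:  out[i] = 'N'; break;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_classify_batch(CharacterVector reads, CharacterVector confs,
                        IntegerVector astart_max, IntegerVector aend_min,
                        int k, int band_w, int min_seeds,
                        int match, int mismatch, int gap) {
  int n_reads = reads.size(), n_conf = confs.size();
  std::vector<std::string> conf_s(n_conf);
  for (int c = 0; c < n_conf; ++c) conf_s[c] = as<std::string>(confs[c]);
  // joint k-mer index over all conformations
  uint32_t mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  std::unordered_map<uint32_t, std::vector<std::pair<int, int>>> index;
  for (int c = 0; c < n_conf; ++c) {
    const std::string& a = conf_s[c];
    uint32_t code = 0; int run = 0;
    for (int i = 0; i < (int)a.size(); ++i) {
      int b = basecode(a[i]);
      if (b == 4) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)b) & mask;
      if (++run >= k) index[code].push_back({c, i - k + 1});
    }
  }
  NumericMatrix score(n_reads, n_conf), divergence(n_reads, n_conf);
  IntegerMatrix covered(n_reads, n_conf), aligned(n_reads, n_conf);
  std::fill(score.begin(), score.end(), NA_REAL);
  std::fill(divergence.begin(), divergence.end(), NA_REAL);
  const int bucket = band_w;
  for (int r = 0; r < n_reads; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string rev = revcomp_str(fwd);
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& b = strand == 0 ? fwd : rev;
      // per-conformation diagonal histogram
      std::unordered_map<int64_t, std::pair<int, int64_t>> buckets;
      uint32_t code = 0; int run = 0;
      for (int j = 0; j < (int)b.size(); ++j) {
        int bb = basecode(b[j]);
        if (bb == 4) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint32_t)bb) & mask;
        if (++run < k) continue;
        auto it = index.find(code);
        if (it == index.end()) continue;
        int jstart = j - k + 1;
        for (auto& cp : it->second) {
          int diag = jstart - cp.second;
          int64_t bk = diag >= 0 ? diag / bucket : -(((int64_t)(-diag) + bucket - 1) / bucket);
          auto& e = buckets[((int64_t)cp.first << 40) ^ (bk + (1 << 20))];
          e.first += 1; e.second += diag;
        }
      }
      for (int c = 0; c < n_conf; ++c) {
        int bestc = 0; int64_t bestsum = 0;
        for (auto& kv : buckets) {
          if ((int)(kv.first >> 40) != c) continue;
          int cnt = kv.second.first; int64_t sm = kv.second.second;
          auto nb = buckets.find(kv.first + 1);
          if (nb != buckets.end()) { cnt += nb->second.first; sm += nb->second.second; }
          if (cnt > bestc) { bestc = cnt; bestsum = sm; }
        }
        if (bestc < min_seeds) continue;
        int diag = (int)(bestsum / bestc);
        BandAln aln = band_align(conf_s[c], b, diag, band_w, match, mismatch, gap);
        if (!aln.ok || aln.score <= 0) continue;
        bool cov = aln.a_start <= astart_max[c] && aln.a_end >= aend_min[c];
        double dv = (double)(aln.mismatches + aln.gapcols) / aln.columns;
        bool better = aligned(r, c) == 0 ||
          (cov && covered(r, c) == 0) ||
          (cov == (covered(r, c) == 1) && aln.score > score(r, c));
        if (better) {
          aligned(r, c) = 1;
          covered(r, c) = cov ? 1 : 0;
          score(r, c) = aln.score;
          divergence(r, c) = dv;
        }
      }
    }
  }
  return List::create(_["score"] = score, _["divergence"] = divergence,
                      _["covered"] = covered, _["aligned"] = aligned);
}

// ---------------------------------------------------------------------------
// long-read error model (substitutions, insertions, deletions) driven by
// the R RNG so set.seed() controls the output
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
std::string cpp_inject_errors(std::string seq, double sub_rate, double ins_rate,
                              double del_rate) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  std::string out;
  out.reserve(seq.size() + (size_t)(seq.size() * ins_rate * 2) + 16);
  for (size_t i = 0; i < seq.size(); ++i) {
    double u = unif_rand();
    if (u < del_rate) {
      // deleted base
    } else if (u < del_rate + sub_rate) {
      int b = basecode(seq[i]);
      if (b == 4) b = (int)(unif_rand() * 4.0);
      int nb = (b + 1 + (int)(unif_rand() * 3.0)) % 4;
      out.push_back(B[nb]);
    } else {
      out.push_back(seq[i]);
    }
    if (unif_rand() < ins_rate) out.push_back(B[(int)(unif_rand() * 4.0)]);
  }
  return out;
}
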