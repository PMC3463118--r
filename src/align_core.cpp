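// Core kernels: 2-bit k-mer encoding and index construction, heap-merge seed
// collation, fragment coalescing, banded affine-gap DP (global fill, X-drop
// extension) and an unbanded local Smith-Waterman used as the in-package
// accuracy oracle.
#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cstdint>
#include <queue>
#include <string>
#include <vector>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;  // safe -infinity for additive DP

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline bool base_eq(char a, char b) {
  int ca = base_code(a), cb = base_code(b);
  return ca >= 0 && ca == cb;  // ambiguous bases never match anything
}

// [[Rcpp::export]]
int encode_kmer_cpp(const std::string& kmer) {
  int code = 0;
  for (char ch : kmer) {
    int c = base_code(ch);
    if (c < 0) return -1;  // AMBIGUOUS sentinel
    code = (code << 2) | c;
  }
  return code;
}

// Scan every sequence, emitting (key, concatenated offset) for seed start
// positions {0, skip, 2*skip, ...} per sequence whose k-mer is unambiguous.
// Returns a CSR posting list: sorted unique keys, 0-based start offsets into
// the Reference Offset Array, and the ROA itself (ascending per key because
// positions are appended in genome order and the sort is by (key, pos)).
// [[Rcpp::export]]
List build_posting_cpp(CharacterVector seqs, int k, int skip) {
  std::vector<uint64_t> items;
  long long off = 0;
  const uint32_t mask = (uint32_t)((1u << (2 * k)) - 1u);  // k <= 15 -> <= 30 bits
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    std::string s = as<std::string>(seqs[si]);
    const int len = (int)s.size();
    uint32_t code = 0;
    long long lastBad = -1;
    for (int p = 0; p < len; ++p) {
      int c = base_code(s[p]);
      if (c < 0) { lastBad = p; c = 0; }
      code = ((code << 2) | (uint32_t)c) & mask;
      int start = p - k + 1;
      if (start >= 0 && start % skip == 0 && lastBad < start)
        items.push_back(((uint64_t)code << 32) | (uint32_t)(start + off));
    }
    off += len;
  }
  std::sort(items.begin(), items.end());
  const size_t n = items.size();
  std::vector<int> keys, starts, roa;
  roa.reserve(n);
  uint32_t prev = UINT32_MAX;
  for (size_t i = 0; i < n; ++i) {
    uint32_t key = (uint32_t)(items[i] >> 32);
    if (key != prev) {
      keys.push_back((int)key);
      starts.push_back((int)i);
      prev = key;
    }
    roa.push_back((int)(uint32_t)items[i]);
  }
  starts.push_back((int)n);
  return List::create(_["keys"] = wrap(keys), _["starts"] = wrap(starts),
                      _["roa"] = wrap(roa));
}

struct HeapEnt {
  int diag, qo, idx, end;
};
struct HeapCmp {
  bool operator()(const HeapEnt& a, const HeapEnt& b) const {
    if (a.diag != b.diag) return a.diag > b.diag;  // min-heap on (diag, qo)
    return a.qo > b.qo;
  }
};

// QL-way heap merge of the per-query-position pre-sorted ROA slices.
// Each slice is ascending in reference offset, hence ascending in diagonal
// for its fixed query offset, so popping by (diagonal, qo) yields a globally
// (diagonal, qo)-sorted seed stream with at most QL live heap entries.
// [[Rcpp::export]]
List collect_seeds_cpp(IntegerVector keys, IntegerVector starts,
                       IntegerVector roa, int k, const std::string& q) {
  const int len = (int)q.size();
  std::priority_queue<HeapEnt, std::vector<HeapEnt>, HeapCmp> heap;
  const uint32_t mask = (uint32_t)((1u << (2 * k)) - 1u);
  uint32_t code = 0;
  long long lastBad = -1;
  const int nk = keys.size();
  for (int p = 0; p < len; ++p) {
    int c = base_code(q[p]);
    if (c < 0) { lastBad = p; c = 0; }
    code = ((code << 2) | (uint32_t)c) & mask;
    int qo = p - k + 1;
    if (qo < 0 || lastBad >= qo) continue;
    // binary search for the key
    int lo = std::lower_bound(keys.begin(), keys.end(), (int)code) - keys.begin();
    if (lo < nk && keys[lo] == (int)code) {
      int idx = starts[lo], end = starts[lo + 1];
      if (idx < end) heap.push({roa[idx] - qo, qo, idx, end});
    }
  }
  const int peak = (int)heap.size();  // heap only shrinks or stays level
  std::vector<int> qos, ros;
  while (!heap.empty()) {
    HeapEnt e = heap.top();
    heap.pop();
    qos.push_back(e.qo);
    ros.push_back(roa[e.idx]);
    if (e.idx + 1 < e.end)
      heap.push({roa[e.idx + 1] - e.qo, e.qo, e.idx + 1, e.end});
  }
  return List::create(_["qo"] = wrap(qos), _["ro"] = wrap(ros),
                      _["peakHeap"] = peak);
}

// Coalesce (diagonal, qo)-sorted seeds into maximal fragments: successive
// seeds on one diagonal merge while next.qo <= prev.qo + k (abut or overlap),
// which keeps every merged span an exact match by construction.
// [[Rcpp::export]]
DataFrame build_fragments_cpp(IntegerVector qo, IntegerVector ro, int k) {
  std::vector<int> qs, qe, rs, re, cnt;
  const int n = qo.size();
  int curDiag = 0, curQs = 0, curQe = -1, lastQo = 0, curCnt = 0;
  for (int i = 0; i < n; ++i) {
    int d = ro[i] - qo[i];
    if (curQe >= 0 && d == curDiag && qo[i] <= lastQo + k) {
      if (qo[i] + k > curQe) curQe = qo[i] + k;
      lastQo = qo[i];
      ++curCnt;
    } else {
      if (curQe >= 0) {
        qs.push_back(curQs); qe.push_back(curQe);
        rs.push_back(curQs + curDiag); re.push_back(curQe + curDiag);
        cnt.push_back(curCnt);
      }
      curDiag = d; curQs = qo[i]; curQe = qo[i] + k; lastQo = qo[i]; curCnt = 1;
    }
  }
  if (curQe >= 0) {
    qs.push_back(curQs); qe.push_back(curQe);
    rs.push_back(curQs + curDiag); re.push_back(curQe + curDiag);
    cnt.push_back(curCnt);
  }
  return DataFrame::create(_["qStart"] = wrap(qs), _["qEnd"] = wrap(qe),
                           _["rStart"] = wrap(rs), _["rEnd"] = wrap(re),
                           _["seedCount"] = wrap(cnt));
}

// traceback byte layout: bits 0-1 H-choice (0 diag, 1 E, 2 F, 3 local stop),
// bit 2 E came from E (gap extension), bit 3 F came from F.
static std::string cigar_from_runs(const std::vector<std::pair<char, int> >& runs) {
  std::string out;
  for (size_t i = 0; i < runs.size(); ++i) {
    out += std::to_string(runs[i].second);
    out += runs[i].first;
  }
  return out;
}

// append op to reversed run list built during traceback
static void push_op(std::vector<std::pair<char, int> >& rev, char op) {
  if (!rev.empty() && rev.back().first == op) rev.back().second++;
  else rev.push_back(std::make_pair(op, 1));
}

// Global banded affine-gap alignment of a (query rows) vs b (reference cols).
// Band is |j - i| <= band around the main diagonal; if the endpoint diagonal
// lb-la falls outside, the corridor is widened once to cover it (flagged).
// Gap of length L costs gapOpen + gapExtend*L. Ties prefer M over D over I.
// [[Rcpp::export]]
List global_affine_cpp(const std::string& a, const std::string& b, int match,
                       int mismatch, int gapOpen, int gapExtend, int band) {
  const int la = (int)a.size(), lb = (int)b.size(), delta = lb - la;
  bool widened = false;
  int dLo = -band, dHi = band;
  if (delta < dLo || delta > dHi) {
    widened = true;
    dLo = std::min(0, delta) - band;
    dHi = std::max(0, delta) + band;
  }
  const int W = dHi - dLo + 1;
  if ((double)(la + 1) * W > 8e7) stop("banded fill too large");
  std::vector<int> Hprev(W, NEG), Fprev(W, NEG), Hcur(W, NEG), Fcur(W, NEG),
      Ecur(W, NEG);
  std::vector<unsigned char> tb((size_t)(la + 1) * W, 0);
  // row 0
  for (int d = 0; d < W; ++d) {
    int j = 0 + dLo + d;
    if (j < 0 || j > lb) continue;
    if (j == 0) { Hprev[d] = 0; }
    else {
      Hprev[d] = gapOpen + gapExtend * j;
      tb[d] = 1 | ((j > 1) ? 4 : 0);  // via E, extending if j > 1
    }
  }
  for (int i = 1; i <= la; ++i) {
    std::fill(Hcur.begin(), Hcur.end(), NEG);
    std::fill(Fcur.begin(), Fcur.end(), NEG);
    std::fill(Ecur.begin(), Ecur.end(), NEG);
    const int jmin = std::max(0, i + dLo), jmax = std::min(lb, i + dHi);
    for (int j = jmin; j <= jmax; ++j) {
      const int d = j - i - dLo;
      unsigned char bits = 0;
      // F: vertical (consumes query, I), from row i-1 same j -> offset d+1
      int f = NEG;
      if (d + 1 < W) {
        int fromH = (Hprev[d + 1] > NEG) ? Hprev[d + 1] + gapOpen + gapExtend : NEG;
        int fromF = (Fprev[d + 1] > NEG) ? Fprev[d + 1] + gapExtend : NEG;
        if (fromF > fromH) { f = fromF; bits |= 8; }
        else f = fromH;
      }
      Fcur[d] = f;
      // E: horizontal (consumes reference, D), from (i, j-1) -> offset d-1
      int e = NEG;
      if (d - 1 >= 0 && j - 1 >= jmin) {
        int fromH = (Hcur[d - 1] > NEG) ? Hcur[d - 1] + gapOpen + gapExtend : NEG;
        int fromE = (Ecur[d - 1] > NEG) ? Ecur[d - 1] + gapExtend : NEG;
        if (fromE > fromH) { e = fromE; bits |= 4; }
        else e = fromH;
      }
      Ecur[d] = e;
      int diag = NEG;
      if (j - 1 >= 0 && Hprev[d] > NEG)
        diag = Hprev[d] + (base_eq(a[i - 1], b[j - 1]) ? match : mismatch);
      int h;
      if (diag >= e && diag >= f) { h = diag; }
      else if (e >= f) { h = e; bits |= 1; }
      else { h = f; bits |= 2; }
      Hcur[d] = h;
      tb[(size_t)i * W + d] = bits;
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }
  const int dEnd = lb - la - dLo;
  const int score = Hprev[dEnd];
  // traceback
  std::vector<std::pair<char, int> > rev;
  int i = la, j = lb, state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 || j > 0) {
    unsigned char bits = tb[(size_t)i * W + (j - i - dLo)];
    if (state == 0) {
      int choice = bits & 3;
      if (choice == 0) { push_op(rev, 'M'); --i; --j; }
      else if (choice == 1) state = 1;
      else state = 2;
    } else if (state == 1) {
      push_op(rev, 'D');
      state = (bits & 4) ? 1 : 0;
      --j;
    } else {
      push_op(rev, 'I');
      state = (bits & 8) ? 2 : 0;
      --i;
    }
  }
  std::reverse(rev.begin(), rev.end());
  return List::create(_["score"] = score, _["cigar"] = cigar_from_runs(rev),
                      _["widened"] = widened);
}

// X-drop extension anchored at (0,0) of a vs b, free end. Banded |j-i|<=band.
// A row is the unit of pruning: once the best H in a row falls more than X
// below the best score seen, extension stops. Returns the best extension
// (empty, score 0, if nothing positive is reachable).
// [[Rcpp::export]]
List xdrop_extend_cpp(const std::string& a, const std::string& b, int match,
                      int mismatch, int gapOpen, int gapExtend, int band,
                      double X) {
  const int la = (int)a.size(), lb = (int)b.size();
  const int dLo = -band, W = 2 * band + 1;
  if ((double)(la + 1) * W > 1.6e8) stop("x-drop extension too large");
  std::vector<int> Hprev(W, NEG), Fprev(W, NEG), Hcur(W, NEG), Fcur(W, NEG),
      Ecur(W, NEG);
  std::vector<unsigned char> tb((size_t)(la + 1) * W, 0);
  int best = 0, bi = 0, bj = 0;
  // row 0
  for (int d = 0; d < W; ++d) {
    int j = dLo + d;
    if (j < 0 || j > lb || j > band) continue;
    if (j == 0) Hprev[d] = 0;
    else {
      Hprev[d] = gapOpen + gapExtend * j;
      tb[d] = 1 | ((j > 1) ? 4 : 0);
    }
  }
  int lastRow = 0;
  for (int i = 1; i <= la; ++i) {
    const int jmin = std::max(0, i + dLo), jmax = std::min(lb, i - dLo);
    if (jmin > jmax) break;
    std::fill(Hcur.begin(), Hcur.end(), NEG);
    std::fill(Fcur.begin(), Fcur.end(), NEG);
    std::fill(Ecur.begin(), Ecur.end(), NEG);
    int rowBest = NEG;
    for (int j = jmin; j <= jmax; ++j) {
      const int d = j - i - dLo;
      unsigned char bits = 0;
      int f = NEG;
      if (d + 1 < W) {
        int fromH = (Hprev[d + 1] > NEG) ? Hprev[d + 1] + gapOpen + gapExtend : NEG;
        int fromF = (Fprev[d + 1] > NEG) ? Fprev[d + 1] + gapExtend : NEG;
        if (fromF > fromH) { f = fromF; bits |= 8; }
        else f = fromH;
      }
      Fcur[d] = f;
      int e = NEG;
      if (d - 1 >= 0 && j - 1 >= jmin) {
        int fromH = (Hcur[d - 1] > NEG) ? Hcur[d - 1] + gapOpen + gapExtend : NEG;
        int fromE = (Ecur[d - 1] > NEG) ? Ecur[d - 1] + gapExtend : NEG;
        if (fromE > fromH) { e = fromE; bits |= 4; }
        else e = fromH;
      }
      Ecur[d] = e;
      int diag = NEG;
      if (j - 1 >= 0 && Hprev[d] > NEG)
        diag = Hprev[d] + (base_eq(a[i - 1], b[j - 1]) ? match : mismatch);
      int h;
      if (diag >= e && diag >= f) h = diag;
      else if (e >= f) { h = e; bits |= 1; }
      else { h = f; bits |= 2; }
      Hcur[d] = h;
      tb[(size_t)i * W + d] = bits;
      if (h > rowBest) rowBest = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    lastRow = i;
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
    if (rowBest < best - X) break;
  }
  (void)lastRow;
  if (best <= 0)
    return List::create(_["score"] = 0, _["qExt"] = 0, _["rExt"] = 0,
                        _["cigar"] = "");
  std::vector<std::pair<char, int> > rev;
  int i = bi, j = bj, state = 0;
  while (i > 0 || j > 0) {
    unsigned char bits = tb[(size_t)i * W + (j - i - dLo)];
    if (state == 0) {
      int choice = bits & 3;
      if (choice == 0) { push_op(rev, 'M'); --i; --j; }
      else if (choice == 1) state = 1;
      else state = 2;
    } else if (state == 1) {
      push_op(rev, 'D'); state = (bits & 4) ? 1 : 0; --j;
    } else {
      push_op(rev, 'I'); state = (bits & 8) ? 2 : 0; --i;
    }
  }
  std::reverse(rev.begin(), rev.end());
  return List::create(_["score"] = best, _["qExt"] = bi, _["rExt"] = bj,
                      _["cigar"] = cigar_from_runs(rev));
}

// Unbanded local affine-gap Smith-Waterman with full traceback; quadratic in
// time and (byte) space. Serves as the exact accuracy benchmark.
// [[Rcpp::export]]
List sw_local_cpp(const std::string& a, const std::string& b, int match,
                  int mismatch, int gapOpen, int gapExtend) {
  const int la = (int)a.size(), lb = (int)b.size();
  if ((double)(la + 1) * (lb + 1) > 1.6e8) stop("local DP too large");
  std::vector<int> Hprev(lb + 1, 0), Hcur(lb + 1, 0), Fcol(lb + 1, NEG);
  std::vector<unsigned char> tb((size_t)(la + 1) * (lb + 1), 3);  // 3 = stop
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= la; ++i) {
    int e = NEG;
    Hcur[0] = 0;
    for (int j = 1; j <= lb; ++j) {
      unsigned char bits = 0;
      int fromH = Hprev[j] + gapOpen + gapExtend;
      int fromF = (Fcol[j] > NEG) ? Fcol[j] + gapExtend : NEG;
      int f;
      if (fromF > fromH) { f = fromF; bits |= 8; }
      else f = fromH;
      Fcol[j] = f;
      int eoH = Hcur[j - 1] + gapOpen + gapExtend;
      int eoE = (e > NEG) ? e + gapExtend : NEG;
      if (eoE > eoH) { e = eoE; bits |= 4; }
      else e = eoH;
      int diag = Hprev[j - 1] + (base_eq(a[i - 1], b[j - 1]) ? match : mismatch);
      int h, choice;
      if (diag >= e && diag >= f) { h = diag; choice = 0; }
      else if (e >= f) { h = e; choice = 1; }
      else { h = f; choice = 2; }
      if (h <= 0) { h = 0; choice = 3; }
      Hcur[j] = h;
      tb[(size_t)i * (lb + 1) + j] = (unsigned char)(choice | (bits & 12));
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  if (best <= 0)
    return List::create(_["score"] = 0, _["qStart"] = 0, _["qEnd"] = 0,
                        _["rStart"] = 0, _["rEnd"] = 0, _["cigar"] = "");
  std::vector<std::pair<char, int> > rev;
  int i = bi, j = bj, state = 0;
  while (true) {
    unsigned char bits = tb[(size_t)i * (lb + 1) + j];
    if (state == 0) {
      int choice = bits & 3;
      if (choice == 3) break;  // reached a zero cell: local start
      if (choice == 0) {
        push_op(rev, 'M'); --i; --j;
        if (i == 0 || j == 0) break;
      } else if (choice == 1) state = 1;
      else state = 2;
    } else if (state == 1) {
      push_op(rev, 'D'); state = (bits & 4) ? 1 : 0; --j;
      if (j == 0) break;
    } else {
      push_op(rev, 'I'); state = (bits & 8) ? 2 : 0; --i;
      if (i == 0) break;
    }
  }
  std::reverse(rev.begin(), rev.end());
  return List::create(_["score"] = best, _["qStart"] = i, _["qEnd"] = bi,
                      _["rStart"] = j, _["rEnd"] = bj,
                      _["cigar"] = cigar_from_runs(rev));
}

// Recompute the affine-gap score of a CIGAR (M/I/D, optionally =/X treated as
// M) against the aligned slices of query and reference.
// [[Rcpp::export]]
List rescore_cigar_cpp(const std::string& a, const std::string& b,
                       const std::string& cigar, int match, int mismatch,
                       int gapOpen, int gapExtend) {
  long long score = 0;
  size_t ia = 0, ib = 0;
  int len = 0;
  for (char ch : cigar) {
    if (ch >= '0' && ch <= '9') { len = len * 10 + (ch - '0'); continue; }
    if (ch == 'M' || ch == '=' || ch == 'X') {
      for (int t = 0; t < len; ++t) {
        if (ia >= a.size() || ib >= b.size()) stop("CIGAR overruns sequences");
        score += base_eq(a[ia], b[ib]) ? match : mismatch;
        ++ia; ++ib;
      }
    } else if (ch == 'I') {
      score += gapOpen + (long long)gapExtend * len;
      ia += len;
    } else if (ch == 'D') {
      score += gapOpen + (long long)gapExtend * len;
      ib += len;
    } else if (ch == 'S') {
      ia += len;
    } else {
      stop("unsupported CIGAR op");
    }
    len = 0;
  }
  if (ia > a.size() || ib > b.size()) stop("CIGAR overruns sequences");
  return List::create(_["score"] = (double)score, _["qConsumed"] = (double)ia,
                      _["rConsumed"] = (double)ib);
}

// [[Rcpp::export]]
RawVector pack_ref_cpp(const std::string& s) {
  const size_t n = s.size();
  RawVector out((n + 3) / 4);
  unsigned char cur = 0;
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) c = 0;  // ambiguous bases packed as A; caller records positions
    cur |= (unsigned char)(c << ((i & 3) * 2));
    if ((i & 3) == 3) { out[i >> 2] = cur; cur = 0; }
  }
  if (n & 3) out[n >> 2] = cur;
  return out;
}

// [[Rcpp::export]]
std::string unpack_ref_cpp(RawVector packed, double len) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  const size_t n = (size_t)len;
  std::string out(n, 'A');
  for (size_t i = 0; i < n; ++i)
    out[i] = bases[(packed[i >> 2] >> ((i & 3) * 2)) & 3];
  return out;
}
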