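#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>

using namespace Rcpp;

// Alignment lattice convention: rows i = 0..l2 index the vertical (second)
// sequence, columns j = 0..l1 the horizontal (first) sequence.  A cell (i,j)
// lies in the band iff -w-(l1-l2) <= i-j <= +w.  CIGAR ops: M consumes both
// sequences, I consumes the vertical one (gap in the horizontal sequence),
// D consumes the horizontal one (gap in the vertical sequence).

static const int NEG_INF = INT_MIN / 4;

// Only A/C/G/T can match; any other letter mismatches even against itself.
static inline int sub_score(char a, char b, int match, int mismatch) {
  if (a == b && (a == 'A' || a == 'C' || a == 'G' || a == 'T')) return match;
  return mismatch;
}

static std::string rle_cigar(const std::vector<char>& ops) {
  std::string out;
  size_t k = 0;
  while (k < ops.size()) {
    size_t run = 1;
    while (k + run < ops.size() && ops[k + run] == ops[k]) ++run;
    out += std::to_string(run);
    out += ops[k];
    k += run;
  }
  return out;
}

struct TraceOut {
  std::string cigar;
  int i0, j0, i1, j1;
  int n_match, n_mismatch, n_gap;
  bool touched_edge;
};

// dir codes: 0 = stop, 1 = diagonal (M), 2 = left (D), 3 = up (I)
static TraceOut walk_back(const std::vector<unsigned char>& dir,
                          long long stride, // index = i*stride + offset(i,j)
                          int i1, int j1,
                          const std::string& h, const std::string& v,
                          int match,
                          bool banded, int whi,
                          int wlo /* offset(i,j) = j - (i - whi) */) {
  std::vector<char> ops;
  TraceOut out;
  out.i1 = i1; out.j1 = j1;
  out.n_match = 0; out.n_mismatch = 0; out.n_gap = 0;
  out.touched_edge = false;
  int i = i1, j = j1;
  for (;;) {
    if (banded && (i - j == whi || i - j == -wlo)) out.touched_edge = true;
    long long idx = (long long)i * stride +
                    (banded ? (j - (i - whi)) : j);
    unsigned char d = dir[idx];
    if (d == 0) break;
    if (d == 1) {
      if (sub_score(h[j - 1], v[i - 1], 1, 0) == 1) out.n_match++;
      else out.n_mismatch++;
      ops.push_back('M');
      --i; --j;
    } else if (d == 2) {
      ops.push_back('D');
      out.n_gap++;
      --j;
    } else {
      ops.push_back('I');
      out.n_gap++;
      --i;
    }
  }
  (void)match;
  out.i0 = i; out.j0 = j;
  std::reverse(ops.begin(), ops.end());
  out.cigar = rle_cigar(ops);
  return out;
}

static List result_list(int score, const TraceOut& t, bool banded) {
  return List::create(
    _["score"] = score,
    _["cigar"] = t.cigar,
    _["i0"] = t.i0, _["j0"] = t.j0, _["i1"] = t.i1, _["j1"] = t.j1,
    _["n_match"] = t.n_match,
    _["n_mismatch"] = t.n_mismatch,
    _["n_gap"] = t.n_gap,
    _["touched_edge"] = banded ? LogicalVector::create(t.touched_edge)
                               : LogicalVector::create(NA_LOGICAL));
}

// [[Rcpp::export]]
List cpp_full_dp(std::string h, std::string v,
                 int match, int mismatch, int gap, bool semiglobal) {
  const int l1 = (int)h.size(), l2 = (int)v.size();
  const long long stride = l1 + 1;
  std::vector<int> S((long long)(l2 + 1) * stride);
  std::vector<unsigned char> dir((long long)(l2 + 1) * stride);

  S[0] = 0; dir[0] = 0;
  for (int j = 1; j <= l1; ++j) {
    S[j] = semiglobal ? 0 : j * gap;
    dir[j] = semiglobal ? 0 : 2;
  }
  for (int i = 1; i <= l2; ++i) {
    S[(long long)i * stride] = semiglobal ? 0 : i * gap;
    dir[(long long)i * stride] = semiglobal ? 0 : 3;
  }
  for (int i = 1; i <= l2; ++i) {
    const char vc = v[i - 1];
    int* Sp = &S[(long long)(i - 1) * stride];
    int* Sc = &S[(long long)i * stride];
    unsigned char* Dc = &dir[(long long)i * stride];
    for (int j = 1; j <= l1; ++j) {
      int diag = Sp[j - 1] + sub_score(h[j - 1], vc, match, mismatch);
      int left = Sc[j - 1] + gap;
      int up = Sp[j] + gap;
      // tie preference: M, then D (left), then I (up)
      if (diag >= left && diag >= up) { Sc[j] = diag; Dc[j] = 1; }
      else if (left >= up)            { Sc[j] = left; Dc[j] = 2; }
      else                            { Sc[j] = up;   Dc[j] = 3; }
    }
  }

  int bi = l2, bj = l1;
  if (semiglobal) {
    int best = NEG_INF;
    for (int j = 0; j <= l1; ++j) {
      int s = S[(long long)l2 * stride + j];
      if (s > best) { best = s; bi = l2; bj = j; }
    }
    for (int i = 0; i < l2; ++i) {
      int s = S[(long long)i * stride + l1];
      if (s > best) { best = s; bi = i; bj = l1; }
    }
  }
  int score = S[(long long)bi * stride + bj];
  TraceOut t = walk_back(dir, stride, bi, bj, h, v, match,
                         false, 0, 0);
  return result_list(score, t, false);
}

// Banded variant.  Requires l1 >= l2 (the caller orients the pair).  The
// band is asymmetric in general: cell (i,j) is in-band iff
// -wlo <= i-j <= +whi.  The corridor band of half-width w has whi = w,
// wlo = w + (l1-l2); the symmetric band has whi = wlo = w.  Row i holds
// columns j in [max(0, i-whi), min(l1, i+wlo)], stored at offset
// j - (i - whi), so each row needs whi+wlo+1 slots and the whole table
// (whi+wlo+1)*(l2+1) cells -- never l1*l2.
// prefer_up mirrors the tie preferences (and the semiglobal end-cell scan
// order); the caller sets it when the pair was transposed so ties resolve
// identically in the original coordinates.
// [[Rcpp::export]]
List cpp_banded_dp(std::string h, std::string v,
                   int match, int mismatch, int gap, bool semiglobal,
                   int whi, int wlo, bool prefer_up = false) {
  const int l1 = (int)h.size(), l2 = (int)v.size();
  if (l1 < l2) stop("banded DP requires length(h) >= length(v)");
  if (whi < 0 || wlo < 0) stop("band half-width must be >= 0");
  if (!semiglobal && wlo < l1 - l2)
    stop("band too narrow to reach the global corner cell");
  const long long stride = (long long)whi + wlo + 1;
  std::vector<int> S((long long)(l2 + 1) * stride, NEG_INF);
  std::vector<unsigned char> dir((long long)(l2 + 1) * stride, 0);

  auto lo = [&](int i) { return std::max(0, i - whi); };
  auto hi = [&](int i) { return std::min(l1, i + wlo); };
  auto at = [&](int i, int j) -> long long {
    return (long long)i * stride + (j - (i - whi));
  };

  for (int j = 0; j <= hi(0); ++j) {
    S[at(0, j)] = semiglobal ? 0 : j * gap;
    dir[at(0, j)] = (semiglobal || j == 0) ? 0 : 2;
  }
  for (int i = 1; i <= std::min(l2, whi); ++i) {
    S[at(i, 0)] = semiglobal ? 0 : i * gap;
    dir[at(i, 0)] = semiglobal ? 0 : 3;
  }
  for (int i = 1; i <= l2; ++i) {
    const char vc = v[i - 1];
    const int jl = std::max(1, lo(i)), jh = hi(i);
    for (int j = jl; j <= jh; ++j) {
      // diagonal predecessor shares i-j, hence is in-band when it exists;
      // left/up predecessors fall outside at the band boundaries.
      int diag = S[at(i - 1, j - 1)] +
                 sub_score(h[j - 1], vc, match, mismatch);
      int left = (i - j < whi) ? S[at(i, j - 1)] + gap : NEG_INF;
      int up = (i - j > -wlo) ? S[at(i - 1, j)] + gap : NEG_INF;
      long long idx = at(i, j);
      bool take_left = prefer_up ? (left > up) : (left >= up);
      if (diag >= left && diag >= up) { S[idx] = diag; dir[idx] = 1; }
      else if (take_left)             { S[idx] = left; dir[idx] = 2; }
      else                            { S[idx] = up;   dir[idx] = 3; }
    }
  }

  int bi = l2, bj = l1;
  if (semiglobal && !prefer_up) {
    int best = NEG_INF;
    for (int j = lo(l2); j <= hi(l2); ++j) {
      int s = S[at(l2, j)];
      if (s > best) { best = s; bi = l2; bj = j; }
    }
    for (int i = 0; i < l2; ++i) {
      if (hi(i) == l1) {
        int s = S[at(i, l1)];
        if (s > best) { best = s; bi = i; bj = l1; }
      }
    }
  } else if (semiglobal) {
    // transposed caller: mirror the scan order (last column first)
    int best = NEG_INF;
    for (int i = 0; i <= l2; ++i) {
      if (hi(i) == l1) {
        int s = S[at(i, l1)];
        if (s > best) { best = s; bi = i; bj = l1; }
      }
    }
    for (int j = lo(l2); j <= hi(l2); ++j) {
      if (j == l1) continue;
      int s = S[at(l2, j)];
      if (s > best) { best = s; bi = l2; bj = j; }
    }
  }
  int score = S[at(bi, bj)];
  if (score <= NEG_INF / 2)
    stop("band admits no valid alignment path");
  TraceOut t = walk_back(dir, stride, bi, bj, h, v, match,
                         true, whi, wlo);
  return result_list(score, t, true);
}
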