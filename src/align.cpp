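#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
#include <cmath>
#include <cctype>

using namespace Rcpp;

// Affine-gap global aligner with free end gaps on the read side, plus the
// column-walking helpers the quantifier needs (indel left-alignment and
// window profile extraction). Scoring: a gap of length k costs
// gap_open + k * gap_extend; N scores 0 against anything and never counts
// as a match.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (char& c : out) c = comp_base(c);
  return out;
}

static inline double sub_score(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return 0.0;
  return (a == b) ? match : mismatch;
}

// Score-only pass (rolling rows), used to pick the read orientation before
// committing to a full traceback.
static double align_score_only(const std::string& read, const std::string& ref,
                               double match, double mismatch,
                               double go, double ge) {
  const size_t n = read.size(), m = ref.size();
  std::vector<double> Hprev(m + 1), Hcur(m + 1), Yprev(m + 1), Ycur(m + 1);
  // i = 0: free leading deletions over the reference
  for (size_t j = 0; j <= m; ++j) { Hprev[j] = 0.0; Yprev[j] = NEG_INF; }
  for (size_t i = 1; i <= n; ++i) {
    double X = NEG_INF;  // gap in read (deletion), rolling within the row
    Hcur[0] = go + ge * (double)i;  // read overhang at the left edge
    Ycur[0] = Hcur[0];
    for (size_t j = 1; j <= m; ++j) {
      double M = Hprev[j - 1] + sub_score(read[i - 1], ref[j - 1], match, mismatch);
      double Yopen = Hprev[j] + go + ge;
      double Yext  = Yprev[j] + ge;
      Ycur[j] = (Yopen >= Yext) ? Yopen : Yext;
      double Xopen = Hcur[j - 1] + go + ge;
      double Xext  = X + ge;
      X = (Xopen >= Xext) ? Xopen : Xext;
      double h = M;
      if (X > h) h = X;
      if (Ycur[j] > h) h = Ycur[j];
      Hcur[j] = h;
    }
    std::swap(Hprev, Hcur);
    std::swap(Yprev, Ycur);
  }
  double best = NEG_INF;
  for (size_t j = 0; j <= m; ++j) if (Hprev[j] > best) best = Hprev[j];  // free trailing deletions
  return best;
}

struct AlnResult {
  std::string aread, aref;
  double score;
};

// Full Gotoh with traceback. Ties resolve substitution > deletion (gap in
// read) > insertion (gap in ref); gap state ties prefer extension. Free
// leading/trailing deletions let a short read sit inside a longer amplicon.
static AlnResult align_full(const std::string& read, const std::string& ref,
                            double match, double mismatch,
                            double go, double ge) {
  const size_t n = read.size(), m = ref.size();
  const size_t W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
                      Y((n + 1) * W, NEG_INF);
  // traceback codes: for M, predecessor state of the diagonal move (0=M,1=X,2=Y);
  // for X/Y, 0 = opened (from best non-self), 1 = extended.
  std::vector<unsigned char> tM((n + 1) * W, 0), tX((n + 1) * W, 0), tY((n + 1) * W, 0);
  // which state opened X/Y (0=M,2=Y / 0=M,1=X)
  std::vector<unsigned char> oX((n + 1) * W, 0), oY((n + 1) * W, 0);

  M[0] = 0.0;
  for (size_t j = 1; j <= m; ++j) X[j] = 0.0;  // free leading deletion
  for (size_t i = 1; i <= n; ++i) {
    Y[i * W] = go + ge * (double)i;
    tY[i * W] = (i == 1) ? 0 : 1;
  }
  for (size_t i = 1; i <= n; ++i) {
    for (size_t j = 1; j <= m; ++j) {
      const size_t c = i * W + j, dc = (i - 1) * W + (j - 1),
                   up = (i - 1) * W + j, lf = i * W + j - 1;
      // M: diagonal from best of the three predecessor states
      double s = sub_score(read[i - 1], ref[j - 1], match, mismatch);
      double bm = M[dc]; unsigned char bs = 0;
      if (X[dc] > bm) { bm = X[dc]; bs = 1; }
      if (Y[dc] > bm) { bm = Y[dc]; bs = 2; }
      M[c] = (bm == NEG_INF) ? NEG_INF : bm + s;
      tM[c] = bs;
      // X: gap in read, consumes ref[j-1]
      double xo = std::max(M[lf], Y[lf]) + go + ge;
      double xe = X[lf] + ge;
      if (xe >= xo) { X[c] = xe; tX[c] = 1; }
      else { X[c] = xo; tX[c] = 0; oX[c] = (M[lf] >= Y[lf]) ? 0 : 2; }
      // Y: gap in ref, consumes read[i-1]
      double yo = std::max(M[up], X[up]) + go + ge;
      double yev = Y[up] + ge;
      if (yev >= yo) { Y[c] = yev; tY[c] = 1; }
      else { Y[c] = yo; tY[c] = 0; oY[c] = (M[up] >= X[up]) ? 0 : 1; }
    }
  }
  // terminal: best over last row with free trailing deletions; on ties take
  // the largest j (maximal aligned span, trailing gap as short as possible)
  double best = NEG_INF; size_t bj = 0; unsigned char bstate = 0;
  for (size_t j = 0; j <= m; ++j) {
    const size_t c = n * W + j;
    double h = M[c]; unsigned char st = 0;
    if (X[c] > h) { h = X[c]; st = 1; }
    if (Y[c] > h) { h = Y[c]; st = 2; }
    if (h >= best) { best = h; bj = j; bstate = st; }
  }
  AlnResult res;
  res.score = best;
  std::string ar, aref;
  // free trailing deletion padding
  for (size_t j = m; j > bj; --j) { ar.push_back('-'); aref.push_back(ref[j - 1]); }
  size_t i = n, j = bj; unsigned char st = bstate;
  while (i > 0 || j > 0) {
    const size_t c = i * W + j;
    if (i == 0) {  // free leading deletion region
      ar.push_back('-'); aref.push_back(ref[j - 1]); --j; continue;
    }
    if (j == 0) {
      ar.push_back(read[i - 1]); aref.push_back('-'); --i; continue;
    }
    if (st == 0) {
      ar.push_back(read[i - 1]); aref.push_back(ref[j - 1]);
      st = tM[c]; --i; --j;
    } else if (st == 1) {
      ar.push_back('-'); aref.push_back(ref[j - 1]);
      st = tX[c] ? 1 : oX[c]; --j;
    } else {
      ar.push_back(read[i - 1]); aref.push_back('-');
      st = tY[c] ? 2 : oY[c]; --i;
    }
  }
  res.aread = std::string(ar.rbegin(), ar.rend());
  res.aref = std::string(aref.rbegin(), aref.rend());
  return res;
}

// Left-align every indel run against its reference (or read) context so
// window membership does not depend on traceback internals.
static void left_align_pair(std::string& ar, std::string& aref) {
  bool changed = true;
  const size_t L = ar.size();
  while (changed) {
    changed = false;
    size_t k = 0;
    while (k < L) {
      if (ar[k] == '-') {  // deletion run
        size_t a = k, b = k;
        while (b + 1 < L && ar[b + 1] == '-') ++b;
        while (a > 0 && ar[a - 1] != '-' && aref[a - 1] != '-' &&
               aref[a - 1] == aref[b]) {
          ar[b] = ar[a - 1]; ar[a - 1] = '-';
          --a; --b; changed = true;
        }
        k = b + 1;
      } else if (aref[k] == '-') {  // insertion run
        size_t a = k, b = k;
        while (b + 1 < L && aref[b + 1] == '-') ++b;
        while (a > 0 && aref[a - 1] != '-' && ar[a - 1] != '-' &&
               ar[a - 1] == ar[b]) {
          aref[b] = aref[a - 1]; aref[a - 1] = '-';
          --a; --b; changed = true;
        }
        k = b + 1;
      } else ++k;
    }
  }
}

struct Profile {
  std::string window;
  bool indel_iw;
  double identity;
};

// Walk alignment columns, building the gapped window string over
// [qa, qb) (insertions lowercase before the following reference slot,
// deletions '-', uncovered positions 'N') and flagging indels whose
// left-aligned placement overlaps [ia, ib).
static Profile extract_profile(const std::string& ar, const std::string& aref,
                               int qa, int qb, int ia, int ib) {
  Profile p; p.indel_iw = false;
  const size_t L = ar.size();
  // covered span of the read (free end gaps are not deletions)
  size_t first = L, last = 0;
  for (size_t k = 0; k < L; ++k) if (ar[k] != '-') { if (first == L) first = k; last = k; }
  std::vector<std::string> slots(qb - qa);  // per reference offset in window
  std::vector<std::string> inserts(qb - qa + 1);
  int ref_off = 0;
  long matches = 0, read_bases = 0;
  for (size_t k = 0; k < L; ++k) {
    bool covered = (k >= first && k <= last && first < L);
    if (aref[k] == '-') {  // insertion: sits before reference offset ref_off
      ++read_bases;
      if (covered) {
        if (ref_off > ia && ref_off < ib) p.indel_iw = true;
        if (ref_off > qa && ref_off < qb)
          inserts[ref_off - qa] += (char)std::tolower(ar[k]);
      }
      continue;
    }
    if (ar[k] == '-') {  // deletion (or uncovered end)
      if (covered) {
        if (ref_off >= ia && ref_off < ib) p.indel_iw = true;
        if (ref_off >= qa && ref_off < qb) slots[ref_off - qa] = "-";
      } else {
        if (ref_off >= qa && ref_off < qb) slots[ref_off - qa] = "N";
      }
      ++ref_off;
      continue;
    }
    // aligned column
    ++read_bases;
    if (ar[k] == aref[k] && ar[k] != 'N') ++matches;
    if (ref_off >= qa && ref_off < qb) slots[ref_off - qa] = std::string(1, ar[k]);
    ++ref_off;
  }
  std::string w;
  for (int t = 0; t < qb - qa; ++t) {
    w += inserts[t];
    w += slots[t].empty() ? "N" : slots[t];
  }
  p.window = w;
  p.identity = (read_bases > 0) ? (double)matches / (double)read_bases : 0.0;
  return p;
}

// [[Rcpp::export]]
List align_batch_cpp(CharacterVector reads, std::string ref,
                     double match, double mismatch,
                     double gap_open, double gap_extend,
                     int qa, int qb, int ia, int ib,
                     double min_identity, bool check_rc) {
  const int N = reads.size();
  NumericVector score(N), identity(N);
  LogicalVector rc(N), accepted(N), indel_iw(N);
  CharacterVector aread(N), aref_out(N), window(N);
  for (int r = 0; r < N; ++r) {
    std::string rd = as<std::string>(reads[r]);
    bool used_rc = false;
    if (check_rc) {
      double sf = align_score_only(rd, ref, match, mismatch, gap_open, gap_extend);
      std::string rdrc = revcomp(rd);
      double sr = align_score_only(rdrc, ref, match, mismatch, gap_open, gap_extend);
      if (sr > sf) { rd = rdrc; used_rc = true; }
    }
    AlnResult a = align_full(rd, ref, match, mismatch, gap_open, gap_extend);
    left_align_pair(a.aread, a.aref);
    Profile p = extract_profile(a.aread, a.aref, qa, qb, ia, ib);
    score[r] = a.score;
    identity[r] = p.identity;
    rc[r] = used_rc;
    accepted[r] = p.identity >= min_identity;
    aread[r] = a.aread;
    aref_out[r] = a.aref;
    window[r] = p.window;
    indel_iw[r] = p.indel_iw;
  }
  return List::create(_["score"] = score, _["identity"] = identity,
                      _["rc"] = rc, _["accepted"] = accepted,
                      _["aligned_read"] = aread, _["aligned_ref"] = aref_out,
                      _["window"] = window, _["indel_in_window"] = indel_iw);
}

// [[Rcpp::export]]
List merge_pair_cpp(std::string s1, std::string q1,
                    std::string s2, std::string q2,
                    int min_overlap, int qual_cap) {
  // s2/q2 given in sequencing orientation (reverse-strand mate)
  std::string s2r = revcomp(s2);
  std::string q2r(q2.rbegin(), q2.rend());
  const int n1 = (int)s1.size(), n2 = (int)s2r.size();
  // shift d: position of s2r start relative to s1 start
  int best_d = 0, best_len = -1;
  double best_score = NEG_INF;
  for (int d = -(n2 - min_overlap); d <= n1 - min_overlap; ++d) {
    int lo = std::max(0, d), hi = std::min(n1, d + n2);
    int len = hi - lo;
    if (len < min_overlap) continue;
    double sc = 0.0;
    for (int k = lo; k < hi; ++k) {
      char a = s1[k], b = s2r[k - d];
      if (a == 'N' || b == 'N') continue;
      sc += (a == b) ? 1.0 : -1.0;
    }
    if (sc > best_score || (sc == best_score && len > best_len)) {
      best_score = sc; best_d = d; best_len = len;
    }
  }
  // require positive overlap evidence (more matches than mismatches)
  if (best_len < min_overlap || best_score <= 0.0) {
    return List::create(_["ok"] = false, _["reason"] = "no_overlap");
  }
  const int d = best_d;
  int start = std::min(0, d), end = std::max(n1, d + n2);
  std::string seq, qual;
  for (int pos = start; pos < end; ++pos) {
    bool in1 = (pos >= 0 && pos < n1);
    bool in2 = (pos >= d && pos < d + n2);
    if (in1 && in2) {
      char a = s1[pos], b = s2r[pos - d];
      int pa = q1[pos] - 33, pb = q2r[pos - d] - 33;
      if (a == b) {
        seq.push_back(a);
        qual.push_back((char)(std::min(pa + pb, qual_cap) + 33));
      } else if (a == 'N') {
        seq.push_back(b); qual.push_back((char)(pb + 33));
      } else if (b == 'N') {
        seq.push_back(a); qual.push_back((char)(pa + 33));
      } else if (pa >= pb) {  // tie keeps the first mate's call
        seq.push_back(a); qual.push_back((char)(pa + 33));
      } else {
        seq.push_back(b); qual.push_back((char)(pb + 33));
      }
    } else if (in1) {
      seq.push_back(s1[pos]); qual.push_back(q1[pos]);
    } else {
      seq.push_back(s2r[pos - d]); qual.push_back(q2r[pos - d]);
    }
  }
  return List::create(_["ok"] = true, _["seq"] = seq, _["qual"] = qual,
                      _["overlap"] = best_len, _["shift"] = d);
}
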