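// Read-level primitives for the amplicon screening pipeline:
//  - k-mer assignment of reads to amplicons
//  - fit (global-in-read) Gotoh alignment with affine gaps
//  - windowed ref/alt classification of aligned reads at a panel site
//  - longest tandem GAA run per read (repeat-per-read frequency)
//  - <=1-mismatch anchor search of a read against the repeat flank
//  - a batch driver combining the above per sample chunk

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static inline int baseCode(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// ------------------------------------------------------------------
// k-mer index over the amplicon set
// ------------------------------------------------------------------

struct KmerHit { int amp; int pos; };

struct KmerIndex {
  int k;
  int namp;
  std::unordered_map<uint64_t, std::vector<KmerHit> > map;
};

static KmerIndex buildIndex(const std::vector<std::string>& amps, int k) {
  KmerIndex idx;
  idx.k = k;
  idx.namp = (int)amps.size();
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int a = 0; a < (int)amps.size(); ++a) {
    const std::string& s = amps[a];
    uint64_t key = 0;
    int run = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int c = baseCode(s[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        // one entry per (k-mer, amplicon): assignment counts a read k-mer
        // position once per amplicon containing it, and the first position
        // is a sufficient diagonal representative (amplicon k-mers repeat
        // only inside the GAA tract, where no diagonal vote is needed)
        std::vector<KmerHit>& v = idx.map[key];
        if (v.empty() || v.back().amp != a)
          v.push_back(KmerHit{a, i - k + 1});
      }
    }
  }
  return idx;
}

struct AssignOut { int amp; int shared; int offset; };

// Per amplicon, count read k-mer positions whose k-mer occurs in that
// amplicon.  Winner must reach minShared and be strict (ties -> unassigned).
// The returned offset is the modal (amplicon pos - read pos) diagonal vote
// (ties -> smallest offset).
static AssignOut assignRead(const std::string& r, const KmerIndex& idx, int minShared,
                            std::vector<int>& counts,
                            std::vector<std::vector<int> >& offs,
                            std::vector<int>& touched) {
  const int k = idx.k;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t key = 0;
  int run = 0;
  for (int i = 0; i < (int)r.size(); ++i) {
    int c = baseCode(r[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run < k) continue;
    std::unordered_map<uint64_t, std::vector<KmerHit> >::const_iterator it = idx.map.find(key);
    if (it == idx.map.end()) continue;
    const int rp = i - k + 1;
    for (size_t h = 0; h < it->second.size(); ++h) {
      const KmerHit& hit = it->second[h];
      if (counts[hit.amp] == 0) touched.push_back(hit.amp);
      counts[hit.amp]++;
      offs[hit.amp].push_back(hit.pos - rp);
    }
  }
  AssignOut out;
  out.amp = -1; out.shared = 0; out.offset = 0;
  int best = -1, bestCount = 0, second = 0;
  for (size_t t = 0; t < touched.size(); ++t) {
    int a = touched[t];
    if (counts[a] > bestCount) { second = bestCount; bestCount = counts[a]; best = a; }
    else if (counts[a] > second) second = counts[a];
  }
  if (best >= 0 && bestCount >= minShared && bestCount > second) {
    std::vector<int>& v = offs[best];
    std::sort(v.begin(), v.end());
    int bo = v[0], bn = 1, cn = 1;
    for (size_t i = 1; i < v.size(); ++i) {
      if (v[i] == v[i - 1]) ++cn; else cn = 1;
      if (cn > bn) { bn = cn; bo = v[i]; }
    }
    out.amp = best; out.shared = bestCount; out.offset = bo;
  }
  for (size_t t = 0; t < touched.size(); ++t) {
    counts[touched[t]] = 0;
    offs[touched[t]].clear();
  }
  touched.clear();
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_assign_reads(CharacterVector reads, CharacterVector amps,
                               int k, int minShared) {
  std::vector<std::string> as(amps.size());
  for (int i = 0; i < amps.size(); ++i) as[i] = std::string(amps[i]);
  KmerIndex idx = buildIndex(as, k);
  std::vector<int> counts(idx.namp, 0);
  std::vector<std::vector<int> > offs(idx.namp);
  std::vector<int> touched;
  IntegerVector out(reads.size());
  for (int i = 0; i < reads.size(); ++i) {
    std::string r = std::string(reads[i]);
    AssignOut a = assignRead(r, idx, minShared, counts, offs, touched);
    out[i] = (a.amp < 0) ? NA_INTEGER : (a.amp + 1);
  }
  return out;
}

// ------------------------------------------------------------------
// Gotoh fit alignment: read is aligned end-to-end, reference flanks free.
// match +1, mismatch -1, gap of length L costs 3 + (L - 1) (open -3, ext -1).
// ------------------------------------------------------------------

static const int NEG = -1000000;

struct Aln {
  int score;
  int refStart;                 // 0-based reference offset of first aligned base
  std::vector<char> ops;        // 'M', 'I' (read insertion), 'D' (ref deletion)
  std::vector<int> lens;
};

static Aln fitAlign(const std::string& read, const std::string& ref) {
  const int m = (int)read.size(), n = (int)ref.size();
  const int W = n + 1;
  static std::vector<int> H, E, F;
  H.assign((size_t)(m + 1) * W, NEG);
  E.assign((size_t)(m + 1) * W, NEG);
  F.assign((size_t)(m + 1) * W, NEG);
  for (int j = 0; j <= n; ++j) H[j] = 0;            // free leading reference
  for (int i = 1; i <= m; ++i) {                    // read overhang before ref
    F[(size_t)i * W] = -2 - i;
    H[(size_t)i * W] = F[(size_t)i * W];
  }
  for (int i = 1; i <= m; ++i) {
    const char rc = read[i - 1];
    const bool rOk = baseCode(rc) >= 0;
    const size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    for (int j = 1; j <= n; ++j) {
      int e = std::max(H[row + j - 1] - 3, E[row + j - 1] - 1);
      int f = std::max(H[prow + j] - 3, F[prow + j] - 1);
      int s = (rOk && baseCode(ref[j - 1]) >= 0 && rc == ref[j - 1]) ? 1 : -1;
      int d = H[prow + j - 1] + s;
      int h = d;
      if (e > h) h = e;
      if (f > h) h = f;
      E[row + j] = e;
      F[row + j] = f;
      H[row + j] = h;
    }
  }
  // best end column in the last row; ties -> leftmost
  int bestJ = 0, bestS = NEG;
  const size_t lrow = (size_t)m * W;
  for (int j = 0; j <= n; ++j) {
    if (H[lrow + j] > bestS) { bestS = H[lrow + j]; bestJ = j; }
  }
  // traceback; at equal score prefer M, then D (ref gap), then I
  std::vector<char> rops;
  std::vector<int> rlens;
  int i = m, j = bestJ;
  char state = 'H';
  char pend = 0; int pendLen = 0;
  while (i > 0) {
    const size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    char op;
    if (j == 0) {
      op = 'I'; --i;
    } else if (state == 'H') {
      int s = (baseCode(read[i - 1]) >= 0 && baseCode(ref[j - 1]) >= 0 &&
               read[i - 1] == ref[j - 1]) ? 1 : -1;
      if (H[row + j] == H[prow + j - 1] + s) { op = 'M'; --i; --j; }
      else if (H[row + j] == E[row + j]) { state = 'E'; continue; }
      else { state = 'F'; continue; }
    } else if (state == 'E') {
      op = 'D';
      if (E[row + j] == H[row + j - 1] - 3) state = 'H';
      --j;
    } else { // F
      op = 'I';
      if (F[row + j] == H[prow + j] - 3) state = 'H';
      --i;
    }
    if (op == pend) ++pendLen;
    else {
      if (pend) { rops.push_back(pend); rlens.push_back(pendLen); }
      pend = op; pendLen = 1;
    }
  }
  if (pend) { rops.push_back(pend); rlens.push_back(pendLen); }
  Aln out;
  out.score = bestS;
  out.refStart = j;
  out.ops.assign(rops.rbegin(), rops.rend());
  out.lens.assign(rlens.rbegin(), rlens.rend());
  return out;
}

static std::string cigarString(const Aln& a) {
  std::string s;
  for (size_t t = 0; t < a.ops.size(); ++t) {
    s += std::to_string(a.lens[t]);
    s += a.ops[t];
  }
  return s;
}

// [[Rcpp::export]]
List cpp_fit_align(std::string read, std::string ref) {
  Aln a = fitAlign(read, ref);
  return List::create(_["score"] = a.score,
                      _["ref_start"] = a.refStart,
                      _["cigar"] = cigarString(a));
}

static void parseCigar(const std::string& cig, std::vector<char>& ops,
                       std::vector<int>& lens) {
  ops.clear(); lens.clear();
  int L = 0;
  for (size_t i = 0; i < cig.size(); ++i) {
    char c = cig[i];
    if (c >= '0' && c <= '9') L = L * 10 + (c - '0');
    else { ops.push_back(c); lens.push_back(L); L = 0; }
  }
}

// ------------------------------------------------------------------
// windowed classification of an aligned read at one panel site
// ------------------------------------------------------------------

// read index aligned (M) to reference position q; -1 deleted, -2 not covered
static int readIndexAt(int refStart, const std::vector<char>& ops,
                       const std::vector<int>& lens, int q) {
  if (q < refStart) return -2;
  int rp = 0, fp = refStart;
  for (size_t t = 0; t < ops.size(); ++t) {
    const char o = ops[t];
    const int L = lens[t];
    if (o == 'M') {
      if (q < fp + L) return rp + (q - fp);
      fp += L; rp += L;
    } else if (o == 'D') {
      if (q < fp + L) return -1;
      fp += L;
    } else if (o == 'I') {
      rp += L;
    }
  }
  return -2;
}

// 0 = ref, 1 = alt, 2 = other, -1 = window not covered (no depth)
static int classifyWindow(const std::string& read, int refStart,
                          const std::vector<char>& ops, const std::vector<int>& lens,
                          int a, int b,
                          const std::string& refWin, const std::string& altWin) {
  const int ra = readIndexAt(refStart, ops, lens, a);
  const int rb = readIndexAt(refStart, ops, lens, b);
  if (ra == -2 || rb == -2) return -1;
  if (ra < 0 || rb < 0 || rb < ra) return 2;
  const std::string obs = read.substr(ra, rb - ra + 1);
  if (obs == refWin) return 0;
  if (obs == altWin) return 1;
  return 2;
}

// [[Rcpp::export]]
IntegerVector cpp_classify_reads(CharacterVector reads, IntegerVector refStarts,
                                 CharacterVector cigars, int winStart, int winEnd,
                                 std::string refWin, std::string altWin) {
  IntegerVector out(reads.size());
  std::vector<char> ops; std::vector<int> lens;
  for (int i = 0; i < reads.size(); ++i) {
    parseCigar(std::string(cigars[i]), ops, lens);
    out[i] = classifyWindow(std::string(reads[i]), refStarts[i], ops, lens,
                            winStart, winEnd, refWin, altWin);
  }
  return out;
}

// ------------------------------------------------------------------
// longest tandem GAA run (triplets), scanning all phases/rotations
// ------------------------------------------------------------------

static inline bool gaaRotation(char x, char y, char z) {
  return (x == 'G' && y == 'A' && z == 'A') ||
         (x == 'A' && y == 'A' && z == 'G') ||
         (x == 'A' && y == 'G' && z == 'A');
}

static int gaaRun(const std::string& s) {
  const int n = (int)s.size();
  int best = 0, i = 0;
  while (i + 2 < n) {
    int j = i + 3;
    while (j < n && s[j] == s[j - 3]) ++j;
    if (gaaRotation(s[i], s[i + 1], s[i + 2]))
      best = std::max(best, (j - i) / 3);
    i = std::max(i + 1, j - 2);
  }
  return best;
}

// [[Rcpp::export]]
IntegerVector cpp_gaa_runs(CharacterVector reads) {
  IntegerVector out(reads.size());
  for (int i = 0; i < reads.size(); ++i) out[i] = gaaRun(std::string(reads[i]));
  return out;
}

// ------------------------------------------------------------------
// anchor search: does the read share a >= anchorLen stretch with the
// flank sequence at <= maxMis mismatches (any diagonal)?
// ------------------------------------------------------------------

static bool anchorHit(const std::string& r, const std::string& f,
                      int anchorLen, int maxMis) {
  const int m = (int)r.size(), L = (int)f.size();
  std::vector<int> q;
  for (int d = -(L - 1); d <= m - 1; ++d) {
    const int pLo = std::max(0, d), pHi = std::min(m - 1, d + L - 1);
    if (pHi - pLo + 1 < anchorLen) continue;
    q.clear();
    size_t qh = 0;
    int lo = pLo;
    for (int p = pLo; p <= pHi; ++p) {
      const char rc = r[p];
      if (!(baseCode(rc) >= 0 && rc == f[p - d])) {
        q.push_back(p);
        if ((int)(q.size() - qh) > maxMis) { lo = q[qh] + 1; ++qh; }
      }
      if (p - lo + 1 >= anchorLen) return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
LogicalVector cpp_anchor_hits(CharacterVector reads, std::string flank,
                              int anchorLen, int maxMismatch) {
  LogicalVector out(reads.size());
  for (int i = 0; i < reads.size(); ++i)
    out[i] = anchorHit(std::string(reads[i]), flank, anchorLen, maxMismatch);
  return out;
}

// ------------------------------------------------------------------
// batch driver: assign -> align (ungapped fast path, Gotoh fallback)
// -> per-variant windowed classification, plus GAA counts for reads on
// the repeat-locus amplicon.  Depths are accumulated per sample.
// ------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_screen_batch(CharacterVector reads, IntegerVector sampleIdx, int nSamples,
                      CharacterVector ampSeqs, int k, int minShared,
                      IntegerVector varAmp, IntegerVector varWinStart,
                      IntegerVector varWinEnd, CharacterVector varRefWin,
                      CharacterVector varAltWin, int fxnAmp,
                      int maxFastMismatch, double scoreFloorFrac, int minRepeats) {
  const int nVar = varAmp.size();
  std::vector<std::string> as(ampSeqs.size());
  for (int i = 0; i < ampSeqs.size(); ++i) as[i] = std::string(ampSeqs[i]);
  KmerIndex idx = buildIndex(as, k);
  std::vector<int> counts(idx.namp, 0);
  std::vector<std::vector<int> > offs(idx.namp);
  std::vector<int> touched;
  // variants per amplicon
  std::vector<std::vector<int> > byAmp(idx.namp);
  for (int v = 0; v < nVar; ++v) byAmp[varAmp[v] - 1].push_back(v);
  std::vector<std::string> refWins(nVar), altWins(nVar);
  for (int v = 0; v < nVar; ++v) {
    refWins[v] = std::string(varRefWin[v]);
    altWins[v] = std::string(varAltWin[v]);
  }
  IntegerMatrix refD(nSamples, nVar), altD(nSamples, nVar), othD(nSamples, nVar);
  IntegerVector assigned(reads.size());
  std::vector<int> fxnSample, fxnRepeats;
  std::vector<char> ops; std::vector<int> lens;
  for (int i = 0; i < reads.size(); ++i) {
    const std::string r = std::string(reads[i]);
    AssignOut a = assignRead(r, idx, minShared, counts, offs, touched);
    assigned[i] = (a.amp < 0) ? NA_INTEGER : (a.amp + 1);
    if (a.amp < 0) continue;
    const int smp = sampleIdx[i] - 1;
    if (a.amp == fxnAmp - 1) {
      const int g = gaaRun(r);
      if (g >= minRepeats) { fxnSample.push_back(smp + 1); fxnRepeats.push_back(g); }
      continue;
    }
    if (byAmp[a.amp].empty()) continue;
    const std::string& ref = as[a.amp];
    const int n = (int)ref.size(), m = (int)r.size();
    // ungapped fast path at the voted diagonal
    int mis = 0;
    for (int p = 0; p < m && mis <= maxFastMismatch; ++p) {
      const int fp = a.offset + p;
      if (fp < 0 || fp >= n || r[p] != ref[fp] || baseCode(r[p]) < 0) ++mis;
    }
    int refStart;
    if (mis <= maxFastMismatch) {
      refStart = a.offset;
      ops.assign(1, 'M');
      lens.assign(1, m);
    } else {
      Aln al = fitAlign(r, ref);
      if (al.score < -scoreFloorFrac * m) continue;   // below score floor
      refStart = al.refStart;
      ops = al.ops;
      lens = al.lens;
    }
    const std::vector<int>& vs = byAmp[a.amp];
    for (size_t t = 0; t < vs.size(); ++t) {
      const int v = vs[t];
      const int cls = classifyWindow(r, refStart, ops, lens, varWinStart[v],
                                     varWinEnd[v], refWins[v], altWins[v]);
      if (cls == 0) refD(smp, v)++;
      else if (cls == 1) altD(smp, v)++;
      else if (cls == 2) othD(smp, v)++;
    }
  }
  return List::create(_["ref"] = refD, _["alt"] = altD, _["other"] = othD,
                      _["assigned"] = assigned,
                      _["fxn_sample"] = wrap(fxnSample),
                      _["fxn_repeats"] = wrap(fxnRepeats));
}
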