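// Seed-and-extend local aligner.
//
// Exact k-mer seeding on both strands; candidate diagonals are extended
// with an ungapped pass and, when the ungapped alignment is not a perfect
// full-length match, with a full affine-gap Smith-Waterman restricted to a
// reference window wide enough to contain any optimal local alignment that
// includes the seed (window pad = read length, the upper bound on total
// productive gap length when gap_extend <= -1 and match <= 1... in general
// pad = read length covers all gaps paid for by read-length matches).
//
// Gap scoring: a gap of length g scores gap_open + g * gap_extend (both
// negative), i.e. the first gap base pays both the opening and an
// extension. Only the single best (primary) hit is reported; ties break by
// highest score, then lexicographically smallest reference name, then
// smallest start, then '+' strand.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N and friends: never part of a seed
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': case 'a': c = 'T'; break;
      case 'C': case 'c': c = 'G'; break;
      case 'G': case 'g': c = 'C'; break;
      case 'T': case 't': c = 'A'; break;
      default: c = 'N'; break;
    }
  }
  return r;
}

struct SeedHit { int ref; int pos; };

struct KmerIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<SeedHit>> table;
};

// Enumerate valid k-mers of s, calling f(kmer_code, position).
template <typename F>
static void for_each_kmer(const std::string& s, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t code = 0;
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base_code(s[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) f(code, (int)(i + 1 - k));
  }
}

static KmerIndex build_index(const std::vector<std::string>& refs, int k) {
  KmerIndex idx;
  idx.k = k;
  for (size_t r = 0; r < refs.size(); ++r) {
    for_each_kmer(refs[r], k, [&](uint64_t code, int pos) {
      idx.table[code].push_back(SeedHit{(int)r, pos});
    });
  }
  return idx;
}

struct Hit {
  bool mapped = false;
  int ref = -1;       // index into refs
  int start = 0;      // 0-based half-open on the forward reference
  int end = 0;
  char strand = '+';
  int aligned = 0;    // read bases in match/mismatch columns
  int score = 0;
};

struct AlignBuffers {
  std::vector<int> H, E, F;
};

// Full affine-gap local DP of read (length m) against window (length n).
// Returns best score; fills ref start/end (window coordinates, half-open)
// and the count of read bases in match/mismatch columns via traceback.
static int smith_waterman(const std::string& read, const char* win, int n,
                          int ma, int mi, int go, int ge,
                          AlignBuffers& buf,
                          int& w_start, int& w_end, int& aligned) {
  const int m = (int)read.size();
  const int W = n + 1;
  buf.H.assign((size_t)(m + 1) * W, 0);
  buf.E.assign((size_t)(m + 1) * W, INT32_MIN / 4);
  buf.F.assign((size_t)(m + 1) * W, INT32_MIN / 4);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int rc = base_code(read[i - 1]);
    int* Hi = &buf.H[(size_t)i * W];
    int* Hp = &buf.H[(size_t)(i - 1) * W];
    int* Ei = &buf.E[(size_t)i * W];
    int* Fi = &buf.F[(size_t)i * W];
    int* Fp = &buf.F[(size_t)(i - 1) * W];
    for (int j = 1; j <= n; ++j) {
      int wc = base_code(win[j - 1]);
      int sub = (rc >= 0 && rc == wc) ? ma : mi;
      int e = std::max(Hi[j - 1] + go + ge, Ei[j - 1] + ge);
      int f = std::max(Hp[j] + go + ge, Fp[j] + ge);
      int h = Hp[j - 1] + sub;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      Ei[j] = e; Fi[j] = f; Hi[j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback (recompute decisions from stored matrices)
  aligned = 0;
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = E (gap consuming window), 2 = F (gap in read)
  while (i > 0 && j > 0) {
    const size_t ro = (size_t)i * W, rp = (size_t)(i - 1) * W;
    if (state == 0) {
      int h = buf.H[ro + j];
      if (h == 0) break;
      int rc = base_code(read[i - 1]);
      int wc = base_code(win[j - 1]);
      int sub = (rc >= 0 && rc == wc) ? ma : mi;
      if (h == buf.H[rp + j - 1] + sub) { ++aligned; --i; --j; }
      else if (h == buf.E[ro + j]) state = 1;
      else state = 2;
    } else if (state == 1) {
      if (buf.E[ro + j] == buf.E[ro + j - 1] + ge) { --j; }
      else { --j; state = 0; }
    } else {
      if (buf.F[ro + j] == buf.F[rp + j] + ge) { --i; }
      else { --i; state = 0; }
    }
  }
  w_start = j;
  w_end = bj;
  return best;
}

// Candidate diagonal on one reference, for one read orientation.
struct Cand { int ref; int diag; };

static void collect_cands(const std::string& read, const KmerIndex& idx,
                          std::vector<Cand>& out) {
  out.clear();
  for_each_kmer(read, idx.k, [&](uint64_t code, int qpos) {
    auto it = idx.table.find(code);
    if (it == idx.table.end()) return;
    for (const SeedHit& sh : it->second)
      out.push_back(Cand{sh.ref, sh.pos - qpos});
  });
  std::sort(out.begin(), out.end(), [](const Cand& a, const Cand& b) {
    return a.ref != b.ref ? a.ref < b.ref : a.diag < b.diag;
  });
  // merge near-identical diagonals; the SW window pad covers the drift
  std::vector<Cand> merged;
  for (const Cand& c : out) {
    if (!merged.empty() && merged.back().ref == c.ref &&
        c.diag - merged.back().diag <= 12)
      continue;
    merged.push_back(c);
  }
  out.swap(merged);
}

// true if `cand` beats `best` under the deterministic tie-break
static bool better(const Hit& cand, const Hit& best,
                   const std::vector<std::string>& names) {
  if (!best.mapped) return true;
  if (cand.score != best.score) return cand.score > best.score;
  int c = names[cand.ref].compare(names[best.ref]);
  if (c != 0) return c < 0;
  if (cand.start != best.start) return cand.start < best.start;
  return cand.strand == '+' && best.strand == '-';
}

static void align_one_orientation(const std::string& oriented, char strand,
                                  const std::vector<std::string>& refs,
                                  const std::vector<std::string>& names,
                                  const KmerIndex& idx,
                                  int ma, int mi, int go, int ge,
                                  std::vector<Cand>& cands,
                                  AlignBuffers& buf, Hit& best) {
  const int L = (int)oriented.size();
  collect_cands(oriented, idx, cands);
  for (const Cand& c : cands) {
    const std::string& ref = refs[c.ref];
    const int rl = (int)ref.size();
    // ungapped perfect-match fast path
    if (c.diag >= 0 && c.diag + L <= rl) {
      bool perfect = true;
      for (int i = 0; i < L; ++i) {
        if (ref[c.diag + i] != oriented[i]) { perfect = false; break; }
      }
      if (perfect) {
        Hit h; h.mapped = true; h.ref = c.ref; h.start = c.diag;
        h.end = c.diag + L; h.strand = strand; h.aligned = L;
        h.score = L * ma;
        if (better(h, best, names)) best = h;
        continue;
      }
    }
    int w0 = std::max(0, c.diag - L);
    int w1 = std::min(rl, c.diag + 2 * L + idx.k);
    if (w1 <= w0) continue;
    int ws, we, aligned;
    int score = smith_waterman(oriented, ref.data() + w0, w1 - w0,
                               ma, mi, go, ge, buf, ws, we, aligned);
    if (score <= 0) continue;
    Hit h; h.mapped = true; h.ref = c.ref; h.start = w0 + ws;
    h.end = w0 + we; h.strand = strand; h.aligned = aligned; h.score = score;
    if (better(h, best, names)) best = h;
  }
}

// [[Rcpp::export]]
DataFrame cpp_align_batch(CharacterVector reads,
                          CharacterVector ref_seqs,
                          CharacterVector ref_names,
                          int seed_k, int match, int mismatch,
                          int gap_open, int gap_extend, int min_score) {
  if (ref_seqs.size() == 0) stop("empty reference set");
  if (seed_k < 8 || seed_k > 32) stop("seed_k must be in [8, 32]");
  std::vector<std::string> refs(ref_seqs.size());
  std::vector<std::string> names(ref_seqs.size());
  for (int i = 0; i < ref_seqs.size(); ++i) {
    refs[i] = as<std::string>(ref_seqs[i]);
    names[i] = as<std::string>(ref_names[i]);
  }
  KmerIndex idx = build_index(refs, seed_k);

  const int n = reads.size();
  LogicalVector mapped(n);
  CharacterVector ref_id(n);
  IntegerVector start(n), end(n), aligned(n), score(n);
  CharacterVector strand(n);

  std::vector<Cand> cands;
  AlignBuffers buf;
  for (int r = 0; r < n; ++r) {
    std::string read = as<std::string>(reads[r]);
    Hit best;
    if ((int)read.size() >= seed_k) {
      align_one_orientation(read, '+', refs, names, idx, match, mismatch,
                            gap_open, gap_extend, cands, buf, best);
      std::string rc = revcomp(read);
      align_one_orientation(rc, '-', refs, names, idx, match, mismatch,
                            gap_open, gap_extend, cands, buf, best);
    }
    if (best.mapped && best.score >= min_score) {
      mapped[r] = true;
      ref_id[r] = names[best.ref];
      start[r] = best.start; end[r] = best.end;
      strand[r] = std::string(1, best.strand);
      aligned[r] = best.aligned; score[r] = best.score;
    } else {
      mapped[r] = false;
      ref_id[r] = NA_STRING;
      start[r] = NA_INTEGER; end[r] = NA_INTEGER;
      strand[r] = NA_STRING;
      aligned[r] = NA_INTEGER; score[r] = NA_INTEGER;
    }
  }
  return DataFrame::create(
      _["mapped"] = mapped, _["ref_id"] = ref_id, _["start"] = start,
      _["end"] = end, _["strand"] = strand,
      _["aligned_read_bases"] = aligned, _["score"] = score,
      _["stringsAsFactors"] = false);
}
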