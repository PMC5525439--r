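#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Seed-and-extend local aligner used by local_align().
//
// Strategy: exact k-mer seeding against a per-subject k-mer index, seeds
// grouped by diagonal (clusters capped at 3*band of diagonal drift), then a
// full local dynamic-programming pass with traceback restricted to a subject
// window around each seeded diagonal cluster (window margin = band).  Linear
// gap costs: every gap column costs `gap`.  Scores are kept as 2x-scaled
// integers so the conventional half-point gap penalty stays exact.

namespace {

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;  // ambiguous: never seeds, always mismatches
  }
}

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'a': return 't';
    case 'C': return 'G'; case 'c': return 'g';
    case 'G': return 'C'; case 'g': return 'c';
    case 'T': return 'A'; case 't': return 'a';
    default: return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

struct RawHit {
  double score;       // raw score (match/mismatch/gap units)
  int matches, mismatches, gapopen, aln_len;
  int qstart, qend;   // 0-based inclusive on the aligned (possibly rc) read
  int sstart, send;   // 0-based inclusive on subject
};

struct SubjectIndex {
  std::unordered_map<uint32_t, std::vector<int>> kmers;
};

void index_subject(const std::string& s, int k, SubjectIndex& idx) {
  const int n = (int)s.size();
  if (n < k) return;
  uint32_t key = 0, mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xffffffffu;
  int run = 0;  // consecutive unambiguous bases
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint32_t)c) & mask;
    if (++run >= k) idx.kmers[key].push_back(i - k + 1);
  }
}

// Local alignment with traceback of `read` against subject window
// [wlo, whi) of `subj`.  Returns true when a positive-score hit was found.
bool window_sw(const std::string& read, const std::string& subj,
               int wlo, int whi, int im, int ix, int ig, RawHit& out) {
  const int m = (int)read.size();
  const int w = whi - wlo;
  if (w <= 0 || m == 0) return false;
  // H[(i)*(w+1)+j], i over read 0..m, j over window 0..w
  std::vector<int> H((size_t)(m + 1) * (w + 1), 0);
  std::vector<uint8_t> tb((size_t)(m + 1) * (w + 1), 0);  // 0 stop,1 diag,2 up(q gap? ),3 left
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int rc = base_code(read[i - 1]);
    int* Hp = &H[(size_t)(i - 1) * (w + 1)];
    int* Hc = &H[(size_t)i * (w + 1)];
    uint8_t* T = &tb[(size_t)i * (w + 1)];
    for (int j = 1; j <= w; ++j) {
      const int sc = base_code(subj[wlo + j - 1]);
      const int sub = (rc <= 3 && rc == sc) ? im : ix;
      int v = Hp[j - 1] + sub; uint8_t d = 1;
      const int up = Hp[j] + ig;    // gap in subject (consumes read)
      if (up > v) { v = up; d = 2; }
      const int lf = Hc[j - 1] + ig;  // gap in read (consumes subject)
      if (lf > v) { v = lf; d = 3; }
      if (v <= 0) { v = 0; d = 0; }
      Hc[j] = v; T[j] = d;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (best <= 0) return false;
  // traceback
  int i = bi, j = bj;
  int matches = 0, mismatches = 0, gapopen = 0, cols = 0;
  uint8_t prev = 1;
  while (i > 0 && j > 0) {
    uint8_t d = tb[(size_t)i * (w + 1) + j];
    if (d == 0) break;
    ++cols;
    if (d == 1) {
      int rc = base_code(read[i - 1]), sc = base_code(subj[wlo + j - 1]);
      if (rc <= 3 && rc == sc) ++matches; else ++mismatches;
      --i; --j;
    } else if (d == 2) {
      if (prev != 2) ++gapopen;
      --i;
    } else {
      if (prev != 3) ++gapopen;
      --j;
    }
    prev = d;
  }
  out.score = best / 2.0;
  out.matches = matches; out.mismatches = mismatches;
  out.gapopen = gapopen; out.aln_len = cols;
  out.qstart = i; out.qend = bi - 1;
  out.sstart = wlo + j; out.send = wlo + bj - 1;
  return true;
}

// All seeded-window alignments of one read orientation vs one subject.
void align_one(const std::string& read, const std::string& subj,
               const SubjectIndex& idx, int k, int band,
               int im, int ix, int ig, std::vector<RawHit>& hits) {
  const int m = (int)read.size();
  const int n = (int)subj.size();
  if (m < k || n < k) return;
  std::vector<int> diags;
  uint32_t key = 0, mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xffffffffu;
  int run = 0;
  for (int q = 0; q < m; ++q) {
    int c = base_code(read[q]);
    if (c > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint32_t)c) & mask;
    if (++run < k) continue;
    auto it = idx.kmers.find(key);
    if (it == idx.kmers.end()) continue;
    const int qpos = q - k + 1;
    for (int spos : it->second) diags.push_back(spos - qpos);
  }
  if (diags.empty()) return;
  std::sort(diags.begin(), diags.end());
  diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
  size_t c0 = 0;
  std::vector<RawHit> found;
  for (size_t i = 1; i <= diags.size(); ++i) {
    bool close = i < diags.size() &&
      diags[i] - diags[i - 1] <= band &&
      diags[i] - diags[c0] <= 3 * band;
    if (close) continue;
    int dmin = diags[c0], dmax = diags[i - 1];
    int wlo = std::max(0, dmin - band);
    int whi = std::min(n, dmax + m + band);
    RawHit h;
    if (window_sw(read, subj, wlo, whi, im, ix, ig, h)) found.push_back(h);
    c0 = i;
  }
  // Greedy non-redundant selection: keep best-scoring hits whose subject
  // intervals do not substantially overlap an already-kept hit.
  std::sort(found.begin(), found.end(),
            [](const RawHit& a, const RawHit& b) { return a.score > b.score; });
  for (const auto& h : found) {
    bool dup = false;
    for (const auto& kpt : hits) {
      int ov = std::min(h.send, kpt.send) - std::max(h.sstart, kpt.sstart) + 1;
      int len = h.send - h.sstart + 1;
      if (ov > 0 && ov * 2 > len) { dup = true; break; }
    }
    if (!dup) hits.push_back(h);
  }
}

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_local_align(CharacterVector reads, CharacterVector read_names,
                          CharacterVector subjects, CharacterVector subject_names,
                          double match, double mismatch, double gap,
                          int seed_len, int band, bool best_per_pair) {
  const int im = (int)std::lround(match * 2);
  const int ix = (int)std::lround(mismatch * 2);
  const int ig = (int)std::lround(gap * 2);
  const int ns = subjects.size(), nr = reads.size();

  std::vector<std::string> subj(ns);
  std::vector<SubjectIndex> idx(ns);
  for (int s = 0; s < ns; ++s) {
    subj[s] = as<std::string>(subjects[s]);
    index_subject(subj[s], seed_len, idx[s]);
  }

  std::vector<std::string> o_q, o_s;
  std::vector<double> o_pid, o_score;
  std::vector<int> o_len, o_mm, o_go, o_qs, o_qe, o_ss, o_se, o_qlen;

  for (int r = 0; r < nr; ++r) {
    const std::string rd = as<std::string>(reads[r]);
    const std::string rc = revcomp(rd);
    const int m = (int)rd.size();
    const std::string qname = as<std::string>(read_names[r]);
    for (int s = 0; s < ns; ++s) {
      std::vector<RawHit> fwd, rev;
      align_one(rd, subj[s], idx[s], seed_len, band, im, ix, ig, fwd);
      align_one(rc, subj[s], idx[s], seed_len, band, im, ix, ig, rev);
      // collect (strand-tagged) hits
      struct Tag { RawHit h; bool minus; };
      std::vector<Tag> all;
      for (auto& h : fwd) all.push_back({h, false});
      for (auto& h : rev) all.push_back({h, true});
      if (all.empty()) continue;
      std::sort(all.begin(), all.end(),
                [](const Tag& a, const Tag& b) { return a.h.score > b.h.score; });
      const size_t keep = best_per_pair ? 1 : all.size();
      for (size_t t = 0; t < keep && t < all.size(); ++t) {
        const RawHit& h = all[t].h;
        int qs, qe, ss, se;
        if (!all[t].minus) {
          qs = h.qstart + 1; qe = h.qend + 1;
          ss = h.sstart + 1; se = h.send + 1;
        } else {
          // coordinates were on the reverse complement; flip to the
          // original read (qstart < qend) and report subject descending
          qs = m - h.qend; qe = m - h.qstart;
          ss = h.send + 1; se = h.sstart + 1;
        }
        o_q.push_back(qname);
        o_s.push_back(as<std::string>(subject_names[s]));
        o_pid.push_back(100.0 * h.matches / (double)h.aln_len);
        o_len.push_back(h.aln_len);
        o_mm.push_back(h.mismatches);
        o_go.push_back(h.gapopen);
        o_qs.push_back(qs); o_qe.push_back(qe);
        o_ss.push_back(ss); o_se.push_back(se);
        o_score.push_back(h.score);
        o_qlen.push_back(m);
      }
    }
  }

  return DataFrame::create(
      _["qseqid"] = o_q, _["sseqid"] = o_s, _["pident"] = o_pid,
      _["length"] = o_len, _["mismatch"] = o_mm, _["gapopen"] = o_go,
      _["qstart"] = o_qs, _["qend"] = o_qe, _["sstart"] = o_ss,
      _["send"] = o_se, _["score"] = o_score, _["qlen"] = o_qlen,
      _["stringsAsFactors"] = false);
}
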