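#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <set>
#include <cstring>
#include <cmath>
using namespace Rcpp;

// Local alignment and ungapped scan kernels. Affine gap cost for a run of
// length g is gap_open + g * gap_extend (blastn convention).

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp_one(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t j = 0; j < r.size(); ++j) r[j] = comp_base(r[j]);
  return r;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) out[i] = revcomp_one(as<std::string>(x[i]));
  return out;
}

struct Aln {
  int score = 0;
  int q_start = 0, q_end = 0, s_start = 0, s_end = 0;
  int matches = 0, mismatches = 0, gap_opens = 0, aln_len = 0;
  std::string aq, as;
};

// Smith-Waterman with affine gaps and a full traceback.
// Pointer codes in H: 0 stop, 1 diag, 2 up (gap in subject row, consumes
// query), 3 left (gap in query row, consumes subject). Tie preference
// diag > up > left for deterministic output.
static bool sw_core(const std::string &q, const std::string &s,
                    int match, int mismatch, int gap_open, int gap_extend,
                    Aln &out) {
  const int m = q.size(), n = s.size();
  if (m == 0 || n == 0) return false;
  const int NEG = -1000000000;
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
  std::vector<int> Eprev(n + 1, NEG), Ecur(n + 1, NEG); // gap in query (left)
  std::vector<int> Fprev(n + 1, NEG), Fcur(n + 1, NEG); // gap in subject (up)
  std::vector<unsigned char> ptrH((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> ptrE((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> ptrF((size_t)(m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0; Ecur[0] = NEG; Fcur[0] = NEG;
    const char qi = q[i - 1];
    const size_t row = (size_t)i * (n + 1);
    for (int j = 1; j <= n; ++j) {
      int f_open = Hprev[j] - gap_open - gap_extend;
      int f_ext  = Fprev[j] - gap_extend;
      if (f_open >= f_ext) { Fcur[j] = f_open; ptrF[row + j] = 1; }
      else                 { Fcur[j] = f_ext;  ptrF[row + j] = 0; }
      int e_open = Hcur[j - 1] - gap_open - gap_extend;
      int e_ext  = Ecur[j - 1] - gap_extend;
      if (e_open >= e_ext) { Ecur[j] = e_open; ptrE[row + j] = 1; }
      else                 { Ecur[j] = e_ext;  ptrE[row + j] = 0; }
      const char sj = s[j - 1];
      int sub = (qi == sj && qi != 'N') ? match : -mismatch;
      int diag = Hprev[j - 1] + sub;
      int h = 0; unsigned char p = 0;
      if (diag > h) { h = diag; p = 1; }
      if (Fcur[j] > h) { h = Fcur[j]; p = 2; }
      if (Ecur[j] > h) { h = Ecur[j]; p = 3; }
      Hcur[j] = h; ptrH[row + j] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
    std::swap(Fprev, Fcur);
  }
  if (best < match) return false; // no alignment worth reporting
  std::string aq, as;
  int i = bi, j = bj;
  int state = 0; // 0 = in H, 1 = in F (up), 2 = in E (left)
  int matches = 0, mism = 0, gapopens = 0;
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0) {
      unsigned char p = ptrH[idx];
      if (p == 0) break;
      if (p == 1) {
        aq.push_back(q[i - 1]); as.push_back(s[j - 1]);
        if (q[i - 1] == s[j - 1] && q[i - 1] != 'N') ++matches; else ++mism;
        --i; --j;
      } else if (p == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // F: query char vs gap
      aq.push_back(q[i - 1]); as.push_back('-');
      unsigned char p = ptrF[idx];
      --i;
      if (p == 1) { state = 0; ++gapopens; }
    } else { // E: gap vs subject char
      aq.push_back('-'); as.push_back(s[j - 1]);
      unsigned char p = ptrE[idx];
      --j;
      if (p == 1) { state = 0; ++gapopens; }
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(as.begin(), as.end());
  out.score = best;
  out.q_start = i + 1; out.q_end = bi;
  out.s_start = j + 1; out.s_end = bj;
  out.matches = matches; out.mismatches = mism; out.gap_opens = gapopens;
  out.aln_len = (int)aq.size();
  out.aq = aq; out.as = as;
  return true;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
SEXP sw_align_cpp(std::string q, std::string s,
                  int match, int mismatch, int gap_open, int gap_extend) {
  Aln a;
  if (!sw_core(q, s, match, mismatch, gap_open, gap_extend, a))
    return R_NilValue;
  return List::create(
    _["score"] = a.score,
    _["q_start"] = a.q_start, _["q_end"] = a.q_end,
    _["s_start"] = a.s_start, _["s_end"] = a.s_end,
    _["aligned_query"] = a.aq, _["aligned_subject"] = a.as,
    _["matches"] = a.matches, _["mismatches"] = a.mismatches,
    _["gap_opens"] = a.gap_opens, _["aln_length"] = a.aln_len);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// Seed-and-extend alignment of reads against an exact k-mer index of the
// genomes. For every shared k-mer seed, a Smith-Waterman extension is run on
// a genome window wide enough to hold any local alignment of the read that
// passes through the seed; the best-scoring extension per read x genome and
// strand wins. Reverse-strand hits are reported in m8 convention (query
// coordinates on the read as sequenced, s_start > s_end).
// [[Rcpp::export(name = ".seed_extend_cpp")]]
List seed_extend_cpp(CharacterVector read_ids, CharacterVector read_seqs,
                     CharacterVector genome_ids, CharacterVector genome_seqs,
                     int k, int seed_step, int match, int mismatch,
                     int gap_open, int gap_extend, double lambda, double K,
                     double db_size, int min_score, double max_evalue) {
  const int ng = genome_seqs.size();
  std::vector<std::string> gseq(ng);
  for (int g = 0; g < ng; ++g) gseq[g] = as<std::string>(genome_seqs[g]);
  // k-mer index: 2-bit encoded k-mer -> packed (genome, position)
  std::unordered_map<uint64_t, std::vector<uint64_t> > index;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int g = 0; g < ng; ++g) {
    const std::string &s = gseq[g];
    uint64_t enc = 0; int run = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int c = base_code(s[p]);
      if (c < 0) { run = 0; enc = 0; continue; }
      enc = ((enc << 2) | (uint64_t)c) & mask;
      if (++run >= k)
        index[enc].push_back(((uint64_t)g << 40) | (uint64_t)(p - k + 1));
    }
  }
  struct Best { int score = -1; Aln a; bool rev = false; };
  std::vector<std::string> o_qid, o_sid;
  std::vector<double> o_pid, o_ev, o_bs, o_raw;
  std::vector<int> o_alen, o_mm, o_go, o_qs, o_qe, o_ss, o_se, o_qlen;
  const int nr = read_seqs.size();
  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(read_seqs[r]);
    const int L = fwd.size();
    std::string rev = revcomp_one(fwd);
    std::map<int, Best> best;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string &rs = (strand == 0) ? fwd : rev;
      // windows already extended for this (read, strand), keyed by
      // genome * big + coarse window start
      std::set<std::pair<int, int> > seen;
      for (int off = 0; off <= L - k; off += seed_step) {
        uint64_t enc = 0; bool ok = true;
        for (int j = 0; j < k; ++j) {
          int c = base_code(rs[off + j]);
          if (c < 0) { ok = false; break; }
          enc = (enc << 2) | (uint64_t)c;
        }
        if (!ok) continue;
        auto it = index.find(enc & mask);
        if (it == index.end()) continue;
        for (uint64_t packed : it->second) {
          int g = (int)(packed >> 40);
          int pos = (int)(packed & ((1ULL << 40) - 1)); // 0-based
          int glen = gseq[g].size();
          int w_start = pos - off - L - 10; if (w_start < 0) w_start = 0;
          int w_end = pos + k + (L - off - k) + L + 10;
          if (w_end > glen) w_end = glen;
          std::pair<int, int> key(g, w_start / 25);
          if (seen.count(key)) continue;
          seen.insert(key);
          Aln a;
          if (!sw_core(rs, gseq[g].substr(w_start, w_end - w_start),
                       match, mismatch, gap_open, gap_extend, a)) continue;
          a.s_start += w_start; a.s_end += w_start;
          Best &b = best[g];
          if (a.score > b.score) { b.score = a.score; b.a = a;
                                   b.rev = (strand == 1); }
        }
      }
    }
    for (auto &kv : best) {
      const Best &b = kv.second;
      if (b.score < min_score) continue;
      double ev = K * (double)L * db_size * std::exp(-lambda * b.score);
      if (ev > max_evalue) continue;
      int qs, qe, ss, se;
      if (b.rev) {
        qs = L - b.a.q_end + 1; qe = L - b.a.q_start + 1;
        ss = b.a.s_end; se = b.a.s_start;
      } else {
        qs = b.a.q_start; qe = b.a.q_end;
        ss = b.a.s_start; se = b.a.s_end;
      }
      o_qid.push_back(as<std::string>(read_ids[r]));
      o_sid.push_back(as<std::string>(genome_ids[kv.first]));
      o_pid.push_back(100.0 * b.a.matches / b.a.aln_len);
      o_alen.push_back(b.a.aln_len);
      o_mm.push_back(b.a.mismatches);
      o_go.push_back(b.a.gap_opens);
      o_qs.push_back(qs); o_qe.push_back(qe);
      o_ss.push_back(ss); o_se.push_back(se);
      o_ev.push_back(ev);
      o_bs.push_back((lambda * b.score - std::log(K)) / std::log(2.0));
      o_qlen.push_back(L);
      o_raw.push_back(b.score);
    }
  }
  return List::create(
    _["query_id"] = wrap(o_qid), _["subject_id"] = wrap(o_sid),
    _["percent_identity"] = wrap(o_pid), _["aln_length"] = wrap(o_alen),
    _["mismatches"] = wrap(o_mm), _["gap_opens"] = wrap(o_go),
    _["q_start"] = wrap(o_qs), _["q_end"] = wrap(o_qe),
    _["s_start"] = wrap(o_ss), _["s_end"] = wrap(o_se),
    _["evalue"] = wrap(o_ev), _["bit_score"] = wrap(o_bs),
    _["query_length"] = wrap(o_qlen), _["raw_score"] = wrap(o_raw));
}

// Minimum ungapped mismatch count of `read` against `ref` over all offsets
// and both strands, with early exit once a window with <= max_mm is found.
// Returns max_mm + 1 when no window qualifies.
// [[Rcpp::export(name = ".min_mismatch_cpp")]]
int min_mismatch_cpp(std::string read, std::string ref, int max_mm) {
  const int lr = read.size(), ln = ref.size();
  if (lr > ln) return max_mm + 1;
  std::string rc = revcomp_one(read);
  int bestv = max_mm + 1;
  const char *refp = ref.c_str();
  for (int strand = 0; strand < 2; ++strand) {
    const char *rp = (strand == 0) ? read.c_str() : rc.c_str();
    for (int off = 0; off + lr <= ln; ++off) {
      int mm = 0;
      const char *w = refp + off;
      for (int j = 0; j < lr; ++j) {
        if (rp[j] != w[j]) { if (++mm >= bestv) break; }
      }
      if (mm < bestv) {
        bestv = mm;
        if (bestv == 0) return 0;
      }
    }
  }
  return bestv;
}

// Vectorised over reads: does each read match `ref` with <= max_mm ungapped
// mismatches on either strand?
// [[Rcpp::export(name = ".matches_within_cpp")]]
LogicalVector matches_within_cpp(CharacterVector reads, std::string ref,
                                 int max_mm) {
  int n = reads.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = min_mismatch_cpp(as<std::string>(reads[i]), ref, max_mm)
      <= max_mm;
  return out;
}

// Best ungapped placement of `read` on `ref`: minimizes mismatches; ties go
// to the forward strand, then the smallest offset. Offset is 0-based.
// [[Rcpp::export(name = ".best_placement_cpp")]]
List best_placement_cpp(std::string read, std::string ref) {
  const int lr = read.size(), ln = ref.size();
  if (lr > ln)
    return List::create(_["offset"] = -1, _["strand"] = NA_STRING,
                        _["mismatches"] = NA_INTEGER);
  std::string rc = revcomp_one(read);
  int bestv = lr + 1, bestoff = -1, beststrand = 0;
  const char *refp = ref.c_str();
  for (int strand = 0; strand < 2; ++strand) {
    const char *rp = (strand == 0) ? read.c_str() : rc.c_str();
    for (int off = 0; off + lr <= ln; ++off) {
      int mm = 0;
      const char *w = refp + off;
      for (int j = 0; j < lr; ++j) {
        if (rp[j] != w[j]) { if (++mm >= bestv) break; }
      }
      if (mm < bestv) { bestv = mm; bestoff = off; beststrand = strand; }
      if (bestv == 0 && strand == 0) break;
    }
    if (bestv == 0 && beststrand == 0) break;
  }
  return List::create(_["offset"] = bestoff,
                      _["strand"] = beststrand == 0 ? "forward" : "reverse",
                      _["mismatches"] = bestv);
}
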