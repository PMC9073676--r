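// Seed-and-extend read aligner used for desk-scale combined-reference mapping.
// Exact k-mer seeds over the forward strand of every contig; candidate loci are
// scored with a 3-state affine-gap DP (Gotoh), either glocal ("end-to-end":
// the whole read must align, free reference ends) or local (Smith-Waterman,
// unaligned read ends become soft clips).  Gap of length g costs open + g*ext.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

const int NEG_INF = -1000000000;

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 'T'; case 'c': return 'G';
    case 'g': return 'C'; case 't': return 'A';
    default: return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) c = comp_base(c);
  return r;
}

struct SeedIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;       // uppercase
  std::vector<long long> offsets;      // global start of each contig
  long long total;
  std::unordered_map<uint64_t, std::vector<uint32_t>> kmers;

  int contig_of(long long gpos) const {
    // binary search over offsets
    int lo = 0, hi = (int)offsets.size() - 1;
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if (offsets[mid] <= gpos) lo = mid; else hi = mid - 1;
    }
    return lo;
  }
};

struct Scoring {
  int match, mismatch, gap_open, gap_ext, min_score, uniq_margin;
};

struct AlnResult {
  bool mapped = false;
  int contig = -1;
  long long pos = 0;         // 0-based within contig
  bool fwd = true;
  int score = NEG_INF;
  std::string cigar;
};

// DP working buffers, reused across reads
struct DPBuf {
  std::vector<int> M, X, Y;
  std::vector<uint8_t> tM, tX, tY;
  void resize(size_t n) {
    if (M.size() < n) {
      M.resize(n); X.resize(n); Y.resize(n);
      tM.resize(n); tX.resize(n); tY.resize(n);
    }
  }
};

void append_op(std::string& cig, char op, int len) {
  cig += std::to_string(len);
  cig += op;
}

// Align read (query) against window (reference slice).
// glocal: full read must be consumed; reference ends free.
// local:  Smith-Waterman; unaligned read ends reported as soft clips.
// Returns score; fills ref_start (0-based in window) and cigar.
int dp_align(const std::string& q, const char* w, int wlen,
             const Scoring& sc, bool local, DPBuf& buf,
             int& ref_start, std::string& cigar) {
  const int m = (int)q.size();
  const int W = wlen + 1;
  buf.resize((size_t)(m + 1) * W);
  int* M = buf.M.data(); int* X = buf.X.data(); int* Y = buf.Y.data();
  uint8_t* tM = buf.tM.data(); uint8_t* tX = buf.tX.data(); uint8_t* tY = buf.tY.data();
  const int OPEN = -(sc.gap_open < 0 ? -sc.gap_open : sc.gap_open); // negative
  const int EXT = -(sc.gap_ext < 0 ? -sc.gap_ext : sc.gap_ext);
  const int first_gap = OPEN + EXT; // cost of a length-1 gap

  // row 0
  for (int j = 0; j <= wlen; ++j) {
    M[j] = 0;                 // alignment may start at any reference position
    X[j] = NEG_INF; Y[j] = NEG_INF;
    tM[j] = 0;
  }
  int best = local ? 0 : NEG_INF;
  int best_i = 0, best_j = 0; uint8_t best_state = 0; // 0=M,1=X,2=Y

  for (int i = 1; i <= m; ++i) {
    int* Mi = M + (size_t)i * W; int* Mp = M + (size_t)(i - 1) * W;
    int* Xi = X + (size_t)i * W; int* Xp = X + (size_t)(i - 1) * W;
    int* Yi = Y + (size_t)i * W; int* Yp = Y + (size_t)(i - 1) * W;
    uint8_t* tMi = tM + (size_t)i * W;
    uint8_t* tXi = tX + (size_t)i * W;
    uint8_t* tYi = tY + (size_t)i * W;
    // column 0: read prefix unaligned -> only via insertion state in glocal
    Mi[0] = NEG_INF; Xi[0] = NEG_INF;
    Yi[0] = local ? NEG_INF : (first_gap + EXT * (i - 1));
    tYi[0] = (i == 1) ? 0 : 2;
    const int qc = base_code(q[(size_t)i - 1]);
    for (int j = 1; j <= wlen; ++j) {
      const int rc = base_code(w[j - 1]);
      const int s = (qc >= 0 && qc == rc) ? sc.match : sc.mismatch;
      // M
      int dM = Mp[j - 1], dX = Xp[j - 1], dY = Yp[j - 1];
      int mv = dM; uint8_t mt = 0;
      if (dX > mv) { mv = dX; mt = 1; }
      if (dY > mv) { mv = dY; mt = 2; }
      mv = (mv == NEG_INF) ? NEG_INF : mv + s;
      if (local && mv < 0) { mv = 0; mt = 3; } // 3 = local start
      Mi[j] = mv; tMi[j] = mt;
      // X: gap in read (deletion, consumes reference)
      int xo = Mi[j - 1] == NEG_INF ? NEG_INF : Mi[j - 1] + first_gap;
      int xo2 = Yi[j - 1] == NEG_INF ? NEG_INF : Yi[j - 1] + first_gap;
      if (xo2 > xo) xo = xo2;
      int xe = Xi[j - 1] == NEG_INF ? NEG_INF : Xi[j - 1] + EXT;
      if (xo >= xe) { Xi[j] = xo; tXi[j] = 0; } else { Xi[j] = xe; tXi[j] = 1; }
      // Y: insertion (consumes read)
      int yo = Mp[j] == NEG_INF ? NEG_INF : Mp[j] + first_gap;
      int yo2 = Xp[j] == NEG_INF ? NEG_INF : Xp[j] + first_gap;
      if (yo2 > yo) yo = yo2;
      int ye = Yp[j] == NEG_INF ? NEG_INF : Yp[j] + EXT;
      if (yo >= ye) { Yi[j] = yo; tYi[j] = 0; } else { Yi[j] = ye; tYi[j] = 2; }
      if (local && Mi[j] > best) {
        best = Mi[j]; best_i = i; best_j = j; best_state = 0;
      }
    }
  }
  if (!local) {
    int* Mm = M + (size_t)m * W; int* Ym = Y + (size_t)m * W;
    for (int j = 0; j <= wlen; ++j) {
      if (Mm[j] > best) { best = Mm[j]; best_j = j; best_state = 0; }
      if (Ym[j] > best) { best = Ym[j]; best_j = j; best_state = 2; }
    }
    best_i = m;
  }
  if (best <= (local ? 0 : NEG_INF)) { cigar.clear(); ref_start = 0; return best; }

  // traceback
  std::vector<std::pair<char, int>> ops; // reversed
  auto push = [&ops](char op) {
    if (!ops.empty() && ops.back().first == op) ops.back().second++;
    else ops.emplace_back(op, 1);
  };
  int i = best_i, j = best_j; uint8_t st = best_state;
  while (i > 0) {
    if (st == 0) {
      if (local && M[(size_t)i * W + j] == 0) break; // SW start reached
      uint8_t t = tM[(size_t)i * W + j];
      push('M'); st = t; --i; --j;
      if (local && st == 3) break; // predecessor was a floored (start) cell
      if (i == 0) break;
      if (!local && j == 0 && st == 0) break;
    } else if (st == 1) {
      uint8_t t = tX[(size_t)i * W + j];
      push('D'); st = (t == 1) ? 1 : 0; --j;
      if (st == 0 && t == 0) {
        // came from M or Y at (i, j) ; disambiguate by values
        int mval = M[(size_t)i * W + j], yval = Y[(size_t)i * W + j];
        st = (yval > mval) ? 2 : 0;
      }
    } else {
      uint8_t t = tY[(size_t)i * W + j];
      push('I'); --i;
      if (t == 2) st = 2;
      else {
        int mval = M[(size_t)i * W + j], xval = X[(size_t)i * W + j];
        st = (xval > mval) ? 1 : 0;
      }
      if (i == 0) break;
    }
  }
  ref_start = j;
  // build cigar (ops are reversed)
  cigar.clear();
  int lead_clip = i;                  // read bases before alignment start
  int tail_clip = m - best_i;         // read bases after alignment end
  if (local && lead_clip > 0) append_op(cigar, 'S', lead_clip);
  for (auto it = ops.rbegin(); it != ops.rend(); ++it)
    append_op(cigar, it->first, it->second);
  if (local && tail_clip > 0) append_op(cigar, 'S', tail_clip);
  return best;
}

struct Candidate {
  long long gstart;  // global window start
  int wlen;
  bool fwd;
  int votes;
};

void collect_candidates(const SeedIndex& idx, const std::string& read, bool fwd,
                        int stride, int pad, int max_cand,
                        std::vector<Candidate>& out) {
  const int k = idx.k;
  const int len = (int)read.size();
  if (len < k) return;
  std::vector<long long> diags;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  // sampled offsets: every `stride`, plus the final k-mer
  std::vector<int> offs;
  for (int o = 0; o + k <= len; o += stride) offs.push_back(o);
  if (offs.empty() || offs.back() != len - k) offs.push_back(len - k);
  for (int o : offs) {
    uint64_t code = 0; bool ok = true;
    for (int t = 0; t < k; ++t) {
      int c = base_code(read[(size_t)o + t]);
      if (c < 0) { ok = false; break; }
      code = ((code << 2) | (uint64_t)c) & mask;
    }
    if (!ok) continue;
    auto it = idx.kmers.find(code);
    if (it == idx.kmers.end()) continue;
    if ((int)it->second.size() > 256) continue; // over-frequent seed
    for (uint32_t p : it->second) diags.push_back((long long)p - o);
  }
  if (diags.empty()) return;
  std::sort(diags.begin(), diags.end());
  // cluster diagonals within 16 bp
  std::vector<Candidate> cands;
  size_t i = 0;
  while (i < diags.size()) {
    size_t j = i + 1;
    while (j < diags.size() && diags[j] - diags[j - 1] <= 16) ++j;
    Candidate c;
    long long d0 = diags[i], d1 = diags[j - 1];
    c.gstart = d0 - pad;
    c.wlen = (int)(d1 - d0) + len + 2 * pad;
    c.fwd = fwd;
    c.votes = (int)(j - i);
    cands.push_back(c);
    i = j;
  }
  std::stable_sort(cands.begin(), cands.end(),
                   [](const Candidate& a, const Candidate& b) { return a.votes > b.votes; });
  if ((int)cands.size() > max_cand) cands.resize(max_cand);
  out.insert(out.end(), cands.begin(), cands.end());
}

bool locus_lt(int c1, long long p1, bool f1, int c2, long long p2, bool f2) {
  if (c1 != c2) return c1 < c2;
  if (p1 != p2) return p1 < p2;
  return f1 && !f2; // '+' sorts before '-'
}

} // namespace

// [[Rcpp::export(name = ".tg_build_index")]]
SEXP tg_build_index(CharacterVector names, CharacterVector seqs, int k) {
  if (k < 11 || k > 31) stop("k must be between 11 and 31");
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  long long off = 0;
  for (R_xlen_t i = 0; i < names.size(); ++i) {
    std::string nm = as<std::string>(names[i]);
    std::string sq = as<std::string>(seqs[i]);
    for (char& c : sq) c = (char)toupper((unsigned char)c);
    if ((int)sq.size() < k) {
      delete idx;
      stop("contig '%s' is shorter than k", nm.c_str());
    }
    idx->names.push_back(nm);
    idx->offsets.push_back(off);
    idx->seqs.push_back(sq);
    off += (long long)sq.size();
  }
  idx->total = off;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t ci = 0; ci < idx->seqs.size(); ++ci) {
    const std::string& s = idx->seqs[ci];
    long long base = idx->offsets[ci];
    uint64_t code = 0; int valid = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int c = base_code(s[p]);
      if (c < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)c) & mask;
      if (++valid >= k) {
        idx->kmers[code].push_back((uint32_t)(base + (long long)p - k + 1));
      }
    }
  }
  XPtr<SeedIndex> xp(idx, true);
  xp.attr("k") = k;
  xp.attr("contigs") = names;
  return xp;
}

// [[Rcpp::export(name = ".tg_index_contigs")]]
CharacterVector tg_index_contigs(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  return wrap(idx->names);
}

// [[Rcpp::export(name = ".tg_align_batch")]]
List tg_align_batch(SEXP xp, CharacterVector reads, std::string mode,
                    int match, int mismatch, int gap_open, int gap_ext,
                    int min_score, int uniq_margin,
                    int stride, int max_candidates, int pad) {
  XPtr<SeedIndex> idx(xp);
  const bool local = (mode == "local");
  if (!local && mode != "e2e") stop("mode must be 'e2e' or 'local'");
  Scoring sc{match, mismatch, gap_open, gap_ext, min_score, uniq_margin};
  const R_xlen_t n = reads.size();
  IntegerVector out_contig(n, NA_INTEGER);
  NumericVector out_pos(n, NA_REAL);
  CharacterVector out_strand(n, NA_STRING);
  CharacterVector out_cigar(n, NA_STRING);
  IntegerVector out_score(n, NA_INTEGER);
  IntegerVector out_second(n, NA_INTEGER);
  LogicalVector out_mapped(n, false);
  DPBuf buf;
  std::vector<Candidate> cands;
  for (R_xlen_t r = 0; r < n; ++r) {
    if (reads[r] == NA_STRING) continue;
    std::string fw = as<std::string>(reads[r]);
    for (char& c : fw) c = (char)toupper((unsigned char)c);
    if ((int)fw.size() < idx->k) continue;
    std::string rc = revcomp(fw);
    cands.clear();
    collect_candidates(*idx, fw, true, stride, pad, max_candidates, cands);
    collect_candidates(*idx, rc, false, stride, pad, max_candidates, cands);
    AlnResult best, second;
    bool have_second = false;
    for (const Candidate& cd : cands) {
      int ci = idx->contig_of(std::max(0LL, std::min(cd.gstart, idx->total - 1)));
      long long coff = idx->offsets[ci];
      long long clen = (long long)idx->seqs[ci].size();
      long long ws = std::max(cd.gstart - coff, 0LL);
      long long we = std::min(ws + cd.wlen, clen);
      if (we - ws < idx->k) continue;
      const std::string& q = cd.fwd ? fw : rc;
      int rstart; std::string cig;
      int scv = dp_align(q, idx->seqs[ci].c_str() + ws, (int)(we - ws), sc,
                         local, buf, rstart, cig);
      if (scv < sc.min_score) continue;
      long long apos = ws + rstart; // 0-based in contig
      AlnResult res;
      res.mapped = true; res.contig = ci; res.pos = apos; res.fwd = cd.fwd;
      res.score = scv; res.cigar = cig;
      auto same_locus = [](const AlnResult& a, const AlnResult& b) {
        return a.contig == b.contig && a.fwd == b.fwd &&
               (a.pos > b.pos ? a.pos - b.pos : b.pos - a.pos) <= 30;
      };
      auto better = [](const AlnResult& a, const AlnResult& b) {
        if (a.score != b.score) return a.score > b.score;
        return locus_lt(a.contig, a.pos, a.fwd, b.contig, b.pos, b.fwd);
      };
      if (!best.mapped) { best = res; continue; }
      if (same_locus(res, best)) {
        if (better(res, best)) best = res;
        continue;
      }
      if (better(res, best)) {
        second = best; have_second = true;
        best = res;
      } else if (!have_second || res.score > second.score) {
        if (!have_second || !same_locus(res, second) || res.score > second.score) {
          second = res; have_second = true;
        }
      }
    }
    if (best.mapped) {
      out_mapped[r] = true;
      out_contig[r] = best.contig + 1;
      out_pos[r] = (double)(best.pos + 1);
      out_strand[r] = best.fwd ? "+" : "-";
      out_cigar[r] = best.cigar;
      out_score[r] = best.score;
      if (have_second) out_second[r] = second.score;
    }
  }
  return List::create(
      _["contig_idx"] = out_contig, _["pos"] = out_pos, _["strand"] = out_strand,
      _["cigar"] = out_cigar, _["score"] = out_score, _["second"] = out_second,
      _["mapped"] = out_mapped);
}
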