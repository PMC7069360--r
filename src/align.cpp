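// Local alignment kernels: full affine-gap Smith-Waterman (Gotoh) with
// traceback, anchored x-drop gapped extension, and the k-mer seeded scan
// of a query against scaffold sequences.
//
// Conventions shared with the R layer:
//  - coordinates are 0-based half-open;
//  - CIGAR-like ops are along the first ("a"/query) sequence:
//      M = column consuming both sequences (match or mismatch)
//      D = column consuming a only  (gap in b / "scaffold-gap")
//      I = column consuming b only  (gap in a / "query-gap")
//  - a gap of length L costs gap_open + L * gap_extend;
//  - any residue outside {A,C,G,T} (e.g. N) scores as a mismatch and is
//    never counted as a match.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <climits>
#include <algorithm>

using namespace Rcpp;

static const int NEG_INF = INT_MIN / 4;

struct Sc {
  int match, mismatch, go, ge;
};

static inline int bc(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static inline int pair_score(char a, char b, const Sc &s) {
  int x = bc(a), y = bc(b);
  if (x < 0 || y < 0) return s.mismatch;
  return x == y ? s.match : s.mismatch;
}

static inline bool is_match(char a, char b) {
  int x = bc(a), y = bc(b);
  return x >= 0 && x == y;
}

static std::string compress_ops(const std::vector<char> &ops) {
  std::string out;
  size_t i = 0;
  while (i < ops.size()) {
    size_t j = i;
    while (j < ops.size() && ops[j] == ops[i]) ++j;
    out += std::to_string(j - i);
    out += ops[i];
    i = j;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Full Smith-Waterman (Gotoh three-state recurrence) with traceback.
// Direction byte per cell: bits 0-1 = H source (0 stop, 1 diag, 2 E, 3 F),
// bit 2 = E extends E, bit 3 = F extends F.
// E = gap in a (consumes b); F = gap in b (consumes a).
// ---------------------------------------------------------------------------

struct AlnRes {
  int score;
  int a0, a1, b0, b1;          // half-open intervals on a and b
  std::string cigar;
  int matches, gaps, cols;
};

static AlnRes sw_full(const std::string &a, const std::string &b, const Sc &sc) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0), Fcol(m + 1, NEG_INF);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int Erow = NEG_INF;
    Hcur[0] = 0;
    uint8_t *trow = &tb[(size_t)i * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      uint8_t d = 0;
      int eopen = Hcur[j - 1] - sc.go - sc.ge;
      int eext = Erow - sc.ge;
      Erow = eopen >= eext ? eopen : eext;   // tie -> open (shorter gaps)
      if (eext > eopen) d |= 4;
      int fopen = Hprev[j] - sc.go - sc.ge;
      int fext = Fcol[j] - sc.ge;
      Fcol[j] = fopen >= fext ? fopen : fext;
      if (fext > fopen) d |= 8;
      int diag = Hprev[j - 1] + pair_score(a[i - 1], b[j - 1], sc);
      int h = 0;                              // local: floor at 0
      uint8_t src = 0;
      if (diag > h) { h = diag; src = 1; }
      if (Erow > h) { h = Erow; src = 2; }
      if (Fcol[j] > h) { h = Fcol[j]; src = 3; }
      Hcur[j] = h;
      trow[j] = d | src;
      if (h > best || (h == best && i + j > bi + bj)) {
        best = h; bi = i; bj = j;
      }
    }
    std::swap(Hprev, Hcur);
  }

  // traceback from (bi, bj), state H
  std::vector<char> ops;
  int matches = 0, gaps = 0;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    uint8_t d = tb[(size_t)i * (m + 1) + j];
    uint8_t src = d & 3;
    if (src == 0) break;
    if (src == 1) {
      ops.push_back('M');
      if (is_match(a[i - 1], b[j - 1])) ++matches;
      --i; --j;
    } else if (src == 2) {
      // gap in a: consume b until the E chain opened
      for (;;) {
        ops.push_back('I');
        ++gaps;
        uint8_t dd = tb[(size_t)i * (m + 1) + j];
        --j;
        if (!(dd & 4)) break;
      }
    } else {
      for (;;) {
        ops.push_back('D');
        ++gaps;
        uint8_t dd = tb[(size_t)i * (m + 1) + j];
        --i;
        if (!(dd & 8)) break;
      }
    }
  }
  std::reverse(ops.begin(), ops.end());

  AlnRes r;
  r.score = best;
  r.a0 = i; r.a1 = bi; r.b0 = j; r.b1 = bj;
  r.cigar = compress_ops(ops);
  r.matches = matches;
  r.gaps = gaps;
  r.cols = (int)ops.size();
  return r;
}

// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, int match, int mismatch,
                  int gap_open, int gap_extend) {
  if ((double)a.size() * (double)b.size() > 1e7)
    stop("smith_waterman size guard exceeded: |a|*|b| must be <= 1e7");
  Sc sc{match, mismatch, gap_open, gap_extend};
  AlnRes r = sw_full(a, b, sc);
  return List::create(
    _["score"] = r.score,
    _["a_start"] = r.a0, _["a_end"] = r.a1,
    _["b_start"] = r.b0, _["b_end"] = r.b1,
    _["cigar"] = r.cigar,
    _["matches"] = r.matches, _["gaps"] = r.gaps, _["aln_len"] = r.cols);
}

// ---------------------------------------------------------------------------
// Anchored x-drop gapped extension.
// Aligns prefixes of a and b starting at (0,0); cells whose best state falls
// more than x_drop below the running best are pruned, the active window per
// row shrinks/advances accordingly, and the extension stops when it empties.
// ---------------------------------------------------------------------------

struct ExtRes {
  int score;
  int ai, bj;                  // consumed lengths on a and b
  std::vector<char> ops;       // forward order over a
  int matches, gaps;
};

static ExtRes xdrop_extend(const std::string &a, const std::string &b,
                           const Sc &sc, int xdrop) {
  const int n = (int)a.size(), m = (int)b.size();
  // per-row traceback: (jlo, direction bytes for jlo..jhi)
  std::vector<int> row_jlo(n + 1, 0);
  std::vector<std::vector<uint8_t>> row_tb(n + 1);

  std::vector<int> Hprev(m + 2, NEG_INF), Hcur(m + 2, NEG_INF);
  std::vector<int> Fprev(m + 2, NEG_INF), Fcur(m + 2, NEG_INF);

  int best = 0, bi = 0, bj = 0;

  // row 0: leading gaps in a (consume b)
  int jlo = 0, jhi = 0;        // inclusive window of alive cells in prev row
  Hprev[0] = 0;
  row_jlo[0] = 0;
  {
    std::vector<uint8_t> t0;
    t0.push_back(0);
    for (int j = 1; j <= m; ++j) {
      int h = -(sc.go + j * sc.ge);
      if (h < best - xdrop) break;
      Hprev[j] = h;
      t0.push_back((uint8_t)(2 | (j > 1 ? 4 : 0)));
      jhi = j;
    }
    row_tb[0] = t0;
  }

  int last_row = 0;
  for (int i = 1; i <= n && jlo <= jhi + 1; ++i) {
    int new_jlo = -1, new_jhi = -2;
    std::vector<uint8_t> trow;
    int start_j = jlo;                  // cells left of prev window are dead
    int Erow = NEG_INF;
    int first_stored = start_j;
    bool stored_any = false;

    for (int j = start_j; j <= m; ++j) {
      // sources from previous row are valid only within [jlo, jhi]
      int hp_diag = (j - 1 >= jlo && j - 1 <= jhi) ? Hprev[j - 1]
                    : (j - 1 == -1 ? NEG_INF : NEG_INF);
      if (i == 1 && j - 1 == 0 && jlo == 0) hp_diag = Hprev[0];
      int hp_up = (j >= jlo && j <= jhi) ? Hprev[j] : NEG_INF;
      int fp_up = (j >= jlo && j <= jhi) ? Fprev[j] : NEG_INF;

      uint8_t d = 0;
      int eopen = (j >= 1) ? Hcur[j - 1] - sc.go - sc.ge : NEG_INF;
      int eext = Erow - sc.ge;
      int E = eopen >= eext ? eopen : eext;
      if (eext > eopen) d |= 4;
      int fopen = hp_up == NEG_INF ? NEG_INF : hp_up - sc.go - sc.ge;
      int fext = fp_up == NEG_INF ? NEG_INF : fp_up - sc.ge;
      int F = fopen >= fext ? fopen : fext;
      if (fext > fopen) d |= 8;
      int diag = (hp_diag == NEG_INF || j == 0) ? NEG_INF
                 : hp_diag + pair_score(a[i - 1], b[j - 1], sc);

      int h = NEG_INF;
      uint8_t src = 0;
      if (diag > h) { h = diag; src = 1; }
      if (E > h) { h = E; src = 2; }
      if (F > h) { h = F; src = 3; }

      int alive_score = h;
      if (E > alive_score) alive_score = E;
      if (F > alive_score) alive_score = F;

      bool alive = alive_score >= best - xdrop && alive_score > NEG_INF / 2;
      if (!alive) { h = NEG_INF; E = NEG_INF; F = NEG_INF; src = 0; }

      if (!stored_any) {
        if (!alive) {
          // haven't found the window start yet
          if (j > jhi + 1) break;     // nothing can revive further right
          continue;
        }
        first_stored = j;
        stored_any = true;
      }

      Hcur[j] = h;
      Fcur[j] = F;
      Erow = E;
      trow.push_back(d | src);

      if (alive) {
        if (new_jlo < 0) new_jlo = j;
        new_jhi = j;
        if (h > best || (h == best && h > NEG_INF / 2 && i + j > bi + bj)) {
          if (h > NEG_INF / 2) { best = h; bi = i; bj = j; }
        }
      }
      // beyond the reach of the previous row only the E chain feeds cells
      if (j > jhi + 1 && !alive) break;
      if (j > jhi && E == NEG_INF && h == NEG_INF) break;
    }

    if (!stored_any || new_jlo < 0) break;   // window emptied: stop
    row_jlo[i] = first_stored;
    row_tb[i] = trow;
    last_row = i;
    jlo = new_jlo;
    jhi = new_jhi;
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
    std::fill(Hcur.begin(), Hcur.end(), NEG_INF);
    std::fill(Fcur.begin(), Fcur.end(), NEG_INF);
  }
  (void)last_row;

  // traceback from (bi, bj)
  auto dir_at = [&](int i, int j) -> uint8_t {
    if (i < 0 || i >= (int)row_tb.size()) return 0;
    const std::vector<uint8_t> &t = row_tb[i];
    int off = j - row_jlo[i];
    if (off < 0 || off >= (int)t.size()) return 0;
    return t[off];
  };

  std::vector<char> ops;
  int matches = 0, gaps = 0;
  int i = bi, j = bj;
  while (i > 0 || j > 0) {
    uint8_t d = dir_at(i, j);
    uint8_t src = d & 3;
    if (src == 0) break;
    if (src == 1) {
      ops.push_back('M');
      if (is_match(a[i - 1], b[j - 1])) ++matches;
      --i; --j;
    } else if (src == 2) {
      for (;;) {
        ops.push_back('I');
        ++gaps;
        uint8_t dd = dir_at(i, j);
        --j;
        if (!(dd & 4)) break;
      }
    } else {
      for (;;) {
        ops.push_back('D');
        ++gaps;
        uint8_t dd = dir_at(i, j);
        --i;
        if (!(dd & 8)) break;
      }
    }
  }
  std::reverse(ops.begin(), ops.end());

  ExtRes r;
  r.score = best;
  r.ai = bi;
  r.bj = bj;
  r.ops = ops;
  r.matches = matches;
  r.gaps = gaps;
  return r;
}

// Extend from anchor point (qp, sp): left part aligns q[0,qp) vs s[?,sp),
// right part aligns q[qp,..) vs s[sp,..). Returns NULL-like score 0 result
// when nothing aligns.
struct SeedHit {
  int qs, qe, ss, se;
  int score, matches, gaps, cols;
  std::string cigar;
};

static bool extend_seed_core(const std::string &q, const std::string &s,
                             int qp, int sp, const Sc &sc, int xdrop,
                             SeedHit &out) {
  const int Lq = (int)q.size();
  const int cap = 2 * Lq + 64 + xdrop;   // alignment cannot usefully reach further

  std::string ar = q.substr(qp);
  std::string br = s.substr(sp, std::min((int)s.size() - sp, cap));
  ExtRes right = xdrop_extend(ar, br, sc, xdrop);

  int lb = std::min(sp, cap);
  std::string al(q.rend() - qp, q.rend());              // reverse of q[0,qp)
  std::string bl(s.rbegin() + ((int)s.size() - sp),
                 s.rbegin() + ((int)s.size() - sp) + lb); // reverse of s[sp-lb,sp)
  ExtRes left = xdrop_extend(al, bl, sc, xdrop);

  int qs = qp - left.ai, qe = qp + right.ai;
  int ss = sp - left.bj, se = sp + right.bj;
  if (qe <= qs || se <= ss) return false;

  std::vector<char> ops(left.ops.rbegin(), left.ops.rend());
  ops.insert(ops.end(), right.ops.begin(), right.ops.end());

  out.qs = qs; out.qe = qe; out.ss = ss; out.se = se;
  out.score = left.score + right.score;
  out.matches = left.matches + right.matches;
  out.gaps = left.gaps + right.gaps;
  out.cols = (int)ops.size();
  out.cigar = compress_ops(ops);
  return true;
}

// [[Rcpp::export]]
List extend_seed_cpp(std::string query, std::string scaffold, int qp, int sp,
                     int match, int mismatch, int gap_open, int gap_extend,
                     int x_drop) {
  if (qp < 0 || qp >= (int)query.size() || sp < 0 || sp >= (int)scaffold.size())
    stop("seed anchor outside sequence bounds");
  Sc sc{match, mismatch, gap_open, gap_extend};
  SeedHit h;
  bool ok = extend_seed_core(query, scaffold, qp, sp, sc, x_drop, h);
  if (!ok) return List::create(_["score"] = 0, _["found"] = false);
  return List::create(
    _["found"] = true,
    _["qs"] = h.qs, _["qe"] = h.qe, _["ss"] = h.ss, _["se"] = h.se,
    _["score"] = h.score, _["matches"] = h.matches, _["gaps"] = h.gaps,
    _["aln_len"] = h.cols, _["cigar"] = h.cigar);
}

// ---------------------------------------------------------------------------
// Seeded search of one query against scaffolds, both strands.
// ---------------------------------------------------------------------------

static void index_kmers(const std::string &s, int k,
                        std::unordered_map<uint64_t, std::vector<int>> &idx) {
  uint64_t code = 0, mask = (k == 32) ? ~0ull : ((1ull << (2 * k)) - 1);
  int valid = 0;
  for (int i = 0; i < (int)s.size(); ++i) {
    int c = bc(s[i]);
    if (c < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)c) & mask;
    if (++valid >= k) idx[code].push_back(i - k + 1);
  }
}

// [[Rcpp::export]]
DataFrame search_cpp(std::string query, CharacterVector scaffold_seqs,
                     int k, int match, int mismatch, int gap_open,
                     int gap_extend, int x_drop, int score_min) {
  Sc sc{match, mismatch, gap_open, gap_extend};
  const int Lq = (int)query.size();

  std::string rcq(query.rbegin(), query.rend());
  for (char &c : rcq) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default: c = 'N';
    }
  }

  std::unordered_map<uint64_t, std::vector<int>> fwd, rev;
  index_kmers(query, k, fwd);
  index_kmers(rcq, k, rev);

  std::vector<int> o_scaf, o_qs, o_qe, o_ss, o_se, o_score, o_matches,
      o_gaps, o_len;
  std::vector<std::string> o_cigar, o_strand;

  const int diag_band = 50;

  for (int sidx = 0; sidx < scaffold_seqs.size(); ++sidx) {
    std::string S = as<std::string>(scaffold_seqs[sidx]);
    struct Box { int qs, qe, ss, se; };
    std::vector<Box> plus_hits, minus_hits;

    auto covered = [&](std::vector<Box> &hits, int qp, int spos) {
      for (const Box &b : hits) {
        if (qp >= b.qs && qp < b.qe && spos >= b.ss && spos < b.se &&
            std::abs((spos - qp) - (b.ss - b.qs)) <= diag_band)
          return true;
      }
      return false;
    };

    uint64_t code = 0, mask = (1ull << (2 * k)) - 1;
    int valid = 0;
    for (int i = 0; i < (int)S.size(); ++i) {
      int c = bc(S[i]);
      if (c < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)c) & mask;
      if (++valid < k) continue;
      int spos = i - k + 1;

      auto itf = fwd.find(code);
      if (itf != fwd.end()) {
        for (int qp : itf->second) {
          if (covered(plus_hits, qp, spos)) continue;
          SeedHit h;
          if (!extend_seed_core(query, S, qp, spos, sc, x_drop, h)) continue;
          if (h.score < score_min) continue;
          plus_hits.push_back({h.qs, h.qe, h.ss, h.se});
          o_scaf.push_back(sidx + 1);
          o_qs.push_back(h.qs); o_qe.push_back(h.qe);
          o_ss.push_back(h.ss); o_se.push_back(h.se);
          o_strand.push_back("+");
          o_score.push_back(h.score);
          o_matches.push_back(h.matches);
          o_gaps.push_back(h.gaps);
          o_len.push_back(h.cols);
          o_cigar.push_back(h.cigar);
        }
      }
      auto itr = rev.find(code);
      if (itr != rev.end()) {
        for (int qp : itr->second) {
          if (covered(minus_hits, qp, spos)) continue;
          SeedHit h;
          if (!extend_seed_core(rcq, S, qp, spos, sc, x_drop, h)) continue;
          if (h.score < score_min) continue;
          minus_hits.push_back({h.qs, h.qe, h.ss, h.se});
          // convert reverse-complement query coordinates to forward strand
          int fqs = Lq - h.qe, fqe = Lq - h.qs;
          // cigar is along rc-query (= scaffold forward); reverse the runs
          // to express it along the forward query
          std::vector<char> ops;
          {
            int num = 0;
            for (char ch : h.cigar) {
              if (ch >= '0' && ch <= '9') num = num * 10 + (ch - '0');
              else { for (int t = 0; t < num; ++t) ops.push_back(ch); num = 0; }
            }
            std::reverse(ops.begin(), ops.end());
          }
          o_scaf.push_back(sidx + 1);
          o_qs.push_back(fqs); o_qe.push_back(fqe);
          o_ss.push_back(h.ss); o_se.push_back(h.se);
          o_strand.push_back("-");
          o_score.push_back(h.score);
          o_matches.push_back(h.matches);
          o_gaps.push_back(h.gaps);
          o_len.push_back(h.cols);
          o_cigar.push_back(compress_ops(ops));
        }
      }
    }
  }

  return DataFrame::create(
    _["scaffold"] = o_scaf,
    _["qs"] = o_qs, _["qe"] = o_qe,
    _["ss"] = o_ss, _["se"] = o_se,
    _["strand"] = o_strand,
    _["score"] = o_score, _["matches"] = o_matches, _["gaps"] = o_gaps,
    _["aln_len"] = o_len, _["cigar"] = o_cigar,
    _["stringsAsFactors"] = false);
}
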