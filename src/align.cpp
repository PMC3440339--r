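// Alignment kernels.
//
// cpp_overlap_align: exact end-free (overlap) alignment with linear gap
// cost, used by redundancy depletion to compute the identity fraction
// (matches / aligned span of the shorter sequence).
//
// cpp_seed_extend: exact-word seed + ungapped X-drop extension against a
// small sequence database, used by both tiers of the cascade homology
// search. Scoring comes from an arbitrary substitution matrix, so the same
// kernel serves peptide (BLOSUM62) and nucleotide (+2/-3) searches.

#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstring>
#include <climits>
using namespace Rcpp;

// ---- end-free overlap alignment -------------------------------------------

// returns (score, matches, span_a, span_b)
// match +1, mismatch -1, gap -2; leading/trailing gaps free on both ends
// [[Rcpp::export]]
IntegerVector cpp_overlap_align(std::string a, std::string b) {
  int n = (int)a.size(), m = (int)b.size();
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
  // direction: 0 none (boundary), 1 diag, 2 up (gap in b), 3 left (gap in a)
  std::vector<unsigned char> dir((size_t)(n + 1) * (m + 1), 0);
  int best = INT_MIN, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      int sdiag = Hprev[j - 1] + (a[i - 1] == b[j - 1] ? 1 : -1);
      int sup = Hprev[j] - 2;
      int sleft = Hcur[j - 1] - 2;
      int v = sdiag; unsigned char d = 1;
      if (sup > v) { v = sup; d = 2; }
      if (sleft > v) { v = sleft; d = 3; }
      Hcur[j] = v;
      dir[(size_t)i * (m + 1) + j] = d;
      // end-free: best over last row and last column
      if ((i == n || j == m) && v > best) { best = v; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  if (n == 0 || m == 0)
    return IntegerVector::create(0, 0, 0, 0);
  // traceback
  int i = bi, j = bj, matches = 0;
  while (i > 0 && j > 0) {
    unsigned char d = dir[(size_t)i * (m + 1) + j];
    if (d == 1) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (d == 2) {
      --i;
    } else if (d == 3) {
      --j;
    } else break;
  }
  return IntegerVector::create(best, matches, bi - i, bj - j);
}

// ---- seed-and-extend ungapped search ---------------------------------------

struct Hsp {
  int score = INT_MIN;
  int qs = 0, qe = 0, ss = 0, se = 0, matches = 0;
};

// [[Rcpp::export]]
DataFrame cpp_seed_extend(CharacterVector queries, CharacterVector subjects,
                          IntegerMatrix score_matrix, CharacterVector alphabet,
                          int seed_len, int xdrop) {
  int R = (int)alphabet.size();
  int cmap[256];
  std::fill(cmap, cmap + 256, -1);
  for (int i = 0; i < R; ++i) {
    std::string ch = as<std::string>(alphabet[i]);
    cmap[(unsigned char)ch[0]] = i;
  }
  const int UNK = -4; // score for any pair involving an unmapped character
  auto pair_score = [&](char x, char y) -> int {
    int ix = cmap[(unsigned char)x], iy = cmap[(unsigned char)y];
    if (ix < 0 || iy < 0) return UNK;
    return score_matrix(ix, iy);
  };

  int ns = (int)subjects.size();
  std::vector<std::string> sub(ns);
  for (int i = 0; i < ns; ++i) sub[i] = as<std::string>(subjects[i]);

  std::unordered_map<std::string, std::vector<std::pair<int,int>>> index;
  for (int s = 0; s < ns; ++s) {
    int L = (int)sub[s].size();
    for (int p = 0; p + seed_len <= L; ++p) {
      std::string w = sub[s].substr(p, seed_len);
      bool ok = true;
      for (char c : w) if (cmap[(unsigned char)c] < 0) { ok = false; break; }
      if (ok) index[w].push_back({s, p});
    }
  }

  std::vector<int> o_query, o_subject, o_score, o_matches, o_alen,
      o_qs, o_qe, o_ss, o_se;

  for (int q = 0; q < (int)queries.size(); ++q) {
    std::string qry = as<std::string>(queries[q]);
    int qlen = (int)qry.size();
    std::vector<Hsp> best(ns);
    // per (subject, diagonal) rightmost query end already covered by an HSP
    std::unordered_map<int64_t, int> diag_cover;
    for (int qpos = 0; qpos + seed_len <= qlen; ++qpos) {
      std::string w = qry.substr(qpos, seed_len);
      auto it = index.find(w);
      if (it == index.end()) continue;
      for (auto& sp : it->second) {
        int s = sp.first, spos = sp.second;
        int64_t key = (int64_t)s * 2000003LL + (qpos - spos) + 1000000LL;
        auto dc = diag_cover.find(key);
        if (dc != diag_cover.end() && qpos < dc->second) continue;
        const std::string& sb = sub[s];
        int slen = (int)sb.size();
        int sc = 0;
        for (int t = 0; t < seed_len; ++t)
          sc += pair_score(qry[qpos + t], sb[spos + t]);
        // right extension
        int cur = 0, bestr = 0, rext = 0;
        for (int t = 0; qpos + seed_len + t < qlen && spos + seed_len + t < slen; ++t) {
          cur += pair_score(qry[qpos + seed_len + t], sb[spos + seed_len + t]);
          if (cur > bestr) { bestr = cur; rext = t + 1; }
          else if (cur < bestr - xdrop) break;
        }
        // left extension
        cur = 0; int bestl = 0, lext = 0;
        for (int t = 1; qpos - t >= 0 && spos - t >= 0; ++t) {
          cur += pair_score(qry[qpos - t], sb[spos - t]);
          if (cur > bestl) { bestl = cur; lext = t; }
          else if (cur < bestl - xdrop) break;
        }
        int total = sc + bestr + bestl;
        int qs = qpos - lext, qe = qpos + seed_len + rext;
        int ss2 = spos - lext, se2 = spos + seed_len + rext;
        diag_cover[key] = qe;
        if (total > best[s].score) {
          int matches = 0;
          for (int t = 0; t < qe - qs; ++t)
            if (qry[qs + t] == sb[ss2 + t]) ++matches;
          best[s] = Hsp{total, qs, qe, ss2, se2, matches};
        }
      }
    }
    for (int s = 0; s < ns; ++s) {
      if (best[s].score <= 0 || best[s].score == INT_MIN) continue;
      o_query.push_back(q + 1);
      o_subject.push_back(s + 1);
      o_score.push_back(best[s].score);
      o_matches.push_back(best[s].matches);
      o_alen.push_back(best[s].qe - best[s].qs);
      o_qs.push_back(best[s].qs + 1);
      o_qe.push_back(best[s].qe);
      o_ss.push_back(best[s].ss + 1);
      o_se.push_back(best[s].se);
    }
  }
  return DataFrame::create(
      _["query"] = o_query, _["subject"] = o_subject, _["score"] = o_score,
      _["matches"] = o_matches, _["align_len"] = o_alen,
      _["q_start"] = o_qs, _["q_end"] = o_qe,
      _["s_start"] = o_ss, _["s_end"] = o_se);
}
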