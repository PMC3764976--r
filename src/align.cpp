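// Seed-and-extend local alignment engine with banded affine-gap dynamic
// programming, plus a global (end-to-end) identity aligner and a windowed
// entropy mask.  Sequences arrive as plain strings together with an
// alphabet; characters outside the alphabet are scored through the last
// row/column of the substitution matrix (the "unknown" class, used for N).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

static const int NEG_INF = -0x0FFFFFFF;

// Map characters to integer codes via an alphabet string; unknown -> K.
static std::vector<int> encode_seq(const std::string& s, const std::string& alphabet) {
  int tab[256];
  std::fill(tab, tab + 256, (int)alphabet.size());
  for (size_t i = 0; i < alphabet.size(); ++i)
    tab[(unsigned char)alphabet[i]] = (int)i;
  std::vector<int> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) out[i] = tab[(unsigned char)s[i]];
  return out;
}

struct AlnHit {
  int qs, qe, ss, se;     // 0-based half-open on the two forward sequences
  int len, matches, gaps; // alignment columns, match columns, gap columns
  int score;
};

// Banded local affine-gap alignment restricted to diagonals d = i - j in
// [dlo, dhi] (i indexes q, j indexes s, both 0-based).  A gap of length L
// costs gap_open + L * gap_ext.  Returns the best local alignment within
// the band; false when no cell scores above zero.  The unknown code
// (last row of submat) never counts as a match.
static bool band_align(const std::vector<int>& q, const std::vector<int>& s,
                       const IntegerMatrix& submat, int gap_open, int gap_ext,
                       int dlo, int dhi, AlnHit& out) {
  const int n = (int)q.size(), m = (int)s.size();
  if (n == 0 || m == 0) return false;
  dlo = std::max(dlo, -(m - 1));
  dhi = std::min(dhi, n - 1);
  if (dlo > dhi) return false;
  const int W = dhi - dlo + 1;
  const int K = submat.nrow(); // codes run 0..K-1, K-1 = unknown

  // Row-wise DP; cell (i, j) lives at band column c = j - (i - dhi), which
  // ranges over [0, W-1].  A diagonal move keeps c, a gap-in-query move
  // (consume s) decrements c, a gap-in-subject move (consume q) increments c.
  std::vector<int> H(W, 0), E(W, NEG_INF), F(W, NEG_INF);
  std::vector<int> Hp(W, 0), Ep(W, NEG_INF), Fp(W, NEG_INF);
  // traceback byte: bits 0-1 H-state (0 stop, 1 diag, 2 E, 3 F),
  // bit 2: E opened from H, bit 3: F opened from H
  std::vector<uint8_t> tb((size_t)(n + 1) * W, 0);

  int best = 0, best_i = -1, best_j = -1;

  for (int i = 1; i <= n; ++i) {
    std::swap(H, Hp); std::swap(E, Ep); std::swap(F, Fp);
    std::fill(H.begin(), H.end(), 0);
    std::fill(E.begin(), E.end(), NEG_INF);
    std::fill(F.begin(), F.end(), NEG_INF);
    const int jmin = std::max(1, i - dhi), jmax = std::min(m, i - dlo);
    for (int j = jmin; j <= jmax; ++j) {
      const int c = j - (i - dhi);
      uint8_t t = 0;
      // E: gap in q, from (i, j-1) at band column c-1
      int e = NEG_INF;
      if (c - 1 >= 0 && j - 1 >= 1) {
        const int eo = H[c - 1] - gap_open - gap_ext;
        const int ee = E[c - 1] - gap_ext;
        if (eo >= ee) { e = eo; t |= 4; } else e = ee;
      }
      E[c] = e;
      // F: gap in s, from (i-1, j) at band column c+1 of the previous row
      int f = NEG_INF;
      if (c + 1 <= W - 1 && i - 1 >= 1) {
        const int fo = Hp[c + 1] - gap_open - gap_ext;
        const int fe = Fp[c + 1] - gap_ext;
        if (fo >= fe) { f = fo; t |= 8; } else f = fe;
      }
      F[c] = f;
      // diagonal: (i-1, j-1) at band column c of the previous row; cells
      // outside the band (or the matrix border) act as a fresh local start
      int diag = 0;
      if (i - 1 >= 1 && j - 1 >= 1 && j - 1 >= (i - 1) - dhi && j - 1 <= (i - 1) - dlo)
        diag = Hp[c];
      const int dsc = diag + submat(q[i - 1], s[j - 1]);
      int h = 0, st = 0;
      if (dsc > h) { h = dsc; st = 1; }
      if (e > h)   { h = e;   st = 2; }
      if (f > h)   { h = f;   st = 3; }
      H[c] = h;
      tb[(size_t)i * W + c] = t | (uint8_t)st;
      if (h > best) { best = h; best_i = i; best_j = j; }
    }
  }
  if (best <= 0) return false;

  // traceback from the best cell until a fresh-start cell
  int i = best_i, j = best_j;
  int state = 0; // 0 = H, 2 = E, 3 = F
  int matches = 0, gaps = 0, len = 0;
  const int qe = i, se = j;
  while (i > 0 && j > 0) {
    const int c = j - (i - dhi);
    if (c < 0 || c > W - 1) break; // left the band: fresh start
    const uint8_t t = tb[(size_t)i * W + c];
    if (state == 0) {
      const int st = t & 3;
      if (st == 0) break;
      if (st == 1) {
        ++len;
        if (q[i - 1] == s[j - 1] && q[i - 1] < K - 1) ++matches;
        --i; --j;
      } else if (st == 2) state = 2;
      else state = 3;
    } else if (state == 2) { // gap in q: consume s char
      ++len; ++gaps;
      if (t & 4) state = 0;
      --j;
    } else {                 // gap in s: consume q char
      ++len; ++gaps;
      if (t & 8) state = 0;
      --i;
    }
  }
  out.qs = i; out.qe = qe; out.ss = j; out.se = se;
  out.len = len; out.matches = matches; out.gaps = gaps; out.score = best;
  return true;
}

// [[Rcpp::export]]
List cpp_pair_align(std::string a, std::string b, std::string alphabet,
                    IntegerMatrix submat, int gap_open, int gap_ext,
                    int dlo, int dhi) {
  std::vector<int> q = encode_seq(a, alphabet), s = encode_seq(b, alphabet);
  AlnHit h;
  if (!band_align(q, s, submat, gap_open, gap_ext, dlo, dhi, h))
    return List::create(_["ok"] = false);
  return List::create(_["ok"] = true, _["qs"] = h.qs, _["qe"] = h.qe,
                      _["ss"] = h.ss, _["se"] = h.se, _["aln_len"] = h.len,
                      _["matches"] = h.matches, _["gaps"] = h.gaps,
                      _["score"] = h.score);
}

// Pack a word of `word` codes (each < n_letters, unmasked) starting at p.
static inline bool pack_word(const std::vector<int>& s, const uint8_t* mask,
                             int p, int word, int n_letters, uint64_t& out) {
  uint64_t w = 0;
  for (int k = 0; k < word; ++k) {
    const int c = s[p + k];
    if (c >= n_letters) return false;
    if (mask && mask[p + k]) return false;
    w = w * (uint64_t)n_letters + (uint64_t)c;
  }
  out = w;
  return true;
}

// Ungapped two-way X-drop extension around a seed word; the cheap pretest
// that spares sparse (likely spurious) seed clusters the banded DP.
static int ungapped_extend(const std::vector<int>& q, const std::vector<int>& s,
                           const IntegerMatrix& submat,
                           int qi, int sj, int word, int xdrop) {
  int score = 0;
  for (int k = 0; k < word; ++k) score += submat(q[qi + k], s[sj + k]);
  int best = score;
  // right
  int run = score;
  for (int a = qi + word, b = sj + word;
       a < (int)q.size() && b < (int)s.size(); ++a, ++b) {
    run += submat(q[a], s[b]);
    if (run > best) best = run;
    if (run < best - xdrop) break;
  }
  int right_gain = best - score;
  // left
  best = score; run = score;
  for (int a = qi - 1, b = sj - 1; a >= 0 && b >= 0; --a, --b) {
    run += submat(q[a], s[b]);
    if (run > best) best = run;
    if (run < best - xdrop) break;
  }
  return best + right_gain; // seed + best left gain + best right gain
}

// Seed-and-extend search of each query against a set of subjects.  Shared
// words seed diagonal clusters (clusters split where consecutive diagonals
// differ by more than max_diag_gap); each cluster is extended by banded DP
// padded by band_pad diagonals.  One row per (query, subject, cluster)
// alignment with raw score >= min_raw_score.  Indices in the result are
// 1-based positions into `queries` / `subjects`.
// [[Rcpp::export]]
DataFrame cpp_search(CharacterVector queries, CharacterVector subjects,
                     std::string alphabet, int n_seed_letters,
                     IntegerMatrix submat, int gap_open, int gap_ext,
                     int word, int band_pad, int max_diag_gap,
                     int min_raw_score, List qmask, List smask,
                     int max_word_hits, int min_ungapped_score) {
  const int nq = queries.size(), ns = subjects.size();
  std::vector<std::vector<int>> S(ns);
  std::vector<std::vector<uint8_t>> SM(ns);
  for (int i = 0; i < ns; ++i) {
    S[i] = encode_seq(as<std::string>(subjects[i]), alphabet);
    if (smask.size() == ns && !Rf_isNull(smask[i])) {
      LogicalVector lm = smask[i];
      SM[i].assign(lm.size(), 0);
      for (int k = 0; k < lm.size(); ++k) SM[i][k] = lm[k] ? 1 : 0;
    }
  }
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> index;
  for (int i = 0; i < ns; ++i) {
    const int m = (int)S[i].size();
    const uint8_t* msk = SM[i].empty() ? nullptr : SM[i].data();
    for (int p = 0; p + word <= m; ++p) {
      uint64_t w;
      if (pack_word(S[i], msk, p, word, n_seed_letters, w))
        index[w].push_back(std::make_pair(i, p));
    }
  }

  std::vector<int> r_q, r_s, r_qs, r_qe, r_ss, r_se, r_len, r_match, r_gap, r_score;

  for (int qi = 0; qi < nq; ++qi) {
    std::vector<int> Q = encode_seq(as<std::string>(queries[qi]), alphabet);
    const int n = (int)Q.size();
    std::vector<uint8_t> QM;
    if (qmask.size() == nq && !Rf_isNull(qmask[qi])) {
      LogicalVector lm = qmask[qi];
      QM.assign(lm.size(), 0);
      for (int k = 0; k < lm.size(); ++k) QM[k] = lm[k] ? 1 : 0;
    }
    const uint8_t* msk = QM.empty() ? nullptr : QM.data();
    std::unordered_map<int, std::vector<std::pair<int,int>>> per_subj; // (diag, qpos)
    for (int p = 0; p + word <= n; ++p) {
      uint64_t w;
      if (!pack_word(Q, msk, p, word, n_seed_letters, w)) continue;
      auto it = index.find(w);
      if (it == index.end()) continue;
      if ((int)it->second.size() > max_word_hits) continue;
      for (auto& hit : it->second)
        per_subj[hit.first].push_back(std::make_pair(p - hit.second, p));
    }
    for (auto& kv : per_subj) {
      const int si = kv.first;
      auto& sd = kv.second;
      std::sort(sd.begin(), sd.end());
      size_t a = 0;
      while (a < sd.size()) {
        size_t b = a + 1;
        int dmin = sd[a].first, dmax = sd[a].first;
        while (b < sd.size() && sd[b].first - dmax <= max_diag_gap) {
          dmax = sd[b].first;
          ++b;
        }
        // sparse clusters must first pass an ungapped extension test
        if (min_ungapped_score > 0 && (b - a) < 3) {
          int ug = 0;
          for (size_t z = a; z < b; ++z) {
            const int qp = sd[z].second, sp = qp - sd[z].first;
            const int u = ungapped_extend(Q, S[si], submat, qp, sp, word, 20);
            if (u > ug) ug = u;
          }
          if (ug < min_ungapped_score) { a = b; continue; }
        }
        AlnHit h;
        if (band_align(Q, S[si], submat, gap_open, gap_ext,
                       dmin - band_pad, dmax + band_pad, h) &&
            h.score >= min_raw_score) {
          r_q.push_back(qi + 1); r_s.push_back(si + 1);
          r_qs.push_back(h.qs); r_qe.push_back(h.qe);
          r_ss.push_back(h.ss); r_se.push_back(h.se);
          r_len.push_back(h.len); r_match.push_back(h.matches);
          r_gap.push_back(h.gaps); r_score.push_back(h.score);
        }
        a = b;
      }
    }
  }
  return DataFrame::create(
    _["query"] = r_q, _["subject"] = r_s,
    _["q_start"] = r_qs, _["q_end"] = r_qe,
    _["s_start"] = r_ss, _["s_end"] = r_se,
    _["aln_len"] = r_len, _["matches"] = r_match,
    _["gaps"] = r_gap, _["score"] = r_score);
}

// Global (end-to-end) alignment maximizing matches - gap_pen * gap_columns
// (mismatch scores 0); identity is matches over all alignment columns.
// [[Rcpp::export]]
List cpp_global_identity(std::string a, std::string b, std::string alphabet,
                         int gap_pen) {
  std::vector<int> q = encode_seq(a, alphabet), s = encode_seq(b, alphabet);
  const int n = (int)q.size(), m = (int)s.size();
  const int unk = (int)alphabet.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0); // 1 diag, 2 left, 3 up
  for (int j = 0; j <= m; ++j) { prev[j] = -gap_pen * j; if (j) tb[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = -gap_pen * i;
    tb[(size_t)i * (m + 1)] = 3;
    for (int j = 1; j <= m; ++j) {
      const bool eq = (q[i - 1] == s[j - 1]) && (q[i - 1] < unk);
      const int d = prev[j - 1] + (eq ? 1 : 0);
      const int l = cur[j - 1] - gap_pen;
      const int u = prev[j] - gap_pen;
      int bestv = d; uint8_t t = 1;
      if (l > bestv) { bestv = l; t = 2; }
      if (u > bestv) { bestv = u; t = 3; }
      cur[j] = bestv;
      tb[(size_t)i * (m + 1) + j] = t;
    }
    std::swap(prev, cur);
  }
  int i = n, j = m, matches = 0, cols = 0, gaps = 0;
  while (i > 0 || j > 0) {
    const uint8_t t = tb[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && t == 1) {
      ++cols;
      if (q[i - 1] == s[j - 1] && q[i - 1] < unk) ++matches;
      --i; --j;
    } else if (j > 0 && (t == 2 || i == 0)) {
      ++cols; ++gaps; --j;
    } else {
      ++cols; ++gaps; --i;
    }
  }
  const double ident = cols > 0 ? 100.0 * matches / cols : 0.0;
  return List::create(_["identity_pct"] = ident, _["matches"] = matches,
                      _["columns"] = cols, _["gaps"] = gaps,
                      _["score"] = prev[m]);
}

// Windowed Shannon entropy mask: a position is masked when covered by any
// length-`window` window whose composition entropy is below `threshold`
// bits.  The unknown code counts as its own class.
// [[Rcpp::export]]
LogicalVector cpp_entropy_mask(std::string seq, std::string alphabet,
                               int window, double threshold) {
  std::vector<int> s = encode_seq(seq, alphabet);
  const int n = (int)s.size();
  const int K = (int)alphabet.size() + 1;
  LogicalVector out(n);
  if (n < window) return out;
  std::vector<int> cnt(K, 0);
  for (int i = 0; i < window; ++i) cnt[s[i]]++;
  auto entropy = [&]() {
    double h = 0.0;
    for (int k = 0; k < K; ++k)
      if (cnt[k] > 0) {
        const double p = (double)cnt[k] / window;
        h -= p * std::log2(p);
      }
    return h;
  };
  for (int start = 0; ; ++start) {
    if (entropy() < threshold)
      for (int k = start; k < start + window; ++k) out[k] = true;
    if (start + window >= n) break;
    cnt[s[start]]--;
    cnt[s[start + window]]++;
  }
  return out;
}
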