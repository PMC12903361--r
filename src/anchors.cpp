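#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// 2-bit base codes; anything not ACGT (incl. N) -> -1: never seeds, never matches.
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

struct Anchor {
  int a_start, a_end, b_start, b_end;
  int score, matches;
};

// Ungapped seed-and-extend anchor finder (the dot-plot primitive).
//
// Exact seed_len-mer seeds, extended both ways without gaps under an X-drop
// rule; the reported segment is trimmed to the maximal-scoring extent on each
// side. One extension per (diagonal, region): positions already scanned on a
// diagonal are skipped, which keeps tandem arrays (where every k-mer recurs
// on every copy diagonal) near-linear per diagonal.
//
// Coordinates are 0-based half-open. Iterating seeds in ascending a-order is
// ascending b-order within a diagonal, so results are exactly symmetric in
// (a, b) up to field transposition.
// [[Rcpp::export(name = ".find_anchors_cpp")]]
DataFrame find_anchors_cpp(std::string a, std::string b,
                           int seed_len, int match_score, int mismatch_score,
                           int xdrop, int min_score, double min_identity,
                           double max_diag) {
  const int la = (int)a.size(), lb = (int)b.size();
  std::vector<Anchor> out;
  if (la >= seed_len && lb >= seed_len) {
    std::vector<int8_t> ca(la), cb(lb);
    for (int i = 0; i < la; ++i) ca[i] = (int8_t)base_code(a[i]);
    for (int j = 0; j < lb; ++j) cb[j] = (int8_t)base_code(b[j]);

    // hash all valid seeds of b; position lists are ascending by construction
    std::unordered_map<uint64_t, std::vector<int> > index;
    index.reserve((size_t)lb * 2);
    {
      uint64_t key = 0, mask = (seed_len >= 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);
      int valid = 0; // run length of non-N bases ending at j
      for (int j = 0; j < lb; ++j) {
        if (cb[j] < 0) { valid = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)cb[j]) & mask;
        if (++valid >= seed_len) index[key].push_back(j - seed_len + 1);
      }
    }

    // per-diagonal scan frontier: skip seeds already scanned on that diagonal
    std::vector<int> frontier((size_t)la + lb + 1, -1); // index diag + la
    const int band = (max_diag >= (double)(la + lb)) ? (la + lb) : (int)max_diag;

    uint64_t key = 0, mask = (seed_len >= 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);
    int valid = 0;
    for (int i = 0; i < la; ++i) {
      if (ca[i] < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)ca[i]) & mask;
      if (++valid < seed_len) continue;
      const int s = i - seed_len + 1; // seed start on a
      auto it = index.find(key);
      if (it == index.end()) continue;
      const std::vector<int> &hits = it->second;
      // restrict to |diag| <= band via binary search on sorted hit list
      int lo = 0, hi = (int)hits.size();
      if (band < la + lb) {
        lo = (int)(std::lower_bound(hits.begin(), hits.end(), s - band) - hits.begin());
        hi = (int)(std::upper_bound(hits.begin(), hits.end(), s + band) - hits.begin());
      }
      for (int h = lo; h < hi; ++h) {
        const int t = hits[h];            // seed start on b
        const int diag = t - s;
        int &front = frontier[(size_t)(diag + la)];
        if (s < front) continue;          // already scanned here on this diagonal

        // right extension from seed end
        int cur = seed_len * match_score;
        int best = cur, best_right = 0, best_mr = 0, mr = 0;
        int ia = s + seed_len, ib = t + seed_len, k = 0;
        while (ia + k < la && ib + k < lb) {
          bool m = (ca[ia + k] >= 0) && (ca[ia + k] == cb[ib + k]);
          cur += m ? match_score : mismatch_score;
          if (m) ++mr;
          ++k;
          if (cur > best) { best = cur; best_right = k; best_mr = mr; }
          else if (best - cur > xdrop) break;
        }
        const int scan_right = s + seed_len + k; // a-position where the scan stopped
        // left extension from seed start
        cur = best; int best_left = 0, best_ml = 0, ml = 0;
        k = 0;
        while (s - 1 - k >= 0 && t - 1 - k >= 0) {
          bool m = (ca[s - 1 - k] >= 0) && (ca[s - 1 - k] == cb[t - 1 - k]);
          cur += m ? match_score : mismatch_score;
          if (m) ++ml;
          ++k;
          if (cur > best) { best = cur; best_left = k; best_ml = ml; }
          else if (best - cur > xdrop) break;
        }
        front = scan_right;

        int a0 = s - best_left, a1 = s + seed_len + best_right;
        int b0 = t - best_left;
        // boundary-precision trim: the +5/-4 maximal-score extent is right
        // for sensitivity but lets ends wander ~50%-identity tails past a
        // repeat boundary; re-trim to the maximal-scoring subsegment under
        // +1/-3 so retained ends need >= 75% local identity. Exact matches
        // are unaffected.
        {
          int cur = 0, bsum = 0, bi = 0, bj = -1, start = 0;
          for (int k = 0; k < a1 - a0; ++k) {
            bool m = (ca[a0 + k] >= 0) && (ca[a0 + k] == cb[b0 + k]);
            int v = m ? 1 : -3;
            if (cur + v < v) { cur = v; start = k; } else cur += v;
            if (cur > bsum) { bsum = cur; bi = start; bj = k; }
          }
          if (bj >= bi) { a1 = a0 + bj + 1; a0 += bi; b0 += bi; }
        }
        const int len = a1 - a0;
        int matches = 0, score = 0;
        for (int k = 0; k < len; ++k) {
          bool m = (ca[a0 + k] >= 0) && (ca[a0 + k] == cb[b0 + k]);
          if (m) { ++matches; score += match_score; } else score += mismatch_score;
        }
        if (len >= seed_len && score >= min_score &&
            (double)matches / len >= min_identity) {
          Anchor an;
          an.a_start = a0; an.a_end = a1;
          an.b_start = b0; an.b_end = b0 + len;
          an.score = score; an.matches = matches;
          out.push_back(an);
        }
      }
    }
  }

  const int n = (int)out.size();
  IntegerVector a_start(n), a_end(n), b_start(n), b_end(n), score(n), diag(n);
  NumericVector identity(n);
  for (int i = 0; i < n; ++i) {
    a_start[i] = out[i].a_start; a_end[i] = out[i].a_end;
    b_start[i] = out[i].b_start; b_end[i] = out[i].b_end;
    score[i] = out[i].score; diag[i] = out[i].b_start - out[i].a_start;
    identity[i] = (double)out[i].matches / (out[i].a_end - out[i].a_start);
  }
  return DataFrame::create(
    _["a_start"] = a_start, _["a_end"] = a_end,
    _["b_start"] = b_start, _["b_end"] = b_end,
    _["identity"] = identity, _["score"] = score, _["diag"] = diag,
    _["stringsAsFactors"] = false);
}

// Positions (0-based, on a) of substitutions inside an ungapped segment.
// N against anything is ambiguity, not a substitution.
// [[Rcpp::export(name = ".segment_mismatches_cpp")]]
IntegerVector segment_mismatches_cpp(std::string a, std::string b,
                                     int a_start, int b_start, int len) {
  std::vector<int> pos;
  for (int k = 0; k < len; ++k) {
    int x = base_code(a[a_start + k]), y = base_code(b[b_start + k]);
    if (x >= 0 && y >= 0 && x != y) pos.push_back(a_start + k);
  }
  return wrap(pos);
}
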