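#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Alignment kernels.  All coordinates returned to R are 0-based half-open.

static inline bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// ---------------------------------------------------------------------------
// Tandem repeat scan: banded local self-alignment of s against itself offset
// by `period`, with wraparound drift.  State H[d] is the best local score of
// an alignment ending with s[i] paired against s[j], j = i - period - d.
// Each cell carries the origin (start of the earlier copy), so every maximal
// local segment is recovered without traceback.  A candidate's total score
// adds match_weight * period for the first (defining) copy of the motif, so
// a perfect tract of L bases scores match_weight * L.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame tandem_scan_cpp(std::string s, int period, int match_weight,
                          int mismatch_weight, int indel_weight,
                          int min_score) {
  const int n = (int)s.size();
  const int p = period;
  std::vector<int> starts, ends, scores;
  if (n < p + 1) {
    return DataFrame::create(_["start"] = starts, _["end"] = ends,
                             _["score"] = scores);
  }
  const int dlo = std::max(-(p - 1), -2 * p);
  const int dhi = 2 * p;
  const int nd = dhi - dlo + 1;
  const int NEG = INT32_MIN / 4;
  std::vector<int> Hprev(nd, NEG), Oprev(nd, -1), Hcur(nd, NEG), Ocur(nd, -1);
  // best candidate per origin: origin -> (score, end)
  std::unordered_map<int, std::pair<int, int> > best;

  for (int i = p; i < n; ++i) {
    for (int k = 0; k < nd; ++k) {
      const int d = dlo + k;
      const int j = i - p - d;
      if (j < 0 || j >= i) { Hcur[k] = NEG; Ocur[k] = -1; continue; }
      const int sub = (s[(size_t)i] == s[(size_t)j]) ? match_weight
                                                     : -mismatch_weight;
      // diagonal; fresh alignments may only start at drift 0 so that a
      // period-p call genuinely aligns at offset p
      int h, o;
      if (Hprev[k] > 0)  { h = Hprev[k] + sub; o = Oprev[k]; }
      else if (d == 0)   { h = sub;            o = j; }
      else               { h = NEG;            o = -1; }
      // gap in the earlier copy: s[i] consumed against a gap (drift d-1 -> d)
      if (k > 0 && Hprev[k - 1] > 0) {
        const int g = Hprev[k - 1] - indel_weight;
        if (g > h) { h = g; o = Oprev[k - 1]; }
      }
      if (h <= 0) { Hcur[k] = NEG; Ocur[k] = -1; }
      else        { Hcur[k] = h;   Ocur[k] = o; }
    }
    // gap in the later copy: earlier-copy position consumed, same i
    // (drift d+1 -> d); descending k so chains of gaps resolve in one pass
    for (int k = nd - 2; k >= 0; --k) {
      if (Hcur[k + 1] <= 0) continue;
      const int g = Hcur[k + 1] - indel_weight;
      if (g > Hcur[k]) { Hcur[k] = g; Ocur[k] = Ocur[k + 1]; }
    }
    for (int k = 0; k < nd; ++k) {
      if (Hcur[k] <= 0) continue;
      const int total = Hcur[k] + match_weight * p;
      if (total < min_score) continue;
      auto it = best.find(Ocur[k]);
      if (it == best.end() || total > it->second.first) {
        best[Ocur[k]] = std::make_pair(total, i + 1);
      }
    }
    std::swap(Hprev, Hcur);
    std::swap(Oprev, Ocur);
  }
  for (auto &kv : best) {
    starts.push_back(kv.first);
    ends.push_back(kv.second.second);
    scores.push_back(kv.second.first);
  }
  return DataFrame::create(_["start"] = starts, _["end"] = ends,
                           _["score"] = scores);
}

// ---------------------------------------------------------------------------
// Mask-aware affine Smith-Waterman.  Query may contain '#' (mask): a masked
// position aligns to any target base at zero score, and gaps adjacent to a
// masked query position are free, so differing repeat-tract lengths between
// query and target are absorbed by the mask at no cost.  Masked columns and
// free-gap columns are excluded from the identity denominator.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sw_masked_cpp(std::string q, std::string t, int match_weight,
                   int mismatch_weight, int gap_open, int gap_ext) {
  const int m = (int)q.size(), n = (int)t.size();
  const int NEG = INT32_MIN / 4;
  // H, E (gap in query, consumes target), F (gap in target, consumes query)
  std::vector<int> Hp(n + 1, 0), Hc(n + 1, 0), Ep(n + 1, NEG), Ec(n + 1, NEG);
  // traceback: 0 stop, 1 diag, 2 E-step (from left), 3 F-step (from up)
  std::vector<uint8_t> tbH((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> tbE((size_t)(m + 1) * (n + 1), 0); // 1 = extend
  std::vector<uint8_t> tbF((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> Fcol(n + 1, NEG);
  int bi = 0, bj = 0, bscore = 0;

  for (int i = 1; i <= m; ++i) {
    const char qc = q[(size_t)(i - 1)];
    const bool qmask = (qc == '#');
    const int openF = qmask ? 0 : gap_open;
    const int extF = qmask ? 0 : gap_ext;
    Hc[0] = 0; Ec[0] = NEG;
    for (int j = 1; j <= n; ++j) {
      const char tc = t[(size_t)(j - 1)];
      int sub;
      if (qmask) sub = 0;
      else if (!is_base(qc) || !is_base(tc)) sub = -mismatch_weight;
      else sub = (qc == tc) ? match_weight : -mismatch_weight;
      // E: gap in query (insertion in target); free when current query
      // position is masked (tract-length surplus sits inside the mask)
      const int openE = qmask ? 0 : gap_open;
      const int extE = qmask ? 0 : gap_ext;
      int e_open = Hc[j - 1] - openE - extE;
      int e_ext = (Ec[j - 1] == NEG) ? NEG : Ec[j - 1] - extE;
      Ec[j] = std::max(e_open, e_ext);
      tbE[(size_t)i * (n + 1) + j] = (e_ext >= e_open) ? 1 : 0;
      // F: gap in target (consumes query char)
      int f_open = Hp[j] - openF - extF;
      int f_ext = (Fcol[j] == NEG) ? NEG : Fcol[j] - extF;
      Fcol[j] = std::max(f_open, f_ext);
      tbF[(size_t)i * (n + 1) + j] = (f_ext >= f_open) ? 1 : 0;
      int h = Hp[j - 1] + sub;
      uint8_t tb = 1;
      if (Ec[j] > h) { h = Ec[j]; tb = 2; }
      if (Fcol[j] > h) { h = Fcol[j]; tb = 3; }
      if (h <= 0) { h = 0; tb = 0; }
      Hc[j] = h;
      tbH[(size_t)i * (n + 1) + j] = tb;
      if (h > bscore) { bscore = h; bi = i; bj = j; }
    }
    std::swap(Hp, Hc);
    std::swap(Ep, Ec);
  }
  if (bscore <= 0) {
    return List::create(_["score"] = 0);
  }
  // traceback from (bi, bj)
  int i = bi, j = bj;
  long matches = 0, columns = 0;
  int state = 0; // 0 = in H
  while (i > 0 && j > 0) {
    const size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0) {
      const uint8_t tb = tbH[idx];
      if (tb == 0) break;
      if (tb == 1) {
        const char qc = q[(size_t)(i - 1)], tc = t[(size_t)(j - 1)];
        if (qc != '#') {
          ++columns;
          if (is_base(qc) && qc == tc) ++matches;
        }
        --i; --j;
      } else if (tb == 2) state = 2;
      else state = 3;
    } else if (state == 2) { // E: gap in query, consumes target char
      const char qc = q[(size_t)(i - 1)];
      if (qc != '#') ++columns; // free mask-adjacent insertions not counted
      if (tbE[idx] == 0) state = 0;
      --j;
    } else { // F: gap in target, consumes query char
      const char qc = q[(size_t)(i - 1)];
      if (qc != '#') ++columns;
      if (tbF[idx] == 0) state = 0;
      --i;
    }
  }
  return List::create(
      _["score"] = bscore, _["qstart"] = i, _["qend"] = bi, _["tstart"] = j,
      _["tend"] = bj, _["matches"] = (double)matches,
      _["columns"] = (double)columns);
}

// ---------------------------------------------------------------------------
// Exact word seeding: positions of shared word_size-mers between query
// (skipping masked/ambiguous words) and target (skipping ambiguous words).
// ---------------------------------------------------------------------------

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'T': return 3; default: return -1;
  }
}

// [[Rcpp::export]]
List seed_hits_cpp(std::string q, std::string t, int word_size) {
  const int m = (int)q.size(), n = (int)t.size();
  std::vector<int> qpos, tpos;
  if (m < word_size || n < word_size) {
    return List::create(_["qpos"] = qpos, _["tpos"] = tpos);
  }
  // index the (short) query, stream the (long) target
  const uint64_t mask = ((uint64_t)1 << (2 * word_size)) - 1;
  std::unordered_map<uint64_t, std::vector<int> > index;
  uint64_t key = 0; int run = 0;
  for (int i = 0; i < m; ++i) {
    const int c = base_code(q[(size_t)i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= word_size) index[key].push_back(i - word_size + 1);
  }
  key = 0; run = 0;
  for (int j = 0; j < n; ++j) {
    const int c = base_code(t[(size_t)j]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= word_size) {
      auto it = index.find(key);
      if (it != index.end()) {
        for (int i : it->second) {
          qpos.push_back(i);
          tpos.push_back(j - word_size + 1);
        }
      }
    }
  }
  return List::create(_["qpos"] = qpos, _["tpos"] = tpos);
}

// ---------------------------------------------------------------------------
// Global (Needleman-Wunsch) alignment with affine gaps; a gap of length k
// costs gap_open + k * gap_ext.  Deterministic tie-break: diagonal, then
// gap-in-b (consume a), then gap-in-a.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List nw_affine_cpp(std::string a, std::string b, double match_weight,
                   double mismatch_weight, double gap_open, double gap_ext) {
  const int m = (int)a.size(), n = (int)b.size();
  const double NEG = -1e18;
  std::vector<double> Hp(n + 1), Hc(n + 1), Ep(n + 1), Ec(n + 1),
      Fcol(n + 1, NEG);
  std::vector<uint8_t> tbH((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> tbE((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> tbF((size_t)(m + 1) * (n + 1), 0);
  Hp[0] = 0;
  for (int j = 1; j <= n; ++j) {
    Hp[j] = -gap_open - gap_ext * j;
    Ep[j] = Hp[j];
    tbH[j] = 2;
    tbE[j] = (j > 1);
  }
  for (int i = 1; i <= m; ++i) {
    Hc[0] = -gap_open - gap_ext * i;
    Ec[0] = NEG;
    Fcol[0] = Hc[0];
    tbH[(size_t)i * (n + 1)] = 3;
    tbF[(size_t)i * (n + 1)] = (i > 1);
    for (int j = 1; j <= n; ++j) {
      const size_t idx = (size_t)i * (n + 1) + j;
      const double sub = (a[(size_t)(i - 1)] == b[(size_t)(j - 1)])
                             ? match_weight : -mismatch_weight;
      const double e_open = Hc[j - 1] - gap_open - gap_ext;
      const double e_ext = Ec[j - 1] - gap_ext;
      Ec[j] = std::max(e_open, e_ext);
      tbE[idx] = (e_ext > e_open) ? 1 : 0;
      const double f_open = Hp[j] - gap_open - gap_ext;
      const double f_ext = Fcol[j] - gap_ext;
      Fcol[j] = std::max(f_open, f_ext);
      tbF[idx] = (f_ext > f_open) ? 1 : 0;
      double h = Hp[j - 1] + sub;
      uint8_t tb = 1;
      if (Ec[j] > h) { h = Ec[j]; tb = 2; }
      if (Fcol[j] > h) { h = Fcol[j]; tb = 3; }
      Hc[j] = h;
      tbH[idx] = tb;
    }
    std::swap(Hp, Hc);
    std::swap(Ep, Ec);
  }
  const double score = Hp[n];
  std::string ga, gb;
  int i = m, j = n, state = 0;
  while (i > 0 || j > 0) {
    const size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0) {
      const uint8_t tb = tbH[idx];
      if (tb == 1) {
        ga.push_back(a[(size_t)(i - 1)]);
        gb.push_back(b[(size_t)(j - 1)]);
        --i; --j;
      } else if (tb == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      ga.push_back('-');
      gb.push_back(b[(size_t)(j - 1)]);
      if (tbE[idx] == 0) state = 0;
      --j;
    } else {
      ga.push_back(a[(size_t)(i - 1)]);
      gb.push_back('-');
      if (tbF[idx] == 0) state = 0;
      --i;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["a"] = ga, _["b"] = gb, _["score"] = score);
}

// ---------------------------------------------------------------------------
// Sequence-to-profile global alignment for progressive MSA.  The profile is
// a 5 x L matrix of column fractions (A, C, G, T, gap).  Matching a residue
// to a column scores the expected substitution score against the column's
// residues; the gap fraction contributes -gap_ext per unit.  Returns the op
// string: 1 = consume both, 2 = gap in sequence, 3 = gap column in profile.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix profile, std::string s,
                       double match_weight, double mismatch_weight,
                       double gap_open, double gap_ext) {
  const int n = profile.ncol(); // profile columns
  const int m = (int)s.size();
  const double NEG = -1e18;
  // column scores for each of A,C,G,T against each profile column
  NumericMatrix colscore(4, n);
  const char bases[4] = {'A', 'C', 'G', 'T'};
  for (int j = 0; j < n; ++j) {
    for (int b = 0; b < 4; ++b) {
      double sc = 0;
      for (int r = 0; r < 4; ++r) {
        const double f = profile(r, j);
        if (f <= 0) continue;
        sc += f * ((b == r) ? match_weight : -mismatch_weight);
      }
      sc += profile(4, j) * (-gap_ext);
      colscore(b, j) = sc;
    }
  }
  std::vector<double> Hp(n + 1), Hc(n + 1), Ep(n + 1), Ec(n + 1),
      Fcol(n + 1, NEG);
  std::vector<uint8_t> tbH((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> tbE((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> tbF((size_t)(m + 1) * (n + 1), 0);
  Hp[0] = 0;
  for (int j = 1; j <= n; ++j) {
    Hp[j] = -gap_open - gap_ext * j;
    Ep[j] = Hp[j];
    tbH[j] = 2;
    tbE[j] = (j > 1);
  }
  for (int i = 1; i <= m; ++i) {
    Hc[0] = -gap_open - gap_ext * i;
    Ec[0] = NEG;
    Fcol[0] = Hc[0];
    tbH[(size_t)i * (n + 1)] = 3;
    tbF[(size_t)i * (n + 1)] = (i > 1);
    const int bc = base_code(s[(size_t)(i - 1)]);
    for (int j = 1; j <= n; ++j) {
      const size_t idx = (size_t)i * (n + 1) + j;
      const double sub = (bc >= 0) ? colscore(bc, j - 1) : -mismatch_weight;
      const double e_open = Hc[j - 1] - gap_open - gap_ext;
      const double e_ext = Ec[j - 1] - gap_ext;
      Ec[j] = std::max(e_open, e_ext);
      tbE[idx] = (e_ext > e_open) ? 1 : 0;
      const double f_open = Hp[j] - gap_open - gap_ext;
      const double f_ext = Fcol[j] - gap_ext;
      Fcol[j] = std::max(f_open, f_ext);
      tbF[idx] = (f_ext > f_open) ? 1 : 0;
      double h = Hp[j - 1] + sub;
      uint8_t tb = 1;
      if (Ec[j] > h) { h = Ec[j]; tb = 2; }
      if (Fcol[j] > h) { h = Fcol[j]; tb = 3; }
      Hc[j] = h;
      tbH[idx] = tb;
    }
    std::swap(Hp, Hc);
    std::swap(Ep, Ec);
  }
  const double score = Hp[n];
  std::vector<int> ops;
  int i = m, j = n, state = 0;
  while (i > 0 || j > 0) {
    const size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0) {
      const uint8_t tb = tbH[idx];
      if (tb == 1) { ops.push_back(1); --i; --j; }
      else if (tb == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      ops.push_back(2);
      if (tbE[idx] == 0) state = 0;
      --j;
    } else {
      ops.push_back(3);
      if (tbF[idx] == 0) state = 0;
      --i;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["ops"] = wrap(ops), _["score"] = score);
}
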