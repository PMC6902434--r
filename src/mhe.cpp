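#include <Rcpp.h>
#include <string>
#include <vector>
#include <cstring>
using namespace Rcpp;

// One-directional DP for microhomeology segment search.
//
// p and d are the proximal and distal window bases read AWAY from the
// join-point (for the left flank both strings are reversed by the
// caller). A segment half is a sequence of alignment columns with
// actions: M (match), X (mismatch), P (gap in proximal, consumes a
// distal base), D (gap in distal, consumes a proximal base), subject to
//   - every gap run has length <= max_gap_run,
//   - every gap run is accompanied by >= min_post_gap matched columns on
//     the side selected by `toward` (away from the junction by default,
//     i.e. following the gap in processing order; `toward = true`
//     requires the matches on the junction side, i.e. before the gap),
//   - the far end (last processed column) is a match.
// For every total column count c, every gap-run count r (up to
// max_runs, so the caller can cap runs across the two directions) and
// for the constrained variant whose first (junction-adjacent) column is
// a match, the DP reports the maximum alignment score (match +2,
// mismatch -2, gap open -4, gap column -1, in half-units of the
// conventional +1/-1/-2/-0.5 scheme) plus one optimal action path.
//
// N bases never match.

namespace {

struct Machine {
  int S;
  int start[4];           // state after first action, -1 = forbidden
  std::vector<int> trans; // S x 4
  std::vector<bool> accept;
  std::vector<bool> is_gap; // gap states (a transition into one from a
                            // non-gap state opens a new run)
  int tr(int s, int a) const { return trans[s * 4 + a]; }
};

// actions: 0 = M, 1 = X, 2 = P (gap in prox), 3 = D (gap in dist)
Machine build_machine(int mgr, int mpg, bool toward) {
  Machine mc;
  if (!toward) {
    const int S_X = 0, S_M = 1;
    const int owe_base = 2;          // owe_r at owe_base + r - 1
    const int gp = owe_base + (mpg - 1);
    const int gd = gp + mgr;
    mc.S = gd + mgr;
    mc.trans.assign(mc.S * 4, -1);
    mc.accept.assign(mc.S, false);
    mc.is_gap.assign(mc.S, false);
    mc.accept[S_M] = true;
    const int after_gap = (mpg == 1) ? S_M : owe_base + mpg - 2;
    for (int s : {S_X, S_M}) {
      mc.trans[s * 4 + 0] = S_M;
      mc.trans[s * 4 + 1] = S_X;
      mc.trans[s * 4 + 2] = gp;
      mc.trans[s * 4 + 3] = gd;
    }
    for (int r = 1; r <= mpg - 1; ++r) {
      int s = owe_base + r - 1;
      mc.trans[s * 4 + 0] = (r == 1) ? S_M : owe_base + r - 2;
    }
    for (int k = 1; k <= mgr; ++k) {
      int s = gp + k - 1;
      mc.is_gap[s] = true;
      mc.trans[s * 4 + 0] = after_gap;
      if (k < mgr) mc.trans[s * 4 + 2] = gp + k;
      s = gd + k - 1;
      mc.is_gap[s] = true;
      mc.trans[s * 4 + 0] = after_gap;
      if (k < mgr) mc.trans[s * 4 + 3] = gd + k;
    }
    mc.start[0] = S_M; mc.start[1] = S_X; mc.start[2] = gp; mc.start[3] = gd;
  } else {
    // streak states 0..mpg, then gap states
    const int gp = mpg + 1, gd = gp + mgr;
    mc.S = gd + mgr;
    mc.trans.assign(mc.S * 4, -1);
    mc.accept.assign(mc.S, false);
    mc.is_gap.assign(mc.S, false);
    for (int s = 1; s <= mpg; ++s) mc.accept[s] = true;
    for (int s = 0; s <= mpg; ++s) {
      mc.trans[s * 4 + 0] = std::min(s + 1, mpg);
      mc.trans[s * 4 + 1] = 0;
      if (s == mpg) { mc.trans[s * 4 + 2] = gp; mc.trans[s * 4 + 3] = gd; }
    }
    for (int k = 1; k <= mgr; ++k) {
      int s = gp + k - 1;
      mc.is_gap[s] = true;
      mc.trans[s * 4 + 0] = 1; mc.trans[s * 4 + 1] = 0;
      if (k < mgr) mc.trans[s * 4 + 2] = gp + k;
      s = gd + k - 1;
      mc.is_gap[s] = true;
      mc.trans[s * 4 + 0] = 1; mc.trans[s * 4 + 1] = 0;
      if (k < mgr) mc.trans[s * 4 + 3] = gd + k;
    }
    mc.start[0] = 1; mc.start[1] = 0; mc.start[2] = -1; mc.start[3] = -1;
  }
  return mc;
}

inline bool base_match(char a, char b) {
  return a == b && a != 'N' && b != 'N';
}

} // namespace

// [[Rcpp::export(name = ".mhe_dir_dp_cpp")]]
List mhe_dir_dp_cpp(std::string p, std::string d, int max_cols,
                    int max_gap_run, int min_post_gap, int max_runs,
                    bool toward) {
  const Machine mc = build_machine(max_gap_run, min_post_gap, toward);
  const int np = (int)p.size(), nd = (int)d.size(), C = max_cols, S = mc.S;
  const int NR = max_runs + 1;
  // value[c][i][j][s][f][r]
  const size_t NI = np + 1, NJ = nd + 1;
  const size_t layer = NI * NJ * S * 2 * NR;
  auto at = [&](int i, int j, int s, int f, int r) {
    return (((size_t)i * NJ + j) * S + s) * (2 * NR) + f * NR + r;
  };
  const short INVALID = -20000;
  std::vector<short> cur(layer, INVALID), nxt;
  std::vector<std::vector<signed char>> par_state(C + 1),
      par_action(C + 1);
  std::vector<std::vector<short>> layers(C + 1);

  // results: columns indexed f + 2 * r
  IntegerMatrix matches(C + 1, 2 * NR), pbases(C + 1, 2 * NR),
      dbases(C + 1, 2 * NR), gapcols(C + 1, 2 * NR),
      score2(C + 1, 2 * NR);
  std::fill(matches.begin(), matches.end(), NA_INTEGER);
  std::fill(pbases.begin(), pbases.end(), NA_INTEGER);
  std::fill(dbases.begin(), dbases.end(), NA_INTEGER);
  std::fill(gapcols.begin(), gapcols.end(), NA_INTEGER);
  std::fill(score2.begin(), score2.end(), NA_INTEGER);
  CharacterMatrix path(C + 1, 2 * NR);
  for (int f = 0; f < 2; ++f) {
    matches(0, f) = 0; pbases(0, f) = 0; dbases(0, f) = 0; gapcols(0, f) = 0;
    score2(0, f) = 0;
    path(0, f) = "";
  }

  if (C >= 1) {
    par_state[1].assign(layer, -1);
    par_action[1].assign(layer, -1);
    nxt.assign(layer, INVALID);
    for (int a = 0; a < 4; ++a) {
      int s = mc.start[a];
      if (s < 0) continue;
      int i = (a == 2) ? 0 : 1;
      int j = (a == 3) ? 0 : 1;
      if (i > np || j > nd) continue;
      if ((a == 0 || a == 1) && (np < 1 || nd < 1)) continue;
      if (a == 0 && !base_match(p[0], d[0])) continue;
      if (a == 1 && base_match(p[0], d[0])) continue;
      int r = mc.is_gap[s] ? 1 : 0;
      if (r >= NR) continue;
      int f = (a == 0) ? 1 : 0;
      short val = (a == 0) ? 2 : (a == 1) ? -2 : -5;
      size_t k = at(i, j, s, f, r);
      if (val > nxt[k]) {
        nxt[k] = val;
        par_state[1][k] = -2; // from virtual start
        par_action[1][k] = (signed char)a;
      }
    }
    std::swap(cur, nxt);
    layers[1] = cur;
  }

  for (int c = 1; c < C; ++c) {
    nxt.assign(layer, INVALID);
    par_state[c + 1].assign(layer, -1);
    par_action[c + 1].assign(layer, -1);
    for (int i = 0; i <= std::min(c, np); ++i) {
      for (int j = 0; j <= std::min(c, nd); ++j) {
        if (i + j < c) continue;
        for (int s = 0; s < S; ++s) {
          for (int f = 0; f < 2; ++f) {
            for (int r = 0; r < NR; ++r) {
              short v = cur[at(i, j, s, f, r)];
              if (v <= INVALID) continue;
              for (int a = 0; a < 4; ++a) {
                int s2 = mc.tr(s, a);
                if (s2 < 0) continue;
                bool open_gap = mc.is_gap[s2] && !mc.is_gap[s];
                int r2 = r + (open_gap ? 1 : 0);
                if (r2 >= NR) continue;
                int i2 = i + ((a == 2) ? 0 : 1);
                int j2 = j + ((a == 3) ? 0 : 1);
                if (i2 > np || j2 > nd) continue;
                if (a == 0 && !base_match(p[i2 - 1], d[j2 - 1])) continue;
                if (a == 1 && base_match(p[i2 - 1], d[j2 - 1])) continue;
                short v2 = v + (short)(a == 0 ? 2 : a == 1 ? -2 :
                                       open_gap ? -5 : -1);
                size_t k = at(i2, j2, s2, f, r2);
                if (v2 > nxt[k]) {
                  nxt[k] = v2;
                  par_state[c + 1][k] = (signed char)s;
                  par_action[c + 1][k] = (signed char)a;
                }
              }
            }
          }
        }
      }
    }
    std::swap(cur, nxt);
    layers[c + 1] = cur;
  }

  // harvest per (c, f, r) the best accepting cell and trace its path
  for (int c = 1; c <= C; ++c) {
    const std::vector<short> &lay = layers[c];
    if (lay.empty()) continue;
    for (int f = 0; f < 2; ++f) {
      for (int r = 0; r < NR; ++r) {
        short best = INVALID;
        int bi = -1, bj = -1, bs = -1;
        for (int i = 0; i <= std::min(c, np); ++i) {
          for (int j = 0; j <= std::min(c, nd); ++j) {
            if (i + j < c) continue;
            for (int s = 0; s < S; ++s) {
              if (!mc.accept[s]) continue;
              short v = lay[at(i, j, s, f, r)];
              if (v > best) { best = v; bi = i; bj = j; bs = s; }
            }
          }
        }
        if (best <= INVALID) continue;
        std::string acts;
        int i = bi, j = bj, s = bs, rr = r, gaps = 0, nm = 0;
        for (int cc = c; cc >= 1; --cc) {
          size_t k = at(i, j, s, f, rr);
          int a = par_action[cc][k];
          int ps = par_state[cc][k];
          char ch = "MXPD"[a];
          if (a == 0) ++nm;
          acts.push_back(ch);
          if (a == 2) { --j; ++gaps; }
          else if (a == 3) { --i; ++gaps; }
          else { --i; --j; }
          if (ps >= 0 && mc.is_gap[s] && !mc.is_gap[ps]) --rr;
          s = ps;
          if (ps == -2) break;
        }
        std::reverse(acts.begin(), acts.end());
        int col = f + 2 * r;
        matches(c, col) = nm;
        score2(c, col) = best;
        pbases(c, col) = bi;
        dbases(c, col) = bj;
        gapcols(c, col) = gaps;
        path(c, col) = acts;
      }
    }
  }
  return List::create(_["matches"] = matches, _["score2"] = score2,
                      _["pbases"] = pbases, _["dbases"] = dbases,
                      _["gapcols"] = gapcols, _["path"] = path);
}
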