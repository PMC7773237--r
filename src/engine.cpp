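// Monthly decision-loop engine for the pastoralist agent-based model.
//
// Randomness is counter-based: every (behaviorSeed, agentId, tick) triple
// keys an independent splitmix64 stream, so results are independent of the
// order in which agents are stepped and the R reference implementation of a
// single step can reproduce the engine's draws exactly. Draw order within a
// tick: 1 uniform for the scouting radius, then one uniform per private-cell
// deal attempt, in candidate order.
//
// Event codes: 0 STAYED, 1 MOVED, 2 DEAL_OK, 3 DROPPED_OUT,
//              4 FORCED_RELOCATE.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline uint64_t splitmixNext(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t mix3(uint64_t a, uint64_t b, uint64_t c) {
  uint64_t x = a * 0x9E3779B97F4A7C15ULL ^ b * 0xBF58476D1CE4E5B9ULL ^
               c * 0x94D049BB133111EBULL;
  x ^= x >> 30; x *= 0xBF58476D1CE4E5B9ULL;
  x ^= x >> 27; x *= 0x94D049BB133111EBULL;
  x ^= x >> 31;
  return x;
}

struct Stream {
  uint64_t state;
  Stream(double seed, double id, double tick)
      : state(mix3((uint64_t)(int64_t)seed, (uint64_t)(int64_t)id,
                   (uint64_t)(int64_t)tick)) {}
  double uniform() {
    return (double)(splitmixNext(state) >> 11) *
           (1.0 / 9007199254740992.0);
  }
};

// First n uniforms of the (seed, id, tick) stream; the R-side reference
// step consumes these same numbers in the same order.
// [[Rcpp::export]]
NumericVector cpp_stream_uniforms(double seed, double id, double tick,
                                  int n) {
  Stream s(seed, id, tick);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = s.uniform();
  return out;
}

struct Cand {
  double score;
  double distKm;
  int idx;   // row-major cell index, 1-based
  int row, col;
};

static inline bool candLess(const Cand &a, const Cand &b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.distKm != b.distKm) return a.distKm < b.distKm;
  return a.idx < b.idx;
}

static void gatherCandidates(std::vector<Cand> &out,
                             const NumericMatrix &score,
                             const LogicalMatrix &suit,
                             int row, int col, double radiusKm,
                             double cellKm, bool excludeCurrent) {
  out.clear();
  int nr = score.nrow(), nc = score.ncol();
  int R = (int)std::floor(radiusKm / cellKm + 1e-12);
  for (int dr = -R; dr <= R; ++dr) {
    int rr = row + dr;
    if (rr < 1 || rr > nr) continue;
    for (int dc = -R; dc <= R; ++dc) {
      int cc = col + dc;
      if (cc < 1 || cc > nc) continue;
      double dKm = std::sqrt((double)dr * dr + (double)dc * dc) * cellKm;
      if (dKm > radiusKm + 1e-12) continue;
      if (excludeCurrent && rr == row && cc == col) continue;
      if (!suit(rr - 1, cc - 1)) continue;
      double s = score(rr - 1, cc - 1);
      if (!std::isfinite(s)) continue;  // nodata or unsuitable sentinel
      Cand c;
      c.score = s; c.distKm = dKm;
      c.idx = (rr - 1) * nc + cc;
      c.row = rr; c.col = cc;
      out.push_back(c);
    }
  }
  std::sort(out.begin(), out.end(), candLess);
}

// [[Rcpp::export]]
List cpp_run_simulation(List seasonScores, IntegerVector tickSeason,
                        LogicalVector newSeason, LogicalMatrix suitable,
                        LogicalMatrix privateLand, IntegerVector agentId,
                        IntegerVector agentRow, IntegerVector agentCol,
                        double cellKm, double scoutMinKm, double scoutMaxKm,
                        double pDeal, int maxFail, double behaviorSeed,
                        LogicalVector recordTick) {
  int nTicks = tickSeason.size();
  int nAgents = agentId.size();
  int nc = suitable.ncol();

  std::vector<int> row(agentRow.begin(), agentRow.end());
  std::vector<int> col(agentCol.begin(), agentCol.end());
  std::vector<int> fails(nAgents, 0);
  std::vector<bool> active(nAgents, true);

  // trajectory buffers
  std::vector<int> tTick, tId, tRow, tCol, tState, tEvent, tFails;
  std::vector<double> tFav, tRadius;
  size_t nRec = 0;
  for (int t = 0; t < nTicks; ++t) if (recordTick[t]) ++nRec;
  size_t cap = nRec * (size_t)nAgents + (size_t)nAgents;
  tTick.reserve(cap); tId.reserve(cap); tRow.reserve(cap);
  tCol.reserve(cap); tState.reserve(cap); tEvent.reserve(cap);
  tFails.reserve(cap); tFav.reserve(cap); tRadius.reserve(cap);

  IntegerVector activeCount(nTicks), droppedCount(nTicks);
  int emptyCandidate = 0;

  std::vector<Cand> cands;
  cands.reserve(4096);

  for (int t = 1; t <= nTicks; ++t) {
    const NumericMatrix score =
        as<NumericMatrix>(seasonScores[tickSeason[t - 1] - 1]);
    bool boundary = newSeason[t - 1];
    if (boundary) std::fill(fails.begin(), fails.end(), 0);
    int nActive = 0, nDropped = 0;

    for (int a = 0; a < nAgents; ++a) {
      if (!active[a]) continue;
      Stream rng(behaviorSeed, (double)agentId[a], (double)t);
      double radius = scoutMinKm + rng.uniform() * (scoutMaxKm - scoutMinKm);
      gatherCandidates(cands, score, suitable, row[a], col[a], radius,
                       cellKm, boundary);
      int event = 0;  // STAYED
      int dealFailsTick = 0;
      bool decided = false;
      if (cands.empty()) ++emptyCandidate;
      int curIdx = (row[a] - 1) * nc + col[a];
      for (size_t k = 0; k < cands.size() && !decided; ++k) {
        const Cand &cd = cands[k];
        if (cd.idx == curIdx) {            // best option is to stay put
          event = 0; decided = true;
        } else if (!privateLand(cd.row - 1, cd.col - 1)) {
          row[a] = cd.row; col[a] = cd.col;
          event = boundary ? 4 : 1;        // FORCED_RELOCATE / MOVED
          decided = true;
        } else {
          double u = rng.uniform();
          if (u < pDeal) {
            row[a] = cd.row; col[a] = cd.col;
            event = 2;                     // DEAL_OK
            decided = true;
          } else {
            ++dealFailsTick;
            if (++fails[a] >= maxFail) {
              event = 3;                   // DROPPED_OUT
              decided = true;
            }
          }
        }
      }
      bool dropped = (event == 3);
      if (dropped) { active[a] = false; ++nDropped; }
      else ++nActive;
      if (recordTick[t - 1] || dropped) {
        tTick.push_back(t); tId.push_back(agentId[a]);
        tRow.push_back(row[a]); tCol.push_back(col[a]);
        tFav.push_back(score(row[a] - 1, col[a] - 1));
        tRadius.push_back(radius);
        tState.push_back(dropped ? 1 : 0);
        tEvent.push_back(event);
        tFails.push_back(dealFailsTick);
      }
    }
    activeCount[t - 1] = nActive;
    droppedCount[t - 1] = nDropped;
  }

  return List::create(
      _["tick"] = wrap(tTick), _["id"] = wrap(tId),
      _["row"] = wrap(tRow), _["col"] = wrap(tCol),
      _["favorability"] = wrap(tFav), _["radiusKm"] = wrap(tRadius),
      _["state"] = wrap(tState), _["event"] = wrap(tEvent),
      _["dealFails"] = wrap(tFails),
      _["activeCount"] = activeCount, _["droppedCount"] = droppedCount,
      _["finalRow"] = wrap(row), _["finalCol"] = wrap(col),
      _["finalActive"] = wrap(std::vector<int>(active.begin(), active.end())),
      _["emptyCandidateEvents"] = emptyCandidate);
}

// Ordered candidate list for one agent position (shared with the R-side
// reference step and exposed for tests).
// [[Rcpp::export]]
List cpp_candidate_cells(NumericMatrix score, LogicalMatrix suitable,
                         int row, int col, double radiusKm, double cellKm,
                         bool excludeCurrent) {
  std::vector<Cand> cands;
  gatherCandidates(cands, score, suitable, row, col, radiusKm, cellKm,
                   excludeCurrent);
  int n = cands.size();
  IntegerVector r(n), c(n);
  NumericVector s(n), d(n);
  for (int i = 0; i < n; ++i) {
    r[i] = cands[i].row; c[i] = cands[i].col;
    s[i] = cands[i].score; d[i] = cands[i].distKm;
  }
  return List::create(_["row"] = r, _["col"] = c, _["score"] = s,
                      _["distKm"] = d);
}
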