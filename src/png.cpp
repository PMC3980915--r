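#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Shift-alignment detection of polychronous groups. Fragments are 2-column
// integer matrices (neuron index 0-based, relative time 0-based, < L), each
// a *set* of (neuron, 1 ms bin) pairs.

namespace {

// Best alignment shift of `frag` against the count matrix C: the s in
// [-(L-1), L-1] maximizing sum of C[a, tf - s] over frag pairs (a, tf) with
// tf - s in bounds. Ties: smallest |s|, then smallest s. Visits shifts in
// preference order 0, -1, +1, -2, +2, ... and keeps the first strict max.
void bestShiftCore(const IntegerMatrix& C,
                   const std::vector<std::vector<int>>& nzcol,
                   const IntegerMatrix& frag, int L,
                   int& s_best, int& score_best) {
  std::vector<int> score(2 * L - 1, 0);
  int np = frag.nrow();
  for (int p = 0; p < np; ++p) {
    int a = frag(p, 0), tf = frag(p, 1);
    for (int t : nzcol[a]) {
      int s = tf - t;
      if (s >= -(L - 1) && s <= L - 1) score[s + L - 1] += C(a, t);
    }
  }
  s_best = 0; score_best = score[L - 1];
  for (int m = 1; m <= L - 1; ++m) {
    if (score[-m + L - 1] > score_best) { score_best = score[-m + L - 1]; s_best = -m; }
    if (score[m + L - 1] > score_best)  { score_best = score[m + L - 1];  s_best = m; }
  }
}

void makeNz(const IntegerMatrix& C, std::vector<std::vector<int>>& nzcol) {
  int n = C.nrow(), L = C.ncol();
  nzcol.assign(n, {});
  for (int a = 0; a < n; ++a)
    for (int t = 0; t < L; ++t)
      if (C(a, t) > 0) nzcol[a].push_back(t);
}

} // namespace

// [[Rcpp::export]]
List cpp_best_shift(IntegerMatrix C, IntegerMatrix frag) {
  std::vector<std::vector<int>> nzcol;
  makeNz(C, nzcol);
  int s, score;
  bestShiftCore(C, nzcol, frag, C.ncol(), s, score);
  return List::create(_["shift"] = s, _["score"] = score);
}

// Builds the count matrix C (n_neurons x L): initialized to 1 on the pairs
// of the first fragment, then each later fragment is aligned at its best
// shift and its (in-bounds) pairs incremented. Returns C and the shifts
// applied (first entry 0 by convention).
// [[Rcpp::export]]
List cpp_build_count_matrix(List frags, int n_neurons, int L) {
  int N = frags.size();
  IntegerMatrix C(n_neurons, L);
  std::vector<std::vector<int>> nzcol(n_neurons);
  IntegerVector shifts(N);
  for (int i = 0; i < N; ++i) {
    IntegerMatrix f = frags[i];
    int s = 0;
    if (i > 0) {
      int score;
      bestShiftCore(C, nzcol, f, L, s, score);
    }
    shifts[i] = s;
    for (int p = 0; p < f.nrow(); ++p) {
      int a = f(p, 0), t = f(p, 1) - s;
      if (t >= 0 && t < L) {
        if (C(a, t) == 0) nzcol[a].push_back(t);
        C(a, t) += 1;
      }
    }
  }
  return List::create(_["C"] = C, _["shifts"] = shifts);
}

// Activity of group g in a fragment: max over integer shifts s of
// |shift(g, s) ∩ frag|, where shift adds s to the group's times. Both are
// sets of pairs, so the overlap at shift s equals the number of (g, frag)
// pair matches with tf - tg == s; a histogram over all realizable s gives
// the maximum directly.
namespace {

int maxTime(const IntegerMatrix& m) {
  int mx = 0;
  for (int p = 0; p < m.nrow(); ++p) if (m(p, 1) > mx) mx = m(p, 1);
  return mx;
}

// shared core: g bucketed by neuron, flat shift histogram (s = tf - tg
// ranges over [-gmax, fmax], stored with offset gmax)
int activityCore(const std::vector<std::vector<int>>& gt, int gmax,
                 const IntegerMatrix& f, std::vector<int>& hist) {
  int fmax = maxTime(f);
  size_t span = static_cast<size_t>(gmax) + fmax + 1;
  if (hist.size() < span) hist.resize(span);
  std::fill(hist.begin(), hist.begin() + span, 0);
  int best = 0;
  for (int p = 0; p < f.nrow(); ++p) {
    int a = f(p, 0), tf = f(p, 1);
    for (int tg : gt[a]) {
      int c = ++hist[tf - tg + gmax];
      if (c > best) best = c;
    }
  }
  return best;
}

} // namespace

// [[Rcpp::export]]
int cpp_activity(IntegerMatrix g, IntegerMatrix frag, int n_neurons) {
  std::vector<std::vector<int>> gt(n_neurons);
  for (int p = 0; p < g.nrow(); ++p) gt[g(p, 0)].push_back(g(p, 1));
  std::vector<int> hist;
  return activityCore(gt, maxTime(g), frag, hist);
}

// Batch form: activity of one group in each fragment of a list.
// [[Rcpp::export]]
IntegerVector cpp_activities(IntegerMatrix g, List frags, int n_neurons) {
  int N = frags.size();
  IntegerVector out(N);
  std::vector<std::vector<int>> gt(n_neurons);
  for (int p = 0; p < g.nrow(); ++p) gt[g(p, 0)].push_back(g(p, 1));
  int gmax = maxTime(g);
  std::vector<int> hist;
  for (int i = 0; i < N; ++i) {
    IntegerMatrix f = frags[i];
    out[i] = activityCore(gt, gmax, f, hist);
  }
  return out;
}
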