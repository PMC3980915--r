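#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Clock-driven LIF core on a 1 ms grid. Per step (ending at time tt):
//   v <- v * exp(-1/tau); deliver arrivals scheduled for tt; clamp
//   refractory neurons to 0; fire non-refractory neurons with v >= thr
//   (record at tt, reset to 0, queue one delayed event per efferent edge).
// The network is passed in CSR form indexed by source unit (input nodes
// first, then neurons); weights are signed (< 0 for inhibitory edges).

namespace {

struct Net {
  const int* ptr;     // length n_units + 1
  const int* tgt;     // neuron index 0..n_neurons-1
  const double* w;    // signed weight
  const int* del;     // delay, ms (>= 1)
  int n_in, n_neurons;
};

class LifState {
public:
  LifState(int n_neurons, double tau, double thr, int t_refract, int max_delay)
    : n(n_neurons), decay(std::exp(-1.0 / tau)), thr(thr), T(t_refract),
      D(max_delay + 1), v(n_neurons, 0.0),
      last(n_neurons, -1000000), acc(static_cast<size_t>(D) * n_neurons, 0.0) {}

  // queue a synaptic event arriving at absolute time `at`
  inline void queueEvent(int at, int target, double weight) {
    acc[static_cast<size_t>(at % D) * n + target] += weight;
  }

  // queue all efferent events of a unit spiking at time tt
  inline void queueEfferents(const Net& net, int unit, int tt) {
    for (int e = net.ptr[unit]; e < net.ptr[unit + 1]; ++e)
      queueEvent(tt + net.del[e], net.tgt[e], net.w[e]);
  }

  // advance one step ending at tt; append spiking neuron indices to fired
  void step(const Net& net, int tt, std::vector<int>& fired) {
    double* slot = &acc[static_cast<size_t>(tt % D) * n];
    for (int i = 0; i < n; ++i) {
      v[i] = v[i] * decay + slot[i];
      slot[i] = 0.0;
      if (tt - last[i] < T) { v[i] = 0.0; continue; }  // absolute refractoriness
      if (v[i] >= thr) {
        fired.push_back(i);
        v[i] = 0.0;
        last[i] = tt;
      }
    }
    for (int i : fired) queueEfferents(net, net.n_in + i, tt);
  }

  int n;
  double decay, thr;
  int T, D;
  std::vector<double> v;
  std::vector<int> last;
  std::vector<double> acc;
};

inline int sampleNode(int pool) {
  int k = static_cast<int>(R::unif_rand() * pool);
  return (k >= pool) ? pool - 1 : k;
}

} // namespace

// Open-loop simulation of a fixed input spike list (times sorted ascending).
// Input spikes stamped at time s propagate along afferent edges and arrive
// at s + delay. Returns the neuron raster and the final membrane potentials.
// [[Rcpp::export]]
List cpp_simulate_open(IntegerVector ptr, IntegerVector tgt, NumericVector w,
                       IntegerVector del, int n_in, int n_neurons,
                       IntegerVector in_t, IntegerVector in_id, int t_end,
                       double tau, double thr, int t_refract, int max_delay) {
  Net net{ptr.begin(), tgt.begin(), w.begin(), del.begin(), n_in, n_neurons};
  LifState st(n_neurons, tau, thr, t_refract, max_delay);
  std::vector<int> sp_t, sp_id, fired;
  int k = 0, n_events = in_t.size();
  for (int tt = 0; tt <= t_end; ++tt) {
    fired.clear();
    st.step(net, tt, fired);
    for (int i : fired) { sp_t.push_back(tt); sp_id.push_back(i); }
    while (k < n_events && in_t[k] == tt) {  // emit this step's input spikes
      st.queueEfferents(net, in_id[k], tt);
      ++k;
    }
    if (k < n_events && in_t[k] < tt)
      stop("input spike times must be sorted ascending");
  }
  return List::create(_["time"] = wrap(sp_t), _["neuron"] = wrap(sp_id),
                      _["v"] = wrap(st.v));
}

// Closed-loop presentation run: stimuli are presented one after another,
// each a 30 ms (stim_ms) burst of Poisson spikes on its node subset, on top
// of continuous Poisson background noise over all input nodes. The next
// onset is the first ms >= onset + stim_ms at which the network's reaction
// has faded: the neuron-spike count over the trailing quiet_ms falls back
// to max(quiet_spikes, baseline_factor * floor), where floor is the
// noise-driven activity floor — the running minimum of the trailing count
// observed since the first stimulus ended (a minimum cannot be inflated
// by evoked bumps, so noisy regimes are judged against their own
// baseline while silent regimes keep floor 0). The floor is capped at
// half the refractory-limited maximum so genuinely self-sustaining
// activity can never masquerade as a baseline. Windows are capped at
// onset + max_gap_ms (under strong noise a capped window is ordinary
// scheduling: the trailing count fluctuates and need not revisit the
// floor). The run aborts only when runaway_limit consecutive windows are
// capped while the network fires near its refractory-limited maximum
// (>= 70%), the signature of the small-W- self-sustaining regime.
// [[Rcpp::export]]
List cpp_present_stimuli(IntegerVector ptr, IntegerVector tgt, NumericVector w,
                         IntegerVector del, int n_in, int n_neurons,
                         List stim_nodes, IntegerVector order, int stim_ms,
                         double stim_rate, double noise_rate, double tau,
                         double thr, int t_refract, int max_delay,
                         int quiet_ms, int max_gap_ms, int runaway_limit,
                         int quiet_spikes, double baseline_factor,
                         int warmup_ms) {
  Net net{ptr.begin(), tgt.begin(), w.begin(), del.begin(), n_in, n_neurons};
  LifState st(n_neurons, tau, thr, t_refract, max_delay);

  int n_pres = order.size();
  std::vector<std::vector<int>> stim(stim_nodes.size());
  for (int s = 0; s < stim_nodes.size(); ++s)
    stim[s] = as<std::vector<int>>(stim_nodes[s]);

  std::vector<int> sp_t, sp_id, in_t, in_id, onsets(n_pres), ends(n_pres);
  std::vector<int> fired;
  double noise_mean = n_in * noise_rate / 1000.0;  // expected noise spikes per ms

  // rolling neuron-spike count over the trailing quiet_ms window
  std::vector<int> ring(quiet_ms, 0);
  long trailing = 0;
  long floor_cap =
      static_cast<long>(0.5 * n_neurons * quiet_ms / std::max(1, t_refract));
  long floor = floor_cap;              // running minimum of `trailing`
  int floor_from = warmup_ms / 2;      // skip the warmup transient

  int t = 0, runaway = 0;
  // noise-only warmup: lets the network settle into its noise-driven
  // steady state so the activity floor is measured without stimulation
  for (int tt = 1; tt <= warmup_ms; ++tt) {
    fired.clear();
    st.step(net, tt, fired);
    for (int i : fired) { sp_t.push_back(tt); sp_id.push_back(i); }
    int slot = tt % quiet_ms;
    trailing += static_cast<long>(fired.size()) - ring[slot];
    ring[slot] = static_cast<int>(fired.size());
    if (tt >= floor_from && trailing < floor) floor = trailing;
    int nn = static_cast<int>(R::rpois(noise_mean));
    for (int j = 0; j < nn; ++j) {
      int node = sampleNode(n_in);
      in_t.push_back(tt); in_id.push_back(node);
      st.queueEfferents(net, node, tt);
    }
    t = tt;
  }
  for (int p = 0; p < n_pres; ++p) {
    const std::vector<int>& nodes = stim[order[p]];
    double stim_mean = nodes.size() * stim_rate / 1000.0;
    int onset = t + 1;           // first stimulated ms
    onsets[p] = onset;
    int tt = t;
    for (;;) {
      ++tt;
      fired.clear();
      st.step(net, tt, fired);
      for (int i : fired) { sp_t.push_back(tt); sp_id.push_back(i); }
      int slot = tt % quiet_ms;
      trailing += static_cast<long>(fired.size()) - ring[slot];
      ring[slot] = static_cast<int>(fired.size());
      if (tt >= floor_from && trailing < floor) floor = trailing;
      // background noise on all input nodes
      int nn = static_cast<int>(R::rpois(noise_mean));
      for (int j = 0; j < nn; ++j) {
        int node = sampleNode(n_in);
        in_t.push_back(tt); in_id.push_back(node);
        st.queueEfferents(net, node, tt);
      }
      // stimulus burst on the subset
      if (tt - onset < stim_ms) {
        int ns = static_cast<int>(R::rpois(stim_mean));
        for (int j = 0; j < ns; ++j) {
          int node = nodes[sampleNode(static_cast<int>(nodes.size()))];
          in_t.push_back(tt); in_id.push_back(node);
          st.queueEfferents(net, node, tt);
        }
      }
      if (tt - onset >= stim_ms) {  // stimulus over; test for quiescence
        long quiet_level =
            std::max(static_cast<long>(quiet_spikes),
                     static_cast<long>(baseline_factor * floor));
        if (trailing <= quiet_level) { runaway = 0; break; }
        if (tt - onset + 1 >= max_gap_ms) {
          long saturation =
              static_cast<long>(0.7 * n_neurons * quiet_ms /
                                std::max(1, t_refract));
          if (trailing >= saturation) {
            if (++runaway >= runaway_limit)
              stop("runaway activity: network at refractory-limited rate "
                   "with no quiet period for %d consecutive presentations",
                   runaway_limit);
          } else {
            runaway = 0;
          }
          break;
        }
      }
    }
    ends[p] = tt + 1;  // window is [onset, end); end == next onset
    t = tt;
  }
  return List::create(_["time"] = wrap(sp_t), _["neuron"] = wrap(sp_id),
                      _["in_time"] = wrap(in_t), _["in_node"] = wrap(in_id),
                      _["onset"] = wrap(onsets), _["end"] = wrap(ends));
}
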