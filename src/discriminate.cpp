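#include <Rcpp.h>
using namespace Rcpp;

// Pulse-discriminator state machine.
//
// ARMED: count consecutive working-signal samples strictly above
// `threshold`; once `min_above` such samples have been seen, record an
// event at the first sample of the run (or the last, when
// record_at_end) and enter HOLD.
// HOLD: re-arm only after `min_below` consecutive samples at or below
// `threshold - hysteresis` AND at least `dead_time` samples have
// elapsed since the recorded event.
//
// Indices are 1-based (R convention).
// [[Rcpp::export(name = ".discriminate_core")]]
IntegerVector discriminate_core(NumericVector x, double threshold,
                                int min_above, int min_below,
                                int dead_time, bool record_at_end,
                                double hysteresis) {
  const int n = x.size();
  std::vector<int> events;
  bool armed = true;
  int run_above = 0, run_start = 0, run_below = 0;
  int last_event = -dead_time - 1;  // 0-based sample of last event
  const double rearm = threshold - hysteresis;

  for (int i = 0; i < n; ++i) {
    if (armed) {
      if (x[i] > threshold) {
        if (run_above == 0) run_start = i;
        if (++run_above >= min_above) {
          int ev = record_at_end ? i : run_start;
          events.push_back(ev + 1);
          last_event = ev;
          armed = false;
          run_above = 0;
          run_below = 0;
        }
      } else {
        run_above = 0;
      }
    } else {
      if (x[i] <= rearm) {
        ++run_below;
      } else {
        run_below = 0;
      }
      if (run_below >= min_below && (i - last_event) >= dead_time) {
        armed = true;
        run_above = 0;
      }
    }
  }
  return wrap(events);
}
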