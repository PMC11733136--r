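#include <Rcpp.h>
using namespace Rcpp;

// Streaming peak-detector core.
//
// The detector keeps a ring buffer of the most recent `window`
// baseline-classified samples; samples inside an open peak are excluded so
// the moving average does not drift upward during a transit. A peak opens
// when the signal exceeds mean + k * SD of the window and closes when the
// signal returns to or below the threshold frozen at peak entry.
//
// Sub-threshold pulse flanks would otherwise leak into the baseline window
// and inflate its SD (a positive feedback that eventually swallows small
// peaks), so baseline commits pass through a `guard`-sample lag FIFO that
// is discarded when a peak opens, and the first `guard` samples after a
// peak closes are skipped. The state list round-trips through R unchanged,
// so feeding a trace in arbitrary chunks is bit-identical to a single pass.

static double window_sd(double sum, double sumsq, int n, int sd_mode) {
  if (n < 2) return 0.0;
  double var = (sumsq - sum * sum / n) / (n - 1);
  if (var < 0) var = 0;             // guard cancellation on constant input
  double sd = std::sqrt(var);
  if (sd_mode == 1) sd /= std::sqrt((double)n); // SD of the mean estimator
  return sd;
}

struct Baseline {
  NumericVector buf, pend;
  int head, nbuf, pend_head, pend_n, guard;
  double bsum, bsumsq;

  void commit(double x) {
    int window = buf.size();
    if (nbuf == window) {
      double old = buf[head];
      bsum -= old;
      bsumsq -= old * old;
    } else {
      nbuf += 1;
    }
    buf[head] = x;
    bsum += x;
    bsumsq += x * x;
    head = (head + 1) % window;
  }

  // lagged commit: x waits in the pending FIFO for `guard` samples before
  // entering the moving average, so it can still be discarded if a peak
  // opens right after it (rising flank)
  void push(double x) {
    if (guard == 0) { commit(x); return; }
    if (pend_n == guard) {
      commit(pend[pend_head]);
    } else {
      pend_n += 1;
    }
    pend[pend_head] = x;
    pend_head = (pend_head + 1) % guard;
  }

  void discard_pending() { pend_n = 0; }
};

// [[Rcpp::export(name = ".detector_feed_cpp")]]
List detector_feed_cpp(NumericVector signal, List state) {
  Baseline bl;
  bl.buf = clone(as<NumericVector>(state["buf"]));
  bl.pend = clone(as<NumericVector>(state["pend"]));
  bl.head = state["head"];
  bl.nbuf = state["nbuf"];
  bl.pend_head = state["pend_head"];
  bl.pend_n = state["pend_n"];
  bl.guard = state["guard"];
  bl.bsum = state["bsum"];
  bl.bsumsq = state["bsumsq"];
  int window = bl.buf.size();
  double nseen = state["nseen"]; // double: traces can exceed int range
  int skip     = state["skip"];
  bool in_peak = state["in_peak"];
  double peak_start = state["peak_start"];
  double peak_max   = state["peak_max"];
  double entry_base = state["entry_base"];
  double entry_thr  = state["entry_thr"];
  int peak_nsamp    = state["peak_nsamp"];
  double k          = state["k"];
  int min_len       = state["min_len"];
  int sd_mode       = state["sd_mode"];
  bool ablate       = state["include_peaks_in_baseline"];

  int n = signal.size();
  std::vector<double> p_start, p_end, p_mag, p_base;

  for (int i = 0; i < n; ++i) {
    double x = signal[i];
    double idx = nseen + 1;
    nseen = idx;

    if (ablate) {
      // ablation: every sample enters the moving average directly
      bl.commit(x);
      if (!in_peak) {
        if (nseen > window && bl.nbuf >= 2) {
          double mean = bl.bsum / bl.nbuf;
          double thr = mean + k * window_sd(bl.bsum, bl.bsumsq, bl.nbuf,
                                            sd_mode);
          if (x > thr) {
            in_peak = true;
            peak_start = idx; peak_max = x;
            entry_base = mean; entry_thr = thr; peak_nsamp = 1;
          }
        }
      } else if (x <= entry_thr) {
        if (peak_nsamp >= min_len) {
          p_start.push_back(peak_start); p_end.push_back(idx - 1);
          p_mag.push_back(peak_max - entry_base);
          p_base.push_back(entry_base);
        }
        in_peak = false;
      } else {
        if (x > peak_max) peak_max = x;
        peak_nsamp += 1;
      }
      continue;
    }

    if (in_peak) {
      if (x <= entry_thr) {     // signal back at/below entry threshold
        if (peak_nsamp >= min_len) {
          p_start.push_back(peak_start);
          p_end.push_back(idx - 1);
          p_mag.push_back(peak_max - entry_base);
          p_base.push_back(entry_base);
        }
        in_peak = false;
        skip = bl.guard;        // falling-flank guard band
        if (skip > 0) { skip -= 1; } else { bl.push(x); }
      } else {
        if (x > peak_max) peak_max = x;
        peak_nsamp += 1;
      }
      continue;
    }

    bool opened = false;
    if (nseen > window && bl.nbuf >= 2) {  // warm-up is always baseline
      double mean = bl.bsum / bl.nbuf;
      double thr = mean + k * window_sd(bl.bsum, bl.bsumsq, bl.nbuf,
                                        sd_mode);
      if (x > thr) {            // open a peak; freeze baseline + threshold
        in_peak = true;
        peak_start = idx;
        peak_max = x;
        entry_base = mean;
        entry_thr = thr;
        peak_nsamp = 1;
        bl.discard_pending();   // rising flank never reaches the baseline
        opened = true;
      }
    }
    if (!opened) {
      if (skip > 0) { skip -= 1; } else { bl.push(x); }
    }
  }

  List st = List::create(
    _["buf"] = bl.buf, _["pend"] = bl.pend, _["head"] = bl.head,
    _["nbuf"] = bl.nbuf, _["pend_head"] = bl.pend_head,
    _["pend_n"] = bl.pend_n, _["guard"] = bl.guard,
    _["bsum"] = bl.bsum, _["bsumsq"] = bl.bsumsq, _["nseen"] = nseen,
    _["skip"] = skip,
    _["in_peak"] = in_peak, _["peak_start"] = peak_start,
    _["peak_max"] = peak_max, _["entry_base"] = entry_base,
    _["entry_thr"] = entry_thr, _["peak_nsamp"] = peak_nsamp,
    _["k"] = k, _["min_len"] = min_len, _["sd_mode"] = sd_mode,
    _["include_peaks_in_baseline"] = ablate);

  NumericMatrix peaks(p_start.size(), 4);
  for (size_t j = 0; j < p_start.size(); ++j) {
    peaks(j, 0) = p_start[j];
    peaks(j, 1) = p_end[j];
    peaks(j, 2) = p_mag[j];
    peaks(j, 3) = p_base[j];
  }
  colnames(peaks) = CharacterVector::create("start", "end", "mag", "base");
  return List::create(_["state"] = st, _["peaks"] = peaks);
}
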