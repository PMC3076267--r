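#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Sweep-line overlap join over 0-based half-open intervals.
//
// Both interval sets are turned into start/end events on a shared
// coordinate axis, sorted by (chromosome, position, event type) with end
// events before start events at equal positions -- under half-open
// semantics an interval ending at p does not overlap one starting at p.
// A single linear pass maintains the set of currently open intervals per
// side; opening an interval pairs it against the opposite side's active
// set. Total cost is O(n log n) for the sort plus O(n + k) for the pass,
// where k is the number of overlapping pairs inspected; the n^2
// comparison matrix is never materialized.
//
// Strand codes: 0 = unspecified, 1 = forward, 2 = reverse. Under
// requireStrand an unspecified strand on either side is compatible with
// anything.

namespace {

struct Event {
  int chrom;
  int pos;
  // 0 = close, 1 = open (close sorts first at equal pos)
  int type;
  // 0 = query side, 1 = subject side
  int side;
  int idx;
};

inline bool event_less(const Event& a, const Event& b) {
  if (a.chrom != b.chrom) return a.chrom < b.chrom;
  if (a.pos != b.pos) return a.pos < b.pos;
  return a.type < b.type;
}

// Active set with O(1) insert and O(1) swap-remove keyed by interval index.
class ActiveSet {
 public:
  explicit ActiveSet(int n) : slot_(n, -1) {}
  void insert(int idx) {
    slot_[idx] = static_cast<int>(members_.size());
    members_.push_back(idx);
  }
  void remove(int idx) {
    int s = slot_[idx];
    int last = members_.back();
    members_[s] = last;
    slot_[last] = s;
    members_.pop_back();
    slot_[idx] = -1;
  }
  const std::vector<int>& members() const { return members_; }

 private:
  std::vector<int> members_;
  std::vector<int> slot_;
};

inline bool strand_ok(int a, int b, bool require) {
  if (!require) return true;
  return a == 0 || b == 0 || a == b;
}

}  // namespace

// [[Rcpp::export(name = ".sweep_match_cpp")]]
IntegerMatrix sweep_match_cpp(IntegerVector qStart, IntegerVector qEnd,
                              IntegerVector qChrom, IntegerVector qStrand,
                              IntegerVector sStart, IntegerVector sEnd,
                              IntegerVector sChrom, IntegerVector sStrand,
                              bool requireStrand, int minOverlap) {
  const int nq = qStart.size(), ns = sStart.size();
  std::vector<Event> ev;
  ev.reserve(2 * (static_cast<size_t>(nq) + ns));
  for (int i = 0; i < nq; ++i) {
    ev.push_back({qChrom[i], qStart[i], 1, 0, i});
    ev.push_back({qChrom[i], qEnd[i], 0, 0, i});
  }
  for (int i = 0; i < ns; ++i) {
    ev.push_back({sChrom[i], sStart[i], 1, 1, i});
    ev.push_back({sChrom[i], sEnd[i], 0, 1, i});
  }
  std::sort(ev.begin(), ev.end(), event_less);

  ActiveSet activeQ(nq), activeS(ns);
  std::vector<int> outQ, outS;

  for (const Event& e : ev) {
    if (e.type == 0) {
      if (e.side == 0) activeQ.remove(e.idx); else activeS.remove(e.idx);
      continue;
    }
    if (e.side == 0) {
      const int qi = e.idx;
      for (int si : activeS.members()) {
        if (!strand_ok(qStrand[qi], sStrand[si], requireStrand)) continue;
        int ov = std::min(qEnd[qi], sEnd[si]) - std::max(qStart[qi], sStart[si]);
        if (ov >= minOverlap) { outQ.push_back(qi + 1); outS.push_back(si + 1); }
      }
      activeQ.insert(qi);
    } else {
      const int si = e.idx;
      for (int qi : activeQ.members()) {
        if (!strand_ok(qStrand[qi], sStrand[si], requireStrand)) continue;
        int ov = std::min(qEnd[qi], sEnd[si]) - std::max(qStart[qi], sStart[si]);
        if (ov >= minOverlap) { outQ.push_back(qi + 1); outS.push_back(si + 1); }
      }
      activeS.insert(si);
    }
  }

  IntegerMatrix out(static_cast<int>(outQ.size()), 2);
  for (size_t i = 0; i < outQ.size(); ++i) {
    out(static_cast<int>(i), 0) = outQ[i];
    out(static_cast<int>(i), 1) = outS[i];
  }
  return out;
}
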