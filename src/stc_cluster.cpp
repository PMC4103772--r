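#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Sequential quasi-Dirichlet (Chinese-restaurant style) clustering of unique
// sequences with read counts. One replicate introduces sequences in random
// order, each drawn with probability proportional to its read count (this
// reproduces read-level random ordering, because all reads sharing a
// sequence join the same cluster the moment the first of them is placed).
// A focal sequence joins the existing cluster whose label (current dominant
// sequence) is most similar to it, provided that similarity is at or above
// the threshold gamma; otherwise it starts a new cluster. Ties between
// clusters resolve to the cluster with more reads, then to the
// lexicographically smallest label. Cluster labels are updated after every
// insertion.

struct Cluster {
  std::vector<int> members;  // sequence indices
  double reads;              // total reads
  int dominant;              // index of dominant sequence
};

// counts: reads per unique sequence; sim: percent similarity matrix;
// lexrank: lexicographic rank of each sequence (0 = smallest).
// Returns, for each sequence, the index (1-based) of the dominant sequence
// of its final cluster.
static void one_replicate(const IntegerVector& counts,
                          const NumericMatrix& sim,
                          double gamma_thr,
                          const IntegerVector& lexrank,
                          std::vector<int>& label_out) {
  const int n = counts.size();
  // weighted order without replacement, weights = read counts
  std::vector<double> w(n);
  double total = 0.0;
  for (int i = 0; i < n; ++i) { w[i] = counts[i]; total += w[i]; }
  std::vector<int> order(n);
  for (int k = 0; k < n; ++k) {
    double u = unif_rand() * total;
    double acc = 0.0;
    int pick = -1;
    for (int i = 0; i < n; ++i) {
      if (w[i] <= 0.0) continue;
      acc += w[i];
      if (u < acc) { pick = i; break; }
    }
    if (pick < 0) {  // numerical fallback: last remaining
      for (int i = n - 1; i >= 0; --i) if (w[i] > 0.0) { pick = i; break; }
    }
    order[k] = pick;
    total -= w[pick];
    w[pick] = 0.0;
  }

  std::vector<Cluster> clusters;
  clusters.reserve(n);
  std::vector<int> assign(n, -1);
  for (int k = 0; k < n; ++k) {
    int i = order[k];
    int best = -1;
    double best_sim = -1.0;
    for (size_t c = 0; c < clusters.size(); ++c) {
      double s = sim(i, clusters[c].dominant);
      if (s > best_sim + 1e-12) {
        best = (int)c; best_sim = s;
      } else if (s > best_sim - 1e-12 && best >= 0) {
        // tie: more reads, then lexicographically smaller label
        const Cluster& cb = clusters[best];
        const Cluster& cc = clusters[c];
        if (cc.reads > cb.reads ||
            (cc.reads == cb.reads &&
             lexrank[cc.dominant] < lexrank[cb.dominant])) {
          best = (int)c;
        }
      }
    }
    if (best >= 0 && best_sim >= gamma_thr - 1e-9) {
      Cluster& cl = clusters[best];
      cl.members.push_back(i);
      cl.reads += counts[i];
      // update dominant: most reads, tie -> lexicographically smallest
      int d = cl.dominant;
      if (counts[i] > counts[d] ||
          (counts[i] == counts[d] && lexrank[i] < lexrank[d])) {
        cl.dominant = i;
      }
      assign[i] = best;
    } else {
      Cluster cl;
      cl.members.push_back(i);
      cl.reads = counts[i];
      cl.dominant = i;
      clusters.push_back(cl);
      assign[i] = (int)clusters.size() - 1;
    }
  }
  for (int i = 0; i < n; ++i) {
    label_out[i] = clusters[assign[i]].dominant + 1;  // 1-based
  }
}

// [[Rcpp::export]]
IntegerVector stc_cluster_replicate(IntegerVector counts, NumericMatrix sim,
                                    double gamma, IntegerVector lexrank) {
  std::vector<int> lab(counts.size());
  one_replicate(counts, sim, gamma, lexrank, lab);
  return wrap(lab);
}

// Modal label per sequence over `replicates` runs. Ties between equally
// frequent labels resolve to the lexicographically smallest label.
// [[Rcpp::export]]
IntegerVector stc_modal_labels(IntegerVector counts, NumericMatrix sim,
                               double gamma, int replicates,
                               IntegerVector lexrank) {
  const int n = counts.size();
  std::vector<std::vector<int> > tally(n, std::vector<int>(n, 0));
  std::vector<int> lab(n);
  for (int r = 0; r < replicates; ++r) {
    one_replicate(counts, sim, gamma, lexrank, lab);
    for (int i = 0; i < n; ++i) tally[i][lab[i] - 1] += 1;
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int best = -1, best_count = -1;
    for (int j = 0; j < n; ++j) {
      int c = tally[i][j];
      if (c > best_count ||
          (c == best_count && c > 0 && lexrank[j] < lexrank[best])) {
        best = j; best_count = c;
      }
    }
    out[i] = best + 1;
  }
  return out;
}
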