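#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps, Gotoh recurrences.
// A gap of length L costs gap_open + (L-1) * gap_extend (penalties are
// negative). Among co-optimal alignments the one with the smallest target
// start, then the fewest gap columns, then the smallest query start is
// returned, which makes downstream mapping deterministic.
//
// Coordinates in the returned list are 0-based half-open.

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string target,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int m = (int) query.size();
  const int n = (int) target.size();
  const double NEG = -1e18;

  std::vector<double> H((m + 1) * (n + 1), 0.0);
  std::vector<double> E((m + 1) * (n + 1), NEG); // gap in query (consumes target)
  std::vector<double> F((m + 1) * (n + 1), NEG); // gap in target (consumes query)
  auto idx = [n](int i, int j) { return i * (n + 1) + j; };

  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = (query[i - 1] == target[j - 1]) ? match : mismatch;
      double e = std::max(H[idx(i, j - 1)] + gap_open,
                          E[idx(i, j - 1)] + gap_extend);
      double f = std::max(H[idx(i - 1, j)] + gap_open,
                          F[idx(i - 1, j)] + gap_extend);
      double h = H[idx(i - 1, j - 1)] + s;
      h = std::max(h, std::max(e, f));
      h = std::max(h, 0.0);
      E[idx(i, j)] = e;
      F[idx(i, j)] = f;
      H[idx(i, j)] = h;
      if (h > best) best = h;
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["hit"] = false);
  }

  // Trace back from every co-optimal end cell; keep the preferred alignment.
  std::string best_aq, best_at;
  int best_qs = -1, best_qe = -1, best_ts = -1, best_te = -1;
  long best_gaps = -1;

  for (int ie = 1; ie <= m; ++ie) {
    for (int je = 1; je <= n; ++je) {
      if (H[idx(ie, je)] != best) continue;
      std::string aq, at;
      int i = ie, j = je;
      int state = 0; // 0 = H, 1 = E, 2 = F
      long gaps = 0;
      while (i > 0 && j > 0) {
        if (state == 0) {
          double h = H[idx(i, j)];
          if (h == 0.0) break;
          double s = (query[i - 1] == target[j - 1]) ? match : mismatch;
          if (h == H[idx(i - 1, j - 1)] + s) {
            aq.push_back(query[i - 1]);
            at.push_back(target[j - 1]);
            --i; --j;
          } else if (h == F[idx(i, j)]) {
            state = 2;
          } else {
            state = 1;
          }
        } else if (state == 1) { // gap in query
          aq.push_back('-');
          at.push_back(target[j - 1]);
          ++gaps;
          if (E[idx(i, j)] == E[idx(i, j - 1)] + gap_extend) { --j; }
          else { --j; state = 0; }
        } else { // gap in target
          aq.push_back(query[i - 1]);
          at.push_back('-');
          ++gaps;
          if (F[idx(i, j)] == F[idx(i - 1, j)] + gap_extend) { --i; }
          else { --i; state = 0; }
        }
      }
      std::reverse(aq.begin(), aq.end());
      std::reverse(at.begin(), at.end());
      int ts = j, qs = i;
      bool take = false;
      if (best_qs < 0) take = true;
      else if (ts < best_ts) take = true;
      else if (ts == best_ts && gaps < best_gaps) take = true;
      else if (ts == best_ts && gaps == best_gaps && qs < best_qs) take = true;
      if (take) {
        best_aq = aq; best_at = at;
        best_qs = qs; best_qe = ie; best_ts = ts; best_te = je;
        best_gaps = gaps;
      }
    }
  }

  return List::create(
    _["score"] = best, _["hit"] = true,
    _["query_start"] = best_qs, _["query_end"] = best_qe,
    _["target_start"] = best_ts, _["target_end"] = best_te,
    _["aligned_query"] = best_aq, _["aligned_target"] = best_at,
    _["n_gaps"] = (double) best_gaps);
}
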