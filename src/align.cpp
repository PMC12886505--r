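#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps.
// A gap of length L costs gap_open + L * gap_extend (BLAST convention:
// existence + per-residue extension). N scores as a mismatch against
// everything, including another N.
//
// Tie-break among equal-scoring alignments: lowest query_start, then lowest
// subject_start. Spans are 0-based half-open.
// [[Rcpp::export]]
List cpp_smith_waterman(std::string query, std::string subject,
                        double match = 2.0, double mismatch = -3.0,
                        double gap_open = 5.0, double gap_extend = 2.0) {
  const int n = query.size(), m = subject.size();
  const double NEG = -std::numeric_limits<double>::infinity();

  // full matrices: H (best ending here), E (gap in query), F (gap in subject)
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), NEG);
  std::vector<double> F((n + 1) * (m + 1), NEG);
  #define IDX(i, j) ((i) * (m + 1) + (j))

  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    char qc = query[i - 1];
    for (int j = 1; j <= m; ++j) {
      char sc = subject[j - 1];
      double sub = (qc == sc && qc != 'N') ? match : mismatch;
      double e = std::max(E[IDX(i, j - 1)] - gap_extend,
                          H[IDX(i, j - 1)] - gap_open - gap_extend);
      double f = std::max(F[IDX(i - 1, j)] - gap_extend,
                          H[IDX(i - 1, j)] - gap_open - gap_extend);
      double h = H[IDX(i - 1, j - 1)] + sub;
      h = std::max(h, std::max(e, f));
      h = std::max(h, 0.0);
      E[IDX(i, j)] = e;
      F[IDX(i, j)] = f;
      H[IDX(i, j)] = h;
      if (h > best) best = h;
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0,
                        _["query_start"] = 0, _["query_end"] = 0,
                        _["subject_start"] = 0, _["subject_end"] = 0);
  }

  // traceback from every best-scoring cell; keep the span with the lowest
  // (query_start, subject_start)
  int bq0 = n + 1, bs0 = m + 1, bq1 = 0, bs1 = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (H[IDX(i, j)] != best) continue;
      // walk back through H until a zero cell
      int ci = i, cj = j;
      int state = 0; // 0 = H, 1 = E (gap in query), 2 = F (gap in subject)
      while (true) {
        if (state == 0) {
          double h = H[IDX(ci, cj)];
          if (h == 0.0) break;
          char qc = query[ci - 1], sc = subject[cj - 1];
          double sub = (qc == sc && qc != 'N') ? match : mismatch;
          if (h == H[IDX(ci - 1, cj - 1)] + sub) { --ci; --cj; }
          else if (h == E[IDX(ci, cj)]) state = 1;
          else state = 2;
        } else if (state == 1) {
          double e = E[IDX(ci, cj)];
          if (e == H[IDX(ci, cj - 1)] - gap_open - gap_extend) { --cj; state = 0; }
          else { --cj; } // stay in E
        } else {
          double f = F[IDX(ci, cj)];
          if (f == H[IDX(ci - 1, cj)] - gap_open - gap_extend) { --ci; state = 0; }
          else { --ci; }
        }
      }
      if (ci < bq0 || (ci == bq0 && cj < bs0)) {
        bq0 = ci; bs0 = cj; bq1 = i; bs1 = j;
      }
    }
  }
  #undef IDX

  return List::create(_["score"] = best,
                      _["query_start"] = bq0, _["query_end"] = bq1,
                      _["subject_start"] = bs0, _["subject_end"] = bs1);
}
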