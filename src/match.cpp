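#include <Rcpp.h>
using namespace Rcpp;

// Longest common substring between query and subject over {A,C,G,T}.
// Windows containing N never match: assemblies carry Ns and counting them
// as matches would inflate off-target lengths.
//
// Returns the maximal length and every (query_start, subject_start) pair
// (0-based) at which a match of that length occurs.
// [[Rcpp::export]]
List cpp_longest_match(std::string query, std::string subject) {
  const int n = query.size(), m = subject.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  std::vector<std::pair<int, int> > ends; // (i, j) 1-based end coordinates

  for (int i = 1; i <= n; ++i) {
    char qc = query[i - 1];
    for (int j = 1; j <= m; ++j) {
      char sc = subject[j - 1];
      if (qc == sc && qc != 'N') {
        cur[j] = prev[j - 1] + 1;
        if (cur[j] > best) {
          best = cur[j];
          ends.clear();
          ends.push_back(std::make_pair(i, j));
        } else if (cur[j] == best && best > 0) {
          ends.push_back(std::make_pair(i, j));
        }
      } else {
        cur[j] = 0;
      }
    }
    std::swap(prev, cur);
  }

  // keep only maximal occurrences (an end cell of a run of length `best`
  // whose extension is broken); with the clearing logic above every stored
  // end already has run length exactly `best`, but a longer run records
  // several cells — keep the final cell of each run only.
  IntegerMatrix pos(ends.size(), 2);
  int kept = 0;
  for (size_t k = 0; k < ends.size(); ++k) {
    int i = ends[k].first, j = ends[k].second;
    bool extendable = (i < n && j < m && query[i] == subject[j] && query[i] != 'N');
    if (!extendable) {
      pos(kept, 0) = i - best; // 0-based query start
      pos(kept, 1) = j - best; // 0-based subject start
      ++kept;
    }
  }
  IntegerMatrix out(kept, 2);
  for (int k = 0; k < kept; ++k) { out(k, 0) = pos(k, 0); out(k, 1) = pos(k, 1); }

  return List::create(_["length"] = best, _["positions"] = out);
}

// Maximal match length only (no positions); used by the scanner's hot loop.
// [[Rcpp::export]]
int cpp_longest_match_len(std::string query, std::string subject) {
  const int n = query.size(), m = subject.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    char qc = query[i - 1];
    for (int j = 1; j <= m; ++j) {
      if (qc == subject[j - 1] && qc != 'N') {
        cur[j] = prev[j - 1] + 1;
        if (cur[j] > best) best = cur[j];
      } else {
        cur[j] = 0;
      }
    }
    std::swap(prev, cur);
  }
  return best;
}
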