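#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Positional similarity: matches at identical positions over the shorter
// of the two sequences. Tokens are integer equivalence-class codes
// (words with identical spelling or identical phoneme key share a code).
static int positional_score(const std::vector<int>& a, const std::vector<int>& b) {
  size_t n = std::min(a.size(), b.size());
  int s = 0;
  for (size_t i = 0; i < n; ++i)
    if (a[i] == b[i]) ++s;
  return s;
}

// Greedy equalization: while lengths differ, trial-delete each single word
// from the longer sequence, keep the deletion giving the highest positional
// similarity with the other sequence (leftmost on ties), repeat. The final
// score is the positional match count of the equal-length pair.
static int greedy_core(std::vector<int> res, std::vector<int> tra) {
  while (res.size() != tra.size()) {
    std::vector<int>& longer = (res.size() > tra.size()) ? res : tra;
    const std::vector<int>& other = (res.size() > tra.size()) ? tra : res;
    int best = -1;
    size_t best_j = 0;
    std::vector<int> trial;
    trial.reserve(longer.size() - 1);
    for (size_t j = 0; j < longer.size(); ++j) {
      trial.clear();
      for (size_t i = 0; i < longer.size(); ++i)
        if (i != j) trial.push_back(longer[i]);
      int s = positional_score(trial, other);
      if (s > best) { best = s; best_j = j; }
    }
    longer.erase(longer.begin() + best_j);
  }
  return positional_score(res, tra);
}

// Exhaustive oracle: maximize the positional score over every deletion set
// (taken from the longer sequence) that equalizes lengths.
static int brute_core(const std::vector<int>& res, const std::vector<int>& tra) {
  const std::vector<int>& longer = (res.size() >= tra.size()) ? res : tra;
  const std::vector<int>& shorter = (res.size() >= tra.size()) ? tra : res;
  size_t d = longer.size() - shorter.size();
  if (d == 0) return positional_score(res, tra);

  std::vector<size_t> idx(d);
  for (size_t i = 0; i < d; ++i) idx[i] = i;
  int best = 0;
  std::vector<int> trial;
  trial.reserve(shorter.size());
  while (true) {
    trial.clear();
    size_t k = 0;
    for (size_t i = 0; i < longer.size(); ++i) {
      if (k < d && idx[k] == i) { ++k; continue; }
      trial.push_back(longer[i]);
    }
    int s = positional_score(trial, shorter);
    if (s > best) best = s;
    // next combination
    size_t j = d;
    while (j > 0) {
      --j;
      if (idx[j] < longer.size() - (d - j)) {
        ++idx[j];
        for (size_t m = j + 1; m < d; ++m) idx[m] = idx[m - 1] + 1;
        break;
      }
      if (j == 0) return best;
    }
    if (d == 0) break;
  }
  return best;
}

// [[Rcpp::export(name = ".greedy_align_core")]]
int greedy_align_core(IntegerVector result, IntegerVector transcript) {
  std::vector<int> r = as<std::vector<int>>(result);
  std::vector<int> t = as<std::vector<int>>(transcript);
  return greedy_core(r, t);
}

// [[Rcpp::export(name = ".brute_align_core")]]
int brute_align_core(IntegerVector result, IntegerVector transcript) {
  std::vector<int> r = as<std::vector<int>>(result);
  std::vector<int> t = as<std::vector<int>>(transcript);
  return brute_core(r, t);
}

static void seq_to_string(const std::vector<int>& v, std::string& out) {
  out.clear();
  for (size_t i = 0; i < v.size(); ++i) {
    if (i) out.push_back(' ');
    out.push_back('a' + v[i]);
  }
}

// Exhaustive sweep over every pair of token sequences (transcript length
// 1..max_transcript, result length within max_surplus of it, tokens from an
// alphabet of `alphabet` symbols). Returns instance counts, the number of
// cases where the greedy score exceeds the oracle (must be zero), the number
// of strict shortfalls (greedy < oracle), and up to `max_cases` recorded
// shortfall instances.
// [[Rcpp::export(name = ".alignment_sweep_core")]]
List alignment_sweep_core(int max_transcript, int max_surplus, int alphabet,
                          int max_cases = 1000) {
  long long n_instances = 0, n_exceeds = 0, n_shortfall = 0;
  std::vector<std::string> case_res, case_tra;
  std::vector<int> case_greedy, case_brute;
  std::string buf;

  for (int tlen = 1; tlen <= max_transcript; ++tlen) {
    for (int rlen = std::max(1, tlen - max_surplus);
         rlen <= tlen + max_surplus; ++rlen) {
      std::vector<int> tra(tlen, 0), res(rlen, 0);
      // odometer over transcript sequences
      while (true) {
        std::fill(res.begin(), res.end(), 0);
        while (true) {
          int g = greedy_core(res, tra);
          int b = brute_core(res, tra);
          ++n_instances;
          if (g > b) ++n_exceeds;
          if (g < b) {
            ++n_shortfall;
            if ((int)case_res.size() < max_cases) {
              seq_to_string(res, buf); case_res.push_back(buf);
              seq_to_string(tra, buf); case_tra.push_back(buf);
              case_greedy.push_back(g);
              case_brute.push_back(b);
            }
          }
          int j = rlen - 1;
          while (j >= 0 && res[j] == alphabet - 1) { res[j] = 0; --j; }
          if (j < 0) break;
          ++res[j];
        }
        int j = tlen - 1;
        while (j >= 0 && tra[j] == alphabet - 1) { tra[j] = 0; --j; }
        if (j < 0) break;
        ++tra[j];
      }
    }
  }
  return List::create(
    _["n_instances"] = (double)n_instances,
    _["n_greedy_exceeds_oracle"] = (double)n_exceeds,
    _["n_shortfalls"] = (double)n_shortfall,
    _["shortfall_result"] = case_res,
    _["shortfall_transcript"] = case_tra,
    _["shortfall_greedy"] = case_greedy,
    _["shortfall_oracle"] = case_brute);
}
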