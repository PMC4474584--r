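// Single-threaded CBOW / ICD-segment-target word2vec training kernels with a
// hierarchical soft-max output layer. Fully deterministic: no RNG, fixed
// iteration order, learning rate a pure function of the update counter.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x > 50.0) return 1.0;
  if (x < -50.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// syn0: dim x V input-layer weights (columns are word vectors, the model);
// syn1: dim x n_internal hierarchical-soft-max node weights.
// codes/points: per-leaf Huffman code bits and 1-based internal node ids.
// processed0/total_sched let a caller run the schedule in slices (e.g. to
// evaluate the loss between epochs); total_sched <= 0 means the full run.
// [[Rcpp::export]]
double cpp_cbow_train(List sentences, List codes, List points,
                      NumericMatrix syn0, NumericMatrix syn1,
                      int window, int epochs,
                      double alpha0, double alpha_min,
                      double processed0 = 0.0, double total_sched = -1.0) {
  const int dim = syn0.nrow();
  long long total_tokens = 0;
  for (int s = 0; s < sentences.size(); ++s)
    total_tokens += as<IntegerVector>(sentences[s]).size();
  const double total = total_sched > 0 ? total_sched
                                       : (double)total_tokens * epochs;
  if (total <= 0) return alpha0;

  std::vector<double> neu1(dim), neu1e(dim);
  double processed = processed0;
  double alpha = alpha0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sent = sentences[s];
      const int n = sent.size();
      for (int t = 0; t < n; ++t) {
        alpha = alpha0 * (1.0 - processed / total);
        if (alpha < alpha_min) alpha = alpha_min;
        processed += 1.0;
        int lo = t - window; if (lo < 0) lo = 0;
        int hi = t + window; if (hi > n - 1) hi = n - 1;
        int cw = 0;
        std::fill(neu1.begin(), neu1.end(), 0.0);
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          const int wid = sent[c] - 1;
          for (int k = 0; k < dim; ++k) neu1[k] += syn0(k, wid);
          ++cw;
        }
        if (cw == 0) continue;
        for (int k = 0; k < dim; ++k) neu1[k] /= cw;
        std::fill(neu1e.begin(), neu1e.end(), 0.0);
        const int focus = sent[t] - 1;
        IntegerVector code = codes[focus];
        IntegerVector point = points[focus];
        for (int j = 0; j < code.size(); ++j) {
          const int node = point[j] - 1;
          double f = 0.0;
          for (int k = 0; k < dim; ++k) f += neu1[k] * syn1(k, node);
          f = sigmoid(f);
          const double g = (1.0 - code[j] - f) * alpha;
          for (int k = 0; k < dim; ++k) {
            neu1e[k] += g * syn1(k, node);
            syn1(k, node) += g * neu1[k];
          }
        }
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          const int wid = sent[c] - 1;
          for (int k = 0; k < dim; ++k) syn0(k, wid) += neu1e[k];
        }
      }
    }
  }
  return alpha;
}

// Mean negative log-likelihood of the Huffman paths of all focus tokens
// under the current parameters (the CBOW training objective).
// [[Rcpp::export]]
double cpp_cbow_loss(List sentences, List codes, List points,
                     NumericMatrix syn0, NumericMatrix syn1, int window) {
  const int dim = syn0.nrow();
  std::vector<double> neu1(dim);
  double nll = 0.0;
  long long n_eval = 0;
  for (int s = 0; s < sentences.size(); ++s) {
    IntegerVector sent = sentences[s];
    const int n = sent.size();
    for (int t = 0; t < n; ++t) {
      int lo = t - window; if (lo < 0) lo = 0;
      int hi = t + window; if (hi > n - 1) hi = n - 1;
      int cw = 0;
      std::fill(neu1.begin(), neu1.end(), 0.0);
      for (int c = lo; c <= hi; ++c) {
        if (c == t) continue;
        const int wid = sent[c] - 1;
        for (int k = 0; k < dim; ++k) neu1[k] += syn0(k, wid);
        ++cw;
      }
      if (cw == 0) continue;
      for (int k = 0; k < dim; ++k) neu1[k] /= cw;
      const int focus = sent[t] - 1;
      IntegerVector code = codes[focus];
      IntegerVector point = points[focus];
      double path_nll = 0.0;
      for (int j = 0; j < code.size(); ++j) {
        const int node = point[j] - 1;
        double x = 0.0;
        for (int k = 0; k < dim; ++k) x += neu1[k] * syn1(k, node);
        // label 1 when code bit 0; p(correct) = sigmoid(label ? x : -x)
        const double z = (code[j] == 0) ? x : -x;
        // -log sigmoid(z), numerically stable
        path_nll += (z > 0) ? std::log1p(std::exp(-z))
                            : (-z + std::log1p(std::exp(z)));
      }
      nll += path_nll;
      ++n_eval;
    }
  }
  return n_eval ? nll / n_eval : 0.0;
}

// ICD-segment-target variant: one-hot input word, prediction targets are the
// ICD-10 code segments of the containing note, each hierarchical-soft-max
// gradient scaled by the segment's taxonomy weight.
// note_tokens: word ids per note; note_segs / note_segw: segment leaf ids and
// taxonomy weights per note (general to specific).
// [[Rcpp::export]]
double cpp_icd_train(List note_tokens, List note_segs, List note_segw,
                     List codes, List points,
                     NumericMatrix syn0, NumericMatrix syn1,
                     int epochs, double alpha0, double alpha_min) {
  const int dim = syn0.nrow();
  long long total_pairs = 0;
  for (int m = 0; m < note_tokens.size(); ++m)
    total_pairs += (long long)as<IntegerVector>(note_tokens[m]).size() *
                   as<IntegerVector>(note_segs[m]).size();
  const double total = (double)total_pairs * epochs;
  if (total <= 0) return alpha0;

  std::vector<double> neu1e(dim);
  long long processed = 0;
  double alpha = alpha0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int m = 0; m < note_tokens.size(); ++m) {
      IntegerVector toks = note_tokens[m];
      IntegerVector segs = note_segs[m];
      NumericVector segw = note_segw[m];
      for (int t = 0; t < toks.size(); ++t) {
        const int wid = toks[t] - 1;
        for (int sg = 0; sg < segs.size(); ++sg) {
          alpha = alpha0 * (1.0 - (double)processed / total);
          if (alpha < alpha_min) alpha = alpha_min;
          ++processed;
          const double wscale = segw[sg];
          if (wscale == 0.0) continue;
          const int leaf = segs[sg] - 1;
          IntegerVector code = codes[leaf];
          IntegerVector point = points[leaf];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int j = 0; j < code.size(); ++j) {
            const int node = point[j] - 1;
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += syn0(k, wid) * syn1(k, node);
            f = sigmoid(f);
            const double g = (1.0 - code[j] - f) * alpha * wscale;
            for (int k = 0; k < dim; ++k) {
              neu1e[k] += g * syn1(k, node);
              syn1(k, node) += g * syn0(k, wid);
            }
          }
          for (int k = 0; k < dim; ++k) syn0(k, wid) += neu1e[k];
        }
      }
    }
  }
  return alpha;
}
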