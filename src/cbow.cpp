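// word2vec-style CBOW / skip-gram training with negative sampling.
// Single-threaded with an internal 64-bit LCG so that a given seed yields
// bit-identical vectors on every platform; R's RNG is never touched.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

const int MAX_EXP = 6;
const int EXP_TABLE_SIZE = 1000;

struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed) {}
  uint64_t next() {
    state = state * 25214903917ULL + 11ULL;
    return state;
  }
  // uniform in [0, 1)
  double unif() { return ((next() >> 16) & 0xFFFFULL) / 65536.0; }
};

inline double sigmoid_tab(double f, const std::vector<double>& tab) {
  if (f >= MAX_EXP) return 1.0;
  if (f <= -MAX_EXP) return 0.0;
  int i = (int)((f + MAX_EXP) * (EXP_TABLE_SIZE / (double)MAX_EXP / 2.0));
  if (i < 0) i = 0;
  if (i >= EXP_TABLE_SIZE) i = EXP_TABLE_SIZE - 1;
  return tab[i];
}

} // namespace

// [[Rcpp::export]]
NumericMatrix w2v_train_cpp(List sentences, NumericVector vocab_counts,
                            int dim, int window, int epochs,
                            double lr_start, double lr_end,
                            double sample, int negative,
                            bool cbow, int seed) {
  const int V = vocab_counts.size();
  if (V == 0) stop("empty vocabulary");
  if (dim <= 0 || window <= 0) stop("dim and window must be positive");
  if (epochs < 1) stop("epochs must be >= 1");

  std::vector<double> exp_table(EXP_TABLE_SIZE);
  for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
    double x = std::exp((i / (double)EXP_TABLE_SIZE * 2.0 - 1.0) * MAX_EXP);
    exp_table[i] = x / (x + 1.0);
  }

  // unigram table for negative sampling, counts^0.75
  const int table_size = std::max(100000, 10 * V);
  std::vector<int> uni_table(table_size);
  double norm = 0.0;
  for (int i = 0; i < V; ++i) norm += std::pow(vocab_counts[i], 0.75);
  {
    int i = 0;
    double cum = std::pow(vocab_counts[0], 0.75) / norm;
    for (int a = 0; a < table_size; ++a) {
      uni_table[a] = i;
      if ((a + 1) / (double)table_size > cum && i < V - 1) {
        ++i;
        cum += std::pow(vocab_counts[i], 0.75) / norm;
      }
    }
  }

  double total_words = 0.0;
  for (int i = 0; i < V; ++i) total_words += vocab_counts[i];

  Rng rng((uint64_t)seed);

  // syn0 seeded uniform in (-0.5/dim, 0.5/dim); syn1neg zero
  std::vector<double> syn0((size_t)V * dim), syn1((size_t)V * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  const int n_sent = sentences.size();
  double train_words_total = 0.0;
  std::vector<IntegerVector> sents(n_sent);
  for (int s = 0; s < n_sent; ++s) {
    sents[s] = as<IntegerVector>(sentences[s]);
    train_words_total += sents[s].size();
  }
  train_words_total *= epochs;
  if (train_words_total == 0) stop("corpus has no in-vocabulary tokens");

  std::vector<double> neu1(dim), neu1e(dim);
  std::vector<int> ctx;
  ctx.reserve(2 * window + 1);

  double word_count = 0.0;
  double alpha = lr_start;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      const IntegerVector& sent = sents[s];
      const int len = sent.size();
      // subsample frequent words for this pass over the sentence
      std::vector<int> kept;
      kept.reserve(len);
      for (int i = 0; i < len; ++i) {
        int w = sent[i]; // 0-based
        word_count += 1.0;
        if (sample > 0) {
          double f = vocab_counts[w] / total_words;
          double keep = (std::sqrt(f / sample) + 1.0) * sample / f;
          if (keep < rng.unif()) continue;
        }
        kept.push_back(w);
      }
      alpha = lr_start - (lr_start - lr_end) * (word_count / train_words_total);
      if (alpha < lr_end) alpha = lr_end;

      const int klen = (int)kept.size();
      for (int pos = 0; pos < klen; ++pos) {
        const int word = kept[pos];
        const int b = (int)(rng.next() % (uint64_t)window); // reduced window
        ctx.clear();
        for (int a = b; a < 2 * window + 1 - b; ++a) {
          if (a == window) continue;
          int c = pos - window + a;
          if (c < 0 || c >= klen) continue;
          ctx.push_back(kept[c]);
        }
        if (ctx.empty()) continue;

        if (cbow) {
          const int cw = (int)ctx.size();
          for (int k = 0; k < dim; ++k) neu1[k] = 0.0;
          for (int c : ctx)
            for (int k = 0; k < dim; ++k) neu1[k] += syn0[(size_t)c * dim + k];
          for (int k = 0; k < dim; ++k) neu1[k] /= cw;
          for (int k = 0; k < dim; ++k) neu1e[k] = 0.0;
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) { target = word; label = 1.0; }
            else {
              target = uni_table[rng.next() % (uint64_t)table_size];
              if (target == word) continue;
              label = 0.0;
            }
            double f = 0.0;
            double* row = &syn1[(size_t)target * dim];
            for (int k = 0; k < dim; ++k) f += neu1[k] * row[k];
            double g = (label - sigmoid_tab(f, exp_table)) * alpha;
            for (int k = 0; k < dim; ++k) neu1e[k] += g * row[k];
            for (int k = 0; k < dim; ++k) row[k] += g * neu1[k];
          }
          for (int c : ctx) {
            double* row = &syn0[(size_t)c * dim];
            for (int k = 0; k < dim; ++k) row[k] += neu1e[k];
          }
        } else { // skip-gram
          for (int c : ctx) {
            for (int k = 0; k < dim; ++k) neu1e[k] = 0.0;
            double* in = &syn0[(size_t)c * dim];
            for (int d = 0; d <= negative; ++d) {
              int target;
              double label;
              if (d == 0) { target = word; label = 1.0; }
              else {
                target = uni_table[rng.next() % (uint64_t)table_size];
                if (target == word) continue;
                label = 0.0;
              }
              double f = 0.0;
              double* row = &syn1[(size_t)target * dim];
              for (int k = 0; k < dim; ++k) f += in[k] * row[k];
              double g = (label - sigmoid_tab(f, exp_table)) * alpha;
              for (int k = 0; k < dim; ++k) neu1e[k] += g * row[k];
              for (int k = 0; k < dim; ++k) row[k] += g * in[k];
            }
            for (int k = 0; k < dim; ++k) in[k] += neu1e[k];
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(V, dim);
  for (int i = 0; i < V; ++i)
    for (int k = 0; k < dim; ++k)
      out(i, k) = syn0[(size_t)i * dim + k];
  return out;
}
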