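// Streaming finite-context-model (FCM) mixture core.
//
// A set of order-k Markov models over the 2-bit DNA alphabet shares one
// left-to-right pass: at each position every model emits an alpha-smoothed
// estimate P_k(s|context) from its sparse count table, the mixture combines
// them with performance-tracking weights (exponential forgetting, factor
// gamma), the information content -log2 P(observed) is recorded, weights are
// re-estimated from the probability each model assigned to the observed
// symbol, and only then are the counts updated (the model never sees the
// symbol it is predicting).
//
// Contexts are packed 2 bits/symbol into a uint64 (k <= 31), counts live in a
// hash map keyed by the packed context, so memory scales with the number of
// distinct contexts actually seen, never with 4^k.

#include <Rcpp.h>
#include <array>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

struct Fcm {
  int k;
  double alpha;
  bool frozen;
  uint64_t mask;  // low 2k bits
  std::unordered_map<uint64_t, std::array<uint64_t, 4> > counts;
};

struct FcmSet {
  std::vector<Fcm> models;
};

typedef XPtr<FcmSet> SetPtr;

static FcmSet* get_set(SEXP sp) {
  SetPtr p(sp);
  if (!p) stop("invalid or expired model handle");
  return p.get();
}

// [[Rcpp::export]]
SEXP fcm_set_new(IntegerVector depths, NumericVector alphas) {
  if (depths.size() != alphas.size())
    stop("depths and alphas must have equal length");
  FcmSet* s = new FcmSet();
  s->models.reserve(depths.size());
  for (int i = 0; i < depths.size(); ++i) {
    if (depths[i] < 1 || depths[i] > 31)
      stop("context depth must be in 1..31");
    if (!(alphas[i] > 0)) stop("alpha must be > 0");
    Fcm m;
    m.k = depths[i];
    m.alpha = alphas[i];
    m.frozen = false;
    m.mask = (1ULL << (2 * m.k)) - 1ULL;
    s->models.push_back(m);
  }
  return SetPtr(s, true);
}

// [[Rcpp::export]]
IntegerVector fcm_set_depths(SEXP sp) {
  FcmSet* s = get_set(sp);
  IntegerVector out(s->models.size());
  for (size_t i = 0; i < s->models.size(); ++i) out[i] = s->models[i].k;
  return out;
}

// [[Rcpp::export]]
NumericVector fcm_set_alphas(SEXP sp) {
  FcmSet* s = get_set(sp);
  NumericVector out(s->models.size());
  for (size_t i = 0; i < s->models.size(); ++i) out[i] = s->models[i].alpha;
  return out;
}

// [[Rcpp::export]]
LogicalVector fcm_set_frozen(SEXP sp) {
  FcmSet* s = get_set(sp);
  LogicalVector out(s->models.size());
  for (size_t i = 0; i < s->models.size(); ++i) out[i] = s->models[i].frozen;
  return out;
}

// number of distinct contexts currently stored per model
// [[Rcpp::export]]
NumericVector fcm_set_sizes(SEXP sp) {
  FcmSet* s = get_set(sp);
  NumericVector out(s->models.size());
  for (size_t i = 0; i < s->models.size(); ++i)
    out[i] = (double)s->models[i].counts.size();
  return out;
}

// [[Rcpp::export]]
void fcm_set_freeze(SEXP sp) {
  FcmSet* s = get_set(sp);
  for (size_t i = 0; i < s->models.size(); ++i) s->models[i].frozen = true;
}

static uint64_t pack_context(const Fcm& m, IntegerVector ctx) {
  if ((int)ctx.size() != m.k)
    stop("context length (%d) does not match model order (%d)",
         (int)ctx.size(), m.k);
  uint64_t packed = 0;
  for (int i = 0; i < m.k; ++i) {
    if (ctx[i] < 0 || ctx[i] > 3) stop("context symbols must be codes 0..3");
    packed = (packed << 2) | (uint64_t)ctx[i];
  }
  return packed;
}

// alpha-smoothed estimate for one model / one explicit context (codes 0..3,
// oldest symbol first)
// [[Rcpp::export]]
NumericVector fcm_estimate_ctx(SEXP sp, int idx, IntegerVector ctx) {
  FcmSet* s = get_set(sp);
  if (idx < 0 || idx >= (int)s->models.size()) stop("model index out of range");
  const Fcm& m = s->models[idx];
  uint64_t packed = pack_context(m, ctx);
  NumericVector p(4);
  std::unordered_map<uint64_t, std::array<uint64_t, 4> >::const_iterator it =
      m.counts.find(packed);
  if (it == m.counts.end()) {
    p[0] = p[1] = p[2] = p[3] = 0.25;
  } else {
    const std::array<uint64_t, 4>& c = it->second;
    double tot = (double)(c[0] + c[1] + c[2] + c[3]);
    double denom = tot + 4.0 * m.alpha;
    for (int sy = 0; sy < 4; ++sy) p[sy] = ((double)c[sy] + m.alpha) / denom;
  }
  return p;
}

// raw counts for one model / one context (for inspection and tests)
// [[Rcpp::export]]
NumericVector fcm_counts_ctx(SEXP sp, int idx, IntegerVector ctx) {
  FcmSet* s = get_set(sp);
  if (idx < 0 || idx >= (int)s->models.size()) stop("model index out of range");
  const Fcm& m = s->models[idx];
  uint64_t packed = pack_context(m, ctx);
  NumericVector out(4);
  std::unordered_map<uint64_t, std::array<uint64_t, 4> >::const_iterator it =
      m.counts.find(packed);
  if (it != m.counts.end())
    for (int sy = 0; sy < 4; ++sy) out[sy] = (double)it->second[sy];
  return out;
}

// [[Rcpp::export]]
void fcm_update_ctx(SEXP sp, int idx, IntegerVector ctx, int symbol) {
  FcmSet* s = get_set(sp);
  if (idx < 0 || idx >= (int)s->models.size()) stop("model index out of range");
  Fcm& m = s->models[idx];
  if (symbol < 0 || symbol > 3) stop("symbol must be a code 0..3");
  if (m.frozen) return;  // frozen models ignore updates
  uint64_t packed = pack_context(m, ctx);
  m.counts[packed][symbol] += 1;  // operator[] zero-initializes new entries
}

// One full streaming pass of the mixture over an encoded sequence.
// codes: 0..3 for A,C,G,T; any negative value is a masked (non-ACGT)
// position: it gets NA information and resets the context register.
// learn = false leaves all count tables untouched (conditional profiling).
// Returns per-position information (bits), each model's running average
// information content (Eq.-3-style accounting over valid positions), the
// final mixture weights and the number of valid positions.
// [[Rcpp::export]]
List ip_pass(SEXP sp, IntegerVector codes, double gamma, bool learn) {
  FcmSet* s = get_set(sp);
  if (!(gamma > 0.0 && gamma <= 1.0)) stop("gamma must be in (0, 1]");
  int K = (int)s->models.size();
  if (K == 0) stop("model set is empty");
  R_xlen_t L = codes.size();
  NumericVector info(L);
  std::vector<double> w(K, 1.0 / K), p(K), hsum(K, 0.0);
  uint64_t reg = 0;
  long long run = 0;  // valid symbols since last mask/reset
  double nvalid = 0;
  for (R_xlen_t i = 0; i < L; ++i) {
    int c = codes[i];
    if (c < 0 || c == NA_INTEGER) {
      info[i] = NA_REAL;
      reg = 0;
      run = 0;
      continue;
    }
    double mixed = 0.0;
    for (int m = 0; m < K; ++m) {
      Fcm& M = s->models[m];
      double pm = 0.25;  // warm-up and never-seen contexts are uniform
      if (run >= M.k) {
        std::unordered_map<uint64_t, std::array<uint64_t, 4> >::const_iterator
            it = M.counts.find(reg & M.mask);
        if (it != M.counts.end()) {
          const std::array<uint64_t, 4>& cc = it->second;
          double tot = (double)(cc[0] + cc[1] + cc[2] + cc[3]);
          pm = ((double)cc[c] + M.alpha) / (tot + 4.0 * M.alpha);
        }
      }
      p[m] = pm;
      mixed += w[m] * pm;
      hsum[m] -= std::log2(pm);
    }
    info[i] = -std::log2(mixed);
    double wsum = 0.0;
    for (int m = 0; m < K; ++m) {
      w[m] = std::pow(w[m], gamma) * p[m];
      wsum += w[m];
    }
    for (int m = 0; m < K; ++m) w[m] /= wsum;
    if (learn) {
      for (int m = 0; m < K; ++m) {
        Fcm& M = s->models[m];
        if (!M.frozen && run >= M.k) M.counts[reg & M.mask][c] += 1;
      }
    }
    reg = (reg << 2) | (uint64_t)c;
    ++run;
    ++nvalid;
  }
  NumericVector h(K);
  for (int m = 0; m < K; ++m)
    h[m] = nvalid > 0 ? hsum[m] / nvalid : NA_REAL;
  return List::create(_["info"] = info, _["model_avg_info"] = h,
                      _["final_weights"] = NumericVector(w.begin(), w.end()),
                      _["n_valid"] = nvalid);
}

// Counts-only training pass (no mixture bookkeeping); same masking and
// warm-up rules as ip_pass.
// [[Rcpp::export]]
void fcm_set_train(SEXP sp, IntegerVector codes) {
  FcmSet* s = get_set(sp);
  int K = (int)s->models.size();
  R_xlen_t L = codes.size();
  uint64_t reg = 0;
  long long run = 0;
  for (R_xlen_t i = 0; i < L; ++i) {
    int c = codes[i];
    if (c < 0 || c == NA_INTEGER) {
      reg = 0;
      run = 0;
      continue;
    }
    for (int m = 0; m < K; ++m) {
      Fcm& M = s->models[m];
      if (!M.frozen && run >= M.k) M.counts[reg & M.mask][c] += 1;
    }
    reg = (reg << 2) | (uint64_t)c;
    ++run;
  }
}

// Lossless export of the count tables. Context keys are returned as doubles
// (exact for k <= 16: 4^16 < 2^53) sorted ascending so the dump is
// deterministic regardless of hash-map iteration order.
// [[Rcpp::export]]
List fcm_set_dump(SEXP sp) {
  FcmSet* s = get_set(sp);
  List out(s->models.size());
  for (size_t i = 0; i < s->models.size(); ++i) {
    const Fcm& m = s->models[i];
    std::vector<uint64_t> keys;
    keys.reserve(m.counts.size());
    for (std::unordered_map<uint64_t, std::array<uint64_t, 4> >::const_iterator
             it = m.counts.begin();
         it != m.counts.end(); ++it)
      keys.push_back(it->first);
    std::sort(keys.begin(), keys.end());
    NumericVector kk(keys.size());
    NumericMatrix cc(keys.size(), 4);
    for (size_t j = 0; j < keys.size(); ++j) {
      kk[j] = (double)keys[j];
      const std::array<uint64_t, 4>& v = m.counts.at(keys[j]);
      for (int sy = 0; sy < 4; ++sy) cc(j, sy) = (double)v[sy];
    }
    out[i] = List::create(_["order"] = m.k, _["alpha"] = m.alpha,
                          _["frozen"] = m.frozen, _["contexts"] = kk,
                          _["counts"] = cc);
  }
  return out;
}

// [[Rcpp::export]]
SEXP fcm_set_restore(List models) {
  FcmSet* s = new FcmSet();
  s->models.reserve(models.size());
  for (int i = 0; i < models.size(); ++i) {
    List mi = models[i];
    Fcm m;
    m.k = as<int>(mi["order"]);
    m.alpha = as<double>(mi["alpha"]);
    m.frozen = as<bool>(mi["frozen"]);
    if (m.k < 1 || m.k > 31) stop("context depth must be in 1..31");
    m.mask = (1ULL << (2 * m.k)) - 1ULL;
    NumericVector kk = mi["contexts"];
    NumericMatrix cc = mi["counts"];
    if (kk.size() != cc.nrow()) stop("corrupt model container");
    for (int j = 0; j < kk.size(); ++j) {
      std::array<uint64_t, 4> v;
      for (int sy = 0; sy < 4; ++sy) v[sy] = (uint64_t)cc(j, sy);
      m.counts[(uint64_t)kk[j]] = v;
    }
    s->models.push_back(m);
  }
  return SetPtr(s, true);
}
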