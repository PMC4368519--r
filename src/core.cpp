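// Computational kernels: the sampling-formula coefficient arrays K(D, A)
// (log-space convolution of unsigned-Stirling-number polynomials), the
// two-stage urn sampler for the standard neutral model, and the inner loop
// of the sequential (Moran-type) HL community simulator.
//
// All randomness uses R's RNG so results are reproducible via set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// log(exp(x) + exp(y)) without overflow; terms are all non-negative in the
// convolutions below so there is no cancellation.
static inline double logadd(double x, double y) {
  if (x == R_NegInf) return y;
  if (y == R_NegInf) return x;
  if (x < y) std::swap(x, y);
  return x + log1p(std::exp(y - x));
}

// ---------------------------------------------------------------------------
// Unsigned Stirling numbers of the first kind, in log space.
//
// Row n holds log s(n, a) for a = 1..n (index a-1); these are the
// coefficients of the rising factorial x(x+1)...(x+n-1).  Rows are built by
// incremental polynomial multiplication and cached across calls, because the
// bootstrap test evaluates thousands of samples whose abundances repeat.
// ---------------------------------------------------------------------------

static std::map<int, std::vector<double>> srow_cache;
static size_t srow_cache_bytes = 0;

static const std::vector<double>& stirling_row(int n) {
  auto hit = srow_cache.find(n);
  if (hit != srow_cache.end()) return hit->second;

  if (srow_cache_bytes > (size_t)2e8) {  // crude cap; correctness unaffected
    srow_cache.clear();
    srow_cache_bytes = 0;
  }

  // start from the largest cached row not exceeding n
  std::vector<double> row{0.0};  // s(1,1) = 1
  int n0 = 1;
  auto lb = srow_cache.lower_bound(n);
  if (lb != srow_cache.begin()) {
    --lb;
    row = lb->second;
    n0 = lb->first;
  }

  // multiply by (x + k): s(k+1, a) = s(k, a-1) + k * s(k, a).  Checkpoint
  // intermediate rows so later requests for nearby n extend incrementally
  // instead of rebuilding from a distant base.
  for (int k = n0; k < n; ++k) {
    std::vector<double> nr(k + 1);
    double lk = std::log((double)k);
    nr[0] = lk + row[0];
    for (int i = 1; i < k; ++i) nr[i] = logadd(row[i - 1], lk + row[i]);
    nr[k] = row[k - 1];
    row.swap(nr);
    int kn = k + 1;
    if (kn < n && kn % 64 == 0 && srow_cache.find(kn) == srow_cache.end()) {
      srow_cache_bytes += sizeof(double) * row.size();
      srow_cache.emplace(kn, row);
    }
  }

  srow_cache_bytes += sizeof(double) * row.size();
  auto res = srow_cache.emplace(n, std::move(row));
  return res.first->second;
}

// [[Rcpp::export(name = ".stirling_row_cpp")]]
NumericVector stirling_row_cpp(int n) {
  const std::vector<double>& r = stirling_row(n);
  return NumericVector(r.begin(), r.end());
}

// ---------------------------------------------------------------------------
// log K(D, A) for A = S..J.
//
// K(D, A) = sum over {a_i} with sum a_i = A, 1 <= a_i <= n_i of
//           prod_i s(n_i, a_i) (a_i - 1)! / (n_i - 1)!
// computed as the convolution of the per-species coefficient arrays
// k_i(a) = s(n_i, a) * Gamma(a) / Gamma(n_i), held entirely in logs.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".logkda_cpp")]]
NumericVector logkda_cpp(IntegerVector counts) {
  std::vector<int> ns(counts.begin(), counts.end());
  if (ns.empty()) stop("empty abundance vector");
  for (int n : ns)
    if (n < 1) stop("abundances must be positive integers");
  std::sort(ns.begin(), ns.end());  // small species first keeps the
                                    // accumulator short for skewed samples
  std::vector<double> acc;
  for (size_t s = 0; s < ns.size(); ++s) {
    int n = ns[s];
    const std::vector<double>& srow = stirling_row(n);
    std::vector<double> kv(n);
    double lgn = lgamma((double)n);
    for (int a = 1; a <= n; ++a) kv[a - 1] = srow[a - 1] + lgamma((double)a) - lgn;
    if (s == 0) {
      acc = kv;
    } else if (n == 1) {
      // a singleton contributes k(1) = 1: pure index shift, no work
      continue;
    } else {
      // two-pass log-space convolution: a max-plus pass fixes the scale of
      // every output coefficient, then terms within 45 nats of that scale
      // are accumulated in linear space (the rest are below double
      // precision relative to the output)
      size_t len = acc.size() + n - 1;
      std::vector<double> mx(len, R_NegInf);
      for (size_t i = 0; i < acc.size(); ++i) {
        double ai = acc[i];
        for (int a = 0; a < n; ++a) {
          double v = ai + kv[a];
          if (v > mx[i + a]) mx[i + a] = v;
        }
      }
      std::vector<double> sm(len, 0.0);
      for (size_t i = 0; i < acc.size(); ++i) {
        double ai = acc[i];
        for (int a = 0; a < n; ++a) {
          double v = ai + kv[a] - mx[i + a];
          if (v > -45.0) sm[i + a] += std::exp(v);
        }
      }
      std::vector<double> nw(len);
      for (size_t j = 0; j < len; ++j)
        nw[j] = (mx[j] == R_NegInf) ? R_NegInf : mx[j] + std::log(sm[j]);
      acc.swap(nw);
    }
  }
  return NumericVector(acc.begin(), acc.end());  // index i <-> A = S + i
}

// ---------------------------------------------------------------------------
// Urn sampler for the standard neutral model.
//
// Individual j (1-based) founds a new immigrant ancestor with probability
// I/(I + j - 1), otherwise copies the species of a uniformly chosen earlier
// individual; the a-th ancestor founds a new species with probability
// theta/(theta + a - 1), otherwise takes the species of a uniformly chosen
// earlier ancestor.  Returns per-species counts (labels are arbitrary).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".urn_cpp")]]
IntegerVector urn_cpp(double theta, double I, int J) {
  if (J < 1) stop("J must be >= 1");
  if (theta <= 0 || I <= 0) stop("theta and I must be positive");
  std::vector<int> anc_of_ind;
  anc_of_ind.reserve(J);
  std::vector<int> sp_of_anc;
  std::vector<int> sp_of_ind(J);
  int n_sp = 0;
  for (int j = 0; j < J; ++j) {
    int anc;
    if (unif_rand() * (I + j) < I) {
      int a = (int)sp_of_anc.size();
      int sp;
      if (unif_rand() * (theta + a) < theta) {
        sp = n_sp++;
      } else {
        int idx = (int)(unif_rand() * a);
        if (idx >= a) idx = a - 1;
        sp = sp_of_anc[idx];
      }
      sp_of_anc.push_back(sp);
      anc = a;
    } else {
      int idx = (int)(unif_rand() * j);
      if (idx >= j) idx = j - 1;
      anc = anc_of_ind[idx];
    }
    anc_of_ind.push_back(anc);
    sp_of_ind[j] = sp_of_anc[anc];
  }
  IntegerVector out(n_sp);
  for (int j = 0; j < J; ++j) out[sp_of_ind[j]]++;
  return out;
}

// ---------------------------------------------------------------------------
// Sequential HL dynamics: J elemental death-recruitment updates per
// generation.  Death weights w_i = ((1-gamma) + gamma n_i/J) * n_i/J; the
// recruit is an immigrant with probability m (species drawn from the
// metacommunity, or a fresh label if the metacommunity is infinite), else a
// copy of a uniformly chosen survivor (post-death abundances).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".hl_run_cpp")]]
List hl_run_cpp(IntegerVector labels0, IntegerVector counts0, NumericVector Pcum,
                double gamma, double m, int J, int ngen, bool infinite_meta,
                int next_label) {
  int S0 = labels0.size();
  std::vector<int> lab(labels0.begin(), labels0.end());
  std::vector<int> cnt(counts0.begin(), counts0.end());
  std::unordered_map<int, int> idx_of;
  idx_of.reserve(2 * S0 + 16);
  for (int i = 0; i < S0; ++i) idx_of[lab[i]] = i;

  int ST = Pcum.size();
  NumericVector Straj(ngen), Htraj(ngen);

  for (int g = 0; g < ngen; ++g) {
    for (int e = 0; e < J; ++e) {
      // death
      int S = (int)cnt.size();
      double tot = 0.0;
      for (int i = 0; i < S; ++i) {
        double f = (double)cnt[i] / J;
        tot += ((1.0 - gamma) + gamma * f) * cnt[i];
      }
      double u = unif_rand() * tot;
      int d = S - 1;
      double run = 0.0;
      for (int i = 0; i < S; ++i) {
        double f = (double)cnt[i] / J;
        run += ((1.0 - gamma) + gamma * f) * cnt[i];
        if (u < run) { d = i; break; }
      }
      cnt[d]--;

      // recruitment
      int rec_idx;
      if (unif_rand() < m) {
        int lb;
        if (infinite_meta) {
          lb = next_label++;
        } else {
          double v = unif_rand();
          int lo = 0, hi = ST - 1;
          while (lo < hi) {  // first index with Pcum >= v
            int mid = (lo + hi) / 2;
            if (Pcum[mid] < v) lo = mid + 1; else hi = mid;
          }
          lb = lo + 1;
        }
        auto it = idx_of.find(lb);
        if (it == idx_of.end()) {
          lab.push_back(lb);
          cnt.push_back(0);
          rec_idx = (int)cnt.size() - 1;
          idx_of[lb] = rec_idx;
        } else {
          rec_idx = it->second;
        }
      } else {
        // uniform among the J-1 surviving individuals
        double v = unif_rand() * (J - 1);
        double racc = 0.0;
        rec_idx = (int)cnt.size() - 1;
        for (size_t i = 0; i < cnt.size(); ++i) {
          racc += cnt[i];
          if (v < racc) { rec_idx = (int)i; break; }
        }
      }
      cnt[rec_idx]++;

      // prune the dead species if it went extinct
      if (cnt[d] == 0) {
        int last = (int)cnt.size() - 1;
        idx_of.erase(lab[d]);
        if (d != last) {
          lab[d] = lab[last];
          cnt[d] = cnt[last];
          idx_of[lab[d]] = d;
        }
        lab.pop_back();
        cnt.pop_back();
      }
    }
    // per-generation richness and Shannon index
    double H = 0.0;
    for (size_t i = 0; i < cnt.size(); ++i) {
      double p = (double)cnt[i] / J;
      H -= p * std::log(p);
    }
    Straj[g] = (double)cnt.size();
    Htraj[g] = H;
  }

  return List::create(_["labels"] = IntegerVector(lab.begin(), lab.end()),
                      _["counts"] = IntegerVector(cnt.begin(), cnt.end()),
                      _["S"] = Straj, _["H"] = Htraj,
                      _["next_label"] = next_label);
}
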