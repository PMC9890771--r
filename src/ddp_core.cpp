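// Core numerics for double digest map reconstruction, shared by the
// plaintext model and the ciphertext (order-preserving homomorphic index)
// pipeline, plus the quantum-inspired genetic algorithm search loop.
//
// Ciphertexts are n-component real vectors c with c[j] = k[j]*m + r[j]
// (j < n-1) and c[n-1] = k[n-1]*sum(r). All ciphertext arithmetic here is
// componentwise addition/subtraction; order comparison inspects only the
// first n-1 components and declares x < y iff every component is strictly
// smaller. Under the noise budget enforced at encryption time this rule
// decides every pair of distinct plaintexts correctly; equal plaintexts
// compare by noise (either a dominated verdict or a mixed one), which is
// outcome-neutral for the multiset operations performed here.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// ---------------------------------------------------------------------------
// Plaintext double digest model
// ---------------------------------------------------------------------------

// Implied simultaneous-digest spectrum for arrangement (mu, nu), ascending.
// mu, nu are 0-based. Returns all p+q step differences sorted ascending in
// `diffs`; the caller drops the (p+q-t) smallest.
void plain_diffs(const std::vector<double>& A, const std::vector<double>& B,
                 const int* mu, const int* nu, std::vector<double>& sites,
                 std::vector<double>& diffs) {
  const int p = (int)A.size(), q = (int)B.size();
  sites.resize(p + q);
  double acc = 0.0;
  for (int i = 0; i < p; ++i) { acc += A[mu[i]]; sites[i] = acc; }
  acc = 0.0;
  for (int i = 0; i < q; ++i) { acc += B[nu[i]]; sites[p + i] = acc; }
  std::sort(sites.begin(), sites.end());
  diffs.resize(p + q);
  double prev = 0.0;
  for (int i = 0; i < p + q; ++i) { diffs[i] = sites[i] - prev; prev = sites[i]; }
  std::sort(diffs.begin(), diffs.end());
}

// L1 distance between the implied spectrum and the observed multiset C.
double plain_distance(const std::vector<double>& A, const std::vector<double>& B,
                      const std::vector<double>& C,
                      const int* mu, const int* nu,
                      std::vector<double>& sites, std::vector<double>& diffs) {
  const int p = (int)A.size(), q = (int)B.size(), t = (int)C.size();
  plain_diffs(A, B, mu, nu, sites, diffs);
  const int k = p + q - t;  // zero-length artifacts to discard
  double D = 0.0;
  for (int i = 0; i < t; ++i) D += std::fabs(diffs[k + i] - C[i]);
  return D;
}

// ---------------------------------------------------------------------------
// Ciphertext-domain model (row-major t x n matrices of sub-ciphertexts)
// ---------------------------------------------------------------------------

struct CtMat {
  std::vector<double> v;  // row-major
  int rows, n;
  explicit CtMat(const NumericMatrix& m) : rows(m.nrow()), n(m.ncol()) {
    v.resize((size_t)rows * n);
    for (int i = 0; i < rows; ++i)
      for (int j = 0; j < n; ++j) v[(size_t)i * n + j] = m(i, j);
  }
  const double* row(int i) const { return &v[(size_t)i * n]; }
};

// all-components-strictly-less comparison on the first n-1 coordinates
inline bool ct_less(const double* a, const double* b, int n) {
  for (int j = 0; j < n - 1; ++j)
    if (a[j] >= b[j]) return false;
  return true;
}

// Sort key for ciphertext lists: the first sub-ciphertext alone. Within
// the noise budget it agrees with the all-coordinates comparison on every
// pair of distinct plaintexts; equal plaintexts (where the full rule can
// return either a noise-dominated verdict or a mixed one) get a
// deterministic noise-decided order, which is outcome-neutral for the
// multiset operations downstream. Unlike the ternary rule this is a
// strict weak ordering, as std::stable_sort requires.
inline bool ct_key_less(const double* a, const double* b) {
  return a[0] < b[0];
}

// Encrypted step differences for arrangement (mu, nu), ascending, with the
// (p+q-t) smallest (the zero-length artifacts, noise-sized) dropped.
// Output: t x n row-major in `out`.
void enc_spectrum(const CtMat& Ac, const CtMat& Bc, int t,
                  const int* mu, const int* nu,
                  std::vector<double>& sites, std::vector<double>& diffs,
                  std::vector<const double*>& ptrs, std::vector<double>& out) {
  const int p = Ac.rows, q = Bc.rows, n = Ac.n, s = p + q;
  sites.assign((size_t)s * n, 0.0);
  // running homomorphic sums = encrypted cut-site coordinates
  for (int i = 0; i < p; ++i) {
    const double* a = Ac.row(mu[i]);
    double* dst = &sites[(size_t)i * n];
    const double* prev = (i == 0) ? nullptr : &sites[(size_t)(i - 1) * n];
    for (int j = 0; j < n; ++j) dst[j] = (prev ? prev[j] : 0.0) + a[j];
  }
  for (int i = 0; i < q; ++i) {
    const double* b = Bc.row(nu[i]);
    double* dst = &sites[(size_t)(p + i) * n];
    const double* prev = (i == 0) ? nullptr : &sites[(size_t)(p + i - 1) * n];
    for (int j = 0; j < n; ++j) dst[j] = (prev ? prev[j] : 0.0) + b[j];
  }
  // merge the two site lists: stable sort keeps enzyme-alpha-derived sites
  // ahead of enzyme-beta-derived ones at indistinguishable positions
  ptrs.resize(s);
  for (int i = 0; i < s; ++i) ptrs[i] = &sites[(size_t)i * n];
  std::stable_sort(ptrs.begin(), ptrs.end(), ct_key_less);
  // step differences (homomorphic subtraction), leading site minus zero
  diffs.assign((size_t)s * n, 0.0);
  const double* prev = nullptr;
  for (int i = 0; i < s; ++i) {
    double* dst = &diffs[(size_t)i * n];
    for (int j = 0; j < n; ++j) dst[j] = ptrs[i][j] - (prev ? prev[j] : 0.0);
    prev = ptrs[i];
  }
  ptrs.resize(s);
  for (int i = 0; i < s; ++i) ptrs[i] = &diffs[(size_t)i * n];
  std::stable_sort(ptrs.begin(), ptrs.end(), ct_key_less);
  const int k = s - t;
  out.resize((size_t)t * n);
  for (int i = 0; i < t; ++i)
    for (int j = 0; j < n; ++j) out[(size_t)i * n + j] = ptrs[k + i][j];
}

// Ciphertext-domain residual: summed componentwise absolute differences
// (first n-1 coordinates) between the implied encrypted spectrum and C_c.
double enc_residual(const CtMat& Ac, const CtMat& Bc, const CtMat& Cc,
                    const int* mu, const int* nu,
                    std::vector<double>& sites, std::vector<double>& diffs,
                    std::vector<const double*>& ptrs, std::vector<double>& out) {
  const int t = Cc.rows, n = Cc.n;
  enc_spectrum(Ac, Bc, t, mu, nu, sites, diffs, ptrs, out);
  double r = 0.0;
  for (int i = 0; i < t; ++i) {
    const double* d = &out[(size_t)i * n];
    const double* c = Cc.row(i);
    for (int j = 0; j < n - 1; ++j) r += std::fabs(d[j] - c[j]);
  }
  return r;
}

std::vector<double> as_vec(const NumericVector& x) {
  return std::vector<double>(x.begin(), x.end());
}

std::vector<int> perm0(const IntegerVector& x) {
  std::vector<int> v(x.size());
  for (int i = 0; i < x.size(); ++i) v[i] = x[i] - 1;
  return v;
}

// ---------------------------------------------------------------------------
// Quantum-inspired genetic algorithm
// ---------------------------------------------------------------------------

// Chromosomes hold one rotation angle theta per qubit; amplitudes are
// (alpha, beta) = (cos theta, sin theta), so measuring 1 has probability
// sin^2(theta) and the quantum NOT (mutation) is theta -> pi/2 - theta.

struct Evaluator {
  // plaintext mode
  const std::vector<double>*A = nullptr, *B = nullptr, *C = nullptr;
  // ciphertext mode
  const CtMat *Ac = nullptr, *Bc = nullptr, *Cc = nullptr;
  bool encrypted = false;
  double tie = 0.0;   // values within `tie` are the same fitness class
  double zero = 0.0;  // values <= zero mean an exact solution
  // scratch
  mutable std::vector<double> sites, diffs, out;
  mutable std::vector<const double*> ptrs;

  double value(const int* mu, const int* nu) const {
    if (encrypted) return enc_residual(*Ac, *Bc, *Cc, mu, nu, sites, diffs, ptrs, out);
    return plain_distance(*A, *B, *C, mu, nu, sites, diffs);
  }
  bool better(double a, double b) const { return a < b - tie; }
  bool solved(double a) const { return a <= zero; }
};

inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct Qiga {
  int p, q, b, L, nq;  // L = positions (p+q), nq = total qubits
  int N, gmax;
  double pc, pm, dtheta, thetaLo, thetaHi;
  int restartAfter;  // reinitialise non-elite amplitudes after this many
                     // generations without improvement (0 = never)
  const Evaluator* ev;

  std::vector<std::vector<double> > pop;   // theta per qubit
  std::vector<std::vector<int> > bits;     // last measurement
  std::vector<double> vals;                // last residual/distance
  std::vector<std::vector<int> > mus, nus;

  // all-time best record (monotone; the solver's answer)
  double bestVal;
  std::vector<int> bestMu, bestNu;
  // epoch attractor: best measurement since the last stagnation reset;
  // the rotation gate pulls the population toward these bit values
  double epochVal;
  std::vector<int> epochBits;
  std::vector<double> epochChrom;

  std::vector<int> keyIdx;

  void decode(const std::vector<int>& bt, std::vector<int>& mu, std::vector<int>& nu) {
    // random-key decoding: each position's b-bit string is its sort key;
    // ranks give the permutation, ties broken by position index
    static thread_local std::vector<int> keys;
    keys.resize(L);
    for (int pos = 0; pos < L; ++pos) {
      int g = 0;
      for (int j = 0; j < b; ++j) g = (g << 1) | bt[pos * b + j];
      // reflected Gray decoding: adjacent key values differ by one bit,
      // so a single quantum NOT can shift a fragment by one rank
      int k = g;
      for (int sh = 1; sh < b; sh <<= 1) k ^= k >> sh;
      keys[pos] = k;
    }
    mu.resize(p); nu.resize(q);
    keyIdx.resize(std::max(p, q));
    for (int i = 0; i < p; ++i) keyIdx[i] = i;
    std::stable_sort(keyIdx.begin(), keyIdx.begin() + p,
                     [&](int a, int c) { return keys[a] < keys[c]; });
    for (int i = 0; i < p; ++i) mu[i] = keyIdx[i];
    for (int i = 0; i < q; ++i) keyIdx[i] = i;
    std::stable_sort(keyIdx.begin(), keyIdx.begin() + q,
                     [&](int a, int c) { return keys[p + a] < keys[p + c]; });
    for (int i = 0; i < q; ++i) nu[i] = keyIdx[i];
  }

  void measure(int i) {
    std::vector<int>& bt = bits[i];
    bt.resize(nq);
    const std::vector<double>& th = pop[i];
    for (int j = 0; j < nq; ++j) {
      double s = std::sin(th[j]);
      bt[j] = (unif_rand() < s * s) ? 1 : 0;
    }
    decode(bt, mus[i], nus[i]);
    vals[i] = ev->value(mus[i].data(), nus[i].data());
  }

  List run() {
    const double piq = M_PI / 4.0;
    pop.assign(N, std::vector<double>(nq, piq));
    bits.assign(N, std::vector<int>());
    vals.assign(N, 0.0);
    mus.assign(N, std::vector<int>()); nus.assign(N, std::vector<int>());
    bestVal = R_PosInf;
    epochVal = R_PosInf;
    std::vector<double> trace;
    trace.reserve(256);
    int gen = 0, sinceImprove = 0;
    std::vector<int> shuffled(N - 1);

    for (gen = 1; gen <= gmax; ++gen) {
      bool improved = false;
      int solvedAt = -1;
      for (int i = 0; i < N; ++i) {
        measure(i);
        if (ev->better(vals[i], epochVal)) {
          epochVal = vals[i]; epochBits = bits[i]; epochChrom = pop[i];
          improved = true;
        }
        if (ev->better(vals[i], bestVal)) {
          bestVal = vals[i]; bestMu = mus[i]; bestNu = nus[i];
          if (ev->solved(bestVal)) { solvedAt = i; break; }
        }
      }
      trace.push_back(bestVal);
      if (solvedAt >= 0) break;
      sinceImprove = improved ? 0 : sinceImprove + 1;
      if (gen == gmax) break;

      if (restartAfter > 0 && sinceImprove >= restartAfter) {
        // stagnation catastrophe: collapse the whole population back to
        // uniform superposition and forget the epoch attractor, so the next
        // epoch converges into a fresh basin; the all-time record survives
        for (int s = 0; s < N; ++s) pop[s].assign(nq, piq);
        epochVal = R_PosInf;
        sinceImprove = 0;
        continue;
      }

      // selection: elitism (slot 0 holds the chromosome that produced the
      // epoch-best measurement) + binary tournament on current fitness
      std::vector<std::vector<double> > next(N);
      next[0] = epochChrom;
      for (int s = 1; s < N; ++s) {
        int a = rand_int(N), c = rand_int(N);
        next[s] = pop[ev->better(vals[c], vals[a]) ? c : a];
      }

      // quantum rotation toward the attractor measurement's bit values
      for (int s = 1; s < N; ++s) {
        std::vector<double>& th = next[s];
        for (int j = 0; j < nq; ++j) {
          double v = th[j] + (epochBits[j] ? dtheta : -dtheta);
          th[j] = std::min(thetaHi, std::max(thetaLo, v));
        }
      }

      // quantum crossover: random pairing, single-point suffix exchange
      for (int s = 0; s < N - 1; ++s) shuffled[s] = s + 1;
      for (int s = N - 2; s > 0; --s) std::swap(shuffled[s], shuffled[rand_int(s + 1)]);
      for (int s = 0; s + 1 < N - 1; s += 2) {
        if (unif_rand() < pc) {
          int point = rand_int(nq);
          std::vector<double>&x = next[shuffled[s]], &y = next[shuffled[s + 1]];
          for (int j = point; j < nq; ++j) std::swap(x[j], y[j]);
        }
      }

      // quantum mutation: single-qubit NOT
      for (int s = 1; s < N; ++s) {
        if (unif_rand() < pm) {
          int j = rand_int(nq);
          next[s][j] = M_PI / 2.0 - next[s][j];
        }
      }
      pop.swap(next);
    }
    if (gen > gmax) gen = gmax;

    IntegerVector mu1(p), nu1(q);
    for (int i = 0; i < p; ++i) mu1[i] = bestMu[i] + 1;
    for (int i = 0; i < q; ++i) nu1[i] = bestNu[i] + 1;
    return List::create(
      _["mu"] = mu1, _["nu"] = nu1, _["value"] = bestVal,
      _["solved"] = ev->solved(bestVal), _["generations"] = gen,
      _["trace"] = NumericVector(trace.begin(), trace.end()));
  }
};

List run_qiga(const Evaluator& ev, int p, int q, int N, int gmax, double pc,
              double pm, double dtheta, double clampLo, double clampHi,
              int restartAfter) {
  Qiga ga;
  ga.p = p; ga.q = q;
  int m = std::max(p, q), b = 3;
  while ((1 << (b - 3)) < m) ++b;  // b = ceil(log2(max(p,q))) + 3
  ga.b = b; ga.L = p + q; ga.nq = ga.L * b;
  ga.N = N; ga.gmax = gmax; ga.pc = pc; ga.pm = pm; ga.dtheta = dtheta;
  ga.thetaLo = std::asin(std::sqrt(clampLo));
  ga.thetaHi = std::asin(std::sqrt(clampHi));
  ga.restartAfter = restartAfter;
  ga.ev = &ev;
  return ga.run();
}

}  // namespace

// ---------------------------------------------------------------------------
// Exports
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_plain_spectrum(NumericVector A, NumericVector B, int t,
                                 IntegerVector mu, IntegerVector nu) {
  std::vector<double> a = as_vec(A), b = as_vec(B), sites, diffs;
  std::vector<int> m0 = perm0(mu), n0 = perm0(nu);
  plain_diffs(a, b, m0.data(), n0.data(), sites, diffs);
  const int k = (int)(a.size() + b.size()) - t;
  if (k < 0) stop("t exceeds the number of step differences");
  return NumericVector(diffs.begin() + k, diffs.end());
}

// [[Rcpp::export]]
double cpp_plain_distance(NumericVector A, NumericVector B, NumericVector C,
                          IntegerVector mu, IntegerVector nu) {
  std::vector<double> a = as_vec(A), b = as_vec(B), c = as_vec(C), sites, diffs;
  std::vector<int> m0 = perm0(mu), n0 = perm0(nu);
  return plain_distance(a, b, c, m0.data(), n0.data(), sites, diffs);
}

// [[Rcpp::export]]
NumericMatrix cpp_pairwise_distance(NumericVector A, NumericVector B,
                                    NumericVector C, IntegerMatrix mus,
                                    IntegerMatrix nus) {
  std::vector<double> a = as_vec(A), b = as_vec(B), c = as_vec(C), sites, diffs;
  NumericMatrix out(mus.nrow(), nus.nrow());
  std::vector<int> m0(mus.ncol()), n0(nus.ncol());
  for (int i = 0; i < mus.nrow(); ++i) {
    for (int j = 0; j < mus.ncol(); ++j) m0[j] = mus(i, j) - 1;
    for (int l = 0; l < nus.nrow(); ++l) {
      for (int j = 0; j < nus.ncol(); ++j) n0[j] = nus(l, j) - 1;
      out(i, l) = plain_distance(a, b, c, m0.data(), n0.data(), sites, diffs);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_encrypted_spectrum(NumericMatrix Ac, NumericMatrix Bc, int t,
                                     IntegerVector mu, IntegerVector nu) {
  CtMat a(Ac), b(Bc);
  std::vector<double> sites, diffs, out;
  std::vector<const double*> ptrs;
  std::vector<int> m0 = perm0(mu), n0 = perm0(nu);
  if (a.rows + b.rows - t < 0) stop("t exceeds the number of step differences");
  enc_spectrum(a, b, t, m0.data(), n0.data(), sites, diffs, ptrs, out);
  NumericMatrix res(t, a.n);
  for (int i = 0; i < t; ++i)
    for (int j = 0; j < a.n; ++j) res(i, j) = out[(size_t)i * a.n + j];
  return res;
}

// [[Rcpp::export]]
double cpp_encrypted_residual(NumericMatrix Ac, NumericMatrix Bc,
                              NumericMatrix Cc, IntegerVector mu,
                              IntegerVector nu) {
  CtMat a(Ac), b(Bc), c(Cc);
  std::vector<double> sites, diffs, out;
  std::vector<const double*> ptrs;
  std::vector<int> m0 = perm0(mu), n0 = perm0(nu);
  return enc_residual(a, b, c, m0.data(), n0.data(), sites, diffs, ptrs, out);
}

// [[Rcpp::export]]
NumericMatrix cpp_pairwise_residual(NumericMatrix Ac, NumericMatrix Bc,
                                    NumericMatrix Cc, IntegerMatrix mus,
                                    IntegerMatrix nus) {
  CtMat a(Ac), b(Bc), c(Cc);
  std::vector<double> sites, diffs, out;
  std::vector<const double*> ptrs;
  NumericMatrix res(mus.nrow(), nus.nrow());
  std::vector<int> m0(mus.ncol()), n0(nus.ncol());
  for (int i = 0; i < mus.nrow(); ++i) {
    for (int j = 0; j < mus.ncol(); ++j) m0[j] = mus(i, j) - 1;
    for (int l = 0; l < nus.nrow(); ++l) {
      for (int j = 0; j < nus.ncol(); ++j) n0[j] = nus(l, j) - 1;
      res(i, l) = enc_residual(a, b, c, m0.data(), n0.data(), sites, diffs, ptrs, out);
    }
  }
  return res;
}

// [[Rcpp::export]]
List cpp_decode_bits(IntegerVector bits, int p, int q, int b) {
  Qiga ga;
  ga.p = p; ga.q = q; ga.b = b; ga.L = p + q; ga.nq = ga.L * b;
  if (bits.size() != ga.nq) stop("bit vector has wrong length");
  std::vector<int> bt(bits.begin(), bits.end()), mu, nu;
  ga.decode(bt, mu, nu);
  IntegerVector mu1(p), nu1(q);
  for (int i = 0; i < p; ++i) mu1[i] = mu[i] + 1;
  for (int i = 0; i < q; ++i) nu1[i] = nu[i] + 1;
  return List::create(_["mu"] = mu1, _["nu"] = nu1);
}

// [[Rcpp::export]]
List cpp_qiga_plain(NumericVector A, NumericVector B, NumericVector C, int N,
                    int gmax, double pc, double pm, double dtheta,
                    double clampLo, double clampHi, int restartAfter) {
  Evaluator ev;
  std::vector<double> a = as_vec(A), b = as_vec(B), c = as_vec(C);
  ev.A = &a; ev.B = &b; ev.C = &c;
  ev.encrypted = false;
  ev.tie = 0.25;   // plaintext distances are integers
  ev.zero = 0.25;
  return run_qiga(ev, (int)a.size(), (int)b.size(), N, gmax, pc, pm, dtheta,
                  clampLo, clampHi, restartAfter);
}

// [[Rcpp::export]]
List cpp_qiga_encrypted(NumericMatrix Ac, NumericMatrix Bc, NumericMatrix Cc,
                        double T, int N, int gmax, double pc, double pm,
                        double dtheta, double clampLo, double clampHi,
                        int restartAfter) {
  Evaluator ev;
  CtMat a(Ac), b(Bc), c(Cc);
  ev.Ac = &a; ev.Bc = &b; ev.Cc = &c;
  ev.encrypted = true;
  ev.tie = 2.0 * T;  // residuals of equal plaintext distance fall within 2T
  ev.zero = T;
  return run_qiga(ev, a.rows, b.rows, N, gmax, pc, pm, dtheta, clampLo,
                  clampHi, restartAfter);
}
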