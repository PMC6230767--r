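#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

// Log-odds forward score (nats) of a sequence against a profile HMM.
//
// ematch: L x 20 matrix of log(match emission / background).
// ltrans: (L+1) x 7 matrix of log transition probabilities, columns
//         MM MI MD IM II DM DD; row k holds transitions out of state
//         index k (M_k -> M_{k+1}, ...), with M_0 the begin state.
//         At the final index both M->M and M->D lead to the end state.
// seq:    0-based amino-acid indices; negative entries are skipped.
// [[Rcpp::export]]
double forward_logodds_cpp(NumericMatrix ematch, NumericMatrix ltrans,
                           IntegerVector seq) {
  const int L = ematch.nrow();
  std::vector<int> x;
  x.reserve(seq.size());
  for (int i = 0; i < seq.size(); ++i) if (seq[i] >= 0) x.push_back(seq[i]);
  const int n = (int)x.size();

  std::vector<double> M(L + 1, NEG_INF), I(L + 1, NEG_INF), D(L + 1, NEG_INF);
  std::vector<double> Mn(L + 1), In(L + 1), Dn(L + 1);

  // i = 0: begin state, then silent delete chain
  M[0] = 0.0;
  if (L >= 1) {
    D[1] = M[0] + ltrans(0, 2); // M0 -> D1
    for (int k = 2; k <= L; ++k) D[k] = D[k - 1] + ltrans(k - 1, 6);
  }

  for (int i = 1; i <= n; ++i) {
    const int a = x[i - 1];
    for (int k = 0; k <= L; ++k) { Mn[k] = NEG_INF; In[k] = NEG_INF; Dn[k] = NEG_INF; }
    for (int k = 1; k <= L; ++k) {
      double from = lse3(M[k - 1] + ltrans(k - 1, 0),
                         I[k - 1] + ltrans(k - 1, 3),
                         D[k - 1] + ltrans(k - 1, 5));
      Mn[k] = ematch(k - 1, a) + from;
    }
    for (int k = 0; k <= L; ++k) {
      // insert emission equals background: log-odds contribution 0
      In[k] = lse2(M[k] + ltrans(k, 1), I[k] + ltrans(k, 4));
    }
    for (int k = 1; k <= L; ++k) {
      Dn[k] = lse2(Mn[k - 1] + ltrans(k - 1, 2), Dn[k - 1] + ltrans(k - 1, 6));
    }
    M.swap(Mn); I.swap(In); D.swap(Dn);
  }

  double end = lse3(M[L] + lse2(ltrans(L, 0), ltrans(L, 2)),
                    I[L] + ltrans(L, 3),
                    (L >= 1 ? D[L] + lse2(ltrans(L, 5), ltrans(L, 6)) : NEG_INF));
  return end;
}
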