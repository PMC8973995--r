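#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Seed-weighted local duplex scan (Gotoh affine-gap Smith-Waterman).
//
// q: reversed sncRNA, s: UTR, both encoded A=0 C=1 G=2 T/U=3.
// w: per-position weight aligned to q (seed positions of the original
// sncRNA carry weight > 1); the weight scales every score contribution at
// that query row - substitutions and gap penalties alike - mirroring how
// miRanda applies its seed scale factor. Complementarity: Watson-Crick
// (a+b==3) scores `match`, G:U wobble scores `wobble`, anything else
// `mismatch`.
//
// All non-overlapping sites with score strictly above `threshold` are
// returned best-first: the DP is recomputed after masking each reported
// site's UTR columns, so later sites can never overlap earlier ones.
// Ties on score resolve to the leftmost (smallest end column, then smallest
// query row). All scores are exact sums of the integer-valued constants, so
// equality tests on doubles are safe up to the 1e-9 slack used here.

// [[Rcpp::export]]
DataFrame sw_scan_sites(IntegerVector q, IntegerVector s, NumericVector w,
                        double match, double wobble, double mismatch,
                        double gap_open, double gap_extend, double threshold) {
  const int n = q.size(), m = s.size();
  const double NEG = -1e18, EPS = 1e-9;
  std::vector<bool> masked(m + 1, false);
  std::vector<std::vector<double> > H(n + 1, std::vector<double>(m + 1, 0.0));
  std::vector<std::vector<double> > E(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double> > F(n + 1, std::vector<double>(m + 1, NEG));

  // substitution score at 1-based (i, j)
  struct Sub {
    const IntegerVector &q, &s;
    const NumericVector &w;
    double match, wobble, mismatch;
    double operator()(int i, int j) const {
      int a = q[i - 1], b = s[j - 1];
      double base;
      if (a + b == 3) base = match;
      else if ((a == 2 && b == 3) || (a == 3 && b == 2)) base = wobble;
      else base = mismatch;
      return w[i - 1] * base;
    }
  } sub = {q, s, w, match, wobble, mismatch};

  std::vector<int> out_start, out_end;
  std::vector<double> out_score;
  std::vector<std::string> out_pair;

  for (int iter = 0; iter < m; ++iter) {
    double best = 0.0;
    int bi = -1, bj = -1;
    for (int i = 1; i <= n; ++i) {
      for (int j = 1; j <= m; ++j) {
        if (masked[j]) {
          H[i][j] = 0.0; E[i][j] = NEG; F[i][j] = NEG;
          continue;
        }
        double wi = w[i - 1];
        double e = std::max(H[i][j - 1] + gap_open * wi,
                            E[i][j - 1] + gap_extend * wi);
        double f = std::max(H[i - 1][j] + gap_open * wi,
                            F[i - 1][j] + gap_extend * wi);
        double h = H[i - 1][j - 1] + sub(i, j);
        double v = std::max(0.0, std::max(h, std::max(e, f)));
        E[i][j] = e; F[i][j] = f; H[i][j] = v;
        if (v > best + EPS) {
          best = v; bi = i; bj = j;
        } else if (bi >= 0 && v > 0 && std::abs(v - best) <= EPS &&
                   (j < bj || (j == bj && i < bi))) {
          bi = i; bj = j;
        }
      }
    }
    if (best <= threshold + EPS || bi < 0) break;

    // traceback: diagonal preferred over E (gap in query) over F (gap in
    // subject); E and diagonal moves consume UTR columns
    int i = bi, j = bj, minj = bj;
    std::string pairing;
    while (i > 0 && j > 0 && H[i][j] > EPS) {
      double h = H[i][j];
      if (std::abs(h - (H[i - 1][j - 1] + sub(i, j))) <= EPS) {
        minj = j;
        if (sub(i, j) > 0) {
          std::string tok = std::to_string(n - i + 1) + ":" +
                            std::to_string(j - 1);
          pairing = pairing.empty() ? tok : tok + "," + pairing;
        }
        --i; --j;
      } else if (std::abs(h - E[i][j]) <= EPS) {
        while (true) {
          minj = j;
          if (std::abs(E[i][j] - (H[i][j - 1] + gap_open * w[i - 1])) <= EPS) {
            --j;
            break;
          }
          --j;
        }
      } else {
        while (true) {
          if (std::abs(F[i][j] - (H[i - 1][j] + gap_open * w[i - 1])) <= EPS) {
            --i;
            break;
          }
          --i;
        }
      }
    }
    out_start.push_back(minj - 1); // 0-based half-open
    out_end.push_back(bj);
    out_score.push_back(best);
    out_pair.push_back(pairing);
    for (int jj = minj; jj <= bj; ++jj) masked[jj] = true;
  }

  return DataFrame::create(
      _["utr_start"] = out_start, _["utr_end"] = out_end,
      _["score"] = out_score, _["pairing"] = out_pair,
      _["stringsAsFactors"] = false);
}
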