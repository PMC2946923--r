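#include <Rcpp.h>
using namespace Rcpp;

// Best ungapped overlap placement of b against a over all offsets.
// Candidate ranking: admissible overlap (>= min_overlap) first, then
// identity (compared exactly via cross-multiplication), then overlap
// length, then smaller |offset|. Returns c(offset, overlap, snps).
// [[Rcpp::export(name = ".best_overlap")]]
IntegerVector best_overlap(std::string a, std::string b, int min_overlap) {
  const int la = a.size(), lb = b.size();
  bool have = false;
  int b_off = 0, b_ov = 0, b_snps = 0;
  bool b_adm = false;

  int lo = 1 - lb, hi = la - 1;
  if (std::min(la, lb) >= min_overlap) {
    lo = min_overlap - lb;
    hi = la - min_overlap;
  }
  for (int off = lo; off <= hi; ++off) {
    int i1 = std::max(0, off), i2 = std::min(la, lb + off); // [i1, i2)
    int ov = i2 - i1;
    if (ov < 1) continue;
    int snps = 0;
    for (int i = i1; i < i2; ++i) {
      if (a[i] != b[i - off]) ++snps;
    }
    bool adm = ov >= min_overlap;
    bool better;
    if (!have) {
      better = true;
    } else if (adm != b_adm) {
      better = adm;
    } else {
      // identity comparison: (ov - snps)/ov vs (b_ov - b_snps)/b_ov
      long long lhs = (long long)(ov - snps) * b_ov;
      long long rhs = (long long)(b_ov - b_snps) * ov;
      if (lhs != rhs) {
        better = lhs > rhs;
      } else if (ov != b_ov) {
        better = ov > b_ov;
      } else {
        better = std::abs(off) < std::abs(b_off);
      }
    }
    if (better) {
      have = true;
      b_off = off; b_ov = ov; b_snps = snps; b_adm = adm;
    }
  }
  return IntegerVector::create(b_off, b_ov, b_snps);
}

// All-pairs match edges among unique sequences under the identity/overlap
// rule; returns a matrix with one row per matching pair:
// (i, j, offset, overlap, snps), 1-based indices.
// [[Rcpp::export(name = ".match_edges")]]
IntegerMatrix match_edges(CharacterVector seqs, double min_identity,
                          int min_overlap) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  std::vector<std::array<int, 5>> out;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      IntegerVector r = best_overlap(s[i], s[j], min_overlap);
      int ov = r[1], snps = r[2];
      if (ov >= min_overlap &&
          (double)(ov - snps) >= min_identity * (double)ov - 1e-9) {
        out.push_back({i + 1, j + 1, r[0], ov, snps});
      }
    }
  }
  IntegerMatrix m(out.size(), 5);
  for (size_t k = 0; k < out.size(); ++k) {
    for (int c = 0; c < 5; ++c) m(k, c) = out[k][c];
  }
  return m;
}
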