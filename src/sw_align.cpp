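#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh). A gap of length k
// costs gap_open + k * gap_extend (BLAST convention). Among equal-scoring
// optima the alignment with the smallest b_start, then the shortest b span,
// is returned. Coordinates are 0-based half-open.

// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, NumericMatrix subst,
                  std::vector<std::string> alphabet, double gap_open,
                  double gap_extend) {
  const int n = a.size(), m = b.size();
  std::vector<int> amap(n), bmap(m);
  // map residues to substitution-matrix indices
  int lookup[256];
  std::fill(lookup, lookup + 256, -1);
  for (size_t k = 0; k < alphabet.size(); ++k)
    lookup[(unsigned char)alphabet[k][0]] = (int)k;
  for (int i = 0; i < n; ++i) {
    amap[i] = lookup[(unsigned char)a[i]];
    if (amap[i] < 0) stop("illegal residue '%s' in first sequence",
                          std::string(1, a[i]));
  }
  for (int j = 0; j < m; ++j) {
    bmap[j] = lookup[(unsigned char)b[j]];
    if (bmap[j] < 0) stop("illegal residue '%s' in second sequence",
                          std::string(1, b[j]));
  }

  const double NEG = -1e18;
  const double open_cost = gap_open + gap_extend;  // first gapped residue
  std::vector<double> H((n + 1) * (m + 1), 0.0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // E: gap in a (consumes b)
      double e = std::max(H[at(i, j - 1)] - open_cost,
                          E[at(i, j - 1)] - gap_extend);
      // F: gap in b (consumes a)
      double f = std::max(H[at(i - 1, j)] - open_cost,
                          F[at(i - 1, j)] - gap_extend);
      double diag = H[at(i - 1, j - 1)] + subst(amap[i - 1], bmap[j - 1]);
      double h = std::max(0.0, std::max(diag, std::max(e, f)));
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      H[at(i, j)] = h;
      if (h > best) best = h;
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["a_start"] = NA_INTEGER,
                        _["a_end"] = NA_INTEGER, _["b_start"] = NA_INTEGER,
                        _["b_end"] = NA_INTEGER);
  }

  // traceback from every maximal cell; keep smallest b_start, then shortest
  // b span, then smallest a_start (deterministic)
  int best_as = -1, best_ae = -1, best_bs = -1, best_be = -1;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (H[at(i, j)] != best) continue;
      // greedy traceback preferring diagonal moves
      int ci = i, cj = j;
      int state = 0;  // 0 = H, 1 = E, 2 = F
      while (true) {
        if (state == 0) {
          double h = H[at(ci, cj)];
          if (h == 0.0) break;
          double diag = H[at(ci - 1, cj - 1)] +
                        subst(amap[ci - 1], bmap[cj - 1]);
          if (h == diag) {
            --ci; --cj;
          } else if (h == E[at(ci, cj)]) {
            state = 1;
          } else {
            state = 2;
          }
        } else if (state == 1) {
          double e = E[at(ci, cj)];
          if (e == H[at(ci, cj - 1)] - open_cost) state = 0;
          // else stay in E (extension)
          --cj;
        } else {
          double f = F[at(ci, cj)];
          if (f == H[at(ci - 1, cj)] - open_cost) state = 0;
          --ci;
        }
      }
      int as = ci, ae = i, bs = cj, be = j;
      bool better = false;
      if (best_bs < 0) {
        better = true;
      } else if (bs != best_bs) {
        better = bs < best_bs;
      } else if ((be - bs) != (best_be - best_bs)) {
        better = (be - bs) < (best_be - best_bs);
      } else if (as != best_as) {
        better = as < best_as;
      }
      if (better) {
        best_as = as; best_ae = ae; best_bs = bs; best_be = be;
      }
    }
  }

  return List::create(_["score"] = best, _["a_start"] = best_as,
                      _["a_end"] = best_ae, _["b_start"] = best_bs,
                      _["b_end"] = best_be);
}
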