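#include <Rcpp.h>
using namespace Rcpp;

// Shared union-find core (see decode.cpp for the exported single-genotype
// version). Population evaluation is the innermost loop of the GA: decode
// every individual and compute per-layer modularity from sparse edge lists,
// O(E + n) per layer instead of O(n^2).

static int uf_find2(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static int decode_into(const IntegerMatrix &P, int row, int n,
                       std::vector<int> &parent, std::vector<int> &rnk,
                       std::vector<int> &label, std::vector<int> &memb) {
  for (int i = 0; i < n; ++i) { parent[i] = i; rnk[i] = 0; label[i] = 0; }
  for (int i = 0; i < n; ++i) {
    int j = P(row, i) - 1;
    int r1 = uf_find2(parent, i), r2 = uf_find2(parent, j);
    if (r1 != r2) {
      if (rnk[r1] > rnk[r2]) parent[r2] = r1;
      else if (rnk[r1] < rnk[r2]) parent[r1] = r2;
      else { parent[r1] = r2; rnk[r2] += 1; }
    }
  }
  int k = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf_find2(parent, i);
    if (label[r] == 0) label[r] = ++k;
    memb[i] = label[r] - 1;
  }
  return k;
}

//' Decode and score a population of genotypes
//'
//' For each row of the loci matrix: decode the induced partition and return
//' the objective vector (Q in the target layer, 1 - Q elsewhere) plus the
//' module count. Layers are passed as sparse edge lists so each modularity
//' evaluation costs O(edges + n).
//'
//' @param P integer matrix, one genotype per row (1-based loci).
//' @param ei,ej,ew per-layer parallel lists of edge endpoints (1-based) and
//'   weights, each edge once.
//' @param strength n x M matrix of node strengths per layer.
//' @param two_w per-layer total weight times two.
//' @param m 1-based target layer.
//' @return list with objective matrix `F` and module counts `kmod`.
//' @keywords internal
// [[Rcpp::export]]
List evaluate_population(IntegerMatrix P, List ei, List ej, List ew,
                         NumericMatrix strength, NumericVector two_w,
                         int m) {
  const int nr = P.nrow(), n = P.ncol(), M = ei.size();
  NumericMatrix F(nr, M);
  IntegerVector kmod(nr);
  std::vector<int> parent(n), rnk(n), label(n), memb(n);
  std::vector<double> within, astr;
  for (int r = 0; r < nr; ++r) {
    int k = decode_into(P, r, n, parent, rnk, label, memb);
    kmod[r] = k;
    for (int l = 0; l < M; ++l) {
      IntegerVector li = ei[l], lj = ej[l];
      NumericVector lw = ew[l];
      const double tw = two_w[l];
      within.assign(k, 0.0);
      astr.assign(k, 0.0);
      const int ne = li.size();
      for (int e = 0; e < ne; ++e) {
        int a = memb[li[e] - 1], b = memb[lj[e] - 1];
        if (a == b) within[a] += 2.0 * lw[e];  // both orientations
      }
      for (int i = 0; i < n; ++i) astr[memb[i]] += strength(i, l);
      double q = 0.0;
      for (int c = 0; c < k; ++c)
        q += within[c] / tw - (astr[c] / tw) * (astr[c] / tw);
      F(r, l) = (l == m - 1) ? q : 1.0 - q;
    }
  }
  return List::create(_["F"] = F, _["kmod"] = kmod);
}
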