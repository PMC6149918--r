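#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

//' Connected-component membership of the locus-induced edge set
//'
//' Internal workhorse for genotype decoding: treats \code{(i, loci[i])} as an
//' undirected edge for every node i and returns the component label of each
//' node. Labels are 1..k, assigned in order of the smallest node index a
//' component contains, so the labelling is canonical and stable.
//'
//' @param loci 1-based integer vector; entry i is the partner node of i.
//' @return integer membership vector of the same length.
//' @keywords internal
// [[Rcpp::export]]
IntegerVector decode_membership(IntegerVector loci) {
  const int n = loci.size();
  std::vector<int> parent(n), rnk(n, 0);
  for (int i = 0; i < n; ++i) parent[i] = i;
  for (int i = 0; i < n; ++i) {
    int j = loci[i] - 1;
    if (j < 0 || j >= n) stop("locus out of range at position %d", i + 1);
    int r1 = uf_find(parent, i), r2 = uf_find(parent, j);
    if (r1 != r2) {
      // union by rank
      if (rnk[r1] > rnk[r2]) parent[r2] = r1;
      else if (rnk[r1] < rnk[r2]) parent[r1] = r2;
      else { parent[r1] = r2; rnk[r2] += 1; }
    }
  }
  IntegerVector memb(n);
  std::vector<int> label(n, 0);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf_find(parent, i);
    if (label[r] == 0) label[r] = ++k;
    memb[i] = label[r];
  }
  return memb;
}
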