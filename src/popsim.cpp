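// Forward-in-time mutation-drift simulation of a diploid population and
// gamete formation for structured (half-sib) breeding.
//
// Haplotypes are stored as columns of an integer matrix (markers x 2*n);
// columns 2i, 2i+1 belong to individual i (0-based). Alleles are 0/1.
// Crossovers per chromosome are Poisson(map length in Morgan) with uniform
// positions and no interference; mutation is a symmetric allele flip applied
// per locus per transmitted gamete.

#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

namespace {

struct ChromSpan {
  int begin;  // first marker index (0-based)
  int end;    // one past last
  double length;
};

std::vector<ChromSpan> chrom_spans(const IntegerVector& chrom,
                                   const NumericVector& chrom_len) {
  std::vector<ChromSpan> spans;
  const int m = chrom.size();
  int i = 0;
  while (i < m) {
    int c = chrom[i];
    int j = i;
    while (j < m && chrom[j] == c) ++j;
    ChromSpan sp;
    sp.begin = i;
    sp.end = j;
    sp.length = chrom_len[c - 1];
    spans.push_back(sp);
    i = j;
  }
  return spans;
}

// Build one gamete from the two parental haplotype columns h1, h2 into out.
void make_gamete(const int* h1, const int* h2, int* out,
                 const std::vector<ChromSpan>& spans,
                 const NumericVector& pos, double mu, int m) {
  std::vector<double> cx;
  for (const ChromSpan& sp : spans) {
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    int ncx = (int) R::rpois(sp.length);
    cx.clear();
    for (int t = 0; t < ncx; ++t) cx.push_back(unif_rand() * sp.length);
    std::sort(cx.begin(), cx.end());
    std::size_t ptr = 0;
    // positions within a chromosome are relative to its own start at 0
    for (int i = sp.begin; i < sp.end; ++i) {
      while (ptr < cx.size() && cx[ptr] < pos[i]) {
        cur ^= 1;
        ++ptr;
      }
      out[i] = cur ? h2[i] : h1[i];
    }
  }
  if (mu > 0) {
    // Binomial count + distinct uniform positions == iid Bernoulli(mu) per locus
    int nmut = (int) R::rbinom((double) m, mu);
    if (nmut > 0) {
      std::unordered_set<int> hit;
      hit.reserve(nmut * 2);
      while ((int) hit.size() < nmut) {
        int idx = (int) (unif_rand() * m);
        if (idx >= m) idx = m - 1;
        if (hit.insert(idx).second) out[idx] ^= 1;
      }
    }
  }
}

double mean_heterozygosity(const IntegerMatrix& haps) {
  const int m = haps.nrow();
  const int n = haps.ncol() / 2;
  long long het = 0;
  for (int i = 0; i < n; ++i) {
    const int* a = &haps(0, 2 * i);
    const int* b = &haps(0, 2 * i + 1);
    for (int j = 0; j < m; ++j) het += (a[j] != b[j]);
  }
  return (double) het / ((double) m * n);
}

} // namespace

// [[Rcpp::export]]
List cpp_simulate_base(int ne, int ngen, double mu, NumericVector pos,
                       IntegerVector chrom, NumericVector chrom_len,
                       IntegerVector record_gens) {
  const int m = pos.size();
  std::vector<ChromSpan> spans = chrom_spans(chrom, chrom_len);
  IntegerMatrix cur(m, 2 * ne);  // zero-initialised: founders homozygous 0/0
  IntegerMatrix nxt(m, 2 * ne);
  const int nmale = ne / 2;      // individuals 0..nmale-1 are male
  const int nfem = ne - nmale;
  std::vector<double> het_trace;
  std::vector<int> het_gen;
  std::unordered_set<int> want(record_gens.begin(), record_gens.end());

  if (want.count(0)) {
    het_trace.push_back(mean_heterozygosity(cur));
    het_gen.push_back(0);
  }
  for (int g = 1; g <= ngen; ++g) {
    for (int i = 0; i < ne; ++i) {
      int sire = (int) (unif_rand() * nmale);
      if (sire >= nmale) sire = nmale - 1;
      int dam = nmale + (int) (unif_rand() * nfem);
      if (dam >= ne) dam = ne - 1;
      make_gamete(&cur(0, 2 * sire), &cur(0, 2 * sire + 1), &nxt(0, 2 * i),
                  spans, pos, mu, m);
      make_gamete(&cur(0, 2 * dam), &cur(0, 2 * dam + 1), &nxt(0, 2 * i + 1),
                  spans, pos, mu, m);
    }
    std::swap(cur, nxt);
    if (want.count(g)) {
      het_trace.push_back(mean_heterozygosity(cur));
      het_gen.push_back(g);
    }
    if (g % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["haplotypes"] = cur,
                      _["het_generation"] = wrap(het_gen),
                      _["het_trace"] = wrap(het_trace));
}

// Offspring o gets a paternal gamete from individual sire[o] and a maternal
// gamete from dam[o] (1-based indices into the parent matrix).
// [[Rcpp::export]]
IntegerMatrix cpp_breed_offspring(IntegerMatrix parent_haps, IntegerVector sire,
                                  IntegerVector dam, double mu,
                                  NumericVector pos, IntegerVector chrom,
                                  NumericVector chrom_len) {
  const int m = parent_haps.nrow();
  const int noff = sire.size();
  std::vector<ChromSpan> spans = chrom_spans(chrom, chrom_len);
  IntegerMatrix off(m, 2 * noff);
  for (int o = 0; o < noff; ++o) {
    int s = sire[o] - 1, d = dam[o] - 1;
    make_gamete(&parent_haps(0, 2 * s), &parent_haps(0, 2 * s + 1),
                &off(0, 2 * o), spans, pos, mu, m);
    make_gamete(&parent_haps(0, 2 * d), &parent_haps(0, 2 * d + 1),
                &off(0, 2 * o + 1), spans, pos, mu, m);
    if (o % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return off;
}

// Single meiosis, exposed for map-function checks. No mutation.
// [[Rcpp::export]]
IntegerVector cpp_meiosis(IntegerVector h1, IntegerVector h2, NumericVector pos,
                          IntegerVector chrom, NumericVector chrom_len) {
  const int m = h1.size();
  std::vector<ChromSpan> spans = chrom_spans(chrom, chrom_len);
  IntegerVector out(m);
  make_gamete(h1.begin(), h2.begin(), out.begin(), spans, pos, 0.0, m);
  return out;
}

// Genotype dosages (count of allele 1), individuals x markers.
// [[Rcpp::export]]
IntegerMatrix cpp_dosages(IntegerMatrix haps) {
  const int m = haps.nrow();
  const int n = haps.ncol() / 2;
  IntegerMatrix geno(n, m);
  for (int i = 0; i < n; ++i) {
    const int* a = &haps(0, 2 * i);
    const int* b = &haps(0, 2 * i + 1);
    for (int j = 0; j < m; ++j) geno(i, j) = a[j] + b[j];
  }
  return geno;
}
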