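#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Haplotype storage convention: RawMatrix with n_loci rows and 2*N columns;
// columns 2i, 2i+1 hold the two haplotypes of diploid individual i (0-based).
// Loci are ordered by chromosome, position increasing within chromosome.

namespace {

struct GenomeLayout {
  std::vector<int> begin;   // first locus index of each chromosome
  std::vector<int> end;     // one-past-last locus index
  std::vector<double> len;  // map length in cM
  const double* pos;        // cM position of every locus (within chromosome)
  int n_chrom() const { return (int) begin.size(); }
};

GenomeLayout layout_from(const IntegerVector& chrom, const NumericVector& pos,
                         const NumericVector& chrom_len) {
  GenomeLayout g;
  g.pos = REAL(pos);
  int n = chrom.size();
  int cur = NA_INTEGER;
  for (int i = 0; i < n; ++i) {
    if (chrom[i] != cur) {
      if (cur != NA_INTEGER) g.end.push_back(i);
      g.begin.push_back(i);
      cur = chrom[i];
      g.len.push_back(chrom_len[cur - 1]);
    }
  }
  if (n > 0) g.end.push_back(n);
  return g;
}

// One gamete from the parental haplotype pair (h1, h2): Poisson(len/100)
// crossovers per chromosome, positions uniform, no interference.
void make_gamete(const Rbyte* h1, const Rbyte* h2, Rbyte* out,
                 const GenomeLayout& g, std::vector<double>& xbuf) {
  const Rbyte* H[2] = { h1, h2 };
  for (int c = 0; c < g.n_chrom(); ++c) {
    int b = g.begin[c], e = g.end[c];
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    int nx = (int) R::rpois(g.len[c] / 100.0);
    if (nx == 0) {
      std::memcpy(out + b, H[cur] + b, (size_t)(e - b));
      continue;
    }
    xbuf.clear();
    for (int k = 0; k < nx; ++k) xbuf.push_back(unif_rand() * g.len[c]);
    std::sort(xbuf.begin(), xbuf.end());
    int lo = b;
    for (int k = 0; k < nx && lo < e; ++k) {
      const double* first = g.pos + lo;
      const double* last  = g.pos + e;
      int hi = lo + (int)(std::upper_bound(first, last, xbuf[k]) - first);
      if (hi > lo) std::memcpy(out + lo, H[cur] + lo, (size_t)(hi - lo));
      lo = hi;
      cur = 1 - cur;
    }
    if (lo < e) std::memcpy(out + lo, H[cur] + lo, (size_t)(e - lo));
  }
}

// Recurrent mutation: allele flips, expected count = n_cells * rate.
void apply_mutation(Rbyte* data, R_xlen_t n_loci, R_xlen_t n_hap, double rate) {
  if (rate <= 0.0) return;
  double cells = (double) n_loci * (double) n_hap;
  int nflip = (int) R::rbinom(cells, rate);
  for (int k = 0; k < nflip; ++k) {
    R_xlen_t locus = (R_xlen_t)(unif_rand() * n_loci);
    R_xlen_t hap   = (R_xlen_t)(unif_rand() * n_hap);
    if (locus >= n_loci) locus = n_loci - 1;
    if (hap >= n_hap) hap = n_hap - 1;
    Rbyte* p = data + hap * n_loci + locus;
    *p = (Rbyte)(1 - *p);
  }
}

} // namespace

// Founder pool with exact allele frequency: per locus, round(2N * freq) copies
// of allele 1 placed at random haplotypes (Fisher-Yates column shuffle).
// [[Rcpp::export]]
RawMatrix cpp_founders(int n_loci, int n_ind, double freq) {
  R_xlen_t n_hap = 2 * (R_xlen_t) n_ind;
  RawMatrix hap(n_loci, (int) n_hap);
  Rbyte* data = RAW(hap);
  int k1 = (int) std::lround((double) n_hap * freq);
  std::vector<int> idx(n_hap);
  for (R_xlen_t j = 0; j < n_hap; ++j) idx[j] = (int) j;
  for (int i = 0; i < n_loci; ++i) {
    // partial Fisher-Yates: choose k1 distinct haplotypes for allele 1
    for (int k = 0; k < k1; ++k) {
      int j = k + (int)(unif_rand() * (n_hap - k));
      if (j >= (int) n_hap) j = (int) n_hap - 1;
      std::swap(idx[k], idx[j]);
      data[(R_xlen_t) idx[k] * n_loci + i] = 1;
    }
  }
  return hap;
}

// Historical phase: random union of gametes each generation following a size
// trajectory, recurrent mutation, fixed proportion of males.
// sizes[0] is the founder generation size (matching the matrix passed in).
// [[Rcpp::export]]
RawMatrix cpp_historical(RawMatrix founders, IntegerVector sizes,
                         IntegerVector chrom, NumericVector pos,
                         NumericVector chrom_len, double prop_male,
                         double mut_rate) {
  GenomeLayout g = layout_from(chrom, pos, chrom_len);
  int n_loci = founders.nrow();
  int n_gen = sizes.size();
  if (n_gen < 1) stop("empty size trajectory");
  if (founders.ncol() != 2 * sizes[0])
    stop("founder matrix does not match sizes[0]");
  if (n_gen == 1) return founders;
  int n_max = *std::max_element(sizes.begin(), sizes.end());
  // two reusable buffers (ping-pong) avoid a 2N x n_loci allocation + GC
  // sweep per generation
  std::vector<Rbyte> bufA((size_t) n_loci * 2 * n_max),
                     bufB((size_t) n_loci * 2 * n_max);
  std::memcpy(bufA.data(), RAW(founders),
              (size_t) n_loci * founders.ncol());
  Rbyte* cd = bufA.data();
  Rbyte* nd = bufB.data();
  std::vector<double> xbuf;
  for (int gidx = 1; gidx < n_gen; ++gidx) {
    int Np = sizes[gidx - 1];       // parent generation size
    int N  = sizes[gidx];
    if (N < 2) stop("population size below 2 in generation trajectory");
    int n_m = (int) std::lround(prop_male * Np);
    if (n_m < 1 || n_m >= Np)
      stop("a historical generation has zero males or zero females");
    for (int i = 0; i < N; ++i) {
      int sire = (int)(unif_rand() * n_m);
      int dam  = n_m + (int)(unif_rand() * (Np - n_m));
      if (sire >= n_m) sire = n_m - 1;
      if (dam >= Np) dam = Np - 1;
      make_gamete(cd + (R_xlen_t)(2 * sire) * n_loci,
                  cd + (R_xlen_t)(2 * sire + 1) * n_loci,
                  nd + (R_xlen_t)(2 * i) * n_loci, g, xbuf);
      make_gamete(cd + (R_xlen_t)(2 * dam) * n_loci,
                  cd + (R_xlen_t)(2 * dam + 1) * n_loci,
                  nd + (R_xlen_t)(2 * i + 1) * n_loci, g, xbuf);
    }
    apply_mutation(nd, n_loci, 2 * (R_xlen_t) N, mut_rate);
    std::swap(cd, nd);
    if (gidx % 64 == 0) Rcpp::checkUserInterrupt();
  }
  int n_last = sizes[n_gen - 1];
  RawMatrix out(n_loci, 2 * n_last);
  std::memcpy(RAW(out), cd, (size_t) n_loci * 2 * n_last);
  return out;
}

// Offspring haplotypes for an explicit mating list (0-based parent indices
// into the parent haplotype matrix).
// [[Rcpp::export]]
RawMatrix cpp_offspring(RawMatrix parents, IntegerVector sire_idx,
                        IntegerVector dam_idx, IntegerVector chrom,
                        NumericVector pos, NumericVector chrom_len,
                        double mut_rate) {
  GenomeLayout g = layout_from(chrom, pos, chrom_len);
  int n_loci = parents.nrow();
  int n_off = sire_idx.size();
  if (dam_idx.size() != n_off) stop("sire_idx and dam_idx lengths differ");
  RawMatrix off(n_loci, 2 * n_off);
  Rbyte* od = RAW(off);
  Rbyte* pd = RAW(parents);
  std::vector<double> xbuf;
  int n_par = parents.ncol() / 2;
  for (int i = 0; i < n_off; ++i) {
    int s = sire_idx[i], d = dam_idx[i];
    if (s < 0 || s >= n_par || d < 0 || d >= n_par)
      stop("parent index out of range");
    make_gamete(pd + (R_xlen_t)(2 * s) * n_loci,
                pd + (R_xlen_t)(2 * s + 1) * n_loci,
                od + (R_xlen_t)(2 * i) * n_loci, g, xbuf);
    make_gamete(pd + (R_xlen_t)(2 * d) * n_loci,
                pd + (R_xlen_t)(2 * d + 1) * n_loci,
                od + (R_xlen_t)(2 * i + 1) * n_loci, g, xbuf);
  }
  apply_mutation(od, n_loci, 2 * (R_xlen_t) n_off, mut_rate);
  return off;
}

// Single gamete from one haplotype pair (exposed for the meiosis operation).
// [[Rcpp::export]]
RawVector cpp_gamete(RawVector h1, RawVector h2, IntegerVector chrom,
                     NumericVector pos, NumericVector chrom_len) {
  GenomeLayout g = layout_from(chrom, pos, chrom_len);
  int n_loci = h1.size();
  if (h2.size() != n_loci) stop("haplotype lengths differ");
  RawVector out(n_loci);
  std::vector<double> xbuf;
  make_gamete(RAW(h1), RAW(h2), RAW(out), g, xbuf);
  return out;
}

// Allele dosages (0/1/2) for selected individuals (0-based) at selected loci.
// [[Rcpp::export]]
IntegerMatrix cpp_dosage(RawMatrix hap, IntegerVector ind_idx,
                         IntegerVector locus_idx) {
  int n_loci_all = hap.nrow();
  int n_ind = ind_idx.size();
  int n_loc = locus_idx.size();
  IntegerMatrix out(n_ind, n_loc);
  Rbyte* hd = RAW(hap);
  for (int i = 0; i < n_ind; ++i) {
    R_xlen_t c1 = (R_xlen_t)(2 * ind_idx[i]) * n_loci_all;
    R_xlen_t c2 = c1 + n_loci_all;
    for (int j = 0; j < n_loc; ++j) {
      int l = locus_idx[j];
      out(i, j) = (int) hd[c1 + l] + (int) hd[c2 + l];
    }
  }
  return out;
}

// Inbreeding coefficients by the Meuwissen-Luo walk of the T-D decomposition:
// a_ii = sum_j L_ij^2 D_j over ancestors j, F_i = a_ii - 1.  Pedigree must be
// topologically ordered (parents before offspring); 0 codes unknown parents.
// [[Rcpp::export]]
NumericVector cpp_inbreeding(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n + 1), L(n + 1);
  for (int i = 1; i <= n; ++i) {
    int s = sire[i - 1], d = dam[i - 1];
    double v = 1.0;
    if (s > 0) v -= 0.25 * (1.0 + F[s - 1]);
    if (d > 0) v -= 0.25 * (1.0 + F[d - 1]);
    D[i] = v;
    if (s == 0 || d == 0) { F[i - 1] = 0.0; continue; }
    std::fill(L.begin(), L.begin() + i + 1, 0.0);
    L[i] = 1.0;
    double a = 0.0;
    for (int j = i; j >= 1; --j) {
      double lj = L[j];
      if (lj == 0.0) continue;
      a += lj * lj * D[j];
      int js = sire[j - 1], jd = dam[j - 1];
      if (js > 0) L[js] += 0.5 * lj;
      if (jd > 0) L[jd] += 0.5 * lj;
    }
    F[i - 1] = a - 1.0;
  }
  return F;
}

// Triplets of the sparse A-inverse by Henderson's rules with inbreeding
// (alpha_i = 1/D_i with D_i as above).
// [[Rcpp::export]]
List cpp_ainverse_triplets(IntegerVector sire, IntegerVector dam,
                           NumericVector F) {
  int n = sire.size();
  std::vector<int> ii, jj;
  std::vector<double> xx;
  ii.reserve(9 * (size_t) n); jj.reserve(9 * (size_t) n); xx.reserve(9 * (size_t) n);
  for (int i = 1; i <= n; ++i) {
    int s = sire[i - 1], d = dam[i - 1];
    double v = 1.0;
    if (s > 0) v -= 0.25 * (1.0 + F[s - 1]);
    if (d > 0) v -= 0.25 * (1.0 + F[d - 1]);
    double al = 1.0 / v;
    ii.push_back(i); jj.push_back(i); xx.push_back(al);
    if (s > 0) {
      ii.push_back(i); jj.push_back(s); xx.push_back(-0.5 * al);
      ii.push_back(s); jj.push_back(i); xx.push_back(-0.5 * al);
      ii.push_back(s); jj.push_back(s); xx.push_back(0.25 * al);
    }
    if (d > 0) {
      ii.push_back(i); jj.push_back(d); xx.push_back(-0.5 * al);
      ii.push_back(d); jj.push_back(i); xx.push_back(-0.5 * al);
      ii.push_back(d); jj.push_back(d); xx.push_back(0.25 * al);
    }
    if (s > 0 && d > 0) {
      ii.push_back(s); jj.push_back(d); xx.push_back(0.25 * al);
      ii.push_back(d); jj.push_back(s); xx.push_back(0.25 * al);
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["x"] = wrap(xx));
}

// Dense numerator relationship matrix by the tabular (recursive) method.
// [[Rcpp::export]]
NumericMatrix cpp_A_tabular(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericMatrix A(n, n);
  double* a = REAL(A);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;  // -1 = unknown
    if (s >= i || d >= i) stop("pedigree not topologically ordered");
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * a[(R_xlen_t) j * n + s];
      if (d >= 0) v += 0.5 * a[(R_xlen_t) j * n + d];
      a[(R_xlen_t) j * n + i] = v;
      a[(R_xlen_t) i * n + j] = v;
    }
    double dia = 1.0;
    if (s >= 0 && d >= 0) dia += 0.5 * a[(R_xlen_t) d * n + s];
    a[(R_xlen_t) i * n + i] = dia;
  }
  return A;
}
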