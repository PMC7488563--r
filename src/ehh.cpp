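#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Extended haplotype homozygosity by outward partition refinement.
// hap is an n_hap x n_sites 0/1 matrix for ONE chromosome; a haplotype
// class (the rows in `rows`) starts as a single group at the focal site
// and is split by each successive site's alleles.  EHH at a site is
// sum_h C(c_h,2) / C(n,2) over the current groups.

class EhhWalker {
  const IntegerMatrix& hap;
  std::vector<int> grp;
  std::vector<int> rows;
  std::vector<int> remap;
  std::vector<int> cnt;
  double pairs_tot;

public:
  EhhWalker(const IntegerMatrix& hap_, const std::vector<int>& rows_)
    : hap(hap_), rows(rows_) {
    int n = rows.size();
    grp.assign(n, 0);
    remap.assign(2 * n + 2, -1);
    cnt.assign(n, 0);
    pairs_tot = 0.5 * n * (n - 1.0);
  }

  // split groups by the alleles at `site`; return the new EHH
  double refine(int site) {
    int n = rows.size();
    std::fill(remap.begin(), remap.end(), -1);
    int ngrp = 0;
    for (int i = 0; i < n; ++i) {
      int key = 2 * grp[i] + hap(rows[i], site);
      if (remap[key] < 0) remap[key] = ngrp++;
      grp[i] = remap[key];
    }
    std::fill(cnt.begin(), cnt.begin() + ngrp, 0);
    for (int i = 0; i < n; ++i) cnt[grp[i]]++;
    double pairs = 0.0;
    for (int g = 0; g < ngrp; ++g) pairs += 0.5 * cnt[g] * (cnt[g] - 1.0);
    return pairs / pairs_tot;
  }
};

// One-sided trapezoidal integral of EHH over genetic distance (cM).
// Truncated where EHH < cutoff (the sub-cutoff trapezoid is excluded) or
// at a physical gap > max_gap_bp; gaps > gap_scale_bp down-weight their
// trapezoid by gap_scale_bp/gap.  If the chromosome end is reached with
// EHH still >= cutoff the side is unscored.
static double side_ihh(const IntegerMatrix& hap, int focal,
                       const std::vector<int>& rows,
                       const NumericVector& pos, const NumericVector& cm,
                       int dir, double cutoff, double max_gap,
                       double gap_scale, bool& unscored) {
  int S = hap.ncol();
  EhhWalker w(hap, rows);
  double ihh = 0.0, ehh_prev = 1.0, x_prev = 0.0, p_prev = pos[focal];
  unscored = false;
  for (int j = focal + dir; j >= 0 && j < S; j += dir) {
    double gap = std::fabs(pos[j] - p_prev);
    if (gap > max_gap) return ihh;
    double e = w.refine(j);
    if (e < cutoff) return ihh;
    double x = std::fabs(cm[j] - cm[focal]);
    double wgt = (gap > gap_scale) ? gap_scale / gap : 1.0;
    ihh += wgt * 0.5 * (ehh_prev + e) * (x - x_prev);
    ehh_prev = e;
    x_prev = x;
    p_prev = pos[j];
  }
  unscored = true;
  return ihh;
}

// [[Rcpp::export]]
List ehh_profile_cpp(IntegerMatrix hap, int focal0, IntegerVector members0,
                     NumericVector cm, int dir) {
  std::vector<int> rows(members0.begin(), members0.end());
  if (rows.size() < 2) stop("EHH undefined for haplotype classes of size < 2");
  int S = hap.ncol();
  EhhWalker w(hap, rows);
  std::vector<double> dist, ehh;
  std::vector<int> sites;
  for (int j = focal0 + dir; j >= 0 && j < S; j += dir) {
    double e = w.refine(j);
    dist.push_back(std::fabs(cm[j] - cm[focal0]));
    ehh.push_back(e);
    sites.push_back(j + 1);
    if (e == 0.0) break;
  }
  return List::create(_["site"] = wrap(sites), _["distance_cM"] = wrap(dist),
                      _["ehh"] = wrap(ehh));
}

// [[Rcpp::export]]
NumericVector ihh_cpp(IntegerMatrix hap, int focal0, IntegerVector members0,
                      NumericVector pos, NumericVector cm, double cutoff,
                      double max_gap, double gap_scale) {
  std::vector<int> rows(members0.begin(), members0.end());
  if (rows.size() < 2) stop("iHH undefined for haplotype classes of size < 2");
  bool un_l = false, un_r = false;
  double left = side_ihh(hap, focal0, rows, pos, cm, -1, cutoff, max_gap,
                         gap_scale, un_l);
  double right = side_ihh(hap, focal0, rows, pos, cm, +1, cutoff, max_gap,
                          gap_scale, un_r);
  NumericVector out = NumericVector::create(left + right,
                                            (un_l || un_r) ? 1.0 : 0.0);
  return out;
}

// Full-chromosome iHS scan: per polarized site with MAF >= maf_min,
// raw = ln(iHH_ancestral / iHH_derived).  Columns of the result:
// derived_freq, raw, scored (1/0).
// [[Rcpp::export]]
NumericMatrix ihs_scan_cpp(IntegerMatrix hap, NumericVector pos,
                           NumericVector cm, double maf_min, double cutoff,
                           double max_gap, double gap_scale) {
  int n = hap.nrow(), S = hap.ncol();
  NumericMatrix out(S, 3);
  std::vector<int> anc, der;
  for (int s = 0; s < S; ++s) {
    anc.clear();
    der.clear();
    for (int i = 0; i < n; ++i)
      (hap(i, s) == 1 ? der : anc).push_back(i);
    double p = (double)der.size() / n;
    out(s, 0) = p;
    out(s, 2) = 0.0;
    if (std::min(p, 1.0 - p) < maf_min) continue;
    if (anc.size() < 2 || der.size() < 2) continue;
    bool ua_l, ua_r, ud_l, ud_r;
    double ihh_a = side_ihh(hap, s, anc, pos, cm, -1, cutoff, max_gap,
                            gap_scale, ua_l) +
                   side_ihh(hap, s, anc, pos, cm, +1, cutoff, max_gap,
                            gap_scale, ua_r);
    double ihh_d = side_ihh(hap, s, der, pos, cm, -1, cutoff, max_gap,
                            gap_scale, ud_l) +
                   side_ihh(hap, s, der, pos, cm, +1, cutoff, max_gap,
                            gap_scale, ud_r);
    if (ua_l || ua_r || ud_l || ud_r) continue;
    if (ihh_a <= 0.0 || ihh_d <= 0.0) continue;
    out(s, 1) = std::log(ihh_a / ihh_d);
    out(s, 2) = 1.0;
  }
  return out;
}

// Full-chromosome XP-EHH scan over two phased panels on the same sites:
// raw = ln(iHH_A / iHH_B), EHH over all haplotypes of each population.
// Columns: pooled_freq, raw, scored (1/0).
// [[Rcpp::export]]
NumericMatrix xpehh_scan_cpp(IntegerMatrix hapA, IntegerMatrix hapB,
                             NumericVector pos, NumericVector cm,
                             double cutoff, double max_gap,
                             double gap_scale) {
  if (hapA.ncol() != hapB.ncol())
    stop("panels must share one site set");
  int nA = hapA.nrow(), nB = hapB.nrow(), S = hapA.ncol();
  std::vector<int> allA(nA), allB(nB);
  for (int i = 0; i < nA; ++i) allA[i] = i;
  for (int i = 0; i < nB; ++i) allB[i] = i;
  NumericMatrix out(S, 3);
  for (int s = 0; s < S; ++s) {
    int cnt = 0;
    for (int i = 0; i < nA; ++i) cnt += hapA(i, s);
    for (int i = 0; i < nB; ++i) cnt += hapB(i, s);
    double p = (double)cnt / (nA + nB);
    out(s, 0) = p;
    out(s, 2) = 0.0;
    if (p <= 0.0 || p >= 1.0) continue;  // not segregating in the pool
    bool a_l, a_r, b_l, b_r;
    double ihh_a = side_ihh(hapA, s, allA, pos, cm, -1, cutoff, max_gap,
                            gap_scale, a_l) +
                   side_ihh(hapA, s, allA, pos, cm, +1, cutoff, max_gap,
                            gap_scale, a_r);
    double ihh_b = side_ihh(hapB, s, allB, pos, cm, -1, cutoff, max_gap,
                            gap_scale, b_l) +
                   side_ihh(hapB, s, allB, pos, cm, +1, cutoff, max_gap,
                            gap_scale, b_r);
    if (a_l || a_r || b_l || b_r) continue;
    if (ihh_a <= 0.0 || ihh_b <= 0.0) continue;
    out(s, 1) = std::log(ihh_a / ihh_b);
    out(s, 2) = 1.0;
  }
  return out;
}
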