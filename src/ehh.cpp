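#include <Rcpp.h>
using namespace Rcpp;

// One-sided EHH/EHHS decay by haplotype group refinement.
//
// Starting from the groups in `groups0` (compact 0-based ids over the
// carrier rows), markers are visited outward from the focal column; at
// each marker every group is split by the allele carried there and the
// homozygosity sum_k n_k (n_k - 1) / (n (n - 1)) is recorded. The scan
// stops when the value falls below `stop` (truncated), reaches zero (all
// singleton groups), runs past `max_ext` bp from the focal position, or
// runs off the chromosome end.
//
// haps: 0/1 matrix, rows = haplotypes; focal: 0-based column;
// rows: 0-based carrier row indices; side: +1 (right) or -1 (left).
// [[Rcpp::export]]
List ehh_side_cpp(const IntegerMatrix& haps, int focal,
                  const IntegerVector& rows, const IntegerVector& groups0,
                  int side, double stop, double max_ext,
                  const NumericVector& pos) {
  const int n = rows.size();
  const int m = haps.ncol();
  const double denom = (double)n * (n - 1);
  std::vector<int> gid(groups0.begin(), groups0.end());
  int ngroups = 0;
  for (int i = 0; i < n; ++i) if (gid[i] + 1 > ngroups) ngroups = gid[i] + 1;

  std::vector<int> out_idx;
  std::vector<double> out_ehh;
  bool truncated = false, hit_end = false;
  const double p0 = pos[focal];

  int t = focal + side;
  std::vector<int> remap;
  std::vector<int> count;
  while (true) {
    if (t < 0 || t >= m) { hit_end = true; break; }
    if (std::abs(pos[t] - p0) > max_ext) break;
    // split every group by the allele at marker t
    remap.assign(2 * (size_t)ngroups, -1);
    int nnew = 0;
    for (int i = 0; i < n; ++i) {
      int key = 2 * gid[i] + haps(rows[i], t);
      if (remap[key] < 0) remap[key] = nnew++;
      gid[i] = remap[key];
    }
    ngroups = nnew;
    count.assign(ngroups, 0);
    for (int i = 0; i < n; ++i) count[gid[i]]++;
    double s = 0.0;
    for (int k = 0; k < ngroups; ++k) s += (double)count[k] * (count[k] - 1);
    double ehh = denom > 0 ? s / denom : 0.0;
    out_idx.push_back(t);
    out_ehh.push_back(ehh);
    if (ehh < stop) { truncated = true; break; }
    if (s == 0.0) break;  // fully refined; stays 0 from here on
    t += side;
  }

  return List::create(_["idx"] = wrap(out_idx), _["ehh"] = wrap(out_ehh),
                      _["truncated"] = truncated, _["hit_end"] = hit_end);
}

// Per-site integrated EHH/EHHS with on-the-fly trapezoid integration:
// both sides, gap-capped widths, linear interpolation down to the stop
// threshold on truncation. Semantics match ehh_side_cpp + the R-side
// trapezoid integration; this fused version is the scans' fast path.
//
// lo/hi: 0-based inclusive column bounds of the focal chromosome.
// Returns (area, hit_end) where hit_end = 1 when either side ran off the
// chromosome while still at or above the stop threshold.
// [[Rcpp::export]]
NumericVector ihh_site_cpp(const IntegerMatrix& haps, int focal,
                           const IntegerVector& rows,
                           const IntegerVector& groups0, double anchor,
                           double stop, double max_ext, double gap_cap,
                           const NumericVector& pos, int lo, int hi,
                           const LogicalVector& poly) {
  const int n = rows.size();
  const double denom = (double)n * (n - 1);
  const double p0 = pos[focal];
  double area = 0.0;
  bool hit_end = false;
  std::vector<int> gid, remap, count;
  int ngroups0 = 0;
  for (int i = 0; i < n; ++i)
    if (groups0[i] + 1 > ngroups0) ngroups0 = groups0[i] + 1;

  for (int side = -1; side <= 1; side += 2) {
    gid.assign(groups0.begin(), groups0.end());
    int ngroups = ngroups0;
    double prev_val = anchor, prev_pos = p0;
    int t = focal + side;
    while (true) {
      if (t < lo || t > hi) { hit_end = true; break; }
      if (std::abs(pos[t] - p0) > max_ext) break;
      if (!poly[t]) {
        // marker monomorphic across all haplotypes: no group can split,
        // the curve is flat over this interval
        double w = std::min(std::abs(pos[t] - prev_pos), gap_cap);
        area += prev_val * w;
        prev_pos = pos[t];
        t += side;
        continue;
      }
      remap.assign(2 * (size_t)ngroups, -1);
      int nnew = 0;
      for (int i = 0; i < n; ++i) {
        int key = 2 * gid[i] + haps(rows[i], t);
        if (remap[key] < 0) remap[key] = nnew++;
        gid[i] = remap[key];
      }
      ngroups = nnew;
      count.assign(ngroups, 0);
      for (int i = 0; i < n; ++i) count[gid[i]]++;
      double s = 0.0;
      for (int k = 0; k < ngroups; ++k) s += (double)count[k] * (count[k] - 1);
      double ehh = denom > 0 ? s / denom : 0.0;
      double w = std::min(std::abs(pos[t] - prev_pos), gap_cap);
      if (ehh < stop) {
        double drop = prev_val - ehh;
        double f = (drop > 0 && prev_val > stop) ? (prev_val - stop) / drop : 0.0;
        area += 0.5 * (prev_val + stop) * w * f;
        break;
      }
      area += 0.5 * (prev_val + ehh) * w;
      if (s == 0.0) break;  // all singletons; zero from here on
      prev_val = ehh;
      prev_pos = pos[t];
      t += side;
    }
  }
  return NumericVector::create(area, hit_end ? 1.0 : 0.0);
}

// Homozygosity of a partition of `rows` defined by the alleles at one
// column (used for the EHHS anchor value at the focal site itself).
// [[Rcpp::export]]
double group_homozygosity_cpp(const IntegerMatrix& haps, int col,
                              const IntegerVector& rows) {
  const int n = rows.size();
  if (n < 2) return NA_REAL;
  int c1 = 0;
  for (int i = 0; i < n; ++i) c1 += haps(rows[i], col);
  const int c0 = n - c1;
  return ((double)c0 * (c0 - 1) + (double)c1 * (c1 - 1)) / ((double)n * (n - 1));
}
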