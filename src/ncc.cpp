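#include <Rcpp.h>
using namespace Rcpp;

// Normalized cross-correlation of one template against a volume at many
// candidate centers.  The template is given as parallel vectors of integer
// offsets (relative to the center, any sign) and gray values, restricted to
// its support mask.  Centers are 1-based (x, y, z) array indices.  A center
// whose window leaves the volume, or whose window has zero variance, scores
// NA (the caller maps that to "not a candidate").
// [[Rcpp::export]]
NumericVector ncc_at_centers(const NumericVector& vol,
                             const IntegerVector& dim,
                             const IntegerVector& offx,
                             const IntegerVector& offy,
                             const IntegerVector& offz,
                             const NumericVector& tval,
                             const IntegerMatrix& centers) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t np = tval.size();
  const int nc = centers.nrow();

  // template-side moments are fixed across centers
  double sb = 0.0, sbb = 0.0;
  for (R_xlen_t p = 0; p < np; ++p) { sb += tval[p]; sbb += tval[p] * tval[p]; }
  const double mb = sb / np;
  const double ssb = sbb - np * mb * mb;

  // bounding box of the offsets for a cheap in-volume test
  int lox = 0, hix = 0, loy = 0, hiy = 0, loz = 0, hiz = 0;
  for (R_xlen_t p = 0; p < np; ++p) {
    if (offx[p] < lox) lox = offx[p]; if (offx[p] > hix) hix = offx[p];
    if (offy[p] < loy) loy = offy[p]; if (offy[p] > hiy) hiy = offy[p];
    if (offz[p] < loz) loz = offz[p]; if (offz[p] > hiz) hiz = offz[p];
  }

  NumericVector out(nc);
  const double* v = REAL(vol);
  for (int c = 0; c < nc; ++c) {
    const int cx = centers(c, 0), cy = centers(c, 1), cz = centers(c, 2);
    if (cx + lox < 1 || cx + hix > nx ||
        cy + loy < 1 || cy + hiy > ny ||
        cz + loz < 1 || cz + hiz > nz) {
      out[c] = NA_REAL;
      continue;
    }
    double sa = 0.0, saa = 0.0, sab = 0.0;
    for (R_xlen_t p = 0; p < np; ++p) {
      const R_xlen_t idx = (R_xlen_t)(cx + offx[p] - 1)
        + (R_xlen_t)nx * (cy + offy[p] - 1)
        + (R_xlen_t)nx * ny * (cz + offz[p] - 1);
      const double a = v[idx];
      sa += a; saa += a * a; sab += a * tval[p];
    }
    const double ma = sa / np;
    const double ssa = saa - np * ma * ma;
    if (ssa <= 1e-12 || ssb <= 1e-12) { out[c] = NA_REAL; continue; }
    out[c] = (sab - np * ma * mb) / std::sqrt(ssa * ssb);
  }
  return out;
}

// 26-connectivity labeling of a 3D logical mask (flood fill).  Returns an
// integer volume of component labels, 0 for background.
// [[Rcpp::export]]
IntegerVector label_components_26(const LogicalVector& mask,
                                  const IntegerVector& dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int z = cur / ((R_xlen_t)nx * ny);
      const int rem = cur - (R_xlen_t)z * nx * ny;
      const int y = rem / nx;
      const int x = rem - y * nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            const R_xlen_t nb = (R_xlen_t)xx + (R_xlen_t)nx * yy
              + (R_xlen_t)nx * ny * zz;
            if (mask[nb] && lab[nb] == 0) { lab[nb] = next; stack.push_back(nb); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
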