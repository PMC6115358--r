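#include "sorpflex.h"
using namespace Rcpp;

namespace {
inline void mi(double& dx, double& dy, double& dz,
               const double* box, const int* per) {
  if (per[0]) { dx -= box[0] * std::floor(dx / box[0] + 0.5); if (dx == -0.5*box[0]) dx += box[0]; }
  if (per[1]) { dy -= box[1] * std::floor(dy / box[1] + 0.5); if (dy == -0.5*box[1]) dy += box[1]; }
  if (per[2]) { dz -= box[2] * std::floor(dz / box[2] + 0.5); if (dz == -0.5*box[2]) dz += box[2]; }
}
}

// Geometric hydrogen-bond detection. One record per (donor H, acceptor) pair
// meeting the distance cut (O_to_H: H...acceptor; O_to_O: donorO...acceptor)
// and the angular cut (deviation from donorO-H...acceptor linearity at H, or
// the H-donorO-acceptor angle at the donor oxygen).
// [[Rcpp::export]]
IntegerMatrix cpp_detect_hb(NumericMatrix pos, NumericVector box, LogicalVector periodic,
                            IntegerVector donor_H, IntegerVector donor_O,
                            IntegerVector acceptors, IntegerVector molid,
                            double d_max, double angle_max_deg,
                            int dist_conv,      // 0 = O_to_H, 1 = O_to_O
                            int angle_at) {     // 0 = at H, 1 = at donor O
  int per[3]; double bx[3];
  for (int a = 0; a < 3; ++a) { per[a] = periodic[a]; bx[a] = box[a]; }
  int nd = donor_H.size(), na = acceptors.size();
  std::vector<int> rec;
  double d2max = d_max * d_max;
  double cos_lim = std::cos(angle_max_deg * M_PI / 180.0);
  for (int d = 0; d < nd; ++d) {
    int h = donor_H[d] - 1, o = donor_O[d] - 1;
    for (int t = 0; t < na; ++t) {
      int a = acceptors[t] - 1;
      if (molid[a] == molid[h]) continue;
      double ddx, ddy, ddz;
      if (dist_conv == 0) { ddx = pos(a,0)-pos(h,0); ddy = pos(a,1)-pos(h,1); ddz = pos(a,2)-pos(h,2); }
      else                { ddx = pos(a,0)-pos(o,0); ddy = pos(a,1)-pos(o,1); ddz = pos(a,2)-pos(o,2); }
      mi(ddx, ddy, ddz, bx, per);
      if (ddx*ddx + ddy*ddy + ddz*ddz > d2max) continue;
      double ca;
      if (angle_at == 0) {
        // vectors H->donorO and H->acceptor; linear HB has angle 180 deg
        double ux = pos(o,0)-pos(h,0), uy = pos(o,1)-pos(h,1), uz = pos(o,2)-pos(h,2);
        double wx = pos(a,0)-pos(h,0), wy = pos(a,1)-pos(h,1), wz = pos(a,2)-pos(h,2);
        mi(ux, uy, uz, bx, per); mi(wx, wy, wz, bx, per);
        double nu = std::sqrt(ux*ux+uy*uy+uz*uz), nw = std::sqrt(wx*wx+wy*wy+wz*wz);
        ca = -(ux*wx + uy*wy + uz*wz) / (nu*nw);   // cos(180 - angle) = deviation cosine
      } else {
        double ux = pos(h,0)-pos(o,0), uy = pos(h,1)-pos(o,1), uz = pos(h,2)-pos(o,2);
        double wx = pos(a,0)-pos(o,0), wy = pos(a,1)-pos(o,1), wz = pos(a,2)-pos(o,2);
        mi(ux, uy, uz, bx, per); mi(wx, wy, wz, bx, per);
        double nu = std::sqrt(ux*ux+uy*uy+uz*uz), nw = std::sqrt(wx*wx+wy*wy+wz*wz);
        ca = (ux*wx + uy*wy + uz*wz) / (nu*nw);
      }
      if (ca < cos_lim) continue;
      rec.push_back(o + 1); rec.push_back(h + 1); rec.push_back(a + 1);
    }
  }
  int nr = (int)rec.size() / 3;
  IntegerMatrix out(nr, 3);
  for (int r = 0; r < nr; ++r) {
    out(r,0) = rec[3*r]; out(r,1) = rec[3*r+1]; out(r,2) = rec[3*r+2];
  }
  colnames(out) = CharacterVector::create("donor_O", "donor_H", "acceptor");
  return out;
}

// intermolecular energy of an isolated pair of molecules: full LJ + bare
// (undamped, uncut) Coulomb at minimum image
// [[Rcpp::export]]
List cpp_pair_isolation_energy(NumericMatrix pos, NumericVector box, LogicalVector periodic,
                               NumericVector q, NumericVector sig, NumericVector eps,
                               IntegerVector idxA, IntegerVector idxB) {
  int per[3]; double bx[3];
  for (int a = 0; a < 3; ++a) { per[a] = periodic[a]; bx[a] = box[a]; }
  double elj = 0, ec = 0;
  for (int ii = 0; ii < idxA.size(); ++ii) {
    int i = idxA[ii] - 1;
    for (int jj = 0; jj < idxB.size(); ++jj) {
      int j = idxB[jj] - 1;
      double dx = pos(i,0)-pos(j,0), dy = pos(i,1)-pos(j,1), dz = pos(i,2)-pos(j,2);
      mi(dx, dy, dz, bx, per);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 < 1e-12) stop("overlapping sites in isolated pair");
      double r = std::sqrt(r2);
      double epsij = std::sqrt(eps[i] * eps[j]);
      if (epsij > 0) {
        double sij = 0.5 * (sig[i] + sig[j]);
        double sr6 = std::pow(sij * sij / r2, 3.0);
        elj += 4.0 * epsij * sr6 * (sr6 - 1.0);
      }
      ec += KCOUL * q[i] * q[j] / r;
    }
  }
  return List::create(_["lj"] = elj, _["coulomb"] = ec, _["total"] = elj + ec);
}

// raw pair-distance histogram between two site selections (counts, binned on
// [0, rmax)); same-molecule pairs optionally excluded; normalization in R
// [[Rcpp::export]]
NumericVector cpp_pair_histogram(NumericMatrix pos, NumericVector box, LogicalVector periodic,
                                 IntegerVector sel1, IntegerVector sel2,
                                 IntegerVector molid, bool exclude_same_mol,
                                 double rmax, int nbins) {
  int per[3]; double bx[3];
  for (int a = 0; a < 3; ++a) { per[a] = periodic[a]; bx[a] = box[a]; }
  NumericVector h(nbins);
  double w = rmax / nbins;
  for (int ii = 0; ii < sel1.size(); ++ii) {
    int i = sel1[ii] - 1;
    for (int jj = 0; jj < sel2.size(); ++jj) {
      int j = sel2[jj] - 1;
      if (i == j) continue;
      if (exclude_same_mol && molid[i] == molid[j]) continue;
      double dx = pos(i,0)-pos(j,0), dy = pos(i,1)-pos(j,1), dz = pos(i,2)-pos(j,2);
      mi(dx, dy, dz, bx, per);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (r >= rmax) continue;
      int b = (int)(r / w);
      if (b >= 0 && b < nbins) h[b] += 1.0;
    }
  }
  return h;
}

// Stochastic largest-inscribed-sphere pore size distribution.
// Returns one pore diameter per accepted void test point; sites are hard
// spheres of radius r_site; free radii are capped at half the smallest box
// length so reported spheres fit in the periodic cell.
// [[Rcpp::export]]
NumericVector cpp_psd_sample(NumericMatrix pos, NumericVector box, LogicalVector periodic,
                             double r_site, int n_centers, int n_points) {
  int per[3]; double bx[3];
  for (int a = 0; a < 3; ++a) { per[a] = periodic[a]; bx[a] = box[a]; }
  int n = pos.nrow();
  double rcap = 0.5 * std::min(bx[0], std::min(bx[1], bx[2]));

  auto free_radius = [&](double cx, double cy, double cz) {
    double rmin = rcap + r_site;
    for (int i = 0; i < n; ++i) {
      double dx = cx - pos(i,0), dy = cy - pos(i,1), dz = cz - pos(i,2);
      mi(dx, dy, dz, bx, per);
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (d < rmin) { rmin = d; if (rmin <= r_site) break; }
    }
    return std::min(rmin - r_site, rcap);
  };

  std::vector<double> cx(n_centers), cy(n_centers), cz(n_centers), cr(n_centers);
  for (int c = 0; c < n_centers; ++c) {
    cx[c] = unif_rand() * bx[0]; cy[c] = unif_rand() * bx[1]; cz[c] = unif_rand() * bx[2];
    cr[c] = free_radius(cx[c], cy[c], cz[c]);
  }

  std::vector<double> diam;
  diam.reserve(n_points);
  int tries = 0, max_tries = 50 * n_points;
  while ((int)diam.size() < n_points && tries < max_tries) {
    ++tries;
    double pxx = unif_rand() * bx[0], pyy = unif_rand() * bx[1], pzz = unif_rand() * bx[2];
    double rp = free_radius(pxx, pyy, pzz);
    if (rp <= 0.0) continue;             // inside a site: not void space
    double best = rp;
    for (int c = 0; c < n_centers; ++c) {
      if (cr[c] <= best) continue;
      double dx = pxx - cx[c], dy = pyy - cy[c], dz = pzz - cz[c];
      mi(dx, dy, dz, bx, per);
      if (dx*dx + dy*dy + dz*dz <= cr[c] * cr[c]) best = cr[c];
    }
    diam.push_back(2.0 * best);
  }
  return wrap(diam);
}
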