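#include "sorpflex.h"
using namespace Rcpp;

System parse_system(const List& packed) {
  System S;
  NumericMatrix pos = packed["pos"];
  S.n = pos.nrow();
  S.px.resize(S.n); S.py.resize(S.n); S.pz.resize(S.n);
  for (int i = 0; i < S.n; ++i) { S.px[i] = pos(i,0); S.py[i] = pos(i,1); S.pz[i] = pos(i,2); }
  S.q   = as<std::vector<double> >(packed["q"]);
  S.sig = as<std::vector<double> >(packed["sigma"]);
  S.eps = as<std::vector<double> >(packed["epsilon"]);
  S.mass= as<std::vector<double> >(packed["mass"]);
  std::vector<int> mid = as<std::vector<int> >(packed["molid"]);
  S.molid.resize(S.n);
  for (int i = 0; i < S.n; ++i) S.molid[i] = mid[i] - 1;
  LogicalVector fr = packed["frozen"];
  S.frozen.resize(S.n);
  for (int i = 0; i < S.n; ++i) S.frozen[i] = fr[i] ? 1 : 0;
  NumericVector bx = packed["box"];
  LogicalVector pb = packed["periodic"];
  for (int a = 0; a < 3; ++a) { S.box[a] = bx[a]; S.per[a] = pb[a]; }

  IntegerMatrix bidx = packed["bond_idx"]; NumericMatrix bpar = packed["bond_par"];
  for (int b = 0; b < bidx.nrow(); ++b) {
    S.b_i.push_back(bidx(b,0) - 1); S.b_j.push_back(bidx(b,1) - 1);
    S.b_k.push_back(bpar(b,0));     S.b_r0.push_back(bpar(b,1));
  }
  IntegerMatrix aidx = packed["angle_idx"]; NumericMatrix apar = packed["angle_par"];
  for (int a = 0; a < aidx.nrow(); ++a) {
    S.a_i.push_back(aidx(a,0) - 1); S.a_j.push_back(aidx(a,1) - 1); S.a_k.push_back(aidx(a,2) - 1);
    S.a_kt.push_back(apar(a,0));    S.a_t0.push_back(apar(a,1));
  }
  IntegerMatrix didx = packed["dihedral_idx"]; NumericMatrix dpar = packed["dihedral_par"];
  for (int d = 0; d < didx.nrow(); ++d) {
    S.d_i.push_back(didx(d,0) - 1); S.d_j.push_back(didx(d,1) - 1);
    S.d_k.push_back(didx(d,2) - 1); S.d_l.push_back(didx(d,3) - 1);
    std::array<double,6> c{}; c.fill(0.0);
    for (int m = 0; m < std::min(6, (int)dpar.ncol()); ++m) c[m] = dpar(d,m);
    S.d_c.push_back(c);
  }
  S.ex_start = as<std::vector<int> >(packed["excl_start"]);   // 0-based CSR, length n+1
  S.ex_idx   = as<std::vector<int> >(packed["excl_idx"]);
  IntegerMatrix cidx = packed["constraint_idx"]; NumericVector cd = packed["constraint_d"];
  for (int c = 0; c < cidx.nrow(); ++c) {
    S.c_i.push_back(cidx(c,0) - 1); S.c_j.push_back(cidx(c,1) - 1);
    S.c_d.push_back(cd[c]);
  }
  S.cutoff = as<double>(packed["cutoff"]);
  S.alpha  = as<double>(packed["alpha"]);
  S.dsf_setup();
  for (int i = 0; i < S.n; ++i)
    if (!std::isfinite(S.px[i]) || !std::isfinite(S.py[i]) || !std::isfinite(S.pz[i]))
      stop("non-finite coordinate at site %d", i + 1);
  return S;
}

void bonded_terms(const System& S, EnergyVirial& ev,
                  std::vector<double>* fx, std::vector<double>* fy,
                  std::vector<double>* fz) {
  // bonds: E = k (r - r0)^2
  for (size_t b = 0; b < S.b_i.size(); ++b) {
    int i = S.b_i[b], j = S.b_j[b];
    double dx = S.px[i] - S.px[j], dy = S.py[i] - S.py[j], dz = S.pz[i] - S.pz[j];
    S.min_image(dx, dy, dz);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dr = r - S.b_r0[b];
    ev.bonded += S.b_k[b] * dr * dr;
    if (fx) {
      double fmag = -2.0 * S.b_k[b] * dr / r;   // force on i along +dr vector
      double fxi = fmag * dx, fyi = fmag * dy, fzi = fmag * dz;
      (*fx)[i] += fxi; (*fy)[i] += fyi; (*fz)[i] += fzi;
      (*fx)[j] -= fxi; (*fy)[j] -= fyi; (*fz)[j] -= fzi;
      ev.w[0] += fxi * dx; ev.w[1] += fyi * dy; ev.w[2] += fzi * dz;
    }
  }
  // angles: E = k (theta - theta0)^2
  for (size_t a = 0; a < S.a_i.size(); ++a) {
    int i = S.a_i[a], j = S.a_j[a], k = S.a_k[a];
    double r1x = S.px[i]-S.px[j], r1y = S.py[i]-S.py[j], r1z = S.pz[i]-S.pz[j];
    double r2x = S.px[k]-S.px[j], r2y = S.py[k]-S.py[j], r2z = S.pz[k]-S.pz[j];
    S.min_image(r1x, r1y, r1z); S.min_image(r2x, r2y, r2z);
    double n1 = std::sqrt(r1x*r1x + r1y*r1y + r1z*r1z);
    double n2 = std::sqrt(r2x*r2x + r2y*r2y + r2z*r2z);
    double ct = (r1x*r2x + r1y*r2y + r1z*r2z) / (n1 * n2);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct), dth = th - S.a_t0[a];
    ev.bonded += S.a_kt[a] * dth * dth;
    if (fx) {
      // floor sin(theta) so the harmonic-in-theta force stays bounded through
      // near-linear configurations (the energy itself is regular there)
      double st = std::max(0.05, std::sqrt(std::max(0.0, 1.0 - ct * ct)));
      double dEdth = 2.0 * S.a_kt[a] * dth;
      double c = dEdth / st;  // -dE/d(cos th) chain handled below
      // dcos/dri etc.
      double dix = (r2x/(n1*n2)) - ct * r1x/(n1*n1);
      double diy = (r2y/(n1*n2)) - ct * r1y/(n1*n1);
      double diz = (r2z/(n1*n2)) - ct * r1z/(n1*n1);
      double dkx = (r1x/(n1*n2)) - ct * r2x/(n2*n2);
      double dky = (r1y/(n1*n2)) - ct * r2y/(n2*n2);
      double dkz = (r1z/(n1*n2)) - ct * r2z/(n2*n2);
      double fix = c * dix, fiy = c * diy, fiz = c * diz;
      double fkx = c * dkx, fky = c * dky, fkz = c * dkz;
      (*fx)[i] += fix; (*fy)[i] += fiy; (*fz)[i] += fiz;
      (*fx)[k] += fkx; (*fy)[k] += fky; (*fz)[k] += fkz;
      (*fx)[j] -= fix + fkx; (*fy)[j] -= fiy + fky; (*fz)[j] -= fiz + fkz;
      ev.w[0] += fix * r1x + fkx * r2x;
      ev.w[1] += fiy * r1y + fky * r2y;
      ev.w[2] += fiz * r1z + fkz * r2z;
    }
  }
  // dihedrals: E = sum_m c_m cos^m(phi)
  for (size_t d = 0; d < S.d_i.size(); ++d) {
    int i = S.d_i[d], j = S.d_j[d], k = S.d_k[d], l = S.d_l[d];
    double b1x=S.px[j]-S.px[i], b1y=S.py[j]-S.py[i], b1z=S.pz[j]-S.pz[i];
    double b2x=S.px[k]-S.px[j], b2y=S.py[k]-S.py[j], b2z=S.pz[k]-S.pz[j];
    double b3x=S.px[l]-S.px[k], b3y=S.py[l]-S.py[k], b3z=S.pz[l]-S.pz[k];
    S.min_image(b1x,b1y,b1z); S.min_image(b2x,b2y,b2z); S.min_image(b3x,b3y,b3z);
    double ax = b1y*b2z - b1z*b2y, ay = b1z*b2x - b1x*b2z, az = b1x*b2y - b1y*b2x;
    double bx_ = b2y*b3z - b2z*b3y, by_ = b2z*b3x - b2x*b3z, bz_ = b2x*b3y - b2y*b3x;
    double na = std::sqrt(ax*ax+ay*ay+az*az), nb = std::sqrt(bx_*bx_+by_*by_+bz_*bz_);
    if (na < 1e-10 || nb < 1e-10) continue;
    double ct = (ax*bx_ + ay*by_ + az*bz_) / (na*nb);
    ct = std::max(-1.0, std::min(1.0, ct));
    const std::array<double,6>& c = S.d_c[d];
    double e = 0.0, dEdc = 0.0, cp = 1.0;
    for (int m = 0; m < 6; ++m) {
      e += c[m] * cp;
      if (m < 5) dEdc += c[m+1] * (m+1) * cp;
      cp *= ct;
    }
    ev.bonded += e;
    if (fx && dEdc != 0.0) {
      // numerical gradient on the four sites (dihedrals are rare in the shipped
      // forcefields; robustness over speed)
      const double h = 1e-6;
      int idx[4] = {i, j, k, l};
      System& Sm = const_cast<System&>(S);
      for (int s = 0; s < 4; ++s) {
        double* comp[3] = {&Sm.px[idx[s]], &Sm.py[idx[s]], &Sm.pz[idx[s]]};
        for (int a2 = 0; a2 < 3; ++a2) {
          double orig = *comp[a2];
          double ep, em;
          auto eval = [&]() {
            double c1x=Sm.px[j]-Sm.px[i], c1y=Sm.py[j]-Sm.py[i], c1z=Sm.pz[j]-Sm.pz[i];
            double c2x=Sm.px[k]-Sm.px[j], c2y=Sm.py[k]-Sm.py[j], c2z=Sm.pz[k]-Sm.pz[j];
            double c3x=Sm.px[l]-Sm.px[k], c3y=Sm.py[l]-Sm.py[k], c3z=Sm.pz[l]-Sm.pz[k];
            S.min_image(c1x,c1y,c1z); S.min_image(c2x,c2y,c2z); S.min_image(c3x,c3y,c3z);
            double aax = c1y*c2z-c1z*c2y, aay = c1z*c2x-c1x*c2z, aaz = c1x*c2y-c1y*c2x;
            double abx = c2y*c3z-c2z*c3y, aby = c2z*c3x-c2x*c3z, abz = c2x*c3y-c2y*c3x;
            double nna = std::sqrt(aax*aax+aay*aay+aaz*aaz), nnb = std::sqrt(abx*abx+aby*aby+abz*abz);
            double cct = (aax*abx+aay*aby+aaz*abz)/(nna*nnb);
            cct = std::max(-1.0, std::min(1.0, cct));
            double ee = 0.0, ccp = 1.0;
            for (int m = 0; m < 6; ++m) { ee += c[m]*ccp; ccp *= cct; }
            return ee;
          };
          *comp[a2] = orig + h; ep = eval();
          *comp[a2] = orig - h; em = eval();
          *comp[a2] = orig;
          double f = -(ep - em) / (2*h);
          if (a2 == 0) (*fx)[idx[s]] += f;
          if (a2 == 1) (*fy)[idx[s]] += f;
          if (a2 == 2) (*fz)[idx[s]] += f;
        }
      }
    }
  }
}

EnergyVirial compute_energy_forces(const System& S,
                                   std::vector<double>* fx,
                                   std::vector<double>* fy,
                                   std::vector<double>* fz) {
  EnergyVirial ev;
  double rc2 = S.cutoff * S.cutoff;
  for (int i = 0; i < S.n; ++i) {
    for (int j = i + 1; j < S.n; ++j) {
      if (S.molid[i] == S.molid[j] && S.excluded(i, j)) continue;
      double dx = S.px[i]-S.px[j], dy = S.py[i]-S.py[j], dz = S.pz[i]-S.pz[j];
      S.min_image(dx, dy, dz);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 > rc2) continue;
      if (r2 < 1e-12 && (S.eps[i]*S.eps[j] > 0 || S.q[i]*S.q[j] != 0))
        stop("site overlap between %d and %d", i + 1, j + 1);
      double f_r = 0.0;
      pair_eval(S, i, j, r2, ev.lj, ev.coul, fx ? &f_r : nullptr);
      if (fx) {
        double fxi = f_r * dx, fyi = f_r * dy, fzi = f_r * dz;
        (*fx)[i] += fxi; (*fy)[i] += fyi; (*fz)[i] += fzi;
        (*fx)[j] -= fxi; (*fy)[j] -= fyi; (*fz)[j] -= fzi;
        ev.w[0] += fxi * dx; ev.w[1] += fyi * dy; ev.w[2] += fzi * dz;
      }
    }
  }
  bonded_terms(S, ev, fx, fy, fz);
  return ev;
}

double molecule_energy(const System& S, int s0, int s1,
                       const double* mx, const double* my, const double* mz) {
  double rc2 = S.cutoff * S.cutoff, elj = 0.0, ec = 0.0;
  for (int m = s0; m < s1; ++m) {
    for (int j = 0; j < S.n; ++j) {
      if (S.molid[j] == S.molid[s0]) continue;
      double dx = mx[m - s0] - S.px[j], dy = my[m - s0] - S.py[j], dz = mz[m - s0] - S.pz[j];
      S.min_image(dx, dy, dz);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 > rc2) continue;
      if (r2 < 1e-10) return 1e30;   // hard overlap -> effectively infinite
      pair_eval(S, m, j, r2, elj, ec, nullptr);
    }
  }
  return elj + ec;
}

// [[Rcpp::export]]
List cpp_total_energy(List packed) {
  System S = parse_system(packed);
  EnergyVirial ev = compute_energy_forces(S, nullptr, nullptr, nullptr);
  return List::create(_["lj"] = ev.lj, _["coulomb"] = ev.coul,
                      _["bonded"] = ev.bonded, _["total"] = ev.total());
}

// [[Rcpp::export]]
List cpp_forces(List packed) {
  System S = parse_system(packed);
  std::vector<double> fx(S.n, 0.0), fy(S.n, 0.0), fz(S.n, 0.0);
  EnergyVirial ev = compute_energy_forces(S, &fx, &fy, &fz);
  NumericMatrix F(S.n, 3);
  for (int i = 0; i < S.n; ++i) { F(i,0) = fx[i]; F(i,1) = fy[i]; F(i,2) = fz[i]; }
  return List::create(_["forces"] = F,
                      _["virial"] = NumericVector::create(ev.w[0], ev.w[1], ev.w[2]),
                      _["lj"] = ev.lj, _["coulomb"] = ev.coul,
                      _["bonded"] = ev.bonded, _["total"] = ev.total());
}

// single pair of sites: LJ (LB mixing) + DSF Coulomb at minimum-image distance
// [[Rcpp::export]]
double cpp_pair_energy(NumericVector r1, NumericVector r2,
                       NumericVector box, LogicalVector periodic,
                       double qi, double qj, double si, double sj,
                       double ei, double ej, double cutoff, double alpha) {
  System S;
  S.n = 2;
  S.px = {r1[0], r2[0]}; S.py = {r1[1], r2[1]}; S.pz = {r1[2], r2[2]};
  S.q = {qi, qj}; S.sig = {si, sj}; S.eps = {ei, ej};
  for (int a = 0; a < 3; ++a) { S.box[a] = box[a]; S.per[a] = periodic[a]; }
  S.cutoff = cutoff; S.alpha = alpha; S.dsf_setup();
  for (int c = 0; c < 3; ++c)
    if (!std::isfinite(r1[c]) || !std::isfinite(r2[c])) stop("non-finite coordinates");
  double dx = S.px[0]-S.px[1], dy = S.py[0]-S.py[1], dz = S.pz[0]-S.pz[1];
  S.min_image(dx, dy, dz);
  double r2sq = dx*dx + dy*dy + dz*dz;
  if (r2sq > cutoff * cutoff) return 0.0;
  if (r2sq < 1e-12 && (ei * ej > 0 || qi * qj != 0)) stop("site overlap");
  double elj = 0, ec = 0;
  pair_eval(S, 0, 1, r2sq, elj, ec, nullptr);
  return elj + ec;
}
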