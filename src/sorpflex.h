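#pragma once
#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>

// Internal units: nm, ps, K, e, kJ/mol, g/mol (the "molecular" unit system:
// accelerations in nm/ps^2 come out of F[kJ/mol/nm]/m[g/mol] with no factor).
constexpr double KB_KJMOL   = 0.0083144621;     // kJ mol-1 K-1
constexpr double KCOUL      = 138.935458;       // kJ mol-1 nm e-2
constexpr double PA_PER_KJMOLNM3 = 1.66053907e6; // 1 kJ/mol/nm3 expressed in Pa

struct System {
  int n = 0;
  std::vector<double> px, py, pz;          // positions, nm (unwrapped)
  std::vector<double> q, sig, eps, mass;
  std::vector<int>    molid;               // 0-based molecule index
  std::vector<char>   frozen;              // per-site immobile flag
  double box[3] = {0, 0, 0};
  bool   per[3] = {true, true, true};

  // bonded terms (0-based indices); bond E = k*(r-r0)^2, angle E = k*(th-th0)^2,
  // dihedral E = sum_m c_m cos^m(phi) (Ryckaert-Bellemans-style polynomial)
  std::vector<int> b_i, b_j;               std::vector<double> b_k, b_r0;
  std::vector<int> a_i, a_j, a_k;          std::vector<double> a_kt, a_t0;
  std::vector<int> d_i, d_j, d_k, d_l;     std::vector<std::array<double,6>> d_c;

  // nonbonded exclusions, CSR per site (sorted)
  std::vector<int> ex_start, ex_idx;

  // distance constraints (rigid groups expanded to all intragroup pairs)
  std::vector<int> c_i, c_j;               std::vector<double> c_d;

  // nonbonded model: LJ 12-6 truncated + damped shifted-force Coulomb
  double cutoff = 0.9, alpha = 2.0;
  double dsf_e_shift = 0.0, dsf_f_shift = 0.0;

  bool excluded(int i, int j) const {
    for (int t = ex_start[i]; t < ex_start[i + 1]; ++t)
      if (ex_idx[t] == j) return true;
    return false;
  }
  void min_image(double& dx, double& dy, double& dz) const {
    if (per[0]) { dx -= box[0] * std::floor(dx / box[0] + 0.5); if (dx == -0.5 * box[0]) dx += box[0]; }
    if (per[1]) { dy -= box[1] * std::floor(dy / box[1] + 0.5); if (dy == -0.5 * box[1]) dy += box[1]; }
    if (per[2]) { dz -= box[2] * std::floor(dz / box[2] + 0.5); if (dz == -0.5 * box[2]) dz += box[2]; }
  }
  double volume() const { return box[0] * box[1] * box[2]; }
  void dsf_setup() {
    double rc = cutoff;
    dsf_e_shift = std::erfc(alpha * rc) / rc;
    dsf_f_shift = dsf_e_shift / rc +
      2.0 * alpha / std::sqrt(M_PI) * std::exp(-alpha * alpha * rc * rc) / rc;
  }
};

System parse_system(const Rcpp::List& packed);

// pair LJ + DSF Coulomb energy at squared distance r2 (r2 <= cutoff^2 assumed
// checked by caller); also returns force magnitude / r in *for_r when non-null.
inline void pair_eval(const System& S, int i, int j, double r2,
                      double& elj, double& ecoul, double* for_r) {
  double r = std::sqrt(r2);
  double eL = 0.0, eC = 0.0, f = 0.0;
  double epsij = std::sqrt(S.eps[i] * S.eps[j]);
  if (epsij > 0.0) {
    double sij = 0.5 * (S.sig[i] + S.sig[j]);
    double sr2 = sij * sij / r2;
    double sr6 = sr2 * sr2 * sr2;
    eL = 4.0 * epsij * sr6 * (sr6 - 1.0);
    f += 24.0 * epsij * sr6 * (2.0 * sr6 - 1.0) / r2;
  }
  double qq = S.q[i] * S.q[j];
  if (qq != 0.0) {
    double kqq = KCOUL * qq;
    eC = kqq * (std::erfc(S.alpha * r) / r - S.dsf_e_shift + S.dsf_f_shift * (r - S.cutoff));
    double fr = std::erfc(S.alpha * r) / r2 +
      2.0 * S.alpha / std::sqrt(M_PI) * std::exp(-S.alpha * S.alpha * r2) / r -
      S.dsf_f_shift;
    f += kqq * fr / r;
  }
  elj += eL; ecoul += eC;
  if (for_r) *for_r = f;
}

struct EnergyVirial {
  double lj = 0, coul = 0, bonded = 0;
  double w[3] = {0, 0, 0};                 // per-axis virial sum f_a * dr_a
  double total() const { return lj + coul + bonded; }
};

// all-pairs nonbonded + bonded; forces optional (fx.. sized n, zeroed by caller)
EnergyVirial compute_energy_forces(const System& S,
                                   std::vector<double>* fx,
                                   std::vector<double>* fy,
                                   std::vector<double>* fz);

void bonded_terms(const System& S, EnergyVirial& ev,
                  std::vector<double>* fx, std::vector<double>* fy,
                  std::vector<double>* fz);

// energy of one molecule (contiguous site range [s0,s1)) with all sites outside
// that molecule; used by GCMC particle moves
double molecule_energy(const System& S, int s0, int s1,
                       const double* mx, const double* my, const double* mz);
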