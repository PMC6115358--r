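#include "sorpflex.h"
using namespace Rcpp;

// Grand canonical moves for rigid three-site water against an ideal-vapor
// reservoir (activity z = P/kBT). Host sites are never touched. Waters are
// stored after host sites as contiguous triplets, one molecule each; R
// rebuilds topology/exclusions from the returned arrays.

namespace {

void random_rotation(double R[3][3]) {
  // uniform quaternion from 4 normals
  double q0 = norm_rand(), q1 = norm_rand(), q2 = norm_rand(), q3 = norm_rand();
  double nq = std::sqrt(q0*q0 + q1*q1 + q2*q2 + q3*q3);
  q0 /= nq; q1 /= nq; q2 /= nq; q3 /= nq;
  R[0][0] = 1 - 2*(q2*q2 + q3*q3); R[0][1] = 2*(q1*q2 - q0*q3); R[0][2] = 2*(q1*q3 + q0*q2);
  R[1][0] = 2*(q1*q2 + q0*q3); R[1][1] = 1 - 2*(q1*q1 + q3*q3); R[1][2] = 2*(q2*q3 - q0*q1);
  R[2][0] = 2*(q1*q3 - q0*q2); R[2][1] = 2*(q2*q3 + q0*q1); R[2][2] = 1 - 2*(q1*q1 + q2*q2);
}

} // namespace

// [[Rcpp::export]]
List cpp_run_gcmc(List packed, int water_start,        // 1-based first water site (n+1 if none)
                  NumericMatrix wat_rel,               // 3x3 body-frame site positions
                  NumericVector wat_q, NumericVector wat_sig,
                  NumericVector wat_eps, NumericVector wat_mass,
                  double T, double z,                  // activity, nm^-3
                  int n_attempts, NumericVector probs, // insert, delete, translate, rotate
                  double dmax, double amax,
                  int trace_stride) {
  System S = parse_system(packed);
  int ws = water_start - 1;
  if ((S.n - ws) % 3 != 0) stop("water block is not a whole number of molecules");
  double beta = 1.0 / (KB_KJMOL * T);
  double V = S.volume();
  int host_mols = 0;
  for (int i = 0; i < ws; ++i) host_mols = std::max(host_mols, S.molid[i] + 1);

  int att[4] = {0,0,0,0}, acc[4] = {0,0,0,0};
  std::vector<int> nw_trace;
  std::vector<double> du_accum;           // accepted energy changes (diagnostics)
  double pcum[4];
  pcum[0] = probs[0];
  for (int k = 1; k < 4; ++k) pcum[k] = pcum[k-1] + probs[k];
  if (std::fabs(pcum[3] - 1.0) > 1e-9) stop("move probabilities must sum to 1");

  auto n_w = [&]() { return (S.n - ws) / 3; };
  auto mol_first_site = [&](int w) { return ws + 3 * w; };

  for (int a = 0; a < n_attempts; ++a) {
    double u = unif_rand();
    int kind = 0;
    while (kind < 3 && u > pcum[kind]) ++kind;
    ++att[kind];
    int N = n_w();

    if (kind == 0) {                        // insert
      double cx = unif_rand() * S.box[0], cy = unif_rand() * S.box[1], cz = unif_rand() * S.box[2];
      double R[3][3]; random_rotation(R);
      double nx[3], ny[3], nz[3];
      for (int s = 0; s < 3; ++s) {
        nx[s] = cx + R[0][0]*wat_rel(s,0) + R[0][1]*wat_rel(s,1) + R[0][2]*wat_rel(s,2);
        ny[s] = cy + R[1][0]*wat_rel(s,0) + R[1][1]*wat_rel(s,1) + R[1][2]*wat_rel(s,2);
        nz[s] = cz + R[2][0]*wat_rel(s,0) + R[2][1]*wat_rel(s,1) + R[2][2]*wat_rel(s,2);
      }
      // append trial sites
      int molnew = host_mols + N;
      for (int s = 0; s < 3; ++s) {
        S.px.push_back(nx[s]); S.py.push_back(ny[s]); S.pz.push_back(nz[s]);
        S.q.push_back(wat_q[s]); S.sig.push_back(wat_sig[s]); S.eps.push_back(wat_eps[s]);
        S.mass.push_back(wat_mass[s]); S.molid.push_back(molnew); S.frozen.push_back(0);
      }
      S.n += 3;
      double dU = molecule_energy(S, S.n - 3, S.n, &S.px[S.n-3], &S.py[S.n-3], &S.pz[S.n-3]);
      double pacc = (dU >= 1e29) ? 0.0 : std::min(1.0, z * V / (N + 1) * std::exp(-beta * dU));
      if (unif_rand() < pacc) { ++acc[0]; du_accum.push_back(dU); }
      else {
        for (int s = 0; s < 3; ++s) {
          S.px.pop_back(); S.py.pop_back(); S.pz.pop_back();
          S.q.pop_back(); S.sig.pop_back(); S.eps.pop_back();
          S.mass.pop_back(); S.molid.pop_back(); S.frozen.pop_back();
        }
        S.n -= 3;
      }
    } else if (kind == 1 && N > 0) {        // delete (empty system: rejected, no-op)
      int w = (int)std::floor(unif_rand() * N); if (w == N) w = N - 1;
      int s0 = mol_first_site(w);
      double U_old = molecule_energy(S, s0, s0 + 3, &S.px[s0], &S.py[s0], &S.pz[s0]);
      double pacc = std::min(1.0, N / (z * V) * std::exp(beta * U_old));
      if (unif_rand() < pacc) {
        ++acc[1]; du_accum.push_back(-U_old);
        // move last molecule into the gap, keep triplet layout
        int last = mol_first_site(N - 1);
        if (last != s0)
          for (int s = 0; s < 3; ++s) {
            S.px[s0+s] = S.px[last+s]; S.py[s0+s] = S.py[last+s]; S.pz[s0+s] = S.pz[last+s];
            S.q[s0+s] = S.q[last+s]; S.sig[s0+s] = S.sig[last+s]; S.eps[s0+s] = S.eps[last+s];
            S.mass[s0+s] = S.mass[last+s];
          }
        for (int s = 0; s < 3; ++s) {
          S.px.pop_back(); S.py.pop_back(); S.pz.pop_back();
          S.q.pop_back(); S.sig.pop_back(); S.eps.pop_back();
          S.mass.pop_back(); S.molid.pop_back(); S.frozen.pop_back();
        }
        S.n -= 3;
      }
    } else if (kind >= 2 && N > 0) {        // translate / rotate
      int w = (int)std::floor(unif_rand() * N); if (w == N) w = N - 1;
      int s0 = mol_first_site(w);
      double U_old = molecule_energy(S, s0, s0 + 3, &S.px[s0], &S.py[s0], &S.pz[s0]);
      double nx[3], ny[3], nz[3];
      if (kind == 2) {
        double ddx = (2*unif_rand() - 1) * dmax, ddy = (2*unif_rand() - 1) * dmax,
               ddz = (2*unif_rand() - 1) * dmax;
        for (int s = 0; s < 3; ++s) { nx[s] = S.px[s0+s] + ddx; ny[s] = S.py[s0+s] + ddy; nz[s] = S.pz[s0+s] + ddz; }
      } else {
        // rotate about molecular COM by uniform axis, uniform angle in [-amax, amax]
        double ux, uy, uz, nn;
        do { ux = norm_rand(); uy = norm_rand(); uz = norm_rand();
             nn = std::sqrt(ux*ux + uy*uy + uz*uz); } while (nn < 1e-12);
        ux /= nn; uy /= nn; uz /= nn;
        double th = (2*unif_rand() - 1) * amax;
        double c = std::cos(th), sgn = std::sin(th), t = 1 - c;
        double R[3][3] = {
          {t*ux*ux + c,     t*ux*uy - sgn*uz, t*ux*uz + sgn*uy},
          {t*ux*uy + sgn*uz, t*uy*uy + c,     t*uy*uz - sgn*ux},
          {t*ux*uz - sgn*uy, t*uy*uz + sgn*ux, t*uz*uz + c}};
        double cmx = 0, cmy = 0, cmz = 0, msum = 0;
        for (int s = 0; s < 3; ++s) {
          cmx += S.mass[s0+s]*S.px[s0+s]; cmy += S.mass[s0+s]*S.py[s0+s];
          cmz += S.mass[s0+s]*S.pz[s0+s]; msum += S.mass[s0+s];
        }
        cmx /= msum; cmy /= msum; cmz /= msum;
        for (int s = 0; s < 3; ++s) {
          double rx = S.px[s0+s]-cmx, ry = S.py[s0+s]-cmy, rz = S.pz[s0+s]-cmz;
          nx[s] = cmx + R[0][0]*rx + R[0][1]*ry + R[0][2]*rz;
          ny[s] = cmy + R[1][0]*rx + R[1][1]*ry + R[1][2]*rz;
          nz[s] = cmz + R[2][0]*rx + R[2][1]*ry + R[2][2]*rz;
        }
      }
      double U_new = molecule_energy(S, s0, s0 + 3, nx, ny, nz);
      double dU = U_new - U_old;
      double pacc = (U_new >= 1e29) ? 0.0 : std::min(1.0, std::exp(-beta * dU));
      if (unif_rand() < pacc) {
        ++acc[kind];
        for (int s = 0; s < 3; ++s) { S.px[s0+s] = nx[s]; S.py[s0+s] = ny[s]; S.pz[s0+s] = nz[s]; }
      }
    }
    if (trace_stride > 0 && ((a + 1) % trace_stride) == 0) nw_trace.push_back(n_w());
  }

  int NW = n_w();
  NumericMatrix wpos(NW * 3, 3);
  for (int i = 0; i < NW * 3; ++i) {
    wpos(i,0) = S.px[ws+i]; wpos(i,1) = S.py[ws+i]; wpos(i,2) = S.pz[ws+i];
  }
  IntegerVector attempted(4), accepted(4);
  for (int k = 0; k < 4; ++k) { attempted[k] = att[k]; accepted[k] = acc[k]; }
  attempted.names() = CharacterVector::create("insert","delete","translate","rotate");
  accepted.names() = CharacterVector::create("insert","delete","translate","rotate");
  return List::create(_["water_pos"] = wpos, _["n_water"] = NW,
                      _["attempted"] = attempted, _["accepted"] = accepted,
                      _["nw_trace"] = wrap(nw_trace));
}
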