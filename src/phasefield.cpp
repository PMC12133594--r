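// Core numerics of the 3D multiphase-field monolayer model.
//
// Each cell i carries a phase field phi_i on a grid that is periodic in x
// and y and bounded in z (no-flux walls; the substrate sits at the bottom
// as a static field phi_w).  The free energy has Cahn-Hilliard bulk +
// gradient terms (cortex tension gamma, interface width lambda), a soft
// volume constraint (mu, V0), cell-cell and cell-substrate repulsion
// (kappa) and adhesion (omega) couplings.  Gradient-square terms are
// discretized as sums over grid links (forward differences), so the
// 7-point laplacian used in the functional derivative is the exact
// gradient of the discrete energy.  Dynamics: overdamped translation
// driven by the interaction stress, relaxational interface dynamics, and
// contact-inhibition-of-locomotion polarity with rotational noise.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz, nc;
  double h;   // a0
  std::vector<int> xp, xm, yp, ym;  // periodic neighbour tables
  Grid(int nx_, int ny_, int nz_, int nc_, double h_)
      : nx(nx_), ny(ny_), nz(nz_), nc(nc_), h(h_),
        xp(nx_), xm(nx_), yp(ny_), ym(ny_) {
    for (int i = 0; i < nx; ++i) { xp[i] = (i + 1) % nx; xm[i] = (i + nx - 1) % nx; }
    for (int j = 0; j < ny; ++j) { yp[j] = (j + 1) % ny; ym[j] = (j + ny - 1) % ny; }
  }
  inline int n() const { return nx * ny * nz; }
  inline int idx(int i, int j, int k) const { return i + nx * (j + ny * k); }
};

// 7-point laplacian with periodic x,y and no-flux z (out-of-domain links
// dropped, the exact gradient of the link energy)
void laplacian(const Grid& g, const double* f, double* out) {
  const double ih2 = 1.0 / (g.h * g.h);
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        const int id = g.idx(i, j, k);
        double acc = 0.0;
        acc += f[g.idx(g.xp[i], j, k)] - f[id];
        acc += f[g.idx(g.xm[i], j, k)] - f[id];
        acc += f[g.idx(i, g.yp[j], k)] - f[id];
        acc += f[g.idx(i, g.ym[j], k)] - f[id];
        if (k + 1 < g.nz) acc += f[g.idx(i, j, k + 1)] - f[id];
        if (k > 0)        acc += f[g.idx(i, j, k - 1)] - f[id];
        out[id] = acc * ih2;
      }
}

// central-difference gradient (clamped one-sided at z walls)
inline void gradAt(const Grid& g, const double* f, int i, int j, int k,
                   double& gx, double& gy, double& gz) {
  const double i2h = 1.0 / (2.0 * g.h);
  gx = (f[g.idx(g.xp[i], j, k)] - f[g.idx(g.xm[i], j, k)]) * i2h;
  gy = (f[g.idx(i, g.yp[j], k)] - f[g.idx(i, g.ym[j], k)]) * i2h;
  const int kp = (k + 1 < g.nz) ? k + 1 : k;
  const int km = (k > 0) ? k - 1 : k;
  gz = (f[g.idx(i, j, kp)] - f[g.idx(i, j, km)]) / ((kp - km) * g.h);
}

// link-based gradient-square sum: sum over forward links of (df)^2 / h^2
double linkGradSq(const Grid& g, const double* f) {
  double acc = 0.0;
  const double ih2 = 1.0 / (g.h * g.h);
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        const int id = g.idx(i, j, k);
        double d;
        d = f[g.idx(g.xp[i], j, k)] - f[id]; acc += d * d;
        d = f[g.idx(i, g.yp[j], k)] - f[id]; acc += d * d;
        if (k + 1 < g.nz) { d = f[g.idx(i, j, k + 1)] - f[id]; acc += d * d; }
      }
  return acc * ih2;
}

// link-based cross-gradient sum of two fields
double linkGradDot(const Grid& g, const double* f, const double* w) {
  double acc = 0.0;
  const double ih2 = 1.0 / (g.h * g.h);
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        const int id = g.idx(i, j, k);
        acc += (f[g.idx(g.xp[i], j, k)] - f[id]) * (w[g.idx(g.xp[i], j, k)] - w[id]);
        acc += (f[g.idx(i, g.yp[j], k)] - f[id]) * (w[g.idx(i, g.yp[j], k)] - w[id]);
        if (k + 1 < g.nz)
          acc += (f[g.idx(i, j, k + 1)] - f[id]) * (w[g.idx(i, j, k + 1)] - w[id]);
      }
  return acc * ih2;
}

struct Params {
  std::vector<double> gamma, mu, omcc, omcs, kcc, kcs, zS, zQ, alpha, Dr, taupol;
  double lambda, Gamma, xi, dt, V0, h;
};

Params readParams(const List& par, double lambda, double Gamma, double xi,
                  double dt, double V0, double h) {
  Params p;
  auto getv = [&](const char* nm) {
    NumericVector v = par[nm];
    return std::vector<double>(v.begin(), v.end());
  };
  p.gamma = getv("gamma"); p.mu = getv("mu");
  p.omcc = getv("omegaCC"); p.omcs = getv("omegaCS");
  p.kcc = getv("kappaCC"); p.kcs = getv("kappaCS");
  p.zS = getv("zetaS"); p.zQ = getv("zetaQ");
  p.alpha = getv("alpha"); p.Dr = getv("Dr"); p.taupol = getv("tauPol");
  p.lambda = lambda; p.Gamma = Gamma; p.xi = xi; p.dt = dt; p.V0 = V0; p.h = h;
  return p;
}

// Scratch holding per-step fields; dF overwrites the laplacian storage.
struct Fields {
  std::vector<double> sumPhi2, sumKPhi2, sumLap, dF;  // dF: nc * n
  std::vector<double> phiw2, well;
  std::vector<double> V;                       // per-cell integral of phi^2
  std::vector<double> S;                       // per-cell 9 (row-major 3x3)
  std::vector<double> Piso;
  std::vector<double> PiS;                     // 6 * n (xx,yy,zz,xy,xz,yz)
  double Qw[9];
  double zQsum;
  double energy;
};

// substrate-dependent precomputations (static over a run)
// The substrate repulsion uses phi_i^2 phi_w^2; the substrate adhesion is
// a contact well -(omega_cs/lambda^2) int phi_i^2 W(phi_w) with
// W = 16 phi_w^2 (1 - phi_w)^2, peaked on the substrate surface band.  A
// well (rather than the cross-gradient form used between cells) keeps the
// adhesive force proportional to the cell's own presence, so no spurious
// wetting layer forms away from the cell.
void substratePrep(const Grid& g, const double* phiw, Fields& F) {
  const int n = g.n();
  F.phiw2.resize(n); F.well.resize(n);
  for (int q = 0; q < n; ++q) {
    const double w = phiw[q];
    F.phiw2[q] = w * w;
    const double ww = w * (1.0 - w);
    F.well[q] = 16.0 * ww * ww;
  }
}

// Pass 1 + 2: laplacians, volumes, shape tensors, functional derivatives,
// interaction-stress fields, total energy.
void computeFields(const Grid& g, const double* phi, const double* phiw,
                   const Params& p, Fields& F) {
  const int n = g.n(), nc = g.nc;
  const double h3 = p.h * p.h * p.h;
  F.sumPhi2.assign(n, 0.0);
  F.sumKPhi2.assign(n, 0.0);
  F.sumLap.assign(n, 0.0);
  F.dF.resize(static_cast<size_t>(nc) * n);
  F.V.assign(nc, 0.0);
  F.S.assign(nc * 9, 0.0);
  F.Piso.assign(n, 0.0);
  F.PiS.assign(static_cast<size_t>(6) * n, 0.0);
  F.energy = 0.0;

  // Q_w for stress fibres along x (upsilon = 0), d = 3:
  // Q = (d/(d-1)) (n x n - |n|^2/d I) -> diag(1, -1/2, -1/2)
  for (int q = 0; q < 9; ++q) F.Qw[q] = 0.0;
  F.Qw[0] = 1.0; F.Qw[4] = -0.5; F.Qw[8] = -0.5;
  F.zQsum = 0.0;
  for (int c = 0; c < nc; ++c) F.zQsum += p.zQ[c];

  // pass 1: per-cell laplacian (stored in dF slots), volume, shape tensor,
  // global sums, per-cell local energy pieces
  for (int c = 0; c < nc; ++c) {
    const double* f = phi + static_cast<size_t>(c) * n;
    double* lap = F.dF.data() + static_cast<size_t>(c) * n;
    laplacian(g, f, lap);
    double V = 0.0, Gt[6] = {0, 0, 0, 0, 0, 0};  // xx,yy,zz,xy,xz,yz
    double ebulk = 0.0;
    for (int k = 0; k < g.nz; ++k)
      for (int j = 0; j < g.ny; ++j)
        for (int i = 0; i < g.nx; ++i) {
          const int id = g.idx(i, j, k);
          const double v = f[id];
          V += v * v;
          F.sumPhi2[id] += v * v;
          F.sumKPhi2[id] += p.kcc[c] * v * v;
          F.sumLap[id] += lap[id];
          const double om = v * (1.0 - v);
          ebulk += 4.0 * om * om;
          double gx, gy, gz;
          gradAt(g, f, i, j, k, gx, gy, gz);
          Gt[0] += gx * gx; Gt[1] += gy * gy; Gt[2] += gz * gz;
          Gt[3] += gx * gy; Gt[4] += gx * gz; Gt[5] += gy * gz;
        }
    V *= h3;
    F.V[c] = V;
    const double tr = (Gt[0] + Gt[1] + Gt[2]) * h3;
    double* S = F.S.data() + c * 9;
    S[0] = -Gt[0] * h3 + tr / 3.0; S[4] = -Gt[1] * h3 + tr / 3.0;
    S[8] = -Gt[2] * h3 + tr / 3.0;
    S[1] = S[3] = -Gt[3] * h3; S[2] = S[6] = -Gt[4] * h3;
    S[5] = S[7] = -Gt[5] * h3;
    // tension (bulk + link gradient) and volume-constraint energy
    F.energy += (p.gamma[c] / p.lambda) *
        (ebulk * h3 + p.lambda * p.lambda * linkGradSq(g, f) * h3);
    const double dv = 1.0 - V / p.V0;
    F.energy += p.mu[c] * dv * dv;
  }

  // pass 2: functional derivatives (overwrite laplacian storage), stress
  // fields and the interaction energies
  for (int c = 0; c < nc; ++c) {
    const double* f = phi + static_cast<size_t>(c) * n;
    double* lap = F.dF.data() + static_cast<size_t>(c) * n;  // becomes dF
    const double cg = p.gamma[c] / p.lambda;
    const double volPref = -4.0 * p.mu[c] / p.V0 * (1.0 - F.V[c] / p.V0);
    const double il2 = 1.0 / (p.lambda * p.lambda);
    const double kcsl = 2.0 * p.kcs[c] * il2;
    double erep = 0.0, erepw = 0.0, ewell = 0.0;
    for (int q = 0; q < n; ++q) {
      const double v = f[q];
      const double v2 = v * v;
      const double others = F.sumPhi2[q] - v2;
      const double kothers = F.sumKPhi2[q] - p.kcc[c] * v2;
      const double d =
          cg * 8.0 * v * (1.0 - v) * (1.0 - 2.0 * v)
          - 2.0 * p.gamma[c] * p.lambda * lap[q]
          + volPref * v
          // exact gradient of the double-sum repulsion energy:
          // (2/l^2) phi [kappa_c * sum_{j!=c} phi_j^2 + sum_{j!=c} kappa_j phi_j^2]
          + 2.0 * il2 * v * (p.kcc[c] * others + kothers)
          - 2.0 * p.omcc[c] * (F.sumLap[q] - lap[q])
          + kcsl * v * F.phiw2[q]
          - 2.0 * p.omcs[c] * il2 * v * F.well[q];
      erep += v2 * others;
      erepw += v2 * F.phiw2[q];
      ewell += v2 * F.well[q];
      F.Piso[q] -= d;
      lap[q] = d;
    }
    F.energy += p.kcc[c] * il2 * erep * h3 + p.kcs[c] * il2 * erepw * h3
              - p.omcs[c] * il2 * ewell * h3;
  }

  // active shape stress field: sum_i -zS_i phi_i S_i
  for (int c = 0; c < nc; ++c) {
    if (p.zS[c] == 0.0) continue;
    const double* f = phi + static_cast<size_t>(c) * n;
    const double* S = F.S.data() + c * 9;
    const double s6[6] = {S[0], S[4], S[8], S[1], S[2], S[5]};
    for (int q = 0; q < n; ++q) {
      const double w = -p.zS[c] * f[q];
      F.PiS[q] += w * s6[0];
      F.PiS[n + q] += w * s6[1];
      F.PiS[2 * n + q] += w * s6[2];
      F.PiS[3 * n + q] += w * s6[3];
      F.PiS[4 * n + q] += w * s6[4];
      F.PiS[5 * n + q] += w * s6[5];
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".pf_fields")]]
List pf_fields(NumericVector phi, NumericVector phiw, IntegerVector dims,
               List cellParams, double a0, double lambda, double Gamma,
               double xi, double V0) {
  Grid g(dims[0], dims[1], dims[2], dims[3], a0);
  const int n = g.n(), nc = g.nc;
  Params p = readParams(cellParams, lambda, Gamma, xi, 0.0, V0, a0);
  Fields F;
  substratePrep(g, REAL(phiw), F);
  computeFields(g, REAL(phi), REAL(phiw), p, F);

  // adhesion energies (exact link sums, via the summed field)
  const double h3 = a0 * a0 * a0;
  std::vector<double> phiTot(n, 0.0);
  for (int c = 0; c < nc; ++c) {
    const double* f = REAL(phi) + static_cast<size_t>(c) * n;
    for (int q = 0; q < n; ++q) phiTot[q] += f[q];
  }
  double eadh = 0.0;
  for (int c = 0; c < nc; ++c) {
    const double* f = REAL(phi) + static_cast<size_t>(c) * n;
    if (p.omcc[c] != 0.0)
      eadh += p.omcc[c] *
          (linkGradDot(g, f, phiTot.data()) - linkGradSq(g, f)) * h3;
  }
  F.energy += eadh;

  // per-cell interaction force F_int = -int Pi . grad(phi_i) dx
  NumericMatrix Fint(nc, 3);
  for (int c = 0; c < nc; ++c) {
    const double* f = REAL(phi) + static_cast<size_t>(c) * n;
    double fx = 0, fy = 0, fz = 0;
    for (int k = 0; k < g.nz; ++k)
      for (int j = 0; j < g.ny; ++j)
        for (int i = 0; i < g.nx; ++i) {
          const int id = g.idx(i, j, k);
          double gx, gy, gz;
          gradAt(g, f, i, j, k, gx, gy, gz);
          const double piso = F.Piso[id];
          const double qw = -p.zQ[c] * REAL(phiw)[id];
          const double pxx = piso + F.PiS[id] + qw * F.Qw[0];
          const double pyy = piso + F.PiS[n + id] + qw * F.Qw[4];
          const double pzz = piso + F.PiS[2 * n + id];  // fibres act in-plane
          const double pxy = F.PiS[3 * n + id];
          const double pxz = F.PiS[4 * n + id];
          const double pyz = F.PiS[5 * n + id];
          fx -= (pxx * gx + pxy * gy + pxz * gz);
          fy -= (pxy * gx + pyy * gy + pyz * gz);
          fz -= (pxz * gx + pyz * gy + pzz * gz);
        }
    Fint(c, 0) = fx * h3; Fint(c, 1) = fy * h3; Fint(c, 2) = fz * h3;
  }

  NumericVector dF(F.dF.begin(), F.dF.end());
  dF.attr("dim") = dims;
  NumericVector Piso(F.Piso.begin(), F.Piso.end());
  Piso.attr("dim") = IntegerVector::create(dims[0], dims[1], dims[2]);
  NumericVector PiS(F.PiS.begin(), F.PiS.end());
  PiS.attr("dim") = IntegerVector::create(dims[0], dims[1], dims[2], 6);
  NumericMatrix S(9, nc);
  for (int c = 0; c < nc; ++c)
    for (int q = 0; q < 9; ++q) S(q, c) = F.S[c * 9 + q];
  return List::create(_["dF"] = dF, _["energy"] = F.energy,
                      _["V"] = NumericVector(F.V.begin(), F.V.end()),
                      _["S"] = S, _["Piso"] = Piso, _["PiS"] = PiS,
                      _["zQsum"] = F.zQsum, _["Fint"] = Fint);
}

// [[Rcpp::export(name = ".pf_run")]]
List pf_run(NumericVector phi0, NumericVector theta0, NumericVector phiw,
            IntegerVector dims, List cellParams, double a0, double lambda,
            double Gamma, double xi, double dt, double V0, int nsteps) {
  Grid g(dims[0], dims[1], dims[2], dims[3], a0);
  const int n = g.n(), nc = g.nc;
  const double h3 = a0 * a0 * a0;
  Params p = readParams(cellParams, lambda, Gamma, xi, dt, V0, a0);

  std::vector<double> phi(REAL(phi0), REAL(phi0) + static_cast<size_t>(nc) * n);
  std::vector<double> theta(REAL(theta0), REAL(theta0) + nc);
  const double* pw = REAL(phiw);

  Fields F;
  substratePrep(g, pw, F);

  // cell-cell adhesion energy needs the sum field; keep one scratch field
  std::vector<double> phiTot(n);

  NumericVector energy(nsteps);
  // diagnostics: step, id, V, contact, cx, cy, cz, Tx, Ty, Tz, vx, vy, vz, theta
  NumericMatrix diag(static_cast<size_t>(nsteps) * nc, 14);
  std::vector<double> newphi(n);
  int errStep = -1;

  for (int s = 0; s < nsteps; ++s) {
    computeFields(g, phi.data(), pw, p, F);

    // adhesion energy via total field (omcc may differ per cell)
    for (int q = 0; q < n; ++q) phiTot[q] = 0.0;
    for (int c = 0; c < nc; ++c) {
      const double* f = phi.data() + static_cast<size_t>(c) * n;
      for (int q = 0; q < n; ++q) phiTot[q] += f[q];
    }
    double eadh = 0.0;
    for (int c = 0; c < nc; ++c) {
      const double* f = phi.data() + static_cast<size_t>(c) * n;
      if (p.omcc[c] != 0.0)
        eadh += p.omcc[c] * (linkGradDot(g, f, phiTot.data()) - linkGradSq(g, f)) * h3;
    }
    energy[s] = F.energy + eadh;

    // forces, velocities, update
    for (int c = 0; c < nc; ++c) {
      const double* f = phi.data() + static_cast<size_t>(c) * n;
      double fx = 0, fy = 0, fz = 0;
      double cxs = 0, cxc = 0, cys = 0, cyc = 0, cz = 0, mass = 0, contact = 0;
      const double twoPi = 2.0 * M_PI;
      for (int k = 0; k < g.nz; ++k)
        for (int j = 0; j < g.ny; ++j)
          for (int i = 0; i < g.nx; ++i) {
            const int id = g.idx(i, j, k);
            const double v = f[id];
            double gx, gy, gz;
            gradAt(g, f, i, j, k, gx, gy, gz);
            const double piso = F.Piso[id];
            const double qw = -p.zQ[c] * pw[id];
            const double pxx = piso + F.PiS[id] + qw * F.Qw[0];
            const double pyy = piso + F.PiS[n + id] + qw * F.Qw[4];
            const double pzz = piso + F.PiS[2 * n + id];  // fibres act in-plane
            const double pxy = F.PiS[3 * n + id];
            const double pxz = F.PiS[4 * n + id];
            const double pyz = F.PiS[5 * n + id];
            fx -= (pxx * gx + pxy * gy + pxz * gz);
            fy -= (pxy * gx + pyy * gy + pyz * gz);
            fz -= (pxz * gx + pyz * gy + pzz * gz);
            const double w = v * v;
            mass += w;
            const double ax = twoPi * (i + 0.5) / g.nx;
            const double ay = twoPi * (j + 0.5) / g.ny;
            cxs += w * std::sin(ax); cxc += w * std::cos(ax);
            cys += w * std::sin(ay); cyc += w * std::cos(ay);
            cz += w * (k + 0.5) * a0;
            contact += w * F.phiw2[id];
          }
      fx *= h3; fy *= h3; fz *= h3;
      const double px = std::cos(theta[c]), py = std::sin(theta[c]);
      // advection CFL cap: protects the explicit upwind scheme against the
      // large transient repulsion of overlapping initial droplets
      const double vcap = 0.4 * a0 / dt;
      auto clamp = [vcap](double v) {
        return v > vcap ? vcap : (v < -vcap ? -vcap : v);
      };
      const double vx = clamp((p.alpha[c] * px + fx) / p.xi);
      const double vy = clamp((p.alpha[c] * py + fy) / p.xi);
      const double vz = clamp(fz / p.xi);

      // circular centre of mass for the periodic axes; +0.5 aligns the
      // value with 1-based pixel indices
      double cx = std::atan2(cxs / mass, cxc / mass) / twoPi * g.nx;
      if (cx < 0) cx += g.nx;
      double cy = std::atan2(cys / mass, cyc / mass) / twoPi * g.ny;
      if (cy < 0) cy += g.ny;
      cx = (cx + 0.5) * a0; cy = (cy + 0.5) * a0;
      cz /= mass;

      const size_t row = static_cast<size_t>(s) * nc + c;
      diag(row, 0) = s + 1; diag(row, 1) = c + 1;
      diag(row, 2) = F.V[c]; diag(row, 3) = contact * h3;
      diag(row, 4) = cx; diag(row, 5) = cy; diag(row, 6) = cz;
      diag(row, 7) = fx; diag(row, 8) = fy; diag(row, 9) = fz;
      diag(row, 10) = vx; diag(row, 11) = vy; diag(row, 12) = vz;
      diag(row, 13) = theta[c];

      // advect (first-order upwind, rigid per-cell velocity) + relax
      const double* dFc = F.dF.data() + static_cast<size_t>(c) * n;
      double maxAbs = 0.0;
      for (int k = 0; k < g.nz; ++k)
        for (int j = 0; j < g.ny; ++j)
          for (int i = 0; i < g.nx; ++i) {
            const int id = g.idx(i, j, k);
            double adv = 0.0;
            if (vx > 0) adv += vx * (f[id] - f[g.idx(g.xm[i], j, k)]) / a0;
            else if (vx < 0) adv += vx * (f[g.idx(g.xp[i], j, k)] - f[id]) / a0;
            if (vy > 0) adv += vy * (f[id] - f[g.idx(i, g.ym[j], k)]) / a0;
            else if (vy < 0) adv += vy * (f[g.idx(i, g.yp[j], k)] - f[id]) / a0;
            if (vz > 0) adv += vz * (f[id] - f[g.idx(i, j, k > 0 ? k - 1 : k)]) / a0;
            else if (vz < 0) adv += vz * (f[g.idx(i, j, k + 1 < g.nz ? k + 1 : k)] - f[id]) / a0;
            const double nv = f[id] + dt * (-adv - p.Gamma * dFc[id]);
            newphi[id] = nv;
            if (std::fabs(nv) > maxAbs) maxAbs = std::fabs(nv);
          }
      if (maxAbs > 2.0) { errStep = s + 1; break; }
      std::copy(newphi.begin(), newphi.end(),
                phi.begin() + static_cast<size_t>(c) * n);

      // polarity: align to the in-plane interaction force, plus rotational
      // diffusion (Euler-Maruyama); alignment skipped when |T_xy| = 0
      double th = theta[c];
      const double tmag = std::hypot(fx, fy);
      // a numerically-zero force has no defined direction: skip alignment
      if (tmag > 1e-10 && p.taupol[c] > 0.0) {
        double dtheta = th - std::atan2(fy, fx);
        while (dtheta > M_PI) dtheta -= twoPi;
        while (dtheta <= -M_PI) dtheta += twoPi;
        th -= dtheta / p.taupol[c] * dt;
      }
      if (p.Dr[c] > 0.0)
        th += std::sqrt(2.0 * p.Dr[c] * dt) * R::norm_rand();
      while (th > M_PI) th -= twoPi;
      while (th <= -M_PI) th += twoPi;
      theta[c] = th;
    }
    if (errStep > 0) break;
  }

  NumericVector phiOut(phi.begin(), phi.end());
  phiOut.attr("dim") = dims;
  return List::create(_["phi"] = phiOut,
                      _["theta"] = NumericVector(theta.begin(), theta.end()),
                      _["energy"] = energy, _["diag"] = diag,
                      _["errStep"] = errStep);
}
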