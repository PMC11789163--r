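// Site-site Lennard-Jones + Coulomb lattice energy of a rigid-molecule
// crystal under space-group symmetry, plus the harmonic extended-variable
// coupling.  This is the hot path of every local minimization, so the full
// pipeline (cell matrix, symmetry expansion, periodic image sum, finite
// difference gradient) lives here.
//
// Units: kJ/mol, Angstrom, degrees.  Lattice energy is per molecule
// (half the asymmetric-unit pair sum divided by Z'); the harmonic penalty
// is the total over the Z' cluster.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

struct System {
  int ns, zp, nops;
  const double* sites;   // ns x 3 column-major
  const double* eps;
  const double* sig;
  const double* q;
  const double* opsW;    // 9 * nops, column-major 3x3 each, frac rotation
  const double* opsT;    // 3 * nops
  double cell0[6];
  const int* freeCell;   // 0-based indices into cell0
  int nFreeCell;
  double cutoff, kc;
  double kcom, keul;
  const double* S;       // zp x 6 column-major (com xyz, euler abc) or NULL
  int margin;
  bool clamp, shift;
};

static System parseSystem(const List& sys) {
  System s;
  NumericMatrix sites = sys["sites"];
  s.ns = sites.nrow();
  s.sites = REAL(sites);
  NumericVector eps = sys["eps"], sig = sys["sig"], q = sys["q"];
  s.eps = REAL(eps); s.sig = REAL(sig); s.q = REAL(q);
  NumericVector opsW = sys["opsW"], opsT = sys["opsT"];
  s.nops = opsT.size() / 3;
  s.opsW = REAL(opsW); s.opsT = REAL(opsT);
  s.zp = as<int>(sys["zp"]);
  NumericVector c0 = sys["cell0"];
  for (int i = 0; i < 6; ++i) s.cell0[i] = c0[i];
  IntegerVector fc = sys["freeCell"];
  s.freeCell = INTEGER(fc);
  s.nFreeCell = fc.size();
  s.cutoff = as<double>(sys["cutoff"]);
  s.kc = as<double>(sys["kc"]);
  s.kcom = as<double>(sys["kcom"]);
  s.keul = as<double>(sys["keul"]);
  s.S = Rf_isNull(sys["S"]) ? nullptr : REAL(as<NumericMatrix>(sys["S"]));
  s.margin = as<int>(sys["margin"]);
  s.clamp = as<bool>(sys["clamp"]);
  s.shift = as<bool>(sys["shift"]);
  return s;
}

// cell matrix, rows = lattice vectors; returns false on degenerate cell
static bool cellMatrix(const double cell[6], double H[3][3]) {
  double a = cell[0], b = cell[1], c = cell[2];
  if (a <= 0.05 || b <= 0.05 || c <= 0.05) return false;
  double al = cell[3] * DEG, be = cell[4] * DEG, ga = cell[5] * DEG;
  if (cell[3] <= 1 || cell[3] >= 179 || cell[4] <= 1 || cell[4] >= 179 ||
      cell[5] <= 1 || cell[5] >= 179) return false;
  double cal = cos(al), cbe = cos(be), cga = cos(ga), sga = sin(ga);
  double v2 = 1 - cal*cal - cbe*cbe - cga*cga + 2*cal*cbe*cga;
  if (v2 <= 1e-10) return false;
  H[0][0] = a;       H[0][1] = 0;             H[0][2] = 0;
  H[1][0] = b * cga; H[1][1] = b * sga;       H[1][2] = 0;
  H[2][0] = c * cbe; H[2][1] = c * (cal - cbe * cga) / sga;
  H[2][2] = c * sqrt(v2) / sga;
  return true;
}

static void invert3(const double M[3][3], double Mi[3][3]) {
  double d = M[0][0]*(M[1][1]*M[2][2]-M[1][2]*M[2][1])
           - M[0][1]*(M[1][0]*M[2][2]-M[1][2]*M[2][0])
           + M[0][2]*(M[1][0]*M[2][1]-M[1][1]*M[2][0]);
  double id = 1.0 / d;
  Mi[0][0] =  (M[1][1]*M[2][2]-M[1][2]*M[2][1]) * id;
  Mi[0][1] = -(M[0][1]*M[2][2]-M[0][2]*M[2][1]) * id;
  Mi[0][2] =  (M[0][1]*M[1][2]-M[0][2]*M[1][1]) * id;
  Mi[1][0] = -(M[1][0]*M[2][2]-M[1][2]*M[2][0]) * id;
  Mi[1][1] =  (M[0][0]*M[2][2]-M[0][2]*M[2][0]) * id;
  Mi[1][2] = -(M[0][0]*M[1][2]-M[0][2]*M[1][0]) * id;
  Mi[2][0] =  (M[1][0]*M[2][1]-M[1][1]*M[2][0]) * id;
  Mi[2][1] = -(M[0][0]*M[2][1]-M[0][1]*M[2][0]) * id;
  Mi[2][2] =  (M[0][0]*M[1][1]-M[0][1]*M[1][0]) * id;
}

static void eulerMatrix(double a, double b, double g, double R[3][3]) {
  a *= DEG; b *= DEG; g *= DEG;
  double ca = cos(a), sa = sin(a), cb = cos(b), sb = sin(b),
         cg = cos(g), sg = sin(g);
  R[0][0] = ca*cb*cg - sa*sg; R[0][1] = -ca*cb*sg - sa*cg; R[0][2] = ca*sb;
  R[1][0] = sa*cb*cg + ca*sg; R[1][1] = -sa*cb*sg + ca*cg; R[1][2] = sa*sb;
  R[2][0] = -sb*cg;           R[2][1] = sb*sg;             R[2][2] = cb;
}

static inline double wrapAngle(double d) {
  return d - 360.0 * floor((d + 180.0) / 360.0);
}

// Unbiased lattice energy per molecule.  Returns a huge finite value for a
// degenerate cell in clamped mode, R_PosInf when clamp is off and sites
// overlap (r < 0.1 A) or the cell is degenerate.
static double latticeEnergy(const System& s, const double* par) {
  const int zp = s.zp, ns = s.ns, nops = s.nops;
  double cell[6];
  for (int i = 0; i < 6; ++i) cell[i] = s.cell0[i];
  for (int i = 0; i < s.nFreeCell; ++i) cell[s.freeCell[i]] = par[6*zp + i];
  double H[3][3];
  if (!cellMatrix(cell, H)) return s.clamp ? 1e12 : R_PosInf;
  double Hi[3][3];
  invert3(H, Hi);

  // per-molecule rotated body sites; par layout: com (3*zp), euler (3*zp),
  // then the free cell parameters
  std::vector<double> rot(zp * ns * 3);
  for (int m = 0; m < zp; ++m) {
    double R[3][3];
    eulerMatrix(par[3*zp + 3*m], par[3*zp + 3*m + 1], par[3*zp + 3*m + 2], R);
    for (int i = 0; i < ns; ++i) {
      double x = s.sites[i], y = s.sites[ns+i], z = s.sites[2*ns+i];
      for (int d = 0; d < 3; ++d)
        rot[(m*ns + i)*3 + d] = R[d][0]*x + R[d][1]*y + R[d][2]*z;
    }
  }

  // wrapped fractional coms of the asymmetric unit
  std::vector<double> fcom(zp * 3);
  for (int m = 0; m < zp; ++m) {
    double cx = par[3*m], cy = par[3*m+1], cz = par[3*m+2];
    for (int d = 0; d < 3; ++d) {
      // frac = cart %*% Hi  (row vector times matrix)
      double f = cx*Hi[0][d] + cy*Hi[1][d] + cz*Hi[2][d];
      f -= floor(f);
      fcom[3*m + d] = f;
    }
  }

  const int ninst = nops * zp;          // molecule instances in the cell
  const int ntot = ninst * ns;          // sites in the cell
  std::vector<double> pos(ntot * 3);
  std::vector<int> molOf(ntot), opOf(ntot), siteOf(ntot);
  for (int k = 0; k < nops; ++k) {
    const double* W = s.opsW + 9*k;     // column-major 3x3
    const double* tv = s.opsT + 3*k;
    // Rcart = A W A^-1 where A = t(H) (cart = A f)
    // A[i][j] = H[j][i]
    double AW[3][3], Rc[3][3], Ai[3][3];
    // Ai = inverse of A = t(Hi) since A = t(H)
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        Ai[i][j] = Hi[j][i];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        AW[i][j] = H[0][i]*W[j*3+0] + H[1][i]*W[j*3+1] + H[2][i]*W[j*3+2];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        Rc[i][j] = AW[i][0]*Ai[0][j] + AW[i][1]*Ai[1][j] + AW[i][2]*Ai[2][j];
    for (int m = 0; m < zp; ++m) {
      double f[3];
      for (int i = 0; i < 3; ++i) {
        f[i] = W[0*3+i]*fcom[3*m] + W[1*3+i]*fcom[3*m+1] +
               W[2*3+i]*fcom[3*m+2] + tv[i];
        f[i] -= floor(f[i]);
      }
      double cc[3];
      for (int i = 0; i < 3; ++i)
        cc[i] = f[0]*H[0][i] + f[1]*H[1][i] + f[2]*H[2][i];
      for (int i = 0; i < ns; ++i) {
        int idx = (k*zp + m)*ns + i;
        const double* p = &rot[(m*ns + i)*3];
        for (int d = 0; d < 3; ++d)
          pos[idx*3 + d] = cc[d] + Rc[d][0]*p[0] + Rc[d][1]*p[1] +
                           Rc[d][2]*p[2];
        molOf[idx] = k*zp + m;
        opOf[idx] = k;
        siteOf[idx] = i;
      }
    }
  }

  // reciprocal-axis extents: |n + frac(d0)| * spacing <= cutoff bounds the
  // image indices that can put a pair inside the cutoff sphere
  double V = H[0][0]*(H[1][1]*H[2][2]-H[1][2]*H[2][1])
           - H[0][1]*(H[1][0]*H[2][2]-H[1][2]*H[2][0])
           + H[0][2]*(H[1][0]*H[2][1]-H[1][1]*H[2][0]);
  double ext[3];
  for (int ax = 0; ax < 3; ++ax) {
    int u = (ax + 1) % 3, v = (ax + 2) % 3;
    double cxx = H[u][1]*H[v][2]-H[u][2]*H[v][1];
    double cyy = H[u][2]*H[v][0]-H[u][0]*H[v][2];
    double czz = H[u][0]*H[v][1]-H[u][1]*H[v][0];
    double area = sqrt(cxx*cxx + cyy*cyy + czz*czz);
    ext[ax] = s.cutoff * area / fabs(V) + s.margin;
  }

  const double rc2 = s.cutoff * s.cutoff;
  double E = 0;
  bool overlap = false;
  const int nasym = zp * ns;            // asym sites are op 0 block
  for (int i = 0; i < nasym && !overlap; ++i) {
    const double xi = pos[i*3], yi = pos[i*3+1], zi = pos[i*3+2];
    const double ei = s.eps[siteOf[i]], si = s.sig[siteOf[i]],
                 qi = s.q[siteOf[i]];
    for (int j = 0; j < ntot && !overlap; ++j) {
      const double ej = s.eps[siteOf[j]], sj = s.sig[siteOf[j]],
                   qj = s.q[siteOf[j]];
      const double epsij = sqrt(ei * ej), sigij = 0.5 * (si + sj);
      const double qq = qi * qj * s.kc;
      const bool sameInst = (molOf[j] == molOf[i]);
      const double d0x = pos[j*3] - xi, d0y = pos[j*3+1] - yi,
                   d0z = pos[j*3+2] - zi;
      // fractional coordinates of the pair displacement
      double f0[3], lo[3], hi[3];
      for (int d = 0; d < 3; ++d) {
        f0[d] = d0x*Hi[0][d] + d0y*Hi[1][d] + d0z*Hi[2][d];
        lo[d] = ceil(-f0[d] - ext[d]);
        hi[d] = floor(-f0[d] + ext[d]);
      }
      for (int ia = (int)lo[0]; ia <= (int)hi[0]; ++ia) {
        const double ax = d0x + ia*H[0][0], ay = d0y + ia*H[0][1],
                     az = d0z + ia*H[0][2];
        for (int ib = (int)lo[1]; ib <= (int)hi[1]; ++ib) {
          const double bx = ax + ib*H[1][0], by = ay + ib*H[1][1],
                       bz = az + ib*H[1][2];
          for (int ic = (int)lo[2]; ic <= (int)hi[2]; ++ic) {
            if (sameInst && ia == 0 && ib == 0 && ic == 0) continue;
            double dx = bx + ic*H[2][0];
            double dy = by + ic*H[2][1];
            double dz = bz + ic*H[2][2];
            double r2 = dx*dx + dy*dy + dz*dz;
            if (r2 > rc2) continue;
            double r = sqrt(r2);
            if (!s.clamp && r < 0.1) { overlap = true; break; }
            double rmin = 0.6 * sigij;
            if (s.clamp && r < rmin) {
              // linear continuation below 0.6 sigma keeps the optimizer
              // finite
              double sr6 = pow(sigij / rmin, 6);
              double e0 = 4*epsij*(sr6*sr6 - sr6) + qq / rmin;
              double de = (-24*epsij*(2*sr6*sr6 - sr6) / rmin) -
                          qq/(rmin*rmin);
              E += e0 + de * (r - rmin);
              continue;
            }
            double sr6 = sigij*sigij/r2; sr6 = sr6*sr6*sr6;
            E += 4*epsij*(sr6*sr6 - sr6);
            if (qq != 0) E += qq / r;
            if (s.shift) {
              // force-shifted truncation: energy and force continuous at rc
              double sc6 = sigij*sigij/rc2; sc6 = sc6*sc6*sc6;
              double u_c = 4*epsij*(sc6*sc6 - sc6) + qq / s.cutoff;
              double du_c = -24*epsij*(2*sc6*sc6 - sc6) / s.cutoff -
                            qq / rc2;
              E -= u_c + du_c * (r - s.cutoff);
            }
          }
          if (overlap) break;
        }
        if (overlap) break;
      }
    }
  }
  if (overlap) return R_PosInf;
  return 0.5 * E / zp;
}

static double penaltyEnergy(const System& s, const double* par) {
  if (s.S == nullptr || (s.kcom == 0 && s.keul == 0)) return 0.0;
  const int zp = s.zp;
  double p = 0;
  for (int m = 0; m < zp; ++m) {
    for (int d = 0; d < 3; ++d) {
      double dc = par[3*m + d] - s.S[d*zp + m];
      p += 0.5 * s.kcom * dc * dc;
      double da = wrapAngle(par[3*zp + 3*m + d] - s.S[(3 + d)*zp + m]);
      p += 0.5 * s.keul * da * da;
    }
  }
  return p;
}

// [[Rcpp::export]]
NumericVector cpp_energy_terms(NumericVector par, List sys) {
  System s = parseSystem(sys);
  double u = latticeEnergy(s, REAL(par));
  double p = penaltyEnergy(s, REAL(par));
  return NumericVector::create(u, p);
}

// [[Rcpp::export]]
double cpp_energy_total(NumericVector par, List sys) {
  System s = parseSystem(sys);
  return latticeEnergy(s, REAL(par)) + penaltyEnergy(s, REAL(par));
}

// Central finite-difference gradient of the (clamped) total energy.  The
// harmonic part is differentiated analytically; Euler components of
// single-site molecules contribute nothing to the lattice term.
// [[Rcpp::export]]
NumericVector cpp_energy_grad(NumericVector par, List sys) {
  System s = parseSystem(sys);
  s.clamp = true;
  const int zp = s.zp;
  const int n = par.size();
  std::vector<double> x(REAL(par), REAL(par) + n);
  NumericVector g(n);

  for (int i = 0; i < n; ++i) {
    bool isEuler = (i >= 3*zp && i < 6*zp);
    bool isCellAngle = false;
    if (i >= 6*zp) isCellAngle = (s.freeCell[i - 6*zp] >= 3);
    if (isEuler && s.ns == 1) { g[i] = 0; continue; }
    double h = (isEuler || isCellAngle) ? 1e-4 : 1e-5;
    double x0 = x[i];
    x[i] = x0 + h;
    double ep = latticeEnergy(s, x.data());
    x[i] = x0 - h;
    double em = latticeEnergy(s, x.data());
    x[i] = x0;
    g[i] = (ep - em) / (2*h);
  }
  if (s.S != nullptr && (s.kcom != 0 || s.keul != 0)) {
    for (int m = 0; m < zp; ++m)
      for (int d = 0; d < 3; ++d) {
        g[3*m + d] += s.kcom * (x[3*m + d] - s.S[d*zp + m]);
        g[3*zp + 3*m + d] +=
          s.keul * wrapAngle(x[3*zp + 3*m + d] - s.S[(3 + d)*zp + m]);
      }
  }
  return g;
}
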