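#include <Rcpp.h>
using namespace Rcpp;

// Natural-extension reference frame placement: position atom D given the
// three previous atoms A, B, C, the C-D bond length, the B-C-D angle and
// the A-B-C-D dihedral (angles in radians).
static inline void nerf_place(const double *A, const double *B,
                              const double *C, double bond, double angle,
                              double dihedral, double *D) {
  double bc[3], ab[3], n[3], m[3];
  double nbc = 0.0, nab = 0.0;
  for (int k = 0; k < 3; ++k) {
    bc[k] = C[k] - B[k];
    ab[k] = B[k] - A[k];
  }
  nbc = sqrt(bc[0] * bc[0] + bc[1] * bc[1] + bc[2] * bc[2]);
  for (int k = 0; k < 3; ++k) bc[k] /= nbc;
  nab = sqrt(ab[0] * ab[0] + ab[1] * ab[1] + ab[2] * ab[2]);
  for (int k = 0; k < 3; ++k) ab[k] /= nab;
  // n = unit(ab x bc); m = n x bc
  n[0] = ab[1] * bc[2] - ab[2] * bc[1];
  n[1] = ab[2] * bc[0] - ab[0] * bc[2];
  n[2] = ab[0] * bc[1] - ab[1] * bc[0];
  double nn = sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
  for (int k = 0; k < 3; ++k) n[k] /= nn;
  m[0] = n[1] * bc[2] - n[2] * bc[1];
  m[1] = n[2] * bc[0] - n[0] * bc[2];
  m[2] = n[0] * bc[1] - n[1] * bc[0];
  double d0 = -bond * cos(angle);
  double d1 = bond * sin(angle) * cos(dihedral);
  double d2 = bond * sin(angle) * sin(dihedral);
  for (int k = 0; k < 3; ++k)
    D[k] = C[k] + d0 * bc[k] + d1 * m[k] + d2 * n[k];
}

// Build backbone N, CA, C coordinates for one chain from per-residue
// phi/psi dihedrals (degrees) and fixed peptide geometry. Row order is
// N1, CA1, C1, N2, CA2, C2, ... phi[0] is unused (no preceding C).
// [[Rcpp::export]]
NumericMatrix build_backbone_cpp(NumericVector phi, NumericVector psi,
                                 double omega, double b_n_ca, double b_ca_c,
                                 double b_c_n, double a_c_n_ca,
                                 double a_n_ca_c, double a_ca_c_n) {
  const double DEG = M_PI / 180.0;
  int L = phi.size();
  if (psi.size() != L) stop("phi and psi must have equal length");
  NumericMatrix out(3 * L, 3);
  std::vector<double> X(9 * L);
  // first residue in a canonical frame
  double *N1 = &X[0], *CA1 = &X[3], *C1 = &X[6];
  N1[0] = 0.0; N1[1] = 0.0; N1[2] = 0.0;
  CA1[0] = b_n_ca; CA1[1] = 0.0; CA1[2] = 0.0;
  C1[0] = b_n_ca - b_ca_c * cos(a_n_ca_c * DEG);
  C1[1] = b_ca_c * sin(a_n_ca_c * DEG);
  C1[2] = 0.0;
  for (int i = 1; i < L; ++i) {
    double *Np = &X[9 * (i - 1)], *CAp = &X[9 * (i - 1) + 3],
           *Cp = &X[9 * (i - 1) + 6];
    double *Ni = &X[9 * i], *CAi = &X[9 * i + 3], *Ci = &X[9 * i + 6];
    nerf_place(Np, CAp, Cp, b_c_n, a_ca_c_n * DEG, psi[i - 1] * DEG, Ni);
    nerf_place(CAp, Cp, Ni, b_n_ca, a_c_n_ca * DEG, omega * DEG, CAi);
    nerf_place(Cp, Ni, CAi, b_ca_c, a_n_ca_c * DEG, phi[i] * DEG, Ci);
  }
  for (int i = 0; i < 3 * L; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = X[3 * i + k];
  return out;
}
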