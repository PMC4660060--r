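// Optimal rigid superposition (Horn's quaternion method) and pairwise
// RMSD matrices over coordinate ensembles.  The 4x4 symmetric eigenproblem
// is solved by cyclic Jacobi, which is deterministic and ample for the
// ensemble sizes handled here.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// largest eigenvalue/eigenvector of a symmetric 4x4 by cyclic Jacobi
static void jacobi4(double A[4][4], double *eval, double evec[4][4]) {
  double V[4][4] = {{1, 0, 0, 0}, {0, 1, 0, 0}, {0, 0, 1, 0}, {0, 0, 0, 1}};
  for (int sweep = 0; sweep < 60; sweep++) {
    double off = 0;
    for (int p = 0; p < 4; p++)
      for (int q = p + 1; q < 4; q++) off += A[p][q] * A[p][q];
    if (off < 1e-24) break;
    for (int p = 0; p < 4; p++)
      for (int q = p + 1; q < 4; q++) {
        if (std::fabs(A[p][q]) < 1e-30) continue;
        double theta = (A[q][q] - A[p][p]) / (2.0 * A[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 4; k++) {
          double akp = A[k][p], akq = A[k][q];
          A[k][p] = c * akp - s * akq;
          A[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < 4; k++) {
          double apk = A[p][k], aqk = A[q][k];
          A[p][k] = c * apk - s * aqk;
          A[q][k] = s * apk + c * aqk;
        }
        for (int k = 0; k < 4; k++) {
          double vkp = V[k][p], vkq = V[k][q];
          V[k][p] = c * vkp - s * vkq;
          V[k][q] = s * vkp + c * vkq;
        }
      }
  }
  for (int i = 0; i < 4; i++) {
    eval[i] = A[i][i];
    for (int k = 0; k < 4; k++) evec[k][i] = V[k][i];
  }
}

// fills q (unit quaternion, rotates mov onto ref after centering) and
// returns rmsd; P = ref, Q = mov, both n x 3
static double horn(const double *P, const double *Q, int n, double *quat) {
  double cp[3] = {0, 0, 0}, cq[3] = {0, 0, 0};
  for (int i = 0; i < n; i++)
    for (int k = 0; k < 3; k++) {
      cp[k] += P[i + k * n];
      cq[k] += Q[i + k * n];
    }
  for (int k = 0; k < 3; k++) { cp[k] /= n; cq[k] /= n; }
  double Sxx = 0, Sxy = 0, Sxz = 0, Syx = 0, Syy = 0, Syz = 0,
         Szx = 0, Szy = 0, Szz = 0, Gp = 0, Gq = 0;
  for (int i = 0; i < n; i++) {
    double p[3], q[3];
    for (int k = 0; k < 3; k++) {
      p[k] = P[i + k * n] - cp[k];
      q[k] = Q[i + k * n] - cq[k];
    }
    Gp += p[0] * p[0] + p[1] * p[1] + p[2] * p[2];
    Gq += q[0] * q[0] + q[1] * q[1] + q[2] * q[2];
    // correlation of mov (q) against ref (p)
    Sxx += q[0] * p[0]; Sxy += q[0] * p[1]; Sxz += q[0] * p[2];
    Syx += q[1] * p[0]; Syy += q[1] * p[1]; Syz += q[1] * p[2];
    Szx += q[2] * p[0]; Szy += q[2] * p[1]; Szz += q[2] * p[2];
  }
  double K[4][4] = {
    {Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx},
    {Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz},
    {Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy},
    {Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz}};
  double eval[4], evec[4][4];
  jacobi4(K, eval, evec);
  int best = 0;
  for (int i = 1; i < 4; i++)
    if (eval[i] > eval[best]) best = i;
  for (int k = 0; k < 4; k++) quat[k] = evec[k][best];
  double msd = (Gp + Gq - 2.0 * eval[best]) / n;
  if (msd < 0) msd = 0;
  return std::sqrt(msd);
}

static void quat_to_rot(const double *q, double *Rm) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  Rm[0] = w * w + x * x - y * y - z * z; Rm[1] = 2 * (x * y - w * z); Rm[2] = 2 * (x * z + w * y);
  Rm[3] = 2 * (x * y + w * z); Rm[4] = w * w - x * x + y * y - z * z; Rm[5] = 2 * (y * z - w * x);
  Rm[6] = 2 * (x * z - w * y); Rm[7] = 2 * (y * z + w * x); Rm[8] = w * w - x * x - y * y + z * z;
}

//' @noRd
// [[Rcpp::export(name = ".rmsd_pair_cpp")]]
double rmsd_pair_cpp(NumericMatrix a, NumericMatrix b) {
  if (a.nrow() != b.nrow()) stop("coordinate sets differ in size");
  double q[4];
  return horn(REAL(a), REAL(b), a.nrow(), q);
}

//' @noRd
// [[Rcpp::export(name = ".pairwise_rmsd_cpp")]]
NumericMatrix pairwise_rmsd_cpp(List models) {
  int n = models.size();
  std::vector<NumericMatrix> ms(n);
  for (int i = 0; i < n; i++) ms[i] = as<NumericMatrix>(models[i]);
  NumericMatrix D(n, n);
  double q[4];
  for (int i = 0; i < n; i++)
    for (int j = i + 1; j < n; j++) {
      double r = horn(REAL(ms[i]), REAL(ms[j]), ms[i].nrow(), q);
      D(i, j) = r;
      D(j, i) = r;
    }
  return D;
}

//' @noRd
// [[Rcpp::export(name = ".superpose_cpp")]]
NumericMatrix superpose_cpp(NumericMatrix ref, NumericMatrix mov) {
  if (ref.nrow() != mov.nrow()) stop("coordinate sets differ in size");
  int n = ref.nrow();
  double q[4], Rm[9];
  horn(REAL(ref), REAL(mov), n, q);
  quat_to_rot(q, Rm);
  double cp[3] = {0, 0, 0}, cq[3] = {0, 0, 0};
  for (int i = 0; i < n; i++)
    for (int k = 0; k < 3; k++) {
      cp[k] += ref(i, k);
      cq[k] += mov(i, k);
    }
  for (int k = 0; k < 3; k++) { cp[k] /= n; cq[k] /= n; }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; i++) {
    double v[3] = {mov(i, 0) - cq[0], mov(i, 1) - cq[1], mov(i, 2) - cq[2]};
    for (int k = 0; k < 3; k++)
      out(i, k) = Rm[3 * k] * v[0] + Rm[3 * k + 1] * v[1] + Rm[3 * k + 2] * v[2] + cp[k];
  }
  return out;
}
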