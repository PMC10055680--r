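#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

// Opcode table shared with R/sequence.R (schedule_ops):
//   1 RF(flip_deg, phase_deg)   flip scaled by the atom's B1 factor
//   2 RELAX(dt_ms)              free T1/T2 relaxation, z0 recovery
//   3 READOUT                   record F+[0]
//   4 SHIFT                     unbalanced-gradient dephasing, +1 order
//   5 SPOIL                     ideal RF spoiling: transverse zeroed
//   6 INVERT(efficiency)        adiabatic inversion (B1-insensitive)
//   7 T1RHO(tsl_ms)             spin-lock prep: z *= exp(-tsl/T1rho), F crushed

// Simulate fingerprints for a batch of tissue parameter sets.
// ops: n_ops x 3 (code, p1, p2); params: n_atoms x 5 (t1, t2, t1rho, pd, b1).
// Returns complex matrix n_atoms x n_readouts.
// [[Rcpp::export]]
ComplexMatrix epg_simulate_batch_cpp(NumericMatrix ops, NumericMatrix params,
                                     int max_order) {
  const int n_ops = ops.nrow();
  const int n_atoms = params.nrow();
  const int K = max_order;

  int n_read = 0;
  for (int i = 0; i < n_ops; ++i)
    if ((int)ops(i, 0) == 3) ++n_read;

  ComplexMatrix out(n_atoms, n_read);

  std::vector<cplx> Fp(K + 1), Fm(K + 1), Z(K + 1);

  for (int a = 0; a < n_atoms; ++a) {
    const double t1 = params(a, 0), t2 = params(a, 1);
    const double t1rho = params(a, 2), pd = params(a, 3), b1 = params(a, 4);
    if (!(t1 > 0.0) || !(t2 > 0.0) || !(t1rho > 0.0))
      stop("tissue parameters must be positive");

    std::fill(Fp.begin(), Fp.end(), cplx(0.0, 0.0));
    std::fill(Fm.begin(), Fm.end(), cplx(0.0, 0.0));
    std::fill(Z.begin(), Z.end(), cplx(0.0, 0.0));
    Z[0] = cplx(1.0, 0.0);
    int kmax = 0;  // highest populated dephasing order
    int ir = 0;

    for (int i = 0; i < n_ops; ++i) {
      const int code = (int)ops(i, 0);
      const double p1 = ops(i, 1), p2 = ops(i, 2);
      switch (code) {
      case 1: {  // RF rotation, phase 0 = about +x, F = Mx + i My
        const double alpha = p1 * b1 * M_PI / 180.0;
        const double phi = p2 * M_PI / 180.0;
        const double ca2 = std::cos(alpha / 2.0), sa2 = std::sin(alpha / 2.0);
        const double sa = std::sin(alpha), ca = std::cos(alpha);
        const cplx eip(std::cos(phi), std::sin(phi));
        const cplx eip2 = eip * eip;
        const cplx t00(ca2 * ca2, 0.0);
        const cplx t01 = eip2 * (sa2 * sa2);
        const cplx t02 = cplx(0.0, -sa) * eip;
        const cplx t10 = std::conj(eip2) * (sa2 * sa2);
        const cplx t11(ca2 * ca2, 0.0);
        const cplx t12 = cplx(0.0, sa) * std::conj(eip);
        const cplx t20 = cplx(0.0, -0.5 * sa) * std::conj(eip);
        const cplx t21 = cplx(0.0, 0.5 * sa) * eip;
        const cplx t22(ca, 0.0);
        for (int k = 0; k <= kmax; ++k) {
          const cplx fp = Fp[k], fm = Fm[k], z = Z[k];
          Fp[k] = t00 * fp + t01 * fm + t02 * z;
          Fm[k] = t10 * fp + t11 * fm + t12 * z;
          Z[k]  = t20 * fp + t21 * fm + t22 * z;
        }
        break;
      }
      case 2: {  // free relaxation over p1 ms
        const double e1 = std::exp(-p1 / t1), e2 = std::exp(-p1 / t2);
        for (int k = 0; k <= kmax; ++k) {
          Fp[k] *= e2;
          Fm[k] *= e2;
          Z[k]  *= e1;
        }
        Z[0] += 1.0 - e1;
        break;
      }
      case 3: {  // readout: observed signal is F+[0]
        out(a, ir).r = Fp[0].real() * pd;
        out(a, ir).i = Fp[0].imag() * pd;
        ++ir;
        break;
      }
      case 4: {  // gradient shift: F ladder moves +1 order
        const int knew = std::min(kmax + 1, K);
        for (int k = knew; k >= 1; --k) Fp[k] = Fp[k - 1];
        Fp[0] = std::conj(Fm[1]);
        for (int k = 0; k < knew; ++k) Fm[k] = Fm[k + 1];
        Fm[knew] = cplx(0.0, 0.0);
        kmax = knew;
        break;
      }
      case 5: {  // ideal spoiling
        for (int k = 0; k <= kmax; ++k) {
          Fp[k] = cplx(0.0, 0.0);
          Fm[k] = cplx(0.0, 0.0);
        }
        break;
      }
      case 6: {  // inversion with efficiency p1 (not B1-scaled: adiabatic)
        for (int k = 0; k <= kmax; ++k) {
          Z[k] *= -p1;
          Fp[k] = cplx(0.0, 0.0);
          Fm[k] = cplx(0.0, 0.0);
        }
        break;
      }
      case 7: {  // T1rho spin-lock preparation, mono-exponential decay
        const double att = std::exp(-p1 / t1rho);
        for (int k = 0; k <= kmax; ++k) {
          Z[k] *= att;
          Fp[k] = cplx(0.0, 0.0);
          Fm[k] = cplx(0.0, 0.0);
        }
        break;
      }
      default:
        stop("unknown opcode");
      }
    }
  }
  return out;
}
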