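#include <Rcpp.h>
using namespace Rcpp;

// Exact event-driven simulation of single-cell R-M dynamics in absolute
// molecule counts, with deterministic divisions once per time unit.
//
// Between divisions the only state change that alters any propensity is a C
// birth (R and M births leave all rates unchanged), so C births are simulated
// event-by-event with exponential waiting times while R and M births over
// each inter-event interval are drawn as Poisson counts at constant rate.
// This samples the full jump process exactly.
//
// Per-plasmid rates (molecules per division time):
//   regulated:   C: rate_l + rate_m * z1/(1+z1+z2+z3), statistical weights
//                   from the free monomer at count-unit dissociation
//                   constants (z1 = cf~^2, z2 = (omega/p) cf~^4,
//                   z3 = cf~^2/p, cf~ = Cfree/sqrt(kd1*kd2));
//                M: rate_M / (1 + D/kdm), D = Cfree^2/kd1 (dimer repression)
//   unregulated: C: rate_l (constant), M: rate_M (constant)
// R births form an independent Poisson channel at k_rc times the C rate
// (co-transcription proportionality); with cotranscribe = true R is instead
// produced alongside each C event (Poisson with mean k_rc per event).
//
// At each division plasmids duplicate, then every species partitions
// binomially with probability 1/2; one daughter is followed. Pre- and
// post-division states are recorded.

// [[Rcpp::export]]
List ssa_ensemble_cpp(IntegerVector n0, IntegerVector c0, IntegerVector r0,
                      IntegerVector m0, int n_divisions,
                      double rate_l, double rate_m, double rate_M,
                      double k_rc, double kd1, double kd2, double kdm,
                      double p, double omega,
                      bool regulated, bool cotranscribe) {
  const int n_cells = n0.size();
  const double kd = std::sqrt(kd1 * kd2);

  IntegerMatrix n_post(n_cells, n_divisions + 1);
  IntegerMatrix c_post(n_cells, n_divisions + 1);
  IntegerMatrix r_post(n_cells, n_divisions + 1);
  IntegerMatrix m_post(n_cells, n_divisions + 1);
  IntegerMatrix n_pre(n_cells, n_divisions);
  IntegerMatrix c_pre(n_cells, n_divisions);
  IntegerMatrix r_pre(n_cells, n_divisions);
  IntegerMatrix m_pre(n_cells, n_divisions);

  for (int cell = 0; cell < n_cells; ++cell) {
    double n = n0[cell], C = c0[cell], R = r0[cell], M = m0[cell];
    n_post(cell, 0) = (int)n; c_post(cell, 0) = (int)C;
    r_post(cell, 0) = (int)R; m_post(cell, 0) = (int)M;

    for (int d = 0; d < n_divisions; ++d) {
      double t = 0.0;
      while (true) {
        double act, mrate;
        if (regulated) {
          double cf = 2.0 * C / (1.0 + std::sqrt(1.0 + 8.0 * C / kd1));
          double cfr = cf / kd;
          double z1 = cfr * cfr;
          double z2 = (omega / p) * z1 * z1;
          double z3 = z1 / p;
          act = rate_l + rate_m * z1 / (1.0 + z1 + z2 + z3);
          double D = cf * cf / kd1;
          mrate = rate_M / (1.0 + D / kdm);
        } else {
          act = rate_l;
          mrate = rate_M;
        }
        double lamC = n * act;
        double lamR = cotranscribe ? 0.0 : k_rc * lamC;
        double lamM = n * mrate;

        if (lamC <= 0.0) {
          double rest = 1.0 - t;
          if (lamR > 0.0) R += R::rpois(lamR * rest);
          if (lamM > 0.0) M += R::rpois(lamM * rest);
          break;
        }
        double dt = R::rexp(1.0 / lamC);
        double step = std::min(dt, 1.0 - t);
        if (lamR > 0.0) R += R::rpois(lamR * step);
        if (lamM > 0.0) M += R::rpois(lamM * step);
        if (dt < 1.0 - t) {
          C += 1.0;
          if (cotranscribe) R += R::rpois(k_rc);
          t += dt;
        } else {
          break;
        }
      }
      n_pre(cell, d) = (int)n; c_pre(cell, d) = (int)C;
      r_pre(cell, d) = (int)R; m_pre(cell, d) = (int)M;

      n = R::rbinom(2.0 * n, 0.5);
      C = R::rbinom(C, 0.5);
      R = R::rbinom(R, 0.5);
      M = R::rbinom(M, 0.5);

      n_post(cell, d + 1) = (int)n; c_post(cell, d + 1) = (int)C;
      r_post(cell, d + 1) = (int)R; m_post(cell, d + 1) = (int)M;
    }
  }

  return List::create(
    Named("n_post") = n_post, Named("c_post") = c_post,
    Named("r_post") = r_post, Named("m_post") = m_post,
    Named("n_pre") = n_pre, Named("c_pre") = c_pre,
    Named("r_pre") = r_pre, Named("m_pre") = m_pre);
}
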