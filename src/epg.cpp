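// Extended phase graph (EPG) simulation of gradient-dephased RF trains,
// vectorised over (T1, T2) atoms.  States are the configuration orders
// (F+_k, F-_k, Z_k) with F-_k stored in the conjugate representation, so the
// RF mixing matrix acts linearly on (F+_k, F-_k, Z_k) for every k.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// One TR: RF rotation -> signal at TE -> relaxation/recovery over TR ->
// unit gradient dephasing shift.  fa_deg/phase_deg are per-pulse, t1/t2 are
// per-atom (columns).  Returns the n x D matrix of complex F0 signals at TE.
// [[Rcpp::export(name = ".epg_sim_batch")]]
arma::cx_mat epg_sim_batch(const arma::vec& fa_deg,
                           const arma::vec& phase_deg,
                           double tr_ms, double te_ms,
                           const arma::vec& t1_ms, const arma::vec& t2_ms,
                           bool invert, int kmax) {
  const uword n = fa_deg.n_elem;
  const uword D = t1_ms.n_elem;
  if (t2_ms.n_elem != D) Rcpp::stop("t1 and t2 grids must have equal length");
  if (t1_ms.min() <= 0 || t2_ms.min() <= 0)
    Rcpp::stop("relaxation times must be positive");
  const int K = std::min<int>(kmax, (int)n);

  rowvec e1(D), e2(D), e2te(D), rec(D);
  for (uword d = 0; d < D; ++d) {
    e1(d)   = std::exp(-tr_ms / t1_ms(d));
    e2(d)   = std::exp(-tr_ms / t2_ms(d));
    e2te(d) = std::exp(-te_ms / t2_ms(d));
    rec(d)  = 1.0 - e1(d);
  }
  cx_rowvec ce2  = conv_to<cx_rowvec>::from(e2);
  cx_rowvec ce1  = conv_to<cx_rowvec>::from(e1);
  cx_rowvec crec = conv_to<cx_rowvec>::from(rec);

  cx_mat Fp(K + 1, D, fill::zeros), Fm(K + 1, D, fill::zeros);
  cx_mat Z(K + 1, D, fill::zeros);
  Z.row(0).fill(cx_double(invert ? -1.0 : 1.0, 0.0));

  cx_mat Fp2(K + 1, D), Fm2(K + 1, D), Z2(K + 1, D);
  cx_mat sig(n, D, fill::zeros);
  const cx_double I(0.0, 1.0);

  for (uword p = 0; p < n; ++p) {
    const double a   = fa_deg(p)   * datum::pi / 180.0;
    const double phi = phase_deg(p) * datum::pi / 180.0;
    const double ca2 = std::cos(a / 2.0), sa2 = std::sin(a / 2.0);
    const double sa  = std::sin(a), caa = std::cos(a);
    const cx_double eip  = std::exp(I * phi);
    const cx_double ei2p = std::exp(I * (2.0 * phi));
    const cx_double t11(ca2 * ca2, 0.0);
    const cx_double t12 = ei2p * (sa2 * sa2);
    const cx_double t13 = -I * eip * sa;
    const cx_double t21 = std::conj(t12);
    const cx_double t22 = t11;
    const cx_double t23 = I * std::conj(eip) * sa;
    const cx_double t31 = -0.5 * I * std::conj(eip) * sa;
    const cx_double t32 = 0.5 * I * eip * sa;
    const cx_double t33(caa, 0.0);

    Fp2 = t11 * Fp + t12 * Fm + t13 * Z;
    Fm2 = t21 * Fp + t22 * Fm + t23 * Z;
    Z2  = t31 * Fp + t32 * Fm + t33 * Z;

    sig.row(p) = Fp2.row(0) % conv_to<cx_rowvec>::from(e2te);

    // relaxation over the full TR plus longitudinal recovery towards M0 = 1
    Fp2.each_row() %= ce2;
    Fm2.each_row() %= ce2;
    Z2.each_row()  %= ce1;
    Z2.row(0) += crec;

    // gradient shift: F+ up one order, F- down one order; F+_0 = conj(F-_0)
    for (int k = K; k >= 1; --k) Fp.row(k) = Fp2.row(k - 1);
    for (int k = 0; k <= K - 1; ++k) Fm.row(k) = Fm2.row(k + 1);
    Fm.row(K).zeros();
    Fp.row(0) = conj(Fm.row(0));
    Z = Z2;
  }
  return sig;
}

// Longitudinal k=0 state after m TRs of an all-zero flip train (diagnostic
// used to validate the recovery recursion against 1 - 2 exp(-m tr / T1)).
// [[Rcpp::export(name = ".epg_z0_free_recovery")]]
arma::vec epg_z0_free_recovery(int m, double tr_ms, double t1_ms, bool invert) {
  double z = invert ? -1.0 : 1.0;
  const double e1 = std::exp(-tr_ms / t1_ms);
  vec out(m);
  for (int i = 0; i < m; ++i) {
    z = z * e1 + (1.0 - e1);
    out(i) = z;
  }
  return out;
}
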