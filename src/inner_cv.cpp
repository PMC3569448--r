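// Inner Monte-Carlo cross-validation kernel for fixed-gamma powered PLS-DA.
//
// For each stratified split and each gamma on the grid this fits a
// max_components powered PLS-DA model on the inner training rows (empirical
// priors, under which the prior/size diagonal is the constant 1/n^2 and all
// weighted moments reduce to unweighted ones), projects the inner test rows,
// and records the LDA prediction error for every leading-component prefix.
// For two groups the centered dummy columns are exact multiples of the signed
// class vector, so the candidate matrix has a single independent column and
// the canonical combination step is a sign choice; the R engine carries the
// full two-column machinery and the two paths are asserted equivalent in the
// test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// one powered loading-weight vector from the deflated matrix
static vec powered_weight(const mat& X, const vec& c0, const vec& ss,
                          double gamma) {
  const uword p = X.n_cols;
  vec cov = X.t() * c0;                       // proportional to covariance
  vec s = sqrt(clamp(ss, 0.0, datum::inf));
  // deflation residue in extracted indicator columns is O(1e-16) but keeps a
  // scale-invariant correlation; count such features as zero-variance
  double scut = s.max() * 1e-9;
  for (uword k = 0; k < p; ++k) if (s(k) < scut) s(k) = 0.0;
  vec r(p);
  for (uword k = 0; k < p; ++k)
    r(k) = (s(k) > 0) ? cov(k) / s(k) : 0.0;  // prop. to correlation
  // proportionality constants are shared across features and cancel in the
  // per-column normalisation of the powered weights
  vec w(p, fill::zeros);
  if (gamma == 0.0) {
    uword i = s.index_max();
    if (s(i) > 0) w(i) = (r(i) < 0) ? -1.0 : 1.0;
  } else if (gamma == 1.0) {
    vec ar = abs(r);
    uword i = ar.index_max();
    if (ar(i) > 0) w(i) = (r(i) < 0) ? -1.0 : 1.0;
  } else {
    const double e_rho = gamma / (1.0 - gamma);
    const double e_s = (1.0 - gamma) / gamma;
    // |r| here is |rho| times a constant; normalise it away before powering
    double smax = s.max();
    double rmax = abs(r).max();
    if (smax <= 0 || rmax <= 0) {
      uword i = s.index_max();
      if (s(i) > 0) w(i) = 1.0;
      return w;
    }
    vec lw(p);
    double best = -datum::inf;
    for (uword k = 0; k < p; ++k) {
      if (s(k) <= 0) { lw(k) = -datum::inf; continue; }
      double lr = std::log(std::max(std::abs(r(k)) / rmax, 1e-300));
      double lsd = std::log(std::max(s(k) / smax, 1e-300));
      lw(k) = e_rho * lr + e_s * lsd;
      if (lw(k) > best) best = lw(k);
    }
    for (uword k = 0; k < p; ++k) {
      if (s(k) <= 0 || r(k) == 0.0) continue;
      w(k) = std::exp(lw(k) - best) * ((r(k) < 0) ? -1.0 : 1.0);
    }
  }
  double nw = norm(w);
  if (nw > 0) w /= nw;
  // sign convention: first entry with magnitude above 1e-12 positive
  for (uword k = 0; k < p; ++k) {
    if (std::abs(w(k)) > 1e-12) { if (w(k) < 0) w = -w; break; }
  }
  return w;
}

// sequential fixed-gamma fit; fills W, P, T and returns the number of
// components actually extracted
static int ppls_fixed_fit(mat X, const vec& c0, double gamma, int ncomp,
                          mat& W, mat& P, mat& T) {
  vec ss = sum(square(X), 0).t();             // column sums of squares
  int got = 0;
  for (int a = 0; a < ncomp; ++a) {
    vec w = powered_weight(X, c0, ss, gamma);
    if (norm(w) == 0) break;
    vec t = X * w;
    double tt = dot(t, t);
    if (tt < 1e-280) break;
    vec pl = X.t() * t / tt;
    X -= t * pl.t();
    ss -= square(pl) * tt;                    // exact column-SS update
    W.col(a) = w; P.col(a) = pl; T.col(a) = t;
    ++got;
  }
  return got;
}

// LDA prediction errors for the leading-component prefixes 1..ncomp
static void lda_prefix_pe(const mat& Ttr, const uvec& ytr, const mat& Tte,
                          const uvec& yte, int ncomp, double* out) {
  const uword n1 = accu(ytr == 1), n2 = Ttr.n_rows - n1;
  const double lp = std::log((double) n1 / (double) Ttr.n_rows) -
                    std::log((double) n2 / (double) Ttr.n_rows);
  for (int A = 1; A <= ncomp; ++A) {
    mat S1 = Ttr.head_cols(A);
    rowvec mu1(A, fill::zeros), mu2(A, fill::zeros);
    for (uword i = 0; i < S1.n_rows; ++i) {
      if (ytr(i) == 1) mu1 += S1.row(i); else mu2 += S1.row(i);
    }
    mu1 /= (double) n1; mu2 /= (double) n2;
    mat Sw(A, A, fill::zeros);
    for (uword i = 0; i < S1.n_rows; ++i) {
      rowvec d = S1.row(i) - ((ytr(i) == 1) ? mu1 : mu2);
      Sw += d.t() * d;
    }
    Sw /= (double) (S1.n_rows - 2);
    Sw = symmatu(Sw);
    vec ev;
    bool ok = eig_sym(ev, Sw);
    if (!ok || ev(0) <= 0 || ev(A - 1) / ev(0) > 1e12)
      Sw.diag() += 1e-8 * std::max(trace(Sw), 1e-300) / (double) A;
    vec beta = solve(Sw, (mu1 - mu2).t(), solve_opts::likely_sympd);
    double thr = 0.5 * dot(mu1 + mu2, beta) - lp;
    uword wrong = 0;
    mat S2 = Tte.head_cols(A);
    vec proj = S2 * beta;
    for (uword i = 0; i < S2.n_rows; ++i) {
      // ties (proj == thr) go to the first group, matching the R rule
      uword pred = (proj(i) >= thr) ? 1 : 2;
      if (pred != yte(i)) ++wrong;
    }
    out[A - 1] = (double) wrong / (double) S2.n_rows;
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_inner_cv(const arma::mat& X,
                                 const arma::ivec& y1,
                                 const arma::imat& train_idx,
                                 const arma::imat& test_idx,
                                 const arma::vec& gammas,
                                 int max_components) {
  const uword q = train_idx.n_cols;
  const uword ng = gammas.n_elem;
  Rcpp::NumericVector out(Rcpp::Dimension(ng, q, max_components));
  double* o = out.begin();

  for (uword s = 0; s < q; ++s) {
    uvec tr = conv_to<uvec>::from(train_idx.col(s));
    uvec te = conv_to<uvec>::from(test_idx.col(s));
    mat Xtr = X.rows(tr);
    rowvec mu = mean(Xtr, 0);
    Xtr.each_row() -= mu;
    mat Xte = X.rows(te);
    Xte.each_row() -= mu;

    uvec ytr(tr.n_elem), yte(te.n_elem);
    for (uword i = 0; i < tr.n_elem; ++i) ytr(i) = y1(tr(i)) == 1 ? 1 : 2;
    for (uword i = 0; i < te.n_elem; ++i) yte(i) = y1(te(i)) == 1 ? 1 : 2;

    // centered signed response (+1 first group, -1 second)
    vec c0(tr.n_elem);
    for (uword i = 0; i < tr.n_elem; ++i) c0(i) = (ytr(i) == 1) ? 1.0 : -1.0;
    c0 -= mean(c0);

    for (uword gi = 0; gi < ng; ++gi) {
      mat W(X.n_cols, max_components, fill::zeros);
      mat P(X.n_cols, max_components, fill::zeros);
      mat T(tr.n_elem, max_components, fill::zeros);
      int got = ppls_fixed_fit(Xtr, c0, gammas(gi), max_components, W, P, T);
      if (got < 1) {
        for (int A = 1; A <= max_components; ++A)
          o[gi + s * ng + (A - 1) * ng * q] = 0.5;
        continue;
      }
      mat Wg = W.head_cols(got), Pg = P.head_cols(got), Tg = T.head_cols(got);
      mat R = solve(Pg.t() * Wg, eye(got, got));
      mat Tte = Xte * (Wg * R);
      std::vector<double> pe(max_components);
      lda_prefix_pe(Tg, ytr, Tte, yte, got, pe.data());
      for (int A = got + 1; A <= max_components; ++A) pe[A - 1] = pe[got - 1];
      for (int A = 1; A <= max_components; ++A)
        o[gi + s * ng + (A - 1) * ng * q] = pe[A - 1];
    }
  }
  return out;
}
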