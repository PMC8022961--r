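// Least-squares RSS kernels for Haley-Knott genome scans.
// All scans reduce to residual sums of squares of y on small design
// matrices.  Scans over many positions share a base design (null
// covariates + any model context): the base is orthonormalized once and
// projected out of both the phenotypes and the per-position columns, so
// each position costs only a small orthonormalization.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// orthonormal basis of the column space, rank-guarded; `scale` sets the
// cutoff for directions considered numerically zero
static mat orth_basis(const mat& X, const double scale) {
  uvec keep = find(sum(square(X), 0) > scale * scale * 1e-20);
  if (keep.n_elem == 0) return mat(X.n_rows, 0);
  mat Xk = X.cols(keep);
  mat Q, R;
  bool ok = qr_econ(Q, R, Xk);
  if (ok) {
    vec d = abs(R.diag());
    if (d.min() <= 1e-7 * std::max(d.max(), scale)) ok = false;
  }
  if (!ok) {
    mat U, V; vec s;
    svd_econ(U, s, V, Xk);
    Q = U.cols(find(s > 1e-7 * std::max(s.max(), scale)));
  }
  return Q;
}

static double design_scale(const mat& X) {
  if (X.n_cols == 0) return 1.0;
  return std::max(1e-300, norm(X, "fro"));
}

// RSS of each column of Y regressed on X
static rowvec rss_multi(const mat& X, const mat& Y) {
  rowvec yss = sum(square(Y), 0);
  if (X.n_cols == 0) return yss;
  mat Q = orth_basis(X, design_scale(X));
  rowvec rss = yss - sum(square(Q.t() * Y), 0);
  rss.transform([](double v) { return v > 0.0 ? v : 0.0; });
  return rss;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_rss(const arma::mat& X, const arma::mat& Y) {
  rowvec r = rss_multi(X, Y);
  return Rcpp::NumericVector(r.begin(), r.end());
}

// all pairwise elementwise products of the columns of A and B
static mat prod_cols(const mat& A, const mat& B) {
  mat out(A.n_rows, A.n_cols * B.n_cols);
  uword k = 0;
  for (uword i = 0; i < A.n_cols; ++i)
    for (uword j = 0; j < B.n_cols; ++j)
      out.col(k++) = A.col(i) % B.col(j);
  return out;
}

// residualize A against the orthonormal basis Q
static mat resid(const mat& A, const mat& Q) {
  if (Q.n_cols == 0) return A;
  return A - Q * (Q.t() * A);
}

// RSS of Yr (already residualized) on [base, C] given base residuals:
// rss_base - squared projection on the orthonormalized residual of C
static rowvec rss_extend(const mat& Cres, const double scale,
                         const rowvec& rss_base, const mat& Yr) {
  mat Qc = orth_basis(Cres, scale);
  rowvec rss = rss_base - sum(square(Qc.t() * Yr), 0);
  rss.transform([](double v) { return v > 0.0 ? v : 0.0; });
  return rss;
}

// Single-position scan: at each position p the design is
// [Xbase, C_p, C_p*P_1, C_p*P_2, ...] for the optional partner column
// sets P_k (interaction scans / profile scans).  Returns npos x B RSS.
// [[Rcpp::export]]
arma::mat cpp_rss_scan(const Rcpp::List& cols, const arma::mat& Xbase,
                       const arma::mat& Y, const Rcpp::List& partners) {
  const int npos = cols.size();
  mat out(npos, Y.n_cols);
  std::vector<mat> P;
  for (int k = 0; k < partners.size(); ++k)
    P.push_back(Rcpp::as<mat>(partners[k]));
  const double bscale = design_scale(Xbase);
  mat Qb = orth_basis(Xbase, bscale);
  mat Yr = resid(Y, Qb);
  rowvec rss_b = sum(square(Yr), 0);
  for (int p = 0; p < npos; ++p) {
    mat C = Rcpp::as<mat>(cols[p]);
    for (size_t k = 0; k < P.size(); ++k)
      C = join_rows(C, prod_cols(Rcpp::as<mat>(cols[p]), P[k]));
    double cscale = std::max(design_scale(C), bscale);
    out.row(p) = rss_extend(resid(C, Qb), cscale, rss_b, Yr);
  }
  return out;
}

// interaction columns of a pair: products of the two main-effect column
// sets, plus -- for a mixed autosome-X pair -- products of the autosomal
// columns with the stratum indicator covariates (sex-stratified epistasis)
static mat pair_prod(const mat& Ci, const mat& Cj, const bool xi,
                     const bool xj, const mat& strat) {
  mat out = prod_cols(Ci, Cj);
  if (strat.n_cols > 0 && xi != xj)
    out = join_rows(out, prod_cols(xi ? Cj : Ci, strat));
  return out;
}

// Two-QTL scan over an explicit pair list (0-based indices into cols).
// Returns full and additive RSS per pair (npair x B each).
// [[Rcpp::export]]
Rcpp::List cpp_rss_pairs(const Rcpp::List& cols, const arma::mat& X0,
                         const arma::mat& Y, const arma::ivec& pi,
                         const arma::ivec& pj, const arma::ivec& isx,
                         const arma::mat& strat) {
  const uword npair = pi.n_elem;
  const double bscale = design_scale(X0);
  mat Qb = orth_basis(X0, bscale);
  mat Yr = resid(Y, Qb);
  rowvec rss_b = sum(square(Yr), 0);
  const int npos = cols.size();
  std::vector<mat> C(npos), Cr(npos);
  for (int p = 0; p < npos; ++p) {
    C[p] = Rcpp::as<mat>(cols[p]);
    Cr[p] = resid(C[p], Qb);
  }
  mat rss_add(npair, Y.n_cols), rss_full(npair, Y.n_cols);
  for (uword p = 0; p < npair; ++p) {
    mat Cadd = join_rows(Cr[pi[p]], Cr[pj[p]]);
    double cscale = std::max(design_scale(Cadd), bscale);
    rss_add.row(p) = rss_extend(Cadd, cscale, rss_b, Yr);
    mat prod = pair_prod(C[pi[p]], C[pj[p]], isx[pi[p]] != 0,
                         isx[pj[p]] != 0, strat);
    mat Cfull = join_rows(Cadd, resid(prod, Qb));
    rss_full.row(p) = rss_extend(Cfull, cscale, rss_b, Yr);
  }
  return Rcpp::List::create(Rcpp::Named("rss_full") = rss_full,
                            Rcpp::Named("rss_add") = rss_add);
}

// Condensed two-QTL null-scan summaries: per phenotype and per
// chromosome pair (chrpair[p] in 0..nchrpair-1), the maxima over the
// pair's 2D grid of the full and of the additive LOD, maximized
// separately (the convention under which the interaction LOD of a
// chromosome pair is max(full) - max(add)); plus the per-chromosome
// maximum single-QTL LOD (chr[p] per position) for the full-versus-one
// statistic.  LODs are against the null model (X0 only).
// [[Rcpp::export]]
Rcpp::List cpp_pairs_chrpair_max(const Rcpp::List& cols, const arma::mat& X0,
                                 const arma::mat& Y, const arma::ivec& pi,
                                 const arma::ivec& pj,
                                 const arma::ivec& chrpair, const int nchrpair,
                                 const arma::ivec& chr, const int nchr,
                                 const arma::ivec& isx,
                                 const arma::mat& strat) {
  const uword npair = pi.n_elem;
  const double n2 = Y.n_rows / 2.0, l10 = std::log(10.0);
  const double bscale = design_scale(X0);
  mat Qb = orth_basis(X0, bscale);
  mat Yr = resid(Y, Qb);
  rowvec rss_b = sum(square(Yr), 0);
  rowvec lrss0 = log(rss_b);
  const int npos = cols.size();
  std::vector<mat> C(npos), Cr(npos);
  mat max1(nchr, Y.n_cols, fill::value(-datum::inf));
  for (int p = 0; p < npos; ++p) {
    C[p] = Rcpp::as<mat>(cols[p]);
    Cr[p] = resid(C[p], Qb);
    rowvec r1 = rss_extend(Cr[p], std::max(design_scale(C[p]), bscale),
                           rss_b, Yr);
    max1.row(chr[p]) = arma::max(max1.row(chr[p]),
                                 (lrss0 - log(r1)) * n2 / l10);
  }
  mat max_full(nchrpair, Y.n_cols, fill::value(-datum::inf));
  mat max_add(nchrpair, Y.n_cols, fill::value(-datum::inf));
  for (uword p = 0; p < npair; ++p) {
    mat Cadd = join_rows(Cr[pi[p]], Cr[pj[p]]);
    double cscale = std::max(design_scale(Cadd), bscale);
    rowvec ra = rss_extend(Cadd, cscale, rss_b, Yr);
    mat prod = pair_prod(C[pi[p]], C[pj[p]], isx[pi[p]] != 0,
                         isx[pj[p]] != 0, strat);
    mat Cfull = join_rows(Cadd, resid(prod, Qb));
    rowvec rf = rss_extend(Cfull, cscale, rss_b, Yr);
    int cp = chrpair[p];
    max_add.row(cp) = arma::max(max_add.row(cp), (lrss0 - log(ra)) * n2 / l10);
    max_full.row(cp) = arma::max(max_full.row(cp), (lrss0 - log(rf)) * n2 / l10);
  }
  return Rcpp::List::create(Rcpp::Named("max_full") = max_full,
                            Rcpp::Named("max_add") = max_add,
                            Rcpp::Named("max1") = max1);
}
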