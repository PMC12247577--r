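// Cross-validated Mahalanobis (LDC) kernels.
//
// These are the numeric hot paths of the package: fold-wise condition-mean
// patterns, Ledoit-Wolf shrinkage covariance, pseudoinverse, and the
// bilinear cross-validated distance forms. All randomness (fold assignment,
// subsampling) draws from R's RNG, so results are reproducible under
// set.seed() and identical to the pure-R reference engines given the same
// draws structure.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// stratified fold assignment: per condition, counts differ by <= 1
static arma::ivec make_folds(const arma::ivec& cond, int n_cond, int k) {
  int n = cond.n_elem;
  arma::ivec folds(n);
  for (int c = 1; c <= n_cond; ++c) {
    arma::uvec idx = arma::find(cond == c);
    int m = idx.n_elem;
    // random rotation of fold labels, then random assignment to trials
    IntegerVector base = sample(k, k, false);
    IntegerVector lab(m);
    for (int i = 0; i < m; ++i) lab[i] = base[i % k];
    IntegerVector shuffled = sample(lab, m, false);
    for (int i = 0; i < m; ++i) folds[idx[i]] = shuffled[i];
  }
  return folds;
}

// random subsample of `idx` equalising per-condition counts to the minimum
static arma::uvec equalise(const arma::uvec& idx, const arma::ivec& cond,
                           int n_cond) {
  std::vector<std::vector<arma::uword>> per(n_cond);
  for (arma::uword i = 0; i < idx.n_elem; ++i) {
    per[cond[idx[i]] - 1].push_back(idx[i]);
  }
  arma::uword m = arma::uword(-1);
  for (int c = 0; c < n_cond; ++c) {
    if (!per[c].empty() && per[c].size() < m) m = per[c].size();
  }
  std::vector<arma::uword> out;
  out.reserve(m * n_cond);
  for (int c = 0; c < n_cond; ++c) {
    int nc = per[c].size();
    if (nc == 0) continue;
    IntegerVector ord = sample(nc, nc, false);
    for (arma::uword j = 0; j < m; ++j) {
      out.push_back(per[c][ord[j] - 1]);
    }
  }
  return arma::uvec(out);
}

// condition-mean matrix (n_cond x p) over the rows `sel`
static arma::mat cond_means(const arma::mat& x, const arma::ivec& cond,
                            const arma::uvec& sel, int n_cond) {
  int p = x.n_cols;
  arma::mat m(n_cond, p, arma::fill::zeros);
  arma::vec cnt(n_cond, arma::fill::zeros);
  for (arma::uword i = 0; i < sel.n_elem; ++i) {
    int c = cond[sel[i]] - 1;
    m.row(c) += x.row(sel[i]);
    cnt[c] += 1.0;
  }
  for (int c = 0; c < n_cond; ++c) {
    if (cnt[c] > 0) m.row(c) /= cnt[c];
  }
  return m;
}

// Ledoit-Wolf shrinkage covariance of column-centred data
static arma::mat lw_cov(arma::mat x) {
  int n = x.n_rows, p = x.n_cols;
  arma::rowvec cm = arma::mean(x, 0);
  x.each_row() -= cm;
  arma::mat s = x.t() * x / double(n);
  double mu = arma::trace(s) / p;
  arma::mat tgt = arma::eye(p, p) * mu;
  double d2 = arma::accu(arma::square(s - tgt)) / p;
  if (d2 <= std::numeric_limits<double>::epsilon() * mu * mu) return s;
  arma::vec r2 = arma::sum(arma::square(x), 1);
  double b2bar = arma::accu(arma::square(r2)) / (double(n) * n * p) -
    arma::accu(arma::square(s)) / (double(n) * p);
  double b2 = std::min(std::max(b2bar, 0.0), d2);
  double rho = b2 / d2;
  return rho * tgt + (1.0 - rho) * s;
}

// eigendecomposition pseudoinverse with relative tolerance cutoff
static arma::mat psd_pinv_cpp(const arma::mat& sigma) {
  arma::vec eigval;
  arma::mat eigvec;
  arma::eig_sym(eigval, eigvec, arma::symmatu(sigma));
  double tol = eigval.max() * sigma.n_rows *
    std::numeric_limits<double>::epsilon();
  arma::vec inv(eigval.n_elem, arma::fill::zeros);
  for (arma::uword i = 0; i < eigval.n_elem; ++i) {
    if (eigval[i] > tol) inv[i] = 1.0 / eigval[i];
  }
  return eigvec * arma::diagmat(inv) * eigvec.t();
}

//' @noRd
// [[Rcpp::export(name = ".rdm_cv_cpp")]]
arma::mat rdm_cv_cpp(const arma::mat& x, const arma::ivec& cond,
                     int n_cond, int k, int n_reps, bool identity,
                     Rcpp::Nullable<Rcpp::IntegerMatrix> folds_in) {
  arma::mat acc(n_cond, n_cond, arma::fill::zeros);
  bool have_folds = folds_in.isNotNull();
  Rcpp::IntegerMatrix fm;
  if (have_folds) fm = folds_in.get();
  for (int rep = 0; rep < n_reps; ++rep) {
    arma::ivec folds;
    if (have_folds) {
      folds.set_size(fm.nrow());
      for (int i = 0; i < fm.nrow(); ++i) folds[i] = fm(i, rep % fm.ncol());
    } else {
      folds = make_folds(cond, n_cond, k);
    }
    for (int f = 1; f <= k; ++f) {
      arma::uvec te_all = arma::find(folds == f);
      arma::uvec tr_all = arma::find(folds != f);
      arma::uvec tr = equalise(tr_all, cond, n_cond);
      arma::uvec te = equalise(te_all, cond, n_cond);
      arma::mat m_tr = cond_means(x, cond, tr, n_cond);
      arma::mat m_te = cond_means(x, cond, te, n_cond);
      arma::mat m;
      if (identity) {
        m = m_tr * m_te.t();
      } else {
        arma::mat xc(tr.n_elem, x.n_cols);
        for (arma::uword i = 0; i < tr.n_elem; ++i) {
          xc.row(i) = x.row(tr[i]) - m_tr.row(cond[tr[i]] - 1);
        }
        arma::mat sigma = lw_cov(xc);
        m = m_tr * psd_pinv_cpp(sigma) * m_te.t();
      }
      arma::vec d = m.diag();
      acc += arma::repmat(d, 1, n_cond) + arma::repmat(d.t(), n_cond, 1) -
        m - m.t();
    }
  }
  acc /= double(n_reps * k);
  acc = (acc + acc.t()) / 2.0;
  acc.diag().zeros();
  return acc;
}

//' @noRd
// [[Rcpp::export(name = ".decode_cv_cpp")]]
arma::vec decode_cv_cpp(const arma::mat& x_train, const arma::mat& x_test,
                        const arma::ivec& lab_train,
                        const arma::ivec& lab_test,
                        const arma::uvec& test_mask, int n_class,
                        int k, int n_reps, const arma::mat& basis,
                        const arma::mat& cosmat,
                        Rcpp::Nullable<Rcpp::IntegerMatrix> folds_in) {
  int n = x_train.n_rows;
  arma::vec acc(n, arma::fill::zeros);
  bool have_folds = folds_in.isNotNull();
  Rcpp::IntegerMatrix fm;
  if (have_folds) fm = folds_in.get();
  for (int rep = 0; rep < n_reps; ++rep) {
    arma::ivec folds;
    if (have_folds) {
      folds.set_size(fm.nrow());
      for (int i = 0; i < fm.nrow(); ++i) folds[i] = fm(i, rep % fm.ncol());
    } else {
      folds = make_folds(lab_train, n_class, k);
    }
    for (int f = 1; f <= k; ++f) {
      arma::uvec te = arma::find((folds == f) && (test_mask == 1));
      if (te.n_elem == 0) continue;
      arma::uvec tr_all = arma::find(folds != f);
      arma::uvec tr = equalise(tr_all, lab_train, n_class);
      arma::mat m = cond_means(x_train, lab_train, tr, n_class);
      arma::mat xc(tr.n_elem, x_train.n_cols);
      for (arma::uword i = 0; i < tr.n_elem; ++i) {
        xc.row(i) = x_train.row(tr[i]) - m.row(lab_train[tr[i]] - 1);
      }
      arma::mat pinv = psd_pinv_cpp(lw_cov(xc));
      arma::mat sm = basis * m;                       // smoothed class means
      arma::mat xp = x_test.rows(te) * pinv;          // te x p
      arma::vec qx = arma::sum(xp % x_test.rows(te), 1);
      arma::mat sp = sm * pinv;
      arma::vec qm = arma::sum(sp % sm, 1);
      arma::mat d2 = arma::repmat(qx, 1, n_class) +
        arma::repmat(qm.t(), te.n_elem, 1) - 2.0 * x_test.rows(te) * sp.t();
      d2.transform([](double v) { return v < 0.0 ? 0.0 : v; });
      arma::mat d = arma::sqrt(d2);
      arma::vec rm = arma::mean(d, 1);
      d.each_col() -= rm;
      for (arma::uword i = 0; i < te.n_elem; ++i) {
        acc[te[i]] -= arma::dot(cosmat.row(te[i]), d.row(i)) / n_class;
      }
    }
  }
  return acc / double(n_reps);
}
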