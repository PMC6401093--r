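#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Ledoit-Wolf shrinkage intensity toward the scaled identity nu*I.
// Rows of Xc must already be centered at their own class mean.
static double lw_intensity(const arma::mat& Xc) {
  const double n = Xc.n_rows;
  const double p = Xc.n_cols;
  arma::mat Sbar = (Xc.t() * Xc) / n;
  double m = arma::trace(Sbar) / p;
  double d2 = arma::accu(arma::square(Sbar)) / p - m * m;
  if (d2 <= 0.0) return 1.0;
  double sum4 = 0.0;
  for (arma::uword i = 0; i < Xc.n_rows; ++i) {
    double q = arma::dot(Xc.row(i), Xc.row(i));
    sum4 += q * q;
  }
  double b2 = (sum4 / n - arma::accu(arma::square(Sbar))) / (n * p);
  if (b2 < 0.0) b2 = 0.0;
  if (b2 > d2) b2 = d2;
  return b2 / d2;
}

// fold-wise discriminant weights by direct dense solve (general path)
static arma::vec fold_weights_direct(const arma::mat& Sai, const arma::mat& Sb_full,
                                     const arma::rowvec& db, double cb,
                                     double dfp, double lam, double p,
                                     const arma::rowvec& delta) {
  arma::mat S = Sai + Sb_full - cb * (db.t() * db);
  S /= dfp;
  double nu = arma::trace(S) / p;
  S *= (1.0 - lam);
  S.diag() += lam * nu;
  arma::vec w;
  // a structurally rank-deficient scatter (fewer training df than
  // features, only possible at lam = 0) goes straight to the
  // minimum-norm pseudo-inverse; a numerically spurious solve of a
  // near-singular system is caught by its residual
  bool ok = (lam > 0.0 || dfp >= p) &&
    arma::solve(w, S, delta.t(),
                arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
  if (ok) {
    double rel = arma::norm(S * w - delta.t()) /
      std::max(arma::norm(delta), 1e-300);
    if (!std::isfinite(rel) || rel > 1e-6) ok = false;
  }
  if (!ok) w = arma::pinv(S) * delta.t();
  return w;
}

// Leave-one-stimulus-pair-out CV accuracy for a two-class LDA with a
// pooled covariance refit inside every training fold.  lambda = 0 is
// plain LDA (minimum-norm pseudo-inverse if singular); lambda in (0, 1]
// shrinks toward the scaled identity; lambda < 0 requests the
// Ledoit-Wolf intensity estimated once on the full class-centered data
// of the pair.  matched = TRUE pairs trial i of class a with trial i of
// class b (n folds); otherwise all na*nb cross-class pairs are folds.
// Discriminant ties (score exactly 0) are assigned to the first class.
//
// For lambda = 0 the fold covariance differs from the full pooled
// scatter by two symmetric rank-1 downdates, so the fold discriminant
// is obtained from the precomputed full inverse by two Sherman-Morrison
// steps (O(p) per fold); near-singular downdates fall back to a dense
// solve.
static double pair_cv_impl(const arma::mat& Xa, const arma::mat& Xb,
                           double lambda, bool matched) {
  const int na = Xa.n_rows, nb = Xb.n_rows;
  const double p = Xa.n_cols;
  arma::rowvec ma = arma::mean(Xa, 0), mb = arma::mean(Xb, 0);
  arma::mat Xac = Xa.each_row() - ma;
  arma::mat Xbc = Xb.each_row() - mb;
  arma::mat Sa = Xac.t() * Xac;
  arma::mat Sb = Xbc.t() * Xbc;
  const double ca = na / (na - 1.0), cb = nb / (nb - 1.0);
  const double dfp = na + nb - 4.0;  // pooled df after both training means

  double lam = lambda;
  if (lam < 0.0) lam = lw_intensity(arma::join_cols(Xac, Xbc));

  int correct = 0, total = 0;

  if (lam == 0.0) {
    arma::mat Sfull = Sa + Sb;
    arma::mat Sinv;
    // the Sherman-Morrison shortcut needs a comfortably invertible full
    // scatter: enough df to absorb both rank-1 downdates, a successful
    // SPD inverse, and decent conditioning.  Otherwise every fold takes
    // the dense path (with its pseudo-inverse fallback): a spuriously
    // "successful" inverse of a singular scatter would leak the held-out
    // trials back in through amplified round-off.
    bool spd = (dfp >= p + 2) && arma::inv_sympd(Sinv, Sfull);
    if (spd && arma::rcond(Sfull) < 1e-10) spd = false;
    // columns: Sinv * centered trials; Sinv * (ma - mb)
    arma::vec delta0 = (ma - mb).t();
    arma::mat U, V;
    arma::vec sdelta0;
    if (spd) {
      U = Sinv * Xac.t();
      V = Sinv * Xbc.t();
      sdelta0 = Sinv * delta0;
    }
    for (int i = 0; i < na; ++i) {
      arma::vec da = Xac.row(i).t();
      arma::vec u;
      double denom_a = 0.0;
      if (spd) {
        u = U.col(i);
        denom_a = 1.0 - ca * arma::dot(da, u);
      }
      arma::rowvec mai = ma - Xac.row(i) / (na - 1.0);
      const int jlo = matched ? i : 0;
      const int jhi = matched ? i + 1 : nb;
      for (int j = jlo; j < jhi; ++j) {
        arma::vec db = Xbc.row(j).t();
        arma::rowvec mbj = mb - Xbc.row(j) / (nb - 1.0);
        arma::vec delta = delta0 - da / (na - 1.0) + db / (nb - 1.0);
        arma::vec w;
        double denom_b = 0.0;
        bool sm_ok = spd && std::abs(denom_a) > 1e-10;
        if (sm_ok) {
          arma::vec sdelta = sdelta0 - U.col(i) / (na - 1.0) + V.col(j) / (nb - 1.0);
          arma::vec w1 = sdelta + (ca * arma::dot(da, sdelta) / denom_a) * u;
          arma::vec b1 = V.col(j) + (ca * arma::dot(da, V.col(j)) / denom_a) * u;
          denom_b = 1.0 - cb * arma::dot(db, b1);
          if (std::abs(denom_b) > 1e-10)
            w = w1 + (cb * arma::dot(db, w1) / denom_b) * b1;
          else sm_ok = false;
        }
        if (!sm_ok) {
          arma::mat Sai = Sa - ca * (da * da.t());
          w = fold_weights_direct(Sai, Sb, Xbc.row(j), cb, dfp, 0.0, p,
                                  arma::rowvec(delta.t()));
        }
        double c0 = 0.5 * arma::dot(w, (mai + mbj).t());
        double sa = arma::dot(w, Xa.row(i).t()) - c0;
        double sb = arma::dot(w, Xb.row(j).t()) - c0;
        correct += (sa >= 0.0 ? 1 : 0) + (sb < 0.0 ? 1 : 0);
        total += 2;
      }
    }
    return static_cast<double>(correct) / total;
  }

  for (int i = 0; i < na; ++i) {
    arma::rowvec da = Xac.row(i);
    arma::rowvec mai = ma - da / (na - 1.0);
    arma::mat Sai = Sa - ca * (da.t() * da);
    const int jlo = matched ? i : 0;
    const int jhi = matched ? i + 1 : nb;
    for (int j = jlo; j < jhi; ++j) {
      arma::rowvec db = Xbc.row(j);
      arma::rowvec mbj = mb - db / (nb - 1.0);
      arma::rowvec delta = mai - mbj;
      arma::vec w = fold_weights_direct(Sai, Sb, db, cb, dfp, lam, p, delta);
      double c0 = arma::dot(w, 0.5 * (mai + mbj).t());
      double sa = arma::dot(w, Xa.row(i).t()) - c0;
      double sb = arma::dot(w, Xb.row(j).t()) - c0;
      correct += (sa >= 0.0 ? 1 : 0) + (sb < 0.0 ? 1 : 0);
      total += 2;
    }
  }
  return static_cast<double>(correct) / total;
}

// [[Rcpp::export]]
double lda_pair_cv_cpp(const arma::mat& Xa, const arma::mat& Xb,
                       double lambda, bool matched) {
  if (Xa.n_cols != Xb.n_cols)
    stop("class pattern matrices must share the feature dimension");
  if (Xa.n_rows != Xb.n_rows)
    stop("pairwise decoding requires equal class sizes");
  if (Xa.n_rows < 2) stop("need at least 2 trials per class");
  return pair_cv_impl(Xa, Xb, lambda, matched);
}

// All pairwise CV accuracies among k classes.  y holds 0-based class ids;
// the returned k x k matrix is symmetric with NaN on the diagonal.
// [[Rcpp::export]]
NumericMatrix pair_accuracy_matrix_cpp(const arma::mat& X, const IntegerVector& y,
                                       int k, double lambda, bool matched) {
  std::vector<std::vector<arma::uword> > rows(k);
  for (int i = 0; i < y.size(); ++i) {
    if (y[i] < 0 || y[i] >= k) stop("class id out of range");
    rows[y[i]].push_back(i);
  }
  NumericMatrix out(k, k);
  std::fill(out.begin(), out.end(), R_NaN);
  for (int a = 0; a < k; ++a) {
    for (int b = a + 1; b < k; ++b) {
      arma::uvec ia(rows[a]), ib(rows[b]);
      if (ia.n_elem < 2 || ib.n_elem < 2)
        stop("need at least 2 trials per class");
      if (ia.n_elem != ib.n_elem)
        stop("pairwise decoding requires equal class sizes");
      double acc = pair_cv_impl(X.rows(ia), X.rows(ib), lambda, matched);
      out(a, b) = acc;
      out(b, a) = acc;
    }
  }
  return out;
}

// Search over random assignments of trials to the 2x2 similarity cells.
// pair_i/pair_j are 0-based trial ids of every unordered trial pair and
// pair_cat the pair's true cell (0..3).  A pair contributes to a cell only
// when both trials land in it and the cell matches the pair's category.
// The score of a draw is the geometric mean of each cell's share of all
// retained (congruent) pairs, so equal spread across cells wins; draws
// leaving any cell without a congruent pair score zero.  Uses R's RNG.
// [[Rcpp::export]]
List best_cell_draw_cpp(const IntegerVector& pair_i, const IntegerVector& pair_j,
                        const IntegerVector& pair_cat, int n_trials, int n_draws) {
  const int npair = pair_i.size();
  IntegerVector best_assign(n_trials, 0);
  double best_score = -1.0;
  int best_draw = -1;
  std::vector<int> assign(n_trials);
  for (int d = 0; d < n_draws; ++d) {
    for (int t = 0; t < n_trials; ++t) {
      int c = static_cast<int>(unif_rand() * 4.0);
      if (c > 3) c = 3;
      assign[t] = c;
    }
    int cong[4] = {0, 0, 0, 0};
    for (int q = 0; q < npair; ++q) {
      int ci = assign[pair_i[q]];
      if (ci == assign[pair_j[q]] && ci == pair_cat[q]) ++cong[ci];
    }
    double tot = cong[0] + cong[1] + cong[2] + cong[3];
    double score = 0.0;
    if (cong[0] > 0 && cong[1] > 0 && cong[2] > 0 && cong[3] > 0) {
      double lg = 0.0;
      for (int c = 0; c < 4; ++c) lg += std::log(cong[c] / tot);
      score = std::exp(lg / 4.0);
    }
    if (score > best_score || best_draw < 0) {
      best_score = score;
      best_draw = d;
      std::copy(assign.begin(), assign.end(), best_assign.begin());
    }
  }
  return List::create(_["assignment"] = best_assign,
                      _["score"] = best_score,
                      _["congruent"] = best_score > 0.0,
                      _["draw"] = best_draw + 1);
}
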