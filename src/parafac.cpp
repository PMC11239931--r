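// Fixed-mode rank-R CP (PARAFAC) alternating least squares and the core
// consistency diagnostic, specialised for a 3-way tensor whose first mode
// is frozen to a model-derived factor matrix. Also hosts the 4-connected
// component labelling used by the cluster permutation test.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// mode-1 slice X(i, :, :) as a J x K matrix
static mat mode1_slice(const cube& X, uword i) {
  const uword J = X.n_cols, K = X.n_slices;
  mat out(J, K);
  for (uword k = 0; k < K; ++k) out.col(k) = X.slice(k).row(i).t();
  return out;
}

// mode-3 unfolding, K x (I*J), column index i + j*I
static mat unfold3(const cube& X) {
  const uword I = X.n_rows, J = X.n_cols, K = X.n_slices;
  mat out(K, I * J);
  for (uword k = 0; k < K; ++k) {
    out.row(k) = vectorise(X.slice(k)).t();
  }
  return out;
}

static mat solve_gram(const mat& gram, const mat& rhs) {
  // factor update solves rhs * gram^{-1} for a tiny symmetric gram;
  // rank-2 grams are inverted in closed form, falling back to the
  // pseudo-inverse when (near-)singular
  if (gram.n_rows == 2) {
    const double a = gram(0, 0), b = gram(0, 1), d = gram(1, 1);
    const double det = a * d - b * b;
    if (std::fabs(det) > 1e-12 * std::max(a * d, b * b) && det != 0.0) {
      mat out(rhs.n_rows, 2);
      const double i00 = d / det, i01 = -b / det, i11 = a / det;
      out.col(0) = rhs.col(0) * i00 + rhs.col(1) * i01;
      out.col(1) = rhs.col(0) * i01 + rhs.col(1) * i11;
      return out;
    }
  }
  mat sol;
  if (!solve(sol, gram, rhs.t(), solve_opts::no_approx)) {
    sol = pinv(gram) * rhs.t();
  }
  return sol.t();
}

struct AlsFit {
  mat B, C;
  double rss;
  int n_iter;
  bool converged;
  bool monotone;
};

// ALS updating only B and C with A fixed; stops when the relative change
// in RSS falls below tol. The first mode has length 2, so the tensor is
// carried as its two mode-1 slices Xm[0], Xm[1] (J x K each) and each
// cell precontracts T_r = A(0,r) Xm[0] + A(1,r) Xm[1], after which both
// factor updates are plain matrix-vector products.
static AlsFit als_fixed(const mat& Xm0, const mat& Xm1, const mat& A,
                        mat C, double tol, int max_iter) {
  const uword R = A.n_cols;
  const uword J = Xm0.n_rows, K = Xm0.n_cols;
  const mat AtA = A.t() * A;
  const double normX = accu(square(Xm0)) + accu(square(Xm1));
  std::vector<mat> T(R);
  for (uword r = 0; r < R; ++r) T[r] = A(0, r) * Xm0 + A(1, r) * Xm1;
  AlsFit fit;
  fit.converged = false;
  fit.monotone = true;
  double rss_prev = datum::inf;
  mat B(J, R), Brhs(J, R), Crhs(K, R);
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    for (uword r = 0; r < R; ++r) Brhs.col(r) = T[r] * C.col(r);
    B = solve_gram((C.t() * C) % AtA, Brhs);
    for (uword r = 0; r < R; ++r) Crhs.col(r) = T[r].t() * B.col(r);
    mat gramB = (B.t() * B) % AtA;
    C = solve_gram(gramB, Crhs);
    // rss via the normal-equation identity; clamp tiny negative round-off
    double rss = normX - 2.0 * accu(C % Crhs) + accu((C.t() * C) % gramB);
    if (rss < 0) rss = 0;
    if (rss > rss_prev * (1.0 + 1e-10) + 1e-12 * normX) fit.monotone = false;
    // exact fits bottom out at numerical zero relative to the tensor norm
    if (rss <= 1e-14 * normX) {
      rss_prev = rss;
      fit.converged = true;
      break;
    }
    double denom = std::max(rss_prev, 1e-300);
    if (std::isfinite(rss_prev) && std::fabs(rss_prev - rss) / denom < tol) {
      rss_prev = rss;
      fit.converged = true;
      break;
    }
    rss_prev = rss;
  }
  fit.B = B;
  fit.C = C;
  fit.rss = rss_prev;
  fit.n_iter = std::min(it, max_iter);
  return fit;
}

// deterministic start: leading left singular vectors of the mode-3 unfolding
static mat det_start(const mat& X3, uword R) {
  mat U;
  vec s;
  mat V;
  if (svd_econ(U, s, V, X3, "left") && U.n_cols >= R) {
    return U.cols(0, R - 1);
  }
  return ones<mat>(X3.n_rows, R);
}

// least-squares Tucker core given the CP factors (fixed A included as an
// ordinary factor), then Bro & Kiers' consistency in percent with the
// superdiagonal target; denominator = sum(t^2) = R.
// g_{pqr} = sum_i pA(p,i) * (pB * Xm_i * pC')(q,r).
static double core_consistency_slices(const mat& Xm0, const mat& Xm1,
                                      const mat& A, const mat& B,
                                      const mat& C) {
  const uword R = A.n_cols;
  if (norm(B, "fro") == 0 || norm(C, "fro") == 0) return datum::nan;
  mat pA, pB, pC;
  bool ok = pinv(pA, A) && pinv(pB, B) && pinv(pC, C);
  if (!ok) return datum::nan;
  mat W0 = pB * (Xm0 * pC.t());
  mat W1 = pB * (Xm1 * pC.t());
  double num = 0.0;
  for (uword p = 0; p < R; ++p) {
    for (uword q = 0; q < R; ++q) {
      for (uword r = 0; r < R; ++r) {
        double g = pA(p, 0) * W0(q, r) + pA(p, 1) * W1(q, r);
        double t = (p == q && q == r) ? 1.0 : 0.0;
        num += (g - t) * (g - t);
      }
    }
  }
  if (!std::isfinite(num)) return datum::nan;
  return 100.0 * (1.0 - num / double(R));
}

static double core_consistency_impl(const cube& X, const mat& A,
                                    const mat& B, const mat& C) {
  return core_consistency_slices(mode1_slice(X, 0), mode1_slice(X, 1),
                                 A, B, C);
}

// fix the scale and sign indeterminacy left by the frozen mode: unit-norm
// C columns with the largest-magnitude entry positive, magnitude and sign
// absorbed into B
static void normalise_fit(mat& B, mat& C) {
  for (uword r = 0; r < C.n_cols; ++r) {
    double nrm = norm(C.col(r));
    if (nrm > 0) {
      C.col(r) /= nrm;
      B.col(r) *= nrm;
      uword imax = index_max(abs(C.col(r)));
      if (C(imax, r) < 0) {
        C.col(r) = -C.col(r);
        B.col(r) = -B.col(r);
      }
    }
  }
}

// [[Rcpp::export(name = ".cp_als_fixed_cpp")]]
Rcpp::List cp_als_fixed_cpp(const arma::cube& X, const arma::mat& A,
                            const arma::mat& C0, double tol, int max_iter,
                            bool also_det_start) {
  mat Xm0 = mode1_slice(X, 0);
  mat Xm1 = mode1_slice(X, 1);
  AlsFit best = als_fixed(Xm0, Xm1, A, C0, tol, max_iter);
  int n_starts = 1;
  if (also_det_start) {
    mat X3 = unfold3(X);
    AlsFit alt = als_fixed(Xm0, Xm1, A, det_start(X3, A.n_cols), tol, max_iter);
    ++n_starts;
    if (alt.rss < best.rss) best = alt;
  }
  normalise_fit(best.B, best.C);
  double cc = core_consistency_impl(X, A, best.B, best.C);
  return Rcpp::List::create(
      Rcpp::Named("B") = best.B, Rcpp::Named("C") = best.C,
      Rcpp::Named("rss") = best.rss,
      Rcpp::Named("core_consistency") = cc,
      Rcpp::Named("converged") = best.converged,
      Rcpp::Named("n_iter") = best.n_iter,
      Rcpp::Named("monotone") = best.monotone,
      Rcpp::Named("n_starts") = n_starts);
}

// [[Rcpp::export(name = ".core_consistency_cpp")]]
double core_consistency_cpp(const arma::cube& X, const arma::mat& A,
                            const arma::mat& B, const arma::mat& C) {
  return core_consistency_impl(X, A, B, C);
}

// Evaluate the full scaling-factor grid: one fixed-mode fit per candidate
// contrast matrix, shared random start plus a deterministic start per cell.
// [[Rcpp::export(name = ".cp_grid_cpp")]]
Rcpp::List cp_grid_cpp(const arma::cube& X, const arma::cube& Amats,
                       const arma::mat& C0, double tol, int max_iter) {
  const uword ncell = Amats.n_slices;
  mat Xm0 = mode1_slice(X, 0);
  mat Xm1 = mode1_slice(X, 1);
  mat Cdet = det_start(unfold3(X), Amats.n_cols);
  vec rss(ncell), cc(ncell);
  ivec n_iter(ncell);
  for (uword c = 0; c < ncell; ++c) {
    const mat A = Amats.slice(c);
    AlsFit f1 = als_fixed(Xm0, Xm1, A, C0, tol, max_iter);
    AlsFit f2 = als_fixed(Xm0, Xm1, A, Cdet, tol, max_iter);
    AlsFit& best = (f2.rss < f1.rss) ? f2 : f1;
    normalise_fit(best.B, best.C);
    rss(c) = best.rss;
    cc(c) = core_consistency_slices(Xm0, Xm1, A, best.B, best.C);
    n_iter(c) = best.n_iter;
    if (c % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("rss") = rss,
                            Rcpp::Named("core_consistency") = cc,
                            Rcpp::Named("n_iter") = n_iter);
}

// 4-connected component labelling of a logical matrix (no diagonals).
// [[Rcpp::export(name = ".label_components_cpp")]]
Rcpp::IntegerMatrix label_components_cpp(const Rcpp::LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  Rcpp::IntegerMatrix labels(nr, nc);
  int next_label = 0;
  std::vector<std::pair<int, int>> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || labels(i, j) != 0) continue;
      ++next_label;
      stack.clear();
      stack.emplace_back(i, j);
      labels(i, j) = next_label;
      while (!stack.empty()) {
        auto [r, c] = stack.back();
        stack.pop_back();
        const int dr[4] = {-1, 1, 0, 0};
        const int dc[4] = {0, 0, -1, 1};
        for (int d = 0; d < 4; ++d) {
          int rr = r + dr[d], cc2 = c + dc[d];
          if (rr < 0 || rr >= nr || cc2 < 0 || cc2 >= nc) continue;
          if (mask(rr, cc2) && labels(rr, cc2) == 0) {
            labels(rr, cc2) = next_label;
            stack.emplace_back(rr, cc2);
          }
        }
      }
    }
  }
  return labels;
}
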