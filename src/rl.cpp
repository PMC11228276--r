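#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Mode-n products of a 3-way array with per-axis transfer matrices,
// writing into a caller-supplied buffer.  F has dims (ox, oy, oz);
// Ax is (dx x ox), Ay (dy x oy), Az (dz x oz); out has dims (dx, dy, dz).
static void mode_products(const cube& F, const mat& Ax, const mat& Ay,
                          const mat& Az, cube& T1, cube& T2, cube& out) {
  const uword dx = Ax.n_rows, dy = Ay.n_rows;
  const uword oy = F.n_cols, oz = F.n_slices;
  for (uword k = 0; k < oz; ++k) T1.slice(k) = Ax * F.slice(k);
  for (uword k = 0; k < oz; ++k) T2.slice(k) = T1.slice(k) * Ay.t();
  const mat M(const_cast<double*>(T2.memptr()), dx * dy, oz, false, true);
  mat R(out.memptr(), dx * dy, Az.n_rows, false, true);
  R = M * Az.t();
}

// Richardson-Lucy iterations for a separable, column-normalized forward
// operator A = Az (x) Ay (x) Ax (Kronecker over axes).  Columns of A sum to
// one, so the total flux of the iterate equals sum(counts) at every
// iteration exactly (up to round-off).  Returns the final estimate, the
// Poisson log-likelihood trace and the iteration count.
// [[Rcpp::export(name = ".rl_core")]]
Rcpp::List rl_core(const arma::cube& counts, const arma::mat& Ax,
                   const arma::mat& Ay, const arma::mat& Az,
                   const int n_iter, const double tol) {
  const uword ox = Ax.n_cols, oy = Ay.n_cols, oz = Az.n_cols;
  const uword dx = Ax.n_rows, dy = Ay.n_rows, dz = Az.n_rows;
  const double total = accu(counts);
  const bool d1 = (oy == 1 && oz == 1 && dy == 1 && dz == 1);

  cube f(ox, oy, oz);
  f.fill(total / double(ox * oy * oz));
  std::vector<double> ll_trace;
  double ll_prev = -datum::inf;
  int it = 0;
  const mat Axt = Ax.t(), Ayt = Ay.t(), Azt = Az.t();

  // workspaces
  cube m(dx, dy, dz), T1f(dx, oy, oz), T2f(dx, dy, oz), ratio(dx, dy, dz);
  cube corr(ox, oy, oz), T1b(ox, dy, dz), T2b(ox, oy, dz);

  // 1D fast path views
  vec fv(f.memptr(), ox, false, true);
  vec mv(m.memptr(), dx, false, true);
  vec cv(corr.memptr(), ox, false, true);
  const vec dvec = d1 ? vec(counts.memptr(), dx) : vec();

  for (it = 0; it < n_iter; ++it) {
    double ll;
    if (d1) {
      mv = Ax * fv;
      mv.transform([](double v) { return v > 1e-300 ? v : 1e-300; });
      ll = dot(dvec, log(mv)) - total;
      cv = Axt * (dvec / mv);
      fv %= cv;
    } else {
      mode_products(f, Ax, Ay, Az, T1f, T2f, m);
      m.transform([](double v) { return v > 1e-300 ? v : 1e-300; });
      ll = accu(counts % log(m)) - total;  // sum(m) == total exactly
      ratio = counts / m;
      mode_products(ratio, Axt, Ayt, Azt, T1b, T2b, corr);
      f %= corr;
    }
    ll_trace.push_back(ll);
    if (tol > 0 && it > 0) {
      double gain = ll - ll_prev;
      if (gain >= 0 && gain < tol * std::abs(ll)) { ++it; break; }
    }
    ll_prev = ll;
  }
  return Rcpp::List::create(
      Rcpp::Named("estimate") = f,
      Rcpp::Named("loglik") = ll_trace,
      Rcpp::Named("iterations") = it);
}
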