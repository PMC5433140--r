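// Multiplicative-update NMF for the generalized Kullback-Leibler
// divergence (Brunet-style), with an epsilon guard inside divisions and
// two early-stopping rules: relative loss change below tol (assessed at
// a check interval), or the column-cluster (connectivity) assignment of
// H staying unchanged for conn_stop consecutive iterations.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// D(V || WH) = sum V log(V/WH) - V + WH over all entries, 0 log 0 := 0.
// vlogv (= sum v log v over nonzeros) and sum(V) are precomputed; the
// sum over WH uses sum(WH) = dot(colsums(W), rowsums(H)).
static double kl_loss(const mat& V, const mat& W, const mat& H,
                      const uvec& nz, double vlogv, double vsum,
                      double eps) {
  double whsum = dot(sum(W, 0), sum(H, 1));
  mat WH = W * H;
  vec wh = WH.elem(nz);
  vec v = V.elem(nz);
  return vlogv - accu(v % arma::log(wh + eps)) - vsum + whsum;
}

// cluster index per column of H (argmax over rows; ties -> lowest row)
static uvec h_clusters(const mat& H) {
  uvec cl(H.n_cols);
  for (uword k = 0; k < H.n_cols; ++k) {
    cl(k) = H.col(k).index_max();
  }
  return cl;
}

// [[Rcpp::export(name = ".nmf_kl_cpp")]]
Rcpp::List nmf_kl_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol, int conn_stop,
                      double eps, bool trace_loss) {
  const uvec nz = find(V > 0);
  const vec vnz = V.elem(nz);
  const double vlogv = accu(vnz % arma::log(vnz));
  const double vsum = accu(V);
  const int loss_interval = trace_loss ? 1 : 10;

  double loss = kl_loss(V, W, H, nz, vlogv, vsum, eps);
  std::vector<double> trace;
  if (trace_loss) trace.push_back(loss);

  uvec conn = h_clusters(H);
  int conn_unchanged = 0;
  int iter = 0;
  int last_check = 0;
  std::string stopped = "max_iter";

  mat R(V.n_rows, V.n_cols);
  mat numH(H.n_rows, H.n_cols);
  mat numW(W.n_rows, W.n_cols);
  for (iter = 1; iter <= max_iter; ++iter) {
    // H update
    R = W * H;
    R += eps;
    R = V / R;
    rowvec wsum = sum(W, 0);          // 1 x r
    numH = W.t() * R;
    H %= numH;
    H.each_col() /= (wsum.t() + eps);

    // W update with fresh H
    R = W * H;
    R += eps;
    R = V / R;
    colvec hsum = sum(H, 1);          // r x 1
    numW = R * H.t();
    W %= numW;
    W.each_row() /= (hsum.t() + eps);

    if (iter % loss_interval == 0 || iter == max_iter) {
      double new_loss = kl_loss(V, W, H, nz, vlogv, vsum, eps);
      if (trace_loss) trace.push_back(new_loss);
      if (!std::isfinite(new_loss)) {
        Rcpp::stop("NMF loss became non-finite at iteration %d", iter);
      }
      // per-iteration relative change, averaged over the check window
      double rel = std::fabs(loss - new_loss) /
        (std::max(std::fabs(loss), eps) * (iter - last_check));
      loss = new_loss;
      last_check = iter;
      if (rel < tol) { stopped = "loss_tol"; break; }
    }

    if (conn_stop > 0) {
      uvec new_conn = h_clusters(H);
      if (all(new_conn == conn)) {
        if (++conn_unchanged >= conn_stop) {
          stopped = "connectivity";
          break;
        }
      } else {
        conn_unchanged = 0;
        conn = new_conn;
      }
    }
  }

  loss = kl_loss(V, W, H, nz, vlogv, vsum, eps);
  double rss = accu(square(V - W * H));
  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("H") = H,
    Rcpp::Named("loss") = loss,
    Rcpp::Named("rss") = rss,
    Rcpp::Named("n_iter") = std::min(iter, max_iter),
    Rcpp::Named("stopped") = stopped,
    Rcpp::Named("loss_trace") = trace
  );
}
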