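// Sum-factorised 3-mode tensor contraction for the spline design.
//
// Computes F[i,j,k] = sum_{p,q,r} Mx[i,p] My[j,q] Mz[k,r] A[p,q,r]
// without materialising permuted copies: mode 1 as one GEMM, mode 2 as
// slice-wise GEMMs, mode 3 as one GEMM on the flattened slab.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".contract3")]]
arma::vec contract3(const arma::vec& a, const arma::ivec& dims,
                    const arma::mat& Mx, const arma::mat& My,
                    const arma::mat& Mz) {
  const arma::uword nx = dims[0], ny = dims[1], nz = dims[2];
  const arma::uword vx = Mx.n_rows, vy = My.n_rows, vz = Mz.n_rows;

  // mode 1: (vx, ny*nz)
  arma::mat m1 = Mx * arma::reshape(a, nx, ny * nz);

  // mode 2: per z-slice (vx, ny) * (ny, vy)
  arma::cube c1(m1.memptr(), vx, ny, nz);
  arma::cube c2(vx, vy, nz);
  for (arma::uword k = 0; k < nz; ++k)
    c2.slice(k) = c1.slice(k) * My.t();

  // mode 3: (vx*vy, nz) * (nz, vz)
  arma::mat m3(c2.memptr(), vx * vy, nz, false, true);
  arma::mat out = m3 * Mz.t();
  return arma::vectorise(out);
}
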