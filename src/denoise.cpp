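#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Kernel factors. Normalizing constants are omitted: every quantity the
// procedure computes (WLS coefficients, weighted residual mean squares,
// their differences D) uses weight ratios only, so a constant factor per
// kernel cancels exactly. ktype 0 = truncated Gaussian, 1 = eps-optimal
// bimodal (used by the modified CV; K_eps(0) = 0 makes leave-one-out
// automatic).
static inline double kern_eval(double v, int ktype, double eps) {
  double a = std::fabs(v);
  if (a >= 1.0) return 0.0;
  if (ktype == 0) {
    return std::exp(-0.5 * v * v) - 0.60653065971263342; // exp(-1/2)
  }
  if (a >= eps) return 0.75 * (1.0 - v * v);
  return 0.75 * (1.0 - eps * eps) / eps * a;
}

// Solve the 4x4 (or 3x3 when the temporal window holds a single frame)
// normal equations. Returns false when the moment matrix is ill-conditioned
// (reciprocal condition below 1e-12), in which case the caller falls back.
static inline bool solve_normal(const arma::mat& M, const arma::vec& r,
                                arma::vec& beta) {
  double rc = arma::rcond(M);
  if (!std::isfinite(rc) || rc < 1e-12) return false;
  return arma::solve(beta, M, r, arma::solve_opts::no_approx);
}

// Full denoising pass. Evaluates the combined jump-preserving estimator at
// every voxel on the (sx, sy, st) strided sublattice (stride 1 = all voxels).
// Returns the estimate array, the per-voxel decision code
// (0 FULL, 1 SIDE1, 2 SIDE2, 3 TIE_AVG, NA where not evaluated), and the
// mean squared difference between the estimate and the observation over the
// evaluated voxels (this is the modified CV score when ktype = 1).
// [[Rcpp::export]]
List denoise_engine(NumericVector z, double hx, double hy, double ht,
                    double u, int ktype, double eps, bool jump,
                    int sx, int sy, int st) {
  IntegerVector dims = z.attr("dim");
  if (dims.size() != 3) stop("`z` must be a 3-D array");
  const int nx = dims[0], ny = dims[1], nt = dims[2];
  const double* zp = REAL(z);

  // Spatial offsets with positive weight: radial kernel on the ellipse
  // (dx/hx)^2 + (dy/hy)^2 <= 1 in [0,1]-scale coordinates x_i = i/nx.
  std::vector<int> sdi, sdj;
  std::vector<double> sdx, sdy, swt;
  const int rx = (int)std::floor(hx * nx + 1e-9);
  const int ry = (int)std::floor(hy * ny + 1e-9);
  for (int di = -rx; di <= rx; ++di) {
    for (int dj = -ry; dj <= ry; ++dj) {
      double ux = di / (hx * nx), vy = dj / (hy * ny);
      double w = kern_eval(std::sqrt(ux * ux + vy * vy), ktype, eps);
      if (w > 0.0) {
        sdi.push_back(di); sdj.push_back(dj);
        sdx.push_back((double)di / nx); sdy.push_back((double)dj / ny);
        swt.push_back(w);
      }
    }
  }
  // Temporal offsets with positive weight.
  std::vector<int> tdk;
  std::vector<double> tdt, twt;
  const int rt = (int)std::floor(ht * nt + 1e-9);
  for (int dk = -rt; dk <= rt; ++dk) {
    double w = kern_eval(dk / (ht * nt), ktype, eps);
    if (w > 0.0) {
      tdk.push_back(dk); tdt.push_back((double)dk / nt); twt.push_back(w);
    }
  }
  if (sdi.empty() || tdk.empty())
    stop("degenerate neighborhood: no voxel receives positive weight; increase the bandwidths");

  // With a single-frame temporal window the t-offsets are identically zero
  // and the d column is dropped (per-frame 2-D fit). The same drop is
  // applied per voxel when boundary clipping leaves no temporal spread.
  const bool fit_t_global = !(tdk.size() == 1 && tdk[0] == 0);

  const size_t nmax = sdi.size() * tdk.size();
  std::vector<double> zv(nmax), wv(nmax), ox(nmax), oy(nmax), ot(nmax);
  std::vector<int> side(nmax);

  NumericVector fhat(nx * ny * nt, NA_REAL);
  IntegerVector decision(nx * ny * nt, NA_INTEGER);
  fhat.attr("dim") = dims;
  decision.attr("dim") = dims;

  arma::mat M(4, 4), M1(4, 4), M2(4, 4);
  arma::vec rhs(4), r1(4), r2(4), b1, b2;

  double ss = 0.0;
  long long n_eval = 0;
  const int ox0 = sx / 2, oy0 = sy / 2, ot0 = st / 2;

  for (int ck = ot0; ck < nt; ck += st) {
    for (int cj = oy0; cj < ny; cj += sy) {
      for (int ci = ox0; ci < nx; ci += sx) {
        // Gather the clipped neighborhood.
        int n = 0;
        double tmin = 1e30, tmax = -1e30;
        for (size_t q = 0; q < tdk.size(); ++q) {
          int k2 = ck + tdk[q];
          if (k2 < 0 || k2 >= nt) continue;
          const double* frame = zp + (size_t)nx * ny * k2;
          if (tdt[q] < tmin) tmin = tdt[q];
          if (tdt[q] > tmax) tmax = tdt[q];
          for (size_t s = 0; s < sdi.size(); ++s) {
            int i2 = ci + sdi[s], j2 = cj + sdj[s];
            if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny) continue;
            zv[n] = frame[i2 + (size_t)nx * j2];
            wv[n] = swt[s] * twt[q];
            ox[n] = sdx[s]; oy[n] = sdy[s]; ot[n] = tdt[q];
            ++n;
          }
        }
        if (n < 4)
          stop("degenerate neighborhood at voxel (%d, %d, %d): fewer than 4 voxels with positive weight",
               ci + 1, cj + 1, ck + 1);
        // no temporal spread in this clipped neighborhood: drop the d column
        const bool fit_t = fit_t_global && (tmax > tmin);
        const int p = fit_t ? 4 : 3;

        // Full-neighborhood moments and right-hand side.
        M.zeros(); rhs.zeros();
        double swsum = 0.0, swz = 0.0;
        for (int m = 0; m < n; ++m) {
          double w = wv[m], x = ox[m], y = oy[m], t = ot[m], zz = zv[m];
          swsum += w; swz += w * zz;
          M(0, 0) += w;
          M(0, 1) += w * x; M(0, 2) += w * y;
          M(1, 1) += w * x * x; M(1, 2) += w * x * y;
          M(2, 2) += w * y * y;
          rhs(0) += w * zz; rhs(1) += w * zz * x; rhs(2) += w * zz * y;
          if (fit_t) {
            M(0, 3) += w * t; M(1, 3) += w * x * t; M(2, 3) += w * y * t;
            M(3, 3) += w * t * t;
            rhs(3) += w * zz * t;
          }
        }
        arma::mat Mp = arma::symmatu(M.submat(0, 0, p - 1, p - 1));
        arma::vec rp = rhs.subvec(0, p - 1);
        arma::vec bp;

        double a_full, bg, cg, dg;
        bool full_ok = solve_normal(Mp, rp, bp);
        if (full_ok) {
          a_full = bp(0); bg = bp(1); cg = bp(2);
          dg = fit_t ? bp(3) : 0.0;
        } else {
          // Rank-deficient clipped neighborhood: intercept-only fallback.
          a_full = swz / swsum; bg = cg = dg = 0.0;
        }

        const size_t cidx = ci + (size_t)nx * (cj + (size_t)ny * ck);

        double val; int dec;
        if (!jump || !full_ok || (bg == 0.0 && cg == 0.0 && dg == 0.0)) {
          // LLK-only mode, singular full fit, or no split direction.
          val = a_full; dec = 0;
        } else {
          // WRMS of the full fit and gradient-orthogonal split.
          // Closed half-neighborhoods: voxels exactly on the split plane
          // (side 0; always includes the center) belong to BOTH sides, so
          // each one-sided fit is anchored by the center observation and
          // the WRMS comparison cannot favor a fit extrapolating from
          // across the edge.
          double e_full = 0.0;
          int n1 = 0, n2 = 0;
          for (int m = 0; m < n; ++m) {
            double res = zv[m] - (a_full + bg * ox[m] + cg * oy[m] + dg * ot[m]);
            e_full += wv[m] * res * res;
            double s = bg * ox[m] + cg * oy[m] + dg * ot[m];
            side[m] = (s > 0.0) ? 1 : (s < 0.0 ? 2 : 0);
            if (side[m] != 2) ++n1;
            if (side[m] != 1) ++n2;
          }
          e_full /= swsum;

          bool sides_ok = (n1 >= 4 && n2 >= 4);
          if (sides_ok) {
            M1.zeros(); M2.zeros(); r1.zeros(); r2.zeros();
            for (int m = 0; m < n; ++m) {
              double w = wv[m], x = ox[m], y = oy[m], t = ot[m], zz = zv[m];
              for (int sd = 1; sd <= 2; ++sd) {
                if (side[m] != 0 && side[m] != sd) continue;
                arma::mat& Ms = (sd == 1) ? M1 : M2;
                arma::vec& rs = (sd == 1) ? r1 : r2;
                Ms(0, 0) += w;
                Ms(0, 1) += w * x; Ms(0, 2) += w * y;
                Ms(1, 1) += w * x * x; Ms(1, 2) += w * x * y;
                Ms(2, 2) += w * y * y;
                rs(0) += w * zz; rs(1) += w * zz * x; rs(2) += w * zz * y;
                if (fit_t) {
                  Ms(0, 3) += w * t; Ms(1, 3) += w * x * t; Ms(2, 3) += w * y * t;
                  Ms(3, 3) += w * t * t;
                  rs(3) += w * zz * t;
                }
              }
            }
            arma::mat M1p = arma::symmatu(M1.submat(0, 0, p - 1, p - 1));
            arma::mat M2p = arma::symmatu(M2.submat(0, 0, p - 1, p - 1));
            sides_ok = solve_normal(M1p, r1.subvec(0, p - 1), b1) &&
              solve_normal(M2p, r2.subvec(0, p - 1), b2);
          }

          if (!sides_ok) {
            val = a_full; dec = 0;
          } else {
            double e1 = 0.0, e2 = 0.0, w1 = 0.0, w2 = 0.0;
            double d1t = fit_t ? b1(3) : 0.0, d2t = fit_t ? b2(3) : 0.0;
            for (int m = 0; m < n; ++m) {
              if (side[m] != 2) {
                double res = zv[m] - (b1(0) + b1(1) * ox[m] + b1(2) * oy[m] + d1t * ot[m]);
                e1 += wv[m] * res * res; w1 += wv[m];
              }
              if (side[m] != 1) {
                double res = zv[m] - (b2(0) + b2(1) * ox[m] + b2(2) * oy[m] + d2t * ot[m]);
                e2 += wv[m] * res * res; w2 += wv[m];
              }
            }
            e1 /= w1; e2 /= w2;
            double D = std::max(e_full - e1, e_full - e2);
            if (D <= u) {
              val = a_full; dec = 0;
            } else if (e1 < e2) {
              val = b1(0); dec = 1;
            } else if (e1 > e2) {
              val = b2(0); dec = 2;
            } else {
              val = 0.5 * (b1(0) + b2(0)); dec = 3;
            }
          }
        }

        fhat[cidx] = val;
        decision[cidx] = dec;
        double diff = val - zp[cidx];
        ss += diff * diff;
        ++n_eval;
      }
    }
  }

  return List::create(_["fhat"] = fhat, _["decision"] = decision,
                      _["score"] = ss / (double)n_eval,
                      _["n_eval"] = (double)n_eval);
}
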