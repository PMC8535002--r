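#' Mean squared error between two arrays
#'
#' @param estimate,truth Numeric arrays of identical shape.
#' @return Mean of squared voxelwise differences over the full grid.
#' @export
mse <- function(estimate, truth) {
  if (!identical(dim(estimate), dim(truth)))
    stop("`estimate` and `truth` must have identical dimensions", call. = FALSE)
  mean((estimate - truth)^2)
}

#' Cumulative jump magnitude (JS) of a 3-D field
#'
#' Average over interior voxels of the Euclidean norm of the three central
#' differences: for voxel `(i, j, k)` the vector
#' `(f[i+1,j,k] - f[i-1,j,k], f[i,j+1,k] - f[i,j-1,k], f[i,j,k+1] - f[i,j,k-1])`.
#' For a field with sharp edges most of this quantity comes from the jumps,
#' so it measures the cumulative jump magnitude; an oversmoothed estimate
#' loses part of it.
#'
#' @param field 3-D numeric array with every dimension `>= 3`.
#' @return Nonnegative scalar.
#' @export
js_statistic <- function(field) {
  check_sequence(field)
  d <- dim(field)
  if (any(d < 3)) stop("`field` must be at least 3 voxels along every axis", call. = FALSE)
  nx <- d[1]; ny <- d[2]; nt <- d[3]
  ii <- 2:(nx - 1); jj <- 2:(ny - 1); kk <- 2:(nt - 1)
  gx <- field[ii + 1, jj, kk, drop = FALSE] - field[ii - 1, jj, kk, drop = FALSE]
  gy <- field[ii, jj + 1, kk, drop = FALSE] - field[ii, jj - 1, kk, drop = FALSE]
  gt <- field[ii, jj, kk + 1, drop = FALSE] - field[ii, jj, kk - 1, drop = FALSE]
  mean(sqrt(gx^2 + gy^2 + gt^2))
}

#' Edge-preservation (EP) criterion
#'
#' Relative absolute loss of cumulative jump magnitude after denoising:
#' `|JS(estimate) - JS(truth)| / JS(truth)`. Smaller is better; 0 means the
#' denoiser preserved exactly as much gradient/jump content as the truth
#' holds. Returned as a fraction (multiply by 100 for percent).
#'
#' @inheritParams mse
#' @return Nonnegative scalar (fraction).
#' @export
edge_preservation <- function(estimate, truth) {
  jt <- js_statistic(truth)
  if (jt == 0) stop("JS of `truth` is zero; EP is undefined", call. = FALSE)
  abs(js_statistic(estimate) - jt) / jt
}

#' Evaluate a denoised sequence against the truth
#'
#' @inheritParams mse
#' @return One-row tibble with `mse`, `js_estimate`, `js_truth` and `ep`.
#' @export
evaluate_estimate <- function(estimate, truth) {
  jt <- js_statistic(truth)
  je <- js_statistic(estimate)
  tibble::tibble(mse = mse(estimate, truth), js_estimate = je, js_truth = jt,
                 ep = abs(je - jt) / jt)
}
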