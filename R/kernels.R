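#' Truncated Gaussian estimation kernel
#'
#' The density kernel used by the local linear smoothing procedure:
#' proportional to \eqn{\exp(-v^2/2) - \exp(-1/2)} on \eqn{|v| \le 1} and
#' zero outside, normalized so that it integrates to 1 over \eqn{[-1, 1]}.
#' The normalizing constant is immaterial to the denoiser itself (all
#' estimator formulas use weight ratios) but makes the exported kernel a
#' proper density.
#'
#' @param v Numeric vector of evaluation points.
#' @return Nonnegative kernel weights, same length as `v`.
#' @examples
#' kernel_truncated_gaussian(c(-1, 0, 0.5, 1, 2))
#' integrate(kernel_truncated_gaussian, -1, 1)
#' @export
kernel_truncated_gaussian <- function(v) {
  ifelse(abs(v) <= 1, pmax(exp(-v^2 / 2) - exp(-0.5), 0) / .tgauss_norm, 0)
}

# integral of exp(-v^2/2) - exp(-1/2) over [-1, 1]
.tgauss_norm <- sqrt(2 * pi) * (2 * stats::pnorm(1) - 1) - 2 * exp(-0.5)

#' Epsilon-optimal bimodal kernel
#'
#' The bimodal kernel used by the modified cross-validation. It is an
#' Epanechnikov-type density with the mass near the origin redistributed
#' linearly so that \eqn{K_\epsilon(0) = 0}: the self-observation and
#' near-origin (hence strongly correlated) observations receive no weight,
#' which is what lets leave-one-out cross-validation tolerate
#' spatio-temporally correlated noise. With the prefactor
#' \eqn{4/(4 - 3\epsilon - \epsilon^3)} it integrates to 1 exactly.
#'
#' @param v Numeric vector of evaluation points.
#' @param eps Shape parameter in (0, 1); 0.1 is the standard choice.
#' @return Nonnegative kernel weights, same length as `v`.
#' @examples
#' kernel_bimodal(0)          # exactly zero
#' kernel_bimodal(c(0.05, 0.1, 0.5, 1))
#' @export
kernel_bimodal <- function(v, eps = 0.1) {
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0 || eps >= 1)
    stop("`eps` must be a single number in (0, 1)", call. = FALSE)
  a <- abs(v)
  pref <- 4 / (4 - 3 * eps - eps^3)
  out <- numeric(length(v))
  mid <- a >= eps & a <= 1
  low <- a < eps
  out[mid] <- pref * 0.75 * (1 - v[mid]^2)
  out[low] <- pref * 0.75 * (1 - eps^2) / eps * a[low]
  out
}

#' Bivariate spatial kernel
#'
#' Radial extension of a univariate kernel to the two spatial axes:
#' `kernel(sqrt(u^2 + v^2))`. Its support is the unit disk, which coincides
#' exactly with the elliptical spatial neighborhood
#' \eqn{(x'-x)^2/h_x^2 + (y'-y)^2/h_y^2 \le 1} once offsets are scaled by
#' the bandwidths.
#'
#' @param u,v Numeric vectors of bandwidth-scaled spatial offsets.
#' @param kernel Univariate kernel function (default the truncated Gaussian).
#' @return Nonnegative weights.
#' @export
kernel_spatial <- function(u, v, kernel = kernel_truncated_gaussian) {
  kernel(sqrt(u^2 + v^2))
}
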