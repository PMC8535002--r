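# Shared fixtures and independent oracles for the test suite.

# z[i,j,k] = a + b*x_i + c*y_j + d*t_k on the package's coordinate grid
planar_sequence <- function(nx, ny, nt, coef = c(1, 2, 3, -1)) {
  x <- (1:nx) / nx; y <- (1:ny) / ny; t <- (1:nt) / nt
  array(coef[1] +
          coef[2] * rep(x, times = ny * nt) +
          coef[3] * rep(rep(y, each = nx), times = nt) +
          coef[4] * rep(t, each = nx * ny),
        c(nx, ny, nt))
}

# independent weighted-least-squares oracle (QR path, unlike the normal
# equations used by the implementation)
wls_oracle <- function(nbhd, rows = seq_len(nrow(nbhd)), fit_t = TRUE) {
  nb <- nbhd[rows, ]
  X <- if (fit_t) cbind(1, nb$dx, nb$dy, nb$dt) else cbind(1, nb$dx, nb$dy)
  fit <- stats::lm.wfit(X, nb$z, nb$w)
  coef <- unname(fit$coefficients)
  if (!fit_t) coef <- c(coef, 0)
  coef
}

decision_code <- function(label) {
  c(full = 0L, side1 = 1L, side2 = 2L, tie_avg = 3L)[[label]]
}

# lag-1 sample autocorrelation along one axis of a 3-D array
axis_lag1 <- function(e, axis) {
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(e, perm)
  n <- dim(a)[1]
  stats::cor(as.vector(a[-n, , ]), as.vector(a[-1, , ]))
}
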