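#' Areal Gaussian filter (S- and L-filter kernel)
#'
#' Separable convolution with the standard areal Gaussian weighting
#' function
#' \deqn{w(x, y) = \frac{1}{\alpha^2 \lambda_c^2}
#'   \exp\left(-\pi \frac{x^2 + y^2}{(\alpha \lambda_c)^2}\right),
#'   \quad \alpha = \sqrt{\ln 2 / \pi},}
#' which transmits 50% of the amplitude at the cutoff wavelength
#' \eqn{\lambda_c}. The kernel is sampled on the grid, truncated at
#' \eqn{\pm\lambda_c} (where its value is below `1e-6` of the peak) and
#' normalized to unit sum, so a constant surface passes unchanged.
#' Borders are handled by symmetric (mirror) padding.
#'
#' @param hm A fully measured [height_map].
#' @param cutoff_um Cutoff wavelength \eqn{\lambda_c} in µm; must exceed
#'   twice the larger sample spacing.
#' @param mode `"lowpass"` returns the smoothed surface, `"highpass"`
#'   the input minus the lowpass, so the two outputs always sum to the
#'   input exactly.
#' @return A [height_map] at the same stage as the input.
#' @export
gaussian_areal_filter <- function(hm, cutoff_um,
                                  mode = c("lowpass", "highpass")) {
  stopifnot(is_height_map(hm))
  mode <- match.arg(mode)
  assert_filled(hm, "gaussian_areal_filter")
  if (cutoff_um <= 2 * max(hm$dx, hm$dy))
    stopf("cutoff %.3g um is below the resolvable limit 2*max(dx, dy) = %.3g um",
          cutoff_um, 2 * max(hm$dx, hm$dy))
  kx <- gaussian_kernel_1d(cutoff_um, hm$dx)
  ky <- gaussian_kernel_1d(cutoff_um, hm$dy)
  lo <- conv_cols(conv_rows(hm$heights, kx), ky)
  z <- if (mode == "lowpass") lo else hm$heights - lo
  height_map(z, hm$dx, hm$dy, stage = hm$stage, border_um = hm$border_um)
}

gaussian_kernel_1d <- function(cutoff_um, spacing) {
  alpha <- sqrt(log(2) / pi)
  L <- ceiling(cutoff_um / spacing)
  x <- (-L:L) * spacing
  w <- exp(-pi * x^2 / (alpha * cutoff_um)^2)
  w / sum(w)
}

## convolve every row of `mat` with kernel `w` (odd length), symmetric
## (mirror) padding; the reflection index handles kernels wider than the
## grid itself (pattern x1..xn, xn..x1 repeating)
conv_rows <- function(mat, w) {
  L <- (length(w) - 1) / 2
  nc <- ncol(mat)
  if (L == 0) return(mat * w)
  p <- (1 - L):(nc + L)
  p0 <- ((p - 1) %% (2 * nc) + 2 * nc) %% (2 * nc)
  idx <- ifelse(p0 < nc, p0 + 1, 2 * nc - p0)
  padded <- mat[, idx, drop = FALSE]
  out <- matrix(0, nrow(mat), nc)
  for (t in seq_along(w))
    out <- out + w[t] * padded[, t:(t + nc - 1), drop = FALSE]
  out
}

conv_cols <- function(mat, w) t(conv_rows(t(mat), w))

#' Remove form by polynomial least squares (F-operator)
#'
#' Fits a bivariate polynomial of total degree `degree` to the surface
#' by least squares and subtracts it, suppressing form such as the
#' overall curvature of the facet. The default degree 2 removes tilt and
#' quadratic curvature. Residuals have exactly zero mean (the fit
#' includes an intercept).
#'
#' @param hm A fully measured [height_map].
#' @param degree Total polynomial degree, `>= 0`; default 2.
#' @return A [height_map] containing the residual surface.
#' @export
remove_form <- function(hm, degree = 2) {
  stopifnot(is_height_map(hm))
  assert_filled(hm, "remove_form")
  z <- hm$heights
  nr <- nrow(z); nc <- ncol(z)
  if (degree >= 1 && (nr < 2 || nc < 2))
    stopf("degenerate grid (single row or column) with degree >= 1")
  X <- poly_basis(nr, nc, degree)
  if (nrow(X) <= ncol(X)) stopf("grid has too few points for degree %d", degree)
  fit <- stats::lm.fit(X, as.vector(z))
  height_map(matrix(fit$residuals, nr, nc), hm$dx, hm$dy,
             stage = hm$stage, border_um = hm$border_um)
}

## monomial basis x^a * y^b, a + b <= degree, on [-1, 1]-scaled coordinates
poly_basis <- function(nr, nc, degree) {
  xs <- if (nc > 1) seq(-1, 1, length.out = nc) else 0
  ys <- if (nr > 1) seq(-1, 1, length.out = nr) else 0
  xg <- rep(xs, each = nr)
  yg <- rep(ys, times = nc)
  cols <- list()
  for (d in 0:degree)
    for (a in 0:d)
      cols[[length(cols) + 1]] <- xg^a * yg^(d - a)
  do.call(cbind, cols)
}

#' The S-filter / F-operator / L-filter processing chain
#'
#' Produces the three analysis stages from a raw, fully measured height
#' map: the *primary* surface (areal Gaussian lowpass at the short
#' cutoff, removing the smallest-scale elements and measurement noise),
#' the *S-F* surface (primary after polynomial form removal) and the
#' *S-L* surface (S-F after Gaussian highpass at the long cutoff,
#' removing waviness). On the S-L surface a border band of width
#' `l_cutoff_um / 2` is flagged (via `border_um`) and excluded from
#' texture-parameter evaluation, containing the Gaussian end effects.
#'
#' The cutoffs are not dictated by the measurement protocol and are
#' deliberately configuration-exposed; defaults are `s_cutoff_um = 2.5`
#' µm (denoising; about 8 sample spacings on the default synthetic grid)
#' and `l_cutoff_um = 25` µm (a quarter of the 0.1 mm field class,
#' nesting-index style).
#'
#' @param hm_raw Raw, fully measured [height_map].
#' @param s_cutoff_um S-filter cutoff (µm).
#' @param l_cutoff_um L-filter cutoff (µm); must exceed `s_cutoff_um`.
#' @param f_degree Polynomial degree of the F-operator; default 2.
#' @return A list with components `primary`, `s_f`, `s_l`, each a
#'   [height_map] with its stage label set.
#' @export
filter_chain <- function(hm_raw, s_cutoff_um = 2.5, l_cutoff_um = 25,
                         f_degree = 2) {
  stopifnot(is_height_map(hm_raw))
  assert_filled(hm_raw, "filter_chain")
  if (s_cutoff_um >= l_cutoff_um)
    stopf("cutoff ordering violated: s_cutoff_um (%.3g) must be < l_cutoff_um (%.3g)",
          s_cutoff_um, l_cutoff_um)
  primary <- gaussian_areal_filter(hm_raw, s_cutoff_um, "lowpass")
  primary$stage <- "primary"
  s_f <- remove_form(primary, f_degree)
  s_f$stage <- "S-F"
  s_l <- gaussian_areal_filter(s_f, l_cutoff_um, "highpass")
  s_l$stage <- "S-L"
  s_l$border_um <- l_cutoff_um / 2
  list(primary = primary, s_f = s_f, s_l = s_l)
}
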