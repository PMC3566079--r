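## Height and hybrid ISO 25178-style parameter families.

## Reference a height matrix to its least-squares mean plane.
ref_mean_plane <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  X <- poly_basis(nr, nc, 1)
  matrix(stats::lm.fit(X, as.vector(z))$residuals, nr, nc)
}

#' Height (amplitude) parameters
#'
#' Computes the seven height parameters from the distribution of surface
#' heights referenced to the least-squares mean plane: `Sa` (arithmetic
#' mean height), `Sq` (RMS height), `Ssk` (skewness), `Sku` (kurtosis),
#' `Sp` (maximum peak height above the mean plane), `Sv` (maximum pit
#' depth below it) and `Sz = Sp + Sv` (maximum height). Mean-plane
#' referencing (rather than mean-value subtraction) prevents residual
#' tilt from biasing the skewness and kurtosis.
#'
#' On a perfectly constant (zero-`Sq`) surface `Ssk` and `Sku` are
#' undefined; they are returned as `NA` with a warning of class
#' `dentexture_undefined`.
#'
#' @param hm A fully measured [height_map].
#' @return Named numeric vector with elements `Sa`, `Sq`, `Ssk`, `Sku`,
#'   `Sp`, `Sv`, `Sz` (µm; `Ssk`, `Sku` unitless).
#' @export
height_params <- function(hm) {
  stopifnot(is_height_map(hm))
  assert_filled(hm, "height_params")
  z <- as.vector(ref_mean_plane(hm$heights))
  Sa <- mean(abs(z))
  Sq <- sqrt(mean(z^2))
  Sp <- max(z)
  Sv <- -min(z)
  # on an exactly planar input the residuals are pure round-off; treat
  # anything at machine level (relative to the input heights) as zero
  if (Sq <= 1e-12 * max(abs(hm$heights), 1e-12)) {
    warning(structure(class = c("dentexture_undefined", "warning", "condition"),
      list(message = "Ssk and Sku are undefined on a constant surface",
           call = sys.call(-1))))
    Ssk <- NA_real_; Sku <- NA_real_
  } else {
    Ssk <- mean(z^3) / Sq^3
    Sku <- mean(z^4) / Sq^4
  }
  c(Sa = Sa, Sq = Sq, Ssk = Ssk, Sku = Sku, Sp = Sp, Sv = Sv, Sz = Sp + Sv)
}

## central-difference gradient; one-sided at the borders
surface_gradient <- function(z, dx, dy) {
  nr <- nrow(z); nc <- ncol(z)
  zx <- matrix(0, nr, nc); zy <- matrix(0, nr, nc)
  if (nc >= 3) {
    zx[, 2:(nc - 1)] <- (z[, 3:nc] - z[, 1:(nc - 2)]) / (2 * dx)
  }
  if (nc >= 2) {
    zx[, 1] <- (z[, 2] - z[, 1]) / dx
    zx[, nc] <- (z[, nc] - z[, nc - 1]) / dx
  }
  if (nr >= 3) {
    zy[2:(nr - 1), ] <- (z[3:nr, ] - z[1:(nr - 2), ]) / (2 * dy)
  }
  if (nr >= 2) {
    zy[1, ] <- (z[2, ] - z[1, ]) / dy
    zy[nr, ] <- (z[nr, ] - z[nr - 1, ]) / dy
  }
  list(zx = zx, zy = zy)
}

#' Hybrid parameters
#'
#' `Sdq` is the root-mean-square surface gradient and `Sdr` the
#' developed interfacial area ratio, the percentage by which the true
#' (developed) surface area exceeds the projected area. Both are
#' computed from finite-difference gradients (central differences in the
#' interior, one-sided at the borders); the developed area element is
#' \eqn{\sqrt{1 + z_x^2 + z_y^2}} per point.
#'
#' @param hm A fully measured [height_map].
#' @return Named numeric vector with elements `Sdq` (unitless) and `Sdr`
#'   (%).
#' @export
hybrid_params <- function(hm) {
  stopifnot(is_height_map(hm))
  assert_filled(hm, "hybrid_params")
  g <- surface_gradient(hm$heights, hm$dx, hm$dy)
  g2 <- g$zx^2 + g$zy^2
  c(Sdq = sqrt(mean(g2)), Sdr = (mean(sqrt(1 + g2)) - 1) * 100)
}
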