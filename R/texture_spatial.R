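## Spatial parameter family: Sal, Str (autocorrelation) and Std
## (texture direction).

## Linear (zero-padded) normalized areal autocorrelation of a height
## matrix, returned with the zero lag at the centre.
areal_acf <- function(z) {
  z <- z - mean(z)
  nr <- nrow(z); nc <- ncol(z)
  P <- 2 * max(nr, nc)
  zp <- matrix(0, P, P); zp[1:nr, 1:nc] <- z
  op <- matrix(0, P, P); op[1:nr, 1:nc] <- 1
  F <- stats::fft(zp)
  C <- stats::fft(op)
  raw <- Re(stats::fft(Mod(F)^2, inverse = TRUE)) / P^2
  cnt <- Re(stats::fft(Mod(C)^2, inverse = TRUE)) / P^2
  cnt <- round(cnt)
  keep_r <- c((P - nr + 2):P, 1:nr)   # lags -(nr-1) .. (nr-1)
  keep_c <- c((P - nc + 2):P, 1:nc)
  raw <- raw[keep_r, keep_c]
  cnt <- cnt[keep_r, keep_c]
  acf <- raw / pmax(cnt, 1)
  acf / acf[nr, nc]                    # normalize to 1 at zero lag
}

## bilinear interpolation of matrix `m` (rows = y index) at fractional
## (row, col) positions
bilinear_at <- function(m, ri, ci) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- pmin(pmax(floor(ri), 1), nr - 1); c0 <- pmin(pmax(floor(ci), 1), nc - 1)
  fr <- ri - r0; fc <- ci - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Spatial parameters: autocorrelation length, texture aspect ratio and
#' texture direction
#'
#' From the normalized areal autocorrelation function (ACF), the decay
#' distance to a threshold `s` (default 0.2) is measured along rays in
#' 1° steps. `Sal` is the shortest such distance, `Str` the ratio of the
#' shortest to the longest. Directions whose ACF never falls below `s`
#' inside the searchable field (strongly anisotropic surfaces) are
#' capped at the field limit and flagged via the `"capped"` attribute;
#' if *no* direction decays below `s` the surface is out of range and an
#' error is raised.
#'
#' `Std`, the texture direction, is the direction of the dominant lay in
#' `[0°, 180°)` measured from the x axis: the angular power spectrum of
#' the (Hann-windowed, plane-detrended) surface is accumulated in 1°
#' bins, the peak bin is refined by parabolic interpolation, and 90° is
#' added because the spectral energy of a lay lies perpendicular to it.
#' Ties are broken toward the smaller angle.
#'
#' @param hm A fully measured [height_map].
#' @param s ACF decay threshold in `(0, 1)`; default 0.2.
#' @return Named numeric vector with `Sal` (µm), `Str` (unitless, in
#'   `(0, 1]`) and `Std` (degrees), with attribute `capped` (logical).
#' @export
spatial_params <- function(hm, s = 0.2) {
  stopifnot(is_height_map(hm))
  assert_filled(hm, "spatial_params")
  if (s <= 0 || s >= 1) stopf("s must lie in (0, 1)")
  z <- ref_mean_plane(hm$heights)
  nr <- nrow(z); nc <- ncol(z)
  acf <- areal_acf(z)
  ctr_r <- nr; ctr_c <- nc                      # zero-lag position
  rmax <- min((nr - 1) / 2 * hm$dy, (nc - 1) / 2 * hm$dx)
  step <- min(hm$dx, hm$dy) / 2
  radii <- seq(0, rmax, by = step)
  angs <- seq(0, 179, by = 1) * pi / 180
  decay <- rep(NA_real_, length(angs))
  for (k in seq_along(angs)) {
    ux <- cos(angs[k]); uy <- sin(angs[k])
    ri <- ctr_r + radii * uy / hm$dy
    ci <- ctr_c + radii * ux / hm$dx
    v <- bilinear_at(acf, ri, ci)
    idx <- which(v <= s)[1]
    if (!is.na(idx) && idx > 1) {
      # linear interpolation between the bracketing radii
      r1 <- radii[idx - 1]; r2 <- radii[idx]
      v1 <- v[idx - 1]; v2 <- v[idx]
      decay[k] <- r1 + (s - v1) / (v2 - v1) * (r2 - r1)
    } else if (!is.na(idx)) decay[k] <- radii[idx]
  }
  if (all(is.na(decay)))
    stopf("autocorrelation never decays below s = %.3g within the field", s)
  capped <- any(is.na(decay))
  decay[is.na(decay)] <- rmax
  Sal <- min(decay)
  Str <- Sal / max(decay)
  out <- c(Sal = Sal, Str = Str, Std = texture_direction(z, hm$dx, hm$dy))
  attr(out, "capped") <- capped
  out
}

## dominant texture direction from the angular power spectrum
texture_direction <- function(z, dx, dy) {
  nr <- nrow(z); nc <- ncol(z)
  wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
  zw <- z * outer(wr, wc)
  P <- Mod(stats::fft(zw))^2
  fx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / (nc * dx)
  fy <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / (nr * dy)
  FX <- matrix(fx, nr, nc, byrow = TRUE)
  FY <- matrix(fy, nr, nc)
  fr2 <- FX^2 + FY^2
  sel <- fr2 > 0
  ang <- (atan2(FY[sel], FX[sel]) * 180 / pi) %% 180
  pow <- P[sel]
  bins <- floor(ang) %% 180
  spec <- vapply(0:179, function(b) sum(pow[bins == b]), numeric(1))
  pk <- which.max(spec)                 # which.max takes the first (smaller) angle on ties
  lo <- spec[(pk - 2) %% 180 + 1]; hi <- spec[pk %% 180 + 1]; ce <- spec[pk]
  denom <- lo - 2 * ce + hi
  frac <- if (denom != 0) 0.5 * (lo - hi) / denom else 0
  (pk - 1 + frac + 90) %% 180  # lay direction is perpendicular to the lobe
}
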