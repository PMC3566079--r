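#' Gridded occlusal height map
#'
#' The central container of the package: surface heights on a regular
#' rectangular grid, in micrometres, together with a measured-point mask
#' and a processing-stage label. Row `i` of `heights` is the scan line at
#' `y = (i - 1) * dy`, column `j` the position `x = (j - 1) * dx`; the
#' origin is the lower-left corner of the field and heights are positive
#' upward.
#'
#' @param heights Numeric matrix of surface heights (µm). Non-measured
#'   points may be encoded as `NA`/`NaN` when `mask` is omitted.
#' @param dx,dy Lateral sample spacing (µm), both `> 0`.
#' @param mask Logical matrix, `TRUE` at measured points. Defaults to
#'   `is.finite(heights)`.
#' @param stage Processing stage, one of `"raw"`, `"primary"`, `"S-F"`,
#'   `"S-L"`.
#' @param border_um Width (µm) of a border band flagged for exclusion
#'   from texture-parameter evaluation (set by the L-filter stage).
#' @return An object of class `height_map` with fields `heights`, `dx`,
#'   `dy`, `mask`, `stage`, `extent_x`, `extent_y`, `border_um`.
#' @examples
#' hm <- height_map(matrix(0, 4, 4), dx = 1, dy = 1)
#' hm$extent_x # 3 um
#' @export
height_map <- function(heights, dx, dy, mask = NULL, stage = "raw",
                       border_um = 0) {
  if (!is.matrix(heights) || !is.numeric(heights))
    stopf("heights must be a numeric matrix")
  if (!is.numeric(dx) || !is.numeric(dy) || dx <= 0 || dy <= 0)
    stopf("dx and dy must be positive")
  if (is.null(mask)) mask <- is.finite(heights)
  if (!is.logical(mask) || !identical(dim(mask), dim(heights)))
    stopf("mask must be a logical matrix with the dimensions of heights")
  stage <- match.arg(stage, c("raw", "primary", "S-F", "S-L"))
  if (any(!is.finite(heights[mask])))
    stopf("heights must be finite at every measured point")
  hm <- structure(list(
    heights = heights, dx = as.numeric(dx), dy = as.numeric(dy),
    mask = mask, stage = stage,
    extent_x = (ncol(heights) - 1) * dx,
    extent_y = (nrow(heights) - 1) * dy,
    border_um = as.numeric(border_um)
  ), class = "height_map")
  hm
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf(
    "<height_map> %d x %d points, %.4g x %.4g um (dx = %.4g, dy = %.4g), stage = %s\n",
    nrow(x$heights), ncol(x$heights), x$extent_y, x$extent_x, x$dx, x$dy,
    x$stage))
  frac <- mean(x$mask)
  cat(sprintf("  measured fraction: %.3f", frac))
  if (x$border_um > 0)
    cat(sprintf("; flagged border band: %.3g um", x$border_um))
  cat("\n")
  invisible(x)
}

is_height_map <- function(x) inherits(x, "height_map")

assert_filled <- function(hm, what = "this operation") {
  if (!all(hm$mask))
    stopf("%s requires a fully measured surface; call fill_nonmeasured() first",
          what)
  invisible(hm)
}

## x / y coordinate vectors of the grid, in um
hm_x <- function(hm) (seq_len(ncol(hm$heights)) - 1) * hm$dx
hm_y <- function(hm) (seq_len(nrow(hm$heights)) - 1) * hm$dy

#' Check a height map against the measured-point acceptance threshold
#'
#' Surfaces from confocal scanning contain non-measured points; a field
#' is only analysed when at least a threshold fraction of its points was
#' recorded (default 80%).
#'
#' @param hm A [height_map].
#' @param threshold Acceptance threshold in `(0, 1]`; default `0.80`.
#' @return A list with `status` (`"accept"` or `"reject"`) and
#'   `fraction`, the measured-point fraction. Acceptance uses `>=`.
#' @export
validate_measured_fraction <- function(hm, threshold = 0.80) {
  stopifnot(is_height_map(hm))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stopf("threshold must lie in (0, 1]")
  if (length(hm$mask) == 0) stopf("empty grid")
  fraction <- mean(hm$mask)
  list(status = if (fraction >= threshold) "accept" else "reject",
       fraction = fraction)
}

#' Fill non-measured points of a height map
#'
#' Replaces masked (non-measured) points by a deterministic interpolation
#' so that filtering and parameter computation can operate on a complete
#' grid. Each masked point receives the average of a linear interpolation
#' along its row and along its column between the nearest measured
#' neighbours (bilinear in effect); at borders, where only one side is
#' measured, the nearest measured value along that line is used. Points
#' whose entire row and column are unmeasured fall back to the nearest
#' measured point in the grid. Measured points are never altered and the
#' operation is idempotent.
#'
#' @param hm A [height_map] accepted by [validate_measured_fraction()]
#'   at the 80% threshold.
#' @return A fully measured [height_map].
#' @export
fill_nonmeasured <- function(hm) {
  stopifnot(is_height_map(hm))
  v <- validate_measured_fraction(hm, 0.80)
  if (v$status == "reject")
    stopf("surface rejected: only %.1f%% of points measured (threshold 80%%)",
          100 * v$fraction)
  if (all(hm$mask)) return(hm)
  z <- hm$heights
  mk <- hm$mask
  nr <- nrow(z); nc <- ncol(z)
  fill_row <- matrix(NA_real_, nr, nc)
  fill_col <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    mi <- which(mk[i, ])
    bad <- which(!mk[i, ])
    if (length(bad) == 0 || length(mi) == 0) next
    if (length(mi) == 1) {
      fill_row[i, bad] <- z[i, mi]
    } else {
      fill_row[i, bad] <- stats::approx(mi, z[i, mi], xout = bad,
                                        rule = 2)$y
    }
  }
  for (j in seq_len(nc)) {
    mj <- which(mk[, j])
    bad <- which(!mk[, j])
    if (length(bad) == 0 || length(mj) == 0) next
    if (length(mj) == 1) {
      fill_col[bad, j] <- z[mj, j]
    } else {
      fill_col[bad, j] <- stats::approx(mj, z[mj, j], xout = bad,
                                        rule = 2)$y
    }
  }
  bad <- which(!mk)
  est <- rowMeans(cbind(fill_row[bad], fill_col[bad]), na.rm = TRUE)
  if (any(!is.finite(est))) {
    # isolated points with fully unmeasured row and column: nearest measured
    meas <- which(mk, arr.ind = TRUE)
    for (k in which(!is.finite(est))) {
      idx <- arrayInd(bad[k], dim(z))
      d2 <- (meas[, 1] - idx[1])^2 * hm$dy^2 + (meas[, 2] - idx[2])^2 * hm$dx^2
      est[k] <- z[meas[which.min(d2), , drop = FALSE]]
    }
  }
  z[bad] <- est
  height_map(z, hm$dx, hm$dy, mask = matrix(TRUE, nr, nc),
             stage = hm$stage, border_um = hm$border_um)
}
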