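## Watershed motif segmentation (closed dales / hills) and the feature
## parameter family built on it.

#' Segment a surface into closed dales and hills
#'
#' Watershed segmentation of the (mean-plane referenced) surface: dales
#' grow from local minima of the surface, hills from local minima of the
#' inverted surface. Shallow motifs are merged into their neighbours by
#' Wolf pruning: a motif survives only if its local relief (extreme to
#' bounding saddle) is at least `pruning_fraction * Sz` (default 5%, the
#' usual nesting choice; exposed because the measurement protocol does
#' not pin it). The watershed itself is delegated to
#' [EBImage::watershed()], whose `tolerance` implements exactly this
#' relief-based merging.
#'
#' For every motif the report contains its area (µm²), its enclosed
#' volume relative to its bounding saddle (µm³; for a dale the volume
#' below the lowest point of its rim, for a hill the volume above the
#' highest rim point) and its extreme height (peak height or pit depth,
#' µm, relative to the mean plane).
#'
#' @param hm A fully measured, non-constant [height_map].
#' @param pruning_fraction Wolf-pruning threshold as a fraction of `Sz`;
#'   default 0.05.
#' @return An object of class `segmentation_motifs`: a list with
#'   data frames `dales` and `hills` (columns `area_um2`, `volume_um3`,
#'   `extreme_um`, `peak_row`, `peak_col`), `pruning_height_um` and
#'   `eval_area_um2`.
#' @export
segment_motifs <- function(hm, pruning_fraction = 0.05) {
  stopifnot(is_height_map(hm))
  assert_filled(hm, "segment_motifs")
  z <- ref_mean_plane(hm$heights)
  rng <- max(z) - min(z)
  if (rng == 0) stopf("constant surface has no motifs")
  prune_h <- pruning_fraction * rng
  hills <- motif_table(z, hm$dx, hm$dy, prune_h, invert = FALSE)
  dales <- motif_table(z, hm$dx, hm$dy, prune_h, invert = TRUE)
  structure(list(
    dales = dales, hills = hills,
    pruning_height_um = prune_h,
    eval_area_um2 = (nrow(z) - 1) * hm$dy * (ncol(z) - 1) * hm$dx
  ), class = "segmentation_motifs")
}

#' @export
print.segmentation_motifs <- function(x, ...) {
  cat(sprintf("<segmentation_motifs> %d dales, %d hills (pruning height %.4g um)\n",
              nrow(x$dales), nrow(x$hills), x$pruning_height_um))
  invisible(x)
}

## label image -> per-motif area / saddle-referenced volume / extreme.
## invert = TRUE segments dales (basins of the surface itself).
motif_table <- function(z, dx, dy, prune_h, invert) {
  relief <- if (invert) max(z) - z else z - min(z)
  lab <- EBImage::watershed(relief + 1e-9, tolerance = prune_h, ext = 1)
  lab <- as.matrix(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # rim = pixels adjacent (4-neighbourhood) to a different label or the border
  rim <- matrix(FALSE, nr, nc)
  rim[1, ] <- rim[nr, ] <- TRUE
  rim[, 1] <- rim[, nc] <- TRUE
  rim[-1, ] <- rim[-1, ] | (lab[-1, ] != lab[-nr, ])
  rim[-nr, ] <- rim[-nr, ] | (lab[-nr, ] != lab[-1, ])
  rim[, -1] <- rim[, -1] | (lab[, -1] != lab[, -nc])
  rim[, -nc] <- rim[, -nc] | (lab[, -nc] != lab[, -1])
  ids <- sort(unique(as.vector(lab)))
  ids <- ids[ids > 0]
  cell <- dx * dy
  out <- data.frame(area_um2 = numeric(0), volume_um3 = numeric(0),
                    extreme_um = numeric(0), peak_row = integer(0),
                    peak_col = integer(0))
  if (length(ids) == 0) return(out)
  labv <- as.vector(lab)
  idx_by <- split(seq_along(labv), labv)
  idx_by <- idx_by[names(idx_by) != "0"]
  zz <- as.vector(z)
  rimv <- as.vector(rim)
  res <- lapply(idx_by, function(ii) {
    zi <- zz[ii]
    ri <- ii[rimv[ii]]
    if (invert) {
      pour <- if (length(ri)) min(zz[ri]) else max(zi)
      vol <- sum(pmax(pour - zi, 0)) * cell
      ext_i <- ii[which.min(zi)]
      extreme <- -min(zi)               # pit depth, positive
    } else {
      pour <- if (length(ri)) max(zz[ri]) else min(zi)
      vol <- sum(pmax(zi - pour, 0)) * cell
      ext_i <- ii[which.max(zi)]
      extreme <- max(zi)                # peak height
    }
    pos <- arrayInd(ext_i, dim(z))
    c(length(ii) * cell, vol, extreme, pos[1], pos[2])
  })
  m <- do.call(rbind, res)
  data.frame(area_um2 = m[, 1], volume_um3 = m[, 2], extreme_um = m[, 3],
             peak_row = as.integer(m[, 4]), peak_col = as.integer(m[, 5]))
}

## mean curvature at a peak from a local quadric fit over a (2w+1)^2
## window; finite-difference curvature alone is too noise-fragile.
quadric_mean_curvature <- function(z, row, col, dx, dy, w = 2) {
  nr <- nrow(z); nc <- ncol(z)
  r0 <- max(1, row - w); r1 <- min(nr, row + w)
  c0 <- max(1, col - w); c1 <- min(nc, col + w)
  rs <- r0:r1; cs <- c0:c1
  if (length(rs) < 3 || length(cs) < 3) return(NA_real_)
  u <- rep((cs - col) * dx, each = length(rs))
  v <- rep((rs - row) * dy, times = length(cs))
  X <- cbind(1, u, v, u^2, u * v, v^2)
  b <- stats::lm.fit(X, as.vector(z[rs, cs]))$coefficients
  -(b[4] + b[6])                        # -(z_uu + z_vv)/2 * 2 = 1/R for a cap
}

#' Feature parameters from motif segmentation
#'
#' Computes the segmentation-derived parameter family: `Spd` (density of
#' peaks, hills per unit area), `Spc` (arithmetic mean peak curvature
#' from local quadric fits at each hill peak), `S5p`/`S5v` (mean of the
#' five highest peak heights / five deepest pit depths; when fewer
#' motifs exist, all are used and the result is flagged),
#' `S10z = S5p + S5v`, and the arithmetic means over closed motifs
#' `Sda`, `Sha` (dale/hill area) and `Sdv`, `Shv` (dale/hill volume).
#'
#' @param motifs A [segment_motifs()] result computed on `hm`.
#' @param hm The same fully measured [height_map].
#' @return Named numeric vector with `Spd`, `Spc`, `S10z`, `S5p`, `S5v`,
#'   `Sda`, `Sha`, `Sdv`, `Shv`; attribute `few_motifs` is `TRUE` when
#'   fewer than five hills or dales were available.
#' @export
feature_params <- function(motifs, hm) {
  stopifnot(inherits(motifs, "segmentation_motifs"), is_height_map(hm))
  if (nrow(motifs$hills) == 0 || nrow(motifs$dales) == 0)
    stopf("empty motif set")
  z <- ref_mean_plane(hm$heights)
  hl <- motifs$hills; dl <- motifs$dales
  top5 <- function(x) mean(sort(x, decreasing = TRUE)[seq_len(min(5, length(x)))])
  S5p <- top5(hl$extreme_um)
  S5v <- top5(dl$extreme_um)
  curv <- vapply(seq_len(nrow(hl)), function(i)
    quadric_mean_curvature(z, hl$peak_row[i], hl$peak_col[i], hm$dx, hm$dy),
    numeric(1))
  out <- c(Spd = nrow(hl) / motifs$eval_area_um2,
           Spc = mean(curv, na.rm = TRUE),
           S10z = S5p + S5v, S5p = S5p, S5v = S5v,
           Sda = mean(dl$area_um2), Sha = mean(hl$area_um2),
           Sdv = mean(dl$volume_um3), Shv = mean(hl$volume_um3))
  attr(out, "few_motifs") <- nrow(hl) < 5 || nrow(dl) < 5
  out
}
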