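## Aggregation of all parameter families into one TextureParameterSet.

texture_param_names <- c(
  "Sa", "Sq", "Ssk", "Sku", "Sp", "Sv", "Sz",
  "Smr", "Smc", "Sxp",
  "Sal", "Str", "Std",
  "Sdq", "Sdr",
  "Vm", "Vv", "Vmp", "Vmc", "Vvc", "Vvv",
  "Spd", "Spc", "S10z", "S5p", "S5v", "Sda", "Sha", "Sdv", "Shv")

texture_param_units <- c(
  Sa = "um", Sq = "um", Ssk = "-", Sku = "-", Sp = "um", Sv = "um", Sz = "um",
  Smr = "%", Smc = "um", Sxp = "um",
  Sal = "um", Str = "-", Std = "deg",
  Sdq = "-", Sdr = "%",
  Vm = "um3/um2", Vv = "um3/um2", Vmp = "um3/um2", Vmc = "um3/um2",
  Vvc = "um3/um2", Vvv = "um3/um2",
  Spd = "1/um2", Spc = "1/um", S10z = "um", S5p = "um", S5v = "um",
  Sda = "um2", Sha = "um2", Sdv = "um3", Shv = "um3")

#' Compute the full areal surface-texture parameter set
#'
#' Evaluates every parameter of the height, spatial, hybrid, functional
#' and segmentation families on one surface stage. If the stage carries
#' a flagged border band (`border_um > 0`, set by the L-filter), that
#' band is cropped before evaluation. The cropped surface is referenced
#' to its least-squares mean plane once, and all families are computed
#' on the referenced heights, so the parameter set is self-consistent.
#'
#' Undefined values (e.g. `Ssk`/`Sku` on a constant surface, or spatial
#' parameters when the autocorrelation never decays) are reported as
#' `NA` with the reason recorded in `$flags`.
#'
#' @param hm A fully measured [height_map] at a defined stage.
#' @param conditions Condition constants ([default_conditions()]).
#' @param pruning_fraction Wolf-pruning threshold for the segmentation
#'   family; default 0.05.
#' @param families Character vector of families to evaluate (defaults to
#'   all of `"height"`, `"spatial"`, `"hybrid"`, `"functional"`,
#'   `"segmentation"`); parameters of skipped families are `NA`.
#' @return An object of class `texture_params`: a list with `stage`,
#'   `values` (named numeric over all 30 parameters), `units`,
#'   `conditions` and `flags`.
#' @export
compute_all <- function(hm, conditions = default_conditions(),
                        pruning_fraction = 0.05,
                        families = c("height", "spatial", "hybrid",
                                     "functional", "segmentation")) {
  stopifnot(is_height_map(hm))
  assert_filled(hm, "compute_all")
  families <- match.arg(families, several.ok = TRUE)
  hm <- crop_border(hm)
  hm$heights <- ref_mean_plane(hm$heights)
  values <- stats::setNames(rep(NA_real_, length(texture_param_names)),
                            texture_param_names)
  flags <- list()
  if ("height" %in% families) {
    hp <- withCallingHandlers(
      height_params(hm),
      dentexture_undefined = function(w) {
        flags$ssk_sku_undefined <<- TRUE
        invokeRestart("muffleWarning")
      })
    values[names(hp)] <- hp
  }
  if ("hybrid" %in% families) {
    yp <- hybrid_params(hm)
    values[names(yp)] <- yp
  }
  if ("functional" %in% families) {
    fp <- functional_params(hm, conditions)
    values[names(fp)] <- fp
  }
  if ("spatial" %in% families) {
    sp <- tryCatch(spatial_params(hm, s = conditions$s),
                   error = function(e) {
                     flags$spatial_out_of_range <<- TRUE
                     NULL
                   })
    if (!is.null(sp)) {
      values[names(sp)] <- sp
      if (isTRUE(attr(sp, "capped"))) flags$str_capped <- TRUE
    }
  }
  if ("segmentation" %in% families) {
    seg <- tryCatch(segment_motifs(hm, pruning_fraction),
                    error = function(e) {
                      flags$no_motifs <<- TRUE
                      NULL
                    })
    if (!is.null(seg) && nrow(seg$hills) > 0 && nrow(seg$dales) > 0) {
      mp <- feature_params(seg, hm)
      values[names(mp)] <- mp
      if (isTRUE(attr(mp, "few_motifs"))) flags$few_motifs <- TRUE
    } else if (is.null(flags$no_motifs)) flags$no_motifs <- TRUE
  }
  structure(list(stage = hm$stage, values = values,
                 units = texture_param_units,
                 conditions = conditions, flags = flags),
            class = "texture_params")
}

crop_border <- function(hm) {
  if (hm$border_um <= 0) return(hm)
  bi <- ceiling(hm$border_um / hm$dy)
  bj <- ceiling(hm$border_um / hm$dx)
  nr <- nrow(hm$heights); nc <- ncol(hm$heights)
  if (2 * bi >= nr - 2 || 2 * bj >= nc - 2)
    stopf("border band of %.3g um leaves no evaluable area", hm$border_um)
  rows <- (bi + 1):(nr - bi); cols <- (bj + 1):(nc - bj)
  height_map(hm$heights[rows, cols], hm$dx, hm$dy,
             mask = hm$mask[rows, cols], stage = hm$stage, border_um = 0)
}

#' @export
print.texture_params <- function(x, ...) {
  cat(sprintf("<texture_params> stage = %s\n", x$stage))
  df <- data.frame(parameter = names(x$values),
                   value = signif(unname(x$values), 5),
                   unit = unname(x$units[names(x$values)]))
  print(df, row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(names(x$flags), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy one or more texture parameter sets
#'
#' @param x A `texture_params` object or list of them.
#' @param animal_id,group Optional identifiers recycled into the output.
#' @return A data frame with columns `animal_id`, `group`, `stage`,
#'   `parameter`, `value`, `unit`.
#' @export
tidy_texture_params <- function(x, animal_id = NA, group = NA) {
  if (inherits(x, "texture_params")) x <- list(x)
  do.call(rbind, lapply(x, function(tp) {
    data.frame(animal_id = animal_id, group = group, stage = tp$stage,
               parameter = names(tp$values), value = unname(tp$values),
               unit = unname(tp$units[names(tp$values)]))
  }))
}
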