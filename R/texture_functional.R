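## Functional (material-ratio / Abbott-Firestone curve) parameter family.

#' Default condition constants for the functional parameters
#'
#' The fixed conditions under which the functional parameters are
#' evaluated: `Smr` at a section 1 µm under the highest peak, `Smc`,
#' `Vm`, `Vv`, `Vmp` at material ratio p = 10%, the core volumes between
#' p = 10% and q = 80%, `Vvv` at p = 80%, and `Sxp` between p = 50% and
#' q = 97.5%. The autocorrelation threshold s = 0.2 used by the spatial
#' family is included for completeness.
#'
#' @return A named list of condition constants.
#' @export
default_conditions <- function() {
  list(smr_c_um = 1, p_pct = 10, q_pct = 80,
       sxp_p_pct = 50, sxp_q_pct = 97.5, s = 0.2)
}

## height at a given material ratio p (%): the areal material ratio
## curve is the fraction of points at or above a section height, so its
## inverse is the (1 - p/100) quantile of the height distribution
## (type-7 linear interpolation between order statistics).
height_at_ratio <- function(z, p_pct) {
  stats::quantile(z, 1 - p_pct / 100, names = FALSE, type = 7)
}

#' Functional parameters from the areal material ratio curve
#'
#' All nine functional parameters derive from the areal material ratio
#' (Abbott-Firestone) curve, the monotone non-increasing mapping from
#' section height to the percentage of material intersected:
#' * `Smr` — material ratio (%) at a section `c` µm under the highest
#'   peak (default c = 1 µm);
#' * `Smc` — inverse material ratio: the height (µm) at material ratio
#'   p (default 10%);
#' * `Sxp` — peak extreme height: height difference between material
#'   ratios p = 50% and q = 97.5%;
#' * `Vm(p)`, `Vv(p)` — material volume above and void volume below the
#'   section at ratio p, per projected area (µm³/µm²), with
#'   `Vmp = Vm(10%)`, `Vmc = Vm(80%) - Vm(10%)`,
#'   `Vvc = Vv(10%) - Vv(80%)` and `Vvv = Vv(80%)`.
#'
#' @param hm A fully measured [height_map].
#' @param conditions Condition constants, see [default_conditions()].
#' @return Named numeric vector with elements `Smr`, `Smc`, `Sxp`, `Vm`,
#'   `Vv`, `Vmp`, `Vmc`, `Vvc`, `Vvv`.
#' @export
functional_params <- function(hm, conditions = default_conditions()) {
  stopifnot(is_height_map(hm))
  assert_filled(hm, "functional_params")
  z <- as.vector(hm$heights)
  p <- conditions$p_pct; q <- conditions$q_pct
  Vm <- function(pp) mean(pmax(z - height_at_ratio(z, pp), 0))
  Vv <- function(pp) mean(pmax(height_at_ratio(z, pp) - z, 0))
  c(Smr = 100 * mean(z >= max(z) - conditions$smr_c_um),
    Smc = height_at_ratio(z, p),
    Sxp = height_at_ratio(z, conditions$sxp_p_pct) -
          height_at_ratio(z, conditions$sxp_q_pct),
    Vm = Vm(p), Vv = Vv(p),
    Vmp = Vm(p),
    Vmc = Vm(q) - Vm(p),
    Vvc = Vv(p) - Vv(q),
    Vvv = Vv(q))
}
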