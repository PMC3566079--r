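#' @keywords internal
"_PACKAGE"

## Run code under a fixed RNG seed and restore the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible per-unit seed from a master seed
#'
#' Deterministic polynomial hash of `(master_seed, label, index)` onto
#' `[1, 2^31 - 2]`, so every animal in an experiment gets an independent,
#' reproducible RNG stream.
#'
#' @param master_seed Integer master seed for the whole experiment.
#' @param label Character scalar (e.g. a diet-group label).
#' @param index Integer scalar (e.g. the animal index within the group).
#' @return A positive integer seed.
#' @export
derive_seed <- function(master_seed, label, index) {
  m <- 2147483629 # large prime < 2^31
  h <- (as.numeric(master_seed) %% m + m) %% m
  for (c in utf8ToInt(as.character(label))) h <- (h * 131 + c) %% m
  h <- (h * 131 + as.numeric(index) + 7) %% m
  as.integer(h + 1)
}

## FNV-1a hash of a character representation; used to stamp output files
## so a report can be traced to its exact configuration.
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## linear map anchored at two points; used for the silica -> rate coupling
affine_through <- function(x, x1, y1, x2, y2) {
  y1 + (x - x1) * (y2 - y1) / (x2 - x1)
}
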