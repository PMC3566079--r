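## Synthetic occlusal-surface and wear-feature generator.
##
## The generator emulates the four-diet rabbit feeding experiment:
## groups G (grass), GO (grass + oats), LO (lucerne + oats) and L
## (lucerne), n = 7, 6, 7, 6 animals, with dietary silica concentration
## (11.96 mg/g dry matter for grass down to 0.10 mg/g for lucerne) as
## the driving covariate. Wear-feature rates, scratch-direction
## concentration and between-animal variability are coupled to
## log(silica): more silica means more and more aligned scratches and a
## *less* variable signal; less silica means a pit-dominated, more
## variable signal.

#' Default diet-group configurations
#'
#' Builds the four group configurations. Pit rate and mean scratch
#' length are anchored at the published group means of the grass and
#' lucerne endpoints (Np 21.7 and 45.9 per counting square; Ls 59.1 and
#' 38.9 µm) and interpolated affinely in log(silica) for the
#' intermediate oat groups. Scratch rate, orientation concentration
#' (von Mises kappa) and between-animal coefficient of variation are
#' likewise log-silica-affine, with endpoint values chosen as realistic
#' for heavily vs lightly abraded enamel (see the methods vignette).
#'
#' @param silica_GO,silica_LO Silica concentration (mg/g dry matter) of
#'   the intermediate oat-containing diets; the endpoint values 11.96
#'   (G) and 0.10 (L) are fixed by the experiment.
#' @return A named list of `diet_group_config` objects (labels G, GO,
#'   LO, L).
#' @export
default_diet_configs <- function(silica_GO = 3.2, silica_LO = 3.0) {
  sil <- c(G = 11.96, GO = silica_GO, LO = silica_LO, L = 0.10)
  nn <- c(G = 7L, GO = 6L, LO = 7L, L = 6L)
  ls <- log(sil)
  lG <- log(11.96); lL <- log(0.10)
  cfgs <- lapply(names(sil), function(lab) {
    x <- ls[[lab]]
    diet_group_config(
      label = lab,
      n_animals = nn[[lab]],
      silica_mg_g = sil[[lab]],
      pit_rate = affine_through(x, lG, 21.7, lL, 45.9),
      scratch_rate = affine_through(x, lG, 36, lL, 18),
      orientation_kappa = exp(affine_through(x, lG, log(8), lL, log(1.2))),
      depth_scale_um = 1.5,
      between_animal_cv = affine_through(x, lG, 0.12, lL, 0.45),
      target_Np = affine_through(x, lG, 21.7, lL, 45.9),
      target_Ls_um = affine_through(x, lG, 59.1, lL, 38.9),
      micropit_rate = affine_through(x, lG, 10, lL, 80),
      roughness_um = affine_through(x, lG, 0.04, lL, 0.36))
  })
  stats::setNames(cfgs, names(sil))
}

#' Construct a diet-group configuration
#'
#' @param label Group label (e.g. `"G"`).
#' @param n_animals Number of animals in the group.
#' @param silica_mg_g Dietary silica concentration, mg/g dry matter.
#' @param scratch_rate,pit_rate Expected scratches / pits per 300x300 µm
#'   counting square.
#' @param orientation_kappa von Mises concentration of scratch
#'   directions (0 = isotropic).
#' @param depth_scale_um Characteristic feature depth, µm.
#' @param between_animal_cv Coefficient of variation of the per-animal
#'   rate multiplier.
#' @param target_Np,target_Ls_um Calibration targets: expected mean pit
#'   count and mean scratch length.
#' @param micropit_rate Expected fine micro-pits (sub-resolution for the
#'   2D protocol) per 300x300 µm on the 3D surface; models the fine
#'   pitting that accumulates on low-abrasion enamel.
#' @param roughness_um Residual instrument/surface roughness standard
#'   deviation (µm); higher on low-abrasion surfaces, whose relief is
#'   overwritten more slowly and less uniformly.
#' @return An object of class `diet_group_config`.
#' @export
diet_group_config <- function(label, n_animals, silica_mg_g, scratch_rate,
                              pit_rate, orientation_kappa, depth_scale_um,
                              between_animal_cv,
                              target_Np = pit_rate,
                              target_Ls_um = 50,
                              micropit_rate = 0,
                              roughness_um = 0.05) {
  if (silica_mg_g < 0 || scratch_rate < 0 || pit_rate < 0 ||
      orientation_kappa < 0 || between_animal_cv < 0 || depth_scale_um <= 0 ||
      micropit_rate < 0 || roughness_um < 0)
    stopf("rates, silica, kappa and cv must be non-negative; depth positive")
  structure(list(label = label, n_animals = as.integer(n_animals),
                 silica_mg_g = silica_mg_g, scratch_rate = scratch_rate,
                 pit_rate = pit_rate, orientation_kappa = orientation_kappa,
                 depth_scale_um = depth_scale_um,
                 between_animal_cv = between_animal_cv,
                 target_Np = target_Np, target_Ls_um = target_Ls_um,
                 micropit_rate = micropit_rate,
                 roughness_um = roughness_um),
            class = "diet_group_config")
}

## von Mises sampler (Best & Fisher 1979); kappa = 0 falls back to uniform
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    zz <- cos(pi * u[1])
    f <- (1 + r * zz) / (r + zz)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  out
}

## lognormal multiplier with mean 1 and coefficient of variation cv
rate_jitter <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

## Draw wear features over a rectangular field. Rates are per 300x300 um
## counting square; the expected count scales with the field area.
## Pit diameters are log-normal around 8 um so the >5 um and >10 um size
## classes are both populated; pit aspect ratios stay below the
## pit/scratch threshold of 4, scratch aspects above it.
sample_features <- function(config, rate_multiplier, depth_multiplier,
                            field_um, preferred_deg = 80,
                            include_micropits = FALSE) {
  area_scale <- field_um^2 / 300^2
  n_pit <- stats::rpois(1, config$pit_rate * rate_multiplier * area_scale)
  n_scr <- stats::rpois(1, config$scratch_rate * rate_multiplier * area_scale)
  n_mp <- if (include_micropits)
    stats::rpois(1, config$micropit_rate * rate_multiplier * area_scale) else 0L
  feats <- list()
  if (n_mp > 0) {
    len <- stats::rlnorm(n_mp, log(3), 0.3)
    aspect <- stats::runif(n_mp, 1, 2)
    feats$micropit <- data.frame(
      kind = "pit",
      center_x = stats::runif(n_mp, 0, field_um),
      center_y = stats::runif(n_mp, 0, field_um),
      length_um = len, width_um = len / aspect,
      depth_um = 0.3 * config$depth_scale_um * depth_multiplier *
        stats::rlnorm(n_mp, -0.05, 0.3),
      orientation_deg = stats::runif(n_mp, 0, 180))
  }
  if (n_pit > 0) {
    len <- stats::rlnorm(n_pit, log(8), 0.45)
    aspect <- stats::runif(n_pit, 1, 2)
    feats$pit <- data.frame(
      kind = "pit",
      center_x = stats::runif(n_pit, 0, field_um),
      center_y = stats::runif(n_pit, 0, field_um),
      length_um = len, width_um = len / aspect,
      depth_um = config$depth_scale_um * depth_multiplier *
        stats::rlnorm(n_pit, -0.05, 0.3),
      orientation_deg = stats::runif(n_pit, 0, 180))
  }
  if (n_scr > 0) {
    sdlog <- 0.35
    len <- stats::rlnorm(n_scr, log(config$target_Ls_um) - sdlog^2 / 2, sdlog)
    wid <- pmin(stats::rlnorm(n_scr, log(3), 0.5), len / 4)
    th <- rvonmises(n_scr, 0, config$orientation_kappa) * 90 / pi
    feats$scratch <- data.frame(
      kind = "scratch",
      center_x = stats::runif(n_scr, 0, field_um),
      center_y = stats::runif(n_scr, 0, field_um),
      length_um = len, width_um = wid,
      depth_um = 0.6 * config$depth_scale_um * depth_multiplier *
        stats::rlnorm(n_scr, -0.05, 0.3),
      orientation_deg = (preferred_deg + th) %% 180)
  }
  out <- do.call(rbind, feats)
  if (is.null(out))
    out <- data.frame(kind = character(0), center_x = numeric(0),
                      center_y = numeric(0), length_um = numeric(0),
                      width_um = numeric(0), depth_um = numeric(0),
                      orientation_deg = numeric(0))
  rownames(out) <- NULL
  out
}

#' Imprint a single wear feature onto a height map
#'
#' Subtracts a smooth anisotropic depression: an elliptical-Gaussian
#' profile with semi-axes `length_um / 2` and `width_um / 2` (taken as
#' two standard deviations each), rotated by `orientation_deg` and with
#' peak depth `depth_um` at the centre. The profile is truncated at
#' three semi-axis lengths, beyond which the surface is exactly
#' unchanged; rendering disjoint features therefore commutes.
#'
#' @param feature One-row data frame (or list) with fields `center_x`,
#'   `center_y`, `length_um`, `width_um`, `depth_um`, `orientation_deg`.
#' @param hm A [height_map]; the feature centre must lie inside its
#'   extent.
#' @return The modified [height_map].
#' @export
render_feature <- function(feature, hm) {
  stopifnot(is_height_map(hm))
  cx <- feature$center_x; cy <- feature$center_y
  if (cx < 0 || cx > hm$extent_x || cy < 0 || cy > hm$extent_y)
    stopf("feature centre (%.3g, %.3g) lies outside the %g x %g um extent",
          cx, cy, hm$extent_x, hm$extent_y)
  au <- feature$length_um / 2          # semi-axes
  av <- feature$width_um / 2
  th <- feature$orientation_deg * pi / 180
  # conservative bounding box at 3 semi-axis lengths
  hx <- 3 * sqrt((au * cos(th))^2 + (av * sin(th))^2)
  hy <- 3 * sqrt((au * sin(th))^2 + (av * cos(th))^2)
  xs <- hm_x(hm); ys <- hm_y(hm)
  jj <- which(xs >= cx - hx & xs <= cx + hx)
  ii <- which(ys >= cy - hy & ys <= cy + hy)
  if (!length(ii) || !length(jj)) return(hm)
  X <- matrix(xs[jj] - cx, length(ii), length(jj), byrow = TRUE)
  Y <- matrix(ys[ii] - cy, length(ii), length(jj))
  u <- X * cos(th) + Y * sin(th)
  v <- -X * sin(th) + Y * cos(th)
  su <- au / 2; sv <- av / 2           # semi-axis = 2 standard deviations
  q <- (u / su)^2 + (v / sv)^2
  inside <- (u / au)^2 + (v / av)^2 <= 9   # truncate at 3 semi-axes
  dep <- feature$depth_um * exp(-q / 2) * inside
  hm$heights[ii, jj] <- hm$heights[ii, jj] - dep
  hm
}

#' Generate one synthetic occlusal surface with ground truth
#'
#' Builds a raw height map as the sum of form (a quadratic bowl),
#' waviness (two low-frequency sinusoids with random phase), rendered
#' wear features (counts Poisson at the animal's jittered rate, scratch
#' orientations von Mises), white instrument noise, and a random
#' non-measured dropout mask (default 5%, always below the 20%
#' rejection ceiling). Identical `(config, animal_index, seed)`
#' reproduce the output bit-exactly, and the returned feature list is
#' exact ground truth for the rendered features.
#'
#' @param config A [diet_group_config()].
#' @param animal_index Animal index within the group.
#' @param seed Integer seed for this surface.
#' @param grid_n Grid points per side; default 512.
#' @param extent_um Field size (µm); default 160 (square field).
#' @param noise_sd Instrument/residual-roughness noise standard
#'   deviation (µm); by default (`NULL`) the group's `roughness_um`
#'   jittered by the between-animal coefficient of variation.
#' @param dropout_rate Expected non-measured point fraction; default 0.05.
#' @return A list with `height_map` (stage `"raw"`) and `features` (a
#'   data frame of the rendered features, one row each).
#' @export
generate_surface <- function(config, animal_index, seed, grid_n = 512,
                             extent_um = 160, noise_sd = NULL,
                             dropout_rate = 0.05) {
  stopifnot(inherits(config, "diet_group_config"))
  if (dropout_rate < 0 || dropout_rate >= 0.2)
    stopf("dropout_rate must lie in [0, 0.2)")
  with_seed(seed, {
    dx <- extent_um / (grid_n - 1)
    xs <- (seq_len(grid_n) - 1) * dx
    mult <- rate_jitter(3, config$between_animal_cv)
    if (is.null(noise_sd)) noise_sd <- config$roughness_um * mult[3]
    # form: shallow quadratic bowl with jittered centre, ~4 um sag
    cx <- extent_um * stats::runif(1, 0.35, 0.65)
    cy <- extent_um * stats::runif(1, 0.35, 0.65)
    sag <- 4
    X <- matrix(xs, grid_n, grid_n, byrow = TRUE)
    Y <- matrix(xs, grid_n, grid_n)
    z <- -sag * ((X - cx)^2 + (Y - cy)^2) / extent_um^2
    # waviness: two low-frequency sinusoids
    for (wl in c(50, 80)) {
      ph <- stats::runif(1, 0, 2 * pi)
      dir <- stats::runif(1, 0, pi)
      amp <- if (wl == 50) 0.4 else 0.3
      z <- z + amp * sin(2 * pi * (X * cos(dir) + Y * sin(dir)) / wl + ph)
    }
    hm <- height_map(z, dx, dx, stage = "raw")
    feats <- sample_features(config, mult[1], mult[2], field_um = extent_um,
                             include_micropits = TRUE)
    for (i in seq_len(nrow(feats))) hm <- render_feature(feats[i, ], hm)
    if (noise_sd > 0)
      hm$heights <- hm$heights + matrix(stats::rnorm(grid_n^2, 0, noise_sd),
                                        grid_n, grid_n)
    if (dropout_rate > 0) {
      drop <- matrix(stats::runif(grid_n^2) < dropout_rate, grid_n, grid_n)
      hm$mask[drop] <- FALSE
      hm$heights[drop] <- NA_real_
    }
    list(height_map = hm, features = feats)
  })
}

#' Generate the 2D microwear counting field for one animal
#'
#' The 2D protocol tallies features inside a 300x300 µm square at lower
#' (stereomicroscope) magnification, a different observation scale than
#' the 160x160 µm 3D field; the counting field is therefore simulated as
#' a separate, coarser realisation of the same feature process. Features
#' are drawn over a square field with a margin around the counting
#' square, with coordinates centred on the square's centre at (0, 0).
#'
#' @inheritParams generate_surface
#' @param field_um Side of the simulated field; default 360 (a 30 µm
#'   margin around the 300 µm counting square).
#' @return A data frame of features (coordinates centred on the counting
#'   square).
#' @export
generate_counting_features <- function(config, animal_index, seed,
                                       field_um = 360) {
  stopifnot(inherits(config, "diet_group_config"))
  with_seed(seed, {
    mult <- rate_jitter(2, config$between_animal_cv)
    feats <- sample_features(config, mult[1], mult[2], field_um = field_um)
    feats$center_x <- feats$center_x - field_um / 2
    feats$center_y <- feats$center_y - field_um / 2
    feats
  })
}

#' Generate a full synthetic experiment bundle
#'
#' One surface, its ground-truth feature list, a 2D counting field and a
#' per-animal silica covariate for every animal of every group (default
#' group sizes 7, 6, 7, 6). Per-animal seeds are derived
#' deterministically from the master seed, so the whole bundle is
#' reproducible bit-exactly.
#'
#' @param configs Named list of [diet_group_config()]s with distinct
#'   labels; default [default_diet_configs()].
#' @param master_seed Integer master seed.
#' @param render_surfaces If `FALSE`, skip the 3D height maps (for
#'   microwear-only studies); default `TRUE`.
#' @param ... Passed to [generate_surface()] (`grid_n`, `extent_um`,
#'   `noise_sd`, `dropout_rate`).
#' @return An object of class `experiment_bundle`: a list with
#'   `animals` (a list of per-animal records: `group`, `animal_id`,
#'   `silica_mg_g`, `height_map`, `features`, `counting_features`) and
#'   `master_seed`.
#' @export
generate_group_sample <- function(configs = default_diet_configs(),
                                  master_seed = 1, render_surfaces = TRUE,
                                  ...) {
  labels <- vapply(configs, function(c) c$label, character(1))
  if (anyDuplicated(labels)) stopf("duplicate group labels")
  animals <- list()
  for (cfg in configs) {
    for (i in seq_len(cfg$n_animals)) {
      seed_surface <- derive_seed(master_seed, paste0(cfg$label, ":3d"), i)
      seed_count <- derive_seed(master_seed, paste0(cfg$label, ":2d"), i)
      seed_cov <- derive_seed(master_seed, paste0(cfg$label, ":sc"), i)
      surf <- if (render_surfaces)
        generate_surface(cfg, i, seed_surface, ...) else NULL
      silica <- with_seed(seed_cov,
                          cfg$silica_mg_g * rate_jitter(1, 0.04))
      animals[[length(animals) + 1]] <- list(
        group = cfg$label,
        animal_id = sprintf("%s%d", cfg$label, i),
        silica_mg_g = silica,
        height_map = surf$height_map,
        features = surf$features,
        counting_features = generate_counting_features(cfg, i, seed_count))
    }
  }
  structure(list(animals = animals, master_seed = master_seed,
                 labels = unname(labels)),
            class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  grp <- table(vapply(x$animals, function(a) a$group, character(1)))
  cat(sprintf("<experiment_bundle> %d animals (%s), master seed %s\n",
              length(x$animals),
              paste(sprintf("%s: %d", names(grp), grp), collapse = ", "),
              format(x$master_seed)))
  invisible(x)
}

#' Write an experiment bundle's feature lists to CSV
#'
#' @param bundle An `experiment_bundle`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(bundle, path) {
  rows <- do.call(rbind, lapply(bundle$animals, function(a) {
    if (is.null(a$counting_features) || nrow(a$counting_features) == 0)
      return(NULL)
    cbind(data.frame(animal_id = a$animal_id, group = a$group),
          a$counting_features)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
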