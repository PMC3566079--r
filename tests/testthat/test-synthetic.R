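# The calibrated synthetic-surface generator.

test_that("feature rendering digs where asked and commutes for disjoint features", {
  hm <- make_plane(101, a = 0, dx = 1, dy = 1)
  pit <- data.frame(kind = "pit", center_x = 50, center_y = 50,
                    length_um = 10, width_um = 8, depth_um = 2,
                    orientation_deg = 0)
  out <- render_feature(pit, hm)
  expect_equal(min(out$heights), -2, tolerance = 1e-6)
  idx <- which(out$heights == min(out$heights), arr.ind = TRUE)
  expect_equal(unname(idx[1, ]), c(51, 51))   # grid point at (50, 50)

  # a scratch's deepest trough runs along its orientation (image moments)
  scr <- data.frame(kind = "scratch", center_x = 50, center_y = 50,
                    length_um = 60, width_um = 4, depth_um = 2,
                    orientation_deg = 30)
  s <- render_feature(scr, hm)
  deep <- which(s$heights < -0.5, arr.ind = TRUE)
  xy <- cbind(x = deep[, 2] - 1, y = deep[, 1] - 1)
  cc <- cov(xy)
  ang <- (atan2(2 * cc[1, 2], cc[1, 1] - cc[2, 2]) / 2 * 180 / pi) %% 180
  expect_lt(abs(ang - 30), 2)

  # disjoint features commute
  f1 <- pit; f2 <- pit; f2$center_x <- 15; f2$center_y <- 15
  ab <- render_feature(f2, render_feature(f1, hm))
  ba <- render_feature(f1, render_feature(f2, hm))
  expect_identical(ab$heights, ba$heights)

  bad <- pit; bad$center_x <- 500
  expect_error(render_feature(bad, hm), "outside")
})

test_that("surface generation is deterministic and additive in its components", {
  cfg <- default_diet_configs()$G
  s1 <- generate_surface(cfg, 1, 42, grid_n = 64)
  s2 <- generate_surface(cfg, 1, 42, grid_n = 64)
  expect_identical(s1$height_map$heights, s2$height_map$heights)
  expect_identical(s1$features, s2$features)
  s3 <- generate_surface(cfg, 1, 43, grid_n = 64)
  expect_false(identical(s1$height_map$heights, s3$height_map$heights))

  # no features, no noise, no dropout: the surface is pure smooth
  # form + waviness — fully measured, featureless, and invariant (to
  # within the filter's tiny attenuation of 50-80 um wavelengths) under
  # a short-cutoff denoising lowpass
  quiet <- diet_group_config("Q", 4, 1, 0, 0, 1, 1, 0, micropit_rate = 0,
                             roughness_um = 0)
  sq <- generate_surface(quiet, 1, 7, grid_n = 96, noise_sd = 0,
                         dropout_rate = 0)
  expect_true(all(sq$height_map$mask))
  expect_equal(nrow(sq$features), 0)
  lo <- gaussian_areal_filter(sq$height_map, 4, "lowpass")
  expect_lt(max(abs(lo$heights - sq$height_map$heights)), 0.02)
})

test_that("feature counts follow the configured Poisson rates", {
  cfg <- diet_group_config("T", 4, 1, scratch_rate = 30, pit_rate = 0,
                           orientation_kappa = 2, depth_scale_um = 1,
                           between_animal_cv = 0, target_Ls_um = 50)
  counts <- vapply(1:200, function(i) {
    f <- generate_counting_features(cfg, 1, 1000 + i, field_um = 300)
    nrow(f[f$kind == "scratch", ])
  }, numeric(1))
  expect_lt(abs(mean(counts) - 30) / 30, 0.1)
})

test_that("scratch orientation concentration follows kappa", {
  circ_var <- function(deg) {
    th <- deg * pi / 90                # axial data on the half-circle
    1 - sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  }
  cvs <- vapply(c(0.5, 4, 16), function(kap) {
    cfg <- diet_group_config("K", 4, 1, scratch_rate = 40, pit_rate = 0,
                             orientation_kappa = kap, depth_scale_um = 1,
                             between_animal_cv = 0, target_Ls_um = 50)
    ori <- unlist(lapply(1:30, function(i)
      generate_counting_features(cfg, 1, 2000 + i)$orientation_deg))
    circ_var(ori)
  }, numeric(1))
  expect_true(all(diff(cvs) < 0))
})

test_that("the experiment bundle has the study's group structure", {
  b <- generate_group_sample(master_seed = 5, render_surfaces = FALSE)
  expect_equal(length(b$animals), 26)
  grp <- table(vapply(b$animals, function(a) a$group, character(1)))
  expect_equal(unname(grp[c("G", "GO", "LO", "L")]), c(7L, 6L, 7L, 6L),
               ignore_attr = TRUE)
  # reproducibility of the whole bundle
  b2 <- generate_group_sample(master_seed = 5, render_surfaces = FALSE)
  expect_identical(b$animals, b2$animals)
  # silica covariates centred on the dietary values
  sil <- vapply(b$animals, function(a) a$silica_mg_g, numeric(1))
  gl <- vapply(b$animals, function(a) a$group, character(1))
  expect_lt(abs(mean(sil[gl == "G"]) - 11.96), 0.6)
  expect_lt(abs(mean(sil[gl == "L"]) - 0.10), 0.01)

  dup <- default_diet_configs()[c(1, 1)]
  expect_error(generate_group_sample(dup, 1), "duplicate")
})

test_that("dropout stays under the rejection ceiling and masks points", {
  cfg <- default_diet_configs()$L
  s <- generate_surface(cfg, 2, 11, grid_n = 128, dropout_rate = 0.08)
  frac <- mean(!s$height_map$mask)
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.14)
  v <- validate_measured_fraction(s$height_map, 0.8)
  expect_identical(v$status, "accept")
})
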