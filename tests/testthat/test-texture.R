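# ISO-style areal texture parameters against closed forms and
# brute-force definitional oracles.

test_that("height parameters match closed forms on a sampled sinusoid", {
  # enough periods that the mean-plane fit is orthogonal to the sinusoid
  hm <- make_sinusoid(periods = 16, samples_per_period = 512, A = 1.4,
                      nrows = 4)
  hp <- height_params(hm)
  expect_equal(hp[["Sa"]], 2 * 1.4 / pi, tolerance = 0.005)
  expect_equal(hp[["Sq"]], 1.4 / sqrt(2), tolerance = 0.005)
  expect_equal(hp[["Ssk"]], 0, tolerance = 1e-6)
  expect_equal(hp[["Sku"]], 1.5, tolerance = 0.005)
  expect_equal(hp[["Sz"]], 2 * 1.4, tolerance = 0.005)
  expect_equal(hp[["Sz"]], hp[["Sp"]] + hp[["Sv"]])
})

test_that("a plane is flat and Ssk/Sku are signalled as undefined", {
  hm <- make_plane(8, a = 2, bx = 0.5)
  expect_warning(hp <- height_params(hm), class = "dentexture_undefined")
  expect_equal(unname(hp[c("Sa", "Sq", "Sp", "Sv", "Sz")]), rep(0, 5),
               tolerance = 1e-12)
  expect_true(all(is.na(hp[c("Ssk", "Sku")])))
})

test_that("height, hybrid and functional parameters match the brute-force oracle", {
  for (seed in 1:10) {
    hm <- random_height_map(16, seed = seed)
    hp <- height_params(hm)
    o <- oracle_height_params(hm$heights)
    for (p in names(o))
      expect_equal(hp[[p]], o[[p]], tolerance = 1e-12, label = p)
    yp <- hybrid_params(hm)
    oh <- oracle_hybrid_params(hm$heights, hm$dx, hm$dy)
    expect_equal(yp[["Sdq"]], oh$Sdq, tolerance = 1e-12)
    expect_equal(yp[["Sdr"]], oh$Sdr, tolerance = 1e-12)
    fp <- functional_params(hm)
    of <- oracle_functional_params(hm$heights)
    for (p in names(of))
      expect_equal(fp[[p]], of[[p]], tolerance = 1e-9, label = p)
  }
})

test_that("hybrid parameters are exact on constant-gradient surfaces", {
  flat <- make_plane(16, a = 3)
  expect_equal(unname(hybrid_params(flat)), c(0, 0))

  # tilted plane with gradient magnitude 0.5
  tilt <- make_plane(32, bx = 0.3, by = 0.4)
  yp <- hybrid_params(tilt)
  expect_equal(yp[["Sdq"]], 0.5, tolerance = 1e-12)
  expect_equal(yp[["Sdr"]], (sqrt(1.25) - 1) * 100, tolerance = 1e-12)

  # sinusoid: RMS gradient (2 pi A / lambda) / sqrt(2)
  hm <- make_sinusoid(periods = 4, samples_per_period = 256, A = 2,
                      wavelength = 64)
  expect_equal(hybrid_params(hm)[["Sdq"]], (2 * pi * 2 / 64) / sqrt(2),
               tolerance = 0.01)
})

test_that("functional parameters handle degenerate and two-level surfaces", {
  flat <- make_plane(8, a = 1)
  fp <- functional_params(flat)
  expect_equal(fp[["Smr"]], 100)
  expect_equal(fp[["Vv"]], 0)
  expect_equal(fp[["Sxp"]], 0)

  # two-level step: half at +d/2, half at -d/2
  d <- 2
  z <- matrix(rep(c(d / 2, -d / 2), each = 32), 8, 8)
  fp2 <- functional_params(height_map(z, 1, 1))
  of2 <- oracle_functional_params(z)
  for (p in names(of2))
    expect_equal(fp2[[p]], of2[[p]], tolerance = 1e-9, label = p)
  expect_equal(fp2[["Smc"]], d / 2)   # height at 10% material ratio
})

test_that("material-ratio volumes are monotone in the ratio", {
  hm <- random_height_map(24, seed = 3)
  z <- as.vector(hm$heights)
  ps <- seq(5, 95, by = 10)
  Vm <- vapply(ps, function(p)
    mean(pmax(z - stats::quantile(z, 1 - p / 100, names = FALSE), 0)),
    numeric(1))
  Vv <- vapply(ps, function(p)
    mean(pmax(stats::quantile(z, 1 - p / 100, names = FALSE) - z, 0)),
    numeric(1))
  expect_true(all(diff(Vm) >= -1e-12))
  expect_true(all(diff(Vv) <= 1e-12))
})

test_that("spatial parameters see isotropy, anisotropy and rotation", {
  set.seed(21)
  noise <- height_map(matrix(rnorm(128 * 128), 128), 0.5, 0.5)
  sp <- spatial_params(noise)
  expect_gt(sp[["Str"]], 0.9)
  expect_lt(sp[["Sal"]], 2 * 0.5)

  gro <- make_grooves(30)
  spg <- spatial_params(gro)
  expect_lt(abs(spg[["Std"]] - 30), 2)
  expect_lt(spg[["Str"]], 0.3)

  # rotation by 90 degrees shifts Std, leaves Sal and Str
  rot <- height_map(t(gro$heights)[nrow(gro$heights):1, ], 0.5, 0.5)
  spr <- spatial_params(rot)
  expect_lt(abs((spr[["Std"]] - spg[["Std"]]) %% 180 - 90), 2.5)
  expect_lt(abs(spr[["Sal"]] - spg[["Sal"]]) / spg[["Sal"]], 0.01)
  expect_lt(abs(spr[["Str"]] - spg[["Str"]]) / spg[["Str"]], 0.01)
})

test_that("watershed motifs count constructed pits and bumps under pruning", {
  n <- 128
  z <- -3 * gaussian_bump(n, 30, 30, 1) - 3 * gaussian_bump(n, 90, 40, 1) -
    3 * gaussian_bump(n, 60, 100, 1)
  hm <- height_map(z, 1, 1)
  m <- segment_motifs(hm, 0.05)
  expect_equal(nrow(m$dales), 3)

  # one isolated bump: exactly one hill, Spd = 1 / evaluated area
  zb <- 2 * gaussian_bump(64, 32, 32, 1)
  hb <- height_map(zb, 1, 1)
  mb <- segment_motifs(hb, 0.05)
  expect_equal(nrow(mb$hills), 1)
  fp <- feature_params(mb, hb)
  expect_equal(fp[["Spd"]] * mb$eval_area_um2, 1)
  expect_equal(fp[["Sha"]], mb$hills$area_um2[1])

  # shallow noise below the pruning height does not create extra dales
  set.seed(4)
  zn <- z + matrix(rnorm(n * n, 0, 0.02), n, n)
  hmn <- height_map(zn, 1, 1)
  expect_equal(nrow(segment_motifs(hmn, 0.05)$dales), 3)
  expect_gt(nrow(segment_motifs(hmn, 1e-6)$dales), 3)  # un-pruned count

  expect_error(segment_motifs(make_plane(8, a = 1), 0.05), "constant")
})

test_that("peak curvature and dale volume recover constructed geometry", {
  # spherical cap of radius R: mean peak curvature 1/R
  R <- 40; n <- 129; dx <- 0.5
  x <- ((seq_len(n) - 1) - (n - 1) / 2) * dx
  r2 <- outer(x^2, x^2, "+")
  cap <- ifelse(r2 < (0.8 * R)^2, sqrt(pmax(R^2 - r2, 0)) - R * 0.6, -R * 0.4)
  cap <- pmax(cap, 0)
  hm <- height_map(cap, dx, dx)
  m <- segment_motifs(hm, 0.05)
  fp <- feature_params(m, hm)
  expect_equal(fp[["Spc"]], 1 / R, tolerance = 0.05)

  # three identical pits: Sdv equals each pit's integrated volume
  n <- 192; sigma <- 4; depth <- 3
  z <- -depth * (gaussian_bump(n, 40, 40, 1, sigma) +
                 gaussian_bump(n, 140, 50, 1, sigma) +
                 gaussian_bump(n, 90, 150, 1, sigma))
  hm3 <- height_map(z, 1, 1)
  m3 <- segment_motifs(hm3, 0.02)
  expect_equal(nrow(m3$dales), 3)
  fp3 <- feature_params(m3, hm3)
  v_one <- depth * 2 * pi * sigma^2     # integral of the gaussian pit
  expect_equal(fp3[["Sdv"]], v_one, tolerance = 0.02)
})

test_that("compute_all emits all 30 parameters with the right homogeneity", {
  set.seed(30)
  n <- 96; dx <- 1
  z <- matrix(rnorm(n * n, 0, 0.3), n, n) +
    2 * gaussian_bump(n, 30, 40, 1, 5) - 2 * gaussian_bump(n, 70, 60, 1, 5)
  hm <- height_map(z, dx, dx)
  tp <- compute_all(hm)
  expect_setequal(names(tp$values), dentexture:::texture_param_names)
  expect_equal(length(tp$values), 30L)
  expect_true(all(is.finite(tp$values)))
  # the headline discriminating subset is present
  expect_true(all(c("S5v", "Sda", "Sdq", "Sdr", "Sdv", "Sp", "Ssk", "Sxp",
                    "Sz", "Vvv") %in% names(tp$values)))
  # identities
  expect_equal(tp$values[["Sz"]], tp$values[["Sp"]] + tp$values[["Sv"]])
  expect_equal(tp$values[["S10z"]], tp$values[["S5p"]] + tp$values[["S5v"]])
  expect_gte(tp$values[["Sq"]], tp$values[["Sa"]])
  expect_gt(tp$values[["Str"]], 0)
  expect_lte(tp$values[["Str"]], 1)

  # scaling heights by 2: first-degree parameters double, shape invariants stay
  tp2 <- compute_all(height_map(2 * z, dx, dx))
  for (p in c("Sa", "Sq", "Sp", "Sv", "Sz", "S5p", "S5v", "S10z", "Smc", "Sxp"))
    expect_equal(tp2$values[[p]], 2 * tp$values[[p]], tolerance = 1e-6,
                 label = p)
  for (p in c("Ssk", "Sku", "Str"))
    expect_equal(tp2$values[[p]], tp$values[[p]], tolerance = 1e-6, label = p)
  # determinism
  expect_identical(compute_all(hm)$values, tp$values)
})
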