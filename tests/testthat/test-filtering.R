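# The S-filter / F-operator / L-filter chain.

test_that("Gaussian lowpass transmits DC unchanged and 50% at the cutoff", {
  const <- height_map(matrix(3.2, 32, 32), 1, 1)
  lo <- gaussian_areal_filter(const, 8, "lowpass")
  expect_equal(lo$heights, const$heights, tolerance = 1e-12)

  # sinusoid at the cutoff wavelength: amplitude halves (away from borders)
  n <- 512; dx <- 0.5; lc <- 16
  x <- (0:(n - 1)) * dx
  hm <- height_map(matrix(sin(2 * pi * x / lc), 16, n, byrow = TRUE), dx, dx)
  out <- gaussian_areal_filter(hm, lc, "lowpass")
  amp <- max(out$heights[8, 100:400])
  expect_lt(abs(amp - 0.5), 0.01 * 0.5)

  hi <- gaussian_areal_filter(hm, lc, "highpass")
  expect_equal(out$heights + hi$heights, hm$heights, tolerance = 1e-14)

  expect_error(gaussian_areal_filter(hm, 2 * dx, "lowpass"), "resolvable")
  z <- hm$heights; z[1, 1] <- NA
  expect_error(gaussian_areal_filter(height_map(z, dx, dx), lc),
               "fill_nonmeasured")
})

test_that("form removal reproduces polynomial surfaces exactly", {
  n <- 64
  x <- seq(-1, 1, length.out = n)
  X <- matrix(x, n, n, byrow = TRUE); Y <- matrix(x, n, n)
  bowl <- height_map(3 * X^2 + 2 * Y^2 - X * Y, 0.5, 0.5)
  r <- remove_form(bowl, 2)
  expect_lt(max(abs(r$heights)), 1e-6)
  expect_lt(abs(mean(r$heights)), 1e-9)

  tilt <- height_map(2 + 0.3 * X + 0.1 * Y, 0.5, 0.5)
  expect_lt(max(abs(remove_form(tilt, 1)$heights)), 1e-9)

  # quadratic bowl + short cosine: the oscillation survives form removal
  # (cosine phase is orthogonal to odd monomials; its residual coupling
  # to x^2 falls off as wavelength^2, negligible at 1/16 of the extent)
  nf <- 256
  xf <- seq(-1, 1, length.out = nf)
  Xf <- matrix(xf, nf, nf, byrow = TRUE)
  osc <- cos(2 * pi * Xf / 0.125)
  both <- height_map(3 * Xf^2 + osc, 0.5, 0.5)
  res <- remove_form(both, 2)
  # amplitude recovered by lock-in projection at the known frequency
  amp <- sqrt((2 * mean(res$heights * cos(2 * pi * Xf / 0.125)))^2 +
              (2 * mean(res$heights * sin(2 * pi * Xf / 0.125)))^2)
  expect_lt(abs(amp - 1), 0.01)

  expect_error(remove_form(height_map(matrix(1:5, 1), 1, 1), 1), "degenerate")
})

test_that("filter_chain produces labelled stages with the expected content", {
  n <- 96; dx <- 160 / (n - 1)
  x <- (0:(n - 1)) * dx
  X <- matrix(x, n, n, byrow = TRUE); Y <- matrix(x, n, n)
  flat <- height_map(0.5 + 0.01 * X, dx, dx)
  st <- filter_chain(flat, s_cutoff_um = 4, l_cutoff_um = 25)
  expect_identical(st$primary$stage, "primary")
  expect_identical(st$s_f$stage, "S-F")
  expect_identical(st$s_l$stage, "S-L")
  # flat input: residuals only from mirror-padding border bend, well
  # below any feature scale
  expect_lt(max(abs(st$s_f$heights)), 0.01)
  expect_lt(max(abs(st$s_l$heights)), 0.01)
  expect_equal(st$s_l$border_um, 12.5)

  # short-wavelength sinusoid passes S-F -> S-L nearly unchanged
  # (amplitude by lock-in projection, insensitive to form residue)
  z <- 4 * (X / 160)^2 + 0.5 * sin(2 * pi * X / 8)
  st2 <- filter_chain(height_map(z, dx, dx), s_cutoff_um = 4, l_cutoff_um = 50)
  ctr <- 25:72
  amp <- function(hmx) {
    row <- hmx$heights[48, ctr]
    xs <- x[ctr]
    sqrt((2 * mean(row * sin(2 * pi * xs / 8)))^2 +
         (2 * mean(row * cos(2 * pi * xs / 8)))^2)
  }
  a_sf <- amp(st2$s_f); a_sl <- amp(st2$s_l)
  expect_lt(abs(a_sl - a_sf) / a_sf, 0.01)

  expect_error(filter_chain(flat, s_cutoff_um = 30, l_cutoff_um = 25),
               "ordering")
})

test_that("the chain is linear and offset-invariant after form removal", {
  set.seed(42)
  n <- 64; dx <- 1
  z <- matrix(rnorm(n * n), n, n)
  hm <- height_map(z, dx, dx)
  st1 <- filter_chain(hm, 4, 16)
  st2 <- filter_chain(height_map(2.5 * z, dx, dx), 4, 16)
  for (s in c("primary", "s_f", "s_l"))
    expect_equal(st2[[s]]$heights, 2.5 * st1[[s]]$heights, tolerance = 1e-10)

  st3 <- filter_chain(height_map(z + 7, dx, dx), 4, 16)
  expect_equal(st3$s_f$heights, st1$s_f$heights, tolerance = 1e-9)
  expect_equal(st3$s_l$heights, st1$s_l$heights, tolerance = 1e-9)
})
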