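# Small constructed surfaces used across the texture tests.

make_plane <- function(n = 16, a = 0, bx = 0, by = 0, dx = 1, dy = 1) {
  x <- (seq_len(n) - 1) * dx
  y <- (seq_len(n) - 1) * dy
  z <- a + outer(y * by, x * bx, "+")
  height_map(z, dx, dy)
}

# z = A cos(2*pi*(x - centre) / wavelength), constant along y; whole
# periods fit and the cosine is centred on the grid, so it is exactly
# orthogonal (in the discrete sum) to the mean-plane basis
make_sinusoid <- function(periods = 2, samples_per_period = 512, A = 1,
                          nrows = 16, wavelength = NULL) {
  n <- periods * samples_per_period
  dx <- if (is.null(wavelength)) 1 else wavelength / samples_per_period
  wl <- if (is.null(wavelength)) samples_per_period else wavelength
  x <- (seq_len(n) - 1) * dx
  xc <- x - (n - 1) * dx / 2
  z <- matrix(A * cos(2 * pi * xc / wl), nrows, n, byrow = TRUE)
  height_map(z, dx, dx)
}

random_height_map <- function(n = 16, seed = 1, dx = 0.7, dy = 1.3) {
  set.seed(seed)
  height_map(matrix(rnorm(n * n), n, n), dx, dy)
}

# groove field: parallel sinusoidal grooves running along `angle_deg`
make_grooves <- function(angle_deg, n = 128, dx = 0.5, wavelength = 8) {
  x <- (seq_len(n) - 1) * dx
  X <- matrix(x, n, n, byrow = TRUE)
  Y <- matrix(x, n, n)
  th <- angle_deg * pi / 180
  u <- -X * sin(th) + Y * cos(th)
  height_map(sin(2 * pi * u / wavelength), dx, dx)
}

# plane with isolated gaussian depressions (pits) or bumps
gaussian_bump <- function(n, cx, cy, depth, sigma = 3) {
  outer(seq_len(n), seq_len(n),
        function(i, j) depth * exp(-((i - cy)^2 + (j - cx)^2) / (2 * sigma^2)))
}
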