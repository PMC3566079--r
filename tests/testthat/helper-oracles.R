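# Brute-force definitional oracles, coded independently of the package
# implementation (explicit loops and normal equations), used to verify
# the texture parameters on small grids.

# least-squares plane via explicitly assembled normal equations
oracle_plane_residuals <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  xs <- if (nc > 1) seq(-1, 1, length.out = nc) else 0
  ys <- if (nr > 1) seq(-1, 1, length.out = nr) else 0
  A <- matrix(NA_real_, nr * nc, 3)
  b <- numeric(nr * nc)
  k <- 0
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    k <- k + 1
    A[k, ] <- c(1, xs[j], ys[i])
    b[k] <- z[i, j]
  }
  coef <- solve(t(A) %*% A, t(A) %*% b)
  matrix(b - A %*% coef, nr, nc)
}

oracle_height_params <- function(z) {
  r <- as.vector(oracle_plane_residuals(z))
  n <- length(r)
  Sq <- sqrt(sum(r^2) / n)
  list(Sa = sum(abs(r)) / n,
       Sq = Sq,
       Ssk = (sum(r^3) / n) / Sq^3,
       Sku = (sum(r^4) / n) / Sq^4,
       Sp = max(r), Sv = -min(r), Sz = max(r) - min(r))
}

oracle_hybrid_params <- function(z, dx, dy) {
  nr <- nrow(z); nc <- ncol(z)
  sum_g2 <- 0; sum_dev <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    zx <- if (j == 1) (z[i, 2] - z[i, 1]) / dx
      else if (j == nc) (z[i, nc] - z[i, nc - 1]) / dx
      else (z[i, j + 1] - z[i, j - 1]) / (2 * dx)
    zy <- if (i == 1) (z[2, j] - z[1, j]) / dy
      else if (i == nr) (z[nr, j] - z[nr - 1, j]) / dy
      else (z[i + 1, j] - z[i - 1, j]) / (2 * dy)
    g2 <- zx^2 + zy^2
    sum_g2 <- sum_g2 + g2
    sum_dev <- sum_dev + sqrt(1 + g2)
  }
  n <- nr * nc
  list(Sdq = sqrt(sum_g2 / n), Sdr = (sum_dev / n - 1) * 100)
}

# empirical material-ratio curve: height at ratio p via linear
# interpolation between order statistics (descending)
oracle_height_at_ratio <- function(z, p_pct) {
  s <- sort(as.vector(z), decreasing = TRUE)
  n <- length(s)
  h <- (n - 1) * p_pct / 100 + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

oracle_functional_params <- function(z, conditions = default_conditions()) {
  zv <- as.vector(z)
  n <- length(zv)
  p <- conditions$p_pct; q <- conditions$q_pct
  vm <- function(pp) {
    h <- oracle_height_at_ratio(zv, pp)
    tot <- 0
    for (v in zv) if (v > h) tot <- tot + (v - h)
    tot / n
  }
  vv <- function(pp) {
    h <- oracle_height_at_ratio(zv, pp)
    tot <- 0
    for (v in zv) if (v < h) tot <- tot + (h - v)
    tot / n
  }
  list(Smr = 100 * sum(zv >= max(zv) - conditions$smr_c_um) / n,
       Smc = oracle_height_at_ratio(zv, p),
       Sxp = oracle_height_at_ratio(zv, conditions$sxp_p_pct) -
         oracle_height_at_ratio(zv, conditions$sxp_q_pct),
       Vm = vm(p), Vv = vv(p), Vmp = vm(p),
       Vmc = vm(q) - vm(p), Vvc = vv(p) - vv(q), Vvv = vv(q))
}

# exhaustive-enumeration Cliff delta
oracle_cliff_delta <- function(x, y) {
  tot <- 0
  for (xi in x) for (yj in y) tot <- tot + sign(xi - yj)
  tot / (length(x) * length(y))
}
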