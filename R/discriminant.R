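## Forward-stepping canonical discriminant analysis with group-centroid
## confidence ellipses.

## within-group (W) and total (T) SSCP matrices on a variable subset
sscp_matrices <- function(X, labels) {
  X <- as.matrix(X)
  Tm <- crossprod(scale(X, center = TRUE, scale = FALSE))
  W <- matrix(0, ncol(X), ncol(X))
  for (g in unique(labels)) {
    Xg <- X[labels == g, , drop = FALSE]
    W <- W + crossprod(scale(Xg, center = TRUE, scale = FALSE))
  }
  list(W = W, T = Tm)
}

wilks_lambda <- function(X, labels, vars) {
  if (length(vars) == 0) return(1)
  s <- sscp_matrices(X[, vars, drop = FALSE], labels)
  dW <- det(s$W); dT <- det(s$T)
  if (!is.finite(dW) || !is.finite(dT) || dT <= 0) return(NA_real_)
  dW / dT
}

#' Forward-stepping variable selection by partial Wilks lambda
#'
#' Greedy forward selection: at each step the candidate variable with
#' the largest partial F (from the ratio of Wilks lambdas with and
#' without the variable) enters if its partial F is at least `f_enter`;
#' after every entry, any included variable whose partial F has fallen
#' below `f_remove` is removed. `f_remove < f_enter` guarantees
#' termination. Defaults `f_enter = 1`, `f_remove = 0.9` follow standard
#' stepping practice for discriminant analysis.
#'
#' The partial F for variable v given the selected set S is
#' \deqn{F = \frac{n - k - p}{k - 1} \cdot \frac{1 - \lambda}{\lambda},
#'   \quad \lambda = \Lambda(S \cup v) / \Lambda(S),}
#' with `n` animals, `k` groups and `p = |S|`.
#'
#' @param X Data frame or matrix, animals in rows, candidate variables
#'   in columns (named).
#' @param labels Group labels, length `nrow(X)`.
#' @param f_enter,f_remove Entry / removal thresholds; `f_remove` must
#'   be `< f_enter`.
#' @return Character vector of selected variable names, in entry order.
#' @export
stepwise_select <- function(X, labels, f_enter = 1, f_remove = 0.9) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (f_remove >= f_enter) stopf("f_remove must be < f_enter")
  k <- length(unique(labels))
  if (k < 2) stopf("at least 2 groups required")
  n <- nrow(X)
  selected <- character(0)
  partial_f <- function(v, S) {
    lam_S <- wilks_lambda(X, labels, S)
    lam_Sv <- wilks_lambda(X, labels, c(S, v))
    if (!is.finite(lam_S) || !is.finite(lam_Sv) || lam_Sv <= 0) return(NA_real_)
    lam <- lam_Sv / lam_S
    (n - k - length(S)) / (k - 1) * (1 - lam) / lam
  }
  repeat {
    cand <- setdiff(colnames(X), selected)
    if (length(cand) == 0 || n - k - length(selected) <= 0) break
    fs <- vapply(cand, partial_f, numeric(1), S = selected)
    fs[is.na(fs)] <- -Inf
    best <- which.max(fs)
    if (fs[best] < f_enter) break
    selected <- c(selected, cand[best])
    # backward pass: drop any variable whose partial F fell below f_remove
    repeat {
      if (length(selected) <= 1) break
      fr <- vapply(selected, function(v)
        partial_f(v, setdiff(selected, v)), numeric(1))
      fr[is.na(fr)] <- Inf
      worst <- which.min(fr)
      if (fr[worst] >= f_remove) break
      selected <- selected[-worst]
    }
  }
  selected
}

#' Canonical discriminant analysis
#'
#' Canonical axes from the generalized eigenproblem of between-group
#' against within-group scatter on the supplied (already selected)
#' variables. Axes are ordered by decreasing eigenvalue (ties broken by
#' variable order), scores are centred on the grand mean, and
#' coefficients are scaled so canonical scores have unit pooled
#' within-group variance on every axis. The sign of each axis is fixed
#' by making its largest-magnitude coefficient positive, so results are
#' reproducible.
#'
#' @param X Data frame or matrix of the selected variables (animals in
#'   rows).
#' @param labels Group labels.
#' @return An object of class `discriminant_result`: list with
#'   `variables`, `coefficients` (variables x axes), `eigenvalues`,
#'   `scores` (animals x axes, first `min(k - 1, p)` axes), `centroids`
#'   (per group, first two axes), `labels`.
#' @export
canonical_da <- function(X, labels) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  labels <- as.character(labels)
  k <- length(unique(labels))
  if (k < 2) stopf("at least 2 groups required")
  n <- nrow(X); p <- ncol(X)
  s <- sscp_matrices(X, labels)
  W <- s$W; B <- s$T - s$W
  Sw <- W / (n - k)
  ev <- tryCatch(eigen(solve(Sw, B / (n - k))),
                 error = function(e)
                   stopf("singular within-group scatter on {%s}",
                         paste(colnames(X), collapse = ", ")))
  naxes <- min(k - 1, p)
  vals <- Re(ev$values)[seq_len(naxes)]
  A <- Re(ev$vectors)[, seq_len(naxes), drop = FALSE]
  # normalize: unit pooled within-group variance of scores
  for (a in seq_len(naxes)) {
    sc <- sqrt(drop(t(A[, a]) %*% Sw %*% A[, a]))
    A[, a] <- A[, a] / sc
    if (A[which.max(abs(A[, a])), a] < 0) A[, a] <- -A[, a]
  }
  rownames(A) <- colnames(X)
  colnames(A) <- paste0("axis", seq_len(naxes))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  scores <- Xc %*% A
  centroids <- do.call(rbind, lapply(unique(labels), function(g)
    colMeans(scores[labels == g, , drop = FALSE])))
  rownames(centroids) <- unique(labels)
  structure(list(variables = colnames(X), coefficients = A,
                 eigenvalues = vals, scores = scores,
                 centroids = centroids, labels = labels),
            class = "discriminant_result")
}

#' @export
print.discriminant_result <- function(x, ...) {
  cat(sprintf("<discriminant_result> %d axes on {%s}; eigenvalues %s\n",
              ncol(x$scores), paste(x$variables, collapse = ", "),
              paste(signif(x$eigenvalues, 4), collapse = ", ")))
  invisible(x)
}

#' Group-centroid confidence ellipses
#'
#' For each group, a confidence region for the *centroid* (not a data
#' ellipse): the group's 2-D score covariance scaled by
#' `qchisq(confidence, 2) / n_g`. Reported as centre, semi-axes and
#' orientation. Groups with (numerically) zero score covariance give a
#' degenerate zero-area ellipse, flagged.
#'
#' @param scores Numeric matrix of canonical scores (at least two
#'   columns; the first two are used).
#' @param labels Group labels.
#' @param confidence Confidence level in `(0, 1)`; default 0.90.
#' @return Data frame with one row per group: `group`, `n`, `cx`, `cy`,
#'   `a` and `b` (semi-axes), `angle_deg`, `area`, `degenerate`, plus an
#'   attribute `"cov"` with the per-group scaled covariance matrices.
#' @export
centroid_ellipses <- function(scores, labels, confidence = 0.90) {
  group_ellipses(scores, labels, confidence, per_n = TRUE)
}

#' Group factor-space (data-concentration) ellipses
#'
#' The region a group's canonical scores occupy: the group's 2-D score
#' covariance scaled by the chi-square quantile at the given confidence
#' (no division by group size). Unlike the centroid regions of
#' [centroid_ellipses()], the size of a factor space reflects the
#' within-group variability itself, so overlap between factor spaces is
#' the right reading of statements like "two diets occupy distinct
#' factor spaces".
#'
#' @inheritParams centroid_ellipses
#' @return As [centroid_ellipses()].
#' @export
factor_space_ellipses <- function(scores, labels, confidence = 0.90) {
  group_ellipses(scores, labels, confidence, per_n = FALSE)
}

group_ellipses <- function(scores, labels, confidence, per_n) {
  if (confidence <= 0 || confidence >= 1) stopf("confidence must be in (0, 1)")
  scores <- as.matrix(scores)
  if (ncol(scores) < 2) stopf("need at least two score axes")
  labels <- as.character(labels)
  covs <- list()
  rows <- lapply(unique(labels), function(g) {
    S <- scores[labels == g, 1:2, drop = FALSE]
    ng <- nrow(S)
    if (ng < 3) stopf("group %s has fewer than 3 animals", g)
    V <- stats::cov(S) * stats::qchisq(confidence, 2) /
      (if (per_n) ng else 1)
    covs[[g]] <<- V
    e <- eigen(V, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    degenerate <- lam[1] <= 0 || lam[2] / max(lam[1], .Machine$double.eps) < 1e-12
    data.frame(group = g, n = ng, cx = mean(S[, 1]), cy = mean(S[, 2]),
               a = sqrt(lam[1]), b = sqrt(lam[2]),
               angle_deg = (atan2(e$vectors[2, 1], e$vectors[1, 1]) *
                              180 / pi) %% 180,
               area = pi * sqrt(lam[1] * lam[2]),
               degenerate = degenerate)
  })
  out <- do.call(rbind, rows)
  attr(out, "cov") <- covs
  out
}

## points on an ellipse boundary (row of a centroid_ellipses table)
ellipse_boundary <- function(e, npts = 181) {
  th <- seq(0, 2 * pi, length.out = npts)
  phi <- e$angle_deg * pi / 180
  x <- e$a * cos(th); y <- e$b * sin(th)
  cbind(e$cx + x * cos(phi) - y * sin(phi),
        e$cy + x * sin(phi) + y * cos(phi))
}

point_in_ellipse <- function(pt, e) {
  phi <- e$angle_deg * pi / 180
  dx <- pt[1] - e$cx; dy <- pt[2] - e$cy
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  if (e$a <= 0 || e$b <= 0) return(FALSE)
  (u / e$a)^2 + (v / e$b)^2 <= 1
}

#' Do two centroid ellipses overlap?
#'
#' Boundary-sampling test: the ellipses overlap if either centre lies
#' inside the other ellipse or any sampled boundary point of one lies
#' inside the other (361 boundary points each).
#'
#' @param e1,e2 Single rows of a [centroid_ellipses()] table.
#' @return Logical.
#' @export
ellipses_overlap <- function(e1, e2) {
  if (point_in_ellipse(c(e1$cx, e1$cy), e2)) return(TRUE)
  if (point_in_ellipse(c(e2$cx, e2$cy), e1)) return(TRUE)
  b1 <- ellipse_boundary(e1, 361)
  if (any(apply(b1, 1, point_in_ellipse, e = e2))) return(TRUE)
  b2 <- ellipse_boundary(e2, 361)
  any(apply(b2, 1, point_in_ellipse, e = e1))
}
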