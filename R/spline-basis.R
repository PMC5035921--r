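#' Cyclic cubic regression spline basis
#'
#' Standard cyclic cubic regression spline parameterised by the function
#' values at `k` evenly spaced knots over `[0, period]`, with the value at
#' the last knot identified with the first (so `k - 1` free coefficients).
#' Continuity of value, first and second derivative holds across the wrap
#' point.  The penalty is the integrated squared second derivative, a
#' symmetric positive semi-definite matrix whose null space is the constant
#' function.
#'
#' @param x evaluation points; reduced modulo `period` into `[0, period)`.
#' @param k basis dimension (number of knots, >= 4); the design matrix has
#'   `k - 1` columns.
#' @param period cycle length (default 24 h).
#' @return list with `X` (design matrix, `length(x)` by `k - 1`), `S`
#'   (penalty, `k - 1` square), `knots`.
#' @export
cyclic_spline_basis <- function(x, k = 10, period = 24) {
  if (k < 4) {
    stop("cyclic basis needs k >= 4")
  }
  n_k <- k - 1L                       # unique knots
  knots <- seq(0, period, length.out = k)[seq_len(n_k)]
  h <- rep(period / (k - 1L), n_k)    # spacing, uniform and cyclic

  # cyclic matrices linking knot values b to knot second derivatives g:
  # B g = D b  (Wood-style cyclic smoother construction)
  B <- matrix(0, n_k, n_k)
  D <- matrix(0, n_k, n_k)
  for (j in seq_len(n_k)) {
    jm <- if (j == 1) n_k else j - 1L  # previous knot (cyclic)
    jp <- if (j == n_k) 1L else j + 1L
    B[j, jm] <- B[j, jm] + h[jm] / 6
    B[j, j]  <- B[j, j] + (h[jm] + h[j]) / 3
    B[j, jp] <- B[j, jp] + h[j] / 6
    D[j, jm] <- D[j, jm] + 1 / h[jm]
    D[j, j]  <- D[j, j] - 1 / h[jm] - 1 / h[j]
    D[j, jp] <- D[j, jp] + 1 / h[j]
  }
  Fm <- solve(B, D)                   # g = Fm %*% b
  S <- t(D) %*% Fm                    # integral of f''^2
  S <- (S + t(S)) / 2

  xr <- x %% period
  j <- pmin(floor(xr / h[1]) + 1L, n_k)
  jp <- ifelse(j == n_k, 1L, j + 1L)
  x0 <- knots[j]
  hj <- h[1]
  am <- (x0 + hj - xr) / hj
  ap <- (xr - x0) / hj
  cm <- ((x0 + hj - xr)^3 / hj - hj * (x0 + hj - xr)) / 6
  cp <- ((xr - x0)^3 / hj - hj * (xr - x0)) / 6

  X <- matrix(0, length(x), n_k)
  for (i in seq_along(x)) {
    row <- cm[i] * Fm[j[i], ] + cp[i] * Fm[jp[i], ]
    row[j[i]] <- row[j[i]] + am[i]
    row[jp[i]] <- row[jp[i]] + ap[i]
    X[i, ] <- row
  }
  list(X = X, S = S, knots = knots, period = period)
}

#' Natural cubic regression spline basis (1-D smoother)
#'
#' Low-rank 1-D smoother with the integrated-squared-second-derivative
#' penalty, parameterised by the function values at `k` knots spread over
#' the range of `x` (natural boundary conditions: zero second derivative at
#' the end knots).  The penalty null space is spanned by `{1, x}`.  This is
#' the 1-D workhorse used where a thin-plate-class default smoother is
#' called for; in one dimension the two have the same penalty null space
#' and practically indistinguishable fits.
#'
#' @param x evaluation points.
#' @param k number of knots (>= 3).
#' @param knots optional explicit knot vector (sorted, unique).
#' @return list with `X` (`length(x)` by `k`), `S` (`k` square), `knots`.
#' @export
natural_spline_basis <- function(x, k = 10, knots = NULL) {
  if (is.null(knots)) {
    knots <- seq(min(x), max(x), length.out = k)
  }
  n_k <- length(knots)
  if (n_k < 3) {
    stop("natural spline basis needs k >= 3")
  }
  h <- diff(knots)

  # B (n-2 x n-2), D (n-2 x n): g_interior = B^{-1} D b, natural BCs
  B <- matrix(0, n_k - 2L, n_k - 2L)
  D <- matrix(0, n_k - 2L, n_k)
  for (j in seq_len(n_k - 2L)) {
    B[j, j] <- (h[j] + h[j + 1]) / 3
    if (j > 1) B[j, j - 1] <- h[j] / 6
    if (j < n_k - 2L) B[j, j + 1] <- h[j + 1] / 6
    D[j, j] <- 1 / h[j]
    D[j, j + 1] <- -1 / h[j] - 1 / h[j + 1]
    D[j, j + 2] <- 1 / h[j + 1]
  }
  Fm <- solve(B, D)
  S <- t(D) %*% Fm
  S <- (S + t(S)) / 2

  xr <- pmin(pmax(x, knots[1]), knots[n_k])  # clamp to knot range
  j <- pmin(findInterval(xr, knots, rightmost.closed = TRUE), n_k - 1L)
  hj <- h[j]
  am <- (knots[j + 1] - xr) / hj
  ap <- (xr - knots[j]) / hj
  cm <- ((knots[j + 1] - xr)^3 / hj - hj * (knots[j + 1] - xr)) / 6
  cp <- ((xr - knots[j])^3 / hj - hj * (xr - knots[j])) / 6

  G <- rbind(0, Fm, 0)                # second derivatives at all knots
  X <- matrix(0, length(x), n_k)
  for (i in seq_along(x)) {
    row <- cm[i] * G[j[i], ] + cp[i] * G[j[i] + 1L, ]
    row[j[i]] <- row[j[i]] + am[i]
    row[j[i] + 1L] <- row[j[i] + 1L] + ap[i]
    X[i, ] <- row
  }
  list(X = X, S = S, knots = knots)
}

# absorb the sum-to-zero identifiability constraint colSums(X) %*% b = 0
# into the basis: X <- X Z, S <- Z' S Z with Z an orthonormal null basis
absorb_constraint <- function(X, S) {
  C <- matrix(colSums(X), nrow = 1)
  qrC <- qr(t(C))
  Z <- qr.Q(qrC, complete = TRUE)[, -1, drop = FALSE]
  list(X = X %*% Z, S = t(Z) %*% S %*% Z, Z = Z)
}
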