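#' Linear mixed model by restricted maximum likelihood
#'
#' Gaussian LMM with independent random intercepts per grouping factor.
#' Variance components are estimated by maximizing the REML criterion with
#' Fisher scoring (analytic score and expected information on the
#' variance-component scale), with step halving and an active-set guard
#' that allows components to sit exactly on the zero boundary.
#'
#' @param formula model formula for the response and fixed effects.
#' @param data data frame.
#' @param random character vector of random-intercept factor names
#'   (columns of `data`).  Factors with fewer than two levels are dropped
#'   with a message.
#' @param max_iter,tol scoring iteration controls.
#' @return An object of class `lmm_fit`: `varcomp` (named variance
#'   components incl. `residual`), `fixef` tibble with t-tests
#'   (`df = n - p`, a simple residual-df convention), `reml_loglik`,
#'   `fitted`, `converged`.
#' @export
fit_lmm <- function(formula, data, random = character(), max_iter = 200,
                    tol = 1e-12) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  p <- qr(X)$rank

  Zs <- list()
  for (rname in random) {
    f <- factor(data[[rname]][as.integer(rownames(mf))])
    if (nlevels(f) < 2) {
      message("random factor '", rname, "' has fewer than 2 levels; dropped")
      next
    }
    Zs[[rname]] <- stats::model.matrix(~ f - 1)
  }
  r <- length(Zs)
  Gs <- lapply(Zs, tcrossprod)              # Z_j Z_j'

  lm0 <- stats::lm.fit(X, y)
  v0 <- max(sum(lm0$residuals^2) / max(n - p, 1), 1e-10)
  theta <- c(rep(v0 / (r + 1), r), v0 * (if (r > 0) r / (r + 1) else 1))
  names(theta) <- c(names(Zs), "residual")

  neg2reml <- function(theta) {
    V <- diag(rep(theta[r + 1], n))
    for (j in seq_len(r)) V <- V + theta[j] * Gs[[j]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(val = Inf))
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    A <- XtVi %*% X
    chA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(chA)) return(list(val = Inf))
    beta <- drop(chol2inv(chA) %*% (XtVi %*% y))
    rres <- y - drop(X %*% beta)
    Py <- drop(Vi %*% rres)
    val <- 2 * sum(log(diag(ch))) + 2 * sum(log(diag(chA))) + sum(rres * Py)
    P <- Vi - t(XtVi) %*% chol2inv(chA) %*% XtVi
    list(val = val, P = P, Py = Py, beta = beta, Vi = Vi, A = A)
  }

  st <- neg2reml(theta)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    G_all <- c(Gs, list(diag(n)))
    PG <- lapply(G_all, function(G) st$P %*% G)
    score <- vapply(seq_len(r + 1), function(j) {
      -0.5 * (sum(diag(PG[[j]])) - drop(crossprod(st$Py, G_all[[j]] %*% st$Py)))
    }, numeric(1))
    info <- matrix(0, r + 1, r + 1)
    for (j in seq_len(r + 1)) {
      for (kk in j:(r + 1)) {
        info[j, kk] <- info[kk, j] <- 0.5 * sum(PG[[j]] * t(PG[[kk]]))
      }
    }
    # active set: components pinned at zero with inward-pointing score stay
    free <- !(theta[seq_len(r + 1)] <= 0 & score < 0)
    free[r + 1] <- TRUE
    if (max(abs(score[free])) < 1e-8 * (1 + abs(st$val))) {
      converged <- TRUE
      break
    }
    dir <- rep(0, r + 1)
    Ifree <- info[free, free, drop = FALSE]
    dir[free] <- tryCatch(
      drop(solve(Ifree + diag(1e-10, sum(free)), score[free])),
      error = function(e) score[free] / (diag(Ifree) + 1e-10))
    step <- 1
    repeat {
      cand <- pmax(theta + step * dir, 0)
      cand[r + 1] <- max(cand[r + 1], 1e-12)
      st_new <- neg2reml(cand)
      if (st_new$val <= st$val + 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    moved <- max(abs(cand - theta))
    theta <- cand
    st <- st_new
    if (moved < tol * (1 + max(theta))) {
      converged <- TRUE
      break
    }
  }

  Vb <- chol2inv(chol(st$A))
  se <- sqrt(diag(Vb))
  est <- st$beta
  tval <- est / se
  df <- n - p
  fixef <- tibble::tibble(
    term = colnames(X), estimate = est, se = se, t = tval, df = df,
    p = 2 * stats::pt(-abs(tval), df)
  )
  structure(list(
    varcomp = theta, fixef = fixef, vcov = Vb,
    reml_loglik = -0.5 * st$val,
    fitted = drop(X %*% est), residuals = y - drop(X %*% est),
    converged = converged, n = n
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> REML, n =", x$n, "\n variance components:\n")
  print(round(x$varcomp, 6))
  cat(" fixed effects:\n")
  print(as.data.frame(x$fixef), digits = 4)
  invisible(x)
}

#' Residual day/night trend analysis after the hourly GAMM
#'
#' Extracts the working residuals of the hourly (24 h lumped) GAMM, splits
#' them into day and night observations, averages them per individual per
#' day before departure, and fits, separately for day and night, the LMM
#' `residual ~ days_before_departure * status` with random intercepts for
#' individual and year.  The interaction term tests whether activity
#' changed as departure approached differently in migrants and residents.
#'
#' @param fit hourly `rhythm_fit` whose `data` carries `bird_id`, `status`,
#'   `year`, `days_before_departure` and `daynight`.
#' @return list with elements `day` and `night`, each a list of the
#'   `lmm_fit` and the one-row interaction test tibble.
#' @export
residual_daynight_lmm <- function(fit) {
  df <- fit$data
  need <- c("bird_id", "status", "year", "days_before_departure", "daynight")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("fit data lacks column(s): ", paste(miss, collapse = ", "))
  }
  df$resid <- fit$working_residuals
  out <- list()
  for (dn in c("day", "night")) {
    sub <- df[df$daynight == dn, , drop = FALSE]
    agg <- dplyr::summarise(
      dplyr::group_by(sub, bird_id, status, year, days_before_departure),
      resid = mean(resid), .groups = "drop"
    )
    lf <- fit_lmm(resid ~ days_before_departure * status, agg,
                  random = c("bird_id", "year"))
    inter <- grep(":", lf$fixef$term, value = TRUE)[1]
    out[[dn]] <- list(fit = lf,
                      interaction = lf$fixef[lf$fixef$term == inter, ])
  }
  out
}

#' August versus pre-migration nocturnal activity comparison
#'
#' Log-transformed mean night activity (a small offset handles zeros:
#' default half of the smallest nonzero per-bin proportion, 1/60) modelled
#' with period (August vs pre-migration), migratory status and their
#' interaction as fixed effects, and individual and year random intercepts.
#'
#' @param night_means tibble with columns `bird_id`, `status`, `year`,
#'   `period` (`"august"` / `"pre_migration"`) and `night_mean`
#'   (see [night_mean_series()]); rows with `NA` means are dropped.
#' @param eps offset added before the log transform.
#' @return list: `fit` (`lmm_fit`) and `tests` (fixed-effect tibble).
#' @export
august_comparison <- function(night_means, eps = 1 / 60) {
  nm <- night_means[!is.na(night_means$night_mean), , drop = FALSE]
  if (nrow(nm) < 4) {
    stop("too few birds with night means in both periods")
  }
  nm$log_act <- log(nm$night_mean + eps)
  if (stats::sd(nm$log_act) == 0) {
    warning("night activity is constant (variance 0); ",
            "the comparison is degenerate")
  }
  nm$period <- factor(nm$period, c("august", "pre_migration"))
  fit <- fit_lmm(log_act ~ period * status, nm,
                 random = c("bird_id", "year"))
  list(fit = fit, tests = fit$fixef)
}
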