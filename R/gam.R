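#' Smooth term specification
#'
#' @param var name of the covariate in the data.
#' @param bs basis type: `"cc"` (cyclic cubic, for time-of-day) or `"tp"`
#'   (1-D thin-plate-class default, implemented as a natural cubic
#'   regression spline with identical penalty null space).
#' @param k basis dimension (default 10).
#' @param by optional name of a grouping factor: one independent smooth
#'   (own smoothing parameter) per level.
#' @param period cycle length for `bs = "cc"` (default 24).
#' @return A `smooth_spec` list.
#' @export
smooth_spec <- function(var, bs = c("cc", "tp"), k = 10, by = NULL,
                        period = 24) {
  bs <- match.arg(bs)
  if (bs == "cc" && k < 4) stop("cyclic smooth needs k >= 4")
  structure(list(var = var, bs = bs, k = k, by = by, period = period),
            class = "smooth_spec")
}

#' @keywords internal
gam_control <- function(eps_dev = 1e-8, max_pirls = 200, max_outer = 40,
                        tol_outer = 5e-3, lambda_min = 1e-7,
                        lambda_max = 1e8) {
  list(eps_dev = eps_dev, max_pirls = max_pirls, max_outer = max_outer,
       tol_outer = tol_outer, lambda_min = lambda_min,
       lambda_max = lambda_max)
}

prepare_smooth <- function(spec, data) {
  x <- data[[spec$var]]
  if (is.null(x)) stop("smooth covariate '", spec$var, "' not in data")
  raw <- if (spec$bs == "cc") {
    cyclic_spline_basis(x, spec$k, spec$period)
  } else {
    natural_spline_basis(x, spec$k)
  }
  con <- absorb_constraint(raw$X, raw$S)
  rank <- qr(con$S)$rank
  levels_by <- if (!is.null(spec$by)) levels(factor(data[[spec$by]])) else NULL
  list(spec = spec, knots = raw$knots, Z = con$Z, S = con$S, rank = rank,
       levels_by = levels_by)
}

eval_smooth_base <- function(prep, data) {
  x <- data[[prep$spec$var]]
  raw <- if (prep$spec$bs == "cc") {
    cyclic_spline_basis(x, prep$spec$k, prep$spec$period)
  } else {
    natural_spline_basis(x, prep$spec$k, knots = prep$knots)
  }
  raw$X %*% prep$Z
}

# assemble design blocks: fixed, smooths (by-level expanded), random factors
build_design <- function(data, fixed, smooth_preps, random) {
  Xf <- stats::model.matrix(fixed, data)
  blocks <- list(list(label = "fixed", type = "fixed",
                      cols = seq_len(ncol(Xf)), S = NULL, rank = 0))
  Xs <- list(Xf)
  col_at <- ncol(Xf)
  for (prep in smooth_preps) {
    Xb <- eval_smooth_base(prep, data)
    if (is.null(prep$levels_by)) {
      blocks[[length(blocks) + 1L]] <- list(
        label = paste0("s(", prep$spec$var, ")"), type = "smooth",
        cols = col_at + seq_len(ncol(Xb)), S = prep$S, rank = prep$rank)
      Xs[[length(Xs) + 1L]] <- Xb
      col_at <- col_at + ncol(Xb)
    } else {
      f <- factor(data[[prep$spec$by]], levels = prep$levels_by)
      for (lev in prep$levels_by) {
        Xl <- Xb * as.numeric(f == lev)
        blocks[[length(blocks) + 1L]] <- list(
          label = paste0("s(", prep$spec$var, "):", prep$spec$by, lev),
          type = "smooth",
          cols = col_at + seq_len(ncol(Xl)), S = prep$S, rank = prep$rank)
        Xs[[length(Xs) + 1L]] <- Xl
        col_at <- col_at + ncol(Xl)
      }
    }
  }
  for (rname in random) {
    f <- factor(data[[rname]])
    if (nlevels(f) < 2) {
      message("random factor '", rname, "' has fewer than 2 levels; dropped")
      next
    }
    Xr <- stats::model.matrix(~ f - 1)
    colnames(Xr) <- paste0(rname, levels(f))
    q <- ncol(Xr)
    blocks[[length(blocks) + 1L]] <- list(
      label = paste0("re(", rname, ")"), type = "re",
      cols = col_at + seq_len(q), S = diag(q), rank = q)
    Xs[[length(Xs) + 1L]] <- Xr
    col_at <- col_at + q
  }
  X <- do.call(cbind, Xs)
  list(X = X, blocks = blocks)
}

penalty_matrix <- function(blocks, p, lambda) {
  S <- matrix(0, p, p)
  k <- 0
  for (b in blocks) {
    if (b$type == "fixed") next
    k <- k + 1
    S[b$cols, b$cols] <- S[b$cols, b$cols] + lambda[k] * b$S
  }
  S
}

binomial_deviance <- function(s, m, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  t1 <- ifelse(s > 0, s * log(s / (m * mu)), 0)
  t2 <- ifelse(m - s > 0, (m - s) * log((m - s) / (m * (1 - mu))), 0)
  2 * sum(t1 + t2)
}

#' Fit a binomial GAMM by penalized IRLS
#'
#' Logit-link binomial model for (successes, trials) pairs with
#' penalized-spline smooth terms, random intercepts, and an optional
#' observation-level random effect (OLRE) absorbing extra-binomial
#' variation.  Random intercepts are represented as ridge-penalized dummy
#' coefficient blocks (variance sigma^2 corresponds to ridge weight
#' 1/sigma^2).  Smoothing parameters and variance components are selected
#' by generalized Fellner-Schall updates of the Laplace/PQL-class marginal
#' criterion, interleaved with penalized IRLS for the coefficients; the
#' OLRE block is folded into the working weights by block elimination, so
#' the solved system stays small.  Inner iterations use step halving and
#' stop when the relative penalized-deviance change is below `1e-8`.
#'
#' @param successes,trials integer vectors (successes <= trials).
#' @param data data frame holding covariates.
#' @param fixed one-sided formula for the parametric part (default `~ 1`).
#' @param smooths list of [smooth_spec()] terms.
#' @param random character vector of random-intercept factor names.
#' @param olre logical: include an observation-level random intercept.
#' @param lambda optional named/numeric vector of fixed smoothing
#'   parameters (one per penalized block, OLRE last); when supplied the
#'   Fellner-Schall outer loop is skipped.
#' @param control list from `gam_control()`.
#' @return An object of class `rhythm_fit`: coefficients, block map,
#'   smoothing parameters (`lambda`), variance components (`sigma2`),
#'   posterior covariance `Vp` of the non-OLRE coefficients, linear
#'   predictor, fitted probabilities, working residuals, effective degrees
#'   of freedom and convergence diagnostics.
#' @export
fit_binomial_gam <- function(successes, trials, data, fixed = ~ 1,
                             smooths = list(), random = character(),
                             olre = FALSE, lambda = NULL,
                             control = gam_control()) {
  stopifnot(length(successes) == length(trials),
            all(successes >= 0), all(successes <= trials))
  keep <- trials > 0
  s <- successes[keep]
  m <- trials[keep]
  data <- data[keep, , drop = FALSE]
  n <- length(s)

  smooth_preps <- lapply(smooths, prepare_smooth, data = data)
  des <- build_design(data, fixed, smooth_preps, random)
  X <- des$X
  blocks <- des$blocks
  p <- ncol(X)
  pen_blocks <- Filter(function(b) b$type != "fixed", blocks)
  n_pen <- length(pen_blocks)

  n_lam <- n_pen + as.integer(olre)
  fixed_lambda <- !is.null(lambda)
  lam <- if (fixed_lambda) rep_len(lambda, n_lam) else rep(1, n_lam)
  lam_olre <- if (olre) lam[n_lam] else Inf

  pirls <- function(lam, beta0 = NULL) {
    lam_o <- if (olre) lam[n_lam] else Inf
    Spen <- penalty_matrix(blocks, p, lam)
    beta <- if (is.null(beta0)) rep(0, p) else beta0
    compute_state <- function(beta) {
      eta0 <- drop(X %*% beta)
      # one fixed-point pass for the OLRE contribution
      eta <- eta0
      u <- rep(0, n)
      if (olre) {
        for (it in 1:25) {
          mu <- pmin(pmax(stats::plogis(eta), 1e-10), 1 - 1e-10)
          w <- pmax(m * mu * (1 - mu), 1e-10)
          z <- eta + (s / m - mu) / (mu * (1 - mu))
          u_new <- w * (z - eta0) / (w + lam_o)
          if (max(abs(u_new - u)) < 1e-10) {
            u <- u_new
            break
          }
          u <- u_new
          eta <- eta0 + u
        }
        eta <- eta0 + u
      }
      mu <- pmin(pmax(stats::plogis(eta), 1e-10), 1 - 1e-10)
      pdev <- binomial_deviance(s, m, mu) +
        drop(t(beta) %*% Spen %*% beta) +
        if (olre) lam_o * sum(u^2) else 0
      list(beta = beta, eta0 = eta0, eta = eta, u = u, mu = mu, pdev = pdev)
    }
    st <- compute_state(beta)
    trace <- st$pdev
    conv <- FALSE
    for (iter in seq_len(control$max_pirls)) {
      mu <- st$mu
      w <- pmax(m * mu * (1 - mu), 1e-10)
      z <- st$eta + (s / m - mu) / (mu * (1 - mu))
      wt <- if (olre) w * lam_o / (w + lam_o) else w
      M <- crossprod(X, X * wt) + Spen
      beta_try <- drop(solve(M, crossprod(X, wt * z)))
      st_try <- compute_state(beta_try)
      halve <- 0
      while (st_try$pdev > st$pdev + 1e-12 && halve < 30) {
        beta_try <- (beta_try + st$beta) / 2
        st_try <- compute_state(beta_try)
        halve <- halve + 1
      }
      rel <- abs(st$pdev - st_try$pdev) / (abs(st$pdev) + 0.1)
      st <- st_try
      trace <- c(trace, st$pdev)
      if (rel < control$eps_dev) {
        conv <- TRUE
        break
      }
    }
    if (!conv) {
      stop(structure(class = c("gam_no_convergence", "error", "condition"),
                     list(message = paste0(
                       "penalized IRLS did not converge in ",
                       control$max_pirls, " iterations"),
                       call = sys.call(-1), trace = trace)))
    }
    mu <- st$mu
    w <- pmax(m * mu * (1 - mu), 1e-10)
    wt <- if (olre) w * lam_o / (w + lam_o) else w
    M <- crossprod(X, X * wt) + Spen
    c(st, list(M = M, w = w, wt = wt, trace = trace))
  }

  fit <- pirls(lam)
  outer_iter <- 0
  if (!fixed_lambda && n_lam > 0) {
    for (outer_iter in seq_len(control$max_outer)) {
      Minv <- solve(fit$M)
      lam_new <- lam
      k <- 0
      for (b in pen_blocks) {
        k <- k + 1
        tr_pinv <- b$rank / lam[k]
        tr_H <- sum(Minv[b$cols, b$cols] * t(b$S))
        bsb <- drop(t(fit$beta[b$cols]) %*% b$S %*% fit$beta[b$cols])
        num <- max(tr_pinv - tr_H, 1e-10)
        lam_new[k] <- min(max(lam[k] * num / max(bsb, 1e-10),
                              control$lambda_min), control$lambda_max)
      }
      if (olre) {
        lam_o <- lam[n_lam]
        d <- 1 / (fit$w + lam_o)
        A <- X * (fit$w * d)            # D^{-1} W X
        tr_H <- sum(d) + sum(A * t(solve(fit$M, t(A))))
        num <- max(n / lam_o - tr_H, 1e-10)
        lam_new[n_lam] <- min(max(lam_o * num / max(sum(fit$u^2), 1e-10),
                                  control$lambda_min), control$lambda_max)
      }
      step <- max(abs(log(lam_new) - log(lam)))
      lam <- lam_new
      fit <- pirls(lam, beta0 = fit$beta)
      if (step < control$tol_outer) break
    }
  }

  if (max(abs(fit$eta0)) > 25) {
    warning("very large linear predictor: possible complete separation; ",
            "estimates are penalized")
  }

  Vp <- solve(fit$M)
  coefs <- fit$beta
  names(coefs) <- colnames(X)
  lam_named <- lam
  labs <- vapply(pen_blocks, `[[`, "", "label")
  names(lam_named) <- c(labs, if (olre) "olre")
  sigma2 <- 1 / lam_named[grepl("^re\\(", names(lam_named)) |
                            names(lam_named) == "olre"]

  structure(list(
    coefficients = coefs, blocks = blocks, lambda = lam_named,
    sigma2 = sigma2, Vp = Vp, X = X,
    smooth_preps = smooth_preps, fixed = fixed, random = random,
    olre = olre, olre_effects = fit$u,
    linear_predictor = fit$eta, eta_coef = fit$eta0,
    fitted = fit$mu, successes = s, trials = m,
    working_residuals = (s / m - fit$mu) / (fit$mu * (1 - fit$mu)),
    edf = sum(Vp * t(fit$M - penalty_matrix(blocks, p, lam))),
    deviance = binomial_deviance(s, m, fit$mu),
    pdev_trace = fit$trace, outer_iterations = outer_iter,
    data = data
  ), class = "rhythm_fit")
}

#' @export
print.rhythm_fit <- function(x, ...) {
  cat("<rhythm_fit> binomial GAMM, ", length(x$successes), " obs, edf ",
      round(x$edf, 1), "\n  lambda: ",
      paste(sprintf("%s=%.3g", names(x$lambda), x$lambda), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Wald test of a fixed-effect coefficient
#'
#' Estimate and standard error from the penalized information matrix,
#' z = estimate / SE, two-sided normal p-value.
#'
#' @param fit a `rhythm_fit`.
#' @param term coefficient name (a column of the fixed design), e.g.
#'   `"statusresident"`.
#' @return one-row tibble: `term`, `estimate`, `se`, `z`, `p`.
#' @export
wald_fixed_effect <- function(fit, term) {
  i <- match(term, names(fit$coefficients))
  if (is.na(i)) {
    stop("no coefficient '", term, "'; available: ",
         paste(names(fit$coefficients)[fit$blocks[[1]]$cols], collapse = ", "))
  }
  est <- fit$coefficients[[i]]
  se <- sqrt(fit$Vp[i, i])
  z <- est / se
  tibble::tibble(term = term, estimate = est, se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)))
}

#' Predicted activity curve with pointwise 95% CI
#'
#' Population-level prediction (fixed effects + smooths; random-intercept
#' and OLRE blocks set to their zero mean): linear predictor +/- 1.96 SE,
#' inverse-linked to the response scale, so the CI bounds always lie
#' between 0 and 1.
#'
#' @param fit a `rhythm_fit`.
#' @param newdata data frame with the covariates used by the fixed part and
#'   the smooths.
#' @return tibble: `newdata` columns plus `eta`, `se_eta`, `fit`, `lower`,
#'   `upper`.
#' @export
predict_curve <- function(fit, newdata) {
  Xf <- stats::model.matrix(fit$fixed, newdata)
  Xs <- list(Xf)
  for (prep in fit$smooth_preps) {
    Xb <- eval_smooth_base(prep, newdata)
    if (is.null(prep$levels_by)) {
      Xs[[length(Xs) + 1L]] <- Xb
    } else {
      f <- factor(newdata[[prep$spec$by]], levels = prep$levels_by)
      for (lev in prep$levels_by) {
        Xs[[length(Xs) + 1L]] <- Xb * as.numeric(f == lev)
      }
    }
  }
  Xn <- do.call(cbind, Xs)
  pcols <- seq_len(ncol(Xn))
  eta <- drop(Xn %*% fit$coefficients[pcols])
  V <- fit$Vp[pcols, pcols, drop = FALSE]
  se <- sqrt(pmax(rowSums((Xn %*% V) * Xn), 0))
  dplyr::bind_cols(
    tibble::as_tibble(newdata),
    tibble::tibble(eta = eta, se_eta = se,
                   fit = stats::plogis(eta),
                   lower = stats::plogis(eta - 1.96 * se),
                   upper = stats::plogis(eta + 1.96 * se))
  )
}
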