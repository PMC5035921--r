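test_that("a known sinusoidal rhythm is recovered on the logit scale", {
  grid <- data.frame(tod = seq(0, 23.5, by = 0.5))
  truth_eta <- -3 + 2.5 * sin(2 * pi * grid$tod / 24)
  coverage <- rmse <- numeric(3)
  for (r in 1:3) {
    set.seed(6 + r)
    tod <- rep(seq(0, 23.5, by = 0.5), times = 20 * 7)
    bird <- rep(sprintf("b%02d", 1:20), each = 48 * 7)
    eta_true <- -3 + 2.5 * sin(2 * pi * tod / 24)
    m <- rep(30L, length(tod))
    s <- rbinom(length(tod), m, plogis(eta_true))
    df <- data.frame(tod = tod, bird_id = bird)
    fit <- fit_binomial_gam(s, m, df, fixed = ~ 1,
                            smooths = list(smooth_spec("tod", "cc", k = 10)),
                            random = "bird_id", olre = TRUE)
    pr <- predict_curve(fit, grid)
    rmse[r] <- sqrt(mean((pr$eta - truth_eta)^2))
    coverage[r] <- mean(plogis(truth_eta) >= pr$lower &
                          plogis(truth_eta) <= pr$upper)
    if (r == 1) {
      # CI bounds live on the probability scale
      expect_true(all(pr$lower >= 0 & pr$upper <= 1))
      # prediction at observed design points equals fitted values (no REs
      # here: bird variance shrinks to ~0 because none was generated)
      pr_obs <- predict_curve(fit, df[1:48, , drop = FALSE])
      expect_lt(max(abs(pr_obs$fit - fit$fitted[1:48])), 0.02)
    }
  }
  expect_lt(max(rmse), 0.15)
  # mean pointwise 95% CI coverage of the true curve across replicates
  expect_gte(mean(coverage), 0.90)
})

test_that("constant truth shrinks the smooth to a flat line", {
  set.seed(15)
  tod <- rep(seq(0, 23.5, by = 0.5), times = 30)
  m <- rep(30L, length(tod))
  s <- rbinom(length(tod), m, 0.3)
  fit <- fit_binomial_gam(s, m, data.frame(tod = tod),
                          smooths = list(smooth_spec("tod", "cc", k = 10)))
  icpt <- fit$coefficients[1]
  se <- sqrt(fit$Vp[1, 1])
  expect_lt(abs(icpt - qlogis(0.3)), 3 * se + 0.05)
  # fitted probabilities hug the overall mean
  expect_lt(diff(range(fit$fitted)), 0.05)
})

test_that("heavy smoothing collapses the cyclic smooth to its null space", {
  set.seed(20)
  tod <- rep(seq(0, 23.5, by = 0.5), times = 10)
  m <- rep(30L, length(tod))
  s <- rbinom(length(tod), m, plogis(-1 + sin(2 * pi * tod / 24)))
  fit <- fit_binomial_gam(s, m, data.frame(tod = tod),
                          smooths = list(smooth_spec("tod", "cc", k = 8)),
                          lambda = 1e9)
  expect_lt(diff(range(fit$fitted)), 0.01)
  expect_equal(mean(fit$fitted), sum(s) / sum(m), tolerance = 0.01)
})

test_that("penalized deviance is non-increasing across accepted IRLS steps", {
  set.seed(33)
  tod <- rep(seq(0, 23.5, by = 0.5), times = 6)
  m <- rep(30L, length(tod))
  s <- rbinom(length(tod), m, plogis(-2 + 1.5 * sin(2 * pi * tod / 24)))
  fit <- fit_binomial_gam(s, m, data.frame(tod = tod),
                          smooths = list(smooth_spec("tod", "cc", k = 8)),
                          lambda = 5)
  expect_true(all(diff(fit$pdev_trace) <= 1e-8))
})

test_that("OLRE variance collapses when the data are exactly binomial", {
  set.seed(40)
  tod <- rep(seq(0, 23.5, by = 0.5), times = 12)
  m <- rep(30L, length(tod))
  s <- rbinom(length(tod), m, plogis(-1.5 + sin(2 * pi * tod / 24)))
  fit <- fit_binomial_gam(s, m, data.frame(tod = tod),
                          smooths = list(smooth_spec("tod", "cc", k = 8)),
                          olre = TRUE)
  expect_lt(fit$sigma2[["olre"]], 0.02)
})

test_that("random intercepts centre to about zero and absorb bird effects", {
  set.seed(50)
  nb <- 16
  tod <- rep(seq(0, 23.5, by = 0.5), times = nb)
  bird <- rep(sprintf("b%02d", 1:nb), each = 48)
  re <- rnorm(nb, 0, 0.8)
  m <- rep(30L, length(tod))
  s <- rbinom(length(tod), m,
              plogis(-1 + sin(2 * pi * tod / 24) + re[match(bird, sprintf("b%02d", 1:nb))]))
  fit <- fit_binomial_gam(s, m, data.frame(tod = tod, bird_id = bird),
                          smooths = list(smooth_spec("tod", "cc", k = 8)),
                          random = "bird_id")
  reblk <- Filter(function(b) b$label == "re(bird_id)", fit$blocks)[[1]]
  u <- fit$coefficients[reblk$cols]
  expect_lt(abs(mean(u)), 0.15)
  expect_gt(cor(u, re), 0.8)
  expect_gt(fit$sigma2[["re(bird_id)"]], 0.1)
})

test_that("fits agree with mgcv as an independent cross-check", {
  set.seed(60)
  tod <- rep(seq(0, 23.5, by = 0.5), times = 8)
  m <- rep(30L, length(tod))
  s <- rbinom(length(tod), m, plogis(-1.2 + 1.7 * sin(2 * pi * tod / 24)))
  df <- data.frame(tod = tod)
  fit <- fit_binomial_gam(s, m, df,
                          smooths = list(smooth_spec("tod", "cc", k = 10)))
  gm <- mgcv::gam(cbind(s, m - s) ~ s(tod, bs = "cc", k = 10),
                  family = stats::binomial(),
                  knots = list(tod = seq(0, 24, length.out = 10)),
                  data = df, method = "REML")
  expect_lt(max(abs(fit$fitted - stats::fitted(gm))), 0.02)
})

test_that("Wald tests reproduce the printed-statistic arithmetic", {
  # the published daily-model triple: -0.2088 / 0.1228 -> z = -1.70
  z <- -0.2088 / 0.1228
  expect_equal(round(z, 2), -1.70)
  p_normal <- 2 * pnorm(-abs(z))
  p_erfc <- pracma::erfc(abs(z) / sqrt(2))
  expect_equal(p_normal, p_erfc, tolerance = 1e-12)
  # on a fitted model: z = estimate / SE and two-sided normal p
  set.seed(70)
  tod <- rep(seq(0, 23.5, by = 0.5), times = 8)
  grp <- rep(c("migrant", "resident"), each = length(tod) / 2)
  m <- rep(30L, length(tod))
  s <- rbinom(length(tod), m, plogis(-1 + 0.5 * (grp == "resident")))
  fit <- fit_binomial_gam(s, m, data.frame(tod = tod, status = factor(grp)),
                          fixed = ~ status,
                          smooths = list(smooth_spec("tod", "cc", k = 6)))
  w <- wald_fixed_effect(fit, "statusresident")
  expect_equal(w$z, w$estimate / w$se)
  expect_equal(w$p, 2 * pnorm(-abs(w$z)))
  expect_error(wald_fixed_effect(fit, "nope"), "no coefficient")
})
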