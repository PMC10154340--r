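# -- OLS ---------------------------------------------------------------------

test_that("an exactly linear outcome is fit with zero residuals and R^2 = 1", {
  tm <- tidyr::expand_grid(
    mode = c("synchronized", "syncopated"),
    phase = c("pacing", "continuation"),
    design = c("blocked", "alternating"),
    rep = 1:3
  )
  tm$value_ms <- -30 + 10 * (tm$mode == "syncopated") +
    50 * (tm$phase == "continuation") + 20 * (tm$design == "alternating")
  fit <- fit_ols(regression_input(tm, interactions = FALSE))
  expect_equal(unname(residuals(fit$fit)), rep(0, nrow(tm)), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  est <- fit$coefficients$estimate
  names(est) <- fit$coefficients$term
  expect_equal(unname(est["phasecontinuation"]), 50)
  expect_equal(unname(est["designalternating"]), 20)
})

test_that("an intercept-only fit returns the outcome mean", {
  y <- c(3, 1, 4, 1, 5)
  fit <- fit_ols(list(
    data = data.frame(value_ms = y),
    formula = value_ms ~ 1
  ))
  expect_equal(fit$coefficients$estimate, mean(y))
})

test_that("coefficients agree with a hand normal-equations solve on a toy set", {
  # 6 points, intercept + 2 predictors
  X <- cbind(1, c(0, 1, 2, 3, 4, 5), c(1, 0, 1, 0, 1, 0))
  y <- c(1.2, 2.1, 2.8, 4.4, 4.9, 6.3)
  beta_hand <- solve(t(X) %*% X, t(X) %*% y) # normal equations, by hand
  dat <- data.frame(value_ms = y, x1 = X[, 2], x2 = X[, 3])
  fit <- fit_ols(list(data = dat, formula = value_ms ~ x1 + x2))
  expect_equal(fit$coefficients$estimate, as.numeric(beta_hand), tolerance = 1e-10)
  # SEs from unbiased residual variance, also by hand
  res <- y - X %*% beta_hand
  s2 <- sum(res^2) / (6 - 3)
  se_hand <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(fit$coefficients$se, unname(se_hand), tolerance = 1e-10)
})

test_that("rank-deficient inputs raise an error naming the collinear column", {
  dat <- data.frame(value_ms = rnorm(6), x1 = 1:6, x2 = 2 * (1:6))
  expect_error(
    fit_ols(list(data = dat, formula = value_ms ~ x1 + x2)),
    "rank deficient.*x2"
  )
})

test_that("residuals are orthogonal to the design and R^2 equals cor^2", {
  set.seed(14)
  tm <- tidyr::expand_grid(
    mode = c("synchronized", "syncopated"),
    phase = c("pacing", "continuation"),
    design = c("blocked", "alternating"),
    rep = 1:5
  )
  tm$value_ms <- rnorm(nrow(tm), sd = 20) + 30 * (tm$phase == "continuation")
  fit <- fit_ols(regression_input(tm))
  X <- model.matrix(fit$fit)
  expect_lt(max(abs(crossprod(X, residuals(fit$fit)))), 1e-8)
  expect_equal(fit$r_squared, cor(tm$value_ms, fitted(fit$fit))^2)
})

# -- effect table ------------------------------------------------------------

test_that("effect F and partial eta^2 are invariant to outcome rescaling", {
  set.seed(3)
  tm <- tidyr::expand_grid(
    mode = c("synchronized", "syncopated"),
    phase = c("pacing", "continuation"),
    design = c("blocked", "alternating"),
    rep = 1:4
  )
  tm$value_ms <- rnorm(nrow(tm)) + (tm$phase == "continuation")
  t1 <- effect_table(fit_ols(regression_input(tm)))
  tm2 <- dplyr::mutate(tm, value_ms = 2 * value_ms)
  t2 <- effect_table(fit_ols(regression_input(tm2)))
  expect_equal(t1$f, t2$f)
  expect_equal(t1$partial_eta_sq, t2$partial_eta_sq)
  expect_equal(t2$sum_sq, 4 * t1$sum_sq)
})

test_that("the single-factor two-group F equals the squared pooled t", {
  set.seed(21)
  g <- rep(c("pacing", "continuation"), each = 8)
  y <- rnorm(16) + 0.8 * (g == "continuation")
  tm <- tibble::tibble(
    mode = "synchronized", design = "blocked", phase = g, value_ms = y
  )
  fit <- fit_ols(regression_input(tm, interactions = FALSE))
  tab <- effect_table(fit)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(tab$f[tab$term == "phase"], unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("a null factor's empirical type-I error is near alpha", {
  set.seed(77)
  reps <- 400
  p_mode <- replicate(reps, {
    tm <- tidyr::expand_grid(
      mode = c("synchronized", "syncopated"),
      phase = c("pacing", "continuation"),
      design = c("blocked", "alternating"),
      rep = 1:4
    )
    # phase has a real effect; mode has none
    tm$value_ms <- rnorm(nrow(tm)) + 1.5 * (tm$phase == "continuation")
    tab <- effect_table(fit_ols(regression_input(tm, interactions = FALSE)))
    tab$p[tab$term == "mode"]
  })
  rate <- mean(p_mode < 0.05)
  # binomial 3 SE band around 0.05 at 400 reps
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

# -- Tukey HSD ---------------------------------------------------------------

test_that("identical groups produce zero differences and no significance", {
  v <- rep(c(1, 2, 3), times = 3)
  g <- rep(c("a", "b", "c"), each = 3)
  tk <- tukey_hsd(v, g)
  expect_equal(tk$diff, rep(0, 3))
  expect_false(any(tk$significant))
})

test_that("the two-group Tukey decision matches the pooled t test (q = t*sqrt(2))", {
  set.seed(8)
  for (delta in c(0, 1.2)) {
    y <- c(rnorm(10), rnorm(10) + delta)
    g <- rep(c("a", "b"), each = 10)
    tk <- tukey_hsd(y, g, alpha = 0.05)
    tt <- t.test(y ~ g, var.equal = TRUE)
    expect_equal(tk$significant[1], tt$p.value < 0.05)
    expect_equal(tk$p_adj[1], tt$p.value, tolerance = 1e-8)
  }
})

test_that("the three-group critical value matches direct integration of the studentized range", {
  # P(Q_{k,df} <= q): integrate over the range of k standard normals and an
  # independent chi-scaled sd estimate
  ptukey_by_integration <- function(q, k, df) {
    inner <- function(s) {
      f_range <- function(z) {
        k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - q * s))^(k - 1)
      }
      stats::integrate(f_range, -Inf, Inf, rel.tol = 1e-9)$value
    }
    dens_s <- function(s) {
      # density of s = sd estimate / sigma with df degrees of freedom
      2 * (df / 2)^(df / 2) / gamma(df / 2) * s^(df - 1) * exp(-df * s^2 / 2)
    }
    stats::integrate(function(s) {
      vapply(s, function(si) dens_s(si) * inner(si), numeric(1))
    }, 0, Inf, rel.tol = 1e-8)$value
  }
  q_crit <- qtukey(0.95, nmeans = 3, df = 12)
  expect_equal(ptukey_by_integration(q_crit, 3, 12), 0.95, tolerance = 1e-5)

  # and the critical value governs the significance flags
  set.seed(5)
  y <- c(rnorm(5), rnorm(5) + 3, rnorm(5))
  g <- rep(c("a", "b", "c"), each = 5)
  tk <- tukey_hsd(y, g)
  expect_true(tk$significant[tk$contrast == "b-a"])
})

# -- power -------------------------------------------------------------------

test_that("power at zero effect size equals alpha", {
  expect_equal(posthoc_power(0, n = 23, predictors = 3, alpha = 0.05), 0.05)
  expect_equal(posthoc_power(0, n = 50, predictors = 5, alpha = 0.10), 0.10)
})

test_that("power increases strictly with sample size", {
  ns <- c(10, 15, 23, 40, 80, 200)
  p <- vapply(ns, function(n) posthoc_power(0.39, n), numeric(1))
  expect_true(all(diff(p) > 0))
  expect_error(posthoc_power(0.39, n = 4, predictors = 3), "exceed")
})

test_that("noncentral-F power matches Monte-Carlo regression simulation", {
  # Simulate the overall F test of a k-predictor regression whose systematic
  # part is scaled to Cohen's f exactly: ||X beta||^2 = f^2 * n * sigma^2.
  set.seed(2024)
  f <- 0.39
  n <- 23
  k <- 3
  reps <- 10000
  X <- qr.Q(qr(cbind(1, matrix(rnorm(n * k), n, k))))
  Xc <- sqrt(n) * X[, -1, drop = FALSE] # orthonormal * sqrt(n): unit columns
  beta <- rep(f / sqrt(k), k)
  mu <- Xc %*% beta # ||mu||^2 = f^2 * n
  crit <- qf(0.95, k, n - k - 1)
  hits <- replicate(reps, {
    y <- mu + rnorm(n)
    fit <- stats::lm.fit(cbind(1, Xc), y)
    rss1 <- sum(fit$residuals^2)
    rss0 <- sum((y - mean(y))^2)
    fstat <- ((rss0 - rss1) / k) / (rss1 / (n - k - 1))
    fstat > crit
  })
  p_mc <- mean(hits)
  p_theory <- posthoc_power(f, n, k)
  mc_se <- sqrt(p_theory * (1 - p_theory) / reps)
  expect_lt(abs(p_mc - p_theory), 2 * mc_se)
})

test_that("the phase coefficient recovers the planted continuation increase", {
  # Planted phase effect: mean continuation - pacing asynchrony = 5.5 * drift.
  drift <- 8.9
  p <- generator_params(continuation_drift = drift, miss_prob = 0, outlier_prob = 0)
  taps <- simulate_cohort(6, 0, params_block_group = p, seed = 17)
  prep <- preprocess_cohort(taps, "asynchrony", seed = 17)
  fit <- fit_ols(regression_input(prep$trial_means, interactions = FALSE))
  co <- fit$coefficients
  est <- co$estimate[co$term == "phasecontinuation"]
  se <- co$se[co$term == "phasecontinuation"]
  expect_lt(abs(est - 5.5 * drift), 3 * se)
})
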