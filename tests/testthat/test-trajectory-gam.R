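test_that("age basis is centered with a linear null space", {
  set.seed(21)
  ages <- runif(60, 5, 36)
  b <- build_age_basis(ages, k = 3)
  B <- age_basis_eval(b, ages)
  expect_identical(ncol(B), 2L)
  expect_lt(max(abs(colMeans(B))), 1e-12)       # constant absorbed by intercept
  S <- basis_penalty(b)
  expect_identical(S[1, 1], 0)                  # linear direction unpenalized
  expect_identical(S[2, 2], 1)
  # unpenalized least squares on [1, basis] reproduces any quadratic
  y <- 2 - 0.3 * ages + 0.01 * ages^2
  fitq <- lm.fit(cbind(1, B), y)
  expect_lt(max(abs(fitq$residuals)), 1e-6)
  expect_error(build_age_basis(c(1, 1, 2, 2), k = 3),
               class = "laminardev_invalid_parameter")
})

test_that("noiseless linear truth is recovered exactly", {
  set.seed(22)
  df <- data.frame(age = runif(100, 5, 36), sex = rep(c("F", "M"), 50))
  df$value <- 2 + 0.5 * df$age
  f <- fit_gam(df)
  expect_lt(max(abs(f$fitted - df$value)), 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  band <- derivative_band(f, seed = 1)
  expect_equal(unname(range(band$estimate)), c(0.5, 0.5), tolerance = 1e-8)
})

test_that("lambda extremes: collapse to the linear null space / OLS oracle", {
  set.seed(23)
  n <- 150
  df <- data.frame(age = runif(n, 5, 36), sex = sample(c("F", "M"), n, TRUE))
  df$value <- 1 + 0.02 * df$age + 0.002 * (df$age - 20)^2 + rnorm(n, 0, 0.05)
  # lambda -> infinity: penalized fit equals OLS on intercept+sex+linear
  f_inf <- fit_gam(df, lambda_grid = 14)
  ols_lin <- lm(value ~ sex + age, df)
  expect_equal(unname(f_inf$fitted), unname(fitted(ols_lin)), tolerance = 1e-6)
  # lambda = 0: equals unpenalized normal-equations solve on the full basis
  f0 <- fit_gam(df, lambda_grid = -300)
  b <- build_age_basis(df$age, 3)
  X <- cbind(1, df$sex == "M", age_basis_eval(b, df$age))
  beta_ne <- solve(crossprod(X), crossprod(X, df$value))
  expect_equal(unname(f0$coefficients), drop(beta_ne), tolerance = 1e-8)
})

test_that("REML smoothing matches mgcv on shared data", {
  skip_if_not_installed("mgcv")
  set.seed(24)
  for (i in 1:3) {
    n <- 150
    df <- data.frame(age = runif(n, 5, 36),
                     sex = factor(sample(c("F", "M"), n, TRUE)))
    df$value <- 1.2 + 0.3 * (1 - exp(-0.15 * (df$age - 4))) +
      0.02 * (df$sex == "M") + rnorm(n, 0, 0.05)
    f <- fit_gam(df)
    g <- mgcv::gam(value ~ sex + s(age, k = 3), data = df, method = "REML")
    expect_equal(unname(f$fitted), unname(fitted(g)), tolerance = 5e-3)
    expect_equal(f$edf, sum(g$edf), tolerance = 0.15)
  }
})

test_that("flat truth yields near-zero mean slope and honest significance", {
  set.seed(25)
  slopes <- replicate(30, {
    df <- flat_data(200)
    mean(derivative_band(fit_gam(df), seed = 3)$estimate)
  })
  expect_lt(abs(mean(slopes)), 5e-4)
  # strong linear signal: tiny p
  df <- flat_data(500, sigma = 0.01)
  df$value <- df$value + 0.02 * df$age
  full <- fit_gam(df); red <- fit_gam(df, include_age = FALSE)
  expect_lt(age_significance(full, red), 1e-10)
  expect_lt(age_significance(full, red, method = "deviance"), 1e-10)
  # y ignoring age entirely: wald p = 1 in the exact-zero case
  df0 <- data.frame(age = 1:20, sex = rep(c("F", "M"), 10),
                    value = rep(c(1, 2), 10))
  f0 <- fit_gam(df0); r0 <- fit_gam(df0, include_age = FALSE)
  expect_equal(age_significance(f0, r0), 1, tolerance = 1e-6)
  expect_error(age_significance(red, full), class = "laminardev_invalid_parameter")
})

test_that("signed partial R2 has the right magnitude and sign", {
  set.seed(26)
  df <- data.frame(age = runif(200, 5, 36), sex = rep(c("F", "M"), 100))
  # noiseless monotone quadratic (exactly representable at k = 3)
  df$value <- 1 + 0.02 * df$age - 2e-4 * df$age^2
  full <- fit_gam(df); red <- fit_gam(df, include_age = FALSE)
  band <- derivative_band(full, seed = 4)
  expect_gt(partial_r2_signed(full, red, band), 0.999)  # noiseless increasing
  df$value <- 2 - 0.05 * df$age                          # decreasing
  full <- fit_gam(df); red <- fit_gam(df, include_age = FALSE)
  band <- derivative_band(full, seed = 4)
  expect_equal(partial_r2_signed(full, red, band), -1, tolerance = 1e-6)
  # flat truth: small magnitude
  dff <- flat_data(200)
  fullf <- fit_gam(dff); redf <- fit_gam(dff, include_age = FALSE)
  expect_lt(abs(partial_r2_signed(fullf, redf, derivative_band(fullf, seed = 5))),
            0.1)
})

test_that("derivative bands are simultaneous, deterministic, and accurate", {
  set.seed(27)
  n <- 400
  df <- data.frame(age = runif(n, 5, 36), sex = sample(c("F", "M"), n, TRUE))
  df$value <- 1 + 0.01 * df$age + rnorm(n, 0, 0.05)
  f <- fit_gam(df)
  b1 <- derivative_band(f, seed = 9)
  b2 <- derivative_band(f, seed = 9)
  expect_identical(b1$lower, b2$lower)
  # simultaneous dominates pointwise (up to Monte Carlo quantile noise)
  expect_gte(b1$crit, qnorm(0.975) - 0.05)
  expect_true(all(b1$lower <= b1$estimate & b1$estimate <= b1$upper))
  # estimate near the true constant slope (3 SE tolerance)
  mid <- 25:75
  expect_true(all(abs(b1$estimate[mid] - 0.01) <= 3 * b1$se[mid] + 1e-9))
  expect_error(derivative_band(fit_gam(df, include_age = FALSE)),
               class = "laminardev_invalid_parameter")
})

test_that("plateau rule follows the positive-growth window semantics", {
  g <- seq(5, 36, length.out = 32)
  # growth significant on [5, 15], then indistinguishable from zero
  est <- ifelse(g <= 15, 0.05, 0.001)
  b <- fake_band(g, est, half_width = 0.01)
  pl <- plateau_age(b)
  expect_true(pl$plateau_reached)
  expect_equal(pl$plateau_age, max(g[g <= 15]))
  # significant through the final grid point: right-censored
  b2 <- fake_band(g, rep(0.05, 32), half_width = 0.01)
  pl2 <- plateau_age(b2)
  expect_false(pl2$plateau_reached)
  expect_true(is.na(pl2$plateau_age))
  expect_identical(nrow(pl2$windows), 1L)
  # never significant: no windows at all
  pl3 <- plateau_age(fake_band(g, rep(0.001, 32), half_width = 0.01))
  expect_false(pl3$plateau_reached)
  expect_identical(nrow(pl3$windows), 0L)
  # late significant *decline* is reported as a window but does not censor
  est4 <- ifelse(g <= 15, 0.05, ifelse(g >= 30, -0.05, 0.001))
  pl4 <- plateau_age(fake_band(g, est4, half_width = 0.01))
  expect_true(pl4$plateau_reached)
  expect_equal(pl4$plateau_age, max(g[g <= 15]))
  expect_identical(sort(unique(pl4$windows$sign)), c(-1L, 1L))
})

test_that("BH adjustment matches its brute-force definition", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(0.37), 0.37)
  set.seed(28)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    expect_equal(fdr_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  p_na <- c(0.01, NA, 0.5)
  q <- fdr_adjust(p_na)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_oracle(p_na[c(1, 3)]))
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "laminardev_invalid_parameter")
})

test_that("subject-intercept variance is recovered in longitudinal fits", {
  set.seed(29)
  est <- replicate(2, {
    ns <- 50; tp <- 5; sb <- 0.08
    subj <- rep(seq_len(ns), each = tp)
    df <- data.frame(
      subject_id = subj,
      age = as.vector(replicate(ns, seq(0.1, 3, length.out = tp))),
      sex = rep(sample(c("F", "M"), ns, TRUE), each = tp))
    df$value <- 1.2 + 0.3 * (1 - exp(-1.0 * df$age)) + 0.02 * (df$sex == "M") +
      rnorm(ns, 0, sb)[subj] + rnorm(ns * tp, 0, 0.05)
    fit_gam(df, random_intercept = "subject")$sigma_b2
  })
  expect_true(all(est > 0.0064 * 0.5 & est < 0.0064 * 1.8))
})

test_that("fit_trajectories returns complete, reproducible results", {
  tr <- structured_truth(1:4, c(0, 0.33, 0.67, 1), n_depth_bins = 2,
                         timescale = "human", sigma = 0.04)
  des <- study_design("cross_sectional", 60, c(5.5, 36), seed = 12)
  tab <- generate_dataset(des, tr)
  res <- fit_trajectories(tab, n_sim = 2000, seed = 7, keep_bands = TRUE)
  expect_identical(nrow(res), 8L)
  expect_true(all(abs(res$partial_r2) <= 1))
  expect_true(all(res$p_age >= 0 & res$p_age <= 1))
  expect_true(all(is.na(res$plateau_age) | !res$plateau_reached |
                  (res$plateau_age >= 5.5 & res$plateau_age <= 36)))
  expect_true(all(!res$plateau_reached | !is.na(res$plateau_age)))
  expect_length(attr(res, "bands"), 8L)
  # q-values adjusted within depth bin
  for (b in unique(res$depth_bin))
    expect_equal(res$q_age[res$depth_bin == b],
                 fdr_adjust(res$p_age[res$depth_bin == b]))
  res2 <- fit_trajectories(tab, n_sim = 2000, seed = 7)
  expect_equal(as.data.frame(res)[names(as.data.frame(res2))],
               as.data.frame(res2), ignore_attr = TRUE)
})
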