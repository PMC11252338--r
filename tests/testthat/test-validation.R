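test_that("r_squared has the right fixed points and rejects constant obs", {
  obs <- c(1, 2, 3, 4)
  expect_equal(r_squared(obs, obs), 1.0)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0.0)
  expect_error(r_squared(rep(2, 4), obs), "constant")
  expect_error(r_squared(1:3, 1:4), "equal length")
})

test_that("adjusted R2 is exact algebra", {
  expect_equal(r_squared_adjusted(0.722, 27, 5), 0.656, tolerance = 5e-4)
  expect_equal(r_squared_adjusted(1.0, 27, 5), 1.0)
  expect_equal(r_squared_adjusted(0.0, 27, 5), -5 / 21)
  expect_error(r_squared_adjusted(0.5, 6, 5), "n > p")
})

test_that("mse matches an elementwise summation oracle", {
  expect_equal(mse(c(1, 2, 3, 4), c(1, 2, 3, 4), 1), 0)
  set.seed(3)
  obs <- rnorm(20); pred <- obs + rnorm(20, 0, 0.1)
  rss <- 0
  for (i in seq_along(obs)) rss <- rss + (obs[i] - pred[i])^2
  expect_equal(mse(obs, pred, 4), rss / (20 - 4 - 1), tolerance = 1e-12)
  expect_equal(mse(obs, pred, 4, method = "n"), rss / 20, tolerance = 1e-12)
  expect_error(mse(obs[1:5], pred[1:5], 4), "degrees of freedom")
})

test_that("F statistic equals the classical SSreg/RSS form", {
  obs <- c(3.1, 3.9, 4.2, 4.8, 5.3, 5.9, 6.4)
  pred <- c(3.0, 4.1, 4.1, 4.9, 5.5, 5.8, 6.2)
  p <- 2
  n <- length(obs)
  ssreg <- sum((pred - mean(pred))^2)
  rss <- sum((obs - pred)^2)
  expect_equal(f_statistic(obs, pred, p),
               (ssreg / p) / (rss / (n - p - 1)), tolerance = 1e-10)
  expect_equal(f_statistic(obs, rep(mean(obs), n), p), 0)
  expect_equal(f_statistic(obs, obs, p), Inf)
})

test_that("LOO Q2 matches an explicit lm refit loop and exact data gives 1", {
  ds <- toy_synthetic(seed = 21)
  q2 <- q2_loo(ds)
  tr <- qsar_subset(ds, "train")
  form <- stats::reformulate(ds$descriptors, response = "pic50_obs")
  press_pred <- vapply(seq_len(nrow(tr)), function(i) {
    f <- lm(form, data = tr[-i, ])
    unname(predict(f, tr[i, ]))
  }, numeric(1))
  q2_oracle <- 1 - sum((tr$pic50_obs - press_pred)^2) /
    sum((tr$pic50_obs - mean(tr$pic50_obs))^2)
  expect_equal(q2, q2_oracle, tolerance = 1e-10)
  expect_equal(q2_loo(toy_exact_dataset()), 1.0, tolerance = 1e-10)
})

test_that("external R2 modes: squared correlation vs the literal ratio", {
  obs <- c(4.4, 4.1, 4.0, 4.3, 3.9)
  expect_equal(r2_external(obs, obs), 1.0)
  tz <- triazinone_mcf7()
  te <- qsar_subset(tz$dataset, "test")
  # the literal ratio form is strongly negative on the study's test pairs,
  # which is why squared correlation is the primary mode
  expect_lt(r2_external(te$pic50_obs, te$pic50_pred_paper, "literal"), 0)
  expect_gt(r2_external(te$pic50_obs, te$pic50_pred_paper), 0.7)
  expect_error(r2_external(obs, rep(1, 5)), "constant")
})

test_that("through-origin slopes: scaling behaviour and Cauchy-Schwarz", {
  obs <- c(3.5, 4.1, 4.6, 5.0)
  expect_equal(unname(gt_slopes(obs, obs)), c(1, 1))
  expect_equal(unname(gt_slopes(obs, 2 * obs)), c(0.5, 2))
  set.seed(8)
  for (i in 1:20) {
    o <- runif(6, 3, 6); p <- o + rnorm(6, 0, 0.5)
    ks <- gt_slopes(o, p)
    expect_lte(ks[["k"]] * ks[["k_prime"]], 1 + 1e-12)
  }
  # equality iff proportional
  ks <- gt_slopes(obs, 3 * obs)
  expect_equal(ks[["k"]] * ks[["k_prime"]], 1, tolerance = 1e-12)
  expect_error(gt_slopes(c(0, 0), c(0, 0)), "all-zero")
})

test_that("R0^2 matches a brute-force through-origin regression oracle", {
  obs <- c(4.445, 4.113, 4.112, 4.251, 4.064)
  pred <- c(3.973, 4.257, 4.356, 3.924, 4.476)
  r0 <- gt_r0(obs, pred)
  # oracle: least-squares through the origin via lm(), then the residual
  # ratios of the printed definitions
  k_fit <- unname(coef(lm(obs ~ 0 + pred)))
  kp_fit <- unname(coef(lm(pred ~ 0 + obs)))
  r0_oracle <- 1 - sum((pred - k_fit * pred)^2) / sum((pred - mean(pred))^2)
  r0p_oracle <- 1 - sum((obs - kp_fit * obs)^2) / sum((obs - mean(obs))^2)
  expect_equal(r0[["r0_sq"]], r0_oracle, tolerance = 1e-10)
  expect_equal(r0[["r0_sq_prime"]], r0p_oracle, tolerance = 1e-10)
  expect_equal(unname(gt_r0(obs, obs)), c(1, 1))
})

test_that("rm2 metrics: fixed point, symmetry of the difference", {
  m <- rm2_metrics(0.7, 0.7, 0.65)
  expect_equal(m$rm2, 0.7)
  a <- rm2_metrics(0.7, 0.6, 0.65)
  b <- rm2_metrics(0.7, 0.65, 0.6)
  expect_equal(a$rm2_delta, b$rm2_delta)
  expect_equal(a$rm2_mean, b$rm2_mean)
  # absolute value keeps the metric real when r0 exceeds r2
  expect_true(is.finite(rm2_metrics(0.7, 0.99, 0.99)$rm2))
})

test_that("criteria verdicts implement the thresholds with strict bounds", {
  base <- list(R2 = 0.722, Q2_loo = 0.542, R2_test = 0.710,
               k = 0.996, k_prime = 0.997,
               R0_sq = 0.9936, R0_sq_prime = 0.9944,
               rm2_mean = 0.530, rm2_delta = 0.0005)
  verdicts <- gt_report(base)
  expect_true(attr(verdicts, "all_pass"))
  bad_k <- base; bad_k$k <- 1.5
  expect_false(gt_report(bad_k)[["k_in_band"]])
  boundary <- base; boundary$R2 <- 0.6
  expect_false(gt_report(boundary)[["r2_gt_0.6"]])
  incomplete <- base; incomplete$k <- NULL
  expect_error(gt_report(incomplete), "missing scalar")
})

test_that("validation metrics are invariant to row ordering", {
  tz <- triazinone_mcf7()
  fit <- fit_mlr(tz$dataset)
  rep1 <- validate_model(fit, tz$dataset)
  shuffled <- tz$dataset$data[rev(seq_len(nrow(tz$dataset$data))), ]
  ds2 <- qsar_dataset(shuffled, triazinone_descriptors)
  rep2 <- validate_model(fit_mlr(ds2), ds2)
  for (f in c("R2", "Q2_loo", "R2_test", "k", "k_prime", "rm2_mean")) {
    expect_equal(rep1[[f]], rep2[[f]], tolerance = 1e-10, label = f)
  }
})

test_that("training R2 of any OLS fit is in [0,1] and equals cor^2", {
  for (seed in c(2, 4, 6)) {
    ds <- toy_synthetic(seed = seed)
    fit <- fit_mlr(ds)
    tr <- qsar_subset(ds, "train")
    pred <- predict(fit, tr)
    r2 <- r_squared(tr$pic50_obs, pred)
    expect_gte(r2, 0); expect_lte(r2, 1)
    expect_equal(r2, cor(tr$pic50_obs, pred)^2, tolerance = 1e-10)
    # cross-validation pessimism
    expect_lte(q2_loo(ds), r2)
  }
  tz <- triazinone_mcf7()
  fit <- fit_mlr(tz$dataset)
  tr <- qsar_subset(tz$dataset, "train")
  expect_lte(q2_loo(tz$dataset),
             r_squared(tr$pic50_obs, predict(fit, tr)))
})
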