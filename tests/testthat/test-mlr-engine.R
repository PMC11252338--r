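test_that("exact linear data is interpolated to machine precision", {
  ds <- toy_exact_dataset()
  fit <- fit_mlr(ds)
  expect_equal(unname(coef(fit)), c(1, 2, -0.5), tolerance = 1e-10)
  expect_equal(predict(fit, ds$data), ds$data$pic50_obs, tolerance = 1e-10)
})

test_that("QR solution matches the explicit normal-equations oracle", {
  ds <- toy_synthetic(seed = 11)
  fit <- fit_mlr(ds)
  tr <- qsar_subset(ds, "train")
  X <- cbind(1, as.matrix(tr[, ds$descriptors]))
  beta_ne <- solve(t(X) %*% X, t(X) %*% tr$pic50_obs)
  expect_equal(unname(coef(fit)), unname(drop(beta_ne)), tolerance = 1e-8)
  # normal-equation consequences: zero-mean residuals, orthogonal to design
  res <- tr$pic50_obs - predict(fit, tr)
  expect_equal(mean(predict(fit, tr)), mean(tr$pic50_obs), tolerance = 1e-10)
  # orthogonality scaled by each column's norm (TE is ~1e4 in magnitude)
  expect_lt(max(abs(drop(crossprod(X, res))) / colSums(X^2)), 1e-12)
})

test_that("rank deficiency is a named error, not a silent drop", {
  ds <- toy_exact_dataset()
  ds$data$a_copy <- ds$data$a
  ds2 <- qsar_dataset(ds$data, c("a", "b", "a_copy"))
  expect_error(fit_mlr(ds2), "collinear.*a_copy")
})

test_that("prediction is the affine form and names missing descriptors", {
  model <- triazinone_published_model()
  zero <- data.frame(chi = 0, TE = 0, NHD = 0, LogS = 0, I_shape = 0)
  expect_equal(predict(model, zero), -10.12)
  tz <- triazinone_mcf7()
  pred1 <- tz$candidates[tz$candidates$label == "Pred1", ]
  expect_equal(round(predict(model, pred1), 2), 5.56)
  pred13 <- tz$candidates[tz$candidates$label == "Pred13", ]
  expect_equal(predict(model, pred13), 5.97, tolerance = 0.01 / 5.97)
  expect_error(predict(model, pred1[, -which(names(pred1) == "TE")]),
               "missing descriptor.*TE")
})

test_that("VIF equals its brute-force definition and handles edge cases", {
  # mutually orthogonal centered columns -> exactly 1
  orth <- toy_orthogonal_dataset()
  expect_equal(unname(vif(orth)), rep(1, 3), tolerance = 1e-12)
  # definition oracle on the study data: 1/(1 - R_j^2) by explicit lm loop
  tz <- triazinone_mcf7()
  v <- vif(tz$dataset)
  tr <- qsar_subset(tz$dataset, "train")
  for (d in triazinone_descriptors) {
    others <- setdiff(triazinone_descriptors, d)
    f <- lm(stats::reformulate(others, response = d), data = tr)
    expect_equal(unname(v[d]), 1 / (1 - summary(f)$r.squared),
                 tolerance = 1e-8, label = d)
  }
  # perfect collinearity -> infinite VIF, not an error
  dup <- tr
  dup$chi2 <- dup$chi
  ds2 <- qsar_dataset(dup, c("chi", "chi2", "TE"))
  expect_true(is.infinite(vif(ds2)[["chi"]]))
})

test_that("backward elimination keeps informative descriptors, drops noise", {
  ds <- simulate_qsar(generator_config(
    n_train = 100, n_test = 10, nuisance_descriptors = 5,
    nuisance_rho = 0.5, seed = 5
  ))
  model <- backward_eliminate(ds, ds$descriptors)
  expect_true(all(c("chi", "TE", "NHD", "LogS", "I_shape") %in%
                    model$descriptors))
  expect_true(length(model$removal_log) >= 1)
})

test_that("elimination with inactive thresholds returns the full model", {
  tz <- triazinone_mcf7()
  model <- backward_eliminate(tz$dataset, alpha = 1, vif_cap = Inf)
  expect_identical(model$descriptors, triazinone_descriptors)
  expect_length(model$removal_log, 0)
})

test_that("a single informative descriptor among noise survives alone", {
  set.seed(9)
  n <- 300
  df <- data.frame(
    label = sprintf("n%03d", 1:n), subset = "train",
    x = runif(n), z1 = rnorm(n), z2 = rnorm(n), z3 = rnorm(n)
  )
  df$pic50_obs <- 2 + 3 * df$x + rnorm(n, 0, 0.3)
  ds <- qsar_dataset(df, c("x", "z1", "z2", "z3"))
  model <- backward_eliminate(ds)
  expect_identical(model$descriptors, "x")
})

test_that("scale equivariance: rescaling a column rescales its slope only", {
  ds <- toy_synthetic(seed = 13)
  fit1 <- fit_mlr(ds)
  scaled <- ds$data
  scaled$chi <- scaled$chi * 100
  ds2 <- qsar_dataset(scaled, ds$descriptors)
  fit2 <- fit_mlr(ds2)
  expect_equal(fit2$slopes[["chi"]], fit1$slopes[["chi"]] / 100,
               tolerance = 1e-8)
  expect_equal(predict(fit2, ds2$data), predict(fit1, ds$data),
               tolerance = 1e-8)
})

test_that("refitting one-descriptor model on its own predictions is identity", {
  ds <- toy_exact_dataset()
  sub <- qsar_dataset(ds$data, "a")
  fit <- fit_mlr(sub)
  refit_df <- sub$data
  refit_df$pic50_obs <- predict(fit, sub$data)
  sub2 <- qsar_dataset(refit_df, "a")
  # regress predictions on original predictions' descriptor, then on itself
  d3 <- data.frame(label = refit_df$label, subset = refit_df$subset,
                   a = predict(fit, sub$data),
                   pic50_obs = refit_df$pic50_obs)
  fit3 <- fit_mlr(qsar_dataset(d3, "a"))
  expect_equal(unname(coef(fit3)), c(0, 1), tolerance = 1e-8)
})

test_that("model JSON round trip preserves predictions exactly", {
  tz <- triazinone_mcf7()
  fit <- fit_mlr(tz$dataset)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_identical(back$descriptors, fit$descriptors)
  expect_equal(predict(back, tz$dataset$data),
               predict(fit, tz$dataset$data), tolerance = 1e-12)
  expect_error(read_model_json(withr::local_tempfile(lines = "{}",
                                                     fileext = ".json")),
               "not a serialized")
})
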