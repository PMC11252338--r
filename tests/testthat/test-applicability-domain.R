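test_that("hat-matrix trace equals the number of fitted coefficients", {
  tz <- triazinone_mcf7()
  tr <- qsar_subset(tz$dataset, "train")
  h <- leverages(tr[, triazinone_descriptors])
  expect_equal(sum(h), 6, tolerance = 1e-10)
  expect_true(all(h > 0 & h <= 1))
  expect_true(all(h >= 1 / nrow(tr) - 1e-12))
  for (seed in c(1, 3)) {
    ds <- toy_synthetic(seed = seed)
    trn <- qsar_subset(ds, "train")
    hs <- leverages(trn[, ds$descriptors])
    expect_equal(sum(hs), length(ds$descriptors) + 1, tolerance = 1e-10)
  }
})

test_that("leverage matches the explicit quadratic-form oracle", {
  tz <- triazinone_mcf7()
  tr <- qsar_subset(tz$dataset, "train")
  query <- rbind(tr, qsar_subset(tz$dataset, "test"))
  h <- leverages(tr[, triazinone_descriptors],
                 query[, triazinone_descriptors])
  X <- cbind(1, as.matrix(tr[, triazinone_descriptors]))
  XtXi <- solve(t(X) %*% X)
  for (i in seq_len(nrow(query))) {
    xi <- c(1, as.numeric(query[i, triazinone_descriptors]))
    expect_equal(h[i], drop(t(xi) %*% XtXi %*% xi), tolerance = 1e-10)
  }
})

test_that("a query at the training centroid has the minimum leverage 1/N", {
  ds <- toy_synthetic(seed = 6)
  tr <- qsar_subset(ds, "train")
  centroid <- as.data.frame(t(colMeans(tr[, ds$descriptors])))
  h <- leverages(tr[, ds$descriptors], centroid)
  expect_equal(unname(h), 1 / nrow(tr), tolerance = 1e-10)
})

test_that("warning leverage is 3(k+1)/n", {
  expect_equal(warning_leverage(5, 32), 0.5625)
  expect_equal(warning_leverage(5, 27), 2 / 3, tolerance = 1e-10)
  expect_equal(warning_leverage(0, 3), 1)
  expect_error(warning_leverage(5, 0), "positive")
})

test_that("standardized residuals normalize to unit RMS", {
  expect_equal(standardized_residuals(c(4, 5), c(4 - 0.2, 5 + 0.2)),
               c(1, -1))
  expect_equal(standardized_residuals(c(4, 5, 6), c(4, 5, 6.3))[1], 0)
  set.seed(12)
  obs <- rnorm(15); pred <- obs + rnorm(15, 0, 0.4)
  sdr <- standardized_residuals(obs, pred)
  expect_equal(sqrt(mean(sdr^2)), 1, tolerance = 1e-12)
  expect_error(standardized_residuals(obs, obs), "zero")
})

test_that("every study compound lies inside the applicability domain", {
  tz <- triazinone_mcf7()
  fit <- fit_mlr(tz$dataset)
  ad <- assess_domain(tz$dataset, fit)
  expect_equal(nrow(ad$compounds), 32)
  expect_true(all(ad$compounds$in_domain))
  # standardized residuals stay within the plot's display limit of 2.5
  expect_true(all(abs(ad$compounds$sdr) <= 2.5))
})

test_that("an injected extreme candidate is flagged by leverage alone", {
  ds <- toy_synthetic(seed = 10)
  fit <- fit_mlr(ds)
  far <- inject_outlier(ds, 10)
  ad <- assess_domain(far, fit)
  out_row <- ad$compounds[ad$compounds$label == "outlier", ]
  expect_false(out_row$in_domain)
  expect_true(is.na(out_row$sdr))
  near <- inject_outlier(ds, 0.1)
  ad2 <- assess_domain(near, fit)
  expect_true(ad2$compounds[ad2$compounds$label == "outlier", "in_domain"])
})

test_that("designed candidates all receive a leverage value and flag", {
  tz <- triazinone_mcf7()
  fit <- fit_mlr(tz$dataset)
  ad <- assess_domain(tz$dataset, fit, candidates = tz$candidates)
  cand_rows <- ad$compounds[ad$compounds$subset == "designed", ]
  expect_equal(nrow(cand_rows), 28)
  expect_true(all(is.finite(cand_rows$leverage)))
  expect_true(all(is.na(cand_rows$sdr)))
  expect_type(cand_rows$in_domain, "logical")
})

test_that("domain flags are invariant to descriptor rescaling after refit", {
  ds <- toy_synthetic(seed = 14)
  fit <- fit_mlr(ds)
  flags1 <- assess_domain(ds, fit)$compounds$in_domain
  scaled <- ds$data
  scaled$TE <- scaled$TE / 1000
  ds2 <- qsar_dataset(scaled, ds$descriptors)
  flags2 <- assess_domain(ds2, fit_mlr(ds2))$compounds$in_domain
  expect_identical(flags1, flags2)
  h1 <- assess_domain(ds, fit)$compounds$leverage
  h2 <- assess_domain(ds2, fit_mlr(ds2))$compounds$leverage
  expect_equal(h1, h2, tolerance = 1e-8)
})
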