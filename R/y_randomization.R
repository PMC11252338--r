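#' Y-randomization (response scrambling) test
#'
#' Refits the model `n_iterations` times with the training responses
#' permuted uniformly at random (a permutation, not a resample: each
#' iteration uses exactly the observed multiset of activities), leaving the
#' descriptors and the train/test split untouched. For each iteration the
#' correlation R, the determination coefficient R^2 and the leave-one-out
#' Q^2 of the scrambled fit are recorded. A genuine structure-activity
#' relationship must have its real R^2/Q^2 far above these null averages.
#'
#' A rank-deficient scrambled refit (possible only through degenerate
#' descriptors, since permuting y leaves the design matrix unchanged) is
#' skipped and logged, never silently dropped from the stored series.
#'
#' @param dataset A [qsar_dataset()].
#' @param descriptors Descriptor names of the model under test.
#' @param n_iterations Number of permutations (default 100).
#' @param seed Integer seed; the result is fully reproducible from it.
#' @return Object of class `yrand_result`: per-iteration series `R_rand`,
#'   `R2_rand`, `Q2_rand`, their means, `cRp2`, the seed, and a `skipped`
#'   log.
#' @examples
#' tz <- triazinone_mcf7()
#' yr <- y_randomization(tz$dataset, n_iterations = 10, seed = 1)
#' yr$mean_R2_rand
#' @export
y_randomization <- function(dataset, descriptors = dataset$descriptors,
                            n_iterations = 100, seed = 1) {
  stopifnot(inherits(dataset, "qsar_dataset"), n_iterations >= 1)
  tr <- qsar_subset(dataset, "train")
  p <- length(descriptors)
  if (nrow(tr) <= p + 2L) {
    stop("training set too small for randomized LOO refits", call. = FALSE)
  }

  real_fit <- fit_mlr(dataset, descriptors)
  pred_tr <- predict(real_fit, tr)
  real_r2 <- r_squared(tr$pic50_obs, pred_tr)
  real_r <- sqrt(real_r2)

  R_rand <- R2_rand <- Q2_rand <- rep(NA_real_, n_iterations)
  skipped <- character()

  run <- function() {
    for (i in seq_len(n_iterations)) {
      perm <- tr
      perm$pic50_obs <- sample(tr$pic50_obs)
      ds_i <- qsar_dataset(rbind(perm, qsar_subset(dataset, "test")),
                           descriptors)
      stats_i <- tryCatch({
        fit_i <- fit_mlr(ds_i, descriptors)
        pr <- predict(fit_i, perm)
        r2 <- r_squared(perm$pic50_obs, pr)
        c(sqrt(max(r2, 0)), r2, q2_loo(ds_i, descriptors))
      }, error = function(e) {
        skipped <<- c(skipped,
                      sprintf("iteration %d skipped: %s", i,
                              conditionMessage(e)))
        c(NA_real_, NA_real_, NA_real_)
      })
      R_rand[i] <<- stats_i[1]
      R2_rand[i] <<- stats_i[2]
      Q2_rand[i] <<- stats_i[3]
    }
  }
  .with_seed(seed, run())

  mean_R <- mean(R_rand, na.rm = TRUE)
  structure(list(
    n_iterations = n_iterations,
    R_rand = R_rand, R2_rand = R2_rand, Q2_rand = Q2_rand,
    mean_R_rand = mean_R,
    mean_R2_rand = mean(R2_rand, na.rm = TRUE),
    mean_Q2_rand = mean(Q2_rand, na.rm = TRUE),
    real_R = real_r, real_R2 = real_r2,
    cRp2 = crp2(real_r, real_r2, mean_R),
    seed = seed,
    skipped = skipped
  ), class = "yrand_result")
}

#' @export
print.yrand_result <- function(x, ...) {
  cat("Y-randomization:", x$n_iterations, "permutations (seed", x$seed,
      ")\n")
  cat(sprintf("  mean R_rand  = %.3f\n  mean R2_rand = %.3f\n",
              x$mean_R_rand, x$mean_R2_rand))
  cat(sprintf("  mean Q2_rand = %.3f\n  cRp2         = %.3f\n",
              x$mean_Q2_rand, x$cRp2))
  if (length(x$skipped)) cat("  skipped:", length(x$skipped), "iterations\n")
  invisible(x)
}

#' cRp2 randomization-margin statistic
#'
#' cRp2 = R * sqrt(R^2 - (mean R_rand)^2): the margin of the real model's
#' correlation over the randomized-null average; a value above 0.5 passes
#' the randomization test.
#'
#' @param r Real-model correlation R.
#' @param r2 Real-model R^2.
#' @param mean_r_rand Average of the per-permutation R values.
#' @return Scalar cRp2.
#' @examples
#' crp2(0.849, 0.722, 0.438)
#' @export
crp2 <- function(r, r2, mean_r_rand) {
  rad <- r2 - mean_r_rand^2
  if (rad < 0) {
    stop("negative radicand: R^2 = ", signif(r2, 4),
         " < (mean R_rand)^2 = ", signif(mean_r_rand^2, 4),
         "; the model does not beat its randomized null", call. = FALSE)
  }
  r * sqrt(rad)
}

#' Serialize a Y-randomization result (with full per-iteration series)
#'
#' @param result A `yrand_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_yrand_json <- function(result, path) {
  stopifnot(inherits(result, "yrand_result"))
  obj <- unclass(result)
  obj$type <- "yrand_result"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
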