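#' Coefficient of determination
#'
#' R^2 = 1 - RSS/TSS. The default (`standard`) total sum of squares is
#' Sum (Yobs - mean(Yobs))^2. A `printed` variant with denominator
#' Sum (Ypred - mean(Yobs))^2 is also exposed; on the packaged study data it
#' does not reproduce the published training R^2 and exists for comparison
#' only.
#'
#' @param obs,pred Equal-length numeric vectors (n >= 3).
#' @param denominator `"standard"` (default) or `"printed"`.
#' @return Scalar R^2 (<= 1; can be negative for poor predictions).
#' @export
r_squared <- function(obs, pred, denominator = c("standard", "printed")) {
  denominator <- match.arg(denominator)
  .check_pair(obs, pred, min_n = 3L)
  if (stats::var(obs) == 0) {
    stop("observed responses are constant; R^2 undefined", call. = FALSE)
  }
  rss <- sum((obs - pred)^2)
  tss <- if (denominator == "standard") sum((obs - mean(obs))^2)
         else sum((pred - mean(obs))^2)
  1 - rss / tss
}

#' Adjusted R^2
#'
#' ((n - 1) R^2 - p) / (n - p - 1): penalizes R^2 for the number of
#' descriptors p fitted on n training compounds.
#'
#' @param r2 Unadjusted R^2.
#' @param n Training-set size.
#' @param p Number of descriptors.
#' @return Scalar adjusted R^2.
#' @export
r_squared_adjusted <- function(r2, n, p) {
  if (n <= p + 1) stop("need n > p + 1 for adjusted R^2", call. = FALSE)
  ((n - 1) * r2 - p) / (n - p - 1)
}

#' Residual mean square of a fitted model
#'
#' Default (`"residual_df"`): RSS / (n - p - 1), the residual mean square on
#' model degrees of freedom, which is what the published model statistics
#' correspond to. The plain RSS / n variant is exposed as `"n"`.
#'
#' @param obs,pred Numeric vectors.
#' @param p Number of descriptors in the model.
#' @param method `"residual_df"` (default) or `"n"`.
#' @return Scalar mean squared error.
#' @export
mse <- function(obs, pred, p, method = c("residual_df", "n")) {
  method <- match.arg(method)
  .check_pair(obs, pred, min_n = 2L)
  n <- length(obs)
  rss <- sum((obs - pred)^2)
  if (method == "residual_df") {
    if (n - p - 1 <= 0) stop("no residual degrees of freedom", call. = FALSE)
    rss / (n - p - 1)
  } else {
    rss / n
  }
}

#' Fisher F statistic of the regression
#'
#' F = [Sum (Ypred - mean(Ypred))^2 / RSS] * (n - p - 1) / p, i.e. explained
#' over residual variance on their degrees of freedom.
#'
#' @inheritParams mse
#' @return Scalar F; `Inf` when RSS is zero.
#' @export
f_statistic <- function(obs, pred, p) {
  .check_pair(obs, pred, min_n = 3L)
  n <- length(obs)
  if (n - p - 1 <= 0) stop("no residual degrees of freedom", call. = FALSE)
  rss <- sum((obs - pred)^2)
  ssreg <- sum((pred - mean(pred))^2)
  if (rss == 0) return(Inf)
  (ssreg / rss) * (n - p - 1) / p
}

#' Leave-one-out cross-validated Q^2
#'
#' For each training compound in turn, the model is refitted on the other
#' N - 1 compounds and the held-out compound predicted; Q^2 = 1 - PRESS/TSS
#' with TSS about the full training mean. The refits are explicit (no hat
#' -matrix shortcut), so any row whose removal makes the design singular is
#' reported by label.
#'
#' @param dataset A [qsar_dataset()].
#' @param descriptors Descriptor names of the model.
#' @return Scalar Q^2.
#' @examples
#' tz <- triazinone_mcf7()
#' q2_loo(tz$dataset)
#' @export
q2_loo <- function(dataset, descriptors = dataset$descriptors) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  tr <- qsar_subset(dataset, "train")
  n <- nrow(tr)
  p <- length(descriptors)
  if (n <= p + 2L) stop("need N > p + 2 training rows for LOO", call. = FALSE)
  press_pred <- numeric(n)
  for (i in seq_len(n)) {
    sub <- qsar_dataset(tr[-i, , drop = FALSE], descriptors)
    fit <- tryCatch(fit_mlr(sub, descriptors), error = function(e) {
      stop("LOO refit failed leaving out compound `", tr$label[i], "`: ",
           conditionMessage(e), call. = FALSE)
    })
    press_pred[i] <- predict(fit, tr[i, , drop = FALSE])
  }
  1 - sum((tr$pic50_obs - press_pred)^2) /
    sum((tr$pic50_obs - mean(tr$pic50_obs))^2)
}

#' External (test-set) R^2
#'
#' Primary mode (`"pearson"`): the squared Pearson correlation between
#' observed and predicted test activities, which is what the published
#' external R^2 corresponds to. The `"literal"` mode evaluates
#' 1 - Sum (Ypred - Yobs)^2 / Sum (Yobs - mean(Ypred))^2 instead; on the
#' packaged study data it is strongly negative and is retained only to
#' document that fact.
#'
#' @param obs,pred Test-set observed and predicted activities (n >= 3).
#' @param method `"pearson"` (default) or `"literal"`.
#' @return Scalar.
#' @export
r2_external <- function(obs, pred, method = c("pearson", "literal")) {
  method <- match.arg(method)
  .check_pair(obs, pred, min_n = 3L)
  if (method == "pearson") {
    if (stats::var(obs) == 0 || stats::var(pred) == 0) {
      stop("constant series; correlation undefined", call. = FALSE)
    }
    stats::cor(obs, pred)^2
  } else {
    1 - sum((pred - obs)^2) / sum((obs - mean(pred))^2)
  }
}

#' Through-origin regression slopes k and k'
#'
#' k = Sum(Yobs Ypred) / Sum(Ypred^2) (observed regressed on predicted
#' through the origin) and k' = Sum(Yobs Ypred) / Sum(Yobs^2) (the reverse).
#'
#' @param obs,pred Numeric vectors.
#' @return Named numeric vector `c(k =, k_prime =)`.
#' @export
gt_slopes <- function(obs, pred) {
  .check_pair(obs, pred, min_n = 2L)
  sp2 <- sum(pred^2); so2 <- sum(obs^2)
  if (sp2 == 0 || so2 == 0) {
    stop("all-zero series; through-origin slope undefined", call. = FALSE)
  }
  c(k = sum(obs * pred) / sp2, k_prime = sum(obs * pred) / so2)
}

#' Through-origin determination coefficients R0^2 and R0'^2
#'
#' With Y0obs = k Ypred and Y0pred = k' Yobs (the through-origin regression
#' lines of [gt_slopes()]):
#' R0^2  = 1 - Sum (Ypred - Y0obs)^2 / Sum (Ypred - mean(Ypred))^2 and
#' R0'^2 = 1 - Sum (Yobs - Y0pred)^2 / Sum (Yobs - mean(Yobs))^2.
#'
#' @param obs,pred Numeric vectors.
#' @return Named numeric vector `c(r0_sq =, r0_sq_prime =)`.
#' @export
gt_r0 <- function(obs, pred) {
  .check_pair(obs, pred, min_n = 3L)
  if (stats::var(obs) == 0 || stats::var(pred) == 0) {
    stop("zero variance; R0^2 undefined", call. = FALSE)
  }
  ks <- gt_slopes(obs, pred)
  y0_obs <- ks[["k"]] * pred
  y0_pred <- ks[["k_prime"]] * obs
  c(r0_sq = 1 - sum((pred - y0_obs)^2) / sum((pred - mean(pred))^2),
    r0_sq_prime = 1 - sum((obs - y0_pred)^2) / sum((obs - mean(obs))^2))
}

#' rm^2 external-validation metrics
#'
#' rm^2 = r^2 (1 - sqrt(|r^2 - r0^2|)) and the primed variant with r0'^2;
#' their mean and absolute difference summarize external predictivity
#' (pass: mean > 0.5, difference < 0.2). The absolute value inside the
#' radical keeps the metric real when r0^2 exceeds r^2.
#'
#' @param r2 Squared correlation between observed and predicted.
#' @param r0_sq,r0_sq_prime Through-origin determination coefficients from
#'   [gt_r0()].
#' @return Named list `rm2`, `rm2_prime`, `rm2_mean`, `rm2_delta`.
#' @export
rm2_metrics <- function(r2, r0_sq, r0_sq_prime) {
  rm2 <- r2 * (1 - sqrt(abs(r2 - r0_sq)))
  rm2_prime <- r2 * (1 - sqrt(abs(r2 - r0_sq_prime)))
  list(rm2 = rm2, rm2_prime = rm2_prime,
       rm2_mean = (rm2 + rm2_prime) / 2,
       rm2_delta = abs(rm2 - rm2_prime))
}

#' Golbraikh-Tropsha criteria verdicts
#'
#' Evaluates the external-predictivity checklist on a set of computed
#' scalars: R^2 > 0.6; Q^2 > 0.5; (R^2 - R0^2)/R^2 < 0.1 with
#' 0.85 <= k <= 1.15, or the primed variant; |R0^2 - R0'^2| < 0.3;
#' mean rm^2 > 0.5; delta rm^2 < 0.2. Thresholds are strict inequalities
#' where written as such (an R^2 of exactly 0.6 fails).
#'
#' @param report A [validation_report] (from [validate_model()]) or a named
#'   list carrying `R2`, `Q2_loo`, `R2_test`, `k`, `k_prime`, `R0_sq`,
#'   `R0_sq_prime`, `rm2_mean`, `rm2_delta`.
#' @return Named logical vector of per-criterion verdicts, with an
#'   `all_pass` attribute.
#' @export
gt_report <- function(report) {
  need <- c("R2", "Q2_loo", "R2_test", "k", "k_prime",
            "R0_sq", "R0_sq_prime", "rm2_mean", "rm2_delta")
  miss <- need[!vapply(need, function(f)
    !is.null(report[[f]]) && is.finite(report[[f]]), logical(1))]
  if (length(miss)) {
    stop("report is missing scalar(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  r2t <- report$R2_test
  branch_plain <- (r2t - report$R0_sq) / r2t < 0.1 &&
    report$k >= 0.85 && report$k <= 1.15
  branch_prime <- (r2t - report$R0_sq_prime) / r2t < 0.1 &&
    report$k_prime >= 0.85 && report$k_prime <= 1.15
  out <- c(
    r2_gt_0.6 = report$R2 > 0.6,
    q2_gt_0.5 = report$Q2_loo > 0.5,
    r0_and_k = branch_plain || branch_prime,
    k_in_band = report$k >= 0.85 && report$k <= 1.15,
    k_prime_in_band = report$k_prime >= 0.85 && report$k_prime <= 1.15,
    delta_r0_lt_0.3 = abs(report$R0_sq - report$R0_sq_prime) < 0.3,
    rm2_mean_gt_0.5 = report$rm2_mean > 0.5,
    rm2_delta_lt_0.2 = report$rm2_delta < 0.2
  )
  attr(out, "all_pass") <- all(out)
  out
}

#' Full internal/external validation of a fitted model
#'
#' Computes every fit, internal-validation and external-validation statistic
#' of the modelling workflow in one pass: training R/R^2/adjusted R^2/MSE/F,
#' leave-one-out Q^2, external R^2, through-origin slopes and determination
#' coefficients, rm^2 metrics, and the Golbraikh-Tropsha verdicts.
#'
#' @param model A `qsar_model` (its descriptors define the refits for Q^2).
#' @param dataset A [qsar_dataset()] with train and test subsets.
#' @return A `validation_report` (list, class `validation_report`) whose
#'   print method mirrors a parameter/value/threshold/verdict table.
#' @examples
#' tz <- triazinone_mcf7()
#' rep <- validate_model(fit_mlr(tz$dataset), tz$dataset)
#' rep
#' @export
validate_model <- function(model, dataset) {
  stopifnot(inherits(model, "qsar_model"), inherits(dataset, "qsar_dataset"))
  tr <- qsar_subset(dataset, "train")
  te <- qsar_subset(dataset, "test")
  pred_tr <- predict(model, tr)
  pred_te <- predict(model, te)
  r2 <- r_squared(tr$pic50_obs, pred_tr)
  p <- model$p
  rep <- list(
    R = sqrt(max(r2, 0)) * sign(stats::cor(tr$pic50_obs, pred_tr)),
    R2 = r2,
    R2_adj = r_squared_adjusted(r2, nrow(tr), p),
    MSE = mse(tr$pic50_obs, pred_tr, p),
    F = f_statistic(tr$pic50_obs, pred_tr, p),
    Q2_loo = q2_loo(dataset, model$descriptors),
    R2_test = r2_external(te$pic50_obs, pred_te),
    test_cor_sign = sign(stats::cor(te$pic50_obs, pred_te)),
    n_train = nrow(tr), n_test = nrow(te), p = p
  )
  ks <- gt_slopes(te$pic50_obs, pred_te)
  r0 <- gt_r0(te$pic50_obs, pred_te)
  rep$k <- ks[["k"]]; rep$k_prime <- ks[["k_prime"]]
  rep$R0_sq <- r0[["r0_sq"]]; rep$R0_sq_prime <- r0[["r0_sq_prime"]]
  rep <- c(rep, rm2_metrics(rep$R2_test, rep$R0_sq, rep$R0_sq_prime))
  rep$criteria <- gt_report(rep)
  structure(rep, class = "validation_report")
}

#' @export
print.validation_report <- function(x, digits = 3, ...) {
  rnd <- function(v) .round_half_away(v, digits)
  cat("QSAR validation report (N =", x$n_train, ", p =", x$p,
      ", test n =", x$n_test, ")\n")
  cat("Fitting:    R =", rnd(x$R), " R2 =", rnd(x$R2),
      " R2_adj =", rnd(x$R2_adj), " MSE =", rnd(x$MSE),
      " F =", rnd(x$F), "\n")
  cat("Internal:   Q2(LOO) =", rnd(x$Q2_loo), "\n")
  cat("External:   R2_test =", rnd(x$R2_test),
      if (x$test_cor_sign < 0) "(note: obs/pred correlation is negative)",
      "\n")
  cat("            k =", rnd(x$k), " k' =", rnd(x$k_prime),
      " R0^2 =", rnd(x$R0_sq), " R0'^2 =", rnd(x$R0_sq_prime), "\n")
  cat("            rm2 mean =", rnd(x$rm2_mean),
      " rm2 delta =", rnd(x$rm2_delta), "\n")
  crit <- x$criteria
  cat("Criteria:\n")
  for (nm in names(crit)) {
    cat(sprintf("  %-18s %s\n", nm, if (crit[[nm]]) "pass" else "FAIL"))
  }
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report A `validation_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  obj <- unclass(report)
  obj$criteria <- as.list(report$criteria)
  obj$all_pass <- isTRUE(attr(report$criteria, "all_pass"))
  obj$type <- "validation_report"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# round half away from zero (matches the published tables' display rounding;
# base round() rounds half to even)
.round_half_away <- function(x, digits = 3) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

.check_pair <- function(obs, pred, min_n = 2L) {
  if (!is.numeric(obs) || !is.numeric(pred) || length(obs) != length(pred)) {
    stop("`obs` and `pred` must be numeric vectors of equal length",
         call. = FALSE)
  }
  if (length(obs) < min_n) {
    stop("need at least ", min_n, " pairs", call. = FALSE)
  }
  if (any(!is.finite(obs)) || any(!is.finite(pred))) {
    stop("non-finite values in `obs`/`pred`", call. = FALSE)
  }
  invisible(TRUE)
}
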