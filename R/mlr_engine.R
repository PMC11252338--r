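#' @keywords internal
new_qsar_model <- function(intercept, slopes, n_train,
                           diagnostics = NULL, removal_log = character(),
                           source = "fit") {
  structure(
    list(
      descriptors = names(slopes),
      intercept = unname(intercept),
      slopes = slopes,
      n_train = as.integer(n_train),
      p = length(slopes),
      diagnostics = diagnostics,
      removal_log = removal_log,
      source = source
    ),
    class = "qsar_model"
  )
}

# Training design matrix with intercept column, in model descriptor order.
.design_matrix <- function(df, descriptors) {
  X <- as.matrix(df[, descriptors, drop = FALSE])
  storage.mode(X) <- "double"
  cbind(`(Intercept)` = 1, X)
}

#' Fit an ordinary-least-squares QSAR model
#'
#' Regresses observed pIC50 on the named descriptors over the training subset
#' of `dataset`. The fit goes through base R's QR decomposition (a
#' rank-revealing factorization); a rank-deficient design aborts with the
#' offending columns named rather than silently dropping them.
#'
#' @param dataset A [qsar_dataset()] with a non-empty training subset.
#' @param descriptors Character vector of descriptor names to include
#'   (default: all dataset descriptors).
#' @return A `qsar_model`: intercept, named slope vector, `n_train`, `p`, and
#'   `diagnostics` (a data.frame of coefficient estimates, standard errors,
#'   t values and p-values, plus the residual degrees of freedom as an
#'   attribute).
#' @examples
#' tz <- triazinone_mcf7()
#' fit <- fit_mlr(tz$dataset)
#' coef(fit)
#' @export
fit_mlr <- function(dataset, descriptors = dataset$descriptors) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  tr <- qsar_subset(dataset, "train")
  p <- length(descriptors)
  if (nrow(tr) <= p + 1L) {
    stop("training set has ", nrow(tr), " rows; need more than p + 1 = ",
         p + 1L, call. = FALSE)
  }
  missing_d <- setdiff(descriptors, names(tr))
  if (length(missing_d)) {
    stop("descriptor(s) not in dataset: ", paste(missing_d, collapse = ", "),
         call. = FALSE)
  }
  X <- .design_matrix(tr, descriptors)
  qrx <- qr(X, tol = 1e-10)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("singular fit: collinear column(s) ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  y <- tr$pic50_obs
  beta <- qr.coef(qrx, y)
  res <- y - drop(X %*% beta)
  dof <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / dof
  XtX_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), dof, lower.tail = FALSE)
  diagnostics <- data.frame(
    term = colnames(X), estimate = unname(beta), std_error = unname(se),
    t_value = unname(tval), p_value = unname(pval),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(diagnostics, "df_residual") <- dof
  slopes <- beta[-1]
  names(slopes) <- descriptors
  new_qsar_model(beta[1], slopes, nrow(tr), diagnostics)
}

#' @export
coef.qsar_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$slopes)
}

#' @export
print.qsar_model <- function(x, ...) {
  cat("QSAR MLR model (", x$source, "): pIC50 ~ ",
      paste(x$descriptors, collapse = " + "), "\n", sep = "")
  cat("  N =", x$n_train, "  p =", x$p, "\n")
  print(signif(coef(x), 4))
  if (length(x$removal_log)) {
    cat("Elimination log:\n")
    cat(paste0("  - ", x$removal_log, "\n"), sep = "")
  }
  invisible(x)
}

#' Predict pIC50 for new compounds
#'
#' @param object A `qsar_model`.
#' @param newdata Data.frame (or [qsar_dataset()]) carrying every model
#'   descriptor; a missing descriptor column is a keyed error naming it.
#' @param ... Unused.
#' @return Numeric vector of predicted pIC50, one per row of `newdata`.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  if (inherits(newdata, "qsar_dataset")) newdata <- newdata$data
  stopifnot(is.data.frame(newdata))
  missing_d <- setdiff(object$descriptors, names(newdata))
  if (length(missing_d)) {
    stop("missing descriptor(s): ", paste(missing_d, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(newdata[, object$descriptors, drop = FALSE])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) {
    stop("non-finite descriptor values in `newdata`", call. = FALSE)
  }
  unname(drop(object$intercept + X %*% object$slopes))
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R_j^2), with R_j^2 the coefficient of determination from
#' regressing descriptor j on all remaining descriptors (plus intercept).
#' A perfectly collinear descriptor is reported as `Inf`, not an error.
#'
#' @param dataset A [qsar_dataset()].
#' @param descriptors Descriptor names (>= 2).
#' @param rows Which rows to compute on: `"train"` (default; the model is a
#'   training-set object) or `"all"` (train + test).
#' @return Named numeric vector of VIFs.
#' @examples
#' tz <- triazinone_mcf7()
#' vif(tz$dataset)
#' @export
vif <- function(dataset, descriptors = dataset$descriptors,
                rows = c("train", "all")) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  rows <- match.arg(rows)
  if (length(descriptors) < 2L) {
    stop("VIF needs at least two descriptors", call. = FALSE)
  }
  df <- if (rows == "train") qsar_subset(dataset, "train") else
    dataset$data[dataset$data$subset %in% c("train", "test"), , drop = FALSE]
  out <- vapply(descriptors, function(d) {
    others <- setdiff(descriptors, d)
    X <- .design_matrix(df, others)
    y <- df[[d]]
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  out
}

#' Backward ("descendent") descriptor elimination
#'
#' Starting from the full candidate panel, repeatedly refits and removes the
#' descriptor with the largest coefficient p-value while that p-value exceeds
#' `alpha`; then removes descriptors whose VIF exceeds `vif_cap`, largest
#' first, refitting after each removal. Ties in p-value are broken by
#' candidate order, so the procedure is deterministic. The intercept is never
#' a removal candidate. Every removal is recorded in the returned model's
#' `removal_log`.
#'
#' @param dataset A [qsar_dataset()].
#' @param descriptors Candidate descriptor names (>= 2).
#' @param alpha Significance threshold for the p-value stage (default 0.05).
#' @param vif_cap Multicollinearity ceiling for the VIF stage (default 10).
#' @return The surviving `qsar_model`.
#' @export
backward_eliminate <- function(dataset, descriptors = dataset$descriptors,
                               alpha = 0.05, vif_cap = 10) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  if (length(descriptors) < 2L) {
    stop("need at least two candidate descriptors", call. = FALSE)
  }
  current <- descriptors
  log <- character()
  repeat {
    if (length(current) == 0L) {
      stop("all descriptors eliminated at alpha = ", alpha, call. = FALSE)
    }
    fit <- fit_mlr(dataset, current)
    pv <- fit$diagnostics$p_value[-1]  # drop intercept row
    worst <- which.max(pv)             # first max wins on ties
    if (pv[worst] <= alpha) break
    log <- c(log, sprintf("dropped %s (p = %.4g > alpha = %g)",
                          current[worst], pv[worst], alpha))
    current <- current[-worst]
  }
  while (length(current) >= 2L) {
    v <- vif(dataset, current)
    worst <- which.max(v)
    if (v[worst] <= vif_cap) break
    log <- c(log, sprintf("dropped %s (VIF = %.4g > cap = %g)",
                          current[worst], v[worst], vif_cap))
    current <- current[-worst]
  }
  if (length(current) == 0L) {
    stop("all descriptors eliminated by VIF screening", call. = FALSE)
  }
  fit <- fit_mlr(dataset, current)
  fit$removal_log <- log
  fit
}

#' Serialize / restore a model as JSON
#'
#' Coefficients are written at full precision together with the descriptor
#' order, fit dimensions and the elimination log, so a restored model
#' predicts identically.
#'
#' @param model A `qsar_model`.
#' @param path Output file.
#' @return `write_model_json()` returns `path` invisibly; `read_model_json()`
#'   returns the restored `qsar_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "qsar_model"))
  obj <- list(
    type = "qsar_model",
    source = model$source,
    descriptors = model$descriptors,
    intercept = model$intercept,
    slopes = as.list(model$slopes),
    n_train = model$n_train,
    p = model$p,
    removal_log = model$removal_log
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$type) || obj$type != "qsar_model") {
    stop("not a serialized qsar_model: ", path, call. = FALSE)
  }
  slopes <- unlist(obj$slopes)[obj$descriptors]
  new_qsar_model(obj$intercept, slopes, obj$n_train,
                 removal_log = as.character(obj$removal_log %||% character()),
                 source = obj$source %||% "fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
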