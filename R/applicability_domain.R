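#' Leverage (hat-matrix diagonal) of query compounds
#'
#' h_i = x_i' (X'X)^-1 x_i, where X is the intercept-augmented training
#' design matrix and x_i each intercept-augmented query row. The query may
#' be the training set itself (giving the classical hat diagonal, which sums
#' to the number of fitted coefficients), the test set, or designed
#' candidates. Computed through the QR factor of X (triangular solves), not
#' an explicit inverse.
#'
#' @param train_X Numeric matrix or data.frame of training descriptors
#'   (rows = compounds).
#' @param query_X Numeric matrix or data.frame with the same columns;
#'   defaults to `train_X`.
#' @return Numeric vector of leverages, one per query row.
#' @export
leverages <- function(train_X, query_X = train_X) {
  Xt <- as.matrix(train_X); storage.mode(Xt) <- "double"
  Xq <- as.matrix(query_X); storage.mode(Xq) <- "double"
  if (ncol(Xq) != ncol(Xt)) {
    stop("query and training descriptor matrices must have the same columns",
         call. = FALSE)
  }
  Xt <- cbind(1, Xt)
  Xq <- cbind(1, Xq)
  qrx <- qr(Xt)
  if (qrx$rank < ncol(Xt)) {
    stop("singular X'X: training design matrix is rank deficient",
         call. = FALSE)
  }
  R <- qr.R(qrx)[, order(qrx$pivot), drop = FALSE]
  # h_i = || R^-T x_i ||^2 since (X'X)^-1 = R^-1 R^-T
  W <- backsolve(R, t(Xq), transpose = TRUE)
  colSums(W^2)
}

#' Warning leverage h*
#'
#' h* = 3 (k + 1) / n, with k the number of model descriptors and n the
#' number of compounds used to define the domain.
#'
#' @param k Descriptor count.
#' @param n Compound count (> 0).
#' @return Scalar h*.
#' @examples
#' warning_leverage(5, 32)  # 0.5625
#' @export
warning_leverage <- function(k, n) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  3 * (k + 1) / n
}

#' Standardized residuals (SDR)
#'
#' SDR_i = (Yobs_i - Ypred_i) / sqrt(Sum (Yobs - Ypred)^2 / n). By default
#' the root-mean-square denominator is computed from the supplied residuals
#' themselves (so the SDR series has RMS exactly 1); pass `rms` to
#' standardize test or query residuals against a training-set scale.
#'
#' @param obs,pred Numeric vectors (n >= 2).
#' @param rms Optional externally supplied root-mean-square residual.
#' @return Numeric vector of standardized residuals.
#' @export
standardized_residuals <- function(obs, pred, rms = NULL) {
  .check_pair(obs, pred, min_n = 2L)
  res <- obs - pred
  if (is.null(rms)) rms <- sqrt(mean(res^2))
  if (rms == 0) {
    stop("all residuals are zero; SDR undefined", call. = FALSE)
  }
  res / rms
}

#' Applicability-domain (Williams plot) assessment
#'
#' Combines per-compound leverage against the warning leverage
#' h* = 3 (k + 1) / n and standardized residuals against `sdr_limit` into
#' in/out-of-domain flags. Train and test compounds get both checks;
#' compounds without an observed response (designed candidates) are
#' assessed on leverage alone. The SDR denominator is the training-set
#' root-mean-square residual for every row.
#'
#' @param dataset A [qsar_dataset()] (its training subset defines the
#'   domain).
#' @param model A `qsar_model` fitted on the training subset.
#' @param candidates Optional data.frame of additional compounds (e.g.
#'   designed candidates) to assess alongside the dataset rows.
#' @param sdr_limit Residual boundary (default 3; 2.5 is the common
#'   alternative display limit). Both the limit used and h* are returned.
#' @return Object of class `domain_assessment`: data.frame `compounds`
#'   (label, subset, leverage, sdr, in_domain) plus `h_star`, `sdr_limit`,
#'   `n_train`, `k`.
#' @examples
#' tz <- triazinone_mcf7()
#' ad <- assess_domain(tz$dataset, fit_mlr(tz$dataset))
#' sum(!ad$compounds$in_domain)
#' @export
assess_domain <- function(dataset, model, candidates = NULL, sdr_limit = 3) {
  stopifnot(inherits(dataset, "qsar_dataset"), inherits(model, "qsar_model"))
  tr <- qsar_subset(dataset, "train")
  rows <- dataset$data
  if (!is.null(candidates)) {
    candidates <- as.data.frame(candidates, stringsAsFactors = FALSE)
    miss <- setdiff(model$descriptors, names(candidates))
    if (length(miss)) {
      stop("candidates missing descriptor(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(candidates$subset)) candidates$subset <- "designed"
    if (is.null(candidates$pic50_obs)) candidates$pic50_obs <- NA_real_
    common <- intersect(names(rows), names(candidates))
    rows <- rbind(rows[, common, drop = FALSE],
                  candidates[, common, drop = FALSE])
  }
  h <- leverages(tr[, model$descriptors, drop = FALSE],
                 rows[, model$descriptors, drop = FALSE])
  h_star <- warning_leverage(model$p, nrow(tr))
  pred <- predict(model, rows)
  train_rms <- sqrt(mean((tr$pic50_obs - predict(model, tr))^2))
  sdr <- ifelse(is.finite(rows$pic50_obs),
                (rows$pic50_obs - pred) / train_rms, NA_real_)
  in_domain <- h < h_star & (is.na(sdr) | abs(sdr) <= sdr_limit)
  structure(list(
    compounds = data.frame(
      label = rows$label, subset = rows$subset,
      leverage = h, sdr = sdr, in_domain = in_domain,
      stringsAsFactors = FALSE
    ),
    h_star = h_star, sdr_limit = sdr_limit,
    n_train = nrow(tr), k = model$p
  ), class = "domain_assessment")
}

#' @export
print.domain_assessment <- function(x, ...) {
  n_out <- sum(!x$compounds$in_domain)
  cat("Applicability domain: h* =", round(x$h_star, 4),
      " (k =", x$k, ", n =", x$n_train, "),  |SDR| limit =", x$sdr_limit,
      "\n")
  cat(nrow(x$compounds), "compounds assessed;", n_out, "out of domain\n")
  if (n_out > 0) {
    out <- x$compounds[!x$compounds$in_domain, ]
    print(out, row.names = FALSE)
  }
  invisible(x)
}

#' Export Williams-plot data as CSV
#'
#' Writes label, leverage h, SDR and the in-domain flag, one row per
#' compound, for external plotting.
#'
#' @param assessment A `domain_assessment`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_williams_csv <- function(assessment, path) {
  stopifnot(inherits(assessment, "domain_assessment"))
  utils::write.csv(assessment$compounds, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Williams plot
#'
#' Standardized residual versus leverage, with a vertical line at h* and
#' horizontal lines at +/- the SDR limit. Compounds without an observed
#' response are drawn at SDR 0 with an open symbol (leverage-only
#' assessment). Requires ggplot2.
#'
#' @param assessment A `domain_assessment`.
#' @return A ggplot object.
#' @export
williams_plot <- function(assessment) {
  stopifnot(inherits(assessment, "domain_assessment"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("williams_plot() needs the ggplot2 package", call. = FALSE)
  }
  df <- assessment$compounds
  df$sdr_plot <- ifelse(is.na(df$sdr), 0, df$sdr)
  df$response <- ifelse(is.na(df$sdr), "predicted only", "observed")
  ggplot2::ggplot(df, ggplot2::aes(x = leverage, y = sdr_plot,
                                   colour = subset, shape = response)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = assessment$h_star, linetype = 2) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * assessment$sdr_limit,
                        linetype = 2) +
    ggplot2::labs(x = "Leverage h", y = "Standardized residual",
                  title = "Williams plot") +
    ggplot2::theme_minimal()
}
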