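utils::globalVariables(c("leverage", "sdr_plot", "subset", "response"))

#' Screen designed candidate compounds
#'
#' Predicts pIC50 for each candidate with the supplied model, attaches
#' leverage and the leverage-based applicability-domain flag (candidates
#' carry no observed activity, so no residual check applies), and returns
#' the table ranked by descending predicted activity, ties broken by label.
#'
#' When the candidate table carries a `pic50_pred_paper` column (a
#' previously published prediction), the published values are kept alongside
#' and any candidate whose published value differs from this package's
#' evaluation of the *published* coefficients by more than `flag_tol` is
#' marked `published_inconsistent` - surfacing transcription or data-entry
#' inconsistencies in the source table rather than silently altering them.
#'
#' @param model A `qsar_model` used for the ranked predictions.
#' @param candidates Data.frame of candidate compounds carrying every model
#'   descriptor (e.g. `triazinone_mcf7()$candidates`).
#' @param dataset Training [qsar_dataset()] defining the applicability
#'   domain.
#' @param published_model Optional `qsar_model` with the published
#'   coefficients, used only for the consistency flag (default
#'   [triazinone_published_model()] when the candidate table has a
#'   `pic50_pred_paper` column).
#' @param flag_tol Discrepancy threshold for the consistency flag
#'   (default 0.05 pIC50 units).
#' @return Object of class `screening_result`: data.frame `ranked` with
#'   columns label, predicted, leverage, in_domain, and when available
#'   pic50_pred_paper, predicted_published, published_inconsistent.
#' @examples
#' tz <- triazinone_mcf7()
#' sc <- screen_candidates(triazinone_published_model(), tz$candidates,
#'                         tz$dataset)
#' head(sc$ranked)
#' @export
screen_candidates <- function(model, candidates, dataset,
                              published_model = NULL, flag_tol = 0.05) {
  stopifnot(inherits(model, "qsar_model"), inherits(dataset, "qsar_dataset"))
  candidates <- as.data.frame(candidates, stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L) {
    return(structure(list(ranked = data.frame(
      label = character(), predicted = numeric(), leverage = numeric(),
      in_domain = logical(), stringsAsFactors = FALSE
    ), h_star = NA_real_), class = "screening_result"))
  }
  pred <- predict(model, candidates)
  tr <- qsar_subset(dataset, "train")
  h <- leverages(tr[, model$descriptors, drop = FALSE],
                 candidates[, model$descriptors, drop = FALSE])
  h_star <- warning_leverage(model$p, nrow(tr))
  out <- data.frame(
    label = as.character(candidates$label),
    predicted = pred,
    leverage = h,
    in_domain = h < h_star,
    stringsAsFactors = FALSE
  )
  if ("pic50_pred_paper" %in% names(candidates)) {
    if (is.null(published_model)) {
      published_model <- triazinone_published_model()
    }
    out$pic50_pred_paper <- candidates$pic50_pred_paper
    out$predicted_published <- predict(published_model, candidates)
    out$published_inconsistent <-
      is.finite(out$pic50_pred_paper) &
      abs(out$predicted_published - out$pic50_pred_paper) > flag_tol
  }
  ord <- order(-out$predicted, out$label)
  structure(list(ranked = out[ord, , drop = FALSE], h_star = h_star),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, n = 10, ...) {
  cat("Candidate screening:", nrow(x$ranked), "compounds, h* =",
      round(x$h_star, 4), "\n")
  if (nrow(x$ranked)) {
    show <- utils::head(x$ranked, n)
    show$predicted <- round(show$predicted, 3)
    show$leverage <- round(show$leverage, 4)
    print(show, row.names = FALSE)
    flagged <- if ("published_inconsistent" %in% names(x$ranked)) {
      x$ranked$label[x$ranked$published_inconsistent]
    } else character()
    if (length(flagged)) {
      cat("Published-prediction inconsistency flagged for:",
          paste(flagged, collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Write a screening result to CSV
#'
#' @param result A `screening_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_screening_csv <- function(result, path) {
  stopifnot(inherits(result, "screening_result"))
  utils::write.csv(result$ranked, path, row.names = FALSE, na = "")
  invisible(path)
}
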