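#' Convert an IC50 concentration to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the half-maximal inhibitory
#' concentration expressed in mol/L; larger values mean higher potency.
#'
#' @param ic50 Numeric vector of IC50 values in mol/L. Must be strictly
#'   positive and finite.
#' @return Numeric vector of pIC50 values, `-log10(ic50)`.
#' @examples
#' ic50_to_pic50(1e-4)   # 4
#' ic50_to_pic50(3.47e-4)
#' @export
ic50_to_pic50 <- function(ic50) {
  if (!is.numeric(ic50)) {
    stop("`ic50` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("IC50 values must be positive and finite (concentration in mol/L)",
         call. = FALSE)
  }
  -log10(ic50)
}

#' Derived electronic descriptors from frontier orbital energies
#'
#' Computes absolute hardness eta, absolute electronegativity chi and the
#' reactivity (electrophilicity) index omega from HOMO/LUMO energies and the
#' dipole moment. Two sign/definition conventions are supported:
#' \describe{
#'   \item{printed}{chi = (E_LUMO + E_HOMO)/2 and omega = mu^2 / (2 eta), the
#'     formulas as commonly printed alongside DFT descriptor tables. For the
#'     usual negative orbital energies this chi is negative.}
#'   \item{conventional}{Mulliken electronegativity chi = -(E_LUMO + E_HOMO)/2
#'     and Parr electrophilicity omega = chi^2 / (2 eta).}
#' }
#' eta = (E_LUMO - E_HOMO)/2 under both conventions.
#'
#' @param e_homo,e_lumo HOMO and LUMO orbital energies (any consistent unit,
#'   e.g. eV). `e_lumo` must be >= `e_homo`.
#' @param dipole_mu Dipole moment (Debye), used by the printed omega.
#' @param convention `"printed"` (default) or `"conventional"`.
#' @return Named list with components `eta`, `chi`, `omega`.
#' @examples
#' derived_electronic(-6, -2, 2)                   # eta 2, chi -4, omega 1
#' derived_electronic(-6, -2, 2, "conventional")   # eta 2, chi  4, omega 4
#' @export
derived_electronic <- function(e_homo, e_lumo, dipole_mu,
                               convention = c("printed", "conventional")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(e_homo), is.numeric(e_lumo), is.numeric(dipole_mu))
  if (any(e_lumo < e_homo)) {
    stop("`e_lumo` must be >= `e_homo` (non-negative HOMO-LUMO gap)",
         call. = FALSE)
  }
  eta <- (e_lumo - e_homo) / 2
  if (convention == "printed") {
    chi <- (e_lumo + e_homo) / 2
    if (any(eta == 0)) {
      stop("omega undefined: zero HOMO-LUMO gap (eta = 0)", call. = FALSE)
    }
    omega <- dipole_mu^2 / (2 * eta)
  } else {
    chi <- -(e_lumo + e_homo) / 2
    if (any(eta == 0)) {
      stop("omega undefined: zero HOMO-LUMO gap (eta = 0)", call. = FALSE)
    }
    omega <- chi^2 / (2 * eta)
  }
  list(eta = eta, chi = chi, omega = omega)
}

# Columns every dataset CSV must carry, in canonical order. Additional
# descriptor columns may appear between I_shape and pic50_obs.
.qsar_core_cols <- c("label", "subset", "pic50_obs", "pic50_pred_paper")
.qsar_subsets <- c("train", "test", "designed")

#' Construct a QSAR dataset
#'
#' Bundles a compound table with the list of descriptor columns available for
#' modelling, and validates the structural invariants: unique labels, a
#' recognised subset tag per row (`train`, `test` or `designed`), finite
#' descriptor values, and an observed pIC50 for every train/test compound.
#'
#' @param data A data.frame with columns `label`, `subset`, one column per
#'   descriptor, `pic50_obs` (may be `NA` for designed compounds only) and
#'   optionally `pic50_pred_paper` (a previously published prediction).
#' @param descriptors Character vector of descriptor column names. Defaults to
#'   every column not among the reserved ones.
#' @return An object of class `qsar_dataset`: a list with elements `data`
#'   (the validated data.frame) and `descriptors`.
#' @export
qsar_dataset <- function(data, descriptors = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(descriptors)) {
    descriptors <- setdiff(names(data), .qsar_core_cols)
  }
  missing_cols <- setdiff(c("label", "subset", descriptors), names(data))
  if (length(missing_cols)) {
    stop("dataset is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"pic50_obs" %in% names(data)) data$pic50_obs <- NA_real_
  data$label <- as.character(data$label)
  data$subset <- as.character(data$subset)
  if (anyDuplicated(data$label)) {
    stop("compound labels must be unique; duplicated: ",
         paste(unique(data$label[duplicated(data$label)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(data$subset), .qsar_subsets)
  if (length(bad)) {
    stop("unknown subset tag(s): ", paste(bad, collapse = ", "),
         " (expected train/test/designed)", call. = FALSE)
  }
  for (d in descriptors) {
    if (!is.numeric(data[[d]]) || any(!is.finite(data[[d]]))) {
      stop("descriptor column `", d, "` must be finite numeric", call. = FALSE)
    }
  }
  fit_rows <- data$subset %in% c("train", "test")
  if (any(fit_rows & !is.finite(data$pic50_obs))) {
    stop("observed pIC50 required for every train/test compound",
         call. = FALSE)
  }
  structure(list(data = data, descriptors = descriptors),
            class = "qsar_dataset")
}

#' @export
print.qsar_dataset <- function(x, ...) {
  n <- table(factor(x$data$subset, levels = .qsar_subsets))
  cat("QSAR dataset:", nrow(x$data), "compounds (",
      n[["train"]], "train /", n[["test"]], "test /",
      n[["designed"]], "designed )\n")
  cat("Descriptors:", paste(x$descriptors, collapse = ", "), "\n")
  invisible(x)
}

#' Subset accessors
#'
#' @param dataset A [qsar_dataset()].
#' @param which One of `"train"`, `"test"`, `"designed"`.
#' @return Data.frame of the matching rows.
#' @export
qsar_subset <- function(dataset, which = c("train", "test", "designed")) {
  which <- match.arg(which)
  stopifnot(inherits(dataset, "qsar_dataset"))
  dataset$data[dataset$data$subset == which, , drop = FALSE]
}

#' Read / write QSAR dataset CSV
#'
#' The on-disk format is plain UTF-8 CSV with a header row and columns
#' `label, subset, <descriptors...>, pic50_obs, pic50_pred_paper`; missing
#' values are empty fields. Writing then re-reading reproduces every field.
#'
#' @param path File path.
#' @param descriptors Optional descriptor names; defaults to all non-reserved
#'   columns.
#' @return `read_qsar_csv()` returns a [qsar_dataset()]; `write_qsar_csv()`
#'   returns `path` invisibly.
#' @export
read_qsar_csv <- function(path, descriptors = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty dataset file: ", path, call. = FALSE)
  qsar_dataset(df, descriptors)
}

#' @rdname read_qsar_csv
#' @param dataset A [qsar_dataset()] to write.
#' @export
write_qsar_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  ord <- c("label", "subset", dataset$descriptors,
           intersect(c("pic50_obs", "pic50_pred_paper"),
                     names(dataset$data)))
  ord <- c(ord, setdiff(names(dataset$data), ord))
  utils::write.csv(dataset$data[, ord, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# The five descriptors of the published MCF-7 model, in equation order.
#' @export
triazinone_descriptors <- c("chi", "TE", "NHD", "LogS", "I_shape")

#' The 1,2,4-triazin-3(2H)-one MCF-7 study data
#'
#' Loads the packaged study tables: 32 triazinone derivatives with observed
#' MCF-7 pIC50 (27 training + 5 test compounds) and 28 designed candidate
#' compounds with published predicted activities. Descriptors are the
#' absolute electronegativity `chi`, total energy `TE` (a.u.-scale, large
#' negative), hydrogen-bond donor count `NHD`, aqueous solubility `LogS` and
#' shape coefficient `I_shape`. The loader verifies fixture integrity
#' (subset counts, finite descriptors, observed pIC50 in the assay range)
#' and refuses to return a corrupted table.
#'
#' @return List with elements `dataset` (a [qsar_dataset()] of the 32
#'   modelled compounds) and `candidates` (data.frame of the 28 designed
#'   compounds, subset `"designed"`, with `pic50_pred_paper` carrying the
#'   published predictions).
#' @examples
#' tz <- triazinone_mcf7()
#' tz$dataset
#' @export
triazinone_mcf7 <- function() {
  main <- system.file("extdata", "triazinone_mcf7.csv", package = "qsarmlr",
                      mustWork = TRUE)
  cand <- system.file("extdata", "designed_candidates.csv",
                      package = "qsarmlr", mustWork = TRUE)
  dataset <- read_qsar_csv(main, triazinone_descriptors)
  candidates <- utils::read.csv(cand, stringsAsFactors = FALSE)
  n <- table(factor(dataset$data$subset, levels = .qsar_subsets))
  ok <- n[["train"]] == 27L && n[["test"]] == 5L &&
    nrow(candidates) == 28L &&
    all(candidates$subset == "designed") &&
    all(is.finite(as.matrix(candidates[triazinone_descriptors]))) &&
    all(dataset$data$pic50_obs >= 3.460 - 1e-9) &&
    all(dataset$data$pic50_obs <= 4.963 + 1e-9)
  if (!ok) {
    stop("packaged triazinone tables failed their integrity check",
         call. = FALSE)
  }
  list(dataset = dataset, candidates = candidates)
}

#' Published MCF-7 triazinone model coefficients
#'
#' The five-descriptor regression equation reported for this dataset:
#' pIC50 = -10.12 + 1.64 chi - 5.69e-05 TE + 1.48 NHD - 1.37 LogS
#' - 0.36 I. Returned as a [qsar_model] so it can be used with
#' [predict()][predict.qsar_model], [screen_candidates()] and
#' [assess_domain()] interchangeably with refitted models.
#'
#' @return A `qsar_model` with the published coefficients (no fit
#'   diagnostics; `n_train = 27`, `p = 5`).
#' @export
triazinone_published_model <- function() {
  new_qsar_model(
    intercept = -10.12,
    slopes = c(chi = 1.64, TE = -5.69e-05, NHD = 1.48,
               LogS = -1.37, I_shape = -0.36),
    n_train = 27L,
    source = "published"
  )
}
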