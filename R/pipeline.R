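# Orchestration layer: file-in / file-out wrappers over the modelling,
# validation, randomization, domain and screening functions, plus a thin
# command-line front end (inst/cli/qsarmlr) built on them.

.run_metadata <- function(config, seed = NULL) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  on.exit(unlink(tmp))
  list(
    package = "qsarmlr",
    version = as.character(utils::packageVersion("qsarmlr")),
    seed = seed,
    config = config,
    config_md5 = unname(tools::md5sum(tmp))
  )
}

.write_artifact <- function(obj, meta, path) {
  jsonlite::write_json(c(list(run = meta), obj), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Fit-and-validate pipeline run
#'
#' Reads a dataset CSV, fits the model (optionally after backward
#' elimination), runs the full validation suite and writes three artifacts
#' into `outdir`: `model.json`, `validation.json` and a human-readable
#' `report.txt` laid out as parameter / value / threshold / verdict. Every
#' artifact embeds the package version, a hash of the run configuration and
#' the seed, sufficient to reproduce the run.
#'
#' @param input Path to a dataset CSV (see [read_qsar_csv()]).
#' @param outdir Output directory (created if needed).
#' @param descriptors Descriptor subset to model (default: all).
#' @param eliminate If `TRUE`, run [backward_eliminate()] with `alpha` and
#'   `vif_cap` instead of fitting the full panel.
#' @param alpha,vif_cap Elimination thresholds.
#' @param seed Seed recorded in the artifacts (the fit itself is
#'   deterministic).
#' @return Invisibly, a named list of the written file paths.
#' @export
qsar_run_fit <- function(input, outdir, descriptors = NULL,
                         eliminate = FALSE, alpha = 0.05, vif_cap = 10,
                         seed = NULL) {
  dataset <- read_qsar_csv(input, descriptors)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  model <- if (eliminate) {
    backward_eliminate(dataset, dataset$descriptors, alpha, vif_cap)
  } else {
    fit_mlr(dataset)
  }
  report <- validate_model(model, dataset)
  meta <- .run_metadata(list(input = input, descriptors = dataset$descriptors,
                             eliminate = eliminate, alpha = alpha,
                             vif_cap = vif_cap), seed)
  model_path <- file.path(outdir, "model.json")
  write_model_json(model, model_path)
  report_path <- file.path(outdir, "validation.json")
  obj <- unclass(report)
  obj$criteria <- as.list(report$criteria)
  obj$all_pass <- isTRUE(attr(report$criteria, "all_pass"))
  .write_artifact(obj, meta, report_path)
  txt_path <- file.path(outdir, "report.txt")
  con <- file(txt_path, "w")
  sink(con)
  print(model)
  cat("\n")
  print(report)
  sink()
  close(con)
  invisible(list(model = model_path, validation = report_path,
                 report = txt_path))
}

#' Y-randomization pipeline run
#'
#' @inheritParams qsar_run_fit
#' @param n_iterations Number of response permutations.
#' @return Invisibly, the path of the written `yrandomization.json`.
#' @export
qsar_run_randomize <- function(input, outdir, descriptors = NULL,
                               n_iterations = 100, seed = 1) {
  dataset <- read_qsar_csv(input, descriptors)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  yr <- y_randomization(dataset, dataset$descriptors, n_iterations, seed)
  meta <- .run_metadata(list(input = input, n_iterations = n_iterations),
                        seed)
  path <- file.path(outdir, "yrandomization.json")
  .write_artifact(unclass(yr), meta, path)
  invisible(path)
}

#' Applicability-domain pipeline run
#'
#' Writes `domain.json` and the Williams-plot CSV `williams.csv`.
#'
#' @inheritParams qsar_run_fit
#' @param model_path Optional serialized model (`model.json`); when absent
#'   the model is refitted from the input's training subset.
#' @param sdr_limit Standardized-residual boundary.
#' @return Invisibly, a named list of written paths.
#' @export
qsar_run_domain <- function(input, outdir, model_path = NULL,
                            descriptors = NULL, sdr_limit = 3,
                            seed = NULL) {
  dataset <- read_qsar_csv(input, descriptors)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  model <- if (is.null(model_path)) fit_mlr(dataset) else {
    if (!file.exists(model_path)) {
      stop("model file not found: ", model_path,
           " (run the fit step first)", call. = FALSE)
    }
    read_model_json(model_path)
  }
  ad <- assess_domain(dataset, model, sdr_limit = sdr_limit)
  meta <- .run_metadata(list(input = input, sdr_limit = sdr_limit), seed)
  json_path <- file.path(outdir, "domain.json")
  .write_artifact(list(h_star = ad$h_star, sdr_limit = ad$sdr_limit,
                       n_out_of_domain = sum(!ad$compounds$in_domain),
                       compounds = ad$compounds), meta, json_path)
  csv_path <- file.path(outdir, "williams.csv")
  write_williams_csv(ad, csv_path)
  invisible(list(domain = json_path, williams = csv_path))
}

#' Candidate-screening pipeline run
#'
#' Writes the ranked candidate table `screening.csv` and a summary
#' `screening.json`.
#'
#' @inheritParams qsar_run_domain
#' @param candidates Path to a candidates CSV (same schema, subset
#'   `designed`).
#' @return Invisibly, a named list of written paths.
#' @export
qsar_run_screen <- function(input, candidates, outdir, model_path = NULL,
                            descriptors = NULL, seed = NULL) {
  dataset <- read_qsar_csv(input, descriptors)
  cand <- utils::read.csv(candidates, stringsAsFactors = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  model <- if (is.null(model_path)) fit_mlr(dataset) else {
    if (!file.exists(model_path)) {
      stop("model file not found: ", model_path,
           " (run the fit step first)", call. = FALSE)
    }
    read_model_json(model_path)
  }
  sc <- screen_candidates(model, cand, dataset)
  meta <- .run_metadata(list(input = input, candidates = candidates), seed)
  csv_path <- file.path(outdir, "screening.csv")
  write_screening_csv(sc, csv_path)
  json_path <- file.path(outdir, "screening.json")
  .write_artifact(list(h_star = sc$h_star, n_candidates = nrow(sc$ranked),
                       top = utils::head(sc$ranked$label, 5)),
                  meta, json_path)
  invisible(list(screening = csv_path, summary = json_path))
}

#' Synthetic-dataset pipeline run
#'
#' Generates a dataset under the default study-like configuration (or a
#' caller-modified one) and writes it as CSV.
#'
#' @param out Output CSV path.
#' @param config A [generator_config()].
#' @return Invisibly, `out`.
#' @export
qsar_run_simulate <- function(out, config = generator_config()) {
  ds <- simulate_qsar(config)
  dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
  write_qsar_csv(ds, out)
  invisible(out)
}

#' Command-line entry point
#'
#' Dispatches `fit`, `validate`, `randomize`, `domain`, `screen` and
#' `simulate` subcommands to the `qsar_run_*` functions. Used by the
#' installed script `inst/cli/qsarmlr`; exposed as a function so the
#' dispatch logic is testable. Exit status: 0 on success, 2 on
#' configuration/schema errors, 3 on numerical failure.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit status, invisibly.
#' @export
qsar_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: qsarmlr <fit|validate|randomize|domain|screen|simulate> [options]",
    "  common options: --input PATH --outdir DIR [--seed INT]",
    "  fit/validate:   [--eliminate] [--alpha A] [--vif-cap V]",
    "  randomize:      [--n N]",
    "  domain:         [--model PATH] [--sdr-limit L]",
    "  screen:         --candidates PATH [--model PATH]",
    "  simulate:       --out PATH [--seed INT]",
    sep = "\n")
  if (length(args) == 0L) {
    message(usage)
    return(invisible(2L))
  }
  cmd <- args[1]
  opts <- .parse_cli_opts(args[-1])
  status <- tryCatch({
    switch(cmd,
      fit = ,
      validate = qsar_run_fit(
        .req(opts, "input"), .req(opts, "outdir"),
        eliminate = isTRUE(opts$eliminate),
        alpha = as.numeric(opts$alpha %||% 0.05),
        vif_cap = as.numeric(opts$`vif-cap` %||% 10),
        seed = if (!is.null(opts$seed)) as.integer(opts$seed)),
      randomize = qsar_run_randomize(
        .req(opts, "input"), .req(opts, "outdir"),
        n_iterations = as.integer(opts$n %||% 100),
        seed = as.integer(opts$seed %||% 1)),
      domain = qsar_run_domain(
        .req(opts, "input"), .req(opts, "outdir"),
        model_path = opts$model,
        sdr_limit = as.numeric(opts$`sdr-limit` %||% 3)),
      screen = qsar_run_screen(
        .req(opts, "input"), .req(opts, "candidates"),
        .req(opts, "outdir"), model_path = opts$model),
      simulate = qsar_run_simulate(
        .req(opts, "out"),
        generator_config(seed = as.integer(opts$seed %||% 1))),
      stop("unknown subcommand: ", cmd, call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("qsarmlr error: ", conditionMessage(e))
    numeric_failure <- grepl("singular|rank deficient|radicand|undefined",
                             conditionMessage(e))
    if (numeric_failure) 3L else 2L
  })
  invisible(status)
}

.parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      stop("unexpected argument: ", a, call. = FALSE)
    }
    key <- substring(a, 3)
    if (key == "eliminate") {
      opts$eliminate <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) stop("missing value for --", key, call. = FALSE)
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

.req <- function(opts, key) {
  if (is.null(opts[[key]])) {
    stop("required option --", key, " is missing", call. = FALSE)
  }
  opts[[key]]
}
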