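#' Configuration for the synthetic QSAR data generator
#'
#' Defaults mirror the statistical structure of the packaged triazinone
#' study data: 27 training + 5 test compounds, response linear in the five
#' model descriptors with the published coefficients, descriptor ranges
#' matching the study table (chi uniform on [2.9, 4.1], TE uniform on
#' [-106000, -22000], NHD categorical 1..6, LogS uniform on [-5.2, -2.7],
#' I binary), and Gaussian noise with standard deviation 0.24 (the
#' residual scale of the published fit). Optional nuisance descriptors are
#' pure-noise columns mixed with the informative ones at pairwise
#' correlation `nuisance_rho` (Cholesky mixing on standardized columns).
#'
#' @param n_train,n_test Subset sizes.
#' @param true_intercept Intercept of the generating linear model.
#' @param true_slopes Named numeric vector of generating slopes; names
#'   define the informative descriptors.
#' @param descriptor_distributions Named list, one entry per informative
#'   descriptor: either `c(lo, hi)` for a uniform range or
#'   `list(levels = ...)` for a categorical draw.
#' @param nuisance_descriptors Count of uninformative correlated columns
#'   (named `nuis1`, `nuis2`, ...).
#' @param nuisance_rho Target correlation between each nuisance column and
#'   its paired informative column (|rho| < 1).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed; identical configs generate identical datasets.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    n_train = 27, n_test = 5,
    true_intercept = -10.12,
    true_slopes = c(chi = 1.64, TE = -5.69e-05, NHD = 1.48,
                    LogS = -1.37, I_shape = -0.36),
    descriptor_distributions = list(
      chi = c(2.9, 4.1),
      TE = c(-106000, -22000),
      NHD = list(levels = 1:6),
      LogS = c(-5.2, -2.7),
      I_shape = list(levels = 0:1)
    ),
    nuisance_descriptors = 0,
    nuisance_rho = 0.5,
    noise_sd = 0.24,
    seed = 1) {
  stopifnot(noise_sd >= 0, n_train >= 1, n_test >= 0,
            is.numeric(true_slopes), !is.null(names(true_slopes)))
  if (!setequal(names(true_slopes), names(descriptor_distributions))) {
    stop("`descriptor_distributions` must name exactly the slope descriptors",
         call. = FALSE)
  }
  if (abs(nuisance_rho) >= 1) {
    stop("non-positive-definite correlation structure: |rho| must be < 1",
         call. = FALSE)
  }
  structure(list(
    n_train = as.integer(n_train), n_test = as.integer(n_test),
    true_intercept = true_intercept, true_slopes = true_slopes,
    descriptor_distributions = descriptor_distributions,
    nuisance_descriptors = as.integer(nuisance_descriptors),
    nuisance_rho = nuisance_rho,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "generator_config")
}

#' Generate a synthetic QSAR dataset with known ground truth
#'
#' Draws descriptors per the configured distributions, builds the response
#' as `true_intercept + X true_slopes + Normal(0, noise_sd)`, and splits
#' compounds into train/test by a seeded permutation. Ground truth (the
#' generating coefficients) is attached as the `truth` attribute for
#' parameter-recovery tests.
#'
#' @param config A [generator_config()].
#' @return A [qsar_dataset()]; `attr(, "truth")` carries the generating
#'   intercept, slopes and noise_sd.
#' @examples
#' ds <- simulate_qsar(generator_config(seed = 7))
#' ds
#' @export
simulate_qsar <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_train + config$n_test
  informative <- names(config$true_slopes)

  build <- function() {
    cols <- lapply(informative, function(d) {
      spec <- config$descriptor_distributions[[d]]
      if (is.list(spec)) {
        as.numeric(sample(spec$levels, n, replace = TRUE))
      } else {
        stats::runif(n, spec[1], spec[2])
      }
    })
    names(cols) <- informative
    X <- as.data.frame(cols)
    if (config$nuisance_descriptors > 0) {
      rho <- config$nuisance_rho
      for (j in seq_len(config$nuisance_descriptors)) {
        partner <- X[[informative[((j - 1) %% length(informative)) + 1]]]
        z <- (partner - mean(partner)) / stats::sd(partner)
        # Cholesky mixing of the standardized partner with fresh noise
        mixed <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
        X[[paste0("nuis", j)]] <- mixed
      }
    }
    y <- config$true_intercept +
      as.matrix(X[, informative, drop = FALSE]) %*% config$true_slopes +
      stats::rnorm(n, 0, config$noise_sd)
    split <- sample(rep(c("train", "test"),
                        c(config$n_train, config$n_test)))
    data.frame(
      label = sprintf("S%03d", seq_len(n)),
      subset = split,
      X,
      pic50_obs = drop(y),
      stringsAsFactors = FALSE
    )
  }
  df <- .with_seed(config$seed, build())
  ds <- qsar_dataset(df, setdiff(names(df), .qsar_core_cols))
  attr(ds, "truth") <- list(intercept = config$true_intercept,
                            slopes = config$true_slopes,
                            noise_sd = config$noise_sd)
  ds
}

#' Append an extreme synthetic candidate
#'
#' Adds one `designed`-subset compound whose descriptors sit
#' `sigma_multiplier` standard deviations from the training centroid along
#' the first principal direction of the training descriptor matrix - a
#' controlled probe for leverage-based domain flagging.
#'
#' @param dataset A [qsar_dataset()].
#' @param sigma_multiplier Positive displacement in SD units.
#' @return The dataset with one appended compound (label `outlier`).
#' @export
inject_outlier <- function(dataset, sigma_multiplier) {
  stopifnot(inherits(dataset, "qsar_dataset"), sigma_multiplier > 0)
  tr <- qsar_subset(dataset, "train")
  X <- as.matrix(tr[, dataset$descriptors, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance descriptor; principal direction undefined",
         call. = FALSE)
  }
  Z <- scale(X)
  pc1 <- stats::prcomp(Z, center = FALSE, scale. = FALSE)$rotation[, 1]
  centroid <- colMeans(X)
  new_x <- centroid + sigma_multiplier * (pc1 * sds)
  row <- dataset$data[1, , drop = FALSE]
  row$label <- "outlier"
  row$subset <- "designed"
  row[dataset$descriptors] <- as.list(new_x)
  row$pic50_obs <- NA_real_
  qsar_dataset(rbind(dataset$data, row), dataset$descriptors)
}
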