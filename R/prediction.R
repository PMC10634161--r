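# Random-forest regression (ranger backend) and accuracy metrics.

#' Random-forest configuration
#'
#' Bundles the forest hyperparameters. Defaults are the standard regression
#' settings: 500 trees, `mtry = floor(sqrt(p_used))` recomputed from the
#' number of features actually supplied at fit time, and a minimal node size
#' of 5. Results are deterministic for a fixed `seed` and fixed `n_threads`;
#' across thread counts only statistical equivalence should be expected.
#'
#' @param n_trees Number of trees.
#' @param mtry Features tried per split; `NULL` (default) means
#'   `floor(sqrt(p_used))` at fit time.
#' @param min_node_size Minimal terminal node size.
#' @param seed Master seed; per-fit seeds are derived from it.
#' @param n_threads Threads passed to the forest backend.
#' @return A list of class `forest_config`.
#' @export
forest_config <- function(n_trees = 500, mtry = NULL, min_node_size = 5,
                          seed = 1, n_threads = 1) {
  stopifnot(n_trees >= 1, min_node_size >= 1, n_threads >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_node_size = as.integer(min_node_size),
                 seed = as.integer(seed),
                 n_threads = as.integer(n_threads)),
            class = "forest_config")
}

#' Fit a regression forest on selected SNPs and individuals
#'
#' Trains a bootstrap regression forest (via \pkg{ranger}) on the
#' `feature_idx` columns of the `train_idx` rows. Predictions are the mean
#' over trees.
#'
#' @param g A [genotype_matrix] (no missing values among the used cells).
#' @param phenotype Numeric phenotype aligned with `g`.
#' @param feature_idx SNP column indices to use (non-empty).
#' @param train_idx Individual row indices to train on.
#' @param cfg A [forest_config].
#' @param seed Seed for this particular fit; defaults to `cfg$seed`.
#' @return An object of class `ifs_forest` wrapping the fitted backend
#'   model and the feature set.
#' @export
fit_forest <- function(g, phenotype, feature_idx,
                       train_idx = seq_along(phenotype), cfg = forest_config(),
                       seed = cfg$seed) {
  stopifnot(inherits(g, "genotype_matrix"), length(feature_idx) >= 1,
            length(phenotype) == nrow(g$dosages))
  feature_idx <- as.integer(feature_idx)
  train_idx <- as.integer(train_idx)
  X <- g$dosages[train_idx, feature_idx, drop = FALSE]
  storage.mode(X) <- "double"
  colnames(X) <- paste0("f", feature_idx)
  y <- phenotype[train_idx]
  if (anyNA(X) || anyNA(y)) stop("missing values in training data")
  p_used <- length(feature_idx)
  mtry <- if (is.null(cfg$mtry)) max(1L, floor(sqrt(p_used))) else
    min(cfg$mtry, p_used)
  fit <- ranger::ranger(x = X, y = y,
                        num.trees = cfg$n_trees,
                        mtry = mtry,
                        min.node.size = cfg$min_node_size,
                        replace = TRUE,
                        num.threads = cfg$n_threads,
                        seed = seed,
                        oob.error = FALSE)
  structure(list(model = fit, feature_idx = feature_idx, mtry = mtry,
                 cfg = cfg),
            class = "ifs_forest")
}

#' Predict phenotypes for selected individuals
#'
#' @param object An `ifs_forest` from [fit_forest].
#' @param g The [genotype_matrix] to predict from (same SNP columns as at
#'   fit time).
#' @param idx Individual row indices to predict; defaults to all.
#' @param ... Ignored.
#' @return Numeric vector, one prediction per requested individual.
#' @export
predict.ifs_forest <- function(object, g, idx = seq_len(nrow(g$dosages)),
                               ...) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (max(object$feature_idx) > ncol(g$dosages)) {
    stop("genotype matrix has fewer SNPs than the model's feature set")
  }
  X <- g$dosages[as.integer(idx), object$feature_idx, drop = FALSE]
  storage.mode(X) <- "double"
  colnames(X) <- paste0("f", object$feature_idx)
  if (anyNA(X)) stop("missing values in prediction data")
  as.numeric(stats::predict(object$model, data = X,
                            num.threads = object$cfg$n_threads)$predictions)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` computed on observed/predicted pairs. This is
#' not a squared correlation: it can be negative whenever the predictions
#' are worse than simply predicting the mean of the observations, and such
#' negative values are propagated unclipped throughout the pipeline.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return A single number `<= 1`.
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("R^2 undefined: observed values have zero variance")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Pearson correlation between observed and predicted values
#'
#' Offered as an alternative reporting metric only; note that `R^2` equals
#' the square of `r` only for unconstrained linear regression fits.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return The sample correlation, or `NA` with a warning when either
#'   vector is constant.
#' @export
pearson_r <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    warning("correlation undefined for constant input")
    return(NA_real_)
  }
  stats::cor(observed, predicted)
}
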