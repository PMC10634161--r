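# Incremental feature selection: step schedule and repeated-CV accuracy curve.

#' Default step-size regimes for the incremental sweep
#'
#' Each row is `(upper_bound, step_size)`: marker counts advance by
#' `step_size` until `upper_bound`, then the next regime takes over. The
#' `"full"` profile uses step 1 until 100 markers, 5 until 500, 10 until
#' 1000, 50 until 5000, 100 until 10,000, 500 until 50,000, 1000 until
#' 100,000 and 5000 beyond that. The `"test"` profile is a coarser grid
#' (step 1 until 10, 5 until 50, 10 until 100, 50 until 500, 100 until
#' 1000, 500 until 5000, 1000 until 10,000, 5000 beyond) that traces the
#' same accuracy trend with far fewer model fits — useful for test suites
#' and quick first passes.
#'
#' @param profile `"full"` or `"test"`.
#' @return Two-column matrix with columns `upper`, `step`.
#' @export
default_regimes <- function(profile = c("full", "test")) {
  profile <- match.arg(profile)
  reg <- switch(profile,
    full = cbind(upper = c(100, 500, 1000, 5000, 1e4, 5e4, 1e5, Inf),
                 step  = c(1,   5,   10,   50,   100, 500, 1000, 5000)),
    test = cbind(upper = c(10, 50, 100, 500, 1000, 5000, 1e4, Inf),
                 step  = c(1,  5,  10,  50,  100,  500,  1000, 5000)))
  reg
}

#' Build the marker-count schedule for an incremental sweep
#'
#' Produces the strictly increasing sequence of SNP counts at which models
#' are trained: starting from 1, counts advance by each regime's step size
#' up to its upper bound, values are capped at `p`, and `p` itself is
#' appended if not already present — so the final point is always the
#' all-SNP model.
#'
#' @param p Total number of SNPs (>= 1).
#' @param regimes Two-column matrix `(upper, step)` with increasing bounds
#'   and positive steps; see [default_regimes].
#' @return Integer vector of SNP counts, first element 1, last element `p`.
#' @export
build_schedule <- function(p, regimes = default_regimes("full")) {
  p <- as.integer(p)
  if (is.na(p) || p < 1) stop("p must be a positive integer")
  regimes <- as.matrix(regimes)
  stopifnot(ncol(regimes) == 2, all(regimes[, 2] > 0),
            !is.unsorted(regimes[, 1], strictly = TRUE))
  counts <- integer()
  cur <- 0
  for (r in seq_len(nrow(regimes))) {
    upper <- min(regimes[r, 1], p)
    step <- regimes[r, 2]
    if (cur + step <= upper) {
      new <- seq(cur + step, upper, by = step)
      counts <- c(counts, new)
      cur <- new[length(new)]
    } else {
      cur <- max(cur, min(regimes[r, 1], p))
    }
    if (cur >= p) break
  }
  counts <- as.integer(counts)
  if (!length(counts) || counts[length(counts)] != p) counts <- c(counts, p)
  counts
}

#' Cross-validation plan with repeated random fold assignments
#'
#' For each repetition, individuals are randomly partitioned into
#' `n_folds` folds whose sizes differ by at most one. With the default
#' 5 folds, each training set is 80% of the individuals and each test fold
#' the remaining 20%.
#'
#' @param n Number of individuals.
#' @param n_folds Folds per repetition (default 5).
#' @param n_reps Repetitions with freshly shuffled individuals (default 10).
#' @param seed Seed making the plan reproducible.
#' @return Object of class `cv_plan`: list with `assignments` (an
#'   `n x n_reps` integer matrix of fold labels), `n_folds`, `n_reps`,
#'   `seed`.
#' @export
make_cv_plan <- function(n, n_folds = 5, n_reps = 10, seed = 1) {
  stopifnot(n >= n_folds, n_folds >= 2, n_reps >= 1)
  old_seed <- .GlobalEnv$.Random.seed
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = .GlobalEnv))
  set.seed(seed)
  assignments <- vapply(seq_len(n_reps), function(r) {
    rep_len(seq_len(n_folds), n)[sample.int(n)]
  }, integer(n))
  structure(list(assignments = assignments, n_folds = as.integer(n_folds),
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "cv_plan")
}

#' Run the incremental feature selection sweep
#'
#' The core procedure: for every repetition and fold, a GWAS scan and SNP
#' ranking are computed on that fold's training individuals only — the test
#' fold contributes to neither the ranking nor any model fit, which is what
#' keeps the accuracy estimates honest. For every SNP count `s` in the
#' schedule, a forest is trained on the top-`s` ranked SNPs and the held-out
#' fold is predicted. Within each repetition the out-of-fold predictions
#' from all folds are pooled and a single `R^2` against the observed
#' phenotypes is computed per `s`; the curve reports the mean and standard
#' error of those per-repetition values. The final schedule point (`s = p`)
#' is the all-SNP baseline.
#'
#' @param g A [genotype_matrix] without missing values.
#' @param phenotype Numeric phenotype aligned with `g`.
#' @param schedule Integer vector from [build_schedule].
#' @param plan A [make_cv_plan] object for the same `n`.
#' @param cfg A [forest_config].
#' @param per_fold If `TRUE`, compute `R^2` per fold and average within each
#'   repetition instead of pooling out-of-fold predictions.
#' @param fit_callback Optional function called before every forest fit with
#'   `(rep, fold, s, train_idx, test_idx, ranking)`; used for structural
#'   audits of the procedure (e.g. leakage checks) and cost accounting.
#' @return Object of class `ifs_curve`: list with `snp_counts`, `mean_r2`,
#'   `se_r2`, `per_repetition_r2` (`length(schedule) x n_reps` matrix),
#'   `n_models` (total forests fitted), `plan`, `p`.
#' @export
run_ifs <- function(g, phenotype, schedule, plan, cfg = forest_config(),
                    per_fold = FALSE, fit_callback = NULL) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(plan, "cv_plan"),
            nrow(plan$assignments) == length(phenotype),
            length(phenotype) == nrow(g$dosages))
  if (anyNA(g$dosages) || anyNA(phenotype)) {
    stop("missing values present; run filter_missing first")
  }
  schedule <- as.integer(schedule)
  p <- ncol(g$dosages)
  stopifnot(!is.unsorted(schedule, strictly = TRUE),
            schedule[length(schedule)] <= p)
  n <- length(phenotype)
  n_s <- length(schedule)
  per_rep <- matrix(NA_real_, n_s, plan$n_reps)
  n_models <- 0L
  seed_counter <- 0L

  for (r in seq_len(plan$n_reps)) {
    fold_of <- plan$assignments[, r]
    pooled <- matrix(NA_real_, n, n_s)        # out-of-fold predictions
    fold_r2 <- matrix(NA_real_, plan$n_folds, n_s)
    for (f in seq_len(plan$n_folds)) {
      test_idx <- which(fold_of == f)
      train_idx <- which(fold_of != f)
      ranking <- rank_snps(gwas_scan(g, phenotype, train_idx))
      for (si in seq_len(n_s)) {
        s <- schedule[si]
        feats <- ranking[seq_len(s)]
        if (!is.null(fit_callback)) {
          fit_callback(r, f, s, train_idx, test_idx, ranking)
        }
        seed_counter <- seed_counter + 1L
        fit <- fit_forest(g, phenotype, feats, train_idx, cfg,
                          seed = cfg$seed + seed_counter)
        preds <- predict(fit, g, test_idx)
        n_models <- n_models + 1L
        pooled[test_idx, si] <- preds
        if (per_fold) {
          fold_r2[f, si] <- r_squared(phenotype[test_idx], preds)
        }
      }
    }
    per_rep[, r] <- if (per_fold) {
      colMeans(fold_r2)
    } else {
      vapply(seq_len(n_s), function(si) r_squared(phenotype, pooled[, si]),
             numeric(1))
    }
  }

  mean_r2 <- rowMeans(per_rep)
  se_r2 <- apply(per_rep, 1, stats::sd) / sqrt(plan$n_reps)
  structure(list(snp_counts = schedule, mean_r2 = mean_r2, se_r2 = se_r2,
                 per_repetition_r2 = per_rep, n_models = n_models,
                 plan = plan, p = p),
            class = "ifs_curve")
}

#' @export
print.ifs_curve <- function(x, ...) {
  best <- which.max(x$mean_r2)
  cat("ifs_curve:", length(x$snp_counts), "schedule points,",
      ncol(x$per_repetition_r2), "CV repetitions,",
      x$n_models, "models fitted\n")
  cat("  raw best mean R^2 =", round(x$mean_r2[best], 4), "at",
      x$snp_counts[best], "SNPs; all-SNP mean R^2 =",
      round(x$mean_r2[length(x$mean_r2)], 4), "\n")
  invisible(x)
}

#' Export an accuracy curve as TSV
#'
#' Columns `n_snps`, `mean_r2`, `se_r2` plus one `rep_k` column per CV
#' repetition.
#'
#' @param curve An `ifs_curve`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "ifs_curve"))
  reps <- as.data.frame(curve$per_repetition_r2)
  names(reps) <- paste0("rep_", seq_along(reps))
  out <- cbind(data.frame(n_snps = curve$snp_counts,
                          mean_r2 = curve$mean_r2,
                          se_r2 = curve$se_r2), reps)
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
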