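# Hold-out evaluation: select on the 80% partition, report on the 20%.

#' Split individuals into an 80%/20% hold-out partition
#'
#' The larger part (phi) is used for feature selection and model training;
#' the smaller (psi) only for the final performance report. The phi size is
#' `round-half-up(0.8 * n)`; the split is a deterministic function of the
#' seed.
#'
#' @param n Number of individuals (>= 10).
#' @param seed Integer seed.
#' @return List with integer index vectors `phi` and `psi`: disjoint,
#'   covering `1..n`.
#' @export
split_phi_psi <- function(n, seed = 1) {
  if (n < 10) stop("need at least 10 individuals for an 80/20 split")
  old_seed <- .GlobalEnv$.Random.seed
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = .GlobalEnv))
  set.seed(seed)
  n_phi <- floor(0.8 * n + 0.5)
  perm <- sample.int(n)
  list(phi = sort(perm[seq_len(n_phi)]),
       psi = sort(perm[(n_phi + 1):n]))
}

#' Run the full hold-out evaluation of incremental feature selection
#'
#' The complete protocol: individuals are split 80%/20% into phi/psi; the
#' incremental sweep ([run_ifs]) with repeated cross-validation runs on phi
#' only and the smoothed accuracy curve picks an optimal SNP count
#' ([select_optimum]); a fresh GWAS ranking on all of phi chooses the final
#' top SNPs; one forest is trained on phi with those SNPs and one with all
#' SNPs; both are evaluated once on psi with [r_squared]. The psi
#' individuals touch nothing before that final prediction. When the
#' selection recommends using all SNPs, the selected-model entry is
#' reported as `NA` since it would duplicate the baseline column.
#'
#' @param g A [genotype_matrix] without missing values (see
#'   [filter_missing]).
#' @param phenotype Numeric phenotype aligned with `g`.
#' @param regimes Step-size regimes for [build_schedule].
#' @param n_folds,n_reps Cross-validation layout for the sweep.
#' @param cfg A [forest_config].
#' @param seed Master seed; the phi/psi split, CV plan and forest fits all
#'   derive from it.
#' @param x_scale,bass Passed to [select_optimum].
#' @param per_fold Passed to [run_ifs].
#' @return Object of class `ifs_report`: list with `n_selected`,
#'   `pct_selected`, `r2_selected_psi` (`NA` when all SNPs are
#'   recommended), `r2_all_psi`, `advantage` (`NA` likewise),
#'   `use_all_snps`, `selected_snp_ids`, `curve`, `selection`, `split`,
#'   `n_individuals`, `n_snps` and `seeds`.
#' @export
evaluate_ifs <- function(g, phenotype, regimes = default_regimes("full"),
                         n_folds = 5, n_reps = 10, cfg = forest_config(),
                         seed = 1, x_scale = c("log", "linear"), bass = 0,
                         per_fold = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"),
            length(phenotype) == nrow(g$dosages))
  if (anyNA(g$dosages) || anyNA(phenotype)) {
    stop("missing values present; run filter_missing first")
  }
  x_scale <- match.arg(x_scale)
  n <- length(phenotype)
  p <- ncol(g$dosages)

  seeds <- list(master = seed, split = seed, cv_plan = seed + 1L,
                forest = cfg$seed)
  split <- split_phi_psi(n, seed = seeds$split)
  g_phi <- g[split$phi, ]
  y_phi <- phenotype[split$phi]

  schedule <- build_schedule(p, regimes)
  plan <- make_cv_plan(length(split$phi), n_folds, n_reps,
                       seed = seeds$cv_plan)
  curve <- run_ifs(g_phi, y_phi, schedule, plan, cfg, per_fold = per_fold)
  selection <- select_optimum(curve, x_scale = x_scale, bass = bass)

  # final ranking from a GWAS on all of phi (psi untouched)
  ranking_phi <- rank_snps(gwas_scan(g_phi, y_phi))
  n_sel <- selection$optimal_count
  selected_ids <- g$snp_meta$id[ranking_phi[seq_len(n_sel)]]

  fit_all <- fit_forest(g, phenotype, seq_len(p), split$phi, cfg,
                        seed = cfg$seed + 1L)
  r2_all <- r_squared(phenotype[split$psi], predict(fit_all, g, split$psi))

  if (selection$use_all_snps) {
    r2_sel <- NA_real_
    advantage <- NA_real_
  } else {
    fit_sel <- fit_forest(g, phenotype, ranking_phi[seq_len(n_sel)],
                          split$phi, cfg, seed = cfg$seed + 2L)
    r2_sel <- r_squared(phenotype[split$psi], predict(fit_sel, g, split$psi))
    advantage <- r2_sel - r2_all
  }

  structure(list(n_selected = n_sel,
                 pct_selected = 100 * n_sel / p,
                 r2_selected_psi = r2_sel,
                 r2_all_psi = r2_all,
                 advantage = advantage,
                 use_all_snps = selection$use_all_snps,
                 selected_snp_ids = selected_ids,
                 curve = curve, selection = selection, split = split,
                 n_individuals = n, n_snps = p, seeds = seeds),
            class = "ifs_report")
}

#' @export
print.ifs_report <- function(x, ...) {
  cat("ifs_report:", x$n_individuals, "individuals x", x$n_snps, "SNPs\n")
  cat("  selected SNPs:", x$n_selected,
      sprintf("(%.2f%%)", x$pct_selected), "\n")
  if (x$use_all_snps) {
    cat("  selection recommends all SNPs; R^2 (selected) = -\n")
  } else {
    cat("  R^2 on held-out 20% (selected SNPs):",
        sprintf("%.3f", x$r2_selected_psi), "\n")
  }
  cat("  R^2 on held-out 20% (all SNPs):   ",
      sprintf("%.3f", x$r2_all_psi), "\n")
  if (!is.na(x$advantage)) {
    cat("  advantage (selected - all):       ",
        sprintf("%+.3f", x$advantage), "\n")
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes `report.json` (scalar summary, seeds, selected SNP identifiers),
#' `curve.tsv` (the accuracy curve with per-repetition columns) and
#' `selected_snps.txt` (ranked selected identifiers, one per line) into
#' `dir`.
#'
#' @param report An `ifs_report`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ifs_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  curve_path <- file.path(dir, "curve.tsv")
  snp_path <- file.path(dir, "selected_snps.txt")
  scalar <- report[c("n_selected", "pct_selected", "r2_selected_psi",
                     "r2_all_psi", "advantage", "use_all_snps",
                     "n_individuals", "n_snps")]
  jsonlite::write_json(list(summary = scalar, seeds = report$seeds,
                            selected_snp_ids = report$selected_snp_ids,
                            split = report$split),
                       json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  write_curve(report$curve, curve_path)
  writeLines(report$selected_snp_ids, snp_path)
  invisible(c(json_path, curve_path, snp_path))
}

#' Read back a written evaluation report
#'
#' Restores the scalar summary, seeds, selected identifiers, split and the
#' accuracy curve from a directory written by [write_report].
#'
#' @param dir Directory containing `report.json` and `curve.tsv`.
#' @return List with `summary`, `seeds`, `selected_snp_ids`, `split` and
#'   `curve` (data frame).
#' @export
read_report <- function(dir) {
  js <- jsonlite::read_json(file.path(dir, "report.json"),
                            simplifyVector = TRUE)
  js$curve <- utils::read.table(file.path(dir, "curve.tsv"), header = TRUE,
                                sep = "\t")
  js
}
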