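# Variable-span (Friedman) super smoother and smoothed-maximum selection.

# Running local-linear smooth with symmetric nearest-neighbour windows of
# half-width `half`, truncated at the boundaries. Returns the fitted values
# and the absolute leave-one-out cross-validated residuals (obtained from
# the in-window leverage, so no refitting is needed).
.running_linear <- function(x, y, half) {
  n <- length(x)
  cx <- cumsum(c(0, x)); cx2 <- cumsum(c(0, x^2))
  cy <- cumsum(c(0, y)); cxy <- cumsum(c(0, x * y))
  fit <- numeric(n)
  loo <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    m <- hi - lo + 1L
    sx <- cx[hi + 1L] - cx[lo]
    sx2 <- cx2[hi + 1L] - cx2[lo]
    sy <- cy[hi + 1L] - cy[lo]
    sxy <- cxy[hi + 1L] - cxy[lo]
    xb <- sx / m
    sxx <- sx2 - sx^2 / m
    if (sxx <= .Machine$double.eps * max(1, sx2)) {
      fit[i] <- sy / m
      hii <- 1 / m
    } else {
      b <- (sxy - sx * sy / m) / sxx
      fit[i] <- sy / m + b * (x[i] - xb)
      hii <- 1 / m + (x[i] - xb)^2 / sxx
    }
    denom <- max(1 - hii, 1e-8)
    loo[i] <- abs(y[i] - fit[i]) / denom
  }
  list(fit = fit, loo = loo)
}

# Leave-one-out-selected running-line smooth: fallback for short inputs.
.short_smooth <- function(x, y) {
  n <- length(x)
  if (n <= 2) return(list(smoothed = y, span = rep(1, n)))
  halves <- seq_len(n - 1L)
  sse <- vapply(halves, function(h) sum(.running_linear(x, y, h)$loo^2),
                numeric(1))
  best <- halves[which.min(sse)]
  list(smoothed = .running_linear(x, y, best)$fit,
       span = rep(min(1, 2 * best / n), n))
}

#' Variable-span super smoother
#'
#' Friedman's scatterplot smoother: running local-linear smooths are
#' computed at three spans (fractions 0.05, 0.2 and 0.5 of the data, the
#' "tweeter", "midrange" and "woofer"), the leave-one-out absolute residual
#' of each span is itself smoothed against `x` with the midrange span, each
#' point picks the span with the smallest cross-validated residual, that
#' span sequence is smoothed with the midrange span, and the final value at
#' each point is interpolated between the smooths of the two bracketing
#' spans. A last pass with the tweeter span polishes the interpolated
#' values. The `bass` parameter (0 to 10) biases the per-point span choice
#' toward the woofer for smoother output: the chosen span is moved toward
#' 0.5 by the factor `(e_best/e_woofer)^(10 - bass)`.
#'
#' Inputs with fewer than 5 points fall back to a single running-line
#' smooth whose half-width is chosen by leave-one-out cross-validation;
#' 1- and 2-point inputs pass through unchanged.
#'
#' @param x Strictly increasing numeric vector.
#' @param y Numeric response, same length, no `NA`/`NaN`.
#' @param bass Span-bias parameter in `[0, 10]`; 0 (default) disables it.
#' @param spans The three ascending span fractions.
#' @return Object of class `smoothed_curve`: list with `x`, `y`, `smoothed`
#'   and `span` (the per-point span actually used).
#' @export
supersmooth <- function(x, y, bass = 0, spans = c(0.05, 0.2, 0.5)) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n == 0) stop("empty input")
  if (anyNA(x) || anyNA(y) || any(!is.finite(y))) stop("NA/NaN in input")
  if (is.unsorted(x, strictly = TRUE)) stop("x must be strictly increasing")
  stopifnot(length(spans) == 3, !is.unsorted(spans, strictly = TRUE),
            bass >= 0, bass <= 10)

  if (n < 5) {
    res <- .short_smooth(x, y)
    return(structure(list(x = x, y = y, smoothed = res$smoothed,
                          span = res$span),
                     class = "smoothed_curve"))
  }

  halves <- pmax(2L, as.integer(floor(spans * n / 2)))
  sm <- lapply(halves, function(h) .running_linear(x, y, h))
  mid <- halves[2]
  # cross-validated absolute residuals, smoothed over x at the midrange span
  e <- vapply(sm, function(s) .running_linear(x, s$loo, mid)$fit, numeric(n))
  e <- pmax(e, 0)

  best <- max.col(-e, ties.method = "first")
  span_i <- spans[best]
  if (bass > 0) {
    e_best <- e[cbind(seq_len(n), best)]
    e_woof <- e[, 3]
    ratio <- ifelse(e_woof > 0, pmin(e_best / e_woof, 1), 1)
    span_i <- span_i + (spans[3] - span_i) * ratio^(10 - bass)
  }
  span_bar <- .running_linear(x, span_i, mid)$fit
  span_bar <- pmin(pmax(span_bar, spans[1]), spans[3])

  fits <- vapply(sm, `[[`, numeric(n), "fit")
  smoothed <- numeric(n)
  lowband <- span_bar <= spans[2]
  f_lo <- (span_bar - spans[1]) / (spans[2] - spans[1])
  f_hi <- (span_bar - spans[2]) / (spans[3] - spans[2])
  smoothed[lowband] <- (1 - f_lo[lowband]) * fits[lowband, 1] +
    f_lo[lowband] * fits[lowband, 2]
  smoothed[!lowband] <- (1 - f_hi[!lowband]) * fits[!lowband, 2] +
    f_hi[!lowband] * fits[!lowband, 3]

  smoothed <- .running_linear(x, smoothed, halves[1])$fit
  structure(list(x = x, y = y, smoothed = smoothed, span = span_bar),
            class = "smoothed_curve")
}

#' @export
print.smoothed_curve <- function(x, ...) {
  cat("smoothed_curve:", length(x$x), "points; span range",
      paste(round(range(x$span), 3), collapse = "-"), "\n")
  invisible(x)
}

#' Pick the optimal SNP count from a smoothed accuracy curve
#'
#' Smooths the mean `R^2` values of an [run_ifs] curve (against
#' `log10(snp_counts)` by default, matching the geometric spacing of the
#' schedule's upper range) and returns the SNP count at the maximum of the
#' smoothed values. Ties are broken toward the smallest SNP count
#' (parsimony). When the maximum falls on the final schedule point, the
#' procedure recommends using all SNPs and `use_all_snps` is set.
#'
#' @param curve An `ifs_curve`.
#' @param x_scale `"log"` (default) or `"linear"` x-axis for smoothing.
#' @param bass Passed to [supersmooth].
#' @return Object of class `ifs_selection`: list with `optimal_count`,
#'   `optimal_smoothed_r2`, `use_all_snps`, and `smoothed` (the
#'   `smoothed_curve` over the schedule).
#' @export
select_optimum <- function(curve, x_scale = c("log", "linear"), bass = 0) {
  stopifnot(inherits(curve, "ifs_curve"))
  x_scale <- match.arg(x_scale)
  xs <- if (x_scale == "log") log10(curve$snp_counts) else
    as.numeric(curve$snp_counts)
  sm <- supersmooth(xs, curve$mean_r2, bass = bass)
  # ties (within floating-point noise of the maximum) go to the smallest count
  m <- max(sm$smoothed)
  tol <- 1e-8 * max(abs(m), diff(range(sm$smoothed)), 1e-8)
  best <- which(sm$smoothed >= m - tol)[1]
  structure(list(optimal_count = curve$snp_counts[best],
                 optimal_smoothed_r2 = sm$smoothed[best],
                 use_all_snps = best == length(curve$snp_counts) &&
                   curve$snp_counts[best] == curve$p,
                 smoothed = structure(list(snp_counts = curve$snp_counts,
                                           smoothed_r2 = sm$smoothed,
                                           span_used = sm$span,
                                           x = sm$x),
                                      class = "smoothed_curve")),
            class = "ifs_selection")
}

#' @export
print.ifs_selection <- function(x, ...) {
  cat("ifs_selection: optimal SNP count =", x$optimal_count,
      "(smoothed R^2 =", round(x$optimal_smoothed_r2, 4), ")",
      if (x$use_all_snps) "- all SNPs recommended" else "", "\n")
  invisible(x)
}

#' Plot an accuracy curve with its smoothed trend
#'
#' Mean `R^2` against the (log-scaled) number of SNPs with the smoothed
#' trend, a vertical line at the selected optimum and a horizontal band for
#' the all-SNP baseline (mean plus/minus one standard error over CV
#' repetitions).
#'
#' @param x An `ifs_curve`.
#' @param selection Optional `ifs_selection` for the optimum line; computed
#'   with defaults when omitted.
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.ifs_curve <- function(x, selection = NULL, ...) {
  if (is.null(selection)) selection <- select_optimum(x)
  lx <- log10(x$snp_counts)
  last <- length(x$snp_counts)
  plot(lx, x$mean_r2, pch = 16, cex = 0.6, col = "grey40",
       xlab = "log10(number of SNPs)", ylab = expression(mean ~ R^2), ...)
  base <- x$mean_r2[last]
  se <- x$se_r2[last]
  graphics::rect(min(lx), base - se, max(lx), base + se,
                 col = grDevices::adjustcolor("grey", 0.4), border = NA)
  graphics::abline(h = base, col = "black")
  graphics::lines(lx, selection$smoothed$smoothed_r2, lwd = 2)
  graphics::abline(v = log10(selection$optimal_count), col = "darkgreen")
  invisible(x)
}
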