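#' Assign CPS values to equal-width bins
#'
#' Bin i covers `[i/n, (i+1)/n)` with the last bin closed at 1, so 0 falls in
#' bin 0 and 1 in bin `n_bins - 1`.
#'
#' @param cps_values numeric vector in `[0, 1]`.
#' @param n_bins number of equal bins (default 5).
#' @return Integer bin labels in `0:(n_bins - 1)`.
#' @examples
#' bin_cps(c(0, 0.2, 0.5, 1))  # 0 1 2 4
#' @export
bin_cps <- function(cps_values, n_bins = 5L) {
  if (any(!is.finite(cps_values)) || any(cps_values < 0 | cps_values > 1))
    stop("CPS values must lie in [0, 1]")
  as.integer(pmin(floor(cps_values * n_bins), n_bins - 1L))
}

#' Per-bin change test against the lowest-CPS bin
#'
#' Divides the CPS range into `n_bins` equal bins and fits the additive
#' piecewise-constant model `y ~ 1 + indicator(bin)` by least squares with
#' bin 0 (the least-affected donors) as reference. Each non-reference bin's
#' coefficient is the mean change relative to bin 0, tested with a two-tailed
#' t-statistic on the residual degrees of freedom. Bins with fewer than two
#' observations are flagged untested. Multiple-testing correction across a
#' batch of variables is applied by [per_bin_change_batch()].
#'
#' @param y numeric response (one variable's values across donors).
#' @param cps numeric CPS values in `[0, 1]`, same length as `y`.
#' @param n_bins number of equal CPS bins.
#' @return Data frame with one row per non-reference bin: `bin`, `n`,
#'   `effect`, `t`, `p`, `tested`, plus attribute `degenerate` if the fit
#'   had zero residual variance.
#' @export
per_bin_change_test <- function(y, cps, n_bins = 5L) {
  ok <- is.finite(y) & is.finite(cps)
  y <- y[ok]; cps <- cps[ok]
  bins <- bin_cps(cps, n_bins)
  tab <- tabulate(bins + 1L, n_bins)
  if (tab[1] < 2) stop("need at least 2 observations in the reference bin")
  if (sum(tab >= 2) < 2) stop("all observations fall in a single bin")
  testable <- which(tab[-1] >= 2)  # indices into bins 1..n_bins-1
  use <- bins == 0L | bins %in% testable
  f <- factor(bins[use], levels = c(0L, testable))
  fit <- stats::lm(y[use] ~ f)
  sm <- suppressWarnings(summary(fit))$coefficients  # perfect fits warn
  degenerate <- stats::sigma(fit) < sqrt(.Machine$double.eps)
  res <- data.frame(bin = seq_len(n_bins - 1L), n = tab[-1],
                    effect = NA_real_, t = NA_real_, p = NA_real_,
                    tested = FALSE)
  for (i in seq_along(testable)) {
    b <- testable[i]
    row <- which(rownames(sm) == paste0("f", b))
    res$effect[b] <- sm[row, 1]
    res$t[b] <- sm[row, 3]
    res$p[b] <- if (degenerate) as.numeric(sm[row, 1] == 0) else sm[row, 4]
    res$tested[b] <- TRUE
  }
  attr(res, "degenerate") <- degenerate
  res
}

#' Batch per-bin change tests with Benjamini-Hochberg correction
#'
#' Runs [per_bin_change_test()] for every variable of a [variable_matrix()]
#' against a common CPS vector, adjusts all p-values jointly by
#' Benjamini-Hochberg, and reports each variable's first significant bin at
#' level `alpha`.
#'
#' @param matrix a [variable_matrix()] (typically raw or z-scored values).
#' @param cps per-donor CPS values aligned with the matrix rows.
#' @param n_bins number of equal CPS bins.
#' @param alpha significance level applied to adjusted p-values.
#' @return List: `tests` (data frame variable, bin, n, effect, t, p, p_adj,
#'   significant), `first_significant` (named integer, `NA` when none).
#' @export
per_bin_change_batch <- function(matrix, cps, n_bins = 5L, alpha = 0.05) {
  stopifnot(inherits(matrix, "variable_matrix"),
            length(cps) == nrow(matrix$values))
  pieces <- lapply(seq_along(matrix$variable_names), function(v) {
    res <- per_bin_change_test(matrix$values[, v], cps, n_bins)
    res$variable <- matrix$variable_names[v]
    res
  })
  tests <- do.call(rbind, pieces)
  tests$p_adj <- NA_real_
  tested <- tests$tested
  tests$p_adj[tested] <- stats::p.adjust(tests$p[tested], method = "BH")
  tests$significant <- !is.na(tests$p_adj) & tests$p_adj < alpha
  first <- vapply(matrix$variable_names, function(v) {
    sig <- tests$bin[tests$variable == v & tests$significant]
    if (length(sig) == 0) NA_integer_ else min(sig)
  }, 0L)
  tests <- tests[, c("variable", "bin", "n", "effect", "t", "p", "p_adj",
                     "significant")]
  list(tests = tests, first_significant = first, alpha = alpha)
}

#' Subsample-bootstrap LOESS trend curve
#'
#' Repeats `n_boot` times: draw `floor(frac_subsample * n)` points without
#' replacement, fit a degree-1 LOESS (tricube weights, given span), and
#' evaluate on a common grid. Reports the pointwise mean curve and the
#' standard deviation across fits (the trend's standard error under
#' subsampling). Grid points outside a subsample's x-range are extrapolated
#' from the nearest local fit and counted in `n_extrapolated`.
#'
#' @param x,y numeric vectors (at least 10 points).
#' @param frac_subsample fraction of points per bootstrap fit.
#' @param n_boot number of subsample fits.
#' @param span LOESS span.
#' @param grid_size number of evaluation points spanning `range(x)`.
#' @param seed integer seed for the subsampling.
#' @return An object of class `trend_curve`: list with `grid`, `mean`, `se`,
#'   `n_boot`, `frac_subsample`, `span`, `seed`, `n_extrapolated`.
#' @export
loess_bootstrap <- function(x, y, frac_subsample = 0.8, n_boot = 1000L,
                            span = 0.6, grid_size = 100L, seed = 1L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("need at least 10 (x, y) pairs")
  stopifnot(frac_subsample > 0, frac_subsample <= 1, n_boot >= 1)
  grid <- seq(min(x), max(x), length.out = grid_size)
  m <- max(2L, floor(frac_subsample * n))
  fits <- matrix(NA_real_, n_boot, grid_size)
  n_extrap <- 0L
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, m)
    df <- data.frame(xx = x[idx], yy = y[idx])
    fit <- stats::loess(yy ~ xx, data = df, span = span, degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    outside <- grid < min(df$xx) | grid > max(df$xx)
    n_extrap <- n_extrap + sum(outside)
    fits[b, ] <- stats::predict(fit, data.frame(xx = grid))
  }
  structure(list(grid = grid, mean = colMeans(fits),
                 se = apply(fits, 2, stats::sd),
                 n_boot = n_boot, frac_subsample = frac_subsample,
                 span = span, seed = seed, n_extrapolated = n_extrap),
            class = "trend_curve")
}

#' @export
print.trend_curve <- function(x, ...) {
  cat(sprintf(
    "trend_curve: %d grid points, %d LOESS fits on %.0f%% subsamples (span %.2f)\n",
    length(x$grid), x$n_boot, 100 * x$frac_subsample, x$span))
  invisible(x)
}
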