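#' Root mean square relative error between two calibrated fields
#'
#' `rmsre = sqrt(mean(((x_i - xhat_i) / xbar_i)^2))` where
#' `xbar_i = (x_i + xhat_i) / 2` is the pairwise mean of the two values —
#' the mean-normalized form, which makes the statistic symmetric in its
#' arguments. Returned as a fraction (multiply by 100 for percent).
#'
#' @param x Numeric vector (conventionally the phantom-based values).
#' @param x_hat Numeric vector, same length (the phantomless values).
#' @return Non-negative scalar fraction.
#' @examples
#' rmsre(c(100), c(110))  # 10/105
#' @export
rmsre <- function(x, x_hat) {
  p <- .check_pairs(x, x_hat)
  sqrt(mean(((p$x - p$x_hat) / p$xbar)^2))
}

#' Point-wise relative differences between two calibrated fields
#'
#' Per item, `100 * |x_i - xhat_i| / xbar_i` with the pairwise mean
#' `xbar_i = (x_i + xhat_i) / 2` as normalizer (consistent with [rmsre()],
#' so that `rmsre` equals the root mean square of these values / 100).
#'
#' @inheritParams rmsre
#' @return Numeric vector of percentages.
#' @export
relative_differences <- function(x, x_hat) {
  p <- .check_pairs(x, x_hat)
  100 * abs(p$x - p$x_hat) / p$xbar
}

.check_pairs <- function(x, x_hat) {
  x <- as.numeric(x); x_hat <- as.numeric(x_hat)
  if (length(x) != length(x_hat))
    stop("`x` and `x_hat` must have equal length", call. = FALSE)
  if (length(x) < 1L) stop("empty input", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(x_hat)))
    stop("inputs must be finite", call. = FALSE)
  xbar <- (x + x_hat) / 2
  zero <- which(xbar == 0)
  if (length(zero))
    stop("pairwise mean is zero at index ", zero[1],
         "; relative difference undefined", call. = FALSE)
  list(x = x, x_hat = x_hat, xbar = xbar)
}

#' Interquartile-range outlier screen
#'
#' Partitions a sample into values kept and removed by the 1.5 IQR rule:
#' with Q1 and Q3 the 25th and 75th percentiles (linear interpolation
#' between order statistics, [stats::quantile()] type 7), values outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are removed. Fences are computed once on
#' the full input, not iteratively.
#'
#' @param values Numeric vector, length >= 4.
#' @return List with `kept`, `removed` (partitioning the input) and
#'   `fences` (length-2 numeric).
#' @examples
#' iqr_filter(c(1:9, 100))
#' @export
iqr_filter <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4L)
    stop("IQR screening needs at least 4 values, got ", length(values),
         call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
  keep <- values >= fences[1] & values <= fences[2]
  list(kept = values[keep], removed = values[!keep], fences = fences)
}

#' Regression agreement between two calibrated fields
#'
#' Ordinary least-squares regression of `y` on `x` with the coefficient of
#' determination, for agreement plots between phantom-based and phantomless
#' derived quantities.
#'
#' @param x Numeric vector (regressor; not constant), length >= 3.
#' @param y Numeric vector (response), same length.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
regression_agreement <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  if (length(x) < 3L)
    stop("regression needs at least 3 points", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite", call. = FALSE)
  if (stats::var(x) == 0)
    stop("`x` is constant; regression undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 1 else
    suppressWarnings(summary(fit)$r.squared)  # silence perfect-fit notice
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Compare two calibrated Young's-modulus fields
#'
#' Full agreement report between two [calibrated_modulus_field()] results on
#' the same mask: the mean-normalized RMSRE over all voxel pairs, point-wise
#' relative differences (summarized after the optional 1.5 IQR outlier
#' screen, which never touches the RMSRE), and the OLS regression agreement
#' of field b on field a.
#'
#' @param e_a,e_b Two `modulus_field` objects on identical masks
#'   (conventionally a = phantom-based, b = phantomless).
#' @param with_outlier_removal Apply [iqr_filter()] to the relative
#'   differences before summarizing them (default `TRUE`).
#' @return An object of class `comparison_report`: list with `rmsre`
#'   (fraction), `rmsre_pct`, `mean_rel_diff`, `median_rel_diff`,
#'   `max_rel_diff` (percent, post-screen), `n_total`,
#'   `n_outliers_removed`, `r_squared`, and `per_item_diffs` (all percent,
#'   unscreened).
#' @export
compare_fields <- function(e_a, e_b, with_outlier_removal = TRUE) {
  stopifnot(inherits(e_a, "modulus_field"), inherits(e_b, "modulus_field"))
  if (!identical(dim(e_a$mask), dim(e_b$mask)) || !identical(
    which(e_a$mask), which(e_b$mask)))
    stop("modulus fields are defined on different masks", call. = FALSE)
  x <- e_a$values; y <- e_b$values
  diffs <- relative_differences(x, y)
  if (with_outlier_removal && length(diffs) >= 4L) {
    scr <- iqr_filter(diffs)
    summ <- scr$kept
    n_removed <- length(scr$removed)
  } else {
    summ <- diffs
    n_removed <- 0L
  }
  reg <- regression_agreement(x, y)
  structure(list(rmsre = rmsre(x, y), rmsre_pct = 100 * rmsre(x, y),
                 mean_rel_diff = mean(summ),
                 median_rel_diff = stats::median(summ),
                 max_rel_diff = max(summ),
                 n_total = length(diffs),
                 n_outliers_removed = n_removed,
                 r_squared = reg$r_squared,
                 regression = reg,
                 per_item_diffs = diffs),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", x$n_total, " paired values\n", sep = "")
  cat(sprintf("  RMSRE: %.4f%%\n", x$rmsre_pct))
  cat(sprintf("  relative differences (%%): mean %.4f, median %.4f, max %.4f",
              x$mean_rel_diff, x$median_rel_diff, x$max_rel_diff))
  if (x$n_outliers_removed > 0)
    cat(" (", x$n_outliers_removed, " outliers screened)", sep = "")
  cat("\n")
  cat(sprintf("  regression agreement: R^2 = %.6f\n", x$r_squared))
  invisible(x)
}
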