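# Agreement and reliability statistics used to compare CLS procedures:
# Bland-Altman limits of agreement, Cronbach's alpha with the
# conventional interpretation bands, and root mean square error.

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b` between two aligned sets of measurements. The
#' bias is `mean(d)`; the 95% limits of agreement are
#' `bias +/- 1.96 sd(d)` when the differences pass a Kolmogorov-Smirnov
#' normality check (mean and SD estimated from the data, so the p-value
#' is approximate in the Lilliefors sense) and `bias +/- 2 sd(d)`
#' otherwise. The 95% confidence interval of the bias is
#' `bias +/- 1.96 sd(d) / sqrt(n)`; an interval excluding zero flags a
#' systematic error.
#'
#' @param a,b Equal-length numeric vectors (levels in dB SPL, aligned by
#'   subject and CU). Pairs with a missing value in either vector are
#'   dropped.
#' @return A list of class `bland_altman`: `bias`, `sd`, `loa_low`,
#'   `loa_high`, `loa_multiplier`, `bias_ci` (length 2), `normality_p`,
#'   `n`.
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 3L) {
    stop("Bland-Altman analysis needs at least 3 complete pairs",
         call. = FALSE)
  }
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  p <- if (s > 0) {
    suppressWarnings(stats::ks.test(d, "pnorm", bias, s)$p.value)
  } else {
    NA_real_
  }
  mult <- if (!is.na(p) && p < 0.05) 2 else 1.96
  structure(list(bias = bias,
                 sd = s,
                 loa_low = bias - mult * s,
                 loa_high = bias + mult * s,
                 loa_multiplier = mult,
                 bias_ci = c(bias - 1.96 * s / sqrt(n),
                             bias + 1.96 * s / sqrt(n)),
                 normality_p = p,
                 n = n),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, bias = %.3f, LOA = [%.3f, %.3f] (+/- %g SD)\n",
              x$n, x$bias, x$loa_low, x$loa_high, x$loa_multiplier))
  invisible(x)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability over k aligned measurement vectors:
#' `alpha = k / (k - 1) * (1 - sum(var_i) / var_total)` with sample
#' variances of the individual items and of the case-wise sum. Cases with
#' any missing item are dropped. The label follows the conventional
#' bands: >= 0.9 excellent, >= 0.8 good, >= 0.7 acceptable, >= 0.6
#' questionable, >= 0.5 poor, below that unacceptable.
#'
#' @param items A numeric matrix/data frame (cases x items) or a list of
#'   equal-length vectors; at least 2 items and 3 complete cases.
#' @return A list of class `cronbach_alpha`: `alpha`, `label`, `k`, `n`.
#' @export
#' @examples
#' cronbach_alpha(cbind(1:10, 1:10))  # identical items: alpha = 1
cronbach_alpha <- function(items) {
  if (is.list(items) && !is.data.frame(items)) {
    items <- do.call(cbind, items)
  }
  x <- as.matrix(items)
  storage.mode(x) <- "double"
  if (ncol(x) < 2L) {
    stop("Cronbach's alpha needs at least 2 items", call. = FALSE)
  }
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3L) {
    stop("Cronbach's alpha needs at least 3 complete cases", call. = FALSE)
  }
  k <- ncol(x)
  total_var <- stats::var(rowSums(x))
  if (total_var == 0) {
    stop("zero total variance: alpha is undefined", call. = FALSE)
  }
  alpha <- k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / total_var)
  label <- if (alpha >= 0.9) "excellent"
  else if (alpha >= 0.8) "good"
  else if (alpha >= 0.7) "acceptable"
  else if (alpha >= 0.6) "questionable"
  else if (alpha >= 0.5) "poor"
  else "unacceptable"
  structure(list(alpha = alpha, label = label, k = k, n = nrow(x)),
            class = "cronbach_alpha")
}

#' @export
print.cronbach_alpha <- function(x, ...) {
  cat(sprintf("<cronbach_alpha> alpha = %.4f (%s), k = %d items, n = %d cases\n",
              x$alpha, x$label, x$k, x$n))
  invisible(x)
}

#' Root mean square error
#'
#' `sqrt(mean((a - b)^2))` over complete pairs.
#'
#' @param a,b Equal-length numeric vectors; pairs with missing values are
#'   dropped.
#' @return RMSE in the units of the inputs (dB for level comparisons).
#' @export
rmse <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !(is.na(a) | is.na(b))
  if (!any(keep)) {
    stop("rmse needs at least one complete pair", call. = FALSE)
  }
  sqrt(mean((a[keep] - b[keep])^2))
}
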