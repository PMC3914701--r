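#' Bland-Altman method agreement
#'
#' Bias and 95% limits of agreement for paired measurements of the same
#' quantity by two methods (or occasions): `bias = mean(A - B)`,
#' `LoA = bias +/- 1.96 sd(A - B)`.
#'
#' @param data data frame of paired measurements.
#' @param a,b column names (tidy-eval) of the two measurements.
#' @param subject optional subject-id column.
#' @return object of class `bland_altman`; see [tidy()], [glance()],
#'   [autoplot()].
#' @examples
#' df <- data.frame(m1 = c(10, 12, 11), m2 = c(11, 12, 10))
#' glance(bland_altman(df, m1, m2))
#' @export
bland_altman <- function(data, a, b, subject = NULL) {
  av <- dplyr::pull(data, {{ a }})
  bv <- dplyr::pull(data, {{ b }})
  sid <- tryCatch(dplyr::pull(data, {{ subject }}), error = function(e) NULL)
  if (is.null(sid)) sid <- seq_along(av)
  if (length(av) != length(bv) || length(av) < 2)
    stop("need at least two complete pairs", call. = FALSE)
  if (any(!is.finite(av)) || any(!is.finite(bv)))
    stop("measurements must be finite", call. = FALSE)
  diffs <- av - bv
  bias <- mean(diffs)
  s <- sd(diffs)
  structure(list(
    pairs = tibble::tibble(subject = sid, a = av, b = bv,
                           mean = (av + bv) / 2, difference = diffs),
    bias = bias, sd_diff = s,
    loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
    n = length(av)), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman> n =", x$n, " bias =", signif(x$bias, 4),
      " LoA [", signif(x$loa_lower, 4), ",", signif(x$loa_upper, 4), "]\n")
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) x$pairs

#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd_diff = x$sd_diff,
                 loa_lower = x$loa_lower, loa_upper = x$loa_upper, n = x$n)
}

#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "mean of methods", y = "difference (A - B)",
                  title = "Bland-Altman agreement")
}

#' Intraclass correlation, two-way random, absolute agreement
#'
#' Single-measure ICC(2,1) (Shrout-Fleiss; ICC(A,1) in McGraw-Wong
#' notation) from the two-way ANOVA mean squares of an n-subjects x
#' k-occasions table:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' with the standard F-distribution confidence bounds.
#'
#' @param data data frame or matrix with one column per occasion/rater and
#'   one row per subject (n >= 3, k = 2 occasions for test-retest use).
#' @param conf_level confidence level for the interval.
#' @return object of class `icc`; `glance()` gives a one-row tibble.
#' @examples
#' m <- cbind(c(10, 12, 14, 16), c(11, 12, 15, 15))
#' glance(icc_absolute_agreement(m))
#' @export
icc_absolute_agreement <- function(data, conf_level = 0.95) {
  m <- as.matrix(data)
  storage.mode(m) <- "double"
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2) stop("need >= 3 subjects and >= 2 occasions", call. = FALSE)
  if (any(!is.finite(m))) stop("values must be finite", call. = FALSE)
  G <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  ssr <- k * sum((rowm - G)^2)
  ssc <- n * sum((colm - G)^2)
  sst <- sum((m - G)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr < 1e-12 * max(1, mse))
    stop("degenerate ICC: no between-subject variance", call. = FALSE)
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # McGraw & Wong confidence bounds for ICC(A,1); the interval degenerates
  # when there is no residual variance at all
  if (1 - icc < 1e-12) {
    return(structure(list(icc = icc, ci_lower = icc, ci_upper = icc,
                          conf_level = conf_level, msr = msr, msc = msc,
                          mse = mse, n = n, k = k), class = "icc"))
  }
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  structure(list(icc = icc, ci_lower = lower, ci_upper = upper,
                 conf_level = conf_level, msr = msr, msc = msc, mse = mse,
                 n = n, k = k), class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat("<icc(2,1) absolute agreement> ", signif(x$icc, 4), " (",
      100 * x$conf_level, "% CI ", signif(x$ci_lower, 4), " - ",
      signif(x$ci_upper, 4), "), n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' @export
glance.icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                 conf_level = x$conf_level, msr = x$msr, msc = x$msc,
                 mse = x$mse, n_subjects = x$n, n_occasions = x$k)
}
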