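#' Per-point test-retest difference field
#'
#' The subjects x points matrix of paired thickness differences
#' `d_ij = x_ij - y_ij` between two acquisitions, tagged with the imaging
#' modality it came from.
#'
#' @param x,y N x P matrices of per-point thickness (mm), or `x` may already
#'   be the difference matrix (then leave `y` NULL).
#' @param modality `"2D"` or `"3D"`.
#' @return object of class `difference_field`.
#' @export
difference_field <- function(x, y = NULL, modality = c("3D", "2D")) {
  modality <- match.arg(modality)
  x <- as.matrix(x)
  d <- if (is.null(y)) x else x - as.matrix(y)
  if (any(!is.finite(d))) stop("differences must be finite", call. = FALSE)
  structure(list(d = d, modality = modality), class = "difference_field")
}

#' @export
print.difference_field <- function(x, ...) {
  cat("<difference_field> ", x$modality, ": ", nrow(x$d), " subjects x ",
      ncol(x$d), " points\n", sep = "")
  invisible(x)
}

as_diff_matrix <- function(diff) {
  if (inherits(diff, "difference_field")) diff$d else as.matrix(diff)
}

#' Normal-quantile power factor f(alpha/P, p)
#'
#' The constant in the per-point sample-size formula:
#' `f = (u_{alpha/P} + u_{2(1-p)})^2`, where `u_gamma` is the two-sided
#' standard-normal critical value with central mass `1 - gamma`
#' (`u_gamma = qnorm(1 - gamma/2)`). The significance level is Bonferroni
#' divided by `n_points` before the quantile is taken. With alpha 0.05,
#' power 0.9 and 16386 points, f = 35.3892.
#'
#' @param alpha familywise significance level (0 < alpha < 1).
#' @param p target power (0.5 <= p < 1).
#' @param n_points number of simultaneous tests P (Bonferroni divisor).
#' @return scalar f.
#' @examples
#' power_constant(0.05, 0.9, 16386)
#' @export
power_constant <- function(alpha, p, n_points = 1) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (!is.finite(p) || p < 0.5 || p >= 1)
    stop("`p` must be in [0.5, 1)", call. = FALSE)
  if (!is.finite(n_points) || n_points < 1)
    stop("`n_points` must be >= 1", call. = FALSE)
  u_alpha <- qnorm(1 - (alpha / n_points) / 2)
  u_power <- qnorm(1 - (2 * (1 - p)) / 2)
  (u_alpha + u_power)^2
}

#' Per-point required sample size from test-retest variance
#'
#' For each template point `j`, the number of subjects per group needed to
#' detect a wall-thickness difference `delta` with power `p` at the
#' Bonferroni-adjusted level `alpha / P`:
#' `N_j = 2 f(alpha/P, p) sigma_j^2 / delta^2`, with `sigma_j^2` the sample
#' variance of the paired test-retest differences at point `j`. Both the
#' raw (continuous) and the ceiling-integer sample sizes are kept; zero
#' variance gives `N_j = 0` and is flagged.
#'
#' @param diff a [difference_field()] or N x P matrix (N >= 2).
#' @param delta_mm detectable difference, mm (> 0).
#' @param alpha familywise significance level.
#' @param p target power.
#' @return object of class `sample_size_map`; `tidy()` gives a per-point
#'   tibble, `glance()` the median and IQR over points.
#' @export
sample_size_map <- function(diff, delta_mm = 1, alpha = 0.05, p = 0.9) {
  d <- as_diff_matrix(diff)
  if (nrow(d) < 2) stop("need at least two subjects", call. = FALSE)
  if (!is.finite(delta_mm) || delta_mm <= 0)
    stop("`delta_mm` must be > 0", call. = FALSE)
  P <- ncol(d)
  f <- power_constant(alpha, p, P)
  sigma2 <- apply(d, 2, var)
  n_raw <- 2 * f * sigma2 / delta_mm^2
  structure(list(
    variance = sigma2, n_raw = n_raw, n_int = ceiling(n_raw),
    zero_variance = sigma2 == 0,
    params = list(delta_mm = delta_mm, alpha = alpha, p = p, P = P, f = f),
    modality = if (inherits(diff, "difference_field")) diff$modality else NA_character_),
    class = "sample_size_map")
}

#' @export
print.sample_size_map <- function(x, ...) {
  q <- quantile(x$n_raw, c(0.25, 0.5, 0.75))
  cat("<sample_size_map> ", x$params$P, " points, median N = ",
      round(q[2], 1), " (IQR ", round(q[1], 1), " - ", round(q[3], 1),
      "), delta = ", x$params$delta_mm, " mm\n", sep = "")
  invisible(x)
}

#' @export
tidy.sample_size_map <- function(x, ...) {
  tibble::tibble(point_index = seq_along(x$n_raw),
                 variance = x$variance, n_raw = x$n_raw, n_int = x$n_int,
                 zero_variance = x$zero_variance)
}

#' @export
glance.sample_size_map <- function(x, ...) {
  q <- quantile(x$n_raw, c(0.25, 0.5, 0.75))
  qi <- quantile(x$n_int, c(0.25, 0.5, 0.75))
  tibble::tibble(median_n = q[[2]], q25_n = q[[1]], q75_n = q[[3]],
                 median_n_int = qi[[2]], q25_n_int = qi[[1]], q75_n_int = qi[[3]],
                 f = x$params$f, delta_mm = x$params$delta_mm,
                 alpha = x$params$alpha, p = x$params$p, n_points = x$params$P)
}

#' @export
autoplot.sample_size_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_raw)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "required sample size N_j", y = "points",
                  title = paste0("Per-point sample size (",
                                 object$modality %||% "", ")"))
}

#' Per-point Shapiro-Wilk normality screen
#'
#' The sample-size formula assumes normally distributed test-retest
#' differences; this screens every point with a Shapiro-Wilk test at the
#' Bonferroni-adjusted level `alpha / P`. Constant columns are reported as
#' indeterminate (`NA`).
#'
#' @param diff a [difference_field()] or N x P matrix (N >= 3).
#' @param alpha familywise level before Bonferroni adjustment.
#' @return tibble with `point_index`, `p_value`, `fail`; the failing
#'   fraction and adjusted threshold are attached as attributes.
#' @export
normality_screen <- function(diff, alpha = 0.05) {
  d <- as_diff_matrix(diff)
  if (nrow(d) < 3) stop("Shapiro-Wilk needs at least 3 subjects", call. = FALSE)
  P <- ncol(d)
  thr <- alpha / P
  pv <- apply(d, 2, function(col) {
    if (max(col) - min(col) < 1e-12) return(NA_real_)
    shapiro.test(col)$p.value
  })
  out <- tibble::tibble(point_index = seq_len(P), p_value = pv,
                        fail = !is.na(pv) & pv < thr)
  attr(out, "threshold") <- thr
  attr(out, "failing_fraction") <- mean(out$fail[!is.na(pv)])
  out
}

#' Percentage reduction in sample size, 2D vs 3D
#'
#' `100 (N_j^2D - N_j^3D) / N_j^2D` at each point; positive values mean the
#' 3D acquisition needs fewer subjects. Points with `N_j^2D = 0` are
#' undefined and returned as `NA`. (Clipping the display to +/-90% is a
#' rendering choice for surface maps, not a data mutation.)
#'
#' @param map_2d,map_3d [sample_size_map()]s with identical `P` and
#'   parameters.
#' @return numeric vector of length P (percent).
#' @export
percent_reduction <- function(map_2d, map_3d) {
  stopifnot(inherits(map_2d, "sample_size_map"), inherits(map_3d, "sample_size_map"))
  p2 <- map_2d$params; p3 <- map_3d$params
  if (p2$P != p3$P || p2$delta_mm != p3$delta_mm || p2$alpha != p3$alpha ||
      p2$p != p3$p)
    stop("sample-size maps have different points or parameters", call. = FALSE)
  out <- 100 * (map_2d$n_raw - map_3d$n_raw) / map_2d$n_raw
  out[map_2d$n_raw == 0] <- NA_real_
  out
}

#' Voxelwise Wilcoxon signed-rank significance map
#'
#' Paired Wilcoxon signed-rank test at every template point between two
#' modalities' thickness values, rendered as `-ln(p)`. Exact p-values are
#' used for N <= 25 subjects and the normal approximation with continuity
#' correction above. The Bonferroni significance threshold on the map scale
#' is `-ln(alpha / P)` (12.70 for alpha 0.05 and P = 16386). Points with no
#' nonzero differences are masked (`NA`).
#'
#' @param values_a,values_b N x P matrices of paired per-point values.
#' @param alpha familywise level.
#' @return tibble with `point_index`, `statistic`, `p_value`, `minus_ln_p`,
#'   `significant`; threshold attached as attribute `threshold_minus_ln_p`.
#' @export
wilcoxon_significance_map <- function(values_a, values_b, alpha = 0.05) {
  a <- as.matrix(values_a); b <- as.matrix(values_b)
  if (!all(dim(a) == dim(b))) stop("matrices must have equal shape", call. = FALSE)
  N <- nrow(a)
  if (N < 5) stop("need at least 5 paired subjects", call. = FALSE)
  P <- ncol(a)
  thr_p <- alpha / P
  res <- vapply(seq_len(P), function(j) {
    d <- a[, j] - b[, j]
    d <- d[d != 0]
    if (length(d) == 0) return(c(NA_real_, NA_real_))
    wt <- suppressWarnings(wilcox.test(d, exact = N <= 25, correct = TRUE))
    c(unname(wt$statistic), wt$p.value)
  }, numeric(2))
  out <- tibble::tibble(point_index = seq_len(P),
                        statistic = res[1, ], p_value = res[2, ],
                        minus_ln_p = -log(res[2, ]),
                        significant = !is.na(res[2, ]) & res[2, ] < thr_p)
  attr(out, "threshold_minus_ln_p") <- -log(thr_p)
  attr(out, "alpha_adjusted") <- thr_p
  out
}

#' Empirical power of the per-point sample size by simulation
#'
#' Draws replicate pairs of Gaussian groups (size `n_per_group`, true mean
#' difference `delta`, SD `sigma`), applies a two-sided two-sample test at
#' level `alpha_level`, and reports the rejection fraction. Used to verify
#' that the analytic sample-size formula attains its nominal power.
#'
#' @param n_per_group subjects per group.
#' @param delta true mean difference.
#' @param sigma common SD.
#' @param alpha_level (already adjusted) two-sided significance level.
#' @param n_replicates Monte-Carlo replicates.
#' @param seed RNG seed.
#' @param test `"z"` (known variance) or `"t"` (Welch).
#' @return rejection fraction in `[0, 1]`.
#' @export
empirical_power <- function(n_per_group, delta = 1, sigma = 1,
                            alpha_level = 0.05 / 16386,
                            n_replicates = 10000, seed = 1L,
                            test = c("z", "t")) {
  test <- match.arg(test)
  stopifnot(n_per_group >= 2, n_replicates >= 1)
  withr::with_seed(seed, {
    g1 <- matrix(rnorm(n_per_group * n_replicates, 0, sigma), n_per_group)
    g2 <- matrix(rnorm(n_per_group * n_replicates, delta, sigma), n_per_group)
  })
  m1 <- colMeans(g1); m2 <- colMeans(g2)
  if (test == "z") {
    z <- (m2 - m1) / (sigma * sqrt(2 / n_per_group))
    crit <- qnorm(1 - alpha_level / 2)
    mean(abs(z) > crit)
  } else {
    v1 <- apply(g1, 2, var); v2 <- apply(g2, 2, var)
    se <- sqrt(v1 / n_per_group + v2 / n_per_group)
    tt <- (m2 - m1) / se
    df <- se^4 / ((v1 / n_per_group)^2 / (n_per_group - 1) +
                    (v2 / n_per_group)^2 / (n_per_group - 1))
    mean(abs(tt) > qt(1 - alpha_level / 2, df))
  }
}
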