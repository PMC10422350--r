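#' Two-group one-way ANOVA F test
#'
#' Classical one-way ANOVA for two groups: F is the ratio of between-group
#' to within-group mean squares on (1, n_a + n_b - 2) degrees of freedom; a
#' high F indicates that variation between groups exceeds variation within
#' groups. Used here to compare per-cycle cumulative AUCs between breathing
#' conditions (e.g. 1000 mL vs 500 mL tidal volume).
#'
#' Degenerate inputs: if both groups are constant with different means, F is
#' reported as `Inf` with p = 0 and `degenerate = TRUE`; two identical
#' constant groups are an error (no variance to compare).
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param alpha Significance level for the critical value (default 0.05).
#' @param labels Length-2 character vector of group names.
#' @return A `group_comparison`: list with `group_labels`, `n_per_group`,
#'   `f_value`, `p_value`, `f_critical`, `alpha`, `df`, `degenerate`, and a
#'   `boxplot` list of per-group [boxplot_summary()] results.
#' @export
one_way_f_test <- function(group_a, group_b, alpha = 0.05,
                           labels = c("group_a", "group_b")) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (anyNA(group_a) || anyNA(group_b)) {
    stop("groups must not contain missing values", call. = FALSE)
  }
  na <- length(group_a); nb <- length(group_b)
  ma <- mean(group_a); mb <- mean(group_b)
  g <- (sum(group_a) + sum(group_b)) / (na + nb)
  ssb <- na * (ma - g)^2 + nb * (mb - g)^2
  ssw <- sum((group_a - ma)^2) + sum((group_b - mb)^2)
  df1 <- 1L
  df2 <- na + nb - 2L
  msb <- ssb / df1
  msw <- ssw / df2
  degenerate <- FALSE
  if (msw == 0) {
    if (msb == 0) {
      stop("both groups are identical constants: F test undefined",
           call. = FALSE)
    }
    f <- Inf
    p <- 0
    degenerate <- TRUE
  } else {
    f <- msb / msw
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(list(
    group_labels = labels,
    n_per_group = c(na, nb),
    f_value = f,
    p_value = p,
    f_critical = f_critical(alpha, df1, df2),
    alpha = alpha,
    df = c(df1 = df1, df2 = df2),
    degenerate = degenerate,
    boxplot = list(boxplot_summary(group_a), boxplot_summary(group_b))
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s (n=%d) vs %s (n=%d): F(%d,%d) = %.4g, p = %.4g (critical %.3f at alpha=%g)%s\n",
    x$group_labels[1], x$n_per_group[1], x$group_labels[2], x$n_per_group[2],
    x$df[1], x$df[2], x$f_value, x$p_value, x$f_critical, x$alpha,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Upper-alpha F critical value
#'
#' The upper-`alpha` quantile of the F distribution: the value an observed F
#' statistic must exceed to reject equality of group means at level `alpha`.
#' For two groups of five cycles each, df = (1, 8) and the 5% critical value
#' is 5.318; for six cycles per group, df = (1, 10) gives 4.965.
#'
#' @param alpha Significance level in (0, 1).
#' @param df1,df2 Degrees of freedom (>= 1).
#' @return Positive scalar.
#' @export
f_critical <- function(alpha, df1, df2) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1",
                               call. = FALSE)
  stats::qf(1 - alpha, df1, df2)
}

#' Five-number box-plot summary
#'
#' Quartiles use the linear-interpolation convention (`stats::quantile`
#' type 7); outliers are values beyond 1.5 x IQR from the quartiles. `min`
#' and `max` are the data extremes (outliers included).
#'
#' @param values Numeric vector, length >= 1.
#' @return A `boxplot_summary`: list with `min`, `q1`, `median`, `q3`,
#'   `max`, `outliers`.
#' @export
boxplot_summary <- function(values) {
  if (!length(values)) stop("no values", call. = FALSE)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7,
                              names = FALSE))
  iqr <- q[3] - q[1]
  out <- values[values < q[1] - 1.5 * iqr | values > q[3] + 1.5 * iqr]
  structure(list(min = min(values), q1 = q[1], median = q[2], q3 = q[3],
                 max = max(values), outliers = out),
            class = "boxplot_summary")
}

#' Monte-Carlo type-I error of the two-group F test
#'
#' Simulates `n_rep` pairs of standard-normal groups under the null of equal
#' means and returns the fraction rejected at level `alpha`. A calibrated
#' test rejects at a rate close to `alpha`.
#'
#' @param n_rep Number of replicates.
#' @param n_per_group Group size.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return Rejection rate in `[0, 1]`.
#' @export
f_test_type_i_error <- function(n_rep = 10000L, n_per_group = 5L,
                                alpha = 0.05, seed = 1L) {
  withr::with_seed(seed, {
    a <- matrix(stats::rnorm(n_rep * n_per_group), n_rep)
    b <- matrix(stats::rnorm(n_rep * n_per_group), n_rep)
    ma <- rowMeans(a); mb <- rowMeans(b)
    g <- (ma + mb) / 2
    ssb <- n_per_group * ((ma - g)^2 + (mb - g)^2)
    ssw <- rowSums((a - ma)^2) + rowSums((b - mb)^2)
    f <- ssb / (ssw / (2 * n_per_group - 2))
    crit <- f_critical(alpha, 1, 2 * n_per_group - 2)
    mean(f > crit)
  })
}
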