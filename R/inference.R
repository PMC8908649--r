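# Statistical layer: normality-gated two-group tests, Benjamini-Hochberg
# FDR, chi-square for categorical tables, logistic age adjustment,
# partial correlation with covariates, rater reliability.

shapiro_ok <- function(x, alpha = 0.05) {
  if (length(unique(x)) < 3) return(FALSE)   # degenerate -> nonparametric
  n <- length(x)
  if (n > 5000) x <- x[round(seq(1, n, length.out = 5000))]
  p <- tryCatch(shapiro.test(x)$p.value, error = function(e) 0)
  p >= alpha
}

#' Choose the two-group test by a normality gate
#'
#' Returns `"t_test"` iff both samples pass Shapiro-Wilk at `alpha`
#' (default 0.05), else `"mann_whitney_u"`.  Constant samples fail the
#' gate (normality is undefined, so the nonparametric branch is taken).
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 3.
#' @param alpha gate significance level.
#' @return `"t_test"` or `"mann_whitney_u"`.
#' @export
normality_gate <- function(sample_a, sample_b, alpha = 0.05) {
  if (length(sample_a) < 3 || length(sample_b) < 3)
    stop_wmhnet("each sample needs at least 3 observations")
  if (shapiro_ok(sample_a, alpha) && shapiro_ok(sample_b, alpha))
    "t_test" else "mann_whitney_u"
}

fmt_summary <- function(x, normal) {
  if (normal)
    sprintf("%.3f ± %.3f", mean(x), sd(x))
  else
    sprintf("%.3f (%.3f)", median(x), unname(quantile(x, 0.75) -
                                               quantile(x, 0.25)))
}

#' Two-group comparison with the normality gate
#'
#' Two-sided Welch t-test or Mann-Whitney U test, selected by
#' [normality_gate()].  Group summaries follow the convention
#' mean +/- SD when normal, median (IQR) otherwise.  The reported
#' statistic is the t value or, for the U test, the standardized U
#' (so swapping the groups flips its sign in both branches).
#'
#' @param values_a,values_b numeric samples for groups A and B.
#' @param metric_name label carried into the result.
#' @param alpha significance level for the `significant` flag.
#' @return List of class `group_comparison`.
#' @export
compare_groups <- function(values_a, values_b, metric_name = "metric",
                           alpha = 0.05) {
  test <- normality_gate(values_a, values_b)
  n1 <- length(values_a); n2 <- length(values_b)
  if (test == "t_test") {
    ht <- t.test(values_a, values_b)       # Welch; unequal group sizes
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    ht <- suppressWarnings(wilcox.test(values_a, values_b,
                                       exact = FALSE, correct = FALSE))
    u <- unname(ht$statistic)
    mu <- n1 * n2 / 2
    ties <- table(c(values_a, values_b))
    sig <- sqrt(n1 * n2 / 12 *
                  ((n1 + n2 + 1) - sum(ties^3 - ties) /
                     ((n1 + n2) * (n1 + n2 - 1))))
    statistic <- if (sig > 0) (u - mu) / sig else 0
    p <- ht$p.value
  }
  normal <- test == "t_test"
  structure(list(metric_name = metric_name,
                 group_a_summary = fmt_summary(values_a, normal),
                 group_b_summary = fmt_summary(values_b, normal),
                 mean_a = mean(values_a), mean_b = mean(values_b),
                 median_a = median(values_a), median_b = median(values_b),
                 test_used = test, statistic = statistic, p_raw = p,
                 p_fdr = NA_real_, significant = p < alpha),
            class = "group_comparison")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `min_k>=rank (p_k * m / k)` capped at 1;
#' order-preserving, monotone and idempotent.  Implemented directly from
#' the step-up definition.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop_wmhnet("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Pearson chi-square test for a contingency table
#'
#' Classic Pearson statistic without continuity correction,
#' `sum((O - E)^2 / E)` with `df = (r - 1)(c - 1)`.
#'
#' @param tab matrix of nonnegative integer counts with no zero marginal.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop_wmhnet("counts must be nonnegative integers")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop_wmhnet("zero marginal in contingency table")
  expected <- outer(rs, cs) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Age-adjusted group effect of a metric
#'
#' Logistic regression of group membership on the metric plus age (the
#' "binary regression for age correction" reading): returns the metric's
#' coefficient and Wald p-value.  Perfect or near-perfect separation is
#' flagged rather than raised.
#'
#' @param metric_values numeric vector.
#' @param group_labels vector with exactly two levels (e.g. "A"/"B").
#' @param age numeric covariate.
#' @return List with `coefficient`, `p`, `separation` flag.
#' @export
age_adjusted_group_effect <- function(metric_values, group_labels, age) {
  n <- length(metric_values)
  if (n < 10) stop_wmhnet("need at least 10 observations")
  g <- as.integer(factor(group_labels)) - 1L
  if (length(unique(g)) != 2) stop_wmhnet("both groups must be present")
  if (sd(metric_values) == 0)
    return(list(coefficient = 0, p = 1, separation = FALSE))
  fit <- suppressWarnings(glm(g ~ metric_values + age,
                              family = binomial()))
  sm <- suppressWarnings(summary(fit)$coefficients)
  sep <- !fit$converged || sm["metric_values", "Std. Error"] > 1e3
  list(coefficient = unname(coef(fit)["metric_values"]),
       p = unname(sm["metric_values", "Pr(>|z|)"]),
       separation = sep)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the OLS residuals of `x` and `y` on an
#' intercept plus the covariate columns; the p-value comes from
#' `t = r sqrt(df / (1 - r^2))` with `df = n - 2 - k`.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data frame with `length(x)` rows, or
#'   `NULL` for a plain Pearson correlation.
#' @param x_name,y_name labels carried into the result.
#' @return List of class `partial_correlation` with `r`, `p`, `n`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL, x_name = "x",
                                y_name = "y") {
  n <- length(x)
  if (length(y) != n) stop_wmhnet("x and y lengths differ")
  C <- if (is.null(covariates))
    matrix(numeric(0), n, 0)
  else as.matrix(as.data.frame(covariates))
  storage.mode(C) <- "double"
  k <- ncol(C)
  df <- n - 2 - k
  if (df < 1) stop_wmhnet("not enough observations for the covariate count")
  X <- cbind(1, C)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop_wmhnet("rank-deficient covariate matrix")
  rx <- x - X %*% qr.coef(qx, x)
  ry <- y - X %*% qr.coef(qx, y)
  r <- cor(rx, ry)[1, 1]
  r <- max(-1, min(1, r))
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  structure(list(x_name = x_name, y_name = y_name,
                 covariate_names = colnames(C), r = r, p = p, n = n,
                 df = df),
            class = "partial_correlation")
}

#' Pearson correlation with a t-based p-value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r` and two-sided `p`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop_wmhnet("need equal lengths >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop_wmhnet("zero-variance input")
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tstat), n - 2))
}

#' Inter-rater reliability: Cohen's kappa and Cronbach's alpha
#'
#' Unweighted Cohen's kappa from the raters' cross-tabulation,
#' `(p_o - p_e) / (1 - p_e)`, and Cronbach's alpha from the two-column
#' item matrix.  If both raters use a single identical category, kappa
#' is undefined and flagged.
#'
#' @param ratings_a,ratings_b equal-length ordinal rating vectors.
#' @return List with `kappa`, `cronbach_alpha`, `kappa_defined`.
#' @export
rater_reliability <- function(ratings_a, ratings_b) {
  n <- length(ratings_a)
  if (length(ratings_b) != n) stop_wmhnet("rating vectors differ in length")
  lev <- sort(unique(c(ratings_a, ratings_b)))
  tab <- table(factor(ratings_a, lev), factor(ratings_b, lev))
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa_defined <- pe < 1
  kappa <- if (kappa_defined) (po - pe) / (1 - pe) else NA_real_
  a <- as.numeric(ratings_a); b <- as.numeric(ratings_b)
  tot_var <- var(a + b)
  alpha <- if (tot_var > 0) 2 * (1 - (var(a) + var(b)) / tot_var)
  else NA_real_
  list(kappa = kappa, cronbach_alpha = alpha,
       kappa_defined = kappa_defined)
}
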