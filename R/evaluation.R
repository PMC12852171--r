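#' Percentage of features significantly different across two sites
#'
#' The core harmonization-quality measure: for every feature, a two-sided
#' two-sample t-test compares the two sites; the statistic is the
#' percentage of features with p < `alpha`. No multiple-comparison
#' correction is applied — the quantity of interest is the rejection rate
#' itself, whose null expectation is `100 * alpha`. Default is the
#' pooled-variance Student test; set `welch = TRUE` for the
#' unequal-variance flavor. Features with zero variance in both groups
#' cannot be tested and are excluded with a warning.
#'
#' @param data a [feature_dataset()] containing exactly 2 sites, each with
#'   >= 2 subjects.
#' @param alpha significance level (default 0.05).
#' @param welch logical; use the Welch-Satterthwaite test instead of the
#'   pooled-variance test.
#' @return Percentage in \[0, 100\], with attribute `n_tested`.
#' @export
site_difference_rate <- function(data, alpha = 0.05, welch = FALSE) {
  stopifnot(inherits(data, "feature_dataset"))
  site <- droplevels(data$site)
  if (nlevels(site) != 2)
    stop("site_difference_rate requires exactly 2 sites; got ",
         nlevels(site))
  p <- feature_t_pvalues(data$values, site, welch = welch)
  tested <- !is.na(p)
  if (!all(tested))
    warning(sum(!tested), " feature(s) with zero variance in both groups ",
            "excluded from the site-difference rate")
  if (!any(tested)) stop("no testable features")
  structure(100 * mean(p[tested] < alpha), n_tested = sum(tested))
}

# vectorized two-sample t-test p-values per column; NA for untestable
# (zero pooled variance) features
feature_t_pvalues <- function(values, site, welch = FALSE) {
  g <- as.integer(droplevels(as.factor(site)))
  a <- values[g == 1L, , drop = FALSE]
  b <- values[g == 2L, , drop = FALSE]
  n1 <- nrow(a); n2 <- nrow(b)
  if (n1 < 2 || n2 < 2) stop("each site needs >= 2 subjects for a t-test")
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- colSums(sweep(a, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(b, 2, m2)^2) / (n2 - 1)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(se2))
  }
  p <- rep(NA_real_, ncol(values))
  ok <- se2 > 0
  tstat <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
  p[ok] <- 2 * stats::pt(-abs(tstat), df[ok])
  p
}

#' Average features within atlas regions
#'
#' Collapses a voxel-level dataset to the ROI level: one column per
#' nonzero atlas label, equal to the mean of member features for each
#' subject. Label 0 marks background/excluded voxels and never
#' contributes.
#'
#' @param data a [feature_dataset()].
#' @param atlas integer vector of per-feature ROI labels (length = feature
#'   count; 0 = background), optionally named via `roi_names`.
#' @param roi_names optional character vector naming each distinct nonzero
#'   label (in sorted label order).
#' @return A [feature_dataset()] of ROI means with feature ids
#'   `"roi_<label>"` (or `roi_names`).
#' @export
roi_average <- function(data, atlas, roi_names = NULL) {
  stopifnot(inherits(data, "feature_dataset"))
  atlas <- as.integer(atlas)
  if (length(atlas) != ncol(data$values))
    stop("atlas labels length (", length(atlas),
         ") must equal feature count (", ncol(data$values), ")")
  labs <- sort(unique(atlas[atlas > 0]))
  if (!length(labs)) stop("atlas contains no nonzero ROI labels")
  out <- vapply(labs, function(l)
    rowMeans(data$values[, atlas == l, drop = FALSE]),
    numeric(nrow(data$values)))
  out <- matrix(out, nrow = nrow(data$values))
  ids <- if (!is.null(roi_names)) {
    if (length(roi_names) != length(labs))
      stop("roi_names must have one entry per nonzero label")
    roi_names
  } else paste0("roi_", labs)
  feature_dataset(out, site = data$site, covariates = data$covariates,
                  feature_ids = ids, subject_ids = data$subject_ids)
}

#' Proportion within full-ComBat performance
#'
#' Fraction of transfer-harmonization performance samples strictly less
#' than the 95th percentile (linear-interpolation convention,
#' `quantile(type = 7)`) of the full-ComBat performance samples. Values
#' near 0.95 mean the transferred harmonization is statistically
#' indistinguishable from refitting on everything.
#'
#' @param tc numeric vector of per-iteration performance values for the
#'   transferred harmonization (percentages of significantly different
#'   features).
#' @param fc numeric vector of per-iteration performance values for full
#'   ComBat.
#' @param probs percentile of `fc` used as the reference (default 0.95).
#' @return Proportion in \[0, 1\].
#' @export
pwfc <- function(tc, fc, probs = 0.95) {
  if (!length(tc) || !length(fc)) stop("empty performance distribution")
  ref <- stats::quantile(fc, probs = probs, type = 7, names = FALSE)
  mean(tc < ref)
}

#' Overlap index between two sample distributions
#'
#' Estimates \eqn{\eta = \int \min(f_a, f_b)} where each density is a
#' Gaussian kernel density estimate with its own automatic plug-in
#' bandwidth, evaluated on a shared grid spanning both samples padded by 3
#' bandwidths (4096 points), renormalized to integrate to 1 by the
#' trapezoidal rule. 1 means identical distributions, 0 disjoint support.
#'
#' @param a,b numeric sample vectors (>= 10 values each, non-degenerate).
#' @param n_grid number of grid points (default 4096).
#' @return \eqn{\eta} in \[0, 1\].
#' @export
overlap_index <- function(a, b, n_grid = 4096) {
  if (length(a) < 10 || length(b) < 10)
    stop("overlap_index needs >= 10 samples per distribution")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("degenerate (zero-variance) sample set")
  bw_a <- stats::bw.nrd0(a)
  bw_b <- stats::bw.nrd0(b)
  lo <- min(min(a) - 3 * bw_a, min(b) - 3 * bw_b)
  hi <- max(max(a) + 3 * bw_a, max(b) + 3 * bw_b)
  fa <- stats::density(a, bw = bw_a, from = lo, to = hi, n = n_grid)$y
  fb <- stats::density(b, bw = bw_b, from = lo, to = hi, n = n_grid)$y
  dx <- (hi - lo) / (n_grid - 1)
  trap <- function(y) dx * (sum(y) - (y[1] + y[length(y)]) / 2)
  fa <- fa / trap(fa)
  fb <- fb / trap(fb)
  eta <- trap(pmin(fa, fb))
  min(max(eta, 0), 1)
}

#' Pearson chi-squared test of independence
#'
#' For an r x c contingency table of counts: Pearson statistic,
#' df = (r-1)(c-1), upper-tail p-value. No continuity correction.
#'
#' @param table numeric matrix of non-negative counts, >= 2 rows and
#'   columns, no zero row/column sums.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi2_independence <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("need a table with >= 2 rows and >= 2 columns")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column sum; drop the empty category")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Two-sample t-test from summary statistics
#'
#' Two-sided test of equal means computed from group means, standard
#' deviations and sizes, with Welch-Satterthwaite degrees of freedom.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @return List with `t`, `df` (fractional) and `p`.
#' @export
welch_t_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (s1 < 0 || s2 < 0) stop("standard deviations must be >= 0")
  se2 <- s1^2 / n1 + s2^2 / n2
  if (se2 == 0) return(list(t = 0, df = n1 + n2 - 2, p = 1))
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Two-sided test of equal proportions
#'
#' Pooled-variance z test by default; `exact = TRUE` uses Fisher's exact
#' test instead.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @param exact use Fisher's exact test.
#' @return Two-sided p-value.
#' @export
two_proportion_test <- function(k1, n1, k2, n2, exact = FALSE) {
  if (n1 == 0 || n2 == 0) stop("group sizes must be positive")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2)
    stop("need 0 <= k <= n in both groups")
  if (exact) {
    tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, 2)
    return(stats::fisher.test(tab)$p.value)
  }
  p_pool <- (k1 + k2) / (n1 + n2)
  if (p_pool == 0 || p_pool == 1) return(1)
  z <- (k1 / n1 - k2 / n2) /
    sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  2 * stats::pnorm(-abs(z))
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum p-value: exact when
#' n1 + n2 <= 12 and there are no ties, otherwise the normal approximation
#' with tie correction and continuity correction.
#'
#' @param a,b numeric sample vectors.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  exact <- (length(a) + length(b)) <= 12
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
}

#' Multiple linear regression coefficient report
#'
#' Ordinary least-squares regression of a per-subject scalar (e.g. FA
#' averaged over a white-matter mask) on covariates including site;
#' returns the standard coefficient table used to decide which covariates
#' the harmonization must protect.
#'
#' @param y numeric response vector (one value per subject).
#' @param predictors data.frame of predictor columns (site may be entered
#'   as a factor or numeric indicator).
#' @return Object of class `covariate_regression`: list with `coefficients`
#'   (data.frame: term, estimate, std_error, t, p), `fit` (the `lm`
#'   object), `n`.
#' @export
covariate_regression <- function(y, predictors) {
  predictors <- as.data.frame(predictors)
  if (length(y) != nrow(predictors))
    stop("y and predictors must describe the same subjects")
  if (length(y) <= ncol(predictors) + 1)
    stop("need n > number of predictors + 1")
  dat <- cbind(data.frame(.y = y), predictors)
  fit <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("collinear predictors: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  tab <- summary(fit)$coefficients
  structure(list(coefficients = data.frame(term = rownames(tab),
                                           estimate = tab[, 1],
                                           std_error = tab[, 2],
                                           t = tab[, 3],
                                           p = tab[, 4],
                                           row.names = NULL),
                 fit = fit, n = length(y)),
            class = "covariate_regression")
}

#' @export
print.covariate_regression <- function(x, ...) {
  cat("Covariate regression (n = ", x$n, ")\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Partial F test between nested regression models
#'
#' Tests whether the predictors present only in the full model add
#' explanatory value:
#' \eqn{F = ((RSS_r - RSS_f)/q) / (RSS_f/(n - p_f))} with upper-tail
#' p-value, q = difference in model dimension.
#'
#' @param full,reduced fitted `lm` objects or [covariate_regression()]
#'   results; `reduced` must be nested in `full` and fitted to the same
#'   subjects.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
partial_f_test <- function(full, reduced) {
  lm_of <- function(x) if (inherits(x, "covariate_regression")) x$fit else x
  full <- lm_of(full); reduced <- lm_of(reduced)
  stopifnot(inherits(full, "lm"), inherits(reduced, "lm"))
  n <- length(stats::residuals(full))
  if (n != length(stats::residuals(reduced)))
    stop("models were fitted to different subjects")
  p_f <- n - stats::df.residual(full)
  p_r <- n - stats::df.residual(reduced)
  if (p_r >= p_f)
    stop("'reduced' must have strictly fewer parameters than 'full'")
  rss_f <- sum(stats::residuals(full)^2)
  rss_r <- sum(stats::residuals(reduced)^2)
  if (rss_r < rss_f - 1e-8 * rss_f)
    stop("reduced model fits better than the full model; models are ",
         "not nested")
  if (rss_f == 0) stop("full model has zero residual sum of squares")
  q <- p_f - p_r
  Fstat <- ((rss_r - rss_f) / q) / (rss_f / (n - p_f))
  list(F = Fstat, df1 = q, df2 = n - p_f,
       p = stats::pf(Fstat, q, n - p_f, lower.tail = FALSE))
}
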