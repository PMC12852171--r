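test_that("site_difference_rate counts constructed rejections", {
  # 10 features; feature 1 has an enormous mean gap, the other nine have
  # exactly the same values in both groups (t = 0 there)
  vals <- withr::with_seed(3, {
    m <- matrix(rnorm(20 * 10), 20, 10)
    both <- rbind(m, m)
    both[1:20, 1] <- both[1:20, 1] + 100
    both
  })
  d <- feature_dataset(vals, site = rep(c("A", "B"), each = 20))
  expect_equal(as.numeric(site_difference_rate(d)), 10)
})

test_that("null data rejects at close to the nominal rate (both t flavors)", {
  d <- withr::with_seed(5, feature_dataset(matrix(rnorm(60 * 2000), 60),
                                           site = rep(c("A", "B"), 30)))
  se <- sqrt(0.05 * 0.95 / 2000) * 100
  expect_lt(abs(as.numeric(site_difference_rate(d)) - 5), 3 * se)
  expect_lt(abs(as.numeric(site_difference_rate(d, welch = TRUE)) - 5),
            3 * se)
})

test_that("t-test p-values match stats::t.test feature by feature", {
  d <- random_dataset(seed = 9, n_per_site = c(A = 5, B = 8), V = 3,
                      covariates = FALSE)
  p_pkg <- tcombat:::feature_t_pvalues(d$values, d$site)
  p_welch <- tcombat:::feature_t_pvalues(d$values, d$site, welch = TRUE)
  for (v in 1:3) {
    a <- d$values[d$site == "A", v]; b <- d$values[d$site == "B", v]
    expect_equal(p_pkg[v], t.test(a, b, var.equal = TRUE)$p.value,
                 tolerance = 1e-10)
    expect_equal(p_welch[v], t.test(a, b)$p.value, tolerance = 1e-10)
  }
})

test_that("rate is invariant to feature order and global shifts", {
  d <- random_dataset(seed = 15, n_per_site = c(A = 10, B = 10), V = 50,
                      covariates = FALSE)
  r0 <- site_difference_rate(d)
  perm <- withr::with_seed(1, sample(50))
  d_perm <- feature_dataset(d$values[, perm], site = d$site,
                            feature_ids = d$feature_ids[perm])
  d_shift <- feature_dataset(d$values + 3.2, site = d$site)
  expect_equal(site_difference_rate(d_perm), r0, ignore_attr = TRUE)
  expect_equal(as.numeric(site_difference_rate(d_shift)), as.numeric(r0),
               tolerance = 1e-10)
})

test_that("untestable zero-variance features are excluded with a warning", {
  vals <- withr::with_seed(2, matrix(rnorm(80), 8, 10))
  vals[, 4] <- 1
  d <- feature_dataset(vals, site = rep(c("A", "B"), each = 4))
  expect_warning(r <- site_difference_rate(d), "zero variance")
  expect_equal(attr(r, "n_tested"), 9)
  d3 <- feature_dataset(vals, site = rep(c("A", "B", "C"), c(3, 3, 2)))
  expect_error(site_difference_rate(d3), "exactly 2 sites")
})

test_that("ROI averaging matches a hand-computed oracle, skipping background", {
  vals <- matrix(as.numeric(1:24), 4, 6)
  atlas <- c(1L, 2L, 0L, 1L, 2L, 0L)
  d <- feature_dataset(vals, site = rep(c("A", "B"), each = 2))
  r <- roi_average(d, atlas)
  expect_identical(r$feature_ids, c("roi_1", "roi_2"))
  for (s in 1:4) {
    expect_equal(r$values[s, 1], mean(vals[s, c(1, 4)]))
    expect_equal(r$values[s, 2], mean(vals[s, c(2, 5)]))
  }
  # all member voxels equal c -> ROI mean = c
  d2 <- feature_dataset(matrix(0.7, 3, 4), site = c("A", "A", "B"))
  expect_equal(unname(roi_average(d2, c(3L, 3L, 0L, 3L))$values),
               matrix(0.7, 3, 1))
  expect_error(roi_average(d, rep(0L, 6)), "no nonzero")
  expect_error(roi_average(d, c(1L, 1L)), "length")
})

test_that("pwfc follows the strict 95th-percentile convention", {
  x <- withr::with_seed(11, rnorm(1000))
  expect_lt(abs(pwfc(x, x) - 0.95), 0.02)
  expect_equal(pwfc(c(1, 2, 3), c(10, 11, 12)), 1)
  expect_equal(pwfc(c(1, 2, 3, 4), rep(2.5, 20)), 0.5)
  # shifting every value up cannot increase pwfc
  fc <- withr::with_seed(12, rnorm(200, 5))
  tc <- withr::with_seed(13, rnorm(200, 5))
  expect_lte(pwfc(tc + 0.5, fc), pwfc(tc, fc))
  expect_error(pwfc(numeric(), x), "empty")
})

test_that("overlap index: identical, disjoint, closed-form and symmetry", {
  x <- withr::with_seed(21, rnorm(1000))
  expect_gte(overlap_index(x, x), 0.98)
  far <- withr::with_seed(22, rnorm(1000, mean = 100))
  expect_lte(overlap_index(x, far), 0.01)
  # equal-variance normals one SD apart: eta = 2*pnorm(-1/2) ~ 0.617
  a <- withr::with_seed(23, rnorm(3e4))
  b <- withr::with_seed(24, rnorm(3e4, 1))
  expect_lt(abs(overlap_index(a, b) - 2 * pnorm(-0.5)), 0.02)
  expect_lt(abs(overlap_index(a, b) - overlap_index(b, a)), 1e-6)
  expect_error(overlap_index(rep(1, 20), x), "degenerate")
  expect_error(overlap_index(x[1:5], x), ">= 10")
})

test_that("chi-squared independence test: published table and closed forms", {
  eth <- cbind(UCSD = c(1, 18, 0, 11, 128, 22),
               OHSU = c(1, 11, 3, 1, 111, 7))
  res <- chi2_independence(eth)
  expect_equal(res$df, 5)
  expect_equal(round(res$p, 3), 0.008)
  # perfectly proportional table
  prop <- chi2_independence(rbind(c(10, 20), c(30, 60)))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p, 1)
  # 2x2 closed form n(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  res22 <- chi2_independence(rbind(c(10, 0), c(0, 10)))
  expect_equal(res22$statistic, 20)
  expect_error(chi2_independence(rbind(c(1, 0), c(2, 0))), "zero")
})

test_that("summary-statistic t test: published ages, null, closed form", {
  age <- welch_t_summary(16.0, 2.4, 180, 16.2, 2.6, 134)
  expect_gt(age$p, 0.05)
  same <- welch_t_summary(1, 2, 10, 1, 2, 10)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  res <- welch_t_summary(0, 1, 100, 1, 1, 100)
  expect_equal(abs(res$t), 1 / sqrt(2 / 100), tolerance = 1e-10)
  expect_error(welch_t_summary(0, 1, 1, 0, 1, 10), "n >= 2")
})

test_that("two-proportion test: published sex split, null, separation", {
  expect_gt(two_proportion_test(93, 180, 67, 134), 0.05)
  expect_equal(two_proportion_test(30, 100, 15, 50), 1)
  expect_lt(two_proportion_test(90, 100, 10, 100), 1e-10)
  expect_error(two_proportion_test(5, 4, 1, 10), "0 <= k <= n")
})

test_that("rank-sum test: exact enumeration, ties, separation", {
  # {1,2,3} vs {4,5,6}: 2 of the C(6,3)=20 assignments are as extreme
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  x <- withr::with_seed(31, rnorm(500))
  expect_gt(rank_sum_test(x, x), 0.9)
  y <- withr::with_seed(32, rnorm(5000))
  expect_lt(rank_sum_test(y, y + 5), 1e-10)
})

test_that("covariate regression recovers zero-noise coefficients exactly", {
  n <- 60
  dat <- withr::with_seed(41, data.frame(
    site = rep(0:1, each = n / 2),
    sex = rbinom(n, 1, 0.5),
    age = runif(n, 12, 21)))
  y <- 0.456 - 0.02 * dat$site + 0.008 * dat$sex + 0.002 * dat$age
  # zero noise: lm flags the perfect fit, which is the point here
  expect_warning(res <- covariate_regression(y, dat),
                 "essentially perfect fit")
  est <- setNames(res$coefficients$estimate, res$coefficients$term)
  expect_equal(unname(est["(Intercept)"]), 0.456, tolerance = 1e-10)
  expect_equal(unname(est["site"]), -0.02, tolerance = 1e-10)
  expect_equal(unname(est["sex"]), 0.008, tolerance = 1e-10)
  expect_equal(unname(est["age"]), 0.002, tolerance = 1e-10)
})

test_that("covariate regression matches a normal-equations oracle and is order-invariant", {
  n <- 40
  dat <- withr::with_seed(42, data.frame(site = rep(0:1, each = n / 2),
                                         age = runif(n, 12, 21)))
  y <- withr::with_seed(43,
                        0.4 - 0.01 * dat$site + 0.002 * dat$age +
                          rnorm(n, 0, 0.02))
  res <- covariate_regression(y, dat)
  X <- cbind(1, dat$site, dat$age)
  bhat <- solve(t(X) %*% X, t(X) %*% y)
  rss <- sum((y - X %*% bhat)^2)
  se <- sqrt(diag(solve(t(X) %*% X)) * rss / (n - 3))
  tstat <- drop(bhat) / se
  p <- 2 * pt(-abs(tstat), n - 3)
  expect_equal(res$coefficients$estimate, drop(bhat), tolerance = 1e-10)
  expect_equal(res$coefficients$std_error, se, tolerance = 1e-10)
  expect_equal(res$coefficients$p, p, tolerance = 1e-10)
  perm <- withr::with_seed(44, sample(n))
  res_perm <- covariate_regression(y[perm], dat[perm, ])
  expect_equal(res_perm$coefficients$estimate, res$coefficients$estimate,
               tolerance = 1e-10)
  dat$age2 <- dat$age
  expect_error(covariate_regression(y, dat), "collinear")
})

test_that("partial F test: power, null calibration, formula identity", {
  n <- 300
  dat <- withr::with_seed(51, data.frame(x1 = rnorm(n), x2 = rnorm(n)))
  y <- withr::with_seed(52, 1 + dat$x1 + 2 * dat$x2 + rnorm(n))
  full <- covariate_regression(y, dat)
  reduced <- covariate_regression(y, dat["x1"])
  res <- partial_f_test(full, reduced)
  expect_lt(res$p, 0.001)
  # identity against anova()
  an <- anova(reduced$fit, full$fit)
  expect_equal(res$F, an$F[2], tolerance = 1e-10)
  expect_equal(res$p, an$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, n - 3)
  # adding pure noise gives a uniform p-value distribution
  ps <- withr::with_seed(53, vapply(1:400, function(i) {
    nn <- 50
    x <- rnorm(nn); noise <- rnorm(nn)
    yy <- 1 + x + rnorm(nn)
    partial_f_test(lm(yy ~ x + noise), lm(yy ~ x))$p
  }, 0))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_error(partial_f_test(reduced, full), "fewer parameters")
})
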