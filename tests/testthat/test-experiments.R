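make_pool <- function(world = "null", V = 200, n = 40, seed = 1)
  simulate_dataset(default_world(world, n_features = V,
                                 n_per_site = c(A = n, B = n)),
                   seed = seed)$dataset

test_that("splits are disjoint, exactly sized and seed-deterministic", {
  pool <- make_pool(n = 30)
  s1 <- make_split(pool, n_train = 12, n_test = 8, seed = 42)
  s2 <- make_split(pool, n_train = 12, n_test = 8, seed = 42)
  s3 <- make_split(pool, n_train = 12, n_test = 8, seed = 43)
  expect_identical(s1$train$subject_ids, s2$train$subject_ids)
  expect_false(identical(s1$train$subject_ids, s3$train$subject_ids))
  expect_length(intersect(s1$train$subject_ids, s1$test$subject_ids), 0)
  expect_equal(unname(table(s1$train$site)), c(12, 12), ignore_attr = TRUE)
  expect_equal(unname(table(s1$test$site)), c(8, 8), ignore_attr = TRUE)
  expect_error(make_split(pool, 25, 10, seed = 1), "fewer than")
})

test_that("split sampling is uniform over the per-site pools", {
  pool <- make_pool(V = 4, n = 20)
  hits <- setNames(numeric(40), pool$subject_ids)
  n_rep <- 1000
  for (i in seq_len(n_rep)) {
    s <- make_split(pool, n_train = 5, n_test = 5, seed = i)
    picked <- c(s$train$subject_ids, s$test$subject_ids)
    hits[picked] <- hits[picked] + 1
  }
  p_inc <- 10 / 20     # per-site inclusion probability
  se <- sqrt(p_inc * (1 - p_inc) / n_rep)
  expect_true(all(abs(hits / n_rep - p_inc) < 3 * se + 0.01))
})

test_that("the complete-harmonization rule thresholds correctly", {
  pass_rates <- c(rep(1, 96), rep(7, 4))     # 96% below 5
  fail_rates <- c(rep(1, 94), rep(7, 6))     # 94% below 5
  expect_true(combined_criterion(pass_rates))
  expect_false(combined_criterion(fail_rates))
  # boundary: exactly 95% qualifying passes; "below" is strict
  expect_true(combined_criterion(c(rep(1, 95), rep(7, 5))))
  expect_false(combined_criterion(c(rep(5, 95), rep(1, 5))))
  expect_error(combined_criterion(numeric()), "empty")
})

test_that("training-size sweep has coherent structure and reproduces", {
  pool <- make_pool("strong", V = 200, n = 50, seed = 2)
  cfg <- sweep_config(n_train_grid = c(10, 25), n_test = 10,
                      iterations = 12, baseline_iterations = 15,
                      master_seed = 99)
  sw1 <- run_train_sweep(pool, cfg)
  sw2 <- run_train_sweep(pool, cfg)
  expect_identical(sw1$distributions, sw2$distributions)
  expect_identical(sw1$metrics, sw2$metrics)
  expect_length(sw1$distributions, 2)
  expect_true(all(vapply(sw1$distributions, length, 0L) == 12))
  all_rates <- c(unlist(sw1$distributions), sw1$unharmonized,
                 sw1$full_combat)
  expect_true(all(all_rates >= 0 & all_rates <= 100))
  expect_true(all(sw1$metrics$pwfc >= 0 & sw1$metrics$pwfc <= 1))
  expect_true(all(sw1$metrics$eta >= 0 & sw1$metrics$eta <= 1))
  # strong world: unharmonized baseline far above the ceiling
  expect_gt(median(sw1$unharmonized), median(sw1$full_combat))
})

test_that("null-world sweep centers near the nominal rate everywhere", {
  pool <- make_pool("null", V = 400, n = 45, seed = 3)
  cfg <- sweep_config(n_train_grid = c(15, 30), n_test = 15,
                      iterations = 10, baseline_iterations = 10,
                      master_seed = 5)
  sw <- run_train_sweep(pool, cfg)
  for (dist in sw$distributions)
    expect_lt(abs(mean(dist) - 5), 3)
  expect_lt(abs(mean(sw$unharmonized) - 5), 3)
})

test_that("combined sweep: null world passes the whole grid", {
  pool <- make_pool("null", V = 150, n = 30, seed = 4)
  cfg <- sweep_config(n_train_grid = c(15), n_test_grid = c(2, 5, 10),
                      combined_iterations = 10, master_seed = 11)
  cs <- run_combined_sweep(pool, cfg)
  expect_true(all(cs$pass))
  expect_equal(unname(cs$max_n_test), 10)
  expect_false(any(cs$non_monotone))
})

test_that("within-site baseline sits at the nominal rate on null data", {
  pool <- make_pool("null", V = 300, n = 45, seed = 6)
  cfg <- sweep_config(baseline_iterations = 15, group_size = 20,
                      master_seed = 21)
  ws <- run_within_site_baseline(pool, cfg,
                                 full_combat_dist = rnorm(100, 5, 0.5))
  for (dist in ws$distributions)
    expect_lt(abs(median(dist) - 5), 3)
  expect_true(all(ws$rank_sum_p >= 0 & ws$rank_sum_p <= 1))
})

test_that("rank-sum comparison detects a shifted baseline distribution", {
  # within-site distribution stochastically larger than the reference by
  # 1 percentage point: detectable at 500 trials
  a <- withr::with_seed(31, rnorm(500, mean = 5, sd = 1))
  b <- withr::with_seed(32, rnorm(500, mean = 4, sd = 1))
  expect_lt(rank_sum_test(a, b), 0.05)
})

test_that("unharmonized-frequency map flags prior-violating features", {
  # small training group: shrinkage is strong, so features whose true
  # additive effect sits far outside the prior keep a visible residual
  pool <- simulate_dataset(
    default_world("prior_violating", n_features = 400,
                  n_per_site = c(A = 60, B = 60)), seed = 7)$dataset
  cfg <- sweep_config(n_train_grid = 20, n_test = 25, iterations = 50,
                      master_seed = 13)
  freq <- unharmonized_frequency_map(pool, cfg)
  expect_length(freq, 400)
  expect_true(all(freq >= 0 & freq <= 100))
  planted <- seq_len(4)   # 1% of 400 features, planted first
  expect_lt(wilcox.test(freq[planted], freq[-planted],
                        alternative = "greater")$p.value, 0.01)
})

test_that("null-world frequency map concentrates near the nominal rate", {
  pool <- make_pool("null", V = 300, n = 40, seed = 8)
  cfg <- sweep_config(n_train_grid = 25, n_test = 15, iterations = 20,
                      master_seed = 17)
  freq <- unharmonized_frequency_map(pool, cfg)
  se_mc <- sqrt(0.05 * 0.95 / (300 * 20)) * 100
  expect_lt(abs(mean(freq) - 5), 3 * se_mc + 1)
})
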