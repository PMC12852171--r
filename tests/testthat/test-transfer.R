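test_that("archive save/load round trip is value-exact", {
  sim <- simulate_dataset(default_world("moderate", n_features = 100,
                                        n_per_site = c(A = 15, B = 15)),
                          seed = 4)
  fit <- tcombat(sim$dataset)
  path <- withr::local_tempfile(fileext = ".json")
  save_combat_model(fit, path)
  m <- load_combat_model(path)
  expect_identical(m$ls$alpha, fit$ls$alpha)
  expect_identical(m$ls$beta, fit$ls$beta)
  expect_identical(m$ls$sigma, fit$ls$sigma)
  expect_identical(m$eb$gamma_star, fit$eb$gamma_star)
  expect_identical(m$eb$delta_star, fit$eb$delta_star)
  expect_identical(m$priors$tau2, fit$priors$tau2)
  expect_identical(m$site_registry, fit$site_registry)
  expect_identical(m$feature_ids, fit$feature_ids)
})

test_that("manifest is human-readable JSON listing sites in fitted order", {
  sim <- simulate_dataset(default_world("null", n_features = 5,
                                        n_per_site = c(B = 4, A = 4)),
                          seed = 1)
  fit <- tcombat(sim$dataset)
  path <- withr::local_tempfile(fileext = ".json")
  save_combat_model(fit, path)
  man <- jsonlite::fromJSON(path)$manifest
  expect_identical(unlist(man$site_registry), fit$site_registry)
  expect_identical(man$format_version, "1.0")
  expect_equal(man$n_features, 5)
})

test_that("reloaded archive harmonizes held-out subjects identically", {
  sim <- simulate_dataset(default_world("strong", n_features = 100,
                                        n_per_site = c(A = 40, B = 40)),
                          seed = 6)
  split <- make_split(sim$dataset, n_train = 30, n_test = 5, seed = 2)
  fit <- tcombat(split$train)
  path <- withr::local_tempfile(fileext = ".json")
  save_combat_model(fit, path)
  m <- load_combat_model(path)
  h_mem <- suppressWarnings(apply_transfer(fit, split$test))
  h_disk <- suppressWarnings(apply_transfer(m, split$test))
  expect_identical(h_mem$values, h_disk$values)
})

test_that("corrupt, truncated and mis-versioned archives are rejected", {
  sim <- simulate_dataset(default_world("null", n_features = 10,
                                        n_per_site = c(A = 8, B = 8)),
                          seed = 3)
  fit <- tcombat(sim$dataset)
  path <- withr::local_tempfile(fileext = ".json")
  save_combat_model(fit, path)
  txt <- readLines(path)
  trunc_path <- withr::local_tempfile(fileext = ".json")
  writeLines(txt[seq_len(length(txt) %/% 2)], trunc_path)
  expect_error(load_combat_model(trunc_path), "corrupt")
  ver_path <- withr::local_tempfile(fileext = ".json")
  writeLines(sub('"format_version": "1.0"',
                 '"format_version": "9.9"', txt), ver_path)
  expect_error(load_combat_model(ver_path), "version")
  expect_error(load_combat_model(withr::local_tempfile()), "no such")
})

test_that("harmonization is invariant to stored/new feature order", {
  sim <- simulate_dataset(default_world("moderate", n_features = 30,
                                        n_per_site = c(A = 10, B = 10)),
                          seed = 8)
  fit <- tcombat(sim$dataset)
  new <- subset_subjects(sim$dataset, 1:4)
  perm <- withr::with_seed(1, sample(ncol(new$values)))
  new_perm <- feature_dataset(new$values[, perm], site = new$site,
                              covariates = new$covariates,
                              feature_ids = new$feature_ids[perm],
                              subject_ids = new$subject_ids)
  h <- apply_transfer(fit, new)
  h_perm <- apply_transfer(fit, new_perm)
  expect_identical(h_perm$values, h$values[, perm])
})

test_that("transfer on the training data reproduces the fit exactly, repeatedly", {
  sizes <- withr::with_seed(77, cbind(sample(5:12, 50, TRUE),
                                      sample(5:12, 50, TRUE)))
  for (r in 1:50) {
    sim <- simulate_dataset(
      default_world("moderate", n_features = 30,
                    n_per_site = c(A = sizes[r, 1], B = sizes[r, 2])),
      seed = 1000 + r)
    fit <- tcombat(sim$dataset)
    h <- apply_transfer(fit, sim$dataset)
    expect_lt(max(abs(h$values - fit$harmonized$values)), 1e-12)
  }
})

test_that("permuting new subjects permutes outputs identically", {
  sim <- simulate_dataset(default_world("strong", n_features = 40,
                                        n_per_site = c(A = 20, B = 20)),
                          seed = 10)
  fit <- tcombat(sim$dataset)
  new <- subset_subjects(sim$dataset, 5:16)
  perm <- withr::with_seed(2, sample(12))
  h <- apply_transfer(fit, new)
  h_perm <- apply_transfer(fit, subset_subjects(new, perm))
  expect_identical(h_perm$values, h$values[perm, ])
})

test_that("transfer quality improves with training size", {
  sim <- simulate_dataset(default_world("strong", n_features = 500,
                                        n_per_site = c(A = 120, B = 120)),
                          seed = 12)
  grid <- c(20, 50, 100)
  medians <- vapply(seq_along(grid), function(k) {
    rates <- vapply(1:30, function(i) {
      split <- make_split(sim$dataset, grid[k], 20,
                          seed = substream_seed(5, k * 1000 + i))
      fit <- tcombat(split$train)
      h <- suppressWarnings(apply_transfer(fit, split$test))
      as.numeric(site_difference_rate(h))
    }, 0)
    median(rates)
  }, 0)
  expect_lte(cor(grid, medians, method = "spearman"), 0)
})
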