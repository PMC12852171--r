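#' Configuration for the Monte-Carlo evaluation protocols
#'
#' Defaults mirror the published protocol at full scale: training sizes 50
#' to 110 per site in steps of 10, a fixed test group of 20 per site, 1000
#' transfer iterations per training size, 5000 baseline iterations, 500
#' combined-cohort trials per grid cell with test sizes
#' \{2, 5, 10, 15, 20, 25\}, significance level 0.05, and the "complete
#' harmonization" rule that at least 95% of trials must leave fewer than
#' 5% of features significantly different. Tests and examples scale the
#' grids and iteration counts down.
#'
#' @param n_train_grid per-site training sizes to sweep.
#' @param n_test per-site test-group size for the training-size sweep.
#' @param n_test_grid per-site test sizes for the combined-cohort sweep.
#' @param iterations transfer iterations per training size.
#' @param baseline_iterations iterations for the unharmonized and
#'   full-ComBat baseline distributions.
#' @param combined_iterations trials per combined-sweep grid cell.
#' @param group_size per-site group size used for baseline resampling and
#'   the within-site analysis.
#' @param alpha significance level of the per-feature t-tests.
#' @param level `"voxel"` (features as-is) or `"roi"` (averaged with
#'   `atlas` first).
#' @param atlas per-feature integer ROI labels, required when
#'   `level = "roi"`.
#' @param criterion_prop,criterion_threshold the complete-harmonization
#'   rule: at least `criterion_prop` of trials below
#'   `criterion_threshold` percent.
#' @param master_seed master seed; every random draw derives from it via
#'   [substream_seed()].
#' @return Object of class `sweep_config`.
#' @export
sweep_config <- function(n_train_grid = seq(50, 110, by = 10),
                         n_test = 20,
                         n_test_grid = c(2, 5, 10, 15, 20, 25),
                         iterations = 1000,
                         baseline_iterations = 5000,
                         combined_iterations = 500,
                         group_size = 20,
                         alpha = 0.05,
                         level = c("voxel", "roi"),
                         atlas = NULL,
                         criterion_prop = 0.95,
                         criterion_threshold = 5,
                         master_seed = 1) {
  level <- match.arg(level)
  if (any(n_train_grid <= 0) || is.unsorted(n_train_grid))
    stop("n_train_grid must be positive and non-decreasing")
  if (any(n_test_grid <= 0) || is.unsorted(n_test_grid))
    stop("n_test_grid must be positive and non-decreasing")
  if (iterations < 1 || baseline_iterations < 1 || combined_iterations < 1)
    stop("iteration counts must be >= 1")
  if (level == "roi" && is.null(atlas))
    stop("level = 'roi' requires atlas labels")
  structure(list(n_train_grid = n_train_grid, n_test = n_test,
                 n_test_grid = n_test_grid, iterations = iterations,
                 baseline_iterations = baseline_iterations,
                 combined_iterations = combined_iterations,
                 group_size = group_size, alpha = alpha, level = level,
                 atlas = atlas, criterion_prop = criterion_prop,
                 criterion_threshold = criterion_threshold,
                 master_seed = master_seed),
            class = "sweep_config")
}

# rate at the configured assessment level
config_rate <- function(data, config) {
  if (config$level == "roi") data <- roi_average(data, config$atlas)
  as.numeric(site_difference_rate(data, alpha = config$alpha))
}

#' Stratified random train/test split
#'
#' Draws, independently per site, `n_train` training subjects uniformly at
#' random and then `n_test` test subjects from the remainder. Train and
#' test are disjoint by construction.
#'
#' @param dataset a [feature_dataset()].
#' @param n_train,n_test per-site group sizes.
#' @param seed integer seed; the split is a deterministic function of
#'   `(dataset, n_train, n_test, seed)`.
#' @return List with `train` and `test` [feature_dataset()]s.
#' @export
make_split <- function(dataset, n_train, n_test, seed) {
  counts <- tabulate(dataset$site)
  short <- counts < n_train + n_test
  if (any(short))
    stop("site(s) ", paste(levels(dataset$site)[short], collapse = ", "),
         " have fewer than n_train + n_test = ", n_train + n_test,
         " subjects")
  with_seed(seed, {
    train_idx <- integer(); test_idx <- integer()
    for (i in seq_len(nlevels(dataset$site))) {
      pool <- which(as.integer(dataset$site) == i)
      pick <- sample(pool, n_train + n_test)
      train_idx <- c(train_idx, pick[seq_len(n_train)])
      test_idx <- c(test_idx, pick[n_train + seq_len(n_test)])
    }
    list(train = subset_subjects(dataset, train_idx),
         test = subset_subjects(dataset, test_idx))
  })
}

# sample one group of group_size per site (for baseline resampling)
sample_groups <- function(dataset, group_size, seed) {
  with_seed(seed, {
    idx <- integer()
    for (i in seq_len(nlevels(dataset$site))) {
      pool <- which(as.integer(dataset$site) == i)
      if (length(pool) < group_size)
        stop("site pool smaller than the baseline group size")
      idx <- c(idx, sample(pool, group_size))
    }
    idx
  })
}

#' Training-size sweep of transfer-harmonization performance
#'
#' The main evaluation protocol. For each training size in the grid it
#' repeatedly (1) splits each site into disjoint training and test
#' groups, (2) fits the harmonization on the training group, (3)
#' transfer-harmonizes the test group with the saved parameters only, and
#' (4) records the percentage of features significantly different across
#' sites in the test group. Two baseline distributions are computed by
#' resampling `group_size`-per-site groups: from the unharmonized pool and
#' from the pool harmonized once in full (the performance ceiling). The
#' same resampled groups are used for both baselines (paired draws). Each
#' training size is summarized against the full-ComBat baseline by
#' [pwfc()] and the overlap index [overlap_index()].
#'
#' @param dataset a [feature_dataset()] with 2 sites.
#' @param config a [sweep_config()].
#' @return Object of class `train_sweep`: list with `distributions` (one
#'   numeric vector of per-iteration percentages per training size),
#'   `unharmonized` and `full_combat` baseline vectors, and `metrics`
#'   (data.frame: n_train, median, pwfc, eta).
#' @export
run_train_sweep <- function(dataset, config) {
  stopifnot(inherits(config, "sweep_config"))
  check_sweep_feasible(dataset, max(config$n_train_grid) + config$n_test)
  base <- run_baselines(dataset, config)
  dists <- vector("list", length(config$n_train_grid))
  names(dists) <- paste0("n_train_", config$n_train_grid)
  for (k in seq_along(config$n_train_grid)) {
    n_train <- config$n_train_grid[k]
    rates <- numeric(config$iterations)
    for (i in seq_len(config$iterations)) {
      seed <- substream_seed(config$master_seed, k * 1000000 + i)
      split <- make_split(dataset, n_train, config$n_test, seed)
      fit <- tcombat(split$train)
      rates[i] <- config_rate(quiet_transfer(fit, split$test), config)
    }
    dists[[k]] <- rates
  }
  metrics <- data.frame(
    n_train = config$n_train_grid,
    median = vapply(dists, stats::median, 0),
    pwfc = vapply(dists, pwfc, 0, fc = base$full_combat),
    eta = vapply(dists, overlap_index, 0, b = base$full_combat),
    row.names = NULL)
  structure(list(distributions = dists,
                 unharmonized = base$unharmonized,
                 full_combat = base$full_combat,
                 metrics = metrics, config = config),
            class = "train_sweep")
}

# the two baseline distributions (paired resampling of group_size/site)
run_baselines <- function(dataset, config) {
  full_fit <- tcombat(dataset)
  pool_harm <- full_fit$harmonized
  B <- config$baseline_iterations
  unharm <- numeric(B); fc <- numeric(B)
  for (b in seq_len(B)) {
    seed <- substream_seed(config$master_seed, 900000000 + b)
    idx <- sample_groups(dataset, config$group_size, seed)
    unharm[b] <- config_rate(subset_subjects(dataset, idx), config)
    fc[b] <- config_rate(subset_subjects(pool_harm, idx), config)
  }
  list(unharmonized = unharm, full_combat = fc)
}

#' @export
print.train_sweep <- function(x, ...) {
  cat("Training-size sweep (", x$config$iterations,
      " iterations per size, level = ", x$config$level, ")\n", sep = "")
  cat(sprintf("  unharmonized baseline median: %.2f%%\n",
              stats::median(x$unharmonized)))
  cat(sprintf("  full-ComBat baseline median:  %.2f%%\n",
              stats::median(x$full_combat)))
  print(x$metrics, digits = 3)
  invisible(x)
}

#' Complete-harmonization rule
#'
#' TRUE when at least `prop` of the per-trial rates are strictly below
#' `threshold` percent.
#'
#' @param rates per-trial percentages of significantly different features.
#' @param prop required proportion of passing trials (default 0.95).
#' @param threshold rate threshold in percent (default 5).
#' @return Logical.
#' @export
combined_criterion <- function(rates, prop = 0.95, threshold = 5) {
  if (!length(rates)) stop("empty rate list")
  mean(rates < threshold) >= prop
}

#' Combined-cohort expansion sweep
#'
#' Asks how many never-seen subjects can be folded into an already
#' harmonized cohort: for each training size, test-group sizes are
#' escalated through the grid; at each cell, repeated trials fit on the
#' training group, transfer-harmonize the test group, pool the harmonized
#' training and test subjects, and measure the site-difference rate on the
#' combined cohort. A cell passes when [combined_criterion()] holds. The
#' whole grid is evaluated (not stopped at the first failure) and the
#' largest test size in the contiguous passing run from the smallest size
#' is reported; non-monotone pass patterns are flagged.
#'
#' @param dataset a [feature_dataset()] with 2 sites.
#' @param config a [sweep_config()].
#' @return Object of class `combined_sweep`: `pass` (logical matrix
#'   n_train x n_test), `rates` (list of per-cell trial rates),
#'   `max_n_test` (named vector: largest contiguous passing test size per
#'   training size, NA if none), `non_monotone` flags.
#' @export
run_combined_sweep <- function(dataset, config) {
  stopifnot(inherits(config, "sweep_config"))
  check_sweep_feasible(dataset,
                       max(config$n_train_grid) + max(config$n_test_grid))
  nT <- length(config$n_train_grid); nE <- length(config$n_test_grid)
  pass <- matrix(NA, nT, nE,
                 dimnames = list(paste0("n_train_", config$n_train_grid),
                                 paste0("n_test_", config$n_test_grid)))
  rates_all <- list()
  for (k in seq_len(nT)) {
    n_train <- config$n_train_grid[k]
    for (e in seq_len(nE)) {
      n_test <- config$n_test_grid[e]
      rates <- numeric(config$combined_iterations)
      for (i in seq_len(config$combined_iterations)) {
        seed <- substream_seed(config$master_seed,
                               100000000 + (k * 100 + e) * 100000 + i)
        split <- make_split(dataset, n_train, n_test, seed)
        fit <- tcombat(split$train)
        test_h <- quiet_transfer(fit, split$test)
        combined <- pool_datasets(fit$harmonized, test_h)
        rates[i] <- config_rate(combined, config)
      }
      rates_all[[paste(n_train, n_test, sep = "_")]] <- rates
      pass[k, e] <- combined_criterion(rates, config$criterion_prop,
                                       config$criterion_threshold)
    }
  }
  max_n_test <- apply(pass, 1, function(p) {
    run <- cumprod(p) == 1
    if (!any(run)) NA_real_ else max(config$n_test_grid[run])
  })
  non_monotone <- apply(pass, 1, function(p) any(diff(p) > 0))
  structure(list(pass = pass, rates = rates_all, max_n_test = max_n_test,
                 non_monotone = non_monotone, config = config),
            class = "combined_sweep")
}

# row-bind two datasets with identical features
pool_datasets <- function(a, b) {
  stopifnot(identical(a$feature_ids, b$feature_ids))
  feature_dataset(rbind(a$values, b$values),
                  site = factor(c(as.character(a$site),
                                  as.character(b$site))),
                  covariates = if (is.null(a$covariates)) NULL else
                    rbind(a$covariates, b$covariates),
                  feature_ids = a$feature_ids,
                  subject_ids = make.unique(c(a$subject_ids,
                                              b$subject_ids)))
}

#' @export
print.combined_sweep <- function(x, ...) {
  cat("Combined-cohort expansion sweep\n")
  print(x$pass)
  cat("largest contiguous passing n_test per n_train:\n")
  print(x$max_n_test)
  if (any(x$non_monotone))
    cat("note: non-monotone pass pattern for ",
        paste(names(x$non_monotone)[x$non_monotone], collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Within-site baseline of chance group differences
#'
#' How often do two groups drawn from the *same* site differ? For each
#' site, repeated trials draw two disjoint `group_size` groups from the
#' site's pool and record the percentage of features significantly
#' different between them — the floor any harmonization method should be
#' compared against. Each site's distribution is compared to the
#' full-ComBat baseline distribution by a Wilcoxon rank-sum test.
#'
#' @param dataset a [feature_dataset()].
#' @param config a [sweep_config()] (`baseline_iterations` trials,
#'   `group_size` per group).
#' @param full_combat_dist optional precomputed full-ComBat baseline
#'   vector; computed via [run_baselines()] when omitted.
#' @return Object of class `within_site_baseline`: `distributions` (list
#'   per site), `full_combat`, `rank_sum_p` (named per-site p-values).
#' @export
run_within_site_baseline <- function(dataset, config,
                                     full_combat_dist = NULL) {
  stopifnot(inherits(config, "sweep_config"))
  counts <- tabulate(dataset$site)
  if (any(counts < 2 * config$group_size))
    stop("each site pool must hold at least two disjoint groups of ",
         config$group_size)
  if (is.null(full_combat_dist))
    full_combat_dist <- run_baselines(dataset, config)$full_combat
  dists <- list()
  for (i in seq_len(nlevels(dataset$site))) {
    site_name <- levels(dataset$site)[i]
    pool <- which(as.integer(dataset$site) == i)
    rates <- numeric(config$baseline_iterations)
    for (b in seq_len(config$baseline_iterations)) {
      seed <- substream_seed(config$master_seed,
                             700000000 + i * 1000000 + b)
      idx <- with_seed(seed, sample(pool, 2 * config$group_size))
      g <- rep(c("g1", "g2"), each = config$group_size)
      two <- feature_dataset(dataset$values[idx, , drop = FALSE],
                             site = g,
                             feature_ids = dataset$feature_ids,
                             subject_ids = dataset$subject_ids[idx])
      rates[b] <- config_rate(two, config)
    }
    dists[[site_name]] <- rates
  }
  p <- vapply(dists, rank_sum_test, 0, b = full_combat_dist)
  structure(list(distributions = dists, full_combat = full_combat_dist,
                 rank_sum_p = p, config = config),
            class = "within_site_baseline")
}

#' @export
print.within_site_baseline <- function(x, ...) {
  cat("Within-site chance-difference baseline (",
      x$config$baseline_iterations, " trials, ", x$config$group_size,
      " per group)\n", sep = "")
  for (nm in names(x$distributions))
    cat(sprintf("  %s: median %.2f%%  (rank-sum vs full ComBat p = %.3g)\n",
                nm, stats::median(x$distributions[[nm]]), x$rank_sum_p[nm]))
  invisible(x)
}

#' Per-feature frequency of remaining unharmonized
#'
#' Over repeated train/test iterations, the percentage of iterations in
#' which each feature's across-site t-test on the transfer-harmonized test
#' group stays significant — a per-voxel map of where transfer
#' harmonization tends to fail (e.g. features whose site effects violate
#' the prior).
#'
#' @param dataset a [feature_dataset()] with 2 sites.
#' @param config a [sweep_config()]; uses the first entry of
#'   `n_train_grid`, `n_test` and `iterations`.
#' @return Numeric vector (length = features) of frequencies in
#'   \[0, 100\], named by feature id.
#' @export
unharmonized_frequency_map <- function(dataset, config) {
  stopifnot(inherits(config, "sweep_config"))
  n_train <- config$n_train_grid[1]
  check_sweep_feasible(dataset, n_train + config$n_test)
  count <- numeric(ncol(dataset$values))
  for (i in seq_len(config$iterations)) {
    seed <- substream_seed(config$master_seed, 500000000 + i)
    split <- make_split(dataset, n_train, config$n_test, seed)
    fit <- tcombat(split$train)
    test_h <- quiet_transfer(fit, split$test)
    p <- feature_t_pvalues(test_h$values, test_h$site)
    count <- count + (!is.na(p) & p < config$alpha)
  }
  stats::setNames(100 * count / config$iterations, dataset$feature_ids)
}

check_sweep_feasible <- function(dataset, needed) {
  counts <- tabulate(dataset$site)
  if (any(counts < needed))
    stop("infeasible configuration: site(s) ",
         paste(levels(dataset$site)[counts < needed], collapse = ", "),
         " have fewer than the required ", needed, " subjects")
  invisible(TRUE)
}
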