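# Fixtures and independent brute-force oracles used across test files.
# Oracles deliberately use a different computational path (per-feature
# loops, stats::lm, stats::t.test) from the vectorized package code.

# small random two-site dataset
random_dataset <- function(seed = 1, n_per_site = c(A = 6, B = 6), V = 4,
                           covariates = TRUE) {
  withr::with_seed(seed, {
    n <- sum(n_per_site)
    site <- rep(names(n_per_site), n_per_site)
    cov <- if (covariates)
      data.frame(age = runif(n, 12, 21), sex = rbinom(n, 1, 0.5))
    else NULL
    feature_dataset(matrix(rnorm(n * V, mean = 0.4, sd = 0.05), n, V),
                    site = site, covariates = cov)
  })
}

# per-feature OLS oracle via stats::lm with treatment coding, mapped to
# the weighted-grand-mean parametrization
lm_ls_oracle <- function(dataset) {
  n_i <- tabulate(dataset$site)
  w <- n_i / sum(n_i)
  has_cov <- !is.null(dataset$covariates)
  V <- ncol(dataset$values)
  alpha <- numeric(V)
  beta <- if (has_cov) matrix(NA_real_, ncol(dataset$covariates), V)
          else matrix(0, 0, V)
  sigma2 <- numeric(V)
  for (v in seq_len(V)) {
    df <- data.frame(y = dataset$values[, v], site = dataset$site)
    if (has_cov) df <- cbind(df, dataset$covariates)
    fml <- if (has_cov)
      stats::as.formula(paste("y ~ site +",
                              paste(names(dataset$covariates),
                                    collapse = " + ")))
    else y ~ site
    fit <- stats::lm(fml, data = df)
    cf <- stats::coef(fit)
    site_levels <- cf["(Intercept)"] +
      c(0, cf[paste0("site", levels(dataset$site)[-1])])
    alpha[v] <- sum(w * site_levels)
    if (has_cov) beta[, v] <- cf[names(dataset$covariates)]
    sigma2[v] <- sum(stats::residuals(fit)^2) / nrow(df)
  }
  if (has_cov) rownames(beta) <- names(dataset$covariates)
  list(alpha = alpha, beta = beta, sigma = sqrt(sigma2))
}

# elementwise standardization oracle (explicit double loop)
loop_standardize_oracle <- function(dataset, ls) {
  Y <- dataset$values
  z <- Y * NA_real_
  has_cov <- !is.null(dataset$covariates)
  for (j in seq_len(nrow(Y))) {
    for (v in seq_len(ncol(Y))) {
      xb <- 0
      if (has_cov)
        for (k in seq_len(nrow(ls$beta)))
          xb <- xb + dataset$covariates[[rownames(ls$beta)[k]]][j] *
            ls$beta[k, v]
      z[j, v] <- (Y[j, v] - ls$alpha[v] - xb) / ls$sigma[v]
    }
  }
  z
}

# per-site mean/variance oracle (groupby loop)
groupby_site_oracle <- function(z, site) {
  site <- droplevels(as.factor(site))
  g <- matrix(NA_real_, nlevels(site), ncol(z))
  d2 <- g
  for (i in seq_len(nlevels(site))) {
    rows <- which(site == levels(site)[i])
    for (v in seq_len(ncol(z))) {
      g[i, v] <- mean(z[rows, v])
      d2[i, v] <- stats::var(z[rows, v])
    }
  }
  list(gamma_hat = g, delta2_hat = d2)
}

# brute-force fixed-point oracle: the same coupled updates run as a plain
# per-feature scalar loop for a fixed large number of iterations
brute_eb_oracle <- function(z, site, se, pr, n_iter = 10000) {
  site <- droplevels(as.factor(site))
  gamma_star <- se$gamma_hat
  delta2_star <- se$delta2_hat
  for (i in seq_len(nlevels(site))) {
    rows <- which(site == levels(site)[i])
    n <- length(rows)
    for (v in seq_len(ncol(z))) {
      g_hat <- se$gamma_hat[i, v]
      g <- g_hat
      d2 <- se$delta2_hat[i, v]
      for (it in seq_len(n_iter)) {
        g <- (n * pr$tau2[i] * g_hat + d2 * pr$gamma_bar[i]) /
          (n * pr$tau2[i] + d2)
        d2 <- (pr$theta[i] + 0.5 * sum((z[rows, v] - g)^2)) /
          (n / 2 + pr$lambda[i] - 1)
      }
      gamma_star[i, v] <- g
      delta2_star[i, v] <- d2
    }
  }
  list(gamma_star = gamma_star, delta_star = sqrt(delta2_star))
}

# elementwise harmonization transform oracle
loop_harmonize_oracle <- function(dataset, model) {
  z <- loop_standardize_oracle(dataset, model$ls)
  out <- dataset$values * NA_real_
  has_cov <- !is.null(dataset$covariates)
  for (j in seq_len(nrow(out))) {
    i <- match(as.character(dataset$site[j]), model$site_registry)
    for (v in seq_len(ncol(out))) {
      xb <- 0
      if (has_cov)
        for (k in seq_len(nrow(model$ls$beta)))
          xb <- xb + dataset$covariates[[rownames(model$ls$beta)[k]]][j] *
            model$ls$beta[k, v]
      out[j, v] <- model$ls$sigma[v] / model$eb$delta_star[i, v] *
        (z[j, v] - model$eb$gamma_star[i, v]) + model$ls$alpha[v] + xb
    }
  }
  out
}
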