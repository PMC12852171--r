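#' Least-squares stage of the harmonization model
#'
#' Fits, feature by feature, the linear model
#' \eqn{y_{ijv} = \alpha_v + X_{ij}\beta_v + \gamma_{iv} + \delta_{iv}\varepsilon_{ijv}}
#' by ordinary least squares with the identifiability constraint that the
#' additive site effects have zero weighted mean (weights \eqn{n_i/N}).
#' \eqn{\hat\alpha_v} is therefore the grand-mean level, and
#' \eqn{\hat\sigma_v} is the pooled residual standard deviation of the full
#' (site + covariates) fit, with denominator N.
#'
#' @param dataset a [feature_dataset()] satisfying the fitting invariants.
#' @param design the matching [build_design()] matrix.
#' @return An object of class `ls_estimates`: list with `alpha` (length-V),
#'   `beta` (covariates x V matrix), `sigma` and `residual_variance`
#'   (length-V), `site_coef` (sites x V, constrained site effects),
#'   `constant_feature_mask` (logical V), plus bookkeeping.
#' @export
fit_ls_model <- function(dataset, design) {
  stopifnot(inherits(dataset, "feature_dataset"),
            inherits(design, "combat_design"))
  check_fittable(dataset)
  Y <- dataset$values
  X <- unclass(design)
  attributes(X)[setdiff(names(attributes(X)), c("dim", "dimnames"))] <- NULL
  n <- nrow(Y)
  if (n < ncol(X) + 1)
    stop("need at least ", ncol(X) + 1, " subjects to fit ", ncol(X),
         " design columns; got ", n)
  XtX <- crossprod(X)
  r <- qr(XtX)$rank
  if (r < ncol(X))
    stop("design matrix is rank deficient (rank ", r, " < ", ncol(X),
         " columns); check for collinear covariates")
  B <- solve(XtX, crossprod(X, Y))           # (S + p) x V
  site_cols <- attr(design, "site_cols")
  cov_cols <- attr(design, "cov_cols")
  n_i <- attr(design, "n_per_site")
  w <- n_i / n
  site_coef_raw <- B[site_cols, , drop = FALSE]
  alpha <- drop(crossprod(site_coef_raw, w))  # weighted grand mean, length V
  site_coef <- sweep(site_coef_raw, 2, alpha) # constrained: sum_i w_i g_i = 0
  beta <- B[cov_cols, , drop = FALSE]
  resid <- Y - X %*% B
  residual_variance <- colMeans(resid^2)      # pooled, denominator N
  # constant features: no variation at all around the fitted covariate model
  tot_scale <- colMeans(Y^2)
  constant <- residual_variance <= 1e-24 * pmax(tot_scale, 1e-300) |
    residual_variance == 0
  structure(
    list(alpha = alpha,
         beta = beta,
         sigma = sqrt(residual_variance),
         residual_variance = residual_variance,
         site_coef = site_coef,
         constant_feature_mask = as.vector(constant),
         feature_ids = dataset$feature_ids,
         n_subjects = n),
    class = "ls_estimates")
}

#' Standardize a feature matrix using least-squares estimates
#'
#' Computes \eqn{z_{ijv} = (y_{ijv} - \hat\alpha_v - X_{ij}\hat\beta_v)/\hat\sigma_v}:
#' the data with overall level and covariate contributions removed, scaled
#' by the pooled residual standard deviation. Features flagged constant get
#' z = 0 and are excluded from all downstream estimation.
#'
#' @param dataset a [feature_dataset()] (training data or new subjects).
#' @param design the [build_design()] matrix for `dataset`.
#' @param ls an [fit_ls_model()] result (possibly from other data, as in
#'   transfer).
#' @return Matrix `z` of standardized values, same shape as
#'   `dataset$values`, with attribute `constant_feature_mask`.
#' @export
standardize <- function(dataset, design, ls) {
  stopifnot(inherits(ls, "ls_estimates"))
  Y <- dataset$values
  if (ncol(Y) != length(ls$alpha))
    stop("feature count mismatch between data and estimates")
  cov_cols <- attr(design, "cov_cols")
  Xcov <- unclass(design)[, cov_cols, drop = FALSE]
  mu <- matrix(ls$alpha, nrow(Y), ncol(Y), byrow = TRUE)
  if (length(cov_cols)) mu <- mu + Xcov %*% ls$beta
  keep <- !ls$constant_feature_mask
  if (any(ls$sigma[keep] == 0))
    stop("sigma = 0 for an unflagged feature; cannot standardize")
  z <- matrix(0, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  z[, keep] <- sweep(Y[, keep, drop = FALSE] - mu[, keep, drop = FALSE],
                     2, ls$sigma[keep], "/")
  attr(z, "constant_feature_mask") <- ls$constant_feature_mask
  z
}

#' Per-site moments of the standardized data
#'
#' The standardized values are modelled as
#' \eqn{z_{ijv} \sim N(\gamma_{iv}, \delta_{iv}^2)}; this computes their
#' empirical per-site estimates: \eqn{\hat\gamma_{iv}} = within-site mean
#' and \eqn{\hat\delta^2_{iv}} = within-site unbiased variance
#' (denominator n_i - 1).
#'
#' @param z standardized matrix from [standardize()].
#' @param site per-subject site factor.
#' @return Object of class `site_effects`: list with `gamma_hat` and
#'   `delta2_hat` (sites x features), `n_per_site`, `sites`.
#' @export
estimate_site_effects <- function(z, site) {
  site <- droplevels(as.factor(site))
  counts <- tabulate(site)
  if (any(counts < 2))
    stop("every site needs >= 2 subjects to estimate a variance; site(s) ",
         paste(levels(site)[counts < 2], collapse = ", "), " have fewer")
  S <- nlevels(site)
  gamma_hat <- matrix(NA_real_, S, ncol(z),
                      dimnames = list(levels(site), colnames(z)))
  delta2_hat <- gamma_hat
  for (i in seq_len(S)) {
    zi <- z[as.integer(site) == i, , drop = FALSE]
    m <- colMeans(zi)
    gamma_hat[i, ] <- m
    delta2_hat[i, ] <- colSums(sweep(zi, 2, m)^2) / (nrow(zi) - 1)
  }
  structure(list(gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                 n_per_site = counts, sites = levels(site)),
            class = "site_effects")
}

#' Method-of-moments prior hyperparameters
#'
#' The per-feature site effects are given parametric priors
#' \eqn{\gamma_{iv} \sim N(\gamma_i, \tau_i^2)} and
#' \eqn{\delta^2_{iv} \sim} Inverse-Gamma\eqn{(\lambda_i, \theta_i)}; their
#' hyperparameters are estimated by matching moments across features:
#' \eqn{\gamma_i, \tau_i^2} are the across-feature mean and variance
#' (denominator V - 1) of \eqn{\hat\gamma_{iv}}, and with m, s^2 the
#' across-feature mean and variance of \eqn{\hat\delta^2_{iv}},
#' \eqn{\lambda_i = (m^2 + 2 s^2)/s^2}, \eqn{\theta_i = (m^3 + m s^2)/s^2}
#' (so the prior mean \eqn{\theta/(\lambda-1)} equals m and the prior
#' variance \eqn{\theta^2/((\lambda-1)^2(\lambda-2))} equals s^2).
#'
#' @param se an [estimate_site_effects()] result; features flagged constant
#'   should already be excluded from its columns (see `exclude`).
#' @param exclude optional logical vector of features to drop from the
#'   moment computations (e.g. constant features).
#' @return Object of class `combat_priors`: per-site `gamma_bar`, `tau2`,
#'   `lambda`, `theta`, plus `degenerate` flags (TRUE where the
#'   across-feature variance of \eqn{\hat\delta^2} is zero and the
#'   inverse-gamma prior is undefined) and `finite_variance` flags
#'   (lambda > 2).
#' @export
estimate_hyperparameters <- function(se, exclude = NULL) {
  stopifnot(inherits(se, "site_effects"))
  g <- se$gamma_hat
  d2 <- se$delta2_hat
  if (!is.null(exclude)) {
    g <- g[, !exclude, drop = FALSE]
    d2 <- d2[, !exclude, drop = FALSE]
  }
  if (ncol(g) < 2)
    stop("need >= 2 features to estimate across-feature moments")
  gamma_bar <- rowMeans(g)
  tau2 <- apply(g, 1, stats::var)
  m <- rowMeans(d2)
  s2 <- apply(d2, 1, stats::var)
  degenerate <- s2 == 0
  lambda <- ifelse(degenerate, NA_real_, (m^2 + 2 * s2) / s2)
  theta <- ifelse(degenerate, NA_real_, (m^3 + m * s2) / s2)
  if (any(degenerate))
    warning("inverse-gamma prior degenerate (zero across-feature variance ",
            "of delta^2) for site(s) ",
            paste(se$sites[degenerate], collapse = ", "),
            "; empirical Bayes will fall back to per-feature estimates")
  structure(list(gamma_bar = gamma_bar, tau2 = tau2,
                 lambda = lambda, theta = theta,
                 degenerate = degenerate,
                 finite_variance = !degenerate & lambda > 2,
                 sites = se$sites),
            class = "combat_priors")
}

#' Empirical-Bayes site-effect estimates
#'
#' Computes \eqn{\gamma^*_{iv}} and \eqn{\delta^*_{iv}} as the fixed point
#' of the coupled conditional-posterior-mean updates: with n = n_i,
#' \deqn{\gamma^* = (n \tau^2 \hat\gamma + \delta^{2*} \gamma_i) / (n \tau^2 + \delta^{2*})}
#' \deqn{\delta^{2*} = (\theta_i + \tfrac12 \sum_j (z_{ijv} - \gamma^*)^2) / (n/2 + \lambda_i - 1)}
#' iterated from \eqn{(\hat\gamma, \hat\delta^2)} until the maximum
#' relative change of both arrays falls below `tol`. Each \eqn{\gamma^*}
#' is a convex combination of \eqn{\hat\gamma_{iv}} and \eqn{\gamma_i},
#' hence lies weakly between them. For a site with a degenerate prior the
#' per-feature estimates are returned unchanged.
#'
#' @param z standardized matrix from [standardize()].
#' @param site per-subject site factor matching `z`.
#' @param se [estimate_site_effects()] result.
#' @param pr [estimate_hyperparameters()] result.
#' @param exclude optional logical: features to leave untouched (constant).
#' @param tol convergence tolerance on the maximum relative change
#'   (default 1e-4).
#' @param max_iter iteration cap per site (default 1000).
#' @return Object of class `eb_estimates`: `gamma_star`, `delta_star`
#'   (sites x features; `delta_star` on the standard-deviation scale),
#'   `iterations` and `converged` per site.
#' @export
eb_posterior_means <- function(z, site, se, pr, exclude = NULL,
                               tol = 1e-4, max_iter = 1000) {
  stopifnot(inherits(se, "site_effects"), inherits(pr, "combat_priors"))
  site <- droplevels(as.factor(site))
  S <- nlevels(site)
  V <- ncol(z)
  keep <- if (is.null(exclude)) rep(TRUE, V) else !exclude
  gamma_star <- se$gamma_hat
  delta2_star <- se$delta2_hat
  iterations <- integer(S)
  converged <- logical(S)
  for (i in seq_len(S)) {
    if (pr$degenerate[i]) { converged[i] <- TRUE; next }
    zi <- z[as.integer(site) == i, keep, drop = FALSE]
    n <- nrow(zi)
    s1 <- colSums(zi)
    s2 <- colSums(zi^2)
    g_hat <- se$gamma_hat[i, keep]
    g <- g_hat
    d2 <- se$delta2_hat[i, keep]
    tau2 <- pr$tau2[i]; gbar <- pr$gamma_bar[i]
    lam <- pr$lambda[i]; th <- pr$theta[i]
    ok <- FALSE
    it <- 0
    while (it < max_iter) {
      it <- it + 1
      g_new <- (n * tau2 * g_hat + d2 * gbar) / (n * tau2 + d2)
      ss <- s2 - 2 * g_new * s1 + n * g_new^2   # sum_j (z - g_new)^2
      d2_new <- (th + 0.5 * ss) / (n / 2 + lam - 1)
      change <- max(abs(g_new - g) / pmax(abs(g), .Machine$double.eps),
                    abs(d2_new - d2) / d2)
      g <- g_new; d2 <- d2_new
      if (change < tol) { ok <- TRUE; break }
    }
    gamma_star[i, keep] <- g
    delta2_star[i, keep] <- d2
    iterations[i] <- it
    converged[i] <- ok
  }
  if (!all(converged))
    warning("empirical-Bayes updates did not converge within ", max_iter,
            " iterations for site(s) ",
            paste(se$sites[!converged], collapse = ", "))
  structure(list(gamma_star = gamma_star,
                 delta_star = sqrt(delta2_star),
                 iterations = iterations, converged = converged,
                 sites = se$sites),
            class = "eb_estimates")
}

#' Apply the harmonization transform
#'
#' Maps each observation through
#' \deqn{y^{ComBat}_{ijv} = \frac{\hat\sigma_v}{\delta^*_{iv}} (z_{ijv} - \gamma^*_{iv}) + \hat\alpha_v + X_{ij}\hat\beta_v}
#' using the pooled per-feature \eqn{\hat\sigma_v} throughout. Constant
#' features are passed through unchanged.
#'
#' @param dataset a [feature_dataset()] whose sites are all in
#'   `model$site_registry`.
#' @param design the [build_design()] matrix for `dataset`, built with the
#'   model's covariate schema.
#' @param model a fitted [tcombat()] model.
#' @return A [feature_dataset()] of harmonized values with metadata equal
#'   to the input.
#' @export
harmonize <- function(dataset, design, model) {
  stopifnot(inherits(model, "tcombat"))
  unseen <- setdiff(levels(dataset$site), model$site_registry)
  if (length(unseen))
    stop("site(s) not in the fitted model's registry: ",
         paste(unseen, collapse = ", "))
  if (!identical(as.character(dataset$feature_ids),
                 as.character(model$feature_ids)))
    stop("feature_ids of the data do not match the fitted model")
  ls <- model$ls
  z <- standardize(dataset, design, ls)
  idx <- match(as.character(dataset$site), model$site_registry)
  keep <- !ls$constant_feature_mask
  cov_cols <- attr(design, "cov_cols")
  Xcov <- unclass(design)[, cov_cols, drop = FALSE]
  mu <- matrix(ls$alpha, nrow(z), ncol(z), byrow = TRUE)
  if (length(cov_cols)) mu <- mu + Xcov %*% ls$beta
  out <- dataset$values
  g <- model$eb$gamma_star[idx, keep, drop = FALSE]
  d <- model$eb$delta_star[idx, keep, drop = FALSE]
  sig <- matrix(ls$sigma[keep], nrow(z), sum(keep), byrow = TRUE)
  out[, keep] <- sig / d * (z[, keep, drop = FALSE] - g) +
    mu[, keep, drop = FALSE]
  feature_dataset(out, site = dataset$site, covariates = dataset$covariates,
                  feature_ids = dataset$feature_ids,
                  subject_ids = dataset$subject_ids)
}

#' Fit transferable ComBat harmonization
#'
#' The main fitting function. Runs the full empirical-Bayes harmonization
#' chain on a multisite training dataset: ordinary least squares for the
#' overall level, covariate effects and pooled residual scale;
#' standardization; per-site site-effect moments; method-of-moments prior
#' hyperparameters; iterative conditional-posterior-mean shrinkage; and the
#' final location/scale transform. The returned object carries every fitted
#' parameter and the covariate coding, so it can be saved
#' ([save_combat_model()]) and applied unchanged to new subjects from the
#' same sites ([apply_transfer()] / `predict()`). The fit is deterministic.
#'
#' @param dataset a [feature_dataset()] with >= 2 sites and >= 2 subjects
#'   per site, or a numeric matrix (then `site`/`covariates` are required).
#' @param site,covariates used only when `dataset` is a bare matrix.
#' @param schema a [covariate_schema()]; defaults to all covariates in the
#'   dataset.
#' @param tol,max_iter empirical-Bayes convergence controls; see
#'   [eb_posterior_means()].
#' @return An object of class `tcombat`: list with components `ls`,
#'   `site_effects`, `priors`, `eb`, `site_registry`, `covariate_schema`,
#'   `feature_ids`, `fit_options`, `n_per_site` and `harmonized` (the
#'   harmonized training data as a [feature_dataset()]).
#' @seealso [apply_transfer()], [save_combat_model()], [harmonize()]
#' @export
#' @examples
#' sim <- simulate_dataset(default_world("strong", n_features = 50,
#'                                       n_per_site = c(A = 15, B = 15)),
#'                         seed = 1)
#' fit <- tcombat(sim$dataset)
#' fit
tcombat <- function(dataset, site = NULL, covariates = NULL,
                    schema = NULL, tol = 1e-4, max_iter = 1000) {
  if (!inherits(dataset, "feature_dataset"))
    dataset <- feature_dataset(dataset, site = site, covariates = covariates)
  check_fittable(dataset)
  if (is.null(schema)) schema <- covariate_schema(dataset)
  design <- build_design(dataset, schema)
  ls <- fit_ls_model(dataset, design)
  z <- standardize(dataset, design, ls)
  se <- estimate_site_effects(z, dataset$site)
  excl <- ls$constant_feature_mask
  pr <- estimate_hyperparameters(se, exclude = excl)
  eb <- eb_posterior_means(z, dataset$site, se, pr, exclude = excl,
                           tol = tol, max_iter = max_iter)
  model <- structure(
    list(ls = ls, site_effects = se, priors = pr, eb = eb,
         site_registry = levels(dataset$site),
         covariate_schema = schema,
         feature_ids = dataset$feature_ids,
         n_per_site = stats::setNames(tabulate(dataset$site),
                                      levels(dataset$site)),
         fit_options = list(tol = tol, max_iter = max_iter,
                            sigma_denominator = "N",
                            delta2_denominator = "n_i - 1"),
         covariate_range = covariate_range(design)),
    class = "tcombat")
  model$harmonized <- harmonize(dataset, design, model)
  model
}

#' @export
print.tcombat <- function(x, ...) {
  cat("Transferable ComBat harmonization fit\n")
  cat("  features: ", length(x$feature_ids),
      " (", sum(x$ls$constant_feature_mask), " constant, passed through)\n",
      sep = "")
  cat("  sites:    ",
      paste(sprintf("%s (n=%d)", x$site_registry, x$n_per_site),
            collapse = ", "), "\n", sep = "")
  covs <- vapply(x$covariate_schema, `[[`, "", "name")
  cat("  covariates: ",
      if (length(covs)) paste(covs, collapse = ", ") else "none",
      "\n", sep = "")
  cat("  EB iterations per site: ",
      paste(x$eb$iterations, collapse = ", "),
      if (all(x$eb$converged)) " (converged)" else " (NOT converged)",
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.tcombat <- function(object, ...) {
  pr <- object$priors
  out <- data.frame(
    site = object$site_registry,
    n = as.integer(object$n_per_site),
    gamma_bar = pr$gamma_bar,
    tau2 = pr$tau2,
    lambda = pr$lambda,
    theta = pr$theta,
    mean_gamma_star = rowMeans(object$eb$gamma_star),
    mean_delta_star = rowMeans(object$eb$delta_star),
    eb_iterations = object$eb$iterations,
    converged = object$eb$converged,
    row.names = NULL)
  structure(list(sites = out,
                 n_features = length(object$feature_ids),
                 n_constant = sum(object$ls$constant_feature_mask),
                 fit_options = object$fit_options),
            class = "summary.tcombat")
}

#' @export
print.summary.tcombat <- function(x, ...) {
  cat("Transferable ComBat fit: ", x$n_features, " features (",
      x$n_constant, " constant)\n\n", sep = "")
  print(x$sites, digits = 4)
  invisible(x)
}

#' Extract fitted harmonization coefficients
#'
#' @param object a fitted [tcombat()] model.
#' @param ... unused.
#' @return List with `alpha` (per-feature level), `beta` (covariate
#'   coefficients), `sigma` (pooled residual SD), `gamma_star` and
#'   `delta_star` (empirical-Bayes site effects, sites x features).
#' @export
coef.tcombat <- function(object, ...) {
  list(alpha = object$ls$alpha, beta = object$ls$beta,
       sigma = object$ls$sigma, gamma_star = object$eb$gamma_star,
       delta_star = object$eb$delta_star)
}

#' Harmonize new subjects with a fitted model
#'
#' `predict()` on a `tcombat` fit is the transfer operation: new subjects
#' from known sites are harmonized using only the saved parameters. See
#' [apply_transfer()].
#'
#' @param object a fitted [tcombat()] model.
#' @param newdata a [feature_dataset()] of new subjects (sites must be in
#'   the model's registry). Defaults to the training data.
#' @param ... unused.
#' @return A harmonized [feature_dataset()].
#' @export
predict.tcombat <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$harmonized)
  apply_transfer(object, newdata)
}

#' Residuals of the harmonization model
#'
#' Standardized residuals of the training fit: the z matrix with the
#' empirical-Bayes site effect removed and rescaled,
#' \eqn{(z_{ijv} - \gamma^*_{iv})/\delta^*_{iv}}; approximately zero-mean,
#' unit-variance noise when the model holds.
#'
#' @param object a fitted [tcombat()] model.
#' @param dataset the training [feature_dataset()] used for the fit (the
#'   model does not store raw training values). Required.
#' @param ... unused.
#' @return Matrix of standardized residuals.
#' @export
residuals.tcombat <- function(object, dataset, ...) {
  design <- build_design(dataset, object$covariate_schema)
  z <- standardize(dataset, design, object$ls)
  idx <- match(as.character(dataset$site), object$site_registry)
  keep <- !object$ls$constant_feature_mask
  r <- z
  r[, keep] <- (z[, keep, drop = FALSE] -
                  object$eb$gamma_star[idx, keep, drop = FALSE]) /
    object$eb$delta_star[idx, keep, drop = FALSE]
  r
}
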