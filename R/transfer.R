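#' Harmonize new subjects using only saved parameters
#'
#' The transfer step: each new subject from a known site is passed through
#' standardization and the location/scale transform using exclusively the
#' parameters fitted on the training cohort. Nothing is refit; previously
#' harmonized data are untouched by construction. A site label absent from
#' the model's registry is a hard error. Covariate values outside the
#' training experience (e.g. older subjects) are allowed — the covariate
#' model extrapolates linearly — with a warning.
#'
#' @param model a fitted [tcombat()] model (in memory or loaded via
#'   [load_combat_model()]).
#' @param new_data a [feature_dataset()] of new subjects. Feature ids must
#'   match the model's (any order; columns are aligned by id).
#' @return A harmonized [feature_dataset()] with the ordering and metadata
#'   of `new_data`.
#' @export
#' @examples
#' sim <- simulate_dataset(default_world("strong", n_features = 40,
#'                                       n_per_site = c(A = 20, B = 20)),
#'                         seed = 2)
#' fit <- tcombat(sim$dataset)
#' new <- subset_subjects(sim$dataset, 1:4)
#' harmonized <- apply_transfer(fit, new)
apply_transfer <- function(model, new_data) {
  stopifnot(inherits(model, "tcombat"), inherits(new_data, "feature_dataset"))
  unseen <- setdiff(unique(as.character(new_data$site)), model$site_registry)
  if (length(unseen))
    stop("unseen site label(s): ", paste(unseen, collapse = ", "),
         "; a transfer model is only valid for sites it was fitted on")
  perm <- match(model$feature_ids, new_data$feature_ids)
  if (anyNA(perm) || length(new_data$feature_ids) != length(model$feature_ids))
    stop("feature_ids of new data do not match the model (",
         length(model$feature_ids), " features expected)")
  aligned <- feature_dataset(new_data$values[, perm, drop = FALSE],
                             site = factor(as.character(new_data$site),
                                           levels = model$site_registry),
                             covariates = new_data$covariates,
                             feature_ids = model$feature_ids,
                             subject_ids = new_data$subject_ids)
  design <- build_design(aligned, model$covariate_schema)
  check_covariate_range(model, design)
  harm <- harmonize(aligned, design, model)
  # restore the caller's feature order
  back <- match(new_data$feature_ids, model$feature_ids)
  feature_dataset(harm$values[, back, drop = FALSE],
                  site = new_data$site, covariates = new_data$covariates,
                  feature_ids = new_data$feature_ids,
                  subject_ids = new_data$subject_ids)
}

# warn when numeric covariates extrapolate beyond the training range
check_covariate_range <- function(model, design) {
  rng <- model$covariate_range
  if (is.null(rng)) return(invisible())
  cov_cols <- attr(design, "cov_cols")
  X <- unclass(design)[, cov_cols, drop = FALSE]
  for (nm in intersect(colnames(X), rownames(rng))) {
    lo <- rng[nm, 1]; hi <- rng[nm, 2]
    if (any(X[, nm] < lo | X[, nm] > hi))
      warning(warningCondition(
        paste0("covariate '", nm, "' outside the training range [",
               signif(lo, 4), ", ", signif(hi, 4),
               "]; the linear covariate model extrapolates"),
        class = "tcombat_extrapolation_warning"))
  }
  invisible()
}

ARCHIVE_FORMAT_VERSION <- "1.0"

# doubles -> strings that round-trip exactly (17 significant digits)
fmt_exact <- function(x) sprintf("%.17g", as.numeric(x))

num_payload <- function(x) {
  if (is.matrix(x))
    list(dim = dim(x), dimnames = dimnames(x), data = fmt_exact(x))
  else
    list(names = names(x), data = fmt_exact(x))
}

payload_to_num <- function(p) {
  v <- as.numeric(p$data)
  if (anyNA(v)) stop("corrupt archive: non-numeric payload entry")
  if (!is.null(p$dim)) {
    v <- array(v, dim = unlist(p$dim))
    if (!is.null(p$dimnames)) dimnames(v) <- lapply(p$dimnames, as.character)
  } else if (!is.null(p$names) && length(p$names)) {
    names(v) <- as.character(unlist(p$names))
  }
  v
}

#' Save a fitted harmonization model to a portable archive
#'
#' Writes a single plain-text JSON file with two top-level members: a
#' human-readable `manifest` (format version, site registry in fitted
#' order, covariate schema, fit options, feature ids) and a `payload` of
#' named numeric arrays (`alpha`, `beta`, `sigma`,
#' `constant_feature_mask`, `gamma_hat`, `delta2_hat`, `gamma_star`,
#' `delta_star`, `gamma_bar`, `tau2`, `lambda`, `theta`, `n_per_site`,
#' `covariate_range`). Matrices are stored column-major with explicit
#' `dim`. Every double is serialized with 17 significant digits, so
#' `load_combat_model(save_combat_model(m, f))` reproduces all parameters
#' value-exactly. The archive never contains subject-level data, so it can
#' be shared across sites without disclosing measurements.
#'
#' @param model a fitted [tcombat()] model.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
save_combat_model <- function(model, path) {
  stopifnot(inherits(model, "tcombat"))
  manifest <- list(
    format_version = ARCHIVE_FORMAT_VERSION,
    model_class = "tcombat",
    site_registry = as.list(model$site_registry),
    covariate_schema = lapply(model$covariate_schema, function(sc)
      sc[!vapply(sc, is.null, TRUE)]),
    fit_options = model$fit_options,
    n_features = length(model$feature_ids),
    n_sites = length(model$site_registry),
    feature_ids = as.list(model$feature_ids))
  payload <- list(
    alpha = num_payload(model$ls$alpha),
    beta = num_payload(model$ls$beta),
    sigma = num_payload(model$ls$sigma),
    constant_feature_mask = num_payload(as.numeric(
      model$ls$constant_feature_mask)),
    gamma_hat = num_payload(model$site_effects$gamma_hat),
    delta2_hat = num_payload(model$site_effects$delta2_hat),
    gamma_star = num_payload(model$eb$gamma_star),
    delta_star = num_payload(model$eb$delta_star),
    gamma_bar = num_payload(model$priors$gamma_bar),
    tau2 = num_payload(model$priors$tau2),
    lambda = num_payload(model$priors$lambda),
    theta = num_payload(model$priors$theta),
    n_per_site = num_payload(as.numeric(model$n_per_site)))
  if (!is.null(model$covariate_range))
    payload$covariate_range <- num_payload(model$covariate_range)
  txt <- jsonlite::toJSON(list(manifest = manifest, payload = payload),
                          auto_unbox = TRUE, pretty = TRUE, null = "null",
                          na = "null")
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write model archive to '", path, "'")
  invisible(path)
}

#' Load a harmonization model archive
#'
#' Reads an archive written by [save_combat_model()] and reconstructs a
#' `tcombat` model ready for [apply_transfer()]. Corrupt files, unknown
#' format versions and manifest/payload shape mismatches are hard errors.
#'
#' @param path archive file path.
#' @return A `tcombat` model.
#' @export
load_combat_model <- function(path) {
  if (!file.exists(path)) stop("no such archive: ", path)
  arch <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("corrupt archive '", path, "': ",
                             conditionMessage(e)))
  if (is.null(arch$manifest) || is.null(arch$payload))
    stop("corrupt archive: missing manifest or payload")
  man <- arch$manifest
  if (!identical(man$format_version, ARCHIVE_FORMAT_VERSION))
    stop("unknown archive format version: ",
         if (is.null(man$format_version)) "<absent>" else man$format_version)
  pl <- lapply(arch$payload, payload_to_num)
  feature_ids <- as.character(unlist(man$feature_ids))
  sites <- as.character(unlist(man$site_registry))
  V <- length(feature_ids); S <- length(sites)
  if (man$n_features != V || man$n_sites != S)
    stop("corrupt archive: manifest counts disagree with feature/site lists")
  need <- c("alpha", "beta", "sigma", "constant_feature_mask", "gamma_hat",
            "delta2_hat", "gamma_star", "delta_star", "gamma_bar", "tau2",
            "lambda", "theta", "n_per_site")
  missing <- setdiff(need, names(pl))
  if (length(missing))
    stop("corrupt archive: missing payload array(s) ",
         paste(missing, collapse = ", "))
  if (length(pl$alpha) != V || !identical(dim(pl$gamma_star), c(S, V)) ||
      !identical(dim(pl$delta_star), c(S, V)))
    stop("corrupt archive: payload shapes do not match the manifest")
  schema <- structure(lapply(man$covariate_schema, function(sc) {
    out <- list(name = sc$name, type = sc$type)
    if (!is.null(sc$levels)) out$levels <- as.character(unlist(sc$levels))
    out
  }), class = "covariate_schema")
  degenerate <- is.na(pl$lambda)
  model <- structure(
    list(ls = structure(list(alpha = pl$alpha, beta = pl$beta,
                             sigma = pl$sigma,
                             residual_variance = pl$sigma^2,
                             site_coef = NULL,
                             constant_feature_mask =
                               as.logical(pl$constant_feature_mask),
                             feature_ids = feature_ids,
                             n_subjects = sum(pl$n_per_site)),
                        class = "ls_estimates"),
         site_effects = structure(list(gamma_hat = pl$gamma_hat,
                                       delta2_hat = pl$delta2_hat,
                                       n_per_site = as.integer(pl$n_per_site),
                                       sites = sites),
                                  class = "site_effects"),
         priors = structure(list(gamma_bar = pl$gamma_bar, tau2 = pl$tau2,
                                 lambda = pl$lambda, theta = pl$theta,
                                 degenerate = degenerate,
                                 finite_variance = !degenerate &
                                   pl$lambda > 2,
                                 sites = sites),
                            class = "combat_priors"),
         eb = structure(list(gamma_star = pl$gamma_star,
                             delta_star = pl$delta_star,
                             iterations = NA_integer_,
                             converged = rep(TRUE, S), sites = sites),
                        class = "eb_estimates"),
         site_registry = sites,
         covariate_schema = schema,
         feature_ids = feature_ids,
         n_per_site = stats::setNames(as.integer(pl$n_per_site), sites),
         fit_options = man$fit_options,
         covariate_range = pl$covariate_range),
    class = "tcombat")
  model
}
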