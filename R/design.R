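#' Describe how covariates enter the harmonization design
#'
#' A covariate schema records, for each biological covariate, its name and
#' coding so that the identical design columns can be rebuilt for new
#' subjects at transfer time. Continuous covariates enter uncentered;
#' two-level covariates are coded 0/1 with the stored level order (first
#' level = 0, second = 1).
#'
#' @param dataset a [feature_dataset()] whose covariate table supplies
#'   names and types, or `NULL` for a covariate-free schema.
#' @param covariates character vector selecting covariate columns; default
#'   all columns of `dataset$covariates`.
#' @return An object of class `covariate_schema`: list of per-covariate
#'   descriptors (`name`, `type` one of `"numeric"`/`"binary"`, and for
#'   binary the `levels` in 0/1 order).
#' @export
covariate_schema <- function(dataset = NULL, covariates = NULL) {
  if (is.null(dataset) || is.null(dataset$covariates))
    return(structure(list(), class = "covariate_schema"))
  tab <- dataset$covariates
  if (is.null(covariates)) covariates <- names(tab)
  missing <- setdiff(covariates, names(tab))
  if (length(missing))
    stop("unknown covariate name(s): ", paste(missing, collapse = ", "))
  schema <- lapply(covariates, function(nm) {
    x <- tab[[nm]]
    if (is.numeric(x)) {
      list(name = nm, type = "numeric")
    } else {
      lev <- sort(unique(as.character(x)))
      if (length(lev) != 2)
        stop("covariate '", nm, "' is non-numeric with ", length(lev),
             " levels; only two-level factors have a defined 0/1 coding")
      list(name = nm, type = "binary", levels = lev)
    }
  })
  structure(schema, class = "covariate_schema")
}

# numeric covariate block (n x p) for a dataset under a schema
encode_covariates <- function(dataset, schema) {
  if (!length(schema))
    return(matrix(0, nrow(dataset$values), 0))
  cols <- lapply(schema, function(sc) {
    x <- dataset$covariates[[sc$name]]
    if (is.null(x)) stop("covariate '", sc$name, "' absent from dataset")
    if (sc$type == "numeric") {
      if (!is.numeric(x)) stop("covariate '", sc$name, "' must be numeric")
      as.numeric(x)
    } else {
      x <- as.character(x)
      bad <- setdiff(unique(x), sc$levels)
      if (length(bad))
        stop("covariate '", sc$name, "' has level(s) ",
             paste(bad, collapse = ", "), " outside the schema coding {",
             paste(sc$levels, collapse = ", "), "}")
      as.numeric(x == sc$levels[2])
    }
  })
  out <- do.call(cbind, cols)
  colnames(out) <- vapply(schema, `[[`, "", "name")
  out
}

#' Build the harmonization design matrix
#'
#' Realizes the linear model design: one indicator column per site followed
#' by the covariate block. The site indicators jointly span the intercept,
#' so the matrix is full rank without a separate constant column; the
#' identifiability constraint (site effects sum to zero weighted by site
#' proportions n_i/N, making the overall level the grand mean) is imposed
#' downstream when the least-squares coefficients are decomposed, and is
#' recorded in the `encoding` attribute.
#'
#' @param dataset a [feature_dataset()].
#' @param schema a [covariate_schema()]; defaults to a schema built from
#'   all covariates of `dataset`.
#' @return An object of class `combat_design`: the numeric design matrix
#'   with attributes `site_cols`, `cov_cols`, `n_per_site`, `sites`,
#'   `schema` and `encoding`.
#' @export
build_design <- function(dataset, schema = covariate_schema(dataset)) {
  stopifnot(inherits(dataset, "feature_dataset"))
  site <- dataset$site
  S <- nlevels(site)
  n <- length(site)
  ind <- matrix(0, n, S)
  ind[cbind(seq_len(n), as.integer(site))] <- 1
  colnames(ind) <- paste0("site_", levels(site))
  cov_block <- encode_covariates(dataset, schema)
  X <- cbind(ind, cov_block)
  structure(X,
            class = c("combat_design", "matrix", "array"),
            site_cols = seq_len(S),
            cov_cols = if (ncol(cov_block)) S + seq_len(ncol(cov_block))
                       else integer(),
            n_per_site = tabulate(site, nbins = S),
            sites = levels(site),
            schema = schema,
            encoding = paste("one indicator per site (site block spans the",
                             "intercept); site effects constrained to zero",
                             "weighted mean with weights n_i/N; numeric",
                             "covariates uncentered; binary covariates 0/1"))
}

# observed [min, max] of each numeric covariate column, for the
# extrapolation warning at transfer time
covariate_range <- function(design) {
  cov_cols <- attr(design, "cov_cols")
  schema <- attr(design, "schema")
  numeric_names <- vapply(Filter(function(sc) sc$type == "numeric", schema),
                          `[[`, "", "name")
  if (!length(numeric_names)) return(NULL)
  X <- unclass(design)[, cov_cols, drop = FALSE]
  out <- t(vapply(numeric_names,
                  function(nm) range(X[, nm]), numeric(2)))
  colnames(out) <- c("min", "max")
  out
}
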